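# Shared fixtures, built once per test session. Everything is generated in
# code; sizes are desk-scale so the whole suite stays fast.

.fixture_env <- new.env(parent = emptyenv())

# Small end-to-end dataset: 10 drugs, 6 cell lines, 200 records, short
# fingerprints. Cached because featurization costs a couple of seconds.
tiny_dataset <- function() {
  if (is.null(.fixture_env$tiny)) {
    cfg <- synthetic_config(n_drugs = 10L, n_cells = 6L, n_records = 200L,
                            g_expr = 16L, g_mut = 12L, sigma_label = 5,
                            seed = 42L)
    .fixture_env$tiny <- generate_synergy_dataset(cfg, n_bits = 128L,
                                                  dims = 128L)
  }
  .fixture_env$tiny
}

# Small model/training configurations used by the unit tests.
tiny_model_config <- function(...) {
  model_config(d = 8L, d_hat = 16L, d_tilde = 8L, head_hidden = 4L,
               channels = c(2L, 3L, 4L), ...)
}

tiny_train_config <- function(epochs = 3L, ...) {
  train_config(lr = 1e-3, batch_size = 64L, epochs = epochs, val_frac = 0,
               patience = Inf, ...)
}

# Direct (loop-based) 1-D convolution oracle: stride 1, symmetric zero
# padding, independent of the package's im2col path.
oracle_conv1d <- function(x, w, b) {
  # x: L x c_in matrix; w: h x c_in x c_out; b: length c_out
  L <- nrow(x); h <- dim(w)[1]; cin <- dim(w)[2]; cout <- dim(w)[3]
  pad <- (h - 1) %/% 2
  out <- matrix(0, L, cout)
  for (l in seq_len(L)) {
    for (co in seq_len(cout)) {
      acc <- b[co]
      for (t in seq_len(h)) {
        ls <- l + t - 1 - pad
        if (ls >= 1 && ls <= L) {
          for (ci in seq_len(cin)) acc <- acc + x[ls, ci] * w[t, ci, co]
        }
      }
      out[l, co] <- acc
    }
  }
  out
}

oracle_gelu <- function(x) x * pnorm(x)
oracle_swish <- function(x) x * plogis(x)

oracle_layernorm <- function(x, gamma, beta, eps = 1e-5) {
  # row-wise over columns
  t(apply(x, 1, function(r) {
    (r - mean(r)) / sqrt(mean((r - mean(r))^2) + eps) * gamma + beta
  }))
}
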