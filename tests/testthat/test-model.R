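test_that("conv encoder matches a by-hand convolution + projection oracle", {
  # tiny case: L = 6, kernel 3, channels (1, 1, 1), D = 2, hand-set weights
  set.seed(21)
  cfg <- model_config(channels = c(1L, 1L, 1L), kernel = 3L, d = 2L,
                      d_hat = 4L, d_tilde = 2L, head_hidden = 1L)
  x <- c(0.5, -1, 2, 0, 1, -0.5)
  w <- list(W1 = array(c(0.1, 0.2, -0.1), c(3, 1, 1)), b1 = 0.05,
            W2 = array(c(-0.3, 0.5, 0.2), c(3, 1, 1)), b2 = -0.1,
            W3 = array(c(0.4, -0.2, 0.1), c(3, 1, 1)), b3 = 0.2,
            Wp = matrix(seq(-0.5, 0.6, length.out = 12), 6, 2), bp = c(1, -1))
  got <- conv_encode(x, w, cfg)
  a1 <- oracle_gelu(oracle_conv1d(matrix(x), w$W1, w$b1))
  a2 <- oracle_gelu(oracle_conv1d(a1, w$W2, w$b2))
  a3 <- oracle_gelu(oracle_conv1d(a2, w$W3, w$b3))
  want <- drop(as.numeric(a3) %*% w$Wp + w$bp)
  expect_equal(got, want, tolerance = 1e-12)
  expect_error(conv_encode(c(1, 2), w, cfg), class = "shape_error")
})

test_that("conv encoder keeps length at every layer and 32 channels in layer 3", {
  cfg <- model_config(d = 8L)
  mdl <- init_model(cfg, list(hashtt = 40L, map4 = 40L, maccs = 166L,
                              expr = 20L, mut = 20L), seed = 2)
  enc <- mdl$params$hashtt$enc_drug
  x <- array(rnorm(40), c(1L, 40L, 1L))
  l1 <- synfuse:::.conv1d_fwd(x, enc$W1, enc$b1)
  l2 <- synfuse:::.conv1d_fwd(l1$out, enc$W2, enc$b2)
  l3 <- synfuse:::.conv1d_fwd(l2$out, enc$W3, enc$b3)
  expect_identical(dim(l1$out), c(1L, 40L, 8L))
  expect_identical(dim(l2$out), c(1L, 40L, 16L))
  expect_identical(dim(l3$out), c(1L, 40L, 32L))
  # zero input with zero biases: projection returns its bias exactly
  w0 <- enc
  w0$b1 <- w0$b1 * 0; w0$b2 <- w0$b2 * 0; w0$b3 <- w0$b3 * 0
  expect_equal(conv_encode(rep(0, 40), w0, cfg), unname(w0$bp),
               tolerance = 1e-14)
})

test_that("stack_features builds the 4 x D view tensor in fixed order", {
  z <- lapply(1:4, function(i) rnorm(3))
  h <- stack_features(z[[1]], z[[2]], z[[3]], z[[4]])
  expect_identical(dim(h), c(4L, 3L))
  expect_identical(rownames(h), c("drug_i", "drug_j", "expr", "mut"))
  expect_equal(unname(h[1, ]), z[[1]])
  for (i in 1:4) expect_equal(unname(h[i, ]), z[[i]]) # round-trip
  expect_error(stack_features(rnorm(3), rnorm(4), rnorm(3), rnorm(3)),
               class = "shape_error")
})

test_that("permute-MLP block with zeroed branch weights is the exact identity", {
  for (d in c(3L, 8L)) {
    h <- matrix(rnorm(4 * d), 4, d)
    out <- permute_mlp_block(h, zero_block_weights(4L, d))
    expect_identical(unname(out), unname(h)) # bit-for-bit
  }
  # shape conservation for arbitrary (N, D) with random weights
  set.seed(31)
  for (nd in list(c(2L, 5L), c(4L, 8L), c(6L, 3L))) {
    n <- nd[1]; d <- nd[2]
    blk <- synfuse:::.with_seed(9, synfuse:::.init_block(
      model_config(d = d, d_hat = 4L, d_tilde = 4L, head_hidden = 2L)))
    blk$WN1 <- synfuse:::.init_mat(n, d)
    blk$WN2 <- synfuse:::.init_mat(d, n)
    blk$bN2 <- synfuse:::.init_vec(n, d)
    blk$gN <- rep(1, n); blk$betN <- rep(0, n)
    h <- matrix(rnorm(n * d), n, d)
    expect_identical(dim(permute_mlp_block(h, blk)), c(n, d))
  }
})

test_that("permute-MLP block matches a by-hand evaluation of its equations", {
  # 2 x 3 tensor, small hand-set weights, layer norm at default affine
  h <- matrix(c(1, -1, 0.5, 2, -0.5, 0.25), 2, 3)
  d <- 3L; n <- 2L
  blk <- list(WD1 = matrix(c(0.1, -0.2, 0.3, 0, 0.2, -0.1, 0.4, 0.1, 0), d, d),
              bD1 = c(0.1, 0, -0.1),
              WD2 = matrix(c(0.2, 0.1, 0, -0.3, 0.1, 0.2, 0, 0.5, -0.2), d, d),
              bD2 = c(0, 0.2, -0.2),
              gD = c(1, 1.5, 0.5), betD = c(0.1, -0.1, 0),
              WN1 = matrix(c(0.3, -0.1, 0.2, 0.4, 0, 0.1), n, d),
              bN1 = c(0, 0.1, -0.1),
              WN2 = matrix(c(0.1, 0.2, -0.2, 0.3, 0, -0.1), d, n),
              bN2 = c(0.05, -0.05),
              gN = c(1, 2), betN = c(0, 0.1))
  got <- permute_mlp_block(h, blk, model_config())
  # independent evaluation with explicit matrix algebra
  ln <- oracle_layernorm
  h1 <- h + ln(oracle_swish(sweep(h %*% blk$WD1, 2, blk$bD1, "+")) %*% blk$WD2 +
                 matrix(blk$bD2, n, d, byrow = TRUE), blk$gD, blk$betD)
  ht <- t(h1)
  h2 <- ht + ln(oracle_swish(sweep(ht %*% blk$WN1, 2, blk$bN1, "+")) %*% blk$WN2 +
                  matrix(blk$bN2, d, n, byrow = TRUE), blk$gN, blk$betN)
  want <- t(h2)
  expect_equal(unname(got), unname(want), tolerance = 1e-12)
})

test_that("fuse_and_project flattens, projects, activates and projects", {
  set.seed(5)
  h <- matrix(rnorm(8), 4, 2)
  w <- list(Wf1 = matrix(rnorm(8 * 3), 8, 3), bf1 = rnorm(3),
            Wf2 = matrix(rnorm(3 * 2), 3, 2), bf2 = rnorm(2))
  got <- fuse_and_project(h, w)
  want <- drop(oracle_gelu(as.numeric(h) %*% w$Wf1 + rep(w$bf1, each = 1)) %*%
                 w$Wf2 + w$bf2)
  expect_equal(got, want, tolerance = 1e-12)
  expect_length(got, 2L)
  w0 <- lapply(w, function(x) x * 0)
  expect_equal(fuse_and_project(matrix(0, 4, 2), w0), c(0, 0))
})

test_that("fsn_forward emits a finite synergy feature and score", {
  cfg <- tiny_model_config(fingerprints = "maccs")
  mdl <- init_model(cfg, list(maccs = 166L, expr = 10L, mut = 10L), seed = 3)
  fp1 <- rbinom(166, 1, 0.3); fp2 <- rbinom(166, 1, 0.3)
  ex <- rnorm(10); mu <- rbinom(10, 1, 0.1)
  out <- fsn_forward(fp1, fp2, ex, mu, mdl$params$maccs, cfg)
  expect_length(out$feature, cfg$d_tilde)
  expect_true(is.finite(out$score))
  # swapping the drugs changes the row order; the score may change (no
  # symmetry is enforced) but the computation stays valid
  out2 <- fsn_forward(fp2, fp1, ex, mu, mdl$params$maccs, cfg)
  expect_true(is.finite(out2$score))
})

test_that("the prediction is the exact mean of the subnetwork heads", {
  ds <- tiny_dataset()
  cfg <- tiny_model_config()
  mdl <- init_model(cfg, synfuse:::.feature_lengths(ds$features, cfg), seed = 4)
  data <- synfuse:::.build_data(ds$records, ds$features, cfg)
  out <- model_forward(mdl, data)
  expect_identical(out$y_hat,
                   (out$y_kind[, 1] + out$y_kind[, 2] + out$y_kind[, 3]) / 3)
  expect_identical(colnames(out$y_kind), c("hashtt", "map4", "maccs"))
  # explicit arithmetic examples
  expect_equal(mean(c(3, 6, 9)), 6)
  expect_true(all(is.finite(out$y_hat)))
})

test_that("mse_loss is the mean squared residual", {
  expect_equal(mse_loss(c(1, 2), c(1, 2)), 0)
  expect_equal(mse_loss(0, 2), 4)
  set.seed(6)
  a <- rnorm(7); b <- rnorm(7)
  acc <- 0
  for (i in 1:7) acc <- acc + (a[i] - b[i])^2
  expect_equal(mse_loss(a, b), acc / 7, tolerance = 1e-14)
  expect_error(mse_loss(1:3, 1:2), class = "shape_error")
})

test_that("model gradients agree with finite differences on a tiny network", {
  set.seed(42)
  cfg <- model_config(fingerprints = c("hashtt", "maccs"),
                      channels = c(2L, 3L, 4L), kernel = 3L, d = 4L,
                      d_hat = 6L, d_tilde = 4L, head_hidden = 2L)
  mdl <- init_model(cfg, list(hashtt = 8L, maccs = 8L, expr = 6L, mut = 5L),
                    seed = 7)
  data <- list(fp = list(hashtt = matrix(rbinom(24, 1, 0.5), 3),
                         maccs = matrix(rbinom(24, 1, 0.5), 3)),
               ia = c(1L, 2L, 3L, 1L), ib = c(2L, 3L, 1L, 3L),
               ic = c(1L, 2L, 1L, 2L),
               expr = matrix(rnorm(12), 2), mut = matrix(rnorm(10), 2))
  y <- rnorm(4)
  loss_fn <- function(params) {
    f <- synfuse:::.model_fwd(params, data, cfg)
    mean((f$y_hat - y)^2)
  }
  fwd <- synfuse:::.model_fwd(mdl$params, data, cfg)
  dy <- 2 * (fwd$y_hat - y) / 4
  gr <- synfuse:::.align_grads(
    mdl$params, synfuse:::.model_bwd(dy, fwd, mdl$params, data, cfg))
  fl_p <- synfuse:::.tree_flatten(mdl$params)
  fl_g <- synfuse:::.tree_flatten(gr)
  expect_identical(names(fl_p), names(fl_g))
  eps <- 1e-5
  worst <- 0
  picks <- synfuse:::.with_seed(123, sample(names(fl_p), 50))
  for (nm in picks) {
    leaf <- fl_p[[nm]]
    i <- synfuse:::.with_seed(nchar(nm) + 7L, sample(length(leaf), 1))
    bump <- function(delta) {
      l2 <- leaf
      l2[i] <- l2[i] + delta
      loss_fn(synfuse:::.tree_unflatten(
        mdl$params, modifyList(fl_p, stats::setNames(list(l2), nm))))
    }
    num <- (bump(eps) - bump(-eps)) / (2 * eps)
    ana <- fl_g[[nm]][i]
    worst <- max(worst, abs(num - ana) / max(1e-8, abs(num) + abs(ana)))
  }
  expect_lt(worst, 1e-4)
})
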