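# The synergy network: per fingerprint kind, a subnetwork of Conv1D encoders
# (shared weights for the two drugs; separate encoders for expression and
# mutation) whose outputs are stacked into a 4 x D view tensor, fused by two
# permutable MLP blocks (a residual MLP along the feature axis, a transpose,
# a residual MLP along the view axis, a transpose back), projected to a
# synergy feature, and scored by a two-layer GELU head. The three per-kind
# scores are averaged into the prediction.

#' Model configuration
#'
#' Collects every architectural hyperparameter of the synergy network. The
#' defaults define the reference architecture used throughout the package:
#' three convolutional layers of 8/16/32 channels with window 3, feature
#' dimension `d = 64`, fusion hidden width `d_hat = 256`, synergy-feature
#' width `d_tilde = 64`, and a prediction head of width `d_tilde / 2`; sizes
#' chosen so the full study runs comfortably on a single CPU.
#'
#' @param fingerprints Character subset of `c("hashtt", "map4", "maccs")`;
#'   one subnetwork is built per kind and their scores averaged.
#' @param channels Integer triple of convolution channel widths.
#' @param kernel Odd convolution window width.
#' @param d Feature dimension D shared by all encoders.
#' @param d_hat Hidden width of the fusion projection.
#' @param d_tilde Synergy feature dimension.
#' @param head_hidden Hidden width of the prediction head.
#' @param n_blocks Number of permutable MLP blocks (the architecture uses 2).
#' @param use_permute_mlp If `FALSE`, the fusion blocks are replaced by the
#'   identity (the stacked views feed the projection directly).
#' @param encoder `"conv"` for the Conv1D encoders or `"mlp"` for the
#'   feedforward variant in which every encoder is an affine + GELU stack of
#'   matched output dimension.
#' @param ln_eps Layer-norm epsilon.
#' @return A list of class `synergy_model_config`.
#' @export
model_config <- function(fingerprints = c("hashtt", "map4", "maccs"),
                         channels = c(8L, 16L, 32L), kernel = 3L,
                         d = 64L, d_hat = 256L, d_tilde = 64L,
                         head_hidden = d_tilde %/% 2L,
                         n_blocks = 2L, use_permute_mlp = TRUE,
                         encoder = c("conv", "mlp"), ln_eps = 1e-5) {
  encoder <- match.arg(encoder)
  fingerprints <- match.arg(fingerprints, c("hashtt", "map4", "maccs"),
                            several.ok = TRUE)
  if (length(channels) != 3L) stop_domain("channels must be an integer triple")
  if (kernel %% 2L != 1L) stop_domain("kernel width must be odd")
  structure(list(fingerprints = fingerprints,
                 channels = as.integer(channels), kernel = as.integer(kernel),
                 d = as.integer(d), d_hat = as.integer(d_hat),
                 d_tilde = as.integer(d_tilde),
                 head_hidden = as.integer(head_hidden),
                 n_views = 4L, n_blocks = as.integer(n_blocks),
                 use_permute_mlp = isTRUE(use_permute_mlp),
                 encoder = encoder, ln_eps = ln_eps),
            class = "synergy_model_config")
}

# ---- parameter initialization ---------------------------------------------

.init_encoder <- function(cfg, L) {
  if (cfg$encoder == "conv") {
    ch <- cfg$channels
    list(W1 = .init_conv(cfg$kernel, 1L, ch[1]), b1 = .init_vec(ch[1], cfg$kernel),
         W2 = .init_conv(cfg$kernel, ch[1], ch[2]), b2 = .init_vec(ch[2], cfg$kernel * ch[1]),
         W3 = .init_conv(cfg$kernel, ch[2], ch[3]), b3 = .init_vec(ch[3], cfg$kernel * ch[2]),
         Wp = .init_mat(L * ch[3], cfg$d), bp = .init_vec(cfg$d, L * ch[3]))
  } else {
    list(W1 = .init_mat(L, cfg$d), b1 = .init_vec(cfg$d, L),
         W2 = .init_mat(cfg$d, cfg$d), b2 = .init_vec(cfg$d, cfg$d))
  }
}

.init_block <- function(cfg) {
  d <- cfg$d; n <- cfg$n_views
  list(WD1 = .init_mat(d, d), bD1 = .init_vec(d, d),
       WD2 = .init_mat(d, d), bD2 = .init_vec(d, d),
       gD = rep(1, d), betD = rep(0, d),
       WN1 = .init_mat(n, d), bN1 = .init_vec(d, n),
       WN2 = .init_mat(d, n), bN2 = .init_vec(n, d),
       gN = rep(1, n), betN = rep(0, n))
}

.init_fsn <- function(cfg, L_fp, L_expr, L_mut) {
  nd <- cfg$n_views * cfg$d
  fsn <- list(enc_drug = .init_encoder(cfg, L_fp),
              enc_expr = .init_encoder(cfg, L_expr),
              enc_mut = .init_encoder(cfg, L_mut))
  blocks <- list()
  for (b in seq_len(cfg$n_blocks)) blocks[[paste0("b", b)]] <- .init_block(cfg)
  fsn$blocks <- blocks
  fsn$Wf1 <- .init_mat(nd, cfg$d_hat); fsn$bf1 <- .init_vec(cfg$d_hat, nd)
  fsn$Wf2 <- .init_mat(cfg$d_hat, cfg$d_tilde)
  fsn$bf2 <- .init_vec(cfg$d_tilde, cfg$d_hat)
  fsn$Wh1 <- .init_mat(cfg$d_tilde, cfg$head_hidden)
  fsn$bh1 <- .init_vec(cfg$head_hidden, cfg$d_tilde)
  fsn$Wh2 <- .init_mat(cfg$head_hidden, 1L)
  fsn$bh2 <- .init_vec(1L, cfg$head_hidden)
  fsn
}

#' Initialize model parameters
#'
#' Draws fan-in uniform initial weights for every subnetwork under a
#' recorded seed. `input_lengths` gives the input sequence length of each
#' encoder; fingerprint entries must cover `config$fingerprints` and the
#' `expr` / `mut` entries the cell-line profile lengths.
#'
#' @param config A [model_config()].
#' @param input_lengths Named list/vector, e.g.
#'   `list(hashtt = 512, map4 = 512, maccs = 166, expr = 128, mut = 128)`.
#' @param seed Integer seed.
#' @return A list of class `synergy_model` with elements `config`,
#'   `input_lengths`, `seed` and `params`.
#' @export
init_model <- function(config, input_lengths, seed = 1L) {
  stopifnot(inherits(config, "synergy_model_config"))
  need <- c(config$fingerprints, "expr", "mut")
  if (!all(need %in% names(input_lengths))) {
    stop_domain(paste("input_lengths must name:", paste(need, collapse = ", ")))
  }
  params <- .with_seed(seed, {
    out <- list()
    for (k in config$fingerprints) {
      out[[k]] <- .init_fsn(config, as.integer(input_lengths[[k]]),
                            as.integer(input_lengths[["expr"]]),
                            as.integer(input_lengths[["mut"]]))
    }
    out
  })
  structure(list(config = config,
                 input_lengths = lapply(input_lengths, as.integer),
                 seed = as.integer(seed), params = params),
            class = "synergy_model")
}

#' @export
print.synergy_model <- function(x, ...) {
  np <- sum(vapply(.tree_flatten(x$params), length, numeric(1)))
  cat(sprintf("<synergy model> %s encoder | fingerprints: %s | D=%d | %s | %s parameters\n",
              x$config$encoder, paste(x$config$fingerprints, collapse = "+"),
              x$config$d,
              if (x$config$use_permute_mlp)
                sprintf("%d permute-MLP blocks", x$config$n_blocks)
              else "no permute-MLP",
              format(np, big.mark = ",")))
  invisible(x)
}

# ---- encoder forward/backward (batched) ------------------------------------

.encoder_fwd <- function(x, enc, cfg) {
  # x: matrix (n, L)
  if (cfg$encoder == "mlp") {
    l1 <- .linear_fwd(x, enc$W1, enc$b1)
    a1 <- .gelu_fwd(l1$out)
    l2 <- .linear_fwd(a1$out, enc$W2, enc$b2)
    return(list(out = l2$out, cache = list(l1 = l1$cache, a1 = a1$cache,
                                           l2 = l2$cache)))
  }
  n <- nrow(x); L <- ncol(x)
  a0 <- array(x, c(n, L, 1L))
  c1 <- .conv1d_fwd(a0, enc$W1, enc$b1); g1 <- .gelu_fwd(c1$out)
  c2 <- .conv1d_fwd(g1$out, enc$W2, enc$b2); g2 <- .gelu_fwd(c2$out)
  c3 <- .conv1d_fwd(g2$out, enc$W3, enc$b3); g3 <- .gelu_fwd(c3$out)
  flat <- g3$out
  dim(flat) <- c(n, L * cfg$channels[3])
  pr <- .linear_fwd(flat, enc$Wp, enc$bp)
  list(out = pr$out,
       cache = list(c1 = c1$cache, g1 = g1$cache, c2 = c2$cache, g2 = g2$cache,
                    c3 = c3$cache, g3 = g3$cache, pr = pr$cache,
                    n = n, L = L))
}

.encoder_bwd <- function(dout, cache, enc, cfg) {
  if (cfg$encoder == "mlp") {
    l2 <- .linear_bwd(dout, cache$l2, enc$W2)
    da1 <- .gelu_bwd(l2$dx, cache$a1)
    l1 <- .linear_bwd(da1, cache$l1, enc$W1)
    return(list(grads = list(W1 = l1$dw, b1 = l1$db, W2 = l2$dw, b2 = l2$db)))
  }
  n <- cache$n; L <- cache$L
  pr <- .linear_bwd(dout, cache$pr, enc$Wp)
  dflat <- pr$dx
  dim(dflat) <- c(n, L, cfg$channels[3])
  dg3 <- .gelu_bwd(dflat, cache$g3)
  b3 <- .conv1d_bwd(dg3, cache$c3, enc$W3)
  dg2 <- .gelu_bwd(b3$dx, cache$g2)
  b2 <- .conv1d_bwd(dg2, cache$c2, enc$W2)
  dg1 <- .gelu_bwd(b2$dx, cache$g1)
  b1 <- .conv1d_bwd(dg1, cache$c1, enc$W1)
  list(grads = list(W1 = b1$dw, b1 = b1$db, W2 = b2$dw, b2 = b2$db,
                    W3 = b3$dw, b3 = b3$db, Wp = pr$dw, bp = pr$db))
}

# ---- permutable MLP block (batched) ----------------------------------------
# h: array (B, N, D). Feature-axis unit, transpose, view-axis unit,
# transpose back. Layer norm runs over the axis being mixed.

.block_fwd <- function(h, blk, cfg) {
  dm <- dim(h); B <- dm[1]; N <- dm[2]; D <- dm[3]
  xD <- h
  dim(xD) <- c(B * N, D)
  lD1 <- .linear_fwd(xD, blk$WD1, blk$bD1)
  sD <- .swish_fwd(lD1$out)
  lD2 <- .linear_fwd(sD$out, blk$WD2, blk$bD2)
  lnD <- .layernorm_fwd(lD2$out, blk$gD, blk$betD, cfg$ln_eps)
  h1 <- xD + lnD$out
  dim(h1) <- c(B, N, D)
  xN <- cpp_permute_nd(h1, B, N, D) # (B, D, N)
  dim(xN) <- c(B * D, N)
  lN1 <- .linear_fwd(xN, blk$WN1, blk$bN1)
  sN <- .swish_fwd(lN1$out)
  lN2 <- .linear_fwd(sN$out, blk$WN2, blk$bN2)
  lnN <- .layernorm_fwd(lN2$out, blk$gN, blk$betN, cfg$ln_eps)
  h2 <- xN + lnN$out
  dim(h2) <- c(B, D, N)
  out <- cpp_permute_nd(h2, B, D, N) # back to (B, N, D)
  list(out = out,
       cache = list(B = B, N = N, D = D, lD1 = lD1$cache, sD = sD$cache,
                    lD2 = lD2$cache, lnD = lnD$cache, lN1 = lN1$cache,
                    sN = sN$cache, lN2 = lN2$cache, lnN = lnN$cache))
}

.block_bwd <- function(dout, cache, blk) {
  B <- cache$B; N <- cache$N; D <- cache$D
  dh2 <- cpp_permute_nd(dout, B, N, D) # (B, D, N)
  dim(dh2) <- c(B * D, N)
  lnN <- .layernorm_bwd(dh2, cache$lnN)
  lN2 <- .linear_bwd(lnN$dx, cache$lN2, blk$WN2)
  dsN <- .swish_bwd(lN2$dx, cache$sN)
  lN1 <- .linear_bwd(dsN, cache$lN1, blk$WN1)
  dxN <- dh2 + lN1$dx # residual
  dim(dxN) <- c(B, D, N)
  dh1 <- cpp_permute_nd(dxN, B, D, N) # (B, N, D)
  dim(dh1) <- c(B * N, D)
  lnD <- .layernorm_bwd(dh1, cache$lnD)
  lD2 <- .linear_bwd(lnD$dx, cache$lD2, blk$WD2)
  dsD <- .swish_bwd(lD2$dx, cache$sD)
  lD1 <- .linear_bwd(dsD, cache$lD1, blk$WD1)
  dx <- dh1 + lD1$dx
  dim(dx) <- c(B, N, D)
  list(dx = dx,
       grads = list(WD1 = lD1$dw, bD1 = lD1$db, WD2 = lD2$dw, bD2 = lD2$db,
                    gD = lnD$dgamma, betD = lnD$dbeta,
                    WN1 = lN1$dw, bN1 = lN1$db, WN2 = lN2$dw, bN2 = lN2$db,
                    gN = lnN$dgamma, betN = lnN$dbeta))
}

# ---- public single-sample operations ---------------------------------------

#' Encode one input sequence with a convolutional encoder
#'
#' Applies the three-layer Conv1D encoder (stride 1, symmetric zero padding,
#' GELU after each layer, so every layer preserves the sequence length),
#' flattens the final L x k' feature map and projects it to the feature
#' dimension D.
#'
#' @param seq Numeric vector of length L (a fingerprint or profile).
#' @param weights Encoder weight list with elements `W1, b1, W2, b2, W3, b3,
#'   Wp, bp` (see [init_model()]; `W*` are `kernel x c_in x c_out` arrays,
#'   `Wp` is `(L * c_out) x D`).
#' @param config A [model_config()]; only `channels`, `kernel` and `encoder`
#'   are consulted.
#' @return Numeric vector of length D.
#' @export
conv_encode <- function(seq, weights, config = model_config()) {
  seq <- as.numeric(seq)
  if (config$encoder == "conv" && length(seq) < config$kernel) {
    stop_shape("input length must be at least the kernel width")
  }
  drop(.encoder_fwd(matrix(seq, 1L), weights, config)$out)
}

#' Stack the four view features into a fusion tensor
#'
#' Rows are fixed as (drug i, drug j, expression, mutation), giving the
#' 4 x D view tensor consumed by the permutable MLP blocks.
#'
#' @param z_di,z_dj,z_e,z_m Numeric vectors of equal length D.
#' @return A 4 x D matrix with row names `drug_i`, `drug_j`, `expr`, `mut`.
#' @export
stack_features <- function(z_di, z_dj, z_e, z_m) {
  lens <- c(length(z_di), length(z_dj), length(z_e), length(z_m))
  if (length(unique(lens)) != 1L) {
    stop_shape("all four feature vectors must have equal length")
  }
  rbind(drug_i = z_di, drug_j = z_dj, expr = z_e, mut = z_m)
}

#' Apply one permutable MLP block to a view tensor
#'
#' Computes the residual feature-axis unit
#' `H + LN(Swish(H W1_D) W2_D)`, transposes to D x N, applies the residual
#' view-axis unit `Ht + LN(Swish(Ht W1_N) W2_N)`, and transposes back, so the
#' output has the shape of the input. With all branch weights and biases at
#' zero the block is the exact identity.
#'
#' @param h Numeric N x D matrix.
#' @param weights Block weight list (`WD1, bD1, WD2, bD2, gD, betD, WN1,
#'   bN1, WN2, bN2, gN, betN`).
#' @param config A [model_config()] (for the layer-norm epsilon).
#' @return N x D matrix.
#' @export
permute_mlp_block <- function(h, weights, config = model_config()) {
  h <- as.matrix(h)
  a <- array(h, c(1L, nrow(h), ncol(h)))
  out <- .block_fwd(a, weights, config)$out
  matrix(out, nrow(h), ncol(h), dimnames = dimnames(h))
}

#' Zero-initialized permutable MLP block weights
#'
#' Convenience constructor for the identity configuration of a block: all
#' MLP weights and biases zero, layer-norm affine at its default. Useful for
#' tests and for the fusion-free model variant.
#'
#' @param n_views,d Block dimensions.
#' @return Block weight list accepted by [permute_mlp_block()].
#' @export
zero_block_weights <- function(n_views = 4L, d) {
  list(WD1 = matrix(0, d, d), bD1 = rep(0, d),
       WD2 = matrix(0, d, d), bD2 = rep(0, d),
       gD = rep(1, d), betD = rep(0, d),
       WN1 = matrix(0, n_views, d), bN1 = rep(0, d),
       WN2 = matrix(0, d, n_views), bN2 = rep(0, n_views),
       gN = rep(1, n_views), betN = rep(0, n_views))
}

#' Fuse a view tensor into the synergy feature
#'
#' Flattens the N x D tensor, projects to the hidden width, applies GELU and
#' projects to the synergy-feature dimension.
#'
#' @param h N x D matrix (output of the last fusion block).
#' @param weights List with `Wf1, bf1, Wf2, bf2`.
#' @return Numeric vector of length `ncol(weights$Wf2)`.
#' @export
fuse_and_project <- function(h, weights) {
  x <- matrix(as.numeric(h), 1L) # column-major flatten of N x D
  l1 <- .linear_fwd(x, weights$Wf1, weights$bf1)
  g <- .gelu_fwd(l1$out)
  l2 <- .linear_fwd(g$out, weights$Wf2, weights$bf2)
  drop(l2$out)
}

#' Mean squared error
#'
#' @param y_true,y_pred Equal-length numeric vectors.
#' @return `mean((y_true - y_pred)^2)`.
#' @export
mse_loss <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) {
    stop_shape("y_true and y_pred must have equal length")
  }
  if (length(y_true) == 0L) stop_shape("need at least one observation")
  mean((y_true - y_pred)^2)
}

# ---- full forward/backward over a batch ------------------------------------
# data: list with elements
#   fp[[kind]] : matrix (unique drugs x L_kind), rownames drug ids
#   ia, ib     : integer indices of drug A / drug B into fp rows
#   expr, mut  : matrices (unique cells x g), rownames cell ids
#   ic         : integer indices of each record's cell line
# Encoders run once per unique drug / cell line and results are gathered per
# record; gradients are scattered back with rowsum().

.model_fwd <- function(params, data, cfg) {
  kinds <- cfg$fingerprints
  B <- length(data$ia)
  per <- list()
  y_kind <- matrix(0, B, length(kinds), dimnames = list(NULL, kinds))
  for (k in kinds) {
    fsn <- params[[k]]
    ed <- .encoder_fwd(data$fp[[k]], fsn$enc_drug, cfg)
    ee <- .encoder_fwd(data$expr, fsn$enc_expr, cfg)
    em <- .encoder_fwd(data$mut, fsn$enc_mut, cfg)
    D <- ncol(ed$out)
    h <- array(0, c(B, 4L, D))
    h[, 1L, ] <- ed$out[data$ia, , drop = FALSE]
    h[, 2L, ] <- ed$out[data$ib, , drop = FALSE]
    h[, 3L, ] <- ee$out[data$ic, , drop = FALSE]
    h[, 4L, ] <- em$out[data$ic, , drop = FALSE]
    bl <- list()
    cur <- h
    if (cfg$use_permute_mlp) {
      for (b in seq_len(cfg$n_blocks)) {
        bf <- .block_fwd(cur, fsn$blocks[[paste0("b", b)]], cfg)
        bl[[b]] <- bf$cache
        cur <- bf$out
      }
    }
    flat <- cur
    dim(flat) <- c(B, 4L * D)
    f1 <- .linear_fwd(flat, fsn$Wf1, fsn$bf1)
    fg <- .gelu_fwd(f1$out)
    f2 <- .linear_fwd(fg$out, fsn$Wf2, fsn$bf2)
    h1 <- .linear_fwd(f2$out, fsn$Wh1, fsn$bh1)
    hg <- .gelu_fwd(h1$out)
    h2 <- .linear_fwd(hg$out, fsn$Wh2, fsn$bh2)
    y_kind[, k] <- drop(h2$out)
    per[[k]] <- list(ed = ed, ee = ee, em = em, blocks = bl,
                     f1 = f1$cache, fg = fg$cache, f2 = f2$cache,
                     h1 = h1$cache, hg = hg$cache, h2 = h2$cache, D = D)
  }
  acc <- y_kind[, 1L]
  for (j in seq_along(kinds)[-1L]) acc <- acc + y_kind[, j]
  list(y_hat = acc / length(kinds), y_kind = y_kind,
       cache = list(per = per, B = B))
}

.model_bwd <- function(dy_hat, fwd, params, data, cfg) {
  kinds <- cfg$fingerprints
  B <- fwd$cache$B
  grads <- list()
  for (k in kinds) {
    fsn <- params[[k]]
    cc <- fwd$cache$per[[k]]
    D <- cc$D
    dy <- matrix(dy_hat / length(kinds), ncol = 1L)
    h2 <- .linear_bwd(dy, cc$h2, fsn$Wh2)
    dhg <- .gelu_bwd(h2$dx, cc$hg)
    h1 <- .linear_bwd(dhg, cc$h1, fsn$Wh1)
    f2 <- .linear_bwd(h1$dx, cc$f2, fsn$Wf2)
    dfg <- .gelu_bwd(f2$dx, cc$fg)
    f1 <- .linear_bwd(dfg, cc$f1, fsn$Wf1)
    dflat <- f1$dx
    dim(dflat) <- c(B, 4L, D)
    gblocks <- list()
    if (cfg$use_permute_mlp) {
      for (b in rev(seq_len(cfg$n_blocks))) {
        bb <- .block_bwd(dflat, cc$blocks[[b]],
                         fsn$blocks[[paste0("b", b)]])
        gblocks[[paste0("b", b)]] <- bb$grads
        dflat <- bb$dx
      }
    }
    # scatter per-record gradients back onto unique drugs / cells
    dzi <- matrix(dflat[, 1L, ], B, D)
    dzj <- matrix(dflat[, 2L, ], B, D)
    dze <- matrix(dflat[, 3L, ], B, D)
    dzm <- matrix(dflat[, 4L, ], B, D)
    dZd <- matrix(0, nrow(data$fp[[k]]), D)
    rs <- rowsum(rbind(dzi, dzj), group = c(data$ia, data$ib))
    dZd[as.integer(rownames(rs)), ] <- rs
    dZc_e <- matrix(0, nrow(data$expr), D)
    rse <- rowsum(dze, group = data$ic)
    dZc_e[as.integer(rownames(rse)), ] <- rse
    dZc_m <- matrix(0, nrow(data$mut), D)
    rsm <- rowsum(dzm, group = data$ic)
    dZc_m[as.integer(rownames(rsm)), ] <- rsm
    gd <- .encoder_bwd(dZd, cc$ed$cache, fsn$enc_drug, cfg)
    ge <- .encoder_bwd(dZc_e, cc$ee$cache, fsn$enc_expr, cfg)
    gm <- .encoder_bwd(dZc_m, cc$em$cache, fsn$enc_mut, cfg)
    g <- list(enc_drug = gd$grads, enc_expr = ge$grads, enc_mut = gm$grads)
    if (cfg$use_permute_mlp) {
      g$blocks <- gblocks[paste0("b", seq_len(cfg$n_blocks))]
    }
    g$Wf1 <- f1$dw; g$bf1 <- f1$db
    g$Wf2 <- f2$dw; g$bf2 <- f2$db
    g$Wh1 <- h1$dw; g$bh1 <- h1$db
    g$Wh2 <- h2$dw; g$bh2 <- h2$db
    grads[[k]] <- g
  }
  grads
}

# Order the gradient tree to match the parameter tree exactly (required by
# the flattened optimizer state).
.align_grads <- function(params, grads) {
  if (!is.list(params)) return(grads)
  out <- params
  for (nm in names(params)) out[[nm]] <- .align_grads(params[[nm]], grads[[nm]])
  out
}

#' One forward pass of a single subnetwork
#'
#' Runs drug-pair and cell-line inputs through the encoders, the stack, the
#' fusion blocks and the prediction head of one fingerprint-specific
#' subnetwork.
#'
#' @param fp_i,fp_j Fingerprint vectors of the subnetwork's kind.
#' @param expression,mutation Cell-line profile vectors.
#' @param fsn One element of `model$params` (e.g. `model$params$maccs`).
#' @param config The model's [model_config()].
#' @return List with `feature` (synergy feature, length `d_tilde`) and
#'   `score` (scalar).
#' @export
fsn_forward <- function(fp_i, fp_j, expression, mutation, fsn,
                        config = model_config()) {
  data <- list(fp = list(k = matrix(as.numeric(rbind(fp_i, fp_j)), 2L)),
               ia = 1L, ib = 2L,
               expr = matrix(as.numeric(expression), 1L),
               mut = matrix(as.numeric(mutation), 1L), ic = 1L)
  cfg <- config
  cfg$fingerprints <- "k"
  fwd <- .model_fwd(list(k = fsn), data, cfg)
  cc <- fwd$cache$per$k
  # recompute the synergy feature (input of the head) from the cached head input
  list(feature = drop(cc$h1), score = unname(fwd$y_hat))
}

#' Predict synergy scores for feature-indexed trios
#'
#' Low-level batched forward pass. Most users should call
#' [predict.synergy_trainer()] instead, which handles id lookup and label
#' de-standardization.
#'
#' @param model A `synergy_model` (see [init_model()]).
#' @param data Batch list: `fp` (named list of unique-drug fingerprint
#'   matrices), `ia`, `ib`, `ic` (record indices into drugs/cells), `expr`,
#'   `mut` (unique-cell profile matrices).
#' @return List with `y_hat` (length-B vector, the mean of the per-kind
#'   scores) and `y_kind` (B x kinds matrix).
#' @export
model_forward <- function(model, data) {
  fwd <- .model_fwd(model$params, data, model$config)
  list(y_hat = fwd$y_hat, y_kind = fwd$y_kind)
}
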