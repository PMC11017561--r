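# Minimal dense/conv neural-network primitives with hand-written gradients.
# Every layer exposes a *_fwd() returning list(out, cache) and a *_bwd()
# taking the upstream gradient plus the cache. All heavy lifting is BLAS
# matrix multiplication; batches sit in the leading array dimension.
#
# Parameter containers are plain nested lists of numeric arrays; the tree
# utilities at the bottom flatten them for the optimizer and for
# finite-difference gradient checks.

# ---- activations -----------------------------------------------------------

.gelu_fwd <- function(x) {
  list(out = cpp_gelu_fwd(x), cache = x)
}

.gelu_bwd <- function(dout, cache) {
  cpp_gelu_bwd(dout, cache)
}

.swish_fwd <- function(x) {
  list(out = cpp_swish_fwd(x), cache = x)
}

.swish_bwd <- function(dout, cache) {
  cpp_swish_bwd(dout, cache)
}

# ---- affine ----------------------------------------------------------------

.linear_fwd <- function(x, w, b) {
  out <- x %*% w
  cpp_add_bias_inplace(out, b)
  list(out = out, cache = x)
}

.linear_bwd <- function(dout, cache, w) {
  list(dx = dout %*% t(w),
       dw = crossprod(cache, dout),
       db = colSums(dout))
}

# ---- layer normalization over the last (column) axis -----------------------

.layernorm_fwd <- function(x, gamma, beta, eps = 1e-5) {
  mu <- rowMeans(x)
  xc <- x - mu
  v <- rowMeans(xc * xc)
  inv <- 1 / sqrt(v + eps)
  xhat <- xc * inv
  out <- sweep(sweep(xhat, 2L, gamma, "*"), 2L, beta, "+")
  list(out = out, cache = list(xhat = xhat, inv = inv, gamma = gamma))
}

.layernorm_bwd <- function(dout, cache) {
  xhat <- cache$xhat
  dxhat <- sweep(dout, 2L, cache$gamma, "*")
  m1 <- rowMeans(dxhat)
  m2 <- rowMeans(dxhat * xhat)
  dx <- cache$inv * (dxhat - m1 - xhat * m2)
  list(dx = dx,
       dgamma = colSums(dout * xhat),
       dbeta = colSums(dout))
}

# ---- 1-D convolution, stride 1, symmetric zero padding ---------------------
# Input x: array (n, L, c_in); weight w: array (h, c_in, c_out); bias b:
# length c_out. Output keeps length L at every layer. Implemented as im2col:
# patches (n*L, h*c_in) times the reshaped kernel.

.conv1d_fwd <- function(x, w, b) {
  dx <- dim(x)
  n <- dx[1]; L <- dx[2]; cin <- dx[3]
  h <- dim(w)[1]
  pad <- (h - 1L) %/% 2L
  stopifnot(h %% 2L == 1L, dim(w)[2] == cin, L >= 1L)
  p <- cpp_im2col(x, n, L, cin, h)
  wm <- w
  dim(wm) <- c(h * cin, dim(w)[3])
  y <- p %*% wm
  cpp_add_bias_inplace(y, b)
  dim(y) <- c(n, L, dim(w)[3])
  list(out = y, cache = list(p = p, n = n, L = L, h = h, cin = cin, pad = pad))
}

.conv1d_bwd <- function(dout, cache, w) {
  n <- cache$n; L <- cache$L; h <- cache$h; cin <- cache$cin; pad <- cache$pad
  cout <- dim(w)[3]
  dm <- dout
  dim(dm) <- c(n * L, cout)
  wm <- w
  dim(wm) <- c(h * cin, cout)
  dw <- crossprod(cache$p, dm)
  dim(dw) <- c(h, cin, cout)
  db <- colSums(dm)
  dp <- dm %*% t(wm)
  dx <- cpp_col2im(dp, n, L, cin, h)
  list(dx = dx, dw = dw, db = db)
}

# ---- initialization --------------------------------------------------------
# Fan-in uniform init, U(-1/sqrt(fan_in), 1/sqrt(fan_in)), for weights and
# biases alike; layer-norm affine starts at the identity (gamma 1, beta 0).

.init_mat <- function(nr, nc, fan_in = nr) {
  lim <- 1 / sqrt(fan_in)
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

.init_vec <- function(n, fan_in) {
  lim <- 1 / sqrt(fan_in)
  stats::runif(n, -lim, lim)
}

.init_conv <- function(h, cin, cout) {
  lim <- 1 / sqrt(h * cin)
  array(stats::runif(h * cin * cout, -lim, lim), c(h, cin, cout))
}

# ---- parameter-tree utilities ---------------------------------------------

.tree_flatten <- function(tree, prefix = "") {
  if (!is.list(tree)) {
    out <- list(tree)
    names(out) <- prefix
    return(out)
  }
  out <- list()
  for (nm in names(tree)) {
    child <- .tree_flatten(tree[[nm]],
                           if (nzchar(prefix)) paste(prefix, nm, sep = "/") else nm)
    out <- c(out, child)
  }
  out
}

.tree_unflatten <- function(skeleton, leaves, prefix = "") {
  if (!is.list(skeleton)) return(leaves[[prefix]])
  out <- skeleton
  for (nm in names(skeleton)) {
    out[[nm]] <- .tree_unflatten(
      skeleton[[nm]], leaves,
      if (nzchar(prefix)) paste(prefix, nm, sep = "/") else nm)
  }
  out
}

.tree_get <- function(tree, path) {
  for (nm in strsplit(path, "/", fixed = TRUE)[[1]]) tree <- tree[[nm]]
  tree
}

.tree_set <- function(tree, path, value) {
  parts <- strsplit(path, "/", fixed = TRUE)[[1]]
  if (length(parts) == 1L) {
    tree[[parts]] <- value
    return(tree)
  }
  tree[[parts[1]]] <- .tree_set(tree[[parts[1]]],
                                paste(parts[-1], collapse = "/"), value)
  tree
}

# Elementwise zero tree mirroring a parameter tree.
.tree_zeros <- function(tree) {
  if (!is.list(tree)) return(array(0, dim = dim(tree) %||% length(tree)))
  lapply(tree, .tree_zeros)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Sum two parameter trees of identical shape (used to merge shared-encoder
# gradient contributions).
.tree_add <- function(a, b) {
  if (!is.list(a)) return(a + b)
  Map(.tree_add, a, b)
}

# ---- Adam ------------------------------------------------------------------

.adam_init <- function(params) {
  leaves <- .tree_flatten(params)
  list(m = lapply(leaves, function(x) x * 0),
       v = lapply(leaves, function(x) x * 0),
       t = 0L)
}

# In-place Adam step: mutates the leaves of `params` (and the moment
# buffers) through the compiled kernel, so the caller must own them; use
# .tree_copy() to snapshot parameters before or after.
.adam_step <- function(params, grads, state, lr = 1e-4,
                       beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  p <- .tree_flatten(params)
  g <- .tree_flatten(grads)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (i in seq_along(p)) {
    cpp_adam_inplace(p[[i]], state$m[[i]], state$v[[i]], g[[i]],
                     lr, beta1, beta2, bc1, bc2, eps)
  }
  list(params = params, state = state)
}

# Deep copy of a parameter tree (leaves are otherwise updated in place).
.tree_copy <- function(tree) {
  if (!is.list(tree)) return(tree + 0)
  lapply(tree, .tree_copy)
}
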