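# Cell-line features: landmark-gene restriction, per-gene standardization
# fit on training folds only, one-hot descriptor baseline, and the Gaussian
# noise operators of the robustness study.

# Run `expr` with a temporarily seeded RNG, restoring the caller's RNG state.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

# Substream seed for one cell line under a master seed; depends only on the
# (seed, id) pair so adding cell lines never perturbs existing draws.
.substream_seed <- function(seed, id) {
  (as.numeric(seed) * 69069 + .hash_string(as.character(id))) %% 2147483647
}

#' Restrict a cell-by-gene matrix to a landmark gene set
#'
#' Keeps the columns whose gene symbols intersect the landmark list and
#' orders them by sorted symbol, so feature positions are a pure function of
#' the resulting panel.
#'
#' @param matrix Numeric matrix, rows = cell lines, columns named by gene
#'   symbol.
#' @param landmark Character vector of landmark gene symbols.
#' @return List with `matrix` (filtered, columns sorted) and `genes`
#'   (the ordered intersection).
#' @export
select_landmark_genes <- function(matrix, landmark) {
  if (is.null(colnames(matrix))) stop_domain("matrix must have gene symbols as colnames")
  if (length(landmark) == 0L) stop_domain("landmark list must be non-empty")
  keep <- sort(intersect(colnames(matrix), unique(landmark)))
  if (length(keep) == 0L) {
    stop_empty_intersection("no genes shared between the matrix and the landmark set")
  }
  list(matrix = matrix[, keep, drop = FALSE], genes = keep)
}

#' Per-gene z-score normalization fit on a training matrix
#'
#' Standardizes `apply_matrix` gene-wise using means and standard deviations
#' estimated on `train_matrix` only, preventing information leakage from
#' evaluation folds. Genes constant in the training matrix map to zero.
#'
#' @param train_matrix,apply_matrix Numeric matrices over the same gene panel
#'   (identical column names and order).
#' @return `apply_matrix`, standardized.
#' @export
normalize_expression <- function(train_matrix, apply_matrix) {
  if (!identical(colnames(train_matrix), colnames(apply_matrix))) {
    stop_shape("train and apply matrices must share an identical gene panel")
  }
  mu <- colMeans(train_matrix)
  sdv <- apply(train_matrix, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- Inf # constant genes -> 0 after scaling
  out <- sweep(apply_matrix, 2L, mu, "-")
  sweep(out, 2L, sdv, "/")
}

.check_sigma <- function(sigma) {
  if (!is.finite(sigma) || sigma < 0) stop_domain("noise sigma must be >= 0")
  sigma
}

#' Multiplicative Gaussian noise on a profile vector
#'
#' Returns `x * eps` with `eps ~ N(1, sigma_mul)` drawn independently per
#' entry, emulating contamination of a tumour profile by normal cells. With
#' `sigma_mul = 0` the input is returned unchanged. Reproducible for a fixed
#' seed; the caller's RNG state is left untouched.
#'
#' @param x Numeric profile vector (expression or mutation; binariness of
#'   mutation profiles is deliberately not preserved).
#' @param sigma_mul Noise standard deviation, >= 0.
#' @param seed Integer seed.
#' @return Numeric vector of the same length as `x`.
#' @export
inject_multiplicative_noise <- function(x, sigma_mul, seed) {
  .check_sigma(sigma_mul)
  if (sigma_mul == 0) return(x)
  .with_seed(seed, x * stats::rnorm(length(x), mean = 1, sd = sigma_mul))
}

#' Additive Gaussian noise on a profile vector
#'
#' Returns `x + eps` with `eps ~ N(0, sigma_add)` per entry; otherwise
#' behaves exactly like [inject_multiplicative_noise()].
#'
#' @inheritParams inject_multiplicative_noise
#' @param sigma_add Noise standard deviation, >= 0.
#' @export
inject_additive_noise <- function(x, sigma_add, seed) {
  .check_sigma(sigma_add)
  if (sigma_add == 0) return(x)
  .with_seed(seed, x + stats::rnorm(length(x), mean = 0, sd = sigma_add))
}

#' Noise a matrix of cell-line profiles row-wise
#'
#' Applies one of the two noise operators to every row of a profile matrix.
#' Each cell line draws from its own substream derived from `seed` and the
#' row name, so extending the panel never changes the noise of existing
#' cell lines.
#'
#' @param mat Numeric matrix, rows = cell lines (row names required).
#' @param sigma Noise standard deviation, >= 0.
#' @param mode `"mul"` or `"add"`.
#' @param seed Master integer seed.
#' @return Noised matrix of the same shape.
#' @export
noise_profiles <- function(mat, sigma, mode = c("mul", "add"), seed) {
  mode <- match.arg(mode)
  .check_sigma(sigma)
  if (sigma == 0) return(mat)
  if (is.null(rownames(mat))) stop_domain("profile matrix needs cell ids as rownames")
  out <- mat
  fn <- if (mode == "mul") inject_multiplicative_noise else inject_additive_noise
  for (i in seq_len(nrow(mat))) {
    out[i, ] <- fn(mat[i, ], sigma, .substream_seed(seed, rownames(mat)[i]))
  }
  out
}

#' One-hot cell-line descriptors
#'
#' Encodes each query cell line as its unit basis vector over the training
#' cell-line set; cell lines unseen during training are encoded as all-zero
#' vectors.
#'
#' @param train_cells Character vector of unique training cell ids.
#' @param query_cells Character vector of cell ids to encode.
#' @return Matrix of shape `length(query_cells)` x `length(train_cells)`
#'   with query ids as row names and training ids as column names.
#' @export
onehot_descriptors <- function(train_cells, query_cells) {
  train_cells <- as.character(train_cells)
  query_cells <- as.character(query_cells)
  if (length(train_cells) == 0L) stop_domain("train_cells must be non-empty")
  if (anyDuplicated(train_cells)) stop_domain("train_cells must be unique")
  m <- matrix(0, nrow = length(query_cells), ncol = length(train_cells),
              dimnames = list(query_cells, train_cells))
  hit <- match(query_cells, train_cells)
  ok <- which(!is.na(hit))
  m[cbind(ok, hit[ok])] <- 1
  m
}
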