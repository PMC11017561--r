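# Synergy labels used by the oncology combination screens: the Loewe score
# from a sigmoidal dose-response parameterization, and the ComboScore summed
# over a concentration grid.

#' Dose-response parameter set
#'
#' Container for the four-parameter sigmoid used by the Loewe score:
#' responses run from `r_min` (zero dose) towards `r_max`, with midpoint
#' dose `m` and Hill-type shape `lam`.
#'
#' @param r_min,r_max Minimum and maximum drug response (response units).
#' @param m Dose producing the midpoint response; must be > 0.
#' @param lam Shape parameter; must be > 0.
#' @return A list of class `dose_response_params`.
#' @export
dose_response_params <- function(r_min, r_max, m, lam) {
  if (!is.finite(m) || m <= 0) stop_domain("midpoint dose m must be > 0")
  if (!is.finite(lam) || lam <= 0) stop_domain("shape parameter lam must be > 0")
  structure(list(r_min = r_min, r_max = r_max, m = m, lam = lam),
            class = "dose_response_params")
}

#' Loewe synergy score
#'
#' Evaluates the dose-equivalence (sham combination) response at the total
#' dose of the two drugs:
#' \deqn{(R_{min} + R_{max}\,((x_A+x_B)/m)^\lambda) /
#'       (1 + ((x_A+x_B)/m)^\lambda).}
#' The score depends on the doses only through their sum, so
#' `loewe_score(p, a, b) == loewe_score(p, a + b, 0)` exactly.
#'
#' @param params A [dose_response_params()] object.
#' @param x_a,x_b Non-negative doses of the two drugs (same concentration
#'   units as `params$m`). Vectorized.
#' @return Numeric score(s), finite for all valid inputs.
#' @examples
#' p <- dose_response_params(r_min = 0, r_max = 100, m = 1, lam = 2)
#' loewe_score(p, 0.5, 0.5)  # total dose m -> (r_min + r_max) / 2
#' @export
loewe_score <- function(params, x_a, x_b) {
  if (!inherits(params, "dose_response_params")) {
    params <- do.call(dose_response_params, as.list(params))
  }
  if (any(x_a < 0) || any(x_b < 0)) stop_domain("doses must be >= 0")
  ratio <- ((x_a + x_b) / params$m)^params$lam
  (params$r_min + params$r_max * ratio) / (1 + ratio)
}

#' Combination grid of observed and expected growth fractions
#'
#' @param observed Matrix of observed growth fractions over the
#'   (drug A concentration, drug B concentration) grid.
#' @param expected Matrix of expected (null-model) growth fractions of the
#'   same shape.
#' @param mask Optional logical matrix of the same shape; `FALSE` cells are
#'   excluded from the score (ragged screening grids).
#' @return A list of class `combination_grid`.
#' @export
combination_grid <- function(observed, expected, mask = NULL) {
  observed <- as.matrix(observed)
  expected <- as.matrix(expected)
  if (!all(dim(observed) == dim(expected))) {
    stop_shape("observed and expected grids must have identical shape")
  }
  if (length(observed) == 0L) stop_shape("grid must be at least 1x1")
  if (!is.null(mask)) {
    mask <- as.matrix(mask)
    if (!all(dim(mask) == dim(observed))) {
      stop_shape("mask must match the grid shape")
    }
  }
  structure(list(observed = observed, expected = expected, mask = mask),
            class = "combination_grid")
}

#' ComboScore of a combination grid
#'
#' Sums observed minus expected growth fractions over every concentration
#' pair: \eqn{\sum_{p,q} Y_{pq} - Z_{pq}}. The sign convention follows the
#' formula as printed (observed minus expected), so a combination that
#' suppresses growth below the null expectation scores negative. Masked
#' cells, if any, are skipped.
#'
#' @param grid A [combination_grid()].
#' @return A single numeric score.
#' @export
combo_score <- function(grid) {
  if (!inherits(grid, "combination_grid")) {
    stop_domain("expected a 'combination_grid'")
  }
  diffs <- grid$observed - grid$expected
  if (!is.null(grid$mask)) diffs <- diffs[grid$mask]
  sum(diffs)
}
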