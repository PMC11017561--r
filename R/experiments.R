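# Evaluation harness: independent hold-out, the three cross-validation split
# strategies (random, leave-cell-out, leave-combination-out), regression
# metrics, ablation variants, the noise-robustness study and ranking of
# unmeasured combinations.

.pair_key <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  paste(pmin(a, b), pmax(a, b), sep = "\r")
}

#' Deduplicate drug-order duplicates
#'
#' Combinations are unordered: rows that repeat the same (drug pair, cell
#' line) trio in either drug order are collapsed to one row whose score is
#' the mean of the duplicates (with a warning). The first-seen drug order is
#' kept.
#'
#' @param records Synergy record data frame.
#' @return Deduplicated data frame.
#' @export
dedupe_records <- function(records) {
  records <- as.data.frame(.check_records(records))
  key <- paste(.pair_key(records$drug_a, records$drug_b),
               as.character(records$cell_line), sep = "\r")
  if (!anyDuplicated(key)) return(records)
  warning(sprintf("%d duplicated trio(s) collapsed by averaging scores",
                  sum(duplicated(key))))
  first <- !duplicated(key)
  out <- records[first, , drop = FALSE]
  if ("score" %in% names(records)) {
    out$score <- as.numeric(tapply(records$score, key, mean)[key[first]])
  }
  rownames(out) <- NULL
  out
}

#' Split records into a cross-validation set and an independent test set
#'
#' Simple seeded random split; the independent set receives
#' `round(frac * n)` records and is used only for final evaluation.
#'
#' @param records Synergy record data frame.
#' @param frac Independent-set fraction, in (0, 1); default 0.10.
#' @param seed Integer seed.
#' @return List with `cv` and `independent` data frames.
#' @export
holdout_split <- function(records, frac = 0.10, seed = 1L) {
  records <- as.data.frame(records)
  if (frac <= 0 || frac >= 1) stop_domain("frac must be in (0, 1)")
  n <- nrow(records)
  idx <- .with_seed(seed, sample.int(n, round(frac * n)))
  list(cv = records[setdiff(seq_len(n), idx), , drop = FALSE],
       independent = records[idx, , drop = FALSE])
}

#' Build a k-fold split plan under one of three strategies
#'
#' `random` shuffles records into `k` near-equal folds. `leave_cell_out`
#' partitions the cell-line set into `k` folds and assigns each record its
#' cell line's fold, so no test cell line is ever seen in training.
#' `leave_combination_out` does the same for unordered drug pairs, so both
#' orderings of a pair always land in the same fold.
#'
#' @param records Synergy record data frame.
#' @param strategy One of `"random"`, `"leave_cell_out"`,
#'   `"leave_combination_out"`.
#' @param k Number of folds; default 5.
#' @param seed Integer seed.
#' @return List of class `split_plan` with `strategy`, `k`, `seed` and
#'   `folds` (list of `k` disjoint, exhaustive record index vectors).
#' @export
make_split_plan <- function(records, strategy = c("random", "leave_cell_out",
                                                  "leave_combination_out"),
                            k = 5L, seed = 1L) {
  strategy <- match.arg(strategy)
  records <- as.data.frame(.check_records(records))
  n <- nrow(records)
  if (n == 0L) stop_domain("records must be non-empty")
  k <- as.integer(k)
  entity <- switch(strategy,
    random = as.character(seq_len(n)),
    leave_cell_out = as.character(records$cell_line),
    leave_combination_out = .pair_key(records$drug_a, records$drug_b))
  units <- unique(entity)
  if (length(units) < k) {
    stop_insufficient_entities(sprintf(
      "strategy '%s' needs at least %d distinct entities, found %d",
      strategy, k, length(units)))
  }
  fold_of_unit <- .with_seed(seed, {
    shuffled <- sample(units)
    stats::setNames(rep(seq_len(k), length.out = length(shuffled)), shuffled)
  })
  folds <- lapply(seq_len(k), function(f) {
    unname(which(fold_of_unit[entity] == f))
  })
  structure(list(strategy = strategy, k = k, seed = as.integer(seed),
                 folds = folds),
            class = "split_plan")
}

#' Regression metrics: RMSE, coefficient of determination, Pearson r
#'
#' RMSE is the root mean squared error; R^2 is the standard coefficient of
#' determination `1 - SSE / SStot`; PCC is Pearson's correlation. Perfect
#' prediction yields `(0, 1, 1)`.
#'
#' @param y_true,y_pred Equal-length numeric vectors, `n >= 2`; `y_true`
#'   must not be constant.
#' @return List of class `metrics_report` with `rmse`, `r2`, `pcc` and `n`.
#' @export
compute_metrics <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop_shape("length mismatch")
  n <- length(y_true)
  if (n < 2L) stop_degenerate_input("need at least two observations")
  if (stats::sd(y_true) == 0) {
    stop_degenerate_input("y_true is constant; R^2 and PCC are undefined")
  }
  sse <- sum((y_true - y_pred)^2)
  sst <- sum((y_true - mean(y_true))^2)
  structure(list(rmse = sqrt(sse / n),
                 r2 = 1 - sse / sst,
                 pcc = stats::cor(y_true, y_pred),
                 n = n),
            class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("RMSE %.4f | R2 %.4f | PCC %.4f (n = %d)\n",
              x$rmse, x$r2, x$pcc, x$n))
  invisible(x)
}

#' k-fold cross-validation of the synergy model
#'
#' For every fold of the plan, trains on the remaining folds and evaluates
#' on the held-out fold. The aggregate report is the arithmetic mean of the
#' per-fold metrics; pooled metrics over the concatenated predictions are
#' reported alongside.
#'
#' @param records Synergy record data frame.
#' @param features Feature list (see [train_model()]). Expression profiles
#'   are re-standardized per fold on the training part only.
#' @param strategy Split strategy, as in [make_split_plan()].
#' @param model_cfg,train_cfg Model and training configuration.
#' @param k Number of folds.
#' @param seed Integer seed (drives the plan and per-fold training).
#' @return List with `folds` (per-fold `metrics_report`), `aggregate`,
#'   `pooled`, `predictions` (row-bound per-fold prediction frames with a
#'   `fold` column) and `plan`.
#' @export
run_cv <- function(records, features, strategy = "random",
                   model_cfg = model_config(), train_cfg = train_config(),
                   k = 5L, seed = 1L) {
  records <- as.data.frame(records)
  plan <- make_split_plan(records, strategy, k = k, seed = seed)
  fold_reports <- vector("list", plan$k)
  preds <- vector("list", plan$k)
  for (f in seq_len(plan$k)) {
    test_idx <- plan$folds[[f]]
    train_idx <- setdiff(seq_len(nrow(records)), test_idx)
    feats <- features
    feats$expression <- normalize_expression(
      features$expression[unique(as.character(records$cell_line[train_idx])), ,
                          drop = FALSE],
      features$expression)
    trainer <- train_model(records[train_idx, , drop = FALSE], feats,
                           model_cfg, train_cfg, seed = seed + f)
    p <- stats::predict(trainer, records[test_idx, , drop = FALSE], feats)
    p$fold <- f
    preds[[f]] <- p
    fold_reports[[f]] <- compute_metrics(p$y_true, p$y_hat)
  }
  all_preds <- do.call(rbind, preds)
  agg <- structure(list(
    rmse = mean(vapply(fold_reports, `[[`, numeric(1), "rmse")),
    r2 = mean(vapply(fold_reports, `[[`, numeric(1), "r2")),
    pcc = mean(vapply(fold_reports, `[[`, numeric(1), "pcc")),
    n = nrow(all_preds)), class = "metrics_report")
  list(folds = fold_reports, aggregate = agg,
       pooled = compute_metrics(all_preds$y_true, all_preds$y_hat),
       predictions = all_preds, plan = plan)
}

.ablation_variants <- c("full", "wo_hashtt", "wo_map4", "wo_maccs",
                        "only_hashtt", "only_map4", "only_maccs",
                        "wo_permute_mlp", "feedforward_encoder")

#' Model configuration of an ablation variant
#'
#' Fingerprint-subset variants drop the corresponding subnetwork(s) and
#' average the remaining heads; `wo_permute_mlp` replaces both fusion blocks
#' with the identity; `feedforward_encoder` swaps every convolutional encoder
#' for a feedforward affine + GELU stack of matched output dimension.
#'
#' @param variant One of `r paste0('"', .ablation_variants, '"', collapse = ", ")`.
#' @param base A [model_config()] to modify.
#' @return A [model_config()].
#' @export
ablation_config <- function(variant, base = model_config()) {
  if (!variant %in% .ablation_variants) stop_unknown_variant(variant)
  cfg <- base
  all_fp <- c("hashtt", "map4", "maccs")
  if (startsWith(variant, "wo_") && variant != "wo_permute_mlp") {
    cfg$fingerprints <- setdiff(all_fp, sub("^wo_", "", variant))
  } else if (startsWith(variant, "only_")) {
    cfg$fingerprints <- sub("^only_", "", variant)
  } else if (variant == "wo_permute_mlp") {
    cfg$use_permute_mlp <- FALSE
  } else if (variant == "feedforward_encoder") {
    cfg$encoder <- "mlp"
  }
  cfg
}

#' Train and evaluate one ablation variant
#'
#' Applies [ablation_config()] to the base configuration, trains on a seeded
#' 80/20 train/test split of the records and reports test metrics.
#'
#' @param variant Ablation variant name.
#' @param records,features Data as in [train_model()].
#' @param model_cfg,train_cfg Base configurations.
#' @param seed Integer seed.
#' @return List with `variant`, `metrics` (a `metrics_report`),
#'   `predictions` and `trainer`.
#' @export
run_ablation <- function(variant, records, features,
                         model_cfg = model_config(),
                         train_cfg = train_config(), seed = 1L) {
  cfg <- ablation_config(variant, model_cfg)
  split <- holdout_split(records, frac = 0.2, seed = seed)
  trainer <- train_model(split$cv, features, cfg, train_cfg, seed = seed)
  p <- stats::predict(trainer, split$independent, features)
  list(variant = variant, metrics = compute_metrics(p$y_true, p$y_hat),
       predictions = p, trainer = trainer)
}

#' Noise-robustness study
#'
#' For each noise level, trains the model on cell-line profiles (expression
#' and mutation) perturbed by multiplicative or additive Gaussian noise and
#' reports the Pearson correlation between its predictions and those of the
#' model trained on the unperturbed profiles, on a common held-out test set.
#' At `sigma = 0` the training data, and hence the predictions, are
#' identical, so the correlation is exactly 1.
#'
#' @param records,features Data as in [train_model()].
#' @param sigmas Non-negative noise standard deviations to test.
#' @param mode `"mul"` or `"add"`.
#' @param model_cfg,train_cfg Configurations shared by all runs.
#' @param test_frac Held-out fraction used for the prediction comparison.
#' @param seed Integer seed (same training seed for all runs).
#' @return Data frame with columns `sigma`, `mode`, `correlation`.
#' @export
noise_study <- function(records, features, sigmas, mode = c("mul", "add"),
                        model_cfg = model_config(),
                        train_cfg = train_config(), test_frac = 0.2,
                        seed = 1L) {
  mode <- match.arg(mode)
  if (any(sigmas < 0)) stop_domain("sigmas must be >= 0")
  split <- holdout_split(records, frac = test_frac, seed = seed)
  base_trainer <- train_model(split$cv, features, model_cfg, train_cfg,
                              seed = seed)
  base_pred <- stats::predict(base_trainer, split$independent, features)$y_hat
  cors <- vapply(sigmas, function(s) {
    feats <- features
    feats$expression <- noise_profiles(features$expression, s, mode, seed)
    feats$mutation <- noise_profiles(features$mutation, s, mode, seed)
    trainer <- train_model(split$cv, feats, model_cfg, train_cfg, seed = seed)
    pred <- stats::predict(trainer, split$independent, feats)$y_hat
    stats::cor(base_pred, pred)
  }, numeric(1))
  data.frame(sigma = sigmas, mode = mode, correlation = cors)
}

#' Rank unmeasured drug-pair / cell-line trios
#'
#' Enumerates every (unordered drug pair, cell line) trio absent from the
#' measured records, predicts their synergy and returns them sorted by
#' decreasing predicted score; ties are broken lexicographically by
#' (drug_a, drug_b, cell_line).
#'
#' @param drugs Character vector of drug ids to combine.
#' @param cells Character vector of cell-line ids.
#' @param measured_records Data frame of already measured trios (may have
#'   zero rows).
#' @param trainer A `synergy_trainer` covering all drugs and cells.
#' @param features Feature list covering all drugs and cells.
#' @return Prediction data frame sorted by decreasing `y_hat`.
#' @export
rank_unmeasured <- function(drugs, cells, measured_records, trainer,
                            features) {
  drugs <- sort(unique(as.character(drugs)))
  if (length(drugs) < 2L) stop_domain("need at least two drugs")
  pairs <- utils::combn(drugs, 2L)
  cand <- data.frame(
    drug_a = rep(pairs[1L, ], times = length(cells)),
    drug_b = rep(pairs[2L, ], times = length(cells)),
    cell_line = rep(sort(unique(as.character(cells))), each = ncol(pairs)),
    stringsAsFactors = FALSE)
  if (nrow(measured_records) > 0L) {
    .check_records(measured_records)
    seen <- paste(.pair_key(measured_records$drug_a, measured_records$drug_b),
                  as.character(measured_records$cell_line), sep = "\r")
    key <- paste(.pair_key(cand$drug_a, cand$drug_b), cand$cell_line,
                 sep = "\r")
    cand <- cand[!key %in% seen, , drop = FALSE]
  }
  if (nrow(cand) == 0L) {
    out <- cand
    out$y_hat <- numeric(0)
    return(out)
  }
  p <- stats::predict(trainer, cand, features)
  p[order(-p$y_hat, p$drug_a, p$drug_b, p$cell_line), , drop = FALSE]
}
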