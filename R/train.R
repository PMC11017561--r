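# Training loop: Adam on the mean-squared-error loss, mini-batches, inner
# validation split with early stopping. Labels are standardized (fit on the
# training part) so optimizer settings are independent of the synergy-score
# scale; predictions are mapped back to the original scale.

#' Training configuration
#'
#' @param lr Adam learning rate.
#' @param batch_size Mini-batch size.
#' @param epochs Maximum number of epochs.
#' @param patience Early-stopping patience in epochs on the inner validation
#'   loss; `Inf` disables early stopping.
#' @param target_loss Optional convergence threshold: training stops once the
#'   epoch training loss (on the standardized label scale) falls below it.
#' @param val_frac Fraction of the training records held out as the inner
#'   validation split (0 disables; early stopping then watches training loss).
#' @param standardize_labels Standardize labels to zero mean / unit variance
#'   during optimization (predictions are always returned on the original
#'   scale).
#' @param swap_augment Add a drug-order-swapped copy of every training
#'   record (optional symmetrization augmentation).
#' @param verbose Print per-epoch losses.
#' @return A list of class `synergy_train_config`.
#' @export
train_config <- function(lr = 1e-4, batch_size = 128L, epochs = 500L,
                         patience = 20L, val_frac = 0.1, target_loss = NULL,
                         standardize_labels = TRUE, swap_augment = FALSE,
                         verbose = FALSE) {
  structure(list(lr = lr, batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), patience = patience,
                 val_frac = val_frac, target_loss = target_loss,
                 standardize_labels = isTRUE(standardize_labels),
                 swap_augment = isTRUE(swap_augment),
                 verbose = isTRUE(verbose)),
            class = "synergy_train_config")
}

.check_records <- function(records) {
  need <- c("drug_a", "drug_b", "cell_line")
  if (!all(need %in% names(records))) {
    stop_domain("records need columns drug_a, drug_b, cell_line")
  }
  records
}

# Assemble the batched-forward data list for a set of records, restricted to
# the entities the records actually reference.
.build_data <- function(records, features, config) {
  .check_records(records)
  kinds <- config$fingerprints
  drugs <- unique(c(as.character(records$drug_a), as.character(records$drug_b)))
  cells <- unique(as.character(records$cell_line))
  for (k in kinds) {
    m <- features$fingerprints[[k]]
    if (is.null(m)) stop_data_coverage(sprintf("missing '%s' fingerprint matrix", k))
    missing <- setdiff(drugs, rownames(m))
    if (length(missing) > 0L) {
      stop_data_coverage(paste("records reference drugs without fingerprints:",
                               paste(missing, collapse = ", ")))
    }
  }
  for (nm in c("expression", "mutation")) {
    missing <- setdiff(cells, rownames(features[[nm]]))
    if (length(missing) > 0L) {
      stop_data_coverage(paste("records reference cell lines without profiles:",
                               paste(missing, collapse = ", ")))
    }
  }
  fp <- lapply(kinds, function(k) {
    m <- features$fingerprints[[k]][drugs, , drop = FALSE]
    storage.mode(m) <- "double"
    m
  })
  names(fp) <- kinds
  expr <- features$expression[cells, , drop = FALSE]
  mut <- features$mutation[cells, , drop = FALSE]
  storage.mode(expr) <- "double"
  storage.mode(mut) <- "double"
  list(fp = fp,
       ia = match(as.character(records$drug_a), drugs),
       ib = match(as.character(records$drug_b), drugs),
       ic = match(as.character(records$cell_line), cells),
       expr = expr, mut = mut)
}

.subset_data <- function(data, idx) {
  list(fp = data$fp, ia = data$ia[idx], ib = data$ib[idx], ic = data$ic[idx],
       expr = data$expr, mut = data$mut)
}

.feature_lengths <- function(features, config) {
  out <- lapply(features$fingerprints[config$fingerprints], ncol)
  out$expr <- ncol(features$expression)
  out$mut <- ncol(features$mutation)
  out
}

#' Train the synergy model
#'
#' Minimizes the mean squared error between predicted and observed synergy
#' scores with Adam. A fraction of the training records forms an inner
#' validation split used for early stopping; the parameters achieving the
#' best validation loss are restored at the end. Fully deterministic for a
#' fixed seed under single-threaded execution.
#'
#' @param records Data frame with columns `drug_a`, `drug_b`, `cell_line`,
#'   `score`.
#' @param features List with `fingerprints` (named list of drugs-by-bits
#'   matrices, see [fingerprint_matrices()]), `expression` and `mutation`
#'   (cells-by-genes matrices with cell ids as row names).
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param seed Integer seed governing initialization, the validation split
#'   and batch shuffling.
#' @return Object of class `synergy_trainer` with elements `model`,
#'   `label_center`, `label_scale`, `log` (per-epoch losses), `best_epoch`,
#'   `train_config` and `seed`.
#' @export
train_model <- function(records, features, model_cfg = model_config(),
                        train_cfg = train_config(), seed = 1L) {
  .check_records(records)
  if (!"score" %in% names(records)) stop_domain("records need a 'score' column")
  if (nrow(records) == 0L) stop_domain("empty training set")
  records <- as.data.frame(records)
  if (train_cfg$swap_augment) {
    swapped <- records
    swapped$drug_a <- records$drug_b
    swapped$drug_b <- records$drug_a
    records <- rbind(records, swapped)
  }
  data <- .build_data(records, features, model_cfg)
  y_all <- as.numeric(records$score)

  .with_seed(seed, {
    n <- nrow(records)
    n_val <- if (train_cfg$val_frac > 0) round(train_cfg$val_frac * n) else 0L
    val_idx <- if (n_val >= 1L && n - n_val >= 1L) sample.int(n, n_val) else integer(0)
    tr_idx <- setdiff(seq_len(n), val_idx)

    center <- 0; scale <- 1
    if (train_cfg$standardize_labels) {
      center <- mean(y_all[tr_idx])
      scale <- stats::sd(y_all[tr_idx])
      if (!is.finite(scale) || scale == 0) scale <- 1
    }
    y <- (y_all - center) / scale

    model <- init_model(model_cfg, .feature_lengths(features, model_cfg),
                        seed = sample.int(2^30, 1L))
    params <- .tree_copy(model$params) # Adam updates leaves in place
    opt <- .adam_init(params)
    tr_data <- .subset_data(data, tr_idx)
    val_data <- if (length(val_idx)) .subset_data(data, val_idx) else NULL

    best <- list(loss = Inf, params = params, epoch = 0L)
    bad <- 0L
    log <- data.frame(epoch = integer(0), train_loss = numeric(0),
                      val_loss = numeric(0))
    for (ep in seq_len(train_cfg$epochs)) {
      ord <- sample(seq_along(tr_idx))
      starts <- seq(1L, length(ord), by = train_cfg$batch_size)
      ep_loss <- 0
      for (s in starts) {
        bi <- ord[s:min(s + train_cfg$batch_size - 1L, length(ord))]
        bd <- .subset_data(tr_data, bi)
        yb <- y[tr_idx][bi]
        fwd <- .model_fwd(params, bd, model_cfg)
        resid <- fwd$y_hat - yb
        ep_loss <- ep_loss + sum(resid^2)
        dy <- 2 * resid / length(yb)
        grads <- .model_bwd(dy, fwd, params, bd, model_cfg)
        grads <- .align_grads(params, grads)
        upd <- .adam_step(params, grads, opt, lr = train_cfg$lr)
        params <- upd$params
        opt <- upd$state
      }
      ep_loss <- ep_loss / length(tr_idx)
      watch <- ep_loss
      val_loss <- NA_real_
      if (!is.null(val_data)) {
        vf <- .model_fwd(params, val_data, model_cfg)
        val_loss <- mean((vf$y_hat - y[val_idx])^2)
        watch <- val_loss
      }
      log <- rbind(log, data.frame(epoch = ep, train_loss = ep_loss,
                                   val_loss = val_loss))
      if (train_cfg$verbose) {
        message(sprintf("epoch %3d  train %.5f  val %s", ep, ep_loss,
                        if (is.na(val_loss)) "-" else sprintf("%.5f", val_loss)))
      }
      if (watch < best$loss) {
        best <- list(loss = watch, params = .tree_copy(params), epoch = ep)
        bad <- 0L
      } else {
        bad <- bad + 1L
        if (is.finite(train_cfg$patience) && bad >= train_cfg$patience) break
      }
      if (!is.null(train_cfg$target_loss) &&
          ep_loss <= train_cfg$target_loss) break
    }
    model$params <- best$params
    structure(list(model = model, label_center = center, label_scale = scale,
                   log = log, best_epoch = best$epoch,
                   train_config = train_cfg, seed = as.integer(seed)),
              class = "synergy_trainer")
  })
}

#' Predict synergy scores for trios
#'
#' @param object A `synergy_trainer` from [train_model()].
#' @param records Data frame with `drug_a`, `drug_b`, `cell_line` (a `score`
#'   column, if present, is copied through as `y_true`).
#' @param features Feature list as in [train_model()]; must cover every
#'   referenced drug and cell line.
#' @param ... Unused.
#' @return `records` extended with `y_hat` plus one column per subnetwork:
#'   `y_t` (hashtt), `y_p` (map4), `y_s` (maccs), all on the original score
#'   scale.
#' @export
predict.synergy_trainer <- function(object, records, features, ...) {
  records <- as.data.frame(.check_records(records))
  data <- .build_data(records, features, object$model$config)
  fwd <- .model_fwd(object$model$params, data, object$model$config)
  descale <- function(z) z * object$label_scale + object$label_center
  out <- records[, c("drug_a", "drug_b", "cell_line"), drop = FALSE]
  if ("score" %in% names(records)) out$y_true <- records$score
  out$y_hat <- descale(fwd$y_hat)
  letter <- c(hashtt = "t", map4 = "p", maccs = "s")
  for (k in colnames(fwd$y_kind)) {
    out[[paste0("y_", letter[[k]])]] <- descale(fwd$y_kind[, k])
  }
  out
}

#' Save a trained model
#'
#' Writes the trainer object as an opaque binary file plus a human-readable
#' sidecar JSON (`<path>.json`) recording the architecture, training
#' configuration, seed and label scaling. Loading restores bit-identical
#' predictions.
#'
#' @param trainer A `synergy_trainer`.
#' @param path Destination file.
#' @return `path`, invisibly.
#' @export
save_model <- function(trainer, path) {
  stopifnot(inherits(trainer, "synergy_trainer"))
  saveRDS(trainer, path)
  meta <- list(
    package = "synfuse",
    config = unclass(trainer$model$config),
    input_lengths = trainer$model$input_lengths,
    train_config = unclass(trainer$train_config),
    seed = trainer$seed,
    label_center = trainer$label_center,
    label_scale = trainer$label_scale,
    best_epoch = trainer$best_epoch
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' Load a trained model saved by [save_model()]
#'
#' @param path File written by [save_model()].
#' @return A `synergy_trainer`.
#' @export
load_model <- function(path) {
  trainer <- readRDS(path)
  stopifnot(inherits(trainer, "synergy_trainer"))
  trainer
}
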