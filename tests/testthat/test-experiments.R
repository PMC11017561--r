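make_records <- function(n_drugs = 8, n_cells = 6, n = 60, seed = 1) {
  synfuse:::.with_seed(seed, {
    drugs <- paste0("D", seq_len(n_drugs))
    pairs <- t(combn(drugs, 2))
    grid <- expand.grid(pair = seq_len(nrow(pairs)),
                        cell = paste0("C", seq_len(n_cells)))
    pick <- sample(nrow(grid), n)
    data.frame(drug_a = pairs[grid$pair[pick], 1],
               drug_b = pairs[grid$pair[pick], 2],
               cell_line = grid$cell[pick],
               score = rnorm(n), stringsAsFactors = FALSE)
  })
}

test_that("holdout split is a seeded disjoint 90/10 partition", {
  rec <- make_records(n = 100)
  sp <- holdout_split(rec, 0.10, seed = 3)
  expect_equal(nrow(sp$independent), 10L)
  expect_equal(nrow(sp$cv), 90L)
  key <- function(d) paste(d$drug_a, d$drug_b, d$cell_line, d$score)
  expect_length(intersect(key(sp$cv), key(sp$independent)), 0L)
  expect_setequal(c(key(sp$cv), key(sp$independent)), key(rec))
  sp2 <- holdout_split(rec, 0.10, seed = 3)
  expect_identical(sp, sp2)
  expect_error(holdout_split(rec, 0), class = "domain_error")
})

test_that("random split plans partition indices into near-equal folds", {
  rec <- make_records(n = 10)
  plan <- make_split_plan(rec, "random", k = 5, seed = 1)
  expect_identical(sort(lengths(plan$folds)), rep(2L, 5))
  expect_setequal(unlist(plan$folds), 1:10)
  expect_identical(make_split_plan(rec, "random", k = 5, seed = 1)$folds,
                   plan$folds)
})

test_that("leave-cell-out folds never share a cell line", {
  rec <- make_records(n = 120, n_cells = 11)
  plan <- make_split_plan(rec, "leave_cell_out", k = 5, seed = 2)
  cells <- lapply(plan$folds, function(f) unique(rec$cell_line[f]))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(cells[[i]], cells[[j]]), 0L)
  }
  expect_setequal(unlist(plan$folds), seq_len(nrow(rec)))
})

test_that("leave-combination-out keeps both orderings of a pair together", {
  # constructed toy set containing both (A,B) and (B,A) orderings
  rec <- data.frame(
    drug_a = c("A", "B", "A", "C", "B", "D", "E", "F", "A", "G",
               "C", "D", "E", "F", "G", "H", "A", "B", "C", "D"),
    drug_b = c("B", "A", "C", "A", "C", "E", "D", "G", "D", "F",
               "B", "A", "F", "E", "H", "G", "E", "F", "G", "H"),
    cell_line = rep(c("c1", "c2"), 10),
    score = rnorm(20), stringsAsFactors = FALSE)
  plan <- make_split_plan(rec, "leave_combination_out", k = 5, seed = 4)
  key <- function(f) unique(paste(pmin(rec$drug_a[f], rec$drug_b[f]),
                                  pmax(rec$drug_a[f], rec$drug_b[f])))
  for (i in 1:4) for (j in (i + 1):5) {
    expect_length(intersect(key(plan$folds[[i]]), key(plan$folds[[j]])), 0L)
  }
  # (A,B) and (B,A) rows share a fold
  fold_of <- integer(nrow(rec))
  for (f in seq_along(plan$folds)) fold_of[plan$folds[[f]]] <- f
  expect_identical(fold_of[1], fold_of[2])
})

test_that("entity strategies fail below k distinct entities", {
  rec <- make_records(n = 30, n_cells = 3)
  expect_error(make_split_plan(rec, "leave_cell_out", k = 5, seed = 1),
               class = "insufficient_entities_error")
})

test_that("metrics match independent textbook oracles", {
  set.seed(10)
  for (i in 1:100) {
    y <- rnorm(20); p <- rnorm(20)
    m <- compute_metrics(y, p)
    rmse_o <- sqrt(mean((y - p)^2))
    r2_o <- 1 - sum((y - p)^2) / sum((y - mean(y))^2)
    pcc_o <- sum((y - mean(y)) * (p - mean(p))) /
      (sqrt(sum((y - mean(y))^2)) * sqrt(sum((p - mean(p))^2)))
    expect_equal(m$rmse, rmse_o, tolerance = 1e-10)
    expect_equal(m$r2, r2_o, tolerance = 1e-10)
    expect_equal(m$pcc, pcc_o, tolerance = 1e-10)
  }
  y <- rnorm(15)
  perf <- compute_metrics(y, y)
  expect_equal(c(perf$rmse, perf$r2, perf$pcc), c(0, 1, 1))
  anti <- compute_metrics(y, -y + 2)
  expect_equal(anti$pcc, -1)
  expect_error(compute_metrics(rep(1, 5), rnorm(5)),
               class = "degenerate_input_error")
  expect_error(compute_metrics(1, 1), class = "degenerate_input_error")
})

test_that("drug-order duplicate trios are collapsed by averaging", {
  rec <- data.frame(drug_a = c("A", "B", "A"), drug_b = c("B", "A", "C"),
                    cell_line = c("c1", "c1", "c1"), score = c(1, 3, 5),
                    stringsAsFactors = FALSE)
  expect_warning(out <- dedupe_records(rec), "collapsed")
  expect_equal(nrow(out), 2L)
  expect_equal(out$score[1], 2) # mean of 1 and 3
  clean <- make_records(n = 20)
  expect_identical(dedupe_records(clean), clean)
})

test_that("ablation variants adjust the architecture as declared", {
  base <- tiny_model_config()
  expect_identical(ablation_config("only_hashtt", base)$fingerprints, "hashtt")
  expect_setequal(ablation_config("wo_maccs", base)$fingerprints,
                  c("hashtt", "map4"))
  expect_false(ablation_config("wo_permute_mlp", base)$use_permute_mlp)
  expect_identical(ablation_config("feedforward_encoder", base)$encoder, "mlp")
  expect_identical(ablation_config("full", base), base)
  expect_error(ablation_config("nope", base), class = "unknown_variant_error")
})

test_that("single-fingerprint and two-fingerprint variants average their heads", {
  ds <- tiny_dataset()
  t1 <- train_model(ds$records, ds$features,
                    ablation_config("only_maccs", tiny_model_config()),
                    tiny_train_config(epochs = 2L), seed = 1)
  p1 <- predict(t1, ds$records[1:5, ], ds$features)
  expect_named(p1, c("drug_a", "drug_b", "cell_line", "y_true", "y_hat", "y_s"))
  expect_equal(p1$y_hat, p1$y_s)
  t2 <- train_model(ds$records, ds$features,
                    ablation_config("wo_maccs", tiny_model_config()),
                    tiny_train_config(epochs = 2L), seed = 1)
  p2 <- predict(t2, ds$records[1:5, ], ds$features)
  expect_equal(p2$y_hat, (p2$y_t + p2$y_p) / 2, tolerance = 1e-12)
})

test_that("the fusion-free variant equals zeroing every fusion block", {
  ds <- tiny_dataset()
  cfg_off <- tiny_model_config(use_permute_mlp = FALSE)
  mdl <- init_model(cfg_off, synfuse:::.feature_lengths(ds$features, cfg_off),
                    seed = 8)
  data <- synfuse:::.build_data(ds$records[1:20, ], ds$features, cfg_off)
  out_off <- model_forward(mdl, data)
  # same parameters, blocks present but zero-weighted: identical computation
  cfg_on <- tiny_model_config(use_permute_mlp = TRUE)
  mdl_on <- init_model(cfg_on, synfuse:::.feature_lengths(ds$features, cfg_on),
                       seed = 8)
  for (k in cfg_on$fingerprints) {
    for (nm in setdiff(names(mdl$params[[k]]), "blocks")) {
      mdl_on$params[[k]][[nm]] <- mdl$params[[k]][[nm]]
    }
    for (b in names(mdl_on$params[[k]]$blocks)) {
      mdl_on$params[[k]]$blocks[[b]] <- zero_block_weights(4L, cfg_on$d)
    }
  }
  out_on <- model_forward(mdl_on, data)
  expect_equal(out_on$y_hat, out_off$y_hat, tolerance = 1e-12)
})

test_that("run_cv returns per-fold and aggregate reports without leakage", {
  ds <- tiny_dataset()
  res <- run_cv(ds$records, ds$features, "random",
                tiny_model_config(), tiny_train_config(epochs = 2L),
                k = 3L, seed = 1)
  expect_length(res$folds, 3L)
  expect_equal(res$aggregate$rmse,
               mean(vapply(res$folds, `[[`, numeric(1), "rmse")))
  expect_equal(nrow(res$predictions), nrow(ds$records))
  # every record predicted exactly once
  expect_setequal(res$predictions$fold, 1:3)
  res_lco <- run_cv(ds$records, ds$features, "leave_cell_out",
                    tiny_model_config(), tiny_train_config(epochs = 2L),
                    k = 3L, seed = 2)
  for (f in seq_len(3)) {
    test_cells <- unique(res_lco$predictions$cell_line[
      res_lco$predictions$fold == f])
    train_cells <- unique(ds$records$cell_line[
      -res_lco$plan$folds[[f]]])
    expect_length(intersect(test_cells, train_cells), 0L)
  }
})

test_that("noise study reports one correlation per sigma with exact 1 at zero", {
  ds <- tiny_dataset()
  res <- noise_study(ds$records, ds$features, sigmas = c(0, 1.5),
                     mode = "mul", model_cfg = tiny_model_config(),
                     train_cfg = tiny_train_config(epochs = 3L), seed = 1)
  expect_identical(res$sigma, c(0, 1.5))
  expect_equal(res$correlation[1], 1, tolerance = 1e-12)
  expect_lte(res$correlation[2], 1)
  expect_error(noise_study(ds$records, ds$features, sigmas = -1,
                           mode = "add"), class = "domain_error")
})

test_that("rank_unmeasured enumerates, sorts and breaks ties deterministically", {
  ds <- tiny_dataset()
  tr <- train_model(ds$records, ds$features, tiny_model_config(),
                    tiny_train_config(epochs = 2L), seed = 1)
  drugs <- unique(c(ds$records$drug_a, ds$records$drug_b))[1:3]
  cells <- unique(ds$records$cell_line)[1:2]
  out <- rank_unmeasured(drugs, cells, ds$records[0, ], tr, ds$features)
  expect_equal(nrow(out), choose(3, 2) * 2) # 6 candidate trios
  expect_true(all(diff(out$y_hat) <= 1e-12))
  # measured trios are excluded; fully measured space yields nothing
  all_meas <- out[, c("drug_a", "drug_b", "cell_line")]
  all_meas$score <- 0
  out2 <- rank_unmeasured(drugs, cells, all_meas, tr, ds$features)
  expect_equal(nrow(out2), 0L)
  # swapped-order measurements are also recognized
  swapped <- all_meas
  swapped$drug_a <- all_meas$drug_b
  swapped$drug_b <- all_meas$drug_a
  expect_equal(nrow(rank_unmeasured(drugs, cells, swapped, tr, ds$features)),
               0L)
})

test_that("random-split CV is no harder than leave-combination-out on planted data", {
  ds <- tiny_dataset()
  tcfg <- train_config(lr = 1e-3, batch_size = 64L, epochs = 20L,
                       val_frac = 0, patience = Inf)
  pcc <- function(strategy, seed) {
    run_cv(ds$records, ds$features, strategy, tiny_model_config(), tcfg,
           k = 3L, seed = seed)$aggregate$pcc
  }
  rand <- vapply(1:3, function(s) pcc("random", s), numeric(1))
  lco <- vapply(1:3, function(s) pcc("leave_combination_out", s), numeric(1))
  # planted pair-specific interaction effects cannot be learned for unseen
  # combinations, so on average the random split does at least as well
  expect_gte(mean(rand), mean(lco) - 0.05)
})
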