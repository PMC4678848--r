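# Small grids keep the property tests fast; grid contents are asserted
# against the model's own grid report, not against external values.
small_grid <- list(cost_grid = 2^c(-1, 3, 7), gamma_grid = 2^c(-7, -3, 1))

test_that("grid search separates far-apart compositional classes", {
  syn <- synthetic_proteome(n_pos = 100, n_neg = 100, effect_delta = 0.25,
                            seed = 31)
  # separability oracle: leave-one-out nearest-centroid on compositions
  x <- aa_composition(syn$dataset)
  y <- syn$dataset$label
  centroids <- rbind(colMeans(x[y == "DNA_BP", ]),
                     colMeans(x[y == "NON_DNA_BP", ]))
  loo_correct <- vapply(seq_len(nrow(x)), function(i) {
    cl <- y[i] == "DNA_BP"
    n <- sum(y == y[i])
    cen <- centroids
    cen[if (cl) 1 else 2, ] <- (n * centroids[if (cl) 1 else 2, ] -
                                  x[i, ]) / (n - 1)
    d <- colSums((t(cen) - x[i, ])^2)
    (d[1] < d[2]) == cl
  }, logical(1))
  expect_equal(mean(loo_correct), 1)

  fit <- dbp_train(syn$dataset, cost_grid = small_grid$cost_grid,
                   gamma_grid = small_grid$gamma_grid, seed = 31)
  expect_equal(fit$inner_cv_accuracy, 1)
  # selected pair attains the grid maximum by construction
  expect_true(all(fit$inner_cv_accuracy >= fit$grid$accuracy))

  # the positive-class centroid is called DNA-binding with high confidence
  centroid <- matrix(centroids[1, ], nrow = 1,
                     dimnames = list("centroid", AA_CANONICAL))
  pred <- predict(fit, centroid)
  expect_equal(pred$predicted_label, "DNA_BP")
  expect_gt(pred$probability_score, 0.9)
})

test_that("degenerate training inputs are rejected", {
  syn <- synthetic_proteome(n_pos = 30, n_neg = 30, seed = 1)
  only_pos <- syn$dataset[syn$dataset$label == "DNA_BP", ]
  expect_error(dbp_train(only_pos, seed = 1), "both classes")
  expect_error(dbp_train(syn$dataset, inner_folds = 1, seed = 1))
})

test_that("training is deterministic under the seed", {
  syn <- synthetic_proteome(n_pos = 40, n_neg = 40, seed = 8)
  fit1 <- dbp_train(syn$dataset, cost_grid = small_grid$cost_grid,
                    gamma_grid = small_grid$gamma_grid, seed = 5)
  fit2 <- dbp_train(syn$dataset, cost_grid = small_grid$cost_grid,
                    gamma_grid = small_grid$gamma_grid, seed = 5)
  expect_identical(fit1$grid, fit2$grid)
  expect_identical(predict(fit1, syn$dataset), predict(fit2, syn$dataset))

  # with a unique grid maximizer, the selected pair is seed-independent
  fit3 <- dbp_train(syn$dataset, cost_grid = small_grid$cost_grid,
                    gamma_grid = small_grid$gamma_grid, seed = 6)
  if (sum(fit1$grid$accuracy == max(fit1$grid$accuracy)) == 1 &&
      sum(fit3$grid$accuracy == max(fit3$grid$accuracy)) == 1 &&
      max(fit1$grid$accuracy) == max(fit3$grid$accuracy))
    expect_equal(c(fit1$cost, fit1$gamma), c(fit3$cost, fit3$gamma))
})

test_that("probability scores are bounded and empty input is handled", {
  syn <- synthetic_proteome(n_pos = 40, n_neg = 40, seed = 12)
  fit <- dbp_train(syn$dataset, cost_grid = small_grid$cost_grid,
                   gamma_grid = small_grid$gamma_grid, seed = 2)
  pred <- predict(fit, syn$dataset)
  expect_true(all(pred$probability_score >= 0.5))
  expect_true(all(pred$probability_score <= 1))
  expect_equal(pred$probability_score,
               pmax(pred$p_dna_bp, 1 - pred$p_dna_bp))
  non_tie <- pred$p_dna_bp != 0.5
  expect_identical(pred$predicted_label[non_tie],
                   ifelse(pred$p_dna_bp[non_tie] > 0.5,
                          "DNA_BP", "NON_DNA_BP"))
  expect_equal(nrow(predict(fit, syn$dataset[0, ])), 0)
  expect_identical(pred$protein_id, syn$dataset$id)
})

test_that("label swap flips calibrated probabilities within tolerance", {
  syn <- synthetic_proteome(n_pos = 60, n_neg = 60, seed = 7)
  held <- synthetic_proteome(n_pos = 25, n_neg = 25, seed = 70)
  fit <- dbp_train(syn$dataset, cost_grid = small_grid$cost_grid,
                   gamma_grid = small_grid$gamma_grid, seed = 3)
  swapped <- syn$dataset
  swapped$label <- factor(ifelse(swapped$label == "DNA_BP",
                                 "NON_DNA_BP", "DNA_BP"),
                          levels = levels(swapped$label))
  fit_swap <- dbp_train(swapped, cost_grid = small_grid$cost_grid,
                        gamma_grid = small_grid$gamma_grid, seed = 3)
  p <- predict(fit, held$dataset)$p_dna_bp
  p_swap <- predict(fit_swap, held$dataset)$p_dna_bp
  expect_lt(max(abs(p_swap - (1 - p))), 0.05)
})

test_that("no compositional signal gives chance-level inner-CV accuracy", {
  syn <- synthetic_proteome(n_pos = 500, n_neg = 500, effect_delta = 0,
                            seed = 19)
  fit <- dbp_train(syn$dataset, cost_grid = small_grid$cost_grid,
                   gamma_grid = small_grid$gamma_grid, seed = 19)
  expect_gte(fit$inner_cv_accuracy, 0.4)
  expect_lte(fit$inner_cv_accuracy, 0.6)
})

test_that("model files round-trip bit-identically and validate on load", {
  syn <- synthetic_proteome(n_pos = 50, n_neg = 50, seed = 23)
  fit <- dbp_train(syn$dataset, cost_grid = small_grid$cost_grid,
                   gamma_grid = small_grid$gamma_grid, seed = 4)
  pred_before <- predict(fit, syn$dataset)
  path <- tempfile(fileext = ".rds")
  save_model(fit, path)
  reloaded <- load_model(path)
  expect_identical(predict(reloaded, syn$dataset), pred_before)

  # permuted feature order is refused
  broken <- fit
  broken$feature_order <- rev(broken$feature_order)
  bad_path <- tempfile(fileext = ".rds")
  saveRDS(list(format = "plantDBP-model", version = 1L, model = broken),
          bad_path)
  expect_error(load_model(bad_path), "feature order")

  # truncated file is refused
  trunc_path <- tempfile(fileext = ".rds")
  bytes <- readBin(path, "raw", n = file.size(path))
  writeBin(bytes[seq_len(floor(length(bytes) / 3))], trunc_path)
  expect_error(load_model(trunc_path), "cannot read|not a plantDBP")

  # an arbitrary RDS is not a model file
  other <- tempfile(fileext = ".rds")
  saveRDS(list(a = 1), other)
  expect_error(load_model(other), "not a plantDBP model")
})

test_that("print, summary and plot methods run cleanly", {
  syn <- synthetic_proteome(n_pos = 30, n_neg = 30, seed = 2)
  fit <- dbp_train(syn$dataset, cost_grid = small_grid$cost_grid,
                   gamma_grid = small_grid$gamma_grid, seed = 1)
  expect_output(print(fit), "RBF-kernel SVM")
  expect_output(print(summary(fit)), "Grid search")
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})
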