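test_that("metrics reproduce the published model statistics at 2 d.p.", {
  # species-specific model evaluated on its own 100/100 test set
  m <- confusion_metrics(c(TP = 77, FN = 23, FP = 15, TN = 85))
  expect_equal(round(m$accuracy, 2), 0.81)
  expect_equal(round(m$sensitivity, 2), 0.77)
  expect_equal(round(m$specificity, 2), 0.85)
  expect_equal(round(m$mcc, 2), 0.62)

  m <- confusion_metrics(c(TP = 81, FN = 19, FP = 29, TN = 71))
  expect_equal(round(m$accuracy, 2), 0.76)
  expect_equal(round(m$sensitivity, 2), 0.81)
  expect_equal(round(m$specificity, 2), 0.71)
  expect_equal(round(m$mcc, 2), 0.52)

  perfect <- confusion_metrics(c(TP = 50, TN = 50, FP = 0, FN = 0))
  expect_equal(unlist(perfect), c(accuracy = 1, sensitivity = 1,
                                  specificity = 1, mcc = 1))
})

test_that("undefined metrics are NA and empty matrices are errors", {
  m <- confusion_metrics(c(TP = 0, FN = 0, FP = 2, TN = 8))
  expect_true(is.na(m$sensitivity))
  expect_true(is.na(m$mcc))
  expect_equal(m$specificity, 0.8)
  expect_error(confusion_metrics(c(TP = 0, FN = 0, FP = 0, TN = 0)),
               "all zero")
  expect_error(confusion_metrics(c(TP = -1, FN = 1, FP = 1, TN = 1)),
               "negative")
})

test_that("MCC equals the correlation-coefficient oracle on 1000 matrices", {
  set.seed(41)
  for (i in 1:1000) {
    cm <- c(TP = rpois(1, 20), FN = rpois(1, 20), FP = rpois(1, 20),
            TN = rpois(1, 20))
    if (sum(cm) == 0) next
    m <- confusion_metrics(cm)
    # oracle: MCC is the Pearson correlation of the binary truth and
    # prediction vectors, computed by stats::cor on reconstructed labels
    truth <- rep(c(1, 1, 0, 0), cm)
    pred <- rep(c(1, 0, 1, 0), cm)
    oracle <- suppressWarnings(stats::cor(truth, pred))
    if (is.na(oracle)) {
      expect_true(is.na(m$mcc))
    } else {
      expect_equal(m$mcc, oracle, tolerance = 1e-12)
    }
    # inverting every prediction negates the MCC
    inverted <- confusion_metrics(c(TP = cm[["FN"]], FN = cm[["TP"]],
                                    FP = cm[["TN"]], TN = cm[["FP"]]))
    if (!is.na(m$mcc) && !is.na(inverted$mcc))
      expect_equal(inverted$mcc, -m$mcc)
    # accuracy identity: weighted mean of sensitivity and specificity
    P <- cm[["TP"]] + cm[["FN"]]; N <- cm[["TN"]] + cm[["FP"]]
    if (P > 0 && N > 0)
      expect_equal(m$accuracy,
                   (m$sensitivity * P + m$specificity * N) / (P + N))
  }
})

test_that("confusion_matrix counts the four cells correctly", {
  truth <- c("DNA_BP", "DNA_BP", "NON_DNA_BP", "NON_DNA_BP", "DNA_BP")
  pred <- c("DNA_BP", "NON_DNA_BP", "NON_DNA_BP", "DNA_BP", "DNA_BP")
  expect_equal(confusion_matrix(truth, pred),
               c(TP = 2L, FN = 1L, FP = 1L, TN = 1L))
})

test_that("cross-validation folds partition the dataset exactly", {
  syn <- synthetic_proteome(n_pos = 25, n_neg = 25, seed = 14)
  cv <- cross_validate(syn$dataset, k = 5, seed = 14,
                       cost_grid = 2^c(0, 4), gamma_grid = 2^c(-3, 1))
  expect_equal(sort(unique(cv$assignments)), 1:5)
  expect_equal(as.vector(table(cv$assignments)), rep(10, 5))
  # every entry is tested exactly once: pooled matrix totals the dataset
  expect_equal(sum(cv$pooled_cm), 50)
  expect_equal(Reduce(`+`, lapply(cv$folds, `[[`, "cm")), cv$pooled_cm)
  # folds are stratified: 5 of each class per fold
  y <- syn$dataset$label
  expect_true(all(table(cv$assignments, y) == 5))
})

test_that("threshold sweep counts match a brute-force recount", {
  pred <- data.frame(protein_id = paste0("p", 1:3),
                     predicted_label = "DNA_BP",
                     p_dna_bp = c(0.8, 0.85, 0.9),
                     probability_score = c(0.8, 0.85, 0.9),
                     stringsAsFactors = FALSE)
  sw <- threshold_sweep(pred, thresholds = c(0.8, 0.85, 0.9))
  expect_equal(sw$n_total, c(3, 2, 1))
  expect_equal(threshold_sweep(pred, thresholds = 0.95)$n_total, 0)

  # 200 random predictions with annotation classes
  set.seed(51)
  p <- runif(200, 0, 0.5)
  pred <- data.frame(
    protein_id = paste0("p", 1:200),
    predicted_label = sample(c("DNA_BP", "NON_DNA_BP"), 200, TRUE),
    p_dna_bp = 0.5 + p,
    probability_score = 0.5 + p,
    stringsAsFactors = FALSE)
  goa <- sample(c("GOA_DB", "GOA_OTHER", "GOA_UNKNOWN"), 200, TRUE)
  th <- seq(0.5, 0.95, by = 0.05)
  sw <- threshold_sweep(pred, goa, th)
  for (i in seq_along(th)) {
    sel <- pred$predicted_label == "DNA_BP" &
      pred$probability_score >= th[i]
    expect_equal(sw$n_total[i], sum(sel))
    expect_equal(sw$n_goa_db[i], sum(sel & goa == "GOA_DB"))
    expect_equal(sw$n_goa_db[i] + sw$n_goa_other[i] + sw$n_goa_unknown[i],
                 sw$n_total[i])
  }
  # totals are non-increasing in the threshold
  expect_true(all(diff(sw$n_total) <= 0))
})

test_that("expected-fraction threshold selection follows the rule", {
  sw <- data.frame(threshold = c(0.80, 0.85, 0.90),
                   n_total = c(2438, 1459, 659))
  sel <- select_threshold(sw, proteome_size = 34725,
                          expected_fraction = 0.06)
  expect_equal(as.numeric(sel), 0.85)
  expect_equal(attr(sel, "expected_count"), 2084)

  # all counts within expectation: smallest threshold
  sel <- select_threshold(data.frame(threshold = c(0.6, 0.7),
                                     n_total = c(10, 5)), 1000)
  expect_equal(as.numeric(sel), 0.6)
  # none within expectation: largest threshold, with a warning
  expect_warning(
    sel <- select_threshold(data.frame(threshold = c(0.6, 0.7),
                                       n_total = c(900, 800)), 1000),
    "largest threshold")
  expect_equal(as.numeric(sel), 0.7)
  # half-up rounding of the expected count
  expect_equal(attr(select_threshold(data.frame(threshold = 0.9,
                                                n_total = 1), 25),
                    "expected_count"), 2)  # 0.06*25 = 1.5 -> 2
})

test_that("held-out evaluation reports the same metrics as direct counts", {
  syn <- synthetic_proteome(n_pos = 40, n_neg = 40, effect_delta = 0.2,
                            seed = 61)
  test_set <- synthetic_proteome(n_pos = 20, n_neg = 20,
                                 effect_delta = 0.2, seed = 62)
  fit <- dbp_train(syn$dataset, cost_grid = 2^c(0, 4),
                   gamma_grid = 2^c(-3, 1), seed = 6)
  ev <- evaluate_model(fit, test_set$dataset)
  direct <- confusion_matrix(test_set$dataset$label,
                             predict(fit, test_set$dataset)$predicted_label)
  expect_equal(ev$cm, direct)
  expect_equal(ev$metrics, confusion_metrics(direct))
})
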