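#' Train an RBF-kernel SVM DNA-binding protein classifier
#'
#' Fits the package's central model: a soft-margin support vector machine
#' with a radial basis function kernel on 20-dimensional amino-acid
#' composition vectors. Cost and gamma are selected by a grid search using
#' stratified inner cross-validation on the training data; the selected pair
#' is refit on the full training set, and class probabilities are calibrated
#' by fitting a Platt sigmoid to cross-validated decision values under the
#' same seed. Composition fractions are already in \[0, 1\] and are used
#' raw (no additional scaling).
#'
#' @param data A [labeled_dataset()] (protein records with a binary
#'   `label`), or a list with a numeric feature matrix `x` (columns
#'   [AA_CANONICAL]) and factor `y`.
#' @param cost_grid Geometric grid of cost values (default `2^seq(-5, 15,
#'   2)`, the standard libSVM practitioner grid).
#' @param gamma_grid Geometric grid of gamma values (default
#'   `2^seq(-15, 3, 2)`).
#' @param inner_folds Number of stratified folds for grid search and
#'   calibration (default 5).
#' @param seed Integer seed governing fold assignment and calibration.
#' @param provenance Free-text training-set tag stored in the model.
#' @return An object of class `dbp_model`: the fitted SVM, the selected
#'   `cost` and `gamma`, the sigmoid calibration parameters `platt_a`,
#'   `platt_b`, the full `grid` report (inner-CV accuracy per pair), the
#'   fixed `feature_order`, and provenance. Grid ties are broken toward
#'   smaller cost, then smaller gamma (smoother models).
#' @seealso [predict.dbp_model()], [save_model()], [cross_validate()]
#' @examples
#' syn <- synthetic_proteome(n_pos = 30, n_neg = 30, seed = 1)
#' fit <- dbp_train(syn$dataset, cost_grid = 2^c(0, 4),
#'                  gamma_grid = 2^c(-3, 1), seed = 1)
#' predict(fit, syn$dataset[1:3, ])
#' @export
dbp_train <- function(data, cost_grid = 2^seq(-5, 15, 2),
                      gamma_grid = 2^seq(-15, 3, 2), inner_folds = 5,
                      seed = 1, provenance = NULL) {
  stopifnot(length(cost_grid) >= 1, length(gamma_grid) >= 1,
            inner_folds >= 2)
  xy <- as_xy(data)
  x <- xy$x; y <- xy$y
  if (nlevels(droplevels(y)) < 2)
    stop("training data must contain both classes")
  if (any(!is.finite(x))) stop("non-finite feature value in training data")
  if (is.null(provenance))
    provenance <- attr(data, "provenance") %||% "unspecified"

  folds <- local_seed(seed, stratified_folds(y, inner_folds))
  grid <- expand.grid(cost = sort(cost_grid), gamma = sort(gamma_grid))
  grid$accuracy <- vapply(seq_len(nrow(grid)), function(i) {
    correct <- 0L
    for (f in seq_len(inner_folds)) {
      tr <- folds != f
      fit <- svm_fit(x[tr, , drop = FALSE], y[tr],
                     grid$cost[i], grid$gamma[i])
      pred <- predict(fit, x[!tr, , drop = FALSE])
      correct <- correct + sum(pred == y[!tr])
    }
    correct / length(y)
  }, numeric(1))
  # maximize accuracy; ties -> smaller cost, then smaller gamma
  ord <- order(-grid$accuracy, grid$cost, grid$gamma)
  best <- grid[ord[1], ]

  fit <- svm_fit(x, y, best$cost, best$gamma)
  cal <- local_seed(seed + 1L,
    platt_calibrate(x, y, best$cost, best$gamma, inner_folds))

  structure(list(svm = fit, cost = best$cost, gamma = best$gamma,
                 platt_a = cal$a, platt_b = cal$b,
                 inner_cv_accuracy = best$accuracy, grid = grid,
                 feature_order = AA_CANONICAL,
                 positive_label = "DNA_BP",
                 provenance = provenance, seed = seed,
                 n_train = length(y), class_counts = table(y)),
            class = "dbp_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Coerce a labeled dataset / x-y list to a feature matrix + label factor.
as_xy <- function(data) {
  if (is.list(data) && !is.data.frame(data) &&
      all(c("x", "y") %in% names(data))) {
    x <- as.matrix(data$x)
    if (!identical(colnames(x), AA_CANONICAL))
      stop("feature matrix columns must be the canonical residue order")
    return(list(x = x, y = factor(data$y,
                                  levels = c("DNA_BP", "NON_DNA_BP"))))
  }
  stopifnot(is.data.frame(data), "label" %in% names(data))
  list(x = aa_composition(data),
       y = factor(data$label, levels = c("DNA_BP", "NON_DNA_BP")))
}

svm_fit <- function(x, y, cost, gamma) {
  e1071::svm(x, y, type = "C-classification", kernel = "radial",
             cost = cost, gamma = gamma, scale = FALSE)
}

# Stratified fold labels 1..k, randomised within class.
stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in levels(y)) {
    idx <- which(y == cl)
    if (length(idx) < k)
      stop("class ", cl, " has fewer members (", length(idx),
           ") than folds (", k, ")")
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# Decision values oriented so that positive favours DNA_BP.
decision_values <- function(fit, x) {
  d <- attr(predict(fit, x, decision.values = TRUE), "decision.values")
  sign <- if (startsWith(colnames(d)[1], "DNA_BP/")) 1 else -1
  sign * as.numeric(d[, 1])
}

# Platt (2000) sigmoid calibration with the Lin-Weng-Keerthi Newton update,
# fitted to k-fold cross-validated decision values (the libSVM "-b 1"
# procedure, but under an R seed so it is reproducible).
platt_calibrate <- function(x, y, cost, gamma, k) {
  folds <- stratified_folds(y, k)
  f <- numeric(length(y))
  for (fold in seq_len(k)) {
    tr <- folds != fold
    fit <- svm_fit(x[tr, , drop = FALSE], y[tr], cost, gamma)
    f[!tr] <- decision_values(fit, x[!tr, , drop = FALSE])
  }
  # fit on scale-normalised decision values: the sigmoid is reparameterised
  # exactly (a -> a/s), but Newton stays well-conditioned when the selected
  # cost/gamma give decision values far from unit scale
  s <- stats::sd(f)
  if (!is.finite(s) || s < .Machine$double.eps) s <- 1
  fit <- platt_fit(f / s, y == "DNA_BP")
  list(a = fit$a / s, b = fit$b)
}

# Fit p(pos | f) = 1 / (1 + exp(a*f + b)) by regularised maximum likelihood.
platt_fit <- function(f, is_pos, max_iter = 100, min_step = 1e-10,
                      sigma = 1e-12) {
  n_pos <- sum(is_pos); n_neg <- sum(!is_pos)
  t <- ifelse(is_pos, (n_pos + 1) / (n_pos + 2), 1 / (n_neg + 2))
  a <- 0; b <- log((n_neg + 1) / (n_pos + 1))
  fval <- platt_nll(f, t, a, b)
  for (it in seq_len(max_iter)) {
    fApB <- a * f + b
    p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)),
                1 / (1 + exp(fApB)))
    q <- 1 - p
    d1 <- t - p
    d2 <- p * q
    g1 <- sum(f * d1); g2 <- sum(d1)
    if (abs(g1) < 1e-5 && abs(g2) < 1e-5) break
    h11 <- sum(f * f * d2) + sigma
    h22 <- sum(d2) + sigma
    h21 <- sum(f * d2)
    det <- h11 * h22 - h21 * h21
    dA <- -(h22 * g1 - h21 * g2) / det
    dB <- -(-h21 * g1 + h11 * g2) / det
    gd <- g1 * dA + g2 * dB
    step <- 1
    while (step >= min_step) {
      new_a <- a + step * dA; new_b <- b + step * dB
      new_f <- platt_nll(f, t, new_a, new_b)
      if (new_f < fval + 1e-4 * step * gd) {
        a <- new_a; b <- new_b; fval <- new_f
        break
      }
      step <- step / 2
    }
    if (step < min_step) break
  }
  list(a = a, b = b)
}

platt_nll <- function(f, t, a, b) {
  fApB <- a * f + b
  sum(ifelse(fApB >= 0, t * fApB + log1p(exp(-fApB)),
             (t - 1) * fApB + log1p(exp(fApB))))
}

#' Predict DNA-binding class and probability scores
#'
#' Applies a trained model to new protein records. Each prediction carries
#' `p_dna_bp`, the calibrated posterior probability of the DNA-binding
#' class, and `probability_score = max(p_dna_bp, 1 - p_dna_bp)`, the
#' posterior of the *predicted* class, which by construction lies in
#' \[0.5, 1.0\] and is the quantity the probability threshold (e.g. 0.85)
#' is applied to.
#'
#' @param object A `dbp_model`.
#' @param newdata Protein record data frame, or a feature matrix with the
#'   canonical column order.
#' @param ... Unused.
#' @return A data frame with columns `protein_id`, `predicted_label`,
#'   `p_dna_bp`, `probability_score`, one row per input record in input
#'   order.
#' @export
predict.dbp_model <- function(object, newdata, ...) {
  if (is.matrix(newdata)) {
    if (!identical(colnames(newdata), object$feature_order))
      stop("feature matrix columns do not match the model's feature order")
    x <- newdata
    ids <- rownames(newdata) %||% paste0("seq", seq_len(nrow(newdata)))
  } else {
    if (nrow(newdata) == 0)
      return(data.frame(protein_id = character(),
                        predicted_label = character(),
                        p_dna_bp = numeric(),
                        probability_score = numeric(),
                        stringsAsFactors = FALSE))
    x <- aa_composition(newdata)
    ids <- newdata$id
  }
  f <- decision_values(object$svm, x)
  fApB <- object$platt_a * f + object$platt_b
  p <- ifelse(fApB >= 0, exp(-fApB) / (1 + exp(-fApB)), 1 / (1 + exp(fApB)))
  label <- ifelse(p > 0.5 | (p == 0.5 & f > 0), "DNA_BP", "NON_DNA_BP")
  data.frame(protein_id = ids, predicted_label = label, p_dna_bp = p,
             probability_score = pmax(p, 1 - p), stringsAsFactors = FALSE)
}

#' @export
print.dbp_model <- function(x, ...) {
  cat("DNA-binding protein classifier (RBF-kernel SVM)\n")
  cat("  training set:", x$provenance, "(", x$n_train, "proteins:",
      paste(names(x$class_counts), as.integer(x$class_counts),
            collapse = ", "), ")\n")
  cat("  selected cost =", format(x$cost), ", gamma =", format(x$gamma),
      "(inner-CV accuracy", round(x$inner_cv_accuracy, 3), ")\n")
  cat("  probability calibration: sigmoid a =", signif(x$platt_a, 4),
      ", b =", signif(x$platt_b, 4), "\n")
  invisible(x)
}

#' @export
summary.dbp_model <- function(object, ...) {
  structure(list(model = object), class = "summary.dbp_model")
}

#' @export
print.summary.dbp_model <- function(x, ...) {
  m <- x$model
  print(m)
  cat("\nGrid search (top 5 of", nrow(m$grid), "cost/gamma pairs):\n")
  ord <- order(-m$grid$accuracy, m$grid$cost, m$grid$gamma)
  print(utils::head(m$grid[ord, ], 5), row.names = FALSE)
  cat("\nSupport vectors:", nrow(m$svm$SV), "\n")
  invisible(x)
}

#' Plot the grid-search accuracy surface
#'
#' Heatmap of inner-cross-validation accuracy over the cost/gamma grid,
#' with the selected pair marked.
#'
#' @param x A `dbp_model`.
#' @param ... Passed to [graphics::image()].
#' @export
plot.dbp_model <- function(x, ...) {
  costs <- sort(unique(x$grid$cost))
  gammas <- sort(unique(x$grid$gamma))
  z <- matrix(NA_real_, length(costs), length(gammas))
  z[cbind(match(x$grid$cost, costs), match(x$grid$gamma, gammas))] <-
    x$grid$accuracy
  graphics::image(log2(costs), log2(gammas), z,
                  xlab = "log2(cost)", ylab = "log2(gamma)",
                  main = "Grid-search inner-CV accuracy", ...)
  graphics::points(log2(x$cost), log2(x$gamma), pch = 4, cex = 2, lwd = 2)
  invisible(x)
}

#' Save / load a trained model
#'
#' The model file is a single self-describing RDS archive embedding the SVM
#' parameters, the calibration sigmoid, the fixed feature order and the
#' training provenance. Loading verifies the format version and the feature
#' order, and refuses a file whose feature order does not match the
#' canonical residue ordering, so feature columns can never silently
#' permute. A reloaded model reproduces predictions bit-identically.
#'
#' @param model A `dbp_model`.
#' @param path File path.
#' @return `save_model`: `path`, invisibly. `load_model`: the `dbp_model`.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "dbp_model"))
  saveRDS(list(format = "plantDBP-model", version = 1L, model = model),
          path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- tryCatch(readRDS(path),
                  error = function(e) stop("cannot read model file ", path,
                                           ": ", conditionMessage(e)))
  if (!is.list(obj) || !identical(obj$format, "plantDBP-model"))
    stop("not a plantDBP model file: ", path)
  if (!identical(obj$version, 1L))
    stop("unsupported model file version: ", obj$version)
  model <- obj$model
  if (!identical(model$feature_order, AA_CANONICAL))
    stop("model file feature order does not match the canonical ",
         "residue ordering")
  model
}

#' Write predictions as a TSV artifact
#'
#' @param predictions Output of [predict.dbp_model()], optionally with a
#'   `goa_class` column.
#' @param path Output path.
#' @param metadata Optional metadata for the comment header.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(predictions, path, metadata = NULL) {
  write_tsv(predictions, path, metadata = metadata)
}
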