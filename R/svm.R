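## Linear SVM with Kullback-Leibler classification error.
##
## The classifier is a soft-margin linear-kernel C-SVC (cost 1 by
## default) solved by an SMO routine on a precomputed Gram matrix
## (src/smo.cpp). Working on the Gram matrix lets backward elimination
## drop a feature by a rank-1 downdate instead of refitting from the
## feature matrix, which makes exhaustive candidate evaluation tractable.
## Features are standardized with training-set statistics only; the
## standardization travels with the frozen model.

# column standardization from training data; constant columns get scale 1
colStats <- function(x) {
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[!is.finite(scl) | scl == 0] <- 1
  list(center = ctr, scale = scl)
}

applyStats <- function(x, st)
  sweep(sweep(x, 2, st$center), 2, st$scale, "/")

# +1/-1 encoding, positive class first
encodeLabels <- function(labels, groups) {
  y <- ifelse(labels == groups[1], 1L, ifelse(labels == groups[2], -1L, NA))
  if (anyNA(y)) stopf("labels outside the contrast: %s",
                      paste(unique(labels[is.na(y)]), collapse = ", "))
  as.integer(y)
}

# raw SMO fit from a standardized feature matrix
smoFromFeatures <- function(z, y, cost, eps = 1e-3) {
  fit <- .smo_solve(tcrossprod(z), y, cost, eps)
  fit$coef <- fit$alpha * y              # alpha_i y_i
  fit$w <- drop(crossprod(z, fit$coef))
  fit
}

#' Train a frozen linear SVM on an antibody panel
#'
#' Fits a linear-kernel C-SVC on the training samples, standardizing each
#' panel antibody with training-set mean/sd (stored in the model). The
#' decision value of a sample x is \code{w . standardized(x) + bias};
#' positive values vote for the first-listed group. The returned model is
#' frozen: evaluation never changes it.
#'
#' @param m an \linkS4class{ArrayExpressionSet} (or antibodies x samples
#'   matrix) restricted to the training samples
#' @param groups character(2); the first is the positive class
#' @param panel antibody ids to use as features (default: all)
#' @param labels named sample -> group assignment; defaults to metadata
#' @param cost SVM cost of constraints violation (default 1)
#' @return an \linkS4class{SvmModel}
#' @export
trainLinearSvm <- function(m, groups, panel = NULL, labels = NULL,
                           cost = 1.0) {
  v <- if (is.matrix(m)) m else exprValues(m)
  if (is.null(labels)) {
    if (is.matrix(m)) stopf("labels required when passing a bare matrix")
    labels <- setNames(sampleData(m)$group, colnames(m))
  }
  if (is.null(panel)) panel <- rownames(v)
  if (!all(panel %in% rownames(v)))
    stopf("panel antibodies missing from the matrix")
  x <- t(v[panel, , drop = FALSE])
  y <- encodeLabels(labels[rownames(x)], groups)
  if (length(unique(y)) < 2L) stopf("training data contains a single class")
  st <- colStats(x)
  z <- applyStats(x, st)
  fit <- smoFromFeatures(z, y, cost)
  new("SvmModel", panel = panel, weights = setNames(fit$w, panel),
      bias = -fit$rho, cost = cost, center = st$center, scale = st$scale,
      positiveClass = groups[1], negativeClass = groups[2],
      trainingSamples = rownames(x))
}

#' @describeIn trainLinearSvm decision values of a frozen model on new
#'   samples
#' @param x an \linkS4class{SvmModel}
#' @param newdata \linkS4class{ArrayExpressionSet} or antibodies x samples
#'   matrix
#' @export
setMethod("decisionValues", "SvmModel", function(x, newdata) {
  v <- if (is.matrix(newdata)) newdata else exprValues(newdata)
  if (!all(x@panel %in% rownames(v)))
    stopf("newdata lacks panel antibodies")
  z <- applyStats(t(v[x@panel, , drop = FALSE]),
                  list(center = x@center, scale = x@scale))
  drop(z %*% x@weights) + x@bias
})

#' Cross-validated decision values
#'
#' Each sample's decision value comes from the stratified-fold model that
#' did not train on it, so downstream error estimates are not
#' resubstitution-biased. Folds are dealt by a seeded stratified
#' round-robin; \code{kFolds = n} gives leave-one-out.
#'
#' @param m \linkS4class{ArrayExpressionSet} or antibodies x samples matrix
#'   (training samples only)
#' @param groups character(2), positive class first
#' @param panel antibody ids used as features
#' @param labels named sample -> group map (defaults to metadata)
#' @param kFolds number of stratified folds (default 5; reduced with a
#'   warning if a class is smaller)
#' @param cost SVM cost parameter
#' @param seed fold-assignment seed
#' @return named decision-value vector over the input samples
#' @export
cvDecisionValues <- function(m, groups, panel = NULL, labels = NULL,
                             kFolds = 5L, cost = 1.0, seed = 1L) {
  v <- if (is.matrix(m)) m else exprValues(m)
  if (is.null(labels)) {
    if (is.matrix(m)) stopf("labels required when passing a bare matrix")
    labels <- setNames(sampleData(m)$group, colnames(m))
  }
  if (is.null(panel)) panel <- rownames(v)
  x <- t(v[panel, , drop = FALSE])
  y <- encodeLabels(labels[rownames(x)], groups)
  minClass <- min(table(y))
  if (minClass < 2L) stopf("each class needs at least 2 samples")
  k <- as.integer(kFolds)
  if (k > nrow(x)) { k <- nrow(x) }
  folds <- stratifiedFolds(y, k, seed)
  d <- setNames(rep(NA_real_, nrow(x)), rownames(x))
  for (f in sort(unique(folds))) {
    tr <- folds != f; te <- folds == f
    if (length(unique(y[tr])) < 2L)
      stopf("fold %d leaves a single-class training set; reduce kFolds", f)
    st <- colStats(x[tr, , drop = FALSE])
    ztr <- applyStats(x[tr, , drop = FALSE], st)
    zte <- applyStats(x[te, , drop = FALSE], st)
    fit <- smoFromFeatures(ztr, y[tr], cost)
    d[te] <- drop(zte %*% fit$w) - fit$rho
  }
  d
}

#' Kullback-Leibler classification error
#'
#' Decision values are mapped to class-1 probabilities by the logistic
#' link p = 1 / (1 + exp(-d)), clipped to [1e-6, 1 - 1e-6]; the error is
#' the total Kullback-Leibler divergence from the point-mass truth to the
#' prediction, i.e. the cross-entropy
#' \deqn{\sum_i -\log p_i [y_i = +1] - \log(1 - p_i) [y_i = -1]}
#' in nats. Lower is better; a maximally uncertain classifier (d = 0)
#' contributes log 2 per sample.
#'
#' @param d numeric decision values
#' @param y labels: +1/-1 (or logical, TRUE = positive)
#' @return K-L error (nats)
#' @export
klError <- function(d, y) {
  if (!length(d)) stopf("empty decision-value vector")
  if (is.logical(y)) y <- ifelse(y, 1L, -1L)
  if (any(!is.finite(d))) stopf("decision values must be finite")
  p <- pmin(pmax(stats::plogis(d), 1e-6), 1 - 1e-6)
  -sum(log(ifelse(y > 0, p, 1 - p)))
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the Mann-Whitney statistic on
#' decision values (ties counted 1/2); invariant under monotone transforms
#' of the decision values.
#'
#' @param d decision values
#' @param y labels, +1/-1 or logical
#' @return AUC in [0, 1]
#' @export
aucRank <- function(d, y) {
  if (is.logical(y)) y <- ifelse(y, 1L, -1L)
  npos <- sum(y > 0); nneg <- sum(y < 0)
  if (npos == 0L || nneg == 0L)
    stopf("AUC undefined: both classes must be present")
  r <- rank(d)
  (sum(r[y > 0]) - npos * (npos + 1) / 2) / (npos * nneg)
}

#' Evaluate a frozen panel model on an independent test set
#'
#' Computes test-set decision values, the rank-statistic AUC, and
#' sensitivity / specificity / PPV / NPV (percent) from the confusion
#' matrix at the given decision-value threshold (default 0; values
#' strictly above the threshold predict the positive class). If the test
#' set lacks one class the AUC is reported as NA with a warning while the
#' point metrics are still computed.
#'
#' @param model a frozen \linkS4class{SvmModel}
#' @param mTest test-set \linkS4class{ArrayExpressionSet} or matrix
#'   (must be disjoint from the training samples)
#' @param labels named sample -> group map (defaults to metadata)
#' @param threshold decision-value cutoff (default 0)
#' @return a \linkS4class{PanelEvaluation}
#' @export
evaluatePanel <- function(model, mTest, labels = NULL, threshold = 0) {
  if (is.null(labels)) {
    if (is.matrix(mTest)) stopf("labels required when passing a bare matrix")
    labels <- setNames(sampleData(mTest)$group, colnames(mTest))
  }
  ids <- if (is.matrix(mTest)) colnames(mTest) else colnames(mTest)
  overlap <- intersect(ids, model@trainingSamples)
  if (length(overlap))
    warnf("%d test sample(s) were in the training set", length(overlap))
  d <- decisionValues(model, mTest)
  y <- encodeLabels(labels[names(d)],
                    c(model@positiveClass, model@negativeClass))
  tp <- sum(d > threshold & y > 0); fn <- sum(d <= threshold & y > 0)
  tn <- sum(d <= threshold & y < 0); fp <- sum(d > threshold & y < 0)
  auc <- if (sum(y > 0) == 0L || sum(y < 0) == 0L) {
    warnf("test set lacks one class; AUC undefined")
    NA_real_
  } else aucRank(d, y)
  pct <- function(a, b) if (a + b == 0) NA_real_ else 100 * a / (a + b)
  new("PanelEvaluation", auc = auc,
      sensitivity = pct(tp, fn), specificity = pct(tn, fp),
      ppv = pct(tp, fp), npv = pct(tn, fn),
      decisionValues = d, threshold = threshold,
      confusion = c(TP = tp, FP = fp, TN = tn, FN = fn),
      positiveClass = model@positiveClass)
}
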