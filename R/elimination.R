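## Signature discovery: repeated stratified splits, exhaustive SVM
## backward elimination ranked by cross-validated Kullback-Leibler error,
## endurance scoring, consensus panels, K-L-minimum panel sizing and
## frozen-model test-set evaluation.

#' Repeated stratified train/test splits
#'
#' Per repeat and per group, floor(trainFraction x group size) samples go
#' to the training set and the rest to the test set; assignments are drawn
#' from seeded, repeat-specific streams.
#'
#' @param sheet a \linkS4class{SampleSheet} (or any data.frame with
#'   \code{sample_id} and \code{group})
#' @param groups character(2): the contrasted groups
#' @param trainFraction training share per group (default 2/3)
#' @param nRepeats number of independent splits (default 10)
#' @param seed master seed
#' @return a \linkS4class{SplitSpec} whose \code{assignments} list holds,
#'   per repeat, a named vector of "train"/"test" over the contrast samples
#' @export
stratifiedSplit <- function(sheet, groups, trainFraction = 2 / 3,
                            nRepeats = 10L, seed = 1L) {
  df <- if (is(sheet, "SampleSheet")) sampleData(sheet) else as.data.frame(sheet)
  df <- df[df$group %in% groups, , drop = FALSE]
  sizes <- table(factor(df$group, levels = groups))
  if (any(sizes < 3L))
    stopf("group '%s' has fewer than 3 samples", names(sizes)[sizes < 3][1])
  assignments <- lapply(seq_len(nRepeats), function(r) {
    a <- setNames(rep("test", nrow(df)), df$sample_id)
    withSeed(childSeed(seed, "split", r), {
      for (g in groups) {
        ids <- df$sample_id[df$group == g]
        a[sample(ids, floor(trainFraction * length(ids)))] <- "train"
      }
    })
    a
  })
  new("SplitSpec", trainFraction = trainFraction,
      nRepeats = as.integer(nRepeats), seed = as.integer(seed),
      groups = groups, assignments = assignments)
}

#' Exhaustive SVM backward elimination by Kullback-Leibler error
#'
#' Starting from the full panel, each round evaluates every remaining
#' antibody by removing it, recomputing stratified cross-validated
#' decision values for the reduced panel, and measuring the K-L error;
#' the antibody whose removal yields the smallest error is eliminated
#' (ties broken by antibody id). Fold assignments are fixed within a
#' round (seed-derived per round) so all candidates are compared on
#' identical folds. Continues until one antibody remains; the survivor is
#' assigned the last removal position so the order is a full permutation.
#'
#' Internally, per fold the standardized Gram matrix of the current panel
#' is computed once and each candidate's kernel is obtained by a rank-1
#' downdate, so the exhaustive search costs O(N^2) SMO solves, not
#' O(N^2) feature-matrix refits.
#'
#' @param m training-set \linkS4class{ArrayExpressionSet} or antibodies x
#'   samples matrix
#' @param groups character(2), positive class first
#' @param labels named sample -> group map (defaults to metadata)
#' @param startPanel antibodies to start from (default: all rows)
#' @param kFolds stratified folds for the internal decision values
#' @param cost SVM cost parameter
#' @param seed master seed for the fold streams
#' @param repeatIndex stored in the trace for bookkeeping
#' @param method \code{"exhaustive"} (the default, faithful procedure) or
#'   \code{"weight"}, a fast approximation that removes the antibody with
#'   the smallest mean absolute standardized SVM weight across folds
#'   instead of refitting every candidate; the K-L curve is still measured
#'   by cross-validation on the surviving panel after each removal
#' @return an \linkS4class{EliminationTrace}; \code{klCurve[s]} is the
#'   K-L error of the surviving panel of size s (s = N is the full panel)
#' @export
backwardEliminate <- function(m, groups, labels = NULL, startPanel = NULL,
                              kFolds = 5L, cost = 1.0, seed = 1L,
                              repeatIndex = 1L,
                              method = c("exhaustive", "weight")) {
  method <- match.arg(method)
  v <- if (is.matrix(m)) m else exprValues(m)
  if (is.null(labels)) {
    if (is.matrix(m)) stopf("labels required when passing a bare matrix")
    labels <- setNames(sampleData(m)$group, colnames(m))
  }
  if (is.null(startPanel)) startPanel <- rownames(v)
  if (length(startPanel) < 2L) stopf("need at least 2 antibodies to eliminate")
  x <- t(v[startPanel, , drop = FALSE])
  y <- encodeLabels(labels[rownames(x)], groups)
  n <- nrow(x)
  k <- min(as.integer(kFolds), n)

  current <- startPanel
  N <- length(current)
  klCurve <- rep(NA_real_, N)
  removed <- character(0)

  for (round in seq_len(N - 1L)) {
    folds <- stratifiedFolds(y, k, childSeed(seed, "folds", round))
    ufolds <- sort(unique(folds))
    # per-fold standardized panels, Gram and cross-Gram for current panel
    fold_data <- lapply(ufolds, function(f) {
      tr <- folds != f; te <- folds == f
      st <- colStats(x[tr, current, drop = FALSE])
      ztr <- applyStats(x[tr, current, drop = FALSE], st)
      zte <- applyStats(x[te, current, drop = FALSE], st)
      Ktr <- tcrossprod(ztr)
      ytr <- y[tr]
      # base fit on the untouched panel; candidates warm-start from it
      fit0 <- .smo_solve(Ktr, ytr, cost)
      list(tr = which(tr), te = which(te), ztr = ztr, zte = zte,
           Ktr = Ktr, Kte = zte %*% t(ztr), ytr = ytr, alpha0 = fit0$alpha,
           d0 = drop((zte %*% t(ztr)) %*% (fit0$alpha * ytr)) - fit0$rho)
    })
    if (round == 1L) {            # K-L of the untouched full panel
      d0 <- rep(NA_real_, n)
      for (fd in fold_data) d0[fd$te] <- fd$d0
      klCurve[N] <- klError(d0, y)
    }
    if (method == "exhaustive") {
      kl <- rep(NA_real_, length(current))
      d <- rep(NA_real_, n)
      for (a in seq_along(current)) {
        for (fd in fold_data) {
          ktr <- fd$Ktr - tcrossprod(fd$ztr[, a])
          kte <- fd$Kte - fd$zte[, a] %o% fd$ztr[, a]
          fit <- .smo_solve(ktr, fd$ytr, cost, alpha0 = fd$alpha0)
          d[fd$te] <- drop(kte %*% (fit$alpha * fd$ytr)) - fit$rho
        }
        kl[a] <- klError(d, y)
      }
      best <- orderWithIdTies(kl, current)[1]
      klCurve[length(current) - 1L] <- kl[best]
    } else {
      # approximation: drop the feature the base models weight least
      w <- rep(0, length(current))
      for (fd in fold_data)
        w <- w + abs(drop(crossprod(fd$ztr, fd$alpha0 * fd$ytr)))
      best <- orderWithIdTies(w, current)[1]
      d <- rep(NA_real_, n)
      for (fd in fold_data) {
        ktr <- fd$Ktr - tcrossprod(fd$ztr[, best])
        kte <- fd$Kte - fd$zte[, best] %o% fd$ztr[, best]
        fit <- .smo_solve(ktr, fd$ytr, cost, alpha0 = fd$alpha0)
        d[fd$te] <- drop(kte %*% (fit$alpha * fd$ytr)) - fit$rho
      }
      klCurve[length(current) - 1L] <- klError(d, y)
    }
    removed <- c(removed, current[best])
    current <- current[-best]
  }
  new("EliminationTrace", removalOrder = c(removed, current),
      klCurve = klCurve, repeatIndex = as.integer(repeatIndex))
}

#' Endurance scores over elimination repeats
#'
#' An antibody removed at position n has endurance n (1 = first out, N =
#' final survivor); its score is the mean endurance over traces.
#'
#' @param traces list of \linkS4class{EliminationTrace} over the same
#'   antibody set
#' @return an \linkS4class{AntibodyScore}
#' @export
antibodyScores <- function(traces) {
  if (!length(traces)) stopf("no traces")
  abs <- sort(removalOrder(traces[[1]]))
  endur <- vapply(traces, function(tr) {
    ro <- removalOrder(tr)
    if (!identical(sort(ro), abs))
      stopf("traces cover different antibody sets")
    match(abs, ro)
  }, integer(length(abs)))
  endur <- matrix(endur, nrow = length(abs),
                  dimnames = list(abs, paste0("repeat", seq_along(traces))))
  new("AntibodyScore", scores = setNames(rowMeans(endur), abs),
      endurances = endur)
}

#' Antibody-to-antigen annotation table
#'
#' Maps antibody clones to their target antigens (several clones may share
#' one antigen), used to count nonredundant markers in a panel.
#'
#' @param antibody_id character vector of unique clone identifiers
#' @param antigen target antigen per clone (non-empty)
#' @param clone_suffix optional clone label within an antigen
#' @return validated data.frame with the three columns
#' @export
antibodyAnnotation <- function(antibody_id, antigen, clone_suffix = "") {
  if (anyDuplicated(antibody_id)) stopf("antibody_id must be unique")
  if (any(!nzchar(antigen))) stopf("antigen names must be non-empty")
  data.frame(antibody_id = as.character(antibody_id),
             antigen = as.character(antigen),
             clone_suffix = as.character(rep_len(clone_suffix,
                                                 length(antibody_id))),
             stringsAsFactors = FALSE)
}

#' Consensus panel from endurance scores
#'
#' The k antibodies with the highest mean endurance (ties broken by
#' antibody id). With an annotation mapping antibodies to antigens, the
#' number of nonredundant markers (distinct antigens) is reported.
#'
#' @param scores an \linkS4class{AntibodyScore}
#' @param k panel size (default 25)
#' @param annotation optional data.frame with \code{antibody_id} and
#'   \code{antigen}
#' @return list with \code{panel} and \code{n_nonredundant}
#' @export
consensusPanel <- function(scores, k = 25L, annotation = NULL) {
  s <- scores@scores
  if (k > length(s)) stopf("k = %d exceeds %d antibodies", k, length(s))
  panel <- names(s)[orderWithIdTies(s, names(s), decreasing = TRUE)][seq_len(k)]
  nnr <- if (is.null(annotation)) length(unique(panel)) else {
    idx <- match(panel, annotation$antibody_id)
    if (anyNA(idx)) stopf("annotation lacks antibodies: %s",
                          paste(panel[is.na(idx)], collapse = ", "))
    length(unique(annotation$antigen[idx]))
  }
  list(panel = panel, n_nonredundant = nnr)
}

#' Panel at the Kullback-Leibler minimum
#'
#' The panel size minimizing the K-L curve of a trace (ties resolved in
#' favor of the smaller panel) and the surviving antibodies at that size.
#'
#' @param trace an \linkS4class{EliminationTrace}
#' @return list with \code{panel_size}, \code{kl_min}, \code{panel}
#' @export
klMinimumPanel <- function(trace) {
  curve <- klCurve(trace)
  s <- which.min(curve)                 # first index = smallest size on ties
  ro <- removalOrder(trace)
  N <- length(ro)
  list(panel_size = as.integer(s), kl_min = unname(curve[s]),
       panel = ro[(N - s + 1L):N])
}

#' Full signature-discovery procedure for one contrast
#'
#' For each of \code{nRepeats} stratified 2/3 splits: backward elimination
#' on the training set, a frozen linear SVM on the last-\code{panelSize}
#' surviving antibodies, and evaluation on the held-out test set. Scores
#' are aggregated into a consensus panel and the per-repeat metrics are
#' summarized.
#'
#' @param m preprocessed \linkS4class{ArrayExpressionSet}
#' @param groups character(2), positive class first
#' @param labels named sample -> group map (defaults to metadata group)
#' @param nRepeats number of split repeats (default 10)
#' @param trainFraction training share per group (default 2/3)
#' @param panelSize frozen-model panel size (default 25, capped at the
#'   antibody count)
#' @param kFolds internal CV folds during elimination
#' @param cost SVM cost parameter
#' @param seed master seed (split and fold streams are derived from it)
#' @return list with \code{traces}, \code{scores}, \code{consensus},
#'   \code{evaluations}, \code{split} and \code{summary} (mean AUC / SN /
#'   SP / PPV / NPV over repeats)
#' @export
runSignatureDiscovery <- function(m, groups, labels = NULL, nRepeats = 10L,
                                  trainFraction = 2 / 3, panelSize = 25L,
                                  kFolds = 5L, cost = 1.0, seed = 1L) {
  if (is.null(labels)) labels <- setNames(sampleData(m)$group, colnames(m))
  keep <- colnames(m)[labels[colnames(m)] %in% groups]
  mm <- m[, keep]
  lab <- labels[keep]
  panelSize <- min(as.integer(panelSize), nrow(mm))
  split <- stratifiedSplit(data.frame(sample_id = keep, group = lab,
                                      stringsAsFactors = FALSE),
                           groups, trainFraction = trainFraction,
                           nRepeats = nRepeats, seed = seed)
  traces <- list(); evals <- list()
  for (r in seq_len(split@nRepeats)) {
    a <- split@assignments[[r]]
    trIds <- names(a)[a == "train"]; teIds <- names(a)[a == "test"]
    trace <- backwardEliminate(mm[, trIds], groups, labels = lab[trIds],
                               kFolds = kFolds, cost = cost,
                               seed = childSeed(seed, "elim", r),
                               repeatIndex = r)
    panel <- utils::tail(removalOrder(trace), panelSize)
    model <- trainLinearSvm(mm[, trIds], groups, panel = panel,
                            labels = lab[trIds], cost = cost)
    evals[[r]] <- evaluatePanel(model, mm[, teIds], labels = lab[teIds])
    traces[[r]] <- trace
  }
  scores <- antibodyScores(traces)
  metric <- function(slot) vapply(evals, function(e) methods::slot(e, slot),
                                  numeric(1))
  list(traces = traces, scores = scores,
       consensus = consensusPanel(scores, k = panelSize),
       evaluations = evals, split = split,
       summary = list(n_repeats = split@nRepeats,
                      mean_auc = mean(metric("auc")),
                      mean_sensitivity = mean(metric("sensitivity")),
                      mean_specificity = mean(metric("specificity")),
                      mean_ppv = mean(metric("ppv")),
                      mean_npv = mean(metric("npv")),
                      auc = metric("auc")))
}
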