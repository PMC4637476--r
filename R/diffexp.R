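## Differential expression: row-wise two-group Student t-tests with
## Benjamini-Hochberg q-values and log10 fold changes, one-way ANOVA,
## significance fractions, ranked top tables, and p-filtered PCA.

# Vectorized per-row equal-variance two-sided t-test. Degenerate rows
# (zero pooled variance): equal means -> t = 0, p = 1; unequal means ->
# p = 0, flagged.
rowTtest <- function(v, g1idx, g2idx) {
  x <- v[, g1idx, drop = FALSE]; y <- v[, g2idx, drop = FALSE]
  n1 <- rowSums(!is.na(x)); n2 <- rowSums(!is.na(y))
  m1 <- rowMeans(x, na.rm = TRUE); m2 <- rowMeans(y, na.rm = TRUE)
  ss1 <- rowSums((x - m1)^2, na.rm = TRUE)
  ss2 <- rowSums((y - m2)^2, na.rm = TRUE)
  df <- n1 + n2 - 2
  sp2 <- (ss1 + ss2) / df
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  t <- (m1 - m2) / se
  p <- 2 * pt(-abs(t), df)
  degen <- sp2 <= 0
  t[degen & m1 == m2] <- 0
  p[degen & m1 == m2] <- 1
  p[degen & m1 != m2] <- 0
  list(t = t, p = p, df = df, fc = m1 - m2, degenerate = degen & m1 != m2)
}

# Vectorized per-row one-way fixed-effects ANOVA across >= 2 groups.
rowAnova <- function(v, groups) {
  groups <- as.character(groups)
  keep <- !is.na(groups)
  v <- v[, keep, drop = FALSE]; groups <- groups[keep]
  lv <- sort(unique(groups))
  k <- length(lv)
  if (k < 2L) stopf("ANOVA needs at least 2 groups")
  n <- ncol(v)
  grand <- rowMeans(v, na.rm = TRUE)
  ssb <- 0; ssw <- 0
  for (g in lv) {
    idx <- which(groups == g)
    gm <- rowMeans(v[, idx, drop = FALSE], na.rm = TRUE)
    ssb <- ssb + length(idx) * (gm - grand)^2
    ssw <- ssw + rowSums((v[, idx, drop = FALSE] - gm)^2, na.rm = TRUE)
  }
  df1 <- k - 1; df2 <- n - k
  f <- (ssb / df1) / (ssw / df2)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  zero <- ssw <= 0 & ssb <= 0          # no variance at all: p = 1 convention
  f[zero] <- 0; p[zero] <- 1
  sep <- ssw <= 0 & ssb > 0            # perfectly separated groups
  p[sep] <- 0; f[sep] <- Inf
  list(F = f, p = p, df1 = df1, df2 = df2)
}

#' Benjamini-Hochberg step-up q-values
#'
#' @param p numeric vector of p-values in [0, 1]
#' @return q-values in the input order
#' @export
bhAdjust <- function(p) {
  if (!length(p)) return(numeric(0))
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stopf("p-values must be in [0, 1] and non-missing")
  stats::p.adjust(p, method = "BH")
}

#' Two-group differential expression table
#'
#' Row-wise two-sided equal-variance Student t-tests with BH q-values and
#' log10 fold changes (group1 mean minus group2 mean; positive = up in
#' group1).
#'
#' @param m an \linkS4class{ArrayExpressionSet} (log10 stage)
#' @param labels named group assignment (sample -> label), or NULL to use
#'   the \code{group} column of the attached metadata
#' @param groups character(2): the two labels to compare (first = "up")
#' @param welch use Welch's unequal-variance test instead of the pooled
#'   test
#' @return data.frame: antibody_id, t_stat, p_value, q_value, log10_fc,
#'   fold_change (10^|log10_fc| signed by direction), direction (up/down)
#' @export
ttestTable <- function(m, groups, labels = NULL, welch = FALSE) {
  v <- exprValues(m)
  if (is.null(labels)) labels <- setNames(sampleData(m)$group, colnames(m))
  lab <- labels[colnames(v)]
  g1 <- which(lab == groups[1]); g2 <- which(lab == groups[2])
  if (length(g1) < 2L || length(g2) < 2L)
    stopf("need at least 2 samples per group (%s: %d, %s: %d)",
          groups[1], length(g1), groups[2], length(g2))
  res <- if (welch) {
    tt <- apply(v, 1, function(row)
      tryCatch(unlist(stats::t.test(row[g1], row[g2])[c("statistic", "p.value")]),
               error = function(e) c(statistic.t = 0, p.value = 1)))
    list(t = tt[1, ], p = tt[2, ],
         fc = rowMeans(v[, g1, drop = FALSE], na.rm = TRUE) -
              rowMeans(v[, g2, drop = FALSE], na.rm = TRUE))
  } else rowTtest(v, g1, g2)
  data.frame(antibody_id = rownames(v), t_stat = unname(res$t),
             p_value = unname(res$p), q_value = bhAdjust(unname(res$p)),
             log10_fc = unname(res$fc),
             fold_change = unname(sign(res$fc) * 10^abs(res$fc)),
             direction = ifelse(res$fc > 0, "up", "down"),
             stringsAsFactors = FALSE)
}

#' Multigroup one-way ANOVA table
#'
#' @param m an \linkS4class{ArrayExpressionSet}
#' @param labels named group assignment (sample -> label), or NULL for the
#'   metadata \code{group} column
#' @return data.frame: antibody_id, F, p_value, q_value
#' @export
anovaTable <- function(m, labels = NULL) {
  v <- exprValues(m)
  if (is.null(labels)) labels <- setNames(sampleData(m)$group, colnames(m))
  res <- rowAnova(v, labels[colnames(v)])
  data.frame(antibody_id = rownames(v), F = unname(res$F),
             p_value = unname(res$p), q_value = bhAdjust(unname(res$p)),
             stringsAsFactors = FALSE)
}

#' Percentage of p-values below a threshold
#' @param p numeric vector of p-values
#' @param threshold significance threshold
#' @return percentage (0-100)
#' @export
significanceFraction <- function(p, threshold) {
  if (!length(p)) stopf("empty p-value vector")
  100 * mean(p < threshold)
}

#' Top discriminating antibodies
#'
#' The k antibodies with the smallest q-values (ties broken by p-value,
#' then antibody id), optionally split by direction as in published
#' up/down tables.
#'
#' @param d a data.frame from \code{ttestTable}
#' @param k panel size
#' @param split also return up/down partitions
#' @return the ranked subset (list with \code{table}, \code{up},
#'   \code{down} when \code{split}), sorted ascending by q
#' @export
topMarkers <- function(d, k = 25L, split = FALSE) {
  if (k > nrow(d)) stopf("k = %d exceeds table size %d", k, nrow(d))
  ord <- order(d$q_value, d$p_value, d$antibody_id)
  top <- d[ord, ][seq_len(k), ]
  rownames(top) <- NULL
  if (!split) return(top)
  list(table = top, up = top[top$direction == "up", ],
       down = top[top$direction == "down", ])
}

#' P-filtered principal component projection
#'
#' Keeps antibodies with p below \code{threshold}, z-scores each kept
#' antibody across samples (mean 0, sd 1), and projects samples onto the
#' leading principal components. The sign of each component is fixed by
#' making its largest-magnitude loading positive, so coordinates are
#' reproducible across runs.
#'
#' @param m an \linkS4class{ArrayExpressionSet}
#' @param p named per-antibody p-values (e.g. from \code{anovaTable})
#' @param threshold filter threshold (default 1e-10)
#' @param nComponents number of components (default 3)
#' @return list with \code{antibodies_kept}, \code{coordinates} (samples x
#'   components), \code{variance_explained}
#' @export
pcaProjection <- function(m, p, threshold = 1e-10, nComponents = 3L) {
  v <- exprValues(m)
  if (is.null(names(p))) names(p) <- rownames(v)
  keep <- names(p)[!is.na(p) & p < threshold]
  if (length(keep) < nComponents)
    stopf("only %d antibodies pass p < %g; need at least %d",
          length(keep), threshold, nComponents)
  x <- t(v[keep, , drop = FALSE])            # samples x antibodies
  x <- scale(x)
  x[, attr(x, "scaled:scale") == 0] <- 0
  pc <- prcomp(x, center = FALSE, scale. = FALSE, rank. = nComponents)
  flip <- apply(pc$rotation, 2, function(l) sign(l[which.max(abs(l))]))
  flip[flip == 0] <- 1
  coords <- sweep(pc$x, 2, flip, "*")
  ve <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(nComponents)]
  list(antibodies_kept = keep, coordinates = coords,
       variance_explained = ve)
}
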