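## Spot-level preprocessing: background subtraction, replicate aggregation
## with the CV dismissal rule, failed-sample exclusion, log transform,
## two-step normalization, and preanalytical-factor screening.

#' Aggregate replicate spots with the CV dismissal rule
#'
#' Each spot is background-subtracted (intensity - background, floored at
#' 1.0). Per (sample, antibody), the value is the mean of the three
#' replicates unless their coefficient of variation (100 * sd / mean,
#' linear scale) exceeds \code{cvCutoff} percent, in which case the
#' replicate farthest from the three-replicate mean is dismissed and the
#' mean of the remaining two is used. Pairs (a failed spot already
#' missing) are averaged as-is; singletons are flagged missing (NA).
#'
#' @param spots a \linkS4class{SpotTable}
#' @param sheet a \linkS4class{SampleSheet} for the same samples
#' @param cvCutoff dismissal threshold in percent (default 15)
#' @return list with \code{matrix} (an \linkS4class{ArrayExpressionSet},
#'   stage \code{raw_aggregated}, linear units, with an \code{nReplicates}
#'   assay) and \code{replicateStats} (data.frame: sample_id, antibody_id,
#'   cv, n_used, dismissed_replicate)
#' @export
aggregateReplicates <- function(spots, sheet, cvCutoff = 15.0) {
  df <- spotData(spots)
  sub <- pmax(df$intensity - df$background, 1.0)

  samples <- unique(df$sample_id)
  abs <- sort(unique(df$antibody_id))
  si <- match(df$sample_id, samples)
  ai <- match(df$antibody_id, abs)
  cell <- (si - 1L) * length(abs) + ai
  ncell <- length(samples) * length(abs)

  # per-cell replicate values in index order (replicate_index is a prefix
  # of 1..3 by SpotTable validity)
  v1 <- v2 <- v3 <- rep(NA_real_, ncell)
  v1[cell[df$replicate_index == 1L]] <- sub[df$replicate_index == 1L]
  v2[cell[df$replicate_index == 2L]] <- sub[df$replicate_index == 2L]
  v3[cell[df$replicate_index == 3L]] <- sub[df$replicate_index == 3L]

  nrep <- (!is.na(v1)) + (!is.na(v2)) + (!is.na(v3))
  mean3 <- rowMeans(cbind(v1, v2, v3), na.rm = TRUE)
  mean3[nrep == 0L] <- NA_real_
  dev1 <- abs(v1 - mean3); dev2 <- abs(v2 - mean3); dev3 <- abs(v3 - mean3)
  ss <- rowSums(cbind(dev1^2, dev2^2, dev3^2), na.rm = TRUE)
  sdv <- ifelse(nrep >= 2L, sqrt(ss / pmax(nrep - 1L, 1L)), NA_real_)
  cv <- 100 * sdv / mean3

  value <- mean3
  nUsed <- nrep
  dismissed <- rep(NA_integer_, ncell)
  hit <- which(nrep == 3L & cv > cvCutoff)
  if (length(hit)) {
    dv <- cbind(dev1[hit], dev2[hit], dev3[hit])
    worst <- max.col(dv, ties.method = "first")
    dismissed[hit] <- worst
    vals <- cbind(v1[hit], v2[hit], v3[hit])
    vals[cbind(seq_along(hit), worst)] <- NA_real_
    value[hit] <- rowMeans(vals, na.rm = TRUE)
    nUsed[hit] <- 2L
  }
  value[nrep < 2L] <- NA_real_

  vmat <- matrix(value, nrow = length(abs), ncol = length(samples),
                 dimnames = list(abs, samples))
  nmat <- matrix(nUsed, nrow = length(abs), ncol = length(samples),
                 dimnames = list(abs, samples))
  stats <- data.frame(
    sample_id = rep(samples, each = length(abs)),
    antibody_id = rep(abs, times = length(samples)),
    cv = cv, n_used = nUsed, dismissed_replicate = dismissed,
    stringsAsFactors = FALSE)
  list(matrix = ArrayExpressionSet(vmat, sheet = sheet,
                                   stage = "raw_aggregated",
                                   nReplicates = nmat),
       replicateStats = stats)
}

#' Flag near-signal-free samples
#'
#' A sample is flagged when the robust z-score of its median log10
#' intensity (against the cohort median and MAD of those medians) falls
#' below \code{zCutoff}. If the MAD is zero the rule degenerates and an
#' absolute floor is used instead (median log10 below \code{floorLog10}).
#'
#' @param m \linkS4class{ArrayExpressionSet}, stage \code{raw_aggregated}
#' @param zCutoff robust z threshold (default -4)
#' @param floorLog10 absolute fallback threshold (default 1.0)
#' @return character vector of flagged sample ids
#' @export
flagFailedSamples <- function(m, zCutoff = -4.0, floorLog10 = 1.0) {
  stopifnot(arrayStage(m) == "raw_aggregated")
  med <- apply(log10(pmax(exprValues(m), 1)), 2, median, na.rm = TRUE)
  center <- median(med)
  spread <- mad(med)
  if (spread > 0) names(med)[(med - center) / spread < zCutoff]
  else names(med)[med < floorLog10]
}

#' Drop samples from a matrix, recording the reason
#' @param m an \linkS4class{ArrayExpressionSet}
#' @param sampleIds samples to exclude
#' @param reason reason string recorded alongside each exclusion
#' @return the reduced \linkS4class{ArrayExpressionSet}
#' @export
excludeSamples <- function(m, sampleIds, reason = "failed QC") {
  if (!length(sampleIds)) return(m)
  keep <- setdiff(colnames(m), sampleIds)
  out <- m[, keep]
  out@excluded <- rbind(excludedSamples(m),
                        data.frame(sample_id = sampleIds, reason = reason,
                                   stringsAsFactors = FALSE))
  validObject(out)
  out
}

#' Log10-transform a linear-scale matrix
#'
#' Values are floored at 1.0 first, so the transform is total and the
#' floor maps to 0.
#'
#' @param m \linkS4class{ArrayExpressionSet}, stage \code{raw_aggregated}
#' @return \linkS4class{ArrayExpressionSet}, stage \code{logged}
#' @export
logTransform <- function(m) {
  stopifnot(arrayStage(m) == "raw_aggregated")
  SummarizedExperiment::assay(m, "exprs") <-
    log10(pmax(exprValues(m), 1.0))
  m@stage <- "logged"
  m
}

#' Remove between-round batch differences (subtract group mean)
#'
#' For every antibody, the mean log10 intensity within each analysis round
#' is subtracted from that round's values and the global antibody mean is
#' added back, zero-centering rounds without moving the antibody's overall
#' level. After this step every (antibody, round) mean equals the global
#' antibody mean.
#'
#' @param m \linkS4class{ArrayExpressionSet}, stage \code{logged}
#' @param rounds optional named round assignment (sample -> round);
#'   defaults to the \code{round} column of the attached sample metadata
#' @return \linkS4class{ArrayExpressionSet}, stage \code{round_normalized}
#' @export
normalizeRoundMeans <- function(m, rounds = NULL) {
  stopifnot(arrayStage(m) == "logged")
  if (is.null(rounds)) {
    rounds <- setNames(sampleData(m)$round, colnames(m))
  }
  r <- rounds[colnames(m)]
  if (anyNA(r)) stopf("every sample needs a round assignment")
  v <- exprValues(m)
  global <- rowMeans(v, na.rm = TRUE)
  for (rr in unique(r)) {
    idx <- which(r == rr)
    if (length(idx) == 1L)
      warnf("round %s has a single sample; it maps exactly to the global mean", rr)
    rmean <- rowMeans(v[, idx, drop = FALSE], na.rm = TRUE)
    v[, idx] <- v[, idx, drop = FALSE] - rmean + global
  }
  SummarizedExperiment::assay(m, "exprs") <- v
  m@stage <- "round_normalized"
  m
}

#' Per-array scaling from low-CV reference antibodies
#'
#' Array-to-array intensity differences (e.g. sample background
#' fluorescence) are removed with a scaling factor per subarray, computed
#' from the reference set of antibodies with the lowest cross-sample CV
#' (bottom \code{lowcvFraction}, CV on the linear scale, ties broken by
#' antibody id). Working in log10 space the factor is a subtractive
#' per-sample offset: the sample's mean over the reference set minus the
#' grand mean of that quantity. Afterwards all per-sample reference-set
#' means are equal.
#'
#' @param m \linkS4class{ArrayExpressionSet}, stage \code{round_normalized}
#' @param lowcvFraction fraction of antibodies forming the reference set
#' @return \linkS4class{ArrayExpressionSet}, stage \code{fully_normalized},
#'   with the reference set recorded in
#'   \code{metadata(m)$scaling_reference}
#' @export
normalizeArrayScale <- function(m, lowcvFraction = 0.20) {
  stopifnot(arrayStage(m) == "round_normalized")
  v <- exprValues(m)
  lin <- 10^v
  cv <- apply(lin, 1, sd, na.rm = TRUE) / rowMeans(lin, na.rm = TRUE)
  nRef <- floor(nrow(v) * lowcvFraction)
  if (nRef < 1L) stopf("lowcvFraction %.3f leaves an empty reference set",
                       lowcvFraction)
  ref <- rownames(v)[orderWithIdTies(cv, rownames(v))][seq_len(nRef)]
  refMean <- colMeans(v[ref, , drop = FALSE], na.rm = TRUE)
  offset <- refMean - mean(refMean)
  v <- sweep(v, 2, offset)
  SummarizedExperiment::assay(m, "exprs") <- v
  S4Vectors::metadata(m)$scaling_reference <- ref
  m@stage <- "fully_normalized"
  m
}

#' Screen preanalytical factors by per-antibody ANOVA
#'
#' For each factor (clinical center, gender, age quartile, subarray
#' position, analysis round) a one-way ANOVA is run per antibody and the
#' fraction of antibodies with p below \code{alpha} is reported, without
#' multiplicity correction (screening use: under the null the fraction
#' should sit near \code{alpha}).
#'
#' @param m \linkS4class{ArrayExpressionSet}, stage \code{logged} or later
#' @param sheet optional \linkS4class{SampleSheet}; defaults to the
#'   attached sample metadata
#' @param alpha significance threshold (default 0.01)
#' @return data.frame with columns \code{factor}, \code{n_levels},
#'   \code{fraction_significant} (factors with fewer than 2 levels are
#'   reported with NA and a note)
#' @export
checkPreanalyticalFactors <- function(m, sheet = NULL, alpha = 0.01) {
  stopifnot(arrayStage(m) %in% c("logged", "round_normalized",
                                 "fully_normalized"))
  df <- if (is.null(sheet)) sampleData(m) else {
    sd0 <- sampleData(sheet)
    sd0[match(colnames(m), sd0$sample_id), , drop = FALSE]
  }
  ageBin <- cut(df$age, breaks = unique(quantile(df$age, probs = 0:4 / 4)),
                include.lowest = TRUE)
  factors <- list(center = df$hospital, gender = df$gender,
                  age_quartile = as.character(ageBin),
                  subarray = as.character(df$subarray),
                  round = as.character(df$round))
  v <- exprValues(m)
  out <- lapply(names(factors), function(nm) {
    f <- factors[[nm]]
    nl <- length(unique(f[!is.na(f)]))
    if (nl < 2L)
      return(data.frame(factor = nm, n_levels = nl,
                        fraction_significant = NA_real_,
                        note = "skipped: fewer than 2 levels",
                        stringsAsFactors = FALSE))
    p <- rowAnova(v, f)$p
    data.frame(factor = nm, n_levels = nl,
               fraction_significant = mean(p < alpha, na.rm = TRUE),
               note = "", stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Run the full preprocessing pipeline
#'
#' Background subtraction, replicate aggregation (CV rule), failed-sample
#' exclusion, log10 transform, round normalization, array scaling, and the
#' preanalytical-factor report, in that order.
#'
#' @param spots a \linkS4class{SpotTable}
#' @param sheet a \linkS4class{SampleSheet}
#' @param cvCutoff replicate CV dismissal threshold (percent)
#' @param lowcvFraction reference-set fraction for array scaling
#' @param zCutoff robust-z threshold for failed samples
#' @param alpha preanalytical screening threshold
#' @param verbose print stage-by-stage counts
#' @return list with \code{matrix} (stage \code{fully_normalized}),
#'   \code{replicateStats}, \code{preanalytical}, \code{excluded},
#'   \code{stats} (named counts: samples, antibodies, exclusions, percent
#'   of values from all 3 replicates)
#' @export
runPreprocessing <- function(spots, sheet, cvCutoff = 15.0,
                             lowcvFraction = 0.20, zCutoff = -4.0,
                             alpha = 0.01, verbose = FALSE) {
  agg <- aggregateReplicates(spots, sheet, cvCutoff = cvCutoff)
  m <- agg$matrix
  rs <- agg$replicateStats
  pct3 <- 100 * mean(rs$n_used == 3L, na.rm = TRUE)
  if (verbose)
    message(sprintf("aggregated %d x %d values (%.1f%% from all 3 replicates)",
                    nrow(m), ncol(m), pct3))
  failed <- flagFailedSamples(m, zCutoff = zCutoff)
  m <- excludeSamples(m, failed, reason = "near-signal-free (robust z)")
  if (verbose && length(failed))
    message(sprintf("excluded %d sample(s): %s", length(failed),
                    paste(failed, collapse = ", ")))
  m <- logTransform(m)
  m <- normalizeRoundMeans(m)
  m <- normalizeArrayScale(m, lowcvFraction = lowcvFraction)
  pre <- checkPreanalyticalFactors(m, alpha = alpha)
  list(matrix = m, replicateStats = rs, preanalytical = pre,
       excluded = excludedSamples(m),
       stats = list(n_samples = ncol(m), n_antibodies = nrow(m),
                    n_excluded = length(failed),
                    pct_from_3_replicates = pct3))
}
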