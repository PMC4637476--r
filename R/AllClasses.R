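## Core S4 classes for the antibody-microarray signature pipeline.

GROUP_LEVELS   <- c("PDAC", "OPD", "NPC")
SUBSITE_LEVELS <- c("head", "body", "tail", "other", "unspecified")
GENDER_LEVELS  <- c("M", "F")
STAGE_LEVELS   <- c("raw_aggregated", "logged", "round_normalized",
                    "fully_normalized")

SPOT_COLUMNS <- c("sample_id", "round", "slide", "subarray", "antibody_id",
                  "replicate_index", "segment", "intensity", "background")
SHEET_COLUMNS <- c("sample_id", "group", "subsite", "diagnosis_detail",
                   "hospital", "round", "slide", "subarray", "gender", "age")

#' Spot-level antibody microarray intensities
#'
#' One row per (sample, antibody, replicate spot) carrying the raw
#' fluorescence intensity and its local background estimate, together with
#' the physical layout of the measurement (analysis round/day, slide,
#' subarray, segment). Background subtraction is deliberately left to the
#' preprocessing stage so that it is explicit and testable.
#'
#' @slot spots data.frame with columns \code{sample_id}, \code{round},
#'   \code{slide}, \code{subarray}, \code{antibody_id},
#'   \code{replicate_index}, \code{segment}, \code{intensity},
#'   \code{background}.
#' @export
setClass("SpotTable", representation(spots = "data.frame"))

setValidity("SpotTable", function(object) {
  df <- object@spots
  msgs <- character()
  missing <- setdiff(SPOT_COLUMNS, names(df))
  if (length(missing))
    return(sprintf("missing spot column(s): %s", paste(missing, collapse = ", ")))
  if (!is.numeric(df$intensity) || !is.numeric(df$background))
    return("intensity and background must be numeric")
  bad <- !is.finite(df$intensity) | df$intensity < 0 |
         !is.finite(df$background) | df$background < 0
  if (any(bad))
    msgs <- c(msgs, sprintf("non-finite or negative intensity/background at row %d",
                            which(bad)[1]))
  if (any(df$replicate_index < 1 | df$replicate_index > 3))
    msgs <- c(msgs, "replicate_index must be in 1..3")
  key <- paste(df$sample_id, df$antibody_id, sep = "\r")
  dup <- duplicated(paste(key, df$replicate_index, sep = "\r"))
  if (any(dup))
    msgs <- c(msgs, sprintf("duplicate (sample, antibody, replicate) at row %d",
                            which(dup)[1]))
  else {
    # with distinct indices in 1..3, indices form a prefix of {1,2,3} iff
    # their per-key sum equals n(n+1)/2
    cnt <- rowsum(rep(1L, nrow(df)), key)
    s   <- rowsum(as.numeric(df$replicate_index), key)
    offkey <- s[, 1] != cnt[, 1] * (cnt[, 1] + 1) / 2
    if (any(offkey))
      msgs <- c(msgs, sprintf("replicate indices not a prefix of {1,2,3} for %s",
                              sub("\r", " / ", rownames(cnt)[which(offkey)[1]])))
  }
  if (length(msgs)) msgs else TRUE
})

#' Per-sample clinical and technical metadata
#'
#' Diagnosis group (PDAC, OPD or NPC), pancreatic tumor subsite for PDAC
#' cases, collecting hospital, the array layout position the sample was
#' incubated on (round, slide, subarray), and basic demographics.
#'
#' @slot samples data.frame with columns \code{sample_id}, \code{group},
#'   \code{subsite}, \code{diagnosis_detail}, \code{hospital}, \code{round},
#'   \code{slide}, \code{subarray}, \code{gender}, \code{age}.
#' @export
setClass("SampleSheet", representation(samples = "data.frame"))

setValidity("SampleSheet", function(object) {
  df <- object@samples
  msgs <- character()
  missing <- setdiff(SHEET_COLUMNS, names(df))
  if (length(missing))
    return(sprintf("missing sample sheet column(s): %s",
                   paste(missing, collapse = ", ")))
  if (anyDuplicated(df$sample_id))
    msgs <- c(msgs, sprintf("duplicate sample_id '%s'",
                            df$sample_id[duplicated(df$sample_id)][1]))
  badg <- !df$group %in% GROUP_LEVELS
  if (any(badg))
    msgs <- c(msgs, sprintf("unknown group '%s' (allowed: %s)",
                            df$group[badg][1], paste(GROUP_LEVELS, collapse = ", ")))
  bads <- !is.na(df$subsite) & !df$subsite %in% SUBSITE_LEVELS
  if (any(bads))
    msgs <- c(msgs, sprintf("unknown subsite '%s' (allowed: %s or NA)",
                            df$subsite[bads][1], paste(SUBSITE_LEVELS, collapse = ", ")))
  wrong <- !is.na(df$subsite) & df$group != "PDAC"
  if (any(wrong))
    msgs <- c(msgs, sprintf("sample '%s' has a tumor subsite but group %s",
                            df$sample_id[wrong][1], df$group[wrong][1]))
  if (!all(df$gender %in% GENDER_LEVELS))
    msgs <- c(msgs, "gender must be 'M' or 'F'")
  slot_key <- paste(df$round, df$slide, df$subarray)
  if (anyDuplicated(slot_key))
    msgs <- c(msgs, sprintf("two samples share array position (round slide subarray) %s",
                            slot_key[duplicated(slot_key)][1]))
  if (length(msgs)) msgs else TRUE
})

#' Antibody-by-sample expression matrix with processing provenance
#'
#' A \linkS4class{SummarizedExperiment} holding one \code{exprs} assay
#' (antibodies as rows, samples as columns; linear fluorescence units at
#' stage \code{raw_aggregated}, log10 units afterwards), an optional
#' \code{nReplicates} assay recording how many replicate spots entered each
#' value, the sample sheet as \code{colData}, the processing \code{stage},
#' and the samples excluded so far with their reasons.
#'
#' @slot stage one of \code{raw_aggregated}, \code{logged},
#'   \code{round_normalized}, \code{fully_normalized}.
#' @slot excluded data.frame with columns \code{sample_id}, \code{reason}.
#' @export
setClass("ArrayExpressionSet",
         contains = "SummarizedExperiment",
         representation(stage = "character", excluded = "data.frame"))

setValidity("ArrayExpressionSet", function(object) {
  msgs <- character()
  if (length(object@stage) != 1L || !object@stage %in% STAGE_LEVELS)
    msgs <- c(msgs, sprintf("stage must be one of: %s",
                            paste(STAGE_LEVELS, collapse = ", ")))
  if (!"exprs" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "an 'exprs' assay is required")
  else {
    v <- SummarizedExperiment::assay(object, "exprs")
    if (any(is.infinite(v)))
      msgs <- c(msgs, "expression values must be finite (NA allowed for missing)")
  }
  if (!all(c("sample_id", "reason") %in% names(object@excluded)))
    msgs <- c(msgs, "excluded must have columns sample_id, reason")
  else if (any(object@excluded$sample_id %in% colnames(object)))
    msgs <- c(msgs, "excluded samples must not remain in the matrix")
  if (length(msgs)) msgs else TRUE
})

#' Synthetic cohort design configuration
#'
#' Group sizes, PDAC subsite composition, and the physical array capacity
#' (rounds x slides x subarrays) used to lay a cohort out. Defaults follow
#' the multicenter pancreatic-cancer serum study design this package
#' emulates: 156 PDAC / 152 OPD / 30 NPC sera from 5 hospitals, analyzed
#' over 5 rounds of 8 slides carrying 13 subarrays each, on 293-plex
#' antibody arrays printed in triplicate.
#' @export
setClass("CohortConfig", representation(
  nPdac = "integer", nOpd = "integer", nNpc = "integer",
  subsiteCounts = "integer", nHospitals = "integer",
  nRounds = "integer", slidesPerRound = "integer",
  subarraysPerSlide = "integer", nAntibodies = "integer",
  replicates = "integer", seed = "integer"))

setValidity("CohortConfig", function(object) {
  msgs <- character()
  if (!identical(sort(names(object@subsiteCounts)), sort(SUBSITE_LEVELS)))
    msgs <- c(msgs, "subsiteCounts must name exactly: head, body, tail, other, unspecified")
  else if (sum(object@subsiteCounts) != object@nPdac)
    msgs <- c(msgs, sprintf("subsiteCounts sum (%d) must equal nPdac (%d)",
                            sum(object@subsiteCounts), object@nPdac))
  capacity <- object@nRounds * object@slidesPerRound * object@subarraysPerSlide
  total <- object@nPdac + object@nOpd + object@nNpc
  if (capacity < total)
    msgs <- c(msgs, sprintf("array capacity %d < %d samples", capacity, total))
  if (object@replicates < 1L || object@replicates > 3L)
    msgs <- c(msgs, "replicates must be 1..3")
  if (length(msgs)) msgs else TRUE
})

#' Planted differential-expression structure for the simulator
#'
#' Per-antibody log10 shifts for the three study contrasts (PDAC vs NPC,
#' PDAC vs OPD, head vs body/tail tumors) plus the named lists of
#' informative antibodies. Non-informative antibodies carry zero deltas.
#' @export
setClass("EffectProfile", representation(
  deltas = "data.frame", informativeSets = "list"))

setValidity("EffectProfile", function(object) {
  need <- c("antibody_id", "delta_pdac_vs_npc", "delta_pdac_vs_opd",
            "delta_head_vs_bodytail")
  if (!all(need %in% names(object@deltas)))
    return(sprintf("deltas must have columns: %s", paste(need, collapse = ", ")))
  if (anyDuplicated(object@deltas$antibody_id))
    return("duplicate antibody_id in deltas")
  TRUE
})

#' Technical noise model for the spot-level simulator
#'
#' Parameters of the generative model: antibody baselines in log10 units,
#' between-sample biological spread, linear-scale replicate noise with a
#' small outlier rate, per-round batch offsets (round 1 inflated, mimicking
#' printing-day humidity effects), per-array offsets, near-signal-free
#' failed samples, and the local background level.
#' @export
setClass("NoiseModel", representation(
  baselineMu = "numeric", baselineSigmaAntibody = "numeric",
  sigmaBiological = "numeric", sigmaReplicate = "numeric",
  roundOffsets = "numeric", roundOffsetSigma = "numeric",
  round1Inflation = "numeric", arrayScaleSigma = "numeric",
  outlierRate = "numeric", outlierFactor = "numeric",
  failedSampleIds = "character", nFailedSamples = "integer",
  failedGroup = "character", failedAttenuation = "numeric",
  backgroundMu = "numeric", backgroundSigma = "numeric"))

setValidity("NoiseModel", function(object) {
  msgs <- character()
  sig <- c(object@baselineSigmaAntibody, object@sigmaBiological,
           object@sigmaReplicate, object@arrayScaleSigma,
           object@roundOffsetSigma, object@backgroundSigma)
  if (any(sig < 0)) msgs <- c(msgs, "all sigmas must be >= 0")
  if (object@outlierRate < 0 || object@outlierRate > 1)
    msgs <- c(msgs, "outlierRate must be in [0, 1]")
  if (object@failedAttenuation < 0 || object@failedAttenuation > 1)
    msgs <- c(msgs, "failedAttenuation must be in [0, 1]")
  if (length(msgs)) msgs else TRUE
})

#' Repeated stratified train/test split specification
#'
#' For each repeat, each diagnosis group contributes floor(trainFraction x
#' group size) samples to the training set and the remainder to the test
#' set. Assignments are seeded and reproducible.
#' @export
setClass("SplitSpec", representation(
  trainFraction = "numeric", nRepeats = "integer", seed = "integer",
  groups = "character", assignments = "list"))

#' Frozen linear support vector machine panel model
#'
#' Weights, bias and the training-set standardization (per-antibody mean
#' and sd) of a linear-kernel SVM fit on a fixed antibody panel. The model
#' is frozen after fitting: evaluation never mutates it. Decision values
#' are \code{w . standardized(x) + bias}; positive values vote for
#' \code{positiveClass}.
#' @export
setClass("SvmModel", representation(
  panel = "character", weights = "numeric", bias = "numeric",
  cost = "numeric", center = "numeric", scale = "numeric",
  positiveClass = "character", negativeClass = "character",
  trainingSamples = "character"))

setValidity("SvmModel", function(object) {
  if (length(object@weights) != length(object@panel))
    return("one weight per panel antibody required")
  TRUE
})

#' Backward-elimination trace for one training set
#'
#' The complete removal order of antibodies (position 1 = first eliminated;
#' the last element is the final survivor) and the Kullback-Leibler error
#' of the surviving panel at every panel size from the full panel down
#' to one antibody.
#' @export
setClass("EliminationTrace", representation(
  removalOrder = "character", klCurve = "numeric", repeatIndex = "integer"))

setValidity("EliminationTrace", function(object) {
  n <- length(object@removalOrder)
  if (anyDuplicated(object@removalOrder))
    return("removalOrder must be a permutation of the panel")
  if (length(object@klCurve) != n)
    return("klCurve must have one entry per panel size 1..N")
  TRUE
})

#' Endurance scores aggregated over elimination repeats
#'
#' An antibody eliminated at position n in a trace has endurance n (1 =
#' first out; N = last survivor); its score is the mean endurance over
#' repeats, so high-scoring antibodies persistently survive elimination.
#' @export
setClass("AntibodyScore", representation(
  scores = "numeric", endurances = "matrix"))

#' Frozen-model test-set evaluation
#'
#' AUC (Mann-Whitney rank statistic over decision values), plus
#' sensitivity, specificity, PPV and NPV in percent from the confusion
#' matrix at the stated decision-value threshold (default 0).
#' @export
setClass("PanelEvaluation", representation(
  auc = "numeric", sensitivity = "numeric", specificity = "numeric",
  ppv = "numeric", npv = "numeric", decisionValues = "numeric",
  threshold = "numeric", confusion = "numeric", positiveClass = "character"))

#' Cross-validation report for a spot table / sample sheet pair
#'
#' Violations are data, not exceptions: an empty report means the pair is
#' consistent.
#' @export
setClass("ValidationReport", representation(violations = "data.frame"))

#' Full study report
#'
#' Container for the end-to-end analysis: per-contrast differential
#' expression tables, PCA projections, elimination traces, endurance score
#' tables, consensus panels, frozen-model metrics, preprocessing summaries
#' and a provenance block (seed, configuration, package version).
#' @export
setClass("StudyReport", representation(
  preprocessing = "list", contrasts = "list", provenance = "list"))
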