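## Constructors, accessors and show methods.

#' Construct a SpotTable from a data.frame
#'
#' @param spots data.frame with the nine spot-level columns (see
#'   \linkS4class{SpotTable}). Row order is preserved.
#' @return a validated \linkS4class{SpotTable}
#' @export
SpotTable <- function(spots) {
  spots <- as.data.frame(spots)
  rownames(spots) <- NULL
  for (col in c("round", "slide", "subarray", "replicate_index", "segment"))
    if (col %in% names(spots)) spots[[col]] <- as.integer(spots[[col]])
  for (col in c("sample_id", "antibody_id"))
    if (col %in% names(spots)) spots[[col]] <- as.character(spots[[col]])
  new("SpotTable", spots = spots)
}

#' Construct a SampleSheet from a data.frame
#'
#' @param samples data.frame with the ten metadata columns (see
#'   \linkS4class{SampleSheet}).
#' @return a validated \linkS4class{SampleSheet}
#' @export
SampleSheet <- function(samples) {
  samples <- as.data.frame(samples)
  rownames(samples) <- NULL
  for (col in c("round", "slide", "subarray", "age"))
    if (col %in% names(samples)) samples[[col]] <- as.integer(samples[[col]])
  for (col in c("sample_id", "group", "subsite", "diagnosis_detail",
                "hospital", "gender"))
    if (col %in% names(samples)) samples[[col]] <- as.character(samples[[col]])
  if ("subsite" %in% names(samples))
    samples$subsite[samples$subsite %in% c("", "NA")] <- NA_character_
  new("SampleSheet", samples = samples)
}

#' Construct an ArrayExpressionSet
#'
#' @param values numeric matrix, antibodies as rows and samples as columns
#'   (dimnames required).
#' @param sheet a \linkS4class{SampleSheet} covering at least the matrix
#'   samples, or NULL.
#' @param stage processing stage label.
#' @param nReplicates optional integer matrix (same shape) of replicate
#'   counts behind each value.
#' @param excluded data.frame of excluded samples (sample_id, reason).
#' @return an \linkS4class{ArrayExpressionSet}
#' @export
ArrayExpressionSet <- function(values, sheet = NULL, stage = "raw_aggregated",
                               nReplicates = NULL,
                               excluded = data.frame(sample_id = character(),
                                                     reason = character())) {
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs antibody rownames and sample colnames")
  assays <- list(exprs = values)
  if (!is.null(nReplicates)) assays$nReplicates <- nReplicates
  cd <- S4Vectors::DataFrame(row.names = colnames(values))
  if (!is.null(sheet)) {
    df <- sampleData(sheet)
    idx <- match(colnames(values), df$sample_id)
    if (anyNA(idx))
      stopf("sample '%s' missing from the sample sheet",
            colnames(values)[which(is.na(idx))[1]])
    cd <- S4Vectors::DataFrame(df[idx, , drop = FALSE],
                               row.names = colnames(values))
  }
  se <- SummarizedExperiment::SummarizedExperiment(assays = assays, colData = cd)
  new("ArrayExpressionSet", se, stage = stage, excluded = excluded)
}

#' @describeIn SpotTable underlying data.frame
#' @param x object
#' @export
setMethod("spotData", "SpotTable", function(x) x@spots)

#' @describeIn SampleSheet underlying data.frame
#' @param x object
#' @export
setMethod("sampleData", "SampleSheet", function(x) x@samples)

#' @export
setMethod("sampleData", "ArrayExpressionSet", function(x)
  as.data.frame(SummarizedExperiment::colData(x)))

#' @export
setMethod("exprValues", "ArrayExpressionSet", function(x)
  SummarizedExperiment::assay(x, "exprs"))

#' @export
setMethod("arrayStage", "ArrayExpressionSet", function(x) x@stage)

#' @export
setMethod("excludedSamples", "ArrayExpressionSet", function(x) x@excluded)

#' @export
setMethod("nReplicatesUsed", "ArrayExpressionSet", function(x) {
  if (!"nReplicates" %in% SummarizedExperiment::assayNames(x)) NULL
  else SummarizedExperiment::assay(x, "nReplicates")
})

#' @export
setMethod("removalOrder", "EliminationTrace", function(x) x@removalOrder)

#' @export
setMethod("klCurve", "EliminationTrace", function(x) x@klCurve)

#' @describeIn AntibodyScore scores as a sorted data.frame (score
#'   descending, ties broken by antibody id)
#' @param x object
#' @export
setMethod("scoreTable", "AntibodyScore", function(x) {
  ord <- orderWithIdTies(x@scores, names(x@scores), decreasing = TRUE)
  data.frame(antibody_id = names(x@scores)[ord], score = unname(x@scores[ord]),
             stringsAsFactors = FALSE)
})

#' @export
setMethod("decisionValues", "PanelEvaluation", function(x, ...) x@decisionValues)

#' @export
setMethod("violations", "ValidationReport", function(x) x@violations)

setMethod("show", "SpotTable", function(object) {
  df <- object@spots
  cat(sprintf("SpotTable: %d spots | %d samples x %d antibodies\n",
              nrow(df), length(unique(df$sample_id)),
              length(unique(df$antibody_id))))
})

setMethod("show", "SampleSheet", function(object) {
  df <- object@samples
  tab <- table(factor(df$group, levels = GROUP_LEVELS))
  cat(sprintf("SampleSheet: %d samples (%s)\n", nrow(df),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
})

setMethod("show", "ArrayExpressionSet", function(object) {
  cat(sprintf("ArrayExpressionSet: %d antibodies x %d samples | stage: %s\n",
              nrow(object), ncol(object), object@stage))
  if (nrow(object@excluded))
    cat(sprintf("  excluded: %s\n",
                paste(object@excluded$sample_id, collapse = ", ")))
})

setMethod("show", "SvmModel", function(object) {
  cat(sprintf("SvmModel: linear kernel, cost %g | panel of %d antibodies\n",
              object@cost, length(object@panel)))
  cat(sprintf("  %s (+) vs %s (-), %d training samples\n",
              object@positiveClass, object@negativeClass,
              length(object@trainingSamples)))
})

setMethod("show", "EliminationTrace", function(object) {
  n <- length(object@removalOrder)
  kmin <- which.min(object@klCurve)
  cat(sprintf("EliminationTrace (repeat %d): %d antibodies, K-L min %.3f at panel size %d\n",
              object@repeatIndex, n, object@klCurve[kmin], kmin))
})

setMethod("show", "PanelEvaluation", function(object) {
  cat(sprintf("PanelEvaluation: AUC %.3f | SN %.1f%% SP %.1f%% PPV %.1f%% NPV %.1f%% (threshold %g)\n",
              object@auc, object@sensitivity, object@specificity,
              object@ppv, object@npv, object@threshold))
})

setMethod("show", "ValidationReport", function(object) {
  if (!nrow(object@violations)) cat("ValidationReport: no violations\n")
  else {
    cat(sprintf("ValidationReport: %d violation(s)\n", nrow(object@violations)))
    for (i in seq_len(min(nrow(object@violations), 10)))
      cat("  -", object@violations$message[i], "\n")
  }
})

setMethod("show", "StudyReport", function(object) {
  cat(sprintf("StudyReport: %d contrast(s): %s\n", length(object@contrasts),
              paste(names(object@contrasts), collapse = ", ")))
  for (nm in names(object@contrasts)) {
    s <- object@contrasts[[nm]]$summary
    if (!is.null(s))
      cat(sprintf("  %s: mean test AUC %.3f over %d repeats\n", nm,
                  s$mean_auc, s$n_repeats))
  }
})
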