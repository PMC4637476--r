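## Study-shaped orchestration: preprocess once, then run differential
## expression, p-filtered PCA and SVM signature discovery for the three
## study contrasts (PDAC vs NPC, PDAC vs OPD, head vs body/tail tumors),
## and export the table/figure analogs with a checksummed manifest.

#' Analysis configuration
#'
#' Defaults match the emulated study's stated parameters: 15\% replicate
#' CV cutoff, 20\% low-CV scaling reference, 2/3 stratified training
#' split repeated 10 times, 25-antibody frozen panels, SVM cost 1, and a
#' p < 1e-10 PCA filter.
#'
#' @param cvCutoff,lowcvFraction,zCutoff,alpha preprocessing parameters
#' @param pcaThreshold PCA p-value filter
#' @param nRepeats,trainFraction,panelSize,kFolds,cost signature discovery
#'   parameters
#' @param seed master seed
#' @param contrasts named list of character(2) group pairs; the special
#'   labels \code{head}/\code{bodytail} select PDAC tumor subsites (body
#'   and tail pooled; other/unspecified excluded)
#' @return named list of settings
#' @export
studyConfig <- function(cvCutoff = 15.0, lowcvFraction = 0.20,
                        zCutoff = -4.0, alpha = 0.01,
                        pcaThreshold = 1e-10, nRepeats = 10L,
                        trainFraction = 2 / 3, panelSize = 25L,
                        kFolds = 5L, cost = 1.0, seed = 1L,
                        contrasts = list(
                          pdac_vs_npc = c("PDAC", "NPC"),
                          pdac_vs_opd = c("PDAC", "OPD"),
                          head_vs_bodytail = c("head", "bodytail"))) {
  list(cvCutoff = cvCutoff, lowcvFraction = lowcvFraction,
       zCutoff = zCutoff, alpha = alpha, pcaThreshold = pcaThreshold,
       nRepeats = as.integer(nRepeats), trainFraction = trainFraction,
       panelSize = as.integer(panelSize), kFolds = as.integer(kFolds),
       cost = cost, seed = as.integer(seed), contrasts = contrasts)
}

# contrast labels over the matrix samples; NA drops a sample from the
# contrast (e.g. other/unspecified subsites in the intrapancreatic one)
contrastLabels <- function(m, groups) {
  df <- sampleData(m)
  if (all(groups %in% c("head", "bodytail"))) {
    lab <- rep(NA_character_, ncol(m))
    lab[df$group == "PDAC" & !is.na(df$subsite) & df$subsite == "head"] <- "head"
    lab[df$group == "PDAC" & !is.na(df$subsite) &
          df$subsite %in% c("body", "tail")] <- "bodytail"
  } else {
    lab <- ifelse(df$group %in% groups, df$group, NA_character_)
  }
  setNames(lab, colnames(m))
}

#' Run the complete study-shaped analysis
#'
#' Preprocesses the spot data and, for every configured contrast, runs the
#' t-test table, the multigroup ANOVA, the p-filtered PCA and the full
#' SVM backward-elimination signature discovery. Contrasts with too few
#' samples are skipped with a recorded reason rather than failing the run.
#'
#' @param spots a \linkS4class{SpotTable}
#' @param sheet a \linkS4class{SampleSheet}
#' @param config a list from \code{studyConfig()}
#' @return a \linkS4class{StudyReport}
#' @export
runFullAnalysis <- function(spots, sheet, config = studyConfig()) {
  prep <- runPreprocessing(spots, sheet, cvCutoff = config$cvCutoff,
                           lowcvFraction = config$lowcvFraction,
                           zCutoff = config$zCutoff, alpha = config$alpha)
  m <- prep$matrix
  contrasts <- list()
  for (nm in names(config$contrasts)) {
    groups <- config$contrasts[[nm]]
    lab <- contrastLabels(m, groups)
    sizes <- table(factor(lab, levels = groups))
    if (any(sizes < 6L)) {
      warnf("contrast %s skipped: group sizes %s", nm,
            paste(sizes, collapse = "/"))
      contrasts[[nm]] <- list(groups = groups,
                              skipped = sprintf("group sizes %s below 6",
                                                paste(sizes, collapse = "/")))
      next
    }
    keep <- names(lab)[!is.na(lab)]
    mc <- m[, keep]
    de <- ttestTable(mc, groups, labels = lab[keep])
    an <- anovaTable(mc, labels = lab[keep])
    pca <- tryCatch(
      pcaProjection(mc, setNames(an$p_value, an$antibody_id),
                    threshold = config$pcaThreshold),
      error = function(e) list(skipped = conditionMessage(e)))
    sig <- runSignatureDiscovery(
      mc, groups, labels = lab[keep], nRepeats = config$nRepeats,
      trainFraction = config$trainFraction, panelSize = config$panelSize,
      kFolds = config$kFolds, cost = config$cost,
      seed = childSeed(config$seed, nm))
    contrasts[[nm]] <- list(
      groups = groups, diffexp = de, anova = an,
      top = topMarkers(de, k = min(config$panelSize, nrow(de)), split = TRUE),
      pca = pca, signature = sig, summary = sig$summary)
  }
  new("StudyReport", preprocessing = prep, contrasts = contrasts,
      provenance = list(seed = config$seed,
                        config = config[setdiff(names(config), "contrasts")],
                        contrast_names = names(config$contrasts),
                        package_version = as.character(
                          utils::packageVersion("sigpanel"))))
}

#' Export a study report as TSV/JSON files with a checksummed manifest
#'
#' Writes, per contrast, the differential-expression table, endurance
#' score table, K-L curves (one row per repeat and panel size), PCA
#' coordinates and per-repeat test metrics; plus the preanalytical report,
#' exclusion list, provenance block and a manifest listing every file
#' with its MD5 checksum.
#'
#' @param report a \linkS4class{StudyReport}
#' @param outdir output directory (created if needed)
#' @return character vector of file paths (invisibly)
#' @export
exportReportTables <- function(report, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(outdir)) stopf("cannot create output directory %s", outdir)
  files <- character(0)
  wtsv <- function(df, name) {
    path <- file.path(outdir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  wjson <- function(x, name) {
    path <- file.path(outdir, name)
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    files <<- c(files, path)
  }

  prep <- report@preprocessing
  if (length(prep)) {
    wtsv(prep$preanalytical, "preanalytical.tsv")
    wtsv(prep$excluded, "excluded_samples.tsv")
    wjson(prep$stats, "preprocessing_stats.json")
  }
  for (nm in names(report@contrasts)) {
    ct <- report@contrasts[[nm]]
    if (!is.null(ct$skipped)) {
      wjson(list(contrast = nm, skipped = ct$skipped),
            sprintf("skipped_%s.json", nm))
      next
    }
    wtsv(ct$diffexp, sprintf("diffexp_%s.tsv", nm))
    wtsv(scoreTable(ct$signature$scores), sprintf("scores_%s.tsv", nm))
    curves <- do.call(rbind, lapply(ct$signature$traces, function(tr)
      data.frame(repeat_index = tr@repeatIndex,
                 panel_size = seq_along(klCurve(tr)),
                 kl_error = unname(klCurve(tr)))))
    wtsv(curves, sprintf("klcurves_%s.tsv", nm))
    trace_df <- do.call(rbind, lapply(ct$signature$traces, function(tr)
      data.frame(repeat_index = tr@repeatIndex,
                 antibody_id = removalOrder(tr),
                 removal_position = seq_along(removalOrder(tr)))))
    wtsv(trace_df, sprintf("traces_%s.tsv", nm))
    if (is.null(ct$pca$skipped)) {
      pdf_ <- data.frame(sample_id = rownames(ct$pca$coordinates),
                         ct$pca$coordinates, check.names = FALSE)
      wtsv(pdf_, sprintf("pca_%s.tsv", nm))
    }
    evals <- ct$signature$evaluations
    wjson(list(contrast = nm,
               consensus_panel = ct$signature$consensus$panel,
               summary = ct$summary[setdiff(names(ct$summary), "auc")],
               per_repeat = lapply(evals, function(e) list(
                 auc = e@auc, sensitivity = e@sensitivity,
                 specificity = e@specificity, ppv = e@ppv, npv = e@npv))),
          sprintf("metrics_%s.json", nm))
  }
  wjson(report@provenance, "provenance.json")

  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  manifest <- manifest[order(manifest$file), ]
  write.table(manifest, file.path(outdir, "MANIFEST.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(c(files, file.path(outdir, "MANIFEST.tsv")))
}

#' Self-contained demonstration: simulate a cohort and analyze it
#'
#' Generates a reduced synthetic cohort with planted effects for all three
#' contrasts, writes the simulated inputs (spot table, sample sheet,
#' ground-truth effects), runs the full analysis and exports the report.
#' The demo scale (90 cases / 20 controls, 60 antibodies, 3 split repeats)
#' keeps the exhaustive elimination fast while exercising every stage.
#'
#' @param outdir output directory
#' @param seed master seed driving simulation and analysis
#' @param cfg cohort configuration (default: reduced demo cohort)
#' @param effects planted effects (default: 8 informative antibodies per
#'   diagnosis contrast at 0.5 log10, 6 site markers upregulated in head
#'   tumors)
#' @param noise a \linkS4class{NoiseModel}
#' @param config analysis configuration (default: study parameters with 3
#'   split repeats)
#' @return the \linkS4class{StudyReport}, invisibly
#' @export
simulateAndRun <- function(outdir, seed = 7L,
                           cfg = cohortConfig(nPdac = 45L, nOpd = 45L,
                                              nNpc = 20L, nAntibodies = 60L,
                                              seed = seed),
                           effects = NULL, noise = noiseModel(),
                           config = studyConfig(nRepeats = 3L, seed = seed)) {
  if (is.null(effects)) {
    eff_diag <- plantEffectProfile(antibodyIds(cfg@nAntibodies),
                                   kNpc = 8L, kOpd = 8L, kSite = 0L,
                                   delta = 0.5, directionMix = 0.5,
                                   seed = seed)
    eff_site <- plantEffectProfile(antibodyIds(cfg@nAntibodies),
                                   kNpc = 0L, kOpd = 0L, kSite = 6L,
                                   delta = 0.5, directionMix = 0,
                                   seed = childSeed(seed, "site"))
    deltas <- eff_diag@deltas
    deltas$delta_head_vs_bodytail <- eff_site@deltas$delta_head_vs_bodytail
    sets <- eff_diag@informativeSets
    sets$head_vs_bodytail <- eff_site@informativeSets$head_vs_bodytail
    effects <- new("EffectProfile", deltas = deltas, informativeSets = sets)
  }
  sim <- simulateCohort(cfg, effects = effects, noise = noise, seed = seed)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  writeSpotTable(sim$spots, file.path(outdir, "spots.tsv"))
  writeSampleSheet(sim$sheet, file.path(outdir, "sheet.tsv"))
  write.table(sim$effects@deltas, file.path(outdir, "true_effects.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  report <- runFullAnalysis(sim$spots, sim$sheet, config = config)
  exportReportTables(report, file.path(outdir, "results"))
  invisible(report)
}
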