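## TSV input/output. All interchange files are tab-delimited UTF-8 with a
## header row and "." as decimal separator; expression matrices travel with
## a small key-value sidecar ("<path>.meta") holding the processing stage
## and any excluded samples, so the matrix itself stays plain numeric.

#' Read a spot-level intensity table
#'
#' @param path TSV file with columns \code{sample_id, round, slide,
#'   subarray, antibody_id, replicate_index, segment, intensity,
#'   background}.
#' @return a validated \linkS4class{SpotTable}; input row order is kept.
#' @export
readSpotTable <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(SPOT_COLUMNS, names(df))
  if (length(missing))
    stopf("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  for (col in c("round", "slide", "subarray", "replicate_index", "segment",
                "intensity", "background")) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & !is.na(df[[col]]))
    if (length(bad))
      stopf("%s line %d: non-numeric %s value '%s'", path, bad[1] + 1L,
            col, df[[col]][bad[1]])
    df[[col]] <- v
  }
  key <- paste(df$sample_id, df$antibody_id, df$replicate_index)
  dup <- which(duplicated(key))
  if (length(dup))
    stopf("%s line %d: duplicate (sample, antibody, replicate) %s",
          path, dup[1] + 1L, key[dup[1]])
  SpotTable(df)
}

#' Read a sample metadata sheet
#'
#' @param path TSV file with columns \code{sample_id, group, subsite,
#'   diagnosis_detail, hospital, round, slide, subarray, gender, age}.
#' @return a validated \linkS4class{SampleSheet}
#' @export
readSampleSheet <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  df <- read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                   colClasses = "character", check.names = FALSE)
  missing <- setdiff(SHEET_COLUMNS, names(df))
  if (length(missing))
    stopf("%s: missing column(s): %s", path, paste(missing, collapse = ", "))
  bad <- which(!df$group %in% GROUP_LEVELS)
  if (length(bad))
    stopf("%s line %d: unknown group '%s' (allowed: %s)", path, bad[1] + 1L,
          df$group[bad[1]], paste(GROUP_LEVELS, collapse = ", "))
  SampleSheet(df)
}

#' Write a spot table to TSV
#' @param spots a \linkS4class{SpotTable}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeSpotTable <- function(spots, path) {
  write.table(spotData(spots), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a sample sheet to TSV
#' @param sheet a \linkS4class{SampleSheet}
#' @param path output file
#' @return \code{path}, invisibly
#' @export
writeSampleSheet <- function(sheet, path) {
  write.table(sampleData(sheet), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write an expression matrix (with sidecar metadata) to TSV
#'
#' Samples are written as rows (first column \code{sample_id}) and
#' antibodies as columns. The processing stage and the excluded-sample list
#' go to a "<path>.meta" key-value sidecar so the matrix itself stays a
#' plain numeric table.
#'
#' @param m an \linkS4class{ArrayExpressionSet}
#' @param path output TSV
#' @return \code{path}, invisibly
#' @export
writeExpressionMatrix <- function(m, path) {
  v <- t(exprValues(m))
  df <- data.frame(sample_id = rownames(v), v, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  meta <- c(sprintf("stage\t%s", arrayStage(m)),
            sprintf("excluded\t%s\t%s", excludedSamples(m)$sample_id,
                    excludedSamples(m)$reason))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

#' Read an expression matrix written by \code{writeExpressionMatrix}
#'
#' @param path matrix TSV (a "<path>.meta" sidecar is read if present)
#' @param sheet optional \linkS4class{SampleSheet} to attach as colData
#' @return an \linkS4class{ArrayExpressionSet}
#' @export
readExpressionMatrix <- function(path, sheet = NULL) {
  df <- read.delim(path, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df$sample_id
  stage <- "raw_aggregated"
  excluded <- data.frame(sample_id = character(), reason = character(),
                         stringsAsFactors = FALSE)
  metapath <- paste0(path, ".meta")
  if (file.exists(metapath)) {
    for (line in readLines(metapath)) {
      parts <- strsplit(line, "\t", fixed = TRUE)[[1]]
      if (parts[1] == "stage") stage <- parts[2]
      if (parts[1] == "excluded")
        excluded <- rbind(excluded,
                          data.frame(sample_id = parts[2],
                                     reason = if (length(parts) > 2) parts[3] else "",
                                     stringsAsFactors = FALSE))
    }
  }
  ArrayExpressionSet(t(v), sheet = sheet, stage = stage, excluded = excluded)
}

#' Cross-validate a spot table against a sample sheet
#'
#' Checks that the two files describe the same cohort: identical sample id
#' sets, matching (round, slide, subarray) layout assignments, and every
#' antibody measured for every sample. Violations are returned as data;
#' this function never throws on structurally parseable input.
#'
#' @param spots a \linkS4class{SpotTable}
#' @param sheet a \linkS4class{SampleSheet}
#' @return a \linkS4class{ValidationReport}; empty means consistent
#' @export
validateDataset <- function(spots, sheet) {
  sp <- spotData(spots)
  sh <- sampleData(sheet)
  v <- list()
  add <- function(check, msg) v[[length(v) + 1L]] <<- data.frame(
    check = check, message = msg, stringsAsFactors = FALSE)

  only_spots <- setdiff(unique(sp$sample_id), sh$sample_id)
  for (s in only_spots)
    add("sample_sets", sprintf("sample '%s' in spot table but not in sheet", s))
  only_sheet <- setdiff(sh$sample_id, unique(sp$sample_id))
  for (s in only_sheet)
    add("sample_sets", sprintf("sample '%s' in sheet but has no spots", s))

  common <- intersect(sh$sample_id, unique(sp$sample_id))
  if (length(common)) {
    spos <- unique(sp[sp$sample_id %in% common,
                      c("sample_id", "round", "slide", "subarray")])
    multi <- spos$sample_id[duplicated(spos$sample_id)]
    for (s in unique(multi))
      add("layout", sprintf("sample '%s' measured at more than one array position", s))
    idx <- match(spos$sample_id, sh$sample_id)
    off <- spos$round != sh$round[idx] | spos$slide != sh$slide[idx] |
           spos$subarray != sh$subarray[idx]
    for (s in unique(spos$sample_id[off]))
      add("layout", sprintf("sample '%s' array position differs between spots and sheet", s))

    abs <- sort(unique(sp$antibody_id))
    cnt <- table(sp$sample_id, factor(sp$antibody_id, levels = abs)) > 0
    missing <- which(!cnt[common, , drop = FALSE], arr.ind = TRUE)
    if (nrow(missing))
      for (i in seq_len(nrow(missing)))
        add("completeness", sprintf("antibody '%s' missing for sample '%s'",
                                    abs[missing[i, 2]], common[missing[i, 1]]))
  }
  new("ValidationReport",
      violations = if (length(v)) do.call(rbind, v)
                   else data.frame(check = character(), message = character(),
                                   stringsAsFactors = FALSE))
}
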