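# Readers and writers for the flat-file interchange formats.
# Delimiter is auto-detected from the extension: .csv => comma, else tab.
# Validation reports the first offending line (1-based, header included).

delim_for <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

read_delim_checked <- function(path, required, numeric_cols = character(0)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "n/a", ""), quote = "\"",
                          comment.char = "")
  miss <- setdiff(required, names(df))
  if (length(miss) > 0L) {
    stop(path, ": missing column(s): ", paste(miss, collapse = ", "))
  }
  for (cc in numeric_cols) {
    raw <- df[[cc]]
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(is.na(val) & !is.na(raw))
    if (length(bad) > 0L) {
      stop(path, ": line ", bad[1] + 1L, ": column '", cc,
           "' has non-numeric value '", raw[bad[1]], "'")
    }
    df[[cc]] <- val
  }
  df
}

write_delim_file <- function(df, path) {
  utils::write.table(df, path, sep = delim_for(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a plate table of viability or raw-signal readings
#'
#' Expects columns `sample`, `drug`, `dose`, `replicate` and one of
#' `viability` (pre-normalized) or `signal` (raw; normalize with
#' [normalize_viability()]). An optional `plate` column groups wells for
#' control matching. Doses are molar; scientific notation is accepted.
#'
#' @param path TSV or CSV file.
#' @return Validated data.frame.
#' @export
read_plate_table <- function(path) {
  df <- read_delim_checked(path, c("sample", "drug", "dose", "replicate"),
                           numeric_cols = "dose")
  if (!("viability" %in% names(df)) && !("signal" %in% names(df))) {
    stop(path, ": need a 'viability' or 'signal' column")
  }
  for (cc in intersect(c("viability", "signal"), names(df))) {
    df[[cc]] <- as.numeric(df[[cc]])
  }
  bad <- which(!is.finite(df$dose) | df$dose < 0)
  if (length(bad) > 0L) {
    stop(path, ": line ", bad[1] + 1L, ": dose must be non-negative")
  }
  df
}

#' Read a combination design table
#'
#' Maps each combination label to its component drugs and drug 1's
#' fraction of the total mixture dose. Columns: `combo`, `drug_a`,
#' `drug_b`, `fraction_a`.
#'
#' @param path TSV or CSV file.
#' @return Validated data.frame.
#' @export
read_design_table <- function(path) {
  df <- read_delim_checked(path, c("combo", "drug_a", "drug_b", "fraction_a"),
                           numeric_cols = "fraction_a")
  bad <- which(df$fraction_a <= 0 | df$fraction_a >= 1)
  if (length(bad) > 0L) {
    stop(path, ": line ", bad[1] + 1L, ": fraction_a must be in (0, 1)")
  }
  df
}

#' Read an expression matrix
#'
#' Genes in rows (first column = gene ID), samples in columns. A
#' GCT-style header (`#1.2` line followed by a dimensions line) is
#' skipped if present.
#'
#' @param path TSV or CSV file.
#' @return Numeric matrix with gene rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  first <- readLines(path, n = 1L)
  skip <- if (startsWith(first, "#1.2")) 2L else 0L
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          skip = skip, quote = "\"", comment.char = "")
  ids <- as.character(df[[1L]])
  if (anyDuplicated(ids)) {
    stop(path, ": duplicate gene ID '", ids[duplicated(ids)][1], "'")
  }
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

#' Read a per-sample phenotype (IC50) table
#'
#' Columns `sample`, `ic50`.
#'
#' @param path TSV or CSV file.
#' @return Named numeric vector of IC50 values.
#' @export
read_phenotype_table <- function(path) {
  df <- read_delim_checked(path, c("sample", "ic50"), numeric_cols = "ic50")
  stats::setNames(df$ic50, df$sample)
}

#' Read survival records
#'
#' Columns `sample`, `time`, `event` (time units declared by the study
#' config; months by convention here).
#'
#' @param path TSV or CSV file.
#' @return Validated data.frame.
#' @export
read_survival_table <- function(path) {
  df <- read_delim_checked(path, c("sample", "time", "event"),
                           numeric_cols = c("time", "event"))
  bad <- which(!is.finite(df$time) | df$time < 0)
  if (length(bad) > 0L) {
    stop(path, ": line ", bad[1] + 1L, ": time must be non-negative")
  }
  bad <- which(!(df$event %in% c(0, 1)))
  if (length(bad) > 0L) {
    stop(path, ": line ", bad[1] + 1L, ": event must be 0 or 1")
  }
  df
}

#' Read an immunohistochemistry grade table
#'
#' Accepts either pre-computed scores (column `score`) or grades
#' (`intensity` plus `cellularity`, the latter as a 0-3 grade or a
#' percentage which is converted with [cellularity_grade()]). Rows whose
#' grades are unscorable (e.g. "Acellular" blocks, `n/a`) are marked
#' non-evaluable.
#'
#' @param path TSV or CSV file.
#' @return data.frame with at least `sample`, `score`, `evaluable`.
#' @export
read_ihc_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.table(path, header = TRUE, sep = delim_for(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          quote = "\"", comment.char = "")
  if (!("sample" %in% names(df))) stop(path, ": missing column: sample")

  parse_num <- function(x) suppressWarnings(as.numeric(x))

  if (all(c("intensity", "cellularity") %in% names(df))) {
    intensity <- parse_num(df$intensity)
    cellularity <- parse_num(df$cellularity)
    # percentages are converted to grades; grades pass through
    pct <- !is.na(cellularity) & cellularity > 3
    cellularity[pct] <- cellularity_grade(cellularity[pct])
    evaluable <- !is.na(intensity) & !is.na(cellularity)
    score <- rep(NA_integer_, nrow(df))
    score[evaluable] <- expression_score(intensity[evaluable],
                                         cellularity[evaluable])
    df$intensity <- intensity
    df$cellularity <- cellularity
    df$score <- score
    df$evaluable <- evaluable
  } else if ("score" %in% names(df)) {
    score <- parse_num(df$score)
    df$score <- score
    df$evaluable <- !is.na(score)
  } else {
    stop(path, ": need 'score' or 'intensity' + 'cellularity' columns")
  }
  df
}

#' Write a table of median-effect fits
#'
#' One row per (sample, drug) with `Dm`, `m`, `n_used`, `r_squared`.
#'
#' @param fits data.frame as produced by [run_synergy()] internals.
#' @param path output TSV/CSV path.
#' @return The path, invisibly.
#' @export
write_fit_table <- function(fits, path) {
  stopifnot(all(c("sample", "drug", "Dm", "m", "n_used", "r_squared")
                %in% names(fits)))
  write_delim_file(fits, path)
}

#' Read a table of median-effect fits
#'
#' @param path TSV/CSV written by [write_fit_table()].
#' @return Validated data.frame.
#' @export
read_fit_table <- function(path) {
  read_delim_checked(path, c("sample", "drug", "Dm", "m", "n_used",
                             "r_squared"),
                     numeric_cols = c("Dm", "m", "n_used", "r_squared"))
}
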