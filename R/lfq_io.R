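# Reading/writing protein-group quantification tables and experiment designs.
#
# Two table dialects are supported:
#  * "maxquant": the proteinGroups.txt layout ("Majority protein IDs",
#    "LFQ intensity <sample>", "MS/MS count <sample>", "+"-marked flag columns)
#  * "generic": literal columns protein_id, gene_name, reverse, contaminant,
#    site_only, lfq_<sample>, msms_<sample>
# Intensity 0 (or a blank/NaN cell) is the "not quantified" sentinel.

LFQ_FLAGS <- c("reverse", "contaminant", "site_only")

new_lfq_table <- function(df) {
  structure(tibble::as_tibble(df),
            class = c("lfq_tbl", "tbl_df", "tbl", "data.frame"))
}

#' Coerce a data frame to an LFQ protein-group table
#'
#' Validates and normalises an in-memory protein-group table into the shape
#' the rest of the pipeline expects: one row per protein group, a unique
#' `protein_id`, logical flag columns (`reverse`, `contaminant`, `site_only`),
#' raw LFQ intensities in `lfq_<sample>` columns (0 meaning "not quantified")
#' and spectral counts in `msms_<sample>` columns. A missing `msms_<sample>`
#' column for a quantified sample is filled with zeros; blank/NaN intensities
#' are recoded to 0.
#'
#' @param df A data frame with a `protein_id` column and at least one
#'   `lfq_<sample>` column.
#' @return A tibble of class `lfq_tbl`.
#' @export
as_lfq_table <- function(df) {
  df <- tibble::as_tibble(df)
  if (!"protein_id" %in% names(df)) {
    stop("missing required column(s): protein_id", call. = FALSE)
  }
  lfq_cols <- grep("^lfq_", names(df), value = TRUE)
  if (length(lfq_cols) == 0) {
    stop("missing required column(s): at least one 'lfq_<sample>' column",
         call. = FALSE)
  }
  df$protein_id <- as.character(df$protein_id)
  dup <- unique(df$protein_id[duplicated(df$protein_id)])
  if (length(dup) > 0) {
    stop("duplicate protein_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  if (!"gene_name" %in% names(df)) df$gene_name <- ""
  df$gene_name <- dplyr::coalesce(as.character(df$gene_name), "")
  for (fl in LFQ_FLAGS) {
    if (!fl %in% names(df)) df[[fl]] <- FALSE
    df[[fl]] <- parse_flag(df[[fl]])
  }
  samples <- sub("^lfq_", "", lfq_cols)
  for (s in samples) {
    lc <- paste0("lfq_", s)
    v <- suppressWarnings(as.numeric(df[[lc]]))
    v[!is.finite(v)] <- 0
    if (any(v < 0)) {
      stop("negative LFQ intensity in column ", lc, call. = FALSE)
    }
    df[[lc]] <- v
    mc <- paste0("msms_", s)
    if (!mc %in% names(df)) df[[mc]] <- 0L
    m <- suppressWarnings(as.numeric(df[[mc]]))
    m[!is.finite(m)] <- 0
    if (any(m < 0)) stop("negative MS/MS count in column ", mc, call. = FALSE)
    df[[mc]] <- as.integer(round(m))
  }
  keep <- c("protein_id", "gene_name", LFQ_FLAGS,
            paste0("lfq_", samples), paste0("msms_", samples))
  new_lfq_table(df[, keep])
}

parse_flag <- function(x) {
  if (is.logical(x)) return(dplyr::coalesce(x, FALSE))
  x <- trimws(as.character(x))
  out <- x %in% c("+", "TRUE", "true", "T", "1")
  out
}

#' Sample identifiers carried by an LFQ table
#'
#' @param table An `lfq_tbl`.
#' @return Character vector of sample ids, in column order.
#' @export
lfq_samples <- function(table) {
  sub("^lfq_", "", grep("^lfq_", names(table), value = TRUE))
}

#' Read a protein-group quantification table
#'
#' Reads a tab-delimited protein-group table in either the MaxQuant
#' `proteinGroups.txt` dialect or the package's generic dialect (see
#' [as_lfq_table()]). In the MaxQuant dialect the protein identifier is the
#' first semicolon-separated accession of the "Majority protein IDs" cell, and
#' rows are flagged from "+" marks in the "Reverse", "Potential contaminant"
#' and "Only identified by site" columns.
#'
#' @param path Path to a tab-delimited file with a header row.
#' @param dialect `"maxquant"` or `"generic"`.
#' @return A tibble of class `lfq_tbl`.
#' @export
read_protein_table <- function(path, dialect = c("maxquant", "generic")) {
  dialect <- match.arg(dialect)
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE, na = character())
  if (dialect == "generic") {
    return(as_lfq_table(raw))
  }
  id_col <- "Majority protein IDs"
  lfq_cols <- grep("^LFQ intensity ", names(raw), value = TRUE)
  missing <- character()
  if (!id_col %in% names(raw)) missing <- c(missing, id_col)
  if (length(lfq_cols) == 0) missing <- c(missing, "LFQ intensity <sample>")
  if (length(missing) > 0) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  samples <- sub("^LFQ intensity ", "", lfq_cols)
  out <- tibble::tibble(
    protein_id = first_token(raw[[id_col]]),
    gene_name = if ("Gene names" %in% names(raw)) {
      first_token(raw[["Gene names"]])
    } else "",
    reverse = mq_flag(raw, "Reverse"),
    contaminant = mq_flag(raw, "Potential contaminant"),
    site_only = mq_flag(raw, "Only identified by site")
  )
  for (s in samples) {
    out[[paste0("lfq_", s)]] <- raw[[paste0("LFQ intensity ", s)]]
    mc <- paste0("MS/MS count ", s)
    out[[paste0("msms_", s)]] <- if (mc %in% names(raw)) raw[[mc]] else 0L
  }
  as_lfq_table(out)
}

first_token <- function(x) {
  x <- dplyr::coalesce(as.character(x), "")
  vapply(strsplit(x, ";", fixed = TRUE),
         function(t) if (length(t) == 0) "" else trimws(t[[1]]),
         character(1))
}

mq_flag <- function(raw, col) {
  if (col %in% names(raw)) trimws(raw[[col]]) == "+" else rep(FALSE, nrow(raw))
}

#' Write a protein-group table
#'
#' Serialises an `lfq_tbl` as a tab-delimited UTF-8 file in either dialect.
#' The generic dialect round-trips exactly through
#' `read_protein_table(dialect = "generic")`.
#'
#' @param table An `lfq_tbl`.
#' @param path Output path.
#' @param dialect `"generic"` or `"maxquant"`.
#' @return `path`, invisibly.
#' @export
write_protein_table <- function(table, path, dialect = c("generic", "maxquant")) {
  dialect <- match.arg(dialect)
  if (dialect == "generic") {
    readr::write_tsv(table, path, progress = FALSE)
    return(invisible(path))
  }
  samples <- lfq_samples(table)
  out <- tibble::tibble(
    `Majority protein IDs` = table$protein_id,
    `Gene names` = table$gene_name,
    Reverse = ifelse(table$reverse, "+", ""),
    `Potential contaminant` = ifelse(table$contaminant, "+", ""),
    `Only identified by site` = ifelse(table$site_only, "+", "")
  )
  for (s in samples) {
    out[[paste0("LFQ intensity ", s)]] <- table[[paste0("lfq_", s)]]
    out[[paste0("MS/MS count ", s)]] <- table[[paste0("msms_", s)]]
  }
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

# ---------------------------------------------------------------------------
# Experiment design

#' Coerce a data frame to an experiment design
#'
#' The design maps each MS sample to its treatment condition, biological
#' replicate and experiment. Conditions are `"vehicle"` (the DMSO control;
#' `"dmso"` is accepted as a synonym) and `"bafa1"` (bafilomycin A1, which
#' blocks lysosomal degradation so autophagic cargo accumulates). Every
#' experiment must contribute at least two samples per condition; the total
#' row count per experiment is the sample size n used as the meta-analysis
#' weight base.
#'
#' @param df Data frame with columns `sample_id`, `condition`, `replicate`
#'   and optionally `experiment` (defaults to `"exp1"`).
#' @return A tibble of class `lfq_design`.
#' @export
as_lfq_design <- function(df) {
  df <- tibble::as_tibble(df)
  if (nrow(df) == 0) stop("experiment design is empty", call. = FALSE)
  need <- c("sample_id", "condition", "replicate")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0) {
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (!"experiment" %in% names(df)) df$experiment <- "exp1"
  df$sample_id <- as.character(df$sample_id)
  df$experiment <- as.character(df$experiment)
  cond <- tolower(trimws(as.character(df$condition)))
  cond[cond == "dmso"] <- "vehicle"
  bad <- setdiff(unique(cond), c("vehicle", "bafa1"))
  if (length(bad) > 0) {
    stop("condition must be 'vehicle'/'dmso' or 'bafa1'; got: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  df$condition <- cond
  df$replicate <- as.integer(df$replicate)
  if (any(is.na(df$replicate) | df$replicate < 1)) {
    stop("replicate must be a positive integer", call. = FALSE)
  }
  dup <- unique(df$sample_id[duplicated(df$sample_id)])
  if (length(dup) > 0) {
    stop("duplicate sample_id: ", paste(dup, collapse = ", "), call. = FALSE)
  }
  counts <- dplyr::count(df, .data$experiment, .data$condition)
  for (e in unique(df$experiment)) {
    for (cc in c("vehicle", "bafa1")) {
      k <- counts$n[counts$experiment == e & counts$condition == cc]
      if (length(k) == 0 || k < 2) {
        stop("experiment '", e, "' needs >= 2 samples in condition '", cc, "'",
             call. = FALSE)
      }
    }
  }
  structure(df[, c("sample_id", "condition", "replicate", "experiment")],
            class = c("lfq_design", "tbl_df", "tbl", "data.frame"))
}

#' Read an experiment design file
#'
#' The design file is a tab-delimited table with columns `sample_id`,
#' `condition`, `replicate` and `experiment`; see [as_lfq_design()].
#'
#' @param path Path to the design TSV.
#' @return A tibble of class `lfq_design`.
#' @export
read_design <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                        progress = FALSE)
  as_lfq_design(df)
}

#' Sample size per experiment
#'
#' Counts design rows per experiment; these totals (e.g. n = 8 for a
#' 4-vs-4 design) are the weight bases of the meta-analysis.
#'
#' @param design An `lfq_design`.
#' @return Named integer vector, experiments in order of appearance.
#' @export
n_per_experiment <- function(design) {
  exps <- unique(design$experiment)
  stats::setNames(vapply(exps, function(e) sum(design$experiment == e),
                         integer(1)), exps)
}

#' Write a results table
#'
#' Writes any per-protein results tibble (differential, meta, correlation) as
#' a tab-delimited UTF-8 file with Unix newlines, columns in their documented
#' order and doubles serialised at full round-trip precision.
#'
#' @param rows A data frame (may have zero rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_results_table <- function(rows, path) {
  stopifnot(is.data.frame(rows))
  readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read back a results table
#'
#' @param path Path written by [write_results_table()].
#' @return A tibble.
#' @export
read_results_table <- function(path) {
  readr::read_tsv(path, progress = FALSE, show_col_types = FALSE)
}
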