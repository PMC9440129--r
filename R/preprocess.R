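# Inclusion filters and the log2 transform.
#
# Order of play in the full pipeline: decoy/contaminant removal, the
# spectral-count filter, log2 transform, imputation, background filter,
# per-protein t tests, then proteinase-K-resistance exclusion of candidates.

#' Drop decoy, contaminant and site-only identifications
#'
#' Removes rows flagged as reversed-decoy, potential contaminant or
#' "only identified by site". Row order is preserved; an all-flagged table
#' legally becomes empty.
#'
#' @param table An `lfq_tbl`.
#' @return The filtered `lfq_tbl`.
#' @export
remove_flagged <- function(table) {
  keep <- !(table$reverse | table$contaminant | table$site_only)
  table[keep, ]
}

#' Filter proteins on spectral-count support
#'
#' Keeps proteins with at least `min_total` summed MS/MS spectral counts
#' across the replicates of *each* condition ("more than two spectral counts
#' across the biological replicates in both treatment groups" reads as a
#' summed count > 2, i.e. >= 3, per condition group). With
#' `per_replicate = TRUE` the stricter reading is applied instead: every
#' single replicate must carry `min_total` counts. The rule is applied per
#' experiment in the design; a protein must pass in every experiment present.
#'
#' @param table An `lfq_tbl`.
#' @param design An `lfq_design` whose samples are all present in `table`.
#' @param min_total Minimum summed (or, with `per_replicate`, per-replicate)
#'   spectral count; default 3.
#' @param per_replicate Apply the threshold to each replicate separately.
#' @return The filtered `lfq_tbl`.
#' @export
filter_spectral_counts <- function(table, design, min_total = 3,
                                   per_replicate = FALSE) {
  if (min_total < 0) stop("min_total must be >= 0", call. = FALSE)
  check_design_samples(table, design)
  keep <- rep(TRUE, nrow(table))
  groups <- split(design$sample_id,
                  paste(design$experiment, design$condition, sep = "\r"))
  for (ids in groups) {
    counts <- as.matrix(table[, paste0("msms_", ids), drop = FALSE])
    ok <- if (per_replicate) {
      rowSums(counts >= min_total) == length(ids)
    } else {
      rowSums(counts) >= min_total
    }
    keep <- keep & ok
  }
  table[keep, ]
}

check_design_samples <- function(table, design) {
  missing <- setdiff(design$sample_id, lfq_samples(table))
  if (length(missing) > 0) {
    stop("design sample(s) absent from the protein table: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Log2-transform LFQ intensities into a long intensity matrix
#'
#' Produces a long tibble with one row per protein x design sample. Quantified
#' entries (raw intensity > 0) get `log2_intensity = log2(raw)` and
#' `observed = TRUE`; the 0/NaN "not quantified" sentinel becomes
#' `observed = FALSE` with an `NA` placeholder value. Rows are ordered
#' sample-major (samples in design order, proteins in table order), which is
#' also the documented draw order of [impute_downshifted()].
#'
#' @param table A filtered `lfq_tbl`.
#' @param design An `lfq_design`.
#' @return A tibble of class `lfq_matrix` with columns `protein_id`,
#'   `sample_id`, `log2_intensity`, `observed`.
#' @export
log2_transform <- function(table, design) {
  check_design_samples(table, design)
  cols <- purrr::map(design$sample_id, function(s) {
    raw <- table[[paste0("lfq_", s)]]
    if (any(raw < 0)) stop("negative intensity in sample ", s, call. = FALSE)
    observed <- is.finite(raw) & raw > 0
    tibble::tibble(
      protein_id = table$protein_id,
      sample_id = s,
      log2_intensity = ifelse(observed, log2(raw), NA_real_),
      observed = observed
    )
  })
  out <- dplyr::bind_rows(cols)
  structure(out, class = c("lfq_matrix", "tbl_df", "tbl", "data.frame"))
}

#' Exclude proteinase-K-resistant candidates
#'
#' Candidates surviving proteinase K in the detergent (RAPIGest) control —
#' where membranes are dissolved, so survival marks digestion resistance
#' rather than membrane protection — are artefacts and are removed from the
#' candidate set by plain set difference.
#'
#' @param candidates Character vector of candidate protein ids.
#' @param rapigest_candidates Character vector of ids called in the
#'   detergent + proteinase K control run.
#' @return `candidates` without the resistant ids (order preserved).
#' @export
exclude_protk_resistant <- function(candidates, rapigest_candidates) {
  candidates <- as.character(candidates)
  setdiff(candidates, as.character(rapigest_candidates))
}
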