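# End-to-end orchestration. Stage order is fixed: read -> decoy/contaminant
# removal -> spectral-count filter -> log2 -> imputation -> background filter
# -> t tests -> proteinase-K-resistance exclusion -> meta-analysis. The
# pre-imputation observed mask stays authoritative for the background filter.

#' Run the cargo-calling pipeline end-to-end
#'
#' Executes the full analysis for one or more experiments and, when at least
#' two are supplied, combines them by weighted-Z meta-analysis. Each
#' experiment is a `list(table, design)` where either element may also be a
#' file path (`table` read with [read_protein_table()] using `dialect`,
#' `design` with [read_design()]). An optional detergent (RAPIGest) +
#' proteinase K control run, given the same way, is analysed identically; its
#' candidates are digestion-resistant artefacts and are removed from every
#' experiment's candidate set.
#'
#' Per experiment the stages are: [remove_flagged()],
#' [filter_spectral_counts()] (`min_msms_total`), [log2_transform()],
#' [impute_downshifted()] (`width_factor`, `downshift`, seeded),
#' [filter_background()] (`min_observed`), [ttest_volcano()] (`alpha`).
#' Meta-analysis ([meta_analyse()]) uses all tested proteins' (p, direction)
#' pairs over the cross-experiment intersection, not only candidates.
#'
#' Row counts of every stage are logged; re-running with the same inputs and
#' `seed` is bit-reproducible. The imputation seed of experiment i is
#' `seed + i` (the control uses `seed + 1000`).
#'
#' @param experiments Named list of experiments (`list(table, design)`).
#' @param rapigest Optional control run (`list(table, design)`) or a plain
#'   character vector of resistant protein ids.
#' @param dialect Table dialect used when `table` entries are paths.
#' @param min_msms_total Spectral-count threshold per condition group.
#' @param per_replicate Use the per-replicate spectral-count reading.
#' @param min_observed Observation threshold of the background filter.
#' @param width_factor,downshift Imputation parameters.
#' @param alpha Per-experiment candidate-calling level.
#' @param fdr_threshold Meta-analysis FDR level.
#' @param seed Integer seed driving all imputation draws.
#' @param out_dir Optional directory; when given, differential tables, the
#'   meta table, candidate lists, the stage log and a JSON run manifest are
#'   written there.
#' @return An object of class `cargo_run`: list with `differential` (named
#'   list of `lfq_differential`), `candidates` (named list of id vectors,
#'   post-exclusion), `rapigest_resistant` (id vector), `meta` (`lfq_meta` or
#'   `NULL` for a single experiment), `log` (tibble) and `manifest` (list).
#' @export
run_cargo_pipeline <- function(experiments, rapigest = NULL,
                               dialect = "maxquant",
                               min_msms_total = 3, per_replicate = FALSE,
                               min_observed = 2,
                               width_factor = 0.25, downshift = 1.8,
                               alpha = 0.05, fdr_threshold = 0.05,
                               seed = 1, out_dir = NULL) {
  if (length(experiments) == 0) stop("no experiments supplied", call. = FALSE)
  if (is.null(names(experiments)) || any(names(experiments) == "")) {
    stop("experiments must be a named list", call. = FALSE)
  }
  log_rows <- list()
  note <- function(experiment, stage, n) {
    log_rows[[length(log_rows) + 1]] <<-
      tibble::tibble(experiment = experiment, stage = stage, n_proteins = n)
  }

  run_one <- function(name, exp, exp_seed) {
    table <- if (is.character(exp$table)) {
      read_protein_table(exp$table, dialect = dialect)
    } else exp$table
    design <- if (is.character(exp$design)) {
      read_design(exp$design)
    } else exp$design
    withCallingHandlers({
      note(name, "input", nrow(table))
      table <- remove_flagged(table)
      note(name, "remove_flagged", nrow(table))
      table <- filter_spectral_counts(table, design,
                                      min_total = min_msms_total,
                                      per_replicate = per_replicate)
      note(name, "filter_spectral_counts", nrow(table))
      mat <- log2_transform(table, design)
      mat <- impute_downshifted(mat, width_factor = width_factor,
                                downshift = downshift, seed = exp_seed)
      mat <- filter_background(mat, design, min_observed = min_observed)
      note(name, "filter_background", length(unique(mat$protein_id)))
      diff <- ttest_volcano(mat, design, alpha = alpha)
      note(name, "ttest_volcano", nrow(diff))
      list(design = design, differential = diff)
    }, error = function(e) {
      stop("experiment '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }

  runs <- purrr::imap(experiments,
                      function(exp, name) {
                        i <- match(name, names(experiments))
                        run_one(name, exp, seed + i)
                      })

  resistant <- character()
  if (!is.null(rapigest)) {
    resistant <- if (is.character(rapigest)) {
      rapigest
    } else {
      ctrl <- run_one("rapigest_control", rapigest, seed + 1000)
      ctrl$differential$protein_id[ctrl$differential$candidate]
    }
  }

  candidates <- purrr::map(runs, function(r) {
    called <- r$differential$protein_id[r$differential$candidate]
    exclude_protk_resistant(called, resistant)
  })

  meta <- NULL
  if (length(runs) >= 2) {
    design_all <- as_lfq_design(
      dplyr::bind_rows(purrr::map(runs, "design"))
    )
    meta <- meta_analyse(purrr::map(runs, "differential"), design_all,
                         fdr_threshold = fdr_threshold)
  }

  manifest <- list(
    package = "cargocall",
    version = as.character(utils::packageVersion("cargocall")),
    seed = seed,
    parameters = list(
      dialect = dialect, min_msms_total = min_msms_total,
      per_replicate = per_replicate, min_observed = min_observed,
      width_factor = width_factor, downshift = downshift,
      alpha = alpha, fdr_threshold = fdr_threshold
    ),
    experiments = names(experiments),
    rapigest_control = !is.null(rapigest)
  )

  out <- structure(list(
    differential = purrr::map(runs, "differential"),
    candidates = candidates,
    rapigest_resistant = resistant,
    meta = meta,
    log = dplyr::bind_rows(log_rows),
    manifest = manifest
  ), class = "cargo_run")

  if (!is.null(out_dir)) write_run(out, out_dir)
  out
}

write_run <- function(run, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (e in names(run$differential)) {
    write_results_table(run$differential[[e]],
                        file.path(out_dir, paste0("differential_", e, ".tsv")))
    writeLines(run$candidates[[e]],
               file.path(out_dir, paste0("candidates_", e, ".txt")))
  }
  if (!is.null(run$meta)) {
    write_results_table(run$meta, file.path(out_dir, "meta.tsv"))
  }
  write_results_table(run$log, file.path(out_dir, "stage_log.tsv"))
  jsonlite::write_json(run$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.cargo_run <- function(x, ...) {
  cat("<cargo_run>", length(x$differential), "experiment(s)\n")
  for (e in names(x$differential)) {
    cat("  ", e, ": ", nrow(x$differential[[e]]), " proteins tested, ",
        length(x$candidates[[e]]), " candidate(s)\n", sep = "")
  }
  if (!is.null(x$meta)) {
    cat("  meta: ", nrow(x$meta), " shared proteins, ",
        sum(x$meta$significant), " significant at FDR ",
        attr(x$meta, "fdr_threshold"), "\n", sep = "")
  }
  invisible(x)
}

#' Tidy a pipeline run into one per-protein table
#'
#' Returns the meta-analysis table when one was computed, otherwise the
#' single experiment's differential table.
#'
#' @param x A `cargo_run`.
#' @param ... Unused.
#' @return A tibble.
#' @method tidy cargo_run
#' @export
tidy.cargo_run <- function(x, ...) {
  if (!is.null(x$meta)) tibble::as_tibble(x$meta)
  else tibble::as_tibble(x$differential[[1]])
}

#' One-row summary of a pipeline run
#'
#' @param x A `cargo_run`.
#' @param ... Unused.
#' @return A one-row tibble with experiment, candidate and meta counts.
#' @method glance cargo_run
#' @export
glance.cargo_run <- function(x, ...) {
  tibble::tibble(
    n_experiments = length(x$differential),
    n_proteins_tested = sum(vapply(x$differential, nrow, integer(1))),
    n_candidates = length(unique(unlist(x$candidates))),
    n_rapigest_resistant = length(x$rapigest_resistant),
    n_meta_proteins = if (is.null(x$meta)) NA_integer_ else nrow(x$meta),
    n_meta_significant = if (is.null(x$meta)) NA_integer_
                         else sum(x$meta$significant),
    seed = x$manifest$seed
  )
}

#' @method glance lfq_differential
#' @export
glance.lfq_differential <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_candidates = sum(x$candidate),
    alpha = attr(x, "alpha"),
    min_p = if (nrow(x)) min(x$p_value) else NA_real_
  )
}

#' @method glance lfq_meta
#' @export
glance.lfq_meta <- function(x, ...) {
  tibble::tibble(
    n_proteins = nrow(x),
    n_significant = sum(x$significant),
    fdr_threshold = attr(x, "fdr_threshold"),
    min_q = if (nrow(x)) min(x$q_value) else NA_real_
  )
}
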