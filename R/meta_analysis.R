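# Cross-experiment combination: each experiment's two-tailed p and fold-change
# direction become a signed normal deviate; deviates are combined with
# square-root-of-sample-size weights (Stouffer) and the combined p-values are
# Benjamini-Hochberg corrected across the proteins detected in every
# experiment.

#' Convert a two-tailed p-value and a direction to a signed z-score
#'
#' `z = sign(direction) * qnorm(1 - p/2)`. p-values are floored at 1e-300
#' before inversion to avoid infinite deviates.
#'
#' @param p_two_tailed p-value(s) in (0, 1].
#' @param direction Sign carrier (e.g. the log2 fold change); only its sign
#'   is used. A zero direction yields z = 0.
#' @return Signed z-score(s).
#' @export
p_to_signed_z <- function(p_two_tailed, direction) {
  if (any(!is.finite(p_two_tailed)) ||
      any(p_two_tailed <= 0 | p_two_tailed > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  p <- pmax(p_two_tailed, 1e-300)
  sign(direction) * stats::qnorm(p / 2, lower.tail = FALSE)
}

#' Combine signed z-scores with square-root-of-n weights
#'
#' Stouffer's weighted method:
#' `z_meta = sum(sqrt(n_i) * z_i) / sqrt(sum(n_i))`, with the two-tailed
#' `p_meta = 2 * (1 - pnorm(|z_meta|))`. `n_i` is the *total* sample count of
#' experiment i (e.g. 8 for a 4-vs-4 design).
#'
#' @param z_list Numeric vector of signed z-scores, one per experiment.
#' @param n_list Sample sizes (>= 1), same length.
#' @return A list with elements `z_meta` and `p_meta`.
#' @export
stouffer_weighted <- function(z_list, n_list) {
  if (length(z_list) == 0 || length(z_list) != length(n_list)) {
    stop("z_list and n_list must be non-empty and of equal length",
         call. = FALSE)
  }
  if (any(n_list < 1)) stop("sample sizes must be >= 1", call. = FALSE)
  z_meta <- sum(sqrt(n_list) * z_list) / sqrt(sum(n_list))
  p_meta <- 2 * stats::pnorm(abs(z_meta), lower.tail = FALSE)
  list(z_meta = z_meta, p_meta = max(p_meta, 1e-300))
}

#' Benjamini-Hochberg step-up q-values
#'
#' Standard step-up adjustment: sort ascending, `q_i = min_{j >= i} p_j * m/j`
#' clipped at 1, returned in input order.
#'
#' @param p_vector Non-empty vector of p-values in (0, 1].
#' @return q-values in input order.
#' @export
benjamini_hochberg <- function(p_vector) {
  if (length(p_vector) == 0) stop("p_vector must be non-empty", call. = FALSE)
  if (any(!is.finite(p_vector)) || any(p_vector <= 0 | p_vector > 1)) {
    stop("p-values must lie in (0, 1]", call. = FALSE)
  }
  stats::p.adjust(p_vector, method = "BH")
}

#' Meta-analyse per-experiment differential tables
#'
#' Restricts to proteins detected in *every* experiment, converts each
#' experiment's (p, fold-change sign) to a signed z ([p_to_signed_z()]),
#' combines with [stouffer_weighted()] using each experiment's total n from
#' the design, BH-corrects the combined p-values across the intersection and
#' flags proteins with `q < fdr_threshold`. Directional combination means
#' experiments disagreeing in sign cancel rather than reinforce.
#'
#' @param tables Named list (>= 2) of `lfq_differential` tables; names must
#'   match experiments in `design`.
#' @param design An `lfq_design` covering all experiments.
#' @param fdr_threshold FDR level for the `significant` flag (default 0.05).
#' @return A tibble of class `lfq_meta` with per-experiment signed z columns
#'   (`z_<experiment>`), `z_meta`, `p_meta`, `q_value`, `significant`.
#' @export
meta_analyse <- function(tables, design, fdr_threshold = 0.05) {
  if (length(tables) < 2) {
    stop("meta_analyse needs >= 2 experiments", call. = FALSE)
  }
  if (is.null(names(tables)) || any(names(tables) == "")) {
    stop("tables must be a named list keyed by experiment", call. = FALSE)
  }
  n_map <- n_per_experiment(design)
  missing <- setdiff(names(tables), names(n_map))
  if (length(missing) > 0) {
    stop("experiment(s) absent from design: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  shared <- Reduce(intersect, lapply(tables, function(t) t$protein_id))
  if (length(shared) == 0) {
    warning("no protein detected in every experiment; empty meta table",
            call. = FALSE)
    out <- tibble::tibble(protein_id = character(), z_meta = double(),
                          p_meta = double(), q_value = double(),
                          significant = logical())
    return(structure(out, fdr_threshold = fdr_threshold,
                     class = c("lfq_meta", "tbl_df", "tbl", "data.frame")))
  }
  z_cols <- purrr::map(tables, function(t) {
    idx <- match(shared, t$protein_id)
    p_to_signed_z(t$p_value[idx], t$log2fc[idx])
  })
  z_mat <- do.call(cbind, z_cols)
  n <- n_map[names(tables)]
  z_meta <- as.numeric(z_mat %*% sqrt(n)) / sqrt(sum(n))
  p_meta <- pmax(2 * stats::pnorm(abs(z_meta), lower.tail = FALSE), 1e-300)
  q <- benjamini_hochberg(p_meta)
  out <- tibble::tibble(protein_id = shared)
  for (e in names(tables)) out[[paste0("z_", e)]] <- z_cols[[e]]
  out$z_meta <- z_meta
  out$p_meta <- p_meta
  out$q_value <- q
  out$significant <- q < fdr_threshold
  structure(out, fdr_threshold = fdr_threshold,
            class = c("lfq_meta", "tbl_df", "tbl", "data.frame"))
}
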