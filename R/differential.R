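# Per-experiment candidate calling: observation filter, pooled-variance
# Student's t tests on the (imputed) log2 matrix, volcano coordinates, and
# replicate reproducibility.

#' Remove proteins without enough genuinely observed values
#'
#' Keeps proteins with at least `min_observed` non-imputed measurements
#' within at least one condition group ("greater-than-background values in
#' both replicates for at least one condition"). The pre-imputation observed
#' mask stays authoritative, so the filter behaves identically before or
#' after imputation; all-imputed proteins are always removed.
#'
#' @param matrix An `lfq_matrix` (imputed or not).
#' @param design An `lfq_design` covering the matrix's samples.
#' @param min_observed Minimum observed count in some condition group
#'   (default 2).
#' @return The matrix restricted to retained proteins.
#' @export
filter_background <- function(matrix, design, min_observed = 2) {
  if (min_observed < 1) stop("min_observed must be >= 1", call. = FALSE)
  m <- dplyr::inner_join(matrix, design, by = "sample_id")
  best <- m |>
    dplyr::group_by(.data$protein_id, .data$experiment, .data$condition) |>
    dplyr::summarise(n_obs = sum(.data$observed), .groups = "drop") |>
    dplyr::group_by(.data$protein_id) |>
    dplyr::summarise(best = max(.data$n_obs), .groups = "drop")
  keep <- best$protein_id[best$best >= min_observed]
  matrix[matrix$protein_id %in% keep, ]
}

#' Per-protein Student's t tests and volcano table
#'
#' For each protein, runs an unpaired two-tailed equal-variance (pooled)
#' Student's t test of BafA1 versus vehicle on the completed log2 matrix
#' (imputed values participate). The fold change is
#' `log2fc = mean(bafa1) - mean(vehicle)`, i.e. log2(BafA1:vehicle).
#' Candidates are proteins significantly *up* under BafA1:
#' `p < alpha` and `log2fc > 0`. Volcano coordinates are `log2fc` on x and
#' `neg_log10_p = -log10(p)` on y.
#'
#' A protein whose two groups have zero pooled variance gets t = 0, p = 1
#' when the means agree; with differing means the evidence is formally
#' infinite and p is floored at 1e-300.
#'
#' @param matrix A completed (imputed, background-filtered) `lfq_matrix`.
#' @param design An `lfq_design` describing a single experiment.
#' @param alpha Two-tailed significance level for candidate calling
#'   (default 0.05).
#' @return A tibble of class `lfq_differential` with columns `protein_id`,
#'   `log2fc`, `t_stat`, `p_value`, `neg_log10_p`, `n_vehicle`, `n_bafa1`,
#'   `candidate`.
#' @export
ttest_volcano <- function(matrix, design, alpha = 0.05) {
  if (length(unique(design$experiment)) != 1) {
    stop("ttest_volcano runs one experiment at a time; subset the design",
         call. = FALSE)
  }
  wide <- values_by_condition(matrix, design)
  v <- wide$vehicle
  b <- wide$bafa1
  nv <- ncol(v)
  nb <- ncol(b)
  if (nv < 2 || nb < 2) {
    stop("each condition needs >= 2 samples for the t test", call. = FALSE)
  }
  mv <- rowMeans(v)
  mb <- rowMeans(b)
  var_v <- rowSums((v - mv)^2) / (nv - 1)
  var_b <- rowSums((b - mb)^2) / (nb - 1)
  df <- nv + nb - 2
  sp2 <- ((nv - 1) * var_v + (nb - 1) * var_b) / df
  se <- sqrt(sp2 * (1 / nv + 1 / nb))
  log2fc <- mb - mv
  t_stat <- ifelse(se == 0, ifelse(log2fc == 0, 0, sign(log2fc) * Inf),
                   log2fc / se)
  p <- 2 * stats::pt(abs(t_stat), df = df, lower.tail = FALSE)
  p <- pmax(p, 1e-300)
  out <- tibble::tibble(
    protein_id = rownames(v),
    log2fc = unname(log2fc),
    t_stat = unname(t_stat),
    p_value = unname(p),
    neg_log10_p = unname(-log10(p)),
    n_vehicle = nv,
    n_bafa1 = nb,
    candidate = unname(p < alpha & log2fc > 0)
  )
  structure(out, alpha = alpha,
            class = c("lfq_differential", "tbl_df", "tbl", "data.frame"))
}

# protein x sample value matrices per condition, proteins in matrix order
values_by_condition <- function(matrix, design) {
  if (anyNA(matrix$log2_intensity)) {
    stop("matrix still has missing values; run impute_downshifted() first",
         call. = FALSE)
  }
  proteins <- unique(matrix$protein_id)
  lapply(split(design$sample_id, design$condition), function(ids) {
    cols <- vapply(ids, function(s) {
      sub <- matrix[matrix$sample_id == s, ]
      stats::setNames(sub$log2_intensity, sub$protein_id)[proteins]
    }, numeric(length(proteins)))
    cols <- base::matrix(cols, nrow = length(proteins),
                         dimnames = list(proteins, ids))
    cols
  })
}

#' Pairwise replicate reproducibility
#'
#' Pearson correlation of log2 intensities for every within-condition pair of
#' replicates, per experiment, computed over proteins genuinely observed in
#' both members of the pair. Pairs sharing fewer than 3 observed proteins get
#' an undefined (`NA`) coefficient.
#'
#' @param matrix An `lfq_matrix` (imputed values are ignored: only
#'   observed-in-both entries enter each correlation).
#' @param design An `lfq_design` with >= 2 replicates per condition.
#' @return A tibble of class `lfq_replicate_cor` with columns `experiment`,
#'   `condition`, `sample_1`, `sample_2`, `n_shared`, `pearson_r`.
#' @export
replicate_correlation <- function(matrix, design) {
  groups <- split(design,
                  paste(design$experiment, design$condition, sep = "\r"))
  rows <- purrr::map(unname(groups), function(g) {
    ids <- g$sample_id
    pairs <- utils::combn(ids, 2)
    purrr::map(seq_len(ncol(pairs)), function(k) {
      a <- matrix[matrix$sample_id == pairs[1, k], ]
      b <- matrix[matrix$sample_id == pairs[2, k], ]
      joint <- dplyr::inner_join(
        a[a$observed, c("protein_id", "log2_intensity")],
        b[b$observed, c("protein_id", "log2_intensity")],
        by = "protein_id", suffix = c("_1", "_2")
      )
      r <- if (nrow(joint) < 3) NA_real_ else {
        stats::cor(joint$log2_intensity_1, joint$log2_intensity_2)
      }
      tibble::tibble(
        experiment = g$experiment[1], condition = g$condition[1],
        sample_1 = pairs[1, k], sample_2 = pairs[2, k],
        n_shared = nrow(joint), pearson_r = r
      )
    })
  })
  out <- dplyr::bind_rows(rows)
  structure(out, class = c("lfq_replicate_cor", "tbl_df", "tbl", "data.frame"))
}
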