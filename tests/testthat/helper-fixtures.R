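# In-code fixtures: a 4-protein, 2 + 2 replicate toy experiment, and small
# builders used across the test files.

toy_design <- function(n_rep = 2, experiment = "exp1",
                       prefix = c("v", "b")) {
  as_lfq_design(tibble::tibble(
    sample_id = c(paste0(prefix[1], seq_len(n_rep)),
                  paste0(prefix[2], seq_len(n_rep))),
    condition = rep(c("vehicle", "bafa1"), each = n_rep),
    replicate = rep(seq_len(n_rep), 2),
    experiment = experiment
  ))
}

toy_table <- function() {
  as_lfq_table(tibble::tibble(
    protein_id = c("A", "B", "C", "D"),
    lfq_v1 = c(1024, 0, 512, 2048),
    lfq_v2 = c(2048, 0, 256, 1024),
    lfq_b1 = c(4096, 128, 0, 1024),
    lfq_b2 = c(8192, 64, 0, 2048),
    msms_v1 = c(3, 0, 2, 5), msms_v2 = c(2, 0, 1, 4),
    msms_b1 = c(4, 1, 0, 5), msms_b2 = c(5, 1, 0, 3)
  ))
}

# a completed (no missing) matrix from explicit per-sample values
matrix_from_values <- function(values_by_sample, protein_ids = NULL) {
  n <- length(values_by_sample[[1]])
  if (is.null(protein_ids)) protein_ids <- sprintf("P%03d", seq_len(n))
  rows <- purrr::imap(values_by_sample, function(v, s) {
    tibble::tibble(protein_id = protein_ids, sample_id = s,
                   log2_intensity = v, observed = !is.na(v))
  })
  structure(dplyr::bind_rows(rows),
            class = c("lfq_matrix", "tbl_df", "tbl", "data.frame"))
}

# independent standard normal CDF via the error function (pracma), used as
# the cross-check for the z <-> p conversions
phi_indep <- function(x) 0.5 * (1 + pracma::erf(x / sqrt(2)))

# exhaustive Benjamini-Hochberg step-up oracle: q_i = min_{j >= i} p_(j)*m/j
bh_oracle <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    cands <- vapply(i:m, function(j) p[ord[j]] * m / j, numeric(1))
    q_sorted[i] <- min(1, min(cands))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
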