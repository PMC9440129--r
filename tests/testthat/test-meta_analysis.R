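test_that("p-to-z conversion matches the inverse normal and its inverse", {
  expect_equal(p_to_signed_z(1, 1), 0)
  expect_equal(p_to_signed_z(0.05, 1), 1.959964, tolerance = 1e-6)
  expect_equal(p_to_signed_z(0.05, -2), -1.959964, tolerance = 1e-6)
  expect_error(p_to_signed_z(0, 1), "\\(0, 1\\]")
  expect_error(p_to_signed_z(1.2, 1), "\\(0, 1\\]")

  # round trip: z -> two-tailed p -> signed z is the identity on z > 0
  for (z in c(0.1, 0.5, 1, 1.96, 3, 5)) {
    p <- 2 * (1 - phi_indep(z))
    expect_equal(p_to_signed_z(p, 1), z, tolerance = 1e-8)
  }
  # extreme p-values are floored, not infinite
  expect_true(is.finite(p_to_signed_z(1e-320, 1)))
})

test_that("weighted Stouffer combination follows the stated formula", {
  # single study: identity
  one <- stouffer_weighted(2.5, 8)
  expect_equal(one$z_meta, 2.5)
  expect_equal(one$p_meta, 2 * (1 - phi_indep(2.5)), tolerance = 1e-10)

  # derived two-study case, checked against an independent normal CDF
  z <- p_to_signed_z(c(0.05, 0.05), c(1, 1))
  got <- stouffer_weighted(z, c(4, 4))
  z_expect <- sum(sqrt(c(4, 4)) * z) / sqrt(8)
  expect_equal(got$z_meta, z_expect, tolerance = 1e-12)
  expect_equal(got$z_meta, 2.771808, tolerance = 1e-6)
  expect_equal(got$p_meta, 2 * (1 - phi_indep(z_expect)), tolerance = 1e-10)
  expect_equal(got$p_meta, 0.005575, tolerance = 1e-4)

  # concordant evidence never weakens: all-equal z scales by sum(sqrt n)/sqrt(sum n) >= 1
  for (n in list(c(8, 6), c(4, 4, 4), c(2, 10))) {
    got <- stouffer_weighted(rep(1.3, length(n)), n)
    expect_equal(got$z_meta, 1.3 * sum(sqrt(n)) / sqrt(sum(n)))
    expect_gte(got$z_meta, 1.3)
  }

  expect_error(stouffer_weighted(c(1, 2), 8), "equal length")
  expect_error(stouffer_weighted(numeric(), numeric()), "non-empty")
  expect_error(stouffer_weighted(1, 0), ">= 1")
})

test_that("Benjamini-Hochberg equals the brute-force step-up", {
  expect_equal(benjamini_hochberg(0.03), 0.03)
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_equal(benjamini_hochberg(c(0.005, 0.01, 0.03, 0.9)),
               c(0.02, 0.02, 0.04, 0.9))
  expect_error(benjamini_hochberg(numeric()), "non-empty")
  expect_error(benjamini_hochberg(c(0.05, 0)), "\\(0, 1\\]")

  withr::with_seed(202, {
    for (k in 1:50) {
      p <- runif(sample(1:12, 1))
      q <- benjamini_hochberg(p)
      expect_equal(q, bh_oracle(p), tolerance = 1e-12)
      # monotone: p_i <= p_j implies q_i <= q_j
      expect_true(all(diff(q[order(p)]) >= -1e-12))
    }
  })
})

test_that("meta-analysis restricts to shared proteins and combines evidence", {
  d1 <- tibble::tibble(protein_id = c("IL7R", "ONLY1"),
                       log2fc = c(2.22, 1), p_value = c(0.033, 0.2))
  d2 <- tibble::tibble(protein_id = c("IL7R", "ONLY2"),
                       log2fc = c(1.5, -1), p_value = c(0.0089, 0.5))
  design <- as_lfq_design(dplyr::bind_rows(
    toy_design(n_rep = 4, experiment = "exp1", prefix = c("v", "b")),
    toy_design(n_rep = 3, experiment = "exp2", prefix = c("w", "c"))
  ))
  meta <- meta_analyse(list(exp1 = d1, exp2 = d2), design)
  expect_equal(meta$protein_id, "IL7R")      # detected-in-both restriction
  # with a single tested protein, q equals the combined p
  expect_equal(meta$q_value, meta$p_meta)
  ref <- stouffer_weighted(p_to_signed_z(c(0.033, 0.0089), c(1, 1)), c(8, 6))
  expect_equal(meta$z_meta, ref$z_meta)
  expect_equal(meta$p_meta, ref$p_meta)
  expect_true(meta$significant)
  expect_equal(meta$z_exp1, p_to_signed_z(0.033, 1))

  # opposite directions of equal strength and weight cancel
  e1 <- tibble::tibble(protein_id = "X", log2fc = 1, p_value = 0.01)
  e2 <- tibble::tibble(protein_id = "X", log2fc = -1, p_value = 0.01)
  design_eq <- as_lfq_design(dplyr::bind_rows(
    toy_design(n_rep = 2, experiment = "exp1", prefix = c("v", "b")),
    toy_design(n_rep = 2, experiment = "exp2", prefix = c("w", "c"))
  ))
  cancel <- meta_analyse(list(exp1 = e1, exp2 = e2), design_eq)
  expect_equal(cancel$z_meta, 0)
  expect_equal(cancel$p_meta, 1)

  # disjoint experiments: empty table with a warning
  expect_warning(
    empty <- meta_analyse(list(exp1 = d1[2, ], exp2 = d2[2, ]), design),
    "every experiment")
  expect_equal(nrow(empty), 0)

  expect_error(meta_analyse(list(exp1 = d1), design), ">= 2")
  expect_error(meta_analyse(list(d1, d2), design), "named")
})

test_that("meta-analysis controls the FDR on two-experiment null data", {
  m <- 2000
  runs <- 50
  design <- as_lfq_design(dplyr::bind_rows(
    toy_design(n_rep = 4, experiment = "exp1", prefix = c("v", "b")),
    toy_design(n_rep = 3, experiment = "exp2", prefix = c("w", "c"))
  ))
  withr::with_seed(404, {
    rates <- vapply(seq_len(runs), function(r) {
      mk <- function() {
        z <- rnorm(m)
        tibble::tibble(protein_id = sprintf("P%04d", 1:m),
                       log2fc = sign(z) * abs(rnorm(m)),
                       p_value = 2 * pnorm(-abs(z)))
      }
      meta <- meta_analyse(list(exp1 = mk(), exp2 = mk()), design)
      mean(meta$significant)
    }, numeric(1))
  })
  expect_lte(mean(rates), 0.05)
})
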