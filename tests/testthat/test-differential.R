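test_that("background filter counts genuinely observed values per condition", {
  design <- toy_design(n_rep = 4)
  obs_pattern <- list(
    keep_vehicle = c(TRUE, TRUE, FALSE, FALSE,  FALSE, FALSE, FALSE, FALSE),
    drop_spread  = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE),
    keep_full    = rep(TRUE, 8),
    drop_all     = rep(FALSE, 8)
  )
  cols <- purrr::map(seq_along(design$sample_id), function(i) {
    vals <- vapply(obs_pattern, function(p) if (p[i]) 20 else NA_real_,
                   numeric(1))
    vals
  })
  m <- matrix_from_values(stats::setNames(cols, design$sample_id),
                          protein_ids = names(obs_pattern))
  kept <- unique(filter_background(m, design)$protein_id)
  expect_setequal(kept, c("keep_vehicle", "keep_full"))
  expect_error(filter_background(m, design, min_observed = 0), "min_observed")
})

test_that("t statistics match stats::t.test (pooled variance) exactly", {
  design <- toy_design(n_rep = 3)
  m <- matrix_from_values(list(
    v1 = c(1, 10), v2 = c(2, 10), v3 = c(3, 10),
    b1 = c(4, 10), b2 = c(5, 11), b3 = c(6, 9)
  ), protein_ids = c("rising", "flat"))
  out <- ttest_volcano(m, design)
  expect_equal(out$log2fc[1], 3)
  ref <- t.test(c(4, 5, 6), c(1, 2, 3), var.equal = TRUE)
  expect_equal(out$t_stat[1], unname(ref$statistic), tolerance = 1e-12)
  expect_equal(out$p_value[1], ref$p.value, tolerance = 1e-12)
  expect_equal(out$n_vehicle[1], 3)
  expect_equal(out$n_bafa1[1], 3)
  # identical group means with positive variance: t = 0, p = 1
  expect_equal(out$t_stat[2], 0)
  expect_equal(out$p_value[2], 1)
  expect_false(out$candidate[2])

  # 20 random instances against the independent oracle
  withr::with_seed(77, {
    for (k in 1:20) {
      nv <- sample(2:5, 1); nb <- sample(2:5, 1)
      v <- rnorm(nv, 20, 1); b <- rnorm(nb, 20.5, 1)
      d <- as_lfq_design(tibble::tibble(
        sample_id = c(paste0("v", 1:nv), paste0("b", 1:nb)),
        condition = rep(c("vehicle", "bafa1"), c(nv, nb)),
        replicate = c(1:nv, 1:nb)
      ))
      mm <- matrix_from_values(stats::setNames(
        as.list(c(v, b)), d$sample_id), protein_ids = "p")
      got <- ttest_volcano(mm, d)
      ref <- t.test(b, v, var.equal = TRUE)
      expect_equal(got$t_stat, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$p_value, ref$p.value, tolerance = 1e-10)
      expect_equal(got$log2fc, mean(b) - mean(v), tolerance = 1e-12)
    }
  })
})

test_that("candidates are exactly the significantly upregulated proteins", {
  design <- toy_design(n_rep = 3)
  m <- matrix_from_values(list(
    v1 = c(10, 20.0), v2 = c(10.1, 20.1), v3 = c(9.9, 19.9),
    b1 = c(14, 16.0), b2 = c(14.1, 16.1), b3 = c(13.9, 15.9)
  ), protein_ids = c("up", "down"))
  out <- ttest_volcano(m, design, alpha = 0.05)
  expect_true(out$candidate[out$protein_id == "up"])
  down <- out[out$protein_id == "down", ]
  expect_lt(down$p_value, 0.05)
  expect_false(down$candidate)      # direction filter: upregulated only
  expect_equal(out$candidate, out$p_value < 0.05 & out$log2fc > 0)
  expect_equal(out$neg_log10_p, -log10(out$p_value))
})

test_that("t tests are invariant to row order and label swaps", {
  st <- simulate_experiment(simulation_params(n_proteins = 60,
                                              dropout_midpoint = -Inf),
                            seed = 9)
  m <- log2_transform(st$table, st$design)
  base <- ttest_volcano(m, st$design)

  perm <- m[order(m$protein_id, decreasing = TRUE), ]
  class(perm) <- class(m)
  re <- ttest_volcano(perm, st$design)
  re <- re[match(base$protein_id, re$protein_id), ]
  expect_equal(re$t_stat, base$t_stat)

  # swapping replicate labels within a condition changes nothing
  d2 <- st$design
  d2$replicate[d2$condition == "vehicle"] <-
    rev(d2$replicate[d2$condition == "vehicle"])
  expect_equal(ttest_volcano(m, d2)$p_value, base$p_value)

  # swapping the condition labels negates fc and t, preserves p
  d3 <- st$design
  d3$condition <- ifelse(d3$condition == "vehicle", "bafa1", "vehicle")
  flipped <- ttest_volcano(m, d3)
  expect_equal(flipped$log2fc, -base$log2fc)
  expect_equal(flipped$t_stat, -base$t_stat)
  expect_equal(flipped$p_value, base$p_value)
})

test_that("null data yields a uniform significance rate", {
  design <- toy_design(n_rep = 4)
  withr::with_seed(123, {
    vals <- purrr::map(design$sample_id, ~ rnorm(5000, 22, 1))
  })
  m <- matrix_from_values(stats::setNames(vals, design$sample_id))
  out <- ttest_volcano(m, design)
  rate <- mean(out$p_value < 0.05)
  half <- qnorm(0.995) * sqrt(0.05 * 0.95 / 5000)
  expect_gt(rate, 0.05 - half)
  expect_lt(rate, 0.05 + half)
})

test_that("replicate correlations use observed-in-both entries only", {
  design <- toy_design(n_rep = 2)
  x <- c(20, 21, 22, 23, NA)
  m <- matrix_from_values(list(
    v1 = x, v2 = x,                       # duplicates -> r = 1
    b1 = c(1, 2, 3, 4, 5),
    b2 = c(5, 4, 3, 2, 1)                 # exact negation about mean -> -1
  ))
  out <- replicate_correlation(m, design)
  expect_s3_class(out, "lfq_replicate_cor")
  v <- out[out$condition == "vehicle", ]
  expect_equal(v$pearson_r, 1)
  expect_equal(v$n_shared, 4)             # NA row excluded from the pair
  b <- out[out$condition == "bafa1", ]
  expect_equal(b$pearson_r, -1)

  # fewer than 3 shared observed proteins -> undefined
  sparse <- matrix_from_values(list(
    v1 = c(1, 2, NA, NA, NA), v2 = c(NA, 2, 3, NA, NA),
    b1 = c(1, 2, 3, 4, 5), b2 = c(1, 2, 3, 4, 5)
  ))
  sp <- replicate_correlation(sparse, design)
  expect_true(is.na(sp$pearson_r[sp$condition == "vehicle"]))

  # random columns: small |r|, equal to the direct sum-formula evaluation
  withr::with_seed(55, {
    a <- rnorm(1e4); b2 <- rnorm(1e4)
  })
  big <- matrix_from_values(list(v1 = a, v2 = b2,
                                 b1 = a, b2 = a))
  r <- replicate_correlation(big, design)
  r_v <- r$pearson_r[r$condition == "vehicle"]
  sum_formula <- (sum(a * b2) - length(a) * mean(a) * mean(b2)) /
    ((length(a) - 1) * sd(a) * sd(b2))
  expect_equal(r_v, sum_formula, tolerance = 1e-10)
  expect_lt(abs(r_v), 0.05)
})
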