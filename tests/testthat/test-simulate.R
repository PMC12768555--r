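test_that("degenerate class probabilities force the whole row", {
  tb <- builtin_tables()
  probs <- rbind(c(1, 0, 0, 0, 0, 0), tb$overall$probs[c("M", "N"), ])
  spec <- hypothesis_spec("h1", "fixed", class_probs = probs)
  set.seed(1)
  counts <- simulate_participant(spec)
  expect_equal(unname(counts[1, ]), c(8, 0, 0, 0, 0, 0))
  expect_equal(unname(rowSums(counts)), c(8, 8, 8))
  expect_equal(sum(counts), 24)
})

test_that("null-regime rows are identically distributed with binomial means", {
  spec <- hypothesis_spec("h0", "fixed")
  cohort <- simulate_cohort(spec, 10000, seed = 11, keep_counts = TRUE)
  # mean F-row count of the most frequent class: 8 * 0.45 = 3.6
  se <- sqrt(8 * 0.45 * 0.55 / 10000)
  expect_equal(mean(cohort$F_en), 3.6, tolerance = 3 * se / 3.6)
  expect_equal(mean(cohort$M_en), 3.6, tolerance = 3 * se / 3.6)
  expect_equal(mean(cohort$N_en), 3.6, tolerance = 3 * se / 3.6)
})

test_that("sampled-gender design draws gender counts from the marginal", {
  spec <- hypothesis_spec("h1", "sampled")
  expect_equal(unname(spec$gender_weights), c(0.42, 0.38, 0.20))
  cohort <- simulate_cohort(spec, 10000, seed = 12, keep_counts = TRUE)
  f_items <- rowSums(cohort[, paste0("F_", plural_classes())])
  se <- sqrt(24 * 0.42 * 0.58 / 10000)
  expect_equal(mean(f_items), 24 * 0.42, tolerance = 3 * se / (24 * 0.42))
  cell_cols <- as.vector(t(outer(genders(), plural_classes(),
                                 paste, sep = "_")))
  expect_equal(unname(rowSums(cohort[, cell_cols])), rep(24, 10000))
})

test_that("participant summaries hit their closed forms", {
  # all 24 productions in one class
  m <- matrix(0, 3, 6)
  m[, 1] <- 8
  s <- summarize_counts(m)
  expect_equal(s$entropy_bits, 0)
  expect_equal(s$mi_bits, 0)
  expect_equal(s$ratio, 0)
  # perfect conditioning: one class per gender
  m2 <- matrix(0, 3, 6)
  m2[1, 1] <- 8; m2[2, 2] <- 8; m2[3, 3] <- 8
  s2 <- summarize_counts(m2)
  expect_equal(s2$entropy_bits, log2(3), tolerance = 1e-12)
  expect_equal(s2$ratio, 1, tolerance = 1e-12)
  # identical rows: variation but no conditioning
  m3 <- rbind(c(4, 4, 0, 0, 0, 0), c(4, 4, 0, 0, 0, 0), c(4, 4, 0, 0, 0, 0))
  s3 <- summarize_counts(m3)
  expect_equal(s3$entropy_bits, 1, tolerance = 1e-12)
  expect_equal(s3$mi_bits, 0, tolerance = 1e-12)
  expect_error(summarize_counts(matrix(0, 3, 6)), "no productions")
})

test_that("cohorts are reproducible under a fixed seed", {
  spec <- hypothesis_spec("h1", "sampled")
  a <- simulate_cohort(spec, 50, seed = 33)
  b <- simulate_cohort(spec, 50, seed = 33)
  expect_identical(a, b)
  c <- simulate_cohort(spec, 50, seed = 34)
  expect_false(identical(a, c))
})

test_that("null-cohort mean ratio matches exhaustive enumeration on a reduced design", {
  # reduced design: 2 genders x 2 items each, 2 classes, p = (0.5, 0.5);
  # the exact expected plug-in MI/H is computable by summing over all
  # (count_F, count_M) outcomes
  p <- 0.5
  exact_num <- 0
  for (nf in 0:2) {
    for (nm in 0:2) {
      prob <- stats::dbinom(nf, 2, p) * stats::dbinom(nm, 2, p)
      counts <- rbind(c(nf, 2 - nf), c(nm, 2 - nm))
      s <- summarize_counts(counts)
      exact_num <- exact_num + prob * s$ratio
    }
  }
  expect_gt(exact_num, 0) # plug-in noise floor: strictly positive under the null
  spec <- hypothesis_spec(
    "h0", "fixed",
    class_probs = rbind(c(0.5, 0.5), c(0.5, 0.5)),
    items_per_gender = 2, n_items = 4
  )
  cohort <- simulate_cohort(spec, 20000, seed = 55)
  se <- stats::sd(cohort$ratio) / sqrt(20000)
  expect_equal(mean(cohort$ratio), exact_num, tolerance = 4 * se / exact_num)
})

test_that("mean gender conditioning orders h1 > h2 > h0", {
  n <- 10000
  r <- sapply(c("h1", "h2", "h0"), function(h) {
    mean(simulate_cohort(hypothesis_spec(h, "fixed"), n, seed = 77)$ratio)
  })
  expect_gt(r["h1"], r["h2"])
  expect_gt(r["h2"], r["h0"])
  expect_gt(r["h0"], 0) # plug-in noise floor
})

test_that("simulated frequencies converge to the specification", {
  spec <- hypothesis_spec("h1", "fixed")
  cohort <- simulate_cohort(spec, 2000, seed = 88, keep_counts = TRUE)
  for (g in genders()) {
    observed <- colSums(cohort[, paste0(g, "_", plural_classes())])
    p <- spec$class_probs[g, ]
    keep <- p > 0
    fit <- stats::chisq.test(observed[keep], p = p[keep] / sum(p[keep]))
    expect_gt(fit$p.value, 0.001)
    expect_equal(sum(observed[!keep]), 0)
  }
})

test_that("summaries never produce NaN and stay within entropy bounds", {
  spec <- hypothesis_spec("h0", "sampled")
  cohort <- simulate_cohort(spec, 500, seed = 99)
  expect_false(any(is.na(cohort)))
  expect_true(all(cohort$h_bits >= 0 & cohort$h_bits <= log2(6)))
  expect_true(all(cohort$ratio >= 0 & cohort$ratio <= 1))
  expect_lt(mean(cohort$h_bits), log2(6))
})
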