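test_that("entropy matches closed forms and the lexicon-wide value", {
  expect_equal(entropy(c(0.5, 0.5)), 1)
  expect_equal(entropy(c(1, 0, 0, 0, 0, 0)), 0)
  expect_equal(entropy(rep(1 / 6, 6)), log2(6))
  # gender-collapsed plural-class distribution, printed percentages
  expect_equal(entropy(c(45, 26, 18, 4, 4, 3)), 1.98, tolerance = 0.02 / 1.98)
  # counts are renormalized
  expect_equal(entropy(c(5, 5)), 1)
})

test_that("entropy rejects invalid distributions", {
  expect_error(entropy(c(0.5, -0.1)), "non-negative")
  expect_error(entropy(c(0, 0)), "positive")
  expect_error(entropy(numeric(0)), "nonempty")
})

test_that("conditional entropy reduces to row entropy under independence", {
  row <- c(4, 3, 2, 1, 0, 0)
  t <- gender_class_table(rbind(row, row, row))
  expect_equal(conditional_entropy(t), entropy(row), tolerance = 1e-12)
})

test_that("lexicon-wide conditional entropy is near the reported value", {
  tb <- builtin_tables()
  # printed inputs are rounded; the plug-in value from them lands near 1.28
  expect_equal(conditional_entropy(tb$overall), 1.31, tolerance = 0.04 / 1.31)
})

test_that("mutual information handles perfect prediction and independence", {
  diag3 <- gender_class_table(diag(3), weights = rep(1, 3))
  expect_equal(mutual_information(diag3), log2(3), tolerance = 1e-12)
  expect_equal(normalized_mi(diag3), 1, tolerance = 1e-12)
  row <- c(1, 2, 3, 4, 5, 6)
  indep <- gender_class_table(rbind(row, row, row))
  expect_equal(mutual_information(indep), 0, tolerance = 1e-12)
})

test_that("monosyllable table reproduces the printed information row", {
  tb <- builtin_tables()
  s <- info_summary(tb$monosyllable)
  expect_equal(s$entropy_bits, 1.71, tolerance = 0.03 / 1.71)
  expect_equal(s$mi_bits, 0.30, tolerance = 0.02 / 0.30)
  expect_equal(s$ratio, 0.17, tolerance = 0.01 / 0.17)
})

test_that("normalized MI follows the zero-entropy convention", {
  onecell <- gender_class_table(
    rbind(c(8, 0, 0, 0, 0, 0), c(8, 0, 0, 0, 0, 0), c(8, 0, 0, 0, 0, 0))
  )
  expect_equal(normalized_mi(onecell), 0)
  expect_equal(info_summary(onecell)$ratio, 0)
})

test_that("information measures match the double-sum oracle on random tables", {
  set.seed(101)
  for (rep in 1:1000) {
    counts <- random_count_table()
    t <- gender_class_table(counts)
    o <- oracle_info(counts)
    expect_equal(entropy(class_marginal(t)), o$h, tolerance = 1e-9)
    expect_equal(conditional_entropy(t), o$hcg, tolerance = 1e-9)
    expect_equal(mutual_information(t), o$mi, tolerance = 1e-9)
  }
})

test_that("MI obeys bounds, decomposition, and transpose symmetry", {
  set.seed(202)
  for (rep in 1:200) {
    counts <- random_count_table()
    t <- gender_class_table(counts)
    h_c <- entropy(class_marginal(t))
    h_g <- entropy(rowSums(counts))
    mi <- mutual_information(t)
    expect_gte(mi, -1e-9)
    expect_lte(mi, min(h_c, h_g) + 1e-9)
    expect_equal(h_c - conditional_entropy(t) - mi, 0, tolerance = 1e-9)
    # counts transposed: classes conditioning genders, same plug-in MI
    mi_t <- mutual_information(gender_class_table(t(counts)))
    expect_equal(mi, mi_t, tolerance = 1e-9)
    r <- normalized_mi(t)
    expect_gte(r, 0)
    expect_lte(r, 1)
  }
})

test_that("KL divergence matches closed forms and the direct-sum oracle", {
  expect_equal(kl_divergence(c(0.5, 0.5), c(0.5, 0.5), smoothing = 0), 0)
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5), smoothing = 0), 1)
  # direct evaluation with smoothing
  p <- c(0.6, 0.4, 0)
  q <- c(0.2, 0.3, 0.5)
  eps <- 1e-6
  ps <- (p + eps) / (1 + 3 * eps)
  qs <- (q + eps) / (1 + 3 * eps)
  expect_equal(kl_divergence(p, q, smoothing = eps),
               sum(ps * log2(ps / qs)), tolerance = 1e-9)
  # natural-log base
  expect_equal(kl_divergence(c(1, 0), c(0.5, 0.5), smoothing = 0,
                             base = exp(1)),
               log(2), tolerance = 1e-12)
})

test_that("KL divergence flags undefined support and rejects bad smoothing", {
  expect_error(kl_divergence(c(0.5, 0.5), c(1, 0), smoothing = 0),
               "undefined divergence")
  expect_error(kl_divergence(c(0.5, 0.5), c(0.5, 0.5), smoothing = -1),
               "smoothing")
  expect_error(kl_divergence(c(0.5, 0.5), c(0.3, 0.3, 0.4)),
               "same category set")
})

test_that("KL divergence is non-negative and zero only at equality", {
  set.seed(303)
  for (rep in 1:200) {
    p <- as_prob_vector(stats::rgamma(6, 1) + 1e-12)
    q <- as_prob_vector(stats::rgamma(6, 1) + 1e-12)
    expect_gte(kl_divergence(p, q, smoothing = 0), 0)
  }
  p <- as_prob_vector(c(2, 3, 5))
  expect_equal(kl_divergence(p, p, smoothing = 0), 0)
})

test_that("letter-cue baseline matches a brute-force contingency tally", {
  lex <- load_lexicon(system.file("extdata", "toy_lexicon_synthetic.csv",
                                  package = "pluralinfo"))
  s <- baseline_letter_conditioning(lex)
  # independent tally
  has_a <- grepl("a", tolower(lex$spelling), fixed = TRUE)
  has_i <- grepl("i", tolower(lex$spelling), fixed = TRUE)
  lv <- paste(has_a, has_i)
  counts <- unclass(table(lv, factor(lex$plural_class,
                                     levels = plural_classes())))
  o <- oracle_info(counts)
  expect_equal(s$entropy_bits, o$h, tolerance = 1e-9)
  expect_equal(s$mi_bits, o$mi, tolerance = 1e-9)
})

test_that("letter-cue baseline hits its degenerate cases", {
  # constant letter variable: no information
  lex0 <- data.frame(spelling = c("bo", "bu", "bo"), gender = "M",
                     plural_class = c("en", "e", "s"))
  expect_equal(baseline_letter_conditioning(lex0)$mi_bits, 0,
               tolerance = 1e-12)
  # class a deterministic function of the letter variable
  lex1 <- data.frame(spelling = c("ba", "ba", "bi", "bi"), gender = "M",
                     plural_class = c("en", "en", "e", "e"))
  s1 <- baseline_letter_conditioning(lex1)
  expect_equal(s1$mi_bits, s1$entropy_bits, tolerance = 1e-12)
  expect_error(baseline_letter_conditioning(NULL), "empty lexicon")
})
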