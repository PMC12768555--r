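# Independent oracle implementations used to cross-check the package.
# These deliberately take different algebraic routes than the package code
# (direct double sums over cells rather than entropy differences; textbook
# dynamic programming rather than utils::adist).

# direct double-sum evaluation of H(C), H(C|G), MI(C;G) from a count matrix
oracle_info <- function(counts, weights = NULL) {
  counts <- as.matrix(counts)
  if (is.null(weights)) {
    weights <- rowSums(counts)
  }
  w <- weights / sum(weights)
  cond <- counts
  for (g in seq_len(nrow(counts))) {
    if (sum(counts[g, ]) > 0) {
      cond[g, ] <- counts[g, ] / sum(counts[g, ])
    }
  }
  marg <- numeric(ncol(counts))
  for (c in seq_len(ncol(counts))) {
    for (g in seq_len(nrow(counts))) {
      marg[c] <- marg[c] + w[g] * cond[g, c]
    }
  }
  h <- 0
  for (c in seq_along(marg)) {
    if (marg[c] > 0) h <- h - marg[c] * log2(marg[c])
  }
  hcg <- 0
  for (g in seq_len(nrow(counts))) {
    if (w[g] > 0) {
      for (c in seq_len(ncol(counts))) {
        if (cond[g, c] > 0) {
          hcg <- hcg - w[g] * cond[g, c] * log2(cond[g, c])
        }
      }
    }
  }
  # MI through the joint, not as an entropy difference
  mi <- 0
  for (g in seq_len(nrow(counts))) {
    if (w[g] > 0) {
      for (c in seq_len(ncol(counts))) {
        p_joint <- w[g] * cond[g, c]
        if (p_joint > 0 && marg[c] > 0) {
          mi <- mi + p_joint * log2(cond[g, c] / marg[c])
        }
      }
    }
  }
  list(h = as.numeric(h), hcg = as.numeric(hcg), mi = as.numeric(mi))
}

# textbook DP edit distance
oracle_levenshtein <- function(a, b) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  d <- matrix(0L, length(ca) + 1, length(cb) + 1)
  d[, 1] <- 0:length(ca)
  d[1, ] <- 0:length(cb)
  for (i in seq_along(ca)) {
    for (j in seq_along(cb)) {
      cost <- if (ca[i] == cb[j]) 0L else 1L
      d[i + 1, j + 1] <- min(d[i, j + 1] + 1L, d[i + 1, j] + 1L,
                             d[i, j] + cost)
    }
  }
  d[length(ca) + 1, length(cb) + 1]
}

# random small count table with occasional zero cells
random_count_table <- function(n_gender = 3, n_class = 6) {
  m <- matrix(stats::rpois(n_gender * n_class, 3), n_gender, n_class)
  zero <- stats::runif(length(m)) < 0.2
  m[zero] <- 0L
  for (g in seq_len(n_gender)) {
    if (sum(m[g, ]) == 0) m[g, sample.int(n_class, 1)] <- 1L
  }
  m
}

# cohort drawn directly from the Beta-regression generative model
model_generated_cohort <- function(n, b0, b1, phi,
                                   h_range = c(0.5, 2.5)) {
  h <- stats::runif(n, h_range[1], h_range[2])
  mu <- stats::plogis(b0 + b1 * h)
  data.frame(
    participant_id = seq_len(n),
    h_bits = h,
    mi_bits = NA_real_,
    ratio = stats::rbeta(n, mu * phi, (1 - mu) * phi)
  )
}
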