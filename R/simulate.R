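# Hypothesis simulators: per-participant multinomial plural-class production
# under the competing gender-conditioning regimes.
#
# Three regimes are supported, mirroring the hypotheses the package tests:
#   h0  -- gender-ignoring: every item's class is drawn from the
#          gender-collapsed lexicon distribution, independently of gender.
#   h1  -- lexicon-level conditioning: classes are drawn from the per-gender
#          class distributions of the full noun lexicon.
#   h2  -- monosyllable-mediated conditioning: classes are drawn from the
#          per-gender distributions computed over monosyllabic nouns only,
#          the stratum the novel-noun stimuli belong to.
# and two designs:
#   fixed   -- 8 items presented per gender (24 items total), the
#              counterbalanced elicitation design;
#   sampled -- participants assign gender themselves: per-participant gender
#              counts are drawn Multinomial(24, P(G)) first, then classes
#              per gender.
#
# Draw order within a cohort is documented and fixed (for the sampled
# design: all participants' gender counts first; then class draws per
# participant in F, M, N row order) so cohorts are bit-reproducible.

#' Specify a generative hypothesis regime
#'
#' Bundles the per-gender class probabilities, the experimental design, and
#' (for the sampled-gender design) the gender marginal that one simulated
#' participant is generated from.
#'
#' Default gender marginals under the sampled design: the lexicon-wide
#' marginal (42/38/20) for `h0` and `h1`; for `h2` the monosyllable marginal
#' (13/64/23), since that regime models production over monosyllabic nouns
#' and experimental gender choices track the monosyllable distribution.
#' Either default can be overridden via `gender_weights`.
#'
#' @param name `"h0"`, `"h1"`, or `"h2"`.
#' @param design `"fixed"` (items-per-gender presented) or `"sampled"`
#'   (gender self-assigned per item).
#' @param tables A `lexicon_tables` list as from [builtin_tables()].
#' @param gender_weights Optional probability vector over genders for the
#'   sampled design (counts or percentages accepted).
#' @param class_probs Optional explicit per-gender class-probability matrix
#'   (rows = genders), overriding the regime's lexicon table; used for
#'   reduced designs in calibration studies.
#' @param items_per_gender Items presented per gender under the fixed design
#'   (default 8).
#' @param n_items Total items per participant (default 24).
#' @return An object of class `hypothesis_spec`.
#' @export
hypothesis_spec <- function(name = c("h0", "h1", "h2"),
                            design = c("fixed", "sampled"),
                            tables = builtin_tables(),
                            gender_weights = NULL,
                            class_probs = NULL,
                            items_per_gender = 8,
                            n_items = items_per_gender * 3) {
  name <- match.arg(name)
  design <- match.arg(design)
  if (is.null(class_probs)) {
    class_probs <- switch(name,
      h0 = {
        p <- as_prob_vector(tables$all)
        matrix(rep(p, each = 3), nrow = 3,
               dimnames = list(genders(), names(p)))
      },
      h1 = tables$overall$probs,
      h2 = tables$monosyllable$probs
    )
  } else {
    class_probs <- as.matrix(class_probs)
    class_probs <- t(apply(class_probs, 1, as_prob_vector))
  }
  n_gender <- nrow(class_probs)
  if (design == "fixed") {
    if (n_items != items_per_gender * n_gender) {
      stop("fixed design requires n_items = items_per_gender * genders")
    }
  }
  if (is.null(gender_weights)) {
    gender_weights <- switch(name,
      h0 = ,
      h1 = tables$overall$weights,
      h2 = tables$monosyllable$weights
    )
    if (!is.null(gender_weights)) {
      gender_weights <- gender_weights[seq_len(n_gender)]
    }
  }
  if (design == "sampled") {
    gender_weights <- as_prob_vector(gender_weights)
    if (length(gender_weights) != n_gender) {
      stop("gender_weights must have one entry per gender row")
    }
  }
  structure(
    list(name = name, design = design, class_probs = class_probs,
         gender_weights = gender_weights,
         items_per_gender = items_per_gender, n_items = n_items),
    class = "hypothesis_spec"
  )
}

#' Simulate one participant's production counts
#'
#' Under the fixed design, each gender's `items_per_gender` classes are
#' drawn i.i.d. from that gender's class distribution (all rows share the
#' gender-collapsed distribution under `h0`). Under the sampled design,
#' per-gender item counts are drawn `Multinomial(n_items, P(G))` first.
#' Consumes the R session RNG; seed via [set.seed()] or use
#' [simulate_cohort()] for reproducible cohorts.
#'
#' @param spec A [hypothesis_spec()].
#' @return Integer matrix of production counts (genders x classes).
#' @export
simulate_participant <- function(spec) {
  stopifnot(inherits(spec, "hypothesis_spec"))
  n_gender <- nrow(spec$class_probs)
  if (spec$design == "fixed") {
    sizes <- rep(spec$items_per_gender, n_gender)
  } else {
    sizes <- as.vector(stats::rmultinom(1, spec$n_items, spec$gender_weights))
  }
  counts <- matrix(0L, n_gender, ncol(spec$class_probs),
                   dimnames = dimnames(spec$class_probs))
  for (g in seq_len(n_gender)) {
    if (sizes[g] > 0) {
      counts[g, ] <- as.vector(
        stats::rmultinom(1, sizes[g], spec$class_probs[g, ])
      )
    }
  }
  counts
}

# columnwise entropy of a matrix whose columns are distributions
.entropy_cols <- function(p) {
  -colSums(.plogp(p))
}

#' Information summary of one participant's counts
#'
#' Plug-in entropy, mutual information, and normalized MI computed from a
#' production count table, weighting genders by the participant's own
#' empirical gender counts (which is the presentation design 8/8/8 under the
#' fixed design, and the participant's sampled gender counts otherwise).
#' Genders with zero items contribute nothing to the conditional entropy.
#'
#' @param counts Genders-by-classes count matrix with positive total.
#' @return An [info_summary()].
#' @export
summarize_counts <- function(counts) {
  counts <- as.matrix(counts)
  if (sum(counts) <= 0) {
    stop("participant has no productions")
  }
  info_summary(gender_class_table(counts))
}

#' Simulate a cohort of participants under one regime
#'
#' Generates `n` independent participants from `spec` and returns their
#' per-participant information summaries, the calibration data for the
#' Beta-regression hypothesis models. Reproducible: the same `seed` yields
#' a bit-identical cohort.
#'
#' @param spec A [hypothesis_spec()].
#' @param n Number of participants (>= 1).
#' @param seed Optional integer seed.
#' @param keep_counts If `TRUE`, attach the per-cell counts as extra columns.
#' @return Data frame with columns `participant_id`, `h_bits`, `mi_bits`,
#'   `ratio` (and count columns when requested).
#' @export
simulate_cohort <- function(spec, n, seed = NULL, keep_counts = FALSE) {
  stopifnot(inherits(spec, "hypothesis_spec"), n >= 1)
  if (!is.null(seed)) {
    set.seed(seed)
  }
  probs <- spec$class_probs
  n_gender <- nrow(probs)
  n_class <- ncol(probs)

  if (spec$design == "fixed" && !keep_counts) {
    # vectorized path: one size-n multinomial block per gender row
    ipg <- spec$items_per_gender
    marg <- matrix(0, n_class, n)
    hcg <- numeric(n)
    w <- 1 / n_gender
    for (g in seq_len(n_gender)) {
      block <- stats::rmultinom(n, ipg, probs[g, ]) / ipg # classes x n
      marg <- marg + w * block
      hcg <- hcg + w * .entropy_cols(block)
    }
    h <- .entropy_cols(marg)
    mi <- pmax(h - hcg, 0)
    return(data.frame(
      participant_id = seq_len(n),
      h_bits = h, mi_bits = mi,
      ratio = ifelse(h > 0, pmin(mi / h, 1), 0)
    ))
  }

  rows <- vector("list", n)
  sizes_all <- if (spec$design == "sampled") {
    stats::rmultinom(n, spec$n_items, spec$gender_weights)
  } else {
    matrix(spec$items_per_gender, n_gender, n)
  }
  for (i in seq_len(n)) {
    counts <- matrix(0L, n_gender, n_class, dimnames = dimnames(probs))
    for (g in seq_len(n_gender)) {
      if (sizes_all[g, i] > 0) {
        counts[g, ] <- as.vector(
          stats::rmultinom(1, sizes_all[g, i], probs[g, ])
        )
      }
    }
    s <- summarize_counts(counts)
    row <- data.frame(participant_id = i, h_bits = s$entropy_bits,
                      mi_bits = s$mi_bits, ratio = s$ratio)
    if (keep_counts) {
      flat <- as.vector(t(counts))
      names(flat) <- paste(rep(rownames(counts), each = n_class),
                           rep(colnames(counts), n_gender), sep = "_")
      row <- cbind(row, as.data.frame(as.list(flat)))
    }
    rows[[i]] <- row
  }
  do.call(rbind, rows)
}

#' Write or read a cohort summary CSV
#'
#' @param cohort Data frame from [simulate_cohort()] or
#'   [summarize_productions()].
#' @param path File path.
#' @return `read_cohort` returns the cohort data frame.
#' @export
write_cohort <- function(cohort, path) {
  utils::write.csv(cohort, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  df <- utils::read.csv(path)
  need <- c("participant_id", "h_bits", "mi_bits", "ratio")
  if (!all(need %in% names(df))) {
    stop("cohort CSV must have columns: ", paste(need, collapse = ", "))
  }
  df
}
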