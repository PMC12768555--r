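# Synthetic novel-noun ("wug") elicitation cohorts.
#
# Real participant data for this paradigm are not redistributable, so the
# package ships a generator that emulates the experimental designs at the
# strategy level: each simulated participant draws a latent production
# strategy (gender-ignoring, lexicon-level conditioning, monosyllable-level
# conditioning, or a deterministic "super-lexical" rule) and then produces
# one plural form per stimulus item by sampling a plural class from the
# strategy's gender-conditional distribution and rendering it as a suffixed
# string. The generator is deliberately strategy-level: it has no
# item-specific effects (no analogical attraction to similar real nouns),
# so it emulates the designs, not every feature of human data.

#' The 24 novel noun stimuli
#'
#' Monosyllabic nonce nouns used in the elicitation designs, in canonical
#' order. The first twelve are "rhymes" (phonologically similar to existing
#' German nouns), the last twelve "non-rhymes".
#'
#' @return Character vector of length 24.
#' @export
wug_stimuli <- function() {
  c("Bral", "Kach", "Klot", "Mur", "Nuhl", "Pind",
    "Pisch", "Pund", "Raun", "Spand", "Spert", "Vag",
    "Bnaupf", "Bneik", "Bnöhk", "Fnahf", "Fneik", "Fnöhk",
    "Pläk", "Plaupf", "Pleik", "Pnähf", "Pröng", "Snauk")
}

#' Specify a mixture of production strategies
#'
#' Weights over the latent strategies a simulated participant can follow:
#' `ignore` (classes drawn from the gender-collapsed lexicon distribution,
#' null-like), `lexicon` (per-gender lexicon distributions), `monosyllable`
#' (per-gender distributions over monosyllabic nouns), and `super` (a
#' deterministic rule: feminine takes *-(e)n*, everything else *-e*,
#' modeling the rare participants with super-lexical gender conditioning).
#'
#' @param ignore,lexicon,monosyllable,super Non-negative weights
#'   (renormalized to sum to 1; at least one must be positive, and every
#'   weight defaults to zero so a mixture is always stated explicitly).
#' @return Named probability vector of class `strategy_mixture`.
#' @export
strategy_mixture <- function(ignore = 0, lexicon = 0, monosyllable = 0,
                             super = 0) {
  w <- c(ignore = ignore, lexicon = lexicon,
         monosyllable = monosyllable, super = super)
  structure(as_prob_vector(w), class = "strategy_mixture")
}

#' Render a plural form from a class label
#'
#' Deterministic suffixation: `en` and `er` and `e` and `s` append the
#' corresponding suffix, `zero` leaves the singular unchanged, and `other`
#' appends the out-of-class token `-se` (an arbitrary documented rendering
#' whose only job is to round-trip through [classify_plural()] as `other`).
#'
#' @param singular Character vector of singular forms.
#' @param class Character vector of plural-class labels (recycled).
#' @return Character vector of plural forms.
#' @export
render_plural_form <- function(singular, class) {
  if (any(!nzchar(singular))) {
    stop("empty singular form")
  }
  n <- max(length(singular), length(class))
  singular <- rep_len(singular, n)
  class <- rep_len(as.character(class), n)
  bad <- setdiff(unique(class), plural_classes())
  if (length(bad)) {
    stop("unknown plural class: ", bad[1])
  }
  suffix <- c(en = "en", e = "e", zero = "", s = "s", er = "er",
              other = "se")[class]
  paste0(singular, suffix)
}

.deumlaut <- function(x) {
  chartr("äöüÄÖÜ", "aouAOU", x)
}

#' Classify a typed plural form by suffix
#'
#' Maps a (singular, plural) pair to one of the six plural classes. Only
#' suffixes define classes here, so umlaut is normalized away in both forms
#' before comparison (an umlaut-only plural is classed `zero`), and
#' comparison is case-insensitive. The plural must extend the singular stem;
#' remainders are matched exactly: `en` or `n` map to the *-(e)n* class
#' (`-n` being the variant after stems in *-e*), `er`, `e`, and `s` to their
#' classes, an empty remainder to `zero`, and anything else -- including a
#' plural that does not contain the stem -- to `other`.
#'
#' @param singular,plural Nonempty character vectors (recycled).
#' @return Character vector of class labels.
#' @export
classify_plural <- function(singular, plural) {
  if (any(!nzchar(singular)) || any(!nzchar(plural))) {
    stop("empty input form")
  }
  n <- max(length(singular), length(plural))
  s <- tolower(.deumlaut(rep_len(singular, n)))
  p <- tolower(.deumlaut(rep_len(plural, n)))
  out <- character(n)
  is_ext <- startsWith(p, s)
  rest <- ifelse(is_ext, substring(p, nchar(s) + 1), NA_character_)
  out[!is_ext] <- "other"
  out[is_ext] <- vapply(rest[is_ext], function(r) {
    switch(r,
           "en" = "en", "n" = "en", "er" = "er", "e" = "e", "s" = "s",
           if (r == "") "zero" else "other")
  }, character(1), USE.NAMES = FALSE)
  out
}

# per-gender class probability rows for each strategy
.strategy_rows <- function(tables) {
  all_rows <- matrix(rep(tables$all, each = 3), nrow = 3,
                     dimnames = list(genders(), names(tables$all)))
  super <- matrix(0, 3, 6, dimnames = list(genders(), plural_classes()))
  super["F", "en"] <- 1
  super[c("M", "N"), "e"] <- 1
  list(ignore = all_rows, lexicon = tables$overall$probs,
       monosyllable = tables$monosyllable$probs, super = super)
}

#' Generate a synthetic elicitation cohort
#'
#' Emulates one of the three experimental designs. Under `exp1` and `exp2`
#' each participant is assigned to one of three lists; gender is
#' counterbalanced so that every participant sees 8 feminine, 8 masculine,
#' and 8 neuter items and every item carries a different gender in each
#' list (lists are assigned cyclically, so cohorts divisible by 3 are
#' exactly balanced). Under `exp3` the participant chooses the gender:
#' each item's gender is drawn from `gender_marginal` (default the
#' monosyllable gender marginal, which experimental gender choices
#' resemble; the lexicon-wide marginal can be supplied instead). Plural
#' classes are then drawn from the participant's latent strategy (see
#' [strategy_mixture()]) and rendered as strings.
#'
#' @param n Number of participants (>= 1).
#' @param mixture A [strategy_mixture()].
#' @param experiment `"exp1"`, `"exp2"`, or `"exp3"`.
#' @param seed Optional integer seed.
#' @param tables Lexicon tables, see [builtin_tables()].
#' @param gender_marginal Probability vector over genders for `exp3`.
#' @return Data frame of per-trial production records: `participant_id`,
#'   `experiment`, `list_id`, `item`, `gender`, `raw_plural`,
#'   `plural_class`, plus the latent `strategy` (ground truth for recovery
#'   studies; dropped on CSV round trips through [read_productions()] if
#'   absent).
#' @export
generate_cohort <- function(n, mixture = strategy_mixture(ignore = 1),
                            experiment = c("exp1", "exp2", "exp3"),
                            seed = NULL, tables = builtin_tables(),
                            gender_marginal = NULL) {
  experiment <- match.arg(experiment)
  stopifnot(n >= 1, inherits(mixture, "strategy_mixture"))
  if (!is.null(seed)) {
    set.seed(seed)
  }
  if (is.null(gender_marginal)) {
    gender_marginal <- tables$monosyllable$weights
  }
  gender_marginal <- as_prob_vector(gender_marginal)
  items <- wug_stimuli()
  n_items <- length(items)
  rows <- .strategy_rows(tables)
  strategies <- sample(names(mixture), n, replace = TRUE, prob = mixture)
  g_levels <- genders()

  out <- vector("list", n)
  for (p in seq_len(n)) {
    list_id <- ((p - 1L) %% 3L) + 1L
    if (experiment == "exp3") {
      gender <- sample(g_levels, n_items, replace = TRUE,
                       prob = gender_marginal)
    } else {
      # Latin-square counterbalancing: item i gets gender (i + list) mod 3
      gender <- g_levels[((seq_len(n_items) + list_id) %% 3L) + 1L]
    }
    probs <- rows[[strategies[p]]]
    class <- vapply(gender, function(g) {
      sample(plural_classes(), 1, prob = probs[g, ])
    }, character(1), USE.NAMES = FALSE)
    out[[p]] <- data.frame(
      participant_id = p,
      experiment = experiment,
      list_id = list_id,
      item = items,
      gender = gender,
      raw_plural = render_plural_form(items, class),
      plural_class = class,
      strategy = strategies[p]
    )
  }
  do.call(rbind, out)
}

#' Summarize production records per participant
#'
#' Tallies each participant's gender-by-class counts and computes the
#' plug-in information summary (gender weighted by the participant's own
#' empirical gender counts).
#'
#' @param records Data frame of production records (see
#'   [generate_cohort()] / [read_productions()]).
#' @return Data frame with `participant_id`, `h_bits`, `mi_bits`, `ratio`.
#' @export
summarize_productions <- function(records) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no production records")
  }
  ids <- unique(records$participant_id)
  out <- lapply(ids, function(id) {
    sub <- records[records$participant_id == id, ]
    counts <- unclass(table(factor(sub$gender, levels = genders()),
                            factor(sub$plural_class,
                                   levels = plural_classes())))
    s <- summarize_counts(counts)
    data.frame(participant_id = id, h_bits = s$entropy_bits,
               mi_bits = s$mi_bits, ratio = s$ratio)
  })
  do.call(rbind, out)
}

#' Recover strategy fractions from a classified cohort
#'
#' Summarizes and classifies every participant under the supplied fitted
#' hypothesis models and reports the fraction assigned to each best-fit
#' label, with bootstrap percentile confidence intervals over participants.
#' A validation utility for the pipeline: on cohorts generated with a known
#' [strategy_mixture()] the recovered fractions should track the generating
#' weights.
#'
#' @param records Production records.
#' @param posteriors Named list of `beta_reg_fit` models (see
#'   [classify_cohort()]).
#' @param n_boot Bootstrap replicates (default 200).
#' @param conf Confidence level (default 0.95).
#' @param ... Passed to [classify_cohort()].
#' @return Data frame with `hypothesis`, `fraction`, `lower`, `upper`.
#' @export
recover_mixture <- function(records, posteriors, n_boot = 200,
                            conf = 0.95, ...) {
  if (is.null(records) || nrow(records) == 0) {
    stop("no production records")
  }
  summaries <- summarize_productions(records)
  if (nrow(summaries) < 50) {
    warning("fewer than 50 participants; recovered fractions will be noisy")
  }
  cls <- classify_cohort(summaries, posteriors, ...)
  labels <- names(posteriors)
  frac <- vapply(labels, function(l) mean(cls$best_fit == l), numeric(1))
  boots <- matrix(0, n_boot, length(labels),
                  dimnames = list(NULL, labels))
  for (b in seq_len(n_boot)) {
    idx <- sample.int(nrow(cls), replace = TRUE)
    boots[b, ] <- vapply(labels, function(l) {
      mean(cls$best_fit[idx] == l)
    }, numeric(1))
  }
  a <- (1 - conf) / 2
  data.frame(
    hypothesis = labels,
    fraction = frac,
    lower = apply(boots, 2, stats::quantile, a),
    upper = apply(boots, 2, stats::quantile, 1 - a),
    row.names = NULL
  )
}
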