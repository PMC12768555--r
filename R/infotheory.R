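# Plug-in information measures over categorical distributions.
#
# All measures use log base 2 (bits) unless stated otherwise, with the
# 0 * log 0 = 0 convention. Estimation is deliberately plug-in (maximum
# likelihood from relative frequencies): the hypothesis-testing design of
# this package absorbs small-sample plug-in bias by simulating the null
# distribution rather than assuming MI = 0 under independence, so
# bias-corrected estimators are not used.

#' Canonical plural-class and gender labels
#'
#' German plural classes are defined by suffix: *-(e)n*, *-e*, the null
#' marker, *-s*, *-er*, plus a catchall "other" class. Grammatical gender is
#' feminine, masculine, or neuter. The fixed orderings returned here are used
#' in every table and output of the package.
#'
#' @return Character vector of labels.
#' @export
plural_classes <- function() c("en", "e", "zero", "s", "er", "other")

#' @rdname plural_classes
#' @export
genders <- function() c("F", "M", "N")

#' Validate and normalize a probability vector
#'
#' Accepts raw counts or probabilities; entries must be non-negative with a
#' positive total. Counts (or percentages) are renormalized to sum to one.
#'
#' @param x Numeric vector of non-negative weights, counts, or probabilities.
#' @return Numeric vector summing to 1, names preserved.
#' @export
as_prob_vector <- function(x) {
  if (!is.numeric(x) || length(x) == 0) {
    stop("probability vector must be a nonempty numeric vector")
  }
  if (anyNA(x) || any(x < 0)) {
    stop("invalid distribution: entries must be non-negative and non-missing")
  }
  total <- sum(x)
  if (total <= 0) {
    stop("invalid distribution: total mass must be positive")
  }
  x / total
}

# 0*log2(0) = 0 convention, columnwise over a matrix of probabilities
.plogp <- function(p) {
  out <- p * log2(p)
  out[p == 0] <- 0
  out
}

#' Shannon entropy of a categorical distribution
#'
#' \eqn{H(C) = -\sum_c P(c) \log_2 P(c)} in bits, with \eqn{0 \log 0 = 0}.
#' Counts are renormalized before computation.
#'
#' @param p Probability (or count) vector; see [as_prob_vector()].
#' @return Entropy in bits, between 0 and `log2(length(p))`.
#' @examples
#' entropy(c(0.5, 0.5)) # 1 bit
#' entropy(c(45, 26, 18, 4, 4, 3)) # about 1.99 bits
#' @export
entropy <- function(p) {
  p <- as_prob_vector(p)
  -sum(.plogp(p))
}

#' Gender-by-class probability table
#'
#' Container for the joint behaviour of a conditioning variable (rows;
#' canonically grammatical gender) and a target variable (columns; canonically
#' plural class). Rows hold per-condition class distributions; `weights` holds
#' the marginal distribution over conditions. Cells may be given as counts,
#' percentages, or probabilities; each row is renormalized to a conditional
#' distribution. When counts are given and `weights` is omitted, row totals
#' are used as the condition marginal.
#'
#' @param x Numeric matrix (or object coercible to one) of non-negative cells,
#'   one row per condition level, one column per target class.
#' @param weights Optional non-negative vector over rows (counts, percentages,
#'   or probabilities); defaults to row totals.
#' @return An object of class `gender_class_table` with elements `cells` (the
#'   input cells as given), `probs` (row-normalized conditionals), and
#'   `weights` (normalized condition marginal).
#' @export
gender_class_table <- function(x, weights = NULL) {
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x) || any(x < 0)) {
    stop("table cells must be non-negative and non-missing")
  }
  if (sum(x) <= 0) {
    stop("table must have at least one positive cell")
  }
  if (is.null(rownames(x))) {
    rownames(x) <- if (nrow(x) == 3) genders() else
      paste0("g", seq_len(nrow(x)))
  }
  if (is.null(colnames(x))) {
    colnames(x) <- if (ncol(x) == 6) plural_classes() else
      paste0("c", seq_len(ncol(x)))
  }
  rs <- rowSums(x)
  probs <- x
  nonzero <- rs > 0
  probs[nonzero, ] <- x[nonzero, , drop = FALSE] / rs[nonzero]
  if (is.null(weights)) {
    weights <- rs
  }
  if (length(weights) != nrow(x)) {
    stop("weights must have one entry per table row")
  }
  w <- as_prob_vector(weights)
  if (any(w > 0 & rs == 0)) {
    stop("a condition with positive weight has an all-zero row")
  }
  structure(
    list(cells = x, probs = probs, weights = w),
    class = "gender_class_table"
  )
}

#' @export
print.gender_class_table <- function(x, digits = 3, ...) {
  cat("gender_class_table:", nrow(x$cells), "conditions x",
      ncol(x$cells), "classes\n")
  print(round(x$probs, digits))
  cat("weights:", paste(round(x$weights, digits), collapse = " "), "\n")
  invisible(x)
}

#' Marginal class distribution of a table
#'
#' \eqn{P(c) = \sum_g P(g) P(c \mid g)}.
#'
#' @param t A [gender_class_table()].
#' @return Probability vector over classes.
#' @export
class_marginal <- function(t) {
  stopifnot(inherits(t, "gender_class_table"))
  as.vector(t$weights %*% t$probs)
}

#' Conditional entropy H(C | G)
#'
#' \eqn{H(C \mid G) = \sum_g P(g) H(C \mid G = g)} in bits. Conditions with
#' zero marginal probability contribute nothing.
#'
#' @param t A [gender_class_table()].
#' @return Conditional entropy in bits.
#' @export
conditional_entropy <- function(t) {
  stopifnot(inherits(t, "gender_class_table"))
  row_h <- -rowSums(.plogp(t$probs))
  sum(t$weights[t$weights > 0] * row_h[t$weights > 0])
}

#' Mutual information MI(C; G)
#'
#' Uncertainty reduction about the target class from knowing the condition:
#' \eqn{MI(C; G) = H(C) - H(C \mid G)}, with \eqn{H(C)} computed from the
#' table's marginal class distribution. Plug-in MI is non-negative; tiny
#' negative values from floating-point cancellation are clipped to zero.
#'
#' @param t A [gender_class_table()].
#' @return Mutual information in bits.
#' @export
mutual_information <- function(t) {
  mi <- entropy(class_marginal(t)) - conditional_entropy(t)
  max(mi, 0)
}

#' Normalized mutual information MI/H
#'
#' The fraction of class variation conditioned on the row variable,
#' \eqn{MI(C; G) / H(C) \in [0, 1]}. When \eqn{H(C) = 0} (no variation at
#' all) the ratio is defined as 0: if there is no variation in class
#' production, none of it can be conditioned on gender.
#'
#' @param t A [gender_class_table()].
#' @return Ratio in `[0, 1]`.
#' @export
normalized_mi <- function(t) {
  h <- entropy(class_marginal(t))
  if (h == 0) {
    return(0)
  }
  min(mutual_information(t) / h, 1)
}

#' Full information summary of a table
#'
#' Computes plural-class entropy \eqn{H(C)}, conditional entropy
#' \eqn{H(C|G)}, mutual information \eqn{MI(C;G)}, and the normalized ratio
#' \eqn{MI/H} for one table, the per-row summary used throughout the package
#' (both for lexicon tables and for single participants).
#'
#' @param t A [gender_class_table()].
#' @return An object of class `info_summary`: list with `entropy_bits`,
#'   `conditional_entropy_bits`, `mi_bits`, `ratio`.
#' @export
info_summary <- function(t) {
  h <- entropy(class_marginal(t))
  hc <- conditional_entropy(t)
  mi <- max(h - hc, 0)
  structure(
    list(
      entropy_bits = h,
      conditional_entropy_bits = hc,
      mi_bits = mi,
      ratio = if (h > 0) min(mi / h, 1) else 0
    ),
    class = "info_summary"
  )
}

#' @export
print.info_summary <- function(x, digits = 3, ...) {
  cat(sprintf(
    "H(C) = %.*f bits, H(C|G) = %.*f bits, MI(C;G) = %.*f bits, MI/H = %.*f\n",
    digits, x$entropy_bits, digits, x$conditional_entropy_bits,
    digits, x$mi_bits, digits, x$ratio
  ))
  invisible(x)
}

#' Kullback-Leibler divergence between categorical distributions
#'
#' \eqn{D_{KL}(P \Vert Q) = \sum_x P(x) \log P(x)/Q(x)}. Both vectors are
#' additively smoothed by `smoothing` and renormalized before the sum, which
#' keeps the divergence finite when the reference `q` has zero cells where
#' `p` has mass (common when comparing model predictions to observed
#' production counts). At `smoothing = 0` a zero `q` cell with positive `p`
#' mass is an error.
#'
#' @param p,q Probability (or count) vectors over the same category set.
#' @param smoothing Non-negative additive smoothing constant (default 1e-6).
#' @param base Logarithm base; 2 (bits, the default) or any base > 1.
#' @return Non-negative divergence; 0 iff `p == q`.
#' @export
kl_divergence <- function(p, q, smoothing = 1e-6, base = 2) {
  p <- as_prob_vector(p)
  q <- as_prob_vector(q)
  if (length(p) != length(q)) {
    stop("p and q must be over the same category set")
  }
  if (length(smoothing) != 1 || smoothing < 0) {
    stop("smoothing must be a single non-negative number")
  }
  if (smoothing > 0) {
    p <- (p + smoothing) / (1 + length(p) * smoothing)
    q <- (q + smoothing) / (1 + length(q) * smoothing)
  } else if (any(q == 0 & p > 0)) {
    stop("undefined divergence: q has a zero cell where p > 0 (use smoothing)")
  }
  keep <- p > 0
  sum(p[keep] * (log(p[keep] / q[keep]) / log(base)))
}

#' Baseline conditioning of plural class on an arbitrary letter cue
#'
#' A sanity baseline for interpreting mutual information values: conditions
#' plural class on a prima facie irrelevant four-level variable -- whether the
#' singular spelling contains the letter *a*, the letter *i*, both, or
#' neither (case-insensitive; umlauted vowels are distinct letters and do not
#' count). A well-calibrated "irrelevant" cue should carry near-zero MI on a
#' large lexicon. On the small lexicon fixture shipped with this package the
#' plug-in value is noisy and illustrative only; the near-zero large-lexicon
#' value reported in the literature needs a full lexical database.
#'
#' @param lexicon Data frame with columns `spelling` and `plural_class`
#'   (see [load_lexicon()]).
#' @return [info_summary()] of the letter-variable-by-class table.
#' @export
baseline_letter_conditioning <- function(lexicon) {
  if (is.null(lexicon) || nrow(lexicon) == 0) {
    stop("empty lexicon")
  }
  s <- tolower(lexicon$spelling)
  has_a <- grepl("a", s, fixed = TRUE)
  has_i <- grepl("i", s, fixed = TRUE)
  level <- ifelse(has_a & has_i, "both",
           ifelse(has_a, "a-only",
           ifelse(has_i, "i-only", "neither")))
  level <- factor(level, levels = c("a-only", "i-only", "both", "neither"))
  cls <- factor(as.character(lexicon$plural_class), levels = plural_classes())
  counts <- table(level, cls)
  keep <- rowSums(counts) > 0
  info_summary(gender_class_table(unclass(counts)[keep, , drop = FALSE]))
}
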