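# Orthographic-neighborhood analysis: normalized Levenshtein neighbor
# retrieval and neighborhood-level gender-conditioning statistics.
# Orthography stands in for phonology here (the elicitation is written), so
# comparisons are case-folded but umlaut-preserving: an umlauted vowel is a
# different letter from its plain counterpart.

#' Levenshtein edit distance
#'
#' Minimal number of single-character insertions, deletions, and
#' substitutions, computed elementwise over recycled vectors (delegates to
#' [utils::adist()]). Case-sensitive; callers that want case folding fold
#' first (as [normalized_distance()] does).
#'
#' @param a,b Character vectors (recycled to common length).
#' @return Integer vector of edit counts.
#' @export
levenshtein <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) {
    return(integer(0))
  }
  n <- max(length(a), length(b))
  a <- rep_len(as.character(a), n)
  b <- rep_len(as.character(b), n)
  out <- integer(n)
  for (i in seq_len(n)) {
    out[i] <- utils::adist(a[i], b[i])[1, 1]
  }
  out
}

#' Length-normalized edit distance from a stimulus
#'
#' Levenshtein distance divided by word length, comparison case-insensitive
#' (umlauts preserved). "Word length" is ambiguous in general; the default
#' normalizes by the stimulus length, with the maximum of the two lengths
#' available via `norm = "max"` (neighbor sets differ at the margin between
#' the two conventions).
#'
#' @param stimulus Nonempty stimulus string (scalar).
#' @param word Character vector of candidate words.
#' @param norm `"stimulus"` (default) or `"max"`.
#' @return Numeric vector of normalized distances.
#' @export
normalized_distance <- function(stimulus, word,
                                norm = c("stimulus", "max")) {
  norm <- match.arg(norm)
  if (length(stimulus) != 1 || !nzchar(stimulus)) {
    stop("stimulus must be a single nonempty string")
  }
  d <- levenshtein(tolower(stimulus), tolower(word))
  len <- switch(norm,
    stimulus = nchar(stimulus),
    max = pmax(nchar(stimulus), nchar(word))
  )
  d / len
}

#' Retrieve the orthographic neighborhood of a stimulus
#'
#' All lexicon entries whose normalized Levenshtein distance from the
#' stimulus is at most `threshold` (default 0.5). Entries whose spelling
#' equals the stimulus (case-insensitively) are excluded as self-matches;
#' duplicate lexicon spellings each count once. The empty neighborhood is a
#' legitimate result: phonologically atypical stimuli can have no neighbors.
#'
#' @param stimulus Single nonempty string.
#' @param lexicon Data frame from [load_lexicon()].
#' @param threshold Maximum normalized distance (default 0.5).
#' @param norm Normalization convention, see [normalized_distance()].
#' @return Object of class `neighbor_set`: list with `stimulus`,
#'   `neighbors` (data frame with `spelling`, `gender`, `plural_class`,
#'   `distance`, `normalized_distance`), and `table` (a
#'   [gender_class_table()] of neighbor counts, or `NULL` when empty).
#' @export
find_neighbors <- function(stimulus, lexicon, threshold = 0.5,
                           norm = c("stimulus", "max")) {
  norm <- match.arg(norm)
  if (is.null(lexicon) || nrow(lexicon) == 0) {
    stop("empty lexicon")
  }
  nd <- normalized_distance(stimulus, lexicon$spelling, norm = norm)
  keep <- nd <= threshold &
    tolower(lexicon$spelling) != tolower(stimulus)
  nb <- lexicon[keep, , drop = FALSE]
  nb$distance <- levenshtein(tolower(stimulus), tolower(nb$spelling))
  nb$normalized_distance <- nd[keep]
  rownames(nb) <- NULL
  tab <- if (nrow(nb) > 0) tally_lexicon(nb) else NULL
  structure(
    list(stimulus = stimulus, neighbors = nb, table = tab,
         threshold = threshold, norm = norm),
    class = "neighbor_set"
  )
}

#' @export
print.neighbor_set <- function(x, ...) {
  cat("neighborhood of '", x$stimulus, "': ", nrow(x$neighbors),
      " neighbors (threshold ", x$threshold, ", norm ", x$norm, ")\n",
      sep = "")
  if (nrow(x$neighbors) > 0) {
    print(utils::head(x$neighbors, 10))
  }
  invisible(x)
}

#' Gender-conditioning summary of a neighborhood
#'
#' Information summary of the neighbor gender-by-class count table, with
#' gender weighted by empirical neighbor counts: how much of the plural
#' class variation among a stimulus's lexical neighbors is conditioned on
#' gender. An empty neighborhood is an explicit error condition, not a
#' silent zero.
#'
#' @param ns A `neighbor_set` from [find_neighbors()].
#' @return An [info_summary()].
#' @export
neighborhood_info <- function(ns) {
  stopifnot(inherits(ns, "neighbor_set"))
  if (is.null(ns$table)) {
    stop("empty neighborhood: no words within threshold of '",
         ns$stimulus, "'")
  }
  info_summary(ns$table)
}

#' Neighborhood statistics for a set of stimuli
#'
#' Convenience wrapper running [find_neighbors()] and
#' [neighborhood_info()] over many stimuli.
#'
#' @param stimuli Character vector.
#' @param lexicon Data frame from [load_lexicon()].
#' @param threshold,norm See [find_neighbors()].
#' @return Data frame with `stimulus`, `n_neighbors`, `h_bits`, `mi_bits`,
#'   `ratio` (information columns `NA` for empty neighborhoods).
#' @export
neighborhood_table <- function(stimuli, lexicon, threshold = 0.5,
                               norm = c("stimulus", "max")) {
  norm <- match.arg(norm)
  rows <- lapply(stimuli, function(s) {
    ns <- find_neighbors(s, lexicon, threshold = threshold, norm = norm)
    if (is.null(ns$table)) {
      data.frame(stimulus = s, n_neighbors = 0L, h_bits = NA_real_,
                 mi_bits = NA_real_, ratio = NA_real_)
    } else {
      info <- neighborhood_info(ns)
      data.frame(stimulus = s, n_neighbors = nrow(ns$neighbors),
                 h_bits = info$entropy_bits, mi_bits = info$mi_bits,
                 ratio = info$ratio)
    }
  })
  do.call(rbind, rows)
}
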