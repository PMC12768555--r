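# Packaged lexical distributions and lexicon I/O.
#
# The gender-by-plural-class percentages for the German noun lexicon
# (overall and restricted to monosyllables) and the gender marginals are
# stored verbatim as the printed integer percentages; probabilities are
# obtained by renormalization at construction time, never by re-rounding,
# so downstream values are stable. Two rows do not sum to exactly 100
# (feminine overall: 99; masculine monosyllable: 101) -- printed rounding
# that renormalization absorbs.

#' Built-in gender-by-plural-class percentage tables
#'
#' The lexical distributions that drive every simulator and reference value
#' in this package, as integer percentages:
#'
#' * `overall`: plural-class percentages per gender over the full noun
#'   lexicon (rows F/M/N), with the lexicon-wide gender marginal
#'   (42/38/20) as weights.
#' * `all`: the gender-collapsed class distribution (45/26/18/4/4/3), used
#'   directly as the null-hypothesis production distribution (it is the
#'   printed marginal, not recomputed as a mixture of the rows).
#' * `monosyllable`: the same table restricted to monosyllabic nouns, with
#'   the monosyllable gender marginal (13/64/23) as weights.
#'
#' @return A list of class `lexicon_tables` with elements `overall` and
#'   `monosyllable` (both [gender_class_table()]) and `all` (probability
#'   vector over plural classes).
#' @export
builtin_tables <- function() {
  cls <- plural_classes()
  overall <- matrix(
    c(94, 3, 0, 1, 0, 1,
      13, 45, 34, 5, 1, 2,
      2, 39, 26, 9, 17, 7),
    nrow = 3, byrow = TRUE, dimnames = list(genders(), cls)
  )
  mono <- matrix(
    c(61, 25, 1, 11, 0, 2,
      7, 76, 1, 14, 2, 1,
      3, 43, 17, 14, 21, 1),
    nrow = 3, byrow = TRUE, dimnames = list(genders(), cls)
  )
  all_row <- c(45, 26, 18, 4, 4, 3)
  names(all_row) <- cls
  structure(
    list(
      overall = gender_class_table(overall, weights = c(42, 38, 20)),
      all = as_prob_vector(all_row),
      monosyllable = gender_class_table(mono, weights = c(13, 64, 23))
    ),
    class = "lexicon_tables"
  )
}

#' Read and write gender-by-class tables as CSV
#'
#' The on-disk dialect has a header `gender,en,e,zero,s,er,other` plus an
#' optional `weight` column; cells may be counts, percentages, or
#' probabilities (the constructor renormalizes either way). A write/read
#' round trip reproduces the stored cells exactly.
#'
#' @param t A [gender_class_table()].
#' @param path File path.
#' @return `read_gender_class_table` returns a [gender_class_table()];
#'   `write_gender_class_table` returns `path` invisibly.
#' @export
write_gender_class_table <- function(t, path) {
  stopifnot(inherits(t, "gender_class_table"))
  df <- data.frame(gender = rownames(t$cells), t$cells,
                   weight = t$weights, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_gender_class_table
#' @export
read_gender_class_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  if (!"gender" %in% names(df)) {
    stop("table CSV must have a 'gender' column")
  }
  weights <- if ("weight" %in% names(df)) df$weight else NULL
  cells <- as.matrix(df[, setdiff(names(df), c("gender", "weight")),
                        drop = FALSE])
  storage.mode(cells) <- "double"
  rownames(cells) <- df$gender
  gender_class_table(cells, weights = weights)
}

#' Load an annotated word list
#'
#' Reads a CSV with columns `spelling`, `gender`, `plural_class` (one row
#' per noun) and validates every label against the canonical category sets.
#' A small illustrative lexicon ships with the package; it is a synthetic
#' toy constructed for examples and tests, not an extract of any lexical
#' database:
#' `system.file("extdata", "toy_lexicon_synthetic.csv", package = "pluralinfo")`.
#'
#' @param path CSV file path.
#' @return Data frame with character columns `spelling`, `gender`,
#'   `plural_class`.
#' @export
load_lexicon <- function(path) {
  df <- utils::read.csv(path, colClasses = "character")
  need <- c("spelling", "gender", "plural_class")
  if (!all(need %in% names(df))) {
    stop("lexicon CSV must have columns: ", paste(need, collapse = ", "))
  }
  df <- df[, need]
  bad <- which(!nzchar(df$spelling))
  if (length(bad)) {
    stop("empty spelling at line ", bad[1] + 1L)
  }
  bad <- which(!df$gender %in% genders())
  if (length(bad)) {
    stop("unknown gender '", df$gender[bad[1]], "' at line ", bad[1] + 1L)
  }
  bad <- which(!df$plural_class %in% plural_classes())
  if (length(bad)) {
    stop("unknown plural class '", df$plural_class[bad[1]],
         "' at line ", bad[1] + 1L)
  }
  df
}

#' Tally a word list into a gender-by-class count table
#'
#' @param lexicon Data frame as returned by [load_lexicon()].
#' @return A [gender_class_table()] of counts with empirical gender weights.
#' @export
tally_lexicon <- function(lexicon) {
  if (is.null(lexicon) || nrow(lexicon) == 0) {
    stop("empty lexicon")
  }
  g <- factor(lexicon$gender, levels = genders())
  cls <- factor(lexicon$plural_class, levels = plural_classes())
  counts <- unclass(table(g, cls))
  gender_class_table(counts)
}
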