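# Corpus input/output and rule-based preprocessing.
#
# The on-disk corpus format is the challenge-style TSV: one snippet pair per
# line, `snippetA<TAB>snippetB<TAB>score` when labeled (score on the 0-5
# similarity scale), two columns when unlabeled.  No quoting; literal tabs
# inside snippets are therefore forbidden.

#' Read an STS corpus from a tab-separated file
#'
#' Each non-empty line must carry two snippets (and a gold score when
#' `labeled = TRUE`) separated by literal tabs.  Scores are validated
#' against the 0-5 similarity scale.
#'
#' @param path Path to the TSV file.
#' @param labeled Logical; does the file carry a third, score column?
#' @return A data frame with columns `pair_id`, `snippet_a`, `snippet_b`
#'   and (when labeled) `g_score`, one row per input line in file order.
#' @export
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' writeLines("patient denies chest pain .\tno chest pain reported .\t4.5", tf)
#' read_sts_tsv(tf)
read_sts_tsv <- function(path, labeled = TRUE) {
  if (!file.exists(path)) stop("corpus file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(lines))
  want <- if (labeled) 3L else 2L
  a <- character(length(keep)); b <- character(length(keep))
  g <- numeric(length(keep))
  for (j in seq_along(keep)) {
    i <- keep[j]
    fields <- strsplit(lines[i], "\t", fixed = TRUE)[[1]]
    if (length(fields) != want) {
      stop(sprintf("line %d: expected %d tab-separated fields, found %d",
                   i, want, length(fields)))
    }
    if (!nzchar(trimws(fields[1])) || !nzchar(trimws(fields[2]))) {
      stop(sprintf("line %d: empty snippet", i))
    }
    a[j] <- fields[1]; b[j] <- fields[2]
    if (labeled) {
      s <- suppressWarnings(as.numeric(fields[3]))
      if (is.na(s)) stop(sprintf("line %d: score '%s' is not numeric", i, fields[3]))
      if (s < 0 || s > 5) {
        stop(sprintf("line %d: score %s outside the [0, 5] similarity scale", i, fields[3]))
      }
      g[j] <- s
    }
  }
  out <- data.frame(pair_id = sprintf("p%05d", seq_along(keep)),
                    snippet_a = a, snippet_b = b,
                    stringsAsFactors = FALSE)
  if (labeled) out$g_score <- g
  out
}

#' Write an STS corpus to a tab-separated file
#'
#' Inverse of [read_sts_tsv()]: snippets and scores round-trip exactly.
#'
#' @param pairs Data frame with `snippet_a`, `snippet_b` and optionally
#'   `g_score` columns.
#' @param path Output path.
#' @export
write_sts_tsv <- function(pairs, path) {
  if (any(grepl("\t", c(pairs$snippet_a, pairs$snippet_b), fixed = TRUE))) {
    stop("snippets must not contain literal tabs")
  }
  if (!is.null(pairs$g_score)) {
    lines <- paste(pairs$snippet_a, pairs$snippet_b,
                   format(pairs$g_score, trim = TRUE, digits = 15,
                          scientific = FALSE),
                   sep = "\t")
  } else {
    lines <- paste(pairs$snippet_a, pairs$snippet_b, sep = "\t")
  }
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Write predicted similarity scores, one per line
#'
#' @param pairs Data frame of snippet pairs the scores belong to (used only
#'   to check lengths match).
#' @param scores Numeric vector of predicted scores.
#' @param path Output path.
#' @param digits Decimal places in the fixed-format output.
#' @export
write_predictions <- function(pairs, scores, path, digits = 4) {
  if (nrow(pairs) != length(scores)) {
    stop("length mismatch: ", nrow(pairs), " pairs but ",
         length(scores), " scores")
  }
  writeLines(sprintf(paste0("%.", digits, "f"), scores), path)
  invisible(path)
}

#' Preprocess a clinical text snippet into tokens
#'
#' Applies the corpus preprocessing rules: the snippet is lowercased and
#' split on whitespace and on the special symbols `[`, `]`, `/`, `,` and
#' `.`, each emitted as a standalone token.  A period immediately flanked
#' by digits on both sides is a decimal point and is kept inside its token
#' (so `"2.5 mg."` tokenizes as `"2.5"`, `"mg"`, `"."`).  The symbol set is
#' fixed and closed so that tokenization is reproducible.
#'
#' @param snippet A single non-empty character string.
#' @return Character vector of lowercase tokens, length at least 1.
#' @export
#' @examples
#' preprocess("Albuterol [PROVENTIL/VENTOLIN] 90")
#' preprocess("dose 2.5 mg.")
preprocess <- function(snippet) {
  if (length(snippet) != 1L || is.na(snippet)) {
    stop("preprocess() expects a single snippet string")
  }
  if (!nzchar(trimws(snippet))) stop("empty snippet")
  x <- tolower(snippet)
  # always-split symbols: [ ] / ,
  x <- gsub("([][/,])", " \\1 ", x)
  # protect decimal points (digit on both sides), then split remaining periods
  x <- gsub("(?<=[0-9])\\.(?=[0-9])", "\x01", x, perl = TRUE)
  x <- gsub(".", " . ", x, fixed = TRUE)
  x <- gsub("\x01", ".", x, fixed = TRUE)
  tokens <- strsplit(trimws(x), "[[:space:]]+")[[1]]
  tokens[nzchar(tokens)]
}
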