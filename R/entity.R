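# Entity layer: dictionary tagging of token sequences with the nine
# standard clinical mention types, mention extraction, and mapping of
# mentions to knowledge-graph identifiers.
#
# The tagger is a deterministic greedy longest-match dictionary tagger; it
# stands behind the same contract an external clinical NER system would
# fill (per-token labels aligned 1:1 with the tokens), so tagged output
# from such a system can be substituted without touching the model.

#' The closed entity-type label vocabulary
#'
#' The nine clinical mention types plus the non-entity label `"O"`.
#'
#' @return Character vector of the 10 labels.
#' @export
entity_types <- function() {
  c("AnatomicalSiteMention", "DiseaseDisorderMention", "FractionAnnotation",
    "MedicationMention", "Predicate", "ProcedureMention",
    "RomanNumeralAnnotation", "SignSymptomMention", "TemporalInformation",
    "O")
}

#' Build an entity lexicon
#'
#' @param surface Character vector of surface strings (stored lowercase;
#'   lookup is case-insensitive).  Multi-token surfaces are written with
#'   single spaces between tokens.
#' @param type Entity type for each surface, one of [entity_types()]
#'   excluding `"O"`.
#' @param kg_id Optional knowledge-graph identifier per surface (`NA` for
#'   unmapped entries).
#' @return A data frame of class `entity_lexicon`.
#' @export
entity_lexicon <- function(surface, type, kg_id = NA_character_) {
  surface <- tolower(trimws(surface))
  bad <- setdiff(unique(type), setdiff(entity_types(), "O"))
  if (length(bad)) stop("unknown entity type(s): ", paste(bad, collapse = ", "))
  if (anyDuplicated(surface)) stop("duplicate lexicon surfaces")
  lex <- data.frame(surface = surface, type = type,
                    kg_id = rep_len(as.character(kg_id), length(surface)),
                    stringsAsFactors = FALSE)
  class(lex) <- c("entity_lexicon", "data.frame")
  lex
}

#' Read an entity lexicon from a TSV file
#'
#' Format: `surface<TAB>entity_type[<TAB>kg_entity_id]`, one entry per line.
#'
#' @param path Path to the lexicon file.
#' @return An `entity_lexicon` data frame.
#' @export
read_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  n <- lengths(fields)
  if (any(n < 2L | n > 3L)) {
    stop("lexicon line ", which(n < 2L | n > 3L)[1], ": expected 2 or 3 fields")
  }
  entity_lexicon(surface = vapply(fields, `[`, "", 1L),
                 type = vapply(fields, `[`, "", 2L),
                 kg_id = vapply(fields, function(f)
                   if (length(f) >= 3L && nzchar(f[3])) f[3] else NA_character_, ""))
}

#' Write an entity lexicon to a TSV file
#'
#' @param lexicon An `entity_lexicon` data frame.
#' @param path Output path.
#' @export
write_lexicon <- function(lexicon, path) {
  kg <- ifelse(is.na(lexicon$kg_id), "", paste0("\t", lexicon$kg_id))
  writeLines(paste0(lexicon$surface, "\t", lexicon$type, kg), path)
  invisible(path)
}

#' Tag a token sequence with entity-type labels
#'
#' Greedy longest-match, leftmost-first dictionary tagging over token
#' n-grams: at each position the longest lexicon surface starting there is
#' matched (ties impossible: surfaces are unique), every token it covers
#' receives the surface's type, and scanning resumes after it.  Unmatched
#' tokens are labeled `"O"`.  The output is aligned 1:1 with the tokens.
#'
#' @param tokens Character vector of (lowercase) tokens, e.g. from
#'   [preprocess()].
#' @param lexicon An `entity_lexicon`; empty lexica yield all-`"O"`.
#' @return Character vector of labels, same length as `tokens`.
#' @export
#' @examples
#' lex <- entity_lexicon(c("zocor", "tablet", "mouth"),
#'                       c("MedicationMention", "MedicationMention",
#'                         "AnatomicalSiteMention"))
#' tag_entities(preprocess("Zocor 40 mg tablet 1 tablet by mouth one time daily."), lex)
tag_entities <- function(tokens, lexicon) {
  if (length(tokens) == 0L) stop("empty token sequence")
  labels <- rep("O", length(tokens))
  if (is.null(lexicon) || nrow(lexicon) == 0L) return(labels)
  surf_tokens <- strsplit(lexicon$surface, " ", fixed = TRUE)
  max_n <- max(lengths(surf_tokens))
  type_of <- stats::setNames(lexicon$type, lexicon$surface)
  toks <- tolower(tokens)
  i <- 1L
  L <- length(toks)
  while (i <= L) {
    matched <- 0L
    for (n in seq(min(max_n, L - i + 1L), 1L)) {
      key <- paste(toks[i:(i + n - 1L)], collapse = " ")
      if (!is.na(type_of[key])) {
        labels[i:(i + n - 1L)] <- type_of[[key]]
        matched <- n
        break
      }
    }
    i <- i + max(matched, 1L)
  }
  labels
}

#' Extract entity mentions from a label sequence
#'
#' A mention is a maximal run of identical non-`"O"` labels; adjacent runs
#' of different types are distinct mentions.
#'
#' @param labels Character vector of entity-type labels.
#' @param tokens Optional token vector aligned with `labels`; when given,
#'   each mention carries its surface text.
#' @return Data frame with columns `start`, `end`, `type` and (when tokens
#'   are supplied) `surface`; zero rows when no entity is present.
#' @export
entity_mentions <- function(labels, tokens = NULL) {
  if (!is.null(tokens) && length(tokens) != length(labels)) {
    stop("labels and tokens must be aligned")
  }
  r <- rle(labels)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "O"
  out <- data.frame(start = starts[keep], end = ends[keep],
                    type = r$values[keep], stringsAsFactors = FALSE)
  if (!is.null(tokens)) {
    out$surface <- vapply(seq_len(nrow(out)), function(i)
      paste(tokens[out$start[i]:out$end[i]], collapse = " "), "")
  }
  out
}

#' Knowledge-graph identifiers of the entities mentioned in a snippet
#'
#' For each mention (in left-to-right order) whose surface has a KG
#' identifier in the lexicon, that identifier is emitted; mentions without
#' one are skipped.  Repeated mentions repeat their identifier.
#'
#' @param labels Label sequence from [tag_entities()].
#' @param tokens Token sequence aligned with `labels`.
#' @param lexicon The `entity_lexicon` used for tagging.
#' @return Character vector of KG entity identifiers (possibly empty).
#' @export
kg_entity_ids <- function(labels, tokens, lexicon) {
  m <- entity_mentions(labels, tokens)
  if (nrow(m) == 0L || is.null(lexicon) || nrow(lexicon) == 0L) return(character())
  id_of <- stats::setNames(lexicon$kg_id, lexicon$surface)
  ids <- id_of[tolower(m$surface)]
  as.character(ids[!is.na(ids)])
}

#' Mention-level knowledge-graph coverage of a corpus
#'
#' Fraction of extracted entity mentions that carry a KG identifier --
#' the bookkeeping statistic for how much of the entity signal the
#' KG-embedding representation can see.
#'
#' @param pairs Data frame of snippet pairs (`snippet_a`, `snippet_b`).
#' @param lexicon The `entity_lexicon`.
#' @return List with `n_mentions`, `n_mapped` and `coverage`.
#' @export
kg_coverage <- function(pairs, lexicon) {
  n_men <- 0L; n_map <- 0L
  for (text in c(pairs$snippet_a, pairs$snippet_b)) {
    toks <- preprocess(text)
    labs <- tag_entities(toks, lexicon)
    m <- entity_mentions(labs, toks)
    n_men <- n_men + nrow(m)
    n_map <- n_map + length(kg_entity_ids(labs, toks, lexicon))
  }
  list(n_mentions = n_men, n_mapped = n_map,
       coverage = if (n_men > 0L) n_map / n_men else NA_real_)
}
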