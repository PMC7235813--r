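# BIO tagging scheme: entity spans <-> tag sequences over the 13-label vocabulary.

#' Clinical entity types
#'
#' The six entity categories recognised by the tagger: disease (`Dis`),
#' symptom (`Sym`), test (`Test`), treatment (`Tre`), medicine (`Med`) and
#' abnormal inspection result (`Abn`).
#'
#' @return Character vector of length 6, in canonical order.
#' @export
entity_types <- function() {
  c("Dis", "Sym", "Test", "Tre", "Med", "Abn")
}

#' BIO tag vocabulary
#'
#' The 13-label set used throughout the package: `B-t` and `I-t` for each of
#' the six entity types, plus `O`. The order is stable (type order of
#' [entity_types()], B before I) with `O` last; model output heads and column
#' files rely on this ordering.
#'
#' @return Character vector of 13 unique labels, `"O"` last.
#' @export
#' @examples
#' tag_vocabulary()
tag_vocabulary <- function() {
  ty <- entity_types()
  c(as.vector(rbind(paste0("B-", ty), paste0("I-", ty))), "O")
}

#' Construct a set of entity spans
#'
#' Spans use 0-based, half-open offsets: a span `[start, end)` covers
#' characters `start .. end - 1`. Spans are validated and returned sorted by
#' start offset.
#'
#' @param type Character vector of entity types (see [entity_types()]).
#' @param start,end Integer vectors of 0-based character offsets,
#'   `start < end`.
#' @return A `data.frame` with columns `type`, `start`, `end`, class
#'   `entity_spans`, sorted by `start`.
#' @export
#' @examples
#' entity_spans("Dis", 0, 3)
entity_spans <- function(type = character(), start = integer(), end = integer()) {
  stopifnot(length(type) == length(start), length(start) == length(end))
  type <- as.character(type)
  start <- as.integer(start)
  end <- as.integer(end)
  bad_type <- setdiff(unique(type), entity_types())
  if (length(bad_type) > 0) {
    stop("unknown entity type(s): ", paste(bad_type, collapse = ", "))
  }
  if (any(start >= end)) {
    stop("entity spans must satisfy start < end (0-based, half-open)")
  }
  df <- data.frame(type = type, start = start, end = end,
                   stringsAsFactors = FALSE)
  df <- df[order(df$start, df$end), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("entity_spans", "data.frame")
  df
}

as_entity_spans <- function(x) {
  if (inherits(x, "entity_spans")) return(x)
  if (is.null(x) || (is.data.frame(x) && nrow(x) == 0)) {
    return(entity_spans())
  }
  entity_spans(x$type, x$start, x$end)
}

# Overlap check on a start-sorted span set; returns index of first colliding
# pair or NULL.
find_overlap <- function(spans) {
  if (nrow(spans) < 2) return(NULL)
  for (i in seq_len(nrow(spans) - 1)) {
    if (spans$end[i] > spans$start[i + 1]) return(c(i, i + 1))
  }
  NULL
}

validate_spans <- function(spans, length) {
  spans <- as_entity_spans(spans)
  if (nrow(spans) == 0) return(spans)
  if (any(spans$start < 0) || any(spans$end > length)) {
    stop("entity spans must lie within [0, ", length, ")")
  }
  ov <- find_overlap(spans)
  if (!is.null(ov)) {
    stop(sprintf(
      "overlapping entity spans: (%s,%d,%d) and (%s,%d,%d)",
      spans$type[ov[1]], spans$start[ov[1]], spans$end[ov[1]],
      spans$type[ov[2]], spans$start[ov[2]], spans$end[ov[2]]))
  }
  spans
}

#' Encode entity spans as a BIO tag sequence
#'
#' Position `start` receives `B-t`, positions `start+1 .. end-1` receive
#' `I-t`, and every other position receives `O`.
#'
#' @param spans An [entity_spans()] set (or data.frame with the same
#'   columns); spans must be non-overlapping and lie within `[0, length)`.
#' @param length Sentence length in characters.
#' @return Character vector of `length` tags from [tag_vocabulary()].
#' @seealso [tags_to_spans()] for the inverse.
#' @export
#' @examples
#' spans_to_tags(entity_spans("Dis", 0, 3), 4)
spans_to_tags <- function(spans, length) {
  length <- as.integer(length)
  spans <- validate_spans(spans, length)
  tags <- rep("O", length)
  for (i in seq_len(nrow(spans))) {
    s <- spans$start[i]
    e <- spans$end[i]
    tags[s + 1L] <- paste0("B-", spans$type[i])
    if (e - s > 1L) tags[(s + 2L):e] <- paste0("I-", spans$type[i])
  }
  tags
}

#' Decode a BIO tag sequence into entity spans
#'
#' A span opens at `B-t` and closes at `O`, at any `B-`, at an `I-` of a
#' different type, or at the end of the sentence. An `I-t` with no valid
#' predecessor (sentence-initial, after `O`, or after a different type) is
#' handled by the repair policy: `"start-new"` opens a new span of type `t`
#' (the default, matching common scorer practice); `"strict"` raises an error
#' reporting the offending position.
#'
#' For any input drawn from [tag_vocabulary()] the result is a set of
#' non-overlapping spans sorted by start offset.
#'
#' @param tags Character vector of tags from [tag_vocabulary()].
#' @param repair `"start-new"` or `"strict"`.
#' @return An [entity_spans()] set.
#' @export
#' @examples
#' tags_to_spans(c("B-Dis", "I-Dis", "O", "B-Med"))
#' tags_to_spans(c("I-Dis", "I-Dis"), repair = "start-new")
tags_to_spans <- function(tags, repair = c("start-new", "strict")) {
  repair <- match.arg(repair)
  vocab <- tag_vocabulary()
  bad <- which(!(tags %in% vocab))
  if (length(bad) > 0) {
    stop(sprintf("unknown tag '%s' at position %d", tags[bad[1]], bad[1]))
  }
  type <- character(0)
  start <- integer(0)
  end <- integer(0)
  cur_type <- NULL
  cur_start <- NA_integer_
  close_span <- function(pos) {
    if (!is.null(cur_type)) {
      type[length(type) + 1L] <<- cur_type
      start[length(start) + 1L] <<- cur_start
      end[length(end) + 1L] <<- pos
      cur_type <<- NULL
    }
  }
  for (i in seq_along(tags)) {
    tg <- tags[i]
    if (tg == "O") {
      close_span(i - 1L)
    } else {
      prefix <- substr(tg, 1L, 1L)
      ty <- substring(tg, 3L)
      if (prefix == "B") {
        close_span(i - 1L)
        cur_type <- ty
        cur_start <- i - 1L
      } else { # I-
        if (!is.null(cur_type) && cur_type == ty) {
          # continue current span
        } else if (repair == "strict") {
          stop(sprintf("invalid BIO sequence: '%s' at position %d has no valid predecessor",
                       tg, i))
        } else {
          close_span(i - 1L)
          cur_type <- ty
          cur_start <- i - 1L
        }
      }
    }
  }
  close_span(length(tags))
  entity_spans(type, start, end)
}
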