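# Strict entity-level precision / recall / F1: a predicted entity is correct
# only if its type AND exact character boundaries match a gold entity in the
# same sentence. evaluate() is the production scorer; evaluate_bruteforce()
# recomputes the same contract by exhaustive pairwise matching and serves as
# its oracle twin in the tests.

prf <- function(tp, fp, fn) {
  # zero-denominator policy: undefined P/R/F1 are reported as 0
  p <- if (tp + fp > 0) tp / (tp + fp) else 0
  r <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = p, recall = r, f1 = f1)
}

new_metric_report <- function(counts) {
  # counts: data.frame(type, tp, fp, fn), one row per entity type
  per_type <- counts
  scores <- t(vapply(seq_len(nrow(counts)), function(i) {
    unlist(prf(counts$tp[i], counts$fp[i], counts$fn[i]))
  }, numeric(3)))
  per_type$precision <- scores[, 1]
  per_type$recall <- scores[, 2]
  per_type$f1 <- scores[, 3]
  micro_counts <- c(tp = sum(counts$tp), fp = sum(counts$fp),
                    fn = sum(counts$fn))
  micro <- c(as.list(micro_counts),
             prf(micro_counts[["tp"]], micro_counts[["fp"]],
                 micro_counts[["fn"]]))
  macro <- list(precision = mean(per_type$precision),
                recall = mean(per_type$recall), f1 = mean(per_type$f1))
  structure(list(per_type = per_type, micro = micro, macro = macro),
            class = "metric_report")
}

#' @export
print.metric_report <- function(x, ...) {
  fmt <- function(v) sprintf("%6.2f", 100 * v)
  cat(sprintf("%-6s %6s %6s %6s %7s %7s %7s\n", "type", "TP", "FP", "FN",
              "P%", "R%", "F1%"))
  for (i in seq_len(nrow(x$per_type))) {
    r <- x$per_type[i, ]
    cat(sprintf("%-6s %6d %6d %6d %7s %7s %7s\n", r$type, r$tp, r$fp, r$fn,
                fmt(r$precision), fmt(r$recall), fmt(r$f1)))
  }
  cat(sprintf("%-6s %6d %6d %6d %7s %7s %7s\n", "micro", x$micro$tp,
              x$micro$fp, x$micro$fn, fmt(x$micro$precision),
              fmt(x$micro$recall), fmt(x$micro$f1)))
  cat(sprintf("%-6s %6s %6s %6s %7s %7s %7s  (macro average)\n",
              "macro", "", "", "", fmt(x$macro$precision),
              fmt(x$macro$recall), fmt(x$macro$f1)))
  invisible(x)
}

#' Flatten a metric report to a data.frame
#'
#' @param x A `metric_report`.
#' @param row.names,optional,... Ignored (S3 signature compatibility).
#' @return data.frame with one row per type plus `micro` and `macro` rows.
#' @export
as.data.frame.metric_report <- function(x, row.names = NULL, optional = FALSE,
                                        ...) {
  rows <- x$per_type
  rows[nrow(rows) + 1L, ] <- list("micro", x$micro$tp, x$micro$fp, x$micro$fn,
                                  x$micro$precision, x$micro$recall,
                                  x$micro$f1)
  rows[nrow(rows) + 1L, ] <- list("macro", NA_integer_, NA_integer_,
                                  NA_integer_, x$macro$precision,
                                  x$macro$recall, x$macro$f1)
  rows
}

check_eval_inputs <- function(gold, predicted) {
  if (length(gold) != length(predicted)) {
    stop(sprintf("validation error: %d gold sentences but %d predictions",
                 length(gold), length(predicted)))
  }
  for (i in seq_along(gold)) {
    if (length(gold[[i]]$tokens) != length(predicted[[i]])) {
      stop(sprintf(
        "validation error: sentence %d has %d tokens but %d predicted tags",
        i, length(gold[[i]]$tokens), length(predicted[[i]])))
    }
  }
  invisible(TRUE)
}

#' Strict entity-level evaluation
#'
#' Decodes the predicted tags to spans (repair policy `"start-new"`) and
#' matches them against the gold spans of the same sentence: a predicted span
#' is a true positive iff a gold span with identical (type, start, end)
#' exists; each gold span can be matched at most once, so duplicated
#' predictions cannot double-count. Unmatched predictions are false
#' positives; unmatched gold spans are false negatives. P, R and F1 are
#' reported per type, micro-averaged (from summed counts - the headline
#' number) and macro-averaged; undefined ratios are reported as 0.
#'
#' @param gold List of [annotated_sentence()].
#' @param predicted List of character tag vectors, same sentence count and
#'   per-sentence lengths as `gold`.
#' @param repair Repair policy for invalid BIO sequences (see
#'   [tags_to_spans()]).
#' @return Object of class `metric_report`.
#' @export
#' @examples
#' gold <- list(annotated_sentence(strsplit("Dab,Sde", "")[[1]],
#'                                 entity_spans(c("Dis", "Sym"), c(0, 4), c(3, 7))))
#' pred <- list(c("B-Dis", "I-Dis", "I-Dis", "O", "B-Sym", "I-Sym", "I-Sym"))
#' evaluate(gold, pred)
evaluate <- function(gold, predicted, repair = "start-new") {
  check_eval_inputs(gold, predicted)
  types <- entity_types()
  tp <- fp <- fn <- stats::setNames(integer(length(types)), types)
  for (i in seq_along(gold)) {
    g <- as_entity_spans(gold[[i]]$entities)
    p <- tags_to_spans(predicted[[i]], repair = repair)
    gkey <- paste(g$type, g$start, g$end)
    pkey <- paste(p$type, p$start, p$end)
    gt <- table(gkey)
    pt <- table(pkey)
    shared <- intersect(names(gt), names(pt))
    matched <- pmin(gt[shared], pt[shared])
    # per-type attribution of matched counts
    for (k in seq_along(shared)) {
      ty <- sub(" .*", "", shared[k])
      tp[ty] <- tp[ty] + matched[k]
    }
    for (ty in types) {
      n_pred <- sum(p$type == ty)
      n_gold <- sum(g$type == ty)
      m <- if (length(shared)) {
        sum(matched[sub(" .*", "", shared) == ty])
      } else 0L
      fp[ty] <- fp[ty] + n_pred - m
      fn[ty] <- fn[ty] + n_gold - m
    }
  }
  new_metric_report(data.frame(type = types, tp = as.integer(tp),
                               fp = as.integer(fp), fn = as.integer(fn),
                               stringsAsFactors = FALSE))
}

#' Brute-force oracle scorer
#'
#' Same contract as [evaluate()], computed by exhaustive pairwise comparison:
#' every predicted span scans the gold spans of its sentence for an unmatched
#' exact (type, start, end) duplicate. Quadratic per sentence, with no
#' data-structure shortcuts; used as the independent cross-check in tests.
#'
#' @inheritParams evaluate
#' @return Object of class `metric_report`.
#' @export
evaluate_bruteforce <- function(gold, predicted, repair = "start-new") {
  check_eval_inputs(gold, predicted)
  types <- entity_types()
  tp <- fp <- fn <- stats::setNames(integer(length(types)), types)
  for (i in seq_along(gold)) {
    g <- as_entity_spans(gold[[i]]$entities)
    p <- tags_to_spans(predicted[[i]], repair = repair)
    gold_used <- rep(FALSE, nrow(g))
    for (j in seq_len(nrow(p))) {
      hit <- FALSE
      for (k in seq_len(nrow(g))) {
        if (!gold_used[k] && g$type[k] == p$type[j] &&
            g$start[k] == p$start[j] && g$end[k] == p$end[j]) {
          gold_used[k] <- TRUE
          hit <- TRUE
          break
        }
      }
      if (hit) {
        tp[p$type[j]] <- tp[p$type[j]] + 1L
      } else {
        fp[p$type[j]] <- fp[p$type[j]] + 1L
      }
    }
    for (k in seq_len(nrow(g))) {
      if (!gold_used[k]) fn[g$type[k]] <- fn[g$type[k]] + 1L
    }
  }
  new_metric_report(data.frame(type = types, tp = as.integer(tp),
                               fp = as.integer(fp), fn = as.integer(fn),
                               stringsAsFactors = FALSE))
}
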