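# Micro-averaged multiclass scoring over the five evaluated CPR classes.
#
# The confusion matrix is 6x6 in the fixed order NEG, CPR:3, CPR:4, CPR:5,
# CPR:6, CPR:9; rows are gold labels, columns predictions. Micro metrics
# pool true/false positives across the five positive classes only: the
# negative class is excluded from the positive set, but NEG instances
# predicted as a relation count as false positives and relations predicted
# NEG as false negatives.

#' Build a confusion matrix from gold and predicted labels
#'
#' @param gold,pred character vectors of labels from [cpi_classes()] (or
#'   0-based integer ids), equal length.
#' @return A `cpie_confusion` integer matrix (gold rows x predicted
#'   columns) in the fixed class order.
#' @export
confusion_from_predictions <- function(gold, pred) {
  if (length(gold) != length(pred)) stop("gold and pred lengths differ")
  if (is.numeric(gold)) gold <- id_to_class(gold)
  if (is.numeric(pred)) pred <- id_to_class(pred)
  class_to_id(gold); class_to_id(pred)  # validate labels
  cm <- table(factor(gold, levels = CPI_CLASS_ORDER),
              factor(pred, levels = CPI_CLASS_ORDER))
  cm <- matrix(as.integer(cm), 6L, 6L,
               dimnames = list(gold = CPI_CLASS_ORDER, pred = CPI_CLASS_ORDER))
  structure(cm, class = c("cpie_confusion", "matrix"))
}

as_confusion <- function(cm) {
  cm <- as.matrix(cm)
  if (!all(dim(cm) == c(6L, 6L))) stop("confusion matrix must be 6x6")
  if (any(cm < 0) || any(cm != round(cm))) stop("confusion counts must be non-negative integers")
  dimnames(cm) <- list(gold = CPI_CLASS_ORDER, pred = CPI_CLASS_ORDER)
  structure(cm, class = c("cpie_confusion", "matrix"))
}

#' Per-class precision, recall, F-score and support
#'
#' `P = cm[c,c] / colsum(c)`, `R = cm[c,c] / rowsum(c)`, `F` their harmonic
#' mean; a zero denominator yields 0 by convention. Support is the gold
#' row sum.
#'
#' @param cm 6x6 confusion matrix (gold x predicted, fixed class order).
#' @param class one of the five positive classes.
#' @return Named numeric vector `(precision, recall, f, support)`.
#' @export
per_class_metrics <- function(cm, class) {
  cm <- as_confusion(cm)
  if (!class %in% EVALUATED_CPR) stop("per-class metrics are defined for positive classes")
  tp <- cm[class, class]
  colsum <- sum(cm[, class]); rowsum_ <- sum(cm[class, ])
  p <- if (colsum > 0) tp / colsum else 0
  r <- if (rowsum_ > 0) tp / rowsum_ else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f, support = rowsum_)
}

#' Micro-averaged precision, recall and F over the positive classes
#'
#' @param cm 6x6 confusion matrix (gold x predicted, fixed class order).
#' @return Named numeric vector `(precision, recall, f)`.
#' @export
micro_metrics <- function(cm) {
  cm <- as_confusion(cm)
  pos <- EVALUATED_CPR
  tp <- sum(vapply(pos, function(cl) cm[cl, cl], 0))
  pred_pos <- sum(cm[, pos])
  gold_pos <- sum(cm[pos, ])
  p <- if (pred_pos > 0) tp / pred_pos else 0
  r <- if (gold_pos > 0) tp / gold_pos else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  c(precision = p, recall = r, f = f)
}

#' Full evaluation report
#'
#' @param cm 6x6 confusion matrix, or NULL to build one from `gold`/`pred`.
#' @param gold,pred label vectors (used when `cm` is NULL).
#' @param keywords optional attention-keyword list to attach
#'   (see [attention_keywords()]).
#' @return A `cpie_eval_report`: list with `confusion`, `per_class` data
#'   frame, `micro`, and optional `keywords`.
#' @export
eval_report <- function(cm = NULL, gold = NULL, pred = NULL, keywords = NULL) {
  if (is.null(cm)) cm <- confusion_from_predictions(gold, pred)
  cm <- as_confusion(cm)
  pc <- do.call(rbind, lapply(EVALUATED_CPR, function(cl) {
    m <- per_class_metrics(cm, cl)
    data.frame(label = cl, support = unname(m["support"]),
               precision = unname(m["precision"]),
               recall = unname(m["recall"]), f = unname(m["f"]),
               stringsAsFactors = FALSE)
  }))
  structure(list(confusion = cm, per_class = pc, micro = micro_metrics(cm),
                 keywords = keywords),
            class = "cpie_eval_report")
}

#' @export
print.cpie_eval_report <- function(x, digits = 3L, ...) {
  # round half-even to the printed precision
  r3 <- function(v) format(round(v, digits), nsmall = digits)
  cat("Per-class performance:\n")
  pc <- x$per_class
  cat(sprintf("  %-7s %7s %9s %7s %7s\n", "label", "support", "precision",
              "recall", "F"))
  for (i in seq_len(nrow(pc))) {
    cat(sprintf("  %-7s %7d %9s %7s %7s\n", pc$label[i], pc$support[i],
                r3(pc$precision[i]), r3(pc$recall[i]), r3(pc$f[i])))
  }
  cat(sprintf("Micro average: precision %s, recall %s, F %s\n",
              r3(x$micro["precision"]), r3(x$micro["recall"]),
              r3(x$micro["f"])))
  if (!is.null(x$keywords)) {
    cat("Top attention keywords:\n")
    for (cl in names(x$keywords)) {
      cat(sprintf("  %-7s %s\n", cl, paste(x$keywords[[cl]], collapse = ", ")))
    }
  }
  invisible(x)
}

#' Write / read a confusion matrix as TSV
#'
#' Header row `gold` + predicted class names; one row per gold class. This
#' makes externally published confusion matrices directly scoreable.
#'
#' @param cm 6x6 confusion matrix.
#' @param path file path.
#' @export
write_confusion_tsv <- function(cm, path) {
  cm <- as_confusion(cm)
  lines <- c(paste(c("gold", colnames(cm)), collapse = "\t"),
             vapply(rownames(cm), function(rn)
               paste(c(rn, cm[rn, ]), collapse = "\t"), ""))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_confusion_tsv
#' @export
read_confusion_tsv <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- fields[[1]][-1]
  if (!identical(header, CPI_CLASS_ORDER)) {
    stop("confusion TSV header must list the classes in the fixed order: ",
         paste(CPI_CLASS_ORDER, collapse = ", "))
  }
  body <- fields[-1]
  cm <- matrix(0L, 6L, 6L, dimnames = list(gold = CPI_CLASS_ORDER,
                                           pred = CPI_CLASS_ORDER))
  for (f in body) cm[f[1], ] <- as.integer(f[-1])
  as_confusion(cm)
}

#' Rank attention keywords per predicted class
#'
#' Aggregates attention-pooling weights over all instances predicted as
#' each class: each (lowercased) token's score is the mean (default) or
#' sum of the pooling weights it received. Mean aggregation normalizes
#' away token frequency, so ubiquitous function words do not outrank the
#' class-specific tokens the model actually attends to; sum aggregation is
#' available for frequency-weighted rankings. Entity placeholders and
#' padding are excluded; a class with no predicted instances gets an empty
#' vector. Stopwords are not filtered.
#'
#' @param tokens_list list of per-instance token vectors.
#' @param weights_list list of per-instance pooling-weight vectors
#'   (aligned with the tokens).
#' @param pred_labels per-instance predicted labels.
#' @param k number of keywords per class.
#' @param agg `"mean"` (default) or `"sum"` aggregation.
#' @param min_count minimum number of occurrences (within the class's
#'   predicted instances) for a token to be ranked; protects the mean
#'   against tokens seen once with an incidentally high weight.
#' @param exclude tokens to exclude from the ranking.
#' @return Named list (one entry per class in [cpi_classes()], NEG
#'   included) of up to `k` tokens, highest score first.
#' @export
attention_keywords <- function(tokens_list, weights_list, pred_labels,
                               k = 5L, agg = c("mean", "sum"),
                               min_count = 2L,
                               exclude = c("chem_ent", "gene_ent", "<pad>", "<oov>")) {
  agg <- match.arg(agg)
  out <- stats::setNames(vector("list", length(CPI_CLASS_ORDER)), CPI_CLASS_ORDER)
  for (cl in CPI_CLASS_ORDER) {
    idx <- which(pred_labels == cl)
    if (length(idx) == 0L || k == 0L) {
      out[[cl]] <- character(0)
      next
    }
    toks <- tolower(unlist(tokens_list[idx], use.names = FALSE))
    wts <- unlist(weights_list[idx], use.names = FALSE)
    keep <- !(toks %in% exclude)
    toks <- toks[keep]; wts <- wts[keep]
    if (length(toks) == 0L) {
      out[[cl]] <- character(0)
      next
    }
    score <- tapply(wts, toks, if (agg == "sum") sum else mean)
    counts <- table(toks)
    score <- score[counts[names(score)] >= min_count]
    out[[cl]] <- names(sort(score, decreasing = TRUE))[seq_len(min(k, length(score)))]
  }
  out
}

#' Export an evaluation report as JSON
#'
#' @param report a `cpie_eval_report`.
#' @param path file path.
#' @export
write_report_json <- function(report, path) {
  jsonlite::write_json(list(
    confusion = unclass(report$confusion),
    per_class = report$per_class,
    micro = as.list(report$micro),
    keywords = report$keywords
  ), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
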