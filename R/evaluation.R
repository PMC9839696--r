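# Evaluation: confusion matrices, precision/recall/F1, the two-stage
# inference cascade, and the per-acquisition SCD marker (percentage of
# tank-treading cells among reliable cells).

#' Binary classes of each cascade stage
#'
#' Stage 1 separates `unreliable` from `reliable` (positive class:
#' `reliable`); stage 2 separates `tank_treading` from `flipping` (positive
#' class: `flipping`, the minority group).
#'
#' @param stage 1 or 2.
#' @return character vector of the two class names, negative class first.
#' @export
stage_classes <- function(stage) {
  switch(as.character(stage),
         "1" = c("unreliable", "reliable"),
         "2" = c("tank_treading", "flipping"),
         stop("stage must be 1 or 2"))
}

#' Positive class of a cascade stage
#' @inheritParams stage_classes
#' @export
stage_positive <- function(stage) stage_classes(stage)[2]

#' Collapse three-way motion labels to the binary labels of a stage
#'
#' @param labels character vector over [MOTION_LABELS].
#' @inheritParams stage_classes
#' @return for stage 1, `"reliable"`/`"unreliable"`; for stage 2 the labels
#'   must already be reliable and are returned unchanged.
#' @export
collapse_labels <- function(labels, stage) {
  if (stage == 1)
    return(ifelse(labels == "unreliable", "unreliable", "reliable"))
  if (any(labels == "unreliable"))
    stop("stage 2 labels must be reliable (tank_treading or flipping)")
  labels
}

#' Binary confusion matrix
#'
#' @param true,predicted parallel character vectors of binary labels.
#' @param positive the declared positive class.
#' @return an object of class `rbc_confusion` with counts `tp`, `fp`, `fn`,
#'   `tn`.
#' @export
confusion <- function(true, predicted, positive) {
  if (length(true) != length(predicted)) stop("label vectors must be parallel")
  classes <- unique(c(true, predicted))
  if (length(classes) > 2) stop("confusion() expects binary labels")
  structure(list(
    tp = sum(true == positive & predicted == positive),
    fp = sum(true != positive & predicted == positive),
    fn = sum(true == positive & predicted != positive),
    tn = sum(true != positive & predicted != positive),
    positive = positive, total = length(true)), class = "rbc_confusion")
}

#' @export
print.rbc_confusion <- function(x, ...) {
  cat(sprintf("<confusion, positive = %s>\n", x$positive))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(true = c("positive", "negative"),
                              predicted = c("positive", "negative")))
  print(m)
  invisible(x)
}

#' Accuracy, precision, recall and F1 from a confusion matrix
#'
#' `accuracy = (TP+TN)/total`, `precision = TP/(TP+FP)`,
#' `recall = TP/(TP+FN)` and the F1-score as the harmonic mean of precision
#' and recall. A zero denominator yields 0 with a warning (and a
#' `degenerate` flag in the result) so that F1 stays computable.
#'
#' @param cm an `rbc_confusion`, or a list with fields `tp`, `fp`, `fn`, `tn`.
#' @return a list with `accuracy`, `precision`, `recall`, `f1`, `degenerate`.
#' @export
prf_metrics <- function(cm) {
  total <- cm$tp + cm$fp + cm$fn + cm$tn
  if (total == 0) stop("empty confusion matrix")
  degenerate <- FALSE
  div <- function(num, den) {
    if (den == 0) {
      warning("zero denominator in precision/recall; reporting 0")
      degenerate <<- TRUE
      return(0)
    }
    num / den
  }
  precision <- div(cm$tp, cm$tp + cm$fp)
  recall <- div(cm$tp, cm$tp + cm$fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  list(accuracy = (cm$tp + cm$tn) / total, precision = precision,
       recall = recall, f1 = f1, degenerate = degenerate)
}

#' Run the two-stage inference cascade
#'
#' Stage 1 classifies each sequence as reliable or unreliable; sequences
#' predicted unreliable are excluded from further processing. Stage 2
#' classifies the remainder as flipping or tank-treading. Every input
#' receives exactly one of the three final labels. Each stage applies its
#' own preprocessing configuration to the raw sequences.
#'
#' @param stage1_model,stage2_model trained classifiers (see [train_model]);
#'   any object with a [predict_proba] method over the stage's classes works.
#' @param sequences list of [rbc_sequence] objects (raw, unpreprocessed).
#' @param cfg1,cfg2 [preprocess_config]s for the two stages.
#' @return character vector of final labels over [MOTION_LABELS].
#' @export
two_stage_predict <- function(stage1_model, stage2_model, sequences,
                              cfg1, cfg2) {
  prep <- function(s, cfg) {
    down <- if (cfg$sampling == "uniform") uniform_downsample
            else similarity_downsample
    s <- down(s, cfg$K)
    if (cfg$pad_to_K) s <- pad_sequence(s, cfg$K)
    s
  }
  vapply(sequences, function(s) {
    p1 <- predict_proba(stage1_model, prep(s, cfg1))
    if (names(which.max(p1)) == "unreliable") return("unreliable")
    p2 <- predict_proba(stage2_model, prep(s, cfg2))
    names(which.max(p2))
  }, character(1))
}

#' Per-acquisition SCD marker
#'
#' For every acquisition, the percentage of tank-treading cells among its
#' reliable cells: `100 * n_tank / (n_tank + n_flip)`. Sequences labeled
#' unreliable are excluded from both numerator and denominator. An
#' acquisition with no reliable sequence is reported as `NA` (undefined),
#' never as 0.
#'
#' @param final_labels character vector over [MOTION_LABELS].
#' @param acquisition_ids parallel vector of acquisition ids.
#' @return data.frame with columns `acquisition_id`, `n_tank`, `n_flip`,
#'   `n_reliable`, `ratio_pct`.
#' @export
marker_ratio <- function(final_labels, acquisition_ids) {
  if (length(final_labels) != length(acquisition_ids))
    stop("label and acquisition vectors must be parallel")
  acqs <- unique(acquisition_ids)
  out <- do.call(rbind, lapply(acqs, function(a) {
    l <- final_labels[acquisition_ids == a]
    nt <- sum(l == "tank_treading"); nf <- sum(l == "flipping")
    data.frame(acquisition_id = a, n_tank = nt, n_flip = nf,
               n_reliable = nt + nf,
               ratio_pct = if (nt + nf > 0) 100 * nt / (nt + nf) else NA_real_)
  }))
  rownames(out) <- NULL
  out
}

#' Assemble an evaluation report
#'
#' Computes the stage's confusion matrix and metrics and, for stage 2, the
#' per-acquisition marker table comparing ground-truth and estimated
#' tank-treading percentages. The report checks internally that F1 equals
#' the harmonic mean of precision and recall.
#'
#' @param true,predicted parallel binary label vectors (stage vocabulary).
#' @param acquisition_ids parallel acquisition ids (stage 2 marker table);
#'   ignored for stage 1.
#' @param stage 1 or 2.
#' @return an object of class `rbc_eval_report`.
#' @export
evaluate_run <- function(true, predicted, acquisition_ids = NULL, stage = 1) {
  cm <- confusion(true, predicted, positive = stage_positive(stage))
  m <- prf_metrics(cm)
  hm <- if (m$precision + m$recall == 0) 0 else
    2 * m$precision * m$recall / (m$precision + m$recall)
  stopifnot(abs(m$f1 - hm) < 1e-12)
  markers <- NULL
  if (stage == 2 && !is.null(acquisition_ids)) {
    gt <- marker_ratio(true, acquisition_ids)
    est <- marker_ratio(predicted, acquisition_ids)
    markers <- data.frame(acquisition_id = gt$acquisition_id,
                          ground_truth_pct = gt$ratio_pct,
                          estimated_pct = est$ratio_pct,
                          n_reliable = gt$n_reliable)
  }
  structure(list(stage = stage, confusion = cm, metrics = m,
                 per_acquisition_markers = markers),
            class = "rbc_eval_report")
}

#' @export
print.rbc_eval_report <- function(x, ...) {
  cat(sprintf("<stage %d evaluation>\n", x$stage))
  print(x$confusion)
  m <- x$metrics
  cat(sprintf("accuracy %.2f  precision %.2f  recall %.2f  F1 %.2f\n",
              m$accuracy, m$precision, m$recall, m$f1))
  if (!is.null(x$per_acquisition_markers)) {
    cat("per-acquisition tank-treading percentage (ground truth vs estimated):\n")
    df <- x$per_acquisition_markers
    df$ground_truth_pct <- round(df$ground_truth_pct, 1)
    df$estimated_pct <- round(df$estimated_pct, 1)
    print(df, row.names = FALSE)
  }
  invisible(x)
}

#' Serialize an evaluation report to JSON
#'
#' @param report an `rbc_eval_report`.
#' @param path output file path.
#' @export
write_eval_report <- function(report, path) {
  x <- list(stage = report$stage,
            confusion = report$confusion[c("tp", "fp", "fn", "tn", "positive")],
            metrics = report$metrics,
            per_acquisition_markers = report$per_acquisition_markers)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
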