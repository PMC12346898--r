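# Confusion-matrix metrics (one-vs-rest accuracy, precision, recall,
# specificity, F1), the channel-ablation experiment grid, and report
# tables.

#' Confusion matrix from actual/predicted class vectors
#'
#' @param y_true,y_pred Integer class vectors (0-based, values in
#'   `0..n_classes-1`) of equal length.
#' @param n_classes Number of classes (default 3).
#' @return `n_classes` x `n_classes` integer matrix; rows are actual
#'   classes, columns predicted.
#' @export
confusion_counts <- function(y_true, y_pred, n_classes = 3L) {
  if (length(y_true) != length(y_pred)) stop("length mismatch", call. = FALSE)
  if (any(!(y_true %in% 0:(n_classes - 1))) || any(!(y_pred %in% 0:(n_classes - 1)))) {
    stop("labels out of range 0..", n_classes - 1, call. = FALSE)
  }
  cm <- matrix(0L, n_classes, n_classes,
               dimnames = list(actual = SOUND_CLASSES[seq_len(n_classes)],
                               predicted = SOUND_CLASSES[seq_len(n_classes)]))
  for (i in seq_along(y_true)) {
    cm[y_true[i] + 1L, y_pred[i] + 1L] <- cm[y_true[i] + 1L, y_pred[i] + 1L] + 1L
  }
  cm
}

#' Evaluation metrics from a confusion matrix
#'
#' Per class (one-vs-rest): TP/FP/FN/TN, accuracy `(TP+TN)/total`,
#' precision `TP/(TP+FP)`, recall (sensitivity) `TP/(TP+FN)`, specificity
#' `TN/(TN+FP)`, and F1 `2PR/(P+R)`.  Macro metrics are unweighted means
#' over classes; `overall_accuracy` is the trace over the total.  A `0/0`
#' cell is reported as 0 and flagged in `zero_flags`.
#'
#' @param cm Confusion matrix (rows actual, columns predicted).
#' @return An object of class `eval_report`: list with `confusion`,
#'   `per_class` (data frame), `macro` (named vector), `overall_accuracy`,
#'   `zero_flags`.
#' @export
eval_metrics <- function(cm) {
  cm <- as.matrix(cm)
  if (nrow(cm) != ncol(cm) || any(cm < 0)) stop("invalid confusion matrix", call. = FALSE)
  if (is.null(rownames(cm))) {
    nm <- if (nrow(cm) == 3) SOUND_CLASSES else paste0("class", seq_len(nrow(cm)) - 1)
    dimnames(cm) <- list(actual = nm, predicted = nm)
  }
  total <- sum(cm)
  if (total == 0) stop("empty confusion matrix", call. = FALSE)
  K <- nrow(cm)
  flags <- character()
  safe_div <- function(num, den, what, cls) {
    if (den == 0) {
      flags <<- c(flags, sprintf("%s undefined (0/0) for class %s; reported as 0", what, cls))
      return(0)
    }
    num / den
  }
  rows <- lapply(seq_len(K), function(k) {
    cls <- rownames(cm)[k]
    tp <- cm[k, k]
    fp <- sum(cm[-k, k])
    fn <- sum(cm[k, -k])
    tn <- total - tp - fp - fn
    p <- safe_div(tp, tp + fp, "precision", cls)
    r <- safe_div(tp, tp + fn, "recall", cls)
    data.frame(class = cls, tp = tp, fp = fp, fn = fn, tn = tn,
               accuracy = (tp + tn) / total, precision = p, recall = r,
               specificity = safe_div(tn, tn + fp, "specificity", cls),
               f1 = safe_div(2 * p * r, p + r, "f1", cls))
  })
  per_class <- do.call(rbind, rows)
  macro <- c(accuracy = mean(per_class$accuracy),
             precision = mean(per_class$precision),
             sensitivity = mean(per_class$recall),
             specificity = mean(per_class$specificity),
             f1 = mean(per_class$f1))
  structure(list(confusion = cm, per_class = per_class, macro = macro,
                 overall_accuracy = sum(diag(cm)) / total, zero_flags = flags),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat("confusion matrix (rows actual, cols predicted):\n")
  print(x$confusion)
  cat(sprintf("overall accuracy: %.4f\n", x$overall_accuracy))
  cat("macro: ", paste(sprintf("%s=%.4f", names(x$macro), x$macro), collapse = "  "), "\n")
  if (length(x$zero_flags)) cat("flags:\n ", paste(x$zero_flags, collapse = "\n  "), "\n")
  invisible(x)
}

#' Channel-ablation experiment
#'
#' For each requested position subset, rebuilds the model inputs from only
#' those channels, runs the full ensemble training pipeline with the same
#' base seed and the same subject-level split, and reports the aggregated
#' metrics -- so the comparison isolates channel count/placement.
#' Duplicate subsets are deduplicated.
#'
#' @param recordings List of [multi_channel_recording()] objects.
#' @param subsets List of position vectors (each a subset of the cohort's
#'   channels).
#' @param model_cfg A [model_config()].
#' @param tr_config A [train_config()].
#' @param sp A [split_spec()].
#' @param params An [mfcc_params()].
#' @param frontend `"mfcc"` or `"ts"`.
#' @param verbose Passed through to training.
#' @return An object of class `ablation_result`: named list of
#'   [train_ensemble()] outputs (one per subset, named by hyphenated
#'   positions), with the split attached as an attribute.
#' @export
run_ablation <- function(recordings, subsets, model_cfg, tr_config,
                         sp = split_spec(), params = mfcc_params(),
                         frontend = c("mfcc", "ts"), verbose = FALSE) {
  frontend <- match.arg(frontend)
  keys <- vapply(subsets, function(s) paste(order_positions(canonical_position(s)),
                                            collapse = "-"), "")
  keep <- !duplicated(keys)
  subsets <- subsets[keep]; keys <- keys[keep]
  have <- names(recordings[[1]]$channels)
  for (s in subsets) {
    miss <- setdiff(canonical_position(s), have)
    if (length(miss)) stop("cohort lacks position(s): ", paste(miss, collapse = ", "),
                           call. = FALSE)
  }
  labels <- vapply(recordings, function(r) r$label, "")
  subj <- vapply(recordings, function(r) r$subject_id, "")
  parts <- split_dataset(labels, subj, sp)
  y <- match(labels, SOUND_CLASSES) - 1L
  results <- list()
  for (i in seq_along(subsets)) {
    pos <- canonical_position(subsets[[i]])
    inputs <- lapply(recordings, function(r) {
      if (frontend == "mfcc") {
        recording_to_input(r, pos, params, model_cfg$input_shape)
      } else {
        recording_to_ts_input(r, pos, shape = model_cfg$input_shape)
      }
    })
    splits <- lapply(parts, function(ix) list(inputs = inputs[ix], labels = y[ix]))
    results[[keys[i]]] <- train_ensemble(model_cfg, splits, tr_config, verbose = verbose)
  }
  structure(results, class = "ablation_result", split = parts)
}

#' Format ablation results as report tables
#'
#' One row per position subset with accuracy, sensitivity, specificity,
#' precision, and F1 as `"mean ± sd"` cells; optionally written as CSV
#' (numeric mean/sd columns) and as an aligned text table.
#'
#' @param ablation An [run_ablation()] result, or any named list of
#'   [train_ensemble()] outputs.
#' @param path_prefix Optional path prefix; writes
#'   `<prefix>.csv` and `<prefix>.txt`.
#' @return Data frame of the numeric table (invisibly when written).
#' @export
report_tables <- function(ablation, path_prefix = NULL) {
  if (length(ablation) == 0L) stop("empty ablation result", call. = FALSE)
  rows <- lapply(names(ablation), function(k) {
    s <- ablation[[k]]$summary
    out <- data.frame(subset = k)
    for (i in seq_len(nrow(s))) {
      out[[paste0(s$metric[i], "_mean")]] <- s$mean[i]
      out[[paste0(s$metric[i], "_sd")]] <- s$sd[i]
    }
    out
  })
  df <- do.call(rbind, rows)
  if (!is.null(path_prefix)) {
    utils::write.csv(df, paste0(path_prefix, ".csv"), row.names = FALSE, quote = FALSE)
    metrics <- c("accuracy", "sensitivity", "specificity", "precision", "f1")
    txt <- c(sprintf("%-28s %s", "positions",
                     paste(sprintf("%-14s", metrics), collapse = " ")))
    for (i in seq_len(nrow(df))) {
      cells <- vapply(metrics, function(m)
        sprintf("%.2f ± %.2f", df[[paste0(m, "_mean")]][i], df[[paste0(m, "_sd")]][i]), "")
      txt <- c(txt, sprintf("%-28s %s", df$subset[i],
                            paste(sprintf("%-14s", cells), collapse = " ")))
    }
    writeLines(txt, paste0(path_prefix, ".txt"))
    return(invisible(df))
  }
  df
}
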