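# Data splitting, seeded training sessions, and the three-session ensemble
# protocol.

#' Split specification
#'
#' @param fractions Train/validation/test fractions, default
#'   `c(0.70, 0.15, 0.15)`; must sum to 1.
#' @param stratified Stratify per class (largest-remainder apportionment
#'   within each class).
#' @param group_by_subject Keep all recordings of one subject in one
#'   partition.
#' @param seed Integer seed.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(fractions = c(0.70, 0.15, 0.15), stratified = TRUE,
                       group_by_subject = TRUE, seed = 1) {
  if (length(fractions) != 3 || any(fractions < 0) || abs(sum(fractions) - 1) > 1e-8) {
    stop("fractions must be 3 non-negative values summing to 1", call. = FALSE)
  }
  structure(list(fractions = as.numeric(fractions), stratified = isTRUE(stratified),
                 group_by_subject = isTRUE(group_by_subject), seed = as.integer(seed)),
            class = "split_spec")
}

#' Split a labeled dataset into train/validation/test partitions
#'
#' Partitions are disjoint and exhaustive.  With stratification, each
#' class's items are apportioned by largest remainder; with subject
#' grouping, the units being apportioned are subjects, so no subject spans
#' partitions.
#'
#' Augmentation-derived items (subject ids carrying an `_aug<k>` suffix,
#' as produced by [rebalance()]) are grouped with their source subject, so
#' they can never leak into a different partition than their original.
#'
#' @param labels Character vector of class labels, one per item.
#' @param subject_ids Optional subject identifier per item (required when
#'   `group_by_subject`).
#' @param spec A [split_spec()].
#' @return List with integer index vectors `train`, `val`, `test`.
#' @export
split_dataset <- function(labels, subject_ids = NULL, spec = split_spec()) {
  stopifnot(inherits(spec, "split_spec"))
  n <- length(labels)
  labels <- canonical_class(labels)
  if (spec$group_by_subject && is.null(subject_ids)) subject_ids <- as.character(seq_len(n))
  if (!is.null(subject_ids)) subject_ids <- sub("_aug[0-9]+$", "", subject_ids)
  units <- if (spec$group_by_subject) {
    u <- unique(subject_ids)
    list(ids = u, label = vapply(u, function(s) labels[match(s, subject_ids)], ""))
  } else {
    list(ids = seq_len(n), label = labels)
  }
  strata <- if (spec$stratified) split(seq_along(units$ids), units$label) else
    list(all = seq_along(units$ids))
  if (spec$stratified) {
    small <- vapply(strata, length, 0L) < 3
    if (any(small)) {
      stop("class too small to stratify into 3 partitions: ",
           paste(names(strata)[small], collapse = ", "), call. = FALSE)
    }
  }
  parts <- list(train = integer(), val = integer(), test = integer())
  for (sname in names(strata)) {
    idx <- strata[[sname]]
    idx <- idx[withr::with_seed(derive_seed(spec$seed, "split", sname),
                                sample.int(length(idx)))]
    sizes <- largest_remainder(length(idx), spec$fractions)
    parts$train <- c(parts$train, idx[seq_len(sizes[1])])
    parts$val <- c(parts$val, idx[sizes[1] + seq_len(sizes[2])])
    parts$test <- c(parts$test, idx[sizes[1] + sizes[2] + seq_len(sizes[3])])
  }
  if (spec$group_by_subject) {
    lapply(parts, function(ui) sort(which(subject_ids %in% units$ids[ui])))
  } else {
    lapply(parts, function(ui) sort(units$ids[ui]))
  }
}

#' Training configuration
#'
#' Defaults follow the reference protocol: 50 epochs, batch size 20,
#' categorical cross-entropy, rectified Adam with epsilon 1e-6, learning
#' rate decaying linearly from 1e-4 to 5e-5, and 3 ensemble sessions.
#'
#' @param epochs Number of epochs (>= 1).
#' @param batch_size Minibatch size.
#' @param lr_start,lr_end Linear learning-rate schedule endpoints
#'   (`0 < lr_end <= lr_start`).
#' @param radam_eps RAdam epsilon.
#' @param n_sessions Ensemble sessions.
#' @param seed Base seed; session `i` uses `seed + i`.
#' @return An object of class `train_config`.
#' @export
train_config <- function(epochs = 50, batch_size = 20, lr_start = 1e-4,
                         lr_end = 5e-5, radam_eps = 1e-6, n_sessions = 3, seed = 1) {
  if (epochs < 1) stop("epochs must be >= 1", call. = FALSE)
  if (!(lr_end > 0 && lr_end <= lr_start)) {
    stop("need 0 < lr_end <= lr_start", call. = FALSE)
  }
  structure(list(epochs = as.integer(epochs), batch_size = as.integer(batch_size),
                 lr_start = lr_start, lr_end = lr_end, radam_eps = radam_eps,
                 n_sessions = as.integer(n_sessions), seed = as.integer(seed)),
            class = "train_config")
}

# Per-epoch learning rate under linear decay.
.lr_at <- function(cfg, epoch) {
  if (cfg$epochs == 1L) return(cfg$lr_start)
  cfg$lr_start + (cfg$lr_end - cfg$lr_start) * (epoch - 1) / (cfg$epochs - 1)
}

.stack_inputs <- function(inputs, idx, S) {
  vapply(inputs[idx], function(mi) as.vector(mi$grid), numeric(S))
}

#' Run one seeded training session
#'
#' Minibatch RAdam on categorical cross-entropy with the linear
#' learning-rate schedule; per-epoch train/validation loss and accuracy are
#' logged and the checkpoint with the best validation loss is returned.
#' Non-finite loss aborts with a condition of class
#' `auscultnet_divergence`.
#'
#' @param model_cfg A [model_config()].
#' @param train,val Lists with elements `inputs` (list of `model_input`)
#'   and `labels` (0-based integer classes).
#' @param config A [train_config()].
#' @param session_seed Seed for this session (initialization, shuffling,
#'   dropout).
#' @param verbose Print one line per epoch.
#' @return List with `model` (best checkpoint), `history` (data frame),
#'   and `best_epoch`.
#' @export
train_session <- function(model_cfg, train, val, config, session_seed = 1,
                          verbose = FALSE) {
  stopifnot(inherits(model_cfg, "model_config"), inherits(config, "train_config"))
  if (length(train$inputs) == 0L || length(val$inputs) == 0L) {
    stop("empty train/val partition", call. = FALSE)
  }
  S <- prod(model_cfg$input_shape)
  model <- build_model(model_cfg, seed = session_seed)
  opt <- radam_init(model$params, lr = config$lr_start, eps = config$radam_eps)
  n <- length(train$inputs)
  hist <- data.frame(epoch = integer(), lr = numeric(), train_loss = numeric(),
                     train_acc = numeric(), val_loss = numeric(), val_acc = numeric())
  best <- list(loss = Inf, params = NULL, bn = NULL, epoch = NA_integer_)
  for (epoch in seq_len(config$epochs)) {
    lr <- .lr_at(config, epoch)
    ord <- withr::with_seed(derive_seed(session_seed, "shuffle", epoch), sample.int(n))
    ep_loss <- 0; ep_correct <- 0
    starts <- seq(1L, n, by = config$batch_size)
    for (bi in seq_along(starts)) {
      idx <- ord[starts[bi]:min(starts[bi] + config$batch_size - 1L, n)]
      Xb <- .stack_inputs(train$inputs, idx, S)
      y <- train$labels[idx]
      step <- withr::with_seed(derive_seed(session_seed, "batch", epoch, bi), {
        fw <- nn_forward(model, Xb, training = TRUE)
        ce <- cross_entropy(fw$probs, y)
        bk <- nn_backward(fw$model, fw$caches, ce$dlogits)
        list(fw = fw, ce = ce, grads = bk$grads)
      })
      if (!is.finite(step$ce$loss)) {
        cond <- structure(class = c("auscultnet_divergence", "error", "condition"),
                          list(message = sprintf("non-finite loss at epoch %d", epoch),
                               call = sys.call()))
        stop(cond)
      }
      model <- step$fw$model           # batch-norm running stats updated
      model$params <- radam_step(opt, model$params, step$grads, lr = lr)
      ep_loss <- ep_loss + step$ce$loss * length(idx)
      ep_correct <- ep_correct +
        sum((max.col(t(step$fw$probs), ties.method = "first") - 1L) == y)
    }
    vl <- .eval_loss(model, val, S, config$batch_size)
    hist <- rbind(hist, data.frame(
      epoch = epoch, lr = lr, train_loss = ep_loss / n, train_acc = ep_correct / n,
      val_loss = vl$loss, val_acc = vl$acc))
    if (verbose) {
      message(sprintf("epoch %3d lr=%.2e train loss %.4f acc %.3f | val loss %.4f acc %.3f",
                      epoch, lr, ep_loss / n, ep_correct / n, vl$loss, vl$acc))
    }
    if (vl$loss < best$loss) {
      best <- list(loss = vl$loss, params = model$params, bn = model$bn, epoch = epoch)
    }
  }
  model$params <- best$params
  model$bn <- best$bn
  list(model = model, history = hist, best_epoch = best$epoch)
}

.eval_loss <- function(model, part, S, batch_size = 50L) {
  n <- length(part$inputs)
  loss <- 0; correct <- 0
  for (s in seq(1L, n, by = batch_size)) {
    idx <- s:min(s + batch_size - 1L, n)
    Xb <- .stack_inputs(part$inputs, idx, S)
    fw <- nn_forward(model, Xb, training = FALSE, want_cache = FALSE)
    ce <- cross_entropy(fw$probs, part$labels[idx])
    loss <- loss + ce$loss * length(idx)
    correct <- correct +
      sum((max.col(t(fw$probs), ties.method = "first") - 1L) == part$labels[idx])
  }
  list(loss = loss / n, acc = correct / n)
}

#' Train an ensemble of independent sessions
#'
#' Runs `n_sessions` seeded sessions (seeds `seed + 1 .. seed + n`),
#' evaluates each on the test partition, and aggregates the evaluation
#' metrics as mean and standard deviation across sessions.  An alternative
#' reading that averages the predicted class probabilities across sessions
#' before evaluation is available via `aggregate = "probs"`.
#'
#' @param model_cfg A [model_config()].
#' @param splits List with `train`, `val`, `test`, each holding `inputs`
#'   and `labels`.
#' @param config A [train_config()].
#' @param aggregate `"metrics"` (default) or `"probs"`.
#' @param verbose Passed to [train_session()].
#' @return List with `models`, `session_reports` (one [eval_metrics()]
#'   report per session), `summary` (mean/sd data frame), and, for
#'   `aggregate = "probs"`, `prob_report`.
#' @export
train_ensemble <- function(model_cfg, splits, config, aggregate = c("metrics", "probs"),
                           verbose = FALSE) {
  aggregate <- match.arg(aggregate)
  if (config$n_sessions < 1) stop("n_sessions must be >= 1", call. = FALSE)
  models <- list(); reports <- list(); probs_acc <- NULL
  S <- prod(model_cfg$input_shape)
  for (si in seq_len(config$n_sessions)) {
    sess <- train_session(model_cfg, splits$train, splits$val, config,
                          session_seed = config$seed + si, verbose = verbose)
    models[[si]] <- sess$model
    pr <- predict(sess$model, splits$test$inputs)
    reports[[si]] <- eval_metrics(confusion_counts(splits$test$labels, pr$pred))
    if (aggregate == "probs") {
      probs_acc <- if (is.null(probs_acc)) pr$probs else probs_acc + pr$probs
    }
  }
  out <- list(models = models, session_reports = reports,
              summary = summarize_reports(reports))
  if (aggregate == "probs") {
    pm <- probs_acc / config$n_sessions
    pred <- max.col(t(pm), ties.method = "first") - 1L
    out$prob_report <- eval_metrics(confusion_counts(splits$test$labels, pred))
  }
  out
}

#' Aggregate evaluation reports as mean and standard deviation
#'
#' @param reports List of [eval_metrics()] reports.
#' @return Data frame with one row per summary metric (accuracy,
#'   sensitivity, specificity, precision, F1) and columns `mean`, `sd`.
#' @export
summarize_reports <- function(reports) {
  pull <- function(r) c(accuracy = r$overall_accuracy,
                        sensitivity = r$macro["sensitivity"],
                        specificity = r$macro["specificity"],
                        precision = r$macro["precision"],
                        f1 = r$macro["f1"])
  m <- t(vapply(reports, pull, numeric(5)))
  colnames(m) <- c("accuracy", "sensitivity", "specificity", "precision", "f1")
  data.frame(metric = colnames(m), mean = colMeans(m),
             sd = if (nrow(m) > 1) apply(m, 2, stats::sd) else rep(0, 5),
             row.names = NULL)
}
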