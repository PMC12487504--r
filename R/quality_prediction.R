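#' Sample same-quality session subgroups
#'
#' Subgroups stabilize HMM estimation: individual sessions are too short for
#' reliable per-session fits, so bundles of `size` sessions (sampled without
#' replacement within a subgroup, with replacement across subgroups) become
#' the unit of feature extraction and classification.
#'
#' @param pool an `mi_session_set` restricted to one quality, or a character
#'   vector of session ids.
#' @param quality quality label of the pool ("high" or "low"); inferred when
#'   `pool` is a session set of a single quality.
#' @param n_subgroups number of subgroups to draw.
#' @param size sessions per subgroup (default 7).
#' @param seed integer seed; sampling is deterministic given the seed.
#' @return list of `mi_subgroup` objects (`subgroup_id`, `quality`,
#'   `member_sessions`).
#' @export
make_subgroups <- function(pool, n_subgroups, size = 7L, seed = 1L,
                           quality = NULL) {
  if (inherits(pool, "mi_session_set")) {
    q <- unique(session_qualities(pool))
    if (length(q) != 1L) {
      stop_validation("pool must contain a single quality; got: %s",
                      paste(q, collapse = ", "))
    }
    quality <- q
    ids <- session_ids(pool)
  } else {
    ids <- as.character(pool)
    if (is.null(quality)) stop_validation("quality must be given with an id pool")
  }
  quality <- match.arg(quality, c("high", "low"))
  if (length(ids) < size) {
    stop_validation("subgroup size %d exceeds pool size %d", size, length(ids))
  }
  with_local_seed(derive_seed(seed, paste0("subgroups_", quality)), {
    lapply(seq_len(n_subgroups), function(g) {
      structure(list(
        subgroup_id = sprintf("%s_%02d", quality, g),
        quality = quality,
        member_sessions = sample(ids, size, replace = FALSE)),
        class = "mi_subgroup")
    })
  })
}

#' Transition-matrix features for one subgroup
#'
#' Fits a multi-sequence HMM on the subgroup's member sessions and flattens
#' the canonical labelled transition matrix row-major in (Towards Change,
#' Non-Determined, Away From Change) order into 9 features. Each consecutive
#' triple of features is a transition-matrix row and sums to 1.
#'
#' @param subgroup an `mi_subgroup`.
#' @param sessions the full `mi_session_set` holding the member sessions.
#' @param config an [hmm_config()].
#' @return a one-row `data.frame` (class `mi_feature_row`): `subgroup_id`,
#'   features `A11..A33`, `label`, `gradient_valid`.
#' @export
subgroup_features <- function(subgroup, sessions, config = hmm_config()) {
  stopifnot(inherits(subgroup, "mi_subgroup"),
            inherits(sessions, "mi_session_set"))
  ids <- session_ids(sessions)
  miss <- setdiff(subgroup$member_sessions, ids)
  if (length(miss)) {
    stop_validation("subgroup '%s': member session(s) not found: %s",
                    subgroup$subgroup_id, paste(miss, collapse = ", "))
  }
  seqs <- lapply(sessions$sessions[match(subgroup$member_sessions, ids)],
                 client_scores)
  fit <- tryCatch(fit_sequences_canonical(seqs, config), error = identity)
  feat_names <- as.vector(t(outer(1:3, 1:3,
                                  function(i, j) sprintf("A%d%d", i, j))))
  if (inherits(fit, "error")) {
    warning(sprintf("subgroup '%s': HMM fit failed (%s); flagged row",
                    subgroup$subgroup_id, conditionMessage(fit)),
            call. = FALSE)
    feats <- setNames(rep(NA_real_, 9), feat_names)
    gv <- FALSE
  } else {
    feats <- setNames(as.vector(t(fit$A)), feat_names)  # row-major
    gv <- fit$gradient_valid
  }
  row <- as.data.frame(as.list(feats))
  row <- cbind(data.frame(subgroup_id = subgroup$subgroup_id,
                          stringsAsFactors = FALSE),
               row,
               data.frame(label = subgroup$quality, gradient_valid = gv,
                          stringsAsFactors = FALSE))
  class(row) <- c("mi_feature_row", class(row))
  row
}

feature_cols <- function() {
  as.vector(t(outer(1:3, 1:3, function(i, j) sprintf("A%d%d", i, j))))
}

#' Leave-one-out predictions for a table of subgroup feature rows
#'
#' One deterministic LOOCV pass: for each fold the held-out subgroup's row is
#' removed, a binary ridge-regularized logistic regression is fitted on the
#' remaining rows, and the held-out probability of the low-quality class is
#' recorded. Training folds containing a single class are skipped with a
#' warning and counted.
#'
#' @param rows a `data.frame` of feature rows (rbind of [subgroup_features()]
#'   outputs). Rows with `gradient_valid = FALSE` or missing features are
#'   excluded with a warning.
#' @param ridge_c inverse regularization strength C (the glmnet lambda is
#'   `1 / (C * n_train)`); default 1.
#' @param standardize standardize features before fitting (default FALSE:
#'   transition probabilities are already commensurate).
#' @return `data.frame`: `subgroup_id`, `truth`, `prob_low`, `pred`, plus
#'   attribute `skipped_folds`.
#' @export
loocv_predict <- function(rows, ridge_c = 1, standardize = FALSE) {
  rows <- as.data.frame(rows)
  fc <- feature_cols()
  ok <- rows$gradient_valid & stats::complete.cases(rows[, fc])
  if (!all(ok)) {
    warning(sprintf("excluding %d flagged/incomplete feature row(s)",
                    sum(!ok)), call. = FALSE)
    rows <- rows[ok, , drop = FALSE]
  }
  if (length(unique(rows$label)) < 2L || min(table(rows$label)) < 2L) {
    stop_validation("need >= 2 feature rows per class")
  }
  if (anyDuplicated(rows$subgroup_id)) {
    stop_validation("duplicate subgroup_id in feature rows")
  }
  X <- as.matrix(rows[, fc])
  y <- factor(rows$label, levels = c("high", "low"))
  n <- nrow(rows)
  prob_low <- rep(NA_real_, n)
  skipped <- 0L
  for (i in seq_len(n)) {
    ytr <- y[-i]
    if (length(unique(ytr)) < 2L) {
      skipped <- skipped + 1L
      warning("single-class training fold skipped", call. = FALSE)
      next
    }
    lambda <- 1 / (ridge_c * (n - 1))
    fit <- withCallingHandlers(
      glmnet::glmnet(X[-i, , drop = FALSE], ytr, family = "binomial",
                     alpha = 0, lambda = lambda, standardize = standardize),
      # small LOOCV folds routinely trip glmnet's class-size caution; the
      # subgroup designs here are intentionally small
      warning = function(w) {
        if (grepl("fewer than 8", conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      })
    prob_low[i] <- as.numeric(predict(fit, X[i, , drop = FALSE],
                                      type = "response"))
  }
  out <- data.frame(subgroup_id = rows$subgroup_id,
                    truth = as.character(y),
                    prob_low = prob_low,
                    pred = ifelse(prob_low >= 0.5, "low", "high"),
                    stringsAsFactors = FALSE)
  attr(out, "skipped_folds") <- skipped
  out
}

#' ROC AUC by the rank (Mann-Whitney) statistic
#'
#' Equals the trapezoidal area under the ROC curve; ties in the scores are
#' handled with mean ranks, so an all-constant score vector gives 0.5.
#'
#' @param truth character vector of class labels.
#' @param prob numeric score for the positive class.
#' @param positive which label counts as positive (default "low").
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(truth, prob, positive = "low") {
  pos <- truth == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(prob)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metric bundle
#'
#' Accuracy, rank-statistic ROC AUC, per-class precision / recall
#' (sensitivity) / specificity / F1 (harmonic mean of precision and recall),
#' and a row-normalized 2x2 confusion matrix. A class with no predicted
#' positives gets precision 0 with `undefined_precision` flagging it.
#'
#' @param truth,pred aligned character label vectors.
#' @param prob_positive numeric probability of the positive class (for AUC);
#'   optional.
#' @param classes the two class labels, `c(negative, positive)` order for the
#'   confusion matrix rows/cols.
#' @param positive label treated as positive for AUC.
#' @return list of class `mi_metrics`.
#' @export
compute_metrics <- function(truth, pred, prob_positive = NULL,
                            classes = c("high", "low"), positive = "low") {
  if (length(truth) == 0L || length(truth) != length(pred)) {
    stop_validation("truth and pred must be aligned non-empty vectors")
  }
  truth <- as.character(truth); pred <- as.character(pred)
  acc <- mean(truth == pred)
  per_class <- lapply(classes, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    undef_p <- (tp + fp) == 0L
    precision <- if (undef_p) 0 else tp / (tp + fp)
    recall <- if ((tp + fn) == 0L) NA_real_ else tp / (tp + fn)
    specificity <- if ((tn + fp) == 0L) NA_real_ else tn / (tn + fp)
    f1 <- if ((precision + recall) == 0 || is.na(recall)) 0 else {
      2 * precision * recall / (precision + recall)
    }
    list(precision = precision, recall_sensitivity = recall,
         specificity = specificity, f1 = f1,
         undefined_precision = undef_p)
  })
  names(per_class) <- classes
  conf <- table(factor(truth, levels = classes),
                factor(pred, levels = classes))
  conf_prop <- prop.table(conf + 0, margin = 1)
  conf_prop[is.nan(conf_prop)] <- 0
  auc <- if (is.null(prob_positive)) NA_real_ else {
    roc_auc(truth, prob_positive, positive)
  }
  structure(list(accuracy = acc, roc_auc = auc, per_class = per_class,
                 confusion_matrix = as.matrix(conf_prop),
                 confusion_counts = as.matrix(conf),
                 n = length(truth), positive = positive),
            class = "mi_metrics")
}

metrics_to_row <- function(m) {
  pc <- m$per_class
  row <- c(accuracy = m$accuracy, roc_auc = m$roc_auc)
  for (cl in names(pc)) {
    v <- pc[[cl]]
    row <- c(row, setNames(
      c(v$precision, v$recall_sensitivity, v$specificity, v$f1),
      paste0(cl, "_", c("precision", "recall", "specificity", "f1"))))
  }
  row
}

#' Subgroup-level LOOCV quality classification
#'
#' The full quality-prediction experiment: per iteration, subgroups are
#' freshly resampled from each quality pool (so the iteration-to-iteration
#' variability reported as mean +- SD comes from subgroup composition), each
#' subgroup's transition-matrix features are extracted, and a
#' leave-one-subgroup-out logistic regression produces held-out class
#' probabilities that are pooled into one metric bundle per iteration.
#'
#' @param sessions an `mi_session_set` with high- and low-quality sessions.
#' @param config [hmm_config()] for subgroup fits.
#' @param design "balanced" (equal subgroup counts per class) or
#'   "imbalanced_3to1" (3:1 high:low subgroup counts, mirroring a 30/10
#'   session pool).
#' @param n_subgroups subgroups per class in the balanced design (default
#'   30); the imbalanced design uses `c(n_subgroups, n_subgroups / 3)`.
#' @param size sessions per subgroup (default 7).
#' @param n_iterations repeated resampling + LOOCV iterations (default 10).
#' @param seed integer seed.
#' @param ridge_c,standardize passed to [loocv_predict()].
#' @param permute_labels if TRUE, subgroup labels are randomly permuted
#'   relative to the features in every iteration (chance-level control).
#' @return object of class `mi_classification_report`: `per_iteration`
#'   (data.frame of metric rows), `mean`, `sd`, `confusion_matrix` (mean of
#'   row-normalized matrices), `held_out` (per-iteration prediction tables),
#'   `skipped_folds`, `design`, `seeds`.
#' @export
loocv_classify <- function(sessions, config = hmm_config(),
                           design = c("balanced", "imbalanced_3to1"),
                           n_subgroups = 30L, size = 7L, n_iterations = 10L,
                           seed = 1L, ridge_c = 1, standardize = FALSE,
                           permute_labels = FALSE) {
  stopifnot(inherits(sessions, "mi_session_set"))
  design <- match.arg(design)
  n_high_sub <- as.integer(n_subgroups)
  n_low_sub <- if (design == "balanced") n_high_sub else {
    max(1L, as.integer(round(n_subgroups / 3)))
  }
  high_pool <- filter_quality(sessions, "high")
  low_pool <- filter_quality(sessions, "low")

  per_iter <- list()
  held_out <- list()
  confs <- list()
  skipped <- 0L
  seeds <- integer(n_iterations)
  for (it in seq_len(n_iterations)) {
    it_seed <- derive_seed(seed, paste0("loocv_iter_", it))
    seeds[it] <- it_seed
    sg <- c(make_subgroups(high_pool, n_high_sub, size, seed = it_seed),
            make_subgroups(low_pool, n_low_sub, size, seed = it_seed))
    rows <- do.call(rbind, lapply(sg, subgroup_features,
                                  sessions = sessions, config = config))
    if (permute_labels) {
      rows$label <- with_local_seed(derive_seed(it_seed, "permute_labels"),
                                    sample(rows$label))
    }
    preds <- loocv_predict(rows, ridge_c = ridge_c,
                           standardize = standardize)
    skipped <- skipped + attr(preds, "skipped_folds")
    done <- !is.na(preds$prob_low)
    m <- compute_metrics(preds$truth[done], preds$pred[done],
                         preds$prob_low[done])
    per_iter[[it]] <- metrics_to_row(m)
    confs[[it]] <- m$confusion_matrix
    held_out[[it]] <- preds
  }
  per_iter <- as.data.frame(do.call(rbind, per_iter))
  structure(list(
    per_iteration = per_iter,
    mean = colMeans(per_iter),
    sd = apply(per_iter, 2, sd),
    confusion_matrix = Reduce(`+`, confs) / length(confs),
    held_out = held_out,
    skipped_folds = skipped,
    design = design,
    n_subgroups = c(high = n_high_sub, low = n_low_sub),
    size = as.integer(size),
    n_iterations = as.integer(n_iterations),
    seeds = seeds,
    permuted_labels = isTRUE(permute_labels)),
    class = "mi_classification_report")
}

#' @export
print.mi_classification_report <- function(x, ...) {
  cat(sprintf("<mi_classification_report> %s design, %d+%d subgroups of %d, %d iterations%s\n",
              x$design, x$n_subgroups["high"], x$n_subgroups["low"], x$size,
              x$n_iterations,
              if (x$permuted_labels) " (labels permuted)" else ""))
  cat(sprintf("  accuracy %.3f +- %.3f, ROC AUC %.3f +- %.3f\n",
              x$mean["accuracy"], x$sd["accuracy"],
              x$mean["roc_auc"], x$sd["roc_auc"]))
  cat("  mean row-normalized confusion matrix (rows = truth):\n")
  print(round(x$confusion_matrix, 3))
  invisible(x)
}
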