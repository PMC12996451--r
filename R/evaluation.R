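# Evaluation machinery: per-class ROC/AUC, DeLong's paired AUC test,
# confusion matrices and group-wise (confounder) metrics.

#' ROC curve and AUC
#'
#' AUC is the tie-corrected Mann-Whitney statistic (ties credit 1/2),
#' computed from midranks; the curve is a threshold sweep over the unique
#' scores, from (0, 0) to (1, 1).
#'
#' @param labels binary 0/1 vector (1 = positive).
#' @param scores numeric scores, higher = more positive.
#' @return object of class "roc_curve": thresholds, fpr, tpr, auc.
#' @export
roc_auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  labels <- as.integer(labels)
  n1 <- sum(labels == 1); n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0)
    stop("degenerate input: both classes must be present", call. = FALSE)
  r <- rank(scores)   # midranks
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
  thr <- sort(unique(scores), decreasing = TRUE)
  tpr <- fpr <- numeric(length(thr))
  for (k in seq_along(thr)) {
    tpr[k] <- sum(scores >= thr[k] & labels == 1) / n1
    fpr[k] <- sum(scores >= thr[k] & labels == 0) / n0
  }
  structure(list(thresholds = c(Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr),
                 auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("roc_curve: AUC = %.4f over %d thresholds\n",
              x$auc, length(x$thresholds)))
  invisible(x)
}

# midrank-based structural components (one score vector):
# V10[i] = fraction of negatives scored below positive i (ties 1/2), V01
# symmetric.
delong_components <- function(labels, scores) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  m <- length(pos); n <- length(neg)
  r_all <- rank(c(pos, neg))
  r_pos <- rank(pos); r_neg <- rank(neg)
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(v10 = v10, v01 = v01, auc = mean(v10))
}

#' DeLong's test for two correlated AUCs
#'
#' Fast midrank formulation: the covariance of the paired AUC estimates is
#' assembled from the structural components of both score vectors on the
#' same items; the two-sided p-value uses the normal approximation (no
#' continuity correction).
#'
#' @param labels shared binary truth vector.
#' @param scores_a,scores_b paired score vectors on the same items.
#' @return list(auc_a, auc_b, z, p, var_diff, cov).
#' @export
delong_test <- function(labels, scores_a, scores_b) {
  stopifnot(length(labels) == length(scores_a),
            length(labels) == length(scores_b))
  ca <- delong_components(labels, scores_a)
  cb <- delong_components(labels, scores_b)
  m <- length(ca$v10); n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  S <- s10 / m + s01 / n
  v <- S[1, 1] + S[2, 2] - 2 * S[1, 2]
  d <- ca$auc - cb$auc
  if (v <= .Machine$double.eps) {
    z <- 0
    p <- if (abs(d) < 1e-15) 1 else .Machine$double.xmin
    if (abs(d) >= 1e-15) z <- sign(d) * Inf
  } else {
    z <- d / sqrt(v)
    p <- 2 * stats::pnorm(-abs(z))
  }
  list(auc_a = ca$auc, auc_b = cb$auc, z = z, p = p, var_diff = v, cov = S)
}

#' Confusion matrix, accuracies and per-class AUCs
#'
#' @param records data.frame with columns p_epithelium, p_stroma,
#'   p_adipocyte, pred (0/1/2) and truth (0/1/2), e.g. the output of
#'   \code{predict_probs} with a truth column added.
#' @return object of class "metrics_table": 3 x 3 confusion matrix (rows =
#'   truth), per-class accuracy (diagonal / row sum), per-class
#'   one-vs-rest AUC (using that class's probability as score; NA when a
#'   class is absent), and overall accuracy.
#' @export
confusion_and_accuracy <- function(records) {
  if (!nrow(records)) stop("empty input", call. = FALSE)
  stopifnot(all(records$truth %in% 0:2), all(records$pred %in% 0:2))
  conf <- matrix(0L, 3, 3, dimnames = list(truth = CLASS_NAMES, pred = CLASS_NAMES))
  for (k in seq_len(nrow(records)))
    conf[records$truth[k] + 1L, records$pred[k] + 1L] <-
      conf[records$truth[k] + 1L, records$pred[k] + 1L] + 1L
  rs <- rowSums(conf)
  class_acc <- ifelse(rs > 0, diag(conf) / rs, NA_real_)
  prob_cols <- c("p_epithelium", "p_stroma", "p_adipocyte")
  class_auc <- rep(NA_real_, 3)
  for (cl in 0:2) {
    y <- as.integer(records$truth == cl)
    if (length(unique(y)) == 2)
      class_auc[cl + 1] <- roc_auc(y, records[[prob_cols[cl + 1]]])$auc
  }
  structure(list(confusion = conf,
                 class_accuracy = stats::setNames(class_acc, CLASS_NAMES),
                 class_auc = stats::setNames(class_auc, CLASS_NAMES),
                 overall_accuracy = sum(diag(conf)) / sum(conf),
                 n = nrow(records)),
            class = "metrics_table")
}

#' @export
print.metrics_table <- function(x, ...) {
  cat(sprintf("metrics_table: n = %d, overall accuracy %.4f\n", x$n, x$overall_accuracy))
  print(x$confusion)
  cat("class accuracy:", sprintf("%.4f", x$class_accuracy), "\n")
  cat("class AUC:     ", sprintf("%.4f", x$class_auc), "\n")
  invisible(x)
}

#' Group-wise (confounder) metrics
#'
#' Computes a metrics_table independently per group (e.g. age band or
#' tissue source). Optional class-capped resampling mirrors the repeat
#' sampling protocol: per repetition, up to n_per_class records per class
#' (per source when a `source` column is present) are drawn by seeded
#' sampling without replacement.
#'
#' @param records as for \code{confusion_and_accuracy}, plus columns used
#'   by `groups`/`source`.
#' @param groups vector of group keys, one per record.
#' @param n_per_class optional per-class (per-source) cap.
#' @param repeats number of resampling repetitions (1 when uncapped).
#' @param seed integer seed.
#' @return named list: per group, a metrics_table (or a list of them when
#'   repeats > 1). Empty groups are dropped with a warning.
#' @export
group_metrics <- function(records, groups, n_per_class = NULL, repeats = 1, seed = 1) {
  stopifnot(length(groups) == nrow(records))
  out <- list()
  for (g in sort(unique(as.character(groups)))) {
    sub <- records[as.character(groups) == g, , drop = FALSE]
    if (!nrow(sub)) { warning("empty group ", g, " omitted", call. = FALSE); next }
    if (is.null(n_per_class)) {
      out[[g]] <- confusion_and_accuracy(sub)
    } else {
      reps <- lapply(seq_len(repeats), function(rep_i) {
        keep <- integer(0)
        strata <- if ("source" %in% names(sub))
          paste(sub$source, sub$truth) else as.character(sub$truth)
        for (st in sort(unique(strata))) {
          idx <- which(strata == st)
          take <- min(length(idx), n_per_class)
          keep <- c(keep, with_seed(sub_seed(seed, rep_i * 1000 +
                     which(sort(unique(strata)) == st)), sample(idx, take)))
        }
        confusion_and_accuracy(sub[sort(keep), , drop = FALSE])
      })
      out[[g]] <- if (repeats == 1) reps[[1]] else reps
    }
  }
  out
}

#' Write a metrics table as CSV
#' @param metrics a metrics_table.
#' @param path output CSV.
#' @export
write_metrics_csv <- function(metrics, path) {
  df <- data.frame(class = CLASS_NAMES,
                   accuracy = as.numeric(metrics$class_accuracy),
                   auc = as.numeric(metrics$class_auc),
                   support = rowSums(metrics$confusion))
  df$overall_accuracy <- metrics$overall_accuracy
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
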