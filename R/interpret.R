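# Post-hoc analysis: impurity-based feature importance, feature
# correlations, per-stress-level group statistics, time-in-level summaries,
# and emergency-segment validation.

#' Mean-decrease-in-impurity feature importance
#'
#' For a tree ensemble, the importance of feature f is
#' `I(f) = (1/T) * sum over trees of sum over nodes splitting on f of di(n)`
#' where `di(n)` is the impurity decrease at node n, weighted by the
#' fraction of (in-bag) samples reaching the node; the raw scores are then
#' normalized to sum to one. For the random forest the per-node Gini
#' decreases are recomputed here by routing the stored training samples
#' (with their bootstrap multiplicities) through every tree; for gradient
#' boosting the per-node loss reductions recorded in the booster dump are
#' accumulated with the same equation.
#'
#' @param model A fitted `sw_rf` or `sw_gb` model.
#' @return An `importance_table`: data frame of features and normalized
#'   importances (non-negative, summing to 1), sorted decreasing.
#' @export
mdi_importance <- function(model) {
  if (!inherits(model, "sw_model"))
    sw_abort("mdi_importance needs a fitted sw_model", "sw_unsupported_model_error")
  raw <- switch(model$kind,
    RF = rf_node_importance(model),
    GB = gb_node_importance(model),
    sw_abort(sprintf("MDI importance is defined for tree ensembles, not %s",
                     model$kind), "sw_unsupported_model_error")
  )
  if (sum(raw) <= 0)
    sw_abort("ensemble contains no splits; importance undefined",
             "sw_unsupported_model_error")
  imp <- raw / sum(raw)
  out <- data.frame(feature = names(imp), importance = unname(imp))
  out <- out[order(-out$importance), ]
  rownames(out) <- NULL
  structure(out, class = c("importance_table", "data.frame"))
}

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# Route the training samples (bootstrap multiplicities from keep.inbag)
# through each ranger tree, accumulating the weighted Gini decrease of every
# split node onto its split feature.
rf_node_importance <- function(model) {
  rf <- model$fit
  X <- model$X
  yf <- factor(model$y, levels = model$classes)
  p <- ncol(X)
  imp <- stats::setNames(numeric(p), colnames(X))
  for (t in seq_len(rf$num.trees)) {
    ti <- ranger::treeInfo(rf, t)
    wts <- as.numeric(rf$inbag.counts[[t]])
    N <- sum(wts)
    members <- vector("list", nrow(ti))
    members[[1L]] <- which(wts > 0)
    for (r in seq_len(nrow(ti))) {
      if (ti$terminal[r]) next
      idx <- members[[ti$nodeID[r] + 1L]]
      if (length(idx) == 0L) next
      v <- X[idx, ti$splitvarID[r] + 1L]
      left <- idx[v <= ti$splitval[r]]
      right <- idx[v > ti$splitval[r]]
      members[[ti$leftChild[r] + 1L]] <- left
      members[[ti$rightChild[r] + 1L]] <- right
      cnt <- function(s) tapply(wts[s], yf[s], sum, default = 0)
      c_n <- cnt(idx); c_l <- cnt(left); c_r <- cnt(right)
      n_n <- sum(c_n); n_l <- sum(c_l); n_r <- sum(c_r)
      di <- (n_n / N) * (gini_impurity(c_n) -
                           (n_l / n_n) * gini_impurity(c_l) -
                           (n_r / n_n) * gini_impurity(c_r))
      fname <- colnames(X)[ti$splitvarID[r] + 1L]
      imp[fname] <- imp[fname] + di
    }
  }
  imp / rf$num.trees
}

# Sum the recorded gain of every split node per feature across all boosted
# trees (the booster's split criterion plays the role of the impurity).
gb_node_importance <- function(model) {
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = model$fit$booster))
  gain_col <- if ("Gain" %in% names(dump)) "Gain" else "Quality"
  splits <- dump[dump$Feature != "Leaf", , drop = FALSE]
  imp <- stats::setNames(numeric(length(model$feature_names)), model$feature_names)
  agg <- tapply(splits[[gain_col]], splits$Feature, sum)
  agg <- agg[names(agg) %in% names(imp)]
  imp[names(agg)] <- agg
  n_trees <- length(unique(dump$Tree))
  imp / max(n_trees, 1L)
}

#' @export
print.importance_table <- function(x, ...) {
  cat(sprintf("<importance_table> %d features (sums to %.6f); top 5:\n",
              nrow(x), sum(x$importance)))
  print.data.frame(utils::head(x, 5), row.names = FALSE)
  invisible(x)
}

#' Pearson correlation matrix of feature columns
#'
#' Constant columns have undefined correlations and are excluded with a
#' warning.
#'
#' @param table Feature table with at least 2 rows.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
feature_correlations <- function(table) {
  cols <- feature_columns(table)
  if (nrow(table) < 2L)
    sw_abort("need at least 2 rows for correlations", "sw_insufficient_data_error")
  M <- as.matrix(table[cols])
  sds <- apply(M, 2L, stats::sd)
  if (any(sds == 0)) {
    warning(sprintf("excluding constant column(s): %s",
                    paste(cols[sds == 0], collapse = ", ")))
    M <- M[, sds > 0, drop = FALSE]
  }
  stats::cor(M)
}

#' Per-stress-level means and level-vs-baseline t-tests
#'
#' For each channel mean (HR_Mean, TEMP_Mean, EDA_Mean) and each comparison
#' (level 1 vs 0, level 2 vs 0), computes the two-sample Welch t-statistic
#' and two-sided p-value (direction: level minus baseline), or optionally a
#' subject-paired t-test on per-subject level means. Also returns the
#' per-level mean table.
#'
#' @param features Feature table containing the channel mean columns.
#' @param labels Integer stress classes per row.
#' @param paired If `TRUE`, pair per-subject level means (requires
#'   `subject_id`); default `FALSE` (Welch).
#' @param subject_id Per-row subject ids (needed for the paired variant).
#' @param alpha Significance threshold for the flag column (default 0.001).
#' @return A `level_tests` object: `means` (metric x level) and `tests`
#'   (comparison, metric, t, p, significant).
#' @export
level_comparison_tests <- function(features, labels, paired = FALSE,
                                   subject_id = NULL, alpha = 0.001) {
  metrics <- intersect(c("HR_Mean", "TEMP_Mean", "EDA_Mean"), names(features))
  if (length(metrics) == 0L)
    sw_abort("features lack the channel mean columns", "sw_schema_error")
  levels_present <- sort(unique(labels))
  means <- sapply(0:2, function(lv) {
    vapply(metrics, function(m) {
      if (any(labels == lv)) mean(features[[m]][labels == lv]) else NA_real_
    }, numeric(1))
  })
  colnames(means) <- paste0("level", 0:2)
  tests <- data.frame(comparison = character(0), metric = character(0),
                      t = numeric(0), p = numeric(0), significant = logical(0))
  for (lv in c(1L, 2L)) {
    for (m in metrics) {
      if (paired) {
        if (is.null(subject_id))
          sw_abort("paired tests need subject_id", "sw_validation_error")
        ag <- stats::aggregate(features[[m]],
                               list(subject = subject_id, level = labels), mean)
        a <- ag[ag$level == lv, ]
        b <- ag[ag$level == 0L, ]
        common <- intersect(a$subject, b$subject)
        x <- a$x[match(common, a$subject)]
        y <- b$x[match(common, b$subject)]
        if (length(common) < 2L)
          sw_abort(sprintf("fewer than 2 subjects have both level %d and level 0", lv),
                   "sw_degenerate_group_error")
        tt <- stats::t.test(x, y, paired = TRUE)
      } else {
        x <- features[[m]][labels == lv]
        y <- features[[m]][labels == 0L]
        if (length(x) < 2L || length(y) < 2L)
          sw_abort(sprintf("level %d vs 0 (%s): a group has fewer than 2 observations",
                           lv, m), "sw_degenerate_group_error")
        tt <- stats::t.test(x, y, var.equal = FALSE)
      }
      tests <- rbind(tests, data.frame(
        comparison = sprintf("Stress Level %d vs. Stress Level 0", lv),
        metric = m, t = unname(tt$statistic), p = tt$p.value,
        significant = tt$p.value < alpha
      ))
    }
  }
  structure(list(means = means, tests = tests, alpha = alpha,
                 paired = paired), class = "level_tests")
}

#' @export
print.level_tests <- function(x, ...) {
  cat("Per-level means:\n")
  print(round(x$means, 4))
  cat(sprintf("\n%s t-tests (alpha = %g):\n",
              if (x$paired) "Subject-paired" else "Welch two-sample", x$alpha))
  df <- x$tests
  df$t <- sprintf("%.4f", df$t)
  df$p <- format(df$p, digits = 3)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Time spent in each stress level per subject
#'
#' Per-subject fractions of windows at each class, with a high-stress flag
#' when strictly more than `flag_threshold` of the windows are class 2.
#'
#' @param labels Integer stress classes per window.
#' @param subject_id Subject id per window.
#' @param success Optional named logical vector (or per-window vector) of
#'   treatment-success flags.
#' @param flag_threshold Flag when the class-2 fraction exceeds this
#'   (strict; default 0.25).
#' @return A `level_summary` data frame: subject, fractions `f0 f1 f2`,
#'   `flag_high_stress`, optional `success`; a `crosstab` attribute holds
#'   the flag-by-success table when success is supplied.
#' @export
time_in_levels <- function(labels, subject_id, success = NULL,
                           flag_threshold = 0.25) {
  subjects <- unique(subject_id)
  rows <- lapply(subjects, function(s) {
    l <- labels[subject_id == s]
    if (length(l) == 0L)
      sw_abort(sprintf("subject %s has no labeled windows", s), "sw_coverage_error")
    f <- as.numeric(table(factor(l, levels = 0:2))) / length(l)
    data.frame(subject = s, f0 = f[1L], f1 = f[2L], f2 = f[3L],
               flag_high_stress = f[3L] > flag_threshold)
  })
  out <- do.call(rbind, rows)
  if (!is.null(success)) {
    out$success <- if (!is.null(names(success))) unname(success[out$subject])
                   else vapply(subjects, function(s)
                     success[which(subject_id == s)[1L]], logical(1))
    attr(out, "crosstab") <- table(flag = out$flag_high_stress,
                                   success = out$success)
  }
  class(out) <- c("level_summary", "data.frame")
  out
}

#' Validate that the emergency segment is classified as elevated stress
#'
#' A subject passes when at least `threshold` (default 50%) of its windows
#' in the emergency segment carry class 1 or 2.
#'
#' @param labels Integer stress classes per window.
#' @param segment_id Scenario segment per window (1-based).
#' @param subject_id Subject per window.
#' @param emergency_segment Which segment holds the emergency (default 4).
#' @param threshold Minimum fraction of elevated windows to pass.
#' @return Data frame (subject, n_windows, frac_elevated, pass) with a
#'   `summary` attribute counting passing subjects.
#' @export
segment_validation <- function(labels, segment_id, subject_id,
                               emergency_segment = 4L, threshold = 0.5) {
  subjects <- unique(subject_id)
  rows <- lapply(subjects, function(s) {
    sel <- subject_id == s & segment_id == emergency_segment
    if (!any(sel))
      sw_abort(sprintf("subject %s has no windows in segment %d", s,
                       emergency_segment), "sw_coverage_error")
    frac <- mean(labels[sel] >= 1L)
    data.frame(subject = s, n_windows = sum(sel), frac_elevated = frac,
               pass = frac >= threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "summary") <- c(n_pass = sum(out$pass), n_subjects = nrow(out))
  out
}
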