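check_two_classes <- function(scores, labels) {
  if (length(scores) != length(labels)) {
    stop("scores and labels differ in length", call. = FALSE)
  }
  keep <- !is.na(scores) & !is.na(labels)
  y <- as.numeric(labels[keep]); s <- as.numeric(scores[keep])
  if (!any(y == 1) || !any(y == 0)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  list(scores = s, labels = y)
}

#' Empirical ROC curve
#'
#' One operating point per distinct score threshold (predicted positive
#' when `score >= threshold`) plus the two sentinel points (Se, Sp) =
#' (1, 0) and (0, 1).
#'
#' @param scores Per-sample numeric scores (higher = more case-like).
#' @param labels Case indicators (logical or 0/1).
#' @return A tibble of class `roc_curve` with columns `threshold`,
#'   `sensitivity`, `specificity`.
#' @export
roc_curve <- function(scores, labels) {
  d <- check_two_classes(scores, labels)
  thr <- sort(unique(d$scores))
  n_case <- sum(d$labels == 1); n_ctrl <- sum(d$labels == 0)
  pts <- purrr::map_dfr(thr, function(t) {
    pos <- d$scores >= t
    tibble::tibble(
      threshold = t,
      sensitivity = sum(pos & d$labels == 1) / n_case,
      specificity = sum(!pos & d$labels == 0) / n_ctrl
    )
  })
  out <- dplyr::bind_rows(
    tibble::tibble(threshold = -Inf, sensitivity = 1, specificity = 0),
    pts,
    tibble::tibble(threshold = Inf, sensitivity = 0, specificity = 1)
  )
  class(out) <- c("roc_curve", class(out))
  out
}

#' Plot an ROC curve
#' @param object A [roc_curve()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.roc_curve <- function(object, ...) {
  df <- dplyr::arrange(tibble::as_tibble(object), .data$threshold)
  ggplot2::ggplot(df, ggplot2::aes(x = 1 - .data$specificity,
                                   y = .data$sensitivity)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "Sensitivity") +
    ggplot2::theme_minimal()
}

# DeLong structural components: per-case and per-control placement values
delong_components <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  m <- length(x); n <- length(y)
  psi <- outer(x, y, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = 1 - colMeans(psi),
       auc = mean(psi), m = m, n = n)
}

#' AUC by Mann-Whitney pair counting with DeLong standard error
#'
#' The AUC equals the probability that a random case outscores a random
#' control, ties counting one half; the standard error comes from the
#' variance of the DeLong structural components.
#'
#' @inheritParams roc_curve
#' @return A one-row tibble: `auc`, `se`, `n_case`, `n_control`.
#' @export
auc_mann_whitney <- function(scores, labels) {
  d <- check_two_classes(scores, labels)
  cmp <- delong_components(d$scores, d$labels)
  s10 <- if (cmp$m > 1) stats::var(cmp$v10) else 0
  s01 <- if (cmp$n > 1) stats::var(cmp$v01) else 0
  tibble::tibble(
    auc = cmp$auc,
    se = sqrt(s10 / cmp$m + s01 / cmp$n),
    n_case = cmp$m, n_control = cmp$n
  )
}

#' Paired DeLong comparison of two correlated AUCs
#'
#' Both score vectors must be computed on the same samples. Returns the
#' DeLong z statistic for `auc_a - auc_b` and its two-sided p-value; a
#' degenerate (zero) variance of the difference yields `z = 0`, `p = 1`.
#'
#' @param scores_a,scores_b Per-sample score vectors.
#' @inheritParams roc_curve
#' @return A one-row tibble: `auc_a`, `auc_b`, `delta_auc`, `z`, `p`.
#' @export
compare_paired_auc <- function(scores_a, scores_b, labels) {
  if (length(scores_a) != length(scores_b)) {
    stop("paired score vectors differ in length", call. = FALSE)
  }
  keep <- !is.na(scores_a) & !is.na(scores_b) & !is.na(labels)
  y <- as.numeric(labels[keep])
  if (!any(y == 1) || !any(y == 0)) {
    stop("need at least one case and one control", call. = FALSE)
  }
  ca <- delong_components(as.numeric(scores_a[keep]), y)
  cb <- delong_components(as.numeric(scores_b[keep]), y)
  m <- ca$m; n <- ca$n
  # 2x2 covariance of (auc_a, auc_b) from the component vectors
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  s <- s10 / m + s01 / n
  v <- s[1, 1] + s[2, 2] - 2 * s[1, 2]
  delta <- ca$auc - cb$auc
  z <- if (v <= .Machine$double.eps) 0 else delta / sqrt(v)
  tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, delta_auc = delta,
                 z = z, p = if (z == 0) 1 else wald_pvalue(z))
}

#' Confusion-matrix metrics at a score threshold
#'
#' Predicted positive when `score >= threshold`. Ratios with empty
#' denominators (e.g. PVP with no predicted positives) are `NA`.
#'
#' @inheritParams roc_curve
#' @param threshold Decision threshold.
#' @return A one-row tibble: `threshold`, `tp`, `fp`, `tn`, `fn`,
#'   `sensitivity`, `specificity`, `pvp`, `pvn`, `percent_correct`.
#' @export
classification_metrics <- function(scores, labels, threshold) {
  d <- check_two_classes(scores, labels)
  pos <- d$scores >= threshold
  tp <- sum(pos & d$labels == 1); fp <- sum(pos & d$labels == 0)
  fn <- sum(!pos & d$labels == 1); tn <- sum(!pos & d$labels == 0)
  ratio <- function(a, b) if (b == 0) NA_real_ else a / b
  tibble::tibble(
    threshold = threshold, tp = tp, fp = fp, tn = tn, fn = fn,
    sensitivity = ratio(tp, tp + fn), specificity = ratio(tn, tn + fp),
    pvp = ratio(tp, tp + fp), pvn = ratio(tn, tn + fn),
    percent_correct = (tp + tn) / length(d$scores)
  )
}

#' Sensitivity/specificity sweep over all thresholds
#'
#' @inheritParams roc_curve
#' @return A tibble with one [classification_metrics()] row per distinct
#'   score value.
#' @export
classification_sweep <- function(scores, labels) {
  d <- check_two_classes(scores, labels)
  purrr::map_dfr(sort(unique(d$scores)),
                 function(t) classification_metrics(d$scores, d$labels, t))
}

#' Select the optimal score set from an AUC sequence
#'
#' Walks the per-set AUC sequence in order and selects the first set
#' followed by two consecutive AUC decreases; if the sequence never
#' triggers the rule, the set with the maximum AUC is selected
#' (first maximum on ties). `rule = "literal"` instead selects the first
#' i with `auc[i] > auc[i+1]` and `auc[i] > auc[i+2]`.
#'
#' @param auc Numeric vector of per-set AUCs in set order (set 1 = one
#'   marker, set 2 = two markers, ...).
#' @param rule `"consecutive"` (default, two successive decreases) or
#'   `"literal"`.
#' @return The 1-based index (= marker count) of the selected set.
#' @export
select_optimal_set <- function(auc, rule = c("consecutive", "literal")) {
  rule <- match.arg(rule)
  stopifnot(length(auc) >= 1, !anyNA(auc))
  n <- length(auc)
  if (n >= 3) {
    for (i in seq_len(n - 2)) {
      hit <- if (rule == "consecutive") {
        auc[i + 1] < auc[i] && auc[i + 2] < auc[i + 1]
      } else {
        auc[i] > auc[i + 1] && auc[i] > auc[i + 2]
      }
      if (hit) return(i)
    }
  }
  which.max(auc)
}

#' Evaluate a ladder of nested score sets
#'
#' Scores every set on the given genotypes and labels, computes AUC with
#' DeLong SE, the paired DeLong p against the first (single-marker) set
#' and against the previous set, and the AUC increment.
#'
#' @param sets List of `score_set`s from [build_nested_score_sets()].
#' @param g A [genotype_matrix()].
#' @param labels Per-sample case indicators aligned with `sample_ids(g)`.
#' @return A tibble of class `score_set_evaluation`: `label`,
#'   `n_markers`, `auc`, `se`, `p_vs_first`, `p_vs_prev`, `delta_auc`
#'   (0 with `first = TRUE` flag for the first set), `n_case`,
#'   `n_control`.
#' @export
evaluate_score_sets <- function(sets, g, labels) {
  stopifnot(length(sets) >= 1)
  score_list <- purrr::map(sets, function(s) compute_sample_scores(s, g)$score)
  out <- purrr::map_dfr(seq_along(sets), function(k) {
    a <- auc_mann_whitney(score_list[[k]], labels)
    first <- k == 1
    p_first <- if (first) NA_real_ else {
      compare_paired_auc(score_list[[k]], score_list[[1]], labels)$p
    }
    p_prev <- if (first) NA_real_ else {
      compare_paired_auc(score_list[[k]], score_list[[k - 1]], labels)$p
    }
    tibble::tibble(
      label = sets[[k]]$label, n_markers = nrow(sets[[k]]$markers),
      auc = a$auc, se = a$se,
      p_vs_first = p_first, p_vs_prev = p_prev,
      delta_auc = NA_real_, first = first,
      n_case = a$n_case, n_control = a$n_control
    )
  })
  out$delta_auc <- c(0, diff(out$auc))
  class(out) <- c("score_set_evaluation", class(out))
  out
}

#' Plot per-set AUC values and increments
#' @param object A [evaluate_score_sets()] tibble.
#' @param ... Unused.
#' @return A ggplot of AUC by set with the increment overlaid.
#' @export
autoplot.score_set_evaluation <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(df$label, levels = df$label)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$label)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$delta_auc), fill = "grey70") +
    ggplot2::geom_point(ggplot2::aes(y = .data$auc)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$auc, group = 1)) +
    ggplot2::labs(x = "Score set", y = "AUC (points) / ΔAUC (bars)") +
    ggplot2::theme_minimal()
}

#' Write a score-set evaluation table as TSV
#' @param evaluation Tibble from [evaluate_score_sets()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_evaluation_table <- function(evaluation, path) {
  out <- data.frame(
    Score = evaluation$label,
    AUC = sprintf("%.2f ± %.2f", evaluation$auc, evaluation$se),
    P.vs.A = ifelse(evaluation$first, "N/A", signif(evaluation$p_vs_first, 2)),
    P.vs.Prev = ifelse(evaluation$first, "N/A", signif(evaluation$p_vs_prev, 2)),
    dAUC = ifelse(evaluation$first, "N/A", sprintf("%.3f", evaluation$delta_auc))
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
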