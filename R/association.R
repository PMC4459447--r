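#' Two-sided Wald p-value from a z statistic
#'
#' @param stat Wald z value(s).
#' @return `2 * pnorm(-|z|)`, the two-sided normal tail.
#' @examples
#' wald_pvalue(4.83)  # ~1.4e-6
#' @export
wald_pvalue <- function(stat) {
  if (any(!is.finite(stat))) stop("Wald statistic must be finite", call. = FALSE)
  2 * stats::pnorm(-abs(stat))
}

#' Additive logistic association for one marker
#'
#' Fits `status ~ dose` by maximum-likelihood logistic regression
#' (additive minor-allele coding). Samples with missing dose are
#' excluded. The reported statistic is the Wald z (slope over
#' observed-information standard error) with a two-sided normal-tail
#' p-value, matching the convention of standard association toolkits.
#'
#' @param dose Per-sample 0/1/2 dose vector, `NA` allowed.
#' @param status Per-sample case indicator (logical or 0/1).
#' @param marker_id Optional marker label carried into the result.
#' @return A one-row tibble: `marker_id`, `or` (odds ratio per minor
#'   allele), `beta`, `se`, `stat`, `p`, `maf`, `n_used`, `separated`.
#'   Complete separation is flagged (`separated = TRUE`, `p = NA`) with a
#'   warning.
#' @export
fit_additive_logistic <- function(dose, status, marker_id = NA_character_) {
  if (length(dose) != length(status)) {
    stop("dose and status vectors differ in length", call. = FALSE)
  }
  status <- as.numeric(status)
  keep <- !is.na(dose) & !is.na(status)
  d <- as.numeric(dose[keep]); y <- status[keep]
  if (!any(y == 1) || !any(y == 0)) {
    stop("need at least one case and one control with non-missing dose",
         call. = FALSE)
  }
  if (length(unique(d)) < 2) {
    stop("constant dose: association undefined", call. = FALSE)
  }
  maf <- min(sum(d) / (2 * length(d)), 1 - sum(d) / (2 * length(d)))
  separated <- FALSE
  fit <- withCallingHandlers(
    stats::glm(y ~ d, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-12, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  beta <- unname(stats::coef(fit)[2])
  se <- sqrt(stats::vcov(fit)[2, 2])
  if (!separated && (!is.finite(beta) || !is.finite(se) || se > 100)) {
    separated <- TRUE
  }
  if (separated) {
    warning("complete or quasi-complete separation",
            if (!is.na(marker_id)) paste0(" at marker ", marker_id),
            call. = FALSE)
  }
  stat <- if (separated) NA_real_ else beta / se
  tibble::tibble(
    marker_id = marker_id,
    or = exp(beta), beta = beta, se = se, stat = stat,
    p = if (separated) NA_real_ else wald_pvalue(stat),
    maf = maf, n_used = length(d), separated = separated
  )
}

#' Rank an association table
#'
#' Sorts ascending by p, breaking ties by |stat| descending then
#' marker_id; rows with missing p (e.g. separated fits) sort last.
#'
#' @param results Tibble of per-marker association rows.
#' @return The ranked tibble with a `rank` column.
#' @export
rank_association <- function(results) {
  ord <- order(results$p, -abs(results$stat), results$marker_id, na.last = TRUE)
  out <- results[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Per-marker association scan
#'
#' Runs [fit_additive_logistic()] for every marker of a QC-passing
#' genotype matrix, comparing the named case groups against all other
#' samples in `samples` (controls), and returns the p-value-ranked table.
#'
#' @param g A [genotype_matrix()] (QC already applied).
#' @param samples Cohort tibble (see [as_cohort_table()]); only samples
#'   present in `g` are used.
#' @param case_groups Character vector of group labels treated as cases
#'   (default both AD subtypes).
#' @return A ranked tibble of association results (see
#'   [fit_additive_logistic()]); degenerate markers yield flagged
#'   `NA`-statistic rows rather than errors.
#' @export
run_association_scan <- function(g, samples,
                                 case_groups = c("AmnAD", "AtAD")) {
  idx <- match(samples$sample_id, rownames(g$dose))
  samples <- samples[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  status <- as.numeric(samples$group %in% case_groups)
  if (!any(status == 1)) stop("no cases in selection", call. = FALSE)
  if (!any(status == 0)) stop("no controls in selection", call. = FALSE)
  if (ncol(g$dose) == 0) {
    empty <- tibble::tibble(
      marker_id = character(), or = numeric(), beta = numeric(),
      se = numeric(), stat = numeric(), p = numeric(), maf = numeric(),
      n_used = integer(), separated = logical()
    )
    return(rank_association(empty))
  }
  res <- purrr::map_dfr(colnames(g$dose), function(m) {
    d <- g$dose[idx, m]
    tryCatch(
      fit_additive_logistic(d, status, marker_id = m),
      error = function(e) {
        warning("marker ", m, " skipped: ", conditionMessage(e), call. = FALSE)
        tibble::tibble(marker_id = m, or = NA_real_, beta = NA_real_,
                       se = NA_real_, stat = NA_real_, p = NA_real_,
                       maf = NA_real_, n_used = sum(!is.na(d)),
                       separated = FALSE)
      }
    )
  })
  rank_association(res)
}

#' Bonferroni-significant subset
#'
#' @param results Ranked association tibble.
#' @param alpha Family-wise error rate (default 0.05).
#' @param k Number of tests in the family (e.g. markers genotyped).
#' @return The rows with `p < alpha / k`.
#' @export
bonferroni_significant <- function(results, alpha = 0.05, k) {
  stopifnot(k >= 1)
  results[!is.na(results$p) & results$p < alpha / k, , drop = FALSE]
}

#' Carrier enrichment test between two groups
#'
#' Pearson chi-square (1 df, no continuity correction) on the 2x2 table
#' of carrier status by group membership.
#'
#' @param carrier Named logical vector (names are sample ids).
#' @param group_a,group_b Character vectors of sample ids.
#' @return A tibble with `chi2`, `df`, `p` and the carrier fractions.
#' @export
carrier_enrichment_test <- function(carrier, group_a, group_b) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be non-empty", call. = FALSE)
  }
  ca <- carrier[group_a]; cb <- carrier[group_b]
  ca <- ca[!is.na(ca)]; cb <- cb[!is.na(cb)]
  tab <- rbind(c(sum(ca), sum(!ca)), c(sum(cb), sum(!cb)))
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0)) {
    stop("degenerate 2x2 table (zero margin)", call. = FALSE)
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  tibble::tibble(
    chi2 = unname(ct$statistic), df = unname(ct$parameter),
    p = ct$p.value,
    carrier_frac_a = mean(ca), carrier_frac_b = mean(cb)
  )
}

#' Write an association table as TSV
#'
#' Columns mirror the conventional candidate-study report: Gene, SNP,
#' OR, STAT, P, MAF.
#'
#' @param results Ranked association tibble.
#' @param path Output path.
#' @param variants Optional variant table supplying `gene_label`.
#' @return `path`, invisibly.
#' @export
write_association_table <- function(results, path, variants = NULL) {
  gene <- if (!is.null(variants)) {
    variants$gene_label[match(results$marker_id, variants$marker_id)]
  } else NA_character_
  out <- data.frame(
    Gene = gene, SNP = results$marker_id,
    OR = signif(results$or, 3), STAT = signif(results$stat, 3),
    P = signif(results$p, 3), MAF = signif(results$maf, 3)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
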