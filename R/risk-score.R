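#' Squared dose correlation between two markers
#'
#' Composite (genotype-level) LD: the squared Pearson correlation of the
#' additive dose vectors over pairwise-complete samples. Phase-free and
#' deterministic; adequate as a pruning criterion at high r2 cutoffs.
#'
#' @param dose_a,dose_b Per-sample dose vectors.
#' @return r2 in \[0, 1\].
#' @export
genotype_r2 <- function(dose_a, dose_b) {
  keep <- !is.na(dose_a) & !is.na(dose_b)
  if (sum(keep) < 2) stop("fewer than 2 pairwise-complete samples", call. = FALSE)
  a <- dose_a[keep]; b <- dose_b[keep]
  if (stats::var(a) == 0 || stats::var(b) == 0) {
    stop("constant dose vector: LD undefined", call. = FALSE)
  }
  stats::cor(a, b)^2
}

#' Greedy LD pruning of a ranked association list
#'
#' Scans markers in rank order; a marker is retained iff its r2 with
#' every already-retained marker is at or below the threshold, so the
#' most strongly associated member of each linked set survives.
#'
#' @param ranked Ranked association tibble (see [rank_association()]).
#' @param g A [genotype_matrix()] containing all ranked markers.
#' @param threshold r2 cutoff; markers exceeding it against a retained
#'   marker are dropped (default 0.8).
#' @return The pruned ranked tibble, rank order preserved (ranks
#'   renumbered).
#' @export
ld_prune_ranked <- function(ranked, g, threshold = 0.8) {
  missing_m <- setdiff(ranked$marker_id, colnames(g$dose))
  if (length(missing_m)) {
    stop("ranked markers absent from genotypes: ",
         paste(missing_m, collapse = ", "), call. = FALSE)
  }
  retained <- character(0)
  for (m in ranked$marker_id) {
    linked <- FALSE
    for (r in retained) {
      r2 <- tryCatch(genotype_r2(g$dose[, m], g$dose[, r]),
                     error = function(e) 0)
      if (r2 > threshold) { linked <- TRUE; break }
    }
    if (!linked) retained <- c(retained, m)
  }
  out <- ranked[ranked$marker_id %in% retained, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out
}

#' Orient the risk allele of an association result
#'
#' Scoring counts risk alleles, so markers whose minor allele is
#' protective (OR below 1) are flipped to count the major allele; an OR
#' of exactly 1 keeps the minor allele by convention.
#'
#' @param result One-row association tibble (or a row with `marker_id`
#'   and `or`).
#' @param weight Scoring weight for the marker (default 1, allele
#'   counting; pass `log(or)` magnitudes for weighted scores).
#' @return A one-row tibble: `marker_id`, `risk_allele`
#'   (`"minor"`/`"major"`), `weight`, `source_or`.
#' @export
orient_risk_allele <- function(result, weight = 1) {
  or <- result$or
  if (is.null(or) || is.na(or) || !is.finite(or)) {
    stop("association result lacks a finite odds ratio", call. = FALSE)
  }
  tibble::tibble(
    marker_id = result$marker_id,
    risk_allele = if (or >= 1) "minor" else "major",
    weight = weight,
    source_or = or
  )
}

#' Build nested score sets from a pruned ranked list
#'
#' Set k contains the top k risk-oriented markers; sets are labelled
#' A, B, C, ... in order, so each set extends the previous one by the
#' next most significant unlinked marker.
#'
#' @param pruned Pruned ranked association tibble.
#' @param max_sets Maximum number of sets (default 26, labels A-Z).
#' @param weights `"unit"` (allele counting, default) or `"log_or"`
#'   (|log OR| weights).
#' @return A list of `score_set` objects, each a list with `label` and a
#'   `markers` tibble of oriented markers.
#' @export
build_nested_score_sets <- function(pruned, max_sets = 26,
                                    weights = c("unit", "log_or")) {
  weights <- match.arg(weights)
  if (!nrow(pruned)) stop("no markers to build score sets from", call. = FALSE)
  oriented <- purrr::map_dfr(seq_len(nrow(pruned)), function(i) {
    w <- if (weights == "unit") 1 else abs(log(pruned$or[i]))
    orient_risk_allele(pruned[i, ], weight = w)
  })
  n_sets <- min(nrow(oriented), max_sets)
  purrr::map(seq_len(n_sets), function(k) {
    structure(
      list(label = set_label(k), markers = oriented[seq_len(k), , drop = FALSE]),
      class = "score_set"
    )
  })
}

set_label <- function(k) {
  if (k <= 26) LETTERS[k] else paste0(LETTERS[(k - 1) %/% 26], LETTERS[(k - 1) %% 26 + 1])
}

#' @export
print.score_set <- function(x, ...) {
  cat(sprintf("<score_set %s> %d marker(s)\n", x$label, nrow(x$markers)))
  invisible(x)
}

#' Per-sample risk scores for one score set
#'
#' Classic allele-count scoring: each marker contributes its risk-allele
#' dose (the minor-allele dose, or `2 - dose` for flipped markers) times
#' its weight; missing doses are mean-imputed from the in-sample
#' risk-allele frequency of that marker (computed over non-missing
#' samples of `g`), and the total is divided by twice the number of
#' markers, so unit-weight scores are mean risk-allele fractions in
#' \[0, 1\].
#'
#' @param set A `score_set` from [build_nested_score_sets()].
#' @param g A [genotype_matrix()] containing the set's markers.
#' @param impute_missing If `FALSE`, samples missing any set marker get
#'   `NA` instead of mean imputation at markers they miss.
#' @return A tibble: `sample_id`, `score`, `n_markers_used`.
#' @export
compute_sample_scores <- function(set, g, impute_missing = TRUE) {
  mk <- set$markers
  absent <- setdiff(mk$marker_id, colnames(g$dose))
  if (length(absent)) {
    stop("score-set markers absent from genotypes: ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  d <- g$dose[, mk$marker_id, drop = FALSE]
  flip <- mk$risk_allele == "major"
  d[, flip] <- 2 - d[, flip]
  freqs <- colMeans(d, na.rm = TRUE) / 2  # in-sample risk-allele frequency
  n_used <- rowSums(!is.na(d))
  if (impute_missing) {
    for (j in seq_len(ncol(d))) {
      miss <- is.na(d[, j])
      d[miss, j] <- 2 * freqs[j]
    }
    score <- as.vector(d %*% mk$weight) / (2 * nrow(mk))
    score[n_used == 0] <- NA_real_
  } else {
    score <- as.vector(d %*% mk$weight) / (2 * nrow(mk))
  }
  tibble::tibble(sample_id = rownames(g$dose), score = score,
                 n_markers_used = as.integer(n_used))
}

#' Write a scoring file
#'
#' Three-column text file in the classic scoring dialect: marker id,
#' risk allele token (`minor`/`major`, or the base if known), weight.
#'
#' @param set A `score_set`.
#' @param path Output path.
#' @param variants Optional variant table to resolve allele bases.
#' @return `path`, invisibly.
#' @export
write_score_file <- function(set, path, variants = NULL) {
  mk <- set$markers
  allele <- mk$risk_allele
  if (!is.null(variants)) {
    i <- match(mk$marker_id, variants$marker_id)
    base <- ifelse(mk$risk_allele == "minor",
                   variants$minor_allele[i], variants$major_allele[i])
    allele <- ifelse(is.na(base), allele, base)
  }
  out <- data.frame(marker_id = mk$marker_id, risk_allele = allele,
                    weight = mk$weight)
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
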