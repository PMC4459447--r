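#' Marker inclusion thresholds
#'
#' Defaults follow common candidate-marker inclusion criteria: call rate
#' strictly above 0.80, minor allele frequency at least 0.01, and exact
#' Hardy-Weinberg p strictly above 0.001.
#'
#' @param min_call_rate Call-rate threshold (exclusive).
#' @param min_maf MAF threshold (inclusive).
#' @param min_hwe_p HWE p-value threshold (exclusive).
#' @return A named list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_call_rate = 0.80, min_maf = 0.01,
                          min_hwe_p = 0.001) {
  vals <- c(min_call_rate, min_maf, min_hwe_p)
  if (any(vals <= 0 | vals > 1)) {
    stop("QC thresholds must lie in (0, 1]", call. = FALSE)
  }
  structure(list(min_call_rate = min_call_rate, min_maf = min_maf,
                 min_hwe_p = min_hwe_p), class = "qc_thresholds")
}

#' Per-marker quality-control metrics
#'
#' Computes, for every marker, the call rate (non-missing fraction), the
#' minor allele frequency over non-missing doses, and the exact HWE
#' p-value from the non-missing genotype counts, then applies the
#' inclusion thresholds.
#'
#' @param g A [genotype_matrix()].
#' @param thresholds A [qc_thresholds()] object.
#' @param hwe_samples Optional character vector of sample ids on which to
#'   assess HWE (e.g. controls only); default all samples.
#' @return A tibble with columns `marker_id`, `call_rate`, `maf`,
#'   `hwe_p`, `pass`, `fail_reasons` (comma-separated, `""` if passing).
#' @export
marker_qc_metrics <- function(g, thresholds = qc_thresholds(),
                              hwe_samples = NULL) {
  stopifnot(inherits(g, "genotype_matrix"), nrow(g$dose) >= 1)
  hwe_rows <- if (is.null(hwe_samples)) seq_len(nrow(g$dose)) else {
    match(hwe_samples, rownames(g$dose))
  }
  purrr::map_dfr(seq_len(ncol(g$dose)), function(j) {
    d <- g$dose[, j]
    call_rate <- mean(!is.na(d))
    nm <- d[!is.na(d)]
    maf <- if (length(nm)) {
      f <- sum(nm) / (2 * length(nm))
      min(f, 1 - f)
    } else NA_real_
    dh <- g$dose[hwe_rows, j]
    dh <- dh[!is.na(dh)]
    hwe_p <- if (length(dh)) {
      hwe_exact_test(sum(dh == 0), sum(dh == 1), sum(dh == 2))
    } else NA_real_
    reasons <- c(
      if (is.na(call_rate) || call_rate <= thresholds$min_call_rate) "call_rate",
      if (is.na(maf) || maf < thresholds$min_maf) "maf",
      if (is.na(hwe_p) || hwe_p <= thresholds$min_hwe_p) "hwe"
    )
    tibble::tibble(
      marker_id = colnames(g$dose)[j],
      call_rate = call_rate, maf = maf, hwe_p = hwe_p,
      pass = length(reasons) == 0,
      fail_reasons = paste(reasons, collapse = ",")
    )
  })
}

#' Apply marker QC filters
#'
#' @inheritParams marker_qc_metrics
#' @return A list with `genotypes` (the matrix restricted to passing
#'   markers, original order preserved) and `report` (the
#'   [marker_qc_metrics()] tibble for all input markers).
#' @export
apply_qc <- function(g, thresholds = qc_thresholds(), hwe_samples = NULL) {
  report <- marker_qc_metrics(g, thresholds, hwe_samples)
  keep <- report$marker_id[report$pass]
  if (!length(keep)) {
    warning("no markers pass QC", call. = FALSE)
  }
  list(genotypes = g[, report$pass], report = report)
}

#' Write a QC report as TSV
#' @param report Tibble from [marker_qc_metrics()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qc_report <- function(report, path) {
  utils::write.table(report, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
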