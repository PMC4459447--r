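#' Exact Hardy-Weinberg equilibrium test
#'
#' Levene-Haldane conditional exact test: given the observed allele
#' counts, the number of heterozygotes is compared against its exact
#' conditional distribution under random mating. The two-sided p-value is
#' the total probability of all heterozygote counts whose conditional
#' probability does not exceed that of the observed count.
#'
#' @param n_AA,n_Aa,n_aa Genotype counts (major homozygote, heterozygote,
#'   minor homozygote). Which homozygote is labelled major is irrelevant.
#' @return The exact two-sided p-value. Monomorphic markers return 1.
#' @examples
#' hwe_exact_test(25, 50, 25)  # modal configuration -> 1
#' hwe_exact_test(1, 0, 1)     # 1/3
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  counts <- c(n_AA, n_Aa, n_aa)
  if (anyNA(counts) || any(counts < 0) || any(counts != round(counts))) {
    stop("genotype counts must be non-negative integers", call. = FALSE)
  }
  n <- sum(counts)
  if (n == 0) stop("all genotype counts are zero", call. = FALSE)
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) return(1)
  hets <- hwe_het_support(n, n_minor)
  logp <- hwe_het_logprob(n, n_minor, hets)
  obs <- which(hets == n_Aa)
  # tolerance guards against log-scale rounding when summing the tail
  p <- sum(exp(logp)[logp <= logp[obs] + 1e-10])
  min(1, p)
}

# heterozygote counts compatible with n samples and n_minor minor alleles
hwe_het_support <- function(n, n_minor) {
  lo <- if (n_minor %% 2 == 0) 0 else 1
  seq(lo, min(n_minor, 2 * n - n_minor), by = 2)
}

hwe_het_logprob <- function(n, n_minor, hets) {
  n_major <- 2 * n - n_minor
  lgamma(n + 1) + lgamma(n_minor + 1) + lgamma(n_major + 1) - lgamma(2 * n + 1) +
    hets * log(2) -
    lgamma((n_minor - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma((n_major - hets) / 2 + 1)
}
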