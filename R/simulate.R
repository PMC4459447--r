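#' Default candidate-marker panel
#'
#' A 75-marker biallelic panel emulating a candidate-gene study of
#' heterogeneous Alzheimer's disease: the APOE epsilon-4 composite
#' marker, 23 named candidate SNPs in AD/neuropsychiatric genes with
#' field-typical minor allele frequencies, and 51 null filler markers.
#' Default planted effects mirror the study's leading subtype-specific
#' drivers, one strong driver per subtype: an APOE effect (per-allele OR
#' 4.3) in amnestic AD and an HFE rs1799945 effect of the same strength
#' in atypical AD (the pooled all-AD scan estimate for HFE, OR 2.83, is
#' diluted by the amnestic case majority and so understates the
#' subtype-specific effect); all other markers are null.
#'
#' The APOE marker's population MAF (0.119) is the control epsilon-4
#' allele frequency implied by a 22.3% control carrier rate under
#' Hardy-Weinberg equilibrium.
#'
#' @return A tibble: `marker_id`, `gene_label`, `maf`, `log_or_amn`,
#'   `log_or_aty`.
#' @export
default_marker_panel <- function() {
  named <- tibble::tribble(
    ~marker_id,          ~gene_label, ~maf,
    "rs429358/rs7412",   "APOE",      0.119,
    "rs1799945",         "HFE",       0.15,
    "rs3851179",         "PICALM",    0.42,
    "rs6701713",         "CR1",       0.19,
    "rs2020942",         "SLC6A4",    0.40,
    "rs1799913",         "TPH1",      0.44,
    "rs4504469",         "KIAA0319",  0.35,
    "rs1320490",         "CDC42BPA",  0.20,
    "rs6599389",         "TMEM175",   0.08,
    "rs2070045",         "SORL1",     0.22,
    "rs17236239",        "CNTNAP2",   0.16,
    "rs8053211",         "ATP2C2",    0.43,
    "rs9349407",         "CD2AP",     0.29,
    "rs7814569",         "TPD52",     0.09,
    "rs4680",            "COMT",      0.50,
    "rs3849942",         "C9ORF72",   0.24,
    "rs11186856",        "CPE",       0.33,
    "rs12285364",        "SORL1",     0.04,
    "rs4130047",         "RIT2",      0.31,
    "rs1768208",         "MOBP",      0.29,
    "rs4343",            "ACE",       0.47,
    "rs5848",            "GRN",       0.30,
    "rs13312998",        "GSK3B",     0.12,
    "rs1091047",         "DCDC2",     0.35
  )
  n_fill <- 75 - nrow(named)
  fill <- tibble::tibble(
    marker_id = sprintf("rs9%05d", seq_len(n_fill)),
    gene_label = NA_character_,
    maf = round(seq(0.05, 0.50, length.out = n_fill), 3)
  )
  panel <- dplyr::bind_rows(named, fill)
  panel$log_or_amn <- ifelse(panel$gene_label %in% "APOE", log(4.3), 0)
  panel$log_or_aty <- ifelse(panel$gene_label %in% "HFE", log(4.3), 0)
  panel
}

#' Simulation configuration
#'
#' Defaults reproduce the global structure of the emulated study: group
#' sizes 283 controls / 126 amnestic AD / 39 atypical AD, ages of
#' 75.4 +/- 7.0 years truncated to the study's 65-101 range, an overall
#' 51.8% female fraction, 2% missing genotypes, and the
#' [default_marker_panel()] effect architecture. Age and sex are by
#' default *not* causal for case status (all groups share one
#' distribution), so genetic structure alone drives the planted signal;
#' pass `demographics = study_demographics()` to give each group its
#' study-calibrated age/sex profile instead.
#'
#' @param n_per_group Named counts for `control`, `AmnAD`, `AtAD`.
#' @param markers Marker panel tibble (`marker_id`, `gene_label`, `maf`,
#'   `log_or_amn`, `log_or_aty`).
#' @param age_mean_sd Named list of `c(mean, sd)` per group.
#' @param frac_female Named per-group female fractions.
#' @param age_range Truncation bounds for simulated ages.
#' @param missing_rate Independent per-genotype missingness probability.
#' @param ld_blocks List of `list(parent =, n_proxies =, fidelity =)`
#'   entries appending LD-proxy markers after base simulation.
#' @param seed Integer seed; every stochastic draw derives from it.
#' @return A list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_per_group = c(control = 283, AmnAD = 126, AtAD = 39),
    markers = default_marker_panel(),
    age_mean_sd = list(control = c(75.4, 7.0), AmnAD = c(75.4, 7.0),
                       AtAD = c(75.4, 7.0)),
    frac_female = c(control = 0.518, AmnAD = 0.518, AtAD = 0.518),
    age_range = c(65, 101),
    missing_rate = 0.02,
    ld_blocks = list(),
    seed = 1L) {
  markers <- tibble::as_tibble(markers)
  need <- c("marker_id", "maf", "log_or_amn", "log_or_aty")
  if (!all(need %in% names(markers))) {
    stop("marker panel needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (any(markers$maf <= 0 | markers$maf > 0.5)) {
    stop("marker MAFs must lie in (0, 0.5]", call. = FALSE)
  }
  stopifnot(all(n_per_group >= 0),
            all(frac_female >= 0 & frac_female <= 1),
            missing_rate >= 0, missing_rate < 1)
  structure(list(
    n_per_group = n_per_group, markers = markers,
    age_mean_sd = age_mean_sd, frac_female = frac_female,
    age_range = age_range, missing_rate = missing_rate,
    ld_blocks = ld_blocks, seed = as.integer(seed)
  ), class = "simulation_config")
}

#' Study-calibrated group demographics
#'
#' Per-group age means/SDs and female fractions of the emulated cohort
#' (controls 75.4 +/- 7.0 years, 55.1% female; amnestic AD 79.2 +/- 8.5,
#' 50.0%; atypical AD 77.6 +/- 9.0, 33.3%). Supplying these to
#' [simulation_config()] makes age and sex informative about case
#' status, as in the real cohort.
#'
#' @return A list with elements `age_mean_sd` and `frac_female` in the
#'   shapes [simulation_config()] expects.
#' @export
study_demographics <- function() {
  list(
    age_mean_sd = list(control = c(75.4, 7.0), AmnAD = c(79.2, 8.5),
                       AtAD = c(77.6, 9.0)),
    frac_female = c(control = 0.551, AmnAD = 0.500, AtAD = 0.333)
  )
}

# genotype probabilities for one marker in one group: HWE tilted by the
# additive logit effect (retrospective case-control sampling)
tilted_genotype_probs <- function(maf, log_or) {
  hwe <- c((1 - maf)^2, 2 * maf * (1 - maf), maf^2)
  w <- hwe * exp((0:2) * log_or)
  w / sum(w)
}

rtruncnorm_int <- function(n, mean, sd, lo, hi) {
  u <- stats::runif(n, stats::pnorm(lo, mean, sd), stats::pnorm(hi, mean, sd))
  pmin(hi, pmax(lo, round(stats::qnorm(u, mean, sd))))
}

#' Simulate a case/control genotype cohort
#'
#' Controls are drawn at Hardy-Weinberg equilibrium with the configured
#' population MAFs; cases of each subtype are drawn with genotype
#' probabilities tilted by `exp(dose * log OR)` and renormalised
#' (retrospective sampling under the additive logit model). Ages are
#' truncated-normal and rounded, sex Bernoulli, and missingness applied
#' independently. Fully reproducible from `config$seed`.
#'
#' @param config A [simulation_config()].
#' @param id_prefix Prefix for generated sample ids.
#' @return A list of class `simulated_cohort` with elements `genotypes`
#'   (a [genotype_matrix()]), `samples` (cohort tibble) and `config`.
#' @export
simulate_cohort <- function(config = simulation_config(), id_prefix = "S") {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  groups <- rep(names(config$n_per_group), times = config$n_per_group)
  n <- length(groups)
  ids <- sprintf("%s%04d", id_prefix, seq_len(n))
  mk <- config$markers
  dose <- matrix(NA_real_, nrow = n, ncol = nrow(mk),
                 dimnames = list(ids, mk$marker_id))
  log_or <- list(control = rep(0, nrow(mk)),
                 AmnAD = mk$log_or_amn, AtAD = mk$log_or_aty)
  for (g in unique(groups)) {
    rows <- which(groups == g)
    for (j in seq_len(nrow(mk))) {
      pr <- tilted_genotype_probs(mk$maf[j], log_or[[g]][j])
      dose[rows, j] <- sample(0:2, length(rows), replace = TRUE, prob = pr)
    }
  }
  age <- numeric(n); female <- logical(n)
  for (g in unique(groups)) {
    rows <- which(groups == g)
    ms <- config$age_mean_sd[[g]]
    age[rows] <- rtruncnorm_int(length(rows), ms[1], ms[2],
                                config$age_range[1], config$age_range[2])
    female[rows] <- stats::runif(length(rows)) < config$frac_female[[g]]
  }
  if (config$missing_rate > 0 && length(dose)) {
    dose[stats::runif(length(dose)) < config$missing_rate] <- NA_real_
  }
  geno <- genotype_matrix(dose, tibble::tibble(
    marker_id = mk$marker_id,
    gene_label = if ("gene_label" %in% names(mk)) mk$gene_label else NA_character_,
    minor_allele = NA_character_, major_allele = NA_character_
  ))
  for (blk in config$ld_blocks) {
    n_prox <- if (is.null(blk$n_proxies)) 1L else blk$n_proxies
    for (k in seq_len(n_prox)) {
      geno <- plant_ld_proxy(geno, blk$parent, blk$fidelity,
                             seed = NULL,
                             proxy_id = paste0(blk$parent, "_proxy", k))
    }
  }
  samples <- as_cohort_table(tibble::tibble(
    sample_id = ids, group = groups, age = age,
    sex = ifelse(female, "female", "male"), split = "unassigned"
  ))
  structure(list(genotypes = geno, samples = samples, config = config),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  tab <- table(x$samples$group)
  cat(sprintf("<simulated_cohort> %s; %d markers; seed %d\n",
              paste(names(tab), tab, sep = "=", collapse = ", "),
              ncol(x$genotypes$dose), x$config$seed))
  invisible(x)
}

#' Append an LD-proxy marker
#'
#' The proxy copies the parent's dose and, independently per sample with
#' probability `1 - fidelity`, resamples the genotype from the parent's
#' empirical genotype distribution; `fidelity = 1` gives an exact copy,
#' `fidelity = 0` an independent marker with the same marginal.
#'
#' @param g A [genotype_matrix()].
#' @param parent Parent marker id.
#' @param fidelity Copy fidelity in \[0, 1\].
#' @param seed Optional seed (set `NULL` to use the current RNG stream).
#' @param proxy_id Id for the new marker (default `<parent>_proxy`).
#' @return The matrix with the proxy appended as the last column.
#' @export
plant_ld_proxy <- function(g, parent, fidelity, seed = NULL,
                           proxy_id = paste0(parent, "_proxy")) {
  if (!parent %in% colnames(g$dose)) {
    stop("unknown parent marker: ", parent, call. = FALSE)
  }
  stopifnot(fidelity >= 0, fidelity <= 1)
  if (!is.null(seed)) set.seed(seed)
  d <- g$dose[, parent]
  nm <- d[!is.na(d)]
  marg <- tabulate(nm + 1, nbins = 3) / length(nm)
  proxy <- d
  resample <- stats::runif(length(d)) < (1 - fidelity)
  n_res <- sum(resample)
  if (n_res > 0) {
    proxy[resample] <- sample(0:2, n_res, replace = TRUE, prob = marg)
  }
  dose <- cbind(g$dose, proxy)
  colnames(dose)[ncol(dose)] <- proxy_id
  variants <- dplyr::bind_rows(
    g$variants,
    tibble::tibble(marker_id = proxy_id,
                   gene_label = NA_character_,
                   minor_allele = NA_character_,
                   major_allele = NA_character_)
  )
  genotype_matrix(dose, variants)
}

#' Assign discovery/validation splits by stratified sampling
#'
#' Within each group, `round(discovery_fraction * n)` samples are drawn
#' into the discovery stage and the rest into validation, so group
#' proportions are preserved.
#'
#' @param samples Cohort tibble.
#' @param discovery_fraction Fraction assigned to discovery, in (0, 1).
#' @param seed Integer seed.
#' @return The tibble with the `split` column filled in.
#' @export
split_cohort <- function(samples, discovery_fraction, seed = 1L) {
  stopifnot(discovery_fraction > 0, discovery_fraction < 1)
  set.seed(seed)
  split <- as.character(samples$split)
  for (g in levels(samples$group)) {
    rows <- which(samples$group == g)
    if (!length(rows)) next
    if (length(rows) < 2) {
      warning("group ", g, " has fewer than 2 samples; all to discovery",
              call. = FALSE)
      split[rows] <- "discovery"
      next
    }
    n_disc <- round(discovery_fraction * length(rows))
    disc <- sample(rows, n_disc)
    split[rows] <- "validation"
    split[disc] <- "discovery"
  }
  samples$split <- factor(split, levels = SPLIT_LEVELS)
  samples
}

#' Study-design group counts
#'
#' The per-stage group sizes of the emulated two-stage design, together
#' with each stage's reported total (the validation stage reports 276
#' participants although its subtyped case counts sum to 106 cases; both
#' figures are recorded, neither asserted).
#'
#' @return A tibble: `stage`, `group`, `n`, `stage_total_reported`.
#' @export
study_design_counts <- function() {
  tibble::tribble(
    ~stage,        ~group,    ~n,  ~stage_total_reported,
    "discovery",   "control", 133, 192,
    "discovery",   "AmnAD",   42,  192,
    "discovery",   "AtAD",    17,  192,
    "validation",  "control", 150, 276,
    "validation",  "AmnAD",   84,  276,
    "validation",  "AtAD",    22,  276
  )
}

#' Subtype percentage of a stage
#'
#' Percentage of a stage's reported total made up by one group, as
#' study reports print it (e.g. AmnAD share of the discovery stage).
#'
#' @param design Count tibble from [study_design_counts()] (or the same
#'   shape with different counts).
#' @param stage `"discovery"` or `"validation"`.
#' @param group Group label.
#' @return Percentage (0-100 scale).
#' @export
subtype_percentage <- function(design, stage, group) {
  row <- design[design$stage == stage & design$group == group, ]
  if (nrow(row) != 1) stop("stage/group not found in design", call. = FALSE)
  100 * row$n / row$stage_total_reported
}

#' Simulate a two-stage study cohort
#'
#' Simulates discovery and validation stages at the study-design group
#' sizes (from [study_design_counts()]) with a shared marker panel and
#' stage-specific seeds derived from `seed`, and concatenates them with
#' split labels assigned.
#'
#' @param seed Integer seed.
#' @param markers Marker panel (default [default_marker_panel()]).
#' @param design Count tibble in the [study_design_counts()] shape.
#' @param ... Further arguments passed to [simulation_config()] for both
#'   stages.
#' @return A `simulated_cohort` whose samples carry discovery/validation
#'   split labels.
#' @export
simulate_study_cohort <- function(seed = 1L, markers = default_marker_panel(),
                                  design = study_design_counts(), ...) {
  stage_counts <- function(stage) {
    d <- design[design$stage == stage, ]
    stats::setNames(d$n, d$group)[c("control", "AmnAD", "AtAD")]
  }
  disc <- simulate_cohort(
    simulation_config(n_per_group = stage_counts("discovery"),
                      markers = markers, seed = seed, ...),
    id_prefix = "D")
  vali <- simulate_cohort(
    simulation_config(n_per_group = stage_counts("validation"),
                      markers = markers, seed = seed + 1000003L, ...),
    id_prefix = "V")
  disc$samples$split <- factor("discovery", levels = SPLIT_LEVELS)
  vali$samples$split <- factor("validation", levels = SPLIT_LEVELS)
  dose <- rbind(disc$genotypes$dose, vali$genotypes$dose)
  structure(list(
    genotypes = genotype_matrix(dose, disc$genotypes$variants),
    samples = dplyr::bind_rows(disc$samples, vali$samples),
    config = disc$config
  ), class = "simulated_cohort")
}
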