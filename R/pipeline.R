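#' Run the two-stage risk-score study
#'
#' Discovery stage: marker QC, additive logistic scan of discovery
#' samples, p-value ranking, greedy LD pruning, risk-allele orientation,
#' nested score sets, per-set AUC evaluation and optimal-set selection by
#' the two-consecutive-decreases stopping rule. Validation stage: the
#' selected set's scoring file is applied unchanged to the validation
#' samples and its AUC compared (paired DeLong) against the
#' single-marker baseline set A.
#'
#' @param cohort A `simulated_cohort` or any list with `genotypes` (a
#'   [genotype_matrix()]) and `samples` (cohort tibble with discovery/
#'   validation split labels). `NULL` simulates the default study cohort
#'   from `seed`.
#' @param seed Seed used when `cohort` is simulated here.
#' @param qc [qc_thresholds()] for marker inclusion.
#' @param hwe_in `"controls"` (default) assesses Hardy-Weinberg
#'   equilibrium in controls only — the usual case/control practice,
#'   since a marker with a true effect departs from HWE in the pooled
#'   sample — or `"all"` to use every sample.
#' @param ld_threshold r2 cutoff for pruning.
#' @param max_sets Maximum number of nested sets.
#' @param case_groups Group labels treated as cases.
#' @param stopping_rule Passed to [select_optimal_set()].
#' @param output_dir Optional directory; when given, all report tables
#'   (QC, association, evaluations, scoring file, classification sweep,
#'   run log) are written there as TSV/text.
#' @return A list of class `two_stage_study`: `qc_report`,
#'   `association`, `pruned`, `sets`, `discovery_eval`,
#'   `selected_index`, `selected_label`, `validation_eval`,
#'   `validation_sweep`, `scores`, `cohort`.
#' @export
run_two_stage_study <- function(cohort = NULL, seed = 1L,
                                qc = qc_thresholds(),
                                hwe_in = c("controls", "all"),
                                ld_threshold = 0.8,
                                max_sets = 26,
                                case_groups = c("AmnAD", "AtAD"),
                                stopping_rule = "consecutive",
                                output_dir = NULL) {
  hwe_in <- match.arg(hwe_in)
  if (is.null(cohort)) cohort <- simulate_study_cohort(seed)
  samples <- cohort$samples
  if (!any(samples$split == "discovery") || !any(samples$split == "validation")) {
    stop("cohort lacks discovery/validation split labels", call. = FALSE)
  }
  hwe_ids <- if (hwe_in == "controls") {
    samples$sample_id[samples$group == "control"]
  } else NULL
  qc_res <- apply_qc(cohort$genotypes, qc, hwe_samples = hwe_ids)
  g <- qc_res$genotypes
  disc_ids <- samples$sample_id[samples$split == "discovery"]
  vali_ids <- samples$sample_id[samples$split == "validation"]
  g_disc <- g[disc_ids, ]
  g_vali <- g[vali_ids, ]
  disc_samples <- samples[samples$split == "discovery", ]

  ranked <- run_association_scan(g_disc, disc_samples, case_groups)
  ranked <- ranked[!is.na(ranked$p), , drop = FALSE]
  pruned <- ld_prune_ranked(ranked, g_disc, ld_threshold)
  sets <- build_nested_score_sets(pruned, max_sets = max_sets)

  case_of <- function(ids) {
    as.numeric(samples$group[match(ids, samples$sample_id)] %in% case_groups)
  }
  disc_eval <- evaluate_score_sets(sets, g_disc, case_of(disc_ids))
  selected <- select_optimal_set(disc_eval$auc, rule = stopping_rule)

  sel_set <- sets[[selected]]
  first_set <- sets[[1]]
  vali_labels <- case_of(vali_ids)
  score_a <- compute_sample_scores(first_set, g_vali)
  score_q <- compute_sample_scores(sel_set, g_vali)
  auc_a <- auc_mann_whitney(score_a$score, vali_labels)
  auc_q <- auc_mann_whitney(score_q$score, vali_labels)
  cmp <- compare_paired_auc(score_q$score, score_a$score, vali_labels)
  validation_eval <- tibble::tibble(
    label = c(first_set$label, sel_set$label),
    n_markers = c(nrow(first_set$markers), nrow(sel_set$markers)),
    auc = c(auc_a$auc, auc_q$auc), se = c(auc_a$se, auc_q$se),
    p_vs_first = c(NA_real_, cmp$p),
    n = c(sum(!is.na(score_a$score)), sum(!is.na(score_q$score)))
  )
  sweep <- classification_sweep(score_q$score, vali_labels)

  out <- structure(list(
    qc_report = qc_res$report, association = ranked, pruned = pruned,
    sets = sets, discovery_eval = disc_eval,
    selected_index = selected, selected_label = sel_set$label,
    validation_eval = validation_eval, validation_sweep = sweep,
    scores = list(discovery = purrr::map(sets, compute_sample_scores, g = g_disc),
                  validation = list(first = score_a, selected = score_q)),
    cohort = cohort, seed = seed
  ), class = "two_stage_study")
  if (!is.null(output_dir)) write_study_bundle(out, output_dir)
  out
}

#' @export
print.two_stage_study <- function(x, ...) {
  cat(sprintf(
    "<two_stage_study> selected set %s (%d markers); discovery AUC %.3f, validation AUC %.3f\n",
    x$selected_label, x$selected_index,
    x$discovery_eval$auc[x$selected_index],
    x$validation_eval$auc[2]
  ))
  invisible(x)
}

#' @export
glance.two_stage_study <- function(x, ...) {
  tibble::tibble(
    n_markers_pass_qc = sum(x$qc_report$pass),
    n_pruned = nrow(x$pruned),
    selected_index = x$selected_index,
    selected_label = x$selected_label,
    discovery_auc = x$discovery_eval$auc[x$selected_index],
    validation_auc = x$validation_eval$auc[2],
    validation_p_vs_first = x$validation_eval$p_vs_first[2]
  )
}

write_study_bundle <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_qc_report(study$qc_report, file.path(dir, "qc_report.tsv"))
  write_association_table(study$association, file.path(dir, "association.tsv"),
                          variants = study$cohort$genotypes$variants)
  write_evaluation_table(study$discovery_eval,
                         file.path(dir, "discovery_evaluation.tsv"))
  utils::write.table(study$validation_eval,
                     file.path(dir, "validation_evaluation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  write_score_file(study$sets[[study$selected_index]],
                   file.path(dir, "selected_score_set.tsv"),
                   variants = study$cohort$genotypes$variants)
  utils::write.table(study$validation_sweep,
                     file.path(dir, "validation_classification_sweep.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  writeLines(c(
    sprintf("seed: %s", study$seed),
    sprintf("selected_set: %s (%d markers)", study$selected_label,
            study$selected_index),
    sprintf("markers_pass_qc: %d", sum(study$qc_report$pass)),
    sprintf("package: adgenrisk %s",
            as.character(utils::packageVersion("adgenrisk")))
  ), file.path(dir, "run_log.txt"))
  invisible(dir)
}

#' Build the decision-tree predictor frame for a cohort
#'
#' Predictors are sex (0 = male, 1 = female), age in years, every
#' QC-passing marker's minor-allele dose, and the derived APOE
#' epsilon-4 dose (from the composite epsilon-4 marker if present, or
#' from rs429358 + rs7412 via [derive_apoe_e4_dose()]).
#'
#' @param genotypes A QC-passed [genotype_matrix()].
#' @param samples Cohort tibble aligned with the matrix rows.
#' @return A list: `data` (data frame of predictor values) and
#'   `manifest` (tibble `name`, `kind`).
#' @export
tree_predictors <- function(genotypes, samples) {
  idx <- match(samples$sample_id, rownames(genotypes$dose))
  if (anyNA(idx)) stop("samples missing from genotype matrix", call. = FALSE)
  dose <- genotypes$dose[idx, , drop = FALSE]
  df <- data.frame(
    sex = as.numeric(samples$sex == "female"),
    age = samples$age,
    check.names = FALSE
  )
  manifest <- tibble::tibble(name = c("sex", "age"),
                             kind = c("binary", "continuous"))
  e4_col <- intersect(c("APOE_e4", "rs429358/rs7412"), colnames(dose))
  if (length(e4_col)) {
    df[["APOE_e4"]] <- dose[, e4_col[1]]
    manifest <- dplyr::bind_rows(manifest,
                                 tibble::tibble(name = "APOE_e4", kind = "dose"))
    dose <- dose[, setdiff(colnames(dose), e4_col), drop = FALSE]
  } else if (all(c("rs429358", "rs7412") %in% colnames(dose))) {
    df[["APOE_e4"]] <- derive_apoe_e4_dose(dose[, "rs429358"], dose[, "rs7412"])
    manifest <- dplyr::bind_rows(manifest,
                                 tibble::tibble(name = "APOE_e4", kind = "dose"))
  }
  for (m in colnames(dose)) df[[m]] <- dose[, m]
  manifest <- dplyr::bind_rows(
    manifest, tibble::tibble(name = colnames(dose), kind = "dose"))
  list(data = df, manifest = manifest)
}

#' Fit the three stratified decision trees
#'
#' One tree for all AD cases versus controls, one for amnestic AD versus
#' controls and one for atypical AD versus controls, each over sex, age,
#' the APOE epsilon-4 dose and all QC-passing markers.
#'
#' @param cohort A `simulated_cohort` or list with `genotypes` and
#'   `samples`.
#' @param config A [tree_config()].
#' @param qc [qc_thresholds()] applied before predictor construction.
#' @param hwe_in `"controls"` (default) or `"all"`; see
#'   [run_two_stage_study()].
#' @param output_dir Optional directory for JSON/DOT/metric exports.
#' @return A list of class `subtype_trees` with elements `all_ad`,
#'   `amnestic`, `atypical` (each a `risk_tree`, or `NULL` with a
#'   warning if its stratum is single-class) and `qc_report`.
#' @export
run_subtype_trees <- function(cohort, config = tree_config(),
                              qc = qc_thresholds(),
                              hwe_in = c("controls", "all"),
                              output_dir = NULL) {
  hwe_in <- match.arg(hwe_in)
  hwe_ids <- if (hwe_in == "controls") {
    cohort$samples$sample_id[cohort$samples$group == "control"]
  } else NULL
  qc_res <- apply_qc(cohort$genotypes, qc, hwe_samples = hwe_ids)
  strata <- list(all_ad = c("AmnAD", "AtAD"), amnestic = "AmnAD",
                 atypical = "AtAD")
  trees <- purrr::imap(strata, function(case_groups, nm) {
    keep <- cohort$samples$group %in% c("control", case_groups)
    samples <- cohort$samples[keep, , drop = FALSE]
    labels <- as.numeric(samples$group %in% case_groups)
    if (!any(labels == 1) || !any(labels == 0)) {
      warning("stratum ", nm, " has a single class; tree skipped",
              call. = FALSE)
      return(NULL)
    }
    pred <- tree_predictors(qc_res$genotypes, samples)
    grow_tree(pred$data, labels, pred$manifest, config)
  })
  out <- structure(c(trees, list(qc_report = qc_res$report)),
                   class = "subtype_trees")
  if (!is.null(output_dir)) {
    dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(strata)) {
      if (is.null(trees[[nm]])) next
      writeLines(export_tree(trees[[nm]], "json"),
                 file.path(output_dir, paste0("tree_", nm, ".json")))
      writeLines(export_tree(trees[[nm]], "dot"),
                 file.path(output_dir, paste0("tree_", nm, ".dot")))
      utils::write.table(node_path_metrics(trees[[nm]]),
                         file.path(output_dir, paste0("tree_", nm, "_nodes.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }
  out
}

#' @export
print.subtype_trees <- function(x, ...) {
  for (nm in c("all_ad", "amnestic", "atypical")) {
    cat("==", nm, "==\n")
    if (is.null(x[[nm]])) cat("(skipped)\n") else print(x[[nm]])
    cat("\n")
  }
  invisible(x)
}
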