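GROUP_LEVELS <- c("control", "AmnAD", "AtAD")
SPLIT_LEVELS <- c("discovery", "validation", "unassigned")

#' Read a phenotype table
#'
#' Reads a tab-delimited phenotype file with header columns `id`, `group`,
#' `age`, `sex` and optionally `split`. Groups must be one of `control`,
#' `AmnAD` (amnestic Alzheimer's disease) or `AtAD` (atypical AD); sex one
#' of `male`/`female`; split one of `discovery`/`validation`/`unassigned`.
#'
#' @param path Path to a TSV file.
#' @param age_range Plausible age bounds; ages outside raise an error.
#' @return A tibble with columns `sample_id`, `group`, `age`, `sex`,
#'   `split` (factors for the categorical columns).
#' @export
read_cohort_table <- function(path, age_range = c(40, 110)) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  required <- c("id", "group", "age", "sex")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("phenotype file missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  if (!"split" %in% names(df)) df$split <- rep("unassigned", nrow(df))
  as_cohort_table(tibble::tibble(
    sample_id = df$id, group = df$group,
    age = suppressWarnings(as.numeric(df$age)),
    sex = df$sex, split = df$split
  ), age_range = age_range)
}

#' Validate and normalise a phenotype data frame
#'
#' @param samples Data frame with columns `sample_id`, `group`, `age`,
#'   `sex` and optionally `split`.
#' @param age_range Plausible age bounds.
#' @return A validated tibble with factor-coded categorical columns.
#' @export
as_cohort_table <- function(samples, age_range = c(40, 110)) {
  samples <- tibble::as_tibble(samples)
  if (!"split" %in% names(samples)) samples$split <- "unassigned"
  stopifnot(all(c("sample_id", "group", "age", "sex") %in% names(samples)))
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample ids in phenotype table", call. = FALSE)
  }
  bad_group <- setdiff(unique(as.character(samples$group)), GROUP_LEVELS)
  if (length(bad_group)) {
    stop("unknown group token(s): ", paste(bad_group, collapse = ", "),
         "; expected ", paste(GROUP_LEVELS, collapse = "/"), call. = FALSE)
  }
  bad_sex <- setdiff(unique(as.character(samples$sex)), c("male", "female"))
  if (length(bad_sex)) {
    stop("unknown sex token(s): ", paste(bad_sex, collapse = ", "), call. = FALSE)
  }
  bad_split <- setdiff(unique(as.character(samples$split)), SPLIT_LEVELS)
  if (length(bad_split)) {
    stop("unknown split token(s): ", paste(bad_split, collapse = ", "), call. = FALSE)
  }
  if (nrow(samples) && (anyNA(samples$age) ||
      any(samples$age < age_range[1] | samples$age > age_range[2]))) {
    stop("ages must be numeric and within [", age_range[1], ", ",
         age_range[2], "]", call. = FALSE)
  }
  tibble::tibble(
    sample_id = as.character(samples$sample_id),
    group = factor(as.character(samples$group), levels = GROUP_LEVELS),
    age = as.numeric(samples$age),
    sex = factor(as.character(samples$sex), levels = c("male", "female")),
    split = factor(as.character(samples$split), levels = SPLIT_LEVELS)
  )
}

#' Write a phenotype table
#'
#' @param samples Cohort tibble as returned by [read_cohort_table()].
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_cohort_table <- function(samples, path) {
  out <- data.frame(
    id = samples$sample_id, group = as.character(samples$group),
    age = samples$age, sex = as.character(samples$sex),
    split = as.character(samples$split)
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype matrix from VCF or a dose TSV
#'
#' For VCF input only the GT field of biallelic sites is consumed;
#' multi-allelic records are skipped with a warning. Doses count the
#' *minor* allele as determined from the in-sample allele frequency among
#' non-missing genotypes (ties broken by taking the alphabetically first
#' allele as minor), so a site whose ALT allele is the common allele is
#' re-oriented to count REF copies.
#'
#' For `dose_tsv` input the file must have samples as rows, markers as
#' columns, a leading `sample_id` column, integer doses 0/1/2 and `NA`
#' for missing; doses are taken as already minor-allele oriented.
#'
#' @param path Input file path.
#' @param format `"vcf"` or `"dose_tsv"`.
#' @return A [genotype_matrix()].
#' @export
read_genotype_matrix <- function(path, format = c("vcf", "dose_tsv")) {
  format <- match.arg(format)
  if (format == "dose_tsv") read_dose_tsv(path) else read_genotype_vcf(path)
}

read_dose_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"sample_id" %in% names(df)) {
    stop("dose TSV needs a leading sample_id column", call. = FALSE)
  }
  ids <- as.character(df$sample_id)
  mat <- as.matrix(df[setdiff(names(df), "sample_id")])
  suppressWarnings(storage.mode(mat) <- "double")
  vals <- mat[!is.na(mat)]
  if (length(vals) && !all(vals %in% c(0, 1, 2))) {
    stop("non-integer or out-of-range dose in TSV", call. = FALSE)
  }
  rownames(mat) <- ids
  genotype_matrix(mat)
}

read_genotype_vcf <- function(path) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1, dimnames = list(NULL, names(fix)))
  multi <- grepl(",", fix[, "ALT"])
  if (any(multi)) {
    warning(sum(multi), " multi-allelic record(s) skipped", call. = FALSE)
  }
  gt <- vcfR::extract.gt(vcf, element = "GT")
  if (is.null(dim(gt))) gt <- matrix(gt, nrow = nrow(fix), dimnames = list(rownames(gt), colnames(gt)))
  keep <- which(!multi)
  ids <- fix[, "ID"]
  ids[is.na(ids) | ids == "."] <- paste0(
    fix[is.na(ids) | ids == ".", "CHROM"], ":", fix[is.na(ids) | ids == ".", "POS"])
  n_samp <- ncol(gt)
  dose <- matrix(NA_real_, nrow = n_samp, ncol = length(keep),
                 dimnames = list(colnames(gt), ids[keep]))
  minor <- major <- character(length(keep))
  for (k in seq_along(keep)) {
    i <- keep[k]
    alt_count <- alt_dose_from_gt(gt[i, ])
    ref <- fix[i, "REF"]; alt <- fix[i, "ALT"]
    nm <- alt_count[!is.na(alt_count)]
    alt_freq <- if (length(nm)) sum(nm) / (2 * length(nm)) else 0
    alt_is_minor <- alt_freq < 0.5 ||
      (alt_freq == 0.5 && alt <= ref)  # tie: alphabetically first allele is minor
    if (alt_is_minor) {
      dose[, k] <- alt_count
      minor[k] <- alt; major[k] <- ref
    } else {
      dose[, k] <- 2 - alt_count
      minor[k] <- ref; major[k] <- alt
    }
  }
  genotype_matrix(dose, tibble::tibble(
    marker_id = ids[keep], gene_label = NA_character_,
    minor_allele = minor, major_allele = major
  ))
}

alt_dose_from_gt <- function(gt) {
  vapply(gt, function(x) {
    if (is.na(x) || x %in% c(".", "./.", ".|.")) return(NA_real_)
    alleles <- strsplit(x, "[/|]")[[1]]
    if (any(alleles == ".")) return(NA_real_)
    sum(alleles != "0")
  }, numeric(1))
}

#' Write a genotype matrix as a dose TSV
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_dose_tsv <- function(g, path) {
  df <- data.frame(sample_id = rownames(g$dose), g$dose,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix as a minimal VCF
#'
#' Emits a VCF 4.2 file with GT-only genotypes on synthetic chromosome
#' coordinates (marker order preserved); minor/major alleles become
#' ALT/REF when allele tokens are available, otherwise A/B placeholders.
#' Heterozygous and homozygous doses are written unphased.
#'
#' @param g A [genotype_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_genotype_vcf <- function(g, path) {
  v <- g$variants
  ref <- ifelse(is.na(v$major_allele), "A", v$major_allele)
  alt <- ifelse(is.na(v$minor_allele), "C", v$minor_allele)
  gt_code <- c(`0` = "0/0", `1` = "0/1", `2` = "1/1")
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", rownames(g$dose)), collapse = "\t")
  )
  body <- vapply(seq_len(ncol(g$dose)), function(j) {
    d <- g$dose[, j]
    gt <- ifelse(is.na(d), "./.", gt_code[as.character(d)])
    paste(c("1", j, v$marker_id[j], ref[j], alt[j], ".", "PASS", ".",
            "GT", gt), collapse = "\t")
  }, character(1))
  writeLines(c(lines, body), path)
  invisible(path)
}

#' Derive the APOE epsilon-4 dose from the two coding SNPs
#'
#' The APOE epsilon haplotypes are defined by rs429358 and rs7412:
#' epsilon-4 carries rs429358-C together with rs7412-C. Under unphased
#' genotypes the epsilon-4 dose is `min(rs429358 C dose, 2 - rs7412 T dose)`
#' restricted by the standard convention that the ambiguous
#' rs429358 C/T + rs7412 C/T double heterozygote is called
#' epsilon-2/epsilon-4 (dose 1); set `ambiguous_het = 0` to call it
#' epsilon-1/epsilon-3 instead.
#'
#' @param rs429358_dose Per-sample dose of the rs429358 C allele (0/1/2/NA).
#' @param rs7412_dose Per-sample dose of the rs7412 T allele (0/1/2/NA).
#' @param ambiguous_het Dose assigned to the double heterozygote
#'   (default 1, the epsilon-2/epsilon-4 convention).
#' @return Integer vector of epsilon-4 doses with `NA` where either
#'   input is missing.
#' @export
derive_apoe_e4_dose <- function(rs429358_dose, rs7412_dose, ambiguous_het = 1) {
  if (length(rs429358_dose) != length(rs7412_dose)) {
    stop("rs429358 and rs7412 dose vectors differ in length", call. = FALSE)
  }
  c_dose <- as.numeric(rs429358_dose)   # C at rs429358 (e4-defining)
  t_dose <- as.numeric(rs7412_dose)     # T at rs7412 (e2-defining)
  out <- pmin(c_dose, 2 - t_dose)
  amb <- !is.na(c_dose) & !is.na(t_dose) & c_dose == 1 & t_dose == 1
  out[amb] <- ambiguous_het
  out[is.na(c_dose) | is.na(t_dose)] <- NA_real_
  out
}
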