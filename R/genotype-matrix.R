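#' Construct a genotype dose matrix
#'
#' Container for additive minor-allele dose genotypes: a numeric matrix of
#' samples (rows) by markers (columns) with entries in \{0, 1, 2\} and `NA`
#' for missing calls, together with a per-marker variant table.
#'
#' @param dose Numeric matrix, samples x markers, values 0/1/2 or `NA`.
#'   Row names are sample ids, column names marker ids.
#' @param variants A data frame with one row per marker and columns
#'   `marker_id`, and optionally `gene_label`, `minor_allele`,
#'   `major_allele`. Defaults are derived from `colnames(dose)`.
#'
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(dose, variants = NULL) {
  dose <- as.matrix(dose)
  storage.mode(dose) <- "double"
  if (is.null(rownames(dose)) && nrow(dose) > 0) {
    rownames(dose) <- paste0("S", seq_len(nrow(dose)))
  }
  if (is.null(colnames(dose)) && ncol(dose) > 0) {
    colnames(dose) <- paste0("M", seq_len(ncol(dose)))
  }
  bad <- dose[!is.na(dose)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("genotype doses must be 0, 1, 2 or NA", call. = FALSE)
  }
  if (anyDuplicated(rownames(dose))) {
    stop("duplicate sample ids in genotype matrix", call. = FALSE)
  }
  if (anyDuplicated(colnames(dose))) {
    stop("duplicate marker ids in genotype matrix", call. = FALSE)
  }
  marker_ids <- colnames(dose)
  if (is.null(marker_ids)) marker_ids <- character(0)  # 0-column matrix
  if (is.null(variants)) {
    variants <- tibble::tibble(marker_id = marker_ids)
  }
  variants <- tibble::as_tibble(variants)
  if (!"marker_id" %in% names(variants)) {
    if (nrow(variants) == 0 && length(marker_ids) == 0) {
      variants <- tibble::tibble(marker_id = character(0))
    } else {
      stop("variant table needs a marker_id column", call. = FALSE)
    }
  }
  for (col in c("gene_label", "minor_allele", "major_allele")) {
    if (!col %in% names(variants)) variants[[col]] <- NA_character_
  }
  if (!identical(variants$marker_id, marker_ids)) {
    stop("variant table must match matrix columns in order", call. = FALSE)
  }
  structure(list(dose = dose, variants = variants), class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf(
    "<genotype_matrix> %d samples x %d markers (%.1f%% missing)\n",
    nrow(x$dose), ncol(x$dose),
    100 * mean(is.na(x$dose))
  ))
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dose)

#' Sample ids of a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Character vector of sample ids.
#' @export
sample_ids <- function(g) rownames(g$dose)

#' Marker ids of a genotype matrix
#' @param g A `genotype_matrix`.
#' @return Character vector of marker ids.
#' @export
marker_ids <- function(g) colnames(g$dose)

#' Subset a genotype matrix
#'
#' @param x A `genotype_matrix`.
#' @param i Sample selector (names, indices or logical).
#' @param j Marker selector.
#' @param ... Unused.
#' @return A `genotype_matrix` restricted to the selection.
#' @export
`[.genotype_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$dose))
  if (missing(j)) j <- seq_len(ncol(x$dose))
  dose <- x$dose[i, j, drop = FALSE]
  keep <- match(colnames(dose), x$variants$marker_id)
  genotype_matrix(dose, x$variants[keep, , drop = FALSE])
}

#' Tidy a genotype matrix into long form
#'
#' @param x A `genotype_matrix`.
#' @param ... Unused.
#' @return A tibble with columns `sample_id`, `marker_id`, `dose`.
#' @export
tidy.genotype_matrix <- function(x, ...) {
  tibble::tibble(
    sample_id = rep(rownames(x$dose), times = ncol(x$dose)),
    marker_id = rep(colnames(x$dose), each = nrow(x$dose)),
    dose = as.vector(x$dose)
  )
}

#' Per-sample dose vector for one marker
#' @param g A `genotype_matrix`.
#' @param marker Marker id.
#' @return Named numeric vector of doses.
#' @export
marker_dose <- function(g, marker) {
  if (!marker %in% colnames(g$dose)) {
    stop("unknown marker: ", marker, call. = FALSE)
  }
  g$dose[, marker]
}
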