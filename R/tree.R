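#' Decision-tree configuration
#'
#' @param kappa_weight Trade-off r between sensitivity and specificity in
#'   the split criterion (0.5 weighs them equally).
#' @param min_subgroup Smallest admissible child size (both sides of a
#'   split must reach it; nodes below twice this size become leaves).
#' @param alpha Significance floor: a split whose multiple-testing
#'   corrected chi-square p exceeds this is rejected.
#' @param max_path_splits Maximum number of splits along any root-to-leaf
#'   path (interaction depth cap).
#' @param correction `"bonferroni_predictors"` (multiply the chi-square p
#'   by the number of predictors searched at the node, default) or
#'   `"bonferroni_cuts"` (by the number of admissible predictor/cut
#'   pairs).
#' @param criterion `"weighted_sesp"` (r*Se + (1-r)*Sp, default) or
#'   `"kraemer_kappa"` (chance-corrected weighted kappa; equals Cohen's
#'   kappa at r = 0.5).
#' @return A list of class `tree_config`.
#' @export
tree_config <- function(kappa_weight = 0.5, min_subgroup = 10, alpha = 0.01,
                        max_path_splits = 4,
                        correction = c("bonferroni_predictors", "bonferroni_cuts"),
                        criterion = c("weighted_sesp", "kraemer_kappa")) {
  stopifnot(kappa_weight >= 0, kappa_weight <= 1, min_subgroup >= 1,
            alpha > 0, alpha <= 1, max_path_splits >= 1)
  structure(list(
    kappa_weight = kappa_weight, min_subgroup = min_subgroup, alpha = alpha,
    max_path_splits = max_path_splits,
    correction = match.arg(correction), criterion = match.arg(criterion)
  ), class = "tree_config")
}

#' Candidate split cuts for a predictor
#'
#' All rules are of the form `value >= cut`. Dose predictors yield cuts
#' at 1 and 2, binary predictors at 1, continuous predictors one cut at
#' each distinct observed value except the minimum (everyone satisfies
#' `>= min`, a degenerate split).
#'
#' @param values Per-sample predictor values (`NA` allowed).
#' @param kind `"dose"`, `"binary"` or `"continuous"`.
#' @return Numeric vector of cuts (possibly empty).
#' @export
candidate_splits <- function(values, kind = c("continuous", "dose", "binary")) {
  kind <- match.arg(kind)
  v <- values[!is.na(values)]
  if (length(unique(v)) < 2) return(numeric(0))
  switch(kind,
    dose = c(1, 2),
    binary = 1,
    continuous = sort(unique(v))[-1]
  )
}

#' Split quality as a weighted diagnostic test
#'
#' Treats the split's positive side as a diagnostic test for case
#' status. `weighted_sesp` scores it `r*Se + (1-r)*Sp`; `kraemer_kappa`
#' applies the chance-corrected weighted kappa
#' `P*P' * (Se + Sp - 1) / (r*P*Q' + (1-r)*P'*Q)` with P the case
#' prevalence and Q the positive rate, which at r = 0.5 reduces to
#' Cohen's kappa of the 2x2 table.
#'
#' @param labels Case indicators at the node.
#' @param positive Logical: test-positive side membership.
#' @param kappa_weight Weight r.
#' @param criterion `"weighted_sesp"` or `"kraemer_kappa"`.
#' @return Scalar quality.
#' @export
split_quality <- function(labels, positive, kappa_weight = 0.5,
                          criterion = c("weighted_sesp", "kraemer_kappa")) {
  criterion <- match.arg(criterion)
  y <- as.numeric(labels)
  if (!any(y == 1) || !any(y == 0)) {
    stop("split quality undefined in a single-class node", call. = FALSE)
  }
  r <- kappa_weight
  se <- sum(positive & y == 1) / sum(y == 1)
  sp <- sum(!positive & y == 0) / sum(y == 0)
  if (criterion == "weighted_sesp") return(r * se + (1 - r) * sp)
  p <- mean(y == 1); q <- mean(positive)
  denom <- r * p * (1 - q) + (1 - r) * (1 - p) * q
  if (denom == 0) return(0)
  p * (1 - p) * (se + sp - 1) / denom
}

#' Best admissible split at a node
#'
#' Exhaustively scores every (predictor, cut) pair: samples with a
#' missing value of the predictor are left out of that pair's
#' evaluation, the side with the higher case fraction is designated
#' test-positive, both sides must reach `min_subgroup`, and the pair
#' maximising [split_quality()] wins (ties broken by predictor manifest
#' order, then lower cut). The winner's Pearson chi-square p (1 df, no
#' continuity correction) is Bonferroni-corrected; the split is rejected
#' if the corrected p exceeds `alpha`.
#'
#' @param data Data frame of predictor values for the node's samples.
#' @param labels Case indicators for the node's samples.
#' @param manifest Tibble with columns `name`, `kind` defining predictor
#'   order and typing; defaults to treating all columns as continuous.
#' @param config A [tree_config()].
#' @return `NULL` if no admissible significant split, else a list:
#'   `predictor`, `cut`, `positive_side` (`"ge"` or `"lt"`), `quality`,
#'   `chi2`, `p_raw`, `p_corrected`, `n_predictors_searched`,
#'   `n_cuts_searched`.
#' @export
best_split_at_node <- function(data, labels, manifest = NULL,
                               config = tree_config()) {
  if (is.null(manifest)) {
    manifest <- tibble::tibble(name = names(data), kind = "continuous")
  }
  y <- as.numeric(labels)
  best <- NULL
  n_pred <- 0L; n_cuts <- 0L
  for (i in seq_len(nrow(manifest))) {
    pname <- manifest$name[i]
    v <- data[[pname]]
    cuts <- candidate_splits(v, manifest$kind[i])
    searched <- FALSE
    for (cut in cuts) {
      ok <- !is.na(v)
      if (!any(y[ok] == 1) || !any(y[ok] == 0)) next
      ge <- v[ok] >= cut
      if (sum(ge) < config$min_subgroup || sum(!ge) < config$min_subgroup) next
      searched <- TRUE
      n_cuts <- n_cuts + 1L
      case_frac_ge <- mean(y[ok][ge]); case_frac_lt <- mean(y[ok][!ge])
      side <- if (case_frac_ge >= case_frac_lt) "ge" else "lt"
      positive <- if (side == "ge") ge else !ge
      q <- split_quality(y[ok], positive, config$kappa_weight, config$criterion)
      if (is.null(best) || q > best$quality + 1e-12) {
        tab <- table(factor(positive, levels = c(FALSE, TRUE)),
                     factor(y[ok], levels = c(0, 1)))
        ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
        best <- list(predictor = pname, cut = cut, positive_side = side,
                     quality = q, chi2 = unname(ct$statistic),
                     p_raw = ct$p.value)
      }
    }
    if (searched) n_pred <- n_pred + 1L
  }
  if (is.null(best)) return(NULL)
  factor_n <- if (config$correction == "bonferroni_predictors") n_pred else n_cuts
  best$p_corrected <- min(1, best$p_raw * factor_n)
  best$n_predictors_searched <- n_pred
  best$n_cuts_searched <- n_cuts
  if (is.na(best$p_corrected) || best$p_corrected > config$alpha) return(NULL)
  best
}

#' Grow a kappa-weighted ROC decision tree
#'
#' Recursive partitioning: each node is split by [best_split_at_node()]
#' until a stopping rule fires — fewer than twice `min_subgroup` samples
#' (`min_subgroup`), no admissible split (`min_subgroup`), corrected
#' chi-square p above `alpha` (`not_significant`), path length at
#' `max_path_splits` (`max_depth`), or a single-class node (`pure`).
#' Samples missing the split predictor follow the larger child
#' (ties to the positive side).
#'
#' @param data Data frame of predictor values (one row per sample).
#' @param labels Case indicators aligned with `data` rows.
#' @param manifest Predictor manifest (`name`, `kind`); see
#'   [best_split_at_node()].
#' @param config A [tree_config()].
#' @return An object of class `risk_tree`.
#' @export
grow_tree <- function(data, labels, manifest = NULL, config = tree_config()) {
  y <- as.numeric(labels)
  stopifnot(nrow(data) == length(y), !anyNA(y))
  if (!any(y == 1) || !any(y == 0)) {
    stop("root node must contain both classes", call. = FALSE)
  }
  if (is.null(manifest)) {
    manifest <- tibble::tibble(name = names(data), kind = "continuous")
  }
  id_counter <- new.env()
  id_counter$next_id <- 1L

  build <- function(idx, depth, path) {
    node <- list(
      id = id_counter$next_id, depth = depth,
      n_case = sum(y[idx] == 1), n_control = sum(y[idx] == 0),
      path = path, split = NULL, leaf_reason = NULL,
      chi2_p_raw = NA_real_, chi2_p_corrected = NA_real_,
      children = NULL
    )
    id_counter$next_id <- id_counter$next_id + 1L
    if (node$n_case == 0 || node$n_control == 0) {
      node$leaf_reason <- "pure"; return(node)
    }
    if (depth >= config$max_path_splits) {
      node$leaf_reason <- "max_depth"; return(node)
    }
    if (length(idx) < 2 * config$min_subgroup) {
      node$leaf_reason <- "min_subgroup"; return(node)
    }
    bs <- best_split_at_node(data[idx, , drop = FALSE], y[idx], manifest, config)
    if (is.null(bs)) {
      # distinguish "no admissible cut" from "not significant"
      relaxed <- config; relaxed$alpha <- 1
      any_split <- best_split_at_node(data[idx, , drop = FALSE], y[idx],
                                      manifest, relaxed)
      node$leaf_reason <- if (is.null(any_split)) "min_subgroup" else "not_significant"
      if (!is.null(any_split)) {
        node$chi2_p_raw <- any_split$p_raw
        node$chi2_p_corrected <- any_split$p_corrected
      }
      return(node)
    }
    node$split <- bs
    node$chi2_p_raw <- bs$p_raw
    node$chi2_p_corrected <- bs$p_corrected
    v <- data[[bs$predictor]][idx]
    ge <- !is.na(v) & v >= bs$cut
    lt <- !is.na(v) & v < bs$cut
    pos_is_ge <- bs$positive_side == "ge"
    pos <- if (pos_is_ge) ge else lt
    neg <- if (pos_is_ge) lt else ge
    miss <- is.na(v)
    if (any(miss)) {
      to_pos <- sum(pos) >= sum(neg)
      if (to_pos) pos <- pos | miss else neg <- neg | miss
    }
    cond <- function(positive) {
      op <- if (pos_is_ge == positive) ">=" else "<"
      sprintf("%s %s %g", bs$predictor, op, bs$cut)
    }
    node$children <- list(
      positive = build(idx[pos], depth + 1L, c(path, cond(TRUE))),
      negative = build(idx[neg], depth + 1L, c(path, cond(FALSE)))
    )
    node
  }

  root <- build(seq_along(y), 0L, character(0))
  structure(list(root = root, config = config, manifest = manifest,
                 n_case = sum(y == 1), n_control = sum(y == 0)),
            class = "risk_tree")
}

walk_nodes <- function(node, f, acc = list()) {
  acc <- c(acc, list(f(node)))
  if (!is.null(node$children)) {
    acc <- walk_nodes(node$children$positive, f, acc)
    acc <- walk_nodes(node$children$negative, f, acc)
  }
  acc
}

#' Per-node path-membership classification metrics
#'
#' Treats membership in each node (the conjunction of its path
#' conditions) as a diagnostic test against the full root sample:
#' PVP = cases in node / node size, PVN = controls in node / node size,
#' sensitivity = cases in node / all cases, specificity = controls
#' outside / all controls, percent correct = (cases in node + controls
#' outside) / total.
#'
#' @param tree A fitted `risk_tree`.
#' @return A tibble with one row per node: `id`, `depth`, `path`,
#'   `n_case`, `n_control`, `leaf`, `leaf_reason`, `split_predictor`,
#'   `split_cut`, `chi2_p_raw`, `chi2_p_corrected`, `sensitivity`,
#'   `specificity`, `pvp`, `pvn`, `percent_correct`.
#' @export
node_path_metrics <- function(tree) {
  tot_case <- tree$n_case; tot_ctrl <- tree$n_control
  rows <- walk_nodes(tree$root, function(nd) {
    n <- nd$n_case + nd$n_control
    tibble::tibble(
      id = nd$id, depth = nd$depth,
      path = paste(nd$path, collapse = " & "),
      n_case = nd$n_case, n_control = nd$n_control,
      leaf = is.null(nd$split),
      leaf_reason = if (is.null(nd$leaf_reason)) NA_character_ else nd$leaf_reason,
      split_predictor = if (is.null(nd$split)) NA_character_ else nd$split$predictor,
      split_cut = if (is.null(nd$split)) NA_real_ else nd$split$cut,
      chi2_p_raw = nd$chi2_p_raw, chi2_p_corrected = nd$chi2_p_corrected,
      sensitivity = nd$n_case / tot_case,
      specificity = (tot_ctrl - nd$n_control) / tot_ctrl,
      pvp = nd$n_case / n, pvn = nd$n_control / n,
      percent_correct = (nd$n_case + (tot_ctrl - nd$n_control)) /
        (tot_case + tot_ctrl)
    )
  })
  dplyr::bind_rows(rows)
}

#' @export
tidy.risk_tree <- function(x, ...) node_path_metrics(x)

#' @export
glance.risk_tree <- function(x, ...) {
  nodes <- node_path_metrics(x)
  tibble::tibble(
    n_nodes = nrow(nodes), n_leaves = sum(nodes$leaf),
    max_depth = max(nodes$depth),
    n_case = x$n_case, n_control = x$n_control
  )
}

#' @export
print.risk_tree <- function(x, ...) {
  cat(export_tree(x, "text"))
  invisible(x)
}

node_to_list <- function(nd) {
  out <- list(
    id = nd$id, depth = nd$depth, path = nd$path,
    n_case = nd$n_case, n_control = nd$n_control,
    leaf_reason = nd$leaf_reason,
    chi2_p_raw = nd$chi2_p_raw, chi2_p_corrected = nd$chi2_p_corrected
  )
  if (!is.null(nd$split)) {
    out$split <- nd$split[c("predictor", "cut", "positive_side", "quality",
                            "chi2", "p_raw", "p_corrected")]
    out$children <- list(positive = node_to_list(nd$children$positive),
                         negative = node_to_list(nd$children$negative))
  }
  out
}

list_to_node <- function(lst) {
  nd <- list(
    id = lst$id, depth = lst$depth,
    n_case = lst$n_case, n_control = lst$n_control,
    path = if (is.null(lst$path)) character(0) else as.character(lst$path),
    split = NULL, leaf_reason = lst$leaf_reason,
    chi2_p_raw = if (is.null(lst$chi2_p_raw)) NA_real_ else lst$chi2_p_raw,
    chi2_p_corrected = if (is.null(lst$chi2_p_corrected)) NA_real_ else lst$chi2_p_corrected,
    children = NULL
  )
  if (!is.null(lst$split)) {
    nd$split <- lst$split
    nd$children <- list(positive = list_to_node(lst$children$positive),
                        negative = list_to_node(lst$children$negative))
  }
  nd
}

#' Export a fitted tree
#'
#' `"json"` is lossless and round-trips through [tree_from_json()];
#' `"dot"` renders a Graphviz graph; `"text"` an indented outline with
#' branch labels such as `age >= 77`.
#'
#' @param tree A `risk_tree`.
#' @param format `"json"`, `"dot"` or `"text"`.
#' @return A character scalar (the document).
#' @export
export_tree <- function(tree, format = c("json", "dot", "text")) {
  format <- match.arg(format)
  if (format == "json") {
    doc <- list(
      config = unclass(tree$config),
      manifest = as.data.frame(tree$manifest),
      n_case = tree$n_case, n_control = tree$n_control,
      root = node_to_list(tree$root)
    )
    return(as.character(jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA,
                                         null = "null")))
  }
  nodes <- node_path_metrics(tree)
  if (format == "dot") {
    lab <- sprintf(
      "n%d [label=\"%s\\ncases %d / controls %d\"];", nodes$id,
      ifelse(nodes$leaf, paste0("leaf (", nodes$leaf_reason, ")"),
             paste0(nodes$split_predictor, " >= ", nodes$split_cut)),
      nodes$n_case, nodes$n_control
    )
    edges <- unlist(walk_nodes(tree$root, function(nd) {
      if (is.null(nd$children)) return(character(0))
      c(sprintf("n%d -> n%d [label=\"positive\"];", nd$id, nd$children$positive$id),
        sprintf("n%d -> n%d [label=\"negative\"];", nd$id, nd$children$negative$id))
    }))
    return(paste(c("digraph risk_tree {", lab, edges, "}"), collapse = "\n"))
  }
  lines <- vapply(seq_len(nrow(nodes)), function(i) {
    nd <- nodes[i, ]
    cond <- if (nd$path == "") "<root>" else sub(".*& ", "", nd$path)
    sprintf("%s%s  [cases %d, controls %d]%s",
            strrep("  ", nd$depth), cond, nd$n_case, nd$n_control,
            ifelse(nd$leaf, paste0("  <leaf:", nd$leaf_reason, ">"), ""))
  }, character(1))
  paste(lines, collapse = "\n")
}

#' Rebuild a tree from its JSON export
#'
#' @param json JSON string (or path to a file containing one).
#' @return A `risk_tree` equal to the exported one.
#' @export
tree_from_json <- function(json) {
  if (length(json) == 1 && file.exists(json)) json <- paste(readLines(json), collapse = "\n")
  doc <- jsonlite::fromJSON(json, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cfg <- do.call(tree_config, doc$config)
  manifest <- tibble::tibble(
    name = vapply(doc$manifest, function(r) r$name, character(1)),
    kind = vapply(doc$manifest, function(r) r$kind, character(1))
  )
  structure(list(root = list_to_node(doc$root), config = cfg,
                 manifest = manifest,
                 n_case = doc$n_case, n_control = doc$n_control),
            class = "risk_tree")
}
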