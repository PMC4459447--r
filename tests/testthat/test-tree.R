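test_that("candidate cuts follow predictor typing", {
  expect_equal(candidate_splits(c(0, 1, 2, 1), "dose"), c(1, 2))
  expect_equal(candidate_splits(c(0, 1, 0, 1), "binary"), 1)
  expect_equal(candidate_splits(c(66, 70, 77, 70), "continuous"), c(70, 77))
  expect_equal(candidate_splits(rep(1, 5), "binary"), numeric(0))
  expect_equal(candidate_splits(c(NA, NA, 3), "continuous"), numeric(0))
})

test_that("split quality: weighted Se/Sp arithmetic and the kappa oracle", {
  # perfect split
  y <- c(1, 1, 1, 0, 0, 0)
  expect_equal(split_quality(y, y == 1, 0.5), 1)
  # Se 0.8, Sp 0.6 at r = 0.5 -> 0.7
  y2 <- c(rep(1, 10), rep(0, 10))
  pos <- c(rep(TRUE, 8), rep(FALSE, 2), rep(TRUE, 4), rep(FALSE, 6))
  expect_equal(split_quality(y2, pos, 0.5), 0.7)
  expect_equal(split_quality(y2, pos, 1), 0.8)
  expect_equal(split_quality(y2, pos, 0), 0.6)

  # Kraemer kappa at r = 0.5 equals Cohen's kappa from the agreement formula
  # 2x2: TP 40, FN 10, FP 20, TN 30
  y3 <- c(rep(1, 50), rep(0, 50))
  pos3 <- c(rep(TRUE, 40), rep(FALSE, 10), rep(TRUE, 20), rep(FALSE, 30))
  q <- split_quality(y3, pos3, 0.5, criterion = "kraemer_kappa")
  expect_equal(q, 0.4, tolerance = 1e-12)
  po <- (40 + 30) / 100
  pe <- (50 / 100) * (60 / 100) + (50 / 100) * (40 / 100)
  expect_equal(q, (po - pe) / (1 - pe), tolerance = 1e-12)
  # random tables: identity holds generally at r = 0.5
  set.seed(17)
  for (i in 1:20) {
    yy <- rbinom(80, 1, 0.4); pp <- rbinom(80, 1, 0.5) == 1
    if (length(unique(yy)) < 2) next
    qq <- split_quality(yy, pp, 0.5, criterion = "kraemer_kappa")
    tab <- table(pp, yy)
    po <- sum(diag(tab[c("TRUE", "FALSE"), c("1", "0")])) / 80
    pe <- (mean(yy) * mean(pp)) + (1 - mean(yy)) * (1 - mean(pp))
    expect_equal(qq, (po - pe) / (1 - pe), tolerance = 1e-12)
  }
  expect_error(split_quality(rep(1, 5), rep(TRUE, 5)), "single-class")
})

test_that("a perfectly separating predictor is always chosen with quality 1", {
  set.seed(23)
  n <- 60
  y <- rep(c(1, 0), each = n / 2)
  data <- data.frame(
    perfect = as.numeric(y == 1),
    noise1 = sample(0:2, n, TRUE),
    noise2 = runif(n, 60, 90)
  )
  manifest <- tibble::tibble(name = c("perfect", "noise1", "noise2"),
                             kind = c("binary", "dose", "continuous"))
  bs <- best_split_at_node(data, y, manifest, tree_config())
  expect_equal(bs$predictor, "perfect")
  expect_equal(bs$quality, 1)
  expect_equal(bs$positive_side, "ge")
})

test_that("best split equals the exhaustive oracle on random fixtures", {
  set.seed(29)
  cfg <- tree_config(min_subgroup = 5)
  for (i in 1:20) {
    n <- sample(30:50, 1)
    data <- data.frame(
      sex = rbinom(n, 1, 0.5),
      age = sample(65:95, n, TRUE),
      d1 = sample(0:2, n, TRUE),
      d2 = sample(0:2, n, TRUE),
      d3 = sample(0:2, n, TRUE)
    )
    if (i %% 3 == 0) data$age[sample(n, 3)] <- NA  # missing values too
    y <- rbinom(n, 1, plogis(-0.5 + 0.5 * data$d1))
    if (length(unique(y)) < 2) next
    manifest <- tibble::tibble(name = names(data),
                               kind = c("binary", "continuous", "dose",
                                        "dose", "dose"))
    got <- best_split_at_node(data, y, manifest, cfg)
    want <- oracle_best_split(data, y, manifest, cfg)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got[c("predictor", "cut", "positive_side")],
                   want[c("predictor", "cut", "positive_side")])
      expect_equal(got$quality, want$quality, tolerance = 1e-12)
      expect_equal(got$chi2, want$chi2, tolerance = 1e-9)
      expect_equal(got$p_corrected, want$p_corrected, tolerance = 1e-9)
    }
  }
})

test_that("pure-noise nodes are declared unsplittable almost always", {
  set.seed(37)
  none <- sum(vapply(1:60, function(s) {
    n <- 200
    data <- data.frame(a = sample(0:2, n, TRUE), b = sample(0:2, n, TRUE),
                       c = sample(0:2, n, TRUE), d = rbinom(n, 1, 0.5),
                       e = sample(0:2, n, TRUE), f = sample(0:2, n, TRUE))
    y <- rbinom(n, 1, 0.4)
    manifest <- tibble::tibble(name = names(data),
                               kind = c("dose", "dose", "dose", "binary",
                                        "dose", "dose"))
    is.null(best_split_at_node(data, y, manifest, tree_config()))
  }, logical(1)))
  expect_gte(none / 60, 0.95)
})

test_that("grow_tree matches the recursive oracle and conserves counts", {
  set.seed(41)
  cfg <- tree_config(min_subgroup = 5, alpha = 0.05)
  for (i in 1:8) {
    n <- 40 + 5 * i
    data <- data.frame(
      g1 = sample(0:2, n, TRUE), g2 = sample(0:2, n, TRUE),
      age = sample(65:90, n, TRUE)
    )
    # planted 2-level structure: g1 drives risk, age modifies it among carriers
    y <- rbinom(n, 1, plogis(-2 + 2.2 * (data$g1 >= 1) +
                               1.5 * (data$age >= 78)))
    if (length(unique(y)) < 2) next
    manifest <- tibble::tibble(name = names(data),
                               kind = c("dose", "dose", "continuous"))
    tree <- grow_tree(data, y, manifest, cfg)
    want <- oracle_grow(data, y, manifest, cfg)
    expect_equal(tree_signature(tree$root), tree_signature(want))

    # invariants on the fitted tree
    nodes <- node_path_metrics(tree)
    expect_true(all(nodes$depth <= cfg$max_path_splits))
    expect_true(all(nodes$leaf_reason[nodes$leaf] %in%
                      c("min_subgroup", "not_significant", "max_depth", "pure")))
    internal <- nodes[!nodes$leaf, ]
    expect_true(all(internal$chi2_p_corrected <= cfg$alpha))
    check_sums <- function(nd) {
      if (is.null(nd$children)) return(invisible())
      expect_equal(nd$n_case, nd$children$positive$n_case +
                     nd$children$negative$n_case)
      expect_equal(nd$n_control, nd$children$positive$n_control +
                     nd$children$negative$n_control)
      check_sums(nd$children$positive); check_sums(nd$children$negative)
    }
    check_sums(tree$root)
  }
  expect_error(grow_tree(data.frame(a = 1:4), rep(0, 4)), "both classes")
})

test_that("depth cap and min-subgroup rules terminate growth", {
  set.seed(47)
  n <- 400
  data <- data.frame(x = runif(n))
  y <- as.numeric(data$x >= stats::median(data$x))  # splits forever if allowed
  cfg <- tree_config(max_path_splits = 2, min_subgroup = 10, alpha = 0.05)
  tree <- grow_tree(data, y, tibble::tibble(name = "x", kind = "continuous"),
                    cfg)
  nodes <- node_path_metrics(tree)
  expect_lte(max(nodes$depth), 2)
  small <- grow_tree(data[1:15, , drop = FALSE], y[1:15],
                     tibble::tibble(name = "x", kind = "continuous"), cfg)
  expect_true(is.null(small$root$split))
})

test_that("node path metrics treat node membership as the test", {
  set.seed(51)
  n <- 200
  data <- data.frame(g = sample(0:2, n, TRUE), z = sample(0:2, n, TRUE))
  y <- rbinom(n, 1, plogis(-1.2 + 1.6 * (data$g >= 1)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  tree <- grow_tree(data, y, tibble::tibble(name = c("g", "z"), kind = "dose"),
                    tree_config(alpha = 0.05))
  nodes <- node_path_metrics(tree)
  root <- nodes[nodes$depth == 0, ]
  expect_equal(root$sensitivity, 1)
  expect_equal(root$specificity, 0)
  expect_equal(root$pvp, sum(y == 1) / n)
  # every node: recompute from counts
  expect_equal(nodes$pvp, nodes$n_case / (nodes$n_case + nodes$n_control))
  expect_equal(nodes$sensitivity, nodes$n_case / sum(y == 1))
  expect_equal(nodes$specificity,
               (sum(y == 0) - nodes$n_control) / sum(y == 0))
  # a hypothetical pure node of 20/100 cases, 0 controls
  fake <- list(id = 9L, depth = 2L, n_case = 20, n_control = 0,
               path = c("g >= 1", "z >= 2"), split = NULL,
               leaf_reason = "pure", chi2_p_raw = NA_real_,
               chi2_p_corrected = NA_real_, children = NULL)
  ft <- structure(list(root = fake, config = tree_config(),
                       manifest = tree$manifest,
                       n_case = 100, n_control = 100), class = "risk_tree")
  fm <- node_path_metrics(ft)
  expect_equal(fm$pvp, 1)
  expect_equal(fm$sensitivity, 0.2)
  expect_equal(fm$specificity, 1)
})

test_that("tree exports round-trip and enumerate every node", {
  set.seed(61)
  n <- 150
  data <- data.frame(g = sample(0:2, n, TRUE), age = sample(65:95, n, TRUE))
  y <- rbinom(n, 1, plogis(-1 + 1.4 * (data$g >= 1)))
  if (length(unique(y)) < 2) y[1:2] <- c(0, 1)
  tree <- grow_tree(data, y,
                    tibble::tibble(name = c("g", "age"),
                                   kind = c("dose", "continuous")),
                    tree_config(alpha = 0.05))
  json <- export_tree(tree, "json")
  back <- tree_from_json(json)
  expect_equal(tree_signature(back$root), tree_signature(tree$root))
  expect_equal(node_path_metrics(back), node_path_metrics(tree),
               tolerance = 1e-12)
  expect_equal(unclass(back$config), unclass(tree$config))

  nodes <- node_path_metrics(tree)
  dot <- export_tree(tree, "dot")
  expect_equal(length(gregexpr("label=", dot)[[1]]) -
                 sum(nodes$leaf == FALSE) * 2, nrow(nodes))
  txt <- export_tree(tree, "text")
  expect_equal(length(strsplit(txt, "\n")[[1]]), nrow(nodes))
  expect_error(export_tree(tree, "xml"), "arg")

  # single-leaf tree exports one node
  lone <- grow_tree(data.frame(x = rep(c(0, 1), 8)), rep(c(1, 0), 8),
                    tibble::tibble(name = "x", kind = "binary"),
                    tree_config(min_subgroup = 10))
  expect_equal(nrow(node_path_metrics(lone)), 1)
})
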