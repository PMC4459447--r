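test_that("genotype_r2 is the squared dose correlation on complete pairs", {
  expect_equal(genotype_r2(c(0, 1, 2, 1), c(0, 1, 2, 1)), 1)
  expect_equal(genotype_r2(c(0, 0, 1, 1), c(0, 1, 0, 1)), 0)
  set.seed(9)
  a <- sample(0:2, 30, replace = TRUE)
  b <- sample(0:2, 30, replace = TRUE)
  # brute-force sums oracle
  n <- 30
  num <- (n * sum(a * b) - sum(a) * sum(b))^2
  den <- (n * sum(a^2) - sum(a)^2) * (n * sum(b^2) - sum(b)^2)
  expect_equal(genotype_r2(a, b), num / den, tolerance = 1e-12)
  # pairwise-complete handling
  a2 <- a; a2[1:3] <- NA
  expect_equal(genotype_r2(a2, b), genotype_r2(a[-(1:3)], b[-(1:3)]))
  expect_error(genotype_r2(rep(1, 10), sample(0:2, 10, replace = TRUE)),
               "constant")
})

ranked_fixture <- function(g) {
  tibble::tibble(
    marker_id = colnames(g$dose),
    or = 2, beta = log(2), se = 0.3,
    stat = seq(5, 5 - 0.1 * (ncol(g$dose) - 1), by = -0.1),
    p = seq(1e-5, by = 1e-5, length.out = ncol(g$dose)),
    maf = 0.3, n_used = nrow(g$dose), separated = FALSE,
    rank = seq_len(ncol(g$dose))
  )
}

test_that("greedy LD pruning keeps the top marker of each linked set", {
  set.seed(15)
  n <- 200
  a <- rbinom(n, 2, 0.4)
  c_ <- rbinom(n, 2, 0.4)
  # chain: A-B r2 high, B-C r2 high, A-C low
  b <- a; flip <- runif(n) < 0.3; b[flip] <- c_[flip]
  dose <- cbind(A = a, B = b, C = c_)
  g <- genotype_matrix(dose)
  r2ab <- genotype_r2(a, b); r2bc <- genotype_r2(b, c_); r2ac <- genotype_r2(a, c_)
  # pick a threshold between the pair r2s so the chain case is exercised
  thr <- (max(r2ac, 0) + min(r2ab, r2bc)) / 2
  expect_true(r2ab > thr && r2bc > thr && r2ac < thr)
  pruned <- ld_prune_ranked(ranked_fixture(g), g, threshold = thr)
  expect_equal(pruned$marker_id, c("A", "C"))

  # exact duplicate of the top marker is removed wherever it ranks
  g2 <- genotype_matrix(cbind(A = a, X = c_, dupA = a))
  pruned2 <- ld_prune_ranked(ranked_fixture(g2), g2, threshold = 0.8)
  expect_equal(pruned2$marker_id, c("A", "X"))

  # nothing linked -> identity
  g3 <- random_genotype_fixture(n = 300, m = 6, seed = 2)
  r <- ranked_fixture(g3)
  expect_equal(ld_prune_ranked(r, g3, 0.8)$marker_id, r$marker_id)
})

test_that("after pruning every retained pair is at or below the threshold", {
  for (seed in 1:4) {
    g <- random_genotype_fixture(n = 80, m = 12, seed = seed)
    # plant correlated copies
    g <- plant_ld_proxy(g, "m1", fidelity = 0.97, seed = seed + 100)
    g <- plant_ld_proxy(g, "m5", fidelity = 0.95, seed = seed + 200)
    pruned <- ld_prune_ranked(ranked_fixture(g), g, threshold = 0.8)
    ids <- pruned$marker_id
    for (i in seq_along(ids)) for (j in seq_len(i - 1)) {
      expect_lte(genotype_r2(g$dose[, ids[i]], g$dose[, ids[j]]), 0.8)
    }
  }
})

test_that("risk-allele orientation flips protective minor alleles", {
  row <- function(or) tibble::tibble(marker_id = "m", or = or)
  expect_equal(orient_risk_allele(row(0.1))$risk_allele, "major")
  expect_equal(orient_risk_allele(row(2.83))$risk_allele, "minor")
  expect_equal(orient_risk_allele(row(1.0))$risk_allele, "minor")
  expect_equal(orient_risk_allele(row(0.5))$source_or, 0.5)
  expect_error(orient_risk_allele(row(NA_real_)), "odds ratio")
})

test_that("nested score sets grow one marker at a time with A.. labels", {
  g <- random_genotype_fixture(n = 50, m = 30, seed = 6)
  r <- ranked_fixture(g)
  sets <- build_nested_score_sets(r[1, ])
  expect_length(sets, 1)
  expect_equal(sets[[1]]$label, "A")

  sets20 <- build_nested_score_sets(r[1:20, ])
  expect_length(sets20, 20)
  expect_equal(sets20[[17]]$label, "Q")
  expect_equal(nrow(sets20[[17]]$markers), 17)
  # nesting: set k extends set k-1
  for (k in 2:20) {
    expect_equal(sets20[[k]]$markers$marker_id[1:(k - 1)],
                 sets20[[k - 1]]$markers$marker_id)
  }
  # cap at 26
  expect_length(build_nested_score_sets(r), 26)
  expect_error(build_nested_score_sets(r[0, ]), "no markers")
})

test_that("sample scores are mean risk-allele fractions with mean imputation", {
  dose <- rbind(
    s1 = c(2, 1, 0),
    s2 = c(0, 0, 0),
    s3 = c(2, NA, 0),
    s4 = c(0, 1, 0),
    s5 = c(0, 0, 0),
    s6 = c(0, 0, 0)
  )
  colnames(dose) <- c("a", "b", "c")
  g <- genotype_matrix(dose)
  set <- structure(list(label = "C", markers = tibble::tibble(
    marker_id = c("a", "b", "c"), risk_allele = "minor",
    weight = 1, source_or = 2
  )), class = "score_set")
  sc <- compute_sample_scores(set, g)
  expect_equal(sc$score[sc$sample_id == "s2"], 0)
  expect_equal(sc$score[sc$sample_id == "s1"], 0.5)  # (2+1+0)/6
  # marker b risk-allele frequency among non-missing = 2/10 = 0.2;
  # s3: (2 + 2*0.2 + 0)/6 = 0.4
  expect_equal(sc$score[sc$sample_id == "s3"], (2 + 0.4) / 6)
  expect_equal(sc$n_markers_used[sc$sample_id == "s3"], 2L)
  # the spec's worked value: risk-allele frequency 0.25 at the missing marker
  dose2 <- rbind(s1 = c(2, NA, 0), s2 = c(1, 1, 1), s3 = c(0, 0, 2))
  colnames(dose2) <- c("a", "b", "c")
  sc2 <- compute_sample_scores(set, genotype_matrix(dose2))
  expect_equal(sc2$score[1], (2 + 2 * 0.25 + 0) / 6, tolerance = 1e-12)

  # disabled imputation -> NA for incomplete samples
  sc3 <- compute_sample_scores(set, g, impute_missing = FALSE)
  expect_true(is.na(sc3$score[sc3$sample_id == "s3"]))
  expect_false(anyNA(sc3$score[sc3$sample_id != "s3"]))
})

test_that("scores respect flipping, monotonicity and order invariance", {
  g <- random_genotype_fixture(n = 40, m = 6, seed = 8)
  mk <- tibble::tibble(
    marker_id = paste0("m", 1:6),
    risk_allele = rep(c("minor", "major"), 3),
    weight = 1, source_or = rep(c(2, 0.5), 3)
  )
  set <- structure(list(label = "F", markers = mk), class = "score_set")
  sc <- compute_sample_scores(set, g)
  # unit weights, no missingness: score * 2m is an integer allele count
  expect_true(all(abs(sc$score * 12 - round(sc$score * 12)) < 1e-9))
  expect_true(all(sc$score >= 0 & sc$score <= 1))

  # monotone: raising any risk-allele dose never lowers the score
  g2 <- g
  i <- 3; j <- which(mk$risk_allele == "minor")[1]
  if (g2$dose[i, j] < 2) g2$dose[i, j] <- g2$dose[i, j] + 1
  sc2 <- compute_sample_scores(set, g2)
  expect_gte(sc2$score[i], sc$score[i])

  # marker order within the set does not matter
  perm <- c(4, 1, 6, 2, 5, 3)
  set_p <- structure(list(label = "F", markers = mk[perm, ]),
                     class = "score_set")
  expect_equal(compute_sample_scores(set_p, g)$score, sc$score,
               tolerance = 1e-12)
})

test_that("scoring files carry marker, allele token and weight", {
  mk <- tibble::tibble(marker_id = c("m1", "m2"),
                       risk_allele = c("minor", "major"),
                       weight = 1, source_or = c(2, 0.4))
  set <- structure(list(label = "B", markers = mk), class = "score_set")
  path <- withr::local_tempfile(fileext = ".tsv")
  variants <- tibble::tibble(marker_id = c("m1", "m2"),
                             gene_label = NA, minor_allele = c("A", "G"),
                             major_allele = c("C", "T"))
  write_score_file(set, path, variants)
  lines <- readLines(path)
  expect_equal(lines, c("m1\tA\t1", "m2\tT\t1"))
})
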