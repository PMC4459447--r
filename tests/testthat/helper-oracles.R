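# Independent oracles used across the suite. Each one is deliberately
# written via a different route than the implementation it checks.

# logistic regression by hand-coded Newton/IRLS (checks stats::glm path)
oracle_irls_logistic <- function(y, x, iter = 50) {
  X <- cbind(1, x)
  b <- c(0, 0)
  for (i in seq_len(iter)) {
    eta <- as.vector(X %*% b)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    step <- solve(t(X) %*% (X * w), t(X) %*% (y - mu))
    b <- b + as.vector(step)
    if (max(abs(step)) < 1e-12) break
  }
  eta <- as.vector(X %*% b)
  mu <- 1 / (1 + exp(-eta))
  info <- t(X) %*% (X * (mu * (1 - mu)))
  list(beta = b[2], se = sqrt(solve(info)[2, 2]))
}

# Levene-Haldane conditional distribution by ratio recurrence over the
# heterozygote-count support (checks the log-gamma closed form)
oracle_hwe_exact <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  n_minor <- min(2 * n_AA + n_Aa, 2 * n_aa + n_Aa)
  if (n_minor == 0) return(1)
  n_major <- 2 * n - n_minor
  hets <- seq(n_minor %% 2, min(n_minor, n_major), by = 2)
  w <- numeric(length(hets))
  w[1] <- 1
  if (length(hets) > 1) {
    for (k in seq_len(length(hets) - 1)) {
      h <- hets[k]
      w[k + 1] <- w[k] * 4 * ((n_minor - h) / 2) * ((n_major - h) / 2) /
        ((h + 2) * (h + 1))
    }
  }
  p <- w / sum(w)
  obs <- which(hets == n_Aa)
  sum(p[p <= p[obs] * (1 + 1e-9)])
}

# AUC by explicit pair counting (checks the placement-value route)
oracle_auc_pairs <- function(scores, labels) {
  x <- scores[labels == 1]; y <- scores[labels == 0]
  tot <- 0
  for (xi in x) for (yj in y) {
    tot <- tot + if (xi > yj) 1 else if (xi == yj) 0.5 else 0
  }
  tot / (length(x) * length(y))
}

# candidate cuts, replicated independently of candidate_splits()
oracle_cuts <- function(v, kind) {
  u <- sort(unique(v[!is.na(v)]))
  if (length(u) < 2) return(numeric(0))
  if (kind == "dose") c(1, 2) else if (kind == "binary") 1 else u[-1]
}

oracle_chi2 <- function(a, b, c, d) {
  # 2x2 Pearson chi-square, no continuity correction, from the cell formula
  n <- a + b + c + d
  num <- n * (a * d - b * c)^2
  den <- (a + b) * (c + d) * (a + c) * (b + d)
  chi2 <- num / den
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

# exhaustive best-split search with the same admissibility and tie rules
oracle_best_split <- function(data, labels, manifest, config) {
  y <- as.numeric(labels)
  best <- NULL
  n_pred <- 0; n_cuts <- 0
  for (i in seq_len(nrow(manifest))) {
    v <- data[[manifest$name[i]]]
    cuts <- oracle_cuts(v, manifest$kind[i])
    any_cut <- FALSE
    for (cut in cuts) {
      ok <- !is.na(v)
      yy <- y[ok]
      if (!any(yy == 1) || !any(yy == 0)) next
      ge <- v[ok] >= cut
      if (sum(ge) < config$min_subgroup || sum(!ge) < config$min_subgroup) next
      any_cut <- TRUE; n_cuts <- n_cuts + 1
      side <- if (mean(yy[ge]) >= mean(yy[!ge])) "ge" else "lt"
      pos <- if (side == "ge") ge else !ge
      se <- sum(pos & yy == 1) / sum(yy == 1)
      sp <- sum(!pos & yy == 0) / sum(yy == 0)
      r <- config$kappa_weight
      q <- if (config$criterion == "weighted_sesp") {
        r * se + (1 - r) * sp
      } else {
        p <- mean(yy); qq <- mean(pos)
        den <- r * p * (1 - qq) + (1 - r) * (1 - p) * qq
        if (den == 0) 0 else p * (1 - p) * (se + sp - 1) / den
      }
      if (is.null(best) || q > best$quality + 1e-12) {
        ch <- oracle_chi2(sum(pos & yy == 1), sum(pos & yy == 0),
                          sum(!pos & yy == 1), sum(!pos & yy == 0))
        best <- list(predictor = manifest$name[i], cut = cut,
                     positive_side = side, quality = q,
                     chi2 = ch$chi2, p_raw = ch$p)
      }
    }
    if (any_cut) n_pred <- n_pred + 1
  }
  if (is.null(best)) return(NULL)
  fac <- if (config$correction == "bonferroni_predictors") n_pred else n_cuts
  best$p_corrected <- min(1, best$p_raw * fac)
  if (best$p_corrected > config$alpha) return(NULL)
  best
}

# recursive tree oracle mirroring the stopping rules
oracle_grow <- function(data, labels, manifest, config, depth = 0) {
  y <- as.numeric(labels)
  node <- list(n_case = sum(y == 1), n_control = sum(y == 0), split = NULL)
  if (node$n_case == 0 || node$n_control == 0) return(node)
  if (depth >= config$max_path_splits) return(node)
  if (length(y) < 2 * config$min_subgroup) return(node)
  bs <- oracle_best_split(data, y, manifest, config)
  if (is.null(bs)) return(node)
  node$split <- bs[c("predictor", "cut", "positive_side")]
  v <- data[[bs$predictor]]
  ge <- !is.na(v) & v >= bs$cut
  lt <- !is.na(v) & v < bs$cut
  pos <- if (bs$positive_side == "ge") ge else lt
  neg <- if (bs$positive_side == "ge") lt else ge
  miss <- is.na(v)
  if (any(miss)) {
    if (sum(pos) >= sum(neg)) pos <- pos | miss else neg <- neg | miss
  }
  node$children <- list(
    positive = oracle_grow(data[pos, , drop = FALSE], y[pos], manifest, config,
                           depth + 1),
    negative = oracle_grow(data[neg, , drop = FALSE], y[neg], manifest, config,
                           depth + 1)
  )
  node
}

# flatten both tree representations for structural comparison
tree_signature <- function(node) {
  if (is.null(node$split)) {
    return(sprintf("leaf[%d/%d]", node$n_case, node$n_control))
  }
  sprintf("(%s>=%g:%s[%d/%d] %s %s)", node$split$predictor, node$split$cut,
          node$split$positive_side, node$n_case, node$n_control,
          tree_signature(node$children$positive),
          tree_signature(node$children$negative))
}

# small random genotype fixture
random_genotype_fixture <- function(n = 30, m = 5, seed = 1, miss = 0) {
  set.seed(seed)
  dose <- matrix(sample(0:2, n * m, replace = TRUE), n, m,
                 dimnames = list(paste0("s", 1:n), paste0("m", 1:m)))
  if (miss > 0) dose[runif(n * m) < miss] <- NA
  genotype_matrix(dose)
}

# cohort tibble helper
make_samples <- function(ids, groups, age = 75, sex = "female",
                         split = "unassigned") {
  as_cohort_table(tibble::tibble(
    sample_id = ids, group = groups, age = age, sex = sex, split = split
  ))
}
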