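test_that("pairwise correlations match hand-computed Pearson r and p", {
  m <- cbind(E1 = c(1, 2, 3, 4, 5), E2 = c(2, 1, 4, 3, 5),
             E3 = c(2, 4, 6, 8, 10))
  rownames(m) <- paste0("G", 1:5)
  cm <- pairwise_correlations(gxescan:::new_pheno_matrix(m))
  r <- attr(cm, "r"); p <- attr(cm, "p")

  expect_equal(diag(r), c(E1 = 1, E2 = 1, E3 = 1))
  expect_equal(r["E1", "E3"], 1)            # exact linearity

  # textbook formula by hand
  x <- m[, 1]; y <- m[, 2]
  r_hand <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(r["E1", "E2"], r_hand)
  t_hand <- r_hand * sqrt(3 / (1 - r_hand^2))
  expect_equal(p["E1", "E2"], 2 * stats::pt(-abs(t_hand), df = 3))

  expect_true(isSymmetric(r))
  expect_true(all(abs(r) <= 1 + 1e-12))
})

test_that("pairs with too few shared genotypes or zero variance are missing", {
  m <- cbind(E1 = c(1, 2, NA, NA, 5), E2 = c(NA, NA, 3, 1, NA),
             E3 = c(5, 5, 5, 5, 5), E4 = c(1, 3, 2, 4, 5))
  rownames(m) <- paste0("G", 1:5)
  expect_message(cm <- pairwise_correlations(gxescan:::new_pheno_matrix(m)),
                 "zero-variance")
  expect_true(is.na(attr(cm, "r")["E1", "E2"]))  # 0 shared genotypes
  expect_true(is.na(attr(cm, "r")["E3", "E4"]))  # constant member
  expect_false(is.na(attr(cm, "r")["E1", "E4"]))
})

test_that("significance counting is monotone and handles edge alphas", {
  set.seed(5)
  m <- matrix(rnorm(60), 10, 6, dimnames = list(paste0("G", 1:10),
                                                paste0("E", 1:6)))
  m[, 2] <- m[, 1] + rnorm(10, sd = 0.01)   # collinear trio member
  m[, 3] <- m[, 1] * 2 + 1
  cm <- pairwise_correlations(gxescan:::new_pheno_matrix(m))

  counts <- count_significant(cm, alpha = 1e-12)
  expect_gte(counts$n_significant[counts$experiment == "E1"], 2)
  # alpha = 1 counts every non-missing partner
  all_in <- count_significant(cm, alpha = 1)
  expect_true(all(all_in$n_significant == 5))
  # monotone non-decreasing in alpha
  alphas <- c(1e-6, 1e-3, 0.05, 0.5, 1)
  runs <- sapply(alphas, function(a) count_significant(cm, a)$n_significant)
  expect_true(all(apply(runs, 1, function(x) all(diff(x) >= 0))))
  # sign split partitions the count
  split <- count_significant(cm, alpha = 0.5, sign_split = TRUE)
  expect_equal(split$n_significant, split$n_positive + split$n_negative)
})

test_that("type-I error rate of partner counting matches alpha", {
  set.seed(99)
  n_exp <- 10; n_geno <- 10; reps <- 500
  mean_counts <- replicate(reps, {
    m <- matrix(rnorm(n_geno * n_exp), n_geno, n_exp,
                dimnames = list(paste0("G", seq_len(n_geno)),
                                paste0("E", seq_len(n_exp))))
    cm <- pairwise_correlations(gxescan:::new_pheno_matrix(m))
    mean(count_significant(cm, alpha = 0.05)$n_significant)
  })
  expected <- 0.05 * (n_exp - 1)
  expect_lt(abs(mean(mean_counts) - expected), 0.2 * expected)
})

test_that("t-transform p agrees with exact permutation p at small n", {
  set.seed(4)
  for (rep in 1:3) {
    x <- rnorm(7); y <- 0.5 * x + rnorm(7)
    m <- cbind(E1 = x, E2 = y)
    rownames(m) <- paste0("G", 1:7)
    cm <- pairwise_correlations(gxescan:::new_pheno_matrix(m))
    p_t <- attr(cm, "p")["E1", "E2"]
    # full enumeration of the 7! pairings of y against x
    all_perm <- function(v) {
      if (length(v) == 1) return(list(v))
      out <- list()
      for (i in seq_along(v)) {
        for (rest in all_perm(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
      }
      out
    }
    perm_idx <- all_perm(1:7)
    r_obs <- abs(cor(x, y))
    r_perm <- vapply(perm_idx, function(pp) abs(cor(x, y[pp])), numeric(1))
    p_perm <- mean(r_perm >= r_obs - 1e-12)
    expect_lt(abs(p_t - p_perm), 0.05)
  }
})

test_that("PC-covariate correlations behave at the extremes", {
  scores <- tibble::tibble(label = paste0("E", 1:6),
                           PC1 = c(-2, -1, 0, 1, 2, 3),
                           PC2 = c(1, -1, 2, -2, 0, 0.5))
  covs <- tibble::tibble(label = paste0("E", 1:6),
                         same = c(-2, -1, 0, 1, 2, 3),
                         flat = rep(7, 6),
                         other = c(0.3, -0.1, 0.8, 0.2, -0.5, 0.9))
  expect_message(out <- pc_env_correlations(scores, covs), "zero variance")
  expect_equal(out$r[out$covariate == "same" & out$pc == "PC1"], 1)
  expect_false("flat" %in% out$covariate)
  # matches cor.test directly
  ct <- cor.test(covs$other, scores$PC2)
  row <- out[out$covariate == "other" & out$pc == "PC2", ]
  expect_equal(row$r, unname(ct$estimate))
  expect_equal(row$p, ct$p.value)
})

test_that("null covariate p-values are uniform (K-S check)", {
  set.seed(11)
  reps <- 500
  ps <- replicate(reps, {
    scores <- tibble::tibble(label = paste0("E", 1:12), PC1 = rnorm(12))
    covs <- tibble::tibble(label = paste0("E", 1:12), cov = rnorm(12))
    pc_env_correlations(scores, covs)$p
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("formatted export stars the right significance levels", {
  m <- cbind(E1 = c(1, 2, 3, 4, 5, 6), E2 = c(1.1, 2, 3.2, 3.9, 5, 6.1),
             E3 = c(3, 1, 4, 1, 5, 9))
  rownames(m) <- paste0("G", 1:6)
  cm <- pairwise_correlations(gxescan:::new_pheno_matrix(m))
  fm <- format_correlations(cm)
  expect_match(fm["E1", "E2"], "\\*\\*\\*$")
  expect_identical(diag(fm), c(E1 = "1", E2 = "1", E3 = "1"))
})
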