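test_that("association F equals the squared pooled-variance t", {
  # hand-sized case: groups {0: (1,2,3)}, {1: (5,6,7)}
  ind <- matrix(c(0, 0, 0, 1, 1, 1), nrow = 6, ncol = 1,
                dimnames = list(paste0("G", 1:6), NULL))
  storage.mode(ind) <- "integer"
  blocks <- make_blocks(ind)
  pheno <- make_pheno(c(G1 = 1, G2 = 2, G3 = 3, G4 = 5, G5 = 6, G6 = 7))
  rec <- block_association(blocks, pheno, "E1")
  tt <- t.test(c(5, 6, 7), c(1, 2, 3), var.equal = TRUE)
  expect_equal(rec$F, unname(tt$statistic)^2, tolerance = 1e-12)
  expect_equal(rec$p, tt$p.value, tolerance = 1e-12)
  expect_equal(rec$sign, 1)

  # the identity holds across random small datasets
  set.seed(17)
  for (i in 1:100) {
    n <- sample(6:20, 1)
    ind <- matrix(0L, n, 1, dimnames = list(paste0("G", 1:n), NULL))
    ind[sample(n, sample(2:(n - 2), 1)), 1] <- 1L
    y <- rnorm(n)
    rec <- block_association(make_blocks(ind), make_pheno(setNames(y, rownames(ind))), "E1")
    tt <- t.test(y[ind == 1], y[ind == 0], var.equal = TRUE)
    expect_equal(rec$F, unname(tt$statistic)^2, tolerance = 1e-8)
    expect_equal(rec$p, tt$p.value, tolerance = 1e-8)
  }
})

test_that("constant phenotype gives F = 0, p = 1; monomorphic windows skip", {
  ind <- matrix(c(0L, 1L, 0L, 1L, 1L, 0L,
                  1L, 1L, 1L, 1L, 1L, 1L,
                  1L, 0L, 0L, 0L, 0L, 0L), nrow = 6,
                dimnames = list(paste0("G", 1:6), NULL))
  blocks <- make_blocks(ind)
  pheno <- make_pheno(setNames(rep(4, 6), paste0("G", 1:6)))
  rec <- block_association(blocks, pheno, "E1")
  expect_identical(rec$window, 1L)  # windows 2 (monomorphic) and 3 (1 minor) skipped
  expect_equal(rec$F, 0)
  expect_equal(rec$p, 1)
  skipped <- attr(rec, "skipped")
  expect_equal(sum(skipped$n_windows), 2)

  pheno_na <- make_pheno(setNames(rep(NA_real_, 6), paste0("G", 1:6)))
  expect_error(block_association(blocks, pheno_na, "E1"), "all-missing")
})

test_that("null p-values are uniform under no association", {
  set.seed(23)
  n_geno <- 20
  ps <- unlist(lapply(1:10, function(i) {
    ind <- matrix(rbinom(n_geno * 100, 1, 0.4), n_geno, 100,
                  dimnames = list(sprintf("G%02d", 1:n_geno), NULL))
    storage.mode(ind) <- "integer"
    y <- rnorm(n_geno)
    rec <- block_association(make_blocks(ind),
                             make_pheno(setNames(y, rownames(ind))), "E1")
    rec$p
  }))
  expect_gt(length(ps), 900)
  expect_gt(stats::ks.test(ps, "punif")$p.value, 0.01)
})

test_that("significance filtering uses strict inequality", {
  rec <- tibble::tibble(p = c(0.001, 0.0005, 0.002))
  expect_message(out <- filter_significant(rec, 0.001), "1 of 3")
  expect_equal(out$p, 0.0005)            # p == alpha excluded
  expect_equal(nrow(suppressMessages(filter_significant(rec, 1))), 3)
})

test_that("book-ended windows merge into maximal regions per track", {
  mk <- function(starts, trait = "rdw", exp = "E1", chrom = "chr01") {
    tibble::tibble(chrom = chrom, start = starts, end = starts + 100000L,
                   window = starts %/% 100000L + 1L, donor_group = "japonica",
                   trait = trait, experiment = exp)
  }
  # adjacency: 39.7-39.8 and 39.8-39.9 merge
  r <- merge_regions(mk(c(39700000L, 39800000L)))
  expect_equal(nrow(r), 1)
  expect_equal(c(r$start, r$end), c(39700000L, 39900000L))

  # a one-window gap splits regions
  r2 <- merge_regions(mk(c(39700000L, 39900000L)))
  expect_equal(nrow(r2), 2)

  # 10 contiguous windows -> one 1.0 Mb region (interval-merge oracle)
  starts <- seq(0L, by = 100000L, length.out = 10)
  r3 <- merge_regions(mk(starts))
  expect_equal(nrow(r3), 1)
  expect_equal(r3$end - r3$start, 1000000L)
  expect_equal(r3$n_windows, 10L)

  # tracks never merge across traits or experiments
  r4 <- merge_regions(dplyr::bind_rows(mk(39700000L, trait = "rdw"),
                                       mk(39800000L, trait = "yield")))
  expect_equal(nrow(r4), 2)
})

test_that("hot-spot detection follows the co-location depth profile", {
  # construct per-window depths {3,5,6,5,2} over 5 consecutive windows
  win_start <- function(i) (i - 1L) * 100000L
  cover <- list(  # each track covers a run of windows
    c(1, 4), c(1, 4), c(1, 4),            # 3 tracks over windows 1-4
    c(2, 4), c(2, 4),                     # +2 over 2-4  -> depths 3,5,5,5
    c(3, 3),                              # +1 on window 3 -> 3,5,6,5
    c(5, 5), c(5, 5)                      # 2 tracks only on window 5
  )
  regions <- dplyr::bind_rows(lapply(seq_along(cover), function(i) {
    tibble::tibble(chrom = "chr01", start = win_start(cover[[i]][1]),
                   end = win_start(cover[[i]][2]) + 100000L,
                   trait = paste0("t", i), experiment = "E1",
                   donor_group = "japonica", n_windows = NA_integer_,
                   windows = list(cover[[i]][1]:cover[[i]][2]))
  }))
  hs <- detect_hotspots(regions, min_traits = 5)
  expect_equal(nrow(hs), 1)
  expect_equal(hs$start, win_start(2))
  expect_equal(hs$end, win_start(4) + 100000L)
  expect_equal(hs$depth_profile[[1]], c(5L, 6L, 5L))
  expect_equal(hs$max_depth, 6L)
  expect_equal(hs$n_combinations, 6)

  # brute-force depth oracle over all windows
  depth <- sapply(1:5, function(w) sum(vapply(cover, function(cv)
    cv[1] <= w && w <= cv[2], logical(1))))
  expect_equal(depth, c(3, 5, 6, 5, 2))

  # threshold boundary: exactly 5 tracks -> hotspot; 4 -> none
  five <- regions[1:5, ]; five$start <- win_start(2); five$end <- win_start(3)
  five$windows <- list(2L)
  expect_equal(nrow(detect_hotspots(five, min_traits = 5)), 1)
  expect_equal(nrow(detect_hotspots(five[1:4, ], min_traits = 5)), 0)

  # invariance to track ordering
  hs_shuffled <- detect_hotspots(regions[sample(nrow(regions)), ],
                                 min_traits = 5)
  expect_equal(hs_shuffled, hs)
})

test_that("a strong causal window is recovered at p < 0.001 (power)", {
  set.seed(31)
  hits <- replicate(200, {
    ind <- matrix(0L, 20, 1, dimnames = list(sprintf("G%02d", 1:20), NULL))
    ind[sample(20, 10), 1] <- 1L          # balanced 10/10 split
    y <- 3 * ind[, 1] + rnorm(20)         # effect = 3 phenotype SD
    rec <- block_association(make_blocks(ind),
                             make_pheno(setNames(y, rownames(ind))), "E1")
    rec$p < 0.001
  })
  expect_gt(mean(hits), 0.8)
})
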