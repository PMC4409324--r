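# Independent reference computations used across the suite.

# Balanced plot observations with known genotype/block structure.
make_balanced_obs <- function(g_means, block_offsets, environment = "E1") {
  d <- expand.grid(genotype = names(g_means), block = names(block_offsets),
                   stringsAsFactors = FALSE)
  d$environment <- environment
  d$trait <- "trait"
  d$value <- g_means[d$genotype] + block_offsets[d$block]
  tibble::as_tibble(d[c("genotype", "environment", "block", "trait", "value")])
}

# Two-way ANOVA SS partition on a complete cell-mean matrix, computed
# directly from the textbook sums (no sweep/polish machinery).
brute_ss <- function(m) {
  mu <- mean(m)
  g <- nrow(m); e <- ncol(m)
  ss_G <- e * sum((rowMeans(m) - mu)^2)
  ss_E <- g * sum((colMeans(m) - mu)^2)
  ss_tot <- sum((m - mu)^2)
  c(G = ss_G, E = ss_E, GxE = ss_tot - ss_G - ss_E, total = ss_tot)
}

# Plot-level ANOVA fractions via stats::aov (independent of the package).
aov_fractions <- function(obs) {
  fit <- stats::aov(value ~ genotype * environment, data = obs)
  ss <- summary(fit)[[1]][["Sum Sq"]]
  names(ss) <- trimws(rownames(summary(fit)[[1]]))
  tot <- sum(ss)
  c(G = ss[["genotype"]], E = ss[["environment"]],
    GxE = ss[["genotype:environment"]]) / tot
}

# Hypergeometric upper tail by brute-force enumeration of all draws of
# size n from a small universe (exact combinatorial count).
enum_upper_tail <- function(h, n, K, N) {
  hits <- seq_len(N) <= K
  draws <- utils::combn(N, n)
  mean(colSums(matrix(hits[draws], nrow = n)) >= h)
}

# O(n^3) average-linkage agglomeration recomputing every inter-cluster
# distance from the original distance matrix at each step.
naive_average_linkage <- function(dmat) {
  n <- nrow(dmat)
  clusters <- as.list(seq_len(n))
  merges <- list()
  while (length(clusters) > 1) {
    best <- NULL; best_d <- Inf
    for (a in seq_along(clusters)[-length(clusters)]) {
      for (b in (a + 1):length(clusters)) {
        d_ab <- mean(dmat[clusters[[a]], clusters[[b]]])
        if (d_ab < best_d - 1e-12) { best_d <- d_ab; best <- c(a, b) }
      }
    }
    merges[[length(merges) + 1]] <-
      list(members = sort(c(clusters[[best[1]]], clusters[[best[2]]])),
           height = best_d)
    clusters[[best[1]]] <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    clusters[[best[2]]] <- NULL
  }
  merges
}

# Members of each cluster formed at every merge step of an hclust tree.
hclust_merge_members <- function(tree) {
  members <- list()
  for (s in seq_len(nrow(tree$merge))) {
    take <- function(id) if (id < 0) -id else members[[id]]
    members[[s]] <- sort(c(take(tree$merge[s, 1]), take(tree$merge[s, 2])))
  }
  members
}

# Minimal block matrix + phenotype pair for scan tests.
make_blocks <- function(ind, chrom = "chr01", donor = "japonica") {
  nw <- ncol(ind)
  out <- tibble::tibble(
    chrom = chrom,
    start = (seq_len(nw) - 1L) * 100000L,
    end = seq_len(nw) * 100000L,
    window = seq_len(nw),
    donor_group = donor
  )
  out <- dplyr::bind_cols(out, tibble::as_tibble(t(ind)))
  attr(out, "indicator") <- ind
  out
}

make_pheno <- function(values, genotypes = names(values), env = "E1") {
  m <- matrix(values, ncol = 1, dimnames = list(genotypes, env))
  gxescan:::new_pheno_matrix(m, trait = "trait")
}
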