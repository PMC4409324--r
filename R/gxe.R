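#' Impute missing genotype x environment cells by additive fit + low-rank SVD
#'
#' EM-style imputation for a two-way table with missing cells: missing
#' entries are initialized at `row mean + column mean - grand mean`,
#' iterated to the additive fixed point (so exactly additive tables are
#' recovered exactly), then the algorithm alternates an additive
#' main-effect fit with a rank-`rank` SVD reconstruction of the interaction
#' residual, updating only the missing cells, until the largest absolute
#' change falls below `tol` or `max_iter` is reached.  Observed cells are
#' never altered.
#'
#' @param matrix A `pheno_matrix` tibble (see [ls_means()]).
#' @param rank SVD rank of the interaction structure used for
#'   reconstruction; defaults to 2, the number of interpreted principal
#'   components.
#' @param tol Convergence tolerance on the max absolute cell change.
#' @param max_iter Iteration cap; non-convergence returns the last iterate
#'   with a warning and attribute `converged = FALSE`.
#' @return A complete `pheno_matrix`; attribute `imputed` marks filled
#'   cells (logical matrix), attribute `converged` reports convergence.
#' @export
impute_missing <- function(matrix, rank = 2, tol = 1e-8, max_iter = 500) {
  m <- pheno_values(matrix)
  miss <- is.na(m)
  if (!any(miss)) return(matrix)
  if (any(rowSums(!miss) < 2) || any(colSums(!miss) < 2)) {
    stop("each row and column needs >= 2 observed cells for imputation",
         call. = FALSE)
  }
  # initialize at the additive fixed point: iterate the row+column-grand
  # fill until the additive model is self-consistent, so purely additive
  # tables are recovered exactly before any multiplicative term enters
  rows <- rowMeans(m, na.rm = TRUE)
  cols <- colMeans(m, na.rm = TRUE)
  mu <- mean(m, na.rm = TRUE)
  m[miss] <- (outer(rows, cols, "+") - mu)[miss]
  for (it in seq_len(max_iter)) {
    fill <- (outer(rowMeans(m), colMeans(m), "+") - mean(m))[miss]
    if (max(abs(fill - m[miss])) < tol) break
    m[miss] <- fill
  }

  rank <- min(rank, dim(m) - 1)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    mu <- mean(m); g <- rowMeans(m) - mu; e <- colMeans(m) - mu
    add <- mu + outer(g, e, "+")
    resid <- m - add
    sv <- svd(resid)
    k <- seq_len(rank)
    recon <- add + sv$u[, k, drop = FALSE] %*%
      (sv$d[k] * t(sv$v[, k, drop = FALSE]))
    delta <- max(abs(recon[miss] - m[miss]))
    m[miss] <- recon[miss]
    if (delta < tol) { converged <- TRUE; break }
  }
  if (!converged) {
    warning("imputation did not converge in ", max_iter, " iterations",
            call. = FALSE)
  }
  out <- new_pheno_matrix(m, trait = attr(matrix, "trait"),
                          n = attr(matrix, "n"))
  attr(out, "imputed") <- miss
  attr(out, "converged") <- converged
  out
}

# shared decomposition scaffolding: SVD scores with deterministic signs
svd_scores <- function(resid) {
  sv <- svd(resid)
  k <- length(sv$d)
  for (j in seq_len(k)) {
    i_max <- which.max(abs(sv$u[, j]))
    if (sv$u[i_max, j] < 0) {
      sv$u[, j] <- -sv$u[, j]
      sv$v[, j] <- -sv$v[, j]
    }
  }
  sv
}

new_gxe_decomposition <- function(kind, m, mu, g_eff, e_eff, resid, sv,
                                  denom_label) {
  lam2 <- sv$d^2
  pc_pct <- if (sum(lam2) > 0) lam2 / sum(lam2) * 100 else rep(0, length(lam2))
  structure(
    list(
      kind = kind,
      grand_mean = mu,
      genotype_effects = g_eff,
      environment_effects = e_eff,
      singular_values = sv$d,
      genotype_scores = sv$u,
      environment_scores = sv$v,
      residual = resid,
      pc_percent = pc_pct,
      pc_percent_of = denom_label,
      matrix = m
    ),
    class = "gxe_decomposition"
  )
}

#' AMMI decomposition of a genotype x environment table
#'
#' Additive Main effects and Multiplicative Interaction model: a mean
#' polish removes the grand mean and the genotype and environment main
#' effects, and the doubly-centered interaction residual is decomposed by
#' SVD.  Per-PC percentages are shares of the interaction sum of squares
#' (`lambda_k^2 / sum lambda^2 * 100`).  The sum-of-squares table
#' partitions the complete table: `ss_G + ss_E + ss_GxE = ss_total`.
#'
#' When the `pheno_matrix` carries per-cell replicate counts (attribute
#' `n`, as produced by [ls_means()]) and `weighted = TRUE`, sums of squares
#' weight each cell by its replication; otherwise cells weigh equally.
#'
#' Score signs are fixed so the largest-magnitude genotype score on each
#' PC is positive (SVD signs are otherwise arbitrary).
#'
#' @param matrix Complete `pheno_matrix` (impute first if needed), with at
#'   least 3 genotypes and 3 environments.
#' @param weighted Weight SS by per-cell replicate counts when available.
#' @return A `gxe_decomposition` with main effects, singular values,
#'   genotype/environment scores, residual, and an `ss` table; see
#'   [tidy.gxe_decomposition()] and [glance.gxe_decomposition()].
#' @examples
#' sim <- sim_phenotypes(sim_config(n_genotypes = 8, n_environments = 5,
#'                                  missing_rate = 0, seed = 9))
#' fit <- ammi_decompose(ls_means(sim$observations))
#' glance(fit)
#' @export
ammi_decompose <- function(matrix, weighted = FALSE) {
  m <- pheno_values(matrix)
  if (anyNA(m)) stop("matrix has missing cells; run impute_missing() first",
                     call. = FALSE)
  if (nrow(m) < 3 || ncol(m) < 3) {
    stop("AMMI needs >= 3 genotypes and >= 3 environments", call. = FALSE)
  }
  w <- NULL
  if (weighted && !is.null(attr(matrix, "n"))) w <- attr(matrix, "n")

  mu <- mean(m)
  g_eff <- rowMeans(m) - mu
  e_eff <- colMeans(m) - mu
  resid <- m - mu - outer(g_eff, e_eff, "+")
  sv <- svd_scores(resid)

  cellw <- if (is.null(w)) matrix(1, nrow(m), ncol(m)) else w
  ss <- tibble::tibble(
    term = c("G", "E", "GxE", "total"),
    ss = c(sum(cellw * outer(g_eff, rep(1, ncol(m)))^2),
           sum(cellw * outer(rep(1, nrow(m)), e_eff)^2),
           sum(cellw * resid^2),
           sum(cellw * (m - mu)^2)),
    df = c(nrow(m) - 1L, ncol(m) - 1L,
           (nrow(m) - 1L) * (ncol(m) - 1L),
           nrow(m) * ncol(m) - 1L)
  )
  out <- new_gxe_decomposition("AMMI", m, mu, g_eff, e_eff, resid, sv,
                               denom_label = "GxE")
  out$ss <- ss
  if (sum(sv$d[-1]^2) <= 1e-12 * max(1, sv$d[1]^2)) {
    warning("fewer than 2 non-degenerate interaction axes; PC2 is 0",
            call. = FALSE)
  }
  out
}

#' GGE decomposition on an environment-standardized table
#'
#' The "location standardized" model: each environment column is centered
#' by its mean and scaled by its standard deviation, so the standardized
#' table retains the genotype main effect plus the interaction (G + GxE);
#' this table is decomposed directly by SVD.  Per-PC percentages are shares
#' of the G + GxE variation.  Because of the per-column standardization the
#' scores are invariant to any per-environment affine rescaling of the
#' input.
#'
#' @inheritParams ammi_decompose
#' @return A `gxe_decomposition` (kind `"GGE"`); zero-variance environment
#'   columns are dropped with a warning.
#' @export
gge_decompose <- function(matrix) {
  m <- pheno_values(matrix)
  if (anyNA(m)) stop("matrix has missing cells; run impute_missing() first",
                     call. = FALSE)
  if (nrow(m) < 3 || ncol(m) < 3) {
    stop("GGE needs >= 3 genotypes and >= 3 environments", call. = FALSE)
  }
  sds <- apply(m, 2, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance environment(s): ",
            paste(colnames(m)[sds == 0], collapse = ", "), call. = FALSE)
    m <- m[, sds > 0, drop = FALSE]
    sds <- sds[sds > 0]
  }
  z <- scale(m, center = TRUE, scale = sds)
  attr(z, "scaled:center") <- NULL
  attr(z, "scaled:scale") <- NULL
  sv <- svd_scores(z)
  mu <- mean(m)
  new_gxe_decomposition("GGE", m, mu,
                        g_eff = rowMeans(z),
                        e_eff = colMeans(m) - mu,
                        resid = z, sv = sv,
                        denom_label = "G+GxE")
}

#' Percentage partition of the total sum of squares
#'
#' Expresses the G / E / GxE sums of squares of an AMMI decomposition as
#' percentages of the total (printed scale, e.g. `11.3` not `0.113`),
#' together with the per-PC percentages of the interaction (AMMI) or
#' G + GxE (GGE) variation for the first `n_pc` axes.
#'
#' @param d A `gxe_decomposition`.
#' @param n_pc How many PC percentages to report (default 4).
#' @return One-row tibble with `pct_G`, `pct_E`, `pct_GxE` (AMMI only) and
#'   `pct_PC1` ... `pct_PC<n_pc>`.
#' @export
ss_partition_percent <- function(d, n_pc = 4) {
  stopifnot(inherits(d, "gxe_decomposition"))
  pcs <- d$pc_percent[seq_len(min(n_pc, length(d$pc_percent)))]
  pcs <- c(pcs, rep(0, max(0, n_pc - length(pcs))))
  names(pcs) <- paste0("pct_PC", seq_len(n_pc))
  if (!is.null(d$ss)) {
    ss <- stats::setNames(d$ss$ss, d$ss$term)
    out <- tibble::tibble(pct_G = 100 * ss[["G"]] / ss[["total"]],
                          pct_E = 100 * ss[["E"]] / ss[["total"]],
                          pct_GxE = 100 * ss[["GxE"]] / ss[["total"]])
  } else {
    out <- tibble::tibble(.rows = 1)
  }
  dplyr::bind_cols(out, tibble::as_tibble(as.list(pcs)))
}

#' Agglomerative dendrogram of genotypes or environments
#'
#' Builds an average-linkage dendrogram over Euclidean distances between
#' standardized profiles: for genotype clustering each environment column
#' is standardized (and vice versa), and distances are computed
#' pairwise-complete (rescaled by the fraction of shared observed cells).
#' Agglomeration is deterministic: when merge heights tie, the
#' lowest-index pair merges first.
#'
#' @param matrix A `pheno_matrix`.
#' @param axis `"genotypes"` (rows) or `"environments"` (columns).
#' @return An `hclust` object (labels, merge order, heights); convert with
#'   `ape::as.phylo()` or serialize with [write_newick()].
#' @export
cluster_dendrogram <- function(matrix, axis = c("genotypes", "environments")) {
  axis <- match.arg(axis)
  m <- pheno_values(matrix)
  if (axis == "environments") m <- t(m)
  z <- scale(m)                      # standardize each variable column
  z[is.nan(z)] <- 0                  # zero-variance variable: no contribution
  n <- nrow(z)
  if (n < 2) stop("need >= 2 labels to cluster", call. = FALSE)
  labs <- rownames(z)

  dmat <- matrix(0, n, n)
  p <- ncol(z)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      shared <- !is.na(z[i, ]) & !is.na(z[j, ])
      if (sum(shared) < 2) {
        stop("labels '", labs[i], "' and '", labs[j],
             "' share < 2 observed cells", call. = FALSE)
      }
      dmat[i, j] <- dmat[j, i] <-
        sqrt(sum((z[i, shared] - z[j, shared])^2) * p / sum(shared))
    }
  }

  # deterministic average-linkage agglomeration, lowest-index tie-break
  active <- seq_len(n)
  id <- -seq_len(n)                  # hclust convention: negatives = leaves
  size <- rep(1L, n)
  merge <- matrix(0L, n - 1, 2)
  height <- numeric(n - 1)
  for (s in seq_len(n - 1)) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_along(active)[-length(active)]) {
      for (b in (a + 1):length(active)) {
        dij <- dmat[active[a], active[b]]
        if (dij < best_d - 1e-12) { best_d <- dij; best <- c(a, b) }
      }
    }
    a <- best[1]; b <- best[2]
    merge[s, ] <- sort(c(id[active[a]], id[active[b]]))
    height[s] <- best_d
    # average linkage update on representative row a
    ia <- active[a]; ib <- active[b]
    wa <- size[ia]; wb <- size[ib]
    for (other in active[-c(a, b)]) {
      dmat[ia, other] <- dmat[other, ia] <-
        (wa * dmat[ia, other] + wb * dmat[ib, other]) / (wa + wb)
    }
    size[ia] <- wa + wb
    id[ia] <- s
    active <- active[-b]
  }

  order <- order_leaves(merge)
  structure(list(merge = merge, height = height, order = order,
                 labels = labs, method = "average",
                 dist.method = "euclidean (pairwise-complete)"),
            class = "hclust")
}

order_leaves <- function(merge) {
  rec <- function(node) {
    if (node < 0) return(-node)
    c(rec(merge[node, 1]), rec(merge[node, 2]))
  }
  rec(nrow(merge))
}

#' Serialize a dendrogram to a newick file
#'
#' @param tree An `hclust` (e.g. from [cluster_dendrogram()]).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_newick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
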