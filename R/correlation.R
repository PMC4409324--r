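#' Pairwise-complete Pearson correlations among experiments
#'
#' Correlates every pair of experiment (environment) columns of a
#' genotype-means table with Pearson's r, using for each pair the
#' genotypes observed in both (pairwise-complete, because experiments
#' share only subsets of genotypes).  Two-sided p-values come from the t
#' transform `t = r * sqrt((n-2) / (1-r^2))` with `n - 2` degrees of
#' freedom.  Pairs with fewer than 3 shared genotypes, or a zero-variance
#' member, are reported as missing.
#'
#' @param matrix A `pheno_matrix` (genotypes x experiments).
#' @return A `correlation_matrix`: tibble with one row per ordered pair
#'   (`exp1`, `exp2`, `r`, `p`, `n`), including the diagonal; the square
#'   `r`/`p`/`n` grids are attached as attributes of the same names.
#' @export
pairwise_correlations <- function(matrix) {
  m <- pheno_values(matrix)
  if (ncol(m) < 2) stop("need >= 2 experiment columns", call. = FALSE)
  labs <- colnames(m)
  k <- ncol(m)
  r <- p <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  n <- matrix(0L, k, k, dimnames = list(labs, labs))
  for (i in seq_len(k)) {
    for (j in i:k) {
      shared <- !is.na(m[, i]) & !is.na(m[, j])
      n[i, j] <- n[j, i] <- sum(shared)
      if (i == j) { r[i, i] <- 1; p[i, i] <- 0; next }
      if (sum(shared) < 3) next
      x <- m[shared, i]; y <- m[shared, j]
      if (stats::sd(x) == 0 || stats::sd(y) == 0) {
        message("zero-variance column in pair (", labs[i], ", ", labs[j],
                "); correlation undefined")
        next
      }
      ct <- stats::cor.test(x, y, method = "pearson",
                            alternative = "two.sided")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  long <- tidyr::expand_grid(exp1 = labs, exp2 = labs)
  long$r <- r[cbind(long$exp1, long$exp2)]
  long$p <- p[cbind(long$exp1, long$exp2)]
  long$n <- n[cbind(long$exp1, long$exp2)]
  structure(long, r = r, p = p, n = n,
            class = c("correlation_matrix", class(long)))
}

#' Count significantly correlated partner experiments
#'
#' For each experiment, the number of other experiments whose pairwise
#' correlation has `p < alpha` (raw p-values, no multiple-testing
#' correction — the counting is over uncorrected tests by design).
#' Optionally splits the count by the sign of r.
#'
#' @param cm A `correlation_matrix` from [pairwise_correlations()].
#' @param alpha Significance threshold (strict `<`).
#' @param sign_split Also return positive/negative counts separately.
#' @return Tibble with `experiment`, `n_significant` (and `n_positive`,
#'   `n_negative` when `sign_split`).
#' @export
count_significant <- function(cm, alpha = 0.05, sign_split = FALSE) {
  stopifnot(inherits(cm, "correlation_matrix"))
  off <- tibble::as_tibble(cm[cm$exp1 != cm$exp2, ])
  off$sig <- !is.na(off$p) & off$p < alpha
  out <- dplyr::summarise(
    dplyr::group_by(off, experiment = .data$exp1),
    n_significant = sum(.data$sig),
    n_positive = sum(.data$sig & .data$r > 0),
    n_negative = sum(.data$sig & .data$r < 0),
    .groups = "drop"
  )
  if (!sign_split) out <- out[c("experiment", "n_significant")]
  out
}

#' Correlate biplot PC scores with environment covariates
#'
#' Pearson r and two-sided p for every covariate x principal-component
#' pair, pairwise-complete over environments.  Covariates with fewer than
#' 3 non-missing paired values, or zero variance, are skipped with a
#' message.
#'
#' @param scores Tibble of environment scores with columns `label` and
#'   `PC1`, `PC2`, ... (e.g. from [tidy.gxe_decomposition()] filtered to
#'   environments).
#' @param covariates Tibble with column `label` (environment) plus one
#'   numeric column per covariate.
#' @return Tibble of (`covariate`, `pc`, `r`, `p`, `n`).
#' @export
pc_env_correlations <- function(scores, covariates) {
  scores <- tibble::as_tibble(scores)
  covariates <- tibble::as_tibble(covariates)
  stopifnot("label" %in% names(scores), "label" %in% names(covariates))
  pcs <- grep("^PC\\d+$", names(scores), value = TRUE)
  covs <- setdiff(names(covariates), "label")
  d <- dplyr::inner_join(scores, covariates, by = "label")
  out <- list()
  for (cv in covs) {
    for (pc in pcs) {
      ok <- !is.na(d[[cv]]) & !is.na(d[[pc]])
      if (sum(ok) < 3) {
        message("skipping covariate '", cv, "' x ", pc,
                ": < 3 paired values")
        next
      }
      if (stats::sd(d[[cv]][ok]) == 0 || stats::sd(d[[pc]][ok]) == 0) {
        message("skipping covariate '", cv, "' x ", pc, ": zero variance")
        next
      }
      ct <- stats::cor.test(d[[cv]][ok], d[[pc]][ok], method = "pearson")
      out[[length(out) + 1]] <- tibble::tibble(
        covariate = cv, pc = pc, r = unname(ct$estimate), p = ct$p.value,
        n = sum(ok))
    }
  }
  if (length(out) == 0) {
    return(tibble::tibble(covariate = character(), pc = character(),
                          r = numeric(), p = numeric(), n = integer()))
  }
  dplyr::bind_rows(out)
}

#' Formatted correlation matrix with significance stars
#'
#' @param cm A `correlation_matrix`.
#' @return Character matrix of `r` rounded to 2 decimals with stars at
#'   p < 0.05 (*), < 0.01 (**), < 0.001 (***).
#' @export
format_correlations <- function(cm) {
  stopifnot(inherits(cm, "correlation_matrix"))
  r <- attr(cm, "r"); p <- attr(cm, "p")
  stars <- ifelse(is.na(p), "",
                  ifelse(p < 0.001, "***",
                         ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", ""))))
  out <- matrix(paste0(ifelse(is.na(r), "NA", sprintf("%.2f", r)), stars),
                nrow(r), dimnames = dimnames(r))
  diag(out) <- "1"
  out
}
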