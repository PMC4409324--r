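#' Simulation configuration for the synthetic study design
#'
#' Bundles the parameters of the synthetic multi-environment trial and
#' introgression-block generator: a diversity panel of `n_genotypes` grown in
#' `n_environments` environments with `n_blocks_per_env` replicate blocks,
#' phenotypic variance split into genotype (G), environment (E), interaction
#' (GxE) and plot-level error components, plus a binary introgression-block
#' matrix over contiguous 100 kb genome windows.
#'
#' The interaction component is built from `interaction_rank` multiplicative
#' terms (random orthonormal genotype and environment factors, then
#' double-centered), so main effects and interaction are exactly orthogonal
#' and the realized sum-of-squares partition matches the requested fractions
#' up to sampling noise in the error term.
#'
#' @param n_genotypes Number of genotypes (>= 3).
#' @param n_environments Number of environments (>= 2).
#' @param variance_fractions Named list/vector with components `G`, `E`,
#'   `GxE`, `error`, each a fraction of total phenotypic variance; must sum
#'   to 1.
#' @param interaction_rank Number of multiplicative GxE terms; at most
#'   `min(n_genotypes, n_environments) - 1`.
#' @param missing_rate Fraction of genotype x environment cells deleted
#'   completely at random, in `[0, 1)`.
#' @param n_chromosomes,windows_per_chromosome Introgression-block grid:
#'   each chromosome carries `windows_per_chromosome` contiguous 100 kb
#'   windows.
#' @param donor_fraction Named vector of per-donor-group fractions of windows
#'   carrying introgressions (groups `aus`, `indica`, `japonica`).
#' @param causal_windows Optional data frame with columns `window` (1-based
#'   window index) and `effect` (effect size in phenotype SD units) of
#'   windows whose introgression carriers receive a genotype-level phenotype
#'   shift.
#' @param n_blocks_per_env Replicate blocks per environment.
#' @param grand_mean,total_sd Location and total phenotypic SD of the trait
#'   (arbitrary trait units; defaults give a standardized trait).
#' @param block_share Fraction of the error variance attributed to replicate
#'   block effects (drawn i.i.d. normal within environment); the remainder is
#'   plot-level residual.
#' @param exclude Optional character vector of genotype ids to drop from all
#'   observations (mirrors panel-specific exclusion lists).
#' @param seed Integer seed; every sub-generator derives its own stream from
#'   it, so phenotypes, blocks and annotations are individually reproducible.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @examples
#' cfg <- sim_config(n_genotypes = 12, n_environments = 6, seed = 1)
#' sim <- sim_phenotypes(cfg)
#' head(sim$observations)
#' @export
sim_config <- function(n_genotypes = 20,
                       n_environments = 10,
                       variance_fractions = c(G = 0.10, E = 0.60,
                                              GxE = 0.20, error = 0.10),
                       interaction_rank = 2,
                       missing_rate = 0.05,
                       n_chromosomes = 12,
                       windows_per_chromosome = 25,
                       donor_fraction = c(aus = 0.05, indica = 0.05,
                                          japonica = 0.15),
                       causal_windows = NULL,
                       n_blocks_per_env = 3,
                       grand_mean = 0,
                       total_sd = 1,
                       block_share = 0.25,
                       exclude = character(),
                       seed = 1L) {
  vf <- unlist(variance_fractions)
  if (!all(c("G", "E", "GxE", "error") %in% names(vf))) {
    stop("variance_fractions must have components G, E, GxE, error",
         call. = FALSE)
  }
  vf <- vf[c("G", "E", "GxE", "error")]
  if (any(vf < 0) || abs(sum(vf) - 1) > 1e-9) {
    stop("variance_fractions must be non-negative and sum to 1", call. = FALSE)
  }
  if (n_genotypes < 3) stop("n_genotypes must be >= 3", call. = FALSE)
  if (n_environments < 2) stop("n_environments must be >= 2", call. = FALSE)
  if (interaction_rank > min(n_genotypes, n_environments) - 1) {
    stop("interaction_rank must be <= min(n_genotypes, n_environments) - 1",
         call. = FALSE)
  }
  if (interaction_rank < 1 && vf[["GxE"]] > 0) {
    stop("interaction_rank must be >= 1 when the GxE fraction is positive",
         call. = FALSE)
  }
  if (missing_rate < 0 || missing_rate >= 1) {
    stop("missing_rate must be in [0, 1)", call. = FALSE)
  }
  df <- unlist(donor_fraction)
  if (is.null(names(df)) || any(!nzchar(names(df))) ||
      any(df < 0) || any(df > 1)) {
    stop("donor_fraction must be a named vector of fractions in [0, 1]",
         call. = FALSE)
  }
  if (!is.null(causal_windows)) {
    causal_windows <- tibble::as_tibble(causal_windows)
    stopifnot(all(c("window", "effect") %in% names(causal_windows)))
    n_win <- n_chromosomes * windows_per_chromosome
    if (any(causal_windows$window < 1) || any(causal_windows$window > n_win)) {
      stop("causal window index outside the window population", call. = FALSE)
    }
  }
  if (block_share < 0 || block_share > 1) {
    stop("block_share must be in [0, 1]", call. = FALSE)
  }
  structure(
    list(
      n_genotypes = as.integer(n_genotypes),
      n_environments = as.integer(n_environments),
      variance_fractions = vf,
      interaction_rank = as.integer(interaction_rank),
      missing_rate = missing_rate,
      n_chromosomes = as.integer(n_chromosomes),
      windows_per_chromosome = as.integer(windows_per_chromosome),
      donor_fraction = df,
      causal_windows = causal_windows,
      n_blocks_per_env = as.integer(n_blocks_per_env),
      grand_mean = grand_mean,
      total_sd = total_sd,
      block_share = block_share,
      exclude = as.character(exclude),
      seed = as.integer(seed)
    ),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genotypes x %d environments x %d blocks\n",
              x$n_genotypes, x$n_environments, x$n_blocks_per_env))
  cat(sprintf("  variance fractions: G %.3f, E %.3f, GxE %.3f (rank %d), error %.3f\n",
              x$variance_fractions[["G"]], x$variance_fractions[["E"]],
              x$variance_fractions[["GxE"]], x$interaction_rank,
              x$variance_fractions[["error"]]))
  cat(sprintf("  %d chromosomes x %d windows of 100 kb; missing rate %.2f; seed %d\n",
              x$n_chromosomes, x$windows_per_chromosome, x$missing_rate,
              x$seed))
  invisible(x)
}

# Derive a named, stage-specific RNG stream from the config seed so each
# generator is individually reproducible.  Keeps derived seeds < 2^31.
stage_seed <- function(seed, stage) {
  offset <- c(phenotype = 101L, blocks = 211L, annotations = 307L,
              pipeline = 401L)[[stage]]
  (as.integer(seed) %% 1000003L) * 1009L + offset
}
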