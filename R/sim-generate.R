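#' Generate plot-level phenotype observations with known structure
#'
#' Simulates a multi-environment trial under the model
#' `value = mu + G_g + E_e + sum_k lambda_k alpha_gk gamma_ek + block + error`,
#' with every component rescaled so its realized variance matches the
#' requested fraction of the total.  Genotype and environment effects are
#' empirically centered and standardized, and the interaction matrix is
#' built from random orthonormal factors then double-centered, so the
#' G / E / GxE sum-of-squares partition is exact by construction; only the
#' error term contributes sampling noise.
#'
#' When the config carries `causal_windows`, the introgression-block matrix
#' for the same config is generated first and each carrier genotype's main
#' effect is shifted by `effect * total_sd` for every causal window carried.
#' Whole genotype x environment cells are then deleted completely at random
#' at `missing_rate` (all blocks of a deleted cell are removed together,
#' mirroring a genotype absent from an experiment).
#'
#' @param config A [sim_config()].
#' @param trait Trait name stamped on the observations.
#' @return A list with elements
#'   * `observations`: tibble of plot records
#'     (genotype, environment, block, trait, value);
#'   * `truth`: list with the true effect vectors (`genotype_effects`,
#'     `environment_effects`), the double-centered `interaction` matrix,
#'     `causal_effects`, and `variance_fractions` realized at the
#'     structural (noise-free) level.
#' @examples
#' sim <- sim_phenotypes(sim_config(n_genotypes = 10, n_environments = 5,
#'                                  seed = 42))
#' dplyr::count(sim$observations, environment)
#' @export
sim_phenotypes <- function(config, trait = "trait") {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "phenotype"))
  g <- config$n_genotypes
  e <- config$n_environments
  b <- config$n_blocks_per_env
  vf <- config$variance_fractions
  v_tot <- config$total_sd^2

  genotypes <- sprintf("G%02d", seq_len(g))
  environments <- sprintf("E%02d", seq_len(e))

  # population-SD standardization: center, then scale so mean(x^2) == 1
  std <- function(x) {
    x <- x - mean(x)
    s <- sqrt(mean(x^2))
    if (s == 0) x else x / s
  }

  g_eff <- if (vf[["G"]] > 0) std(stats::rnorm(g)) * sqrt(vf[["G"]] * v_tot) else numeric(g)
  e_eff <- if (vf[["E"]] > 0) std(stats::rnorm(e)) * sqrt(vf[["E"]] * v_tot) else numeric(e)

  inter <- matrix(0, g, e, dimnames = list(genotypes, environments))
  if (vf[["GxE"]] > 0) {
    k <- config$interaction_rank
    # random orthonormal factors orthogonal to the intercept, via QR of
    # [1 | noise]: dropping the first column leaves centered orthonormal cols
    a <- qr.Q(qr(cbind(1, matrix(stats::rnorm(g * k), g, k))))[, -1, drop = FALSE]
    cmat <- qr.Q(qr(cbind(1, matrix(stats::rnorm(e * k), e, k))))[, -1, drop = FALSE]
    lam <- sort(abs(stats::rnorm(k, sd = 2)) + 0.5, decreasing = TRUE)
    inter[] <- a %*% (lam * t(cmat))
    # already double-centered because both factor sets are centered;
    # rescale to the requested variance fraction
    inter <- inter / sqrt(mean(inter^2)) * sqrt(vf[["GxE"]] * v_tot)
  }

  causal <- NULL
  if (!is.null(config$causal_windows) && nrow(config$causal_windows) > 0) {
    blocks <- sim_blocks(config)
    ind <- attr(blocks, "indicator")   # genotype x window matrix
    shift <- numeric(g)
    for (i in seq_len(nrow(config$causal_windows))) {
      w <- config$causal_windows$window[i]
      shift <- shift + ind[, w] * config$causal_windows$effect[i] * config$total_sd
    }
    g_eff <- g_eff + shift
    causal <- tibble::tibble(config$causal_windows,
                             carriers = colSums(ind)[config$causal_windows$window])
  }

  sd_err <- sqrt(vf[["error"]] * v_tot)
  sd_block <- sd_err * sqrt(config$block_share)
  sd_resid <- sd_err * sqrt(1 - config$block_share)

  obs <- tidyr::expand_grid(environment = environments,
                            block = sprintf("B%d", seq_len(b)),
                            genotype = genotypes)
  block_eff <- stats::rnorm(e * b, sd = sd_block)
  names(block_eff) <- paste(rep(environments, each = b),
                            rep(sprintf("B%d", seq_len(b)), e), sep = ".")
  obs$value <- config$grand_mean +
    g_eff[match(obs$genotype, genotypes)] +
    e_eff[match(obs$environment, environments)] +
    inter[cbind(match(obs$genotype, genotypes),
                match(obs$environment, environments))] +
    block_eff[paste(obs$environment, obs$block, sep = ".")] +
    stats::rnorm(nrow(obs), sd = sd_resid)
  obs$trait <- trait
  obs <- obs[, c("genotype", "environment", "block", "trait", "value")]

  if (config$missing_rate > 0) {
    cells <- tidyr::expand_grid(genotype = genotypes,
                                environment = environments)
    drop <- stats::runif(nrow(cells)) < config$missing_rate
    if (any(drop)) {
      key <- paste(cells$genotype[drop], cells$environment[drop])
      obs <- obs[!(paste(obs$genotype, obs$environment) %in% key), ]
    }
  }
  if (length(config$exclude) > 0) {
    obs <- obs[!(obs$genotype %in% config$exclude), ]
  }

  struct_var <- c(G = mean((g_eff - mean(g_eff))^2), E = mean(e_eff^2),
                  GxE = mean(inter^2))
  truth <- list(
    grand_mean = config$grand_mean,
    genotype_effects = stats::setNames(g_eff, genotypes),
    environment_effects = stats::setNames(e_eff, environments),
    interaction = inter,
    causal_effects = causal,
    variance_fractions = struct_var / (sum(struct_var) + sd_err^2)
  )
  list(observations = tibble::as_tibble(obs), truth = truth)
}

#' Generate a binary introgression-block matrix over 100 kb windows
#'
#' Lays out `windows_per_chromosome` contiguous 0-based half-open 100 kb
#' windows on each of `n_chromosomes` chromosomes, assigns each window a
#' donor group with probability proportional to `donor_fraction` (windows
#' drawing no group are introgression-free), and for each introgressed
#' window samples which genotypes carry the donor haplotype (carrier counts
#' between 1 and half the panel, so every introgressed window is
#' polymorphic).
#'
#' @param config A [sim_config()].
#' @return A tibble with one row per window: `chrom`, `start`, `end`,
#'   `window` (1-based index), `donor_group` (`NA` for introgression-free
#'   windows), and one 0/1 column per genotype.  The genotype x window
#'   indicator matrix is attached as attribute `"indicator"`.
#' @examples
#' blocks <- sim_blocks(sim_config(n_chromosomes = 2,
#'                                 windows_per_chromosome = 5, seed = 3))
#' blocks[, 1:6]
#' @export
sim_blocks <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(stage_seed(config$seed, "blocks"))
  g <- config$n_genotypes
  genotypes <- sprintf("G%02d", seq_len(g))
  wpc <- config$windows_per_chromosome
  n_win <- config$n_chromosomes * wpc

  win <- tibble::tibble(
    chrom = sprintf("chr%02d", rep(seq_len(config$n_chromosomes), each = wpc)),
    start = rep((seq_len(wpc) - 1L) * 100000L, config$n_chromosomes),
    end = rep(seq_len(wpc) * 100000L, config$n_chromosomes),
    window = seq_len(n_win)
  )

  groups <- names(config$donor_fraction)
  p_group <- config$donor_fraction
  p_none <- max(0, 1 - sum(p_group))
  assign <- sample(c(groups, NA_character_), n_win, replace = TRUE,
                   prob = c(p_group, p_none))
  win$donor_group <- assign

  ind <- matrix(0L, g, n_win, dimnames = list(genotypes, NULL))
  # causal windows must be introgressed and carried by a balanced-ish subset
  causal_idx <- integer()
  if (!is.null(config$causal_windows) && nrow(config$causal_windows) > 0) {
    causal_idx <- config$causal_windows$window
    win$donor_group[causal_idx][is.na(win$donor_group[causal_idx])] <- groups[[1]]
  }
  for (w in which(!is.na(win$donor_group))) {
    n_carriers <- if (w %in% causal_idx) {
      max(2L, floor(g / 2))
    } else {
      sample.int(max(1L, floor(g / 2)), 1L)
    }
    ind[sample.int(g, n_carriers), w] <- 1L
  }

  out <- dplyr::bind_cols(win, tibble::as_tibble(t(ind)))
  attr(out, "indicator") <- ind
  class(out) <- c("block_matrix", class(out))
  out
}

#' Generate QTL annotation sets over a window population
#'
#' Assigns each annotation the requested number of 100 kb windows, sampled
#' without replacement from a population of `pop_total` window ids
#' (emulating published QTL records mapped to the windows they intersect).
#'
#' @param n_qtls Number of annotations; must equal
#'   `length(per_qtl_window_counts)` when both given.
#' @param pop_total Size of the window population the ids are drawn from.
#' @param per_qtl_window_counts Integer vector of windows per annotation.
#' @param seed Integer seed.
#' @return A tibble with columns `qtl_id`, `category`, `trait`, `windows`
#'   (list-column of integer window ids), `reference`.
#' @examples
#' sim_qtl_annotations(pop_total = 3680, per_qtl_window_counts = c(28, 42),
#'                     seed = 1)
#' @export
sim_qtl_annotations <- function(n_qtls = length(per_qtl_window_counts),
                                pop_total,
                                per_qtl_window_counts,
                                seed = 1L) {
  if (n_qtls == 0) {
    return(tibble::tibble(qtl_id = character(), category = character(),
                          trait = character(), windows = list(),
                          reference = character()))
  }
  stopifnot(n_qtls == length(per_qtl_window_counts))
  if (any(per_qtl_window_counts > pop_total)) {
    stop("per-QTL window count exceeds the window population", call. = FALSE)
  }
  set.seed(stage_seed(seed, "annotations"))
  tibble::tibble(
    qtl_id = sprintf("SYNQ%03d", seq_len(n_qtls)),
    category = "synthetic",
    trait = sprintf("trait%d", seq_len(n_qtls)),
    windows = lapply(per_qtl_window_counts,
                     function(k) sort(sample.int(pop_total, k))),
    reference = "synthetic"
  )
}
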