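#' Least-squares genotype means per environment
#'
#' Fits, within each environment, the additive two-way fixed-effect model
#' `value = mu + genotype + block` by ordinary least squares and returns
#' the adjusted (least-squares) genotype means: the model prediction for
#' each genotype averaged over all block levels present in that
#' environment.  For balanced complete data these coincide with the
#' per-genotype arithmetic means (and with mixed-model LS means when blocks
#' are random); with a single block the observed value is returned as-is.
#'
#' Genotypes absent from an environment are missing in that column.
#' Environments with fewer than two distinct genotypes are dropped with a
#' warning.
#'
#' @param obs Tibble of plot observations with columns `genotype`,
#'   `environment`, `block`, `trait`, `value`.
#' @param trait Which trait to extract (`obs` may hold several).
#' @return A `pheno_matrix`: a tibble with one row per genotype, one column
#'   per environment, genotype ids in column `genotype`, `NA` for missing
#'   cells.  Attributes: `trait`, and `n` (genotype x environment replicate
#'   count matrix).
#' @examples
#' sim <- sim_phenotypes(sim_config(n_genotypes = 6, n_environments = 3,
#'                                  seed = 2))
#' ls_means(sim$observations)
#' @export
ls_means <- function(obs, trait = NULL) {
  obs <- tibble::as_tibble(obs)
  stopifnot(all(c("genotype", "environment", "block", "value") %in% names(obs)))
  if (!is.null(trait)) {
    stopifnot("trait" %in% names(obs))
    obs <- obs[obs$trait == trait, ]
  } else if ("trait" %in% names(obs)) {
    tr <- unique(obs$trait)
    if (length(tr) > 1) {
      stop("observations hold several traits; pass `trait`", call. = FALSE)
    }
    trait <- tr
  }
  obs <- obs[is.finite(obs$value), ]
  if (nrow(obs) == 0) stop("no observations for requested trait", call. = FALSE)
  if (anyDuplicated(obs[c("genotype", "environment", "block")])) {
    stop("duplicate (genotype, environment, block) observation keys",
         call. = FALSE)
  }

  genotypes <- sort(unique(obs$genotype))
  fit_env <- function(d) {
    if (length(unique(d$genotype)) < 2) return(NULL)
    if (length(unique(d$block)) < 2) {
      return(stats::setNames(d$value, d$genotype))
    }
    d$genotype <- factor(d$genotype)
    d$block <- factor(d$block)
    fit <- stats::lm(value ~ genotype + block, data = d)
    grid <- expand.grid(genotype = levels(d$genotype),
                        block = levels(d$block))
    pred <- stats::predict(fit, newdata = grid)
    tapply(pred, grid$genotype, mean)
  }

  envs <- sort(unique(obs$environment))
  cols <- lapply(envs, function(env) fit_env(obs[obs$environment == env, ]))
  names(cols) <- envs
  dropped <- envs[vapply(cols, is.null, logical(1))]
  if (length(dropped) > 0) {
    warning("dropping environment(s) with < 2 distinct genotypes: ",
            paste(dropped, collapse = ", "), call. = FALSE)
    cols <- cols[!vapply(cols, is.null, logical(1))]
    envs <- setdiff(envs, dropped)
  }

  m <- matrix(NA_real_, length(genotypes), length(envs),
              dimnames = list(genotypes, envs))
  for (env in envs) m[names(cols[[env]]), env] <- cols[[env]]
  n <- table(factor(obs$genotype, genotypes),
             factor(obs$environment, envs))
  new_pheno_matrix(m, trait = trait %||% "trait", n = unclass(n))
}

new_pheno_matrix <- function(m, trait = "trait", n = NULL) {
  out <- tibble::as_tibble(m, rownames = "genotype")
  attr(out, "trait") <- trait
  attr(out, "n") <- n
  class(out) <- c("pheno_matrix", class(out))
  out
}

#' Convert a phenotype tibble to its genotype x environment value matrix
#'
#' @param x A `pheno_matrix` (tibble with a `genotype` id column).
#' @return Numeric matrix with genotype rownames and environment colnames.
#' @export
pheno_values <- function(x) {
  m <- as.matrix(x[setdiff(names(x), "genotype")])
  rownames(m) <- x$genotype
  storage.mode(m) <- "double"
  m
}

#' Percentage of root mass below a depth cutoff
#'
#' Computes `% deep roots` from a depth-binned root dry weight profile:
#' `100 * (weight below cutoff) / (total weight)`.  The cutoff must
#' coincide with a bin boundary (no interpolation across bins), matching
#' profiles sampled at 20 cm or 30 cm horizons.
#'
#' @param profile Tibble with columns `depth_top_cm`, `depth_bottom_cm`,
#'   `rdw_g` (one root-sampling profile; bins contiguous from 0, weights
#'   non-negative).
#' @param cutoff_cm Depth cutoff in cm.
#' @return Percentage in `[0, 100]`.
#' @examples
#' prof <- tibble::tibble(depth_top_cm = c(0, 20), depth_bottom_cm = c(20, 60),
#'                        rdw_g = c(3, 1))
#' percent_deep_roots(prof, 20)  # 25
#' @export
percent_deep_roots <- function(profile, cutoff_cm = 20) {
  profile <- tibble::as_tibble(profile)
  stopifnot(all(c("depth_top_cm", "depth_bottom_cm", "rdw_g") %in%
                  names(profile)))
  profile <- profile[order(profile$depth_top_cm), ]
  if (any(profile$rdw_g < 0)) stop("negative root weights", call. = FALSE)
  b <- c(profile$depth_top_cm[1], profile$depth_bottom_cm)
  if (b[1] != 0 || any(diff(b) <= 0) ||
      any(profile$depth_top_cm[-1] != profile$depth_bottom_cm[-nrow(profile)])) {
    stop("depth bins must be contiguous and strictly increasing from 0",
         call. = FALSE)
  }
  total <- sum(profile$rdw_g)
  if (total <= 0) stop("total root weight is zero; %DR undefined",
                       call. = FALSE)
  if (!cutoff_cm %in% b) {
    stop("cutoff ", cutoff_cm, " cm is not a bin boundary", call. = FALSE)
  }
  100 * sum(profile$rdw_g[profile$depth_top_cm >= cutoff_cm]) / total
}

#' Drought stress-response indices
#'
#' Computes the five paired control/stress indices per genotype:
#' \itemize{
#'   \item `% shoot biomass reduction` = (shoot_control - shoot_stress) /
#'     shoot_control x 100
#'   \item `% RDW reduction` = (RDW_control - RDW_stress) / RDW_control x 100
#'   \item `% MRL increase` = (MRL_stress - MRL_control) / MRL_control x 100
#'   \item `%DR increase` = %DR_stress - %DR_control (a percentage-point
#'     difference, not a ratio)
#'   \item `% grain yield reduction` = (yield_control - yield_stress) /
#'     yield_control x 100
#' }
#'
#' @param control,stress Tibbles with column `genotype` plus any of
#'   `shoot_biomass`, `rdw`, `mrl`, `pdr`, `yield` (paired by genotype).
#' @return A tibble per genotype with columns `shoot_reduction`,
#'   `rdw_reduction`, `mrl_increase`, `pdr_increase`, `yield_reduction`;
#'   an index is `NA` where either member of the pair is missing and
#'   `NaN`-flagged (with a warning) where a ratio index has control 0.
#'   Genotypes lacking both members entirely are omitted.
#' @examples
#' ctrl <- tibble::tibble(genotype = "A", rdw = 4, pdr = 20)
#' strs <- tibble::tibble(genotype = "A", rdw = 3, pdr = 30)
#' stress_indices(ctrl, strs)
#' @export
stress_indices <- function(control, stress) {
  control <- tibble::as_tibble(control)
  stress <- tibble::as_tibble(stress)
  stopifnot("genotype" %in% names(control), "genotype" %in% names(stress))
  d <- dplyr::full_join(control, stress, by = "genotype",
                        suffix = c("_c", "_s"))

  ratio_red <- function(ctrl, strs, what) {
    out <- rep(NA_real_, nrow(d))
    ok <- !is.na(ctrl) & !is.na(strs)
    zero <- ok & ctrl == 0
    if (any(zero)) {
      warning("control ", what, " is 0 for genotype(s) ",
              paste(d$genotype[zero], collapse = ", "),
              "; reduction index undefined", call. = FALSE)
      out[zero] <- NaN
    }
    use <- ok & !zero
    out[use] <- (ctrl[use] - strs[use]) / ctrl[use] * 100
    out
  }
  ratio_inc <- function(ctrl, strs, what) -ratio_red(ctrl, strs, what)

  get2 <- function(var) {
    if (!var %in% names(control) || !var %in% names(stress)) {
      return(list(c = rep(NA_real_, nrow(d)), s = rep(NA_real_, nrow(d))))
    }
    cn <- if (paste0(var, "_c") %in% names(d)) paste0(var, "_c") else var
    sn <- if (paste0(var, "_s") %in% names(d)) paste0(var, "_s") else var
    list(c = d[[cn]], s = d[[sn]])
  }

  sb <- get2("shoot_biomass"); rd <- get2("rdw"); mr <- get2("mrl")
  pd <- get2("pdr"); yl <- get2("yield")
  out <- tibble::tibble(
    genotype = d$genotype,
    shoot_reduction = ratio_red(sb$c, sb$s, "shoot biomass"),
    rdw_reduction = ratio_red(rd$c, rd$s, "RDW"),
    mrl_increase = ratio_inc(mr$c, mr$s, "MRL"),
    pdr_increase = pd$s - pd$c,
    yield_reduction = ratio_red(yl$c, yl$s, "grain yield")
  )
  vals <- as.matrix(out[-1])
  keep <- rowSums(!is.na(vals) | is.nan(vals)) > 0  # NaN = flagged, kept
  if (any(!keep)) {
    message("omitting genotype(s) with no paired trait: ",
            paste(out$genotype[!keep], collapse = ", "))
  }
  out[keep, ]
}
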