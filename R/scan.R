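#' Associate introgression-block indicators with a phenotype
#'
#' For every 100 kb window whose binary indicator splits the scored
#' genotypes into two classes of at least `min_minor` members each, fits
#' the simple regression `phenotype ~ indicator` and reports the one-way
#' ANOVA F statistic (numerator df 1) with its p-value.  For a binary
#' regressor the ANOVA F equals the squared pooled-variance two-sample t
#' of the slope, so the regression and ANOVA formulations coincide.
#'
#' Windows failing the minor-class threshold (including monomorphic
#' windows) are skipped and tallied in the `skipped` attribute, never
#' silently dropped.  Donor groups are scanned as separate tracks: a
#' window's record carries its donor-group label.
#'
#' @param blocks A block-matrix tibble from [sim_blocks()] or
#'   [read_blocks_tsv()].
#' @param pheno A `pheno_matrix` of genotype means (genotype ids shared
#'   with `blocks`).
#' @param experiment Which experiment (environment column) to scan.
#' @param trait Trait label stamped on the records (defaults to the
#'   matrix's trait attribute).
#' @param min_minor Minimum minor-class count (default 2; a 1-vs-rest
#'   split is formally computable but fragile).
#' @return Tibble of association records (`chrom`, `start`, `end`,
#'   `window`, `donor_group`, `trait`, `experiment`, `sign`, `F`, `p`,
#'   `n`, `minor_count`), with attribute `skipped` summarising skipped
#'   windows.
#' @export
block_association <- function(blocks, pheno, experiment, trait = NULL,
                              min_minor = 2) {
  ind <- attr(blocks, "indicator")
  if (is.null(ind)) {
    gcols <- setdiff(names(blocks),
                     c("chrom", "start", "end", "window", "donor_group"))
    ind <- t(as.matrix(blocks[gcols]))
    rownames(ind) <- gcols
  }
  trait <- trait %||% attr(pheno, "trait") %||% "trait"
  if (!experiment %in% names(pheno)) {
    stop("experiment '", experiment, "' not found in phenotype matrix",
         call. = FALSE)
  }
  y_all <- stats::setNames(pheno[[experiment]], pheno$genotype)
  shared <- intersect(rownames(ind), names(y_all))
  y <- y_all[shared]
  keep <- !is.na(y)
  if (!any(keep)) stop("phenotype all-missing for experiment '", experiment,
                       "'", call. = FALSE)
  y <- y[keep]
  x <- ind[names(y), , drop = FALSE]
  n <- length(y)

  n1 <- colSums(x)
  minor <- pmin(n1, n - n1)
  introgressed <- !is.na(blocks$donor_group)
  testable <- introgressed & minor >= min_minor

  # vectorized one-way ANOVA over windows: F = t^2 of the binary slope
  sum1 <- colSums(x * y)
  mean1 <- sum1 / n1
  mean0 <- (sum(y) - sum1) / (n - n1)
  ssb <- n1 * (n - n1) / n * (mean1 - mean0)^2
  ssw <- sum((y - mean(y))^2) - ssb
  df2 <- n - 2
  Fstat <- ifelse(ssw > 0, ssb / (ssw / df2), ifelse(ssb > 0, Inf, 0))
  pval <- stats::pf(Fstat, 1, df2, lower.tail = FALSE)
  pval[Fstat == 0] <- 1

  out <- tibble::tibble(
    chrom = blocks$chrom, start = blocks$start, end = blocks$end,
    window = blocks$window, donor_group = blocks$donor_group,
    trait = trait, experiment = experiment,
    sign = sign(mean1 - mean0), F = Fstat, p = pval,
    n = n, minor_count = as.integer(minor)
  )[testable, ]
  attr(out, "skipped") <- tibble::tibble(
    reason = c("not introgressed", "minor class below threshold"),
    n_windows = c(sum(!introgressed), sum(introgressed & minor < min_minor))
  )
  out
}

#' Filter association records at a significance cutoff
#'
#' Strict inequality `p < alpha`, matching a fixed raw cutoff with no
#' multiple-testing correction.
#'
#' @param records Association records from [block_association()].
#' @param alpha Cutoff (default 0.001).
#' @return The surviving records; the survivor count is reported with
#'   `message()`.
#' @export
filter_significant <- function(records, alpha = 0.001) {
  out <- records[records$p < alpha, ]
  message(nrow(out), " of ", nrow(records), " association records at p < ",
          alpha)
  out
}

#' Merge book-ended significant windows into regions
#'
#' Within each (trait, experiment, donor group) track and chromosome,
#' merges runs of windows that touch (gap = 0: the next window starts
#' where the previous ends) into maximal regions with coordinates
#' min start / max end.  Windows separated by any gap stay in separate
#' regions.
#'
#' @param records Significant association records (see
#'   [filter_significant()]).
#' @return Tibble of regions (`chrom`, `start`, `end`, `trait`,
#'   `experiment`, `donor_group`, `n_windows`, `windows` list-column).
#' @export
merge_regions <- function(records) {
  if (nrow(records) == 0) {
    return(tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), trait = character(),
                          experiment = character(),
                          donor_group = character(), n_windows = integer(),
                          windows = list()))
  }
  records |>
    dplyr::group_by(.data$trait, .data$experiment, .data$donor_group,
                    .data$chrom) |>
    dplyr::arrange(.data$start, .by_group = TRUE) |>
    dplyr::mutate(run = cumsum(c(1L, (.data$start[-1] !=
                                        .data$end[-dplyr::n()]) * 1L))) |>
    dplyr::group_by(.data$run, .add = TRUE) |>
    dplyr::summarise(start = min(.data$start), end = max(.data$end),
                     n_windows = dplyr::n(),
                     windows = list(sort(.data$window)),
                     .groups = "drop") |>
    dplyr::select("chrom", "start", "end", "trait", "experiment",
                  "donor_group", "n_windows", "windows") |>
    dplyr::arrange(.data$chrom, .data$start, .data$trait, .data$experiment)
}

#' Detect trait co-location hot spots
#'
#' Scans the genome in 100 kb windows and, for each window, counts the
#' distinct (trait, experiment) combinations whose merged regions cover
#' it (the co-location depth).  Maximal runs of contiguous windows with
#' depth >= `min_traits` are reported as hot spots, together with the full
#' set of aligned combinations overlapping the hot spot and the per-window
#' depth profile.  The result does not depend on the order of the input
#' tracks.
#'
#' @param regions Region tibble from [merge_regions()].
#' @param min_traits Minimum co-location depth (default 5).
#' @param window_size Window width in bp (default 100000).
#' @return Tibble of hot spots (`chrom`, `start`, `end`, `n_combinations`,
#'   `combinations` list-column of "trait:experiment" strings,
#'   `max_depth`, `depth_profile` list-column of per-window depths).
#' @export
detect_hotspots <- function(regions, min_traits = 5, window_size = 100000L) {
  empty <- tibble::tibble(chrom = character(), start = integer(),
                          end = integer(), n_combinations = integer(),
                          combinations = list(), max_depth = integer(),
                          depth_profile = list())
  if (nrow(regions) == 0) return(empty)
  regions$combo <- paste(regions$trait, regions$experiment, sep = ":")
  out <- list()
  for (ch in sort(unique(regions$chrom))) {
    rg <- regions[regions$chrom == ch, ]
    lo <- min(rg$start) %/% window_size
    hi <- (max(rg$end) - 1L) %/% window_size
    wins <- lo:hi
    starts <- wins * window_size
    # depth: distinct combos covering each window
    cover <- matrix(FALSE, length(wins), length(unique(rg$combo)),
                    dimnames = list(NULL, unique(rg$combo)))
    for (i in seq_len(nrow(rg))) {
      w0 <- rg$start[i] %/% window_size
      w1 <- (rg$end[i] - 1L) %/% window_size
      cover[(w0:w1) - lo + 1L, rg$combo[i]] <- TRUE
    }
    depth <- rowSums(cover)
    hot <- depth >= min_traits
    if (!any(hot)) next
    runs <- rle(hot)
    idx_end <- cumsum(runs$lengths)
    idx_start <- idx_end - runs$lengths + 1L
    for (r in which(runs$values)) {
      i0 <- idx_start[r]; i1 <- idx_end[r]
      combos <- sort(colnames(cover)[colSums(
        cover[i0:i1, , drop = FALSE]) > 0])
      out[[length(out) + 1]] <- tibble::tibble(
        chrom = ch,
        start = starts[i0],
        end = starts[i1] + window_size,
        n_combinations = length(combos),
        combinations = list(combos),
        max_depth = as.integer(max(depth[i0:i1])),
        depth_profile = list(as.integer(depth[i0:i1]))
      )
    }
  }
  if (length(out) == 0) return(empty)
  dplyr::bind_rows(out)
}
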