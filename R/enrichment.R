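#' Upper-tail hypergeometric probability (one-tailed Fisher's exact test)
#'
#' Probability of observing at least `list_hits` annotated windows when
#' `list_total` windows are drawn without replacement from a population of
#' `population_total` windows of which `population_hits` are annotated:
#' `P(X >= list_hits)` for `X ~ Hypergeometric(population_total,
#' population_hits, list_total)`.  This is the one-tailed (enrichment
#' direction) Fisher's exact test on the 2x2 overlap table.
#'
#' The tail is accumulated in log space from log-gamma binomial
#' coefficients, so values far below double underflow in the individual
#' ratios (down to ~1e-300, and in practice the 1e-25-scale p-values of
#' dense QTL overlaps) are computed accurately.
#'
#' @param list_hits Overlap count (successes in the drawn list).
#' @param list_total Size of the drawn list (windows in the region).
#' @param population_hits Annotated windows genome-wide.
#' @param population_total Window population size.
#' @return The upper-tail probability, in `(0, 1]`.  Vectorized over its
#'   arguments.
#' @examples
#' hypergeom_upper_tail(11, 11, 28, 3680)   # 5.19e-25
#' hypergeom_upper_tail(0, 11, 28, 3680)    # 1
#' @export
hypergeom_upper_tail <- function(list_hits, list_total, population_hits,
                                 population_total) {
  n <- max(length(list_hits), length(list_total), length(population_hits),
           length(population_total))
  h <- rep_len(list_hits, n); nl <- rep_len(list_total, n)
  K <- rep_len(population_hits, n); N <- rep_len(population_total, n)
  if (any(h > nl | K > N | nl > N | h < 0)) {
    stop("infeasible counts: need 0 <= list_hits <= list_total <= ",
         "population_total and population_hits <= population_total",
         call. = FALSE)
  }
  lchoose_ <- function(a, b) lgamma(a + 1) - lgamma(b + 1) - lgamma(a - b + 1)
  vapply(seq_len(n), function(i) {
    if (h[i] <= 0) return(1)
    if (h[i] > min(nl[i], K[i])) {
      stop("infeasible counts: list_hits exceeds min(list_total, ",
           "population_hits)", call. = FALSE)
    }
    k <- h[i]:min(nl[i], K[i])
    lp <- lchoose_(K[i], k) + lchoose_(N[i] - K[i], nl[i] - k) -
      lchoose_(N[i], nl[i])
    m <- max(lp)
    min(1, exp(m + log(sum(exp(lp - m)))))
  }, numeric(1))
}

#' Exact hypergeometric upper tail by integer enumeration
#'
#' Reference computation of the same tail as [hypergeom_upper_tail()] by
#' exact rational arithmetic: binomial coefficients are built by Pascal's
#' triangle in 64-bit integers and the tail is the exact integer sum
#' `sum_k C(K, k) C(N-K, n-k)` divided by `C(N, n)`.  Exact (up to one
#' final double division) for `population_total <= 62`, where every
#' intermediate fits in a signed 64-bit integer; larger populations are
#' rejected.
#'
#' @inheritParams hypergeom_upper_tail
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail_exact <- function(list_hits, list_total,
                                       population_hits, population_total) {
  if (population_total > 62) {
    stop("exact enumeration supports population_total <= 62", call. = FALSE)
  }
  if (list_hits > min(list_total, population_hits) || list_hits < 0 ||
      list_total > population_total || population_hits > population_total) {
    stop("infeasible counts", call. = FALSE)
  }
  hyper_tail_exact_cpp(as.integer(list_hits), as.integer(list_total),
                       as.integer(population_hits),
                       as.integer(population_total))
}

#' Enrich a region against QTL annotation sets
#'
#' For each annotation, builds the 2x2 overlap between the region's
#' windows and the annotation's windows over a fixed window population
#' and computes the one-tailed Fisher's exact p-value:
#' `list_total` = windows in the region, `list_hits` = overlap,
#' `population_hits` = annotation windows genome-wide,
#' `population_total` = fixed population size (a configuration value, not
#' derived from the annotation union).
#'
#' @param region_windows Integer vector of window ids in the region (or a
#'   hot-spot/region row with a `windows` list-column).
#' @param annotations Annotation tibble (see [sim_qtl_annotations()] /
#'   [read_annotations_tsv()]): columns `qtl_id`, `category`, `trait`,
#'   `windows` (list of window ids), `reference`.
#' @param population_total Window population size (e.g. 3680).
#' @return Tibble of enrichment records sorted by ascending p
#'   (`qtl_id`, `category`, `trait`, `list_hits`, `list_total`,
#'   `population_hits`, `population_total`, `p`, `p_formatted` at 3
#'   significant figures).
#' @examples
#' ann <- tibble::tibble(qtl_id = "Q1", category = "vigor", trait = "roots",
#'                       windows = list(1:28), reference = "x")
#' enrich_region(1:11, ann, population_total = 3680)
#' @export
enrich_region <- function(region_windows, annotations, population_total) {
  if (is.data.frame(region_windows)) {
    stopifnot("windows" %in% names(region_windows))
    region_windows <- unique(unlist(region_windows$windows))
  }
  region_windows <- unique(as.integer(region_windows))
  annotations <- tibble::as_tibble(annotations)
  bad <- vapply(annotations$windows,
                function(w) length(w) == 0 || any(w < 1) ||
                  any(w > population_total), logical(1))
  if (any(bad)) {
    stop("annotation(s) reference windows outside the population: ",
         paste(annotations$qtl_id[bad], collapse = ", "), call. = FALSE)
  }
  out <- annotations
  out$list_total <- length(region_windows)
  out$list_hits <- vapply(annotations$windows, function(w)
    length(intersect(region_windows, w)), integer(1))
  out$population_hits <- vapply(annotations$windows, length, integer(1))
  out$population_total <- population_total
  out$p <- hypergeom_upper_tail(out$list_hits, out$list_total,
                                out$population_hits, population_total)
  out$p_formatted <- format(signif(out$p, 3), scientific = TRUE)
  out$windows <- NULL
  dplyr::arrange(out[, c("qtl_id", "category", "trait", "list_hits",
                         "list_total", "population_hits",
                         "population_total", "p", "p_formatted",
                         "reference")], .data$p)
}
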