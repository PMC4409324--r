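#' Tidy biplot coordinates of a G x E decomposition
#'
#' @param x A `gxe_decomposition` from [ammi_decompose()] or
#'   [gge_decompose()].
#' @param n_pc Number of principal components to return (default 2, the
#'   interpreted biplot axes).
#' @param ... Unused.
#' @return Tibble with `label`, `kind` (`"genotype"`/`"environment"`) and
#'   `PC1` ... columns.  Scores are scaled symmetrically
#'   (`sqrt(lambda_k)` on each mode) for biplotting.
#' @export
tidy.gxe_decomposition <- function(x, n_pc = 2, ...) {
  k <- seq_len(min(n_pc, length(x$singular_values)))
  sl <- sqrt(x$singular_values[k])
  gs <- sweep(x$genotype_scores[, k, drop = FALSE], 2, sl, `*`)
  es <- sweep(x$environment_scores[, k, drop = FALSE], 2, sl, `*`)
  colnames(gs) <- colnames(es) <- paste0("PC", k)
  dplyr::bind_rows(
    dplyr::bind_cols(tibble::tibble(label = rownames(x$matrix),
                                    kind = "genotype"),
                     tibble::as_tibble(gs)),
    dplyr::bind_cols(tibble::tibble(label = colnames(x$matrix),
                                    kind = "environment"),
                     tibble::as_tibble(es))
  )
}

#' One-row summary of a G x E decomposition
#'
#' @param x A `gxe_decomposition`.
#' @param ... Unused.
#' @return Tibble with the SS percentages ([ss_partition_percent()]),
#'   `pc1_plus_pc2` (share of the decomposed variation explained by the
#'   two interpreted axes), and dimensions.
#' @export
glance.gxe_decomposition <- function(x, ...) {
  part <- ss_partition_percent(x)
  dplyr::bind_cols(
    tibble::tibble(kind = x$kind,
                   n_genotypes = nrow(x$matrix),
                   n_environments = ncol(x$matrix),
                   pc1_plus_pc2 = sum(x$pc_percent[1:min(2, length(x$pc_percent))])),
    part
  )
}

#' @export
print.gxe_decomposition <- function(x, ...) {
  cat(sprintf("<gxe_decomposition: %s, %d genotypes x %d environments>\n",
              x$kind, nrow(x$matrix), ncol(x$matrix)))
  cat(sprintf("  PC%% of %s: %s\n", x$pc_percent_of,
              paste(sprintf("%.1f", utils::head(x$pc_percent, 4)),
                    collapse = ", ")))
  if (!is.null(x$ss)) {
    pct <- ss_partition_percent(x)
    cat(sprintf("  %% of total SS: G %.1f, E %.1f, GxE %.1f\n",
                pct$pct_G, pct$pct_E, pct$pct_GxE))
  }
  invisible(x)
}

#' Biplot of a G x E decomposition
#'
#' @param object A `gxe_decomposition`.
#' @param ... Passed to [tidy.gxe_decomposition()].
#' @return A ggplot: genotypes as points, environments as labeled arrows
#'   from the origin.
#' @export
autoplot.gxe_decomposition <- function(object, ...) {
  d <- tidy(object, ...)
  env <- d[d$kind == "environment", ]
  gen <- d[d$kind == "genotype", ]
  pc_lab <- sprintf("PC%d (%.1f%% of %s)", 1:2,
                    object$pc_percent[1:2], object$pc_percent_of)
  ggplot2::ggplot(gen, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey70") +
    ggplot2::geom_segment(data = env,
                          ggplot2::aes(x = 0, y = 0, xend = .data$PC1,
                                       yend = .data$PC2),
                          colour = "steelblue",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_text(data = env, ggplot2::aes(label = .data$label),
                       colour = "steelblue", vjust = -0.6, size = 3) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), vjust = 1.4,
                       size = 3) +
    ggplot2::labs(x = pc_lab[1], y = pc_lab[2],
                  title = paste(object$kind, "biplot")) +
    ggplot2::theme_minimal()
}

#' Manhattan-style plot of an association scan
#'
#' @param records Association records from [block_association()].
#' @param alpha Significance cutoff drawn as a horizontal line.
#' @return A ggplot of -log10(p) by genome position, faceted by
#'   chromosome.
#' @export
plot_association_scan <- function(records, alpha = 0.001) {
  ggplot2::ggplot(records,
                  ggplot2::aes((.data$start + .data$end) / 2e6,
                               -log10(.data$p),
                               colour = .data$donor_group)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_wrap(~chrom, scales = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = expression(-log[10](p)),
                  colour = "donor group") +
    ggplot2::theme_minimal()
}
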