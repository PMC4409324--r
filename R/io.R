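#' Read and write the pipeline's TSV formats
#'
#' One strict TSV dialect is used throughout: tab-separated, UTF-8,
#' header row, `"NA"` as the missing marker.
#'
#' @name gxescan-io
#' @param path File path.
#' @param x Object to write.
NULL

#' @describeIn gxescan-io Read a genotype x environment phenotype matrix
#'   (first column `genotype`, one column per environment).
#' @param trait Trait label to attach.
#' @export
read_phenotype_tsv <- function(path, trait = "trait") {
  d <- utils::read.delim(path, check.names = FALSE, na.strings = "NA")
  if (names(d)[1] != "genotype") {
    stop("phenotype TSV must start with a 'genotype' column", call. = FALSE)
  }
  if (anyDuplicated(d$genotype)) {
    stop("duplicate genotype ids in ", path, call. = FALSE)
  }
  m <- as.matrix(d[-1])
  rownames(m) <- d$genotype
  storage.mode(m) <- "double"
  new_pheno_matrix(m, trait = trait)
}

#' @describeIn gxescan-io Write a phenotype matrix.
#' @export
write_phenotype_tsv <- function(x, path) {
  d <- as.data.frame(x)
  num <- vapply(d, is.numeric, logical(1))
  d[num] <- lapply(d[num], function(v) ifelse(is.na(v), NA, format(v, digits = 15)))
  utils::write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @describeIn gxescan-io Read a BED-like introgression-block matrix
#'   (`chrom`, `start`, `end`, `donor_group`, then one 0/1 column per
#'   genotype).  Windows must be 100 kb, sorted, with unique coordinates.
#' @export
read_blocks_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE, na.strings = "NA")
  need <- c("chrom", "start", "end", "donor_group")
  if (!all(need %in% names(d))) {
    stop("blocks TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  len <- d$end - d$start
  if (any(len != 100000L)) {
    stop("non-100kb window(s) at line(s) ",
         paste(which(len != 100000L) + 1L, collapse = ", "), call. = FALSE)
  }
  o <- order(d$chrom, d$start)
  if (!identical(o, seq_len(nrow(d)))) {
    stop("windows must be sorted by (chrom, start)", call. = FALSE)
  }
  if (anyDuplicated(d[c("chrom", "start")])) {
    stop("duplicate window coordinates", call. = FALSE)
  }
  gcols <- setdiff(names(d), c(need, "window"))
  if (!"window" %in% names(d)) d$window <- seq_len(nrow(d))
  ind <- t(as.matrix(d[gcols]))
  storage.mode(ind) <- "integer"
  if (any(!ind %in% c(0L, 1L))) {
    stop("genotype indicator columns must be 0/1", call. = FALSE)
  }
  rownames(ind) <- gcols
  out <- tibble::as_tibble(d[c(need[1:3], "window", "donor_group")])
  out <- dplyr::bind_cols(out, tibble::as_tibble(t(ind)))
  attr(out, "indicator") <- ind
  class(out) <- c("block_matrix", class(out))
  out
}

#' @describeIn gxescan-io Write a block matrix as BED-like TSV.
#' @export
write_blocks_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}

#' @describeIn gxescan-io Read QTL annotations
#'   (`qtl_id`, `category`, `trait`, `windows` comma-separated window ids,
#'   `reference`).
#' @export
read_annotations_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE,
                         colClasses = "character")
  need <- c("qtl_id", "category", "trait", "windows", "reference")
  if (!all(need %in% names(d))) {
    stop("annotation TSV needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(d$qtl_id)) stop("duplicate qtl_id", call. = FALSE)
  d <- tibble::as_tibble(d)
  d$windows <- lapply(strsplit(d$windows, ","), function(w) {
    w <- as.integer(w)
    if (anyNA(w) || length(w) == 0) {
      stop("malformed window id list in annotation TSV", call. = FALSE)
    }
    sort(w)
  })
  d[need]
}

#' @describeIn gxescan-io Write QTL annotations.
#' @export
write_annotations_tsv <- function(x, path) {
  d <- tibble::as_tibble(x)
  d$windows <- vapply(d$windows, function(w) paste(w, collapse = ","),
                      character(1))
  utils::write.table(as.data.frame(d), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @describeIn gxescan-io Write regions or hot spots as BED (0-based
#'   half-open); hot spots encode `count|combo1;combo2;...` in the name
#'   field.
#' @export
write_bed <- function(x, path) {
  name <- if ("combinations" %in% names(x)) {
    paste0(x$n_combinations, "|",
           vapply(x$combinations, paste, character(1), collapse = ";"))
  } else if (all(c("trait", "experiment") %in% names(x))) {
    paste(x$trait, x$experiment, sep = ":")
  } else {
    rep(".", nrow(x))
  }
  bed <- data.frame(chrom = x$chrom, start = x$start, end = x$end,
                    name = name)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
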