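#' Gene-level count container
#'
#' A light list container (in the style of edgeR's DGEList) holding the
#' integer gene x sample count matrix, per-gene transcript lengths and the
#' parsed sample design.
#'
#' @param counts integer matrix, genes x samples; row names are gene ids,
#'   column names are \code{Strain_Stress_Time} sample ids.
#' @param lengths_bp positive integer vector of transcript lengths, one per
#'   gene (recycled names checked against \code{rownames(counts)}).
#' @param design optional design data frame; parsed from the column names
#'   when omitted.
#' @return An object of class \code{"stress_counts"}: a list with elements
#'   \code{counts}, \code{lengths_bp}, \code{design}.
#' @export
stress_counts <- function(counts, lengths_bp, design = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry gene row names and sample column names")
  if (anyDuplicated(rownames(counts)) || anyDuplicated(colnames(counts)))
    stop("gene and sample ids must be unique")
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be nonnegative integers")
  if (length(lengths_bp) != nrow(counts))
    stop("one length per gene required")
  if (any(lengths_bp <= 0)) stop("gene lengths must be positive")
  if (!is.null(names(lengths_bp)) &&
      !identical(names(lengths_bp), rownames(counts)))
    lengths_bp <- lengths_bp[rownames(counts)]
  if (is.null(design)) design <- parse_sample_ids(colnames(counts))
  stopifnot(identical(design$sample, colnames(counts)))
  structure(list(counts = counts,
                 lengths_bp = stats::setNames(as.numeric(lengths_bp),
                                              rownames(counts)),
                 design = design),
            class = "stress_counts")
}

#' @export
print.stress_counts <- function(x, ...) {
  cat("stress_counts:", nrow(x$counts), "genes x", ncol(x$counts),
      "samples\n")
  cat("strains:", paste(unique(x$design$strain), collapse = ", "), "\n")
  invisible(x)
}

#' @export
dim.stress_counts <- function(x) dim(x$counts)

#' Subset genes of a stress_counts object
#' @noRd
subset_genes <- function(x, keep) {
  x$counts <- x$counts[keep, , drop = FALSE]
  x$lengths_bp <- x$lengths_bp[keep]
  x
}

.transforms <- c("fpkm", "log2_quantile", "logclr", "tmm_cpm")

#' Tagged expression matrix
#'
#' Wraps a numeric genes x samples matrix with its transform tag so that
#' downstream operations can check what scale they receive.
#'
#' @param values numeric matrix with gene row names and sample column names.
#' @param transform one of \code{"fpkm"}, \code{"log2_quantile"},
#'   \code{"logclr"}, \code{"tmm_cpm"}.
#' @return an \code{expression_matrix}.
#' @export
expression_matrix <- function(values, transform) {
  as_expression(as.matrix(values), transform)
}

#' Tag a numeric matrix with its expression transform
#' @noRd
as_expression <- function(values, transform) {
  transform <- match.arg(transform, .transforms)
  attr(values, "transform") <- transform
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Transform tag of an expression matrix
#' @noRd
transform_tag <- function(expr) {
  tag <- attr(expr, "transform")
  if (is.null(tag)) NA_character_ else tag
}

#' @export
`[.expression_matrix` <- function(x, i, j, drop = TRUE) {
  m <- unclass(x)
  out <- if (missing(i) && missing(j)) m[, , drop = drop]
  else if (missing(i)) m[, j, drop = drop]
  else if (missing(j)) m[i, , drop = drop]
  else m[i, j, drop = drop]
  if (is.matrix(out)) {
    attr(out, "transform") <- attr(x, "transform")
    attr(out, "tmm_scaled") <- attr(x, "tmm_scaled")
    class(out) <- c("expression_matrix", class(out))
  }
  out
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat("expression_matrix (", transform_tag(x), "): ", nrow(x), " genes x ",
      ncol(x), " samples\n", sep = "")
  invisible(x)
}

#' Write / read a count matrix with its gene-length sidecar
#'
#' Counts go to a TSV with gene ids in the first column and
#' \code{Strain_Stress_Time} sample headers; lengths to a two-column TSV
#' (\code{gene_id}, \code{length_bp}).
#'
#' @param x a [stress_counts()] object.
#' @param counts_file,lengths_file output / input paths.
#' @return \code{write_count_matrix} returns the paths invisibly;
#'   \code{read_count_matrix} returns a \code{stress_counts} object.
#' @export
write_count_matrix <- function(x, counts_file, lengths_file) {
  stopifnot(inherits(x, "stress_counts"))
  df <- data.frame(gene_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(data.frame(gene_id = names(x$lengths_bp),
                                length_bp = x$lengths_bp),
                     lengths_file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(counts_file, lengths_file))
}

#' @rdname write_count_matrix
#' @export
read_count_matrix <- function(counts_file, lengths_file) {
  df <- utils::read.delim(counts_file, check.names = FALSE)
  counts <- as.matrix(df[, -1, drop = FALSE])
  rownames(counts) <- df[[1]]
  len <- utils::read.delim(lengths_file)
  stress_counts(counts, stats::setNames(len$length_bp, len$gene_id))
}

#' Write an expression matrix as TSV with its transform tag
#'
#' The transform tag is recorded in a \code{# transform:} header comment.
#'
#' @param expr a tagged expression matrix.
#' @param file output path.
#' @export
write_expression <- function(expr, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(paste0("# transform: ", transform_tag(expr)), con)
  df <- data.frame(gene_id = rownames(expr), unclass(expr),
                   check.names = FALSE)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
}
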