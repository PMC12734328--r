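#' Remove genes with too many zero counts
#'
#' The study retains genes with at most \code{max_zero_samples} zero counts
#' across the libraries (default 12 of 18), discarding low-read genes before
#' any transformation. Gene order is preserved and the operation is
#' idempotent.
#'
#' @param x a [stress_counts()] object.
#' @param max_zero_samples maximum tolerated number of zero-count samples
#'   per gene.
#' @return the filtered \code{stress_counts} object.
#' @export
filter_zero_genes <- function(x, max_zero_samples = 12) {
  stopifnot(inherits(x, "stress_counts"),
            max_zero_samples >= 0, max_zero_samples <= ncol(x$counts))
  n_zero <- rowSums(x$counts == 0)
  keep <- n_zero <= max_zero_samples
  if (!any(keep)) warning("all genes removed by the zero-count filter")
  subset_genes(x, keep)
}

#' FPKM transform
#'
#' value = count * 1e9 / (length_bp * column sum). Library size is the
#' post-filter column sum; lengths only enter here, so counts themselves are
#' length-independent.
#'
#' @param x a [stress_counts()] object (already filtered).
#' @return expression matrix tagged \code{"fpkm"}.
#' @export
fpkm <- function(x) {
  stopifnot(inherits(x, "stress_counts"))
  lib <- colSums(x$counts)
  if (any(lib == 0))
    stop("zero library size in sample(s): ",
         paste(colnames(x$counts)[lib == 0], collapse = ", "))
  vals <- sweep(x$counts * 1e9 / x$lengths_bp, 2, lib, "/")
  as_expression(vals, "fpkm")
}

#' log2(FPKM + 1) with quantile normalization
#'
#' Each cell becomes log2(value + pseudocount); columns are then quantile
#' normalized to the across-column mean of order statistics, so every
#' column shares an identical sorted value multiset.
#'
#' Tie handling: with \code{ties = "reference"} (default) tied values are
#' assigned adjacent reference quantiles in stable row order, which keeps
#' the sorted multisets of all columns exactly identical; with
#' \code{ties = "mean"} a tie group shares the mean of its reference
#' quantiles (then the multiset identity holds only up to tie groups).
#' Both policies are deterministic.
#'
#' @param expr an \code{"fpkm"}-tagged expression matrix.
#' @param pseudocount added before the log (1, matching the FPKM + 1 rule).
#' @param ties tie policy, \code{"reference"} or \code{"mean"}.
#' @return expression matrix tagged \code{"log2_quantile"}.
#' @export
log2_quantile <- function(expr, pseudocount = 1,
                          ties = c("reference", "mean")) {
  stopifnot(pseudocount > 0)
  ties <- match.arg(ties)
  if (!identical(transform_tag(expr), "fpkm"))
    stop("log2_quantile expects an fpkm-tagged matrix")
  lg <- log2(unclass(expr) + pseudocount)
  if (ncol(lg) == 1) {
    warning("single column: quantile step is the identity")
    return(as_expression(lg, "log2_quantile"))
  }
  ref <- rowMeans(apply(lg, 2, sort))
  out <- apply(lg, 2, function(col) {
    res <- numeric(length(col))
    res[order(col)] <- ref
    if (ties == "mean") res <- stats::ave(res, col, FUN = mean)
    res
  })
  dimnames(out) <- dimnames(lg)
  as_expression(out, "log2_quantile")
}

#' Log-centered log-ratio transform of gene count profiles
#'
#' Per gene, with a +1 pseudocount guarding zeros:
#' p_j = (count_j + 1) / sum_j (count_j + 1), value_j = ln p_j - mean ln p.
#' Rows are exactly centered (sum 0). Natural log, as is conventional for
#' compositional transforms; fold changes elsewhere use log2.
#'
#' With \code{tmm_scale = TRUE} counts are first divided by their
#' TMM-scaled effective library size (rescaled to geometric mean 1 so
#' magnitudes stay count-like) and the transform is applied to the scaled
#' values: the co-expression compendium is built on TMM-normalized logCLR
#' values, which removes sequencing-depth variation from the across-sample
#' profiles. The order (TMM on counts, then logCLR) is recorded in the
#' \code{"tmm_scaled"} attribute.
#'
#' @param x a [stress_counts()] object.
#' @param tmm_scale apply TMM/library-size scaling before the transform.
#' @return expression matrix tagged \code{"logclr"}.
#' @export
logclr <- function(x, tmm_scale = FALSE) {
  stopifnot(inherits(x, "stress_counts"))
  vals <- x$counts
  if (tmm_scale) {
    eff <- colSums(vals) * tmm_factors(x)
    vals <- sweep(vals, 2, eff / exp(mean(log(eff))), "/")
  }
  p <- vals + 1
  p <- p / rowSums(p)
  lp <- log(p)
  out <- as_expression(lp - rowMeans(lp), "logclr")
  attr(out, "tmm_scaled") <- tmm_scale
  out
}

#' Trimmed mean of M-values scale factors
#'
#' Between-sample scaling factors from doubly trimmed, precision-weighted
#' means of per-gene log2 count-fraction ratios (M values) against a
#' reference column, the sample whose 75th percentile of library-scaled
#' counts is closest to the mean 75th percentile. M values are trimmed by
#' \code{trim_m} (default 0.30) and absolute intensities by \code{trim_a}
#' (default 0.05); factors are normalized to geometric mean 1.
#'
#' @param x a [stress_counts()] object with at least 2 samples.
#' @param trim_m,trim_a two-sided trim fractions for M and A statistics.
#' @return named positive numeric vector of per-sample factors.
#' @export
tmm_factors <- function(x, trim_m = 0.30, trim_a = 0.05) {
  stopifnot(inherits(x, "stress_counts"), ncol(x$counts) >= 2,
            trim_m >= 0, trim_m < 0.5, trim_a >= 0, trim_a < 0.5)
  counts <- x$counts
  lib <- colSums(counts)
  if (any(lib == 0))
    stop("all-zero column(s): ",
         paste(colnames(counts)[lib == 0], collapse = ", "))
  f75 <- vapply(seq_len(ncol(counts)),
                function(j) stats::quantile(counts[, j], 0.75) / lib[j], 0)
  ref <- which.min(abs(f75 - mean(f75)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], lib[j], counts[, ref], lib[ref], trim_m, trim_a)
  }, 0)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(counts))
}

#' One TMM factor: sample obs against reference ref
#' @noRd
.tmm_pair <- function(obs, n_obs, ref, n_ref, trim_m, trim_a) {
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- (log2(obs / n_obs) + log2(ref / n_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(m) & is.finite(a) & a > -1e10
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  if (length(m) == 0 || max(abs(m)) < 1e-6) return(1)
  n <- length(m)
  lo_m <- floor(n * trim_m) + 1; hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1; hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  f <- 2^(sum(m[keep] / v[keep], na.rm = TRUE) /
            sum(1 / v[keep], na.rm = TRUE))
  if (!is.finite(f)) 1 else f
}

#' Pairwise Pearson correlation of samples
#'
#' @param expr an expression matrix (genes x samples), any transform.
#' @return symmetric sample x sample correlation matrix (diagonal 1;
#'   zero-variance columns give \code{NA}, not 0) with an \code{"order"}
#'   attribute holding the average-linkage hierarchical leaf order.
#' @export
sample_correlation <- function(expr) {
  m <- unclass(expr)
  stopifnot(nrow(m) >= 2)
  sds <- apply(m, 2, stats::sd)
  r <- suppressWarnings(stats::cor(m))
  r[sds == 0, ] <- NA_real_
  r[, sds == 0] <- NA_real_
  diag(r) <- 1
  ok <- sds > 0
  ord <- seq_len(ncol(m))
  if (sum(ok) >= 2) {
    hc <- stats::hclust(stats::as.dist(1 - r[ok, ok, drop = FALSE]),
                        method = "average")
    ord <- c(which(ok)[hc$order], which(!ok))
  }
  attr(r, "order") <- ord
  r
}
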