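#' Parameters for weighted co-expression network construction
#'
#' Defaults are community-standard: unsigned adjacency, scale-free fit
#' target R^2 0.8 over a power grid 1..20, minimum module size 30, static
#' cut at height 0.99 on the 1 - TOM dendrogram, eigengene-correlation
#' merge cut 0.75.
#'
#' @param powers candidate soft-threshold powers.
#' @param rsq_target scale-free topology fit target.
#' @param sign_mode \code{"unsigned"} (|r|^beta) or \code{"signed"}
#'   (((1 + r)/2)^beta).
#' @param min_module_size smallest reportable module; smaller clusters are
#'   left unassigned ("grey").
#' @param cut_height static cut height on the 1 - TOM dendrogram.
#' @param merge_cut modules whose eigengenes correlate above this are merged.
#' @param edge_threshold default TOM threshold for network export.
#' @return a \code{network_params} list.
#' @export
network_params <- function(powers = 1:20, rsq_target = 0.8,
                           sign_mode = c("unsigned", "signed"),
                           min_module_size = 30, cut_height = 0.99,
                           merge_cut = 0.75, edge_threshold = 0.1) {
  stopifnot(all(powers >= 1), cut_height > 0, cut_height <= 1,
            merge_cut > 0, merge_cut <= 1, min_module_size >= 2)
  structure(list(powers = powers, rsq_target = rsq_target,
                 sign_mode = match.arg(sign_mode),
                 min_module_size = min_module_size,
                 cut_height = cut_height, merge_cut = merge_cut,
                 edge_threshold = edge_threshold),
            class = "network_params")
}

.module_colors <- c("turquoise", "blue", "brown", "yellow", "green", "red",
                    "black", "pink", "magenta", "purple", "greenyellow",
                    "tan", "salmon", "cyan", "midnightblue", "lightcyan",
                    "grey60", "lightgreen", "lightyellow", "royalblue")

#' Genes differentially expressed in at least one mutant contrast
#'
#' @param deg_sets list of DEG tables from [mutant_deg_sets()].
#' @return sorted character vector (union of non-\code{none} labels).
#' @export
select_coexpression_genes <- function(deg_sets) {
  stopifnot(length(deg_sets) >= 1)
  genes <- sort(unique(unlist(lapply(deg_sets, function(s)
    s$gene[s$label != "none"]))))
  if (length(genes) == 0) warning("no differentially expressed genes found")
  genes
}

#' k-means co-expression compendium
#'
#' Squared-Euclidean k-means on gene rows (k-means++ seeding feeding Lloyd
#' iterations, 10 restarts, best total within-cluster sum of squares wins).
#'
#' @param expr a \code{"logclr"}-tagged expression matrix (genes x samples).
#' @param K number of clusters.
#' @param seed integer seed (fixed seed gives a deterministic assignment).
#' @param n_restarts independent k-means++ restarts.
#' @return named integer vector gene -> cluster with a \code{"tot_withinss"}
#'   attribute.
#' @export
kmeans_modules <- function(expr, K, seed = 1, n_restarts = 10) {
  if (!identical(transform_tag(expr), "logclr"))
    stop("kmeans_modules expects a logclr-tagged matrix")
  m <- unclass(expr)
  if (K <= 0) stop("K must be positive")
  stopifnot(K <= nrow(m))
  if (K == 1) {
    res <- stats::setNames(rep(1L, nrow(m)), rownames(m))
    attr(res, "tot_withinss") <- sum(scale(m, scale = FALSE)^2)
    return(res)
  }
  best <- NULL
  withr::with_seed(seed, {
    for (r in seq_len(n_restarts)) {
      centers <- m[.kmpp_init(m, K), , drop = FALSE]
      km <- suppressWarnings(
        stats::kmeans(m, centers = centers, algorithm = "Lloyd",
                      iter.max = 200))
      if (is.null(best) || km$tot.withinss < best$tot.withinss) best <- km
    }
  })
  res <- stats::setNames(best$cluster, rownames(m))
  attr(res, "tot_withinss") <- best$tot.withinss
  res
}

#' k-means++ center selection
#' @noRd
.kmpp_init <- function(m, K) {
  n <- nrow(m)
  centers <- sample.int(n, 1)
  d2 <- rowSums(sweep(m, 2, m[centers, ])^2)
  while (length(centers) < K) {
    prob <- d2 / sum(d2)
    if (all(prob == 0)) prob <- rep(1 / n, n)
    nxt <- sample.int(n, 1, prob = prob)
    centers <- c(centers, nxt)
    d2 <- pmin(d2, rowSums(sweep(m, 2, m[nxt, ])^2))
  }
  centers
}

#' Scale-free fit of one connectivity distribution
#' @noRd
.scale_free_fit <- function(k, n_bins = 10) {
  k <- k[k > 0]
  if (length(k) < n_bins) n_bins <- max(2L, length(k) %/% 2L)
  br <- seq(min(k), max(k), length.out = n_bins + 1)
  bin <- cut(k, br, include.lowest = TRUE)
  pk <- as.numeric(table(bin)) / length(k)
  dk <- tapply(k, bin, mean)
  keep <- pk > 0 & !is.na(dk)
  if (sum(keep) < 3) return(c(sf_r2 = 0, slope = 0))
  fit <- stats::lm(log10(pk[keep]) ~ log10(dk[keep]))
  r2 <- summary(fit)$r.squared
  slope <- stats::coef(fit)[[2]]
  c(sf_r2 = ifelse(slope < 0, r2, -r2), slope = slope)
}

#' Soft-threshold power selection by scale-free topology fit
#'
#' For each candidate power the adjacency is formed, per-gene connectivity
#' computed, and the fit R^2 of log10 p(k) against log10 k over binned
#' connectivities evaluated (signed: a positive slope counts against the
#' fit). The smallest power reaching \code{rsq_target} is selected; if none
#' qualifies, the power maximizing the fit is returned with a warning.
#'
#' @param expr expression matrix, genes x samples (>= 3 samples).
#' @param params a [network_params()] object.
#' @return list: \code{power}, \code{fit} (data frame with \code{power},
#'   \code{sf_r2}, \code{slope}, \code{mean_k}).
#' @export
pick_soft_threshold <- function(expr, params = network_params()) {
  m <- unclass(expr)
  stopifnot(ncol(m) >= 3)
  if (any(apply(m, 1, stats::sd) == 0))
    stop("constant (zero-variance) gene profiles; remove before network construction")
  r <- stats::cor(t(m))
  base <- if (params$sign_mode == "unsigned") abs(r) else (1 + r) / 2
  diag(base) <- 0
  fit <- do.call(rbind, lapply(params$powers, function(p) {
    a <- base^p
    k <- rowSums(a)
    sf <- .scale_free_fit(k)
    data.frame(power = p, sf_r2 = sf[["sf_r2"]], slope = sf[["slope"]],
               mean_k = mean(k))
  }))
  ok <- fit$power[fit$sf_r2 >= params$rsq_target]
  if (length(ok) > 0) {
    power <- min(ok)
  } else {
    power <- fit$power[which.max(fit$sf_r2)]
    warning("no power reached the scale-free fit target; returning the ",
            "best-fitting power ", power)
  }
  list(power = power, fit = fit)
}

#' Topological overlap matrix from soft-thresholded adjacency
#'
#' Adjacency a_ij = |cor(i,j)|^beta (unsigned) or ((1 + cor)/2)^beta
#' (signed); TOM_ij = (sum_u a_iu a_uj + a_ij) /
#' (min(k_i, k_j) + 1 - a_ij) with k_i the connectivity of gene i,
#' diagonal set to 1.
#'
#' @param expr expression matrix, genes x samples, no missing values.
#' @param beta soft-threshold power.
#' @param sign_mode \code{"unsigned"} or \code{"signed"}.
#' @return symmetric TOM matrix with entries in [0, 1] and a \code{"beta"}
#'   attribute.
#' @export
adjacency_and_tom <- function(expr, beta,
                              sign_mode = c("unsigned", "signed")) {
  sign_mode <- match.arg(sign_mode)
  m <- unclass(expr)
  if (anyNA(m)) stop("missing values in expression matrix")
  sds <- apply(m, 1, stats::sd)
  if (any(sds == 0))
    stop("zero-variance gene(s): ",
         paste(rownames(m)[sds == 0], collapse = ", "))
  r <- stats::cor(t(m))
  a <- if (sign_mode == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
  diag(a) <- 0
  l <- a %*% a
  k <- rowSums(a)
  kmin <- outer(k, k, pmin)
  tom <- (l + a) / (kmin + 1 - a)
  diag(tom) <- 1
  dimnames(tom) <- dimnames(r)
  attr(tom, "beta") <- beta
  attr(tom, "sign_mode") <- sign_mode
  tom
}

#' Module detection by static tree cut with eigengene merging
#'
#' Average-linkage hierarchical clustering on 1 - TOM, static cut at
#' \code{params$cut_height}; clusters below \code{min_module_size} are left
#' unassigned ("grey"). When \code{expr} is supplied, modules whose
#' eigengenes correlate above \code{merge_cut} are merged iteratively.
#' Surviving modules are given color labels by decreasing size.
#'
#' @param tom TOM matrix from [adjacency_and_tom()].
#' @param params a [network_params()] object.
#' @param expr optional expression matrix (genes x samples) used for the
#'   eigengene merge step; skipped when \code{NULL}.
#' @return named character vector gene -> module color ("grey" =
#'   unassigned) with a \code{"sizes"} attribute.
#' @export
detect_modules <- function(tom, params = network_params(), expr = NULL) {
  hc <- stats::hclust(stats::as.dist(1 - tom), method = "average")
  cl <- stats::cutree(hc, h = params$cut_height)
  sizes <- table(cl)
  cl[cl %in% as.integer(names(sizes)[sizes < params$min_module_size])] <- 0L
  if (!is.null(expr) && length(unique(cl[cl != 0])) > 1) {
    repeat {
      labs <- sort(unique(cl[cl != 0]))
      if (length(labs) < 2) break
      eig <- module_eigengenes(expr, stats::setNames(cl, rownames(tom)))
      cm <- stats::cor(t(eig))
      diag(cm) <- -Inf
      mx <- which(cm == max(cm), arr.ind = TRUE)[1, ]
      if (cm[mx[1], mx[2]] <= params$merge_cut) break
      a <- as.integer(sub("^module_", "", rownames(cm)[mx[1]]))
      b <- as.integer(sub("^module_", "", rownames(cm)[mx[2]]))
      cl[cl == b] <- a
    }
  }
  out <- rep("grey", length(cl))
  labs <- sort(unique(cl[cl != 0]))
  ord <- labs[order(-tabulate(match(cl, labs)))]
  palette <- c(.module_colors,
               paste0("module", seq_len(max(0, length(ord) -
                                              length(.module_colors)))))
  for (i in seq_along(ord)) out[cl == ord[i]] <- palette[i]
  names(out) <- rownames(tom)
  attr(out, "sizes") <- sort(table(out[out != "grey"]), decreasing = TRUE)
  out
}

#' Module eigengenes
#'
#' The eigengene of a module is the first principal component (unit-norm
#' left singular vector) of its gene-standardized expression submatrix,
#' sign-oriented so that its correlation with the module's mean
#' standardized profile is nonnegative.
#'
#' @param expr expression matrix, genes x samples.
#' @param assignment named gene -> module vector; \code{"grey"} / \code{0}
#'   entries are skipped.
#' @return module x sample matrix with a \code{"var_explained"} attribute.
#' @export
module_eigengenes <- function(expr, assignment) {
  m <- unclass(expr)
  assignment <- assignment[rownames(m)]
  mods <- sort(unique(assignment[!assignment %in% c("grey", 0, NA)]))
  if (length(mods) == 0) stop("no assigned modules")
  ve <- numeric(length(mods))
  eig <- matrix(NA_real_, length(mods), ncol(m),
                dimnames = list(
                  if (is.numeric(mods)) paste0("module_", mods) else mods,
                  colnames(m)))
  for (i in seq_along(mods)) {
    sub <- m[which(assignment == mods[i]), , drop = FALSE]
    if (nrow(sub) < 2) stop("module ", mods[i], " has fewer than 2 genes")
    sds <- apply(sub, 1, stats::sd)
    if (any(sds == 0))
      stop("constant gene profile(s) in module ", mods[i])
    z <- (sub - rowMeans(sub)) / sds
    sv <- svd(t(z))
    e <- sv$u[, 1]
    avg <- colMeans(z)
    if (sum(e * avg) < 0) e <- -e
    eig[i, ] <- e
    ve[i] <- sv$d[1]^2 / sum(sv$d^2)
  }
  attr(eig, "var_explained") <- stats::setNames(ve, rownames(eig))
  eig
}

#' Module-trait correlation with Student-t p-values
#'
#' r = Pearson correlation of each eigengene with each binary trait
#' indicator; two-sided p from t = r sqrt(n - 2) / sqrt(1 - r^2) with
#' n - 2 degrees of freedom.
#'
#' @param eig module x sample eigengene matrix.
#' @param traits sample x trait indicator matrix (see [trait_design()]).
#' @return list of module x trait matrices \code{r} and \code{p}; constant
#'   trait columns give \code{NA} entries.
#' @export
module_trait <- function(eig, traits) {
  stopifnot(ncol(eig) == nrow(traits))
  n <- ncol(eig)
  const <- apply(traits, 2, function(x) stats::var(x) == 0)
  r <- suppressWarnings(stats::cor(t(eig), traits))
  r[, const] <- NA_real_
  tstat <- r * sqrt(n - 2) / sqrt(pmax(1 - r^2, 0))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  p[is.nan(p)] <- 0  # |r| = 1 underflow
  list(r = r, p = p)
}

#' Export the weighted network as an edge list
#'
#' @param tom TOM matrix.
#' @param assignment gene -> module vector for the node table.
#' @param threshold minimum edge weight in [0, 1]; edges with
#'   weight >= threshold are kept, each unordered pair once.
#' @return list: \code{edges} (\code{gene_a}, \code{gene_b},
#'   \code{weight}), \code{nodes} (\code{gene}, \code{module}).
#' @export
export_network <- function(tom, assignment, threshold) {
  stopifnot(threshold >= 0, threshold <= 1)
  ut <- which(upper.tri(tom) & tom >= threshold, arr.ind = TRUE)
  edges <- data.frame(gene_a = rownames(tom)[ut[, 1]],
                      gene_b = colnames(tom)[ut[, 2]],
                      weight = tom[ut], row.names = NULL)
  nodes <- data.frame(gene = rownames(tom),
                      module = unname(assignment[rownames(tom)]),
                      row.names = NULL)
  list(edges = edges, nodes = nodes)
}
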