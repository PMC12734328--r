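#' Fold-change and responsiveness thresholds
#'
#' Genes with |log2FC| >= \code{deg_cut} (default 2) are differentially
#' expressed; genes with |log2FC| <= \code{silent_cut} (default 0.5) are
#' silent. Boundaries are inclusive.
#'
#' \code{silent_mode} controls the mutant-side silence criterion of
#' [classify_mutant_response()]: \code{"one_sided_as_printed"} bounds the
#' mutant fold change on one side only (>= -silent_cut for the up rule,
#' <= +silent_cut for the down rule, exactly as the screening inequalities
#' are written); \code{"two_sided"} requires |fc_mut| <= silent_cut.
#'
#' @param deg_cut,silent_cut positive cutoffs, \code{deg_cut > silent_cut}.
#' @param silent_mode see above.
#' @return a \code{response_thresholds} list.
#' @export
response_thresholds <- function(deg_cut = 2, silent_cut = 0.5,
                                silent_mode = c("one_sided_as_printed",
                                                "two_sided")) {
  stopifnot(deg_cut > silent_cut, silent_cut > 0)
  structure(list(deg_cut = deg_cut, silent_cut = silent_cut,
                 silent_mode = match.arg(silent_mode)),
            class = "response_thresholds")
}

#' Per-gene log2 fold changes of stressed samples against baseline
#'
#' log2FC = log2((FPKM_st + 1) / (FPKM_nor + 1)), the baseline being the
#' same strain's unstressed time-0 sample.
#'
#' @param expr an \code{"fpkm"}-tagged expression matrix.
#' @param design design data frame matching the matrix columns.
#' @param pseudocount added to both numerator and denominator (default 1).
#' @return long data frame: \code{gene}, \code{strain}, \code{stress},
#'   \code{time_h}, \code{sample}, \code{baseline}, \code{log2fc}.
#' @export
fold_changes <- function(expr, design, pseudocount = 1) {
  if (!identical(transform_tag(expr), "fpkm"))
    stop("fold_changes expects an fpkm-tagged matrix")
  stopifnot(identical(design$sample, colnames(expr)))
  m <- unclass(expr)
  stressed <- which(design$stress != "none" | design$time_h > 0)
  base_of <- function(strain) {
    j <- which(design$strain == strain & design$stress == "none" &
                 design$time_h == 0)
    if (length(j) != 1)
      stop("missing unstressed baseline for strain ", strain)
    j
  }
  out <- lapply(stressed, function(j) {
    b <- base_of(design$strain[j])
    data.frame(gene = rownames(m), strain = design$strain[j],
               stress = design$stress[j], time_h = design$time_h[j],
               sample = design$sample[j], baseline = design$sample[b],
               log2fc = log2((m[, j] + pseudocount) /
                               (m[, b] + pseudocount)),
               row.names = NULL)
  })
  do.call(rbind, out)
}

#' Screen genes as DEG / silent / intermediate within a strain
#'
#' @param fc a fold-change table from [fold_changes()] (or any data frame
#'   with a \code{log2fc} column).
#' @param th a [response_thresholds()] object.
#' @return the input with a \code{screen} column in
#'   \{\code{deg}, \code{silent}, \code{intermediate}\}.
#' @export
screen_degs <- function(fc, th = response_thresholds()) {
  a <- abs(fc$log2fc)
  fc$screen <- ifelse(a >= th$deg_cut, "deg",
                      ifelse(a <= th$silent_cut, "silent", "intermediate"))
  fc
}

#' Classify mutant stress responsiveness of one gene
#'
#' The curated screening rule: a gene is \code{up_in_mutant} (relatively
#' upregulated in the mutant) when the wild type responds downward
#' (fc_wt <= -deg_cut) while the mutant stays silent (fc_mut >= -silent_cut
#' in the printed one-sided mode, |fc_mut| <= silent_cut in two-sided
#' mode); \code{down_in_mutant} is the mirror image (fc_wt >= deg_cut,
#' fc_mut <= silent_cut). Everything else is \code{none}. Note the
#' direction semantics: "up in mutant" records a wild-type down-response
#' the mutant fails to mount.
#'
#' @param fc_wt,fc_mut finite log2 fold changes (stress vs baseline) of the
#'   wild type and the mutant; vectorized.
#' @param th a [response_thresholds()] object.
#' @return character vector of labels.
#' @export
classify_mutant_response <- function(fc_wt, fc_mut,
                                     th = response_thresholds()) {
  stopifnot(all(is.finite(fc_wt)), all(is.finite(fc_mut)),
            length(fc_wt) == length(fc_mut))
  two_sided <- th$silent_mode == "two_sided"
  up_silent <- if (two_sided) abs(fc_mut) <= th$silent_cut else
    fc_mut >= -th$silent_cut
  dn_silent <- if (two_sided) abs(fc_mut) <= th$silent_cut else
    fc_mut <= th$silent_cut
  ifelse(fc_wt <= -th$deg_cut & up_silent, "up_in_mutant",
         ifelse(fc_wt >= th$deg_cut & dn_silent, "down_in_mutant", "none"))
}

#' Build per-contrast mutant DEG tables from a fold-change table
#'
#' For every (mutant, stress, time) combination present in the fold-change
#' table that has a matching wild-type contrast, pairs each gene's WT and
#' mutant fold changes and applies [classify_mutant_response()]. Genes
#' missing from either strain's table are excluded; their count is recorded
#' in the \code{n_dropped} attribute.
#'
#' @param fc a [fold_changes()] table covering WT and mutant samples.
#' @param th a [response_thresholds()] object.
#' @return named list of DEG tables (\code{gene}, \code{fc_wt},
#'   \code{fc_mut}, \code{label}), one per contrast, each carrying
#'   \code{mutant}, \code{stress}, \code{time_h}, \code{thresholds}
#'   attributes.
#' @export
mutant_deg_sets <- function(fc, th = response_thresholds()) {
  muts <- unique(fc[fc$strain != "WT", c("strain", "stress", "time_h")])
  sets <- list()
  for (i in seq_len(nrow(muts))) {
    mut <- muts$strain[i]; st <- muts$stress[i]; tt <- muts$time_h[i]
    wt <- fc[fc$strain == "WT" & fc$stress == st & fc$time_h == tt, ]
    mu <- fc[fc$strain == mut & fc$stress == st & fc$time_h == tt, ]
    if (nrow(wt) == 0) next
    common <- intersect(wt$gene, mu$gene)
    wt <- wt[match(common, wt$gene), ]
    mu <- mu[match(common, mu$gene), ]
    ds <- data.frame(gene = common, fc_wt = wt$log2fc, fc_mut = mu$log2fc,
                     label = classify_mutant_response(wt$log2fc, mu$log2fc,
                                                      th),
                     row.names = NULL)
    attr(ds, "mutant") <- mut
    attr(ds, "stress") <- st
    attr(ds, "time_h") <- tt
    attr(ds, "thresholds") <- th
    attr(ds, "n_dropped") <-
      length(union(wt$gene, mu$gene)) - length(common)
    sets[[paste(mut, st, tt, sep = "_")]] <- ds
  }
  sets
}

#' Count summary of one DEG table
#'
#' @param ds a DEG table from [mutant_deg_sets()] (or any data frame with a
#'   \code{label} column).
#' @return named vector: \code{up}, \code{down}, \code{total},
#'   \code{up_pct}, \code{down_pct} (percentages of the total DEG count).
#' @export
deg_summary <- function(ds) {
  up <- sum(ds$label == "up_in_mutant")
  dn <- sum(ds$label == "down_in_mutant")
  tot <- up + dn
  c(up = up, down = dn, total = tot,
    up_pct = if (tot > 0) 100 * up / tot else NA_real_,
    down_pct = if (tot > 0) 100 * dn / tot else NA_real_)
}

#' Overlap of two DEG tables (same mutant, different time points)
#'
#' @param a,b DEG tables from [mutant_deg_sets()].
#' @return named vector: \code{co_up} (up in both), \code{co_down} (down in
#'   both), \code{total} (labelled non-none in both), \code{discordant}
#'   (labelled in both with opposite directions).
#' @export
overlap_degs <- function(a, b) {
  la <- stats::setNames(a$label, a$gene)
  lb <- stats::setNames(b$label, b$gene)
  common <- intersect(names(la)[la != "none"], names(lb)[lb != "none"])
  co_up <- sum(la[common] == "up_in_mutant" &
                 lb[common] == "up_in_mutant")
  co_dn <- sum(la[common] == "down_in_mutant" &
                 lb[common] == "down_in_mutant")
  c(co_up = co_up, co_down = co_dn, total = length(common),
    discordant = length(common) - co_up - co_dn)
}

#' Jointly regulated genes across the three MAPK mutants
#'
#' @param sets list of exactly three DEG tables (one per mutant) over a
#'   shared gene universe, same stress-time regime (acute or sustained).
#' @return list with character vectors \code{jointly_up} and
#'   \code{jointly_down}.
#' @export
crosstalk_degs <- function(sets) {
  if (length(sets) != 3)
    stop("crosstalk requires DEG tables for all three mutants")
  pick <- function(lab)
    Reduce(intersect, lapply(sets, function(s) s$gene[s$label == lab]))
  list(jointly_up = pick("up_in_mutant"),
       jointly_down = pick("down_in_mutant"))
}
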