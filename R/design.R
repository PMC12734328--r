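#' Sample design of the strain x stress x time study
#'
#' The study profiles the wild type (WT) and three MAPK deletion mutants
#' (dHog1, dSlt2, dMpk1) of \emph{Beauveria bassiana}. WT is sampled
#' unstressed (time 0) and under four stress agents (sorbitol, menadione,
#' Congo red, 32 C heat) at 0.5 h and 12 h; each mutant is sampled unstressed
#' and under its sensitive stress only (dHog1: sorbitol, dSlt2: heat,
#' dMpk1: menadione), giving 18 pooled libraries in total.
#'
#' Sample identifiers follow the \code{Strain_Stress_Time} convention with
#' the stress codes \code{none}, \code{SOB} (sorbitol), \code{MND}
#' (menadione), \code{CR} (Congo red) and \code{HT} (heat), e.g.
#' \code{"WT_SOB_0.5"} or \code{"dHog1_none_0"}.
#'
#' @name design
NULL

.strains <- c("WT", "dHog1", "dSlt2", "dMpk1")
.stresses <- c("none", "sorbitol", "menadione", "congo_red", "heat")
.stress_codes <- c(none = "none", sorbitol = "SOB", menadione = "MND",
                   congo_red = "CR", heat = "HT")
.times <- c(0, 0.5, 12)

#' Stress whose response each mutant fails to mount
#' @noRd
.sensitive_stress <- c(dHog1 = "sorbitol", dSlt2 = "heat", dMpk1 = "menadione")

#' The default 18-condition design
#'
#' @return A data frame with columns \code{sample}, \code{strain},
#'   \code{stress}, \code{time_h}; one row per pooled library.
#' @export
default_design <- function() {
  rows <- list(data.frame(strain = "WT", stress = "none", time_h = 0))
  for (st in setdiff(.stresses, "none"))
    for (tt in c(0.5, 12))
      rows[[length(rows) + 1L]] <- data.frame(strain = "WT", stress = st, time_h = tt)
  for (mut in names(.sensitive_stress)) {
    rows[[length(rows) + 1L]] <- data.frame(strain = mut, stress = "none", time_h = 0)
    for (tt in c(0.5, 12))
      rows[[length(rows) + 1L]] <-
        data.frame(strain = mut, stress = .sensitive_stress[[mut]], time_h = tt)
  }
  design <- do.call(rbind, rows)
  design <- data.frame(sample = format_sample_id(design$strain, design$stress,
                                                 design$time_h),
                       design, row.names = NULL)
  design
}

#' Compose a Strain_Stress_Time sample identifier
#'
#' @param strain,stress,time_h vectors of strain names, long stress names
#'   (\code{"sorbitol"}, ...) and times in hours.
#' @return character vector of identifiers such as \code{"WT_SOB_0.5"}.
#' @export
format_sample_id <- function(strain, stress, time_h) {
  stopifnot(all(strain %in% .strains), all(stress %in% .stresses))
  paste(strain, .stress_codes[stress], vapply(time_h, as.character, ""),
        sep = "_")
}

#' Parse Strain_Stress_Time sample identifiers
#'
#' @param ids character vector of identifiers.
#' @return data frame with columns \code{sample}, \code{strain},
#'   \code{stress}, \code{time_h}.
#' @export
parse_sample_ids <- function(ids) {
  parts <- strsplit(ids, "_", fixed = TRUE)
  bad <- vapply(parts, length, 1L) != 3L
  if (any(bad))
    stop("malformed sample id(s): ", paste(ids[bad], collapse = ", "))
  strain <- vapply(parts, `[[`, "", 1L)
  code <- vapply(parts, `[[`, "", 2L)
  time_h <- suppressWarnings(as.numeric(vapply(parts, `[[`, "", 3L)))
  long <- stats::setNames(names(.stress_codes), .stress_codes)
  if (!all(strain %in% .strains) || !all(code %in% .stress_codes) ||
      anyNA(time_h) || !all(time_h %in% .times))
    stop("unrecognized strain/stress/time in sample ids")
  data.frame(sample = ids, strain = strain, stress = unname(long[code]),
             time_h = time_h, row.names = NULL)
}

#' Binary trait indicator matrix for module-trait correlation
#'
#' One 0/1 indicator column per strain, per stress level (including
#' \code{none}, the non-stress trait) and per time point, as in the
#' module-trait association heatmap of the study design.
#'
#' @param design a design data frame (see [default_design()]).
#' @return numeric matrix, samples x traits, entries 0/1; row names are
#'   sample ids, column names \code{strain_*}, \code{stress_*}, \code{time_*}.
#' @export
trait_design <- function(design) {
  stopifnot(all(c("sample", "strain", "stress", "time_h") %in% names(design)))
  cols <- list()
  for (s in intersect(.strains, unique(design$strain)))
    cols[[paste0("strain_", s)]] <- as.numeric(design$strain == s)
  for (st in intersect(.stresses, unique(design$stress)))
    cols[[paste0("stress_", st)]] <- as.numeric(design$stress == st)
  for (tt in sort(unique(design$time_h)))
    cols[[paste0("time_", as.character(tt))]] <-
      as.numeric(design$time_h == tt)
  m <- do.call(cbind, cols)
  rownames(m) <- design$sample
  m
}
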