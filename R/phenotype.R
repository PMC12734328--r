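#' Relative growth inhibition from colony diameters
#'
#' RGI = (Dc - Ds) / (Ds - d) * 100 with Dc the control colony diameter,
#' Ds the stressed colony diameter and d the inoculum plug diameter
#' (5 mm). An alternate convention normalizing by the control growth,
#' (Dc - Ds) / (Dc - d) * 100, is available via \code{formula =
#' "conventional"} and is always labelled in the result.
#'
#' @param Dc,Ds mean control and stressed colony diameters (mm); vectorized.
#' @param d inoculum plug diameter (mm).
#' @param formula \code{"printed"} (denominator Ds - d) or
#'   \code{"conventional"} (denominator Dc - d).
#' @return numeric vector of RGI percentages with a \code{"formula"}
#'   attribute.
#' @export
rgi <- function(Dc, Ds, d = 5, formula = c("printed", "conventional")) {
  formula <- match.arg(formula)
  if (formula == "printed" && any(Ds <= d))
    stop("stressed diameter Ds must exceed the plug diameter d")
  if (formula == "conventional" && any(Dc <= d))
    stop("control diameter Dc must exceed the plug diameter d")
  denom <- if (formula == "printed") Ds - d else Dc - d
  structure((Dc - Ds) / denom * 100, formula = formula)
}

#' RGI table from replicate colony-diameter records
#'
#' Per strain x medium x stress condition: mean control and stressed
#' diameters, RGI of the means, and the replicate SD of per-replicate RGI
#' values (replicate i control paired with replicate i stressed plate).
#' The result doubles as long-format radar-plot data.
#'
#' @param records data frame with columns \code{strain}, \code{medium},
#'   \code{stress}, \code{replicate}, \code{diameter_mm},
#'   \code{is_control} (see [simulate_growth()]).
#' @param d inoculum plug diameter (mm).
#' @param formula passed to [rgi()].
#' @return data frame: \code{strain}, \code{medium}, \code{stress},
#'   \code{Dc}, \code{Ds}, \code{rgi}, \code{rgi_sd}, \code{n_rep}.
#' @export
rgi_table <- function(records, d = 5, formula = c("printed", "conventional")) {
  formula <- match.arg(formula)
  need <- c("strain", "medium", "stress", "replicate", "diameter_mm",
            "is_control")
  stopifnot(all(need %in% names(records)))
  key <- interaction(records$strain, records$medium, records$stress,
                     drop = TRUE)
  out <- lapply(levels(key), function(kk) {
    rec <- records[key == kk, ]
    ctl <- rec[rec$is_control, ]
    str <- rec[!rec$is_control, ]
    if (nrow(ctl) == 0 || nrow(str) == 0)
      stop("missing control/stress pairing for condition ", kk)
    per_rep <- merge(ctl[c("replicate", "diameter_mm")],
                     str[c("replicate", "diameter_mm")], by = "replicate",
                     suffixes = c("_c", "_s"))
    rep_rgi <- rgi(per_rep$diameter_mm_c, per_rep$diameter_mm_s, d, formula)
    data.frame(strain = rec$strain[1], medium = rec$medium[1],
               stress = rec$stress[1], Dc = mean(ctl$diameter_mm),
               Ds = mean(str$diameter_mm),
               rgi = as.numeric(rgi(mean(ctl$diameter_mm),
                                    mean(str$diameter_mm), d, formula)),
               rgi_sd = stats::sd(rep_rgi), n_rep = nrow(per_rep))
  })
  out <- do.call(rbind, out)
  out <- out[order(out$strain, out$medium, out$stress), ]
  rownames(out) <- NULL
  attr(out, "formula") <- formula
  out
}

#' Extracellular acidification rates from a plate time series
#'
#' Per well, the ordinary least-squares slope of signal against time within
#' the analysis window (default after the 30-min equilibration). Group
#' rates are means over wells of a type, blank-corrected by subtracting the
#' mean blank drift slope.
#'
#' @param plate data frame with columns \code{well}, \code{well_type}
#'   (\code{measurement}, \code{dg_control}, \code{blank}), \code{t_min},
#'   \code{signal} (see [simulate_ecar()]).
#' @param window numeric length-2 analysis window (min).
#' @return list: \code{well_slopes} (per well), \code{rates}
#'   (blank-corrected per type), \code{blank_slope}.
#' @export
ecar_slopes <- function(plate, window = c(30, 100)) {
  stopifnot(all(c("well", "well_type", "t_min", "signal") %in%
                  names(plate)))
  sub <- plate[plate$t_min >= window[1] & plate$t_min <= window[2], ]
  if (nrow(sub) == 0) stop("analysis window contains no readings")
  ws <- vapply(split(sub, sub$well), function(w) {
    if (nrow(w) < 2) stop("well ", w$well[1], " has fewer than 2 readings ",
                          "in the window")
    stats::coef(stats::lm(signal ~ t_min, data = w))[[2]]
  }, 0)
  type_of <- vapply(split(sub$well_type, sub$well), `[[`, "", 1L)
  by_type <- tapply(ws, type_of, mean)
  blank <- if ("blank" %in% names(by_type)) by_type[["blank"]] else {
    warning("no blank wells; skipping blank correction")
    0
  }
  rates <- by_type[setdiff(names(by_type), "blank")] - blank
  list(well_slopes = ws, rates = rates, blank_slope = blank)
}

#' Hexokinase-mediated ECAR and between-strain percent difference
#'
#' The 2-deoxy-D-glucose control wells competitively inhibit hexokinases,
#' so the hexokinase-mediated ECAR is the measurement rate minus the 2-DG
#' residual rate. The percent difference of strain A over strain B is
#' 100 (hex_A - hex_B) / hex_B.
#'
#' @param results named list of [ecar_slopes()] results, one per strain.
#' @return list: \code{hexokinase_ecar} (named per-strain vector),
#'   \code{percent_difference} (matrix, \code{[A, B]} = \% of A over B;
#'   \code{NA} when hex_B <= 0).
#' @export
hexokinase_ecar <- function(results) {
  hex <- vapply(results, function(res) {
    r <- res$rates
    if (!all(c("measurement", "dg_control") %in% names(r)))
      stop("both measurement and 2-DG control rates are required")
    r[["measurement"]] - r[["dg_control"]]
  }, 0)
  pd <- outer(hex, hex, function(a, b) ifelse(b > 0, 100 * (a - b) / b,
                                              NA_real_))
  diag(pd) <- 0
  list(hexokinase_ecar = hex, percent_difference = pd)
}

#' Percent difference of a over b
#'
#' @param a,b positive rates.
#' @return 100 (a - b) / b, \code{NA} when b <= 0.
#' @export
percent_difference <- function(a, b) ifelse(b > 0, 100 * (a - b) / b,
                                            NA_real_)
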