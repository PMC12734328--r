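#' Simulation configuration for the 18-library stress study
#'
#' Configures the negative-binomial count simulator that emulates the pooled
#' strain x stress x time RNA-seq design: per condition, three replicate
#' cultures are grown and mixed evenly into a single sequencing library.
#' Biological variability enters as a per-culture gamma factor with squared
#' coefficient of variation \code{nb_dispersion}; averaging \code{n_pool}
#' such factors and Poisson sequencing yields library counts that are
#' exactly negative binomial with dispersion \code{nb_dispersion / n_pool}.
#'
#' Planted structure, recorded in the returned ground truth:
#' \itemize{
#'   \item \emph{responsive genes}: per stress x time combination, a set of
#'     genes whose wild-type expression shifts by \code{effect} log2 units
#'     under that stress while every mutant's effect is forced to zero
#'     ("silent") -- the signal the mutant-responsiveness classifier must
#'     recover;
#'   \item \emph{co-expression blocks}: groups of genes sharing a per-sample
#'     latent factor scaled by per-gene loadings, producing the correlated
#'     blocks that module detection assumes.
#' }
#'
#' @param n_genes number of genes.
#' @param design design data frame (default [default_design()], 18 samples).
#' @param baseline_log2_mu,baseline_log2_sd log2-scale mean and sd of the
#'   baseline relative-abundance distribution.
#' @param nb_dispersion per-culture negative-binomial dispersion
#'   (var = mu + phi mu^2).
#' @param n_pool replicate cultures pooled per library (3 in the study).
#' @param planted_response data frame with columns \code{stress},
#'   \code{time_h}, \code{size}, \code{effect}; see
#'   [default_planted_response()]. \code{NULL} plants none.
#' @param planted_modules \code{NULL}, or a list with \code{n_blocks},
#'   \code{block_size} (scalar or per-block vector), \code{loading_mean},
#'   \code{loading_sd}, \code{factor_sd} describing latent-factor
#'   co-expression blocks; latent factors are orthogonalized across blocks.
#' @param length_range_bp bounds for uniform gene-length sampling.
#' @param libsize_range bounds for uniform library-size sampling.
#' @param exact_means if \code{TRUE}, counts are the rounded expected means
#'   (no sampling noise) -- the noiseless mode used for exact-recovery checks.
#' @param seed integer seed; identical configs give identical output.
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 2000,
                       design = default_design(),
                       baseline_log2_mu = 9,
                       baseline_log2_sd = 1.8,
                       nb_dispersion = 0.05,
                       n_pool = 3,
                       planted_response = default_planted_response(),
                       planted_modules = NULL,
                       length_range_bp = c(500, 4000),
                       libsize_range = c(2e6, 3e6),
                       exact_means = FALSE,
                       seed = 1) {
  stopifnot(n_genes >= 1, nb_dispersion >= 0, n_pool >= 1,
            length_range_bp[1] > 0, diff(length_range_bp) >= 0,
            libsize_range[1] > 0, diff(libsize_range) >= 0)
  if (anyDuplicated(design$sample)) stop("design sample labels must be unique")
  n_resp <- 0L
  if (!is.null(planted_response)) {
    stopifnot(all(c("stress", "time_h", "size", "effect") %in%
                    names(planted_response)),
              all(planted_response$size > 0))
    n_resp <- sum(planted_response$size)
  }
  n_mod <- 0L
  if (!is.null(planted_modules)) {
    planted_modules <- utils::modifyList(
      list(n_blocks = 3, block_size = 100, loading_mean = 1,
           loading_sd = 0.15, factor_sd = 1), planted_modules)
    planted_modules$block_size <- rep(planted_modules$block_size,
                                      length.out = planted_modules$n_blocks)
    stopifnot(planted_modules$n_blocks >= 1,
              all(planted_modules$block_size >= 2))
    n_mod <- sum(planted_modules$block_size)
  }
  if (n_resp + n_mod > n_genes)
    stop("planted sets (", n_resp + n_mod, " genes) exceed n_genes (",
         n_genes, ")")
  structure(list(n_genes = n_genes, design = design,
                 baseline_log2_mu = baseline_log2_mu,
                 baseline_log2_sd = baseline_log2_sd,
                 nb_dispersion = nb_dispersion, n_pool = n_pool,
                 planted_response = planted_response,
                 planted_modules = planted_modules,
                 length_range_bp = length_range_bp,
                 libsize_range = libsize_range,
                 exact_means = exact_means, seed = seed),
            class = "sim_config")
}

#' Default planted responsive-gene layout
#'
#' 25 genes per stress x time combination (4 stresses x 2 time points =
#' 200 genes in total), wild-type effect magnitude 3 log2 units. Within each
#' set the realized signs alternate (+effect / -effect) so that both
#' classifier directions are exercised.
#'
#' @param size genes per combination.
#' @param effect wild-type log2 effect magnitude.
#' @return data frame with columns \code{stress}, \code{time_h},
#'   \code{size}, \code{effect}.
#' @export
default_planted_response <- function(size = 25, effect = 3) {
  expand.grid(stress = setdiff(.stresses, "none"), time_h = c(0.5, 12),
              size = size, effect = effect,
              KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
}

#' Simulate the pooled-library count matrix with ground truth
#'
#' @param config a [sim_config()].
#' @return list with elements:
#'   \describe{
#'     \item{counts}{a [stress_counts()] object;}
#'     \item{design}{the design data frame;}
#'     \item{truth}{ground truth: \code{gene_truth} (per-gene planted set,
#'       signed effect, module id), \code{expected_labels} (per mutant
#'       contrast, the classifier label implied by the planted effects under
#'       the default thresholds), \code{mu} (expected count matrix),
#'       \code{module} (named gene -> block vector).}
#'   }
#' @export
simulate_counts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  design <- config$design
  n_g <- config$n_genes
  n_s <- nrow(design)
  genes <- sprintf("g%05d", seq_len(n_g))

  # allocate planted gene indices: responsive sets first, then blocks
  gene_truth <- data.frame(gene = genes, set = NA_character_, effect = 0,
                           module = NA_integer_)
  nxt <- 1L
  pr <- config$planted_response
  if (!is.null(pr)) {
    for (i in seq_len(nrow(pr))) {
      idx <- nxt:(nxt + pr$size[i] - 1L)
      nxt <- nxt + pr$size[i]
      gene_truth$set[idx] <- paste0(pr$stress[i], "_", pr$time_h[i])
      sgn <- rep(c(1, -1), length.out = pr$size[i])
      gene_truth$effect[idx] <- sgn * pr$effect[i]
    }
  }
  pm <- config$planted_modules
  if (!is.null(pm)) {
    for (b in seq_len(pm$n_blocks)) {
      idx <- nxt:(nxt + pm$block_size[b] - 1L)
      nxt <- nxt + pm$block_size[b]
      gene_truth$module[idx] <- b
    }
  }

  out <- withr::with_seed(config$seed, {
    lengths_bp <- round(stats::runif(n_g, config$length_range_bp[1],
                                     config$length_range_bp[2]))
    libsize <- stats::runif(n_s, config$libsize_range[1],
                            config$libsize_range[2])
    base <- stats::rnorm(n_g, config$baseline_log2_mu,
                         config$baseline_log2_sd)
    # planted (responsive or block) genes are drawn from the expressed part
    # of the abundance distribution (z >= -1.5): under the pseudocounted
    # fold-change formula a gene below a few FPKM can never register a
    # down-response, so censored planted truth would be unrecoverable by
    # construction, not by failure of the classifier; likewise the study's
    # co-expression analysis operates on (expressed) DEGs
    resp <- which(!is.na(gene_truth$set) | !is.na(gene_truth$module))
    if (length(resp) > 0) {
      z <- stats::qnorm(stats::runif(length(resp), stats::pnorm(-1.5), 1))
      base[resp] <- config$baseline_log2_mu + config$baseline_log2_sd * z
    }
    shift <- matrix(0, n_g, n_s, dimnames = list(genes, design$sample))
    if (!is.null(pr)) {
      planted <- !is.na(gene_truth$set)
      key <- paste0(design$stress, "_", design$time_h)
      for (j in which(design$strain == "WT" & design$stress != "none")) {
        hit <- planted & gene_truth$set == key[j]
        shift[hit, j] <- shift[hit, j] + gene_truth$effect[hit]
      }
    }
    if (!is.null(pm)) {
      # latent factors orthogonalized across blocks so that between-block
      # correlation is ~0 by construction (chance correlation of
      # independent length-18 factors is otherwise substantial)
      fmat <- matrix(stats::rnorm(n_s * pm$n_blocks), n_s, pm$n_blocks)
      if (pm$n_blocks > 1 && pm$n_blocks <= n_s) {
        fmat <- qr.Q(qr(fmat))
        fmat <- sweep(fmat, 2, sqrt(colSums(fmat^2) / n_s), "/")
      }
      fmat <- fmat * pm$factor_sd
      for (b in seq_len(pm$n_blocks)) {
        idx <- which(gene_truth$module == b)
        loading <- stats::rnorm(length(idx), pm$loading_mean, pm$loading_sd)
        shift[idx, ] <- shift[idx, ] + outer(loading, fmat[, b])
      }
    }
    # libsize-scaled baseline x 2^effects; the denominator is the baseline
    # total (not the per-column total), so a planted log2 effect e yields an
    # exact expected-count ratio of 2^e against the unstressed column
    rel <- 2^(base + shift)
    mu <- sweep(rel / sum(2^base), 2, libsize, "*")
    disp <- config$nb_dispersion / config$n_pool
    counts <- if (config$exact_means) {
      round(mu)
    } else if (disp == 0) {
      matrix(stats::rpois(length(mu), mu), n_g, n_s)
    } else {
      matrix(stats::rnbinom(length(mu), mu = mu, size = 1 / disp), n_g, n_s)
    }
    dimnames(counts) <- dimnames(mu)
    list(counts = counts, lengths_bp = lengths_bp, mu = mu)
  })

  truth <- list(gene_truth = gene_truth,
                expected_labels = expected_mutant_labels(gene_truth),
                mu = out$mu,
                module = stats::setNames(gene_truth$module, genes))
  list(counts = stress_counts(out$counts,
                              stats::setNames(out$lengths_bp, genes),
                              design),
       design = design, truth = truth)
}

#' Classifier labels implied by planted effects under default thresholds
#' @noRd
expected_mutant_labels <- function(gene_truth, th = response_thresholds()) {
  planted <- gene_truth[!is.na(gene_truth$set) & gene_truth$effect != 0, ]
  if (nrow(planted) == 0)
    return(data.frame(gene = character(), mutant = character(),
                      stress = character(), time_h = numeric(),
                      label = character()))
  parts <- strsplit(planted$set, "_(?=[0-9.]+$)", perl = TRUE)
  stress <- vapply(parts, `[[`, "", 1L)
  time_h <- as.numeric(vapply(parts, `[[`, "", 2L))
  mutant <- names(.sensitive_stress)[match(stress, .sensitive_stress)]
  keep <- !is.na(mutant)  # congo_red has no mutant contrast in the design
  lab <- ifelse(planted$effect <= -th$deg_cut, "up_in_mutant",
                ifelse(planted$effect >= th$deg_cut, "down_in_mutant",
                       "none"))
  data.frame(gene = planted$gene[keep], mutant = mutant[keep],
             stress = stress[keep], time_h = time_h[keep],
             label = lab[keep], row.names = NULL)
}

#' Precision and recall of mutant-responsiveness classification
#'
#' Compares predicted labels against the simulator's ground truth over all
#' mutant contrasts. A true positive is a gene whose predicted label equals
#' its planted label (and is not \code{"none"}).
#'
#' @param deg_sets list of per-contrast DEG tables from [mutant_deg_sets()].
#' @param truth the \code{truth} element returned by [simulate_counts()].
#' @return named numeric vector: \code{precision}, \code{recall}, \code{tp},
#'   \code{fp}, \code{fn}.
#' @export
classification_performance <- function(deg_sets, truth) {
  exp_lab <- truth$expected_labels
  tp <- fp <- fn <- 0L
  for (ds in deg_sets) {
    meta <- attributes(ds)
    el <- exp_lab[exp_lab$mutant == meta$mutant &
                    exp_lab$stress == meta$stress &
                    exp_lab$time_h == meta$time_h, ]
    want <- stats::setNames(rep("none", nrow(ds)), ds$gene)
    want[el$gene[el$gene %in% ds$gene]] <-
      el$label[el$gene %in% ds$gene]
    got <- stats::setNames(ds$label, ds$gene)
    pos_pred <- got != "none"
    pos_true <- want != "none"
    tp <- tp + sum(pos_pred & got == want)
    fp <- fp + sum(pos_pred & got != want)
    fn <- fn + sum(pos_true & got != want)
  }
  c(precision = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    recall = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    tp = tp, fp = fp, fn = fn)
}

# ---- colony growth -----------------------------------------------------

#' True colony diameters encoding the study's growth-inhibition profile
#'
#' Control diameter Dc is fixed at 50 mm and stressed diameters are
#' back-solved from per strain x medium x stress relative growth inhibition
#' values via Ds = (Dc + RGI/100 * d) / (1 + RGI/100), plug d = 5 mm.
#'
#' @param Dc control colony diameter (mm).
#' @param d inoculum plug diameter (mm).
#' @return data frame: \code{strain}, \code{medium}, \code{stress},
#'   \code{Dc}, \code{Ds}, \code{rgi_true}.
#' @export
default_growth_truth <- function(Dc = 50, d = 5) {
  rgi_vals <- rbind(
    data.frame(stress = "sorbitol",
               strain = c("WT", "dHog1", "dSlt2", "dMpk1"),
               SDA = c(58.69, 99.04, 55.45, 35.00),
               CZA = c(57.75, 98.46, 50.00, 32.26)),
    data.frame(stress = "heat",
               strain = c("WT", "dHog1", "dSlt2", "dMpk1"),
               SDA = c(68.25, 51.37, 87.00, 67.38),
               CZA = c(81.23, 62.57, 75.43, 70.00)),
    data.frame(stress = "congo_red",
               strain = c("WT", "dHog1", "dSlt2", "dMpk1"),
               SDA = c(15.00, 16.00, 22.40, 30.00),
               CZA = c(5.00, 5.50, 8.73, 9.64)),
    data.frame(stress = "menadione",
               strain = c("WT", "dHog1", "dSlt2", "dMpk1"),
               SDA = c(12.00, 13.00, 12.50, 1.95),
               CZA = c(15.00, 16.00, 15.50, 4.08)))
  long <- rbind(
    data.frame(rgi_vals[c("strain", "stress")], medium = "SDA",
               rgi_true = rgi_vals$SDA),
    data.frame(rgi_vals[c("strain", "stress")], medium = "CZA",
               rgi_true = rgi_vals$CZA))
  long$Dc <- Dc
  long$Ds <- (Dc + long$rgi_true / 100 * d) / (1 + long$rgi_true / 100)
  long[c("strain", "medium", "stress", "Dc", "Ds", "rgi_true")]
}

#' Simulate replicate colony-diameter records
#'
#' @param truth diameter truth table (see [default_growth_truth()]).
#' @param n_rep replicate colonies per condition (>= 3 in the assays).
#' @param noise_sd Gaussian measurement noise on diameters (mm).
#' @param d inoculum plug diameter (mm).
#' @param seed integer seed.
#' @return list with \code{records} (long data frame: \code{strain},
#'   \code{medium}, \code{stress}, \code{replicate}, \code{diameter_mm},
#'   \code{is_control}) and \code{truth} (input table with true RGI).
#' @export
simulate_growth <- function(truth = default_growth_truth(), n_rep = 3,
                            noise_sd = 1, d = 5, seed = 1) {
  stopifnot(n_rep >= 1, noise_sd >= 0)
  if (any(truth$Ds <= d))
    stop("configured stressed diameter Ds must exceed the plug diameter d")
  if (any(truth$Dc <= d))
    stop("configured control diameter Dc must exceed the plug diameter d")
  records <- withr::with_seed(seed, {
    n <- nrow(truth)
    do.call(rbind, lapply(seq_len(n), function(i) {
      data.frame(strain = truth$strain[i], medium = truth$medium[i],
                 stress = truth$stress[i],
                 replicate = rep(seq_len(n_rep), 2),
                 diameter_mm = c(truth$Dc[i] + stats::rnorm(n_rep, 0, noise_sd),
                                 truth$Ds[i] + stats::rnorm(n_rep, 0, noise_sd)),
                 is_control = rep(c(TRUE, FALSE), each = n_rep))
    }))
  })
  list(records = records, truth = truth)
}

# ---- glycolysis stress plate ------------------------------------------

#' Default well slopes for the glycolysis stress assay
#'
#' Raw well slopes (relative fluorescence units / min) include a common
#' blank drift of 0.2. Net rates: WT total ECAR 10, 2-DG residual 4
#' (hexokinase-mediated ECAR 6); dHog1 total ECAR 6.6 (34\% below WT) with
#' hexokinase-mediated ECAR 6/1.58 (the WT rate sits 58\% above it).
#'
#' @param strain \code{"WT"} or \code{"dHog1"}.
#' @return named vector: \code{measurement}, \code{dg_control},
#'   \code{blank}.
#' @export
default_ecar_slopes <- function(strain = c("WT", "dHog1")) {
  strain <- match.arg(strain)
  drift <- 0.2
  if (strain == "WT")
    c(measurement = 10 + drift, dg_control = 4 + drift, blank = drift)
  else {
    hex <- 6 / 1.58
    c(measurement = 6.6 + drift, dg_control = 6.6 - hex + drift,
      blank = drift)
  }
}

#' Simulate a plate-reader fluorescence time series
#'
#' Readings every \code{dt_min} minutes, \code{n_readings} per well
#' (26 readings at 4-min spacing cover 0--100 min), linear trend plus
#' Gaussian noise.
#'
#' @param slopes named vector of raw well slopes (units/min) for
#'   \code{measurement}, \code{dg_control} (2-deoxy-D-glucose control) and
#'   \code{blank} wells.
#' @param n_wells wells per type.
#' @param noise_sd Gaussian reading noise.
#' @param n_readings readings per well.
#' @param dt_min minutes between readings.
#' @param baseline signal at t = 0.
#' @param seed integer seed.
#' @return data frame: \code{well}, \code{well_type}, \code{t_min},
#'   \code{signal}.
#' @export
simulate_ecar <- function(slopes = default_ecar_slopes("WT"), n_wells = 3,
                          noise_sd = 0.5, n_readings = 26, dt_min = 4,
                          baseline = 100, seed = 1) {
  stopifnot(all(c("measurement", "dg_control", "blank") %in% names(slopes)))
  if (n_readings < 2) stop("n_readings must be at least 2")
  if (n_wells < 1) stop("n_wells must be positive")
  t_min <- seq(0, by = dt_min, length.out = n_readings)
  withr::with_seed(seed, {
    rows <- list()
    for (type in c("measurement", "dg_control", "blank")) {
      for (w in seq_len(n_wells)) {
        rows[[length(rows) + 1L]] <- data.frame(
          well = paste0(type, "_", w), well_type = type, t_min = t_min,
          signal = baseline + slopes[[type]] * t_min +
            stats::rnorm(n_readings, 0, noise_sd))
      }
    }
    do.call(rbind, rows)
  })
}
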