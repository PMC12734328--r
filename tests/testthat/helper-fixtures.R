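# Fixture builders shared across the suite. Everything is generated in code;
# seeds are fixed so expected values frozen in tests stay valid.

# small count container with hand-chosen counts
tiny_counts <- function(counts, lengths = NULL) {
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("g%02d", seq_len(nrow(counts)))
  if (is.null(lengths)) lengths <- rep(1000, nrow(counts))
  stress_counts(counts, stats::setNames(lengths, rownames(counts)))
}

# n genes x 4 WT samples with reproducible pseudo-random counts
random_counts <- function(n_genes = 50, seed = 9, mu = 200, size = 10) {
  withr::with_seed(seed, {
    m <- matrix(stats::rnbinom(n_genes * 4, mu = mu, size = size),
                n_genes, 4,
                dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                                c("WT_none_0", "WT_SOB_0.5", "WT_SOB_12",
                                  "WT_HT_0.5")))
    tiny_counts(m, lengths = round(stats::runif(n_genes, 500, 4000)))
  })
}

# a DEG table with the given numbers of up/down labels over a gene universe
made_deg_set <- function(n_up, n_down, n_none = 0, mutant = "dHog1",
                         stress = "sorbitol", time_h = 0.5,
                         genes = NULL) {
  n <- n_up + n_down + n_none
  if (is.null(genes)) genes <- sprintf("g%05d", seq_len(n))
  ds <- data.frame(gene = genes,
                   fc_wt = c(rep(3, n_up), rep(-3, n_down), rep(0, n_none)),
                   fc_mut = 0,
                   label = c(rep("up_in_mutant", n_up),
                             rep("down_in_mutant", n_down),
                             rep("none", n_none)))
  attr(ds, "mutant") <- mutant
  attr(ds, "stress") <- stress
  attr(ds, "time_h") <- time_h
  ds
}

# well-separated 3-block co-expression fixture embedded in a background
# genome; returns the simulation plus the block-gene expression submatrix
block_fixture <- function(seed = 7, loading_sd = 0.4) {
  cfg <- sim_config(n_genes = 1500, planted_response = NULL,
                    planted_modules = list(n_blocks = 3, block_size = 100,
                                           loading_sd = loading_sd),
                    seed = seed)
  sim <- simulate_counts(cfg)
  cm <- filter_zero_genes(sim$counts)
  qn <- log2_quantile(fpkm(cm))
  genes <- names(sim$truth$module)[!is.na(sim$truth$module)]
  genes <- intersect(genes, rownames(qn))
  list(sim = sim, cm = cm, expr = qn[genes, ],
       truth = sim$truth$module[genes])
}

# tiny annotation universe with planted terms
toy_annotation <- function(n_universe = 200, seed = 3) {
  universe <- sprintf("g%03d", seq_len(n_universe))
  withr::with_seed(seed, {
    sets <- lapply(stats::setNames(seq_len(20), sprintf("T%02d", 1:20)),
                   function(i) sample(universe, 15))
  })
  annotation_map(sets, universe)
}
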