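test_that("co-expression gene selection is the union of labelled genes", {
  genes <- sprintf("g%05d", 1:10)
  a <- made_deg_set(5, 0, n_none = 5, genes = genes)
  b <- made_deg_set(0, 0, n_none = 10, genes = sprintf("g%05d", 6:15))
  b$label[1:10] <- c(rep("down_in_mutant", 10))
  sel <- select_coexpression_genes(list(a, b))
  expect_equal(sel, sort(unique(c(genes[1:5], sprintf("g%05d", 6:15)))))
  expect_equal(length(sel), 15)
  empty <- made_deg_set(0, 0, n_none = 4)
  expect_warning(out <- select_coexpression_genes(list(empty)),
                 "no differentially expressed")
  expect_equal(out, character(0))
})

test_that("k-means recovers well-separated planted blocks", {
  fx <- block_fixture(seed = 7)
  lc <- logclr(fx$cm, tmm_scale = TRUE)[names(fx$truth), ]
  km <- kmeans_modules(lc, K = 3, seed = 5)
  expect_gte(mclust::adjustedRandIndex(km, fx$truth), 0.9)
  # fixed seed -> deterministic
  expect_identical(km, kmeans_modules(lc, K = 3, seed = 5))
  # two blocks, K = 2 -> perfect recovery
  cfg2 <- sim_config(n_genes = 800, planted_response = NULL,
                     planted_modules = list(n_blocks = 2, block_size = 80),
                     seed = 12)
  sim2 <- simulate_counts(cfg2)
  g2 <- names(sim2$truth$module)[!is.na(sim2$truth$module)]
  lc2 <- logclr(filter_zero_genes(sim2$counts), tmm_scale = TRUE)[g2, ]
  km2 <- kmeans_modules(lc2, K = 2, seed = 3)
  expect_equal(mclust::adjustedRandIndex(km2, sim2$truth$module[g2]), 1.0)
  # identical profiles land in the same cluster
  dup <- expression_matrix(rbind(a = lc2[1, ], b = lc2[1, ],
                                 c = lc2[150, ]), "logclr")
  kd <- kmeans_modules(dup, K = 2, seed = 1)
  expect_equal(unname(kd["a"]), unname(kd["b"]))
  # K = 1 puts everything together; K <= 0 is an error
  expect_equal(unname(unique(kmeans_modules(lc2, K = 1))), 1L)
  expect_error(kmeans_modules(lc2, K = 0), "positive")
})

test_that("soft-threshold selection tracks scale-free fit", {
  cfg <- sim_config(n_genes = 1200, planted_response = NULL,
                    planted_modules = list(n_blocks = 5,
                                           block_size = c(200, 100, 50, 25, 12),
                                           loading_sd = 0.5), seed = 11)
  sim <- simulate_counts(cfg)
  qn <- log2_quantile(fpkm(filter_zero_genes(sim$counts)))
  ps <- pick_soft_threshold(qn)
  expect_gte(ps$fit$sf_r2[ps$fit$power == ps$power], 0.8)
  # mean connectivity strictly decreases with increasing power
  expect_true(all(diff(ps$fit$mean_k) < 0))
  # grid of one power returns that power
  one <- pick_soft_threshold(qn, network_params(powers = 6,
                                                rsq_target = 0))
  expect_equal(one$power, 6)
  # degenerate input refused
  flat <- expression_matrix(matrix(1, 4, 5), "logclr")
  expect_error(pick_soft_threshold(flat), "zero-variance")
})

test_that("TOM equals a triple-loop evaluation of its formula", {
  withr::with_seed(15, {
    m <- matrix(rnorm(8 * 12), 8, 12,
                dimnames = list(paste0("g", 1:8), paste0("s", 1:12)))
  })
  for (mode in c("unsigned", "signed")) {
    beta <- if (mode == "unsigned") 6 else 12
    tom <- adjacency_and_tom(expression_matrix(m, "logclr"), beta, mode)
    r <- cor(t(m))
    a <- if (mode == "unsigned") abs(r)^beta else ((1 + r) / 2)^beta
    diag(a) <- 0
    oracle <- diag(8)
    for (i in 1:8) for (j in 1:8) {
      if (i == j) next
      l <- sum(sapply(seq_len(8)[-c(i, j)], function(u) a[i, u] * a[u, j]))
      ki <- sum(a[i, -i]); kj <- sum(a[j, -j])
      oracle[i, j] <- (l + a[i, j]) / (min(ki, kj) + 1 - a[i, j])
    }
    expect_equal(unname(unclass(tom)), oracle, tolerance = 1e-10,
                 ignore_attr = TRUE)
    expect_true(isSymmetric(unclass(tom)))
    expect_true(all(tom >= 0 & tom <= 1))
  }
  # perfectly correlated genes with identical (perfect) neighborhoods -> TOM 1
  base <- m[1, ]
  dup <- rbind(a = base, b = 2 * base + 1, c = 3 * base - 2, d = -base)
  tom2 <- adjacency_and_tom(expression_matrix(dup, "logclr"), 6)
  expect_equal(unname(tom2["a", "b"]), 1, tolerance = 1e-12)
  # independent noise genes: off-diagonal TOM collapses toward 0
  withr::with_seed(16, {
    noise <- matrix(rnorm(40 * 200), 40, 200)
  })
  tom3 <- adjacency_and_tom(expression_matrix(noise, "logclr"), 8)
  expect_lt(max(tom3[upper.tri(tom3)]), 0.05)
  # zero-variance gene is named in the error
  bad <- rbind(m, gflat = rep(2, 12))
  expect_error(adjacency_and_tom(expression_matrix(bad, "logclr"), 6),
               "gflat")
})

test_that("static tree cut recovers planted modules and applies size rules", {
  fx <- block_fixture(seed = 7)
  tom <- adjacency_and_tom(fx$expr, beta = 6)
  mods <- detect_modules(tom, network_params(), expr = fx$expr)
  expect_gte(mclust::adjustedRandIndex(mods, fx$truth), 0.9)
  expect_equal(length(attr(mods, "sizes")), 3)
  # labels are colors ordered by decreasing module size
  sz <- attr(mods, "sizes")
  expect_true(all(diff(as.numeric(sz)) <= 0))
  # one coherent block -> a single module
  one_genes <- names(fx$truth)[fx$truth == 1]
  tom1 <- adjacency_and_tom(fx$expr[one_genes, ], beta = 6)
  mods1 <- detect_modules(tom1, network_params(), expr = fx$expr[one_genes, ])
  expect_equal(unname(unique(mods1)), "turquoise")
  # blocks smaller than min_module_size all fall into grey
  mods_small <- detect_modules(tom, network_params(min_module_size = 150))
  expect_true(all(mods_small == "grey"))
})

test_that("module eigengenes are unit-norm oriented first PCs", {
  fx <- block_fixture(seed = 7)
  expr <- fx$expr
  assign3 <- fx$truth
  eig <- module_eigengenes(expr, assign3)
  expect_equal(unname(sqrt(rowSums(eig^2))), rep(1, 3), tolerance = 1e-9)
  # gene order within a module is irrelevant
  perm <- sample(names(assign3))
  eig2 <- module_eigengenes(expr[perm, ], assign3[perm])
  expect_equal(eig, eig2, tolerance = 1e-9)
  # sign flip of all module genes leaves the eigengene unchanged
  flip <- expression_matrix(-unclass(expr), "log2_quantile")
  eig3 <- module_eigengenes(flip, assign3)
  expect_equal(abs(eig3), abs(eig), tolerance = 1e-9)
  # identical profiles: eigengene is the standardized common profile
  prof <- expr[1, ]
  same <- expression_matrix(rbind(a = prof, b = prof), "log2_quantile")
  eigs <- module_eigengenes(same, c(a = 1, b = 1))
  z <- (prof - mean(prof)) / sd(prof)
  expect_equal(unname(eigs[1, ]), unname(z / sqrt(sum(z^2))),
               tolerance = 1e-9)
  expect_equal(unname(attr(eigs, "var_explained")), 1, tolerance = 1e-12)
  # two-gene module matches the closed-form 2x2 PCA
  g2 <- expression_matrix(unclass(expr)[3:4, ], "log2_quantile")
  eig4 <- module_eigengenes(g2, setNames(c(1, 1), rownames(g2)))
  z1 <- (g2[1, ] - mean(g2[1, ])) / sd(g2[1, ])
  z2 <- (g2[2, ] - mean(g2[2, ])) / sd(g2[2, ])
  r12 <- cor(g2[1, ], g2[2, ])
  # leading eigenvector of the 2x2 correlation matrix is (1, 1)/sqrt(2)
  # (or (1,-1) for negative correlation), so the PC is z1 +/- z2 normalized
  pc <- if (r12 >= 0) z1 + z2 else z1 - z2
  pc <- pc / sqrt(sum(pc^2))
  if (cor(pc, (z1 + z2) / 2) < 0) pc <- -pc
  expect_equal(unname(eig4[1, ]), unname(pc), tolerance = 1e-9)
  # variance explained equals (1 + |r|) / 2 for two standardized genes
  expect_equal(unname(attr(eig4, "var_explained")), (1 + abs(r12)) / 2,
               tolerance = 1e-6)
  # degenerate module is refused
  const <- expression_matrix(rbind(a = rep(1, 10), b = rnorm(10)), "logclr")
  expect_error(module_eigengenes(const, c(a = 1, b = 1)), "constant")
})

test_that("module-trait correlation p-values match an independent F oracle", {
  fx <- block_fixture(seed = 7)
  eig <- module_eigengenes(fx$expr, fx$truth)
  traits <- trait_design(fx$sim$design)
  mt <- module_trait(eig, traits)
  n <- ncol(eig)
  keep <- !is.na(mt$r)
  expect_true(all(mt$r[keep] >= -1 & mt$r[keep] <= 1))
  # independent route: t^2 ~ F(1, n - 2)
  p_oracle <- pf(mt$r^2 * (n - 2) / (1 - mt$r^2), 1, n - 2,
                 lower.tail = FALSE)
  expect_equal(mt$p[keep], p_oracle[keep], tolerance = 1e-9)
  # r = 0 -> p = 1; proportional trait -> p underflows to 0
  e <- rbind(m1 = c(1, -1, 1, -1, 1, -1, 1, -1) / sqrt(8))
  tr <- cbind(t_orth = rep(c(1, 1, 0, 0), 2),
              t_prop = as.numeric(e[1, ] > 0),
              t_const = rep(1, 8))
  mt2 <- module_trait(e, tr)
  expect_equal(unname(mt2$p[1, "t_orth"]), 1)
  expect_equal(unname(mt2$r[1, "t_prop"]), 1)
  expect_equal(unname(mt2$p[1, "t_prop"]), 0)
  expect_true(is.na(mt2$r[1, "t_const"]))
  # worked value: n = 18, r = 0.5 -> t = 2.3094, p ~ 0.0344
  t <- 0.5 * sqrt(16) / sqrt(1 - 0.25)
  expect_equal(t, 2.3094, tolerance = 1e-4)
  expect_equal(2 * pt(-t, 16), 0.0346, tolerance = 1e-3)
})

test_that("network export filters edges at the weight threshold", {
  tom <- matrix(c(1, .9, .2, .9, 1, .05, .2, .05, 1), 3, 3,
                dimnames = list(paste0("g", 1:3), paste0("g", 1:3)))
  assign3 <- setNames(c("blue", "blue", "grey"), paste0("g", 1:3))
  net <- export_network(tom, assign3, threshold = 0.2)
  expect_equal(nrow(net$edges), 2)  # the 0.9 and the 0.2 edge (inclusive)
  expect_equal(sort(net$edges$weight), c(0.2, 0.9))
  expect_equal(net$nodes$module, c("blue", "blue", "grey"))
  # threshold 1 with no off-diagonal ones -> empty
  expect_equal(nrow(export_network(tom, assign3, 1)$edges), 0)
  # threshold 0 -> complete graph
  expect_equal(nrow(export_network(tom, assign3, 0)$edges), 3)
})
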