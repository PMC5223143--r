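# Differential acetylation, proximity enrichment, persistence classes.

test_that("identical replicate columns across groups yield no signal", {
  base <- matrix(rep(c(30L, 300L, 60L, 900L, 120L), 3), ncol = 3)
  k <- cbind(base, base)  # HFD columns literally repeat Chow columns
  x <- count_matrix(k, rep(c("Chow", "HFD"), each = 3))
  res <- differential_acetylation(x, contrast("Chow", "HFD"))
  expect_true(all(res$p > 0.5))
  expect_equal(res$log2fc, rep(0, 5))
})

test_that("differential acetylation recovers planted 2-fold gains", {
  set.seed(141)
  # region-level acetylation counts: moderately deep, low-dispersion
  n <- 5000
  mu <- rlnorm(n, log(150), 0.7)
  planted <- sample(n, 100)
  fold <- rep(1, n); fold[planted] <- 2
  x <- nb_matrix(n, mu, 0.02, fold = fold)
  res <- differential_acetylation(x, contrast("Chow", "HFD"))
  hit <- !is.na(res$fdr) & res$fdr < 0.1 & res$log2fc > 0
  expect_gte(mean(hit[planted]), 0.6)
  false_frac <- sum(hit[-planted]) / max(1, sum(hit))
  expect_lte(false_frac, 0.15)
})

test_that("proximity enrichment is seed-reproducible and order-invariant", {
  b <- simulate_study(sim_config(seed = 5, n_genes = 300, n_regions = 400,
                                 genome_bp = 2e7))
  tr <- b$truth_regions
  ids <- tr$feature_id[tr$class == "induced"]
  sub <- b$regions[b$regions$id %in% ids, ]
  class(sub) <- class(b$regions)
  up <- b$truth_genes$feature_id[b$truth_genes$true_log2fc_dio > 0]
  e1 <- proximity_enrichment(sub, b$genes, up, seed = 42)
  e2 <- proximity_enrichment(sub, b$genes, up, seed = 42)
  expect_identical(e1, e2)
  shuf <- sub[rev(seq_len(nrow(sub))), ]
  class(shuf) <- class(sub)
  e3 <- proximity_enrichment(shuf, b$genes, up, seed = 42)
  expect_equal(e3$observed, e1$observed)
  expect_equal(e3$null_values, e1$null_values)
  # empty region set -> missing ratio and p
  none <- region_set(character(), integer(), integer())
  e0 <- proximity_enrichment(none, b$genes, up, seed = 1)
  expect_equal(e0$observed, 0)
  expect_true(all(e0$null_values == 0))
  expect_true(is.na(e0$ratio) && is.na(e0$p))
  expect_error(proximity_enrichment(sub, b$genes, up, n_random = 1e5,
                                    seed = 1), "background")
  expect_error(proximity_enrichment(sub, b$genes, c(up, "nope")), "unknown")
})

test_that("planted enhancer-gene coupling produces strong enrichment", {
  b <- simulate_study(sim_config(seed = 9))
  tr <- b$truth_regions
  ind <- b$regions[b$regions$id %in%
                     tr$feature_id[tr$class == "induced"], ]
  class(ind) <- class(b$regions)
  up <- b$truth_genes$feature_id[b$truth_genes$true_log2fc_dio > 0]
  e <- proximity_enrichment(ind, b$genes, up, seed = 17)
  expect_gt(e$ratio, 2)
  expect_lt(e$p, 0.05)
  expect_gt(e$frac_genes_with_hit, 0.5)
  # a size-matched random gene set shows no such enrichment
  rnd <- local({set.seed(18); sample(setdiff(b$genes$gene_id, up), length(up))})
  er <- proximity_enrichment(ind, b$genes, rnd, seed = 19)
  expect_lt(er$ratio, 2)
  expect_gt(er$ratio, 0.5)
})

test_that("persistence partition is exhaustive and mutually exclusive", {
  mk <- function(lfc, p) {
    data.frame(feature_id = sprintf("r%d", seq_along(lfc)), base_mean = 50,
               log2fc = lfc, se = 0.2, stat = lfc / 0.2, p = p,
               fdr = bh_fdr(p))
  }
  dio <- mk(c(2, 2, -2, 0.1, 0), c(1e-4, 1e-3, 1e-3, 0.5, 0.9))
  rev <- mk(c(2, -1, 0.1, 2, 0), c(1e-3, 1e-3, 0.6, 1e-4, 0.8))
  pc <- classify_persistence(dio, rev)
  expect_equal(pc$calls$class,
               c("putative_persistent",  # both significant, concordant
                 "reversible",           # rev significant but discordant
                 "reversible",           # dio only
                 "weightloss_specific",  # rev only
                 "unregulated"))
  expect_equal(sum(table(pc$calls$class)), 5)
  expect_equal(unname(pc$venn_p), c(1, 1, 2))
  # no reversal signal at all -> zero putative persistent
  rev0 <- mk(rep(0.01, 5), rep(0.9, 5))
  pc0 <- classify_persistence(dio, rev0)
  expect_equal(sum(pc0$calls$class == "putative_persistent"), 0)
  expect_error(classify_persistence(dio, rev[1:3, ]), "universe")
})

test_that("planted persistent regions are recovered with strong reversal evidence", {
  cfg <- sim_config(seed = 23,
                    region_props = c(induced = 0.05, reduced = 0.03,
                                     persistent = 50 / 8000,
                                     weightloss_only = 0))
  b <- simulate_study(cfg)
  dio <- differential_acetylation(b$counts_k27ac, contrast("Chow", "HFD"))
  rev <- differential_acetylation(b$counts_k27ac,
                                  contrast("ChowChow", "HFDChow"))
  pc <- classify_persistence(dio, rev)
  truth <- b$truth_regions
  pids <- truth$feature_id[truth$class == "persistent"]
  got <- pc$calls$class[match(pids, pc$calls$region_id)]
  expect_gte(mean(got == "putative_persistent"), 0.7)
  diag <- persistence_diagnostics(pc, b$counts_k27ac)
  # planted persistents carry strong reversal-contrast evidence
  fdr_rev_planted <- pc$calls$fdr_rev[match(pids, pc$calls$region_id)]
  expect_lt(median(fdr_rev_planted), 0.1)
  expect_true("putative_persistent" %in% names(diag))
  expect_equal(diag$putative_persistent$n,
               sum(pc$calls$class == "putative_persistent"))
})

test_that("diagnostics expose weak reversal evidence for false persistents", {
  # fully reversible study: any putative persistent is a false positive
  b <- simulate_study(sim_config(seed = 29))
  dio <- differential_acetylation(b$counts_k27ac, contrast("Chow", "HFD"))
  rev <- differential_acetylation(b$counts_k27ac,
                                  contrast("ChowChow", "HFDChow"))
  pc <- classify_persistence(dio, rev)
  pp <- pc$calls[pc$calls$class == "putative_persistent", ]
  dio_reg <- pc$calls[pc$calls$class %in% c("putative_persistent",
                                            "reversible"), ]
  if (nrow(pp) > 0) {
    expect_gt(median(pp$fdr_rev), median(dio_reg$fdr_dio))
  }
  # single-region class summaries are that region's values
  one <- classify_persistence(dio[1:1, ], rev[1:1, ])
  d1 <- persistence_diagnostics(one, b$counts_k27ac)
  expect_equal(d1[[one$calls$class]]$n, 1)
})
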