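# Synthetic-study generator: determinism, planted structure, moments,
# bundle round-trip.

test_that("the same seed yields a bit-identical bundle", {
  cfg <- sim_config(seed = 202, n_genes = 150, n_regions = 200,
                    genome_bp = 1e7)
  b1 <- simulate_study(cfg)
  b2 <- simulate_study(cfg)
  expect_identical(b1, b2)
  b3 <- simulate_study(sim_config(seed = 203, n_genes = 150,
                                  n_regions = 200, genome_bp = 1e7))
  expect_false(identical(b1$counts_exon$counts, b3$counts_exon$counts))
})

test_that("zero class proportions give a null study", {
  cfg <- sim_config(seed = 7, n_genes = 200, n_regions = 150,
                    genome_bp = 1e7,
                    gene_props = c(up_transcriptional = 0),
                    region_props = c(induced = 0))
  b <- simulate_study(cfg)
  expect_true(all(b$truth_genes$class == "null"))
  expect_true(all(b$truth_regions$class == "null"))
  expect_true(all(b$truth_genes$true_log2fc_dio == 0))
  expect_false(any(b$truth_regions$motif_planted))
})

test_that("null-feature means track depth * abundance within 5%", {
  b <- simulate_study(sim_config(seed = 31))
  k <- b$counts_exon$counts
  sf <- b$samples$size_factor[match(colnames(k), b$samples$sample_id)]
  y <- sweep(k, 2, sf, "/")
  nul <- b$truth_genes$class == "null"
  obs <- rowMeans(y[nul, ])
  expected <- b$config$rna_depth * b$truth_genes$abundance[nul]
  expect_lt(abs(sum(obs) / sum(expected) - 1), 0.05)
  expect_gt(cor(obs, expected), 0.99)
})

test_that("simulated count variance follows mu + alpha mu^2", {
  set.seed(191)
  cfg <- sim_config(seed = 1)
  n <- 5000
  mu <- 150
  draws <- rnbinom(n, mu = mu, size = 1 / cfg$dispersion)
  v <- var(draws)
  expect_lt(abs(v - (mu + cfg$dispersion * mu^2)) /
              (mu + cfg$dispersion * mu^2), 0.15)
  # and the generator's own matrices show overdispersion beyond Poisson
  b <- simulate_study(sim_config(seed = 37, n_genes = 400, n_regions = 100,
                                 genome_bp = 1e7))
  k <- b$counts_exon$counts
  sf <- b$samples$size_factor[match(colnames(k), b$samples$sample_id)]
  y <- sweep(k, 2, sf, "/")
  grp <- b$counts_exon$meta$group
  vg <- apply(y[, grp == "Chow"], 1, var)
  mg <- rowMeans(y[, grp == "Chow"])
  hi <- mg > 100
  alpha_hat <- median((vg[hi] - mg[hi]) / mg[hi]^2)
  expect_gt(alpha_hat, 0.005)
  expect_lt(alpha_hat, 0.2)
})

test_that("every coupled region lies within the window of its linked gene", {
  b <- simulate_study(sim_config(seed = 43))
  tr <- b$truth_regions
  coupled <- which(!is.na(tr$linked_gene))
  expect_gt(length(coupled), 0)
  for (i in coupled) {
    g <- b$genes[b$genes$gene_id == tr$linked_gene[i], ]
    r <- b$regions[b$regions$id == tr$feature_id[i], ]
    expect_true(r$start <= g$tss + 1e5 && r$end > g$tss - 1e5)
    # direction of the linked gene matches the region class
    expect_equal(sign(tr$true_log2fc_dio[i]),
                 sign(b$truth_genes$true_log2fc_dio[
                   b$truth_genes$feature_id == tr$linked_gene[i]]))
  }
  # roughly the configured coupling fraction is linked
  frac <- length(coupled) / sum(tr$class %in% c("induced", "reduced"))
  expect_gt(frac, 0.7)
  expect_lt(frac, 0.9)
})

test_that("planted persistent effects appear in both contrasts", {
  cfg <- sim_config(seed = 47, n_genes = 300, n_regions = 300,
                    genome_bp = 1e7,
                    gene_props = c(up_transcriptional = 0.05,
                                   persistent_up = 0.05),
                    region_props = c(induced = 0.1, persistent = 0.1))
  b <- simulate_study(cfg)
  tg <- b$truth_genes
  expect_true(all(tg$true_log2fc_rev[tg$class == "persistent_up"] ==
                    tg$true_log2fc_dio[tg$class == "persistent_up"]))
  expect_true(all(tg$true_log2fc_rev[tg$class == "up_transcriptional"] == 0))
  tr <- b$truth_regions
  expect_true(all(tr$true_log2fc_rev[tr$class == "persistent"] ==
                    tr$true_log2fc_dio[tr$class == "persistent"]))
})

test_that("bundle write/read round-trip is semantically identical", {
  b <- simulate_study(sim_config(seed = 53, n_genes = 60, n_regions = 50,
                                 genome_bp = 5e6))
  d <- withr::local_tempdir()
  write_bundle(b, d)
  expect_true(all(file.exists(file.path(d, c(
    "genes.tsv", "regions.bed", "counts_exon.tsv", "counts_intron.tsv",
    "counts_k27ac.tsv", "counts_dnase.tsv", "regions.fa", "truth.tsv",
    "samples.tsv", "config.yaml")))))
  back <- read_bundle(d)
  expect_equal(as.data.frame(back$genes), as.data.frame(b$genes))
  expect_equal(back$regions$start, b$regions$start)
  expect_equal(back$regions$id, b$regions$id)
  expect_equal(back$counts_exon$counts, b$counts_exon$counts)
  expect_equal(back$counts_dnase$meta, b$counts_dnase$meta)
  expect_equal(back$sequences, b$sequences)
  expect_equal(back$truth_regions$class, b$truth_regions$class)
  expect_equal(back$config$n_genes, b$config$n_genes)
  expect_equal(back$config$gene_props, b$config$gene_props)
})

test_that("tag-cluster simulation is seeded and validates inputs", {
  region <- region_set("chr1", 1000, 1200)
  t1 <- simulate_tag_cluster(region, 50, 1e-5, genome_bp = 1e6, seed = 9)
  t2 <- simulate_tag_cluster(region, 50, 1e-5, genome_bp = 1e6, seed = 9)
  expect_identical(t1, t2)
  expect_gte(t1$total, 50)
  in_region <- sum(t1$pos >= 1000 & t1$pos < 1200)
  expect_gte(in_region, 50)
  t0 <- simulate_tag_cluster(region, 0, 0, seed = 1)
  expect_equal(t0$total, 0)
  expect_error(simulate_tag_cluster(region, -1, 0), "n_tags")
  expect_error(simulate_tag_cluster(region, 1, -2), "rate")
})
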