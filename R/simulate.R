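# Seed-reproducible generator of a complete four-group dietary-intervention
# study with known ground truth: gene models and accessible regions on one
# synthetic chromosome, NB exon/intron/acetylation/accessibility counts with
# library-size factors and planted effect classes, enhancer-gene coupling
# within 100 kb of TSSs, and motif-planted region sequences.

SIM_GROUPS <- c("Chow", "HFD", "ChowChow", "HFDChow")
GENE_CLASSES <- c("null", "up_transcriptional", "down_transcriptional",
                  "up_turnover", "down_turnover", "persistent_up")
REGION_CLASSES <- c("null", "induced", "reduced", "persistent",
                    "weightloss_only")

#' Configuration of a synthetic study
#'
#' Defaults emulate the statistical structure of a four-group (Chow, HFD,
#' Chow-chow, HFD-chow) liver study: three RNA/ChIP replicates and two
#' accessibility replicates per group, NB counts with dispersion 0.05 and
#' log-uniform library-size factors, a fully reversible effect structure
#' (no persistent class planted), 80% of induced/reduced regions coupled
#' to within 100 kb of a same-direction regulated gene's TSS, and a motif
#' planted in 70% of induced-region sequences.
#'
#' @param seed integer seed; the whole bundle is a pure function of it.
#' @param n_genes,n_regions numbers of genes and accessible regions.
#' @param reps_rna,reps_chip,reps_dnase replicates per group per assay.
#' @param rna_depth,chip_depth,dnase_depth expected total tags per sample.
#' @param dispersion NB dispersion alpha (`var = mu + alpha mu^2`).
#' @param gene_props named proportions for gene classes
#'   (`up_transcriptional`, `down_transcriptional`, `up_turnover`,
#'   `down_turnover`, `persistent_up`); the remainder is null.
#' @param region_props named proportions for region classes (`induced`,
#'   `reduced`, `persistent`, `weightloss_only`); remainder null.
#' @param effect_log2fc planted |log2 fold change| (default 1.5).
#' @param coupling fraction of induced/reduced regions placed within
#'   `coupling_window_bp` of a same-direction regulated gene's TSS.
#' @param coupling_window_bp coupling window half-width (default 100 kb).
#' @param motif_prob probability that an induced region's sequence carries
#'   the planted motif.
#' @param genome_bp length of the single synthetic chromosome.
#' @param region_width_bp accessible-region width (and sequence length).
#' @param intron_factor intronic abundance relative to exonic.
#' @param dnase_effects when `TRUE`, region classes also shift
#'   accessibility counts; default `FALSE` (accessibility invariant).
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1, n_genes = 3000, n_regions = 8000,
                       reps_rna = 3, reps_chip = 3, reps_dnase = 2,
                       rna_depth = 5e5, chip_depth = 5e5,
                       dnase_depth = 3e5, dispersion = 0.05,
                       gene_props = c(up_transcriptional = 0.03,
                                      down_transcriptional = 0.03,
                                      up_turnover = 0.02,
                                      down_turnover = 0.02,
                                      persistent_up = 0),
                       region_props = c(induced = 0.05, reduced = 0.03,
                                        persistent = 0,
                                        weightloss_only = 0),
                       effect_log2fc = 1.5, coupling = 0.8,
                       coupling_window_bp = 1e5, motif_prob = 0.7,
                       genome_bp = 5e7, region_width_bp = 500,
                       intron_factor = 0.5, dnase_effects = FALSE) {
  gp <- c(up_transcriptional = 0, down_transcriptional = 0,
          up_turnover = 0, down_turnover = 0, persistent_up = 0)
  gp[names(gene_props)] <- gene_props
  rp <- c(induced = 0, reduced = 0, persistent = 0, weightloss_only = 0)
  rp[names(region_props)] <- region_props
  if (any(gp < 0) || sum(gp) > 1) stop("gene_props must be >= 0, sum <= 1")
  if (any(rp < 0) || sum(rp) > 1) stop("region_props must be >= 0, sum <= 1")
  stopifnot(n_genes > 0, n_regions > 0, reps_rna >= 1, reps_chip >= 1,
            reps_dnase >= 1, rna_depth > 0, chip_depth > 0,
            dnase_depth > 0, dispersion >= 0, effect_log2fc >= 0,
            coupling >= 0, coupling <= 1, motif_prob >= 0, motif_prob <= 1,
            genome_bp > 0, region_width_bp > 0, intron_factor > 0)
  structure(list(seed = seed, n_genes = n_genes, n_regions = n_regions,
                 reps_rna = reps_rna, reps_chip = reps_chip,
                 reps_dnase = reps_dnase, rna_depth = rna_depth,
                 chip_depth = chip_depth, dnase_depth = dnase_depth,
                 dispersion = dispersion, gene_props = gp,
                 region_props = rp, effect_log2fc = effect_log2fc,
                 coupling = coupling, coupling_window_bp = coupling_window_bp,
                 motif_prob = motif_prob, genome_bp = genome_bp,
                 region_width_bp = region_width_bp,
                 intron_factor = intron_factor,
                 dnase_effects = dnase_effects),
            class = "sim_config")
}

#' The built-in direct-repeat motif used for planting
#'
#' A 13-column DR1-style nuclear-receptor half-site repeat
#' (consensus AGGTCAAAGGTCA) with 0.97 probability on the consensus base
#' at every column; uniform background.
#'
#' @return A [pwm()].
#' @export
default_pwm <- function() {
  cons <- strsplit("AGGTCAAAGGTCA", "")[[1]]
  m <- matrix(0.01, 4, length(cons), dimnames = list(BASES, NULL))
  m[cbind(match(cons, BASES), seq_along(cons))] <- 0.97
  pwm(m, motif_id = "DR1_synthetic")
}

# positions on a jittered regular grid: guaranteed spacing >= pitch/2
grid_positions <- function(n, genome_bp) {
  pitch <- genome_bp / (n + 1)
  pitch * seq_len(n) + stats::runif(n, -pitch / 4, pitch / 4)
}

# draw classes by rounded proportions, shuffled assignment
assign_classes <- function(n, props) {
  counts <- round(props * n)
  cls <- rep("null", n)
  idx <- sample.int(n)
  at <- 1
  for (nm in names(props)) {
    if (counts[nm] > 0) {
      cls[idx[at:(at + counts[nm] - 1)]] <- nm
      at <- at + counts[nm]
    }
  }
  cls
}

nb_draw <- function(mu, alpha) {
  k <- if (alpha <= 0) stats::rpois(length(mu), mu)
  else stats::rnbinom(length(mu), mu = mu, size = 1 / alpha)
  matrix(k, nrow = nrow(mu))
}

#' Simulate a complete four-group study with ground truth
#'
#' Counts are NB with mean `depth * s_j * q_i * 2^effect` where `q_i` are
#' log-normal relative abundances normalized to sum to 1, `s_j` are
#' log-uniform library-size factors on `[0.7, 1.4]`, and the effect is the
#' planted class effect of the sample's group.  Turnover-class genes shift
#' exon means only; transcriptional-class genes shift exon and intron
#' means.  Persistent classes apply the effect in the HFD and HFD-chow
#' groups; reversible classes in HFD only; weight-loss-only regions in
#' HFD-chow only.  Accessibility counts carry no class effect by default.
#' The same seed yields a bit-identical bundle.
#'
#' @param config a [sim_config()].
#' @return A `sim_study` list: `genes` ([gene_models()]), `regions`
#'   ([region_set()]), `counts_exon`, `counts_intron`, `counts_k27ac`,
#'   `counts_dnase` ([count_matrix()] objects), `sequences` (named by
#'   region id), `truth_genes`, `truth_regions`, `samples`, `pwm`,
#'   `config`.
#' @export
simulate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  local_seed(config$seed, simulate_study_impl(config))
}

simulate_study_impl <- function(config) {
  ng <- config$n_genes
  nr <- config$n_regions
  eff <- config$effect_log2fc

  ## gene models on a jittered grid
  anchor <- grid_positions(ng, config$genome_bp)
  strand <- sample(c("+", "-"), ng, replace = TRUE)
  exon_starts <- vector("list", ng)
  exon_ends <- vector("list", ng)
  for (i in seq_len(ng)) {
    ne <- sample(2:4, 1)
    el <- round(stats::runif(ne, 150, 500))
    il <- round(stats::runif(ne - 1, 400, 2000))
    off_s <- cumsum(c(0, el[-ne] + il))
    off_e <- off_s + el
    tot <- off_e[ne]
    if (strand[i] == "+") {
      s <- anchor[i] + off_s
    } else {
      s <- anchor[i] - tot + off_s
    }
    if (s[1] < 0) s <- s - s[1]
    exon_starts[[i]] <- s
    exon_ends[[i]] <- s + el
  }
  gid <- sprintf("G%04d", seq_len(ng))
  genes <- gene_models(gid, rep("chrS", ng), strand, exon_starts, exon_ends)

  ## gene classes and true effects
  gcls <- assign_classes(ng, config$gene_props)
  gsign <- ifelse(grepl("^up|persistent", gcls), 1,
                  ifelse(grepl("^down", gcls), -1, 0))
  g_dio <- gsign * eff
  g_rev <- ifelse(gcls == "persistent_up", eff, 0)
  transcriptional <- gcls %in% c("up_transcriptional",
                                 "down_transcriptional", "persistent_up")

  ## region placement, classes, coupling
  rstart <- round(grid_positions(nr, config$genome_bp))
  rstart <- pmin(rstart, config$genome_bp - config$region_width_bp)
  rcls <- assign_classes(nr, config$region_props)
  rsign <- ifelse(rcls %in% c("induced", "persistent", "weightloss_only"),
                  1, ifelse(rcls == "reduced", -1, 0))
  r_dio <- ifelse(rcls %in% c("induced", "reduced", "persistent"),
                  rsign * eff, 0)
  r_rev <- ifelse(rcls %in% c("persistent", "weightloss_only"),
                  rsign * eff, 0)
  linked <- rep(NA_character_, nr)
  up_genes <- gid[g_dio > 0]
  down_genes <- gid[g_dio < 0]
  w <- config$coupling_window_bp
  for (i in which(rcls %in% c("induced", "reduced"))) {
    if (stats::runif(1) > config$coupling) next
    pool <- if (rcls[i] == "induced") up_genes else down_genes
    if (!length(pool))
      stop("infeasible coupling: no regulated genes of matching direction")
    gsel <- sample(pool, 1)
    tss <- genes$tss[match(gsel, genes$gene_id)]
    lo <- max(0, tss - w)
    hi <- min(config$genome_bp, tss + w) - config$region_width_bp
    rstart[i] <- round(stats::runif(1, lo, hi))
    linked[i] <- gsel
  }
  rid <- sprintf("R%05d", seq_len(nr))
  regions <- region_set(rep("chrS", nr), rstart,
                        rstart + config$region_width_bp, id = rid,
                        name = "accessible_regions")

  ## sample sheets and size factors
  mk_samples <- function(assay, reps) {
    data.frame(sample_id = sprintf("%s_%s_%d", assay,
                                   rep(SIM_GROUPS, each = reps),
                                   rep(seq_len(reps), length(SIM_GROUPS))),
               assay = assay, group = rep(SIM_GROUPS, each = reps),
               replicate = rep(seq_len(reps), length(SIM_GROUPS)),
               stringsAsFactors = FALSE)
  }
  samples <- rbind(mk_samples("rna", config$reps_rna),
                   mk_samples("k27ac", config$reps_chip),
                   mk_samples("dnase", config$reps_dnase))
  samples$size_factor <- exp(stats::runif(nrow(samples),
                                          log(0.7), log(1.4)))

  ## count matrices
  group_fold <- function(l2_dio, l2_rev, groups) {
    f <- matrix(1, length(l2_dio), length(groups))
    f[, groups == "HFD"] <- 2^l2_dio
    f[, groups == "HFDChow"] <- 2^l2_rev
    f
  }
  draw_counts <- function(base, l2_dio, l2_rev, meta, depth) {
    q <- base / sum(base)
    fold <- group_fold(l2_dio, l2_rev, meta$group)
    mu <- (depth * q) * fold              # features x samples
    mu <- sweep(mu, 2, meta$size_factor, "*")
    k <- nb_draw(mu, config$dispersion)
    dimnames(k) <- list(names(base), meta$sample_id)
    k
  }
  abund_g <- stats::setNames(stats::rlnorm(ng, 0, 1), gid)
  abund_r <- stats::setNames(stats::rlnorm(nr, 0, 1), rid)
  srna <- samples[samples$assay == "rna", ]
  schip <- samples[samples$assay == "k27ac", ]
  sdnase <- samples[samples$assay == "dnase", ]

  exon_k <- draw_counts(abund_g, g_dio, g_rev, srna, config$rna_depth)
  intr_dio <- ifelse(transcriptional, g_dio, 0)
  intr_rev <- ifelse(transcriptional, g_rev, 0)
  intron_k <- draw_counts(abund_g * config$intron_factor, intr_dio,
                          intr_rev, srna, config$rna_depth)
  chip_k <- draw_counts(abund_r, r_dio, r_rev, schip, config$chip_depth)
  if (config$dnase_effects) {
    dnase_k <- draw_counts(abund_r, r_dio, r_rev, sdnase,
                           config$dnase_depth)
  } else {
    dnase_k <- draw_counts(abund_r, rep(0, nr), rep(0, nr), sdnase,
                           config$dnase_depth)
  }

  ## sequences with planted motifs
  mot <- default_pwm()
  L <- ncol(mot$matrix)
  seqs <- vapply(seq_len(nr), function(i)
    paste(sample(BASES, config$region_width_bp, replace = TRUE),
          collapse = ""), "")
  names(seqs) <- rid
  planted <- rcls == "induced" & stats::runif(nr) < config$motif_prob
  at <- floor((config$region_width_bp - L) / 2) + 1
  for (i in which(planted)) {
    ins <- paste(vapply(seq_len(L), function(j)
      sample(BASES, 1, prob = mot$matrix[, j]), ""), collapse = "")
    substr(seqs[i], at, at + L - 1) <- ins
  }

  truth_genes <- data.frame(feature_id = gid, class = gcls,
                            true_log2fc_dio = g_dio,
                            true_log2fc_rev = g_rev,
                            abundance = abund_g / sum(abund_g),
                            stringsAsFactors = FALSE)
  truth_regions <- data.frame(feature_id = rid, class = rcls,
                              true_log2fc_dio = r_dio,
                              true_log2fc_rev = r_rev,
                              abundance = abund_r / sum(abund_r),
                              linked_gene = linked,
                              motif_planted = planted,
                              stringsAsFactors = FALSE)
  structure(list(
    genes = genes, regions = regions,
    counts_exon = count_matrix(exon_k, srna$group, srna$replicate),
    counts_intron = count_matrix(intron_k, srna$group, srna$replicate),
    counts_k27ac = count_matrix(chip_k, schip$group, schip$replicate),
    counts_dnase = count_matrix(dnase_k, sdnase$group, sdnase$replicate),
    sequences = seqs, truth_genes = truth_genes,
    truth_regions = truth_regions, samples = samples, pwm = mot,
    config = config), class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(paste0("sim_study (seed %s): %d genes, %d regions; ",
                     "%d regulated genes, %d regulated regions\n"),
              format(x$config$seed), nrow(x$genes), nrow(x$regions),
              sum(x$truth_genes$class != "null"),
              sum(x$truth_regions$class != "null")))
  invisible(x)
}

#' Simulate a tag track with one planted cluster over uniform background
#'
#' `n_tags` positions uniform within `region` plus a Poisson background of
#' `background_rate` tags per bp over `[0, genome_bp)` on the region's
#' chromosome.
#'
#' @param region a single-row [region_set()] (or list with `chrom`,
#'   `start`, `end`).
#' @param n_tags cluster size (>= 0).
#' @param background_rate background tags per bp (>= 0).
#' @param genome_bp background span in bp.
#' @param seed optional seed.
#' @return A [tag_track()].
#' @export
simulate_tag_cluster <- function(region, n_tags, background_rate,
                                 genome_bp = 1e7, seed = NULL) {
  if (n_tags < 0) stop("n_tags must be >= 0")
  if (background_rate < 0) stop("background_rate must be >= 0")
  local_seed(seed, {
    fg <- if (n_tags > 0)
      floor(stats::runif(n_tags, region$start[1], region$end[1])) else numeric(0)
    nbg <- stats::rpois(1, background_rate * genome_bp)
    bg <- if (nbg > 0) floor(stats::runif(nbg, 0, genome_bp)) else numeric(0)
    pos <- c(fg, bg)
    tag_track(rep(region$chrom[1], length(pos)), pos, "sim_cluster")
  })
}

#' Write a simulated study bundle to a directory
#'
#' Files: `genes.tsv`, `regions.bed`, `counts_exon.tsv`,
#' `counts_intron.tsv`, `counts_k27ac.tsv`, `counts_dnase.tsv`,
#' `regions.fa`, `truth.tsv` (genes and regions, `feature_type` column),
#' `samples.tsv`, `config.yaml`.
#'
#' @param bundle a `sim_study`.
#' @param dir output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_bundle <- function(bundle, dir) {
  stopifnot(inherits(bundle, "sim_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_genes_tsv(bundle$genes, fp("genes.tsv"))
  write_bed(bundle$regions, fp("regions.bed"))
  write_counts_tsv(bundle$counts_exon, fp("counts_exon.tsv"))
  write_counts_tsv(bundle$counts_intron, fp("counts_intron.tsv"))
  write_counts_tsv(bundle$counts_k27ac, fp("counts_k27ac.tsv"))
  write_counts_tsv(bundle$counts_dnase, fp("counts_dnase.tsv"))
  write_fasta(bundle$sequences, fp("regions.fa"))
  tg <- cbind(feature_type = "gene", bundle$truth_genes,
              linked_gene = NA_character_, motif_planted = NA)
  tr <- cbind(feature_type = "region", bundle$truth_regions)
  utils::write.table(rbind(tg, tr[, names(tg)]), fp("truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(bundle$samples, fp("samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cfg <- unclass(bundle$config)
  cfg$gene_props <- as.list(cfg$gene_props)   # keep names in the YAML map
  cfg$region_props <- as.list(cfg$region_props)
  yaml::write_yaml(cfg, fp("config.yaml"))
  invisible(dir)
}

#' Read a study bundle written by [write_bundle()]
#'
#' @param dir bundle directory.
#' @return A `sim_study` list (without the generator's internal state;
#'   semantically identical to the in-memory bundle).
#' @export
read_bundle <- function(dir) {
  if (!dir.exists(dir)) stop("bundle directory not found: ", dir)
  fp <- function(f) file.path(dir, f)
  samples <- utils::read.delim(fp("samples.tsv"))
  truth <- utils::read.delim(fp("truth.tsv"))
  cm <- function(f, assay) {
    tab <- utils::read.delim(fp(f), check.names = FALSE)
    m <- as.matrix(tab[, -1, drop = FALSE])
    rownames(m) <- tab[[1]]
    s <- samples[match(colnames(m), samples$sample_id), ]
    count_matrix(m, s$group, s$replicate)
  }
  cfg <- yaml::read_yaml(fp("config.yaml"))
  cfg$gene_props <- unlist(cfg$gene_props)
  cfg$region_props <- unlist(cfg$region_props)
  config <- do.call(sim_config, cfg[names(cfg) %in% names(formals(sim_config))])
  tg <- truth[truth$feature_type == "gene", ]
  tr <- truth[truth$feature_type == "region", ]
  structure(list(
    genes = read_genes_tsv(fp("genes.tsv")),
    regions = read_bed(fp("regions.bed"), name = "accessible_regions"),
    counts_exon = cm("counts_exon.tsv", "rna"),
    counts_intron = cm("counts_intron.tsv", "rna"),
    counts_k27ac = cm("counts_k27ac.tsv", "k27ac"),
    counts_dnase = cm("counts_dnase.tsv", "dnase"),
    sequences = read_fasta(fp("regions.fa")),
    truth_genes = tg[, c("feature_id", "class", "true_log2fc_dio",
                         "true_log2fc_rev", "abundance")],
    truth_regions = tr[, c("feature_id", "class", "true_log2fc_dio",
                           "true_log2fc_rev", "abundance", "linked_gene",
                           "motif_planted")],
    samples = samples, pwm = default_pwm(), config = config),
    class = "sim_study")
}
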