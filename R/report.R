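# Pipeline orchestration and replicate-concordance summaries
# (row z-scores, PCA, pairwise Pearson correlation).

#' Row z-scores of a numeric matrix
#'
#' Each row is centered by its mean and scaled by its sample standard
#' deviation.  Constant rows become all zeros and are flagged.
#'
#' @param m numeric matrix with at least 2 columns.
#' @return List with `z` (matrix) and `constant` (logical per row).
#' @export
zscore_rows <- function(m) {
  m <- as.matrix(m)
  if (ncol(m) < 2) stop("need at least 2 columns to z-score")
  mu <- rowMeans(m)
  sd <- apply(m, 1, stats::sd)
  constant <- sd == 0
  sd[constant] <- 1
  list(z = (m - mu) / sd, constant = constant)
}

#' Replicate concordance: pairwise Pearson correlation and PCA
#'
#' Counts are normalized by size factors and transformed as
#' `log2(normalized + 1)`.  Pearson correlation is computed between all
#' sample pairs; PCA scores (first two components) come from the
#' column-centered feature matrix, with each component's sign fixed so
#' that its largest-magnitude loading is positive.
#'
#' @param x a [count_matrix()] with at least 3 samples.
#' @return List with `pearson` (sample x sample matrix) and `pca`
#'   (data frame `sample_id`, `group`, `PC1`, `PC2`, plus the proportion
#'   of variance explained as an attribute).
#' @export
replicate_concordance <- function(x) {
  stopifnot(inherits(x, "count_matrix"))
  if (ncol(x$counts) < 3) stop("need at least 3 samples")
  sf <- estimate_size_factors(x)
  lg <- log2(sweep(x$counts, 2, sf, "/") + 1)
  if (all(apply(lg, 1, stats::sd) == 0)) stop("constant matrix")
  pearson <- stats::cor(lg)
  pc <- stats::prcomp(t(lg), center = TRUE, scale. = FALSE)
  k <- min(2, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  for (j in seq_len(k)) {
    ld <- pc$rotation[, j]
    if (ld[which.max(abs(ld))] < 0) {
      scores[, j] <- -scores[, j]
      pc$rotation[, j] <- -ld
    }
  }
  pca <- data.frame(sample_id = x$meta$sample_id, group = x$meta$group,
                    PC1 = scores[, 1],
                    PC2 = if (k >= 2) scores[, 2] else NA_real_,
                    row.names = NULL)
  attr(pca, "var_explained") <- (pc$sdev^2 / sum(pc$sdev^2))[seq_len(k)]
  list(pearson = pearson, pca = pca)
}

#' Configuration of a full pipeline run
#'
#' @param sim a [sim_config()] used to simulate the study inline, or
#'   `NULL` with `input_dir` naming a bundle written by [write_bundle()].
#' @param input_dir optional bundle directory to load instead of
#'   simulating.
#' @param out_dir output directory for tables and the summary JSON.
#' @param seed seed for the stochastic stages (proximity resampling).
#' @param mrna_fdr FDR for mRNA regulation (default 0.05).
#' @param ongoing_exon_fdr,ongoing_min_fc exon thresholds of the
#'   ongoing-transcription classifier (defaults 0.01, 1.5).
#' @param intron_fdr_grid intron-FDR grid (default 0.01, 0.05, 0.1).
#' @param region_p,region_fdr lenient p and FDR thresholds for region
#'   regulation (defaults 0.01, 0.1).
#' @param window_bp,n_random,rounds proximity-enrichment parameters
#'   (defaults 100 kb, 200, 4).
#' @return A `run_config` list.
#' @export
run_config <- function(sim = sim_config(), input_dir = NULL,
                       out_dir = tempfile("enhancerflux_run_"), seed = 1,
                       mrna_fdr = 0.05, ongoing_exon_fdr = 0.01,
                       ongoing_min_fc = 1.5,
                       intron_fdr_grid = c(0.01, 0.05, 0.1),
                       region_p = 0.01, region_fdr = 0.1,
                       window_bp = 1e5, n_random = 200, rounds = 4) {
  stopifnot(mrna_fdr > 0, mrna_fdr < 1, region_p > 0, region_p < 1,
            region_fdr > 0, region_fdr < 1, window_bp > 0,
            n_random > 0, rounds > 0)
  structure(list(sim = sim, input_dir = input_dir, out_dir = out_dir,
                 seed = seed, mrna_fdr = mrna_fdr,
                 ongoing_exon_fdr = ongoing_exon_fdr,
                 ongoing_min_fc = ongoing_min_fc,
                 intron_fdr_grid = intron_fdr_grid,
                 region_p = region_p, region_fdr = region_fdr,
                 window_bp = window_bp, n_random = n_random,
                 rounds = rounds),
            class = "run_config")
}

#' Run the full analysis pipeline
#'
#' Simulates (or loads) a study bundle, then runs: differential exon,
#' intron, acetylation and accessibility testing for the perturbation
#' (HFD vs Chow) and reversal (HFD-chow vs Chow-chow) contrasts; the
#' ongoing-transcription classification; proximity enrichment of induced
#' and reduced regions around the regulated gene sets; the persistence
#' classification with diagnostics; motif occurrence/strength analyses on
#' the region sequences; and replicate-concordance summaries.  All tables
#' are written as TSV/BED under `cfg$out_dir` together with a
#' machine-readable `summary.json`.  The run is deterministic given the
#' seeds in `cfg`.  Any stage failure aborts with the stage name and
#' removes partial outputs.
#'
#' @param cfg a [run_config()].
#' @param quiet suppress per-stage log lines.
#' @return Invisibly, a list with the bundle, all intermediate results and
#'   the `summary` list.
#' @export
run_full_analysis <- function(cfg, quiet = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  state <- new.env()
  log_stage <- function(name, what) {
    if (!quiet) message(sprintf("[%s] %s", name, what))
  }
  run_stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      unlink(list.files(cfg$out_dir, full.names = TRUE), recursive = TRUE)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  fp <- function(f) file.path(cfg$out_dir, f)
  ctr_dio <- contrast("Chow", "HFD")
  ctr_rev <- contrast("ChowChow", "HFDChow")

  bundle <- run_stage("input", {
    b <- if (!is.null(cfg$input_dir)) read_bundle(cfg$input_dir)
    else simulate_study(cfg$sim)
    log_stage("input", sprintf("%d genes, %d regions", nrow(b$genes),
                               nrow(b$regions)))
    b
  })

  diffs <- run_stage("difftest", {
    d <- list(exon_dio = diff_test(bundle$counts_exon, ctr_dio),
              exon_rev = diff_test(bundle$counts_exon, ctr_rev),
              intron_dio = diff_test(bundle$counts_intron, ctr_dio),
              intron_rev = diff_test(bundle$counts_intron, ctr_rev),
              k27ac_dio = differential_acetylation(bundle$counts_k27ac,
                                                   ctr_dio),
              k27ac_rev = differential_acetylation(bundle$counts_k27ac,
                                                   ctr_rev),
              dnase_dio = differential_acetylation(bundle$counts_dnase,
                                                   ctr_dio))
    for (nm in names(d)) write_diff_tsv(d[[nm]], fp(paste0("diff_", nm, ".tsv")))
    log_stage("difftest", sprintf("%d tables written", length(d)))
    d
  })

  nascent <- run_stage("nascent", {
    nc <- classify_ongoing(diffs$exon_dio, diffs$intron_dio,
                           exon_fdr_max = cfg$ongoing_exon_fdr,
                           min_fc = cfg$ongoing_min_fc,
                           intron_fdr_grid = cfg$intron_fdr_grid)
    utils::write.table(nc$calls, fp("nascent_calls.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(nc$fractions, fp("nascent_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    log_stage("nascent", sprintf("%d exon-regulated genes", nrow(nc$calls)))
    nc
  })

  enrich <- run_stage("proximity", {
    k27_sets <- threshold_results(diffs$k27ac_dio, fdr_max = cfg$region_fdr)
    gene_sets <- threshold_results(diffs$exon_dio, fdr_max = cfg$mrna_fdr)
    sub_rs <- function(ids) {
      m <- match(ids, bundle$regions$id)
      region_set(bundle$regions$chrom[m], bundle$regions$start[m],
                 bundle$regions$end[m], id = ids)
    }
    combos <- list(
      list(rc = "induced", gs = "up_genes", rids = k27_sets$up,
           gids = gene_sets$up),
      list(rc = "reduced", gs = "down_genes", rids = k27_sets$down,
           gids = gene_sets$down))
    res <- list()
    for (i in seq_along(combos)) {
      cb <- combos[[i]]
      res[[cb$rc]] <- if (length(cb$gids) == 0) NULL
      else proximity_enrichment(sub_rs(cb$rids), bundle$genes, cb$gids,
                                window_bp = cfg$window_bp,
                                n_random = cfg$n_random,
                                rounds = cfg$rounds,
                                seed = cfg$seed + i,
                                region_class = cb$rc,
                                gene_set_name = cb$gs)
    }
    tab <- do.call(rbind, lapply(Filter(Negate(is.null), res), function(e)
      data.frame(gene_set = e$gene_set_name, region_class = e$region_class,
                 observed = e$observed, null_mean = mean(e$null_values),
                 ratio = e$ratio, p = e$p,
                 frac_genes_with_hit = e$frac_genes_with_hit)))
    if (!is.null(tab))
      utils::write.table(tab, fp("proximity_enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    log_stage("proximity", sprintf("%d region-class enrichments",
                                   length(Filter(Negate(is.null), res))))
    res
  })

  persist <- run_stage("persistence", {
    pc <- classify_persistence(diffs$k27ac_dio, diffs$k27ac_rev,
                               p_cut = cfg$region_p,
                               fdr_cut = cfg$region_fdr)
    write_persistence(pc, bundle$regions, fp("persistence_calls.tsv"),
                      fp("persistence_calls.bed"))
    diag <- persistence_diagnostics(pc, bundle$counts_k27ac)
    log_stage("persistence",
              paste(names(table(pc$calls$class)),
                    table(pc$calls$class), sep = "=", collapse = ", "))
    list(calls = pc, diagnostics = diag)
  })

  motifs <- run_stage("motifs", {
    if (is.null(bundle$sequences) || is.null(bundle$pwm)) NULL
    else {
      tr <- bundle$truth_regions
      k27_sets <- threshold_results(diffs$k27ac_dio,
                                    fdr_max = cfg$region_fdr)
      ind <- bundle$sequences[k27_sets$up]
      red <- bundle$sequences[k27_sets$down]
      rand <- local_seed(cfg$seed + 10, {
        bundle$sequences[sample(setdiff(names(bundle$sequences),
                                        c(k27_sets$up, k27_sets$down)),
                                min(500, nrow(tr)))]
      })
      occ <- if (length(ind) >= 1)
        occurrence_enrichment(ind, rand, bundle$pwm, score_min = 10)
      else NULL
      sets <- Filter(function(s) length(s) >= 2,
                     list(induced = ind, reduced = red, random = rand))
      strg <- if (length(sets) >= 2)
        strength_comparison(sets, bundle$pwm) else NULL
      if (!is.null(strg)) {
        utils::write.table(strg$summary, fp("motif_strength_summary.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
        utils::write.table(strg$pairwise, fp("motif_strength_pairwise.tsv"),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
      log_stage("motifs", sprintf("occurrence p = %s",
                                  format(occ$p %||% NA)))
      list(occurrence = occ, strength = strg)
    }
  })

  concord <- run_stage("concordance", {
    cc <- replicate_concordance(bundle$counts_exon)
    utils::write.table(round(cc$pearson, 6), fp("pearson_exon.tsv"),
                       sep = "\t", quote = FALSE)
    utils::write.table(cc$pca, fp("pca_exon.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    cc
  })

  summary <- run_stage("summary", {
    gene_sets <- threshold_results(diffs$exon_dio, fdr_max = cfg$mrna_fdr)
    cls <- table(factor(persist$calls$calls$class,
                        levels = c("reversible", "putative_persistent",
                                   "weightloss_specific", "unregulated")))
    s <- list(
      seed = cfg$seed,
      n_genes = nrow(bundle$genes),
      n_regions = nrow(bundle$regions),
      genes_up = length(gene_sets$up),
      genes_down = length(gene_sets$down),
      ongoing_fractions = stats::setNames(
        lapply(seq_len(nrow(nascent$fractions)), function(i)
          list(up = nascent$fractions$up_fraction[i],
               down = nascent$fractions$down_fraction[i])),
        sprintf("fdr_%g", nascent$fractions$threshold)),
      venn_p = as.list(persist$calls$venn_p),
      venn_fdr = as.list(persist$calls$venn_fdr),
      persistence_classes = as.list(cls),
      proximity = lapply(Filter(Negate(is.null), enrich), function(e)
        list(observed = e$observed, null_mean = mean(e$null_values),
             ratio = e$ratio, p = e$p)),
      motif_occurrence_p = if (!is.null(motifs$occurrence))
        motifs$occurrence$p else NULL)
    jsonlite::write_json(s, fp("summary.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    s
  })

  invisible(list(bundle = bundle, diffs = diffs, nascent = nascent,
                 enrichment = enrich, persistence = persist,
                 motifs = motifs, concordance = concord,
                 summary = summary, out_dir = cfg$out_dir))
}
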