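# Differential histone acetylation at accessible regions, enhancer-gene
# proximity enrichment against resampled gene-set nulls, and the
# reversal/persistence classification with its false-positive diagnostics.

#' Differential acetylation at accessible regions
#'
#' Runs the NB differential test on a region-level count matrix (size
#' factors estimated on the full region universe).
#'
#' @param region_counts a [count_matrix()] of acetylation tag counts at the
#'   accessible-region universe.
#' @param ctr a [contrast()].
#' @param min_reps minimal replicates per group (default 2, accommodating
#'   two-replicate accessibility designs).
#' @return A `diff_result` data frame, one row per region.
#' @export
differential_acetylation <- function(region_counts, ctr, min_reps = 2) {
  diff_test(region_counts, ctr, min_reps = min_reps)
}

#' Enhancer-gene proximity enrichment against resampled gene sets
#'
#' A region qualifies for a gene when any part of it lies within
#' `window_bp` of the gene's TSS.  The observed statistic is the number of
#' qualifying region-gene pairs per gene of the test set; the null is the
#' same statistic over `rounds` draws of `n_random` genes sampled (without
#' replacement, excluding the test set) from the gene universe.  The
#' p-value is a two-tailed one-sample t-test of the null round values
#' against the observed value.
#'
#' @param diff_regions a [region_set()] (e.g. regions with induced or
#'   reduced acetylation).
#' @param genes a [gene_models()] table (the gene universe).
#' @param test_set character vector of gene ids (subset of the universe).
#' @param window_bp TSS window half-width in bp (default 100,000).
#' @param n_random genes per random round (default 200).
#' @param rounds number of random rounds (default 4).
#' @param seed optional integer seed making the draws reproducible.
#' @return A `linkage_enrichment` list: `observed`, `null_values`,
#'   `ratio`, `p`, `frac_genes_with_hit`, plus the parameters.
#' @export
proximity_enrichment <- function(diff_regions, genes, test_set,
                                 window_bp = 1e5, n_random = 200,
                                 rounds = 4, seed = NULL,
                                 region_class = "regions",
                                 gene_set_name = "test_set") {
  stopifnot(inherits(diff_regions, "region_set"),
            inherits(genes, "gene_models"))
  if (!all(test_set %in% genes$gene_id))
    stop("test_set contains unknown gene ids")
  bg <- setdiff(genes$gene_id, test_set)
  if (length(bg) < n_random)
    stop("too few background genes for random rounds")
  pairs_per_gene <- function(ids) {
    gi <- match(ids, genes$gene_id)
    tot <- 0L
    hit <- logical(length(gi))
    for (k in seq_along(gi)) {
      i <- gi[k]
      m <- diff_regions$chrom == genes$chrom[i] &
        diff_regions$start <= genes$tss[i] + window_bp &
        diff_regions$end > genes$tss[i] - window_bp
      nh <- sum(m)
      tot <- tot + nh
      hit[k] <- nh > 0
    }
    c(tot / length(gi), mean(hit))
  }
  obs <- pairs_per_gene(test_set)
  null_values <- local_seed(seed, {
    vapply(seq_len(rounds),
           function(r) pairs_per_gene(sample(bg, n_random))[1], 0)
  })
  ratio <- if (nrow(diff_regions) == 0 || mean(null_values) == 0)
    NA_real_ else obs[1] / mean(null_values)
  p <- if (nrow(diff_regions) == 0) {
    NA_real_
  } else if (stats::sd(null_values) == 0) {
    if (all(null_values == obs[1])) 1 else 0
  } else {
    stats::t.test(null_values, mu = obs[1])$p.value
  }
  structure(list(gene_set_name = gene_set_name, region_class = region_class,
                 window_bp = window_bp, n_random = n_random, rounds = rounds,
                 observed = obs[1], null_values = null_values,
                 ratio = ratio, p = p, frac_genes_with_hit = obs[2]),
            class = "linkage_enrichment")
}

#' @export
print.linkage_enrichment <- function(x, ...) {
  cat(sprintf(paste0("proximity enrichment [%s ~ %s, +/-%d kb]: ",
                     "observed %.3f pairs/gene, null mean %.3f, ",
                     "ratio %.2f, p = %.3g\n"),
              x$region_class, x$gene_set_name, x$window_bp / 1000,
              x$observed, mean(x$null_values), x$ratio, x$p))
  invisible(x)
}

#' Classify regulated regions as reversible, persistent or
#' weight-loss-specific
#'
#' Regions significant in the perturbation contrast (`p_dio < p_cut`) are
#' `putative_persistent` when also significant in the reversal contrast
#' with a concordant fold-change sign, otherwise `reversible`.  Regions
#' significant only in the reversal contrast are `weightloss_specific`;
#' the rest are `unregulated`.  Venn overlap counts of the two contrasts'
#' significant sets are reported both at `p < p_cut` and at
#' `fdr < fdr_cut`.
#'
#' @param dio `diff_result` for the perturbation contrast (e.g. HFD vs
#'   Chow).
#' @param rev `diff_result` for the reversal contrast (e.g. HFD-chow vs
#'   Chow-chow), over the same region universe.
#' @param p_cut lenient p-value screen (default 0.01).
#' @param fdr_cut FDR threshold for the Venn analogue (default 0.1).
#' @return List with `calls` (region_id, p/fdr for both contrasts, class),
#'   `venn_p` and `venn_fdr` (named counts: `dio_only`, `rev_only`,
#'   `shared`), and the cutoffs.
#' @export
classify_persistence <- function(dio, rev, p_cut = 0.01, fdr_cut = 0.1) {
  if (!setequal(dio$feature_id, rev$feature_id) ||
      nrow(dio) != nrow(rev))
    stop("dio and rev results must cover the same region universe")
  rev <- rev[match(dio$feature_id, rev$feature_id), ]
  sig_dio <- !is.na(dio$p) & dio$p < p_cut
  sig_rev <- !is.na(rev$p) & rev$p < p_cut
  concord <- sign(dio$log2fc) == sign(rev$log2fc)
  cls <- rep("unregulated", nrow(dio))
  cls[sig_dio] <- "reversible"
  cls[sig_dio & sig_rev & concord] <- "putative_persistent"
  cls[!sig_dio & sig_rev] <- "weightloss_specific"
  calls <- data.frame(region_id = dio$feature_id,
                      log2fc_dio = dio$log2fc, p_dio = dio$p,
                      fdr_dio = dio$fdr,
                      log2fc_rev = rev$log2fc, p_rev = rev$p,
                      fdr_rev = rev$fdr,
                      class = cls, stringsAsFactors = FALSE)
  venn <- function(sa, sb) c(dio_only = sum(sa & !sb),
                             rev_only = sum(!sa & sb),
                             shared = sum(sa & sb))
  fa <- !is.na(dio$fdr) & dio$fdr < fdr_cut
  fb <- !is.na(rev$fdr) & rev$fdr < fdr_cut
  list(calls = calls,
       venn_p = venn(sig_dio, sig_rev),
       venn_fdr = venn(fa, fb),
       p_cut = p_cut, fdr_cut = fdr_cut)
}

#' Diagnostics for persistence calls
#'
#' For each persistence class, summarizes (i) the per-group distribution of
#' row-z-scored normalized counts (quartiles over regions x replicates) and
#' (ii) the empirical distribution of the two contrasts' FDR values.  High
#' reversal-contrast FDR among putative persistent regions is the signature
#' of false positives surviving the lenient p-value screen.
#'
#' @param persistence result of [classify_persistence()].
#' @param region_counts the [count_matrix()] the calls were derived from.
#' @return Named list (one entry per non-empty class) of lists with
#'   `n`, `zscore_quartiles` (group x quartile matrix), `fdr_dio` and
#'   `fdr_rev` (quartile vectors).
#' @export
persistence_diagnostics <- function(persistence, region_counts) {
  stopifnot(inherits(region_counts, "count_matrix"))
  calls <- persistence$calls
  sf <- estimate_size_factors(region_counts)
  y <- sweep(region_counts$counts, 2, sf, "/")
  z <- zscore_rows(y)$z
  groups <- unique(region_counts$meta$group)
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  out <- list()
  for (cl in unique(calls$class)) {
    ids <- calls$region_id[calls$class == cl]
    zi <- z[match(ids, rownames(region_counts$counts)), , drop = FALSE]
    zq <- t(vapply(groups, function(g) {
      stats::quantile(zi[, region_counts$meta$group == g], qs, na.rm = TRUE)
    }, numeric(length(qs))))
    out[[cl]] <- list(
      n = length(ids),
      zscore_quartiles = zq,
      fdr_dio = stats::quantile(calls$fdr_dio[calls$class == cl], qs,
                                na.rm = TRUE),
      fdr_rev = stats::quantile(calls$fdr_rev[calls$class == cl], qs,
                                na.rm = TRUE))
  }
  out
}

#' Write persistence calls as TSV and BED
#'
#' The BED name field carries `<region_id>|<class>`.
#'
#' @param persistence result of [classify_persistence()].
#' @param regions the [region_set()] of the region universe.
#' @param tsv_path,bed_path output paths (either may be `NULL`).
#' @return Invisibly, `tsv_path`.
#' @export
write_persistence <- function(persistence, regions, tsv_path,
                              bed_path = NULL) {
  calls <- persistence$calls
  if (!is.null(tsv_path))
    utils::write.table(calls, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  if (!is.null(bed_path)) {
    m <- match(calls$region_id, regions$id)
    rs <- region_set(regions$chrom[m], regions$start[m], regions$end[m],
                     id = sprintf("%s|%s", calls$region_id, calls$class),
                     strand = regions$strand[m])
    write_bed(rs, bed_path)
  }
  invisible(tsv_path)
}
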