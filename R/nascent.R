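# Intron/exon read partitioning and the ongoing-transcription classifier.
#
# Intronic reads report nascent RNA synthesis (introns are removed
# co-transcriptionally), so a gene whose exonic change is mirrored by a
# same-direction intronic change is called regulated by ongoing
# transcription; an exon-only change reflects altered mRNA turnover.

#' Construct single-isoform gene models
#'
#' Exons must be sorted and non-overlapping within a gene; introns are the
#' gaps between consecutive exons.  The TSS is the start of the first exon
#' on the + strand and the end of the last exon on the - strand.
#'
#' @param gene_id character vector of unique gene ids.
#' @param chrom chromosome per gene.
#' @param strand `"+"` or `"-"` per gene.
#' @param exon_starts,exon_ends lists of integer vectors (0-based
#'   half-open), one vector per gene, or comma-joined strings.
#' @return A `gene_models` data frame with per-gene `tss`, `span_start`,
#'   `span_end`, `exon_length`, `intron_length` and comma-joined exon
#'   coordinate columns.
#' @export
gene_models <- function(gene_id, chrom, strand, exon_starts, exon_ends) {
  n <- length(gene_id)
  if (anyDuplicated(gene_id)) stop("gene ids must be unique")
  if (is.character(exon_starts))
    exon_starts <- lapply(strsplit(exon_starts, ","), as.numeric)
  if (is.character(exon_ends))
    exon_ends <- lapply(strsplit(exon_ends, ","), as.numeric)
  stopifnot(length(exon_starts) == n, length(exon_ends) == n)
  tss <- span_start <- span_end <- exon_len <- intron_len <- numeric(n)
  for (i in seq_len(n)) {
    s <- exon_starts[[i]]; e <- exon_ends[[i]]
    if (!length(s) || length(s) != length(e)) stop("bad exon lists: ", gene_id[i])
    if (any(s >= e)) stop("exon start >= end in gene ", gene_id[i])
    if (is.unsorted(s, strictly = TRUE) || any(s[-1] < e[-length(e)]))
      stop("exons must be sorted and non-overlapping in gene ", gene_id[i])
    span_start[i] <- s[1]; span_end[i] <- e[length(e)]
    tss[i] <- if (strand[i] == "-") e[length(e)] else s[1]
    exon_len[i] <- sum(e - s)
    intron_len[i] <- (span_end[i] - span_start[i]) - exon_len[i]
  }
  out <- data.frame(gene_id = as.character(gene_id),
                    chrom = as.character(chrom),
                    strand = as.character(strand),
                    tss = tss, span_start = span_start, span_end = span_end,
                    exon_length = exon_len, intron_length = intron_len,
                    exon_starts = vapply(exon_starts, paste, "", collapse = ","),
                    exon_ends = vapply(exon_ends, paste, "", collapse = ","),
                    stringsAsFactors = FALSE)
  class(out) <- c("gene_models", "data.frame")
  out
}

#' @export
print.gene_models <- function(x, ...) {
  cat(sprintf("gene_models: %d genes, median exonic %d bp / intronic %d bp\n",
              nrow(x), as.integer(stats::median(x$exon_length)),
              as.integer(stats::median(x$intron_length))))
  invisible(x)
}

# exon or intron intervals of all genes as a region_set; ids "<gene>#k"
feature_intervals <- function(genes, what = c("exon", "intron")) {
  what <- match.arg(what)
  ch <- character(0); st <- en <- numeric(0); gid <- character(0)
  for (i in seq_len(nrow(genes))) {
    s <- as.numeric(strsplit(genes$exon_starts[i], ",")[[1]])
    e <- as.numeric(strsplit(genes$exon_ends[i], ",")[[1]])
    if (what == "intron") {
      if (length(s) < 2) next
      is_ <- e[-length(e)]; ie_ <- s[-1]
      keep <- is_ < ie_
      s <- is_[keep]; e <- ie_[keep]
      if (!length(s)) next
    }
    ch <- c(ch, rep(genes$chrom[i], length(s)))
    st <- c(st, s); en <- c(en, e)
    gid <- c(gid, rep(genes$gene_id[i], length(s)))
  }
  if (!length(st))
    return(structure(region_set(character(), integer(), integer()),
                     gene_id = character(0)))
  rs <- region_set(ch, st, en, id = sprintf("%s#%d", gid, seq_along(gid)))
  attr(rs, "gene_id") <- gid
  rs
}

#' Partition a tag track into per-gene exon and intron counts
#'
#' A tag is counted in a gene's exon tally when its position lies in any
#' exon of that gene, and in the intron tally when it lies in any intron;
#' genes are treated independently, so a tag may count for several genes.
#'
#' @param track a [tag_track()].
#' @param genes a [gene_models()] table.
#' @return Data frame with columns `gene_id`, `exon`, `intron`.
#' @export
partition_tags <- function(track, genes) {
  stopifnot(inherits(track, "tag_track"), inherits(genes, "gene_models"))
  out <- data.frame(gene_id = genes$gene_id, exon = 0L, intron = 0L,
                    stringsAsFactors = FALSE)
  for (what in c("exon", "intron")) {
    rs <- feature_intervals(genes, what)
    if (!nrow(rs)) next
    cnt <- count_tags_in_regions(track, rs)
    agg <- rowsum(cnt, attr(rs, "gene_id"))
    out[[what]] <- agg[match(out$gene_id, rownames(agg)), 1]
    out[[what]][is.na(out[[what]])] <- 0L
  }
  out
}

#' Classify exon-regulated genes by ongoing transcription
#'
#' A gene is exon-regulated when its exonic differential result passes
#' `fdr < exon_fdr_max` at fold change `min_fc` (direction up or down).
#' For each intron-FDR threshold `t` in the grid, the gene is scored as
#' regulated by ongoing transcription when its intronic FDR is below `t`
#' and the intronic fold change has the same sign as the exonic one.
#'
#' @param exon_results,intron_results `diff_result` tables over the same
#'   genes (same feature ids).
#' @param exon_fdr_max exon FDR threshold (default 0.01).
#' @param min_fc minimal linear fold change for exon regulation (1.5).
#' @param intron_fdr_grid intron-FDR thresholds (default 0.01, 0.05, 0.1).
#' @return List with `calls` (one row per exon-regulated gene: direction,
#'   fold changes, intron FDR and one logical `ongoing_<t>` column per
#'   threshold) and `fractions` (per threshold, the fraction of up- and
#'   down-regulated genes called ongoing).
#' @export
classify_ongoing <- function(exon_results, intron_results,
                             exon_fdr_max = 0.01, min_fc = 1.5,
                             intron_fdr_grid = c(0.01, 0.05, 0.1)) {
  if (!length(intron_fdr_grid)) stop("intron_fdr_grid must be non-empty")
  if (!setequal(exon_results$feature_id, intron_results$feature_id))
    stop("exon and intron results must cover the same genes")
  ir <- intron_results[match(exon_results$feature_id,
                             intron_results$feature_id), ]
  sets <- threshold_results(exon_results, fdr_max = exon_fdr_max,
                            min_abs_fc = min_fc)
  reg <- exon_results$feature_id %in% c(sets$up, sets$down)
  calls <- data.frame(gene_id = exon_results$feature_id[reg],
                      direction = ifelse(exon_results$feature_id[reg] %in%
                                           sets$up, "up", "down"),
                      exon_log2fc = exon_results$log2fc[reg],
                      intron_log2fc = ir$log2fc[reg],
                      intron_fdr = ir$fdr[reg],
                      stringsAsFactors = FALSE)
  concord <- sign(calls$intron_log2fc) == sign(calls$exon_log2fc)
  fr <- data.frame(threshold = intron_fdr_grid, up_fraction = NA_real_,
                   down_fraction = NA_real_)
  for (j in seq_along(intron_fdr_grid)) {
    t <- intron_fdr_grid[j]
    ong <- !is.na(calls$intron_fdr) & calls$intron_fdr < t & concord
    calls[[sprintf("ongoing_%g", t)]] <- ong
    fr$up_fraction[j] <- if (any(calls$direction == "up"))
      mean(ong[calls$direction == "up"]) else NA_real_
    fr$down_fraction[j] <- if (any(calls$direction == "down"))
      mean(ong[calls$direction == "down"]) else NA_real_
  }
  list(calls = calls, fractions = fr)
}

#' Reads per kilobase of feature per million library tags
#'
#' @param count tag count in the feature.
#' @param feature_length_bp feature length in bp (> 0).
#' @param library_total total tags in the library (> 0).
#' @return RPKM value(s).
#' @export
rpkm <- function(count, feature_length_bp, library_total) {
  if (any(feature_length_bp <= 0)) stop("feature length must be > 0")
  if (any(library_total <= 0)) stop("library total must be > 0")
  count / ((feature_length_bp / 1000) * (library_total / 1e6))
}

#' Read gene models from a 6-column TSV
#'
#' Columns: `gene_id`, `chrom`, `strand`, `tss`, `exon_starts`,
#' `exon_ends` (the last two comma-joined).  The stored `tss` column is
#' recomputed from the exon coordinates and must agree.
#'
#' @param path path to the TSV (with header).
#' @return A [gene_models()] table.
#' @export
read_genes_tsv <- function(path) {
  tab <- utils::read.delim(path, colClasses = c(exon_starts = "character",
                                                exon_ends = "character"))
  gene_models(tab$gene_id, tab$chrom, tab$strand,
              tab$exon_starts, tab$exon_ends)
}

#' Write gene models as TSV
#' @param genes a [gene_models()] table.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_genes_tsv <- function(genes, path) {
  cols <- c("gene_id", "chrom", "strand", "tss", "exon_starts", "exon_ends")
  utils::write.table(as.data.frame(genes)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
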