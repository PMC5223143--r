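# Negative-binomial differential testing of count matrices for two-group
# contrasts: median-of-ratios size factors, trend-shrunken method-of-moments
# dispersions, a Wald test on group means, and Benjamini-Hochberg FDR.

# weight of the per-feature dispersion estimate when shrinking toward the
# mean-dispersion trend; also sets the moderated-t df in nb_wald_test
DISP_SHRINK_W <- 0.5

#' Construct a count matrix with sample metadata
#'
#' @param counts integer matrix, features x samples, with unique rownames
#'   (feature ids) and colnames (sample ids).
#' @param group character/factor vector of group labels, one per sample
#'   (e.g. `"Chow"`, `"HFD"`, `"ChowChow"`, `"HFDChow"`).
#' @param replicate optional integer replicate index per sample.
#' @return A `count_matrix` object (list with `counts` and `meta`).
#' @export
count_matrix <- function(counts, group, replicate = NULL) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)))
    rownames(counts) <- sprintf("f%d", seq_len(nrow(counts)))
  if (is.null(colnames(counts)))
    colnames(counts) <- sprintf("s%d", seq_len(ncol(counts)))
  if (anyDuplicated(rownames(counts))) stop("feature ids must be unique")
  if (length(group) != ncol(counts))
    stop("group must have one label per sample")
  if (any(is.na(counts)) || any(counts < 0) || any(counts != floor(counts)))
    stop("counts must be non-negative integers")
  if (is.null(replicate)) replicate <- stats::ave(seq_along(group),
                                                  group, FUN = seq_along)
  meta <- data.frame(sample_id = colnames(counts),
                     group = as.character(group),
                     replicate = as.integer(replicate),
                     stringsAsFactors = FALSE)
  structure(list(counts = counts, meta = meta), class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d features x %d samples; groups: %s\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s (n=%d)", names(table(x$meta$group)),
                            table(x$meta$group)), collapse = ", ")))
  invisible(x)
}

#' Median-of-ratios size factors
#'
#' For each sample, the size factor is the median over features of the
#' ratio of that sample's count to the feature's geometric mean across
#' samples; features containing any zero are excluded from the median.
#'
#' @param x a [count_matrix()] or plain counts matrix.
#' @return Named numeric vector of positive size factors, one per sample.
#' @export
estimate_size_factors <- function(x) {
  k <- if (inherits(x, "count_matrix")) x$counts else as.matrix(x)
  ok <- rowSums(k == 0) == 0
  if (!any(ok)) stop("cannot normalize: no feature has all-positive counts")
  lg <- log(k[ok, , drop = FALSE])
  loggeo <- rowMeans(lg)
  sf <- apply(exp(lg - loggeo), 2, stats::median)
  names(sf) <- colnames(k)
  sf
}

#' Per-feature NB dispersion with shrinkage toward a mean trend
#'
#' Method-of-moments dispersion on size-factor-normalized counts pooled
#' within groups (variance model `var = mu + alpha * mu^2`), shrunk halfway
#' toward a trend `a0 + a1/mu` fitted by least squares over features with
#' mean above 5.  Estimates are floored at `1e-8`.
#'
#' @param x a [count_matrix()].
#' @param sf size factors from [estimate_size_factors()].
#' @return Numeric vector of dispersions (one per feature) with the raw
#'   estimates and trend coefficients attached as attributes.
#' @export
estimate_dispersion <- function(x, sf) {
  stopifnot(inherits(x, "count_matrix"))
  k <- x$counts
  y <- sweep(k, 2, sf, "/")
  groups <- unique(x$meta$group)
  use <- groups[vapply(groups, function(g) sum(x$meta$group == g) >= 2, TRUE)]
  if (!length(use)) stop("need at least 2 replicates in some group")
  vsum <- matrix(0, nrow(k), length(use))
  shot <- numeric(length(use))   # Poisson (shot-noise) scale per group
  for (j in seq_along(use)) {
    cols <- which(x$meta$group == use[j])
    yg <- y[, cols, drop = FALSE]
    vsum[, j] <- apply(yg, 1, stats::var)
    shot[j] <- mean(1 / sf[cols])
  }
  mu <- rowMeans(y[, x$meta$group %in% use, drop = FALSE])
  v <- rowMeans(vsum)
  # subtract the depth-rescaled Poisson component before the quadratic term
  raw <- ifelse(mu > 0, (v - mu * mean(shot)) / mu^2, 0)
  raw <- pmax(raw, 0)
  fit_ok <- mu > 5
  if (sum(fit_ok) >= 10) {
    tf <- stats::lm.fit(cbind(1, 1 / mu[fit_ok]), raw[fit_ok])
    a <- tf$coefficients
  } else {
    a <- c(stats::median(raw), 0)
  }
  trend <- pmax(a[1] + a[2] / pmax(mu, 1e-8), 1e-8)
  alpha <- pmax(DISP_SHRINK_W * raw + (1 - DISP_SHRINK_W) * trend, 1e-8)
  alpha[mu == 0 | v == 0] <- 1e-8  # absent or constant features: floor
  names(alpha) <- rownames(k)
  attr(alpha, "raw") <- raw
  attr(alpha, "trend_coef") <- a
  alpha
}

#' Specify a two-group contrast
#'
#' @param reference reference group label (denominator of the fold change).
#' @param test test group label (numerator).
#' @return A `contrast` object.
#' @export
contrast <- function(reference, test) {
  if (identical(reference, test)) stop("contrast groups must differ")
  structure(list(reference = reference, test = test), class = "contrast")
}

#' Negative-binomial Wald test for a two-group contrast
#'
#' Group means are computed on normalized counts with pseudocount 0.5; the
#' standard error of the log2 fold change comes from the NB delta method
#' (`var(count) = mu + alpha * mu^2`), the Wald statistic is
#' `log2fc / se` with a two-sided moderated-t p-value (df reflecting the
#' dispersion shrinkage), and FDR is
#' Benjamini-Hochberg over the tested features.  Features with zero counts
#' in every sample get `NA` p-value and FDR and are excluded from the
#' multiple-testing correction.
#'
#' @param x a [count_matrix()].
#' @param sf size factors.
#' @param alpha per-feature dispersions ([estimate_dispersion()]).
#' @param ctr a [contrast()] whose groups are present in the metadata.
#' @param min_reps minimal replicates per contrast group (default 2; set to
#'   1 only deliberately).
#' @return A `diff_result` data frame with columns `feature_id`,
#'   `base_mean`, `log2fc`, `se`, `stat`, `p`, `fdr`.
#' @export
nb_wald_test <- function(x, sf, alpha, ctr, min_reps = 2) {
  stopifnot(inherits(x, "count_matrix"), inherits(ctr, "contrast"))
  ia <- which(x$meta$group == ctr$reference)
  ib <- which(x$meta$group == ctr$test)
  if (!length(ia) || !length(ib))
    stop("unknown group label in contrast: ",
         paste(setdiff(c(ctr$reference, ctr$test), x$meta$group),
               collapse = ", "))
  if (length(ia) < min_reps || length(ib) < min_reps)
    stop("fewer than ", min_reps, " replicates in a contrast group")
  k <- x$counts
  y <- sweep(k, 2, sf, "/")
  ma <- rowMeans(y[, ia, drop = FALSE]) + 0.5
  mb <- rowMeans(y[, ib, drop = FALSE]) + 0.5
  log2fc <- log2(mb / ma)
  l2 <- log(2)^2
  # delta method: var(log2 mean_g) = sum_j (1/(m_g s_j) + alpha) / (n_g^2 ln2^2)
  va <- (ma * sum(1 / sf[ia]) + alpha * ma^2 * length(ia)) /
    (length(ia)^2 * ma^2 * l2)
  vb <- (mb * sum(1 / sf[ib]) + alpha * mb^2 * length(ib)) /
    (length(ib)^2 * mb^2 * l2)
  se <- sqrt(va + vb)
  stat <- log2fc / se
  # moderated-t reference: shrinking the dispersion halfway toward the
  # (feature-rich, effectively exact) trend quarters its sampling variance,
  # so the effective df is the residual df divided by the shrink weight^2
  df_eff <- (length(ia) - 1 + length(ib) - 1) / DISP_SHRINK_W^2
  p <- 2 * stats::pt(-abs(stat), df = df_eff)
  allzero <- rowSums(k[, c(ia, ib), drop = FALSE]) == 0
  p[allzero] <- NA_real_
  stat[allzero] <- NA_real_
  res <- data.frame(feature_id = rownames(k),
                    base_mean = rowMeans(y[, c(ia, ib), drop = FALSE]),
                    log2fc = log2fc, se = se, stat = stat, p = p,
                    fdr = bh_fdr(p), stringsAsFactors = FALSE)
  rownames(res) <- NULL
  attr(res, "contrast") <- ctr
  class(res) <- c("diff_result", "data.frame")
  res
}

#' @export
print.diff_result <- function(x, ...) {
  ctr <- attr(x, "contrast")
  if (!is.null(ctr))
    cat(sprintf("diff_result: %s vs %s (reference)\n", ctr$test,
                ctr$reference))
  cat(sprintf("%d features tested; %d at FDR < 0.05, %d at FDR < 0.1\n",
              sum(!is.na(x$p)), sum(x$fdr < 0.05, na.rm = TRUE),
              sum(x$fdr < 0.1, na.rm = TRUE)))
  invisible(x)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' `q_(i) = min_(j >= i) p_(j) * m / j` over the sorted p-values, mapped
#' back to the input order.  `NA` entries are excluded from `m` and
#' returned as `NA`.
#'
#' @param p numeric vector of p-values in `[0, 1]` (NAs allowed).
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  ok <- !is.na(p)
  if (any(p[ok] < 0 | p[ok] > 1)) stop("p-values must lie in [0, 1]")
  q <- rep(NA_real_, length(p))
  m <- sum(ok)
  if (m == 0) return(q)
  ps <- p[ok]
  o <- order(ps)
  qs <- ps[o] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  qs <- pmin(qs, 1)
  tmp <- numeric(m)
  tmp[o] <- qs
  q[ok] <- tmp
  q
}

#' Split differential results into up- and down-regulated sets
#'
#' A feature is up-regulated when it passes the significance filter and its
#' fold change is at least `min_abs_fc`; down-regulated when the fold
#' change is at most `1/min_abs_fc`.  The significance filter is
#' `fdr < fdr_max`, or `p < p_max` when `p_max` is supplied (the lenient
#' p-value screen used for putative persistent regions).
#'
#' @param results a `diff_result` data frame.
#' @param fdr_max FDR threshold.
#' @param min_abs_fc minimal linear fold change (>= 1), e.g. 1.5.
#' @param p_max optional p-value threshold replacing the FDR filter.
#' @return List with character vectors `up` and `down` of feature ids.
#' @export
threshold_results <- function(results, fdr_max = 0.05, min_abs_fc = 1,
                              p_max = NULL) {
  if (min_abs_fc < 1) stop("min_abs_fc must be >= 1")
  if (!nrow(results)) return(list(up = character(), down = character()))
  sig <- if (is.null(p_max)) {
    !is.na(results$fdr) & results$fdr < fdr_max
  } else {
    !is.na(results$p) & results$p < p_max
  }
  lfc <- log2(min_abs_fc)
  list(up = results$feature_id[sig & results$log2fc >= lfc],
       down = results$feature_id[sig & results$log2fc <= -lfc])
}

#' One-stop differential test of a count matrix
#'
#' Convenience wrapper chaining [estimate_size_factors()],
#' [estimate_dispersion()] and [nb_wald_test()].
#'
#' @inheritParams nb_wald_test
#' @param x a [count_matrix()].
#' @param ctr a [contrast()].
#' @return A `diff_result` data frame.
#' @export
diff_test <- function(x, ctr, min_reps = 2) {
  sf <- estimate_size_factors(x)
  alpha <- estimate_dispersion(x, sf)
  nb_wald_test(x, sf, alpha, ctr, min_reps = min_reps)
}

#' Read a count matrix and sample sheet from TSV files
#'
#' The counts TSV has a `feature_id` column followed by one column per
#' sample; the sample sheet has columns `sample_id`, `group`, `replicate`.
#'
#' @param counts_path path to the counts TSV.
#' @param samples_path path to the sample sheet TSV.
#' @return A [count_matrix()].
#' @export
read_counts_tsv <- function(counts_path, samples_path) {
  tab <- utils::read.delim(counts_path, check.names = FALSE)
  samp <- utils::read.delim(samples_path)
  m <- as.matrix(tab[, -1, drop = FALSE])
  rownames(m) <- tab[[1]]
  samp <- samp[match(colnames(m), samp$sample_id), ]
  if (any(is.na(samp$sample_id)))
    stop("sample sheet is missing samples present in the counts table")
  count_matrix(m, samp$group, samp$replicate)
}

#' Write a count matrix (and optionally its sample sheet) as TSV
#'
#' @param x a [count_matrix()].
#' @param counts_path output path for the counts TSV.
#' @param samples_path optional output path for the sample sheet TSV.
#' @return Invisibly, `counts_path`.
#' @export
write_counts_tsv <- function(x, counts_path, samples_path = NULL) {
  stopifnot(inherits(x, "count_matrix"))
  df <- data.frame(feature_id = rownames(x$counts), x$counts,
                   check.names = FALSE)
  utils::write.table(df, counts_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(samples_path))
    utils::write.table(x$meta, samples_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(counts_path)
}

#' Write a differential-test result table as TSV
#' @param results a `diff_result` data frame.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_diff_tsv <- function(results, path) {
  utils::write.table(as.data.frame(results), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
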