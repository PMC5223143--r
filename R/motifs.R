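# PWM scanning (log2-odds, both strands), motif-occurrence enrichment
# between sequence sets, and motif-strength comparison.

BASES <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param mat 4 x L matrix of base probabilities (rows A, C, G, T); counts
#'   are accepted and normalized per column.  Columns must sum to 1 within
#'   1e-6 after normalization.
#' @param motif_id motif identifier.
#' @param background background base probabilities (A, C, G, T); default
#'   uniform.
#' @return A `pwm` object.  Probabilities are floored at 1e-3 when the
#'   log-odds score matrix is built, never stored floored.
#' @export
pwm <- function(mat, motif_id = "motif", background = rep(0.25, 4)) {
  mat <- as.matrix(mat)
  if (nrow(mat) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (any(mat < 0)) stop("PWM entries must be non-negative")
  cs <- colSums(mat)
  if (any(cs <= 0)) stop("PWM has an empty column")
  mat <- sweep(mat, 2, cs, "/")
  if (any(abs(colSums(mat) - 1) > 1e-6)) stop("PWM columns must sum to 1")
  if (length(background) != 4 || abs(sum(background) - 1) > 1e-6)
    stop("background must be 4 probabilities summing to 1")
  rownames(mat) <- BASES
  structure(list(motif_id = motif_id, matrix = mat,
                 background = as.numeric(background)),
            class = "pwm")
}

#' @export
print.pwm <- function(x, ...) {
  cons <- paste(BASES[apply(x$matrix, 2, which.max)], collapse = "")
  cat(sprintf("pwm '%s': %d columns, consensus %s\n", x$motif_id,
              ncol(x$matrix), cons))
  invisible(x)
}

#' Read PWMs from a JASPAR-style PFM text file
#'
#' Accepts records of the form `>ID name` followed by four rows, either
#' bare numbers or `A [ 1 2 3 ]` style; counts or probabilities are
#' normalized per column.
#'
#' @param path path to the PFM file.
#' @return A list of [pwm()] objects, named by motif id.
#' @export
read_pfm <- function(path) {
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines)]
  heads <- grep("^>", lines)
  if (!length(heads)) stop("no PFM records (no '>' header) in ", path)
  out <- list()
  bounds <- c(heads, length(lines) + 1L)
  for (k in seq_along(heads)) {
    id <- sub("^>\\s*", "", lines[heads[k]])
    id <- strsplit(id, "\\s+")[[1]][1]
    body <- lines[(heads[k] + 1L):(bounds[k + 1L] - 1L)]
    if (length(body) < 4) stop("PFM record '", id, "' has fewer than 4 rows")
    rows <- lapply(body[1:4], function(ln) {
      ln <- sub("^[ACGTacgt]\\s*", "", ln)
      ln <- gsub("\\[|\\]", " ", ln)
      as.numeric(strsplit(trimws(ln), "\\s+")[[1]])
    })
    L <- unique(lengths(rows))
    if (length(L) != 1) stop("ragged PFM rows in record '", id, "'")
    out[[id]] <- pwm(do.call(rbind, rows), motif_id = id)
  }
  out
}

# 5 x L log2-odds score matrix (rows A,C,G,T,N; N row = 0)
pwm_score_matrix <- function(x) {
  p <- pmax(x$matrix, 1e-3)
  bg <- pmax(x$background, 1e-3)
  rbind(log2(p / bg), N = 0)
}

seq_to_idx <- function(s) {
  v <- strsplit(toupper(s), "")[[1]]
  i <- match(v, c(BASES, "N"))
  if (any(is.na(i))) stop("sequence contains non-ACGTN characters")
  i
}

REV_IDX <- c(4L, 3L, 2L, 1L, 5L)  # complement in index space

# best log2-odds over all offsets of idx vector (one strand)
scan_strand <- function(sm, idx) {
  L <- ncol(sm)
  n <- length(idx) - L + 1
  sc <- numeric(n)
  for (j in seq_len(L)) sc <- sc + sm[idx[j:(j + n - 1)], j]
  sc
}

#' Best PWM match in a sequence (both strands)
#'
#' Scores every offset on the forward strand and on the reverse complement
#' with additive log2-odds (floored probabilities; `N` bases contribute 0)
#' and returns the maximum.  Ties prefer the forward strand, then the
#' smallest 0-based position (position of the match start in the input
#' sequence's coordinates).
#'
#' @param x a [pwm()].
#' @param sequence DNA string over ACGTN, at least as long as the motif.
#' @return List with `score`, `position` (0-based), `strand`.
#' @export
scan_best <- function(x, sequence) {
  stopifnot(inherits(x, "pwm"))
  idx <- seq_to_idx(sequence)
  L <- ncol(x$matrix)
  if (length(idx) < L) stop("sequence shorter than the motif")
  sm <- pwm_score_matrix(x)
  fwd <- scan_strand(sm, idx)
  rev_ <- scan_strand(sm, REV_IDX[rev(idx)])
  n <- length(fwd)
  best_f <- max(fwd); best_r <- max(rev_)
  if (best_f >= best_r) {
    list(score = unname(best_f), position = as.integer(which.max(fwd)) - 1L,
         strand = "+")
  } else {
    # offset o (1-based) in the reverse-complement maps back to start
    # n - o in 0-based original coordinates
    o <- which.max(rev_)
    list(score = unname(best_r), position = as.integer(n - o),
         strand = "-")
  }
}

#' Best-match scores for many sequences
#' @param x a [pwm()].
#' @param sequences character vector of DNA strings.
#' @return Numeric vector of best log2-odds scores.
#' @export
scan_best_scores <- function(x, sequences) {
  vapply(sequences, function(s) scan_best(x, s)$score, 0, USE.NAMES = FALSE)
}

#' Motif occurrence enrichment between two sequence sets
#'
#' A sequence contains the motif when its best score is at least
#' `score_min`.  Enrichment of foreground hits given the pooled hits is
#' tested with the hypergeometric upper tail.
#'
#' @param fg,bg character vectors of foreground/background sequences
#'   (both non-empty).
#' @param x a [pwm()].
#' @param score_min log2-odds threshold (finite).
#' @return List with `fg_frac`, `bg_frac`, `p`.
#' @export
occurrence_enrichment <- function(fg, bg, x, score_min) {
  if (!length(fg) || !length(bg)) stop("both sequence sets must be non-empty")
  if (!is.finite(score_min)) stop("score_min must be finite")
  fh <- sum(scan_best_scores(x, fg) >= score_min)
  bh <- sum(scan_best_scores(x, bg) >= score_min)
  K <- fh + bh
  N <- length(fg) + length(bg)
  p <- stats::phyper(fh - 1, K, N - K, length(fg), lower.tail = FALSE)
  list(fg_frac = fh / length(fg), bg_frac = bh / length(bg), p = p)
}

#' Compare motif strength across sequence sets
#'
#' Motif strength of a sequence is its best-hit log2-odds score.  Reports
#' per-set score quartiles and two-sided Wilcoxon rank-sum p-values for
#' every pair of sets.
#'
#' @param sets named list of character vectors of sequences (each of
#'   length >= 2).
#' @param x a [pwm()].
#' @return List with `summary` (per-set n, quartiles) and `pairwise`
#'   (data frame `set_a`, `set_b`, `p`).
#' @export
strength_comparison <- function(sets, x) {
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be a named list")
  if (any(lengths(sets) < 2)) stop("each set needs at least 2 sequences")
  scores <- lapply(sets, function(s) scan_best_scores(x, s))
  qs <- c(0, 0.25, 0.5, 0.75, 1)
  summary <- data.frame(set = names(sets), n = lengths(sets),
                        t(vapply(scores, stats::quantile, numeric(5), probs = qs)),
                        row.names = NULL, check.names = FALSE)
  names(summary)[3:7] <- c("min", "q25", "median", "q75", "max")
  cmb <- utils::combn(names(sets), 2)
  pairwise <- data.frame(set_a = cmb[1, ], set_b = cmb[2, ],
                         p = apply(cmb, 2, function(ab) {
                           suppressWarnings(stats::wilcox.test(
                             scores[[ab[1]]], scores[[ab[2]]])$p.value)
                         }), stringsAsFactors = FALSE)
  list(summary = summary, pairwise = pairwise)
}

#' Read sequences from a FASTA file
#' @param path FASTA path.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(x), names(x))
}

#' Write sequences to a FASTA file
#' @param sequences named character vector of sequences.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(sequences)), path, width = 80)
  invisible(path)
}
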