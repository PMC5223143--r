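# Genomic-interval data model and operations.
#
# Coordinates are 0-based half-open throughout ([start, end), BED convention);
# sequencing tags are single-bp 5' positions.  Strand is carried but ignored
# by all counting operations.

#' Construct a set of genomic intervals
#'
#' A `region_set` is a data frame with columns `chrom`, `start`, `end`,
#' `id`, `score`, `strand`, using 0-based half-open coordinates.  Ids must
#' be unique within the set; when omitted they are generated as
#' `"<chrom>:<start>-<end>"` (made unique if coordinates repeat).
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors, 0-based half-open (`start < end`).
#' @param id optional character vector of unique region ids.
#' @param strand optional vector in `{"+", "-", "."}`; default `"."`.
#' @param score optional numeric vector (BED score column); default 0.
#' @param name name of the set (carried as an attribute).
#' @return A `region_set` data frame.
#' @export
region_set <- function(chrom, start, end, id = NULL, strand = NULL,
                       score = NULL, name = "regions") {
  start <- as.numeric(start)
  end <- as.numeric(end)
  n <- length(start)
  chrom <- as.character(chrom)
  if (length(chrom) == 1) chrom <- rep(chrom, n)
  if (length(chrom) != n || length(end) != n)
    stop("chrom, start, end must have equal length")
  if (n > 0) {
    if (any(is.na(chrom)) || any(!nzchar(chrom)))
      stop("chrom must be non-empty strings")
    if (any(is.na(start)) || any(is.na(end)) ||
        any(start != floor(start)) || any(end != floor(end)))
      stop("start/end must be integers")
    if (any(start < 0)) stop("start must be >= 0")
    if (any(start >= end)) stop("invalid interval: start >= end")
  }
  if (is.null(strand)) strand <- rep(".", n)
  strand <- as.character(strand)
  if (n > 0 && !all(strand %in% c("+", "-", ".")))
    stop("strand must be one of '+', '-', '.'")
  if (is.null(score)) score <- rep(0, n)
  if (is.null(id)) {
    id <- make.unique(sprintf("%s:%d-%d", chrom, as.integer(start),
                              as.integer(end)), sep = "_")
  } else {
    id <- as.character(id)
    if (anyDuplicated(id)) stop("region ids must be unique within a set")
  }
  out <- data.frame(chrom = chrom, start = start, end = end, id = id,
                    score = as.numeric(score), strand = strand,
                    stringsAsFactors = FALSE)
  attr(out, "set_name") <- name
  class(out) <- c("region_set", "data.frame")
  out
}

#' @export
print.region_set <- function(x, ...) {
  cat(sprintf("region_set '%s': %d regions on %d chromosome(s)\n",
              attr(x, "set_name") %||% "regions", nrow(x),
              length(unique(x$chrom))))
  if (nrow(x) > 0) print.data.frame(utils::head(as.data.frame(x), 6))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a BED3/BED6 file into a region set
#'
#' Tab-separated, no header.  Columns beyond the first three are optional:
#' column 4 becomes the id (auto-generated when absent), column 5 the score,
#' column 6 the strand (`"."` when absent).  Malformed lines (fewer than 3
#' columns, non-integer coordinates, `start >= end`) raise an error naming
#' the offending line number.
#'
#' @param path path to a BED file.
#' @param name name for the resulting set (default: file base name).
#' @return A [region_set()].
#' @export
read_bed <- function(path, name = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0)
    return(region_set(character(), integer(), integer(),
                      name = name %||% basename(path)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  bad <- which(ncol < 3)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: fewer than 3 columns",
                 lineno[bad[1]]))
  chrom <- vapply(fields, `[[`, "", 1L)
  s_raw <- vapply(fields, `[[`, "", 2L)
  e_raw <- vapply(fields, `[[`, "", 3L)
  start <- suppressWarnings(as.numeric(s_raw))
  end <- suppressWarnings(as.numeric(e_raw))
  bad <- which(is.na(start) | is.na(end) |
               start != floor(start) | end != floor(end))
  if (length(bad))
    stop(sprintf("BED parse error at line %d: non-integer coordinates",
                 lineno[bad[1]]))
  bad <- which(start < 0 | start >= end)
  if (length(bad))
    stop(sprintf("BED parse error at line %d: invalid interval %s:%s-%s",
                 lineno[bad[1]], chrom[bad[1]], s_raw[bad[1]], e_raw[bad[1]]))
  id <- ifelse(ncol >= 4, vapply(fields, function(f) f[min(4, length(f))], ""),
               NA_character_)
  id <- ifelse(is.na(id) | !nzchar(id),
               sprintf("%s:%d-%d", chrom, as.integer(start), as.integer(end)),
               id)
  score <- ifelse(ncol >= 5,
                  suppressWarnings(as.numeric(
                    vapply(fields, function(f) f[min(5, length(f))], ""))), 0)
  score[is.na(score)] <- 0
  strand <- ifelse(ncol >= 6, vapply(fields, function(f) f[min(6, length(f))], ""),
                   ".")
  strand[!strand %in% c("+", "-", ".")] <- "."
  region_set(chrom, start, end, id = make.unique(id, sep = "_"),
             strand = strand, score = score, name = name %||% basename(path))
}

#' Write a region set as BED6
#'
#' @param x a [region_set()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_bed <- function(x, path) {
  stopifnot(inherits(x, "region_set"))
  df <- data.frame(x$chrom, as.integer(x$start), as.integer(x$end),
                   x$id, x$score, x$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Construct a tag track
#'
#' A tag track is the multiset of single-bp 5' tag positions for one
#' sequencing library.
#'
#' @param chrom character vector of chromosome names, one per tag.
#' @param pos integer vector of 0-based tag positions.
#' @param sample_id library identifier.
#' @return A `tag_track` object (list with `sample_id`, `chrom`, `pos`,
#'   `total`).
#' @export
tag_track <- function(chrom, pos, sample_id = "sample") {
  chrom <- as.character(chrom)
  pos <- as.numeric(pos)
  if (length(chrom) != length(pos)) stop("chrom and pos lengths differ")
  if (length(pos) && (any(is.na(pos)) || any(pos < 0) ||
                      any(pos != floor(pos))))
    stop("tag positions must be non-negative integers")
  structure(list(sample_id = sample_id, chrom = chrom, pos = pos,
                 total = length(pos)),
            class = "tag_track")
}

#' @export
print.tag_track <- function(x, ...) {
  cat(sprintf("tag_track '%s': %d tags on %d chromosome(s)\n",
              x$sample_id, x$total, length(unique(x$chrom))))
  invisible(x)
}

#' Read tag positions from a BED file of 1-bp intervals
#'
#' @param path BED file whose intervals are single base pairs (the interval
#'   start is taken as the tag position).
#' @param sample_id library identifier (default: file base name).
#' @return A [tag_track()].
#' @export
read_tag_bed <- function(path, sample_id = NULL) {
  rs <- read_bed(path)
  tag_track(rs$chrom, rs$start, sample_id %||% basename(path))
}

#' Write a tag track as a BED file of 1-bp intervals
#' @param x a [tag_track()].
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_tag_bed <- function(x, path) {
  stopifnot(inherits(x, "tag_track"))
  df <- data.frame(x$chrom, as.integer(x$pos), as.integer(x$pos) + 1L)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Count tags falling in each region
#'
#' A tag at position `p` is counted in region `[start, end)` when
#' `start <= p < end` on the same chromosome; a tag overlapping several
#' regions contributes to all of them.
#'
#' @param track a [tag_track()].
#' @param regions a [region_set()].
#' @return Integer vector of counts, one per region in region order.
#' @export
count_tags_in_regions <- function(track, regions) {
  stopifnot(inherits(track, "tag_track"), inherits(regions, "region_set"))
  out <- integer(nrow(regions))
  if (nrow(regions) == 0 || track$total == 0) return(out)
  for (chr in unique(regions$chrom)) {
    ri <- which(regions$chrom == chr)
    p <- sort(track$pos[track$chrom == chr])
    if (!length(p)) next
    # tags < end minus tags < start; positions are integral so -0.5 gives
    # the strict/inclusive bounds wanted by the half-open convention
    out[ri] <- findInterval(regions$end[ri] - 0.5, p) -
      findInterval(regions$start[ri] - 0.5, p)
  }
  out
}

#' Call peaks by a sliding-window Poisson scan
#'
#' Windows of `window_bp` advance by half a window along each chromosome.
#' Each window's tag count is tested against a genome-wide uniform Poisson
#' background (rate = total tags / effective span, where the span is the
#' sum over chromosomes of the maximal tag coordinate + 1).  Windows with
#' Benjamini-Hochberg FDR below `fdr` and at least `min_density` tags are
#' kept; overlapping or book-ended kept windows are merged into maximal
#' regions whose score is the maximal single-window count.
#'
#' @param track a [tag_track()]; must contain at least one tag.
#' @param window_bp window width in bp (> 0).
#' @param fdr FDR threshold on the window-level Poisson p-values.
#' @param min_density minimal tag count per window (> 0).
#' @return A [region_set()] of merged peaks (score = max window tag count).
#' @export
call_peaks <- function(track, window_bp = 200, fdr = 0.001,
                       min_density = 35) {
  stopifnot(inherits(track, "tag_track"))
  if (track$total == 0) stop("tag track is empty")
  if (window_bp <= 0) stop("window_bp must be > 0")
  if (min_density <= 0) stop("min_density must be > 0")
  step <- window_bp / 2
  chroms <- unique(track$chrom)
  span <- 0
  per_chr <- list()
  for (chr in chroms) {
    p <- track$pos[track$chrom == chr]
    span <- span + max(p) + 1
    per_chr[[chr]] <- p
  }
  lambda <- track$total / span * window_bp
  win <- list()
  for (chr in chroms) {
    p <- per_chr[[chr]]
    nwin <- max(1L, ceiling((max(p) + 1) / step))
    k1 <- floor(p / step)                      # window index holding p as 1st half
    tab <- tabulate(k1 + 1L, nbins = nwin + 1L)
    cnt <- tab[seq_len(nwin)] + tab[seq_len(nwin) + 1L]
    win[[chr]] <- data.frame(chrom = chr,
                             start = (seq_len(nwin) - 1) * step,
                             count = cnt)
  }
  win <- do.call(rbind, win)
  pval <- stats::ppois(win$count - 1, lambda, lower.tail = FALSE)
  q <- bh_fdr(pval)
  keep <- which(q < fdr & win$count >= min_density)
  if (!length(keep))
    return(region_set(character(), integer(), integer(), name = "peaks"))
  kept <- win[keep, , drop = FALSE]
  kept <- kept[order(kept$chrom, kept$start), , drop = FALSE]
  # merge overlapping/book-ended windows per chromosome
  starts <- ends <- scores <- numeric(0)
  chr_out <- character(0)
  cs <- kept$start[1]; ce <- kept$start[1] + window_bp
  csc <- kept$count[1]; cchr <- kept$chrom[1]
  flush <- function() {
    chr_out <<- c(chr_out, cchr); starts <<- c(starts, cs)
    ends <<- c(ends, ce); scores <<- c(scores, csc)
  }
  if (nrow(kept) > 1) {
    for (i in 2:nrow(kept)) {
      if (kept$chrom[i] == cchr && kept$start[i] <= ce) {
        ce <- max(ce, kept$start[i] + window_bp)
        csc <- max(csc, kept$count[i])
      } else {
        flush()
        cs <- kept$start[i]; ce <- cs + window_bp
        csc <- kept$count[i]; cchr <- kept$chrom[i]
      }
    }
  }
  flush()
  region_set(chr_out, starts, ends,
             id = sprintf("peak_%d", seq_along(starts)),
             score = scores, name = "peaks")
}

# all (a_idx, b_idx) pairs with >= 1 bp overlap, per chromosome
overlap_pairs <- function(a, b) {
  ai <- integer(0); bi <- integer(0)
  for (chr in intersect(unique(a$chrom), unique(b$chrom))) {
    ia <- which(a$chrom == chr)
    ib <- which(b$chrom == chr)
    bs <- b$start[ib]; be <- b$end[ib]
    for (i in ia) {
      hit <- which(bs < a$end[i] & be > a$start[i])
      if (length(hit)) {
        ai <- c(ai, rep(i, length(hit)))
        bi <- c(bi, ib[hit])
      }
    }
  }
  data.frame(a_idx = ai, b_idx = bi)
}

#' Replicate-concordant regions
#'
#' Returns the regions of `a` that overlap (by at least 1 bp) some region
#' of `b`, with each returned interval widened to the union span of the
#' `a` region and all of its `b` overlaps.  Ids and strands come from `a`.
#'
#' @param a,b [region_set()] objects.
#' @return A [region_set()].
#' @export
concordant_regions <- function(a, b) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  pr <- overlap_pairs(a, b)
  if (!nrow(pr))
    return(region_set(character(), integer(), integer(), name = "concordant"))
  idx <- sort(unique(pr$a_idx))
  st <- a$start[idx]; en <- a$end[idx]
  for (k in seq_along(idx)) {
    bm <- pr$b_idx[pr$a_idx == idx[k]]
    st[k] <- min(st[k], b$start[bm])
    en[k] <- max(en[k], b$end[bm])
  }
  region_set(a$chrom[idx], st, en, id = a$id[idx], strand = a$strand[idx],
             score = a$score[idx], name = "concordant")
}

#' Partition two region sets by coordinate overlap
#'
#' Classifies regions into those unique to `a`, unique to `b`, and the
#' overlapping pairs (>= 1 bp).  A region overlapping several partners is
#' counted once on its own side, so
#' `length(a_only) + length(unique(shared$a_id)) == nrow(a)`.
#'
#' @param a,b [region_set()] objects.
#' @return A list with `a_only` and `b_only` (character id vectors),
#'   `shared` (data frame of `a_id`, `b_id` pairs) and `counts` (named
#'   integer vector `a_only`, `b_only`, `shared_a`, `shared_b`).
#' @export
overlap_classes <- function(a, b) {
  stopifnot(inherits(a, "region_set"), inherits(b, "region_set"))
  pr <- overlap_pairs(a, b)
  shared <- data.frame(a_id = a$id[pr$a_idx], b_id = b$id[pr$b_idx],
                       stringsAsFactors = FALSE)
  a_only <- setdiff(a$id, shared$a_id)
  b_only <- setdiff(b$id, shared$b_id)
  list(a_only = a_only, b_only = b_only, shared = shared,
       counts = c(a_only = length(a_only), b_only = length(b_only),
                  shared_a = length(unique(shared$a_id)),
                  shared_b = length(unique(shared$b_id))))
}

# total union span in bp of a region set
total_span <- function(x) {
  stopifnot(inherits(x, "region_set"))
  if (!nrow(x)) return(0)
  tot <- 0
  for (chr in unique(x$chrom)) {
    xi <- x[x$chrom == chr, , drop = FALSE]
    o <- order(xi$start)
    st <- xi$start[o]; en <- xi$end[o]
    cs <- st[1]; ce <- en[1]
    for (i in seq_along(st)[-1]) {
      if (st[i] <= ce) ce <- max(ce, en[i])
      else { tot <- tot + ce - cs; cs <- st[i]; ce <- en[i] }
    }
    tot <- tot + ce - cs
  }
  tot
}
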