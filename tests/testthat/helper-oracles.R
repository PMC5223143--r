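# Brute-force oracles and small fixture builders used across tests.

# O(N*M) tag-in-region counting by direct membership
brute_count_tags <- function(track, regions) {
  vapply(seq_len(nrow(regions)), function(i) {
    sum(track$chrom == regions$chrom[i] &
          track$pos >= regions$start[i] & track$pos < regions$end[i])
  }, 0L)
}

# all overlapping (a_idx, b_idx) pairs by double loop
brute_pairs <- function(a, b) {
  out <- NULL
  for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
    if (a$chrom[i] == b$chrom[j] &&
        a$start[i] < b$end[j] && b$start[j] < a$end[i])
      out <- rbind(out, c(i, j))
  }
  out
}

# literal BH definition on the sorted order
brute_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q <- numeric(m)
  for (r in seq_len(m)) {
    q[o[r]] <- min(p[o[r:m]] * m / (r:m), 1)
  }
  q
}

# random region set on a couple of chromosomes
random_regions <- function(n, chroms = c("chr1", "chr2"), span = 1e4) {
  chrom <- sample(chroms, n, replace = TRUE)
  start <- sample.int(span, n, replace = TRUE) - 1L
  width <- sample.int(200, n, replace = TRUE)
  region_set(chrom, start, start + width, id = sprintf("r%d", seq_len(n)))
}

random_track <- function(n, chroms = c("chr1", "chr2"), span = 1e4) {
  tag_track(sample(chroms, n, replace = TRUE),
            sample.int(span + 200, n, replace = TRUE) - 1L, "rnd")
}

# NB count matrix with optional planted fold change in the test group
nb_matrix <- function(n, mu, alpha, n_ref = 3, n_test = 3, fold = 1) {
  mu_mat <- cbind(matrix(rep(mu, n_ref), n),
                  matrix(rep(mu * fold, n_test), n))
  k <- matrix(stats::rnbinom(length(mu_mat), mu = mu_mat, size = 1 / alpha),
              nrow = n)
  count_matrix(k, rep(c("Chow", "HFD"), c(n_ref, n_test)))
}

# deterministic draws used by the acceptance tests
local_seed_sample <- function(x, n, seed) {
  set.seed(seed)
  sample(x, n)
}

local_seed_track <- function(n, span, seed) {
  set.seed(seed)
  tag_track(rep("chr1", n), floor(stats::runif(n, 0, span)), "u")
}
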