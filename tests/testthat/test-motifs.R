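# PWM construction, scanning, occurrence enrichment, strength comparison.

test_that("PWM scanning reproduces hand-computed log-odds", {
  # uniform PWM scores 0 everywhere
  uni <- pwm(matrix(0.25, 4, 3))
  expect_equal(scan_best(uni, "ACGTACGT")$score, 0)
  # strongly A-preferring 2-column PWM on "CAAT": best 2*log2(0.97/0.25)
  pa <- pwm(matrix(c(0.97, 0.01, 0.01, 0.01,
                     0.97, 0.01, 0.01, 0.01), 4, 2))
  hit <- scan_best(pa, "CAAT")
  expect_equal(hit$score, 2 * log2(0.97 / 0.25), tolerance = 1e-9)
  expect_equal(hit$position, 1)
  expect_equal(hit$strand, "+")
  # all-N scores 0 (background contribution)
  expect_equal(scan_best(pa, "NNNN")$score, 0)
  expect_error(scan_best(pa, "A"), "shorter")
  expect_error(scan_best(pa, "AXTT"), "non-ACGTN")
})

test_that("scanning is strand-symmetric and consensus-maximal", {
  set.seed(151)
  mot <- default_pwm()
  revcomp <- function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
  }
  cons <- paste(c("A", "C", "G", "T")[apply(mot$matrix, 2, which.max)],
                collapse = "")
  for (rep in 1:20) {
    s <- paste(sample(c("A", "C", "G", "T"), 60, replace = TRUE),
               collapse = "")
    expect_equal(scan_best(mot, revcomp(s))$score, scan_best(mot, s)$score)
    # a sequence equal to the consensus scores at least as high as any other
    expect_lte(scan_best(mot, s)$score, scan_best(mot, cons)$score)
  }
  # reverse-strand hits are found and mapped back to forward coordinates
  planted <- paste0("TTTT", revcomp(cons), "TT")
  hit <- scan_best(mot, planted)
  expect_equal(hit$strand, "-")
  expect_equal(hit$position, 4)
  expect_equal(hit$score, scan_best(mot, cons)$score)
})

test_that("JASPAR-style PFM files parse in both layouts", {
  f <- withr::local_tempfile(fileext = ".pfm")
  writeLines(c(">M1 demo",
               "A [ 8 0 0 ]",
               "C [ 0 8 0 ]",
               "G [ 0 0 8 ]",
               "T [ 0 0 0 ]",
               ">M2",
               "1 0", "0 1", "0 0", "0 0"), f)
  ms <- read_pfm(f)
  expect_named(ms, c("M1", "M2"))
  expect_equal(ms$M1$matrix[, 1], c(A = 1, C = 0, G = 0, T = 0))
  expect_equal(ncol(ms$M2$matrix), 2)
  writeLines("no header", f)
  expect_error(read_pfm(f), "header")
})

test_that("occurrence enrichment behaves at the boundaries and under planting", {
  set.seed(161)
  mot <- default_pwm()
  cons <- paste(c("A", "C", "G", "T")[apply(mot$matrix, 2, which.max)],
                collapse = "")
  rseq <- function(n, len = 100) {
    vapply(seq_len(n), function(i)
      paste(sample(c("A", "C", "G", "T"), len, TRUE), collapse = ""), "")
  }
  plant <- function(s) {
    substr(s, 40, 39 + nchar(cons)) <- cons
    s
  }
  # identical sets: no enrichment
  same <- rseq(30)
  expect_gte(occurrence_enrichment(same, same, mot, 10)$p, 0.5)
  # nothing passes an absurd threshold
  oc0 <- occurrence_enrichment(rseq(20), rseq(20), mot, 1e6)
  expect_equal(oc0$fg_frac, 0)
  expect_equal(oc0$bg_frac, 0)
  expect_equal(oc0$p, 1)
  expect_error(occurrence_enrichment(rseq(5), rseq(5), mot, Inf), "finite")
  expect_error(occurrence_enrichment(character(), rseq(5), mot, 1),
               "non-empty")
  # planted: 80% of fg vs 5% of bg
  fg <- rseq(100); bg <- rseq(1000)
  fg[1:80] <- vapply(fg[1:80], plant, "")
  bg[1:50] <- vapply(bg[1:50], plant, "")
  oc <- occurrence_enrichment(fg, bg, mot, 10)
  expect_lt(oc$p, 1e-10)
  expect_gte(oc$fg_frac, 0.8)
})

test_that("strength comparison separates planted from random sets", {
  set.seed(171)
  mot <- default_pwm()
  cons <- paste(c("A", "C", "G", "T")[apply(mot$matrix, 2, which.max)],
                collapse = "")
  rseq <- function(n) vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), 100, TRUE), collapse = ""), "")
  planted <- vapply(rseq(50), function(s) {
    substr(s, 30, 29 + nchar(cons)) <- cons; s
  }, "", USE.NAMES = FALSE)
  rand1 <- rseq(50); rand2 <- rseq(50)
  sc <- strength_comparison(list(planted = planted, random = rand1,
                                 other = rand2), mot)
  expect_equal(nrow(sc$pairwise), 3)  # three sets -> three comparisons
  p_pr <- sc$pairwise$p[sc$pairwise$set_a == "planted" &
                          sc$pairwise$set_b == "random"]
  expect_lt(p_pr, 0.01)
  p_rr <- sc$pairwise$p[sc$pairwise$set_a == "random"]
  expect_gt(p_rr, 0.01)
  expect_gt(sc$summary$median[sc$summary$set == "planted"],
            sc$summary$median[sc$summary$set == "random"])
  # identical sets at n >= 20: p near 1
  sc2 <- strength_comparison(list(a = rand1, b = rand1), mot)
  expect_gt(sc2$pairwise$p, 0.9)
  expect_error(strength_comparison(list(a = rand1, b = rand1[1]), mot),
               "at least 2")
  expect_error(strength_comparison(list(rand1, rand1), mot), "named")
})

test_that("FASTA round-trip preserves sequences and names", {
  set.seed(181)
  seqs <- c(r1 = "ACGTACGTAC", r2 = "TTTTGGGGCC")
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(seqs, f)
  expect_equal(read_fasta(f), seqs)
})

test_that("the bundled PFM file matches the built-in planting motif", {
  f <- system.file("extdata", "dr1_synthetic.pfm", package = "enhancerFlux")
  ms <- read_pfm(f)
  expect_named(ms, "DR1_synthetic")
  expect_equal(ms$DR1_synthetic$matrix, default_pwm()$matrix,
               tolerance = 1e-12)
})
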