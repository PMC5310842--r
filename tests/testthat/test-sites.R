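test_that("window scoring sums per-position log-odds; N uses background", {
  m1 <- pssm_single()
  expect_equal(score_window("A", m1), 1.5)
  expect_equal(score_window("C", m1), -1)
  expect_equal(score_window("N", m1),
               sum(c(0.25, 0.25, 0.25, 0.25) * c(1.5, -1, -1, -1)))
  expect_error(score_window("AA", m1), "width")

  # 3-mer score equals independent per-position summation
  set.seed(3)
  m3 <- pssm(matrix(rnorm(12), 4, 3,
                    dimnames = list(c("A", "C", "G", "T"))))
  seq <- "ACG"
  manual <- sum(vapply(1:3, function(j)
    unclass(m3)[substr(seq, j, j), j], 0))
  expect_equal(score_window(seq, m3), manual)
})

test_that("scanning AAAA with an AA-favoring 2-mer finds starts 0,1,2", {
  m <- pssm_consensus("AA", match = 1, mismatch = -1)
  hits <- scan_pssm(c(chr1 = "AAAA"), m, min_score = 0)
  plus <- hits[hits$strand == "+", ]
  expect_equal(plus$start, c(0, 1, 2))
  expect_equal(plus$score, rep(2, 3))
  # minus-strand windows score the reverse complement (TT here): below 0
  expect_equal(nrow(hits[hits$strand == "-", ]), 0)
  # a threshold above the maximum yields nothing
  expect_equal(nrow(scan_pssm(c(chr1 = "AAAA"), m, min_score = 3)), 0)
})

test_that("scanning a sequence and its reverse complement mirror each other", {
  set.seed(11)
  seq <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
  m <- pssm_consensus("ACGTA")
  fwd <- scan_pssm(c(chr1 = seq), m, min_score = -20)
  rc <- scan_pssm(c(chr1 = cutrunr:::revcomp(seq)), m, min_score = -20)
  n <- nchar(seq)
  w <- ncol(m)
  # map rc hits back into the original frame with flipped strand
  mapped <- data.frame(start = n - rc$end,
                       strand = ifelse(rc$strand == "+", "-", "+"),
                       score = rc$score)
  mapped <- mapped[order(mapped$start, mapped$strand), ]
  orig <- fwd[order(fwd$start, fwd$strand), c("start", "strand", "score")]
  rownames(mapped) <- rownames(orig) <- NULL
  expect_equal(orig, mapped)
})

test_that("planted motifs are recovered exactly at a stringent threshold", {
  cfg <- small_cfg()
  g <- make_genome(cfg)
  m <- pssm_consensus(cfg$motif)
  max_score <- sum(apply(unclass(m), 2, max))
  hits <- scan_pssm(g$sequences, m, min_score = max_score - 1e-9)
  direct <- g$truth$sites[g$truth$sites$class == "direct", ]
  expect_equal(nrow(hits), nrow(direct))
  expect_equal(sort(hits$start), sort(direct$start))
  expect_equal(hits$strand[order(hits$start)],
               direct$strand[order(direct$start)])
})

test_that("best interval score matches an exhaustive window oracle", {
  set.seed(5)
  seq <- paste(sample(c("A", "C", "G", "T"), 600, TRUE), collapse = "")
  m <- pssm_consensus("ACGT")
  w <- ncol(m)
  oracle_best <- function(lo, hi) {
    best <- -Inf
    for (s in lo:(hi - w)) {
      sub <- substr(seq, s + 1, s + w)
      best <- max(best, score_window(sub, m),
                  score_window(cutrunr:::revcomp(sub), m))
    }
    best
  }
  res <- best_motif_score("chr1", 200, 260, c(chr1 = seq), m, extend = 100)
  expect_equal(res$score, oracle_best(100, 360))
  # extend = 0 on a width-sized interval degenerates to score_window
  res0 <- best_motif_score("chr1", 300, 304, c(chr1 = seq), m, extend = 0)
  sub <- substr(seq, 301, 304)
  expect_equal(res0$score,
               max(score_window(sub, m),
                   score_window(cutrunr:::revcomp(sub), m)))
  # clipping beyond the chromosome warns
  expect_warning(best_motif_score("chr1", 0, 10, c(chr1 = seq), m), "clip")
})

test_that("a planted motif inside the interval is the best match", {
  cfg <- small_cfg()
  g <- make_genome(cfg)
  m <- pssm_consensus(cfg$motif)
  direct <- g$truth$sites[g$truth$sites$class == "direct", ]
  s <- direct[1, ]
  res <- best_motif_score(s$chrom, s$start, s$end, g$sequences, m,
                          extend = 100)
  expect_equal(res$score, sum(apply(unclass(m), 2, max)))
  expect_equal(res$start, s$start)
  expect_equal(res$strand, s$strand)
})

test_that("cross-proximal removal is reciprocal and symmetric", {
  a <- data.frame(chrom = "chr1", start = c(96, 300), end = c(104, 308))
  b <- data.frame(chrom = "chr1", start = 126, end = 134)
  # centers: a at 100, 304; b at 130 -> |100-130| <= 50 removes both
  res <- remove_cross_proximal(a, b, dist = 50)
  expect_equal(res$a$start, 300)
  expect_equal(nrow(res$b), 0)
  # distance 100 > 50: everything retained
  far <- data.frame(chrom = "chr1", start = 196, end = 204)
  res2 <- remove_cross_proximal(a, far, dist = 50)
  expect_equal(nrow(res2$a), 2)
  expect_equal(nrow(res2$b), 1)
  # empty other list is the identity
  res3 <- remove_cross_proximal(a, b[0, ], dist = 50)
  expect_equal(res3$a, a)
  # symmetry in the two arguments
  swapped <- remove_cross_proximal(b, a, dist = 50)
  expect_equal(swapped$a, res$b)
  expect_equal(swapped$b, res$a)
})

test_that("site centers use start + floor(width/2)", {
  expect_equal(site_center(data.frame(start = 100, end = 107)), 103)
  expect_equal(site_center(data.frame(start = 100, end = 108)), 104)
  s <- data.frame(start = c(0, 10), end = c(5, 25))
  cen <- site_center(s)
  expect_true(all(cen >= s$start & cen < s$end))
})

test_that("JASPAR PFMs convert to finite log-odds with pseudocounts", {
  path <- tempfile()
  writeLines(c(">MA0000.1 TEST",
               "A [ 10  0  2 ]",
               "C [  0 10  2 ]",
               "G [  0  0  4 ]",
               "T [  0  0  2 ]"), path)
  m <- read_jaspar(path)
  expect_equal(ncol(m), 3)
  expect_true(all(is.finite(unclass(m))))
  # the dominant base scores highest in each column
  expect_equal(unname(apply(unclass(m), 2, which.max)), c(1, 2, 3))
  # zero counts stay finite because of the pseudocount
  expect_true(unclass(m)["T", 1] < 0)
  # BED6 round trip for the site list it produces
  sites <- scan_pssm(c(chr1 = "AACAGACG"), m, min_score = 0)
  p2 <- tempfile()
  write_bed6(sites, p2)
  back <- read_bed6(p2)
  expect_equal(back$start, sites$start)
  expect_equal(back$strand, sites$strand)
})
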