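test_that("direct/indirect classification is an exhaustive partition", {
  cr <- data.frame(chrom = "chr1", start = c(100, 500, 900),
                   end = c(200, 600, 1000), score = c(5, 3, 1))
  native <- data.frame(chrom = "chr1", start = 150, end = 250)
  cls <- classify_sites(cr, native)
  expect_equal(cls$direct$start, 100)
  expect_equal(cls$indirect$start, c(500, 900))
  expect_equal(nrow(cls$direct) + nrow(cls$indirect), nrow(cr))
  # slop 400 pulls the 500-peak within reach of the native peak
  cls2 <- classify_sites(cr, native, slop = 400)
  expect_equal(cls2$direct$start, c(100, 500))
  # no native peaks: everything indirect
  cls3 <- classify_sites(cr, native[0, ])
  expect_equal(nrow(cls3$direct), 0)
  expect_equal(nrow(cls3$indirect), 3)
  # empty input: empty output, still a partition
  cls4 <- classify_sites(cr[0, ], native)
  expect_equal(nrow(cls4$direct) + nrow(cls4$indirect), 0)
})

test_that("classification partition property holds on random intervals", {
  set.seed(31)
  n <- 200
  s <- sort(sample.int(50000, n))
  cr <- data.frame(chrom = "chr1", start = s, end = s + 100)
  ns <- sample.int(50000, 40)
  native <- data.frame(chrom = "chr1", start = ns, end = ns + 80)
  cls <- classify_sites(cr, native)
  expect_equal(nrow(cls$direct) + nrow(cls$indirect), n)
  # no interval appears in both lists
  key <- function(d) paste(d$chrom, d$start, d$end)
  expect_length(intersect(key(cls$direct), key(cls$indirect)), 0)
})

test_that("anchor categories are symmetric and use direct precedence", {
  cls <- structure(list(
    direct = data.frame(chrom = "chr1", start = 100, end = 200),
    indirect = data.frame(chrom = "chr1", start = 500, end = 600)),
    class = "classified_sites")
  pairs <- data.frame(
    chrom1 = "chr1", start1 = c(120, 520, 120, 900),
    end1 = c(180, 580, 180, 950),
    chrom2 = "chr1", start2 = c(520, 120, 900, 950),
    end2 = c(580, 180, 950, 990),
    score = 1:4)
  ann <- anchor_intersect(pairs, cls)
  expect_equal(ann$category,
               c("direct-indirect", "direct-indirect",
                 "direct-none", "uncategorized"))
  # swapped anchors give the same category
  expect_equal(ann$category[1], ann$category[2])
  expect_equal(ann$indirect_idx[1:2], c(1L, 1L))
  expect_true(is.na(ann$indirect_idx[3]))
  # an anchor overlapping both sets counts as direct
  both <- data.frame(chrom1 = "chr1", start1 = 100, end1 = 600,
                     chrom2 = "chr1", start2 = 520, end2 = 580, score = 1)
  expect_equal(anchor_intersect(both, cls)$classA, "direct")
})

test_that("random controls are reproducible, matched, and in bounds", {
  cs <- chrom_sizes(c(chr1 = 10000, chr2 = 4000))
  sites <- data.frame(chrom = "chr1", start = c(10, 300, 800),
                      end = c(110, 450, 900))
  a <- random_site_control(sites, cs, seed = 99)
  b <- random_site_control(sites, cs, seed = 99)
  expect_identical(a, b)
  c2 <- random_site_control(sites, cs, seed = 100)
  expect_false(identical(a, c2))
  expect_equal(sort(a$end - a$start), sort(sites$end - sites$start))
  lens <- stats::setNames(as.numeric(cs), names(cs))
  expect_true(all(a$start >= 0 & a$end <= lens[a$chrom]))
  # the global RNG stream is untouched
  set.seed(7); before <- rnorm(1)
  set.seed(7); invisible(random_site_control(sites, cs, seed = 1))
  expect_identical(rnorm(1), before)
})

test_that("moving averages are truncated means; big windows go global", {
  cls <- structure(list(
    direct = data.frame(chrom = "chr1", start = 100, end = 200),
    indirect = data.frame(chrom = "chr1",
                          start = c(500, 900, 1300),
                          end = c(600, 1000, 1400))),
    class = "classified_sites")
  pairs <- data.frame(chrom1 = "chr1", start1 = 120, end1 = 180,
                      chrom2 = "chr1",
                      start2 = c(520, 920, 1320),
                      end2 = c(580, 980, 1380),
                      score = c(9, 4, 1))
  ann <- anchor_intersect(pairs, cls)
  site_scores <- c(30, 20, 10)  # one per indirect peak row
  expect_warning(res <- score_contact_association(ann, site_scores,
                                                  window = 1500),
                 "shrinking")
  # window >= n collapses both curves to their global means
  expect_equal(res$cutrun_ma, rep(mean(site_scores), 3))
  expect_equal(res$contact_ma, rep(mean(pairs$score), 3))
  # ranking is by indirect cleavage score, descending
  expect_equal(res$cutrun_score, c(30, 20, 10))
  expect_equal(res$contact_score, c(9, 4, 1))
  # window 1: the MA is the identity
  res1 <- score_contact_association(ann, site_scores, window = 1)
  expect_equal(res1$contact_ma, res1$contact_score)
  # no qualifying pairs is an error
  none <- ann; none$category <- "uncategorized"
  expect_error(score_contact_association(none, site_scores), "no direct")
})

test_that("simulated contacts link indirect cleavage to contact score", {
  cfg <- sim_config(seed = 5, n_direct_sites = 60, n_indirect_sites = 40,
                    n_centromeres = 4)
  sim <- simulate_cutrun(cfg)
  t <- normalize_spikein(coverage_track(sim$fragments),
                         length(sim$spike))
  # match the peak count to the number of bound sites so indirect sites
  # are recovered too (the default 99.5th percentile keeps only the
  # strongest sites on this site-dense simulated genome)
  p <- suppressWarnings(threshold_for_peak_count(
    t, nrow(sim$truth$sites)))
  pk <- call_peaks(t, percentile = as.numeric(p))
  direct_truth <- sim$truth$sites[sim$truth$sites$class == "direct",
                                  c("chrom", "start", "end")]
  cls <- classify_sites(pk, direct_truth, slop = 100)
  expect_gt(nrow(cls$direct), 0)
  expect_gt(nrow(cls$indirect), 0)
  ann <- anchor_intersect(sim$truth$contacts, cls)
  expect_true("direct-indirect" %in% ann$category)
  res <- suppressWarnings(score_contact_association(
    ann, cls$indirect$score, window = 11))
  # both curves decline from the first to the last third of the ranking
  n <- nrow(res)
  third <- max(1, n %/% 3)
  expect_gt(mean(res$cutrun_ma[seq_len(third)]),
            mean(res$cutrun_ma[(n - third + 1):n]))
  expect_gt(mean(res$contact_ma[seq_len(third)]),
            mean(res$contact_ma[(n - third + 1):n]))
  # a width-matched random control categorizes far fewer pairs
  rand <- random_site_control(cls$indirect, sim$chrom_sizes, seed = 1)
  rand$score <- cls$indirect$score
  cls_rand <- structure(list(direct = cls$direct, indirect = rand),
                        class = "classified_sites")
  ann_rand <- anchor_intersect(sim$truth$contacts, cls_rand)
  expect_lt(sum(ann_rand$category == "direct-indirect"),
            sum(ann$category == "direct-indirect") / 2)
})

test_that("BEDPE reading maps columns and honors the score filter", {
  path <- tempfile(fileext = ".bedpe")
  writeLines(c("chr1\t10\t20\tchr2\t30\t40\t5.5",
               "chr1\t50\t60\tchr1\t70\t80\t1.0"), path)
  pairs <- read_bedpe(path)
  expect_equal(nrow(pairs), 2)
  expect_equal(pairs$chrom2[1], "chr2")
  expect_equal(pairs$score, c(5.5, 1.0))
  expect_equal(nrow(read_bedpe(path, min_score = 2)), 1)
  # 6-column files get score 0
  p2 <- tempfile()
  writeLines("chr1\t10\t20\tchr2\t30\t40", p2)
  expect_equal(read_bedpe(p2)$score, 0)
  p3 <- tempfile()
  writeLines("chr1\t10\t20", p3)
  expect_error(read_bedpe(p3), "6 columns")
})
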