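test_that("site matrix centers, orients, and drops edge sites", {
  t <- toy_track(c("100" = 5), len = 400)
  plus <- data.frame(chrom = "chr1", start = 96, end = 104, strand = "+")
  m <- site_matrix(t, plus, flank = 50)
  expect_equal(dim(m), c(1, 100))
  expect_equal(unname(m[1, attr(m, "positions") == 0]), 5)

  # minus-strand site with spike at center+5 shows it at relative -5
  t2 <- toy_track(c("100" = 1, "105" = 9), len = 400)
  minus <- data.frame(chrom = "chr1", start = 96, end = 104, strand = "-")
  m2 <- site_matrix(t2, minus, flank = 50)
  expect_equal(unname(m2[1, attr(m2, "positions") == -5]), 9)
  expect_equal(unname(m2[1, attr(m2, "positions") == 0]), 1)

  # a site too close to the chromosome start is dropped and counted
  both <- rbind(plus, data.frame(chrom = "chr1", start = 6, end = 14,
                                 strand = "+"))
  m3 <- site_matrix(t, both, flank = 50)
  expect_equal(nrow(m3), 1)
  expect_equal(attr(m3, "dropped"), 1)
  expect_error(site_matrix(t, both[2, , drop = FALSE], flank = 50),
               "no site")
})

profile_at_range <- function(p, lo, hi) {
  sel <- p$positions >= lo & p$positions <= hi
  stats::setNames(p$values[sel], p$positions[sel])
}

test_that("mirroring the genome and flipping strands leaves means intact", {
  cfg <- small_cfg()
  sim <- simulate_cutrun(cfg)
  len <- as.integer(sim$chrom_sizes[[1]])
  ends <- end_density_track(sim$fragments)
  truth <- sim$truth$sites[sim$truth$sites$class == "direct", ]
  # odd-width windows centered on the site position: their center maps
  # exactly onto its mirror image (even widths are center-biased)
  direct <- data.frame(chrom = truth$chrom, start = truth$pos - 6,
                       end = truth$pos + 7, strand = truth$strand)
  p <- mean_profile(site_matrix(ends, direct, 200), "mean")
  # mirror the track and the sites, flip strands
  mir <- ends
  mir$values[[1]] <- rev(mir$values[[1]])
  msites <- direct
  msites$start <- len - direct$end
  msites$end <- len - direct$start
  msites$strand <- ifelse(direct$strand == "+", "-", "+")
  pm <- mean_profile(site_matrix(mir, msites, 200), "mean")
  expect_equal(profile_at_range(p, -150, 150),
               profile_at_range(pm, -150, 150), tolerance = 1e-12)
})

test_that("columnwise mean, median and percent-of-max behave", {
  m <- structure(rbind(c(0, 2, 0), c(0, 4, 0)),
                 positions = -1:1, dropped = 0L)
  class(m) <- c("profile_matrix", class(m))
  expect_equal(mean_profile(m, "mean")$values, c(0, 3, 0))
  expect_equal(mean_profile(m, "median")$values, c(0, 3, 0))
  expect_equal(mean_profile(m, "percent-of-max")$values, c(0, 100, 0))
  zero <- m; zero[] <- 0
  expect_error(mean_profile(zero, "percent-of-max"), "all-zero")
})

test_that("sliding smooth is a truncated centered moving average", {
  const <- cutrunr:::new_profile(-50:49, rep(3, 100), "mean")
  expect_equal(smooth_profile(const, 11)$values, rep(3, 100))
  imp <- cutrunr:::new_profile(-50:49, c(rep(0, 50), 1, rep(0, 49)), "mean")
  sm <- smooth_profile(imp, 11)
  expect_equal(sum(sm$values > 0), 11)
  expect_equal(max(sm$values), 1 / 11)
  expect_equal(smooth_profile(imp, 1)$values, imp$values)
  expect_error(smooth_profile(imp, 10), "odd")
})

test_that("autocorrelation finds planted periods and rejects flat input", {
  saw10 <- cutrunr:::new_profile(-200:199, rep(c(rep(0, 9), 5), 40), "mean")
  expect_equal(periodicity_autocorrelation(saw10)$period, 10)
  saw7 <- cutrunr:::new_profile(0:209, rep(c(rep(0, 6), 5), 30), "mean")
  expect_equal(periodicity_autocorrelation(saw7)$period, 7)
  flat <- cutrunr:::new_profile(-200:199, rep(2, 400), "mean")
  expect_error(periodicity_autocorrelation(flat), "zero-variance")
  short <- cutrunr:::new_profile(0:49, rnorm(50), "mean")
  expect_error(periodicity_autocorrelation(short, max_lag = 50), "short")
})

test_that("white-noise residual acf stays within the band on average", {
  set.seed(19)
  reps <- 40
  acc <- matrix(0, reps, 51)
  for (i in seq_len(reps)) {
    p <- cutrunr:::new_profile(0:1999, rnorm(2000), "mean")
    acc[i, ] <- periodicity_autocorrelation(p)$acf
  }
  band <- 2 / sqrt(2000)
  # mean acf at lags beyond the smoothing window is within the band
  expect_true(all(abs(colMeans(acc)[13:51]) < band))
})

test_that("G+C profiles hit composition bounds and detect built-in period", {
  sites <- data.frame(chrom = "chr1", start = 96, end = 104, strand = "+")
  allG <- c(chr1 = paste(rep("G", 400), collapse = ""))
  expect_equal(unique(gc_profile(allG, sites, 50)$values), 1)
  allA <- c(chr1 = paste(rep("A", 400), collapse = ""))
  expect_equal(unique(gc_profile(allA, sites, 50)$values), 0)
  # alternating 5xGC / 5xAT has period 10
  block <- paste(rep(paste0("GCGCG", "ATATA"), 100), collapse = "")
  per <- gc_profile(c(chr1 = block), data.frame(
    chrom = "chr1", start = 496, end = 504, strand = "+"), 200)
  expect_equal(periodicity_autocorrelation(per)$period, 10)
})

test_that("footprint width measures the central depleted span", {
  expect_equal(footprint_width(hole_profile(hole_lo = -10, hole_hi = 9)), 20)
  expect_equal(footprint_width(hole_profile(hole_lo = -5, hole_hi = 5)), 11)
  flat <- cutrunr:::new_profile(-500:499, rep(1, 1000), "mean")
  expect_error(footprint_width(flat), "no footprint")
})

test_that("tram-track separation is the distance between flank maxima", {
  spikes <- function(lpos, rpos) {
    pos <- -200:199
    val <- rnorm(400, 0, 1e-6) + 0.1
    val[pos == lpos] <- 5
    val[pos == rpos] <- 5
    cutrunr:::new_profile(pos, val, "mean")
  }
  set.seed(4)
  expect_equal(tramtrack_separation(spikes(-22, 22)), 44)
  expect_equal(tramtrack_separation(spikes(-10, 30)), 40)
  flat <- cutrunr:::new_profile(-200:199, rep(1, 400), "mean")
  expect_error(tramtrack_separation(flat), "flat")
})

test_that("occupancy scores implement both scoring schemes", {
  pos <- -1000:999
  mk <- function(v) {
    m <- matrix(v, nrow = 1)
    attr(m, "positions") <- pos
    class(m) <- c("profile_matrix", class(m))
    m
  }
  ones <- mk(rep(1, 2000))
  expect_equal(unname(occupancy_scores(ones, "span-mean")), 1)
  central <- mk(as.numeric(pos >= -30 & pos < 30))
  expect_equal(unname(occupancy_scores(central, "center-minus-flank")), 60)
  flanky <- mk(as.numeric((pos >= -1000 & pos < -700) |
                            (pos >= 700 & pos < 1000)))
  expect_equal(unname(occupancy_scores(flanky, "center-minus-flank")), -600)
  narrow <- matrix(1, 1, 10)
  attr(narrow, "positions") <- -5:4
  class(narrow) <- c("profile_matrix", class(narrow))
  expect_error(occupancy_scores(narrow, "span-mean"), "span")
})

test_that("row ordering is stable, reusable, and monotone in score", {
  m <- matrix(1:12, nrow = 3)
  attr(m, "positions") <- -2:1
  class(m) <- c("profile_matrix", class(m))
  ord <- order_rows(m, c(1, 3, 2))
  expect_equal(attr(ord, "permutation"), c(2, 3, 1))
  expect_equal(unclass(ord)[1, ], unclass(m)[2, ])
  # ties keep original relative order
  tied <- order_rows(m, c(2, 2, 1))
  expect_equal(attr(tied, "permutation"), c(1, 2, 3))
  # scores sorted by the permutation are non-increasing
  set.seed(8)
  sc <- rnorm(3)
  perm <- attr(order_rows(m, sc), "permutation")
  expect_true(all(diff(sc[perm]) <= 0))
  expect_error(order_rows(m, 1:2), "length")
})

test_that("cumulative count curves end at 100 and follow the ranking", {
  pos <- -50:49
  m <- rbind(rep(0, 100), rep(0, 100), rep(0, 100))
  m[1, pos >= -30 & pos < 30] <- 2 / 60
  m[2, pos >= -30 & pos < 30] <- 1 / 60
  m[3, pos >= -30 & pos < 30] <- 1 / 60
  attr(m, "positions") <- pos
  class(m) <- c("profile_matrix", class(m))
  cc <- cumulative_count_curve(m, rank_by = c(3, 2, 1))
  expect_equal(cc$cumulative_percent, c(50, 75, 100))
  # uniform counts give a straight line
  u <- m; u[] <- 1
  cu <- cumulative_count_curve(u, rank_by = 3:1)
  expect_equal(cu$cumulative_percent, c(100 / 3, 200 / 3, 100))
  expect_equal(cu$cumulative_percent[3], 100)
})
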