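#' Motif-centered profile matrices and aggregate profiles
#'
#' A `profile_matrix` has one row per motif site and one column per
#' relative position `-flank .. flank-1` (position 0 is the motif center
#' base); rows of minus-strand sites are reversed so all rows share the
#' motif orientation. An `aggregate_profile` is its columnwise summary.
#'
#' @name profile_matrix
NULL

new_profile <- function(positions, values, provenance) {
  stopifnot(length(positions) == length(values), all(is.finite(values)))
  structure(list(positions = as.integer(positions),
                 values = as.numeric(values),
                 provenance = provenance),
            class = "aggregate_profile")
}

#' @export
print.aggregate_profile <- function(x, ...) {
  cat("aggregate_profile [", x$provenance, "]: positions ",
      min(x$positions), "..", max(x$positions), "\n", sep = "")
  invisible(x)
}

#' @export
as.data.frame.aggregate_profile <- function(x, ...)
  data.frame(position = x$positions, value = x$values)

profile_at <- function(p, pos) p$values[match(pos, p$positions)]

#' Build a site-by-position signal matrix
#'
#' Row i holds the track values in the window
#' `[center - flank, center + flank)` around site i's center; windows of
#' minus-strand sites are mirrored so that relative position 0 always
#' lands on the center base and positive positions run in motif
#' orientation. Sites whose window would leave the chromosome are
#' dropped and counted (attribute `dropped`).
#'
#' @param t a [genomic_track()].
#' @param sites motif site data.frame (`chrom`, `start`, `end`,
#'   `strand`; `strand` absent is treated as `+`).
#' @param flank half-window in bp; the matrix has `2 * flank` columns.
#' @return A `profile_matrix` (numeric matrix with attributes
#'   `positions` and `dropped`).
#' @export
site_matrix <- function(t, sites, flank) {
  centers <- site_center(sites)
  strand <- if ("strand" %in% names(sites)) sites$strand else
    rep("+", nrow(sites))
  positions <- seq.int(-flank, flank - 1L)
  rows <- vector("list", nrow(sites))
  keep <- logical(nrow(sites))
  for (i in seq_len(nrow(sites))) {
    v <- t$values[[sites$chrom[i]]]
    if (is.null(v)) next
    c0 <- centers[i] + 1L  # 1-based index of the center base
    if (centers[i] - flank < 0L || centers[i] + flank >= length(v)) next
    keep[i] <- TRUE
    rows[[i]] <- if (strand[i] == "-") {
      rev(v[(c0 - flank + 1L):(c0 + flank)])
    } else {
      v[(c0 - flank):(c0 + flank - 1L)]
    }
  }
  if (!any(keep)) stop("no site survives boundary clipping")
  m <- do.call(rbind, rows[keep])
  rownames(m) <- if ("name" %in% names(sites)) sites$name[keep] else
    which(keep)
  attr(m, "positions") <- positions
  attr(m, "dropped") <- sum(!keep)
  class(m) <- c("profile_matrix", class(m))
  m
}

#' Columnwise aggregate of a profile matrix
#'
#' `mean` and `median` summarize across sites; `percent-of-max` takes
#' the columnwise mean, divides by its maximum within the +/-1 kb window
#' (or the full extent if narrower) and multiplies by 100.
#'
#' @param m a [site_matrix()] result.
#' @param mode `"mean"`, `"median"` or `"percent-of-max"`.
#' @return An `aggregate_profile`.
#' @export
mean_profile <- function(m, mode = c("mean", "median", "percent-of-max")) {
  mode <- match.arg(mode)
  if (!nrow(m)) stop("empty profile matrix")
  pos <- attr(m, "positions")
  v <- if (mode == "median") apply(m, 2, stats::median) else colMeans(m)
  if (mode == "percent-of-max") {
    win <- abs(pos) <= 1000
    mx <- max(v[win])
    if (mx <= 0) stop("all-zero profile: percent-of-max undefined")
    v <- 100 * v / mx
  }
  new_profile(pos, v, mode)
}

#' Sliding-window smoothing of an aggregate profile
#'
#' Centered moving average with an odd window; at the edges the window
#' is truncated to the available positions rather than padded.
#'
#' @param p an `aggregate_profile`.
#' @param window odd window size in bp (default 11).
#' @return A smoothed `aggregate_profile`.
#' @export
smooth_profile <- function(p, window = 11) {
  if (window < 1 || window %% 2 == 0) stop("window must be odd and >= 1")
  v <- p$values
  n <- length(v)
  h <- (window - 1L) / 2L
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  out <- (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
  new_profile(p$positions, out, paste0(p$provenance, ",smoothed"))
}

#' Cleavage periodicity by residual autocorrelation
#'
#' Subtracts the `smooth_window`-bp smoothed profile from the 1-bp
#' profile and computes the Pearson-normalized autocorrelation of the
#' residual at lags 1..`max_lag`. The lag of the dominant interior local
#' maximum is reported as the period estimate; `conf` is the approximate
#' 95% white-noise band `2/sqrt(n)`, and `significant` says whether the
#' dominant peak exceeds it.
#'
#' @param p an `aggregate_profile` (unsmoothed, 1-bp resolution).
#' @param smooth_window window for the trend removed (default 11).
#' @param max_lag largest lag examined (default 50).
#' @return List: `lag`, `acf` (including lag 0 = 1), `period`, `conf`,
#'   `significant`.
#' @export
periodicity_autocorrelation <- function(p, smooth_window = 11, max_lag = 50) {
  if (length(p$values) <= 2 * max_lag)
    stop("profile too short for max_lag = ", max_lag)
  r <- p$values - smooth_profile(p, smooth_window)$values
  if (stats::var(r) == 0) stop("zero-variance residual: no structure to test")
  a <- as.numeric(stats::acf(r, lag.max = max_lag, plot = FALSE,
                             demean = TRUE)$acf)
  interior <- 2:(max_lag - 1)  # lags; exclude lag 1 and max_lag
  is_max <- vapply(interior, function(k) {
    a[k + 1] > a[k] && a[k + 1] >= a[k + 2]
  }, logical(1))
  peaks <- interior[is_max]
  period <- if (length(peaks)) peaks[which.max(a[peaks + 1])] else NA_integer_
  conf <- 2 / sqrt(length(r))
  list(lag = 0:max_lag, acf = a, period = period, conf = conf,
       significant = !is.na(period) && a[period + 1] > conf)
}

#' Mean G+C indicator profile around sites
#'
#' Columnwise mean of a G-or-C indicator over oriented site windows;
#' used as a sequence-composition control for cleavage periodicity.
#'
#' @param genome named sequences or `Biostrings::DNAStringSet`.
#' @param sites motif site data.frame.
#' @param flank half-window in bp.
#' @return An `aggregate_profile` with values in `[0, 1]`.
#' @export
gc_profile <- function(genome, sites, flank) {
  seqs <- as_sequence_list(genome)
  cs <- chrom_sizes(vapply(seqs, nchar, 0L))
  vals <- lapply(seqs, function(s) {
    as.numeric(strsplit(toupper(s), "")[[1]] %in% c("G", "C"))
  })
  gc <- genomic_track(vals, cs, "raw-count")
  m <- site_matrix(gc, sites, flank)
  out <- mean_profile(m, "mean")
  out$provenance <- "gc-content"
  out
}

#' Footprint width of an end-density profile
#'
#' The protected span of a bound factor appears as a central depletion
#' of cleavage-end density. The flank reference level is the mean of the
#' outer 25% of positions on each side of the (unsmoothed) profile; the
#' footprint is the maximal contiguous span containing relative position
#' 0 whose values are below `depletion_frac` times that level.
#'
#' @param p an end-density `aggregate_profile` (unsmoothed).
#' @param depletion_frac fraction of the flank level below which a base
#'   counts as protected (default 0.25).
#' @return Footprint width in bp.
#' @export
footprint_width <- function(p, depletion_frac = 0.25) {
  n <- length(p$values)
  q <- max(1L, floor(n / 4))
  flank_level <- mean(c(p$values[seq_len(q)], p$values[(n - q + 1L):n]))
  theta <- depletion_frac * flank_level
  below <- p$values < theta
  i0 <- match(0L, p$positions)
  if (is.na(i0) || !below[i0])
    stop("no footprint detected: center not depleted below ",
         signif(theta, 4))
  lo <- i0
  while (lo > 1L && below[lo - 1L]) lo <- lo - 1L
  hi <- i0
  while (hi < n && below[hi + 1L]) hi <- hi + 1L
  hi - lo + 1L
}

#' Separation of paired flanking cleavage hotspots ("tram-tracks")
#'
#' Distance between the maximum end-density position left of the motif
#' center (`[-search, 0)`) and right of it (`[0, search)`); ties are
#' broken toward the center.
#'
#' @param p an end-density `aggregate_profile`.
#' @param search half-window searched on each side (default 100 bp).
#' @return Separation in bp.
#' @export
tramtrack_separation <- function(p, search = 100) {
  left_idx <- which(p$positions >= -search & p$positions < 0)
  right_idx <- which(p$positions >= 0 & p$positions < search)
  if (!length(left_idx) || !length(right_idx))
    stop("profile does not cover the +/-", search, " bp search window")
  for (idx in list(left_idx, right_idx)) {
    if (length(unique(p$values[idx])) == 1L)
      stop("flat half-window: no flanking maximum")
  }
  lv <- p$values[left_idx]
  lp <- p$positions[left_idx][max(which(lv == max(lv)))]   # tie: toward 0
  rv <- p$values[right_idx]
  rp <- p$positions[right_idx][min(which(rv == max(rv)))]  # tie: toward 0
  as.integer(rp - lp)
}

#' Per-site occupancy scores
#'
#' `span-mean`: row mean over `[-span, span)`. `center-minus-flank`:
#' sum over `[-center_halfwidth, center_halfwidth)` minus the sum over
#' the two flank blocks `[-flank_outer, -flank_inner)` and
#' `[flank_inner, flank_outer)`.
#'
#' @param m a [site_matrix()] result.
#' @param scheme `"span-mean"` or `"center-minus-flank"`.
#' @param span half-span for `span-mean` (default 1000 bp).
#' @param center_halfwidth center half-width for `center-minus-flank`
#'   (default 30 bp).
#' @param flank_inner,flank_outer flank block bounds (defaults 700 and
#'   1000 bp).
#' @return Numeric score per row.
#' @export
occupancy_scores <- function(m, scheme = c("span-mean", "center-minus-flank"),
                             span = 1000, center_halfwidth = 30,
                             flank_inner = 700, flank_outer = 1000) {
  scheme <- match.arg(scheme)
  pos <- attr(m, "positions")
  need <- if (scheme == "span-mean") c(-span, span - 1) else
    c(-flank_outer, flank_outer - 1)
  if (min(pos) > need[1] || max(pos) < need[2])
    stop("matrix columns do not cover the required span [",
         need[1], ", ", need[2], "]")
  if (scheme == "span-mean") {
    sel <- pos >= -span & pos < span
    rowMeans(m[, sel, drop = FALSE])
  } else {
    center <- pos >= -center_halfwidth & pos < center_halfwidth
    flank <- (pos >= -flank_outer & pos < -flank_inner) |
      (pos >= flank_inner & pos < flank_outer)
    rowSums(m[, center, drop = FALSE]) - rowSums(m[, flank, drop = FALSE])
  }
}

#' Order matrix rows by occupancy score
#'
#' Rows are sorted by descending score (stable on ties). The permutation
#' is returned as attribute `permutation` so that a second matrix (e.g.
#' the other fragment size class, or another technique) can be ordered
#' identically.
#'
#' @param m a [site_matrix()] result.
#' @param scores numeric vector, one per row.
#' @return The reordered `profile_matrix` with attribute `permutation`.
#' @export
order_rows <- function(m, scores) {
  if (length(scores) != nrow(m))
    stop("scores length must equal row count")
  perm <- order(-scores)
  out <- m[perm, , drop = FALSE]
  attr(out, "positions") <- attr(m, "positions")
  attr(out, "permutation") <- perm
  class(out) <- class(m)
  out
}

#' Cumulative percent of central counts by rank
#'
#' Per-row counts are summed over `[-center_halfwidth,
#' center_halfwidth)`; rows are ranked by an external score (descending,
#' stable) and the running total is scaled to end at 100%. A technique
#' concentrating its counts at the strongest sites rises steeply.
#'
#' @param m a [site_matrix()] result.
#' @param rank_by numeric vector, one per row (e.g. motif similarity).
#' @param center_halfwidth half-width of the center window (default 30).
#' @return data.frame `rank`, `row` (original index), `count`,
#'   `cumulative_percent`.
#' @export
cumulative_count_curve <- function(m, rank_by, center_halfwidth = 30) {
  if (length(rank_by) != nrow(m)) stop("rank_by length must equal row count")
  pos <- attr(m, "positions")
  sel <- pos >= -center_halfwidth & pos < center_halfwidth
  counts <- rowSums(m[, sel, drop = FALSE])
  total <- sum(counts)
  if (total <= 0) stop("zero total center counts")
  perm <- order(-rank_by)
  data.frame(rank = seq_along(perm), row = perm, count = counts[perm],
             cumulative_percent = 100 * cumsum(counts[perm]) / total)
}

#' Export a profile matrix as TSV
#'
#' @param m a [site_matrix()] result.
#' @param path output path; columns are `site` then one column per
#'   relative position.
#' @return `path`, invisibly.
#' @export
write_profile_matrix <- function(m, path) {
  df <- data.frame(site = rownames(m), unclass(m)[, , drop = FALSE],
                   check.names = FALSE)
  names(df) <- c("site", attr(m, "positions"))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Export an aggregate profile as two-column TSV
#'
#' @param p an `aggregate_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(p, path) {
  utils::write.table(as.data.frame(p), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
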