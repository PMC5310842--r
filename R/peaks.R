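#' Percentile-threshold peak calling
#'
#' Simple threshold peak calling on a normalized track: (1) the
#' threshold is the given percentile of per-base values (by default over
#' nonzero positions only, genome-wide; sparse cleavage tracks are
#' mostly zero, so an all-positions percentile would sit at zero);
#' (2) maximal runs of bases at or above the threshold become
#' candidates; (3) candidates separated by gaps smaller than `interpeak`
#' are merged; (4) merged intervals narrower than `min_width` or wider
#' than `max_width` are discarded. Percentiles use linear interpolation
#' between order statistics (quantile type 7).
#'
#' @param t a [genomic_track()].
#' @param percentile threshold percentile in (0, 100) (default 99.5).
#' @param interpeak minimum allowed gap between peaks in bp (default
#'   100); smaller gaps are merged.
#' @param min_width,max_width width bounds in bp applied after merging
#'   (defaults 50 and 1000).
#' @param nonzero_only compute the percentile over nonzero positions
#'   only (default TRUE).
#' @param merge_first merge gaps before applying width bounds (default
#'   TRUE); `FALSE` filters widths first.
#' @return data.frame of peaks: `chrom`, `start`, `end` (0-based
#'   half-open), `score` (sum of track values inside) and `summit`
#'   (position of the maximum value, leftmost on ties), sorted by
#'   coordinate. Threshold and parameters are attached as attribute
#'   `params`.
#' @export
call_peaks <- function(t, percentile = 99.5, interpeak = 100,
                       min_width = 50, max_width = 1000,
                       nonzero_only = TRUE, merge_first = TRUE) {
  if (percentile <= 0 || percentile >= 100)
    stop("percentile must be in (0, 100)")
  all_vals <- unlist(t$values, use.names = FALSE)
  pool <- if (nonzero_only) all_vals[all_vals != 0] else all_vals
  if (!length(pool)) stop("all-zero track: nothing to call")
  theta <- stats::quantile(pool, percentile / 100, type = 7, names = FALSE)
  out <- list()
  for (chrom in names(t$values)) {
    v <- t$values[[chrom]]
    r <- rle(v >= theta)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths  # 0-based inclusive
    runs <- data.frame(start = starts[r$values], end = ends[r$values])
    if (!nrow(runs)) next
    width_filter <- function(d)
      d[(d$end - d$start) >= min_width & (d$end - d$start) <= max_width, ,
        drop = FALSE]
    merge_runs <- function(d) {
      if (nrow(d) < 2) return(d)
      keep_start <- d$start[1]
      ms <- integer(0); me <- integer(0)
      for (i in 2:nrow(d)) {
        if (d$start[i] - d$end[i - 1L] < interpeak) next
        ms <- c(ms, keep_start); me <- c(me, d$end[i - 1L])
        keep_start <- d$start[i]
      }
      ms <- c(ms, keep_start); me <- c(me, d$end[nrow(d)])
      data.frame(start = ms, end = me)
    }
    runs <- if (merge_first) width_filter(merge_runs(runs)) else
      merge_runs(width_filter(runs))
    if (!nrow(runs)) next
    score <- numeric(nrow(runs))
    summit <- integer(nrow(runs))
    for (i in seq_len(nrow(runs))) {
      idx <- (runs$start[i] + 1L):runs$end[i]
      score[i] <- sum(v[idx])
      summit[i] <- runs$start[i] + which.max(v[idx]) - 1L
    }
    out[[length(out) + 1L]] <- data.frame(
      chrom = chrom, start = runs$start, end = runs$end,
      score = score, summit = summit, stringsAsFactors = FALSE)
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               score = numeric(), summit = integer(),
               stringsAsFactors = FALSE)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "params") <- list(threshold = theta, percentile = percentile,
                              interpeak = interpeak, min_width = min_width,
                              max_width = max_width,
                              nonzero_only = nonzero_only,
                              merge_first = merge_first)
  res
}

#' Fraction of peaks containing a motif
#'
#' A peak counts when its interval (extended by `slop` bp on both
#' sides) overlaps at least one motif site by at least 1 bp.
#'
#' @param peaks peak data.frame from [call_peaks()].
#' @param sites motif site data.frame.
#' @param slop bp added to each peak side before testing (default 0).
#' @return Fraction in `[0, 1]`.
#' @export
peak_motif_fraction <- function(peaks, sites, slop = 0) {
  if (!nrow(peaks)) stop("empty peak list")
  if (!nrow(sites)) return(0)
  hits <- GenomicRanges::countOverlaps(
    intervals_granges(peaks, slop = slop), intervals_granges(sites),
    minoverlap = 1L)
  mean(hits > 0)
}

#' Percentile recovering a target peak count
#'
#' Binary search over the percentile whose [call_peaks()] output size is
#' closest to `target_n`; used to match peak numbers between datasets
#' before comparing motif content. If the target is unreachable the
#' closest achievable percentile is returned with a warning.
#'
#' @param t a [genomic_track()].
#' @param target_n desired number of peaks (>= 1).
#' @param ... further arguments passed to [call_peaks()].
#' @param tol search stops when the percentile bracket is narrower than
#'   this (default 1e-4).
#' @return The percentile (numeric scalar) with attribute `n_peaks`.
#' @export
threshold_for_peak_count <- function(t, target_n, ..., tol = 1e-4) {
  if (target_n < 1) stop("target_n must be >= 1")
  count_at <- function(p) nrow(call_peaks(t, percentile = p, ...))
  lo <- 1e-6
  hi <- 100 - 1e-6
  best_p <- NA_real_
  best_n <- NA_integer_
  consider <- function(p, n) {
    if (is.na(best_n) || abs(n - target_n) < abs(best_n - target_n)) {
      best_p <<- p; best_n <<- n
    }
  }
  n_lo <- count_at(lo); consider(lo, n_lo)
  n_hi <- count_at(hi); consider(hi, n_hi)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    n_mid <- count_at(mid)
    consider(mid, n_mid)
    if (n_mid == target_n) break
    # peak count is (weakly) non-increasing in the percentile
    if (n_mid > target_n) lo <- mid else hi <- mid
  }
  if (best_n != target_n)
    warning("target of ", target_n, " peaks unreachable; closest is ",
            best_n)
  structure(best_p, n_peaks = best_n)
}

#' Write peaks as BED6
#'
#' @param peaks peak data.frame from [call_peaks()].
#' @param path output path; name = peak index, score = track sum,
#'   strand ".". Parameters are echoed to a JSON sidecar
#'   (`<path>.json`).
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  write_bed6(peaks, path)
  params <- attr(peaks, "params")
  if (!is.null(params))
    jsonlite::write_json(params, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  invisible(path)
}
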