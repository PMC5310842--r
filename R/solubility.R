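#' Solubility log-ratios and midpoint-aligned median profiles
#'
#' Cleavage releases most chromatin particles into the soluble
#' supernatant, but large or anchored complexes (e.g. centromeric
#' kinetochore chromatin) stay in the pellet. Comparing total DNA with
#' the soluble fraction therefore reads out insolubility:
#' `log2(Insoluble) = log2(Total) - log2(Soluble)`.
#'
#' @name solubility
NULL

#' Pair of fraction tracks
#'
#' @param total,soluble [genomic_track()]s of the total and soluble
#'   fractions; same genome and value semantics.
#' @param pseudocount positive value added to both tracks before the
#'   log-ratio (default 1 raw count, scaled to the tracks' semantics by
#'   the caller if needed).
#' @return A `fraction_pair` object.
#' @export
fraction_pair <- function(total, soluble, pseudocount = 1) {
  stopifnot(inherits(total, "genomic_track"),
            inherits(soluble, "genomic_track"))
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (!identical(names(total$values), names(soluble$values)) ||
      !identical(lengths(total$values), lengths(soluble$values)))
    stop("fraction tracks must share chromosomes and lengths")
  if (total$semantics != soluble$semantics)
    stop("fraction tracks must share normalization semantics")
  structure(list(total = total, soluble = soluble,
                 pseudocount = pseudocount),
            class = "fraction_pair")
}

log_ratio_track <- function(num, den, pseudocount) {
  vals <- stats::setNames(lapply(names(num$values), function(chrom) {
    log2((num$values[[chrom]] + pseudocount) /
           (den$values[[chrom]] + pseudocount))
  }), names(num$values))
  genomic_track(vals, num$chrom_sizes, "log2-ratio")
}

#' Per-base insolubility log-ratio
#'
#' `log2((total + pseudocount) / (soluble + pseudocount))`. Positive
#' values mark chromatin cleaved but retained in the pellet.
#'
#' @param fp a [fraction_pair()], or the total track (then `soluble`
#'   and `pseudocount` must be given).
#' @param soluble,pseudocount used when `fp` is a plain track.
#' @return A [genomic_track()] with semantics `"log2-ratio"`.
#' @export
insoluble_log_ratio <- function(fp, soluble = NULL, pseudocount = 1) {
  if (!inherits(fp, "fraction_pair"))
    fp <- fraction_pair(fp, soluble, pseudocount)
  log_ratio_track(fp$total, fp$soluble, fp$pseudocount)
}

#' High- vs low-salt extraction log-ratio
#'
#' Same contract as [insoluble_log_ratio()] with the two fraction roles
#' renamed: `log2((high + pc) / (low + pc))`.
#'
#' @param high,low [genomic_track()]s of the two salt fractions.
#' @param pseudocount positive pseudocount (default 1).
#' @return A [genomic_track()] with semantics `"log2-ratio"`.
#' @export
high_vs_low_salt_ratio <- function(high, low, pseudocount = 1) {
  insoluble_log_ratio(fraction_pair(high, low, pseudocount))
}

#' Columnwise median profile around aligned midpoints
#'
#' Windows are centered on the given midpoints with no strand
#' orientation (appropriate for unoriented features such as
#' centromeres); midpoints whose window leaves the chromosome are
#' dropped and counted.
#'
#' @param t a [genomic_track()].
#' @param midpoints data.frame with columns `chrom` and `pos` (0-based
#'   base position).
#' @param flank half-window in bp.
#' @return An `aggregate_profile` (provenance `"median"`) with
#'   attribute `dropped`.
#' @export
median_midpoint_profile <- function(t, midpoints, flank) {
  sites <- data.frame(chrom = midpoints$chrom,
                      start = midpoints$pos, end = midpoints$pos + 1L,
                      strand = "+", stringsAsFactors = FALSE)
  m <- site_matrix(t, sites, flank)
  out <- mean_profile(m, "median")
  attr(out, "dropped") <- attr(m, "dropped")
  out
}
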