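#' Per-base genomic signal tracks
#'
#' A `genomic_track` stores one dense numeric vector per chromosome
#' (element i = value at 0-based position i-1) together with a value
#' semantics label: `"raw-count"`, `"per-total-ends"` (standard
#' normalization) or `"per-spike-read"` (spike-in normalization). The
#' label is set exactly once; renormalizing an already normalized track
#' is an error.
#'
#' @param values named list of numeric vectors, one per chromosome, each
#'   as long as its chromosome.
#' @param chrom_sizes a [chrom_sizes()] object.
#' @param semantics value semantics label.
#' @return A `genomic_track` object.
#' @export
genomic_track <- function(values, chrom_sizes,
                          semantics = c("raw-count", "per-total-ends",
                                        "per-spike-read", "log2-ratio")) {
  semantics <- match.arg(semantics)
  if (!setequal(names(values), names(chrom_sizes)))
    stop("track chromosomes must match chrom_sizes")
  for (chrom in names(values)) {
    if (length(values[[chrom]]) != chrom_sizes[[chrom]])
      stop("track vector length for ", chrom, " does not match its size")
  }
  structure(list(values = values[names(chrom_sizes)],
                 chrom_sizes = chrom_sizes,
                 semantics = semantics),
            class = "genomic_track")
}

#' @export
print.genomic_track <- function(x, ...) {
  cat("genomic_track [", x$semantics, "]: ",
      length(x$values), " chromosome(s), total signal ",
      format(track_sum(x)), "\n", sep = "")
  invisible(x)
}

#' Total signal in a track
#' @param t a [genomic_track()].
#' @return Sum of all per-base values.
#' @export
track_sum <- function(t) sum(vapply(t$values, sum, 0))

empty_values <- function(cs)
  stats::setNames(lapply(as.integer(cs), numeric), names(cs))

#' Fragment-end density track
#'
#' Each fragment records two MNase cleavage events; both termini are
#' counted, so a fragment `[start, end)` increments position `start` and
#' position `end - 1` by one. Total track mass is therefore twice the
#' fragment count (a length-1 fragment contributes 2 to its single
#' base). End density, not coverage, is what reveals footprints and
#' cleavage hotspots at base-pair resolution.
#'
#' @param fs a [fragment_set()].
#' @param chrom_sizes optional [chrom_sizes()]; defaults to the set's.
#' @return A raw-count [genomic_track()].
#' @export
end_density_track <- function(fs, chrom_sizes = fs$chrom_sizes) {
  vals <- empty_values(chrom_sizes)
  df <- fs$fragments
  for (chrom in unique(df$chrom)) {
    sel <- df$chrom == chrom
    ends <- c(df$start[sel] + 1L, df$end[sel])  # 1-based indices
    vals[[chrom]] <- as.numeric(
      tabulate(ends, nbins = chrom_sizes[[chrom]]))
  }
  genomic_track(vals, chrom_sizes, "raw-count")
}

#' Fragment coverage track
#'
#' Each base covered by a fragment's half-open interval gains 1 per
#' covering fragment; total mass equals the sum of fragment lengths.
#'
#' @inheritParams end_density_track
#' @return A raw-count [genomic_track()].
#' @export
coverage_track <- function(fs, chrom_sizes = fs$chrom_sizes) {
  vals <- empty_values(chrom_sizes)
  df <- fs$fragments
  for (chrom in unique(df$chrom)) {
    sel <- df$chrom == chrom
    n <- chrom_sizes[[chrom]]
    starts <- df$start[sel] + 1L
    ends <- df$end[sel] + 1L  # first position past the fragment, 1-based
    delta <- tabulate(starts, nbins = n + 1L) - tabulate(ends, nbins = n + 1L)
    vals[[chrom]] <- cumsum(delta)[seq_len(n)]
  }
  genomic_track(vals, chrom_sizes, "raw-count")
}

#' Standard (internal) normalization
#'
#' Divides every per-base value by the total number of mapped read ends
#' in the sample (2 x mapped fragment count). Both end-density and
#' coverage tracks of one sample share this single factor. Internal
#' normalization expresses each sample relative to its own sequencing
#' depth and therefore cannot report absolute differences in cleavage
#' yield between samples — that is what spike-in normalization is for.
#'
#' @param t a raw-count [genomic_track()].
#' @param total_mapped_ends positive count of mapped read ends.
#' @return A [genomic_track()] with semantics `"per-total-ends"`.
#' @export
normalize_standard <- function(t, total_mapped_ends) {
  stopifnot(inherits(t, "genomic_track"))
  if (t$semantics != "raw-count")
    stop("can only normalize a raw-count track (is: ", t$semantics, ")")
  if (total_mapped_ends <= 0)
    stop("total_mapped_ends must be > 0")
  t$values <- lapply(t$values, function(v) v / total_mapped_ends)
  t$semantics <- "per-total-ends"
  t
}

#' Spike-in normalization
#'
#' Scales the track by `scale / spike_reads`, where `spike_reads` is the
#' number of fragments mapped to a heterologous spike-in genome added at
#' constant amount per reaction. Because the spike-in yield is constant,
#' this normalization preserves absolute between-sample differences in
#' cleavage (e.g. over a digestion time course), which internal
#' normalization flattens.
#'
#' @param t a raw-count [genomic_track()].
#' @param spike_reads positive count of spike-in fragments.
#' @param scale multiplier applied after division (default 1).
#' @return A [genomic_track()] with semantics `"per-spike-read"`.
#' @export
normalize_spikein <- function(t, spike_reads, scale = 1) {
  stopifnot(inherits(t, "genomic_track"))
  if (t$semantics != "raw-count")
    stop("can only normalize a raw-count track (is: ", t$semantics, ")")
  if (spike_reads <= 0)
    stop("spike_reads must be > 0: no spike-in fragments were detected; ",
         "check that spike-in material was added and mapped")
  f <- scale / spike_reads
  t$values <- lapply(t$values, function(v) v * f)
  t$semantics <- "per-spike-read"
  t
}

#' Partition fragments between primary and spike-in genomes
#'
#' Assigns every fragment to exactly one genome by chromosome name
#' (namespaces must be disjoint); fragments on chromosomes in neither
#' namespace are rejected and counted.
#'
#' @param fs a [fragment_set()] containing mixed-genome fragments (its
#'   own chrom_sizes are ignored; assignment uses the two tables below).
#' @param primary_cs,spike_cs [chrom_sizes()] for the two genomes.
#' @return List with elements `primary` and `spike` ([fragment_set()]s)
#'   and `stats`: `primary_mapped_ends`, `spike_reads`, `rejected`, and
#'   `spike_missing` (TRUE when no spike-in fragment was found).
#' @export
split_by_genome <- function(fs, primary_cs, spike_cs) {
  check_disjoint(primary_cs, spike_cs)
  df <- fs$fragments
  in_primary <- df$chrom %in% names(primary_cs)
  in_spike <- df$chrom %in% names(spike_cs)
  primary <- fragment_set(df[in_primary, , drop = FALSE], primary_cs,
                          meta = fs$meta)
  spike <- fragment_set(df[in_spike, , drop = FALSE], spike_cs,
                        meta = fs$meta)
  stats <- list(primary_mapped_ends = 2L * nrow(primary$fragments),
                spike_reads = nrow(spike$fragments),
                rejected = sum(!in_primary & !in_spike),
                spike_missing = nrow(spike$fragments) == 0L)
  list(primary = primary, spike = spike, stats = stats)
}

#' Percent of DNA released into the supernatant
#'
#' `100 * supernatant / (supernatant + pellet)`, the fraction of total
#' DNA recovered in the soluble fraction after cleavage.
#'
#' @param supernatant_amount,pellet_amount non-negative DNA amounts
#'   (same units), not both zero.
#' @return Percent released, in `[0, 100]`.
#' @export
percent_release <- function(supernatant_amount, pellet_amount) {
  if (supernatant_amount < 0 || pellet_amount < 0)
    stop("amounts must be >= 0")
  if (supernatant_amount + pellet_amount == 0)
    stop("supernatant and pellet cannot both be zero")
  100 * supernatant_amount / (supernatant_amount + pellet_amount)
}

#' Write a track as bedGraph
#'
#' Run-length-compressed 4-column bedGraph; runs of zeros are omitted.
#'
#' @param t a [genomic_track()].
#' @param path output path.
#' @param digits if non-NULL, fixed decimal formatting with this many
#'   digits (for bit-exact diffs); default writes full float precision.
#' @return `path`, invisibly.
#' @export
write_bedgraph <- function(t, path, digits = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  for (chrom in names(t$values)) {
    v <- t$values[[chrom]]
    r <- rle(v)
    ends <- cumsum(r$lengths)          # 1-based inclusive = 0-based exclusive
    starts <- ends - r$lengths         # 0-based inclusive
    keep <- r$values != 0
    if (!any(keep)) next
    val <- if (is.null(digits)) {
      format(r$values[keep], scientific = FALSE, trim = TRUE, digits = 15)
    } else {
      formatC(r$values[keep], format = "f", digits = digits)
    }
    writeLines(paste(chrom, starts[keep], ends[keep], val, sep = "\t"), con)
  }
  invisible(path)
}

#' Read a bedGraph file into a track
#'
#' Positions not covered by any record are zero. Overlapping records are
#' an error: a bedGraph is a function of position, not a pile-up.
#'
#' @param path bedGraph path.
#' @param chrom_sizes a [chrom_sizes()] object.
#' @param semantics semantics label for the resulting track.
#' @return A [genomic_track()].
#' @export
read_bedgraph <- function(path, chrom_sizes, semantics = "raw-count") {
  vals <- empty_values(chrom_sizes)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                   !startsWith(lines, "#")]
  if (length(lines)) {
    tab <- utils::read.table(text = lines, header = FALSE,
                             col.names = c("chrom", "start", "end", "value"),
                             colClasses = c("character", "integer", "integer",
                                            "numeric"))
    covered <- lapply(vals, function(v) logical(length(v)))
    for (i in seq_len(nrow(tab))) {
      chrom <- tab$chrom[i]
      if (!chrom %in% names(vals))
        stop("bedGraph chromosome not in chrom_sizes: ", chrom)
      idx <- (tab$start[i] + 1L):tab$end[i]
      if (any(covered[[chrom]][idx]))
        stop("overlapping bedGraph intervals on ", chrom)
      covered[[chrom]][idx] <- TRUE
      vals[[chrom]][idx] <- tab$value[i]
    }
  }
  genomic_track(vals, chrom_sizes, semantics)
}
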