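#' Fragment sets
#'
#' A `fragment_set` holds mapped paired-end sequencing fragments as
#' 0-based half-open genomic intervals, validated against a
#' [chrom_sizes()] table. Each fragment represents one sequenced insert;
#' its length is `end - start`. Duplicate fragments are retained:
#' identical inserts are distinct cleavage events and no deduplication is
#' applied unless requested explicitly.
#'
#' @param fragments data.frame with columns `chrom`, `start`, `end`
#'   (0-based half-open); extra columns (e.g. a simulation `class`
#'   column) are kept.
#' @param chrom_sizes a [chrom_sizes()] object the fragments must be
#'   valid against.
#' @param meta optional named list of sample metadata (e.g.
#'   `digestion_time`, `fraction` = soluble/total/high-salt).
#' @param rejected count of records discarded during construction
#'   (invalid coordinates or unknown chromosomes).
#' @return A `fragment_set` object: a list with elements `fragments`
#'   (data.frame including a `length` column), `chrom_sizes`, `meta`,
#'   and `rejected`.
#' @export
fragment_set <- function(fragments, chrom_sizes, meta = list(), rejected = 0L) {
  stopifnot(is.data.frame(fragments))
  need <- c("chrom", "start", "end")
  if (!all(need %in% names(fragments)))
    stop("fragments need columns chrom, start, end")
  fragments$chrom <- as.character(fragments$chrom)
  fragments$start <- as.integer(fragments$start)
  fragments$end <- as.integer(fragments$end)

  len <- stats::setNames(as.numeric(chrom_sizes), names(chrom_sizes))
  known <- fragments$chrom %in% names(len)
  ok <- known &
    fragments$start >= 0L &
    fragments$end > fragments$start
  ok[known] <- ok[known] &
    fragments$end[known] <= len[fragments$chrom[known]]
  bad <- sum(!ok)
  fragments <- fragments[ok, , drop = FALSE]
  rownames(fragments) <- NULL
  fragments$length <- fragments$end - fragments$start

  structure(
    list(fragments = fragments,
         chrom_sizes = chrom_sizes,
         meta = meta,
         rejected = as.integer(rejected + bad)),
    class = "fragment_set")
}

#' @export
print.fragment_set <- function(x, ...) {
  cat("fragment_set: ", nrow(x$fragments), " fragments on ",
      length(unique(x$fragments$chrom)), " chromosome(s) (",
      genome_label(x$chrom_sizes), " genome)", sep = "")
  if (x$rejected > 0) cat("; ", x$rejected, " record(s) rejected", sep = "")
  if (length(x$meta)) {
    cat("\n  meta: ",
        paste(names(x$meta), unlist(x$meta), sep = "=", collapse = ", "),
        sep = "")
  }
  cat("\n")
  invisible(x)
}

#' @export
length.fragment_set <- function(x) nrow(x$fragments)

#' Read mapped paired-end fragments
#'
#' Reads fragment intervals from a BED3+ file, or reconstructs insert
#' intervals from a coordinate-resolvable paired-end SAM file (the
#' interval spanning the outer mate coordinates, taken from the leftmost
#' mate's position and TLEN field). Records on chromosomes absent from
#' `chrom_sizes`, or with `end <= start`, are rejected and counted in
#' the returned set's `rejected` field.
#'
#' @param path input file path.
#' @param chrom_sizes a [chrom_sizes()] object.
#' @param format `"bed"` or `"sam"`.
#' @param meta sample metadata list, stored on the returned set.
#' @return A [fragment_set()].
#' @export
read_fragments <- function(path, chrom_sizes, format = c("bed", "sam"),
                           meta = list()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "bed") {
    lines <- readLines(path)
    lines <- lines[nzchar(lines) & !startsWith(lines, "track") &
                     !startsWith(lines, "#")]
    if (!length(lines))
      return(fragment_set(data.frame(chrom = character(), start = integer(),
                                     end = integer()), chrom_sizes, meta))
    fields <- strsplit(lines, "[ \t]+")
    nfield <- lengths(fields)
    if (any(nfield < 3))
      stop("malformed BED line ", which(nfield < 3)[1], ": fewer than 3 fields")
    chrom <- vapply(fields, `[[`, "", 1L)
    start <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 2L)))
    end <- suppressWarnings(as.integer(vapply(fields, `[[`, "", 3L)))
    if (anyNA(start) || anyNA(end))
      stop("malformed BED line ", which(is.na(start) | is.na(end))[1],
           ": non-numeric coordinates")
    df <- data.frame(chrom = chrom, start = start, end = end,
                     stringsAsFactors = FALSE)
  } else {
    df <- read_sam_pairs(path)
  }
  fragment_set(df, chrom_sizes, meta = meta)
}

# Insert intervals from a SAM file: for each properly paired alignment,
# take the leftmost mate (TLEN > 0) and span [POS-1, POS-1+TLEN).
read_sam_pairs <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(chrom = character(), start = integer(), end = integer()))
  fields <- strsplit(lines, "\t")
  bad <- which(lengths(fields) < 11)
  if (length(bad))
    stop("malformed SAM line ", bad[1], ": fewer than 11 fields")
  flag <- as.integer(vapply(fields, `[[`, "", 2L))
  tlen <- as.integer(vapply(fields, `[[`, "", 9L))
  paired <- bitwAnd(flag, 1L) > 0L & bitwAnd(flag, 4L) == 0L
  keep <- paired & tlen > 0L
  pos <- as.integer(vapply(fields, `[[`, "", 4L))
  data.frame(chrom = vapply(fields, `[[`, "", 3L)[keep],
             start = pos[keep] - 1L,
             end = pos[keep] - 1L + tlen[keep],
             stringsAsFactors = FALSE)
}

#' Write fragments as BED3
#'
#' @param fs a [fragment_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fs, path) {
  df <- fs$fragments
  utils::write.table(df[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Select fragments by insert length
#'
#' Partitioning fragments into size classes separates directly
#' TF-protected material (short, <= ~120 bp) from nucleosomal material
#' (>= ~150 bp). Bounds are inclusive; an absent bound is unbounded.
#' Input order is preserved.
#'
#' @param fs a [fragment_set()].
#' @param min_len,max_len inclusive length bounds in bp, or `NULL`.
#' @return A [fragment_set()] with the surviving fragments.
#' @examples
#' # tf_class  <- size_select(fs, max_len = 120)
#' # nuc_class <- size_select(fs, min_len = 150)
#' @export
size_select <- function(fs, min_len = NULL, max_len = NULL) {
  stopifnot(inherits(fs, "fragment_set"))
  if (!is.null(min_len) && !is.null(max_len) && min_len > max_len)
    stop("min_len must be <= max_len")
  keep <- rep(TRUE, nrow(fs$fragments))
  if (!is.null(min_len)) keep <- keep & fs$fragments$length >= min_len
  if (!is.null(max_len)) keep <- keep & fs$fragments$length <= max_len
  out <- fs
  out$fragments <- fs$fragments[keep, , drop = FALSE]
  rownames(out$fragments) <- NULL
  out
}

#' Fragment length distribution
#'
#' Counts (or fractions) of fragments per 1-bp length bin. With
#' `normalize = TRUE` the values are scaled so that the sum over all
#' length steps equals 1, the convention used for comparing insert-size
#' profiles between samples sequenced to different depths.
#'
#' @param fs a [fragment_set()].
#' @param normalize if `TRUE`, return fractions summing to 1.
#' @return A data.frame with columns `length` and `count` (or
#'   `fraction`), one row per observed 1-bp length.
#' @export
length_distribution <- function(fs, normalize = FALSE) {
  stopifnot(inherits(fs, "fragment_set"))
  n <- nrow(fs$fragments)
  if (n == 0 && normalize)
    stop("cannot normalize the length distribution of an empty fragment set")
  tab <- table(fs$fragments$length)
  out <- data.frame(length = as.integer(names(tab)),
                    count = as.numeric(tab))
  if (normalize) {
    out$fraction <- out$count / n
    out$count <- NULL
  }
  out
}

#' Modal fragment length
#'
#' @param fs a [fragment_set()].
#' @return The 1-bp length bin with the highest count (smallest such
#'   length on ties).
#' @export
length_mode <- function(fs) {
  d <- length_distribution(fs)
  if (!nrow(d)) stop("empty fragment set")
  d$length[which.max(d$count)]
}

# fragment_set -> GRanges (internal; 1-based closed for IRanges)
fragments_granges <- function(fs) {
  df <- fs$fragments
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end))
}

intervals_granges <- function(df, slop = 0L) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = pmax(df$start + 1L - slop, 1L),
                              end = df$end + slop))
}
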