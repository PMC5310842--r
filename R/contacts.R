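#' Direct/indirect site classification via 3D-contact fragments
#'
#' An antibody-tethered nuclease cleaves not only at directly bound
#' sites but also at loci brought into contact with the factor in 3D.
#' Peaks in the cleavage map that coincide with a native-ChIP peak are
#' classified as direct binding; the remainder (indirect) are candidate
#' contact partners, testable against proximity-ligation fragment
#' pairs (ChIA-PET / Hi-C, BEDPE records with an interaction score).
#'
#' @name contacts
NULL

#' Read a BEDPE contact-pair file
#'
#' @param path tab-separated file: chrom1 start1 end1 chrom2 start2
#'   end2 \[score\].
#' @param min_score optional score filter (records below are dropped).
#' @return data.frame `chrom1,start1,end1,chrom2,start2,end2,score`
#'   (score 0 when absent from the file).
#' @export
read_bedpe <- function(path, min_score = NULL) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("BEDPE needs at least 6 columns: ", path)
  out <- stats::setNames(tab[, 1:6],
                         c("chrom1", "start1", "end1",
                           "chrom2", "start2", "end2"))
  out$score <- if (ncol(tab) >= 7) as.numeric(tab[[7]]) else 0
  if (!is.null(min_score)) out <- out[out$score >= min_score, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Classify cleavage-map peaks as direct or indirect
#'
#' A peak overlapping (>= 1 bp, after `slop` extension) any native-ChIP
#' peak is direct; all others are indirect. The output is always an
#' exhaustive, disjoint partition of the input peaks.
#'
#' @param cutrun_peaks,native_peaks peak data.frames (`chrom`, `start`,
#'   `end`, ...).
#' @param slop bp added to each cleavage-map peak side (default 0).
#' @return A `classified_sites` object: list with `direct` and
#'   `indirect` peak data.frames.
#' @export
classify_sites <- function(cutrun_peaks, native_peaks, slop = 0) {
  is_direct <- if (nrow(cutrun_peaks) == 0) logical(0) else if
  (nrow(native_peaks) == 0) rep(FALSE, nrow(cutrun_peaks)) else
    GenomicRanges::countOverlaps(
      intervals_granges(cutrun_peaks, slop = slop),
      intervals_granges(native_peaks), minoverlap = 1L) > 0
  direct <- cutrun_peaks[is_direct, , drop = FALSE]
  indirect <- cutrun_peaks[!is_direct, , drop = FALSE]
  rownames(direct) <- rownames(indirect) <- NULL
  structure(list(direct = direct, indirect = indirect),
            class = "classified_sites")
}

#' @export
print.classified_sites <- function(x, ...) {
  cat("classified_sites: ", nrow(x$direct), " direct, ",
      nrow(x$indirect), " indirect\n", sep = "")
  invisible(x)
}

anchor_class <- function(chrom, start, end, classified) {
  gr <- GenomicRanges::GRanges(chrom,
                               IRanges::IRanges(start + 1L, end))
  hit <- function(peaks) {
    if (!nrow(peaks)) return(rep(NA_integer_, length(gr)))
    h <- GenomicRanges::findOverlaps(gr, intervals_granges(peaks),
                                     minoverlap = 1L, select = "first")
    h
  }
  d <- hit(classified$direct)
  i <- hit(classified$indirect)
  cls <- ifelse(!is.na(d), "direct", ifelse(!is.na(i), "indirect", "none"))
  list(class = cls, direct_idx = d, indirect_idx = i)
}

#' Annotate contact pairs with the site category at each anchor
#'
#' Each anchor is tested against the direct and indirect peak sets
#' (direct takes precedence when both overlap). The `category` column
#' combines the two anchor classes, symmetric under swapping anchors
#' (e.g. a direct/indirect pair is `"direct-indirect"` regardless of
#' which anchor carries which).
#'
#' @param pairs BEDPE data.frame from [read_bedpe()].
#' @param classified a [classify_sites()] result.
#' @return `pairs` with added columns `classA`, `classB`, `category`,
#'   and `indirect_idx` (row index into `classified$indirect` of the
#'   indirect-overlapping anchor, if any).
#' @export
anchor_intersect <- function(pairs, classified) {
  a <- anchor_class(pairs$chrom1, pairs$start1, pairs$end1, classified)
  b <- anchor_class(pairs$chrom2, pairs$start2, pairs$end2, classified)
  pairs$classA <- a$class
  pairs$classB <- b$class
  both <- cbind(a$class, b$class)
  pairs$category <- apply(both, 1, function(x)
    paste(sort(x, decreasing = FALSE), collapse = "-"))
  pairs$category[pairs$classA == "none" & pairs$classB == "none"] <-
    "uncategorized"
  idx <- ifelse(a$class == "indirect", a$indirect_idx,
                ifelse(b$class == "indirect", b$indirect_idx, NA_integer_))
  pairs$indirect_idx <- idx
  pairs
}

#' Random interval control matched for count and width
#'
#' Draws the same number of intervals with the same width multiset as
#' the input sites, positions uniform over the valid chromosome space,
#' reproducibly under `seed`.
#'
#' @param sites site/peak data.frame.
#' @param chrom_sizes a [chrom_sizes()] object.
#' @param seed integer seed (required for reproducibility).
#' @return data.frame `chrom`, `start`, `end`.
#' @export
random_site_control <- function(sites, chrom_sizes, seed) {
  stopifnot(!missing(seed))
  widths <- sites$end - sites$start
  lens <- as.numeric(chrom_sizes)
  withr_seed(seed, {
    chrom_idx <- sample.int(length(lens), length(widths), replace = TRUE,
                            prob = lens / sum(lens))
    start <- vapply(seq_along(widths), function(i) {
      space <- lens[chrom_idx[i]] - widths[i]
      if (space < 0) stop("interval wider than chromosome")
      as.integer(floor(stats::runif(1, 0, space + 1)))
    }, integer(1))
    data.frame(chrom = names(chrom_sizes)[chrom_idx],
               start = start, end = start + widths,
               stringsAsFactors = FALSE)
  })
}

# Evaluate expr under a temporary RNG state seeded with `seed`.
withr_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv()) else
    rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Rank contact pairs by cleavage score with moving averages
#'
#' Restricts to pairs linking a direct site to an indirect site, ranks
#' them by the indirect site's cleavage-map peak score (descending) and
#' returns centered moving averages (truncated at the edges) of that
#' score and of the contact interaction score. A decreasing contact
#' curve alongside the decreasing cleavage curve indicates that
#' stronger indirect cleavage marks stronger 3D contacts.
#'
#' @param annotated output of [anchor_intersect()].
#' @param site_scores numeric vector of cleavage-map scores, one per
#'   row of the indirect peak set used in classification.
#' @param window moving-average window in rows (default 1500; shrunk
#'   with a warning when fewer pairs are available).
#' @return data.frame `rank`, `cutrun_score`, `contact_score`,
#'   `cutrun_ma`, `contact_ma`.
#' @export
score_contact_association <- function(annotated, site_scores, window = 1500) {
  keep <- annotated$category == "direct-indirect" &
    !is.na(annotated$indirect_idx)
  d <- annotated[keep, , drop = FALSE]
  if (!nrow(d)) stop("no direct-indirect contact pairs to rank")
  if (window > nrow(d)) {
    warning("window ", window, " larger than ", nrow(d),
            " pairs; shrinking")
    window <- nrow(d)
  }
  cr <- site_scores[d$indirect_idx]
  ord <- order(-cr)
  cr <- cr[ord]
  cs <- d$score[ord]
  ma <- function(x) {
    if (window >= length(x)) return(rep(mean(x), length(x)))
    h <- (window - 1) %/% 2
    n <- length(x)
    cum <- cumsum(c(0, x))
    lo <- pmax(seq_len(n) - h, 1L)
    hi <- pmin(seq_len(n) + h, n)
    (cum[hi + 1L] - cum[lo]) / (hi - lo + 1L)
  }
  data.frame(rank = seq_along(cr), cutrun_score = cr, contact_score = cs,
             cutrun_ma = ma(cr), contact_ma = ma(cs))
}
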