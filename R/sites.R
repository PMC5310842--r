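#' Position-specific scoring matrices and motif sites
#'
#' A `pssm` is a 4 x width matrix of per-position log-odds scores
#' (rows A, C, G, T) with an attached background base distribution.
#' Motif sites are oriented occurrences in the genome, stored as a
#' data.frame with columns `chrom`, `start`, `end` (0-based half-open,
#' `end - start` = motif width), `strand` (`+`/`-`) and `score`
#' (log-odds of the match).
#'
#' @param scores 4 x width numeric matrix; rows named A, C, G, T.
#' @param background background base frequencies (length 4, sums to 1).
#' @return A `pssm` object.
#' @export
pssm <- function(scores, background = rep(0.25, 4)) {
  scores <- as.matrix(scores)
  if (nrow(scores) != 4) stop("a PSSM has 4 rows (A, C, G, T)")
  if (is.null(rownames(scores))) rownames(scores) <- c("A", "C", "G", "T")
  scores <- scores[c("A", "C", "G", "T"), , drop = FALSE]
  if (!all(is.finite(scores))) stop("PSSM scores must be finite")
  if (abs(sum(background) - 1) > 1e-6) stop("background must sum to 1")
  names(background) <- c("A", "C", "G", "T")
  structure(scores, background = background, class = c("pssm", "matrix"))
}

#' @export
print.pssm <- function(x, ...) {
  cat("pssm: width", ncol(x), "\n")
  print(unclass(x)[, , drop = FALSE])
  invisible(x)
}

#' Log-odds PSSM from a position frequency matrix
#'
#' `log2((counts + pseudocount) / colsum / background)`. The pseudocount
#' (default 0.25 per base) keeps zero-count cells finite; it must be
#' pinned for reproducible site lists.
#'
#' @param counts 4 x width count (or frequency) matrix, rows A, C, G, T.
#' @param pseudocount added to every cell before normalization.
#' @param background background base frequencies.
#' @return A [pssm()].
#' @export
pssm_from_pfm <- function(counts, pseudocount = 0.25,
                          background = rep(0.25, 4)) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4) stop("a PFM has 4 rows (A, C, G, T)")
  if (is.null(rownames(counts))) rownames(counts) <- c("A", "C", "G", "T")
  counts <- counts[c("A", "C", "G", "T"), , drop = FALSE]
  adj <- counts + pseudocount
  freq <- sweep(adj, 2, colSums(adj), "/")
  pssm(log2(freq / background), background = background)
}

#' Read a JASPAR-format position frequency matrix
#'
#' Accepts the JASPAR text layout: an optional `>`-header line, then
#' four lines `A [ 1 2 3 ]` (brackets optional).
#'
#' @param path file path.
#' @inheritParams pssm_from_pfm
#' @return A [pssm()].
#' @export
read_jaspar <- function(path, pseudocount = 0.25, background = rep(0.25, 4)) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, ">")]
  if (length(lines) < 4) stop("JASPAR file needs 4 base rows: ", path)
  rows <- lapply(lines[1:4], function(l) {
    l <- gsub("[][]", " ", l)
    parts <- strsplit(trimws(l), "[ \t]+")[[1]]
    list(base = toupper(parts[1]), counts = as.numeric(parts[-1]))
  })
  counts <- do.call(rbind, lapply(rows, `[[`, "counts"))
  rownames(counts) <- vapply(rows, `[[`, "", "base")
  pssm_from_pfm(counts, pseudocount, background)
}

# Map a sequence string to PSSM row indices; N and other ambiguity
# codes return NA and are scored as the background-weighted column mean.
base_index <- function(seq) {
  chars <- strsplit(toupper(seq), "")[[1]]
  match(chars, c("A", "C", "G", "T"))
}

#' Score one window against a PSSM
#'
#' Sum over positions of the log-odds entry for the observed base; an N
#' contributes the background-weighted mean of its column.
#'
#' @param seq DNA string of length equal to the PSSM width.
#' @param mat a [pssm()].
#' @return The log-odds score (numeric scalar).
#' @export
score_window <- function(seq, mat) {
  stopifnot(inherits(mat, "pssm"))
  idx <- base_index(seq)
  w <- ncol(mat)
  if (length(idx) != w)
    stop("sequence length ", length(idx), " != PSSM width ", w)
  bg <- attr(mat, "background")
  colmean <- as.numeric(bg %*% unclass(mat))
  per_pos <- unclass(mat)[cbind(idx, seq_len(w))]
  per_pos[is.na(idx)] <- colmean[is.na(idx)]
  sum(per_pos)
}

# Vectorized scores of every window of width w along one sequence.
scan_scores <- function(seq, mat) {
  idx <- base_index(seq)
  w <- ncol(mat)
  n <- length(idx)
  if (n < w) return(numeric(0))
  bg <- attr(mat, "background")
  colmean <- as.numeric(bg %*% unclass(mat))
  nw <- n - w + 1L
  total <- numeric(nw)
  m <- unclass(mat)
  for (j in seq_len(w)) {
    b <- idx[j:(j + nw - 1L)]
    contrib <- m[cbind(b, rep(j, nw))]
    contrib[is.na(b)] <- colmean[j]
    total <- total + contrib
  }
  total
}

revcomp <- function(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))

as_sequence_list <- function(genome) {
  if (inherits(genome, "DNAStringSet")) {
    stats::setNames(as.character(genome), names(genome))
  } else if (is.character(genome)) {
    if (is.null(names(genome))) stop("genome sequences must be named")
    genome
  } else stop("genome must be a named character vector or DNAStringSet")
}

#' Scan a genome for motif matches
#'
#' Scores every window on both strands (the minus strand is scored on
#' the reverse complement) and reports windows reaching `min_score`.
#' Coordinates are always in the plus-strand frame; output is sorted by
#' (chrom, start, strand).
#'
#' @param genome named character vector of sequences, or a
#'   `Biostrings::DNAStringSet`.
#' @param mat a [pssm()].
#' @param min_score minimum log-odds score to report.
#' @return Motif site data.frame (`chrom`, `start`, `end`, `strand`,
#'   `score`).
#' @export
scan_pssm <- function(genome, mat, min_score) {
  seqs <- as_sequence_list(genome)
  w <- ncol(mat)
  out <- list()
  for (chrom in names(seqs)) {
    seq <- seqs[[chrom]]
    n <- nchar(seq)
    fwd <- scan_scores(seq, mat)
    hit <- which(fwd >= min_score)
    if (length(hit))
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = hit - 1L, end = hit - 1L + w,
        strand = "+", score = fwd[hit], stringsAsFactors = FALSE)
    rev <- scan_scores(revcomp(seq), mat)
    hit <- which(rev >= min_score)
    if (length(hit)) {
      # window i on the reverse complement covers plus-strand
      # positions [n - i - w + 1, n - i + 1) (0-based)
      start <- n - (hit - 1L) - w
      out[[length(out) + 1L]] <- data.frame(
        chrom = chrom, start = start, end = start + w,
        strand = "-", score = rev[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      score = numeric(), stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Best motif match in (an extension of) an interval
#'
#' Extends the interval by `extend` bp on both sides, scores every
#' window on both strands, and returns the maximum. Ties are broken by
#' leftmost start, then plus strand. Extensions beyond the chromosome
#' are clipped with a warning.
#'
#' @param chrom,start,end interval (0-based half-open).
#' @param genome named sequences or `DNAStringSet`.
#' @param mat a [pssm()].
#' @param extend bp added to each side before scanning (default 100).
#' @return List with `score`, `start` (0-based plus-strand frame) and
#'   `strand` of the best window.
#' @export
best_motif_score <- function(chrom, start, end, genome, mat, extend = 100) {
  seqs <- as_sequence_list(genome)
  if (!chrom %in% names(seqs)) stop("unknown chromosome: ", chrom)
  n <- nchar(seqs[[chrom]])
  w <- ncol(mat)
  lo <- start - extend
  hi <- end + extend
  if (lo < 0 || hi > n) {
    warning("extended interval clipped to chromosome bounds")
    lo <- max(lo, 0)
    hi <- min(hi, n)
  }
  if (hi - lo < w) stop("interval too short for the PSSM width")
  sub <- substr(seqs[[chrom]], lo + 1L, hi)
  fwd <- scan_scores(sub, mat)
  rev <- scan_scores(revcomp(sub), mat)
  m <- nchar(sub)
  starts_fwd <- lo + seq_along(fwd) - 1L
  starts_rev <- lo + m - (seq_along(rev) - 1L) - w
  cand <- data.frame(
    start = c(starts_fwd, starts_rev),
    strand = rep(c("+", "-"), c(length(fwd), length(rev))),
    score = c(fwd, rev), stringsAsFactors = FALSE)
  cand <- cand[order(-cand$score, cand$start, cand$strand), , drop = FALSE]
  list(score = cand$score[1], start = cand$start[1], strand = cand$strand[1])
}

#' Remove sites of two factors that lie near one another
#'
#' Reciprocally removes from each list every site whose center is within
#' `dist` bp of any site center in the other list, so that aggregate
#' profiles of one factor are not contaminated by the other's signal.
#'
#' @param sites_a,sites_b motif site data.frames (sorted by position).
#' @param dist center-to-center distance threshold in bp (default 50,
#'   inclusive).
#' @return List with elements `a` and `b`: the filtered site lists.
#' @export
remove_cross_proximal <- function(sites_a, sites_b, dist = 50) {
  ca <- site_center(sites_a)
  cb <- site_center(sites_b)
  near <- function(centers, chroms, other_centers, other_chroms) {
    vapply(seq_along(centers), function(i) {
      sel <- other_chroms == chroms[i]
      any(abs(other_centers[sel] - centers[i]) <= dist)
    }, logical(1))
  }
  drop_a <- if (nrow(sites_a) && nrow(sites_b))
    near(ca, sites_a$chrom, cb, sites_b$chrom) else logical(nrow(sites_a))
  drop_b <- if (nrow(sites_a) && nrow(sites_b))
    near(cb, sites_b$chrom, ca, sites_a$chrom) else logical(nrow(sites_b))
  a <- sites_a[!drop_a, , drop = FALSE]
  b <- sites_b[!drop_b, , drop = FALSE]
  rownames(a) <- rownames(b) <- NULL
  list(a = a, b = b)
}

#' Motif site center
#'
#' `start + floor(width / 2)`; for even widths the convention picks the
#' base just right of the midpoint. Strand orientation is handled
#' downstream by the aggregation step.
#'
#' @param sites motif site data.frame (or any data.frame with `start`
#'   and `end`).
#' @return Integer vector of center positions (0-based).
#' @export
site_center <- function(sites) {
  if (!nrow(sites)) return(integer(0))
  as.integer(sites$start + (sites$end - sites$start) %/% 2)
}

#' Read / write BED6 motif site lists
#'
#' @param path file path.
#' @return `read_bed6`: data.frame `chrom`, `start`, `end`, `name`,
#'   `score`, `strand`.
#' @export
read_bed6 <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 6) stop("BED6 needs 6 columns: ", path)
  stats::setNames(tab[, 1:6],
                  c("chrom", "start", "end", "name", "score", "strand"))
}

#' @param sites site data.frame; missing `name` filled with row index.
#' @rdname read_bed6
#' @export
write_bed6 <- function(sites, path) {
  n <- nrow(sites)
  name <- if ("name" %in% names(sites)) sites$name else seq_len(n)
  score <- if ("score" %in% names(sites)) sites$score else rep(0, n)
  strand <- if ("strand" %in% names(sites)) sites$strand else rep(".", n)
  utils::write.table(
    data.frame(sites$chrom, sites$start, sites$end, name, score, strand),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}
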