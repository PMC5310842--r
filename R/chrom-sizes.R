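#' Chromosome sizes table
#'
#' A named integer vector of chromosome lengths with a genome label
#' (`"primary"` or `"spike-in"`). Primary and spike-in chromosome
#' namespaces must be disjoint so that fragments can be assigned to a
#' genome by name alone.
#'
#' @param sizes named numeric vector, chromosome name -> length in bp.
#' @param genome genome label, `"primary"` or `"spike-in"`.
#' @return A `chrom_sizes` object (named integer vector with a `genome`
#'   attribute).
#' @examples
#' cs <- chrom_sizes(c(chrI = 10000, chrII = 8000))
#' @export
chrom_sizes <- function(sizes, genome = c("primary", "spike-in")) {
  genome <- match.arg(genome)
  if (is.null(names(sizes)) || anyNA(names(sizes)) || any(names(sizes) == ""))
    stop("all chromosomes must be named")
  if (anyDuplicated(names(sizes)))
    stop("chromosome names must be unique")
  if (any(sizes < 1))
    stop("chromosome lengths must be >= 1")
  out <- as.integer(round(sizes))
  names(out) <- names(sizes)
  structure(out, genome = genome, class = "chrom_sizes")
}

#' Read a two-column chrom.sizes file
#'
#' @param path path to a whitespace-separated file with columns
#'   chromosome name and length.
#' @param genome genome label passed to [chrom_sizes()].
#' @return A `chrom_sizes` object.
#' @export
read_chrom_sizes <- function(path, genome = "primary") {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("chrom.sizes file needs two columns: ", path)
  chrom_sizes(stats::setNames(as.numeric(tab[[2]]), as.character(tab[[1]])),
              genome = genome)
}

#' @export
print.chrom_sizes <- function(x, ...) {
  cat("chrom_sizes (", attr(x, "genome"), " genome): ",
      length(x), " chromosome(s), ",
      format(sum(as.numeric(x)), big.mark = ","), " bp\n", sep = "")
  invisible(x)
}

genome_label <- function(cs) attr(cs, "genome")

check_disjoint <- function(primary_cs, spike_cs) {
  shared <- intersect(names(primary_cs), names(spike_cs))
  if (length(shared))
    stop("primary and spike-in chromosome namespaces overlap: ",
         paste(shared, collapse = ", "))
  invisible(TRUE)
}
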