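# Shared fixtures: everything is built in code at test time.

toy_cs <- function(len = 1000, name = "chr1", genome = "primary")
  chrom_sizes(stats::setNames(len, name), genome)

toy_fragments <- function(df, cs = toy_cs()) fragment_set(df, cs)

# A single-chromosome track from a sparse position -> value map (0-based)
toy_track <- function(map, len = 1000, name = "chr1") {
  v <- numeric(len)
  v[as.integer(names(map)) + 1L] <- as.numeric(map)
  genomic_track(stats::setNames(list(v), name), toy_cs(len, name))
}

# Width-1 and small PSSMs used across tests
pssm_single <- function() pssm(matrix(c(1.5, -1, -1, -1), 4, 1,
                                      dimnames = list(c("A", "C", "G", "T"))))

pssm_consensus <- function(consensus, match = 2, mismatch = -2) {
  bases <- strsplit(toupper(consensus), "")[[1]]
  m <- matrix(mismatch, 4, length(bases),
              dimnames = list(c("A", "C", "G", "T"), NULL))
  for (j in seq_along(bases)) m[bases[j], j] <- match
  pssm(m)
}

# Small, fast simulation config for module tests
small_cfg <- function(seed = 42, ...) {
  sim_config(seed = seed, n_direct_sites = 30, n_indirect_sites = 10,
             n_centromeres = 8, ...)
}

# A flat aggregate profile with a rectangular central hole
hole_profile <- function(flank = 500, hole_lo = -10, hole_hi = 9,
                         level = 1) {
  pos <- seq.int(-flank, flank - 1L)
  val <- rep(level, length(pos))
  val[pos >= hole_lo & pos <= hole_hi] <- 0
  cutrunr:::new_profile(pos, val, "mean")
}
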