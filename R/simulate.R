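#' Simulation of antibody-tethered nuclease cleavage data
#'
#' The generator emulates the statistical structure that the downstream
#' analysis assumes: short TF-protected fragments (length mode ~100 bp)
#' whose ends avoid a ~20 bp protected core and fall preferentially on
#' a ~10 bp-periodic comb decaying over ~100 bp of flank; paired
#' cleavage hotspots ("tram-tracks") for the CTCF-like template;
#' phased nucleosomal fragments (mode ~150 bp); uniform background; a
#' heterologous spike-in genome at constant yield; digestion time-course
#' scaling; per-class soluble/total fractionation; and motif-free
#' "indirect" sites that receive cleavage because they contact a direct
#' site in 3D. Everything is deterministic under `(seed, config)`.
#'
#' @param seed integer seed driving all randomness.
#' @param template `"tf"` (yeast-TF-like; no hotspots) or `"ctcf"`
#'   (adds paired cleavage hotspots at `hotspot_offsets`).
#' @param n_chroms number of primary chromosomes.
#' @param motif consensus motif planted at direct sites.
#' @param n_direct_sites,n_indirect_sites,n_centromeres site counts;
#'   indirect sites are motif-free contact partners of direct sites.
#' @param site_spacing center-to-center slot spacing in bp (default
#'   2200, keeping planted sites >= 2 kb apart after jitter).
#' @param margin site-free bp at each chromosome end.
#' @param tf_frag_len_mode modal TF-class fragment length in bp
#'   (default 100); each end's offset from the site center is drawn
#'   from a Gaussian envelope centered at half this value.
#' @param tf_side_sd per-side offset standard deviation in bp.
#' @param nuc_frag_len_mode,nuc_frag_len_sd nucleosomal fragment length
#'   mode and SD in bp (defaults 150 and 8).
#' @param protected_halfwidth half-width of the protected core; ends
#'   never fall in the half-open span `[-hw, hw)` around the center
#'   (default 10, i.e. a 20 bp core).
#' @param flank_period period of the flanking cleavage comb (10 bp).
#' @param flank_decay_span span over which the comb modulation decays
#'   linearly to zero (100 bp).
#' @param comb_amplitude relative amplitude of the comb at the core
#'   edge.
#' @param flank_mix weight of the linearly decaying near-core
#'   component of the end-offset envelope (the rest is the Gaussian
#'   length-mode component).
#' @param hotspot_offsets integer pair of hotspot end positions
#'   relative to the center (CTCF-like template default `c(-22, 22)`).
#' @param hotspot_weight probability that a fragment's two ends sit
#'   exactly at the hotspots.
#' @param site_rate expected TF-class fragments per site per unit
#'   digestion.
#' @param rate_dispersion SD of the per-site log-normal rate
#'   multiplier (site-to-site occupancy heterogeneity).
#' @param nuc_rate expected nucleosomal fragments per site.
#' @param nucleosome_phasing nucleosome repeat length in bp.
#' @param nuc_first_offset center offset of the first phased nucleosome.
#' @param n_nuc_per_side phased nucleosome slots per side.
#' @param nuc_jitter SD of nucleosome positional jitter in bp.
#' @param background_rate untargeted fragments per kb per unit
#'   digestion.
#' @param cen_rate centromere-class fragments per centromere.
#' @param centromere_span protected span released as intact particles
#'   at centromere-like sites.
#' @param spike_genome_length,spike_fragments spike-in genome size and
#'   the exact (constant) fragment yield per time point.
#' @param timecourse_factors per-time-point cleavage multipliers
#'   (default `c(1, 2, 3, 4)`, a 4-fold digestion series).
#' @param soluble_fraction_by_class named per-class probabilities that
#'   a fragment is recovered in the soluble fraction.
#' @param contact_score_scale interaction score per unit of indirect
#'   site rate multiplier in the contact truth table.
#' @return A `sim_config` object (validated list).
#' @export
sim_config <- function(seed = 1,
                       template = c("tf", "ctcf"),
                       n_chroms = 1,
                       motif = "CCGGACTATTAT",
                       n_direct_sites = 200,
                       n_indirect_sites = 20,
                       n_centromeres = 16,
                       site_spacing = 2200,
                       margin = 2000,
                       tf_frag_len_mode = 100,
                       tf_side_sd = 12,
                       nuc_frag_len_mode = 150,
                       nuc_frag_len_sd = 8,
                       protected_halfwidth = 10,
                       flank_period = 10,
                       flank_decay_span = 100,
                       comb_amplitude = 0.6,
                       flank_mix = 0.3,
                       hotspot_offsets = NULL,
                       hotspot_weight = 0.6,
                       site_rate = 50,
                       rate_dispersion = 0.4,
                       nuc_rate = 25,
                       nucleosome_phasing = 165,
                       nuc_first_offset = 100,
                       n_nuc_per_side = 6,
                       nuc_jitter = 15,
                       background_rate = 0.5,
                       cen_rate = 50,
                       centromere_span = 120,
                       spike_genome_length = 20000,
                       spike_fragments = 2000,
                       timecourse_factors = c(1, 2, 3, 4),
                       soluble_fraction_by_class = c(tf = 0.9,
                                                     nucleosome = 0.85,
                                                     background = 0.9,
                                                     centromere = 0.02),
                       contact_score_scale = 10) {
  template <- match.arg(template)
  if (template == "ctcf" && is.null(hotspot_offsets))
    hotspot_offsets <- c(-22L, 22L)
  cfg <- list(seed = as.integer(seed), template = template,
              n_chroms = n_chroms, motif = toupper(motif),
              n_direct_sites = n_direct_sites,
              n_indirect_sites = n_indirect_sites,
              n_centromeres = n_centromeres,
              site_spacing = site_spacing, margin = margin,
              tf_frag_len_mode = tf_frag_len_mode, tf_side_sd = tf_side_sd,
              nuc_frag_len_mode = nuc_frag_len_mode,
              nuc_frag_len_sd = nuc_frag_len_sd,
              protected_halfwidth = as.integer(protected_halfwidth),
              flank_period = flank_period,
              flank_decay_span = flank_decay_span,
              comb_amplitude = comb_amplitude, flank_mix = flank_mix,
              hotspot_offsets = hotspot_offsets,
              hotspot_weight = hotspot_weight,
              site_rate = site_rate, rate_dispersion = rate_dispersion,
              nuc_rate = nuc_rate,
              nucleosome_phasing = nucleosome_phasing,
              nuc_first_offset = nuc_first_offset,
              n_nuc_per_side = n_nuc_per_side, nuc_jitter = nuc_jitter,
              background_rate = background_rate, cen_rate = cen_rate,
              centromere_span = as.integer(centromere_span),
              spike_genome_length = spike_genome_length,
              spike_fragments = spike_fragments,
              timecourse_factors = timecourse_factors,
              soluble_fraction_by_class = soluble_fraction_by_class,
              contact_score_scale = contact_score_scale)
  stopifnot(cfg$protected_halfwidth < cfg$flank_decay_span,
            all(cfg$timecourse_factors > 0),
            cfg$site_rate >= 0, cfg$nuc_rate >= 0,
            cfg$background_rate >= 0)
  class(cfg) <- "sim_config"
  cfg
}

random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

plant <- function(seq, start0, insert) {
  # start0 is 0-based
  paste0(substr(seq, 1, start0), insert,
         substr(seq, start0 + nchar(insert) + 1, nchar(seq)))
}

# Scramble any chance occurrence of the motif (either strand) outside
# the planted positions, so planted sites are the only exact matches.
scrub_motif <- function(seq, motif, keep_starts0) {
  rc <- revcomp(motif)
  for (pat in unique(c(motif, rc))) {
    repeat {
      hits <- gregexpr(pat, seq, fixed = TRUE)[[1]]
      hits <- hits[hits > 0]
      hits0 <- hits - 1L
      bad <- setdiff(hits0, keep_starts0)
      if (!length(bad)) break
      i <- bad[1] + nchar(pat) %/% 2  # 0-based position of a middle base
      old <- substr(seq, i + 1, i + 1)
      repl <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      substr(seq, i + 1, i + 1) <- repl
    }
  }
  seq
}

#' Generate a synthetic genome with planted sites
#'
#' Random background sequence with the exact consensus motif planted at
#' direct-site positions (>= 2 kb apart); indirect sites are motif-free
#' positions, each paired with a random direct partner in the contact
#' truth table; centromere-like midpoints are motif-free and unpaired.
#' Chance motif occurrences in the background are scrambled so the
#' planted direct sites are the only exact matches. A separate random
#' spike-in genome is returned with a disjoint chromosome namespace.
#'
#' @param cfg a [sim_config()].
#' @return List: `sequences` (named character, primary genome),
#'   `spike_sequences`, `chrom_sizes`, `spike_chrom_sizes`, and `truth`
#'   (list with `sites`, `centromeres`, `contacts` data.frames).
#' @export
make_genome <- function(cfg) {
  withr_seed(cfg$seed, {
    w <- nchar(cfg$motif)
    n_sites <- cfg$n_direct_sites + cfg$n_indirect_sites + cfg$n_centromeres
    per_chrom <- rep(n_sites %/% cfg$n_chroms, cfg$n_chroms)
    extra <- n_sites - sum(per_chrom)
    if (extra > 0) per_chrom[seq_len(extra)] <- per_chrom[seq_len(extra)] + 1L
    if (any(per_chrom < 1)) stop("more chromosomes than sites")
    chrom_names <- paste0("sim", seq_len(cfg$n_chroms))
    lens <- per_chrom * cfg$site_spacing + 2L * cfg$margin

    classes <- sample(c(rep("direct", cfg$n_direct_sites),
                        rep("indirect", cfg$n_indirect_sites),
                        rep("centromere", cfg$n_centromeres)))
    chrom_of <- rep(chrom_names, per_chrom)
    slot <- unlist(lapply(per_chrom, seq_len))
    pos <- cfg$margin + (slot - 1L) * cfg$site_spacing +
      cfg$site_spacing %/% 2L +
      as.integer(round(stats::runif(n_sites, -100, 100)))
    strand <- sample(c("+", "-"), n_sites, replace = TRUE)
    mult <- exp(stats::rnorm(n_sites, 0, cfg$rate_dispersion))

    sites <- data.frame(chrom = chrom_of, pos = as.integer(pos),
                        strand = strand, class = classes,
                        rate_multiplier = mult, stringsAsFactors = FALSE)
    cen <- sites[sites$class == "centromere", c("chrom", "pos")]
    rownames(cen) <- NULL
    sites <- sites[sites$class != "centromere", , drop = FALSE]
    rownames(sites) <- NULL
    sites$start <- sites$pos - w %/% 2L
    sites$end <- sites$start + w
    sites$name <- paste0(sites$class, "_", seq_len(nrow(sites)))

    seqs <- stats::setNames(vapply(lens, random_dna, ""), chrom_names)
    for (i in which(sites$class == "direct")) {
      ins <- if (sites$strand[i] == "+") cfg$motif else revcomp(cfg$motif)
      seqs[[sites$chrom[i]]] <- plant(seqs[[sites$chrom[i]]],
                                      sites$start[i], ins)
    }
    for (chrom in chrom_names) {
      keep <- sites$start[sites$chrom == chrom & sites$class == "direct"]
      seqs[[chrom]] <- scrub_motif(seqs[[chrom]], cfg$motif, keep)
    }

    # contact truth: each indirect site pairs with one direct site
    idx_dir <- which(sites$class == "direct")
    idx_ind <- which(sites$class == "indirect")
    partner <- if (length(idx_ind))
      sample(idx_dir, length(idx_ind), replace = TRUE) else integer(0)
    sites$partner <- NA_integer_
    sites$partner[idx_ind] <- partner
    contacts <- if (length(idx_ind)) {
      data.frame(chrom1 = sites$chrom[partner],
                 start1 = sites$pos[partner] - 250L,
                 end1 = sites$pos[partner] + 250L,
                 chrom2 = sites$chrom[idx_ind],
                 start2 = sites$pos[idx_ind] - 250L,
                 end2 = sites$pos[idx_ind] + 250L,
                 score = cfg$contact_score_scale *
                   sites$rate_multiplier[idx_ind],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(chrom1 = character(), start1 = integer(),
                 end1 = integer(), chrom2 = character(),
                 start2 = integer(), end2 = integer(), score = numeric())
    }

    spike_seq <- stats::setNames(random_dna(cfg$spike_genome_length),
                                 "spike1")
    list(sequences = seqs,
         spike_sequences = spike_seq,
         chrom_sizes = chrom_sizes(stats::setNames(lens, chrom_names),
                                   "primary"),
         spike_chrom_sizes = chrom_sizes(
           stats::setNames(cfg$spike_genome_length, "spike1"), "spike-in"),
         truth = list(sites = sites, centromeres = cen,
                      contacts = contacts))
  })
}

# Draw n end offsets (distance from the site center, in bp) for one
# side of the protected core. The envelope is a mixture of (a) a
# component decaying linearly from the core edge over flank_decay_span
# (weight flank_mix; cleavage is commonest right next to the protected
# particle) and (b) a Gaussian centered at half the target
# fragment-length mode (which sets the insert-size mode); both are
# modulated by a comb of period flank_period whose amplitude decays
# linearly over the same span.
side_offsets <- function(n, min_off, mean_off, cfg) {
  if (n == 0) return(integer(0))
  grid <- min_off:(min_off + 199L)
  rel <- grid - min_off
  decay <- pmax(0, 1 - rel / cfg$flank_decay_span)
  lin <- decay * 2 / cfg$flank_decay_span
  gauss <- stats::dnorm(grid, mean_off, cfg$tf_side_sd)
  # comb teeth at helical-repeat multiples of the center offset, so the
  # favored tooth-to-tooth insert lengths stack near tf_frag_len_mode
  comb <- 1 + cfg$comb_amplitude * decay *
    cos(2 * pi * grid / cfg$flank_period)
  w <- (cfg$flank_mix * lin + (1 - cfg$flank_mix) * gauss) * comb
  w <- pmax(w, 1e-12)
  as.integer(sample(grid, n, replace = TRUE, prob = w))
}

# TF-class fragments around one batch of sites (vectorized over
# fragments). Offsets are in the motif frame; minus-strand sites mirror
# them into genomic coordinates.
tf_fragments <- function(n_per_site, sites, cfg) {
  total <- sum(n_per_site)
  if (total == 0)
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), stringsAsFactors = FALSE))
  site_idx <- rep(seq_along(n_per_site), n_per_site)
  hw <- cfg$protected_halfwidth
  half <- cfg$tf_frag_len_mode / 2
  o_l <- side_offsets(total, hw + 1L, half, cfg)        # left end at -o_l
  o_r <- side_offsets(total, hw, half - 1, cfg)         # right end at +o_r
  x_l <- -o_l
  x_r <- o_r
  if (!is.null(cfg$hotspot_offsets)) {
    hot <- stats::runif(total) < cfg$hotspot_weight
    x_l[hot] <- cfg$hotspot_offsets[1]
    x_r[hot] <- cfg$hotspot_offsets[2]
  }
  len <- x_r - x_l + 1L
  keep <- len >= 20L & len <= 500L
  site_idx <- site_idx[keep]; x_l <- x_l[keep]; x_r <- x_r[keep]
  minus <- sites$strand[site_idx] == "-"
  c0 <- sites$pos[site_idx]
  left <- ifelse(minus, c0 - x_r, c0 + x_l)
  right <- ifelse(minus, c0 - x_l, c0 + x_r)
  data.frame(chrom = sites$chrom[site_idx],
             start = as.integer(left),
             end = as.integer(right + 1L),
             stringsAsFactors = FALSE)
}

#' Simulate one time point of cleavage fragments
#'
#' Draws TF-class fragments at direct and indirect sites (Poisson site
#' counts scaled by the time-course multiplier and per-site rate
#' multipliers), phased nucleosomal fragments, uniform background, and
#' intact centromere-class particles; background and nucleosomal ends
#' falling inside a site's protected core are removed (the bound factor
#' blocks cleavage there). The spike-in set has an exact, constant
#' fragment count regardless of the time point.
#'
#' @param cfg a [sim_config()].
#' @param genome a [make_genome()] result.
#' @param time_index index into `cfg$timecourse_factors`.
#' @return List: `primary` ([fragment_set()] with a `class` column) and
#'   `spike` ([fragment_set()]).
#' @export
simulate_fragments <- function(cfg, genome, time_index = 1) {
  if (time_index < 1 || time_index > length(cfg$timecourse_factors))
    stop("time_index out of range")
  factor <- cfg$timecourse_factors[time_index]
  truth <- genome$truth
  cs <- genome$chrom_sizes
  withr_seed(cfg$seed + 7919L * time_index, {
    sites <- truth$sites
    n_tf <- stats::rpois(nrow(sites),
                         cfg$site_rate * sites$rate_multiplier * factor)
    tf <- tf_fragments(n_tf, sites, cfg)
    if (nrow(tf)) tf$class <- "tf"

    # phased nucleosomes flanking every bound site
    n_nuc <- stats::rpois(nrow(sites), cfg$nuc_rate * factor)
    tot <- sum(n_nuc)
    nuc <- if (tot) {
      si <- rep(seq_len(nrow(sites)), n_nuc)
      k <- sample.int(cfg$n_nuc_per_side, tot, replace = TRUE)
      side <- sample(c(-1L, 1L), tot, replace = TRUE)
      off <- side * (cfg$nuc_first_offset +
                       (k - 1L) * cfg$nucleosome_phasing) +
        as.integer(round(stats::rnorm(tot, 0, cfg$nuc_jitter)))
      len <- pmax(50L, as.integer(round(
        stats::rnorm(tot, cfg$nuc_frag_len_mode, cfg$nuc_frag_len_sd))))
      center <- sites$pos[si] + off
      data.frame(chrom = sites$chrom[si],
                 start = as.integer(center - len %/% 2L),
                 end = as.integer(center - len %/% 2L + len),
                 class = "nucleosome", stringsAsFactors = FALSE)
    } else NULL

    # uniform background
    total_kb <- sum(as.numeric(cs)) / 1000
    n_bg <- stats::rpois(1, cfg$background_rate * total_kb * factor)
    bg <- if (n_bg) {
      chrom_idx <- sample.int(length(cs), n_bg, replace = TRUE,
                              prob = as.numeric(cs) / sum(as.numeric(cs)))
      len <- pmin(500L, pmax(30L, as.integer(round(
        stats::rnorm(n_bg, 150, 60)))))
      start <- as.integer(floor(stats::runif(
        n_bg, 0, as.numeric(cs)[chrom_idx] - len)))
      data.frame(chrom = names(cs)[chrom_idx], start = start,
                 end = start + len, class = "background",
                 stringsAsFactors = FALSE)
    } else NULL

    # intact centromere-class particles (fixed protected span)
    cen <- truth$centromeres
    n_cen <- if (nrow(cen)) stats::rpois(nrow(cen), cfg$cen_rate * factor)
      else integer(0)
    cenfrag <- if (sum(n_cen)) {
      ci <- rep(seq_len(nrow(cen)), n_cen)
      half <- cfg$centromere_span %/% 2L
      data.frame(chrom = cen$chrom[ci],
                 start = as.integer(cen$pos[ci] - half),
                 end = as.integer(cen$pos[ci] - half + cfg$centromere_span),
                 class = "centromere", stringsAsFactors = FALSE)
    } else NULL

    frags <- do.call(rbind, Filter(Negate(is.null),
                                   list(tf, nuc, bg, cenfrag)))
    if (is.null(frags))
      frags <- data.frame(chrom = character(), start = integer(),
                          end = integer(), class = character())

    # the bound factor blocks cleavage inside its core, whatever the
    # fragment's origin
    hw <- cfg$protected_halfwidth
    untethered <- frags$class %in% c("nucleosome", "background")
    if (any(untethered) && nrow(sites)) {
      bad <- logical(nrow(frags))
      for (chrom in unique(frags$chrom[untethered])) {
        sp <- sort(sites$pos[sites$chrom == chrom])
        if (!length(sp)) next
        sel <- which(untethered & frags$chrom == chrom)
        near_core <- function(g) {
          j <- findInterval(g, sp)
          lo <- ifelse(j >= 1, abs(g - sp[pmax(j, 1)]), Inf)
          hi <- ifelse(j < length(sp), abs(sp[pmin(j + 1L, length(sp))] - g),
                       Inf)
          pmin(lo, hi) <= hw
        }
        bad[sel] <- near_core(frags$start[sel]) |
          near_core(frags$end[sel] - 1L)
      }
      frags <- frags[!bad, , drop = FALSE]
    }
    cs_lookup <- stats::setNames(as.numeric(cs), names(cs))
    frags <- frags[frags$start >= 0 &
                     frags$end <= cs_lookup[frags$chrom], ,
                   drop = FALSE]
    rownames(frags) <- NULL

    spike_len <- as.integer(genome$spike_chrom_sizes[[1]])
    slen <- pmin(400L, pmax(30L, as.integer(round(
      stats::rnorm(cfg$spike_fragments, 150, 30)))))
    sstart <- as.integer(floor(stats::runif(cfg$spike_fragments, 0,
                                            spike_len - slen)))
    spike <- data.frame(chrom = "spike1", start = sstart,
                        end = sstart + slen, stringsAsFactors = FALSE)

    list(primary = fragment_set(frags, cs,
                                meta = list(time_index = time_index,
                                            factor = factor)),
         spike = fragment_set(spike, genome$spike_chrom_sizes,
                              meta = list(time_index = time_index)))
  })
}

#' Split simulated fragments into soluble and total fractions
#'
#' The total fraction is all fragments; the soluble fraction thins each
#' class by its configured solubility (Bernoulli per fragment), so a
#' class with solubility near 0 (centromere-like particles) is all but
#' absent from the supernatant.
#'
#' @param cfg a [sim_config()].
#' @param fs a [fragment_set()] with a `class` column.
#' @return List: `total` and `soluble` [fragment_set()]s.
#' @export
simulate_fractions <- function(cfg, fs) {
  cls <- fs$fragments$class
  rates <- cfg$soluble_fraction_by_class
  missing_cls <- setdiff(unique(cls), names(rates))
  if (length(missing_cls))
    stop("no soluble fraction configured for class: ",
         paste(missing_cls, collapse = ", "))
  withr_seed(cfg$seed + 104729L, {
    keep <- stats::runif(length(cls)) < rates[cls]
    soluble <- fs
    soluble$fragments <- fs$fragments[keep, , drop = FALSE]
    rownames(soluble$fragments) <- NULL
    soluble$meta <- c(fs$meta, list(fraction = "soluble"))
    total <- fs
    total$meta <- c(fs$meta, list(fraction = "total"))
    list(total = total, soluble = soluble)
  })
}

#' One-call simulation convenience wrapper
#'
#' @param cfg a [sim_config()].
#' @param time_index time point to simulate (default 1).
#' @return List combining [make_genome()] output with `fragments`
#'   (primary) and `spike` from [simulate_fragments()].
#' @export
simulate_cutrun <- function(cfg, time_index = 1) {
  genome <- make_genome(cfg)
  fr <- simulate_fragments(cfg, genome, time_index)
  c(genome, list(fragments = fr$primary, spike = fr$spike))
}
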