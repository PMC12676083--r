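#' Genotype presets for the synthetic measurement generators
#'
#' Bundles the per-genotype parameters the generators draw from: initiation
#' noise at the meristem, the per-plant probability of a decussate episode,
#' the per-triplet probability of an organ-swap permutation (which produces
#' an M-shaped motif), the torsion mean, an internode length scale and a
#' bolting advance. The wild-type-like and PLT-triple-like presets share a
#' counterclockwise torsion mean of 0.6 degrees; the dedicated
#' torsion-mutant presets carry 1.7, 3.2 and -1.1 degrees.
#'
#' @param name One of `"col0"`, `"plt"`, `"spr2"`, `"tor2_t56i"`,
#'   `"tor2_s178d"`, or `"custom"`.
#' @param ... For `name = "custom"` (or to override a preset): any of
#'   `delta_i_sd`, `decussate_rate`, `m_motif_rate`, `torsion_mean_deg`,
#'   `torsion_sd_deg`, `internode_scale`, `bolting_advance_days`,
#'   `rosette_lambda`.
#' @return A list of class `genotype_preset`.
#' @export
genotype_preset <- function(name = c("col0", "plt", "spr2", "tor2_t56i",
                                     "tor2_s178d", "custom"), ...) {
  name <- match.arg(name)
  base <- list(name = name, delta_i_sd = 10, decussate_rate = 0,
               m_motif_rate = 0.01, torsion_mean_deg = 0.6,
               torsion_sd_deg = 0.3, internode_scale = 1,
               bolting_advance_days = 0, rosette_lambda = 0.65)
  preset <- switch(name,
    col0 = list(),
    plt = list(delta_i_sd = 17, decussate_rate = 0.10, m_motif_rate = 0.02,
               internode_scale = 1.35, bolting_advance_days = 3,
               rosette_lambda = 0.35),
    spr2 = list(torsion_mean_deg = 1.7),
    tor2_t56i = list(torsion_mean_deg = 3.2),
    tor2_s178d = list(torsion_mean_deg = -1.1),
    custom = list()
  )
  base[names(preset)] <- preset
  override <- list(...)
  bad <- setdiff(names(override), names(base))
  if (length(bad) > 0L) stop("unknown preset fields: ", paste(bad, collapse = ", "))
  base[names(override)] <- override
  stopifnot(base$delta_i_sd >= 0, base$decussate_rate >= 0,
            base$decussate_rate <= 1, base$m_motif_rate >= 0,
            base$m_motif_rate <= 1)
  class(base) <- "genotype_preset"
  base
}

plant_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * i) %% .Machine$integer.max)
}

# Divergence-angle transform of swapping organs k and k+1 in the azimuth
# sequence: (d[k-1], d[k], d[k+1]) -> (d[k-1]+d[k], 360-d[k], d[k]+d[k+1]).
swap_organs <- function(angles, k) {
  stopifnot(k >= 2, k <= length(angles) - 1)
  d <- angles
  d[k - 1] <- wrap360(angles[k - 1] + angles[k])
  d[k] <- wrap360(360 - angles[k])
  d[k + 1] <- wrap360(angles[k] + angles[k + 1])
  d
}

world_frame <- function(angles, chirality, measurement_sense = "CW") {
  if (chirality == measurement_sense) angles else wrap360(360 - angles)
}

step_direction_of <- function(angles, chirality) {
  opposite <- c(CW = "CCW", CCW = "CW")
  ifelse(angles <= 180, chirality, opposite[[chirality]])
}

#' Generate a synthetic inflorescence measurement table
#'
#' Emulates the statistical structure of measured inflorescences: per plant,
#' a spiral of golden-angle steps with genotype-dependent initiation noise,
#' an optional decussate episode (a contiguous run of alternating ~90/~180
#' degree angles), occasional organ-swap permutations that insert M-shaped
#' motifs, internode lengths drawn from a long-basal to short-apical profile,
#' a quadratically decaying stem radius, and a chirality-dependent torsion
#' displacement applied via [apply_torsion()]. Raw world-frame angles and
#' per-step rotation directions are emitted, so chirality assignment and
#' normalization are exercised end to end on the output.
#'
#' @param preset A [genotype_preset()] (or preset name).
#' @param n_plants Number of plants.
#' @param n_organs Organs per plant (yielding `n_organs - 1` steps).
#' @param seed RNG seed; equal seeds give identical tables.
#' @return A data frame in the measurement-table schema (one row per organ
#'   step): `plant_id`, `genotype`, `organ_type`, `step_index`,
#'   `raw_angle_deg`, `step_direction`, `internode_mm`, `node_position`,
#'   `radius_mm`. Truth attributes: `attr(, "decussate_plants")` (logical per
#'   plant) and `attr(, "seed")`.
#' @export
generate_inflorescence_dataset <- function(preset = genotype_preset("col0"),
                                           n_plants = 50, n_organs = 25,
                                           seed = 1L) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  stopifnot(inherits(preset, "genotype_preset"), n_plants >= 1, n_organs >= 2)
  n_steps <- n_organs - 1L
  imeans <- preset$internode_scale *
    seq(15, 2, length.out = max(n_steps, 2))[seq_len(n_steps)]
  isds <- 0.2 * imeans
  rp <- default_radius_profile()
  radii <- predict_radius(rp$coefficients,
                          seq(1, rp$n_retained, length.out = n_steps))
  rows <- vector("list", n_plants)
  decussate <- logical(n_plants)
  for (i in seq_len(n_plants)) {
    set.seed(plant_seed(seed, i))
    chir <- if (stats::runif(1) < 0.5) "CW" else "CCW"
    delta <- wrap360(stats::rnorm(n_steps, 137.5, preset$delta_i_sd))
    if (stats::runif(1) < preset$decussate_rate && n_steps >= 4L) {
      decussate[i] <- TRUE
      len <- sample(4:min(8L, n_steps), 1L)
      start <- sample.int(n_steps - len + 1L, 1L)
      episode <- wrap360(stats::rnorm(len, rep(c(90, 180), length.out = len), 5))
      delta[start:(start + len - 1L)] <- episode
    }
    internodes <- sample_internode_lengths(imeans, isds)
    alpha <- stats::rnorm(n_steps, preset$torsion_mean_deg,
                          preset$torsion_sd_deg)
    delta <- apply_torsion(delta, alpha, internodes, radii, chir)
    if (preset$m_motif_rate > 0 && n_steps >= 3L) {
      k <- 2L
      while (k <= n_steps - 1L) {
        if (stats::runif(1) < preset$m_motif_rate) {
          delta <- swap_organs(delta, k)
          k <- k + 3L
        } else {
          k <- k + 1L
        }
      }
    }
    rows[[i]] <- data.frame(
      plant_id = sprintf("plant_%03d", i), genotype = preset$name,
      organ_type = "flower", step_index = seq_len(n_steps),
      raw_angle_deg = world_frame(delta, chir),
      step_direction = step_direction_of(delta, chir),
      internode_mm = internodes, node_position = seq_len(n_steps),
      radius_mm = radii)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "decussate_plants") <- decussate
  attr(out, "seed") <- seed
  out
}

#' Generate a synthetic rosette measurement table
#'
#' Leaf divergence angles converge on the golden angle through damped
#' oscillations: pair n carries angle
#' `137.5 + A * exp(-lambda * (n - 1)) * cos(pi * n + phi) + noise`, with the
#' default amplitude A = 42.5 and phase phi = pi placing the first pair near
#' 180 degrees (the first two true leaves arise nearly opposite). Mutant-like
#' presets slow the damping (smaller lambda) and raise the noise, producing
#' larger oscillation amplitudes at mid pairs and more extreme angles.
#'
#' @param preset A [genotype_preset()] (or preset name); uses its
#'   `delta_i_sd` as the angle noise and `rosette_lambda` as the damping
#'   rate.
#' @param n_plants Number of plants.
#' @param n_leaves Number of true leaves (>= 3), yielding `n_leaves - 1`
#'   leaf pairs.
#' @param amplitude Oscillation amplitude A in degrees.
#' @param phase Oscillation phase phi in radians.
#' @param seed RNG seed.
#' @return Measurement-table data frame (one row per leaf pair) with the same
#'   schema as [generate_inflorescence_dataset()] (internode and radius
#'   columns are `NA`: rosette internodes are not elongated).
#' @export
generate_rosette_dataset <- function(preset = genotype_preset("col0"),
                                     n_plants = 60, n_leaves = 10,
                                     amplitude = 42.5, phase = pi, seed = 1L) {
  if (is.character(preset)) preset <- genotype_preset(preset)
  stopifnot(inherits(preset, "genotype_preset"), n_leaves >= 3)
  n_pairs <- n_leaves - 1L
  k <- seq_len(n_pairs)
  trend <- 137.5 + amplitude * exp(-preset$rosette_lambda * (k - 1)) *
    cos(pi * k + phase)
  rows <- vector("list", n_plants)
  for (i in seq_len(n_plants)) {
    set.seed(plant_seed(seed, i))
    chir <- if (stats::runif(1) < 0.5) "CW" else "CCW"
    delta <- wrap360(trend + stats::rnorm(n_pairs, 0, preset$delta_i_sd))
    rows[[i]] <- data.frame(
      plant_id = sprintf("plant_%03d", i), genotype = preset$name,
      organ_type = "rosette_leaf", step_index = k,
      raw_angle_deg = world_frame(delta, chir),
      step_direction = step_direction_of(delta, chir),
      internode_mm = NA_real_, node_position = k, radius_mm = NA_real_)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- seed
  out
}

# Simulate one BC1 gamete: a mosaic of the mutant and wild-type haplotypes.
# loci_pos: sorted positions (Morgans) on one chromosome. Returns logical:
# TRUE where the gamete carries the mutant-haplotype allele.
sim_gamete <- function(loci_pos) {
  n <- length(loci_pos)
  state <- logical(n)
  state[1] <- stats::runif(1) < 0.5
  if (n > 1L) {
    rec <- haldane_c(diff(loci_pos))
    flip <- stats::runif(n - 1L) < rec
    for (j in 2:n) state[j] <- xor(state[j - 1L], flip[j - 1L])
  }
  state
}

#' Generate synthetic BC1F2 bulk-segregant pools
#'
#' Plants an EMS-like causal variant (recessive) on a multi-chromosome
#' genetic map, scatters further EMS variants (C-to-T biased) along the map,
#' simulates BC1F2 individuals as pairs of recombinant gametes under Haldane
#' linkage, assigns them to a phenotype-positive pool (homozygous mutant at
#' the causal locus) and a phenotype-negative pool (the rest), and samples
#' per-variant read depths (Poisson) and allele counts (binomial in the
#' pool's true allele frequency). A backcross-parent variant set is emitted
#' for subtraction, and the truth record names the planted causal variant.
#'
#' Non-causal variants keep a default exclusion halo of 0.25 Morgan around
#' the causal locus: at pooled depths near 100, markers within roughly 20 cM
#' retain an appreciable chance of sneaking under the strict
#' phenotype-positive frequency cutoff, so a clean linked region is what
#' makes a single-candidate outcome reachable (see the methods vignette).
#'
#' @param n_snps Number of non-causal EMS variants (>= 0).
#' @param genome_length_morgans Total map length, split equally over
#'   `n_chromosomes`.
#' @param causal_locus Position (Morgans) of the causal variant on
#'   chromosome 1.
#' @param pool_sizes Plants per pool, `c(pheno_minus, pheno_plus)`.
#' @param mean_depth Mean sequencing depth per variant per pool.
#' @param seed RNG seed.
#' @param n_chromosomes Number of chromosomes.
#' @param causal_halo_morgans Minimum map distance between the causal variant
#'   and any other simulated variant.
#' @param n_parent_variants Background variants present in the backcross
#'   parent (subtracted downstream).
#' @return List of class `bsa_pools`: `variants` (data frame in the
#'   [filter_candidates()] schema), `parent_variants`, and `truth` (causal
#'   chrom/pos/ref/alt plus true pool allele frequencies).
#' @export
generate_bsa_pools <- function(n_snps = 40, genome_length_morgans = 5,
                               causal_locus = 0.5, pool_sizes = c(30, 30),
                               mean_depth = 100, seed = 1L,
                               n_chromosomes = 5,
                               causal_halo_morgans = 0.25,
                               n_parent_variants = 15) {
  stopifnot(n_snps >= 0, genome_length_morgans > 0, all(pool_sizes > 0),
            mean_depth > 0, n_chromosomes >= 1)
  chrom_len <- genome_length_morgans / n_chromosomes
  if (causal_locus < 0 || causal_locus > chrom_len) {
    stop("causal locus must lie within chromosome 1 (0..", chrom_len, " Morgans)")
  }
  set.seed(as.integer(seed))
  bp_per_morgan <- 2.5e7
  # scatter non-causal SNPs uniformly, excluding the causal halo
  snp_chrom <- integer(0); snp_pos <- numeric(0)
  while (length(snp_pos) < n_snps) {
    need <- n_snps - length(snp_pos)
    ch <- sample.int(n_chromosomes, need, replace = TRUE)
    po <- stats::runif(need, 0, chrom_len)
    ok <- !(ch == 1L & abs(po - causal_locus) < causal_halo_morgans)
    snp_chrom <- c(snp_chrom, ch[ok]); snp_pos <- c(snp_pos, po[ok])
  }
  ems_ref <- sample(c("C", "G"), n_snps + 1L, replace = TRUE)
  ems_alt <- ifelse(ems_ref == "C", "T", "A")
  chrom <- c(1L, snp_chrom)
  pos_m <- c(causal_locus, snp_pos)
  ord <- order(chrom, pos_m)
  chrom <- chrom[ord]; pos_m <- pos_m[ord]
  ref <- ems_ref[ord]; alt <- ems_alt[ord]
  causal_idx <- which(chrom == 1L & pos_m == causal_locus)[1]
  pos_bp <- as.integer(round(pos_m * bp_per_morgan)) + seq_along(pos_m)
  n_loci <- length(pos_m)

  # simulate BC1F2 individuals (mutant-haplotype indicator per locus per
  # chromosome copy) until both pools are filled
  need_plus <- pool_sizes[2]; need_minus <- pool_sizes[1]
  plus_chroms <- list(); minus_chroms <- list()
  by_chrom <- split(seq_len(n_loci), chrom)
  while (length(plus_chroms) < need_plus || length(minus_chroms) < need_minus) {
    g1 <- logical(n_loci); g2 <- logical(n_loci)
    for (idx in by_chrom) {
      g1[idx] <- sim_gamete(pos_m[idx])
      g2[idx] <- sim_gamete(pos_m[idx])
    }
    is_mm <- g1[causal_idx] && g2[causal_idx]
    if (is_mm && length(plus_chroms) < need_plus) {
      plus_chroms[[length(plus_chroms) + 1L]] <- cbind(g1, g2)
    } else if (!is_mm && length(minus_chroms) < need_minus) {
      minus_chroms[[length(minus_chroms) + 1L]] <- cbind(g1, g2)
    }
  }
  pool_af <- function(chrom_list) {
    mut <- Reduce(`+`, lapply(chrom_list, rowSums))
    1 - mut / (2 * length(chrom_list))  # WT (ref) allele frequency
  }
  wt_af_minus <- pool_af(minus_chroms)
  wt_af_plus <- pool_af(plus_chroms)
  depth_minus <- stats::rpois(n_loci, mean_depth)
  depth_plus <- stats::rpois(n_loci, mean_depth)
  ad_ref_minus <- stats::rbinom(n_loci, depth_minus, wt_af_minus)
  ad_ref_plus <- stats::rbinom(n_loci, depth_plus, wt_af_plus)
  variants <- data.frame(
    chrom = paste0("Chr", chrom), pos = pos_bp, ref = ref, alt = alt,
    biallelic = TRUE,
    ad_ref_minus = ad_ref_minus, ad_alt_minus = depth_minus - ad_ref_minus,
    ad_ref_plus = ad_ref_plus, ad_alt_plus = depth_plus - ad_ref_plus)

  # backcross-parent background variants: segregate at ~1/2 in both pools
  parent <- NULL
  if (n_parent_variants > 0L) {
    pch <- sample.int(n_chromosomes, n_parent_variants, replace = TRUE)
    ppos <- as.integer(round(stats::runif(n_parent_variants, 0, chrom_len) *
                               bp_per_morgan))
    pref <- sample(c("C", "G"), n_parent_variants, replace = TRUE)
    palt <- ifelse(pref == "C", "T", "A")
    dmin <- stats::rpois(n_parent_variants, mean_depth)
    dplu <- stats::rpois(n_parent_variants, mean_depth)
    rmin <- stats::rbinom(n_parent_variants, dmin, 0.5)
    rplu <- stats::rbinom(n_parent_variants, dplu, 0.5)
    parent_rows <- data.frame(
      chrom = paste0("Chr", pch), pos = ppos, ref = pref, alt = palt,
      biallelic = TRUE, ad_ref_minus = rmin, ad_alt_minus = dmin - rmin,
      ad_ref_plus = rplu, ad_alt_plus = dplu - rplu)
    variants <- rbind(variants, parent_rows)
    parent <- parent_rows[, c("chrom", "pos", "ref", "alt")]
  }
  variants <- variants[order(variants$chrom, variants$pos), ]
  rownames(variants) <- NULL
  variants <- subtract_parent_variants(variants,
                                       if (is.null(parent)) {
                                         data.frame(chrom = character(0),
                                                    pos = integer(0),
                                                    ref = character(0),
                                                    alt = character(0))
                                       } else parent)
  truth <- list(chrom = paste0("Chr", chrom[causal_idx]),
                pos = pos_bp[causal_idx], ref = ref[causal_idx],
                alt = alt[causal_idx],
                wt_af_minus = wt_af_minus[causal_idx],
                wt_af_plus = wt_af_plus[causal_idx], seed = seed)
  structure(list(variants = variants, parent_variants = parent, truth = truth),
            class = "bsa_pools")
}

#' @export
print.bsa_pools <- function(x, ...) {
  cat(sprintf("<bsa_pools> %d variants (%d parent-background); causal %s:%d %s>%s\n",
              nrow(x$variants),
              if (is.null(x$parent_variants)) 0L else nrow(x$parent_variants),
              x$truth$chrom, x$truth$pos, x$truth$ref, x$truth$alt))
  invisible(x)
}
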