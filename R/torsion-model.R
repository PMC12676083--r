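#' Stem-torsion displacement of a divergence angle
#'
#' Post-initiation twisting of the stem displaces organ positions. For a
#' torsion angle alpha (degrees, counterclockwise positive) acting over an
#' internode of length I (mm) on a stem of local radius r (mm), the organ is
#' carried along an arc of length I * tan(alpha), i.e. an arc angle of
#' tan(alpha) * I / r radians. In the plant's own (chirality-normalized)
#' frame the displacement enters with a sign that depends on spiral
#' handedness: counterclockwise torsion shifts clockwise spirals to smaller
#' normalized angles and counterclockwise spirals to larger ones.
#'
#' \deqn{\delta_f = \delta_i + s \cdot \tan(\alpha) \, I / r \cdot 180/\pi
#'   \pmod{360}}
#'
#' with s = +1 for CCW spirals and s = -1 for CW spirals.
#'
#' @param delta_i Initial divergence angle(s) at the meristem, degrees.
#' @param alpha Torsion angle(s) per internode, degrees, counterclockwise
#'   positive; must satisfy `|alpha| < 90`.
#' @param internode Internode length(s), mm.
#' @param radius Local stem radius/radii, mm, strictly positive.
#' @param chirality `"CW"` or `"CCW"` spiral handedness.
#' @return Final divergence angle(s) in degrees, reduced into `[0, 360)`.
#' @export
#' @examples
#' apply_torsion(137.5, 0, 5, 0.8, "CW")          # 137.5: zero torsion
#' apply_torsion(137.5, 0.6, 9.5493, 1, "CCW")    # 143.2296
#' apply_torsion(137.5, 0.6, 9.5493, 1, "CW")     # 131.7704
apply_torsion <- function(delta_i, alpha, internode, radius, chirality) {
  if (any(radius <= 0)) stop("stem radius must be > 0")
  if (any(abs(alpha) >= 90)) stop("|alpha| must be < 90 degrees")
  if (length(chirality) != 1L || !chirality %in% c("CW", "CCW")) {
    stop("chirality must be 'CW' or 'CCW'")
  }
  s <- if (chirality == "CCW") 1 else -1
  disp_deg <- s * tan(alpha * pi / 180) * (internode / radius) * (180 / pi)
  wrap360(delta_i + disp_deg)
}

#' Quadratic stem-radius profile
#'
#' Fits radius (mm) against node position by ordinary least squares with a
#' quadratic polynomial. Positions are rescaled so the maximum observed
#' position maps to `max_position` (default 35), and the first `n_retained`
#' (default 30) predicted values are exposed — the apical few centimetres of
#' a bolt are removed before phyllotaxis is measured, so the top positions
#' are dropped from the generative model.
#'
#' @param positions Node positions (>= 3 distinct values).
#' @param radii Observed stem radii, mm.
#' @param max_position Position the largest observed position is rescaled to.
#' @param n_retained Number of leading predicted radii exposed.
#' @return An object of class `radius_profile`: list with `coefficients`
#'   (a2, a1, a0 of a2*p^2 + a1*p + a0), `max_position`, `n_retained` and
#'   `radii` (the retained predictions).
#' @export
fit_radius_profile <- function(positions, radii, max_position = 35,
                               n_retained = 30) {
  positions <- as.numeric(positions)
  radii <- as.numeric(radii)
  if (length(unique(positions)) < 3L) {
    stop("need at least 3 distinct positions for a quadratic fit")
  }
  p <- positions * max_position / max(positions)
  fit <- stats::lm(radii ~ I(p^2) + p)
  cf <- stats::coef(fit)
  coefficients <- c(a2 = unname(cf["I(p^2)"]), a1 = unname(cf["p"]),
                    a0 = unname(cf["(Intercept)"]))
  coefficients[is.na(coefficients)] <- 0
  pred <- predict_radius(coefficients, seq_len(n_retained))
  if (any(pred <= 0)) {
    warning("fitted radius profile predicts non-positive radii over retained positions")
  }
  structure(
    list(coefficients = coefficients, max_position = max_position,
         n_retained = n_retained, radii = pred),
    class = "radius_profile"
  )
}

predict_radius <- function(coefficients, positions) {
  coefficients[1] * positions^2 + coefficients[2] * positions + coefficients[3]
}

#' Construct a radius profile from known quadratic coefficients
#'
#' @param a2,a1,a0 Quadratic coefficients of radius (mm) vs node position.
#' @inheritParams fit_radius_profile
#' @return A `radius_profile` (see [fit_radius_profile()]).
#' @export
radius_profile <- function(a2, a1, a0, max_position = 35, n_retained = 30) {
  coefficients <- c(a2 = a2, a1 = a1, a0 = a0)
  pred <- predict_radius(coefficients, seq_len(n_retained))
  if (any(pred <= 0)) stop("radius profile must be positive over retained positions")
  structure(
    list(coefficients = coefficients, max_position = max_position,
         n_retained = n_retained, radii = pred),
    class = "radius_profile"
  )
}

#' @export
print.radius_profile <- function(x, ...) {
  cat(sprintf("<radius_profile> r(p) = %.4g p^2 + %.4g p + %.4g; positions 1..%d of %d\n",
              x$coefficients[1], x$coefficients[2], x$coefficients[3],
              x$n_retained, x$max_position))
  invisible(x)
}

#' Draw internode lengths from per-position truncated normals
#'
#' One draw per position from Normal(mean_p, sd_p); negative draws are
#' rejected and redrawn (not clamped), preserving the shape of the
#' distribution near zero.
#'
#' @param means,sds Per-position means and standard deviations (mm), aligned.
#' @return Numeric vector of non-negative lengths, one per position.
#' @export
sample_internode_lengths <- function(means, sds) {
  if (length(means) != length(sds)) stop("means and sds must align per position")
  if (any(sds < 0)) stop("sds must be >= 0")
  out <- stats::rnorm(length(means), means, sds)
  bad <- which(out < 0)
  while (length(bad) > 0L) {
    out[bad] <- stats::rnorm(length(bad), means[bad], sds[bad])
    bad <- bad[out[bad] < 0]
  }
  out
}

#' Generative parameters for in-silico inflorescence populations
#'
#' Bundles every parameter of the forward simulator: the initial divergence
#' angle distribution at the meristem, per-position internode length
#' distributions, the stem-radius profile, the torsion distribution, counts
#' and the RNG seed.
#'
#' @param delta_i_mean,delta_i_sd Mean and sd (degrees) of the initial
#'   divergence angle distribution at the meristem.
#' @param internode_means,internode_sds Per-position internode length
#'   distributions (mm); at least `n_internodes` entries each.
#' @param radius_profile A `radius_profile` with at least `n_internodes`
#'   retained positions.
#' @param torsion_mean,torsion_sd Mean and sd (degrees) of the per-internode
#'   torsion angle, counterclockwise positive.
#' @param n_internodes Internodes (and angles) per inflorescence.
#' @param n_inflorescences Inflorescences per population.
#' @param chirality_prob_cw Probability a simulated inflorescence spirals
#'   clockwise.
#' @param seed Master RNG seed.
#' @return An object of class `torsion_params`.
#' @seealso [preset_torsion_params()] for ready-made genotype presets.
#' @export
torsion_params <- function(delta_i_mean = 137.5, delta_i_sd = 10,
                           internode_means = seq(15, 2, length.out = 30),
                           internode_sds = 0.2 * seq(15, 2, length.out = 30),
                           radius_profile = default_radius_profile(),
                           torsion_mean = 0.6, torsion_sd = 0.3,
                           n_internodes = 30, n_inflorescences = 101,
                           chirality_prob_cw = 0.5, seed = 1L) {
  stopifnot(delta_i_sd >= 0, torsion_sd >= 0,
            chirality_prob_cw >= 0, chirality_prob_cw <= 1,
            inherits(radius_profile, "radius_profile"))
  if (length(internode_means) < n_internodes ||
      length(internode_sds) < n_internodes) {
    stop("internode distribution lists must cover n_internodes positions")
  }
  if (any(internode_sds < 0)) stop("internode sds must be >= 0")
  if (radius_profile$n_retained < n_internodes) {
    stop("radius profile must cover n_internodes positions")
  }
  structure(
    list(delta_i_mean = delta_i_mean, delta_i_sd = delta_i_sd,
         internode_means = internode_means, internode_sds = internode_sds,
         radius_profile = radius_profile,
         torsion_mean = torsion_mean, torsion_sd = torsion_sd,
         n_internodes = as.integer(n_internodes),
         n_inflorescences = as.integer(n_inflorescences),
         chirality_prob_cw = chirality_prob_cw, seed = as.integer(seed)),
    class = "torsion_params"
  )
}

#' Default quadratic stem-radius profile (1.0 to 0.4 mm over 30 positions)
#' @return A `radius_profile`.
#' @export
default_radius_profile <- function() {
  radius_profile(a2 = 5e-4, a1 = -0.0362, a0 = 1.0357)
}

#' Genotype presets for the inflorescence simulator
#'
#' Ready-made [torsion_params()] for a wild-type-like and a
#' PLT-triple-mutant-like inflorescence. The torsion mean (0.6 degrees,
#' counterclockwise) is a measured value shared by both genotypes; the
#' mutant preset carries a noisier initial divergence angle (sd 17 vs 10
#' degrees) and internodes longer by a factor 1.35, reflecting its
#' accelerated bolting. Remaining values are package defaults, not
#' measurements.
#'
#' @param preset `"col0"` or `"plt"`.
#' @param seed Master RNG seed.
#' @param ... Overrides passed on to [torsion_params()].
#' @return A `torsion_params` object.
#' @export
preset_torsion_params <- function(preset = c("col0", "plt"), seed = 1L, ...) {
  preset <- match.arg(preset)
  base_means <- seq(15, 2, length.out = 30)
  args <- switch(preset,
    col0 = list(delta_i_sd = 10, internode_means = base_means,
                internode_sds = 0.2 * base_means),
    plt = list(delta_i_sd = 17, internode_means = 1.35 * base_means,
               internode_sds = 0.2 * 1.35 * base_means)
  )
  args$seed <- seed
  override <- list(...)
  args[names(override)] <- override
  do.call(torsion_params, args)
}

inflorescence_seed <- function(master_seed, i) {
  as.integer((as.numeric(master_seed) + 7919 * i) %% .Machine$integer.max)
}

#' Simulate a population of in-silico inflorescences
#'
#' The generative procedure: each inflorescence gets a chirality
#' (Bernoulli(`chirality_prob_cw`)); each of its `n_internodes` internodes is
#' assigned an initial divergence angle from Normal(delta_i_mean,
#' delta_i_sd), an internode length from the per-position truncated normals
#' ([sample_internode_lengths()]), a local stem radius from the quadratic
#' profile, and a torsion angle from Normal(torsion_mean, torsion_sd); the
#' final divergence angle is the torsion-displaced initial angle
#' ([apply_torsion()]). One RNG stream per inflorescence is derived from the
#' master seed, so populations are reproducible.
#'
#' @param params A [torsion_params()] object.
#' @return An object of class `simulated_population`: list with `records` (a
#'   list of [inflorescence_record()]s whose series carry the final angles;
#'   each record also stores `delta_i` and `alpha` tracks) and `params`.
#' @export
simulate_population <- function(params) {
  stopifnot(inherits(params, "torsion_params"))
  n <- params$n_internodes
  pos <- seq_len(n)
  radii <- params$radius_profile$radii[pos]
  records <- vector("list", params$n_inflorescences)
  for (i in seq_len(params$n_inflorescences)) {
    set.seed(inflorescence_seed(params$seed, i))
    chir <- if (stats::runif(1) < params$chirality_prob_cw) "CW" else "CCW"
    delta_i <- wrap360(stats::rnorm(n, params$delta_i_mean, params$delta_i_sd))
    internodes <- sample_internode_lengths(params$internode_means[pos],
                                           params$internode_sds[pos])
    alpha <- stats::rnorm(n, params$torsion_mean, params$torsion_sd)
    delta_f <- apply_torsion(delta_i, alpha, internodes, radii, chir)
    ser <- organ_series(plant_id = sprintf("sim_%03d", i), angles = delta_f,
                        organ_type = "flower", chirality = chir,
                        genotype = "simulated")
    rec <- inflorescence_record(ser, internodes, node_positions = pos,
                                radii = radii)
    rec$delta_i <- delta_i
    rec$alpha <- alpha
    records[[i]] <- rec
  }
  structure(list(records = records, params = params),
            class = "simulated_population")
}

#' @export
print.simulated_population <- function(x, ...) {
  chir <- vapply(x$records, function(r) r$series$chirality, character(1))
  cat(sprintf("<simulated_population> %d inflorescences x %d internodes (%d CW / %d CCW)\n",
              length(x$records), x$params$n_internodes,
              sum(chir == "CW"), sum(chir == "CCW")))
  invisible(x)
}

#' Export a simulated population to the measurement-table schema
#'
#' Emits one row per internode with raw world-frame angles and per-step
#' rotation directions, exactly as an experimental table would arrive, so the
#' quantify and regress stages are source-agnostic.
#'
#' @param pop A `simulated_population`.
#' @param measurement_sense World rotation sense to emit raw angles in.
#' @return Measurement-table data frame (see [read_measurements()]); the
#'   master seed is attached as `attr(, "seed")`.
#' @export
population_to_table <- function(pop, measurement_sense = "CW") {
  stopifnot(inherits(pop, "simulated_population"))
  rows <- lapply(pop$records, function(r) {
    chir <- r$series$chirality
    a <- r$series$angles
    data.frame(
      plant_id = r$series$plant_id, genotype = r$series$genotype,
      organ_type = r$series$organ_type,
      step_index = seq_along(a),
      raw_angle_deg = world_frame(a, chir, measurement_sense),
      step_direction = step_direction_of(a, chir),
      internode_mm = r$internode_lengths,
      node_position = r$node_positions,
      radius_mm = if (is.null(r$radii)) NA_real_ else r$radii)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "seed") <- pop$params$seed
  out
}

#' Bin a simulated population's final angles
#'
#' Pools consecutive final-angle pairs within each inflorescence (pairs never
#' straddle plants) into one [bin_pairs()] grid — the same binning applied to
#' experimental inflorescence tables.
#'
#' @param pop A `simulated_population`.
#' @param bin_width Bin width in degrees.
#' @param chirality Optional `"CW"`/`"CCW"` to restrict to one chirality
#'   class.
#' @return A `bin_grid2d`.
#' @export
population_bin_grid <- function(pop, bin_width = 22.5, chirality = NULL) {
  recs <- pop$records
  if (!is.null(chirality)) {
    recs <- Filter(function(r) r$series$chirality == chirality, recs)
  }
  if (length(recs) == 0L) stop("no inflorescences in the requested chirality class")
  grids <- lapply(recs, function(r) bin_pairs(r$series$angles, bin_width))
  counts <- Reduce(`+`, lapply(grids, `[[`, "counts"))
  out <- grids[[1L]]
  out$counts <- counts
  out$n_pairs <- sum(vapply(grids, `[[`, integer(1), "n_pairs"))
  out
}

#' Pooled golden-window pair fraction of a population
#' @inheritParams population_bin_grid
#' @return Fraction in `[0, 1]` of consecutive pairs with both members in the
#'   golden window, pooled over inflorescences.
#' @export
population_window_fraction <- function(pop, bin_width = 22.5, chirality = NULL) {
  g <- population_bin_grid(pop, bin_width, chirality)
  sum(g$counts[g$window_bins, g$window_bins]) / g$n_pairs
}

#' Sweep internode-length and torsion scales
#'
#' Simulates one population per (internode scale, torsion scale) grid cell —
#' scaling the per-position internode means and the torsion mean respectively
#' — with identical seeds per cell so the cells are comparable, and bins each
#' population.
#'
#' @param base A [torsion_params()] object.
#' @param internode_scales Positive multipliers for the internode means.
#' @param torsion_scales Non-negative multipliers for the torsion mean.
#' @param bin_width Bin width for the per-cell heatmaps.
#' @return An object of class `torsion_sweep`: list with `summary` (data
#'   frame: scales, modal bin centers, pooled window fraction) and `grids`
#'   (list of `bin_grid2d`, one per cell, row-major over the summary).
#' @export
sweep_parameters <- function(base, internode_scales = c(0.5, 1, 2),
                             torsion_scales = c(0, 1, 2, 4),
                             bin_width = 22.5) {
  stopifnot(inherits(base, "torsion_params"),
            all(internode_scales > 0), all(torsion_scales >= 0))
  cells <- expand.grid(internode_scale = internode_scales,
                       torsion_scale = torsion_scales)
  grids <- vector("list", nrow(cells))
  summary <- cells
  summary$modal_bin <- NA_real_
  summary$window_fraction <- NA_real_
  for (k in seq_len(nrow(cells))) {
    p <- base
    p$internode_means <- base$internode_means * cells$internode_scale[k]
    p$torsion_mean <- base$torsion_mean * cells$torsion_scale[k]
    pop <- simulate_population(p)
    g <- population_bin_grid(pop, bin_width)
    marg <- rowSums(g$counts) + colSums(g$counts)
    summary$modal_bin[k] <- g$centers[which.max(marg)]
    summary$window_fraction[k] <-
      sum(g$counts[g$window_bins, g$window_bins]) / g$n_pairs
    grids[[k]] <- g
  }
  structure(list(summary = summary, grids = grids, bin_width = bin_width),
            class = "torsion_sweep")
}

#' @export
print.torsion_sweep <- function(x, ...) {
  cat("<torsion_sweep>\n")
  print(x$summary)
  invisible(x)
}
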