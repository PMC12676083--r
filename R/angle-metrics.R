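#' @title Circular divergence-angle bookkeeping
#' @description Helpers shared by the binning and window statistics. Angles
#'   live in degrees in `[0, 360)` throughout the public data model; radians
#'   appear only inside trigonometric evaluation.
#' @name angle-metrics
NULL

wrap360 <- function(x) x %% 360

#' Express a divergence angle along the plant's own spiral direction
#'
#' Divergence angles are measured in one fixed world rotation sense (say,
#' clockwise viewed from above). For a plant whose spiral opposes that sense,
#' a golden-angle step reads as 360 - 137.5 = 222.5 degrees in the world
#' frame. Normalization reflects such angles so a golden-angle step maps near
#' 137.5 degrees regardless of chirality, which is what makes heatmaps of
#' clockwise and counterclockwise plants comparable.
#'
#' @param raw_angle Angle(s) in degrees in `[0, 360)`, measured in the fixed
#'   world sense.
#' @param plant_chirality `"CW"` or `"CCW"`; `"ambiguous"` is refused — the
#'   caller must exclude such plants.
#' @param measurement_sense The world rotation sense the raw angles were
#'   measured in (default `"CW"`).
#' @return Angle(s) in degrees in `[0, 360)` along the plant's own spiral.
#' @export
#' @examples
#' normalize_divergence(222.5, "CCW")  # 137.5
#' normalize_divergence(137.5, "CW")   # unchanged
normalize_divergence <- function(raw_angle, plant_chirality,
                                 measurement_sense = c("CW", "CCW")) {
  measurement_sense <- match.arg(measurement_sense)
  if (length(plant_chirality) != 1L ||
      !plant_chirality %in% c("CW", "CCW")) {
    stop("plant_chirality must be 'CW' or 'CCW'; ambiguous plants are excluded")
  }
  raw_angle <- as.numeric(raw_angle)
  if (any(raw_angle < 0 | raw_angle >= 360)) {
    stop("raw angles must be in [0, 360)")
  }
  if (plant_chirality == measurement_sense) raw_angle
  else wrap360(360 - raw_angle)
}

#' Assign spiral chirality from per-step rotation directions
#'
#' The plant's chirality is the strict majority of its per-step rotation
#' directions; an exact tie yields `"ambiguous"` and the plant is dropped
#' from chirality-stratified analyses.
#'
#' @param step_directions Non-empty character vector of `"CW"`/`"CCW"`.
#' @return `"CW"`, `"CCW"` or `"ambiguous"`.
#' @export
#' @examples
#' assign_chirality(c("CW", "CW", "CCW"))  # "CW"
#' assign_chirality(c("CW", "CCW"))        # "ambiguous"
assign_chirality <- function(step_directions) {
  if (length(step_directions) == 0L) stop("step_directions must be non-empty")
  if (!all(step_directions %in% c("CW", "CCW"))) {
    stop("step_directions must be 'CW' or 'CCW'")
  }
  n_cw <- sum(step_directions == "CW")
  n_ccw <- length(step_directions) - n_cw
  if (n_cw > n_ccw) "CW" else if (n_ccw > n_cw) "CCW" else "ambiguous"
}

#' Flag M-shaped motif triplets
#'
#' An M-shaped motif is the divergence-angle signature of a permutation in
#' the order of two organs along the stem: a triplet with angle i >= 202.5,
#' angle i+1 > 180 (strict), angle i+2 >= 202.5. The scan is greedy
#' left-to-right and non-overlapping: the three angles of a flagged triplet
#' cannot seed another flag.
#'
#' @param angles Numeric vector of divergence angles in degrees `[0, 360)`.
#' @return Integer vector of 1-based start indices of flagged triplets
#'   (empty when fewer than 3 angles).
#' @export
#' @examples
#' flag_m_motifs(c(210, 190, 205))            # 1
#' flag_m_motifs(c(202.5, 180, 202.5))        # integer(0): middle test strict
flag_m_motifs <- function(angles) {
  angles <- as.numeric(angles)
  n <- length(angles)
  out <- integer(0)
  i <- 1L
  while (i <= n - 2L) {
    if (angles[i] >= 202.5 && angles[i + 1L] > 180 && angles[i + 2L] >= 202.5) {
      out <- c(out, i)
      i <- i + 3L
    } else {
      i <- i + 1L
    }
  }
  out
}

#' Map angles to bin indices on a circular grid
#'
#' Bin centers sit at integer multiples of `bin_width` starting at 0; the bin
#' for an angle x is the half-open interval `[c - w/2, c + w/2)` around the
#' center c, wrapping across 0/360. For widths that tile 360 exactly (22.5,
#' 45, ...) this is the circular nearest-center rule. Widths like 12.5 or
#' 6.25 do not tile 360 evenly; the leftover arc just below 360 is folded
#' into the bin centred on 0, which never affects bins near the golden angle.
#'
#' @param angles Numeric angles in degrees.
#' @param bin_width Bin width in degrees, in `(0, 120]` so the 3-bin
#'   golden-angle window exists.
#' @return 1-based bin indices into `angle_bin_centers(bin_width)`.
#' @keywords internal
angle_bin_index <- function(angles, bin_width) {
  n_bins <- check_bin_width(bin_width)
  idx <- as.integer(floor((wrap360(angles) + bin_width / 2) / bin_width)) + 1L
  idx[idx > n_bins] <- 1L
  idx
}

check_bin_width <- function(bin_width) {
  if (length(bin_width) != 1L || !is.finite(bin_width) ||
      bin_width <= 0 || bin_width > 120) {
    stop("bin_width must be a single number in (0, 120]")
  }
  as.integer(ceiling(360 / bin_width - 1e-9))
}

#' Bin centers for a circular grid
#' @inheritParams angle_bin_index
#' @return Numeric vector of centers at `k * bin_width`, k = 0 ... 360/w - 1.
#' @export
angle_bin_centers <- function(bin_width) {
  n_bins <- check_bin_width(bin_width)
  (seq_len(n_bins) - 1L) * bin_width
}

#' Indices of the 3-bin golden-angle window
#'
#' The window is the bin containing the golden angle (137.5 degrees) plus one
#' neighbor each side. For widths 22.5 / 12.5 / 6.25 degrees this spans
#' `[101.25, 168.75)` / `[118.75, 156.25)` / `[128.125, 146.875)`.
#'
#' @inheritParams angle_bin_index
#' @return Integer vector of 3 bin indices (wrapping on the circle).
#' @export
golden_window_bins <- function(bin_width) {
  n_bins <- check_bin_width(bin_width)
  mid <- angle_bin_index(137.5, bin_width)
  idx <- ((mid - 2L):(mid)) %% n_bins + 1L
  idx
}

#' 2D binning of consecutive divergence-angle pairs
#'
#' Each consecutive pair (angle i, angle i+1) increments one cell of a square
#' count matrix: the row is the bin of angle i, the column the bin of angle
#' i+1. This is the package's heatmap object; the golden-angle window marks
#' the 3 x 3 block of cells where both members of a pair sit within one bin
#' of the golden angle.
#'
#' @param angles Ordered numeric vector of at least 2 divergence angles in
#'   degrees `[0, 360)`.
#' @param bin_width Bin width in degrees (commonly 22.5, 12.5 or 6.25).
#' @return An object of class `bin_grid2d`: list with `bin_width`, `centers`,
#'   `counts` (square matrix, rows = angle i, cols = angle i+1),
#'   `window_bins` (3 indices), `window_edges` (degrees, `[lo, hi)`) and
#'   `n_pairs`.
#' @export
#' @examples
#' g <- bin_pairs(c(137.5, 140, 135, 90, 137), 22.5)
#' g$n_pairs        # 4
#' sum(g$counts)    # 4
bin_pairs <- function(angles, bin_width) {
  angles <- as.numeric(angles)
  if (length(angles) < 2L) stop("need at least 2 angles to form pairs")
  n_bins <- check_bin_width(bin_width)
  centers <- angle_bin_centers(bin_width)
  idx <- angle_bin_index(angles, bin_width)
  i1 <- idx[-length(idx)]
  i2 <- idx[-1L]
  counts <- matrix(0L, n_bins, n_bins, dimnames = list(centers, centers))
  for (k in seq_along(i1)) {
    counts[i1[k], i2[k]] <- counts[i1[k], i2[k]] + 1L
  }
  win <- golden_window_bins(bin_width)
  mid_center <- centers[angle_bin_index(137.5, bin_width)]
  structure(
    list(bin_width = bin_width, centers = centers, counts = counts,
         window_bins = win,
         window_edges = c(mid_center - 1.5 * bin_width,
                          mid_center + 1.5 * bin_width),
         n_pairs = length(i1)),
    class = "bin_grid2d"
  )
}

#' @export
print.bin_grid2d <- function(x, ...) {
  inwin <- sum(x$counts[x$window_bins, x$window_bins])
  cat(sprintf(
    "<bin_grid2d> %g deg bins (%d x %d), %d pairs; golden window [%g, %g): %.1f%% of pairs\n",
    x$bin_width, nrow(x$counts), ncol(x$counts), x$n_pairs,
    x$window_edges[1], x$window_edges[2],
    if (x$n_pairs > 0) 100 * inwin / x$n_pairs else NA_real_))
  invisible(x)
}

#' @export
#' @importFrom graphics image abline axis box
#' @importFrom grDevices hcl.colors
plot.bin_grid2d <- function(x, main = "Consecutive divergence-angle pairs", ...) {
  w <- x$bin_width
  edges <- c(x$centers - w / 2, max(x$centers) + w / 2)
  image(edges, edges, x$counts, col = hcl.colors(64, "YlOrRd", rev = TRUE),
        xlab = "angle i (deg)", ylab = "angle i + 1 (deg)", main = main,
        axes = FALSE, ...)
  axis(1); axis(2); box()
  abline(v = x$window_edges, h = x$window_edges, lty = 2)
  invisible(x)
}

#' Fraction of consecutive angle pairs inside the golden window
#'
#' The per-plant regularity statistic: the fraction of consecutive divergence
#' angle pairs in which BOTH members fall inside the 3-bin golden-angle
#' window.
#'
#' @param series An [organ_series()] or a numeric vector of
#'   chirality-normalized angles (degrees).
#' @param bin_width Bin width in degrees (default 22.5).
#' @return Fraction in `[0, 1]`.
#' @export
#' @examples
#' window_pair_fraction(c(135, 135, 200), 22.5)  # 0.5
window_pair_fraction <- function(series, bin_width = 22.5) {
  angles <- if (inherits(series, "organ_series")) series$angles else
    as.numeric(series)
  if (length(angles) < 2L) {
    stop("window_pair_fraction is undefined for fewer than 2 angles")
  }
  idx <- angle_bin_index(angles, bin_width)
  win <- golden_window_bins(bin_width)
  inwin <- idx %in% win
  pair_in <- inwin[-length(inwin)] & inwin[-1L]
  mean(pair_in)
}

#' Proportion of extreme divergence angles
#'
#' Extreme angles deviate more than 27.5 degrees from the golden angle:
#' strictly below 110 or strictly above 165 degrees. Typically applied to
#' the angles at one fixed leaf-pair index across plants.
#'
#' @param angles Non-empty numeric vector of divergence angles (degrees).
#' @param lower,upper Strict cutoffs (defaults 110 and 165).
#' @return Proportion in `[0, 1]`.
#' @export
#' @examples
#' extreme_angle_fraction(c(100, 137.5, 170, 140))  # 0.5
extreme_angle_fraction <- function(angles, lower = 110, upper = 165) {
  angles <- as.numeric(angles)
  if (length(angles) == 0L) stop("extreme_angle_fraction needs at least one angle")
  mean(angles < lower | angles > upper)
}

#' Per-leaf-pair mean and SEM of divergence angle
#'
#' Aligns a set of rosette series by leaf-pair index (pair k = leaves k and
#' k+1) and reports the arithmetic mean and standard error of the mean per
#' index. Indices observed in a single plant report `NA` SEM.
#'
#' @param series_set List of [organ_series()] objects or numeric vectors,
#'   each ordered by leaf-pair index.
#' @return Data frame with columns `pair`, `n`, `mean`, `sem`.
#' @export
leafpair_profile <- function(series_set) {
  angle_list <- lapply(series_set, function(s) {
    if (inherits(s, "organ_series")) s$angles else as.numeric(s)
  })
  max_len <- max(lengths(angle_list))
  out <- data.frame(pair = seq_len(max_len), n = 0L,
                    mean = NA_real_, sem = NA_real_)
  for (k in seq_len(max_len)) {
    vals <- unlist(lapply(angle_list, function(a) if (length(a) >= k) a[k] else NULL))
    out$n[k] <- length(vals)
    out$mean[k] <- mean(vals)
    out$sem[k] <- if (length(vals) > 1L) stats::sd(vals) / sqrt(length(vals)) else NA_real_
  }
  out
}
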