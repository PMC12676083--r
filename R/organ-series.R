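#' Ordered divergence-angle series for one plant
#'
#' The central measurement record: one plant's ordered, chirality-normalized
#' divergence angles (degrees, measured along the plant's own spiral
#' direction), together with organ type, chirality and genotype. Raw
#' per-step rotation directions may be kept alongside for provenance.
#'
#' @param plant_id Opaque plant identifier.
#' @param angles Numeric vector of divergence angles in degrees, each in
#'   `[0, 360)`, ordered acropetally (base to apex).
#' @param organ_type One of `"rosette_leaf"`, `"flower"`, `"primordium"`.
#' @param chirality One of `"CW"`, `"CCW"`, `"ambiguous"` — the handedness of
#'   the plant's phyllotactic spiral viewed from above. Ambiguous plants are
#'   excluded from every chirality-stratified analysis.
#' @param step_directions Optional character vector (`"CW"`/`"CCW"`), one per
#'   angle, giving the raw measured rotation direction of each organ step.
#' @param genotype Genotype label.
#'
#' @return An object of class `organ_series`.
#' @seealso [inflorescence_record()], [assign_chirality()],
#'   [normalize_divergence()]
#' @export
#' @examples
#' organ_series("p1", c(137.5, 140.2, 133.0), organ_type = "flower",
#'              chirality = "CW")
organ_series <- function(plant_id, angles,
                         organ_type = c("flower", "rosette_leaf", "primordium"),
                         chirality = c("CW", "CCW", "ambiguous"),
                         step_directions = NULL, genotype = "unknown") {
  organ_type <- match.arg(organ_type)
  chirality <- match.arg(chirality)
  angles <- as.numeric(angles)
  if (any(!is.finite(angles)) || any(angles < 0) || any(angles >= 360)) {
    stop("all divergence angles must be finite and in [0, 360)")
  }
  if (!is.null(step_directions)) {
    step_directions <- as.character(step_directions)
    if (length(step_directions) != length(angles)) {
      stop("step_directions must have one entry per angle")
    }
    if (!all(step_directions %in% c("CW", "CCW"))) {
      stop("step_directions must be 'CW' or 'CCW'")
    }
  }
  structure(
    list(plant_id = plant_id, organ_type = organ_type, chirality = chirality,
         angles = angles, step_directions = step_directions,
         genotype = genotype),
    class = "organ_series"
  )
}

#' @export
print.organ_series <- function(x, ...) {
  cat(sprintf("<organ_series> plant %s (%s, %s, %s): %d angles\n",
              x$plant_id, x$genotype, x$organ_type, x$chirality,
              length(x$angles)))
  invisible(x)
}

#' Inflorescence record: angles paired with internodes
#'
#' Extends an [organ_series()] with per-internode lengths, node positions and
#' optional local stem radii. The pairing convention is positional: the
#' divergence angle between organs k and k+1 pairs with the internode
#' separating those two organs, so angles and internode lengths have equal
#' length.
#'
#' @param series An [organ_series()].
#' @param internode_lengths Numeric vector of internode lengths (mm), all
#'   `>= 0`, one per divergence angle.
#' @param node_positions Strictly increasing 1-based node indices counted
#'   acropetally from the stem base; defaults to `seq_along(angles)`.
#' @param radii Optional local stem radii (mm), one per internode.
#' @param height_mm,age_days Optional plant metadata.
#'
#' @return An object of class `inflorescence_record`.
#' @export
inflorescence_record <- function(series, internode_lengths,
                                 node_positions = NULL, radii = NULL,
                                 height_mm = NA_real_, age_days = NA_real_) {
  stopifnot(inherits(series, "organ_series"))
  internode_lengths <- as.numeric(internode_lengths)
  if (any(internode_lengths < 0, na.rm = TRUE)) {
    stop("internode lengths must be >= 0")
  }
  if (length(internode_lengths) != length(series$angles)) {
    stop("need one internode length per divergence angle (pairing convention)")
  }
  if (is.null(node_positions)) node_positions <- seq_along(series$angles)
  if (any(diff(node_positions) <= 0)) {
    stop("node_positions must be strictly increasing")
  }
  if (!is.null(radii) && length(radii) != length(internode_lengths)) {
    stop("radii must align with internode_lengths")
  }
  structure(
    list(series = series, internode_lengths = internode_lengths,
         node_positions = as.integer(node_positions), radii = radii,
         height_mm = height_mm, age_days = age_days),
    class = "inflorescence_record"
  )
}

#' @export
print.inflorescence_record <- function(x, ...) {
  cat(sprintf("<inflorescence_record> plant %s (%s): %d angle/internode pairs\n",
              x$series$plant_id, x$series$chirality,
              length(x$internode_lengths)))
  invisible(x)
}
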