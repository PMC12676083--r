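#' Chirality-stratified divergence-angle vs internode-length regression
#'
#' Under counterclockwise stem torsion, longer internodes displace divergence
#' angles further — downwards in clockwise spirals, upwards in
#' counterclockwise ones — so a chirality-stratified regression of divergence
#' angle on internode length estimates the torsion displacement rate
#' (180/pi) * tan(alpha) / r in degrees per mm (with sign set by chirality).
#'
#' Internode lengths are binned at `internode_bin_width`; bins holding fewer
#' than `min_per_bin` angle/internode pairs are dropped; the per-bin mean
#' divergence angle is regressed on the bin-center internode length by
#' unweighted OLS, as the heatmap figures are constructed. Raw-pair
#' regression is available with `use_bins = FALSE`. When `apply_m_filter` is
#' set, M-shaped motif triplets ([flag_m_motifs()]) are removed first: none
#' of the three angles of a flagged triplet contributes to any bin.
#'
#' @param records List of [inflorescence_record()]s sharing one chirality
#'   class, or a `simulated_population`.
#' @param internode_bin_width Bin width in mm (0.1 for inflorescence-scale
#'   data, 0.01 for meristem-scale).
#' @param min_per_bin Minimum pairs a bin needs to be kept (4 at 0.1 mm, 2 at
#'   0.01 mm in typical use).
#' @param chirality `"CW"` or `"CCW"`; records of other chirality are
#'   excluded (ambiguous plants never enter).
#' @param apply_m_filter Remove M-shaped motif triplets before pairing
#'   (default TRUE — the motif filter belongs to this analysis only).
#' @param use_bins Regress on bin means (default) or on raw pairs.
#' @return Object of class `div_intern_fit`: slope (deg/mm), intercept,
#'   `pearson_r`, two-sided `p_value`, `slope_se`, `n_bins`, `n_pairs`,
#'   `bins` (data frame center/mean/n) and `ci95_band` (per-bin lower/upper
#'   confidence bounds of the fitted line).
#' @export
divergence_vs_internode <- function(records, internode_bin_width = 0.1,
                                    min_per_bin = 4,
                                    chirality = c("CW", "CCW"),
                                    apply_m_filter = TRUE, use_bins = TRUE) {
  chirality <- match.arg(chirality)
  if (inherits(records, "simulated_population")) records <- records$records
  if (inherits(records, "inflorescence_record")) records <- list(records)
  records <- Filter(function(r) r$series$chirality == chirality, records)
  if (length(records) == 0L) stop("no records in the requested chirality class")
  angles <- numeric(0)
  internodes <- numeric(0)
  for (r in records) {
    a <- r$series$angles
    keep <- rep(TRUE, length(a))
    if (apply_m_filter) {
      for (s in flag_m_motifs(a)) keep[s:(s + 2L)] <- FALSE
    }
    angles <- c(angles, a[keep])
    internodes <- c(internodes, r$internode_lengths[keep])
  }
  ok <- is.finite(angles) & is.finite(internodes)
  angles <- angles[ok]; internodes <- internodes[ok]
  if (use_bins) {
    bin <- floor(internodes / internode_bin_width)
    centers <- (as.numeric(names(table(bin))) + 0.5) * internode_bin_width
    counts <- as.integer(table(bin))
    means <- tapply(angles, bin, mean)
    keep <- counts >= min_per_bin
    bins <- data.frame(center = centers[keep], mean = as.numeric(means[keep]),
                       n = counts[keep])
    if (nrow(bins) < 3L) {
      stop("fewer than 3 internode bins survive min_per_bin; regression refused")
    }
    x <- bins$center; y <- bins$mean
  } else {
    if (length(angles) < 3L) stop("fewer than 3 pairs; regression refused")
    bins <- data.frame(center = internodes, mean = angles, n = 1L)
    x <- internodes; y <- angles
  }
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  band <- stats::predict(fit, newdata = data.frame(x = x),
                         interval = "confidence", level = 0.95)
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         slope_se = summary(fit)$coefficients[2, 2],
         pearson_r = unname(ct$estimate), p_value = ct$p.value,
         n_bins = length(x), n_pairs = length(angles),
         chirality = chirality, bins = bins,
         ci95_band = data.frame(x = x, lower = band[, "lwr"],
                                upper = band[, "upr"]),
         fit = fit),
    class = "div_intern_fit"
  )
}

#' @export
print.div_intern_fit <- function(x, ...) {
  cat(sprintf(
    "<div_intern_fit> %s: slope %.3f deg/mm (SE %.3f), r = %.3f, p = %.3g, %d bins (%d pairs)\n",
    x$chirality, x$slope, x$slope_se, x$pearson_r, x$p_value, x$n_bins,
    x$n_pairs))
  invisible(x)
}

#' Group comparisons with explicit tails and BH adjustment
#'
#' Welch's t (unequal variances) for normally distributed groups, Wilcoxon
#' rank-sum otherwise, or one-way ANOVA followed by Tukey's post-hoc tests
#' for multiple normal groups. With more than two groups under Welch or
#' Wilcoxon, all pairwise comparisons are run and Benjamini-Hochberg-adjusted
#' as one family. Tails must be declared explicitly per hypothesis and are
#' never inferred.
#'
#' @param x Numeric values.
#' @param g Group labels, same length as `x` (at least 2 groups).
#' @param test `"welch_t"`, `"wilcoxon"` or `"anova_tukey"`.
#' @param tail `"two"`, `"left"` or `"right"` (first group relative to
#'   second); ignored by `anova_tukey`, whose Tukey p-values are inherently
#'   two-sided.
#' @return Data frame of class `test_result`: one row per comparison with
#'   `test_name`, `groups`, `statistic`, `p_raw`, `p_bh`, `tail`, `n`.
#' @export
compare_groups <- function(x, g, test = c("welch_t", "wilcoxon", "anova_tukey"),
                           tail = c("two", "left", "right")) {
  test <- match.arg(test)
  tail <- match.arg(tail)
  g <- factor(g)
  if (nlevels(g) < 2L) stop("need at least 2 groups")
  alt <- switch(tail, two = "two.sided", left = "less", right = "greater")
  if (test == "anova_tukey") {
    fit <- stats::aov(x ~ g)
    tk <- stats::TukeyHSD(fit)$g
    out <- data.frame(test_name = "anova_tukey", groups = rownames(tk),
                      statistic = tk[, "diff"], p_raw = tk[, "p adj"],
                      p_bh = tk[, "p adj"], tail = "two",
                      n = length(x), row.names = NULL)
  } else {
    lev <- levels(g)
    pairs <- utils::combn(lev, 2, simplify = FALSE)
    rows <- lapply(pairs, function(pr) {
      x1 <- x[g == pr[1]]; x2 <- x[g == pr[2]]
      if (test == "welch_t") {
        if (length(x1) < 2L || length(x2) < 2L) {
          stop("Welch's t-test needs at least 2 observations per group")
        }
        tt <- stats::t.test(x1, x2, alternative = alt, var.equal = FALSE)
      } else {
        tt <- stats::wilcox.test(x1, x2, alternative = alt, exact = FALSE)
      }
      data.frame(test_name = test, groups = paste(pr, collapse = "-"),
                 statistic = unname(tt$statistic), p_raw = tt$p.value,
                 tail = tail, n = length(x1) + length(x2))
    })
    out <- do.call(rbind, rows)
    out$p_bh <- stats::p.adjust(out$p_raw, method = "BH")
    out <- out[, c("test_name", "groups", "statistic", "p_raw", "p_bh",
                   "tail", "n")]
  }
  class(out) <- c("test_result", class(out))
  out
}

#' Two-proportion z-test with Yates continuity correction
#'
#' Pooled two-proportion comparison with continuity correction, the test used
#' for percentage and proportion contrasts throughout the analysis.
#'
#' @param x1,n1 Successes and trials in group 1.
#' @param x2,n2 Successes and trials in group 2.
#' @param tail `"two"`, `"left"` or `"right"` (p1 relative to p2).
#' @return One-row `test_result` data frame; `statistic` is the signed z.
#' @export
#' @examples
#' two_proportion_test(79, 100, 41, 100)$p_raw  # < 0.001
two_proportion_test <- function(x1, n1, x2, n2,
                                tail = c("two", "left", "right")) {
  tail <- match.arg(tail)
  if (n1 <= 0 || n2 <= 0) stop("group sizes must be positive")
  if (x1 < 0 || x1 > n1 || x2 < 0 || x2 > n2) stop("need 0 <= x <= n")
  alt <- switch(tail, two = "two.sided", left = "less", right = "greater")
  if (x1 / n1 == x2 / n2 && (x1 == 0 || x1 == n1)) {
    # degenerate equality at the boundary: chi-square is 0/0, p floors at 1
    p <- 1; z <- 0
  } else {
    pt <- suppressWarnings(
      stats::prop.test(c(x1, x2), c(n1, n2), alternative = alt, correct = TRUE))
    p <- pt$p.value
    z <- sign(x1 / n1 - x2 / n2) * sqrt(unname(pt$statistic))
  }
  out <- data.frame(test_name = "two_proportion_z_yates",
                    groups = sprintf("%d/%d vs %d/%d", x1, n1, x2, n2),
                    statistic = z, p_raw = p, p_bh = p,
                    tail = tail, n = n1 + n2)
  class(out) <- c("test_result", class(out))
  out
}

#' Growth metrics: plastochron, bolting and synchronized elongation
#'
#' Summarizes an event table of organ counts and/or heights over days for one
#' plant. The plastochron is elapsed time per organ initiated over a stated
#' organ range; bolting is the first observation at or above a height
#' threshold; elongation series can be re-zeroed ("synchronized") to the
#' first observation at or above a threshold height so growth curves of
#' plants bolting on different days are comparable.
#'
#' @param days Observation days (numeric, increasing).
#' @param organ_counts Optional monotone non-decreasing organ counts.
#' @param heights Optional heights (same units as the thresholds, e.g. cm).
#' @param organ_range Optional `c(from, to)` organ counts delimiting the
#'   plastochron window (e.g. `c(3, 15)` for rosette leaves 3-15); default
#'   uses the full observed range.
#' @param sync_threshold Optional height threshold (e.g. 1.5 cm) at which
#'   day 0 is re-zeroed.
#' @return List with `plastochron` (days/organ), `bolting_day`,
#'   `leaves_at_bolting`, `growth_rate` (height units/day over the
#'   synchronized series) and `sync_day0_index`.
#' @export
#' @examples
#' growth_metrics(days = 0:12, organ_counts = 3:15)$plastochron  # 1
growth_metrics <- function(days, organ_counts = NULL, heights = NULL,
                           organ_range = NULL, sync_threshold = NULL) {
  days <- as.numeric(days)
  out <- list(plastochron = NA_real_, bolting_day = NA_real_,
              leaves_at_bolting = NA_real_, growth_rate = NA_real_,
              sync_day0_index = NA_integer_)
  if (!is.null(organ_counts)) {
    if (length(organ_counts) != length(days)) stop("organ_counts must align with days")
    if (any(diff(organ_counts) < 0)) {
      stop("organ counts must be monotone non-decreasing")
    }
    if (is.null(organ_range)) organ_range <- range(organ_counts)
    i_from <- which(organ_counts >= organ_range[1])[1]
    i_to <- which(organ_counts >= organ_range[2])[1]
    if (is.na(i_from) || is.na(i_to)) {
      stop("organ_range not covered by the observed counts")
    }
    n_initiated <- organ_counts[i_to] - organ_counts[i_from]
    if (n_initiated <= 0) stop("no organs initiated over the stated range")
    out$plastochron <- (days[i_to] - days[i_from]) / n_initiated
  }
  if (!is.null(heights)) {
    if (length(heights) != length(days)) stop("heights must align with days")
    bolt <- which(heights > 0)[1]
    if (!is.na(bolt)) {
      out$bolting_day <- days[bolt]
      if (!is.null(organ_counts)) out$leaves_at_bolting <- organ_counts[bolt]
    }
    if (!is.null(sync_threshold)) {
      i0 <- which(heights >= sync_threshold)[1]
      out$sync_day0_index <- i0
      if (!is.na(i0) && i0 < length(days)) {
        sel <- i0:length(days)
        out$growth_rate <- unname(stats::coef(
          stats::lm(heights[sel] ~ days[sel]))[2])
      }
    }
  }
  out
}
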