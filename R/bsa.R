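#' Haldane map function
#'
#' Recombination fraction between two loci separated by a genetic distance of
#' `d` Morgans, assuming crossovers occur as a Poisson process (no
#' interference): c(d) = (1 - exp(-2d)) / 2.
#'
#' @param d Genetic distance(s) in Morgans (>= 0).
#' @return Recombination fraction(s) in `[0, 0.5)`.
#' @export
haldane_c <- function(d) {
  if (any(d < 0)) stop("map distance must be >= 0")
  0.5 * (1 - exp(-2 * d))
}

#' Expected wild-type allele frequency in a BC1F2 bulk-segregant pool
#'
#' For a recessive causal allele mapped in the selfed progeny of a first
#' backcross (BC1F2), two pools are sequenced: a phenotype-positive pool of
#' homozygous mutants, and a phenotype-negative pool of wild-type and
#' heterozygous plants. At the causal locus the wild-type allele frequency is
#' 0 in the positive pool and 2/3 in the negative pool; at a marker a map
#' distance `d` away (Haldane recombination fraction c), it is c and
#' (2 - c)/3 respectively. An unselected marker segregates 1:2:1 and sits at
#' 1/2.
#'
#' @param pool `"pheno_plus"`, `"pheno_minus"` or `"unselected"`.
#' @param map_distance_morgans Distance from the causal locus in Morgans
#'   (default 0, i.e. the causal locus itself). Ignored for `"unselected"`.
#' @param scheme Cross design; only `"BC1F2_recessive"` is defined.
#' @return Expected wild-type (reference) allele frequency.
#' @export
#' @examples
#' expected_wt_af("pheno_minus")  # 2/3, prints as 0.67
#' expected_wt_af("pheno_plus")   # 0
#' expected_wt_af("pheno_plus", map_distance_morgans = Inf)  # 0.5
expected_wt_af <- function(pool = c("pheno_minus", "pheno_plus", "unselected"),
                           map_distance_morgans = 0,
                           scheme = "BC1F2_recessive") {
  pool <- match.arg(pool)
  if (!identical(scheme, "BC1F2_recessive")) {
    stop("unknown cross scheme: ", scheme)
  }
  cc <- haldane_c(map_distance_morgans)
  switch(pool,
         pheno_plus = cc,
         pheno_minus = (2 - cc) / 3,
         unselected = rep(0.5, length(cc)))
}

#' Thresholds of the bulk-segregant candidate filter
#'
#' @param min_depth,max_depth Inclusive window on the per-pool total allele
#'   depth (ref + alt), applied to both pools.
#' @param wt_af_minus_range Inclusive window on the wild-type allele
#'   frequency in the phenotype-negative pool.
#' @param wt_af_plus_max Strict upper bound on the wild-type allele frequency
#'   in the phenotype-positive pool.
#' @param biallelic_only Drop multi-allelic records entirely.
#' @param depth_mode `"total"` applies the depth window to ref + alt per
#'   pool; `"per_allele"` requires each of ref and alt depth within the
#'   window in both pools (an alternative reading of a depth filter).
#' @return A list of class `filter_thresholds`.
#' @export
filter_thresholds <- function(min_depth = 10, max_depth = 500,
                              wt_af_minus_range = c(0.30, 0.90),
                              wt_af_plus_max = 0.05, biallelic_only = TRUE,
                              depth_mode = c("total", "per_allele")) {
  depth_mode <- match.arg(depth_mode)
  stopifnot(min_depth <= max_depth, length(wt_af_minus_range) == 2L,
            all(wt_af_minus_range >= 0), all(wt_af_minus_range <= 1),
            wt_af_plus_max >= 0, wt_af_plus_max <= 1)
  structure(list(min_depth = min_depth, max_depth = max_depth,
                 wt_af_minus_range = wt_af_minus_range,
                 wt_af_plus_max = wt_af_plus_max,
                 biallelic_only = biallelic_only, depth_mode = depth_mode),
            class = "filter_thresholds")
}

#' Flag variants present in the backcross-parent variant set
#'
#' Marks each variant whose (chrom, pos, ref, alt) exactly matches a parent
#' variant; flagged variants are excluded downstream, leaving only mutations
#' novel to the mutagenized line.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`.
#' @param parent_variants Data frame with the same four columns (may be
#'   empty).
#' @return `variants` with a logical `in_parent` column set.
#' @export
subtract_parent_variants <- function(variants, parent_variants) {
  key <- function(d) paste(d$chrom, d$pos, d$ref, d$alt, sep = ":")
  variants$in_parent <- if (is.null(parent_variants) ||
                            nrow(parent_variants) == 0L) {
    rep(FALSE, nrow(variants))
  } else {
    key(variants) %in% key(parent_variants)
  }
  variants
}

pool_wt_af <- function(ad_ref, ad_alt) {
  depth <- ad_ref + ad_alt
  ifelse(depth > 0, ad_ref / depth, NA_real_)
}

#' Filter two-pool variants for recessive causal-allele candidates
#'
#' Applies the candidate filter chain to a two-pool variant table: keep
#' variants that are biallelic, absent from the backcross parent, have total
#' allele depth within the inclusive depth window in both pools, wild-type
#' allele frequency within the inclusive phenotype-negative window, and
#' wild-type allele frequency strictly below the phenotype-positive cutoff.
#' Zero-depth variants are excluded with a reason, never an error.
#'
#' @param variants Data frame with columns `chrom`, `pos`, `ref`, `alt`,
#'   `biallelic` (logical), `ad_ref_minus`, `ad_alt_minus`, `ad_ref_plus`,
#'   `ad_alt_plus`, and optionally `in_parent` (assumed FALSE when absent).
#' @param thresholds A [filter_thresholds()] object.
#' @param return_all Return every variant annotated with `pass` and `reason`
#'   columns instead of the passing subset.
#' @return The passing variants (with per-pool `wt_af_minus` / `wt_af_plus`
#'   columns added), or the fully annotated table when `return_all = TRUE`.
#' @export
filter_candidates <- function(variants, thresholds = filter_thresholds(),
                              return_all = FALSE) {
  stopifnot(inherits(thresholds, "filter_thresholds"))
  need <- c("chrom", "pos", "ref", "alt", "biallelic",
            "ad_ref_minus", "ad_alt_minus", "ad_ref_plus", "ad_alt_plus")
  missing_cols <- setdiff(need, names(variants))
  if (length(missing_cols) > 0L) {
    stop("variant table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  if (is.null(variants$in_parent)) variants$in_parent <- FALSE
  v <- variants
  v$depth_minus <- v$ad_ref_minus + v$ad_alt_minus
  v$depth_plus <- v$ad_ref_plus + v$ad_alt_plus
  v$wt_af_minus <- pool_wt_af(v$ad_ref_minus, v$ad_alt_minus)
  v$wt_af_plus <- pool_wt_af(v$ad_ref_plus, v$ad_alt_plus)
  th <- thresholds
  depth_ok <- if (th$depth_mode == "total") {
    v$depth_minus >= th$min_depth & v$depth_minus <= th$max_depth &
      v$depth_plus >= th$min_depth & v$depth_plus <= th$max_depth
  } else {
    v$ad_ref_minus >= th$min_depth & v$ad_ref_minus <= th$max_depth &
      v$ad_alt_minus >= th$min_depth & v$ad_alt_minus <= th$max_depth &
      v$ad_ref_plus >= th$min_depth & v$ad_ref_plus <= th$max_depth &
      v$ad_alt_plus >= th$min_depth & v$ad_alt_plus <= th$max_depth
  }
  reason <- rep(NA_character_, nrow(v))
  fail <- function(cond, why) ifelse(is.na(reason) & cond, why, reason)
  reason <- fail(th$biallelic_only & !v$biallelic, "multiallelic")
  reason <- fail(v$in_parent, "in_parent")
  reason <- fail(v$depth_minus == 0 | v$depth_plus == 0, "zero_depth")
  reason <- fail(!depth_ok, "depth_window")
  reason <- fail(is.na(v$wt_af_minus) | v$wt_af_minus < th$wt_af_minus_range[1] |
                   v$wt_af_minus > th$wt_af_minus_range[2], "wt_af_minus")
  reason <- fail(is.na(v$wt_af_plus) | v$wt_af_plus >= th$wt_af_plus_max,
                 "wt_af_plus")
  v$pass <- is.na(reason)
  v$reason <- reason
  if (return_all) v else v[v$pass, setdiff(names(v), c("pass", "reason"))]
}

#' Segregation check against a Mendelian recessive expectation
#'
#' Compares an observed affected count against the expected 1/4 proportion of
#' a recessive allele segregating in a selfed F2/BC1F2 family, using a
#' one-sample proportion z-test with continuity correction.
#'
#' @param observed_affected Number of affected plants.
#' @param total Total plants scored (> 0).
#' @param expected Expected affected proportion (default 0.25).
#' @return List with `observed_proportion`, `expected_proportion`, and a
#'   one-row `test_result` data frame under `test`.
#' @export
#' @examples
#' segregation_check(30, 118)$observed_proportion  # 0.254 (c. 25%)
#' segregation_check(22, 125)$observed_proportion  # 0.176 (c. 18%)
segregation_check <- function(observed_affected, total, expected = 0.25) {
  if (total <= 0) stop("total must be > 0")
  if (observed_affected < 0 || observed_affected > total) {
    stop("need 0 <= observed_affected <= total")
  }
  pt <- suppressWarnings(stats::prop.test(observed_affected, total,
                                          p = expected, correct = TRUE))
  z <- sign(observed_affected / total - expected) * sqrt(unname(pt$statistic))
  test <- data.frame(test_name = "one_proportion_z_yates",
                     groups = sprintf("%d/%d vs %.3g", observed_affected,
                                      total, expected),
                     statistic = z, p_raw = pt$p.value, p_bh = pt$p.value,
                     tail = "two", n = total)
  class(test) <- c("test_result", class(test))
  list(observed_proportion = observed_affected / total,
       expected_proportion = expected, test = test)
}
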