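test_that("Mendelian pool expectations under Haldane linkage", {
  expect_equal(expected_wt_af("pheno_minus"), 2 / 3)
  expect_equal(expected_wt_af("pheno_plus"), 0)
  expect_equal(expected_wt_af("unselected"), 0.5)
  # unlinked limit: c -> 1/2, both pools segregate 1:2:1
  expect_equal(expected_wt_af("pheno_plus", Inf), 0.5)
  expect_equal(expected_wt_af("pheno_minus", Inf), 0.5)
  expect_error(expected_wt_af("pheno_plus", scheme = "F2_dominant"), "scheme")

  d <- seq(0, 3, by = 0.05)
  expect_true(all(diff(expected_wt_af("pheno_plus", d)) > 0))   # 0 -> 1/2
  expect_true(all(diff(expected_wt_af("pheno_minus", d)) < 0))  # 2/3 -> 1/2
  expect_true(all(haldane_c(d) >= 0 & haldane_c(d) < 0.5))
  expect_error(haldane_c(-0.1), ">= 0")
})

test_that("parent subtraction flags exact (chrom,pos,ref,alt) matches only", {
  v <- data.frame(chrom = c("Chr1", "Chr1", "Chr2"), pos = c(100, 100, 100),
                  ref = c("C", "C", "G"), alt = c("T", "A", "A"))
  parent <- data.frame(chrom = "Chr1", pos = 100, ref = "C", alt = "T")
  out <- subtract_parent_variants(v, parent)
  expect_identical(out$in_parent, c(TRUE, FALSE, FALSE))
  none <- subtract_parent_variants(v, parent[0, ])
  expect_identical(none$in_parent, rep(FALSE, 3))
})

causal_like <- function(ad_ref_minus = 67, ad_alt_minus = 33,
                        ad_ref_plus = 0, ad_alt_plus = 100,
                        biallelic = TRUE, in_parent = FALSE) {
  data.frame(chrom = "Chr1", pos = 1000, ref = "C", alt = "T",
             biallelic = biallelic, ad_ref_minus = ad_ref_minus,
             ad_alt_minus = ad_alt_minus, ad_ref_plus = ad_ref_plus,
             ad_alt_plus = ad_alt_plus, in_parent = in_parent)
}

test_that("candidate filter applies every criterion with the stated boundaries", {
  expect_equal(nrow(filter_candidates(causal_like())), 1L)

  reason_of <- function(v) filter_candidates(v, return_all = TRUE)$reason
  # depth window inclusive at 10 and 500, per pool
  expect_equal(reason_of(causal_like(ad_ref_minus = 6, ad_alt_minus = 3)),
               "depth_window")
  expect_equal(nrow(filter_candidates(causal_like(ad_ref_minus = 7,
                                                  ad_alt_minus = 3))), 1L)
  expect_equal(nrow(filter_candidates(causal_like(ad_ref_plus = 0,
                                                  ad_alt_plus = 500))), 1L)
  expect_equal(reason_of(causal_like(ad_ref_plus = 0, ad_alt_plus = 501)),
               "depth_window")
  # pheno+ WT AF strict at 0.05
  expect_equal(reason_of(causal_like(ad_ref_plus = 5, ad_alt_plus = 95)),
               "wt_af_plus")
  expect_equal(nrow(filter_candidates(causal_like(ad_ref_plus = 4,
                                                  ad_alt_plus = 96))), 1L)
  # pheno- WT AF inclusive at both ends
  expect_equal(nrow(filter_candidates(causal_like(ad_ref_minus = 30,
                                                  ad_alt_minus = 70))), 1L)
  expect_equal(nrow(filter_candidates(causal_like(ad_ref_minus = 90,
                                                  ad_alt_minus = 10))), 1L)
  expect_equal(reason_of(causal_like(ad_ref_minus = 29, ad_alt_minus = 71)),
               "wt_af_minus")
  expect_equal(reason_of(causal_like(biallelic = FALSE)), "multiallelic")
  expect_equal(reason_of(causal_like(in_parent = TRUE)), "in_parent")
  # zero depth is an exclusion with reason, not an error
  expect_equal(reason_of(causal_like(ad_ref_plus = 0, ad_alt_plus = 0)),
               "zero_depth")
})

test_that("tightening any threshold never adds a passing variant", {
  set.seed(501)
  pools <- generate_bsa_pools(n_snps = 60, seed = 501,
                              causal_halo_morgans = 0.02)
  base <- filter_thresholds()
  passed <- filter_candidates(pools$variants, base)
  key <- function(d) paste(d$chrom, d$pos)
  tighter <- list(
    filter_thresholds(min_depth = 50),
    filter_thresholds(max_depth = 120),
    filter_thresholds(wt_af_minus_range = c(0.5, 0.8)),
    filter_thresholds(wt_af_plus_max = 0.01)
  )
  for (th in tighter) {
    expect_true(all(key(filter_candidates(pools$variants, th)) %in%
                      key(passed)))
  }
})

test_that("segregation check reproduces the worked Mendelian ratios", {
  s1 <- segregation_check(30, 118)
  expect_equal(s1$observed_proportion, 30 / 118)
  expect_equal(round(100 * s1$observed_proportion), 25)
  expect_equal(s1$expected_proportion, 0.25)
  expect_gt(s1$test$p_raw, 0.05)  # consistent with 1:3 recessive segregation

  s2 <- segregation_check(22, 125)
  expect_equal(round(100 * s2$observed_proportion), 18)
  expect_error(segregation_check(0, 0), "> 0")
})

test_that("synthetic pools carry the designed allele-frequency structure", {
  pools <- generate_bsa_pools(seed = 11)
  v <- pools$variants
  tr <- pools$truth
  # the planted causal variant: WT allele absent from the mutant pool
  expect_equal(tr$wt_af_plus, 0)
  causal_row <- v[v$chrom == tr$chrom & v$pos == tr$pos, ]
  expect_equal(causal_row$ad_ref_plus, 0L)
  expect_false(causal_row$in_parent)
  # pool composition at the causal locus: 30 plants, 1:2 WT:het in pheno-
  expect_gt(tr$wt_af_minus, 0.5)
  expect_lt(tr$wt_af_minus, 0.85)
  # determinism
  again <- generate_bsa_pools(seed = 11)
  expect_identical(pools$variants, again$variants)
  expect_false(identical(generate_bsa_pools(seed = 12)$variants, v))
})

test_that("run_bsa recovers the planted variant from a VCF round trip", {
  pools <- generate_bsa_pools(seed = 21)
  vcf <- tempfile(fileext = ".vcf")
  write_pool_vcf(pools$variants, vcf, seed = 21)
  reread <- read_pool_vcf(vcf)
  expect_equal(nrow(reread), nrow(pools$variants))
  expect_equal(reread$ad_ref_minus, pools$variants$ad_ref_minus)
  res <- run_bsa(vcf, parent_variants = pools$parent_variants)
  expect_true(any(res$candidates$chrom == pools$truth$chrom &
                    res$candidates$pos == pools$truth$pos))
  # parent-background variants never survive subtraction
  pk <- paste(pools$parent_variants$chrom, pools$parent_variants$pos)
  expect_false(any(paste(res$candidates$chrom, res$candidates$pos) %in% pk))
})
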