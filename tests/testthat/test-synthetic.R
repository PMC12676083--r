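test_that("noise-free spirals yield perfect window fractions end to end", {
  preset <- genotype_preset("custom", delta_i_sd = 0, torsion_mean_deg = 0,
                            torsion_sd_deg = 0, m_motif_rate = 0,
                            decussate_rate = 0)
  tab <- generate_inflorescence_dataset(preset, n_plants = 8, n_organs = 15,
                                        seed = 3)
  q <- run_quantify(tab)
  expect_true(all(q$window_fractions$window_fraction == 1))
  # pooled heatmap concentrated in the single golden bin
  expect_equal(sum(q$grid$counts), q$grid$counts["135", "135"])
})

test_that("generators are seed-deterministic", {
  p <- genotype_preset("plt")
  expect_identical(generate_inflorescence_dataset(p, 10, 12, seed = 5),
                   generate_inflorescence_dataset(p, 10, 12, seed = 5))
  expect_false(identical(
    generate_inflorescence_dataset(p, 10, 12, seed = 5)$raw_angle_deg,
    generate_inflorescence_dataset(p, 10, 12, seed = 6)$raw_angle_deg))
  expect_identical(generate_rosette_dataset(p, 10, 8, seed = 5),
                   generate_rosette_dataset(p, 10, 8, seed = 5))
})

test_that("noisier presets lower the mean per-plant window fraction", {
  mean_wf <- function(preset, seed) {
    tab <- generate_inflorescence_dataset(genotype_preset(preset),
                                          n_plants = 50, n_organs = 25,
                                          seed = seed)
    mean(run_quantify(tab)$window_fractions$window_fraction)
  }
  expect_gt(mean_wf("col0", 17), mean_wf("plt", 17))
})

test_that("decussate episodes occur at the configured per-plant rate", {
  preset <- genotype_preset("plt", decussate_rate = 0.10)
  tab <- generate_inflorescence_dataset(preset, n_plants = 500, n_organs = 20,
                                        seed = 29)
  hits <- sum(attr(tab, "decussate_plants"))
  ci <- binom.test(hits, 500)$conf.int
  expect_true(ci[1] <= 0.10 && 0.10 <= ci[2])
})

test_that("inserted M-motifs satisfy the flag criterion by construction", {
  preset <- genotype_preset("custom", delta_i_sd = 5, m_motif_rate = 0.3)
  tab <- generate_inflorescence_dataset(preset, n_plants = 30, n_organs = 20,
                                        seed = 31)
  recs <- suppressMessages(measurements_to_records(tab))
  n_flagged <- sum(vapply(recs, function(r) {
    length(flag_m_motifs(r$series$angles))
  }, integer(1)))
  expect_gt(n_flagged, 20)
})

test_that("raw world-frame output exercises chirality assignment and normalization", {
  preset <- genotype_preset("custom", delta_i_sd = 6, torsion_mean_deg = 0,
                            torsion_sd_deg = 0, m_motif_rate = 0)
  tab <- generate_inflorescence_dataset(preset, n_plants = 40, n_organs = 20,
                                        seed = 37)
  recs <- suppressMessages(measurements_to_records(tab))
  chir <- vapply(recs, function(r) r$series$chirality, character(1))
  expect_true(all(chir %in% c("CW", "CCW")))
  expect_gt(sum(chir == "CW"), 5)  # both chiralities represented
  expect_gt(sum(chir == "CCW"), 5)
  # normalized angles cluster at the golden angle for both chirality classes
  for (r in recs) expect_lt(abs(mean(r$series$angles) - 137.5), 10)
  # while raw world-frame angles are bimodal across plants
  raw_means <- tapply(tab$raw_angle_deg, tab$plant_id, mean)
  expect_gt(max(raw_means) - min(raw_means), 50)
})

test_that("rosette angles converge on the golden angle through damped oscillations", {
  # amplitude 0, no noise: all golden
  flat <- genotype_preset("custom", delta_i_sd = 0)
  tab0 <- generate_rosette_dataset(flat, n_plants = 3, n_leaves = 8,
                                   amplitude = 0, seed = 41)
  expect_true(all(abs(tab0$raw_angle_deg %% 360 - 137.5) < 1e-9 |
                    abs((360 - tab0$raw_angle_deg) - 137.5) < 1e-9))

  # near-instant damping: golden from pair 2 onward
  fast <- genotype_preset("custom", delta_i_sd = 0, rosette_lambda = 50)
  tabf <- generate_rosette_dataset(fast, n_plants = 2, n_leaves = 8, seed = 43)
  recs <- suppressMessages(measurements_to_records(
    transform(tabf, internode_mm = 0, radius_mm = NA)))
  for (r in recs) {
    expect_equal(r$series$angles[1], 180, tolerance = 1e-6)
    expect_equal(r$series$angles[-1], rep(137.5, 6), tolerance = 1e-6)
  }

  # default: first pair near 180, oscillation decays below late-pair offset
  tab <- generate_rosette_dataset(genotype_preset("col0"), n_plants = 120,
                                  n_leaves = 10, seed = 47)
  recs <- suppressMessages(measurements_to_records(
    transform(tab, internode_mm = 0)))
  prof <- leafpair_profile(lapply(recs, function(r) r$series))
  expect_lt(abs(prof$mean[1] - 180), 5)
  expect_lt(abs(prof$mean[8] - 137.5), abs(prof$mean[1] - 137.5))

  # slower damping in the mutant-like preset: larger mid-pair deviations
  tabp <- generate_rosette_dataset(genotype_preset("plt"), n_plants = 120,
                                   n_leaves = 10, seed = 47)
  recsp <- suppressMessages(measurements_to_records(
    transform(tabp, internode_mm = 0)))
  profp <- leafpair_profile(lapply(recsp, function(r) r$series))
  expect_gt(abs(profp$mean[5] - 137.5), abs(prof$mean[5] - 137.5))
})

test_that("unlinked variants sit near one-half WT frequency in both pools", {
  pools <- generate_bsa_pools(n_snps = 60, seed = 53)
  v <- pools$variants[!pools$variants$in_parent, ]
  far <- v[v$chrom != pools$truth$chrom, ]
  af_minus <- far$ad_ref_minus / (far$ad_ref_minus + far$ad_alt_minus)
  af_plus <- far$ad_ref_plus / (far$ad_ref_plus + far$ad_alt_plus)
  expect_lt(abs(mean(af_minus) - 0.5), 0.05)
  expect_lt(abs(mean(af_plus) - 0.5), 0.05)
  # EMS spectrum: C->T / G->A only
  expect_true(all(paste(v$ref, v$alt) %in% c("C T", "G A")))
})
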