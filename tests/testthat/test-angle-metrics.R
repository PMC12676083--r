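test_that("normalization maps golden-angle steps to 137.5 for both chiralities", {
  # spiral aligned with the measurement sense: identity
  expect_equal(normalize_divergence(137.5, "CW", measurement_sense = "CW"), 137.5)
  # spiral opposing the measurement sense: reflection 360 - x
  expect_equal(normalize_divergence(222.5, "CCW", measurement_sense = "CW"), 137.5)
  # 0 is a fixed point of the reflection
  expect_equal(normalize_divergence(0, "CCW", measurement_sense = "CW"), 0)
  expect_equal(normalize_divergence(0, "CW", measurement_sense = "CW"), 0)
  expect_error(normalize_divergence(137.5, "ambiguous"), "ambiguous")
})

test_that("the opposing-sense reflection is an involution", {
  set.seed(42)
  x <- runif(200, 0, 360 - 1e-9)
  once <- normalize_divergence(x, "CCW", measurement_sense = "CW")
  twice <- normalize_divergence(once, "CCW", measurement_sense = "CW")
  expect_equal(twice, x)
})

test_that("chirality is the strict majority of step directions, tie is ambiguous", {
  expect_identical(assign_chirality(c("CW", "CW", "CCW")), "CW")
  expect_identical(assign_chirality(c("CW", "CCW")), "ambiguous")
  expect_identical(assign_chirality(rep("CCW", 10)), "CCW")
  expect_error(assign_chirality(character(0)), "non-empty")
})

test_that("M-motif criterion: inclusive at 202.5, strict at 180, greedy non-overlap", {
  expect_identical(flag_m_motifs(c(210, 190, 205)), 1L)
  expect_identical(flag_m_motifs(c(202.5, 180.0, 202.5)), integer(0))
  expect_identical(flag_m_motifs(c(202.5, 180.0001, 202.5)), 1L)
  expect_identical(flag_m_motifs(c(100, 137, 140, 210, 181, 203)), 4L)
  # non-overlapping: positions 1-3 flagged, angles 2-4 cannot seed a new flag
  expect_identical(flag_m_motifs(c(210, 205, 210, 205, 100)), 1L)
  expect_identical(flag_m_motifs(c(137, 140)), integer(0))
})

test_that("M-motif scan returns nothing when all angles are below 202.5", {
  set.seed(7)
  for (i in 1:20) {
    a <- runif(30, 0, 202.5 - 1e-6)
    expect_identical(flag_m_motifs(a), integer(0))
  }
})

test_that("binning matches the brute-force nearest-center oracle on tiling widths", {
  set.seed(11)
  x <- runif(1e5, 0, 360 - 1e-9)
  for (w in c(22.5, 45, 30, 10)) {
    expect_identical(angle_bin_index(x, w), oracle_bin_index(x, w))
  }
  # boundary angles land per the half-open convention
  expect_identical(angle_bin_index(c(11.25, 11.2499, 348.75, 348.7), 22.5),
                   oracle_bin_index(c(11.25, 11.2499, 348.75, 348.7), 22.5))
})

test_that("bin grid geometry matches the printed grids", {
  expect_length(angle_bin_centers(22.5), 16L)
  g <- bin_pairs(c(137.5, 137.5), 22.5)
  expect_equal(g$centers[angle_bin_index(137.5, 22.5)], 135)  # 135 +/- 11.25 bin
  # the 3-bin golden windows at the three working widths
  expect_equal(bin_pairs(c(1, 2), 22.5)$window_edges, c(101.25, 168.75))
  expect_equal(bin_pairs(c(1, 2), 12.5)$window_edges, c(118.75, 156.25))
  expect_equal(bin_pairs(c(1, 2), 6.25)$window_edges, c(128.125, 146.875))
  expect_error(bin_pairs(c(1, 2), -1), "bin_width")
  expect_error(bin_pairs(1, 22.5), "2 angles")
})

test_that("bin counts sum to the number of consecutive pairs", {
  set.seed(13)
  for (i in 1:10) {
    a <- runif(sample(2:80, 1), 0, 360 - 1e-9)
    w <- sample(c(22.5, 12.5, 6.25), 1)
    g <- bin_pairs(a, w)
    expect_identical(sum(g$counts), g$n_pairs)
    expect_identical(g$n_pairs, length(a) - 1L)
    expect_length(g$window_bins, 3L)
    # middle window bin contains 137.5
    mid <- g$window_bins[2]
    expect_lt(abs(g$centers[mid] - 137.5), w / 2 + 1e-12)
  }
})

test_that("window pair fraction counts pairs with both members inside", {
  expect_equal(window_pair_fraction(rep(135, 5), 22.5), 1)
  expect_equal(window_pair_fraction(rep(90, 5), 22.5), 0)
  expect_equal(window_pair_fraction(c(135, 135, 200), 22.5), 0.5)
  expect_error(window_pair_fraction(135, 22.5), "fewer than 2")
})

test_that("window fraction is invariant under chirality normalization of a pure spiral", {
  cw_world <- rep(137.5, 10)    # CW plant measured in CW sense
  ccw_world <- rep(222.5, 10)   # CCW plant measured in CW sense
  ccw_norm <- normalize_divergence(ccw_world, "CCW", measurement_sense = "CW")
  expect_equal(window_pair_fraction(cw_world, 22.5), 1)
  expect_equal(window_pair_fraction(ccw_norm, 22.5), 1)
})

test_that("extreme-angle fraction uses strict cutoffs at 110 and 165", {
  expect_equal(extreme_angle_fraction(109.9), 1)
  expect_equal(extreme_angle_fraction(c(110, 165)), 0)
  expect_equal(extreme_angle_fraction(c(100, 137.5, 170, 140)), 0.5)
  expect_error(extreme_angle_fraction(numeric(0)), "at least one")
})

test_that("leaf-pair profile reports per-index mean and SEM", {
  prof <- leafpair_profile(list(c(130, 140), c(140, 140)))
  expect_equal(prof$mean, c(135, 140))
  expect_equal(prof$sem[1], sd(c(130, 140)) / sqrt(2))  # = 5
  expect_equal(prof$sem[1], 5)
  const <- leafpair_profile(list(rep(137.5, 4), rep(137.5, 4)))
  expect_equal(const$mean, rep(137.5, 4))
  expect_equal(const$sem, rep(0, 4))
  single <- leafpair_profile(list(c(130, 150)))
  expect_true(all(is.na(single$sem)))
  expect_equal(single$n, c(1L, 1L))
})

test_that("organ series validates its invariants", {
  expect_error(organ_series("p", c(-1, 10)), "\\[0, 360\\)")
  expect_error(organ_series("p", c(10, 360)), "\\[0, 360\\)")
  expect_error(organ_series("p", c(10, 20), step_directions = "CW"),
               "one entry per angle")
  rec <- make_record(c(137, 140), c(5, 4))
  expect_error(inflorescence_record(rec$series, c(5, -1)), ">= 0")
  expect_error(inflorescence_record(rec$series, c(5, 4, 3)), "pairing")
  expect_error(inflorescence_record(rec$series, c(5, 4),
                                    node_positions = c(2, 2)),
               "strictly increasing")
})
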