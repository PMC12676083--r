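# Independent oracles used across the suite.

# Brute-force circular nearest-center bin search (exactly tiling widths only):
# loops centers, computes wrapped distance, resolves the boundary tie to the
# half-open [c - w/2, c + w/2) convention.
oracle_bin_index <- function(angles, bin_width) {
  centers <- angle_bin_centers(bin_width)
  vapply(angles, function(x) {
    d <- (x - centers + 180) %% 360 - 180
    which(d >= -bin_width / 2 & d < bin_width / 2)[1]
  }, integer(1))
}

# Quadratic OLS by direct normal equations (no lm).
oracle_quadratic_fit <- function(x, y) {
  X <- cbind(x^2, x, 1)
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

# Benjamini-Hochberg step-up, written from the definition.
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

make_record <- function(angles, internodes, chirality = "CCW",
                        plant_id = "p1") {
  inflorescence_record(
    organ_series(plant_id, angles, organ_type = "flower",
                 chirality = chirality),
    internodes)
}
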