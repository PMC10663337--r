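# Shared fixtures and independent oracles used across test files.

# The reference ground-truth scenario: radii 50/100/150 nm with center
# distances 400 (R-G), 500 (G-B) and 600 (R-B); the angle at G follows from
# the law of cosines, cos = (400^2 + 500^2 - 600^2) / (2*400*500) = 0.125.
ref_angle_deg <- acos(0.125) * 180 / pi

ref_scenario <- function(n, seed = 1, noise = 0, ...) {
  tri_loci_scenario(center_RG_distance = 400, center_GB_distance = 500,
                    center_angle_at_G = ref_angle_deg,
                    radius_R = 50, radius_G = 100, radius_B = 150,
                    n_nuclei = n, localization_noise_sd = noise,
                    seed = seed, ...)
}

# Ranges constructed forward from the survival-zone relations
# (max = center + r_a + r_b, min = center - r_a - r_b):
ref_ranges <- function() {
  pair_ranges(drgmin = 250, drgmax = 550,   # 400 -/+ (50 + 100)
              dgbmin = 250, dgbmax = 750,   # 500 -/+ (100 + 150)
              drbmin = 400, drbmax = 800)   # 600 -/+ (50 + 150)
}

# Brute-force oracle for position reconstruction: plain triple loop over all
# grid-point combinations, strict-inequality update so ties keep the
# earliest (R, then G, then B) enumeration order.
brute_force_positions <- function(triplet, grids) {
  PR <- grids$R$points; PG <- grids$G$points; PB <- grids$B$points
  best <- Inf; best_idx <- c(NA, NA, NA)
  for (r in seq_len(nrow(PR))) for (g in seq_len(nrow(PG)))
    for (b in seq_len(nrow(PB))) {
      d1 <- sqrt(sum((PR[r, ] - PG[g, ])^2))
      d2 <- sqrt(sum((PG[g, ] - PB[b, ])^2))
      d3 <- sqrt(sum((PR[r, ] - PB[b, ])^2))
      cost <- (d1 - triplet[1])^2 + (d2 - triplet[2])^2 + (d3 - triplet[3])^2
      if (cost < best) { best <- cost; best_idx <- c(r, g, b) }
    }
  list(indices = best_idx, residual = sqrt(best / 3))
}

# Full hypergeometric enumeration oracle for the two-sided exact test on a
# 2x2 table (rows = class, columns = condition), written from the
# definition: sum the probabilities of all tables with the observed margins
# that are at most as probable as the observed table.
enumerate_fisher_p <- function(a, b, c, d) {
  r1 <- a + b; r2 <- c + d; c1 <- a + c; n <- r1 + r2
  xs <- max(0, c1 - r2):min(r1, c1)
  pr <- choose(r1, xs) * choose(r2, c1 - xs) / choose(n, c1)
  obs <- pr[xs == a]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Build a DistanceClassTable with given (close, far) counts at the 200-nm
# collapse by synthesizing distances on either side of the threshold.
class_table_from_counts <- function(n_close, n_far, condition = "x") {
  classify_distances(distance_sample(
    c(rep(50, n_close), rep(300, n_far)), condition))
}

# Interval-overlap oracle (half-open arithmetic) for particle mapping.
overlap_particles <- function(start, end, origin, bp, n) {
  which(vapply(seq_len(n), function(k) {
    ps <- origin + (k - 1) * bp; pe <- ps + bp
    ps < end && pe > start
  }, logical(1)))
}
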