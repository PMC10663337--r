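# Three-loci survival-zone inversion: ranges, closed-form radii, geometry,
# grids and per-nucleus position reconstruction.

test_that("summarize_ranges reduces triplets to per-pair extremes", {
  const <- triplet_distance_set(rep(400, 5), rep(500, 5),
                                rep(sqrt(400^2 + 500^2), 5))
  r <- summarize_ranges(const)
  expect_equal(r$drgmin, r$drgmax)
  expect_equal(r$dgbmin, r$dgbmax)
  expect_equal(r$drbmin, r$drbmax)

  two <- triplet_distance_set(c(1, 3), c(1, 5), c(1, 7))
  r2 <- summarize_ranges(two)
  expect_equal(c(r2$drgmin, r2$drgmax), c(1, 3))
  expect_equal(c(r2$dgbmin, r2$dgbmax), c(1, 5))
  expect_equal(c(r2$drbmin, r2$drbmax), c(1, 7))

  expect_error(summarize_ranges(two, lower_q = 0.5, upper_q = 0.5),
               "quantiles")
})

test_that("empirical R-G range approaches 2(Rr+Rg) from below", {
  tr <- generate_triplets(ref_scenario(1e4, seed = 7))
  rng <- summarize_ranges(tr)
  span <- rng$drgmax - rng$drgmin
  expect_lte(span, 300)                  # extremes can only be inside truth
  expect_gt(span, 300 * 0.95)            # within 5% at n = 1e4
})

test_that("solve_radii inverts forward-constructed ranges exactly", {
  sol <- solve_radii(ref_ranges())
  expect_equal(sol$radius_R, 50)
  expect_equal(sol$radius_G, 100)
  expect_equal(sol$radius_B, 150)
  expect_length(sol$flags, 0)

  # degenerate: immobile loci
  z <- solve_radii(pair_ranges(400, 400, 500, 500, 600, 600))
  expect_equal(unname(z$raw_radii), c(0, 0, 0))
})

test_that("raw radii satisfy the pairwise sum identities for random ranges", {
  set.seed(42)
  for (k in 1:1000) {
    mins <- runif(3, 0, 500)
    maxs <- mins + runif(3, 0, 800)
    r <- pair_ranges(mins[1], maxs[1], mins[2], maxs[2], mins[3], maxs[3])
    raw <- solve_radii(r)$raw_radii
    expect_equal(raw[["radius_R"]] + raw[["radius_G"]],
                 (r$drgmax - r$drgmin) / 2)
    expect_equal(raw[["radius_G"]] + raw[["radius_B"]],
                 (r$dgbmax - r$dgbmin) / 2)
    expect_equal(raw[["radius_R"]] + raw[["radius_B"]],
                 (r$drbmax - r$drbmin) / 2)
  }
})

test_that("negative raw radii are clamped to zero and flagged", {
  sol <- solve_radii(pair_ranges(0, 10, 0, 10, 0, 100))
  expect_equal(sol$raw_radii[["radius_G"]], -20)  # (10+10-100)/4
  expect_equal(sol$radius_G, 0)
  expect_match(sol$flags, "clamped")
})

test_that("solve_geometry recovers midranges and the angle at G", {
  # equilateral and right-angle configurations
  eq <- solve_geometry(pair_ranges(100, 100, 100, 100, 100, 100))
  expect_equal(eq$angle_theta, 60)
  rt <- solve_geometry(pair_ranges(400, 400, 300, 300, 500, 500))
  expect_equal(rt$angle_theta, 90)

  g <- solve_geometry(ref_ranges())   # A=600, B=500, C=400
  expect_equal(g$cos_theta, 0.125)
  expect_equal(g$angle_theta, acos(0.125) * 180 / pi)

  degen <- solve_geometry(pair_ranges(10, 10, 0, 0, 10, 10))
  expect_true(is.na(degen$angle_theta))
  expect_match(degen$flags, "degenerate")
})

test_that("zone grids stay inside their disks and honor N, M", {
  sol <- solve_survival_zones(ref_ranges())
  grids <- build_zone_grids(sol, n_radial = 1, n_angular = 4)
  expect_equal(nrow(grids$R$points), 5)   # center + 4 points on the rim
  rim <- grids$R$points[-1, ]
  expect_equal(unname(sqrt(rowSums(sweep(rim, 2, grids$R$center)^2))),
               rep(sol$radius_R, 4))

  grids2 <- build_zone_grids(sol, n_radial = 3, n_angular = 7)
  for (g in grids2) {
    d2 <- rowSums(sweep(g$points, 2, g$center)^2)
    expect_true(all(d2 <= g$radius^2 + 1e-9))
    expect_equal(nrow(g$points), 3 * 7 + 1)
  }

  # zero radius collapses to the center
  immobile <- solve_survival_zones(pair_ranges(400, 400, 500, 500, 600, 600))
  g0 <- build_zone_grids(immobile, 5, 8)
  expect_equal(nrow(g0$R$points), 1)
})

test_that("position reconstruction matches the brute-force oracle", {
  sol <- solve_survival_zones(ref_ranges())
  grids <- build_zone_grids(sol, n_radial = 2, n_angular = 8)
  set.seed(9)
  for (k in 1:100) {
    triplet <- c(runif(1, 250, 550), runif(1, 250, 750), runif(1, 400, 800))
    got <- reconstruct_positions(triplet, grids)
    want <- brute_force_positions(triplet, grids)
    expect_equal(unname(got$indices), want$indices)
    expect_equal(got$residual, want$residual)
  }
})

test_that("immobile loci reconstruct to the centers with zero residual", {
  sol <- solve_survival_zones(pair_ranges(400, 400, 500, 500, 600, 600))
  grids <- build_zone_grids(sol, 2, 8)
  ps <- reconstruct_positions(c(400, 500, 600), grids)
  expect_equal(ps$residual, 0)
  expect_equal(ps$positions["G", ], c(x = 0, y = 0))
  expect_equal(ps$positions["R", ], c(x = 400, y = 0))
  expect_length(ps$flags, 0)

  # a triplet no in-zone configuration can produce
  bad <- reconstruct_positions(c(10, 10, 10), grids)
  expect_gt(bad$residual, 0)
  expect_match(bad$flags, "no in-zone configuration")
})

test_that("zero-noise round trip recovers radii and angle, improving with n", {
  errs <- sapply(c(100, 1000, 10000), function(n) {
    sol <- solve_survival_zones(generate_triplets(ref_scenario(n, seed = 7)))
    rec <- c(sol$radius_R, sol$radius_G, sol$radius_B)
    truth <- c(50, 100, 150)
    expect_true(all(rec <= truth * 1.02))  # min/max estimators biased inward
    max(abs(rec - truth) / truth)
  })
  expect_lt(errs[3], 0.10)
  expect_true(all(diff(errs) < 0))   # recovery error decreases with n

  sol <- solve_survival_zones(generate_triplets(ref_scenario(1e4, seed = 7)))
  expect_lt(abs(sol$angle_theta - ref_angle_deg), 5)
})

test_that("relabeling R and B maps the solution accordingly", {
  tr <- generate_triplets(ref_scenario(2000, seed = 3))
  swapped <- triplet_distance_set(d_RG = tr$d_GB, d_GB = tr$d_RG,
                                  d_RB = tr$d_RB)
  a <- solve_survival_zones(tr)
  b <- solve_survival_zones(swapped)
  expect_equal(b$radius_R, a$radius_B)
  expect_equal(b$radius_B, a$radius_R)
  expect_equal(b$radius_G, a$radius_G)
  expect_equal(b$midrange_B, a$midrange_C)
  expect_equal(b$midrange_C, a$midrange_B)
  expect_equal(b$midrange_A, a$midrange_A)
  expect_equal(b$angle_theta, a$angle_theta)
})

test_that("triangle-inequality violations are flagged but kept by default", {
  tds <- triplet_distance_set(c(100, 10), c(100, 10), c(150, 500))
  expect_equal(attr(tds, "violations"), 2L)
  expect_equal(nrow(tds), 2)
  strict <- triplet_distance_set(c(100, 10), c(100, 10), c(150, 500),
                                 strict = TRUE)
  expect_equal(nrow(strict), 1)
})
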