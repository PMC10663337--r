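# 5C matrix processing: primer filter, scaling, binning, ICE balancing,
# expected-by-distance and window quantification.

# homogeneous symmetric matrix fixture (constant off-diagonal)
flat_matrix <- function(n = 20, value = 10, fragment_size = 4000) {
  counts <- matrix(value, n, n); diag(counts) <- 0
  contact_matrix(counts, data.frame(chr = "chrS",
                                    start = (seq_len(n) - 1) * fragment_size,
                                    end = seq_len(n) * fragment_size))
}

test_that("primer filter masks constructed outliers and nothing else", {
  m <- flat_matrix()
  expect_true(all(filter_primers(m)$mask))

  # a lone x1000 primer among n others reaches |z| = (n-1)/sqrt(n) at most,
  # so the panel must be large enough for the outlier to clear z = 6
  out <- flat_matrix(50)
  out$counts[5, ] <- out$counts[5, ] * 1000
  out$counts[, 5] <- t(out$counts[5, , drop = FALSE])
  out <- contact_matrix(out$counts, out$intervals)
  f <- filter_primers(out)
  expect_false(f$mask[5])
  expect_true(all(f$mask[-5]))

  # masked primers are ignored when z-scores are recomputed
  f2 <- filter_primers(f)
  expect_identical(f2$mask, f$mask)

  small <- flat_matrix(4)
  small$mask <- c(TRUE, TRUE, FALSE, FALSE)
  expect_error(filter_primers(small), "fewer than 3")
})

test_that("read scaling hits the target total and is a no-op at the current one", {
  m <- flat_matrix(10, value = 1)
  tot <- sum(m$counts)
  expect_equal(scale_reads(m, tot)$counts, m$counts)
  s <- scale_reads(m, 10 * tot)
  expect_equal(s$counts, m$counts * 10)
  # two samples scaled to the same target have equal unmasked sums
  m2 <- generate_contact_matrix(synthetic_matrix_spec(10, depth = 50, seed = 1))
  s2 <- scale_reads(m2, 10 * tot)
  expect_equal(sum(s$counts), sum(s2$counts))
})

test_that("binning arithmetic gives the documented step and overlap", {
  cfg <- binning_config(bin_width = 15000, steps_per_bin = 8)
  expect_equal(cfg$step, 1875)
  expect_equal(cfg$overlap, 13125)
  expect_equal(binning_config(steps_per_bin = 1)$overlap, 0)
})

test_that("disjoint binning conserves total counts; overlapping bins overlap", {
  m <- generate_contact_matrix(synthetic_matrix_spec(40, fragment_size = 4000,
                                                     depth = 300, seed = 5))
  b1 <- bin_matrix(m, binning_config(bin_width = 8000, steps_per_bin = 1))
  expect_equal(sum(b1$counts), sum(m$counts))
  expect_true(all(diff(b1$intervals$start) == 8000))

  b8 <- bin_matrix(m, binning_config(bin_width = 16000, steps_per_bin = 8))
  expect_equal(diff(b8$intervals$start)[1], 2000)
  expect_true(isSymmetric(b8$counts))
})

test_that("ICE balancing equalizes row sums and fixes fixed points", {
  # 3x3 positive matrix: sums equal within 1e-6 relative after balancing
  A <- matrix(c(4, 2, 1, 2, 6, 3, 1, 3, 8), 3, 3)
  m <- contact_matrix(A, data.frame(chr = "c", start = 0:2, end = 1:3))
  bal <- ice_balance(m, tol = 1e-6)
  s <- rowSums(bal$counts)
  expect_lt(max(abs(s / mean(s) - 1)), 1e-6)
  expect_true(isSymmetric(bal$counts))

  # already balanced input is a fixed point
  fx <- ice_balance(flat_matrix(6), tol = 1e-6)
  expect_equal(fx$counts, flat_matrix(6)$counts)
  expect_equal(attr(fx, "iterations"), 1L)

  # homogeneity: balancing commutes with global scaling
  m2 <- contact_matrix(3 * A, data.frame(chr = "c", start = 0:2, end = 1:3))
  expect_equal(ice_balance(m2, tol = 1e-8)$counts,
               3 * ice_balance(m, tol = 1e-8)$counts, tolerance = 1e-6)
})

test_that("ICE masks all-zero rows and removes planted multiplicative biases", {
  spec <- synthetic_matrix_spec(40, decay_exponent = 1, depth = 1500,
                                bias_log_sd = 0.4, seed = 17)
  biased <- generate_contact_matrix(spec)
  expect_gt(sum(rowSums(biased$counts)) / 40, 1e4)  # ~1e4 counts per row
  bal <- ice_balance(biased)
  s <- rowSums(bal$counts[bal$mask, bal$mask])
  expect_lt(max(abs(s / mean(s) - 1)), 1e-5)

  # after balancing, the matrix matches the balanced bias-free expectation
  # up to a constant: per-row mean ratios are flat across rows (CV < 5%)
  spec0 <- spec; spec0$bias_log_sd <- 0
  expected0 <- ice_balance(generate_contact_matrix(spec0, sample = FALSE))
  ratio <- bal$counts / expected0$counts
  row_mean_ratio <- sapply(1:40, function(i) mean(ratio[i, -i]))
  expect_lt(sd(row_mean_ratio) / mean(row_mean_ratio), 0.05)

  withzero <- flat_matrix(6)
  withzero$counts[3, ] <- 0; withzero$counts[, 3] <- 0
  expect_message(bz <- ice_balance(contact_matrix(withzero$counts,
                                                  withzero$intervals)),
                 "all-zero")
  expect_false(bz$mask[3])
})

test_that("expected-by-distance recovers a noise-free power law", {
  m <- generate_contact_matrix(synthetic_matrix_spec(50, fragment_size = 4000,
                                                     decay_exponent = 1,
                                                     depth = 100),
                               sample = FALSE)
  em <- expected_by_distance(m)
  interior <- (5:30) * 4000
  pred <- predict(em, interior)
  truth <- 100 * (interior / 4000)^(-1)
  expect_true(all(abs(pred - truth) / truth < 0.05))

  # constant matrix -> flat expected curve
  fm <- expected_by_distance(flat_matrix(30, value = 7))
  expect_equal(fm$fit$expected, rep(7, nrow(fm$fit)), tolerance = 1e-6)

  # observed/expected of the fitted input is centred on 1
  oe <- observed_over_expected(m, em)
  med <- median(oe$counts[upper.tri(oe$counts)])
  expect_equal(med, 1, tolerance = 0.05)

  expect_error(expected_by_distance(flat_matrix(5)), "fewer than 10")
})

test_that("the decay curve has the planted log-log slope and honors masks", {
  m <- generate_contact_matrix(synthetic_matrix_spec(60, decay_exponent = 1,
                                                     depth = 2000, seed = 23))
  cv <- counts_vs_distance(m)
  fit <- lm(log(mean_count) ~ log(separation), data = cv[cv$offset <= 30, ])
  expect_equal(unname(coef(fit)[2]), -1, tolerance = 0.1)

  flat <- counts_vs_distance(flat_matrix(20, value = 4))
  expect_equal(flat$mean_count, rep(4, 19))

  # perturbing a masked row leaves the curve unchanged
  mm <- m; mm$mask[10] <- FALSE
  before <- counts_vs_distance(mm)
  mm$counts[10, ] <- mm$counts[10, ] * 100
  mm$counts[, 10] <- t(mm$counts[10, , drop = FALSE])
  expect_equal(counts_vs_distance(mm), before)
})

test_that("window interaction quantifies anchored pairs symmetrically", {
  m <- flat_matrix(50, value = 3)
  wa <- anchor_window("ERBS1", summit = 10 * 4000, half_width = 6000)
  wb <- anchor_window("TSS", summit = 40 * 4000, half_width = 6000)
  wi <- window_interaction(m, wa, wb)
  expect_equal(wi$mean, 3)
  expect_equal(window_interaction(m, wb, wa)$values, wi$values)

  # planted loop lifts the anchored window ~5x over a background window
  lm <- generate_contact_matrix(synthetic_matrix_spec(
    60, fragment_size = 4000, depth = 5000, loops = list(c(10, 50, 5)),
    seed = 29))
  loop_w <- window_interaction(lm,
                               anchor_window("a", 9.5 * 4000, 1500),
                               anchor_window("b", 49.5 * 4000, 1500))
  bg_w <- window_interaction(lm,
                             anchor_window("a", 9.5 * 4000, 1500),
                             anchor_window("b", 45.5 * 4000, 1500))
  expect_equal(loop_w$mean / bg_w$mean, 5 * 36 / 40, tolerance = 0.2)

  expect_error(window_interaction(m, anchor_window("x", 1e9), wb),
               "outside")
})

test_that("the processing chain runs in the fixed order on raw input only", {
  raw <- generate_contact_matrix(synthetic_matrix_spec(
    60, decay_exponent = 1, depth = 800, bias_log_sd = 0.3, seed = 37))
  out <- process_fivec(raw, config = binning_config(16000, 8))
  expect_equal(out$status, "balanced")
  ops <- sub("\\(.*", "", out$history)
  expect_equal(ops, c("filter_primers", "scale_reads", "bin_matrix",
                      "ice_balance"))
  expect_error(process_fivec(out), "raw")
})

test_that("every operation preserves symmetry", {
  raw <- generate_contact_matrix(synthetic_matrix_spec(
    40, depth = 500, bias_log_sd = 0.2, seed = 41))
  m <- filter_primers(raw)
  expect_true(isSymmetric(m$counts))
  m <- scale_reads(m, 1e5)
  expect_true(isSymmetric(m$counts))
  m <- bin_matrix(m, binning_config(12000, 4))
  expect_true(isSymmetric(m$counts))
  m <- ice_balance(m)
  expect_true(isSymmetric(m$counts))
})
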