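test_that("unmixing recovers exact coefficients on noiseless mixtures", {
  p <- test_pair()
  rd <- band_reference(p$donor, edges32)
  ra <- band_reference(p$acceptor, edges32)
  st <- spectral_stack(rbind(2 * rd + 3 * ra, 0 * rd), edges32, laser = 405)
  um <- unmix(st, rd, ra)
  expect_equal(um$donor_coeff, c(2, 0), tolerance = 1e-9)
  expect_equal(um$acceptor_coeff, c(3, 0), tolerance = 1e-9)
  expect_lt(max(um$residual_norm), 1e-9)
})

test_that("infeasible mixtures match the constrained grid-search oracle", {
  p <- test_pair()
  rd <- band_reference(p$donor, edges32)
  ra <- band_reference(p$acceptor, edges32)
  y <- rd - 0.5 * ra  # negative acceptor contribution is infeasible
  um <- unmix(spectral_stack(rbind(y), edges32, 405), rd, ra)
  expect_equal(um$acceptor_coeff, 0, tolerance = 1e-9)
  oracle <- grid_nnls(cbind(rd, ra), y, dmax = 2, amax = 1, n = 401)
  expect_equal(um$residual_norm^2, oracle$rss, tolerance = 1e-4)
  expect_equal(um$donor_coeff, oracle$donor, tolerance = 0.01)
})

test_that("near-collinear references are rejected", {
  p <- test_pair()
  rd <- band_reference(p$donor, edges32)
  st <- spectral_stack(rbind(rd), edges32, 405)
  expect_error(unmix(st, rd, rd * (1 + 1e-9)), "collinear")
})

test_that("the integral index is the coefficient ratio and flags zero donors", {
  p <- test_pair()
  rd <- band_reference(p$donor, edges32)
  ra <- band_reference(p$acceptor, edges32)
  st <- spectral_stack(rbind(1 * rd + 1 * ra, 2 * rd, 0.5 * ra),
                       edges32, 405)
  um <- unmix(st, rd, ra)
  expect_warning(idx <- fret_index_integral(um), "zero donor")
  expect_equal(idx[1], 1, tolerance = 1e-9)
  expect_equal(idx[2], 0, tolerance = 1e-12)
  expect_true(is.na(idx[3]))
})

test_that("index is invariant to intensity scale and abundance at fixed efficiency", {
  p <- test_pair()
  rd <- band_reference(p$donor, edges32)
  ra <- band_reference(p$acceptor, edges32)
  idx_of <- function(donor_ab) {
    scene <- ground_truth_scene(0.4, donor_abundance = donor_ab,
                                acceptor_abundance = 0)
    st <- simulate_spectral_stack(p$donor, p$acceptor, scene,
                                  cross_excitation = FALSE)
    fret_index_integral(unmix(st, rd, ra))
  }
  # no cross-excitation: index depends only on E, not abundance/scale
  expect_equal(idx_of(1), idx_of(7.3), tolerance = 1e-9)
})

test_that("the peak-ratio index behaves on flat, empty and scaled spectra", {
  wl <- seq(450, 610, by = 5)
  flat <- rep(3, length(wl))
  expect_equal(fret_index_peak(wl, flat), 1)
  zero_acc <- ifelse(wl >= 520 & wl < 525, 0, 5)
  expect_equal(fret_index_peak(wl, zero_acc), 0)
  spec <- exp(-((wl - 500) / 30)^2)
  expect_equal(fret_index_peak(wl, spec), fret_index_peak(wl, 10 * spec))
  expect_error(fret_index_peak(wl, flat, donor_band = c(300, 310)),
               "outside")
})

test_that("the expression window is inclusive at both boundaries", {
  expect_true(qc_expression_window(100, 100))
  expect_false(qc_expression_window(10, 100))
  expect_true(qc_expression_window(20, 170))
  expect_equal(qc_expression_window(c(19.9, 20, 171), c(30, 170, 30)),
               c(FALSE, TRUE, FALSE))
})

test_that("transfer presets evaluate to the published calibration values", {
  fn1 <- transfer_preset("hek_cfp_yfp")
  expect_equal(apply_transfer(fn1, 0), 0.001)
  # at x = c the saturating term is exactly b/2
  expect_equal(apply_transfer(fn1, 2.11), 0.001 + 1.0022 / 2)
  fn2 <- transfer_preset("bact_tfp_venus")
  expect_equal(apply_transfer(fn2, 0), -0.9279)
  clamped <- apply_transfer(fn2, 0, clamp = TRUE)
  expect_equal(as.numeric(clamped), 0)
  expect_true(attr(clamped, "clamped"))
})

test_that("apply_transfer is monotone and inverts exactly", {
  tf <- transfer_preset("hek_cfp_yfp")
  x <- seq(0, 100, length.out = 200)
  e <- apply_transfer(tf, x)
  expect_true(all(diff(e) > 0))
  expect_lt(max(abs(invert_transfer(tf, e[-1]) - x[-1])), 1e-12)
  expect_equal(invert_transfer(tf, tf$a + 1e-15), 0, tolerance = 1e-10)
  expect_error(invert_transfer(tf, 1.5), "range")
  expect_error(transfer_function(0, 1, -2), "positive")
})

test_that("band_ratio is a guarded scale-invariant quotient", {
  expect_equal(band_ratio(2, 4), 0.5)
  expect_equal(band_ratio(0, 4), 0)
  expect_equal(band_ratio(3 * 7, 5 * 7), band_ratio(3, 5))
  expect_error(band_ratio(1, 0), "zero")
})
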