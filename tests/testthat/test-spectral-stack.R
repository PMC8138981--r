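test_that("zero efficiency without acceptor gives a pure donor-shaped stack", {
  p <- test_pair()
  scene <- ground_truth_scene(0, donor_abundance = 2, acceptor_abundance = 0)
  st <- simulate_spectral_stack(p$donor, p$acceptor, scene)
  f_d <- band_capture(p$donor, st$band_edges)
  ratio <- st$data[1, f_d > 1e-6] / f_d[f_d > 1e-6]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
})

test_that("complete transfer without cross-excitation emits only the acceptor shape", {
  p <- test_pair()
  scene <- ground_truth_scene(1, donor_abundance = 1, acceptor_abundance = 1)
  st <- simulate_spectral_stack(p$donor, p$acceptor, scene,
                                cross_excitation = FALSE)
  f_d <- band_capture(p$donor, st$band_edges)
  f_a <- band_capture(p$acceptor, st$band_edges)
  donor_only <- f_d > 1e-4 & f_a < 1e-12
  expect_true(all(st$data[1, donor_only] == 0))
  keep <- f_a > 1e-6
  ratio <- st$data[1, keep] / f_a[keep]
  expect_lt(diff(range(ratio)) / mean(ratio), 1e-12)
})

test_that("the noiseless stack matches the documented forward model exactly", {
  p <- test_pair()
  e <- 0.5
  scene <- ground_truth_scene(e, donor_abundance = 1.5,
                              acceptor_abundance = 0.7)
  st <- simulate_spectral_stack(p$donor, p$acceptor, scene, laser = 405)
  # independent recomputation of the closed-form model
  x_d <- approx(p$donor$wavelengths, p$donor$excitation, 405)$y
  x_a <- approx(p$acceptor$wavelengths, p$acceptor$excitation, 405)$y
  if (is.na(x_a)) x_a <- 0  # laser below the acceptor grid: no cross-excitation
  f_d <- band_capture(p$donor, st$band_edges)
  f_a <- band_capture(p$acceptor, st$band_edges)
  expected <- 1.5 * x_d * p$donor$quantum_yield * (1 - e) * f_d +
    (1.5 * x_d * p$acceptor$quantum_yield * e +
       0.7 * x_a * p$acceptor$quantum_yield) * f_a
  expect_lt(max(abs(st$data[1, ] - expected)), 1e-10)
})

test_that("simulation is deterministic given the seed; noise differs across seeds", {
  p <- test_pair()
  mk <- function(seed) {
    scene <- ground_truth_scene(0.3, noise = "gaussian", noise_param = 0.02,
                                seed = seed)
    simulate_spectral_stack(p$donor, p$acceptor, scene)$data
  }
  expect_identical(mk(42), mk(42))
  expect_false(identical(mk(42), mk(43)))
  # poisson noise preserves the mean on average
  scene <- ground_truth_scene(rep(0.3, 200), noise = "poisson",
                              noise_param = 50, seed = 1)
  noisy <- simulate_spectral_stack(p$donor, p$acceptor, scene)$data
  clean <- simulate_spectral_stack(
    p$donor, p$acceptor, ground_truth_scene(rep(0.3, 200)))$data
  expect_equal(colMeans(noisy), colMeans(clean), tolerance = 0.05)
})

test_that("invalid scenes and lasers are rejected", {
  p <- test_pair()
  expect_error(ground_truth_scene(1.2), "efficiency")
  expect_error(ground_truth_scene(0.5, donor_abundance = -1), "non-negative")
  expect_error(ground_truth_scene(0.5, noise = "gaussian", noise_param = 0.1),
               "seed")
  scene <- ground_truth_scene(0.5)
  expect_error(simulate_spectral_stack(p$donor, p$acceptor, scene,
                                       laser = 300), "laser")
})

test_that("stack CSV and TIFF round trips preserve the data", {
  p <- test_pair()
  scene <- ground_truth_scene(c(0.2, 0.6), donor_abundance = 1)
  st <- simulate_spectral_stack(p$donor, p$acceptor, scene)
  path <- tempfile(fileext = ".csv")
  write_stack_csv(st, path)
  st2 <- read_stack_csv(path)
  expect_equal(st2$data, st$data, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(st2$band_edges, st$band_edges)
  skip_if_not_installed("tiff")
  tpath <- tempfile(fileext = ".tif")
  m <- st$data / max(st$data)  # TIFF stores [0,1]
  pages <- lapply(seq_len(ncol(m)), function(b)
    matrix(m[, b], nrow = 1))
  tiff::writeTIFF(pages, tpath, bits.per.sample = 32L)
  st3 <- read_stack_tiff(tpath)
  expect_equal(st3$data, m, tolerance = 1e-6, ignore_attr = TRUE)
})
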