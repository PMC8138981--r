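test_that("the noiseless reference library peaks at its configured length", {
  scn <- fpa_preset("wt_cam")
  scn$noise_sd <- 0
  prof <- build_profile(simulate_fpa_profile(scn, seed = 1))
  expect_equal(prof$tether_length[which.max(prof$ratio)], 22)
  expect_equal(profile_peak(prof), 22)
})

test_that("chaperone-absent libraries sit at baseline with no peak", {
  scn <- fpa_preset("no_cam")
  constructs <- simulate_fpa_profile(scn, seed = 2)
  prof <- build_profile(constructs)
  expect_true(all(abs(prof$ratio - scn$baseline_ratio) <
                    2 * scn$noise_sd + 1e-9))
  truth <- attr(constructs, "truth")
  expect_true(all(truth$ratio == scn$baseline_ratio))
})

test_that("the broad damped library yields no unique sharp peak", {
  scn <- fpa_preset("w344r_cam")
  scn$noise_sd <- 0
  prof <- build_profile(simulate_fpa_profile(scn, seed = 3))
  expect_true(is.na(profile_peak(prof)))
})

test_that("full-length fraction is linear in the full-length share", {
  # pure truncation: donor only
  expect_equal(full_length_fraction(100, 0), 0)
  # pure full length with equal peaks
  expect_equal(full_length_fraction(100, 100), 1)
  # 50:50 linear mixture of the two pure species
  mix_donor <- 100 + 100
  mix_acceptor <- 0 + 100
  expect_equal(full_length_fraction(mix_donor, mix_acceptor),
               (0 + 1) / 2)
  expect_equal(full_length_fraction(5 * 3, 5 * 2),
               full_length_fraction(3, 2))
})

test_that("profile assembly averages replicates exactly and is order invariant", {
  scn <- fpa_preset("wt_cam")
  constructs <- simulate_fpa_profile(scn, n_replicates = 3, seed = 7)
  prof <- build_profile(constructs)
  expect_equal(nrow(prof), 7)
  expect_equal(prof$tether_length, c(18, 22, 24, 27, 34, 40, 50))
  # brute-force per-length means
  ratio <- constructs$acceptor_peak / constructs$donor_peak
  for (i in seq_len(nrow(prof))) {
    sel <- constructs$tether_length == prof$tether_length[i]
    expect_equal(prof$ratio[i], mean(ratio[sel]), tolerance = 1e-12)
    expect_equal(prof$sd[i], sd(ratio[sel]), tolerance = 1e-12)
  }
  shuffled <- constructs[sample(nrow(constructs)), ]
  expect_equal(build_profile(shuffled)$ratio, prof$ratio, tolerance = 1e-12)
})

test_that("single replicates report sd as unavailable, not zero", {
  constructs <- simulate_fpa_profile(fpa_preset("wt_cam"), n_replicates = 1,
                                     seed = 9)
  prof <- build_profile(constructs)
  expect_true(all(is.na(prof$sd)))
  expect_true(is.na(profile_peak(prof)) || profile_peak(prof) == 22)
})

test_that("malformed construct tables are rejected", {
  constructs <- simulate_fpa_profile(fpa_preset("wt_cam"), seed = 11)
  dup <- rbind(constructs, constructs[1, ])
  expect_error(build_profile(dup), "duplicate")
  mixed <- constructs
  mixed$condition[1] <- "other"
  expect_error(build_profile(mixed), "mix")
  expect_error(fpa_scenario(tether_lengths = c(30, 20)), "increasing")
  expect_error(fpa_scenario(onset_length = 30, peak_length = 22), "onset")
})

test_that("peak detection recovers the truth at realistic noise levels", {
  hits <- 0
  nones <- 0
  for (s in 1:50) {
    pw <- profile_peak(build_profile(
      simulate_fpa_profile(fpa_preset("wt_cam"), seed = 4000 + s)))
    if (!is.na(pw) && pw == 22) hits <- hits + 1
    pn <- profile_peak(build_profile(
      simulate_fpa_profile(fpa_preset("no_cam"), seed = 5000 + s)))
    if (is.na(pn)) nones <- nones + 1
  }
  expect_gte(hits / 50, 0.95)
  expect_gte(nones / 50, 0.9)
})

test_that("soluble fraction is a guarded scale-invariant proportion", {
  expect_equal(soluble_fraction(5, 5), 0.5)
  expect_equal(soluble_fraction(0, 7), 0)
  expect_equal(soluble_fraction(3 * 2, 9 * 2), soluble_fraction(3, 9))
  expect_error(soluble_fraction(0, 0), "zero")
  expect_error(soluble_fraction(-1, 2), "non-negative")
})

test_that("construct tables round-trip through CSV", {
  constructs <- simulate_fpa_profile(fpa_preset("wt_cam"), seed = 13)
  path <- tempfile(fileext = ".csv")
  write_constructs_csv(constructs, path)
  back <- read_constructs_csv(path)
  expect_equal(build_profile(back)$ratio, build_profile(constructs)$ratio,
               tolerance = 1e-9)
})
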