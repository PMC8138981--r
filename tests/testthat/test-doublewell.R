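test_that("the quartic double well hits the requested depths and barrier", {
  set.seed(3)
  for (i in 1:10) {
    tn <- runif(1, 80, 140); tt <- runif(1, 20, 60)
    dn <- runif(1, 0.5, 5); dtt <- runif(1, 0.5, 5)
    bar <- runif(1, 0.5, 3)
    p <- double_well(tn, tt, dn, dtt, bar)
    expect_equal(dw_energy(p, tn), -dn, tolerance = 1e-8)
    expect_equal(dw_energy(p, tt), -dtt, tolerance = 1e-8)
    expect_equal(dw_energy(p, p$barrier_theta), -min(dn, dtt) + bar,
                 tolerance = 1e-8)
    # stationary points of the quartic are exactly the wells and barrier
    expect_lt(max(abs(dw_gradient(p, c(tn, tt, p$barrier_theta)))), 1e-8)
    expect_true(all(is.finite(dw_energy(p, seq(0, 180, by = 0.5)))))
  }
  expect_error(double_well(90, 90, 1, 1, 1), "differ")
  expect_error(double_well(90, 40, 1, 1, -1), "barrier")
})

test_that("zero-temperature dynamics descend to the nearest minimum and stay", {
  p <- dw_preset("wt")
  tr <- simulate_double_well_trajectory(p, kT = 0, dt = 0.5,
                                        n_steps = 3000, theta0 = 110,
                                        seed = 1)
  expect_equal(tail(tr$theta, 1), p$theta_n, tolerance = 0.01)
  expect_lt(max(abs(tail(tr$theta, 100) - p$theta_n)), 0.01)
})

test_that("the sampler is reproducible and refuses unstable settings", {
  p <- dw_preset("w344r")
  t1 <- simulate_double_well_trajectory(p, n_steps = 500, seed = 9)
  t2 <- simulate_double_well_trajectory(p, n_steps = 500, seed = 9)
  expect_identical(t1$theta, t2$theta)
  t3 <- simulate_double_well_trajectory(p, n_steps = 500, seed = 10)
  expect_false(identical(t1$theta, t3$theta))
  expect_error(simulate_double_well_trajectory(p, n_steps = 10, seed = 1,
                                               dt = 500), "dt")
  expect_error(simulate_double_well_trajectory(p, n_steps = 10, kT = -1,
                                               seed = 1), "kT")
  expect_error(simulate_double_well_trajectory(p, n_steps = 10), "seed")
})

test_that("symmetric wells are equally occupied in a long run", {
  p <- double_well(120, 60, 2, 2, 1.2)
  tr <- simulate_double_well_trajectory(p, dt = 0.5, n_steps = 4e5,
                                        theta0 = 90, seed = 21)
  st <- classify_states(tr, boundaries = 90)
  # occupancy ratio -> 1; allow 3 standard errors with a generous
  # effective-sample-size margin for autocorrelation
  n_trans <- max(st$n_transitions, 1)
  se <- 0.5 / sqrt(n_trans)
  expect_lt(abs(st$populations[["N"]] - 0.5), 3 * se)
})

test_that("long trajectories reproduce Boltzmann occupancies (chi-squared)", {
  p <- dw_preset("w344r")
  kT <- KT_298
  tr <- simulate_double_well_trajectory(p, dt = 0.5, n_steps = 1e6,
                                        theta0 = 45, seed = 7)
  th <- tr$theta[seq(1000, length(tr$theta), by = 1000)]  # thin to ~independent
  br <- seq(0, 180, by = 20)
  obs <- hist(th, breaks = br, plot = FALSE)$counts
  grid <- seq(0, 180, by = 0.05)
  w <- exp(-dw_energy(p, grid) / kT)
  w <- w / sum(w)
  expprob <- vapply(seq_len(length(br) - 1), function(i)
    sum(w[grid >= br[i] & grid < br[i + 1]]), numeric(1))
  keep <- expprob > 1e-4
  cs <- suppressWarnings(
    chisq.test(obs[keep], p = expprob[keep] / sum(expprob[keep])))
  expect_gt(cs$p.value, 0.01)
})

test_that("the deep-well preset shows no native-to-tilted escapes at 1e5 steps", {
  tr <- simulate_double_well_trajectory(dw_preset("wt"), dt = 0.5,
                                        n_steps = 1e5, theta0 = 95, seed = 11)
  st <- classify_states(tr, boundaries = 70)
  expect_equal(st$n_transitions, 0)
  expect_equal(st$populations[["N"]], 1)
})

test_that("umbrella windows with zero bias reduce to the unbiased sampler", {
  p <- dw_preset("w344r")
  w <- simulate_umbrella_windows(p, centers = 45, spring_k = 0,
                                 n_steps = 2000, seed = 5, burn_in = 0)
  tr <- simulate_double_well_trajectory(p, n_steps = 2000, theta0 = 45,
                                        seed = 5)
  expect_identical(w[[1]]$traj$theta, tr$theta)
})

test_that("biased windows concentrate around their centres and flag gaps", {
  p <- dw_preset("w344r")
  # centres within the landscape's explored range; outside it the quartic
  # wall legitimately displaces weakly biased windows
  ctr <- c(45, 70, 95)
  w <- suppressWarnings(
    simulate_umbrella_windows(p, centers = ctr, spring_k = 0.2,
                              n_steps = 4000, seed = 5))
  means <- vapply(w, function(x) mean(x$traj$theta), numeric(1))
  expect_lt(max(abs(means - ctr)), 5)
  expect_warning(
    simulate_umbrella_windows(p, centers = c(20, 160), spring_k = 0.5,
                              n_steps = 2000, seed = 5),
    "share")
})

test_that("trajectory CSV IO round-trips", {
  tr <- simulate_double_well_trajectory(dw_preset("wt"), n_steps = 100,
                                        seed = 2)
  path <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, path)
  tr2 <- read_trajectory_csv(path, dt = tr$dt)
  expect_equal(tr2$theta, tr$theta, tolerance = 1e-12)
})
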