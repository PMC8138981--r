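test_that("helix_axis recovers the construction axis and transforms equivariantly", {
  i <- 0:17
  ca <- cbind(2.3 * cos(i * 100 * pi / 180), 2.3 * sin(i * 100 * pi / 180),
              1.5 * i)
  ax <- helix_axis(ca)
  expect_equal(abs(sum(ax * c(0, 0, 1))), 1, tolerance = 1e-3)
  expect_gt(ax[3], 0)  # sign toward increasing residue index
  # rigid rotation
  th <- 0.7
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
  ax_rot <- helix_axis(ca %*% t(rot))
  expect_equal(as.numeric(rot %*% ax), ax_rot, tolerance = 1e-9)
  expect_error(helix_axis(ca[1:3, ]), "at least 4")
})

test_that("helix_axis equals the leading covariance eigenvector (oracle)", {
  set.seed(12)
  cloud <- cbind(rnorm(40, sd = 4), rnorm(40, sd = 1), rnorm(40, sd = 0.5))
  ax <- helix_axis(cloud)
  ev <- eigen(cov(cloud))$vectors[, 1]  # brute-force eigen-decomposition
  expect_equal(abs(sum(ax * ev)), 1, tolerance = 1e-9)
})

test_that("toy complexes reproduce their configured side-chain angle", {
  for (ang in c(100, 45, 90, 0.5)) {
    s <- make_toy_complex("N", angle = ang)
    mid <- s$resno[s$atom == "TIP"]
    expect_equal(sidechain_angle(s, mid), ang, tolerance = 0.5)
  }
  s_t <- make_toy_complex("T")
  expect_equal(sidechain_angle(s_t, s_t$resno[s_t$atom == "TIP"]), 45,
               tolerance = 0.5)
})

test_that("residue-type tip rules work and report missing atoms", {
  # miniature straight helix with a TRP ring and an ARG tip
  ca <- structure_df(rep("CA", 6), rep("GLY", 6), 1:6, "A",
                     cbind(0.1 * cos(1:6), 0.1 * sin(1:6), 1.5 * (1:6)))
  ring_atoms <- c("CD2", "CE2", "CE3", "CZ2", "CZ3", "CH2")
  ring <- structure_df(ring_atoms, rep("TRP", 6), 3L, "A",
                       cbind(1.4 + 0.2 * cos(1:6), 0.2 * sin(1:6),
                             rep(4.5, 6)))
  trp <- rbind(ca, ring)
  trp$resid[trp$resno == 3 & trp$atom == "CA"] <- "TRP"
  class(trp) <- c("structure_df", "data.frame")
  # ring centroid sits perpendicular to the axis from residue 3's CA
  expect_equal(sidechain_angle(trp, 3), 90, tolerance = 2)
  arg <- rbind(ca, structure_df("CZ", "ARG", 4L, "A",
                                matrix(c(0, 0, 9.0), 1)))
  arg$resid[arg$resno == 4 & arg$atom == "CA"] <- "ARG"
  class(arg) <- c("structure_df", "data.frame")
  expect_lt(sidechain_angle(arg, 4), 10)  # tip along the axis
  bad <- trp[trp$atom != "CH2", ]
  class(bad) <- c("structure_df", "data.frame")
  expect_error(sidechain_angle(bad, 3), "CH2")
})

test_that("PDB round trip preserves coordinates and annotations", {
  s <- make_toy_complex("N")
  path <- tempfile(fileext = ".pdb")
  write_structure_pdb(s, path)
  s2 <- read_structure_pdb(path)
  expect_equal(s2$x, s$x, tolerance = 1e-3)
  expect_equal(s2$atom, s$atom)
  expect_equal(s2$chain, s$chain)
  expect_equal(sidechain_angle(s2, s2$resno[s2$atom == "TIP"]),
               95, tolerance = 0.5)
})

test_that("explicit-boundary state classification counts exactly", {
  theta <- c(rep(50, 34), rep(110, 966))
  st <- classify_states(angle_trajectory(theta), boundaries = 75)
  expect_equal(st$populations[["T"]], 0.034)
  expect_equal(st$populations[["N"]], 0.966)
  expect_equal(sum(st$populations), 1)
  expect_equal(st$n_transitions, 1)
  # single state: no transitions
  st1 <- classify_states(angle_trajectory(rep(100, 50)), boundaries = 75)
  expect_equal(st1$n_transitions, 0)
  # alternating series: every frame switches
  alt <- angle_trajectory(rep(c(50, 110), 25))
  expect_equal(classify_states(alt, boundaries = 75)$n_transitions, 49)
})

test_that("relabelling the split swaps populations exactly", {
  set.seed(4)
  theta <- c(runif(300, 20, 60), runif(700, 80, 140))
  a <- classify_states(theta, boundaries = 70)
  b <- classify_states(theta, boundaries = 70,
                       labels = c(low = "N", high = "T"))
  expect_equal(a$populations[["T"]], b$populations[["N"]])
  expect_equal(a$populations[["N"]], b$populations[["T"]])
})

test_that("auto boundaries find the density gap of a bimodal trajectory", {
  set.seed(8)
  theta <- pmin(pmax(c(rnorm(2000, 45, 8), rnorm(6000, 95, 8)), 0), 180)
  st <- classify_states(theta, boundaries = "auto")
  expect_gt(st$boundary, 55)
  expect_lt(st$boundary, 85)
  expect_equal(st$populations[["T"]], 0.25, tolerance = 0.02)
  expect_error(classify_states(runif(500, 88, 92), boundaries = "auto"),
               "explicit")
})

test_that("Boltzmann inversion matches the two-bin closed form", {
  theta <- c(rep(30, 900), rep(120, 100))
  p <- pmf_boltzmann(theta, breaks = c(0, 75, 180), kT = 0.5925)
  expect_equal(p$free_energy[1], 0)
  expect_equal(p$free_energy[2], -0.5925 * log(100 / 900), tolerance = 1e-12)
})

test_that("unvisited bins are undefined, never zero", {
  theta <- runif(500, 80, 100)
  p <- pmf_boltzmann(theta, breaks = seq(0, 180, by = 20))
  expect_true(all(is.na(p$free_energy[!p$defined])))
  expect_true(any(!p$defined))
  expect_equal(min(p$free_energy[p$defined]), 0)
  path <- tempfile(fileext = ".csv")
  write_pmf_csv(p, path)
  p2 <- read_pmf_csv(path)
  expect_equal(p2$free_energy, p$free_energy)
  expect_equal(p2$defined, p$defined)
})

test_that("flat sampling yields a flat PMF within the multinomial bound", {
  set.seed(15)
  n <- 1e5
  nb <- 18
  theta <- runif(n, 0, 180)
  p <- pmf_boltzmann(theta, breaks = seq(0, 180, length.out = nb + 1))
  # 3-sigma multinomial bound on -kT log p around uniform
  sigma_p <- sqrt((1 / nb) * (1 - 1 / nb) / n)
  bound <- 3 * KT_298 * sigma_p / (1 / nb) * 2  # min-shift can double it
  expect_lt(max(p$free_energy), bound)
})

test_that("PMF error shrinks roughly as n^-1/2 on known-density samples", {
  devs <- vapply(c(1e3, 1e5), function(n) {
    set.seed(42)
    theta <- runif(n, 0, 180)
    p <- pmf_boltzmann(theta, breaks = seq(0, 180, by = 20))
    max(p$free_energy)
  }, numeric(1))
  expect_lt(devs[2], devs[1] / 3)  # expect ~10x, allow slack
})
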