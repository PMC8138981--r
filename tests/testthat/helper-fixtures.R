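# Shared fixture builders; everything is generated in code at test time.

# Standard 32-band detector edges.
edges32 <- seq(450, 610, by = 5)

# Default donor/acceptor pair used across spectral tests.
test_pair <- function() {
  list(donor = fluorophore_preset("mCFP"),
       acceptor = fluorophore_preset("mCitrine"))
}

# A rectangular-emission fluorophore for analytic overlap checks.
flat_emitter <- function(lo, hi, step = 0.5, qy = 0.5) {
  wl <- seq(lo - 10, hi + 10, by = step)
  em <- as.numeric(wl >= lo & wl <= hi)
  fluorophore("flat", wl, excitation = em + 1e-12, emission = em + 1e-12,
              quantum_yield = qy, extinction_coeff = 1e4)
}

# A fluorophore with constant extinction over [lo, hi].
flat_absorber <- function(lo, hi, step = 0.5, eps = 1e4) {
  wl <- seq(lo - 10, hi + 10, by = step)
  shp <- as.numeric(wl >= lo & wl <= hi)
  fluorophore("flatA", wl, excitation = shp + 1e-12, emission = shp + 1e-12,
              quantum_yield = 0.5, extinction_coeff = eps)
}

# Brute-force constrained NNLS oracle on a coefficient grid.
grid_nnls <- function(A, y, dmax = 5, amax = 5, n = 201) {
  dg <- seq(0, dmax, length.out = n)
  ag <- seq(0, amax, length.out = n)
  best <- c(NA, NA, Inf)
  for (d in dg) {
    # residual is quadratic in a; evaluate on grid
    r0 <- y - d * A[, 1]
    rss <- vapply(ag, function(a) sum((r0 - a * A[, 2])^2), numeric(1))
    i <- which.min(rss)
    if (rss[i] < best[3]) best <- c(d, ag[i], rss[i])
  }
  list(donor = best[1], acceptor = best[2], rss = best[3])
}
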