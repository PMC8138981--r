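#' Quartic double-well angle potential
#'
#' A two-state free-energy landscape for a side-chain inclination angle
#' theta in `[0, 180]` degrees, parameterized directly by the two well
#' positions, their depths and the barrier height. The functional form is the
#' quartic whose derivative has roots at the two minima and at the
#' intervening barrier position; the barrier position and overall scale are
#' solved so that `U(theta_N) = -depth_n`, `U(theta_T) = -depth_t` and the
#' barrier top sits `barrier` kcal/mol above the shallower well.
#'
#' @param theta_n,theta_t Well positions in degrees within `[0, 180]`
#'   (distinct). By convention `theta_n` is the native-like orientation and
#'   `theta_t` the tilted one.
#' @param depth_n,depth_t Well depths in kcal/mol (>= 0) below the zero
#'   reference.
#' @param barrier Barrier height in kcal/mol above the shallower well (> 0).
#' @return An object of class `"double_well"` with polynomial coefficients
#'   for the potential and its gradient.
#' @export
double_well <- function(theta_n, theta_t, depth_n, depth_t, barrier) {
  if (theta_n == theta_t) stop("theta_n and theta_t must differ")
  for (th in c(theta_n, theta_t))
    if (th < 0 || th > 180) stop("well positions must lie in [0, 180] degrees")
  if (barrier <= 0) stop("barrier must be positive")
  if (depth_n < 0 || depth_t < 0) stop("well depths must be non-negative")
  m1 <- min(theta_n, theta_t)
  m2 <- max(theta_n, theta_t)
  u1 <- if (m1 == theta_n) -depth_n else -depth_t   # U at the lower-angle well
  u2 <- if (m2 == theta_n) -depth_n else -depth_t
  u_sh <- max(u1, u2)                                # shallower well energy
  m_sh <- if (u1 >= u2) m1 else m2
  u_bar <- u_sh + barrier
  # U'(theta) = s (theta - m1)(theta - tb)(theta - m2); antiderivative for s = 1:
  antideriv <- function(tb) {
    p <- c(1,
           -(m1 + tb + m2),
           m1 * tb + m1 * m2 + tb * m2,
           -m1 * tb * m2)            # cubic coefficients, descending powers
    pint <- c(p / (4:1), 0)          # quartic antiderivative
    function(x) ((((pint[1] * x + pint[2]) * x + pint[3]) * x + pint[4]) * x + pint[5])
  }
  # choose the barrier position tb so that the two energy gaps have the right ratio
  h <- function(tb) {
    f <- antideriv(tb)
    a_gap <- f(m2) - f(m1)         # (U(m2) - U(m1)) / s
    b_gap <- f(tb) - f(m_sh)       # (U(barrier) - U(shallow well)) / s
    a_gap * (u_bar - u_sh) - b_gap * (u2 - u1)
  }
  eps <- 1e-6 * (m2 - m1)
  root <- tryCatch(
    stats::uniroot(h, c(m1 + eps, m2 - eps), tol = 1e-12)$root,
    error = function(e)
      stop("could not place the barrier for these depths; check that the ",
           "barrier exceeds the depth difference"))
  f <- antideriv(root)
  scale <- (u_bar - u_sh) / (f(root) - f(m_sh))
  if (!is.finite(scale) || scale <= 0)
    stop("degenerate double-well parameterization")
  # expand s*(x-m1)(x-tb)(x-m2) and integrate for the potential coefficients
  grad_coef <- scale * c(1,
                         -(m1 + root + m2),
                         m1 * root + m1 * m2 + root * m2,
                         -m1 * root * m2)
  pot_coef <- c(grad_coef / (4:1), 0)
  # constant so U(m1) = u1
  u_m1 <- polyval_desc(pot_coef, m1)
  pot_coef[5] <- pot_coef[5] + (u1 - u_m1)
  structure(list(theta_n = theta_n, theta_t = theta_t,
                 depth_n = depth_n, depth_t = depth_t, barrier = barrier,
                 barrier_theta = root,
                 pot_coef = pot_coef, grad_coef = grad_coef,
                 form = "quartic"),
            class = "double_well")
}

# Horner evaluation, coefficients in descending powers.
polyval_desc <- function(coef, x) {
  y <- rep(coef[1], length(x))
  for (k in seq_along(coef)[-1]) y <- y * x + coef[k]
  y
}

#' Evaluate a double-well potential or its gradient
#'
#' @param pot A `"double_well"`.
#' @param theta Angles in degrees.
#' @return Energies in kcal/mol (`dw_energy`) or gradients in kcal/mol/deg
#'   (`dw_gradient`).
#' @export
dw_energy <- function(pot, theta) {
  stopifnot(inherits(pot, "double_well"))
  polyval_desc(pot$pot_coef, theta)
}

#' @rdname dw_energy
#' @export
dw_gradient <- function(pot, theta) {
  stopifnot(inherits(pot, "double_well"))
  polyval_desc(pot$grad_coef, theta)
}

#' @export
print.double_well <- function(x, ...) {
  cat(sprintf("<double_well: N at %g deg (-%g kcal/mol), T at %g deg (-%g kcal/mol), barrier %g kcal/mol at %.1f deg>\n",
              x$theta_n, x$depth_n, x$theta_t, x$depth_t, x$barrier,
              x$barrier_theta))
  invisible(x)
}

#' Double-well landscape presets
#'
#' Two configured landscapes for the side-chain angle at the mutation site:
#' * `"wt"` - a deep native (N) well at 95 degrees (5.0 kcal/mol) and a
#'   shallow tilted (T) well at 45 degrees (0.5 kcal/mol) separated by a
#'   2.0 kcal/mol barrier above the T well. The N-to-T barrier is then
#'   ~6.5 kcal/mol (~11 kT at 298 K), so spontaneous N-to-T transitions are
#'   essentially absent on accessible simulation timescales.
#' * `"w344r"` - a flatter landscape (N 1.0, T 2.0 kcal/mol deep, barrier
#'   1.2 kcal/mol) in which both orientations are visited and the tilted
#'   state is favoured.
#'
#' @param name `"wt"` or `"w344r"`.
#' @return A `"double_well"`.
#' @export
dw_preset <- function(name = c("wt", "w344r")) {
  name <- match.arg(name)
  switch(name,
    wt    = double_well(theta_n = 95, theta_t = 45,
                        depth_n = 5.0, depth_t = 0.5, barrier = 2.0),
    w344r = double_well(theta_n = 95, theta_t = 45,
                        depth_n = 1.0, depth_t = 2.0, barrier = 1.2))
}

#' Harmonic single-well angle potential
#'
#' `U(theta) = k/2 (theta - center)^2`, sharing the polynomial
#' representation of [double_well()] so the same Langevin and umbrella
#' machinery applies. Its analytic PMF is the potential itself, which makes
#' it the reference case for validating free-energy estimators.
#'
#' @param center Well position in degrees.
#' @param spring_k Harmonic constant, kcal/mol/deg^2 (> 0).
#' @return An object of classes `"harmonic_well"` and `"double_well"`.
#' @export
harmonic_potential <- function(center, spring_k) {
  if (spring_k <= 0) stop("spring_k must be positive")
  if (center < 0 || center > 180) stop("center must lie in [0, 180]")
  structure(list(theta_n = center, theta_t = center,
                 depth_n = 0, depth_t = 0, barrier = NA_real_,
                 barrier_theta = NA_real_,
                 pot_coef = c(0, 0, spring_k / 2, -spring_k * center,
                              spring_k * center^2 / 2),
                 grad_coef = c(0, 0, spring_k, -spring_k * center),
                 form = "harmonic"),
            class = c("harmonic_well", "double_well"))
}

#' Thermal energy at 298 K
#'
#' `kT = 0.5925` kcal/mol, the package-wide default temperature for all
#' free-energy profiles.
#' @export
KT_298 <- 0.5925

#' Angle trajectory
#'
#' Time series of a side-chain inclination angle in `[0, 180]` degrees.
#'
#' @param theta Angles in degrees.
#' @param dt Time per frame (arbitrary units).
#' @param provenance `"simulated"` or `"extracted"`.
#' @param seed Seed used if simulated.
#' @return An object of class `"angle_trajectory"`.
#' @export
angle_trajectory <- function(theta, dt = 1, provenance = "simulated",
                             seed = NULL) {
  theta <- as.numeric(theta)
  if (any(!is.finite(theta)))
    stop("trajectory angles must be finite")
  if (any(theta < 0 | theta > 180))
    stop("trajectory angles must lie in [0, 180] degrees")
  structure(list(theta = theta, dt = dt, provenance = provenance,
                 seed = seed),
            class = "angle_trajectory")
}

#' @export
print.angle_trajectory <- function(x, ...) {
  cat(sprintf("<angle_trajectory: %d frames, dt = %g, range %.1f-%.1f deg (%s)>\n",
              length(x$theta), x$dt, min(x$theta), max(x$theta), x$provenance))
  invisible(x)
}

#' Read / write an angle trajectory as CSV
#'
#' Columns `frame`, `theta_deg`.
#' @param traj An `"angle_trajectory"`.
#' @param path File path.
#' @param dt Time per frame to attach on read.
#' @export
write_trajectory_csv <- function(traj, path) {
  stopifnot(inherits(traj, "angle_trajectory"))
  utils::write.csv(data.frame(frame = seq_along(traj$theta),
                              theta_deg = traj$theta),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trajectory_csv
#' @export
read_trajectory_csv <- function(path, dt = 1) {
  df <- utils::read.csv(path)
  if (!all(c("frame", "theta_deg") %in% names(df)))
    stop("trajectory CSV must have columns frame, theta_deg")
  angle_trajectory(df$theta_deg[order(df$frame)], dt = dt,
                   provenance = "extracted")
}

# Core overdamped Langevin integrator on polynomial gradients with
# reflective boundaries at 0 and 180 degrees.
langevin_core <- function(grad_coef, kT, friction, dt, n_steps, theta0, seed) {
  set.seed(seed)
  noise <- if (kT > 0)
    stats::rnorm(n_steps, sd = sqrt(2 * kT * dt / friction))
  else
    numeric(n_steps)
  theta <- numeric(n_steps)
  x <- theta0
  scale <- dt / friction
  c1 <- grad_coef[1]; c2 <- grad_coef[2]; c3 <- grad_coef[3]; c4 <- grad_coef[4]
  for (i in seq_len(n_steps)) {
    g <- ((c1 * x + c2) * x + c3) * x + c4
    step <- -g * scale + noise[i]
    if (abs(step) > 30)
      stop(sprintf("integration unstable (|step| = %.1f deg > 30 deg); reduce dt = %g",
                   abs(step), dt))
    x <- x + step
    # reflective boundaries for an inclination angle
    while (x < 0 || x > 180) {
      if (x < 0) x <- -x
      if (x > 180) x <- 360 - x
    }
    theta[i] <- x
  }
  theta
}

#' Overdamped Langevin sampling of an angle landscape
#'
#' Euler-Maruyama integration of
#' `theta <- theta - U'(theta) dt/gamma + sqrt(2 kT dt/gamma) xi`
#' with reflective boundaries at 0 and 180 degrees (the angle between two
#' vectors is an inclination, not a periodic dihedral). At `kT = 0` the
#' dynamics reduce to gradient descent. The integrator refuses step sizes
#' for which the deterministic drift between the wells exceeds 5 degrees per
#' step, and aborts (naming `dt`) if any realized step exceeds 30 degrees.
#'
#' @param pot A `"double_well"` (or any object with `grad_coef`).
#' @param kT Thermal energy in kcal/mol (>= 0); default [KT_298].
#' @param friction Friction coefficient gamma (energy * time / deg^2).
#' @param dt Time step.
#' @param n_steps Number of steps.
#' @param theta0 Initial angle in degrees.
#' @param seed Integer seed (mandatory).
#' @return An `"angle_trajectory"` of length `n_steps`.
#' @export
simulate_double_well_trajectory <- function(pot, kT = KT_298, friction = 1,
                                            dt = 0.2, n_steps = 10000,
                                            theta0 = NULL, seed) {
  stopifnot(inherits(pot, "double_well"))
  if (missing(seed) || is.null(seed))
    stop("seed is a mandatory argument")
  if (kT < 0) stop("kT must be non-negative")
  if (dt <= 0 || friction <= 0) stop("dt and friction must be positive")
  if (is.null(theta0)) theta0 <- pot$theta_n
  # step-size guard over the region the dynamics start in (and the barrier,
  # which the trajectory must be able to cross cleanly)
  probe <- c(seq(max(0, theta0 - 10), min(180, theta0 + 10), length.out = 50),
             pot$barrier_theta)
  probe <- probe[is.finite(probe)]
  max_drift <- max(abs(dw_gradient(pot, probe))) * dt / friction
  if (max_drift >= 5)
    stop(sprintf("dt = %g too large: deterministic drift reaches %.1f deg/step (limit 5)",
                 dt, max_drift))
  theta <- langevin_core(pot$grad_coef, kT, friction, dt, n_steps, theta0, seed)
  angle_trajectory(theta, dt = dt, provenance = "simulated", seed = seed)
}

#' Umbrella-sampling windows over an angle landscape
#'
#' Samples a set of harmonically biased copies of the landscape,
#' `U(theta) + k/2 (theta - center)^2`, one window per requested center.
#' Because the bias is quadratic, the biased potential remains polynomial
#' and is integrated with the same Langevin core as the unbiased sampler
#' (a window with `spring_k = 0` is the unbiased sampler). Adjacent-window
#' histogram overlap is checked and a warning issued when neighbours share
#' less than 1% of probability mass.
#'
#' @param pot A `"double_well"`.
#' @param centers Window centers in degrees.
#' @param spring_k Harmonic bias constant, kcal/mol/deg^2 (>= 0).
#' @param kT,friction,dt,n_steps See
#'   [simulate_double_well_trajectory()].
#' @param seed Base seed; window i uses `seed + i - 1`.
#' @param burn_in Fraction of initial samples discarded per window.
#' @return A list of `"umbrella_window"` objects, each holding `traj`,
#'   `center`, `spring_k` and `kT`.
#' @export
simulate_umbrella_windows <- function(pot, centers, spring_k, kT = KT_298,
                                      friction = 1, dt = 0.2, n_steps = 5000,
                                      seed, burn_in = 0.1) {
  stopifnot(inherits(pot, "double_well"))
  if (missing(seed) || is.null(seed))
    stop("seed is a mandatory argument")
  if (spring_k < 0) stop("spring_k must be non-negative")
  windows <- vector("list", length(centers))
  for (i in seq_along(centers)) {
    biased <- pot
    # the biased landscape has its own stationary points; the unbiased
    # barrier position is meaningless for the step-size guard
    biased$barrier_theta <- NA_real_
    # add k/2 (theta - c)^2: gradient gains k*theta - k*c
    biased$grad_coef <- pot$grad_coef + c(0, 0, spring_k, -spring_k * centers[i])
    biased$pot_coef <- pot$pot_coef +
      c(0, 0, spring_k / 2, -spring_k * centers[i],
        spring_k * centers[i]^2 / 2)
    traj <- simulate_double_well_trajectory(biased, kT = kT,
                                            friction = friction, dt = dt,
                                            n_steps = n_steps,
                                            theta0 = centers[i],
                                            seed = seed + i - 1L)
    keep <- seq.int(floor(burn_in * n_steps) + 1L, n_steps)
    traj$theta <- traj$theta[keep]
    windows[[i]] <- structure(list(traj = traj, center = centers[i],
                                   spring_k = spring_k, kT = kT),
                              class = "umbrella_window")
  }
  check_window_overlap(windows)
  windows
}

# Warn when adjacent windows share < 1% of histogram mass.
check_window_overlap <- function(windows) {
  if (length(windows) < 2L) return(invisible(TRUE))
  ord <- order(vapply(windows, `[[`, 0, "center"))
  breaks <- seq(0, 180, by = 2)
  probs <- lapply(windows[ord], function(w) {
    h <- graphics::hist(w$traj$theta, breaks = breaks, plot = FALSE)
    h$counts / sum(h$counts)
  })
  for (i in seq_len(length(probs) - 1L)) {
    shared <- sum(pmin(probs[[i]], probs[[i + 1L]]))
    if (shared < 0.01)
      warning(sprintf("umbrella windows at %g and %g deg share only %.2f%% histogram mass",
                      windows[[ord[i]]]$center, windows[[ord[i + 1L]]]$center,
                      100 * shared))
  }
  invisible(TRUE)
}
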