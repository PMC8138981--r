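#' Two-state classification of an angle trajectory
#'
#' Assigns every frame to the tilted (`T`, low angle) or native-like (`N`,
#' high angle) orientation. In `"auto"` mode the angle density is smoothed
#' (kernel density estimate), the two highest modes located, and the split
#' placed at the density minimum between them; an explicit boundary angle
#' may be given instead. Populations, the transition count and mean dwell
#' times per state are reported.
#'
#' @param traj An `"angle_trajectory"` (or numeric angle vector).
#' @param boundaries `"auto"` or an explicit split angle in degrees.
#' @param labels Names for the low- and high-angle states
#'   (default `c(low = "T", high = "N")`).
#' @return An object of class `"state_assignment"` with elements `labels`
#'   (per frame), `boundary`, `populations`, `n_transitions` and
#'   `dwell_times`.
#' @export
classify_states <- function(traj, boundaries = "auto",
                            labels = c(low = "T", high = "N")) {
  theta <- if (inherits(traj, "angle_trajectory")) traj$theta else as.numeric(traj)
  dt <- if (inherits(traj, "angle_trajectory")) traj$dt else 1
  if (length(theta) == 0) stop("trajectory is empty")
  if (identical(boundaries, "auto")) {
    d <- stats::density(theta, from = 0, to = 180, n = 512)
    y <- d$y
    is_max <- which(diff(sign(diff(y))) == -2) + 1L
    if (length(is_max) < 2L)
      stop("auto mode found fewer than 2 wells; supply an explicit boundary")
    top2 <- sort(is_max[order(y[is_max], decreasing = TRUE)][1:2])
    between <- seq(top2[1], top2[2])
    dip <- min(y[between])
    # a genuine two-well split needs a real density gap, not a smoothing
    # wiggle: the dip must fall well below the smaller of the two modes
    if (dip > 0.8 * min(y[top2]))
      stop("auto mode found fewer than 2 wells (no density gap between ",
           "modes); supply an explicit boundary")
    boundary <- d$x[between[which.min(y[between])]]
  } else {
    boundary <- as.numeric(boundaries)
    if (length(boundary) != 1L || boundary <= 0 || boundary >= 180)
      stop("explicit boundary must be a single angle inside (0, 180)")
  }
  lab <- ifelse(theta <= boundary, labels[["low"]], labels[["high"]])
  pops <- c(mean(lab == labels[["low"]]), mean(lab == labels[["high"]]))
  names(pops) <- c(labels[["low"]], labels[["high"]])
  changes <- lab[-1] != lab[-length(lab)]
  runs <- rle(lab)
  dwell <- tapply(runs$lengths * dt, runs$values, mean)
  structure(list(labels = lab, boundary = boundary, populations = pops,
                 n_transitions = sum(changes),
                 dwell_times = dwell),
            class = "state_assignment")
}

#' @export
print.state_assignment <- function(x, ...) {
  cat(sprintf("<state_assignment: boundary %.1f deg; populations %s; %d transitions>\n",
              x$boundary,
              paste(sprintf("%s = %.3f", names(x$populations), x$populations),
                    collapse = ", "),
              x$n_transitions))
  invisible(x)
}

#' Potential of mean force container
#'
#' @param bin_centers Bin centres in degrees.
#' @param free_energy Free energies in kcal/mol, `NA` where undefined.
#' @param kT Thermal energy used.
#' @param method `"boltzmann_inversion"` or `"wham"`.
#' @return A data frame of class `"pmf"` with columns `bin_center`,
#'   `free_energy`, `defined`; defined bins are min-shifted to 0.
#' @export
pmf <- function(bin_centers, free_energy, kT, method) {
  defined <- is.finite(free_energy)
  if (!any(defined)) stop("all PMF bins are undefined")
  free_energy[defined] <- free_energy[defined] - min(free_energy[defined])
  free_energy[!defined] <- NA_real_
  out <- data.frame(bin_center = bin_centers, free_energy = free_energy,
                    defined = defined)
  class(out) <- c("pmf", "data.frame")
  attr(out, "kT") <- kT
  attr(out, "method") <- method
  out
}

#' Free-energy profile by Boltzmann inversion
#'
#' Histograms the trajectory and returns `F = -kT log p`, min-shifted to 0.
#' Bins never visited have infinite apparent free energy and are reported as
#' undefined (`NA`), never as 0.
#'
#' @param traj An `"angle_trajectory"` or numeric angle vector.
#' @param breaks Histogram breaks over `[0, 180]` (a count or a vector).
#' @param kT Thermal energy in kcal/mol.
#' @return A `"pmf"`.
#' @export
pmf_boltzmann <- function(traj, breaks = seq(0, 180, by = 5), kT = KT_298) {
  theta <- if (inherits(traj, "angle_trajectory")) traj$theta else as.numeric(traj)
  if (length(theta) == 0) stop("trajectory is empty")
  if (length(breaks) == 1L) breaks <- seq(0, 180, length.out = breaks + 1L)
  h <- graphics::hist(theta, breaks = breaks, plot = FALSE)
  p <- h$counts / sum(h$counts)
  f <- ifelse(p > 0, -kT * log(p), NA_real_)
  pmf(h$mids, f, kT, "boltzmann_inversion")
}

#' Free-energy profile by WHAM
#'
#' Combines harmonically biased umbrella windows into one unbiased PMF by
#' the standard self-consistent weighted-histogram iteration: with window
#' bias `w_i(b) = k_i/2 (theta_b - c_i)^2`, per-window counts `n_i(b)` and
#' sizes `N_i`, iterate
#' \deqn{P(b) \propto \frac{\sum_i n_i(b)}{\sum_i N_i e^{(f_i - w_i(b))/kT}},
#'   \qquad f_i = -kT \log \sum_b P(b) e^{-w_i(b)/kT}}
#' until the window free energies change by less than `tol`. A single
#' window with zero bias reduces exactly to Boltzmann inversion.
#'
#' @param windows List of `"umbrella_window"` objects (or lists with
#'   elements `theta` or `traj`, `center`, `spring_k`).
#' @param breaks Histogram breaks (count or vector) over `[0, 180]`.
#' @param kT Thermal energy in kcal/mol.
#' @param tol Convergence tolerance on the window free energies, kcal/mol.
#' @param max_iter Iteration cap; non-convergence is an error reporting the
#'   residual.
#' @return A `"pmf"` (method `"wham"`); window free energies are attached
#'   as attribute `"window_f"`.
#' @export
pmf_wham <- function(windows, breaks = seq(0, 180, by = 5), kT = KT_298,
                     tol = 1e-7, max_iter = 1e5) {
  if (length(windows) < 1L) stop("need at least one window")
  get_theta <- function(w) {
    if (!is.null(w$traj)) w$traj$theta else w$theta
  }
  centers <- vapply(windows, `[[`, 0, "center")
  springs <- vapply(windows, `[[`, 0, "spring_k")
  if (length(windows) > 1L) {
    cls <- lapply(windows, function(w)
      structure(list(traj = list(theta = get_theta(w)), center = w$center),
                class = "umbrella_window"))
    check_window_overlap(cls)
  }
  if (length(breaks) == 1L) breaks <- seq(0, 180, length.out = breaks + 1L)
  mids <- (breaks[-1] + breaks[-length(breaks)]) / 2
  nb <- length(mids)
  nw <- length(windows)
  counts <- matrix(0, nw, nb)
  for (i in seq_len(nw))
    counts[i, ] <- graphics::hist(get_theta(windows[[i]]), breaks = breaks,
                                  plot = FALSE)$counts
  n_tot <- rowSums(counts)
  n_b <- colSums(counts)
  bias <- outer(seq_len(nw), seq_len(nb),
                function(i, b) springs[i] / 2 * (mids[b] - centers[i])^2)
  f <- numeric(nw)
  for (iter in seq_len(max_iter)) {
    denom <- colSums(n_tot * exp((f - bias) / kT))
    p <- ifelse(n_b > 0, n_b / denom, 0)
    p <- p / sum(p)
    f_new <- -kT * log(as.vector(exp(-bias / kT) %*% p))
    f_new <- f_new - f_new[1]
    delta <- max(abs(f_new - f))
    f <- f_new
    if (delta < tol) break
    if (iter == max_iter)
      stop(sprintf("WHAM did not converge in %d iterations (residual %.3g kcal/mol)",
                   max_iter, delta))
  }
  fe <- ifelse(p > 0, -kT * log(p), NA_real_)
  out <- pmf(mids, fe, kT, "wham")
  attr(out, "window_f") <- f
  out
}

#' Read / write a PMF as CSV
#'
#' Columns `bin_center_deg`, `free_energy_kcal`, `defined_flag`; undefined
#' bins are written with an empty free energy.
#'
#' @param p A `"pmf"`.
#' @param path File path.
#' @param kT,method Metadata attached on read.
#' @export
write_pmf_csv <- function(p, path) {
  stopifnot(inherits(p, "pmf"))
  utils::write.csv(data.frame(bin_center_deg = p$bin_center,
                              free_energy_kcal = p$free_energy,
                              defined_flag = p$defined),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pmf_csv
#' @export
read_pmf_csv <- function(path, kT = KT_298, method = "boltzmann_inversion") {
  df <- utils::read.csv(path)
  need <- c("bin_center_deg", "free_energy_kcal", "defined_flag")
  if (!all(need %in% names(df)))
    stop("PMF CSV must have columns: ", paste(need, collapse = ", "))
  fe <- df$free_energy_kcal
  fe[!df$defined_flag] <- NA_real_
  pmf(df$bin_center_deg, fe, kT, method)
}
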