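#' Spectral overlap integral
#'
#' Computes the Forster overlap integral
#' \deqn{J = \int f_D(\lambda)\, \varepsilon_A(\lambda)\, \lambda^4\, d\lambda}
#' in M^-1 cm^-1 nm^4, with the donor emission `f_D` area-normalized and the
#' acceptor extinction spectrum reconstructed as
#' `extinction_coeff * excitation shape`. Both spectra are resampled linearly
#' onto the finer of the two grids restricted to their common range;
#' trapezoidal quadrature is used.
#'
#' @param donor,acceptor `"fluorophore"` objects.
#' @return Overlap integral J (scalar). Returns 0 with a warning when the
#'   spectra do not overlap.
#' @export
overlap_integral <- function(donor, acceptor) {
  stopifnot(inherits(donor, "fluorophore"), inherits(acceptor, "fluorophore"))
  lo <- max(min(donor$wavelengths), min(acceptor$wavelengths))
  hi <- min(max(donor$wavelengths), max(acceptor$wavelengths))
  if (hi <= lo) {
    warning("donor emission and acceptor excitation grids do not overlap; J = 0")
    return(0)
  }
  step <- min(min(diff(donor$wavelengths)), min(diff(acceptor$wavelengths)))
  wl <- seq(lo, hi, by = step)
  f_d <- stats::approx(donor$wavelengths, donor$emission, xout = wl)$y
  eps_a <- acceptor$extinction_coeff *
    stats::approx(acceptor$wavelengths, acceptor$excitation, xout = wl)$y
  j <- pracma::trapz(wl, f_d * eps_a * wl^4)
  if (j == 0)
    warning("spectral shapes do not overlap after resampling; J = 0")
  j
}

#' Forster radius
#'
#' Sixth-root law `R0 = 0.211 * (kappa2 * n^-4 * QY_D * J)^(1/6)` with J in
#' M^-1 cm^-1 nm^4, giving R0 in Angstrom. Defaults `kappa2 = 2/3`
#' (isotropic dynamic averaging) and refractive index `n = 1.4` follow the
#' usual convention for fluorescent-protein pairs in cells.
#'
#' @param J Overlap integral, M^-1 cm^-1 nm^4.
#' @param qy_donor Donor quantum yield.
#' @param kappa2 Orientation factor.
#' @param n Refractive index (> 0).
#' @return R0 in Angstrom.
#' @export
forster_radius <- function(J, qy_donor, kappa2 = 2/3, n = 1.4) {
  if (J < 0 || qy_donor < 0 || kappa2 < 0)
    stop("J, qy_donor and kappa2 must be non-negative")
  if (n <= 0) stop("refractive index must be positive")
  0.211 * (kappa2 * n^-4 * qy_donor * J)^(1/6)
}

#' FRET efficiency at a given distance
#'
#' `E = 1 / (1 + (r/R0)^6)`: 50% transfer at `r = R0`, near-complete
#' transfer at contact, and a steep fall-off beyond ~1.6 R0.
#'
#' @param r Donor-acceptor distance, Angstrom (>= 0).
#' @param R0 Forster radius, Angstrom (> 0).
#' @return Efficiency in (0, 1].
#' @export
efficiency_from_distance <- function(r, R0) {
  if (any(r < 0)) stop("distance must be non-negative")
  if (R0 <= 0) stop("R0 must be positive")
  1 / (1 + (r / R0)^6)
}

#' Donor/acceptor Forster pair
#'
#' Bundles a donor and acceptor with the orientation factor and refractive
#' index, computing the overlap integral and Forster radius on construction.
#'
#' @param donor,acceptor `"fluorophore"` objects.
#' @param kappa2 Orientation factor (default 2/3).
#' @param refractive_index Medium refractive index (default 1.4).
#' @return An object of class `"forster_pair"` with elements `J` and `R0`.
#' @export
forster_pair <- function(donor, acceptor, kappa2 = 2/3,
                         refractive_index = 1.4) {
  j <- overlap_integral(donor, acceptor)
  structure(list(donor = donor, acceptor = acceptor, kappa2 = kappa2,
                 refractive_index = refractive_index, J = j,
                 R0 = forster_radius(j, donor$quantum_yield, kappa2,
                                     refractive_index)),
            class = "forster_pair")
}

#' @export
print.forster_pair <- function(x, ...) {
  cat(sprintf("<forster_pair %s -> %s: J = %.4g M-1cm-1nm4, R0 = %.2f A (kappa2 = %.3g, n = %.3g)>\n",
              x$donor$name, x$acceptor$name, x$J, x$R0, x$kappa2,
              x$refractive_index))
  invisible(x)
}

#' Derive an index-to-efficiency transfer function by simulation
#'
#' Reproduces the calibration step that links the measured FRET index to the
#' underlying efficiency: for every efficiency on a grid, a noiseless
#' spectral stack is forward-simulated for the pair, unmixed against the
#' pair's own band references, and the integral FRET index computed; the
#' saturating form `E = a + b * x/(x + c)` is then fitted to the (index,
#' efficiency) pairs by unweighted nonlinear least squares (start values
#' a = 0, b = 1, c = median(x)).
#'
#' @param pair A `"forster_pair"` (its fluorophores define the spectra and
#'   quantum yields).
#' @param laser Excitation line in nm.
#' @param band_edges Detection bands.
#' @param efficiency_grid Grid of true efficiencies (>= 5 points required).
#' @param stoichiometry Acceptor:donor abundance ratio (default 1).
#' @param cross_excitation Include direct acceptor excitation (default
#'   `TRUE`).
#' @return A fitted `"transfer_function"` carrying `r_squared`; a warning is
#'   issued if R^2 < 0.99.
#' @export
derive_transfer_function <- function(pair, laser = 405,
                                     band_edges = seq(450, 610, by = 5),
                                     efficiency_grid = seq(0, 0.95, by = 0.05),
                                     stoichiometry = 1,
                                     cross_excitation = TRUE) {
  stopifnot(inherits(pair, "forster_pair"))
  if (length(efficiency_grid) < 5L)
    stop("degenerate fit: the efficiency grid needs at least 5 points")
  scene <- ground_truth_scene(efficiency_grid, donor_abundance = 1,
                              acceptor_abundance = stoichiometry)
  stack <- simulate_spectral_stack(pair$donor, pair$acceptor, scene,
                                   laser = laser, band_edges = band_edges,
                                   cross_excitation = cross_excitation)
  um <- unmix(stack,
              band_reference(pair$donor, band_edges),
              band_reference(pair$acceptor, band_edges))
  x <- fret_index_integral(um)
  df <- data.frame(x = x, e = efficiency_grid)
  fit <- tryCatch(
    minpack.lm::nlsLM(e ~ a + b * x / (x + c), data = df,
                      start = list(a = 0, b = 1, c = stats::median(x)),
                      control = minpack.lm::nls.lm.control(maxiter = 500)),
    error = function(err)
      stop(sprintf("transfer-function fit failed to converge: %s (index range %.3g-%.3g)",
                   conditionMessage(err), min(x), max(x))))
  p <- stats::coef(fit)
  resid <- df$e - stats::predict(fit)
  r2 <- 1 - sum(resid^2) / sum((df$e - mean(df$e))^2)
  if (r2 < 0.99)
    warning(sprintf("fitted transfer function has R^2 = %.4f < 0.99", r2))
  transfer_function(unname(p["a"]), unname(p["b"]), unname(p["c"]),
                    r_squared = r2,
                    provenance = sprintf(
                      "fitted(%s/%s, laser %g nm, %d bands, %d-point E grid)",
                      pair$donor$name, pair$acceptor$name, laser,
                      length(band_edges) - 1L, length(efficiency_grid)))
}

#' Serialize a transfer function to JSON
#'
#' @param tf A `"transfer_function"`.
#' @param path Output path.
#' @return `path` invisibly; `read_transfer_json` returns the
#'   `"transfer_function"`.
#' @export
write_transfer_json <- function(tf, path) {
  stopifnot(inherits(tf, "transfer_function"))
  jsonlite::write_json(list(a = tf$a, b = tf$b, c = tf$c,
                            r_squared = tf$r_squared,
                            provenance = tf$provenance),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transfer_json
#' @export
read_transfer_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  transfer_function(x$a, x$b, x$c,
                    r_squared = if (is.null(x$r_squared)) NA_real_ else x$r_squared,
                    provenance = x$provenance %||% "file")
}
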