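#' Fluorophore reference spectrum
#'
#' Container for one fluorophore's wavelength-gridded excitation and emission
#' shapes together with its photophysical constants. On construction the
#' excitation shape is normalized to a maximum of 1 and the emission shape to
#' unit area (trapezoidal rule) over its grid, so downstream code can rely on
#' those conventions.
#'
#' @param name Character label (e.g. `"mCFP"`).
#' @param wavelengths Strictly increasing wavelength grid in nm.
#' @param excitation,emission Non-negative spectral shapes on `wavelengths`.
#' @param quantum_yield Donor emission quantum yield, in `[0, 1]`.
#' @param extinction_coeff Molar extinction coefficient at the excitation
#'   peak, in M^-1 cm^-1.
#' @return An object of class `"fluorophore"`.
#' @export
fluorophore <- function(name, wavelengths, excitation, emission,
                        quantum_yield, extinction_coeff) {
  wavelengths <- as.numeric(wavelengths)
  excitation <- as.numeric(excitation)
  emission <- as.numeric(emission)
  if (length(wavelengths) < 3L)
    stop("need at least 3 wavelength points")
  if (any(diff(wavelengths) <= 0))
    stop("wavelengths must be strictly increasing")
  if (length(excitation) != length(wavelengths) ||
      length(emission) != length(wavelengths))
    stop("excitation and emission must match the wavelength grid")
  if (any(excitation < 0) || any(emission < 0))
    stop("spectral shapes must be non-negative")
  if (!is.finite(quantum_yield) || quantum_yield < 0 || quantum_yield > 1)
    stop("quantum_yield must lie in [0, 1]")
  if (!is.finite(extinction_coeff) || extinction_coeff < 0)
    stop("extinction_coeff must be non-negative")
  if (max(excitation) <= 0 || max(emission) <= 0)
    stop("spectral shapes must not be identically zero")
  excitation <- excitation / max(excitation)
  emission <- emission / pracma::trapz(wavelengths, emission)
  structure(
    list(name = as.character(name), wavelengths = wavelengths,
         excitation = excitation, emission = emission,
         quantum_yield = quantum_yield, extinction_coeff = extinction_coeff),
    class = "fluorophore")
}

#' @export
print.fluorophore <- function(x, ...) {
  cat(sprintf("<fluorophore %s: ex peak %g nm, em peak %g nm, QY %.2f, eps %g M-1cm-1>\n",
              x$name,
              x$wavelengths[which.max(x$excitation)],
              x$wavelengths[which.max(x$emission)],
              x$quantum_yield, x$extinction_coeff))
  invisible(x)
}

#' Build a Gaussian fluorophore stand-in
#'
#' Creates a [fluorophore] whose excitation and emission shapes are Gaussians
#' in wavelength, centred at `ex_peak` and `em_peak` with a common standard
#' deviation `width`. Gaussian shapes are idealized stand-ins sufficient for
#' forward-modelling and calibration; measured spectra can be supplied through
#' [read_spectrum_csv()] instead.
#'
#' The default grid covers 450-610 nm in 5 nm steps, matching a 32-band
#' spectral detector. If the emission peak (plus three widths of tail) falls
#' outside the grid, the grid is extended automatically and a warning is
#' issued so the caller knows the detector window was exceeded.
#'
#' @param name Fluorophore label.
#' @param ex_peak,em_peak Excitation/emission peak wavelengths in nm; a Stokes
#'   shift (`em_peak > ex_peak`) is required.
#' @param width Gaussian standard deviation in nm (> 0).
#' @param quantum_yield,extinction_coeff See [fluorophore()].
#' @param grid_min,grid_max,step Wavelength grid specification in nm.
#' @return A `"fluorophore"` object.
#' @examples
#' cfp <- make_fluorophore("mCFP", 433, 475, 30, 0.41, 32500)
#' @export
make_fluorophore <- function(name, ex_peak, em_peak, width,
                             quantum_yield, extinction_coeff,
                             grid_min = 450, grid_max = 610, step = 5) {
  if (!is.finite(width) || width <= 0)
    stop("width must be positive")
  if (em_peak <= ex_peak)
    stop("em_peak must exceed ex_peak (Stokes shift)")
  lo <- grid_min
  hi <- grid_max
  if (em_peak > grid_max || em_peak < grid_min) {
    hi <- max(hi, step * ceiling((em_peak + 3 * width) / step))
    lo <- min(lo, step * floor((em_peak - 3 * width) / step))
    warning(sprintf("emission peak %g nm lies outside [%g, %g] nm; grid extended to [%g, %g] nm",
                    em_peak, grid_min, grid_max, lo, hi))
  }
  # keep most of the excitation band on-grid so laser lines can be looked up
  lo <- min(lo, step * floor((ex_peak - 3 * width) / step))
  wl <- seq(lo, hi, by = step)
  fluorophore(name, wl,
              excitation = exp(-0.5 * ((wl - ex_peak) / width)^2),
              emission = exp(-0.5 * ((wl - em_peak) / width)^2),
              quantum_yield = quantum_yield,
              extinction_coeff = extinction_coeff)
}

#' Built-in fluorophore presets
#'
#' Gaussian stand-ins for the four fluorescent proteins used throughout the
#' package: the CFP/Citrine pair used for live-cell FRET and the
#' mTFP1/mcpVenus pair used for the bacterial folding sensor. Quantum yields
#' are the literature values (0.41 mCFP, 0.74 mCitrine, 0.85 mTFP1,
#' 0.64 mcpVenus).
#'
#' @param name One of `"mCFP"`, `"mCitrine"`, `"mTFP1"`, `"mcpVenus"`.
#' @return A `"fluorophore"` object.
#' @export
fluorophore_preset <- function(name = c("mCFP", "mCitrine", "mTFP1", "mcpVenus")) {
  name <- match.arg(name)
  switch(name,
    mCFP     = make_fluorophore("mCFP",     433, 475, 30, 0.41, 32500),
    mCitrine = make_fluorophore("mCitrine", 516, 529, 25, 0.74, 77000),
    mTFP1    = make_fluorophore("mTFP1",    462, 492, 25, 0.85, 64000),
    mcpVenus = make_fluorophore("mcpVenus", 515, 528, 25, 0.64, 92200))
}

#' Read / write a fluorophore spectrum as CSV
#'
#' The CSV layout has columns `wavelength_nm`, `excitation`, `emission`,
#' `extinction`. On read the shapes are renormalized (excitation to max 1,
#' emission to unit area) and the extinction coefficient is taken as the
#' maximum of the `extinction` column; the quantum yield is not part of the
#' file and must be supplied.
#'
#' @param path File path.
#' @param name Fluorophore label to attach on read.
#' @param quantum_yield Quantum yield to attach on read.
#' @return `read_spectrum_csv` returns a `"fluorophore"`;
#'   `write_spectrum_csv` returns `path` invisibly.
#' @export
read_spectrum_csv <- function(path, name, quantum_yield) {
  df <- utils::read.csv(path)
  need <- c("wavelength_nm", "excitation", "emission", "extinction")
  if (!all(need %in% names(df)))
    stop("spectrum CSV must have columns: ", paste(need, collapse = ", "))
  fluorophore(name, df$wavelength_nm, df$excitation, df$emission,
              quantum_yield = quantum_yield,
              extinction_coeff = max(df$extinction))
}

#' @rdname read_spectrum_csv
#' @param fluor A `"fluorophore"` object.
#' @export
write_spectrum_csv <- function(fluor, path) {
  stopifnot(inherits(fluor, "fluorophore"))
  utils::write.csv(
    data.frame(wavelength_nm = fluor$wavelengths,
               excitation = fluor$excitation,
               emission = fluor$emission,
               extinction = fluor$excitation * fluor$extinction_coeff),
    path, row.names = FALSE)
  invisible(path)
}

# Linear interpolation of a shape at a wavelength; 0 outside the grid.
shape_at <- function(wavelengths, shape, lambda) {
  stats::approx(wavelengths, shape, xout = lambda, rule = 1)$y
}

#' Per-band capture fractions of an emission spectrum
#'
#' Integrates a fluorophore's (unit-area) emission shape over each detection
#' band, returning the fraction of the emitted light captured per band. Bands
#' are the half-open intervals `[edges[k], edges[k+1])`.
#'
#' @param fluor A `"fluorophore"`.
#' @param band_edges Strictly increasing band-edge wavelengths in nm
#'   (length = number of bands + 1).
#' @param resolution Internal quadrature step in nm.
#' @return Numeric vector of band integrals.
#' @export
band_capture <- function(fluor, band_edges, resolution = 0.5) {
  stopifnot(inherits(fluor, "fluorophore"))
  if (any(diff(band_edges) <= 0))
    stop("band_edges must be strictly increasing")
  nb <- length(band_edges) - 1L
  out <- numeric(nb)
  for (k in seq_len(nb)) {
    wl <- seq(band_edges[k], band_edges[k + 1L], by = resolution)
    y <- stats::approx(fluor$wavelengths, fluor$emission, xout = wl,
                       rule = 2, yleft = 0, yright = 0)$y
    y[wl < min(fluor$wavelengths) | wl > max(fluor$wavelengths)] <- 0
    out[k] <- pracma::trapz(wl, y)
  }
  out
}

#' Unit-area band reference for unmixing
#'
#' Band-sampled emission reference normalized so its band integrals sum to 1,
#' the convention under which the integral FRET index reduces to the ratio of
#' unmixing coefficients.
#'
#' @inheritParams band_capture
#' @return Numeric reference vector (one entry per band, summing to 1).
#' @export
band_reference <- function(fluor, band_edges) {
  b <- band_capture(fluor, band_edges)
  if (sum(b) <= 0)
    stop("emission does not overlap the detection bands")
  b / sum(b)
}
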