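#' Non-negative spectral unmixing
#'
#' Decomposes every sample of a spectral stack into non-negative
#' contributions of a donor and an acceptor emission reference by
#' non-negative least squares (NNLS), the open equivalent of vendor
#' unmixing software. Near-collinear references are rejected via the
#' condition number of the reference matrix.
#'
#' @param stack A `"spectral_stack"`.
#' @param donor_ref,acceptor_ref Emission reference vectors sampled on the
#'   stack's bands (see [band_reference()]).
#' @param max_condition Condition-number guard (default `1e6`).
#' @return A data frame of class `"unmix_result"` with columns
#'   `donor_coeff`, `acceptor_coeff`, `residual_norm`; the reference areas
#'   (sums over bands) are attached as attributes `area_donor` /
#'   `area_acceptor`, and the condition number as `condition`.
#' @export
unmix <- function(stack, donor_ref, acceptor_ref, max_condition = 1e6) {
  stopifnot(inherits(stack, "spectral_stack"))
  nb <- ncol(stack$data)
  if (length(donor_ref) != nb || length(acceptor_ref) != nb)
    stop("references must be sampled on the stack's bands")
  if (any(donor_ref < 0) || any(acceptor_ref < 0))
    stop("references must be non-negative")
  a_mat <- cbind(donor = as.numeric(donor_ref),
                 acceptor = as.numeric(acceptor_ref))
  cond <- kappa(a_mat, exact = TRUE)
  if (!is.finite(cond) || cond > max_condition)
    stop(sprintf("references are near-collinear (condition number %.3g)", cond))
  ns <- nrow(stack$data)
  d <- numeric(ns); a <- numeric(ns); rn <- numeric(ns)
  for (i in seq_len(ns)) {
    y <- stack$data[i, ]
    if (all(y == 0)) {
      d[i] <- 0; a[i] <- 0; rn[i] <- 0
    } else {
      fit <- pracma::lsqnonneg(a_mat, y)
      d[i] <- fit$x[1]; a[i] <- fit$x[2]
      rn[i] <- sqrt(sum((y - a_mat %*% fit$x)^2))
    }
  }
  out <- data.frame(donor_coeff = d, acceptor_coeff = a, residual_norm = rn)
  class(out) <- c("unmix_result", "data.frame")
  attr(out, "area_donor") <- sum(donor_ref)
  attr(out, "area_acceptor") <- sum(acceptor_ref)
  attr(out, "condition") <- cond
  out
}

#' Integral FRET index
#'
#' Ratio of total acceptor to total donor emission recovered by unmixing:
#' `(acceptor_coeff * area_A) / (donor_coeff * area_D)`. With unit-area
#' references this reduces to the coefficient ratio. Samples with zero donor
#' signal have an undefined index and are returned as `NA` with a warning.
#'
#' @param um An `"unmix_result"`.
#' @return Numeric vector of FRET indices (>= 0, or `NA` where undefined).
#' @export
fret_index_integral <- function(um) {
  stopifnot(inherits(um, "unmix_result"))
  area_d <- attr(um, "area_donor") %||% 1
  area_a <- attr(um, "area_acceptor") %||% 1
  idx <- (um$acceptor_coeff * area_a) / (um$donor_coeff * area_d)
  bad <- um$donor_coeff == 0
  if (any(bad)) {
    idx[bad] <- NA_real_
    warning(sprintf("%d sample(s) with zero donor coefficient excluded (undefined index)",
                    sum(bad)))
  }
  idx
}

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Peak-ratio FRET index
#'
#' Mean intensity over an acceptor wavelength band divided by the mean over a
#' donor band, the peak-ratio variant used for fluorimeter spectra. Bands are
#' half-open intervals `[lo, hi)` in nm.
#'
#' @param wavelengths,intensities Emission spectrum.
#' @param donor_band,acceptor_band Two-element `c(lo, hi)` nm windows.
#' @return Scalar FRET index.
#' @export
fret_index_peak <- function(wavelengths, intensities,
                            donor_band = c(485, 490),
                            acceptor_band = c(520, 525)) {
  if (length(wavelengths) != length(intensities))
    stop("wavelengths and intensities must have equal length")
  pick <- function(band) {
    if (band[1] < min(wavelengths) || band[2] > max(wavelengths))
      stop(sprintf("band [%g, %g) nm lies outside the spectrum grid",
                   band[1], band[2]))
    sel <- wavelengths >= band[1] & wavelengths < band[2]
    if (!any(sel)) stop("band contains no spectral samples")
    mean(intensities[sel])
  }
  band_ratio(pick(acceptor_band), pick(donor_band))
}

#' Expression-window quality control
#'
#' Includes a sample only when its emission summaries in both the
#' FRET-excitation channel and the direct acceptor-excitation channel fall
#' inside `[low, high]` (inclusive at both ends), ensuring comparable donor
#' and acceptor expression across samples.
#'
#' @param fret_summary,acceptor_summary Per-sample emission summaries
#'   (arbitrary units) under the two excitation lines.
#' @param low,high Window bounds (defaults 20 and 170 a.u.).
#' @return Logical inclusion mask.
#' @export
qc_expression_window <- function(fret_summary, acceptor_summary,
                                 low = 20, high = 170) {
  if (length(fret_summary) != length(acceptor_summary))
    stop("channel summaries must have equal length")
  fret_summary >= low & fret_summary <= high &
    acceptor_summary >= low & acceptor_summary <= high
}

#' Saturating index-to-efficiency transfer function
#'
#' Parameters of the mapping `E(x) = a + b * x / (x + c)` from FRET index x
#' to FRET efficiency, with optional fit quality and provenance.
#'
#' @param a Offset (efficiency at index 0).
#' @param b Scale of the saturating term.
#' @param c Half-saturation index (> 0).
#' @param r_squared Fit quality (NA for presets).
#' @param provenance `"preset"` or a description of the fit.
#' @return An object of class `"transfer_function"`.
#' @export
transfer_function <- function(a, b, c, r_squared = NA_real_,
                              provenance = "preset") {
  if (!is.finite(c) || c <= 0)
    stop("invalid transfer function: c must be positive")
  if (!is.finite(a) || !is.finite(b))
    stop("invalid transfer function: a and b must be finite")
  structure(list(a = a, b = b, c = c, r_squared = r_squared,
                 provenance = provenance),
            class = "transfer_function")
}

#' @export
print.transfer_function <- function(x, ...) {
  cat(sprintf("<transfer_function E(x) = %.4g + %.4g * x/(x + %.4g)%s [%s]>\n",
              x$a, x$b, x$c,
              if (is.na(x$r_squared)) "" else sprintf(", R^2 = %.4f", x$r_squared),
              x$provenance))
  invisible(x)
}

#' Calibrated transfer-function presets
#'
#' The two published calibrations shipped with the package:
#' * `"hek_cfp_yfp"` - living-cell CFP/YFP imaging,
#'   `E = 0.001 + 1.0022 * x/(x + 2.11)`;
#' * `"bact_tfp_venus"` - bacterial mTFP1/mcpVenus folding-sensor spectra,
#'   `E = -0.9279 + 1.9335 * x/(x + 0.6821)` (the negative intercept encodes
#'   acceptor cross-excitation at the donor laser line).
#'
#' @param name Preset name.
#' @return A `"transfer_function"`.
#' @export
transfer_preset <- function(name = c("hek_cfp_yfp", "bact_tfp_venus")) {
  name <- match.arg(name)
  switch(name,
    hek_cfp_yfp = transfer_function(0.001, 1.0022, 2.11,
                                    provenance = "preset hek_cfp_yfp"),
    bact_tfp_venus = transfer_function(-0.9279, 1.9335, 0.6821,
                                       provenance = "preset bact_tfp_venus"))
}

#' Map FRET index to efficiency
#'
#' Evaluates `E = a + b * x / (x + c)`. Clamping to `[0, 1]` is off by
#' default so that calibrations with a negative intercept report their raw
#' values; when `clamp = TRUE` the logical attribute `"clamped"` marks which
#' entries were clipped.
#'
#' @param tf A `"transfer_function"`.
#' @param fret_index Non-negative FRET indices.
#' @param clamp Clamp efficiencies into `[0, 1]`?
#' @return Numeric efficiencies (with a `"clamped"` attribute when
#'   `clamp = TRUE`).
#' @export
apply_transfer <- function(tf, fret_index, clamp = FALSE) {
  stopifnot(inherits(tf, "transfer_function"))
  if (any(fret_index < 0, na.rm = TRUE))
    stop("fret_index must be non-negative")
  e <- tf$a + tf$b * fret_index / (fret_index + tf$c)
  if (clamp) {
    clamped <- e < 0 | e > 1
    e <- pmin(pmax(e, 0), 1)
    attr(e, "clamped") <- clamped
  }
  e
}

#' Invert a transfer function
#'
#' Analytic inverse `x = c * (E - a) / (a + b - E)`, defined on the open
#' interval `a < E < a + b`.
#'
#' @param tf A `"transfer_function"`.
#' @param efficiency Efficiencies to invert.
#' @return FRET indices.
#' @export
invert_transfer <- function(tf, efficiency) {
  stopifnot(inherits(tf, "transfer_function"))
  if (any(efficiency <= tf$a | efficiency >= tf$a + tf$b))
    stop(sprintf("efficiency out of invertible range (%g, %g)",
                 tf$a, tf$a + tf$b))
  tf$c * (efficiency - tf$a) / (tf$a + tf$b - efficiency)
}

#' Intensity band ratio
#'
#' Shared kernel for peak ratios and gel densitometry: `a / b`, scale
#' invariant by construction.
#'
#' @param intensity_a,intensity_b Non-negative intensities; `intensity_b`
#'   must be positive.
#' @return `intensity_a / intensity_b`.
#' @export
band_ratio <- function(intensity_a, intensity_b) {
  if (any(intensity_b == 0))
    stop("denominator intensity is zero; ratio undefined")
  intensity_a / intensity_b
}
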