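#' Ground-truth FRET scene
#'
#' Per-sample (or per-pixel) true FRET efficiencies and fluorophore
#' abundances, with a noise model, used to drive the spectral forward model.
#' Scalars are recycled to the common length.
#'
#' @param efficiency True FRET efficiencies in `[0, 1]`.
#' @param donor_abundance,acceptor_abundance Non-negative abundances in
#'   arbitrary units.
#' @param noise One of `"none"`, `"gaussian"` (additive, sd = `noise_param`)
#'   or `"poisson"` (counts at `signal * noise_param` rescaled back).
#' @param noise_param Noise parameter (sd for gaussian, count scale for
#'   poisson).
#' @param seed Integer seed; mandatory unless `noise = "none"`.
#' @return An object of class `"fret_scene"`.
#' @export
ground_truth_scene <- function(efficiency, donor_abundance = 1,
                               acceptor_abundance = 1,
                               noise = c("none", "gaussian", "poisson"),
                               noise_param = 0, seed = NULL) {
  noise <- match.arg(noise)
  n <- max(length(efficiency), length(donor_abundance),
           length(acceptor_abundance))
  efficiency <- rep_len(as.numeric(efficiency), n)
  donor_abundance <- rep_len(as.numeric(donor_abundance), n)
  acceptor_abundance <- rep_len(as.numeric(acceptor_abundance), n)
  if (any(!is.finite(efficiency)) || any(efficiency < 0 | efficiency > 1))
    stop("efficiency must lie in [0, 1]")
  if (any(donor_abundance < 0) || any(acceptor_abundance < 0))
    stop("abundances must be non-negative")
  if (noise != "none" && is.null(seed))
    stop("seed is mandatory when a noise model is active")
  if (noise == "gaussian" && noise_param < 0)
    stop("gaussian noise sd must be non-negative")
  if (noise == "poisson" && noise_param <= 0)
    stop("poisson count scale must be positive")
  structure(list(efficiency = efficiency,
                 donor_abundance = donor_abundance,
                 acceptor_abundance = acceptor_abundance,
                 noise = noise, noise_param = noise_param, seed = seed),
            class = "fret_scene")
}

#' Multi-band spectral stack
#'
#' Per-sample emission intensities across contiguous detection bands,
#' together with the band edges and the excitation laser line.
#'
#' @param data Numeric matrix, samples x bands.
#' @param band_edges Strictly increasing band edges in nm (bands + 1 values).
#' @param laser Excitation wavelength in nm.
#' @param label Free-text acquisition label.
#' @param truth Optional `"fret_scene"` retained as ground truth.
#' @return An object of class `"spectral_stack"`.
#' @export
spectral_stack <- function(data, band_edges, laser, label = "",
                           truth = NULL) {
  data <- as.matrix(data)
  if (any(diff(band_edges) <= 0))
    stop("band_edges must be strictly increasing")
  if (ncol(data) != length(band_edges) - 1L)
    stop("data must have one column per band")
  structure(list(data = data, band_edges = as.numeric(band_edges),
                 laser = laser, label = label, truth = truth),
            class = "spectral_stack")
}

#' @export
print.spectral_stack <- function(x, ...) {
  cat(sprintf("<spectral_stack: %d samples x %d bands, %g-%g nm, laser %g nm%s>\n",
              nrow(x$data), ncol(x$data), min(x$band_edges), max(x$band_edges),
              x$laser, if (!is.null(x$truth)) ", ground truth attached" else ""))
  invisible(x)
}

#' Forward-simulate a spectral detector stack
#'
#' Generates banded emission signals for a donor/acceptor FRET pair under the
#' linear sensitized-emission model. For donor abundance d, acceptor
#' abundance a, true efficiency E, laser excitation efficiencies
#' `X_D(laser)`/`X_A(laser)` and per-band emission captures `F_D`/`F_A`, the
#' noiseless signal in band b is
#'
#' \deqn{S_b = d X_D Q_D (1-E) F_{D,b} + (d X_D Q_A E + a X_A Q_A) F_{A,b}}
#'
#' i.e. quenched donor emission, FRET-sensitized acceptor emission, and
#' (optionally) directly cross-excited acceptor emission. The ground-truth
#' scene travels with the returned stack.
#'
#' @param donor,acceptor `"fluorophore"` objects.
#' @param scene A [ground_truth_scene()].
#' @param laser Excitation wavelength in nm; must lie inside the donor grid.
#' @param band_edges Detection band edges (default 32 bands of 5 nm covering
#'   450-610 nm).
#' @param cross_excitation Include direct acceptor excitation at the laser
#'   line (default `TRUE`).
#' @param clip_negative Clip noisy intensities at zero (default `TRUE`).
#' @return A `"spectral_stack"` with the scene attached as `truth`.
#' @export
simulate_spectral_stack <- function(donor, acceptor, scene, laser = 405,
                                    band_edges = seq(450, 610, by = 5),
                                    cross_excitation = TRUE,
                                    clip_negative = TRUE) {
  stopifnot(inherits(donor, "fluorophore"), inherits(acceptor, "fluorophore"),
            inherits(scene, "fret_scene"))
  if (laser < min(donor$wavelengths) || laser > max(donor$wavelengths))
    stop("laser line lies outside the donor excitation grid")
  x_d <- shape_at(donor$wavelengths, donor$excitation, laser)
  x_a <- shape_at(acceptor$wavelengths, acceptor$excitation, laser)
  if (!cross_excitation || is.na(x_a)) x_a <- 0
  f_d <- band_capture(donor, band_edges)
  f_a <- band_capture(acceptor, band_edges)
  d <- scene$donor_abundance
  a <- scene$acceptor_abundance
  e <- scene$efficiency
  donor_amp <- d * x_d * donor$quantum_yield * (1 - e)
  acc_amp <- d * x_d * acceptor$quantum_yield * e +
    a * x_a * acceptor$quantum_yield
  signal <- outer(donor_amp, f_d) + outer(acc_amp, f_a)
  if (scene$noise != "none") {
    set.seed(scene$seed)
    signal <- switch(scene$noise,
      gaussian = signal + stats::rnorm(length(signal), sd = scene$noise_param),
      poisson = matrix(stats::rpois(length(signal),
                                    lambda = signal * scene$noise_param),
                       nrow = nrow(signal)) / scene$noise_param)
    if (clip_negative) signal <- pmax(signal, 0)
  }
  spectral_stack(signal, band_edges, laser,
                 label = sprintf("%s/%s simulated", donor$name, acceptor$name),
                 truth = scene)
}

#' Read / write spectral stacks as long-format CSV
#'
#' Columns: `sample`, `band`, `band_lo_nm`, `band_hi_nm`, `intensity`, plus
#' the laser line stored on every row (`laser_nm`).
#'
#' @param stack A `"spectral_stack"`.
#' @param path File path.
#' @return `read_stack_csv` returns a `"spectral_stack"`; `write_stack_csv`
#'   returns `path` invisibly.
#' @export
write_stack_csv <- function(stack, path) {
  stopifnot(inherits(stack, "spectral_stack"))
  nb <- ncol(stack$data)
  ns <- nrow(stack$data)
  df <- data.frame(
    sample = rep(seq_len(ns), times = nb),
    band = rep(seq_len(nb), each = ns),
    band_lo_nm = rep(stack$band_edges[-(nb + 1L)], each = ns),
    band_hi_nm = rep(stack$band_edges[-1L], each = ns),
    intensity = as.vector(stack$data),
    laser_nm = stack$laser)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_stack_csv
#' @export
read_stack_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("sample", "band", "band_lo_nm", "band_hi_nm", "intensity", "laser_nm")
  if (!all(need %in% names(df)))
    stop("stack CSV must have columns: ", paste(need, collapse = ", "))
  bands <- sort(unique(df$band))
  edges <- c(vapply(bands, function(b) df$band_lo_nm[df$band == b][1], 0),
             max(df$band_hi_nm))
  samples <- sort(unique(df$sample))
  m <- matrix(0, length(samples), length(bands))
  for (k in seq_along(bands)) {
    sub <- df[df$band == bands[k], ]
    m[match(sub$sample, samples), k] <- sub$intensity
  }
  spectral_stack(m, edges, laser = df$laser_nm[1], label = basename(path))
}

#' Read a multi-page TIFF spectral stack
#'
#' Each TIFF page is one detection band image; page k covers
#' `[edges[k], edges[k+1])` nm. Pixels become samples (row-major
#' flattening), so an `h x w` image with 32 pages yields an
#' `h*w x 32` stack.
#'
#' @param path TIFF file path.
#' @param band_edges Band edges to attach (default 32 x 5 nm over 450-610).
#' @param laser Laser line to attach, nm.
#' @return A `"spectral_stack"`.
#' @export
read_stack_tiff <- function(path, band_edges = seq(450, 610, by = 5),
                            laser = 405) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the 'tiff' package is required to read TIFF stacks")
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  if (length(pages) != length(band_edges) - 1L)
    stop(sprintf("TIFF has %d pages but %d bands were specified",
                 length(pages), length(band_edges) - 1L))
  m <- vapply(pages, function(p) as.vector(t(p)),
              numeric(length(pages[[1]])))
  spectral_stack(m, band_edges, laser, label = basename(path))
}
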