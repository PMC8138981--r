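#' Arrest-peptide force-profile scenario
#'
#' Ground-truth description of a tether-length construct library for
#' force-profile analysis: the full-length ratio rises once folding can
#' first relieve arrest (`onset_length`), peaks at `peak_length`, then
#' decays exponentially at `decay_rate` per residue; without the chaperone
#' present the folding signal vanishes and every construct sits at
#' `baseline_ratio`. Tether lengths are counted in residues from the
#' C-terminal conserved Pro of the arrest peptide, with the 17 AP residues
#' included in the count.
#'
#' @param tether_lengths Strictly increasing positive tether lengths
#'   (default the 7-construct library 18, 22, 24, 27, 34, 40, 50).
#' @param onset_length Length at which folding can first relieve arrest.
#' @param peak_length Length of maximal force (>= `onset_length`).
#' @param decay_rate Exponential decay per residue past the peak (>= 0).
#' @param chaperone_present Is the folding partner co-expressed?
#' @param baseline_ratio Ratio with no folding force.
#' @param amplitude Peak height above baseline.
#' @param noise_sd Gaussian replicate noise sd.
#' @return An object of class `"fpa_scenario"`.
#' @export
fpa_scenario <- function(tether_lengths = c(18, 22, 24, 27, 34, 40, 50),
                         onset_length = 20, peak_length = 22,
                         decay_rate = 0.15, chaperone_present = TRUE,
                         baseline_ratio = 0.1, amplitude = 1.0,
                         noise_sd = 0.05) {
  if (any(tether_lengths <= 0) || any(diff(tether_lengths) <= 0))
    stop("tether_lengths must be positive and strictly increasing")
  if (onset_length > peak_length)
    stop("onset_length must not exceed peak_length")
  if (decay_rate < 0 || noise_sd < 0 || baseline_ratio < 0)
    stop("decay_rate, noise_sd and baseline_ratio must be non-negative")
  structure(list(tether_lengths = tether_lengths,
                 onset_length = onset_length, peak_length = peak_length,
                 decay_rate = decay_rate,
                 chaperone_present = chaperone_present,
                 baseline_ratio = baseline_ratio, amplitude = amplitude,
                 noise_sd = noise_sd),
            class = "fpa_scenario")
}

#' Force-profile scenario presets
#'
#' * `"wt_cam"` - sharp folding transition: onset 20, peak at the
#'   22-residue tether, decay 0.15 per residue, amplitude 1.0.
#' * `"w344r_cam"` - broad, damped response: onset 24, plateau from the
#'   34-residue tether onward (no decay), amplitude 0.35, so no single
#'   construct stands out as a sharp peak.
#' * `"no_cam"` - chaperone absent: baseline everywhere.
#'
#' All share baseline 0.1, replicate noise sd 0.05 and the 7-length library.
#'
#' @param name Preset name.
#' @return An `"fpa_scenario"`.
#' @export
fpa_preset <- function(name = c("wt_cam", "w344r_cam", "no_cam")) {
  name <- match.arg(name)
  switch(name,
    wt_cam = fpa_scenario(),
    w344r_cam = fpa_scenario(onset_length = 24, peak_length = 34,
                             decay_rate = 0, amplitude = 0.35),
    no_cam = fpa_scenario(chaperone_present = FALSE))
}

# Noiseless profile shape at the given lengths.
fpa_true_ratio <- function(scn, lengths = scn$tether_lengths) {
  if (!scn$chaperone_present)
    return(rep(scn$baseline_ratio, length(lengths)))
  f <- numeric(length(lengths))
  ramp <- lengths >= scn$onset_length & lengths <= scn$peak_length
  if (scn$peak_length > scn$onset_length) {
    f[ramp] <- (lengths[ramp] - scn$onset_length) /
      (scn$peak_length - scn$onset_length)
  } else {
    f[ramp] <- 1
  }
  past <- lengths > scn$peak_length
  f[past] <- exp(-scn$decay_rate * (lengths[past] - scn$peak_length))
  scn$baseline_ratio + scn$amplitude * f
}

#' Simulate an arrest-peptide construct library
#'
#' Generates per-construct, per-replicate full-length ratios under a
#' scenario's ground truth with Gaussian replicate noise (truncated at 0).
#' The donor-peak intensity is fixed at 100 a.u. and the acceptor peak set
#' so that their [band_ratio()] equals the simulated ratio, mimicking the
#' peak-pair readout of a fluorimeter.
#'
#' @param scn An `"fpa_scenario"`.
#' @param n_replicates Replicates per construct.
#' @param condition Condition label stored on the constructs.
#' @param seed Integer seed (mandatory).
#' @return A data frame of class `"fpa_constructs"` with columns
#'   `construct_id`, `tether_length`, `condition`, `replicate`,
#'   `donor_peak`, `acceptor_peak`; the scenario's noiseless profile is
#'   attached as attribute `"truth"`.
#' @export
simulate_fpa_profile <- function(scn, n_replicates = 3,
                                 condition = if (scn$chaperone_present)
                                   "plus_cam" else "no_cam",
                                 seed) {
  stopifnot(inherits(scn, "fpa_scenario"))
  if (missing(seed) || is.null(seed)) stop("seed is a mandatory argument")
  set.seed(seed)
  lengths <- scn$tether_lengths
  truth <- fpa_true_ratio(scn)
  grid <- expand.grid(replicate = seq_len(n_replicates),
                      tether_length = lengths)
  ratio <- pmax(0, rep(truth, each = n_replicates) +
                  stats::rnorm(nrow(grid), sd = scn$noise_sd))
  donor <- 100
  out <- data.frame(
    construct_id = sprintf("L%02d_r%d", grid$tether_length, grid$replicate),
    tether_length = grid$tether_length,
    condition = condition,
    replicate = grid$replicate,
    donor_peak = donor,
    acceptor_peak = donor * ratio)
  class(out) <- c("fpa_constructs", "data.frame")
  attr(out, "truth") <- data.frame(tether_length = lengths, ratio = truth)
  out
}

#' Full-length fraction readout
#'
#' Ratio of acceptor-peak to donor-peak emission, the proxy for the
#' fraction of full-length reporter: a stalled (truncated) product carries
#' only the N-terminal donor and contributes no acceptor emission, so a
#' pure truncation reads 0 and mixtures read linearly in the full-length
#' share.
#'
#' @param donor_peak Donor peak intensity (> 0).
#' @param acceptor_peak Acceptor peak intensity (>= 0).
#' @return `acceptor_peak / donor_peak`.
#' @export
full_length_fraction <- function(donor_peak, acceptor_peak) {
  band_ratio(acceptor_peak, donor_peak)
}

#' Assemble a force profile from a construct table
#'
#' Averages the full-length ratio across replicates for every tether
#' length, reporting the replicate standard deviation (NA, not 0, for a
#' single replicate). All constructs must share one condition and carry
#' unique ids; input order does not matter.
#'
#' @param constructs A data frame with columns `construct_id`,
#'   `tether_length`, `condition`, `replicate`, and either `ratio` or the
#'   pair `donor_peak`/`acceptor_peak`.
#' @return A data frame of class `"force_profile"` with columns
#'   `tether_length`, `ratio`, `sd`, `n`, sorted by length; the condition
#'   is attached as an attribute.
#' @export
build_profile <- function(constructs) {
  need <- c("construct_id", "tether_length", "condition", "replicate")
  if (!all(need %in% names(constructs)))
    stop("construct table must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(constructs$construct_id))
    stop("duplicate construct_id in construct table")
  if (length(unique(constructs$condition)) > 1L)
    stop("constructs mix conditions: ",
         paste(unique(constructs$condition), collapse = ", "))
  if (length(unique(constructs$tether_length)) < 2L)
    stop("need at least 2 distinct tether lengths")
  ratio <- if ("ratio" %in% names(constructs)) constructs$ratio
  else full_length_fraction(constructs$donor_peak, constructs$acceptor_peak)
  lengths <- sort(unique(constructs$tether_length))
  agg <- function(fun) vapply(lengths, function(L)
    fun(ratio[constructs$tether_length == L]), numeric(1))
  out <- data.frame(
    tether_length = lengths,
    ratio = agg(mean),
    sd = agg(function(x) if (length(x) > 1L) stats::sd(x) else NA_real_),
    n = agg(length))
  class(out) <- c("force_profile", "data.frame")
  attr(out, "condition") <- constructs$condition[1]
  out
}

#' Detect the force-profile peak
#'
#' Identifies the tether length of maximal folding force: a candidate point
#' must strictly exceed its two nearest profile points and exceed both by at
#' least `k` times the pooled replicate standard deviation (for an endpoint,
#' the two nearest points both lie to one side, so endpoints face the same
#' two-comparison rigor as interior points). The peak is reported only when
#' exactly one significant candidate exists; broad plateaus, flat profiles
#' and ambiguous multi-peak profiles all return `NA` ("none"). The
#' significance rule is a configurable stand-in for the qualitative
#' peak/no-peak judgement made by eye.
#'
#' @param profile A `"force_profile"` with at least 3 points.
#' @param k Significance multiple of the pooled sd (default 2).
#' @return The peak tether length, or `NA` when no unique significant peak
#'   exists.
#' @export
profile_peak <- function(profile, k = 2) {
  stopifnot(inherits(profile, "force_profile"))
  n <- nrow(profile)
  if (n < 3L) stop("profile needs at least 3 points")
  r <- profile$ratio
  # pooled replicate sd: root mean variance across lengths
  sd_pool <- sqrt(mean(profile$sd^2, na.rm = TRUE))
  if (!is.finite(sd_pool)) sd_pool <- 0
  thresh <- k * sd_pool
  sig <- logical(n)
  for (i in seq_len(n)) {
    nb_idx <- setdiff(seq_len(n), i)
    nb_idx <- nb_idx[order(abs(nb_idx - i))][1:2]  # two nearest points
    nb <- r[nb_idx]
    sig[i] <- all(r[i] > nb) && all(r[i] - nb >= thresh)
  }
  if (sum(sig) == 1L) profile$tether_length[sig] else NA_real_
}

#' Soluble protein fraction
#'
#' Fraction of protein recovered in the supernatant:
#' `SN / (SN + pellet)`, from gel band densitometry.
#'
#' @param supernatant_intensity,pellet_intensity Band intensities (>= 0,
#'   not both 0).
#' @return Soluble fraction in `[0, 1]`.
#' @export
soluble_fraction <- function(supernatant_intensity, pellet_intensity) {
  if (any(supernatant_intensity < 0) || any(pellet_intensity < 0))
    stop("band intensities must be non-negative")
  tot <- supernatant_intensity + pellet_intensity
  if (any(tot == 0)) stop("total band intensity is zero")
  supernatant_intensity / tot
}

#' Read / write force-profile construct tables as CSV
#'
#' Columns as in [build_profile()].
#' @param constructs Construct data frame.
#' @param path File path.
#' @export
write_constructs_csv <- function(constructs, path) {
  utils::write.csv(as.data.frame(constructs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_constructs_csv
#' @export
read_constructs_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("construct_id", "tether_length", "condition", "replicate")
  if (!all(need %in% names(df)))
    stop("construct CSV must have columns: ", paste(need, collapse = ", "))
  class(df) <- c("fpa_constructs", "data.frame")
  df
}
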