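# Seeded chromatogram generator. Areas are produced by inverting the
# Beer-Lambert quantitation from a chosen pigment stoichiometry with
# phylloquinone fixed at 2 copies per monomer, so the full fit ->
# quantify -> normalize pipeline can be scored against exact ground
# truth.

#' Specify a synthetic chromatogram set
#'
#' @param stoichiometry Named copies per monomer; must contain
#'   `phylloquinone = 2` (the internal-standard definition).
#' @param psi_amount_umol PSI complex per injection (umol); the
#'   phylloquinone amount is twice this. The default 1e-4 umol puts the
#'   tallest chlorophyll peak near 1 OD, the working range below which
#'   no dilution is needed.
#' @param channels Species/channel table (default
#'   [species_channel_table()]).
#' @param flow_rate_ml_min,path_length_cm,dilution Instrument settings.
#' @param times Sampling grid (min).
#' @param noise_frac Gaussian noise sd as a fraction of the channel's
#'   tallest peak amplitude (0 = noiseless).
#' @param noise_sd_mOD Absolute noise sd (mOD); overrides `noise_frac`.
#' @param baseline c(intercept mOD, slope mOD/min) linear drift.
#' @param seed RNG seed (default 7521).
#' @return A `chromatogram_spec` list.
#' @export
chromatogram_spec <- function(stoichiometry = c(chl_a = 83, chl_f = 7,
                                                phylloquinone = 2),
                              psi_amount_umol = 1e-4,
                              channels = species_channel_table(),
                              flow_rate_ml_min = 0.5,
                              path_length_cm = 0.98, dilution = 1,
                              times = seq(0, 40, by = 0.05),
                              noise_frac = 0, noise_sd_mOD = NULL,
                              baseline = c(2, 0.05),
                              seed = DEFAULT_SEED) {
  if (!"phylloquinone" %in% names(stoichiometry) ||
      stoichiometry[["phylloquinone"]] != 2)
    stop("stoichiometry must fix phylloquinone at 2 copies per monomer")
  if (!is.null(noise_sd_mOD) && noise_sd_mOD < 0)
    stop("noise sd must be >= 0")
  if (noise_frac < 0) stop("noise fraction must be >= 0")
  if (psi_amount_umol < 0) stop("PSI amount must be >= 0")
  unknown <- setdiff(names(stoichiometry), channels$species)
  if (length(unknown)) stop("species not in channel table: ",
                            paste(unknown, collapse = ", "))
  # retention times must be distinct within every channel
  for (wl in unique(channels$wavelength_nm)) {
    rt <- channels$retention_min[channels$wavelength_nm == wl &
                                   channels$species %in%
                                     names(stoichiometry)]
    if (anyDuplicated(rt)) stop("duplicate retention times at ", wl, " nm")
  }
  structure(list(stoichiometry = stoichiometry,
                 psi_amount_umol = psi_amount_umol, channels = channels,
                 flow_rate_ml_min = flow_rate_ml_min,
                 path_length_cm = path_length_cm, dilution = dilution,
                 times = times, noise_frac = noise_frac,
                 noise_sd_mOD = noise_sd_mOD, baseline = baseline,
                 seed = seed),
            class = "chromatogram_spec")
}

#' Simulate a chromatogram set with ground truth
#'
#' For each species: amount = copies/2 * M(phylloquinone) with
#' M(phylloquinone) = 2 * PSI amount; the peak area is the exact
#' Beer-Lambert inverse `area = amount * eps * l / (FR * dilution)`, so
#' running [quantify_channels()] and
#' [normalize_to_internal_standard()] on a noiseless simulation returns
#' the specified stoichiometry. Traces are sums of Gaussians on a linear
#' baseline plus seeded Gaussian noise; one chromatogram per detection
#' wavelength.
#'
#' @param spec A [chromatogram_spec()].
#' @return List: `chromatograms` (named by wavelength), `truth`
#'   (amounts_umol, areas, stoichiometry, spec).
#' @export
simulate_chromatogram <- function(spec = chromatogram_spec()) {
  stopifnot(inherits(spec, "chromatogram_spec"))
  set.seed(spec$seed)
  phq_umol <- 2 * spec$psi_amount_umol
  sp <- spec$channels[spec$channels$species %in%
                        names(spec$stoichiometry), , drop = FALSE]
  copies <- spec$stoichiometry[sp$species]
  amounts <- setNames(as.numeric(copies) / 2 * phq_umol, sp$species)
  areas <- setNames(amounts * sp$epsilon * spec$path_length_cm /
                      (spec$flow_rate_ml_min * spec$dilution), sp$species)
  chroms <- list()
  for (wl in sort(unique(sp$wavelength_nm))) {
    rows <- sp[sp$wavelength_nm == wl, , drop = FALSE]
    y <- spec$baseline[1] + spec$baseline[2] * spec$times
    amp_max <- 0
    for (i in seq_len(nrow(rows))) {
      A <- areas[[rows$species[i]]] / (rows$sigma_min[i] * sqrt(2 * pi))
      amp_max <- max(amp_max, A)
      y <- y + A * exp(-(spec$times - rows$retention_min[i])^2 /
                         (2 * rows$sigma_min[i]^2))
    }
    sd_noise <- if (!is.null(spec$noise_sd_mOD)) spec$noise_sd_mOD
                else spec$noise_frac * amp_max
    if (sd_noise > 0)
      y <- y + stats::rnorm(length(y), sd = sd_noise)
    chroms[[as.character(wl)]] <- chromatogram(
      spec$times, y, wavelength_nm = wl,
      flow_rate_ml_min = spec$flow_rate_ml_min,
      path_length_cm = spec$path_length_cm, dilution = spec$dilution)
  }
  list(chromatograms = chroms,
       truth = list(amounts_umol = amounts, areas = areas,
                    stoichiometry = spec$stoichiometry, spec = spec))
}

#' Round trip: simulate, fit, quantify, normalize
#'
#' Convenience wrapper running the full quantitation pipeline on a
#' simulated chromatogram set.
#'
#' @param spec A [chromatogram_spec()].
#' @return A `stoichiometry_report`.
#' @export
recover_stoichiometry <- function(spec = chromatogram_spec()) {
  sim <- simulate_chromatogram(spec)
  amounts <- quantify_channels(sim$chromatograms, spec$channels)
  normalize_to_internal_standard(amounts)
}
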