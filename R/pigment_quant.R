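# HPLC pigment quantitation: Gaussian peak deconvolution of single-
# wavelength chromatograms, Beer-Lambert conversion of peak areas to
# amounts, and per-monomer stoichiometry via phylloquinone internal-
# standard normalization (PSI binds exactly two phylloquinones, so all
# injection-scale factors cancel through that ratio).

#' Extinction coefficients used for quantitation
#'
#' Molar extinction coefficients (M^-1 cm^-1) at each species' detection
#' wavelength: Chl a 70,540 (665 nm); Chl f 71,110 (705 nm); beta-carotene
#' 141,000; echinenone 120,000; phylloquinone 17,900 (270 nm).
#'
#' @return Named numeric vector.
#' @export
extinction_coefficients <- function() {
  c(chl_a = 70540, chl_f = 71110, beta_carotene = 141000,
    echinenone = 120000, phylloquinone = 17900)
}

#' Construct a chromatogram
#'
#' @param time_min Strictly increasing, uniformly sampled times (min).
#' @param absorbance_mOD Absorbance trace (mOD).
#' @param wavelength_nm Detection wavelength.
#' @param flow_rate_ml_min Flow rate (ml/min), default 0.5.
#' @param path_length_cm Optical path (cm), default 0.98.
#' @param dilution Dilution factor >= 1; values outside \{1, 3, 5\} are
#'   allowed with a warning.
#' @return A `chromatogram`.
#' @export
chromatogram <- function(time_min, absorbance_mOD, wavelength_nm,
                         flow_rate_ml_min = 0.5, path_length_cm = 0.98,
                         dilution = 1) {
  stopifnot(length(time_min) == length(absorbance_mOD))
  dt <- diff(time_min)
  if (any(dt <= 0)) stop("times must be strictly increasing")
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt))
    stop("times must be uniformly sampled")
  if (flow_rate_ml_min <= 0) stop("flow rate must be positive")
  if (path_length_cm <= 0) stop("path length must be positive")
  if (dilution < 1) stop("dilution must be >= 1")
  if (!dilution %in% c(1, 3, 5))
    warning("dilution ", dilution, " outside the usual {1, 3, 5}")
  structure(list(time_min = as.numeric(time_min),
                 absorbance_mOD = as.numeric(absorbance_mOD),
                 wavelength_nm = wavelength_nm,
                 flow_rate_ml_min = flow_rate_ml_min,
                 path_length_cm = path_length_cm,
                 dilution = dilution),
            class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(paste0("chromatogram @ %s nm: %d samples, %.2f-%.2f min, ",
                     "FR %.2g ml/min, l %.2f cm, dilution %g\n"),
              x$wavelength_nm, length(x$time_min), min(x$time_min),
              max(x$time_min), x$flow_rate_ml_min, x$path_length_cm,
              x$dilution))
  invisible(x)
}

#' Write / read a chromatogram CSV
#'
#' Plain CSV with columns `time_min`, `absorbance_mOD` preceded by
#' comment-style header keys (`# wavelength_nm: ...` etc.).
#'
#' @param x A `chromatogram`.
#' @param path File path.
#' @return `path` (write) or a `chromatogram` (read).
#' @export
write_chromatogram_csv <- function(x, path) {
  stopifnot(inherits(x, "chromatogram"))
  hdr <- sprintf("# %s: %g",
                 c("wavelength_nm", "flow_rate_ml_min", "path_length_cm",
                   "dilution"),
                 c(x$wavelength_nm, x$flow_rate_ml_min, x$path_length_cm,
                   x$dilution))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  writeLines("time_min,absorbance_mOD", con)
  writeLines(sprintf("%.6g,%.6g", x$time_min, x$absorbance_mOD), con)
  invisible(path)
}

#' @rdname write_chromatogram_csv
#' @export
read_chromatogram_csv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^#\\s*([A-Za-z_]+):\\s*([-0-9.eE+]+)", hdr))
  keys <- vapply(kv, `[`, "", 2); vals <- as.numeric(vapply(kv, `[`, "", 3))
  meta <- setNames(vals, keys)
  body <- read.table(text = lines[!grepl("^#", lines)], sep = ",",
                     header = TRUE)
  chromatogram(body$time_min, body$absorbance_mOD,
               wavelength_nm = meta[["wavelength_nm"]],
               flow_rate_ml_min = meta[["flow_rate_ml_min"]],
               path_length_cm = meta[["path_length_cm"]],
               dilution = meta[["dilution"]])
}

#' Initial peak detection
#'
#' Local maxima above a prominence threshold (height over the low-quantile
#' baseline estimate), separated by at least `min_separation_min`;
#' Gaussian width guessed from the half-height width.
#'
#' @param chrom A `chromatogram` (>= 10 samples).
#' @param prominence_mOD Minimum height above baseline; default 10% of
#'   the trace's dynamic range.
#' @param min_separation_min Minimum peak separation (min).
#' @return Data frame of guesses: mu, amplitude, sigma.
#' @export
detect_peaks <- function(chrom, prominence_mOD = NULL,
                         min_separation_min = 0.5) {
  stopifnot(inherits(chrom, "chromatogram"))
  t <- chrom$time_min; y <- chrom$absorbance_mOD
  if (length(y) < 10) stop("need >= 10 samples")
  base <- stats::quantile(y, 0.2, names = FALSE)
  if (is.null(prominence_mOD))
    prominence_mOD <- 0.1 * (max(y) - min(y))
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] >= y[1:(n - 2)] &
                     y[2:(n - 1)] > y[3:n], FALSE)
  cand <- which(is_max & (y - base) > prominence_mOD)
  if (!length(cand)) stop("no peaks above prominence ",
                          signif(prominence_mOD, 3), " mOD")
  cand <- cand[order(-y[cand])]
  kept <- integer(0)
  for (i in cand)
    if (!length(kept) || all(abs(t[i] - t[kept]) >= min_separation_min))
      kept <- c(kept, i)
  kept <- sort(kept)
  half_width <- function(i) {
    half <- base + (y[i] - base) / 2
    l <- i; while (l > 1 && y[l] > half) l <- l - 1
    r <- i; while (r < n && y[r] > half) r <- r + 1
    max(t[r] - t[l], 2 * stats::median(diff(t)))
  }
  data.frame(mu = t[kept], amplitude = y[kept] - base,
             sigma = vapply(kept, half_width, 1) / 2.3548)
}

gaussian_sum <- function(t, pars, k) {
  y <- pars[1] + pars[2] * t
  for (i in seq_len(k)) {
    A <- pars[2 + 3 * i - 2]; mu <- pars[2 + 3 * i - 1]
    sg <- pars[2 + 3 * i]
    y <- y + A * exp(-(t - mu)^2 / (2 * sg^2))
  }
  y
}

#' Fit a sum of Gaussians plus a linear baseline
#'
#' Nonlinear least squares (Levenberg-Marquardt) of
#' `b0 + b1 t + sum_i A_i exp(-(t - mu_i)^2 / (2 sigma_i^2))`. Peak areas
#' are `A * sigma * sqrt(2*pi)`. Fits failing to converge, or converging
#' to non-positive amplitudes or widths, are reported as errors -- a flat
#' trace forced to carry peaks fails rather than returning junk.
#'
#' @param chrom A `chromatogram`.
#' @param guesses Initial peaks (data frame mu/amplitude/sigma); default
#'   from [detect_peaks()].
#' @param max_iter Iteration cap (default 200).
#' @param ptol Relative parameter-change convergence tolerance (1e-8).
#' @return List: `peaks` (mu, sigma, amplitude, area, sorted by mu),
#'   `baseline` c(intercept, slope), `converged`, `fitted`.
#' @export
fit_gaussians <- function(chrom, guesses = NULL, max_iter = 200,
                          ptol = 1e-8) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (is.null(guesses)) guesses <- detect_peaks(chrom)
  k <- nrow(guesses)
  t <- chrom$time_min; y <- chrom$absorbance_mOD
  start <- c(min(y), 0,
             as.numeric(t(as.matrix(guesses[, c("amplitude", "mu",
                                                "sigma")]))))
  fit <- minpack.lm::nls.lm(
    par = start,
    fn = function(p) y - gaussian_sum(t, p, k),
    control = minpack.lm::nls.lm.control(maxiter = max_iter, ptol = ptol,
                                         ftol = ptol))
  if (!fit$info %in% 1:4)
    stop("peak fit did not converge (", fit$message, ")")
  p <- fit$par
  A <- p[seq(3, by = 3, length.out = k)]
  mu <- p[seq(4, by = 3, length.out = k)]
  sg <- abs(p[seq(5, by = 3, length.out = k)])
  if (any(A <= 0) || any(sg <= 0))
    stop("peak fit failed: non-positive amplitude or width")
  ord <- order(mu)
  peaks <- data.frame(mu = mu[ord], sigma = sg[ord], amplitude = A[ord],
                      area = (A * sg * sqrt(2 * pi))[ord])
  list(peaks = peaks, baseline = c(intercept = p[1], slope = p[2]),
       converged = TRUE, fitted = gaussian_sum(t, p, k))
}

#' Trapezoidal peak integration fallback
#'
#' Baseline-subtracted trapezoid area over a time window; used for clean
#' single peaks when a Gaussian fit is unnecessary or fails.
#'
#' @param chrom A `chromatogram`.
#' @param from,to Integration window (min).
#' @param baseline Length-2 c(intercept, slope) to subtract (default 0).
#' @return Area in mOD*min.
#' @export
integrate_trapezoid <- function(chrom, from = -Inf, to = Inf,
                                baseline = c(0, 0)) {
  t <- chrom$time_min; y <- chrom$absorbance_mOD
  sel <- t >= from & t <= to
  t <- t[sel]; y <- y[sel] - (baseline[1] + baseline[2] * t)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

#' Beer-Lambert quantitation of a peak area
#'
#' Converts a chromatographic peak area to an amount of substance:
#' `M[umol] = dilution * Area[mOD min] * FR[ml/min] / (eps[1/(M cm)] * l[cm])`.
#' The unit bookkeeping works out because mOD * ml / (M^-1 cm^-1 * cm)
#' carries the factor 10^-3 M * ml = 1 umol.
#'
#' @param area Peak area (mOD*min), >= 0.
#' @param flow_rate Flow rate (ml/min), > 0.
#' @param epsilon Molar extinction coefficient (M^-1 cm^-1), > 0.
#' @param path_length Optical path (cm), default 0.98.
#' @param dilution Dilution factor applied before injection, default 1.
#' @return Amount in umol.
#' @export
quantify <- function(area, flow_rate, epsilon, path_length = 0.98,
                     dilution = 1) {
  if (any(area < 0)) stop("area must be >= 0")
  if (flow_rate <= 0 || any(epsilon <= 0) || path_length <= 0 ||
      dilution <= 0)
    stop("flow rate, extinction coefficient, path length and dilution must be positive")
  dilution * area * flow_rate / (epsilon * path_length)
}

#' Default species/channel assignment table
#'
#' Retention-time windows and detection channels for the five quantified
#' species. Phylloquinone is monitored at 270 nm, the two carotenoids
#' elute close together at 453 nm (resolved peaks with overlapping
#' tails, separated by the Gaussian deconvolution), Chl a at 665 nm and
#' Chl f at 705 nm. Retention times are nominal positions on
#' a reversed-phase methanol/isopropanol gradient; assignment is by
#' retention window per channel, with no spectral unmixing.
#'
#' @return Data frame: species, wavelength_nm, retention_min, sigma_min,
#'   window_lo, window_hi, epsilon.
#' @export
species_channel_table <- function() {
  eps <- extinction_coefficients()
  d <- data.frame(
    species = c("phylloquinone", "echinenone", "beta_carotene", "chl_a",
                "chl_f"),
    wavelength_nm = c(270, 453, 453, 665, 705),
    retention_min = c(12, 28, 30, 22, 24),
    sigma_min = c(0.5, 0.8, 0.8, 0.5, 0.5),
    stringsAsFactors = FALSE)
  d$window_lo <- d$retention_min - 1.0
  d$window_hi <- d$retention_min + 1.0
  d$epsilon <- unname(eps[d$species])
  d
}

#' Quantify all species from a set of channel chromatograms
#'
#' Fits each channel's trace with a sum of Gaussians (initialized at the
#' expected retention times of that channel's species), assigns fitted
#' peaks to species by retention window, and converts areas to amounts.
#' If a channel's fit fails, a baseline-subtracted trapezoid over each
#' species window is used instead.
#'
#' @param chroms List of `chromatogram` objects.
#' @param channels Assignment table (default [species_channel_table()]).
#' @return Named numeric vector of amounts (umol per injection).
#' @export
quantify_channels <- function(chroms, channels = species_channel_table()) {
  amounts <- numeric(0)
  for (ch in chroms) {
    spec <- channels[channels$wavelength_nm == ch$wavelength_nm, ,
                     drop = FALSE]
    if (!nrow(spec)) next
    idx <- vapply(spec$retention_min, function(m)
      which.min(abs(ch$time_min - m)), 1L)
    base <- stats::quantile(ch$absorbance_mOD, 0.2, names = FALSE)
    guesses <- data.frame(mu = spec$retention_min,
                          amplitude = pmax(ch$absorbance_mOD[idx] - base,
                                           1e-3),
                          sigma = spec$sigma_min)
    fit <- tryCatch(fit_gaussians(ch, guesses), error = function(e) NULL)
    for (i in seq_len(nrow(spec))) {
      area <- if (!is.null(fit)) {
        inw <- fit$peaks$mu >= spec$window_lo[i] &
               fit$peaks$mu <= spec$window_hi[i]
        sum(fit$peaks$area[inw])
      } else {
        integrate_trapezoid(ch, spec$window_lo[i], spec$window_hi[i],
                            baseline = c(base, 0))
      }
      amounts[spec$species[i]] <- quantify(
        max(area, 0), ch$flow_rate_ml_min, spec$epsilon[i],
        ch$path_length_cm, ch$dilution)
    }
  }
  amounts
}

#' Internal-standard stoichiometry
#'
#' Scales species amounts so that the internal standard (phylloquinone,
#' of which PSI binds exactly two per monomer) equals `copies` copies:
#' `copies(s) = copies_std * M(s) / M(std)`. All injection-scale factors
#' (amount loaded, flow rate, dilution) cancel in the ratio.
#'
#' @param amounts Named numeric vector of amounts (umol).
#' @param standard Internal standard species name.
#' @param copies Copies of the standard per monomer (default 2).
#' @return A `stoichiometry_report`: list(`copies` named vector,
#'   `ratios` list).
#' @export
normalize_to_internal_standard <- function(amounts,
                                           standard = "phylloquinone",
                                           copies = 2) {
  if (!standard %in% names(amounts) || !isTRUE(amounts[[standard]] > 0))
    stop("internal standard '", standard, "' missing or zero")
  cp <- copies * amounts / amounts[[standard]]
  ratios <- list()
  if (all(c("chl_a", "chl_f") %in% names(cp)) && cp[["chl_f"]] > 0)
    ratios$chl_a_to_chl_f <- cp[["chl_a"]] / cp[["chl_f"]]
  if (all(c("beta_carotene", "echinenone") %in% names(cp)) &&
      cp[["echinenone"]] > 0)
    ratios$beta_carotene_to_echinenone <-
      cp[["beta_carotene"]] / cp[["echinenone"]]
  structure(list(copies = cp, ratios = ratios, standard = standard),
            class = "stoichiometry_report")
}

#' @export
print.stoichiometry_report <- function(x, ...) {
  cat("copies per monomer (", x$standard, " = ",
      x$copies[[x$standard]], "):\n", sep = "")
  for (s in names(x$copies))
    cat(sprintf("  %-14s %.2f\n", s, x$copies[[s]]))
  for (r in names(x$ratios))
    cat(sprintf("  %-28s %.2f\n", r, x$ratios[[r]]))
  invisible(x)
}

#' Renormalize chlorophyll copies to an assumed total
#'
#' Given measured copies per monomer and an assumed true chlorophyll
#' total (e.g. 90), reports the expected copies of each chlorophyll
#' species: `expected(s) = total * copies(s) / sum(chl copies)`.
#'
#' @param report A `stoichiometry_report` or named copies vector.
#' @param assumed_total Assumed chlorophyll total (default 90).
#' @param chl_species Names of chlorophyll species (default chl_a, chl_f).
#' @return Named numeric vector of expected copies.
#' @export
renormalize_total <- function(report, assumed_total = 90,
                              chl_species = c("chl_a", "chl_f")) {
  cp <- if (inherits(report, "stoichiometry_report")) report$copies
        else report
  chl_species <- intersect(chl_species, names(cp))
  tot <- sum(cp[chl_species])
  if (!length(chl_species) || tot <= 0)
    stop("no chlorophyll species with positive copies")
  assumed_total * cp[chl_species] / tot
}
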