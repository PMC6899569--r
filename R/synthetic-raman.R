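#' Pseudo-Voigt profile and its analytic area
#'
#' `pseudo_voigt()` evaluates `h * (eta * L + (1 - eta) * G)` where `L`
#' and `G` are Lorentzian and Gaussian profiles sharing centre `center`
#' and full width at half maximum `width`. `pv_area()` gives the analytic
#' area of a unit-height profile times `height`; `pv_height()` inverts it.
#'
#' @param x Wavenumber axis (cm^-1).
#' @param center,height,width,eta Band centre (cm^-1), peak height, FWHM
#'   (cm^-1), Lorentzian fraction in `[0, 1]`.
#' @return Intensities (or an area / a height).
#' @export
pseudo_voigt <- function(x, center, height, width, eta) {
  u2 <- 4 * ((x - center) / width)^2
  height * (eta / (1 + u2) + (1 - eta) * exp(-log(2) * u2))
}

#' @rdname pseudo_voigt
#' @export
pv_area <- function(height, width, eta) {
  height * width * (eta * pi / 2 + (1 - eta) * 0.5 * sqrt(pi / log(2)))
}

#' @rdname pseudo_voigt
#' @export
pv_height <- function(area, width, eta) {
  area / (width * (eta * pi / 2 + (1 - eta) * 0.5 * sqrt(pi / log(2))))
}

#' Specification of a synthetic Raman dataset
#'
#' One spec describes one treatment group: spectra are a polynomial
#' baseline plus pseudo-Voigt bands plus white Gaussian noise, with
#' optional single-pixel cosmic-ray spikes. Band areas vary across spectra
#' by a log-normal factor with coefficient of variation `area_cv`
#' (biological spread); the per-spectrum realised areas are returned as
#' the truth table.
#'
#' @param bands Data frame with columns `name`, `center` (cm^-1, within
#'   the wavenumber range), `area` (>= 0), `width` (FWHM, > 0), `eta`.
#' @param baseline_coef Polynomial baseline coefficients (degree <= 9),
#'   constant first, in the scaled variable `u = (x - mid) / halfspan`.
#' @param noise_sd Additive Gaussian noise sd (intensity units).
#' @param spike_count Cosmic-ray spikes per spectrum (single grid point).
#' @param spike_amplitude Spike height (intensity units).
#' @param n_spectra Number of spectra in the group.
#' @param area_cv Relative sd of the per-spectrum area factor.
#' @param wavenumber Wavenumber grid (strictly increasing, cm^-1).
#' @param seed Mandatory RNG seed.
#' @return Object of class `raman_phantom_spec`.
#' @export
raman_phantom_spec <- function(bands, baseline_coef = 0, noise_sd = 0,
                               spike_count = 0L, spike_amplitude = 0,
                               n_spectra = 1L, area_cv = 0,
                               wavenumber = seq(600, 1750, by = 1),
                               seed) {
  stopifnot(is.data.frame(bands),
            all(c("name", "center", "area", "width", "eta") %in% names(bands)))
  if (any(bands$center < min(wavenumber) | bands$center > max(wavenumber)))
    stop("band centers must lie within the wavenumber range")
  if (any(bands$width <= 0)) stop("band widths must be > 0")
  if (any(bands$area < 0)) stop("band areas must be >= 0")
  if (length(baseline_coef) > 10L)
    stop("baseline polynomial degree must be <= 9")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (is.unsorted(wavenumber, strictly = TRUE))
    stop("wavenumber axis must be strictly increasing")
  if (missing(seed)) stop("a seed is mandatory in every phantom spec")
  structure(list(bands = bands, baseline_coef = baseline_coef,
                 noise_sd = noise_sd, spike_count = as.integer(spike_count),
                 spike_amplitude = spike_amplitude,
                 n_spectra = as.integer(n_spectra), area_cv = area_cv,
                 wavenumber = wavenumber, seed = as.integer(seed)),
            class = "raman_phantom_spec")
}

eval_baseline <- function(coef, x) {
  u <- (x - mean(range(x))) / (diff(range(x)) / 2)
  drop(outer(u, seq_along(coef) - 1, "^") %*% coef)
}

#' Generate a synthetic Raman dataset with ground truth
#'
#' @param spec A [raman_phantom_spec].
#' @return List with `spectra` (list of [raman_spectrum]) and `truth`
#'   (data frame: `spectrum`, `band`, `center`, `width`, `eta`,
#'   `area` — the realised per-spectrum band area).
#' @export
generate_raman_dataset <- function(spec) {
  stopifnot(inherits(spec, "raman_phantom_spec"))
  with_seed(spec$seed, {
    x <- spec$wavenumber
    base <- eval_baseline(spec$baseline_coef, x)
    spectra <- vector("list", spec$n_spectra)
    truth <- vector("list", spec$n_spectra)
    for (s in seq_len(spec$n_spectra)) {
      b <- spec$bands
      if (spec$area_cv > 0) {
        sdlog <- sqrt(log(1 + spec$area_cv^2))
        b$area <- b$area * rlnorm(nrow(b), -sdlog^2 / 2, sdlog)
      }
      y <- base
      for (r in seq_len(nrow(b)))
        y <- y + pseudo_voigt(x, b$center[r],
                              pv_height(b$area[r], b$width[r], b$eta[r]),
                              b$width[r], b$eta[r])
      if (spec$noise_sd > 0) y <- y + rnorm(length(x), 0, spec$noise_sd)
      if (spec$spike_count > 0) {
        pos <- sample.int(length(x), spec$spike_count)
        y[pos] <- y[pos] + spec$spike_amplitude
      }
      spectra[[s]] <- raman_spectrum(x, y)
      truth[[s]] <- data.frame(spectrum = s, band = b$name,
                               center = b$center, width = b$width,
                               eta = b$eta, area = b$area,
                               stringsAsFactors = FALSE)
    }
    list(spectra = spectra, truth = do.call(rbind, truth))
  })
}
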