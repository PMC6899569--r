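#' Raman spectrum container
#'
#' Wavenumber/intensity pairs over the fingerprint region with processing
#' state flags.
#'
#' @param wavenumber Strictly increasing axis in cm^-1.
#' @param intensity Intensities, same length.
#' @return Object of class `raman_spectrum`.
#' @export
raman_spectrum <- function(wavenumber, intensity) {
  if (length(wavenumber) != length(intensity))
    stop("wavenumber and intensity lengths differ")
  if (is.unsorted(wavenumber, strictly = TRUE))
    stop("wavenumber axis must be strictly increasing")
  structure(list(wavenumber = wavenumber, intensity = intensity,
                 despiked = FALSE, denoised = FALSE,
                 baseline_corrected = FALSE, normalized = FALSE),
            class = "raman_spectrum")
}

#' @export
print.raman_spectrum <- function(x, ...) {
  flags <- c("despiked", "denoised", "baseline_corrected", "normalized")
  on <- flags[vapply(x[flags], isTRUE, logical(1))]
  cat(sprintf("<raman_spectrum> %d points, %.0f-%.0f cm-1%s\n",
              length(x$wavenumber), min(x$wavenumber), max(x$wavenumber),
              if (length(on)) paste0(" [", paste(on, collapse = ", "), "]")
              else ""))
  invisible(x)
}

#' Read a two-column wavenumber/intensity text file
#'
#' @param path Path to a whitespace- or comma-delimited two-column file.
#' @return A [raman_spectrum].
#' @export
read_raman_txt <- function(path) {
  first <- readLines(path, n = 1L)
  sep <- if (grepl(",", first)) "," else ""
  d <- read.table(path, sep = sep, header = FALSE,
                  comment.char = "#", col.names = c("wavenumber", "intensity"))
  d <- d[order(d$wavenumber), ]
  raman_spectrum(d$wavenumber, d$intensity)
}

# ---- wavelet denoising ------------------------------------------------
# Periodised orthogonal Daubechies-4 transform with hard thresholding at
# the universal threshold (noise scale from the MAD of the finest detail
# level). Small and self-contained; spectra are short 1D signals.

daub4_h <- c(0.4829629131445341, 0.8365163037378079,
             0.2241438680420134, -0.1294095225512604)
daub4_g <- rev(daub4_h) * c(1, -1, 1, -1)

dwt_step <- function(x) {
  n <- length(x); half <- n %/% 2L
  a <- numeric(half); d <- numeric(half)
  for (i in seq_len(half)) {
    js <- ((2L * i - 2L + 0:3) %% n) + 1L
    a[i] <- sum(daub4_h * x[js])
    d[i] <- sum(daub4_g * x[js])
  }
  list(a = a, d = d)
}

idwt_step <- function(a, d) {
  half <- length(a); n <- 2L * half
  x <- numeric(n)
  for (i in seq_len(half)) {
    js <- ((2L * i - 2L + 0:3) %% n) + 1L
    x[js] <- x[js] + daub4_h * a[i] + daub4_g * d[i]
  }
  x
}

wavelet_denoise <- function(y, levels = 4L) {
  n <- length(y)
  n2 <- 2^ceiling(log2(n))
  # symmetric padding to a power of two
  pad <- n2 - n
  yp <- c(y, rev(y)[seq_len(min(pad, n))])
  while (length(yp) < n2) yp <- c(yp, rev(yp)[seq_len(min(n2 - length(yp), length(yp)))])
  details <- vector("list", levels)
  a <- yp
  for (l in seq_len(levels)) {
    st <- dwt_step(a)
    a <- st$a
    details[[l]] <- st$d
  }
  sigma <- mad(details[[1]])
  thr <- sigma * sqrt(2 * log(n2))
  # hard thresholding: suppresses noise-scale coefficients without
  # shrinking genuine band amplitudes (soft thresholding biases weak
  # shoulders downwards)
  for (l in seq_len(levels)) {
    d <- details[[l]]
    d[abs(d) < thr] <- 0
    details[[l]] <- d
  }
  for (l in rev(seq_len(levels))) a <- idwt_step(a, details[[l]])
  a[seq_len(n)]
}

# ---- baseline ---------------------------------------------------------
# Iteratively reweighted polynomial baseline: points above the current
# fit (band candidates) are down-weighted asymmetrically, so the
# polynomial settles onto the band-free lower envelope instead of
# creeping up under broad bands (the known positive bias of clip-to-fit
# polynomial schemes).
polynomial_baseline <- function(x, y, order = 9L, max_iter = 50L,
                                tol = 1e-6, asymmetry = 0.001) {
  u <- (x - mean(range(x))) / (diff(range(x)) / 2)
  Pm <- cbind(1, unclass(stats::poly(u, degree = order)))
  rng <- diff(range(y))
  if (rng == 0) return(rep(y[1], length(y)))
  # high-frequency noise scale; points within ~2 sigma of the fit count
  # as baseline anchors (with a small floor so noise-free spectra keep
  # their anchors)
  sigma <- mad(diff(y)) / sqrt(2)
  band <- max(2 * sigma, 0.003 * rng)
  w <- rep(1, length(y))
  fit <- rep(mean(y), length(y))
  for (it in seq_len(max_iter)) {
    beta <- qr.coef(qr(Pm * sqrt(w)), y * sqrt(w))
    new_fit <- as.vector(Pm %*% beta)
    if (max(abs(new_fit - fit)) < tol * rng) { fit <- new_fit; break }
    fit <- new_fit
    w <- ifelse(y > fit + band, asymmetry, 1)
  }
  fit
}

#' Preprocess a raw Raman spectrum
#'
#' Three steps, in order: (1) despiking — isolated outliers more than
#' `spike_k` robust sds away from a running median are replaced by it
#' (cosmic-ray removal); (2) wavelet denoising — hard thresholding of a
#' Daubechies-4 decomposition at the universal threshold; (3) background
#' correction — an iteratively reweighted 9th-order polynomial baseline
#' is subtracted. The spectrum is cropped to the 600-1750 cm^-1 fingerprint
#' region, which the input axis must cover.
#'
#' @param spectrum A [raman_spectrum].
#' @param poly_order Baseline polynomial order.
#' @param despike,denoise Toggle the respective steps.
#' @param spike_k Despiking threshold in robust sds.
#' @return The processed [raman_spectrum] with state flags set.
#' @export
raman_preprocess <- function(spectrum, poly_order = 9L, despike = TRUE,
                             denoise = TRUE, spike_k = 8) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  x <- spectrum$wavenumber; y <- spectrum$intensity
  if (min(x) > 600 || max(x) < 1750)
    stop("spectrum must cover the 600-1750 cm-1 fingerprint region")
  keep <- x >= 600 & x <= 1750
  x <- x[keep]; y <- y[keep]
  if (despike) {
    med <- runmed(y, 5, endrule = "median")
    resid <- y - med
    s <- mad(resid)
    if (s > 0) {
      spikes <- abs(resid) > spike_k * s
      y[spikes] <- med[spikes]
    }
  }
  if (denoise) y <- wavelet_denoise(y)
  y <- y - polynomial_baseline(x, y, order = poly_order)
  out <- raman_spectrum(x, y)
  out$despiked <- despike
  out$denoised <- denoise
  out$baseline_corrected <- TRUE
  out
}

#' Normalise to the phenylalanine peak at 1004 cm^-1
#'
#' Divides by the intensity of the local maximum within 1004 +/- 5 cm^-1
#' (the phenylalanine ring-breathing band, used as an internal standard
#' for cell spectra).
#'
#' @param spectrum A baseline-corrected [raman_spectrum].
#' @return The normalised [raman_spectrum].
#' @export
raman_normalize <- function(spectrum) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (!isTRUE(spectrum$baseline_corrected))
    stop("normalisation requires a baseline-corrected spectrum")
  x <- spectrum$wavenumber
  win <- which(x >= 999 & x <= 1009)
  if (length(win) == 0) stop("spectrum does not cover 1004 cm-1")
  ref <- max(spectrum$intensity[win])
  if (ref <= 0) stop("non-positive intensity at the 1004 cm-1 reference peak")
  spectrum$intensity <- spectrum$intensity / ref
  spectrum$normalized <- TRUE
  spectrum
}

#' Band configuration for phosphate and matrix deconvolution
#'
#' Sub-band assignments for the v1 phosphate envelope follow common
#' bone-Raman usage: amorphous calcium phosphate (ACP) near 950 cm^-1,
#' octacalcium phosphate (OCP) near 955 cm^-1, carbonated apatite (CAP)
#' near 959-962 cm^-1. Matrix bands (amide I, CH2 deformation, amide III)
#' supply the mineral-to-matrix denominator. Centres float within
#' `center_tol` of their nominal position during fitting.
#'
#' @param phosphate_centers Named nominal centres of the phosphate
#'   sub-bands (cm^-1).
#' @param center_tol Allowed centre shift (cm^-1).
#' @param width_range FWHM bounds (cm^-1).
#' @param eta_init Initial Lorentzian fraction.
#' @param share_shape Share one width and one Lorentzian fraction across
#'   the phosphate sub-bands (default). Sub-bands of the v1 envelope
#'   overlap within their widths, and a fully free fit is not
#'   identifiable: very different area splits fit equally well. A common
#'   band shape restores identifiability; set `FALSE` to free all shapes.
#' @return A list used by [deconvolve_phosphate].
#' @export
phosphate_band_config <- function(phosphate_centers = c(ACP = 950, OCP = 955,
                                                        CAP = 961),
                                  center_tol = 2, width_range = c(3, 14),
                                  eta_init = 0.3, share_shape = TRUE) {
  list(
    phosphate = data.frame(species = names(phosphate_centers),
                           center = unname(phosphate_centers),
                           stringsAsFactors = FALSE),
    phosphate_window = c(935, 985),
    matrix = data.frame(
      species = c("amide_I", "CH2", "amide_III"),
      center = c(1660, 1450, 1275),
      window_lo = c(1590, 1410, 1230),
      window_hi = c(1720, 1495, 1330),
      center_tol = c(25, 10, 30),
      stringsAsFactors = FALSE),
    center_tol = center_tol, width_range = width_range,
    eta_init = eta_init, share_shape = share_shape)
}

# Least-squares fit of `k` pseudo-Voigt bands plus a constant offset over
# one window, with box constraints via minpack.lm. Overlapping sub-bands
# make the problem multimodal, so the fit is stagewise: heights are first
# solved linearly with the shapes held at nominal (a convex subproblem),
# then all parameters are refined; a small multistart over initial widths
# guards against the refinement walking into a neighbouring minimum, and
# the lowest-residual solution wins.
fit_pv_window <- function(x, y, centers, center_tol, width_range,
                          eta_init, share_shape = FALSE,
                          offset_degree = 0L) {
  k <- length(centers)
  nb <- offset_degree + 1L # local residual-baseline coefficients
  u <- (x - mean(range(x))) / (diff(range(x)) / 2)
  U <- outer(u, 0:offset_degree, "^")
  if (share_shape && k > 1) {
    # one common width and Lorentzian fraction across the sub-bands:
    # restores identifiability when bands overlap within their widths
    lower <- c(rep(0, k), centers - center_tol, width_range[1], 0,
               rep(-0.5, nb))
    upper <- c(rep(max(abs(y)) * 3 + 1, k), centers + center_tol,
               width_range[2], 1, rep(0.5, nb))
    model <- function(p) {
      yy <- as.vector(U %*% p[2 * k + 2 + seq_len(nb)])
      for (i in seq_len(k))
        yy <- yy + pseudo_voigt(x, p[k + i], p[i], p[2 * k + 1], p[2 * k + 2])
      yy
    }
    expand <- function(p) c(p[seq_len(2 * k)], rep(p[2 * k + 1], k),
                            rep(p[2 * k + 2], k))
  } else {
    lower <- c(rep(0, k), centers - center_tol, rep(width_range[1], k),
               rep(0, k), rep(-0.5, nb))
    upper <- c(rep(max(abs(y)) * 3 + 1, k), centers + center_tol,
               rep(width_range[2], k), rep(1, k), rep(0.5, nb))
    model <- function(p) {
      yy <- as.vector(U %*% p[4 * k + seq_len(nb)])
      for (i in seq_len(k))
        yy <- yy + pseudo_voigt(x, p[k + i], p[i], p[2 * k + i], p[3 * k + i])
      yy
    }
    expand <- function(p) p[seq_len(4 * k)]
  }
  w_starts <- unique(pmin(pmax(c(0.4, 0.6, 0.9) *
                                 mean(width_range), width_range[1]),
                          width_range[2]))
  best <- NULL
  for (w0 in w_starts) {
    # stage 1: linear height solve at fixed band shapes
    B <- vapply(centers, function(cc) pseudo_voigt(x, cc, 1, w0, eta_init),
                numeric(length(x)))
    B <- cbind(B, U)
    h0 <- tryCatch(qr.solve(B, y), error = function(e) rep(0, k + nb))
    h0 <- pmax(h0[seq_len(k)], 0)
    par0 <- if (share_shape && k > 1)
      c(h0, centers, w0, eta_init, rep(0, nb))
    else c(h0, centers, rep(w0, k), rep(eta_init, k), rep(0, nb))
    par0 <- pmin(pmax(par0, lower), upper)
    res <- minpack.lm::nls.lm(par = par0, lower = lower, upper = upper,
                              fn = function(p) y - model(p),
                              control = minpack.lm::nls.lm.control(
                                maxiter = 200, ptol = 1e-10, ftol = 1e-10))
    if (!res$info %in% 1:4) next
    if (is.null(best) || sum(res$fvec^2) < sum(best$fvec^2)) best <- res
  }
  if (is.null(best))
    stop("band fit did not converge in any start")
  p <- expand(best$par)
  data.frame(height = p[seq_len(k)], center = p[k + seq_len(k)],
             width = p[2 * k + seq_len(k)], eta = p[3 * k + seq_len(k)],
             area = pv_area(p[seq_len(k)], p[2 * k + seq_len(k)],
                            p[3 * k + seq_len(k)]),
             rms = sqrt(mean(best$fvec^2)))
}

#' Deconvolve the phosphate envelope and matrix bands
#'
#' Fits pseudo-Voigt sub-bands to the v1 phosphate envelope (948-970
#' cm^-1 region) — by default ACP, OCP and CAP species — and single
#' pseudo-Voigt bands to the matrix regions (amide I, CH2 1450, amide
#' III), each over its own window with a floating constant offset.
#' Heights are constrained non-negative and centres bounded near their
#' nominal positions.
#'
#' @param spectrum A normalised [raman_spectrum].
#' @param config Band configuration from [phosphate_band_config].
#' @return Object of class `band_fit`: list with `bands` (data frame:
#'   `species`, `center`, `width`, `eta`, `height`, `area`, `rms`),
#'   `species_areas` (named vector over ACP/OCP/CAP), `matrix_areas`,
#'   `phosphate_envelope_area` and `residual_rms`.
#' @export
deconvolve_phosphate <- function(spectrum, config = phosphate_band_config()) {
  stopifnot(inherits(spectrum, "raman_spectrum"))
  if (!isTRUE(spectrum$normalized))
    stop("deconvolution requires a normalised spectrum")
  x <- spectrum$wavenumber; y <- spectrum$intensity

  win <- x >= config$phosphate_window[1] & x <= config$phosphate_window[2]
  ph <- fit_pv_window(x[win], y[win], config$phosphate$center,
                      config$center_tol, config$width_range,
                      config$eta_init, share_shape = config$share_shape)
  ph$species <- config$phosphate$species

  mats <- lapply(seq_len(nrow(config$matrix)), function(i) {
    m <- config$matrix[i, ]
    w <- x >= m$window_lo & x <= m$window_hi
    ft <- fit_pv_window(x[w], y[w], m$center, m$center_tol,
                        c(5, 60), config$eta_init, offset_degree = 1L)
    ft$species <- m$species
    ft
  })
  bands <- rbind(ph, do.call(rbind, mats))
  bands <- bands[, c("species", "center", "width", "eta", "height",
                     "area", "rms")]
  structure(list(
    bands = bands,
    species_areas = setNames(ph$area, ph$species),
    matrix_areas = setNames(vapply(mats, function(m) m$area, numeric(1)),
                            config$matrix$species),
    phosphate_envelope_area = sum(ph$area),
    residual_rms = max(bands$rms)),
    class = "band_fit")
}

#' Mineral-to-matrix ratio
#'
#' Total fitted v1 phosphate envelope area divided by the amide I band
#' area — a Raman index of matrix mineralisation/maturity.
#'
#' @param fit A `band_fit` from [deconvolve_phosphate].
#' @return The ratio (0 when no phosphate is present).
#' @export
mineral_matrix_ratio <- function(fit) {
  stopifnot(inherits(fit, "band_fit"))
  denom <- fit$matrix_areas[["amide_I"]]
  if (is.na(denom) || denom <= 0)
    stop("amide I area is zero; mineral/matrix ratio undefined")
  fit$phosphate_envelope_area / denom
}

#' Signed fold change between two group means
#'
#' Increases are reported as `+A/B`, decreases by the reciprocal
#' convention as `-B/A`, so a halving is -2 rather than 0.5. Equal means
#' give +1.
#'
#' @param mean_a,mean_b Group means (both > 0); `mean_a` is the
#'   comparison group (e.g. knockout), `mean_b` the reference (e.g. wild
#'   type).
#' @return Signed fold change (vectorised).
#' @export
signed_fold_change <- function(mean_a, mean_b) {
  if (any(mean_a <= 0) || any(mean_b <= 0))
    stop("means must be positive")
  ifelse(mean_a >= mean_b, mean_a / mean_b, -mean_b / mean_a)
}
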