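#' Broadband source spectrum
#'
#' The light source is modelled as a Gaussian spectral envelope, sampled
#' uniformly in wavenumber (ideal spectrometer). The default centre
#' wavelength is 840 nm; the default 31 nm FWHM bandwidth puts the
#' theoretical axial resolution `(2 ln 2 / pi) * lambda^2 / dlambda` at
#' about 10 µm, which [axial_resolution()] verifies by simulation.
#'
#' @param center_wavelength nm.
#' @param fwhm_bandwidth full width at half maximum, nm.
#' @param n_samples number of spectral samples; must be a power of two.
#' @return list of class `"source_spectrum"`.
#' @export
source_spectrum <- function(center_wavelength = 840, fwhm_bandwidth = 31,
                            n_samples = 2048L) {
  if (center_wavelength <= 0 || fwhm_bandwidth <= 0)
    stopf("wavelength and bandwidth must be positive")
  n_samples <- as.integer(n_samples)
  if (n_samples < 2L || bitwAnd(n_samples, n_samples - 1L) != 0L)
    stopf("n_samples must be a power of two, got %d", n_samples)
  structure(list(center_wavelength = center_wavelength,
                 fwhm_bandwidth = fwhm_bandwidth,
                 n_samples = n_samples), class = "source_spectrum")
}

#' Scan geometry
#'
#' Defaults follow the acquisition geometry: 1000 A-lines over a 4 mm
#' lateral field (4 µm/px), 1000 depth pixels over a 4 mm depth range
#' (4 µm/px), with the stored image cropped to the top 600 depth rows that
#' contain tissue — reconciling the 1000 x 1000 acquisition with the
#' 1000 x 600 stored images.
#'
#' @param lateral_fov mm.
#' @param n_alines lateral pixels.
#' @param depth_pixels reconstructed depth pixels before cropping.
#' @param depth_crop stored depth rows (top of the image).
#' @param depth_fov mm of reconstructed depth range.
#' @return list of class `"scan_config"` with derived pitches
#'   `lateral_pitch` and `depth_pitch` in µm/pixel.
#' @examples
#' scan_config()$lateral_pitch  # 4
#' @export
scan_config <- function(lateral_fov = 4, n_alines = 1000L,
                        depth_pixels = 1000L, depth_crop = 600L,
                        depth_fov = 4) {
  if (lateral_fov <= 0 || depth_fov <= 0) stopf("fields of view must be positive")
  depth_pixels <- as.integer(depth_pixels)
  depth_crop <- as.integer(depth_crop)
  if (depth_crop > depth_pixels)
    stopf("depth_crop (%d) exceeds depth_pixels (%d)", depth_crop, depth_pixels)
  structure(list(lateral_fov = lateral_fov, n_alines = as.integer(n_alines),
                 depth_pixels = depth_pixels, depth_crop = depth_crop,
                 depth_fov = depth_fov,
                 lateral_pitch = 1000 * lateral_fov / n_alines,
                 depth_pitch = 1000 * depth_fov / depth_pixels),
            class = "scan_config")
}

# wavenumber grid (rad/µm) and Gaussian envelope for a source + geometry.
# Spacing is chosen so that the FFT depth bin equals the configured depth
# pitch: dz = pi / (N * dk).
k_grid <- function(source, depth_pitch_um) {
  n <- source$n_samples
  k0 <- 2 * pi / (source$center_wavelength / 1000)  # rad/µm
  dk <- pi / (n * depth_pitch_um)
  k <- k0 + (seq_len(n) - n / 2) * dk
  dl <- source$fwhm_bandwidth / 1000                 # µm
  dk_fwhm <- 2 * pi * dl / (source$center_wavelength / 1000)^2
  S <- exp(-4 * log(2) * (k - k0)^2 / dk_fwhm^2)
  list(k = k, S = S, dk = dk)
}

#' Simulate a spectral interferogram
#'
#' SD-OCT forward model for one A-line: the detected spectral intensity is
#' the source envelope times the squared magnitude of the reference field
#' plus the sample field, where a reflector at depth `z` contributes a
#' fringe of phase `2 k z`. Depth `z` of element `i` of `profile` is
#' `i * depth_pitch` µm.
#'
#' @param profile depth reflectivity profile, values in \[0, 1\].
#' @param source a [source_spectrum()].
#' @param depth_pitch µm per depth pixel (sets the wavenumber sampling).
#' @param sample_coupling amplitude coupling of the sample arm relative to
#'   the reference arm; small values keep autocorrelation terms negligible.
#' @return list of class `"interferogram"`: `intensities` (nonnegative,
#'   length `n_samples`), `background` (the reference-arm spectrum),
#'   `depth_pitch`.
#' @examples
#' prof <- numeric(200); prof[80] <- 1
#' ig <- simulate_interferogram(prof, source_spectrum(), depth_pitch = 4)
#' all(ig$intensities >= 0)
#' @export
simulate_interferogram <- function(profile, source = source_spectrum(),
                                   depth_pitch = 4, sample_coupling = 0.1) {
  if (length(profile) == 0L) stopf("empty reflectivity profile")
  if (any(profile < 0 | profile > 1)) stopf("profile values must be in [0,1]")
  g <- k_grid(source, depth_pitch)
  z <- seq_along(profile) * depth_pitch
  nz <- which(profile > 0)
  field <- rep(1 + 0i, source$n_samples)
  if (length(nz))
    field <- field + sample_coupling *
      (exp(2i * outer(g$k, z[nz])) %*% profile[nz])[, 1L]
  I <- g$S * Mod(field)^2
  structure(list(intensities = as.numeric(I), background = g$S,
                 depth_pitch = depth_pitch, source = source),
            class = "interferogram")
}

#' Reconstruct an A-line envelope
#'
#' The depth-resolved amplitude is the envelope (magnitude) of the Fourier
#' transform of the background-subtracted spectral signal, keeping
#' positive-depth bins. Element `i` of the result is depth
#' `i * depth_pitch / oversample` µm.
#'
#' @param ig an [simulate_interferogram()] result, or a raw intensity
#'   vector (then `background` must be given explicitly or defaults to the
#'   vector's mean).
#' @param depth_pixels number of depth bins to keep.
#' @param background reference-arm spectrum subtracted before the FFT
#'   (removes the dominant DC term).
#' @param oversample integer zero-padding factor; >1 refines the depth grid
#'   for sub-pixel peak measurements.
#' @return numeric envelope vector of length `depth_pixels * oversample`.
#' @export
reconstruct_aline <- function(ig, depth_pixels = NULL, background = NULL,
                              oversample = 1L) {
  if (inherits(ig, "interferogram")) {
    x <- ig$intensities
    if (is.null(background)) background <- ig$background
  } else {
    x <- as.numeric(ig)
    if (is.null(background)) background <- mean(x)
  }
  n <- length(x)
  if (!is.null(background) && length(background) != 1L &&
      length(background) != n)
    stopf("background length (%d) does not match spectrum length (%d)",
          length(background), n)
  if (is.null(depth_pixels)) depth_pixels <- n %/% 2L
  oversample <- as.integer(oversample)
  if (depth_pixels * oversample > (n * oversample) %/% 2L)
    stopf("depth_pixels (%d) exceeds the unambiguous depth range (%d)",
          depth_pixels, n %/% 2L)
  y <- c(x - background, numeric(n * (oversample - 1L)))
  env <- Mod(fft(y))
  env[seq(2L, depth_pixels * oversample + 1L)]
}

#' Normalize a B-scan by its maximum envelope amplitude
#'
#' The maximum amplitude of the detected envelope is the reference scaling
#' factor; every value is divided by it, so the per-image maximum is
#' exactly 1.
#'
#' @param amplitudes numeric matrix (or vector) of envelope amplitudes.
#' @return same shape, values in \[0, 1\] with `max == 1`.
#' @export
normalize_bscan <- function(amplitudes) {
  m <- max(amplitudes)
  if (!is.finite(m) || m <= 0)
    stopf("cannot normalize: no strictly positive amplitude")
  amplitudes / m
}

#' Log-compress normalized amplitudes to 8-bit
#'
#' Maps amplitude `x` in \[0, 1\] through
#' `255 * clip(1 + dB(x) / |floor_db|, 0, 1)` with `dB(x) = 20 log10(x)`:
#' full scale (1.0) maps to 255, amplitudes at or below the dynamic-range
#' floor map to 0, and the mapping is monotone.
#'
#' @param x normalized amplitudes in \[0, 1\].
#' @param floor_db dynamic-range floor in dB (negative; default -50).
#' @return integer matrix/vector of the same shape, values in \[0, 255\].
#' @examples
#' log_compress_u8(c(1, 10^(-25/20), 10^(-50/20), 0))
#' @export
log_compress_u8 <- function(x, floor_db = -50) {
  if (floor_db >= 0) stopf("floor_db must be negative, got %g", floor_db)
  if (any(x < 0 | x > 1)) stopf("input must be normalized to [0,1]")
  db <- ifelse(x > 0, 20 * log10(x), -Inf)
  out <- round(255 * pmin(pmax(1 + db / abs(floor_db), 0), 1))
  storage.mode(out) <- "integer"
  out
}

#' Precompute the B-scan simulator state
#'
#' Caches the wavenumber grid, source envelope and the complex phase matrix
#' `exp(2 i k z)` for a given source and geometry so that many frames of a
#' cohort can be scanned cheaply.
#'
#' @param source a [source_spectrum()].
#' @param config a [scan_config()].
#' @return list of class `"oct_simulator"`.
#' @export
oct_simulator <- function(source = source_spectrum(), config = scan_config()) {
  g <- k_grid(source, config$depth_pitch)
  z <- seq_len(config$depth_pixels) * config$depth_pitch
  structure(list(source = source, config = config, k = g$k, S = g$S,
                 phase = exp(2i * outer(g$k, z))),
            class = "oct_simulator")
}

#' Scan a reflectivity map into an 8-bit B-scan
#'
#' One A-line is simulated and reconstructed per lateral column of the map
#' (galvanometer sweep); multiplicative speckle and an additive detector
#' noise floor are applied to the envelope, the depth axis is cropped to
#' `depth_crop` rows, and the image is normalized and log-compressed to
#' 8-bit.
#'
#' @param map a [rasterize_phantom()] result or plain reflectivity matrix
#'   (depth rows x lateral columns, values in \[0, 1\]).
#' @param sim an [oct_simulator()]; built on the fly if `NULL`.
#' @param source,config used when `sim` is `NULL`.
#' @param speckle_scale multiplicative speckle magnitude in \[0, 1\]
#'   (0 = off): each envelope amplitude is multiplied by
#'   `(1 - s) + s * R` with `R` Rayleigh-distributed with unit mean.
#' @param noise_floor additive detector noise amplitude relative to the
#'   envelope maximum (default 2e-3).
#' @param floor_db log-compression floor, dB.
#' @param seed RNG seed for the noise draws.
#' @param chick_id,frame_index,label metadata carried on the result.
#' @return object of class `"bscan"`: `pixels` (integer matrix,
#'   `depth_crop` x `n_alines`, values 0–255), metadata fields, and
#'   `quality_score` (mean gradient magnitude, see [quality_score()]).
#' @export
scan_bscan <- function(map, sim = NULL, source = source_spectrum(),
                       config = scan_config(), speckle_scale = NULL,
                       noise_floor = 2e-3, floor_db = -50, seed = NULL,
                       chick_id = NA_integer_, frame_index = NA_integer_,
                       label = NA_character_) {
  R <- if (inherits(map, "reflectivity_map")) map$values else map
  if (is.null(sim)) sim <- oct_simulator(source, config)
  cfg <- sim$config
  if (ncol(R) != cfg$n_alines)
    stopf("map has %d lateral columns but the scan expects %d",
          ncol(R), cfg$n_alines)
  if (nrow(R) > cfg$depth_pixels)
    stopf("map has %d depth rows but the scan reconstructs %d",
          nrow(R), cfg$depth_pixels)
  if (is.null(speckle_scale)) speckle_scale <- 0
  # spectral intensities for all A-lines at once:
  # I(k, x) = S(k) * |1 + a * sum_z r(z, x) exp(2 i k z)|^2
  a <- 0.1
  field <- 1 + a * (sim$phase[, seq_len(nrow(R)), drop = FALSE] %*% R)
  I <- sim$S * Mod(field)^2
  env <- Mod(mvfft(I - sim$S))
  env <- env[seq(2L, cfg$depth_crop + 1L), , drop = FALSE]

  if (speckle_scale > 0 || noise_floor > 0) {
    env <- with_seed(seed, {
      e <- env
      if (speckle_scale > 0) {
        sigma <- sqrt(2 / pi)  # unit-mean Rayleigh
        ray <- sigma * sqrt(-2 * log(runif(length(e))))
        e <- e * ((1 - speckle_scale) + speckle_scale * ray)
      }
      if (noise_floor > 0) {
        ref <- max(e)
        if (ref <= 0) ref <- 1  # empty scene: detector noise still present
        e <- e + ref * noise_floor * abs(rnorm(length(e)))
      }
      e
    })
  }
  pix <- log_compress_u8(normalize_bscan(env), floor_db = floor_db)
  structure(list(pixels = pix, chick_id = chick_id,
                 frame_index = frame_index, label = label,
                 quality_score = quality_score(pix)),
            class = "bscan")
}

#' @export
print.bscan <- function(x, ...) {
  cat(sprintf("B-scan %d x %d px (8-bit), chick %s frame %s, label %s, quality %.3f\n",
              nrow(x$pixels), ncol(x$pixels), x$chick_id, x$frame_index,
              x$label, x$quality_score))
  invisible(x)
}

#' Measure the axial point-spread function by simulation
#'
#' Places a single reflector at depth `z_um`, runs the forward model and
#' reconstruction with oversampled depth sampling, and measures the
#' full width at half maximum of the envelope peak by linear interpolation.
#' For a Gaussian source this should match the coherence-length prediction
#' `(2 ln 2 / pi) * lambda0^2 / dlambda`.
#'
#' @param source a [source_spectrum()].
#' @param depth_pitch µm per depth pixel.
#' @param z_um reflector depth, µm.
#' @param oversample zero-padding factor for sub-pixel width measurement.
#' @return list: `fwhm_um` (measured), `theory_um` (closed form),
#'   `peak_um` (measured peak position).
#' @export
axial_resolution <- function(source = source_spectrum(), depth_pitch = 4,
                             z_um = 1200, oversample = 16L) {
  n_depth <- as.integer(2.5 * z_um / depth_pitch)
  prof <- numeric(n_depth)
  prof[round(z_um / depth_pitch)] <- 1
  ig <- simulate_interferogram(prof, source, depth_pitch)
  env <- reconstruct_aline(ig, depth_pixels = n_depth, oversample = oversample)
  dz <- depth_pitch / oversample
  i_pk <- which.max(env)
  half <- env[i_pk] / 2
  # walk out from the peak and interpolate the half-maximum crossings
  lo <- i_pk; while (lo > 1L && env[lo] > half) lo <- lo - 1L
  hi <- i_pk; while (hi < length(env) && env[hi] > half) hi <- hi + 1L
  xl <- lo + (half - env[lo]) / (env[lo + 1L] - env[lo])
  xr <- hi - 1 + (env[hi - 1L] - half) / (env[hi - 1L] - env[hi])
  lam <- source$center_wavelength / 1000
  dl <- source$fwhm_bandwidth / 1000
  list(fwhm_um = (xr - xl) * dz,
       theory_um = 2 * log(2) / pi * lam^2 / dl,
       peak_um = i_pk * dz)
}
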