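#' Acquisition configuration
#'
#' Describes the ultrasound acquisition geometry and band used both by the
#' RF simulator and by the spectral estimators.  Defaults correspond to a
#' linear-array research scanner: 7 MHz centre frequency, -6 dB band of
#' 4--9 MHz, 40 MHz sampling, frames collected at 1 cm intervals.
#'
#' @param sampling_rate RF sampling rate in Hz.
#' @param center_frequency Transducer centre frequency in Hz.
#' @param band_low,band_high Edges of the usable (-6 dB) band in Hz.
#' @param sound_speed Assumed speed of sound in m/s.
#' @param line_pitch Lateral spacing between scan lines in m (default: a
#'   60 mm aperture with 256 elements).
#' @param frame_count Number of frames in a scan stack.
#' @param frame_spacing Elevational spacing between frames in m.
#' @param n_samples Axial samples per scan line (simulator frame size).
#' @param n_lines Scan lines per frame (simulator frame size).
#'
#' @return An object of class `acq_config`.
#' @export
#' @examples
#' cfg <- acq_config()
#' window_side(cfg) * 1e3  # analysis block side in mm (10 wavelengths)
acq_config <- function(sampling_rate = 40e6,
                       center_frequency = 7e6,
                       band_low = 4e6,
                       band_high = 9e6,
                       sound_speed = 1540,
                       line_pitch = 60e-3 / 256,
                       frame_count = 1L,
                       frame_spacing = 0.01,
                       n_samples = 1024L,
                       n_lines = 48L) {
  stopifnot_scalar(sampling_rate, "sampling_rate")
  stopifnot_scalar(center_frequency, "center_frequency")
  stopifnot_scalar(sound_speed, "sound_speed")
  stopifnot_scalar(line_pitch, "line_pitch")
  if (!(band_low < center_frequency && center_frequency < band_high))
    stop("band_low < center_frequency < band_high is required", call. = FALSE)
  if (sampling_rate <= 2 * band_high)
    stop("sampling_rate must exceed twice band_high (Nyquist)", call. = FALSE)
  structure(list(
    sampling_rate = sampling_rate,
    center_frequency = center_frequency,
    band_low = band_low,
    band_high = band_high,
    sound_speed = sound_speed,
    line_pitch = line_pitch,
    frame_count = as.integer(frame_count),
    frame_spacing = frame_spacing,
    n_samples = as.integer(n_samples),
    n_lines = as.integer(n_lines)
  ), class = "acq_config")
}

#' @export
print.acq_config <- function(x, ...) {
  cat("Acquisition config:\n")
  cat(sprintf("  fc %.1f MHz, band %.1f-%.1f MHz, fs %.0f MHz, c %.0f m/s\n",
              x$center_frequency / 1e6, x$band_low / 1e6, x$band_high / 1e6,
              x$sampling_rate / 1e6, x$sound_speed))
  cat(sprintf("  frame %d samples x %d lines, line pitch %.3f mm\n",
              x$n_samples, x$n_lines, x$line_pitch * 1e3))
  invisible(x)
}

#' Axial sample pitch in metres
#'
#' Round-trip convention: one RF sample spans `c / (2 fs)` of depth.
#' @param config An [acq_config()].
#' @return Axial pitch in m.
#' @export
axial_pitch <- function(config) config$sound_speed / (2 * config$sampling_rate)

#' Analysis window side (10 wavelengths) in metres
#' @param config An [acq_config()].
#' @return Window side in m.
#' @export
window_side <- function(config) 10 * config$sound_speed / config$center_frequency

#' Scatterer phantom specification
#'
#' Ground-truth tissue-mimicking parameters for the RF simulator.  The
#' effective scatterer diameter shapes the per-scatterer spectral response
#' through the same form factor used by the backscatter fit; acoustic
#' concentration scales echo power; `mean_spacing` adds a quasi-regular
#' scatterer lattice producing spectral ripple (the SAS signature);
#' attenuation applies frequency-linear depth-dependent loss.
#'
#' Scatterer density must be high enough for fully developed speckle: with
#' the default pulse (~0.23 mm axial resolution) and 0.234 mm line pitch,
#' about 150 scatterers/mm^2 gives >= 8 per resolution cell; the default is
#' 200/mm^2.
#'
#' @param scatterer_diameter Effective scatterer diameter in m (0 disables
#'   form-factor shaping, i.e. sub-resolution Rayleigh scatterers).
#' @param acoustic_concentration Acoustic concentration in dB relative to
#'   the reference phantom convention (reference = 0 dB).
#' @param mean_spacing Mean regular scatterer spacing in m, or `NA` for a
#'   purely diffuse medium.
#' @param spacing_jitter Fractional jitter (sd / spacing) of the lattice.
#' @param lattice_strength Ratio of coherent lattice echo amplitude to the
#'   diffuse RMS level.
#' @param attenuation Attenuation coefficient in dB/cm/MHz.
#' @param density Scatterer number density per mm^2.
#' @param rng_seed Integer seed making the scatterer field reproducible.
#'
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(scatterer_diameter = 110e-6,
                         acoustic_concentration = 25,
                         mean_spacing = NA_real_,
                         spacing_jitter = 0.02,
                         lattice_strength = 3,
                         attenuation = 0.5,
                         density = 200,
                         rng_seed = 1L) {
  if (scatterer_diameter < 0) stop("scatterer_diameter must be >= 0", call. = FALSE)
  if (attenuation < 0) stop("attenuation must be >= 0", call. = FALSE)
  stopifnot_scalar(density, "density")
  if (!is.na(mean_spacing)) stopifnot_scalar(mean_spacing, "mean_spacing")
  structure(list(
    scatterer_diameter = scatterer_diameter,
    acoustic_concentration = acoustic_concentration,
    mean_spacing = mean_spacing,
    spacing_jitter = spacing_jitter,
    lattice_strength = lattice_strength,
    attenuation = attenuation,
    density = density,
    rng_seed = as.integer(rng_seed)
  ), class = "phantom_spec")
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("Phantom spec:\n")
  cat(sprintf("  ASD %.0f um, AAC %.1f dB, ACE %.2f dB/cm/MHz, density %.0f /mm^2\n",
              x$scatterer_diameter * 1e6, x$acoustic_concentration,
              x$attenuation, x$density))
  if (!is.na(x$mean_spacing))
    cat(sprintf("  lattice spacing %.2f mm (jitter %.0f%%)\n",
                x$mean_spacing * 1e3, 100 * x$spacing_jitter))
  invisible(x)
}

#' Texture extraction configuration
#'
#' Controls GLCM quantisation and the locality scheme for texture maps.
#'
#' @param n_levels Number of grey levels for quantisation.
#' @param distance Pixel offset distance for co-occurrence pairs.
#' @param angles Offsets in degrees; counts are pooled over angles.
#' @param symmetric Whether to symmetrise the co-occurrence counts.
#' @param kernel Side (in map cells) of the sliding kernel used for local
#'   texture maps.
#' @param step Kernel step in cells.
#' @param tex1_mode `"global"` computes first-order texture scalars from the
#'   whole-map GLCM; `"local_mean"` averages the local texture map instead.
#' @return An object of class `texture_config`.
#' @export
texture_config <- function(n_levels = 16L, distance = 1L,
                           angles = c(0, 45, 90, 135), symmetric = TRUE,
                           kernel = 5L, step = 1L,
                           tex1_mode = c("global", "local_mean")) {
  tex1_mode <- match.arg(tex1_mode)
  structure(list(n_levels = as.integer(n_levels), distance = as.integer(distance),
                 angles = angles, symmetric = isTRUE(symmetric),
                 kernel = as.integer(kernel), step = as.integer(step),
                 tex1_mode = tex1_mode),
            class = "texture_config")
}

#' Classifier configuration
#'
#' @param classifier `"knn"` or `"svm"` (radial-basis-function SVM).
#' @param k Neighbourhood size for k-NN (odd; ties in the vote are
#'   impossible for two classes).
#' @param cost SVM cost parameter.
#' @param gamma SVM RBF kernel width; `NULL` uses 1 / n_features on
#'   z-scored features.
#' @param n_subsets Number of class-balanced training subsets in the
#'   majority-voting ensemble.
#' @param max_features Forward-selection cap.
#' @return An object of class `classifier_config`.
#' @export
classifier_config <- function(classifier = c("knn", "svm"), k = 3L, cost = 1,
                              gamma = NULL, n_subsets = 7L, max_features = 3L) {
  classifier <- match.arg(classifier)
  structure(list(classifier = classifier, k = as.integer(k), cost = cost,
                 gamma = gamma, n_subsets = as.integer(n_subsets),
                 max_features = as.integer(max_features)),
            class = "classifier_config")
}
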