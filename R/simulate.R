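## RF speckle-phantom simulator.
##
## Frames are synthesised in the frequency domain: each scan line is a sum of
## point-scatterer echoes with round-trip delay t = 2z/c, shaped by a
## Gaussian-modulated pulse spectrum, a Rayleigh f^2 amplitude factor, the
## scatterer form factor at the phantom's effective diameter, an acoustic
## concentration gain, and per-scatterer frequency-linear attenuation.  The
## attenuation convention is shared with the spectral estimators:
## power-spectrum loss in dB at depth z is 2 * alpha * f_MHz * (2 z_cm).

pulse_spectrum <- function(freq, config) {
  ## Gaussian amplitude envelope whose -6 dB *power* points sit at the band
  ## edges (half-width (band_high - band_low)/2 around the centre frequency).
  half <- (config$band_high - config$band_low) / 2
  sigma <- half / sqrt(0.6 * log(10))
  exp(-(freq - config$center_frequency)^2 / (2 * sigma^2))
}

#' Backscatter form factors
#'
#' `form_factor_gaussian()` is the closed-form Gaussian form factor
#' `exp(-0.827 k^2 (d/2)^2)` with `k = 2 pi f / c`.
#' `form_factor_anderson()` is the fluid-sphere (Anderson) backscatter form
#' factor, computed from the partial-wave series in spherical Bessel
#' functions and normalised to 1 at zero frequency; the series is truncated
#' at `n_terms` partial waves.
#'
#' @param freq Frequencies in Hz.
#' @param diameter Effective scatterer diameter in m.
#' @param sound_speed Speed of sound in the surrounding medium, m/s.
#' @param g,h Density and sound-speed ratios (sphere / medium) for the
#'   fluid-sphere model.
#' @param n_terms Partial-wave truncation order.
#' @return Numeric vector of form-factor values in (0, 1].
#' @export
form_factor_gaussian <- function(freq, diameter, sound_speed = 1540) {
  if (diameter <= 0) return(rep(1, length(freq)))
  k <- 2 * pi * freq / sound_speed
  exp(-0.827 * k^2 * (diameter / 2)^2)
}

sph_bessel_j <- function(n, x) sqrt(pi / (2 * x)) * besselJ(x, n + 0.5)
sph_bessel_y <- function(n, x) sqrt(pi / (2 * x)) * besselY(x, n + 0.5)

#' @rdname form_factor_gaussian
#' @export
form_factor_anderson <- function(freq, diameter, sound_speed = 1540,
                                 g = 1.1, h = 1.05, n_terms = 30) {
  if (diameter <= 0) return(rep(1, length(freq)))
  a <- diameter / 2
  x <- pmax(2 * pi * freq / sound_speed * a, 1e-8)   # ka in the medium
  x1 <- x / h                                        # k'a inside the sphere
  amp <- complex(real = rep(0, length(x)))
  for (n in 0:n_terms) {
    jn_x <- sph_bessel_j(n, x);  yn_x <- sph_bessel_y(n, x)
    jn_x1 <- sph_bessel_j(n, x1)
    ## derivative recurrences: f_n'(x) = f_{n-1}(x) - (n+1)/x f_n(x)
    djn_x <- (if (n == 0) -sph_bessel_j(1, x) else
                sph_bessel_j(n - 1, x) - (n + 1) / x * jn_x)
    dyn_x <- (if (n == 0) -sph_bessel_y(1, x) else
                sph_bessel_y(n - 1, x) - (n + 1) / x * yn_x)
    djn_x1 <- (if (n == 0) -sph_bessel_j(1, x1) else
                 sph_bessel_j(n - 1, x1) - (n + 1) / x1 * jn_x1)
    cn <- (djn_x1 * yn_x / (jn_x1 * djn_x) - g * h * dyn_x / djn_x) /
          (djn_x1 * jn_x / (jn_x1 * djn_x) - g * h)
    amp <- amp + (-1)^n * (2 * n + 1) / (1 + 1i * cn)
  }
  ## |f_inf|^2 up to shared constants; normalise to the Rayleigh (f -> 0)
  ## limit so FF -> 1 at low frequency, matching the Gaussian convention.
  ff <- Mod(amp / x)^2
  x_ref <- 1e-3
  amp0 <- 0i
  for (n in 0:n_terms) {
    jn_x <- sph_bessel_j(n, x_ref); yn_x <- sph_bessel_y(n, x_ref)
    jn_x1 <- sph_bessel_j(n, x_ref / h)
    djn_x <- (if (n == 0) -sph_bessel_j(1, x_ref) else
                sph_bessel_j(n - 1, x_ref) - (n + 1) / x_ref * jn_x)
    dyn_x <- (if (n == 0) -sph_bessel_y(1, x_ref) else
                sph_bessel_y(n - 1, x_ref) - (n + 1) / x_ref * yn_x)
    djn_x1 <- (if (n == 0) -sph_bessel_j(1, x_ref / h) else
                 sph_bessel_j(n - 1, x_ref / h) - (n + 1) / (x_ref / h) * jn_x1)
    cn <- (djn_x1 * yn_x / (jn_x1 * djn_x) - g * h * dyn_x / djn_x) /
          (djn_x1 * jn_x / (jn_x1 * djn_x) - g * h)
    amp0 <- amp0 + (-1)^n * (2 * n + 1) / (1 + 1i * cn)
  }
  ## Rayleigh limit scales as x^2 (amplitude), i.e. |f|^2/x^2 ~ C * x^4 / x^2;
  ## normalise FF(x) by C * x^4 where C = |amp0/x_ref|^2 / x_ref^4.
  c0 <- Mod(amp0 / x_ref)^2 / x_ref^4
  pmin(ff / (c0 * x^4), 1)
}

form_factor <- function(freq, diameter, sound_speed,
                        kind = c("gaussian", "anderson"), ...) {
  kind <- match.arg(kind)
  switch(kind,
         gaussian = form_factor_gaussian(freq, diameter, sound_speed),
         anderson = form_factor_anderson(freq, diameter, sound_speed, ...))
}

#' Simulate one RF frame from a scatterer phantom
#'
#' Synthesises a 2-D RF frame (axial sample x scan line) from a random
#' point-scatterer field described by a [phantom_spec()].  The realisation
#' is deterministic given `phantom$rng_seed` and `frame_index`.
#'
#' @param phantom A [phantom_spec()].
#' @param config An [acq_config()].
#' @param frame_index Frame number within the stack (varies the scatterer
#'   realisation while keeping the same phantom).
#' @param form_factor_kind Form factor shaping the per-scatterer spectrum.
#' @return An object of class `rf_frame` with elements `samples`
#'   (matrix, axial x lateral), `config`, `frame_index` and `truth`.
#' @export
#' @examples
#' cfg <- acq_config(n_samples = 256L, n_lines = 8L)
#' fr <- simulate_rf_frame(phantom_spec(rng_seed = 7L), cfg)
#' dim(fr$samples)
simulate_rf_frame <- function(phantom, config, frame_index = 1L,
                              form_factor_kind = "gaussian") {
  stopifnot(inherits(phantom, "phantom_spec"), inherits(config, "acq_config"))
  ns <- config$n_samples; nl <- config$n_lines
  depth <- ns * axial_pitch(config)            # m
  width <- nl * config$line_pitch              # m
  if (depth < window_side(config))
    stop("frame axial extent is shorter than one analysis window", call. = FALSE)

  old <- .Random.seed_exists()
  set.seed(derive_seed(phantom$rng_seed, frame_index))
  on.exit(.Random.seed_restore(old), add = TRUE)

  area_mm2 <- depth * 1e3 * width * 1e3
  n_scat <- max(1L, round(phantom$density * area_mm2))
  z <- runif(n_scat, 0, depth)
  x <- runif(n_scat, 0, width)
  amp <- rnorm(n_scat)
  line_of <- pmin(nl, floor(x / config$line_pitch) + 1L)
  n_line_exp <- phantom$density * (depth * 1e3) * (config$line_pitch * 1e3)

  ## optional quasi-regular lattice (coherent across lines) for SAS ripple
  lat_z <- numeric(0); lat_amp <- numeric(0)
  if (!is.na(phantom$mean_spacing)) {
    s <- phantom$mean_spacing
    lat_z <- seq(s / 2, depth, by = s)
    lat_z <- lat_z + rnorm(length(lat_z), 0, phantom$spacing_jitter * s)
    lat_z <- lat_z[lat_z > 0 & lat_z < depth]
    lat_amp <- rep(phantom$lattice_strength * sqrt(n_line_exp / length(lat_z)),
                   length(lat_z))
  }

  ## positive-frequency synthesis grid (pulse envelope negligible above 16 MHz)
  fs <- config$sampling_rate
  f_max <- min(16e6, fs / 2 * 0.98)
  j_max <- floor(f_max / (fs / ns))
  f <- (1:j_max) * fs / ns
  env <- pulse_spectrum(f, config) * (f / 1e6)^2 *
    sqrt(form_factor(f, phantom$scatterer_diameter, config$sound_speed,
                     form_factor_kind)) *
    10^(phantom$acoustic_concentration / 20)

  ## power loss 2*alpha*f*(2z) dB  =>  amplitude factor 10^(-alpha f z / 5)
  att_coef <- -log(10) / 5 * phantom$attenuation    # per (MHz * cm), amplitude
  samples <- matrix(0, ns, nl)
  f_mhz <- f / 1e6
  for (l in seq_len(nl)) {
    sel <- line_of == l
    zz <- c(z[sel], lat_z)
    aa <- c(amp[sel], lat_amp)
    if (!length(zz)) next
    tt <- 2 * zz / config$sound_speed
    arg <- outer(-2i * pi * f, tt) + outer(att_coef * f_mhz, zz * 100)
    spec_pos <- env * as.vector(exp(arg) %*% aa) / sqrt(n_line_exp)
    full <- complex(length.out = ns)
    full[2:(j_max + 1)] <- spec_pos
    full[ns:(ns - j_max + 1)] <- Conj(spec_pos)
    samples[, l] <- Re(stats::fft(full, inverse = TRUE)) / ns
  }
  structure(list(samples = samples, config = config,
                 frame_index = as.integer(frame_index), truth = phantom),
            class = "rf_frame")
}

.Random.seed_exists <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("RF frame %d: %d samples x %d lines (%.1f x %.1f mm)\n",
              x$frame_index, nrow(x$samples), ncol(x$samples),
              nrow(x$samples) * axial_pitch(x$config) * 1e3,
              ncol(x$samples) * x$config$line_pitch * 1e3))
  invisible(x)
}

#' Simulate reference-phantom frames
#'
#' A homogeneous phantom of sub-resolution (Rayleigh) scatterers with zero
#' attenuation and acoustic concentration fixed at 0 dB; the averaged
#' power spectrum of these frames is the normalisation reference for all
#' sample spectra.
#'
#' @param config An [acq_config()].
#' @param n_frames Number of independent frames to average over.
#' @param seed Integer seed.
#' @param density Scatterer density per mm^2.
#' @return List of `rf_frame` objects.
#' @export
simulate_reference_frames <- function(config, n_frames = 10L, seed = 1L,
                                      density = 200) {
  if (n_frames < 1) stop("n_frames must be >= 1", call. = FALSE)
  ref_spec <- phantom_spec(scatterer_diameter = 0, acoustic_concentration = 0,
                           attenuation = 0, density = density,
                           rng_seed = derive_seed(seed, 911L))
  lapply(seq_len(n_frames), function(i)
    simulate_rf_frame(ref_spec, config, frame_index = i))
}

default_cohort_effect <- function() {
  ## Week-0 -> week-4 ground-truth parameter shifts per outcome group.
  ## Responding (non-recurring) tumours show the larger backscatter change:
  ## cell death raises acoustic concentration and shrinks effective
  ## scatterer size; recurring tumours change little.
  list(
    recurrence = c(AAC = 1, ASD = -3e-6, ACE = 0),
    nonrecurrence = c(AAC = 6, ASD = -20e-6, ACE = 0)
  )
}

#' Simulate a two-time-point RF cohort with outcomes
#'
#' Each synthetic patient has RF scans (one frame + rectangular tumour ROI)
#' at week 0 and week 4, ground-truth phantom parameters per time point,
#' and a censored time-to-recurrence outcome.  Week-0 parameters are drawn
#' from shared distributions; week-4 parameters are shifted by group-specific
#' effects plus patient-level noise.  Recurrence times follow an exponential
#' hazard with median 24 months; non-recurring patients have a much flatter
#' hazard; administrative censoring is uniform on 48--118 months of
#' follow-up (a minimum four-year follow-up for non-events).
#'
#' @param n_recurrence,n_nonrecurrence Group sizes.
#' @param effect List with elements `recurrence` and `nonrecurrence`, each a
#'   named vector of week-4 shifts for `AAC` (dB), `ASD` (m), `ACE`
#'   (dB/cm/MHz); see `default_cohort_effect` for the defaults.
#' @param seed Integer seed (drives phantom draws, RF speckle and outcomes).
#' @param config An [acq_config()].
#' @param roi_frac Fractional axial/lateral extents of the tumour ROI
#'   within the frame, as `c(ax0, ax1, lat0, lat1)`.
#' @return List of patients, each a list with `patient_id`, `label`
#'   (factor recurrence/nonrecurrence), `scans` (`week0`, `week4`: each
#'   `frame` + `roi` mask), `truth`, and `outcome` (`time` months, `event`).
#' @export
simulate_cohort <- function(n_recurrence, n_nonrecurrence,
                            effect = default_cohort_effect(), seed = 1L,
                            config = acq_config(),
                            roi_frac = c(0.28, 0.72, 0.2, 0.8)) {
  if (n_recurrence < 1 || n_nonrecurrence < 1)
    stop("both groups need at least one patient", call. = FALSE)
  hazards <- c(recurrence = log(2) / 24, nonrecurrence = log(2) / 300)
  if (any(hazards <= 0)) stop("hazards must be positive", call. = FALSE)

  old <- .Random.seed_exists()
  set.seed(derive_seed(seed, 17L))
  on.exit(.Random.seed_restore(old), add = TRUE)

  labels <- c(rep("recurrence", n_recurrence),
              rep("nonrecurrence", n_nonrecurrence))
  n <- length(labels)
  roi <- matrix(FALSE, config$n_samples, config$n_lines)
  roi[max(1, round(roi_frac[1] * config$n_samples)):round(roi_frac[2] * config$n_samples),
      max(1, round(roi_frac[3] * config$n_lines)):round(roi_frac[4] * config$n_lines)] <- TRUE

  patients <- vector("list", n)
  for (i in seq_len(n)) {
    grp <- labels[i]
    w0 <- list(
      AAC = rnorm(1, 25, 4),
      ASD = max(40e-6, rnorm(1, 110e-6, 10e-6)),
      ACE = max(0.05, rnorm(1, 0.5, 0.08))
    )
    eff <- effect[[grp]]
    w4 <- list(
      AAC = w0$AAC + eff[["AAC"]] + rnorm(1, 0, 1),
      ASD = max(40e-6, w0$ASD + eff[["ASD"]] + rnorm(1, 0, 4e-6)),
      ACE = max(0.05, w0$ACE + eff[["ACE"]] + rnorm(1, 0, 0.03))
    )
    ph0 <- phantom_spec(scatterer_diameter = w0$ASD,
                        acoustic_concentration = w0$AAC,
                        attenuation = w0$ACE,
                        rng_seed = derive_seed(seed, 100L + 2L * i))
    ph4 <- phantom_spec(scatterer_diameter = w4$ASD,
                        acoustic_concentration = w4$AAC,
                        attenuation = w4$ACE,
                        rng_seed = derive_seed(seed, 101L + 2L * i))
    t_event <- stats::rexp(1, hazards[[grp]])
    t_censor <- stats::runif(1, 48, 118)
    patients[[i]] <- list(
      patient_id = sprintf("P%03d", i),
      label = factor(grp, levels = c("nonrecurrence", "recurrence")),
      scans = list(
        week0 = list(frame = simulate_rf_frame(ph0, config), roi = roi),
        week4 = list(frame = simulate_rf_frame(ph4, config), roi = roi)
      ),
      truth = list(week0 = ph0, week4 = ph4),
      outcome = data.frame(patient_id = sprintf("P%03d", i),
                           time = min(t_event, t_censor),
                           event = t_event <= t_censor)
    )
  }
  patients
}

#' Simulate a cohort at the feature level
#'
#' Generates per-patient 190-feature model rows (95 week-0 features plus 95
#' week-4 minus week-0 differences) directly, with independent standard
#' normal features and a group mean shift injected into named features.
#' This isolates the classifier protocol from the RF stages: effects can be
#' placed in any feature tier (mean QUS, first-order texture, or texture
#' derivative) with known effect size in SD units.  Censored
#' time-to-recurrence outcomes use the same hazard model as
#' [simulate_cohort()].
#'
#' @param n_recurrence,n_nonrecurrence Group sizes.
#' @param effect Named numeric vector: mean shift (in SD units) added to
#'   the recurrence group for each named model feature (names as in
#'   [qus_feature_names()] with `_W0` / `d` conventions).
#' @param seed Integer seed.
#' @return A data.frame with `patient_id`, `label`, `time`, `event`, and
#'   one column per model feature.
#' @export
#' @examples
#' rows <- simulate_feature_cohort(8, 12, effect = c("dASD-CON-CON" = 2), seed = 1)
#' dim(rows)
simulate_feature_cohort <- function(n_recurrence = 28L, n_nonrecurrence = 55L,
                                    effect = numeric(0), seed = 1L) {
  feats <- qus_feature_names("model")
  if (length(effect) && !all(names(effect) %in% feats))
    stop("unknown feature name(s) in 'effect': ",
         paste(setdiff(names(effect), feats), collapse = ", "), call. = FALSE)
  old <- .Random.seed_exists()
  set.seed(derive_seed(seed, 23L))
  on.exit(.Random.seed_restore(old), add = TRUE)

  n <- n_recurrence + n_nonrecurrence
  labels <- factor(c(rep("recurrence", n_recurrence),
                     rep("nonrecurrence", n_nonrecurrence)),
                   levels = c("nonrecurrence", "recurrence"))
  X <- matrix(rnorm(n * length(feats)), n, length(feats),
              dimnames = list(NULL, feats))
  if (length(effect))
    X[labels == "recurrence", names(effect)] <-
      sweep(X[labels == "recurrence", names(effect), drop = FALSE], 2,
            effect, `+`)
  hz <- ifelse(labels == "recurrence", log(2) / 24, log(2) / 300)
  t_event <- stats::rexp(n, hz)
  t_censor <- stats::runif(n, 48, 118)
  out <- data.frame(patient_id = sprintf("P%03d", seq_len(n)),
                    label = labels,
                    time = pmin(t_event, t_censor),
                    event = t_event <= t_censor,
                    check.names = FALSE)
  cbind(out, as.data.frame(X, check.names = FALSE))
}
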