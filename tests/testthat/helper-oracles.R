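## Independent oracles and shared fixtures for the test suite.

## Brute-force GLCM feature oracle: enumerate every ordered pixel pair at the
## given offsets, accumulate the joint histogram directly, and compute the
## four Haralick features from first principles.
oracle_glcm_features <- function(int_map, n_levels, distance = 1L,
                                 angles = c(0, 45, 90, 135),
                                 symmetric = TRUE) {
  offs <- list("0" = c(0, 1), "45" = c(-1, 1), "90" = c(-1, 0),
               "135" = c(-1, -1))
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(int_map); nc <- ncol(int_map)
  for (a in as.character(angles)) {
    dr <- offs[[a]][1] * distance; dc <- offs[[a]][2] * distance
    for (r in seq_len(nr)) for (cc in seq_len(nc)) {
      r2 <- r + dr; c2 <- cc + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      v1 <- int_map[r, cc]; v2 <- int_map[r2, c2]
      if (is.na(v1) || is.na(v2)) next
      counts[v1 + 1, v2 + 1] <- counts[v1 + 1, v2 + 1] + 1
      if (symmetric) counts[v2 + 1, v1 + 1] <- counts[v2 + 1, v1 + 1] + 1
    }
  }
  p <- counts / sum(counts)
  con <- 0; ene <- 0; hom <- 0; mu_i <- 0; mu_j <- 0
  for (i in 0:(n_levels - 1)) for (j in 0:(n_levels - 1)) {
    con <- con + (i - j)^2 * p[i + 1, j + 1]
    ene <- ene + p[i + 1, j + 1]^2
    hom <- hom + p[i + 1, j + 1] / (1 + abs(i - j))
    mu_i <- mu_i + i * p[i + 1, j + 1]
    mu_j <- mu_j + j * p[i + 1, j + 1]
  }
  v_i <- 0; v_j <- 0; cov <- 0
  for (i in 0:(n_levels - 1)) for (j in 0:(n_levels - 1)) {
    v_i <- v_i + (i - mu_i)^2 * p[i + 1, j + 1]
    v_j <- v_j + (j - mu_j)^2 * p[i + 1, j + 1]
    cov <- cov + (i - mu_i) * (j - mu_j) * p[i + 1, j + 1]
  }
  cor <- if (v_i > 0 && v_j > 0) cov / sqrt(v_i * v_j) else 0
  c(CON = con, COR = cor, ENE = ene, HOM = hom)
}

## Hand product-limit estimator (events before censorings at tied times).
oracle_km <- function(time, event) {
  ord <- order(time, !event)
  time <- time[ord]; event <- event[ord]
  n <- length(time)
  s <- 1
  surv <- numeric(n)
  at_risk <- n
  i <- 1
  while (i <= n) {
    t0 <- time[i]
    d <- sum(time == t0 & event)
    c0 <- sum(time == t0 & !event)
    if (d > 0) s <- s * (1 - d / at_risk)
    idx <- which(time == t0)
    surv[idx] <- s
    at_risk <- at_risk - d - c0
    i <- max(idx) + 1
  }
  list(time = time, event = event, surv = surv)
}

## All-pairs AUC oracle (ties count one half).
oracle_auc <- function(scores, is_pos) {
  sp <- scores[is_pos]; sn <- scores[!is_pos]
  tot <- 0
  for (a in sp) for (b in sn)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(sp) * length(sn))
}

derive_seed_for_test <- function(seed, offset) qusradiomics:::derive_seed(seed, offset)

## ---- cached expensive fixtures (built once per test run) ----

.fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- build()
  .fixture_env[[name]]
}

small_cfg <- function() acq_config(n_samples = 512L, n_lines = 32L)

small_roi <- function(cfg = small_cfg()) {
  roi <- matrix(FALSE, cfg$n_samples, cfg$n_lines)
  roi[140:420, 6:27] <- TRUE
  roi
}

small_reference <- function() fixture("small_reference", function() {
  simulate_reference_frames(small_cfg(), n_frames = 6L, seed = 402L)
})

## One speckle phantom scan through the full spectral stage.
speckle_maps <- function() fixture("speckle_maps", function() {
  cfg <- small_cfg()
  ph <- phantom_spec(scatterer_diameter = 120e-6, acoustic_concentration = 30,
                     attenuation = 1.0, rng_seed = 77L)
  fr <- simulate_rf_frame(ph, cfg)
  build_parametric_maps(fr, small_roi(cfg), small_reference(), cfg)
})

## A flat synthetic spectrum pair for normalisation identities.
flat_ps <- function(level = 1, cfg = acq_config(), nfft = 2048L) {
  freq <- (0:(nfft / 2)) * cfg$sampling_rate / nfft
  list(freq = freq, power = rep(level, length(freq)))
}
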