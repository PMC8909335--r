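## Grey-level co-occurrence texture features (contrast, correlation, energy,
## homogeneity) over parametric maps, sliding-kernel texture maps, and
## texture derivatives ("texture of texture").

#' Quantise a parametric map to integer grey levels
#'
#' Linear min--max binning of the finite cells into `n_levels` levels
#' (0-based, `0 .. n_levels - 1`).  A constant map collapses to a single
#' level; absent (`NA`) cells stay absent.  Monotone linear rescaling of the
#' map leaves the quantised image unchanged.
#'
#' @param map Numeric matrix (or `parametric_map`).
#' @param n_levels Number of grey levels.
#' @return Integer matrix of the same shape with values in
#'   `0 .. n_levels - 1` and `NA` for absent cells.
#' @export
quantize_map <- function(map, n_levels = 16L) {
  g <- if (inherits(map, "parametric_map")) map$grid else map
  fin <- is.finite(g)
  if (!any(fin)) stop("map has no finite cells", call. = FALSE)
  lo <- min(g[fin]); hi <- max(g[fin])
  out <- matrix(NA_integer_, nrow(g), ncol(g))
  if (hi == lo) {
    out[fin] <- 0L
  } else {
    out[fin] <- pmin(n_levels - 1L,
                     as.integer(floor((g[fin] - lo) / (hi - lo) * n_levels)))
  }
  out
}

glcm_offsets <- function(angles, distance) {
  ## (row, col) offsets; 0 deg = along a map row to the right, angles rotate
  ## counter-clockwise as in the usual GLCM convention
  lapply(angles, function(a) {
    switch(as.character(a),
           "0"   = c(0L, 1L),
           "45"  = c(-1L, 1L),
           "90"  = c(-1L, 0L),
           "135" = c(-1L, -1L),
           stop("supported angles are 0, 45, 90, 135 degrees", call. = FALSE)
    ) * distance
  })
}

#' Grey-level co-occurrence matrix
#'
#' Co-occurrences are counted over pairs of cells where both members are
#' present (absent cells never pair), pooled over the requested angle
#' offsets, optionally symmetrised, and normalised to joint probabilities.
#'
#' @param int_map Integer matrix from [quantize_map()] (`NA` = absent).
#' @param n_levels Number of grey levels spanned by the matrix.
#' @param distance Offset distance in cells.
#' @param angles Offset angles in degrees (0, 45, 90, 135).
#' @param symmetric Count each pair in both orders.
#' @return A `glcmatrix`: `p` (`n_levels` x `n_levels` probabilities),
#'   `n_pairs`, `symmetric`.
#' @export
compute_glcm <- function(int_map, n_levels = max(int_map, na.rm = TRUE) + 1L,
                         distance = 1L, angles = c(0, 45, 90, 135),
                         symmetric = TRUE) {
  counts <- matrix(0, n_levels, n_levels)
  nr <- nrow(int_map); nc <- ncol(int_map)
  for (off in glcm_offsets(angles, distance)) {
    dr <- off[1]; dc <- off[2]
    r0 <- max(1L, 1L - dr):min(nr, nr - dr)
    c0 <- max(1L, 1L - dc):min(nc, nc - dc)
    if (!length(r0) || !length(c0)) next
    a <- int_map[r0, c0, drop = FALSE]
    b <- int_map[r0 + dr, c0 + dc, drop = FALSE]
    ok <- !is.na(a) & !is.na(b)
    if (!any(ok)) next
    code <- a[ok] * n_levels + b[ok] + 1L
    counts <- counts + matrix(tabulate(code, nbins = n_levels^2),
                              n_levels, n_levels, byrow = TRUE)
  }
  if (sum(counts) == 0) stop("no valid co-occurrence pairs", call. = FALSE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), n_pairs = sum(counts),
                 symmetric = symmetric),
            class = "glcmatrix")
}

#' Haralick features of a co-occurrence matrix
#'
#' Contrast `sum (i-j)^2 p`, energy `sum p^2`, homogeneity
#' `sum p / (1 + |i-j|)`, and correlation
#' `sum (i - mu_i)(j - mu_j) p / (sigma_i sigma_j)`.  Correlation of a
#' zero-variance matrix (e.g. from a constant map) is undefined (0/0) and
#' returns the 0 sentinel.
#'
#' @param G A `glcmatrix`.
#' @return Named vector `c(CON, COR, ENE, HOM)`.
#' @export
glcm_features <- function(G) {
  p <- G$p
  n <- nrow(p)
  i <- matrix(0:(n - 1L), n, n)
  j <- t(i)
  con <- sum((i - j)^2 * p)
  ene <- sum(p^2)
  hom <- sum(p / (1 + abs(i - j)))
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  s_i <- sqrt(sum((i - mu_i)^2 * p)); s_j <- sqrt(sum((j - mu_j)^2 * p))
  cor <- if (s_i * s_j > 0) sum((i - mu_i) * (j - mu_j) * p) / (s_i * s_j) else 0
  c(CON = con, COR = cor, ENE = ene, HOM = hom)
}

#' Whole-map texture scalars
#'
#' Quantise, form the GLCM, and extract the four Haralick features once for
#' the whole map (the first-order texture values).  With
#' `tex1_mode = "local_mean"` in the config, the scalars are instead the
#' means of the local texture maps.
#'
#' @param map Numeric matrix or `parametric_map`.
#' @param config A [texture_config()].
#' @return Named vector `c(CON, COR, ENE, HOM)`.
#' @export
texture_scalar <- function(map, config = texture_config()) {
  if (config$tex1_mode == "local_mean") {
    tm <- texture_map(map, config)
    return(vapply(tm, function(m) mean(m[is.finite(m)]), numeric(1)))
  }
  q <- quantize_map(map, config$n_levels)
  glcm_features(compute_glcm(q, n_levels = config$n_levels,
                             distance = config$distance, angles = config$angles,
                             symmetric = config$symmetric))
}

#' Local texture maps over a sliding kernel
#'
#' Quantises the map once (global min--max levels) and computes the four
#' GLCM features in a sliding `kernel x kernel` cell neighbourhood, giving
#' one texture map per feature.  Kernels with no valid co-occurrence pair
#' yield absent cells.
#'
#' @param map Numeric matrix or `parametric_map`.
#' @param config A [texture_config()] (fields `kernel`, `step`).
#' @return Named list of four matrices (`CON`, `COR`, `ENE`, `HOM`).
#' @export
texture_map <- function(map, config = texture_config()) {
  g <- if (inherits(map, "parametric_map")) map$grid else map
  k <- config$kernel
  if (nrow(g) < k || ncol(g) < k)
    stop(sprintf("map (%d x %d) smaller than the %d-cell kernel",
                 nrow(g), ncol(g), k), call. = FALSE)
  q <- quantize_map(g, config$n_levels)
  r0 <- seq(1L, nrow(g) - k + 1L, by = config$step)
  c0 <- seq(1L, ncol(g) - k + 1L, by = config$step)
  out <- lapply(c("CON", "COR", "ENE", "HOM"), function(p)
    matrix(NA_real_, length(r0), length(c0)))
  names(out) <- c("CON", "COR", "ENE", "HOM")
  for (ri in seq_along(r0)) for (ci in seq_along(c0)) {
    patch <- q[r0[ri]:(r0[ri] + k - 1L), c0[ci]:(c0[ci] + k - 1L), drop = FALSE]
    feats <- tryCatch(
      glcm_features(compute_glcm(patch, n_levels = config$n_levels,
                                 distance = config$distance,
                                 angles = config$angles,
                                 symmetric = config$symmetric)),
      error = function(e) NULL)
    if (!is.null(feats))
      for (p in names(out)) out[[p]][ri, ci] <- feats[[p]]
  }
  out
}

## Parents whose texture maps feed texture derivatives (SAS and SS excluded).
tex2_parents <- c("MBF", "SI", "ASD", "AAC")
tex1_parents <- c("MBF", "SS", "SI", "SAS", "ASD", "AAC")
glcm_feature_names <- c("CON", "COR", "ENE", "HOM")

#' Texture maps eligible for derivatives
#'
#' The 16 texture maps: four GLCM feature maps for each of the four
#' derivative-eligible parents (MBF, SI, ASD, AAC; SAS- and SS-derived
#' texture maps are excluded).
#'
#' @param maps Named list of the six parametric maps (from
#'   [build_parametric_maps()]`$maps`).
#' @param config A [texture_config()].
#' @return Named list of 16 matrices, names like `"ASD-CON"`.
#' @export
texture_maps <- function(maps, config = texture_config()) {
  out <- list()
  for (parent in tex2_parents) {
    tm <- texture_map(maps[[parent]], config)
    names(tm) <- paste0(parent, "-", names(tm))
    out <- c(out, tm)
  }
  out
}

#' Texture derivatives (texture of texture)
#'
#' Applies the whole-map texture scalars to each of the 16 texture maps,
#' giving 64 named values such as `"ASD-CON-CON"`.
#'
#' @param tmaps Named list of 16 texture maps from [texture_maps()].
#' @param config A [texture_config()].
#' @return Named numeric vector of 64 texture derivatives.
#' @export
texture_derivatives <- function(tmaps, config = texture_config()) {
  if (length(tmaps) != 16L)
    stop("expected the 16 derivative-eligible texture maps", call. = FALSE)
  out <- numeric(0)
  for (nm in names(tmaps)) {
    feats <- texture_scalar(tmaps[[nm]], config)
    names(feats) <- paste0(nm, "-", glcm_feature_names)
    out <- c(out, feats)
  }
  out
}

#' Canonical feature names
#'
#' @param which `"qus"` (7 mean spectral parameters), `"tex1"` (24
#'   first-order texture features), `"tex2"` (64 texture derivatives),
#'   `"timepoint"` (all 95), or `"model"` (190: the 95 week-0 features
#'   suffixed `_W0` plus the 95 week-4-minus-week-0 differences prefixed
#'   `d`).
#' @return Character vector of feature names.
#' @export
qus_feature_names <- function(which = c("timepoint", "qus", "tex1", "tex2",
                                        "model")) {
  which <- match.arg(which)
  qus <- c("MBF", "SS", "SI", "SAS", "ASD", "AAC", "ACE")
  tex1 <- as.vector(t(outer(tex1_parents, glcm_feature_names, paste, sep = "-")))
  tex2 <- as.vector(t(outer(
    as.vector(t(outer(tex2_parents, glcm_feature_names, paste, sep = "-"))),
    glcm_feature_names, paste, sep = "-")))
  tp <- c(qus, tex1, tex2)
  switch(which,
         qus = qus, tex1 = tex1, tex2 = tex2, timepoint = tp,
         model = c(paste0(tp, "_W0"), paste0("d", tp)))
}

#' Extract the 95-feature vector for one scan
#'
#' Runs the texture stage on a scan's parametric maps: 7 mean QUS
#' parameters, 24 first-order texture features from the six maps, and 64
#' texture derivatives from the 16 derivative-eligible texture maps.
#'
#' @param qmaps A `qus_maps` object from [build_parametric_maps()].
#' @param config A [texture_config()].
#' @return Named numeric vector of length 95.
#' @export
scan_feature_vector <- function(qmaps, config = texture_config()) {
  stopifnot(inherits(qmaps, "qus_maps"))
  qus <- qmaps$means[qus_feature_names("qus")]
  tex1 <- numeric(0)
  for (parent in tex1_parents) {
    feats <- texture_scalar(qmaps$maps[[parent]], config)
    names(feats) <- paste0(parent, "-", glcm_feature_names)
    tex1 <- c(tex1, feats)
  }
  tex2 <- texture_derivatives(texture_maps(qmaps$maps, config), config)
  out <- c(qus, tex1, tex2)
  stopifnot(identical(names(out), qus_feature_names("timepoint")))
  out
}

#' Assemble the two-time-point model row
#'
#' Combines the week-0 and week-4 95-feature vectors into the 190-feature
#' model row: week-0 values (suffix `_W0`) and the week-4 minus week-0
#' differences (prefix `d`).
#'
#' @param week0,week4 Named 95-feature vectors from [scan_feature_vector()].
#' @return Named numeric vector of length 190.
#' @export
assemble_features <- function(week0, week4) {
  tp <- qus_feature_names("timepoint")
  miss0 <- setdiff(tp, names(week0)); miss4 <- setdiff(tp, names(week4))
  if (length(miss0) || length(miss4))
    stop("missing feature entries: ",
         paste(unique(c(miss0, miss4)), collapse = ", "), call. = FALSE)
  week0 <- week0[tp]; week4 <- week4[tp]
  out <- c(week0, week4 - week0)
  names(out) <- qus_feature_names("model")
  out
}
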