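test_that("quantisation is linear min-max with absent-cell propagation", {
  expect_identical(unique(as.vector(quantize_map(matrix(3.7, 4, 4), 16))), 0L)
  two <- matrix(c(1, 5, 1, 5), 2, 2)
  expect_setequal(as.vector(quantize_map(two, 8)), c(0L, 7L))
  m <- matrix(c(NA, 1, 2, 3), 2, 2)
  q <- quantize_map(m, 4)
  expect_true(is.na(q[1, 1]) && !anyNA(q[-1]))
  expect_error(quantize_map(matrix(NA_real_, 2, 2)), "finite")

  ## brute-force bin-edge oracle on random 5x5 maps
  set.seed(7)
  for (rep in 1:10) {
    m <- matrix(runif(25, -3, 9), 5, 5)
    ng <- sample(4:16, 1)
    q <- quantize_map(m, ng)
    edges <- seq(min(m), max(m), length.out = ng + 1)
    oracle <- matrix(pmin(findInterval(m, edges, rightmost.closed = TRUE) - 1L,
                          ng - 1L), 5, 5)
    expect_identical(q, oracle)
  }
})

test_that("GLCM counts, normalisation and symmetry are correct", {
  ## constant map: single entry
  g <- compute_glcm(matrix(0L, 4, 4), n_levels = 4)
  expect_equal(g$p[1, 1], 1)
  expect_equal(sum(g$p), 1, tolerance = 1e-12)

  ## 4x4 checkerboard, horizontal offset, symmetric: p(0,1) = p(1,0) = 0.5
  cb <- matrix(rep(c(0L, 1L), 8), 4, 4)
  cb <- abs(outer(1:4, 1:4, `+`) %% 2L)
  gc <- compute_glcm(cb, n_levels = 2, angles = 0, symmetric = TRUE)
  expect_equal(gc$p[1, 2], 0.5)
  expect_equal(gc$p[2, 1], 0.5)
  expect_equal(gc$p[1, 1] + gc$p[2, 2], 0)

  ## row sums equal the first-pixel marginal distribution
  set.seed(3)
  m <- matrix(sample(0:3, 36, replace = TRUE), 6, 6)
  g1 <- compute_glcm(m, n_levels = 4, angles = 0, symmetric = FALSE)
  first <- as.vector(m[, 1:5])
  marg <- tabulate(first + 1L, 4) / length(first)
  expect_equal(rowSums(g1$p), marg, tolerance = 1e-12)

  ## absent cells never pair
  m2 <- matrix(c(0L, NA, 1L, NA), 2, 2)
  expect_error(compute_glcm(matrix(NA_integer_, 2, 2), n_levels = 2), "pairs")

  expect_equal(sum(compute_glcm(m2, n_levels = 2)$p), 1)
})

test_that("Haralick features match the pair-enumeration oracle", {
  ## closed-form checkerboard values
  cb <- abs(outer(1:4, 1:4, `+`) %% 2L)
  f <- glcm_features(compute_glcm(cb, n_levels = 2, angles = 0))
  expect_equal(unname(f), c(1, -1, 0.5, 0.5))

  ## constant map: CON 0, ENE 1, HOM 1, COR sentinel 0
  fc <- glcm_features(compute_glcm(matrix(2L, 4, 4), n_levels = 4))
  expect_equal(unname(fc), c(0, 0, 1, 1))

  set.seed(11)
  for (rep in 1:25) {
    n <- sample(3:6, 1); ng <- sample(2:6, 1)
    m <- matrix(sample(0:(ng - 1L), n * n, replace = TRUE), n, n)
    got <- glcm_features(compute_glcm(m, n_levels = ng))
    want <- oracle_glcm_features(m, n_levels = ng)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("texture scalars are invariant to monotone linear rescaling", {
  set.seed(5)
  m <- matrix(rnorm(100), 10, 10)
  f1 <- texture_scalar(m)
  f2 <- texture_scalar(3 * m + 7)
  expect_equal(f1, f2, tolerance = 1e-12)
  ## permuting cells changes texture but not the mean
  mp <- matrix(sample(as.vector(m)), 10, 10)
  expect_equal(mean(mp), mean(m))
  expect_false(isTRUE(all.equal(texture_scalar(mp)[["CON"]], f1[["CON"]])))
})

test_that("texture maps obey locality, limits and the derivative pipeline", {
  cfgt <- texture_config()
  set.seed(8)
  m <- matrix(rnorm(144), 12, 12)
  tm <- texture_map(m, cfgt)
  expect_named(tm, c("CON", "COR", "ENE", "HOM"))
  expect_equal(dim(tm$CON), c(8, 8))
  ## kernel = whole map reproduces whole-map features
  cfg_full <- texture_config(kernel = 12L)
  tm_full <- texture_map(m, cfg_full)
  whole <- texture_scalar(m, cfgt)
  for (p in names(tm_full)) expect_equal(tm_full[[p]][1, 1], whole[[p]])
  ## constant parent: ENE texture map is identically 1
  tc <- texture_map(matrix(4, 8, 8), cfgt)
  expect_true(all(tc$ENE == 1))
  expect_true(all(tc$CON == 0))
  expect_error(texture_map(matrix(1, 3, 3), cfgt), "smaller")

  ## derivatives: 16 maps in, 64 named values out, matching recomposition
  maps <- lapply(setNames(nm = c("MBF", "SS", "SI", "SAS", "ASD", "AAC")),
                 function(p) matrix(rnorm(144), 12, 12))
  tmaps <- texture_maps(maps, cfgt)
  expect_length(tmaps, 16L)
  expect_true(all(grepl("^(MBF|SI|ASD|AAC)-(CON|COR|ENE|HOM)$", names(tmaps))))
  der <- texture_derivatives(tmaps, cfgt)
  expect_length(der, 64L)
  expect_equal(der[["ASD-CON-CON"]],
               texture_scalar(tmaps[["ASD-CON"]], cfgt)[["CON"]])
  expect_error(texture_derivatives(tmaps[1:5], cfgt), "16")
})

test_that("feature bookkeeping: 7 + 24 + 64 = 95 per time point, 190 per row", {
  expect_length(qus_feature_names("qus"), 7L)
  expect_length(qus_feature_names("tex1"), 24L)
  expect_length(qus_feature_names("tex2"), 64L)
  expect_length(qus_feature_names("timepoint"), 95L)
  expect_length(qus_feature_names("model"), 190L)
  ## ACE contributes no texture; SAS/SS contribute no derivatives
  expect_false(any(grepl("^ACE-", qus_feature_names("tex1"))))
  expect_false(any(grepl("^(SAS|SS)-", qus_feature_names("tex2"))))

  w0 <- setNames(rnorm(95), qus_feature_names("timepoint"))
  w4 <- w0 + 1
  row <- assemble_features(w0, w4)
  expect_length(row, 190L)
  expect_identical(names(row), qus_feature_names("model"))
  expect_equal(unname(row[paste0("d", qus_feature_names("timepoint"))]),
               rep(1, 95))
  ## week4 = week0 -> all differences zero
  expect_equal(unname(assemble_features(w0, w0)[96:190]), rep(0, 95))
  expect_error(assemble_features(w0[-1], w4), "missing feature")
})

test_that("a full scan yields the 95 named features from its maps", {
  qm <- speckle_maps()
  fv <- scan_feature_vector(qm)
  expect_length(fv, 95L)
  expect_identical(names(fv), qus_feature_names("timepoint"))
  expect_equal(fv[["ACE"]], qm$ace)
  expect_true(all(is.finite(fv)))
})
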