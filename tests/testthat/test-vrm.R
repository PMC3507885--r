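test_that("reference statistics are estimated correctly and guarded", {
  set.seed(7)
  vals <- array(rnorm(10000, mean = 1.0, sd = 0.5), c(25, 25, 16))
  m <- as_delta_s_map(vals)
  mask <- array(TRUE, dim(vals))
  st <- reference_stats(m, mask)
  expect_equal(st$mu, 1.0, tolerance = 0.02)
  expect_equal(st$sigma, 0.5, tolerance = 0.02)
  expect_identical(st$n_voxels, 10000L)
  # degenerate constant region: sigma = 0 is rejected
  const <- as_delta_s_map(array(2.0, c(10, 10, 10)))
  expect_error(reference_stats(const, array(TRUE, c(10, 10, 10))), "SD must be > 0")
  # too few defined voxels
  few <- as_delta_s_map(array(c(rnorm(50), rep(NA, 950)), c(10, 10, 10)))
  expect_error(reference_stats(few, array(TRUE, c(10, 10, 10))), "need >= 100")
  expect_error(reference_stats(m, array(TRUE, c(5, 5, 5))), "grid")
})

test_that("z-normalization maps mu to 0, mu + sigma to 1, and self-normalizes", {
  set.seed(8)
  vals <- array(rnorm(4000, 3, 2), c(20, 20, 10))
  vals[1:40] <- NA                       # some undefined voxels persist
  m <- as_delta_s_map(vals)
  mask <- array(FALSE, dim(vals)); mask[, , 3:8] <- TRUE
  st <- reference_stats(m, mask)
  z <- normalize_map(m, st)
  inref <- mask & !is.na(z$z)
  expect_equal(mean(z$z[inref]), 0, tolerance = 1e-12)
  expect_equal(sd(z$z[inref]), 1, tolerance = 1e-12)
  probe <- as_delta_s_map(array(c(st$mu, st$mu + st$sigma, NA, NA), c(2, 2, 1)))
  zp <- normalize_map(probe, st)
  expect_equal(zp$z[1, 1, 1], 0)
  expect_equal(zp$z[2, 1, 1], 1)
  expect_true(is.na(zp$z[1, 2, 1]))
})

test_that("VRM is antisymmetric, zero against itself, and grid-checked", {
  set.seed(9)
  a <- array(rnorm(1000), c(10, 10, 10)); a[1:30] <- NA
  b <- array(rnorm(1000), c(10, 10, 10)); b[21:50] <- NA
  st <- structure(list(mu = 0, sigma = 1, n_voxels = 1000, challenge = "x"),
                  class = "reference_stats")
  zo <- structure(list(z = a, challenge = "hyperoxia", stats = st), class = "z_map")
  zc <- structure(list(z = b, challenge = "hypercapnia", stats = st), class = "z_map")
  v <- compute_vrm(zo, zc)
  zc_swap <- structure(list(z = a, challenge = "hypercapnia", stats = st), class = "z_map")
  zo_swap <- structure(list(z = b, challenge = "hyperoxia", stats = st), class = "z_map")
  v_swap <- compute_vrm(zo_swap, zc_swap)
  expect_identical(v$vrm, -v_swap$vrm)               # bit-exact antisymmetry
  self <- compute_vrm(zo, structure(list(z = a, challenge = "hypercapnia", stats = st),
                                    class = "z_map"))
  expect_true(all(self$vrm[self$defined] == 0))
  expect_identical(v$defined, !is.na(a) & !is.na(b))
  small <- structure(list(z = a[1:5, 1:5, 1:5], challenge = "hypercapnia", stats = st),
                     class = "z_map")
  expect_error(compute_vrm(zo, small), "grids differ")
})

test_that("missing CO2 responses can be floored at the reference minimum", {
  a <- array(1.5, c(4, 4, 2))
  b <- array(seq(-2, 1, length.out = 32), c(4, 4, 2))
  b[1, 1, 1] <- NA                       # O2-defined, CO2-silent voxel
  st <- structure(list(mu = 0, sigma = 1, n_voxels = 32, challenge = "x"),
                  class = "reference_stats")
  zo <- structure(list(z = a, challenge = "hyperoxia", stats = st), class = "z_map")
  zc <- structure(list(z = b, challenge = "hypercapnia", stats = st), class = "z_map")
  v <- compute_vrm(zo, zc, co2_missing = "reference_min")
  expect_equal(v$vrm[1, 1, 1], 1.5 - min(b, na.rm = TRUE))
  expect_true(all(v$defined))
  expect_identical(v$provenance$co2_missing, "reference_min")
})

test_that("abnormality threshold is tissue mean + 2 SD with strict inequality", {
  ref <- cohort_reference_table(c("WM", "GM"), "VRM", c(0.22, 0.50),
                                c(0.10, 0.15), 19)
  at_thr <- as_vrm_map(array(0.42, c(5, 5, 2)))
  mask <- abnormality_mask(at_thr, ref, "WM")
  expect_equal(attr(mask, "threshold"), 0.42)        # 0.22 + 2 x 0.10
  expect_false(any(mask))                            # boundary is excluded
  above <- as_vrm_map(array(0.42 + 1e-9, c(5, 5, 2)))
  expect_true(all(abnormality_mask(above, ref, "WM")))
  expect_equal(attr(abnormality_mask(above, ref, "GM"), "threshold"), 0.80)
  expect_error(abnormality_mask(above, ref[ref$tissue == "WM", ], "GM"), "no .*entry")
})

test_that("tumor mean VRM rises monotonically with the immature fraction", {
  lab <- phantom_labels(c(20, 20, 12), tumor = TRUE, tumor_radius = 4.5)
  tumor <- lab == hri_labels()[["tumor"]]
  ref <- (lab == hri_labels()[["GM"]] | lab == hri_labels()[["WM"]]) & !tumor
  dim(ref) <- dim(lab)
  amps <- list(hyperoxia = c(GM = 2.54, WM = 0.71, tumor = 2.54),
               hypercapnia = c(GM = 1.33, WM = 0.40, tumor = 1.33))
  mean_vrm <- vapply(c(0, 0.3, 0.7, 1), function(frac) {
    cfg <- phantom_config(lab, amps, tumor_immature_fraction = frac,
                          immature_o2_amplitude = 3, noise_sd = 0.2, seed = 31L)
    runs <- lapply(both_paradigms(), function(p) generate_run(cfg, p)$run)
    a <- analyze_subject(runs, ref, co2_missing = "reference_min")
    mean(a$vrm$vrm[tumor], na.rm = TRUE)
  }, 0)
  expect_true(all(diff(mean_vrm) > 0))
  # immature voxels sit far above mature tissue on the VRM scale
  cfg <- phantom_config(lab, amps, tumor_immature_fraction = 0.5,
                        immature_o2_amplitude = 3, noise_sd = 0.2, seed = 32L)
  runs <- lapply(both_paradigms(), function(p) generate_run(cfg, p)$run)
  a <- analyze_subject(runs, ref, co2_missing = "reference_min")
  expect_gt(mean(a$vrm$vrm[cfg$immature_mask], na.rm = TRUE),
            mean(a$vrm$vrm[ref], na.rm = TRUE) + 1)
})

test_that("contralateral reference excludes the lesion hemisphere", {
  lab <- phantom_labels(c(20, 20, 12), tumor = TRUE, tumor_radius = 4)
  tumor <- lab == hri_labels()[["tumor"]]
  tissue <- lab == hri_labels()[["GM"]] | lab == hri_labels()[["WM"]]
  dim(tissue) <- dim(lab)
  ref <- contralateral_reference_mask(tissue, tumor, lr_axis = 1L)
  xs <- slice.index(lab, 1)
  expect_true(all(xs[ref] > 10.5))       # tumor sits on the low-x side
  expect_false(any(ref & tumor))
  excl <- lab == hri_labels()[["CSF"]]; dim(excl) <- dim(lab)
  ref2 <- contralateral_reference_mask(tissue, tumor, 1L, exclusion = excl)
  expect_false(any(ref2 & excl))
})
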