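test_that("tissue probability thresholding is strict, disjoint and exclusion-aware", {
  d <- c(6, 6, 2)
  gm <- array(0, d); wm <- array(0, d)
  gm[1, 1, 1] <- 0.8                     # exactly at threshold: excluded
  gm[2, 1, 1] <- 0.81
  wm[3, 1, 1] <- 0.95
  gm[4, 1, 1] <- 0.9; wm[4, 1, 1] <- 0.95   # overlap: WM larger
  gm[5, 1, 1] <- 0.9; wm[5, 1, 1] <- 0.9    # tie: GM wins
  gm[6, 1, 1] <- 0.99
  masks <- tissue_masks(gm, wm)
  expect_false(masks$GM[1, 1, 1])
  expect_true(masks$GM[2, 1, 1])
  expect_true(masks$WM[4, 1, 1] && !masks$GM[4, 1, 1])
  expect_true(masks$GM[5, 1, 1] && !masks$WM[5, 1, 1])
  expect_false(any(masks$GM & masks$WM))
  excl <- array(FALSE, d); excl[6, 1, 1] <- TRUE
  expect_false(tissue_masks(gm, wm, exclusion = excl)$GM[6, 1, 1])
  expect_error(tissue_masks(gm * 2, wm), "\\[0, 1\\]")
  # 0/1 probabilities from phantom labels reproduce the labels exactly
  lab <- phantom_labels(c(12, 12, 6))
  gm_p <- array(as.numeric(lab == hri_labels()[["GM"]]), dim(lab))
  wm_p <- array(as.numeric(lab == hri_labels()[["WM"]]), dim(lab))
  m2 <- tissue_masks(gm_p, wm_p)
  expect_identical(m2$GM, lab == hri_labels()[["GM"]])
  expect_identical(m2$WM, lab == hri_labels()[["WM"]])
})

test_that("left-right flip is an involution that mirrors coordinates", {
  lab <- phantom_labels(c(21, 16, 10), tumor = TRUE, tumor_radius = 3.5)
  tumor <- lab == hri_labels()[["tumor"]]
  flipped <- flip_voi(tumor, 1L)
  expect_identical(flip_voi(flipped, 1L), tumor)
  expect_identical(sum(flipped), sum(tumor))
  # centroid mirrors across the mid-sagittal plane: x -> (n + 1) - x
  cx <- mean(slice.index(tumor, 1)[tumor])
  cx_f <- mean(slice.index(flipped, 1)[flipped])
  expect_equal(cx_f, 22 - cx, tolerance = 1e-12)
  # a midline-symmetric mask is a fixed point
  sym <- array(FALSE, c(21, 16, 10)); sym[8:14, 5:8, 3:6] <- TRUE
  expect_identical(flip_voi(sym, 1L), sym)
  expect_error(flip_voi(tumor, NA), "lr_axis")
  expect_error(flip_voi(array(TRUE, c(2, 2)), 1L), "3D")
})

test_that("reactivity index counts the whole VOI in its denominator", {
  v <- array(NA_real_, c(6, 6, 1))
  v[1:12] <- 5                            # 12 of 36 defined, all above
  vrm <- as_vrm_map(v)
  voi <- array(TRUE, c(6, 6, 1))
  ref <- cohort_reference_table("WM", "VRM", 0.22, 0.10, 19)
  idx <- reactivity_index(vrm, voi, ref, "WM")
  expect_equal(as.numeric(idx), 100 * 12 / 36)
  all_above <- as_vrm_map(array(5, c(6, 6, 1)))
  expect_equal(as.numeric(reactivity_index(all_above, voi, ref, "WM")), 100)
  none <- as_vrm_map(array(NA_real_, c(6, 6, 1)))
  expect_equal(as.numeric(reactivity_index(none, voi, ref, "WM")), 0)
  expect_error(reactivity_index(vrm, array(FALSE, c(6, 6, 1)), ref, "WM"), "empty")
})

test_that("an O2-responsive, CO2-silent tumor dominates its contralateral VOI", {
  lab <- phantom_labels(c(24, 24, 12), tumor = TRUE, tumor_radius = 4.5)
  tumor <- lab == hri_labels()[["tumor"]]
  amps <- list(hyperoxia = c(GM = 2.54, WM = 0.71, tumor = 2.54),
               hypercapnia = c(GM = 1.33, WM = 0.40, tumor = 1.33))
  cfg <- phantom_config(lab, amps, tumor_immature_fraction = 0.5,
                        immature_o2_amplitude = 3, noise_sd = 0.2, seed = 13L)
  runs <- lapply(both_paradigms(), function(p) generate_run(cfg, p)$run)
  tissue <- lab == hri_labels()[["GM"]] | lab == hri_labels()[["WM"]]
  dim(tissue) <- dim(lab)
  ref_mask <- contralateral_reference_mask(tissue, tumor, 1L)
  a <- analyze_subject(runs, ref_mask, co2_missing = "reference_min")
  cref <- cohort_reference_table("WM", "VRM", 0.0, 0.15, 19)
  rep <- voi_report(list(o2 = a$o2, co2 = a$co2, vrm = a$vrm), tumor, cref, "WM")
  expect_identical(rep$voi, c("lesion", "CLS"))
  lesion <- rep[rep$voi == "lesion", ]; cls <- rep[rep$voi == "CLS", ]
  expect_gt(lesion$mean_ds_o2, lesion$mean_ds_co2)
  expect_gt(lesion$reactivity_index, cls$reactivity_index + 30)
  expect_identical(lesion$threshold_tissue, "WM")
  expect_equal(lesion$n_voxels, sum(tumor))
  # a midline-crossing lesion cannot have a contralateral VOI
  wide <- array(FALSE, dim(lab)); wide[8:17, 10:14, 5:8] <- TRUE
  expect_warning(rep2 <- voi_report(list(o2 = a$o2, co2 = a$co2, vrm = a$vrm),
                                    wide, cref, "WM"),
                 "crosses brain midline")
  expect_identical(rep2$voi, "lesion")
})

test_that("cohort aggregation averages per-subject ratios, not ratio of means", {
  d <- c(10, 10, 4)
  mk_subject <- function(gm_o2, wm_o2) {
    gm <- array(FALSE, d); gm[1:5, , ] <- TRUE
    wm <- array(FALSE, d); wm[6:10, , ] <- TRUE
    o2 <- array(NA_real_, d); o2[gm] <- gm_o2; o2[wm] <- wm_o2
    co2 <- array(NA_real_, d); co2[gm] <- gm_o2 / 2; co2[wm] <- wm_o2 / 2
    list(o2 = as_delta_s_map(o2, "hyperoxia"),
         co2 = as_delta_s_map(co2, "hypercapnia"), gm = gm, wm = wm)
  }
  subjects <- list(mk_subject(2, 1), mk_subject(4, 1))
  ref <- aggregate_reference(subjects)
  ratio <- ref[ref$tissue == "GM/WM" & ref$quantity == "dS_O2", ]
  expect_equal(ratio$mean, mean(c(2 / 1, 4 / 1)))          # 3, not 3 from 3/1
  gm_row <- ref[ref$tissue == "GM" & ref$quantity == "dS_O2", ]
  expect_equal(gm_row$mean, 3)
  expect_equal(gm_row$sd, sd(c(2, 4)))
  expect_identical(gm_row$n_subjects, 2L)
  # heterogeneous cohort where mean-of-ratios != ratio-of-means
  het <- list(mk_subject(2, 0.5), mk_subject(3, 1.5))
  rh <- aggregate_reference(het)
  mor <- rh[rh$tissue == "GM/WM" & rh$quantity == "dS_O2", "mean"]
  rom <- rh[rh$tissue == "GM" & rh$quantity == "dS_O2", "mean"] /
    rh[rh$tissue == "WM" & rh$quantity == "dS_O2", "mean"]
  expect_equal(mor, 3)
  expect_false(isTRUE(all.equal(mor, rom)))
  # identical subjects collapse to SD 0; single subjects are rejected
  same <- list(mk_subject(2, 1), mk_subject(2, 1))
  rs <- aggregate_reference(same)
  expect_true(all(rs$sd == 0))
  expect_error(aggregate_reference(list(mk_subject(2, 1))), ">= 2 subjects")
})

test_that("simulated cohorts show GM > WM for every subject", {
  cfg <- small_config(noise_sd = 0.2, lag = 1L,
                      amplitudes = t2_means, dim = c(16, 16, 8))
  cohort <- generate_cohort(cfg, 5, list(hyperoxia = c(GM = 0.2, WM = 0.1),
                                         hypercapnia = c(GM = 0.1, WM = 0.05)),
                            seed = 12L)
  gm <- label_mask(cfg, "GM"); wm <- label_mask(cfg, "WM")
  per_subject <- vapply(cohort, function(s) {
    m <- compute_delta_s(s$runs$hyperoxia, default_paradigm("hyperoxia"))
    mean(m$delta_s[gm], na.rm = TRUE) - mean(m$delta_s[wm], na.rm = TRUE)
  }, 0)
  expect_true(all(per_subject > 0))      # paired GM-vs-WM sign test passes
})
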