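#' Tissue masks from probability maps
#'
#' Thresholds gray- and white-matter probability maps at a strict `> threshold`
#' (default 0.8) and removes an optional exclusion mask (e.g. an MNI ventricle
#' mask). Voxels exceeding the threshold in both maps are assigned to the
#' tissue with the larger probability; exact ties go to GM. The resulting
#' masks are therefore disjoint by construction.
#'
#' @param gm_prob,wm_prob Numeric 3D arrays of probabilities in \[0, 1\].
#' @param threshold Probability cutoff (strict `>`, default 0.8).
#' @param exclusion Optional logical array to remove from both masks.
#' @return A list with logical arrays `GM` and `WM`.
#' @export
tissue_masks <- function(gm_prob, wm_prob, threshold = 0.8, exclusion = NULL) {
  if (!identical(dim(gm_prob), dim(wm_prob)))
    stop("GM and WM probability grids differ")
  rng <- range(gm_prob, wm_prob)
  if (rng[1L] < 0 || rng[2L] > 1)
    stop("probabilities must lie in [0, 1]")
  gm <- gm_prob > threshold
  wm <- wm_prob > threshold
  both <- gm & wm
  wm_wins <- both & wm_prob > gm_prob
  gm[both & wm_wins] <- FALSE
  wm[both & !wm_wins] <- FALSE
  if (!is.null(exclusion)) {
    gm <- gm & !exclusion
    wm <- wm & !exclusion
  }
  if (!any(gm)) stop("GM mask is empty after thresholding")
  if (!any(wm)) stop("WM mask is empty after thresholding")
  list(GM = gm, WM = wm)
}

#' Left-right flip of a VOI mask
#'
#' Mirrors a volume of interest across the mid-sagittal plane of the grid.
#' This is how the contralateral-side (CLS) VOI is obtained from a lesion
#' VOI. Flipping is an involution and conserves the voxel count.
#'
#' @param voi Logical 3D array.
#' @param lr_axis The grid axis running left-right; must be supplied (1, 2 or
#'   3; the package's phantom convention is axis 1).
#' @return The mirrored logical array.
#' @export
#' @examples
#' m <- array(FALSE, c(4, 3, 3)); m[1, 2, 2] <- TRUE
#' which(flip_voi(m, 1))  # voxel mirrored to x = 4
flip_voi <- function(voi, lr_axis = 1L) {
  if (is.null(lr_axis) || is.na(lr_axis) || !(lr_axis %in% 1:3))
    stop("'lr_axis' must identify the left-right grid axis (1, 2 or 3)")
  if (!is.array(voi) || length(dim(voi)) != 3L)
    stop("'voi' must be a 3D array")
  d <- dim(voi)
  idx <- rep(list(quote(expr = )), 3L)
  idx[[lr_axis]] <- seq.int(d[lr_axis], 1L)
  out <- do.call(`[`, c(list(voi), idx, list(drop = FALSE)))
  dim(out) <- d
  out
}

#' Does a VOI cross the brain midline?
#'
#' Returns `TRUE` when the VOI has voxels in both hemispheres (strictly on
#' both sides of the mid-sagittal plane). For such lesions a contralateral
#' VOI cannot be defined.
#'
#' @inheritParams flip_voi
#' @export
crosses_midline <- function(voi, lr_axis = 1L) {
  idx <- slice.index(voi, lr_axis)[voi]
  mid <- (dim(voi)[lr_axis] + 1) / 2
  any(idx < mid) && any(idx > mid)
}

#' Vascular reactivity index of a VOI
#'
#' The percentage of VOI voxels whose VRM strictly exceeds the
#' healthy-cohort tissue mean + 2 SD threshold. The denominator is the
#' *entire* VOI volume, including voxels where VRM is undefined, so an
#' all-undefined VOI scores 0, not `NA`.
#'
#' @param vrm A [compute_vrm()] result.
#' @param voi Logical 3D VOI mask (non-empty, same grid).
#' @param cohort_reference A [cohort_reference_table()].
#' @param tissue Reference tissue for the threshold, `"WM"` or `"GM"`.
#' @return A single number in \[0, 100\], with attribute `threshold`.
#' @export
reactivity_index <- function(vrm, voi, cohort_reference, tissue = c("WM", "GM")) {
  tissue <- match.arg(tissue)
  stopifnot(inherits(vrm, "vrm_map"))
  if (!identical(dim(voi), dim(vrm$vrm)))
    stop("VOI grid does not match the VRM grid")
  n_voi <- sum(voi)
  if (n_voi == 0L) stop("VOI is empty")
  above <- abnormality_mask(vrm, cohort_reference, tissue)
  out <- 100 * sum(above & voi) / n_voi
  attr(out, "threshold") <- attr(above, "threshold")
  out
}

voi_row <- function(name, voi, maps, cohort_reference, tissue, rcbv) {
  defined_mean <- function(arr) {
    v <- arr[voi & !is.na(arr)]
    c(n = length(v), mean = if (length(v)) mean(v) else NA_real_)
  }
  o2 <- defined_mean(maps$o2$delta_s)
  co2 <- defined_mean(maps$co2$delta_s)
  vr <- defined_mean(maps$vrm$vrm)
  idx <- reactivity_index(maps$vrm, voi, cohort_reference, tissue)
  data.frame(voi = name, n_voxels = sum(voi),
             mean_ds_o2 = o2[["mean"]], n_o2 = o2[["n"]],
             mean_ds_co2 = co2[["mean"]], n_co2 = co2[["n"]],
             mean_vrm = vr[["mean"]], n_vrm = vr[["n"]],
             reactivity_index = as.numeric(idx),
             threshold = attr(idx, "threshold"), threshold_tissue = tissue,
             mean_rcbv = if (is.null(rcbv)) NA_real_ else mean(rcbv[voi]),
             stringsAsFactors = FALSE)
}

#' Per-VOI summary report
#'
#' Summarizes the lesion VOI and its contralateral-side (CLS) mirror: mean
#' \eqn{\Delta}S for both challenges and mean VRM over defined voxels (with
#' defined-voxel counts), the vascular reactivity index with its threshold
#' provenance, and optionally the mean of an externally computed rCBV map.
#' When the lesion crosses the brain midline the CLS row is omitted with a
#' warning, since a contralateral VOI cannot be defined.
#'
#' @param maps Named list with `o2` and `co2` ([compute_delta_s()] results)
#'   and `vrm` ([compute_vrm()]).
#' @param lesion Logical lesion VOI mask.
#' @param cohort_reference A [cohort_reference_table()].
#' @param tissue Threshold reference tissue (`"WM"` for glial lesions, `"GM"`
#'   for meningioma).
#' @param lr_axis Left-right axis used to mirror the lesion.
#' @param rcbv Optional precomputed relative-CBV 3D array (same grid).
#' @return A data frame with one row per VOI.
#' @export
voi_report <- function(maps, lesion, cohort_reference, tissue = c("WM", "GM"),
                       lr_axis = 1L, rcbv = NULL) {
  tissue <- match.arg(tissue)
  stopifnot(inherits(maps$o2, "delta_s_map"), inherits(maps$co2, "delta_s_map"),
            inherits(maps$vrm, "vrm_map"))
  grids <- list(maps$o2$delta_s, maps$co2$delta_s, maps$vrm$vrm, lesion)
  if (!is.null(rcbv)) grids <- c(grids, list(rcbv))
  dims <- lapply(grids, dim)
  if (length(unique(dims)) != 1L)
    stop("all maps and masks must share one grid; got ",
         paste(vapply(dims, paste, "", collapse = "x"), collapse = " vs "))
  if (!any(lesion)) stop("lesion VOI is empty")
  rows <- voi_row("lesion", lesion, maps, cohort_reference, tissue, rcbv)
  if (crosses_midline(lesion, lr_axis)) {
    warning("Lesion crosses brain midline, thus contralateral side VOI could not be defined")
  } else {
    cls <- flip_voi(lesion, lr_axis)
    rows <- rbind(rows, voi_row("CLS", cls, maps, cohort_reference, tissue, rcbv))
  }
  rows
}

subject_tissue_means <- function(subject) {
  quantities <- list(dS_O2 = subject$o2$delta_s, dS_CO2 = subject$co2$delta_s)
  if (!is.null(subject$vrm)) quantities$VRM <- subject$vrm$vrm
  out <- list()
  for (tis in c("GM", "WM")) {
    mask <- subject[[tolower(tis)]]
    for (q in names(quantities)) {
      v <- quantities[[q]][mask & !is.na(quantities[[q]])]
      out[[paste(tis, q, sep = ".")]] <- if (length(v)) mean(v) else NA_real_
    }
  }
  out
}

#' Aggregate a healthy cohort into reference values
#'
#' For each subject, computes tissue means (GM and WM) of \eqn{\Delta}S-O2,
#' \eqn{\Delta}S-CO2 and, when available, VRM over defined voxels; then
#' summarizes each tissue/quantity across subjects as mean and unbiased SD.
#' The GM/WM ratio is computed *per subject* and then averaged (the mean of
#' ratios, not the ratio of means — the two differ on heterogeneous cohorts,
#' and reference tables report the former). Subjects with an empty tissue
#' mask or no defined voxels in a tissue are excluded with a warning.
#'
#' @param subjects A list; each element has `o2` and `co2`
#'   ([compute_delta_s()] results), optionally `vrm` ([compute_vrm()]), and
#'   logical masks `gm` and `wm`.
#' @return A [cohort_reference_table()] with rows per tissue (`GM`, `WM`,
#'   `GM/WM` for the ratio) and quantity.
#' @export
aggregate_reference <- function(subjects) {
  if (length(subjects) < 2L)
    stop("need >= 2 subjects to aggregate a cohort reference (SD undefined for n = 1)")
  per <- lapply(seq_along(subjects), function(i) {
    s <- subjects[[i]]
    if (!any(s$gm) || !any(s$wm)) {
      warning("subject ", i, " has an empty tissue mask; excluded")
      return(NULL)
    }
    m <- subject_tissue_means(s)
    if (anyNA(unlist(m))) {
      warning("subject ", i, " has a tissue with no defined voxels; excluded")
      return(NULL)
    }
    m
  })
  per <- per[!vapply(per, is.null, TRUE)]
  if (length(per) < 2L) stop("fewer than 2 usable subjects after exclusions")
  quantities <- sub("^GM\\.", "", grep("^GM\\.", names(per[[1L]]), value = TRUE))
  rows <- list()
  for (q in quantities) {
    for (tis in c("GM", "WM")) {
      v <- vapply(per, `[[`, 0, paste(tis, q, sep = "."))
      rows[[length(rows) + 1L]] <-
        cohort_reference_table(tis, q, mean(v), stats::sd(v), length(v))
    }
    if (q != "VRM") {  # WM VRM means sit near 0; the ratio is not meaningful
      ratio <- vapply(per, function(m)
        m[[paste0("GM.", q)]] / m[[paste0("WM.", q)]], 0)
      rows[[length(rows) + 1L]] <-
        cohort_reference_table("GM/WM", q, mean(ratio), stats::sd(ratio), length(ratio))
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("cohort_reference", "data.frame")
  out
}
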