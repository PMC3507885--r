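#' Reference-region statistics of a \eqn{\Delta}S map
#'
#' Computes the mean and (unbiased) standard deviation of the defined
#' (significant) \eqn{\Delta}S values inside a reference mask. In healthy
#' subjects the reference is GM + WM of both hemispheres; in patients it is
#' the hemisphere contralateral to the lesion (see
#' [contralateral_reference_mask()]). These statistics drive the z-normalization
#' of [normalize_map()].
#'
#' @param map A [compute_delta_s()] result.
#' @param reference_mask Logical 3D array selecting reference voxels.
#' @param min_voxels Minimum number of defined reference voxels required
#'   (default 100).
#' @return An object of class `reference_stats`: `mu`, `sigma`, `n_voxels`,
#'   `challenge`.
#' @export
reference_stats <- function(map, reference_mask, min_voxels = 100L) {
  stopifnot(inherits(map, "delta_s_map"))
  if (!identical(dim(reference_mask), dim(map$delta_s)))
    stop("reference mask grid ", paste(dim(reference_mask), collapse = "x"),
         " does not match map grid ", paste(dim(map$delta_s), collapse = "x"))
  vals <- map$delta_s[reference_mask & !is.na(map$delta_s)]
  if (length(vals) < min_voxels)
    stop("only ", length(vals), " defined reference voxels; need >= ", min_voxels)
  sigma <- stats::sd(vals)
  if (!is.finite(sigma) || sigma <= 0)
    stop("reference SD must be > 0 (got ", sigma, "); the reference region is degenerate")
  structure(list(mu = mean(vals), sigma = sigma,
                 n_voxels = length(vals), challenge = map$challenge),
            class = "reference_stats")
}

#' @export
print.reference_stats <- function(x, ...) {
  cat(sprintf("<reference_stats> %s: mu = %.4f, sigma = %.4f (n = %d voxels)\n",
              x$challenge, x$mu, x$sigma, x$n_voxels))
  invisible(x)
}

#' Z-normalize a \eqn{\Delta}S map
#'
#' Applies `z(x) = (dS(x) - mu) / sigma` to every defined voxel of the map,
#' including voxels outside the reference mask, so that maps from different
#' subjects and challenges become comparable. By construction the reference
#' voxels of the resulting map have mean 0 and SD 1.
#'
#' @param map A [compute_delta_s()] result.
#' @param stats A [reference_stats()] object (`sigma > 0`).
#' @return An object of class `z_map`: `z` (3D array, `NA` where the input is
#'   undefined), `challenge`, and the `stats` applied.
#' @export
normalize_map <- function(map, stats) {
  stopifnot(inherits(map, "delta_s_map"), inherits(stats, "reference_stats"))
  if (stats$sigma <= 0) stop("'stats$sigma' must be > 0")
  structure(list(z = (map$delta_s - stats$mu) / stats$sigma,
                 challenge = map$challenge, stats = stats),
            class = "z_map")
}

#' Vascular reactivity mismatch (VRM) map
#'
#' Subtracts the normalized hypercapnia map from the normalized hyperoxia map:
#' `VRM(x) = z_O2(x) - z_CO2(x)`. High VRM marks voxels that respond to an
#' oxygenation challenge but not (or less) to a vasodilatory one — the
#' signature of immature vessels lacking smooth-muscle coverage.
#'
#' By default VRM is defined only where both z-maps are defined. The
#' archetypal immature-vessel voxel, however, responds to hyperoxia and is
#' *silent* under hypercapnia, so its z_CO2 is undefined in a
#' significance-masked map; `co2_missing = "reference_min"` handles this by
#' substituting the minimum z_CO2 observed in the reference region for
#' O2-defined/CO2-undefined voxels (a conservative floor for an absent
#' response). This mode is required for the reactivity index of masked tumor
#' maps and is recorded in the map's provenance.
#'
#' @param z_o2 [normalize_map()] result of the hyperoxia challenge.
#' @param z_co2 [normalize_map()] result of the hypercapnia challenge.
#' @param co2_missing `"undefined"` (default) or `"reference_min"`.
#' @param reference_mask Logical array over which the substitution floor is
#'   computed (defaults to all defined z_CO2 voxels).
#' @return An object of class `vrm_map`: `vrm` (3D array), `defined` (logical),
#'   and `provenance` (the two normalizations and the missing-CO2 policy).
#' @export
compute_vrm <- function(z_o2, z_co2,
                        co2_missing = c("undefined", "reference_min"),
                        reference_mask = NULL) {
  co2_missing <- match.arg(co2_missing)
  stopifnot(inherits(z_o2, "z_map"), inherits(z_co2, "z_map"))
  if (!identical(dim(z_o2$z), dim(z_co2$z)))
    stop("z-map grids differ: ", paste(dim(z_o2$z), collapse = "x"), " vs ",
         paste(dim(z_co2$z), collapse = "x"))
  if (z_o2$challenge == z_co2$challenge)
    warning("both z-maps come from the same challenge ('", z_o2$challenge, "')")
  vrm <- z_o2$z - z_co2$z
  if (co2_missing == "reference_min") {
    fill_at <- !is.na(z_o2$z) & is.na(z_co2$z)
    pool <- if (is.null(reference_mask)) z_co2$z else z_co2$z[reference_mask]
    floor_z <- suppressWarnings(min(pool, na.rm = TRUE))
    if (!is.finite(floor_z))
      stop("no defined z_CO2 voxels to compute the reference minimum from")
    vrm[fill_at] <- z_o2$z[fill_at] - floor_z
  }
  structure(list(vrm = vrm, defined = !is.na(vrm),
                 provenance = list(o2 = z_o2$stats, co2 = z_co2$stats,
                                   co2_missing = co2_missing)),
            class = "vrm_map")
}

#' Cohort reference table constructor
#'
#' Builds the healthy-cohort reference table used for abnormality thresholds
#' and reports: one row per tissue and quantity with across-subject mean, SD
#' and subject count. Usually produced by [aggregate_reference()]; this
#' constructor also lets published reference values be supplied directly.
#'
#' @param tissue,quantity,mean,sd,n_subjects Vectors of equal length; quantity
#'   is one of `"dS_O2"`, `"dS_CO2"`, `"VRM"`.
#' @return A data frame of class `cohort_reference`.
#' @export
#' @examples
#' cohort_reference_table(tissue = c("GM", "WM"), quantity = "VRM",
#'                        mean = c(0.50, 0.22), sd = c(0.15, 0.10),
#'                        n_subjects = 19)
cohort_reference_table <- function(tissue, quantity, mean, sd, n_subjects) {
  out <- data.frame(tissue = tissue, quantity = quantity,
                    mean = mean, sd = sd, n_subjects = n_subjects,
                    stringsAsFactors = FALSE)
  class(out) <- c("cohort_reference", "data.frame")
  out
}

reference_row <- function(cohort_reference, tissue, quantity) {
  stopifnot(inherits(cohort_reference, "data.frame"))
  row <- cohort_reference[cohort_reference$tissue == tissue &
                            cohort_reference$quantity == quantity, , drop = FALSE]
  if (nrow(row) != 1L)
    stop("cohort reference has no (unique) entry for tissue '", tissue,
         "', quantity '", quantity, "'")
  row
}

#' Abnormality threshold and mask of a VRM map
#'
#' A voxel is abnormal when its VRM strictly exceeds the healthy-cohort tissue
#' mean plus two SD. The white-matter reference is used for lesions of glial
#' origin; gray matter for meningioma, which has no glial reference tissue.
#'
#' @param vrm A [compute_vrm()] result.
#' @param cohort_reference A [cohort_reference_table()] with a `VRM` row for
#'   the requested tissue.
#' @param tissue `"WM"` (default) or `"GM"`.
#' @return A logical 3D array with attribute `threshold` (the mean + 2 SD
#'   value applied) and `tissue`.
#' @export
#' @examples
#' ref <- cohort_reference_table("WM", "VRM", 0.22, 0.10, 19)
#' # threshold applied is 0.22 + 2 * 0.10 = 0.42
abnormality_mask <- function(vrm, cohort_reference, tissue = c("WM", "GM")) {
  tissue <- match.arg(tissue)
  stopifnot(inherits(vrm, "vrm_map"))
  row <- reference_row(cohort_reference, tissue, "VRM")
  thr <- row$mean + 2 * row$sd
  mask <- !is.na(vrm$vrm) & vrm$vrm > thr
  attr(mask, "threshold") <- thr
  attr(mask, "tissue") <- tissue
  mask
}

#' Contralateral-hemisphere reference mask for patients
#'
#' In patients the normalization reference is the GM + WM of the hemisphere
#' contralateral to the lesion. The hemisphere split is the mid-sagittal plane
#' of the grid along the left-right axis; an optional exclusion mask (e.g.
#' ventricles) is removed.
#'
#' @param tissue_mask Logical array of GM + WM voxels (e.g. union of
#'   [tissue_masks()] output).
#' @param lesion Logical lesion mask; the reference is taken on the opposite
#'   side of its center of mass.
#' @param lr_axis Left-right grid axis (default 1).
#' @param exclusion Optional logical mask to remove.
#' @return A logical 3D array.
#' @export
contralateral_reference_mask <- function(tissue_mask, lesion, lr_axis = 1L,
                                         exclusion = NULL) {
  stopifnot(identical(dim(tissue_mask), dim(lesion)))
  d <- dim(tissue_mask)[lr_axis]
  idx <- slice.index(tissue_mask, lr_axis)
  mid <- (d + 1) / 2
  lesion_side <- mean(idx[lesion]) < mid     # TRUE: lesion on the low-index side
  ref <- tissue_mask & (if (lesion_side) idx > mid else idx < mid)
  if (!is.null(exclusion)) ref <- ref & !exclusion
  ref
}
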