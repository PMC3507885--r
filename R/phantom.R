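#' Tissue label codes used by the phantom
#'
#' Integer codes of the phantom label volume: background 0, gray matter (GM) 1,
#' white matter (WM) 2, cerebrospinal fluid (CSF) 3, tumor 4.
#'
#' @return A named integer vector.
#' @export
hri_labels <- function() {
  c(background = 0L, GM = 1L, WM = 2L, CSF = 3L, tumor = 4L)
}

#' Default phantom tissue layout
#'
#' Builds a simple 3D slab brain: a one-voxel background border, a central
#' CSF "ventricle" box, a cylindrical WM core around it and a GM mantle
#' filling the rest of the interior. An optional tumor sphere is carved out of
#' the left hemisphere (low indices along the first axis, the left-right axis)
#' so that a left-right flip of the tumor mask lands in healthy contralateral
#' tissue. The default 32 x 32 x 16 grid yields roughly 8,000 GM and 4,000 WM
#' voxels, and a tumor of ~1,100 voxels when enabled.
#'
#' @param dim Integer grid size (length 3).
#' @param tumor Logical; carve a lateralized tumor sphere.
#' @param tumor_center,tumor_radius Center (voxel coordinates) and radius of
#'   the tumor sphere; defaults place it in the left hemisphere.
#' @return An integer 3D array of [hri_labels()] codes.
#' @export
#' @examples
#' lab <- phantom_labels()
#' table(lab)
phantom_labels <- function(dim = c(32L, 32L, 16L), tumor = FALSE,
                           tumor_center = NULL, tumor_radius = 6.5) {
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3L, all(dim >= 6L))
  lab <- array(hri_labels()[["background"]], dim = dim)
  ix <- slice.index(lab, 1L); iy <- slice.index(lab, 2L); iz <- slice.index(lab, 3L)
  interior <- ix > 1L & ix < dim[1L] & iy > 1L & iy < dim[2L] & iz > 1L & iz < dim[3L]
  cx <- (dim[1L] + 1) / 2; cy <- (dim[2L] + 1) / 2
  r2 <- (ix - cx)^2 + (iy - cy)^2
  wm_r <- min(dim[1L], dim[2L]) * 10 / 32
  lab[interior] <- hri_labels()[["GM"]]
  lab[interior & r2 <= wm_r^2] <- hri_labels()[["WM"]]
  csf <- abs(ix - cx) <= 2 & abs(iy - cy) <= 2
  lab[interior & csf] <- hri_labels()[["CSF"]]
  if (tumor) {
    if (is.null(tumor_center))
      tumor_center <- c(ceiling(dim[1L] * 0.28), cy, (dim[3L] + 1) / 2)
    d2 <- (ix - tumor_center[1L])^2 + (iy - tumor_center[2L])^2 +
      (iz - tumor_center[3L])^2
    lab[interior & d2 <= tumor_radius^2] <- hri_labels()[["tumor"]]
  }
  lab
}

#' Phantom configuration
#'
#' Bundles everything needed to synthesize dual-challenge BOLD runs with known
#' ground truth: a tissue label volume, a table of true fractional signal
#' changes per tissue and challenge, the immature-vessel tumor fraction,
#' an optional "steal" region with negative hyperoxia response, baseline
#' intensity, noise level and drift. The subset of tumor voxels designated
#' immature (hyperoxia-responsive but hypercapnia-silent, the BOLD signature
#' of vessels lacking smooth-muscle coverage) is drawn once here, seeded, so
#' that both challenge runs of a subject share the same ground-truth masks.
#'
#' @param labels Integer label array from [phantom_labels()] (codes of
#'   [hri_labels()]).
#' @param amplitudes Named list with elements `hyperoxia` and `hypercapnia`,
#'   each a named numeric vector of true percent signal changes per tissue
#'   (must cover `GM` and `WM`; `CSF` and `tumor` default to 0; background is
#'   always 0).
#' @param tumor_immature_fraction Fraction in \[0, 1\] of tumor voxels with a
#'   hyperoxia response but zero hypercapnia response.
#' @param immature_o2_amplitude Optional hyperoxia percent signal change of
#'   the immature tumor voxels (default: the tumor amplitude). Angiogenic
#'   tissue is hypervascular, so its oxygenation response typically exceeds
#'   the mature compartment's; setting this above the tumor amplitude
#'   separates the two response classes.
#' @param steal_mask Optional logical array flagging a steal region whose
#'   hyperoxia response is negative (blood shunted away under vasodilation).
#' @param steal_o2_amplitude Percent signal change assigned to steal voxels
#'   during hyperoxia; must be negative.
#' @param baseline Baseline signal intensity (arbitrary scanner units) of all
#'   brain voxels; background stays at 0.
#' @param noise_sd Gaussian noise SD as percent of baseline (per voxel and
#'   volume, independent).
#' @param drift Linear drift slope, percent of baseline per volume.
#' @param lag_volumes Hemodynamic lag, in volumes, applied to the boxcar when
#'   synthesizing the response (default 1 volume = one TR).
#' @param adaptation Multiplicative attenuation of the response amplitude in
#'   gas blocks after the first (default 1 = no adaptation; values < 1 emulate
#'   physiological adaptation over repeated challenges).
#' @param seed Integer seed controlling the immature-voxel draw and, combined
#'   with the challenge, the run noise.
#' @return An object of class `phantom_config`.
#' @export
phantom_config <- function(labels,
                           amplitudes,
                           tumor_immature_fraction = 0,
                           immature_o2_amplitude = NULL,
                           steal_mask = NULL,
                           steal_o2_amplitude = -1,
                           baseline = 1000,
                           noise_sd = 0.2,
                           drift = 0,
                           lag_volumes = 1L,
                           adaptation = 1,
                           seed = 1L) {
  if (!is.array(labels) || length(dim(labels)) != 3L)
    stop("'labels' must be a 3D integer array")
  if (!all(labels %in% hri_labels()))
    stop("'labels' contains codes outside hri_labels()")
  for (ch in c("hyperoxia", "hypercapnia")) {
    if (is.null(amplitudes[[ch]]))
      stop("'amplitudes' must have an entry for '", ch, "'")
    missing <- setdiff(c("GM", "WM"), names(amplitudes[[ch]]))
    if (length(missing))
      stop("amplitude table for '", ch, "' lacks: ", paste(missing, collapse = ", "))
  }
  if (tumor_immature_fraction < 0 || tumor_immature_fraction > 1)
    stop("'tumor_immature_fraction' must be in [0, 1]")
  if (!is.null(immature_o2_amplitude) && immature_o2_amplitude <= 0)
    stop("'immature_o2_amplitude' must be positive (immature vessels do respond to O2)")
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  if (baseline <= 0) stop("'baseline' must be positive")
  if (!is.null(steal_mask)) {
    stopifnot(identical(dim(steal_mask), dim(labels)))
    if (steal_o2_amplitude >= 0)
      stop("'steal_o2_amplitude' must be negative (steal effect)")
  }
  tumor_mask <- labels == hri_labels()[["tumor"]]
  immature_mask <- array(FALSE, dim = dim(labels))
  if (tumor_immature_fraction > 0) {
    idx <- which(tumor_mask)
    if (!length(idx))
      stop("'tumor_immature_fraction' > 0 but the label volume has no tumor voxels")
    n_imm <- round(tumor_immature_fraction * length(idx))
    set.seed(seed)
    immature_mask[sample(idx, n_imm)] <- TRUE
  }
  structure(
    list(labels = labels, amplitudes = amplitudes,
         tumor_immature_fraction = tumor_immature_fraction,
         immature_o2_amplitude = immature_o2_amplitude,
         immature_mask = immature_mask,
         steal_mask = steal_mask, steal_o2_amplitude = steal_o2_amplitude,
         baseline = baseline, noise_sd = noise_sd, drift = drift,
         lag_volumes = as.integer(lag_volumes), adaptation = adaptation,
         seed = as.integer(seed)),
    class = "phantom_config")
}

# per-voxel true percent signal change for one challenge, plus ground-truth masks
phantom_truth <- function(config, challenge) {
  labs <- hri_labels()
  amp <- config$amplitudes[[challenge]]
  per_label <- setNames(numeric(length(labs)), names(labs))
  per_label[names(amp)] <- amp
  per_label[["background"]] <- 0
  ds <- array(per_label[match(config$labels, labs)], dim = dim(config$labels))
  if (challenge == "hypercapnia")
    ds[config$immature_mask] <- 0
  if (challenge == "hyperoxia" && !is.null(config$immature_o2_amplitude))
    ds[config$immature_mask] <- config$immature_o2_amplitude
  if (challenge == "hyperoxia" && !is.null(config$steal_mask))
    ds[config$steal_mask] <- config$steal_o2_amplitude
  ds
}

#' Generate one synthetic BOLD run
#'
#' Synthesizes a 4D BOLD run for one challenge: per voxel,
#' `signal(t) = baseline * (1 + dS/100 * boxcar(t, lag)) * (1 + drift * (t-1)/100)
#' + noise`, where `dS` is the voxel's true percent signal change (from the
#' amplitude table, the immature mask and the steal mask) and the boxcar of
#' gas blocks after the first is attenuated by the adaptation factor. Noise is
#' independent Gaussian with SD `noise_sd`% of baseline, added to brain voxels
#' only. Reproducible: the same config and paradigm yield bit-identical runs.
#'
#' @param config A [phantom_config()].
#' @param paradigm A [gas_paradigm()]; its challenge selects the amplitude
#'   column and ground-truth masks.
#' @return A list with `run` (a `bold_run`: 4D array `data`, `tr`,
#'   `challenge`) and `truth` (true `ds` array, `immature_mask`, `steal_mask`,
#'   `tissue` label array).
#' @export
#' @examples
#' cfg <- phantom_config(phantom_labels(c(12, 12, 6)),
#'                       amplitudes = list(hyperoxia = c(GM = 2.54, WM = 0.71),
#'                                         hypercapnia = c(GM = 1.33, WM = 0.40)),
#'                       noise_sd = 0)
#' sim <- generate_run(cfg, default_paradigm("hyperoxia"))
#' dim(sim$run$data)
generate_run <- function(config, paradigm) {
  stopifnot(inherits(config, "phantom_config"), inherits(paradigm, "gas_paradigm"))
  challenge <- paradigm$challenge
  ds <- phantom_truth(config, challenge)
  n <- n_volumes(paradigm)
  dims <- dim(config$labels)
  nvox <- prod(dims)

  # lag-shifted boxcars for the first gas block and the remaining gas blocks
  shift_clip <- function(idx) { idx <- idx + config$lag_volumes; idx[idx <= n] }
  vols <- block_volumes(paradigm)
  gas_blocks <- which(paradigm$blocks$condition == "gas")
  box1 <- integer(n); box1[shift_clip(vols[[gas_blocks[1L]]])] <- 1L
  boxr <- integer(n)
  if (length(gas_blocks) > 1L)
    boxr[shift_clip(unlist(vols[gas_blocks[-1L]], use.names = FALSE))] <- 1L

  brain <- config$labels != hri_labels()[["background"]]
  baseline <- ifelse(brain, config$baseline, 0)
  response <- outer(as.vector(ds), box1 + config$adaptation * boxr) / 100
  drift_t <- 1 + config$drift / 100 * (seq_len(n) - 1)
  signal <- as.vector(baseline) * (1 + response) *
    rep(drift_t, each = nvox)
  if (config$noise_sd > 0) {
    set.seed(config$seed + match(challenge, c("hypercapnia", "hyperoxia")))
    noise <- matrix(0, nvox, n)
    nb <- sum(brain)
    noise[as.vector(brain), ] <-
      stats::rnorm(nb * n, sd = config$noise_sd / 100 * config$baseline)
    signal <- signal + noise
  }
  run <- structure(list(data = array(signal, dim = c(dims, n)),
                        tr = paradigm$tr, challenge = challenge),
                   class = "bold_run")
  truth <- list(ds = ds, immature_mask = config$immature_mask,
                steal_mask = config$steal_mask, tissue = config$labels)
  # generation-time consistency: immature voxels are CO2-silent, steal negative
  stopifnot(challenge != "hypercapnia" || all(truth$ds[truth$immature_mask] == 0))
  if (challenge == "hyperoxia" && !is.null(truth$steal_mask))
    stopifnot(all(truth$ds[truth$steal_mask] < 0))
  list(run = run, truth = truth)
}

#' Generate a synthetic healthy cohort
#'
#' Draws per-subject true tissue amplitudes from
#' `Normal(cohort mean, between_subject_sd)` for each tissue and challenge,
#' then synthesizes both challenge runs per subject. This emulates a healthy
#' reference cohort whose across-subject amplitude distribution is set by the
#' caller (e.g. to published healthy reference values).
#'
#' @param config A [phantom_config()] whose amplitude table holds the cohort
#'   means.
#' @param n_subjects Number of subjects (>= 1).
#' @param between_subject_sd Named list mirroring the amplitude table
#'   structure (`hyperoxia` / `hypercapnia`, named per tissue) with
#'   across-subject SDs in percent; tissues not listed get SD 0.
#' @param seed Integer seed for the amplitude draws and per-subject run noise.
#' @param paradigms List with the two paradigms to use (defaults to the
#'   built-in ones).
#' @return A list of subjects, each a list with `runs` (named by challenge),
#'   `truth` (per challenge), and `amplitudes` (the realized per-tissue draws).
#' @export
generate_cohort <- function(config, n_subjects, between_subject_sd,
                            seed = 1L,
                            paradigms = list(hypercapnia = default_paradigm("hypercapnia"),
                                             hyperoxia = default_paradigm("hyperoxia"))) {
  stopifnot(inherits(config, "phantom_config"))
  if (n_subjects < 1L) stop("'n_subjects' must be >= 1")
  for (ch in names(between_subject_sd))
    if (any(between_subject_sd[[ch]] < 0))
      stop("between-subject SDs must be >= 0")
  set.seed(seed)
  subject_seeds <- sample.int(.Machine$integer.max - 10L, n_subjects)
  lapply(seq_len(n_subjects), function(i) {
    amps <- config$amplitudes
    set.seed(subject_seeds[i])
    for (ch in names(amps)) {
      sds <- between_subject_sd[[ch]]
      for (tis in names(amps[[ch]])) {
        s <- if (tis %in% names(sds)) sds[[tis]] else 0
        if (s > 0) amps[[ch]][[tis]] <- stats::rnorm(1, amps[[ch]][[tis]], s)
      }
    }
    sub_cfg <- config
    sub_cfg$amplitudes <- amps
    sub_cfg$seed <- subject_seeds[i]
    out <- lapply(paradigms, function(p) generate_run(sub_cfg, p))
    list(runs = lapply(out, `[[`, "run"),
         truth = lapply(out, `[[`, "truth"),
         amplitudes = amps)
  })
}
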