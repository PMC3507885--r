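#' Read and write NIfTI-1 volumes
#'
#' Thin wrappers over RNifti preserving data, grid and orientation. Masks are
#' written as integer volumes and read back as logical when `logical = TRUE`.
#'
#' @param path File path (`.nii` or `.nii.gz`).
#' @param logical Coerce the voxel data to logical on read.
#' @return `read_volume()` returns a numeric (or logical) array with NIfTI
#'   attributes; `write_volume()` returns the path invisibly.
#' @export
read_volume <- function(path, logical = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  img <- RNifti::readNifti(path)
  if (logical) {
    attrs <- attributes(img)
    img <- img != 0
    dim(img) <- attrs$dim
  }
  img
}

#' @rdname read_volume
#' @param x Array to write (logical masks are stored as 0/1 integers).
#' @param template Optional volume whose NIfTI header (pixel dimensions,
#'   orientation) is copied onto `x`.
#' @export
write_volume <- function(x, path, template = NULL) {
  if (is.logical(x)) {
    d <- dim(x)
    x <- array(as.integer(x), dim = d)
  }
  if (!is.null(template))
    x <- RNifti::asNifti(x, reference = template)
  RNifti::writeNifti(x, path)
  invisible(path)
}

#' Check that volumes share one grid
#'
#' Fails with a message naming the offending dimensions when the (spatial)
#' grids of the supplied arrays differ.
#'
#' @param ... Named arrays to compare (3D, or 4D whose first three dims count).
#' @export
check_same_grid <- function(...) {
  vols <- list(...)
  dims <- lapply(vols, function(v) dim(v)[1:3])
  ref <- dims[[1L]]
  for (i in seq_along(dims)[-1L]) {
    if (!identical(dims[[i]], ref))
      stop("grid mismatch: '", names(vols)[1L], "' is ",
           paste(ref, collapse = "x"), " but '", names(vols)[i], "' is ",
           paste(dims[[i]], collapse = "x"))
  }
  invisible(TRUE)
}

#' Read a pipeline configuration file
#'
#' Parses a YAML (or JSON, which YAML subsumes) pipeline config and validates
#' that every referenced input file exists before any stage runs, listing all
#' problems collectively.
#'
#' @param path Path to the config file.
#' @return The config as a named list, with a `config_hash` attribute used to
#'   tag output sidecars.
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  paths <- unlist(cfg[["inputs"]], use.names = TRUE)
  missing <- if (length(paths)) paths[!file.exists(paths)] else character(0)
  if (length(missing))
    stop("missing input file(s): ",
         paste(sprintf("%s (%s)", missing, names(missing)), collapse = ", "))
  attr(cfg, "config_hash") <- config_hash(cfg)
  cfg
}

config_hash <- function(cfg) {
  tmp <- tempfile()
  on.exit(unlink(tmp))
  saveRDS(cfg, tmp)  # scratch only; deliverables stay text
  unname(tools::md5sum(tmp))
}

write_sidecar <- function(outdir, stage, cfg, extra = list()) {
  meta <- c(list(stage = stage, config_hash = attr(cfg, "config_hash"),
                 written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra)
  writeLines(yaml::as.yaml(meta), file.path(outdir, paste0(stage, ".meta.yaml")))
}

#' Full single-subject HRI analysis
#'
#' Convenience driver running the whole per-subject chain: percent signal
#' change maps for both challenges, reference statistics over the reference
#' mask (pooled GM + WM for healthy subjects; contralateral hemisphere for
#' patients), z-normalization, and the VRM map.
#'
#' @param runs Named list with `hyperoxia` and `hypercapnia` `bold_run`s.
#' @param paradigms Named list of the matching paradigms (defaults built-in).
#' @param reference_mask Logical array defining the normalization reference.
#' @param lag,alpha Passed to [compute_delta_s()].
#' @param co2_missing Passed to [compute_vrm()].
#' @return A list with `o2`, `co2` (delta_s_maps), `stats_o2`, `stats_co2`,
#'   `z_o2`, `z_co2`, and `vrm`.
#' @export
analyze_subject <- function(runs, reference_mask,
                            paradigms = list(hypercapnia = default_paradigm("hypercapnia"),
                                             hyperoxia = default_paradigm("hyperoxia")),
                            lag = 1L, alpha = 0.05,
                            co2_missing = "undefined") {
  o2 <- compute_delta_s(runs$hyperoxia, paradigms$hyperoxia, lag = lag, alpha = alpha)
  co2 <- compute_delta_s(runs$hypercapnia, paradigms$hypercapnia, lag = lag, alpha = alpha)
  stats_o2 <- reference_stats(o2, reference_mask)
  stats_co2 <- reference_stats(co2, reference_mask)
  z_o2 <- normalize_map(o2, stats_o2)
  z_co2 <- normalize_map(co2, stats_co2)
  vrm <- compute_vrm(z_o2, z_co2, co2_missing = co2_missing,
                     reference_mask = reference_mask)
  list(o2 = o2, co2 = co2, stats_o2 = stats_o2, stats_co2 = stats_co2,
       z_o2 = z_o2, z_co2 = z_co2, vrm = vrm)
}

#' Pipeline stages
#'
#' File-level stages behind the `hri` command-line interface. Each stage
#' reads/writes NIfTI-1 volumes and TSV tables in an output directory, logs
#' voxel accounting (voxels in, masked, surviving) so the significance and
#' 2-SD filters are auditable, and writes a sidecar with the config hash.
#'
#' * `stage_simulate()`: phantom runs + label and ground-truth volumes.
#' * `stage_map()`: dS, p and mask volumes for one run.
#' * `stage_vrm()`: z, VRM and abnormality volumes.
#' * `stage_report()`: the per-VOI TSV report.
#' * `stage_reference()`: cohort reference TSV from per-subject map directories.
#'
#' @param cfg Parsed pipeline config (see [read_pipeline_config()]).
#' @param outdir Output directory (created if needed).
#' @name pipeline-stages
NULL

log_line <- function(outdir, ...) {
  cat(sprintf(...), "\n", sep = "", file = file.path(outdir, "hri.log"),
      append = TRUE)
}

#' @rdname pipeline-stages
#' @export
stage_simulate <- function(cfg, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$simulate
  labels <- phantom_labels(dim = if (is.null(sim$dim)) c(32L, 32L, 16L) else unlist(sim$dim),
                           tumor = isTRUE(sim$tumor),
                           tumor_radius = if (is.null(sim$tumor_radius)) 6.5 else sim$tumor_radius)
  amps <- lapply(sim$amplitudes, function(a) unlist(a))
  pc <- phantom_config(labels, amplitudes = amps,
                       tumor_immature_fraction = if (is.null(sim$tumor_immature_fraction)) 0 else sim$tumor_immature_fraction,
                       noise_sd = if (is.null(sim$noise_sd)) 0.2 else sim$noise_sd,
                       drift = if (is.null(sim$drift)) 0 else sim$drift,
                       seed = if (is.null(sim$seed)) 1L else sim$seed)
  for (ch in c("hypercapnia", "hyperoxia")) {
    out <- generate_run(pc, default_paradigm(ch))
    write_volume(out$run$data, file.path(outdir, paste0("bold_", ch, ".nii.gz")))
    write_volume(out$truth$ds, file.path(outdir, paste0("truth_ds_", ch, ".nii.gz")))
  }
  write_volume(labels, file.path(outdir, "labels.nii.gz"))
  write_volume(pc$immature_mask, file.path(outdir, "truth_immature.nii.gz"))
  log_line(outdir, "simulate: %d voxels, tumor=%s", length(labels), isTRUE(sim$tumor))
  write_sidecar(outdir, "simulate", cfg)
  invisible(outdir)
}

#' @rdname pipeline-stages
#' @param run_path Path to a 4D BOLD NIfTI.
#' @param challenge Challenge of the run.
#' @export
stage_map <- function(cfg, run_path, challenge, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  paradigm <- if (!is.null(cfg$paradigms[[challenge]]))
    paradigm_from_config(cfg$paradigms[[challenge]]) else default_paradigm(challenge)
  vol <- read_volume(run_path)
  run <- bold_run(array(as.numeric(vol), dim = dim(vol)),
                  tr = paradigm$tr, challenge = challenge)
  lag <- if (is.null(cfg$lag)) 1L else cfg$lag
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  m <- compute_delta_s(run, paradigm, lag = lag, alpha = alpha)
  ds_out <- m$delta_s; ds_out[is.na(ds_out)] <- 0
  write_volume(ds_out, file.path(outdir, paste0("ds_", challenge, ".nii.gz")))
  write_volume(m$p, file.path(outdir, paste0("p_", challenge, ".nii.gz")))
  write_volume(m$mask, file.path(outdir, paste0("mask_", challenge, ".nii.gz")))
  log_line(outdir, "map %s: %d voxels in, %d brain, %d significant, %d defined, %d bad-baseline",
           challenge, m$qc$n_voxels, m$qc$n_brain, m$qc$n_significant,
           m$qc$n_defined, m$qc$n_bad_baseline)
  write_sidecar(outdir, paste0("map_", challenge), cfg)
  invisible(m)
}

read_delta_s_dir <- function(dir, challenge, alpha, lag) {
  ds <- read_volume(file.path(dir, paste0("ds_", challenge, ".nii.gz")))
  mask <- read_volume(file.path(dir, paste0("mask_", challenge, ".nii.gz")), logical = TRUE)
  p <- read_volume(file.path(dir, paste0("p_", challenge, ".nii.gz")))
  ds <- array(as.numeric(ds), dim = dim(ds))
  ds[!mask] <- NA_real_
  structure(list(delta_s = ds, p = array(as.numeric(p), dim = dim(p)),
                 mask = mask, challenge = challenge, alpha = alpha, lag = lag,
                 settings = list(), qc = list()),
            class = "delta_s_map")
}

#' @rdname pipeline-stages
#' @param map_dir Directory holding the `stage_map()` outputs of both runs.
#' @export
stage_vrm <- function(cfg, map_dir, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  lag <- if (is.null(cfg$lag)) 1L else cfg$lag
  o2 <- read_delta_s_dir(map_dir, "hyperoxia", alpha, lag)
  co2 <- read_delta_s_dir(map_dir, "hypercapnia", alpha, lag)
  ref <- read_volume(cfg$inputs$reference_mask, logical = TRUE)
  check_same_grid(o2 = o2$delta_s, co2 = co2$delta_s, reference = ref)
  s_o2 <- reference_stats(o2, ref)
  s_co2 <- reference_stats(co2, ref)
  z_o2 <- normalize_map(o2, s_o2)
  z_co2 <- normalize_map(co2, s_co2)
  co2_missing <- if (is.null(cfg$co2_missing)) "undefined" else cfg$co2_missing
  vrm <- compute_vrm(z_o2, z_co2, co2_missing = co2_missing, reference_mask = ref)
  for (nm in c("z_o2", "z_co2")) {
    z <- get(nm)$z; z[is.na(z)] <- 0
    write_volume(z, file.path(outdir, paste0(nm, ".nii.gz")))
  }
  v <- vrm$vrm; v[is.na(v)] <- 0
  write_volume(v, file.path(outdir, "vrm.nii.gz"))
  write_volume(vrm$defined, file.path(outdir, "vrm_defined.nii.gz"))
  if (!is.null(cfg$inputs$cohort_reference)) {
    cref <- read_cohort_reference(cfg$inputs$cohort_reference)
    tissue <- if (is.null(cfg$threshold_tissue)) "WM" else cfg$threshold_tissue
    abn <- abnormality_mask(vrm, cref, tissue)
    write_volume(abn, file.path(outdir, "abnormal.nii.gz"))
    log_line(outdir, "vrm: %d defined, %d abnormal (threshold %.4f, %s)",
             sum(vrm$defined), sum(abn), attr(abn, "threshold"), tissue)
  } else {
    log_line(outdir, "vrm: %d defined voxels", sum(vrm$defined))
  }
  write_sidecar(outdir, "vrm", cfg)
  invisible(vrm)
}

#' @rdname pipeline-stages
#' @param vrm_dir Directory holding `stage_vrm()` outputs.
#' @export
stage_report <- function(cfg, map_dir, vrm_dir, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  lag <- if (is.null(cfg$lag)) 1L else cfg$lag
  o2 <- read_delta_s_dir(map_dir, "hyperoxia", alpha, lag)
  co2 <- read_delta_s_dir(map_dir, "hypercapnia", alpha, lag)
  v <- read_volume(file.path(vrm_dir, "vrm.nii.gz"))
  vd <- read_volume(file.path(vrm_dir, "vrm_defined.nii.gz"), logical = TRUE)
  varr <- array(as.numeric(v), dim = dim(v)); varr[!vd] <- NA_real_
  vrm <- structure(list(vrm = varr, defined = vd, provenance = list()),
                   class = "vrm_map")
  lesion <- read_volume(cfg$inputs$lesion, logical = TRUE)
  cref <- read_cohort_reference(cfg$inputs$cohort_reference)
  tissue <- if (is.null(cfg$threshold_tissue)) "WM" else cfg$threshold_tissue
  rcbv <- if (!is.null(cfg$inputs$rcbv)) {
    r <- read_volume(cfg$inputs$rcbv); array(as.numeric(r), dim = dim(r))
  }
  lr_axis <- if (is.null(cfg$lr_axis)) 1L else cfg$lr_axis
  rep <- voi_report(list(o2 = o2, co2 = co2, vrm = vrm), lesion, cref,
                    tissue = tissue, lr_axis = lr_axis, rcbv = rcbv)
  utils::write.table(rep, file.path(outdir, "voi_report.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  log_line(outdir, "report: %d VOI rows (threshold tissue %s)", nrow(rep), tissue)
  write_sidecar(outdir, "report", cfg)
  invisible(rep)
}

#' @rdname pipeline-stages
#' @param subject_dirs Character vector of per-subject directories, each
#'   holding `stage_map()`/`stage_vrm()` outputs plus `gm.nii.gz`/`wm.nii.gz`
#'   tissue masks.
#' @export
stage_reference <- function(cfg, subject_dirs, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  alpha <- if (is.null(cfg$alpha)) 0.05 else cfg$alpha
  lag <- if (is.null(cfg$lag)) 1L else cfg$lag
  subjects <- lapply(subject_dirs, function(d) {
    s <- list(o2 = read_delta_s_dir(d, "hyperoxia", alpha, lag),
              co2 = read_delta_s_dir(d, "hypercapnia", alpha, lag),
              gm = read_volume(file.path(d, "gm.nii.gz"), logical = TRUE),
              wm = read_volume(file.path(d, "wm.nii.gz"), logical = TRUE))
    vrm_path <- file.path(d, "vrm.nii.gz")
    if (file.exists(vrm_path)) {
      v <- read_volume(vrm_path)
      vd <- read_volume(file.path(d, "vrm_defined.nii.gz"), logical = TRUE)
      varr <- array(as.numeric(v), dim = dim(v)); varr[!vd] <- NA_real_
      s$vrm <- structure(list(vrm = varr, defined = vd, provenance = list()),
                         class = "vrm_map")
    }
    s
  })
  ref <- aggregate_reference(subjects)
  write_cohort_reference(ref, file.path(outdir, "cohort_reference.tsv"))
  log_line(outdir, "reference: %d subjects aggregated", length(subjects))
  write_sidecar(outdir, "reference", cfg)
  invisible(ref)
}

#' Read/write a cohort reference TSV
#'
#' Fixed-header TSV (`tissue  quantity  mean  sd  n_subjects`) round-tripping
#' a [cohort_reference_table()].
#'
#' @param path TSV path.
#' @export
read_cohort_reference <- function(path) {
  out <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("tissue", "quantity", "mean", "sd", "n_subjects")
  if (!all(need %in% names(out)))
    stop("cohort reference TSV must have columns: ", paste(need, collapse = ", "))
  class(out) <- c("cohort_reference", "data.frame")
  out
}

#' @rdname read_cohort_reference
#' @param ref A [cohort_reference_table()].
#' @export
write_cohort_reference <- function(ref, path) {
  utils::write.table(ref, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
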