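#' Construct a BOLD run from a 4D array
#'
#' @param data 4D numeric array (x, y, z, t) in arbitrary scanner units.
#' @param tr Repetition time in seconds.
#' @param challenge Challenge type of the acquisition.
#' @return An object of class `bold_run`.
#' @export
bold_run <- function(data, tr, challenge = c("hypercapnia", "hyperoxia")) {
  challenge <- match.arg(challenge)
  if (!is.array(data) || length(dim(data)) != 4L)
    stop("'data' must be a 4D array (x, y, z, t)")
  if (any(!is.finite(data)))
    stop("'data' contains non-finite values")
  structure(list(data = data, tr = as.numeric(tr), challenge = challenge),
            class = "bold_run")
}

check_run_paradigm <- function(run, paradigm) {
  if (run$challenge != paradigm$challenge)
    stop("run challenge ('", run$challenge, "') does not match the paradigm ('",
         paradigm$challenge, "')")
  nt <- dim(run$data)[4L]
  np <- n_volumes(paradigm)
  if (nt != np)
    stop("run has ", nt, " volumes but the paradigm implies ", np)
  invisible(TRUE)
}

# flatten the 4D run into a voxels x time matrix
run_matrix <- function(run) {
  d <- dim(run$data)
  matrix(run$data, nrow = prod(d[1:3]), ncol = d[4L])
}

#' Voxelwise block-design response test
#'
#' Correlates every voxel's time series with the (lag-shifted) boxcar
#' regressor of the breathing paradigm and converts the Pearson correlation to
#' a p-value through the t transform with `n - 2` degrees of freedom. This is
#' the detection step of HRI mapping: it uses the full run (all gas blocks),
#' while the percent-signal-change estimate itself uses only the first gas
#' block (see [compute_delta_s()]). Constant time series (e.g. background) get
#' `r = NA` and `p = 1` by convention.
#'
#' @param run A `bold_run`.
#' @param paradigm The matching [gas_paradigm()].
#' @param lag Hemodynamic lag in volumes applied to the regressor.
#' @param sided `"two"` (default, so negative steal responses are detectable)
#'   or `"one"` (positive responses only).
#' @param detrend If `TRUE`, a linear trend is projected out of every time
#'   series (and the regressor) before correlating.
#' @return A list with 3D arrays `p` and `r`, and `n` (volumes used).
#' @export
test_response <- function(run, paradigm, lag = 1L,
                          sided = c("two", "one"), detrend = FALSE) {
  sided <- match.arg(sided)
  check_run_paradigm(run, paradigm)
  reg <- to_regressor(paradigm, lag_volumes = lag)
  g <- as.numeric(reg$values)
  x <- run_matrix(run)
  n <- length(g)
  if (detrend) {
    tt <- seq_len(n)
    basis <- cbind(1, tt)
    proj <- basis %*% solve(crossprod(basis), t(basis))
    x <- x - x %*% t(proj)
    g <- g - as.vector(proj %*% g)
  }
  xc <- x - rowMeans(x)
  gc <- g - mean(g)
  ss_x <- rowSums(xc^2)
  ss_g <- sum(gc^2)
  r <- as.vector(xc %*% gc) / sqrt(ss_x * ss_g)
  r[ss_x == 0] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  df <- n - 2L
  tval <- r * sqrt(df) / sqrt(pmax(1 - r^2, 0))
  p <- if (sided == "two") 2 * stats::pt(-abs(tval), df) else stats::pt(-tval, df)
  p[is.na(r)] <- 1
  dims <- dim(run$data)[1:3]
  list(p = array(p, dims), r = array(r, dims), n = n)
}

#' Percent signal change (\eqn{\Delta}S) map for one challenge
#'
#' Estimates the voxelwise percent signal change relative to room-air
#' baseline, keeping only voxels whose time series correlates with the
#' breathing paradigm at `p < alpha` (uncorrected, mirroring the original HRI
#' analysis). The estimate uses the FIRST gas block against its immediately
#' preceding baseline block — repeated challenges provoke physiological
#' adaptation, so later blocks understate the response — while detection uses
#' the full run:
#' \deqn{\Delta S = 100 (\bar S_{gas} - \bar S_{base}) / \bar S_{base}}
#' Block "plateau" means are taken after dropping `lag` volumes at each block
#' onset (hemodynamic delay) and, optionally, `discard_transition` further
#' volumes at both block edges. Negative responses (vascular steal) are
#' preserved with their sign. Voxels with non-positive baseline are masked
#' and counted in the QC log.
#'
#' @inheritParams test_response
#' @param alpha Significance level of the uncorrected voxelwise test
#'   (default 0.05).
#' @param discard_transition Extra volumes to drop at both edges of each block
#'   before averaging (default 0).
#' @return An object of class `delta_s_map`: `delta_s` (3D array, `NA` where
#'   masked), `p`, `mask` (logical), `challenge`, `alpha`, `lag`, and a `qc`
#'   list with voxel accounting.
#' @export
#' @examples
#' cfg <- phantom_config(phantom_labels(c(12, 12, 6)),
#'                       amplitudes = list(hyperoxia = c(GM = 2, WM = 0.7),
#'                                         hypercapnia = c(GM = 1.3, WM = 0.4)),
#'                       noise_sd = 0, lag_volumes = 0)
#' sim <- generate_run(cfg, default_paradigm("hyperoxia"))
#' m <- compute_delta_s(sim$run, default_paradigm("hyperoxia"), lag = 0)
#' mean(m$delta_s[cfg$labels == hri_labels()["GM"]])  # 2
compute_delta_s <- function(run, paradigm, lag = 1L, alpha = 0.05,
                            discard_transition = 0L,
                            sided = c("two", "one"), detrend = FALSE) {
  sided <- match.arg(sided)
  check_run_paradigm(run, paradigm)
  if (alpha <= 0 || alpha > 1) stop("'alpha' must be in (0, 1]")
  test <- test_response(run, paradigm, lag = lag, sided = sided, detrend = detrend)

  plateau <- function(idx) {
    keep <- idx[(lag + discard_transition + 1L):(length(idx) - discard_transition)]
    if (length(keep) < 1L)
      stop("lag/discard settings leave no plateau volumes in a ",
           length(idx), "-volume block")
    keep
  }
  gas_idx <- plateau(block_volume_indices(paradigm, "first_gas"))
  base_idx <- plateau(block_volume_indices(paradigm, "baseline_before_first_gas"))

  x <- run_matrix(run)
  m_gas <- rowMeans(x[, gas_idx, drop = FALSE])
  m_base <- rowMeans(x[, base_idx, drop = FALSE])
  dims <- dim(run$data)[1:3]

  brain <- m_base != 0  # phantom/real background is exactly/near zero-mean
  bad_baseline <- brain & m_base < 0
  significant <- as.vector(test$p) < alpha
  keep <- significant & m_base > 0
  ds <- rep(NA_real_, length(m_base))
  ds[keep] <- 100 * (m_gas[keep] - m_base[keep]) / m_base[keep]

  structure(
    list(delta_s = array(ds, dims),
         p = test$p,
         mask = array(keep, dims),
         challenge = run$challenge,
         alpha = alpha, lag = as.integer(lag),
         settings = list(discard_transition = discard_transition,
                         sided = sided, detrend = detrend),
         qc = list(n_voxels = length(ds),
                   n_brain = sum(brain),
                   n_significant = sum(significant & brain),
                   n_bad_baseline = sum(bad_baseline),
                   n_defined = sum(keep))),
    class = "delta_s_map")
}

#' @export
print.delta_s_map <- function(x, ...) {
  cat(sprintf("<delta_s_map> %s: %d/%d voxels defined (alpha = %g, lag = %d)\n",
              x$challenge, x$qc$n_defined, x$qc$n_voxels, x$alpha, x$lag))
  invisible(x)
}

#' Volume-to-volume center-of-mass motion check
#'
#' HRI assumes motion-corrected input. As a guard, this computes the
#' intensity-weighted center of mass of every volume and warns when the
#' maximum volume-to-volume displacement exceeds `max_shift` voxels.
#'
#' @param run A `bold_run`.
#' @param max_shift Displacement bound in voxels (default 0.5).
#' @return Invisibly, the per-volume displacement vector (length `t - 1`).
#' @export
qc_motion <- function(run, max_shift = 0.5) {
  d <- dim(run$data)
  x <- run_matrix(run)
  w <- colSums(x)
  coords <- arrayInd(seq_len(prod(d[1:3])), d[1:3])
  com <- t(vapply(seq_len(d[4L]), function(t)
    colSums(coords * x[, t]) / w[t], numeric(3L)))
  disp <- sqrt(rowSums(diff(com)^2))
  if (any(disp > max_shift))
    warning(sprintf("max volume-to-volume center-of-mass shift %.2f voxels exceeds %g; input may not be motion-corrected",
                    max(disp), max_shift))
  invisible(disp)
}
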