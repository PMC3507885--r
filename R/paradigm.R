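#' Gas-challenge block paradigm
#'
#' A `gas_paradigm` describes one breathing paradigm as an ordered sequence of
#' room-air and gas blocks, together with the repetition time (TR) of the BOLD
#' acquisition. Block durations must be positive integer multiples of the TR so
#' that every acquired volume belongs to exactly one block, and the run must be
#' bracketed by room-air baselines (first and last blocks are air) with at
#' least one gas block in between.
#'
#' @param challenge Challenge type, `"hypercapnia"` (95% air + 5% CO2) or
#'   `"hyperoxia"` (carbogen, 95% O2 + 5% CO2).
#' @param blocks A data frame with columns `condition` (`"air"` or `"gas"`) and
#'   `duration` (seconds), one row per block in temporal order.
#' @param tr Repetition time in seconds per acquired volume.
#' @return An object of class `gas_paradigm`.
#' @seealso [default_paradigm()], [to_regressor()], [block_volume_indices()]
#' @export
#' @examples
#' gas_paradigm("hypercapnia",
#'              data.frame(condition = c("air", "gas", "air"),
#'                         duration  = c(60, 90, 60)),
#'              tr = 5)
gas_paradigm <- function(challenge = c("hypercapnia", "hyperoxia"), blocks, tr) {
  challenge <- match.arg(challenge)
  if (!is.data.frame(blocks) || !all(c("condition", "duration") %in% names(blocks)))
    stop("'blocks' must be a data frame with columns 'condition' and 'duration'")
  blocks$condition <- as.character(blocks$condition)
  if (!all(blocks$condition %in% c("air", "gas")))
    stop("block conditions must be 'air' or 'gas'")
  if (!is.numeric(tr) || length(tr) != 1L || tr <= 0)
    stop("'tr' must be a single positive number of seconds")
  if (any(blocks$duration <= 0))
    stop("every block duration must be > 0 seconds")
  ratio <- blocks$duration / tr
  if (any(abs(ratio - round(ratio)) > 1e-9))
    stop("every block duration must be an integer multiple of tr (tr = ",
         tr, " s; offending durations: ",
         paste(blocks$duration[abs(ratio - round(ratio)) > 1e-9], collapse = ", "), ")")
  n <- nrow(blocks)
  if (n < 3L || blocks$condition[1L] != "air" || blocks$condition[n] != "air")
    stop("paradigm must start and end with a room-air baseline block")
  if (!any(blocks$condition == "gas"))
    stop("paradigm must contain at least one gas block")
  structure(
    list(challenge = challenge,
         blocks = data.frame(condition = blocks$condition,
                             duration = as.numeric(blocks$duration)),
         tr = as.numeric(tr)),
    class = "gas_paradigm")
}

#' Built-in HRI breathing paradigms
#'
#' Returns the standard HRI block design for the requested challenge:
#' hypercapnia runs 1 min air, 1.5 min gas, 2 min air, 1.5 min gas, 1 min air
#' (7 min total); hyperoxia runs 1 min air, 1 min gas, 1.5 min air, 1 min gas,
#' 1 min air (5.5 min total). At the default TR of 5 s these give 84 and 66
#' volumes respectively.
#'
#' @inheritParams gas_paradigm
#' @param tr Repetition time in seconds (default 5, the HRI protocol value).
#' @return A `gas_paradigm`.
#' @export
#' @examples
#' p <- default_paradigm("hyperoxia")
#' total_duration(p)  # 330 s
#' n_volumes(p)       # 66
default_paradigm <- function(challenge = c("hypercapnia", "hyperoxia"), tr = 5) {
  challenge <- match.arg(challenge)
  durations <- switch(challenge,
    hypercapnia = c(60, 90, 120, 90, 60),
    hyperoxia   = c(60, 60,  90, 60, 60))
  gas_paradigm(challenge,
               data.frame(condition = c("air", "gas", "air", "gas", "air"),
                          duration = durations),
               tr = tr)
}

#' @rdname default_paradigm
#' @param paradigm A `gas_paradigm`.
#' @export
total_duration <- function(paradigm) {
  stopifnot(inherits(paradigm, "gas_paradigm"))
  sum(paradigm$blocks$duration)
}

#' @rdname default_paradigm
#' @export
n_volumes <- function(paradigm) {
  stopifnot(inherits(paradigm, "gas_paradigm"))
  as.integer(round(total_duration(paradigm) / paradigm$tr))
}

#' @export
print.gas_paradigm <- function(x, ...) {
  cat(sprintf("<gas_paradigm> %s: %d blocks, %g s total, tr = %g s (%d volumes)\n",
              x$challenge, nrow(x$blocks), total_duration(x), x$tr, n_volumes(x)))
  cat(paste(sprintf("  %-3s %5g s", x$blocks$condition, x$blocks$duration),
            collapse = "\n"), "\n")
  invisible(x)
}

# per-block volume index list (1-based, contiguous); a volume belongs to the
# block containing its start time
block_volumes <- function(paradigm) {
  nb <- round(paradigm$blocks$duration / paradigm$tr)
  ends <- cumsum(nb)
  starts <- c(1L, head(ends, -1L) + 1L)
  mapply(seq.int, starts, ends, SIMPLIFY = FALSE)
}

#' Volume indices of paradigm segments
#'
#' Maps a paradigm segment to the 1-based indices of the volumes it contains.
#' A volume is assigned to the block that contains its start time, so the
#' segments `all_gas` and `all_air` partition the run.
#'
#' @param paradigm A `gas_paradigm`.
#' @param which One of `"first_gas"` (the first gas block),
#'   `"baseline_before_first_gas"` (the air block immediately preceding it),
#'   `"all_gas"`, or `"all_air"`.
#' @return An integer vector of 1-based volume indices.
#' @export
#' @examples
#' block_volume_indices(default_paradigm("hypercapnia"), "first_gas")
block_volume_indices <- function(paradigm,
                                 which = c("first_gas", "baseline_before_first_gas",
                                           "all_gas", "all_air")) {
  stopifnot(inherits(paradigm, "gas_paradigm"))
  which <- match.arg(which)
  vols <- block_volumes(paradigm)
  cond <- paradigm$blocks$condition
  first_gas_block <- match("gas", cond)
  switch(which,
    first_gas = vols[[first_gas_block]],
    baseline_before_first_gas = vols[[first_gas_block - 1L]],
    all_gas = unlist(vols[cond == "gas"], use.names = FALSE),
    all_air = unlist(vols[cond == "air"], use.names = FALSE))
}

#' Boxcar regressor for a paradigm
#'
#' Renders the paradigm as a per-volume boxcar: 1 for volumes inside gas
#' blocks, 0 elsewhere, optionally shifted forward by an integer number of
#' volumes to account for hemodynamic lag (the BOLD response trails the
#' inspired gas by roughly one circulation time). The shifted boxcar is
#' clipped at the end of the run so the regressor length always matches the
#' number of acquired volumes.
#'
#' @param paradigm A `gas_paradigm`.
#' @param lag_volumes Non-negative integer shift in volumes; must be smaller
#'   than the shortest block of the paradigm.
#' @return An object of class `hri_regressor`: a list with `values` (0/1
#'   vector of length [n_volumes()]), `n_volumes` and `lag_volumes`.
#' @export
#' @examples
#' r <- to_regressor(default_paradigm("hypercapnia"), lag_volumes = 0)
#' which(r$values == 1)
to_regressor <- function(paradigm, lag_volumes = 1L) {
  stopifnot(inherits(paradigm, "gas_paradigm"))
  lag_volumes <- as.integer(lag_volumes)
  if (length(lag_volumes) != 1L || is.na(lag_volumes) || lag_volumes < 0L)
    stop("'lag_volumes' must be a single non-negative integer")
  shortest <- min(round(paradigm$blocks$duration / paradigm$tr))
  if (lag_volumes >= shortest)
    stop("'lag_volumes' (", lag_volumes, ") must be smaller than the shortest ",
         "block (", shortest, " volumes)")
  n <- n_volumes(paradigm)
  gas <- block_volume_indices(paradigm, "all_gas") + lag_volumes
  gas <- gas[gas <= n]
  values <- integer(n)
  values[gas] <- 1L
  structure(list(values = values, n_volumes = n, lag_volumes = lag_volumes),
            class = "hri_regressor")
}

# Build a paradigm from a plain config list, e.g. parsed from YAML:
#   challenge: hypercapnia
#   tr: 5
#   blocks: [{condition: air, seconds: 60}, {condition: gas, seconds: 90}, ...]
# A missing 'blocks' entry falls back to the built-in paradigm for the challenge.

#' Build a paradigm from a configuration list
#'
#' Accepts the structured form used in pipeline config files (see Details) and
#' returns a validated [gas_paradigm()]. When no `blocks` entry is present the
#' built-in paradigm for the challenge is used.
#'
#' @details The list must carry `challenge` and optionally `tr` (default 5)
#'   and `blocks`, a list of `(condition, seconds)` pairs.
#' @param config A named list as parsed from YAML/JSON.
#' @return A `gas_paradigm`.
#' @export
paradigm_from_config <- function(config) {
  if (is.null(config$challenge))
    stop("paradigm config must name a 'challenge'")
  tr <- if (is.null(config$tr)) 5 else config$tr
  if (is.null(config$blocks))
    return(default_paradigm(config$challenge, tr = tr))
  blocks <- data.frame(
    condition = vapply(config$blocks, function(b) as.character(b$condition), ""),
    duration = vapply(config$blocks, function(b) as.numeric(b$seconds), 0))
  gas_paradigm(config$challenge, blocks, tr = tr)
}
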