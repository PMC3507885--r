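# Shared fixtures: all phantoms are generated in code at test time.

# healthy reference amplitudes (percent signal change) used across tests
t2_means <- list(hyperoxia = c(GM = 2.54, WM = 0.71),
                 hypercapnia = c(GM = 1.33, WM = 0.40))
t2_sds <- list(hyperoxia = c(GM = 0.63, WM = 0.30),
               hypercapnia = c(GM = 0.33, WM = 0.24))

both_paradigms <- function() {
  list(hypercapnia = default_paradigm("hypercapnia"),
       hyperoxia = default_paradigm("hyperoxia"))
}

# small noiseless phantom with lag 0: downstream estimates are exact
small_config <- function(noise_sd = 0, lag = 0L, dim = c(12, 12, 6),
                         amplitudes = list(hyperoxia = c(GM = 2, WM = 0.7),
                                           hypercapnia = c(GM = 1.3, WM = 0.4)),
                         ...) {
  phantom_config(phantom_labels(dim), amplitudes = amplitudes,
                 noise_sd = noise_sd, lag_volumes = lag, ...)
}

label_mask <- function(config, label) {
  config$labels == hri_labels()[[label]]
}

# wrap a bare delta-S array (NA = undefined) as a delta_s_map for unit tests
as_delta_s_map <- function(arr, challenge = "hyperoxia") {
  structure(list(delta_s = arr, p = array(0, dim(arr)), mask = !is.na(arr),
                 challenge = challenge, alpha = 0.05, lag = 0L,
                 settings = list(), qc = list()),
            class = "delta_s_map")
}

as_vrm_map <- function(arr) {
  structure(list(vrm = arr, defined = !is.na(arr), provenance = list()),
            class = "vrm_map")
}
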