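#' Configuration for a simulated bee
#'
#' Returns the full, validated configuration for the l-ALT circuit model,
#' organised in sections. Any default can be overridden by passing a named
#' list for the section; unknown section or key names are rejected with the
#' nearest valid name.
#'
#' Sections and selected keys (see the methods vignette for the full
#' rationale):
#' \describe{
#'   \item{network}{circuit size (`n_glomeruli`, `orn_per_type`), integration
#'     step `dt` (ms), LIF constants (`tau_pn`, `tau_ln`, `tau_gin`,
#'     `tau_lhn` in ms; normalized-unit `R_m`, `V_thresh`, `V_reset_lif`),
#'     membrane noise, synaptic reversal potentials (`V_E`, `V_I`, `V_gI`)
#'     and time constants (`tau_E` = 5 ms, `tau_I` = 10 ms, `tau_gin_syn` =
#'     20 ms), initial-weight law and per-pathway weight scales and bounds,
#'     GIN gain presets (`gin_weak`, `gin_strong`).}
#'   \item{receptors}{AdEx constants (canonical set: `C_orn` 281 pF, `gL` 30
#'     nS, `EL` -70.6 mV, `DeltaT` 2 mV, `VT` -50.4 mV, `a_adapt` 4 nS,
#'     `tau_w` 144 ms, `b_adapt` 80.5 pA), baseline current `I_base` and
#'     stimulus `gain` (pA), current noise `sigma_orn` (pA), affinity
#'     sampling controls, and `drive_mode` (`"active"` averages Hill
#'     responses over ligands present in the stimulus; `"all"` over the whole
#'     ligand space).}
#'   \item{plasticity}{iSTDP (`eta`, `tau_istdp`, `rho0`), STDP kernel
#'     (`A_plus`, `A_minus`, `tau_plus`, `tau_minus`), octopamine
#'     (`d_oct`, `tau_d`, `strict_eligibility`, `reward_delay` ms).}
#'   \item{protocol}{trial timing (1000 ms trials, stimulus 250-750 ms),
#'     shortened exposure/probe presentations, test repetitions `n_test`,
#'     default training trials `n_training`, `mixture_mode`.}
#' }
#'
#' @param network,receptors,plasticity,protocol Named lists of overrides.
#' @return Nested list of class `bee_config`.
#' @export
bee_config <- function(network = list(), receptors = list(),
                       plasticity = list(), protocol = list()) {
  defaults <- list(
    network = list(
      n_glomeruli = 36, orn_per_type = 10, dt = 0.1,
      tau_pn = 20, tau_ln = 20, tau_gin = 20, tau_lhn = 20, R_m = 1,
      V_thresh = 1, V_reset_lif = 0, refrac_lif = 2,
      sigma_pn = 0.02, sigma_ln = 0.02, sigma_gin = 0.01, sigma_lhn = 0.01,
      V_E = 6, V_I = -2, V_gI = -2, tau_E = 5, tau_I = 10, tau_gin_syn = 20,
      w_init_sd = 10, w_init_mode = "rectify",
      wmax_ln_pn = 25, wmax_ln_ln = 25, wmax_pn_lhn = 1,
      pn_ln_density = 0.2,
      scale_orn_pn = 0.22, scale_orn_ln = 0.26,
      scale_ln_pn = 0.005, scale_ln_ln = 0.002, scale_pn_ln = 0.01,
      scale_pn_lhn = 0.18, c_pn_gin = 0.05,
      gin_weak = 0.1, gin_strong = 0.4,
      pn_lhn_init_min = 0.1, pn_lhn_init_max = 0.25
    ),
    receptors = list(
      C_orn = 281, gL = 30, EL = -70.6, DeltaT = 2, VT = -50.4,
      a_adapt = 4, tau_w = 144, b_adapt = 80.5, v_reset = -70.6,
      V_peak = -40.4, sigma_orn = 180, I_base = 870, gain = 26000,
      refrac_orn = 2, w_init = 240, drive_mode = "all",
      hill_min = 0.5, hill_max = 2.5, suppressive_frac = 0.25,
      affinity_decades = 7, tail_shape = 3
    ),
    plasticity = list(
      eta = 0.005, tau_istdp = 20, rho0 = 15,
      A_plus = 0.0035, A_minus = -0.0035, tau_plus = 20, tau_minus = 20,
      d_oct = 20, tau_d = 400, ln_ln_rate = 0.2, us_drive_lhn = 1.5,
      strict_eligibility = FALSE, reward_delay = 0
    ),
    protocol = list(
      trial_length = 1000, stim_onset = 250, stim_offset = 750,
      exposure_length = 600, exposure_onset = 100, exposure_offset = 600,
      probe_length = 500, probe_onset = 50, probe_offset = 500,
      n_test = 3, n_training = 10, n_probe_odors = 64,
      mixture_mode = "sum-clip"
    )
  )
  user <- list(network = network, receptors = receptors,
               plasticity = plasticity, protocol = protocol)
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), names(defaults[[sec]]))
    if (length(bad)) {
      near <- vapply(bad, function(k) {
        cand <- agrep(k, names(defaults[[sec]]), max.distance = 0.4,
                      value = TRUE)
        if (length(cand)) paste0(" (did you mean '", cand[1], "'?)") else ""
      }, character(1))
      stop("unknown config key", if (length(bad) > 1) "s", " in section '",
           sec, "': ", paste0("'", bad, "'", near, collapse = ", "),
           call. = FALSE)
    }
    defaults[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  structure(defaults, class = "bee_config")
}

# Flat scalar list in the exact shape the C++ integrator expects.
cpp_cfg <- function(bee) {
  nw <- bee$config$network
  rc <- bee$config$receptors
  pl <- bee$config$plasticity
  list(
    dt = nw$dt,
    C_orn = rc$C_orn, gL = rc$gL, EL = rc$EL, DeltaT = rc$DeltaT,
    VT = rc$VT, a_adapt = rc$a_adapt, tau_w = rc$tau_w,
    b_adapt = rc$b_adapt, v_reset = rc$v_reset, V_peak = rc$V_peak,
    sigma_orn = rc$sigma_orn, I_base = rc$I_base, refrac_orn = rc$refrac_orn,
    w_init = rc$w_init,
    tau_pn = nw$tau_pn, tau_ln = nw$tau_ln, tau_gin = nw$tau_gin,
    tau_lhn = nw$tau_lhn, R_m = nw$R_m, V_thresh = nw$V_thresh,
    V_reset_lif = nw$V_reset_lif, refrac_lif = nw$refrac_lif,
    sigma_pn = nw$sigma_pn, sigma_ln = nw$sigma_ln,
    sigma_gin = nw$sigma_gin, sigma_lhn = nw$sigma_lhn,
    V_E = nw$V_E, V_I = nw$V_I, V_gI = nw$V_gI,
    tau_E = nw$tau_E, tau_I = nw$tau_I, tau_gin_syn = nw$tau_gin_syn,
    eta = pl$eta, tau_istdp = pl$tau_istdp, rho0 = pl$rho0,
    A_plus = pl$A_plus, A_minus = pl$A_minus, tau_plus = pl$tau_plus,
    tau_minus = pl$tau_minus, d_oct = pl$d_oct, tau_d = pl$tau_d,
    ln_ln_rate = pl$ln_ln_rate, us_drive_lhn = pl$us_drive_lhn,
    strict_eligibility = as.numeric(isTRUE(pl$strict_eligibility))
  )
}

#' Build a simulated bee
#'
#' Constructs the full l-ALT circuit for one individual: a fixed receptor
#' affinity matrix, 36 glomeruli with one projection neuron (PN) and one
#' local neuron (LN) each wired one-to-one to the 36 receptor types (10 ORNs
#' per type, 360 in total), a single global inhibitory neuron (GIN) fed by
#' and feeding back onto all PNs, and a single lateral horn decision neuron
#' (LHN) receiving all PNs. The inhibitory LN->PN and LN->LN matrices are
#' initialised from a rectified Gaussian N(0, 10) with zero diagonal (no
#' self-glomerulus inhibition); PN->LN excitation is sparse, weak and fixed.
#' All draws derive from named substreams of `seed`, so the affinity,
#' connectome and membrane noise of one component cannot shift another's.
#'
#' @param seed Integer seed identifying the individual.
#' @param config A [bee_config()].
#' @param gin GIN feedback level: `"strong"` (default), `"weak"`, or a
#'   non-negative numeric gain.
#' @return Object of class `bee`.
#' @examples
#' bee <- build_bee(seed = 1)
#' bee
#' @export
build_bee <- function(seed = 1, config = bee_config(), gin = "strong") {
  stopifnot(inherits(config, "bee_config"))
  nw <- config$network
  rc <- config$receptors
  n <- nw$n_glomeruli
  affinity <- sample_affinity(
    seed = derive_seed(seed, "affinity"), n = n,
    hill_range = c(rc$hill_min, rc$hill_max),
    suppressive_frac = rc$suppressive_frac,
    affinity_decades = rc$affinity_decades, tail_shape = rc$tail_shape
  )
  conn <- withr::with_seed(derive_seed(seed, "connectome"), {
    init_inh <- function() {
      m <- matrix(rnorm(n * n, 0, nw$w_init_sd), n, n)
      m <- if (identical(nw$w_init_mode, "abs")) abs(m) else pmax(m, 0)
      m <- pmin(m, nw$wmax_ln_pn)
      diag(m) <- 0
      m
    }
    c_ln_pn <- init_inh()
    c_ln_ln <- pmin(init_inh(), nw$wmax_ln_ln)
    c_pn_ln <- matrix(as.numeric(runif(n * n) < nw$pn_ln_density), n, n)
    diag(c_pn_ln) <- 0
    c_pn_lhn <- runif(n, nw$pn_lhn_init_min, nw$pn_lhn_init_max)
    list(
      n_glomeruli = n, orn_per_type = nw$orn_per_type,
      c_orn_pn = rep(1, n), c_orn_ln = rep(1, n),
      c_ln_pn = c_ln_pn, c_ln_ln = c_ln_ln, c_pn_ln = c_pn_ln,
      c_pn_lhn = c_pn_lhn,
      c_gin_pn = NA_real_, c_pn_gin = nw$c_pn_gin,
      scale_orn_pn = nw$scale_orn_pn, scale_orn_ln = nw$scale_orn_ln,
      scale_ln_pn = nw$scale_ln_pn, scale_ln_ln = nw$scale_ln_ln,
      scale_pn_ln = nw$scale_pn_ln, scale_pn_lhn = nw$scale_pn_lhn,
      wmax_ln_pn = nw$wmax_ln_pn, wmax_ln_ln = nw$wmax_ln_ln,
      wmax_pn_lhn = nw$wmax_pn_lhn
    )
  })
  bee <- structure(
    list(seed = seed, config = config, affinity = affinity,
         connectome = conn, gin_level = NULL, calibration = NULL),
    class = "bee"
  )
  set_gin(bee, gin)
}

#' @export
print.bee <- function(x, ...) {
  n <- x$connectome$n_glomeruli
  cat("<bee> seed ", x$seed, ": ", n * x$connectome$orn_per_type,
      " ORNs (", n, " types), ", n, " glomeruli (1 PN + 1 LN each), ",
      "1 GIN (", format(x$gin_level), "), 1 LHN\n", sep = "")
  if (!is.null(x$calibration)) {
    cat("  calibrated: input-weight factor ",
        signif(x$calibration$factor, 4), ", evoked LN delta ",
        signif(x$calibration$achieved_delta, 4), " Hz\n", sep = "")
  }
  invisible(x)
}

#' Set the global-inhibitory-neuron feedback gain
#'
#' The GIN gain controls how strongly feedback inhibition from the single
#' homogeneous local neuron pushes PN activity down; stronger gain
#' accelerates decorrelation during non-associative exposure.
#'
#' @param bee A [build_bee()] object.
#' @param level `"strong"`, `"weak"`, or a non-negative numeric gain.
#' @return The bee with the gain set (recorded in `gin_level`).
#' @export
set_gin <- function(bee, level = c("strong", "weak")) {
  if (is.numeric(level)) {
    if (level < 0) stop("GIN gain must be non-negative", call. = FALSE)
    bee$connectome$c_gin_pn <- level
    bee$gin_level <- level
  } else {
    level <- match.arg(level)
    bee$connectome$c_gin_pn <-
      if (level == "strong") bee$config$network$gin_strong
      else bee$config$network$gin_weak
    bee$gin_level <- level
  }
  bee
}

#' Trial timing schedule
#'
#' Standard trial: 1000 ms, stimulus from 250 ms to 750 ms; the reward (on
#' rewarded trials) arrives at stimulus onset plus the configured delay.
#'
#' @param trial_length,stim_onset,stim_offset Times in ms.
#' @return List of class `trial_schedule`.
#' @export
trial_schedule <- function(trial_length = 1000, stim_onset = 250,
                           stim_offset = 750) {
  stopifnot(0 <= stim_onset, stim_onset < stim_offset,
            stim_offset <= trial_length)
  structure(list(trial_length = trial_length, stim_onset = stim_onset,
                 stim_offset = stim_offset), class = "trial_schedule")
}

# Internal: run a block of trials through the C++ integrator.
# odors: matrix (n_trials x n_ligands); flags are vectors or scalars.
run_block <- function(bee, odors, schedule = NULL, rewarded = FALSE,
                      istdp = FALSE, assoc = FALSE, seed = NULL,
                      snapshot_after = integer(0), record_spikes = FALSE,
                      record_u = FALSE, orn_only = FALSE) {
  pr <- bee$config$protocol
  rc <- bee$config$receptors
  if (is.null(schedule)) schedule <- trial_schedule(
    pr$trial_length, pr$stim_onset, pr$stim_offset)
  if (is.null(dim(odors))) odors <- matrix(odors, nrow = 1)
  n_trials <- nrow(odors)
  drives <- t(apply(odors, 1, function(v)
    orn_drive_vec(bee$affinity, v, rc$I_base, rc$gain, rc$drive_mode)))
  if (n_trials == 1) drives <- matrix(drives, nrow = 1)
  rew <- as.integer(rep_len(rewarded, n_trials))
  sched <- list(
    onset_ms = rep(schedule$stim_onset, n_trials),
    offset_ms = rep(schedule$stim_offset, n_trials),
    length_ms = rep(schedule$trial_length, n_trials),
    rewarded = rew,
    reward_ms = rep(schedule$stim_onset + bee$config$plasticity$reward_delay,
                    n_trials),
    istdp = as.integer(rep_len(istdp, n_trials)),
    assoc = as.integer(rep_len(assoc, n_trials))
  )
  seed <- seed %||% derive_seed(bee$seed, "noise")
  out <- run_trials_cpp(cpp_cfg(bee), bee$connectome, drives, sched,
                        as.integer(snapshot_after), record_spikes, record_u,
                        orn_only, as.numeric(seed))
  bee$connectome$c_ln_pn <- out$c_ln_pn
  bee$connectome$c_ln_ln <- out$c_ln_ln
  bee$connectome$c_pn_lhn <- as.numeric(out$c_pn_lhn)
  out$bee <- bee
  out
}

pop_names <- c("ORN", "PN", "LN", "GIN", "LHN")

spikes_tbl <- function(out) {
  if (is.null(out$spikes)) return(tibble(
    trial = integer(), population = character(), neuron = integer(),
    time_ms = numeric()))
  tibble(
    trial = out$spikes$trial,
    population = pop_names[out$spikes$pop + 1L],
    neuron = out$spikes$neuron,
    time_ms = out$spikes$time_ms
  )
}

#' Simulate a single stimulus presentation
#'
#' Runs one trial of the full circuit (or the receptor layer alone) for a
#' given odour and returns the spike train and per-population firing rates.
#' Plasticity is off unless requested, so repeated calls with the same seed
#' are exact replays.
#'
#' @param bee A [build_bee()] object.
#' @param odor An odour (one-row tibble or concentration vector); `NULL`
#'   presents a blank (baseline drive only).
#' @param schedule A [trial_schedule()].
#' @param plasticity `"none"`, `"istdp"` (LN->PN), `"assoc"`
#'   (PN->LHN and LN->LN modulated STDP), or `"both"`.
#' @param rewarded Whether the octopamine reward signal is delivered.
#' @param record_u Also return the PN membrane-potential traces.
#' @param orn_only Simulate the receptor layer only.
#' @param seed Noise seed (defaults to the bee's noise substream).
#' @return List with `spikes` (tibble: trial, population, neuron, time_ms),
#'   `rates` (tibble: population, neuron, evoked_hz, spont_hz), the updated
#'   `bee`, and optionally `u_pn_trace`.
#' @export
simulate_trial <- function(bee, odor = NULL, schedule = NULL,
                           plasticity = c("none", "istdp", "assoc", "both"),
                           rewarded = FALSE, record_u = FALSE,
                           orn_only = FALSE, seed = NULL) {
  plasticity <- match.arg(plasticity)
  n <- bee$connectome$n_glomeruli
  v <- if (is.null(odor)) numeric(n) else odor_vec(odor, n_ligands = n)
  out <- run_block(bee, matrix(v, nrow = 1), schedule = schedule,
                   rewarded = rewarded,
                   istdp = plasticity %in% c("istdp", "both"),
                   assoc = plasticity %in% c("assoc", "both"),
                   seed = seed, record_spikes = TRUE, record_u = record_u,
                   orn_only = orn_only)
  rates <- dplyr::bind_rows(
    tibble(population = "ORN", neuron = seq_len(n),
           evoked_hz = as.numeric(out$rates_orn[1, ]),
           spont_hz = as.numeric(out$spont_orn[1, ])),
    tibble(population = "PN", neuron = seq_len(n),
           evoked_hz = as.numeric(out$rates_pn[1, ]),
           spont_hz = as.numeric(out$spont_pn[1, ])),
    tibble(population = "LN", neuron = seq_len(n),
           evoked_hz = as.numeric(out$rates_ln[1, ]),
           spont_hz = as.numeric(out$spont_ln[1, ])),
    tibble(population = "GIN", neuron = 1L,
           evoked_hz = out$rate_gin[1], spont_hz = out$spont_gin[1]),
    tibble(population = "LHN", neuron = 1L,
           evoked_hz = out$rate_lhn[1], spont_hz = out$spont_lhn[1])
  )
  res <- list(spikes = spikes_tbl(out), rates = rates, bee = out$bee)
  if (record_u) res$u_pn_trace <- out$u_pn_trace
  res
}

#' Simulate a receptor-layer trial
#'
#' Convenience wrapper around [simulate_trial()] with `orn_only = TRUE`:
#' 1000 ms of AdEx receptor activity with the stimulus from 250 to 750 ms.
#'
#' @inheritParams simulate_trial
#' @return Tibble of ORN spikes (trial, population, neuron, time_ms).
#' @export
simulate_orn_trial <- function(bee, odor = NULL, schedule = NULL,
                               seed = NULL) {
  simulate_trial(bee, odor, schedule = schedule, orn_only = TRUE,
                 seed = seed)$spikes
}

#' Calibrate input synaptic weights to the target evoked local-neuron rate
#'
#' Scales the ORN->LN and ORN->PN weights by a common factor, iteratively,
#' until the mean evoked-minus-spontaneous LN firing rate over a sample of
#' random odours is within `tol` of `target_delta` (40 Hz by default).
#' Plasticity is off during calibration.
#'
#' @param bee A [build_bee()] object.
#' @param n_odors Number of random probe odours in the calibration sample.
#' @param target_delta Target evoked-minus-spontaneous LN rate (Hz).
#' @param tol Acceptable deviation (Hz).
#' @param max_iter Maximum scaling iterations.
#' @param seed Seed for the calibration odour sample and noise.
#' @return The bee with scaled input weights; `bee$calibration` records the
#'   factor, the achieved delta and the trace of iterates.
#' @export
calibrate_bee <- function(bee, n_odors = 20, target_delta = 40, tol = 5,
                          max_iter = 12, seed = NULL) {
  seed <- seed %||% derive_seed(bee$seed, "calibration")
  n <- bee$connectome$n_glomeruli
  odors <- odor_matrix(generate_odors(
    n_odors, n_total = n, seed = seed,
    allow_out_of_range = n < 36))
  measure <- function(b, it) {
    out <- run_block(b, odors, seed = derive_seed(seed, paste0("iter", it)))
    mean(out$rates_ln - out$spont_ln)
  }
  factor <- 1
  trace <- numeric(0)
  delta <- measure(bee, 0)
  trace <- c(trace, delta)
  it <- 0
  while (abs(delta - target_delta) > tol && it < max_iter) {
    it <- it + 1
    step <- if (delta <= 0 || target_delta <= 0) {
      if (target_delta <= 0) 0 else 2
    } else {
      min(max((target_delta / delta)^0.8, 1 / 3), 3)
    }
    factor <- factor * step
    bee$connectome$c_orn_pn <- rep(factor, n)
    bee$connectome$c_orn_ln <- rep(factor, n)
    delta <- measure(bee, it)
    trace <- c(trace, delta)
  }
  if (abs(delta - target_delta) > tol) {
    stop("calibration did not converge in ", max_iter,
         " iterations; delta trace: ",
         paste(signif(trace, 3), collapse = ", "), call. = FALSE)
  }
  bee$calibration <- list(factor = factor, achieved_delta = delta,
                          target_delta = target_delta, n_odors = n_odors,
                          trace = trace)
  bee
}
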