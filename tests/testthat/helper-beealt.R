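# Shared fixtures: built once per test run.
the <- new.env(parent = emptyenv())

fixture_bee <- function() {
  if (is.null(the$fixture)) the$fixture <- make_fixture(seed = 42)
  the$fixture
}

# Noise-free configuration for deterministic integration tests.
silent_config <- function(n_g = 2, per_type = 1, I_base = 1200, ...) {
  bee_config(
    network = list(n_glomeruli = n_g, orn_per_type = per_type,
                   sigma_pn = 0, sigma_ln = 0, sigma_gin = 0, sigma_lhn = 0,
                   ...),
    receptors = list(sigma_orn = 0, I_base = I_base)
  )
}

# Plain-R forward-Euler reference for a single AdEx neuron under constant
# current; mirrors the update order of the network integrator.
adex_reference <- function(I, p, dt, t_max, w0 = p$w_init) {
  n <- round(t_max / dt)
  v <- p$EL; w <- w0; ref <- 0
  refrac_steps <- round(p$refrac_orn / dt)
  spikes <- numeric(0)
  for (s in seq_len(n) - 1L) {
    if (ref > 0) { ref <- ref - 1; next }
    arg <- (v - p$VT) / p$DeltaT
    ex <- if (arg > -8) p$gL * p$DeltaT * exp(min(arg, 20)) else 0
    vn <- v + dt / p$C_orn * (-p$gL * (v - p$EL) + ex - w + I)
    w <- w + dt / p$tau_w * (p$a_adapt * (v - p$EL) - w)
    v <- vn
    if (v >= p$V_peak) {
      v <- p$v_reset; w <- w + p$b_adapt; ref <- refrac_steps
      spikes <- c(spikes, s * dt)
    }
  }
  spikes
}

# Poisson spike train on [0, t_max) ms at `rate` Hz.
poisson_train <- function(rate, t_max, seed) {
  withr::with_seed(seed, {
    n <- stats::rpois(1, rate * t_max / 1000)
    sort(runif(n, 0, t_max))
  })
}
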