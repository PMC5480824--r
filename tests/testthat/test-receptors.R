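test_that("affinity matrices have a preferred-ligand bijection and heavy tails", {
  for (s in 1:20) {
    aff <- sample_affinity(seed = s)
    expect_equal(dim(aff$K), c(36, 36))
    expect_equal(dim(aff$M), c(36, 36))
    expect_true(all(aff$K > 0) && all(aff$M > 0))
    argmax <- apply(aff$K, 1, which.max)
    expect_setequal(argmax, 1:36)        # unique preferred ligand per row
    expect_equal(argmax, aff$preferred)
    # few high-affinity ligands per receptor: entries above the row's 90th
    # percentile are at most 5 of 36
    above <- apply(aff$K, 1, function(k) sum(k > quantile(k, 0.9)))
    expect_true(all(above <= 5))
  }
})

test_that("Hill activation matches its closed forms and limits", {
  for (m in c(0.5, 1, 2.5)) expect_equal(hill_activation(2, m, 0.5), 0.5)
  expect_equal(hill_activation(1e6, 1.3, 0), 0)
  expect_gt(hill_activation(1e6, 1, 1e3), 1 - 1e-8)
  expect_error(hill_activation(1, 1, -0.1), "negative")
  # monotone nondecreasing in concentration over the full log range
  l <- 10^seq(-7, 0, length.out = 50)
  act <- hill_activation(1e4, 1.7, l)
  expect_true(all(diff(act) >= 0))
  expect_true(all(act >= 0 & act <= 1))
})

test_that("receptor drive averages Hill responses over the ligand space", {
  aff <- sample_affinity(seed = 2)
  # empty odour: baseline everywhere
  d0 <- orn_drive(aff, numeric(36), I_base = 870, gain = 26000)
  expect_equal(d0$drive_pA, rep(870, 36))
  # single ligand, all-ligand mean: the 35 absent ligands contribute zero
  v <- numeric(36); v[7] <- 0.01
  d1 <- orn_drive(aff, v, I_base = 870, gain = 26000)
  t7 <- aff$S[, 7] * hill_activation(aff$K[, 7], aff$M[, 7], 0.01)
  expect_equal(d1$drive_pA, 870 + 26000 * t7 / 36)
  # two ligands: drives add (hand-computed oracle), so a mixture recruits
  # the union of its components' receptor patterns
  v2 <- numeric(36); v2[7] <- 0.01; v2[20] <- 0.3
  d2 <- orn_drive(aff, v2, I_base = 870, gain = 26000)
  t20 <- aff$S[, 20] * hill_activation(aff$K[, 20], aff$M[, 20], 0.3)
  expect_equal(d2$drive_pA, 870 + 26000 * (t7 + t20) / 36)
  expect_equal(d2$drive_pA - 870, (d1$drive_pA - 870) +
                 (orn_drive(aff, {v3 <- numeric(36); v3[20] <- 0.3; v3},
                            I_base = 870, gain = 26000)$drive_pA - 870))
  # active-only mean divides by the number of present ligands instead
  da <- orn_drive(aff, v2, I_base = 870, gain = 2500, mode = "active")
  expect_equal(da$drive_pA, 870 + 2500 * (t7 + t20) / 2)
})

test_that("AdEx integration matches a plain-R reference step for step", {
  cfg <- silent_config(n_g = 2, per_type = 1)
  bee <- build_bee(1, config = cfg)
  sp <- simulate_orn_trial(bee, odor = NULL, seed = 5)
  sp1 <- sp$time_ms[sp$neuron == 1]
  expect_gt(length(sp1), 5)
  p <- bee$config$receptors
  ref <- adex_reference(p$I_base, p, dt = 0.1, t_max = 1000)
  expect_equal(sp1, ref, tolerance = 1e-10)
})

test_that("coarse-step AdEx spike times track a 10x finer integration", {
  cfg_c <- silent_config(n_g = 2, per_type = 1)
  cfg_f <- silent_config(n_g = 2, per_type = 1)
  cfg_f$network$dt <- 0.01
  spikes_at <- function(cfg) {
    bee <- build_bee(1, config = cfg)
    sp <- simulate_orn_trial(bee, odor = NULL, seed = 5)
    sp$time_ms[sp$neuron == 1]
  }
  coarse <- spikes_at(cfg_c)
  fine <- spikes_at(cfg_f)
  n <- min(length(coarse), length(fine))
  expect_gt(n, 5)
  # criterion: less than 1 ms drift per spike over a 1 s simulation
  expect_lt(max(abs(coarse[1:n] - fine[1:n])), 1 * n)
  expect_lt(abs(coarse[1] - fine[1]), 1)
})

test_that("ORN spiking is spontaneously active, odour-modulated and seed-deterministic", {
  bee <- build_bee(3)
  blank <- simulate_trial(bee, NULL, orn_only = TRUE, seed = 21)
  rates <- blank$rates[blank$rates$population == "ORN", ]
  expect_true(all(rates$spont_hz > 5))   # high spontaneous activity
  # strong preferred-ligand stimulus excites its receptor type
  pref_lig <- bee$affinity$preferred[4]
  v <- numeric(36); v[pref_lig] <- 1
  v[setdiff(seq_len(36), pref_lig)[1]] <- 1e-6
  ev <- simulate_trial(bee, v, orn_only = TRUE, seed = 21)
  r4 <- ev$rates[ev$rates$population == "ORN" & ev$rates$neuron == 4, ]
  expect_gt(r4$evoked_hz, r4$spont_hz + 10)
  # a suppressive pair drives the receptor below its spontaneous rate
  sup <- which(bee$affinity$S == -1 & bee$affinity$K > 1e5, arr.ind = TRUE)[1, ]
  v2 <- numeric(36); v2[sup["col"]] <- 1
  v2[setdiff(seq_len(36), sup["col"])[1]] <- 1e-6
  ev2 <- simulate_trial(bee, v2, orn_only = TRUE, seed = 22)
  rs <- ev2$rates[ev2$rates$population == "ORN" &
                    ev2$rates$neuron == sup["row"], ]
  expect_lt(rs$evoked_hz, rs$spont_hz)
  # identical seeds give identical spike trains
  expect_identical(simulate_orn_trial(bee, v, seed = 33),
                   simulate_orn_trial(bee, v, seed = 33))
})

test_that("evoked rate grows with concentration for an excitatory pair", {
  bee <- build_bee(5)
  type <- 9
  lig <- bee$affinity$preferred[type]
  other <- setdiff(seq_len(36), lig)[1]
  rates <- vapply(10^c(-6, -4, -2, 0), function(conc) {
    v <- numeric(36); v[lig] <- conc; v[other] <- 1e-7
    r <- numeric(10)
    for (k in 1:10) {
      tr <- simulate_trial(bee, v, orn_only = TRUE, seed = 100 + k)
      r[k] <- tr$rates$evoked_hz[tr$rates$population == "ORN" &
                                   tr$rates$neuron == type]
    }
    mean(r)
  }, numeric(1))
  expect_true(all(diff(rates) >= -2))  # nondecreasing up to trial noise
  expect_gt(rates[4], rates[1])
})
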