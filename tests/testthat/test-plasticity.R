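test_that("iSTDP pointwise updates follow the symmetric rule", {
  p <- istdp_params()
  expect_equal(p$alpha, 2 * (p$rho_0 / 1000) * p$tau_istdp)
  # no recent post spikes: pure depression by eta * alpha
  expect_equal(istdp_on_pre(10, 0, p), 10 - p$eta * p$alpha)
  # balance point: trace equal to alpha gives zero change
  expect_equal(istdp_on_pre(10, p$alpha, p), 10)
  # post-spike updates are potentiation-only
  expect_equal(istdp_on_post(10, 0, p), 10)
  for (x in c(0, 0.3, 2, 10)) expect_gte(istdp_on_post(5, x, p), 5)
  # clipping at the bounds
  expect_equal(istdp_on_pre(p$w_min, 0, p), p$w_min)
  expect_equal(istdp_on_post(p$w_max, 10, p), p$w_max)
})

test_that("STDP kernel has the two-branch exponential form", {
  p <- stdp_params()
  expect_equal(stdp_kernel(1e-9, p), p$A_plus, tolerance = 1e-6)
  expect_equal(stdp_kernel(-1e-9, p), p$A_minus, tolerance = 1e-6)
  expect_equal(stdp_kernel(0, p), 0)
  expect_equal(stdp_kernel(p$tau_plus, p), p$A_plus / exp(1))
  expect_equal(stdp_kernel(-p$tau_minus, p), p$A_minus / exp(1))
  # causal pairs potentiate, anti-causal depress (default signs)
  expect_gt(stdp_kernel(5, p), 0)
  expect_lt(stdp_kernel(-5, p), 0)
})

test_that("eligibility factor gates updates around the reward", {
  p <- stdp_params()
  expect_equal(eligibility_factor(100, 250, p), 1)
  expect_equal(eligibility_factor(250, 250, p), 1 + p$d)
  expect_equal(eligibility_factor(1e6, 250, p), 1, tolerance = 1e-8)
  # strict as-printed mode grows without bound after the reward
  expect_gt(eligibility_factor(2000, 250, p, strict = TRUE), 1e3)
  # modulated update: no reward reduces to plain STDP
  expect_equal(modulated_update(0.5, 10, 300, Inf, p),
               0.5 + stdp_kernel(10, p))
  # causal pair at the reward is amplified by (1 + d)
  expect_equal(modulated_update(0.5, 10, 250, 250, p) - 0.5,
               (1 + p$d) * stdp_kernel(10, p))
  # capacity clipping
  expect_equal(modulated_update(p$w_max, 1, 250, 250, p), p$w_max)
})

test_that("event-driven iSTDP equals the all-pairs brute force", {
  p <- istdp_params()
  for (s in 1:8) {
    pre <- poisson_train(30, 2000, seed = 100 + s)
    post <- poisson_train(25, 2000, seed = 200 + s)
    if (length(pre) < 2 || length(post) < 2) next
    a <- istdp_all_pairs(pre, post, p)
    b <- istdp_event_driven(pre, post, p)
    expect_equal(b, a, tolerance = 1e-10)
  }
  # including exactly coincident spikes (excluded from both reads)
  pre <- c(10, 20, 30, 30.5); post <- c(10, 15, 30)
  expect_equal(istdp_event_driven(pre, post, p),
               istdp_all_pairs(pre, post, p), tolerance = 1e-12)
})

test_that("iSTDP drift changes sign at the homeostatic target rate", {
  p <- istdp_params()
  drift_at <- function(post_rate) {
    d <- numeric(6)
    for (s in 1:6) {
      pre <- poisson_train(30, 20000, seed = 300 + s)
      post <- poisson_train(post_rate, 20000, seed = 400 + s)
      d[s] <- istdp_event_driven(pre, post, p)
    }
    mean(d)
  }
  expect_lt(drift_at(8), 0)    # below rho_0: net depression
  expect_gt(drift_at(35), 0)   # above rho_0: net potentiation
})

test_that("weights stay within bounds under arbitrary update sequences", {
  ip <- istdp_params(); sp <- stdp_params()
  w1 <- 10; w2 <- 0.5
  withr::with_seed(77, {
    for (k in 1:500) {
      w1 <- if (runif(1) < 0.5) istdp_on_pre(w1, runif(1, 0, 5), ip)
            else istdp_on_post(w1, runif(1, 0, 5), ip)
      w2 <- modulated_update(w2, runif(1, -50, 50), runif(1, 0, 1000),
                             sample(c(250, Inf), 1), sp)
      expect_true(w1 >= ip$w_min && w1 <= ip$w_max)
      expect_true(w2 >= sp$w_min && w2 <= sp$w_max)
    }
  })
})

test_that("in-network modulated plasticity respects structure and bounds", {
  fx <- fixture_bee()
  bee <- fx$bee
  res <- run_conditioning(bee, "absolute",
                          odors = dplyr::bind_rows(fx$odors[1, ],
                                                   fx$odors[2, ]),
                          n_training = 4, pre_test = FALSE,
                          early_stop = FALSE, seed = 5)
  conn <- res$bee$connectome
  expect_equal(diag(conn$c_ln_ln), rep(0, 6))
  expect_equal(diag(conn$c_ln_pn), rep(0, 6))
  expect_true(all(conn$c_ln_ln >= 0 & conn$c_ln_ln <= conn$wmax_ln_ln))
  expect_true(all(conn$c_pn_lhn >= 0 & conn$c_pn_lhn <= conn$wmax_pn_lhn))
  # training changed the LHN input weights
  expect_false(identical(conn$c_pn_lhn, bee$connectome$c_pn_lhn))
})

test_that("different conditioned odours reshape LN-LN connectivity differently", {
  fx <- fixture_bee()
  two <- dplyr::bind_rows(fx$odors[1, ], fx$odors[2, ])
  resX <- run_conditioning(fx$bee, "absolute", odors = two,
                           n_training = 4, pre_test = FALSE,
                           early_stop = FALSE, seed = 5)
  resY <- run_conditioning(fx$bee, "absolute",
                           odors = dplyr::bind_rows(fx$odors[2, ],
                                                    fx$odors[1, ]),
                           n_training = 4, pre_test = FALSE,
                           early_stop = FALSE, seed = 5)
  expect_false(identical(resX$bee$connectome$c_ln_ln,
                         resY$bee$connectome$c_ln_ln))
})
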