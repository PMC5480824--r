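test_that("zero exposure leaves the connectome untouched", {
  bee <- fixture_bee()$bee
  ex <- run_exposure(bee, 0, checkpoints = 0, probe = FALSE)
  expect_identical(ex$bee$connectome$c_ln_pn, bee$connectome$c_ln_pn)
})

test_that("exposure snapshots and decorrelation table line up with checkpoints", {
  bee <- fixture_bee()$bee
  ex <- run_exposure(bee, 20, checkpoints = c(0, 10, 20))
  expect_named(ex$snapshots, c("0", "10", "20"))
  expect_equal(ex$decorrelation$checkpoint, c(0, 10, 20))
  expect_identical(ex$snapshots[["0"]], bee$connectome$c_ln_pn)
  expect_identical(ex$snapshots[["20"]], ex$bee$connectome$c_ln_pn)
  expect_true(all(ex$decorrelation$multi_information >= 0))
  # weights moved during exposure
  expect_false(identical(ex$snapshots[["0"]], ex$snapshots[["20"]]))
})

test_that("conditioning phases are ordered and the test phase is frozen", {
  fx <- fixture_bee()
  res <- run_conditioning(fx$bee, "differential",
                          odors = dplyr::bind_rows(fx$odors[1, ],
                                                   fx$odors[2, ]),
                          n_training = 3, early_stop = FALSE, seed = 2)
  expect_s3_class(res, "conditioning_result")
  expect_equal(unique(res$trials$phase), c("pre", "train", "test"))
  expect_true(all(!res$trials$rewarded[res$trials$phase != "train"]))
  expect_equal(sum(res$trials$phase == "test"), 2 * 3)
  expect_equal(sort(res$test_summary$stimulus), c("A", "B"))
  # test phase does not modify weights: replaying the test block on the
  # returned bee leaves every plastic matrix bit-identical
  before <- res$bee$connectome
  out <- beealt:::run_block(res$bee, odor_matrix(fx$odors[1:2, ]),
                            seed = 99)
  expect_identical(out$bee$connectome$c_ln_pn, before$c_ln_pn)
  expect_identical(out$bee$connectome$c_ln_ln, before$c_ln_ln)
  expect_identical(out$bee$connectome$c_pn_lhn, before$c_pn_lhn)
})

test_that("patterning protocols train on the mixture with its contingencies", {
  fx <- fixture_bee()
  res <- run_conditioning(fx$bee, "positive_patterning",
                          odors = dplyr::bind_rows(fx$odors[1, ],
                                                   fx$odors[2, ]),
                          n_training = 2, early_stop = FALSE, seed = 3)
  tr <- res$trials[res$trials$phase == "train", ]
  expect_setequal(unique(tr$stimulus), c("AB", "A", "B"))
  expect_true(all(tr$rewarded[tr$stimulus == "AB"]))
  expect_true(all(!tr$rewarded[tr$stimulus != "AB"]))
  expect_setequal(res$test_summary$stimulus, c("AB", "A", "B"))
  neg <- run_conditioning(fx$bee, "negative_patterning",
                          odors = dplyr::bind_rows(fx$odors[1, ],
                                                   fx$odors[2, ]),
                          n_training = 2, early_stop = FALSE, seed = 3)
  trn <- neg$trials[neg$trials$phase == "train", ]
  expect_true(all(!trn$rewarded[trn$stimulus == "AB"]))
  expect_true(all(trn$rewarded[trn$stimulus != "AB"]))
})

test_that("generalization returns one rate per test odour with distances", {
  fx <- fixture_bee()
  res <- run_generalization(fx$bee, fx$odors[1, ], fx$odors,
                            n_training_max = 3, seed = 4)
  expect_equal(res$test_odor, fx$odors$odor)
  expect_equal(res$distance[1], 0)
  expect_true(all(res$mean_rate >= 0))
})

test_that("population experiments are reproducible and tidy", {
  cfg <- bee_config(network = list(n_glomeruli = 6, orn_per_type = 2),
                    protocol = list(n_probe_odors = 8))
  run <- function() population_experiment(
    "differential", n_bees = 3, base_seed = 9, n_exposure = 5,
    n_training = 2, config = cfg)
  a <- run(); b <- run()
  expect_equal(a$bees, b$bees)            # same cohort seed, same results
  expect_equal(nrow(a$bees), 3)
  expect_s3_class(glance(a), "tbl_df")
  expect_equal(glance(a)$n_bees, 3)
  expect_true(all(c("test_rewarded", "test_unrewarded") %in%
                    names(tidy(a))))
  ctrl <- population_experiment("differential", n_bees = 2, base_seed = 9,
                                n_exposure = 5, n_training = 2,
                                config = cfg, control = "random")
  expect_equal(ctrl$control, "random")
  expect_error(population_experiment("differential", n_bees = 1),
               "at least 2")
})

test_that("result accessors expose tidy tables and plots build", {
  fx <- fixture_bee()
  res <- run_conditioning(fx$bee, "absolute",
                          odors = dplyr::bind_rows(fx$odors[1, ],
                                                   fx$odors[2, ]),
                          n_training = 2, early_stop = FALSE, seed = 7)
  expect_identical(tidy(res), res$trials)
  g <- glance(res)
  expect_equal(nrow(g), 1)
  expect_true("test_rate_A" %in% names(g))
  p1 <- autoplot(res)
  expect_s3_class(p1, "ggplot")
  ex <- run_exposure(fx$bee, 10, checkpoints = c(0, 10))
  expect_s3_class(autoplot(ex), "ggplot")
  sp <- simulate_trial(fx$bee, fx$odors[1, ], seed = 1)$spikes
  expect_s3_class(plot_spike_raster(sp), "ggplot")
})
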