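default_checkpoints <- function(n_stimuli) {
  if (n_stimuli >= 2000) {
    cp <- c(0, 500, 1000, 2000)
  } else {
    cp <- unique(round(n_stimuli * c(0, 0.25, 0.5, 1)))
  }
  cp[cp <= n_stimuli]
}

#' Non-associative odour exposure
#'
#' Presents a sequence of random odours (one per presentation) with
#' inhibitory STDP active on the LN->PN synapses, emulating the passive
#' olfactory experience that reshapes the antennal lobe early in a bee's
#' life. The LN->PN weight matrix is snapshotted at the requested
#' checkpoints, and at each checkpoint a fixed probe set of odours is
#' presented with plasticity frozen to measure the PN population code; the
#' entropy-reduction and multi-information statistics over the probe
#' responses quantify how decorrelated the code has become.
#'
#' Exposure presentations use a shortened 600 ms trial and probes a 500 ms
#' trial, since only the stimulus-window response enters any statistic;
#' conditioning protocols use the full 1000 ms trial.
#'
#' @param bee A [build_bee()] (optionally [calibrate_bee()]d) object.
#' @param n_stimuli Number of exposure presentations (2000 reproduces the
#'   full protocol; 200 is a scaled-down preset for cohort studies).
#' @param checkpoints Presentation counts at which to snapshot weights and
#'   probe (defaults to 0/500/1000/2000 scaled to `n_stimuli`).
#' @param probe Measure probe responses at checkpoints.
#' @param probe_odors Optional matrix or odour tibble of probe stimuli;
#'   defaults to 64 random odours from the bee's probe substream.
#' @param seed Seed for stimuli and noise.
#' @return Object of class `exposure_result`: the updated `bee`, weight
#'   `snapshots`, `probe_rates` (list of stimuli x PN rate matrices) and a
#'   `decorrelation` tibble (checkpoint, er, multi_information).
#' @export
run_exposure <- function(bee, n_stimuli = 2000, checkpoints = NULL,
                         probe = TRUE, probe_odors = NULL, seed = NULL) {
  seed <- seed %||% derive_seed(bee$seed, "exposure")
  pr <- bee$config$protocol
  n <- bee$connectome$n_glomeruli
  checkpoints <- sort(unique(checkpoints %||% default_checkpoints(n_stimuli)))
  stopifnot(all(checkpoints >= 0), all(checkpoints <= n_stimuli))
  odors <- odor_matrix(generate_odors(
    max(n_stimuli, 1), n_total = n, seed = derive_seed(seed, "odors"),
    allow_out_of_range = n < 36))
  if (is.null(probe_odors)) {
    probe_odors <- odor_matrix(generate_odors(
      pr$n_probe_odors, n_total = n, seed = derive_seed(seed, "probe"),
      allow_out_of_range = n < 36))
  } else if (is.data.frame(probe_odors)) {
    probe_odors <- odor_matrix(probe_odors)
  }
  exp_sched <- trial_schedule(pr$exposure_length, pr$exposure_onset,
                              pr$exposure_offset)
  prb_sched <- trial_schedule(pr$probe_length, pr$probe_onset,
                              pr$probe_offset)

  snapshots <- list()
  probe_rates <- list()
  decor <- list()
  run_probe <- function(b, cp) {
    out <- run_block(b, probe_odors, schedule = prb_sched,
                     seed = derive_seed(seed, paste0("probe", cp)))
    probe_rates[[as.character(cp)]] <<- out$rates_pn
    stats <- entropy_reduction(out$rates_pn)
    decor[[length(decor) + 1L]] <<- tibble(
      checkpoint = cp, er = stats$er,
      multi_information = stats$multi_information)
  }
  marks <- sort(unique(c(checkpoints, n_stimuli)))
  prev <- 0
  if (0 %in% checkpoints) {
    snapshots[["0"]] <- bee$connectome$c_ln_pn
    if (probe) run_probe(bee, 0)
  }
  for (cp in marks[marks > 0]) {
    idx <- seq(prev + 1, cp)
    out <- run_block(bee, odors[idx, , drop = FALSE], schedule = exp_sched,
                     istdp = TRUE,
                     seed = derive_seed(seed, paste0("expose", cp)))
    bee <- out$bee
    prev <- cp
    if (cp %in% checkpoints) {
      snapshots[[as.character(cp)]] <- bee$connectome$c_ln_pn
      if (probe) run_probe(bee, cp)
    }
  }
  structure(list(
    bee = bee, n_stimuli = n_stimuli, checkpoints = checkpoints,
    snapshots = snapshots, probe_rates = probe_rates,
    decorrelation = dplyr::bind_rows(decor),
    gin_level = bee$gin_level, seed = seed
  ), class = "exposure_result")
}

#' @export
print.exposure_result <- function(x, ...) {
  cat("<exposure_result> ", x$n_stimuli, " stimuli, GIN ",
      format(x$gin_level), "\n", sep = "")
  if (nrow(x$decorrelation %||% tibble())) print(x$decorrelation)
  invisible(x)
}

# Contingency table for each conditioning mode: stimulus label, odour row
# index ("AB" = mixture), rewarded flag.
conditioning_plan <- function(mode) {
  switch(mode,
    absolute = list(train = tibble(stimulus = "A", rewarded = TRUE),
                    test = "A"),
    differential = list(
      train = tibble(stimulus = c("A", "B"), rewarded = c(TRUE, FALSE)),
      test = c("A", "B")),
    positive_patterning = list(
      train = tibble(stimulus = c("AB", "A", "B"),
                     rewarded = c(TRUE, FALSE, FALSE)),
      test = c("AB", "A", "B")),
    negative_patterning = list(
      train = tibble(stimulus = c("A", "B", "AB"),
                     rewarded = c(TRUE, TRUE, FALSE)),
      test = c("AB", "A", "B"))
  )
}

#' Olfactory conditioning of the proboscis-extension response
#'
#' Runs a full conditioning experiment on one bee: an unrewarded pre-test,
#' interleaved training rounds in which rewarded stimuli trigger the
#' octopamine signal (modulated STDP on the PN->LHN and LN->LN synapses,
#' active only during training), and an unrewarded test in which each test
#' stimulus is presented `n_test` times with plasticity frozen. The mean
#' lateral-horn-neuron (LHN) rate in the stimulus window is the behavioural
#' readout (proboscis-extension proxy).
#'
#' Modes: `absolute` (A+), `differential` (A+/B-), `positive_patterning`
#' (AB+/A-/B-), `negative_patterning` (A+/B+/AB-). The mixture AB is built
#' with [mix_odors()] using the configured rule.
#'
#' @param bee A bee, normally after [run_exposure()] pre-training.
#' @param mode Conditioning mode.
#' @param odors Odour tibble with at least 2 rows (A and B); defaults to
#'   two random odours from the bee's conditioning substream.
#' @param n_training Training rounds (one presentation per contingency and
#'   round), default from the config (10).
#' @param n_test Unrewarded test presentations per stimulus (default 3).
#' @param pre_test Run the unrewarded pre-test phase.
#' @param early_stop Stop training once the LHN input weights plateau (the
#'   largest per-round change of any PN->LHN weight falls below 0.5% of its
#'   capacity, checked from round 3 on).
#' @param seed Seed for trial order and noise.
#' @return Object of class `conditioning_result` with per-trial rates
#'   (`trials`), the test-phase summary (`test_summary`), and the bee.
#' @export
run_conditioning <- function(bee,
                             mode = c("differential", "absolute",
                                      "positive_patterning",
                                      "negative_patterning"),
                             odors = NULL, n_training = NULL, n_test = NULL,
                             pre_test = TRUE, early_stop = TRUE,
                             seed = NULL) {
  mode <- match.arg(mode)
  pr <- bee$config$protocol
  n <- bee$connectome$n_glomeruli
  seed <- seed %||% derive_seed(bee$seed, paste0("conditioning-", mode))
  n_training <- n_training %||% pr$n_training
  n_test <- n_test %||% pr$n_test
  if (is.null(odors)) {
    odors <- generate_odors(2, n_total = n,
                            seed = derive_seed(seed, "cs-odors"),
                            allow_out_of_range = n < 36, labels = c("A", "B"))
  }
  om <- odor_matrix(odors)
  stim_vec <- function(lab) switch(lab,
    A = om[1, ], B = om[2, ],
    AB = odor_vec(mix_odors(om[1, ], om[2, ], mode = pr$mixture_mode)))
  plan <- conditioning_plan(mode)
  trials <- list()

  present <- function(b, labels, rewarded, phase, assoc, round = NA,
                      block_seed) {
    m <- do.call(rbind, lapply(labels, stim_vec))
    out <- run_block(b, m, rewarded = rewarded, assoc = assoc,
                     seed = block_seed)
    trials[[length(trials) + 1L]] <<- tibble(
      phase = phase, round = round, stimulus = labels, rewarded = rewarded,
      lhn_rate = as.numeric(out$rate_lhn),
      lhn_spont = as.numeric(out$spont_lhn))
    out$bee
  }

  if (pre_test) {
    labs <- withr::with_seed(derive_seed(seed, "pre-order"),
                             sample(rep(plan$test, n_test)))
    bee <- present(bee, labs, rep(FALSE, length(labs)), "pre", FALSE,
                   block_seed = derive_seed(seed, "pre"))
  }
  for (r in seq_len(n_training)) {
    ord <- withr::with_seed(derive_seed(seed, paste0("order", r)),
                            sample(nrow(plan$train)))
    w_before <- bee$connectome$c_pn_lhn
    bee <- present(bee, plan$train$stimulus[ord], plan$train$rewarded[ord],
                   "train", plan$train$rewarded[ord], round = r,
                   block_seed = derive_seed(seed, paste0("train", r)))
    if (early_stop && r >= 3 &&
        max(abs(bee$connectome$c_pn_lhn - w_before)) <
          0.005 * bee$connectome$wmax_pn_lhn) {
      break
    }
  }
  labs <- withr::with_seed(derive_seed(seed, "test-order"),
                           sample(rep(plan$test, n_test)))
  bee <- present(bee, labs, rep(FALSE, length(labs)), "test", FALSE,
                 block_seed = derive_seed(seed, "test"))

  trials <- dplyr::bind_rows(trials)
  test_summary <- trials |>
    dplyr::filter(.data$phase == "test") |>
    dplyr::group_by(.data$stimulus) |>
    dplyr::summarise(mean_rate = mean(.data$lhn_rate), .groups = "drop")
  structure(list(mode = mode, odors = odors, trials = trials,
                 test_summary = test_summary, bee = bee, seed = seed),
            class = "conditioning_result")
}

#' @export
print.conditioning_result <- function(x, ...) {
  cat("<conditioning_result> mode ", x$mode, ", ",
      sum(x$trials$phase == "train"), " training trials\n", sep = "")
  print(x$test_summary)
  invisible(x)
}

#' Generalization from a conditioned odour to novel stimuli
#'
#' Trains the bee with absolute conditioning on `cs` until the LHN response
#' plateaus, then presents every odour of `test_set` unrewarded; the LHN
#' test rate as a function of odour similarity to the CS measures
#' generalization.
#'
#' @param bee A bee (normally exposure pre-trained).
#' @param cs The conditioned odour (one-row tibble or vector).
#' @param test_set Odour tibble of test stimuli (may include the CS).
#' @param n_training_max Maximum training rounds before testing.
#' @param n_test Test presentations per odour.
#' @param seed Seed.
#' @return Tibble with `cs`, `test_odor`, `mean_rate`, `distance`
#'   (Euclidean odour distance to the CS); attribute `bee` holds the
#'   trained bee.
#' @export
run_generalization <- function(bee, cs, test_set, n_training_max = 20,
                               n_test = NULL, seed = NULL) {
  seed <- seed %||% derive_seed(bee$seed, "generalization")
  n <- bee$connectome$n_glomeruli
  n_test <- n_test %||% bee$config$protocol$n_test
  cs_v <- odor_vec(cs, n_ligands = n)
  cs_lab <- odor_label(cs, "CS")
  cond <- run_conditioning(
    bee, "absolute",
    odors = dplyr::bind_rows(odor_tbl(cs_v, cs_lab),
                             odor_tbl(numeric(n), "blank")),
    n_training = n_training_max, n_test = 1, pre_test = FALSE,
    early_stop = TRUE, seed = derive_seed(seed, "train"))
  bee <- cond$bee
  tm <- odor_matrix(test_set)
  labs <- rep(test_set$odor, n_test)
  idx <- rep(seq_len(nrow(tm)), n_test)
  ord <- withr::with_seed(derive_seed(seed, "order"), sample(length(idx)))
  out <- run_block(bee, tm[idx[ord], , drop = FALSE],
                   seed = derive_seed(seed, "test"))
  res <- tibble(cs = cs_lab, test_odor = labs[ord],
                lhn_rate = as.numeric(out$rate_lhn)) |>
    dplyr::group_by(.data$cs, .data$test_odor) |>
    dplyr::summarise(mean_rate = mean(.data$lhn_rate), .groups = "drop")
  res$distance <- unname(vapply(res$test_odor, function(l)
    odor_distance(cs_v, tm[match(l, test_set$odor), ]), numeric(1)))
  attr(res, "bee") <- bee
  res[match(test_set$odor, res$test_odor), ]
}

#' Generalization matrix over a panel of odours
#'
#' For each odour `i` of the panel, a copy of the given bee is conditioned
#' on odour `i` (absolute conditioning to plateau) and tested on every
#' odour `j`; entry `K[i, j]` is the mean LHN test rate. Because the
#' reward-modulated LN->LN plasticity reshapes the antennal lobe
#' differently for different conditioned odours, the matrix is generally
#' asymmetric.
#'
#' @param bee A bee (normally exposure pre-trained); each row of the matrix
#'   starts from an identical copy.
#' @param odors Odour tibble (default: 6 random odours from the bee's
#'   generalization substream).
#' @param seed Seed.
#' @param ... Passed to [run_generalization()] (e.g. `n_training_max`).
#' @return Object of class `generalization_result` with the rate matrix
#'   `K`, the odour panel, and a tidy tibble.
#' @export
generalization_matrix <- function(bee, odors = NULL, seed = NULL, ...) {
  seed <- seed %||% derive_seed(bee$seed, "generalization-matrix")
  n <- bee$connectome$n_glomeruli
  if (is.null(odors)) {
    odors <- generate_odors(6, n_total = n,
                            seed = derive_seed(seed, "panel"),
                            allow_out_of_range = n < 36)
  }
  rows <- lapply(seq_len(nrow(odors)), function(i) {
    run_generalization(bee, odors[i, ], odors, ...,
                       seed = derive_seed(seed, paste0("row", i)))
  })
  tidy_tbl <- dplyr::bind_rows(rows)
  K <- matrix(tidy_tbl$mean_rate, nrow(odors), nrow(odors), byrow = TRUE,
              dimnames = list(trained = odors$odor, tested = odors$odor))
  structure(list(K = K, odors = odors, rates = tidy_tbl, seed = seed),
            class = "generalization_result")
}

#' @export
print.generalization_result <- function(x, ...) {
  cat("<generalization_result> ", nrow(x$K), " x ", ncol(x$K),
      " LHN rate matrix (trained x tested)\n", sep = "")
  print(round(x$K, 1))
  invisible(x)
}

#' Replicated conditioning across a population of simulated bees
#'
#' Repeats a conditioning experiment over `n_bees` independent individuals
#' (fresh affinity matrix, initial connectome, odours and noise per bee;
#' model constants unchanged), each pre-trained by non-associative exposure
#' unless `control = "random"`, which freezes the LN->PN connectivity at
#' its random initialisation (no exposure) to test the contribution of the
#' structured antennal-lobe connectivity. Reports per-bee rewarded and
#' unrewarded test rates and a paired t-test across bees.
#'
#' For patterning modes the rewarded/unrewarded comparison is the mixture
#' AB versus the mean of the single components (positive patterning), or
#' the components versus the mixture (negative patterning).
#'
#' @param mode Conditioning mode (see [run_conditioning()]).
#' @param n_bees Number of simulated bees (>= 2).
#' @param base_seed Cohort seed; every bee derives its own substream.
#' @param n_exposure Pre-training exposure length per bee (scaled-down
#'   default 200; ignored for the random-connectivity control).
#' @param n_training Training rounds per bee.
#' @param config Shared [bee_config()].
#' @param gin GIN level for every bee.
#' @param control `"trained"` (default) or `"random"` connectivity.
#' @param prebuilt_bees Optional list of `n_bees` already-built (typically
#'   exposure-pre-trained) bees; lets several conditioning cohorts share one
#'   exposure pass.
#' @param pre_test Run the unrewarded pre-test phase for every bee (needed
#'   for naive-exchangeability statistics; can be skipped when only test
#'   rates are analysed).
#' @param progress Print one line per bee.
#' @return Object of class `cohort_result`: per-bee tibble `bees`, paired
#'   test-phase `test` statistics, paired pre-test `pre` statistics.
#' @export
population_experiment <- function(mode = c("differential", "absolute",
                                           "positive_patterning",
                                           "negative_patterning"),
                                  n_bees = 50, base_seed = 1,
                                  n_exposure = 200, n_training = NULL,
                                  config = bee_config(), gin = "strong",
                                  control = c("trained", "random"),
                                  prebuilt_bees = NULL, pre_test = TRUE,
                                  progress = FALSE) {
  mode <- match.arg(mode)
  control <- match.arg(control)
  if (n_bees < 2) stop("n_bees must be at least 2", call. = FALSE)
  rate_of <- function(tbl, phase, labs) {
    x <- dplyr::filter(tbl, .data$phase == !!phase,
                       .data$stimulus %in% labs)
    mean(x$lhn_rate)
  }
  plus_labs <- switch(mode,
    differential = "A", absolute = "A",
    positive_patterning = "AB", negative_patterning = c("A", "B"))
  minus_labs <- switch(mode,
    differential = "B", absolute = "B",
    positive_patterning = c("A", "B"), negative_patterning = "AB")
  rows <- lapply(seq_len(n_bees), function(b) {
    seed_b <- derive_seed(base_seed, paste0("bee", b))
    if (!is.null(prebuilt_bees)) {
      bee <- prebuilt_bees[[b]]
      seed_b <- bee$seed
    } else {
      bee <- build_bee(seed_b, config = config, gin = gin)
      if (control == "trained" && n_exposure > 0) {
        bee <- run_exposure(bee, n_exposure, checkpoints = n_exposure,
                            probe = FALSE)$bee
      }
    }
    cond <- run_conditioning(bee, mode, n_training = n_training,
                             pre_test = pre_test)
    if (progress) {
      cat("bee", b, "/", n_bees, "done\n")
    }
    tibble(
      bee = b, seed = seed_b,
      pre_rewarded = rate_of(cond$trials, "pre", plus_labs),
      pre_unrewarded = rate_of(cond$trials, "pre", minus_labs),
      test_rewarded = rate_of(cond$trials, "test", plus_labs),
      test_unrewarded = rate_of(cond$trials, "test", minus_labs),
      n_train_rounds = max(cond$trials$round, na.rm = TRUE)
    )
  })
  bees <- dplyr::bind_rows(rows)
  structure(list(
    mode = mode, control = control, n_bees = n_bees, base_seed = base_seed,
    bees = bees,
    test = cohort_ttest(bees$test_rewarded, bees$test_unrewarded,
                        paired = TRUE),
    pre = cohort_ttest(bees$pre_rewarded, bees$pre_unrewarded,
                       paired = TRUE)
  ), class = "cohort_result")
}

#' @export
print.cohort_result <- function(x, ...) {
  cat("<cohort_result> ", x$mode, " (", x$control, " connectivity), n = ",
      x$n_bees, " bees\n  test (rewarded vs unrewarded): t = ",
      signif(x$test$t, 4), ", p = ", format(x$test$p_value, digits = 3),
      ", d = ", signif(x$test$effect_size, 3), "\n", sep = "")
  invisible(x)
}
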