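#' Sample a receptor affinity matrix
#'
#' Each of the `n` olfactory receptor neuron (ORN) types is characterised by a
#' row of binding affinities `K` (inverse concentration) and Hill exponents
#' `M` over the `n`-ligand space. Affinities are heavy-tailed (each receptor
#' has high affinity for only a few ligands) and every receptor has a unique
#' preferred ligand: the per-row argmax ligands form a permutation of the
#' ligand set. A sign matrix `S` marks a fraction of receptor-ligand pairs as
#' suppressive (-1): those ligands push the receptor below its spontaneous
#' rate, giving the below-baseline responses seen in real dose-response
#' curves. The matrix is sampled once per simulated bee and then fixed.
#'
#' @param seed Optional integer seed.
#' @param n Number of receptor types = number of ligands (default 36).
#' @param hill_range Range of the Hill exponent (dimensionless).
#' @param suppressive_frac Fraction of non-preferred receptor-ligand pairs
#'   with suppressive sign; 0 disables the sign matrix (strict Hill mode).
#' @param affinity_decades Log10 span of affinities; affinities lie in
#'   \[1, 10^affinity_decades\].
#' @param tail_shape Exponent shaping the affinity tail; larger values give
#'   fewer high-affinity ligands per receptor.
#' @return Object of class `bee_affinity`: list with matrices `K`, `M`, `S`
#'   and the preferred-ligand permutation `preferred`.
#' @export
sample_affinity <- function(seed = NULL, n = 36, hill_range = c(0.5, 2.5),
                            suppressive_frac = 0.25, affinity_decades = 7,
                            tail_shape = 3) {
  draw <- function() {
    # heavy tail: most ligand affinities low, a few high per receptor
    u <- matrix(runif(n * n), n, n)
    K <- 10^(0.93 * affinity_decades * u^tail_shape)
    preferred <- sample.int(n)
    for (i in seq_len(n)) {
      K[i, preferred[i]] <- 10^(affinity_decades * (0.95 + 0.05 * runif(1)))
    }
    M <- matrix(runif(n * n, hill_range[1], hill_range[2]), n, n)
    S <- matrix(ifelse(runif(n * n) < suppressive_frac, -1, 1), n, n)
    for (i in seq_len(n)) S[i, preferred[i]] <- 1
    list(K = K, M = M, S = S, preferred = preferred)
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  structure(c(out, list(seed = seed)), class = "bee_affinity")
}

#' @export
print.bee_affinity <- function(x, ...) {
  cat("<bee_affinity> ", nrow(x$K), " receptor types x ", ncol(x$K),
      " ligands; ", sum(x$S < 0), " suppressive pairs\n", sep = "")
  invisible(x)
}

#' Hill dose-response activation
#'
#' Fractional receptor activation for affinity `K`, Hill exponent `m` and
#' ligand concentration `l`: `1 / (1 + (K * l)^(-m))`. Zero concentration
#' gives zero activation (the limit); activation saturates at 1 for large
#' `K * l` and equals 1/2 exactly at `K * l = 1`.
#'
#' @param K Binding affinity (inverse concentration), positive.
#' @param m Hill exponent, positive.
#' @param l Ligand concentration, non-negative.
#' @return Activation in \[0, 1\]; arguments recycle like [pmin()].
#' @export
hill_activation <- function(K, m, l) {
  if (any(l < 0)) stop("negative ligand concentration", call. = FALSE)
  out <- 1 / (1 + (K * l)^(-m))
  out[l == 0] <- 0
  out
}

# Drive vector (pA) across receptor types for one odour: baseline plus
# gain times the signed mean Hill activation over the stimulus's active
# ligands (or all ligands in "all" mode).
orn_drive_vec <- function(affinity, odor, I_base, gain,
                          mode = c("all", "active")) {
  mode <- match.arg(mode)
  v <- odor_vec(odor, n_ligands = ncol(affinity$K))
  active <- which(v > 0)
  if (length(active) == 0L) {
    return(rep(I_base, nrow(affinity$K)))
  }
  idx <- if (mode == "active") active else seq_along(v)
  act <- affinity$S[, idx, drop = FALSE] *
    hill_activation(affinity$K[, idx, drop = FALSE],
                    affinity$M[, idx, drop = FALSE],
                    rep(v[idx], each = nrow(affinity$K)))
  I_base + gain * rowMeans(act)
}

#' Receptor input current for an odour
#'
#' Maps an odour to the input current of each receptor type: baseline current
#' plus gain times the mean signed Hill activation over the ligands present
#' in the stimulus. An empty odour yields the baseline for every type. The
#' current is shared by all ORNs of a type.
#'
#' @param affinity A [sample_affinity()] object.
#' @param odor An odour (one-row tibble or concentration vector).
#' @param I_base Baseline current (pA) sustaining spontaneous activity.
#' @param gain Stimulus gain (pA at full activation).
#' @param mode `"all"` (default) averages the Hill responses over the whole
#'   ligand space (inactive ligands contribute zero, so mixtures add);
#'   `"active"` averages over the ligands present in the stimulus only.
#' @return Tibble with `receptor` and `drive_pA`.
#' @export
orn_drive <- function(affinity, odor, I_base = 870, gain = 26000,
                      mode = c("all", "active")) {
  d <- orn_drive_vec(affinity, odor, I_base, gain, match.arg(mode))
  tibble(receptor = seq_along(d), drive_pA = d)
}
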