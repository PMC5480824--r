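#' Generate synthetic odour stimuli
#'
#' An odour is a vector of ligand concentrations (dilution fractions) over a
#' fixed ligand space. A single odour activates 2 to 5 ligands; the number of
#' active ligands is drawn uniformly from \{2, ..., 5\} unless fixed, and each
#' active concentration is drawn log-uniformly over \[1e-7, 1\] so that all
#' concentration decades are represented. Inactive ligands are exactly zero.
#'
#' @param n Number of odours to generate.
#' @param n_ligands Number of active ligands per odour (2 to 5), or `NULL` to
#'   draw uniformly from 2:5. Values outside 2:5 require
#'   `allow_out_of_range = TRUE`.
#' @param n_total Dimension of the ligand space (default 36).
#' @param concentration Sampling law for active concentrations:
#'   `"log-uniform"` (default) over \[1e-7, 1\] or `"uniform"` over the same
#'   interval.
#' @param seed Optional integer seed; generation is reproducible given a seed.
#' @param allow_out_of_range Permit `n_ligands` outside 2:5 (used for test
#'   fixtures in reduced ligand spaces).
#' @param labels Optional character vector of odour labels.
#'
#' @return A tibble with one row per odour: column `odor` (label) and
#'   columns `l01` ... (one per ligand) holding concentrations in \[0, 1\].
#' @examples
#' odors <- generate_odors(3, seed = 1)
#' rowSums(odors[, -1] > 0) # 2 to 5 active ligands each
#' @export
generate_odors <- function(n = 1, n_ligands = NULL, n_total = 36,
                           concentration = c("log-uniform", "uniform"),
                           seed = NULL, allow_out_of_range = FALSE,
                           labels = NULL) {
  concentration <- match.arg(concentration)
  if (!is.null(n_ligands)) {
    if (any(n_ligands < 2 | n_ligands > 5) && !allow_out_of_range) {
      stop("n_ligands must be between 2 and 5 (set allow_out_of_range = TRUE ",
           "to override)", call. = FALSE)
    }
    if (any(n_ligands > n_total)) {
      stop("n_ligands cannot exceed n_total = ", n_total, call. = FALSE)
    }
  }
  gen <- function() {
    k_max <- min(5L, n_total)
    k <- if (is.null(n_ligands)) sample(2:k_max, 1L) else
      n_ligands[[1L]]
    idx <- sample.int(n_total, k)
    conc <- switch(concentration,
      "log-uniform" = 10^runif(k, -7, 0),
      "uniform" = runif(k, 1e-7, 1)
    )
    v <- numeric(n_total)
    v[idx] <- conc
    v
  }
  draw <- function() {
    m <- matrix(0, n, n_total)
    for (i in seq_len(n)) m[i, ] <- gen()
    m
  }
  m <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  labels <- labels %||% sprintf("odor_%03d", seq_len(n))
  out <- as_tibble(m, .name_repair = ~ ligand_cols(n_total))
  dplyr::bind_cols(tibble(odor = labels), out)
}

#' Mix two odours into a compound stimulus
#'
#' Compound stimuli (e.g. the mixture AB of a patterning task) are formed
#' elementwise: `"sum-clip"` adds the two concentration vectors and clips at 1
#' (superposition of dilutions, the default), `"max"` takes the elementwise
#' maximum. Labels are concatenated.
#'
#' @param a,b Odours: one-row tibbles from [generate_odors()] or bare
#'   concentration vectors of equal length.
#' @param mode Mixing rule, `"sum-clip"` or `"max"`.
#' @return A one-row odour tibble.
#' @export
mix_odors <- function(a, b, mode = c("sum-clip", "max")) {
  mode <- match.arg(mode)
  va <- odor_vec(a)
  vb <- odor_vec(b, n_ligands = length(va))
  v <- switch(mode, "sum-clip" = pmin(va + vb, 1), "max" = pmax(va, vb))
  odor_tbl(v, paste0(odor_label(a, "A"), "+", odor_label(b, "B")))
}

#' Euclidean distance between two odours
#'
#' Physical odour similarity is defined as the Euclidean distance between
#' concentration vectors.
#'
#' @inheritParams mix_odors
#' @return Non-negative scalar.
#' @export
odor_distance <- function(a, b) {
  va <- odor_vec(a)
  vb <- odor_vec(b, n_ligands = length(va))
  sqrt(sum((va - vb)^2))
}

#' Extract the concentration matrix from an odour tibble
#'
#' @param odors Tibble from [generate_odors()].
#' @return Numeric matrix, one row per odour, with odour labels as rownames.
#' @export
odor_matrix <- function(odors) {
  m <- as.matrix(odors[, grep("^l[0-9]+$", names(odors)), drop = FALSE])
  rownames(m) <- odors$odor
  dimnames(m)[[2]] <- NULL
  m
}
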