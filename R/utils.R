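# Internal helpers: seed substreams and odour coercion.

# Derive a named substream seed from a base seed so that draws for one
# component (odours, affinity, connectome, membrane noise) cannot shift
# another's. FNV-style string hash folded into [1, 2^31 - 2]; deterministic
# across platforms, not cryptographic.
derive_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- 2166136261
  for (cp in utf8ToInt(paste0(name, ":", format(seed, scientific = FALSE)))) {
    h <- (h * 16777619 + cp) %% 2147483647
  }
  as.integer(max(1, h))
}

# Accept a single odour as a bare numeric vector, a one-row odour tibble, or
# a one-row data frame slice, and return the plain concentration vector.
odor_vec <- function(x, n_ligands = NULL) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) {
      stop("expected a single odour (one row), got ", nrow(x), " rows",
           call. = FALSE)
    }
    v <- as.numeric(x[, grep("^l[0-9]+$", names(x)), drop = TRUE])
  } else if (is.numeric(x)) {
    v <- as.numeric(x)
  } else {
    stop("cannot interpret object of class '", class(x)[1], "' as an odour",
         call. = FALSE)
  }
  if (!is.null(n_ligands) && length(v) != n_ligands) {
    stop("odour has ", length(v), " ligand entries; expected ", n_ligands,
         call. = FALSE)
  }
  v
}

odor_label <- function(x, default = "odor") {
  if (is.data.frame(x) && "odor" %in% names(x)) as.character(x$odor[1]) else default
}

ligand_cols <- function(n) sprintf("l%02d", seq_len(n))

# One-row odour tibble from a concentration vector.
odor_tbl <- function(v, label) {
  out <- as_tibble(as.list(setNames(v, ligand_cols(length(v)))))
  dplyr::bind_cols(tibble(odor = label), out)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
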