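# Internal helpers shared across modules.

# Derive a stream of child seeds from one master seed, reproducibly and
# independently of the caller's RNG state. Kept below 2^31 - 1.
derive_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1L)
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
  } else {
    NULL
  }
}

restore_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
  invisible(NULL)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  old <- get_rng_state()
  on.exit(restore_rng_state(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}

# Lower-triangle (i < j) entries of a square symmetric matrix as a long tibble.
dist_to_pairs <- function(m, value_name = "value") {
  stopifnot(is.matrix(m), nrow(m) == ncol(m))
  ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
  idx <- which(lower.tri(m), arr.ind = TRUE)
  out <- tibble::tibble(
    sample_i = ids[idx[, "col"]],
    sample_j = ids[idx[, "row"]],
    value = m[idx]
  )
  names(out)[3] <- value_name
  out
}

# Inverse of dist_to_pairs for a known id ordering.
pairs_to_dist <- function(pairs, ids, value_col) {
  m <- matrix(NA_real_, length(ids), length(ids), dimnames = list(ids, ids))
  ii <- match(pairs$sample_i, ids)
  jj <- match(pairs$sample_j, ids)
  if (anyNA(ii) || anyNA(jj)) {
    rlang::abort("pair table contains sample ids absent from `ids`.")
  }
  vals <- pairs[[value_col]]
  m[cbind(ii, jj)] <- vals
  m[cbind(jj, ii)] <- vals
  diag(m) <- 0
  m
}

# Column-wise minima of a matrix restricted to the columns `cols`, returned
# per row; fast path used by the betaMNTD engine.
row_mins <- function(m, cols) {
  if (length(cols) == 1L) return(m[, cols])
  do.call(pmin, lapply(cols, function(j) m[, j]))
}

is_whole_number <- function(x, tol = 1e-8) {
  is.numeric(x) & is.finite(x) & abs(x - round(x)) < tol
}

`%||%` <- rlang::`%||%`
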