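`%||%` <- function(x, y) if (is.null(x)) y else x

stop_gwablup <- function(msg, ..., class = "gwablup_error") {
  rlang::abort(paste0(sprintf(msg, ...)), class = class)
}

assert_symmetric <- function(S, name = deparse(substitute(S)), tol = 1e-8) {
  if (!is.matrix(S) || nrow(S) != ncol(S)) {
    stop_gwablup("`%s` must be a square matrix", name)
  }
  if (max(abs(S - t(S))) > tol * max(1, max(abs(S)))) {
    stop_gwablup("`%s` must be symmetric", name)
  }
  invisible(S)
}

# coerce a phenotype block (tibble or matrix) to a plain numeric matrix
as_trait_matrix <- function(x, trait_names = NULL) {
  if (is.data.frame(x)) {
    if (!is.null(trait_names)) x <- x[, trait_names, drop = FALSE]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

# multiply each of n stacked TxT blocks (rows of `blocks`, flattened
# column-major to length T^2) with the matching rows of an n x T matrix
apply_block_rows <- function(blocks, V) {
  T <- ncol(V)
  out <- matrix(0, nrow(V), T)
  for (t in seq_len(T)) {
    for (s in seq_len(T)) {
      # element (t, s) of block i sits at column (s - 1) * T + t
      out[, t] <- out[, t] + blocks[, (s - 1L) * T + t] * V[, s]
    }
  }
  out
}
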