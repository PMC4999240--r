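# shared memo for expensive enumerations so independent test files can
# reuse them within one run
.nc_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.nc_cache[[key]])) .nc_cache[[key]] <- force(expr)
  .nc_cache[[key]]
}

seq_bfs <- function(n, reduced = FALSE) {
  cached(sprintf("seqbfs_%d_%d", n, reduced),
         bfs_reachable(seq_spec(n, reduced = reduced), words = FALSE))
}

# direct 2x2-pattern scan; independent oracle for the nestedness-based
# is_lonesum implementation
scan_lonesum <- function(A) {
  n <- nrow(A); m <- ncol(A)
  if (n < 2 || m < 2) return(TRUE)
  for (i1 in 1:(n - 1)) for (i2 in (i1 + 1):n)
    for (j1 in 1:(m - 1)) for (j2 in (j1 + 1):m) {
      v <- c(A[i1, j1], A[i1, j2], A[i2, j1], A[i2, j2])
      if (all(v == c(1, 0, 0, 1)) || all(v == c(0, 1, 1, 0))) return(FALSE)
    }
  TRUE
}

all_binary <- function(n, m) {
  lapply(0:(2^(n * m) - 1), function(code)
    matrix(as.integer(intToBits(code)[seq_len(n * m)]), n, m))
}
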