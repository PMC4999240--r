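#' Brute-force minimal-sequence census of a ratchet network
#'
#' Independent oracle for the minimal-sequence recursion
#' ([minimal_sequence_count()]).  At connectivity `l_n = l_m = 1` and
#' threshold 1 the reachable configurations are the lonesum matrices, each
#' with a canonical staircase word.  For higher connectivity, words that use
#' too many distinct regulators become redundant: any generating word for a
#' configuration `A` must use at least one K per nonzero row (only `K_i`
#' writes 1's into row `i`) and one P per column holding a 0 in some nonzero
#' row (only `P_j` can clear such an entry after its row's K has fired), and
#' the staircase word attains both minima.  A configuration therefore
#' survives at `(l_n, l_m)` precisely when its minimal K-count is at most
#' `n - l_n + 1` and its minimal P-count at most `m - l_m`.
#'
#' @param spec a threshold-1 [ratchet_spec()]; the census is run on its
#'   `(n, m)` at `l = 1` and filtered by the spec's `(l_n, l_m)`.
#' @param max_states capacity cap for the underlying BFS.
#' @return An object of class `minseq_set`: list with `configs` (surviving
#'   configurations, one per row), `words` (canonical staircase word per
#'   configuration), `k_used`/`p_used` (the per-configuration minima) and
#'   `count`.
#' @export
#' @examples
#' minimal_sequences_bruteforce(ratchet_spec(2, 2))$count       # 14
#' minimal_sequences_bruteforce(ratchet_spec(3, 3, 2, 2))$count # 43
minimal_sequences_bruteforce <- function(spec, max_states = 1e7) {
  stopifnot(inherits(spec, "ratchet_spec"))
  if (spec$T != 1) stop("the minimal-sequence census is defined at threshold T = 1")
  base <- ratchet_spec(spec$n, spec$m, 1, 1, 1)
  rs <- bfs_reachable(base, max_states = max_states, words = FALSE)
  n <- spec$n; m <- spec$m
  kcap <- n - spec$l_n + 1L
  pcap <- m - spec$l_m

  nconf <- nrow(rs$configs)
  k_used <- integer(nconf); p_used <- integer(nconf)
  for (r in seq_len(nconf)) {
    A <- matrix(rs$configs[r, ], n, m, byrow = TRUE)
    nz <- which(rowSums(A) > 0)
    k_used[r] <- length(nz)
    p_used[r] <- if (length(nz) == 0) 0L else
      sum(apply(A[nz, , drop = FALSE] == 0, 2, any))
  }
  keep <- k_used <= kcap & p_used <= pcap
  configs <- rs$configs[keep, , drop = FALSE]
  words <- vapply(seq_len(nrow(configs)), function(r)
    format_word(staircase_word(matrix(configs[r, ], n, m, byrow = TRUE))),
    character(1))
  structure(list(
    spec = spec,
    configs = configs, words = words,
    k_used = k_used[keep], p_used = p_used[keep],
    count = sum(keep)
  ), class = "minseq_set")
}

#' @export
print.minseq_set <- function(x, ...) {
  cat(sprintf("minimal-sequence census: %d configurations for (n=%d, m=%d, l_n=%d, l_m=%d)\n",
              x$count, x$spec$n, x$spec$m, x$spec$l_n, x$spec$l_m))
  invisible(x)
}
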