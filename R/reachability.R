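#' Breadth-first reachability enumeration
#'
#' Enumerates the closure of a start configuration under a set of regulator
#' actions.  The search is exact and deterministic: configurations are
#' encoded in canonical target order and explored in breadth-first layers,
#' so the discovery order (and every derived output) is reproducible
#' bit-for-bit.
#'
#' @param spec a [ratchet_spec()] or [seq_spec()].
#' @param start start configuration; defaults to all-zero.
#' @param alphabet action tokens to close under; defaults to the full
#'   alphabet.  An empty alphabet yields just the start configuration.
#' @param max_states capacity cap on the number of enumerated
#'   configurations; exceeding it raises an error rather than continuing.
#' @param words if `TRUE` (default), record one shortest witness word per
#'   configuration.
#'
#' @return An object of class `reachable_set`: a list with `configs` (one
#'   configuration per row, discovery order; row 1 is the start), `depth`
#'   (BFS layer of each row), `words` (witness words, if requested), and the
#'   `spec`/`alphabet` used.
#' @export
#' @examples
#' rs <- bfs_reachable(ratchet_spec(2, 2))
#' nrow(rs$configs)        # 14 = poly_bernoulli(2, 2)
bfs_reachable <- function(spec, start = zero_config(spec),
                          alphabet = full_alphabet(spec),
                          max_states = 1e7, words = TRUE) {
  stopifnot(length(start) == spec$N)
  acts <- lapply(alphabet, parse_action)

  # mixed-radix encoding: exact doubles (all spaces in scope are << 2^53)
  base <- if (inherits(spec, "ratchet_spec")) spec$T + 1 else spec$n + 1
  pow <- base^(seq_len(spec$N) - 1)
  enc <- function(M) as.vector(M %*% pow)

  configs <- matrix(as.integer(start), 1, spec$N)
  keys <- enc(configs)
  depth <- 0L
  parent <- 0L      # 0 = start
  act_used <- 0L    # index into alphabet
  frontier <- configs
  frontier_rows <- 1L
  d <- 0L
  while (nrow(frontier) > 0 && length(acts) > 0) {
    d <- d + 1L
    imgs <- vector("list", length(acts))
    for (ai in seq_along(acts)) {
      imgs[[ai]] <- apply_action_matrix(spec, frontier, acts[[ai]]$kind, acts[[ai]]$index)
    }
    allm <- do.call(rbind, imgs)
    allkeys <- enc(allm)
    src <- rep(frontier_rows, times = length(acts))
    via <- rep(seq_along(acts), each = nrow(frontier))
    keep <- !duplicated(allkeys) & !(allkeys %in% keys)
    if (!any(keep)) break
    newm <- allm[keep, , drop = FALSE]
    if (nrow(configs) + nrow(newm) > max_states)
      stop("reachable set exceeds capacity cap (", max_states, " states)")
    nstart <- nrow(configs)
    configs <- rbind(configs, newm)
    keys <- c(keys, allkeys[keep])
    depth <- c(depth, rep(d, nrow(newm)))
    parent <- c(parent, src[keep])
    act_used <- c(act_used, via[keep])
    frontier <- newm
    frontier_rows <- nstart + seq_len(nrow(newm))
  }

  wlist <- NULL
  if (words) {
    wlist <- character(nrow(configs))
    for (r in seq_len(nrow(configs))) {
      toks <- character(depth[r])
      cur <- r
      s <- depth[r]
      while (cur != 1L) {
        toks[s] <- alphabet[act_used[cur]]
        s <- s - 1L
        cur <- parent[cur]
      }
      wlist[r] <- paste(toks, collapse = " ")
    }
  }

  structure(list(
    spec = spec, alphabet = alphabet,
    configs = configs, keys = keys, depth = depth, words = wlist
  ), class = "reachable_set")
}

#' @export
print.reachable_set <- function(x, ...) {
  cat(sprintf("reachable set: %d configurations (alphabet: %s)\n",
              nrow(x$configs), paste(x$alphabet, collapse = " ")))
  invisible(x)
}

#' Number of configurations in a reachable set
#' @param rs a `reachable_set`.
#' @return Integer count (the start configuration is included).
#' @export
reach_count <- function(rs) nrow(rs$configs)
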