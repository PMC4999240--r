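#' Connectivity test for sequestration configurations
#'
#' A configuration is *connected* when every target with three or more arms
#' that sits in a nonzero state `s` is supported by a 2-arm target: some
#' 2-arm target of the spec whose arms are contained in the big target's
#' arms, containing `s`, must also be in state `s`.  Connectivity
#' characterises reachability: the reachable one-colorings of the reduced
#' network are exactly the connected ones.
#'
#' @param x integer state vector (a full configuration), or a 0/1 coloring
#'   vector (interpreted as a one-coloring of state 1).
#' @param spec a [seq_spec()].
#' @return `TRUE` or `FALSE`.
#' @export
#' @examples
#' sp <- seq_spec(4)
#' x <- rep(0L, sp$N); x[sp$N] <- 1L   # only {1,2,3,4} ON, all 2-arm OFF
#' is_connected(x, sp)                 # FALSE: no 2-arm support
is_connected <- function(x, spec) {
  stopifnot(inherits(spec, "seq_spec"), length(x) == spec$N)
  big <- which(spec$arms >= 3)
  if (length(big) == 0) return(TRUE)
  pairs <- which(spec$arms == 2)
  for (t in big) {
    s <- x[t]
    if (s == 0) next
    g <- spec$targets[[t]]
    ok <- FALSE
    for (p in pairs) {
      h <- spec$targets[[p]]
      if (s %in% h && all(h %in% g) && x[p] == s) { ok <- TRUE; break }
    }
    if (!ok) return(FALSE)
  }
  TRUE
}

#' Enumerate the connected one-colorings of a reduced network
#'
#' Filters all `2^N` binary colorings of the reduced network's targets by
#' the connectivity rule.  For the reduced network this count has a closed
#' form ([one_coloring_count()]), and by the reachability correspondence it
#' equals the number of one-colorings found by BFS.
#'
#' @param spec a reduced [seq_spec()].
#' @param max_colorings capacity cap on `2^N`.
#' @return A binary matrix, one connected coloring per row (including the
#'   all-zero row), in lexicographic order.
#' @export
#' @examples
#' nrow(enumerate_connected_one_colorings(seq_spec(4)))   # 89
enumerate_connected_one_colorings <- function(spec, max_colorings = 2^22) {
  stopifnot(inherits(spec, "seq_spec"))
  if (!spec$reduced) stop("connected one-coloring enumeration is defined for reduced networks")
  N <- spec$N
  if (N == 0) return(matrix(integer(0), 1, 0))   # n = 1: the empty coloring
  if (2^N > max_colorings)
    stop("2^", N, " colorings exceed the capacity cap")
  # all colorings, vectorised: column t is bit t
  M <- as.matrix(expand.grid(rep(list(0:1), N), KEEP.OUT.ATTRS = FALSE))
  colnames(M) <- NULL
  storage.mode(M) <- "integer"
  ok <- rep(TRUE, nrow(M))
  pairs <- which(spec$arms == 2)
  for (t in which(spec$arms >= 3)) {
    g <- spec$targets[[t]]
    support <- pairs[vapply(pairs, function(p) all(spec$targets[[p]] %in% g), logical(1))]
    has_support <- rowSums(M[, support, drop = FALSE]) > 0
    ok <- ok & (M[, t] == 0 | has_support)
  }
  M[ok, , drop = FALSE]
}

#' Word reaching a connected one-coloring
#'
#' Produces a word that drives the all-zero configuration of a reduced
#' network to a given connected one-coloring.  Feasibility is decided by the
#' connectivity rule; the word itself is found by exact shortest-path search
#' over the reachable configuration graph and verified by replay, so the
#' returned word is a certificate of reachability.
#'
#' @param target 0/1 vector over the spec's targets (canonical order).
#' @param spec a reduced [seq_spec()].
#' @param max_states capacity cap for the search.
#' @return A word (token vector); empty for the all-zero coloring.
#' @export
#' @examples
#' sp <- seq_spec(4)
#' y <- c(0L, 0L, 1L, 0L, 0L, 0L, 1L)    # the {1,4} + {1,2,3,4} coloring
#' x <- apply_word(zero_config(sp), opposite_word(y, sp), sp)
#' identical(x, y)
opposite_word <- function(target, spec, max_states = 1e7) {
  stopifnot(inherits(spec, "seq_spec"), length(target) == spec$N)
  target <- as.integer(target)
  if (!all(target %in% c(0L, 1L))) stop("target must be a one-coloring (0/1 vector)")
  if (!is_connected(target, spec))
    stop("target coloring is disconnected and therefore unreachable")
  if (all(target == 0L)) return(character(0))
  rs <- bfs_reachable(spec, max_states = max_states, words = TRUE)
  base <- spec$n + 1
  pow <- base^(seq_len(spec$N) - 1)
  hit <- match(sum(target * pow), rs$keys)
  if (is.na(hit))
    stop("internal error: connected coloring not found by search")  # nocov
  w <- parse_word(rs$words[hit])
  stopifnot(identical(apply_word(zero_config(spec), w, spec), target))
  w
}
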