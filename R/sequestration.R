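#' Sequestration network specification
#'
#' Defines a sequestration network with `n` regulator pairs (K_i, P_i),
#' abstracting gene silencing by recruitment to protected nuclear
#' compartments.  A target is a nonempty subset `g` of `{1..n}` (its *arms*:
#' the regulator pairs able to act on it) and carries a state in
#' `{0} union g`; a target in state `i != 0` is sequestered in compartment
#' `i` and protected from every regulator except `P_i`.
#'
#' The *full* network has all `2^n - 1` nonempty subsets as targets; the
#' *reduced* network keeps only the `2^(n-1) - 1` targets containing index 1
#' (the transcribing regulator, e.g. RNA polymerase) and at least one other
#' index.
#'
#' @param n number of regulator pairs (>= 1).
#' @param reduced logical; `TRUE` for the reduced network (default), `FALSE`
#'   for the full network.
#'
#' @return An object of class `seq_spec`: parameters plus the canonical
#'   target list (sorted by arm count, then lexicographically).
#' @seealso [seq_apply()], [bfs_reachable()], [is_connected()]
#' @export
#' @examples
#' seq_spec(4)                # 7 reduced targets, as in the worked examples
#' seq_spec(3, reduced = FALSE)  # full network: 7 targets {1},{2},...,{1,2,3}
seq_spec <- function(n, reduced = TRUE) {
  n <- as.integer(n)
  if (n < 1) stop("n must be >= 1")
  subs <- list()
  for (k in seq_len(n)) subs <- c(subs, utils::combn(n, k, simplify = FALSE))
  if (reduced) subs <- Filter(function(g) 1L %in% g && length(g) >= 2L, subs)
  # canonical order: arm count, then lexicographic on arms
  key <- vapply(subs, function(g) paste(sprintf("%03d", g), collapse = ""), character(1))
  subs <- subs[order(lengths(subs), key)]
  N <- length(subs)
  kmask <- lapply(seq_len(n), function(i)
    which(vapply(subs, function(g) i %in% g, logical(1))))
  structure(list(
    model = "sequestration",
    n = n, reduced = reduced, N = N,
    targets = subs,
    arms = lengths(subs),
    kmask = kmask
  ), class = "seq_spec")
}

#' @export
print.seq_spec <- function(x, ...) {
  cat(sprintf("%s sequestration network: n=%d regulator pairs, %d targets\n",
              if (x$reduced) "reduced" else "full", x$n, x$N))
  invisible(x)
}

#' Apply a single regulator action to a sequestration configuration
#'
#' `K_i` moves every target with arm `i` that is in state 0 into state `i`;
#' `P_i` returns every target in state `i` to 0.  Targets in any other
#' nonzero state are protected (orthogonality), and `K_i` is idempotent.
#'
#' @param config integer state vector (canonical target order); entry `g`
#'   lies in `{0} union arms(g)`.
#' @param action an action token such as `"K2"` or `"P1"`.
#' @param spec a [seq_spec()].
#' @return The new configuration.
#' @export
#' @examples
#' sp <- seq_spec(4)
#' x <- apply_word(zero_config(sp), "K3 K4 K1 P3 P4", sp)
#' x   # only the target {1,2} is in state 1
seq_apply <- function(config, action, spec) {
  a <- parse_action(action)
  apply_action(spec, config, a$kind, a$index)
}

#' @export
apply_action.seq_spec <- function(spec, config, kind, index) {
  if (index < 1 || index > spec$n) stop(kind, " index out of range: ", index)
  idx <- spec$kmask[[index]]
  if (kind == "K") {
    sub <- config[idx]
    sub[sub == 0L] <- index
    config[idx] <- sub
  } else {
    sub <- config[idx]
    sub[sub == index] <- 0L
    config[idx] <- sub
  }
  config
}

#' @export
apply_action_matrix.seq_spec <- function(spec, M, kind, index) {
  idx <- spec$kmask[[index]]
  sub <- M[, idx, drop = FALSE]
  if (kind == "K") sub[sub == 0L] <- index else sub[sub == index] <- 0L
  M[, idx] <- sub
  M
}

# total size of the configuration space (used for capacity checks and
# mixed-radix encoding); per-target state count is arms+1 for sequestration
state_space_size <- function(spec) UseMethod("state_space_size")

#' @export
state_space_size.ratchet_spec <- function(spec) (spec$T + 1)^spec$N

#' @export
state_space_size.seq_spec <- function(spec) prod(spec$arms + 1)
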