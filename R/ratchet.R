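#' Ratchet network specification
#'
#' Defines a two-layer ratchet network in which `n` activators (K's, e.g.
#' kinases or excitatory inputs) and `m` deactivators (P's, e.g. phosphatases
#' or inhibitory inputs) act on integer-valued targets.  Each target is
#' identified by the subset of `l_n` K's and `l_m` P's it responds to, so the
#' network has `N = choose(n, l_n) * choose(m, l_m)` targets.  Each target
#' carries a state in `0..T`; a target is ON when its state equals the
#' threshold `T`.
#'
#' @param n number of K regulators (>= 1).
#' @param m number of P regulators (>= 1).
#' @param l_n number of K's each target connects to (1 <= l_n <= n).
#' @param l_m number of P's each target connects to (1 <= l_m <= m).
#' @param T integer activation threshold (>= 1); targets ratchet through
#'   states 0..T and saturate at the ends.
#'
#' @return An object of class `ratchet_spec`: a list with the parameters,
#'   the canonical target list, and the derived quantities `N` (target
#'   count), `M` (targets per (K, P) pair), `p_n` and `p_m` (targets per K
#'   and per P).
#'
#' @details Targets are ordered lexicographically on (K-subset, P-subset);
#'   for `l_n = l_m = 1` this is row-major order of the n x m connectivity
#'   matrix. Regulator indices are 1-based throughout.
#'
#' @seealso [build_ratchet_targets()], [ratchet_apply()],
#'   [connectivity_matrix()]
#' @export
#' @examples
#' sp <- ratchet_spec(2, 2)        # the four-target network of the examples
#' sp$N                            # 4 targets
ratchet_spec <- function(n, m, l_n = 1, l_m = 1, T = 1) {
  stopifnot(length(n) == 1, length(m) == 1)
  n <- as.integer(n); m <- as.integer(m)
  l_n <- as.integer(l_n); l_m <- as.integer(l_m)
  T <- as.integer(T)
  if (n < 1 || m < 1) stop("n and m must be >= 1")
  if (l_n < 1 || l_n > n) stop("invalid connectivity: l_n must satisfy 1 <= l_n <= n")
  if (l_m < 1 || l_m > m) stop("invalid connectivity: l_m must satisfy 1 <= l_m <= m")
  if (T < 1) stop("threshold T must be >= 1")

  ksets <- utils::combn(n, l_n, simplify = FALSE)
  psets <- utils::combn(m, l_m, simplify = FALSE)
  targets <- vector("list", length(ksets) * length(psets))
  idx <- 1L
  for (ks in ksets) for (ps in psets) {
    targets[[idx]] <- list(k_set = ks, p_set = ps)
    idx <- idx + 1L
  }
  N <- length(targets)
  # per-regulator target index lists (which targets K_i / P_j touch)
  kmask <- lapply(seq_len(n), function(i)
    which(vapply(targets, function(t) i %in% t$k_set, logical(1))))
  pmask <- lapply(seq_len(m), function(j)
    which(vapply(targets, function(t) j %in% t$p_set, logical(1))))

  structure(list(
    model = "ratchet",
    n = n, m = m, l_n = l_n, l_m = l_m, T = T,
    N = N,
    M = choose(n - 1, l_n - 1) * choose(m - 1, l_m - 1),
    p_n = N * l_n / n,
    p_m = N * l_m / m,
    targets = targets,
    kmask = kmask, pmask = pmask
  ), class = "ratchet_spec")
}

#' @export
print.ratchet_spec <- function(x, ...) {
  cat(sprintf(
    "ratchet network: n=%d K's, m=%d P's, l_n=%d, l_m=%d, T=%d (%d targets, M=%d per pair)\n",
    x$n, x$m, x$l_n, x$l_m, x$T, x$N, x$M))
  invisible(x)
}

#' Canonical target list of a ratchet network
#'
#' Returns the targets of a ratchet network in canonical order
#' (lexicographic on the (K-subset, P-subset) pair).  Each K index appears
#' in `p_n = N l_n / n` targets and each P index in `p_m = N l_m / m`.
#'
#' @param spec a [ratchet_spec()].
#' @return A list of targets, each a list with sorted integer vectors
#'   `k_set` and `p_set`.
#' @export
build_ratchet_targets <- function(spec) {
  stopifnot(inherits(spec, "ratchet_spec"))
  spec$targets
}

#' The all-zero configuration
#'
#' @param spec a [ratchet_spec()] or [seq_spec()].
#' @return Integer vector of zeros, one entry per target in canonical order.
#' @export
zero_config <- function(spec) {
  integer(spec$N)
}

#' Apply a single regulator action to a ratchet configuration
#'
#' `K_i` increments (saturating at `T`) the state of every target whose
#' K-subset contains `i`; `P_j` decrements (floored at 0) every target whose
#' P-subset contains `j`.  All other targets are untouched.  This is the
#' one-pot rule: every receptive substrate is acted on at once.
#'
#' @param config integer state vector (canonical target order).
#' @param action an action token such as `"K1"` or `"P2"`.
#' @param spec a [ratchet_spec()].
#' @return The new configuration.
#' @export
#' @examples
#' sp <- ratchet_spec(2, 2)
#' x <- zero_config(sp)
#' x <- ratchet_apply(x, "K1", sp)
#' connectivity_matrix(x, sp)
ratchet_apply <- function(config, action, spec) {
  a <- parse_action(action)
  apply_action(spec, config, a$kind, a$index)
}

# internal generic: fast per-action update (index already validated/parsed)
apply_action <- function(spec, config, kind, index) UseMethod("apply_action")

#' @export
apply_action.ratchet_spec <- function(spec, config, kind, index) {
  if (kind == "K") {
    if (index < 1 || index > spec$n) stop("K index out of range: ", index)
    idx <- spec$kmask[[index]]
    config[idx] <- pmin(config[idx] + 1L, spec$T)
  } else {
    if (index < 1 || index > spec$m) stop("P index out of range: ", index)
    idx <- spec$pmask[[index]]
    config[idx] <- pmax(config[idx] - 1L, 0L)
  }
  config
}

# vectorised variant used by BFS: acts on a matrix of configurations (rows)
apply_action_matrix <- function(spec, M, kind, index) UseMethod("apply_action_matrix")

#' @export
apply_action_matrix.ratchet_spec <- function(spec, M, kind, index) {
  if (kind == "K") {
    idx <- spec$kmask[[index]]
    sub <- M[, idx, drop = FALSE]
    M[, idx] <- pmin(sub + 1L, spec$T)
  } else {
    idx <- spec$pmask[[index]]
    sub <- M[, idx, drop = FALSE]
    M[, idx] <- pmax(sub - 1L, 0L)
  }
  M
}

#' Connectivity-matrix summary of a ratchet configuration
#'
#' For `l_n = l_m = 1` the entry `A[i, j]` is the raw state (0..T) of the
#' unique target controlled by `K_i` and `P_j`.  For higher connectivity each
#' entry summarises the group of `M` targets shared by `K_i` and `P_j`:
#' `A[i, j] = 1` if at least one of them is ON (state == T) and 0 only if
#' all are OFF.
#'
#' @param config integer state vector.
#' @param spec a [ratchet_spec()].
#' @return An `n x m` integer matrix.
#' @export
connectivity_matrix <- function(config, spec) {
  stopifnot(inherits(spec, "ratchet_spec"), length(config) == spec$N)
  if (spec$l_n == 1 && spec$l_m == 1) {
    # canonical order is row-major over (i, j)
    return(matrix(as.integer(config), spec$n, spec$m, byrow = TRUE))
  }
  A <- matrix(0L, spec$n, spec$m)
  on <- config == spec$T
  for (i in seq_len(spec$n)) for (j in seq_len(spec$m)) {
    grp <- intersect(spec$kmask[[i]], spec$pmask[[j]])
    A[i, j] <- as.integer(any(on[grp]))
  }
  A
}

# inverse of connectivity_matrix for l = 1 (used by replay checks)
config_from_matrix <- function(A, spec) {
  stopifnot(spec$l_n == 1, spec$l_m == 1)
  as.integer(t(A))
}
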