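# Closed-form and recursive counting laws.  All counts are computed in
# doubles, which represent integers exactly below 2^53; every function
# guards that range and errors rather than silently losing precision.

.check_exact <- function(x, what) {
  if (any(abs(x) >= 2^53))
    stop(what, " exceeds the exact integer range of doubles (2^53)")
  x
}

#' Stirling numbers of the second kind
#'
#' `stirling2(n, j)` counts the partitions of an `n`-element set into `j`
#' nonempty blocks, via the standard triangular recurrence with
#' `S(0, 0) = 1`.
#'
#' @param n,j non-negative integers.
#' @return The count (exact; errors beyond the 2^53 double-integer range).
#' @export
#' @examples
#' stirling2(3, 2)   # 3
stirling2 <- function(n, j) {
  if (n < 0 || j < 0) stop("stirling2 expects non-negative arguments")
  if (j > n) return(0)
  S <- matrix(0, n + 1, n + 1)
  S[1, 1] <- 1
  if (n >= 1) for (nn in seq_len(n)) for (jj in seq_len(nn))
    S[nn + 1, jj + 1] <- jj * S[nn, jj + 1] + S[nn, jj]
  .check_exact(S[n + 1, j + 1], "stirling2")
}

#' Poly-Bernoulli numbers (lonesum matrix counts)
#'
#' `poly_bernoulli(n, m)` is the number of `n x m` binary lonesum matrices,
#' computed from the double-Stirling form
#' `sum_j (j!)^2 S(n+1, j+1) S(m+1, j+1)`.  This is the scaling law of the
#' threshold-1 ratchet network: its reachable configurations are exactly the
#' lonesum matrices.  Symmetric in `(n, m)`.
#'
#' @param n,m non-negative integers.
#' @return The count.
#' @export
#' @examples
#' poly_bernoulli(2, 2)   # 14
#' poly_bernoulli(3, 3)   # 230
poly_bernoulli <- function(n, m) {
  if (n < 0 || m < 0) stop("poly_bernoulli expects non-negative arguments")
  s <- 0
  for (j in 0:min(n, m))
    s <- s + factorial(j)^2 * stirling2(n + 1, j + 1) * stirling2(m + 1, j + 1)
  .check_exact(s, "poly_bernoulli")
}

#' Combinatorial-logic network specification
#'
#' Parameterises combinatorial (AND-logic) regulation with `u` pools of
#' regulators; pool `i` has `n_i` regulators and each target connects to
#' `l_ni` of them.  A target is ON only when one chosen regulator from each
#' pool is active.
#'
#' @param n_i integer vector of pool sizes.
#' @param l_ni integer vector of per-pool connectivities (recycled).
#' @return An object of class `comb_spec`.
#' @export
comb_spec <- function(n_i, l_ni = 1) {
  n_i <- as.integer(n_i)
  l_ni <- as.integer(rep(l_ni, length.out = length(n_i)))
  if (any(n_i < 1)) stop("pool sizes must be >= 1")
  if (any(l_ni < 1 | l_ni > n_i)) stop("connectivities must satisfy 1 <= l_ni <= n_i")
  structure(list(u = length(n_i), n_i = n_i, l_ni = l_ni), class = "comb_spec")
}

#' Redundancy threshold of a regulator pool
#'
#' The smallest number `alpha_i` of regulators from pool `i` whose joint
#' action is equivalent to activating the whole pool: any subset of size
#' `alpha_i` or more already covers every target column of the connectivity
#' matrix against the partner pool maximising the two-pool target count.
#' Determined by inclusion-exclusion on the per-entry target groups.
#'
#' @param spec a [comb_spec()] with at least two pools.
#' @param pool pool index.
#' @return Integer threshold in `1..n_i`.
#' @export
#' @examples
#' alpha_threshold(comb_spec(c(3, 3), c(2, 2)), 1)   # 2
alpha_threshold <- function(spec, pool) {
  stopifnot(inherits(spec, "comb_spec"))
  if (spec$u < 2) stop("alpha_threshold needs a partner pool (u >= 2)")
  i <- pool
  ni <- spec$n_i[i]; li <- spec$l_ni[i]
  others <- setdiff(seq_len(spec$u), i)
  j <- others[which.max(choose(spec$n_i[others], spec$l_ni[others]))]
  nj <- spec$n_i[j]; lj <- spec$l_ni[j]
  Ni <- choose(ni, li) * choose(nj, lj)
  pnj <- Ni * lj / nj          # targets per partner-regulator column
  Mi <- choose(ni - 1, li - 1) * choose(nj - 1, lj - 1)
  for (r in seq_len(ni)) {
    overlap <- 0
    top <- min(r, li)
    if (top >= 2) for (rp in 2:top)   # alternating inclusion-exclusion terms
      overlap <- overlap + (-1)^rp *
        choose(r, rp) * choose(ni - rp, li - rp) * choose(nj - 1, lj - 1)
    if (Mi * r - overlap >= pnj) return(r)
  }
  ni
}

#' Number of configurations under combinatorial logic
#'
#' Inclusion-exclusion count of the distinct target configurations
#' attainable by combinatorial (AND) logic with `u` pools: all ways of
#' activating at least one regulator per pool, minus the choices made
#' redundant by connectivity (any subset of pool `i` with `alpha_i` or more
#' members acts like the full pool), with the empty choice added back.
#' Always less than `2^(sum n_i)`; increasing any `l_ni` can only reduce it.
#' For a single pool the count is computed directly as
#' `1 + sum_{j >= l} choose(n, j)` (distinct AND-logic ON-sets), which is
#' `2^n` at `l = 1`.
#'
#' @param spec a [comb_spec()].
#' @return The configuration count.
#' @export
#' @examples
#' combinatorial_count(comb_spec(c(2, 2)))        # 10
#' combinatorial_count(comb_spec(5))              # 2^5
combinatorial_count <- function(spec) {
  stopifnot(inherits(spec, "comb_spec"))
  u <- spec$u
  if (u == 1) {
    n <- spec$n_i[1]; l <- spec$l_ni[1]
    return(1 + sum(choose(n, l:n)))
  }
  alpha <- vapply(seq_len(u), function(i) alpha_threshold(spec, i), numeric(1))
  red <- vapply(seq_len(u), function(i) {      # redundant nonempty subsets
    a <- alpha[i]; n <- spec$n_i[i]
    if (a <= n - 1) sum(choose(n, a:(n - 1))) else 0
  }, numeric(1))
  tot <- vapply(spec$n_i, function(n) 2^n - 1, numeric(1))
  S <- 1
  for (k in 0:u) {
    Sk <- 0
    for (sig in if (k == 0) list(integer(0)) else utils::combn(u, k, simplify = FALSE)) {
      Sk <- Sk + prod(red[sig]) * prod(tot[setdiff(seq_len(u), sig)])
    }
    S <- S + (-1)^k * Sk
  }
  .check_exact(S, "combinatorial_count")
}

# a-table: a[j] = number of minimal-word classes using exactly j P's (for a
# fixed j-subset of P's) when n K's are available; extracted from the
# (n, j+1) network where C(j+1, j) placements enumerate them.
.minseq_a <- function(n, jmax) {
  a <- numeric(max(jmax, 1))
  if (jmax >= 1) for (mm in seq_len(jmax)) {
    s <- poly_bernoulli(n, mm + 1) - 2^n
    if (mm >= 2) for (j in seq_len(mm - 1)) s <- s - choose(mm + 1, j) * a[j]
    a[mm] <- s / (mm + 1)
  }
  a
}

# c_n^m(1, l_m): words at K-connectivity 1, P-connectivity l_m
.minseq_c1 <- function(n, m, l_m) {
  a <- .minseq_a(n, m - 1)
  s <- 2^n
  if (m - l_m >= 1) for (j in seq_len(m - l_m)) s <- s + choose(m, j) * a[j]
  s
}

#' Minimal-sequence count of a ratchet network (recursion)
#'
#' Evaluates the recursive count of minimal-length words in the
#' `(n, m, l_n, l_m)` threshold-1 ratchet network.  Words using more than
#' `n - l_n + 1` distinct K's or `m - l_m` distinct P's are redundant with
#' shorter ones; the recursion peels those classes off the poly-Bernoulli
#' totals.  Validated against the independent census of
#' [minimal_sequences_bruteforce()].
#'
#' @param n,m regulator counts.
#' @param l_n,l_m connectivities.
#' @return The number of minimal-length words (equivalently, of surviving
#'   configurations).
#' @export
#' @examples
#' minimal_sequence_count(3, 3, 1, 1)   # 230 = poly_bernoulli(3, 3)
#' minimal_sequence_count(3, 3, 2, 2)   # 43
minimal_sequence_count <- function(n, m, l_n = 1, l_m = 1) {
  if (l_n < 1 || l_n > n || l_m < 1 || l_m > m)
    stop("connectivities must satisfy 1 <= l_n <= n, 1 <= l_m <= m")
  # b[j+1] = words using a fixed set of j K's at P-connectivity l_m
  b <- numeric(n + 1)
  b[1] <- 1
  b[2] <- 2^m - sum(choose(m, 0:(l_m - 1)))
  if (n >= 2) for (nn in 2:n) {
    s <- .minseq_c1(nn, m, l_m)
    for (j in 0:(nn - 1)) s <- s - choose(nn, j) * b[j + 1]
    b[nn + 1] <- s
  }
  tot <- 0
  for (j in 0:(n - l_n + 1)) tot <- tot + choose(n, j) * b[j + 1]
  .check_exact(tot, "minimal_sequence_count")
}

#' Connected one-coloring count of the reduced sequestration network
#'
#' Closed-form count of the reachable one-colorings of the reduced
#' `n`-network: all `2^(2^(n-1) - 1)` binary colorings minus the
#' connectivity violations.  A violation fixes `m >= 2` of the 2-arm targets
#' at 0 (`choose(n-1, m)` ways), forces the multi-arm targets whose support
#' lies entirely inside those zeros to contain at least one illegal ON
#' (`2^A - 1` ways over the `A = sum_k choose(m, k-1)` constrained targets,
#' binomials vanishing once `k - 1 > m`), and leaves the remaining
#' `B = sum_k [choose(n-1, k-1) - choose(m, k-1)]` multi-arm targets free
#' (`2^B` ways), with both inner sums running over arm counts `3 <= k <= n`.
#'
#' @param n number of regulator pairs (>= 1).
#' @return The count; reproduces 1, 2, 7, 89, 16897, 780304385 for
#'   `n = 1..6`.
#' @export
one_coloring_count <- function(n) {
  if (n < 1) stop("n must be >= 1")
  if (n == 1) return(1)
  total <- 2^(2^(n - 1) - 1)
  .check_exact(total, "one_coloring_count")
  viol <- 0
  if (n >= 3) for (m in 2:(n - 1)) {
    ks <- 3:n
    A <- sum(choose(m, ks - 1))
    B <- sum(choose(n - 1, ks - 1) - choose(m, ks - 1))
    viol <- viol + choose(n - 1, m) * (2^A - 1) * 2^B
  }
  total - viol
}

#' Bounds on the full sequestration network's reachable count
#'
#' The reachable count `c_n` of the full `n`-network has no closed form, but
#' it is bounded below by the reduced `(n+1)`-network's one-coloring count
#' `f(n+1)` (each one-coloring there identifies a distinct full-`n`
#' configuration) and above by the falling-factorial sum over nested
#' k-colorings `1 + sum_k (n)_k f(n-k+1) prod_j (f(j) - 1)`.
#'
#' @param n number of regulator pairs.
#' @return Named numeric vector `c(lower = , upper = )`.
#' @export
#' @examples
#' full_network_bounds(3)   # lower 89, upper 130 (c_3 = 94)
full_network_bounds <- function(n) {
  f <- vapply(seq_len(n + 1), one_coloring_count, numeric(1))
  upper <- 1
  for (k in seq_len(n)) {
    falling <- prod(n:(n - k + 1))
    pr <- 1
    if (k >= 2) for (j in (n - k + 2):n) pr <- pr * (f[j] - 1)
    upper <- upper + falling * pr * f[n - k + 1]
  }
  c(lower = f[n + 1], upper = .check_exact(upper, "full_network_bounds"))
}

#' Orbit counts of the threshold-1 ratchet network (recursion)
#'
#' Counts the `i, j`-orbits of the `n x m` ratchet network: families of
#' configurations carrying a forbidden (non-lonesum) pattern on an `i x j`
#' sub-block whose `i` K's and `j` P's are never used.  The per-block count
#' `c_i^j` subtracts, from the `2^(ij) - B(i, j)` forbidden blocks, those
#' configurations already generated by smaller orbits (new origins times the
#' reachable fillings `B'` of the free block, where `B'` degenerates to a
#' power of two when no K or no P action is allowed).  Totals multiply by
#' the `choose(n, i) choose(m, j)` block placements.
#'
#' @param n,m network size (orbits need `i, j >= 2`).
#' @return A data frame with columns `i`, `j`, `c_ij` (orbits per block
#'   choice) and `C_ij` (total orbits in the network).
#' @export
#' @examples
#' ratchet_orbit_count(2, 2)$c_ij   # 2
ratchet_orbit_count <- function(n, m) {
  if (n < 2 || m < 2)
    return(data.frame(i = integer(0), j = integer(0), c_ij = numeric(0), C_ij = numeric(0)))
  memo <- new.env(parent = emptyenv())
  cij <- function(i, j) {
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    val <- 2^(i * j) - poly_bernoulli(i, j)
    for (ip in 2:i) for (jp in 2:j) {
      if (ip + jp > i + j - 1 || (ip == i && jp == j)) next
      di <- i - ip; dj <- j - jp
      Bp <- if (di > 0 && dj > 0) poly_bernoulli(di, dj)
            else if (dj == 0) 2^di else 2^dj
      val <- val - choose(i, ip) * choose(j, jp) * cij(ip, jp) * Bp
    }
    memo[[key]] <- val
    val
  }
  grid <- expand.grid(i = 2:n, j = 2:m)
  grid$c_ij <- mapply(cij, grid$i, grid$j)
  grid$C_ij <- choose(n, grid$i) * choose(m, grid$j) * grid$c_ij
  .check_exact(grid$C_ij, "ratchet_orbit_count")
  grid
}
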