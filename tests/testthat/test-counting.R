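test_that("Stirling numbers satisfy their defining recurrence and cases", {
  expect_equal(stirling2(3, 2), 3)
  expect_equal(stirling2(5, 1), 1)
  expect_equal(stirling2(4, 0), 0)
  expect_equal(stirling2(0, 0), 1)
  for (n in 1:8) expect_equal(stirling2(n, n), 1)
  expect_error(stirling2(-1, 0), "non-negative")
})

test_that("poly-Bernoulli numbers: symmetry and both closed forms agree", {
  expect_equal(poly_bernoulli(2, 2), 14)
  expect_equal(poly_bernoulli(3, 3), 230)
  for (n in 1:6) expect_equal(poly_bernoulli(n, 1), 2^n)
  # alternating single-Stirling form as an independent route
  alt <- function(n, m) {
    s <- 0
    for (j in 0:n) s <- s + (-1)^(n + j) * factorial(j) * stirling2(n, j) * (j + 1)^m
    s
  }
  for (n in 0:7) for (m in 0:7) {
    expect_equal(poly_bernoulli(n, m), poly_bernoulli(m, n))
    expect_equal(poly_bernoulli(n, m), alt(n, m))
  }
  # exhaustive lonesum census at 3x3
  expect_equal(poly_bernoulli(3, 3), sum(vapply(all_binary(3, 3), is_lonesum, logical(1))))
})

test_that("redundancy thresholds alpha behave as derived", {
  expect_equal(alpha_threshold(comb_spec(c(3, 3), c(2, 2)), 1), 2)
  expect_equal(alpha_threshold(comb_spec(c(4, 3), c(1, 2)), 1), 4)  # l = 1: no redundancy
  expect_equal(alpha_threshold(comb_spec(c(2, 5), c(2, 1)), 1), 1)  # one K covers all
  expect_error(alpha_threshold(comb_spec(3, 1), 1), "partner")
})

test_that("combinatorial-logic counts: examples, cap and monotonicity", {
  expect_equal(combinatorial_count(comb_spec(c(2, 2))), 10)
  expect_equal(combinatorial_count(comb_spec(3)), 2^3)
  for (u in 1:3) for (n in 2:4) for (l in 1:n) {
    s <- combinatorial_count(comb_spec(rep(n, u), rep(l, u)))
    # with at least two pools the count is strictly below 2^(total
    # regulators); a single pool at l = 1 attains it exactly
    if (u >= 2) expect_lt(s, 2^(n * u)) else expect_lte(s, 2^n)
  }
  # increasing connectivity can only reduce the count (symmetric grids)
  for (n in 2:5) {
    vals <- vapply(1:n, function(l) combinatorial_count(comb_spec(c(n, n), c(l, l))), numeric(1))
    expect_true(all(diff(vals) <= 0))
  }
})

test_that("minimal-sequence recursion matches the census on a spot grid", {
  expect_equal(minimal_sequence_count(4, 1, 1, 1), 2^4)
  expect_equal(minimal_sequence_count(3, 3, 1, 1), poly_bernoulli(3, 3))
  expect_equal(minimal_sequence_count(3, 3, 2, 2),
               minimal_sequences_bruteforce(ratchet_spec(3, 3, 2, 2))$count)
  expect_equal(minimal_sequence_count(4, 2, 3, 1),
               minimal_sequences_bruteforce(ratchet_spec(4, 2, 3, 1))$count)
  expect_error(minimal_sequence_count(2, 2, 3, 1), "connectivities")
})

test_that("one-coloring counts reproduce the closed-form sequence", {
  expect_equal(vapply(1:6, one_coloring_count, numeric(1)),
               c(1, 2, 7, 89, 16897, 780304385))
  # counts beyond the exact double-integer range are refused, not mangled
  expect_error(one_coloring_count(8), "exact integer range")
})

test_that("full-network bounds bracket the enumerated counts", {
  b3 <- full_network_bounds(3)
  expect_equal(unname(b3["lower"]), 89)
  expect_equal(unname(b3["upper"]), 130)
  for (n in 1:4) {
    b <- full_network_bounds(n)
    expect_lte(b["lower"], b["upper"])
  }
  for (n in 1:3) {
    cn <- reach_count(seq_bfs(n))
    b <- full_network_bounds(n)
    expect_lte(b["lower"], cn)
    expect_lte(cn, b["upper"])
  }
})

test_that("ratchet orbit recursion: base case and degenerate sizes", {
  tab <- ratchet_orbit_count(2, 2)
  expect_equal(tab$c_ij, 2)      # 2^4 - B(2,2)
  expect_equal(tab$C_ij, 2)
  expect_equal(nrow(ratchet_orbit_count(1, 5)), 0)   # no 2x2 violation possible
  tab42 <- ratchet_orbit_count(4, 2)
  expect_true(all(tab42$c_ij >= 0))
})
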