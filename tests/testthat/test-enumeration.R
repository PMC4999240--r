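test_that("BFS closes the configuration space deterministically", {
  sp <- ratchet_spec(2, 2)
  rs <- bfs_reachable(sp)
  expect_equal(reach_count(rs), 14)
  expect_identical(rs$configs[1, ], zero_config(sp))
  # witness words replay to their configurations
  for (r in seq_len(nrow(rs$configs)))
    expect_identical(apply_word(zero_config(sp), rs$words[r], sp), rs$configs[r, ])
  # empty alphabet: just the start
  expect_equal(reach_count(bfs_reachable(sp, alphabet = character(0))), 1)
  # deterministic regeneration
  rs2 <- bfs_reachable(sp)
  expect_identical(rs$configs, rs2$configs)
  expect_identical(rs$words, rs2$words)
})

test_that("sequestration reachability matches the reported counts", {
  expect_equal(reach_count(seq_bfs(1)), 2)
  expect_equal(reach_count(seq_bfs(2)), 7)
  expect_equal(reach_count(seq_bfs(3)), 94)
})

test_that("lonesum test agrees with the forbidden-pattern scan", {
  expect_false(is_lonesum(matrix(c(1, 0, 0, 1), 2, 2)))
  expect_false(is_lonesum(matrix(c(0, 1, 1, 0), 2, 2)))
  expect_true(is_lonesum(matrix(c(1, 0, 1, 1), 2, 2)))
  expect_true(is_lonesum(matrix(0, 3, 3)))
  expect_error(is_lonesum(matrix(2, 2, 2)), "binary")
  for (A in all_binary(3, 3))
    expect_equal(is_lonesum(A), scan_lonesum(A))
})

test_that("every reachable T=1 configuration is lonesum and conversely", {
  sp <- ratchet_spec(3, 3)
  rs <- bfs_reachable(sp, words = FALSE)
  seen <- sort(apply(rs$configs, 1, paste, collapse = ""))
  lone <- Filter(is_lonesum, all_binary(3, 3))
  expect_equal(nrow(rs$configs), length(lone))   # 230 on both routes
  # constructive direction: every lonesum matrix is replayed by its
  # staircase word
  built <- vapply(lone, function(A) {
    x <- apply_word(zero_config(sp), staircase_word(A), sp)
    paste(x, collapse = "")
  }, character(1))
  expect_setequal(built, seen)
  expect_identical(staircase_word(matrix(0L, 2, 2)), character(0))
  expect_identical(staircase_word(matrix(1L, 2, 3)), c("K1", "K2"))
  expect_error(staircase_word(matrix(c(1, 0, 0, 1), 2, 2)), "lonesum")
})

test_that("threshold 2 reaches every binary pattern constructively", {
  sp <- ratchet_spec(2, 2, T = 2)
  for (patt in all_binary(2, 2)) {
    x <- apply_word(zero_config(sp), t2_constructive_word(patt), sp)
    expect_equal(connectivity_matrix(x, sp) == 2, patt == 1)
  }
})

test_that("connectivity rule matches its defining examples", {
  sp <- seq_spec(4)
  # {0,1,3} and {0,1,4} OFF force {0,1,4}... the 3-arm target {1,3,4} OFF
  x <- rep(0L, sp$N)
  x[which(vapply(sp$targets, identical, logical(1), y = c(1L, 3L, 4L)))] <- 1L
  expect_false(is_connected(x, sp))
  expect_true(is_connected(c(0L, 0L, 1L, 0L, 0L, 0L, 1L), sp))
  expect_true(is_connected(zero_config(sp), sp))
  # a nonzero state other than 1 also needs its 2-arm support
  y <- rep(0L, sp$N)
  y[which(vapply(sp$targets, identical, logical(1), y = c(1L, 2L, 3L)))] <- 3L
  expect_false(is_connected(y, sp))
  y[which(vapply(sp$targets, identical, logical(1), y = c(1L, 3L)))] <- 3L
  expect_true(is_connected(y, sp))
})

test_that("connected one-colorings: enumeration equals closed form and BFS", {
  expect_equal(nrow(enumerate_connected_one_colorings(seq_spec(2))), 2)
  expect_equal(nrow(enumerate_connected_one_colorings(seq_spec(3))), 7)
  expect_equal(nrow(enumerate_connected_one_colorings(seq_spec(4))), 89)
  for (n in 2:4) {
    sp <- seq_spec(n)
    rs <- seq_bfs(n, reduced = TRUE)
    onec <- rs$configs[apply(rs$configs <= 1L, 1, all), , drop = FALSE]
    en <- enumerate_connected_one_colorings(sp)
    expect_setequal(apply(onec, 1, paste, collapse = ""),
                    apply(en, 1, paste, collapse = ""))
  }
  expect_error(enumerate_connected_one_colorings(seq_spec(3, reduced = FALSE)),
               "reduced")
})

test_that("opposite_word certificates replay for every connected coloring", {
  sp <- seq_spec(4)
  expect_identical(opposite_word(rep(0L, sp$N), sp), character(0))
  en <- enumerate_connected_one_colorings(sp)
  for (r in seq_len(nrow(en))) {
    w <- opposite_word(en[r, ], sp)
    expect_identical(apply_word(zero_config(sp), w, sp), en[r, ])
  }
  # all-ON coloring of the reduced 3-network
  sp3 <- seq_spec(3)
  w <- opposite_word(rep(1L, sp3$N), sp3)
  expect_identical(apply_word(zero_config(sp3), w, sp3), rep(1L, sp3$N))
  # disconnected target is refused
  bad <- rep(0L, sp$N); bad[sp$N] <- 1L
  expect_error(opposite_word(bad, sp), "disconnected")
})

test_that("minimal-sequence census respects the regulator-use bounds", {
  ms <- minimal_sequences_bruteforce(ratchet_spec(2, 2))
  expect_equal(ms$count, 14)
  # two K's suffice to activate all targets at l = 2: the word K1 K2 turns
  # on the whole (3, 3, 2, 2) network, and its class survives the census
  sp22 <- ratchet_spec(3, 3, 2, 2)
  expect_true(all(apply_word(zero_config(sp22), "K1 K2", sp22) == 1L))
  ms2 <- minimal_sequences_bruteforce(sp22)
  expect_true(any(ms2$words == "K1 K2"))
  # bound: no surviving configuration needs more than n-l_n+1 K's / m-l_m P's
  for (ln in 1:3) for (lm in 1:3) {
    sp <- ratchet_spec(3, 3, ln, lm)
    ms <- minimal_sequences_bruteforce(sp)
    expect_true(all(ms$k_used <= sp$n - sp$l_n + 1))
    expect_true(all(ms$p_used <= sp$m - sp$l_m))
    # the recorded staircase words replay and respect the same bounds
    base <- ratchet_spec(3, 3)
    for (r in seq_len(min(nrow(ms$configs), 20))) {
      x <- apply_word(zero_config(base), ms$words[r], base)
      expect_identical(x, ms$configs[r, ])
    }
  }
  # trivial network: empty word and K1
  ms1 <- minimal_sequences_bruteforce(ratchet_spec(1, 1))
  expect_equal(ms1$count, 2)
  expect_setequal(ms1$words, c("", "K1"))
})
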