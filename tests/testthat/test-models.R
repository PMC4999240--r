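test_that("ratchet target construction matches the handshaking counts", {
  sp <- ratchet_spec(2, 2)
  expect_equal(sp$N, 4)
  expect_equal(length(build_ratchet_targets(sp)), 4)

  sp2 <- ratchet_spec(3, 3, 2, 2)
  expect_equal(sp2$N, 9)
  expect_equal(sp2$M, 4)     # four targets per (K_i, P_j) pair
  # each K appears in p_n targets, each P in p_m
  for (i in 1:3) expect_length(sp2$kmask[[i]], sp2$p_n)
  for (j in 1:3) expect_length(sp2$pmask[[j]], sp2$p_m)

  expect_equal(ratchet_spec(1, 1)$N, 1)
  expect_error(ratchet_spec(2, 2, l_n = 3), "connectivity")
})

test_that("ratchet dynamics reproduce the worked K1 K2 P1 trajectory", {
  sp <- ratchet_spec(2, 2)
  traj <- apply_word(zero_config(sp), "K1 K2 P1", sp, trajectory = TRUE)
  expect_equal(connectivity_matrix(traj[2, ], sp), matrix(c(1L, 0L, 1L, 0L), 2, 2))
  expect_equal(connectivity_matrix(traj[3, ], sp), matrix(1L, 2, 2))
  expect_equal(connectivity_matrix(traj[4, ], sp), matrix(c(0L, 0L, 1L, 1L), 2, 2))
})

test_that("ratchet saturation creates the noncommutative edge effect", {
  sp <- ratchet_spec(2, 2, T = 2)
  x <- zero_config(sp); x[1] <- 2L     # A_{1,1} at threshold
  expect_equal(apply_word(x, "K1 P1", sp)[1], 1L)   # K wasted at the top
  expect_equal(apply_word(x, "P1 K1", sp)[1], 2L)
  # saturating idempotence at T = 1
  sp1 <- ratchet_spec(2, 2)
  y <- apply_word(zero_config(sp1), "K1", sp1)
  expect_identical(apply_word(y, "K1", sp1), y)
  # empty word is the identity
  expect_identical(apply_word(y, "", sp1), y)
})

test_that("sequestration dynamics reproduce the printed configurations", {
  sp <- seq_spec(4)
  # canonical order: {1,2},{1,3},{1,4},{1,2,3},{1,2,4},{1,3,4},{1,2,3,4}
  w <- "K2 K4 P2 K3 K2 P4 K1 P3 K4 P1 K3 P4 K1 P2 P3"
  expect_identical(apply_word(zero_config(sp), w, sp),
                   c(0L, 0L, 1L, 0L, 0L, 0L, 1L))
  # the chromosome-folding example: only the {1,2} gene stays transcribable
  x <- apply_word(zero_config(sp), "K3 K4 K1 P3 P4", sp)
  expect_identical(x, c(1L, 0L, 0L, 0L, 0L, 0L, 0L))
})

test_that("sequestration actions are idempotent, orthogonal and protective", {
  sp <- seq_spec(3, reduced = FALSE)
  fx <- fixture_generator("sequestration", 4, seed = 11, max_n = 3)
  for (f in fx) {
    s <- f$spec
    for (w in f$words) {
      x <- apply_word(zero_config(s), w, s)
      for (i in seq_len(s$n)) {
        ki <- seq_apply(x, paste0("K", i), s)
        expect_identical(seq_apply(ki, paste0("K", i), s), ki)  # K_i^2 = K_i
        # protection: targets in a state j != 0 are fixed by K_i, P_i, i != j
        prot <- which(x != 0L & x != i)
        expect_identical(ki[prot], x[prot])
        expect_identical(seq_apply(x, paste0("P", i), s)[prot], x[prot])
      }
      # conservation: states stay inside {0} union arms
      for (t in seq_len(s$N))
        expect_true(x[t] %in% c(0L, s$targets[[t]]))
    }
  }
})

test_that("pure-K and pure-P words commute; mixed words need not", {
  fx <- fixture_generator("ratchet", 3, seed = 5, max_n = 3, max_m = 3)
  set.seed(42)
  for (f in fx) {
    s <- f$spec
    for (kind in c("K", "P")) {
      nreg <- if (kind == "K") s$n else s$m
      w <- paste0(kind, sample(nreg, 6, replace = TRUE))
      ref <- apply_word(zero_config(s), w, s)
      start <- if (kind == "P") apply_word(zero_config(s), paste0("K", seq_len(s$n)), s)
               else zero_config(s)
      ref <- apply_word(start, w, s)
      for (rep in 1:3)
        expect_identical(apply_word(start, sample(w), s), ref)
    }
  }
  # noncommutativity witnesses
  sp <- ratchet_spec(2, 2)
  x <- zero_config(sp); x[1] <- 1L
  expect_false(identical(apply_word(x, "K1 P1", sp), apply_word(x, "P1 K1", sp)))
  ss <- seq_spec(2, reduced = FALSE)
  expect_false(identical(apply_word(zero_config(ss), "K1 K2", ss),
                         apply_word(zero_config(ss), "K2 K1", ss)))
  # sequestration pure-P words commute from any configuration
  x2 <- apply_word(zero_config(ss), "K1 K2", ss)
  expect_identical(apply_word(x2, "P1 P2", ss), apply_word(x2, "P2 P1", ss))
})

test_that("connectivity matrix summarises groups for l > 1", {
  sp <- ratchet_spec(3, 3, 2, 2)
  x <- zero_config(sp)
  expect_equal(connectivity_matrix(x, sp), matrix(0L, 3, 3))
  # the target ({1,2}, {1,2}) is shared by exactly the four entries
  # (1,1), (1,2), (2,1), (2,2)
  t1 <- which(vapply(sp$targets, function(t)
    identical(t$k_set, c(1L, 2L)) && identical(t$p_set, c(1L, 2L)), logical(1)))
  x[t1] <- 1L
  A <- connectivity_matrix(x, sp)
  expect_equal(A, matrix(c(1L, 1L, 0L, 1L, 1L, 0L, 0L, 0L, 0L), 3, 3))
})

test_that("action indices out of range are rejected", {
  sp <- ratchet_spec(2, 2)
  expect_error(ratchet_apply(zero_config(sp), "K3", sp), "out of range")
  ss <- seq_spec(2)
  expect_error(seq_apply(zero_config(ss), "P5", ss), "out of range")
})
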