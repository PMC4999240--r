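test_that("generators are conservative block rate matrices", {
  os <- operator_spec(seq_spec(2, reduced = FALSE))
  G <- build_generator(os, 1, 0, "K")
  expect_true(all(abs(colSums(G)) < 1e-12))
  # targets without arm 1 contribute a zero block
  t_b <- 2   # target {2} in canonical order {1},{2},{1,2}
  off <- (t_b - 1) * os$block
  expect_true(all(G[off + 1:os$block, off + 1:os$block] == 0))
  # responsive 2-state sub-block is (-g 0 / g 0) in the ladder coordinates
  expect_equal(G[1, 1], -1); expect_equal(G[2, 1], 1)
  expect_error(build_generator(os, 5, 0, "K"), "dimension")
})

test_that("limit operators have the exact sub/super-diagonal block form", {
  # D = 1, T = 1: single responsive block is (0 0 / 1 1), P its transpose
  rs <- ratchet_spec(1, 1)
  os <- operator_spec(rs)
  K <- build_limit_operator(os, 1, "K")
  P <- build_limit_operator(os, 1, "P")
  expect_equal(K, matrix(c(0, 1, 0, 1), 2, 2))
  expect_equal(P, matrix(c(1, 0, 1, 0), 2, 2))
  # numeric route: matrix exponential of the generator at g t = 50
  G <- build_generator(os, 1, 0, "K")
  expect_lt(max(abs(as.matrix(Matrix::expm(G * 50)) - K)), 1e-10)
  H <- build_generator(os, 1, 0, "P")
  expect_lt(max(abs(as.matrix(Matrix::expm(H * 50)) - P)), 1e-10)
  # T = 1 operators are idempotent 0/1 matrices
  os2 <- operator_spec(seq_spec(2, reduced = FALSE))
  for (d in 1:2) for (kind in c("K", "P")) {
    M <- build_limit_operator(os2, d, kind)
    expect_true(all(M %in% c(0, 1)))
    expect_equal(M %*% M, M)
  }
})

test_that("the population-transfer worked example reproduces exactly", {
  os <- operator_spec(seq_spec(2, reduced = FALSE))
  x0 <- config_to_population(zero_config(os$model_spec), os)
  expect_equal(x0, c(1, 0, 0, 1, 0, 0, 1, 0, 0))
  x1 <- operator_apply_word(x0, "K1", os)
  expect_equal(x1, c(0, 1, 0, 1, 0, 0, 0, 1, 0))   # only A and C advance
  # empty word is the identity; block sums stay 1
  expect_equal(operator_apply_word(x1, "", os), x1)
  x2 <- operator_apply_word(x1, "K2 P1 K1", os)
  expect_equal(as.vector(tapply(x2, rep(1:3, each = 3), sum)), c(1, 1, 1))
  expect_error(operator_apply_word(c(1, 0), "K1", os), "malformed")
})

test_that("commutators witness noncommutativity and vanish where expected", {
  os <- operator_spec(ratchet_spec(2, 2))
  K1 <- build_limit_operator(os, 1, "K", os$action_map[["K1"]]$targets)
  K2 <- build_limit_operator(os, 1, "K", os$action_map[["K2"]]$targets)
  P1 <- build_limit_operator(os, 1, "P", os$action_map[["P1"]]$targets)
  expect_equal(commutator(K1, K1), matrix(0, nrow(K1), ncol(K1)))
  expect_equal(commutator(K1, K2), matrix(0, nrow(K1), ncol(K1)))  # disjoint rows
  expect_gt(max(abs(commutator(K1, P1))), 0)
  expect_error(commutator(K1, matrix(0, 2, 2)), "shape")
})

test_that("operator and rule-based pipelines agree on random word suites", {
  for (ms in list(seq_spec(2, reduced = FALSE),
                  ratchet_spec(2, 2),
                  ratchet_spec(2, 2, T = 2))) {
    chk <- operator_equivalence_check(ms, trials = 40, seed = 7)
    expect_true(chk$all_agree)
  }
  expect_error(operator_spec(ratchet_spec(3, 3, 2, 2)), "unsupported")
})
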