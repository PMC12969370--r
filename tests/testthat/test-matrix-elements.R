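# Selection rules, occupation compatibility, the overlap sweep, and full
# matrix elements against the determinant oracle.

test_that("selection rules screen by projection, triangle and parity", {
  ket <- parse_csf("uud0uu2d", 1)
  expect_true(selection_rules(ket, ket, "")$ok)
  # same shape, different intermediate coupling: the identity cannot connect
  bra <- parse_csf("udu0uu2d", 1)
  sr <- selection_rules(bra, ket, "")
  expect_false(sr$ok)
  expect_true(sr$rule %in% c("triangle", "parity"))
  expect_equal(sr$level, 2L)
  # projection balance
  expect_false(selection_rules(parse_csf("uud0uu2d", 0), ket, "")$ok)
  expect_equal(selection_rules(parse_csf("uud0uu2d", 0), ket, "")$rule,
               "projection")
  expect_error(selection_rules(parse_csf("ud", 0), ket, ""), "orbital counts")
})

test_that("occupation compatibility follows the per-level conditions", {
  ket <- apply_sequence(init_state(parse_csf("uud0uu2d", 1)), "1b+ 7b-")
  ok_bra <- init_state(parse_csf("2ud0uuud", 1))
  expect_true(occupation_compat(ok_bra, ket)$ok)
  bad_occ <- init_state(parse_csf("u2d0uuud", 1))
  oc <- occupation_compat(bad_occ, ket)
  expect_false(oc$ok)
  expect_equal(oc$rule, "occupation")
  expect_equal(oc$level, 1L)
  # alpha/beta clash between two spin-fixed levels
  k2 <- apply_sequence(init_state(parse_csf("20", 0)), "1b-")  # q1 = alpha
  b2 <- apply_sequence(init_state(parse_csf("20", 0)), "1a-")  # q1 = beta
  oc2 <- occupation_compat(b2, k2)
  expect_false(oc2$ok)
  expect_equal(oc2$rule, "spin_orbital")
  # an unmodified open level is compatible with either spin branch
  expect_true(occupation_compat(init_state(parse_csf("u0", "1/2")), k2)$ok)
  # null state
  nl <- apply_sequence(init_state(parse_csf("ud", 0)), "1a- 1a-")
  expect_equal(occupation_compat(nl, nl)$rule, "null")
})

test_that("CSFs are orthonormal under the graph overlap", {
  set.seed(401)
  for (k in 1:60) {
    csf <- rand_csf(sample(2:12, 1))
    s <- init_state(csf)
    expect_equal(overlap(s, s), 1)
    expect_true(radsum_equal(overlap(s, s, exact = TRUE), rational(1)))
  }
  # distinct CSFs with identical occupation pattern and M are orthogonal
  pairs <- list(c("uudd", "udud"), c("uud0d", "udu0d"), c("2uudd", "2udud"))
  for (p in pairs) {
    s1 <- init_state(parse_csf(p[1], 0))
    s2 <- init_state(parse_csf(p[2], 0))
    expect_identical(as.numeric(overlap(s1, s2)), 0)
    expect_true(radsum_is_zero(overlap(s1, s2, exact = TRUE)))
  }
  # different occupation pattern or M short-circuits with a reason
  z <- overlap(init_state(parse_csf("20", 0)), init_state(parse_csf("02", 0)))
  expect_equal(z, 0, ignore_attr = TRUE)
  expect_match(attr(z, "reason"), "occupation|prefix|vanished|end_node")
})

test_that("the worked operator example matches the oracle for every bra", {
  ket <- parse_csf("uud0uu2d", 1)
  seq <- parse_ops("1b+ 7b-")
  bras <- enum_compatible_bras(ket, seq)
  expect_gt(length(bras), 0)
  nonzero <- 0
  for (bra in bras) {
    gx <- matrix_element(bra, seq, ket, exact = TRUE)
    ox <- oracle_matrix_element(bra, seq, ket, exact = TRUE)
    expect_true(radsum_equal(gx, ox))
    expect_equal(matrix_element(bra, seq, ket), as.numeric(gx),
                 tolerance = 1e-13, ignore_attr = TRUE)
    if (!radsum_is_zero(gx)) nonzero <- nonzero + 1
  }
  expect_gt(nonzero, 0)
})

test_that("diagonal number operators count occupations", {
  ket <- parse_csf("uud0uu2d", 1)
  for (i in seq_len(ket$n_o)) {
    tot <- matrix_element(ket, sprintf("%da+ %da-", i, i), ket, exact = TRUE) +
      matrix_element(ket, sprintf("%db+ %db-", i, i), ket, exact = TRUE)
    expect_true(radsum_equal(tot, rational(c("0" = 0, u = 1, d = 1,
                                             "2" = 2)[[ket$t[i]]])))
  }
})

test_that("anticommutation relations hold element-wise", {
  set.seed(402)
  for (k in 1:40) {
    n_o <- sample(2:6, 1)
    ket <- rand_csf(n_o)
    bra <- rand_csf(n_o)
    i <- sample(n_o, 1); j <- sample(n_o, 1)
    si <- sample(c("a", "b"), 1); sj <- sample(c("a", "b"), 1)
    v <- matrix_element(bra, sprintf("%d%s- %d%s+", i, si, j, sj), ket,
                        exact = TRUE) +
      matrix_element(bra, sprintf("%d%s+ %d%s-", j, sj, i, si), ket,
                      exact = TRUE)
    delta <- if (i == j && si == sj)
      matrix_element(bra, "", ket, exact = TRUE) else radsum_zero()
    expect_true(radsum_equal(v, delta))
  }
})

test_that("matrix elements obey adjoint symmetry", {
  set.seed(403)
  for (k in 1:30) {
    n_o <- sample(3:6, 1)
    ket <- rand_csf(n_o)
    bra <- rand_csf(n_o)
    seq <- tryCatch(sample_opseq(ket, sample(c(2, 4), 1)),
                    error = function(e) NULL)
    if (is.null(seq)) next
    lhs <- matrix_element(bra, seq, ket, exact = TRUE)
    rhs <- matrix_element(ket, adjoint_ops(seq), bra, exact = TRUE)
    expect_true(radsum_equal(lhs, rhs))
  }
})

test_that("spin and particle-number operators are recovered exactly", {
  set.seed(404)
  for (k in 1:12) {
    n_o <- sample(2:7, 1)
    csf <- rand_csf(n_o)
    S2 <- csf$b[n_o] / 2 * (csf$b[n_o] / 2 + 1)
    M <- csf$M2 / 2
    # S^2 = S-S+ + Sz(Sz + 1); Sz and N are diagonal sums
    acc <- radsum_zero()
    for (i in seq_len(n_o)) for (j in seq_len(n_o)) {
      acc <- acc + matrix_element(csf, sprintf("%db+ %da- %da+ %db-",
                                               j, j, i, i), csf, exact = TRUE)
    }
    expect_true(radsum_equal(acc + rational(csf$M2 * (csf$M2 + 2), 4),
                             rational(S2 * 4, 4)))
    sz <- radsum_zero()
    nn <- radsum_zero()
    for (i in seq_len(n_o)) {
      na <- matrix_element(csf, sprintf("%da+ %da-", i, i), csf, exact = TRUE)
      nb <- matrix_element(csf, sprintf("%db+ %db-", i, i), csf, exact = TRUE)
      sz <- sz + rational(1, 2) * (na - nb)
      nn <- nn + na + nb
    }
    expect_true(radsum_equal(sz, rational(csf$M2, 2)))
    expect_true(radsum_equal(nn, rational(csf$N)))
  }
})

test_that("vanishing elements return zero values with machine-readable reasons", {
  ket <- parse_csf("20", 0)
  z <- matrix_element(parse_csf("02", 0), "", ket)
  expect_equal(z, 0, ignore_attr = TRUE)
  expect_match(attr(z, "reason"), "occupation")
  z1 <- matrix_element(parse_csf("uu", 1), "", parse_csf("ud", 0))
  expect_match(attr(z1, "reason"), "selection")
  z2 <- matrix_element(ket, "1a- 1a-", ket)
  expect_match(attr(z2, "reason"), "selection|annihilated")
  z3 <- matrix_element(ket, "2a+ 1a-", parse_csf("u0", "1/2"))
  expect_true(is.numeric(z3))
})
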