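# Graph states, elementary-operator transitions, coordinate ranges, graphs.

test_that("operator tokens parse and print round-trip", {
  seq <- parse_ops("1b+ 7b-")
  expect_equal(seq$level, c(1L, 7L))
  expect_equal(seq$spin, c("b", "b"))
  expect_equal(seq$dagger, c(TRUE, FALSE))
  expect_identical(format(seq), "1b+ 7b-")
  expect_equal(nrow(parse_ops("  ")), 0)
  expect_error(parse_ops("1c+"), "malformed")
  adj <- adjoint_ops(seq)
  expect_identical(format(adj), "7b+ 1b-")
})

test_that("the worked two-operator application reproduces the stored data", {
  csf <- parse_csf("uud0uu2d", 1)
  s0 <- init_state(csf)
  expect_equal(s0$q, csf$t)
  expect_equal(s0$tau, rep("0", 8))
  expect_equal(s0$d, rep(0L, 8))
  expect_equal(s0$phi, 1L)

  s1 <- apply_elementary(s0, 7, "b")       # annihilate beta at the 2 level
  expect_equal(s1$q, c("u", "u", "d", "0", "u", "u", "a", "d"))
  expect_equal(s1$tau, rep("0", 8))
  expect_equal(s1$d, c(0, 0, 0, 0, 0, 0, 1, 1))
  expect_equal(s1$phi, 1L)

  s2 <- apply_elementary(s1, 1, "b", dagger = TRUE)
  expect_equal(s2$q, c("2", "u", "d", "0", "u", "u", "a", "d"))
  expect_equal(s2$tau, c("a", "0", "0", "0", "0", "0", "0", "0"))
  expect_equal(s2$d, c(-1, -1, -1, -1, -1, -1, 0, 0))
  expect_equal(s2$phi, -1L)

  # the same through the sequence interface, rightmost first
  s <- apply_sequence(init_state(csf), "1b+ 7b-")
  expect_equal(s[c("q", "tau", "d", "phi")], s2[c("q", "tau", "d", "phi")])

  r <- x_ranges(s)
  expect_equal(r$xmin, c(0, -1, -2, -2, -1, 0, 1, 2))
  expect_equal(r$xmax, c(0, 1, 0, 0, 1, 2, 3, 2))
})

test_that("annihilating operators yield the silent null state", {
  s <- init_state(parse_csf("0u", "1/2"))
  expect_equal(apply_elementary(s, 1, "a")$phi, 0L)          # annihilate empty
  expect_equal(apply_elementary(s, 1, "a", TRUE)$phi, 1L)    # create is fine
  s2 <- apply_sequence(s, "2a+ 1a-")                         # null short-circuits
  expect_equal(s2$phi, 0L)
  s3 <- apply_elementary(s2, 2, "b", TRUE)
  expect_equal(s3$phi, 0L)
  expect_error(apply_elementary(s, 3, "a"), "out of range")
  # empty sequence is the identity
  s4 <- apply_sequence(s, parse_ops(""))
  expect_equal(s4[c("q", "tau", "d", "phi")], s[c("q", "tau", "d", "phi")])
})

test_that("create-then-annihilate restores spin-free levels up to phase", {
  # a_sigma adag_sigma = 1 - n_sigma: on an empty or doubly occupied level the
  # stored data must return to the original with phase +1 (or go null); on a
  # singly coupled level the identity only holds operator-wise, which the
  # anticommutation matrix-element test covers
  set.seed(301)
  hits <- 0
  for (k in 1:60) {
    csf <- rand_csf(sample(2:6, 1))
    fixed <- which(csf$t %in% c("0", "2"))
    if (!length(fixed)) next
    i <- fixed[sample.int(length(fixed), 1)]
    sp <- sample(c("a", "b"), 1)
    s0 <- init_state(csf)
    s <- apply_elementary(apply_elementary(s0, i, sp, dagger = TRUE), i, sp)
    if (csf$t[i] == "2") {
      expect_equal(s$phi, 0L)   # creating on a full level annihilates
    } else {
      hits <- hits + 1
      expect_equal(s$q, s0$q)
      expect_equal(s$tau, s0$tau)
      expect_equal(s$d, s0$d)
      expect_equal(s$phi, 1L)
    }
  }
  expect_gt(hits, 5)
})

test_that("fresh-CSF ranges equal the static boundary/window form", {
  set.seed(302)
  for (k in 1:30) {
    csf <- rand_csf(sample(2:8, 1))
    r <- x_ranges(init_state(csf))
    for (i in seq_len(csf$n_o)) {
      slack <- csf$r[csf$n_o] - csf$r[i]
      expect_equal(r$xmin[i], max(-csf$b[i], csf$M2 - slack))
      expect_equal(r$xmax[i], min(csf$b[i], csf$M2 + slack))
    }
  }
})

test_that("edge weights evaluate the original factors at unshifted x", {
  csf <- parse_csf("uud0uu2d", 1)
  fresh <- init_state(csf)
  expect_equal(edge_weight(fresh, 1, 1, branch = "a"), 1)
  expect_equal(edge_weight(fresh, 4, x_ranges(fresh)$xmin[4]), 1)  # t = 0 level
  s <- apply_sequence(init_state(csf), "1b+ 7b-")
  # level 1: the surviving alpha-branch edge, shifted to x = 0, keeps weight 1
  expect_equal(edge_weight(s, 1, 0), 1)
  expect_identical(format(edge_weight(s, 1, 0, exact = TRUE)), "sqrt(1)")
  # level 7 kept the doubly occupied weight (-1)^b at every node
  for (x in 1:3) expect_equal(edge_weight(s, 7, x), -1)
  expect_error(edge_weight(s, 2, 0), "branch required")
})

test_that("explicit graphs have the closed-form size and path counts", {
  g2 <- build_graph(init_state(csfgraph:::ladder_csf(2)))
  expect_equal(nrow(g2$nodes), 4)
  expect_equal(nrow(g2$edges), 4)
  for (n in c(4, 8, 12)) {
    g <- build_graph(init_state(csfgraph:::ladder_csf(n)))
    expect_equal(nrow(g$nodes), count_closed_shell(n)$N_node)
    expect_equal(nrow(g$edges), count_closed_shell(n)$N_edge)
  }
  csf <- parse_csf("uud0uu2d", 1)
  expect_equal(count_paths(init_state(csf)), nrow(expand_csf(csf)))
  # modified state: paths = determinants surviving both operators
  s <- apply_sequence(init_state(csf), "1b+ 7b-")
  e <- expand_csf(csf)
  survivors <- sum(substr(e$det, 1, 1) == "a")  # a7b keeps all, a1b+ needs p1=a
  expect_equal(count_paths(s), survivors)
})

test_that("graph JSON export is well-formed", {
  s <- apply_sequence(init_state(parse_csf("uud0uu2d", 1)), "1b+ 7b-")
  js <- jsonlite::fromJSON(gdg_json(s))
  expect_equal(js$phi, -1)
  expect_true(all(c("level", "x_from", "x_to", "type", "weight",
                    "weight_exact") %in% names(js$edges)))
  expect_equal(nrow(js$nodes), nrow(build_graph(s)$nodes))
})
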