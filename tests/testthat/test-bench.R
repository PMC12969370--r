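# Seeded samplers and the dual-engine benchmark harness.

test_that("CSF sampling is uniform over its support and reproducible", {
  # (N=2, n_o=2, S2=0) has exactly three CSFs: ud, 20, 02
  set.seed(601)
  draws <- replicate(3000, paste(sample_csf(2, 2, 0, 0)$t, collapse = ""))
  tb <- table(draws)
  expect_setequal(names(tb), c("02", "20", "ud"))
  expect_true(all(tb > 800) && all(tb < 1200))   # uniform ~ 1000 each
  # full shell: single candidate
  expect_equal(paste(sample_csf(8, 4, 0, 0)$t, collapse = ""), "2222")
  # determinism under a fixed seed
  set.seed(77)
  a <- replicate(10, paste(sample_csf(5, 5, 1, 1)$t, collapse = ""))
  set.seed(77)
  b <- replicate(10, paste(sample_csf(5, 5, 1, 1)$t, collapse = ""))
  expect_identical(a, b)
  expect_error(sample_csf(3, 1, 1, 1), "infeasible")
})

test_that("sampled step vectors are always valid for the requested numbers", {
  set.seed(602)
  for (k in 1:50) {
    N <- sample(0:10, 1)
    n_o <- sample(max(1, ceiling(N / 2)):6, 1)
    if (N > 2 * n_o) next
    S2s <- seq(N %% 2, min(N, 2 * n_o - N), by = 2)
    if (!length(S2s)) next
    S2 <- S2s[sample.int(length(S2s), 1)]
    csf <- tryCatch(sample_csf(N, n_o, S2, S2 %% 2 * sample(c(-1, 1), 1)),
                    error = function(e) NULL)
    if (is.null(csf)) next
    expect_equal(csf$N, N)
    expect_equal(csf$b[csf$n_o], S2)
    expect_true(all(csf$b >= 0))
  }
})

test_that("operator sequences respect occupations built rightmost-first", {
  set.seed(603)
  shell <- parse_csf("22", 0)
  seq <- sample_opseq(shell, 2)
  # on a closed shell the rightmost operator must annihilate
  expect_false(seq$dagger[2])
  expect_true(seq$dagger[1])
  for (k in 1:30) {
    csf <- rand_csf(sample(2:6, 1))
    nop <- sample(c(2, 4), 1)
    seq <- tryCatch(sample_opseq(csf, nop), error = function(e) NULL)
    if (is.null(seq)) next
    expect_equal(sum(seq$dagger), nop / 2)
    # occupations stay within [0, 2] along the application order
    occ <- unname(csfgraph:::OCC[csf$t])
    for (j in rev(seq_len(nop))) {
      occ[seq$level[j]] <- occ[seq$level[j]] + if (seq$dagger[j]) 1L else -1L
      expect_true(all(occ >= 0 & occ <= 2))
    }
  }
})

test_that("coupled bra sampling hits exactly the admissible candidate set", {
  set.seed(604)
  ket <- parse_csf("uudd", 0)
  expect_identical(format(sample_coupled_csf(ket, parse_ops(""))), format(ket))
  for (k in 1:10) {
    ket <- rand_csf(4)
    seq <- tryCatch(sample_opseq(ket, 2), error = function(e) NULL)
    if (is.null(seq)) next
    cand <- enum_compatible_bras(ket, seq)
    admissible <- Filter(function(b) selection_rules(b, ket, seq)$ok, cand)
    if (!length(admissible)) {
      expect_error(sample_coupled_csf(ket, seq), "no CSF")
      next
    }
    keys <- sort(vapply(admissible, format, ""))
    draws <- unique(replicate(120, format(sample_coupled_csf(ket, seq))))
    expect_true(all(draws %in% keys))
    if (length(keys) <= 4) expect_setequal(sort(draws), keys)
  }
})

test_that("the benchmark reports machine-precision graph errors", {
  res <- run_benchmark(bench_config(6, 6, S2 = 0, N_op = 2, n_coup = 40,
                                    seed = 11))
  tb <- res$results
  expect_equal(tb$engine, c("graph", "determinants"))
  expect_true(all(tb$rmsd <= tb$max_abs + 1e-300))
  expect_lt(tb$max_abs[tb$engine == "graph"], 1e-13)
  expect_lt(tb$max_abs[tb$engine == "determinants"], 1e-12)
  expect_gte(res$zero_fraction, 0)
  expect_lte(res$zero_fraction, 1)
  expect_gt(tb$n_det[1], 0)
  # eight-operator sequences (four-particle-density-style)
  res8 <- run_benchmark(bench_config(7, 7, S2 = 1, M2 = 1, N_op = 8,
                                     n_coup = 25, seed = 12))
  expect_lt(res8$results$max_abs[1], 1e-13)
  expect_lt(res8$results$max_abs[2], 1e-12)
  # identical seeds reproduce identical reports (timings are wall clock)
  res2 <- run_benchmark(bench_config(6, 6, S2 = 0, N_op = 2, n_coup = 40,
                                     seed = 11))
  keep <- setdiff(names(res$results), "time_s")
  expect_identical(res$results[keep], res2$results[keep])
  expect_identical(res$zero_fraction, res2$zero_fraction)
})

test_that("benchmark reports serialize to TSV and JSON", {
  res <- run_benchmark(bench_config(4, 4, S2 = 0, N_op = 2, n_coup = 10,
                                    seed = 5))
  tsv <- tempfile(fileext = ".tsv")
  js <- tempfile(fileext = ".json")
  write_bench_report(res, tsv)
  write_bench_report(res, js, format = "json")
  back <- utils::read.delim(tsv)
  expect_equal(back$rmsd, res$results$rmsd)
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$results$max_abs, res$results$max_abs)
  unlink(c(tsv, js))
})
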