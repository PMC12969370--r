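# Seeded random generation of CSFs, operator sequences and coupled bra CSFs,
# plus the dual-engine accuracy/timing benchmark.
#
# Sampling is uniform over the respective candidate sets, implemented by
# dynamic programming over path counts; randomness comes from R's default
# Mersenne-Twister stream so that a single seed reproduces a whole run.

#' Benchmark configuration
#'
#' @param N electron count.
#' @param n_o orbital count (`N <= 2 n_o`).
#' @param S2 doubled total spin of the sampled kets (`S2 = 2S`, parity of
#'   `N`).
#' @param M2 doubled spin projection (`|M2| <= S2`, same parity); defaults to
#'   `S2`.
#' @param N_op even number of elementary operators per sequence (half
#'   creation, half annihilation).
#' @param n_coup number of matrix elements to sample.
#' @param seed optional integer seed.
#' @return A `bench_config` list.
#' @export
bench_config <- function(N, n_o, S2, M2 = S2, N_op = 2L, n_coup = 100L,
                         seed = NULL) {
  stopifnot(N >= 0, N <= 2 * n_o, S2 >= 0, S2 %% 2 == N %% 2,
            abs(M2) <= S2, (M2 - S2) %% 2 == 0,
            N_op %% 2 == 0, N_op >= 0, n_coup >= 1)
  structure(list(N = as.integer(N), n_o = as.integer(n_o),
                 S2 = as.integer(S2), M2 = as.integer(M2),
                 N_op = as.integer(N_op), n_coup = as.integer(n_coup),
                 seed = seed),
            class = "bench_config")
}

# backward DP: g[i+1, n+1, b+1] = number of valid step-vector completions
# from (level i, n electrons, doubled spin b) to (n_o, N, S2)
csf_count_table <- function(N, n_o, S2) {
  g <- array(0, dim = c(n_o + 1L, N + 1L, n_o + 2L))
  if (S2 <= n_o) g[n_o + 1L, N + 1L, S2 + 1L] <- 1
  steps <- list(c(0L, 0L), c(1L, 1L), c(1L, -1L), c(2L, 0L))
  for (i in n_o:1) {
    for (n in 0:min(N, 2L * (i - 1L))) {
      for (b in 0:min(i - 1L, n)) {
        tot <- 0
        for (s in steps) {
          n2 <- n + s[1]
          b2 <- b + s[2]
          if (n2 <= N && b2 >= 0L && b2 <= n_o) tot <- tot + g[i + 1L, n2 + 1L, b2 + 1L]
        }
        g[i, n + 1L, b + 1L] <- tot
      }
    }
  }
  if (max(g) > 2^53) stop("CSF count exceeds exact double-integer range")
  g
}

#' Sample a random CSF uniformly
#'
#' Draws a step vector uniformly among all valid genealogical CSFs with the
#' prescribed electron count `N`, orbital count `n_o` and final doubled spin
#' `S2`, by dynamic programming over completion counts; the spin projection
#' is fixed to `M2`.
#'
#' @inheritParams bench_config
#' @param table optional precomputed count table (internal reuse).
#' @return A `"csf"`.
#' @export
sample_csf <- function(N, n_o, S2, M2 = S2, table = NULL) {
  if (is.null(table)) table <- csf_count_table(N, n_o, S2)
  if (table[1, 1, 1] == 0) stop("infeasible (N, n_o, S2)")
  lab <- c("0", "u", "d", "2")
  dn <- c(0L, 1L, 1L, 2L)
  db2 <- c(0L, 1L, -1L, 0L)
  t <- character(n_o)
  n <- 0L
  b <- 0L
  for (i in seq_len(n_o)) {
    wt <- numeric(4)
    for (s in 1:4) {
      n2 <- n + dn[s]
      b2 <- b + db2[s]
      if (n2 <= N && b2 >= 0L && b2 <= n_o) wt[s] <- table[i + 1L, n2 + 1L, b2 + 1L]
    }
    s <- sample.int(4, 1, prob = wt)
    t[i] <- lab[s]
    n <- n + dn[s]
    b <- b + db2[s]
  }
  new_csf(t, M2)
}

#' Sample a random operator sequence for a CSF
#'
#' Builds a sequence of `N_op` elementary operators, half creation and half
#' annihilation, constructed rightmost-first while tracking the evolving
#' occupation numbers: every annihilation targets a currently occupied
#' orbital and every creation a currently not doubly occupied orbital, with
#' spins chosen uniformly.  Such a sequence can still annihilate the state
#' through a spin mismatch (occupation numbers do not fix the spin of a
#' singly occupied level); that is allowed and those elements are zero.
#'
#' @param csf the ket CSF.
#' @param N_op even sequence length.
#' @return An `op_seq` in written (leftmost-first) order.
#' @export
sample_opseq <- function(csf, N_op) {
  stopifnot(N_op %% 2 == 0)
  occ <- unname(OCC[csf$t])
  n_ann <- N_op / 2
  n_cre <- N_op / 2
  lev <- integer(0)
  sp <- character(0)
  dag <- logical(0)
  for (k in seq_len(N_op)) {
    can_ann <- n_ann > 0 && any(occ >= 1L)
    can_cre <- n_cre > 0 && any(occ <= 1L)
    if (!can_ann && !can_cre)
      stop("cannot extend operator sequence: no feasible operator")
    create <- if (can_ann && can_cre) stats::runif(1) < 0.5 else can_cre
    pool <- if (create) which(occ <= 1L) else which(occ >= 1L)
    i <- pool[sample.int(length(pool), 1)]
    lev <- c(lev, i)
    sp <- c(sp, c("a", "b")[sample.int(2, 1)])
    dag <- c(dag, create)
    occ[i] <- occ[i] + if (create) 1L else -1L
    if (create) n_cre <- n_cre - 1L else n_ann <- n_ann - 1L
  }
  # generated rightmost-first; written order is the reverse
  structure(data.frame(level = rev(lev), spin = rev(sp), dagger = rev(dag),
                       stringsAsFactors = FALSE),
            class = c("op_seq", "data.frame"))
}

# occupation pattern of the ket after the sequence (well-defined even if the
# state is annihilated by a spin clash)
modified_occ <- function(csf, seq) {
  occ <- unname(OCC[csf$t])
  if (nrow(seq)) for (k in rev(seq_len(nrow(seq)))) {
    i <- seq$level[k]
    occ[i] <- occ[i] + if (seq$dagger[k]) 1L else -1L
    if (occ[i] < 0L || occ[i] > 2L) stop("sequence incompatible with occupations")
  }
  occ
}

#' Sample a bra CSF coupled to an operator-modified ket
#'
#' Draws a CSF uniformly among those that can have a nonzero matrix element
#' with `O |ket>` according to the occupation pattern and the per-level spin
#' selection rules: the bra's occupations must match the modified ket's, its
#' projection is `M' = M + M^op`, and every intermediate doubled spin must
#' satisfy the triangle, projection-bound and parity conditions of
#' [selection_rules()].  Sampling is uniform via dynamic programming over the
#' admissible intermediate-spin paths.
#'
#' @param csf the ket CSF.
#' @param seq the operator sequence (an `op_seq` or token string).
#' @return A `"csf"` for the bra.
#' @export
sample_coupled_csf <- function(csf, seq) {
  if (is.character(seq)) seq <- parse_ops(seq)
  n_o <- csf$n_o
  occ <- modified_occ(csf, seq)
  tl <- op_tallies(seq, n_o)
  M2p <- csf$M2 + tl$M2op
  # admissibility of intermediate doubled spin b' at level i: triangle,
  # projection-bound and parity conditions of the per-level selection rules
  ok_b <- function(i, b) {
    b >= 0L && b <= n_o &&
      abs(csf$b[i] - b) <= tl$nop[i] &&
      csf$b[i] + b >= abs(tl$xop[i]) &&
      (abs(csf$b[i] - b) - tl$nop[i]) %% 2L == 0L
  }
  # h[i+1, b+1] = number of admissible completions given b'_i = b
  h <- matrix(0, nrow = n_o + 1L, ncol = n_o + 1L)
  for (b in 0:n_o)
    if (ok_b(n_o, b) && b >= abs(M2p) && (b - M2p) %% 2L == 0L)
      h[n_o + 1L, b + 1L] <- 1
  step_b <- function(i) if (occ[i] == 1L) c(1L, -1L) else 0L
  for (i in (n_o - 1L):0) {
    for (b in 0:n_o) {
      if (i > 0L && !ok_b(i, b)) next
      tot <- 0
      for (db in step_b(i + 1L)) {
        b2 <- b + db
        if (b2 >= 0L && b2 <= n_o && ok_b(i + 1L, b2))
          tot <- tot + h[i + 2L, b2 + 1L]
      }
      h[i + 1L, b + 1L] <- tot
    }
  }
  if (h[1, 1] == 0) stop("no CSF can couple to this (ket, sequence) pair")
  t <- character(n_o)
  b <- 0L
  for (i in seq_len(n_o)) {
    dbs <- step_b(i)
    w <- vapply(dbs, function(db) {
      b2 <- b + db
      if (b2 >= 0L && b2 <= n_o && ok_b(i, b2)) h[i + 1L, b2 + 1L] else 0
    }, 0)
    s <- if (length(dbs) == 1L) 1L else sample.int(2, 1, prob = w)
    db <- dbs[s]
    b <- b + db
    t[i] <- if (occ[i] == 0L) "0" else if (occ[i] == 2L) "2"
            else if (db == 1L) "u" else "d"
  }
  new_csf(t, M2p)
}

#' Run the dual-engine benchmark
#'
#' Samples `n_coup` matrix-element triples (ket CSF, operator sequence,
#' coupled bra CSF), computes each element exactly with the graph engine as
#' the reference, and in floating point with both the graph engine and the
#' determinant-expansion oracle.  Reports, per engine, the root-mean-square
#' deviation and maximum absolute error against the exact reference, the
#' total time, and the total number of determinants in all ket expansions
#' (duplicates across repeated CSFs included).
#'
#' @param cfg a [bench_config()].
#' @return A list of class `"bench_result"`: `results` (one row per engine),
#'   `zero_fraction` (share of sampled elements that are exactly zero) and
#'   `config`.
#' @examples
#' \donttest{
#' run_benchmark(bench_config(6, 6, S2 = 0, N_op = 2, n_coup = 25, seed = 1))
#' }
#' @export
run_benchmark <- function(cfg) {
  stopifnot(inherits(cfg, "bench_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  tab <- csf_count_table(cfg$N, cfg$n_o, cfg$S2)
  n <- cfg$n_coup
  ref <- g_val <- o_val <- numeric(n)
  ref_zero <- logical(n)
  t_graph <- t_det <- 0
  n_det <- 0
  oracle_skipped <- 0L
  for (k in seq_len(n)) {
    ket <- sample_csf(cfg$N, cfg$n_o, cfg$S2, cfg$M2, table = tab)
    seq <- NULL
    bra <- NULL
    for (try in 1:50) {
      seq <- sample_opseq(ket, cfg$N_op)
      bra <- tryCatch(sample_coupled_csf(ket, seq), error = function(e) NULL)
      if (!is.null(bra)) break
    }
    if (is.null(bra)) stop("could not sample a coupled bra CSF in 50 tries")
    n_det <- n_det + count_determinants(ket)
    rx <- matrix_element(bra, seq, ket, exact = TRUE)
    ref[k] <- as.numeric(rx)
    ref_zero[k] <- radsum_is_zero(rx)
    t0 <- proc.time()[["elapsed"]]
    g_val[k] <- matrix_element(bra, seq, ket, exact = FALSE)
    t_graph <- t_graph + (proc.time()[["elapsed"]] - t0)
    if (ket$r[ket$n_o] <= ORACLE_MAX_OPEN && bra$r[bra$n_o] <= ORACLE_MAX_OPEN) {
      t0 <- proc.time()[["elapsed"]]
      o_val[k] <- oracle_matrix_element(bra, seq, ket, exact = FALSE)
      t_det <- t_det + (proc.time()[["elapsed"]] - t0)
    } else {
      o_val[k] <- NA_real_
      oracle_skipped <- oracle_skipped + 1L
    }
  }
  err_g <- g_val - ref
  err_o <- o_val - ref
  res <- data.frame(
    engine = c("graph", "determinants"),
    n_eval = c(n, n - oracle_skipped),
    rmsd = c(sqrt(mean(err_g^2)), sqrt(mean(err_o^2, na.rm = TRUE))),
    max_abs = c(max(abs(err_g)), suppressWarnings(max(abs(err_o), na.rm = TRUE))),
    time_s = c(t_graph, t_det),
    n_det = n_det,
    stringsAsFactors = FALSE)
  structure(list(results = res, zero_fraction = mean(ref_zero),
                 oracle_skipped = oracle_skipped, config = cfg),
            class = "bench_result")
}

#' @export
print.bench_result <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("benchmark: N=%d n_o=%d 2S=%d 2M=%d N_op=%d n_coup=%d\n",
              cfg$N, cfg$n_o, cfg$S2, cfg$M2, cfg$N_op, cfg$n_coup))
  print(x$results, row.names = FALSE)
  cat(sprintf("zero elements: %.1f%%; oracle skipped: %d\n",
              100 * x$zero_fraction, x$oracle_skipped))
  invisible(x)
}

#' Write a benchmark report
#'
#' @param x a `bench_result`.
#' @param path output file.
#' @param format `"tsv"` or `"json"`.
#' @return `path`, invisibly.
#' @export
write_bench_report <- function(x, path, format = c("tsv", "json")) {
  format <- match.arg(format)
  if (format == "tsv") {
    utils::write.table(x$results, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    jsonlite::write_json(list(config = unclass(x$config),
                              results = x$results,
                              zero_fraction = x$zero_fraction),
                         path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}
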