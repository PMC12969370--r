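# Shared fixtures and independent oracles, all built in code.

# enumerate every valid step vector over n_o levels (intermediate 2S >= 0)
all_step_vectors <- function(n_o) {
  res <- list(character(0))
  bs <- 0L
  for (i in seq_len(n_o)) {
    res2 <- list()
    bs2 <- integer(0)
    for (k in seq_along(res)) {
      for (s in c("0", "u", "d", "2")) {
        b2 <- bs[k] + c("0" = 0L, u = 1L, d = -1L, "2" = 0L)[[s]]
        if (b2 >= 0L) {
          res2[[length(res2) + 1L]] <- c(res[[k]], s)
          bs2 <- c(bs2, b2)
        }
      }
    }
    res <- res2
    bs <- bs2
  }
  list(t = vapply(res, paste, "", collapse = ""), b_end = bs)
}

# every CSF (step vector x admissible M) at a given n_o
all_csfs <- function(n_o) {
  av <- all_step_vectors(n_o)
  out <- list()
  for (k in seq_along(av$t)) {
    for (m2 in seq(-av$b_end[k], av$b_end[k], by = 2)) {
      out[[length(out) + 1L]] <- parse_csf(av$t[k], m2 / 2)
    }
  }
  out
}

# a random CSF with random electron count, spin and projection
rand_csf <- function(n_o) {
  repeat {
    N <- sample(0:(2 * n_o), 1)
    S2max <- min(N, 2 * n_o - N)
    S2s <- seq(N %% 2, S2max, by = 2)
    if (!length(S2s)) next
    S2 <- S2s[sample.int(length(S2s), 1)]
    M2 <- seq(-S2, S2, by = 2)[sample.int(S2 + 1, 1)]
    csf <- tryCatch(sample_csf(N, n_o, S2, M2), error = function(e) NULL)
    if (!is.null(csf)) return(csf)
  }
}

# independent brute-force expansion: enumerate ALL spin assignments of the
# singly occupied levels (2^r of them), keep those with the right projection
# whose path stays inside the spin boundary, and evaluate the coefficient
# with the genealogical-coupling formulas written out directly
brute_expand <- function(csf) {
  t <- csf$t
  b <- csf$b
  sing <- which(t %in% c("u", "d"))
  r <- length(sing)
  dets <- character(0)
  coefs <- numeric(0)
  for (m in seq_len(max(1L, 2L^r)) - 1L) {
    bits <- if (r > 0) as.integer(intToBits(m))[seq_len(r)] else integer(0)
    p <- ifelse(t == "0", "0", ifelse(t == "2", "2", NA))
    p[sing] <- ifelse(bits == 1L, "a", "b")
    x <- cumsum(c("0" = 0L, a = 1L, b = -1L, "2" = 0L)[p])
    if (x[csf$n_o] != csf$M2 || any(abs(x) > b)) next
    cf <- 1
    for (i in seq_len(csf$n_o)) {
      cf <- cf * switch(paste0(t[i], p[i]),
        "00" = 1,
        "22" = (-1)^b[i],
        "ua" = sqrt((b[i] + x[i]) / (2 * b[i])),
        "ub" = sqrt((b[i] - x[i]) / (2 * b[i])),
        "da" = (-1)^(b[i] + 1) * sqrt((b[i] - x[i] + 2) / (2 * (b[i] + 2))),
        "db" = (-1)^b[i] * sqrt((b[i] + x[i] + 2) / (2 * (b[i] + 2))))
    }
    if (cf != 0) {
      dets <- c(dets, paste(p, collapse = ""))
      coefs <- c(coefs, cf)
    }
  }
  data.frame(det = dets, coefficient = coefs, stringsAsFactors = FALSE)
}

# independent fermionic sign convention: spin orbitals ordered level-major
# with alpha before beta; a determinant is the ordered product of creators;
# operators pick up (-1)^(number of occupied spin orbitals preceding theirs)
jw_apply <- function(det_string, level, spin, dagger) {
  p <- strsplit(det_string, "")[[1]]
  occ <- matrix(FALSE, nrow = length(p), ncol = 2) # [level, alpha/beta]
  occ[p == "a" | p == "2", 1] <- TRUE
  occ[p == "b" | p == "2", 2] <- TRUE
  col <- if (spin == "a") 1L else 2L
  if (dagger && occ[level, col]) return(NULL)
  if (!dagger && !occ[level, col]) return(NULL)
  flat <- as.vector(t(occ)) # order: 1a, 1b, 2a, 2b, ...
  pos <- 2L * (level - 1L) + col
  n_below <- sum(flat[seq_len(pos - 1L)])
  occ[level, col] <- dagger
  lab <- ifelse(occ[, 1] & occ[, 2], "2",
                ifelse(occ[, 1], "a", ifelse(occ[, 2], "b", "0")))
  list(det = paste(lab, collapse = ""), phase = if (n_below %% 2 == 0) 1L else -1L)
}

# all bra CSFs that match an operator-modified ket in occupation pattern and
# spin projection (the exhaustive candidate set for nonzero matrix elements;
# occupation-incompatible bras share no determinant with the modified ket)
enum_compatible_bras <- function(ket, seq) {
  if (is.character(seq)) seq <- parse_ops(seq)
  occ <- csfgraph:::modified_occ(ket, seq)
  M2p <- ket$M2 + csfgraph:::op_tallies(seq, ket$n_o)$M2op
  n <- length(occ)
  if (abs(M2p) > n) return(list())
  out <- list()
  rec <- function(i, t, b) {
    if (i > n) {
      if (b >= abs(M2p) && (b - M2p) %% 2L == 0L)
        out[[length(out) + 1L]] <<- parse_csf(paste(t, collapse = ""), M2p / 2)
      return(invisible(NULL))
    }
    if (occ[i] == 1L) {
      rec(i + 1L, c(t, "u"), b + 1L)
      if (b >= 1L) rec(i + 1L, c(t, "d"), b - 1L)
    } else {
      rec(i + 1L, c(t, if (occ[i] == 0L) "0" else "2"), b)
    }
  }
  rec(1L, character(0), 0L)
  out
}

# concatenate two operator sequences in written order
cat_ops <- function(a, b) {
  structure(rbind(as.data.frame(a), as.data.frame(b)),
            class = c("op_seq", "data.frame"))
}

expect_radsum_equal <- function(x, y) {
  expect_true(radsum_equal(x, as_radsum(y)),
              label = sprintf("radsum %s == %s", format(x), format(as_radsum(y))))
}
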