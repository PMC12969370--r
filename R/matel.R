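# Selection-rule screening and the graph-overlap sweep.
#
# A matrix element <t',M'| O |t,M> is computed in two stages: the operator
# sequence is folded into the ket's compact graph state, and the overlap of
# the bra graph with the modified ket graph is then evaluated by propagating
# a vector of node values level by level through the overlaid graphs.  Every
# vanishing matrix element is returned as a zero VALUE carrying a
# machine-readable reason, never raised as an error, so that screening
# statistics can be collected.

zero_value <- function(exact, reason, level = NA_integer_) {
  v <- if (exact) radsum_zero() else 0
  attr(v, "reason") <- reason
  attr(v, "level") <- level
  v
}

#' Spin selection rules for a matrix element
#'
#' Necessary per-level conditions for \eqn{\langle t',M'|\hat O|t,M\rangle}
#' to be nonzero.  With doubled quantities (\eqn{b=2S}, \eqn{x=2M}),
#' \eqn{N_i^{op}} the number of elementary operators at level \eqn{\le i} and
#' \eqn{x_i^{op}} their spin-projection contribution, the rules are:
#' total projection balance \eqn{2M' = 2M + 2M^{op}}; for every level the
#' spin triangle bounds \eqn{|b_i - b_i'| \le N_i^{op}} and
#' \eqn{b_i + b_i' \ge |x_i^{op}|}; and the parity condition
#' \eqn{|b_i - b_i'| \equiv N_i^{op} \pmod 2}.
#'
#' @param bra,ket CSFs over the same orbital count.
#' @param seq an `op_seq` or token string.
#' @return A list of class `"selection_report"`: `ok` flag and, on failure,
#'   the first failing `rule` (`"projection"`, `"triangle"`,
#'   `"projection_bound"`, `"parity"`) and `level`.
#' @export
selection_rules <- function(bra, ket, seq) {
  stopifnot(inherits(bra, "csf"), inherits(ket, "csf"))
  if (is.character(seq)) seq <- parse_ops(seq)
  if (bra$n_o != ket$n_o) stop("bra and ket have different orbital counts")
  tl <- op_tallies(seq, ket$n_o)
  rep_ <- function(ok, rule = NA_character_, level = NA_integer_)
    structure(list(ok = ok, rule = rule, level = level),
              class = "selection_report")
  if (bra$M2 != ket$M2 + tl$M2op) return(rep_(FALSE, "projection"))
  db <- abs(ket$b - bra$b)
  for (i in seq_len(ket$n_o)) {
    if (db[i] > tl$nop[i]) return(rep_(FALSE, "triangle", i))
    if (ket$b[i] + bra$b[i] < abs(tl$xop[i]))
      return(rep_(FALSE, "projection_bound", i))
    if ((db[i] - tl$nop[i]) %% 2L != 0L) return(rep_(FALSE, "parity", i))
  }
  rep_(TRUE)
}

#' @export
print.selection_report <- function(x, ...) {
  if (x$ok) cat("<selection_report> pass\n")
  else cat("<selection_report> fail: ", x$rule,
           if (!is.na(x$level)) paste0(" at level ", x$level), "\n", sep = "")
  invisible(x)
}

#' Occupation compatibility of two graph states
#'
#' The overlap of two graphs requires matching edges at every level: equal
#' occupations, no alpha/beta clash between two spin-fixed levels, and both
#' phases nonzero.
#'
#' @param bra_state,ket_state `gdg_state` objects.
#' @return A list: `ok`, `rule` (`"null"`, `"occupation"`, `"spin_orbital"`),
#'   `level`.
#' @export
occupation_compat <- function(bra_state, ket_state) {
  qb <- bra_state$q
  qk <- ket_state$q
  if (bra_state$phi == 0L || ket_state$phi == 0L)
    return(list(ok = FALSE, rule = "null", level = NA_integer_))
  occ_diff <- which(OCC[qb] != OCC[qk])
  if (length(occ_diff))
    return(list(ok = FALSE, rule = "occupation", level = unname(occ_diff[1])))
  clash <- which(qb %in% c("a", "b") & qk %in% c("a", "b") & qb != qk)
  if (length(clash))
    return(list(ok = FALSE, rule = "spin_orbital", level = unname(clash[1])))
  list(ok = TRUE, rule = NA_character_, level = NA_integer_)
}

# node-value containers: float mode uses a numeric vector indexed by x+off,
# exact mode a list of radsum pointers (NULL = exact zero)
v_new <- function(exact, size) if (exact) vector("list", size) else numeric(size)
v_get <- function(v, idx, exact) {
  if (!exact) return(v[idx])
  if (idx < 1 || idx > length(v)) return(NULL)
  v[[idx]]
}

#' Overlap of two graph states
#'
#' Level-by-level sweep of node values through the overlaid graphs of the bra
#' and ket states.  Starting below the lowest operator level \eqn{\kappa}
#' both states are unmodified CSFs, so the sweep starts at \eqn{\kappa} with
#' the value \eqn{\phi\phi'} on every node \eqn{x \in \{-b_{min}, -b_{min}+2,
#' \ldots, b_{min}\}}, \eqn{b_{min} = b_{\kappa-1}}; it requires
#' \eqn{t_i' = t_i} below \eqn{\kappa} (orthonormality makes the value zero
#' otherwise).  At each level only coordinates in the intersection of the two
#' states' ranges are updated; a level updating nothing, or updating only
#' exact zeros, short-circuits to zero.  At the last level the single end
#' node \eqn{x = 2M + d_{n_o}} is updated and its value is the overlap.
#'
#' @param bra_state,ket_state `gdg_state` objects over the same orbital count.
#' @param exact if `TRUE` compute with exact radical arithmetic.
#' @return A double or `radsum`; zeros carry a `reason` attribute.
#' @examples
#' s <- init_state(parse_csf("uud0uu2d", 1))
#' overlap(s, s)  # 1: any CSF is normalized
#' @export
overlap <- function(bra_state, ket_state, exact = FALSE) {
  stopifnot(inherits(bra_state, "gdg_state"), inherits(ket_state, "gdg_state"))
  csfK <- ket_state$csf
  csfB <- bra_state$csf
  n_o <- csfK$n_o
  if (csfB$n_o != n_o) stop("bra and ket have different orbital counts")
  oc <- occupation_compat(bra_state, ket_state)
  if (!oc$ok) return(zero_value(exact, oc$rule, oc$level))
  applied <- c(bra_state$applied, ket_state$applied)
  kappa <- if (length(applied)) min(applied) else 1L
  if (kappa > 1L) {
    pre <- seq_len(kappa - 1L)
    diff <- which(csfB$t[pre] != csfK$t[pre])
    if (length(diff)) return(zero_value(exact, "prefix", diff[1]))
  }
  b_min <- if (kappa > 1L) csfK$b[kappa - 1L] else 0L
  rk <- x_ranges(ket_state)
  rb <- x_ranges(bra_state)
  # node coordinates live in [-n_o, n_o]; one padding slot on each side keeps
  # the v[x-1]/v[x+1] lookups of the slanted-edge rows in range
  off <- n_o + 2L
  phi2 <- bra_state$phi * ket_state$phi
  v <- v_new(exact, 2L * n_o + 3L)
  init_xs <- seq.int(-b_min, b_min, by = 2L)
  if (exact) {
    pr <- rational(phi2)
    for (x in init_xs) v[[x + off]] <- pr
  } else {
    v[init_xs + off] <- phi2
  }
  for (i in kappa:n_o) {
    lo <- max(rk$xmin[i], rb$xmin[i])
    hi <- min(rk$xmax[i], rb$xmax[i])
    if (i == n_o) {
      xf <- csfK$M2 + ket_state$d[n_o]
      if (xf != csfB$M2 + bra_state$d[n_o])
        return(zero_value(exact, "end_node", i))
      lo <- max(lo, xf)
      hi <- min(hi, xf)
    }
    # node parities of the two lattices must agree
    pk <- (csfK$b[i] + ket_state$d[i]) %% 2L
    pb <- (csfB$b[i] + bra_state$d[i]) %% 2L
    if (pk != pb) return(zero_value(exact, "parity", i))
    if (((lo %% 2L) + 2L) %% 2L != pk) lo <- lo + 1L
    if (lo > hi) return(zero_value(exact, "empty_range", i))
    xs <- seq.int(lo, hi, by = 2L)
    qk <- ket_state$q[i]
    qb <- bra_state$q[i]
    tk <- csfK$t[i]
    tb <- csfB$t[i]
    bk <- csfK$b[i]
    bb <- csfB$b[i]
    dk <- ket_state$d[i]
    db <- bra_state$d[i]
    ttk <- if (qk %in% c("u", "d")) NULL else tau_tilde(ket_state, i)
    ttb <- if (qb %in% c("u", "d")) NULL else tau_tilde(bra_state, i)
    nv <- v_new(exact, 2L * n_o + 3L)
    any_nz <- FALSE
    for (x in xs) {
      if (exact) {
        wk <- function(p) cg_rs(tk, p, bk, x - dk)
        wb <- function(p) cg_rs(tb, p, bb, x - db)
        val <- NULL
        addmul <- function(acc, src, fk, fb) {
          if (is.null(src)) return(acc)
          if (is.null(acc)) acc <- radsum_zero()
          rs_addmul(acc, src, fk * fb)
        }
        if (!qk %in% c("u", "d") && !qb %in% c("u", "d")) {
          shift <- switch(qk, "a" = -1L, "b" = 1L, 0L)
          val <- addmul(val, v_get(v, x + shift + off, TRUE), wk(ttk), wb(ttb))
        } else if (!qk %in% c("u", "d")) {       # ket single edge, bra open
          shift <- switch(qk, "a" = -1L, "b" = 1L, 0L)
          br <- if (qk == "a") "a" else "b"
          val <- addmul(val, v_get(v, x + shift + off, TRUE), wk(ttk), wb(br))
        } else if (!qb %in% c("u", "d")) {       # bra single edge, ket open
          shift <- switch(qb, "a" = -1L, "b" = 1L, 0L)
          br <- if (qb == "a") "a" else "b"
          val <- addmul(val, v_get(v, x + shift + off, TRUE), wk(br), wb(ttb))
        } else {                                  # both open: sum two branches
          val <- addmul(val, v_get(v, x - 1L + off, TRUE), wk("a"), wb("a"))
          val <- addmul(val, v_get(v, x + 1L + off, TRUE), wk("b"), wb("b"))
        }
        if (!is.null(val) && !radsum_is_zero(val)) {
          nv[[x + off]] <- val
          any_nz <- TRUE
        }
      } else {
        if (!qk %in% c("u", "d") && !qb %in% c("u", "d")) {
          shift <- switch(qk, "a" = -1L, "b" = 1L, 0L)
          val <- v[x + shift + off] *
            cg_num(tk, ttk, bk, x - dk) * cg_num(tb, ttb, bb, x - db)
        } else if (!qk %in% c("u", "d")) {
          shift <- switch(qk, "a" = -1L, "b" = 1L, 0L)
          br <- if (qk == "a") "a" else "b"
          val <- v[x + shift + off] *
            cg_num(tk, ttk, bk, x - dk) * cg_num(tb, br, bb, x - db)
        } else if (!qb %in% c("u", "d")) {
          shift <- switch(qb, "a" = -1L, "b" = 1L, 0L)
          br <- if (qb == "a") "a" else "b"
          val <- v[x + shift + off] *
            cg_num(tk, br, bk, x - dk) * cg_num(tb, ttb, bb, x - db)
        } else {
          val <- v[x - 1L + off] *
            cg_num(tk, "a", bk, x - dk) * cg_num(tb, "a", bb, x - db) +
            v[x + 1L + off] *
            cg_num(tk, "b", bk, x - dk) * cg_num(tb, "b", bb, x - db)
        }
        if (val != 0) {
          nv[x + off] <- val
          any_nz <- TRUE
        }
      }
    }
    if (!any_nz) return(zero_value(exact, "vanished", i))
    v <- nv
  }
  xf <- csfK$M2 + ket_state$d[n_o] + off
  if (exact) v[[xf]] else v[xf]
}

#' Matrix element of an operator sequence between two CSFs
#'
#' Runs the full pipeline for \eqn{\langle t',M'|\hat O|t,M\rangle}: spin
#' selection screening ([selection_rules()]), folding of the operator
#' sequence into the ket state ([apply_sequence()]), occupation compatibility
#' ([occupation_compat()]) and the overlap sweep ([overlap()]).  The bra is
#' used as a fresh, unmodified CSF.  All vanishing cases return zero with a
#' `reason` attribute.
#'
#' @param bra,ket CSFs over the same orbital count.
#' @param seq an `op_seq` or token string (`""` is the identity).
#' @param exact if `TRUE` compute with exact radical arithmetic and return a
#'   `radsum`.
#' @return A double, or a `radsum` when `exact = TRUE`.
#' @examples
#' ket <- parse_csf("uud0uu2d", 1)
#' matrix_element(ket, "", ket)                       # 1
#' matrix_element(parse_csf("2ud0uuud", 2), "1b+ 7b-", ket)
#' @export
matrix_element <- function(bra, seq, ket, exact = FALSE) {
  stopifnot(inherits(bra, "csf"), inherits(ket, "csf"))
  if (is.character(seq)) seq <- parse_ops(seq)
  if (bra$n_o != ket$n_o) stop("bra and ket have different orbital counts")
  sr <- selection_rules(bra, ket, seq)
  if (!sr$ok) return(zero_value(exact, paste0("selection_", sr$rule), sr$level))
  ks <- apply_sequence(init_state(ket), seq)
  if (state_is_null(ks)) return(zero_value(exact, "annihilated"))
  overlap(init_state(bra), ks, exact = exact)
}
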