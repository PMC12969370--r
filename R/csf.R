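# CSF and determinant representations, genealogical bookkeeping, and the
# Clebsch-Gordan edge factors, using the step-value alphabet {0, u, d, 2}
# (empty, spin-raising single, spin-lowering single, doubly occupied).
# All spin bookkeeping uses doubled integers internally: b = 2S, x = 2M.

# occupation of step / determinant labels (a = alpha, b = beta)
OCC <- c("0" = 0L, "u" = 1L, "d" = 1L, "2" = 2L, "a" = 1L, "b" = 1L)
# change in doubled intermediate spin per step value
DB <- c("0" = 0L, "u" = 1L, "d" = -1L, "2" = 0L)
# change in doubled spin projection per determinant label
DX <- c("0" = 0L, "a" = 1L, "b" = -1L, "2" = 0L)

norm_spin_label <- function(p) {
  p <- as.character(p)
  p[p == "α" | p == "alpha"] <- "a"
  p[p == "β" | p == "beta"] <- "b"
  p
}

# accepts numeric half-integers (1, 0.5, -1.5) or fraction strings ("1/2")
parse_m2 <- function(M) {
  if (is.character(M)) {
    parts <- strsplit(trimws(M), "/", fixed = TRUE)[[1]]
    v <- as.numeric(parts[1])
    if (length(parts) == 2) v <- v / as.numeric(parts[2])
    M <- v
  }
  m2 <- 2 * as.numeric(M)
  if (!is.finite(m2) || abs(m2 - round(m2)) > 1e-9)
    stop("invalid M: must be integer or half-integer")
  as.integer(round(m2))
}

format_m2 <- function(m2) {
  if (m2 %% 2 == 0) as.character(m2 %/% 2) else paste0(m2, "/2")
}

new_csf <- function(t, M2) {
  b <- cumsum(DB[t])
  if (any(b < 0)) stop("invalid CSF: intermediate spin becomes negative")
  r <- cumsum(OCC[t] %% 2L)
  n_o <- length(t)
  if (abs(M2) > b[n_o] || ((M2 - b[n_o]) %% 2L) != 0L)
    stop("invalid M: |2M| must be <= 2S with matching parity")
  structure(list(t = unname(t), b = unname(as.integer(b)),
                 r = unname(as.integer(r)), M2 = as.integer(M2),
                 N = sum(OCC[t]), n_o = n_o),
            class = "csf")
}

#' Parse a genealogical CSF from its step string
#'
#' A CSF over `n_o` ordered orbitals (levels) is written as a string over the
#' alphabet `0` (empty), `u` (singly occupied, raising the intermediate spin),
#' `d` (singly occupied, lowering it) and `2` (doubly occupied), together with
#' a total spin projection `M`.  The intermediate doubled spins
#' \eqn{b_i = 2S_i} must stay nonnegative, and `M` must satisfy
#' \eqn{|2M| \le b_{n_o}} with matching parity.
#'
#' @param text step string, level 1 leftmost, e.g. `"uud0uu2d"`.
#' @param M spin projection: a numeric half-integer (`1`, `0.5`, `-1.5`) or a
#'   fraction string (`"1/2"`, `"-3/2"`).
#' @return An object of class `"csf"` with fields `t` (step labels), `b`
#'   (doubled intermediate spins), `r` (cumulative count of singly occupied
#'   orbitals), `M2 = 2M`, `N` (electrons) and `n_o`.
#' @examples
#' csf <- parse_csf("uud0uu2d", M = 1)
#' csf$b  # 1 2 1 1 2 3 3 2
#' csf$r  # 1 2 3 3 4 5 5 6
#' @export
parse_csf <- function(text, M) {
  stopifnot(is.character(text), length(text) == 1, nchar(text) >= 1)
  t <- strsplit(text, "")[[1]]
  if (!all(t %in% c("0", "u", "d", "2")))
    stop("invalid CSF: step string may contain only 0, u, d, 2")
  new_csf(t, parse_m2(M))
}

#' @export
format.csf <- function(x, ...) {
  paste0("|", paste(x$t, collapse = ""), ", M = ", format_m2(x$M2), ">")
}

#' @export
print.csf <- function(x, ...) {
  cat("<csf> ", format(x), "  (N = ", x$N, ", 2S = ", x$b[x$n_o], ")\n",
      sep = "")
  invisible(x)
}

#' Parse a Slater determinant occupation string
#'
#' @param text string over `0`, `a` (alpha), `b` (beta), `2`, level 1
#'   leftmost.  The Greek letters are accepted as synonyms of `a`/`b`.
#' @return An object of class `"sdet"` with fields `p` (labels) and `M2`.
#' @export
parse_det <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  p <- norm_spin_label(strsplit(text, "")[[1]])
  if (!all(p %in% c("0", "a", "b", "2")))
    stop("invalid determinant: labels must be 0, a, b, 2")
  structure(list(p = p, M2 = as.integer(sum(DX[p])), n_o = length(p)),
            class = "sdet")
}

#' @export
format.sdet <- function(x, ...) paste0("|", paste(x$p, collapse = ""), ">")

#' @export
print.sdet <- function(x, ...) {
  cat("<sdet> ", format(x), "  (2M = ", x$M2, ")\n", sep = "")
  invisible(x)
}

#' Clebsch-Gordan edge factor
#'
#' The weight attached to the graph edge for step value `t` traversed with
#' determinant label `p`, at doubled intermediate spin `b` (the value at the
#' target level) and doubled intermediate spin projection `x` (the target node
#' coordinate):
#' \deqn{C_{0,0}=1,\quad C_{2,2}=(-1)^b,\quad
#'       C_{u,\alpha}=\sqrt{\tfrac{b+x}{2b}},\quad
#'       C_{u,\beta}=\sqrt{\tfrac{b-x}{2b}},}
#' \deqn{C_{d,\alpha}=(-1)^{b+1}\sqrt{\tfrac{b-x+2}{2(b+2)}},\quad
#'       C_{d,\beta}=(-1)^{b}\sqrt{\tfrac{b+x+2}{2(b+2)}}.}
#' The sign convention follows the unitary-group-approach phase convention.
#'
#' @param t step value, one of `"0" "u" "d" "2"`.
#' @param p determinant label, one of `"0" "a" "b" "2"` (alpha/beta accepted).
#' @param b doubled intermediate spin at the target level (`b >= 1` for `u`).
#' @param x doubled spin projection of the target node.
#' @param exact if `TRUE` return a [radical()] (`radsum`), else a double.
#' @return The factor value; exactly zero factors are permitted (they mark
#'   removable edges).
#' @examples
#' cg_factor("u", "b", b = 2, x = 0)            # sqrt(1/2)
#' cg_factor("d", "a", b = 2, x = 2)            # -1/2
#' format(cg_factor("2", "2", 3, 0, exact = TRUE))
#' @export
cg_factor <- function(t, p, b, x, exact = FALSE) {
  p <- norm_spin_label(p)
  key <- paste0(t, p)
  pq <- switch(key,
    "00" = c(1, 1, 1),
    "22" = c(if (b %% 2 == 0) 1 else -1, 1, 1),
    "ua" = { if (b < 1) stop("no such factor: C_{u,.} needs b >= 1")
             c(1, b + x, 2 * b) },
    "ub" = { if (b < 1) stop("no such factor: C_{u,.} needs b >= 1")
             c(1, b - x, 2 * b) },
    "da" = c(if (b %% 2 == 0) -1 else 1, b - x + 2, 2 * (b + 2)),
    "db" = c(if (b %% 2 == 0) 1 else -1, b + x + 2, 2 * (b + 2)),
    stop("no such factor: C_{", t, ",", p, "}")
  )
  if (pq[2] < 0)
    stop("outside graph boundary: negative radicand for C_{", t, ",", p, "}")
  if (exact) {
    radical(pq[2], pq[3], sign = if (pq[2] == 0) 0L else as.integer(pq[1]))
  } else {
    pq[1] * sqrt(pq[2] / pq[3])
  }
}

# fast float path used by inner loops (no validation)
cg_num <- function(t, p, b, x) {
  if (t == "0") return(1)
  if (t == "2") return(if (b %% 2L == 0L) 1 else -1)
  if (t == "u") {
    if (p == "a") return(sqrt((b + x) / (2 * b)))
    return(sqrt((b - x) / (2 * b)))
  }
  if (p == "a") {
    s <- if (b %% 2L == 0L) -1 else 1
    return(s * sqrt((b - x + 2) / (2 * (b + 2))))
  }
  s <- if (b %% 2L == 0L) 1 else -1
  s * sqrt((b + x + 2) / (2 * (b + 2)))
}

cg_rs <- function(t, p, b, x) cg_factor(t, p, b, x, exact = TRUE)

#' Coefficient of one Slater determinant in a CSF expansion
#'
#' The coefficient is the product over levels of [cg_factor()] evaluated at
#' the determinant's intermediate spin projections.  If the determinant's
#' occupation pattern or total projection does not match the CSF, the
#' coefficient is exactly zero (returned as a value, not an error).
#'
#' @param csf a [parse_csf()] object.
#' @param det a [parse_det()] object or determinant string.
#' @param exact if `TRUE` return an exact `radsum`.
#' @return A double, or a `radsum` when `exact = TRUE`.
#' @examples
#' det_coefficient(parse_csf("uud0uu2d", 1), "aba0ab2a")  # 1/sqrt(72)
#' @export
det_coefficient <- function(csf, det, exact = FALSE) {
  stopifnot(inherits(csf, "csf"))
  if (is.character(det)) det <- parse_det(det)
  zero <- if (exact) radsum_zero() else 0
  if (det$n_o != csf$n_o) stop("determinant and CSF have different lengths")
  if (any(OCC[det$p] != OCC[csf$t]) || det$M2 != csf$M2) return(zero)
  x <- unname(cumsum(DX[det$p]))
  val <- if (exact) rational(1) else 1
  for (i in seq_len(csf$n_o)) {
    f <- if (exact) cg_rs(csf$t[i], det$p[i], csf$b[i], x[i])
         else cg_num(csf$t[i], det$p[i], csf$b[i], x[i])
    val <- if (exact) val * f else val * f
    if (if (exact) radsum_is_zero(val) else val == 0) return(zero)
  }
  val
}

# per-level admissible x window for paths that can reach (M2, n_o):
# |x_i| <= b_i and |x_i - M2| <= r_no - r_i
x_window <- function(csf, i) {
  slack <- csf$r[csf$n_o] - csf$r[i]
  c(max(-csf$b[i], csf$M2 - slack), min(csf$b[i], csf$M2 + slack))
}

# shared expansion core: enumerates paths level by level inside the window
expand_core <- function(csf, exact = FALSE) {
  n_o <- csf$n_o
  keys <- ""
  xs <- 0L
  coef <- 1
  coefx <- if (exact) list(rational(1)) else NULL
  for (i in seq_len(n_o)) {
    t <- csf$t[i]
    w <- x_window(csf, i)
    if (t %in% c("0", "2")) {
      px <- rep(t, length(xs))
      nx <- xs
      src <- seq_along(xs)
    } else {
      px <- c(rep("a", length(xs)), rep("b", length(xs)))
      nx <- c(xs + 1L, xs - 1L)
      src <- c(seq_along(xs), seq_along(xs))
    }
    ok <- nx >= w[1] & nx <= w[2]
    px <- px[ok]; nx <- nx[ok]; src <- src[ok]
    f <- vapply(seq_along(nx),
                function(k) cg_num(t, px[k], csf$b[i], nx[k]), 0)
    nz <- f != 0
    px <- px[nz]; nx <- nx[nz]; src <- src[nz]; f <- f[nz]
    keys <- paste0(keys[src], px)
    coef <- coef[src] * f
    if (exact) {
      coefx <- lapply(seq_along(src), function(k)
        coefx[[src[k]]] * cg_rs(t, px[k], csf$b[i], nx[k]))
    }
    xs <- nx
    if (length(xs) == 0) break
  }
  list(dets = keys, coef = coef, coef_exact = coefx)
}

#' Expand a CSF into Slater determinants
#'
#' Enumerates exactly the determinants with the CSF's occupation pattern and
#' spin projection whose coefficient is nonzero; the squared coefficients sum
#' to one.  Enumeration walks the graph lattice restricted to the nodes that
#' can reach the CSF's end node, not over all spin assignments.
#'
#' @inheritParams det_coefficient
#' @return A data frame with columns `det` (occupation string over
#'   `0 a b 2`), `coefficient` (double) and, when `exact = TRUE`,
#'   `coefficient_exact` (canonical string, see [radical()]).
#' @examples
#' expand_csf(parse_csf("ud", 0))
#' @export
expand_csf <- function(csf, exact = FALSE) {
  stopifnot(inherits(csf, "csf"))
  e <- expand_core(csf, exact)
  out <- data.frame(det = e$dets, coefficient = e$coef,
                    stringsAsFactors = FALSE)
  if (exact)
    out$coefficient_exact <- vapply(e$coef_exact, format, "")
  out
}

#' Count the determinants in a CSF expansion without enumerating them
#'
#' Dynamic-programming count of the lattice paths inside the spin boundary
#' that end at the CSF's end node.  Zero-weight edges cannot occur on
#' in-boundary paths, so this equals `nrow(expand_csf(csf))`.
#'
#' @inheritParams det_coefficient
#' @return A count (double, exact up to 2^53).
#' @export
count_determinants <- function(csf) {
  stopifnot(inherits(csf, "csf"))
  v <- c(`0` = 1)
  for (i in seq_len(csf$n_o)) {
    w <- x_window(csf, i)
    xs <- as.integer(names(v))
    if (csf$t[i] %in% c("0", "2")) nx <- xs else nx <- c(xs + 1L, xs - 1L)
    cnt <- c(v, v)[seq_along(nx)]
    keep <- nx >= w[1] & nx <= w[2]
    v <- tapply(cnt[keep], nx[keep], sum)
    names(v) <- as.character(sort(unique(nx[keep])))
    if (length(v) == 0) return(0)
  }
  unname(v[as.character(csf$M2)])
}

#' Closed-form size of the ladder-type CSF and its graph
#'
#' For the \eqn{S=0} CSF `uu...ud...dd` over an even number `n` of orbitals
#' (and electrons), the determinant expansion grows as
#' \eqn{N_{SD} = \binom{n}{n/2}} while the graph stays quadratic:
#' \eqn{N_{node} = (n/2+1)^2} nodes (including the root) and
#' \eqn{N_{edge} = n(n/2+1)} edges.
#'
#' @param n even number of orbitals, `n >= 2`.
#' @return A list with `N_SD`, `N_node`, `N_edge`.
#' @examples
#' count_closed_shell(20)  # 184756 determinants, 121 nodes
#' @export
count_closed_shell <- function(n) {
  if (length(n) != 1 || n < 2 || n %% 2 != 0)
    stop("n must be an even integer >= 2")
  list(N_SD = choose(n, n / 2),
       N_node = (n / 2 + 1)^2,
       N_edge = n * (n / 2 + 1))
}

# the |uu...ud...dd>, M = 0 ladder CSF used for the scaling counts
ladder_csf <- function(n) {
  parse_csf(paste0(strrep("u", n / 2), strrep("d", n / 2)), 0)
}
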