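# Compact graph states for operator-modified CSFs.
#
# A CSF acted on by a sequence of elementary creation/annihilation operators
# is in general no longer a CSF, but its genealogical determinant graph (GDG)
# is still described compactly by the original CSF data (t, b, r, M) plus:
#   q   modified step values in {0, u, d, a, b, 2}
#   tau original spin branch recorded when a singly occupied level is touched
#   d   per-level shifts of the node x coordinates
#   phi global phase in {-1, 0, +1}; phi = 0 is the annihilated (null) state
# Determinants are never materialized.

#' Elementary second-quantized operator
#'
#' A single annihilation or creation operator acting on one spatial orbital
#' with spin alpha or beta.
#'
#' @param level orbital index, 1-based.
#' @param spin `"a"` (alpha) or `"b"` (beta); Greek letters accepted.
#' @param dagger `TRUE` for a creation operator.
#' @return A one-row operator sequence (see [parse_ops()]).
#' @export
elementary_op <- function(level, spin, dagger = FALSE) {
  spin <- norm_spin_label(spin)
  stopifnot(level >= 1, spin %in% c("a", "b"), is.logical(dagger))
  structure(data.frame(level = as.integer(level), spin = spin,
                       dagger = dagger, stringsAsFactors = FALSE),
            class = c("op_seq", "data.frame"))
}

#' Parse an operator sequence from its token string
#'
#' Tokens are `<level><spin><action>` with spin `a`/`b` and action `+`
#' (creation) or `-` (annihilation), separated by whitespace, listed in the
#' written product order: the leftmost token is the leftmost factor, and is
#' applied to a ket *last*.  `"1b+ 7b-"` is the two-operator sequence
#' "create beta in orbital 1 after annihilating beta in orbital 7".
#'
#' @param text token string; the empty string is the identity operator.
#' @return An `op_seq` data frame with columns `level`, `spin`, `dagger`.
#' @export
parse_ops <- function(text) {
  stopifnot(is.character(text), length(text) == 1)
  toks <- strsplit(trimws(text), "\\s+")[[1]]
  toks <- toks[nzchar(toks)]
  if (length(toks) == 0)
    return(structure(data.frame(level = integer(), spin = character(),
                                dagger = logical(), stringsAsFactors = FALSE),
                     class = c("op_seq", "data.frame")))
  m <- regmatches(toks, regexec("^([0-9]+)([ab])([+-])$", toks))
  bad <- vapply(m, length, 0L) != 4L
  if (any(bad)) stop("malformed operator token: ", toks[bad][1])
  structure(data.frame(level = as.integer(vapply(m, `[`, "", 2)),
                       spin = vapply(m, `[`, "", 3),
                       dagger = vapply(m, `[`, "", 4) == "+",
                       stringsAsFactors = FALSE),
            class = c("op_seq", "data.frame"))
}

#' @export
format.op_seq <- function(x, ...) {
  if (nrow(x) == 0) return("<identity>")
  paste(paste0(x$level, x$spin, ifelse(x$dagger, "+", "-")), collapse = " ")
}

#' @export
print.op_seq <- function(x, ...) {
  cat("<op_seq> ", format(x), "\n", sep = "")
  invisible(x)
}

# doubled spin-projection change of each elementary operator:
# +1 for {annihilate beta, create alpha}, -1 for {annihilate alpha, create beta}
op_dm2 <- function(seq) {
  ifelse(seq$dagger, ifelse(seq$spin == "a", 1L, -1L),
         ifelse(seq$spin == "a", -1L, 1L))
}

# per-level tallies: N_i^op (operators at level <= i) and x_i^op (their
# doubled spin-projection contribution), plus the total M2op
op_tallies <- function(seq, n_o) {
  nop <- integer(n_o)
  xop <- integer(n_o)
  if (nrow(seq) > 0) {
    if (any(seq$level > n_o)) stop("operator level out of range")
    dm <- op_dm2(seq)
    for (k in seq_len(nrow(seq))) {
      i <- seq$level[k]
      nop[i:n_o] <- nop[i:n_o] + 1L
      xop[i:n_o] <- xop[i:n_o] + dm[k]
    }
  }
  list(nop = nop, xop = xop, M2op = if (n_o > 0) xop[n_o] else 0L)
}

#' Adjoint of an operator sequence
#'
#' Reverses the written order and flips every dagger.
#'
#' @param seq an `op_seq`.
#' @return The adjoint `op_seq`.
#' @export
adjoint_ops <- function(seq) {
  out <- seq[rev(seq_len(nrow(seq))), , drop = FALSE]
  out$dagger <- !out$dagger
  rownames(out) <- NULL
  structure(out, class = c("op_seq", "data.frame"))
}

#' Initialize the graph state of a CSF
#'
#' A fresh state has `q = t`, `tau = 0`, `d = 0` and `phi = 1`.
#'
#' @param csf a [parse_csf()] object.
#' @return An object of class `"gdg_state"`.
#' @export
init_state <- function(csf) {
  stopifnot(inherits(csf, "csf"))
  structure(list(csf = csf, q = csf$t, tau = rep("0", csf$n_o),
                 d = integer(csf$n_o), phi = 1L, applied = integer(0)),
            class = "gdg_state")
}

#' @export
print.gdg_state <- function(x, ...) {
  cat("<gdg_state> over ", format(x$csf), "\n", sep = "")
  cat("  q   = (", paste(x$q, collapse = ","), ")\n", sep = "")
  cat("  tau = (", paste(x$tau, collapse = ","), ")\n", sep = "")
  cat("  d   = (", paste(x$d, collapse = ","), ")\n", sep = "")
  cat("  phi = ", x$phi, if (x$phi == 0L) "  [null state]", "\n", sep = "")
  invisible(x)
}

state_is_null <- function(state) state$phi == 0L

# mark the state annihilated; other fields are frozen and meaningless
null_state <- function(state) {
  state$phi <- 0L
  state
}

#' Apply one elementary operator to a graph state
#'
#' Updates `q_i`, `tau_i`, `phi` and the shifts `d_j` for `j >= i`.  The
#' parity of the phase update is set by the electron count up to and
#' including level `i`, counted *before* `q_i` is changed.  Acting with an
#' operator that annihilates the state (e.g. annihilating an empty level)
#' yields the null state `phi = 0`, which propagates silently.
#'
#' @param state a [init_state()] object.
#' @param level orbital index of the operator.
#' @param spin `"a"` or `"b"`.
#' @param dagger `TRUE` for creation.
#' @return The updated `gdg_state`.
#' @examples
#' s <- init_state(parse_csf("uud0uu2d", 1))
#' s <- apply_elementary(s, 7, "b", dagger = FALSE)
#' s$d    # 0 0 0 0 0 0 1 1
#' s <- apply_elementary(s, 1, "b", dagger = TRUE)
#' s$phi  # -1
#' @export
apply_elementary <- function(state, level, spin, dagger = FALSE) {
  stopifnot(inherits(state, "gdg_state"))
  n_o <- state$csf$n_o
  if (level < 1 || level > n_o) stop("operator level out of range")
  spin <- norm_spin_label(spin)
  state$applied <- c(state$applied, as.integer(level))
  if (state_is_null(state)) return(state)
  i <- level
  qv <- state$q[i]
  N <- sum(OCC[state$q[seq_len(i)]])
  single <- qv %in% c("u", "d")
  act <- paste0(if (dagger) "c" else "a", spin)
  res <- switch(act,
    aa = {
      if (qv == "0" || qv == "b") NULL
      else if (single) list(q = "0", tau = "a", pow = N - 1L, shift = -1L)
      else if (qv == "a") list(q = "0", tau = NA, pow = N - 1L, shift = -1L)
      else list(q = "b", tau = NA, pow = N, shift = -1L)          # qv == "2"
    },
    ab = {
      if (qv == "0" || qv == "a") NULL
      else if (single) list(q = "0", tau = "b", pow = N - 1L, shift = 1L)
      else if (qv == "b") list(q = "0", tau = NA, pow = N - 1L, shift = 1L)
      else list(q = "a", tau = NA, pow = N - 1L, shift = 1L)      # qv == "2"
    },
    ca = {
      if (qv == "a" || qv == "2") NULL
      else if (qv == "0") list(q = "a", tau = NA, pow = N, shift = 1L)
      else if (single) list(q = "2", tau = "b", pow = N - 1L, shift = 1L)
      else list(q = "2", tau = NA, pow = N - 1L, shift = 1L)      # qv == "b"
    },
    cb = {
      if (qv == "b" || qv == "2") NULL
      else if (qv == "0") list(q = "b", tau = NA, pow = N, shift = -1L)
      else if (single) list(q = "2", tau = "a", pow = N, shift = -1L)
      else list(q = "2", tau = NA, pow = N, shift = -1L)          # qv == "a"
    },
    stop("invalid spin label")
  )
  if (is.null(res)) return(null_state(state))
  state$q[i] <- res$q
  if (!is.na(res$tau)) state$tau[i] <- res$tau
  if (res$pow %% 2L != 0L) state$phi <- -state$phi
  state$d[i:n_o] <- state$d[i:n_o] + res$shift
  state
}

#' Apply an operator sequence to a graph state
#'
#' The written sequence is a left-to-right operator product, so the operators
#' are applied to the ket from the rightmost token to the leftmost.  The null
#' state short-circuits.
#'
#' @param state a `gdg_state`.
#' @param seq an `op_seq` (see [parse_ops()]) or a token string.
#' @return The updated `gdg_state`.
#' @examples
#' s <- apply_sequence(init_state(parse_csf("uud0uu2d", 1)), "1b+ 7b-")
#' s$q  # "2" "u" "d" "0" "u" "u" "a" "d"
#' @export
apply_sequence <- function(state, seq) {
  if (is.character(seq)) seq <- parse_ops(seq)
  for (k in rev(seq_len(nrow(seq)))) {
    state <- apply_elementary(state, seq$level[k], seq$spin[k], seq$dagger[k])
  }
  state
}

# range increments by modified step value (delta_min, delta_max)
DELTA_MIN <- c("0" = 0L, "2" = 0L, "u" = -1L, "d" = -1L, "a" = 1L, "b" = -1L)
DELTA_MAX <- c("0" = 0L, "2" = 0L, "u" = 1L, "d" = 1L, "a" = 1L, "b" = -1L)

#' Reachable x-coordinate ranges per level
#'
#' Recursive ranges of node coordinates for a (possibly modified) graph
#' state, seeded at \eqn{x_0^{min} = x_0^{max} = 0}: each level advances the
#' previous range by the step-dependent increment and clips it to the shifted
#' spin boundary and to the window of nodes that can still reach the end
#' node.  For a fresh CSF this reduces to the static boundary/window form.
#' An empty range at some level (`xmin > xmax`) signals a vanishing state
#' downstream; it is returned, not raised.
#'
#' @param state a `gdg_state`.
#' @return A list with integer vectors `xmin`, `xmax` of length `n_o`.
#' @examples
#' s <- apply_sequence(init_state(parse_csf("uud0uu2d", 1)), "1b+ 7b-")
#' x_ranges(s)$xmax  # 0 1 0 0 1 2 3 2
#' @export
x_ranges <- function(state) {
  stopifnot(inherits(state, "gdg_state"))
  csf <- state$csf
  n_o <- csf$n_o
  xmin <- integer(n_o)
  xmax <- integer(n_o)
  pmin <- 0L
  pmax <- 0L
  for (i in seq_len(n_o)) {
    w <- x_window(csf, i)
    xmin[i] <- max(pmin + DELTA_MIN[[state$q[i]]], w[1] + state$d[i])
    xmax[i] <- min(pmax + DELTA_MAX[[state$q[i]]], w[2] + state$d[i])
    pmin <- xmin[i]
    pmax <- xmax[i]
  }
  list(xmin = xmin, xmax = xmax)
}

# tau with the fallback to the original step value, as a determinant label;
# used for every single-edge level of a modified graph
tau_tilde <- function(state, i) {
  tv <- state$tau[i]
  if (tv != "0") return(tv)
  tt <- state$csf$t[i]
  if (tt %in% c("0", "2")) return(tt)
  stop("internal error: modified singly coupled level with unset tau")
}

#' Edge weight of a (possibly modified) graph at one level
#'
#' Weights are those of the original CSF evaluated at the unshifted
#' coordinate `x - d_i`; all operator phases are collected in `phi` and never
#' folded into edge weights.  For an unmodified singly occupied level
#' (`q_i` in `u`/`d`) the `branch` argument selects the alpha (right-slanted)
#' or beta (left-slanted) edge into the target node; for all other `q_i` the
#' single surviving edge uses the recorded original spin branch `tau_i`
#' (falling back to `t_i` for levels that were empty or doubly occupied).
#'
#' @param state a `gdg_state`.
#' @param i level.
#' @param x doubled x coordinate of the edge's *target* node.
#' @param branch `"a"` or `"b"`, required iff `q_i` is `u` or `d`.
#' @param exact if `TRUE` return a `radsum`.
#' @return The edge weight.
#' @export
edge_weight <- function(state, i, x, branch = NULL, exact = FALSE) {
  stopifnot(inherits(state, "gdg_state"))
  csf <- state$csf
  qv <- state$q[i]
  if (qv %in% c("u", "d")) {
    if (is.null(branch)) stop("branch required for an unmodified open level")
    p <- norm_spin_label(branch)
  } else {
    p <- tau_tilde(state, i)
  }
  cg_factor(csf$t[i], p, csf$b[i], x - state$d[i], exact = exact)
}

#' Build the explicit graph of a state
#'
#' Materializes the node and edge lists of the genealogical determinant
#' graph: nodes are restricted to the [x_ranges()] lattice (plus the root),
#' edges carry the [edge_weight()] values with zero-weight edges dropped.
#' Intended for visualization, path counting and brute-force verification;
#' the matrix-element sweep never needs it.
#'
#' @param state a `gdg_state`.
#' @param exact if `TRUE` also record canonical exact weight strings.
#' @return A list with `nodes` (data frame `level`, `x`; the root is level 0),
#'   `edges` (data frame `level`, `x_from`, `x_to`, `type`, `weight`, and
#'   `weight_exact` if requested) and `phi`.
#' @export
build_graph <- function(state, exact = FALSE) {
  stopifnot(inherits(state, "gdg_state"))
  if (state_is_null(state)) stop("cannot build the graph of the null state")
  csf <- state$csf
  n_o <- csf$n_o
  rng <- x_ranges(state)
  nodes <- data.frame(level = 0L, x = 0L)
  edges <- NULL
  prev <- 0L
  for (i in seq_len(n_o)) {
    if (rng$xmin[i] > rng$xmax[i]) {
      prev <- integer(0)
      next
    }
    xs <- seq.int(rng$xmin[i], rng$xmax[i], by = 2L)
    nodes <- rbind(nodes, data.frame(level = i, x = xs))
    qv <- state$q[i]
    for (x in xs) {
      if (qv %in% c("u", "d")) {
        cand <- list(list(from = x - 1L, branch = "a", type = "a"),
                     list(from = x + 1L, branch = "b", type = "b"))
      } else {
        from <- x + switch(qv, "a" = -1L, "b" = 1L, 0L)
        cand <- list(list(from = from, branch = NULL, type = tau_tilde(state, i)))
      }
      for (cd in cand) {
        if (!(cd$from %in% prev)) next
        wn <- if (is.null(cd$branch)) edge_weight(state, i, x)
              else edge_weight(state, i, x, branch = cd$branch)
        if (wn == 0) next
        row <- data.frame(level = i, x_from = cd$from, x_to = x,
                          type = cd$type, weight = wn,
                          stringsAsFactors = FALSE)
        if (exact)
          row$weight_exact <- format(
            if (is.null(cd$branch)) edge_weight(state, i, x, exact = TRUE)
            else edge_weight(state, i, x, branch = cd$branch, exact = TRUE))
        edges <- rbind(edges, row)
      }
    }
    prev <- xs
  }
  if (is.null(edges))
    edges <- data.frame(level = integer(), x_from = integer(),
                        x_to = integer(), type = character(),
                        weight = numeric(), stringsAsFactors = FALSE)
  list(nodes = nodes, edges = edges, phi = state$phi)
}

#' Count root-to-end paths of a state's graph
#'
#' Each path is one Slater determinant of the state's expansion; the count is
#' obtained by dynamic programming over the explicit graph.
#'
#' @param state a `gdg_state`.
#' @return The number of paths from the root to the end node at
#'   `x = 2M + d[n_o]`.
#' @export
count_paths <- function(state) {
  g <- build_graph(state)
  csf <- state$csf
  v <- c(`0` = 1)
  for (i in seq_len(csf$n_o)) {
    e <- g$edges[g$edges$level == i, , drop = FALSE]
    if (nrow(e) == 0) return(0)
    src <- v[as.character(e$x_from)]
    src[is.na(src)] <- 0
    v <- tapply(src, e$x_to, sum)
  }
  xf <- as.character(csf$M2 + state$d[csf$n_o])
  if (!xf %in% names(v)) return(0)
  unname(v[xf])
}

#' Export a graph as JSON
#'
#' Serializes the node list, edge list (with exact and float weights) and
#' the global phase, suitable for external plotting of the lattice diagrams.
#'
#' @param state a `gdg_state`.
#' @param path optional file path; if omitted the JSON string is returned.
#' @return The JSON string, invisibly when written to a file.
#' @export
gdg_json <- function(state, path = NULL) {
  g <- build_graph(state, exact = TRUE)
  js <- jsonlite::toJSON(list(nodes = g$nodes, edges = g$edges, phi = g$phi),
                         dataframe = "rows", auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
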