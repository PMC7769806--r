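# Internal envelopment-LP layer.
#
# All DEA problems here are tiny (a few dozen variables, at most a dozen
# constraints), but they are routinely degenerate: synthetic frontier
# panels place DMUs on a common ray, which makes constraint rows exactly
# proportional. The solver below is a dense two-phase primal simplex with
# Bland's anti-cycling rule; Bland's rule is slow in general but immune to
# cycling under degeneracy, and at this problem size speed is irrelevant.
# Redundant rows surface as artificial variables stuck at zero after phase
# one and are dropped. Data are rescaled to O(1) per input/output row
# before solving - the radial score is units-invariant, so this only
# improves conditioning - and slacks are scaled back afterwards.

# Maximise obj'x subject to A x (dir) b, x >= 0, dir[i] in "<=", ">=", "=".
# Returns list(status, x, value); status "optimal", "infeasible", "unbounded".
simplex_lp <- function(obj, A, b, dir, tol = 1e-9, maxit = 50000L) {
  A <- as.matrix(A)
  m <- nrow(A); n <- ncol(A)
  stopifnot(length(obj) == n, length(b) == m, length(dir) == m)

  neg <- b < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    b[neg] <- -b[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  # columns: n structural, then one slack/surplus per inequality row,
  # then one artificial per ">="/"=" row
  n_slack <- sum(dir != "=")
  art_rows <- which(dir != "<=")
  ncols <- n + n_slack + length(art_rows)
  Tab <- cbind(A, matrix(0, m, ncols - n), b)
  basis <- integer(m)
  sc <- n
  for (i in seq_len(m)) {
    if (dir[i] != "=") {
      sc <- sc + 1L
      Tab[i, sc] <- if (dir[i] == "<=") 1 else -1
      if (dir[i] == "<=") basis[i] <- sc
    }
  }
  ac <- n + n_slack
  art_cols <- integer(0)
  for (i in art_rows) {
    ac <- ac + 1L
    Tab[i, ac] <- 1
    basis[i] <- ac
    art_cols <- c(art_cols, ac)
  }

  pivot <- function(Tab, r, c) {
    Tab[r, ] <- Tab[r, ] / Tab[r, c]
    for (i in seq_len(nrow(Tab))) {
      if (i != r && abs(Tab[i, c]) > .Machine$double.eps) {
        Tab[i, ] <- Tab[i, ] - Tab[i, c] * Tab[r, ]
      }
    }
    Tab
  }

  run_phase <- function(Tab, basis, cvec, allowed) {
    it <- 0L
    repeat {
      it <- it + 1L
      if (it > maxit) stop("simplex iteration limit", call. = FALSE)
      cB <- cvec[basis]
      red <- cvec - as.numeric(cB %*% Tab[, seq_len(ncols), drop = FALSE])
      cand <- allowed[red[allowed] > tol]
      if (length(cand) == 0) return(list(Tab = Tab, basis = basis))
      ent <- cand[1]                           # Bland: smallest index
      col <- Tab[, ent]
      pos <- which(col > tol)
      if (length(pos) == 0) return(list(Tab = Tab, basis = basis,
                                        unbounded = TRUE))
      ratio <- Tab[pos, ncols + 1] / col[pos]
      sel <- pos[ratio <= min(ratio) + tol]
      leave <- sel[which.min(basis[sel])]      # Bland tie-break
      Tab <- pivot(Tab, leave, ent)
      basis[leave] <- ent
    }
  }

  # phase 1: drive artificials to zero
  if (length(art_cols) > 0) {
    c1 <- rep(0, ncols); c1[art_cols] <- -1
    ph1 <- run_phase(Tab, basis, c1, seq_len(ncols))
    Tab <- ph1$Tab; basis <- ph1$basis
    if (-sum(Tab[basis %in% art_cols, ncols + 1]) < -tol * max(1, max(abs(b)))) {
      return(list(status = "infeasible", x = NULL, value = NA_real_))
    }
    # pivot out artificials still basic (at zero); drop redundant rows
    keep <- rep(TRUE, m)
    for (i in seq_len(m)) {
      if (basis[i] %in% art_cols) {
        nz <- which(abs(Tab[i, seq_len(n + n_slack)]) > tol)
        if (length(nz) > 0) {
          Tab <- pivot(Tab, i, nz[1])
          basis[i] <- nz[1]
        } else {
          keep[i] <- FALSE                     # redundant constraint
        }
      }
    }
    Tab <- Tab[keep, , drop = FALSE]
    basis <- basis[keep]
    m <- sum(keep)
  }

  # phase 2 over structural + slack columns only
  c2 <- c(obj, rep(0, ncols - n))
  c2[art_cols] <- 0
  ph2 <- run_phase(Tab, basis, c2, seq_len(n + n_slack))
  if (isTRUE(ph2$unbounded)) {
    return(list(status = "unbounded", x = NULL, value = NA_real_))
  }
  Tab <- ph2$Tab; basis <- ph2$basis
  x <- numeric(ncols)
  x[basis] <- Tab[, ncols + 1]
  list(status = "optimal", x = x[seq_len(n)],
       value = sum(obj * x[seq_len(n)]))
}

lp_status_check <- function(sol, what) {
  if (sol$status != "optimal") {
    stop("LP ", sol$status, " in ", what, call. = FALSE)
  }
  sol
}

# scale factors: one per input row and output row, max over all DMUs + obs
lp_scales <- function(M, obs) apply(cbind(M, obs), 1, max)

# Radial output-oriented envelopment problem.
# max phi  s.t.  X lambda <= xo ; Y lambda >= phi * yo ; [sum lambda = 1] ;
#                lambda >= 0, phi >= 0.
# Variables: (phi, lambda_1..n).
lp_radial <- function(X, Y, xo, yo, vrs = FALSE) {
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  sx <- lp_scales(X, xo); sy <- lp_scales(Y, yo)
  Xn <- X / sx; xon <- xo / sx
  Yn <- Y / sy; yon <- yo / sy

  A <- rbind(cbind(0, Xn), cbind(-yon, Yn))
  b <- c(xon, rep(0, s))
  dir <- c(rep("<=", m), rep(">=", s))
  if (vrs) {
    A <- rbind(A, c(0, rep(1, n)))
    b <- c(b, 1)
    dir <- c(dir, "=")
  }
  sol <- simplex_lp(c(1, rep(0, n)), A, b, dir)
  lp_status_check(sol, "radial stage")
  list(phi = sol$value, lambda = sol$x[-1])
}

# Second stage: maximise total slack at fixed radial score.
# Variables: (lambda_1..n, sminus_1..m, splus_1..s), all >= 0.
# X lambda + sminus = xo ; Y lambda - splus = phi * yo ; [sum lambda = 1].
# Returns slacks in ORIGINAL units, both nonnegative.
lp_slacks <- function(X, Y, xo, yo, phi, vrs = FALSE) {
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  sx <- lp_scales(X, xo); sy <- lp_scales(Y, yo)
  Xn <- X / sx; xon <- xo / sx
  Yn <- Y / sy; yon <- yo / sy

  A <- rbind(
    cbind(Xn, diag(m), matrix(0, m, s)),
    cbind(Yn, matrix(0, s, m), -diag(s))
  )
  b <- c(xon, phi * yon)
  dir <- rep("=", m + s)
  if (vrs) {
    A <- rbind(A, c(rep(1, n), rep(0, m + s)))
    b <- c(b, 1)
    dir <- c(dir, "=")
  }
  obj <- c(rep(0, n), rep(1, m + s))
  sol <- simplex_lp(obj, A, b, dir)
  if (sol$status == "infeasible") {
    # fixed phi can sit a hair above the feasible boundary; back off slightly
    b2 <- b; b2[m + seq_len(s)] <- phi * (1 - 1e-9) * yon
    sol <- simplex_lp(obj, A, b2, dir)
  }
  lp_status_check(sol, "slack stage")
  list(lambda = sol$x[seq_len(n)],
       input_slacks = sol$x[n + seq_len(m)] * sx,
       output_slacks = sol$x[n + m + seq_len(s)] * sy)
}

# Range of sum(lambda) over the optimal set of the CRS radial problem.
# min / max sum lambda  s.t.  X lambda <= xo ; Y lambda >= phi * yo.
lp_lambda_range <- function(X, Y, xo, yo, phi) {
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  sx <- lp_scales(X, xo); sy <- lp_scales(Y, yo)
  Xn <- X / sx; xon <- xo / sx
  Yn <- Y / sy; yon <- yo / sy

  A <- rbind(Xn, Yn)
  dir <- c(rep("<=", m), rep(">=", s))
  solve_dir <- function(sign) {
    b <- c(xon, phi * yon)
    sol <- simplex_lp(sign * rep(1, n), A, b, dir)
    if (sol$status == "infeasible") {
      b[m + seq_len(s)] <- phi * (1 - 1e-9) * yon
      sol <- simplex_lp(sign * rep(1, n), A, b, dir)
    }
    lp_status_check(sol, "returns-to-scale stage")
    sign * sol$value
  }
  c(min = solve_dir(-1), max = solve_dir(1))
}
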