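# Independent oracles and small fixture builders used across the suite.

# Hand-built panel: n DMUs x years, quantities supplied as named vectors
# per year or single baselines with multiplicative growth.
toy_panel <- function(dmu, group, years, institutions, beds, staff,
                      outpatient_visits, discharged_patients,
                      population, area_km2, growth = 1) {
  rows <- lapply(seq_along(years), function(ti) {
    g <- growth^(ti - 1)
    tibble::tibble(
      dmu = dmu, year = years[ti], group = group,
      institutions = institutions * g, beds = beds * g, staff = staff * g,
      outpatient_visits = outpatient_visits * g,
      discharged_patients = discharged_patients * g,
      population = population, area_km2 = area_km2)
  })
  resource_panel(dplyr::bind_rows(rows))
}

# Hoover index as the maximum vertical gap between the Lorenz curve and
# the diagonal (computed from cumulative shares, no shared code path).
oracle_hoover_gap <- function(sv) {
  ord <- order(sv$X / sv$Y, sv$units)
  max(cumsum(sv$Y[ord]) - cumsum(sv$X[ord]))
}

# Lorenz-area Gini via the O(n^2) pairwise mean-absolute-difference
# formula on per-base resource ratios weighted by base shares.
oracle_gini_pairwise <- function(sv) {
  r <- sv$X / sv$Y
  w <- sv$Y
  0.5 * sum(outer(w, w) * abs(outer(r, r, "-")))
}

# Brute-force radial output expansion by exhaustive vertex enumeration:
# every candidate basic solution (active-constraint system) of the
# envelopment polytope is solved directly and checked for feasibility, so
# the maximum is exact and shares no code with the simplex path.
oracle_dea_bruteforce <- function(X, Y, xo, yo, vrs = FALSE, tol = 1e-8) {
  m <- nrow(X); s <- nrow(Y); n <- ncol(X)
  # inequalities A z <= b over z = (phi, lambda)
  A <- rbind(cbind(0, X),                        # inputs
             cbind(yo, -Y),                      # outputs (phi yo <= Y lambda)
             c(-1, rep(0, n)),                   # phi >= 0
             cbind(0, -diag(n)))                 # lambda >= 0
  b <- c(xo, rep(0, s), 0, rep(0, n))
  k <- n + 1 - if (vrs) 1 else 0                 # active rows per vertex
  combos <- utils::combn(nrow(A), k)
  best <- -Inf
  for (j in seq_len(ncol(combos))) {
    M <- A[combos[, j], , drop = FALSE]
    rhs <- b[combos[, j]]
    if (vrs) {
      M <- rbind(M, c(0, rep(1, n)))
      rhs <- c(rhs, 1)
    }
    z <- tryCatch(solve(M, rhs), error = function(e) NULL)
    if (is.null(z)) next
    if (all(A %*% z <= b + tol)) best <- max(best, z[1])
  }
  best
}

# Fixed small technologies for oracle comparisons (positive, n <= 4,
# m = s <= 2), generated reproducibly.
oracle_toy_technologies <- function() {
  set.seed(421)
  specs <- list(c(n = 2, m = 1), c(n = 3, m = 2), c(n = 4, m = 1),
                c(n = 4, m = 2), c(n = 3, m = 1), c(n = 2, m = 2))
  lapply(specs, function(sp) {
    list(X = matrix(stats::runif(sp["m"] * sp["n"], 0.5, 3), sp["m"]),
         Y = matrix(stats::runif(sp["m"] * sp["n"], 0.5, 3), sp["m"]))
  })
}

geo_mean <- function(x) exp(mean(log(x)))
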