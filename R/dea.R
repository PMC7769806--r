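#' Construct a DEA technology
#'
#' Bundles the observed input and output matrices of a set of
#' decision-making units (DMUs) with a returns-to-scale assumption. The
#' output-oriented envelopment problems of [dea_radial()] and friends are
#' solved against this object.
#'
#' @param X Input matrix, `m` inputs x `n` DMUs, strictly positive.
#' @param Y Output matrix, `s` outputs x `n` DMUs, strictly positive.
#' @param dmus DMU identifiers (default: column names of `X`, else `D1..Dn`).
#' @param rts `"CRS"` (constant returns) or `"VRS"` (variable returns; adds
#'   the convexity constraint `sum(lambda) = 1`).
#'
#' @return A list of class `dea_technology`.
#' @export
technology <- function(X, Y, dmus = NULL, rts = c("CRS", "VRS")) {
  rts <- match.arg(rts)
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (ncol(X) != ncol(Y)) stop("X and Y must have the same number of DMUs",
                               call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y)) || any(X <= 0) || any(Y <= 0)) {
    stop("all inputs and outputs must be finite and strictly positive",
         call. = FALSE)
  }
  if (is.null(dmus)) dmus <- colnames(X)
  if (is.null(dmus)) dmus <- paste0("D", seq_len(ncol(X)))
  dmus <- as.character(dmus)
  if (anyDuplicated(dmus)) stop("duplicate DMU identifiers", call. = FALSE)
  colnames(X) <- colnames(Y) <- dmus
  if (is.null(rownames(X))) rownames(X) <- paste0("x", seq_len(nrow(X)))
  if (is.null(rownames(Y))) rownames(Y) <- paste0("y", seq_len(nrow(Y)))
  structure(list(dmus = dmus, X = X, Y = Y, rts = rts),
            class = "dea_technology")
}

#' @export
print.dea_technology <- function(x, ...) {
  cat(sprintf("<dea_technology> %d DMUs, %d inputs, %d outputs, %s\n",
              length(x$dmus), nrow(x$X), nrow(x$Y), x$rts))
  invisible(x)
}

#' Technology observed in one panel year
#'
#' @param panel A [resource_panel()].
#' @param year Year to extract; all input and output quantities of every DMU
#'   in that year must be strictly positive.
#' @inheritParams technology
#' @return A [technology()] whose inputs/outputs are the panel's quantity
#'   columns (inputs as rows of `X`, outputs as rows of `Y`).
#' @export
panel_technology <- function(panel, year, rts = c("CRS", "VRS")) {
  stopifnot(inherits(panel, "resource_panel"))
  rts <- match.arg(rts)
  rows <- which(panel$year == year)
  if (length(rows) == 0) stop("year ", year, " not present", call. = FALSE)
  ins <- panel_inputs(panel); outs <- panel_outputs(panel)
  X <- t(as.matrix(as.data.frame(panel[rows, ins])))
  Y <- t(as.matrix(as.data.frame(panel[rows, outs])))
  rownames(X) <- ins; rownames(Y) <- outs
  bad <- panel$dmu[rows][apply(X <= 0, 2, any) | apply(Y <= 0, 2, any)]
  if (length(bad) > 0) {
    stop("nonpositive input/output for DMU(s) in ", year, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  technology(X, Y, dmus = panel$dmu[rows], rts = rts)
}

dmu_index <- function(tech, dmu) {
  i <- match(as.character(dmu), tech$dmus)
  if (is.na(i)) stop("no such DMU: ", dmu, call. = FALSE)
  i
}

#' Radial output-oriented efficiency of one DMU
#'
#' Solves the envelopment linear program
#' `max phi  s.t.  X lambda <= x_o,  Y lambda >= phi * y_o,  lambda >= 0`
#' (plus `sum(lambda) = 1` under VRS): the largest equiproportional
#' expansion of the DMU's outputs feasible within the technology at its
#' observed inputs. `phi >= 1` for any observed DMU evaluated against its
#' own period; technical efficiency is reported as `te = 1/phi <= 1`.
#'
#' @param tech A [technology()].
#' @param dmu DMU identifier to evaluate.
#' @return A list: `dmu`, `phi`, `te`, `lambda` (named reference weights).
#' @export
dea_radial <- function(tech, dmu) {
  stopifnot(inherits(tech, "dea_technology"))
  i <- dmu_index(tech, dmu)
  sol <- lp_radial(tech$X, tech$Y, tech$X[, i], tech$Y[, i],
                   vrs = tech$rts == "VRS")
  list(dmu = tech$dmus[i], phi = sol$phi, te = 1 / sol$phi,
       lambda = setNames(sol$lambda, tech$dmus))
}

#' Second-stage slack maximisation
#'
#' At the fixed radial score `phi`, maximises the sum of all input and
#' output slacks, identifying input excesses and output shortfalls that the
#' radial projection leaves behind. Input slacks are reported as negative
#' numbers (reduction required) and output slacks as positive ones, the
#' sign convention of slack tables in the applied DEA literature; a DMU
#' with `phi = 1` and all slacks zero is strongly efficient.
#'
#' @inheritParams dea_radial
#' @param phi The radial score from [dea_radial()].
#' @return A list: `dmu`, `phi`, `input_slacks` (named, `<= 0`),
#'   `output_slacks` (named, `>= 0`), `lambda`.
#' @export
dea_slacks <- function(tech, dmu, phi = NULL) {
  stopifnot(inherits(tech, "dea_technology"))
  i <- dmu_index(tech, dmu)
  if (is.null(phi)) phi <- dea_radial(tech, dmu)$phi
  sol <- lp_slacks(tech$X, tech$Y, tech$X[, i], tech$Y[, i], phi,
                   vrs = tech$rts == "VRS")
  list(dmu = tech$dmus[i], phi = phi,
       input_slacks = setNames(-sol$input_slacks, rownames(tech$X)),
       output_slacks = setNames(sol$output_slacks, rownames(tech$Y)),
       lambda = setNames(sol$lambda, tech$dmus))
}

#' Returns-to-scale classification
#'
#' Classifies a DMU's local scale behaviour by the Banker criterion on the
#' CRS solution: with `sum(lambda) = 1` at some optimum the DMU (or its
#' projection) operates at most-productive scale size (`"CRS"`);
#' `sum(lambda) < 1` indicates increasing (`"IRS"`) and `> 1` decreasing
#' (`"DRS"`) returns. Because the optimal `lambda` need not be unique, the
#' interval `[min, max]` of `sum(lambda)` over all optima is computed by
#' two auxiliary LPs at fixed `phi`; `"CRS"` is reported whenever 1 lies in
#' that interval (tolerance 1e-6).
#'
#' @inheritParams dea_radial
#' @return `"CRS"`, `"IRS"` or `"DRS"`.
#' @export
dea_rts <- function(tech, dmu) {
  stopifnot(inherits(tech, "dea_technology"))
  i <- dmu_index(tech, dmu)
  crs <- lp_radial(tech$X, tech$Y, tech$X[, i], tech$Y[, i], vrs = FALSE)
  rng <- lp_lambda_range(tech$X, tech$Y, tech$X[, i], tech$Y[, i], crs$phi)
  tol <- 1e-6
  if (rng["min"] <= 1 + tol && rng["max"] >= 1 - tol) "CRS"
  else if (rng["max"] < 1 - tol) "IRS"
  else "DRS"
}

#' Full DEA results for one panel year
#'
#' Runs the radial stage, the slack stage and the returns-to-scale
#' classification for every DMU observed in a year. Results depend only on
#' the set of DMUs, not on their order in the panel.
#'
#' @inheritParams panel_technology
#' @param rts Returns-to-scale assumption for the radial score and slacks
#'   (`"VRS"` default, the BCC model); the RTS class itself always comes
#'   from the CRS solution.
#' @return A tibble with one row per DMU: `dmu`, `phi`, `te`, one
#'   `slack_<input>` column per input (negative sign dialect), one
#'   `slack_<output>` column per output, `rts_class`, and a `lambda`
#'   list-column of reference weights.
#' @export
dea_efficiency <- function(panel, year, rts = c("VRS", "CRS")) {
  rts <- match.arg(rts)
  tech <- panel_technology(panel, year, rts = rts)
  rows <- lapply(tech$dmus, function(d) {
    rad <- dea_radial(tech, d)
    sl <- dea_slacks(tech, d, rad$phi)
    cls <- dea_rts(tech, d)
    tibble::as_tibble(c(
      list(dmu = d, phi = rad$phi, te = rad$te),
      setNames(as.list(sl$input_slacks),
               paste0("slack_", names(sl$input_slacks))),
      setNames(as.list(sl$output_slacks),
               paste0("slack_", names(sl$output_slacks))),
      list(rts_class = cls, lambda = list(rad$lambda))
    ))
  })
  dplyr::bind_rows(rows)
}
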