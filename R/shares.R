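#' Construct a share vector
#'
#' A share vector pairs, for each unit, its share `X` of some resource with
#' its share `Y` of an allocation base (population or area). Both sides are
#' normalised to sum to one. It is the common input of the Lorenz, Gini and
#' Theil computations.
#'
#' @param units Unit identifiers (unique).
#' @param X Nonnegative resource quantities or shares.
#' @param Y Strictly positive base quantities or shares.
#' @param normalize Divide `X` and `Y` by their sums (default `TRUE`).
#'
#' @return A list of class `share_vector` with fields `units`, `X`, `Y`, `k`.
#' @export
share_vector <- function(units, X, Y, normalize = TRUE) {
  units <- as.character(units)
  if (length(units) != length(X) || length(X) != length(Y)) {
    stop("units, X and Y must have equal length", call. = FALSE)
  }
  if (anyDuplicated(units)) stop("duplicate unit identifiers", call. = FALSE)
  if (any(!is.finite(X)) || any(!is.finite(Y))) {
    stop("X and Y must be finite", call. = FALSE)
  }
  if (any(X < 0)) stop("X must be nonnegative", call. = FALSE)
  if (any(Y <= 0)) stop("Y must be strictly positive", call. = FALSE)
  if (normalize) {
    if (sum(X) <= 0) stop("X has zero total", call. = FALSE)
    X <- X / sum(X)
    Y <- Y / sum(Y)
  }
  if (abs(sum(X) - 1) > 1e-12 || abs(sum(Y) - 1) > 1e-12) {
    stop("shares must each sum to 1 (within 1e-12)", call. = FALSE)
  }
  structure(list(units = units, X = as.numeric(X), Y = as.numeric(Y),
                 k = length(units)),
            class = "share_vector")
}

#' @export
print.share_vector <- function(x, ...) {
  cat("<share_vector> k =", x$k, "units\n")
  print(tibble::tibble(unit = x$units, X = x$X, Y = x$Y), ...)
  invisible(x)
}

#' Resource-vs-base shares for one panel year
#'
#' Extracts, for a given year, each DMU's share of a resource (`X`) paired
#' with its share of the allocation base (`Y`): population or geographic
#' area. These are the relative portions underlying the Lorenz curve, the
#' Gini coefficient and the Theil index.
#'
#' @param panel A [resource_panel()].
#' @param year Year to extract.
#' @param resource Name of a quantity column (input or output).
#' @param base `"population"` or `"area"`.
#'
#' @return A [share_vector()] in the panel's DMU order.
#' @export
make_shares <- function(panel, year, resource,
                        base = c("population", "area")) {
  stopifnot(inherits(panel, "resource_panel"))
  base <- match.arg(base)
  rows <- panel$year == year
  if (!any(rows)) stop("year ", year, " not present in panel", call. = FALSE)
  if (!resource %in% names(panel)) {
    stop("no such quantity column: ", resource, call. = FALSE)
  }
  x <- panel[[resource]][rows]
  b <- if (base == "population") panel$population[rows] else panel$area_km2[rows]
  if (sum(x) <= 0) stop("resource '", resource, "' has zero total in ",
                        year, call. = FALSE)
  share_vector(panel$dmu[rows], x, b)
}
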