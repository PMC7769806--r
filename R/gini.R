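#' Equality band for a Gini-type value
#'
#' Maps an inequality value to the conventional qualitative band used in
#' health-resource equity studies. Bands are half-open on the right:
#' `[0, 0.2)` absolute equality, `[0.2, 0.3)` relative equality,
#' `[0.3, 0.4)` proper equality, `[0.4, 0.5)` relative inequality,
#' `[0.5, Inf)` serious inequality.
#'
#' @param value Numeric vector of inequality values.
#' @return Character vector of band labels.
#' @export
gini_band <- function(value) {
  stopifnot(is.numeric(value), all(is.finite(value)), all(value >= 0))
  labels <- c("absolute equality", "relative equality", "proper equality",
              "relative inequality", "serious inequality")
  as.character(cut(value, breaks = c(-Inf, 0.2, 0.3, 0.4, 0.5, Inf),
                   labels = labels, right = FALSE))
}

new_gini_result <- function(value, method) {
  structure(list(value = value, method = method, band = gini_band(value)),
            class = "gini_result")
}

#' @export
print.gini_result <- function(x, ...) {
  cat(sprintf("<gini_result> %s = %.4f (%s)\n", x$method, x$value, x$band))
  invisible(x)
}

#' Hoover (Robin Hood) index of a share vector
#'
#' Computes half the sum of absolute differences between resource shares and
#' base shares, `G = 1/2 * sum(|X_i - Y_i|)`. This equals the maximum
#' vertical gap between the Lorenz curve and the diagonal, and is the share
#' of the resource that would have to be redistributed to reach perfect
#' proportionality. It is a lower bound on the Lorenz-area Gini coefficient.
#'
#' @param shares A [share_vector()].
#' @return A `gini_result` with `method = "hoover"`.
#' @seealso [gini_lorenz()] for the Lorenz-trapezoid Gini.
#' @export
gini_hoover <- function(shares) {
  stopifnot(inherits(shares, "share_vector"))
  new_gini_result(0.5 * sum(abs(shares$X - shares$Y)), "hoover")
}

# equity sort: ascending resource-per-base ratio, ties broken by unit id
lorenz_order <- function(shares) {
  order(shares$X / shares$Y, shares$units)
}

#' Gini coefficient via the Lorenz trapezoid rule
#'
#' The headline Gini coefficient: twice the area between the Lorenz curve
#' and the diagonal. Units are sorted by ascending resource-per-base ratio
#' (ties broken by unit identifier) and the area under the Lorenz curve is
#' accumulated by trapezoids, giving
#' `G = 1 - sum(Y_i * (cumX_{i-1} + cumX_i))` over the sorted units.
#'
#' @param shares A [share_vector()].
#' @return A `gini_result` with `method = "lorenz_trapezoid"`.
#' @export
gini_lorenz <- function(shares) {
  stopifnot(inherits(shares, "share_vector"))
  ord <- lorenz_order(shares)
  X <- shares$X[ord]
  Y <- shares$Y[ord]
  cumX <- cumsum(X)
  g <- 1 - sum(Y * (c(0, head(cumX, -1)) + cumX))
  # clamp tiny negative round-off at perfect equality
  new_gini_result(max(g, 0), "lorenz_trapezoid")
}

#' Points of the Lorenz curve
#'
#' Cumulative resource share against cumulative base share after the equity
#' sort (ascending resource-per-base ratio). The curve starts at (0, 0),
#' ends at (1, 1), and lies on or below the diagonal.
#'
#' @param shares A [share_vector()].
#' @return A tibble with columns `cum_base`, `cum_resource` (first row 0, 0).
#' @export
lorenz_points <- function(shares) {
  stopifnot(inherits(shares, "share_vector"))
  ord <- lorenz_order(shares)
  tibble::tibble(
    cum_base = c(0, cumsum(shares$Y[ord])),
    cum_resource = c(0, cumsum(shares$X[ord]))
  )
}

#' Gini coefficients across years, resources and bases
#'
#' Convenience wrapper computing both Gini forms for every combination of
#' year, resource and allocation base in a panel.
#'
#' @param panel A [resource_panel()].
#' @param years Years to include (default: all in the panel).
#' @param resources Quantity columns to include (default: the panel inputs).
#' @param bases Allocation bases, a subset of `c("population", "area")`.
#'
#' @return A tibble with columns `year`, `resource`, `base`, `gini_hoover`,
#'   `gini_lorenz`, `band` (band of the Lorenz-trapezoid value).
#' @export
gini_table <- function(panel, years = sort(unique(panel$year)),
                       resources = panel_inputs(panel),
                       bases = c("population", "area")) {
  grid <- expand.grid(year = years, resource = resources, base = bases,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sv <- make_shares(panel, grid$year[i], grid$resource[i], grid$base[i])
    gl <- gini_lorenz(sv)
    tibble::tibble(year = grid$year[i], resource = grid$resource[i],
                   base = grid$base[i],
                   gini_hoover = gini_hoover(sv)$value,
                   gini_lorenz = gl$value, band = gl$band)
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$base, .data$resource, .data$year)
}
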