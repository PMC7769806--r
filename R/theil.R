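#' Theil index of a share vector
#'
#' The population-weighted mean log deviation
#' `T = sum(P_i * ln(P_i / R_i))`, where `P_i` is unit i's share of the
#' allocation base (population or area) and `R_i` its share of the resource.
#' `T = 0` exactly when every unit's resource share matches its base share;
#' larger values indicate greater inequality. The natural logarithm is used
#' throughout, which makes the index additively decomposable across groups
#' (see [theil_decompose()]).
#'
#' @param shares A [share_vector()]: `X` holds resource shares (`R`), `Y`
#'   base shares (`P`). Every resource share must be strictly positive —
#'   the index is undefined at zero.
#' @return The index value (dimensionless scalar).
#' @export
theil <- function(shares) {
  stopifnot(inherits(shares, "share_vector"))
  zero <- shares$X <= 0
  if (any(zero)) {
    stop("Theil index undefined: zero resource share for unit(s) ",
         paste(shares$units[zero], collapse = ", "), call. = FALSE)
  }
  sum(shares$Y * log(shares$Y / shares$X))
}

#' Within-/between-group decomposition of the Theil index
#'
#' Splits total inequality for one year and resource into a within-group
#' component `T_intra = sum(p_g * t_g)` and a between-group component
#' `T_inter = sum(p_g * ln(p_g / y_g))`, where `p_g` and `y_g` are group g's
#' base and resource shares and `t_g` is the Theil index computed on shares
#' renormalised within group g. The two components sum exactly to the
#' pooled index, so each one's share of the total (`contribution_intra`,
#' `contribution_inter`) attributes the observed inequality to disparities
#' inside regions versus between regions.
#'
#' @inheritParams make_shares
#' @param grouping Optional named character vector `c(dmu = group, ...)`;
#'   defaults to the panel's own `group` column. Every DMU present in the
#'   year must be grouped and every group must be non-empty.
#'
#' @return A list of class `theil_decomposition`: `year`, `resource`,
#'   `base`, `T`, `T_intra`, `T_inter`, `group_terms` (tibble with `group`,
#'   `p_g`, `y_g`, `t_g`), `contribution_intra`, `contribution_inter`.
#' @export
theil_decompose <- function(panel, year, resource,
                            base = c("population", "area"),
                            grouping = NULL) {
  base <- match.arg(base)
  sv <- make_shares(panel, year, resource, base)
  if (is.null(grouping)) {
    rows <- panel$year == year
    grouping <- setNames(panel$group[rows], panel$dmu[rows])
  }
  ungrouped <- setdiff(sv$units, names(grouping))
  if (length(ungrouped) > 0) {
    stop("no group label for DMU(s): ", paste(ungrouped, collapse = ", "),
         call. = FALSE)
  }
  g <- as.character(grouping[sv$units])
  groups <- unique(g)

  terms <- lapply(groups, function(grp) {
    idx <- which(g == grp)
    p_g <- sum(sv$Y[idx])
    y_g <- sum(sv$X[idx])
    if (y_g <= 0) stop("group '", grp, "' has zero resource share",
                       call. = FALSE)
    t_g <- theil(share_vector(sv$units[idx], sv$X[idx] / y_g,
                              sv$Y[idx] / p_g, normalize = FALSE))
    tibble::tibble(group = grp, p_g = p_g, y_g = y_g, t_g = t_g)
  })
  terms <- dplyr::bind_rows(terms)

  T_intra <- sum(terms$p_g * terms$t_g)
  T_inter <- sum(terms$p_g * log(terms$p_g / terms$y_g))
  T_total <- T_intra + T_inter

  structure(list(
    year = year, resource = resource, base = base,
    T = T_total, T_intra = T_intra, T_inter = T_inter,
    group_terms = terms,
    contribution_intra = if (T_total > 0) T_intra / T_total else NA_real_,
    contribution_inter = if (T_total > 0) T_inter / T_total else NA_real_
  ), class = "theil_decomposition")
}

#' @export
print.theil_decomposition <- function(x, ...) {
  cat(sprintf("<theil_decomposition> %s / %s, %s base\n",
              x$resource, as.character(x$year), x$base))
  cat(sprintf("  T = %.4f = T_intra %.4f + T_inter %.4f  (intra share %.1f%%)\n",
              x$T, x$T_intra, x$T_inter, 100 * x$contribution_intra))
  print(x$group_terms, ...)
  invisible(x)
}

#' Theil decompositions across years and resources
#'
#' @inheritParams gini_table
#' @param base Allocation base for the Theil weights.
#' @return A tibble with one row per (year, resource): `T`, `T_intra`,
#'   `T_inter`, contribution rates, and one `t_<group>` column per group.
#' @export
theil_table <- function(panel, years = sort(unique(panel$year)),
                        resources = panel_inputs(panel),
                        base = c("population", "area")) {
  base <- match.arg(base)
  grid <- expand.grid(year = years, resource = resources,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    d <- theil_decompose(panel, grid$year[i], grid$resource[i], base)
    wide <- setNames(as.list(d$group_terms$t_g),
                     paste0("t_", d$group_terms$group))
    tibble::as_tibble(c(list(year = d$year, resource = d$resource,
                             base = d$base, T = d$T, T_intra = d$T_intra,
                             T_inter = d$T_inter,
                             contribution_intra = d$contribution_intra,
                             contribution_inter = d$contribution_inter),
                        wide))
  })
  dplyr::arrange(dplyr::bind_rows(rows), .data$resource, .data$year)
}

#' Multi-year contribution rate of the within-group component
#'
#' Summarises a series of yearly Theil decompositions into a single
#' within-group (and between-group) contribution rate. The default is the
#' arithmetic mean of the yearly ratios `T_intra / T`; `method = "pooled"`
#' instead divides the summed components, `sum(T_intra) / sum(T)`. Years
#' with `T = 0` carry no defined ratio and are dropped with a warning.
#'
#' @param series Either a list of [theil_decompose()] results (one per
#'   year) or a data frame with numeric columns `T` and `T_intra`.
#' @param method `"mean_of_ratios"` (default) or `"pooled"`.
#' @return A list: `contribution_intra`, `contribution_inter`, `method`,
#'   `n_years`, and `by_year` (tibble of the per-year ratios).
#' @export
contribution_rates <- function(series,
                               method = c("mean_of_ratios", "pooled")) {
  method <- match.arg(method)
  if (is.data.frame(series)) {
    Tt <- series$T
    Ti <- series$T_intra
  } else {
    stopifnot(all(vapply(series, inherits, TRUE, "theil_decomposition")))
    Tt <- vapply(series, `[[`, numeric(1), "T")
    Ti <- vapply(series, `[[`, numeric(1), "T_intra")
  }
  if (length(Tt) < 1) stop("need at least one decomposition", call. = FALSE)
  zero <- Tt == 0
  if (any(zero)) {
    warning(sum(zero), " year(s) with T = 0 excluded from contribution rate")
    Tt <- Tt[!zero]; Ti <- Ti[!zero]
  }
  if (length(Tt) == 0) stop("all years have T = 0", call. = FALSE)
  ci <- if (method == "mean_of_ratios") mean(Ti / Tt) else sum(Ti) / sum(Tt)
  list(contribution_intra = ci,
       contribution_inter = 1 - ci,
       method = method,
       n_years = length(Tt),
       by_year = tibble::tibble(T = Tt, T_intra = Ti, ratio = Ti / Tt))
}
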