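#' Cross-period radial distance
#'
#' Radial output-expansion factor `phi` of an arbitrary observation
#' `(xo, yo)` measured against a frontier built from another (or the same)
#' period's technology. Unlike the own-period score, `phi` may fall below 1
#' when the observation lies beyond the reference frontier. The output
#' distance function used by the Malmquist index is `D = 1/phi`.
#'
#' @param tech A [technology()] defining the reference frontier.
#' @param xo,yo Input and output vectors of the observation, in the same
#'   order as the rows of `tech$X` / `tech$Y`.
#' @return The scalar `phi`.
#' @export
cross_distance <- function(tech, xo, yo) {
  stopifnot(inherits(tech, "dea_technology"))
  if (length(xo) != nrow(tech$X) || length(yo) != nrow(tech$Y)) {
    stop("observation dimensions do not match the technology", call. = FALSE)
  }
  if (any(xo <= 0) || any(yo <= 0)) {
    stop("observation must be strictly positive", call. = FALSE)
  }
  lp_radial(tech$X, tech$Y, xo, yo, vrs = tech$rts == "VRS")$phi
}

#' Malmquist components for one adjacent pair of years
#'
#' Computes, per DMU, the adjacent-period Malmquist total factor
#' productivity change and its four-way decomposition between years `t` and
#' `t1`. Writing `D^a(b)` for the CRS output distance function of the
#' period-`a` frontier evaluated at the period-`b` observation (and `Dv`
#' for its VRS counterpart):
#'
#' * `effch = D^t1(t1) / D^t(t)` — catch-up to the frontier;
#' * `techch = sqrt( (D^t(t1)/D^t1(t1)) * (D^t(t)/D^t1(t)) )` — geometric
#'   mean shift of the frontier itself;
#' * `pech = Dv^t1(t1) / Dv^t(t)` — pure (managerial) efficiency change;
#' * `sech = effch / pech` — scale-efficiency change;
#' * `tfpch = effch * techch` — total factor productivity change.
#'
#' Distances for `effch`/`techch`/`tfpch` are computed under CRS with
#' `pech` under VRS, the standard construction that keeps both identities
#' `tfpch = effch * techch` and `effch = pech * sech` exact and avoids
#' cross-period infeasibility. Values above 1 indicate improvement.
#'
#' @param panel A [resource_panel()].
#' @param t,t1 The two years; both must cover the same set of DMUs with
#'   strictly positive quantities (a balanced pair).
#' @return A tibble with one row per DMU: `dmu`, `period` (label
#'   `"t-t1"`), `effch`, `techch`, `pech`, `sech`, `tfpch`.
#' @export
malmquist_pair <- function(panel, t, t1) {
  stopifnot(inherits(panel, "resource_panel"))
  d_t <- sort(panel$dmu[panel$year == t])
  d_t1 <- sort(panel$dmu[panel$year == t1])
  if (!identical(d_t, d_t1)) {
    asym <- union(setdiff(d_t, d_t1), setdiff(d_t1, d_t))
    stop("unbalanced DMUs between ", t, " and ", t1, ": ",
         paste(asym, collapse = ", "), call. = FALSE)
  }

  crs_t <- panel_technology(panel, t, rts = "CRS")
  crs_t1 <- panel_technology(panel, t1, rts = "CRS")
  vrs_t <- panel_technology(panel, t, rts = "VRS")
  vrs_t1 <- panel_technology(panel, t1, rts = "VRS")
  label <- paste0(t, "-", t1)

  rows <- lapply(crs_t$dmus, function(d) {
    xo_t <- crs_t$X[, d]; yo_t <- crs_t$Y[, d]
    xo_t1 <- crs_t1$X[, d]; yo_t1 <- crs_t1$Y[, d]
    # output distance functions D = 1/phi
    D_tt <- 1 / cross_distance(crs_t, xo_t, yo_t)
    D_t1t1 <- 1 / cross_distance(crs_t1, xo_t1, yo_t1)
    D_tt1 <- 1 / cross_distance(crs_t, xo_t1, yo_t1)
    D_t1t <- 1 / cross_distance(crs_t1, xo_t, yo_t)
    Dv_tt <- 1 / cross_distance(vrs_t, xo_t, yo_t)
    Dv_t1t1 <- 1 / cross_distance(vrs_t1, xo_t1, yo_t1)

    effch <- D_t1t1 / D_tt
    techch <- sqrt((D_tt1 / D_t1t1) * (D_tt / D_t1t))
    pech <- Dv_t1t1 / Dv_tt
    tibble::tibble(dmu = d, period = label, effch = effch, techch = techch,
                   pech = pech, sech = effch / pech, tfpch = effch * techch)
  })
  dplyr::bind_rows(rows)
}

#' Malmquist components over all adjacent pairs of a panel
#'
#' @param panel A balanced [resource_panel()].
#' @param years Years to chain (default: all panel years in order); each
#'   consecutive pair is passed to [malmquist_pair()].
#' @return A tibble stacking the per-pair results.
#' @export
malmquist <- function(panel, years = sort(unique(panel$year))) {
  if (length(years) < 2) stop("need at least two years", call. = FALSE)
  dplyr::bind_rows(lapply(seq_len(length(years) - 1), function(i) {
    malmquist_pair(panel, years[i], years[i + 1])
  }))
}

mq_components <- c("effch", "techch", "pech", "sech", "tfpch")

geomean <- function(x) exp(mean(log(x)))

#' Summaries of Malmquist components
#'
#' Aggregates per-DMU, per-pair Malmquist components into (i) geometric
#' means per period pair across DMUs, (ii) geometric means per DMU across
#' period pairs, and (iii) frequency tables counting, per pair and
#' component, how many DMUs improved (> 1), were unchanged (= 1) or
#' deteriorated (< 1). Membership in the "= 1" class is decided after
#' rounding to `digits` decimals (band `|x - 1| <= 5e-4` at the default 3),
#' mirroring how such tables are conventionally read; the geometric means
#' are reported unrounded.
#'
#' @param components A tibble from [malmquist()] or [malmquist_pair()].
#' @param digits Rounding used only for frequency classification.
#' @return A list of class `malmquist_summary`: `by_period`, `by_dmu`,
#'   `frequency` (long tibble: `period`, `component`, `gt1`, `eq1`, `lt1`).
#' @export
malmquist_summary <- function(components, digits = 3) {
  stopifnot(all(c("dmu", "period", mq_components) %in% names(components)))
  long <- tidyr::pivot_longer(components, dplyr::all_of(mq_components),
                              names_to = "component", values_to = "value")
  long$component <- factor(long$component, levels = mq_components)

  by_period <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(long, .data$period, .data$component),
                     value = geomean(.data$value), .groups = "drop"),
    names_from = "component", values_from = "value")
  by_dmu <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(long, .data$dmu, .data$component),
                     value = geomean(.data$value), .groups = "drop"),
    names_from = "component", values_from = "value")

  rounded <- round(long$value, digits)
  long$class <- ifelse(rounded > 1, "gt1", ifelse(rounded < 1, "lt1", "eq1"))
  frequency <- tidyr::pivot_wider(
    dplyr::summarise(dplyr::group_by(long, .data$period, .data$component,
                                     .data$class),
                     n = dplyr::n(), .groups = "drop"),
    names_from = "class", values_from = "n", values_fill = 0L)
  for (cl in c("gt1", "eq1", "lt1")) {
    if (!cl %in% names(frequency)) frequency[[cl]] <- 0L
  }
  frequency <- frequency[c("period", "component", "gt1", "eq1", "lt1")]

  structure(list(by_period = by_period, by_dmu = by_dmu,
                 frequency = frequency),
            class = "malmquist_summary")
}

#' @export
print.malmquist_summary <- function(x, ...) {
  cat("<malmquist_summary>\nGeometric means by period pair:\n")
  print(x$by_period, ...)
  cat("Frequency of DMUs >1 / =1 / <1:\n")
  print(x$frequency, ...)
  invisible(x)
}
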