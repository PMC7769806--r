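# Seed splitting: one derived stream seed per (base seed, stream name), so
# adding a quantity never perturbs the draws of existing ones.
stream_seed <- function(seed, name) {
  h <- sum(utf8ToInt(name) * (31L^(seq_along(utf8ToInt(name)) %% 7L)))
  (as.integer(seed) %% 1000003L) * 2039L + (h %% 1000003L)
}

with_stream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(stream_seed(seed, name))
  force(expr)
}

#' Specification of a synthetic grouped panel
#'
#' Parameters of the log-normal panel generator. The defaults emulate the
#' structure of the mainland-China province panel on which the analyses are
#' designed to run: 31 DMUs in three unequal regions (11 eastern / 8 middle /
#' 12 western), five yearly waves, strictly positive right-skewed quantities
#' with higher levels in the east, broad within-region heterogeneity, and
#' steady secular growth of every resource and output (roughly 6–10% per
#' year) against near-static population and fixed geography.
#'
#' @param group_sizes Named integer vector of DMUs per group.
#' @param years Ordered year labels.
#' @param quantities A named list, one element per quantity column, each a
#'   list with `meanlog` (named per group), `sdlog` (within-group log-sd),
#'   `growth` (annual multiplicative factor) and `link` (`"population"` to
#'   draw the quantity proportional to the DMU's population with the given
#'   per-capita log-level, or `"none"` for an absolute log-level). Must
#'   include `population` and `area_km2`, both unlinked.
#' @param seed Integer seed; the generator is fully deterministic given it.
#'
#' @return A list of class `panel_spec`.
#' @export
panel_spec <- function(group_sizes = c(eastern = 11, middle = 8, western = 12),
                       years = 2013:2017,
                       quantities = default_quantity_specs(),
                       seed = 1L) {
  stopifnot(length(group_sizes) >= 1, all(group_sizes >= 1),
            !is.null(names(group_sizes)), length(years) >= 1)
  for (qn in c("population", "area_km2")) {
    if (!qn %in% names(quantities)) {
      stop("quantities must include '", qn, "'", call. = FALSE)
    }
  }
  for (qn in names(quantities)) {
    q <- quantities[[qn]]
    if (!all(names(group_sizes) %in% names(q$meanlog))) {
      stop("quantity '", qn, "' lacks a meanlog for every group", call. = FALSE)
    }
    if (q$sdlog < 0) stop("sdlog must be >= 0 for '", qn, "'", call. = FALSE)
    if (q$growth <= 0) stop("growth must be > 0 for '", qn, "'", call. = FALSE)
    link <- if (is.null(q$link)) "none" else q$link
    if (!link %in% c("none", "population")) {
      stop("link must be 'none' or 'population' for '", qn, "'", call. = FALSE)
    }
    if (qn %in% c("population", "area_km2") && link != "none") {
      stop("'", qn, "' cannot be population-linked", call. = FALSE)
    }
  }
  structure(list(group_sizes = group_sizes, years = years,
                 quantities = quantities, seed = as.integer(seed)),
            class = "panel_spec")
}

#' Default per-quantity generator parameters
#'
#' Resource and output quantities are population-linked: each DMU's value is
#' its population times a log-normal per-capita level, so richer-populated
#' DMUs hold proportionally more resources, as in real province panels.
#' Per-capita levels are calibrated to yearbook-like national magnitudes
#' (institutions ~3 per 100,000 persons, beds ~0.6 and staff ~0.45 per
#' 1,000; outpatient visits stored in units of 10,000 visits), with a mild
#' east > middle > western per-capita gradient and annual growth in the
#' observed 6-10% range. Within-group log-dispersions (0.5 for institutions,
#' 0.25 for the rest) put the population-based Gini near 0.28 and 0.10-0.14
#' respectively, while the wide, population-independent spread of land areas
#' (log-sd 1.1, western areas largest) pushes area-based Ginis above 0.5 —
#' the equity regime the analyses are designed around.
#'
#' @return Named list suitable for the `quantities` field of [panel_spec()].
#' @export
default_quantity_specs <- function() {
  ml <- function(e, m, w) c(eastern = e, middle = m, western = w)
  pc <- function(base, e, m, w) ml(log(base) + e, log(base) + m, log(base) + w)
  list(
    institutions = list(meanlog = pc(3.0e-5, 0.08, 0, -0.12), sdlog = 0.5,
                        growth = 1.066, link = "population"),
    beds = list(meanlog = pc(5.8e-4, 0.08, 0, -0.12), sdlog = 0.25,
                growth = 1.094, link = "population"),
    staff = list(meanlog = pc(4.4e-4, 0.08, 0, -0.12), sdlog = 0.25,
                 growth = 1.074, link = "population"),
    outpatient_visits = list(meanlog = pc(6.0e-5, 0.1, 0, -0.15), sdlog = 0.3,
                             growth = 1.059, link = "population"),
    discharged_patients = list(meanlog = pc(1.9e-2, 0.1, 0, -0.15), sdlog = 0.3,
                               growth = 1.097, link = "population"),
    population = list(meanlog = ml(17.7, 17.7, 17.0), sdlog = 0.6,
                      growth = 1.005, link = "none"),
    area_km2 = list(meanlog = ml(11.7, 12.1, 13.0), sdlog = 1.1, growth = 1,
                    link = "none")
  )
}

#' Generate a synthetic grouped panel
#'
#' Draws one log-normal baseline value per DMU and quantity (group-specific
#' log-mean, shared log-dispersion) and applies each quantity's
#' deterministic annual growth factor across years. Every quantity is drawn
#' from its own named pseudo-random stream derived from the seed, so draws
#' are reproducible and independent of which other quantities exist.
#'
#' @param spec A [panel_spec()].
#' @return A validated [resource_panel()]; input columns are those quantity
#'   names that are neither `population`/`area_km2` nor output-like
#'   (`outpatient_visits`, `discharged_patients`).
#' @export
gen_panel <- function(spec) {
  stopifnot(inherits(spec, "panel_spec"))
  groups <- rep(names(spec$group_sizes), spec$group_sizes)
  prefix <- toupper(substr(names(spec$group_sizes), 1, 1))
  dmus <- unlist(lapply(seq_along(spec$group_sizes), function(i) {
    sprintf("%s%02d", prefix[i], seq_len(spec$group_sizes[i]))
  }))
  n <- length(dmus)

  base <- list()
  for (qn in names(spec$quantities)) {      # unlinked first: population is a base
    q <- spec$quantities[[qn]]
    if (is.null(q$link) || q$link == "none") {
      base[[qn]] <- with_stream(spec$seed, qn, {
        exp(rnorm(n, mean = q$meanlog[groups], sd = q$sdlog))
      })
    }
  }
  for (qn in names(spec$quantities)) {
    q <- spec$quantities[[qn]]
    if (!is.null(q$link) && q$link == "population") {
      base[[qn]] <- base[["population"]] * with_stream(spec$seed, qn, {
        exp(rnorm(n, mean = q$meanlog[groups], sd = q$sdlog))
      })
    }
  }
  base <- base[names(spec$quantities)]

  rows <- lapply(seq_along(spec$years), function(ti) {
    vals <- lapply(names(spec$quantities), function(qn) {
      base[[qn]] * spec$quantities[[qn]]$growth^(ti - 1)
    })
    names(vals) <- names(spec$quantities)
    tibble::as_tibble(c(list(dmu = dmus, year = spec$years[ti],
                             group = groups), vals))
  })
  df <- dplyr::bind_rows(rows)

  known_out <- intersect(c("outpatient_visits", "discharged_patients"),
                         names(spec$quantities))
  ins <- setdiff(names(spec$quantities),
                 c(known_out, "population", "area_km2"))
  resource_panel(df, inputs = ins, outputs = known_out)
}

#' Specification of a synthetic production frontier panel
#'
#' Describes a panel whose DEA truth is known by construction. All DMUs
#' share a common input mix and differ in scale, and efficient outputs (in
#' a fixed output mix) are proportional to that scale, so the production
#' frontier is a single constant-returns ray. Every non-frontier DMU is a
#' frontier point with all outputs contracted by a known factor `c_j` in
#' `(0, 1]`, making its true radial expansion exactly `phi = 1/c_j` by
#' elementary algebra — no solver is involved in defining the truth. A
#' Hicks-neutral technology shift multiplies all efficient outputs by `g`
#' each year, so the true frontier shift (Techch) equals `g` under CRS
#' while efficiency change is 1.
#'
#' @param n_dmus Total DMUs.
#' @param n_frontier Number of DMUs with `c_j = 1`.
#' @param m,s Numbers of inputs and outputs (at most 3 and 2: they are
#'   mapped onto the canonical panel quantity columns).
#' @param years Ordered year labels.
#' @param g Annual frontier shift factor (> 0).
#' @param c_range Range the inefficiency factors are drawn from.
#' @param noise_sd Multiplicative log-normal noise on outputs (default 0 so
#'   the DEA truth is exact).
#' @param seed Integer seed.
#' @return A list of class `frontier_spec`.
#' @export
frontier_spec <- function(n_dmus = 31, n_frontier = 8, m = 3, s = 2,
                          years = 2013:2017, g = 1.05,
                          c_range = c(0.6, 0.95), noise_sd = 0, seed = 1L) {
  stopifnot(n_frontier >= 1, n_frontier <= n_dmus, m >= 1, m <= 3,
            s >= 1, s <= 2, g > 0, noise_sd >= 0,
            c_range[1] > 0, c_range[2] <= 1, c_range[1] <= c_range[2])
  structure(list(n_dmus = n_dmus, n_frontier = n_frontier, m = m, s = s,
                 years = years, g = g, c_range = c_range,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "frontier_spec")
}

#' Generate a frontier panel with known inefficiencies
#'
#' @param spec A [frontier_spec()].
#' @return A list: `panel` (a [resource_panel()] whose first `m` input
#'   columns and first `s` output columns carry the constructed technology)
#'   and `truth` (tibble `dmu`, `year`, `c`, `true_phi`, `g`).
#' @export
gen_frontier_panel <- function(spec) {
  stopifnot(inherits(spec, "frontier_spec"))
  n <- spec$n_dmus
  dmus <- sprintf("D%02d", seq_len(n))

  in_names <- default_inputs()[seq_len(spec$m)]
  out_names <- default_outputs()[seq_len(spec$s)]
  in_scale <- c(1500, 30000, 22000)[seq_len(spec$m)]
  out_mix <- c(1.2, 320)[seq_len(spec$s)]

  # one scale draw per DMU along a common input mix: the efficient frontier
  # is then a single CRS ray and true scores are exact by construction
  theta <- with_stream(spec$seed, "frontier_scale", exp(rnorm(n, 0, 0.5)))
  mix <- with_stream(spec$seed, "frontier_mix", {
    stats::runif(spec$m, 0.8, 1.2) * in_scale
  })
  X <- outer(mix, theta)
  cvec <- with_stream(spec$seed, "inefficiency", {
    cc <- stats::runif(n, spec$c_range[1], spec$c_range[2])
    cc[sample.int(n, spec$n_frontier)] <- 1
    cc
  })

  agg <- theta                            # efficient aggregate output level
  years <- spec$years
  rows <- lapply(seq_along(years), function(ti) {
    eff <- outer(out_mix, agg) * spec$g^(ti - 1)   # s x n efficient outputs
    Yt <- eff * rep(cvec, each = spec$s)
    if (spec$noise_sd > 0) {
      Yt <- Yt * with_stream(spec$seed, paste0("noise_", years[ti]), {
        matrix(exp(rnorm(spec$s * n, 0, spec$noise_sd)), spec$s, n)
      })
    }
    vals <- c(setNames(lapply(seq_len(spec$m), function(i) X[i, ]), in_names),
              setNames(lapply(seq_len(spec$s), function(r) Yt[r, ]), out_names))
    tibble::as_tibble(c(list(dmu = dmus, year = years[ti], group = "all"),
                        vals,
                        list(population = rep(1e6, n),
                             area_km2 = rep(1e5, n))))
  })
  panel <- resource_panel(dplyr::bind_rows(rows),
                          inputs = in_names, outputs = out_names)
  truth <- dplyr::arrange(
    tidyr::expand_grid(year = years, tibble::tibble(dmu = dmus, c = cvec)),
    .data$dmu, .data$year)
  truth$true_phi <- 1 / truth$c
  truth$g <- spec$g
  list(panel = panel, truth = truth[c("dmu", "year", "c", "true_phi", "g")])
}

#' Generate a random share vector
#'
#' Draws base shares from a normalised gamma distribution and resource
#' shares by tilting them with a log-normal ratio whose spread is set by
#' `concentration`: 0 gives perfectly proportional shares (all inequality
#' measures 0); large values approach maximal concentration of the resource
#' in a single unit. Intended for property-style testing of the equity
#' measures across regimes.
#'
#' @param n Number of units (>= 2).
#' @param concentration Log-sd of the resource-to-base tilt (>= 0).
#' @param seed Integer seed.
#' @return A [share_vector()].
#' @export
gen_share_vector <- function(n, concentration = 1, seed = 1L) {
  if (n < 2) stop("need at least 2 units", call. = FALSE)
  stopifnot(concentration >= 0)
  with_stream(seed, paste0("shares", n), {
    base <- rgamma(n, shape = 5, rate = 1)
    tilt <- exp(rnorm(n, 0, concentration))
    share_vector(sprintf("U%03d", seq_len(n)), base * tilt, base)
  })
}
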