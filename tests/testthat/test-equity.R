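test_that("make_shares returns normalised paired shares", {
  pan <- toy_panel(dmu = c("A", "B"), group = "g", years = 2020,
                   institutions = c(3, 1), beds = c(1, 1), staff = c(1, 1),
                   outpatient_visits = c(1, 1), discharged_patients = c(1, 1),
                   population = c(1, 1), area_km2 = c(2, 6))
  sv <- make_shares(pan, 2020, "institutions", "population")
  expect_equal(sv$X, c(0.75, 0.25))
  expect_equal(sv$Y, c(0.5, 0.5))
  sva <- make_shares(pan, 2020, "institutions", "area")
  expect_equal(sva$Y, c(0.25, 0.75))
  big <- make_shares(gen_panel(panel_spec(seed = 2)), 2015, "beds")
  expect_equal(sum(big$X), 1)
  expect_equal(sum(big$Y), 1)
})

test_that("Gini forms agree with closed-form cases", {
  even <- share_vector(letters[1:4], rep(1, 4), rep(1, 4))
  expect_equal(gini_hoover(even)$value, 0)
  expect_equal(gini_lorenz(even)$value, 0)

  skew <- share_vector(c("a", "b"), c(1, 0), c(0.5, 0.5), normalize = FALSE)
  expect_equal(gini_hoover(skew)$value, 0.5)

  # one unit holds everything over n equal bases: G = 1 - 1/n
  for (n in c(2, 5, 10)) {
    top <- share_vector(paste0("u", seq_len(n)),
                        c(rep(0, n - 1), 1), rep(1 / n, n),
                        normalize = FALSE)
    expect_equal(gini_lorenz(top)$value, 1 - 1 / n)
  }
})

test_that("Hoover index equals the maximum Lorenz gap (random shares)", {
  for (seed in 1:50) {
    sv <- gen_share_vector(10, concentration = seed %% 4 + 0.2, seed = seed)
    expect_equal(gini_hoover(sv)$value, oracle_hoover_gap(sv),
                 tolerance = 1e-12)
  }
})

test_that("Lorenz-trapezoid Gini matches the pairwise-difference oracle", {
  for (seed in 1:25) {
    sv <- gen_share_vector(10, concentration = 1.5, seed = seed)
    expect_equal(gini_lorenz(sv)$value, oracle_gini_pairwise(sv),
                 tolerance = 1e-12)
  }
})

test_that("Lorenz curve is monotone, convex and anchored at the corners", {
  sv <- gen_share_vector(31, concentration = 1, seed = 9)
  pts <- lorenz_points(sv)
  expect_equal(pts$cum_base[1], 0)
  expect_equal(pts$cum_resource[1], 0)
  expect_equal(pts$cum_base[nrow(pts)], 1)
  expect_equal(pts$cum_resource[nrow(pts)], 1)
  expect_true(all(diff(pts$cum_base) >= 0))
  expect_true(all(diff(pts$cum_resource) >= -1e-15))
  expect_true(all(pts$cum_resource <= pts$cum_base + 1e-12))
  slopes <- diff(pts$cum_resource) / diff(pts$cum_base)
  expect_true(all(diff(slopes) >= -1e-9))

  degen <- share_vector(c("a", "b"), c(1, 0), c(0.5, 0.5), normalize = FALSE)
  expect_equal(lorenz_points(degen)$cum_resource, c(0, 0, 1))
})

test_that("equality bands use half-open intervals at the documented edges", {
  expect_equal(gini_band(c(0, 0.19, 0.2, 0.3, 0.4, 0.499, 0.5, 0.8)),
               c("absolute equality", "absolute equality",
                 "relative equality", "proper equality",
                 "relative inequality", "relative inequality",
                 "serious inequality", "serious inequality"))
})

test_that("Theil index matches hand computation and merge invariance", {
  sv <- share_vector(c("a", "b"), c(0.25, 0.75), c(0.5, 0.5),
                     normalize = FALSE)
  expect_equal(theil(sv), 0.5 * log(2) + 0.5 * log(2 / 3), tolerance = 1e-12)
  expect_equal(round(theil(sv), 5), 0.14384)

  even <- share_vector(letters[1:5], rep(0.2, 5), rep(0.2, 5),
                       normalize = FALSE)
  expect_equal(theil(even), 0)

  # splitting a unit into parts with identical resource-per-base ratios
  # leaves T unchanged (decomposability limit)
  whole <- share_vector(c("a", "b", "c"), c(0.2, 0.3, 0.5),
                        c(0.1, 0.4, 0.5), normalize = FALSE)
  split <- share_vector(c("a", "b", "c1", "c2"),
                        c(0.2, 0.3, 0.25, 0.25), c(0.1, 0.4, 0.25, 0.25),
                        normalize = FALSE)
  expect_equal(theil(split), theil(whole), tolerance = 1e-12)

  zero <- share_vector(c("a", "b"), c(1, 0), c(0.5, 0.5), normalize = FALSE)
  expect_error(theil(zero), "undefined.*b")
})

test_that("both Gini forms and Theil are scale- and permutation-invariant", {
  pan <- gen_panel(panel_spec(seed = 13))
  sv <- make_shares(pan, 2014, "staff", "population")
  scaled <- share_vector(sv$units, sv$X * 1000, sv$Y * 7)
  perm <- sample(sv$k)
  permuted <- share_vector(sv$units[perm], sv$X[perm], sv$Y[perm],
                           normalize = FALSE)
  for (f in list(function(s) gini_hoover(s)$value,
                 function(s) gini_lorenz(s)$value,
                 theil)) {
    expect_equal(f(scaled), f(sv), tolerance = 1e-12)
    expect_equal(f(permuted), f(sv), tolerance = 1e-12)
  }
})

test_that("Pigou-Dalton transfers never increase Lorenz Gini or Theil", {
  for (seed in 1:20) {
    sv <- gen_share_vector(12, concentration = 1, seed = seed)
    r <- sv$X / sv$Y
    rich <- which.max(r); poor <- which.min(r)
    eps <- 0.25 * sv$X[rich]
    X2 <- sv$X; X2[rich] <- X2[rich] - eps; X2[poor] <- X2[poor] + eps
    sv2 <- share_vector(sv$units, X2, sv$Y, normalize = FALSE)
    expect_lte(gini_lorenz(sv2)$value, gini_lorenz(sv)$value + 1e-12)
    expect_lte(theil(sv2), theil(sv) + 1e-12)
  }
})

test_that("group decomposition is exactly additive and covers edge cases", {
  pan <- gen_panel(panel_spec(seed = 21))
  d <- theil_decompose(pan, 2016, "beds")
  expect_equal(d$T, d$T_intra + d$T_inter, tolerance = 1e-14)
  expect_equal(d$T, theil(make_shares(pan, 2016, "beds", "population")),
               tolerance = 1e-10)
  expect_equal(d$contribution_intra + d$contribution_inter, 1,
               tolerance = 1e-12)

  # single group: all inequality is within
  one <- setNames(rep("all", 31), unique(pan$dmu))
  d1 <- theil_decompose(pan, 2016, "beds", grouping = one)
  expect_equal(d1$T_inter, 0, tolerance = 1e-12)
  expect_equal(d1$T_intra, d1$T, tolerance = 1e-12)

  # internally homogeneous groups: all inequality is between
  pan2 <- toy_panel(dmu = paste0("d", 1:4), group = c("g1", "g1", "g2", "g2"),
                    years = 2020, institutions = c(2, 4, 30, 60),
                    beds = c(2, 4, 30, 60), staff = c(2, 4, 30, 60),
                    outpatient_visits = rep(1, 4),
                    discharged_patients = rep(1, 4),
                    population = c(1, 2, 1, 2), area_km2 = rep(1, 4))
  d2 <- theil_decompose(pan2, 2020, "beds")
  expect_equal(d2$T_intra, 0, tolerance = 1e-12)
  expect_equal(d2$T, d2$T_inter, tolerance = 1e-12)

  expect_error(theil_decompose(pan, 2016, "beds",
                               grouping = c(E01 = "eastern")),
               "no group label")
})

test_that("contribution rates average yearly ratios and flag zero years", {
  flat <- tibble::tibble(T = c(0.2, 0.4), T_intra = c(0.1, 0.2))
  expect_equal(contribution_rates(flat)$contribution_intra, 0.5)
  pooled <- contribution_rates(tibble::tibble(T = c(0.1, 0.3),
                                              T_intra = c(0.1, 0.0)),
                               method = "pooled")
  expect_equal(pooled$contribution_intra, 0.25)
  expect_warning(
    cr <- contribution_rates(tibble::tibble(T = c(0, 0.2),
                                            T_intra = c(0, 0.1))),
    "excluded")
  expect_equal(cr$n_years, 1)
  expect_equal(cr$contribution_intra, 0.5)
})
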