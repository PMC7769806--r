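test_that("radial scores solve hand-checkable toy problems", {
  solo <- technology(matrix(2, 1), matrix(3, 1), "only")
  r <- dea_radial(solo, "only")
  expect_equal(r$phi, 1, tolerance = 1e-9)
  expect_equal(unname(r$lambda["only"]), 1, tolerance = 1e-9)

  # A=(x=1,y=1), B=(x=1,y=2): under CRS, A can be expanded to B's output
  tech <- technology(matrix(c(1, 1), 1), matrix(c(1, 2), 1), c("A", "B"))
  expect_equal(dea_radial(tech, "A")$phi, 2, tolerance = 1e-9)
  expect_equal(dea_radial(tech, "B")$phi, 1, tolerance = 1e-9)
  expect_equal(dea_radial(tech, "A")$te, 0.5, tolerance = 1e-9)

  # strict domination in outputs at equal inputs forces phi > 1
  dom <- technology(matrix(c(1, 1, 1, 1), 2), matrix(c(1, 1, 2, 3), 2),
                    c("worse", "better"))
  expect_gt(dea_radial(dom, "worse")$phi, 1)
})

test_that("second-stage slacks recover a hand-solved input excess", {
  # B's radial projection (phi = 1, peer A) leaves 2 units of input 1
  tech <- technology(matrix(c(2, 2, 4, 2), 2), matrix(c(2, 2), 1),
                     c("A", "B"))
  sl <- dea_slacks(tech, "B")
  expect_equal(unname(sl$input_slacks), c(-2, 0), tolerance = 1e-8)
  expect_equal(unname(sl$output_slacks), 0, tolerance = 1e-8)
  slA <- dea_slacks(tech, "A")
  expect_equal(max(abs(c(slA$input_slacks, slA$output_slacks))), 0,
               tolerance = 1e-8)
})

test_that("returns-to-scale classification follows the Banker criterion", {
  ray <- technology(matrix(c(1, 2, 4), 1), matrix(c(2, 4, 8), 1),
                    c("s", "m", "l"))
  for (d in ray$dmus) expect_equal(dea_rts(ray, d), "CRS")

  # concave 1-in/1-out technology: smallest below MPSS, largest above
  conc <- technology(matrix(c(1, 2, 4), 1), matrix(c(1, 3, 4), 1),
                     c("small", "mpss", "large"))
  expect_equal(dea_rts(conc, "small"), "IRS")
  expect_equal(dea_rts(conc, "mpss"), "CRS")
  expect_equal(dea_rts(conc, "large"), "DRS")
})

test_that("LP scores match brute-force vertex enumeration on tiny technologies", {
  toys <- oracle_toy_technologies()
  for (toy in toys) {
    n <- ncol(toy$X)
    for (vrs in c(FALSE, TRUE)) {
      tech <- technology(toy$X, toy$Y, rts = if (vrs) "VRS" else "CRS")
      for (d in tech$dmus) {
        i <- match(d, tech$dmus)
        expected <- oracle_dea_bruteforce(toy$X, toy$Y, toy$X[, i], toy$Y[, i],
                                    vrs = vrs)
        expect_equal(dea_radial(tech, d)$phi, expected, tolerance = 1e-3)
      }
    }
  }
})

test_that("phi is invariant to rescaling any input or output row", {
  toy <- oracle_toy_technologies()[[4]]
  tech <- technology(toy$X, toy$Y)
  scaled <- technology(toy$X * c(1000, 0.01), toy$Y * c(7, 0.5))
  for (d in tech$dmus) {
    expect_equal(dea_radial(scaled, d)$phi, dea_radial(tech, d)$phi,
                 tolerance = 1e-9)
  }
})

test_that("dominated DMUs do not move others' scores; CRS >= VRS >= 1", {
  fp <- gen_frontier_panel(frontier_spec(n_dmus = 12, n_frontier = 4,
                                         seed = 31))
  crs <- panel_technology(fp$panel, 2013, rts = "CRS")
  vrs <- panel_technology(fp$panel, 2013, rts = "VRS")
  phi_crs <- vapply(crs$dmus, function(d) dea_radial(crs, d)$phi, numeric(1))
  phi_vrs <- vapply(vrs$dmus, function(d) dea_radial(vrs, d)$phi, numeric(1))
  expect_true(all(phi_crs >= phi_vrs - 1e-9))
  expect_true(all(phi_vrs >= 1 - 1e-9))

  # append a strictly dominated DMU: nobody else's score may move
  worst <- which.max(phi_crs)
  Xa <- cbind(crs$X, new = crs$X[, worst] * 1.3)
  Ya <- cbind(crs$Y, new = crs$Y[, worst] * 0.7)
  aug <- technology(Xa, Ya, c(crs$dmus, "dominated"))
  for (d in crs$dmus) {
    expect_equal(dea_radial(aug, d)$phi, phi_crs[[d]], tolerance = 1e-9)
  }
})

test_that("efficiency_table recovers constructed frontier membership", {
  fp <- gen_frontier_panel(frontier_spec(seed = 17))
  eff <- dea_efficiency(fp$panel, 2015, rts = "CRS")
  expect_equal(nrow(eff), 31)
  expect_true(all(eff$phi >= 1 - 1e-9))
  truth <- fp$truth[fp$truth$year == 2015, ]
  frontier <- truth$dmu[truth$c == 1]
  slack_cols <- grep("^slack_", names(eff), value = TRUE)
  on_front <- eff$dmu[abs(eff$phi - 1) < 1e-6 &
                        rowSums(abs(as.matrix(eff[slack_cols]))) < 1e-6]
  expect_setequal(on_front, frontier)
  expect_equal(eff$phi[match(truth$dmu, eff$dmu)], truth$true_phi,
               tolerance = 1e-6)

  # permuting panel rows leaves every per-DMU result unchanged
  perm <- resource_panel(fp$panel[sample(nrow(fp$panel)), ])
  eff2 <- dea_efficiency(perm, 2015, rts = "CRS")
  eff2 <- eff2[match(eff$dmu, eff2$dmu), ]
  expect_equal(eff2$phi, eff$phi, tolerance = 1e-12)
})

test_that("radial scores agree with an independent simplex implementation", {
  skip_if_not_installed("boot")
  toy <- oracle_toy_technologies()[[2]]  # non-degenerate 3-DMU toy
  tech <- technology(toy$X, toy$Y)
  for (i in seq_along(tech$dmus)) {
    n <- ncol(toy$X)
    ref <- boot::simplex(
      a = c(1, rep(0, n)),
      A1 = cbind(0, toy$X), b1 = toy$X[, i],
      A2 = cbind(-toy$Y[, i], toy$Y), b2 = rep(0, nrow(toy$Y)),
      maxi = TRUE)
    expect_equal(dea_radial(tech, tech$dmus[i])$phi, unname(ref$value),
                 tolerance = 1e-7)
  }
})

test_that("nonpositive data are rejected up front", {
  expect_error(technology(matrix(c(1, 0), 1), matrix(c(1, 1), 1)),
               "strictly positive")
  pan <- gen_panel(panel_spec(group_sizes = c(eastern = 3), seed = 2))
  pan$beds[2] <- 0
  df <- tibble::as_tibble(unclass(pan))
  expect_error(panel_technology(resource_panel(df), pan$year[2]),
               "nonpositive input/output")
})
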