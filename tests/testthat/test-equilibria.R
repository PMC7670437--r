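# Solid-liquid equilibria, partition coefficients and cocrystal
# thermodynamics.

fus_for_ideal_x <- function(x_sat, Tm = 400, T = 300) {
  fusion_properties(log(x_sat) * 8.314 / (1 / Tm - 1 / T), Tm)
}

test_that("ideal solubility has its closed-form values and limits", {
  fus <- fusion_properties(20000, 400)
  expect_equal(ideal_ln_solubility(fus, 400), 0)
  expect_equal(exp(ideal_ln_solubility(fus, 300)),
               exp((20000 / 8.314) * (1 / 400 - 1 / 300)),
               tolerance = 1e-12)
  expect_equal(exp(ideal_ln_solubility(fus, 300)), 0.1347, tolerance = 1e-4)
  # heat-capacity term vanishes identically at T = Tm
  with_cp <- fusion_properties(20000, 400, dCp = 75)
  expect_equal(ideal_ln_solubility(with_cp, 400), 0)
  expect_false(isTRUE(all.equal(ideal_ln_solubility(with_cp, 300),
                                ideal_ln_solubility(fus, 300))))
})

test_that("ideal solubility increases monotonically with T below Tm", {
  fus <- fusion_properties(30000, 420)
  Ts <- seq(280, 415, by = 5)
  xs <- exp(ideal_ln_solubility(fus, Ts))
  expect_true(all(diff(xs) > 0))
})

test_that("the solubility solver is exact for ideal solutions and self-consistent otherwise", {
  fus <- fusion_properties(20000, 400)
  id <- ideal_model(2)
  x <- solve_solubility(id, fus, 300)
  expect_equal(as.numeric(x), exp(ideal_ln_solubility(fus, 300)),
               tolerance = 1e-12)
  expect_equal(attr(x, "iterations"), 1L)

  mod <- flory_huggins(toy_fh_records())
  xs <- solve_solubility(mod, fus, 300)
  lng <- lngamma(mod, c(xs, 1 - xs), 300)[1L]
  expect_lt(abs(log(as.numeric(xs)) - (ideal_ln_solubility(fus, 300) - lng)),
            1e-7)
  expect_warning(solve_solubility(id, fus, 410), "x = 1")
})

test_that("the solver agrees with a dense grid scan of the equilibrium residual", {
  fus <- fusion_properties(18000, 380)
  recs <- toy_fh_records()
  mod <- flory_huggins(recs)
  xs <- as.numeric(solve_solubility(mod, fus, 300))
  grid <- seq(1e-6, 1 - 1e-6, length.out = 1e6)
  resid <- abs(log(grid) -
                 (ideal_ln_solubility(fus, 300) -
                    oracle_fh_binary_lng1(grid, as.data.frame(recs), 300)))
  x_scan <- grid[which.min(resid)]
  expect_equal(xs, x_scan, tolerance = 2e-6)
})

test_that("partition coefficients reduce to the concentration ratio and rescale-invariance", {
  expect_equal(kow_from_gammas(3.7, 3.7), log10(0.151), tolerance = 1e-12)
  expect_equal(kow_from_gammas(3.7, 3.7), -0.8210, tolerance = 1e-4)
  expect_equal(kow_from_gammas(10 * 2.5, 10 * 0.8),
               kow_from_gammas(2.5, 0.8), tolerance = 1e-12)
  expect_error(kow_from_gammas(-1, 1), "positive")
})

test_that("log_kow evaluates infinite dilution in the two phases", {
  # ideal phases: gammas equal 1, so the constant is recovered
  expect_equal(log_kow(ideal_model(2), ideal_model(3), 298.15),
               log10(0.151), tolerance = 1e-12)
  # Flory-Huggins via the named-substance wrapper equals the assembled call
  tab <- bundled_hansen_table()
  rec <- list(hansen_lookup("Camphor", tab), hansen_lookup("Water", tab),
              hansen_lookup("Octanol", tab))
  manual <- log_kow(flory_huggins(rec[1:2]), flory_huggins(rec), 298.15)
  expect_equal(fh_log_kow("Camphor"), manual, tolerance = 1e-12)
})

test_that("solubility product calibration is plain activity arithmetic", {
  expect_equal(kcc_from_point(0.1, 0.1, 1, 1), 0.01)
  expect_equal(kcc_from_point(0.1, 0.2, 1, 1, a = 2, b = 1), 0.002)
  expect_error(kcc_from_point(0, 0.1, 1, 1), "positive")
})

test_that("ideal invariant points have the closed-form hyperbola intersections", {
  fusA <- fus_for_ideal_x(0.2)
  fusB <- fus_for_ideal_x(0.3)
  spec <- cocrystal_spec(1, 1, K_cc = 0.01)
  inv <- invariant_points(ideal_model(3), fusA, fusB, spec, 300)
  expect_equal(inv["on_A_line", "x_A"], 0.2, tolerance = 1e-7)
  expect_equal(inv["on_A_line", "x_B"], 0.01 / 0.2, tolerance = 1e-7)
  expect_equal(inv["on_B_line", "x_B"], 0.3, tolerance = 1e-7)
  expect_equal(inv["on_B_line", "x_A"], 0.01 / 0.3, tolerance = 1e-7)
  # canonical order: the A-rich point first
  expect_gt(inv$x_A[1L], inv$x_A[2L])
  expect_true(all(abs(inv$residual) < 1e-8))
})

test_that("a solubility product of the pure-saturation activities degenerates to one point", {
  fusA <- fus_for_ideal_x(0.2)
  fusB <- fus_for_ideal_x(0.3)
  # K chosen so both intersections coincide at (0.2, 0.3)
  spec <- cocrystal_spec(1, 1, K_cc = 0.2 * 0.3)
  inv <- invariant_points(ideal_model(3), fusA, fusB, spec, 300)
  expect_equal(inv$x_A[1L], inv$x_A[2L], tolerance = 1e-6)
  expect_equal(inv$x_B[1L], inv$x_B[2L], tolerance = 1e-6)
})

test_that("the ideal cocrystal line is the K/x hyperbola with invariant endpoints", {
  fusA <- fus_for_ideal_x(0.2)
  fusB <- fus_for_ideal_x(0.3)
  spec <- cocrystal_spec(1, 1, K_cc = 0.01)
  inv <- invariant_points(ideal_model(3), fusA, fusB, spec, 300)
  cl <- cocrystal_line(ideal_model(3), fusA, fusB, spec, 300,
                       invariants = inv, n_points = 9)
  expect_equal(cl$x_B, 0.01 / cl$x_A, tolerance = 1e-8)
  two <- cocrystal_line(ideal_model(3), fusA, fusB, spec, 300,
                        invariants = inv, n_points = 2)
  expect_equal(two$x_A, inv$x_A, tolerance = 1e-12)
  expect_equal(two$x_B, inv$x_B, tolerance = 1e-7)
})

test_that("non-ideal cocrystal lines satisfy the activity product bin by bin", {
  recs <- rbind(toy_fh_records(),
                hansen_record("coformer", 18, 7, 8, V = 80))[c(1, 3, 2), ]
  mod <- flory_huggins(recs)  # components (A, B, solvent)
  fusA <- fusion_properties(21000, 390)
  fusB <- fusion_properties(19000, 370)
  spec <- cocrystal_spec(1, 1, K_cc = 2e-3)
  inv <- invariant_points(mod, fusA, fusB, spec, 310)
  cl <- cocrystal_line(mod, fusA, fusB, spec, 310, invariants = inv,
                       n_points = 7)
  for (k in seq_len(nrow(cl))) {
    x <- c(cl$x_A[k], cl$x_B[k], cl$x_solvent[k])
    lg <- lngamma(mod, x, 310)
    expect_equal((x[1] * exp(lg[1])) * (x[2] * exp(lg[2])), 2e-3,
                 tolerance = 1e-8)
  }
})

test_that("the cocrystal region narrows monotonically as the solubility product rises", {
  # a larger K_CC means a more soluble (less stable) cocrystal: on the ideal
  # toy the invariant points sit at (x_A.sat, K/x_A.sat) and (K/x_B.sat,
  # x_B.sat), so their separation shrinks monotonically and vanishes when K
  # reaches the product of the pure saturation activities
  fusA <- fus_for_ideal_x(0.2)
  fusB <- fus_for_ideal_x(0.3)
  widths <- vapply(c(0.002, 0.01, 0.03), function(K) {
    inv <- invariant_points(ideal_model(3), fusA, fusB,
                            cocrystal_spec(1, 1, K_cc = K), 300)
    inv$x_A[1L] - inv$x_A[2L]
  }, 0)
  expect_equal(widths, 0.2 - c(0.002, 0.01, 0.03) / 0.3, tolerance = 1e-6)
  expect_gt(widths[1L], widths[2L])
  expect_gt(widths[2L], widths[3L])
})

test_that("ternary diagrams close their mass balance and hit both lines at the invariants", {
  recs <- rbind(toy_fh_records(),
                hansen_record("coformer", 18, 7, 8, V = 80))[c(1, 3, 2), ]
  mod <- flory_huggins(recs)
  fusA <- fusion_properties(21000, 390)
  fusB <- fusion_properties(19000, 370)
  spec <- cocrystal_spec(1, 1, K_cc = 2e-3)
  dia <- ternary_diagram(mod, fusA, fusB, spec, 310, n_points = 7)
  for (df in list(dia$solubility_A, dia$solubility_B, dia$cocrystal)) {
    expect_equal(df$x_A + df$x_B + df$x_solvent, rep(1, nrow(df)),
                 tolerance = 1e-9)
  }
  inv <- dia$invariant_points
  for (k in 1:2) {
    x <- as.numeric(inv[k, 1:3])
    lg <- lngamma(mod, x, 310)
    solid <- if (k == 1L) 1L else 2L
    fus <- if (k == 1L) fusA else fusB
    # on the solid's own solubility line ...
    expect_lt(abs(log(x[solid]) + lg[solid] - ideal_ln_solubility(fus, 310)),
              1e-6)
    # ... and on the cocrystal line
    expect_lt(abs((log(x[1]) + lg[1]) + (log(x[2]) + lg[2]) - log(2e-3)),
              1e-6)
  }
  # mass-fraction conversion keeps the balance closed
  dm <- ternary_diagram(mod, fusA, fusB, spec, 310, n_points = 5,
                        units = "mass",
                        molar_masses = c(A = 151.2, B = 138.1, solvent = 32))
  expect_equal(dm$cocrystal$x_A + dm$cocrystal$x_B + dm$cocrystal$x_solvent,
               rep(1, 5), tolerance = 1e-9)
})

test_that("ideal-system solubility lines are constant-composition loci", {
  fusA <- fus_for_ideal_x(0.2)
  fusB <- fus_for_ideal_x(0.3)
  spec <- cocrystal_spec(1, 1, K_cc = 0.01)
  dia <- ternary_diagram(ideal_model(3), fusA, fusB, spec, 300, n_points = 6)
  expect_equal(dia$solubility_A$x_A, rep(0.2, 6), tolerance = 1e-9)
  expect_equal(dia$solubility_B$x_B, rep(0.3, 6), tolerance = 1e-9)
})
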