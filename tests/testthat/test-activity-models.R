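# The three activity models: combinatorial term, exchange energies,
# segment activity coefficients, full models vs independent oracles, and
# the Hansen/Flory-Huggins pieces.

test_that("combinatorial term vanishes for pure and for identical components", {
  expect_equal(combinatorial_lngamma(1, r = 2, q = 3), 0)
  expect_equal(combinatorial_lngamma(c(0.3, 0.7), r = c(2, 2), q = c(1.5, 1.5)),
               c(0, 0), tolerance = 1e-12)
})

test_that("combinatorial term matches the literal evaluation on a binary", {
  x <- c(0.5, 0.5); r <- c(2, 1); q <- c(2, 1)
  expect_equal(combinatorial_lngamma(x, r, q, z = 10),
               oracle_sg_combinatorial(x, r, q, z = 10), tolerance = 1e-12)
  x2 <- c(0.2, 0.5, 0.3); r2 <- c(3, 1.2, 0.7); q2 <- c(2.5, 1, 0.9)
  expect_equal(combinatorial_lngamma(x2, r2, q2),
               oracle_sg_combinatorial(x2, r2, q2), tolerance = 1e-12)
})

test_that("original exchange energy has the misfit and hb limits", {
  expect_equal(exchange_energy_2002(0, 0), 0)
  expect_equal(exchange_energy_2002(0.005, -0.005), 0)
  expect_equal(exchange_energy_2002(0.01, 0.01), 16466.72 * 0.0004 / 2,
               tolerance = 1e-12)
  # symmetric, and hb term attractive for a strong donor/acceptor pair
  expect_equal(exchange_energy_2002(0.012, -0.013),
               exchange_energy_2002(-0.013, 0.012))
  p <- cosmosac2002_params()
  hb <- exchange_energy_2002(0.012, -0.012) -
    (p$alpha_prime / 2) * (0.012 - 0.012)^2
  expect_lt(hb, 0)
})

test_that("revised exchange energy selects hb constants by class pair and sign", {
  expect_equal(exchange_energy_2010(0, 0, "OH", "OH", 298.15), 0)
  expect_equal(exchange_energy_2010(0.02, -0.02, "NHB", "NHB", 298.15),
               0 + 0)  # (sm+sn)=0 and NHB has no hb term
  expect_equal(exchange_energy_2010(0.01, -0.01, "OH", "OH", 298.15),
               -4013.78 * 0.02^2, tolerance = 1e-12)
  expect_equal(exchange_energy_2010(0.01, -0.01, "OT", "OH", 298.15),
               -3016.43 * 0.02^2, tolerance = 1e-12)
  # same-sign pairs carry no hb term
  expect_equal(exchange_energy_2010(0.01, 0.02, "OH", "OH", 298.15),
               (6525.69 + 1.4859e8 / 298.15^2) * 0.03^2, tolerance = 1e-9)
  expect_error(exchange_energy_2010(0, 0, "XX", "OH", 298.15), "classes")
  # printed (repulsive) sign available as a flag
  p_plus <- cosmosac2010_params(hb_sign = 1)
  expect_equal(exchange_energy_2010(0.01, -0.01, "OH", "OH", 298.15, p_plus),
               +4013.78 * 0.02^2, tolerance = 1e-12)
})

test_that("segment activity coefficients solve the fixed point", {
  # zero exchange energy: the sum collapses to sum(p) = 1
  p <- rep(1 / 51, 51)
  expect_equal(segment_gamma(p, matrix(0, 51, 51), 298.15), rep(1, 51))

  # 2-bin toy vs naive brute force
  T <- 298.15; R <- 0.001987
  w <- R * T
  p2 <- c(0.5, 0.5)
  W2 <- matrix(c(0, w, w, 0), 2, 2)
  gam <- segment_gamma(p2, W2, T)
  expect_equal(gam, oracle_segment_gamma(p2, W2, T, iters = 1e5L),
               tolerance = 1e-8)

  # re-inserting the converged solution reproduces it
  E <- exp(-W2 / (R * T))
  rhs <- 1 / as.vector(E %*% (p2 * gam))
  expect_lt(max(abs(rhs - gam) / gam), 1e-8)
})

test_that("original model: pure components and indistinguishable components are ideal", {
  comps <- toy_binary_components()
  mod <- cosmosac(comps, version = "2002")
  expect_equal(lngamma(mod, c(1, 0), 298.15)[1L], 0, tolerance = 1e-10)
  expect_equal(lngamma(mod, c(0, 1), 298.15)[2L], 0, tolerance = 1e-10)
  twin <- cosmosac(list(comps[[1L]], comps[[1L]]), version = "2002")
  expect_equal(lngamma(twin, c(0.25, 0.75), 310), c(0, 0), tolerance = 1e-10)
})

test_that("original model matches the independent oracle on a toy binary", {
  comps <- toy_binary_components()
  mod <- cosmosac(comps, version = "2002")
  got <- lngamma(mod, c(0.5, 0.5), 298.15)
  want <- oracle_cosmosac2002(lapply(comps, as_oracle_comp), c(0.5, 0.5), 298.15)
  expect_equal(got, want, tolerance = 1e-9)
})

test_that("revised model matches the independent oracle on an hb-active binary", {
  comps <- toy_hb_binary_components()
  mod <- cosmosac(comps, version = "2010")
  got <- lngamma(mod, c(0.4, 0.6), 298.15)
  want <- oracle_cosmosac2010(lapply(comps, as_oracle_comp), c(0.4, 0.6), 298.15)
  expect_equal(got, want, tolerance = 1e-9)
  expect_equal(lngamma(mod, c(1, 0), 298.15)[1L], 0, tolerance = 1e-10)
})

test_that("revised model degenerates to the original for NHB-only molecules", {
  comps <- toy_binary_components()  # neutral-apolar: no hb area, |sigma| < cutoff
  p02 <- cosmosac2002_params()
  mod02 <- cosmosac(comps, version = "2002", params = p02)
  mod10 <- cosmosac(comps, version = "2010",
                    params = cosmosac2010_params(A_ES = p02$alpha_prime / 2,
                                                 B_ES = 0))
  x <- c(0.35, 0.65)
  expect_equal(lngamma(mod10, x, 305), lngamma(mod02, x, 305),
               tolerance = 1e-9)
})

test_that("residuals are invariant under a global charge sign flip", {
  mols <- list(make_toy_molecule(seed = 1L),
               make_toy_molecule(seed = 2L, total_area = 150,
                                 cavity_volume = 140))
  mirr <- lapply(mols, mirror_molecule)
  x <- c(0.5, 0.5)
  for (ver in c("2002", "2010")) {
    lg <- lngamma(cosmosac(mols, version = ver), x, 298.15)
    lg_m <- lngamma(cosmosac(mirr, version = ver), x, 298.15)
    expect_equal(lg_m, lg, tolerance = 1e-9)
  }
})

test_that("interaction parameter reproduces the hand-computed value and asymmetry", {
  water <- hansen_lookup("Water")
  apap <- hansen_lookup("Acetaminophen")
  chi_aw <- fh_chi(apap, water, 298.15)
  direct <- 60.07 / (8.314 * 298.15) *
    ((23.37 - 15.6)^2 + 0.25 * (15.75 - 16)^2 + 0.25 * (1.85 - 42.3)^2)
  expect_equal(chi_aw, direct, tolerance = 1e-12)
  expect_equal(chi_aw, 11.38, tolerance = 0.01)
  expect_equal(fh_chi(water, apap, 298.15), chi_aw * water$V / apap$V,
               tolerance = 1e-12)
  expect_equal(fh_chi(water, water, 298.15), 0)
})

test_that("Flory-Huggins model is ideal for pure or identical components", {
  recs <- toy_fh_records()
  mod <- flory_huggins(recs)
  expect_equal(lngamma(mod, c(1, 0), 298.15)[1L], 0, tolerance = 1e-12)
  same <- flory_huggins(rbind(recs[1, ], recs[1, ]))
  expect_equal(lngamma(same, c(0.4, 0.6), 298.15), c(0, 0), tolerance = 1e-12)
})

test_that("Flory-Huggins matches the literal triple-loop oracle in both conventions", {
  recs <- toy_fh_records()
  x <- c(0.3, 0.7)
  for (conv in c("per-volume", "as-printed")) {
    mod <- flory_huggins(recs, convention = conv)
    expect_equal(lngamma(mod, x, 310),
                 oracle_flory_huggins(x, as.data.frame(recs), 310, conv),
                 tolerance = 1e-9)
  }
  # ternary with a third record
  recs3 <- rbind(recs, hansen_record("cosolvent", 17, 5, 12, V = 90))
  x3 <- c(0.2, 0.3, 0.5)
  mod3 <- flory_huggins(recs3)
  expect_equal(lngamma(mod3, x3, 298.15),
               oracle_flory_huggins(x3, as.data.frame(recs3), 298.15),
               tolerance = 1e-9)
})

test_that("group contributions compose Hansen parameters as specified", {
  one <- hansen_from_groups(data.frame(F_d = 420, F_p = 210, E_h = 2000, V = 50))
  expect_equal(one$delta_d, 420 / 50)
  expect_equal(one$delta_p, 210 / 50)
  expect_equal(one$delta_h, sqrt(2000) / 50)
  two <- hansen_from_groups(data.frame(F_d = c(420, 270), F_p = c(210, 0),
                                       E_h = c(2000, 400), V = c(50, 30)))
  expect_equal(two$delta_d, (420 + 270) / 80)
  expect_equal(two$delta_p, sqrt(210^2) / 80)
  expect_equal(two$delta_h, sqrt(2400) / 80)
  expect_equal(two$delta_t,
               sqrt(two$delta_d^2 + two$delta_p^2 + two$delta_h^2))
  expect_error(hansen_from_groups(data.frame()[0, ]), "at least one group")
})

test_that("delta_t from printed components reproduces the tabulated totals", {
  expect_equal(round(hansen_delta_t(27.45, 9.46, 1.15), 2), 29.06)
  expect_equal(round(hansen_delta_t(15.6, 16, 42.3), 1), 47.8)
})

test_that("all models satisfy the pure-component limit gamma -> 1", {
  comps <- toy_binary_components()
  recs <- toy_fh_records()
  models <- list(cosmosac(comps, "2002"),
                 cosmosac(toy_hb_binary_components(), "2010"),
                 flory_huggins(recs))
  for (mod in models) {
    for (i in 1:2) {
      x <- c(0, 0); x[i] <- 1
      expect_equal(lngamma(mod, x, 298.15)[i], 0, tolerance = 1e-9)
    }
  }
})

gibbs_duhem_residual <- function(mod, x1, T = 298.15, h = 1e-4) {
  up <- lngamma(mod, c(x1 + h, 1 - x1 - h), T)
  dn <- lngamma(mod, c(x1 - h, 1 - x1 + h), T)
  sum(c(x1, 1 - x1) * (up - dn) / (2 * h))
}

test_that("both segment models satisfy Gibbs-Duhem on toy binaries", {
  models <- list(cosmosac(toy_binary_components(), "2002"),
                 cosmosac(toy_hb_binary_components(), "2010"))
  for (mod in models) {
    for (x1 in c(0.25, 0.5, 0.8)) {
      expect_lt(abs(gibbs_duhem_residual(mod, x1)), 1e-3)
    }
  }
})

test_that("the doubled interaction term makes Flory-Huggins thermodynamically inconsistent", {
  # the activity expression's 2*V_i*sum(chi*phi^2) term double-counts the
  # pair energy relative to a free-energy derivation, so Gibbs-Duhem fails
  # structurally; frozen for equal molar volumes, where the residual has
  # the closed form 2*V*kappa*(2*x1 - 1) with kappa the symmetric kernel
  recs <- rbind(hansen_record("a", 19, 8, 6, V = 100),
                hansen_record("b", 16, 9, 10, V = 100))
  mod <- flory_huggins(recs)
  kappa <- fh_chi(recs[1, ], recs[2, ], 298.15) / 100
  for (x1 in c(0.25, 0.4, 0.8)) {
    expect_equal(gibbs_duhem_residual(mod, x1),
                 2 * 100 * kappa * (2 * x1 - 1), tolerance = 1e-4)
  }
  # consistency is restored in the trivial chi = 0 limit
  same <- flory_huggins(rbind(recs[1, ], recs[1, ]))
  expect_lt(abs(gibbs_duhem_residual(same, 0.3)), 1e-10)
})
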