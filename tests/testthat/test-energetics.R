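test_that("allometric helpers evaluate their closed forms", {
  expect_equal(wetted_area(1), 0.08)
  expect_equal(wetted_area(7000), 25.3, tolerance = 0.002)
  expect_equal(wetted_area(46000), 85.9, tolerance = 0.002)
  expect_error(wetted_area(0), "positive")

  expect_equal(reynolds(7.8, 6.2, 1e-6), 4.84e7, tolerance = 0.002)
  expect_equal(reynolds(10, 0), 0)
  expect_equal(reynolds(10, 4), 2 * reynolds(10, 2))
})

test_that("the shipped registry reproduces the reference masses", {
  expect_equal(mass_from_length("humpback", 7.8), 7000)
  expect_equal(mass_from_length("humpback", 10.5), 17000)
  expect_equal(mass_from_length("humpback", 14.7), 46000)
  expect_error(mass_from_length("narwhal", 5), "humpback")
  reg <- mass_length_registry(extra = list(toy = c(a = 1, b = 3)))
  expect_equal(mass_from_length("toy", 10, reg), 1000)
})

test_that("drag coefficient matches the airship formula", {
  expect_equal(drag_coefficient(1e7, 0.18, F_amp = 2), 0.00662,
               tolerance = 1e-3)
  expect_equal(drag_coefficient(1e7, 0, F_amp = 1), 0.00287,
               tolerance = 2e-3)
  expect_lt(drag_coefficient(1e8, 0.18), drag_coefficient(1e7, 0.18))
  expect_warning(drag_coefficient(1e5, 0.18), "Reynolds")
})

test_that("plateau drag work is linear in duration and matches the oracle", {
  m <- whale1()
  expect_equal(work_drag_plateau(m, 6.2, 0), 0)
  w1 <- work_drag_plateau(m, 6.2, 1)
  expect_equal(w1, 1.49e4, tolerance = 0.005)
  expect_equal(work_drag_plateau(m, 6.2, 2), 2 * w1)
})

test_that("closed-form acceleration drag work matches trapezoid quadrature", {
  cases <- list(
    list(m = whale1(), p = whale1_profile()),
    list(m = morphometry("humpback", 14.8, M_body = 46000),
         p = speed_profile(1.75, 8.1, 12.7)),
    list(m = morphometry("humpback", 10.5, M_body = 17000),
         p = speed_profile(1.75, 7.1, 8.1, T_plat = 2))
  )
  for (cs in cases) {
    acc <- work_drag_acceleration(cs$m, cs$p)
    oracle <- drag_work_quadrature(cs$m, cs$p)
    expect_equal(acc$total, oracle, tolerance = 1e-3)
  }
  # the fixed reference case, against its frozen oracle values
  acc <- work_drag_acceleration(whale1(), whale1_profile())
  expect_equal(acc$friction, 4.35e4, tolerance = 0.005)
  expect_equal(acc$added_mass, 5.57e3, tolerance = 0.005)
})

test_that("the constant-speed limit reduces to the plateau formula", {
  m <- whale1()
  lim <- work_drag_acceleration(m, list(U_i = 6.2, U_f = 6.2, T_acc = 8))
  expect_equal(lim$friction, work_drag_plateau(m, 6.2, 8),
               tolerance = 1e-6)
  expect_equal(lim$added_mass, 0)
  near <- work_drag_acceleration(m, speed_profile(6.2 - 1e-7, 6.2, 8))
  expect_equal(near$friction, lim$friction, tolerance = 1e-5)
})

test_that("the energy budget keeps its books and hits the reference total", {
  b <- breach_energetics(whale1(), whale1_profile())
  expect_equal(b$W_metab_total, 9.2e5, tolerance = 0.01)
  # exact bookkeeping: thrust minus drag equals the kinetic terms
  expect_equal(b$W_thrust_total - b$W_drag_acc - b$W_drag_plat,
               b$dKE_body + b$dKE_added, tolerance = 1e-12)
  expect_equal(b$W_metab_total, b$W_thrust_total / (0.25 * 0.75),
               tolerance = 1e-12)

  # drag and added mass off: pure kinetic energy over the efficiencies
  off <- hydro_coefficients(F_amp = 0, k = 1e-12)
  b0 <- breach_energetics(whale1(), whale1_profile(), off)
  expect_equal(b0$W_metab_total,
               0.5 * 7000 * (6.2^2 - 1.75^2) / 0.1875, tolerance = 1e-6)

  # degenerate: no speed change, no plateau, no drag
  bz <- breach_energetics(whale1(),
                          list(U_i = 3, U_f = 3, T_acc = 5, T_plat = 0),
                          off)
  expect_equal(bz$W_metab_total, 0, tolerance = 1e-6)
})

test_that("metabolic cost increases in speed, mass, plateau, and drag factor", {
  base <- breach_energetics(whale1(), whale1_profile())$W_metab_total
  up_Uf <- breach_energetics(whale1(),
                             speed_profile(1.75, 6.8, 8))$W_metab_total
  expect_gt(up_Uf, base)
  up_M <- breach_energetics(morphometry("humpback", 7.8, M_body = 9000),
                            whale1_profile())$W_metab_total
  expect_gt(up_M, base)
  up_plat <- breach_energetics(whale1(),
                               speed_profile(1.75, 6.2, 8, 2))$W_metab_total
  expect_gt(up_plat, base)
  up_F <- breach_energetics(whale1(), whale1_profile(),
                            hydro_coefficients(F_amp = 3))$W_metab_total
  expect_gt(up_F, base)
})

test_that("last-second muscle power matches the reference reconstructions", {
  w4 <- morphometry("humpback", 14.7, M_body = 46000)
  p4 <- speed_profile(1.75, 8.2, 8.5)
  expect_equal(max_power_last_second(w4, p4), 5.0e5, tolerance = 0.02)
  expect_equal(max_power_last_second(whale1(), whale1_profile()), 5.0e4,
               tolerance = 0.02)
  # constant-speed limit: plateau drag power scaled by the efficiencies
  m <- whale1()
  lim <- max_power_last_second(m, list(U_i = 6.2, U_f = 6.2, T_acc = 8))
  expect_equal(lim, work_drag_plateau(m, 6.2, 1) * 0.25 / 0.1875,
               tolerance = 1e-6)
  expect_warning(max_power_last_second(m, speed_profile(2, 5, 0.5)), "T_acc")
})

test_that("mass-specific cost of an 80%-emergence breach rises with mass", {
  # emergence model sets the exit speed; acceleration fixed at 0.65 m/s^2
  masses <- c(7000, 17000, 30000, 46000)
  reg <- mass_length_registry()
  lengths <- (masses / reg$humpback[["a"]])^(1 / reg$humpback[["b"]])
  cost <- vapply(seq_along(masses), function(i) {
    Uf <- min_exit_speed(0.8, 65, lengths[i])
    Tacc <- (Uf - 1.75) / 0.65
    b <- breach_energetics(
      morphometry("humpback", lengths[i], M_body = masses[i]),
      speed_profile(1.75, Uf, Tacc))
    b$W_metab_total / masses[i]
  }, numeric(1))
  expect_true(all(diff(cost) > 0))
})
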