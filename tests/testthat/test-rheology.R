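newtonian_curve <- function(eta = 0.3, n = 50, hold = TRUE) {
  rates <- seq(0, 300, length.out = n)
  flow_curve(
    up = data.frame(shear_rate = rates, shear_stress = eta * rates),
    hold = if (hold) data.frame(shear_rate = rep(300, 10),
                                shear_stress = rep(eta * 300, 10)) else NULL,
    down = data.frame(shear_rate = rev(rates), shear_stress = eta * rev(rates))
  )
}

test_that("viscosity at 300 1/s from hold segment or up-ramp interpolation", {
  expect_equal(viscosity_at(newtonian_curve(0.3)), 0.3, tolerance = 1e-12)
  expect_equal(viscosity_at(newtonian_curve(0.3, hold = FALSE)), 0.3,
               tolerance = 1e-12)
  expect_equal(viscosity_at(newtonian_curve(0.3, hold = FALSE), rate = 150),
               0.3, tolerance = 1e-12)

  # Herschel-Bulkley synthetic matches the closed form at 300 1/s
  fc <- gen_flow_curve(yield_stress_pa = 20, consistency_k = 3,
                       flow_index = 0.6, seed = 1)
  expect_equal(viscosity_at(fc), (20 + 3 * 300^0.6) / 300, tolerance = 1e-9)

  expect_error(viscosity_at(newtonian_curve(hold = FALSE), rate = 400),
               "outside sampled")
})

test_that("RTLA: reversible loop gives 0, proportional loops give exact fractions", {
  expect_equal(rtla(newtonian_curve()), 0, tolerance = 1e-12)

  # down-ramp stress everywhere half the up-ramp: RTLA = 50 by linearity
  rates <- seq(0, 300, length.out = 40)
  up <- data.frame(shear_rate = rates, shear_stress = 0.2 * rates + 5)
  half <- flow_curve(up = up,
                     down = data.frame(shear_rate = rev(rates),
                                       shear_stress = rev(0.5 * up$shear_stress)))
  expect_equal(rtla(half), 50, tolerance = 1e-12)

  # linear ramps sigma = a*g (up), b*g (down): triangle areas give 100*(1 - b/a)
  a <- 0.35; b <- 0.21
  tri <- flow_curve(up = data.frame(shear_rate = rates, shear_stress = a * rates),
                    down = data.frame(shear_rate = rev(rates),
                                      shear_stress = b * rev(rates)))
  expect_equal(rtla(tri), 100 * (1 - b / a), tolerance = 1e-9)

  # invariance under uniform stress rescaling of both ramps
  tri2 <- flow_curve(up = data.frame(shear_rate = rates, shear_stress = 7 * a * rates),
                     down = data.frame(shear_rate = rev(rates),
                                       shear_stress = 7 * b * rev(rates)))
  expect_equal(rtla(tri2), rtla(tri), tolerance = 1e-12)
})

test_that("trapezoidal loop areas converge at second order on smooth curves", {
  # sigma_up = 2*g^1.5, sigma_down = g^1.5 on [0, 300]; closed-form RTLA = 50
  area_err <- function(n) {
    g <- seq(0, 300, length.out = n)
    up <- data.frame(shear_rate = g, shear_stress = 2 * g^1.5)
    dn <- data.frame(shear_rate = rev(g), shear_stress = rev(g^1.5))
    s_asc <- pracma::trapz(g, 2 * g^1.5)
    abs(s_asc - 2 * 300^2.5 / 2.5)
  }
  e1 <- area_err(101); e2 <- area_err(201)
  expect_gte(log2(e1 / e2), 1.9)
  # and the RTLA itself is grid-converged
  g <- seq(0, 300, length.out = 201)
  cr <- flow_curve(up = data.frame(shear_rate = g, shear_stress = 2 * g^1.5),
                   down = data.frame(shear_rate = rev(g), shear_stress = rev(g^1.5)))
  expect_equal(rtla(cr), 50, tolerance = 1e-6)
})

test_that("yield stress from a step drop, smooth decay, and the no-yield error path", {
  # plateau then step drop at 100 Pa
  s <- 10^seq(-1, 3, by = 0.05)
  gp <- ifelse(s < 100, 1000, 200)
  sw <- osc_sweep(s, gp, gp * 0.5)
  ys <- yield_stress(sw)
  expect_lt(abs(ys - 100) / 100, 10^0.05 - 1 + 1e-9)   # within one log grid step

  # constant G' throughout: no yield detected
  expect_error(yield_stress(osc_sweep(s, rep(1000, length(s)), rep(400, length(s)))),
               "no yield")

  # smooth power-law decay: deviation point has a closed form
  dec <- 8; sc <- 74.2
  sw2 <- gen_osc_sweep(critical_stress = sc, decay_exponent = dec, seed = 2)
  expected <- sc * (1 / 0.9)^(1 / dec)
  expect_lt(abs(yield_stress(sw2) - expected) / expected, 0.05)

  # crossover alternative: G' = G'' crossing
  gp3 <- 1000 * (s / 50)^(-0.4); gpp3 <- rep(1000 * (50 / 50)^(-0.4) * 0.3, length(s))
  gpp3 <- 300 * (s / 50)^(0.2)
  sw3 <- osc_sweep(s, gp3, gpp3)
  # analytic crossing: 1000*(x/50)^-0.4 = 300*(x/50)^0.2 -> x = 50*(10/3)^(1/0.6)
  expect_equal(yield_stress(sw3, method = "crossover"),
               50 * (1000 / 300)^(1 / 0.6), tolerance = 0.02)
})

test_that("LVR moduli: norm identity, degenerate angles and plateau averaging", {
  s <- 10^seq(-1, 2, by = 0.1)
  n <- length(s)
  sw45 <- osc_sweep(s, rep(800, n), rep(800, n))
  m <- lvr_moduli(sw45)
  expect_equal(m$delta_deg, 45, tolerance = 1e-9)
  expect_equal(m$g_star, sqrt(2) * 800, tolerance = 1e-9)

  m2 <- lvr_moduli(osc_sweep(s, rep(1000, n), rep(1e-9, n) + 1e-6))
  expect_equal(m2$delta_deg, 0, tolerance = 1e-3)
  expect_equal(m2$g_star, 1000, tolerance = 1e-3)

  m3 <- lvr_moduli(osc_sweep(s, rep(1300, n), rep(600, n)))
  expect_equal(m3$g_star, sqrt(1300^2 + 600^2), tolerance = 1e-9)  # 1431.78
  expect_equal(round(m3$g_star, 2), 1431.78)
  expect_equal(round(m3$delta_deg, 2), 24.78)

  # delta always within [0, 90] and G* >= max(G', G'') for generated sweeps
  for (seed in 1:5) {
    sw <- gen_osc_sweep(delta_deg = runif(1, 5, 85), noise_cv = 0.03, seed = seed)
    mm <- lvr_moduli(sw)
    expect_gte(mm$delta_deg, 0); expect_lte(mm$delta_deg, 90)
    idx <- seq_along(sw$stress_pa)
    expect_true(all(sqrt(sw$g_prime^2 + sw$g_double_prime^2) >=
                      pmax(sw$g_prime, sw$g_double_prime)))
  }
})

test_that("rheological batch comparison flags 25% differences and passes identity", {
  set.seed(41)
  arm <- function(mult = 1, sd_frac = 0.01) {
    n <- 4
    data.frame(eta300 = rnorm(n, 0.35 * mult, 0.35 * sd_frac),
               rtla = rnorm(n, 52.6 * mult, 52.6 * sd_frac),
               yield_stress = rnorm(n, 74 * mult, 74 * sd_frac),
               g_star = rnorm(n, 1400 * mult, 1400 * sd_frac),
               delta = rnorm(n, 25 * mult, 25 * sd_frac))
  }
  a <- arm()
  same <- rheo_equivalence(a, a)
  expect_true(all(same$status == "within"))
  diff25 <- rheo_equivalence(arm(1.25), a)
  expect_true(all(diff25$status == "outside"))
})

test_that("flow and sweep CSV readers reconstruct the objects", {
  tmpf <- withr::local_tempfile(fileext = ".csv")
  fc <- gen_flow_curve(seed = 3, n_points = 30)
  df <- rbind(data.frame(segment = "up", shear_rate_1_per_s = fc$up$shear_rate,
                         shear_stress_pa = fc$up$shear_stress),
              data.frame(segment = "hold", shear_rate_1_per_s = fc$hold$shear_rate,
                         shear_stress_pa = fc$hold$shear_stress),
              data.frame(segment = "down", shear_rate_1_per_s = fc$down$shear_rate,
                         shear_stress_pa = fc$down$shear_stress))
  write.csv(df, tmpf, row.names = FALSE)
  fc2 <- read_flow_csv(tmpf)
  expect_equal(fc2$up$shear_stress, fc$up$shear_stress, tolerance = 1e-9)
  expect_equal(rtla(fc2), rtla(fc), tolerance = 1e-12)

  tmps <- withr::local_tempfile(fileext = ".csv")
  sw <- gen_osc_sweep(seed = 4)
  write.csv(data.frame(stress_pa = sw$stress_pa, g_prime_pa = sw$g_prime,
                       g_double_prime_pa = sw$g_double_prime), tmps,
            row.names = FALSE)
  sw2 <- read_osc_csv(tmps)
  expect_equal(lvr_moduli(sw2), lvr_moduli(sw), tolerance = 1e-9)
})
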