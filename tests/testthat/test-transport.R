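test_that("porosity follows the sphere-packing formula", {
  expect_equal(porosity(0, 101, 3, 50), 1)
  expect_equal(porosity(0.5, 101, 1e6, 50), 1, tolerance = 1e-10)
  expect_equal(porosity(0.5, 101, 3, 50),
               1 - (4 / 3) * pi * 0.125 * 101 / (9 * 50), tolerance = 1e-12)
  expect_equal(round(porosity(0.5, 101, 3, 50), 4), 0.8825)
  expect_error(porosity(5, 101, 2, 10), "overpacked")
})

test_that("tortuosity families: limits, bounds, monotonicity, closed values", {
  fams <- c("hyperbola_of_revolution", "ordered_packings",
            "heterogeneous_catalyst", "cation_exchange_resin", "custom")
  phi <- seq(0.05, 1, by = 0.05)
  for (f in fams) {
    t2 <- tau_squared(f, phi, k = 0.9)
    expect_equal(tau_squared(f, 1, k = 0.9), 1, tolerance = 1e-10)
    expect_true(all(t2 >= 1 - 1e-12))
    expect_true(all(diff(t2) <= 1e-12))   # non-increasing in phi
  }
  expect_equal(tau_squared("cation_exchange_resin", 0.5), 9)
  expect_error(tau_squared("custom", 0.3, k = 0.2), "domain")
})

test_that("generalized random-walk tortuosity matches its series", {
  expect_equal(generalized_tau(0, 0.5), 1)
  expect_equal(generalized_tau(0.5, 0.75), 3)
  expect_error(generalized_tau(0.5, 1), "divergence")
  # truncated geometric series oracle
  for (pn in c(0.1, 0.5, 0.9)) for (pf in c(0.2, 0.8)) {
    tau_series <- 1 + pf * sum(pn^(0:400))
    expect_equal(generalized_tau(pf, pn), tau_series, tolerance = 1e-10)
  }
  # Mackie-Meares special case: p_next = (2 - phi)/2 reproduces the resin
  # model identically
  phi <- seq(0.1, 0.95, by = 0.05)
  expect_equal(generalized_tau(1 - phi, (2 - phi) / 2), (2 - phi) / phi,
               tolerance = 1e-12)
  # custom family with k = 1/2: p_next = (2 - phi)/2 - (1 - phi)/2... check
  # the algebraic identity through tau_squared directly
  k_mm <- function(phi) ((2 - phi) / 2 + (1 - phi)) / (2 - phi)
  for (p in c(0.3, 0.6, 0.9))
    expect_equal(tau_squared("custom", p, k = k_mm(p)),
                 ((2 - p) / p)^2, tolerance = 1e-10)
})

test_that("model fits recover their own synthetic data", {
  d <- c(2, 2.5, 3, 4, 5, 7, 10)
  L_z <- 100 * d^(-1 / 10)  # mildly d-dependent height

  # custom model, k = 0.96, 1% noise: recovered within 2 std
  phi <- porosity(0.5, 101, d, L_z)
  ratio <- 1 / tau_squared("custom", phi, k = 0.96)
  set.seed(8)
  noisy <- ratio * (1 + rnorm(length(d), sd = 0.01))
  fit <- fit_D_vs_d(data.frame(d = d, ratio = noisy, L_z = L_z), "custom")
  expect_lt(abs(coef(fit)[["k"]] - 0.96), 2 * fit$se[["k"]] + 1e-3)

  # tortuosity family with free a_f: noiseless self-fit
  phi2 <- porosity(0.8, 101, d, L_z)
  ratio2 <- 1 / tau_squared("hyperbola_of_revolution", phi2)
  fit2 <- fit_D_vs_d(data.frame(d = d, ratio = ratio2, L_z = L_z),
                     "hyperbola_of_revolution")
  expect_equal(coef(fit2)[["a_f"]], 0.8, tolerance = 1e-6)

  # power law: exact self-fit and degenerate bulk data
  r3 <- 1 - d^(-0.5) / 1.2
  fit3 <- fit_D_vs_d(data.frame(d = d, ratio = r3), "power_law_d")
  expect_equal(unname(coef(fit3)), c(0.5, 1.2), tolerance = 1e-6)
  fit4 <- fit_D_vs_d(data.frame(d = d, ratio = rep(1, length(d))),
                     "power_law_d")
  pred <- predict(fit4, data.frame(d = d))
  expect_equal(pred, rep(1, length(d)), tolerance = 1e-6)
})

test_that("anisotropy ratio power law fits exactly and degenerately", {
  d <- c(2.5, 3, 4, 5, 7, 10, 15, 25)
  ratio <- 50 * d^(-2.3) + 1
  fit <- fit_ratio_power_law(data.frame(d = d, ratio = ratio))
  expect_equal(unname(coef(fit)[["A"]]), 50, tolerance = 1e-6)
  expect_equal(unname(coef(fit)[["l"]]), 2.3, tolerance = 1e-8)
  # isotropic data: A -> 0
  fit2 <- fit_ratio_power_law(data.frame(d = d, ratio = rep(1, length(d))))
  expect_lt(abs(coef(fit2)[["A"]]), 1e-6)
})

test_that("height scaling fit is exact and linear in A", {
  d <- c(2, 3, 5, 8, 12)
  fit <- fit_height_scaling(data.frame(d = d, L_z = 120 * d^(-2 / 3)))
  expect_equal(coef(fit)[["A"]], 120, tolerance = 1e-10)
  fit2 <- fit_height_scaling(data.frame(d = d, L_z = 240 * d^(-2 / 3)))
  expect_equal(coef(fit2)[["A"]], 240, tolerance = 1e-10)
})

test_that("conductivity follows the Nernst-Einstein form", {
  expect_equal(conductivity(ion_mixture(1, 0, 1e-9)), 0)
  # closed form for a single monovalent species
  mix <- ion_mixture(1, 150, 1e-9, temperature = 310)
  expect_equal(conductivity(mix),
               96485.33212^2 * 1e-9 * 150 / (8.314462618 * 310),
               tolerance = 1e-10)
  # linear in D
  mix2 <- ion_mixture(1, 150, 2e-9, temperature = 310)
  expect_equal(conductivity(mix2), 2 * conductivity(mix), tolerance = 1e-12)
  # valency enters squared
  mix3 <- ion_mixture(2, 150, 1e-9, temperature = 310)
  expect_equal(conductivity(mix3), 4 * conductivity(mix), tolerance = 1e-12)
})

test_that("shell resistance equals the radial quadrature", {
  expect_equal(shell_resistance(1, 1e-6, 0), 0)
  for (r in c(2.5e-6, 1e-5)) for (h in c(1e-7, 5e-7)) {
    closed <- shell_resistance(0.7, r, h)
    quad <- integrate(function(x) 0.7 / (4 * pi * x^2), r, r + h,
                      rel.tol = 1e-12)$value
    expect_equal(closed, quad, tolerance = 1e-10)
  }
})

test_that("traversal time scales as h^2 / D", {
  u <- unit_system()
  t1 <- traversal_time(1, 500e-9, u)
  expect_equal(traversal_time(1, 1000e-9, u), 4 * t1)
  expect_equal(traversal_time(2, 500e-9, u), t1 / 2)
  # dimensional check: D = 1 sigma^2/tau = 1e-18/tau_s m^2/s
  expect_equal(t1, (500e-9)^2 / (2 * 1e-18 / u$tau_seconds), tolerance = 1e-12)
})
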