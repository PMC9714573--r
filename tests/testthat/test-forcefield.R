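test_that("pair potentials match their closed forms", {
  eps <- 0.73
  rmin <- 2^(1 / 6)
  # LJ: zero (shifted) at the minimum-distance cutoff, -eps unshifted
  # (evaluated just inside the cutoff, which sits exactly at the minimum)
  expect_equal(lj_pair_energy(rmin * (1 - 1e-12)), 0, tolerance = 1e-9)
  expect_equal(lj_pair_energy(rmin * (1 - 1e-12), shift = FALSE), -eps,
               tolerance = 1e-9)
  # LJ zero crossing at r = sigma; +eps with the shift
  expect_equal(lj_pair_energy(1, shift = FALSE), 0)
  expect_equal(lj_pair_energy(1), eps)
  # beyond the cutoff
  expect_equal(lj_pair_energy(1.2), 0)
  expect_error(lj_pair_energy(0), "singularity")

  # harmonic bond
  expect_equal(bond_energy(1), 0)
  expect_equal(bond_energy(1.1), 140.2 * 0.1^2)
  expect_equal(bond_energy(1.07), bond_energy(0.93))

  # harmonic bend
  expect_equal(bend_energy(pi), 0)
  expect_equal(bend_energy(pi / 2), 14.02 * (pi / 2)^2)
  expect_equal(bend_energy(0.3, k_bend = 0), 0)

  # Debye: neutral particle, cutoff, sign, Bjerrum value
  expect_equal(debye_pair_energy(1, 0, -1), 0)
  expect_equal(debye_pair_energy(3.5, -1, -1), 0)
  kT <- 2.804
  expect_equal(debye_pair_energy(1, -1, -1) / kT, 0.7 * exp(-1),
               tolerance = 1e-12)
  r <- seq(0.5, 2.9, by = 0.3)
  expect_true(all(debye_pair_energy(r, -1, -1) > 0))
  expect_true(all(debye_pair_energy(r, 1, -1) < 0))
})

test_that("total energy/forces agree with the brute-force R reference", {
  for (seed in 1:3) {
    cfg <- tiny_config(n_beads = 12, seed = seed)
    sys <- build_brush_system(cfg, rng_seed = seed)
    sys$positions[sys$mobile, ] <- sys$positions[sys$mobile, ] +
      matrix(rnorm(sum(sys$mobile) * 3, sd = 0.03), ncol = 3)
    ef <- total_energy_forces(sys)
    ref <- reference_energy(sys)
    expect_equal(ef$u_lj, ref$u_lj, tolerance = 1e-10)
    expect_equal(ef$u_bond, ref$u_bond, tolerance = 1e-10)
    expect_equal(ef$u_bend, ref$u_bend, tolerance = 1e-10)
    expect_equal(ef$u_debye, ref$u_debye, tolerance = 1e-10)
    # breakdown sums to total
    expect_equal(ef$u_total, ef$u_lj + ef$u_bond + ef$u_bend + ef$u_debye,
                 tolerance = 1e-12)
    # per-bead partials sum to the total as well
    expect_equal(sum(ef$per_bead), ef$u_total, tolerance = 1e-8)
  }
})

test_that("forces are the negative energy gradient (finite differences)", {
  cfg <- tiny_config(n_beads = 10, seed = 5)
  sys <- build_brush_system(cfg, rng_seed = 5)
  sys$positions[sys$mobile, ] <- sys$positions[sys$mobile, ] +
    matrix(rnorm(sum(sys$mobile) * 3, sd = 0.05), ncol = 3)
  ef <- total_energy_forces(sys)
  u_of <- function(p) { s <- sys; s$positions <- p; total_energy_forces(s)$u_total }
  h <- 1e-6
  set.seed(1)
  for (i in sample(which(sys$mobile), 4)) for (k in 1:3) {
    p1 <- sys$positions; p1[i, k] <- p1[i, k] + h
    p2 <- sys$positions; p2[i, k] <- p2[i, k] - h
    fd <- -(u_of(p1) - u_of(p2)) / (2 * h)
    expect_equal(ef$forces[i, k], fd, tolerance = 1e-5)
  }
})

test_that("forces sum to zero and energy is translation invariant", {
  cfg <- tiny_config(n_beads = 14, seed = 8)
  sys <- build_brush_system(cfg, rng_seed = 8)
  ef <- total_energy_forces(sys)
  expect_equal(colSums(ef$forces), c(0, 0, 0), tolerance = 1e-9)
  for (shift in list(c(1.7, -2.3, 0), c(8.9, 0.4, 0))) {
    s2 <- sys
    s2$positions <- sweep(sys$positions, 2, shift, "+")
    expect_equal(total_energy_forces(s2)$u_total, ef$u_total,
                 tolerance = 1e-10)
  }
})

test_that("perturbing a distant bead leaves local forces unchanged", {
  cfg <- tiny_config(d = 4, n_beads = 30, seed = 2)
  sys <- build_brush_system(cfg, rng_seed = 2)
  # tracer sits low (z in [2,5]); the chain top beads are far above
  f0 <- total_energy_forces(sys)$forces[sys$tracer, ]
  idx <- which(sys$chain_id == 1)
  top <- idx[length(idx)]   # z = 30, farther than any cutoff from the tracer
  expect_gt(abs(sys$positions[top, 3] - sys$positions[sys$tracer, 3]), 3.5)
  s2 <- sys
  s2$positions[top, ] <- s2$positions[top, ] + c(0.3, -0.2, 0.1)
  f1 <- total_energy_forces(s2)$forces[sys$tracer, ]
  expect_identical(f0, f1)
})

test_that("two neutral beads at the LJ minimum feel no force", {
  pos <- rbind(c(5, 5, 3), c(5, 5, 3 + 2^(1 / 6)))
  params <- forcefield_params()
  ef <- cpp_energy_forces(pos, rep(TRUE, 2), rep(1, 2), rep(1, 2),
                          rep(0, 2), rep(1, 2), c(3L, 3L),
                          matrix(integer(0), 0, 2), matrix(integer(0), 0, 3),
                          matrix(integer(0), 0, 2),
                          pnnbrush:::.ff_cpp(params), c(20, 20))
  expect_equal(ef$forces, matrix(0, 2, 3), tolerance = 1e-10)
  expect_equal(ef$u_total, 0, tolerance = 1e-12)   # WCA shift: zero at minimum
})
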