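test_that("brush construction produces the documented geometry and counts", {
  cfg <- brush_config(d = 3, grid_n = 3, n_beads = 101)
  sys <- build_brush_system(cfg, rng_seed = 4)

  expect_equal(max(sys$chain_id), 9)                       # 9 chains
  expect_equal(sum(sys$species %in% c("tether", "chain")), 909)
  expect_equal(sum(sys$species == "tether"), 18)           # 2 immobile per chain
  expect_equal(sys$box, c(9, 9))                           # Lx = Ly = grid_n * d
  expect_equal(sum(sys$species == "wall"), 81)             # 1-sigma lattice in 9x9
  expect_equal(sum(sys$species == "tracer"), 1)

  # topology sizes per chain
  expect_equal(nrow(sys$bonds), 9 * 100)
  expect_equal(nrow(sys$angles), 9 * 99)

  # tracer close to the wall
  zt <- sys$positions[sys$tracer, 3]
  expect_gte(zt, 2)
  expect_lte(zt, 5)
})

test_that("initial configurations are overlap-free and seed-reproducible", {
  cfg <- tiny_config(n_beads = 20)
  s1 <- build_brush_system(cfg, rng_seed = 11)
  s2 <- build_brush_system(cfg, rng_seed = 11)
  s3 <- build_brush_system(cfg, rng_seed = 12)
  expect_identical(s1$positions, s2$positions)
  expect_false(identical(s1$positions, s3$positions))
  expect_gte(min_pair_distance(s1), 0.9)

  for (d in c(2, 5)) {
    s <- build_brush_system(tiny_config(d = d, n_beads = 15), rng_seed = 3)
    expect_gte(min_pair_distance(s), 0.9)
  }
})

test_that("geometry errors are raised for invalid spacings", {
  expect_error(build_brush_system(brush_config(d = 3, tracer_radius = 2)),
               "geometry")
  expect_error(brush_config(d = -1))
})

test_that("straightened chains are vertical rods at bond spacing", {
  cfg <- tiny_config(n_beads = 101, mode = "straight")
  sys <- build_brush_system(cfg, rng_seed = 2)
  idx <- which(sys$chain_id == 1)
  expect_equal(sys$positions[idx, 3], 1:101)          # top bead at z = 101 sigma
  b <- diff(sys$positions[idx, ])
  expect_equal(sqrt(rowSums(b^2)), rep(1, 100))       # all bonds at r0
  # collinear: interior angles are pi
  cosang <- rowSums(b[-nrow(b), ] * b[-1, ])
  expect_equal(cosang, rep(1, 99))
  # only the tracer is mobile
  expect_identical(sys$mobile, sys$species == "tracer")
})

test_that("physical time mapping follows tau = sigma sqrt(m/eps)", {
  u <- unit_system()
  expect_equal(physical_time(0, dt = 0.005, units = u), 0)
  # 200 steps at dt = 0.005 is one tau
  expect_equal(physical_time(200, 0.005, u), u$tau_seconds)
  # tau from first principles
  m <- u$mass_g_mol * 1e-3 / 6.02214076e23
  eps <- u$energy_kJ_mol * 1e3 / 6.02214076e23
  expect_equal(u$tau_seconds, 1e-9 * sqrt(m / eps), tolerance = 1e-12)
  # doubling the energy unit halves tau^2
  u2 <- unit_system(energy_kJ_mol = 2 * u$energy_kJ_mol)
  expect_equal(u2$tau_seconds^2, u$tau_seconds^2 / 2, tolerance = 1e-12)
})

test_that("immobile beads never move in any mode", {
  for (mode in c("dynamic", "static", "straight")) {
    cfg <- tiny_config(mode = mode, n_beads = 6, n_prod_steps = 100,
                       dump_every = 100)
    tr <- run_realization(cfg, seed = 9)
    sys0 <- build_brush_system(cfg, rng_seed = 9)
    fixed0 <- sys0$positions[!sys0$mobile & sys0$species != "chain", ]
    fixedT <- tr$state$positions[!sys0$mobile & sys0$species != "chain", ]
    expect_identical(fixed0, fixedT)
  }
})
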