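# Shared fixtures: tiny systems and an independent brute-force R reference
# for the pair/bond/angle energies (used as the oracle for the C++ kernels).

tiny_config <- function(...) {
  args <- list(...)
  defaults <- list(d = 3, n_beads = 8, n_tether = 2, n_equil_steps = 0,
                   n_prod_steps = 200, dump_every = 20, seed = 1)
  defaults[names(args)] <- args
  do.call(brush_config, defaults)
}

# brute-force O(N^2) energy evaluation in plain R, independent of the C++
# path: LJ + Debye over all non-excluded pairs (minimum image in x,y),
# harmonic bonds, harmonic angles.
reference_energy <- function(state, params = state$params) {
  pos <- state$positions
  L <- state$box
  n <- nrow(pos)
  k_bend <- if (state$config$mode == "no_stiffness") 0 else params$k_bend
  excl_key <- c()
  if (length(state$exclusions) > 0) {
    e <- state$exclusions
    excl_key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  }
  mi <- function(dv, Lv) dv - Lv * round(dv / Lv)
  u_lj <- u_debye <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    if (paste(i, j) %in% excl_key) next
    dx <- mi(pos[i, 1] - pos[j, 1], L[1])
    dy <- mi(pos[i, 2] - pos[j, 2], L[2])
    dz <- pos[i, 3] - pos[j, 3]
    r <- sqrt(dx^2 + dy^2 + dz^2)
    sij <- 0.5 * (state$sigma[i] + state$sigma[j])
    u_lj <- u_lj + lj_pair_energy(r, params$eps_lj, sij,
                                  params$rc_factor * sij, params$shift_lj)
    u_debye <- u_debye + debye_pair_energy(r, state$charge[i], state$charge[j],
                                           params$coulomb, params$kappa,
                                           params$r_cut_debye)
  }
  u_bond <- 0
  for (b in seq_len(nrow(state$bonds))) {
    i <- state$bonds[b, 1]; j <- state$bonds[b, 2]
    dx <- mi(pos[i, 1] - pos[j, 1], L[1])
    dy <- mi(pos[i, 2] - pos[j, 2], L[2])
    r <- sqrt(dx^2 + dy^2 + (pos[i, 3] - pos[j, 3])^2)
    u_bond <- u_bond + bond_energy(r, params$k_bond, params$r0)
  }
  u_bend <- 0
  if (k_bend > 0) for (a in seq_len(nrow(state$angles))) {
    i <- state$angles[a, 1]; j <- state$angles[a, 2]; k <- state$angles[a, 3]
    d1 <- c(mi(pos[i, 1] - pos[j, 1], L[1]), mi(pos[i, 2] - pos[j, 2], L[2]),
            pos[i, 3] - pos[j, 3])
    d2 <- c(mi(pos[k, 1] - pos[j, 1], L[1]), mi(pos[k, 2] - pos[j, 2], L[2]),
            pos[k, 3] - pos[j, 3])
    ct <- sum(d1 * d2) / sqrt(sum(d1^2) * sum(d2^2))
    theta <- acos(max(-1, min(1, ct)))
    u_bend <- u_bend + bend_energy(theta, k_bend, params$theta0)
  }
  list(u_lj = u_lj, u_bond = u_bond, u_bend = u_bend, u_debye = u_debye,
       u_total = u_lj + u_bond + u_bend + u_debye)
}

# hand-made trajectory with chosen positions/flags for MSD bookkeeping tests
manual_trajectory <- function(pos, in_brush = rep(TRUE, nrow(pos)),
                              dt = 1) {
  structure(list(times = (seq_len(nrow(pos)) - 1) * dt, tracer = pos,
                 in_brush = in_brush, seed = 0),
            class = "brush_trajectory")
}
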