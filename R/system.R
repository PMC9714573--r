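#' Build an initial brush + tracer configuration
#'
#' Constructs the simulation system: a neutral wall lattice at z = 0 with
#' 1 \eqn{\sigma} spacing spanning the periodic box (dense enough that LJ
#' repulsion blocks sigma-sized beads from passing through), `grid_n^2`
#' chains of `n_beads` beads tethered on a quadratic grid with spacing `d`
#' (the first `n_tether` beads of each chain are immobile, stacked
#' vertically at z = 1, 2, ... \eqn{\sigma} above the grid point), and a
#' single tracer inserted close to the wall: uniform (x, y), z uniform in
#' [2, 5] \eqn{\sigma}, redrawn until it overlaps nothing.
#'
#' Mobile chain beads start on near-vertical lines with a small seeded
#' lateral perturbation. The box is periodic in x and y
#' (`Lx = Ly = grid_n * d`) and open above.
#'
#' @param config A [brush_config()].
#' @param params A [forcefield_params()].
#' @param rng_seed Integer seed; rebuilding with the same seed reproduces
#'   the configuration bit-identically.
#' @return An object of class `brush_system`: positions (unwrapped, N x 3),
#'   velocities, per-bead species / mobility / charge / LJ sigma / mass /
#'   damping, bond and angle lists, nonbonded exclusions (first- and
#'   second-neighbour intrachain pairs), chain ids and the periodic box.
#' @examples
#' sys <- build_brush_system(brush_config(d = 3, n_beads = 11))
#' table(sys$species)
#' @export
build_brush_system <- function(config = brush_config(),
                               params = forcefield_params(),
                               rng_seed = config$seed) {
  stopifnot(inherits(config, "brush_config"), inherits(params, "ff_params"))
  if (config$d < 1)
    stop("geometry error: tether spacing d must be at least 1 sigma")
  if (config$d < 2 * config$tracer_radius)
    stop("geometry error: tether spacing d too small for the tracer radius")
  set.seed(rng_seed)

  L <- config$grid_n * config$d
  # wall lattice, spacing 1 sigma (periodic box => round to an integer count)
  nw <- max(1L, round(L))
  wall_sp <- L / nw
  wx <- rep(seq_len(nw) - 1, times = nw) * wall_sp
  wy <- rep(seq_len(nw) - 1, each = nw) * wall_sp
  wall <- cbind(wx, wy, 0)

  # chains on the quadratic tether grid
  n_chains <- config$grid_n^2
  N <- config$n_beads
  gx <- rep(seq_len(config$grid_n) - 1, times = config$grid_n) * config$d
  gy <- rep(seq_len(config$grid_n) - 1, each = config$grid_n) * config$d
  chain_pos <- vector("list", n_chains)
  for (c in seq_len(n_chains)) {
    z <- seq_len(N) * params$r0
    x <- rep(gx[c], N)
    y <- rep(gy[c], N)
    mob <- seq_len(N) > config$n_tether
    x[mob] <- x[mob] + runif(sum(mob), -0.05, 0.05)
    y[mob] <- y[mob] + runif(sum(mob), -0.05, 0.05)
    chain_pos[[c]] <- cbind(x, y, z)
  }
  chains <- do.call(rbind, chain_pos)

  pos <- rbind(wall, chains)
  species <- c(rep("wall", nrow(wall)),
               rep(rep(c("tether", "chain"), c(config$n_tether, N - config$n_tether)),
                   n_chains))
  chain_id <- c(rep(0L, nrow(wall)), rep(seq_len(n_chains), each = N))

  # tracer: uniform in the box, close to the wall, overlap-rejected
  sig_tracer <- 2 * config$tracer_radius
  min_ok <- 0.9 * 0.5 * (1 + sig_tracer)   # 0.9 * pair sigma vs chain beads
  placed <- FALSE
  for (try in seq_len(1000)) {
    tp <- c(runif(1, 0, L), runif(1, 0, L), runif(1, 2, 5))
    if (.min_dist_to(tp, pos, L) >= min_ok) { placed <- TRUE; break }
  }
  if (!placed)
    stop("placement error: could not insert the tracer without overlap")
  pos <- rbind(pos, tp)
  species <- c(species, "tracer")
  chain_id <- c(chain_id, 0L)
  n <- nrow(pos)
  tracer_idx <- n

  # topology
  offs <- nrow(wall) + (seq_len(n_chains) - 1) * N
  bonds <- do.call(rbind, lapply(offs, function(o) cbind(o + 1:(N - 1), o + 2:N)))
  angles <- if (N >= 3)
    do.call(rbind, lapply(offs, function(o) cbind(o + 1:(N - 2), o + 2:(N - 1), o + 3:N)))
  else matrix(integer(0), 0, 3)
  excl <- rbind(bonds, if (N >= 3)
    do.call(rbind, lapply(offs, function(o) cbind(o + 1:(N - 2), o + 3:N)))
    else NULL)

  is_chain <- species %in% c("tether", "chain")
  mass <- rep(1, n)
  mass[tracer_idx] <- (config$tracer_radius / 0.5)^3
  gam <- rep(config$gamma, n)
  gam[tracer_idx] <- config$gamma * config$tracer_radius / 0.5
  charge <- ifelse(is_chain, params$chain_charge, 0)
  charge[tracer_idx] <- config$tracer_charge
  sigma <- rep(1, n)
  sigma[tracer_idx] <- sig_tracer
  mobile <- species == "chain" | species == "tracer"
  if (config$mode == "straight") mobile <- species == "tracer"

  sys <- structure(list(
    positions = unname(pos), velocities = matrix(0, n, 3),
    species = species, mobile = mobile, charge = charge, sigma = sigma,
    mass = mass, gamma = gam, chain_id = chain_id,
    bonds = bonds, angles = angles, exclusions = excl,
    box = c(L, L), tracer = tracer_idx,
    config = config, params = params, seed = rng_seed),
    class = "brush_system")
  if (config$mode == "straight") sys <- straighten_chains(sys)
  sys
}

# minimum-image distance (periodic x,y) from a point to a set of beads
.min_dist_to <- function(p, pos, L) {
  dx <- abs(pos[, 1] - p[1]); dx <- pmin(dx, L - dx)
  dy <- abs(pos[, 2] - p[2]); dy <- pmin(dy, L - dy)
  dz <- pos[, 3] - p[3]
  sqrt(min(dx^2 + dy^2 + dz^2))
}

#' Straighten all chains into vertical rods
#'
#' Places every chain bead on the vertical line above its tether grid point
#' at spacing `r0` and marks all chain beads immobile, producing the
#' straight-chain static system type.
#'
#' @param state A `brush_system`.
#' @return The modified `brush_system`.
#' @export
straighten_chains <- function(state) {
  stopifnot(inherits(state, "brush_system"))
  r0 <- state$params$r0
  for (c in unique(state$chain_id[state$chain_id > 0])) {
    idx <- which(state$chain_id == c)
    base <- state$positions[idx[1], 1:2]
    k <- seq_along(idx)
    state$positions[idx, 1] <- base[1]
    state$positions[idx, 2] <- base[2]
    state$positions[idx, 3] <- k * r0
  }
  state$mobile <- state$species == "tracer"
  state
}

#' @export
print.brush_system <- function(x, ...) {
  cat(sprintf("brush_system: %d beads (%d wall, %d tether, %d chain, %d tracer)\n",
              length(x$species), sum(x$species == "wall"),
              sum(x$species == "tether"), sum(x$species == "chain"),
              sum(x$species == "tracer")))
  cat(sprintf("  box %g x %g sigma (periodic x,y), %d chains, mode %s\n",
              x$box[1], x$box[2], max(x$chain_id), x$config$mode))
  invisible(x)
}

#' Minimum pairwise distance in a system
#'
#' Utility used to verify that initial configurations are overlap-free
#' (minimum-image convention in x and y).
#'
#' @param state A `brush_system`.
#' @return The smallest pairwise bead distance.
#' @export
min_pair_distance <- function(state) {
  pos <- state$positions
  L <- state$box[1]
  n <- nrow(pos)
  mind <- Inf
  for (i in seq_len(n - 1)) {
    d <- .min_dist_to(pos[i, ], pos[(i + 1):n, , drop = FALSE], L)
    if (d < mind) mind <- d
  }
  mind
}
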