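#' Dual mean-square-displacement curves
#'
#' Ensemble-averaged MSD from the production origin, split into the
#' parallel (xy) and perpendicular (z) components. Two families of curves
#' are produced: the all-particle curves average every realization at every
#' time; the in-brush curves average, at each time, only the realizations
#' whose tracer has remained inside the brush (instantaneous flag:
#' tracer z at or below the maximum chain-bead z) at every frame up to and
#' including that time. Once no realization survives, the in-brush curves
#' are truncated (NA) with a warning.
#'
#' @param trajectories A list of `brush_trajectory` objects sharing the
#'   same frame times.
#' @return An object of class `msd_result` with `times`, `msd_xy_all`,
#'   `msd_z_all`, `msd_total_all`, `msd_xy_inbrush`, `msd_z_inbrush` and
#'   `n_inbrush`.
#' @export
compute_msd <- function(trajectories) {
  stopifnot(length(trajectories) >= 1)
  times <- trajectories[[1]]$times
  nf <- length(times)
  n <- length(trajectories)
  dx2 <- dy2 <- dz2 <- matrix(0, nf, n)
  surv <- matrix(TRUE, nf, n)
  for (i in seq_len(n)) {
    tr <- trajectories[[i]]
    stopifnot(length(tr$times) == nf)
    dx2[, i] <- (tr$tracer[, 1] - tr$tracer[1, 1])^2
    dy2[, i] <- (tr$tracer[, 2] - tr$tracer[1, 2])^2
    dz2[, i] <- (tr$tracer[, 3] - tr$tracer[1, 3])^2
    flag <- if (is.null(tr$in_brush)) rep(TRUE, nf) else tr$in_brush
    surv[, i] <- cumprod(flag) > 0   # remained in brush up to t
  }
  xy <- dx2 + dy2
  n_in <- rowSums(surv)
  msd_in <- function(m) {
    out <- rep(NA_real_, nf)
    ok <- n_in > 0
    out[ok] <- rowSums(m * surv)[ok] / n_in[ok]
    out
  }
  if (any(n_in == 0))
    warning("in-brush ensemble empty from t = ",
            signif(times[which(n_in == 0)[1]], 4), "; curve truncated")
  structure(list(times = times,
                 msd_xy_all = rowMeans(xy), msd_z_all = rowMeans(dz2),
                 msd_total_all = rowMeans(xy + dz2),
                 msd_xy_inbrush = msd_in(xy), msd_z_inbrush = msd_in(dz2),
                 n_inbrush = n_in, n = n),
            class = "msd_result")
}

#' @export
print.msd_result <- function(x, ...) {
  cat(sprintf("msd_result: %d frames, %d realizations, %d in brush at end\n",
              length(x$times), x$n, x$n_inbrush[length(x$n_inbrush)]))
  invisible(x)
}

# local log-log slope of a curve by centred regression over +-2 points
.loglog_slope <- function(t, y) {
  n <- length(t)
  s <- rep(NA_real_, n)
  lt <- log(t); ly <- log(pmax(y, .Machine$double.xmin))
  for (i in seq_len(n)) {
    j <- max(1, i - 2):min(n, i + 2)
    j <- j[is.finite(ly[j])]
    if (length(j) >= 3) s[i] <- coef(lm(ly[j] ~ lt[j]))[2]
  }
  s
}

# Fit-window rule: the earliest decade-wide interval, starting after the
# first 20 frames (past the ballistic transient), on which the log-log
# slopes of the all-particle and in-brush curves differ by < 10%.
.select_fit_window <- function(msd, min_frames = 20, slope_tol = 0.10) {
  t <- msd$times
  usable <- t > 0 & is.finite(msd$msd_xy_inbrush) & is.finite(msd$msd_z_inbrush)
  idx <- which(usable)
  idx <- idx[idx > min_frames]
  if (length(idx) < 4) stop("window-selection failure: too few usable frames")
  tot_all <- msd$msd_xy_all + msd$msd_z_all
  tot_in <- msd$msd_xy_inbrush + msd$msd_z_inbrush
  sa <- .loglog_slope(t[idx], tot_all[idx])
  si <- .loglog_slope(t[idx], tot_in[idx])
  ok <- abs(sa - si) / pmax(0.5 * (abs(sa) + abs(si)), 1e-12) < slope_tol
  ok[!is.finite(ok)] <- FALSE
  tmax <- t[idx[length(idx)]]
  for (s in seq_along(idx)) {
    hi_t <- min(10 * t[idx[s]], tmax)
    if (hi_t / t[idx[s]] < 10 && s > 1) break  # no full decade left
    span <- which(t[idx] >= t[idx[s]] & t[idx] <= hi_t)
    if (length(span) >= 4 && all(ok[span]))
      return(c(t[idx[s]], hi_t))
  }
  # less than a decade available in total: accept the full usable range if
  # the slope criterion holds throughout
  if (all(ok, na.rm = TRUE)) return(c(t[idx[1]], tmax))
  stop("window-selection failure: no interval where the two MSD curves have similar slopes")
}

#' Anisotropic diffusion constants from MSD slopes
#'
#' Estimates \eqn{D_\parallel}, \eqn{D_\perp} and \eqn{D_R} from the linear
#' growth of the MSD: \eqn{\langle\Delta x^2 + \Delta y^2\rangle = 4 D_\parallel t},
#' \eqn{\langle\Delta z^2\rangle = 2 D_\perp t},
#' \eqn{\langle\Delta R^2\rangle = 6 D_R t}. The trajectories are divided
#' into `n_groups` groups; the in-brush MSD of each group is fitted by
#' linear least squares on the selected window and the estimate is reported
#' as mean +- standard deviation over groups. Unless supplied, the window
#' is chosen by the dual-curve rule: the earliest decade-wide interval,
#' after the ballistic transient (first 20 frames), on which the
#' all-particle and in-brush curves have log-log slopes within 10% of each
#' other.
#'
#' @param trajectories A list of `brush_trajectory` objects (at least
#'   `n_groups`).
#' @param n_groups Number of error groups (the reference procedure uses 10
#'   groups regardless of ensemble size).
#' @param fit_window Optional `c(t_min, t_max)` to bypass the window rule.
#' @param curve Which curve family to fit: the in-brush curves (default) or
#'   the all-particle curves.
#' @return An object of class `diffusion_estimate` with `D_par`, `D_perp`,
#'   `D_total`, their group standard deviations, the per-group estimates,
#'   the fit window and the group count.
#' @export
fit_diffusion <- function(trajectories, n_groups = 10, fit_window = NULL,
                          curve = c("inbrush", "all")) {
  curve <- match.arg(curve)
  n <- length(trajectories)
  stopifnot(n >= n_groups)
  msd <- compute_msd(trajectories)
  if (is.null(fit_window)) fit_window <- .select_fit_window(msd)
  gsize <- n %/% n_groups
  slope_fit <- function(t, y) {
    ok <- is.finite(y)
    unname(coef(lm(y[ok] ~ t[ok]))[2])
  }
  est <- matrix(NA_real_, n_groups, 3,
                dimnames = list(NULL, c("D_par", "D_perp", "D_total")))
  for (g in seq_len(n_groups)) {
    grp <- trajectories[((g - 1) * gsize + 1):(g * gsize)]
    m <- compute_msd(grp)
    sel <- m$times >= fit_window[1] & m$times <= fit_window[2]
    if (curve == "inbrush") {
      xy <- m$msd_xy_inbrush; zz <- m$msd_z_inbrush
    } else {
      xy <- m$msd_xy_all; zz <- m$msd_z_all
    }
    est[g, 1] <- slope_fit(m$times[sel], xy[sel]) / 4
    est[g, 2] <- slope_fit(m$times[sel], zz[sel]) / 2
    est[g, 3] <- slope_fit(m$times[sel], (xy + zz)[sel]) / 6
  }
  structure(list(D_par = mean(est[, 1]), D_par_sd = sd(est[, 1]),
                 D_perp = mean(est[, 2]), D_perp_sd = sd(est[, 2]),
                 D_total = mean(est[, 3]), D_total_sd = sd(est[, 3]),
                 groups = est, fit_window = fit_window, n_groups = n_groups,
                 n = n, curve = curve),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  cat(sprintf("diffusion_estimate (%d trajectories, %d groups, window [%.3g, %.3g] tau)\n",
              x$n, x$n_groups, x$fit_window[1], x$fit_window[2]))
  cat(sprintf("  D_par   = %.4g +- %.2g\n", x$D_par, x$D_par_sd))
  cat(sprintf("  D_perp  = %.4g +- %.2g\n", x$D_perp, x$D_perp_sd))
  cat(sprintf("  D_total = %.4g +- %.2g\n", x$D_total, x$D_total_sd))
  invisible(x)
}

#' Per-chain radius of gyration
#'
#' Root-mean-square distance of the chain beads from their centre of mass,
#' \eqn{R_g = \sqrt{\frac{1}{N}\sum_i (r_i - \bar r)^2}}, computed per chain
#' from a system snapshot (or directly from an N x 3 coordinate matrix).
#'
#' @param x A `brush_system`, a `brush_trajectory` (final state is used) or
#'   a numeric matrix of one chain's coordinates.
#' @return A numeric vector of per-chain Rg values.
#' @examples
#' radius_of_gyration(cbind(0, 0, c(0, 1)))  # two beads at distance 1 -> 0.5
#' @export
radius_of_gyration <- function(x) {
  rg1 <- function(m) {
    cm <- colMeans(m)
    sqrt(mean(rowSums(sweep(m, 2, cm)^2)))
  }
  if (is.matrix(x)) return(rg1(x))
  if (inherits(x, "brush_trajectory")) x <- x$state
  stopifnot(inherits(x, "brush_system"))
  ids <- sort(unique(x$chain_id[x$chain_id > 0]))
  vapply(ids, function(c) rg1(x$positions[x$chain_id == c, , drop = FALSE]),
         numeric(1))
}

#' Brush height
#'
#' Mean over realizations of the maximal chain-bead z coordinate at the
#' final frame.
#'
#' @param states A list of `brush_system` or `brush_trajectory` objects
#'   (or a single one).
#' @return The mean brush height \eqn{L_z} (\eqn{\sigma}).
#' @export
brush_height <- function(states) {
  if (inherits(states, c("brush_system", "brush_trajectory")))
    states <- list(states)
  mean(vapply(states, function(s) {
    if (inherits(s, "brush_trajectory")) s <- s$state
    max(s$positions[s$chain_id > 0, 3])
  }, numeric(1)))
}

#' Brush correlation length
#'
#' Mean over all chain beads of the distance to the nearest bead on a
#' different chain (minimum image in x and y), evaluated on the final
#' configuration. This is the mesh-size scale that controls when a tracer
#' feels the brush as discrete obstacles.
#'
#' @param state A `brush_system` or `brush_trajectory`, or a list of them
#'   (averaged over realizations).
#' @return The correlation length \eqn{\xi} (\eqn{\sigma}).
#' @export
correlation_length <- function(state) {
  if (is.list(state) && !inherits(state, c("brush_system", "brush_trajectory")))
    return(mean(vapply(state, correlation_length, numeric(1))))
  if (inherits(state, "brush_trajectory")) state <- state$state
  stopifnot(inherits(state, "brush_system"))
  ids <- state$chain_id
  chains <- sort(unique(ids[ids > 0]))
  if (length(chains) < 2)
    stop("correlation length is undefined for fewer than two chains")
  L <- state$box
  pos <- state$positions[ids > 0, , drop = FALSE]
  cid <- ids[ids > 0]
  nearest <- numeric(nrow(pos))
  for (c in chains) {
    a <- pos[cid == c, , drop = FALSE]
    b <- pos[cid != c, , drop = FALSE]
    dx <- abs(outer(a[, 1], b[, 1], "-")); dx <- pmin(dx, L[1] - dx)
    dy <- abs(outer(a[, 2], b[, 2], "-")); dy <- pmin(dy, L[2] - dy)
    dz <- outer(a[, 3], b[, 3], "-")
    nearest[cid == c] <- sqrt(apply(dx^2 + dy^2 + dz^2, 1, min))
  }
  mean(nearest)
}

#' Persistence length from bond-vector correlations
#'
#' Computes \eqn{\langle\cos\theta(s)\rangle}, the mean cosine of the angle
#' between bond vectors separated by s bonds, over an ensemble of chain
#' configurations, and fits the exponential decay
#' \eqn{\langle\cos\theta(s)\rangle = e^{-s\,r_0/l_p}} by least squares on
#' the log scale over \eqn{s \in [1, 3\,\hat l_p]} (initial estimate from
#' s = 1). A perfectly straight ensemble is reported as divergent
#' (`lp = Inf`).
#'
#' @param chains A list of N x 3 coordinate matrices (one chain each), a
#'   single matrix, or a list of `brush_system`/`brush_trajectory` objects
#'   (all chains of each are used).
#' @param r0 Bond length used to convert bond count to arc length.
#' @return A list with `lp` (persistence length, \eqn{\sigma}), `lp_se`
#'   (fit standard error), `s` and `cos_s` (the correlation curve), and the
#'   fitted range `s_fit`.
#' @export
persistence_length <- function(chains, r0 = 1) {
  if (is.matrix(chains)) chains <- list(chains)
  mats <- list()
  for (x in chains) {
    if (inherits(x, "brush_trajectory")) x <- x$state
    if (inherits(x, "brush_system")) {
      for (c in sort(unique(x$chain_id[x$chain_id > 0])))
        mats[[length(mats) + 1]] <- x$positions[x$chain_id == c, , drop = FALSE]
    } else mats[[length(mats) + 1]] <- x
  }
  nb <- nrow(mats[[1]]) - 1
  smax <- nb - 1
  num <- den <- numeric(smax)
  for (m in mats) {
    b <- diff(m)
    b <- b / sqrt(rowSums(b^2))
    for (s in seq_len(smax)) {
      num[s] <- num[s] + sum(rowSums(b[1:(nb - s), , drop = FALSE] *
                                     b[(1 + s):nb, , drop = FALSE]))
      den[s] <- den[s] + (nb - s)
    }
  }
  cos_s <- num / den
  s <- seq_len(smax)
  if (all(cos_s > 1 - 1e-9))
    return(list(lp = Inf, lp_se = NA_real_, s = s, cos_s = cos_s,
                s_fit = NULL))
  if (any(cos_s[1:min(2, smax)] <= 0))
    stop("fit-range error: bond correlations non-positive before s = 2")
  lp0 <- -r0 / log(cos_s[1])
  s_hi <- max(2, min(smax, floor(3 * lp0 / r0)))
  pos_run <- which(cumprod(cos_s > 0) > 0)
  s_hi <- min(s_hi, max(pos_run))
  sel <- 1:s_hi
  # inverse-variance weights on the log scale: Var(log c) ~ Var(c)/c^2 and
  # each lag averages den[s] bond pairs
  w <- den[sel] * cos_s[sel]^2
  fit <- lm(log(cos_s[sel]) ~ 0 + sel, weights = w)
  slope <- unname(coef(fit)[1])
  se <- sqrt(vcov(fit)[1, 1])
  list(lp = -r0 / slope, lp_se = r0 * se / slope^2, s = s, cos_s = cos_s,
       s_fit = range(sel))
}

#' Tracer and chain energy statistics
#'
#' Interaction-energy bookkeeping over production frames, pooled over
#' realizations: `mean_energy_per_step` is the tracer interaction energy
#' averaged over all frames; `mean_energy_when_interacting` averages only
#' frames where the tracer interacts (|u| above `tol`);
#' `interacting_fraction` is the fraction of such frames; and
#' `chain_mean_energy_per_bead` is the frame-averaged chain potential
#' energy per bead. The identity
#' `mean_energy_per_step = mean_energy_when_interacting * interacting_fraction`
#' holds exactly by construction.
#'
#' @param trajectories A `brush_trajectory` or a list of them.
#' @param tol Threshold below which the tracer counts as non-interacting.
#' @return A list with the four statistics and `n_frames`.
#' @export
energy_stats <- function(trajectories, tol = 1e-12) {
  if (inherits(trajectories, "brush_trajectory"))
    trajectories <- list(trajectories)
  u <- unlist(lapply(trajectories, `[[`, "tracer_energy"))
  ch <- unlist(lapply(trajectories, `[[`, "chain_energy_per_bead"))
  act <- abs(u) > tol
  n_e <- mean(act)
  e_mean <- if (any(act)) mean(u[act]) else 0
  list(mean_energy_per_step = mean(u),
       mean_energy_when_interacting = e_mean,
       interacting_fraction = n_e,
       chain_mean_energy_per_bead = mean(ch),
       never_interacting = !any(act),
       n_frames = length(u))
}
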