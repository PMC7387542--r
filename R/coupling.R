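# Mechanical couplers and force experiments: Dam1 ring pulled along the
# MT, large-sphere obstacle opposing growth, force-velocity sweeps and
# stall-force estimation.

#' Couplers for force experiments
#'
#' `coupler_bead()` is the single dragged Dam1 subunit of the isolated-PF
#' force assay.  `dam1_ring_coupler()` threads a 13-subunit ring around
#' the lattice, placed a fixed distance below the lowest curl origin,
#' each subunit at steric contact with the wall; the total load is shared
#' equally by the subunits (positive = plus-end directed).
#' `obstacle_coupler()` places a large sphere ahead of the plus end;
#' positive load opposes growth.  Tubulin additions whose placement would
#' overlap the obstacle are blocked.
#'
#' @param x,z bead position, nm.
#' @param R bead radius, nm.
#' @param force load in pN.
#' @param eta viscosity, Pa s (sets the coupler drag).
#' @param drag_compression divide the coupler drag by this factor; used
#'   with `time_compression` so that cargo diffusion follows the
#'   compressed (physical) kinetic clock rather than the Brownian clock.
#'   Only sensible for the quasi-static obstacle (whose own drag is
#'   enormous); rescaling the ring drag destabilises its contact
#'   dynamics.
#' @return a coupler list consumed by [run_mt()] / [relax_state()].
#' @export
coupler_bead <- function(x = 7, z = 0, R = 3, force = 0, eta = 1e-3) {
  list(type = "bead", x = x, z = z, R = R, F = .from_pN(force),
       gamma = .gamma_q(eta, R))
}

#' @rdname coupler_bead
#' @param state the `mt_state` the ring is threaded on (placement).
#' @param ring a [ring_params()] bundle.
#' @param offset initial axial distance below the lowest curl origin, nm.
#' @param k_ring stiffness of the springs connecting adjacent ring
#'   subunits, kcal mol^-1 nm^-2 (artifact default; keeps the ring
#'   coherent).
#' @param bind_stride steps between linker (re)binding checks.
#' @param wall_tolerance curl-origin detection tolerance, nm.
#' @export
dam1_ring_coupler <- function(state, ring = ring_params(), force = 0,
                              offset = 16, eta = 1e-3, k_ring = 100,
                              bind_stride = 500, wall_tolerance = 1.5,
                              drag_compression = 1) {
  origins <- vapply(state$pf, function(m) {
    curl_origin(pf_trace(z = m[, 2], x = m[, 1]),
                wall_tolerance = wall_tolerance)$origin_z
  }, 1.0)
  z0 <- min(origins) - offset
  x0 <- ring$R_dam1 + 2  # steric contact with wall monomers (x = 0)
  list(type = "ring", R_dam1 = ring$R_dam1, l0 = ring$l0,
       l_max = ring$l_max, k_linker = ring$k_linker,
       F = .from_pN(force),
       gamma = .gamma_q(eta, ring$R_dam1) / drag_compression,
       k_ring = k_ring, bind_stride = as.integer(bind_stride),
       x = rep(x0, state$n_pf), z = rep(z0, state$n_pf))
}

#' @rdname coupler_bead
#' @param gap initial clearance between obstacle surface and the highest
#'   tip monomer, nm.
#' @param diameter obstacle sphere diameter, nm (default 5 um).
#' @param r_tub tubulin radius, nm.
#' @export
obstacle_coupler <- function(state, force = 0, diameter = 5000,
                             gap = 0.5, eta = 1e-3, r_tub = 2,
                             drag_compression = 1) {
  tipz <- max(vapply(state$pf, function(m) max(m[, 2]), 1.0))
  R <- diameter / 2
  list(type = "obstacle", R = R, z = tipz + R + r_tub + gap,
       F = .from_pN(force), gamma = .gamma_q(eta, R) / drag_compression)
}

#' Stall force from a force-velocity table
#'
#' Linear interpolation of the zero crossing of mean velocity between the
#' bracketing loads.
#'
#' @param fv data.frame with columns `force` (pN) and `velocity` (nm/s),
#'   ordered or not.
#' @return list with `stall` (pN, `NA` if not bracketed) and `bracketed`.
#' @examples
#' stall_from_table(data.frame(force = c(0, 2, 4),
#'                             velocity = c(-300, -80, 120)))
#' @export
stall_from_table <- function(fv) {
  fv <- fv[order(fv$force), ]
  v <- fv$velocity
  s <- sign(v)
  i <- which(s[-1] != s[-length(s)] & s[-1] != 0)
  if (all(s == 0)) return(list(stall = fv$force[1], bracketed = TRUE))
  iz <- which(s == 0)
  if (length(iz)) return(list(stall = fv$force[iz[1]], bracketed = TRUE))
  if (!length(i)) return(list(stall = NA_real_, bracketed = FALSE))
  i <- i[1]
  f1 <- fv$force[i]; f2 <- fv$force[i + 1]
  v1 <- v[i]; v2 <- v[i + 1]
  list(stall = f1 - v1 * (f2 - f1) / (v2 - v1), bracketed = TRUE)
}

# shared single-load velocity measurement; the reported velocity is the
# coupler's (the cargo in the corresponding experiments): the ring's mean
# axial position for ring pulling, the obstacle surface for pushing
.velocity_under_load <- function(state, mech, inter, nuc_effect, kin,
                                 coupler, cfg, burn_in,
                                 wall_tolerance = 1.5) {
  run <- run_mt(state, mech, inter, nuc_effect, kin, "constant",
                coupler = coupler, cfg = cfg)
  tr <- run$trace
  z <- if (coupler$type == "ring") tr$ring_z else tr$obstacle_z
  v <- measure_rate(data.frame(t = tr$t, length = z), burn_in = burn_in)
  list(velocity = v, run = run)
}

#' Force-velocity sweep and stall-force estimate
#'
#' Simulates the protocol at each load with `n_seeds` replicate seeds,
#' tabulates mean velocity and its sd, and estimates the stall force as
#' the zero crossing of mean velocity by linear interpolation between the
#' bracketing loads.
#'
#' @param state an `mt_state` prototype (re-used for every run).
#' @param loads loads to sweep, pN.
#' @param mode `"ring"` (Dam1 ring; positive load pulls plus-ward) or
#'   `"obstacle"` (pushing assay; positive load opposes growth).
#' @param n_seeds replicate seeds per load.
#' @param burn_in discarded initial span of each length trace, s
#'   (physical).
#' @param seed base seed; replicate r at load i runs with
#'   `seed + 1000 * i + r`.
#' @inheritParams run_mt
#' @inheritParams dam1_ring_coupler
#' @return list with `table` (force, velocity, sd, n), `stall` (pN or
#'   `NA`), `bracketed`.
#' @export
stall_sweep <- function(state, loads, mode = c("ring", "obstacle"),
                        mech = mechanical_params(),
                        inter = interaction_params(),
                        nuc_effect = NULL, kin = kinetic_params(),
                        ring = ring_params(), cfg = sim_config(),
                        n_seeds = 3, burn_in = 0, seed = 1) {
  mode <- match.arg(mode)
  rows <- lapply(seq_along(loads), function(i) {
    f <- loads[i]
    vs <- vapply(seq_len(n_seeds), function(r) {
      cfg$seed <- seed + 1000 * i + r
      coup <- if (mode == "ring")
        dam1_ring_coupler(state, ring, force = f, eta = cfg$eta)
      else obstacle_coupler(state, force = f, eta = cfg$eta,
                            r_tub = mech$r_tub)
      .velocity_under_load(state, mech, inter, nuc_effect, kin, coup,
                           cfg, burn_in)$velocity
    }, 1.0)
    data.frame(force = f, velocity = mean(vs),
               sd = if (n_seeds > 1) sd(vs) else NA_real_, n = n_seeds)
  })
  tab <- do.call(rbind, rows)
  st <- stall_from_table(tab)
  c(list(table = tab), st)
}

#' Growth acceleration by an assisting load on a Dam1 ring
#'
#' GTP parametrization with hydrolysis off; plus-end directed load applied
#' through the ring.  Returns the growth rate per load and the
#' acceleration factor `rate(F) / rate(0)`.
#'
#' @inheritParams stall_sweep
#' @param loads assisting loads, pN (0 is prepended if absent).
#' @export
assisted_growth <- function(state, loads, mech = mechanical_params(),
                            inter = interaction_params(),
                            kin = kinetic_params(),
                            ring = ring_params(), cfg = sim_config(),
                            n_seeds = 3, burn_in = 0, seed = 1) {
  if (!0 %in% loads) loads <- c(0, loads)
  kin$k_hydr <- 0
  res <- stall_sweep(state, loads, "ring", mech, inter, NULL, kin, ring,
                     cfg, n_seeds, burn_in, seed)
  tab <- res$table
  v0 <- tab$velocity[tab$force == 0]
  tab$acceleration <- tab$velocity / v0
  list(table = tab, rate_unloaded = v0)
}

#' Growth against an obstacle
#'
#' GTP parametrization pushing on a large sphere; the addition-blocking
#' rule (no incorporation into sites overlapping the obstacle) is active.
#'
#' @inheritParams stall_sweep
#' @export
obstacle_growth <- function(state, loads, mech = mechanical_params(),
                            inter = interaction_params(),
                            kin = kinetic_params(), cfg = sim_config(),
                            n_seeds = 3, burn_in = 0, seed = 1) {
  kin$k_hydr <- 0
  stall_sweep(state, loads, "obstacle", mech, inter, NULL, kin,
              ring_params(), cfg, n_seeds, burn_in, seed)
}
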