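# Simulation drivers: thin R layers over the shared compiled kernel.

.k_eff_max <- function(mech, inter, nuc_effect = NULL) {
  b_lat_max <- max(.inter_list(inter, nuc_effect)$b_lat)
  max(mech$k_intra, 2 * mech$k_rep,
      (4 * inter$a_lat + 2 * b_lat_max) / inter$r_lat^2,
      (4 * inter$a_long + 2 * inter$b_long) / inter$r_long^2)
}

# stochastic runs need dt well below the stiffest relaxation time for
# accuracy; pure gradient descent only needs Euler stability (2 gamma/k)
.check_dt <- function(cfg, mech, inter, nuc_effect = NULL,
                      descent = FALSE) {
  k_eff <- .k_eff_max(mech, inter, nuc_effect)
  gq <- .gamma_q(cfg$eta, mech$r_tub)
  bound <- if (descent) gq * 1.2 / k_eff else gq / (5 * k_eff)
  if (cfg$dt > bound)
    stop(sprintf(
      "dt = %.3g s exceeds the %s bound %.3g s",
      cfg$dt, if (descent) "descent stability" else
        "accuracy (gamma_q / 5 k_eff)", bound), call. = FALSE)
  invisible(TRUE)
}

.ctrl_list <- function(cfg, mech, n_steps, monitor = NULL, relax_tol = 0) {
  list(dt = cfg$dt, n_steps = as.double(n_steps),
       kBT = .kB * cfg$temperature,
       gamma_q = .gamma_q(cfg$eta, mech$r_tub),
       gamma_tau = .gamma_tau(cfg$eta, mech$r_tub),
       seed = as.double(cfg$seed),
       record_stride = as.integer(cfg$record_stride),
       snap_stride = as.integer(cfg$snap_stride),
       monitor_index = if (is.null(monitor)) -1L
                       else as.integer(monitor$monitored_index - 1L),
       theta_curved = if (is.null(monitor)) 0.15 else monitor$theta_curved,
       theta_straight = if (is.null(monitor)) 0.05
                        else monitor$theta_straight,
       relax_tol = relax_tol, max_disp = cfg$max_disp)
}

.kin_list <- function(kin, cfg, temperature) {
  if (is.null(kin)) {
    return(list(enabled = FALSE, p_add = 0, p_hyd = 0, kin_stride = 0L,
                detach_stride = 0L, detach_thr_energy = 0,
                window_dimers = 1000L, detach_enabled = FALSE))
  }
  kappa <- kin$time_compression
  imax <- .Machine$integer.max
  list(enabled = TRUE,
       p_add = kin$k_on * kin$c_tub * kin$t_kin,
       p_hyd = 1 - exp(-kin$k_hydr * kin$t_kin),
       kin_stride = as.integer(max(1, min(
         imax, round(kin$t_kin / kappa / cfg$dt)))),
       detach_stride = as.integer(max(1, min(
         imax, round(kin$detach_interval / cfg$dt)))),
       detach_thr_energy = kin$detach_threshold * .kB * temperature,
       window_dimers = kin$window_dimers,
       detach_enabled = TRUE)
}

.as_run <- function(res, state, cfg, kappa = 1) {
  tr <- as.data.frame(res$trace)
  names(tr) <- c("t", "n_monomers", "n_gtp", "tip_z", "ring_z",
                 "obstacle_z", "n_straightening", "theta_mon")
  tr$t <- tr$t * kappa
  ev <- as.data.frame(res$events)
  if (nrow(ev)) {
    names(ev) <- c("t", "pf", "type", "value")
    ev$t <- ev$t * kappa
    ev$type <- c("addition", "hydrolysis", "detachment", "ring_rebind",
                 "ring_lost", "window_exhausted")[ev$type]
  } else {
    ev <- data.frame(t = numeric(), pf = numeric(), type = character(),
                     value = numeric())
  }
  snaps <- res$snapshots
  final <- .new_mt_state(res$state$pf, res$state$nuc,
                         res$state$mobile_from, state$n_pf, state$r_wall,
                         state$lateral)
  structure(list(state = final, trace = tr, events = ev,
                 snapshots = snaps,
                 n_straightening = res$n_straightening,
                 steps = res$steps, converged = res$converged,
                 bead_escaped = res$bead_escaped,
                 ring_lost = res$ring_lost,
                 window_exhausted = res$window_exhausted,
                 final_max_grad = res$final_max_grad,
                 bead_z = res$bead_z %||% NULL,
                 ring_z = res$ring_z %||% NULL,
                 ring_x = res$ring_x %||% NULL,
                 obstacle_z = res$obstacle_z %||% NULL,
                 duration = max(tr$t), compression = kappa,
                 seed = cfg$seed),
            class = "mt_run")
}

#' @export
print.mt_run <- function(x, ...) {
  cat(sprintf(
    "mt_run: %.3g s simulated (%d trace rows, %d snapshots, %d events)\n",
    x$duration, nrow(x$trace), length(x$snapshots), nrow(x$events)))
  invisible(x)
}

.no_coupler <- list(type = "none")

.run <- function(state, mech, inter, nuc_effect = NULL, kin = NULL,
                 coupler = NULL, cfg = sim_config(), monitor = NULL,
                 relax_tol = 0, n_steps = NULL) {
  .check_dt(cfg, mech, inter, nuc_effect, descent = relax_tol > 0)
  kappa <- if (is.null(kin)) 1 else kin$time_compression
  if (is.null(n_steps))
    n_steps <- round(cfg$duration / kappa / cfg$dt)
  res <- bd_run_cpp(state$pf, state$nuc, state$mobile_from,
                    .geom_list(state, mech),
                    .mech_list(mech, nuc_effect),
                    .inter_list(inter, nuc_effect),
                    .kin_list(kin, cfg, cfg$temperature),
                    coupler %||% .no_coupler,
                    .ctrl_list(cfg, mech, n_steps, monitor, relax_tol))
  .as_run(res, state, cfg, kappa)
}

#' Brownian-dynamics trajectory of a single protofilament
#'
#' Propagates an isolated PF with the Euler-Maruyama discretisation of the
#' overdamped Langevin equations (translation and rotation per monomer,
#' drags `6 pi r eta` and `8 pi r^3 eta`).  The bottom dimer is
#' position-restrained.  Identical seed and configuration give a
#' bit-identical trajectory.
#'
#' @param chain an `mt_state` from [pf_chain()].
#' @param mech a [mechanical_params()] bundle.
#' @param cfg a [sim_config()]; set `snap_stride` to record snapshots.
#' @param inter an [interaction_params()] bundle (inter-dimer bonds).
#' @param criteria optional [straightening_criteria()]; when given, the
#'   kernel scores curved-to-straight passages of the monitored hinge at
#'   every step and reports the count in `n_straightening`.
#' @return an `mt_run` with trace, snapshots, events and counters.
#' @examples
#' run <- simulate_single_pf(pf_chain(8), cfg = sim_config(
#'   duration = 2e-8, record_stride = 100, seed = 7))
#' @export
simulate_single_pf <- function(chain, mech = mechanical_params(),
                               cfg = sim_config(),
                               inter = interaction_params(),
                               criteria = NULL) {
  .check(chain$n_pf == 1, "chain must have a single PF (see pf_chain())")
  .run(chain, mech, inter, cfg = cfg, monitor = criteria)
}

#' One (or a few) Brownian substeps of a full state
#'
#' Single Euler-Maruyama update of every mobile monomer, usable on any
#' state including the 13-PF lattice.  The kinetic layer is off.
#'
#' @param state an `mt_state`.
#' @inheritParams simulate_single_pf
#' @param nuc_effect optional [nucleotide_effect()].
#' @param n_steps number of consecutive substeps to take.
#' @return the updated `mt_state`.
#' @export
brownian_substep <- function(state, mech = mechanical_params(),
                             inter = interaction_params(),
                             cfg = sim_config(), nuc_effect = NULL,
                             n_steps = 1) {
  cfg$record_stride <- 0L
  cfg$snap_stride <- 0L
  .run(state, mech, inter, nuc_effect, cfg = cfg,
       n_steps = n_steps)$state
}

#' Zero-temperature relaxation (gradient descent)
#'
#' Runs the Langevin update with the temperature set to zero until the
#' largest gradient component over mobile coordinates falls below `tol`,
#' which is mathematically a gradient-descent minimisation.
#'
#' @inheritParams brownian_substep
#' @param coupler optional coupler list (see [coupler_bead()]).
#' @param tol convergence threshold on the max gradient,
#'   kcal mol^-1 nm^-1.
#' @param max_steps iteration cap; exceeded => error with diagnostics
#'   unless `partial = TRUE`.
#' @param partial return the non-converged run instead of erroring.
#' @param dt descent step, s; defaults to the largest step within the
#'   Euler descent-stability bound (larger than the stochastic dt, which
#'   is held to an accuracy bound instead).
#' @return an `mt_run` with `converged`, `final_max_grad` and the relaxed
#'   state.
#' @export
relax_state <- function(state, mech = mechanical_params(),
                        inter = interaction_params(), nuc_effect = NULL,
                        coupler = NULL, cfg = sim_config(),
                        tol = 1e-4, max_steps = 2e6, partial = FALSE,
                        dt = NULL) {
  cfg$temperature <- 0
  cfg$record_stride <- 0L
  cfg$snap_stride <- 0L
  # largest Euler-stable descent step: translational and rotational
  # stiffness bounds (bond stiffness couples into tau via r_tub^2)
  k_q <- .k_eff_max(mech, inter, nuc_effect)
  k_tau <- (mech$k_intra +
              (4 * inter$a_long + 2 * inter$b_long) / inter$r_long^2) *
    mech$r_tub^2 + max(.mech_list(mech, nuc_effect)$B)
  cfg$dt <- dt %||% (0.45 * min(.gamma_q(cfg$eta, mech$r_tub) / k_q,
                                .gamma_tau(cfg$eta, mech$r_tub) / k_tau))
  run <- .run(state, mech, inter, nuc_effect, coupler = coupler,
              cfg = cfg, relax_tol = tol, n_steps = max_steps)
  if (!run$converged && !run$bead_escaped && !partial)
    stop(sprintf(
      "relaxation did not converge in %g steps (max gradient %.3g)",
      run$steps, run$final_max_grad), call. = FALSE)
  run
}

#' Two-layer microtubule simulation
#'
#' Interleaves Brownian substeps of every mobile monomer with the kinetic
#' Monte-Carlo layer (stochastic GTP-dimer additions at PF tips every
#' `t_kin`, random GTP hydrolysis) and the detachment scan that removes
#' terminal oligomers whose connecting longitudinal bond has effectively
#' broken.
#'
#' @param state an `mt_state` (see [mt_state()], [init_capped_mt()]).
#' @param kin a [kinetic_params()] bundle.
#' @param protocol `"constant"` (fixed `c_tub`) or `"dilution"` (soluble
#'   tubulin set to zero at t = 0).
#' @param coupler optional coupler (see [dam1_ring_coupler()],
#'   [obstacle_coupler()]).
#' @inheritParams brownian_substep
#' @return an `mt_run`; trace times are physical seconds (re-expanded when
#'   `kin$time_compression > 1`).
#' @export
run_mt <- function(state, mech = mechanical_params(),
                   inter = interaction_params(),
                   nuc_effect = nucleotide_effect(),
                   kin = kinetic_params(),
                   protocol = c("constant", "dilution"),
                   coupler = NULL, cfg = sim_config()) {
  protocol <- match.arg(protocol)
  if (protocol == "dilution") kin$c_tub <- 0
  .run(state, mech, inter, nuc_effect, kin = kin, coupler = coupler,
       cfg = cfg)
}

#' Microtubule length trace from recorded snapshots
#'
#' MT length at a time point is the mean over PFs of the axial coordinate
#' of each PF's curl origin (the point where the PF leaves the wall), so
#' flared curls do not count toward length.
#'
#' @param run an `mt_run` recorded with `snap_stride > 0`.
#' @param wall_tolerance radial deviation above which a PF is considered
#'   off the wall, nm.
#' @return data.frame with `t` (s), `length` (nm), `n_gtp` (dimers).
#' @export
mt_length_trace <- function(run, wall_tolerance = 1.5) {
  .check(length(run$snapshots) > 0, "run has no snapshots")
  kappa <- run$compression
  rows <- lapply(run$snapshots, function(sn) {
    origins <- vapply(sn$pf, function(m) {
      tr <- pf_trace(z = m[, 2], x = m[, 1])
      curl_origin(tr, wall_tolerance = wall_tolerance)$origin_z
    }, 1.0)
    data.frame(t = sn$t * kappa, length = mean(origins),
               n_gtp = sum(vapply(sn$nuc, sum, 1L)))
  })
  do.call(rbind, rows)
}

#' Growth or shortening rate from a length trace
#'
#' Least-squares slope of MT length vs time after discarding a burn-in.
#'
#' @param trace data.frame with columns `t` (s) and `length` (nm).
#' @param burn_in initial time span to discard, s.
#' @return slope in nm/s.
#' @examples
#' measure_rate(data.frame(t = 0:10, length = 20 * (0:10)), burn_in = 0)
#' @export
measure_rate <- function(trace, burn_in = 0) {
  .check(is.data.frame(trace) && all(c("t", "length") %in% names(trace)),
         "trace must have columns t and length")
  .check(max(trace$t) > burn_in,
         "trace duration must exceed the burn-in")
  d <- trace[trace$t >= burn_in, ]
  .check(nrow(d) >= 2, "need at least 2 points after burn-in")
  unname(coef(lm(length ~ t, data = d))[2])
}
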