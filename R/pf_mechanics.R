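# Single-protofilament experiments: straightening statistics, maximal
# sustainable force against a dragged Dam1 subunit, dynamic persistence
# length.

#' Straightening frequency of a protofilament hinge
#'
#' Counts complete passages from the curved state (bending angle above
#' `theta_curved`) to the straight state (below `theta_straight`) and
#' divides by the observation time.  The two-threshold hysteresis means
#' dithering at a single threshold is never counted.
#'
#' For an `mt_run` the kernel's dense per-step counter is used (the
#' recorded trace is typically too coarse for MHz passage rates); for a
#' numeric angle signal the same state machine runs in R.
#'
#' @param x an `mt_run` from [simulate_single_pf()] with `criteria`
#'   supplied, or a numeric vector of bending angles (rad).
#' @param criteria a [straightening_criteria()] (signal method).
#' @param duration observation time spanned by the signal, s (signal
#'   method).
#' @param ... unused.
#' @return passages per second.
#' @examples
#' sig <- rep(c(0.2, 0), 10) # square wave: 10 complete passages
#' straightening_frequency(sig, duration = 1)
#' @export
straightening_frequency <- function(x, ...) {
  UseMethod("straightening_frequency")
}

#' @rdname straightening_frequency
#' @export
straightening_frequency.numeric <- function(x,
    criteria = straightening_criteria(), duration, ...) {
  .check(length(x) > 0, "empty trajectory")
  .check(!missing(duration) && duration > 0,
         "duration must be given and > 0")
  hi <- criteria$theta_curved
  lo <- criteria$theta_straight
  state <- if (x[1] > hi) 1L else if (x[1] < lo) 0L else NA_integer_
  n <- 0L
  for (th in x[-1]) {
    if (is.na(state)) {
      if (th > hi) state <- 1L else if (th < lo) state <- 0L
    } else if (state == 1L) {
      if (th < lo) {
        state <- 0L
        n <- n + 1L
      }
    } else if (th > hi) state <- 1L
  }
  n / duration
}

#' @rdname straightening_frequency
#' @export
straightening_frequency.mt_run <- function(x, ...) {
  .check(nrow(x$trace) > 0, "empty trajectory")
  x$n_straightening / x$duration
}

#' Maximal force a curved protofilament can sustain
#'
#' A Dam1 subunit constrained to move only axially at a fixed lateral
#' offset is dragged toward the PF plus-end by a constant force `F`
#' (potential `w(z) = -F z`) and repelled sterically by the tubulins.  The
#' force-balance equation is solved with the Langevin update at zero
#' temperature (gradient descent); the largest `F` for which a stationary
#' configuration exists is found by bisection.
#'
#' @param mech a [mechanical_params()] bundle (its `B` is the stiffness
#'   under test).
#' @param ring a [ring_params()] (subunit radius).
#' @param bead_offset_x lateral offset of the dragged subunit, nm.
#' @param inter an [interaction_params()] bundle.
#' @param n_monomers chain length.
#' @param f_max upper bracket for the search, pN.
#' @param tol bisection tolerance, pN.
#' @param relax_tol zero-temperature convergence threshold,
#'   kcal mol^-1 nm^-1.
#' @param cfg a [sim_config()] (dt, viscosity).
#' @return largest sustainable force, pN.
#' @export
max_sustainable_force <- function(mech = mechanical_params(),
                                  ring = ring_params(),
                                  bead_offset_x = 7,
                                  inter = interaction_params(),
                                  n_monomers = 16, f_max = 80,
                                  tol = 0.05, relax_tol = 1e-4,
                                  cfg = sim_config()) {
  chain <- pf_chain(n_monomers, "equilibrium", mech)
  gamma_b <- .gamma_q(cfg$eta, ring$R_dam1)

  # start the bead just below its first steric contact with the curved
  # chain so the zero-temperature descent is not dominated by transport
  reach <- ring$R_dam1 + mech$r_tub
  m <- chain$pf[[1]]
  lim <- Inf
  for (k in seq_len(nrow(m))) {
    dxk <- abs(m[k, "x"] - bead_offset_x)
    if (dxk < reach)
      lim <- min(lim, m[k, "z"] - sqrt(reach^2 - dxk^2))
  }
  z0 <- if (is.finite(lim)) lim - 1 else 0

  holds <- function(f_pN) {
    bead <- list(type = "bead", x = bead_offset_x, z = z0,
                 R = ring$R_dam1, F = .from_pN(f_pN), gamma = gamma_b)
    run <- relax_state(chain, mech, inter, coupler = bead, cfg = cfg,
                       tol = relax_tol, max_steps = 2.4e7, partial = TRUE)
    if (run$bead_escaped) return(FALSE)
    if (!run$converged)
      stop(sprintf(
        paste("force-balance relaxation did not converge at F = %.2f pN",
              "(max gradient %.3g after %g steps)"),
        f_pN, run$final_max_grad, run$steps), call. = FALSE)
    TRUE
  }

  lo <- 0
  hi <- max(8 * tol, 0.4)
  while (hi < f_max && holds(hi)) {
    lo <- hi
    hi <- hi * 2
  }
  if (hi >= f_max) stop("f_max bracket too small", call. = FALSE)
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (holds(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Dynamic persistence length from angular fluctuations
#'
#' Fits `<cos(delta(s') - delta(s' + s))> = exp(-s / xi_d)` where `delta`
#' is the tangent-angle deflection from the mean (equilibrium) shape and
#' `s` the arc-length separation, by least squares of `log` mean cosine on
#' `s` through the origin.  A noise-free trajectory returns `Inf`.
#'
#' @param x an `mt_run` of a single PF recorded with snapshots, or a
#'   numeric matrix of tangent angles (snapshots in rows, positions along
#'   the filament in columns).
#' @param spacing arc length between adjacent positions, nm.
#' @param exclude number of leading (restrained) positions to drop
#'   (`mt_run` method).
#' @param max_sep largest separation used in the fit, in position counts.
#' @param ... unused.
#' @return dynamic persistence length in nm (divide by 1000 for um).
#' @examples
#' sig <- matrix(rnorm(16 * 400, sd = 0.1), 400, 16)
#' tau <- t(apply(sig, 1, cumsum)) # independent hinge deflections
#' dynamic_persistence_length(tau, spacing = 4)
#' @export
dynamic_persistence_length <- function(x, ...) {
  UseMethod("dynamic_persistence_length")
}

#' @rdname dynamic_persistence_length
#' @export
dynamic_persistence_length.matrix <- function(x, spacing = 4,
                                              max_sep = NULL, ...) {
  .check(nrow(x) >= 100,
         "need >= 100 snapshots for a stable correlation estimate")
  npos <- ncol(x)
  .check(npos >= 4, "need at least 4 positions along the filament")
  if (is.null(max_sep)) max_sep <- npos - 1L
  max_sep <- min(max_sep, npos - 1L)
  delta <- sweep(x, 2, colMeans(x))
  if (all(abs(delta) < 1e-12)) return(Inf)
  seps <- seq_len(max_sep)
  corr <- vapply(seps, function(m) {
    i <- seq_len(npos - m)
    mean(cos(delta[, i + m, drop = FALSE] - delta[, i, drop = FALSE]))
  }, 1.0)
  keep <- corr > 0
  .check(sum(keep) >= 3, "fewer than 3 usable arc-length points")
  s <- seps[keep] * spacing
  y <- log(corr[keep])
  slope <- sum(s * y) / sum(s^2)
  if (slope >= 0) return(Inf)
  -1 / slope
}

#' @rdname dynamic_persistence_length
#' @export
dynamic_persistence_length.mt_run <- function(x, spacing = 4, exclude = 2,
                                              max_sep = NULL, ...) {
  .check(length(x$snapshots) >= 100,
         "need >= 100 snapshots; rerun with snap_stride set")
  tau <- t(vapply(x$snapshots,
                  function(sn) sn$pf[[1]][, 3],
                  numeric(nrow(x$snapshots[[1]]$pf[[1]]))))
  if (exclude > 0) tau <- tau[, -seq_len(exclude), drop = FALSE]
  dynamic_persistence_length(tau, spacing = spacing, max_sep = max_sep)
}
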