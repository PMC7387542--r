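# Staged calibration of the interaction parameters {a_lat, b_lat, b_long,
# k_on, B} against measured growth/shortening rates, curl lengths, stall
# force and critical concentration.  The procedure is an explicit staged
# grid search:
#   Step 1  pick a PF bending stiffness B from the candidate range;
#   Step 2  start from the yeast tubulin association rate constant;
#   Step 3  for each lateral barrier a_lat, vary {b_lat, b_long} to match
#           (A) shortening rate ~ -400 nm/s with 40-80 nm curls and
#           (B) growth rate ~ 20 nm/s at 10 uM with 15-40 nm curls;
#   Step 4  check the shortening sets for a ~30 pN stall force under a
#           Dam1 ring; failure sends the search back to Step 1 with the
#           next B;
#   Step 5  check the growth sets for a 0-2 uM critical concentration and
#           rescale k_on and c_tub keeping their product unchanged to
#           match the concentration-dependence slope.

#' Calibration targets
#'
#' The experimental observables the staged search must reproduce.  "~"
#' targets are matched within `rel_tol` relative tolerance.
#'
#' @param shortening_rate target unloaded shortening rate, nm/s.
#' @param shortening_curl acceptable curl-length window when shortening,
#'   nm.
#' @param growth_rate target growth rate at `growth_conc`, nm/s.
#' @param growth_curl acceptable curl-length window when growing, nm.
#' @param growth_conc tubulin concentration for the growth target, uM.
#' @param stall_force target stall force, pN.
#' @param critical_conc admissible critical-concentration window, uM.
#' @param k_on_start starting association rate constant, uM^-1 s^-1 / PF.
#' @param rel_tol relative tolerance for the "~" targets.
#' @return an object of class `calibration_targets`.
#' @export
calibration_targets <- function(shortening_rate = -400,
                                shortening_curl = c(40, 80),
                                growth_rate = 20,
                                growth_curl = c(15, 40),
                                growth_conc = 10,
                                stall_force = 30,
                                critical_conc = c(0, 2),
                                k_on_start = 0.26,
                                rel_tol = 0.15) {
  .check(diff(shortening_curl) > 0 && diff(growth_curl) > 0 &&
           diff(critical_conc) >= 0, "windows must be nonempty intervals")
  structure(list(shortening_rate = shortening_rate,
                 shortening_curl = shortening_curl,
                 growth_rate = growth_rate, growth_curl = growth_curl,
                 growth_conc = growth_conc, stall_force = stall_force,
                 critical_conc = critical_conc, k_on_start = k_on_start,
                 rel_tol = rel_tol),
            class = "calibration_targets")
}

#' Calibration grid
#'
#' Candidate values for the staged search.  The lateral-barrier values are
#' the three exercised regimes; `b_lat` ranges are coarse defaults around
#' the GDP-like and GTP-like bond strengths.
#'
#' @param B bending stiffnesses to try, kcal mol^-1 rad^-2.
#' @param a_lat lateral activation barriers, kcal/mol.
#' @param b_lat_shorten,b_lat_grow lateral bond depths tried for the
#'   shortening / growth branch, kcal/mol.
#' @param b_long longitudinal bond depths to try, kcal/mol.
#' @return an object of class `calibration_grid`.
#' @export
calibration_grid <- function(B = c(174, 78),
                             a_lat = c(6.3, 4.2, 2.1),
                             b_lat_shorten = seq(4.1, 5.3, by = 0.3),
                             b_lat_grow = seq(7.4, 8.6, by = 0.3),
                             b_long = c(11.0, 11.6, 12.2)) {
  structure(list(B = B, a_lat = a_lat, b_lat_shorten = b_lat_shorten,
                 b_lat_grow = b_lat_grow, b_long = b_long),
            class = "calibration_grid")
}

.close_to <- function(x, target, rel_tol) {
  is.finite(x) && abs(x - target) <= rel_tol * abs(target)
}
.in_window <- function(x, w) is.finite(x) && x >= w[1] && x <= w[2]

#' Simulation-backed measurement functions for the calibration
#'
#' Returns the four measurement closures the staged search consumes; each
#' runs the two-layer simulation at the given parameter point and
#' extracts the observable.  Durations, window depth and the kinetic
#' compression factor for growth measurements are configurable so the
#' search can be run at desk scale.
#'
#' @param shorten_duration,growth_duration physical run lengths, s.
#' @param compression kinetic-clock compression for growth runs.
#' @param window_dimers mobile window depth.
#' @param n_dimers lattice depth of the starting state.
#' @param stall_loads loads used to bracket the stall force, pN.
#' @param ccrit_conc concentrations for the critical-concentration fit,
#'   uM.
#' @param cfg a [sim_config()] prototype.
#' @param mech a [mechanical_params()] prototype (B is overridden).
#' @return list of measurement functions.
#' @export
calibration_measures <- function(shorten_duration = 6e-3,
                                 growth_duration = 1.5,
                                 compression = 150,
                                 window_dimers = 16,
                                 n_dimers = 40,
                                 stall_loads = c(5, 20, 35, 50),
                                 ccrit_conc = c(2, 5, 10, 20),
                                 cfg = sim_config(),
                                 mech = mechanical_params()) {
  snap_every <- function(duration_sim) {
    max(1000L, as.integer(round(duration_sim / cfg$dt / 40)))
  }
  base_state <- function(nd, wd) mt_state(nd, "GDP", wd)

  run_point <- function(B, a_lat, b_lat, b_long, kin, seed, duration,
                        coupler_fn = NULL) {
    mech$B <- B
    inter <- interaction_params(a_lat = a_lat, b_lat = b_lat,
                                b_long = b_long)
    kappa <- kin$time_compression
    cfg$duration <- duration
    cfg$seed <- seed
    cfg$record_stride <- 50000L
    cfg$snap_stride <- snap_every(duration / kappa)
    st <- base_state(n_dimers, window_dimers)
    coup <- if (is.null(coupler_fn)) NULL else coupler_fn(st)
    run_mt(st, mech, inter, NULL, kin, "constant", coup, cfg)
  }

  measure_run <- function(run, burn_frac = 0.25) {
    lt <- mt_length_trace(run)
    rate <- measure_rate(lt, burn_in = burn_frac * max(lt$t))
    tm <- tip_metrics(mt_state_traces(run$state), smooth = FALSE)
    list(rate = rate, curl_length = mean(tm$curl_length))
  }

  list(
    shortening = function(B, a_lat, b_lat, b_long, seeds) {
      kin <- kinetic_params(c_tub = 0, k_hydr = 0,
                            window_dimers = window_dimers)
      out <- lapply(seeds, function(s) {
        measure_run(run_point(B, a_lat, b_lat, b_long, kin, s,
                              shorten_duration))
      })
      list(rate = mean(vapply(out, `[[`, 1.0, "rate")),
           curl_length = mean(vapply(out, `[[`, 1.0, "curl_length")))
    },
    growth = function(B, a_lat, b_lat, b_long, k_on, c_tub, seeds) {
      kin <- kinetic_params(k_on = k_on, c_tub = c_tub, k_hydr = 0,
                            window_dimers = window_dimers,
                            time_compression = compression)
      out <- lapply(seeds, function(s) {
        measure_run(run_point(B, a_lat, b_lat, b_long, kin, s,
                              growth_duration))
      })
      list(rate = mean(vapply(out, `[[`, 1.0, "rate")),
           curl_length = mean(vapply(out, `[[`, 1.0, "curl_length")))
    },
    stall = function(B, a_lat, b_lat, b_long, seeds) {
      mech$B <- B
      inter <- interaction_params(a_lat = a_lat, b_lat = b_lat,
                                  b_long = b_long)
      kin <- kinetic_params(c_tub = 0, k_hydr = 0,
                            window_dimers = window_dimers)
      cfg$duration <- shorten_duration
      cfg$record_stride <- 50000L
      cfg$snap_stride <- snap_every(shorten_duration)
      st <- base_state(n_dimers, window_dimers)
      res <- stall_sweep(st, stall_loads, "ring", mech, inter, NULL,
                         kin, ring_params(), cfg, n_seeds = length(seeds),
                         burn_in = 0.25 * shorten_duration,
                         seed = seeds[1])
      res$stall
    },
    ccrit = function(B, a_lat, b_lat, b_long, k_on, seeds) {
      kin0 <- kinetic_params(k_on = k_on, c_tub = 1, k_hydr = 0,
                             window_dimers = window_dimers,
                             time_compression = compression)
      rates <- vapply(ccrit_conc, function(cc) {
        kin <- kin0
        kin$c_tub <- cc
        mean(vapply(seeds, function(s) {
          run <- run_point(B, a_lat, b_lat, b_long, kin, s,
                           growth_duration)
          lt <- mt_length_trace(run)
          measure_rate(lt, burn_in = 0.25 * max(lt$t))
        }, 1.0))
      }, 1.0)
      critical_concentration(ccrit_conc, rates)
    })
}

#' Staged calibration search
#'
#' Executes the five calibration steps in order over the supplied grid,
#' pruning exactly as specified (a Step-4 stall failure returns to Step 1
#' with the next bending stiffness), and emits a full audit trail of
#' every evaluation with its seeds.
#'
#' @param grid a [calibration_grid()].
#' @param targets a [calibration_targets()].
#' @param measures measurement functions, normally
#'   [calibration_measures()]; injectable for testing.
#' @param budget maximum number of measurement evaluations.
#' @param n_seeds replicate seeds per evaluation.
#' @param seed base seed.
#' @return an object of class `calibration_result` with
#'   `default_shortening`, `default_growth`, `trail` (audit data.frame)
#'   and `complete`.
#' @export
calibrate <- function(grid = calibration_grid(),
                      targets = calibration_targets(),
                      measures = calibration_measures(),
                      budget = 200, n_seeds = 3, seed = 1) {
  trail <- list()
  used <- 0L
  seeds <- seed + seq_len(n_seeds)
  log_row <- function(step, B, a_lat, b_lat, b_long, obs, accepted) {
    trail[[length(trail) + 1]] <<- data.frame(
      step = step, B = B, a_lat = a_lat, b_lat = b_lat, b_long = b_long,
      observable = names(obs), value = unlist(obs, use.names = FALSE),
      accepted = accepted, seeds = paste(seeds, collapse = ","))
  }
  out_of_budget <- function() used >= budget
  shortening_default <- NULL
  growth_default <- NULL

  for (B in grid$B) {            # Step 1
    k_on <- targets$k_on_start   # Step 2
    cand_A <- list()
    cand_B <- list()
    for (a in grid$a_lat) {      # Step 3
      for (bl in grid$b_long) {
        for (b in grid$b_lat_shorten) {
          if (out_of_budget()) break
          m <- measures$shortening(B, a, b, bl, seeds)
          used <- used + 1L
          ok <- .close_to(m$rate, targets$shortening_rate,
                          targets$rel_tol) &&
            .in_window(m$curl_length, targets$shortening_curl)
          log_row("3A", B, a, b, bl, m, ok)
          if (ok) cand_A[[length(cand_A) + 1]] <-
              list(B = B, a_lat = a, b_lat = b, b_long = bl, obs = m)
        }
        for (b in grid$b_lat_grow) {
          if (out_of_budget()) break
          m <- measures$growth(B, a, b, bl, k_on, targets$growth_conc,
                               seeds)
          used <- used + 1L
          ok <- .close_to(m$rate, targets$growth_rate, targets$rel_tol) &&
            .in_window(m$curl_length, targets$growth_curl)
          log_row("3B", B, a, b, bl, m, ok)
          if (ok) cand_B[[length(cand_B) + 1]] <-
              list(B = B, a_lat = a, b_lat = b, b_long = bl,
                   k_on = k_on, obs = m)
        }
      }
    }
    for (ca in cand_A) {         # Step 4
      if (out_of_budget()) break
      st <- measures$stall(ca$B, ca$a_lat, ca$b_lat, ca$b_long, seeds)
      used <- used + 1L
      ok <- .close_to(st, targets$stall_force, targets$rel_tol)
      log_row("4", ca$B, ca$a_lat, ca$b_lat, ca$b_long,
              list(stall = st), ok)
      if (ok) {
        shortening_default <- c(ca, list(stall = st))
        break
      }
    }
    if (is.null(shortening_default)) next  # back to Step 1, next B
    a_star <- shortening_default$a_lat
    for (cb in cand_B) {         # Step 5
      if (cb$a_lat != a_star) next
      if (out_of_budget()) break
      cc <- measures$ccrit(cb$B, cb$a_lat, cb$b_lat, cb$b_long,
                           cb$k_on, seeds)
      used <- used + 1L
      ok <- cc$bracketed && .in_window(cc$ccrit, targets$critical_conc)
      log_row("5", cb$B, cb$a_lat, cb$b_lat, cb$b_long,
              list(ccrit = cc$ccrit), ok)
      if (ok) {
        # match the concentration-dependence slope by rescaling k_on and
        # c_tub, keeping their product unchanged
        slope_target <- targets$growth_rate /
          (targets$growth_conc - cc$ccrit)
        factor <- slope_target / cc$slope
        growth_default <- c(cb, list(
          ccrit = cc$ccrit, slope = cc$slope,
          k_on_adjusted = cb$k_on * factor,
          c_tub_equivalent = targets$growth_conc / factor))
        break
      }
    }
    if (!is.null(growth_default)) break
    shortening_default <- NULL   # growth failed for this B: next B
  }

  structure(list(default_shortening = shortening_default,
                 default_growth = growth_default,
                 trail = do.call(rbind, trail),
                 evaluations = used,
                 complete = !is.null(shortening_default) &&
                   !is.null(growth_default),
                 exhausted = out_of_budget()),
            class = "calibration_result")
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("calibration_result:",
      if (x$complete) "complete" else
        if (x$exhausted) "incomplete (budget exhausted)" else
          "incomplete (no accepted set)", "\n")
  if (!is.null(x$default_shortening)) {
    s <- x$default_shortening
    cat(sprintf(
      "  shortening default: B=%g a_lat=%g b_lat=%g b_long=%g (stall %.1f pN)\n",
      s$B, s$a_lat, s$b_lat, s$b_long, s$stall))
  }
  if (!is.null(x$default_growth)) {
    g <- x$default_growth
    cat(sprintf(
      "  growth default:     B=%g a_lat=%g b_lat=%g b_long=%g (ccrit %.2f uM)\n",
      g$B, g$a_lat, g$b_lat, g$b_long, g$ccrit))
  }
  cat(" ", x$evaluations, "measurement evaluations\n")
  invisible(x)
}

#' Critical tubulin concentration
#'
#' X-intercept of the linear fit of growth rate vs concentration.  Needs
#' at least 4 concentrations; reports `bracketed = FALSE` when the rates
#' do not change sign across the grid.
#'
#' @param conc concentrations, uM.
#' @param rates measured growth rates at `conc`, nm/s.
#' @return list with `ccrit` (uM, `NA` when not bracketed), `bracketed`,
#'   and `slope` (nm/s per uM).
#' @examples
#' critical_concentration(c(1, 2, 5, 10), 2.1 * (c(1, 2, 5, 10) - 1.5))
#' @export
critical_concentration <- function(conc, rates) {
  .check(length(conc) >= 4 && length(rates) == length(conc),
         "need >= 4 concentrations with matching rates")
  fit <- lm(rates ~ conc)
  b <- coef(fit)
  cc <- -b[1] / b[2]
  bracketed <- min(rates) < 0 && max(rates) > 0
  list(ccrit = if (bracketed) unname(cc) else NA_real_,
       bracketed = bracketed, slope = unname(b[2]))
}
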