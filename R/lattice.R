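# R-level kinetic Monte-Carlo operations.  These are the reference
# semantics for the events the compiled two-layer loop performs internally
# (run_mt); they operate on R states and use R's RNG stream.

#' One kinetic Monte-Carlo step
#'
#' For each PF independently, with probability `P = k_on c_tub t_kin`
#' appends one GTP dimer at the tip continuing the tip's current tangent
#' (hinge increments of the equilibrium angle, bonds unstretched); then
#' every GTP dimer hydrolyses with probability `1 - exp(-k_hydr t_kin)`.
#'
#' @param state an `mt_state`.
#' @param kin a [kinetic_params()] bundle.
#' @param mech a [mechanical_params()] bundle (placement geometry).
#' @return list with the updated `state` and an `events` data.frame.
#' @examples
#' set.seed(1)
#' ks <- kinetic_step(mt_state(4, "GTP", n_pf = 13),
#'                    kinetic_params(c_tub = 40))
#' @export
kinetic_step <- function(state, kin = kinetic_params(),
                         mech = mechanical_params()) {
  p_add <- kin$k_on * kin$c_tub * kin$t_kin
  .check(p_add <= 1, "addition probability exceeds 1")
  p_hyd <- 1 - exp(-kin$k_hydr * kin$t_kin)
  rt <- mech$r_tub
  ev <- list()
  for (n in seq_len(state$n_pf)) {
    if (runif(1) < p_add) {
      m <- state$pf[[n]]
      K <- nrow(m)
      t0 <- m[K, "tau"]
      t1 <- t0 + mech$theta0
      t2 <- t1 + mech$theta0
      x1 <- m[K, "x"] + rt * (sin(t0) + sin(t1))
      z1 <- m[K, "z"] + rt * (cos(t0) + cos(t1))
      x2 <- x1 + rt * (sin(t1) + sin(t2))
      z2 <- z1 + rt * (cos(t1) + cos(t2))
      state$pf[[n]] <- rbind(m, c(x1, z1, t1), c(x2, z2, t2))
      state$nuc[[n]] <- c(state$nuc[[n]], 1L)
      ev[[length(ev) + 1]] <- data.frame(pf = n, type = "addition",
                                         value = 1)
    }
    if (p_hyd > 0) {
      gtp <- which(state$nuc[[n]] == 1L)
      if (length(gtp)) {
        hyd <- gtp[runif(length(gtp)) < p_hyd]
        state$nuc[[n]][hyd] <- 0L
        for (d in hyd)
          ev[[length(ev) + 1]] <- data.frame(pf = n, type = "hydrolysis",
                                             value = d)
      }
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(pf = numeric(), type = character(),
                            value = numeric())
  list(state = state, events = events)
}

#' Remove detached terminal oligomers
#'
#' Scans each PF from the tip for the innermost inter-dimer longitudinal
#' bond that has effectively broken (site separation beyond the activation
#' barrier with `|E_long| < threshold * kBT`) and removes everything
#' distal to it as one oligomer.
#'
#' @param state an `mt_state`.
#' @param inter an [interaction_params()] bundle.
#' @param threshold energy threshold in kBT units.
#' @param temperature temperature, K.
#' @param mech a [mechanical_params()] bundle (site geometry).
#' @return list with the updated `state` and an `events` data.frame
#'   (`pf`, `size` in dimers).
#' @export
detach_oligomers <- function(state, inter = interaction_params(),
                             threshold = 0.1, temperature = 310,
                             mech = mechanical_params()) {
  thr <- threshold * .kB * temperature
  res <- detach_scan_cpp(state$pf, state$nuc, state$mobile_from,
                         .geom_list(state, mech),
                         .inter_list(inter), thr)
  cut <- res$cut_dimer
  ev <- list()
  for (n in seq_len(state$n_pf)) {
    d <- cut[n]
    if (d >= 0) {
      ndim <- length(state$nuc[[n]])
      size <- ndim - d
      state$pf[[n]] <- state$pf[[n]][seq_len(2 * d), , drop = FALSE]
      state$nuc[[n]] <- state$nuc[[n]][seq_len(d)]
      ev[[length(ev) + 1]] <- data.frame(pf = n, size = size)
    }
  }
  events <- if (length(ev)) do.call(rbind, ev)
            else data.frame(pf = numeric(), size = numeric())
  list(state = state, events = events)
}
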