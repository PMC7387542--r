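# Microtubule / protofilament state containers and geometry helpers.
#
# A state holds, per PF, a K x 3 matrix of monomer coordinates
# (x = radial deviation from the wall cylinder, z = axial with plus-end
# positive, tau = in-plane rotation), a per-dimer nucleotide vector
# (0 = GDP, 1 = GTP) and the index of the first mobile monomer (everything
# below is the rigid lattice boundary).  PF n lives in the radial plane at
# azimuth 2 pi n / 13; alpha- and beta-monomers are treated identically and
# the 13-PF ring is unstaggered (no seam, no helical rise), which is the
# minimal geometry consistent with per-plane PF motion.

# radius of the cylinder of monomer centres for a 13-PF wall with ~5.15 nm
# lateral spacing
.default_r_wall <- 5.15 / (2 * sin(pi / 13))

.new_mt_state <- function(pf, nuc, mobile_from, n_pf = length(pf),
                          r_wall = .default_r_wall, lateral = n_pf > 1) {
  structure(list(pf = pf, nuc = nuc,
                 mobile_from = as.integer(mobile_from),
                 n_pf = as.integer(n_pf), r_wall = r_wall,
                 lateral = lateral),
            class = "mt_state")
}

#' Build a single isolated protofilament chain
#'
#' A chain of `n_monomers` spheres (default 16 = 8 dimers) whose bottom
#' dimer is position-restrained.  `shape = "equilibrium"` starts with every
#' free hinge at the equilibrium bending angle and all bonds unstretched
#' (the zero-temperature equilibrium); `"straight"` starts the chain along
#' the axis.
#'
#' @param n_monomers number of monomers (even).
#' @param shape starting shape.
#' @param mech a [mechanical_params()] bundle (geometry and theta0).
#' @return an `mt_state` with a single PF.
#' @examples
#' ch <- pf_chain(16)
#' @export
pf_chain <- function(n_monomers = 16,
                     shape = c("equilibrium", "straight"),
                     mech = mechanical_params()) {
  shape <- match.arg(shape)
  .check(n_monomers >= 4 && n_monomers %% 2 == 0,
         "n_monomers must be an even number >= 4")
  rt <- mech$r_tub
  tau <- if (shape == "equilibrium") {
    c(0, 0, mech$theta0 * seq_len(n_monomers - 2))
  } else {
    rep(0, n_monomers)
  }
  x <- numeric(n_monomers)
  z <- numeric(n_monomers)
  for (k in 2:n_monomers) {
    x[k] <- x[k - 1] + rt * (sin(tau[k - 1]) + sin(tau[k]))
    z[k] <- z[k - 1] + rt * (cos(tau[k - 1]) + cos(tau[k]))
  }
  m <- cbind(x = x, z = z, tau = tau)
  .new_mt_state(pf = list(m), nuc = list(rep(1L, n_monomers / 2)),
                mobile_from = 2L, n_pf = 1L, lateral = FALSE)
}

#' Build a straight 13-PF microtubule lattice
#'
#' @param n_dimers dimers per PF.
#' @param nucleotide `"GDP"`, `"GTP"`, or a 0/1 vector per dimer recycled
#'   across PFs.
#' @param window_dimers mobile window depth behind the tip (deeper layers
#'   frozen as the lattice boundary).
#' @param n_pf number of PFs (13 for a microtubule).
#' @param mech a [mechanical_params()] bundle.
#' @return an `mt_state`.
#' @examples
#' st <- mt_state(12, "GDP", window_dimers = 4)
#' @export
mt_state <- function(n_dimers, nucleotide = "GDP", window_dimers = 20,
                     n_pf = 13, mech = mechanical_params()) {
  .check(n_dimers >= 2, "n_dimers must be >= 2")
  K <- 2L * n_dimers
  rt <- mech$r_tub
  nuc <- if (is.character(nucleotide)) {
    rep(if (match.arg(nucleotide, c("GDP", "GTP")) == "GTP") 1L else 0L,
        n_dimers)
  } else {
    as.integer(rep_len(nucleotide, n_dimers))
  }
  z <- rt + 2 * rt * (seq_len(K) - 1)
  m <- cbind(x = numeric(K), z = z, tau = numeric(K))
  mob <- max(2L, K - 2L * as.integer(window_dimers))
  .new_mt_state(pf = replicate(n_pf, m, simplify = FALSE),
                nuc = replicate(n_pf, nuc, simplify = FALSE),
                mobile_from = rep(mob, n_pf), n_pf = n_pf)
}

#' Initialise a GTP-capped microtubule for dilution experiments
#'
#' A straight GDP lattice whose plus-end region carries a stochastic GTP
#' cap: each dimer at depth j layers from the plus end is GTP with
#' probability proportional to `exp(-j * 8 nm / cap_length)`, scaled so
#' the expected total GTP count is `cap_dimers`.
#'
#' @param n_dimers dimers per PF.
#' @param cap_dimers expected number of GTP dimers over the whole MT.
#' @param cap_length exponential decay length of the cap, nm.
#' @param seed RNG seed.
#' @inheritParams mt_state
#' @return an `mt_state`.
#' @examples
#' st <- init_capped_mt(40, cap_dimers = 120, seed = 1)
#' @export
init_capped_mt <- function(n_dimers, cap_dimers = 225, cap_length = 110,
                           window_dimers = 20, n_pf = 13,
                           mech = mechanical_params(), seed = 1) {
  st <- mt_state(n_dimers, "GDP", window_dimers, n_pf, mech)
  if (cap_dimers == 0) return(st)
  .check(cap_dimers <= n_dimers * n_pf, "cap larger than lattice")
  depth <- (n_dimers - 1):0           # layers from plus end, per dimer
  wts <- exp(-depth * 8 / cap_length) # 8 nm per dimer layer
  p <- pmin(1, cap_dimers * wts / (n_pf * sum(wts)))
  rng <- .mini_rng(seed)
  for (n in seq_len(n_pf)) {
    u <- rng(n_dimers)
    st$nuc[[n]] <- as.integer(u < p)
  }
  st
}

# small deterministic uniform generator so state construction does not
# disturb R's global RNG stream
.mini_rng <- function(seed) {
  s <- as.double(seed)
  function(n) {
    out <- numeric(n)
    for (i in seq_len(n)) {
      s <<- (s * 69069 + 1) %% 2^32
      out[i] <- s / 2^32
    }
    out
  }
}

#' @export
print.mt_state <- function(x, ...) {
  K <- vapply(x$pf, nrow, 1L)
  ngtp <- sum(vapply(x$nuc, sum, 1L))
  cat(sprintf(
    "mt_state: %d PF(s), %d-%d monomers/PF, %d GTP dimers, %s\n",
    x$n_pf, min(K), max(K), ngtp,
    if (x$lateral) "lateral bonds on" else "isolated"))
  invisible(x)
}

# --- kernel interface ------------------------------------------------------

.geom_list <- function(state, mech) {
  list(n_pf = state$n_pf, lateral = isTRUE(state$lateral),
       r_wall = state$r_wall, r_tub = mech$r_tub)
}

.mech_list <- function(mech, nuc_effect = NULL) {
  B <- if (is.null(nuc_effect)) c(mech$B, mech$B)
       else c(nuc_effect$B_gdp, nuc_effect$B_gtp)
  list(k_intra = mech$k_intra, theta0 = mech$theta0, k_rep = mech$k_rep,
       B = B)
}

.inter_list <- function(inter, nuc_effect = NULL) {
  b <- if (is.null(nuc_effect)) c(inter$b_lat, inter$b_lat)
       else c(nuc_effect$b_lat_gdp, nuc_effect$b_lat_gtp)
  list(a_lat = inter$a_lat, r_lat = inter$r_lat, b_lat = b,
       a_long = inter$a_long, b_long = inter$b_long,
       r_long = inter$r_long)
}

#' Total lattice energy with additive decomposition
#'
#' Sums bending, intra-dimer spring, inter-dimer longitudinal and lateral
#' bond energies over the whole state.
#'
#' @param state an `mt_state`.
#' @param mech a [mechanical_params()] bundle.
#' @param inter an [interaction_params()] bundle.
#' @param nuc_effect optional [nucleotide_effect()]; when given, per-dimer
#'   nucleotide states select `b_lat` and `B`.
#' @return list with `total` and the per-class components (kcal/mol).
#' @examples
#' total_energy(mt_state(6, "GTP"), mechanical_params(),
#'              interaction_params())$total
#' @export
total_energy <- function(state, mech = mechanical_params(),
                         inter = interaction_params(), nuc_effect = NULL) {
  if (sum(vapply(state$pf, nrow, 1L)) == 0)
    return(list(total = 0, bend = 0, spring = 0, longitudinal = 0,
                lateral = 0))
  e <- total_energy_cpp(state$pf, state$nuc, state$mobile_from,
                        .geom_list(state, mech),
                        .mech_list(mech, nuc_effect),
                        .inter_list(inter, nuc_effect))
  e[c("total", "bend", "spring", "longitudinal", "lateral")]
}

#' Convert a simulated state to protofilament traces
#'
#' Projects each PF into its radial plane (which is the identity for this
#' planar model) and returns one trace per PF, ordered minus-to-plus, for
#' the tip-shape analysis operations.
#'
#' @param state an `mt_state`.
#' @param mt_id identifier stored in each trace.
#' @return list of [pf_trace()] objects.
#' @export
mt_state_traces <- function(state, mt_id = 1L) {
  lapply(seq_len(state$n_pf), function(n) {
    m <- state$pf[[n]]
    pf_trace(z = m[, "z"], x = m[, "x"], mt_id = mt_id,
             pf_index = n - 1L)
  })
}
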