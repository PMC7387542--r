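# Parameter bundles.  Each constructor validates its invariants and returns
# a classed list so downstream code can dispatch/print sensibly.

.check <- function(ok, msg) if (!isTRUE(ok)) stop(msg, call. = FALSE)

#' Mechanical parameters of tubulin and its lattice
#'
#' Houses the Hookean intra-dimer spring stiffness, the harmonic bending
#' stiffness of the protofilament (PF) hinge, the equilibrium inter-monomer
#' bending angle (0.2 rad, matching the intrinsic curvature of tubulin
#' dimers), the tubulin sphere radius and the steric repulsion stiffness
#' used for Dam1/obstacle contacts.
#'
#' @param k_intra intra-dimer longitudinal spring stiffness,
#'   kcal mol^-1 nm^-2.
#' @param B PF bending stiffness, kcal mol^-1 rad^-2.
#' @param theta0 equilibrium bending angle between adjacent monomers, rad.
#' @param r_tub tubulin sphere radius, nm.
#' @param k_rep repulsion stiffness for tubulin vs Dam1/obstacle spheres,
#'   kcal mol^-1 nm^-2.
#' @return an object of class `mechanical_params`.
#' @examples
#' mechanical_params()
#' mechanical_params(B = 35)
#' @export
mechanical_params <- function(k_intra = 310, B = 174, theta0 = 0.2,
                              r_tub = 2, k_rep = 100) {
  .check(k_intra >= 0, "k_intra must be >= 0")
  .check(all(B >= 0), "B must be >= 0")
  .check(theta0 >= 0 && theta0 < pi / 2, "theta0 must be in [0, pi/2)")
  .check(r_tub > 0, "r_tub must be > 0")
  .check(k_rep >= 0, "k_rep must be >= 0")
  structure(list(k_intra = k_intra, B = B, theta0 = theta0,
                 r_tub = r_tub, k_rep = k_rep),
            class = "mechanical_params")
}

#' Breakable tubulin-tubulin bond parameters
#'
#' Lateral and longitudinal inter-dimer contacts are modelled as breakable
#' bonds `E(r) = 2 a (r/w)^2 exp(-r/w) - b exp(-r^2/w^2)`: a potential well
#' of depth `b` at contact separated from the unbound state by an
#' activation barrier whose height scales with `a` and whose position and
#' steepness are set by the width `w`.
#'
#' The widths and the longitudinal barrier are not constrained by directly
#' measured quantities; the defaults here are artifact defaults chosen to
#' give protein-contact-scale bond ranges (fractions of a nm), and are
#' config-exposed.  `b_long` defaults to the value selected by the staged
#' calibration shipped with the package.
#'
#' @param a_lat,a_long activation-barrier scale, kcal/mol.
#' @param b_lat,b_long bond well depth, kcal/mol.
#' @param r_lat,r_long bond width / barrier steepness length, nm.
#' @return an object of class `interaction_params`.
#' @examples
#' interaction_params(a_lat = 6.3, b_lat = 8)
#' @export
interaction_params <- function(a_lat = 6.3, b_lat = 8, r_lat = 1.0,
                               a_long = 2.1, b_long = 7.0, r_long = 0.5) {
  .check(r_lat > 0 && r_long > 0, "bond widths must be > 0")
  .check(b_lat >= 0 && b_long >= 0, "bond depths must be >= 0")
  .check(a_lat >= 0 && a_long >= 0, "barrier scales must be >= 0")
  structure(list(a_lat = a_lat, b_lat = b_lat, r_lat = r_lat,
                 a_long = a_long, b_long = b_long, r_long = r_long),
            class = "interaction_params")
}

#' Dam1 ring geometry and linker potential
#'
#' The ring is 13 spherical subunits, one per PF plane, each tethered to
#' the nearest tubulin by a flexible linker whose attraction is a flat well
#' of depth `E_depth` that rises harmonically between `l0` and `l_max` and
#' vanishes beyond `l_max` (continuity at `l_max` fixes
#' `E_depth = k_linker (l_max - l0)^2 / 2`).
#'
#' @param R_dam1 Dam1 subunit radius, nm.
#' @param l0 equilibrium linker length, nm.
#' @param l_max maximal linker length, nm.
#' @param k_linker linker stiffness, kcal mol^-1 nm^-2.
#' @return an object of class `ring_params` with derived `E_depth`.
#' @examples
#' ring_params()$E_depth
#' @export
ring_params <- function(R_dam1 = 3, l0 = 5, l_max = 6, k_linker = 0.01) {
  .check(R_dam1 > 0, "R_dam1 must be > 0")
  .check(l0 < l_max, "l0 must be < l_max")
  .check(k_linker >= 0, "k_linker must be >= 0")
  structure(list(R_dam1 = R_dam1, l0 = l0, l_max = l_max,
                 k_linker = k_linker,
                 E_depth = 0.5 * k_linker * (l_max - l0)^2),
            class = "ring_params")
}

#' Kinetic Monte-Carlo layer parameters
#'
#' The slow layer adds GTP dimers to PF tips with per-PF probability
#' `P = k_on * c_tub * t_kin` every `t_kin`, hydrolyses GTP dimers with
#' rate `k_hydr`, and removes terminal oligomers whose connecting
#' longitudinal bond energy magnitude has dropped below
#' `detach_threshold * kBT` while stretched past the barrier.
#'
#' `time_compression` (kappa) shrinks the kinetic clock relative to the
#' Brownian clock for desk-scale runs of addition-limited regimes: the
#' kinetic interval becomes `t_kin / kappa` of simulated time while the
#' per-interval probabilities are unchanged, and recorded times are
#' re-expanded to physical seconds.  It is only valid when mechanical
#' relaxation (PF zipping at >= 1e5 /s) remains much faster than the
#' compressed event rate; leave it at 1 for shortening runs.
#'
#' @param k_on tubulin association rate constant per PF, uM^-1 s^-1.
#' @param c_tub free tubulin concentration, uM.
#' @param t_kin kinetic layer interval, s.
#' @param k_hydr GTP hydrolysis rate constant, s^-1.
#' @param detach_threshold detachment energy threshold, kBT units.
#' @param detach_interval how often the detachment scan runs, s.
#' @param window_dimers mobile dimers per PF behind the tip; deeper layers
#'   are held rigid as the lattice boundary.
#' @param time_compression kinetic-clock compression factor (>= 1).
#' @return an object of class `kinetic_params`.
#' @examples
#' kinetic_params(k_on = 0.26, c_tub = 10)
#' @export
kinetic_params <- function(k_on = 0.26, c_tub = 10, t_kin = 0.013,
                           k_hydr = 0.24, detach_threshold = 0.1,
                           detach_interval = 1e-7, window_dimers = 20,
                           time_compression = 1) {
  .check(all(c(k_on, c_tub, t_kin, k_hydr, detach_threshold) >= 0),
         "kinetic parameters must be >= 0")
  .check(time_compression >= 1, "time_compression must be >= 1")
  p <- k_on * c_tub * t_kin
  .check(p <= 1, sprintf(
    "addition probability k_on*c_tub*t_kin = %.3f exceeds 1", p))
  structure(list(k_on = k_on, c_tub = c_tub, t_kin = t_kin,
                 k_hydr = k_hydr, detach_threshold = detach_threshold,
                 detach_interval = detach_interval,
                 window_dimers = as.integer(window_dimers),
                 time_compression = time_compression),
            class = "kinetic_params")
}

#' Nucleotide effect of GTP hydrolysis
#'
#' Hydrolysis destabilises the lattice in one of two ways: by weakening
#' the lateral bond (`lateral-bond` mode; bending stiffness shared) or by
#' stiffening the PF hinge (`bending-stiffness` mode; lateral bond
#' shared).
#'
#' @param mode `"lateral-bond"` or `"bending-stiffness"`.
#' @param b_lat_gtp,b_lat_gdp lateral bond depth per nucleotide, kcal/mol.
#' @param B_gtp,B_gdp bending stiffness per nucleotide,
#'   kcal mol^-1 rad^-2.
#' @return an object of class `nucleotide_effect`.
#' @examples
#' nucleotide_effect("lateral-bond")
#' nucleotide_effect("bending-stiffness")
#' @export
nucleotide_effect <- function(mode = c("lateral-bond", "bending-stiffness"),
                              b_lat_gtp = NULL, b_lat_gdp = NULL,
                              B_gtp = NULL, B_gdp = NULL) {
  mode <- match.arg(mode)
  if (mode == "lateral-bond") {
    b_lat_gtp <- b_lat_gtp %||% 8
    b_lat_gdp <- b_lat_gdp %||% 4.7
    B_gtp <- B_gtp %||% 174
    B_gdp <- B_gdp %||% B_gtp
    .check(isTRUE(all.equal(B_gtp, B_gdp)),
           "in lateral-bond mode B_gtp must equal B_gdp")
  } else {
    b_lat_gtp <- b_lat_gtp %||% 4.7
    b_lat_gdp <- b_lat_gdp %||% b_lat_gtp
    B_gtp <- B_gtp %||% 78
    B_gdp <- B_gdp %||% 174
    .check(isTRUE(all.equal(b_lat_gtp, b_lat_gdp)),
           "in bending-stiffness mode b_lat_gtp must equal b_lat_gdp")
  }
  .check(all(c(b_lat_gtp, b_lat_gdp) >= 0), "b_lat must be >= 0")
  .check(all(c(B_gtp, B_gdp) >= 0), "B must be >= 0")
  structure(list(mode = mode, b_lat_gtp = b_lat_gtp, b_lat_gdp = b_lat_gdp,
                 B_gtp = B_gtp, B_gdp = B_gdp),
            class = "nucleotide_effect")
}

#' Simulation control parameters
#'
#' @param dt Brownian integration step, s.  The stiffest interaction sets
#'   an accuracy bound; construction refuses dt above
#'   `gamma_q / (5 k_eff_max)` when paired with parameter bundles (checked
#'   at run time).
#' @param temperature temperature, K.
#' @param eta solvent viscosity, Pa s.
#' @param duration simulated (physical) time, s.
#' @param record_stride steps between coarse trace rows.
#' @param snap_stride steps between full-coordinate snapshots (0 = none).
#' @param seed RNG seed (integer; all kernel randomness derives from it).
#' @param max_disp instability guard: largest tolerated per-step
#'   displacement, nm.
#' @return an object of class `sim_config`.
#' @examples
#' sim_config(duration = 1e-5)
#' @export
sim_config <- function(dt = 2e-12, temperature = 310, eta = 1e-3,
                       duration = 1e-4, record_stride = 1000,
                       snap_stride = 0, seed = 1, max_disp = 10) {
  .check(dt > 0, "dt must be > 0")
  .check(duration >= dt, "duration must be >= dt")
  .check(temperature >= 0, "temperature must be >= 0")
  .check(eta > 0, "eta must be > 0")
  structure(list(dt = dt, temperature = temperature, eta = eta,
                 duration = duration,
                 record_stride = as.integer(record_stride),
                 snap_stride = as.integer(snap_stride),
                 seed = seed, max_disp = max_disp),
            class = "sim_config")
}

#' Straightening-event scoring thresholds
#'
#' A PF hinge is scored "curved" above `theta_curved` and "straight" below
#' `theta_straight`; a straightening event is a complete passage from the
#' curved to the straight state (two-threshold hysteresis, so dither at a
#' single threshold cannot inflate counts).
#'
#' @param theta_curved curved threshold, rad.
#' @param theta_straight straight threshold, rad.
#' @param monitored_index monomer whose hinge is scored (1-based; default
#'   3 = lowest nonrestrained monomer of a chain with a fixed bottom
#'   dimer).
#' @return an object of class `straightening_criteria`.
#' @examples
#' straightening_criteria()
#' @export
straightening_criteria <- function(theta_curved = 0.15,
                                   theta_straight = 0.05,
                                   monitored_index = 3) {
  .check(theta_straight < theta_curved,
         "theta_straight must be < theta_curved")
  structure(list(theta_curved = theta_curved,
                 theta_straight = theta_straight,
                 monitored_index = as.integer(monitored_index)),
            class = "straightening_criteria")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.mechanical_params <- function(x, ...) {
  cat("Mechanical parameters: k_intra =", x$k_intra,
      "kcal/mol/nm^2, B =", x$B, "kcal/mol/rad^2, theta0 =", x$theta0,
      "rad, r_tub =", x$r_tub, "nm, k_rep =", x$k_rep, "\n")
  invisible(x)
}

#' @export
print.interaction_params <- function(x, ...) {
  cat(sprintf(
    "Breakable bonds: lateral a=%.2f b=%.2f w=%.2f | longitudinal a=%.2f b=%.2f w=%.2f (kcal/mol, nm)\n",
    x$a_lat, x$b_lat, x$r_lat, x$a_long, x$b_long, x$r_long))
  invisible(x)
}
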