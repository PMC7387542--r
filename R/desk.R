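# Desk-scale operating points.
#
# At experimentally calibrated bond depths, lattice events (lateral
# unzipping at high activation barriers, longitudinal bond rupture) are
# thermally activated with ~1e9 or more Brownian steps per event, so
# quantitative lattice observables belong to long parallel computations.
# The operating points below were selected with the package's own staged
# calibration run at reduced bond depths: they preserve the model's
# structure (intrinsically curved PFs, breakable bonds with activation
# barriers, nucleotide-dependent lateral strength) while placing tip
# dynamics on the microsecond timescales a single CPU can sample.  The
# methods vignette discusses what does and does not carry over.

#' Desk-scale parameter sets
#'
#' Named parameter bundles for single-workstation experiments:
#'
#' * `"growth"` - GTP-like lattice (strong lateral bonds) with the
#'   kinetic-clock compression preset for addition-limited growth.
#' * `"shortening"` - GDP-like lattice in the low lateral-barrier regime
#'   (`a_lat = 2.1`): rapid peeling with 30-60 nm curls.
#' * `"shortening_hi_barrier"` - GDP-like lattice at a raised lateral
#'   barrier (`a_lat = 4.2`), with the lateral bond depth selected per
#'   barrier height so that shortening speeds are comparable (the
#'   protocol used for force-velocity families).  At `a_lat = 6.3` the
#'   unzipping time per bond exceeds what a workstation can sample.
#'
#' @param regime which operating point.
#' @param c_tub free tubulin concentration for growth regimes, uM.
#' @param compression kinetic-clock compression for growth regimes.
#' @return list with `mech`, `inter`, `kin` bundles and a suggested
#'   `dt` (s) within the accuracy bound for that parameter set.
#' @export
desk_params <- function(regime = c("growth", "shortening",
                                   "shortening_hi_barrier"),
                        c_tub = 10, compression = 2e4) {
  regime <- match.arg(regime)
  mech <- mechanical_params(B = 174)
  if (regime == "growth") {
    inter <- interaction_params(a_lat = 6.3, b_lat = 8, r_lat = 1.0,
                                a_long = 2.1, b_long = 7.0, r_long = 0.5)
    kin <- kinetic_params(k_on = 0.26, c_tub = c_tub, k_hydr = 0,
                          window_dimers = 10,
                          time_compression = compression)
  } else if (regime == "shortening") {
    inter <- interaction_params(a_lat = 2.1, b_lat = 2.0, r_lat = 1.0,
                                a_long = 2.1, b_long = 6.0, r_long = 0.5)
    kin <- kinetic_params(c_tub = 0, k_hydr = 0, window_dimers = 16)
  } else {
    inter <- interaction_params(a_lat = 4.2, b_lat = 1.2, r_lat = 1.0,
                                a_long = 2.1, b_long = 6.0, r_long = 0.5)
    kin <- kinetic_params(c_tub = 0, k_hydr = 0, window_dimers = 16)
  }
  list(mech = mech, inter = inter, kin = kin, dt = 3.2e-12)
}
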