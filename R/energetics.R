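# Pure energy functions shared by every simulation, with analytic
# gradients.  These are the reference implementations; the compiled kernel
# carries identical formulas and is cross-checked against them in the test
# suite via the total-energy decomposition.

#' Intra-dimer longitudinal spring energy
#'
#' `U(r) = k/2 r^2` for the Hookean spring connecting the two monomers of
#' a tubulin dimer through their longitudinal interaction sites.
#'
#' @param d site-site distance, nm (>= 0).
#' @param params a [mechanical_params()] bundle.
#' @return energy in kcal/mol.
#' @examples
#' spring_energy(0.1, mechanical_params()) # 1.55
#' @export
spring_energy <- function(d, params = mechanical_params()) {
  if (any(d < 0)) stop("spring extension d must be >= 0", call. = FALSE)
  0.5 * params$k_intra * d^2
}

#' @rdname spring_energy
#' @export
spring_energy_grad <- function(d, params = mechanical_params()) {
  if (any(d < 0)) stop("spring extension d must be >= 0", call. = FALSE)
  params$k_intra * d
}

#' Protofilament bending energy
#'
#' `W(theta) = B/2 (theta - theta0)^2`: the harmonic penalty for deviating
#' from the intrinsically curved equilibrium angle between adjacent
#' monomers.
#'
#' @param theta bending angle, rad.
#' @param params a [mechanical_params()] bundle.
#' @return energy in kcal/mol.
#' @examples
#' bending_energy(0.3, mechanical_params(B = 174)) # 0.87
#' @export
bending_energy <- function(theta, params = mechanical_params()) {
  0.5 * params$B * (theta - params$theta0)^2
}

#' @rdname bending_energy
#' @export
bending_energy_grad <- function(theta, params = mechanical_params()) {
  params$B * (theta - params$theta0)
}

#' Steric repulsion between tubulin and a Dam1 subunit or obstacle
#'
#' `rho(d) = k_rep (R + r - d)^2` inside contact and 0 outside.  Note the
#' deliberate absence of a 1/2 prefactor: the potential is implemented
#' exactly as the model defines it, which differs from the spring
#' convention.
#'
#' @param d centre-centre distance, nm (>= 0).
#' @param R radius of the partner sphere, nm.
#' @param r tubulin radius, nm.
#' @param k_rep repulsion stiffness, kcal mol^-1 nm^-2.
#' @return energy in kcal/mol.
#' @examples
#' repulsion_energy(4.9, R = 3, r = 2) # 1.0
#' @export
repulsion_energy <- function(d, R = 3, r = 2, k_rep = 100) {
  if (any(d < 0)) stop("distance d must be >= 0", call. = FALSE)
  ifelse(d < R + r, k_rep * (R + r - d)^2, 0)
}

#' @rdname repulsion_energy
#' @export
repulsion_energy_grad <- function(d, R = 3, r = 2, k_rep = 100) {
  if (any(d < 0)) stop("distance d must be >= 0", call. = FALSE)
  ifelse(d < R + r, -2 * k_rep * (R + r - d), 0)
}

#' Breakable bond with an activation barrier
#'
#' `E(r) = 2 a (r/w)^2 exp(-r/w) - b exp(-r^2/w^2)`: a well of depth
#' exactly `b` at contact (r = 0), an interior activation barrier whose
#' height scales with `a` (for `b = 0` the maximum is `8 exp(-2) a` at
#' `2 w`), and decay to 0 as r grows.  The same functional form
#' describes lateral and inter-dimer longitudinal tubulin contacts.
#'
#' @param d site-site distance, nm (>= 0).
#' @param a activation-barrier scale, kcal/mol.
#' @param b well depth, kcal/mol.
#' @param w bond width, nm (> 0).
#' @return energy in kcal/mol.
#' @examples
#' bond_energy(0, a = 6.3, b = 8)    # -8: well depth at contact
#' bond_energy(0.6, a = 6.3, b = 0)  # barrier region
#' @export
bond_energy <- function(d, a, b, w = 0.3) {
  if (any(d < 0)) stop("distance d must be >= 0", call. = FALSE)
  if (w <= 0) stop("bond width w must be > 0", call. = FALSE)
  p <- d / w
  2 * a * p^2 * exp(-p) - b * exp(-p^2)
}

#' @rdname bond_energy
#' @export
bond_energy_grad <- function(d, a, b, w = 0.3) {
  if (any(d < 0)) stop("distance d must be >= 0", call. = FALSE)
  if (w <= 0) stop("bond width w must be > 0", call. = FALSE)
  p <- d / w
  (2 * a / w) * p * (2 - p) * exp(-p) + (2 * b / w) * p * exp(-p^2)
}

#' Height and position of the activation barrier of a breakable bond
#'
#' Located numerically by a dense grid with local refinement; used for
#' reporting and calibration diagnostics.
#'
#' @inheritParams bond_energy
#' @return list with `height` (kcal/mol, relative to zero) and `at` (nm).
#' @export
bond_barrier <- function(a, b, w = 0.3) {
  grid <- seq(1e-4, 8 * w, length.out = 2000)
  e <- bond_energy(grid, a, b, w)
  i <- which.max(e)
  lo <- grid[max(1, i - 2)]
  hi <- grid[min(length(grid), i + 2)]
  op <- stats::optimize(function(r) bond_energy(r, a, b, w),
                        c(lo, hi), maximum = TRUE)
  list(height = op$objective, at = op$maximum)
}

#' Dam1 linker attraction
#'
#' Piecewise potential for the flexible C-terminal linker tethering a
#' Dam1 subunit to the nearest tubulin: a flat well of depth `E_depth`
#' up to the equilibrium linker length `l0`, a harmonic rise between `l0`
#' and `l_max`, and zero beyond `l_max`.  `E_depth` is defined so the
#' potential is continuous at `l_max`.
#'
#' @param d centre-centre distance, nm (>= 0).
#' @param params a [ring_params()] bundle.
#' @param r_tub tubulin radius, nm (flat-well inner edge is the contact
#'   distance `R_dam1 + r_tub`; inside that, steric repulsion takes over).
#' @return energy in kcal/mol.
#' @examples
#' linker_energy(5.5, ring_params())
#' @export
linker_energy <- function(d, params = ring_params(), r_tub = 2) {
  if (any(d < 0)) stop("distance d must be >= 0", call. = FALSE)
  E <- params$E_depth
  out <- numeric(length(d))
  out[d <= params$l_max] <- -E
  mid <- d >= params$l0 & d <= params$l_max
  out[mid] <- -E + 0.5 * params$k_linker * (params$l0 - d[mid])^2
  out[d > params$l_max] <- 0
  out
}

#' @rdname linker_energy
#' @export
linker_energy_grad <- function(d, params = ring_params(), r_tub = 2) {
  if (any(d < 0)) stop("distance d must be >= 0", call. = FALSE)
  out <- numeric(length(d))
  mid <- d >= params$l0 & d <= params$l_max
  out[mid] <- params$k_linker * (d[mid] - params$l0)
  out
}
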