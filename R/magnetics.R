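# Magnetic model: low-field magnetization, the chain equivalent-sphere
# model, the magnetic pulling force, and the gradient-limit input scaling.
#
# The swarm is advected as independent particles sharing one chain model: a
# rod of n particles of diameter d, represented in the force law by a sphere
# of equal volume (diameter D_eq). Magnetization per unit mass (emu/g, i.e.
# A m^2/kg) is converted to volumetric magnetization by multiplying with the
# material density; the commanded gradient (mT/m) is treated as a flux
# density gradient, so the vacuum permeability never appears numerically.

#' Low-field magnetization of magnetite particles
#'
#' Empirical unsaturated-regime law `M_m = 1 + 19 (10 B)^0.16` with `B` in
#' mT, anchored so that a 3 mT field gives 33.74 emu/g.
#'
#' @param B Magnetic flux density, mT. Must be positive.
#' @return Magnetization per unit mass, emu/g (numerically A m^2/kg).
#' @examples
#' magnetization(3)  # 33.74
#' @export
magnetization <- function(B) {
  if (any(B <= 0)) stop("magnetization: B must be > 0 (mT)")
  1 + 19 * (10 * B)^0.16
}

#' Equivalent-sphere diameter of a particle chain
#'
#' A chain of `n` particles of diameter `d` is modelled as a cylinder of
#' diameter `d` and height `n d`; the diameter of the volume-equivalent
#' sphere used by the force law is `D_eq = d (3 n)^(1/3)`.
#'
#' @param d Individual particle diameter, m.
#' @param n Chain length, particles.
#' @return Equivalent diameter, m.
#' @examples
#' chain_equivalent_diameter(75e-9, 12000)  # 2.48e-6
#' @export
chain_equivalent_diameter <- function(d, n) {
  if (any(d <= 0)) stop("chain_equivalent_diameter: d must be > 0")
  if (any(n < 1)) stop("chain_equivalent_diameter: n must be >= 1")
  d * (3 * n)^(1 / 3)
}

#' Equivalent sphere volume
#'
#' @param D_eq Equivalent diameter, m.
#' @return Volume `(4/3) pi (D_eq/2)^3`, m^3.
#' @examples
#' equivalent_volume(chain_equivalent_diameter(75e-9, 12000))  # 7.95e-18
#' @export
equivalent_volume <- function(D_eq) {
  if (any(D_eq <= 0)) stop("equivalent_volume: D_eq must be > 0")
  (4 / 3) * pi * (D_eq / 2)^3
}

#' Field-dependent chain length
#'
#' The chain length grows with the applied field. The packaged default rule
#' is linear through the recorded anchor (12000 particles at 3 mT),
#' `n(B) = round(4000 B)`, clamped to `[1, n_max]`. The rule is a pluggable
#' convention, not a measured law: pass any function of `B` via `rule`.
#'
#' @param B Magnetic flux density, mT.
#' @param n_max Upper clamp for the chain length. Default 40000.
#' @param rule Optional replacement rule, a function of `B` returning a
#'   chain length.
#' @return Integer chain length in `[1, n_max]`.
#' @examples
#' chain_length_for_field(3)  # 12000
#' @export
chain_length_for_field <- function(B, n_max = 40000, rule = NULL) {
  n <- if (is.null(rule)) round(4000 * B) else rule(B)
  as.integer(pmin(pmax(n, 1), n_max))
}

#' Magnetic parameter set
#'
#' Bundles the field, particle and chain parameters and derives the
#' equivalent diameter and volume. Defaults reproduce the reference
#' parameter set: B = 3 mT, d = 75 nm, n = 12000, rho = 4800 kg/m^3,
#' M_m = 33.74 emu/g, D_eq = 2.48e-6 m, V_eq = 7.95e-18 m^3.
#'
#' @param B Magnetic flux density, mT.
#' @param d Individual particle diameter, m.
#' @param n Chain length; defaults to [chain_length_for_field()] at `B`.
#' @param rho Particle density, kg/m^3.
#' @param M_m Magnetization, emu/g; defaults to [magnetization()] at `B`.
#' @param mu0 Vacuum permeability, N/A^2 (carried for completeness; the
#'   force law works with the flux-density gradient directly).
#' @return An object of class `magnetic_params`.
#' @export
magnetic_params <- function(B = 3, d = 75e-9, n = NULL, rho = 4800,
                            M_m = NULL, mu0 = 4 * pi * 1e-7) {
  if (B <= 0 || d <= 0 || rho <= 0) stop("magnetic_params: B, d, rho must be > 0")
  if (is.null(n)) n <- chain_length_for_field(B)
  if (is.null(M_m)) M_m <- magnetization(B)
  D_eq <- chain_equivalent_diameter(d, n)
  structure(list(B = B, M_m = M_m, d = d, n = n, rho = rho, mu0 = mu0,
                 D_eq = D_eq, V_eq = equivalent_volume(D_eq)),
            class = "magnetic_params")
}

#' @export
print.magnetic_params <- function(x, ...) {
  cat("<magnetic_params> B =", x$B, "mT, M_m =", round(x$M_m, 2),
      "emu/g, n =", x$n, "\n  d =", format(x$d), "m, D_eq =",
      format(signif(x$D_eq, 3)), "m, V_eq =", format(signif(x$V_eq, 3)),
      "m^3, rho =", x$rho, "kg/m^3\n")
  invisible(x)
}

#' Cap a raw steering input to the gradient limit
#'
#' The operator (or a scripted policy) supplies a dimensionless 2D input of
#' magnitude at most 1; the commanded gradient is that input scaled by the
#' configured limit, so its magnitude never exceeds the limit. Inputs of
#' magnitude above 1 are renormalized to 1 first.
#'
#' @param raw Length-2 dimensionless input vector.
#' @param limit Gradient limit, mT/m (study range 100-1000; default 500).
#' @return An object of class `gradient_command`: list with `gradient`
#'   (length-2, mT/m) and `limit`.
#' @examples
#' limit_gradient(c(0.6, 0.8), 1000)  # magnitude 1000 mT/m
#' @export
limit_gradient <- function(raw, limit = 500) {
  if (limit <= 0) stop("limit_gradient: limit must be > 0")
  m <- sqrt(sum(raw^2))
  if (m > 1) raw <- raw / m
  structure(list(gradient = raw * limit, limit = limit),
            class = "gradient_command")
}

#' Magnetic force on the equivalent chain sphere
#'
#' `F = V_eq M_m rho grad(B)`, with the commanded gradient converted from
#' mT/m to T/m. The force is parallel to the commanded gradient; at the
#' reference parameters a 1000 mT/m command gives about 1.29e-12 N.
#'
#' @param params A `magnetic_params`.
#' @param cmd A `gradient_command` (or a raw length-2 gradient in mT/m).
#' @return Length-2 force vector, N.
#' @export
magnetic_force <- function(params, cmd) {
  stopifnot(inherits(params, "magnetic_params"))
  grad <- if (inherits(cmd, "gradient_command")) cmd$gradient else cmd
  params$V_eq * params$M_m * params$rho * (grad * 1e-3)
}
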