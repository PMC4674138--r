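#' Anisotropic modified Mooney-Rivlin material parameters
#'
#' Material constants of the modified Mooney-Rivlin strain-energy density
#' used for the coronary vessel wall,
#' \deqn{W = c_1(I_1-3) + c_2(I_2-3) + D_1[\exp(D_2(I_1-3)) - 1] +
#'       \frac{K_1}{2K_2}\{\exp[K_2(I_4-1)^2] - 1\},}
#' where \eqn{I_1, I_2} are the first two invariants of the right
#' Cauchy-Green tensor C and \eqn{I_4 = n_c^T C\, n_c} is the squared
#' stretch along the circumferential unit direction \eqn{n_c}.  The default
#' constants are biaxial-test fits for human coronary arteries.
#'
#' The anisotropic term is normalized so that W = 0 in the reference
#' configuration (C = identity); `printed_form = TRUE` switches to the
#' unnormalized variant \eqn{\frac{K_1}{2K_2}\exp[K_2(I_4-1)^2 - 1]}, which
#' carries a constant energy offset at the identity and is provided for
#' comparison only.
#'
#' @param c1_kPa,c2_kPa,D1_kPa,D2,K1_kPa,K2 material constants (stress-like
#'   constants in kPa, `D2` and `K2` dimensionless).
#' @param isotropic_only drop the anisotropic K-term (the simplified
#'   isotropic form used for plaque components).
#' @param printed_form use the unnormalized anisotropic term (see Details).
#' @return An object of class `material_params`.
#' @examples
#' mp <- material_params()
#' strain_energy(mp, deformation_state(diag(3)))  # 0 at the identity
#' @export
material_params <- function(c1_kPa = -1312.9, c2_kPa = 114.7,
                            D1_kPa = 629.7, D2 = 2.0,
                            K1_kPa = 35.9, K2 = 23.5,
                            isotropic_only = FALSE, printed_form = FALSE) {
  stopifnot(is.finite(c1_kPa), is.finite(c2_kPa), is.finite(D1_kPa))
  if (D2 <= 0) stop("D2 must be positive")
  if (!isotropic_only && K2 <= 0) stop("K2 must be positive when the anisotropic term is active")
  structure(list(c1_kPa = c1_kPa, c2_kPa = c2_kPa, D1_kPa = D1_kPa, D2 = D2,
                 K1_kPa = K1_kPa, K2 = K2,
                 isotropic_only = isotropic_only, printed_form = printed_form),
            class = "material_params")
}

#' Deformation state for the strain-energy model
#'
#' @param C symmetric positive-definite 3 x 3 right Cauchy-Green tensor.
#' @param n_c unit circumferential direction vector (length 3); normalized
#'   on input.
#' @return An object of class `deformation_state`.
#' @export
deformation_state <- function(C, n_c = c(1, 0, 0)) {
  C <- as.matrix(C)
  stopifnot(all(dim(C) == c(3L, 3L)), is.numeric(C), length(n_c) == 3L)
  if (max(abs(C - t(C))) > 1e-8) stop("C must be symmetric")
  ev <- eigen(C, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0) stop("C must be positive-definite (min eigenvalue ", min(ev), ")")
  nrm <- sqrt(sum(n_c^2))
  if (nrm < 1e-12) stop("n_c must be a nonzero direction vector")
  structure(list(C = C, n_c = n_c / nrm), class = "deformation_state")
}

#' Invariants of the right Cauchy-Green tensor
#'
#' @param state a [deformation_state()].
#' @return Named numeric vector `(I1, I2, I4)` with
#'   `I1 = tr(C)`, `I2 = (I1^2 - tr(C C)) / 2`, `I4 = n_c' C n_c`.
#' @export
cg_invariants <- function(state) {
  stopifnot(inherits(state, "deformation_state"))
  C <- state$C
  I1 <- sum(diag(C))
  I2 <- (I1^2 - sum(C * C)) / 2
  I4 <- drop(crossprod(state$n_c, C %*% state$n_c))
  c(I1 = I1, I2 = I2, I4 = I4)
}

# Strain energy from invariants (kPa); shared by the tensor and the
# equibiaxial parameterizations.
.W_inv <- function(p, I1, I2, I4) {
  e1 <- p$D2 * (I1 - 3)
  if (any(e1 > 700)) stop("exponential overflow in the isotropic term: D2*(I1-3) = ", max(e1))
  W <- p$c1_kPa * (I1 - 3) + p$c2_kPa * (I2 - 3) + p$D1_kPa * (exp(e1) - 1)
  if (!p$isotropic_only) {
    e2 <- p$K2 * (I4 - 1)^2
    if (any(e2 > 700)) stop("exponential overflow in the anisotropic term: K2*(I4-1)^2 = ", max(e2))
    W <- W + if (p$printed_form) {
      p$K1_kPa / (2 * p$K2) * exp(e2 - 1)
    } else {
      p$K1_kPa / (2 * p$K2) * (exp(e2) - 1)
    }
  }
  W
}

#' Strain-energy density
#'
#' Evaluates the modified Mooney-Rivlin strain-energy density (kPa) at a
#' deformation state.  See [material_params()] for the functional form.
#'
#' @param params a [material_params()].
#' @param state a [deformation_state()].
#' @return Strain-energy density in kPa.
#' @export
strain_energy <- function(params, state) {
  stopifnot(inherits(params, "material_params"))
  inv <- cg_invariants(state)
  .W_inv(params, inv[["I1"]], inv[["I2"]], inv[["I4"]])
}

# Invariants of the incompressible equibiaxial stretch C = diag(l^2, l^2,
# l^-4), with the circumferential direction in-plane (I4 = l^2).
.equibiaxial_invariants <- function(lambda) {
  list(I1 = 2 * lambda^2 + lambda^-4,
       I2 = lambda^4 + 2 * lambda^-2,
       I4 = lambda^2)
}

#' Strain energy under incompressible equibiaxial stretch
#'
#' @param params a [material_params()].
#' @param lambda in-plane stretch ratio(s), > 0; the deformation is
#'   `C = diag(lambda^2, lambda^2, lambda^-4)` with the circumferential
#'   direction in-plane.
#' @return Strain-energy density in kPa, vectorized over `lambda`.
#' @export
equibiaxial_energy <- function(params, lambda) {
  stopifnot(inherits(params, "material_params"), all(lambda > 0))
  iv <- .equibiaxial_invariants(lambda)
  .W_inv(params, iv$I1, iv$I2, iv$I4)
}

#' Membrane Cauchy stress under incompressible equibiaxial stretch
#'
#' Mean in-plane Cauchy stress for the incompressible equibiaxial
#' deformation `(lambda, lambda, lambda^-2)`, obtained by analytic
#' differentiation of the strain-energy density:
#' \eqn{\sigma = \frac{\lambda}{2}\,\frac{dW}{d\lambda}}.
#'
#' @inheritParams equibiaxial_energy
#' @return Membrane stress in kPa, vectorized over `lambda`; zero at
#'   `lambda = 1`.
#' @export
equibiaxial_stress <- function(params, lambda) {
  stopifnot(inherits(params, "material_params"), all(lambda > 0))
  p <- params
  iv <- .equibiaxial_invariants(lambda)
  e1 <- p$D2 * (iv$I1 - 3)
  if (any(e1 > 700)) stop("exponential overflow at stretch ", max(lambda))
  dI1 <- 4 * lambda - 4 * lambda^-5
  dI2 <- 4 * lambda^3 - 4 * lambda^-3
  dI4 <- 2 * lambda
  dWdI1 <- p$c1_kPa + p$D1_kPa * p$D2 * exp(e1)
  dWdI2 <- p$c2_kPa
  dWdlam <- dWdI1 * dI1 + dWdI2 * dI2
  if (!p$isotropic_only) {
    e2 <- p$K2 * (iv$I4 - 1)^2
    if (any(e2 > 700)) stop("exponential overflow at stretch ", max(lambda))
    off <- if (p$printed_form) -1 else 0
    dWdlam <- dWdlam + p$K1_kPa * (iv$I4 - 1) * exp(e2 + off) * dI4
  }
  lambda / 2 * dWdlam
}

#' Invert the equibiaxial stress response to a strain
#'
#' Finds the Green-Lagrange strain \eqn{E = (\lambda^2 - 1)/2} at which the
#' equibiaxial membrane stress equals a target stress, by monotone
#' interpolation of the stress-stretch response on a dense grid.  Strains
#' are clipped to `[0, max_strain]`; non-positive target stresses map to 0.
#'
#' @param params a [material_params()].
#' @param stress_kPa target membrane stress(es) in kPa.
#' @param max_strain clip limit for the returned strain (default 0.5).
#' @return Green-Lagrange strain(s), dimensionless, in `[0, max_strain]`.
#' @export
equibiaxial_strain_from_stress <- function(params, stress_kPa, max_strain = 0.5) {
  stopifnot(inherits(params, "material_params"), max_strain > 0)
  lam_max <- sqrt(2 * max_strain + 1)
  lam <- 1 + (lam_max - 1) * seq(0, 1, length.out = 600L)^1.5
  sig <- equibiaxial_stress(params, lam)
  if (any(diff(sig) <= 0))
    stop("equibiaxial response is not strictly increasing on [1, ", round(lam_max, 3),
         "]; cannot invert for these material constants")
  strain <- (lam^2 - 1) / 2
  out <- stats::approx(x = sig, y = strain, xout = pmax(stress_kPa, 0),
                       rule = 2, ties = "ordered")$y
  pmin(pmax(out, 0), max_strain)
}
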