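#' Loss-factor models
#'
#' Material damping enters the model through a dimensionless loss factor
#' eta, the ratio of loss to storage modulus. Two laws are supported:
#'
#' * `loss_constant(eta0)` — eta is frequency-independent (used for the
#'   cranial bone, eta = 0.01);
#' * `loss_linear(eta_ref, f_ref)` — eta grows linearly with ordinary
#'   frequency, `eta(f) = (eta_ref / f_ref) * f` (used for the
#'   polyurethane lining, calibrated to eta = 0.1 at 1 kHz, hence 0.01 at
#'   100 Hz and 1 at 10 kHz).
#'
#' The linear law is parameterised on ordinary frequency f in Hz; its slope
#' per Hz is `alpha_f = eta_ref / f_ref`.
#'
#' @param eta0 constant loss factor, >= 0.
#' @param eta_ref loss factor at the calibration frequency.
#' @param f_ref calibration frequency in Hz.
#' @param alpha_f slope per Hz; alternative to `eta_ref`/`f_ref`.
#' @return an object of class `loss_model`.
#' @export
loss_constant <- function(eta0) {
  if (eta0 < 0) stop("eta0 must be >= 0")
  structure(list(kind = "constant", eta0 = eta0), class = "loss_model")
}

#' @rdname loss_constant
#' @export
loss_linear <- function(eta_ref = NULL, f_ref = NULL, alpha_f = NULL) {
  if (is.null(alpha_f)) {
    if (is.null(eta_ref) || is.null(f_ref))
      stop("give either alpha_f or both eta_ref and f_ref")
    if (f_ref <= 0) stop("f_ref must be positive")
    alpha_f <- eta_ref / f_ref
  }
  if (alpha_f < 0) stop("alpha_f must be >= 0")
  structure(list(kind = "linear_in_f", alpha_f = alpha_f),
            class = "loss_model")
}

#' Evaluate a loss model
#'
#' @param loss a [loss_constant()] or [loss_linear()] model.
#' @param f frequency in Hz (vectorised); must be positive.
#' @return loss factor(s), dimensionless.
#' @examples
#' loss_factor(loss_linear(eta_ref = 0.1, f_ref = 1000), c(100, 1000, 10000))
#' @export
loss_factor <- function(loss, f) {
  stopifnot(inherits(loss, "loss_model"))
  if (any(f <= 0)) stop("frequency must be positive")
  switch(loss$kind,
         constant = rep(loss$eta0, length(f)),
         linear_in_f = loss$alpha_f * f,
         stop("unknown loss model kind '", loss$kind, "'"))
}

#' Isotropic viscoelastic material
#'
#' A material is described by its storage Young's modulus `E1` (Pa, taken
#' frequency-independent), Poisson ratio `nu`, density `rho` (kg/m^3) and a
#' loss model. The complex Young's modulus at frequency f is
#' `E(f) = E1 * (1 + 1i * eta(f))`: the imaginary (loss) part
#' `E2 = E1 * eta` carries all damping.
#'
#' @param E1 storage modulus, Pa (> 0).
#' @param nu Poisson ratio, in `[0, 0.5)`.
#' @param rho density, kg/m^3 (> 0).
#' @param loss a [loss_constant()] or [loss_linear()] model.
#' @return an object of class `material`.
#' @export
material <- function(E1, nu, rho, loss = loss_constant(0)) {
  if (E1 <= 0) stop("E1 must be positive")
  if (nu < 0 || nu >= 0.5) stop("nu must lie in [0, 0.5)")
  if (rho <= 0) stop("rho must be positive")
  stopifnot(inherits(loss, "loss_model"))
  structure(list(E1 = E1, nu = nu, rho = rho, loss = loss),
            class = "material")
}

#' Complex Young's modulus at a frequency
#'
#' @param mat a [material()].
#' @param f frequency in Hz (vectorised, positive).
#' @return complex modulus `E1 * (1 + 1i * eta(f))` in Pa; the phase angle
#'   equals `atan(eta(f))`.
#' @examples
#' pu <- material(1e6, 0.33, 997.40, loss_linear(eta_ref = 0.1, f_ref = 1000))
#' complex_modulus(pu, 100) # 1e6 + 1e4i
#' @export
complex_modulus <- function(mat, f) {
  stopifnot(inherits(mat, "material"))
  mat$E1 * (1 + 1i * loss_factor(mat$loss, f))
}

#' Isotropic constitutive matrix (Voigt notation)
#'
#' The 6x6 elasticity matrix D relating stress to strain in Voigt order
#' (exx, eyy, ezz, gyz, gxz, gxy) with engineering shear strains:
#' normal diagonal `lambda + 2 mu`, normal coupling `lambda`, shear
#' diagonal `mu`, with the Lame parameters
#' `lambda = E nu / ((1 + nu)(1 - 2 nu))` and `mu = E / (2 (1 + nu))`.
#' A complex E scales every entry identically, so
#' `D(E1 (1 + 1i eta)) = (1 + 1i eta) D(E1)`.
#'
#' @param E Young's modulus, Pa; may be complex.
#' @param nu Poisson ratio in `[0, 0.5)`.
#' @return 6x6 (possibly complex) symmetric matrix, Pa.
#' @export
constitutive_matrix <- function(E, nu) {
  if (nu < 0 || nu >= 0.5)
    stop("nu must lie in [0, 0.5): the incompressible limit is singular")
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(if (is.complex(E)) 0i else 0, 6L, 6L)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

#' Named material presets
#'
#' `"stenfelt2002_dry_skull"` reproduces the dry-skull preparation used in
#' the classic bone-conduction impedance experiments: homogeneous cranial
#' bone (E1 = 7.3 GPa, nu = 0.3, rho = 870.23 kg/m^3, constant eta = 0.01)
#' lined with poured polyurethane (E1 = 1 MPa, nu = 0.33,
#' rho = 997.40 kg/m^3, eta linear in frequency, 0.1 at 1 kHz).
#'
#' @param name preset name.
#' @return a `material_set`: named list of [material()] objects, one per
#'   mesh region.
#' @export
material_preset <- function(name = "stenfelt2002_dry_skull") {
  if (!identical(name, "stenfelt2002_dry_skull"))
    stop("unknown preset '", name, "'")
  material_set(
    bone = material(7.3e9, 0.30, 870.23, loss_constant(0.01)),
    polyurethane = material(1e6, 0.33, 997.40,
                            loss_linear(eta_ref = 0.1, f_ref = 1000)))
}

#' Bundle materials by region name
#'
#' @param ... named [material()] objects, one per mesh region.
#' @return a named list of class `material_set`.
#' @export
material_set <- function(...) {
  mats <- list(...)
  if (length(mats) == 1L && is.list(mats[[1L]]) &&
      !inherits(mats[[1L]], "material"))
    mats <- mats[[1L]]
  if (is.null(names(mats)) || any(names(mats) == ""))
    stop("every material must be named by its region")
  for (m in mats) stopifnot(inherits(m, "material"))
  structure(mats, class = "material_set")
}
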