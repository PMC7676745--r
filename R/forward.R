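# Forward-model layer: the stress map sigma_vm_max(t, alpha, beta) the
# risk indices integrate over. Any callable honouring the contract
# (strictly positive finite stress in kPa from a wall-parameter triple)
# can be plugged in; the packaged desk-scale model is a hyperelastic
# membrane balloon using the aneurysm-wall strain-energy function
# psi(I1) = alpha (I1 - 3) + beta (I1 - 3)^2.

#' Blood-pressure protocol
#'
#' @param systolic,diastolic Pressures in mmHg (defaults 121 and 87).
#' @param elevation_factor Multiplier applied to the mean arterial
#'   pressure to emulate elevated blood-pressure conditions (default 1.5,
#'   a 50\% elevation).
#' @return List of class `pressure_protocol`.
#' @export
pressure_protocol <- function(systolic = 121, diastolic = 87,
                              elevation_factor = 1.5) {
  stopifnot(is_scalar_number_(systolic), is_scalar_number_(diastolic),
            is_scalar_number_(elevation_factor))
  if (!(systolic > diastolic && diastolic > 0)) {
    stop("require systolic > diastolic > 0", call. = FALSE)
  }
  if (elevation_factor < 0) {
    stop("elevation_factor must be non-negative", call. = FALSE)
  }
  structure(list(systolic = systolic, diastolic = diastolic,
                 elevation_factor = elevation_factor),
            class = "pressure_protocol")
}

#' Mean arterial pressure
#'
#' `MAP = systolic / 3 + 2 diastolic / 3` in mmHg.
#'
#' @param protocol A [pressure_protocol()].
#' @return MAP in mmHg.
#' @export
mean_arterial_pressure <- function(protocol) {
  protocol$systolic / 3 + 2 * protocol$diastolic / 3
}

MMHG_TO_KPA <- 0.133322

# Applied pressure in kPa after elevation.
applied_pressure_kpa_ <- function(protocol) {
  protocol$elevation_factor * mean_arterial_pressure(protocol) * MMHG_TO_KPA
}

#' Wall-parameter triple
#'
#' @param t Wall thickness, mm.
#' @param alpha,beta Stiffness parameters, kPa.
#' @return Named numeric vector of class `wall_params`.
#' @export
wall_params <- function(t, alpha, beta) {
  v <- c(t = t, alpha = alpha, beta = beta)
  stopifnot_positive_(v, "wall parameters (t, alpha, beta)")
  structure(v, class = "wall_params")
}

#' Membrane-balloon forward model
#'
#' A statically determinate spherical membrane of reference radius `R0`
#' and thickness `t` inflated to the elevated mean arterial pressure.
#' With equibiaxial stretch `lambda`, first invariant
#' `I1 = 2 lambda^2 + lambda^-4` and strain energy
#' `w(I1) = alpha (I1 - 3) + beta (I1 - 3)^2`, static equilibrium reads
#' `P = (t / R0) lambda^-2 w'(lambda)` with
#' `w'(lambda) = (alpha + 2 beta (I1 - 3)) (4 lambda - 4 lambda^-5)`.
#' The model solves for the smallest root `lambda* >= 1` by bracketed
#' root-finding and reports the membrane von Mises (equibiaxial wall)
#' stress `sigma = (lambda*/2) w'(lambda*)` in kPa. Stress decreases in
#' `t` and is non-increasing in `alpha` and `beta` at fixed pressure.
#'
#' @param reference_radius Reference radius `R0` in mm (default 25).
#' @param protocol A [pressure_protocol()].
#' @return Object of class `membrane_balloon`; also a valid forward model
#'   for [as_forward_model()].
#' @export
membrane_balloon_model <- function(reference_radius = 25,
                                   protocol = pressure_protocol()) {
  stopifnot_positive_(reference_radius, "reference_radius")
  structure(list(reference_radius = reference_radius, protocol = protocol),
            class = "membrane_balloon")
}

#' @export
print.membrane_balloon <- function(x, ...) {
  cat(sprintf(paste0("Membrane-balloon forward model: R0 = %g mm, ",
                     "applied pressure %.3f kPa (%.2f mmHg MAP x %.2f)\n"),
              x$reference_radius, applied_pressure_kpa_(x$protocol),
              mean_arterial_pressure(x$protocol),
              x$protocol$elevation_factor))
  invisible(x)
}

# w'(lambda) for the wall material.
wall_dw_ <- function(lambda, alpha, beta) {
  I1 <- 2 * lambda^2 + lambda^-4
  (alpha + 2 * beta * (I1 - 3)) * (4 * lambda - 4 * lambda^-5)
}

# Pressure-stretch relation P(lambda).
balloon_pressure_ <- function(lambda, t, alpha, beta, R0) {
  (t / R0) * lambda^-2 * wall_dw_(lambda, alpha, beta)
}

#' Membrane-balloon wall stress
#'
#' @param model A [membrane_balloon_model()].
#' @param params A [wall_params()] or numeric triple (t, alpha, beta).
#' @return Wall stress in kPa.
#' @export
balloon_stress <- function(model, params) {
  p <- as.numeric(params)
  stopifnot_positive_(p, "wall parameters")
  t <- p[1L]; alpha <- p[2L]; beta <- p[3L]
  R0 <- model$reference_radius
  P <- applied_pressure_kpa_(model$protocol)
  if (P == 0) return(0)

  # bracket: from 1 up to the first local maximum of P(lambda), or 10
  f <- function(l) balloon_pressure_(l, t, alpha, beta, R0) - P
  grid <- seq(1, 10, length.out = 2000L)
  Pg <- balloon_pressure_(grid, t, alpha, beta, R0)
  turn <- which(diff(Pg) <= 0)
  upper <- if (length(turn)) grid[turn[1L]] else 10
  if (f(upper) < 0) {
    stop(sprintf(paste0("limit-point instability: applied pressure ",
                        "%.4f kPa exceeds the limit pressure %.4f kPa"),
                 P, balloon_pressure_(upper, t, alpha, beta, R0)),
         call. = FALSE)
  }
  lam <- stats::uniroot(f, c(1, upper), tol = 1e-10)$root
  (lam / 2) * wall_dw_(lam, alpha, beta)
}

#' Coerce to a forward-model function
#'
#' Returns a function `theta -> stress [kPa]` from either a
#' `membrane_balloon` object or any user-supplied function already
#' honouring the contract. External field-valued solvers should reduce
#' their stress field to a scalar summary (e.g. a high percentile of the
#' von Mises field) before returning.
#'
#' @param x A `membrane_balloon` or a function of a length-3 numeric.
#' @return A function taking `(t, alpha, beta)` and returning kPa.
#' @export
as_forward_model <- function(x) {
  if (inherits(x, "membrane_balloon")) {
    function(theta) balloon_stress(x, theta)
  } else if (is.function(x)) {
    x
  } else {
    stop("cannot interpret forward model", call. = FALSE)
  }
}
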