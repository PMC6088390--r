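#' Two-species toy kinetic system of compartment binding and dimerization
#'
#' The mechanistic basis of the affinity model: two proteins bind reversibly
#' to the structures of one ROI (rates \code{k1l}/\code{km1l} and
#' \code{k2l}/\code{km2l}) and, once bound, dimerize with rates
#' \code{kappa12}/\code{kappam12}.  Free concentrations are held constant
#' (binding sites are not limiting).  Dissociation constants are
#' \code{K1l = km1l/k1l}, \code{K2l = km2l/k2l},
#' \code{theta12 = kappam12/kappa12}.
#'
#' @param A1,A2 free concentrations (held constant).
#' @param k1l,km1l,k2l,km2l compartment binding/unbinding rates.
#' @param kappa12,kappam12 dimerization/undimerization rates.
#' @return An object of class \code{toy_kinetic_system}.
#' @export
toy_kinetic_system <- function(A1, A2, k1l, km1l, k2l, km2l,
                               kappa12, kappam12) {
  rates <- c(A1 = A1, A2 = A2, k1l = k1l, km1l = km1l, k2l = k2l,
             km2l = km2l, kappa12 = kappa12, kappam12 = kappam12)
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all concentrations and rates must be positive", call. = FALSE)
  structure(c(as.list(rates),
              list(K1l = km1l / k1l, K2l = km2l / k2l,
                   theta12 = kappam12 / kappa12)),
            class = "toy_kinetic_system")
}

#' Closed-form steady state of the toy kinetic system
#'
#' At steady state the bound concentrations are \code{A1l = A1/K1l},
#' \code{A2l = A2/K2l} and the dimer concentration is
#' \code{A1 * A2 / (K1l * K2l * theta12)}.
#'
#' @param sys a [toy_kinetic_system()].
#' @return Named numeric: \code{A1l}, \code{A2l}, \code{complex}.
#' @export
steady_state_closed_form <- function(sys) {
  stopifnot(inherits(sys, "toy_kinetic_system"))
  A1l <- sys$A1 / sys$K1l
  A2l <- sys$A2 / sys$K2l
  c(A1l = A1l, A2l = A2l,
    complex = sys$A1 * sys$A2 / (sys$K1l * sys$K2l * sys$theta12))
}

#' Steady state of the toy kinetic system by ODE integration
#'
#' Integrates the mass-action ODEs for the bound species and the dimer
#' (free pools held constant) until the relative change of all states over
#' a time block falls below \code{tol}.
#'
#' @param sys a [toy_kinetic_system()].
#' @param horizon maximum integration time (default 1e6).
#' @param tol relative-change convergence tolerance (default 1e-10).
#' @return Named numeric equilibrium: \code{A1l}, \code{A2l},
#'   \code{complex}.
#' @export
steady_state_ode <- function(sys, horizon = 1e6, tol = 1e-10) {
  stopifnot(inherits(sys, "toy_kinetic_system"))
  deriv <- function(t, y, p) {
    with(as.list(c(y, p)), {
      dA1l <- k1l * A1 - km1l * A1l - kappa12 * A1l * A2l + kappam12 * complex
      dA2l <- k2l * A2 - km2l * A2l - kappa12 * A1l * A2l + kappam12 * complex
      dC <- kappa12 * A1l * A2l - kappam12 * complex
      list(c(dA1l, dA2l, dC))
    })
  }
  pars <- unlist(sys[c("A1", "A2", "k1l", "km1l", "k2l", "km2l",
                       "kappa12", "kappam12")])
  y <- c(A1l = 0, A2l = 0, complex = 0)
  t_block <- 2 / min(pars[c("km1l", "km2l", "kappam12")])  # slowest relaxation
  t_now <- 0
  repeat {
    out <- deSolve::ode(y = y, times = c(0, t_block), func = deriv,
                        parms = pars, rtol = 1e-12, atol = 1e-12,
                        maxsteps = 1e5)
    y_new <- out[nrow(out), -1]
    rel <- max(abs(y_new - y) / pmax(abs(y_new), 1e-300))
    t_now <- t_now + t_block
    y <- y_new
    if (rel < tol) break
    if (t_now > horizon)
      stop("steady state not reached within the integration horizon", call. = FALSE)
    t_block <- t_block * 2
  }
  stats::setNames(as.numeric(y), c("A1l", "A2l", "complex"))
}
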