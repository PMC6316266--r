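#' Pitting-corrosion model parameters
#'
#' Bundles the constants of the CDM pitting model.  The damage rate of an
#' exposed element is
#' \deqn{\frac{\partial d_P}{\partial t} =
#'       \frac{\delta_u}{L_e} K_u \lambda_p,}
#' where `Ku` (1/h) is the kinetic constant of the underlying uniform
#' corrosion process, `delta_u` (mm) the material characteristic length,
#' `Le` (mm) the element characteristic length, and `lambda_p` the
#' element-specific dimensionless pitting parameter, Weibull-distributed
#' on the initial surface (shape `gamma`, scale `psi`).  When an element
#' is fully damaged it is removed and its face neighbours inherit
#' `beta * lambda_p` of the removed donor.
#'
#' `delta_u = NULL` (the default) resolves to the mesh `Le` at
#' initialisation, so `delta_u/Le = 1` and `Ku` alone sets the rate.
#' For mesh-convergence series pass a fixed `delta_u` instead, so that
#' the surface recession speed is mesh-independent.
#'
#' The remaining arguments select documented variants of the update
#' rules; the defaults are the reference model:
#'
#' * `mode`: `"pitting"` (Weibull lambda field) or `"uniform"`
#'   (lambda_p = 1 everywhere, homogeneous surface recession).
#' * `accounting`: `"partial"` counts fractional damage
#'   (`sum(dP * V) / sum(V)`); `"removed"` counts deleted elements only.
#' * `inherit_donor`: `"current"` passes beta times the donor's lambda at
#'   removal (inheritance compounds along removal chains); `"initial"`
#'   passes beta times the lambda the donor had when it was first
#'   exposed (no compounding).
#' * `inherit_recipients`: `"all"` updates every surviving face
#'   neighbour (max rule); `"newly"` only neighbours not yet exposed.
#' * `rate_law`: `"direct"` uses the rate above (rate proportional to
#'   lambda_p); `"lifetime"` uses rate `(delta_u/Le) * Ku / lambda_p`,
#'   i.e. element lifetimes proportional to the Weibull draws.
#' * `lambda_cap`: upper bound applied to inherited lambda values, a
#'   numerical guard against unbounded geometric growth along long
#'   removal chains (`beta^k` overflows for beta > 1).
#' * `dt_frac`: adaptive time-step safety factor; the explicit Euler
#'   step is chosen so the fastest active element gains at most
#'   `dt_frac` damage per step.
#'
#' @param gamma,psi Weibull shape and scale of the pit field, > 0.
#' @param beta inheritance scale, >= 0.
#' @param Ku kinetic parameter (1/h), >= 0.
#' @param delta_u material characteristic length (mm), > 0, or `NULL`
#'   to use the mesh `Le`.
#' @param seed integer seed for the pit-field sampling.
#' @param mode,accounting,inherit_donor,inherit_recipients,rate_law
#'   model-variant switches, see Details.
#' @param lambda_cap cap on inherited lambda values.
#' @param dt_frac maximum damage increment per adaptive step.
#' @return An object of class `pit_params`.
#' @export
#' @examples
#' pit_params(gamma = 2.74898, psi = 2.60477, beta = 5.1, Ku = 0.1005)
pit_params <- function(gamma, psi, beta, Ku,
                       delta_u = NULL, seed = 1L,
                       mode = c("pitting", "uniform"),
                       accounting = c("partial", "removed"),
                       inherit_donor = c("current", "initial"),
                       inherit_recipients = c("all", "newly"),
                       rate_law = c("direct", "lifetime"),
                       lambda_cap = 1e9, dt_frac = 0.1) {
  mode <- match.arg(mode)
  accounting <- match.arg(accounting)
  inherit_donor <- match.arg(inherit_donor)
  inherit_recipients <- match.arg(inherit_recipients)
  rate_law <- match.arg(rate_law)
  check_shape_params(gamma, psi)
  stopifnot(
    is.numeric(beta), length(beta) == 1L, beta >= 0,
    is.numeric(Ku), length(Ku) == 1L, Ku >= 0,
    is.null(delta_u) || (is.numeric(delta_u) && delta_u > 0),
    is.numeric(lambda_cap), lambda_cap > 0,
    is.numeric(dt_frac), dt_frac > 0, dt_frac <= 1
  )
  structure(
    list(
      gamma = gamma, psi = psi, beta = beta, Ku = Ku,
      delta_u = if (is.null(delta_u)) NULL else as.numeric(delta_u),
      seed = as.integer(seed), mode = mode, accounting = accounting,
      inherit_donor = inherit_donor,
      inherit_recipients = inherit_recipients,
      rate_law = rate_law,
      lambda_cap = lambda_cap, dt_frac = dt_frac
    ),
    class = "pit_params"
  )
}

#' @export
print.pit_params <- function(x, ...) {
  cat("<pit_params>\n")
  cat(sprintf("  gamma = %g, psi = %g, beta = %g, Ku = %g 1/h\n",
              x$gamma, x$psi, x$beta, x$Ku))
  cat(sprintf("  delta_u = %s mm, seed = %d\n",
              if (is.null(x$delta_u)) "Le (mesh)" else format(x$delta_u),
              x$seed))
  cat(sprintf("  mode = %s, accounting = %s, inheritance = %s/%s, rate law = %s\n",
              x$mode, x$accounting, x$inherit_donor,
              x$inherit_recipients, x$rate_law))
  invisible(x)
}

# delta_u resolved against a mesh (delta_u = Le default)
resolve_delta_u <- function(params, mesh) {
  if (is.null(params$delta_u)) mesh$Le else params$delta_u
}
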