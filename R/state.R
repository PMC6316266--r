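STATUS_INTERIOR <- 0L
STATUS_EXPOSED  <- 1L
STATUS_REMOVED  <- 2L

#' Initialise the simulation state of a mesh
#'
#' Sets per-element damage to zero, marks the boundary elements (or a
#' caller-supplied subset) as exposed, and assigns each exposed element
#' a pitting parameter: a Weibull draw in pitting mode, exactly 1 in
#' uniform mode.  Draws are taken in mesh-index order from the seed in
#' `params`, so a given `(mesh, params)` pair always yields the same
#' pit field.
#'
#' @param mesh a `voxel_mesh`.
#' @param params a [pit_params()] object.
#' @param exposed optional logical vector (length `n_elements`) or
#'   integer index vector overriding the initially exposed set; used to
#'   mask faces in verification studies (for example exposing a bar on
#'   one end only).
#' @return A `sim_state`: list with `dP` (damage in `[0, 1]`), `lambda`
#'   (pitting parameter, `NA` where never exposed), `lambda_expo` (the
#'   value an element had when first exposed, used by the
#'   `inherit_donor = "initial"` variant), `status`
#'   (0 = interior, 1 = exposed, 2 = removed), `time` (h), and the
#'   resolved rate scale `delta_u / Le`.
#' @export
init_state <- function(mesh, params, exposed = NULL) {
  stopifnot(inherits(mesh, "voxel_mesh"), inherits(params, "pit_params"))
  n <- mesh$n_elements
  if (is.null(exposed)) {
    exposed_idx <- which(mesh$boundary)
  } else if (is.logical(exposed)) {
    stopifnot(length(exposed) == n)
    exposed_idx <- which(exposed)
  } else {
    exposed_idx <- sort(unique(as.integer(exposed)))
    stopifnot(all(exposed_idx >= 1L), all(exposed_idx <= n))
  }
  lambda <- rep(NA_real_, n)
  set.seed(params$seed)
  lambda[exposed_idx] <- if (params$mode == "uniform") {
    1
  } else {
    sample_lambda(length(exposed_idx), params$gamma, params$psi)
  }
  status <- rep(STATUS_INTERIOR, n)
  status[exposed_idx] <- STATUS_EXPOSED
  structure(
    list(
      dP = numeric(n),
      lambda = lambda,
      lambda_expo = lambda,
      status = status,
      time = 0,
      rate_scale = resolve_delta_u(params, mesh) / mesh$Le
    ),
    class = "sim_state"
  )
}

#' @export
print.sim_state <- function(x, ...) {
  cat("<sim_state>\n")
  cat(sprintf("  t = %.4g h; %d interior, %d exposed, %d removed\n",
              x$time, sum(x$status == STATUS_INTERIOR),
              sum(x$status == STATUS_EXPOSED), sum(x$status == STATUS_REMOVED)))
  cat(sprintf("  mean damage %.4g\n", mean(x$dP)))
  invisible(x)
}

check_state <- function(mesh, state) {
  if (!inherits(state, "sim_state") || length(state$dP) != mesh$n_elements) {
    stop("state is not sized to this mesh", call. = FALSE)
  }
  invisible(TRUE)
}

# per-element damage rate (1/h) of currently active elements
damage_rate <- function(state, params, idx) {
  lam <- state$lambda[idx]
  if (params$rate_law == "direct") {
    state$rate_scale * params$Ku * lam
  } else {
    state$rate_scale * params$Ku / pmax(lam, 1e-12)
  }
}

#' Advance damage by one explicit Euler step
#'
#' For each exposed, non-removed element with an assigned pitting
#' parameter, damage grows by `(delta_u / Le) * Ku * lambda_p * dt`,
#' capped at 1.  Interior and removed elements are untouched; time
#' advances by `dt`.
#'
#' @param state a `sim_state`.
#' @param params a [pit_params()] object.
#' @param dt time step in hours, > 0.
#' @return The updated `sim_state`.
#' @export
damage_increment <- function(state, params, dt) {
  stopifnot(inherits(state, "sim_state"), inherits(params, "pit_params"))
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0) {
    stop("'dt' must be a positive time step in hours", call. = FALSE)
  }
  act <- which(state$status == STATUS_EXPOSED & state$lambda > 0)
  if (length(act)) {
    dp <- state$dP[act] + damage_rate(state, params, act) * dt
    # snap within 1e-9 of full damage so accumulated float error cannot
    # delay removal by an extra step
    dp[dp >= 1 - 1e-9] <- 1
    state$dP[act] <- dp
  }
  state$time <- state$time + dt
  state
}

#' Remove fully damaged elements and propagate pit inheritance
#'
#' Every element with damage >= 1 becomes removed.  Each surviving face
#' neighbour is exposed (if it was interior) and receives
#' `beta * lambda_p(donor)`; when several donors compete, or the
#' neighbour already carries a pitting parameter, the neighbour keeps
#' the maximum (a pit accelerates the most-attacked path; the rule is
#' deterministic and order-independent).  Inherited values are capped
#' at `params$lambda_cap`.  In uniform mode newly exposed elements
#' receive 1.  The `inherit_donor` / `inherit_recipients` switches in
#' [pit_params()] select documented variants of this rule.
#'
#' @inheritParams damage_increment
#' @param mesh the `voxel_mesh` the state lives on.
#' @return The updated `sim_state`.
#' @export
remove_and_inherit <- function(state, mesh, params) {
  check_state(mesh, state)
  done <- which(state$dP >= 1 & state$status != STATUS_REMOVED)
  if (!length(done)) return(state)
  state$dP[done] <- 1
  state$status[done] <- STATUS_REMOVED

  donor_val <- if (params$inherit_donor == "initial") {
    state$lambda_expo[done]
  } else {
    state$lambda[done]
  }
  nb <- mesh$adjacency[done, , drop = FALSE]
  recip <- as.vector(nb)
  don <- rep(donor_val, times = 6L)
  keep <- recip > 0L
  recip <- recip[keep]; don <- don[keep]
  keep <- state$status[recip] != STATUS_REMOVED
  recip <- recip[keep]; don <- don[keep]
  if (params$inherit_recipients == "newly") {
    keep <- state$status[recip] == STATUS_INTERIOR
    recip <- recip[keep]; don <- don[keep]
  }
  if (length(recip)) {
    inherited <- if (params$mode == "uniform") {
      rep(1, length(don))
    } else {
      pmin(params$beta * don, params$lambda_cap)
    }
    agg <- tapply(inherited, recip, max)
    idx <- as.integer(names(agg))
    cur <- state$lambda[idx]
    cur[is.na(cur)] <- -Inf
    new_lam <- pmax(cur, as.numeric(agg))
    state$lambda[idx] <- new_lam
    fresh <- state$status[idx] == STATUS_INTERIOR
    state$lambda_expo[idx[fresh]] <- new_lam[fresh]
    state$status[idx][fresh] <- STATUS_EXPOSED
  }
  state
}

#' Mass loss of the coupon
#'
#' `accounting = "partial"` counts fractional damage,
#' `100 * sum(dP_e V_e) / sum(V_e)` with removed elements contributing
#' `dP = 1`; `"removed"` counts removed volume only.  Elements all have
#' volume `Le^3`, so both reduce to element counts/sums.
#'
#' @inheritParams remove_and_inherit
#' @param accounting `"partial"` or `"removed"`.
#' @return Mass loss as a percentage of the initial coupon mass.
#' @export
compute_mass_loss <- function(state, mesh,
                              accounting = c("partial", "removed")) {
  check_state(mesh, state)
  accounting <- match.arg(accounting)
  if (accounting == "partial") {
    100 * sum(state$dP) / mesh$n_elements
  } else {
    100 * sum(state$status == STATUS_REMOVED) / mesh$n_elements
  }
}
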