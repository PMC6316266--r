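FACTOR_NAMES <- c("gamma", "psi", "beta", "Ku")

#' Default calibration ranges for the pitting parameters
#'
#' The three-level ranges used to calibrate the Mg-1.2Zn-0.5Ca model:
#' gamma and psi in `[0.1, 5.1]` (centre 2.6), beta in `[0.1, 10.1]`
#' (centre 5.1) and Ku in `[0.001, 0.2]` (centre 0.1005).
#'
#' @return Named list of `c(low, center, high)` per factor.
#' @export
default_pit_ranges <- function() {
  list(
    gamma = c(0.1, 2.6, 5.1),
    psi   = c(0.1, 2.6, 5.1),
    beta  = c(0.1, 5.1, 10.1),
    Ku    = c(0.001, 0.1005, 0.2)
  )
}

#' Three-level, four-factor Box-Behnken design
#'
#' Generates the 24 edge runs (every factor pair at its low/high levels
#' with the remaining factors at centre) plus `center_replicates`
#' centre runs.  Only the four-factor design used for the pitting
#' calibration is supported.
#'
#' @param factors named list of four `c(low, center, high)` level
#'   vectors, e.g. [default_pit_ranges()].
#' @param center_replicates number of centre runs appended (default 3,
#'   for 27 runs in total).
#' @return A `bb_design`: list with `runs` (data frame in natural
#'   units), `coded` (the same runs in -1/0/+1 units), `factors` and
#'   `center_replicates`.
#' @export
#' @examples
#' design <- box_behnken(default_pit_ranges())
#' nrow(design$runs)  # 27
box_behnken <- function(factors, center_replicates = 3) {
  if (length(factors) != 4L) {
    stop("only the 4-factor Box-Behnken design is supported", call. = FALSE)
  }
  stopifnot(center_replicates >= 0)
  lv <- do.call(rbind, factors)
  if (ncol(lv) != 3L || any(lv[, 1] >= lv[, 2]) || any(lv[, 2] >= lv[, 3])) {
    stop("each factor needs levels c(low, center, high) with ",
         "low < center < high", call. = FALSE)
  }
  pairs <- utils::combn(4L, 2L)
  pm <- as.matrix(expand.grid(a = c(-1, 1), b = c(-1, 1)))
  coded <- matrix(0, 0, 4)
  for (p in seq_len(ncol(pairs))) {
    block <- matrix(0, 4, 4)
    block[, pairs[1, p]] <- pm[, 1]
    block[, pairs[2, p]] <- pm[, 2]
    coded <- rbind(coded, block)
  }
  coded <- rbind(coded, matrix(0, center_replicates, 4))
  colnames(coded) <- names(factors)
  runs <- coded
  for (f in 1:4) {
    # pick the exact level value (low/centre/high) by coded index
    runs[, f] <- lv[f, coded[, f] + 2]
  }
  structure(
    list(runs = as.data.frame(runs), coded = coded, factors = factors,
         center_replicates = center_replicates),
    class = "bb_design"
  )
}

#' @export
print.bb_design <- function(x, ...) {
  cat(sprintf("<bb_design> %d runs (%d edge + %d centre), factors: %s\n",
              nrow(x$runs), nrow(x$runs) - x$center_replicates,
              x$center_replicates, paste(names(x$factors), collapse = ", ")))
  invisible(x)
}

#' Chi-square discrepancy between observed and predicted series
#'
#' \eqn{\chi^2 = \sum_i (obs_i - pred_i)^2 / obs_i} over matched
#' points.  Observations must be strictly positive (the day-0 point of
#' an immersion curve is excluded upstream).
#'
#' @param observed,predicted numeric vectors of equal length >= 1.
#' @return The chi-square value.
#' @export
#' @examples
#' chi2_discrepancy(c(10.80, 35.33), c(11.80, 35.33))  # 1/10.80
chi2_discrepancy <- function(observed, predicted) {
  if (length(observed) != length(predicted)) {
    stop("observed and predicted series differ in length", call. = FALSE)
  }
  if (length(observed) < 1L) {
    stop("need at least one matched point", call. = FALSE)
  }
  if (any(!is.finite(observed)) || any(observed <= 0)) {
    stop("observed values must be positive and finite", call. = FALSE)
  }
  sum((observed - predicted)^2 / observed)
}

#' Simulate every design run and score it against a dataset
#'
#' For each run of the design, the pitting simulator is executed `reps`
#' times (to the final experimental mass loss), each replicate is
#' aligned on dimensionless time and scored with [curve_chi2()], and
#' the replicate chi-squares are averaged.  The same replicate seeds
#' are reused across runs (common random numbers), so runs that differ
#' only in parameters the aligned curve is invariant to score exactly
#' alike instead of differing by Monte-Carlo noise.  A run whose
#' corrosion stalls before the target scores `Inf`.
#'
#' @param design a [box_behnken()] design over gamma, psi, beta, Ku.
#' @param mesh_spec a `voxel_mesh` or a list of [build_coupon_mesh()]
#'   arguments.
#' @param dataset an `immersion_dataset`.
#' @param reps replicates per run, >= 1.
#' @param seed master seed; replicate seeds are derived from it.
#' @param params_template a [pit_params()] carrying the non-designed
#'   settings (mode, accounting, variants, `delta_u`); its gamma, psi,
#'   beta and Ku are overridden run by run.
#' @param max_steps per-replicate step limit before a run is declared
#'   stalled.
#' @return Data frame with the run parameters, `chi2` (replicate mean)
#'   and per-replicate values as attribute `chi2_reps`.
#' @export
evaluate_design <- function(design, mesh_spec, dataset, reps = 3, seed = 1,
                            params_template = NULL, max_steps = 2e5) {
  stopifnot(inherits(design, "bb_design"), reps >= 1,
            inherits(dataset, "immersion_dataset"))
  mesh <- as_voxel_mesh(mesh_spec)
  final_obs <- dataset$mass_loss_pct[nrow(dataset)]
  if (is.null(params_template)) {
    params_template <- pit_params(1, 1, 1, 1)
  }
  rep_seeds <- derive_seeds(seed, reps)
  runs <- design$runs
  chi2_reps <- matrix(NA_real_, nrow(runs), reps)
  for (r in seq_len(nrow(runs))) {
    pr <- modifyList(params_template, as.list(runs[r, FACTOR_NAMES]))
    class(pr) <- "pit_params"
    for (j in seq_len(reps)) {
      pr$seed <- rep_seeds[j]
      curve <- suppressWarnings(
        simulate_corrosion(mesh, pr, mass_loss_target = final_obs,
                           max_steps = max_steps)
      )
      chi2_reps[r, j] <- as.numeric(curve_chi2(dataset, curve))
    }
  }
  out <- cbind(runs, chi2 = rowMeans(chi2_reps))
  attr(out, "chi2_reps") <- chi2_reps
  attr(out, "rep_seeds") <- rep_seeds
  out
}

# deterministic child seeds below 2^31
derive_seeds <- function(seed, n) {
  (as.integer(seed) * 10007L + 7919L * seq_len(n)) %% 2147483647L
}

#' Fit the full quadratic response surface
#'
#' Ordinary least squares fit of the 15-coefficient model (4 linear,
#' 4 quadratic, 6 two-way interaction terms and an intercept) to the
#' design responses.  Factors are coded to `[-1, 1]` internally for
#' conditioning; coefficients are reported in coded units together
#' with the coding record, and `transform = "log"` fits the log
#' response (useful when chi-square spans orders of magnitude).
#'
#' @param points data frame or matrix of run parameters (columns
#'   gamma, psi, beta, Ku), >= 15 rank-sufficient rows.
#' @param responses numeric response vector (chi-square per run).
#' @param transform `"none"` or `"log"`.
#' @return A `quadratic_surface` with coefficients `a1..a15` (terms
#'   gamma, psi, beta, Ku, their squares, the six pairwise
#'   interactions, intercept), the coding record, `r_squared`,
#'   residuals and the coefficient t-test table.
#' @export
fit_quadratic <- function(points, responses, transform = c("none", "log")) {
  transform <- match.arg(transform)
  points <- as.matrix(as.data.frame(points)[, FACTOR_NAMES])
  stopifnot(nrow(points) == length(responses))
  if (nrow(points) < 15L) {
    stop("need at least 15 design points for the 15-coefficient model",
         call. = FALSE)
  }
  if (any(!is.finite(responses))) {
    stop("responses must be finite; cap or drop failed runs first",
         call. = FALSE)
  }
  y <- if (transform == "log") {
    if (any(responses <= 0)) {
      stop("log transform needs positive responses", call. = FALSE)
    }
    log(responses)
  } else {
    responses
  }
  center <- (apply(points, 2, max) + apply(points, 2, min)) / 2
  half <- (apply(points, 2, max) - apply(points, 2, min)) / 2
  if (any(half <= 0)) {
    stop("design points do not span all four factors (singular design)",
         call. = FALSE)
  }
  Z <- sweep(sweep(points, 2, center), 2, half, "/")
  X <- quad_model_matrix(Z)
  fit <- lm(y ~ X - 1)
  if (anyNA(coef(fit))) {
    stop("singular design: the quadratic model is not estimable from ",
         "these points", call. = FALSE)
  }
  cf <- setNames(coef(fit), colnames(X))
  res <- y - as.vector(X %*% cf)
  r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
  ct <- tryCatch(suppressWarnings(summary(fit)$coefficients),
                 error = function(e) NULL)
  if (!is.null(ct)) rownames(ct) <- colnames(X)[seq_len(nrow(ct))]
  structure(
    list(coefficients = cf, center = center, half = half,
         transform = transform, r_squared = r2, residuals = res,
         coef_table = ct, responses = responses),
    class = "quadratic_surface"
  )
}

# 15-term quadratic model matrix from coded factors
quad_model_matrix <- function(Z) {
  Z <- as.matrix(Z)
  pairs <- utils::combn(4L, 2L)
  inter <- sapply(seq_len(ncol(pairs)), function(p) {
    Z[, pairs[1, p]] * Z[, pairs[2, p]]
  })
  if (is.null(dim(inter))) inter <- matrix(inter, nrow = 1)
  X <- cbind(Z, Z^2, inter, 1)
  colnames(X) <- c(FACTOR_NAMES, paste0(FACTOR_NAMES, "^2"),
                   apply(pairs, 2, function(ij) {
                     paste(FACTOR_NAMES[ij], collapse = ":")
                   }),
                   "intercept")
  X
}

#' @export
print.quadratic_surface <- function(x, ...) {
  cat(sprintf("<quadratic_surface> 15 coefficients, %s response, R^2 = %.4f\n",
              if (x$transform == "log") "log" else "raw", x$r_squared))
  invisible(x)
}

#' Predict from a fitted response surface
#'
#' @param object a `quadratic_surface`.
#' @param newdata data frame or matrix with columns gamma, psi, beta, Ku.
#' @param scale `"response"` back-transforms a log fit;
#'   `"link"` returns the fitted (possibly log) scale.
#' @param ... unused.
#' @return Numeric vector of predictions.
#' @export
predict.quadratic_surface <- function(object, newdata,
                                      scale = c("response", "link"), ...) {
  scale <- match.arg(scale)
  pts <- as.matrix(as.data.frame(newdata)[, FACTOR_NAMES])
  Z <- sweep(sweep(pts, 2, object$center), 2, object$half, "/")
  eta <- as.vector(quad_model_matrix(Z) %*% object$coefficients)
  if (object$transform == "log" && scale == "response") exp(eta) else eta
}

#' Minimise a fitted response surface over a box
#'
#' Deterministic constrained minimisation: a dense grid over the box
#' (default 11 levels per factor, 14641 points) locates the basin, a
#' box-constrained quasi-Newton refinement polishes the optimum.  Grid
#' points whose value ties with the minimum (within relative 1e-9) are
#' resolved towards the centre of the box: when the surface is flat
#' along a factor — which happens by construction for factors the
#' aligned mass-loss curve is invariant to — the reported optimum
#' stays at the design centre rather than drifting to an arbitrary
#' bound.
#'
#' @param surface a `quadratic_surface`.
#' @param bounds named list of `c(low, high)` or `c(low, center, high)`
#'   per factor (a [default_pit_ranges()] object works).
#' @param n_grid grid resolution per factor.
#' @return Named vector (gamma, psi, beta, Ku) of the minimiser, with
#'   the surface value at the optimum as attribute `value`.
#' @export
surface_minimize <- function(surface, bounds, n_grid = 11) {
  stopifnot(inherits(surface, "quadratic_surface"))
  bl <- bounds_matrix(bounds)
  grids <- lapply(seq_len(4), function(f) {
    seq(bl[f, "low"], bl[f, "high"], length.out = n_grid)
  })
  G <- as.matrix(expand.grid(grids))
  colnames(G) <- FACTOR_NAMES
  v <- predict(surface, G, scale = "link")
  vmin <- min(v)
  tol <- 1e-9 * max(1, abs(vmin))
  tied <- which(v <= vmin + tol)
  ctr <- (bl[, "low"] + bl[, "high"]) / 2
  scale <- (bl[, "high"] - bl[, "low"]) / 2
  if (length(tied) > 1L) {
    d2 <- colSums(((t(G[tied, , drop = FALSE]) - ctr) / scale)^2)
    tied <- tied[order(d2, tied)]
  }
  start <- G[tied[1], ]
  obj <- function(x) {
    predict(surface, matrix(x, 1, dimnames = list(NULL, FACTOR_NAMES)),
            scale = "link")
  }
  ref <- optim(start, obj, method = "L-BFGS-B",
               lower = bl[, "low"], upper = bl[, "high"],
               control = list(factr = 1e4))
  # keep the centre-resolved grid point unless refinement genuinely improves
  opt <- if (ref$value < vmin - tol) {
    pmin(pmax(ref$par, bl[, "low"]), bl[, "high"])
  } else {
    start
  }
  structure(setNames(as.numeric(opt), FACTOR_NAMES), value = obj(opt))
}

bounds_matrix <- function(bounds) {
  stopifnot(length(bounds) == 4L)
  if (!is.null(names(bounds)) && all(FACTOR_NAMES %in% names(bounds))) {
    bounds <- bounds[FACTOR_NAMES]
  }
  bl <- t(vapply(bounds, function(b) range(b), numeric(2)))
  dimnames(bl) <- list(FACTOR_NAMES, c("low", "high"))
  if (any(bl[, 1] >= bl[, 2])) stop("degenerate bounds", call. = FALSE)
  bl
}

#' Calibrate the pitting parameters against an immersion dataset
#'
#' The end-to-end response-surface calibration: build the Box-Behnken
#' design over `ranges`, simulate and score every run
#' ([evaluate_design()]), fit the quadratic surface to the (by default
#' log) chi-square responses, minimise it over the box, and re-simulate
#' at the optimum to report the achieved chi-square.  Runs that
#' stalled (infinite chi-square) are capped at ten times the largest
#' finite response before fitting, so a handful of infeasible corners
#' cannot derail the fit.
#'
#' @inheritParams evaluate_design
#' @param ranges named list of `c(low, center, high)` per factor.
#' @param transform response transform for [fit_quadratic()];
#'   the default `"log"` stabilises responses spanning orders of
#'   magnitude.
#' @return A `calibration_result`: list with the design, the per-run
#'   table, the fitted surface, `optimum`, `optimum_chi2` (re-simulated
#'   replicate mean at the optimum) and the bookkeeping (seeds, reps,
#'   transform).
#' @export
calibrate_pitting <- function(mesh_spec, dataset,
                              ranges = default_pit_ranges(),
                              reps = 3, seed = 1,
                              transform = c("log", "none"),
                              params_template = NULL, max_steps = 2e5) {
  transform <- match.arg(transform)
  mesh <- as_voxel_mesh(mesh_spec)
  design <- box_behnken(ranges)
  per_run <- evaluate_design(design, mesh, dataset, reps = reps, seed = seed,
                             params_template = params_template,
                             max_steps = max_steps)
  y <- per_run$chi2
  if (any(!is.finite(y))) {
    cap <- 10 * max(y[is.finite(y)])
    y[!is.finite(y)] <- cap
    warning(sum(!is.finite(per_run$chi2)),
            " stalled run(s) capped at 10x the largest finite chi-square")
  }
  surface <- fit_quadratic(per_run[, FACTOR_NAMES], y, transform = transform)
  optimum <- surface_minimize(surface, ranges)

  if (is.null(params_template)) params_template <- pit_params(1, 1, 1, 1)
  popt <- modifyList(params_template, as.list(optimum))
  class(popt) <- "pit_params"
  final_obs <- dataset$mass_loss_pct[nrow(dataset)]
  rep_seeds <- attr(per_run, "rep_seeds")
  opt_chi2 <- vapply(rep_seeds, function(s) {
    popt$seed <- s
    curve <- suppressWarnings(
      simulate_corrosion(mesh, popt, mass_loss_target = final_obs,
                         max_steps = max_steps))
    as.numeric(curve_chi2(dataset, curve))
  }, numeric(1))
  achieved <- mean(opt_chi2)
  if (is.finite(achieved) && achieved > min(per_run$chi2)) {
    warning("achieved chi-square at the surface optimum exceeds the best ",
            "design run; the quadratic surrogate may be inadequate")
  }
  structure(
    list(design = design, per_run = per_run, surface = surface,
         optimum = optimum, optimum_chi2 = achieved,
         optimum_chi2_reps = opt_chi2, reps = reps, seed = seed,
         transform = transform),
    class = "calibration_result"
  )
}

#' @export
print.calibration_result <- function(x, ...) {
  cat("<calibration_result>\n")
  cat(sprintf("  %d runs x %d replicates, %s-response surface (R^2 = %.3f)\n",
              nrow(x$per_run), x$reps, x$transform, x$surface$r_squared))
  cat(sprintf("  optimum: gamma = %.5g, psi = %.5g, beta = %.5g, Ku = %.5g\n",
              x$optimum["gamma"], x$optimum["psi"], x$optimum["beta"],
              x$optimum["Ku"]))
  cat(sprintf("  achieved chi-square at optimum: %.4g (best design run %.4g)\n",
              x$optimum_chi2, min(x$per_run$chi2)))
  invisible(x)
}

#' Mesh-convergence study of the simulated mass loss
#'
#' Runs the simulator on a series of meshes of increasing resolution
#' and reports the mean mass loss at a fixed dimensionless time,
#' together with the relative error against the finest mesh.  `delta_u`
#' is held fixed across the series (if the template leaves it `NULL`
#' it is pinned to the Le of the coarsest mesh): a per-mesh
#' `delta_u = Le` would change the physical recession speed with
#' resolution and the series would not converge.
#'
#' @param params a [pit_params()] object (its seed starts the
#'   replicate seed sequence).
#' @param element_counts target element counts, coarse to fine.
#' @param diameter,thickness coupon dimensions (mm).
#' @param n_seeds replicates per mesh.
#' @param tau dimensionless time at which curves are compared.
#' @param final_mass_loss anchor for the dimensionless axis.
#' @return Data frame with one row per mesh: target and realised
#'   element counts, `Le`, mean mass loss at `tau`, and
#'   `rel_err_vs_finest`.
#' @export
mesh_convergence_study <- function(params, element_counts,
                                   diameter = 15, thickness = 3,
                                   n_seeds = 5, tau = 0.5,
                                   final_mass_loss = 89.27) {
  stopifnot(length(element_counts) >= 1, all(element_counts >= 1))
  meshes <- lapply(element_counts, function(n) {
    build_coupon_mesh(diameter, thickness, target_elements = n)
  })
  if (is.null(params$delta_u)) params$delta_u <- meshes[[1]]$Le
  seeds <- derive_seeds(params$seed, n_seeds)
  mean_mass <- vapply(meshes, function(mesh) {
    vals <- vapply(seeds, function(s) {
      p <- params; p$seed <- s
      curve <- suppressWarnings(
        simulate_corrosion(mesh, p, mass_loss_target = final_mass_loss))
      curve <- to_dimensionless(curve, final_mass_loss = final_mass_loss)
      approx(curve$dimensionless_time, curve$mass_loss_pct, xout = tau,
             rule = 2)$y
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  finest <- which.max(vapply(meshes, function(m) m$n_elements, numeric(1)))
  data.frame(
    target_elements = element_counts,
    n_elements = vapply(meshes, function(m) m$n_elements, numeric(1)),
    Le_mm = vapply(meshes, function(m) m$Le, numeric(1)),
    mean_mass_at_tau = mean_mass,
    rel_err_vs_finest = abs(mean_mass - mean_mass[finest]) /
      abs(mean_mass[finest])
  )
}
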