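#' Gravimetric mass loss per exposed area
#'
#' `(mi - mf) / A`, the standard immersion-test mass-loss measure in
#' mg/cm^2.  A final mass above the initial one (corrosion-product
#' gain) yields a negative value and a warning, but is returned.
#'
#' @param mi initial sample mass (mg).
#' @param mf final sample mass after cleaning (mg).
#' @param A exposed surface area (cm^2), > 0.
#' @return Mass loss in mg/cm^2.
#' @export
#' @examples
#' mass_loss_per_area(100, 90, 5)  # 2 mg/cm^2
mass_loss_per_area <- function(mi, mf, A) {
  if (!is.numeric(A) || any(A <= 0)) {
    stop("exposed area 'A' must be positive", call. = FALSE)
  }
  if (any(mf > mi)) {
    warning("final mass exceeds initial mass; reporting a negative loss ",
            "(corrosion-product gain)")
  }
  (mi - mf) / A
}

#' Construct an immersion mass-loss dataset
#'
#' @param times_days measurement times in days, strictly increasing,
#'   starting at 0.
#' @param mass_loss_pct mass loss in percent, in `[0, 100]`, 0 at day 0.
#' @param n_samples number of replicate coupons behind each mean value.
#' @param label free-text dataset label.
#' @return An `immersion_dataset` (a data frame with columns
#'   `time_days` and `mass_loss_pct` plus metadata attributes).
#' @export
immersion_dataset <- function(times_days, mass_loss_pct,
                              n_samples = NA_integer_, label = "") {
  stopifnot(length(times_days) == length(mass_loss_pct),
            length(times_days) >= 1)
  if (times_days[1] != 0 || mass_loss_pct[1] != 0) {
    stop("an immersion dataset starts at (0 days, 0 %)", call. = FALSE)
  }
  if (any(diff(times_days) <= 0)) {
    stop("measurement times must be strictly increasing", call. = FALSE)
  }
  if (any(mass_loss_pct < 0 | mass_loss_pct > 100)) {
    stop("mass loss must lie within [0, 100] percent", call. = FALSE)
  }
  if (any(diff(mass_loss_pct) < 0)) {
    stop("mass loss must be non-decreasing", call. = FALSE)
  }
  structure(
    data.frame(time_days = as.numeric(times_days),
               mass_loss_pct = as.numeric(mass_loss_pct)),
    class = c("immersion_dataset", "data.frame"),
    n_samples = as.integer(n_samples),
    label = label
  )
}

#' @export
print.immersion_dataset <- function(x, ...) {
  cat(sprintf("<immersion_dataset> \"%s\" (n = %s)\n", attr(x, "label"),
              attr(x, "n_samples")))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Packaged Mg-1.2Zn-0.5Ca immersion dataset
#'
#' Mean mass loss of Mg-1.2Zn-0.5Ca (wt.%) disc coupons (15 mm x 3 mm,
#' n = 7) immersed in simulated body fluid at pH 7.3-7.8 and 37 degrees
#' C over 28 days.  The values ship as a plain CSV under
#' `extdata/mgznca_sbf_massloss.csv`.
#'
#' @return An `immersion_dataset` with measurements at days
#'   0, 3, 7, 14, 21 and 28.
#' @export
#' @examples
#' mgznca_immersion()
mgznca_immersion <- function() {
  path <- system.file("extdata", "mgznca_sbf_massloss.csv",
                      package = "pitcorr", mustWork = TRUE)
  read_immersion_csv(path, n_samples = 7L, label = "Mg-1.2Zn-0.5Ca SBF 37C")
}

#' Read / write immersion datasets as CSV
#'
#' CSV schema: `time_days`, `mass_loss_pct` (an optional `sd_pct`
#' column is carried through as an attribute).
#'
#' @param path CSV file.
#' @param n_samples,label metadata, see [immersion_dataset()].
#' @return `read_immersion_csv()` returns an `immersion_dataset`;
#'   `write_immersion_csv()` returns `path` invisibly.
#' @export
read_immersion_csv <- function(path, n_samples = NA_integer_, label = "") {
  df <- read.csv(path)
  need <- c("time_days", "mass_loss_pct")
  if (!all(need %in% names(df))) {
    stop("immersion CSV needs columns time_days and mass_loss_pct ",
         "(line 1 of ", path, ")", call. = FALSE)
  }
  out <- immersion_dataset(df$time_days, df$mass_loss_pct,
                           n_samples = n_samples, label = label)
  if ("sd_pct" %in% names(df)) attr(out, "sd_pct") <- df$sd_pct
  out
}

#' @rdname read_immersion_csv
#' @param dataset an `immersion_dataset`.
#' @export
write_immersion_csv <- function(dataset, path) {
  df <- as.data.frame(dataset)
  if (!is.null(attr(dataset, "sd_pct"))) df$sd_pct <- attr(dataset, "sd_pct")
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Attach a dimensionless time axis
#'
#' Adds a `dimensionless_time` column, `tau = t / t_final`.  For an
#' experimental dataset `t_final` is the last recorded time.  For a
#' simulated curve `t_final` is the first time the mass loss reaches
#' `final_mass_loss` (default: the curve's own final value), matching
#' the convention that each simulation is run until it reaches the
#' final experimental mass loss.  The operation is idempotent.
#'
#' @param x an `immersion_dataset` or `mass_loss_curve`.
#' @param final_mass_loss anchor mass loss in percent (curves only).
#' @return `x` with a `dimensionless_time` column.
#' @export
to_dimensionless <- function(x, final_mass_loss = NULL) {
  UseMethod("to_dimensionless")
}

#' @export
to_dimensionless.immersion_dataset <- function(x, final_mass_loss = NULL) {
  tf <- max(x$time_days)
  if (tf <= 0 || max(x$mass_loss_pct) <= 0) {
    stop("cannot nondimensionalise an empty or zero curve", call. = FALSE)
  }
  x$dimensionless_time <- x$time_days / tf
  x
}

#' @export
to_dimensionless.mass_loss_curve <- function(x, final_mass_loss = NULL) {
  if (is.null(final_mass_loss)) final_mass_loss <- x$mass_loss_pct[nrow(x)]
  if (final_mass_loss <= 0) {
    stop("cannot nondimensionalise an empty or zero curve", call. = FALSE)
  }
  hit <- which(x$mass_loss_pct >= final_mass_loss - 1e-9)
  if (!length(hit)) {
    stop("curve never reaches the anchor mass loss (",
         format(final_mass_loss), " %)", call. = FALSE)
  }
  tf <- x$time_h[hit[1]]
  if (tf <= 0) stop("anchor reached at t = 0; degenerate curve", call. = FALSE)
  x$dimensionless_time <- x$time_h / tf
  x
}

#' Chi-square discrepancy between a dataset and a simulated curve
#'
#' Aligns the two on dimensionless time (experiment: `t / t_last`;
#' simulation: `t` / first time the curve reaches the experimental
#' final mass loss), linearly interpolates the simulated mass loss at
#' the experimental dimensionless times, drops the day-0 point (whose
#' zero observation would divide by zero), and evaluates
#' [chi2_discrepancy()].  A curve that never reaches the experimental
#' final mass loss gets `Inf`.
#'
#' @param dataset an `immersion_dataset`.
#' @param curve a `mass_loss_curve`.
#' @return The chi-square value, with the aligned predictions attached
#'   as attribute `predicted`.
#' @export
curve_chi2 <- function(dataset, curve) {
  stopifnot(inherits(dataset, "immersion_dataset"),
            inherits(curve, "mass_loss_curve"))
  final_obs <- dataset$mass_loss_pct[nrow(dataset)]
  if (max(curve$mass_loss_pct) < final_obs) {
    return(structure(Inf, predicted = NULL))
  }
  curve <- to_dimensionless(curve, final_mass_loss = final_obs)
  ds <- to_dimensionless(dataset)
  keep <- ds$mass_loss_pct > 0
  tau_obs <- ds$dimensionless_time[keep]
  obs <- ds$mass_loss_pct[keep]
  pred <- approx(curve$dimensionless_time, curve$mass_loss_pct,
                 xout = tau_obs, rule = 2)$y
  structure(chi2_discrepancy(obs, pred), predicted = pred)
}

#' Generate a pseudo-experimental immersion dataset
#'
#' Simulates a mass-loss curve with known ("true") parameters, samples
#' it at evenly spaced dimensionless times, and perturbs the sampled
#' values with i.i.d. Gaussian noise truncated to `[0, 100]`.  The
#' perturbed series is monotonised with a running maximum so the result
#' satisfies the gravimetric invariants of [immersion_dataset()]; the
#' day-0 point is forced to (0, 0).  The simulation seed lives in
#' `true_params`, the noise seed is `seed`, so the same underlying
#' curve can be re-noised independently.
#'
#' @param true_params a [pit_params()] object, the ground truth.
#' @param mesh_spec a `voxel_mesh`, or a list of [build_coupon_mesh()]
#'   arguments.
#' @param noise_sd Gaussian noise standard deviation in percent points.
#' @param n_times number of sampled time points (including day 0).
#' @param seed noise RNG seed.
#' @param final_mass_loss mass-loss percentage the simulation runs to.
#' @return An `immersion_dataset` labelled `"synthetic"`, with the true
#'   parameters attached as attribute `true_params`.
#' @export
synth_experiment <- function(true_params, mesh_spec, noise_sd = 1,
                             n_times = 6, seed = 1,
                             final_mass_loss = 89.27) {
  stopifnot(noise_sd >= 0, n_times >= 2)
  mesh <- as_voxel_mesh(mesh_spec)
  curve <- simulate_corrosion(mesh, true_params,
                              mass_loss_target = final_mass_loss)
  curve <- to_dimensionless(curve, final_mass_loss = final_mass_loss)
  tf_h <- curve$time_h[which(curve$dimensionless_time >= 1)[1]]
  tau <- seq(0, 1, length.out = n_times)
  truth <- approx(curve$dimensionless_time, curve$mass_loss_pct,
                  xout = tau, rule = 2)$y
  set.seed(seed)
  noisy <- truth + rnorm(n_times, 0, noise_sd)
  noisy <- pmin(pmax(noisy, 0), 100)
  noisy[1] <- 0
  noisy <- cummax(noisy)
  out <- immersion_dataset(tau * tf_h / 24, noisy,
                           n_samples = 1L, label = "synthetic")
  attr(out, "true_params") <- true_params
  out
}

# accept a ready mesh or a spec list of build_coupon_mesh() arguments
as_voxel_mesh <- function(mesh_spec) {
  if (inherits(mesh_spec, "voxel_mesh")) return(mesh_spec)
  if (is.list(mesh_spec)) return(do.call(build_coupon_mesh, mesh_spec))
  stop("'mesh_spec' must be a voxel_mesh or a list of arguments for ",
       "build_coupon_mesh()", call. = FALSE)
}
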