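#' Run the pitting-corrosion simulation
#'
#' Alternates [damage_increment()] and [remove_and_inherit()] with an
#' adaptive explicit Euler step until a stop criterion is met, and
#' records the mass-loss history.  The step is chosen as
#' `dt = dt_frac / max(rate)` over the active elements, so the fastest
#' element gains at most `dt_frac` damage per step (default 0.1);
#' removal and inheritance are processed after each increment
#' (operator splitting).  With a fixed seed the whole trajectory is
#' reproducible.
#'
#' @param mesh a `voxel_mesh`.
#' @param params a [pit_params()] object.
#' @param t_end stop after this many hours (may be combined with
#'   `mass_loss_target`; the first criterion reached stops the run).
#' @param mass_loss_target stop once mass loss (under the accounting in
#'   `params`) reaches this percentage.
#' @param record_times optional vector of times (h) at which to report
#'   the curve; default reports every step.
#' @param exposed optional initial exposure override, see [init_state()].
#' @param snapshot_times,snapshot_dir optional times (h) at which VTK
#'   snapshots of the damage field are written to
#'   `snapshot_dir/snapshot_<idx>.vtk` via [write_field_snapshot()].
#' @param keep_removed passed to [write_field_snapshot()].
#' @param max_steps hard step limit (guards degenerate parameter sets).
#' @return A `mass_loss_curve`: data frame with `time_h`,
#'   `mass_loss_pct` (under the accounting in `params`),
#'   `mass_partial_pct` and `mass_removed_pct`, with the final
#'   `sim_state` attached as attribute `final_state` and
#'   `target_reached` indicating whether a requested mass-loss target
#'   was met.
#' @export
#' @examples
#' mesh <- build_coupon_mesh(6, 2, element_size = 1)
#' p <- pit_params(gamma = 2.6, psi = 2.6, beta = 5.1, Ku = 0.1005, seed = 7)
#' simulate_corrosion(mesh, p, mass_loss_target = 50)
simulate_corrosion <- function(mesh, params,
                               t_end = NULL, mass_loss_target = NULL,
                               record_times = NULL, exposed = NULL,
                               snapshot_times = NULL, snapshot_dir = NULL,
                               keep_removed = FALSE,
                               max_steps = 1e6) {
  stopifnot(inherits(mesh, "voxel_mesh"), inherits(params, "pit_params"))
  if (is.null(t_end) && is.null(mass_loss_target)) {
    stop("give a stop criterion: 't_end' and/or 'mass_loss_target'",
         call. = FALSE)
  }
  if (!is.null(mass_loss_target)) {
    stopifnot(mass_loss_target > 0, mass_loss_target <= 100)
    if (params$Ku <= 0 && is.null(t_end)) {
      stop("Ku = 0 cannot reach a mass-loss target: the run would not ",
           "terminate", call. = FALSE)
    }
  }
  if (!is.null(snapshot_times) && is.null(snapshot_dir)) {
    stop("'snapshot_dir' is required when snapshot times are given",
         call. = FALSE)
  }

  state <- init_state(mesh, params, exposed = exposed)
  snap_pending <- sort(unique(snapshot_times))
  snap_idx <- 0L
  write_snap <- function(state) {
    snap_idx <<- snap_idx + 1L
    path <- file.path(snapshot_dir, sprintf("snapshot_%03d.vtk", snap_idx))
    write_field_snapshot(mesh, state, path, keep_removed = keep_removed)
  }
  if (length(snap_pending) && isTRUE(snap_pending[1] == 0)) {
    write_snap(state)
    snap_pending <- snap_pending[-1]
  }

  cap <- 4096L
  rec_t <- numeric(cap); rec_p <- numeric(cap); rec_r <- numeric(cap)
  nrec <- 0L
  push <- function(t, mp, mr) {
    nrec <<- nrec + 1L
    if (nrec > cap) {
      cap <<- cap * 2L
      length(rec_t) <<- cap; length(rec_p) <<- cap; length(rec_r) <<- cap
    }
    rec_t[nrec] <<- t; rec_p[nrec] <<- mp; rec_r[nrec] <<- mr
  }

  target_reached <- is.null(mass_loss_target)
  steps <- 0L
  repeat {
    act <- which(state$status == STATUS_EXPOSED & state$lambda > 0)
    if (!length(act)) {
      # corrosion has stalled; with a time horizon we coast to it
      if (!is.null(t_end) && state$time < t_end) {
        state$time <- t_end
        push(t_end, compute_mass_loss(state, mesh, "partial"),
             compute_mass_loss(state, mesh, "removed"))
      }
      break
    }
    rates <- damage_rate(state, params, act)
    rmax <- max(rates)
    if (!is.finite(rmax) || rmax <= 0) break
    dt <- params$dt_frac / rmax
    if (length(snap_pending)) dt <- min(dt, snap_pending[1] - state$time)
    if (!is.null(t_end)) dt <- min(dt, t_end - state$time)
    if (dt <= 0) break
    state <- damage_increment(state, params, dt)
    state <- remove_and_inherit(state, mesh, params)
    steps <- steps + 1L

    mp <- compute_mass_loss(state, mesh, "partial")
    mr <- compute_mass_loss(state, mesh, "removed")
    push(state$time, mp, mr)

    if (length(snap_pending) && state$time >= snap_pending[1] - 1e-12) {
      write_snap(state)
      snap_pending <- snap_pending[-1]
    }
    m_stop <- if (params$accounting == "partial") mp else mr
    if (!is.null(mass_loss_target) && m_stop >= mass_loss_target) {
      target_reached <- TRUE
      break
    }
    if (!is.null(t_end) && state$time >= t_end - 1e-12) break
    if (steps >= max_steps) {
      warning("simulation stopped at max_steps before the stop criterion")
      break
    }
  }
  if (!target_reached && is.null(t_end)) {
    warning("corrosion stalled before reaching the mass-loss target")
  }

  time_h <- c(0, rec_t[seq_len(nrec)])
  mp <- c(0, rec_p[seq_len(nrec)])
  mr <- c(0, rec_r[seq_len(nrec)])
  if (!is.null(record_times)) {
    rt <- sort(unique(record_times))
    mp <- approx(time_h, mp, xout = rt, rule = 2)$y
    mr <- approx(time_h, mr, xout = rt, rule = 2)$y
    time_h <- rt
  }
  new_mass_loss_curve(
    time_h = time_h,
    mass_partial_pct = mp,
    mass_removed_pct = mr,
    accounting = params$accounting,
    target_reached = target_reached,
    final_state = state,
    steps = steps
  )
}

#' Construct a mass-loss curve from raw series
#'
#' Mostly useful for turning tabulated or externally computed curves
#' into the container [simulate_corrosion()] returns, e.g. to score
#' them with [curve_chi2()].
#'
#' @param time_h times in hours, starting at 0.
#' @param mass_loss_pct mass loss in percent, non-decreasing.
#' @param accounting label for the accounting the series represents.
#' @return A `mass_loss_curve`.
#' @export
mass_loss_curve <- function(time_h, mass_loss_pct,
                            accounting = c("partial", "removed")) {
  accounting <- match.arg(accounting)
  stopifnot(length(time_h) == length(mass_loss_pct), length(time_h) >= 1,
            time_h[1] == 0, all(diff(time_h) >= 0),
            all(diff(mass_loss_pct) >= 0))
  new_mass_loss_curve(time_h, mass_loss_pct, mass_loss_pct,
                      accounting = accounting)
}

new_mass_loss_curve <- function(time_h, mass_partial_pct, mass_removed_pct,
                                accounting, target_reached = TRUE,
                                final_state = NULL, steps = NA_integer_) {
  mass <- if (accounting == "partial") mass_partial_pct else mass_removed_pct
  out <- data.frame(
    time_h = time_h,
    time_days = time_h / 24,
    mass_loss_pct = mass,
    mass_partial_pct = mass_partial_pct,
    mass_removed_pct = mass_removed_pct
  )
  structure(out,
            class = c("mass_loss_curve", "data.frame"),
            accounting = accounting,
            target_reached = target_reached,
            final_state = final_state,
            steps = steps)
}

#' @export
print.mass_loss_curve <- function(x, ...) {
  cat(sprintf("<mass_loss_curve> %d records over %.4g h (%s accounting)\n",
              nrow(x), max(x$time_h), attr(x, "accounting")))
  cat(sprintf("  final mass loss %.2f%%; target reached: %s\n",
              x$mass_loss_pct[nrow(x)], attr(x, "target_reached")))
  invisible(x)
}

#' Write a mass-loss curve to CSV
#'
#' Columns: `time_h`, `time_days`, `dimensionless_time` (when present),
#' `mass_loss_pct`.
#'
#' @param curve a `mass_loss_curve`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_mass_loss_csv <- function(curve, path) {
  cols <- intersect(c("time_h", "time_days", "dimensionless_time",
                      "mass_loss_pct"), names(curve))
  write.csv(as.data.frame(curve)[, cols], path, row.names = FALSE)
  invisible(path)
}
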