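#' Assign particles to radial shells
#'
#' Swimmers packed around the target organize into an inner shell at contact
#' (mean radius near `2a`) and an outer shell near twice that.  Assignment
#' is windowed because particles exchange between shells: within each time
#' window (default 1 s) a particle is `inner` if its window-mean distance to
#' the target is below `boundary`, else `outer`.  The default boundary `3a`
#' is the midpoint of the nominal shell radii `2a` and `4a`.
#'
#' @param traj A `swim_trajectory`.
#' @param boundary Shell boundary radius (um); default `3 a`.
#' @param window Window length (s).
#' @return Object of class `shell_assignment`: data frame with columns
#'   `particle`, `window`, `t_mid`, `mean_r`, `shell`; attributes `R_in`,
#'   `R_out` (occupancy-weighted mean radii, `NA` for an empty shell) and
#'   `boundary`.
#' @export
assign_shells <- function(traj, boundary = NULL, window = 1) {
  stopifnot(inherits(traj, "swim_trajectory"))
  if (is.null(boundary)) boundary <- 3 * traj$params$a
  n <- ncol(traj$x)
  win <- floor(traj$time / window)
  rows <- lapply(seq_len(n), function(i) {
    r <- sqrt(traj$x[, i]^2 + traj$y[, i]^2)
    mr <- tapply(r, win, mean)
    tm <- tapply(traj$time, win, mean)
    cnt <- tapply(r, win, length)
    data.frame(particle = i, window = as.integer(names(mr)),
               t_mid = as.numeric(tm), mean_r = as.numeric(mr),
               n_samples = as.integer(cnt))
  })
  d <- do.call(rbind, rows)
  d$shell <- ifelse(d$mean_r < boundary, "inner", "outer")
  wmean <- function(sh) {
    sel <- d$shell == sh
    if (!any(sel)) return(NA_real_)
    sum(d$mean_r[sel] * d$n_samples[sel]) / sum(d$n_samples[sel])
  }
  structure(d, class = c("shell_assignment", "data.frame"),
            R_in = wmean("inner"), R_out = wmean("outer"),
            boundary = boundary, window = window)
}

# per-particle unwrapped polar angle phi(t) (avoids branch-cut artifacts in
# angular velocities)
unwrap_phi <- function(x, y) {
  phi <- atan2(y, x)
  dphi <- diff(phi)
  dphi <- dphi - 2 * pi * round(dphi / (2 * pi))
  phi[1] + c(0, cumsum(dphi))
}

#' Per-shell bifurcation point estimates
#'
#' Applies the single-particle bifurcation logic shell-wise: propulsion
#' angles of samples assigned to each shell are pooled, and the modes are
#' reported against the shell-specific control parameter
#' \eqn{\omega_0^{shell}\delta t = v_0 \delta t / R^{shell}}.
#'
#' @param traj A `swim_trajectory`.
#' @param assignment The matching [assign_shells()] result.
#' @param use_total_delay Include the instrumental latency in the delay.
#' @return Data frame with one row per occupied shell: `shell`, `R`,
#'   `control`, `mode_pos`, `mode_neg` (rad).
#' @export
per_shell_bifurcation <- function(traj, assignment, use_total_delay = TRUE) {
  stopifnot(inherits(traj, "swim_trajectory"),
            inherits(assignment, "shell_assignment"))
  ser <- propulsion_angle(traj)
  win_len <- attr(assignment, "window")
  ser$window <- floor(ser$time / win_len)
  key <- paste(assignment$particle, assignment$window)
  shell_of <- setNames(assignment$shell, key)
  ser$shell <- shell_of[paste(ser$particle, ser$window)]
  eff_dt <- traj$params$delta_t +
    if (use_total_delay) traj$params$instr_delay else 0
  rows <- lapply(c("inner", "outer"), function(sh) {
    th <- ser$theta[!is.na(ser$shell) & ser$shell == sh]
    if (length(th) == 0) return(NULL)
    R <- if (sh == "inner") attr(assignment, "R_in")
         else attr(assignment, "R_out")
    m <- theta_modes(th)
    data.frame(shell = sh, R = R, control = traj$params$v0 / R * eff_dt,
               mode_pos = m[["mode_pos"]], mode_neg = m[["mode_neg"]])
  })
  do.call(rbind, rows)
}

#' Sense of rotation of the shells
#'
#' Mean angular velocity \eqn{\langle\dot\phi\rangle} per shell from
#' unwrapped polar angles, with a noise floor of twice the standard error
#' (estimated from per-window means).  The shells are labeled `"co"` when
#' both means are significant and share a sign, `"counter"` when they are
#' significant with opposite signs, `"none"` otherwise.
#'
#' @param assignment A [assign_shells()] result.
#' @param traj The matching `swim_trajectory`.
#' @return List with `per_shell` (data frame `shell`, `omega`, `se`,
#'   `n_windows`, `significant`) and `label` (`"co"`, `"counter"` or
#'   `"none"`).
#' @export
rotation_sense <- function(assignment, traj) {
  stopifnot(inherits(assignment, "shell_assignment"),
            inherits(traj, "swim_trajectory"))
  n <- ncol(traj$x)
  win_len <- attr(assignment, "window")
  win <- floor(traj$time / win_len)
  dt <- diff(traj$time)
  # per-particle, per-window mean angular velocity
  rows <- lapply(seq_len(n), function(i) {
    phi <- unwrap_phi(traj$x[, i], traj$y[, i])
    om <- diff(phi) / dt
    wmid <- win[-1]
    data.frame(particle = i, window = wmid,
               omega = om)
  })
  d <- do.call(rbind, rows)
  agg <- stats::aggregate(omega ~ particle + window, data = d, FUN = mean)
  key <- paste(assignment$particle, assignment$window)
  shell_of <- setNames(assignment$shell, key)
  agg$shell <- shell_of[paste(agg$particle, agg$window)]
  agg <- agg[!is.na(agg$shell), ]
  per <- lapply(c("inner", "outer"), function(sh) {
    o <- agg$omega[agg$shell == sh]
    if (length(o) == 0) return(NULL)
    se <- sd(o) / sqrt(length(o))
    data.frame(shell = sh, omega = mean(o), se = se,
               n_windows = length(o),
               significant = is.finite(se) && abs(mean(o)) > 2 * se)
  })
  per <- do.call(rbind, per)
  label <- "none"
  if (!is.null(per) && nrow(per) == 2 && all(per$significant)) {
    label <- if (prod(per$omega) > 0) "co" else "counter"
  }
  list(per_shell = per, label = label)
}

#' Gridded mean velocity field
#'
#' Finite-difference velocities of all particles binned by mid-step
#' position on a square grid; bins never visited carry no velocity value.
#'
#' @param traj A `swim_trajectory`, uniformly sampled in time.
#' @param grid_step Bin edge length (um), positive.
#' @return Data frame with columns `x`, `y` (bin centers), `xm`, `ym`
#'   (mean sample position within the bin, um), `vx`, `vy` (mean velocity,
#'   um/s) and `n` (samples per bin); only occupied bins are returned.
#' @export
velocity_field <- function(traj, grid_step) {
  stopifnot(inherits(traj, "swim_trajectory"))
  if (!is.numeric(grid_step) || length(grid_step) != 1L || grid_step <= 0)
    stop("grid_step must be a positive number")
  dt <- diff(traj$time)
  n <- ncol(traj$x)
  xs <- ys <- vxs <- vys <- vector("list", n)
  for (i in seq_len(n)) {
    vxs[[i]] <- diff(traj$x[, i]) / dt
    vys[[i]] <- diff(traj$y[, i]) / dt
    xs[[i]] <- (traj$x[-1, i] + traj$x[-nrow(traj$x), i]) / 2
    ys[[i]] <- (traj$y[-1, i] + traj$y[-nrow(traj$y), i]) / 2
  }
  x <- unlist(xs); y <- unlist(ys)
  vx <- unlist(vxs); vy <- unlist(vys)
  ix <- floor(x / grid_step); iy <- floor(y / grid_step)
  key <- paste(ix, iy)
  agg <- function(v) tapply(v, key, mean)
  cnt <- tapply(vx, key, length)
  out <- data.frame(x = as.numeric(tapply(ix, key, function(k) k[1])) *
                        grid_step + grid_step / 2,
                    y = as.numeric(tapply(iy, key, function(k) k[1])) *
                        grid_step + grid_step / 2,
                    xm = as.numeric(agg(x)), ym = as.numeric(agg(y)),
                    vx = as.numeric(agg(vx)), vy = as.numeric(agg(vy)),
                    n = as.integer(cnt))
  rownames(out) <- NULL
  out
}

#' Tangential-bias hook (default stub)
#'
#' Placeholder for conjectured hydrodynamic/thermophoretic rotational
#' biases: a function of a particle's propulsion angle returning a
#' tangential drift speed (um/s, positive = counter-clockwise) that
#' [simulate_swimmers()] adds to the propulsion.  The default returns 0 for
#' every angle (no bias); supply any finite-valued function to explore
#' bias-driven co-rotation scenarios.
#'
#' @param theta Propulsion angle (rad).
#' @return Tangential bias magnitude; 0 by default.
#' @export
bias_hook <- function(theta) {
  rep(0, length(theta))
}
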