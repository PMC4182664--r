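# Strike kinematics of the forelimb-powered Class 1 lever bite.
#
# The strike is a single rigid anterior rotation of the neck-and-skull
# unit about the fixed virtual point (the center of the maxillary canine
# curvature, slightly anteroventral to the TMJ), while the mandible --
# pinned against the prey -- translates without changing orientation so
# that its TMJ attachment tracks the cranium's TMJ.  Because the
# rotation center is the canine curvature center, the canine tip traces
# its own curvature circle and enters tissue along its long axis; and
# because the cranium turns by phi while the mandible's orientation is
# constant, the gape closes by exactly phi.

# low-level: advance the strike by phi (anterior positive; negative phi
# is the withdrawal phase)
#' Apply a strike rotation
#'
#' Rotates the neck and cranium anteriorly by `phi_deg` about the fixed
#' virtual point and translates the mandible so it stays attached at the
#' TMJ with its orientation preserved.  Negative `phi_deg` is the
#' withdrawal phase; strike followed by equal withdrawal restores the
#' starting configuration.
#'
#' @param config A `skull_config` containing `VIRTUAL_POINT`.
#' @param phi_deg Strike progress in degrees, anterior positive.
#' @return The transformed `skull_config`.
#' @export
apply_strike <- function(config, phi_deg) {
  validate_skull(config, tol = Inf)
  if (!is.numeric(phi_deg) || !is.finite(phi_deg))
    stop_domain("phi_deg must be finite")
  lm <- config$landmarks
  if (!("VIRTUAL_POINT" %in% rownames(lm)))
    stop_lookup("configuration has no VIRTUAL_POINT landmark")
  vp <- lm["VIRTUAL_POINT", ]
  unit_lms <- setdiff(names(CHAIN_RANK), "VIRTUAL_POINT")
  tmj0 <- lm["TMJ", ]
  lm[unit_lms, ] <- rotate_about(lm[unit_lms, , drop = FALSE], vp,
                                 -phi_deg)   # anterior = clockwise
  shift <- lm["TMJ", ] - tmj0
  lm[MANDIBLE_LANDMARKS, ] <- sweep(lm[MANDIBLE_LANDMARKS, , drop = FALSE],
                                    2L, shift, "+")
  new_skull_config(lm, config$segments)
}

#' Compute a strike trajectory
#'
#' Samples the strike at `steps + 1` equally spaced progress values
#' `phi in {0, ..., total_angle_deg}`.  At every state the canine tip
#' lies on the circle about the virtual point at its initial radius, the
#' mandible orientation is unchanged, and the gape equals the initial
#' gape minus `phi`.
#'
#' @param config The starting `skull_config` (typically the bulldogging
#'   posture at 90 degrees gape).
#' @param total_angle_deg Total strike arc, degrees; must be positive
#'   and no greater than the initial gape (the jaws cannot over-close).
#' @param steps Number of increments, >= 1.
#' @return An object of class `strike_trajectory`: list with `phi_deg`
#'   (numeric vector), `gape_deg`, `tip_trace` ((steps+1) x 2 matrix of
#'   upper canine tip positions), `virtual_point`, `tip_radius_mm`,
#'   `states` (list of `skull_config`s).
#' @examples
#' traj <- strike_trajectory(generate_skull(skull_preset("bulldogging")),
#'                           90, steps = 9)
#' range(traj$gape_deg) # 0 .. 90
#' @export
strike_trajectory <- function(config, total_angle_deg, steps = 90) {
  validate_skull(config, tol = Inf)
  gape0 <- measure_gape(config)
  if (!is.numeric(total_angle_deg) || !is.finite(total_angle_deg) ||
      total_angle_deg <= 0)
    stop_domain("total_angle_deg must be positive")
  if (total_angle_deg > gape0 + 1e-9)
    stop_domain(sprintf(paste0("over-closure: strike arc %.3f deg exceeds ",
                               "the initial gape %.3f deg"),
                        total_angle_deg, gape0))
  if (!is.numeric(steps) || steps < 1)
    stop_domain("steps must be >= 1")
  steps <- as.integer(steps)
  phi <- seq(0, total_angle_deg, length.out = steps + 1L)
  states <- lapply(phi, function(a) apply_strike(config, a))
  tips <- t(vapply(states,
                   function(s) s$landmarks["UPPER_CANINE_TIP", ],
                   numeric(2L)))
  colnames(tips) <- c("x", "y")
  vp <- config$landmarks["VIRTUAL_POINT", ]
  structure(list(phi_deg = phi,
                 gape_deg = vapply(states, measure_gape, numeric(1L)),
                 tip_trace = tips,
                 virtual_point = vp,
                 tip_radius_mm = vnorm(
                   config$landmarks["UPPER_CANINE_TIP", ] - vp),
                 states = states),
            class = "strike_trajectory")
}

#' Tangency error of the canine-tip trace
#'
#' Maximum angle (degrees) between each finite-difference step of the
#' canine-tip trace and the local tangent of the curvature circle at the
#' step's starting point.  For exact circular motion this is half the
#' per-step arc, so it vanishes as the trajectory is refined: the canine
#' traverses tissue along its own long axis.
#'
#' @param traj A `strike_trajectory` with at least 2 states.
#' @return Maximum tangency error in degrees.
#' @export
tip_tangency_error <- function(traj) {
  stopifnot(inherits(traj, "strike_trajectory"))
  n <- nrow(traj$tip_trace)
  if (n < 2L) stop_domain("tangency error needs at least 2 states")
  vp <- traj$virtual_point
  errs <- vapply(seq_len(n - 1L), function(i) {
    chord <- traj$tip_trace[i + 1L, ] - traj$tip_trace[i, ]
    if (vnorm(chord) == 0) return(0)
    radial <- traj$tip_trace[i, ] - vp
    tangent <- c(radial[2], -radial[1])   # direction of anterior motion
    rad2deg(atan2(abs(cross2(tangent, chord)), sum(tangent * chord)))
  }, numeric(1L))
  max(errs)
}

#' Penetration depth of the canine tip past the hide line
#'
#' Signed perpendicular distance of the upper canine tip past a straight
#' line modeling the prey-neck entry surface; positive means the tip has
#' penetrated (moved to the `inward` side of the line).
#'
#' @param state A `skull_config` (e.g. one element of
#'   `strike_trajectory()$states`) or a length-2 tip position.
#' @param line_point A point on the hide line.
#' @param line_dir Nonzero direction of the hide line.
#' @param inward Optional vector pointing into the prey; defaults to the
#'   left normal of `line_dir`.
#' @return Signed depth in mm.
#' @export
penetration_depth <- function(state, line_point, line_dir, inward = NULL) {
  tip <- if (inherits(state, "skull_config")) {
    if (!("UPPER_CANINE_TIP" %in% rownames(state$landmarks)))
      stop_lookup("configuration has no UPPER_CANINE_TIP landmark")
    state$landmarks["UPPER_CANINE_TIP", ]
  } else as_pt(state, "canine tip")
  line_point <- as_pt(line_point, "line point")
  d <- unit_vec(line_dir, "hide line direction")
  n_hat <- c(-d[2], d[1])
  if (!is.null(inward)) {
    inward <- unit_vec(inward, "inward normal")
    if (abs(sum(inward * d)) > 1e-9)
      stop_domain("inward normal must be perpendicular to the hide line")
    n_hat <- inward
  }
  unname(sum((tip - line_point) * n_hat))
}

#' @export
print.strike_trajectory <- function(x, ...) {
  cat(sprintf(paste0("Strike trajectory: %d states over %.2f deg; gape ",
                     "%.2f -> %.2f deg\n"),
              length(x$phi_deg), max(x$phi_deg) - min(x$phi_deg),
              x$gape_deg[1], x$gape_deg[length(x$gape_deg)]))
  cat(sprintf("  canine tip radius about the virtual point: %.3f mm\n",
              x$tip_radius_mm))
  invisible(x)
}

#' Strike trajectory table
#'
#' @param traj A `strike_trajectory`.
#' @param hide_point,hide_dir,inward Optional hide line (see
#'   [penetration_depth()]); if given, a `penetration_mm` column is
#'   added.
#' @return A data frame with columns `phi_deg`, `gape_deg`, `tip_x_mm`,
#'   `tip_y_mm` and optionally `penetration_mm`.
#' @export
strike_table <- function(traj, hide_point = NULL, hide_dir = NULL,
                         inward = NULL) {
  stopifnot(inherits(traj, "strike_trajectory"))
  out <- data.frame(phi_deg = traj$phi_deg, gape_deg = traj$gape_deg,
                    tip_x_mm = traj$tip_trace[, 1],
                    tip_y_mm = traj$tip_trace[, 2])
  if (!is.null(hide_point)) {
    out$penetration_mm <- apply(traj$tip_trace, 1L, penetration_depth,
                                line_point = hide_point,
                                line_dir = hide_dir, inward = inward)
  }
  out
}
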