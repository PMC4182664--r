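# Pivot rotation experiments on the articulated neck-cranium-mandible
# chain.  The core experiment rotates the neck-and-skull unit ventrally
# at one of four pivots (caudal neck, mid-neck, AOJ, TMJ) under one of
# three mandible policies, and asks whether the TMJ -- and hence a
# mandible pinned against the prey -- can remain stationary.  Only
# rotation at the TMJ itself leaves the TMJ in place; at every other
# pivot the TMJ is translated along a chord of length
# 2 * r * sin(arc / 2), which falsifies neck-powered jaw closure with a
# stationary mandible.

ROTATION_PIVOTS <- c("CAUDAL_NECK", "MID_NECK", "AOJ", "TMJ")
MANDIBLE_POLICIES <- c("FIXED_TO_CRANIUM", "FREE_RETURN_TO_VERTICAL",
                       "STATIONARY_MANDIBLE")

#' Define a rotation trial
#'
#' @param pivot One of `"CAUDAL_NECK"`, `"MID_NECK"`, `"AOJ"`, `"TMJ"`.
#' @param arc_deg Ventral arc of rotation in degrees, positive (the
#'   experiment's arbitrarily chosen arc is 15).
#' @param policy Mandible policy: `"FIXED_TO_CRANIUM"` (mandible held in
#'   constant position relative to the cranium),
#'   `"FREE_RETURN_TO_VERTICAL"` (mandible then rotates freely at the
#'   TMJ back to vertical), or `"STATIONARY_MANDIBLE"` (mandible must
#'   not move; feasibility is judged by whether the TMJ stayed put).
#' @return An object of class `rotation_trial`.
#' @export
rotation_trial <- function(pivot, arc_deg = 15,
                           policy = c("FIXED_TO_CRANIUM",
                                      "FREE_RETURN_TO_VERTICAL",
                                      "STATIONARY_MANDIBLE")) {
  policy <- match.arg(policy)
  if (!is.character(pivot) || length(pivot) != 1L ||
      !(pivot %in% ROTATION_PIVOTS))
    stop_lookup(sprintf("pivot must be one of %s",
                        paste(ROTATION_PIVOTS, collapse = ", ")))
  if (!is.numeric(arc_deg) || !is.finite(arc_deg) || arc_deg <= 0)
    stop_domain("arc_deg must be a positive finite angle")
  structure(list(pivot = pivot, arc_deg = arc_deg, policy = policy),
            class = "rotation_trial")
}

# rotate every landmark of `lm` whose chain rank exceeds the pivot's
# about the pivot point (mandible landmarks excluded; handled by policy)
rotate_chain <- function(lm, pivot, angle_deg) {
  center <- lm[pivot, ]
  moving <- names(CHAIN_RANK)[CHAIN_RANK > CHAIN_RANK[[pivot]]]
  moving <- intersect(rownames(lm), moving)
  if (length(moving))
    lm[moving, ] <- rotate_about(lm[moving, , drop = FALSE], center,
                                 angle_deg)
  lm
}

#' Apply a rotation trial to a configuration
#'
#' Rotates the neck-and-skull unit ventrally by `trial$arc_deg` about
#' the pivot: every landmark rostral to the pivot along the articulated
#' chain moves; the pivot and everything caudal of it stay fixed.  The
#' mandible follows the trial policy; under `STATIONARY_MANDIBLE` it is
#' left untouched and the trial is feasible only if the TMJ displacement
#' stays below the stationarity tolerance.
#'
#' @param config A `skull_config`.
#' @param trial A `rotation_trial`.
#' @param stationarity_tol Stationarity threshold relative to the
#'   configuration's characteristic length; default `1e-6`.  The
#'   published judgement ("the TMJ remained stationary") was visual, so
#'   a numeric threshold is required here.
#' @return An object of class `experiment_result`: list with
#'   `transformed` (the resulting `skull_config`), `trial`,
#'   `tmj_displacement` (length-2 vector, mm), `tmj_disp_mm`
#'   (magnitude), `mandible_return_deg` (dorsal rotation restoring the
#'   mandible to vertical; `NA` unless the policy is free return),
#'   `mandible_angle_after_deg` (unsigned degrees from vertical),
#'   `feasible` and `infeasibility_reason`.
#' @examples
#' cfg <- generate_skull(skull_preset("bulldogging"))
#' r <- apply_trial(cfg, rotation_trial("CAUDAL_NECK", 15,
#'                                      "FREE_RETURN_TO_VERTICAL"))
#' r$mandible_return_deg # 15
#' @export
apply_trial <- function(config, trial, stationarity_tol = 1e-6) {
  validate_skull(config, tol = Inf)   # structural checks only
  if (!inherits(trial, "rotation_trial"))
    stop_domain("trial must be a rotation_trial object")
  lm0 <- config$landmarks
  if (!(trial$pivot %in% rownames(lm0)))
    stop_lookup(sprintf("pivot landmark '%s' not in configuration",
                        trial$pivot))
  internal_angle <- -trial$arc_deg    # ventral = clockwise
  pivot_pt <- lm0[trial$pivot, ]

  lm <- rotate_chain(lm0, trial$pivot, internal_angle)
  tmj_new <- lm["TMJ", ]
  mandible_return <- NA_real_

  if (trial$policy %in% c("FIXED_TO_CRANIUM", "FREE_RETURN_TO_VERTICAL")) {
    # mandible rides with the cranium: same rotation, then reattach to
    # the (possibly displaced) TMJ
    lm[MANDIBLE_LANDMARKS, ] <-
      rotate_about(lm0[MANDIBLE_LANDMARKS, , drop = FALSE], pivot_pt,
                   internal_angle)
    if (trial$policy == "FREE_RETURN_TO_VERTICAL") {
      interim <- new_skull_config(lm, config$segments)
      tilt <- measure_mandible_angle(interim)   # signed, CCW positive
      mandible_return <- -tilt                  # dorsal (CCW) restoring turn
      lm[MANDIBLE_LANDMARKS, ] <-
        rotate_about(lm[MANDIBLE_LANDMARKS, , drop = FALSE], tmj_new,
                     mandible_return)
    }
  }
  # STATIONARY_MANDIBLE: mandible rows of lm are already the originals

  out <- new_skull_config(lm, config$segments)
  disp <- tmj_new - lm0["TMJ", ]
  disp_mm <- vnorm(disp)

  feasible <- TRUE
  reason <- ""
  if (trial$policy == "STATIONARY_MANDIBLE") {
    tol_mm <- stationarity_tol * characteristic_length(config)
    feasible <- disp_mm <= tol_mm
    if (!feasible)
      reason <- sprintf(paste0("TMJ translated %.3f mm (> %.3g mm): the ",
                               "neck-and-skull unit cannot rotate at %s ",
                               "while the mandible stays stationary"),
                        disp_mm, tol_mm, trial$pivot)
  }

  structure(list(transformed = out, trial = trial,
                 tmj_displacement = disp, tmj_disp_mm = disp_mm,
                 mandible_return_deg = mandible_return,
                 mandible_angle_after_deg = abs(measure_mandible_angle(out)),
                 feasible = feasible, infeasibility_reason = reason),
            class = "experiment_result")
}

#' Gape after a trial
#'
#' @param result An `experiment_result`.
#' @return Gape of the transformed configuration, degrees.
#' @export
gape_after_trial <- function(result) {
  if (!inherits(result, "experiment_result"))
    stop_domain("result must be an experiment_result")
  measure_gape(result$transformed)
}

#' Four-pivot experiment table
#'
#' Runs one trial per pivot at the given arc and policy and tabulates
#' the TMJ displacement, mandible return rotation, resulting gape and
#' feasibility verdict.
#'
#' @param config A `skull_config`.
#' @param arc_deg Ventral arc in degrees.
#' @param policy Mandible policy (see [rotation_trial()]).
#' @param stationarity_tol Passed to [apply_trial()].
#' @return A data frame with one row per pivot and columns `pivot`,
#'   `policy`, `arc_deg`, `tmj_dx_mm`, `tmj_dy_mm`, `tmj_disp_mm`,
#'   `mandible_return_deg`, `gape_after_deg`, `feasible`.
#' @export
experiment_table <- function(config, arc_deg = 15,
                             policy = "STATIONARY_MANDIBLE",
                             stationarity_tol = 1e-6) {
  rows <- lapply(ROTATION_PIVOTS, function(pv) {
    r <- apply_trial(config, rotation_trial(pv, arc_deg, policy),
                     stationarity_tol = stationarity_tol)
    data.frame(pivot = pv, policy = policy, arc_deg = arc_deg,
               tmj_dx_mm = r$tmj_displacement[1],
               tmj_dy_mm = r$tmj_displacement[2],
               tmj_disp_mm = r$tmj_disp_mm,
               mandible_return_deg = r$mandible_return_deg,
               gape_after_deg = gape_after_trial(r),
               feasible = r$feasible,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Stationary-mandible feasibility across the four pivots
#'
#' The falsification table: for each pivot, can the neck-and-skull unit
#' rotate ventrally by `arc_deg` while the mandible (and hence the TMJ,
#' to which it is articulated) remains stationary?  For any valid
#' configuration with distinct pivots the answer is no at the caudal
#' neck, mid-neck and AOJ -- the TMJ is carried along a chord -- and yes
#' only at the TMJ itself (a rotation about a point fixes that point).
#'
#' @inheritParams experiment_table
#' @return The four-row data frame of [experiment_table()] under the
#'   `STATIONARY_MANDIBLE` policy.
#' @examples
#' feasibility_table(generate_skull(skull_preset("bulldogging")), 15)
#' @export
feasibility_table <- function(config, arc_deg = 15,
                              stationarity_tol = 1e-6) {
  experiment_table(config, arc_deg, "STATIONARY_MANDIBLE",
                   stationarity_tol)
}

#' Rotate the cranium alone at the TMJ
#'
#' Anterior rotation of the cranium about the jaw joint against a
#' stationary mandible and neck -- the only cranial rotation that closes
#' the jaws (gape decreases by exactly the arc).
#'
#' @param config A `skull_config`.
#' @param arc_deg Anterior arc in degrees (positive closes the jaws).
#' @return The transformed `skull_config`.
#' @export
rotate_cranium <- function(config, arc_deg) {
  validate_skull(config, tol = Inf)
  if (!is.numeric(arc_deg) || !is.finite(arc_deg))
    stop_domain("arc_deg must be finite")
  lm <- config$landmarks
  cranial <- names(CHAIN_RANK)[CHAIN_RANK > CHAIN_RANK[["TMJ"]]]
  lm[cranial, ] <- rotate_about(lm[cranial, , drop = FALSE], lm["TMJ", ],
                                -arc_deg)   # anterior = clockwise
  new_skull_config(lm, config$segments)
}

#' @export
print.experiment_result <- function(x, ...) {
  cat(sprintf("Rotation trial: pivot %s, arc %.2f deg ventral, policy %s\n",
              x$trial$pivot, x$trial$arc_deg, x$trial$policy))
  cat(sprintf("  TMJ displacement: %.3f mm (dx %.3f, dy %.3f)\n",
              x$tmj_disp_mm, x$tmj_displacement[1], x$tmj_displacement[2]))
  if (!is.na(x$mandible_return_deg))
    cat(sprintf("  mandible return rotation: %.3f deg dorsal\n",
                x$mandible_return_deg))
  cat(sprintf("  mandible %.3f deg from vertical; feasible: %s\n",
              x$mandible_angle_after_deg, x$feasible))
  if (nzchar(x$infeasibility_reason))
    cat("  ", x$infeasibility_reason, "\n", sep = "")
  invisible(x)
}
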