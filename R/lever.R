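# Jaw lever mechanics: in-lever, out-lever, mechanical advantage,
# lever-class identification, and the three named bite levers.
#
# Forces are modeled geometrically as a point of application plus a line
# of action; magnitudes are out of scope (the comparison is about
# geometry, not Newtons).  The in-lever is the perpendicular distance
# from the effort line of action to the fulcrum, the out-lever the
# perpendicular distance from the resistance line of action to the
# fulcrum, and the mechanical advantage MA = in-lever / out-lever.

#' Construct a lever system
#'
#' @param fulcrum Length-2 point (mm).
#' @param force_point Point of application of the effort force.
#' @param force_dir Nonzero direction of the effort line of action.
#' @param resist_point Point of application of the resistance.
#' @param resist_dir Nonzero direction of the resistance line of action.
#' @param label Optional label.
#' @return An object of class `lever_system`.
#' @export
lever_system <- function(fulcrum, force_point, force_dir,
                         resist_point, resist_dir, label = "") {
  fulcrum <- as_pt(fulcrum, "fulcrum")
  force_point <- as_pt(force_point, "force point")
  resist_point <- as_pt(resist_point, "resistance point")
  force_dir <- unit_vec(force_dir, "force direction")
  resist_dir <- unit_vec(resist_dir, "resistance direction")
  if (vnorm(force_point - fulcrum) == 0 ||
      vnorm(resist_point - fulcrum) == 0)
    stop_domain("application points must be distinct from the fulcrum")
  structure(list(fulcrum = fulcrum,
                 force_point = force_point, force_dir = force_dir,
                 resist_point = resist_point, resist_dir = resist_dir,
                 label = label),
            class = "lever_system")
}

#' In-lever length
#'
#' Perpendicular distance from the effort line of action to the fulcrum.
#'
#' @param lever A `lever_system`.
#' @return Length in mm (non-negative).
#' @export
in_lever <- function(lever) {
  stopifnot(inherits(lever, "lever_system"))
  perpendicular_distance(lever$fulcrum, lever$force_point, lever$force_dir)
}

#' Out-lever length
#'
#' Perpendicular distance from the resistance line of action to the
#' fulcrum.
#'
#' @param lever A `lever_system`.
#' @return Length in mm (non-negative).
#' @export
out_lever <- function(lever) {
  stopifnot(inherits(lever, "lever_system"))
  perpendicular_distance(lever$fulcrum, lever$resist_point,
                         lever$resist_dir)
}

#' Mechanical advantage
#'
#' `MA = in-lever / out-lever`.
#'
#' @param lever A `lever_system` with positive out-lever.
#' @return Dimensionless ratio.
#' @export
mechanical_advantage <- function(lever) {
  ol <- out_lever(lever)
  if (ol == 0)
    stop_domain("out-lever is zero: the resistance line passes through the fulcrum")
  in_lever(lever) / ol
}

#' Classify a lever as Class 1, 2 or 3
#'
#' Projects the fulcrum and the two application points onto the lever
#' axis (the line through the force and resistance application points).
#' Class 1 if the fulcrum projects between force and resistance, Class 2
#' if the resistance is in the middle, Class 3 if the force is.
#'
#' @param lever A `lever_system`.
#' @param tol Relative tolerance for coincident projections, default
#'   `1e-9` of the force-resistance span.
#' @return Integer 1, 2 or 3.
#' @export
classify_lever <- function(lever, tol = 1e-9) {
  stopifnot(inherits(lever, "lever_system"))
  axis <- lever$resist_point - lever$force_point
  span <- vnorm(axis)
  if (span == 0)
    stop_domain("ambiguous lever: force and resistance applied at the same point")
  ax <- axis / span
  s <- c(force = 0,
         resistance = span,
         fulcrum = sum((lever$fulcrum - lever$force_point) * ax))
  if (min(stats::dist(matrix(s))) <= tol * span)
    stop_domain("ambiguous lever: coincident projections on the lever axis")
  middle <- names(sort(s))[2L]
  switch(middle, fulcrum = 1L, resistance = 2L, force = 3L)
}

#' Build one of the named bite levers from a configuration
#'
#' * `shear_bite`: the neck-powered canine bite as a lever -- fulcrum at
#'   the AOJ, effort from the ventral neck flexors applied between the
#'   AOJ and the canine tips (modeled at the AOJ-TMJ midpoint, directed
#'   ventrally), resistance at the upper canine tip.  A Class 3 lever.
#' * `c1lm`: the forelimb-powered Class 1 lever -- fulcrum at the TMJ,
#'   effort applied dorsally at the caudal neck force point, resistance
#'   at the upper canine tip.  A Class 1 lever.
#' * `mandibular_bite`: the conventional jaw-adductor bite -- fulcrum at
#'   the TMJ, effort at the coronoid process along the modeled
#'   temporalis line of action (only the temporalis is considered),
#'   same resistance.
#'
#' The resistance line of action is modeled normal to the fulcrum-to-
#' bite-point radius, so the out-lever equals the distance from the
#' fulcrum to the bite point; `c1lm` and `mandibular_bite` therefore
#' share fulcrum and out-lever exactly, and their MA ratio equals the
#' ratio of their in-levers.
#'
#' @param config A `skull_config`.
#' @param name One of `"shear_bite"`, `"c1lm"`, `"mandibular_bite"`.
#' @param bite_point Landmark name of the resistance point; defaults to
#'   `"UPPER_CANINE_TIP"`, but the compressive bite point may be placed
#'   more posteriorly in the mouth.
#' @param temporalis_attachment Optional length-2 point for the cranial
#'   attachment of the temporalis; by default a point 30 mm caudal and
#'   50 mm dorsal of the TMJ in the cranium frame (documented plumbing:
#'   no measured attachment exists).
#' @param shear_force_point Optional application point for the ventral
#'   neck flexors; default is the AOJ-TMJ midpoint.
#' @return A `lever_system`.
#' @export
build_named_lever <- function(config,
                              name = c("c1lm", "shear_bite",
                                       "mandibular_bite"),
                              bite_point = "UPPER_CANINE_TIP",
                              temporalis_attachment = NULL,
                              shear_force_point = NULL) {
  name <- match.arg(name)
  lm <- config$landmarks
  need <- c("AOJ", "TMJ", "NECK_FORCE_POINT", "CORONOID_PROCESS",
            "UPPER_INCISOR_TIP", bite_point)
  missing <- setdiff(need, rownames(lm))
  if (length(missing))
    stop_lookup(paste0("missing landmarks: ", paste(missing, collapse = ", ")))
  bite <- lm[bite_point, ]
  resist_normal <- function(fulcrum) {
    r <- bite - fulcrum
    if (vnorm(r) == 0) stop_domain("bite point coincides with the fulcrum")
    c(-r[2], r[1]) / vnorm(r)
  }
  switch(name,
    c1lm = lever_system(
      fulcrum = lm["TMJ", ],
      force_point = lm["NECK_FORCE_POINT", ], force_dir = c(0, 1),
      resist_point = bite, resist_dir = resist_normal(lm["TMJ", ]),
      label = "c1lm"),
    shear_bite = {
      fp <- if (is.null(shear_force_point))
        (lm["AOJ", ] + lm["TMJ", ]) / 2 else as_pt(shear_force_point)
      lever_system(
        fulcrum = lm["AOJ", ],
        force_point = fp, force_dir = c(0, -1),
        resist_point = bite, resist_dir = resist_normal(lm["AOJ", ]),
        label = "shear_bite")
    },
    mandibular_bite = {
      fr <- cranium_frame(lm)
      att <- if (is.null(temporalis_attachment))
        lm["TMJ", ] - 30 * fr$u + 50 * fr$w else as_pt(temporalis_attachment)
      lever_system(
        fulcrum = lm["TMJ", ],
        force_point = lm["CORONOID_PROCESS", ],
        force_dir = att - lm["CORONOID_PROCESS", ],
        resist_point = bite, resist_dir = resist_normal(lm["TMJ", ]),
        label = "mandibular_bite")
    })
}

#' Lever report for the three named bite mechanisms
#'
#' @param config A `skull_config`.
#' @param bite_point Passed to [build_named_lever()].
#' @return A data frame with columns `label`, `class`, `in_lever_mm`,
#'   `out_lever_mm`, `MA`.
#' @export
lever_report <- function(config, bite_point = "UPPER_CANINE_TIP") {
  rows <- lapply(c("shear_bite", "c1lm", "mandibular_bite"), function(nm) {
    lv <- build_named_lever(config, nm, bite_point = bite_point)
    data.frame(label = nm, class = classify_lever(lv),
               in_lever_mm = in_lever(lv), out_lever_mm = out_lever(lv),
               MA = mechanical_advantage(lv), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert a pressure from mm Hg to N/mm^2
#'
#' `1 mm Hg = 133.322 Pa = 133.322e-6 N/mm^2`.  Carotid arteries
#' collapse at roughly 120 mm Hg (about 0.016 N/mm^2), the resting
#' systolic blood pressure of a horse.
#'
#' @param p Pressure in mm Hg, non-negative.
#' @return Pressure in N/mm^2.
#' @examples
#' mmHg_to_N_per_mm2(120) # ~0.016
#' @export
mmHg_to_N_per_mm2 <- function(p) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0))
    stop_domain("pressure must be finite and non-negative")
  p * 133.322e-6
}

#' @export
print.lever_system <- function(x, ...) {
  cat(sprintf("Lever system%s: Class %d\n",
              if (nzchar(x$label)) paste0(" '", x$label, "'") else "",
              classify_lever(x)))
  cat(sprintf("  in-lever %.2f mm, out-lever %.2f mm, MA %.4f\n",
              in_lever(x), out_lever(x), mechanical_advantage(x)))
  invisible(x)
}
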