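# Synthetic landmark generator for the neck-cranium-mandible chain.
#
# The generator emulates a lateral-view (sagittal) landmark digitization
# of a sabertooth skull posed for the bite experiments: cranium extended
# at the atlantooccipital joint (AOJ), mandible hanging vertically at a
# 90 degree gape, four collinear-chain pivots along the neck, and the
# maxillary canine lying on a circle whose center (the "virtual point")
# sits slightly anteroventral to the jaw joint (TMJ).  No published
# measurements exist for the absolute dimensions, so the defaults below
# are documented, configurable plumbing; every property the package
# tests holds for any valid parameter set.

#' Canonical landmark names, in TPS file order
#'
#' The twelve named landmarks of a skull configuration.  Positional
#' formats (TPS) use exactly this order.
#' @export
SKULL_LANDMARKS <- c(
  "CAUDAL_NECK", "MID_NECK", "AOJ", "TMJ",
  "UPPER_INCISOR_TIP", "LOWER_INCISOR_TIP",
  "UPPER_CANINE_BASE", "UPPER_CANINE_TIP", "LOWER_CANINE_TIP",
  "CORONOID_PROCESS", "VIRTUAL_POINT", "NECK_FORCE_POINT"
)

# segment membership of each landmark
SKULL_SEGMENTS <- c(
  CAUDAL_NECK = "neck", MID_NECK = "neck", AOJ = "neck",
  TMJ = "cranium", UPPER_INCISOR_TIP = "cranium",
  UPPER_CANINE_BASE = "cranium", UPPER_CANINE_TIP = "cranium",
  LOWER_INCISOR_TIP = "mandible", LOWER_CANINE_TIP = "mandible",
  CORONOID_PROCESS = "mandible",
  VIRTUAL_POINT = "derived", NECK_FORCE_POINT = "neck"
)

# position along the caudal -> rostral articulated chain; landmarks with
# rank greater than a pivot's rank move when the unit rotates at that
# pivot (mandible landmarks are governed by the trial policy instead).
CHAIN_RANK <- c(
  CAUDAL_NECK = 1, NECK_FORCE_POINT = 1, MID_NECK = 2, AOJ = 3, TMJ = 4,
  UPPER_INCISOR_TIP = 5, UPPER_CANINE_BASE = 5, UPPER_CANINE_TIP = 5,
  VIRTUAL_POINT = 5
)

MANDIBLE_LANDMARKS <- c("LOWER_INCISOR_TIP", "LOWER_CANINE_TIP",
                        "CORONOID_PROCESS")

#' Skull generator parameters
#'
#' Parameter set for [generate_skull()].  All lengths in mm, angles in
#' degrees.  The published experiment states the gape (90 degrees) and
#' the increment of cranial extension (+36 degrees) but no absolute
#' dimensions; the length defaults here are arbitrary, documented
#' plumbing chosen at a plausible large-felid scale.
#'
#' @param neck_caudal_mid,neck_mid_aoj Neck segment lengths along the
#'   (straight) caudal-neck to AOJ chain.
#' @param aoj_tmj Distance from the atlantooccipital joint to the jaw
#'   joint.
#' @param tmj_upper_incisor,tmj_lower_incisor Distances from the TMJ to
#'   the upper and lower incisor tips.
#' @param canine_radius Radius of the maxillary canine curvature circle.
#' @param vp_anterior,vp_ventral Offset of the virtual point (the canine
#'   curvature center) from the TMJ, measured in the cranium frame:
#'   anterior along the cranial axis and ventral perpendicular to it.
#'   Both must be positive so the virtual point is anteroventral to the
#'   TMJ.
#' @param gape Gape angle at the TMJ between the two incisor tips,
#'   degrees in `[0, 180)`.  The experimental posture uses the maximum
#'   gape of 90.
#' @param extension Absolute extension of the cranium at the AOJ,
#'   degrees; 0 means the cranial axis prolongs the straight neck chain.
#'   The experimental posture increases extension by 36 degrees from an
#'   unstated neutral, so extension is exposed as an absolute parameter
#'   with the neutral pose defined as 0.
#' @param cranial_base_angle Dorsal inclination of the TMJ-to-AOJ line
#'   relative to the (reversed) cranial axis, degrees.
#' @param canine_base_angle Position of the upper canine base on its
#'   curvature circle, degrees from the cranial axis as seen from the
#'   virtual point.
#' @param canine_sweep Arc length of the canine from base to tip on its
#'   curvature circle, degrees (the tip lies ventral of the base).
#' @param noise_sd Isotropic Gaussian digitization noise added per
#'   landmark after exact construction, mm.  The derived virtual point
#'   is never noised.
#' @param seed Optional integer seed for the noise; the generator leaves
#'   the global RNG state untouched.
#' @return An object of class `skull_params`.
#' @export
skull_params <- function(neck_caudal_mid = 120, neck_mid_aoj = 120,
                         aoj_tmj = 90,
                         tmj_upper_incisor = 180, tmj_lower_incisor = 160,
                         canine_radius = 110,
                         vp_anterior = 15, vp_ventral = 20,
                         gape = 90, extension = 36,
                         cranial_base_angle = 30,
                         canine_base_angle = 10, canine_sweep = 55,
                         noise_sd = 0, seed = NULL) {
  p <- list(neck_caudal_mid = neck_caudal_mid, neck_mid_aoj = neck_mid_aoj,
            aoj_tmj = aoj_tmj, tmj_upper_incisor = tmj_upper_incisor,
            tmj_lower_incisor = tmj_lower_incisor,
            canine_radius = canine_radius,
            vp_anterior = vp_anterior, vp_ventral = vp_ventral,
            gape = gape, extension = extension,
            cranial_base_angle = cranial_base_angle,
            canine_base_angle = canine_base_angle,
            canine_sweep = canine_sweep,
            noise_sd = noise_sd, seed = seed)
  validate_skull_params(p)
  structure(p, class = "skull_params")
}

validate_skull_params <- function(p) {
  bad <- character()
  lens <- c("neck_caudal_mid", "neck_mid_aoj", "aoj_tmj",
            "tmj_upper_incisor", "tmj_lower_incisor", "canine_radius")
  for (nm in lens) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      bad <- c(bad, sprintf("%s must be a positive finite length", nm))
  }
  for (nm in c("vp_anterior", "vp_ventral")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      bad <- c(bad, sprintf("%s must be > 0 (virtual point anteroventral to TMJ)", nm))
  }
  if (!is.numeric(p$gape) || !is.finite(p$gape) ||
      p$gape < 0 || p$gape >= 180)
    bad <- c(bad, "gape must lie in [0, 180) degrees")
  if (!is.numeric(p$extension) || !is.finite(p$extension) ||
      p$extension < 0 || p$extension >= 180)
    bad <- c(bad, "extension must lie in [0, 180) degrees")
  if (!is.finite(p$cranial_base_angle) ||
      p$cranial_base_angle <= 0 || p$cranial_base_angle >= 90)
    bad <- c(bad, "cranial_base_angle must lie in (0, 90) degrees")
  if (!is.finite(p$canine_sweep) || p$canine_sweep <= 0 ||
      p$canine_sweep >= 180)
    bad <- c(bad, "canine_sweep must lie in (0, 180) degrees")
  if (!is.numeric(p$noise_sd) || !is.finite(p$noise_sd) || p$noise_sd < 0)
    bad <- c(bad, "noise_sd must be non-negative")
  if (length(bad))
    stop_validation(paste0("invalid skull parameters:\n  - ",
                           paste(bad, collapse = "\n  - ")))
  invisible(TRUE)
}

#' Named parameter presets for the bite experiments
#'
#' * `bulldogging`: mandible vertical, maximum gape of 90 degrees,
#'   cranium extended (+36 degrees) on a straight, fully extended neck
#'   chain -- the starting posture of both bite models.
#' * `strike_end`: jaws fully closed (gape 0) after a 90-degree strike.
#' * `shear_bite_start`: alias of `bulldogging` (the two hypotheses
#'   share the starting posture).
#'
#' @param name One of `"bulldogging"`, `"strike_end"`,
#'   `"shear_bite_start"`.
#' @param ... Overrides passed on to [skull_params()].
#' @return A `skull_params` object.
#' @export
skull_preset <- function(name, ...) {
  if (!is.character(name) || length(name) != 1L)
    stop_lookup("preset name must be a single string")
  switch(name,
    bulldogging = skull_params(gape = 90, extension = 36, ...),
    shear_bite_start = skull_params(gape = 90, extension = 36, ...),
    strike_end = skull_params(gape = 0, extension = 36, ...),
    stop_lookup(sprintf("unknown preset '%s'", name))
  )
}

new_skull_config <- function(landmarks, segments = SKULL_SEGMENTS) {
  structure(list(landmarks = landmarks,
                 segments = segments[rownames(landmarks)]),
            class = "skull_config")
}

# cranium frame unit vectors of a configuration: axis (TMJ -> upper
# incisor, "anterior") and its left normal ("dorsal")
cranium_frame <- function(lm) {
  u <- unit_vec(lm["UPPER_INCISOR_TIP", ] - lm["TMJ", ], "cranial axis")
  list(u = u, w = c(-u[2], u[1]))
}

#' Generate a skull configuration
#'
#' Constructs the twelve named landmarks exactly from the parameters:
#' the mandible axis (TMJ to lower incisor tip) is vertical (straight
#' ventral), the cranial axis is opened from it by the gape angle, the
#' AOJ sits caudodorsal to the TMJ, and the straight neck chain leaves
#' the AOJ at the requested extension angle.  The canine base and tip
#' lie exactly on the circle of radius `canine_radius` centered on the
#' virtual point.  Optional seeded Gaussian noise is added afterwards to
#' every digitized (non-derived) landmark.
#'
#' @param params A `skull_params` object (default: the bulldogging
#'   posture).
#' @return An object of class `skull_config`: a list with `landmarks`
#'   (12 x 2 matrix, mm) and `segments` (named character vector).
#' @examples
#' cfg <- generate_skull(skull_preset("bulldogging"))
#' measure_gape(cfg) # 90
#' @export
generate_skull <- function(params = skull_params()) {
  if (!inherits(params, "skull_params"))
    params <- do.call(skull_params, as.list(params))
  p <- params

  tmj <- c(0, 0)
  m_dir <- c(0, -1)                              # mandible axis, vertical
  u <- rotate_about(m_dir, c(0, 0), p$gape)      # cranial axis
  w <- c(-u[2], u[1])                            # cranium dorsal normal
  p_m <- c(-m_dir[2], m_dir[1])                  # mandible anterior normal

  lower_incisor <- tmj + p$tmj_lower_incisor * m_dir
  upper_incisor <- tmj + p$tmj_upper_incisor * u
  lower_canine <- tmj + 0.92 * p$tmj_lower_incisor * m_dir + 8 * p_m
  coronoid <- tmj + 40 * m_dir + 30 * p_m

  vpoint <- tmj + p$vp_anterior * u - p$vp_ventral * w
  ang_u <- atan2(u[2], u[1])
  th_b <- ang_u + deg2rad(p$canine_base_angle)
  th_t <- th_b - deg2rad(p$canine_sweep)
  canine_base <- vpoint + p$canine_radius * c(cos(th_b), sin(th_b))
  canine_tip <- vpoint + p$canine_radius * c(cos(th_t), sin(th_t))

  d <- rotate_about(-u, c(0, 0), -p$cranial_base_angle)  # TMJ -> AOJ
  aoj <- tmj + p$aoj_tmj * d
  n_dir <- rotate_about(-d, c(0, 0), -p$extension)       # rostral neck dir
  mid_neck <- aoj - p$neck_mid_aoj * n_dir
  caudal_neck <- mid_neck - p$neck_caudal_mid * n_dir
  neck_force <- caudal_neck

  lm <- rbind(CAUDAL_NECK = caudal_neck, MID_NECK = mid_neck, AOJ = aoj,
              TMJ = tmj,
              UPPER_INCISOR_TIP = upper_incisor,
              LOWER_INCISOR_TIP = lower_incisor,
              UPPER_CANINE_BASE = canine_base,
              UPPER_CANINE_TIP = canine_tip,
              LOWER_CANINE_TIP = lower_canine,
              CORONOID_PROCESS = coronoid,
              VIRTUAL_POINT = vpoint,
              NECK_FORCE_POINT = neck_force)
  colnames(lm) <- c("x", "y")
  cfg <- new_skull_config(lm)
  validate_skull(cfg)

  if (p$noise_sd > 0) {
    noisy <- setdiff(SKULL_LANDMARKS, "VIRTUAL_POINT")
    eps <- with_local_seed(p$seed,
      matrix(stats::rnorm(2L * length(noisy), sd = p$noise_sd),
             ncol = 2L))
    cfg$landmarks[noisy, ] <- cfg$landmarks[noisy, ] + eps
  }
  cfg
}

# run `expr` under a private RNG state seeded with `seed` (NULL = use
# the current stream without disturbing determinism guarantees)
with_local_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (had) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Validate a skull configuration
#'
#' Checks the structural invariants: all twelve landmarks present and
#' finite; upper canine base and tip equidistant from the virtual point;
#' virtual point anteroventral to the TMJ in the cranium frame; the neck
#' chain landmarks distinct and ordered caudal to rostral.  Tolerances
#' are relative to the characteristic length (largest pairwise landmark
#' distance); pass a larger `tol` for noisy digitizations.
#'
#' @param config A `skull_config`.
#' @param tol Relative tolerance, default `1e-9`.
#' @return `TRUE` invisibly, or an error listing every violated
#'   invariant.
#' @export
validate_skull <- function(config, tol = 1e-9) {
  if (!inherits(config, "skull_config") || !is.matrix(config$landmarks))
    stop_validation("not a skull_config object")
  lm <- config$landmarks
  missing <- setdiff(SKULL_LANDMARKS, rownames(lm))
  if (length(missing))
    stop_validation(paste0("missing required landmarks: ",
                           paste(missing, collapse = ", ")))
  dup <- rownames(lm)[duplicated(rownames(lm))]
  if (length(dup))
    stop_validation(paste0("duplicated landmarks: ",
                           paste(unique(dup), collapse = ", ")))
  if (!all(is.finite(lm)))
    stop_validation("non-finite landmark coordinates")

  bad <- character()
  L <- characteristic_length(config)
  r_base <- vnorm(lm["UPPER_CANINE_BASE", ] - lm["VIRTUAL_POINT", ])
  r_tip <- vnorm(lm["UPPER_CANINE_TIP", ] - lm["VIRTUAL_POINT", ])
  if (abs(r_base - r_tip) > tol * L)
    bad <- c(bad, "canine base and tip are not equidistant from the virtual point")
  fr <- cranium_frame(lm)
  dv <- lm["VIRTUAL_POINT", ] - lm["TMJ", ]
  if (sum(dv * fr$u) <= 0 || sum(dv * fr$w) >= 0)
    bad <- c(bad, "virtual point is not anteroventral to the TMJ")
  a <- lm["CAUDAL_NECK", ]; b <- lm["MID_NECK", ]; c_ <- lm["AOJ", ]
  d_tol <- if (is.finite(tol)) tol * L else 0   # tol = Inf: structural only
  if (vnorm(b - a) <= d_tol || vnorm(c_ - b) <= d_tol ||
      vnorm(c_ - a) <= d_tol) {
    bad <- c(bad, "neck chain landmarks are not distinct")
  } else {
    ax <- unit_vec(c_ - a)
    t_mid <- sum((b - a) * ax)
    if (t_mid <= 0 || t_mid >= vnorm(c_ - a))
      bad <- c(bad, "neck chain is not ordered caudal to rostral")
  }
  if (length(bad))
    stop_validation(paste0("invalid skull configuration:\n  - ",
                           paste(bad, collapse = "\n  - ")))
  invisible(TRUE)
}

#' Characteristic length of a configuration
#'
#' Largest pairwise distance among the landmarks; the package scales
#' its degeneracy and stationarity tolerances by this length.
#'
#' @param config A `skull_config`.
#' @return Length in mm.
#' @export
characteristic_length <- function(config) {
  max(stats::dist(config$landmarks))
}

#' Measure the gape angle
#'
#' Unsigned angle at the TMJ between the rays to the upper and lower
#' incisor tips, in `[0, 180]` degrees.
#'
#' @param config A `skull_config`.
#' @return Gape in degrees.
#' @export
measure_gape <- function(config) {
  lm <- config$landmarks
  angle_at_vertex(lm["TMJ", ], lm["UPPER_INCISOR_TIP", ],
                  lm["LOWER_INCISOR_TIP", ])
}

#' Measure the cranial extension at the AOJ
#'
#' Extension is 180 degrees minus the angle at the AOJ between the rays
#' to the mid-neck and to the TMJ; 0 means the cranial base prolongs the
#' straight neck chain.
#'
#' @param config A `skull_config`.
#' @return Extension in degrees.
#' @export
measure_extension <- function(config) {
  lm <- config$landmarks
  180 - angle_at_vertex(lm["AOJ", ], lm["MID_NECK", ], lm["TMJ", ])
}

#' Signed mandible angle from vertical
#'
#' Signed angle (degrees, counterclockwise positive) of the mandible
#' axis (TMJ to lower incisor tip) from the straight-ventral direction.
#' Zero means the mandible hangs exactly vertical, as in the bulldogging
#' posture.
#'
#' @param config A `skull_config`.
#' @return Angle in degrees, in `(-180, 180]`.
#' @export
measure_mandible_angle <- function(config) {
  lm <- config$landmarks
  v <- lm["LOWER_INCISOR_TIP", ] - lm["TMJ", ]
  if (vnorm(v) == 0) stop_domain("degenerate mandible axis")
  ref <- c(0, -1)
  unname(rad2deg(atan2(cross2(ref, v), sum(ref * v))))
}

#' Exact points on the canine curvature arc
#'
#' Samples `n` noiseless points on the maxillary canine circle between
#' the base and tip angles of the configuration built from `params`.
#' Useful for round-trip checks of [fit_circle()] against the
#' generator's virtual point and radius.
#'
#' @param params A `skull_params` object.
#' @param n Number of points, >= 2 (endpoints are the canine base and
#'   tip).
#' @return An n x 2 coordinate matrix.
#' @export
canine_arc_points <- function(params = skull_params(), n = 7) {
  if (!inherits(params, "skull_params"))
    params <- do.call(skull_params, as.list(params))
  if (n < 2) stop_domain("need at least 2 arc points")
  p <- params
  m_dir <- c(0, -1)
  u <- rotate_about(m_dir, c(0, 0), p$gape)
  w <- c(-u[2], u[1])
  vpoint <- p$vp_anterior * u - p$vp_ventral * w   # TMJ at origin
  ang_u <- atan2(u[2], u[1])
  th <- seq(ang_u + deg2rad(p$canine_base_angle),
            ang_u + deg2rad(p$canine_base_angle - p$canine_sweep),
            length.out = n)
  sweep(cbind(cos(th), sin(th)) * p$canine_radius, 2L, vpoint, "+")
}

#' @export
print.skull_config <- function(x, ...) {
  cat(sprintf("Skull configuration: %d landmarks, gape %.2f deg, extension %.2f deg\n",
              nrow(x$landmarks), measure_gape(x), measure_extension(x)))
  cat(sprintf("  mandible %.3f deg from vertical; characteristic length %.1f mm\n",
              measure_mandible_angle(x), characteristic_length(x)))
  invisible(x)
}

#' @export
print.skull_params <- function(x, ...) {
  cat("Skull generator parameters:\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-18s %s\n", nm, if (is.null(v)) "NULL" else format(v)))
  }
  invisible(x)
}
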