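# Randomized fixtures used across test files.  Every property test sets
# its own seed so runs are reproducible.

random_skull_params <- function(noise_sd = 0, seed = NULL) {
  skull_params(
    neck_caudal_mid = runif(1, 60, 200),
    neck_mid_aoj = runif(1, 60, 200),
    aoj_tmj = runif(1, 40, 150),
    tmj_upper_incisor = runif(1, 100, 250),
    tmj_lower_incisor = runif(1, 80, 220),
    canine_radius = runif(1, 60, 180),
    vp_anterior = runif(1, 5, 30),
    vp_ventral = runif(1, 5, 40),
    gape = runif(1, 30, 150),
    extension = runif(1, 1, 80),
    cranial_base_angle = runif(1, 10, 60),
    canine_base_angle = runif(1, -10, 25),
    canine_sweep = runif(1, 20, 100),
    noise_sd = noise_sd, seed = seed
  )
}

random_lever <- function() {
  repeat {
    fulcrum <- runif(2, -100, 100)
    fp <- runif(2, -100, 100)
    rp <- runif(2, -100, 100)
    ok <- sqrt(sum((fp - fulcrum)^2)) > 1 &&
      sqrt(sum((rp - fulcrum)^2)) > 1 &&
      sqrt(sum((rp - fp)^2)) > 1
    if (!ok) next
    lv <- lever_system(fulcrum, fp, runif(2, -1, 1) + c(0.01, 0.02),
                       rp, runif(2, -1, 1) + c(0.02, 0.01))
    # reject near-ambiguous projections so both routes are well posed
    ax <- (rp - fp) / sqrt(sum((rp - fp)^2))
    s <- c(0, sqrt(sum((rp - fp)^2)), sum((fulcrum - fp) * ax))
    if (min(dist(matrix(s))) > 1e-3) return(lv)
  }
}

# independent lever-class oracle: order the three projections along the
# axis through the application points and name the middle element
classify_oracle <- function(lv) {
  ax <- lv$resist_point - lv$force_point
  proj <- function(p) sum(p * ax)   # monotone in position along axis
  s <- c(force = proj(lv$force_point), resistance = proj(lv$resist_point),
         fulcrum = proj(lv$fulcrum))
  middle <- names(sort(s))[2]
  c(fulcrum = 1L, resistance = 2L, force = 3L)[[middle]]
}
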