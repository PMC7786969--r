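#' Particle population specification
#'
#' Describes the initial population of rod-like particles in the reactor
#' field of view. Lengths and widths are log-normal (median and log-sd),
#' matching the broad, right-skewed size dispersion of milled plant
#' particles; each particle's width is capped at its length so that
#' "length" is always the major axis. Orientations are uniform on
#' \[0, 180) degrees by default, or drawn from a supplied set of angles
#' (e.g. `c(0, 90)` for axis-aligned scenes where projected extents are
#' analytically known).
#'
#' @param n_particles number of particles (>= 1).
#' @param length_median_um,length_log_sd log-normal length distribution.
#' @param width_median_um,width_log_sd log-normal width distribution.
#' @param intensity_range gray-level range (within \[1, 255\]) from which
#'   per-particle intensities are drawn uniformly.
#' @param orientations `NULL` for uniform \[0, 180) degrees, or a numeric
#'   vector of angles to sample from.
#' @param fraction_recalcitrant fraction of particles in \[0, 1\] that never
#'   degrade.
#' @return A `particle_population_spec` object.
#' @export
particle_population_spec <- function(n_particles = 200,
                                     length_median_um = 250, length_log_sd = 0.6,
                                     width_median_um = 60, width_log_sd = 0.4,
                                     intensity_range = c(120, 220),
                                     orientations = NULL,
                                     fraction_recalcitrant = 0.5) {
  if (n_particles < 1 || n_particles != round(n_particles))
    stop("`n_particles` must be an integer >= 1")
  if (length_median_um <= 0 || width_median_um <= 0)
    stop("size medians must be > 0")
  if (length_log_sd < 0 || width_log_sd < 0) stop("log-sds must be >= 0")
  if (length(intensity_range) != 2 || intensity_range[1] < 1 ||
      intensity_range[2] > 255 || intensity_range[1] > intensity_range[2])
    stop("`intensity_range` must lie within [1, 255]")
  if (fraction_recalcitrant < 0 || fraction_recalcitrant > 1)
    stop("`fraction_recalcitrant` must be in [0, 1]")
  structure(list(n_particles = as.integer(n_particles),
                 length_median_um = length_median_um, length_log_sd = length_log_sd,
                 width_median_um = width_median_um, width_log_sd = width_log_sd,
                 intensity_range = intensity_range,
                 orientations = orientations,
                 fraction_recalcitrant = fraction_recalcitrant),
            class = "particle_population_spec")
}

#' Degradation scenario
#'
#' Encodes how degradable particles disappear during enzymatic hydrolysis.
#' Three elementary fates are supported, mirroring the three ways a particle
#' population can lose gray-level mass: `dissolve` (a particle vanishes
#' whole at an exponentially distributed time, leaving the survivors' size
#' distribution untouched), `shrink` (every dimension is eroded linearly at
#' `shrink_rate_um_per_h` until extinction) and `fragment` (a particle
#' splits into `k >= 2` equal-area children at an exponential time). `mixed`
#' assigns each degradable particle one of the three fates with
#' `mixture_weights`.
#'
#' The cumulative sugar-release curve is coupled to the degraded particle
#' volume (length x width^2): `sugar(t) = sugar_max_yield_pct *
#' degraded_volume(t) / initial_degradable_volume`, so it plateaus at
#' `sugar_max_yield_pct`. Fragmentation conserves mass and releases no
#' sugar.
#'
#' @param mode `"dissolve"`, `"shrink"`, `"fragment"` or `"mixed"`.
#' @param dissolve_hazard_per_h per-hour hazard of whole-particle dissolution.
#' @param shrink_rate_um_per_h linear erosion rate of each dimension, um/h.
#' @param fragment_rate_per_h per-hour hazard of fragmentation.
#' @param fragment_counts integer vector (values >= 2) of possible child
#'   counts, sampled uniformly.
#' @param sugar_max_yield_pct asymptotic sugar release, % of total sugars.
#' @param mixture_weights length-3 non-negative weights
#'   (dissolve, shrink, fragment) summing to 1; used for `mode = "mixed"`.
#' @return A `degradation_scenario` object.
#' @export
degradation_scenario <- function(mode = c("dissolve", "shrink", "fragment", "mixed"),
                                 dissolve_hazard_per_h = 0,
                                 shrink_rate_um_per_h = 0,
                                 fragment_rate_per_h = 0,
                                 fragment_counts = c(2L, 3L),
                                 sugar_max_yield_pct = 37,
                                 mixture_weights = c(dissolve = 1, shrink = 0, fragment = 0)) {
  mode <- match.arg(mode)
  if (dissolve_hazard_per_h < 0 || shrink_rate_um_per_h < 0 || fragment_rate_per_h < 0)
    stop("rates must be >= 0")
  if (any(fragment_counts < 2) || any(fragment_counts != round(fragment_counts)))
    stop("`fragment_counts` must be integers >= 2")
  if (sugar_max_yield_pct < 0 || sugar_max_yield_pct > 100)
    stop("`sugar_max_yield_pct` must be in [0, 100]")
  if (length(mixture_weights) != 3 || any(mixture_weights < 0) ||
      abs(sum(mixture_weights) - 1) > 1e-9)
    stop("`mixture_weights` must be 3 non-negative values summing to 1")
  structure(list(mode = mode,
                 dissolve_hazard_per_h = dissolve_hazard_per_h,
                 shrink_rate_um_per_h = shrink_rate_um_per_h,
                 fragment_rate_per_h = fragment_rate_per_h,
                 fragment_counts = as.integer(fragment_counts),
                 sugar_max_yield_pct = sugar_max_yield_pct,
                 mixture_weights = unname(mixture_weights)),
            class = "degradation_scenario")
}

#' Imaging configuration
#'
#' Frame geometry, acquisition schedule and noise model of the simulated
#' reactor camera. Defaults reproduce a macro-imaging setup: 1220 x 1620 px
#' monochrome frames at 8.2 um/px, 10 replicate frames per time point, and
#' an acquisition schedule densifying early (every 5 min over the first half
#' hour) then relaxing to hourly up to 7 h.
#'
#' @param height_px,width_px frame size in pixels.
#' @param pixel_size_um physical pixel size, um.
#' @param n_replicates replicate frames per time point (>= 1).
#' @param time_points_h ascending acquisition times in hours, starting at 0.
#' @param background_amplitude peak amplitude (gray levels) of the smooth
#'   background field added to each frame.
#' @param background_scale_px spatial scale of the background field; should
#'   be much larger than the tophat SE so background removal can work.
#' @param noise_sd per-pixel Gaussian noise sd, gray levels.
#' @param allow_overlap if `FALSE`, particle bounding boxes are placed
#'   without overlap (rejection sampling), making total frame mass equal the
#'   sum of per-particle masses.
#' @param seed integer seed; one pseudo-random stream drives the whole run.
#' @return An `imaging_config` object.
#' @export
imaging_config <- function(height_px = 1220, width_px = 1620, pixel_size_um = 8.2,
                           n_replicates = 10,
                           time_points_h = c(0, 5, 10, 15, 20, 25, 30, 45,
                                             60, 90, 120, 150, 180, 240,
                                             300, 360, 420) / 60,
                           background_amplitude = 20, background_scale_px = 400,
                           noise_sd = 2, allow_overlap = TRUE, seed = 1L) {
  if (pixel_size_um <= 0) stop("`pixel_size_um` must be > 0")
  if (n_replicates < 1) stop("`n_replicates` must be >= 1")
  if (any(time_points_h < 0)) stop("negative time points are not allowed")
  if (time_points_h[1] != 0 || is.unsorted(time_points_h, strictly = TRUE))
    stop("`time_points_h` must be strictly ascending and start at 0")
  if (noise_sd < 0 || background_amplitude < 0) stop("noise/background must be >= 0")
  structure(list(height_px = as.integer(height_px), width_px = as.integer(width_px),
                 pixel_size_um = pixel_size_um, n_replicates = as.integer(n_replicates),
                 time_points_h = time_points_h,
                 background_amplitude = background_amplitude,
                 background_scale_px = background_scale_px,
                 noise_sd = noise_sd, allow_overlap = isTRUE(allow_overlap),
                 seed = as.integer(seed)),
            class = "imaging_config")
}

# mean of the two axis-projected extents of a rotated L x W rectangle
projected_extent_mean <- function(L, W, theta_deg) {
  th <- theta_deg * pi / 180
  (L + W) * (abs(cos(th)) + abs(sin(th))) / 2
}

# render one particle (anti-aliased rotated rectangle) into frame matrix
render_particle <- function(frame, cx_px, cy_px, L_px, W_px, theta_deg, intensity) {
  half_diag <- sqrt(L_px^2 + W_px^2) / 2 + 1
  nr <- nrow(frame); nc <- ncol(frame)
  r0 <- max(1L, floor(cy_px - half_diag)); r1 <- min(nr, ceiling(cy_px + half_diag))
  c0 <- max(1L, floor(cx_px - half_diag)); c1 <- min(nc, ceiling(cx_px + half_diag))
  if (r0 > r1 || c0 > c1) return(frame)
  th <- theta_deg * pi / 180
  dy <- (r0:r1) - cy_px
  dx <- (c0:c1) - cx_px
  u <- outer(dy, dx, function(y, x) cos(th) * x + sin(th) * y)
  v <- outer(dy, dx, function(y, x) -sin(th) * x + cos(th) * y)
  au <- pmin(1, pmax(0, L_px / 2 - abs(u) + 0.5))
  av <- pmin(1, pmax(0, W_px / 2 - abs(v) + 0.5))
  patch <- intensity * au * av
  frame[r0:r1, c0:c1] <- pmax(frame[r0:r1, c0:c1], patch)
  frame
}

# smooth background: tilted plane + bilinearly upsampled coarse noise
background_field <- function(nr, nc, amplitude, scale_px) {
  if (amplitude <= 0) return(matrix(0, nr, nc))
  plane_cf <- runif(3, -1, 1)
  y <- seq(0, 1, length.out = nr); x <- seq(0, 1, length.out = nc)
  plane <- plane_cf[1] + outer(plane_cf[2] * y, plane_cf[3] * x, `+`)
  gr <- max(2L, ceiling(nr / scale_px) + 1L)
  gc <- max(2L, ceiling(nc / scale_px) + 1L)
  coarse <- matrix(runif(gr * gc), gr, gc)
  iy <- seq(1, gr, length.out = nr); ix <- seq(1, gc, length.out = nc)
  fy <- floor(iy); fy[fy == gr] <- gr - 1L; wy <- iy - fy
  fx <- floor(ix); fx[fx == gc] <- gc - 1L; wx <- ix - fx
  a <- (1 - wy) * coarse[fy, fx, drop = FALSE] + wy * coarse[fy + 1L, fx, drop = FALSE]
  b <- (1 - wy) * coarse[fy, fx + 1L, drop = FALSE] + wy * coarse[fy + 1L, fx + 1L, drop = FALSE]
  smooth <- sweep(a, 2, wx, function(m, w) m * (1 - w)) + sweep(b, 2, wx, function(m, w) m * w)
  f <- plane / 2 + smooth
  f <- f - min(f)
  if (max(f) > 0) f <- f / max(f)
  amplitude * f
}

#' Simulate a degrading particle suspension under time-lapse imaging
#'
#' Generates a seeded, fully ground-truth-annotated image time series: an
#' initial particle population, a per-particle degradation fate drawn up
#' front (so every replicate frame at a time point shares the same truth), a
#' coupled cumulative sugar-release curve, and rendered frames (anti-aliased
#' rotated rectangles, smooth additive background, Gaussian noise, clipped
#' to \[0, 255\]). Particle positions are redrawn per frame, emulating a
#' stirred suspension.
#'
#' @param spec a [particle_population_spec()].
#' @param scenario a [degradation_scenario()].
#' @param imaging an [imaging_config()].
#' @param render if `FALSE`, skip frame rendering and return the truth only.
#' @return A list with
#'   \describe{
#'     \item{frames}{list over time points, each a list of `n_replicates`
#'       [gray_image()] frames (when `render = TRUE`).}
#'     \item{truth}{data frame per time point: `time_h`, `n_particles`,
#'       `count_ratio` (vs T0), `mass_ratio` (relative gray-level mass, the
#'       quantity the sum-of-gray proxy estimates; equals `count_ratio` when
#'       whole identical particles disappear), `mean_length_um` and
#'       `mean_projected_um` (area-weighted over surviving particles),
#'       `total_area_um2`, `gray_mass_um2`, `sugar_pct`.}
#'     \item{particles}{per-particle fate table: initial dimensions,
#'       orientation, intensity, fate and event time.}
#'     \item{times_h}{the acquisition schedule.}
#'   }
#' @export
simulate_time_lapse <- function(spec, scenario, imaging, render = TRUE) {
  stopifnot(inherits(spec, "particle_population_spec"),
            inherits(scenario, "degradation_scenario"),
            inherits(imaging, "imaging_config"))
  frame_um <- c(imaging$height_px, imaging$width_px) * imaging$pixel_size_um
  set.seed(imaging$seed)
  n <- spec$n_particles
  L <- exp(log(spec$length_median_um) + rnorm(n, 0, spec$length_log_sd))
  W <- exp(log(spec$width_median_um) + rnorm(n, 0, spec$width_log_sd))
  W <- pmin(W, L)
  if (any(L > min(frame_um)))
    stop("particle larger than frame: reduce `length_median_um` or enlarge the frame")
  theta <- if (is.null(spec$orientations)) runif(n, 0, 180)
           else sample(rep(spec$orientations, length.out = max(n, length(spec$orientations))), n)
  intensity <- runif(n, spec$intensity_range[1], spec$intensity_range[2])
  recal <- runif(n) < spec$fraction_recalcitrant
  fate <- rep("recalcitrant", n)
  if (scenario$mode == "mixed") {
    modes <- c("dissolve", "shrink", "fragment")
    fate[!recal] <- sample(modes, sum(!recal), replace = TRUE,
                           prob = scenario$mixture_weights)
  } else fate[!recal] <- scenario$mode
  event <- rep(Inf, n)
  d <- fate == "dissolve"
  event[d] <- if (scenario$dissolve_hazard_per_h > 0)
    rexp(sum(d), scenario$dissolve_hazard_per_h) else Inf
  fr <- fate == "fragment"
  event[fr] <- if (scenario$fragment_rate_per_h > 0)
    rexp(sum(fr), scenario$fragment_rate_per_h) else Inf
  frag_k <- rep(NA_integer_, n)
  frag_k[fr] <- sample(rep(scenario$fragment_counts, length.out = max(sum(fr), 1)),
                       sum(fr), replace = TRUE)
  particles <- data.frame(id = seq_len(n), length_um = L, width_um = W,
                          orientation_deg = theta, intensity = intensity,
                          fate = fate, event_time_h = event, fragment_k = frag_k,
                          stringsAsFactors = FALSE)

  vol0 <- L * W^2
  degradable <- fate %in% c("dissolve", "shrink")
  vol_degradable <- sum(vol0[degradable])

  state_at <- function(t) {
    # matrix of surviving (possibly shrunken / fragmented) particles at time t
    out <- vector("list", n)
    for (i in seq_len(n)) {
      li <- L[i]; wi <- W[i]
      if (fate[i] == "dissolve" && t >= event[i]) next
      if (fate[i] == "shrink") {
        li <- li - scenario$shrink_rate_um_per_h * t
        wi <- wi - scenario$shrink_rate_um_per_h * t
        if (li <= 0 || wi <= 0) next
      }
      if (fate[i] == "fragment" && t >= event[i]) {
        k <- frag_k[i]
        out[[i]] <- data.frame(id = i, length_um = rep(li / k, k), width_um = wi,
                               orientation_deg = theta[i], intensity = intensity[i])
        next
      }
      out[[i]] <- data.frame(id = i, length_um = li, width_um = wi,
                             orientation_deg = theta[i], intensity = intensity[i])
    }
    do.call(rbind, out[!vapply(out, is.null, logical(1))])
  }

  sugar_at <- function(t) {
    if (vol_degradable == 0) return(0)
    rel <- 0
    for (i in which(degradable)) {
      if (fate[i] == "dissolve") {
        if (t >= event[i]) rel <- rel + vol0[i]
      } else { # shrink
        li <- max(L[i] - scenario$shrink_rate_um_per_h * t, 0)
        wi <- max(W[i] - scenario$shrink_rate_um_per_h * t, 0)
        rel <- rel + vol0[i] - li * wi^2
      }
    }
    scenario$sugar_max_yield_pct * rel / vol_degradable
  }

  times <- imaging$time_points_h
  states <- lapply(times, state_at)
  truth <- do.call(rbind, lapply(seq_along(times), function(j) {
    st <- states[[j]]
    if (is.null(st) || nrow(st) == 0)
      return(data.frame(time_h = times[j], n_particles = 0L, count_ratio = NA_real_,
                        mass_ratio = NA_real_,
                        mean_length_um = NA_real_, mean_projected_um = NA_real_,
                        total_area_um2 = 0, gray_mass_um2 = 0,
                        sugar_pct = sugar_at(times[j])))
    area <- st$length_um * st$width_um
    data.frame(time_h = times[j], n_particles = nrow(st),
               count_ratio = NA_real_,
               mass_ratio = NA_real_,
               mean_length_um = sum(st$length_um * area) / sum(area),
               mean_projected_um = sum(projected_extent_mean(
                 st$length_um, st$width_um, st$orientation_deg) * area) / sum(area),
               total_area_um2 = sum(area),
               gray_mass_um2 = sum(area * st$intensity),
               sugar_pct = sugar_at(times[j]))
  }))
  truth$count_ratio <- truth$n_particles / truth$n_particles[1]
  # relative gray-level mass (area x intensity): the quantity the image
  # proxy "sum of gray levels" actually estimates; equals count_ratio when
  # whole identical particles disappear
  truth$mass_ratio <- truth$gray_mass_um2 / truth$gray_mass_um2[1]

  frames <- NULL
  if (render) {
    px <- imaging$pixel_size_um
    nr <- imaging$height_px; nc <- imaging$width_px
    frames <- lapply(seq_along(times), function(j) {
      st <- states[[j]]
      lapply(seq_len(imaging$n_replicates), function(rep_i) {
        frame <- matrix(0, nr, nc)
        placed <- list() # AABBs for the non-overlap policy
        if (!is.null(st) && nrow(st) > 0) {
          for (i in seq_len(nrow(st))) {
            Lpx <- st$length_um[i] / px; Wpx <- st$width_um[i] / px
            th <- st$orientation_deg[i] * pi / 180
            hx <- (Lpx * abs(cos(th)) + Wpx * abs(sin(th))) / 2 + 1
            hy <- (Lpx * abs(sin(th)) + Wpx * abs(cos(th))) / 2 + 1
            ok <- FALSE
            for (try in 1:1000) {
              cx <- runif(1, hx + 1, nc - hx - 1)
              cy <- runif(1, hy + 1, nr - hy - 1)
              if (imaging$allow_overlap || !length(placed) ||
                  !any(vapply(placed, function(b)
                    cx - hx < b[2] && cx + hx > b[1] &&
                    cy - hy < b[4] && cy + hy > b[3], logical(1)))) {
                ok <- TRUE; break
              }
            }
            if (!ok) stop("could not place particle without overlap after 200 tries")
            placed[[length(placed) + 1L]] <- c(cx - hx, cx + hx, cy - hy, cy + hy)
            frame <- render_particle(frame, cx, cy, Lpx, Wpx,
                                     st$orientation_deg[i], st$intensity[i])
          }
        }
        frame <- frame + background_field(nr, nc, imaging$background_amplitude,
                                          imaging$background_scale_px)
        if (imaging$noise_sd > 0)
          frame <- frame + matrix(rnorm(nr * nc, 0, imaging$noise_sd), nr, nc)
        gray_image(pmin(pmax(frame, 0), 255), pixel_size_um = px)
      })
    })
  }
  list(frames = frames, truth = truth, particles = particles, times_h = times)
}
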