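#' Gray-level granulometry (pattern spectrum) of a particle image
#'
#' Measures the size distribution of bright particles without segmenting them.
#' The image is opened by linear structuring elements of increasing length
#' `s = step_px, 2*step_px, ...` up to `max_size_px`, at 0 and 90 degrees.
#' For each orientation the retained gray-level mass `G(s)` after each opening
#' is recorded; the granulometric density in the size bin ending at `s_i` is
#' `G(s_{i-1}) - G(s_i)` with `G(s_0)` the mass of the unopened image. The
#' final curve is the mean of the two orientation densities, so it measures
#' the distribution of the average projected length of the particles along
#' the two image axes. The opening at nominal size `s` uses an SE of `s + 1`
#' pixels, which removes objects of extent up to `s` pixels: a bar of
#' physical length `s * pixel_size_um` falls exactly in the size-`s` bin.
#' Mass surviving the largest opening (objects longer than `max_size_px`
#' in both orientations) is reported as `residual_mass`.
#'
#' Densities are computed as pixelwise difference sums between consecutive
#' openings, so the sieving property (density >= 0) holds exactly, not merely
#' to rounding.
#'
#' @param img a [gray_image()], normally tophat-preprocessed.
#' @param max_size_px largest SE length analyzed, in pixels (default 131,
#'   i.e. 1074.2 um at 8.2 um/px).
#' @param step_px SE length increment in pixels (default 2, i.e. 16.4 um).
#' @return An object of class `granulometric_curve` with fields `size_um`
#'   (ascending bin sizes, `s_px * pixel_size_um`), `density` (non-negative
#'   gray-level mass per bin), `residual_mass`, `total` (mass of the input
#'   image), `normalization` (`"none"`), `ref_total`, `pixel_size_um`,
#'   `step_px`.
#' @seealso [normalize_curve()], [graylevel_mean_size()], [size_class_masses()]
#' @export
graylevel_granulometry <- function(img, max_size_px = 131, step_px = 2) {
  stopifnot(is.matrix(img), is.numeric(img))
  if (step_px < 1 || step_px != round(step_px)) stop("`step_px` must be a positive integer")
  if (max_size_px < step_px) stop("`max_size_px` must be >= `step_px`")
  px <- if (is_gray_image(img)) pixel_size(img) else 8.2
  sizes_px <- seq(step_px, max_size_px, by = step_px)
  m <- unclass(img)
  total <- sum(m)
  dens <- numeric(length(sizes_px))
  resid <- 0
  if (total > 0) {
    dens_or <- matrix(0, length(sizes_px), 2)
    resid_or <- numeric(2)
    for (o in 1:2) {
      horizontal <- o == 1L
      prev <- m
      for (i in seq_along(sizes_px)) {
        # SE of s+1 pixels removes objects of extent <= s px, so a bar of
        # physical length s * pixel_size lands exactly in the size-s bin
        cur <- cpp_open_line(prev, as.integer(sizes_px[i]) + 1L, horizontal)
        dens_or[i, o] <- sum(prev - cur)
        prev <- cur
      }
      resid_or[o] <- sum(prev)
    }
    dens <- rowMeans(dens_or)
    resid <- mean(resid_or)
  }
  structure(list(size_um = sizes_px * px,
                 density = dens,
                 residual_mass = resid,
                 total = total,
                 normalization = "none",
                 ref_total = total,
                 pixel_size_um = px,
                 step_px = step_px),
            class = "granulometric_curve")
}

#' @export
print.granulometric_curve <- function(x, ...) {
  cat(sprintf("<granulometric_curve> %d bins, %.1f-%.1f um, normalization=%s, total mass %.4g (residual %.4g)\n",
              length(x$size_um), min(x$size_um), max(x$size_um),
              x$normalization, sum(x$density), x$residual_mass))
  invisible(x)
}

#' Normalize a granulometric curve
#'
#' Two normalizations are meaningful in a degradation time series:
#' `"self"` divides by the curve's own total gray-level mass, giving a shape
#' comparison between times, while `"T0"` divides by the total mass of the
#' initial (time-zero) image so that the curve height also tracks the
#' disappearance of particles.
#'
#' @param curve a `granulometric_curve` with `normalization == "none"`.
#' @param mode `"self"` or `"T0"`.
#' @param ref_total reference gray-level mass; required (and > 0) for
#'   `mode = "T0"`, ignored for `"self"`.
#' @return The normalized curve; under `"self"`,
#'   `sum(density) + residual_mass == 1`.
#' @export
normalize_curve <- function(curve, mode = c("self", "T0"), ref_total = NULL) {
  stopifnot(inherits(curve, "granulometric_curve"))
  mode <- match.arg(mode)
  if (curve$normalization != "none")
    stop("curve is already normalized (", curve$normalization, ")")
  ref <- if (mode == "self") curve$total else ref_total
  if (is.null(ref) || !is.numeric(ref) || length(ref) != 1L || ref <= 0)
    stop("`ref_total` must be a single positive number")
  curve$density <- curve$density / ref
  curve$residual_mass <- curve$residual_mass / ref
  curve$normalization <- mode
  curve$ref_total <- ref
  curve
}

#' Average granulometric curves over replicate frames
#'
#' Pointwise mean of curves measured on replicate images of the same time
#' point. All curves must share the size grid and normalization; replicate
#' pixels are never pooled before measurement.
#'
#' @param curves a list of `granulometric_curve` objects.
#' @return A single `granulometric_curve`, the elementwise mean.
#' @export
average_curves <- function(curves) {
  stopifnot(is.list(curves), length(curves) >= 1)
  lapply(curves, function(x) stopifnot(inherits(x, "granulometric_curve")))
  ref <- curves[[1]]
  for (x in curves[-1]) {
    if (length(x$size_um) != length(ref$size_um) ||
        any(abs(x$size_um - ref$size_um) > 1e-9))
      stop("curves have mismatched size grids")
    if (x$normalization != ref$normalization)
      stop("curves have mismatched normalizations")
  }
  out <- ref
  out$density <- rowMeans(vapply(curves, `[[`, numeric(length(ref$density)), "density"))
  out$residual_mass <- mean(vapply(curves, `[[`, numeric(1), "residual_mass"))
  out$total <- mean(vapply(curves, `[[`, numeric(1), "total"))
  out$ref_total <- mean(vapply(curves, `[[`, numeric(1), "ref_total"))
  out
}

#' Gray-level mean size
#'
#' Mass-weighted mean of the granulometric density over the in-range bins,
#' in micrometers. This is the segmentation-free proxy for the mean projected
#' particle length. Residual mass (objects larger than the largest opening)
#' is excluded: such objects are unmeasurable by the sieve.
#'
#' @param curve a `granulometric_curve`.
#' @return Mean size in um.
#' @export
graylevel_mean_size <- function(curve) {
  stopifnot(inherits(curve, "granulometric_curve"))
  tot <- sum(curve$density)
  if (tot <= 0) stop("zero-mass granulometric curve: mean size undefined")
  sum(curve$size_um * curve$density) / tot
}

#' Size-class accounting of a granulometric curve
#'
#' Sums the granulometric density into size classes. The bin with nominal
#' size `s` collects objects of extent in `(s - step, s]` um; it is assigned
#' to the class whose interval contains its lower extent bound `s - step`.
#' Class edges rarely coincide with bin boundaries (45 and 225 um fall
#' between 16.4 um bins), so the effective edges — the largest nominal bin
#' size in each class, e.g. 49.2 and 229.6 um for the default edges — are
#' reported alongside. Residual mass is assigned to the top class.
#'
#' @param curve a `granulometric_curve`.
#' @param edges_um ascending class boundaries starting at 0; the default
#'   `c(0, 45, 225, Inf)` gives the classes \[0-45\], \[45-225\] and > 225 um.
#' @return An object of class `size_class_summary` with `edges_um`,
#'   `effective_edges_um`, `class_mass` and `normalization`.
#' @export
size_class_masses <- function(curve, edges_um = c(0, 45, 225, Inf)) {
  stopifnot(inherits(curve, "granulometric_curve"))
  if (length(edges_um) < 2 || edges_um[1] != 0 || any(diff(edges_um) <= 0))
    stop("`edges_um` must be ascending and start at 0")
  n_class <- length(edges_um) - 1L
  lower_bound_um <- curve$size_um - curve$size_um[1]
  cls <- findInterval(lower_bound_um, edges_um)
  cls[cls < 1] <- 1L
  cls[cls > n_class] <- n_class
  mass <- vapply(seq_len(n_class), function(k) sum(curve$density[cls == k]), numeric(1))
  mass[n_class] <- mass[n_class] + curve$residual_mass
  eff <- vapply(seq_len(n_class), function(k) {
    s <- curve$size_um[cls == k]
    if (length(s)) max(s) else NA_real_
  }, numeric(1))
  structure(list(edges_um = edges_um,
                 effective_edges_um = eff,
                 class_mass = mass,
                 normalization = curve$normalization),
            class = "size_class_summary")
}

#' @export
print.size_class_summary <- function(x, ...) {
  lab <- paste0("(", head(x$edges_um, -1), ", ", tail(x$edges_um, -1), "]")
  cat("<size_class_summary>\n")
  print(setNames(x$class_mass, lab))
  invisible(x)
}

#' Per-class relative change between two time points
#'
#' Elementwise ratio of class masses at time t over time T0. Classes empty at
#' T0 yield `NA` (flagged undefined rather than silently dividing by zero).
#'
#' @param summary_t,summary_T0 `size_class_summary` objects with identical
#'   edges.
#' @return Numeric vector of per-class ratios, `NA` where the T0 class mass
#'   is zero; attribute `undefined` marks those classes.
#' @export
class_relative_change <- function(summary_t, summary_T0) {
  stopifnot(inherits(summary_t, "size_class_summary"),
            inherits(summary_T0, "size_class_summary"))
  if (length(summary_t$edges_um) != length(summary_T0$edges_um) ||
      any(summary_t$edges_um != summary_T0$edges_um))
    stop("class edges differ between summaries")
  ratio <- summary_t$class_mass / summary_T0$class_mass
  undef <- summary_T0$class_mass == 0
  ratio[undef] <- NA_real_
  attr(ratio, "undefined") <- undef
  ratio
}

#' Relative particle number along a time series
#'
#' The total gray-level mass of each preprocessed frame is the proxy for the
#' number of particles; per time point the replicate masses are averaged and
#' divided by the averaged mass at time zero, so the series starts exactly
#' at 1.
#'
#' @param frames list parallel to `times_h`; each element a list of
#'   [gray_image()] replicates (already tophat-preprocessed).
#' @param times_h ascending acquisition times in hours; must contain 0.
#' @return A data frame with columns `time_h`, `relative_particle_number`,
#'   `n_replicates`.
#' @export
relative_particle_number <- function(frames, times_h) {
  stopifnot(is.list(frames), length(frames) == length(times_h))
  if (!any(times_h == 0)) stop("time series must contain a T0 (time 0) entry")
  means <- vapply(frames, function(reps) {
    stopifnot(is.list(reps), length(reps) >= 1)
    mean(vapply(reps, total_gray, numeric(1)))
  }, numeric(1))
  ref <- means[which(times_h == 0)[1]]
  if (ref <= 0) stop("T0 frames have zero gray-level mass")
  data.frame(time_h = times_h,
             relative_particle_number = means / ref,
             n_replicates = vapply(frames, length, integer(1)))
}

#' Full granulometric measurement of a time-lapse series
#'
#' Convenience wrapper running the whole image branch of the pipeline:
#' tophat preprocessing of every frame, relative particle number, per-time
#' averaged granulometric curves and gray-level mean sizes.
#'
#' @param frames list parallel to `times_h`; each element a list of raw
#'   [gray_image()] replicates.
#' @param times_h acquisition times in hours, containing 0.
#' @param tophat_side_px square SE side for background removal (odd).
#' @param max_size_px,step_px granulometry grid, see
#'   [graylevel_granulometry()].
#' @param class_edges_um size-class boundaries, see [size_class_masses()].
#' @return A list with `measurements` (data frame: `time_h`,
#'   `relative_particle_number`, `mean_size_um`, `n_replicates`), `curves`
#'   (per-time averaged raw curves), `curves_T0norm` (same curves normalized
#'   to the T0 total), `class_change` (matrix of per-class ratios vs T0).
#' @export
measure_time_lapse <- function(frames, times_h, tophat_side_px = 131,
                               max_size_px = 131, step_px = 2,
                               class_edges_um = c(0, 45, 225, Inf)) {
  stopifnot(is.list(frames), length(frames) == length(times_h))
  if (!any(times_h == 0)) stop("time series must contain a T0 (time 0) entry")
  pre <- lapply(frames, function(reps)
    lapply(reps, tophat_preprocess, se_side_px = tophat_side_px))
  rpn <- relative_particle_number(pre, times_h)
  curves <- lapply(pre, function(reps)
    average_curves(lapply(reps, graylevel_granulometry,
                          max_size_px = max_size_px, step_px = step_px)))
  t0_idx <- which(times_h == 0)[1]
  ref_total <- curves[[t0_idx]]$total
  curves_T0 <- lapply(curves, normalize_curve, mode = "T0", ref_total = ref_total)
  mean_size <- vapply(curves, function(cv) {
    if (sum(cv$density) > 0) graylevel_mean_size(cv) else NA_real_
  }, numeric(1))
  cls <- lapply(curves_T0, size_class_masses, edges_um = class_edges_um)
  cls_change <- t(vapply(cls, function(s) class_relative_change(s, cls[[t0_idx]]),
                         numeric(length(class_edges_um) - 1L)))
  rownames(cls_change) <- paste0("t", times_h)
  list(measurements = data.frame(time_h = times_h,
                                 relative_particle_number = rpn$relative_particle_number,
                                 mean_size_um = mean_size,
                                 n_replicates = rpn$n_replicates),
       curves = curves,
       curves_T0norm = curves_T0,
       class_change = cls_change)
}
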