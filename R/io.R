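#' Write a grayscale frame to disk
#'
#' 8-bit grayscale TIFF (default) or PNG. Gray levels are rounded to the
#' nearest integer before quantization, so a write/read round trip of an
#' integer-valued image is bit-exact.
#'
#' @param img a [gray_image()].
#' @param path output path ending in `.tif`, `.tiff` or `.png`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(is_gray_image(img))
  m <- round(unclass(img)) / 255
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) tiff::writeTIFF(m, path, bits.per.sample = 8L)
  else if (ext == "png") png::writePNG(m, path)
  else stop("unsupported image format: .", ext)
  invisible(path)
}

#' Read a grayscale frame from disk
#'
#' Accepts 8-bit grayscale TIFF or PNG; RGB or deeper-bit input is rejected
#' with an error naming the offending file.
#'
#' @param path image path.
#' @param pixel_size_um physical pixel size to attach, um.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, pixel_size_um = 8.2) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    m <- tiff::readTIFF(path, info = TRUE)
    bits <- attr(m, "bits.per.sample")
    if (!is.null(bits) && bits != 8L)
      stop("not an 8-bit image: ", path)
  } else if (ext == "png") {
    m <- png::readPNG(path)
  } else stop("unsupported image format: ", path)
  if (!is.matrix(m))
    stop("not a single-channel grayscale image: ", path)
  gray_image(round(m * 255), pixel_size_um = pixel_size_um)
}

#' Write a simulated time-lapse series as TIFF frames plus manifest
#'
#' One 8-bit grayscale TIFF per (time point, replicate) and a manifest CSV
#' with columns `time_h`, `replicate`, `path`.
#'
#' @param sim result of [simulate_time_lapse()] (with frames).
#' @param dir output directory, created if needed.
#' @return Path of the manifest CSV, invisibly.
#' @export
write_image_series <- function(sim, dir) {
  stopifnot(!is.null(sim$frames))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list()
  for (j in seq_along(sim$times_h)) {
    for (r in seq_along(sim$frames[[j]])) {
      fn <- file.path(dir, sprintf("t%07.3fh_rep%02d.tif", sim$times_h[j], r))
      write_gray_image(sim$frames[[j]][[r]], fn)
      rows[[length(rows) + 1L]] <- data.frame(time_h = sim$times_h[j],
                                              replicate = r, path = fn)
    }
  }
  manifest <- do.call(rbind, rows)
  mp <- file.path(dir, "manifest.csv")
  write.csv(manifest, mp, row.names = FALSE)
  invisible(mp)
}

#' Read a manifest of time-lapse frames
#'
#' @param path manifest CSV with columns `time_h`, `replicate`, `path`
#'   (paths relative to the manifest's directory or absolute).
#' @return The manifest data frame with resolved paths; errors if a path is
#'   missing or a (time, replicate) pair is duplicated.
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_h", "replicate", "path")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  rel <- !file.exists(m$path)
  m$path[rel] <- file.path(dirname(path), m$path[rel])
  missing <- !file.exists(m$path)
  if (any(missing))
    stop("manifest paths do not exist: ", paste(m$path[missing], collapse = ", "))
  if (anyDuplicated(m[c("time_h", "replicate")]))
    stop("duplicated (time_h, replicate) entries in manifest")
  m[order(m$time_h, m$replicate), ]
}

#' Load an image time series from a manifest
#'
#' @param manifest a manifest data frame ([read_manifest()]) or the path of
#'   a manifest CSV.
#' @param pixel_size_um physical pixel size to attach, um.
#' @return A list with `frames` (list over times, each a list of replicate
#'   [gray_image()]s) and `times_h`.
#' @export
read_image_series <- function(manifest, pixel_size_um = 8.2) {
  if (is.character(manifest)) manifest <- read_manifest(manifest)
  times <- sort(unique(manifest$time_h))
  frames <- lapply(times, function(t) {
    sub <- manifest[manifest$time_h == t, ]
    lapply(sub$path, read_gray_image, pixel_size_um = pixel_size_um)
  })
  list(frames = frames, times_h = times)
}

#' Write / read a CPMG decay as CSV plus YAML metadata
#'
#' The decay goes to a two-column CSV (`time_ms`, `amplitude`); moisture
#' content, echo spacing and any known noise sd go to a YAML sidecar
#' (same path with extension `.yml`).
#'
#' @param decay a [cpmg_decay()].
#' @param path CSV path.
#' @return `path`, invisibly (writer); a [cpmg_decay()] (reader).
#' @export
write_cpmg_decay <- function(decay, path) {
  stopifnot(inherits(decay, "cpmg_decay"))
  write.csv(data.frame(time_ms = decay$times_ms, amplitude = decay$amplitudes),
            path, row.names = FALSE)
  meta <- list(echo_spacing_ms = decay$echo_spacing_ms)
  if (!is.null(decay$moisture_content)) meta$moisture_content <- decay$moisture_content
  if (!is.null(decay$noise_sd_estimate)) meta$noise_sd <- decay$noise_sd_estimate
  yaml::write_yaml(meta, sub("\\.csv$", ".yml", path))
  invisible(path)
}

#' @rdname write_cpmg_decay
#' @export
read_cpmg_decay <- function(path) {
  d <- read.csv(path)
  if (!all(c("time_ms", "amplitude") %in% names(d)))
    stop("decay CSV must have columns time_ms, amplitude")
  meta_path <- sub("\\.csv$", ".yml", path)
  meta <- if (file.exists(meta_path)) yaml::read_yaml(meta_path) else list()
  cpmg_decay(d$time_ms, d$amplitude,
             moisture_content = meta$moisture_content,
             noise_sd_estimate = meta$noise_sd)
}

run_config_schema <- list(
  seed = NULL,
  output_dir = NULL,
  simulate = c("n_particles", "length_median_um", "length_log_sd",
               "width_median_um", "width_log_sd", "fraction_recalcitrant",
               "orientations", "mode", "dissolve_hazard_per_h",
               "shrink_rate_um_per_h", "fragment_rate_per_h",
               "sugar_max_yield_pct", "height_px", "width_px",
               "pixel_size_um", "n_replicates", "time_points_h",
               "background_amplitude", "noise_sd"),
  granulometry = c("tophat_side_px", "max_size_px", "step_px", "class_edges_um"),
  kinetics = c("n_components")
)

#' Validated configuration of a full pipeline run
#'
#' Builds the configuration consumed by [run_pipeline()]. Unknown keys at
#' any level are rejected before any computation, so a typo cannot silently
#' fall back to a default.
#'
#' @param seed integer seed driving the whole run.
#' @param output_dir directory for all outputs.
#' @param simulate named list of overrides for
#'   [particle_population_spec()], [degradation_scenario()] and
#'   [imaging_config()] fields.
#' @param granulometry named list: `tophat_side_px`, `max_size_px`,
#'   `step_px`, `class_edges_um`.
#' @param kinetics named list: `n_components` (1, 2 or "auto").
#' @return A `run_config` object.
#' @export
run_config <- function(seed = 1L, output_dir = tempfile("sacchmon_run_"),
                       simulate = list(), granulometry = list(),
                       kinetics = list()) {
  for (section in c("simulate", "granulometry", "kinetics")) {
    vals <- get(section)
    unknown <- setdiff(names(vals), run_config_schema[[section]])
    if (length(unknown))
      stop("unknown config key(s) in `", section, "`: ",
           paste(unknown, collapse = ", "))
  }
  structure(list(seed = as.integer(seed), output_dir = output_dir,
                 simulate = simulate, granulometry = granulometry,
                 kinetics = kinetics),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' @param path YAML file with top-level keys `seed`, `output_dir`,
#'   `simulate`, `granulometry`, `kinetics`; unknown keys are rejected.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  unknown <- setdiff(names(y), names(run_config_schema))
  if (length(unknown))
    stop("unknown top-level config key(s): ", paste(unknown, collapse = ", "))
  do.call(run_config, y)
}

pick <- function(overrides, defaults) {
  known <- intersect(names(overrides), names(defaults))
  defaults[known] <- overrides[known]
  defaults
}

#' Run the full synthetic monitoring pipeline
#'
#' Simulation -> granulometric measurement -> kinetic fits -> coupled
#' trajectory, writing every intermediate as CSV/JSON into
#' `config$output_dir` together with a run log (package version, seed and
#' the morphological parameters, so the um/px convention is auditable).
#' Identical configuration and seed give byte-identical outputs.
#'
#' @param config a [run_config()].
#' @return Invisibly, a list with `truth`, `measurements`, `fits`,
#'   `coupled`, `output_dir`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$output_dir, "run_log.txt")
  logf <- function(...) {
    line <- sprintf(...)
    message(line)
    cat(line, "\n", file = log_path, append = TRUE, sep = "")
  }
  cat("", file = log_path)
  gran <- pick(config$granulometry,
               list(tophat_side_px = 131, max_size_px = 131, step_px = 2,
                    class_edges_um = c(0, 45, 225, Inf)))
  kin <- pick(config$kinetics, list(n_components = "auto"))
  logf("sacchmon %s | seed %d", as.character(utils::packageVersion("sacchmon")),
       config$seed)
  logf("granulometry: tophat side %d px, sizes %d..%d px step %d",
       gran$tophat_side_px, gran$step_px, gran$max_size_px, gran$step_px)

  stage <- "simulate"
  res <- tryCatch({
    spec <- do.call(particle_population_spec,
                    pick(config$simulate, formals_defaults(particle_population_spec)))
    if (!is.null(config$simulate$orientations))
      spec$orientations <- config$simulate$orientations
    scen <- do.call(degradation_scenario,
                    c(list(mode = config$simulate$mode %||% "dissolve"),
                      pick(config$simulate, formals_defaults(degradation_scenario)[-1])))
    img_over <- pick(config$simulate, formals_defaults(imaging_config))
    img_over$seed <- config$seed
    imaging <- do.call(imaging_config, img_over)
    sim <- simulate_time_lapse(spec, scen, imaging)
    write.csv(sim$truth, file.path(config$output_dir, "truth.csv"), row.names = FALSE)
    logf("simulated %d time points x %d replicates, %d particles",
         length(sim$times_h), imaging$n_replicates, spec$n_particles)

    stage <- "granulometry"
    meas <- measure_time_lapse(sim$frames, sim$times_h,
                               tophat_side_px = gran$tophat_side_px,
                               max_size_px = gran$max_size_px,
                               step_px = gran$step_px,
                               class_edges_um = gran$class_edges_um)
    write.csv(meas$measurements, file.path(config$output_dir, "measurements.csv"),
              row.names = FALSE)
    curves_long <- do.call(rbind, lapply(seq_along(sim$times_h), function(j) {
      cv <- meas$curves_T0norm[[j]]
      data.frame(time_h = sim$times_h[j], size_um = cv$size_um,
                 density = cv$density, normalization = cv$normalization)
    }))
    write.csv(curves_long, file.path(config$output_dir, "curves.csv"),
              row.names = FALSE)

    stage <- "kinetics"
    m <- meas$measurements
    sugar <- kinetic_series(sim$truth$time_h, sim$truth$sugar_pct,
                            kind = "sugar_release")
    number <- kinetic_series(m$time_h, m$relative_particle_number,
                             kind = "particle_number")
    size <- kinetic_series(m$time_h, m$mean_size_um / m$mean_size_um[1],
                           kind = "mean_size")
    fits <- list(sugar = fit_exponential(sugar, kin$n_components),
                 number = fit_exponential(number, kin$n_components),
                 size = fit_exponential(size, kin$n_components))
    fit_json <- lapply(fits, function(f) {
      if (!f$converged) return(list(converged = FALSE))
      list(converged = TRUE, n_components = f$n_components,
           amplitudes = f$amplitudes, rates_per_h = f$rates_per_h,
           baseline = f$baseline, t_half_h = f$t_half_h, rss = f$rss,
           r2 = f$r2, aicc = f$aicc)
    })
    jsonlite::write_json(fit_json, file.path(config$output_dir, "fits.json"),
                         auto_unbox = TRUE, digits = 10)
    coupled <- couple_chem_phys(sugar, number, size)
    write.csv(coupled, file.path(config$output_dir, "coupled.csv"),
              row.names = FALSE)
    logf("kinetic fits: sugar t1/2 %s h, number t1/2 %s h",
         format(fits$sugar$t_half_h, digits = 4),
         format(fits$number$t_half_h, digits = 4))
    list(truth = sim$truth, measurements = m, fits = fits, coupled = coupled,
         output_dir = config$output_dir)
  }, error = function(e) {
    stop("pipeline failed at stage [", stage, "]: ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(res)
}

# defaults of a function's formals that are plain values (skip NULL/language)
formals_defaults <- function(fn) {
  fl <- formals(fn)
  out <- list()
  for (nm in names(fl)) {
    v <- fl[[nm]]
    if (is.call(v) || is.symbol(v)) {
      v <- tryCatch(eval(v, envir = asNamespace("sacchmon")), error = function(e) NULL)
    }
    if (!is.null(v) && !is.function(v)) out[[nm]] <- v
  }
  out
}
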