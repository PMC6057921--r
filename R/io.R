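## Readers/writers for the package's table formats, run configuration,
## and the pipeline driver chaining simulation to fitting.

.EVENT_COLS <- c("event_id", "channel", "site_id", "site_class", "x_um",
                 "y_um", "start_frame", "n_frames", "censored")

#' Read / write binding-event tables
#'
#' Events are CSV with columns `event_id`, `channel`, `site_id`,
#' `site_class`, `x_um`, `y_um`, `start_frame` (0-based), `n_frames`,
#' `censored` (0/1). Unknown columns are preserved; missing required
#' columns raise an error naming them. `writeEvents` fills `channel` and
#' `site_id` with defaults when absent.
#'
#' @param path CSV file path.
#' @return `readEvents`: data.frame with `censored` as logical.
#' @export
readEvents <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(.EVENT_COLS, names(ev))
  if (length(missing))
    stop("events file is missing required column(s): ",
         paste(missing, collapse = ", "))
  ev$censored <- as.logical(ev$censored)
  ev
}

#' @rdname readEvents
#' @param events event data.frame.
#' @export
writeEvents <- function(events, path) {
  if (!"channel" %in% names(events)) events$channel <- "a"
  if (!"site_id" %in% names(events)) events$site_id <- NA_character_
  if (!"site_class" %in% names(events))
    events$site_class <- NA_character_
  if (!"event_id" %in% names(events))
    events$event_id <- seq_len(nrow(events))
  out <- events
  out$censored <- as.integer(out$censored)
  front <- intersect(.EVENT_COLS, names(out))
  out <- out[, c(front, setdiff(names(out), front)), drop = FALSE]
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write site maps
#'
#' Sites are CSV with `site_id`, `class` (`filament` or `branch`),
#' `vertices` (a JSON string of `[x, y]` pairs in um), and `length_um`.
#'
#' @param path CSV file path.
#' @return `readSites`: a [SiteMap-class].
#' @export
readSites <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  fil <- lapply(df$vertices[df$class == "filament"], function(v) {
    m <- jsonlite::fromJSON(v)
    matrix(m, ncol = 2)
  })
  br <- do.call(rbind, lapply(df$vertices[df$class == "branch"], function(v)
    matrix(jsonlite::fromJSON(v), ncol = 2)))
  SiteMap(filaments = fil, branches = br)
}

#' @rdname readSites
#' @param siteMap a [SiteMap-class].
#' @export
writeSites <- function(siteMap, path) {
  rows <- list()
  for (i in seq_along(siteMap@filaments)) {
    f <- siteMap@filaments[[i]]
    rows[[length(rows) + 1]] <- data.frame(
      site_id = paste0("filament_", i), class = "filament",
      vertices = as.character(jsonlite::toJSON(f)),
      length_um = sum(sqrt(rowSums(diff(f)^2))))
  }
  for (i in seq_len(nBranches(siteMap))) {
    rows[[length(rows) + 1]] <- data.frame(
      site_id = paste0("branch_", i), class = "branch",
      vertices = as.character(jsonlite::toJSON(
        matrix(siteMap@branches[i, ], ncol = 2))),
      length_um = 0)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read / write intensity traces
#'
#' Traces are CSV with `trace_id`, `frame`, `time_s`, `intensity`.
#'
#' @param path CSV file path.
#' @return `readTraces`: data.frame.
#' @export
readTraces <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(c("trace_id", "frame", "time_s", "intensity"),
                     names(tr))
  if (length(missing))
    stop("traces file is missing required column(s): ",
         paste(missing, collapse = ", "))
  tr
}

#' @rdname readTraces
#' @param traces trace data.frame.
#' @export
writeTraces <- function(traces, path) {
  utils::write.csv(traces, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write / read a movie stack as multi-page TIFF
#'
#' @param stack array height x width x frames.
#' @param path TIFF file path.
#' @return `readMovieTiff`: the stack array.
#' @export
writeMovieTiff <- function(stack, path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to write TIFF stacks")
  mx <- max(stack, 1)
  imgs <- lapply(seq_len(dim(stack)[3]), function(f) stack[, , f] / mx)
  tiff::writeTIFF(imgs, path, bits.per.sample = 32L)
  invisible(path)
}

#' @rdname writeMovieTiff
#' @export
readMovieTiff <- function(path) {
  if (!requireNamespace("tiff", quietly = TRUE))
    stop("the tiff package is required to read TIFF stacks")
  imgs <- tiff::readTIFF(path, all = TRUE)
  array(unlist(imgs), dim = c(dim(imgs[[1]]), length(imgs)))
}

#' Run configuration
#'
#' Collects every knob of an end-to-end run in one serializable list:
#' the seed, the acquisition interval, geometry constants, and fitting
#' options. Round-trips losslessly through JSON.
#'
#' @param seed integer RNG seed driving all randomness in the run.
#' @param frameIntervalS frame interval dt (s).
#' @param pixelSizeUm pixel size (um).
#' @param boxAreaUm2 detection box area (um^2).
#' @param siteDensityPerUm filament-side site density (sites/um).
#' @param nBoot bootstrap replicates.
#' @param estimator dwell estimator.
#' @param ... further fields (e.g. `durationS`, `tau`, `nEvents`, paths).
#' @return a named list with class `RunConfig`.
#' @export
runConfig <- function(seed = 1, frameIntervalS = 0.25, pixelSizeUm = 0.27,
                      boxAreaUm2 = 1.14, siteDensityPerUm = 370,
                      nBoot = 10000,
                      estimator = "phase_marginalized", ...) {
  cfg <- c(list(seed = seed, frameIntervalS = frameIntervalS,
                pixelSizeUm = pixelSizeUm, boxAreaUm2 = boxAreaUm2,
                siteDensityPerUm = siteDensityPerUm, nBoot = nBoot,
                estimator = estimator), list(...))
  stopIfNot(all(vapply(c("frameIntervalS", "pixelSizeUm", "boxAreaUm2",
                         "siteDensityPerUm"),
                       function(f) cfg[[f]] > 0, logical(1))),
            "all physical quantities must be > 0")
  class(cfg) <- "RunConfig"
  cfg
}

#' @rdname runConfig
#' @param config a `RunConfig`.
#' @param path JSON path.
#' @export
writeConfig <- function(config, path) {
  jsonlite::write_json(unclass(config), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname runConfig
#' @export
readConfig <- function(path) {
  cfg <- jsonlite::fromJSON(path)
  class(cfg) <- "RunConfig"
  cfg
}

## Tiny stable polynomial hash of the serialized config, recorded on
## artifacts so outputs can be traced back to their exact configuration.
configHash <- function(config) {
  s <- utf8ToInt(jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                                  digits = NA))
  h <- 0
  for (b in s) h <- (h * 31 + b) %% 2147483647
  sprintf("%08x", h)
}

#' Run a chained analysis pipeline
#'
#' Executes the requested stages in order on a shared state, validating
#' the dependency chain before execution. Available stages:
#' `simulate` (dwell-process simulation from `config$tau` or
#' `config$tShort`/`tLong`/`fracLong`, `config$nEvents`), `fit_dwell`
#' (single and/or two-exponential fit per `config$model`), and
#' `occupancy` (two-state site simulation from `config$dutyRatio`,
#' `config$nSites`, `config$durationS`). Every result bundle records the
#' config hash, seed, and package version; per-stage event counts are
#' logged via `message()`.
#'
#' @param config a `RunConfig` (see [runConfig()]).
#' @param stages character vector of stage names, in order.
#' @param outDir optional directory; when given, results are written as
#'   JSON and the events table as CSV.
#' @return named list of stage results plus `meta`.
#' @export
runPipeline <- function(config, stages, outDir = NULL) {
  known <- c("simulate", "fit_dwell", "occupancy")
  bad <- setdiff(stages, known)
  if (length(bad)) stop("unknown stage(s): ", paste(bad, collapse = ", "))
  needs <- list(simulate = character(0), fit_dwell = "simulate",
                occupancy = character(0))
  for (i in seq_along(stages)) {
    missing <- setdiff(needs[[stages[i]]], stages[seq_len(i - 1)])
    if (length(missing))
      stop(sprintf("stage '%s' requires prior stage(s): %s", stages[i],
                   paste(missing, collapse = ", ")))
  }
  meta <- list(configHash = configHash(config), seed = config$seed,
               package = as.character(utils::packageVersion("smKinetics")))
  state <- list(meta = meta)
  for (st in stages) {
    state <- tryCatch(switch(st,
      simulate = {
        dwell <- if (!is.null(config$tau)) list(tau = config$tau)
          else list(tShort = config$tShort, tLong = config$tLong,
                    fracLong = config$fracLong)
        s <- simulateDwells(config$nEvents, dwell, config$frameIntervalS,
                            seed = config$seed)
        message(sprintf("[simulate] %d events at dt = %g s", nEvents(s),
                        config$frameIntervalS))
        c(state, list(sample = s))
      },
      fit_dwell = {
        model <- if (is.null(config$model)) "1exp" else config$model
        fits <- list()
        if (model %in% c("1exp", "both"))
          fits$exp1 <- fitExponential(state$sample,
                                      estimator = config$estimator)
        if (model %in% c("2exp", "both"))
          fits$exp2 <- fitTwoExponential(state$sample,
                                         estimator = config$estimator)
        message(sprintf("[fit_dwell] fitted %s on n = %d", model,
                        nEvents(state$sample)))
        c(state, list(fits = fits))
      },
      occupancy = {
        ev <- simulateOccupancyTrace(config$nSites, config$dutyRatio,
                                     config$meanBoundS, config$durationS,
                                     seed = config$seed)
        q <- quantizeToFrames(ev, config$frameIntervalS,
                              durationS = config$durationS)
        occ <- occupancy(q, nSites = config$nSites,
                         observationS = config$durationS,
                         frameIntervalS = config$frameIntervalS)
        message(sprintf("[occupancy] %d bound intervals, occupancy %.3f",
                        nrow(q), occ$occupancy))
        c(state, list(occupancy = occ))
      }), error = function(e)
        stop(sprintf("pipeline stage '%s' failed: %s", st,
                     conditionMessage(e)), call. = FALSE))
  }
  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    summary <- list(meta = state$meta)
    if (!is.null(state$fits)) {
      summary$fits <- lapply(state$fits, function(f) {
        p <- as.list(paramVector(f))
        c(p, list(loglik = f@loglik, n = f@n, estimator = f@estimator))
      })
    }
    if (!is.null(state$occupancy)) summary$occupancy <- state$occupancy
    jsonlite::write_json(summary, file.path(outDir, "results.json"),
                         auto_unbox = TRUE, digits = 10, pretty = TRUE)
    if (!is.null(state$sample)) {
      s <- state$sample
      writeEvents(data.frame(event_id = seq_len(nEvents(s)),
                             site_class = "side", x_um = 0, y_um = 0,
                             start_frame = 0L,
                             n_frames = frameCounts(s),
                             censored = isCensored(s)),
                  file.path(outDir, "events.csv"))
    }
  }
  state
}
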