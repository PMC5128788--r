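# End-to-end pipeline: load or simulate a count table, tabulate diversity,
# build TACs per Hill order, run the depth analysis, fit TAD models, and
# write a manifest. Reruns with an identical config are byte-identical
# (run.log, which carries wall-clock timings, is deliberately excluded from
# the manifest checksums).

#' Build a validated pipeline configuration
#'
#' All defaults are the package-wide conventions: orders 0/1/2, 100 TAC
#' orderings, 10 subsampling replicates, 999 bootstrap replicates,
#' stability window 0.1 with tolerance 0.02, and the 25,000-400,000
#' log-spaced depth grid (clipped to the data).
#'
#' @param input path to a \code{.shared} or TSV count table, or NULL to
#'   simulate.
#' @param format \code{"shared"} or \code{"tsv"} (for \code{input}).
#' @param orientation TSV orientation (see [readCountTsv()]).
#' @param preset \code{"amazon"}, \code{"texas"} or NULL; used when
#'   \code{input} is NULL.
#' @param spec a \linkS4class{CommunitySpec} overriding \code{preset}.
#' @param nSamples,depthPerSample,overdispersion simulation design (defaults
#'   from the preset when one is named).
#' @param orders Hill orders analysed.
#' @param nPerm TAC orderings.
#' @param reps subsampling replicates per depth.
#' @param nBoot bootstrap replicates of the deviation test.
#' @param depths depth grid or NULL for [defaultDepthGrid()].
#' @param windowFrac,tol stability criterion (see [stabilityScore()]).
#' @param seed master seed; every stage derives its own stream from it.
#' @param outDir output directory.
#' @return A validated config (list, class \code{"hilltacConfig"}).
#' @examples
#' cfg <- runConfig(preset = "texas", nPerm = 5, reps = 2, nBoot = 99,
#'                  outDir = tempfile())
#' @export
runConfig <- function(input = NULL,
                      format = c("shared", "tsv"),
                      orientation = "taxa_by_samples",
                      preset = NULL,
                      spec = NULL,
                      nSamples = NULL,
                      depthPerSample = NULL,
                      overdispersion = 0,
                      orders = c(0, 1, 2),
                      nPerm = 100L,
                      reps = 10L,
                      nBoot = 999L,
                      depths = NULL,
                      windowFrac = 0.1,
                      tol = 0.02,
                      seed = 1L,
                      outDir = "hilltac_out") {
  format <- match.arg(format)
  seed <- checkSeed(seed)
  if (is.null(input)) {
    if (is.null(spec)) {
      if (is.null(preset))
        stop("provide 'input', a 'spec', or a 'preset'", call. = FALSE)
      ps <- studyPreset(preset, seed = seed)
      spec <- ps$spec
      if (is.null(nSamples)) nSamples <- ps$nSamples
      if (is.null(depthPerSample)) depthPerSample <- ps$depthPerSample
    }
    if (is.null(nSamples) || is.null(depthPerSample))
      stop("simulation needs 'nSamples' and 'depthPerSample'", call. = FALSE)
    validObject(spec)
  } else if (!file.exists(input)) {
    stop("input file not found: ", input, call. = FALSE)
  }
  if (any(orders < 0) || is.unsorted(orders))
    stop("'orders' must be ascending and >= 0", call. = FALSE)
  cfg <- list(input = input, format = format, orientation = orientation,
              preset = preset, spec = spec, nSamples = nSamples,
              depthPerSample = depthPerSample,
              overdispersion = overdispersion, orders = as.numeric(orders),
              nPerm = as.integer(nPerm), reps = as.integer(reps),
              nBoot = as.integer(nBoot), depths = depths,
              windowFrac = windowFrac, tol = tol, seed = seed,
              outDir = outDir)
  class(cfg) <- "hilltacConfig"
  cfg
}

#' Read a pipeline configuration from a flat key=value file
#'
#' One \code{key = value} pair per line; \code{#} starts a comment. Vector
#' values (orders, depths) are comma-separated. Keys mirror the arguments of
#' [runConfig()]; simulation parameters use \code{tad, S, mu, sigma, gamma}.
#'
#' @param path config file path.
#' @param ... overrides applied on top of the file (flags win over file).
#' @return A validated config, as [runConfig()].
#' @export
readRunConfig <- function(path, ...) {
  if (!file.exists(path))
    stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[nzchar(trimws(lines))])
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- which(vapply(kv, length, integer(1)) < 2L)
  if (length(bad))
    stop("malformed config line: '", lines[bad[1L]], "'", call. = FALSE)
  keys <- trimws(vapply(kv, `[[`, character(1), 1L))
  vals <- trimws(vapply(kv, function(x) paste(x[-1L], collapse = "="),
                        character(1)))
  raw <- setNames(as.list(vals), keys)
  num <- function(x) as.numeric(strsplit(x, ",", fixed = TRUE)[[1L]])
  args <- list()
  for (k in names(raw)) {
    v <- raw[[k]]
    args[[k]] <- switch(k,
      orders = , depths = num(v),
      nPerm = , reps = , nBoot = , seed = , nSamples = ,
      depthPerSample = , S = as.integer(v),
      windowFrac = , tol = , overdispersion = , mu = , sigma = ,
      gamma = as.numeric(v),
      v)
  }
  specKeys <- intersect(names(args), c("tad", "S", "mu", "sigma", "gamma"))
  if (length(specKeys)) {
    sa <- args[specKeys]
    names(sa)[names(sa) == "tad"] <- "tad"
    args$spec <- do.call(communitySpec, c(sa,
      if (!is.null(args$seed)) list(seed = args$seed)))
    args[specKeys] <- NULL
  }
  over <- list(...)
  args[names(over)] <- over
  do.call(runConfig, args)
}

.writeJson <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Run the full diversity pipeline
#'
#' Stages: load/simulate the count table; per-sample and pooled diversity
#' summary (\code{diversity.csv}); one smoothed TAC per order
#' (\code{tac_a<order>.csv}); depth analysis on the pooled reads
#' (\code{depth_analysis.csv} + \code{stability.json}); log-normal and Zipf
#' TAD fits with model selection and the deviation test
#' (\code{rad_models.csv} + \code{rad.json}); and \code{manifest.json}
#' listing every payload with its md5 checksum alongside the effective
#' config. A stage failure aborts with the stage name; files already
#' written are flagged \code{status = "partial"} in the manifest.
#'
#' @param config a config from [runConfig()] or [readRunConfig()].
#' @param quiet suppress progress messages.
#' @return Invisibly, a list with the in-memory results (table, diversity,
#'   tacs, depth, rad, manifest path).
#' @examples
#' cfg <- runConfig(spec = communitySpec(60, "zipf", gamma = 1.1),
#'                  nSamples = 4, depthPerSample = 300, nPerm = 10,
#'                  reps = 3, nBoot = 99, outDir = tempfile(), seed = 7)
#' res <- runPipeline(cfg, quiet = TRUE)
#' @export
runPipeline <- function(config, quiet = FALSE) {
  stopifnot(inherits(config, "hilltacConfig"))
  dir.create(config$outDir, recursive = TRUE, showWarnings = FALSE)
  outputs <- character(0)
  logLines <- character(0)
  t0 <- proc.time()[["elapsed"]]
  note <- function(...) {
    line <- paste0(...)
    logLines <<- c(logLines, line)
    if (!quiet) message(line)
  }
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      .writeManifest(config, outputs, status = "partial",
                     failedStage = name)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
    note(sprintf("[stage %s] done in %.2fs", name,
                 proc.time()[["elapsed"]] - ts))
    res
  }
  emit <- function(file) {
    outputs <<- c(outputs, file)
    file
  }
  note("effective config: ", .configString(config))

  table <- stage("load", {
    if (!is.null(config$input)) {
      note("reading ", config$input, " (", config$format, ")")
      if (config$format == "shared") readShared(config$input)
      else readCountTsv(config$input, config$orientation)
    } else {
      note("simulating study: ", config$spec@S, " taxa, ", config$spec@tad,
           " TAD, ", config$nSamples, " x ", config$depthPerSample,
           " reads, seed ", config$seed)
      makeStudy(config$spec, config$nSamples, config$depthPerSample,
                overdispersion = config$overdispersion,
                seed = deriveSeed(config$seed, 1L))
    }
  })

  div <- stage("diversity", {
    d <- diversityTable(table, pooled = TRUE)
    f <- file.path(config$outDir, "diversity.csv")
    write.csv(d, emit(f), row.names = FALSE)
    d
  })

  tacs <- stage("tac", {
    if (ncol(table) < 2L) {
      note("single sample: skipping TACs")
      list()
    } else {
      out <- list()
      for (a in config$orders) {
        curve <- smoothedTAC(table, a, nPerm = config$nPerm,
                             seed = deriveSeed(config$seed, 2L))
        f <- file.path(config$outDir,
                       sprintf("tac_a%s.csv", format(a)))
        write.csv(as.data.frame(curve), emit(f), row.names = FALSE)
        out[[paste0("a", format(a))]] <- curve
      }
      out
    }
  })

  pooled <- poolSamples(table)

  depth <- stage("depth", {
    depths <- config$depths
    if (is.null(depths))
      depths <- defaultDepthGrid(totalReads(pooled))
    res <- depthAnalysis(pooled, depths = depths, orders = config$orders,
                         reps = config$reps,
                         seed = deriveSeed(config$seed, 3L),
                         windowFrac = config$windowFrac, tol = config$tol)
    long <- do.call(rbind, lapply(seq_along(res@orders), function(oi) {
      do.call(rbind, lapply(seq_along(res@depths), function(di) {
        data.frame(order = res@orders[oi], depth = res@depths[di],
                   rep = seq_len(res@reps),
                   value = res@values[, di, oi])
      }))
    }))
    write.csv(long, emit(file.path(config$outDir, "depth_analysis.csv")),
              row.names = FALSE)
    sd <- stabilityDepth(res)
    .writeJson(list(orders = res@orders,
                    stability_depth = ifelse(is.na(sd), "not reached",
                                             as.character(sd)),
                    window_frac = config$windowFrac, tol = config$tol),
               emit(file.path(config$outDir, "stability.json")))
    res
  })

  rad <- stage("rad", {
    fits <- list(suppressMessages(fitLognormal(pooled)), fitZipf(pooled))
    best <- selectModel(fits)
    dev <- deviationTest(pooled, nBoot = config$nBoot,
                         seed = deriveSeed(config$seed, 4L))
    tab <- do.call(rbind, lapply(fits, function(f) {
      data.frame(model = f@model,
                 params = paste(names(f@params), "=",
                                format(f@params, digits = 10),
                                collapse = "; "),
                 logLik = f@logLik, aic = f@aic, nPar = f@nPar,
                 degenerate = f@degenerate)
    }))
    write.csv(tab, emit(file.path(config$outDir, "rad_models.csv")),
              row.names = FALSE)
    .writeJson(list(selected = best@model,
                    tie = attr(best, "selection")$tie[1L],
                    params = as.list(radParams(best)),
                    deviation = list(D = dev@D, p_value = dev@pValue,
                                     n_boot = dev@nBoot)),
               emit(file.path(config$outDir, "rad.json")))
    list(fits = fits, best = best, deviation = dev)
  })

  manifest <- .writeManifest(config, outputs, status = "complete")
  note(sprintf("pipeline complete in %.2fs", proc.time()[["elapsed"]] - t0))
  writeLines(logLines, file.path(config$outDir, "run.log"))
  invisible(list(table = table, diversity = div, tacs = tacs,
                 depth = depth, rad = rad, manifest = manifest))
}

.configString <- function(config) {
  paste0("orders=", paste(config$orders, collapse = ","),
         " nPerm=", config$nPerm, " reps=", config$reps,
         " nBoot=", config$nBoot, " windowFrac=", config$windowFrac,
         " tol=", config$tol, " seed=", config$seed)
}

.writeManifest <- function(config, outputs, status, failedStage = NULL) {
  files <- lapply(outputs, function(f) {
    list(file = basename(f), md5 = unname(tools::md5sum(f)))
  })
  specList <- if (is.null(config$spec)) NULL else list(
    S = config$spec@S, tad = config$spec@tad, mu = config$spec@mu,
    sigma = config$spec@sigma, gamma = config$spec@gamma,
    seed = config$spec@seed)
  cfg <- list(input = config$input, format = config$format,
              orientation = config$orientation, preset = config$preset,
              spec = specList, nSamples = config$nSamples,
              depthPerSample = config$depthPerSample,
              overdispersion = config$overdispersion,
              orders = config$orders, nPerm = config$nPerm,
              reps = config$reps, nBoot = config$nBoot,
              depths = config$depths, windowFrac = config$windowFrac,
              tol = config$tol, seed = config$seed)
  manifest <- list(
    package = "hilltac",
    version = as.character(utils::packageVersion("hilltac")),
    status = status,
    failed_stage = failedStage,
    input_md5 = if (!is.null(config$input))
      unname(tools::md5sum(config$input)) else NULL,
    config = cfg,
    outputs = files)
  path <- file.path(config$outDir, "manifest.json")
  .writeJson(manifest, path)
  path
}
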