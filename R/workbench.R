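## Experiment workbench: run-configuration presets, structured-text (YAML)
## config I/O, the experiment runner that writes a result bundle to disk,
## and the conductivity/thickness sensitivity suite.

.geometryDefaults <- function() {
    list(type = "slice", widthMm = 60, heightMm = 40, layerMm = 4,
         cellsAcrossGm = 5, unstableWidthMm = 4, wmFine = FALSE,
         sigmaT = 0.1, sigmaL = 1.0, kOInf = 4)
}

.analysisDefaults <- function() {
    list(threshold = -20, refractoryMs = 2, maxGapMs = 500, minSpikes = 10,
         fMin = 100, fMax = 5000, probeStride = 1, spectrumOn = "trace",
         adaptiveUeThreshold = TRUE)
}

.mergeDefaults <- function(given, defaults, where) {
    unknown <- setdiff(names(given), names(defaults))
    if (length(unknown))
        stop("unknown ", where, " key(s): ", paste(unknown, collapse = ", "))
    defaults[names(given)] <- given
    defaults
}

#' Construct a run configuration
#'
#' @param modelPreset "A".."G" or "custom".
#' @param geometry list of geometry settings (see
#'   \code{\link{buildIdealizedSlice}}); \code{type} is "point" (pure cell
#'   model), "slice" (built-in 2D geometry) or "mesh" (external file).
#' @param conductivityTable named list label -> c(mi, me), mS/cm.
#' @param anisotropy apply the white-matter anisotropy tensor.
#' @param wmCellModel "none" or "cressman_stable".
#' @param durationMs simulated duration, ms.
#' @param solver a \linkS4class{SolverConfig}.
#' @param analysis list of spike/burst/spectrum settings.
#' @param outputDir directory for \code{\link{runExperiment}} outputs.
#' @param meshPath external labeled mesh path ("" for built-in geometry).
#' @param seed integer seed (synthetic fixture generation only).
#' @return a \linkS4class{RunConfig}.
#' @export
runConfig <- function(modelPreset = "custom", geometry = list(),
                      conductivityTable = defaultConductivityTable(),
                      anisotropy = TRUE,
                      wmCellModel = c("none", "cressman_stable"),
                      durationMs = 10000, solver = solverConfig(),
                      analysis = list(), outputDir = "results",
                      meshPath = "", seed = 1L) {
    wmCellModel <- match.arg(wmCellModel)
    geometry <- .mergeDefaults(geometry, .geometryDefaults(), "geometry")
    analysis <- .mergeDefaults(analysis, .analysisDefaults(), "analysis")
    if (!geometry$type %in% c("point", "slice", "mesh"))
        stop("geometry type must be 'point', 'slice' or 'mesh'")
    obj <- new("RunConfig", modelPreset = modelPreset, geometry = geometry,
               conductivityTable = conductivityTable,
               anisotropy = anisotropy, wmCellModel = wmCellModel,
               durationMs = durationMs, solver = solver,
               analysis = analysis, outputDir = outputDir,
               meshPath = meshPath, seed = as.integer(seed))
    validObject(obj)
    obj
}

#' Named experiment presets
#'
#' The seven standard model configurations: A and B are pure point-neuron
#' runs (stable, 4 mM bath potassium, and seizure-like, 8 mM); C is the
#' idealized 2D slice with anisotropic white matter and no white-matter
#' cell model; D adds the stable cell model in the white matter; E, F and G
#' are user-supplied 3D head meshes (isotropic, anisotropic, and isotropic
#' with a stable white-matter cell model) and require \code{meshPath}.
#'
#' @param preset one of "A".."G".
#' @param meshPath external mesh path (required for E-G).
#' @param ... further arguments passed to \code{\link{runConfig}}.
#' @return a \linkS4class{RunConfig}.
#' @examples
#' presetConfig("C")
#' @export
presetConfig <- function(preset = c("A", "B", "C", "D", "E", "F", "G"),
                         meshPath = "", ...) {
    preset <- match.arg(preset)
    base <- switch(preset,
        A = list(geometry = list(type = "point", kOInf = 4),
                 anisotropy = FALSE, analysis = list(spectrumOn = "burst")),
        B = list(geometry = list(type = "point", kOInf = 8),
                 anisotropy = FALSE, analysis = list(spectrumOn = "burst")),
        C = list(geometry = list(type = "slice"), anisotropy = TRUE,
                 wmCellModel = "none"),
        D = list(geometry = list(type = "slice"), anisotropy = TRUE,
                 wmCellModel = "cressman_stable"),
        E = list(geometry = list(type = "mesh"), anisotropy = FALSE,
                 wmCellModel = "none"),
        F = list(geometry = list(type = "mesh"), anisotropy = TRUE,
                 wmCellModel = "none"),
        G = list(geometry = list(type = "mesh"), anisotropy = FALSE,
                 wmCellModel = "cressman_stable"))
    args <- c(list(modelPreset = preset, meshPath = meshPath), base,
              list(...))
    ## user-supplied arguments override the preset skeleton
    dup <- duplicated(names(args), fromLast = TRUE)
    do.call(runConfig, args[!dup])
}

## RunConfig <-> plain list (for YAML round-tripping)
.configToList <- function(config) {
    s <- config@solver
    list(modelPreset = config@modelPreset,
         geometry = config@geometry,
         conductivity = lapply(config@conductivityTable, as.numeric),
         anisotropy = config@anisotropy,
         wmCellModel = config@wmCellModel,
         durationMs = config@durationMs,
         solver = list(dt = s@dt, theta = s@theta,
                       krylovRtol = s@krylovRtol, krylovAtol = s@krylovAtol,
                       maxIterations = s@maxIterations,
                       activeLabels = as.list(s@activeLabels),
                       method = s@method, odeSubsteps = s@odeSubsteps,
                       massLumping = s@massLumping),
         analysis = config@analysis,
         outputDir = config@outputDir,
         meshPath = config@meshPath,
         seed = config@seed)
}

.configFromList <- function(lst) {
    known <- c("modelPreset", "geometry", "conductivity", "anisotropy",
               "wmCellModel", "durationMs", "solver", "analysis",
               "outputDir", "meshPath", "seed")
    unknown <- setdiff(names(lst), known)
    if (length(unknown))
        stop("unknown configuration key(s): ",
             paste(unknown, collapse = ", "))
    sdef <- solverConfig()
    sl <- .mergeDefaults(
        if (is.null(lst$solver)) list() else lst$solver,
        list(dt = sdef@dt, theta = sdef@theta, krylovRtol = sdef@krylovRtol,
             krylovAtol = sdef@krylovAtol,
             maxIterations = sdef@maxIterations,
             activeLabels = as.list(sdef@activeLabels),
             method = sdef@method, odeSubsteps = sdef@odeSubsteps,
             massLumping = sdef@massLumping), "solver")
    solver <- solverConfig(dt = sl$dt, theta = sl$theta,
                           krylovRtol = sl$krylovRtol,
                           krylovAtol = sl$krylovAtol,
                           maxIterations = sl$maxIterations,
                           activeLabels = unlist(sl$activeLabels),
                           method = sl$method, odeSubsteps = sl$odeSubsteps,
                           massLumping = sl$massLumping)
    ct <- if (is.null(lst$conductivity)) defaultConductivityTable()
          else lapply(lst$conductivity, as.numeric)
    preset <- if (is.null(lst$modelPreset)) "custom" else lst$modelPreset
    runConfig(modelPreset = preset,
              geometry = if (is.null(lst$geometry)) list() else lst$geometry,
              conductivityTable = ct,
              anisotropy = if (is.null(lst$anisotropy)) TRUE
                           else lst$anisotropy,
              wmCellModel = if (is.null(lst$wmCellModel)) "none"
                            else lst$wmCellModel,
              durationMs = if (is.null(lst$durationMs)) 10000
                           else lst$durationMs,
              solver = solver,
              analysis = if (is.null(lst$analysis)) list() else lst$analysis,
              outputDir = if (is.null(lst$outputDir)) "results"
                          else lst$outputDir,
              meshPath = if (is.null(lst$meshPath)) "" else lst$meshPath,
              seed = if (is.null(lst$seed)) 1L else lst$seed)
}

#' Load a run configuration from a YAML file
#'
#' Unspecified keys are filled with the documented defaults; unknown keys
#' raise an error listing them.  The returned object carries an attribute
#' \code{"provenance"} naming which top-level keys came from the file and
#' which were defaulted.  An empty file yields the all-default "custom"
#' configuration.  Configurations round-trip through
#' \code{\link{saveConfig}}.
#'
#' @param path YAML file path.
#' @return a \linkS4class{RunConfig}.
#' @export
loadConfig <- function(path) {
    lst <- yaml::read_yaml(path)
    if (is.null(lst)) lst <- list()
    if (!is.list(lst)) stop("configuration file must hold a key/value map")
    if (!is.null(lst$modelPreset) && lst$modelPreset %in% LETTERS[1:7]) {
        base <- .configToList(presetConfig(
            lst$modelPreset,
            meshPath = if (is.null(lst$meshPath)) "" else lst$meshPath))
        for (k in setdiff(names(base), names(lst))) lst[[k]] <- base[[k]]
        for (k in intersect(c("geometry", "analysis"), names(lst)))
            lst[[k]] <- .mergeDefaults(lst[[k]], base[[k]], k)
    }
    cfg <- .configFromList(lst)
    attr(cfg, "provenance") <- list(
        fromFile = names(lst),
        defaulted = setdiff(c("modelPreset", "geometry", "conductivity",
                              "anisotropy", "wmCellModel", "durationMs",
                              "solver", "analysis", "outputDir", "meshPath",
                              "seed"), names(lst)))
    cfg
}

#' Save a run configuration to a YAML file
#'
#' @param config a \linkS4class{RunConfig}.
#' @param path output YAML path.
#' @return \code{path}, invisibly.
#' @export
saveConfig <- function(config, path) {
    stopifnot(is(config, "RunConfig"))
    ## full double precision so configurations round-trip losslessly
    yaml::write_yaml(.configToList(config), path, precision = 15L)
    invisible(path)
}

## ---------------------------------------------------------------------------
## Execution
## ---------------------------------------------------------------------------

## Build mesh + conductivity + cell configuration for a tissue run.
.buildScene <- function(config) {
    g <- config@geometry
    if (g$type == "slice") {
        mesh <- buildIdealizedSlice(widthMm = g$widthMm,
                                    heightMm = g$heightMm,
                                    layerMm = g$layerMm,
                                    cellsAcrossGm = g$cellsAcrossGm,
                                    unstableWidthMm = g$unstableWidthMm,
                                    wmFine = isTRUE(g$wmFine))
    } else {
        mesh <- readLabeledMesh(config@meshPath)
        if (config@anisotropy)
            stop("anisotropy for external meshes requires per-cell ",
                 "tensors; supply an isotropic configuration")
    }
    wmSpec <- if (config@anisotropy && g$type == "slice")
        anisotropySpec(sigmaT = g$sigmaT, sigmaL = g$sigmaL) else NULL
    cond <- buildConductivityMap(mesh, config@conductivityTable,
                                 wmSpec = wmSpec)
    cellConfig <- list(GM_STABLE = cressmanParams(4),
                       GM_UNSTABLE = cressmanParams(8))
    if (config@wmCellModel == "cressman_stable") {
        for (lb in intersect(c("WM", "WM_LEFT", "WM_RIGHT"),
                             unique(mesh@cellLabels)))
            cellConfig[[lb]] <- cressmanParams(4)
    }
    list(mesh = mesh, cond = cond, cellConfig = cellConfig)
}

## Run a configuration in memory; returns list(traces, eventLog, complete).
.executeConfig <- function(config, verbose = FALSE) {
    g <- config@geometry
    an <- config@analysis
    if (g$type == "point") {
        r <- simulateCressman(cressmanParams(g$kOInf), config@durationMs,
                              dt = config@solver@dt,
                              stride = an$probeStride)
        return(list(traces = list("point:v" = r$trace),
                    eventLog = list(steps = round(config@durationMs /
                                                  config@solver@dt),
                                    dt = config@solver@dt, method = "euler"),
                    complete = TRUE))
    }
    scene <- .buildScene(config)
    res <- runSimulation(scene$mesh, scene$cond, physicalParams(),
                         cellConfig = scene$cellConfig, cfg = config@solver,
                         durationMs = config@durationMs,
                         probeStride = an$probeStride, verbose = verbose)
    list(traces = res@probeTraces, eventLog = res@eventLog,
         complete = res@complete)
}

## Analysis over a list of traces; adaptive threshold for extracellular
## traces (midrange of the 1st/99th percentiles) when configured.
.analyzeTraces <- function(traces, an) {
    lapply(traces, function(tr) {
        thr <- an$threshold
        if (isTRUE(an$adaptiveUeThreshold) && grepl(":ue$", tr@label))
            thr <- mean(stats::quantile(tr@values, c(0.01, 0.99)))
        analyzeTrace(tr, threshold = thr, refractoryMs = an$refractoryMs,
                     maxGapMs = an$maxGapMs, minSpikes = an$minSpikes,
                     fMin = an$fMin, fMax = an$fMax,
                     spectrumOn = an$spectrumOn)
    })
}

.writeBundle <- function(dir, config, traces, analyses, eventLog,
                         complete) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    ## traces.csv: shared time column plus one column per trace
    tdf <- data.frame(time_ms = traces[[1]]@times)
    for (nm in names(traces)) tdf[[nm]] <- traces[[nm]]@values
    utils::write.csv(tdf, file.path(dir, "traces.csv"), row.names = FALSE)

    spikes <- do.call(rbind, lapply(names(analyses), function(nm) {
        st <- analyses[[nm]]$spikes
        if (!length(st@spikeTimes)) return(NULL)
        data.frame(trace = nm, spikeTimeMs = st@spikeTimes,
                   threshold = st@threshold)
    }))
    if (is.null(spikes))
        spikes <- data.frame(trace = character(0), spikeTimeMs = numeric(0),
                             threshold = numeric(0))
    utils::write.csv(spikes, file.path(dir, "spikes.csv"),
                     row.names = FALSE)

    bursts <- do.call(rbind, lapply(names(analyses), function(nm) {
        b <- analyses[[nm]]$bursts
        if (!nrow(b)) return(NULL)
        cbind(data.frame(trace = nm), b)
    }))
    if (is.null(bursts))
        bursts <- data.frame(trace = character(0), startMs = numeric(0),
                             endMs = numeric(0), durationMs = numeric(0),
                             nSpikes = integer(0))
    utils::write.csv(bursts, file.path(dir, "bursts.csv"),
                     row.names = FALSE)

    psd <- do.call(rbind, lapply(names(analyses), function(nm) {
        p <- analyses[[nm]]$psd
        if (is.null(p)) return(NULL)
        cbind(data.frame(trace = nm), p)
    }))
    if (is.null(psd))
        psd <- data.frame(trace = character(0), frequency = numeric(0),
                          power = numeric(0))
    utils::write.csv(psd, file.path(dir, "psd.csv"), row.names = FALSE)

    fits <- do.call(rbind, lapply(names(analyses), function(nm) {
        f <- analyses[[nm]]$fit
        if (is.null(f)) return(NULL)
        data.frame(trace = nm, beta = f@beta, intercept = f@intercept,
                   fMin = f@fMin, fMax = f@fMax, rSquared = f@rSquared)
    }))
    if (is.null(fits))
        fits <- data.frame(trace = character(0), beta = numeric(0),
                           intercept = numeric(0), fMin = numeric(0),
                           fMax = numeric(0), rSquared = numeric(0))
    utils::write.csv(fits, file.path(dir, "fits.csv"), row.names = FALSE)

    saveConfig(config, file.path(dir, "config.yaml"))
    log <- c(sprintf("complete: %s", complete),
             vapply(names(eventLog), function(k)
                 sprintf("%s: %s", k, format(eventLog[[k]])), ""))
    writeLines(log, file.path(dir, "run.log"))
    invisible(dir)
}

#' Run an experiment and write a result bundle
#'
#' Executes the configured simulation (pure point-neuron for "point"
#' geometry, coupled tissue otherwise), runs the analysis pipeline on every
#' probe trace, and writes \code{traces.csv}, \code{spikes.csv},
#' \code{bursts.csv}, \code{psd.csv}, \code{fits.csv}, the resolved
#' \code{config.yaml} and \code{run.log} into \code{config@outputDir}.
#' Reruns with an identical configuration produce byte-identical trace
#' files.
#'
#' @param config a \linkS4class{RunConfig}.
#' @param verbose print progress.
#' @return invisibly, a list with \code{dir}, \code{traces},
#'   \code{analyses}, \code{complete}.
#' @export
runExperiment <- function(config, verbose = FALSE) {
    stopifnot(is(config, "RunConfig"))
    validObject(config)
    run <- .executeConfig(config, verbose = verbose)
    analyses <- .analyzeTraces(run$traces, config@analysis)
    .writeBundle(config@outputDir, config, run$traces, analyses,
                 run$eventLog, run$complete)
    invisible(list(dir = config@outputDir, traces = run$traces,
                   analyses = analyses, complete = run$complete))
}

#' Conductivity and thickness sensitivity suite
#'
#' Runs the base 2D configuration plus low/high variations of the selected
#' factors: \code{"thickness"} scales the outer-layer thickness,
#' \code{"sigmaL"} and \code{"sigmaT"} scale the white-matter anisotropy
#' components, each to (1 - delta) and (1 + delta) of the base value
#' (\code{mode = "scale"}), or to base/3 and 3*base
#' (\code{mode = "multiply"}, the alternative reading of "by a factor of
#' 1/3").  With all three factors this is a 7-run family.  Reports the
#' fitted gray-matter power-law exponent and the mean log10 spectral power
#' per run, so magnitude shifts can be compared against slope invariance.
#'
#' @param config base \linkS4class{RunConfig}; must use the built-in 2D
#'   slice geometry.
#' @param factors subset of c("thickness", "sigmaL", "sigmaT"); empty gives
#'   the single base run.
#' @param delta perturbation size (default 1/3).
#' @param mode "scale" (1 +/- delta) or "multiply" (x delta, x 1/delta).
#' @param verbose print progress.
#' @return list with \code{report} (data.frame: run, factor, level, trace,
#'   beta, meanLog10Power) and \code{runs} (per-run analysis lists).  When
#'   \code{config@outputDir} exists or can be created, per-run bundles and
#'   \code{sensitivity.csv} are written beneath it.
#' @export
sensitivitySuite <- function(config, factors = c("thickness", "sigmaL",
                                                 "sigmaT"),
                             delta = 1/3, mode = c("scale", "multiply"),
                             verbose = FALSE) {
    stopifnot(is(config, "RunConfig"))
    mode <- match.arg(mode)
    if (config@geometry$type != "slice")
        stop("sensitivity analysis requires the built-in 2D slice geometry")
    factors <- unique(factors)
    bad <- setdiff(factors, c("thickness", "sigmaL", "sigmaT"))
    if (length(bad)) stop("unknown factor(s): ", paste(bad, collapse = ", "))
    levels <- if (mode == "scale") c(low = 1 - delta, high = 1 + delta)
              else c(low = delta, high = 1 / delta)
    variants <- list(base = config)
    for (f in factors) for (lv in names(levels)) {
        v <- config
        s <- levels[[lv]]
        if (f == "thickness") v@geometry$layerMm <- v@geometry$layerMm * s
        if (f == "sigmaL") v@geometry$sigmaL <- v@geometry$sigmaL * s
        if (f == "sigmaT") v@geometry$sigmaT <- v@geometry$sigmaT * s
        variants[[paste(f, lv, sep = "_")]] <- v
    }
    report <- NULL
    runs <- list()
    for (nm in names(variants)) {
        v <- variants[[nm]]
        v@outputDir <- file.path(config@outputDir, nm)
        if (verbose) message("sensitivity run: ", nm)
        run <- .executeConfig(v, verbose = FALSE)
        analyses <- .analyzeTraces(run$traces, v@analysis)
        .writeBundle(v@outputDir, v, run$traces, analyses, run$eventLog,
                     run$complete)
        runs[[nm]] <- analyses
        for (tn in names(analyses)) {
            a <- analyses[[tn]]
            if (is.null(a$psd)) next
            sel <- a$psd$frequency > 0 & a$psd$power > 0
            report <- rbind(report, data.frame(
                run = nm,
                factor = sub("_(low|high)$", "", nm),
                level = if (nm == "base") "base"
                        else sub("^.*_", "", nm),
                trace = tn,
                beta = if (is.null(a$fit)) NA_real_ else a$fit@beta,
                meanLog10Power = mean(log10(a$psd$power[sel]))))
        }
    }
    if (!is.null(report))
        utils::write.csv(report,
                         file.path(config@outputDir, "sensitivity.csv"),
                         row.names = FALSE)
    list(report = report, runs = runs)
}
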