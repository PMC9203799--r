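#' Accessors for mesh and trace objects
#'
#' @param x an object.
#' @return \code{meshVertices}, \code{meshCells}, \code{probePoints}: the
#'   corresponding matrix; \code{cellLabels}: character vector of tissue
#'   labels; \code{meshDimension}: 2 or 3; \code{nCells}, \code{nVertices}:
#'   integer counts; \code{traceTimes}, \code{traceValues}: numeric vectors;
#'   \code{sampleRate}: sampling rate in Hz; \code{traceLabel}: character.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("meshVertices", function(x) standardGeneric("meshVertices"))
#' @rdname accessors
#' @export
setGeneric("meshCells", function(x) standardGeneric("meshCells"))
#' @rdname accessors
#' @export
setGeneric("cellLabels", function(x) standardGeneric("cellLabels"))
#' @rdname accessors
#' @export
setGeneric("probePoints", function(x) standardGeneric("probePoints"))
#' @rdname accessors
#' @export
setGeneric("meshDimension", function(x) standardGeneric("meshDimension"))
#' @rdname accessors
#' @export
setGeneric("nCells", function(x) standardGeneric("nCells"))
#' @rdname accessors
#' @export
setGeneric("nVertices", function(x) standardGeneric("nVertices"))
#' @rdname accessors
#' @export
setGeneric("traceTimes", function(x) standardGeneric("traceTimes"))
#' @rdname accessors
#' @export
setGeneric("traceValues", function(x) standardGeneric("traceValues"))
#' @rdname accessors
#' @export
setGeneric("sampleRate", function(x) standardGeneric("sampleRate"))
#' @rdname accessors
#' @export
setGeneric("traceLabel", function(x) standardGeneric("traceLabel"))
#' @rdname accessors
#' @export
setGeneric("spikeTimes", function(x) standardGeneric("spikeTimes"))
#' @rdname accessors
#' @export
setGeneric("probeTraces", function(x) standardGeneric("probeTraces"))

#' @rdname accessors
setMethod("meshVertices", "LabeledMesh", function(x) x@vertices)
#' @rdname accessors
setMethod("meshCells", "LabeledMesh", function(x) x@cells)
#' @rdname accessors
setMethod("cellLabels", "LabeledMesh", function(x) x@cellLabels)
#' @rdname accessors
setMethod("probePoints", "LabeledMesh", function(x) x@probePoints)
#' @rdname accessors
setMethod("meshDimension", "LabeledMesh", function(x) x@dimension)
#' @rdname accessors
setMethod("nCells", "LabeledMesh", function(x) nrow(x@cells))
#' @rdname accessors
setMethod("nVertices", "LabeledMesh", function(x) nrow(x@vertices))

#' @rdname accessors
setMethod("traceTimes", "ProbeTrace", function(x) x@times)
#' @rdname accessors
setMethod("traceValues", "ProbeTrace", function(x) x@values)
#' @rdname accessors
setMethod("traceLabel", "ProbeTrace", function(x) x@label)
#' @rdname accessors
setMethod("sampleRate", "ProbeTrace", function(x) {
    if (length(x@times) < 2) return(NA_real_)
    1000 / (x@times[2] - x@times[1])
})
#' @rdname accessors
setMethod("spikeTimes", "SpikeTrain", function(x) x@spikeTimes)
#' @rdname accessors
setMethod("probeTraces", "SimulationResult", function(x) x@probeTraces)

setMethod("show", "LabeledMesh", function(object) {
    cat(sprintf("LabeledMesh: %dD, %d vertices, %d cells, %d probes\n",
                object@dimension, nrow(object@vertices), nrow(object@cells),
                nrow(object@probePoints)))
    tab <- table(object@cellLabels)
    cat("  cells per label:",
        paste(sprintf("%s=%d", names(tab), as.integer(tab)), collapse = ", "),
        "\n")
})

setMethod("show", "ConductivityMap", function(object) {
    cat(sprintf("ConductivityMap: %d cells (%dD), mS/cm\n",
                nrow(object@Mi), object@dimension))
})

setMethod("show", "CressmanParams", function(object) {
    regime <- if (object@kOInf >= 6) "seizure-like (unstable)" else "stable"
    cat(sprintf("CressmanParams: kOInf = %g mM [%s]\n", object@kOInf, regime))
})

setMethod("show", "CressmanState", function(object) {
    n <- length(object@v)
    if (n == 1) {
        cat(sprintf(paste0("CressmanState: v=%.3f mV, n=%.4f, h=%.4f, ",
                           "Ko=%.3f mM, Nai=%.3f mM\n"),
                    object@v, object@gateN, object@gateH, object@kOut,
                    object@naIn))
    } else {
        cat(sprintf("CressmanState: collection of %d neurons, v in [%.2f, %.2f] mV\n",
                    n, min(object@v), max(object@v)))
    }
})

setMethod("show", "ProbeTrace", function(object) {
    n <- length(object@times)
    cat(sprintf("ProbeTrace '%s': %d samples", object@label, n))
    if (n > 1)
        cat(sprintf(", %.4g-%.4g ms at %.5g Hz", object@times[1],
                    object@times[n], sampleRate(object)))
    cat("\n")
})

setMethod("show", "SpikeTrain", function(object) {
    cat(sprintf("SpikeTrain: %d spikes (threshold %g mV, refractory %g ms)\n",
                length(object@spikeTimes), object@threshold,
                object@refractory))
})

setMethod("show", "PowerLawFit", function(object) {
    cat(sprintf("PowerLawFit: beta = %.4f over [%g, %g] Hz (R2 = %.4f)\n",
                object@beta, object@fMin, object@fMax, object@rSquared))
})

setMethod("show", "SimulationResult", function(object) {
    cat(sprintf("SimulationResult: %d probe traces, %d snapshots, %s\n",
                length(object@probeTraces), length(object@snapshots),
                if (object@complete) "complete" else "INCOMPLETE"))
})

setMethod("show", "RunConfig", function(object) {
    cat(sprintf("RunConfig: preset %s, duration %g ms, wm cell model %s, %s\n",
                object@modelPreset, object@durationMs, object@wmCellModel,
                if (object@anisotropy) "anisotropic WM" else "isotropic WM"))
})
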