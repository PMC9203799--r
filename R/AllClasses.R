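#' @import methods
#' @importFrom stats approx fft lm median quantile rnorm runif sd var
#' @importFrom utils read.csv write.csv head tail
#' @useDynLib neurofield, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

## Tissue labels understood throughout the package.  GM carries the active
## (ODE-bearing) cell model; CSF/SKULL/SCALP are passive volume conductors.
.tissueLabels <- c("GM_STABLE", "GM_UNSTABLE", "WM_LEFT", "WM_RIGHT", "WM",
                   "CSF", "SKULL", "SCALP")

#' Labeled simplicial mesh
#'
#' A conforming triangular (2D) or tetrahedral (3D) mesh whose cells carry a
#' tissue label, together with probe locations at which simulated potentials
#' are sampled.  Coordinates are stored in centimetres.
#'
#' @slot vertices numeric matrix, one row per vertex (cm).
#' @slot cells integer matrix, one row per cell; 3 columns for triangles,
#'   4 for tetrahedra (1-based vertex indices).
#' @slot cellLabels character vector, one tissue label per cell.
#' @slot probePoints numeric matrix of probe coordinates (cm); may have
#'   zero rows.  Row names identify the probes.
#' @slot dimension integer, 2 or 3.
#' @exportClass LabeledMesh
setClass("LabeledMesh",
         representation(vertices = "matrix", cells = "matrix",
                        cellLabels = "character", probePoints = "matrix",
                        dimension = "integer"))

setValidity("LabeledMesh", function(object) {
    d <- object@dimension
    msg <- character()
    if (!d %in% c(2L, 3L)) msg <- c(msg, "dimension must be 2 or 3")
    if (ncol(object@vertices) != d)
        msg <- c(msg, "vertices must have 'dimension' columns")
    if (ncol(object@cells) != d + 1L)
        msg <- c(msg, "cells must have dimension + 1 columns")
    if (length(object@cellLabels) != nrow(object@cells))
        msg <- c(msg, "need exactly one label per cell")
    if (nrow(object@cells) > 0) {
        idx <- range(object@cells)
        if (idx[1] < 1L || idx[2] > nrow(object@vertices))
            msg <- c(msg, "cell vertex indices out of range")
    }
    if (!all(object@cellLabels %in% .tissueLabels))
        msg <- c(msg, paste("unknown tissue label(s):",
                            paste(setdiff(unique(object@cellLabels),
                                          .tissueLabels), collapse = ", ")))
    if (nrow(object@probePoints) > 0) {
        if (ncol(object@probePoints) != d)
            msg <- c(msg, "probe points must have 'dimension' columns")
        else {
            lo <- apply(object@vertices, 2, min)
            hi <- apply(object@vertices, 2, max)
            inside <- apply(object@probePoints, 1, function(p)
                all(p >= lo - 1e-12) && all(p <= hi + 1e-12))
            if (!all(inside))
                msg <- c(msg, "probe points outside the mesh bounding box")
        }
    }
    if (length(msg)) msg else TRUE
})

#' White-matter anisotropy specification
#'
#' Longitudinal/transverse conductivities (mS/cm) and the unit orientation of
#' the principal (longitudinal) fibre axis.
#'
#' @slot sigmaL numeric(1), longitudinal conductivity, mS/cm.
#' @slot sigmaT numeric(1), transverse conductivity, mS/cm.
#' @slot orientation numeric unit vector (length 2 or 3).
#' @exportClass AnisotropySpec
setClass("AnisotropySpec",
         representation(sigmaL = "numeric", sigmaT = "numeric",
                        orientation = "numeric"))

setValidity("AnisotropySpec", function(object) {
    msg <- character()
    if (length(object@sigmaL) != 1 || object@sigmaL <= 0)
        msg <- c(msg, "sigmaL must be a positive scalar")
    if (length(object@sigmaT) != 1 || object@sigmaT <= 0)
        msg <- c(msg, "sigmaT must be a positive scalar")
    nrm <- sqrt(sum(object@orientation^2))
    if (!length(object@orientation) %in% c(2L, 3L) || nrm == 0)
        msg <- c(msg, "orientation must be a nonzero vector of length 2 or 3")
    else if (abs(nrm - 1) > 1e-8)
        msg <- c(msg, "orientation must have unit norm")
    if (length(msg)) msg else TRUE
})

#' Per-cell conductivity tensors
#'
#' Symmetric intracellular (Mi) and extracellular (Me) conductivity tensors,
#' one per mesh cell, in mS/cm.  Tensors are stored in packed form: columns
#' (xx, yy, xy) in 2D and (xx, yy, zz, xy, xz, yz) in 3D.
#'
#' @slot Mi numeric matrix of packed symmetric tensors, mS/cm.
#' @slot Me numeric matrix of packed symmetric tensors, mS/cm.
#' @slot dimension integer, 2 or 3.
#' @exportClass ConductivityMap
setClass("ConductivityMap",
         representation(Mi = "matrix", Me = "matrix", dimension = "integer"))

setValidity("ConductivityMap", function(object) {
    d <- object@dimension
    nc <- if (d == 2L) 3L else 6L
    msg <- character()
    if (ncol(object@Mi) != nc || ncol(object@Me) != nc)
        msg <- c(msg, sprintf("packed tensors need %d columns in %dD", nc, d))
    if (nrow(object@Mi) != nrow(object@Me))
        msg <- c(msg, "Mi and Me must cover the same cells")
    ok <- function(m) {
        if (d == 2L) {
            det2 <- m[, 1] * m[, 2] - m[, 3]^2
            all(m[, 1] > 0) && all(det2 > 0)
        } else {
            ## leading minors of the packed 3x3 tensor
            d1 <- m[, 1]
            d2 <- m[, 1] * m[, 2] - m[, 4]^2
            d3 <- m[, 1] * (m[, 2] * m[, 3] - m[, 6]^2) -
                m[, 4] * (m[, 4] * m[, 3] - m[, 6] * m[, 5]) +
                m[, 5] * (m[, 4] * m[, 6] - m[, 2] * m[, 5])
            all(d1 > 0) && all(d2 > 0) && all(d3 > 0)
        }
    }
    if (nrow(object@Mi) > 0) {
        if (!ok(object@Mi)) msg <- c(msg, "Mi must be positive definite")
        if (!ok(object@Me)) msg <- c(msg, "Me must be positive definite")
    }
    if (length(msg)) msg else TRUE
})

#' Cressman point-neuron parameters
#'
#' All named coefficients of the conductance-based neuron model with slow
#' extracellular potassium and intracellular sodium dynamics.  The regime
#' switch is the steady-state bath potassium \code{kOInf}: 4 mM gives the
#' stable (normal) cell, 8 mM the seizure-like (bursting) cell.
#'
#' Conductances are in mS/cm2, concentrations in mM, rates of the slow
#' subsystem in mM/s (converted internally by \code{tau}), capacitance in
#' uF/cm2.
#'
#' @slot kOInf steady-state extracellular potassium, mM.
#' @slot gNa,gK maximal sodium / potassium conductances, mS/cm2.
#' @slot gNaL,gKL,gClL leak conductances, mS/cm2.
#' @slot phi gating rate scale, 1/ms.
#' @slot rho maximal Na/K pump rate, mM/s.
#' @slot gGlia maximal glial potassium uptake, mM/s.
#' @slot epsK lateral potassium diffusion rate, 1/s.
#' @slot beta intracellular-to-extracellular volume ratio (dimensionless).
#' @slot tau unit conversion of the slow subsystem, ms per s (1000).
#' @slot gamma current-to-concentration conversion, mM cm2 / (uA s).
#' @slot Cm membrane capacitance of the point model, uF/cm2.
#' @slot nernst Nernst prefactor RT/F, mV.
#' @slot clIn,clOut fixed chloride concentrations, mM.
#' @slot naOutBase,naInRef,kInBase ion-conservation constants, mM.
#' @exportClass CressmanParams
setClass("CressmanParams",
         representation(kOInf = "numeric", gNa = "numeric", gK = "numeric",
                        gNaL = "numeric", gKL = "numeric", gClL = "numeric",
                        phi = "numeric", rho = "numeric", gGlia = "numeric",
                        epsK = "numeric", beta = "numeric", tau = "numeric",
                        gamma = "numeric", Cm = "numeric", nernst = "numeric",
                        clIn = "numeric", clOut = "numeric",
                        naOutBase = "numeric", naInRef = "numeric",
                        kInBase = "numeric"))

setValidity("CressmanParams", function(object) {
    msg <- character()
    for (nm in slotNames(object)) {
        x <- slot(object, nm)
        if (length(x) != 1 || !is.finite(x))
            msg <- c(msg, sprintf("%s must be a finite scalar", nm))
    }
    if (length(msg)) return(msg)
    if (object@kOInf <= 0) msg <- c(msg, "kOInf must be positive")
    nonneg <- c("gNa", "gK", "gNaL", "gKL", "gClL", "phi", "rho", "gGlia",
                "epsK")
    for (nm in nonneg)
        if (slot(object, nm) < 0)
            msg <- c(msg, sprintf("%s must be nonnegative", nm))
    if (object@Cm <= 0) msg <- c(msg, "Cm must be positive")
    if (length(msg)) msg else TRUE
})

#' Cressman point-neuron state
#'
#' State of one neuron or of a collection of neurons (all slots are parallel
#' vectors): membrane potential \code{v} (mV), potassium activation
#' \code{gateN} and sodium inactivation \code{gateH} (both in [0,1]),
#' extracellular potassium \code{kOut} (mM) and intracellular sodium
#' \code{naIn} (mM).
#'
#' @slot v numeric, membrane potential, mV.
#' @slot gateN numeric in [0,1].
#' @slot gateH numeric in [0,1].
#' @slot kOut numeric, positive, mM.
#' @slot naIn numeric, positive, mM.
#' @exportClass CressmanState
setClass("CressmanState",
         representation(v = "numeric", gateN = "numeric", gateH = "numeric",
                        kOut = "numeric", naIn = "numeric"))

setValidity("CressmanState", function(object) {
    n <- length(object@v)
    msg <- character()
    if (any(lengths(list(object@gateN, object@gateH, object@kOut,
                         object@naIn)) != n))
        msg <- c(msg, "all state slots must have equal length")
    if (!all(is.finite(object@v))) msg <- c(msg, "v must be finite")
    if (any(object@gateN < 0 | object@gateN > 1))
        msg <- c(msg, "gateN must lie in [0,1]")
    if (any(object@gateH < 0 | object@gateH > 1))
        msg <- c(msg, "gateH must lie in [0,1]")
    if (any(object@kOut <= 0)) msg <- c(msg, "kOut must be positive")
    if (any(object@naIn <= 0)) msg <- c(msg, "naIn must be positive")
    if (length(msg)) msg else TRUE
})

#' Tissue-level physical parameters
#'
#' @slot chi membrane surface area per unit volume, 1/cm.
#' @slot Cm membrane capacitance, uF/cm2.
#' @exportClass PhysicalParams
setClass("PhysicalParams", representation(chi = "numeric", Cm = "numeric"))

setValidity("PhysicalParams", function(object) {
    if (length(object@chi) != 1 || object@chi <= 0) return("chi must be > 0")
    if (length(object@Cm) != 1 || object@Cm <= 0) return("Cm must be > 0")
    TRUE
})

#' Time-stepping and linear-solver configuration
#'
#' @slot dt time step, ms.
#' @slot theta PDE time-stepping weight in [0,1] (0.5 = Crank-Nicolson).
#' @slot krylovRtol,krylovAtol iterative-solver tolerances.
#' @slot maxIterations iteration cap for the iterative solver.
#' @slot activeLabels tissue labels in which cell ODEs are solved.
#' @slot method "direct" (cached sparse LU) or "gmres".
#' @slot odeSubsteps forward-Euler substeps per splitting half-step.
#' @slot massLumping logical; use a lumped mass matrix.
#' @exportClass SolverConfig
setClass("SolverConfig",
         representation(dt = "numeric", theta = "numeric",
                        krylovRtol = "numeric", krylovAtol = "numeric",
                        maxIterations = "integer", activeLabels = "character",
                        method = "character", odeSubsteps = "integer",
                        massLumping = "logical"))

setValidity("SolverConfig", function(object) {
    msg <- character()
    if (object@dt <= 0) msg <- c(msg, "dt must be positive")
    if (object@theta < 0 || object@theta > 1)
        msg <- c(msg, "theta must lie in [0,1]")
    if (object@krylovRtol <= 0 || object@krylovAtol <= 0)
        msg <- c(msg, "solver tolerances must be positive")
    if (object@odeSubsteps < 1L) msg <- c(msg, "odeSubsteps must be >= 1")
    if (!object@method %in% c("direct", "gmres"))
        msg <- c(msg, "method must be 'direct' or 'gmres'")
    if (length(msg)) msg else TRUE
})

#' Nodal bidomain fields at one time point
#'
#' @slot v nodal transmembrane potential, mV.
#' @slot ue nodal extracellular potential, mV (zero weighted mean).
#' @slot t current time, ms.
#' @exportClass BidomainFields
setClass("BidomainFields",
         representation(v = "numeric", ue = "numeric", t = "numeric"))

setValidity("BidomainFields", function(object) {
    if (length(object@v) != length(object@ue))
        return("v and ue must have equal length")
    if (!all(is.finite(object@v)) || !all(is.finite(object@ue)))
        return("fields must be finite")
    TRUE
})

#' Sampled potential time series at a probe
#'
#' @slot times sampling times, ms, strictly increasing uniform grid.
#' @slot values potential values, mV.
#' @slot label probe identity plus field name ("v" or "ue").
#' @exportClass ProbeTrace
setClass("ProbeTrace",
         representation(times = "numeric", values = "numeric",
                        label = "character"))

setValidity("ProbeTrace", function(object) {
    if (length(object@times) != length(object@values))
        return("times and values must have equal length")
    if (length(object@times) > 2) {
        dt <- diff(object@times)
        if (any(dt <= 0)) return("times must be strictly increasing")
        if (max(abs(dt - dt[1])) > 1e-9 * max(abs(dt[1]), 1))
            return("times must form a uniform grid (1e-9 relative)")
    }
    TRUE
})

#' Detected spike train
#'
#' @slot spikeTimes spike times, ms, strictly increasing.
#' @slot threshold detection threshold, mV.
#' @slot refractory enforced minimal inter-spike interval, ms.
#' @exportClass SpikeTrain
setClass("SpikeTrain",
         representation(spikeTimes = "numeric", threshold = "numeric",
                        refractory = "numeric"))

setValidity("SpikeTrain", function(object) {
    if (length(object@spikeTimes) > 1) {
        d <- diff(object@spikeTimes)
        if (any(d <= 0)) return("spikeTimes must be strictly increasing")
        if (any(d < object@refractory - 1e-9))
            return("spikes closer than the refractory period")
    }
    TRUE
})

#' Fitted power-law spectrum descriptor (p ~ f^-beta)
#'
#' @slot beta power-law exponent (positive for decaying spectra).
#' @slot intercept log10 power at 1 Hz.
#' @slot fMin,fMax fitting band, Hz.
#' @slot rSquared goodness of fit of the log-log regression.
#' @exportClass PowerLawFit
setClass("PowerLawFit",
         representation(beta = "numeric", intercept = "numeric",
                        fMin = "numeric", fMax = "numeric",
                        rSquared = "numeric"))

setValidity("PowerLawFit", function(object) {
    if (object@fMin >= object@fMax) return("fMin must be < fMax")
    TRUE
})

#' Result of a tissue simulation
#'
#' @slot probeTraces list of \linkS4class{ProbeTrace} (u_e and v per probe),
#'   all on the same time grid.
#' @slot snapshots list of \linkS4class{BidomainFields} at requested times.
#' @slot eventLog list with solver statistics (steps, wall time, iterations).
#' @slot complete logical; FALSE if the run was aborted.
#' @exportClass SimulationResult
setClass("SimulationResult",
         representation(probeTraces = "list", snapshots = "list",
                        eventLog = "list", complete = "logical"))

setValidity("SimulationResult", function(object) {
    if (!all(vapply(object@probeTraces, is, TRUE, "ProbeTrace")))
        return("probeTraces must all be ProbeTrace objects")
    if (length(object@probeTraces) > 1) {
        t0 <- object@probeTraces[[1]]@times
        same <- vapply(object@probeTraces, function(tr)
            length(tr@times) == length(t0) && all(tr@times == t0), TRUE)
        if (!all(same)) return("all traces must share one time grid")
    }
    TRUE
})

#' Resolved run configuration
#'
#' Mirrors the study's model presets: A/B are pure point-neuron runs, C/D the
#' idealized two-dimensional slice with anisotropic white matter (without and
#' with a stable white-matter cell model), E/F/G user-supplied
#' three-dimensional head meshes.
#'
#' @slot modelPreset one of "A".."G" or "custom".
#' @slot geometry list of idealized-slice parameters (mm).
#' @slot conductivityTable named list label -> c(mi, me), mS/cm.
#' @slot anisotropy logical; apply the white-matter anisotropy tensor.
#' @slot wmCellModel "none" or "cressman_stable".
#' @slot durationMs simulated duration, ms.
#' @slot solver a \linkS4class{SolverConfig}.
#' @slot analysis list of spike/burst/PSD settings.
#' @slot outputDir where \code{runExperiment} writes results.
#' @slot meshPath external labeled mesh (presets E-G), or "".
#' @slot seed integer seed for the synthetic-fixture generator.
#' @exportClass RunConfig
setClass("RunConfig",
         representation(modelPreset = "character", geometry = "list",
                        conductivityTable = "list", anisotropy = "logical",
                        wmCellModel = "character", durationMs = "numeric",
                        solver = "SolverConfig", analysis = "list",
                        outputDir = "character", meshPath = "character",
                        seed = "integer"))

setValidity("RunConfig", function(object) {
    msg <- character()
    if (!object@modelPreset %in% c(LETTERS[1:7], "custom"))
        msg <- c(msg, "modelPreset must be one of A..G or 'custom'")
    if (object@modelPreset %in% c("E", "F", "G") && !nzchar(object@meshPath))
        msg <- c(msg, sprintf("preset %s requires an external mesh path",
                              object@modelPreset))
    if (object@modelPreset %in% c("A", "B") && nzchar(object@meshPath))
        msg <- c(msg, "presets A and B are pure ODE runs and forbid a mesh")
    if (!object@wmCellModel %in% c("none", "cressman_stable"))
        msg <- c(msg, "wmCellModel must be 'none' or 'cressman_stable'")
    if (object@durationMs <= 0) msg <- c(msg, "durationMs must be positive")
    if (length(msg)) msg else TRUE
})
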