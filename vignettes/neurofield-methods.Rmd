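---
title: "Methods: bidomain simulation of seizure-like waves in head tissue"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bidomain simulation of seizure-like waves in head tissue}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neurofield)
```

# Overview

`neurofield` simulates seizure-like electrical activity in a cross-section
of head tissue.  It couples two ingredients:

* a **tissue model** — the bidomain equations, which treat gray and white
  matter as two interpenetrating conducting continua (intracellular and
  extracellular) linked through the cell membrane, and treat cerebrospinal
  fluid (CSF), skull, and scalp as passive volume conductors; and
* a **cell model** — a conductance-based point-neuron model with slow ion
  concentration dynamics (extracellular potassium and intracellular
  sodium), which in one parameterization settles to a stable resting state
  and in another produces long recurring bursts of fast spiking, a
  seizure-like regime.

The package also contains a spectral-analysis pipeline (spike counting,
burst segmentation, Welch power spectral densities, band-restricted
power-law fits) and a small experiment workbench with named presets, YAML
configuration files, and a command-line entry point.

# The cell model

The membrane carries transient sodium, delayed-rectifier potassium, leak,
calcium-gated potassium, and chloride currents.  Two slow variables — the
extracellular potassium concentration and the intracellular sodium
concentration — evolve through pump, glia, and diffusion terms, and feed
back on the reversal potentials.  The model state is five-dimensional:
membrane potential `v` (mV), gating variables `n` and `h`, extracellular
potassium (mM), and intracellular sodium (mM).

The single free parameter exposed by `cressmanParams()` is the bath
potassium concentration `kOInf` (mM), the value toward which extracellular
potassium diffuses:

* `kOInf = 4`: the **stable** regime.  From the package's documented seed
  state the neuron fires a handful of spikes while the ion concentrations
  relax, then stays quiescent.
* `kOInf = 8`: the **seizure-like** regime.  The neuron produces a long
  burst of fast spiking (hundreds of spikes over several seconds), falls
  silent while the pumps recover, and then bursts again tens of seconds
  later.

```{r cell, fig.width = 7, fig.height = 3, eval = FALSE}
r <- simulateCressman(cressmanParams(8), durationMs = 10000)
plot(traceTimes(r$trace) / 1000, traceValues(r$trace), type = "l",
     xlab = "time (s)", ylab = "v (mV)")
```

The integrator is plain forward Euler (a compiled kernel), matching the
stiffness profile of the model at the default `dt = 0.025` ms; gating
variables and concentrations are guarded against leaving their physical
ranges, and an informative error names the offending state if the step
size is too large.

# The tissue model

On the brain subdomain (gray and white matter) the bidomain equations read

$$\nabla\cdot(M_i\nabla v) + \nabla\cdot(M_i\nabla u_e)
  = \chi C_m \frac{\partial v}{\partial t} + \chi I_{\mathrm{ion}}(v, s),$$
$$\nabla\cdot(M_i\nabla v) + \nabla\cdot((M_i+M_e)\nabla u_e) = 0,$$

where `v` is the transmembrane potential, `u_e` the extracellular
potential, `M_i`/`M_e` the intracellular/extracellular conductivity
tensors, `χ` the membrane area per unit volume, and `C_m` the membrane
capacitance per unit area.  Passive tissues (CSF, skull, scalp) carry only
the second equation: their intracellular conductivity is set to a
negligible value so no membrane dynamics occur there, and the
extracellular potential is solved across the whole slice.  The boundary is
insulating (homogeneous Neumann), so `u_e` is determined only up to a
constant; the package fixes the gauge by constraining its mass-weighted
mean to zero with a Lagrange multiplier row in the linear system.

Default conductivities (mS/cm, intracellular/extracellular): gray matter
1/2.78, white matter 1/1.26, CSF —/17, skull —/0.1, scalp —/4.3.  White
matter can be made **anisotropic**: the tensor is
$\sigma_t I + (\sigma_l - \sigma_t)\, d d^\top$ with longitudinal
$\sigma_l = 1$ and transverse $\sigma_t = 0.1$ along a per-region fiber
direction `d` (vertical fibers in the left half, horizontal in the right
half of the built-in slice).

# Geometry

`buildIdealizedSlice()` builds a 60 mm × 40 mm cross-section with, from
the top: scalp, skull, CSF, and gray matter layers of 4 mm each, over
24 mm of white matter.  A 4 mm-wide central square of the gray-matter
layer is labeled `GM_UNSTABLE` and given the seizure-like cell
parameterization; the rest of the gray matter is `GM_STABLE`.  The
triangulation is graded — fine in the gray matter (5 cells across the
layer by default, ~0.8 mm), coarser in the passive layers — and
conforming across the grading transitions.  `wmFine = TRUE` meshes the
white matter at gray-matter resolution, which is required when a cell
model is active there.  Meshes round-trip through a plain-text mesh format
(`writeLabeledMesh()` / `readLabeledMesh()`), so externally generated
labeled meshes (2D or 3D) can be used instead.

Mesh resolution is not a mere accuracy knob here: on meshes much coarser
than the ~1 mm wavefront width, traveling waves launched by the unstable
focus die out before reaching distant gray matter, a qualitative failure
mode (not just larger errors) that the test suite demonstrates.

# Discretization

Space: first-order Lagrange (P1) finite elements on triangles or
tetrahedra; per-cell conductivity tensors; optional mass lumping.
Time: second-order operator (Strang) splitting.  Each step of size `dt`
advances the cell ODEs a half step at active vertices, solves the coupled
two-field linear system for one step with a θ-scheme (θ = ½ by default,
which preserves the splitting's second order), and advances the ODEs
another half step.  The linear system is symmetric and is solved either by
a cached sparse LU factorization (`method = "direct"`, the default — the
matrix is constant so the factorization is reused every step) or by
restarted GMRES with Jacobi preconditioning (`method = "gmres"`).

The test suite verifies second-order convergence of the full
split scheme against a closed-form solution of the bidomain system with a
linear reaction term, checks the assembled operators against an
independent dense assembly, and checks the iterative and direct solvers
against each other.

# Spectral analysis

* `countSpikes()` counts upward threshold crossings (default −20 mV) with
  a refractory window.
* `detectBursts()` groups spikes separated by less than `maxGapMs`
  (default 500 ms) into bursts and reports start, end, duration, and
  spike count.
* `welchPSD()` computes the Welch power spectral density: periodic Hann
  window, 50% overlap, per-segment mean removal, one-sided density
  normalization.  The implementation is tested to ~1e-10 against a direct
  segment-loop reference.
* `fitPowerLaw()` fits `log10(power) ~ log10(frequency)` over a band
  (default 100–5000 Hz) and reports the negated slope β, so a `1/f^β`
  spectrum yields β.
* `synthPowerLawTrace()` generates synthetic traces with a prescribed
  exponent, used to calibrate the estimator: across β = 0…5 the mean
  absolute bias stays below 0.1 when the trace is long enough for the
  default segmentation (the test suite uses 2^17 samples at 40 kHz).

The membrane trace of the seizure-like point model, restricted to its
initial burst, has a fitted exponent between 2 and 3 in the 100–5000 Hz
band — the quantitative signature the acceptance tests check.

# The workbench

`presetConfig()` provides seven named model configurations:

| preset | geometry | anisotropy | WM cell model |
|--------|----------|------------|---------------|
| A | point neuron, stable (`kOInf = 4`) | — | — |
| B | point neuron, seizure-like (`kOInf = 8`) | — | — |
| C | built-in 2D slice | yes | none |
| D | built-in 2D slice | yes | stable everywhere in WM |
| E | external labeled mesh | no | none |
| F | external labeled mesh | yes | none |
| G | external labeled mesh | no | stable everywhere in WM |

Anisotropy requires the built-in slice (the external-mesh presets that
use it must carry fiber directions through the conductivity table).
`runExperiment()` builds the scene, runs the simulation, analyzes every
probe trace, and writes a self-describing bundle (`traces.csv`,
`spikes.csv`, `bursts.csv`, `psd.csv`, `fits.csv`, `config.yaml`,
`run.log`).  Runs are deterministic: an identical configuration yields a
byte-identical bundle.  `sensitivitySuite()` perturbs layer thicknesses
and the white-matter anisotropy strengths around a base configuration and
tabulates the effect on the fitted exponents.  A thin command-line entry
point (`inst/exec/neurofield`) exposes `mesh`, `run`, `analyze`, `sweep`,
and `presets` subcommands; all logic lives in the exported R functions.

```{r workbench, eval = FALSE}
cfg <- presetConfig("B", durationMs = 10000, outputDir = "pointB")
res <- runExperiment(cfg)
res$analyses[["point:v"]]$bursts
```

# Reproduction tiers and limitations

Desk-scale checks (minutes) run in the test suite: the point-model spike
counts, burst statistics and spectra at full 10 s duration, and 1 s
scaled-down tissue runs demonstrating wave propagation, coarse-mesh
propagation failure, anisotropy-dependent penetration of the extracellular
signal into white matter, and scalp attenuation.  The full 10 s tissue
experiments are hours of CPU; they ship as a standalone script
(`system.file("scripts", "long_reproduction.R", package = "neurofield")`)
with their reference outcomes documented in its header.

Known limitations:

* forward Euler for the cell ODEs restricts `dt`; the package detects and
  reports instability rather than silently producing garbage;
* the built-in geometry is an idealized layered slice, not an
  image-derived anatomy; external meshes are supported but fiber fields on
  them are not;
* the bidomain model omits capillary/blood compartments and temperature
  or pharmacological modulation of the cell model;
* spectra from short traces carry segmentation bias; the calibration
  facilities quantify it, but short-burst exponents should be read with
  that in mind.
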