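# neurofield

Bidomain simulation of seizure-like electrical waves in an idealized 2D
head slice (scalp, skull, CSF, gray matter, white matter), coupled to a
conductance-based point-neuron model with slow potassium/sodium
concentration dynamics, plus a spectral-analysis pipeline and an
experiment workbench.

* **Geometry** — graded conforming triangulation of a 60 × 40 mm layered
  slice with a seizure-prone gray-matter focus, per-tissue conductivity
  tensors, optional white-matter anisotropy, probe placement, and a
  plain-text labeled-mesh format (2D and 3D) for external meshes.
* **Cell model** — five-state neuron (`v`, `n`, `h`, extracellular K⁺,
  intracellular Na⁺); bath potassium `kOInf = 4` gives a stable resting
  state, `kOInf = 8` gives recurring seizure-like bursts.
* **Solver** — P1 finite elements, second-order operator splitting,
  θ-scheme PDE step, cached sparse LU or preconditioned GMRES, zero-mean
  gauge for the extracellular potential.
* **Spectral analysis** — spike counting, burst segmentation, Welch PSD,
  band-restricted power-law exponent fits, synthetic calibration traces.
* **Workbench** — presets A–G, YAML configs, deterministic CSV result
  bundles, sensitivity sweeps, and a thin CLI.

## Worked example

Point-neuron seizure dynamics and burst spectrum:

```r
library(neurofield)

## seizure-like regime: 10 s at dt = 0.025 ms
r <- simulateCressman(cressmanParams(kOInf = 8), durationMs = 10000)
spikes <- countSpikes(r$trace, threshold = -20, refractoryMs = 2)
bursts <- detectBursts(spikes, maxGapMs = 500, minSpikes = 10)
bursts
#>   startMs    endMs durationMs nSpikes
#> 1     0.5   6596.9     6596.4     246

## power-law exponent of the initial burst, 100-5000 Hz
tt <- traceTimes(r$trace)
sel <- tt >= bursts$startMs[1] & tt <= bursts$endMs[1]
fit <- fitPowerLaw(welchPSD(probeTrace(tt[sel], traceValues(r$trace)[sel])),
                   fMin = 100, fMax = 5000)
fit@beta   # ~2.25
```

A short coupled tissue run on the built-in slice:

```r
mesh <- buildIdealizedSlice()            # graded 2D head slice, ~1.9e3 cells
cond <- buildConductivityMap(mesh, wmSpec = anisotropySpec())
res <- runSimulation(mesh, cond, physicalParams(),
                     cellConfig = list(GM_STABLE = cressmanParams(4),
                                       GM_UNSTABLE = cressmanParams(8)),
                     cfg = solverConfig(), durationMs = 1000,
                     probes = defaultProbePoints(mesh))
countSpikes(probeTraces(res)[["GM:v"]])   # waves arriving at the GM probe
```

Or drive everything from a configuration:

```r
cfg <- presetConfig("C", durationMs = 1000,
                    outputDir = "results_C")
runExperiment(cfg)        # writes traces.csv, spikes.csv, psd.csv, ...
```

The CLI wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("exec", "neurofield", package = "neurofield"))')
Rscript "$CLI" presets
Rscript "$CLI" run --config my.yaml --out results/
```

See the methods vignette (`vignettes/neurofield-methods.Rmd`) for the
model equations, discretization, and preset table.

## Reproduction

Three tiers:

1. **Test suite** (minutes):

   ```r
   testthat::test_dir("tests/testthat", package = "neurofield",
                      load_package = "installed")
   ```

   covers unit oracles for every module plus acceptance blocks: point-model
   spike/burst statistics at full 10 s duration, burst spectra, estimator
   calibration, solver convergence order, and 1 s scaled-down tissue runs
   (propagation, coarse-mesh propagation failure, anisotropic white-matter
   penetration, scalp attenuation).

2. **Acceptance script** (≈2 min) — computes the headline numbers from
   scratch against the installed package and writes bare-number JSON:

   ```sh
   Rscript scripts/acceptance.R --seed 1 --out acceptance.json
   ```

   Targets: stable-model spike count over 10 s, seizure-model initial-burst
   spike count and duration, and the burst power-law exponent
   (lower/upper bound check).

3. **Long tier** (hours of CPU) — full 10 s tissue experiments with and
   without a white-matter cell model, plus the sensitivity family:

   ```sh
   Rscript scripts/long_reproduction.R --out long_results
   ```

   Reference outcomes are documented in the script header.
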