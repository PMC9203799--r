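test_that("presets match the study table field-for-field", {
    a <- presetConfig("A")
    expect_equal(a@geometry$type, "point")
    expect_equal(a@geometry$kOInf, 4)
    expect_false(a@anisotropy)
    expect_equal(a@meshPath, "")
    b <- presetConfig("B")
    expect_equal(b@geometry$kOInf, 8)
    cc <- presetConfig("C")
    expect_equal(cc@geometry$type, "slice")
    expect_true(cc@anisotropy)
    expect_equal(cc@wmCellModel, "none")
    expect_equal(cc@durationMs, 10000)
    d <- presetConfig("D")
    expect_equal(d@geometry$type, "slice")
    expect_true(d@anisotropy)
    expect_equal(d@wmCellModel, "cressman_stable")
    e <- presetConfig("E", meshPath = "head.msh")
    expect_equal(e@geometry$type, "mesh")
    expect_false(e@anisotropy)
    expect_equal(e@wmCellModel, "none")
    f <- presetConfig("F", meshPath = "head.msh")
    expect_true(f@anisotropy)
    g <- presetConfig("G", meshPath = "head.msh")
    expect_false(g@anisotropy)
    expect_equal(g@wmCellModel, "cressman_stable")
})

test_that("preset/mesh invariants are enforced", {
    expect_error(presetConfig("E"), "mesh")
    expect_error(presetConfig("A", meshPath = "x.msh"), "forbid")
})

test_that("configurations round-trip through YAML", {
    cfg <- presetConfig("D", durationMs = 1234,
                        solver = solverConfig(dt = 0.05, method = "gmres"),
                        analysis = list(fMin = 40))
    p <- tempfile(fileext = ".yaml")
    saveConfig(cfg, p)
    cfg2 <- loadConfig(p)
    expect_equal(neurofield:::.configToList(cfg2),
                 neurofield:::.configToList(cfg))
    unlink(p)
})

test_that("empty config file yields all defaults with preset custom", {
    p <- tempfile(fileext = ".yaml")
    writeLines("", p)
    cfg <- loadConfig(p)
    expect_equal(cfg@modelPreset, "custom")
    expect_equal(cfg@durationMs, 10000)
    prov <- attr(cfg, "provenance")
    expect_true("durationMs" %in% prov$defaulted)
    unlink(p)
})

test_that("unknown configuration keys raise a listing error", {
    p <- tempfile(fileext = ".yaml")
    writeLines(c("modelPreset: C", "bogus: 1", "alsoBad: 2"), p)
    expect_error(loadConfig(p), "bogus")
    writeLines(c("geometry:", "  nonsense: 3"), p)
    expect_error(loadConfig(p), "nonsense")
    writeLines(c("solver:", "  warp: 9"), p)
    expect_error(loadConfig(p), "warp")
    unlink(p)
})

test_that("config files can override preset fields", {
    p <- tempfile(fileext = ".yaml")
    writeLines(c("modelPreset: C", "durationMs: 500",
                 "geometry:", "  cellsAcrossGm: 2"), p)
    cfg <- loadConfig(p)
    expect_equal(cfg@durationMs, 500)
    expect_equal(cfg@geometry$cellsAcrossGm, 2)
    expect_true(cfg@anisotropy)           # inherited from preset C
    unlink(p)
})

test_that("point-model experiment writes a complete, parseable bundle", {
    td <- tempfile()
    cfg <- presetConfig("B", durationMs = 1500, outputDir = td)
    r <- runExperiment(cfg)
    expect_true(r$complete)
    files <- c("traces.csv", "spikes.csv", "bursts.csv", "psd.csv",
               "fits.csv", "config.yaml", "run.log")
    for (f in files) expect_true(file.exists(file.path(td, f)), info = f)
    tr <- read.csv(file.path(td, "traces.csv"))
    expect_true(all(c("time_ms", "point.v") %in% names(tr)) ||
                "point:v" %in% names(read.csv(file.path(td, "traces.csv"),
                                              check.names = FALSE)))
    sp <- read.csv(file.path(td, "spikes.csv"))
    expect_gt(nrow(sp), 10)
    fits <- read.csv(file.path(td, "fits.csv"))
    expect_true(is.finite(fits$beta[1]))
    cfg2 <- loadConfig(file.path(td, "config.yaml"))
    expect_equal(cfg2@durationMs, 1500)
    unlink(td, recursive = TRUE)
})

test_that("reruns of an identical config are byte-identical", {
    t1 <- tempfile(); t2 <- tempfile()
    r1 <- runExperiment(presetConfig("B", durationMs = 800,
                                     outputDir = t1))
    r2 <- runExperiment(presetConfig("B", durationMs = 800,
                                     outputDir = t2))
    for (f in c("traces.csv", "spikes.csv", "psd.csv", "fits.csv")) {
        expect_identical(readLines(file.path(t1, f)),
                         readLines(file.path(t2, f)), info = f)
    }
    unlink(c(t1, t2), recursive = TRUE)
})

test_that("a coupled slice experiment runs end to end on a coarse mesh", {
    td <- tempfile()
    cfg <- presetConfig("C", durationMs = 20,
                        geometry = list(cellsAcrossGm = 1),
                        outputDir = td)
    r <- runExperiment(cfg)
    expect_true(r$complete)
    tdf <- read.csv(file.path(td, "traces.csv"), check.names = FALSE)
    expect_true("GM:ue" %in% names(tdf))
    expect_true(any(abs(tdf[["GM:v"]] + 50) > 1))  # membrane moved
    unlink(td, recursive = TRUE)
})

test_that("sensitivity suite validates inputs and handles the trivial case", {
    expect_error(sensitivitySuite(presetConfig("B")), "2D")
    expect_error(sensitivitySuite(presetConfig("C"),
                                  factors = "viscosity"), "unknown factor")
    td <- tempfile()
    cfg <- presetConfig("C", durationMs = 20,
                        geometry = list(cellsAcrossGm = 1),
                        analysis = list(probeStride = 2),
                        outputDir = td)
    r <- sensitivitySuite(cfg, factors = character(0))
    expect_equal(names(r$runs), "base")
    expect_true(all(r$report$run == "base"))
    expect_true(file.exists(file.path(td, "sensitivity.csv")))
    unlink(td, recursive = TRUE)
})

test_that("sensitivity variants perturb the intended parameters", {
    td <- tempfile()
    cfg <- presetConfig("C", durationMs = 10,
                        geometry = list(cellsAcrossGm = 1),
                        analysis = list(probeStride = 2),
                        outputDir = td)
    r <- sensitivitySuite(cfg, factors = "sigmaT")
    expect_setequal(names(r$runs), c("base", "sigmaT_low", "sigmaT_high"))
    lowCfg <- loadConfig(file.path(td, "sigmaT_low", "config.yaml"))
    expect_equal(lowCfg@geometry$sigmaT, 0.1 * (1 - 1/3), tolerance = 1e-12)
    unlink(td, recursive = TRUE)
})

test_that("the command-line entry point is shipped and lists presets", {
    cli <- system.file("exec", "neurofield", package = "neurofield")
    expect_true(nzchar(cli))
    out <- system2("Rscript", c(cli, "presets"), stdout = TRUE,
                   stderr = TRUE)
    expect_true(any(grepl("preset C", out)))
})
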