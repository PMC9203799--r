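test_that("element assembly matches a hand oracle on a two-triangle mesh", {
    verts <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
    cells <- rbind(c(1L, 2L, 3L), c(1L, 3L, 4L))
    mesh <- new("LabeledMesh", vertices = verts, cells = cells,
                cellLabels = rep("GM_STABLE", 2),
                probePoints = matrix(numeric(0), 0, 2), dimension = 2L)
    ## anisotropic, non-diagonal tensors, distinct per cell
    M1 <- matrix(c(2, 0.5, 0.5, 1), 2)
    M2 <- matrix(c(1, -0.3, -0.3, 3), 2)
    cond <- new("ConductivityMap",
                Mi = rbind(c(2, 1, 0.5), c(1, 3, -0.3)),
                Me = rbind(c(2, 1, 0.5), c(1, 3, -0.3)),
                dimension = 2L)
    ops <- assembleOperators(mesh, cond, physicalParams())
    Kref <- oracleStiffness(mesh, list(M1, M2))
    expect_equal(as.matrix(ops@stiffI), Kref, tolerance = 1e-13,
                 ignore_attr = TRUE)
    expect_equal(as.matrix(ops@stiffIE), 2 * Kref, tolerance = 1e-13,
                 ignore_attr = TRUE)
    ## consistent P1 mass matrix of the unit square
    Mref <- matrix(0, 4, 4)
    for (e in 1:2) {
        ids <- cells[e, ]
        Mref[ids, ids] <- Mref[ids, ids] +
            (1 / 2) / 12 * (matrix(1, 3, 3) + diag(3))
    }
    expect_equal(as.matrix(ops@mass), Mref, tolerance = 1e-13,
                 ignore_attr = TRUE)
})

test_that("assembled operators are symmetric with the constant null vector", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 2, probes = FALSE)
    cond <- buildConductivityMap(mesh, wmSpec = anisotropySpec())
    ops <- assembleOperators(mesh, cond)
    for (K in list(ops@stiffI, ops@stiffIE)) {
        expect_lt(max(abs(K - Matrix::t(K))), 1e-12)
        expect_lt(max(abs(K %*% rep(1, nVertices(mesh)))), 1e-10)
    }
    ## total mass = domain area (6 x 4 cm)
    expect_equal(sum(ops@massVec), 24, tolerance = 1e-10)
    ## lumped mass preserves the total
    opsL <- assembleOperators(mesh, cond, massLumping = TRUE)
    expect_equal(sum(Matrix::diag(opsL@mass)), 24, tolerance = 1e-10)
})

test_that("3D assembly matches the oracle and null-space/compatibility hold", {
    mesh <- unitCubeMesh()
    cond <- identityConductivity(mesh, mi = 1, me = 2)
    ops <- assembleOperators(mesh, cond)
    Kref <- oracleStiffness(mesh, replicate(6, diag(3), simplify = FALSE))
    expect_equal(as.matrix(ops@stiffI), Kref, tolerance = 1e-13,
                 ignore_attr = TRUE)
    expect_equal(as.matrix(ops@stiffIE), 3 * Kref, tolerance = 1e-13,
                 ignore_attr = TRUE)
    expect_lt(max(abs(ops@stiffI %*% rep(1, 8))), 1e-12)
    ## unit cube volume
    expect_equal(sum(ops@massVec), 1, tolerance = 1e-12)
    ## Dirichlet energy of u = x is |grad|^2 * volume = 1
    x <- meshVertices(mesh)[, 1]
    expect_equal(as.numeric(x %*% (ops@stiffI %*% x)), 1,
                 tolerance = 1e-12)
})

test_that("small Krylov solutions match dense direct solves", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 1, probes = FALSE)
    cond <- buildConductivityMap(mesh, wmSpec = anisotropySpec())
    ops <- assembleOperators(mesh, cond)
    sys <- bidomainSystem(ops, solverConfig(method = "direct"))
    set.seed(11)
    b <- rnorm(nrow(sys@A))
    xDense <- solve(as.matrix(sys@A), b)
    xLU <- solveLinearSystem(sys, b)
    xG <- solveLinearSystem(sys@A, b,
                            solverConfig(method = "gmres",
                                         krylovRtol = 1e-12))
    scale <- max(abs(xDense))
    expect_lt(max(abs(xLU - xDense)) / scale, 1e-8)
    expect_lt(max(abs(xG - xDense)) / scale, 1e-8)
})

test_that("extracellular potential keeps a zero weighted mean", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 2, probes = FALSE)
    cond <- buildConductivityMap(mesh, wmSpec = anisotropySpec())
    res <- runSimulation(mesh, cond, physicalParams(),
                         cellConfig = list(GM_STABLE = cressmanParams(4),
                                           GM_UNSTABLE = cressmanParams(8)),
                         cfg = solverConfig(), durationMs = 5,
                         probes = matrix(numeric(0), 0, 2),
                         snapshotTimes = c(2.5, 5))
    ops <- assembleOperators(mesh, cond)
    for (s in res@snapshots) {
        expect_lt(abs(sum(ops@massVec * s@ue)) / sum(ops@massVec), 1e-9)
        expect_true(all(is.finite(s@v)))
    }
})

test_that("zero-data runs stay identically zero", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 1, probes = FALSE)
    cond <- buildConductivityMap(mesh, wmSpec = anisotropySpec())
    init <- new("BidomainFields", v = rep(0, nVertices(mesh)),
                ue = rep(0, nVertices(mesh)), t = 0)
    res <- runSimulation(mesh, cond, physicalParams(),
                         cellConfig = list(), cfg = solverConfig(),
                         durationMs = 2,
                         probes = matrix(numeric(0), 0, 2),
                         initialFields = init, snapshotTimes = 2)
    s <- res@snapshots[[1]]
    expect_equal(max(abs(s@v)), 0, tolerance = 1e-12)
    expect_equal(max(abs(s@ue)), 0, tolerance = 1e-12)
    ## constant v is preserved in a purely passive run (null space of K)
    init2 <- new("BidomainFields", v = rep(-50, nVertices(mesh)),
                 ue = rep(0, nVertices(mesh)), t = 0)
    res2 <- runSimulation(mesh, cond, physicalParams(),
                          cellConfig = list(), cfg = solverConfig(),
                          durationMs = 2,
                          probes = matrix(numeric(0), 0, 2),
                          initialFields = init2, snapshotTimes = 2)
    expect_equal(res2@snapshots[[1]]@v, rep(-50, nVertices(mesh)),
                 tolerance = 1e-8)
})

test_that("splitting converges at second order on an exact solution", {
    ## v = cos(pi x) cos(pi y) T(t), ue = -v/2 on the unit square with
    ## identity tensors and linear reaction I_ion = c v: an exact solution
    ## of the coupled system with T(t) = exp(-(pi^2 + chi c)/(chi Cm) t).
    mesh <- unitSquareMesh(12)
    cond <- identityConductivity(mesh)
    phys <- physicalParams(chi = 1, Cm = 1)
    xy <- meshVertices(mesh)
    v0 <- cos(pi * xy[, 1]) * cos(pi * xy[, 2])
    init <- new("BidomainFields", v = v0, ue = -v0 / 2, t = 0)
    Tend <- 0.08
    runIt <- function(dt) {
        res <- runSimulation(mesh, cond, phys,
                             cellConfig = list(GM_STABLE =
                                 list(type = "linear", coef = 1)),
                             cfg = solverConfig(dt = dt, theta = 0.5),
                             durationMs = Tend,
                             probes = matrix(numeric(0), 0, 2),
                             initialFields = init, snapshotTimes = Tend)
        res@snapshots[[length(res@snapshots)]]
    }
    ref <- runIt(Tend / 128)
    errs <- sapply(c(Tend / 4, Tend / 8, Tend / 16),
                   function(dt) max(abs(runIt(dt)@v - ref@v)))
    orders <- log2(errs[-length(errs)] / errs[-1])
    expect_true(all(orders >= 1.9))
    ## and the fully discrete solution approximates the exact fields
    s <- runIt(Tend / 64)
    vex <- v0 * exp(-(pi^2 + 1) * Tend)
    expect_lt(max(abs(s@v - vex)) / max(abs(vex)), 0.05)
    expect_lt(max(abs(s@ue + s@v / 2)) / max(abs(s@v / 2)), 0.05)
})

test_that("gmres and direct time stepping agree", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 1, probes = FALSE)
    cond <- buildConductivityMap(mesh, wmSpec = anisotropySpec())
    pr <- rbind(GM = c(3.0, 2.6))
    run <- function(method, rtol = 1e-5) {
        runSimulation(mesh, cond, physicalParams(),
                      cellConfig = list(GM_STABLE = cressmanParams(4),
                                        GM_UNSTABLE = cressmanParams(8)),
                      cfg = solverConfig(method = method,
                                         krylovRtol = rtol),
                      durationMs = 2, probes = pr)
    }
    d <- run("direct")
    g <- run("gmres", rtol = 1e-9)
    vd <- traceValues(probeTraces(d)[["GM:v"]])
    vg <- traceValues(probeTraces(g)[["GM:v"]])
    expect_equal(vg, vd, tolerance = 1e-6)
})

test_that("active labels with conflicting parameters are rejected", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 1, probes = FALSE)
    cond <- buildConductivityMap(mesh, wmSpec = anisotropySpec())
    expect_error(
        runSimulation(mesh, cond, physicalParams(),
                      cellConfig = list(
                          GM_STABLE = cressmanParams(4, gNa = 90),
                          GM_UNSTABLE = cressmanParams(8)),
                      cfg = solverConfig(), durationMs = 1,
                      probes = matrix(numeric(0), 0, 2)),
        "kOInf")
})

test_that("unstable label wins on shared boundary nodes", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 2, probes = FALSE)
    layout <- neurofield:::.buildCellLayout(
        mesh, list(GM_STABLE = cressmanParams(4),
                   GM_UNSTABLE = cressmanParams(8)), physicalParams())
    cl <- meshCells(mesh); lab <- cellLabels(mesh)
    unstNodes <- unique(as.vector(cl[lab == "GM_UNSTABLE", ]))
    stNodes <- unique(as.vector(cl[lab == "GM_STABLE", ]))
    shared <- intersect(unstNodes, stNodes)
    expect_gt(length(shared), 0)
    k <- layout$cressman$kinf[match(shared, layout$cressman$nodes)]
    expect_true(all(k == 8))
})

test_that("a failing step aborts with partial results flagged incomplete", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 1, probes = FALSE)
    cond <- buildConductivityMap(mesh, wmSpec = anisotropySpec())
    expect_warning(
        res <- runSimulation(mesh, cond, physicalParams(),
                             cellConfig = list(
                                 GM_STABLE = cressmanParams(4),
                                 GM_UNSTABLE = cressmanParams(8)),
                             cfg = solverConfig(dt = 1.0),
                             durationMs = 50,
                             probes = rbind(GM = c(3.0, 2.6))),
        "aborted")
    expect_false(res@complete)
})
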