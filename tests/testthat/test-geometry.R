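test_that("idealized slice has the documented layer structure", {
    mesh <- buildIdealizedSlice()
    expect_s4_class(mesh, "LabeledMesh")
    expect_equal(meshDimension(mesh), 2L)
    v <- meshVertices(mesh)
    ## 60 x 40 mm rectangle, coordinates in cm
    expect_equal(range(v[, 1]), c(0, 6))
    expect_equal(range(v[, 2]), c(0, 4))
    cent <- cellCentroids(mesh)
    lab <- cellLabels(mesh)
    ## bottom-up: WM (24 mm), GM, CSF, SKULL, SCALP (4 mm each)
    bands <- list(WM_LEFT = c(0, 2.4), WM_RIGHT = c(0, 2.4),
                  GM_STABLE = c(2.4, 2.8), GM_UNSTABLE = c(2.4, 2.8),
                  CSF = c(2.8, 3.2), SKULL = c(3.2, 3.6),
                  SCALP = c(3.6, 4.0))
    for (lb in names(bands)) {
        y <- cent[lab == lb, 2]
        expect_true(all(y > bands[[lb]][1] - 1e-9 &
                        y < bands[[lb]][2] + 1e-9), info = lb)
    }
    ## unstable square: central 4 mm of the GM
    xu <- cent[lab == "GM_UNSTABLE", 1]
    expect_true(all(abs(xu - 3) <= 0.2 + 1e-9))
    ## WM split at the midline (a straddling cell with centroid exactly on
    ## the midline is assigned to the right half)
    expect_true(all(cent[lab == "WM_LEFT", 1] < 3))
    expect_true(all(cent[lab == "WM_RIGHT", 1] >= 3))
    ## cell measures tile the rectangle
    expect_equal(sum(cellMeasures(mesh)), 6 * 4, tolerance = 1e-12)
})

test_that("mesh is conforming and positively sized at all resolutions", {
    for (n in c(1, 2, 5)) {
        mesh <- buildIdealizedSlice(cellsAcrossGm = n, probes = FALSE)
        expect_true(all(cellMeasures(mesh) > 0))
        ## conformity: every interior edge shared by exactly 2 cells
        cl <- meshCells(mesh)
        edges <- rbind(cl[, c(1, 2)], cl[, c(2, 3)], cl[, c(1, 3)])
        key <- paste(pmin(edges[, 1], edges[, 2]),
                     pmax(edges[, 1], edges[, 2]))
        cnt <- table(key)
        expect_true(all(cnt <= 2))
        ## no orphan vertices
        expect_equal(sort(unique(as.vector(cl))),
                     seq_len(nVertices(mesh)))
    }
})

test_that("resolution presets land in the documented cell-count classes", {
    expect_gt(nCells(buildIdealizedSlice(probes = FALSE)), 1738 * 0.9)
    expect_lt(nCells(buildIdealizedSlice(probes = FALSE)), 1738 * 1.25)
    fine <- buildIdealizedSlice(wmFine = TRUE, probes = FALSE)
    expect_gt(nCells(fine), 6120 * 0.9)
    expect_lt(nCells(fine), 6120 * 1.1)
})

test_that("degenerate geometry requests are rejected", {
    expect_error(buildIdealizedSlice(widthMm = 0), "positive")
    expect_error(buildIdealizedSlice(layerMm = 11), "exceed")
    expect_error(buildIdealizedSlice(unstableWidthMm = 100), "unstableWidth")
})

test_that("anisotropy tensor has the right eigenstructure", {
    spec <- anisotropySpec(sigmaT = 0.1, sigmaL = 1.0,
                           orientation = "vertical")
    M <- wmAnisotropyTensor(spec)
    expect_equal(M, matrix(c(0.1, 0, 0, 1.0), 2), tolerance = 1e-14)
    spec2 <- anisotropySpec(orientation = "horizontal")
    expect_equal(wmAnisotropyTensor(spec2),
                 matrix(c(1.0, 0, 0, 0.1), 2), tolerance = 1e-14)
    ## oblique orientation: eigenvalues sigmaL along d, sigmaT across
    d <- c(1, 1) / sqrt(2)
    Mo <- wmAnisotropyTensor(anisotropySpec(orientation = d))
    expect_equal(as.numeric(Mo %*% d), 1.0 * d, tolerance = 1e-14)
    dp <- c(1, -1) / sqrt(2)
    expect_equal(as.numeric(Mo %*% dp), 0.1 * dp, tolerance = 1e-14)
    expect_error(anisotropySpec(orientation = c(0, 0)), "orientation")
})

test_that("conductivity map applies the table and WM anisotropy", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 2, probes = FALSE)
    cond <- buildConductivityMap(mesh, wmSpec = anisotropySpec())
    lab <- cellLabels(mesh)
    gm <- which(lab == "GM_STABLE")[1]
    expect_equal(cond@Mi[gm, ], c(1, 1, 0))
    expect_equal(cond@Me[gm, ], c(2.78, 2.78, 0))
    wl <- which(lab == "WM_LEFT")[1]
    wr <- which(lab == "WM_RIGHT")[1]
    ## vertical on the left: (xx, yy, xy) = (0.1, 1, 0); swapped on the right
    expect_equal(cond@Mi[wl, ], c(0.1, 1, 0))
    expect_equal(cond@Mi[wr, ], c(1, 0.1, 0))
    expect_equal(cond@Me[wl, ], c(0.1, 1, 0))
    ## isotropic fallback uses the WM table row
    iso <- buildConductivityMap(mesh)
    expect_equal(iso@Mi[wl, ], c(1, 1, 0))
    expect_equal(iso@Me[wl, ], c(1.26, 1.26, 0))
    ## anisotropy only on Mi when requested
    mi <- buildConductivityMap(mesh, wmSpec = anisotropySpec(),
                               applyTo = "mi")
    expect_equal(mi@Mi[wl, ], c(0.1, 1, 0))
    expect_equal(mi@Me[wl, ], c(1.26, 1.26, 0))
})

test_that("missing conductivity entry is a configuration error", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 1, probes = FALSE)
    tab <- defaultConductivityTable()
    tab$SKULL <- NULL
    expect_error(buildConductivityMap(mesh, tab), "SKULL")
})

test_that("interpolation matrix reproduces linear fields exactly", {
    mesh <- buildIdealizedSlice(cellsAcrossGm = 2, probes = FALSE)
    set.seed(3)
    pts <- cbind(runif(20, 0, 6), runif(20, 0, 4))
    P <- interpolationMatrix(mesh, pts)
    v <- meshVertices(mesh)
    f <- 2 * v[, 1] - 3 * v[, 2] + 1
    expect_equal(as.numeric(P %*% f), 2 * pts[, 1] - 3 * pts[, 2] + 1,
                 tolerance = 1e-10)
    ## rows are convex combinations
    expect_equal(as.numeric(P %*% rep(1, nVertices(mesh))), rep(1, 20),
                 tolerance = 1e-12)
    expect_error(interpolationMatrix(mesh, cbind(10, 10)), "outside")
})

test_that("default probes sit mid-layer on the focus line", {
    mesh <- buildIdealizedSlice()
    pr <- probePoints(mesh)
    expect_true(all(c("SCALP", "SKULL", "CSF", "GM", "WM",
                      "GM_UNSTABLE_CENTROID") %in% rownames(pr)))
    expect_equal(unname(pr["GM", ]), c(3.0, 2.6), tolerance = 1e-9)
    expect_equal(unname(pr["SCALP", 2]), 3.8, tolerance = 1e-9)
})

test_that("labeled mesh round-trips through the mesh file format", {
    for (n in c(1, 3)) {
        m1 <- buildIdealizedSlice(cellsAcrossGm = n)
        f <- tempfile(fileext = ".msh")
        writeLabeledMesh(m1, f)
        m2 <- readLabeledMesh(f)
        expect_identical(meshVertices(m1), meshVertices(m2))
        expect_identical(meshCells(m1), meshCells(m2))
        expect_identical(cellLabels(m1), cellLabels(m2))
        unlink(f)
    }
})

test_that("3D meshes round-trip and unknown labels error", {
    m1 <- unitCubeMesh()
    f <- tempfile(fileext = ".msh")
    writeLabeledMesh(m1, f)
    m2 <- readLabeledMesh(f)
    expect_identical(meshCells(m1), meshCells(m2))
    expect_identical(cellLabels(m1), cellLabels(m2))
    expect_equal(meshDimension(m2), 3L)
    ## a physical tag absent from the label map must error
    f2 <- tempfile(fileext = ".msh")
    lines <- readLines(f)
    i <- grep("^\\$Elements$", lines) + 2L
    parts <- strsplit(lines[i], " ")[[1]]
    parts[4] <- "99"
    lines[i] <- paste(parts, collapse = " ")
    writeLines(lines, f2)
    expect_error(readLabeledMesh(f2), "99")
    unlink(c(f, f2))
})
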