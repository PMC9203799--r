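## Geometry: idealized head-slice meshing, conductivity tensor fields,
## probe placement, and labeled-mesh I/O.
##
## All meshes are stored in cm; user-facing lengths are taken in mm and
## converted, which keeps the unit system (mS/cm, uF/cm2, mV, ms) consistent
## so both sides of the bidomain balance are in uA/cm3.

.MM_PER_CM <- 10

#' Construct an anisotropy specification
#'
#' @param sigmaT transverse conductivity, mS/cm.
#' @param sigmaL longitudinal conductivity, mS/cm.
#' @param orientation principal-axis direction; either a numeric vector or
#'   one of \code{"vertical"}, \code{"horizontal"}.  Normalized internally.
#' @return an \linkS4class{AnisotropySpec}.
#' @examples
#' anisotropySpec(0.1, 1.0, "vertical")
#' @export
anisotropySpec <- function(sigmaT = 0.1, sigmaL = 1.0,
                           orientation = "vertical") {
    if (is.character(orientation)) {
        orientation <- switch(match.arg(orientation,
                                        c("vertical", "horizontal")),
                              vertical = c(0, 1), horizontal = c(1, 0))
    }
    nrm <- sqrt(sum(orientation^2))
    if (nrm == 0) stop("orientation must be a nonzero vector")
    new("AnisotropySpec", sigmaL = as.numeric(sigmaL),
        sigmaT = as.numeric(sigmaT), orientation = orientation / nrm)
}

#' White-matter anisotropic conductivity tensor
#'
#' Returns the symmetric conductivity tensor with eigenvalue \code{sigmaL}
#' along the fibre orientation and \code{sigmaT} across it:
#' \code{sigmaT * I + (sigmaL - sigmaT) * d d'} for unit orientation d.
#' For a vertical orientation in 2D this is \code{diag(sigmaT, sigmaL)}.
#'
#' @param spec an \linkS4class{AnisotropySpec}.
#' @return a dense symmetric matrix (2x2 or 3x3), mS/cm.
#' @examples
#' wmAnisotropyTensor(anisotropySpec(0.1, 1.0, "vertical"))
#' @export
wmAnisotropyTensor <- function(spec) {
    stopifnot(is(spec, "AnisotropySpec"))
    validObject(spec)
    d <- spec@orientation
    spec@sigmaT * diag(length(d)) + (spec@sigmaL - spec@sigmaT) * tcrossprod(d)
}

## ---------------------------------------------------------------------------
## Idealized 2D slice
## ---------------------------------------------------------------------------

## A band is one horizontal strip of element rows.  Bands at different
## lateral resolution levels (columns = nx0 / 2^level) are joined by
## conforming 2:1 transition rows (3 triangles per coarse interval).
.bandRows <- function(label, height, levelBottom, levelTop, nrows) {
    list(label = label, height = height, levelBottom = levelBottom,
         levelTop = levelTop, nrows = nrows)
}

## Decompose a layer of given thickness into an optional transition band
## (from `fromLevel` at the GM side to `toLevel`) plus uniform coarse rows.
## `side` is "above" (fine bottom) or "below" (fine top).
.coarsenedLayer <- function(label, thickness, hx, fromLevel, toLevel, side) {
    if (toLevel == fromLevel) {
        h <- hx * 2^fromLevel
        return(list(.bandRows(label, thickness, fromLevel, fromLevel,
                              max(1L, round(thickness / h)))))
    }
    tH <- min(hx * 2^toLevel, thickness)
    rem <- thickness - tH
    hC <- hx * 2^toLevel
    trans <- if (side == "above")
        .bandRows(label, tH, fromLevel, toLevel, 1L)
    else
        .bandRows(label, tH, toLevel, fromLevel, 1L)
    if (rem < 0.5 * hC) {
        trans$height <- thickness
        return(list(trans))
    }
    unif <- .bandRows(label, rem, toLevel, toLevel, max(1L, round(rem / hC)))
    if (side == "above") list(trans, unif) else list(unif, trans)
}

#' Build the idealized two-dimensional head-slice mesh
#'
#' Generates a conforming triangulation of a rectangle with horizontal
#' tissue layers, from the top: scalp, skull, cerebrospinal fluid and grey
#' matter (each \code{layerMm} thick) above a white-matter block filling the
#' remainder.  A central segment of the grey matter of width
#' \code{unstableWidthMm} is labeled \code{GM_UNSTABLE} (seizure-like cell
#' model); the rest of the GM is \code{GM_STABLE}.  The white matter is
#' split at the vertical midline into \code{WM_LEFT} and \code{WM_RIGHT}
#' (vertical and horizontal fibre orientation respectively).
#'
#' The grey matter is resolved with \code{cellsAcrossGm} element rows; the
#' surrounding tissue is meshed coarser (2:1 graded, conforming) unless
#' \code{outerCoarsen = 1}.  When a white-matter cell model is used the WM
#' must be meshed at GM resolution: set \code{wmFine = TRUE}.  The defaults
#' yield roughly 1.9e3 cells at 5 cells across the GM; \code{wmFine} raises
#' this to roughly 6e3.
#'
#' @param widthMm,heightMm rectangle dimensions, mm.
#' @param layerMm thickness of scalp, skull, CSF and GM, mm.
#' @param cellsAcrossGm number of element rows across the GM layer.
#' @param unstableWidthMm width of the central seizure-prone GM segment, mm.
#' @param wmFine logical; mesh the white matter at GM resolution.
#' @param outerCoarsen 1 (uniform) or 2 (outer layers at twice the GM target
#'   edge length).
#' @param wmCoarsenLevels number of 2:1 coarsening levels in the white
#'   matter (ignored when \code{wmFine}), at most 2.
#' @param probes logical; attach \code{\link{defaultProbePoints}}.
#' @return a \linkS4class{LabeledMesh} (coordinates in cm).
#' @examples
#' mesh <- buildIdealizedSlice(cellsAcrossGm = 2)
#' mesh
#' @export
buildIdealizedSlice <- function(widthMm = 60, heightMm = 40, layerMm = 4,
                                cellsAcrossGm = 5, unstableWidthMm = 4,
                                wmFine = FALSE, outerCoarsen = 2,
                                wmCoarsenLevels = 2, probes = TRUE) {
    if (widthMm <= 0 || heightMm <= 0 || layerMm <= 0)
        stop("degenerate dimensions: width, height and layer must be positive")
    if (4 * layerMm > heightMm + 1e-12)
        stop("the four surface layers exceed the slice height")
    if (cellsAcrossGm < 1) stop("cellsAcrossGm must be at least 1")
    if (unstableWidthMm < 0 || unstableWidthMm > widthMm)
        stop("unstableWidthMm must lie in [0, widthMm]")
    if (!outerCoarsen %in% c(1, 2))
        stop("outerCoarsen must be 1 or 2")
    wmCoarsenLevels <- max(0L, min(2L, as.integer(wmCoarsenLevels)))

    W <- widthMm; H <- heightMm
    wmTh <- H - 4 * layerMm
    hGm <- layerMm / cellsAcrossGm
    outerLevel <- if (outerCoarsen == 2) 1L else 0L
    wmLevel <- if (wmFine || wmTh == 0) 0L else wmCoarsenLevels
    maxLevel <- max(outerLevel, wmLevel, 1L)
    div <- 2L^maxLevel
    nx0 <- div * max(1L, round(W / hGm / div))
    hx <- W / nx0

    bands <- list()
    if (wmTh > 0) {
        if (wmFine || wmLevel == 0L) {
            bands <- c(bands, list(.bandRows("WM", wmTh, 0L, 0L,
                                             max(1L, round(wmTh / hGm)))))
        } else {
            ## stacked transitions: deepest WM coarsest, finest next to GM
            need <- sum(hx * 2^seq_len(wmLevel))
            lvl <- wmLevel
            while (lvl > 1L && wmTh < need + hx * 2^lvl) {
                lvl <- lvl - 1L
                need <- sum(hx * 2^seq_len(lvl))
            }
            if (wmTh < need) {
                bands <- c(bands, list(.bandRows("WM", wmTh, 1L, 0L, 1L)))
            } else {
                deepH <- wmTh - need
                hDeep <- hx * 2^lvl
                if (deepH >= 0.5 * hDeep)
                    bands <- c(bands,
                               list(.bandRows("WM", deepH, lvl, lvl,
                                              max(1L, round(deepH / hDeep)))))
                else if (deepH > 0) {
                    ## fold the sliver into the deepest transition
                    extra <- deepH; deepH <- 0
                    bands <- c(bands, list(.bandRows("WM",
                                                     hx * 2^lvl + extra,
                                                     lvl, lvl - 1L, 1L)))
                    lvl <- lvl - 1L
                }
                for (l in seq(lvl, 1L))
                    bands <- c(bands, list(.bandRows("WM", hx * 2^l,
                                                     l, l - 1L, 1L)))
            }
        }
    }
    bands <- c(bands, list(.bandRows("GM", layerMm, 0L, 0L,
                                     as.integer(cellsAcrossGm))))
    bands <- c(bands, .coarsenedLayer("CSF", layerMm, hx, 0L, outerLevel,
                                      "above"))
    hOut <- hx * 2^outerLevel
    bands <- c(bands, list(.bandRows("SKULL", layerMm, outerLevel, outerLevel,
                                     max(1L, round(layerMm / hOut)))))
    bands <- c(bands, list(.bandRows("SCALP", layerMm, outerLevel, outerLevel,
                                     max(1L, round(layerMm / hOut)))))

    mesh <- .meshFromBands(W, bands, nx0)
    verts <- mesh$vertices
    cells <- matrix(as.integer(mesh$cells), ncol = 3L)
    labels <- mesh$labels

    cx <- (verts[cells[, 1], 1] + verts[cells[, 2], 1] +
               verts[cells[, 3], 1]) / 3
    gm <- labels == "GM"
    inUnstable <- gm & unstableWidthMm > 0 &
        abs(cx - W / 2) <= unstableWidthMm / 2 + 1e-9
    labels[gm] <- ifelse(inUnstable[gm], "GM_UNSTABLE", "GM_STABLE")
    wm <- labels == "WM"
    labels[wm] <- ifelse(cx[wm] < W / 2, "WM_LEFT", "WM_RIGHT")

    out <- new("LabeledMesh", vertices = verts / .MM_PER_CM,
               cells = cells, cellLabels = labels,
               probePoints = matrix(numeric(0), 0, 2), dimension = 2L)
    validObject(out)
    if (probes) out@probePoints <- defaultProbePoints(out)
    out
}

## Assemble vertices/cells from a bottom-to-top band profile.  Coordinates
## in mm; conversion to cm happens in the caller.
.meshFromBands <- function(W, bands, nx0) {
    rowLevels <- bands[[1]]$levelBottom
    rowYs <- 0
    elemRows <- list()  # (bottomRow, topRow, label)
    y <- 0
    for (b in bands) {
        if (b$levelBottom == b$levelTop) {
            dy <- b$height / b$nrows
            for (k in seq_len(b$nrows)) {
                y <- y + dy
                rowYs <- c(rowYs, y)
                rowLevels <- c(rowLevels, b$levelBottom)
                elemRows[[length(elemRows) + 1L]] <-
                    list(bottom = length(rowYs) - 1L, top = length(rowYs),
                         label = b$label)
            }
        } else {
            if (abs(b$levelBottom - b$levelTop) != 1L)
                stop("internal: transition bands must differ by one level")
            y <- y + b$height
            rowYs <- c(rowYs, y)
            rowLevels <- c(rowLevels, b$levelTop)
            elemRows[[length(elemRows) + 1L]] <-
                list(bottom = length(rowYs) - 1L, top = length(rowYs),
                     label = b$label)
        }
    }
    ## snap the final row to the exact top
    nRows <- length(rowYs)
    nodeStart <- integer(nRows)
    nNodesRow <- nx0 / 2L^rowLevels + 1L
    nodeStart <- cumsum(c(0L, nNodesRow[-nRows]))
    verts <- matrix(0, sum(nNodesRow), 2)
    for (r in seq_len(nRows)) {
        idx <- nodeStart[r] + seq_len(nNodesRow[r])
        verts[idx, 1] <- seq(0, W, length.out = nNodesRow[r])
        verts[idx, 2] <- rowYs[r]
    }
    tri <- vector("list", length(elemRows))
    labs <- vector("list", length(elemRows))
    for (e in seq_along(elemRows)) {
        er <- elemRows[[e]]
        lb <- rowLevels[er$bottom]; lt <- rowLevels[er$top]
        b0 <- nodeStart[er$bottom]; t0 <- nodeStart[er$top]
        if (lb == lt) {
            nc <- nx0 / 2L^lb
            i <- seq_len(nc)
            t1 <- cbind(b0 + i, b0 + i + 1L, t0 + i + 1L)
            t2 <- cbind(b0 + i, t0 + i + 1L, t0 + i)
            tri[[e]] <- rbind(t1, t2)
        } else if (lb > lt) {
            ## coarse bottom, fine top
            nc <- nx0 / 2L^lb
            i <- seq_len(nc)
            f <- t0 + 2L * (i - 1L) + 1L  # f, f+1, f+2
            t1 <- cbind(b0 + i, f + 1L, f)
            t2 <- cbind(b0 + i, b0 + i + 1L, f + 1L)
            t3 <- cbind(b0 + i + 1L, f + 2L, f + 1L)
            tri[[e]] <- rbind(t1, t2, t3)
        } else {
            ## fine bottom, coarse top
            nc <- nx0 / 2L^lt
            i <- seq_len(nc)
            f <- b0 + 2L * (i - 1L) + 1L
            t1 <- cbind(f, f + 1L, t0 + i)
            t2 <- cbind(f + 1L, t0 + i + 1L, t0 + i)
            t3 <- cbind(f + 1L, f + 2L, t0 + i + 1L)
            tri[[e]] <- rbind(t1, t2, t3)
        }
        labs[[e]] <- rep(er$label, nrow(tri[[e]]))
    }
    list(vertices = verts, cells = do.call(rbind, tri),
         labels = unlist(labs))
}

## ---------------------------------------------------------------------------
## Mesh measures and point location
## ---------------------------------------------------------------------------

#' Cell areas (2D) or volumes (3D)
#'
#' @param mesh a \linkS4class{LabeledMesh}.
#' @return numeric vector, cm^2 or cm^3.
#' @export
cellMeasures <- function(mesh) {
    v <- mesh@vertices; c1 <- mesh@cells
    if (mesh@dimension == 2L) {
        a <- v[c1[, 2], ] - v[c1[, 1], ]
        b <- v[c1[, 3], ] - v[c1[, 1], ]
        abs(a[, 1] * b[, 2] - a[, 2] * b[, 1]) / 2
    } else {
        a <- v[c1[, 2], ] - v[c1[, 1], ]
        b <- v[c1[, 3], ] - v[c1[, 1], ]
        d <- v[c1[, 4], ] - v[c1[, 1], ]
        abs(a[, 1] * (b[, 2] * d[, 3] - b[, 3] * d[, 2]) -
            a[, 2] * (b[, 1] * d[, 3] - b[, 3] * d[, 1]) +
            a[, 3] * (b[, 1] * d[, 2] - b[, 2] * d[, 1])) / 6
    }
}

#' Cell centroids
#'
#' @param mesh a \linkS4class{LabeledMesh}.
#' @return numeric matrix of centroid coordinates, cm.
#' @export
cellCentroids <- function(mesh) {
    v <- mesh@vertices; cl <- mesh@cells
    out <- 0
    for (k in seq_len(ncol(cl))) out <- out + v[cl[, k], , drop = FALSE]
    out / ncol(cl)
}

## Locate points in the mesh: returns cell index and barycentric weights.
.locatePoints <- function(mesh, points, tol = 1e-10) {
    v <- mesh@vertices; cl <- mesh@cells
    d <- mesh@dimension
    n <- nrow(points)
    cellIdx <- integer(n)
    weights <- matrix(0, n, d + 1L)
    for (i in seq_len(n)) {
        p <- points[i, ]
        found <- 0L
        for (e in seq_len(nrow(cl))) {
            a <- v[cl[e, 1], ]
            Tm <- t(v[cl[e, -1], , drop = FALSE]) - a
            lam <- tryCatch(solve(Tm, p - a), error = function(err) NULL)
            if (is.null(lam)) next
            l0 <- 1 - sum(lam)
            if (l0 >= -tol && all(lam >= -tol)) { found <- e
                weights[i, ] <- c(l0, lam); break }
        }
        if (found == 0L)
            stop(sprintf("point (%s) lies outside the mesh",
                         paste(signif(p, 6), collapse = ", ")))
        cellIdx[i] <- found
    }
    list(cell = cellIdx, weights = weights)
}

#' P1 interpolation matrix for a set of points
#'
#' Sparse matrix P with P %*% nodalValues giving linear interpolation of a
#' nodal field at the points.
#'
#' @param mesh a \linkS4class{LabeledMesh}.
#' @param points coordinate matrix, cm.
#' @return a sparse p x nVertices matrix.
#' @export
interpolationMatrix <- function(mesh, points) {
    loc <- .locatePoints(mesh, points)
    p <- nrow(points)
    nv <- nrow(mesh@vertices)
    i <- rep(seq_len(p), each = ncol(loc$weights))
    j <- as.vector(t(mesh@cells[loc$cell, , drop = FALSE]))
    Matrix::sparseMatrix(i = i, j = j, x = as.vector(t(loc$weights)),
                         dims = c(p, nv))
}

## ---------------------------------------------------------------------------
## Conductivity
## ---------------------------------------------------------------------------

#' Reference conductivity table
#'
#' Isotropic intracellular/extracellular conductivities per tissue, mS/cm:
#' grey matter 1 / 2.78, white matter 1 / 1.26, CSF 1e-4 / 17, skull
#' 1e-4 / 0.1, scalp 1e-4 / 4.3.  In passive tissue the intracellular
#' conductivity is four orders of magnitude below the active extracellular
#' values.
#'
#' @return named list label -> c(mi, me).
#' @export
defaultConductivityTable <- function() {
    list(GM_STABLE = c(1, 2.78), GM_UNSTABLE = c(1, 2.78),
         WM = c(1, 1.26), WM_LEFT = c(1, 1.26), WM_RIGHT = c(1, 1.26),
         CSF = c(1e-4, 17), SKULL = c(1e-4, 0.1), SCALP = c(1e-4, 4.3))
}

.packTensor2 <- function(m) c(m[1, 1], m[2, 2], m[1, 2])
.packTensor3 <- function(m) c(m[1, 1], m[2, 2], m[3, 3],
                              m[1, 2], m[1, 3], m[2, 3])

#' Build per-cell conductivity tensors
#'
#' Isotropic tensors \code{value * I} per tissue from \code{table}; when
#' \code{wmSpec} is supplied, white-matter cells instead receive the
#' anisotropic tensor of \code{\link{wmAnisotropyTensor}} -- oriented
#' vertically in \code{WM_LEFT} and horizontally in \code{WM_RIGHT} -- for
#' both the intracellular and extracellular field (configurable via
#' \code{applyTo}).
#'
#' @param mesh a \linkS4class{LabeledMesh}.
#' @param table named list label -> c(mi, me), mS/cm.
#' @param wmSpec an \linkS4class{AnisotropySpec}, or NULL for isotropic WM.
#' @param applyTo which fields receive the WM anisotropy tensor.
#' @return a \linkS4class{ConductivityMap}.
#' @export
buildConductivityMap <- function(mesh, table = defaultConductivityTable(),
                                 wmSpec = NULL,
                                 applyTo = c("both", "mi", "me")) {
    applyTo <- match.arg(applyTo)
    labs <- unique(mesh@cellLabels)
    missing <- setdiff(labs, names(table))
    if (length(missing))
        stop("no conductivity entry for label(s): ",
             paste(missing, collapse = ", "))
    d <- mesh@dimension
    nc <- if (d == 2L) 3L else 6L
    m <- nrow(mesh@cells)
    Mi <- matrix(0, m, nc)
    Me <- matrix(0, m, nc)
    isoCols <- seq_len(d)  # diagonal entries of the packed tensor
    for (lb in labs) {
        sel <- mesh@cellLabels == lb
        Mi[sel, isoCols] <- table[[lb]][1]
        Me[sel, isoCols] <- table[[lb]][2]
    }
    if (!is.null(wmSpec)) {
        stopifnot(is(wmSpec, "AnisotropySpec"))
        pack <- if (d == 2L) .packTensor2 else .packTensor3
        vert <- wmSpec
        horiz <- anisotropySpec(wmSpec@sigmaT, wmSpec@sigmaL,
                                orientation = c(1, rep(0, d - 1L)))
        tensors <- list(WM_LEFT = pack(wmAnisotropyTensor(vert)),
                        WM_RIGHT = pack(wmAnisotropyTensor(horiz)),
                        WM = pack(wmAnisotropyTensor(vert)))
        for (lb in intersect(names(tensors), labs)) {
            sel <- mesh@cellLabels == lb
            tt <- matrix(tensors[[lb]], sum(sel), nc, byrow = TRUE)
            if (applyTo %in% c("both", "mi")) Mi[sel, ] <- tt
            if (applyTo %in% c("both", "me")) Me[sel, ] <- tt
        }
    }
    out <- new("ConductivityMap", Mi = Mi, Me = Me, dimension = d)
    validObject(out)
    out
}

## ---------------------------------------------------------------------------
## Probes
## ---------------------------------------------------------------------------

#' Default probe points
#'
#' For the idealized slice: one probe at mid-thickness of each tissue layer
#' on the vertical line through the centre of the unstable region, plus the
#' centroid of the unstable region itself.  For other (e.g. 3D) meshes:
#' measure-weighted centroids of each labeled region.
#'
#' @param mesh a \linkS4class{LabeledMesh}.
#' @return numeric matrix of probe coordinates (cm) with informative
#'   row names.
#' @export
defaultProbePoints <- function(mesh) {
    cent <- cellCentroids(mesh)
    meas <- cellMeasures(mesh)
    labs <- mesh@cellLabels
    groups <- list(SCALP = "SCALP", SKULL = "SKULL", CSF = "CSF",
                   GM = c("GM_STABLE", "GM_UNSTABLE"),
                   WM = c("WM", "WM_LEFT", "WM_RIGHT"))
    isSlice <- mesh@dimension == 2L &&
        all(c("SCALP", "SKULL", "CSF") %in% labs)
    if (!isSlice) {
        present <- names(groups)[vapply(groups, function(g)
            any(labs %in% g), TRUE)]
        pts <- t(vapply(present, function(nm) {
            sel <- labs %in% groups[[nm]]
            colSums(cent[sel, , drop = FALSE] * meas[sel]) / sum(meas[sel])
        }, numeric(mesh@dimension)))
        rownames(pts) <- present
        return(pts)
    }
    ## slice: midline through the unstable region (domain midline fallback)
    xs <- range(mesh@vertices[, 1])
    if (any(labs == "GM_UNSTABLE")) {
        sel <- labs == "GM_UNSTABLE"
        xc <- sum(cent[sel, 1] * meas[sel]) / sum(meas[sel])
    } else xc <- mean(xs)
    pts <- NULL; nms <- character()
    for (nm in names(groups)) {
        sel <- labs %in% groups[[nm]]
        if (!any(sel)) next
        yr <- range(mesh@vertices[unique(as.vector(
            mesh@cells[sel, , drop = FALSE])), 2])
        pts <- rbind(pts, c(xc, mean(yr)))
        nms <- c(nms, nm)
    }
    if (any(labs == "GM_UNSTABLE")) {
        sel <- labs == "GM_UNSTABLE"
        pts <- rbind(pts, colSums(cent[sel, , drop = FALSE] * meas[sel]) /
                              sum(meas[sel]))
        nms <- c(nms, "GM_UNSTABLE_CENTROID")
    }
    rownames(pts) <- nms
    pts
}

## ---------------------------------------------------------------------------
## Gmsh MSH 2.2 ASCII I/O
## ---------------------------------------------------------------------------

.defaultLabelMap <- function() {
    m <- seq_along(.tissueLabels)
    names(m) <- .tissueLabels
    m
}

#' Write a labeled mesh as Gmsh MSH 2.2 ASCII
#'
#' The tissue label is stored as the physical tag of each element
#' (triangles in 2D, tetrahedra in 3D).
#'
#' @param mesh a \linkS4class{LabeledMesh}.
#' @param path output file path.
#' @param labelMap named integer vector mapping tissue label -> tag.
#' @return \code{path}, invisibly.
#' @export
writeLabeledMesh <- function(mesh, path, labelMap = .defaultLabelMap()) {
    missing <- setdiff(unique(mesh@cellLabels), names(labelMap))
    if (length(missing))
        stop("labelMap lacks entries for: ", paste(missing, collapse = ", "))
    v <- mesh@vertices
    if (ncol(v) == 2) v <- cbind(v, 0)
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("$MeshFormat", "2.2 0 8", "$EndMeshFormat", "$Nodes",
                 as.character(nrow(v))), con)
    writeLines(sprintf("%d %.17g %.17g %.17g", seq_len(nrow(v)),
                       v[, 1], v[, 2], v[, 3]), con)
    writeLines(c("$EndNodes", "$Elements", as.character(nrow(mesh@cells))),
               con)
    type <- if (mesh@dimension == 2L) 2L else 4L
    tags <- labelMap[mesh@cellLabels]
    nodeCols <- apply(mesh@cells, 1, paste, collapse = " ")
    writeLines(sprintf("%d %d 2 %d %d %s", seq_len(nrow(mesh@cells)),
                       type, tags, tags, nodeCols), con)
    writeLines("$EndElements", con)
    invisible(path)
}

#' Read a labeled mesh from Gmsh MSH 2.2 ASCII
#'
#' Triangles (element type 2) or tetrahedra (type 4) are read together with
#' their physical tag, which is mapped to a tissue label through
#' \code{labelMap}; lower-dimensional elements are ignored.
#'
#' @param path input file path.
#' @param labelMap named integer vector mapping tissue label -> tag.
#' @param probePoints optional probe coordinate matrix (cm).
#' @return a \linkS4class{LabeledMesh}.
#' @export
readLabeledMesh <- function(path, labelMap = .defaultLabelMap(),
                            probePoints = NULL) {
    if (!file.exists(path)) stop("file not found: ", path)
    lines <- readLines(path)
    sec <- function(name) {
        a <- match(paste0("$", name), lines)
        b <- match(paste0("$End", name), lines)
        if (is.na(a) || is.na(b)) stop("malformed MSH file: missing ", name)
        lines[(a + 2):(b - 1)]
    }
    nodeLines <- sec("Nodes")
    nm <- do.call(rbind, lapply(strsplit(trimws(nodeLines), "\\s+"),
                                as.numeric))
    nodes <- nm[order(nm[, 1]), 2:4, drop = FALSE]
    elemLines <- sec("Elements")
    parts <- strsplit(trimws(elemLines), "\\s+")
    types <- vapply(parts, function(p) as.integer(p[2]), 1L)
    keepTri <- types == 2L; keepTet <- types == 4L
    if (any(keepTet)) { keep <- keepTet; nv <- 4L; d <- 3L }
    else if (any(keepTri)) { keep <- keepTri; nv <- 3L; d <- 2L }
    else stop("no triangle or tetrahedron elements with labels in file")
    rows <- parts[keep]
    getRow <- function(p) {
        ntags <- as.integer(p[3])
        if (ntags < 1L) stop("element without a label tag")
        tag <- as.integer(p[4])
        c(tag, as.integer(p[(4 + ntags):(3 + ntags + nv)]))
    }
    em <- do.call(rbind, lapply(rows, getRow))
    tags <- em[, 1]
    cells <- em[, -1, drop = FALSE]
    rev <- names(labelMap)[match(tags, labelMap)]
    if (anyNA(rev))
        stop("label tag(s) absent from labelMap: ",
             paste(sort(unique(tags[is.na(rev)])), collapse = ", "))
    verts <- nodes[, seq_len(d), drop = FALSE]
    if (d == 2L && any(abs(nodes[, 3]) > 1e-12))
        stop("triangle mesh with nonplanar z-coordinates")
    mesh <- new("LabeledMesh", vertices = verts, cells = cells,
                cellLabels = rev,
                probePoints = if (is.null(probePoints))
                    matrix(numeric(0), 0, d) else probePoints,
                dimension = d)
    validObject(mesh)
    .checkConforming(mesh)
    mesh
}

## Each facet (edge in 2D, triangle face in 3D) may be shared by at most two
## cells; more indicates a non-conforming mesh.
.checkConforming <- function(mesh) {
    cl <- mesh@cells
    d <- mesh@dimension
    combs <- utils::combn(d + 1L, d)
    facets <- do.call(rbind, lapply(seq_len(ncol(combs)), function(k)
        t(apply(cl[, combs[, k], drop = FALSE], 1, sort))))
    key <- apply(facets, 1, paste, collapse = "-")
    if (any(table(key) > 2))
        stop("non-conforming mesh: a facet is shared by more than two cells")
    invisible(TRUE)
}
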