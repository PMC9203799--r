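## Bidomain tissue model: P1 finite-element assembly, theta-scheme linear
## system with zero-mean gauge fixing of the extracellular potential,
## second-order operator splitting against the cell model, and the
## simulation driver.
##
## Weak form (v transmembrane, u_e extracellular, K_i / K_ie stiffness with
## M_i and M_i + M_e, M mass, a = chi*Cm/dt, theta-weighted):
##   [ a M + theta K_i   K_i  ] [v]   [ a M v0 - (1-theta) K_i v0 ]
##   [ theta K_i         K_ie ] [u] = [       - (1-theta) K_i v0  ]
## under pure Neumann conditions, giving the one-dimensional null space
## (v, u) = (0, const), removed by a Lagrange-multiplier row that enforces
## a zero mass-weighted mean of u_e.

#' Discrete bidomain operators
#'
#' @slot mass consistent (or lumped) P1 mass matrix.
#' @slot stiffI stiffness matrix for the intracellular tensor M_i.
#' @slot stiffIE stiffness matrix for M_i + M_e.
#' @slot massVec lumped mass vector (row sums of \code{mass}).
#' @slot chiCm product chi * Cm, uF/cm3.
#' @slot nVertices number of mesh vertices.
#' @exportClass BidomainOperators
setClass("BidomainOperators",
         representation(mass = "ANY", stiffI = "ANY", stiffIE = "ANY",
                        massVec = "numeric", chiCm = "numeric",
                        nVertices = "integer"))

#' Factorized theta-scheme system
#'
#' @slot ops the \linkS4class{BidomainOperators}.
#' @slot cfg the \linkS4class{SolverConfig} used to build the system.
#' @slot A bordered (2n+1) sparse system matrix.
#' @slot fact cached sparse LU factorization (direct method) or NULL.
#' @exportClass BidomainSystem
setClass("BidomainSystem",
         representation(ops = "BidomainOperators", cfg = "SolverConfig",
                        A = "ANY", fact = "ANY"))

#' Construct tissue-level physical parameters
#'
#' Defaults: membrane capacitance 1 uF/cm2 and membrane surface per unit
#' volume 1.26e3 1/cm.
#'
#' @param chi membrane surface area per unit volume, 1/cm.
#' @param Cm membrane capacitance, uF/cm2.
#' @return a \linkS4class{PhysicalParams}.
#' @export
physicalParams <- function(chi = 1.26e3, Cm = 1) {
    obj <- new("PhysicalParams", chi = as.numeric(chi), Cm = as.numeric(Cm))
    validObject(obj)
    obj
}

#' Construct a solver configuration
#'
#' @param dt time step, ms.
#' @param theta PDE time weight (0.5 = Crank-Nicolson, preserving the
#'   second-order splitting; 1 = implicit Euler).
#' @param krylovRtol,krylovAtol iterative-solver tolerances.
#' @param maxIterations iterative-solver iteration cap.
#' @param activeLabels labels in which cell ODEs are solved.
#' @param method "direct" (cached sparse LU) or "gmres".
#' @param odeSubsteps forward-Euler substeps per splitting half-step.
#' @param massLumping use a lumped mass matrix.
#' @return a \linkS4class{SolverConfig}.
#' @export
solverConfig <- function(dt = 0.025, theta = 0.5, krylovRtol = 1e-5,
                         krylovAtol = 1e-50, maxIterations = 10000L,
                         activeLabels = c("GM_STABLE", "GM_UNSTABLE"),
                         method = c("direct", "gmres"), odeSubsteps = 1L,
                         massLumping = FALSE) {
    method <- match.arg(method)
    obj <- new("SolverConfig", dt = dt, theta = theta,
               krylovRtol = krylovRtol, krylovAtol = krylovAtol,
               maxIterations = as.integer(maxIterations),
               activeLabels = activeLabels, method = method,
               odeSubsteps = as.integer(odeSubsteps),
               massLumping = massLumping)
    validObject(obj)
    obj
}

## ---------------------------------------------------------------------------
## P1 assembly
## ---------------------------------------------------------------------------

.assembleStiffness <- function(mesh, tensors) {
    v <- mesh@vertices; cl <- mesh@cells
    m <- nrow(cl); d <- mesh@dimension
    if (m > 0 && !all(is.finite(tensors))) stop("non-finite tensor entries")
    if (d == 2L) {
        x <- matrix(v[cl, 1], m, 3); y <- matrix(v[cl, 2], m, 3)
        detJ <- (x[, 2] - x[, 1]) * (y[, 3] - y[, 1]) -
            (x[, 3] - x[, 1]) * (y[, 2] - y[, 1])
        if (any(abs(detJ) < 1e-300)) {
            bad <- which(abs(detJ) < 1e-300)[1]
            stop("degenerate cell ", bad)
        }
        area <- abs(detJ) / 2
        gx <- cbind(y[, 2] - y[, 3], y[, 3] - y[, 1], y[, 1] - y[, 2]) / detJ
        gy <- cbind(x[, 3] - x[, 2], x[, 1] - x[, 3], x[, 2] - x[, 1]) / detJ
        Mxx <- tensors[, 1]; Myy <- tensors[, 2]; Mxy <- tensors[, 3]
        ii <- jj <- xx <- vector("list", 9L)
        k <- 0L
        for (a in 1:3) {
            mgx <- Mxx * gx[, a] + Mxy * gy[, a]
            mgy <- Mxy * gx[, a] + Myy * gy[, a]
            for (b in 1:3) {
                k <- k + 1L
                ii[[k]] <- cl[, b]; jj[[k]] <- cl[, a]
                xx[[k]] <- area * (gx[, b] * mgx + gy[, b] * mgy)
            }
        }
    } else {
        x <- matrix(v[cl, 1], m, 4); y <- matrix(v[cl, 2], m, 4)
        z <- matrix(v[cl, 3], m, 4)
        e1 <- cbind(x[, 2] - x[, 1], y[, 2] - y[, 1], z[, 2] - z[, 1])
        e2 <- cbind(x[, 3] - x[, 1], y[, 3] - y[, 1], z[, 3] - z[, 1])
        e3 <- cbind(x[, 4] - x[, 1], y[, 4] - y[, 1], z[, 4] - z[, 1])
        detJ <- e1[, 1] * (e2[, 2] * e3[, 3] - e2[, 3] * e3[, 2]) -
            e1[, 2] * (e2[, 1] * e3[, 3] - e2[, 3] * e3[, 1]) +
            e1[, 3] * (e2[, 1] * e3[, 2] - e2[, 2] * e3[, 1])
        if (any(abs(detJ) < 1e-300)) stop("degenerate cell")
        vol <- abs(detJ) / 6
        ## rows of inv(J)^T via cross products: grad lambda_{k+1}
        cr <- function(u, w) cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
                                   u[, 3] * w[, 1] - u[, 1] * w[, 3],
                                   u[, 1] * w[, 2] - u[, 2] * w[, 1])
        g2 <- cr(e2, e3) / detJ
        g3 <- cr(e3, e1) / detJ
        g4 <- cr(e1, e2) / detJ
        g1 <- -(g2 + g3 + g4)
        G <- list(g1, g2, g3, g4)
        Mxx <- tensors[, 1]; Myy <- tensors[, 2]; Mzz <- tensors[, 3]
        Mxy <- tensors[, 4]; Mxz <- tensors[, 5]; Myz <- tensors[, 6]
        ii <- jj <- xx <- vector("list", 16L)
        k <- 0L
        for (a in 1:4) {
            ga <- G[[a]]
            mg <- cbind(Mxx * ga[, 1] + Mxy * ga[, 2] + Mxz * ga[, 3],
                        Mxy * ga[, 1] + Myy * ga[, 2] + Myz * ga[, 3],
                        Mxz * ga[, 1] + Myz * ga[, 2] + Mzz * ga[, 3])
            for (b in 1:4) {
                k <- k + 1L
                gb <- G[[b]]
                ii[[k]] <- cl[, b]; jj[[k]] <- cl[, a]
                xx[[k]] <- vol * rowSums(gb * mg)
            }
        }
    }
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = rep(nrow(v), 2))
}

.assembleMass <- function(mesh, lumped = FALSE) {
    v <- mesh@vertices; cl <- mesh@cells
    meas <- cellMeasures(mesh)
    nvert <- ncol(cl)
    if (lumped) {
        diagv <- numeric(nrow(v))
        for (a in seq_len(nvert)) {
            add <- tapply(meas / nvert, cl[, a], sum)
            diagv[as.integer(names(add))] <- diagv[as.integer(names(add))] +
                add
        }
        return(Matrix::Diagonal(x = diagv))
    }
    denom <- if (nvert == 3L) 12 else 20
    ii <- jj <- xx <- vector("list", nvert * nvert)
    k <- 0L
    for (a in seq_len(nvert)) for (b in seq_len(nvert)) {
        k <- k + 1L
        ii[[k]] <- cl[, b]; jj[[k]] <- cl[, a]
        xx[[k]] <- meas * (1 + (a == b)) / denom
    }
    Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                         dims = rep(nrow(v), 2))
}

#' Assemble the discrete bidomain operators
#'
#' Builds the P1 stiffness matrices for M_i and M_i + M_e and the mass
#' matrix on a labeled mesh.  All operators are symmetric; under the pure
#' Neumann boundary conditions the coupled two-field system has the
#' one-dimensional null space spanned by (v, u_e) = (0, constant).
#'
#' @param mesh a \linkS4class{LabeledMesh}.
#' @param cond a \linkS4class{ConductivityMap}.
#' @param phys a \linkS4class{PhysicalParams}.
#' @param massLumping logical; lump the mass matrix.
#' @return a \linkS4class{BidomainOperators}.
#' @export
assembleOperators <- function(mesh, cond, phys = physicalParams(),
                              massLumping = FALSE) {
    stopifnot(is(mesh, "LabeledMesh"), is(cond, "ConductivityMap"))
    if (nrow(cond@Mi) != nrow(mesh@cells))
        stop("conductivity map does not match the mesh")
    Ki <- .assembleStiffness(mesh, cond@Mi)
    Kie <- .assembleStiffness(mesh, cond@Mi + cond@Me)
    M <- .assembleMass(mesh, lumped = massLumping)
    new("BidomainOperators", mass = M, stiffI = Ki, stiffIE = Kie,
        massVec = as.numeric(M %*% rep(1, nrow(mesh@vertices))),
        chiCm = phys@chi * phys@Cm, nVertices = nrow(mesh@vertices))
}

#' Build (and factorize) the theta-scheme linear system
#'
#' @param ops a \linkS4class{BidomainOperators}.
#' @param cfg a \linkS4class{SolverConfig}.
#' @return a \linkS4class{BidomainSystem} with a cached sparse LU
#'   factorization when \code{cfg@method == "direct"}.
#' @export
bidomainSystem <- function(ops, cfg = solverConfig()) {
    n <- ops@nVertices
    a <- ops@chiCm / cfg@dt
    th <- cfg@theta
    Z <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(n, 1))
    mvec <- Matrix::Matrix(ops@massVec, n, 1, sparse = TRUE)
    A <- rbind(
        cbind(a * ops@mass + th * ops@stiffI, ops@stiffI, Z),
        cbind(th * ops@stiffI, ops@stiffIE, mvec),
        cbind(Matrix::t(Z), Matrix::t(mvec),
              Matrix::sparseMatrix(i = integer(0), j = integer(0),
                                   x = numeric(0), dims = c(1, 1))))
    A <- methods::as(A, "CsparseMatrix")
    fact <- if (cfg@method == "direct") Matrix::lu(A) else NULL
    new("BidomainSystem", ops = ops, cfg = cfg, A = A, fact = fact)
}

## ---------------------------------------------------------------------------
## Linear solves
## ---------------------------------------------------------------------------

#' Solve a sparse linear system under the configured solver contract
#'
#' Direct method: sparse LU.  Iterative method: restarted GMRES with Jacobi
#' preconditioning, stopping when the residual norm falls below
#' \code{max(krylovRtol * ||r0||, krylovAtol)}.
#'
#' @param A sparse (or dense) square matrix, or a
#'   \linkS4class{BidomainSystem} whose bordered matrix is solved with its
#'   cached factorization.
#' @param b right-hand side.
#' @param cfg a \linkS4class{SolverConfig}.
#' @return the solution vector.
#' @export
solveLinearSystem <- function(A, b, cfg = solverConfig()) {
    if (is(A, "BidomainSystem")) {
        if (A@cfg@method == "direct" && !is.null(A@fact))
            return(as.numeric(Matrix::solve(A@fact, b)))
        return(.gmres(A@A, b, rtol = A@cfg@krylovRtol,
                      atol = A@cfg@krylovAtol, maxit = A@cfg@maxIterations))
    }
    if (cfg@method == "direct")
        return(as.numeric(Matrix::solve(A, b)))
    .gmres(A, b, rtol = cfg@krylovRtol, atol = cfg@krylovAtol,
           maxit = cfg@maxIterations)
}

## Restarted GMRES with Jacobi (diagonal) preconditioning.
.gmres <- function(A, b, rtol = 1e-5, atol = 1e-50, maxit = 10000L,
                   restart = 200L) {
    n <- length(b)
    dg <- Matrix::diag(A)
    dg[dg == 0] <- 1
    Pinv <- 1 / dg
    x <- numeric(n)
    r <- b - as.numeric(A %*% x)
    target <- max(rtol * sqrt(sum((Pinv * r)^2)), atol)
    total <- 0L
    repeat {
        z <- Pinv * r
        beta <- sqrt(sum(z^2))
        if (beta <= target || total >= maxit) break
        mdim <- min(restart, maxit - total)
        V <- matrix(0, n, mdim + 1L)
        H <- matrix(0, mdim + 1L, mdim)
        cs <- sn <- numeric(mdim)
        g <- numeric(mdim + 1L); g[1] <- beta
        V[, 1] <- z / beta
        k <- 0L
        for (j in seq_len(mdim)) {
            w <- Pinv * as.numeric(A %*% V[, j])
            for (i in seq_len(j)) {
                H[i, j] <- sum(w * V[, i])
                w <- w - H[i, j] * V[, i]
            }
            H[j + 1L, j] <- sqrt(sum(w^2))
            if (H[j + 1L, j] > 0) V[, j + 1L] <- w / H[j + 1L, j]
            ## apply accumulated Givens rotations
            for (i in seq_len(j - 1L)) {
                t1 <- cs[i] * H[i, j] + sn[i] * H[i + 1L, j]
                H[i + 1L, j] <- -sn[i] * H[i, j] + cs[i] * H[i + 1L, j]
                H[i, j] <- t1
            }
            dn <- sqrt(H[j, j]^2 + H[j + 1L, j]^2)
            if (dn == 0) { k <- j; break }
            cs[j] <- H[j, j] / dn; sn[j] <- H[j + 1L, j] / dn
            H[j, j] <- dn; H[j + 1L, j] <- 0
            g[j + 1L] <- -sn[j] * g[j]
            g[j] <- cs[j] * g[j]
            k <- j
            if (abs(g[j + 1L]) <= target) break
        }
        y <- backsolve(H[seq_len(k), seq_len(k), drop = FALSE],
                       g[seq_len(k)])
        x <- x + V[, seq_len(k), drop = FALSE] %*% y
        x <- as.numeric(x)
        total <- total + k
        r <- b - as.numeric(A %*% x)
        if (sqrt(sum((Pinv * r)^2)) <= target) break
        if (total >= maxit)
            stop(sprintf(
                "GMRES did not converge in %d iterations (residual %.3e)",
                total, sqrt(sum(r^2))))
    }
    attr(x, "iterations") <- total
    x
}

## ---------------------------------------------------------------------------
## Cell-state bookkeeping for tissue runs
## ---------------------------------------------------------------------------

## cellConfig: named list tissue label -> one of
##   * a CressmanParams (active Cressman membrane at those nodes)
##   * list(type = "linear", coef = c) for I_ion = c * v (verification model)
##   * "none" / NULL (passive)
## Nodes incident to several active labels take the label with the larger
## bath potassium (the seizure focus wins on its boundary).
.buildCellLayout <- function(mesh, cellConfig, phys) {
    labs <- names(cellConfig)
    active <- labs[vapply(labs, function(lb) {
        x <- cellConfig[[lb]]
        !is.null(x) && !identical(x, "none")
    }, TRUE)]
    cress <- active[vapply(active, function(lb)
        is(cellConfig[[lb]], "CressmanParams"), TRUE)]
    linear <- setdiff(active, cress)
    nodeOf <- function(lb) sort(unique(as.vector(
        mesh@cells[mesh@cellLabels == lb, , drop = FALSE])))
    layout <- list(linear = NULL, cressman = NULL)
    if (length(linear)) {
        if (!all(vapply(linear, function(lb)
            identical(cellConfig[[lb]]$type, "linear"), TRUE)))
            stop("unsupported cell model entry; use CressmanParams, ",
                 "list(type='linear', coef=...), or 'none'")
        nodes <- integer(0); coef <- numeric(0)
        for (lb in linear) {
            nd <- nodeOf(lb)
            nodes <- c(nodes, nd)
            coef <- c(coef, rep(cellConfig[[lb]]$coef, length(nd)))
        }
        keep <- !duplicated(nodes)
        layout$linear <- list(nodes = nodes[keep], coef = coef[keep],
                              Cm = phys@Cm)
    }
    if (length(cress)) {
        base <- cellConfig[[cress[1]]]
        baseVec <- .parsVector(base); baseVec[1] <- NA
        for (lb in cress) {
            pv <- .parsVector(cellConfig[[lb]]); pv[1] <- NA
            if (!isTRUE(all.equal(pv, baseVec)))
                stop("active Cressman labels may differ only in kOInf")
        }
        ## order by increasing kOInf so higher-k labels override shared nodes
        ord <- cress[order(vapply(cress, function(lb)
            cellConfig[[lb]]@kOInf, 1))]
        nodeK <- new.env()
        for (lb in ord)
            for (nd in nodeOf(lb))
                assign(as.character(nd), cellConfig[[lb]]@kOInf,
                       envir = nodeK)
        nodes <- sort(as.integer(ls(nodeK)))
        kinf <- vapply(as.character(nodes), function(k)
            get(k, envir = nodeK), 1)
        layout$cressman <- list(nodes = nodes, kinf = unname(kinf),
                                pars = .parsVector(base))
    }
    layout
}

## ---------------------------------------------------------------------------
## Time stepping
## ---------------------------------------------------------------------------

## One theta-scheme PDE step; returns list(v, ue).
.pdeStep <- function(system, v, ue, forcing = NULL, t = 0) {
    ops <- system@ops; cfg <- system@cfg
    n <- ops@nVertices
    a <- ops@chiCm / cfg@dt
    Kv <- as.numeric(ops@stiffI %*% v)
    rhs1 <- a * as.numeric(ops@mass %*% v) - (1 - cfg@theta) * Kv
    rhs2 <- -(1 - cfg@theta) * Kv
    if (!is.null(forcing)) {
        f <- forcing(t + cfg@theta * cfg@dt)
        if (!is.null(f$fv))
            rhs1 <- rhs1 + as.numeric(ops@mass %*% f$fv)
        if (!is.null(f$fu))
            rhs2 <- rhs2 + as.numeric(ops@mass %*% f$fu)
    }
    sol <- solveLinearSystem(system, c(rhs1, rhs2, 0))
    vNew <- sol[seq_len(n)]
    ueNew <- sol[n + seq_len(n)]
    ## re-gauge: exact for the direct path, cheap insurance for gmres
    ueNew <- ueNew - sum(ops@massVec * ueNew) / sum(ops@massVec)
    if (!all(is.finite(vNew)) || !all(is.finite(ueNew)))
        stop("non-finite fields after PDE solve")
    list(v = vNew, ue = ueNew)
}

## Reaction half-step of length hdt, mutating cellStates$cressman$state
## (matrix, columns v,n,h,ko,nai) in place and returning the updated nodal v.
.odeHalfStep <- function(v, layout, states, hdt, nsub, clampEps) {
    if (!is.null(layout$linear)) {
        nd <- layout$linear$nodes
        v[nd] <- v[nd] * exp(-layout$linear$coef * hdt / layout$linear$Cm)
    }
    if (!is.null(layout$cressman)) {
        nd <- layout$cressman$nodes
        ## assign through the environment binding so the in-place kernel
        ## advances the persistent state (a local copy would be discarded)
        states$cressman[, 1] <- v[nd]
        .cressmanEulerCpp(states$cressman, layout$cressman$pars,
                          layout$cressman$kinf, hdt / nsub,
                          as.integer(nsub), numeric(0), 0L, -1L, clampEps)
        v[nd] <- states$cressman[, 1]
    }
    v
}

#' One second-order splitting step
#'
#' Strang step: advance the cell ODEs for dt/2 in active tissue, solve the
#' coupled PDE system for one dt with the theta scheme, advance the cell
#' ODEs for the remaining dt/2.  Passive tissue has no membrane dynamics
#' (I_ion = 0, no cell state).  The extracellular potential is re-gauged to
#' zero weighted mean after the PDE solve.
#'
#' @param fields a \linkS4class{BidomainFields}.
#' @param system a \linkS4class{BidomainSystem}.
#' @param layout internal cell layout from a tissue run (see
#'   \code{\link{runSimulation}}); may be NULL for a purely passive step.
#' @param states environment holding the Cressman state matrix (mutated).
#' @param forcing optional function(t) -> list(fv, fu) of nodal source
#'   terms (verification use).
#' @param clampEps gating clamp tolerance.
#' @return the updated \linkS4class{BidomainFields}.
#' @export
splittingStep <- function(fields, system, layout = NULL, states = NULL,
                          forcing = NULL, clampEps = 1e-3) {
    cfg <- system@cfg
    hdt <- cfg@dt / 2
    v <- fields@v; ue <- fields@ue
    if (!is.null(layout))
        v <- .odeHalfStep(v, layout, states, hdt, cfg@odeSubsteps, clampEps)
    sol <- .pdeStep(system, v, ue, forcing, fields@t)
    v <- sol$v; ue <- sol$ue
    if (!is.null(layout)) {
        if (!is.null(layout$cressman))
            states$cressman[, 1] <- v[layout$cressman$nodes]
        v <- .odeHalfStep(v, layout, states, hdt, cfg@odeSubsteps, clampEps)
    }
    new("BidomainFields", v = v, ue = ue, t = fields@t + cfg@dt)
}

#' Run a coupled bidomain-cell simulation
#'
#' Initializes the transmembrane potential to the cell model's starting
#' potential in active tissue (and the same constant in passive tissue),
#' the extracellular potential to zero, and advances the splitting scheme
#' until \code{durationMs}, sampling u_e and v at the probe points by P1
#' interpolation every \code{probeStride} steps.  The run is deterministic
#' given its configuration.
#'
#' @param mesh a \linkS4class{LabeledMesh}.
#' @param cond a \linkS4class{ConductivityMap}.
#' @param phys a \linkS4class{PhysicalParams}.
#' @param cellConfig named list: tissue label -> \linkS4class{CressmanParams}
#'   (active), \code{list(type = "linear", coef = c)} (verification model)
#'   or \code{"none"}.
#' @param cfg a \linkS4class{SolverConfig}.
#' @param durationMs simulated duration, ms.
#' @param probes probe coordinate matrix (cm); defaults to the mesh's
#'   probe points.
#' @param probeStride sample every this many steps.
#' @param initMode "seed" starts active nodes from the documented seed
#'   state; "rest" relaxes stable parameterizations first.
#' @param snapshotTimes times (ms) at which full fields are kept.
#' @param forcing optional manufactured source terms, function(t) ->
#'   list(fv, fu).
#' @param initialFields optional \linkS4class{BidomainFields} overriding
#'   the default initialization.
#' @param clampEps gating clamp tolerance for the reaction steps.
#' @param verbose print progress.
#' @return a \linkS4class{SimulationResult}; traces are labeled
#'   "<probe>:ue" and "<probe>:v".
#' @export
runSimulation <- function(mesh, cond, phys = physicalParams(),
                          cellConfig = list(), cfg = solverConfig(),
                          durationMs = 1000, probes = NULL,
                          probeStride = 1L, initMode = c("seed", "rest"),
                          snapshotTimes = numeric(0), forcing = NULL,
                          initialFields = NULL, clampEps = 1e-3,
                          verbose = FALSE) {
    stopifnot(durationMs > 0)
    initMode <- match.arg(initMode)
    t0 <- proc.time()[["elapsed"]]
    ops <- assembleOperators(mesh, cond, phys,
                             massLumping = cfg@massLumping)
    system <- bidomainSystem(ops, cfg)
    layout <- .buildCellLayout(mesh, cellConfig, phys)
    if (is.null(layout$linear) && is.null(layout$cressman)) layout <- NULL

    n <- ops@nVertices
    states <- new.env()
    v0const <- 0
    if (!is.null(layout) && !is.null(layout$cressman)) {
        m <- length(layout$cressman$nodes)
        if (initMode == "seed") {
            init <- cressmanSeedState(m)
        } else {
            stable <- cressmanRestState(cressmanParams(
                kOInf = min(layout$cressman$kinf)))
            init <- cressmanState(rep(stable@v, m), rep(stable@gateN, m),
                                  rep(stable@gateH, m), rep(stable@kOut, m),
                                  rep(stable@naIn, m))
            unst <- layout$cressman$kinf > min(layout$cressman$kinf) + 1e-9
            if (any(unst)) {
                sd0 <- cressmanSeedState()
                init@v[unst] <- sd0@v; init@gateN[unst] <- sd0@gateN
                init@gateH[unst] <- sd0@gateH; init@kOut[unst] <- sd0@kOut
                init@naIn[unst] <- sd0@naIn
            }
        }
        states$cressman <- .stateMatrix(init) + 0
        v0const <- init@v[1]
    }
    if (is.null(initialFields)) {
        v <- rep(v0const, n)
        if (!is.null(layout) && !is.null(layout$cressman))
            v[layout$cressman$nodes] <- states$cressman[, 1]
        fields <- new("BidomainFields", v = v, ue = rep(0, n), t = 0)
    } else fields <- initialFields

    if (is.null(probes)) probes <- mesh@probePoints
    P <- if (nrow(probes) > 0) interpolationMatrix(mesh, probes) else NULL
    probeNames <- rownames(probes)
    if (is.null(probeNames) && nrow(probes) > 0)
        probeNames <- paste0("probe", seq_len(nrow(probes)))

    nsteps <- as.integer(round(durationMs / cfg@dt))
    nrec <- nsteps %/% probeStride
    recUe <- if (!is.null(P)) matrix(NA_real_, nrec, nrow(probes)) else NULL
    recV <- recUe
    recT <- numeric(nrec)
    snapshots <- list()
    complete <- TRUE
    ir <- 0L
    err <- tryCatch({
        for (s in seq_len(nsteps)) {
            fields <- splittingStep(fields, system, layout, states, forcing,
                                    clampEps)
            if (s %% probeStride == 0L) {
                ir <- ir + 1L
                recT[ir] <- fields@t
                if (!is.null(P)) {
                    recUe[ir, ] <- as.numeric(P %*% fields@ue)
                    recV[ir, ] <- as.numeric(P %*% fields@v)
                }
            }
            if (length(snapshotTimes) &&
                any(abs(snapshotTimes - fields@t) < cfg@dt / 2))
                snapshots[[length(snapshots) + 1L]] <- fields
            if (verbose && s %% max(1L, nsteps %/% 10L) == 0L)
                message(sprintf("  t = %.1f / %.1f ms", fields@t,
                                durationMs))
        }
        NULL
    }, error = function(e) e)
    if (!is.null(err)) {
        warning("simulation aborted: ", conditionMessage(err))
        complete <- FALSE
        keep <- seq_len(ir)
        recT <- recT[keep]
        if (!is.null(recUe)) { recUe <- recUe[keep, , drop = FALSE]
            recV <- recV[keep, , drop = FALSE] }
    }
    traces <- list()
    if (!is.null(P) && length(recT)) {
        for (j in seq_len(nrow(probes))) {
            traces[[paste0(probeNames[j], ":ue")]] <-
                probeTrace(recT, recUe[, j],
                           label = paste0(probeNames[j], ":ue"))
            traces[[paste0(probeNames[j], ":v")]] <-
                probeTrace(recT, recV[, j],
                           label = paste0(probeNames[j], ":v"))
        }
    }
    new("SimulationResult", probeTraces = traces, snapshots = snapshots,
        eventLog = list(steps = nsteps, dt = cfg@dt, method = cfg@method,
                        wallTimeSec = proc.time()[["elapsed"]] - t0),
        complete = complete)
}
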