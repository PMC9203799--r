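## Independent reference implementations and tiny fixture builders used by
## the unit and acceptance tests.  These are written directly from the model
## equations / textbook formulas and deliberately do not call package code.

## Cressman right-hand side, independent R transcription.
oracleCressmanRHS <- function(v, n, h, ko, nai, kinf = 4, iext = 0) {
    nao <- 144 - 7 * (nai - 18)
    ki <- 140 + (18 - nai)
    eNa <- 26.64 * log(nao / nai)
    eK <- 26.64 * log(ko / ki)
    eCl <- 26.64 * log(6 / 130)
    am <- 0.1 * (v + 30) / (1 - exp(-0.1 * (v + 30)))
    bm <- 4 * exp(-(v + 55) / 18)
    minf <- am / (am + bm)
    an <- 0.01 * (v + 34) / (1 - exp(-0.1 * (v + 34)))
    bn <- 0.125 * exp(-(v + 44) / 80)
    ah <- 0.07 * exp(-(v + 44) / 20)
    bh <- 1 / (1 + exp(-0.1 * (v + 14)))
    iNa <- 100 * minf^3 * h * (v - eNa) + 0.0175 * (v - eNa)
    iK <- (40 * n^4 + 0.05) * (v - eK)
    iCl <- 0.05 * (v - eCl)
    ipump <- (1.25 / (1 + exp((25 - nai) / 3))) / (1 + exp(5.5 - ko))
    iglia <- 66 / (1 + exp((18 - ko) / 2.5))
    idiff <- 1.2 * (ko - kinf)
    c(dv = -(iNa + iK + iCl) + iext,
      dn = 3 * (an * (1 - n) - bn * n),
      dh = 3 * (ah * (1 - h) - bh * h),
      dko = (0.044695 * 7 * iK - 2 * 7 * ipump - iglia - idiff) / 1000,
      dnai = (-0.044695 * iNa - 3 * ipump) / 1000,
      iion = iNa + iK + iCl)
}

## Direct segment-loop Welch estimator (periodic Hann, 50% overlap,
## per-segment mean removal, one-sided density scaling).
oracleWelch <- function(x, fs, L, overlap = 0.5) {
    step <- round(L * (1 - overlap))
    starts <- seq(1, length(x) - L + 1, by = step)
    w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / L)
    nf <- L %/% 2 + 1
    acc <- numeric(nf)
    for (s in starts) {
        seg <- x[s:(s + L - 1)]
        seg <- seg - mean(seg)
        X <- stats::fft(seg * w)[1:nf]
        P <- (Mod(X)^2) * 2 / (fs * sum(w^2))
        P[1] <- P[1] / 2
        if (L %% 2 == 0) P[nf] <- P[nf] / 2
        acc <- acc + P
    }
    list(frequency = fs * (0:(nf - 1)) / L, power = acc / length(starts))
}

## Structured unit-square triangulation, all cells carrying one label.
unitSquareMesh <- function(n, label = "GM_STABLE") {
    g <- seq(0, 1, length.out = n + 1)
    vv <- unname(as.matrix(expand.grid(g, g)))
    idx <- function(i, j) (j - 1L) * (n + 1L) + i
    cells <- matrix(0L, 2L * n * n, 3L)
    k <- 0L
    for (j in 1:n) for (i in 1:n) {
        a <- idx(i, j); b <- idx(i + 1L, j)
        cc <- idx(i + 1L, j + 1L); d <- idx(i, j + 1L)
        cells[k + 1L, ] <- c(a, b, cc)
        cells[k + 2L, ] <- c(a, cc, d)
        k <- k + 2L
    }
    new("LabeledMesh", vertices = vv, cells = cells,
        cellLabels = rep(label, nrow(cells)),
        probePoints = matrix(numeric(0), 0, 2), dimension = 2L)
}

## Unit cube split into six conforming tetrahedra (Kuhn triangulation),
## optionally split into two labels (three tets each).
unitCubeMesh <- function(labels = c("GM_STABLE", "CSF")) {
    vv <- as.matrix(expand.grid(x = 0:1, y = 0:1, z = 0:1))
    ## corner ids: 1=(0,0,0) 2=(1,0,0) 3=(0,1,0) 4=(1,1,0)
    ##             5=(0,0,1) 6=(1,0,1) 7=(0,1,1) 8=(1,1,1)
    cells <- rbind(c(1, 2, 4, 8), c(1, 2, 6, 8), c(1, 3, 4, 8),
                   c(1, 3, 7, 8), c(1, 5, 6, 8), c(1, 5, 7, 8))
    storage.mode(cells) <- "integer"
    lab <- rep(labels, length.out = 2)
    new("LabeledMesh", vertices = unname(vv) + 0.0, cells = cells,
        cellLabels = rep(lab, each = 3L),
        probePoints = matrix(numeric(0), 0, 3), dimension = 3L)
}

## Identity-tensor conductivity map for an arbitrary mesh.
identityConductivity <- function(mesh, mi = 1, me = 1) {
    m <- nCells(mesh)
    if (meshDimension(mesh) == 2L) {
        Mi <- cbind(rep(mi, m), mi, 0)
        Me <- cbind(rep(me, m), me, 0)
    } else {
        Mi <- cbind(rep(mi, m), mi, mi, 0, 0, 0)
        Me <- cbind(rep(me, m), me, me, 0, 0, 0)
    }
    new("ConductivityMap", Mi = Mi, Me = Me,
        dimension = meshDimension(mesh))
}

## Dense P1 stiffness by per-element quadrature-free formula, written
## independently (gradient of barycentric coordinates via matrix inverse).
oracleStiffness <- function(mesh, tensorList) {
    v <- meshVertices(mesh); cl <- meshCells(mesh)
    d <- meshDimension(mesh)
    K <- matrix(0, nrow(v), nrow(v))
    for (e in seq_len(nrow(cl))) {
        ids <- cl[e, ]
        X <- v[ids, , drop = FALSE]
        ## rows of G are gradients of the d+1 barycentric functions
        A <- cbind(1, X)
        Ginv <- solve(A)            # (d+1) x (d+1)
        G <- t(Ginv[-1, , drop = FALSE])   # (d+1) x d, row i = grad lambda_i
        vol <- abs(det(A)) / factorial(d)
        M <- tensorList[[e]]
        K[ids, ids] <- K[ids, ids] + vol * G %*% M %*% t(G)
    }
    K
}
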