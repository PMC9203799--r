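test_that("constructors validate and default correctly", {
    p <- cressmanParams(4)
    expect_s4_class(p, "CressmanParams")
    expect_equal(p@kOInf, 4)
    expect_equal(p@gNa, 100)
    expect_error(cressmanParams(4, bogus = 1), "unknown parameter")
    expect_error(cressmanParams(-1), "kOInf")
    s <- cressmanSeedState()
    expect_equal(s@v, -50)
    expect_equal(s@naIn, 15.5)
    expect_error(cressmanState(0, 2, 0.5, 4, 10), "gateN")
    expect_error(cressmanState(0, 0.5, 0.5, -1, 10), "kOut")
})

test_that("right-hand side matches an independent transcription on random states", {
    set.seed(42)
    p4 <- cressmanParams(4)
    for (i in 1:100) {
        v <- runif(1, -90, 50)
        n <- runif(1, 0.01, 0.99)
        h <- runif(1, 0.01, 0.99)
        ko <- runif(1, 3, 12)
        nai <- runif(1, 10, 24)
        kinf <- sample(c(4, 8), 1)
        iext <- runif(1, -2, 2)
        st <- cressmanState(v, n, h, ko, nai)
        got <- cressmanRHS(st, p4, couplingCurrent = iext, kOInf = kinf)
        ref <- oracleCressmanRHS(v, n, h, ko, nai, kinf, iext)
        expect_equal(as.numeric(got$derivatives),
                     unname(ref[c("dv", "dn", "dh", "dko", "dnai")]),
                     tolerance = 1e-12)
        expect_equal(as.numeric(got$iIon), unname(ref["iion"]),
                     tolerance = 1e-12)
    }
})

test_that("vectorized RHS equals per-neuron evaluation", {
    set.seed(7)
    m <- 20
    st <- cressmanState(runif(m, -80, 40), runif(m, 0.05, 0.95),
                        runif(m, 0.05, 0.95), runif(m, 3, 11),
                        runif(m, 11, 22))
    p <- cressmanParams(4)
    kinf <- sample(c(4, 8), m, replace = TRUE)
    all <- cressmanRHS(st, p, kOInf = kinf)
    for (i in seq_len(m)) {
        one <- cressmanRHS(cressmanState(st@v[i], st@gateN[i], st@gateH[i],
                                         st@kOut[i], st@naIn[i]),
                           p, kOInf = kinf[i])
        expect_equal(all$derivatives[i, ], one$derivatives[1, ])
    }
})

test_that("stable parameterization relaxes to a stationary rest state", {
    rs <- cressmanRestState(cressmanParams(4), settleTimeMs = 10000)
    expect_true(attr(rs, "stationary"))
    d <- cressmanRHS(rs, cressmanParams(4))$derivatives
    ## the slow concentrations relax on a minutes timescale: after 10 s the
    ## residual drift is small but not machine-zero
    expect_lt(max(abs(d)), 1e-3)
    expect_lt(rs@v, -60)   # hyperpolarized rest
})

test_that("unstable parameterization has no rest state", {
    rs <- cressmanRestState(cressmanParams(8), settleTimeMs = 2000)
    expect_false(attr(rs, "stationary"))
})

test_that("forward Euler converges at first order to the adaptive reference", {
    p <- cressmanParams(8)
    y0 <- cressmanSeedState()
    Tend <- 5  # ms, within the first upstroke
    ref <- deSolve::lsoda(c(y0@v, y0@gateN, y0@gateH, y0@kOut, y0@naIn),
                          c(0, Tend), function(t, y, parms) {
                              list(unname(oracleCressmanRHS(
                                  y[1], y[2], y[3], y[4], y[5],
                                  kinf = 8)[1:5]))
                          }, parms = NULL, rtol = 1e-11, atol = 1e-11)
    vref <- ref[2, 2]
    errs <- sapply(c(0.01, 0.005, 0.0025), function(dt) {
        r <- simulateCressman(p, Tend, dt = dt)
        abs(r$finalState@v - vref)
    })
    orders <- log2(errs[-length(errs)] / errs[-1])
    expect_true(all(orders > 0.8))
    expect_true(all(orders < 1.4))
})

test_that("a too-large step raises a gating error naming dt", {
    expect_error(simulateCressman(cressmanParams(8), 50, dt = 1),
                 "dt")
})

test_that("non-finite states are rejected with the field named", {
    p <- cressmanParams(4)
    st <- cressmanState(0, 0.5, 0.5, 4, 15)
    st@v <- NaN
    expect_error(cressmanRHS(st, p), "'v'")
})

test_that("forwardEulerStep does not mutate its input", {
    st <- cressmanSeedState()
    v0 <- st@v
    out <- forwardEulerStep(st, cressmanParams(8), dt = 0.025)
    expect_equal(st@v, v0)
    expect_false(out@v == v0)
})

test_that("coupling current shifts the membrane derivative linearly", {
    st <- cressmanSeedState()
    p <- cressmanParams(4)
    d0 <- cressmanRHS(st, p, couplingCurrent = 0)$derivatives[1, 1]
    d5 <- cressmanRHS(st, p, couplingCurrent = 5)$derivatives[1, 1]
    expect_equal(d5 - d0, 5, tolerance = 1e-12)  # Cm = 1
})
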