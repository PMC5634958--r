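zeroGate <- function(D, C) {
    g <- list()
    for (nm in c("i", "f", "o", "g")) {
        g[[paste0("W", nm)]] <- matrix(0, D, C)
        g[[paste0("U", nm)]] <- matrix(0, C, C)
        g[[paste0("b", nm)]] <- numeric(C)
    }
    g
}

test_that("lstmCellStep matches the zero-parameter closed form", {
    D <- 4L; C <- 3L
    p <- zeroGate(D, C)
    cPrev <- c(0.4, -1.2, 2)
    st <- lstmCellStep(rnorm(D), numeric(C), cPrev, p)
    expect_equal(st$i, rep(0.5, C))
    expect_equal(st$f, rep(0.5, C))
    expect_equal(st$o, rep(0.5, C))
    expect_equal(st$g, rep(0, C))
    expect_equal(st$c, 0.5 * cPrev)
    expect_equal(st$h, 0.5 * tanh(0.5 * cPrev))
})

test_that("lstmCellStep reproduces a hand-evaluated two-step recurrence", {
    ## one cell, open gates (large biases), candidate reads x[1] directly
    p <- zeroGate(2L, 1L)
    p$bi <- p$bf <- p$bo <- 10
    p$Wg <- matrix(c(1, 0), 2L, 1L)
    x1 <- c(0.7, 0); x2 <- c(-0.3, 0)
    s1 <- lstmCellStep(x1, 0, 0, p)
    s2 <- lstmCellStep(x2, s1$h, s1$c, p)
    ## hand recurrence with the same scalar formulas
    sg <- 1 / (1 + exp(-10))
    c1 <- sg * tanh(0.7)
    h1 <- sg * tanh(c1)
    c2 <- sg * c1 + sg * tanh(-0.3)
    h2 <- sg * tanh(c2)
    expect_equal(s1$h, h1, tolerance = 1e-6)
    expect_equal(s2$c, c2, tolerance = 1e-6)
    expect_equal(s2$h, h2, tolerance = 1e-6)
})

test_that("hidden state length equals the configured cell count", {
    m <- initBLSTMModel(encoderConfig(window = 3, fixedLength = 10),
                        modelConfig(cells = 50, seed = 1))
    st <- lstmCellStep(rnorm(60), numeric(50), numeric(50), m@forward)
    expect_length(st$h, 50L)
    expect_error(lstmCellStep(rnorm(61), numeric(50), numeric(50),
                              m@forward), "length")
})

test_that("runBLSTM aligns forward and backward streams per position", {
    set.seed(21)
    Tn <- 6L; D <- 20L; C <- 4L
    mp <- randomParams(D, C, Tn)
    s <- randomSample(Tn, D)

    ## zero parameters: every h_t identical, halves equal
    z <- list(forward = zeroGate(D, C), backward = zeroGate(D, C))
    hz <- runBLSTM(s, z)
    expect_true(all(hz$H == 0))

    ## symmetric parameters + reversed input: halves swap and reverse
    sym <- list(forward = mp$forward, backward = mp$forward)
    h1 <- runBLSTM(s, sym)
    rev_s <- new("EncodedSample", id = "r",
                 mat = s@mat[Tn:1, , drop = FALSE], mask = s@mask[Tn:1])
    h2 <- runBLSTM(rev_s, sym)
    expect_equal(h2$forward, h1$backward[Tn:1, , drop = FALSE],
                 tolerance = 1e-12)
    expect_equal(h2$backward, h1$forward[Tn:1, , drop = FALSE],
                 tolerance = 1e-12)

    ## single time step with symmetric parameters: the two halves agree
    s1 <- randomSample(1L, D)
    hs <- runBLSTM(s1, sym)
    expect_equal(hs$forward, hs$backward, tolerance = 1e-12)
})

test_that("forward half depends only on the prefix, backward only on the suffix", {
    set.seed(4)
    Tn <- 8L; D <- 20L; C <- 3L
    mp <- randomParams(D, C, Tn)
    s <- randomSample(Tn, D)
    base <- runBLSTM(s, mp)
    t0 <- 4L
    pert <- s@mat
    pert[t0, ] <- 0
    pert[t0, sample.int(D, 1L)] <- 1
    after <- runBLSTM(new("EncodedSample", id = "p", mat = pert,
                          mask = s@mask), mp)
    ## rows before t0 of the forward half and after t0 of the backward half
    ## are bit-identical; the perturbed position itself changes
    expect_identical(after$forward[seq_len(t0 - 1L), , drop = FALSE],
                     base$forward[seq_len(t0 - 1L), , drop = FALSE])
    expect_identical(after$backward[(t0 + 1L):Tn, , drop = FALSE],
                     base$backward[(t0 + 1L):Tn, , drop = FALSE])
    expect_false(isTRUE(all.equal(after$forward[t0, ], base$forward[t0, ])))
    expect_false(isTRUE(all.equal(after$backward[t0, ], base$backward[t0, ])))
})

test_that("time-distributed dense applies shared weights with ReLU", {
    set.seed(8)
    Tn <- 5L; C <- 3L
    H <- matrix(rnorm(Tn * 2 * C), Tn, 2 * C)
    expect_equal(timeDistributedDense(H, list(tdd = list(w = numeric(2 * C),
                                                         b = -1))),
                 rep(0, Tn))
    expect_equal(timeDistributedDense(H, list(tdd = list(w = numeric(2 * C),
                                                         b = 2))),
                 rep(2, Tn))
    w <- rnorm(2 * C); b <- rnorm(1)
    byHand <- vapply(seq_len(Tn), function(t) max(0, sum(w * H[t, ]) + b),
                     numeric(1L))
    expect_equal(timeDistributedDense(H, list(tdd = list(w = w, b = b))),
                 byHand, tolerance = 1e-6)
})

test_that("predictScore is the logistic of the output-layer projection", {
    v <- c(0.3, 0, 1.2, 0.7)
    expect_equal(predictScore(v, list(output = list(w = numeric(4), b = 0))),
                 0.5)
    expect_gt(predictScore(v, list(output = list(w = numeric(4), b = 30))),
              1 - 1e-12)
    w <- c(0.11, -0.45, 0.9, 0.02); b <- -0.3
    expect_equal(predictScore(v, list(output = list(w = w, b = b))),
                 1 / (1 + exp(-(sum(w * v) + b))), tolerance = 1e-9)
    expect_error(predictScore(c(v, 1), list(output = list(w = w, b = b))),
                 "length")
})

test_that("analytic gradients match finite differences", {
    set.seed(12)
    Tn <- 3L; D <- 20L; C <- 2L
    mp <- randomParams(D, C, Tn)
    samples <- lapply(1:4, function(i) randomSample(Tn, D, paste0("s", i)))
    X <- profileBLSTM:::.stackSamples(samples)
    y <- c(1, 0, 0, 1)
    lg <- profileBLSTM:::.lossGrad(mp, X, y)
    v <- profileBLSTM:::.flattenParams(mp)
    gv <- profileBLSTM:::.flattenParams(lg$grads)
    h <- 1e-5
    fd <- vapply(seq_along(v), function(k) {
        vp <- v; vp[k] <- vp[k] + h
        vm <- v; vm[k] <- vm[k] - h
        (profileBLSTM:::.lossGrad(
             profileBLSTM:::.unflattenParams(vp, mp), X, y)$loss -
         profileBLSTM:::.lossGrad(
             profileBLSTM:::.unflattenParams(vm, mp), X, y)$loss) / (2 * h)
    }, numeric(1L))
    relErr <- max(abs(fd - gv)) / max(abs(gv))
    expect_lt(relErr, 1e-4)
})

test_that("batched inference equals the per-sample reference path", {
    set.seed(30)
    enc <- encoderConfig(window = 2, fixedLength = 12)
    cfg <- modelConfig(cells = 7, seed = 99)
    m <- initBLSTMModel(enc, cfg)
    samples <- lapply(1:5, function(i)
        encodeProtein(paste(sample(profileBLSTM:::.AA20, sample(5:12, 1L),
                                   TRUE), collapse = ""),
                      cfg = enc, id = paste0("s", i)))
    batched <- scoreSamples(m, samples)
    single <- vapply(samples, function(s)
        predictScore(timeDistributedDense(runBLSTM(s, m), m), m), numeric(1L))
    expect_equal(unname(batched), single, tolerance = 1e-12)
    ## purity: scoring alone equals scoring within a batch, twice
    expect_identical(scoreSamples(m, samples[3]), batched[3])
    expect_identical(scoreSamples(m, samples), batched)
    expect_true(all(batched > 0 & batched < 1))
})

test_that("training reduces loss, is deterministic, and rejects one-class input", {
    set.seed(55)
    enc <- encoderConfig(window = 3, fixedLength = 30)
    motifA <- "WWWHHHWWW"; motifB <- "CCCPPPCCC"
    mk <- function(motif, i) {
        bg <- paste(sample(profileBLSTM:::.AA20, 30, TRUE), collapse = "")
        at <- sample(1:21, 1L)
        sq <- paste0(substr(bg, 1, at - 1), motif,
                     substr(bg, at + 9, 30))
        encodeProtein(substr(sq, 1, 30), cfg = enc, id = paste0(motif, i))
    }
    samples <- c(lapply(1:10, function(i) mk(motifA, i)),
                 lapply(1:10, function(i) mk(motifB, i)))
    y <- rep(c(1, 0), each = 10)
    cfg <- modelConfig(cells = 8, epochs = 5, seed = 3, batchSize = 8)
    m1 <- trainBLSTM(samples, y, enc, cfg)
    tr <- lossTrace(m1)
    expect_length(tr, 5L)
    expect_lt(tr[5], tr[1])
    m2 <- trainBLSTM(samples, y, enc, cfg)
    expect_identical(m1@forward, m2@forward)
    expect_identical(m1@tdd, m2@tdd)
    expect_identical(scoreSamples(m1, samples), scoreSamples(m2, samples))
    expect_error(trainBLSTM(samples, rep(1, 20), enc, cfg), "both classes")
})

test_that("models round-trip through save/load with their provenance", {
    enc <- encoderConfig(window = 2, fixedLength = 8)
    m <- initBLSTMModel(enc, modelConfig(cells = 3, seed = 5))
    path <- withr::local_tempfile(fileext = ".rds")
    saveModel(m, path)
    back <- loadModel(path)
    expect_identical(back@forward, m@forward)
    expect_identical(configHash(back), configHash(m))
    expect_match(configHash(m), "^[0-9a-f]{32}$")
})
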