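## Bidirectional LSTM core: forward pass, backpropagation through time,
## RMSprop training. All heavy math is batched base-R matrix algebra; a
## per-sample reference path (lstmCellStep / runBLSTM) mirrors it for
## inspection and cross-checking.

.sigmoid <- function(z) 1 / (1 + exp(-z))

## slice time step t out of a (B, T, K) array as a B x K matrix
.slice <- function(A, t) {
    m <- A[, t, , drop = FALSE]
    dim(m) <- dim(A)[c(1L, 3L)]
    m
}

.addBias <- function(Z, b) Z + rep(b, each = nrow(Z))

#' One LSTM memory-cell update
#'
#' The standard non-peephole cell: logistic input/forget/output gates, tanh
#' candidate and state squashing:
#' i = sigma(Wi x + Ui h + bi), f = sigma(Wf x + Uf h + bf),
#' o = sigma(Wo x + Uo h + bo), g = tanh(Wg x + Ug h + bg),
#' c' = f c + i g, h' = o tanh(c').
#'
#' @param x input vector (length 20 w).
#' @param hPrev,cPrev previous hidden and cell state (length cells).
#' @param params one direction's gate parameters: list with `Wi, Ui, bi, Wf,
#'   Uf, bf, Wo, Uo, bo, Wg, Ug, bg`; input weights are (20 w x cells),
#'   recurrent weights (cells x cells).
#' @return list with elements `h` and `c` (length cells), plus the gate
#'   activations `i, f, o, g` for inspection.
#' @export
lstmCellStep <- function(x, hPrev, cPrev, params) {
    C <- length(params$bi)
    if (length(x) != nrow(params$Wi))
        stop(sprintf("input length %d does not match weight rows %d",
                     length(x), nrow(params$Wi)))
    if (length(hPrev) != C || length(cPrev) != C)
        stop("state length does not match cell count")
    zi <- drop(x %*% params$Wi + hPrev %*% params$Ui) + params$bi
    zf <- drop(x %*% params$Wf + hPrev %*% params$Uf) + params$bf
    zo <- drop(x %*% params$Wo + hPrev %*% params$Uo) + params$bo
    zg <- drop(x %*% params$Wg + hPrev %*% params$Ug) + params$bg
    i <- .sigmoid(zi); f <- .sigmoid(zf); o <- .sigmoid(zo); g <- tanh(zg)
    cNew <- f * cPrev + i * g
    list(h = o * tanh(cNew), c = cNew, i = i, f = f, o = o, g = g)
}

#' Run the bidirectional LSTM over one encoded sample
#'
#' The forward stream reads windows 1..T (N- to C-terminus), the backward
#' stream T..1, both from zero initial state; per position t the two hidden
#' values are concatenated so both halves describe the same input window.
#'
#' @param sample an [EncodedSample] (T rows).
#' @param model a [BLSTMModel] (or a bare list with `forward`/`backward`
#'   gate parameter lists).
#' @return list with `H` (T x 2 cells; columns 1..C forward, C+1..2C
#'   backward), `forward` and `backward` (each T x C).
#' @export
runBLSTM <- function(sample, model) {
    mat <- if (is(sample, "EncodedSample")) sample@mat else sample
    p <- if (is(model, "BLSTMModel"))
        list(forward = model@forward, backward = model@backward) else model
    Tn <- nrow(mat)
    C <- length(p$forward$bi)
    dir1 <- matrix(0, Tn, C); dir2 <- matrix(0, Tn, C)
    h <- numeric(C); cc <- numeric(C)
    for (t in seq_len(Tn)) {
        st <- lstmCellStep(mat[t, ], h, cc, p$forward)
        h <- st$h; cc <- st$c; dir1[t, ] <- h
    }
    h <- numeric(C); cc <- numeric(C)
    for (t in rev(seq_len(Tn))) {
        st <- lstmCellStep(mat[t, ], h, cc, p$backward)
        h <- st$h; cc <- st$c; dir2[t, ] <- h
    }
    list(H = cbind(dir1, dir2), forward = dir1, backward = dir2)
}

#' Time-distributed dense fusion of the hidden sequence
#'
#' One shared dense weight set maps each position's concatenated hidden value
#' to a single ReLU-activated scalar: alpha_t = max(0, w . h_t + b).
#'
#' @param hidden output of [runBLSTM()] (or a T x 2 cells matrix).
#' @param model a [BLSTMModel] (or list with `tdd = list(w, b)`).
#' @return numeric vector alpha of length T (the per-position learned
#'   feature vector).
#' @export
timeDistributedDense <- function(hidden, model) {
    H <- if (is.list(hidden) && !is.null(hidden$H)) hidden$H else hidden
    tdd <- if (is(model, "BLSTMModel")) model@tdd else model$tdd
    if (ncol(H) != length(tdd$w))
        stop("hidden width does not match time-distributed dense weights")
    pmax(drop(H %*% tdd$w) + tdd$b, 0)
}

#' Output-layer probability for one feature vector
#'
#' Single logistic node over the concatenated time-distributed dense outputs.
#'
#' @param v numeric feature vector of length T.
#' @param model a [BLSTMModel] (or list with `output = list(w, b)`).
#' @return probability in (0, 1) of superfamily membership.
#' @export
predictScore <- function(v, model) {
    out <- if (is(model, "BLSTMModel")) model@output else model$output
    if (length(v) != length(out$w))
        stop(sprintf("feature length %d does not match output weights %d",
                     length(v), length(out$w)))
    .sigmoid(sum(out$w * v) + out$b)
}

## ---- batched forward / backward -------------------------------------------

## stack encoded samples into a (N, T, D) array
.stackSamples <- function(samples) {
    if (is(samples, "EncodedSample")) samples <- list(samples)
    Tn <- nrow(samples[[1L]]@mat); D <- ncol(samples[[1L]]@mat)
    X <- array(0, c(length(samples), Tn, D))
    for (n in seq_along(samples)) {
        m <- samples[[n]]@mat
        if (!all(dim(m) == c(Tn, D)))
            stop("all samples must share the same encoding dimensions")
        X[n, , ] <- m
    }
    X
}

## one direction over a batch; ts is the processing order of time steps
.forwardDir <- function(X, p, reverse = FALSE, dropMask = NULL) {
    B <- dim(X)[1L]; Tn <- dim(X)[2L]
    C <- length(p$bi)
    ts <- if (reverse) rev(seq_len(Tn)) else seq_len(Tn)
    H <- array(0, c(B, Tn, C))
    I <- array(0, c(B, Tn, C)); F <- array(0, c(B, Tn, C))
    O <- array(0, c(B, Tn, C)); G <- array(0, c(B, Tn, C))
    Cc <- array(0, c(B, Tn, C)); Th <- array(0, c(B, Tn, C))
    h <- matrix(0, B, C); cc <- matrix(0, B, C)
    for (t in ts) {
        x <- .slice(X, t)
        if (!is.null(dropMask)) x <- x * dropMask
        i <- .sigmoid(.addBias(x %*% p$Wi + h %*% p$Ui, p$bi))
        f <- .sigmoid(.addBias(x %*% p$Wf + h %*% p$Uf, p$bf))
        o <- .sigmoid(.addBias(x %*% p$Wo + h %*% p$Uo, p$bo))
        g <- tanh(.addBias(x %*% p$Wg + h %*% p$Ug, p$bg))
        cc <- f * cc + i * g
        th <- tanh(cc)
        h <- o * th
        H[, t, ] <- h; I[, t, ] <- i; F[, t, ] <- f; O[, t, ] <- o
        G[, t, ] <- g; Cc[, t, ] <- cc; Th[, t, ] <- th
    }
    list(H = H, I = I, F = F, O = O, G = G, Cc = Cc, Th = Th, ts = ts)
}

## full network forward over a batch; mp is a plain parameter list.
## dropMask (B x D) masks the recurrent layer's input connections; hMask
## (B*T x 2C) masks its output connections (the hidden values feeding the
## fusion layer). Both are NULL at inference.
.forwardFull <- function(X, mp, dropMask = NULL, hMask = NULL) {
    B <- dim(X)[1L]; Tn <- dim(X)[2L]
    C <- length(mp$forward$bi)
    fwd <- .forwardDir(X, mp$forward, reverse = FALSE, dropMask = dropMask)
    bwd <- .forwardDir(X, mp$backward, reverse = TRUE, dropMask = dropMask)
    Hcat <- array(0, c(B, Tn, 2L * C))
    Hcat[, , seq_len(C)] <- fwd$H
    Hcat[, , C + seq_len(C)] <- bwd$H
    Hmat <- Hcat; dim(Hmat) <- c(B * Tn, 2L * C)
    if (!is.null(hMask)) Hmat <- Hmat * hMask
    pre <- matrix(drop(Hmat %*% mp$tdd$w) + mp$tdd$b, B, Tn)
    alpha <- pmax(pre, 0)
    logits <- drop(alpha %*% mp$output$w) + mp$output$b
    list(fwd = fwd, bwd = bwd, Hmat = Hmat, pre = pre, alpha = alpha,
         logits = logits, prob = .sigmoid(logits))
}

## numerically stable mean binary cross-entropy from logits
.bceLoss <- function(logits, y) {
    mean(pmax(logits, 0) - logits * y + log1p(exp(-abs(logits))))
}

.zeroLike <- function(p) lapply(p, function(a) a * 0)

## BPTT through one direction; dH is (B, T, C) gradient wrt that direction's
## hidden outputs. Returns parameter gradients.
.backwardDir <- function(X, dH, p, cache, dropMask = NULL) {
    B <- dim(X)[1L]; C <- length(p$bi)
    g <- .zeroLike(p)
    ts <- cache$ts
    dhNext <- matrix(0, B, C); dcNext <- matrix(0, B, C)
    for (k in rev(seq_along(ts))) {
        t <- ts[k]
        i <- .slice(cache$I, t); f <- .slice(cache$F, t)
        o <- .slice(cache$O, t); gg <- .slice(cache$G, t)
        th <- .slice(cache$Th, t)
        cPrev <- if (k > 1L) .slice(cache$Cc, ts[k - 1L]) else matrix(0, B, C)
        hPrev <- if (k > 1L) .slice(cache$H, ts[k - 1L]) else matrix(0, B, C)
        dh <- .slice(dH, t) + dhNext
        do_ <- dh * th
        dc <- dcNext + dh * o * (1 - th * th)
        di <- dc * gg; dg <- dc * i; df <- dc * cPrev
        dzi <- di * i * (1 - i); dzf <- df * f * (1 - f)
        dzo <- do_ * o * (1 - o); dzg <- dg * (1 - gg * gg)
        x <- .slice(X, t)
        if (!is.null(dropMask)) x <- x * dropMask
        g$Wi <- g$Wi + crossprod(x, dzi); g$Ui <- g$Ui + crossprod(hPrev, dzi)
        g$bi <- g$bi + colSums(dzi)
        g$Wf <- g$Wf + crossprod(x, dzf); g$Uf <- g$Uf + crossprod(hPrev, dzf)
        g$bf <- g$bf + colSums(dzf)
        g$Wo <- g$Wo + crossprod(x, dzo); g$Uo <- g$Uo + crossprod(hPrev, dzo)
        g$bo <- g$bo + colSums(dzo)
        g$Wg <- g$Wg + crossprod(x, dzg); g$Ug <- g$Ug + crossprod(hPrev, dzg)
        g$bg <- g$bg + colSums(dzg)
        dhNext <- dzi %*% t(p$Ui) + dzf %*% t(p$Uf) +
            dzo %*% t(p$Uo) + dzg %*% t(p$Ug)
        dcNext <- dc * f
    }
    g
}

## loss + analytic gradients for a batch; mirrors .forwardFull exactly
.lossGrad <- function(mp, X, y, dropMask = NULL, hMask = NULL) {
    B <- dim(X)[1L]; Tn <- dim(X)[2L]
    C <- length(mp$forward$bi)
    fw <- .forwardFull(X, mp, dropMask = dropMask, hMask = hMask)
    loss <- .bceLoss(fw$logits, y)
    dz <- (fw$prob - y) / B                       # d loss / d logits
    gOut <- list(w = drop(crossprod(fw$alpha, dz)), b = sum(dz))
    dalpha <- outer(dz, mp$output$w)              # B x T
    dpre <- dalpha * (fw$pre > 0)
    gTdd <- list(w = drop(crossprod(fw$Hmat, as.vector(dpre))), b = sum(dpre))
    dHmat <- outer(as.vector(dpre), mp$tdd$w)     # B*T x 2C
    if (!is.null(hMask)) dHmat <- dHmat * hMask
    dHcat <- array(dHmat, c(B, Tn, 2L * C))
    gF <- .backwardDir(X, dHcat[, , seq_len(C), drop = FALSE],
                       mp$forward, fw$fwd, dropMask)
    gB <- .backwardDir(X, dHcat[, , C + seq_len(C), drop = FALSE],
                       mp$backward, fw$bwd, dropMask)
    list(loss = loss,
         grads = list(forward = gF, backward = gB, tdd = gTdd, output = gOut),
         prob = fw$prob, aliveFrac = mean(fw$alpha > 0))
}

## ---- initialization and training ------------------------------------------

.glorot <- function(nr, nc) {
    lim <- sqrt(6 / (nr + nc))
    matrix(runif(nr * nc, -lim, lim), nr, nc)
}

.orthogonal <- function(n) {
    qrD <- qr(matrix(rnorm(n * n), n, n))
    Q <- qr.Q(qrD)
    Q %*% diag(sign(diag(qr.R(qrD))), n)
}

.initGate <- function(D, C) {
    out <- list()
    for (g in c("i", "f", "o", "g")) {
        out[[paste0("W", g)]] <- .glorot(D, C)
        out[[paste0("U", g)]] <- .orthogonal(C)
        out[[paste0("b", g)]] <- numeric(C)
    }
    out
}

.initParams <- function(D, C, Tn) {
    ## the fusion layer is a single ReLU unit: a small positive bias keeps it
    ## out of the dead regime at initialization (with b = 0 roughly half of
    ## the random starts collapse to all-zero activations and stop learning)
    list(forward = .initGate(D, C), backward = .initGate(D, C),
         tdd = list(w = drop(.glorot(2L * C, 1L)), b = 0.1),
         output = list(w = drop(.glorot(Tn, 1L)), b = 0))
}

.configHash <- function(encoder, config) {
    js <- jsonlite::toJSON(list(
        window = encoder@window, fixed_length = encoder@fixedLength,
        alphabet = encoder@alphabet, cells = config@cells,
        dropout = config@dropout, learning_rate = config@learningRate,
        batch_size = config@batchSize, epochs = config@epochs,
        seed = config@seed), auto_unbox = TRUE)
    tf <- tempfile()
    on.exit(unlink(tf))
    writeLines(js, tf)
    unname(tools::md5sum(tf))
}

.makeModel <- function(mp, encoder, config, lossTrace = numeric()) {
    new("BLSTMModel", forward = mp$forward, backward = mp$backward,
        tdd = mp$tdd, output = mp$output, encoder = encoder, config = config,
        lossTrace = lossTrace, configHash = .configHash(encoder, config))
}

.modelParams <- function(model)
    list(forward = model@forward, backward = model@backward,
         tdd = model@tdd, output = model@output)

#' Initialize an untrained model
#'
#' Input weights are Glorot-uniform, recurrent weights orthogonal (QR of a
#' standard-normal matrix, sign-fixed), biases zero; all draws are taken
#' under `config@seed`.
#'
#' @param encoder an [EncoderConfig].
#' @param config a [ModelConfig].
#' @return a [BLSTMModel] with an empty loss trace.
#' @export
initBLSTMModel <- function(encoder = encoderConfig(), config = modelConfig()) {
    set.seed(config@seed)
    mp <- .initParams(20L * encoder@window, config@cells, nTimeSteps(encoder))
    .makeModel(mp, encoder, config)
}

#' Train the bidirectional LSTM classifier
#'
#' Minimizes mean binary cross-entropy with RMSprop (decay 0.9, epsilon
#' 1e-8) at `config@learningRate`, in shuffled minibatches of
#' `config@batchSize`, for `config@epochs` epochs. Dropout at
#' `config@dropout` is applied to the recurrent layer's input connections
#' during training only (one inverted-dropout mask per sample per batch,
#' shared across time steps and gates). Everything — initialization, epoch
#' shuffles, dropout draws — is driven by `config@seed`, so identical inputs
#' give bit-identical models.
#'
#' @param samples list of [EncodedSample] (all with the same encoder
#'   dimensions).
#' @param labels 0/1 vector, one per sample; both classes must be present.
#' @param encoder an [EncoderConfig] matching the samples.
#' @param config a [ModelConfig].
#' @param dropoutSite where the dropout disconnections are applied:
#'   `"input"` (default) drops the bidirectional layer's input connections
#'   (one mask per sample, shared across time steps and gates); `"hidden"`
#'   drops its output connections (each hidden value feeding the fusion
#'   layer, independently per time step).
#' @param verbose print per-epoch loss.
#' @return a trained [BLSTMModel]; `lossTrace()` holds the per-epoch mean
#'   training loss.
#' @export
trainBLSTM <- function(samples, labels, encoder = encoderConfig(),
                       config = modelConfig(),
                       dropoutSite = c("input", "hidden"), verbose = FALSE) {
    dropoutSite <- match.arg(dropoutSite)
    labels <- as.numeric(labels)
    stopifnot(length(samples) == length(labels), all(labels %in% c(0, 1)))
    if (length(unique(labels)) < 2L)
        stop("training set must contain both classes")
    X <- .stackSamples(samples)
    if (dim(X)[2L] != nTimeSteps(encoder) ||
        dim(X)[3L] != 20L * encoder@window)
        stop("sample dimensions do not match the encoder configuration")
    N <- dim(X)[1L]; D <- dim(X)[3L]; Tn <- dim(X)[2L]
    rho <- 0.9; eps <- 1e-8; lr <- config@learningRate
    keep <- 1 - config@dropout
    ## A single ReLU fusion unit has an absorbing failure state: once its
    ## pre-activation is negative for every sample and position, every
    ## parameter except the output bias receives an exactly-zero gradient and
    ## training can provably never recover. When a whole epoch passes with
    ## identically-zero fusion activations (or the loss turns non-finite),
    ## training restarts deterministically from the next derived seed.
    maxRestarts <- 5L
    for (attempt in seq_len(maxRestarts)) {
        set.seed(config@seed + (attempt - 1L) * 1000003L)
        mp <- .initParams(D, config@cells, nTimeSteps(encoder))
        cache <- rapply(mp, function(a) a * 0, how = "replace")
        trace <- numeric(config@epochs)
        failed <- FALSE
        for (ep in seq_len(config@epochs)) {
            ord <- sample.int(N)
            epLoss <- 0
            epAlive <- FALSE
            for (start in seq(1L, N, by = config@batchSize)) {
                idx <- ord[start:min(start + config@batchSize - 1L, N)]
                B <- length(idx)
                Xb <- X[idx, , , drop = FALSE]
                mask <- NULL; hMask <- NULL
                if (config@dropout > 0) {
                    if (dropoutSite == "input")
                        mask <- matrix(rbinom(B * D, 1L, keep), B, D) / keep
                    else
                        hMask <- matrix(rbinom(B * Tn * 2L * config@cells, 1L,
                                               keep),
                                        B * Tn, 2L * config@cells) / keep
                }
                lg <- .lossGrad(mp, Xb, labels[idx], dropMask = mask,
                                hMask = hMask)
                epLoss <- epLoss + lg$loss * B
                epAlive <- epAlive || lg$aliveFrac > 0
                ## RMSprop update, walking the nested parameter lists in
                ## lockstep
                for (top in names(mp)) for (nm in names(mp[[top]])) {
                    gr <- lg$grads[[top]][[nm]]
                    cache[[top]][[nm]] <- rho * cache[[top]][[nm]] +
                        (1 - rho) * gr * gr
                    mp[[top]][[nm]] <- mp[[top]][[nm]] -
                        lr * gr / (sqrt(cache[[top]][[nm]]) + eps)
                }
            }
            trace[ep] <- epLoss / N
            if (!epAlive || !is.finite(trace[ep])) { failed <- TRUE; break }
            if (verbose)
                message(sprintf("epoch %3d/%d  loss %.5f", ep, config@epochs,
                                trace[ep]))
        }
        if (!failed)
            return(.makeModel(mp, encoder, config, lossTrace = trace))
        if (verbose)
            message("fusion unit collapsed; restarting (attempt ",
                    attempt + 1L, ")")
    }
    warning("fusion unit collapsed in all ", maxRestarts,
            " restarts; returning the last (degenerate) model")
    .makeModel(mp, encoder, config, lossTrace = trace)
}

#' Score proteins with a trained model
#'
#' Deterministic inference (no dropout), independent of batch composition.
#'
#' @param model a trained [BLSTMModel].
#' @param samples an [EncodedSample] or list thereof.
#' @param chunk internal batching size for the vectorized forward pass.
#' @return named numeric vector of superfamily-membership probabilities.
#' @export
scoreSamples <- function(model, samples, chunk = 128L) {
    if (is(samples, "EncodedSample")) samples <- list(samples)
    mp <- .modelParams(model)
    out <- numeric(length(samples))
    names(out) <- vapply(samples, function(s) s@id, character(1L))
    for (start in seq(1L, length(samples), by = chunk)) {
        idx <- start:min(start + chunk - 1L, length(samples))
        X <- .stackSamples(samples[idx])
        if (dim(X)[2L] != nTimeSteps(model))
            stop("sample encoding does not match the model's encoder config")
        out[idx] <- .forwardFull(X, mp)$prob
    }
    out
}

#' Save / load a trained model
#'
#' The container keeps the full parameter set, both configs, the loss trace
#' and the config hash, so a loaded model refuses inputs encoded under a
#' different encoder configuration.
#'
#' @param model a [BLSTMModel].
#' @param path file path (`.rds`).
#' @return `saveModel()` returns `path` invisibly; `loadModel()` returns the
#'   [BLSTMModel].
#' @export
saveModel <- function(model, path) {
    stopifnot(is(model, "BLSTMModel"))
    saveRDS(model, path)
    invisible(path)
}

#' @rdname saveModel
#' @export
loadModel <- function(path) {
    model <- readRDS(path)
    stopifnot(is(model, "BLSTMModel"))
    validObject(model)
    model
}

## flatten parameters to one numeric vector (finite-difference checks)
.flattenParams <- function(mp) {
    unlist(mp, use.names = FALSE)
}

.unflattenParams <- function(v, template) {
    rel <- utils::relist(v, template)
    for (top in names(template)) for (nm in names(template[[top]])) {
        d <- dim(template[[top]][[nm]])
        if (!is.null(d)) dim(rel[[top]][[nm]]) <- d
    }
    rel
}
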