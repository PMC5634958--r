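#' Extract the per-position learned feature vector
#'
#' The vector V = [alpha_1, ..., alpha_T] of time-distributed dense outputs —
#' exactly what the output layer consumes during prediction, returned without
#' the final logistic step. Each alpha_t is the fused dependency signal of
#' the window at position t.
#'
#' @param sample an [EncodedSample].
#' @param model a trained [BLSTMModel].
#' @return non-negative numeric vector of length T.
#' @export
extractFeatures <- function(sample, model) {
    stopifnot(is(sample, "EncodedSample"), is(model, "BLSTMModel"))
    if (nrow(sample@mat) != nTimeSteps(model))
        stop("sample encoding does not match the model's encoder config")
    timeDistributedDense(runBLSTM(sample, model), model)
}

#' Feature matrices for many samples
#'
#' @param samples list of [EncodedSample].
#' @param model a trained [BLSTMModel].
#' @return numeric matrix, one row per sample (rownames = sample ids).
#' @export
extractFeatureMatrix <- function(samples, model) {
    mp <- .modelParams(model)
    X <- .stackSamples(samples)
    fw <- .forwardFull(X, mp)
    rownames(fw$alpha) <- vapply(samples, function(s) s@id, character(1L))
    fw$alpha
}

#' Write / read a feature matrix TSV
#'
#' First column `sample_id`, then one column per position.
#'
#' @param features numeric matrix with sample ids as rownames.
#' @param path file path.
#' @return `writeFeatureTSV()` returns `path` invisibly.
#' @export
writeFeatureTSV <- function(features, path) {
    df <- data.frame(sample_id = rownames(features), features,
                     check.names = FALSE)
    colnames(df) <- c("sample_id", paste0("t", seq_len(ncol(features))))
    utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeFeatureTSV
#' @export
readFeatureTSV <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t")
    m <- as.matrix(df[, -1L, drop = FALSE])
    rownames(m) <- df$sample_id
    m
}

#' 2-D t-SNE embedding of feature vectors
#'
#' Exact (O(n^2)) t-SNE: per-point Gaussian bandwidths calibrated to the
#' target perplexity by bisection, early exaggeration, and momentum gradient
#' descent with adaptive gains on the Student-t low-dimensional affinities.
#' Output coordinates are min-max normalized per axis to [0, 1]. Fully
#' deterministic given `seed`.
#'
#' @param features numeric matrix (rows = samples) or list of feature
#'   vectors.
#' @param seed integer seed for the initial layout.
#' @param perplexity target perplexity; capped at (n - 1)/3 for small n.
#' @param iterations gradient-descent iterations.
#' @return n x 2 matrix of coordinates in [0, 1]^2 (rownames preserved).
#' @export
tsneEmbed <- function(features, seed = 1L, perplexity = 30, iterations = 500L) {
    if (is.list(features)) features <- do.call(rbind, features)
    X <- as.matrix(features)
    n <- nrow(X)
    if (n < 3L) stop("need at least 3 samples to embed")
    perplexity <- max(1, min(perplexity, (n - 1) / 3))
    P <- .tsneAffinities(X, perplexity)
    set.seed(seed)
    Y <- matrix(rnorm(n * 2L, sd = 1e-4), n, 2L)
    dY <- matrix(0, n, 2L); gains <- matrix(1, n, 2L)
    eta <- 200
    for (it in seq_len(iterations)) {
        Pit <- if (it <= 100L) P * 12 else P       # early exaggeration
        sum2 <- rowSums(Y * Y)
        num <- 1 / (1 + outer(sum2, sum2, "+") - 2 * tcrossprod(Y))
        diag(num) <- 0
        Q <- pmax(num / sum(num), 1e-12)
        W <- (Pit - Q) * num
        grad <- 4 * (diag(rowSums(W)) - W) %*% Y
        gains <- pmax(ifelse(sign(grad) != sign(dY), gains + 0.2,
                             gains * 0.8), 0.01)
        mom <- if (it < 250L) 0.5 else 0.8
        dY <- mom * dY - eta * gains * grad
        Y <- Y + dY
        Y <- sweep(Y, 2L, colMeans(Y))
    }
    for (j in 1:2) {
        rg <- range(Y[, j])
        Y[, j] <- if (diff(rg) < 1e-12) 0.5 else (Y[, j] - rg[1L]) / diff(rg)
    }
    rownames(Y) <- rownames(features)
    colnames(Y) <- c("x", "y")
    Y
}

## symmetrized high-dimensional affinities at a fixed perplexity
.tsneAffinities <- function(X, perplexity) {
    n <- nrow(X)
    sum2 <- rowSums(X * X)
    D2 <- pmax(outer(sum2, sum2, "+") - 2 * tcrossprod(X), 0)
    targetH <- log(perplexity)
    P <- matrix(0, n, n)
    for (i in seq_len(n)) {
        di <- D2[i, -i]
        beta <- 1; lo <- -Inf; hi <- Inf
        for (iter in 1:50) {
            w <- exp(-di * beta)
            sw <- sum(w)
            if (sw < 1e-300) { p <- rep(1 / length(di), length(di)) }
            else p <- w / sw
            H <- -sum(p * log(pmax(p, 1e-300)))
            if (abs(H - targetH) < 1e-5) break
            if (H > targetH) { lo <- beta; beta <- if (is.finite(hi)) (beta + hi) / 2 else beta * 2 }
            else { hi <- beta; beta <- if (is.finite(lo)) (beta + lo) / 2 else beta / 2 }
        }
        P[i, -i] <- p
    }
    pmax((P + t(P)) / (2 * n), 1e-12)
}

#' Scatter plot of an embedding, colored by label
#'
#' Positive samples are drawn red, negatives blue, and the plot is written to
#' `path` (device chosen by extension: .png, .svg or .pdf).
#'
#' @param points n x 2 coordinate matrix (e.g. from [tsneEmbed()]).
#' @param labels 0/1 vector of the same length.
#' @param path output image path.
#' @param title plot title.
#' @return invisibly, a data.frame of the plotted x, y, label and color
#'   (usable to audit the label-color mapping).
#' @export
plotEmbedding <- function(points, labels, path, title = "Learned feature embedding") {
    points <- as.matrix(points)
    if (length(labels) == 0L) stop("empty label set")
    if (nrow(points) != length(labels))
        stop("points and labels must have the same length")
    if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
    cols <- ifelse(labels == 1, "red", "blue")
    ext <- tolower(tools::file_ext(path))
    dev <- switch(ext,
                  png = function(p) grDevices::png(p, width = 800, height = 800),
                  svg = function(p) grDevices::svg(p, width = 7, height = 7),
                  pdf = function(p) grDevices::pdf(p, width = 7, height = 7),
                  stop("unsupported image extension: ", ext))
    dev(path)
    on.exit(grDevices::dev.off())
    graphics::plot(points[, 1L], points[, 2L], col = cols, pch = 19,
                   xlab = "x", ylab = "y", main = title,
                   xlim = c(0, 1), ylim = c(0, 1))
    graphics::legend("topright", legend = c("positive", "negative"),
                     col = c("red", "blue"), pch = 19, bty = "n")
    invisible(data.frame(x = points[, 1L], y = points[, 2L],
                         label = labels, color = cols,
                         stringsAsFactors = FALSE))
}
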