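#' Constructors and accessors for the core classes
#'
#' Small wrappers that build validated objects and read their slots without
#' touching `@`.
#'
#' @param window,fixedLength,alphabet encoder settings; see [EncoderConfig].
#' @return `encoderConfig()` returns an [EncoderConfig].
#' @examples
#' cfg <- encoderConfig(window = 3, fixedLength = 400)
#' nTimeSteps(cfg)  # 398
#' @export
encoderConfig <- function(window = 3L, fixedLength = 400L, alphabet = .AA20) {
    new("EncoderConfig", window = as.integer(window),
        fixedLength = as.integer(fixedLength), alphabet = toupper(alphabet))
}

#' @rdname encoderConfig
#' @param cells,dropout,learningRate,batchSize,epochs,seed network and
#'   optimizer settings; see [ModelConfig].
#' @export
modelConfig <- function(cells = 50L, dropout = 0.2, learningRate = 0.01,
                        batchSize = 32L, epochs = 150L, seed = 1L) {
    new("ModelConfig", cells = as.integer(cells), dropout = dropout,
        learningRate = learningRate, batchSize = as.integer(batchSize),
        epochs = as.integer(epochs), seed = as.integer(seed))
}

#' @rdname encoderConfig
#' @param x an object of the matching class.
#' @export
nTimeSteps <- function(x) {
    cfg <- if (is(x, "BLSTMModel")) x@encoder else x
    stopifnot(is(cfg, "EncoderConfig"))
    cfg@fixedLength - cfg@window + 1L
}

#' @rdname encoderConfig
#' @export
queryResidues <- function(x) { stopifnot(is(x, "PSSMProfile")); x@query }

#' @rdname encoderConfig
#' @export
pssmScores <- function(x) { stopifnot(is(x, "PSSMProfile")); x@scores }

#' @rdname encoderConfig
#' @export
residues <- function(x) { stopifnot(is(x, "PseudoProtein")); x@residues }

#' @rdname encoderConfig
#' @export
sampleMatrix <- function(x) { stopifnot(is(x, "EncodedSample")); x@mat }

#' @rdname encoderConfig
#' @export
windowMask <- function(x) { stopifnot(is(x, "EncodedSample")); x@mask }

#' @rdname encoderConfig
#' @export
lossTrace <- function(x) { stopifnot(is(x, "BLSTMModel")); x@lossTrace }

#' @rdname encoderConfig
#' @export
configHash <- function(x) { stopifnot(is(x, "BLSTMModel")); x@configHash }

#' @rdname encoderConfig
#' @export
rocValue <- function(x) { stopifnot(is(x, "ROCResult")); x@roc }

#' @rdname encoderConfig
#' @export
roc50Value <- function(x) { stopifnot(is(x, "ROCResult")); x@roc50 }

#' @rdname encoderConfig
#' @export
splitSets <- function(x) {
    stopifnot(is(x, "BenchmarkSplit"))
    list(targetFamily = x@targetFamily, posTest = x@posTest,
         posTrain = x@posTrain, extendedPos = x@extendedPos,
         negTest = x@negTest, negTrain = x@negTrain)
}

setMethod("show", "PSSMProfile", function(object) {
    cat("PSSMProfile:", nchar(object@query), "positions x 20 log-odds columns\n")
    cat("  query:", .abbrevSeq(object@query), "\n")
})

setMethod("show", "PseudoProtein", function(object) {
    cat(sprintf("PseudoProtein '%s' (%s), %d residues\n", object@id,
                object@source, nchar(object@residues)))
    cat("  ", .abbrevSeq(object@residues), "\n", sep = "")
})

setMethod("show", "EncoderConfig", function(object) {
    cat(sprintf("EncoderConfig: window = %d, fixedLength = %d (T = %d)\n",
                object@window, object@fixedLength, nTimeSteps(object)))
})

setMethod("show", "EncodedSample", function(object) {
    cat(sprintf("EncodedSample '%s': %d windows x %d features (%d real)\n",
                object@id, nrow(object@mat), ncol(object@mat),
                sum(object@mask)))
})

setMethod("show", "ModelConfig", function(object) {
    cat(sprintf(paste0("ModelConfig: %d cells/direction, dropout %.2f, ",
                       "RMSprop lr %g, batch %d, %d epochs, seed %d\n"),
                object@cells, object@dropout, object@learningRate,
                object@batchSize, object@epochs, object@seed))
})

setMethod("show", "BLSTMModel", function(object) {
    cat("BLSTMModel (bidirectional LSTM + time-distributed dense + logistic output)\n")
    show(object@encoder)
    show(object@config)
    if (length(object@lossTrace))
        cat(sprintf("  trained %d epochs; final loss %.4f\n",
                    length(object@lossTrace),
                    object@lossTrace[length(object@lossTrace)]))
    cat("  config hash:", object@configHash, "\n")
})

setMethod("show", "ROCResult", function(object) {
    cat(sprintf("ROCResult: ROC = %.4f, ROC50 = %.4f (%d pos / %d neg)\n",
                object@roc, object@roc50, object@nPos, object@nNeg))
})

setMethod("show", "BenchmarkSplit", function(object) {
    cat(sprintf("BenchmarkSplit for family '%s'\n", object@targetFamily))
    cat(sprintf("  +test %d | +train %d | +extended %d | -test %d | -train %d\n",
                length(object@posTest), length(object@posTrain),
                length(object@extendedPos), length(object@negTest),
                length(object@negTrain)))
})

setMethod("show", "SyntheticSpec", function(object) {
    cat(sprintf(paste0("SyntheticSpec: %d superfamilies x %d families x %d ",
                       "proteins, lengths %d-%d\n"),
                object@nSuperfamilies, object@familiesPerSuperfamily,
                object@proteinsPerFamily, object@lengthRange[1L],
                object@lengthRange[2L]))
    cat(sprintf("  motif %d aa, mutation rate %.2f, seed %d\n",
                object@motifLength, object@mutationRate, object@seed))
})

.abbrevSeq <- function(s, n = 40L) {
    if (nchar(s) <= n) s else paste0(substr(s, 1L, n), "...")
}
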