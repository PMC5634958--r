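#' @import methods
#' @importFrom stats rnorm runif rbinom plogis sd t.test kmeans
#' @importFrom utils read.delim write.table head
NULL

## Column order of the PSI-BLAST ASCII PSSM log-odds block, as printed in the
## file header.
.PSSM_COLS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

## One-hot alphabet: the 20 standard amino acids, alphabetical.
.AA20 <- sort(.PSSM_COLS)

## Ambiguity / non-standard letters tolerated in input sequences; they encode
## to the all-zero vector.
.AA_WILDCARDS <- c("X", "B", "Z", "U", "J", "O")

## Padding symbol appended when a sequence is shorter than the fixed length.
.AA_PAD <- "-"

#' PSSMProfile: a PSI-BLAST position-specific scoring matrix
#'
#' One row per query position, 20 integer log-odds columns in the PSI-BLAST
#' header order (A R N D C Q E G H I L K M F P S T W Y V).
#'
#' @slot query single string; the query residues the profile is aligned to.
#' @slot scores integer matrix, `nchar(query)` rows by 20 columns.
#' @export
setClass("PSSMProfile", slots = c(query = "character", scores = "matrix"))

setValidity("PSSMProfile", function(object) {
    msg <- character()
    if (length(object@query) != 1L || !nzchar(object@query))
        msg <- c(msg, "'query' must be a single non-empty string")
    if (ncol(object@scores) != 20L)
        msg <- c(msg, "'scores' must have exactly 20 columns")
    if (length(object@query) == 1L && nrow(object@scores) != nchar(object@query))
        msg <- c(msg, "row count of 'scores' must equal query length")
    if (!is.numeric(object@scores))
        msg <- c(msg, "'scores' must be numeric")
    if (length(msg)) msg else TRUE
})

#' PseudoProtein: a profile-derived rewritten protein sequence
#'
#' Each position carries the amino acid most favoured by the profile
#' (source `"from_pssm"`), or the original residues when no profile was
#' available (source `"passthrough"`).
#'
#' @slot id single non-empty string.
#' @slot residues single string; only the 20 standard letters when derived
#'   from a profile.
#' @slot source `"from_pssm"` or `"passthrough"`.
#' @export
setClass("PseudoProtein",
         slots = c(id = "character", residues = "character", source = "character"))

setValidity("PseudoProtein", function(object) {
    msg <- character()
    if (length(object@id) != 1L || !nzchar(object@id))
        msg <- c(msg, "'id' must be a single non-empty string")
    if (length(object@residues) != 1L)
        msg <- c(msg, "'residues' must be a single string")
    if (!object@source %in% c("from_pssm", "passthrough"))
        msg <- c(msg, "'source' must be 'from_pssm' or 'passthrough'")
    if (identical(object@source, "from_pssm")) {
        ## standard letters only, plus the C-terminal padding symbol
        letters <- strsplit(object@residues, "", fixed = TRUE)[[1L]]
        if (!all(letters %in% c(.AA20, .AA_PAD)))
            msg <- c(msg, "profile-derived residues must be standard amino acids")
    }
    if (length(msg)) msg else TRUE
})

#' EncoderConfig: sliding-window one-hot encoder settings
#'
#' @slot window window size w (number of residues per time step).
#' @slot fixedLength length L every sequence is truncated/padded to.
#' @slot alphabet the ordered 20-letter one-hot alphabet.
#' @export
setClass("EncoderConfig",
         slots = c(window = "integer", fixedLength = "integer",
                   alphabet = "character"))

setValidity("EncoderConfig", function(object) {
    msg <- character()
    if (object@window < 1L) msg <- c(msg, "'window' must be >= 1")
    if (object@fixedLength < object@window)
        msg <- c(msg, "'fixedLength' must be >= 'window'")
    if (length(object@alphabet) != 20L || anyDuplicated(object@alphabet))
        msg <- c(msg, "'alphabet' must hold 20 unique letters")
    if (length(msg)) msg else TRUE
})

#' EncodedSample: the windowed one-hot input matrix for one protein
#'
#' Row t is the concatenation of the one-hot vectors of residues
#' t..t+w-1 of the length-fixed pseudo protein; wildcards and padding encode
#' to all-zero 20-blocks.
#'
#' @slot id sample identifier.
#' @slot mat binary matrix, (L - w + 1) rows by 20 w columns.
#' @slot mask integer 0/1 vector marking windows fully inside the unpadded
#'   sequence (stored for analysis; time steps are not skipped).
#' @export
setClass("EncodedSample",
         slots = c(id = "character", mat = "matrix", mask = "integer"))

setValidity("EncodedSample", function(object) {
    msg <- character()
    if (ncol(object@mat) %% 20L != 0L)
        msg <- c(msg, "column count must be a multiple of 20")
    if (!all(object@mat %in% c(0, 1)))
        msg <- c(msg, "matrix entries must be 0/1")
    if (length(object@mask) != nrow(object@mat))
        msg <- c(msg, "mask length must equal row count")
    if (length(msg)) msg else TRUE
})

#' ModelConfig: network and optimizer hyperparameters
#'
#' Defaults are the reference configuration: 50 memory cells per direction,
#' dropout 0.2 on the recurrent layer's input connections, RMSprop at learning
#' rate 0.01, batch size 32, 150 epochs.
#'
#' @slot cells memory cells per LSTM direction.
#' @slot dropout input-connection dropout rate in [0, 1).
#' @slot learningRate RMSprop learning rate.
#' @slot batchSize minibatch size.
#' @slot epochs training epochs.
#' @slot seed integer seed driving initialization, shuffling and dropout.
#' @export
setClass("ModelConfig",
         slots = c(cells = "integer", dropout = "numeric",
                   learningRate = "numeric", batchSize = "integer",
                   epochs = "integer", seed = "integer"))

setValidity("ModelConfig", function(object) {
    msg <- character()
    if (object@cells < 1L) msg <- c(msg, "'cells' must be positive")
    if (object@dropout < 0 || object@dropout >= 1)
        msg <- c(msg, "'dropout' must lie in [0, 1)")
    if (object@learningRate <= 0) msg <- c(msg, "'learningRate' must be positive")
    if (object@batchSize < 1L) msg <- c(msg, "'batchSize' must be positive")
    if (object@epochs < 1L) msg <- c(msg, "'epochs' must be positive")
    if (length(msg)) msg else TRUE
})

#' BLSTMModel: trained parameters of the four-layer network
#'
#' @slot forward,backward per-direction LSTM gate parameters: lists with
#'   input weights `W<g>` (input-dim x cells), recurrent weights `U<g>`
#'   (cells x cells) and biases `b<g>` for gates g in i, f, o, g.
#' @slot tdd time-distributed dense fusion: list(w, b), `w` of length
#'   2*cells, shared across all time steps.
#' @slot output output node: list(w, b), `w` of length T = L - w + 1.
#' @slot encoder the [EncoderConfig] the model was trained under.
#' @slot config the [ModelConfig] used for training.
#' @slot lossTrace per-epoch mean training loss.
#' @slot configHash md5 of the serialized configs + seed, stamped into
#'   artifacts produced from this model.
#' @export
setClass("BLSTMModel",
         slots = c(forward = "list", backward = "list", tdd = "list",
                   output = "list", encoder = "EncoderConfig",
                   config = "ModelConfig", lossTrace = "numeric",
                   configHash = "character"))

setValidity("BLSTMModel", function(object) {
    msg <- character()
    C <- object@config@cells
    D <- 20L * object@encoder@window
    Tn <- object@encoder@fixedLength - object@encoder@window + 1L
    for (dir in c("forward", "backward")) {
        p <- slot(object, dir)
        for (g in c("i", "f", "o", "g")) {
            W <- p[[paste0("W", g)]]; U <- p[[paste0("U", g)]]
            b <- p[[paste0("b", g)]]
            if (is.null(W) || !all(dim(W) == c(D, C)))
                msg <- c(msg, sprintf("%s W%s must be %d x %d", dir, g, D, C))
            if (is.null(U) || !all(dim(U) == c(C, C)))
                msg <- c(msg, sprintf("%s U%s must be %d x %d", dir, g, C, C))
            if (is.null(b) || length(b) != C)
                msg <- c(msg, sprintf("%s b%s must have length %d", dir, g, C))
        }
    }
    if (length(object@tdd$w) != 2L * C)
        msg <- c(msg, "tdd weights must have length 2*cells")
    if (length(object@output$w) != Tn)
        msg <- c(msg, sprintf("output weights must have length %d", Tn))
    if (length(msg)) msg else TRUE
})

#' ROCResult: ROC and ROC50 for one ranked prediction set
#'
#' @slot roc normalized area under the full ROC curve.
#' @slot roc50 normalized area up to the 50th false positive.
#' @slot nPos,nNeg class counts.
#' @export
setClass("ROCResult",
         slots = c(roc = "numeric", roc50 = "numeric",
                   nPos = "integer", nNeg = "integer"))

setValidity("ROCResult", function(object) {
    msg <- character()
    if (object@roc < 0 || object@roc > 1) msg <- c(msg, "'roc' must lie in [0,1]")
    if (object@roc50 < 0 || object@roc50 > 1)
        msg <- c(msg, "'roc50' must lie in [0,1]")
    if (object@nPos < 1L || object@nNeg < 1L)
        msg <- c(msg, "need at least one positive and one negative")
    if (length(msg)) msg else TRUE
})

#' BenchmarkSplit: the five id sets of a family-holdout split
#'
#' For target family k: positive test = members of k; positive train = the
#' rest of k's superfamily; every other superfamily donates one whole family
#' to the negative test set and its remaining families to the negative train
#' set. An optional extended positive set (externally retrieved homologs)
#' augments training.
#'
#' @slot targetFamily family id the split is built around.
#' @slot posTest,posTrain,extendedPos,negTest,negTrain protein id vectors;
#'   pairwise disjoint.
#' @export
setClass("BenchmarkSplit",
         slots = c(targetFamily = "character", posTest = "character",
                   posTrain = "character", extendedPos = "character",
                   negTest = "character", negTrain = "character"))

setValidity("BenchmarkSplit", function(object) {
    ids <- c(object@posTest, object@posTrain, object@extendedPos,
             object@negTest, object@negTrain)
    if (anyDuplicated(ids))
        return("the five id sets must be pairwise disjoint")
    if (length(object@posTest) < 1L)
        return("positive test set must be non-empty")
    TRUE
})

#' SyntheticSpec: parameters of the planted-motif sequence generator
#'
#' @slot nSuperfamilies,familiesPerSuperfamily,proteinsPerFamily hierarchy
#'   sizes.
#' @slot lengthRange integer (min, max) sequence length.
#' @slot motifLength length of the ungapped superfamily motif; the family
#'   sub-motif is half as long (rounded up).
#' @slot mutationRate per-position point-mutation probability applied to each
#'   planted motif copy.
#' @slot background amino-acid frequency vector (20 entries, sums to 1).
#' @slot seed integer seed; generation is fully deterministic given the spec.
#' @export
setClass("SyntheticSpec",
         slots = c(nSuperfamilies = "integer", familiesPerSuperfamily = "integer",
                   proteinsPerFamily = "integer", lengthRange = "integer",
                   motifLength = "integer", mutationRate = "numeric",
                   background = "numeric", seed = "integer"))

setValidity("SyntheticSpec", function(object) {
    msg <- character()
    if (any(c(object@nSuperfamilies, object@familiesPerSuperfamily,
              object@proteinsPerFamily, object@motifLength) < 1L))
        msg <- c(msg, "hierarchy sizes and motif length must be positive")
    if (length(object@lengthRange) != 2L ||
        object@lengthRange[1L] > object@lengthRange[2L])
        msg <- c(msg, "'lengthRange' must be (min, max) with min <= max")
    if (object@mutationRate < 0 || object@mutationRate > 1)
        msg <- c(msg, "'mutationRate' must lie in [0, 1]")
    if (length(object@background) != 20L ||
        abs(sum(object@background) - 1) > 1e-9)
        msg <- c(msg, "'background' must be 20 frequencies summing to 1")
    famMotif <- as.integer(ceiling(object@motifLength / 2))
    if (object@lengthRange[1L] < object@motifLength + famMotif)
        msg <- c(msg, "minimum length must fit the superfamily and family motifs")
    if (length(msg)) msg else TRUE
})
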