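#' Build the family-holdout split for one target family
#'
#' For target family k: its members form the positive test set; the other
#' families of its superfamily form the positive training set; each remaining
#' superfamily donates exactly one whole family to the negative test set and
#' all of its other families to the negative training set. An optional
#' pre-computed extended positive id list (externally retrieved homologs)
#' augments training. The five sets are pairwise disjoint by construction.
#'
#' @param labels label table (data.frame with id, family, superfamily; see
#'   [readLabelTable()]).
#' @param targetFamily the family id to hold out.
#' @param negChooser how the held-out negative family of each non-target
#'   superfamily is picked: `"lexicographic"` (smallest family id,
#'   deterministic) or `"random"` (seeded draw).
#' @param seed seed for the random chooser.
#' @param extendedPos character vector of extra positive training ids (must
#'   not collide with benchmark ids).
#' @return a [BenchmarkSplit].
#' @export
makeSplit <- function(labels, targetFamily,
                      negChooser = c("lexicographic", "random"),
                      seed = 1L, extendedPos = character()) {
    negChooser <- match.arg(negChooser)
    labels <- .validateLabelTable(labels)
    if (!targetFamily %in% labels$family)
        stop("unknown family: ", targetFamily)
    if (any(extendedPos %in% labels$id))
        stop("extended positive ids collide with benchmark ids")
    targetSF <- labels$superfamily[match(targetFamily, labels$family)]
    posTest <- labels$id[labels$family == targetFamily]
    posTrain <- labels$id[labels$superfamily == targetSF &
                          labels$family != targetFamily]
    if (length(posTrain) == 0L && length(extendedPos) == 0L)
        warning("superfamily of '", targetFamily,
                "' has no other family: positive training set is empty")
    negTest <- character(); negTrain <- character()
    if (negChooser == "random") set.seed(seed)
    for (sf in setdiff(sort(unique(labels$superfamily)), targetSF)) {
        fams <- sort(unique(labels$family[labels$superfamily == sf]))
        held <- if (negChooser == "lexicographic") fams[1L]
                else fams[sample.int(length(fams), 1L)]
        negTest <- c(negTest, labels$id[labels$family == held])
        negTrain <- c(negTrain,
                      labels$id[labels$superfamily == sf &
                                labels$family != held])
    }
    new("BenchmarkSplit", targetFamily = targetFamily, posTest = posTest,
        posTrain = posTrain, extendedPos = extendedPos, negTest = negTest,
        negTrain = negTrain)
}

#' Build splits for every eligible family
#'
#' @inheritParams makeSplit
#' @param minPositives keep only families with at least this many members
#'   (the benchmark-dataset convention is 10; default 0 so toy hierarchies
#'   are not filtered).
#' @return named list of [BenchmarkSplit], one per eligible family, in
#'   lexicographic family order.
#' @export
makeAllSplits <- function(labels, negChooser = c("lexicographic", "random"),
                          seed = 1L, minPositives = 0L) {
    negChooser <- match.arg(negChooser)
    labels <- .validateLabelTable(labels)
    sizes <- table(labels$family)
    fams <- sort(names(sizes)[sizes >= minPositives])
    out <- lapply(seq_along(fams), function(k)
        makeSplit(labels, fams[k], negChooser = negChooser,
                  seed = seed + k - 1L))
    names(out) <- fams
    out
}

#' Write a split manifest
#'
#' One JSON object per target family listing the five id sets.
#'
#' @param splits a [BenchmarkSplit] or list thereof.
#' @param path output JSON path.
#' @return `path`, invisibly.
#' @export
writeSplitManifest <- function(splits, path) {
    if (is(splits, "BenchmarkSplit")) splits <- list(splits)
    obj <- lapply(splits, splitSets)
    names(obj) <- vapply(splits, function(s) s@targetFamily, character(1L))
    jsonlite::write_json(obj, path, pretty = TRUE)
    invisible(path)
}

#' @rdname writeSplitManifest
#' @export
readSplitManifest <- function(path) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    lapply(obj, function(s)
        new("BenchmarkSplit",
            targetFamily = s$targetFamily,
            posTest = as.character(unlist(s$posTest)),
            posTrain = as.character(unlist(s$posTrain)),
            extendedPos = as.character(unlist(s$extendedPos)),
            negTest = as.character(unlist(s$negTest)),
            negTrain = as.character(unlist(s$negTrain))))
}
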