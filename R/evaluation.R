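#' ROC score of a ranked prediction set
#'
#' The normalized area under the ROC curve, computed by the pair convention:
#' the fraction of (positive, negative) pairs in which the positive outscores
#' the negative, with ties credited 0.5. This equals the trapezoidal area
#' under the ROC curve with tied score groups drawn as diagonal segments.
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector, same length, higher = more positive.
#' @return ROC score in [0, 1]; 1 for a perfect ranking.
#' @examples
#' rocScore(c(1, 1, 0, 0), c(0.9, 0.8, 0.4, 0.1))  # 1
#' @export
rocScore <- function(labels, scores) {
    .checkPreds(labels, scores, needNeg = TRUE)
    pos <- labels == 1
    r <- rank(scores, ties.method = "average")
    nPos <- sum(pos); nNeg <- sum(!pos)
    (sum(r[pos]) - nPos * (nPos + 1) / 2) / (nPos * nNeg)
}

#' ROC50 score: early-retrieval area up to the 50th false positive
#'
#' Predictions are walked in decreasing score order; the area under the
#' true-positive vs. false-positive step curve is accumulated until `fpCap`
#' false positives have been seen and normalized by `fpCap * n_pos`, so a
#' ranking that places every positive above all counted negatives scores 1
#' and one whose positives all trail the first `fpCap` negatives scores 0.
#' Tied score groups advance diagonally: each counted negative in a tie group
#' credits half of the group's positives. When fewer than `fpCap` negatives
#' exist the cap is the number of negatives (making ROC50 equal ROC).
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector, same length.
#' @param fpCap number of false positives after which accumulation stops.
#' @return ROC50 score in [0, 1].
#' @export
roc50Score <- function(labels, scores, fpCap = 50L) {
    .checkPreds(labels, scores, needNeg = FALSE)
    if (sum(labels == 0) < 1L)
        stop("need at least one negative")
    cap <- min(as.integer(fpCap), sum(labels == 0))
    ## per counted negative: positives strictly above + half the tied ones
    ord <- order(scores, decreasing = TRUE)
    lab <- labels[ord]; sc <- scores[ord]
    nPos <- sum(lab == 1)
    grp <- cumsum(!duplicated(sc))                 # tie-group index, sorted
    posIn <- tapply(lab == 1, grp, sum)
    negIn <- tapply(lab == 0, grp, sum)
    posAbove <- cumsum(c(0, head(posIn, -1L)))
    area <- 0; fp <- 0L
    for (k in seq_along(posIn)) {
        if (negIn[k] == 0L) next
        take <- min(negIn[k], cap - fp)
        area <- area + take * (posAbove[k] + posIn[k] / 2)
        fp <- fp + take
        if (fp >= cap) break
    }
    as.numeric(area) / (cap * nPos)
}

.checkPreds <- function(labels, scores, needNeg = TRUE) {
    if (length(labels) != length(scores))
        stop("labels and scores must have the same length")
    if (!all(labels %in% c(0, 1)))
        stop("labels must be 0/1")
    if (any(!is.finite(scores)))
        stop("scores must be finite")
    if (sum(labels == 1) < 1L)
        stop("need at least one positive")
    if (needNeg && sum(labels == 0) < 1L)
        stop("need at least one negative")
    invisible(TRUE)
}

#' Evaluate a scored prediction set
#'
#' @param labels 0/1 vector.
#' @param scores numeric vector, same length.
#' @param fpCap false-positive cap for the ROC50 component.
#' @return an [ROCResult].
#' @export
evaluateScores <- function(labels, scores, fpCap = 50L) {
    new("ROCResult", roc = rocScore(labels, scores),
        roc50 = roc50Score(labels, scores, fpCap),
        nPos = as.integer(sum(labels == 1)),
        nNeg = as.integer(sum(labels == 0)))
}

#' Mean ROC / ROC50 across families
#'
#' Unweighted arithmetic means of the per-family results, the summary used to
#' compare methods across a family-holdout benchmark.
#'
#' @param results list of [ROCResult] (one per target family).
#' @return named numeric vector `c(meanROC, meanROC50)`.
#' @export
meanScores <- function(results) {
    if (length(results) == 0L) stop("empty result list")
    stopifnot(all(vapply(results, is, logical(1L), "ROCResult")))
    c(meanROC = mean(vapply(results, rocValue, numeric(1L))),
      meanROC50 = mean(vapply(results, roc50Value, numeric(1L))))
}

#' Paired t-test between two methods' per-family scores
#'
#' Tests the per-family differences a - b; two-sided by default, with a
#' one-sided option for directional comparisons.
#'
#' @param a,b numeric vectors of per-family scores, paired by family.
#' @param alternative "two.sided" (default), "greater" or "less".
#' @return list with `statistic`, `pValue`, `meanDifference`, `df`.
#' @export
pairedTTest <- function(a, b, alternative = c("two.sided", "greater", "less")) {
    alternative <- match.arg(alternative)
    if (length(a) != length(b))
        stop("score vectors must be paired (equal length)")
    if (length(a) < 2L)
        stop("need at least two pairs")
    d <- a - b
    if (stats::sd(d) == 0)
        stop("degenerate comparison: all per-family differences are equal")
    tt <- stats::t.test(a, b, paired = TRUE, alternative = alternative)
    list(statistic = unname(tt$statistic), pValue = tt$p.value,
         meanDifference = unname(tt$estimate), df = unname(tt$parameter))
}

#' Read / write scored predictions
#'
#' Three-column TSV: `sample_id`, `label`, `score`.
#'
#' @param scores data.frame with columns sample_id, label, score.
#' @param path file path.
#' @param meta optional named list (e.g. config hash and seed) written as
#'   leading `# key=value` comment lines so every artifact records its
#'   provenance.
#' @return `writeScoresTSV()` returns `path` invisibly; `readScoresTSV()`
#'   the data.frame.
#' @export
writeScoresTSV <- function(scores, path, meta = NULL) {
    stopifnot(all(c("sample_id", "label", "score") %in% names(scores)))
    con <- file(path, "w")
    on.exit(close(con))
    if (!is.null(meta))
        writeLines(sprintf("# %s=%s", names(meta),
                           vapply(meta, as.character, character(1L))), con)
    utils::write.table(
        data.frame(sample_id = scores$sample_id,
                   label = scores$label,
                   score = sprintf("%.12g", scores$score)),
        con, sep = "\t", quote = FALSE, row.names = FALSE)
    invisible(path)
}

#' @rdname writeScoresTSV
#' @export
readScoresTSV <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                            colClasses = c("character", "integer", "numeric"))
    stopifnot(all(c("sample_id", "label", "score") %in% names(df)))
    df
}
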