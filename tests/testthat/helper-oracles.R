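# Independent reference implementations and small fixture builders used
# across the suite.

# Exhaustive pairwise ROC: credit 1 per correctly ordered (pos, neg) pair,
# 0.5 per tie.
oracleROC <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    tot <- 0
    for (p in pos)
        for (n in neg)
            tot <- tot + (p > n) + 0.5 * (p == n)
    tot / (length(pos) * length(neg))
}

# Prefix-walk ROC50: each of the cap highest-scoring negatives credits the
# positives ranked strictly above it plus half of the tied ones.
oracleROC50 <- function(labels, scores, cap = 50L) {
    negScores <- sort(scores[labels == 0], decreasing = TRUE)
    m <- min(cap, length(negScores))
    pos <- scores[labels == 1]
    tot <- 0
    for (j in seq_len(m))
        tot <- tot + sum(pos > negScores[j]) + 0.5 * sum(pos == negScores[j])
    tot / (m * length(pos))
}

randomPredictions <- function(n, nPos, tied = FALSE) {
    labels <- sample(rep(c(1, 0), c(nPos, n - nPos)))
    scores <- if (tied) sample(seq_len(max(2L, n %/% 4)), n, replace = TRUE)
              else stats::rnorm(n)
    list(labels = labels, scores = scores)
}

# random one-hot encoded sample with given dimensions
randomSample <- function(Tn, D, id = "s") {
    mat <- matrix(0, Tn, D)
    for (t in seq_len(Tn)) {
        blockStarts <- seq(1L, D, by = 20L)
        on <- blockStarts + sample.int(20L, length(blockStarts)) - 1L
        mat[t, on] <- 1
    }
    new("EncodedSample", id = id, mat = mat, mask = rep(1L, Tn))
}

# small random model parameter list (plain list form used by the internals)
randomParams <- function(D, C, Tn, sd = 0.3) {
    gate <- function() {
        out <- list()
        for (g in c("i", "f", "o", "g")) {
            out[[paste0("W", g)]] <- matrix(stats::rnorm(D * C, sd = sd), D, C)
            out[[paste0("U", g)]] <- matrix(stats::rnorm(C * C, sd = sd), C, C)
            out[[paste0("b", g)]] <- stats::rnorm(C, sd = sd)
        }
        out
    }
    list(forward = gate(), backward = gate(),
         tdd = list(w = stats::rnorm(2 * C, sd = sd), b = stats::rnorm(1)),
         output = list(w = stats::rnorm(Tn, sd = sd), b = stats::rnorm(1)))
}

# random label hierarchy (sizes drawn, no sequences) for split property tests
randomHierarchyLabels <- function() {
    nSf <- sample(2:5, 1L)
    ids <- character(); fams <- character(); sfs <- character()
    for (s in seq_len(nSf)) {
        sfId <- sprintf("sf%02d", s)
        for (f in seq_len(sample(1:4, 1L))) {
            famId <- sprintf("%s.f%02d", sfId, f)
            for (p in seq_len(sample(2:6, 1L))) {
                ids <- c(ids, sprintf("%s.p%02d", famId, p))
                fams <- c(fams, famId); sfs <- c(sfs, sfId)
            }
        }
    }
    data.frame(id = ids, family = fams, superfamily = sfs,
               stringsAsFactors = FALSE)
}

# vectorized variants of the same oracles (outer products instead of loops),
# used where thousands of instances are checked
oracleROCouter <- function(labels, scores) {
    pos <- scores[labels == 1]
    neg <- scores[labels == 0]
    mean(outer(pos, neg, ">") + 0.5 * outer(pos, neg, "=="))
}

oracleROC50outer <- function(labels, scores, cap = 50L) {
    negScores <- sort(scores[labels == 0], decreasing = TRUE)
    m <- min(cap, length(negScores))
    pos <- scores[labels == 1]
    top <- negScores[seq_len(m)]
    sum(outer(pos, top, ">") + 0.5 * outer(pos, top, "==")) /
        (m * length(pos))
}
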