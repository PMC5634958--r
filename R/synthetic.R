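#' Planted-motif synthetic benchmark specification
#'
#' Defines a SCOP-like two-level label hierarchy with learnable sequence
#' signal: every superfamily carries a distinct ungapped motif present (with
#' point mutations) in all of its members, and every family adds a shorter
#' family sub-motif, both inserted at random non-overlapping positions in
#' i.i.d. background sequence.
#'
#' @param nSuperfamilies,familiesPerSuperfamily,proteinsPerFamily hierarchy
#'   sizes.
#' @param lengthRange integer (min, max) sequence lengths, drawn uniformly.
#' @param motifLength superfamily motif length; the family sub-motif is half
#'   as long (rounded up).
#' @param mutationRate per-position probability that a planted motif copy is
#'   point-mutated.
#' @param background amino-acid frequencies (20 values summing to 1) over the
#'   one-hot alphabet; default uniform.
#' @param seed integer; generation is fully deterministic given the spec.
#' @return a [SyntheticSpec].
#' @export
syntheticSpec <- function(nSuperfamilies = 2L, familiesPerSuperfamily = 2L,
                          proteinsPerFamily = 25L, lengthRange = c(80L, 120L),
                          motifLength = 10L, mutationRate = 0.1,
                          background = rep(1 / 20, 20L), seed = 1L) {
    new("SyntheticSpec", nSuperfamilies = as.integer(nSuperfamilies),
        familiesPerSuperfamily = as.integer(familiesPerSuperfamily),
        proteinsPerFamily = as.integer(proteinsPerFamily),
        lengthRange = as.integer(lengthRange),
        motifLength = as.integer(motifLength), mutationRate = mutationRate,
        background = background, seed = as.integer(seed))
}

#' Robinson-Robinson-style background frequencies
#'
#' A fixed non-uniform amino-acid composition (ordered by the one-hot
#' alphabet) for generators that should not use a uniform background.
#'
#' @return numeric vector of 20 frequencies summing to 1.
#' @export
aaBackgroundFrequencies <- function() {
    f <- c(A = 0.0780, C = 0.0192, D = 0.0536, E = 0.0629, F = 0.0387,
           G = 0.0738, H = 0.0219, I = 0.0514, K = 0.0572, L = 0.0901,
           M = 0.0224, N = 0.0448, P = 0.0520, Q = 0.0426, R = 0.0512,
           S = 0.0712, T = 0.0584, V = 0.0644, W = 0.0132, Y = 0.0330)
    f / sum(f)
}

.randomSeq <- function(n, background) {
    paste(sample(.AA20, n, replace = TRUE, prob = background), collapse = "")
}

.mutateMotif <- function(motif, rate) {
    if (rate <= 0) return(motif)
    letters <- strsplit(motif, "", fixed = TRUE)[[1L]]
    hit <- runif(length(letters)) < rate
    if (any(hit))
        letters[hit] <- vapply(letters[hit], function(a)
            sample(setdiff(.AA20, a), 1L), character(1L))
    paste(letters, collapse = "")
}

#' Generate a planted-motif protein hierarchy
#'
#' @param spec a [SyntheticSpec].
#' @return list with `labels` (data.frame id/family/superfamily), `sequences`
#'   (named character vector) and `motifs` (per-superfamily and per-family
#'   motif strings, for oracle detectors).
#' @export
generateHierarchy <- function(spec = syntheticSpec()) {
    stopifnot(is(spec, "SyntheticSpec"))
    set.seed(spec@seed)
    famMotifLen <- as.integer(ceiling(spec@motifLength / 2))
    sfMotifs <- character(); famMotifs <- character()
    ids <- character(); fams <- character(); sfs <- character()
    seqs <- character()
    for (s in seq_len(spec@nSuperfamilies)) {
        sfId <- sprintf("sf%02d", s)
        sfMotifs[sfId] <- .randomSeq(spec@motifLength, spec@background)
        for (f in seq_len(spec@familiesPerSuperfamily)) {
            famId <- sprintf("%s.f%02d", sfId, f)
            famMotifs[famId] <- .randomSeq(famMotifLen, spec@background)
            for (p in seq_len(spec@proteinsPerFamily)) {
                id <- sprintf("%s.p%03d", famId, p)
                len <- sample(seq(spec@lengthRange[1L], spec@lengthRange[2L]),
                              1L)
                sq <- .plantMotifs(len, sfMotifs[sfId], famMotifs[famId],
                                   spec)
                ids <- c(ids, id); fams <- c(fams, famId)
                sfs <- c(sfs, sfId); seqs <- c(seqs, sq)
            }
        }
    }
    names(seqs) <- ids
    list(labels = data.frame(id = ids, family = fams, superfamily = sfs,
                             stringsAsFactors = FALSE),
         sequences = seqs,
         motifs = list(superfamily = sfMotifs, family = famMotifs))
}

## place the (mutated) superfamily motif and family sub-motif at random
## non-overlapping positions inside a background sequence of length len
.plantMotifs <- function(len, sfMotif, famMotif, spec) {
    sq <- strsplit(.randomSeq(len, spec@background), "", fixed = TRUE)[[1L]]
    m1 <- .mutateMotif(sfMotif, spec@mutationRate)
    m2 <- .mutateMotif(famMotif, spec@mutationRate)
    l1 <- nchar(m1); l2 <- nchar(m2)
    ## split the sequence in two blocks: motif 1 in the first, motif 2 in the
    ## second, so the copies can never overlap
    cut <- l1 + sample.int(len - l1 - l2 + 1L, 1L) - 1L
    p1 <- sample.int(cut - l1 + 1L, 1L)
    p2 <- cut + sample.int(len - cut - l2 + 1L, 1L)
    sq[p1:(p1 + l1 - 1L)] <- strsplit(m1, "", fixed = TRUE)[[1L]]
    sq[p2:(p2 + l2 - 1L)] <- strsplit(m2, "", fixed = TRUE)[[1L]]
    paste(sq, collapse = "")
}

#' Write the synthetic benchmark to disk
#'
#' Emits the FASTA, label TSV and (optionally) one PSSM file per protein, the
#' exact inputs the rest of the pipeline consumes.
#'
#' @param spec a [SyntheticSpec].
#' @param dir output directory (created if missing).
#' @param pssm generate per-protein PSSM files under `dir/pssm/`?
#' @param conservation PSSM conservation level passed to [generatePSSM()].
#' @return list with paths `fasta`, `labels`, `pssmDir` (NULL if `pssm` is
#'   FALSE) and the in-memory hierarchy.
#' @export
writeSyntheticBenchmark <- function(spec = syntheticSpec(), dir,
                                    pssm = TRUE, conservation = 1) {
    hier <- generateHierarchy(spec)
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    fasta <- file.path(dir, "proteins.fasta")
    writeFasta(hier$sequences, fasta)
    labPath <- file.path(dir, "labels.tsv")
    utils::write.table(hier$labels, labPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    pssmDir <- NULL
    if (pssm) {
        pssmDir <- file.path(dir, "pssm")
        dir.create(pssmDir, showWarnings = FALSE)
        for (i in seq_along(hier$sequences))
            generatePSSM(hier$sequences[i], conservation = conservation,
                         seed = spec@seed + i,
                         path = file.path(pssmDir,
                                          paste0(names(hier$sequences)[i],
                                                 ".pssm")))
    }
    list(fasta = fasta, labels = labPath, pssmDir = pssmDir, hierarchy = hier)
}

#' Generate a synthetic PSI-BLAST ASCII PSSM for a sequence
#'
#' Writes a syntactically valid `-out_ascii_pssm`-style file. Per row, a
#' target residue (the query residue with probability `conservation`, else a
#' random other letter) receives a high log-odds score (8..12) while all
#' other letters receive low scores (-10..4), so the row argmax equals the
#' target. Percentage and statistics columns are filled with plausible
#' values; the parser ignores them.
#'
#' @param seq residue string (optionally named with the protein id).
#' @param conservation probability in [0, 1] that a row's argmax is the query
#'   residue.
#' @param seed integer seed.
#' @param path output file path; if `NULL` a tempfile is used.
#' @return the written [PSSMProfile], invisibly, with the path in attribute
#'   `path`.
#' @export
generatePSSM <- function(seq, conservation = 1, seed = 1L, path = NULL) {
    stopifnot(conservation >= 0, conservation <= 1)
    res <- strsplit(toupper(seq[[1L]]), "", fixed = TRUE)[[1L]]
    set.seed(seed)
    l <- length(res)
    scores <- matrix(sample(-10:4, l * 20L, replace = TRUE), l, 20L,
                     dimnames = list(NULL, .PSSM_COLS))
    for (i in seq_len(l)) {
        q <- res[i]
        ## wildcard query rows keep a random standard target
        pool <- if (q %in% .PSSM_COLS) q else sample(.PSSM_COLS, 1L)
        target <- if (runif(1L) <= conservation) pool
                  else sample(setdiff(.PSSM_COLS, pool), 1L)
        scores[i, target] <- sample(8:12, 1L)
    }
    if (is.null(path)) path <- tempfile(fileext = ".pssm")
    .writePSSMFile(res, scores, path)
    prof <- new("PSSMProfile", query = paste(res, collapse = ""),
                scores = scores)
    attr(prof, "path") <- path
    invisible(prof)
}

.writePSSMFile <- function(res, scores, path) {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("",
                 "Last position-specific scoring matrix computed, weighted observed percentages rounded down, information per position, and relative weight of gapless real matches to pseudocounts"),
               con)
    writeLines(paste0("           ",
                      paste(sprintf("%3s", c(.PSSM_COLS, .PSSM_COLS)),
                            collapse = " ")), con)
    for (i in seq_along(res)) {
        pct <- as.integer(round(100 * (scores[i, ] - min(scores[i, ])) /
                                    max(1, diff(range(scores[i, ])))))
        writeLines(paste0(sprintf("%5d %s ", i, res[i]),
                          paste(sprintf("%3d", scores[i, ]), collapse = " "),
                          " ",
                          paste(sprintf("%3d", pct), collapse = " "),
                          sprintf("  %4.2f %8.2f", 0.35, 0.12)), con)
    }
    writeLines(c("", "                      K         Lambda",
                 "Standard Ungapped    0.1347     0.3179"), con)
    invisible(path)
}

#' Exact motif-scan oracle detector
#'
#' Scores each sequence by the best (lowest) Hamming distance of any window
#' to the given motif, negated so higher = better match. With mutation rate 0
#' this detector separates a superfamily perfectly, guaranteeing that the
#' generated data carry learnable signal.
#'
#' @param sequences named character vector.
#' @param motif motif string.
#' @return named numeric scores.
#' @export
motifOracleScores <- function(sequences, motif) {
    m <- strsplit(motif, "", fixed = TRUE)[[1L]]
    vapply(sequences, function(sq) {
        s <- strsplit(sq, "", fixed = TRUE)[[1L]]
        n <- length(s) - length(m) + 1L
        if (n < 1L) return(-length(m))
        best <- length(m)
        for (i in seq_len(n))
            best <- min(best, sum(s[i:(i + length(m) - 1L)] != m))
        -best
    }, numeric(1L))
}
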