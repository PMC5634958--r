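test_that("readFasta parses, normalizes and round-trips records", {
    fa <- withr::local_tempfile(fileext = ".fasta")
    writeLines(c(">p1", "ACDEF", ">p2 some description", "acd"), fa)
    seqs <- readFasta(fa)
    expect_identical(seqs, c(p1 = "ACDEF", p2 = "ACD"))

    ## stop characters are stripped
    writeLines(c(">p1", "ACD*"), fa)
    expect_identical(unname(readFasta(fa)), "ACD")

    ## write/read round trip on random records
    set.seed(42)
    aa <- sort(c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V"))
    rnd <- vapply(1:100, function(i)
        paste(sample(aa, sample(30:90, 1L), replace = TRUE), collapse = ""),
        character(1L))
    names(rnd) <- sprintf("prot%03d", 1:100)
    writeFasta(rnd, fa)
    back <- readFasta(fa)
    expect_identical(back, rnd)
})

test_that("readFasta rejects empty files and empty records", {
    fa <- withr::local_tempfile(fileext = ".fasta")
    writeLines(character(), fa)
    expect_error(readFasta(fa), "no records")
    writeLines(c(">ok", "ACD", ">empty1", ">alsoempty", ""), fa)
    expect_error(readFasta(fa), "empty1")
})

test_that("parsePSSM recovers the exact log-odds block from a fixture", {
    prof <- generatePSSM(c(q1 = "ACD"), conservation = 1, seed = 5)
    parsed <- parsePSSM(attr(prof, "path"))
    expect_identical(queryResidues(parsed), "ACD")
    expect_identical(dim(pssmScores(parsed)), c(3L, 20L))
    expect_identical(unname(pssmScores(parsed)), unname(pssmScores(prof)))
})

test_that("parsePSSM errors name the malformed position", {
    prof <- generatePSSM(c(q1 = "ACDEF"), conservation = 1, seed = 2)
    lines <- readLines(attr(prof, "path"))
    ## drop one score field from the row of position 3 (header is 3 lines)
    tok <- strsplit(trimws(lines[6]), "\\s+")[[1L]]
    lines[6] <- paste(tok[-5L], collapse = " ")
    bad <- withr::local_tempfile(fileext = ".pssm")
    writeLines(lines, bad)
    expect_error(parsePSSM(bad), "position 3")

    ## truncated: header only
    writeLines(readLines(attr(prof, "path"))[1:3], bad)
    expect_error(parsePSSM(bad), "truncated")
})

test_that("pseudoProtein takes the per-position argmax with documented ties", {
    ## unique maximum at K in every row
    sc <- matrix(-3L, 4L, 20L,
                 dimnames = list(NULL, profileBLSTM:::.PSSM_COLS))
    sc[, "K"] <- 7L
    prof <- new("PSSMProfile", query = "ACDE", scores = sc)
    expect_identical(residues(pseudoProtein(c(x = "ACDE"), prof)), "KKKK")

    ## all-equal row falls back to the original query residue
    flat <- new("PSSMProfile", query = "WCD",
                scores = matrix(0L, 3L, 20L,
                                dimnames = list(NULL,
                                                profileBLSTM:::.PSSM_COLS)))
    expect_identical(residues(pseudoProtein(c(x = "WCD"), flat)), "WCD")

    ## tie not containing the query: alphabetically first tied letter
    sc2 <- matrix(0L, 1L, 20L, dimnames = list(NULL, profileBLSTM:::.PSSM_COLS))
    sc2[, c("Y", "D")] <- 5L
    expect_identical(residues(pseudoProtein(c(x = "A"),
                                            new("PSSMProfile", query = "A",
                                                scores = sc2))), "D")

    ## length mismatch names both lengths
    expect_error(pseudoProtein(c(x = "ACDEF"), prof), "4.*5|5.*4")

    ## passthrough keeps wildcards and is flagged as such
    pp <- pseudoProtein(c(x = "ACXBD"))
    expect_identical(pp@source, "passthrough")
    expect_identical(residues(pp), "ACXBD")
})

test_that("pseudo proteins preserve length, alphabet and determinism", {
    set.seed(7)
    for (i in 1:10) {
        l <- sample(5:40, 1L)
        q <- paste(sample(profileBLSTM:::.AA20, l, TRUE), collapse = "")
        prof <- generatePSSM(q, conservation = 0.5, seed = i)
        a <- pseudoProtein(q, prof)
        b <- pseudoProtein(q, prof)
        expect_identical(a, b)
        expect_identical(nchar(residues(a)), l)
        expect_true(all(strsplit(residues(a), "")[[1L]] %in%
                        profileBLSTM:::.AA20))
    }
})

test_that("label tables are validated", {
    tsv <- withr::local_tempfile(fileext = ".tsv")
    writeLines(c("id\tfamily\tsuperfamily", "p1\tf1\tsf1", "p2\tf1\tsf1",
                 "p3\tf2\tsf1"), tsv)
    df <- readLabelTable(tsv)
    expect_identical(nrow(df), 3L)
    writeLines(c("id\tfamily\tsuperfamily", "p1\tf1\tsf1", "p1\tf2\tsf2"), tsv)
    expect_error(readLabelTable(tsv), "duplicate")
    writeLines(c("id\tfamily\tsuperfamily", "p1\tf1\tsf1", "p2\tf1\tsf2"), tsv)
    expect_error(readLabelTable(tsv), "more than one superfamily")
})
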