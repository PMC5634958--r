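#' Read protein sequences from a FASTA file
#'
#' Records are returned in file order with residues uppercased and stop
#' characters (`*`) stripped. Both wrapped and single-line FASTA are accepted.
#'
#' @param path path to a FASTA file.
#' @return a named character vector of residue strings (names are record ids,
#'   the first whitespace-delimited token of each header).
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "ACDEF", ">p2", "acd"), fa)
#' readFasta(fa)
#' @export
readFasta <- function(path) {
    if (!file.exists(path))
        stop("FASTA file not found: ", path)
    ## read through BStringSet so lowercase and '*' survive until normalization
    set <- Biostrings::readBStringSet(path)
    if (length(set) == 0L)
        stop("no records in FASTA file: ", path)
    ids <- sub("\\s.*$", "", names(set))
    seqs <- toupper(gsub("*", "", as.character(set), fixed = TRUE))
    empty <- !nzchar(seqs)
    if (any(empty))
        stop("FASTA record(s) with empty sequence: ",
             paste(ids[empty], collapse = ", "))
    bad <- !grepl(paste0("^[", paste(c(.AA20, .AA_WILDCARDS), collapse = ""),
                         "]+$"), seqs)
    if (any(bad))
        stop("FASTA record(s) with non-amino-acid characters: ",
             paste(ids[bad], collapse = ", "))
    names(seqs) <- ids
    seqs
}

#' Write protein sequences to a FASTA file
#'
#' @param seqs named character vector of residue strings.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeFasta <- function(seqs, path) {
    stopifnot(!is.null(names(seqs)), all(nzchar(names(seqs))))
    set <- Biostrings::BStringSet(seqs)
    Biostrings::writeXStringSet(set, path, width = 70L)
    invisible(path)
}

#' Parse a PSI-BLAST ASCII position-specific scoring matrix
#'
#' Reads the `-out_ascii_pssm` dialect: three header lines (blank, title, the
#' 40-letter column header), then one row per query position holding the
#' position index, the query residue, 20 integer log-odds scores, 20 weighted
#' percentage columns and two trailing statistics. Only the log-odds block and
#' the query residues are retained.
#'
#' @param path path to a PSSM file.
#' @return a [PSSMProfile].
#' @export
parsePSSM <- function(path) {
    if (!file.exists(path))
        stop("PSSM file not found: ", path)
    lines <- readLines(path, warn = FALSE)
    ## locate the column-header line: 40 single-letter tokens
    hdr <- 0L
    for (i in seq_along(lines)) {
        tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
        if (length(tok) == 40L && all(nchar(tok) == 1L)) { hdr <- i; break }
    }
    if (hdr == 0L)
        stop("truncated or malformed PSSM file (no column header): ", path)
    if (!identical(strsplit(trimws(lines[hdr]), "\\s+")[[1L]][1:20], .PSSM_COLS))
        stop("unexpected amino-acid column order in PSSM header: ", path)
    if (hdr >= length(lines))
        stop("truncated PSSM file (no score rows): ", path)
    rows <- list(); resid <- character()
    pos <- 0L
    for (i in (hdr + 1L):length(lines)) {
        ln <- trimws(lines[i])
        if (!nzchar(ln)) break                    # footer starts
        tok <- strsplit(ln, "\\s+")[[1L]]
        pos <- pos + 1L
        if (length(tok) != 44L)
            stop(sprintf("malformed PSSM row at position %d (%d fields, expected 44)",
                         pos, length(tok)))
        idx <- suppressWarnings(as.integer(tok[1L]))
        if (is.na(idx) || idx != pos)
            stop(sprintf("PSSM row index mismatch at position %d", pos))
        sc <- suppressWarnings(as.integer(tok[3:22]))
        if (anyNA(sc))
            stop(sprintf("non-integer log-odds score in PSSM row at position %d", pos))
        rows[[pos]] <- sc
        resid[pos] <- toupper(tok[2L])
    }
    if (pos == 0L)
        stop("truncated PSSM file (no score rows): ", path)
    scores <- do.call(rbind, rows)
    colnames(scores) <- .PSSM_COLS
    new("PSSMProfile", query = paste(resid, collapse = ""), scores = scores)
}

#' Convert a protein into its pseudo protein
#'
#' With a profile, position i receives the amino acid whose log-odds score in
#' row i is maximal ("most favoured residue"); ties are broken in favour of
#' the original query residue if it is among the tied letters, otherwise the
#' alphabetically first tied letter. Without a profile the sequence passes
#' through unchanged (wildcards retained; they later one-hot encode to zero
#' vectors).
#'
#' @param seq residue string (or a single named element of [readFasta()]
#'   output).
#' @param profile a [PSSMProfile] for this sequence, or `NULL`.
#' @param id sample identifier; defaults to `names(seq)`.
#' @return a [PseudoProtein].
#' @examples
#' pp <- pseudoProtein(c(p1 = "ACDEF"))
#' residues(pp)
#' @export
pseudoProtein <- function(seq, profile = NULL, id = names(seq)) {
    stopifnot(is.character(seq), length(seq) == 1L)
    if (is.null(id) || !nzchar(id)) id <- "query"
    res <- toupper(seq[[1L]])
    if (is.null(profile))
        return(new("PseudoProtein", id = id, residues = res,
                   source = "passthrough"))
    stopifnot(is(profile, "PSSMProfile"))
    l <- nchar(res)
    if (nrow(profile@scores) != l)
        stop(sprintf("profile length (%d) does not match sequence length (%d)",
                     nrow(profile@scores), l))
    letters <- strsplit(res, "", fixed = TRUE)[[1L]]
    out <- character(l)
    for (i in seq_len(l)) {
        row <- profile@scores[i, ]
        tied <- .PSSM_COLS[row == max(row)]
        out[i] <- if (letters[i] %in% tied) letters[i] else sort(tied)[1L]
    }
    new("PseudoProtein", id = id, residues = paste(out, collapse = ""),
        source = "from_pssm")
}

#' Read a protein label table
#'
#' Tab-separated file with columns `id`, `family`, `superfamily`; one row per
#' protein. Ids must be unique and every family must sit inside exactly one
#' superfamily.
#'
#' @param path path to the TSV.
#' @return a data.frame with character columns id, family, superfamily.
#' @export
readLabelTable <- function(path) {
    df <- utils::read.delim(path, header = TRUE, sep = "\t",
                            colClasses = "character")
    .validateLabelTable(df)
}

.validateLabelTable <- function(df) {
    need <- c("id", "family", "superfamily")
    if (!all(need %in% names(df)))
        stop("label table must have columns: ", paste(need, collapse = ", "))
    df <- df[, need]
    if (anyDuplicated(df$id))
        stop("duplicate protein ids in label table")
    fam2sf <- unique(df[, c("family", "superfamily")])
    if (anyDuplicated(fam2sf$family))
        stop("a family maps to more than one superfamily")
    df
}
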