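#' Fix a pseudo protein to the encoder's reference length
#'
#' Sequences longer than `fixedLength` are truncated at the C-terminus;
#' shorter sequences are padded at the C-terminus with the padding symbol
#' `-`, which one-hot encodes to the all-zero vector. The N-terminus, read
#' first by the forward LSTM, is always preserved.
#'
#' @param p a [PseudoProtein] (or bare residue string).
#' @param cfg an [EncoderConfig].
#' @return a [PseudoProtein] of length exactly `cfg@fixedLength`, with the
#'   original (unpadded) length in attribute `realLength` of its residues
#'   slot kept implicit via [encodeWindows()]'s mask.
#' @export
fixLength <- function(p, cfg = encoderConfig()) {
    if (is.character(p)) p <- pseudoProtein(p, id = names(p))
    stopifnot(is(p, "PseudoProtein"), is(cfg, "EncoderConfig"))
    L <- cfg@fixedLength
    res <- p@residues
    if (!nzchar(res)) stop("cannot length-fix an empty sequence")
    if (nchar(res) > L) {
        res <- substr(res, 1L, L)
    } else if (nchar(res) < L) {
        res <- paste0(res, strrep(.AA_PAD, L - nchar(res)))
    }
    out <- new("PseudoProtein", id = p@id, residues = res, source = p@source)
    attr(out, "realLength") <- min(nchar(p@residues), L)
    out
}

#' One-hot encode a single residue
#'
#' Standard amino acids map to a 20-vector with a single 1 at their alphabet
#' index; wildcards (X, B, Z, U, J, O) and the padding symbol map to the
#' all-zero vector, contributing no input signal.
#'
#' @param r a single residue character.
#' @param cfg an [EncoderConfig].
#' @return binary numeric vector of length 20.
#' @export
oneHotResidue <- function(r, cfg = encoderConfig()) {
    stopifnot(is.character(r), nchar(r) == 1L)
    v <- numeric(20L)
    j <- match(toupper(r), cfg@alphabet)
    if (!is.na(j)) v[j] <- 1
    v
}

#' Encode a length-fixed pseudo protein as a windowed one-hot matrix
#'
#' Row t (t = 1..T, stride 1, T = L - w + 1) concatenates the one-hot vectors
#' of residues t..t+w-1. The mask marks windows lying entirely within the
#' unpadded prefix; it is stored for analysis but no time step is skipped.
#'
#' @param p a [PseudoProtein] of length exactly `cfg@fixedLength` (see
#'   [fixLength()]).
#' @param cfg an [EncoderConfig].
#' @return an [EncodedSample] with a T x 20w binary matrix.
#' @export
encodeWindows <- function(p, cfg = encoderConfig()) {
    stopifnot(is(p, "PseudoProtein"), is(cfg, "EncoderConfig"))
    L <- cfg@fixedLength; w <- cfg@window
    if (nchar(p@residues) != L)
        stop(sprintf("sequence length %d != fixedLength %d; apply fixLength() first",
                     nchar(p@residues), L))
    Tn <- L - w + 1L
    letters <- strsplit(p@residues, "", fixed = TRUE)[[1L]]
    idx <- match(letters, cfg@alphabet)          # NA for wildcard / padding
    ## residue-level one-hot, L x 20
    oh <- matrix(0, nrow = L, ncol = 20L)
    hit <- which(!is.na(idx))
    oh[cbind(hit, idx[hit])] <- 1
    mat <- matrix(0, nrow = Tn, ncol = 20L * w)
    for (k in seq_len(w))
        mat[, (k - 1L) * 20L + seq_len(20L)] <- oh[(k:(k + Tn - 1L)), , drop = FALSE]
    realLen <- attr(p, "realLength")
    if (is.null(realLen)) {
        pad <- regexpr(paste0("\\", .AA_PAD, "+$"), p@residues)
        realLen <- if (pad > 0L) pad - 1L else L
    }
    mask <- as.integer(seq_len(Tn) + w - 1L <= realLen)
    new("EncodedSample", id = p@id, mat = mat, mask = mask)
}

#' Full encoding pipeline for one protein
#'
#' Convenience wrapper: pseudo-protein conversion (optional), length fixing,
#' and window encoding.
#'
#' @param seq residue string (optionally named with the sample id).
#' @param profile a [PSSMProfile] or `NULL` for passthrough.
#' @param cfg an [EncoderConfig].
#' @param id sample id; defaults to `names(seq)`.
#' @return an [EncodedSample].
#' @export
encodeProtein <- function(seq, profile = NULL, cfg = encoderConfig(),
                          id = names(seq)) {
    encodeWindows(fixLength(pseudoProtein(seq, profile, id = id), cfg), cfg)
}
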