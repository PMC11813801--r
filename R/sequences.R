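#' Sequence sets
#'
#' A `sequence_set` is an ordered, named character vector of uppercase
#' DNA sequences over the alphabet A, C, G, T, N with a `label`
#' attribute recording its role in the analysis (`"positive"` for
#' ChIP-seq peaks, `"negative"` for background sequences, `"promoter"`
#' for the threshold-calibration set).  Order is significant: recognition
#' profiles are index-aligned to it.
#'
#' @param seqs character vector of sequences; names are the sequence ids.
#' @param label optional role label, one of `"positive"`, `"negative"`,
#'   `"promoter"` (free-form labels are tolerated).
#' @return an object of class `sequence_set`.
#' @export
sequence_set <- function(seqs, label = NULL) {
  ids <- names(seqs)
  seqs <- as.character(seqs)
  names(seqs) <- ids
  if (is.null(ids) || any(!nzchar(ids)))
    stop("every sequence needs a non-empty id")
  dup <- ids[duplicated(ids)]
  if (length(dup))
    stop("duplicate sequence id: ", dup[[1L]])
  if (length(seqs) < 1L)
    stop("no sequences")
  if (any(nchar(seqs) < 1L))
    stop("zero-length sequence: ", ids[nchar(seqs) < 1L][[1L]])
  seqs <- normalize_dna(seqs)
  structure(seqs, label = label, class = "sequence_set")
}

# Uppercase, U->T, anything outside {A,C,G,T,N} -> N.  Reports how many
# characters were masked (peaks genuinely contain such characters; they
# are unscoreable, not an error).
normalize_dna <- function(seqs) {
  up <- chartr("u", "T", toupper(seqs))
  up <- chartr("U", "T", up)
  masked <- gsub("[^ACGTN]", "N", up)
  n_bad <- sum(vapply(seq_along(up), function(i) {
    sum(charToRaw(up[[i]]) != charToRaw(masked[[i]]))
  }, integer(1)))
  if (n_bad > 0L)
    message(n_bad, " non-ACGTN character(s) masked to N")
  masked
}

#' @export
print.sequence_set <- function(x, ...) {
  lab <- attr(x, "label")
  cat("sequence_set of ", length(x), " sequence(s)",
      if (!is.null(lab)) paste0(" [", lab, "]"), "\n", sep = "")
  cat("  lengths: ", min(nchar(x)), "-", max(nchar(x)), " bp\n", sep = "")
  invisible(x)
}

#' @export
`[.sequence_set` <- function(x, i) {
  structure(unclass(x)[i], label = attr(x, "label"), class = "sequence_set")
}

#' Read a FASTA file into a sequence set
#'
#' Sequences are uppercased, U is mapped to T, and any character outside
#' A, C, G, T, N is masked to N (with a message giving the count).  The
#' id of each record is the first whitespace-delimited token of its
#' header line.
#'
#' @param path path to a FASTA file.
#' @param label optional role label (see [sequence_set()]).
#' @return a [sequence_set()].
#' @export
read_fasta <- function(path, label = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no sequences in ", path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  sequence_set(seqs, label = label)
}

#' Write a sequence set to FASTA
#'
#' @param x a [sequence_set()] (or named character vector).
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path) {
  ss <- Biostrings::DNAStringSet(unclass(x))
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Reverse complement
#'
#' @param seqs character vector of DNA sequences (A, C, G, T, N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(seqs) {
  vapply(seqs, function(s) {
    chartr("ACGT", "TGCA", paste(rev(strsplit(s, "", fixed = TRUE)[[1L]]),
                                 collapse = ""))
  }, character(1), USE.NAMES = FALSE)
}

#' G/C fraction per sequence
#'
#' N characters are excluded from the denominator.
#'
#' @param seqs character vector of DNA sequences.
#' @return numeric vector of G/C fractions in `[0, 1]`.
#' @export
gc_fraction <- function(seqs) {
  vapply(seqs, function(s) {
    codes <- encode_dna(s)
    ok <- !is.na(codes)
    if (!any(ok)) return(NA_real_)
    mean(codes[ok] == 2L | codes[ok] == 3L)
  }, numeric(1), USE.NAMES = FALSE)
}

# --- internal base coding -------------------------------------------------
# A=1 C=2 G=3 T=4, N (and anything else) = NA; complement(code) = 5 - code.

.DNA_CODE <- local({
  x <- rep(NA_integer_, 256L)
  x[utf8ToInt("A")] <- 1L
  x[utf8ToInt("C")] <- 2L
  x[utf8ToInt("G")] <- 3L
  x[utf8ToInt("T")] <- 4L
  x
})

encode_dna <- function(seq) .DNA_CODE[utf8ToInt(seq)]

revcomp_codes <- function(codes) rev(5L - codes)
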