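#' Read a motif count matrix
#'
#' Parses a nucleotide count (or frequency) matrix from any of the
#' common text dialects and returns it in a single canonical layout:
#' an L x 4 matrix with columns A, C, G, T, one row per motif position.
#'
#' Supported dialects:
#' \describe{
#'   \item{`jaspar`}{four rows `A [ 3 0 ... ]`, `C [...]`, ... with an
#'     optional `>name` header; brackets optional.}
#'   \item{`hocomoco_pcm`}{`>name` header followed by L rows of four
#'     counts in A C G T column order.}
#'   \item{`meme_minimal`}{MEME minimal format; probabilities are scaled
#'     by `nsites` when present.}
#'   \item{`plain_tsv`}{whitespace-separated numbers, either L x 4 or
#'     4 x L (4-row matrices with more than 4 columns are transposed).}
#' }
#'
#' @param path path to the matrix file.
#' @param dialect one of `"auto"`, `"jaspar"`, `"hocomoco_pcm"`,
#'   `"meme_minimal"`, `"plain_tsv"`.
#' @param name motif name; defaults to the in-file name or the file
#'   basename.
#' @return an object of class `motif_matrix`: a list with elements
#'   `name`, `counts` (L x 4, columns A,C,G,T) and `dialect`.
#' @export
read_motif_matrix <- function(path,
                              dialect = c("auto", "jaspar", "hocomoco_pcm",
                                          "meme_minimal", "plain_tsv"),
                              name = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty matrix file: ", path)
  if (dialect == "auto") dialect <- detect_matrix_dialect(lines)
  parsed <- switch(dialect,
    jaspar       = parse_jaspar(lines),
    hocomoco_pcm = parse_hocomoco(lines),
    meme_minimal = parse_meme_minimal(lines),
    plain_tsv    = parse_plain(lines))
  counts <- parsed$counts
  if (is.null(name)) name <- parsed$name
  if (is.null(name) || !nzchar(name))
    name <- sub("\\.[^.]*$", "", basename(path))
  motif_matrix(counts, name = name, dialect = dialect)
}

#' Construct a motif count matrix
#'
#' @param counts numeric L x 4 matrix (columns A, C, G, T), all entries
#'   non-negative, every row with a positive sum, L >= 1.
#' @param name motif name.
#' @param dialect source dialect tag (bookkeeping only).
#' @return an object of class `motif_matrix`.
#' @export
motif_matrix <- function(counts, name = "motif", dialect = "plain_tsv") {
  counts <- as.matrix(counts)
  storage.mode(counts) <- "double"
  if (ncol(counts) != 4L)
    stop("motif matrix must have 4 columns (A, C, G, T)")
  if (any(!is.finite(counts)))
    stop("non-finite entry in motif matrix")
  if (any(counts < 0))
    stop("negative entry in motif matrix")
  rs <- rowSums(counts)
  if (any(rs <= 0))
    stop("all-zero row in motif matrix (position ",
         which(rs <= 0)[[1L]], ")")
  dimnames(counts) <- list(NULL, c("A", "C", "G", "T"))
  structure(list(name = name, counts = counts, dialect = dialect),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("motif_matrix \"", x$name, "\": ", nrow(x$counts),
      " positions [", x$dialect, "]\n", sep = "")
  cat("  consensus: ", consensus_of(x$counts), "\n", sep = "")
  invisible(x)
}

consensus_of <- function(counts) {
  paste(c("A", "C", "G", "T")[max.col(counts, ties.method = "first")],
        collapse = "")
}

detect_matrix_dialect <- function(lines) {
  if (any(grepl("letter-probability matrix", lines, fixed = TRUE)))
    return("meme_minimal")
  if (any(grepl("^[ACGT]\\b", trimws(lines)) | grepl("\\[", lines)))
    return("jaspar")
  if (grepl("^>", lines[[1L]]))
    return("hocomoco_pcm")
  "plain_tsv"
}

num_fields <- function(line) {
  toks <- strsplit(trimws(line), "[\\s,]+", perl = TRUE)[[1L]]
  out <- suppressWarnings(as.numeric(toks))
  if (any(is.na(out))) stop("non-numeric field in matrix row: ", line)
  out
}

parse_jaspar <- function(lines) {
  name <- NULL
  if (grepl("^>", lines[[1L]])) {
    name <- sub("^>\\s*", "", lines[[1L]])
    name <- strsplit(name, "\\s+")[[1L]][[1L]]
    lines <- lines[-1L]
  }
  rows <- list()
  for (ln in lines) {
    ln <- trimws(ln)
    base <- substr(ln, 1L, 1L)
    if (!base %in% c("A", "C", "G", "T"))
      stop("unexpected row in JASPAR matrix: ", ln)
    body <- gsub("\\[|\\]", " ", substr(ln, 2L, nchar(ln)))
    rows[[base]] <- num_fields(body)
  }
  if (!setequal(names(rows), c("A", "C", "G", "T")))
    stop("JASPAR matrix must have one row for each of A, C, G, T")
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("ragged rows in JASPAR matrix")
  counts <- cbind(A = rows$A, C = rows$C, G = rows$G, T = rows$T)
  list(counts = counts, name = name)
}

parse_hocomoco <- function(lines) {
  name <- NULL
  if (grepl("^>", lines[[1L]])) {
    name <- strsplit(sub("^>\\s*", "", lines[[1L]]), "\\s+")[[1L]][[1L]]
    lines <- lines[-1L]
  }
  parse_numeric_block(lines, name = name, allow_transpose = FALSE)
}

parse_meme_minimal <- function(lines) {
  mi <- grep("^MOTIF\\b", lines)
  name <- if (length(mi)) strsplit(trimws(lines[[mi[[1L]]]]), "\\s+")[[1L]][[2L]] else NULL
  hi <- grep("letter-probability matrix", lines, fixed = TRUE)
  if (!length(hi)) stop("no letter-probability matrix header")
  header <- lines[[hi[[1L]]]]
  nsites <- 1
  m <- regmatches(header, regexpr("nsites=\\s*[0-9.]+", header))
  if (length(m) && nzchar(m)) nsites <- as.numeric(sub("nsites=\\s*", "", m))
  w <- NA_integer_
  m <- regmatches(header, regexpr("w=\\s*[0-9]+", header))
  if (length(m) && nzchar(m)) w <- as.integer(sub("w=\\s*", "", m))
  body <- lines[seq.int(hi[[1L]] + 1L, length(lines))]
  body <- body[grepl("^[-+0-9.eE \t]+$", trimws(body)) & nzchar(trimws(body))]
  if (!is.na(w)) body <- utils::head(body, w)
  parsed <- parse_numeric_block(body, name = name, allow_transpose = FALSE)
  parsed$counts <- parsed$counts * nsites
  parsed
}

parse_plain <- function(lines) {
  lines <- lines[!grepl("^[#>]", trimws(lines))]
  parse_numeric_block(lines, name = NULL, allow_transpose = TRUE)
}

parse_numeric_block <- function(lines, name = NULL, allow_transpose = FALSE) {
  rows <- lapply(lines, num_fields)
  lens <- lengths(rows)
  if (length(unique(lens)) != 1L)
    stop("ragged rows in matrix (widths ",
         paste(unique(lens), collapse = ", "), ")")
  counts <- do.call(rbind, rows)
  if (ncol(counts) != 4L) {
    if (allow_transpose && nrow(counts) == 4L) {
      counts <- t(counts)
    } else {
      stop("ragged rows in matrix: expected 4 columns, got ", ncol(counts))
    }
  }
  list(counts = counts, name = name)
}

#' Write a motif matrix as plain TSV
#'
#' One row per position, four tab-separated counts in A, C, G, T order,
#' preceded by a `>name` header line.
#'
#' @param x a [motif_matrix()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_motif_matrix <- function(x, path) {
  stopifnot(inherits(x, "motif_matrix"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0(">", x$name), con)
  utils::write.table(x$counts, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
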