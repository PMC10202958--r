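## FASTA/FASTQ I/O (Biostrings-backed) and small sequence utilities.

#' Read a FASTA or FASTQ file
#'
#' Format (and gzip compression) is auto-detected from the first record
#' marker. FASTA line wrapping is handled by the Biostrings parser.
#'
#' @param path file path (\code{.gz} allowed).
#' @return data.frame with columns \code{id}, \code{seq} and, for FASTQ,
#'   \code{qual} (\code{NA} for FASTA input).
#' @export
readFastx <- function(path) {
    if (!file.exists(path)) stop("cannot open sequence file: ", path)
    con <- gzfile(path, "rt")
    first <- readLines(con, n = 1L)
    close(con)
    if (length(first) == 0L) stop("empty sequence file: ", path)
    marker <- substr(trimws(first), 1L, 1L)
    if (marker == ">") {
        x <- Biostrings::readBStringSet(path, format = "fasta")
        data.frame(id = sub("\\s.*$", "", names(x)),
                   seq = as.character(unname(x)), qual = NA_character_,
                   stringsAsFactors = FALSE)
    } else if (marker == "@") {
        x <- Biostrings::readBStringSet(path, format = "fastq",
                                        with.qualities = TRUE)
        data.frame(id = sub("\\s.*$", "", names(x)),
                   seq = as.character(unname(x)),
                   qual = as.character(S4Vectors::mcols(x)$qualities),
                   stringsAsFactors = FALSE)
    } else {
        stop("file does not look like FASTA or FASTQ: ", path)
    }
}

#' Write sequences to FASTA or FASTQ
#'
#' @param x data.frame with \code{id}, \code{seq} and optionally \code{qual}
#'   columns, or a named character vector of sequences.
#' @param path output path; \code{.gz} suffix enables compression.
#' @param format \code{"fasta"} or \code{"fastq"}; default picks FASTQ when
#'   qualities are present.
#' @return \code{path}, invisibly.
#' @export
writeFastx <- function(x, path, format = NULL) {
    if (!is.data.frame(x))
        x <- data.frame(id = names(x), seq = as.character(x),
                        qual = NA_character_, stringsAsFactors = FALSE)
    hasQual <- !is.null(x$qual) && !anyNA(x$qual)
    if (is.null(format)) format <- if (hasQual) "fastq" else "fasta"
    s <- Biostrings::BStringSet(setNames(as.character(x$seq),
                                         as.character(x$id)))
    compress <- grepl("\\.gz$", path)
    if (format == "fastq") {
        qual <- if (hasQual) as.character(x$qual)
                else strrep("I", nchar(x$seq))
        Biostrings::writeXStringSet(s, path, format = "fastq",
                                    compress = compress,
                                    qualities = Biostrings::BStringSet(qual))
    } else {
        Biostrings::writeXStringSet(s, path, format = "fasta", width = 80L,
                                    compress = compress)
    }
    invisible(path)
}

#' Reverse complement
#'
#' @param seqs character vector of DNA sequences (non-ACGT characters map
#'   to \code{N}).
#' @return character vector of reverse complements.
#' @export
revComp <- function(seqs) .revcomp_cpp(as.character(seqs))
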