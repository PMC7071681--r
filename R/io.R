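#' Read sequences from FASTA or FASTQ
#'
#' Format is detected from the file's first character (`>` FASTA, `@` FASTQ);
#' gzip-compressed files are handled transparently.
#'
#' @param path path to a FASTA/FASTQ file, optionally gzipped.
#' @return list with `seq` (named character vector of sequences) and `qual`
#'   (named character vector of quality strings, or `NULL` for FASTA input).
#' @export
read_sequences <- function(path) {
    if (!file.exists(path)) stop("file not found: ", path)
    con <- gzfile(path, "r")
    first <- substr(readLines(con, n = 1L), 1L, 1L)
    close(con)
    if (identical(first, "@")) {
        # the quality-scaled reader warns about dropping the (empty) mcols
        # it sets while pairing sequences with qualities
        x <- withCallingHandlers(
            Biostrings::readQualityScaledDNAStringSet(path),
            warning = function(w) {
                if (grepl("metadata columns", conditionMessage(w)))
                    invokeRestart("muffleWarning")
            })
        list(seq = stats::setNames(as.character(x), names(x)),
             qual = stats::setNames(as.character(Biostrings::quality(x)),
                                    names(x)))
    } else if (identical(first, ">")) {
        x <- Biostrings::readDNAStringSet(path)
        list(seq = stats::setNames(as.character(x), names(x)), qual = NULL)
    } else {
        stop("cannot detect FASTA/FASTQ format of ", path)
    }
}

#' Write reads to FASTQ
#'
#' @param seqs named character vector of sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @param qual optional named character vector of quality strings; when
#'   missing a constant quality is written.
#' @param const_qual single quality character used when `qual` is `NULL`.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(seqs, path, qual = NULL, const_qual = "I") {
    ids <- names(seqs) %||% paste0("read", seq_along(seqs))
    if (is.null(qual))
        qual <- vapply(nchar(seqs), function(n)
            paste(rep(const_qual, n), collapse = ""), character(1))
    x <- Biostrings::DNAStringSet(stats::setNames(unname(seqs), ids))
    # writeXStringSet warns that it drops (empty) mcols; that is expected
    withCallingHandlers(
        Biostrings::writeXStringSet(x, path, format = "fastq",
                                    compress = grepl("\\.gz$", path),
                                    qualities =
                                        Biostrings::BStringSet(unname(qual))),
        warning = function(w) {
            if (grepl("metadata columns", conditionMessage(w)))
                invokeRestart("muffleWarning")
        })
    invisible(path)
}

#' Write sequences to FASTA
#'
#' @param seqs named character vector of sequences.
#' @param path output path; a `.gz` suffix triggers gzip compression.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    Biostrings::writeXStringSet(x, path, compress = grepl("\\.gz$", path))
    invisible(path)
}
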