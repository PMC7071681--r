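# Argmax k-mer assignment of pooled long reads to sample indexes.

check_indexes <- function(indexes) {
    if (!is.list(indexes) || length(indexes) < 2L ||
        !all(vapply(indexes, inherits, logical(1), "sample_kmer_index")))
        stop("need a list of >= 2 sample_kmer_index objects")
    ids <- vapply(indexes, `[[`, character(1), "sample_id")
    if (anyDuplicated(ids))
        stop("duplicate sample ids: ",
             paste(unique(ids[duplicated(ids)]), collapse = ", "))
    ks <- vapply(indexes, function(i) i$config$k, integer(1))
    if (length(unique(ks)) != 1L)
        stop("indexes disagree on k: ", paste(ks, collapse = ", "))
    ids
}

#' Score reads against all sample indexes
#'
#' For each read, the number of read k-mers present in each sample's
#' cleaned index. In `per_window` mode (default) every ACGT-only window
#' contributes one hit to each sample containing its canonical k-mer; in
#' `distinct` mode each distinct canonical k-mer contributes once.
#' Deterministic and orientation-invariant.
#'
#' @param reads character vector of read sequences.
#' @param indexes list of `sample_kmer_index` objects sharing one k.
#' @param count_mode `"per_window"` or `"distinct"`.
#' @return list with `hits` (integer matrix, reads x samples) and
#'   `n_read_kmers` (valid windows per read).
#' @export
score_reads <- function(reads, indexes, count_mode = c("per_window",
                                                       "distinct")) {
    count_mode <- match.arg(count_mode)
    ids <- check_indexes(indexes)
    k <- indexes[[1]]$config$k
    res <- cpp_score_reads(as.character(reads),
                           lapply(indexes, function(i) i$kmers$kmer),
                           k, count_mode == "distinct")
    colnames(res$hits) <- ids
    rownames(res$hits) <- names(reads)
    list(hits = res$hits, n_read_kmers = res$n_kmers)
}

#' @param sequence a single read sequence.
#' @rdname score_reads
#' @export
score_read <- function(sequence, indexes,
                       count_mode = c("per_window", "distinct")) {
    s <- score_reads(sequence, indexes, count_mode)
    list(hits = s$hits[1L, ], n_read_kmers = s$n_read_kmers[1L])
}

#' Assign one read from its hit vector
#'
#' The read goes to the sample with the maximal hit count; draws are broken
#' uniformly at random using the current RNG stream. With `min_hits > 0`
#' (an opt-in extension; the reference behavior is `0`) reads whose best
#' hit count falls below the threshold are routed to `"unassigned"`.
#'
#' @param hits named numeric vector of per-sample hit counts.
#' @param min_hits non-negative threshold; 0 disables the unassigned bin.
#' @return list with `assigned_sample`, `is_tie`, `n_tied`.
#' @export
assign_read <- function(hits, min_hits = 0) {
    stopifnot(length(hits) >= 1L, !is.null(names(hits)))
    m <- max(hits)
    if (min_hits > 0 && m < min_hits)
        return(list(assigned_sample = "unassigned", is_tie = FALSE,
                    n_tied = 1L))
    cand <- which(hits == m)
    n_tied <- length(cand)
    pick <- if (n_tied > 1L) cand[sample.int(n_tied, 1L)] else cand
    list(assigned_sample = names(hits)[pick], is_tie = n_tied > 1L,
         n_tied = n_tied)
}

#' Demultiplex a pool of long reads
#'
#' Assigns every read of a pooled long-read run to the sample whose cleaned
#' k-mer index contains the largest number of the read's k-mers, breaking
#' draws uniformly at random. A single seeded RNG stream is consumed in
#' read order, so a rerun with the same inputs and seed reproduces the
#' assignments exactly. Reads shorter than k have zero valid windows and
#' therefore enter an all-way draw.
#'
#' @param reads named character vector of read sequences, or path(s) to
#'   FASTA/FASTQ (optionally gzipped) files.
#' @param indexes list of `sample_kmer_index` objects sharing one k.
#' @param seed integer RNG seed for tie-breaking (logged in the summary).
#' @param count_mode `"per_window"` (default) or `"distinct"`.
#' @param min_hits see [assign_read()].
#' @param outdir optional directory; when given, per-sample FASTQ files,
#'   `assignments.tsv` and `summary.json` are written there.
#' @return list with `assignments` (data.frame: read_id, read_length,
#'   n_read_kmers, assigned_sample, is_tie, n_tied, then one hit column per
#'   sample, rows in input order) and `summary` (per-sample read/base
#'   counts, tie rate, parameters).
#' @export
classify_pool <- function(reads, indexes, seed = 42,
                          count_mode = c("per_window", "distinct"),
                          min_hits = 0, outdir = NULL) {
    count_mode <- match.arg(count_mode)
    ids <- check_indexes(indexes)
    qual <- NULL
    if (is.character(reads) && length(reads) &&
        all(nchar(reads) < 1000) && all(file.exists(reads))) {
        parts <- lapply(reads, read_sequences)
        qual <- unlist(lapply(parts, `[[`, "qual"))
        reads <- unlist(lapply(parts, `[[`, "seq"))
    }
    if (!length(reads)) stop("no reads to classify")
    if (is.null(names(reads)))
        names(reads) <- paste0("read", seq_along(reads))
    blank <- is.na(names(reads)) | names(reads) == ""
    if (any(blank)) names(reads)[blank] <- paste0("read", which(blank))
    if (anyDuplicated(names(reads))) {
        warning("duplicate read ids; disambiguating with suffixes")
        names(reads) <- make.unique(names(reads), sep = "_dup")
        if (!is.null(qual)) names(qual) <- names(reads)
    }

    sc <- score_reads(reads, indexes, count_mode)
    hits <- sc$hits
    n <- length(reads)
    assigned <- character(n); is_tie <- logical(n); n_tied <- integer(n)
    with_seed(seed, {
        for (i in seq_len(n)) {
            a <- assign_read(hits[i, ], min_hits = min_hits)
            assigned[i] <- a$assigned_sample
            is_tie[i] <- a$is_tie
            n_tied[i] <- a$n_tied
        }
    })

    assignments <- data.frame(
        read_id = names(reads),
        read_length = nchar(reads),
        n_read_kmers = sc$n_read_kmers,
        assigned_sample = assigned,
        is_tie = is_tie,
        n_tied = n_tied,
        stringsAsFactors = FALSE
    )
    hitdf <- as.data.frame(hits)
    names(hitdf) <- paste0("hits_", ids)
    assignments <- cbind(assignments, hitdf)
    rownames(assignments) <- NULL

    bins <- c(ids, if (min_hits > 0) "unassigned")
    per_sample <- lapply(bins, function(s) {
        sel <- assigned == s
        list(n_reads = sum(sel), n_bases = sum(nchar(reads)[sel]))
    })
    names(per_sample) <- bins
    summary <- list(
        n_reads = n,
        n_bases = sum(nchar(reads)),
        per_sample = per_sample,
        tie_rate = mean(is_tie),
        n_reads_shorter_than_k = sum(sc$n_read_kmers == 0L),
        parameters = list(k = indexes[[1]]$config$k, seed = seed,
                          count_mode = count_mode, min_hits = min_hits,
                          samples = ids)
    )

    if (!is.null(outdir)) {
        dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
        for (s in bins) {
            sel <- assigned == s
            write_fastq(reads[sel], file.path(outdir, paste0(s, ".fastq")),
                        qual = if (!is.null(qual)) qual[sel])
        }
        write_assignment_table(assignments,
                               file.path(outdir, "assignments.tsv"))
        jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                             auto_unbox = TRUE, pretty = TRUE, digits = NA)
    }
    list(assignments = assignments, summary = summary)
}

#' Write / read the per-read assignment table
#'
#' Tab-separated, one row per read in input order: read_id, read_length,
#' n_read_kmers, assigned_sample, is_tie, n_tied, then one `hits_<sample>`
#' column per sample.
#'
#' @param assignments assignment data.frame from [classify_pool()].
#' @param path TSV path.
#' @return `write_assignment_table` returns `path` invisibly;
#'   `read_assignment_table` returns the parsed data.frame.
#' @export
write_assignment_table <- function(assignments, path) {
    data.table::fwrite(assignments, path, sep = "\t", quote = FALSE)
    invisible(path)
}

#' @rdname write_assignment_table
#' @export
read_assignment_table <- function(path) {
    df <- as.data.frame(data.table::fread(path, sep = "\t"))
    df$read_id <- as.character(df$read_id)
    df$assigned_sample <- as.character(df$assigned_sample)
    df$is_tie <- as.logical(df$is_tie)
    df
}
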