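# Per-sample canonical k-mer index: counting, unitig construction,
# coverage-based cleaning, serialization.

#' Index configuration
#'
#' Parameters of the per-sample k-mer index. The index is the node set of a
#' de Bruijn graph built from a sample's short reads: canonical k-mers with
#' occurrence counts. `k` must be odd so that no k-mer equals its own
#' reverse complement.
#'
#' @param k odd k-mer length between 11 and 31. The default 19 balances the
#'   number of sample-specific k-mers against the expected k-mer survival
#'   rate (1 - e)^k in error-prone long reads.
#' @param min_unitig_coverage unitigs (maximal non-branching paths) whose
#'   mean member-k-mer count falls below this threshold are removed during
#'   cleaning; must be >= 1. At 40-100x short-read coverage with ~0.5%
#'   per-base error, sequencing-error unitigs sit near coverage 1 and the
#'   default 5 separates them cleanly from genomic unitigs.
#' @param canonical always `TRUE`; kept explicit to document that all
#'   k-mers are stored in canonical (lexicographic-minimum) form.
#' @return object of class `index_config`.
#' @export
index_config <- function(k = 19L, min_unitig_coverage = 5,
                         canonical = TRUE) {
    k <- as.integer(k)
    if (length(k) != 1L || is.na(k) || k < 11L || k > 31L || k %% 2L == 0L)
        stop("k must be an odd integer in [11, 31], got ", k)
    if (!is.numeric(min_unitig_coverage) || length(min_unitig_coverage) != 1L ||
        is.na(min_unitig_coverage) || min_unitig_coverage < 1)
        stop("min_unitig_coverage must be a number >= 1")
    if (!isTRUE(canonical))
        stop("only canonical k-mer indexes are supported")
    structure(list(k = k, min_unitig_coverage = min_unitig_coverage,
                   canonical = TRUE),
              class = "index_config")
}

#' @export
print.index_config <- function(x, ...) {
    cat("k-mer index configuration: k =", x$k,
        "| min unitig coverage =", x$min_unitig_coverage,
        "| canonical k-mers\n")
    invisible(x)
}

as_k <- function(config) {
    if (inherits(config, "index_config")) config$k
    else if (is.numeric(config) && length(config) == 1L) as.integer(config)
    else stop("expected an index_config or a single k value")
}

#' Canonicalize k-mers
#'
#' Maps each k-mer to the lexicographic minimum of itself and its reverse
#' complement, so that read strand does not affect index membership.
#' Idempotent. Non-ACGT characters are rejected with their position.
#'
#' @param kmers character vector of DNA k-mers (may differ in length).
#' @return character vector of canonical k-mers.
#' @export
canonicalize_kmers <- function(kmers) {
    cpp_canonicalize(as.character(kmers))
}

#' Extract canonical k-mers from a sequence
#'
#' Returns one canonical k-mer per window whose bases are all ACGT, in
#' window order. Windows containing ambiguous bases (N etc.) are skipped
#' rather than substituted, so no k-mer is fabricated. Sequences shorter
#' than k yield an empty vector.
#'
#' @param sequence single DNA string.
#' @param config an [index_config()] (or a bare k).
#' @return character vector of canonical k-mers.
#' @export
extract_kmers <- function(sequence, config = index_config()) {
    stopifnot(length(sequence) == 1L)
    cpp_extract_kmers(as.character(sequence), as_k(config))
}

#' Canonical k-mer count table
#'
#' Container mapping canonical k-mers to their total occurrence counts.
#' Normally produced by [count_kmers()]; the constructor validates a
#' hand-built table.
#'
#' @param kmers character vector of canonical k-mers (all of length k).
#' @param counts integer occurrence counts, all >= 1.
#' @param k the k-mer length.
#' @return object of class `kmer_count_table` with fields `kmer`, `count`,
#'   `k`, sorted by k-mer.
#' @export
kmer_count_table <- function(kmers, counts, k) {
    k <- as.integer(k)
    kmers <- as.character(kmers)
    counts <- as.integer(counts)
    if (length(kmers) != length(counts))
        stop("kmers and counts differ in length")
    if (length(kmers) && any(nchar(kmers) != k))
        stop("all k-mers must have length k = ", k)
    if (any(is.na(counts)) || any(counts < 1L))
        stop("all counts must be >= 1")
    if (length(kmers)) {
        canon <- cpp_canonicalize(kmers)
        if (any(canon != kmers))
            stop("k-mers must be canonical; offending: ",
                 paste(utils::head(kmers[canon != kmers], 3), collapse = ", "))
        if (anyDuplicated(kmers)) stop("duplicate k-mers in table")
        o <- order(kmers)
        kmers <- kmers[o]; counts <- counts[o]
    }
    structure(list(kmer = kmers, count = counts, k = k),
              class = "kmer_count_table")
}

#' @export
print.kmer_count_table <- function(x, ...) {
    cat("canonical k-mer count table: ", length(x$kmer), " k-mers (k = ",
        x$k, ")\n", sep = "")
    invisible(x)
}

#' @export
length.kmer_count_table <- function(x) length(x$kmer)

#' @export
as.data.frame.kmer_count_table <- function(x, ...) {
    data.frame(kmer = x$kmer, count = x$count, stringsAsFactors = FALSE)
}

#' Count canonical k-mers in short-read data
#'
#' Counts total occurrences of each canonical k-mer across all reads.
#' The result is independent of file order, read order and read
#' orientation. Reads may come from one or several FASTQ/FASTA files
#' (paired files need not be synchronized; pairing is unused).
#'
#' @param reads character vector of read sequences, a
#'   `Biostrings::DNAStringSet`, or a vector of paths to FASTQ/FASTA
#'   (optionally gzipped) files.
#' @param config an [index_config()].
#' @param sample_id optional sample name used in error messages.
#' @return a [kmer_count_table()].
#' @export
count_kmers <- function(reads, config = index_config(), sample_id = NULL) {
    k <- as_k(config)
    if (methods::is(reads, "DNAStringSet")) {
        reads <- as.character(reads)
    } else if (is.character(reads) && length(reads) &&
               all(nchar(reads) < 1000) && all(file.exists(reads))) {
        reads <- unlist(lapply(reads, function(p) read_sequences(p)$seq),
                        use.names = FALSE)
    }
    reads <- as.character(reads)
    who <- if (is.null(sample_id)) "input" else paste0("sample ", sample_id)
    if (!length(reads))
        stop(who, ": no reads supplied")
    if (!any(nchar(reads) >= k))
        stop(who, ": no read of length >= k (", k, ")")
    tab <- cpp_count_kmers(reads, k)
    if (!length(tab$kmer))
        stop(who, ": reads contain no ACGT-only window of length ", k)
    structure(list(kmer = tab$kmer, count = tab$count, k = k),
              class = "kmer_count_table")
}

#' Partition a k-mer table into unitigs
#'
#' Builds the bidirected de Bruijn graph induced by the table's k-mer set
#' and partitions it into unitigs: maximal non-branching paths. A node is a
#' path boundary on a side with anything other than exactly one neighbor
#' (both orientations considered). Every k-mer belongs to exactly one
#' unitig, and the partition does not depend on table order.
#'
#' @param table a [kmer_count_table()].
#' @param config an [index_config()]; its k must match the table.
#' @return data.frame with one row per unitig: `sequence` (spelled in an
#'   arbitrary orientation), `n_kmers`, `mean_coverage`, and list-column
#'   `member_kmers` (canonical member k-mers in walk order).
#' @export
build_unitigs <- function(table, config = index_config()) {
    stopifnot(inherits(table, "kmer_count_table"))
    k <- as_k(config)
    if (k != table$k)
        stop("config k (", k, ") != table k (", table$k, ")")
    if (!length(table$kmer)) stop("empty k-mer table")
    u <- cpp_build_unitigs(table$kmer, k)
    nu <- length(u$sequence)
    mean_cov <- as.numeric(rowsum(as.numeric(table$count),
                                  u$unitig_id)) / u$n_members
    members <- split(table$kmer[u$walk_order],
                     rep.int(seq_len(nu), u$n_members))
    names(members) <- NULL
    data.frame(
        sequence = u$sequence,
        n_kmers = u$n_members,
        mean_coverage = mean_cov,
        member_kmers = I(members),
        stringsAsFactors = FALSE
    )
}

#' Automatic cleaning threshold from the count histogram
#'
#' Chooses the first local minimum of the k-mer multiplicity histogram in
#' \[2, 20\] — the valley between the error peak (near count 1) and the
#' genomic coverage peak — falling back to 5 when no such minimum exists.
#'
#' @param table a [kmer_count_table()].
#' @return single numeric threshold.
#' @export
auto_min_coverage <- function(table) {
    stopifnot(inherits(table, "kmer_count_table"))
    maxc <- max(table$count)
    h <- tabulate(table$count, nbins = max(maxc, 21L))
    upper <- min(20L, maxc - 1L)
    for (cc in 2:max(2L, upper)) {
        if (cc > upper) break
        if (h[cc] < h[cc - 1L] && h[cc] <= h[cc + 1L]) return(cc)
    }
    5
}

#' Clean a k-mer table by unitig coverage
#'
#' Removes every k-mer belonging to a unitig whose mean member-k-mer count
#' is below the threshold — the supernode-level low-coverage cleaning that
#' strips sequencing-error k-mers from the sample graph. Counts of the
#' surviving k-mers are retained.
#'
#' @param table a [kmer_count_table()].
#' @param config an [index_config()]; set `min_unitig_coverage` there, or
#'   pass `min_unitig_coverage = "auto"` here to use [auto_min_coverage()].
#' @param sample_id sample identifier stored in the index.
#' @param min_unitig_coverage optional override: a number or `"auto"`.
#' @return object of class `sample_kmer_index` with fields `sample_id`,
#'   `config`, `kmers` (cleaned [kmer_count_table()]), `n_raw_kmers`,
#'   `n_cleaned_kmers`.
#' @export
clean_index <- function(table, config = index_config(),
                        sample_id = "sample", min_unitig_coverage = NULL) {
    stopifnot(inherits(table, "kmer_count_table"))
    thr <- min_unitig_coverage %||% config$min_unitig_coverage
    if (identical(thr, "auto")) thr <- auto_min_coverage(table)
    config <- index_config(k = as_k(config), min_unitig_coverage = thr)
    u <- cpp_build_unitigs(table$kmer, config$k)
    mean_cov <- as.numeric(rowsum(as.numeric(table$count),
                                  u$unitig_id)) / u$n_members
    keep <- mean_cov[u$unitig_id] >= thr
    if (!any(keep))
        stop("sample ", sample_id, ": cleaning removed every k-mer; ",
             "lower min_unitig_coverage or provide more coverage")
    cleaned <- structure(list(kmer = table$kmer[keep],
                              count = table$count[keep],
                              k = table$k),
                         class = "kmer_count_table")
    structure(list(sample_id = as.character(sample_id), config = config,
                   kmers = cleaned,
                   n_raw_kmers = length(table$kmer),
                   n_cleaned_kmers = sum(keep)),
              class = "sample_kmer_index")
}

#' @export
print.sample_kmer_index <- function(x, ...) {
    cat("sample k-mer index '", x$sample_id, "': ", x$n_cleaned_kmers,
        " / ", x$n_raw_kmers, " k-mers after cleaning (k = ", x$config$k,
        ", min unitig coverage = ", x$config$min_unitig_coverage, ")\n",
        sep = "")
    invisible(x)
}

#' Build a cleaned sample index from short reads
#'
#' Convenience wrapper: [count_kmers()] then [clean_index()].
#'
#' @param sample_id sample identifier.
#' @param reads as in [count_kmers()]: sequences or FASTQ/FASTA paths.
#' @param config an [index_config()].
#' @param min_unitig_coverage optional override (number or `"auto"`).
#' @return a `sample_kmer_index`.
#' @export
build_index <- function(sample_id, reads, config = index_config(),
                        min_unitig_coverage = NULL) {
    tab <- count_kmers(reads, config, sample_id = sample_id)
    clean_index(tab, config, sample_id = sample_id,
                min_unitig_coverage = min_unitig_coverage)
}

INDEX_MAGIC <- "#kmerplex_index"
INDEX_VERSION <- "1"

#' Save / load a sample k-mer index
#'
#' The on-disk format is a gzipped tab-separated text file with a header
#' (magic tag, format version, k, sample id, cleaning threshold, raw and
#' cleaned k-mer counts) followed by one `kmer<TAB>count` row per k-mer.
#' `load_index(save_index(x))` reproduces the sample id, configuration and
#' the exact k-mer-to-count mapping.
#'
#' @param index a `sample_kmer_index`.
#' @param path file path (written gzip-compressed regardless of suffix).
#' @return `save_index` returns `path` invisibly; `load_index` returns the
#'   restored `sample_kmer_index`.
#' @export
save_index <- function(index, path) {
    stopifnot(inherits(index, "sample_kmer_index"))
    con <- gzfile(path, "wb")
    on.exit(close(con))
    writeLines(c(
        paste(INDEX_MAGIC, INDEX_VERSION, sep = "\t"),
        paste("#k", index$config$k, sep = "\t"),
        paste("#sample_id", index$sample_id, sep = "\t"),
        paste("#min_unitig_coverage", index$config$min_unitig_coverage,
              sep = "\t"),
        paste("#n_raw_kmers", index$n_raw_kmers, sep = "\t"),
        paste("#n_cleaned_kmers", index$n_cleaned_kmers, sep = "\t"),
        paste(index$kmers$kmer, index$kmers$count, sep = "\t")
    ), con)
    invisible(path)
}

#' @param expected_k if given, loading fails unless the file's k matches —
#'   guards against mixing indexes of different k in one run.
#' @rdname save_index
#' @export
load_index <- function(path, expected_k = NULL) {
    lines <- readLines(gzfile(path))
    if (length(lines) < 6L || !startsWith(lines[1L], INDEX_MAGIC))
        stop("not a kmerplex index file: ", path)
    hdr <- strsplit(lines[1:6], "\t", fixed = TRUE)
    version <- hdr[[1]][2]
    if (!identical(version, INDEX_VERSION))
        stop("index file version ", version, " unsupported (expected ",
             INDEX_VERSION, "): ", path)
    k <- as.integer(hdr[[2]][2])
    if (!is.null(expected_k) && k != as.integer(expected_k))
        stop("index file ", path, " has k = ", k,
             " but k = ", expected_k, " was requested")
    sample_id <- hdr[[3]][2]
    thr <- as.numeric(hdr[[4]][2])
    n_raw <- as.integer(hdr[[5]][2])
    n_cleaned <- as.integer(hdr[[6]][2])
    body <- lines[-(1:6)]
    km <- character(0); ct <- integer(0)
    if (length(body)) {
        parts <- strsplit(body, "\t", fixed = TRUE)
        km <- vapply(parts, `[`, character(1), 1L)
        ct <- as.integer(vapply(parts, `[`, character(1), 2L))
    }
    if (length(km) != n_cleaned)
        stop("corrupt index file ", path, ": expected ", n_cleaned,
             " k-mers, found ", length(km))
    structure(list(
        sample_id = sample_id,
        config = index_config(k = k, min_unitig_coverage = thr),
        kmers = structure(list(kmer = km, count = ct, k = k),
                          class = "kmer_count_table"),
        n_raw_kmers = n_raw, n_cleaned_kmers = n_cleaned),
        class = "sample_kmer_index")
}
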