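test_that("canonicalization returns the lexicographic minimum of k-mer and reverse complement", {
    expect_identical(canonicalize_kmers(c("ACG", "CGT", "AAA")),
                     c("ACG", "ACG", "AAA"))
    # idempotent
    set.seed(101)
    km <- replicate(50, random_seq(sample(11:31, 1) * 2 %/% 2 + 1))
    once <- canonicalize_kmers(km)
    expect_identical(canonicalize_kmers(once), once)
    expect_identical(once, oracle_canon(km))
    expect_error(canonicalize_kmers("ACNG"), "position 3")
})

test_that("k-mer extraction skips ambiguous windows and short sequences", {
    expect_identical(extract_kmers("ACGTACGT", 4),
                     c("ACGT", "CGTA", "GTAC", "CGTA", "ACGT"))
    expect_identical(extract_kmers("ACGNACGT", 4), "ACGT")
    expect_identical(extract_kmers("ACG", 4), character(0))
})

test_that("index configuration enforces odd k and a sane threshold", {
    cfg <- index_config()
    expect_equal(cfg$k, 19L)
    expect_equal(cfg$min_unitig_coverage, 5)
    expect_error(index_config(k = 20), "odd")
    expect_error(index_config(k = 9), "odd")
    expect_error(index_config(min_unitig_coverage = 0.5), ">= 1")
})

test_that("counting is strand-aggregated and independent of read order", {
    tab <- count_kmers(c("AACC", "GGTT"), 3)
    expect_identical(as.data.frame(tab),
                     data.frame(kmer = c("AAC", "ACC"), count = c(2L, 2L)))
    tab2 <- count_kmers("AAAA", 3)
    expect_identical(tab2$kmer, "AAA")
    expect_identical(tab2$count, 2L)

    set.seed(7)
    reads <- replicate(40, random_seq(sample(25:80, 1)))
    a <- count_kmers(reads, 19)
    b <- count_kmers(rev(reads), 19)
    cc <- count_kmers(oracle_rc(reads), 19)
    expect_identical(a, b)
    expect_identical(a, cc)

    expect_error(count_kmers("ACGT", 19, sample_id = "S9"), "S9")
    expect_error(count_kmers(c("NNNNNNNNNNNNNNNNNNNNNNNN"), 19),
                 "ACGT-only")
})

test_that("counting from files ignores file order and gzip", {
    set.seed(8)
    reads <- replicate(30, random_seq(40))
    names(reads) <- paste0("r", 1:30)
    f1 <- tempfile(fileext = ".fastq")
    f2 <- tempfile(fileext = ".fastq.gz")
    write_fastq(reads[1:15], f1)
    write_fastq(reads[16:30], f2)
    cfg <- index_config()
    expect_identical(count_kmers(c(f1, f2), cfg),
                     count_kmers(c(f2, f1), cfg))
    expect_identical(count_kmers(c(f1, f2), cfg), count_kmers(reads, cfg))
})

test_that("a single non-branching sequence yields one unitig", {
    tab <- count_kmers("ACGTAGGCAT", 5)
    u <- build_unitigs(tab, 5)
    expect_equal(nrow(u), 1L)
    expect_true(u$sequence %in% c("ACGTAGGCAT", oracle_rc("ACGTAGGCAT")))
    expect_equal(u$n_kmers, length(tab))

    tab2 <- kmer_count_table("AAA", 10L, 3)
    u2 <- build_unitigs(tab2, 3)
    expect_identical(u2$sequence, "AAA")
    expect_equal(u2$mean_coverage, 10)
})

test_that("unitig partition covers every k-mer exactly once", {
    set.seed(21)
    for (rep in 1:10) {
        s1 <- random_seq(60); s2 <- random_seq(60)
        tab <- count_kmers(c(s1, s2), 7)
        u <- build_unitigs(tab, 7)
        members <- unlist(u$member_kmers)
        expect_equal(sort(members), tab$kmer)
        expect_equal(sum(u$n_kmers), length(tab))
        # member count matches sequence length
        expect_equal(u$n_kmers, nchar(u$sequence) - 7L + 1L)
    }
})

test_that("two sequences without shared (k-1)-mers form two unitigs", {
    s1 <- "ACGTAGGCATT"
    s2 <- "CCCGGATCGGA"
    tab <- count_kmers(c(s1, s2), 7)
    u <- build_unitigs(tab, 7)
    expect_equal(nrow(u), 2L)
})

test_that("unitig partition is invariant to table construction order", {
    set.seed(33)
    s <- random_seq(200)
    tab <- count_kmers(s, 9)
    perm <- sample(length(tab))
    tab2 <- kmer_count_table(tab$kmer[perm], tab$count[perm], 9)
    expect_identical(partition_of(build_unitigs(tab, 9)$member_kmers),
                     partition_of(build_unitigs(tab2, 9)$member_kmers))
})

test_that("cleaning removes low-mean-coverage unitigs and records counts", {
    # two disjoint unitigs with mean coverages ~1.2 and 40
    set.seed(44)
    s1 <- random_seq(15); s2 <- random_seq(15)
    k1 <- unique(oracle_canon(substring(s1, 1:5, 11:15)))
    k2 <- setdiff(unique(oracle_canon(substring(s2, 1:5, 11:15))), k1)
    cnt <- c(rep(1L, length(k1)), rep(40L, length(k2)))
    cnt[1] <- 2L  # mean ~1.2
    tab <- kmer_count_table(c(k1, k2), cnt, 11)
    idx <- clean_index(tab, index_config(k = 11, min_unitig_coverage = 5),
                       sample_id = "s")
    expect_setequal(idx$kmers$kmer, k2)
    expect_true(all(idx$kmers$count == 40L))
    expect_equal(idx$n_raw_kmers, length(tab))
    expect_equal(idx$n_cleaned_kmers, length(k2))

    # threshold 1 keeps everything
    idx1 <- clean_index(tab, index_config(k = 11, min_unitig_coverage = 1))
    expect_identical(idx1$kmers$kmer, tab$kmer)

    # everything removed -> advisory error
    expect_error(
        clean_index(kmer_count_table(k1, rep(1L, length(k1)), 11),
                    index_config(k = 11, min_unitig_coverage = 50),
                    sample_id = "weak"),
        "weak.*lower min_unitig_coverage")
})

test_that("raising the cleaning threshold never adds k-mers", {
    set.seed(5)
    reads <- unlist(lapply(1:30, function(i)
        substring(random_seq(300), seq(1, 260, 20), seq(40, 300, 20))))
    tab <- count_kmers(reads, 11)
    prev <- NULL
    for (thr in c(1, 2, 4, 8)) {
        idx <- try(clean_index(tab, index_config(k = 11,
                                                 min_unitig_coverage = thr)),
                   silent = TRUE)
        kset <- if (inherits(idx, "try-error")) character(0)
                else idx$kmers$kmer
        if (!is.null(prev)) expect_true(all(kset %in% prev))
        prev <- kset
    }
})

test_that("automatic threshold finds the valley of a bimodal count histogram", {
    # error peak at count 1-2, genomic peak near 30
    set.seed(9)
    counts <- c(rep(1L, 400), rep(2L, 80), rep(3L, 10), rep(4L, 3),
                sample(25:35, 300, replace = TRUE))
    km <- character(0)
    while (length(unique(km)) < length(counts))
        km <- unique(c(km, oracle_canon(replicate(200, random_seq(11)))))
    tab <- kmer_count_table(km[seq_along(counts)], counts, 11)
    thr <- auto_min_coverage(tab)
    expect_gte(thr, 3)
    expect_lte(thr, 20)
})

test_that("index files round-trip exactly and reject mismatching k", {
    set.seed(12)
    reads <- replicate(50, random_seq(60))
    idx <- build_index("sampleA", reads,
                       index_config(k = 15, min_unitig_coverage = 1))
    f <- tempfile(fileext = ".idx")
    save_index(idx, f)
    back <- load_index(f)
    expect_identical(back$sample_id, idx$sample_id)
    expect_identical(back$config$k, idx$config$k)
    expect_identical(back$kmers$kmer, idx$kmers$kmer)
    expect_identical(back$kmers$count, idx$kmers$count)
    expect_identical(back$n_raw_kmers, idx$n_raw_kmers)
    expect_error(load_index(f, expected_k = 19), "k = 15")

    # large random index round-trips bit-exactly (digest by checksum)
    big <- fake_index("big", unique(replicate(5000, random_seq(17))), 17)
    f2 <- tempfile(fileext = ".idx")
    save_index(big, f2)
    back2 <- load_index(f2)
    expect_identical(paste(back2$kmers$kmer, back2$kmers$count),
                     paste(big$kmers$kmer, big$kmers$count))

    # non-index file rejected
    junk <- tempfile()
    writeLines(c("a", "b", "c", "d", "e", "f", "g"), junk)
    expect_error(load_index(junk), "not a kmerplex index")
})
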