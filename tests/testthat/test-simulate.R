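test_that("community divergence, sharing and plasmids behave as specified", {
    # divergence 0: identical genomes
    com0 <- simulate_community(community_spec(3, 5e3,
                                              pairwise_divergence = 0,
                                              seed = 1))
    chroms <- vapply(com0$isolates, function(i) i$contigs[["chromosome"]],
                     character(1))
    expect_true(all(chroms == chroms[1]))

    # per-isolate rate p gives realized pairwise mismatch ~ 2p(1-p)
    p <- 0.01
    com <- simulate_community(community_spec(2, 1e5,
                                             pairwise_divergence = p,
                                             seed = 2))
    a <- strsplit(com$isolates[[1]]$contigs[["chromosome"]], "")[[1]]
    b <- strsplit(com$isolates[[2]]$contigs[["chromosome"]], "")[[1]]
    mm <- mean(a != b)
    # two independent mutation processes: 2p(1-p) + (2/3)p^2 ~ 0.0199
    expect_gt(mm, 0.0199 - 0.002)
    expect_lt(mm, 0.0199 + 0.002)

    # shared segment is byte-identical across isolates
    com_s <- simulate_community(community_spec(
        3, 2e4, pairwise_divergence = 0.05,
        shared_segment_fraction = 0.3, seed = 3))
    st <- com_s$manifest$shared_start
    len <- com_s$manifest$shared_length
    expect_equal(len, 6e3)
    blocks <- vapply(com_s$isolates, function(i)
        substr(i$contigs[["chromosome"]], st, st + len - 1L), character(1))
    expect_true(all(blocks == blocks[1]))

    # shared plasmid byte-identical; carrier subsets respected
    com_p <- simulate_community(community_spec(
        3, 1e4, pairwise_divergence = 0.02,
        plasmids = list(list(length = 2000, copy_number = 3,
                             shared_across = "all"),
                        list(length = 1500, copy_number = 1,
                             shared_across = c(1L, 2L))),
        seed = 4))
    pl <- vapply(com_p$isolates, function(i) i$contigs[["plasmid1"]],
                 character(1))
    expect_true(all(pl == pl[1]))
    expect_true("plasmid2" %in% names(com_p$isolates[[1]]$contigs))
    expect_false("plasmid2" %in% names(com_p$isolates[[3]]$contigs))
    expect_equal(unname(com_p$isolates[[1]]$weights[["plasmid1"]]),
                 unname(nchar(pl[1])) * 3)

    # chromosome-plasmid repeat present verbatim in both replicons
    com_r <- simulate_community(community_spec(
        2, 1e4, pairwise_divergence = 0.01,
        plasmids = list(list(length = 3000, shared_across = "all")),
        chrom_plasmid_repeat = list(length = 600), seed = 5))
    iso <- com_r$isolates[[1]]
    rep_at <- com_r$manifest$repeat_at
    rep_seq <- substr(iso$contigs[["chromosome"]], rep_at, rep_at + 599L)
    expect_true(grepl(rep_seq, iso$contigs[["plasmid1"]], fixed = TRUE))
    expect_equal(nchar(iso$contigs[["chromosome"]]), 1e4 + 600)

    expect_error(community_spec(2, 1e3, chrom_plasmid_repeat =
                                    list(length = 5e3),
                                plasmids = list(list(length = 1000))),
                 "repeat longer")
})

test_that("error-free short reads are exact genome substrings with the right yield", {
    set.seed(10)
    g <- c(chr = random_seq(5e4))
    sp <- short_read_params(base_error_rate = 0, yield_bp = 1e6)
    sim <- simulate_short_reads(g, sp, seed = 11)
    expect_equal(length(sim$r1), round(1e6 / 300))
    expect_equal(length(sim$r1), 3333L)
    expect_true(all(nchar(sim$r1) == 150L))
    # reconstruct templates from the simulation log (fragments may wrap
    # the circular origin): exact matches
    m <- sim$meta
    gd <- paste0(g[["chr"]], g[["chr"]])
    left <- substring(gd, m$start, m$start + 149L)
    right <- oracle_rc(substring(gd, m$start + m$insert - 150L,
                                 m$start + m$insert - 1L))
    expect_identical(unname(sim$r1), ifelse(m$flip, right, left))
    expect_identical(unname(sim$r2), ifelse(m$flip, left, right))
    expect_error(simulate_short_reads(c(tiny = "ACGTACGT"), sp),
                 "genome too short")
})

test_that("short-read substitution errors hit the configured rate", {
    set.seed(12)
    g <- c(chr = random_seq(1e5))
    sp <- short_read_params(yield_bp = 1e6)  # e = 0.005
    sim <- simulate_short_reads(g, sp, seed = 13)
    m <- sim$meta
    gd <- paste0(g[["chr"]], g[["chr"]])
    left <- substring(gd, m$start, m$start + 149L)
    right <- oracle_rc(substring(gd, m$start + m$insert - 150L,
                                 m$start + m$insert - 1L))
    t1 <- ifelse(m$flip, right, left)
    t2 <- ifelse(m$flip, left, right)
    mism <- function(x, y) {
        xs <- strsplit(paste(x, collapse = ""), "")[[1]]
        ys <- strsplit(paste(y, collapse = ""), "")[[1]]
        mean(xs != ys)
    }
    rate <- (mism(sim$r1, t1) + mism(sim$r2, t2)) / 2
    expect_equal(rate, 0.005, tolerance = 0.1)
    expect_equal(sum(sim$meta$n_sub_1 + sim$meta$n_sub_2) / 1e6, 0.005,
                 tolerance = 0.1)
})

test_that("error-free long reads are exact substrings; truth is conserved", {
    set.seed(14)
    g <- c(chr = random_seq(3e4))
    lp <- long_read_params(length_mean = 2000, length_sd = 1500,
                           length_min = 200, length_max = 8000,
                           accuracy_mean = 1)
    sim <- simulate_long_reads(g, lp, yield_bp = 2e5, seed = 15)
    expect_equal(anyDuplicated(sim$truth$read_id), 0L)
    expect_setequal(names(sim$reads), sim$truth$read_id)
    expect_gte(sum(sim$truth$template_length), 2e5)
    gd <- paste0(g[["chr"]], g[["chr"]])
    for (i in seq_along(sim$reads)) {
        tr <- sim$truth[i, ]
        tmpl <- substr(gd, tr$start, tr$start + tr$template_length - 1L)
        if (tr$strand == "-") tmpl <- oracle_rc(tmpl)
        expect_identical(unname(sim$reads[[tr$read_id]]), tmpl)
    }
    expect_true(all(sim$truth$template_length >= 200))
    expect_true(all(sim$truth$template_length <= 8000))
})

test_that("pooled long reads split the flow-cell yield evenly per isolate", {
    com <- simulate_community(community_spec(4, 2e4,
                                             pairwise_divergence = 0.01,
                                             seed = 16))
    lp <- long_read_params(length_mean = 1500, length_sd = 800,
                           length_min = 200, length_max = 5000,
                           total_yield_bp = 8e5)
    pool <- simulate_long_read_pool(com, lp, seed = 17)
    per <- tapply(pool$truth$template_length, pool$truth$sample_id, sum)
    expect_equal(length(per), 4L)
    # each isolate hits total/n to within one read
    expect_true(all(per >= 8e5 / 4))
    expect_true(all(per < 8e5 / 4 + 5000))
    expect_equal(anyDuplicated(pool$truth$read_id), 0L)
    expect_equal(sort(names(pool$reads)), sort(pool$truth$read_id))
})

test_that("identical seeds reproduce identical simulations", {
    spec <- community_spec(2, 1e4, pairwise_divergence = 0.01, seed = 20)
    expect_identical(simulate_community(spec), simulate_community(spec))
    g <- c(chr = random_seq(2e4))
    sp <- short_read_params(yield_bp = 1e5)
    expect_identical(simulate_short_reads(g, sp, seed = 21),
                     simulate_short_reads(g, sp, seed = 21))
    lp <- long_read_params(length_mean = 1000, length_sd = 500,
                           length_min = 200, length_max = 3000)
    expect_identical(simulate_long_reads(g, lp, 5e4, seed = 22),
                     simulate_long_reads(g, lp, 5e4, seed = 22))
})

test_that("long-read error rate matches 1 - accuracy_mean", {
    set.seed(23)
    g <- c(chr = random_seq(5e4))
    lp <- long_read_params(length_mean = 5000, length_sd = 2000,
                           length_min = 500, length_max = 20000,
                           accuracy_mean = 0.88)
    sim <- simulate_long_reads(g, lp, yield_bp = 1e6, seed = 24)
    # align a few reads back to their template: edit distance / length ~ e
    idx <- seq_len(min(20, length(sim$reads)))
    gd <- paste0(g[["chr"]], g[["chr"]])
    ds <- vapply(idx, function(i) {
        tr <- sim$truth[i, ]
        tmpl <- substr(gd, tr$start, tr$start + tr$template_length - 1L)
        ends_free_edit_distance(sim$reads[[tr$read_id]], tmpl) /
            tr$template_length
    }, numeric(1))
    # edit distance is a lower bound on the number of injected errors,
    # but stays close at a 1:1:1 mix
    expect_gt(mean(ds), 0.08)
    expect_lt(mean(ds), 0.13)
})
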