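# Independent reference implementations used as oracles. These are kept
# deliberately naive (string operations, full DP) and separate from the
# package's code paths.

oracle_rc <- function(x) {
    vapply(x, function(s) {
        paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]),
              collapse = "")
    }, character(1), USE.NAMES = FALSE)
}

oracle_canon <- function(x) {
    r <- oracle_rc(x)
    ifelse(x <= r, x, r)
}

# semi-global edit distance: query global, target ends free; row-wise DP
# with the min-plus prefix-scan trick for the horizontal (target-gap) move
oracle_infix_edit <- function(q, t) {
    qc <- strsplit(q, "")[[1]]
    tc <- strsplit(t, "")[[1]]
    m <- length(qc); n <- length(tc)
    if (m == 0L) return(0L)
    if (n == 0L) return(m)
    prev <- rep(0L, n + 1L)            # row 0: free start anywhere in t
    for (i in seq_len(m)) {
        tmp <- pmin(prev[1:n] + (qc[i] != tc), prev[2:(n + 1L)] + 1L)
        v <- c(i, tmp)
        prev <- cummin(v - 0:n) + 0:n  # free-gap scan along the target
    }
    min(prev)
}

# both strands, multiple contigs
oracle_ends_free <- function(read, genome) {
    min(c(vapply(genome, oracle_infix_edit, integer(1), q = read),
          vapply(genome, oracle_infix_edit, integer(1),
                 q = oracle_rc(read))))
}

# brute-force unitig partition of a canonical k-mer set: two k-mers chain
# iff each is the unique neighbor on the side facing the other; unitigs are
# the connected components of the chain relation. Returns the partition as
# a sorted list of sorted member vectors (orientation-free).
oracle_unitigs <- function(kmers, k) {
    neighbors <- function(km, side) {
        exts <- if (side == 0) paste0(substr(km, 2L, k), c("A", "C", "G", "T"))
                else paste0(c("A", "C", "G", "T"), substr(km, 1L, k - 1L))
        out <- list()
        for (e in exts) {
            cn <- oracle_canon(e)
            if (!(cn %in% kmers)) next
            facing <- if (cn == e) { if (side == 0) 1L else 0L
            } else { if (side == 0) 0L else 1L }
            out[[length(out) + 1L]] <- list(node = cn, side = facing)
        }
        out
    }
    linked <- function(u, s) {
        nb <- neighbors(u, s)
        if (length(nb) != 1L || nb[[1L]]$node == u) return(NULL)
        back <- neighbors(nb[[1L]]$node, nb[[1L]]$side)
        if (length(back) == 1L && back[[1L]]$node == u &&
            back[[1L]]$side == s) nb[[1L]]$node else NULL
    }
    parent <- stats::setNames(kmers, kmers)
    find <- function(x) { while (parent[[x]] != x) x <- parent[[x]]; x }
    for (u in kmers) for (s in 0:1) {
        v <- linked(u, s)
        if (!is.null(v)) parent[[find(u)]] <- find(v)
    }
    comp <- vapply(kmers, find, character(1))
    parts <- lapply(split(kmers, comp), sort)
    names(parts) <- NULL
    parts[order(vapply(parts, `[`, character(1), 1L))]
}

# canonicalize a member_kmers partition for comparison
partition_of <- function(member_list) {
    parts <- lapply(member_list, sort)
    parts[order(vapply(parts, `[`, character(1), 1L))]
}

random_seq <- function(n) {
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a sample_kmer_index wrapper around an explicit k-mer set (for small k
# that the user-facing config would reject)
fake_index <- function(sample_id, kmers, k, counts = NULL) {
    kmers <- sort(unique(oracle_canon(kmers)))
    counts <- counts %||% rep(10L, length(kmers))
    structure(list(
        sample_id = sample_id,
        config = structure(list(k = as.integer(k), min_unitig_coverage = 1,
                                canonical = TRUE), class = "index_config"),
        kmers = structure(list(kmer = kmers, count = as.integer(counts),
                               k = as.integer(k)),
                          class = "kmer_count_table"),
        n_raw_kmers = length(kmers), n_cleaned_kmers = length(kmers)),
        class = "sample_kmer_index")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# truncated normal mean on [lo, hi], closed form
truncnorm_mean <- function(mu, sigma, lo, hi) {
    a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
    mu + sigma * (dnorm(a) - dnorm(b)) / (pnorm(b) - pnorm(a))
}

truncnorm_sd <- function(mu, sigma, lo, hi) {
    a <- (lo - mu) / sigma; b <- (hi - mu) / sigma
    Z <- pnorm(b) - pnorm(a)
    v <- 1 + (a * dnorm(a) - b * dnorm(b)) / Z -
        ((dnorm(a) - dnorm(b)) / Z)^2
    sigma * sqrt(v)
}
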