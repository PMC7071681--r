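# Synthetic communities, paired-end short reads with substitution errors,
# and long reads with mixed errors and a broad (truncated normal) length
# distribution. The simulator reproduces the statistical shape of the
# wgsim/pbsim parameter sets used for the original experiments; the error
# process is fully known, which is what the truth-based tests need.

#' Synthetic community specification
#'
#' Describes a set of related bacterial isolate genomes derived from a
#' common random ancestor: isolate chromosomes receive i.i.d. substitutions
#' at rate `pairwise_divergence` outside an optional shared segment, so two
#' isolates differ at a realized rate of about `2p(1-p)`. Optional plasmids
#' are byte-identical across the isolates that carry them, and an optional
#' repeat can be inserted verbatim into both the chromosome and the first
#' plasmid.
#'
#' @param n_isolates number of isolates (>= 2).
#' @param chromosome_length chromosome length in bp. Default 2.8e6 (a
#'   typical *S. aureus* chromosome); scale down to 1e5-5e5 for quick runs.
#' @param pairwise_divergence per-isolate substitution rate from the
#'   ancestor, in \[0, 0.25\].
#' @param shared_segment_fraction fraction of the chromosome kept
#'   byte-identical across all isolates (one contiguous block), in \[0, 1\].
#' @param plasmids optional list of plasmid descriptions, each a list with
#'   `length` (bp), `copy_number` (sampling weight multiplier, default 1)
#'   and `shared_across` (`"all"` or integer vector of isolate indices).
#' @param chrom_plasmid_repeat optional list with `length` (bp): a repeat
#'   inserted verbatim into every chromosome and the first plasmid.
#' @param seed optional RNG seed.
#' @return object of class `community_spec`.
#' @export
community_spec <- function(n_isolates = 2L, chromosome_length = 2.8e6,
                           pairwise_divergence = 0.01,
                           shared_segment_fraction = 0,
                           plasmids = NULL, chrom_plasmid_repeat = NULL,
                           seed = NULL) {
    n_isolates <- as.integer(n_isolates)
    stopifnot(n_isolates >= 2L, chromosome_length >= 1e3)
    if (pairwise_divergence < 0 || pairwise_divergence > 0.25)
        stop("pairwise_divergence must be in [0, 0.25]")
    if (shared_segment_fraction < 0 || shared_segment_fraction > 1)
        stop("shared_segment_fraction must be in [0, 1]")
    if (!is.null(plasmids))
        for (p in plasmids) stopifnot(is.list(p), p$length >= 100)
    if (!is.null(chrom_plasmid_repeat)) {
        stopifnot(is.list(chrom_plasmid_repeat))
        if (chrom_plasmid_repeat$length > chromosome_length)
            stop("repeat longer than the chromosome")
        if (is.null(plasmids))
            stop("chrom_plasmid_repeat requires at least one plasmid")
    }
    structure(list(n_isolates = n_isolates,
                   chromosome_length = as.integer(chromosome_length),
                   pairwise_divergence = pairwise_divergence,
                   shared_segment_fraction = shared_segment_fraction,
                   plasmids = plasmids,
                   chrom_plasmid_repeat = chrom_plasmid_repeat,
                   seed = seed),
              class = "community_spec")
}

# substitute bases at rate p, never to the same base, skipping positions in
# `protect` (a logical vector or NULL)
mutate_seq <- function(seq, p, protect = NULL) {
    if (p <= 0) return(seq)
    x <- strsplit(seq, "", fixed = TRUE)[[1]]
    hit <- stats::runif(length(x)) < p
    if (!is.null(protect)) hit <- hit & !protect
    idx <- which(hit)
    if (length(idx)) {
        bases <- c("A", "C", "G", "T")
        cur <- match(x[idx], bases)
        off <- sample.int(3L, length(idx), replace = TRUE)
        x[idx] <- bases[((cur - 1L + off) %% 4L) + 1L]
    }
    paste(x, collapse = "")
}

splice_in <- function(seq, insert, at) {
    paste0(substr(seq, 1L, at - 1L), insert,
           substr(seq, at, nchar(seq)))
}

#' Generate a synthetic community
#'
#' Draws the ancestor and derives all isolate genomes per the
#' [community_spec()]. Deterministic given the spec's seed.
#'
#' @param spec a [community_spec()].
#' @return object of class `community`: `isolates` (named list; each has
#'   `contigs`, a named character vector starting with `chromosome`, and
#'   `weights`, the read-sampling weights length x copy number), `spec`,
#'   and `manifest` (shared-segment coordinates, plasmid sharing, repeat
#'   position).
#' @export
simulate_community <- function(spec) {
    stopifnot(inherits(spec, "community_spec"))
    with_seed(spec$seed, {
        L <- spec$chromosome_length
        ancestor <- random_dna(L)
        shared_len <- round(spec$shared_segment_fraction * L)
        shared_start <- if (shared_len > 0)
            sample.int(L - shared_len + 1L, 1L) else NA_integer_
        protect <- if (shared_len > 0) {
            pr <- rep(FALSE, L)
            pr[shared_start:(shared_start + shared_len - 1L)] <- TRUE
            pr
        } else NULL

        plasmid_seqs <- lapply(spec$plasmids, function(p)
            random_dna(p$length))
        rep_seq <- if (!is.null(spec$chrom_plasmid_repeat))
            random_dna(spec$chrom_plasmid_repeat$length) else NULL
        rep_at <- if (!is.null(rep_seq))
            sample.int(L + 1L, 1L) else NA_integer_

        iso_ids <- sprintf("isolate%02d", seq_len(spec$n_isolates))
        isolates <- lapply(seq_len(spec$n_isolates), function(i) {
            chrom <- mutate_seq(ancestor, spec$pairwise_divergence, protect)
            if (!is.null(rep_seq)) chrom <- splice_in(chrom, rep_seq, rep_at)
            contigs <- c(chromosome = chrom)
            weights <- c(chromosome = nchar(chrom))
            for (j in seq_along(spec$plasmids)) {
                p <- spec$plasmids[[j]]
                carriers <- if (identical(p$shared_across, "all"))
                    seq_len(spec$n_isolates) else p$shared_across
                if (!(i %in% carriers)) next
                ps <- plasmid_seqs[[j]]
                if (j == 1L && !is.null(rep_seq))
                    ps <- splice_in(ps, rep_seq,
                                    sample.int(nchar(ps) + 1L, 1L))
                nm <- paste0("plasmid", j)
                contigs[nm] <- ps
                weights[nm] <- nchar(ps) * (p$copy_number %||% 1)
            }
            list(contigs = contigs, weights = weights)
        })
        names(isolates) <- iso_ids
        structure(list(
            isolates = isolates, spec = spec,
            manifest = list(shared_start = shared_start,
                            shared_length = shared_len,
                            repeat_at = rep_at,
                            repeat_length = if (is.null(rep_seq)) 0L
                                            else nchar(rep_seq))),
            class = "community")
    })
}

#' @export
print.community <- function(x, ...) {
    cat("synthetic community:", length(x$isolates), "isolates,",
        x$spec$chromosome_length, "bp chromosome, divergence",
        x$spec$pairwise_divergence, "\n")
    invisible(x)
}

#' Short-read simulation parameters
#'
#' Defaults mirror a typical Illumina simulation: 2 x 150 bp pairs, outer
#' distance 278 +- 128, substitution errors at 0.005 per base, no indels,
#' 300 Mb per isolate (scale `yield_bp` down for quick runs).
#'
#' @param base_error_rate per-base substitution error rate.
#' @param read_length_1,read_length_2 read lengths in bp.
#' @param outer_distance mean outer distance between the pair's ends (bp).
#' @param sd standard deviation of the outer distance.
#' @param yield_bp total sequenced bases per isolate.
#' @return object of class `short_read_params`.
#' @export
short_read_params <- function(base_error_rate = 0.005,
                              read_length_1 = 150L, read_length_2 = 150L,
                              outer_distance = 278L, sd = 128,
                              yield_bp = 3e8) {
    stopifnot(base_error_rate >= 0, base_error_rate < 1,
              read_length_1 > 0, read_length_2 > 0,
              outer_distance > 0, sd > 0, yield_bp > 0)
    structure(list(base_error_rate = base_error_rate,
                   read_length_1 = as.integer(read_length_1),
                   read_length_2 = as.integer(read_length_2),
                   outer_distance = as.integer(outer_distance), sd = sd,
                   yield_bp = yield_bp),
              class = "short_read_params")
}

#' Simulate paired-end short reads
#'
#' Fragments start uniformly on a length-weighted random contig; the outer
#' distance is Normal(`outer_distance`, `sd`) truncated to at least the
#' read lengths and at most the contig length; one read comes from each
#' fragment end, on opposite strands, with the pair orientation flipped at
#' random; substitution errors are i.i.d. at `base_error_rate`. Total
#' bases hit `yield_bp` to within one read pair.
#'
#' @param genome character vector of contig sequences.
#' @param params a [short_read_params()].
#' @param seed optional RNG seed.
#' @param read_prefix prefix for read names (`<prefix>_<i>/1`, `/2`).
#' @param weights optional per-contig sampling weights (default contig
#'   lengths).
#' @param circular sample fragments across the origin (default `TRUE`:
#'   bacterial replicons are circular, and linear sampling would taper
#'   coverage at the artificial contig ends, biasing the k-mer index
#'   built from these reads). Set `FALSE` for genuinely linear contigs;
#'   fragment starts then stay within the contig.
#' @return list with `r1`, `r2` (named character vectors) and `meta`
#'   (data.frame: pair id, contig, fragment start, insert size, strand
#'   flip, substitution counts; a fragment of a circular contig may run
#'   past the contig end, wrapping to its start).
#' @export
simulate_short_reads <- function(genome, params = short_read_params(),
                                 seed = NULL, read_prefix = "sr",
                                 weights = NULL, circular = TRUE) {
    stopifnot(inherits(params, "short_read_params"))
    genome <- as.character(genome)
    lens <- nchar(genome)
    rl <- max(params$read_length_1, params$read_length_2)
    if (max(lens) < params$outer_distance)
        stop("genome too short: longest contig (", max(lens),
             " bp) is below the outer distance (", params$outer_distance,
             " bp)")
    usable <- lens >= params$outer_distance
    w <- (weights %||% lens) * usable
    n_pairs <- max(1L, round(params$yield_bp /
                             (params$read_length_1 + params$read_length_2)))
    with_seed(seed, {
        ci <- sample.int(length(genome), n_pairs, replace = TRUE, prob = w)
        ins <- as.integer(round(stats::rnorm(n_pairs,
                                             params$outer_distance,
                                             params$sd)))
        ins <- pmax(ins, rl)
        ins <- pmin(ins, lens[ci])
        span <- if (circular) lens[ci] else lens[ci] - ins + 1L
        start <- 1L + as.integer(floor(stats::runif(n_pairs) * span))
        frag_end <- start + ins - 1L
        src <- if (circular) paste0(genome, genome)[ci] else genome[ci]
        left <- substring(src, start, start + params$read_length_1 - 1L)
        right <- rev_comp(substring(src,
                                    frag_end - params$read_length_2 + 1L,
                                    frag_end))
        flip <- stats::runif(n_pairs) < 0.5
        r1 <- ifelse(flip, right, left)
        r2 <- ifelse(flip, left, right)
        m1 <- cpp_mutate_subs(r1, params$base_error_rate)
        m2 <- cpp_mutate_subs(r2, params$base_error_rate)
        ids <- paste0(read_prefix, "_", seq_len(n_pairs))
        list(r1 = stats::setNames(m1$seqs, paste0(ids, "/1")),
             r2 = stats::setNames(m2$seqs, paste0(ids, "/2")),
             meta = data.frame(pair_id = ids,
                               contig = names(genome)[ci] %||% ci,
                               start = start, insert = ins, flip = flip,
                               n_sub_1 = m1$n_sub, n_sub_2 = m2$n_sub,
                               stringsAsFactors = FALSE))
    })
}

#' Long-read simulation parameters
#'
#' Defaults reproduce a Nanopore-like run: read lengths from a
#' Normal(8370, 6389) truncated to \[230, 61011\], mean accuracy 0.88
#' (12% errors split 1:1:1 between substitutions, insertions and
#' deletions), and a 5 Gb flow-cell yield that is divided evenly across
#' the pooled isolates.
#'
#' @param length_mean,length_sd,length_min,length_max read length model
#'   (bp).
#' @param accuracy_mean mean per-base accuracy in (0, 1\].
#' @param error_mix relative weights of substitution, insertion and
#'   deletion errors.
#' @param total_yield_bp total pooled yield in bp.
#' @return object of class `long_read_params`.
#' @export
long_read_params <- function(length_mean = 8370, length_sd = 6389,
                             length_min = 230, length_max = 61011,
                             accuracy_mean = 0.88,
                             error_mix = c(sub = 1, ins = 1, del = 1),
                             total_yield_bp = 5e9) {
    stopifnot(length_min <= length_mean, length_mean <= length_max,
              length_sd > 0, accuracy_mean > 0, accuracy_mean <= 1,
              length(error_mix) == 3L, all(error_mix >= 0),
              sum(error_mix) > 0, total_yield_bp > 0)
    structure(list(length_mean = length_mean, length_sd = length_sd,
                   length_min = length_min, length_max = length_max,
                   accuracy_mean = accuracy_mean,
                   error_mix = error_mix / sum(error_mix),
                   total_yield_bp = total_yield_bp),
              class = "long_read_params")
}

# truncated-normal sampler by rejection
rtruncnorm_rej <- function(n, mean, sd, lo, hi) {
    out <- numeric(0)
    while (length(out) < n) {
        x <- stats::rnorm(max(n * 2L, 100L), mean, sd)
        out <- c(out, x[x >= lo & x <= hi])
    }
    out[seq_len(n)]
}

#' Simulate long reads from one genome
#'
#' Read lengths are drawn from the truncated normal of the
#' [long_read_params()] (the upper bound additionally capped at the contig
#' length); start positions are uniform on a length-weighted random
#' contig; strands are uniform; errors are i.i.d. per base at rate
#' `1 - accuracy_mean`, split by `error_mix`. Reads are emitted until the
#' cumulative template bases reach `yield_bp`.
#'
#' @param genome character vector of contig sequences.
#' @param params a [long_read_params()].
#' @param yield_bp bases to emit for this genome.
#' @param seed optional RNG seed.
#' @param read_prefix prefix for read names.
#' @param weights optional per-contig sampling weights (default lengths).
#' @param circular sample reads across the origin (default `TRUE`, as for
#'   [simulate_short_reads()]); a read of a circular contig may wrap past
#'   the contig end.
#' @return list with `reads` (named character vector) and `truth`
#'   (data.frame: read_id, contig, start, template_length, strand).
#' @export
simulate_long_reads <- function(genome, params = long_read_params(),
                                yield_bp, seed = NULL, read_prefix = "lr",
                                weights = NULL, circular = TRUE) {
    stopifnot(inherits(params, "long_read_params"), yield_bp > 0)
    genome <- as.character(genome)
    if (!length(genome) || any(nchar(genome) == 0L))
        stop("empty genome")
    lens <- nchar(genome)
    w <- weights %||% lens
    hi <- min(params$length_max, max(lens))
    lo <- min(params$length_min, hi)
    with_seed(seed, {
        n_guess <- max(16L, ceiling(yield_bp / params$length_mean * 1.3))
        lengths <- integer(0)
        repeat {
            lengths <- c(lengths,
                         as.integer(round(rtruncnorm_rej(
                             n_guess, params$length_mean, params$length_sd,
                             lo, hi))))
            if (sum(lengths) >= yield_bp) break
        }
        n <- which(cumsum(as.numeric(lengths)) >= yield_bp)[1L]
        lengths <- lengths[seq_len(n)]
        ci <- sample.int(length(genome), n, replace = TRUE, prob = w)
        lengths <- pmin(lengths, lens[ci])
        span <- if (circular) lens[ci] else lens[ci] - lengths + 1L
        start <- 1L + as.integer(floor(stats::runif(n) * span))
        tmpl <- if (circular) {
            substring(paste0(genome[ci], genome[ci]), start,
                      start + lengths - 1L)
        } else {
            substring(genome[ci], start, start + lengths - 1L)
        }
        strand <- stats::runif(n) < 0.5
        tmpl[strand] <- rev_comp(tmpl[strand])
        e <- 1 - params$accuracy_mean
        rates <- e * params$error_mix
        reads <- cpp_mutate_mixed(tmpl, rates[1L], rates[2L], rates[3L])
        ids <- paste0(read_prefix, "_", seq_len(n))
        list(reads = stats::setNames(as.character(reads), ids),
             truth = data.frame(read_id = ids,
                                contig = names(genome)[ci] %||% ci,
                                start = start, template_length = lengths,
                                strand = ifelse(strand, "-", "+"),
                                stringsAsFactors = FALSE))
    })
}

#' Simulate a pooled long-read run over a community
#'
#' Splits the flow-cell yield evenly across isolates
#' (`total_yield_bp / n_isolates` each) and simulates each isolate's reads
#' from one seeded RNG stream.
#'
#' @param community a `community` from [simulate_community()].
#' @param params a [long_read_params()].
#' @param seed optional RNG seed.
#' @return list with `reads` (named character vector over all isolates)
#'   and `truth` (data.frame with `read_id`, `sample_id` plus the
#'   per-read coordinates).
#' @export
simulate_long_read_pool <- function(community, params = long_read_params(),
                                    seed = NULL) {
    stopifnot(inherits(community, "community"))
    n <- length(community$isolates)
    per_iso <- params$total_yield_bp / n
    with_seed(seed, {
        parts <- lapply(names(community$isolates), function(id) {
            iso <- community$isolates[[id]]
            sim <- simulate_long_reads(iso$contigs, params, per_iso,
                                       read_prefix = paste0(id, "_lr"),
                                       weights = iso$weights)
            sim$truth$sample_id <- id
            sim
        })
        reads <- unlist(lapply(parts, `[[`, "reads"))
        truth <- do.call(rbind, lapply(parts, `[[`, "truth"))
        truth <- truth[, c("read_id", "sample_id", "contig", "start",
                           "template_length", "strand")]
        list(reads = reads, truth = truth)
    })
}

#' Run the full pipeline on synthetic data
#'
#' Simulates a community, per-isolate short reads and a pooled long-read
#' run; builds the cleaned sample indexes; classifies the pool; and
#' evaluates the assignments against the simulation truth.
#'
#' @param spec a [community_spec()].
#' @param short_params a [short_read_params()] (per-isolate `yield_bp`).
#' @param long_params a [long_read_params()] (pooled `total_yield_bp`).
#' @param config an [index_config()].
#' @param count_mode,min_hits see [classify_pool()].
#' @param n_delta mis-assigned reads to sample for the delta edit
#'   distance analysis.
#' @param seed master seed; every stage draws from the one stream it
#'   starts.
#' @return list with `report` (a `kmerplex_eval`), `assignments`, `truth`,
#'   `community`, `summary`, and `index_stats` (raw/cleaned k-mer counts
#'   per sample).
#' @export
run_end_to_end <- function(spec, short_params = short_read_params(),
                           long_params = long_read_params(),
                           config = index_config(),
                           count_mode = "per_window", min_hits = 0,
                           n_delta = 100, seed = 1) {
    stopifnot(inherits(spec, "community_spec"))
    with_seed(seed, {
        community <- simulate_community(spec)
        indexes <- lapply(names(community$isolates), function(id) {
            sr <- simulate_short_reads(community$isolates[[id]]$contigs,
                                       short_params,
                                       read_prefix = paste0(id, "_sr"),
                                       weights =
                                           community$isolates[[id]]$weights)
            build_index(id, c(sr$r1, sr$r2), config)
        })
        pool <- simulate_long_read_pool(community, long_params)
        cls <- classify_pool(pool$reads, indexes, seed = sample.int(2^30, 1),
                             count_mode = count_mode, min_hits = min_hits)
        genomes <- lapply(community$isolates, `[[`, "contigs")
        report <- evaluate_assignments(cls$assignments, pool$truth,
                                       genomes = genomes,
                                       reads = pool$reads,
                                       n_delta = n_delta,
                                       seed = sample.int(2^30, 1))
        list(report = report, assignments = cls$assignments,
             truth = pool$truth, community = community,
             summary = cls$summary,
             index_stats = data.frame(
                 sample_id = vapply(indexes, `[[`, character(1),
                                    "sample_id"),
                 n_raw_kmers = vapply(indexes, `[[`, integer(1),
                                      "n_raw_kmers"),
                 n_cleaned_kmers = vapply(indexes, `[[`, integer(1),
                                          "n_cleaned_kmers")))
    })
}
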