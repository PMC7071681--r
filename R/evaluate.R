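# Evaluation statistics: classification accuracy, ends-free delta edit
# distance, Phred-scaled QV conversion, k-mer survival model.

as_truth <- function(truth) {
    if (is.data.frame(truth)) {
        stopifnot(all(c("read_id", "sample_id") %in% names(truth)))
        stats::setNames(as.character(truth$sample_id),
                        as.character(truth$read_id))
    } else if (is.character(truth) && !is.null(names(truth))) {
        truth
    } else stop("truth must be a data.frame(read_id, sample_id) or a ",
                "named character vector")
}

#' Read-classification accuracy against a truth table
#'
#' A read counts as correctly assigned if and only if it was assigned to
#' the sample it originated from. Also returns the confusion matrix of
#' true source (rows) against assigned sample (columns); row sums equal
#' the per-source read counts.
#'
#' @param assignments data.frame from [classify_pool()] (needs `read_id`
#'   and `assigned_sample`).
#' @param truth data.frame with columns `read_id`, `sample_id`, or a named
#'   character vector mapping read ids to source samples.
#' @return list with `accuracy`, `n_reads`, `n_correct`, `confusion`.
#' @export
classification_accuracy <- function(assignments, truth) {
    truth <- as_truth(truth)
    ids <- assignments$read_id
    missing <- setdiff(ids, names(truth))
    if (length(missing))
        stop("reads missing from truth table: ",
             paste(utils::head(missing, 5), collapse = ", "),
             if (length(missing) > 5) sprintf(" (+%d more)",
                                              length(missing) - 5))
    src <- unname(truth[ids])
    asg <- assignments$assigned_sample
    lev <- sort(unique(c(src, asg)))
    confusion <- table(factor(src, levels = lev),
                       factor(asg, levels = lev), dnn = c("true", "assigned"))
    n_correct <- sum(src == asg)
    list(accuracy = n_correct / length(ids), n_reads = length(ids),
         n_correct = n_correct, confusion = unclass(confusion))
}

#' Ends-free (infix) edit distance of a read against a genome
#'
#' Minimum Levenshtein distance between the read and any contiguous
#' substring of the genome: the read aligns globally while gaps flanking
#' the genome are free. Exact (bit-parallel dynamic programming), not a
#' heuristic. Multi-contig genomes (chromosome plus plasmids) are searched
#' contig by contig and the minimum is taken; by default both genome
#' strands are searched.
#'
#' @param read a single DNA string.
#' @param genome character vector of contig sequences.
#' @param both_strands search the reverse complement too (default `TRUE`).
#' @return integer edit distance.
#' @export
ends_free_edit_distance <- function(read, genome, both_strands = TRUE) {
    stopifnot(length(read) == 1L, nchar(read) > 0L, length(genome) >= 1L,
              all(nchar(genome) > 0L))
    read <- as.character(read)
    d <- min(vapply(genome, function(g) cpp_infix_edit(read, g), integer(1)))
    if (both_strands && d > 0L) {
        rc <- rev_comp(read)
        d <- min(d, vapply(genome, function(g) cpp_infix_edit(rc, g),
                           integer(1)))
    }
    d
}

#' Delta edit distance of a mis-assigned read
#'
#' `delta = (d1 - d2) / read_length`, where `d1` is the read's ends-free
#' edit distance to the genome it came from and `d2` the distance to the
#' genome it was assigned to. Negative values mean the source genome
#' aligns strictly better; 0 means the two genomes are indistinguishable
#' at the read's locus (identical genomes give exactly 0).
#'
#' @param read a single DNA string.
#' @param source_genome,assigned_genome character vectors of contigs.
#' @param read_id optional identifier carried into the record.
#' @return one-row data.frame: `read_id`, `d1`, `d2`, `read_length`,
#'   `delta`.
#' @export
delta_edit_distance <- function(read, source_genome, assigned_genome,
                                read_id = NA_character_) {
    d1 <- ends_free_edit_distance(read, source_genome)
    d2 <- ends_free_edit_distance(read, assigned_genome)
    data.frame(read_id = read_id, d1 = d1, d2 = d2,
               read_length = nchar(read),
               delta = (d1 - d2) / nchar(read),
               stringsAsFactors = FALSE)
}

#' Sample mis-assigned reads
#'
#' Uniform sample without replacement of up to `n` mis-assigned reads
#' (fewer if fewer exist), seeded for reproducibility.
#'
#' @param assignments data.frame from [classify_pool()].
#' @param truth as in [classification_accuracy()].
#' @param n sample size (default 100, the size used for the delta edit
#'   distance analysis).
#' @param seed optional RNG seed.
#' @return character vector of sampled read ids (empty, with a message,
#'   when nothing was mis-assigned).
#' @export
sample_misassigned <- function(assignments, truth, n = 100, seed = NULL) {
    truth <- as_truth(truth)
    src <- unname(truth[assignments$read_id])
    mis <- assignments$read_id[!is.na(src) &
                               assignments$assigned_sample != src]
    if (!length(mis)) {
        message("no mis-assigned reads")
        return(character(0))
    }
    if (length(mis) <= n) return(mis)
    with_seed(seed, mis[sample.int(length(mis), n)])
}

#' Phred-scaled QV from an average SNP count
#'
#' `QV = round(-10 * log10(avg_snps_per_genome / avg_reference_genome_size))`
#' with rounding half away from zero. An average of 0 SNPs yields `Inf`
#' (a perfect-consensus sentinel) rather than an error.
#'
#' @param avg_snps_per_genome non-negative average number of SNPs between
#'   assembly and reference, per genome.
#' @param avg_reference_genome_size positive average reference genome size
#'   in bp.
#' @return integer QV (or `Inf`).
#' @export
qv_score <- function(avg_snps_per_genome, avg_reference_genome_size) {
    if (any(avg_snps_per_genome < 0) || any(avg_reference_genome_size <= 0))
        stop("SNP count must be >= 0 and genome size > 0")
    x <- -10 * log10(avg_snps_per_genome / avg_reference_genome_size)
    ifelse(is.infinite(x) & x > 0, Inf, sign(x) * floor(abs(x) + 0.5))
}

#' Expected k-mer survival rate
#'
#' Probability `(1 - e)^k` that a k-mer of an error-prone read is
#' error-free, given per-base error rate `e`. The choice of k trades the
#' number of sample-specific k-mers against this survival rate.
#'
#' @param e per-base error rate in `[0, 1)`.
#' @param k k-mer length.
#' @return survival probability in `(0, 1]`.
#' @export
kmer_survival <- function(e, k = 19L) {
    if (any(e < 0) || any(e >= 1)) stop("e must be in [0, 1)")
    (1 - e)^k
}

#' Full evaluation report for a classified pool
#'
#' Combines [classification_accuracy()], the delta edit distance analysis
#' of a seeded sample of mis-assigned reads, and optional SNP-count-to-QV
#' conversions.
#'
#' @param assignments data.frame from [classify_pool()].
#' @param truth as in [classification_accuracy()].
#' @param genomes named list (by sample id) of character vectors of contig
#'   sequences; needed for the delta edit distance analysis.
#' @param reads named character vector of the classified read sequences.
#' @param n_delta number of mis-assigned reads to sample (default 100).
#' @param seed RNG seed for the sampling step.
#' @param qv_entries optional data.frame with columns
#'   `avg_snps_per_genome`, `avg_reference_genome_size` to convert.
#' @return object of class `kmerplex_eval`: `n_reads`, `n_correct`,
#'   `accuracy`, `confusion`, `delta_edit` (data.frame of records),
#'   `delta_edit_mean`, `fraction_delta_zero`, `qv_entries`.
#' @export
evaluate_assignments <- function(assignments, truth, genomes = NULL,
                                 reads = NULL, n_delta = 100, seed = 42,
                                 qv_entries = NULL) {
    acc <- classification_accuracy(assignments, truth)
    truth_vec <- as_truth(truth)

    delta <- data.frame(read_id = character(0), d1 = integer(0),
                        d2 = integer(0), read_length = integer(0),
                        delta = numeric(0), stringsAsFactors = FALSE)
    if (!is.null(genomes) && !is.null(reads)) {
        mis <- sample_misassigned(assignments, truth, n = n_delta,
                                  seed = seed)
        if (length(mis)) {
            asg <- stats::setNames(assignments$assigned_sample,
                                   assignments$read_id)
            delta <- do.call(rbind, lapply(mis, function(id)
                delta_edit_distance(reads[[id]],
                                    genomes[[truth_vec[[id]]]],
                                    genomes[[asg[[id]]]],
                                    read_id = id)))
        }
    }
    if (!is.null(qv_entries)) {
        qv_entries$qv <- qv_score(qv_entries$avg_snps_per_genome,
                                  qv_entries$avg_reference_genome_size)
    }
    structure(list(
        n_reads = acc$n_reads, n_correct = acc$n_correct,
        accuracy = acc$accuracy, confusion = acc$confusion,
        delta_edit = delta,
        delta_edit_mean = if (nrow(delta)) mean(delta$delta) else NA_real_,
        fraction_delta_zero = if (nrow(delta)) mean(delta$delta == 0)
                              else NA_real_,
        qv_entries = qv_entries
    ), class = "kmerplex_eval")
}

#' @export
print.kmerplex_eval <- function(x, ...) {
    cat("read classification: ", x$n_correct, "/", x$n_reads,
        " correct (accuracy ", sprintf("%.4f", x$accuracy), ")\n", sep = "")
    if (nrow(x$delta_edit))
        cat("delta edit distance over ", nrow(x$delta_edit),
            " sampled mis-assigned reads: mean ",
            sprintf("%.4f", x$delta_edit_mean), ", fraction exactly 0: ",
            sprintf("%.2f", x$fraction_delta_zero), "\n", sep = "")
    invisible(x)
}
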