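#' Two-variant transcript model for simulation
#'
#' Describes one variant of a two-variant locus: a span shared with the
#' other variant (upstream, transcribed first) followed by a
#' variant-specific discriminating span that carries one or more polyA
#' sites. A transcript molecule runs from the start of the shared span to
#' a polyA site drawn from the usage probabilities, so alternative sites
#' produce 3'UTRs of different lengths.
#'
#' @param variant_id Variant label.
#' @param chrom Contig name.
#' @param shared_start,shared_end Shared span, 1-based inclusive.
#' @param disc_start,disc_end Discriminating span, 1-based inclusive; must
#'   lie downstream of the shared span.
#' @param polya_sites Genomic positions of polyA sites, inside the
#'   discriminating span.
#' @param polya_usage Usage probabilities, summing to 1.
#' @return A `transcript_model` list.
#' @export
transcript_model <- function(variant_id, chrom, shared_start, shared_end,
                             disc_start, disc_end,
                             polya_sites = disc_end, polya_usage = 1) {
  stopifnot(shared_start <= shared_end, disc_start <= disc_end,
            disc_start > shared_end,
            all(polya_sites >= disc_start), all(polya_sites <= disc_end),
            length(polya_sites) == length(polya_usage),
            all(polya_usage >= 0), abs(sum(polya_usage) - 1) < 1e-9)
  structure(list(
    variant_id = variant_id, chrom = chrom,
    shared_start = shared_start, shared_end = shared_end,
    disc_start = disc_start, disc_end = disc_end,
    shared_len = shared_end - shared_start + 1,
    disc_len = disc_end - disc_start + 1,
    polya_sites = polya_sites, polya_usage = polya_usage
  ), class = "transcript_model")
}

#' Default two-variant locus geometry
#'
#' A locus emulating a gene whose two co-transcribed variants share an
#' upstream span and differ in their 3' ends: the "long-UTR" variant (A)
#' carries a 5819 bp discriminating span ending at a single terminal polyA
#' site, while the "short-UTR" variant (B) carries a 1900 bp discriminating
#' span with two polyA sites (a proximal one 400 bp in and a distal one at
#' the end) used by a 30/70 split, so both truncated and full-length 3'UTRs
#' are produced. Coordinates live on a synthetic contig so no genome build
#' is implied.
#'
#' @param chrom Contig name, default `"sim1"`.
#' @return A list of two [transcript_model] objects (`A`, `B`).
#' @export
braf_like_models <- function(chrom = "sim1") {
  list(
    A = transcript_model("V204like", chrom,
                         shared_start = 1001, shared_end = 3000,
                         disc_start = 9001, disc_end = 14819,
                         polya_sites = 14819, polya_usage = 1),
    B = transcript_model("V220like", chrom,
                         shared_start = 1001, shared_end = 3000,
                         disc_start = 4001, disc_end = 5900,
                         polya_sites = c(4400, 5900),
                         polya_usage = c(0.3, 0.7))
  )
}

#' Region specification matching a pair of transcript models
#'
#' @param models A list of two [transcript_model] objects.
#' @return A [region_spec] covering each model's discriminating span.
#' @export
models_region_spec <- function(models) {
  region_spec(data.frame(
    variant_id = vapply(models, `[[`, character(1), "variant_id"),
    chrom = vapply(models, `[[`, character(1), "chrom"),
    start = vapply(models, `[[`, numeric(1), "disc_start"),
    end = vapply(models, `[[`, numeric(1), "disc_end"),
    strand = "+", stringsAsFactors = FALSE
  ))
}

# Discretized fragment-length distribution actually used by the simulator:
# round(rnorm(mu, sd)) floored at read_length. Returns integer support and
# probabilities.
fragment_length_pmf <- function(fragment_length = c(250, 30), read_length = 100L) {
  mu <- fragment_length[1]; sd <- fragment_length[2]
  lo <- max(read_length, floor(mu - 6 * sd))
  hi <- ceiling(mu + 6 * sd)
  k <- lo:hi
  p <- stats::pnorm(k + 0.5, mu, sd) - stats::pnorm(k - 0.5, mu, sd)
  p[1] <- stats::pnorm(lo + 0.5, mu, sd)  # mass floored at the minimum
  list(len = k, prob = p / sum(p))
}

#' Probability that a simulated fragment covers its discriminating span
#'
#' Closed-form expectation under the simulator's geometry: a fragment of
#' length f starting uniformly on a transcript of length L (shared length
#' S, discriminating suffix of length L - S) touches the discriminating
#' span with at least one sequenced base iff its 3' read reaches past the
#' junction, which happens for `min(L - f + 1, L - S)` of the `L - f + 1`
#' start positions. Averaged over the fragment-length distribution and the
#' polyA-site usage.
#'
#' @param model A [transcript_model].
#' @param fragment_length `(mean, sd)` of the fragment length.
#' @param read_length Read length in bp.
#' @return A probability in (0, 1].
#' @export
disc_overlap_prob <- function(model, fragment_length = c(250, 30), read_length = 100L) {
  pmf <- fragment_length_pmf(fragment_length, read_length)
  S <- model$shared_len
  p_total <- 0
  for (s in seq_along(model$polya_sites)) {
    L <- S + (model$polya_sites[s] - model$disc_start + 1)
    elig <- pmin(L - pmf$len + 1, L - S)
    elig[pmf$len > L] <- 0
    p_total <- p_total + model$polya_usage[s] *
      sum(pmf$prob * elig / pmax(L - pmf$len + 1, 1))
  }
  p_total
}

# Map transcript-coordinate spans [a, b] (vectorized) of one model to SAM
# POS and CIGAR, inserting an N gap when a span crosses the shared/disc
# junction.
transcript_span_to_sam <- function(model, a, b) {
  S <- model$shared_len
  gap <- model$disc_start - model$shared_end - 1
  pos <- ifelse(a <= S, model$shared_start + a - 1,
                model$disc_start + (a - S - 1))
  crosses <- a <= S & b > S
  w1 <- pmin(b, S) - a + 1
  w2 <- b - pmax(a, S + 1) + 1
  cigar <- ifelse(crosses,
                  sprintf("%dM%dN%dM", w1, gap, w2),
                  sprintf("%dM", b - a + 1))
  end <- ifelse(b <= S, model$shared_start + b - 1,
                model$disc_start + (b - S - 1))
  list(pos = as.integer(pos), cigar = cigar, end = as.integer(end))
}

sim_sam_header <- function(chrom, contig_len = 20000L) {
  c("@HD\tVN:1.6\tSO:unsorted",
    sprintf("@SQ\tSN:%s\tLN:%d", chrom, contig_len))
}

write_sim_bam <- function(sam_lines, out_prefix) {
  sam_path <- paste0(out_prefix, ".sam")
  writeLines(sam_lines, sam_path)
  bam <- Rsamtools::asBam(sam_path, destination = out_prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam_path)
  bam
}

#' Simulate a two-variant paired-end sample as an aligned BAM
#'
#' Draws `n_fragments` fragments from a mixture of the two variants
#' (variant A with probability `pi`), truncates each molecule at a polyA
#' site drawn from the model's usage probabilities, places the fragment
#' uniformly on the resulting transcript, and writes the two mates as a
#' coordinate-sorted, indexed BAM on the models' contig. Fragments
#' spanning the shared/discriminating junction become split (N-gap)
#' alignments. A ground-truth sidecar records the mixture proportion and
#' the closed-form expected region counts.
#'
#' @param models List of two [transcript_model] objects; the first is
#'   variant A.
#' @param pi Mixture proportion of variant A, in `[0, 1]`.
#' @param n_fragments Number of fragments, >= 1.
#' @param fragment_length `(mean, sd)` of fragment length in bp.
#' @param read_length Read length in bp.
#' @param seed Integer RNG seed; identical seeds give identical output.
#' @param out_prefix Output path prefix (`<prefix>.bam`, `<prefix>.bam.bai`,
#'   `<prefix>.truth.tsv`).
#' @param contig_len Declared contig length in the BAM header.
#' @return A list: `bam` (path) and `truth` (list with `sample_id`, `pi`,
#'   `n_fragments`, `seed`, `expected_counts`).
#' @export
simulate_two_variant_sample <- function(models, pi, n_fragments,
                                        fragment_length = c(250, 30),
                                        read_length = 100L,
                                        seed = 1L,
                                        out_prefix = tempfile("sim"),
                                        contig_len = 20000L) {
  stopifnot(pi >= 0, pi <= 1, n_fragments >= 1)
  set.seed(seed)
  n <- as.integer(n_fragments)
  vi <- 1L + stats::rbinom(n, 1L, 1 - pi)  # 1 = variant A w.p. pi
  L <- numeric(n)
  for (m in 1:2) {
    idx <- which(vi == m)
    if (!length(idx)) next
    model <- models[[m]]
    site <- sample.int(length(model$polya_sites), length(idx), replace = TRUE,
                       prob = model$polya_usage)
    L[idx] <- model$shared_len + (model$polya_sites[site] - model$disc_start + 1)
  }
  f <- pmax(as.integer(round(stats::rnorm(n, fragment_length[1], fragment_length[2]))),
            as.integer(read_length))
  over <- f > L
  tries <- 0L
  while (any(over)) {
    tries <- tries + 1L
    if (tries > 100L) stop("fragment longer than transcript after 100 resampling rounds")
    f[over] <- pmax(as.integer(round(stats::rnorm(sum(over), fragment_length[1],
                                                  fragment_length[2]))),
                    as.integer(read_length))
    over <- f > L
  }
  s <- 1L + as.integer(floor(stats::runif(n) * (L - f + 1)))
  qname <- sprintf("frag%07d", seq_len(n))
  rl <- as.integer(read_length)
  records <- character(2L * n)
  seq_str <- strrep("A", rl)
  for (m in 1:2) {
    idx <- which(vi == m)
    if (!length(idx)) next
    model <- models[[m]]
    r1 <- transcript_span_to_sam(model, s[idx], s[idx] + rl - 1L)
    r2 <- transcript_span_to_sam(model, s[idx] + f[idx] - rl, s[idx] + f[idx] - 1L)
    tlen <- r2$end - r1$pos + 1L
    records[2L * idx - 1L] <- sprintf(
      "%s\t99\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
      qname[idx], model$chrom, r1$pos, r1$cigar, r2$pos, tlen, seq_str)
    records[2L * idx] <- sprintf(
      "%s\t147\t%s\t%d\t60\t%s\t=\t%d\t%d\t%s\t*",
      qname[idx], model$chrom, r2$pos, r2$cigar, r1$pos, -tlen, seq_str)
  }
  bam <- write_sim_bam(c(sim_sam_header(models[[1]]$chrom, contig_len), records),
                       out_prefix)
  p_disc <- vapply(models, disc_overlap_prob,
                   numeric(1), fragment_length = fragment_length,
                   read_length = read_length)
  expected <- c(n * pi * p_disc[1], n * (1 - pi) * p_disc[2])
  names(expected) <- vapply(models, `[[`, character(1), "variant_id")
  truth <- list(sample_id = basename(out_prefix), pi = pi, n_fragments = n,
                seed = seed, expected_counts = expected)
  truth_df <- data.frame(sample_id = truth$sample_id, pi = pi, n_fragments = n,
                         seed = seed,
                         variant_id = names(expected),
                         expected_count = as.numeric(expected),
                         stringsAsFactors = FALSE)
  utils::write.table(truth_df, paste0(out_prefix, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(bam = bam, truth = truth)
}

#' Estimate the mixture proportion from region counts
#'
#' Inverts the simulation geometry: each variant's region count is divided
#' by the probability that one of its fragments shows a sequenced base in
#' the discriminating span (from [disc_overlap_prob]), turning counts into
#' estimated fragment totals; the mixture proportion of variant A is then
#' `pi_hat = r_A / (r_A + r_B)`. Library size never enters, so the
#' estimate works on locus-sliced alignments.
#'
#' @param quant A `sample_quant` from [quantify_sample] over
#'   [models_region_spec] regions.
#' @param models The [transcript_model] pair used for simulation; the first
#'   is variant A.
#' @param fragment_length,read_length Values used at simulation time.
#' @return `pi_hat` in `[0, 1]`, or `NA` (with a warning) when both counts
#'   are zero.
#' @export
estimate_mixture <- function(quant, models, fragment_length = c(250, 30),
                             read_length = 100L) {
  ids <- vapply(models, `[[`, character(1), "variant_id")
  q <- stats::setNames(quant$count, quant$variant_id)[ids]
  if (anyNA(q)) stop("quantification is missing variants: ",
                     paste(ids[is.na(q)], collapse = ", "))
  p <- vapply(models, disc_overlap_prob, numeric(1),
              fragment_length = fragment_length, read_length = read_length)
  r <- q / p
  if (sum(r) == 0) {
    warning("both region counts are zero; mixture proportion undefined")
    return(NA_real_)
  }
  unname(r[1] / sum(r))
}

#' Simulate 3'-end (QuantSeq REV style) reads around polyA sites
#'
#' Each read's 3' end is placed at a polyA site chosen by usage
#' probability, jittered by a normal positional spread, and the read
#' extends `read_length` bp upstream, so coverage piles up in peaks at the
#' planted sites.
#'
#' @param model A [transcript_model] whose polyA sites are simulated.
#' @param n_reads Number of reads (0 allowed: empty BAM).
#' @param read_length Read length in bp, default 60.
#' @param positional_sd Standard deviation of the 3'-end jitter in bp,
#'   default 20.
#' @param seed Integer RNG seed.
#' @param out_prefix Output path prefix.
#' @param contig_len Declared contig length.
#' @return A list: `bam` (path) and `truth` (data.frame of `site`,
#'   `usage`).
#' @export
simulate_quantseq <- function(model, n_reads, read_length = 60L,
                              positional_sd = 20, seed = 1L,
                              out_prefix = tempfile("quantseq"),
                              contig_len = 20000L) {
  stopifnot(n_reads >= 0)
  set.seed(seed)
  n <- as.integer(n_reads)
  records <- character(0)
  if (n > 0L) {
    site <- sample.int(length(model$polya_sites), n, replace = TRUE,
                       prob = model$polya_usage)
    end3 <- model$polya_sites[site] +
      as.integer(round(stats::rnorm(n, 0, positional_sd)))
    end3 <- pmin(pmax(end3, as.integer(read_length)), contig_len)
    pos <- end3 - as.integer(read_length) + 1L
    records <- sprintf("read%07d\t16\t%s\t%d\t60\t%dM\t*\t0\t0\t%s\t*",
                       seq_len(n), model$chrom, pos, as.integer(read_length),
                       strrep("A", read_length))
  }
  bam <- write_sim_bam(c(sim_sam_header(model$chrom, contig_len), records),
                       out_prefix)
  truth <- data.frame(site = model$polya_sites, usage = model$polya_usage)
  utils::write.table(truth, paste0(out_prefix, ".truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  list(bam = bam, truth = truth)
}

#' Simulate an expression cohort with a planted sponge triad
#'
#' Generates a latent signal per sample and plants a ceRNA-style sign
#' pattern on it: the focal transcript follows the latent signal, the
#' planted target increases with it, the planted miRNA decreases with it;
#' every other feature is independent noise. Feeds the correlation screen
#' with known ground truth.
#'
#' @param n_samples Number of samples, >= 10.
#' @param n_noise_transcripts,n_noise_mirnas Number of independent-noise
#'   features in each matrix.
#' @param signal_strength Slope of the planted (anti)correlations, default
#'   0.8.
#' @param noise_sd Standard deviation of the additive noise on planted
#'   features, default 0.5.
#' @param seed Integer RNG seed.
#' @return A list: `focal` (named numeric vector), `targets` and `mirnas`
#'   ([expression_matrix] objects), and `truth` (planted feature ids).
#' @export
simulate_expression_cohort <- function(n_samples = 200L,
                                       n_noise_transcripts = 50L,
                                       n_noise_mirnas = 20L,
                                       signal_strength = 0.8,
                                       noise_sd = 0.5,
                                       seed = 1L) {
  stopifnot(n_samples >= 10)
  set.seed(seed)
  n <- as.integer(n_samples)
  samples <- sprintf("S%03d", seq_len(n))
  z <- stats::rnorm(n)
  focal <- stats::setNames(z, samples)
  attr(focal, "feature_id") <- "focal_tx"
  target <- signal_strength * z + stats::rnorm(n, 0, noise_sd)
  mirna <- -signal_strength * z + stats::rnorm(n, 0, noise_sd)
  tx <- rbind(
    target_planted = target,
    matrix(stats::rnorm(n_noise_transcripts * n), nrow = n_noise_transcripts,
           dimnames = list(sprintf("tx_noise_%02d", seq_len(n_noise_transcripts)), NULL))
  )
  colnames(tx) <- samples
  mi <- rbind(
    mir_planted = mirna,
    matrix(stats::rnorm(n_noise_mirnas * n), nrow = n_noise_mirnas,
           dimnames = list(sprintf("mir_noise_%02d", seq_len(n_noise_mirnas)), NULL))
  )
  colnames(mi) <- samples
  list(
    focal = focal,
    targets = expression_matrix(tx),
    mirnas = expression_matrix(mi),
    truth = list(focal = "focal_tx", target = "target_planted",
                 mirna = "mir_planted", seed = seed)
  )
}
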