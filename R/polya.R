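#' Per-base coverage over a genomic window
#'
#' Builds the per-base read depth of 3'-end sequencing alignments over a
#' window, the input to polyA-site peak calling. Depth at a position is the
#' number of policy-passing reads whose aligned reference span covers it.
#'
#' @param bam Path to a BAM of single-end 3'-end (QuantSeq REV style) reads.
#' @param chrom Chromosome name.
#' @param start,end Window, 1-based inclusive.
#' @param policy A [counting_policy]; only the record-level filters and
#'   `strand_mode` apply (reads are not paired into fragments for coverage).
#' @param sample_id Sample label carried in the track.
#' @param chrom_alias Optional chromosome alias map.
#' @return A `coverage_track` list: `chrom`, `window_start`, `window_end`,
#'   `depth` (integer vector of length `end - start + 1`), `sample_id`.
#' @export
coverage_track <- function(bam, chrom, start, end,
                           policy = counting_policy(),
                           sample_id = basename(bam),
                           chrom_alias = NULL) {
  if (end < start || start < 1) stop("invalid window: ", chrom, ":", start, "-", end)
  window_spec <- region_spec(data.frame(
    variant_id = "window", chrom = chrom, start = start, end = end,
    strand = ".", stringsAsFactors = FALSE))
  rr <- read_region_records(bam, window_spec, policy, chrom_alias)
  aln <- rr$alignments[rr$pass]
  depth <- integer(end - start + 1L)
  if (length(aln)) {
    blocks <- unlist(GenomicAlignments::grglist(aln))
    cov <- GenomicRanges::coverage(blocks)[[as.character(
      GenomicRanges::seqnames(rr$regions)[1])]]
    upto <- min(length(cov), end)
    if (upto >= start) {
      depth[seq_len(upto - start + 1L)] <-
        as.integer(S4Vectors::window(cov, start = start, end = upto))
    }
  }
  structure(list(chrom = chrom, window_start = start, window_end = end,
                 depth = depth, sample_id = sample_id),
            class = "coverage_track")
}

# plain-vector constructor, used by tests and by simulated pipelines
as_coverage_track <- function(depth, chrom = "sim1", start = 1L,
                              sample_id = "sample") {
  depth <- as.integer(depth)
  if (any(depth < 0)) stop("depths must be non-negative")
  structure(list(chrom = chrom, window_start = as.integer(start),
                 window_end = as.integer(start) + length(depth) - 1L,
                 depth = depth, sample_id = sample_id),
            class = "coverage_track")
}

#' Call polyA-site peaks from a coverage track
#'
#' A candidate peak is a maximal contiguous run of positions whose depth
#' exceeds a threshold relative to the most highly covered position of the
#' track; a peak is emitted when the run is at least `min_length` bp long.
#' Both criteria come from 3'-end sequencing practice: the relative height
#' filter removes low-level background and internal priming noise, the
#' length filter removes spurious spikes.
#'
#' @param track A `coverage_track`.
#' @param min_height_fraction Height threshold as a fraction of the track
#'   maximum, in (0, 1]; positions with depth strictly greater than
#'   `min_height_fraction * max(depth)` are above threshold. Default 0.05.
#' @param min_length Minimum peak length in bp, default 80.
#' @param max_gap Runs separated by at most this many below-threshold
#'   positions are merged; default 0 (no smoothing).
#' @param threshold_mode `"per_base"` (default): the run itself must exceed
#'   the threshold at every base. `"peak_max"`: candidate runs are positions
#'   with depth > 0 and a run is kept when its maximum depth exceeds the
#'   threshold.
#' @return A data.frame of peaks: `chrom`, `start`, `end` (1-based
#'   inclusive genomic), `max_depth`, `sample_id`. Zero rows when the track
#'   maximum is 0.
#' @export
call_peaks <- function(track, min_height_fraction = 0.05, min_length = 80L,
                       max_gap = 0L, threshold_mode = c("per_base", "peak_max")) {
  threshold_mode <- match.arg(threshold_mode)
  if (min_height_fraction <= 0 || min_height_fraction > 1) {
    stop("min_height_fraction must be in (0, 1]")
  }
  depth <- track$depth
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      max_depth = integer(), sample_id = character(),
                      stringsAsFactors = FALSE)
  if (!length(depth) || max(depth) == 0L) return(empty)
  threshold <- min_height_fraction * max(depth)
  above <- if (threshold_mode == "per_base") depth > threshold else depth > 0L
  runs <- rle(above)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1L
  cand <- IRanges::IRanges(start = starts[runs$values], end = ends[runs$values])
  if (max_gap > 0L && length(cand) > 1L) {
    cand <- IRanges::reduce(cand, min.gapwidth = max_gap + 1L)
  }
  if (threshold_mode == "peak_max" && length(cand)) {
    keep <- vapply(seq_along(cand), function(i) {
      max(depth[IRanges::start(cand)[i]:IRanges::end(cand)[i]]) > threshold
    }, logical(1))
    cand <- cand[keep]
  }
  cand <- cand[IRanges::width(cand) >= min_length]
  if (!length(cand)) return(empty)
  data.frame(
    chrom = track$chrom,
    start = track$window_start + IRanges::start(cand) - 1L,
    end = track$window_start + IRanges::end(cand) - 1L,
    max_depth = vapply(seq_along(cand), function(i) {
      max(depth[IRanges::start(cand)[i]:IRanges::end(cand)[i]])
    }, integer(1)),
    sample_id = track$sample_id,
    stringsAsFactors = FALSE
  )
}

#' Cross-sample consensus polyA sites
#'
#' Clusters per-sample peaks by single-linkage on >= 1 bp genomic overlap;
#' each cluster becomes a candidate consensus spanning the union of its
#' member intervals, supported by the number of distinct samples that
#' contribute a peak. A consensus site is emitted when its support fraction
#' strictly exceeds `min_support_fraction` (default: present in more than
#' half of the samples).
#'
#' @param per_sample_peaks Named list, one peaks data.frame (from
#'   [call_peaks]) per sample. Samples with zero peaks must still be
#'   present (possibly as zero-row data.frames) so the denominator is the
#'   full cohort.
#' @param min_support_fraction Strict lower bound on
#'   `n_supporting / n_samples`, default 0.5.
#' @return A data.frame of consensus peaks: `chrom`, `start`, `end`,
#'   `n_supporting`, `n_samples`, `support_fraction`.
#' @export
conserved_peaks <- function(per_sample_peaks, min_support_fraction = 0.5) {
  if (!length(per_sample_peaks)) stop("at least one sample is required")
  if (min_support_fraction < 0 || min_support_fraction >= 1) {
    stop("min_support_fraction must be in [0, 1)")
  }
  n_samples <- length(per_sample_peaks)
  if (is.null(names(per_sample_peaks))) {
    names(per_sample_peaks) <- paste0("sample", seq_len(n_samples))
  }
  pooled <- do.call(rbind, lapply(names(per_sample_peaks), function(s) {
    p <- per_sample_peaks[[s]]
    if (is.null(p) || nrow(p) == 0L) return(NULL)
    data.frame(chrom = p$chrom, start = p$start, end = p$end, sample = s,
               stringsAsFactors = FALSE)
  }))
  empty <- data.frame(chrom = character(), start = integer(), end = integer(),
                      n_supporting = integer(), n_samples = integer(),
                      support_fraction = numeric(), stringsAsFactors = FALSE)
  if (is.null(pooled) || nrow(pooled) == 0L) return(empty)
  gr <- GenomicRanges::GRanges(pooled$chrom,
                               IRanges::IRanges(pooled$start, pooled$end))
  # min.gapwidth = 0: merge only intervals that truly share >= 1 bp
  clusters <- GenomicRanges::reduce(gr, min.gapwidth = 0L)
  ov <- GenomicRanges::findOverlaps(gr, clusters)
  support <- vapply(seq_along(clusters), function(ci) {
    length(unique(pooled$sample[S4Vectors::queryHits(ov)[
      S4Vectors::subjectHits(ov) == ci]]))
  }, integer(1))
  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(clusters)),
    start = GenomicRanges::start(clusters),
    end = GenomicRanges::end(clusters),
    n_supporting = support,
    n_samples = n_samples,
    support_fraction = support / n_samples,
    stringsAsFactors = FALSE
  )
  out[out$support_fraction > min_support_fraction, , drop = FALSE]
}

#' Write peaks as BED6
#'
#' Intervals are converted to 0-based half-open on write; the score column
#' carries `max_depth` for per-sample peaks or `n_supporting` for consensus
#' peaks.
#'
#' @param peaks A peaks data.frame from [call_peaks] or [conserved_peaks].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- if (!is.null(peaks$max_depth)) peaks$max_depth else
    if (!is.null(peaks$n_supporting)) peaks$n_supporting else 0L
  name <- if (!is.null(peaks$sample_id)) peaks$sample_id else "consensus"
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   peaks$chrom, as.integer(peaks$start) - 1L,
                   as.integer(peaks$end), name, as.integer(score))
  writeLines(lines, path)
  invisible(path)
}
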