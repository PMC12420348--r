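# Fixtures are built in code: SAM text -> BAM via Rsamtools::asBam.

sam_header <- function(chrom = "chr1", len = 1000000L) {
  c("@HD\tVN:1.6\tSO:unsorted", sprintf("@SQ\tSN:%s\tLN:%d", chrom, len))
}

# One proper read pair with plain M cigars. Returns two SAM lines.
sam_pair <- function(qname, chrom, pos1, pos2, rl = 50L, mapq = 60L,
                     flag1 = 99L, flag2 = 147L) {
  seqs <- strrep("A", rl)
  tlen <- (pos2 + rl - 1L) - pos1 + 1L
  c(sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t*",
            qname, flag1, chrom, pos1, mapq, rl, pos2, tlen, seqs),
    sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t=\t%d\t%d\t%s\t*",
            qname, flag2, chrom, pos2, mapq, rl, pos1, -tlen, seqs))
}

# Single-end read, plain M cigar.
sam_single <- function(qname, chrom, pos, rl = 50L, mapq = 60L, flag = 0L) {
  sprintf("%s\t%d\t%s\t%d\t%d\t%dM\t*\t0\t0\t%s\t*",
          qname, flag, chrom, pos, mapq, rl, strrep("A", rl))
}

make_bam <- function(records, chrom = "chr1", len = 1000000L,
                     prefix = tempfile("fix")) {
  sam <- paste0(prefix, ".sam")
  writeLines(c(sam_header(chrom, len), records), sam)
  bam <- Rsamtools::asBam(sam, destination = prefix, overwrite = TRUE,
                          indexDestination = TRUE)
  unlink(sam)
  bam
}

# Brute-force counting oracle. fragments: list of fragments, each a list of
# read spans (start, end) on one chromosome. regions: data.frame with
# variant_id, start, end (single chromosome). Mirrors the unique-assignment
# rule: one overlapped region -> count, two or more -> ambiguous drop.
bf_count <- function(fragments, regions, rule = c("any_overlap", "full_containment")) {
  rule <- match.arg(rule)
  counts <- stats::setNames(integer(nrow(regions)), regions$variant_id)
  ambiguous <- 0L
  for (frag in fragments) {
    hit <- logical(nrow(regions))
    for (r in seq_len(nrow(regions))) {
      per_read <- vapply(frag, function(sp) {
        if (rule == "any_overlap") {
          sp[1] <= regions$end[r] && regions$start[r] <= sp[2]
        } else {
          sp[1] >= regions$start[r] && sp[2] <= regions$end[r]
        }
      }, logical(1))
      hit[r] <- if (rule == "any_overlap") any(per_read) else all(per_read)
    }
    if (sum(hit) == 1L) {
      counts[which(hit)] <- counts[which(hit)] + 1L
    } else if (sum(hit) >= 2L && rule == "any_overlap") {
      ambiguous <- ambiguous + 1L
    }
  }
  list(counts = counts, ambiguous = ambiguous)
}

# Brute-force Spearman: explicit mid-ranks, then the Pearson formula.
bf_spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  num <- sum((rx - mean(rx)) * (ry - mean(ry)))
  den <- sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  num / den
}

# Closed-form BH step-up oracle.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  running <- Inf
  for (i in rev(seq_len(m))) {
    running <- min(running, p[o[i]] * m / i)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# Two-variant geometry with mirror-symmetric discriminating spans and a
# single terminal polyA site each; used where symmetry arguments apply.
symmetric_models <- function(chrom = "sim1") {
  list(
    A = isoregion::transcript_model("symA", chrom, 1001, 3000, 4001, 6000,
                                    polya_sites = 6000, polya_usage = 1),
    B = isoregion::transcript_model("symB", chrom, 1001, 3000, 8001, 10000,
                                    polya_sites = 10000, polya_usage = 1)
  )
}
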