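two_region_spec <- function() {
  region_spec(data.frame(
    variant_id = c("A", "B"), chrom = "chr1",
    start = c(1000, 5000), end = c(1999, 5999), strand = "+"
  ))
}

test_that("fragments are counted into the regions they fall in", {
  spec <- two_region_spec()
  recs <- c(
    unlist(lapply(1:7, function(i) sam_pair(paste0("inA", i), "chr1",
                                            1100 + 10 * i, 1500 + 10 * i))),
    unlist(lapply(1:3, function(i) sam_pair(paste0("inB", i), "chr1",
                                            5100 + 10 * i, 5500 + 10 * i))),
    sam_pair("out1", "chr1", 3000, 3400),
    sam_pair("out2", "chr1", 9000, 9400)
  )
  bam <- make_bam(recs)
  cf <- count_fragments(bam, spec)
  expect_equal(cf$counts, c(A = 7L, B = 3L))
  expect_equal(cf$diagnostics$ambiguous, 0L)
})

test_that("a mate straddling a region edge counts under any_overlap only", {
  spec <- two_region_spec()
  # read2 covers 951..1000: exactly 1 bp inside region A ([1000, 1999])
  recs <- c(sam_pair("edge", "chr1", 900, 951),
            sam_pair("deep", "chr1", 1200, 1600))
  bam <- make_bam(recs)
  any_ov <- count_fragments(bam, spec,
                            counting_policy(overlap_rule = "any_overlap"))
  full <- count_fragments(bam, spec,
                          counting_policy(overlap_rule = "full_containment"))
  expect_equal(any_ov$counts[["A"]], 2L)
  expect_equal(full$counts[["A"]], 1L)
})

test_that("an empty alignment file yields zero counts and zero diagnostics", {
  bam <- make_bam(character(0))
  cf <- count_fragments(bam, two_region_spec())
  expect_equal(cf$counts, c(A = 0L, B = 0L))
  expect_equal(cf$diagnostics$fragments_inspected, 0L)
})

test_that("policy filters drop secondary, duplicate and low-MAPQ records", {
  spec <- two_region_spec()
  recs <- c(
    sam_pair("ok", "chr1", 1100, 1500),
    sam_pair("dup", "chr1", 1100, 1500, flag1 = 99L + 1024L, flag2 = 147L + 1024L),
    sam_pair("sec", "chr1", 1200, 1600, flag1 = 99L + 256L, flag2 = 147L + 256L),
    sam_pair("lowq", "chr1", 1300, 1700, mapq = 0L)
  )
  bam <- make_bam(recs)
  default <- count_fragments(bam, spec)  # drops secondary + mapq 0, keeps dup
  expect_equal(default$counts[["A"]], 2L)
  nodup <- count_fragments(bam, spec, counting_policy(drop_duplicates = TRUE))
  expect_equal(nodup$counts[["A"]], 1L)
  lax <- count_fragments(bam, spec, counting_policy(min_mapq = 0L,
                                                    require_primary = FALSE))
  expect_equal(lax$counts[["A"]], 4L)
})

test_that("unknown chromosomes error but an alias map rescues them", {
  spec <- region_spec(data.frame(variant_id = "A", chrom = "chr9",
                                 start = 1000, end = 1999))
  bam <- make_bam(sam_pair("p", "chr1", 1100, 1500))
  expect_error(count_fragments(bam, spec), "chr9.*available")
  cf <- count_fragments(bam, spec, chrom_alias = c(chr9 = "chr1"))
  expect_equal(cf$counts[["A"]], 1L)
})

test_that("counting matches a brute-force per-fragment oracle for both rules", {
  set.seed(202)
  # R1 and R2 are close enough that one pair can straddle both -> ambiguity
  regions <- data.frame(variant_id = c("R1", "R2", "R3"),
                        start = c(1000, 2100, 5000),
                        end = c(1999, 2599, 6499))
  spec <- region_spec(cbind(regions, chrom = "chr1", strand = "+"))
  rl <- 50L
  n <- 90  # 180 alignment records
  pos1 <- sample(500:6800, n, replace = TRUE)
  gap <- sample(0:400, n, replace = TRUE)
  pos2 <- pos1 + gap
  recs <- unlist(lapply(seq_len(n), function(i) {
    sam_pair(sprintf("f%03d", i), "chr1", pos1[i], pos2[i], rl = rl)
  }))
  fragments <- lapply(seq_len(n), function(i) {
    list(c(pos1[i], pos1[i] + rl - 1), c(pos2[i], pos2[i] + rl - 1))
  })
  bam <- make_bam(recs)
  for (rule in c("any_overlap", "full_containment")) {
    got <- count_fragments(bam, spec, counting_policy(overlap_rule = rule))
    want <- bf_count(fragments, regions, rule)
    expect_equal(got$counts, want$counts, info = rule)
    if (rule == "any_overlap") {
      expect_equal(got$diagnostics$ambiguous, want$ambiguous)
    }
  }
  # under full containment no fragment can be ambiguous on disjoint regions
  full <- count_fragments(bam, spec,
                          counting_policy(overlap_rule = "full_containment"))
  expect_equal(full$diagnostics$ambiguous, 0L)
  expect_lte(sum(full$counts), full$diagnostics$fragments_inspected)

  # record order does not matter
  shuffled <- make_bam(sample(recs))
  reshuffle <- count_fragments(shuffled, spec)
  expect_equal(reshuffle$counts, count_fragments(bam, spec)$counts)
})

test_that("per-read mode counts mates separately", {
  spec <- two_region_spec()
  bam <- make_bam(sam_pair("p", "chr1", 1100, 1500))
  paired <- count_fragments(bam, spec)
  per_read <- count_fragments(bam, spec,
                              counting_policy(fragment_mode = "per_read"))
  expect_equal(paired$counts[["A"]], 1L)
  expect_equal(per_read$counts[["A"]], 2L)
})

test_that("FPKM follows q / (l * N) * 1e9 and is scale invariant", {
  expect_equal(compute_fpkm(0, 1900, 1e6), 0)
  expect_equal(compute_fpkm(50, 5819, 2e7), 50 / (5819 * 2e7) * 1e9)
  expect_equal(compute_fpkm(10, 1000, 1e6), 10)
  expect_error(compute_fpkm(10, 0, 1e6), "length")
  expect_error(compute_fpkm(10, 1000, 0), "library")
  expect_error(compute_fpkm(-1, 1000, 1e6), "non-negative")

  set.seed(7)
  q <- as.numeric(sample(0:10000, 1000, replace = TRUE))
  l <- as.numeric(sample(50:100000, 1000, replace = TRUE))
  N <- floor(runif(1000, 1e5, 1e8))
  expect_equal(compute_fpkm(q, l, N), q / (l * N) * 1e9, tolerance = 1e-15)
  for (k in c(2L, 7L, 100L)) {
    expect_equal(compute_fpkm(k * q, l, k * N), compute_fpkm(q, l, N),
                 tolerance = 1e-15)
  }
})

test_that("quantify_sample handles provided, scanned and absent library sizes", {
  spec <- two_region_spec()
  recs <- c(
    unlist(lapply(1:5, function(i) sam_pair(paste0("a", i), "chr1",
                                            1100 + 20 * i, 1400 + 20 * i))),
    sam_pair("b1", "chr1", 5100, 5400),
    sam_pair("o1", "chr1", 8000, 8300)
  )
  bam <- make_bam(recs)

  prov <- quantify_sample(bam, spec, library_size = 1000,
                          library_size_source = "provided")
  expect_equal(prov$count, c(5, 1))
  expect_equal(prov$fpkm, compute_fpkm(c(5, 1), spec$length_bp, 1000))

  scanned <- quantify_sample(bam, spec, library_size_source = "bam_scan")
  expect_equal(unique(scanned$library_size), 7)  # all distinct mapped fragments

  sliced <- quantify_sample(bam, spec, library_size_source = "absent")
  expect_true(all(is.na(sliced$fpkm)))
  expect_equal(sliced$rate, c(5, 1) / spec$length_bp)

  expect_error(quantify_sample(bam, spec, library_size = 0,
                               library_size_source = "provided"),
               "positive library_size")
})

test_that("rate ratios equal FPKM ratios for any library size", {
  spec <- two_region_spec()
  recs <- c(
    unlist(lapply(1:6, function(i) sam_pair(paste0("a", i), "chr1",
                                            1050 + 30 * i, 1500 + 30 * i))),
    unlist(lapply(1:2, function(i) sam_pair(paste0("b", i), "chr1",
                                            5050 + 30 * i, 5500 + 30 * i)))
  )
  bam <- make_bam(recs)
  sliced <- quantify_sample(bam, spec, library_size_source = "absent")
  for (N in c(1e4, 1e6, 3.7e7)) {
    full <- quantify_sample(bam, spec, library_size = N,
                            library_size_source = "provided")
    expect_equal(full$fpkm[1] / full$fpkm[2], sliced$rate[1] / sliced$rate[2],
                 tolerance = 1e-12)
    # with pseudocount 0 the log-ratio is library-size free
    expect_equal(log2(full$fpkm[1] / full$fpkm[2]),
                 log_ratio(sliced$rate[1], sliced$rate[2],
                           pseudocount = .Machine$double.xmin),
                 tolerance = 1e-9)
  }
})
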