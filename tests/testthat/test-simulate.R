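test_that("transcript models validate their geometry", {
  expect_error(transcript_model("v", "c", 100, 50, 200, 300), "shared_start")
  expect_error(transcript_model("v", "c", 1, 100, 50, 300))  # disc inside shared
  expect_error(transcript_model("v", "c", 1, 100, 200, 300,
                                polya_sites = 150))  # site outside disc
  expect_error(transcript_model("v", "c", 1, 100, 200, 300,
                                polya_sites = c(250, 300),
                                polya_usage = c(0.5, 0.6)))  # usage sum != 1
  m <- braf_like_models()
  expect_equal(m$A$disc_len, 5819)
  expect_equal(m$B$disc_len, 1900)
  spec <- models_region_spec(m)
  expect_s3_class(spec, "region_spec")
  expect_equal(sort(spec$length_bp), c(1900, 5819))
})

test_that("simulated BAMs are standard-conformant and deterministic", {
  models <- braf_like_models()
  p1 <- tempfile("det1"); p2 <- tempfile("det2")
  s1 <- simulate_two_variant_sample(models, pi = 0.6, n_fragments = 2000,
                                    seed = 7, out_prefix = p1)
  s2 <- simulate_two_variant_sample(models, pi = 0.6, n_fragments = 2000,
                                    seed = 7, out_prefix = p2)
  # identical truth sidecars (up to the sample label) and identical counts
  t1 <- read.delim(paste0(p1, ".truth.tsv"))
  t2 <- read.delim(paste0(p2, ".truth.tsv"))
  expect_equal(t1[setdiff(names(t1), "sample_id")],
               t2[setdiff(names(t2), "sample_id")])
  spec <- models_region_spec(models)
  q1 <- quantify_sample(s1$bam, spec, library_size_source = "absent")
  q2 <- quantify_sample(s2$bam, spec, library_size_source = "absent")
  expect_equal(q1$count, q2$count)

  # index + pileup round-trip: the BAM parses, is sorted, and its reads
  # are all accounted for
  expect_true(file.exists(paste0(s1$bam, ".bai")))
  aln <- GenomicAlignments::readGAlignments(s1$bam)
  expect_equal(length(aln), 2L * 2000L)
  expect_false(is.unsorted(GenomicAlignments::start(aln)))
})

test_that("degenerate mixtures put every fragment on one variant", {
  models <- braf_like_models()
  spec <- models_region_spec(models)
  sim <- simulate_two_variant_sample(models, pi = 1, n_fragments = 1500,
                                     seed = 13, out_prefix = tempfile("pi1"))
  q <- quantify_sample(sim$bam, spec, library_size_source = "absent")
  expect_equal(q$count[q$variant_id == "V220like"], 0)
  expect_gt(q$count[q$variant_id == "V204like"], 0)
  expect_equal(estimate_mixture(q, models), 1)

  sim0 <- simulate_two_variant_sample(models, pi = 0, n_fragments = 1500,
                                      seed = 13, out_prefix = tempfile("pi0"))
  q0 <- quantify_sample(sim0$bam, spec, library_size_source = "absent")
  expect_equal(q0$count[q0$variant_id == "V204like"], 0)
  expect_equal(estimate_mixture(q0, models), 0)
})

test_that("a symmetric half-half mixture balances counts within binomial noise", {
  models <- symmetric_models()
  spec <- models_region_spec(models)
  n <- 10000
  sim <- simulate_two_variant_sample(models, pi = 0.5, n_fragments = n,
                                     seed = 23, out_prefix = tempfile("sym"))
  q <- quantify_sample(sim$bam, spec, library_size_source = "absent")
  qA <- q$count[q$variant_id == "symA"]
  qB <- q$count[q$variant_id == "symB"]
  expect_lte(abs(qA - qB), 4 * sqrt(n / 4))
  expect_equal(estimate_mixture(q, models), qA / (qA + qB))  # symmetry: p cancels

  # realized counts near the closed-form expectation
  expected <- sim$truth$expected_counts
  expect_lte(abs(qA - expected[["symA"]]), 4 * sqrt(expected[["symA"]]))
  expect_lte(abs(qB - expected[["symB"]]), 4 * sqrt(expected[["symB"]]))
})

test_that("mixture recovery inverts the asymmetric default geometry", {
  models <- braf_like_models()
  spec <- models_region_spec(models)
  sim <- simulate_two_variant_sample(models, pi = 0.8, n_fragments = 20000,
                                     seed = 29, out_prefix = tempfile("rec"))
  q <- quantify_sample(sim$bam, spec, library_size_source = "absent")
  pi_hat <- estimate_mixture(q, models)
  expect_lte(abs(pi_hat - 0.8), 0.02)

  zero <- q
  zero$count <- c(0, 0)
  zero$rate <- c(0, 0)
  expect_warning(pi_na <- estimate_mixture(zero, models), "undefined")
  expect_true(is.na(pi_na))
})

test_that("3'-end read simulation piles coverage at the planted sites", {
  model <- braf_like_models()$B
  qs <- simulate_quantseq(model, n_reads = 3000, seed = 37,
                          out_prefix = tempfile("qs"))
  tr <- coverage_track(qs$bam, "sim1", 3900, 6100)
  pk <- call_peaks(tr)
  expect_equal(nrow(pk), 2)
  for (site in model$polya_sites) {
    expect_true(any(pk$start - 60 <= site & site <= pk$end + 60))
  }

  none <- simulate_quantseq(model, n_reads = 0, seed = 37,
                            out_prefix = tempfile("qs0"))
  tr0 <- coverage_track(none$bam, "sim1", 3900, 6100)
  expect_equal(sum(tr0$depth), 0)
  expect_equal(nrow(call_peaks(tr0)), 0)
})

test_that("expression cohorts carry the planted structure and are seeded", {
  co <- simulate_expression_cohort(n_samples = 60, seed = 43)
  expect_equal(dim(co$targets), c(51, 60))
  expect_equal(dim(co$mirnas), c(21, 60))
  expect_gt(cor(co$focal, co$targets[co$truth$target, ],
                method = "spearman"), 0.5)
  expect_lt(cor(co$focal, co$mirnas[co$truth$mirna, ],
                method = "spearman"), -0.5)
  co2 <- simulate_expression_cohort(n_samples = 60, seed = 43)
  expect_identical(co$focal, co2$focal)
  expect_identical(as.numeric(co$targets), as.numeric(co2$targets))

  # noiseless limit: planted correlations are perfectly monotone
  pure <- simulate_expression_cohort(n_samples = 30, noise_sd = 1e-12, seed = 47)
  expect_equal(cor(pure$focal, pure$targets[pure$truth$target, ],
                   method = "spearman"), 1)
  expect_equal(cor(pure$focal, pure$mirnas[pure$truth$mirna, ],
                   method = "spearman"), -1)
  expect_error(simulate_expression_cohort(n_samples = 5), "n_samples")
})

test_that("the discriminating-span coverage probability matches simulation", {
  models <- braf_like_models()
  spec <- models_region_spec(models)
  n <- 20000
  sim <- simulate_two_variant_sample(models, pi = 1, n_fragments = n,
                                     seed = 53, out_prefix = tempfile("prob"))
  q <- quantify_sample(sim$bam, spec, library_size_source = "absent")
  p_hat <- q$count[q$variant_id == "V204like"] / n
  p_theory <- disc_overlap_prob(models$A)
  expect_lte(abs(p_hat - p_theory), 4 * sqrt(p_theory * (1 - p_theory) / n))
})
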