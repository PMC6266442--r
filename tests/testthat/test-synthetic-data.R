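test_that("an ORF-free spec yields plain background sequence", {
  sim <- simulate_genome(genome_spec(n_orfs = 0, seed = 3))
  expect_equal(nrow(sim$features), 0)
  expect_equal(length(sim$proteins), 0)
  expect_gt(sim$genome$length_bp, 0)
  expect_equal(nrow(annotate_genome(sim$genome)), 0)
})

test_that("planted ORFs are recovered exactly by the annotation pipeline", {
  sim <- simulate_genome(genome_spec(n_orfs = 25, seed = 13))
  cand <- annotate_genome(sim$genome)
  expect_setequal(paste(cand$start, cand$end, cand$strand),
                  paste(sim$features$start, sim$features$end, "+"))
  expect_equal(nrow(cand), 25)
  # recovered proteins equal the recorded ground truth
  feats <- protein_features(sim$genome, cand)
  expect_setequal(feats$protein, unname(sim$proteins))
})

test_that("generators are deterministic under a fixed seed", {
  s1 <- simulate_genome(genome_spec(n_orfs = 10, seed = 17))
  s2 <- simulate_genome(genome_spec(n_orfs = 10, seed = 17))
  expect_identical(s1$genome$sequence, s2$genome$sequence)
  expect_identical(s1$proteins, s2$proteins)
  g1 <- simulate_growth_curve(growth_spec_preset("30C", seed = 19))
  g2 <- simulate_growth_curve(growth_spec_preset("30C", seed = 19))
  expect_identical(g1$titer_pfu_per_ml, g2$titer_pfu_per_ml)
  m1 <- simulate_spot_matrix(20, profile = c("-", "++"), seed = 23)
  m2 <- simulate_spot_matrix(20, profile = c("-", "++"), seed = 23)
  expect_identical(m1, m2)
})

test_that("the GC dial lands near its target", {
  sim <- simulate_genome(genome_spec(n_orfs = 30, gc_target = 44, seed = 29))
  expect_lt(abs(gc_content(sim$genome) - 44), 2)
})

test_that("start-codon draws follow the configured mix", {
  sim <- simulate_genome(genome_spec(n_orfs = 60, seed = 31))
  usage <- start_codon_usage(sim$features$start_codon)
  expect_gt(usage[["ATG"]], 60)   # dominant, as configured (81%)
})

test_that("proteome divergence hits its identity target", {
  sim <- simulate_genome(genome_spec(n_orfs = 12, seed = 37))
  div100 <- diverge_proteome(sim, 100, seed = 38)
  expect_identical(div100$proteins, sim$proteins)
  for (target in c(60, 80, 90)) {
    div <- diverge_proteome(sim, target, seed = target)
    # realized identities measured directly against the parent proteins
    measured <- mapply(function(a, b) {
      av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
      100 * mean(av == bv)
    }, sim$proteins, div$proteins)
    expect_lt(abs(mean(measured) - target), 3)
    expect_equal(unname(measured), div$identities$identity_pct,
                 tolerance = 1e-9)
    # coordinates are untouched, so the diverged genome re-annotates
    expect_equal(nchar(div$genome$sequence), nchar(sim$genome$sequence))
  }
  expect_error(diverge_proteome(sim, 0), class = "phagekit_value_error")
  expect_error(diverge_proteome(sim, 101), class = "phagekit_value_error")
})

test_that("a diverged pair keeps its pairs above a slightly lower cutoff", {
  sim <- simulate_genome(genome_spec(n_orfs = 10, seed = 41))
  div <- diverge_proteome(sim, 90, seed = 42)
  hits <- best_hits(sim$proteins, div$proteins)
  report <- shared_proteins_at_cutoff(hits, 85)
  expect_equal(report$count, length(sim$proteins))
})

test_that("noise-free growth curves follow the planted expectation exactly", {
  spec <- growth_spec(burst = 99, latent_min = 50, lysis_spread_min = 0,
                      noise = FALSE, sampling_times = seq(0, 100, 4),
                      initial_free_phage = 1e6, seed = 1)
  curve <- simulate_growth_curve(spec)
  one <- curve[curve$replicate == 1, ]
  expect_equal(one$titer_pfu_per_ml[one$time_min < 50], rep(1e6, 13))
  expect_equal(one$titer_pfu_per_ml[one$time_min >= 50], rep(1e8, 13))
})

test_that("planted growth parameters are recovered across seeds", {
  presets <- list("20C" = c(602, 102), "30C" = c(64, 54), "37C" = c(2, 55))
  for (nm in names(presets)) {
    est <- vapply(1:40, function(s) {
      e <- estimate_growth_parameters(
        simulate_growth_curve(growth_spec_preset(nm, seed = s)))
      c(e$burst_size, e$latent_min)
    }, numeric(2))
    expect_lt(abs(mean(est[1, ]) / presets[[nm]][1] - 1), 0.10,
              label = paste(nm, "burst relative error"))
    expect_lt(abs(mean(est[2, ]) - presets[[nm]][2]), 10,
              label = paste(nm, "latent error (min)"))
  }
})

test_that("spot matrices realize the requested profile", {
  m <- simulate_spot_matrix(30, profile = "-", seed = 47)
  expect_true(all(m$score == "-"))
  profile <- c(rep("++++", 6), rep("++", 4), rep("+", 12), rep("-", 51))
  m2 <- simulate_spot_matrix(73, profile = profile,
                             pathogenic = rep(c(TRUE, FALSE), length.out = 73),
                             seed = 53)
  expect_equal(nrow(m2), 73)
  expect_equal(count_infected(m2)[["total"]], 10)
  # patterns are prefix-monotone, so rescoring is idempotent
  rescored <- vapply(seq_len(nrow(m2)), function(i) {
    score_spot_test(as.logical(unlist(m2[i, c("d0", "d2", "d4", "d6")])))
  }, "")
  expect_equal(rescored, m2$score)
})

test_that("generated data passes the module input validation unchanged", {
  sim <- simulate_genome(genome_spec(n_orfs = 5, seed = 61))
  f <- withr::local_tempfile(fileext = ".fa")
  write_fasta(sim$genome, f)
  expect_equal(read_fasta(f)[[1]]$sequence, sim$genome$sequence)
  expect_s3_class(sim$features, "feature_table")
  curve <- simulate_growth_curve(growth_spec_preset("20C", seed = 62))
  expect_s3_class(curve, "growth_curve")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_growth_csv(curve, csv)
  expect_length(read_growth_csv(csv), 1)
})
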