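test_that("percent identity divides by the smallest protein, half-up", {
  expect_equal(percent_identity(667, 672, 671), 99)
  expect_equal(percent_identity(0, 50, 60), 0)
  expect_equal(percent_identity(288, 288, 288), 100)
  expect_equal(percent_identity(1, 2, 200), 50)
  # half-up at the boundary: 0.5 rounds away from zero
  expect_equal(percent_identity(1, 200, 200), 1)  # 0.5% -> 1
  expect_error(percent_identity(51, 50, 60), class = "phagekit_value_error")
  expect_error(percent_identity(0, 0, 10), class = "phagekit_value_error")
})

test_that("global alignment scores match an independent Gotoh oracle", {
  expect_equal(align_and_count("MKVLW", "MKVLW")$percent_identity, 100)
  expect_equal(align_and_count("AAAA", "TTTT")$identical_residues, 0)
  set.seed(71)
  for (i in 1:30) {
    a <- random_protein(sample(5:30, 1))
    b <- random_protein(sample(5:30, 1))
    got <- align_and_count(a, b)
    want <- oracle_global_alignment(a, b)
    expect_equal(got$score, want$score, info = paste(a, b))
    # the identical count must be attainable by some optimal alignment
    expect_lte(got$identical_residues, want$max_identical)
    expect_gte(got$identical_residues, want$min_identical)
    expect_lte(got$identical_residues, min(nchar(a), nchar(b)))
  }
})

test_that("self-comparison yields full-identity self-hits", {
  set.seed(73)
  prots <- setNames(vapply(1:8, function(i) random_protein(sample(30:60, 1)),
                           ""), paste0("p", 1:8))
  hits <- best_hits(prots, prots)
  expect_equal(hits$query_id, hits$subject_id)
  expect_true(all(hits$percent_identity == 100))
})

test_that("disjoint random proteomes fall below a 60% identity floor", {
  set.seed(79)
  a <- setNames(vapply(1:6, function(i) random_protein(60), ""),
                paste0("a", 1:6))
  b <- setNames(vapply(1:6, function(i) random_protein(60), ""),
                paste0("b", 1:6))
  # exhaustive pair scan oracle: no pair of unrelated random proteins
  # reaches 60% identity
  all_pairs <- expand.grid(q = names(a), s = names(b))
  max_pct <- max(apply(all_pairs, 1, function(r) {
    align_and_count(a[[r[1]]], b[[r[2]]])$percent_identity
  }))
  expect_lt(max_pct, 60)
  expect_equal(nrow(best_hits(a, b, min_identity = 60)), 0)
})

test_that("planted orthologs at ~90% identity are recovered exactly", {
  sim <- simulate_genome(genome_spec(n_orfs = 12, seed = 83))
  div <- diverge_proteome(sim, 90, seed = 84)
  hits <- best_hits(sim$proteins, div$proteins, min_identity = 60)
  expect_equal(hits$subject_id, hits$query_id)   # each pairs with its parent
  expect_equal(nrow(hits), length(sim$proteins))
  expect_lt(max(abs(hits$percent_identity - 90)), 4)
  # reciprocal best hits agree for a clean one-to-one divergence
  rbh <- best_hits(sim$proteins, div$proteins, reciprocal = TRUE)
  expect_equal(nrow(rbh), length(sim$proteins))
})

test_that("shared-set counts honour the cutoff and strictness", {
  tbl <- fixture_features()
  cds <- tbl[tbl$type == "CDS" & !is.na(tbl$hit_pct_identity), ]
  hits <- data.frame(query_id = cds$orf_id, subject_id = cds$orf_id,
                     percent_identity = cds$hit_pct_identity)
  expect_equal(shared_proteins_at_cutoff(hits, 90, strict = TRUE)$count, 47)
  expect_equal(shared_proteins_at_cutoff(hits, 100, strict = FALSE)$count, 8)
  expect_equal(shared_proteins_at_cutoff(hits, 0, strict = FALSE)$count,
               nrow(hits))
  # >= vs > differ exactly by the ties at the cutoff
  at90 <- sum(cds$hit_pct_identity == 90)
  expect_equal(shared_proteins_at_cutoff(hits, 90, strict = FALSE)$count,
               47 + at90)
})

test_that("shared-set counts are non-increasing in the cutoff", {
  sim <- simulate_genome(genome_spec(n_orfs = 10, seed = 89))
  for (target in c(70, 85, 95)) {
    div <- diverge_proteome(sim, target, seed = target)
    hits <- best_hits(sim$proteins, div$proteins)
    counts <- shared_set_counts(hits, seq(0, 100, by = 5))
    expect_true(all(diff(counts) <= 0), info = paste("target", target))
    expect_true(all(diff(shared_set_counts(hits, seq(0, 100, 5),
                                           strict = TRUE)) <= 0))
  }
})

test_that("the genome map table bands links by identity", {
  ta <- feature_table(data.frame(orf_id = c("A1", "A2", "A3"), strand = "+",
                                 start = c(1, 100, 200),
                                 end = c(90, 190, 290)), genome_id = "A")
  tb <- feature_table(data.frame(orf_id = c("B1", "B2", "B3"), strand = "+",
                                 start = c(1, 100, 200),
                                 end = c(90, 190, 290)), genome_id = "B")
  hits <- list("A|B" = data.frame(
    query_id = c("A1", "A2", "A3"), subject_id = c("B1", "B2", "B3"),
    percent_identity = c(95, 75, 50)))
  map <- genome_map_table(list(A = ta, B = tb), hits,
                          shade_cutoffs = c(70, 80))
  a_rows <- map[map$genome_id == "A", ]
  expect_equal(a_rows$band, c(">80", ">70", "<=70"))
  expect_equal(a_rows$link_orf, c("B1", "B2", "B3"))
  # all rows preserved even without links
  empty <- genome_map_table(list(A = ta, B = tb), list())
  expect_equal(nrow(empty), 6)
  expect_true(all(is.na(empty$band)))
  # identical proteomes land in the top band
  self_hits <- list("A|B" = data.frame(query_id = c("A1", "A2", "A3"),
                                       subject_id = c("B1", "B2", "B3"),
                                       percent_identity = 100))
  full <- genome_map_table(list(A = ta, B = tb), self_hits)
  expect_true(all(full[full$genome_id == "A", "band"] == ">80"))
  # unknown IDs are rejected
  bad <- list("A|B" = data.frame(query_id = "ZZ", subject_id = "B1",
                                 percent_identity = 90))
  expect_error(genome_map_table(list(A = ta, B = tb), bad),
               class = "phagekit_value_error")
})
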