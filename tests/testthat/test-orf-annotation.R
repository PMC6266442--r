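test_that("simple ORF structures are called correctly", {
  g <- genome_record("g", paste(c("ATG", rep("GCT", 45), "TAA"),
                                collapse = ""))
  orfs <- find_orfs(g)
  expect_equal(nrow(orfs), 1)
  expect_equal(orfs$size_aa, 46)
  expect_equal(orfs$start_codon, "ATG")
  expect_equal(orfs$strand, "+")
  expect_equal(orfs$end, g$length_bp)

  # no start codon anywhere: nothing to call
  g2 <- genome_record("g2", paste(rep("CCC", 100), collapse = ""))
  expect_equal(nrow(find_orfs(g2)), 0)

  # below the length floor
  g3 <- genome_record("g3", paste(c("ATG", rep("GCT", 10), "TAA"),
                                  collapse = ""))
  expect_equal(nrow(find_orfs(g3, min_aa = 45)), 0)
  expect_equal(nrow(find_orfs(g3, min_aa = 5)), 1)
})

test_that("the caller matches a brute-force six-frame enumerator", {
  set.seed(101)
  for (i in 1:20) {
    L <- sample(500:5000, 1)
    s <- random_dna(L, gc = sample(30:60, 1))
    g <- genome_record(paste0("r", i), s)
    for (min_aa in c(20L, 45L)) {
      for (all_starts in c(FALSE, TRUE)) {
        got <- find_orfs(g, min_aa = min_aa, all_starts = all_starts)
        want <- oracle_orfs(s, min_aa = min_aa, all_starts = all_starts)
        expect_equal(got[, c("start", "end", "strand")],
                     want, ignore_attr = TRUE,
                     info = sprintf("genome %d min_aa %d all %d",
                                    i, min_aa, all_starts))
        # reported lengths and start codons are internally consistent
        expect_equal(got$size_aa, coords_to_aa_length(got$start, got$end))
      }
    }
  }
})

test_that("annotation is symmetric under reverse complementation", {
  set.seed(55)
  for (i in 1:5) {
    s <- random_dna(3000)
    g <- genome_record("f", s)
    rc <- genome_record("r", oracle_revcomp(s))
    a <- find_orfs(g, min_aa = 20)
    b <- find_orfs(rc, min_aa = 20)
    mapped <- data.frame(start = nchar(s) - b$end + 1,
                         end = nchar(s) - b$start + 1,
                         strand = ifelse(b$strand == "+", "-", "+"))
    expect_setequal(paste(a$start, a$end, a$strand),
                    paste(mapped$start, mapped$end, mapped$strand))
  }
})

test_that("SD placement maximizes matches with deterministic tie-breaking", {
  # exact core at canonical spacing
  win <- paste0("TTTT", SD_CORE, "CCCCCCC")  # spacer 7
  best <- sd_best_match(win)
  expect_equal(best$match_count, 7)
  expect_equal(best$spacer, 7)
  expect_equal(best$matched_positions, 1:7)

  # published context of an endolysin ORF: one mismatch at core position 6
  best24 <- sd_best_match("AGGAGCTgaaaa")
  expect_equal(best24$match_count, 6)
  expect_equal(best24$spacer, 5)
  expect_equal(setdiff(1:7, best24$matched_positions), 6)

  # all-T window: placements exist but nothing matches beyond position 7
  bt <- sd_best_match(paste(rep("T", 22), collapse = ""))
  expect_lte(bt$match_count, 1)

  # two perfect placements (spacers 3 and 10): the tie resolves to the
  # spacer closest to the canonical 7 nt
  win2 <- paste0(SD_CORE, SD_CORE, "AAA")
  b2 <- sd_best_match(win2, min_spacer = 3, max_spacer = 15)
  expect_equal(b2$match_count, 7)
  expect_equal(b2$spacer, 10)
})

test_that("SD match count never decreases when the window is relaxed", {
  set.seed(77)
  for (i in 1:30) {
    win <- random_dna(25)
    tight <- sd_best_match(win, min_spacer = 5, max_spacer = 9)
    wide <- sd_best_match(win, min_spacer = 3, max_spacer = 15)
    wider <- sd_best_match(win, min_spacer = 0, max_spacer = 18)
    expect_gte(wide$match_count, tight$match_count)
    expect_gte(wider$match_count, wide$match_count)
  }
})

test_that("detect_sd applies acceptance thresholds and strand awareness", {
  g <- genome_record("g", paste0("TT", SD_CORE, "CAATT",
                                 "ATG", strrep("AAA", 50), "TAA"))
  orfs <- find_orfs(g, min_aa = 45)
  orf <- orfs[orfs$strand == "+", ][1, ]
  hit <- detect_sd(g, orf)
  expect_equal(hit$match_count, 7)
  expect_equal(hit$spacer, 5)
  expect_null(detect_sd(g, orf, min_match = 8))

  # same gene on the minus strand
  grc <- genome_record("rc", oracle_revcomp(g$sequence))
  orfr <- find_orfs(grc, min_aa = 45)
  orfr <- orfr[orfr$strand == "-", ]
  expect_equal(nrow(orfr), 1)
  hitr <- detect_sd(grc, orfr[1, ])
  expect_equal(hitr$match_count, 7)
  expect_equal(hitr$spacer, 5)
})

test_that("every published ribosome-binding context is recoverable at permissive settings", {
  cds <- fixture_features()
  cds <- cds[cds$type == "CDS", ]
  stats <- vapply(cds$sd_context, function(w) {
    b <- sd_best_match(w, min_spacer = 0, max_spacer = 15)
    c(b$match_count, b$max_run)
  }, numeric(2))
  expect_true(all(stats[1, ] >= 3))
  expect_true(all(stats[2, ] >= 1))
})

test_that("candidate filtering enforces length, start codon and SD", {
  g <- genome_record("g", paste0(
    "TT", SD_CORE, "CAATT", "ATG", strrep("GCA", 44), "TAA",   # 45 aa, SD
    strrep("C", 30), "ATG", strrep("GCA", 43), "TAA"))         # 44 aa, no SD
  orfs <- annotate_sd(g, find_orfs(g, min_aa = 10))
  kept45 <- filter_candidates(orfs, min_aa = 45)
  expect_equal(nrow(kept45), 1)
  expect_equal(kept45$size_aa, 45)
  # a 44-aa ORF is rejected even with a perfect SD
  kept44 <- filter_candidates(orfs[orfs$size_aa == 44, ], min_aa = 45)
  expect_equal(nrow(kept44), 0)
  # dropping the SD requirement can only grow the candidate set
  no_sd <- filter_candidates(orfs, require_sd = FALSE, min_aa = 10)
  with_sd <- filter_candidates(orfs, require_sd = TRUE, min_aa = 10)
  expect_true(all(paste(with_sd$start, with_sd$end) %in%
                  paste(no_sd$start, no_sd$end)))
  expect_gte(nrow(no_sd), nrow(with_sd))
})

test_that("ORFs containing N are flagged and excluded from candidates", {
  g <- genome_record("g", paste0("TT", SD_CORE, "CAATT",
                                 "ATG", strrep("GCA", 20), "NNN",
                                 strrep("GCA", 29), "TAA"))
  orfs <- annotate_sd(g, find_orfs(g, min_aa = 45))
  expect_true(any(orfs$contains_n))
  expect_equal(nrow(filter_candidates(orfs, min_aa = 45)), 0)
})

test_that("start-codon usage reproduces the published percentages", {
  cds <- fixture_features()
  usage <- start_codon_usage(cds[cds$type == "CDS", ])
  expect_equal(unname(usage), c(81.0, 11.4, 7.6))
  expect_equal(names(usage), c("ATG", "GTG", "TTG"))

  expect_equal(unname(start_codon_usage(rep("ATG", 13))["ATG"]), 100)
  expect_equal(unname(start_codon_usage(c("ATG", "ATG", "GTG"))),
               c(66.7, 33.3, 0))
  expect_error(start_codon_usage(character()),
               class = "phagekit_undefined_error")
})
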