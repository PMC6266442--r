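#' Specification of a synthetic phage-like genome
#'
#' Defaults emulate a ~50 kb lytic coliphage genome: about 80 unidirectional
#' ORFs with upstream Shine-Dalgarno cores, GC content near 44\%, and the
#' empirical start-codon mix (ATG 81\%, GTG 11.4\%, TTG 7.6\%). ORF lengths
#' are log-normal (median ~120 aa) truncated at the 45-aa candidate floor.
#'
#' @param n_orfs number of planted ORFs.
#' @param orf_len_aa list(meanlog, sdlog, min, max) for the length draw.
#' @param gc_target target GC percentage of the background composition.
#' @param sd_rate probability that an ORF receives a planted SD core.
#' @param intergenic list(min, max) intergenic spacer lengths (nt).
#' @param start_codon_probs named probabilities over ATG/GTG/TTG.
#' @param sd_spacer_range range of the SD-to-start spacer (nt); the spacer's
#'   final three bases are fixed to an in-frame TAA so the planted start is
#'   always the most upstream start of its stop-bounded region.
#' @param min_aa candidate length floor used when screening decoys.
#' @param seed integer seed.
#' @return list of class \code{genome_spec}.
#' @export
genome_spec <- function(n_orfs = 80L,
                        orf_len_aa = list(meanlog = log(120), sdlog = 0.8,
                                          min = 45L, max = 1300L),
                        gc_target = 44,
                        sd_rate = 1,
                        intergenic = list(min = 20L, max = 150L),
                        start_codon_probs = c(ATG = 0.81, GTG = 0.114,
                                              TTG = 0.076),
                        sd_spacer_range = c(5L, 9L),
                        min_aa = 45L,
                        seed = 1L) {
  stopifnot(gc_target > 0, gc_target < 100, sd_rate >= 0, sd_rate <= 1)
  p <- start_codon_probs / sum(start_codon_probs)
  if (sd_spacer_range[1] < 3L) {
    pk_stop("phagekit_value_error",
            "sd spacer must be at least 3 nt (an in-frame stop is planted in it)")
  }
  structure(list(n_orfs = as.integer(n_orfs), orf_len_aa = orf_len_aa,
                 gc_target = gc_target, sd_rate = sd_rate,
                 intergenic = intergenic, start_codon_probs = p,
                 sd_spacer_range = sd_spacer_range,
                 min_aa = as.integer(min_aa), seed = seed),
            class = "genome_spec")
}

random_bases <- function(n, gc) {
  p <- gc / 100
  sample(c("G", "C", "A", "T"), n, replace = TRUE,
         prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2))
}

# all non-stop codons weighted toward the GC target
codon_pool <- function(gc) {
  bases <- c("A", "C", "G", "T")
  codons <- as.vector(outer(outer(bases, bases, paste0), bases, paste0))
  codons <- setdiff(codons, STOP_CODONS)
  p <- gc / 100
  w <- vapply(strsplit(codons, ""), function(b) {
    prod(ifelse(b %in% c("G", "C"), p / 2, (1 - p) / 2))
  }, 0)
  list(codons = codons, weights = w / sum(w))
}

#' Simulate a phage-like genome with planted ORFs
#'
#' Generates a unidirectional gene layout: for each ORF, an intergenic
#' spacer, a Shine-Dalgarno core (when planted), an SD-to-start spacer
#' ending in an in-frame TAA, a start codon, a random non-stop codon body
#' and a stop codon. After assembly the genome is screened with the
#' package's own candidate caller (both strands, default SD acceptance) and
#' any accidental filter-passing ORF beyond the planted set is disrupted -
#' by resampling intergenic bases, or by a synonymous codon edit inside a
#' planted gene - so that the returned ground truth is exact.
#'
#' @param spec a \code{\link{genome_spec}}.
#' @param max_repair maximum screening iterations before giving up.
#' @return list of class \code{synthetic_genome}: \code{genome}
#'   (\code{genome_record}), \code{features} (\code{feature_table} with
#'   \code{has_sd}), \code{proteins} (named character) and \code{spec}.
#' @export
simulate_genome <- function(spec = genome_spec(), max_repair = 60L) {
  stopifnot(inherits(spec, "genome_spec"))
  with_seed(spec$seed, simulate_genome_impl(spec, max_repair))
}

simulate_genome_impl <- function(spec, max_repair) {
  gid <- sprintf("synthetic_phage_%d", spec$seed %||% 0L)
  pool <- codon_pool(spec$gc_target)
  n <- spec$n_orfs
  if (n == 0L) {
    len <- sample(seq(spec$intergenic$min, spec$intergenic$max), 1) + 400L
    g <- genome_record(gid, paste(random_bases(len, spec$gc_target),
                                  collapse = ""))
    # even a bare background can contain chance ORFs; scrub them too
    g <- scrub_decoys(g, data.frame(), spec, max_repair,
                      gene_map = integer(g$length_bp),
                      reserved = logical(g$length_bp), proteins = character())
    return(structure(list(genome = g$genome, features =
                            feature_table(data.frame(), genome_id = gid),
                          proteins = character(), spec = spec),
                     class = "synthetic_genome"))
  }
  lens <- pmin(pmax(round(stats::rlnorm(n, spec$orf_len_aa$meanlog,
                                        spec$orf_len_aa$sdlog)),
                    spec$orf_len_aa$min), spec$orf_len_aa$max)
  has_sd <- stats::runif(n) < spec$sd_rate
  starts_cod <- sample(names(spec$start_codon_probs), n, replace = TRUE,
                       prob = spec$start_codon_probs)
  segs <- character(0)
  feat <- vector("list", n)
  pos <- 0L
  add <- function(s) {
    segs[[length(segs) + 1L]] <<- s
    pos <<- pos + nchar(s)
  }
  core_pos <- matrix(NA_integer_, nrow = n, ncol = 2)
  for (i in seq_len(n)) {
    add(paste(random_bases(sample(seq(spec$intergenic$min,
                                      spec$intergenic$max), 1),
                           spec$gc_target), collapse = ""))
    spacer_len <- sample(seq(spec$sd_spacer_range[1],
                             spec$sd_spacer_range[2]), 1)
    sd_seq <- if (has_sd[i]) SD_CORE else {
      # draw a neutral window that does not itself look like an SD core
      repeat {
        cand <- paste(random_bases(7L, spec$gc_target), collapse = "")
        m <- sd_best_match(paste0(cand, "AAA"), min_spacer = 3L,
                           max_spacer = 3L)
        if (m$match_count < 4L || m$max_run < 3L) break
      }
      cand
    }
    core_pos[i, ] <- c(pos + 1L, pos + nchar(sd_seq))
    add(sd_seq)
    add(paste(c(random_bases(spacer_len - 3L, spec$gc_target), "T", "A", "A"),
              collapse = ""))
    orf_start <- pos + 1L
    body <- sample(pool$codons, lens[i] - 1L, replace = TRUE,
                   prob = pool$weights)
    add(paste(c(starts_cod[i], body, sample(STOP_CODONS, 1)), collapse = ""))
    feat[[i]] <- data.frame(
      orf_id = sprintf("ORF%d", i), type = "CDS", strand = "+",
      start = orf_start, end = pos, size_aa = lens[i],
      start_codon = starts_cod[i], has_sd = has_sd[i],
      sd_context = if (has_sd[i]) SD_CORE else sd_seq,
      stringsAsFactors = FALSE)
  }
  add(paste(random_bases(sample(seq(spec$intergenic$min,
                                    spec$intergenic$max), 1),
                         spec$gc_target), collapse = ""))
  seq <- paste(segs, collapse = "")
  g <- genome_record(gid, seq)
  features <- do.call(rbind, feat)

  # bookkeeping for the repair pass: which positions belong to which gene,
  # and which must not be touched (SD cores and the planted in-frame stops)
  gene_map <- integer(g$length_bp)
  reserved <- logical(g$length_bp)
  for (i in seq_len(n)) {
    gene_map[features$start[i]:features$end[i]] <- i
    # planted in-frame stop just upstream of the start, plus the SD window
    reserved[(features$start[i] - 3L):(features$start[i] - 1L)] <- TRUE
    reserved[core_pos[i, 1]:core_pos[i, 2]] <- TRUE
  }
  proteins <- stats::setNames(
    vapply(seq_len(n), function(i) {
      translate_dna(substring(g$sequence, features$start[i], features$end[i]))
    }, ""),
    features$orf_id)

  fixed <- scrub_decoys(g, features, spec, max_repair, gene_map, reserved,
                        proteins)
  structure(list(
    genome = fixed$genome,
    features = feature_table(features, genome_id = gid,
                             length_bp = fixed$genome$length_bp),
    proteins = fixed$proteins,
    spec = spec), class = "synthetic_genome")
}

# Disrupt every filter-passing candidate that is not a planted ORF.
#
# Strategy ladder, per decoy: (1) destroy its start codon, by resampling
# free intergenic bases or a synonymous codon edit inside the overlapped
# planted gene; (2) degrade its Shine-Dalgarno window below the acceptance
# threshold; (3) plant an early in-frame stop in the decoy's frame through
# a synonymous edit; (4) resample the whole body of the overlapped gene.
# All gene edits are synonymous except (4), which refreshes the recorded
# protein; planted SD cores and the planted in-frame stops are never
# touched, so planted calls are stable throughout.
scrub_decoys <- function(g, features, spec, max_repair, gene_map, reserved,
                         proteins) {
  planted_key <- if (nrow(features) > 0) {
    paste(features$start[features$has_sd],
          features$end[features$has_sd], "+")
  } else {
    character()
  }
  chars <- strsplit(g$sequence, "")[[1]]
  L <- length(chars)
  gc <- Biostrings::GENETIC_CODE
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  sd <- sd_params()
  core_chars <- strsplit(sd$core, "")[[1]]
  syn_of <- function(codon) {
    aa <- gc[[codon]]
    setdiff(names(gc)[gc == aa], c(codon, STOP_CODONS))
  }
  triplet_at <- function(idx, strand) {
    s <- paste(chars[idx], collapse = "")
    if (strand == "-") revcomp(s) else s
  }
  editable <- function(p) p >= 1L && p <= L && gene_map[p] == 0L && !reserved[p]
  # try every synonymous codon of the planted gene overlapping position p;
  # accept the first substitution for which check() is TRUE
  try_syn_at <- function(p, check) {
    gi <- gene_map[p]
    if (gi == 0L) return(FALSE)
    gstart <- features$start[gi]
    ci <- (p - gstart) %/% 3L + 1L
    if (ci <= 1L || ci > features$size_aa[gi]) return(FALSE)
    cpos <- gstart + (ci - 1L) * 3L
    cur <- paste(chars[cpos:(cpos + 2L)], collapse = "")
    for (alt in syn_of(cur)) {
      old <- chars[cpos:(cpos + 2L)]
      chars[cpos:(cpos + 2L)] <<- strsplit(alt, "")[[1]]
      if (check()) return(TRUE)
      chars[cpos:(cpos + 2L)] <<- old
    }
    FALSE
  }
  kill_start <- function(dec) {
    idx <- if (dec$strand == "+") {
      dec$start:(dec$start + 2L)
    } else {
      (dec$end - 2L):dec$end
    }
    no_start <- function() !(triplet_at(idx, dec$strand) %in% START_CODONS)
    free <- idx[vapply(idx, editable, TRUE)]
    if (length(free) > 0) {
      for (tries in 1:20) {
        chars[free] <<- random_bases(length(free), spec$gc_target)
        if (no_start()) return(TRUE)
      }
    }
    for (p in idx) {
      if (try_syn_at(p, no_start)) return(TRUE)
    }
    FALSE
  }
  sd_hit <- function(dec) {
    g2 <- genome_record("tmp", paste(chars, collapse = ""))
    detect_sd(g2, dec, core = sd$core, min_spacer = sd$min_spacer,
              max_spacer = sd$max_spacer, min_match = sd$min_match,
              min_consecutive = sd$min_consecutive)
  }
  kill_sd <- function(dec) {
    for (round in 1:25) {
      hit <- sd_hit(dec)
      if (is.null(hit)) return(TRUE)
      k <- hit$spacer
      # genomic position of core position j under this placement
      pos_of <- function(j) {
        if (dec$strand == "+") dec$start - k - 8L + j else dec$end + k + 8L - j
      }
      progressed <- FALSE
      for (j in sample(hit$matched_positions)) {
        p <- pos_of(j)
        if (p < 1L || p > L) next
        # base the genome must NOT carry at p for core position j to match
        match_base <- if (dec$strand == "+") {
          core_chars[j]
        } else {
          comp[[core_chars[j]]]
        }
        if (editable(p)) {
          chars[p] <<- sample(setdiff(names(comp), match_base), 1)
          progressed <- TRUE
          break
        }
        if (reserved[p]) next
        changed <- try_syn_at(p, function() chars[p] != match_base)
        if (changed) {
          progressed <- TRUE
          break
        }
      }
      if (!progressed) return(FALSE)
    }
    is.null(sd_hit(dec))
  }
  kill_by_stop <- function(dec) {
    n_cod <- dec$size_aa
    for (d in seq_len(min(n_cod, spec$min_aa))) {
      idx <- if (dec$strand == "+") {
        (dec$start + (d - 1L) * 3L):(dec$start + (d - 1L) * 3L + 2L)
      } else {
        (dec$end - (d - 1L) * 3L - 2L):(dec$end - (d - 1L) * 3L)
      }
      is_stop <- function() triplet_at(idx, dec$strand) %in% STOP_CODONS
      for (p in idx) {
        if (!editable(p) && try_syn_at(p, is_stop)) return(TRUE)
      }
    }
    FALSE
  }
  resample_body <- function(dec) {
    idx <- if (dec$strand == "+") {
      dec$start:(dec$start + 2L)
    } else {
      (dec$end - 2L):dec$end
    }
    genes <- unique(gene_map[idx][gene_map[idx] > 0L])
    if (length(genes) == 0) return(FALSE)
    gi <- genes[1]
    gstart <- features$start[gi]
    pool <- codon_pool(spec$gc_target)
    body <- sample(pool$codons, features$size_aa[gi] - 1L,
                   replace = TRUE, prob = pool$weights)
    bidx <- (gstart + 3L):(gstart + 3L * features$size_aa[gi] - 1L)
    chars[bidx] <<- unlist(strsplit(body, ""))
    proteins[[features$orf_id[gi]]] <<-
      translate_dna(paste(chars[gstart:features$end[gi]], collapse = ""))
    TRUE
  }
  for (iter in seq_len(max_repair)) {
    g2 <- genome_record(g$id, paste(chars, collapse = ""))
    cand <- annotate_genome(g2, min_aa = spec$min_aa, strands = "both",
                            require_sd = TRUE, sd = sd)
    key <- paste(cand$start, cand$end, cand$strand)
    if (length(setdiff(planted_key, key)) > 0) {
      pk_stop("phagekit_internal_error",
              "planted ORF lost during decoy repair")
    }
    extra <- cand[!key %in% planted_key, , drop = FALSE]
    if (nrow(extra) == 0) {
      return(list(genome = g2, proteins = proteins))
    }
    for (r in seq_len(nrow(extra))) {
      dec <- as.list(extra[r, ])
      if (kill_start(dec)) next
      if (kill_sd(dec)) next
      if (kill_by_stop(dec)) next
      resample_body(dec)
    }
  }
  pk_stop("phagekit_infeasible_error",
          sprintf("could not clear decoy ORFs within %d repair passes",
                  max_repair))
}

#' Diverge the proteome of a synthetic genome
#'
#' Introduces codon-level substitutions so that each encoded protein's
#' exact-position identity to its parent is approximately
#' \code{target_identity} percent. Substituted codons always change the
#' amino acid (to a random other residue), never touch the start codon, and
#' never introduce stops, so nucleotide and protein views stay consistent.
#' Returned identities are the realized per-protein values.
#'
#' @param sim a \code{synthetic_genome} from \code{\link{simulate_genome}}.
#' @param target_identity target percent identity in (0, 100].
#' @param seed integer seed.
#' @return list of class \code{synthetic_genome} with an extra
#'   \code{identities} data.frame (\code{orf_id}, \code{identity_pct}).
#' @export
diverge_proteome <- function(sim, target_identity, seed = 1L) {
  stopifnot(inherits(sim, "synthetic_genome"))
  if (target_identity <= 0 || target_identity > 100) {
    pk_stop("phagekit_value_error", "target identity must be in (0, 100]")
  }
  with_seed(seed, {
    chars <- strsplit(sim$genome$sequence, "")[[1]]
    gc <- Biostrings::GENETIC_CODE
    features <- sim$features
    n <- nrow(features)
    ident <- numeric(n)
    for (i in seq_len(n)) {
      size <- features$size_aa[i]
      m <- min(round((1 - target_identity / 100) * size), size - 1L)
      ident[i] <- 100 * (size - m) / size
      if (m == 0) next
      aa_pos <- sample(2:size, m)
      for (ap in aa_pos) {
        cpos <- features$start[i] + (ap - 1L) * 3L
        cur <- paste(chars[cpos:(cpos + 2L)], collapse = "")
        cur_aa <- gc[[cur]]
        alt <- sample(setdiff(names(gc)[gc != cur_aa], STOP_CODONS), 1)
        chars[cpos:(cpos + 2L)] <- strsplit(alt, "")[[1]]
      }
    }
    g <- genome_record(paste0(sim$genome$id, "_div"),
                       paste(chars, collapse = ""))
    proteins <- stats::setNames(
      vapply(seq_len(n), function(i) {
        translate_dna(substring(g$sequence, features$start[i],
                                features$end[i]))
      }, ""),
      features$orf_id)
    structure(list(genome = g, features = features, proteins = proteins,
                   spec = sim$spec,
                   identities = data.frame(orf_id = features$orf_id,
                                           identity_pct = ident,
                                           stringsAsFactors = FALSE)),
              class = "synthetic_genome")
  })
}

#' Specification of a one-step growth-curve simulation
#'
#' Encodes the classical one-step design: free phage adsorb, infected cells
#' lyse around the latent period with normally distributed lysis times, and
#' every sample is titered by plating with Poisson counting noise.
#'
#' @param latent_min latent period (minutes; lysis-time mean).
#' @param burst burst size (new virions per infected cell).
#' @param initial_free_phage starting titer (PFU/mL).
#' @param lysis_spread_min standard deviation of lysis times (minutes).
#' @param sampling_times sampling grid (minutes).
#' @param replicates number of replicate series.
#' @param temperature_C temperature label carried on the curve.
#' @param moi multiplicity of infection metadata.
#' @param plate_volume_ml volume plated when titering.
#' @param max_expected_count largest countable plate count; dilutions are
#'   powers of ten chosen to stay below it (mimicking titration practice).
#' @param noise apply Poisson plating noise (TRUE) or return expected
#'   titers exactly (FALSE).
#' @param seed integer seed.
#' @return list of class \code{growth_spec}.
#' @export
growth_spec <- function(latent_min = 102, burst = 602,
                        initial_free_phage = 1e6, lysis_spread_min = 10,
                        sampling_times = seq(0, 180, by = 10),
                        replicates = 3L, temperature_C = 20, moi = 0.05,
                        plate_volume_ml = 0.1, max_expected_count = 300,
                        noise = TRUE, seed = 1L) {
  stopifnot(latent_min > 0, burst >= 0, initial_free_phage > 0,
            lysis_spread_min >= 0)
  structure(as.list(environment()), class = "growth_spec")
}

#' Preset growth regimes
#'
#' Three temperature regimes spanning the phenotypes reported for
#' low-temperature-adapted coliphages: a large burst with a long latent
#' period at 20 C (602 virions, 102 min), an intermediate burst at 30 C
#' (64 virions, 54 min), and a minimal burst at 37 C (2 virions, 55 min).
#'
#' @param name one of \code{"20C"}, \code{"30C"}, \code{"37C"}.
#' @param ... overrides passed to \code{\link{growth_spec}}.
#' @return a \code{growth_spec}.
#' @export
growth_spec_preset <- function(name = c("20C", "30C", "37C"), ...) {
  name <- match.arg(name)
  base <- switch(name,
    "20C" = list(latent_min = 102, burst = 602, lysis_spread_min = 10,
                 sampling_times = seq(0, 180, by = 10), temperature_C = 20),
    "30C" = list(latent_min = 54, burst = 64, lysis_spread_min = 6,
                 sampling_times = seq(0, 120, by = 10), temperature_C = 30),
    "37C" = list(latent_min = 55, burst = 2, lysis_spread_min = 6,
                 sampling_times = seq(0, 120, by = 10), temperature_C = 37))
  do.call(growth_spec, utils::modifyList(base, list(...)))
}

#' Simulate a one-step growth curve
#'
#' The expected free-phage titer is
#' \code{N0 * (1 + burst * pnorm(t, latent, spread))}: flat at the initial
#' titer until lysis onset, rising to \code{(1 + burst) * N0} as infected
#' cells burst. With \code{noise = TRUE} each sample is titered by Poisson
#' plating at a power-of-ten dilution chosen to keep the expected plate
#' count below \code{max_expected_count}.
#'
#' @param spec a \code{\link{growth_spec}}.
#' @return a \code{\link{growth_curve}}.
#' @export
simulate_growth_curve <- function(spec = growth_spec()) {
  stopifnot(inherits(spec, "growth_spec"))
  with_seed(spec$seed, {
    tt <- spec$sampling_times
    expected <- spec$initial_free_phage *
      (1 + spec$burst * stats::pnorm(tt, spec$latent_min,
                                     max(spec$lysis_spread_min, 1e-9)))
    rows <- lapply(seq_len(spec$replicates), function(r) {
      titer <- if (!spec$noise) {
        expected
      } else {
        vapply(expected, function(e) {
          v <- spec$plate_volume_ml
          d <- 10^max(0, ceiling(log10(e * v / spec$max_expected_count)))
          count <- stats::rpois(1, e * v / d)
          max(count, 1) * d / v
        }, 0)
      }
      data.frame(time_min = tt, titer_pfu_per_ml = titer, replicate = r)
    })
    df <- do.call(rbind, rows)
    gc <- growth_curve(df$time_min, df$titer_pfu_per_ml, df$replicate,
                       temperature_C = spec$temperature_C, moi = spec$moi)
    attr(gc, "spec") <- spec
    gc
  })
}

#' Simulate a spot-test matrix
#'
#' Builds a host-range panel with prescribed per-strain scores. Patterns
#' are prefix-monotone by construction (an infective dilution implies all
#' shallower dilutions are infective), matching the scoring convention of
#' \code{\link{score_spot_test}}. The seed only shuffles strain order, so a
#' fixed profile is recovered exactly.
#'
#' @param n_strains number of strains.
#' @param profile character vector of target scores, recycled to
#'   \code{n_strains} (default all \code{"-"}).
#' @param pathogenic logical vector, recycled.
#' @param seed integer seed.
#' @return spot-test record data.frame (as \code{\link{read_spot_csv}}).
#' @export
simulate_spot_matrix <- function(n_strains, profile = "-",
                                 pathogenic = FALSE, seed = 1L) {
  profile <- rep_len(profile, n_strains)
  pathogenic <- rep_len(as.logical(pathogenic), n_strains)
  if (!all(profile %in% SPOT_SYMBOLS)) {
    pk_stop("phagekit_value_error", "profile contains unknown score symbols")
  }
  with_seed(seed, {
    ord <- sample(n_strains)
    profile <- profile[ord]
    pathogenic <- pathogenic[ord]
    ranks <- spot_rank(profile) - 1L
    df <- data.frame(
      strain_id = sprintf("S%03d", seq_len(n_strains)),
      pathogenic = pathogenic,
      d0 = ranks >= 1L, d2 = ranks >= 2L, d4 = ranks >= 3L, d6 = ranks >= 4L,
      stringsAsFactors = FALSE)
    df$score <- vapply(seq_len(nrow(df)), function(i) {
      score_spot_test(as.logical(unlist(df[i, c("d0", "d2", "d4", "d6")])))
    }, "")
    df
  })
}
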