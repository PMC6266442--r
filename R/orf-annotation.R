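STOP_CODONS <- c("TAA", "TAG", "TGA")
START_CODONS <- c("ATG", "GTG", "TTG")

#' Default Shine-Dalgarno core
#'
#' The conserved ribosome-binding motif 5'-AGGAGGU-3', matched on the DNA
#' strand as AGGAGGT (U/T equivalence).
#' @export
SD_CORE <- "AGGAGGT"

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

codons_at <- function(seq, pos) substring(seq, pos, pos + 2L)

# scan one already-oriented strand; returns ORFs in local (oriented) coords
scan_strand <- function(s, min_aa, all_starts) {
  L <- nchar(s)
  out <- vector("list", 3L)
  for (f in 0:2) {
    p <- seq.int(1L + f, L - 2L, by = 3L)
    if (length(p) == 0) next
    cod <- codons_at(s, p)
    stop_idx <- which(cod %in% STOP_CODONS)
    start_idx <- which(cod %in% START_CODONS)
    if (length(stop_idx) == 0 || length(start_idx) == 0) next
    prev_stop <- c(0L, stop_idx[-length(stop_idx)])
    rows <- list()
    for (k in seq_along(stop_idx)) {
      si <- stop_idx[k]
      cand <- start_idx[start_idx > prev_stop[k] & start_idx < si]
      if (length(cand) == 0) next
      keep <- if (all_starts) cand else cand[1]
      for (ci in keep) {
        aa <- si - ci               # start codon codes; the stop does not
        if (aa < min_aa) next
        rows[[length(rows) + 1L]] <-
          c(start = p[ci], end = p[si] + 2L, frame = f, start_i = ci)
      }
    }
    if (length(rows) > 0) out[[f + 1L]] <- do.call(rbind, rows)
  }
  m <- do.call(rbind, out[!vapply(out, is.null, TRUE)])
  m
}

#' Call open reading frames
#'
#' Six-frame (or forward-only) scan for start-to-stop coding spans. For each
#' stop codon and frame, the most upstream valid start after the previous
#' in-frame stop is reported ("longest ORF per stop"); \code{all_starts}
#' additionally reports every nested start. Spans include the stop codon;
#' the reported amino-acid length excludes it. Reverse-strand calls are
#' mapped back to forward coordinates (start = leftmost base) with strand
#' \code{"-"}. ORFs whose span contains an N are flagged via
#' \code{contains_n} so that translation-dependent steps can drop them.
#'
#' @param g a \code{\link{genome_record}}.
#' @param min_aa minimum protein length in amino acids (default 45, the
#'   conventional floor for small phage proteins).
#' @param strands \code{"both"} or \code{"forward"}.
#' @param all_starts report nested starts within a stop-bounded region.
#' @return a data.frame of class \code{orf_candidates}: \code{start},
#'   \code{end}, \code{strand}, \code{frame}, \code{start_codon},
#'   \code{size_aa}, \code{contains_n}, sorted by start.
#' @export
find_orfs <- function(g, min_aa = 45L, strands = c("both", "forward"),
                      all_starts = FALSE) {
  stopifnot(inherits(g, "genome_record"))
  strands <- match.arg(strands)
  empty <- data.frame(start = integer(), end = integer(),
                      strand = character(), frame = integer(),
                      start_codon = character(), size_aa = integer(),
                      contains_n = logical(), stringsAsFactors = FALSE)
  collect <- list()
  L <- g$length_bp
  if (L >= 6) {
    fwd <- scan_strand(g$sequence, min_aa, all_starts)
    if (!is.null(fwd)) {
      collect$fwd <- data.frame(
        start = fwd[, "start"], end = fwd[, "end"], strand = "+",
        frame = fwd[, "frame"], stringsAsFactors = FALSE)
    }
    if (strands == "both") {
      rc <- revcomp(g$sequence)
      rev <- scan_strand(rc, min_aa, all_starts)
      if (!is.null(rev)) {
        collect$rev <- data.frame(
          start = L - rev[, "end"] + 1L, end = L - rev[, "start"] + 1L,
          strand = "-", frame = rev[, "frame"], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(collect) == 0) {
    return(structure(empty, genome_id = g$id,
                     class = c("orf_candidates", "data.frame")))
  }
  df <- do.call(rbind, collect)
  df$size_aa <- coords_to_aa_length(df$start, df$end)
  df <- df[df$size_aa >= min_aa, , drop = FALSE]
  if (nrow(df) == 0) {
    return(structure(empty, genome_id = g$id,
                     class = c("orf_candidates", "data.frame")))
  }
  span <- substring(g$sequence, df$start, df$end)
  df$start_codon <- ifelse(df$strand == "+",
                           substring(span, 1L, 3L),
                           vapply(substring(span, nchar(span) - 2L, nchar(span)),
                                  revcomp, "", USE.NAMES = FALSE))
  df$contains_n <- grepl("N", span, fixed = TRUE)
  df <- df[order(df$start, df$end, df$strand), , drop = FALSE]
  rownames(df) <- NULL
  structure(df[, c("start", "end", "strand", "frame", "start_codon",
                   "size_aa", "contains_n")],
            genome_id = g$id, class = c("orf_candidates", "data.frame"))
}

#' Best Shine-Dalgarno placement within an upstream window
#'
#' Slides the motif core over the window at every spacer (distance in nt
#' between the core's 3' end and the start codon) in
#' \code{[min_spacer, max_spacer]} and returns the placement maximizing the
#' number of matching positions. Ties are broken deterministically: spacer
#' closest to 7 nt (the canonical spacing), then the smaller spacer.
#' Placements that would extend past the 5' end of the window are skipped,
#' so truncated windows near the genome start are handled naturally.
#'
#' @param window character scalar: upstream sequence, 5' to 3', ending at
#'   the base immediately before the start codon.
#' @param core motif core on the DNA strand (default \code{SD_CORE}).
#' @param min_spacer,max_spacer spacer range searched, in nt.
#' @return list with \code{window_sequence}, \code{spacer},
#'   \code{match_count}, \code{matched_positions} (1-based indices into the
#'   core) and \code{max_run} (longest consecutive match run), or
#'   \code{NULL} when no placement fits the window.
#' @export
sd_best_match <- function(window, core = SD_CORE, min_spacer = 3L,
                          max_spacer = 15L) {
  window <- toupper(window)
  W <- nchar(window)
  n <- nchar(core)
  core_chars <- strsplit(core, "")[[1]]
  best <- NULL
  for (k in seq.int(min_spacer, max_spacer)) {
    lo <- W - k - n + 1L
    if (lo < 1L) next
    seg <- strsplit(substring(window, lo, lo + n - 1L), "")[[1]]
    hits <- which(seg == core_chars)
    runs <- rle(seg == core_chars)
    max_run <- if (any(runs$values)) max(runs$lengths[runs$values]) else 0L
    cand <- list(window_sequence = window, spacer = k,
                 match_count = length(hits), matched_positions = hits,
                 max_run = max_run)
    if (is.null(best) ||
        cand$match_count > best$match_count ||
        (cand$match_count == best$match_count &&
         (abs(cand$spacer - 7L) < abs(best$spacer - 7L) ||
          (abs(cand$spacer - 7L) == abs(best$spacer - 7L) &&
           cand$spacer < best$spacer)))) {
      best <- cand
    }
  }
  best
}

upstream_window <- function(g, start, end, strand, max_spacer, core_len) {
  w <- max_spacer + core_len
  if (strand == "+") {
    lo <- max(1L, start - w)
    if (start <= 1L) return("")
    substring(g$sequence, lo, start - 1L)
  } else {
    hi <- min(g$length_bp, end + w)
    if (end >= g$length_bp) return("")
    revcomp(substring(g$sequence, end + 1L, hi))
  }
}

#' Detect a Shine-Dalgarno motif upstream of an ORF
#'
#' Extracts the upstream window of an ORF (strand-aware) and scores the best
#' core placement with \code{\link{sd_best_match}}. The placement is
#' accepted when it has at least \code{min_match} matching positions of
#' which at least \code{min_consecutive} are consecutive; otherwise
#' \code{NULL} is returned. Published annotation tables show that accepted
#' ribosome-binding contexts can be substantially degenerate, so both
#' thresholds are exposed as knobs (see \code{\link{sd_params}}).
#'
#' @param g a \code{genome_record}.
#' @param orf one row of an \code{orf_candidates} table (or any list with
#'   \code{start}, \code{end}, \code{strand}).
#' @param core motif core (DNA alphabet).
#' @param min_spacer,max_spacer spacer range in nt.
#' @param min_match minimum number of matching core positions.
#' @param min_consecutive minimum length of the longest consecutive run.
#' @return an accepted placement list as in \code{\link{sd_best_match}}, or
#'   \code{NULL}.
#' @export
detect_sd <- function(g, orf, core = SD_CORE, min_spacer = 3L,
                      max_spacer = 15L, min_match = 4L, min_consecutive = 3L) {
  win <- upstream_window(g, orf$start, orf$end, orf$strand,
                         max_spacer, nchar(core))
  if (!nzchar(win)) return(NULL)
  best <- sd_best_match(win, core, min_spacer, max_spacer)
  if (is.null(best)) return(NULL)
  if (best$match_count < min_match || best$max_run < min_consecutive) {
    return(NULL)
  }
  best
}

#' Bundle of Shine-Dalgarno search parameters
#'
#' @param core motif core.
#' @param min_spacer,max_spacer spacer range (nt).
#' @param min_match acceptance threshold on matching positions.
#' @param min_consecutive acceptance threshold on the longest match run.
#' @return named list of parameters.
#' @export
sd_params <- function(core = SD_CORE, min_spacer = 3L, max_spacer = 15L,
                      min_match = 4L, min_consecutive = 3L) {
  list(core = core, min_spacer = min_spacer, max_spacer = max_spacer,
       min_match = min_match, min_consecutive = min_consecutive)
}

#' Annotate Shine-Dalgarno matches on a candidate table
#'
#' Runs \code{\link{detect_sd}} for every candidate and appends the columns
#' \code{sd_found}, \code{sd_match_count}, \code{sd_spacer} and
#' \code{sd_context} (spacer plus core window actually inspected).
#'
#' @param g a \code{genome_record}.
#' @param orfs an \code{orf_candidates} table.
#' @param sd a list from \code{\link{sd_params}}.
#' @return the candidate table with SD columns appended.
#' @export
annotate_sd <- function(g, orfs, sd = sd_params()) {
  n <- nrow(orfs)
  found <- logical(n); cnt <- integer(n)
  spc <- rep(NA_integer_, n); ctx <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    hit <- detect_sd(g, orfs[i, ], core = sd$core,
                     min_spacer = sd$min_spacer, max_spacer = sd$max_spacer,
                     min_match = sd$min_match,
                     min_consecutive = sd$min_consecutive)
    if (!is.null(hit)) {
      found[i] <- TRUE
      cnt[i] <- hit$match_count
      spc[i] <- hit$spacer
      ctx[i] <- hit$window_sequence
    }
  }
  orfs$sd_found <- found
  orfs$sd_match_count <- cnt
  orfs$sd_spacer <- spc
  orfs$sd_context <- ctx
  orfs
}

#' Filter ORF candidates
#'
#' Applies the candidate rule used for phage annotation tables: keep ORFs of
#' at least \code{min_aa} amino acids that begin with an allowed start codon
#' (ATG, GTG or TTG) and, when \code{require_sd}, carry an accepted
#' Shine-Dalgarno match. Candidates containing N bases are dropped since
#' their translation is ambiguous. Sets \code{passes_filter} on the full
#' table and returns the passing subset.
#'
#' @param orfs an \code{orf_candidates} table, with SD columns when
#'   \code{require_sd} (see \code{\link{annotate_sd}}).
#' @param require_sd require an accepted SD match (default TRUE).
#' @param min_aa minimum amino-acid length (default 45).
#' @return the passing subset, with \code{passes_filter = TRUE}.
#' @export
filter_candidates <- function(orfs, require_sd = TRUE, min_aa = 45L) {
  if (require_sd && !"sd_found" %in% names(orfs)) {
    pk_stop("phagekit_state_error",
            "run annotate_sd() before filtering with require_sd = TRUE")
  }
  pass <- orfs$size_aa >= min_aa &
    orfs$start_codon %in% START_CODONS &
    !orfs$contains_n
  if (require_sd) pass <- pass & orfs$sd_found
  orfs$passes_filter <- pass
  out <- orfs[pass, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Start-codon usage statistics
#'
#' Percentage of ORFs initiating with each of ATG, GTG and TTG, rounded
#' half-up to one decimal place.
#'
#' @param x an \code{orf_candidates} table, a \code{feature_table}, or a
#'   character vector of start codons.
#' @return named numeric vector over \code{c("ATG","GTG","TTG")}.
#' @export
start_codon_usage <- function(x) {
  codons <- if (is.character(x)) x else x$start_codon
  codons <- codons[!is.na(codons)]
  if (length(codons) == 0) {
    pk_stop("phagekit_undefined_error",
            "start-codon usage undefined for an empty ORF set")
  }
  counts <- vapply(START_CODONS, function(cc) sum(codons == cc), 0L)
  round_half_up(100 * counts / length(codons), 1)
}

#' Full genome annotation
#'
#' Composition of \code{\link{find_orfs}}, \code{\link{annotate_sd}} and
#' \code{\link{filter_candidates}}: the standard candidate-calling pipeline
#' for a phage genome.
#'
#' @param g a \code{genome_record}.
#' @param min_aa minimum protein length.
#' @param strands \code{"both"} or \code{"forward"}.
#' @param require_sd require an accepted SD match.
#' @param sd SD search parameters (\code{\link{sd_params}}).
#' @return passing \code{orf_candidates} with SD columns.
#' @export
annotate_genome <- function(g, min_aa = 45L, strands = "both",
                            require_sd = TRUE, sd = sd_params()) {
  orfs <- find_orfs(g, min_aa = min_aa, strands = strands)
  orfs <- annotate_sd(g, orfs, sd = sd)
  filter_candidates(orfs, require_sd = require_sd, min_aa = min_aa)
}
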