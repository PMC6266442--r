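# Independent oracles and small data helpers used across the suite.
# These deliberately take different algorithmic routes than the package
# implementations they check.

random_dna <- function(n, gc = 50) {
  p <- gc / 100
  paste(sample(c("G", "C", "A", "T"), n, replace = TRUE,
               prob = c(p / 2, p / 2, (1 - p) / 2, (1 - p) / 2)),
        collapse = "")
}

random_protein <- function(n) {
  paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n, replace = TRUE),
        collapse = "")
}

oracle_revcomp <- function(s) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
}

# Brute-force ORF enumeration: every start position is examined directly
# and walked forward codon by codon to its first in-frame stop, with no
# shared code or frame bookkeeping with the package's caller.
oracle_orfs <- function(seq, min_aa = 45L, strands = "both",
                        all_starts = FALSE) {
  one_strand <- function(s) {
    L <- nchar(s)
    hits <- list()
    for (p in seq_len(max(L - 5L, 0L))) {
      if (!substr(s, p, p + 2L) %in% c("ATG", "GTG", "TTG")) next
      q <- p + 3L
      stop_at <- NA_integer_
      while (q + 2L <= L) {
        if (substr(s, q, q + 2L) %in% c("TAA", "TAG", "TGA")) {
          stop_at <- q
          break
        }
        q <- q + 3L
      }
      if (is.na(stop_at)) next
      aa <- (stop_at - p) / 3L
      if (aa < min_aa) next
      hits[[length(hits) + 1L]] <- c(start = p, end = stop_at + 2L)
    }
    if (length(hits) == 0) return(NULL)
    m <- as.data.frame(do.call(rbind, hits))
    if (!all_starts) {
      # longest ORF per stop: keep the smallest start for each end
      m <- do.call(rbind, lapply(split(m, m$end), function(d) {
        d[which.min(d$start), ]
      }))
    }
    m
  }
  fwd <- one_strand(seq)
  out <- if (!is.null(fwd)) {
    data.frame(start = fwd$start, end = fwd$end, strand = "+")
  } else {
    NULL
  }
  if (strands == "both") {
    L <- nchar(seq)
    rev <- one_strand(oracle_revcomp(seq))
    if (!is.null(rev)) {
      out <- rbind(out, data.frame(start = L - rev$end + 1L,
                                   end = L - rev$start + 1L, strand = "-"))
    }
  }
  if (is.null(out)) {
    return(data.frame(start = integer(), end = integer(),
                      strand = character()))
  }
  out <- out[order(out$start, out$end, out$strand), ]
  rownames(out) <- NULL
  out
}

# Gotoh affine-gap global alignment scoring oracle. Returns the optimal
# score together with the maximum and minimum identical-residue counts
# attainable among all score-optimal alignments (lexicographic DP).
oracle_global_alignment <- function(a, b, gap_open = 10, gap_ext = 1) {
  sub <- get_blosum62()
  av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
  n <- length(av); m <- length(bv)
  NEG <- -1e9
  new_layer <- function() {
    list(s = matrix(NEG, n + 1, m + 1),
         hi = matrix(0L, n + 1, m + 1),
         lo = matrix(0L, n + 1, m + 1))
  }
  M <- new_layer(); X <- new_layer(); Y <- new_layer()
  M$s[1, 1] <- 0
  for (i in seq_len(n)) X$s[i + 1, 1] <- -(gap_open + i * gap_ext)
  for (j in seq_len(m)) Y$s[1, j + 1] <- -(gap_open + j * gap_ext)
  best3 <- function(cands) {
    # cands: list of c(score, hi, lo); lexicographic max on score,
    # then track the hi/lo identity range over all score-ties
    sc <- vapply(cands, `[[`, 0, 1)
    top <- max(sc)
    ties <- cands[sc == top]
    c(top,
      max(vapply(ties, `[[`, 0, 2)),
      min(vapply(ties, `[[`, 0, 3)))
  }
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      eq <- as.integer(av[i] == bv[j])
      sc <- sub[av[i], bv[j]]
      diag <- best3(list(c(M$s[i, j], M$hi[i, j], M$lo[i, j]),
                         c(X$s[i, j], X$hi[i, j], X$lo[i, j]),
                         c(Y$s[i, j], Y$hi[i, j], Y$lo[i, j])))
      M$s[i + 1, j + 1] <- diag[1] + sc
      M$hi[i + 1, j + 1] <- diag[2] + eq
      M$lo[i + 1, j + 1] <- diag[3] + eq
      up <- best3(list(c(M$s[i, j + 1] - gap_open - gap_ext,
                         M$hi[i, j + 1], M$lo[i, j + 1]),
                       c(X$s[i, j + 1] - gap_ext,
                         X$hi[i, j + 1], X$lo[i, j + 1]),
                       c(Y$s[i, j + 1] - gap_open - gap_ext,
                         Y$hi[i, j + 1], Y$lo[i, j + 1])))
      X$s[i + 1, j + 1] <- up[1]; X$hi[i + 1, j + 1] <- up[2]
      X$lo[i + 1, j + 1] <- up[3]
      left <- best3(list(c(M$s[i + 1, j] - gap_open - gap_ext,
                           M$hi[i + 1, j], M$lo[i + 1, j]),
                         c(Y$s[i + 1, j] - gap_ext,
                           Y$hi[i + 1, j], Y$lo[i + 1, j]),
                         c(X$s[i + 1, j] - gap_open - gap_ext,
                           X$hi[i + 1, j], X$lo[i + 1, j])))
      Y$s[i + 1, j + 1] <- left[1]; Y$hi[i + 1, j + 1] <- left[2]
      Y$lo[i + 1, j + 1] <- left[3]
    }
  }
  fin <- best3(list(c(M$s[n + 1, m + 1], M$hi[n + 1, m + 1], M$lo[n + 1, m + 1]),
                    c(X$s[n + 1, m + 1], X$hi[n + 1, m + 1], X$lo[n + 1, m + 1]),
                    c(Y$s[n + 1, m + 1], Y$hi[n + 1, m + 1], Y$lo[n + 1, m + 1])))
  list(score = fin[1], max_identical = fin[2], min_identical = fin[3])
}

get_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# direct sums-of-squares one-way ANOVA
oracle_anova_f <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ss_b <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2, 0))
  ss_w <- sum(vapply(groups, function(g) sum((g - mean(g))^2), 0))
  df_b <- length(groups) - 1
  df_w <- length(all) - length(groups)
  (ss_b / df_b) / (ss_w / df_w)
}

fixture_features <- function() {
  read_feature_table(phagekit_example("st32_feature_table.tsv"))
}

fixture_spots <- function() {
  read_spot_csv(phagekit_example("st32_host_range.csv"))
}
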