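# Average (isotope-averaged) residue masses in Da, as used by the common
# web MW calculators; a peptide mass is the residue sum plus one water.
RESIDUE_MASS_DA <- c(
  A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
  E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
  L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
  S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326
)
WATER_MASS_DA <- 18.01524

# Ionizable-group pKa sets. "bjellqvist" is the set behind the classic
# Compute pI web tool (N-terminal pKa depends on the first residue);
# "emboss" is the simpler set used by EMBOSS iep.
PKA_SETS <- list(
  bjellqvist = list(
    cterm = 3.55,
    nterm_default = 7.50,
    nterm_by_residue = c(A = 7.59, M = 7.00, S = 6.93, P = 8.36, T = 6.82,
                         V = 7.44, E = 7.70, G = 7.50),
    negative = c(D = 4.05, E = 4.45, C = 9.00, Y = 10.00),
    positive = c(H = 5.98, K = 10.00, R = 12.00)
  ),
  emboss = list(
    cterm = 3.60,
    nterm_default = 8.60,
    nterm_by_residue = c(),
    negative = c(D = 3.90, E = 4.10, C = 8.50, Y = 10.10),
    positive = c(H = 6.50, K = 10.80, R = 12.50)
  )
)

check_protein <- function(p) {
  stopifnot(is.character(p), length(p) == 1L)
  p <- toupper(p)
  if (!nzchar(p)) {
    pk_stop("phagekit_undefined_error", "empty protein sequence")
  }
  bad <- regmatches(p, regexpr(sprintf("[^%s]", paste(names(RESIDUE_MASS_DA),
                                                      collapse = "")), p))
  if (length(bad) > 0) {
    pk_stop("phagekit_alphabet_error",
            sprintf("unknown residue letter '%s'", bad))
  }
  p
}

#' Translate a coding DNA sequence
#'
#' Standard bacterial genetic code. A trailing stop codon is allowed and
#' stripped. With \code{treat_start_as_met} (the bacterial convention for
#' translation initiation), a leading GTG or TTG start codon is rendered as
#' methionine. Internal stop codons and ambiguous (N-containing) codons are
#' errors.
#'
#' @param dna character scalar, length divisible by 3.
#' @param treat_start_as_met render alternative start codons as M
#'   (default TRUE).
#' @return amino-acid string.
#' @export
#' @examples
#' translate_dna("ATGAAATAA")  # "MK"
#' translate_dna("TTGAAATAA")  # "MK"
#' translate_dna("TTGAAATAA", treat_start_as_met = FALSE)  # "LK"
translate_dna <- function(dna, treat_start_as_met = TRUE) {
  dna <- toupper(dna)
  n <- nchar(dna)
  if (n == 0 || n %% 3L != 0L) {
    pk_stop("phagekit_frame_error", "DNA length not a positive multiple of 3")
  }
  pos <- seq.int(1L, n - 2L, by = 3L)
  codons <- substring(dna, pos, pos + 2L)
  if (any(grepl("N", codons, fixed = TRUE))) {
    pk_stop("phagekit_ambiguity_error",
            sprintf("ambiguous codon '%s' at codon %d",
                    codons[grepl("N", codons)][1],
                    which(grepl("N", codons))[1]))
  }
  aa <- Biostrings::GENETIC_CODE[codons]
  if (anyNA(aa)) {
    pk_stop("phagekit_alphabet_error",
            sprintf("invalid codon '%s'", codons[is.na(aa)][1]))
  }
  if (aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
    codons <- codons[-length(codons)]
  }
  if (any(aa == "*")) {
    pk_stop("phagekit_premature_stop_error",
            sprintf("internal stop codon at codon %d", which(aa == "*")[1]))
  }
  if (treat_start_as_met && length(aa) > 0 && codons[1] %in% START_CODONS) {
    aa[1] <- "M"
  }
  paste(aa, collapse = "")
}

#' Molecular weight of a protein, in daltons
#'
#' Sum of average residue masses plus one water mass. Exact value, for
#' additivity checks and unit conversions.
#'
#' @param p amino-acid string (20-letter alphabet).
#' @return mass in Da.
#' @export
molecular_weight_da <- function(p) {
  p <- check_protein(p)
  res <- strsplit(p, "")[[1]]
  sum(RESIDUE_MASS_DA[res]) + WATER_MASS_DA
}

#' Molecular weight of a protein, in kDa
#'
#' \code{\link{molecular_weight_da}} divided by 1000 and rounded half-up to
#' one decimal place, the precision used in annotation tables.
#'
#' @param p amino-acid string.
#' @return mass in kDa (1 decimal place).
#' @export
#' @examples
#' molecular_weight("G")  # 0.1
molecular_weight <- function(p) {
  round_half_up(molecular_weight_da(p) / 1000, 1)
}

#' Net charge of a protein at a given pH
#'
#' Henderson-Hasselbalch sum over the ionizable groups: the N-terminal
#' amine, the C-terminal carboxyl, and the side chains of D, E, C, Y
#' (acidic) and H, K, R (basic). Strictly decreasing in pH, which makes the
#' isoelectric point unique.
#'
#' @param p amino-acid string.
#' @param pH numeric vector of pH values.
#' @param pka_set \code{"bjellqvist"} (default) or \code{"emboss"}.
#' @return numeric vector of net charges.
#' @export
protein_charge <- function(p, pH, pka_set = c("bjellqvist", "emboss")) {
  p <- check_protein(p)
  pk <- PKA_SETS[[match.arg(pka_set)]]
  res <- strsplit(p, "")[[1]]
  first <- res[1]
  nterm_pka <- if (first %in% names(pk$nterm_by_residue)) {
    pk$nterm_by_residue[[first]]
  } else {
    pk$nterm_default
  }
  counts_neg <- vapply(names(pk$negative), function(r) sum(res == r), 0L)
  counts_pos <- vapply(names(pk$positive), function(r) sum(res == r), 0L)
  vapply(pH, function(ph) {
    pos <- 1 / (1 + 10^(ph - nterm_pka)) +
      sum(counts_pos / (1 + 10^(ph - pk$positive)))
    neg <- 1 / (1 + 10^(pk$cterm - ph)) +
      sum(counts_neg / (1 + 10^(pk$negative - ph)))
    pos - neg
  }, 0)
}

#' Theoretical isoelectric point
#'
#' The pH at which the net charge of \code{\link{protein_charge}} is zero,
#' found by bisection on [0, 14] to a charge tolerance of 1e-4, then
#' rounded half-up to two decimal places.
#'
#' @param p amino-acid string.
#' @param pka_set pKa set (see \code{\link{protein_charge}}).
#' @param tol charge tolerance at the returned pH.
#' @return pI (2 decimal places).
#' @export
isoelectric_point <- function(p, pka_set = "bjellqvist", tol = 1e-4) {
  lo <- 0; hi <- 14
  c_lo <- protein_charge(p, lo, pka_set)
  c_hi <- protein_charge(p, hi, pka_set)
  if (c_lo < 0) return(round_half_up(lo, 2))   # all-acidic edge case
  if (c_hi > 0) return(round_half_up(hi, 2))
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    c_mid <- protein_charge(p, mid, pka_set)
    if (abs(c_mid) < tol && (hi - lo) < 5e-3) {
      return(round_half_up(mid, 2))
    }
    if (c_mid > 0) lo <- mid else hi <- mid
  }
  pk_stop("phagekit_numeric_error", "isoelectric point bisection failed")
}

#' Protein descriptor table for ORF candidates
#'
#' Translates every filter-passing candidate and appends the theoretical
#' descriptors reported in annotation tables: protein sequence, MW (kDa)
#' and pI.
#'
#' @param g a \code{genome_record}.
#' @param orfs an \code{orf_candidates} table (use the filtered set).
#' @return the table with \code{protein}, \code{mw_kda}, \code{pi} appended.
#' @export
protein_features <- function(g, orfs) {
  n <- nrow(orfs)
  prot <- character(n); mw <- numeric(n); pi <- numeric(n)
  for (i in seq_len(n)) {
    span <- substring(g$sequence, orfs$start[i], orfs$end[i])
    if (orfs$strand[i] == "-") span <- revcomp(span)
    prot[i] <- translate_dna(span)
    mw[i] <- molecular_weight(prot[i])
    pi[i] <- isoelectric_point(prot[i])
  }
  orfs$protein <- prot
  orfs$mw_kda <- mw
  orfs$pi <- pi
  orfs
}

#' Write proteins to FASTA
#'
#' @param proteins named character vector of amino-acid sequences.
#' @param path output path.
#' @return invisibly, \code{path}.
#' @export
write_protein_fasta <- function(proteins, path) {
  set <- Biostrings::AAStringSet(proteins)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read proteins from FASTA
#'
#' @param path protein FASTA path.
#' @return named character vector.
#' @export
read_protein_fasta <- function(path) {
  set <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(set), sub("\\s.*$", "", names(set)))
}
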