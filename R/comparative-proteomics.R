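#' Smallest-protein percent identity
#'
#' The comparative statistic used throughout phage annotation tables: the
#' number of identical aligned residues divided by the length of the
#' smaller of the two (unaligned) proteins, as a percentage rounded half-up
#' to an integer. Note the denominator is the unaligned protein length, not
#' the alignment length.
#'
#' @param identical integer count(s) of identical residues.
#' @param len_a,len_b unaligned protein lengths (aa).
#' @return integer percentage vector.
#' @export
#' @examples
#' percent_identity(667, 672, 671)  # 99
percent_identity <- function(identical, len_a, len_b) {
  smallest <- pmin(len_a, len_b)
  if (any(len_a <= 0 | len_b <= 0)) {
    pk_stop("phagekit_value_error", "protein lengths must be positive")
  }
  if (any(identical < 0 | identical > smallest)) {
    pk_stop("phagekit_value_error",
            "identical residues cannot exceed the smallest protein length")
  }
  as.integer(round_half_up(100 * identical / smallest))
}

#' Alignment parameter bundle
#'
#' Global (Needleman-Wunsch) alignment with BLOSUM62 and affine gaps, the
#' deterministic desk-scale stand-in for a database search when computing
#' the identity statistic.
#'
#' @param substitution_matrix name of a substitution matrix shipped with
#'   \pkg{Biostrings} (default \code{"BLOSUM62"}).
#' @param gap_opening,gap_extension affine gap costs (positive).
#' @return named list.
#' @export
alignment_params <- function(substitution_matrix = "BLOSUM62",
                             gap_opening = 10, gap_extension = 1) {
  list(substitution_matrix = substitution_matrix,
       gap_opening = gap_opening, gap_extension = gap_extension)
}

#' Globally align two proteins and count identical residues
#'
#' Needleman-Wunsch global alignment (affine gaps, substitution matrix per
#' \code{params}); the identical-residue count is the number of aligned
#' columns with equal residues, and the percent identity follows the
#' smallest-protein convention of \code{\link{percent_identity}}.
#'
#' @param a,b amino-acid strings.
#' @param params see \code{\link{alignment_params}}.
#' @param query_id,subject_id optional labels.
#' @return one-row data.frame: \code{query_id}, \code{subject_id},
#'   \code{identical_residues}, \code{query_len}, \code{subject_len},
#'   \code{percent_identity}, \code{score}.
#' @export
align_and_count <- function(a, b, params = alignment_params(),
                            query_id = "query", subject_id = "subject") {
  a <- check_protein(a); b <- check_protein(b)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = params$substitution_matrix,
    gapOpening = params$gap_opening, gapExtension = params$gap_extension,
    type = "global")
  ident <- Biostrings::nmatch(aln)
  data.frame(
    query_id = query_id, subject_id = subject_id,
    identical_residues = ident,
    query_len = nchar(a), subject_len = nchar(b),
    percent_identity = percent_identity(ident, nchar(a), nchar(b)),
    score = Biostrings::score(aln),
    stringsAsFactors = FALSE)
}

#' Best hit of every query protein in a subject proteome
#'
#' For each query the subject maximizing the smallest-protein percent
#' identity is retained (ties resolved to the lowest subject index); hits
#' below \code{min_identity} are dropped. With \code{reciprocal}, a hit is
#' kept only if the query is in turn the best hit of its subject
#' (reciprocal-best-hit orthology).
#'
#' @param proteome_a,proteome_b named character vectors of proteins.
#' @param min_identity identity floor in percent (default 0).
#' @param params alignment parameters.
#' @param reciprocal require reciprocal best hits (default FALSE).
#' @return data.frame of hits (possibly empty), columns as in
#'   \code{\link{align_and_count}}.
#' @export
best_hits <- function(proteome_a, proteome_b, min_identity = 0,
                      params = alignment_params(), reciprocal = FALSE) {
  stopifnot(length(proteome_a) > 0, length(proteome_b) > 0)
  if (is.null(names(proteome_a))) {
    names(proteome_a) <- sprintf("q%03d", seq_along(proteome_a))
  }
  if (is.null(names(proteome_b))) {
    names(proteome_b) <- sprintf("s%03d", seq_along(proteome_b))
  }
  ident_matrix <- function(qs, ss) {
    sset <- Biostrings::AAStringSet(ss)
    t(vapply(qs, function(q) {
      aln <- Biostrings::pairwiseAlignment(
        sset, Biostrings::AAString(q),
        substitutionMatrix = params$substitution_matrix,
        gapOpening = params$gap_opening, gapExtension = params$gap_extension,
        type = "global")
      Biostrings::nmatch(aln)
    }, numeric(length(ss))))
  }
  im <- ident_matrix(proteome_a, proteome_b)   # queries x subjects
  la <- nchar(proteome_a); lb <- nchar(proteome_b)
  pct <- sweep(im, c(1, 2),
               outer(la, lb, pmin), FUN = "/") * 100
  pick <- apply(pct, 1, which.max)             # lowest index on ties
  rows <- lapply(seq_along(proteome_a), function(i) {
    j <- pick[i]
    data.frame(
      query_id = names(proteome_a)[i], subject_id = names(proteome_b)[j],
      identical_residues = im[i, j],
      query_len = la[[i]], subject_len = lb[[j]],
      percent_identity = percent_identity(im[i, j], la[[i]], lb[[j]]),
      stringsAsFactors = FALSE)
  })
  hits <- do.call(rbind, rows)
  if (reciprocal) {
    imr <- ident_matrix(proteome_b, proteome_a)
    pctr <- sweep(imr, c(1, 2), outer(lb, la, pmin), FUN = "/") * 100
    pickr <- apply(pctr, 1, which.max)
    back <- names(proteome_a)[pickr[match(hits$subject_id,
                                          names(proteome_b))]]
    hits <- hits[back == hits$query_id, , drop = FALSE]
  }
  hits <- hits[hits$percent_identity >= min_identity, , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Shared proteins at an identity cutoff
#'
#' @param hits a hit table (see \code{\link{best_hits}}).
#' @param cutoff identity cutoff in percent.
#' @param strict use a strict inequality (share "more than" the cutoff)
#'   rather than greater-or-equal (default FALSE).
#' @return a \code{shared_set_report}: list with \code{cutoff},
#'   \code{strict}, \code{pairs} (query/subject data.frame) and
#'   \code{count}.
#' @export
shared_proteins_at_cutoff <- function(hits, cutoff, strict = FALSE) {
  keep <- if (strict) hits$percent_identity > cutoff
          else hits$percent_identity >= cutoff
  keep[is.na(keep)] <- FALSE
  pairs <- hits[keep, c("query_id", "subject_id"), drop = FALSE]
  rownames(pairs) <- NULL
  structure(list(cutoff = cutoff, strict = strict, pairs = pairs,
                 count = nrow(pairs)),
            class = "shared_set_report")
}

#' @export
print.shared_set_report <- function(x, ...) {
  cat(sprintf("<shared_set_report> %d pairs %s %s%% identity\n",
              x$count, if (x$strict) ">" else ">=", x$cutoff))
  invisible(x)
}

#' Shared-protein counts over a cutoff grid
#'
#' @param hits a hit table.
#' @param cutoffs numeric vector of cutoffs (percent).
#' @param strict strict inequality (see
#'   \code{\link{shared_proteins_at_cutoff}}).
#' @return named integer vector of counts, non-increasing in cutoff.
#' @export
shared_set_counts <- function(hits, cutoffs, strict = FALSE) {
  stats::setNames(
    vapply(cutoffs,
           function(cc) shared_proteins_at_cutoff(hits, cc, strict)$count,
           0L),
    as.character(cutoffs))
}

#' Comparative genome-map table
#'
#' Flattens a set of annotated genomes plus their pairwise hits into one
#' plottable table: each row is an ORF of one genome, with its best
#' cross-genome link and a shading band determined by identity cutoffs
#' (e.g. links above the top cutoff drawn in full colour, intermediate
#' bands shaded, the rest blank) - the layout behind the familiar stacked
#' genome-alignment figures.
#'
#' @param tables named list of \code{feature_table}s.
#' @param hits named list of hit tables; names are
#'   \code{"<genomeA>|<genomeB>"} linking adjacent tables.
#' @param shade_cutoffs ascending identity cutoffs delimiting the bands
#'   (default \code{c(70, 80)}).
#' @return data.frame: \code{genome_id}, \code{orf_id}, \code{start},
#'   \code{end}, \code{strand}, \code{link_genome}, \code{link_orf},
#'   \code{link_identity}, \code{band}.
#' @export
genome_map_table <- function(tables, hits, shade_cutoffs = c(70, 80)) {
  stopifnot(is.list(tables), !is.null(names(tables)))
  shade_cutoffs <- sort(shade_cutoffs)
  band_of <- function(pct) {
    if (is.na(pct)) return(NA_character_)
    above <- shade_cutoffs[pct > shade_cutoffs]
    if (length(above) == 0) {
      sprintf("<=%g", shade_cutoffs[1])
    } else {
      sprintf(">%g", max(above))
    }
  }
  link <- list()
  for (nm in names(hits)) {
    gg <- strsplit(nm, "|", fixed = TRUE)[[1]]
    if (length(gg) != 2 || !all(gg %in% names(tables))) {
      pk_stop("phagekit_value_error",
              sprintf("hit-set name '%s' does not reference two known genomes",
                      nm))
    }
    h <- hits[[nm]]
    unknown <- setdiff(h$query_id, tables[[gg[1]]]$orf_id)
    if (length(unknown) > 0) {
      pk_stop("phagekit_value_error",
              sprintf("hit query '%s' not present in genome '%s'",
                      unknown[1], gg[1]))
    }
    for (i in seq_len(nrow(h))) {
      link[[paste(gg[1], h$query_id[i])]] <-
        list(genome = gg[2], orf = h$subject_id[i],
             identity = h$percent_identity[i])
    }
  }
  rows <- lapply(names(tables), function(gid) {
    t <- tables[[gid]]
    t <- t[t$type == "CDS", , drop = FALSE]
    out <- data.frame(genome_id = gid, orf_id = t$orf_id,
                      start = t$start, end = t$end, strand = t$strand,
                      link_genome = NA_character_, link_orf = NA_character_,
                      link_identity = NA_real_, band = NA_character_,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(out))) {
      key <- paste(gid, out$orf_id[i])
      if (!is.null(link[[key]])) {
        out$link_genome[i] <- link[[key]]$genome
        out$link_orf[i] <- link[[key]]$orf
        out$link_identity[i] <- link[[key]]$identity
        out$band[i] <- band_of(link[[key]]$identity)
      }
    }
    out
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
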