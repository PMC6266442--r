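#' @importFrom methods as is
#' @importFrom utils read.delim write.table head tail
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Create a genome record
#'
#' A genome record is a named linear DNA sequence over the alphabet
#' \{A, C, G, T, N\}. Sequences are normalized to uppercase; any other
#' character is rejected. Phage genomes are treated as linear molecules,
#' so no feature may wrap around the origin.
#'
#' @param id character scalar, sequence label.
#' @param sequence character scalar, DNA sequence (case-insensitive).
#' @return an object of class \code{genome_record} with fields \code{id},
#'   \code{sequence} and \code{length_bp}.
#' @export
#' @examples
#' g <- genome_record("g1", "acgtACGT")
#' g$length_bp  # 8
genome_record <- function(id, sequence) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  bad <- regmatches(sequence, regexpr("[^ACGTN]", sequence))
  if (length(bad) > 0) {
    pk_stop("phagekit_parse_error",
            sprintf("invalid character '%s' in sequence '%s'", bad, id))
  }
  structure(
    list(id = id, sequence = sequence, length_bp = nchar(sequence)),
    class = "genome_record"
  )
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %d bp\n", x$id, x$length_bp))
  invisible(x)
}

#' Read genomes from a FASTA file
#'
#' Parses a (possibly multi-record) FASTA file into a list of
#' \code{\link{genome_record}} objects. Sequences are uppercased. A light
#' structural pre-scan reports the line number of the first malformed line
#' (sequence data before any header, or characters outside the DNA
#' alphabet) before handing parsing to \pkg{Biostrings}.
#'
#' @param path path to a FASTA file.
#' @return list of \code{genome_record}; empty list for an empty file.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) {
    pk_stop("phagekit_io_error", sprintf("file not found: %s", path))
  }
  lines <- readLines(path, warn = FALSE)
  seen_header <- FALSE
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, ">")) {
      seen_header <- TRUE
      next
    }
    if (!seen_header) {
      pk_stop("phagekit_parse_error",
              sprintf("%s: line %d: sequence data before first header", path, i))
    }
    if (grepl("[^ACGTNacgtn]", ln)) {
      pk_stop("phagekit_parse_error",
              sprintf("%s: line %d: character outside DNA alphabet", path, i))
    }
  }
  if (!seen_header) return(list())
  set <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(set))
  out <- lapply(seq_along(set), function(i) {
    genome_record(ids[i], as.character(set[[i]]))
  })
  out
}

#' Write genome records to FASTA
#'
#' @param genomes a \code{genome_record} or list of them.
#' @param path output file path.
#' @return invisibly, \code{path}.
#' @export
write_fasta <- function(genomes, path) {
  if (inherits(genomes, "genome_record")) genomes <- list(genomes)
  seqs <- Biostrings::DNAStringSet(vapply(genomes, `[[`, "", "sequence"))
  names(seqs) <- vapply(genomes, `[[`, "", "id")
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' GC content of a genome
#'
#' Percentage of G+C among unambiguous bases. N bases are excluded from both
#' the numerator and the denominator. The value is rounded half-up to two
#' decimal places, the precision customarily reported for phage genomes.
#'
#' @param g a \code{genome_record}.
#' @return numeric percentage with two decimals.
#' @export
#' @examples
#' gc_content(genome_record("g", "GGCC"))  # 100
gc_content <- function(g) {
  stopifnot(inherits(g, "genome_record"))
  if (g$length_bp == 0) {
    pk_stop("phagekit_undefined_error", "GC content undefined for empty sequence")
  }
  freq <- Biostrings::letterFrequency(Biostrings::DNAString(g$sequence),
                                      letters = c("A", "C", "G", "T"))
  denom <- sum(freq)
  if (denom == 0) {
    pk_stop("phagekit_undefined_error",
            "GC content undefined: sequence contains no unambiguous bases")
  }
  round_half_up(100 * (freq[["C"]] + freq[["G"]]) / denom, 2)
}

#' Amino-acid length from coding-region coordinates
#'
#' Coordinates are 1-based and inclusive, and the span includes the stop
#' codon; the stop codon does not contribute an amino acid. The protein
#' length is therefore span/3 - 1.
#'
#' @param start,end integer vectors of 1-based inclusive coordinates.
#' @return integer vector of amino-acid lengths.
#' @export
#' @examples
#' coords_to_aa_length(673, 2613)  # 646
#' coords_to_aa_length(1, 6)       # 1
coords_to_aa_length <- function(start, end) {
  start <- as.integer(start); end <- as.integer(end)
  if (any(end <= start)) {
    pk_stop("phagekit_coord_error", "end must be greater than start")
  }
  span <- end - start + 1L
  if (any(span %% 3L != 0L)) {
    pk_stop("phagekit_frame_error",
            sprintf("coding span not a multiple of 3 at index %d",
                    which(span %% 3L != 0L)[1]))
  }
  as.integer(span / 3L - 1L)
}

FEATURE_COLUMNS <- c("orf_id", "type", "strand", "start", "end", "size_aa",
                     "mw_kda", "pi", "sd_context", "start_codon",
                     "predicted_function")

#' Create a feature table
#'
#' An ordered table of genome features: called coding regions plus optional
#' non-coding features (for example a tRNA interval). Rows are sorted by
#' start coordinate; coordinates must lie within the genome when its length
#' is supplied.
#'
#' @param rows data.frame with at least columns \code{orf_id}, \code{strand},
#'   \code{start}, \code{end}; missing descriptor columns are filled with NA.
#'   A \code{type} column defaults to \code{"CDS"}.
#' @param genome_id character scalar identifying the parent genome.
#' @param length_bp optional genome length for coordinate validation.
#' @return a \code{feature_table} (a data.frame subclass).
#' @export
feature_table <- function(rows, genome_id = NA_character_, length_bp = NULL) {
  rows <- as.data.frame(rows, stringsAsFactors = FALSE)
  if (nrow(rows) > 0) {
    req <- c("orf_id", "strand", "start", "end")
    miss <- setdiff(req, names(rows))
    if (length(miss) > 0) {
      pk_stop("phagekit_table_error",
              sprintf("feature table lacks columns: %s",
                      paste(miss, collapse = ", ")))
    }
  }
  for (col in FEATURE_COLUMNS) {
    if (!col %in% names(rows)) {
      rows[[col]] <- if (col == "type") {
        rep("CDS", nrow(rows))
      } else if (col %in% c("start", "end", "size_aa", "mw_kda", "pi")) {
        rep(NA_real_, nrow(rows))
      } else {
        rep(NA_character_, nrow(rows))
      }
    }
  }
  extra <- setdiff(names(rows), FEATURE_COLUMNS)
  rows <- rows[, c(FEATURE_COLUMNS, extra), drop = FALSE]
  if (nrow(rows) > 0) {
    rows$start <- as.numeric(rows$start)
    rows$end <- as.numeric(rows$end)
    if (any(rows$start < 1, na.rm = TRUE)) {
      pk_stop("phagekit_coord_error", "feature start below position 1")
    }
    if (!is.null(length_bp) && any(rows$end > length_bp, na.rm = TRUE)) {
      pk_stop("phagekit_coord_error", "feature end beyond genome length")
    }
    rows <- rows[order(rows$start), , drop = FALSE]
    rownames(rows) <- NULL
  }
  structure(rows, genome_id = genome_id,
            class = c("feature_table", "data.frame"))
}

#' Write a feature table
#'
#' TSV output mirrors the columns of a published annotation table
#' (\code{orf_id}, \code{strand}, coordinates, protein size, MW, pI,
#' ribosome-binding-site context, start codon, predicted function). GFF3
#' output uses 1-based inclusive coordinates with the feature \code{type}
#' column as the GFF3 type.
#'
#' @param t a \code{feature_table}.
#' @param path output file path.
#' @param format \code{"tsv"} or \code{"gff3"}.
#' @return invisibly, \code{path}.
#' @export
write_feature_table <- function(t, path, format = c("tsv", "gff3")) {
  format <- match.arg(format)
  stopifnot(inherits(t, "feature_table"))
  if (format == "tsv") {
    df <- as.data.frame(t)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  } else {
    write_feature_gff3(t, path)
  }
  invisible(path)
}

# hand-formatted GFF3 writer: one CDS/tRNA line per row, descriptor fields
# carried in the attributes column so a read round-trips losslessly
write_feature_gff3 <- function(t, path) {
  gid <- attr(t, "genome_id")
  if (is.na(gid)) gid <- "genome"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(t) == 0) return(invisible(path))
  esc <- function(x) {
    x <- gsub("%", "%25", x, fixed = TRUE)
    x <- gsub(";", "%3B", x, fixed = TRUE)
    x <- gsub("=", "%3D", x, fixed = TRUE)
    x <- gsub(",", "%2C", x, fixed = TRUE)
    x
  }
  attr_cols <- setdiff(names(t), c("type", "strand", "start", "end"))
  for (i in seq_len(nrow(t))) {
    attrs <- sprintf("ID=%s", esc(t$orf_id[i]))
    for (col in setdiff(attr_cols, "orf_id")) {
      v <- t[[col]][i]
      if (!is.na(v) && nzchar(as.character(v))) {
        attrs <- paste0(attrs, ";", col, "=", esc(as.character(v)))
      }
    }
    writeLines(sprintf("%s\tphagekit\t%s\t%d\t%d\t.\t%s\t.\t%s",
                       gid, t$type[i], as.integer(t$start[i]),
                       as.integer(t$end[i]), t$strand[i], attrs), con)
  }
  invisible(path)
}

#' Read a feature table
#'
#' Reads TSV tables written by \code{\link{write_feature_table}} (or
#' transcribed annotation tables with the same columns) and GFF3 files
#' produced by the same writer.
#'
#' @param path input file path.
#' @param format \code{"tsv"} or \code{"gff3"}; guessed from the extension
#'   when missing.
#' @param genome_id optional genome label override.
#' @return a \code{feature_table}.
#' @export
read_feature_table <- function(path, format = NULL, genome_id = NULL) {
  if (!file.exists(path)) {
    pk_stop("phagekit_io_error", sprintf("file not found: %s", path))
  }
  if (is.null(format)) {
    format <- if (grepl("\\.gff3?$", path)) "gff3" else "tsv"
  }
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE, na.strings = "NA")
    df$sd_context <- as.character(df$sd_context)
    df$predicted_function[is.na(df$predicted_function)] <- ""
    return(feature_table(df, genome_id = genome_id %||% NA_character_))
  }
  read_feature_gff3(path, genome_id)
}

read_feature_gff3 <- function(path, genome_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(lines)]
  unesc <- function(x) {
    x <- gsub("%2C", ",", x, fixed = TRUE)
    x <- gsub("%3D", "=", x, fixed = TRUE)
    x <- gsub("%3B", ";", x, fixed = TRUE)
    gsub("%25", "%", x, fixed = TRUE)
  }
  if (length(lines) == 0) {
    return(feature_table(data.frame(), genome_id = genome_id %||% NA_character_))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 9L)
  if (length(bad) > 0) {
    pk_stop("phagekit_parse_error",
            sprintf("%s: malformed GFF3 record at data line %d", path, bad[1]))
  }
  rows <- lapply(parts, function(p) {
    kv <- strsplit(strsplit(p[9], ";", fixed = TRUE)[[1]], "=", fixed = TRUE)
    attrs <- stats::setNames(
      vapply(kv, function(x) unesc(x[2]), ""),
      vapply(kv, `[[`, "", 1)
    )
    row <- list(seqid = p[1], type = p[3], start = as.numeric(p[4]),
                end = as.numeric(p[5]), strand = p[7],
                orf_id = unname(attrs[["ID"]]))
    for (nm in setdiff(names(attrs), "ID")) row[[nm]] <- unname(attrs[[nm]])
    row
  })
  all_names <- unique(unlist(lapply(rows, names)))
  df <- as.data.frame(
    stats::setNames(
      lapply(all_names, function(nm) {
        vapply(rows, function(r) {
          if (is.null(r[[nm]])) NA_character_ else as.character(r[[nm]])
        }, "")
      }),
      all_names
    ),
    stringsAsFactors = FALSE
  )
  gid <- genome_id %||% df$seqid[1]
  df$seqid <- NULL
  for (col in c("start", "end", "size_aa", "mw_kda", "pi")) {
    if (col %in% names(df)) df[[col]] <- as.numeric(df[[col]])
  }
  if ("predicted_function" %in% names(df)) {
    df$predicted_function[is.na(df$predicted_function)] <- ""
  }
  feature_table(df, genome_id = gid)
}

#' Summarize an annotation table
#'
#' Headline genome-annotation statistics: number of called coding regions,
#' strand composition, how many carry a functional assignment, start-codon
#' usage, and the length of any annotated tRNA interval.
#'
#' @param t a \code{feature_table}.
#' @return list with \code{orf_count}, \code{forward_orfs},
#'   \code{reverse_orfs}, \code{functional_count}, \code{functional_pct},
#'   \code{start_codon_usage}, \code{trna_length_bp} (NA when no tRNA row).
#' @export
annotation_summary <- function(t) {
  stopifnot(inherits(t, "feature_table"))
  cds <- t[t$type == "CDS", , drop = FALSE]
  trna <- t[t$type == "tRNA", , drop = FALSE]
  fun <- trimws(cds$predicted_function)
  n_fun <- sum(!is.na(fun) & nzchar(fun))
  list(
    orf_count = nrow(cds),
    forward_orfs = sum(cds$strand == "+"),
    reverse_orfs = sum(cds$strand == "-"),
    functional_count = n_fun,
    functional_pct = if (nrow(cds) > 0)
      round_half_up(100 * n_fun / nrow(cds), 1) else NA_real_,
    start_codon_usage = if (nrow(cds) > 0)
      start_codon_usage(cds$start_codon) else NULL,
    trna_length_bp = if (nrow(trna) > 0)
      as.integer(trna$end[1] - trna$start[1] + 1) else NA_integer_
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a
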