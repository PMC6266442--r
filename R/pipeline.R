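#' Path to a bundled example data file
#'
#' The package ships two plain-text fixtures transcribed from the public
#' record of Escherichia phage ST32 (GenBank MF044458.2): its 79-ORF
#' annotation table (\code{"st32_feature_table.tsv"}) and the 73-strain
#' host-range spot-test matrix (\code{"st32_host_range.csv"}).
#'
#' @param file file name within \code{extdata}; with no argument, lists the
#'   available files.
#' @return a file path, or a vector of file names.
#' @export
phagekit_example <- function(file = NULL) {
  if (is.null(file)) {
    return(dir(system.file("extdata", package = "phagekit")))
  }
  path <- system.file("extdata", file, package = "phagekit")
  if (!nzchar(path)) {
    pk_stop("phagekit_io_error", sprintf("no bundled file '%s'", file))
  }
  path
}

write_manifest <- function(outdir, stage, inputs, params) {
  manifest <- list(
    stage = stage,
    package = "phagekit",
    version = as.character(utils::packageVersion("phagekit")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    inputs = inputs,
    parameters = params)
  jsonlite::write_json(manifest, file.path(outdir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, pretty = TRUE, null = "null")
}

#' Annotate a genome end to end
#'
#' Composition of the candidate caller, SD annotation, filtering and
#' protein descriptors. Optionally writes the feature table (TSV and GFF3),
#' the protein FASTA and a machine-readable run manifest.
#'
#' @param genome a \code{genome_record} or path to a FASTA file (first
#'   record used).
#' @param min_aa candidate length floor.
#' @param strands \code{"both"} or \code{"forward"}.
#' @param require_sd require an accepted SD match.
#' @param sd SD parameters (\code{\link{sd_params}}).
#' @param outdir output directory (created if needed); NULL writes nothing.
#' @return list: \code{features} (a \code{feature_table}),
#'   \code{proteins} (named character), \code{report} (ORF count,
#'   start-codon usage, GC content).
#' @export
run_annotate <- function(genome, min_aa = 45L, strands = "both",
                         require_sd = TRUE, sd = sd_params(),
                         outdir = NULL) {
  input_path <- NA_character_
  if (is.character(genome)) {
    input_path <- genome
    gl <- read_fasta(genome)
    if (length(gl) == 0) {
      pk_stop("phagekit_data_error", sprintf("no sequences in %s", genome))
    }
    genome <- gl[[1]]
  }
  stopifnot(inherits(genome, "genome_record"))
  cand <- annotate_genome(genome, min_aa = min_aa, strands = strands,
                          require_sd = require_sd, sd = sd)
  if (nrow(cand) > 0) {
    cand <- protein_features(genome, cand)
    cand$orf_id <- sprintf("ORF%d", seq_len(nrow(cand)))
    cand$predicted_function <- ""
  }
  proteins <- if (nrow(cand) > 0) {
    stats::setNames(cand$protein, cand$orf_id)
  } else {
    character()
  }
  tbl_cols <- intersect(c("orf_id", "strand", "start", "end", "size_aa",
                          "mw_kda", "pi", "sd_context", "start_codon",
                          "predicted_function"), names(cand))
  features <- feature_table(cand[, tbl_cols, drop = FALSE],
                            genome_id = genome$id,
                            length_bp = genome$length_bp)
  report <- list(
    genome_id = genome$id,
    length_bp = genome$length_bp,
    gc_content = if (genome$length_bp > 0) gc_content(genome) else NA_real_,
    orf_count = nrow(features[features$type == "CDS", ]),
    start_codon_usage = if (nrow(cand) > 0)
      start_codon_usage(cand$start_codon) else NULL)
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    write_feature_table(features, file.path(outdir, "features.tsv"), "tsv")
    write_feature_table(features, file.path(outdir, "features.gff3"), "gff3")
    if (length(proteins) > 0) {
      write_protein_fasta(proteins, file.path(outdir, "proteins.faa"))
    }
    write_manifest(outdir, "annotate",
                   list(genome = input_path, genome_id = genome$id),
                   list(min_aa = min_aa, strands = strands,
                        require_sd = require_sd, sd = sd))
  }
  list(features = features, proteins = proteins, report = report)
}

#' Compare two or more proteomes
#'
#' Computes best hits from the first (reference) proteome to every other,
#' shared-protein counts over a cutoff grid, and a genome-map table when
#' feature tables are supplied.
#'
#' @param proteomes named list of named character vectors (or paths to
#'   protein FASTA files); at least two.
#' @param cutoffs identity cutoffs in percent (default
#'   \code{c(60, 70, 80, 90, 100)}).
#' @param strict strict inequality at cutoffs.
#' @param params alignment parameters.
#' @param tables optional named list of \code{feature_table}s matching
#'   \code{proteomes} for the map export.
#' @param outdir output directory or NULL.
#' @return list: \code{hits} (named list of hit tables),
#'   \code{shared_counts} (named list of count vectors), \code{map}
#'   (data.frame or NULL).
#' @export
run_compare <- function(proteomes, cutoffs = c(60, 70, 80, 90, 100),
                        strict = FALSE, params = alignment_params(),
                        tables = NULL, outdir = NULL) {
  if (length(proteomes) < 2) {
    pk_stop("phagekit_config_error", "need at least two proteomes")
  }
  proteomes <- lapply(proteomes, function(p) {
    if (is.character(p) && length(p) == 1 && grepl("\\.(fa|faa|fasta)$", p)) {
      if (!file.exists(p)) {
        pk_stop("phagekit_config_error",
                sprintf("proteome FASTA not found: %s", p))
      }
      read_protein_fasta(p)
    } else {
      p
    }
  })
  if (is.null(names(proteomes))) {
    names(proteomes) <- sprintf("proteome%d", seq_along(proteomes))
  }
  cutoffs <- sort(cutoffs)
  ref <- names(proteomes)[1]
  hit_sets <- list()
  for (other in names(proteomes)[-1]) {
    hit_sets[[paste(ref, other, sep = "|")]] <-
      best_hits(proteomes[[ref]], proteomes[[other]], params = params)
  }
  shared <- lapply(hit_sets, shared_set_counts, cutoffs = cutoffs,
                   strict = strict)
  map <- NULL
  if (!is.null(tables)) {
    map <- genome_map_table(tables, hit_sets, shade_cutoffs = cutoffs)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    for (nm in names(hit_sets)) {
      utils::write.table(hit_sets[[nm]],
                         file.path(outdir, paste0("hits_", gsub("\\|", "_vs_", nm), ".tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    if (!is.null(map)) {
      utils::write.table(map, file.path(outdir, "genome_map.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    }
    write_manifest(outdir, "compare", list(proteomes = names(proteomes)),
                   list(cutoffs = cutoffs, strict = strict, params = params))
  }
  list(hits = hit_sets, shared_counts = shared, map = map)
}

#' Growth-curve and host-range phenotype analysis
#'
#' Estimates burst size and latent period per temperature from replicated
#' one-step growth curves, compares per-replicate burst sizes (log10 scale)
#' across temperatures with a one-way ANOVA followed by a Tukey HSD test, and
#' summarizes a host-range spot-test panel. With a single temperature the
#' ANOVA is skipped with a logged notice.
#'
#' @param growth a growth CSV path, a \code{growth_curve}, or a list of
#'   \code{growth_curve}s; NULL to skip.
#' @param spots a spot CSV path or a spot-record data.frame; NULL to skip.
#' @param alpha significance level for the Tukey test (default 0.01).
#' @param min_score infection floor for host-range counts.
#' @param outdir output directory or NULL.
#' @return list: \code{estimates} (list of \code{burst_estimate}),
#'   \code{anova}, \code{tukey}, \code{host_range} (named counts).
#' @export
run_phenotype <- function(growth = NULL, spots = NULL, alpha = 0.01,
                          min_score = "++", outdir = NULL) {
  estimates <- NULL; anova_res <- NULL; tukey_res <- NULL
  if (!is.null(growth)) {
    curves <- if (is.character(growth)) {
      read_growth_csv(growth)
    } else if (inherits(growth, "growth_curve")) {
      stats::setNames(list(growth), attr(growth, "temperature_C"))
    } else {
      growth
    }
    estimates <- lapply(curves, estimate_growth_parameters)
    if (length(curves) >= 2) {
      # burst sizes are compared on the log scale: plating noise is
      # multiplicative, so log bursts have comparable variances across
      # regimes whose means differ by orders of magnitude
      groups <- lapply(estimates, function(e) log10(e$per_replicate$burst))
      names(groups) <- paste0("T", names(curves))
      anova_res <- one_way_anova(groups)
      tukey_res <- tukey_hsd(groups, alpha = alpha)
    } else {
      message("single temperature: ANOVA/Tukey skipped")
    }
  }
  host <- NULL
  if (!is.null(spots)) {
    records <- if (is.character(spots)) read_spot_csv(spots) else spots
    host <- count_infected(records, min_score = min_score)
  }
  if (!is.null(outdir)) {
    dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
    summary <- list(
      estimates = if (!is.null(estimates)) {
        lapply(estimates, function(e) {
          list(temperature_C = e$temperature_C, burst_size = e$burst_size,
               burst_sd = e$burst_sd, latent_min = e$latent_min,
               latent_sd = e$latent_sd)
        })
      },
      anova = if (!is.null(anova_res))
        list(f = anova_res$f, p = anova_res$p),
      tukey = tukey_res,
      host_range = as.list(host))
    jsonlite::write_json(summary, file.path(outdir, "phenotype_summary.json"),
                         auto_unbox = TRUE, pretty = TRUE, null = "null",
                         digits = NA)
    write_manifest(outdir, "phenotype",
                   list(growth = if (is.character(growth)) growth else NA,
                        spots = if (is.character(spots)) spots else NA),
                   list(alpha = alpha, min_score = min_score))
  }
  list(estimates = estimates, anova = anova_res, tukey = tukey_res,
       host_range = host)
}

#' Check a reference genome against a transcribed annotation table
#'
#' Recomputes genome length, GC content and per-ORF protein descriptors
#' from an actual genome sequence and compares them to a transcribed
#' feature table. Intended for validating the pipeline against a deposited
#' genome when its FASTA is locally available; no download is attempted.
#'
#' @param fasta_path path to the genome FASTA.
#' @param feature_tsv path to the transcribed annotation TSV (defaults to
#'   the bundled table).
#' @return list: \code{length_bp}, \code{gc_content},
#'   \code{mw_max_abs_err_kda}, \code{pi_max_abs_err},
#'   \code{aa_length_mismatches}.
#' @export
verify_reference_genome <- function(fasta_path,
                                    feature_tsv =
                                      phagekit_example("st32_feature_table.tsv")) {
  g <- read_fasta(fasta_path)[[1]]
  tbl <- read_feature_table(feature_tsv)
  cds <- tbl[tbl$type == "CDS", , drop = FALSE]
  mw_err <- pi_err <- numeric(nrow(cds))
  aa_bad <- 0L
  for (i in seq_len(nrow(cds))) {
    span <- substring(g$sequence, cds$start[i], cds$end[i])
    if (cds$strand[i] == "-") span <- revcomp(span)
    prot <- translate_dna(span)
    if (nchar(prot) != cds$size_aa[i]) aa_bad <- aa_bad + 1L
    mw_err[i] <- abs(molecular_weight(prot) - cds$mw_kda[i])
    pi_err[i] <- abs(isoelectric_point(prot) - cds$pi[i])
  }
  list(length_bp = g$length_bp,
       gc_content = gc_content(g),
       mw_max_abs_err_kda = max(mw_err),
       pi_max_abs_err = max(pi_err),
       aa_length_mismatches = aa_bad)
}
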