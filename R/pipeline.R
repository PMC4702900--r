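#' Pipeline configuration
#'
#' Bundles every tunable threshold of the identification cascade and the
#' function predictor. Defaults reproduce the published cutoffs: 200 nt /
#' 2 exons / 50 nt flank / 80% precursor coverage for the structural and
#' annotation filters; 100 aa, 30% and 90% coverage, CDS score 800 for the
#' coding-potential decision table; BLASTX 1e-30 and Pfam 1e-5 for the domain
#' filter; q < 0.05 and |r| >= 0.7 for co-expression edges.
#'
#' @param thresholds A [filter_thresholds()].
#' @param max_orf_aa lncRNA ORF-length cutoff (aa, exclusive).
#' @param max_orf_coverage lncRNA ORF-coverage cutoff (exclusive).
#' @param tucp_coverage_max Upper TUCP coverage bound (inclusive).
#' @param max_cds_score Non-coding CDS-score cutoff (exclusive).
#' @param blastx_evalue,pfam_evalue Domain-filter E-value cutoffs.
#' @param q_threshold,r_threshold,positive_only Co-expression edge selection.
#' @param species_code Three-letter code used for naming.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(thresholds = filter_thresholds(),
                            max_orf_aa = 100, max_orf_coverage = 0.30,
                            tucp_coverage_max = 0.90, max_cds_score = 800,
                            blastx_evalue = 1e-30, pfam_evalue = 1e-5,
                            q_threshold = 0.05, r_threshold = 0.7,
                            positive_only = FALSE, species_code = "hsa") {
  structure(
    list(thresholds = thresholds, max_orf_aa = max_orf_aa,
         max_orf_coverage = max_orf_coverage,
         tucp_coverage_max = tucp_coverage_max,
         max_cds_score = max_cds_score, blastx_evalue = blastx_evalue,
         pfam_evalue = pfam_evalue, q_threshold = q_threshold,
         r_threshold = r_threshold, positive_only = positive_only,
         species_code = species_code),
    class = "pipeline_config"
  )
}

classify_with_config <- function(assessment, config) {
  aa <- if (is.null(assessment$orf)) 0L else assessment$orf$aa_length
  cov <- assessment$orf_coverage
  score <- assessment$cds_score
  if (score >= config$max_cds_score || cov > config$tucp_coverage_max) {
    return("CODING_LIKE")
  }
  if (aa < config$max_orf_aa && cov < config$max_orf_coverage) {
    return("LNCRNA")
  }
  "TUCP"
}

#' Run the lncRNA identification cascade
#'
#' Applies the four filter stages in order — length/exon count, strand-
#' specific known-annotation overlap, ORF-based coding-potential
#' classification, and protein-similarity/domain evidence — then clusters
#' surviving lncRNAs into gene loci and assigns A-B-C names. Every
#' transcript's per-stage verdict is retained so the audit trail shows which
#' filter removed it.
#'
#' @param models List of [transcript_model()] objects (or path to a GTF/BED12
#'   file).
#' @param genome A [Biostrings::DNAStringSet] or FASTA path.
#' @param annotations An [annotation_set()] (or path to an annotation TSV,
#'   see [read_annotation_table()]).
#' @param blastx_hits Optional BLASTX hit data frame (see [read_blast_tab()])
#'   or path.
#' @param pfam_hits Optional Pfam hit data frame (see [read_pfam_table()])
#'   or path.
#' @param cds_scores Optional named vector of external CDS scores keyed by
#'   transcript id; transcripts without an entry fall back to the built-in
#'   surrogate scorer.
#' @param config A [pipeline_config()].
#' @return A list with `report` (one row per input transcript:
#'   `transcript_id`, `length`, `n_exons`, `aa_length`, `orf_coverage`,
#'   `cds_score`, `class`, `status`, `evidence`, `name`, `gene_name`) and
#'   `lncrna_models` (the named surviving lncRNA transcript models).
#'   `status` is the final fate: `LNCRNA` / `TUCP` for survivors, otherwise
#'   the failing stage's verdict (`FAIL_*`, `CODING_LIKE`, `REMOVED_BLASTX`,
#'   `REMOVED_PFAM`).
#' @export
run_identify <- function(models, genome, annotations, blastx_hits = NULL,
                         pfam_hits = NULL, cds_scores = NULL,
                         config = pipeline_config()) {
  if (is.character(models)) {
    models <- if (grepl("\\.bed(12)?$", models, ignore.case = TRUE)) {
      read_bed12(models)
    } else {
      read_gtf(models)
    }
  }
  if (is.character(genome)) genome <- read_genome(genome)
  if (is.character(annotations)) {
    annotations <- read_annotation_table(annotations)
  }
  if (is.character(blastx_hits)) blastx_hits <- read_blast_tab(blastx_hits)
  if (is.character(pfam_hits)) pfam_hits <- read_pfam_table(pfam_hits)

  n <- length(models)
  if (n == 0L) {
    warning("no transcripts in input")
    empty <- data.frame(
      transcript_id = character(), length = integer(), n_exons = integer(),
      aa_length = integer(), orf_coverage = numeric(), cds_score = numeric(),
      class = character(), status = character(), evidence = character(),
      name = character(), gene_name = character(), stringsAsFactors = FALSE
    )
    return(list(report = empty, lncrna_models = list()))
  }
  report <- data.frame(
    transcript_id = vapply(models, `[[`, character(1), "transcript_id"),
    length = vapply(models, `[[`, integer(1), "length"),
    n_exons = vapply(models, n_exons, integer(1)),
    aa_length = NA_integer_, orf_coverage = NA_real_, cds_score = NA_real_,
    class = NA_character_, status = NA_character_, evidence = "",
    name = NA_character_, gene_name = NA_character_,
    stringsAsFactors = FALSE
  )

  # stage 1 + 2
  for (i in seq_len(n)) {
    v <- filter_length_exons(models[[i]], config$thresholds)
    if (v$status == "PASS") {
      v <- filter_known_annotation(models[[i]], annotations,
                                   config$thresholds)
    }
    report$status[i] <- v$status
    report$evidence[i] <- v$evidence
  }

  # stage 3: coding potential on survivors
  surviving <- which(report$status == "PASS")
  for (i in surviving) {
    seq_i <- extract_sequence(models[[i]], genome)
    external <- if (!is.null(cds_scores)) {
      unname(cds_scores[report$transcript_id[i]])
    } else NA_real_
    assessment <- assess_coding(
      seq_i,
      cds_score = if (!is.null(cds_scores) && !is.na(external)) external
                  else NULL
    )
    report$aa_length[i] <- if (is.null(assessment$orf)) 0L
                           else assessment$orf$aa_length
    report$orf_coverage[i] <- assessment$orf_coverage
    report$cds_score[i] <- assessment$cds_score
    report$class[i] <- classify_with_config(assessment, config)
    report$status[i] <- report$class[i]
  }

  # stage 4: domain evidence on non-coding survivors
  candidates <- report$transcript_id[report$status %in% c("LNCRNA", "TUCP")]
  bx <- filter_by_blastx(candidates, blastx_hits,
                         threshold = config$blastx_evalue)
  report$status[report$transcript_id %in% bx$removed] <- "REMOVED_BLASTX"
  pf <- filter_by_pfam(bx$kept, pfam_hits, threshold = config$pfam_evalue)
  report$status[report$transcript_id %in% pf$removed] <- "REMOVED_PFAM"

  # cluster and name the surviving lncRNAs
  lnc_idx <- which(report$status == "LNCRNA")
  lnc_models <- models[lnc_idx]
  if (length(lnc_models)) {
    names_df <- assign_names(lnc_models, config$species_code)
    m <- match(report$transcript_id[lnc_idx], names_df$transcript_id)
    report$name[lnc_idx] <- names_df$name[m]
    report$gene_name[lnc_idx] <- names_df$gene_name[m]
    names(lnc_models) <- names_df$name[m]
  }
  list(report = report, lncrna_models = lnc_models)
}

#' Predict the function of a target lncRNA by guilt-by-association
#'
#' Builds co-expression edges between the target lncRNA and all coding genes
#' in the matrix, takes the significant partners, and tests them for GO-term
#' enrichment against the population of GO-annotated genes present in the
#' expression matrix.
#'
#' @param target_lnc Row id of the target lncRNA in the matrix.
#' @param matrix Expression matrix (or TSV path, see
#'   [read_expression_matrix()]).
#' @param go_annotation GO annotation data frame (or TSV path).
#' @param coding_ids Coding-gene row ids to test; defaults to all
#'   GO-annotated genes present in the matrix.
#' @param config A [pipeline_config()].
#' @return List with `edges` (see [build_coexpression()]), `partners`
#'   (character vector) and `enrichment` (see [go_enrichment()]).
#' @export
run_function <- function(target_lnc, matrix, go_annotation,
                         coding_ids = NULL, config = pipeline_config()) {
  if (is.character(matrix) && length(matrix) == 1L) {
    matrix <- read_expression_matrix(matrix)
  }
  if (is.character(go_annotation) && length(go_annotation) == 1L) {
    go_annotation <- read_go_annotation(go_annotation)
  }
  if (!target_lnc %in% rownames(matrix)) {
    near <- utils::head(
      rownames(matrix)[order(utils::adist(target_lnc, rownames(matrix)))], 3L)
    stop("target lncRNA '", target_lnc, "' not in matrix; nearest ids: ",
         paste(near, collapse = ", "))
  }
  if (is.null(coding_ids)) {
    coding_ids <- intersect(unique(go_annotation$gene_id), rownames(matrix))
  }
  if (length(coding_ids) == 0L) stop("no annotated coding genes in matrix")
  edges <- build_coexpression(
    target_lnc, coding_ids, matrix,
    q_threshold = config$q_threshold, r_threshold = config$r_threshold,
    positive_only = config$positive_only
  )
  partners <- unique(edges$coding_id)
  # population: GO-annotated genes actually present in the matrix
  population <- intersect(unique(go_annotation$gene_id), rownames(matrix))
  if (length(partners) == 0L) {
    warning("no significant co-expression partners for ", target_lnc)
  }
  enrichment <- suppressWarnings(
    go_enrichment(partners, go_annotation, population)
  )
  list(edges = edges, partners = partners, enrichment = enrichment)
}
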