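#' Filter thresholds for the structural and annotation-overlap filters
#'
#' Defaults reproduce the published cascade: transcripts must be multi-exonic
#' and longer than 200 nt; same-strand coding/pseudogene exons within 50 nt
#' disqualify a transcript; a same-strand small-RNA gene covered over at least
#' 80% of its length by transcript exons disqualifies it.
#'
#' @param min_length_nt Minimum transcript length, exclusive (keep if
#'   length > `min_length_nt`). Default 200.
#' @param min_exons Minimum exon count, inclusive. Default 2.
#' @param flank_nt Flank distance (nt) around coding/pseudogene exons within
#'   which a transcript exon triggers removal. Default 50.
#' @param precursor_cover_frac Fraction of a small-RNA gene that must be
#'   covered by transcript exons to trigger removal. Default 0.80.
#' @return A `filter_thresholds` list.
#' @export
filter_thresholds <- function(min_length_nt = 200L, min_exons = 2L,
                              flank_nt = 50L, precursor_cover_frac = 0.80) {
  stopifnot(
    min_length_nt > 0, min_exons > 0, flank_nt > 0,
    precursor_cover_frac > 0, precursor_cover_frac <= 1
  )
  structure(
    list(
      min_length_nt = as.integer(min_length_nt),
      min_exons = as.integer(min_exons),
      flank_nt = as.integer(flank_nt),
      precursor_cover_frac = precursor_cover_frac
    ),
    class = "filter_thresholds"
  )
}

SMALL_RNA_CLASSES <- c("miRNA_precursor", "miRNA", "tRNA", "rRNA",
                       "snRNA", "snoRNA")

# validate one annotation data.frame (chrom, start, end, strand, id[, class])
validate_features <- function(df, what, need_class = FALSE) {
  if (is.null(df) || nrow(df) == 0L) {
    out <- data.frame(chrom = character(), start = integer(),
                      end = integer(), strand = character(),
                      id = character(), stringsAsFactors = FALSE)
    if (need_class) out$class <- character()
    return(out)
  }
  req <- c("chrom", "start", "end", "strand", "id")
  if (need_class) req <- c(req, "class")
  missing_cols <- setdiff(req, names(df))
  if (length(missing_cols)) {
    stop(what, " features must have columns: ", paste(req, collapse = ", "))
  }
  if (any(df$start >= df$end)) stop(what, ": interval with start >= end")
  if (!all(df$strand %in% c("+", "-"))) stop(what, ": strand must be + or -")
  if (need_class && !all(df$class %in% SMALL_RNA_CLASSES)) {
    stop(what, ": class must be one of ",
         paste(SMALL_RNA_CLASSES, collapse = ", "))
  }
  df[, req]
}

#' Build an annotation set for the known-annotation filter
#'
#' All intervals use 0-based half-open coordinates. Each data frame needs
#' columns `chrom`, `start`, `end`, `strand`, `id`; `small_rna_genes`
#' additionally needs `class` drawn from miRNA_precursor, miRNA, tRNA, rRNA,
#' snRNA, snoRNA.
#'
#' @param coding_exons Data frame of known coding-gene exons (or NULL).
#' @param pseudogene_exons Data frame of pseudogene exons (or NULL).
#' @param small_rna_genes Data frame of small-RNA gene spans (or NULL).
#' @return An `annotation_set` object.
#' @export
annotation_set <- function(coding_exons = NULL, pseudogene_exons = NULL,
                           small_rna_genes = NULL) {
  structure(
    list(
      coding_exons = validate_features(coding_exons, "coding_exons"),
      pseudogene_exons = validate_features(pseudogene_exons, "pseudogene_exons"),
      small_rna_genes = validate_features(small_rna_genes, "small_rna_genes",
                                          need_class = TRUE)
    ),
    class = "annotation_set"
  )
}

#' Read an annotation table into an annotation set
#'
#' Expects a TSV with header columns `chrom`, `start`, `end`, `strand`, `id`,
#' `category`, where category is one of `coding_exon`, `pseudogene_exon`, or a
#' small-RNA class (miRNA_precursor, miRNA, tRNA, rRNA, snRNA, snoRNA).
#'
#' @param path Path to the TSV.
#' @return An [annotation_set()].
#' @export
read_annotation_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  srna <- df[df$category %in% SMALL_RNA_CLASSES, , drop = FALSE]
  if (nrow(srna)) srna$class <- srna$category
  annotation_set(
    coding_exons = df[df$category == "coding_exon", , drop = FALSE],
    pseudogene_exons = df[df$category == "pseudogene_exon", , drop = FALSE],
    small_rna_genes = srna
  )
}

filter_verdict <- function(transcript_id, status, evidence = "") {
  stopifnot((status == "PASS") == (evidence == ""))
  structure(
    list(transcript_id = transcript_id, status = status, evidence = evidence),
    class = "filter_verdict"
  )
}

#' Length and exon-count filter (stage 1)
#'
#' A transcript passes iff its length strictly exceeds
#' `thresholds$min_length_nt` and it has at least `thresholds$min_exons`
#' exons.
#'
#' @param model A [transcript_model()].
#' @param thresholds A [filter_thresholds()].
#' @return A `filter_verdict` with status `PASS`, `FAIL_LENGTH` or
#'   `FAIL_EXONS`.
#' @export
filter_length_exons <- function(model, thresholds = filter_thresholds()) {
  if (n_exons(model) < thresholds$min_exons) {
    return(filter_verdict(model$transcript_id, "FAIL_EXONS",
                          sprintf("n_exons=%d", n_exons(model))))
  }
  if (model$length <= thresholds$min_length_nt) {
    return(filter_verdict(model$transcript_id, "FAIL_LENGTH",
                          sprintf("length=%d", model$length)))
  }
  filter_verdict(model$transcript_id, "PASS")
}

# minimal same-strand gap (nt) between any model exon and any feature; NULL if
# no same-strand same-chrom feature. 0 means overlap or adjacency.
min_feature_gap <- function(model, df) {
  df <- df[df$chrom == model$chrom & df$strand == model$strand, , drop = FALSE]
  if (nrow(df) == 0L) return(NULL)
  d <- IRanges::distance(
    IRanges::IRanges(rep(model$starts + 1L, each = nrow(df)),
                     rep(model$ends, each = nrow(df))),
    IRanges::IRanges(rep(df$start + 1L, times = n_exons(model)),
                     rep(df$end, times = n_exons(model)))
  )
  ids <- rep(df$id, times = n_exons(model))
  list(gap = min(d), id = ids[which.min(d)])
}

#' Known-annotation overlap filter (stage 2)
#'
#' Strand-specific: a transcript fails if any exon overlaps, or lies within
#' `flank_nt` of, a same-strand coding or pseudogene exon, or if its exonic
#' overlap with a same-strand small-RNA gene covers at least
#' `precursor_cover_frac` of that gene. Opposite-strand features never trigger
#' failure, so antisense lncRNAs are retained. Features on chromosomes the
#' transcript does not touch are ignored.
#'
#' @param model A [transcript_model()].
#' @param annotations An [annotation_set()].
#' @param thresholds A [filter_thresholds()].
#' @return A `filter_verdict` with status `PASS`, `FAIL_CODING_OVERLAP`,
#'   `FAIL_PSEUDOGENE_OVERLAP` or `FAIL_SMALLRNA_OVERLAP`.
#' @export
filter_known_annotation <- function(model, annotations,
                                    thresholds = filter_thresholds()) {
  cod <- min_feature_gap(model, annotations$coding_exons)
  if (!is.null(cod) && cod$gap <= thresholds$flank_nt) {
    return(filter_verdict(model$transcript_id, "FAIL_CODING_OVERLAP", cod$id))
  }
  pse <- min_feature_gap(model, annotations$pseudogene_exons)
  if (!is.null(pse) && pse$gap <= thresholds$flank_nt) {
    return(filter_verdict(model$transcript_id, "FAIL_PSEUDOGENE_OVERLAP",
                          pse$id))
  }
  srna <- annotations$small_rna_genes
  srna <- srna[srna$chrom == model$chrom & srna$strand == model$strand, ,
               drop = FALSE]
  if (nrow(srna)) {
    for (j in seq_len(nrow(srna))) {
      ov <- sum(pmax(
        0L,
        pmin(model$ends, srna$end[j]) - pmax(model$starts, srna$start[j])
      ))
      gene_len <- srna$end[j] - srna$start[j]
      if (ov / gene_len >= thresholds$precursor_cover_frac) {
        return(filter_verdict(model$transcript_id, "FAIL_SMALLRNA_OVERLAP",
                              srna$id[j]))
      }
    }
  }
  filter_verdict(model$transcript_id, "PASS")
}

#' Export filter verdicts as a data frame
#'
#' @param verdicts List of `filter_verdict` objects.
#' @return Data frame with columns `transcript_id`, `status`, `evidence`.
#' @export
verdicts_to_df <- function(verdicts) {
  data.frame(
    transcript_id = vapply(verdicts, `[[`, character(1), "transcript_id"),
    status = vapply(verdicts, `[[`, character(1), "status"),
    evidence = vapply(verdicts, `[[`, character(1), "evidence"),
    stringsAsFactors = FALSE
  )
}
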