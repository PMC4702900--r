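#' Translate a nucleotide sequence in all three forward frames
#'
#' Standard genetic code; stop codons render as `*`; trailing 1-2 nt that do
#' not complete a codon are dropped. Frames that retain no complete codon
#' yield an empty string.
#'
#' @param sequence Nucleotide string over \{A,C,G,T,N\}, length >= 3.
#' @return Character vector of length 3 (frames 0, 1, 2).
#' @export
translate_three_frames <- function(sequence) {
  sequence <- check_alphabet(sequence)
  L <- nchar(sequence)
  if (L < 3L) stop("sequence must be at least 3 nt")
  vapply(0:2, function(frame) {
    n_codons <- (L - frame) %/% 3L
    if (n_codons < 1L) return("")
    sub <- substring(sequence, frame + 1L, frame + 3L * n_codons)
    as.character(Biostrings::translate(
      Biostrings::DNAString(sub),
      if.fuzzy.codon = "X", no.init.codon = TRUE
    ))
  }, character(1))
}

#' Read BLAST tabular output (outfmt 6)
#'
#' Standard 12-column BLAST tabular format: qseqid, sseqid, pident, length,
#' mismatch, gapopen, qstart, qend, sstart, send, evalue, bitscore.
#'
#' @param path Path to the tabular file.
#' @param target_species Optional species label attached to every hit (used
#'   by the conservation module, where one file is produced per subject
#'   species).
#' @return Data frame with columns `query_id`, `subject_id`, `pident`,
#'   `align_length`, `qstart`, `qend`, `sstart`, `send`, `e_value`,
#'   `bit_score` (and `target_species` when given).
#' @export
read_blast_tab <- function(path, target_species = NULL) {
  cols <- c("query_id", "subject_id", "pident", "align_length", "mismatch",
            "gapopen", "qstart", "qend", "sstart", "send", "e_value",
            "bit_score")
  empty <- stats::setNames(
    data.frame(character(), character(), numeric(), integer(), integer(),
               integer(), integer(), integer(), integer(), integer(),
               numeric(), numeric(), stringsAsFactors = FALSE),
    cols
  )
  info <- file.info(path)
  df <- if (!is.na(info$size) && info$size == 0) empty else {
    out <- utils::read.table(path, header = FALSE, sep = "\t",
                             stringsAsFactors = FALSE, comment.char = "#")
    if (ncol(out) != 12L) stop("BLAST outfmt-6 file must have 12 columns")
    stats::setNames(out, cols)
  }
  df <- df[, setdiff(cols, c("mismatch", "gapopen"))]
  if (!is.null(target_species)) df$target_species <- target_species
  df
}

#' Read HMMER3 per-domain tabular output (domtblout)
#'
#' Parses `hmmscan --domtblout` style output, where the target is a Pfam
#' domain model and the query is a translated transcript frame. Per (query,
#' domain) pair the full-sequence E-value and the best (minimum) independent
#' domain E-value across that pair's domain rows are retained. Query names
#' carrying a `_frameN` suffix (as produced by three-frame translation) are
#' collapsed back to the transcript id.
#'
#' @param path Path to a domtblout file.
#' @return Data frame with columns `query_id`, `domain_id`,
#'   `full_seq_evalue`, `best_domain_evalue`.
#' @export
read_domtblout <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(data.frame(query_id = character(), domain_id = character(),
                      full_seq_evalue = numeric(),
                      best_domain_evalue = numeric(),
                      stringsAsFactors = FALSE))
  }
  f <- strsplit(trimws(lines), "\\s+")
  if (any(lengths(f) < 13L)) stop("malformed domtblout row (needs >= 13 fields)")
  df <- data.frame(
    query_id = sub("_frame[0-2]$", "", vapply(f, `[[`, character(1), 4L)),
    domain_id = vapply(f, `[[`, character(1), 1L),
    full_seq_evalue = as.numeric(vapply(f, `[[`, character(1), 7L)),
    i_evalue = as.numeric(vapply(f, `[[`, character(1), 13L)),
    stringsAsFactors = FALSE
  )
  agg <- stats::aggregate(
    cbind(full_seq_evalue, i_evalue) ~ query_id + domain_id,
    data = df, FUN = min
  )
  data.frame(
    query_id = agg$query_id,
    domain_id = agg$domain_id,
    full_seq_evalue = agg$full_seq_evalue,
    best_domain_evalue = agg$i_evalue,
    stringsAsFactors = FALSE
  )
}

#' Read a simple Pfam evidence table
#'
#' Four-column TSV with header: `query_id`, `domain_id`, `full_seq_evalue`,
#' `best_domain_evalue` (the pre-digested form written by the fixture
#' generator and by [read_domtblout()] post-processing).
#'
#' @param path Path to the TSV.
#' @return Data frame of domain hits.
#' @export
read_pfam_table <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("query_id", "domain_id", "full_seq_evalue", "best_domain_evalue")
  if (!all(req %in% names(df))) {
    stop("Pfam table must have columns: ", paste(req, collapse = ", "))
  }
  df[, req]
}

partition_result <- function(ids, removed_flag) {
  list(removed = ids[removed_flag], kept = ids[!removed_flag])
}

#' Protein-similarity filter over BLASTX hits (stage 4a)
#'
#' A transcript is removed iff it has any BLASTX hit with E-value strictly
#' below `threshold`. Hits naming transcripts absent from `transcript_ids`
#' are ignored with a warning.
#'
#' @param transcript_ids Character vector of candidate transcript ids.
#' @param hits Data frame with columns `query_id` and `e_value`
#'   (see [read_blast_tab()]).
#' @param threshold E-value cutoff, default 1e-30.
#' @return List with character vectors `removed` and `kept` (a disjoint
#'   partition of `transcript_ids`).
#' @export
filter_by_blastx <- function(transcript_ids, hits, threshold = 1e-30) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(partition_result(transcript_ids, rep(FALSE, length(transcript_ids))))
  }
  stopifnot(all(hits$e_value >= 0))
  unknown <- setdiff(unique(hits$query_id), transcript_ids)
  if (length(unknown)) {
    warning("ignoring BLASTX hits for unknown transcripts: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  strong <- unique(hits$query_id[hits$e_value < threshold])
  partition_result(transcript_ids, transcript_ids %in% strong)
}

#' Pfam domain filter (stage 4b)
#'
#' A transcript is removed iff some single Pfam hit satisfies both conditions
#' at once: full-sequence E-value < `threshold` AND best-domain E-value <
#' `threshold`. The conjunction is per hit, not across hits. PfamA and PfamB
#' domains are treated identically.
#'
#' @param transcript_ids Character vector of candidate transcript ids.
#' @param hits Data frame with columns `query_id`, `full_seq_evalue`,
#'   `best_domain_evalue`.
#' @param threshold E-value cutoff applied to both E-values, default 1e-5.
#' @return List with character vectors `removed` and `kept`.
#' @export
filter_by_pfam <- function(transcript_ids, hits, threshold = 1e-5) {
  if (is.null(hits) || nrow(hits) == 0L) {
    return(partition_result(transcript_ids, rep(FALSE, length(transcript_ids))))
  }
  stopifnot(all(hits$full_seq_evalue >= 0), all(hits$best_domain_evalue >= 0))
  unknown <- setdiff(unique(hits$query_id), transcript_ids)
  if (length(unknown)) {
    warning("ignoring Pfam hits for unknown transcripts: ",
            paste(utils::head(unknown, 5L), collapse = ", "))
  }
  strong <- unique(hits$query_id[
    hits$full_seq_evalue < threshold & hits$best_domain_evalue < threshold
  ])
  partition_result(transcript_ids, transcript_ids %in% strong)
}
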