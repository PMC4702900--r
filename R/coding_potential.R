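STOP_CODONS <- c("TAA", "TAG", "TGA")

check_alphabet <- function(sequence) {
  sequence <- toupper(sequence)
  if (grepl("[^ACGTN]", sequence)) {
    stop("sequence contains characters outside {A,C,G,T,N}")
  }
  sequence
}

#' Find the longest open reading frame in the three forward frames
#'
#' An ORF starts at an ATG and runs to the first in-frame stop codon
#' (TAA/TAG/TGA) or, failing that, to the transcript 3' end (an "open" frame).
#' Only the three forward frames are scanned; assemblies are stranded, so
#' reverse-strand ORFs are not considered. Ties in amino-acid length are
#' broken by smaller 5' offset, then by smaller frame.
#'
#' @param sequence Nucleotide string over {A,C,G,T,N}, length >= 3.
#' @return `NULL` if the sequence contains no ATG, else a list with `frame`
#'   (0/1/2), `start_offset` (nt from the 5' end), `aa_length` (amino acids,
#'   stop excluded), `nt_length` (nt, stop codon included when present) and
#'   `has_stop`.
#' @examples
#' find_longest_orf("ATGAAATAG")  # 2 aa, 9 nt, stop present
#' @export
find_longest_orf <- function(sequence) {
  sequence <- check_alphabet(sequence)
  L <- nchar(sequence)
  if (L < 3L) stop("sequence must be at least 3 nt")
  best <- NULL
  for (frame in 0:2) {
    n_codons <- (L - frame) %/% 3L
    if (n_codons < 1L) next
    pos <- frame + 3L * (seq_len(n_codons) - 1L) + 1L
    codons <- substring(sequence, pos, pos + 2L)
    atg <- which(codons == "ATG")
    if (length(atg) == 0L) next
    stops <- which(codons %in% STOP_CODONS)
    # index of first stop at or after each start (NA if none)
    j <- findInterval(atg - 0.5, stops) + 1L
    stop_at <- ifelse(j <= length(stops), stops[j], NA_integer_)
    aa <- ifelse(is.na(stop_at), n_codons - atg + 1L, stop_at - atg)
    for (i in seq_along(atg)) {
      cand <- list(
        frame = frame,
        start_offset = frame + 3L * (atg[i] - 1L),
        aa_length = as.integer(aa[i]),
        nt_length = as.integer(if (is.na(stop_at[i])) 3L * aa[i]
                               else 3L * aa[i] + 3L),
        has_stop = !is.na(stop_at[i])
      )
      if (is.null(best) ||
          cand$aa_length > best$aa_length ||
          (cand$aa_length == best$aa_length &&
           (cand$start_offset < best$start_offset ||
            (cand$start_offset == best$start_offset &&
             cand$frame < best$frame)))) {
        best <- cand
      }
    }
  }
  best
}

#' Surrogate CDS score on the 0-1000 txCdsPredict-compatible scale
#'
#' A deterministic coding-potential score: zero when there is no ORF (or a
#' 0-aa ORF), otherwise a saturating exponential in ORF amino-acid length,
#' `900 * (1 - exp(-aa / 100))`, plus a fixed 50-point bonus for a terminating
#' stop codon and another 50 for a Kozak-consistent initiation context (A or G
#' three bases upstream of the ATG and G immediately downstream), capped at
#' 1000. The score is strictly increasing in ORF length, so the conventional
#' 800 non-coding cutoff remains meaningful: it corresponds to an ORF of
#' roughly 200 aa or more. Scores produced by an external predictor can be
#' supplied instead via [read_cds_scores()].
#'
#' @param sequence Nucleotide string the ORF was found in.
#' @param orf Result of [find_longest_orf()] on `sequence`, or `NULL`.
#' @return Numeric score in \[0, 1000\].
#' @export
score_cds <- function(sequence, orf) {
  if (is.null(orf) || orf$aa_length == 0L) return(0)
  sequence <- check_alphabet(sequence)
  score <- 900 * (1 - exp(-orf$aa_length / 100))
  if (isTRUE(orf$has_stop)) score <- score + 50
  atg_pos <- orf$start_offset + 1L  # 1-based position of the A of ATG
  kozak_up <- atg_pos >= 4L &&
    substring(sequence, atg_pos - 3L, atg_pos - 3L) %in% c("A", "G")
  kozak_down <- atg_pos + 3L <= nchar(sequence) &&
    substring(sequence, atg_pos + 3L, atg_pos + 3L) == "G"
  if (kozak_up && kozak_down) score <- score + 50
  min(score, 1000)
}

#' Read externally computed CDS scores
#'
#' Adapter for txCdsPredict-style output: a headerless TSV whose first column
#' is the transcript id and whose second column is the score. Scores are
#' clamped to \[0, 1000\].
#'
#' @param path Path to the TSV.
#' @return Named numeric vector of scores keyed by transcript id.
#' @export
read_cds_scores <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  scores <- pmin(pmax(as.numeric(df[[2L]]), 0), 1000)
  stats::setNames(scores, df[[1L]])
}

#' Assess the coding potential of a transcript sequence
#'
#' @param sequence Nucleotide string.
#' @param cds_score Optional externally supplied CDS score; when `NULL` the
#'   built-in [score_cds()] surrogate is used.
#' @return A `coding_assessment` list: `orf` (see [find_longest_orf()]),
#'   `orf_coverage` (longest ORF nt length / transcript length, in \[0,1\])
#'   and `cds_score`.
#' @export
assess_coding <- function(sequence, cds_score = NULL) {
  sequence <- check_alphabet(sequence)
  orf <- find_longest_orf(sequence)
  coverage <- if (is.null(orf)) 0 else orf$nt_length / nchar(sequence)
  if (is.null(cds_score)) cds_score <- score_cds(sequence, orf)
  stopifnot(cds_score >= 0, cds_score <= 1000)
  structure(
    list(orf = orf, orf_coverage = coverage, cds_score = cds_score),
    class = "coding_assessment"
  )
}

#' Classify a transcript as lncRNA, TUCP or coding-like
#'
#' Decision table over the three coding-potential metrics:
#' \itemize{
#'   \item LNCRNA: ORF < 100 aa AND ORF coverage < 30\% AND CDS score < 800.
#'   \item TUCP: CDS score < 800 AND coverage in \[30\%, 90\%\] (closed at
#'     both ends). Transcripts with an ORF of 100 aa or more but coverage
#'     below 30\% and score below 800 fall outside both published rules and
#'     are routed to TUCP as the conservative choice.
#'   \item CODING_LIKE: everything else (score >= 800 or coverage > 90\%).
#' }
#'
#' @param assessment A `coding_assessment`, or `NULL` to use the scalar
#'   arguments below.
#' @param aa_length,orf_coverage,cds_score Scalars used when `assessment` is
#'   `NULL`.
#' @return One of `"LNCRNA"`, `"TUCP"`, `"CODING_LIKE"`.
#' @export
classify_transcript <- function(assessment = NULL, aa_length = NULL,
                                orf_coverage = NULL, cds_score = NULL) {
  if (!is.null(assessment)) {
    aa_length <- if (is.null(assessment$orf)) 0L else assessment$orf$aa_length
    orf_coverage <- assessment$orf_coverage
    cds_score <- assessment$cds_score
  }
  stopifnot(orf_coverage >= 0, orf_coverage <= 1,
            cds_score >= 0, cds_score <= 1000)
  if (cds_score >= 800 || orf_coverage > 0.90) return("CODING_LIKE")
  if (aa_length < 100 && orf_coverage < 0.30) return("LNCRNA")
  "TUCP"
}

#' Binary-classifier performance metrics
#'
#' Accuracy, sensitivity and specificity from paired truth/prediction label
#' vectors. A metric whose denominator is zero is reported as `NA` with the
#' matching `*_defined` flag set to `FALSE` rather than as NaN.
#'
#' @param truth,predicted Equal-length vectors over \{"positive","negative"\}.
#' @return List with `accuracy`, `sensitivity`, `specificity`, the four
#'   confusion counts `tp`/`tn`/`fp`/`fn`, and logical `accuracy_defined`,
#'   `sensitivity_defined`, `specificity_defined`.
#' @export
classifier_metrics <- function(truth, predicted) {
  if (length(truth) != length(predicted)) {
    stop("truth and predicted must have equal length")
  }
  if (length(truth) == 0L) stop("empty label vectors")
  ok <- c("positive", "negative")
  if (!all(truth %in% ok) || !all(predicted %in% ok)) {
    stop("labels must be 'positive' or 'negative'")
  }
  tp <- sum(truth == "positive" & predicted == "positive")
  tn <- sum(truth == "negative" & predicted == "negative")
  fp <- sum(truth == "negative" & predicted == "positive")
  fn <- sum(truth == "positive" & predicted == "negative")
  sens_def <- (tp + fn) > 0L
  spec_def <- (tn + fp) > 0L
  list(
    accuracy = (tp + tn) / length(truth),
    sensitivity = if (sens_def) tp / (tp + fn) else NA_real_,
    specificity = if (spec_def) tn / (tn + fp) else NA_real_,
    tp = tp, tn = tn, fp = fp, fn = fn,
    accuracy_defined = TRUE,
    sensitivity_defined = sens_def,
    specificity_defined = spec_def
  )
}
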