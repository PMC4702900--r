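#' Construct a transcript model
#'
#' A transcript model is a multi-exon, stranded transcript with genomic exon
#' intervals in 0-based half-open (BED) coordinates. Exons are stored in
#' genomic order regardless of strand; transcript orientation is applied only
#' when the spliced sequence is extracted.
#'
#' @param transcript_id Character scalar identifier.
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param starts Integer vector of 0-based inclusive exon starts.
#' @param ends Integer vector of 0-based exclusive exon ends.
#' @return An object of class `transcript_model` with fields `transcript_id`,
#'   `chrom`, `strand`, `starts`, `ends` and `length` (sum of exon lengths,
#'   nt).
#' @examples
#' tx <- transcript_model("tx1", "chr1", "+", c(99, 300), c(200, 400))
#' tx$length  # 201
#' @export
transcript_model <- function(transcript_id, chrom, strand, starts, ends) {
  stopifnot(length(transcript_id) == 1L, length(chrom) == 1L)
  if (!strand %in% c("+", "-")) {
    stop("strand must be '+' or '-' for transcript ", transcript_id)
  }
  starts <- as.integer(starts)
  ends <- as.integer(ends)
  if (length(starts) != length(ends) || length(starts) < 1L) {
    stop("exon starts/ends length mismatch for transcript ", transcript_id)
  }
  ord <- order(starts, ends)
  starts <- starts[ord]
  ends <- ends[ord]
  if (any(starts >= ends)) {
    stop("invalid exon interval (start >= end) in transcript ", transcript_id)
  }
  if (length(starts) > 1L && any(starts[-1L] < ends[-length(ends)])) {
    stop("overlapping exons in transcript ", transcript_id)
  }
  structure(
    list(
      transcript_id = as.character(transcript_id),
      chrom = as.character(chrom),
      strand = strand,
      starts = starts,
      ends = ends,
      length = sum(ends - starts)
    ),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf(
    "<transcript_model> %s %s:%d-%d(%s) %d exon(s), %d nt\n",
    x$transcript_id, x$chrom, x$starts[1L], x$ends[length(x$ends)],
    x$strand, length(x$starts), x$length
  ))
  invisible(x)
}

n_exons <- function(model) length(model$starts)

# GRanges view of one model's exons (1-based internally for IRanges)
model_exon_granges <- function(model) {
  GenomicRanges::GRanges(
    seqnames = model$chrom,
    ranges = IRanges::IRanges(start = model$starts + 1L, end = model$ends),
    strand = model$strand
  )
}

# deterministic ordering used by all readers: chrom, start, id
order_models <- function(models) {
  if (length(models) == 0L) return(models)
  chroms <- vapply(models, `[[`, character(1), "chrom")
  starts <- vapply(models, function(m) m$starts[1L], integer(1))
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  models[order(chroms, starts, ids)]
}

#' Read transcript models from a GTF file
#'
#' Parses `exon` features of a GTF 2.2 file (1-based inclusive coordinates)
#' into [transcript_model()] objects in 0-based half-open coordinates. Exons
#' are grouped by their `transcript_id` attribute. Output is deterministically
#' ordered by (chrom, start, transcript_id).
#'
#' @param path Path to a GTF file.
#' @return List of `transcript_model` objects (empty list for an empty file).
#' @export
read_gtf <- function(path) {
  if (!file.exists(path)) stop("GTF file not found: ", path)
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0L) return(list())
  recs <- strsplit(lines[idx], "\t", fixed = TRUE)
  nf <- lengths(recs)
  if (any(nf < 9L)) {
    bad <- idx[which(nf < 9L)[1L]]
    stop("malformed GTF line ", bad, ": expected 9 tab-separated fields")
  }
  feat <- vapply(recs, `[[`, character(1), 3L)
  exon <- which(feat == "exon")
  if (length(exon) == 0L) return(list())
  recs <- recs[exon]
  idx <- idx[exon]
  attrs <- vapply(recs, `[[`, character(1), 9L)
  m <- regmatches(attrs, regexpr('transcript_id "[^"]*"', attrs))
  if (length(m) != length(attrs) || any(!nzchar(m))) {
    miss <- which(!grepl('transcript_id "', attrs))[1L]
    stop("malformed GTF line ", idx[miss], ": missing transcript_id attribute")
  }
  tid <- sub('^transcript_id "([^"]*)"$', "\\1", m)
  chrom <- vapply(recs, `[[`, character(1), 1L)
  start1 <- suppressWarnings(as.integer(vapply(recs, `[[`, character(1), 4L)))
  end1 <- suppressWarnings(as.integer(vapply(recs, `[[`, character(1), 5L)))
  strand <- vapply(recs, `[[`, character(1), 7L)
  if (anyNA(start1) || anyNA(end1)) {
    bad <- idx[which(is.na(start1) | is.na(end1))[1L]]
    stop("malformed GTF line ", bad, ": non-numeric coordinates")
  }
  models <- lapply(split(seq_along(tid), tid), function(i) {
    if (length(unique(chrom[i])) != 1L) {
      stop("exons of transcript ", tid[i[1L]], " span multiple chromosomes")
    }
    if (length(unique(strand[i])) != 1L) {
      stop("exons of transcript ", tid[i[1L]], " lie on both strands")
    }
    # GTF 1-based inclusive -> 0-based half-open
    transcript_model(tid[i[1L]], chrom[i[1L]], strand[i[1L]],
                     start1[i] - 1L, end1[i])
  })
  order_models(unname(models))
}

#' Read transcript models from a BED12 file
#'
#' @param path Path to a BED12 file (0-based half-open, blocked).
#' @return List of `transcript_model` objects ordered by
#'   (chrom, start, name). Duplicate names are an error.
#' @export
read_bed12 <- function(path) {
  if (!file.exists(path)) stop("BED12 file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^(#|track|browser)", lines)]
  if (length(lines) == 0L) return(list())
  recs <- strsplit(lines, "\t", fixed = TRUE)
  models <- lapply(seq_along(recs), function(i) {
    f <- recs[[i]]
    if (length(f) != 12L) {
      stop("malformed BED12 line ", i, ": expected 12 fields, got ", length(f))
    }
    chrom_start <- as.integer(f[2L])
    n_blocks <- as.integer(f[10L])
    sizes <- as.integer(strsplit(sub(",$", "", f[11L]), ",")[[1L]])
    offs <- as.integer(strsplit(sub(",$", "", f[12L]), ",")[[1L]])
    if (length(sizes) != n_blocks || length(offs) != n_blocks) {
      stop("BED12 line ", i, ": blockCount=", n_blocks,
           " does not match blockSizes/blockStarts")
    }
    starts <- chrom_start + offs
    ends <- starts + sizes
    if (ends[n_blocks] != as.integer(f[3L])) {
      stop("BED12 line ", i, ": blocks do not span chromStart..chromEnd")
    }
    transcript_model(f[4L], f[1L], f[6L], starts, ends)
  })
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids)) {
    stop("duplicate transcript id in BED12 file: ", ids[duplicated(ids)][1L])
  }
  order_models(models)
}

#' Write transcript models to a BED12 file
#'
#' `read_bed12()` composed with `write_bed12()` is the identity on canonical
#' records (score 0, thick range collapsed to chromStart, itemRgb 0).
#'
#' @param models List of `transcript_model` objects.
#' @param path Output path.
#' @param names Optional character vector replacing each model's
#'   `transcript_id` in the name column (e.g. assigned lncRNA names).
#' @return Invisibly, `path`.
#' @export
write_bed12 <- function(models, path, names = NULL) {
  if (!is.null(names) && length(names) != length(models)) {
    stop("names must have one entry per model")
  }
  rows <- vapply(seq_along(models), function(i) {
    m <- models[[i]]
    nm <- if (is.null(names)) m$transcript_id else names[[i]]
    cs <- m$starts[1L]
    ce <- m$ends[length(m$ends)]
    paste(
      m$chrom, cs, ce, nm, 0L, m$strand, cs, cs, 0L, length(m$starts),
      paste0(paste(m$ends - m$starts, collapse = ","), ","),
      paste0(paste(m$starts - cs, collapse = ","), ","),
      sep = "\t"
    )
  }, character(1))
  writeLines(rows, path)
  invisible(path)
}

#' Load a genome from a FASTA file
#'
#' @param path Multi-record FASTA (line wrapping tolerated).
#' @return A [Biostrings::DNAStringSet] keyed by sequence name.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  genome <- Biostrings::readDNAStringSet(path)
  # FASTA headers may carry descriptions; key on the first token
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

#' Extract the spliced transcript sequence
#'
#' Exon sequences are concatenated in genomic order; for minus-strand
#' transcripts the concatenation is reverse-complemented, so the result always
#' reads 5' to 3' in transcript orientation.
#'
#' @param model A `transcript_model`.
#' @param genome A [Biostrings::DNAStringSet] (or path to a FASTA file).
#' @return Character scalar nucleotide sequence of length `model$length`.
#' @export
extract_sequence <- function(model, genome) {
  if (is.character(genome) && length(genome) == 1L) genome <- read_genome(genome)
  if (!model$chrom %in% names(genome)) {
    stop("chromosome not found in genome: ", model$chrom)
  }
  chrom_seq <- genome[[model$chrom]]
  if (model$ends[length(model$ends)] > length(chrom_seq) || model$starts[1L] < 0L) {
    stop("exon of transcript ", model$transcript_id,
         " extends beyond chromosome ", model$chrom,
         " (length ", length(chrom_seq), ")")
  }
  pieces <- Biostrings::DNAStringSet(
    chrom_seq,
    start = model$starts + 1L,
    end = model$ends
  )
  spliced <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  if (model$strand == "-") spliced <- Biostrings::reverseComplement(spliced)
  as.character(spliced)
}
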