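#' Specification of a synthetic fixture bundle
#'
#' Describes a deterministic toy dataset: a random genome into which
#' transcripts of known classes are planted by explicit codon construction,
#' plus annotation, similarity-hit tables, an expression matrix with a
#' planted co-expression block, and a GO table with a planted enriched term.
#' Each planted class is built so that its classification is unambiguous and
#' far from every decision boundary.
#'
#' @param seed Master seed; every component derives its own stream from it.
#' @param n_coding Planted coding-like transcripts (long, high-coverage ORF).
#' @param n_lnc Planted lncRNAs (short ORF, low coverage, low CDS score).
#' @param n_tucp Planted TUCPs (mid-coverage ORF, low CDS score).
#' @param n_antisense Planted antisense lncRNAs whose exons exactly overlap
#'   coding annotation exons on the opposite strand.
#' @param n_sense_overlap Planted transcripts overlapping a same-strand
#'   coding annotation exon (filter-2 positives).
#' @param n_smallrna_overlap Planted transcripts fully covering a same-strand
#'   miRNA precursor (filter-2 small-RNA positives).
#' @param n_blastx_flagged,n_pfam_flagged Planted lncRNA-like transcripts
#'   carrying strong BLASTX / Pfam evidence (filter-4 positives).
#' @param genome_length Genome size in nt; must accommodate all plants.
#' @param n_samples Expression samples.
#' @param n_partners Co-expressed coding partners of the target lncRNA.
#' @param n_background_coding Background coding genes in the expression
#'   matrix.
#' @param planted_go_term GO id annotated on every partner gene.
#' @param species_code Three-letter species code used in naming.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 1L, n_coding = 5L, n_lnc = 5L, n_tucp = 3L,
                         n_antisense = 3L, n_sense_overlap = 2L,
                         n_smallrna_overlap = 1L, n_blastx_flagged = 1L,
                         n_pfam_flagged = 1L, genome_length = 100000L,
                         n_samples = 20L, n_partners = 10L,
                         n_background_coding = 40L,
                         planted_go_term = "GO:0006412",
                         species_code = "hsa") {
  counts <- c(n_coding, n_lnc, n_tucp, n_antisense, n_sense_overlap,
              n_smallrna_overlap, n_blastx_flagged, n_pfam_flagged)
  stopifnot(all(counts >= 0), genome_length > 0, n_samples >= 3)
  structure(
    list(seed = as.integer(seed), n_coding = n_coding, n_lnc = n_lnc,
         n_tucp = n_tucp, n_antisense = n_antisense,
         n_sense_overlap = n_sense_overlap,
         n_smallrna_overlap = n_smallrna_overlap,
         n_blastx_flagged = n_blastx_flagged,
         n_pfam_flagged = n_pfam_flagged,
         genome_length = as.integer(genome_length),
         n_samples = as.integer(n_samples), n_partners = n_partners,
         n_background_coding = n_background_coding,
         planted_go_term = planted_go_term, species_code = species_code),
    class = "fixture_spec"
  )
}

# independent deterministic stream per fixture component
stream_seed <- function(master, component) {
  (as.numeric(master) * 31L + component * 7919L) %% 2147483647
}

with_stream <- function(master, component, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(stream_seed(master, component))
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

# filler with no A or T: cannot create ATG or stop codons in any frame
cg_filler <- function(n) {
  paste(sample(c("C", "G"), n, replace = TRUE), collapse = "")
}

ORF_BODY_CODONS <- c("GGC", "GCC", "CGG", "CCG", "GCG", "CGC")

# spliced sequence with exactly one ORF: ATG + (aa-1) C/G codons + TAA,
# embedded at `offset` nt in C/G filler of total length `total`
design_orf_sequence <- function(total, offset, aa) {
  orf <- paste0("ATG",
                paste(sample(ORF_BODY_CODONS, aa - 1L, replace = TRUE),
                      collapse = ""),
                "TAA")
  stopifnot(offset + nchar(orf) <= total)
  paste0(cg_filler(offset), orf, cg_filler(total - offset - nchar(orf)))
}

revcomp_chr <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}

# transcript blueprints per planted class: spliced length, ORF offset, aa
CLASS_DESIGNS <- list(
  coding = list(len = 950L, offset = 21L, aa = 300L),   # cov 0.95, score > 800
  lncRNA = list(len = 400L, offset = 60L, aa = 10L),    # cov 0.08, score ~ 140
  TUCP = list(len = 600L, offset = 99L, aa = 100L),     # cov 0.505, score < 800
  antisense = list(len = 400L, offset = 60L, aa = 10L),
  sense_overlap = list(len = 400L, offset = 60L, aa = 10L),
  smallrna_overlap = list(len = 400L, offset = 60L, aa = 10L),
  blastx_hit = list(len = 400L, offset = 60L, aa = 10L),
  pfam_hit = list(len = 400L, offset = 60L, aa = 10L)
)

#' Generate a synthetic fixture bundle
#'
#' Writes a complete toy dataset into `out_dir`: `genome.fa`,
#' `transcripts.gtf`, `annotations.tsv`, `blastx.tsv` (outfmt 6),
#' `pfam.tsv`, `blastn_<species>.tsv` (outfmt 6), `expression.tsv`,
#' `go_annotation.tsv` and `truth.tsv`. Byte-identical for a given spec.
#' The truth table records every planted transcript's intended class and
#' filter fate.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if absent).
#' @return Invisibly, a list with the file `paths`, the planted
#'   `models`, `annotations`, `truth` data frame, expression `matrix`,
#'   `go` table, and bookkeeping ids (`target_lnc`, `partner_ids`,
#'   `population_ids`).
#' @export
generate_fixture <- function(spec, out_dir) {
  stopifnot(inherits(spec, "fixture_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list(
    genome = file.path(out_dir, "genome.fa"),
    transcripts = file.path(out_dir, "transcripts.gtf"),
    annotations = file.path(out_dir, "annotations.tsv"),
    blastx = file.path(out_dir, "blastx.tsv"),
    pfam = file.path(out_dir, "pfam.tsv"),
    expression = file.path(out_dir, "expression.tsv"),
    go = file.path(out_dir, "go_annotation.tsv"),
    truth = file.path(out_dir, "truth.tsv")
  )

  classes <- rep(
    c("coding", "lncRNA", "TUCP", "antisense", "sense_overlap",
      "smallrna_overlap", "blastx_hit", "pfam_hit"),
    times = c(spec$n_coding, spec$n_lnc, spec$n_tucp, spec$n_antisense,
              spec$n_sense_overlap, spec$n_smallrna_overlap,
              spec$n_blastx_flagged, spec$n_pfam_flagged)
  )
  n_tx <- length(classes)
  slot_width <- 2500L
  n_decoy_features <- 6L
  needed <- (n_tx + n_decoy_features) * slot_width + 1000L
  if (needed > spec$genome_length) {
    stop("infeasible placement: need >= ", needed, " nt of genome for ",
         n_tx, " transcripts, got ", spec$genome_length)
  }

  # --- genome background (stream 1)
  genome_chars <- with_stream(spec$seed, 1L, {
    sample(c("A", "C", "G", "T"), spec$genome_length, replace = TRUE)
  })

  # --- transcript plants (stream 2)
  ann_rows <- list()
  models <- vector("list", n_tx)
  truth <- vector("list", n_tx)
  with_stream(spec$seed, 2L, {
    for (i in seq_len(n_tx)) {
      cls <- classes[i]
      d <- CLASS_DESIGNS[[cls]]
      tid <- sprintf("TX%03d_%s", i, cls)
      strand <- if (cls == "antisense") "-" else c("+", "-")[1L + i %% 2L]
      spliced <- design_orf_sequence(d$len, d$offset, d$aa)
      # split into 2 exons separated by a 300-nt intron
      e1 <- as.integer(floor(d$len * 0.4))
      slot0 <- (i - 1L) * slot_width + 500L  # 0-based slot origin
      starts <- c(slot0, slot0 + e1 + 300L)
      ends <- c(slot0 + e1, slot0 + d$len + 300L)
      genomic <- if (strand == "+") spliced else revcomp_chr(spliced)
      pieces <- c(substring(genomic, 1L, e1),
                  substring(genomic, e1 + 1L, d$len))
      for (k in 1:2) {
        idx <- (starts[k] + 1L):ends[k]
        genome_chars[idx] <- strsplit(pieces[k], "")[[1L]]
      }
      models[[i]] <- transcript_model(tid, "chr1", strand, starts, ends)
      if (cls == "antisense") {
        # coding exons at identical coordinates, opposite strand
        opp <- if (strand == "+") "-" else "+"
        for (k in 1:2) {
          ann_rows[[length(ann_rows) + 1L]] <- data.frame(
            chrom = "chr1", start = starts[k], end = ends[k], strand = opp,
            id = sprintf("CODEX_anti_%d_%d", i, k), category = "coding_exon",
            stringsAsFactors = FALSE)
        }
      } else if (cls == "sense_overlap") {
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          chrom = "chr1", start = starts[1L] + 10L, end = starts[1L] + 90L,
          strand = strand, id = sprintf("CODEX_sense_%d", i),
          category = "coding_exon", stringsAsFactors = FALSE)
      } else if (cls == "smallrna_overlap") {
        # 80-nt miRNA precursor fully inside exon 1, same strand
        ann_rows[[length(ann_rows) + 1L]] <- data.frame(
          chrom = "chr1", start = starts[1L] + 20L, end = starts[1L] + 100L,
          strand = strand, id = sprintf("MIR_%d", i),
          category = "miRNA_precursor", stringsAsFactors = FALSE)
      }
      fate <- switch(cls,
        coding = "CODING_LIKE", lncRNA = "LNCRNA", TUCP = "TUCP",
        antisense = "LNCRNA", sense_overlap = "FAIL_CODING_OVERLAP",
        smallrna_overlap = "FAIL_SMALLRNA_OVERLAP",
        blastx_hit = "REMOVED_BLASTX", pfam_hit = "REMOVED_PFAM")
      truth[[i]] <- data.frame(transcript_id = tid, planted_class = cls,
                                expected_fate = fate,
                                stringsAsFactors = FALSE)
    }
  })
  truth <- do.call(rbind, truth)

  # decoy annotation far from every transcript, in trailing slots
  decoy0 <- n_tx * slot_width + 1000L
  decoys <- data.frame(
    chrom = "chr1",
    start = decoy0 + (0:(n_decoy_features - 1L)) * slot_width,
    end = decoy0 + (0:(n_decoy_features - 1L)) * slot_width + 150L,
    strand = rep(c("+", "-"), length.out = n_decoy_features),
    id = sprintf("DECOY%d", seq_len(n_decoy_features)),
    category = rep(c("coding_exon", "pseudogene_exon", "tRNA"),
                   length.out = n_decoy_features),
    stringsAsFactors = FALSE
  )
  ann_df <- rbind(do.call(rbind, ann_rows), decoys)
  ann_df <- ann_df[order(ann_df$start, ann_df$id), ]

  # --- write genome + transcripts + annotation
  genome <- Biostrings::DNAStringSet(paste(genome_chars, collapse = ""))
  names(genome) <- "chr1"
  Biostrings::writeXStringSet(genome, paths$genome, width = 70L)
  write_gtf(models, paths$transcripts)
  utils::write.table(ann_df, paths$annotations, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- similarity-evidence tables (stream 3)
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  blastx_targets <- ids[classes == "blastx_hit"]
  decoy_blastx <- utils::head(ids[classes == "lncRNA"], 1L)
  blastx <- rbind(
    if (length(blastx_targets)) data.frame(
      query_id = blastx_targets, subject_id = "UniRef90_P10000",
      pident = 92.5, align_length = 110L, mismatch = 8L, gapopen = 0L,
      qstart = 1L, qend = 330L, sstart = 1L, send = 110L,
      e_value = 1e-40, bit_score = 220.0, stringsAsFactors = FALSE),
    if (length(decoy_blastx)) data.frame(
      query_id = decoy_blastx, subject_id = "UniRef90_P20000",
      pident = 35.0, align_length = 40L, mismatch = 26L, gapopen = 1L,
      qstart = 10L, qend = 130L, sstart = 5L, send = 44L,
      e_value = 1e-10, bit_score = 45.0, stringsAsFactors = FALSE)
  )
  utils::write.table(blastx, paths$blastx, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  pfam_targets <- ids[classes == "pfam_hit"]
  decoy_pfam <- utils::head(ids[classes == "lncRNA"], 1L)
  pfam <- rbind(
    if (length(pfam_targets)) data.frame(
      query_id = pfam_targets, domain_id = "PF00001",
      full_seq_evalue = 1e-8, best_domain_evalue = 1e-7,
      stringsAsFactors = FALSE),
    if (length(decoy_pfam)) data.frame(
      query_id = decoy_pfam, domain_id = "PF09999",
      full_seq_evalue = 1e-8, best_domain_evalue = 1e-3,
      stringsAsFactors = FALSE)
  )
  utils::write.table(pfam, paths$pfam, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # cross-species BLASTN hits per target species (stream 3)
  lnc_ids <- ids[classes %in% c("lncRNA", "antisense")]
  blastn_species <- c("ptr", "mml")
  with_stream(spec$seed, 3L, {
    for (sp in blastn_species) {
      p <- file.path(out_dir, sprintf("blastn_%s.tsv", sp))
      paths[[paste0("blastn_", sp)]] <- p
      if (length(lnc_ids) == 0L) { writeLines(character(), p); next }
      n_hits <- sample(1:3, length(lnc_ids), replace = TRUE)
      rows <- lapply(seq_along(lnc_ids), function(j) {
        h <- n_hits[j]
        data.frame(
          query_id = lnc_ids[j],
          subject_id = sprintf("%s_lnc_%d_%d", sp, j, seq_len(h)),
          pident = round(stats::runif(h, 70, 99), 1),
          align_length = sample(50:350, h, replace = TRUE),
          mismatch = sample(0:30, h, replace = TRUE), gapopen = 0L,
          qstart = 1L, qend = 200L, sstart = 1L, send = 200L,
          e_value = 10^(-stats::runif(h, 6, 40)),
          bit_score = round(stats::runif(h, 40, 300), 1),
          stringsAsFactors = FALSE)
      })
      utils::write.table(do.call(rbind, rows), p, sep = "\t", quote = FALSE,
                         row.names = FALSE, col.names = FALSE)
    }
  })

  # --- expression matrix with a planted co-expressed block (stream 4)
  target_lnc <- if (length(lnc_ids)) lnc_ids[1L] else NA_character_
  partner_ids <- sprintf("PG%03d", seq_len(spec$n_partners))
  background_ids <- sprintf("BG%03d", seq_len(spec$n_background_coding))
  coding_gene_ids <- c(partner_ids, background_ids)
  expr <- with_stream(spec$seed, 4L, {
    base <- stats::rlnorm(spec$n_samples, meanlog = 2, sdlog = 1)
    rows <- list()
    for (lid in lnc_ids) {
      rows[[lid]] <- if (identical(lid, target_lnc)) base
        else stats::rlnorm(spec$n_samples, meanlog = 1, sdlog = 1)
    }
    for (pid in partner_ids) {
      rows[[pid]] <- base * exp(stats::rnorm(spec$n_samples, 0, 0.05))
    }
    for (bid in background_ids) {
      rows[[bid]] <- stats::rlnorm(spec$n_samples, meanlog = 2, sdlog = 1)
    }
    m <- do.call(rbind, rows)
    colnames(m) <- sprintf("S%02d", seq_len(spec$n_samples))
    round(m, 4)
  })
  expr_df <- data.frame(feature_id = rownames(expr), expr,
                        check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(expr_df, paths$expression, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  # --- GO annotation with a planted enriched term (stream 5)
  go <- with_stream(spec$seed, 5L, {
    other_terms <- sprintf("GO:%07d", 1:10)
    rows <- list()
    for (pid in partner_ids) {
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = pid, go_term = spec$planted_go_term,
        category = "biological_process", stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = pid, go_term = sample(other_terms, 1L),
        category = "biological_process", stringsAsFactors = FALSE)
    }
    # planted term at ~10% background frequency
    n_bg_term <- max(1L, round(0.1 * length(background_ids)))
    bg_with_term <- background_ids[seq_len(n_bg_term)]
    for (bid in background_ids) {
      if (bid %in% bg_with_term) {
        rows[[length(rows) + 1L]] <- data.frame(
          gene_id = bid, go_term = spec$planted_go_term,
          category = "biological_process", stringsAsFactors = FALSE)
      }
      rows[[length(rows) + 1L]] <- data.frame(
        gene_id = bid, go_term = sample(other_terms, 1L),
        category = "biological_process", stringsAsFactors = FALSE)
    }
    do.call(rbind, rows)
  })
  utils::write.table(go, paths$go, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  utils::write.table(truth, paths$truth, sep = "\t", quote = FALSE,
                     row.names = FALSE)

  invisible(list(
    paths = paths, models = models,
    annotations = read_annotation_table(paths$annotations),
    truth = truth, matrix = expr, go = go,
    target_lnc = target_lnc, partner_ids = partner_ids,
    population_ids = coding_gene_ids, lnc_ids = lnc_ids,
    blastn_species = blastn_species
  ))
}

#' Write transcript models as GTF exon records
#'
#' @param models List of [transcript_model()] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gtf <- function(models, path) {
  rows <- unlist(lapply(models, function(m) {
    sprintf(
      '%s\tlncseekr\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s";',
      m$chrom, m$starts + 1L, m$ends, m$strand, m$transcript_id,
      m$transcript_id
    )
  }))
  writeLines(rows, path)
  invisible(path)
}
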