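#' Cluster transcripts into gene loci
#'
#' Two transcripts belong to the same gene iff they are connected,
#' transitively, by same-strand exonic overlap of at least 1 nt (the standard
#' Cufflinks-style locus notion; intronic span does not connect). Gene
#' indices are 1-based and assigned in order of each locus's leftmost genomic
#' position (chrom, then start).
#'
#' @param models List of [transcript_model()] objects.
#' @return Named integer vector mapping transcript_id to gene index.
#' @export
cluster_into_genes <- function(models) {
  if (length(models) == 0L) return(stats::setNames(integer(), character()))
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  if (anyDuplicated(ids)) stop("duplicate transcript ids in input")
  exon_gr <- do.call(c, lapply(models, model_exon_granges))
  tx_of_exon <- rep(seq_along(models),
                    vapply(models, n_exons, integer(1)))
  hits <- GenomicRanges::findOverlaps(exon_gr, exon_gr, minoverlap = 1L)
  from <- tx_of_exon[S4Vectors::queryHits(hits)]
  to <- tx_of_exon[S4Vectors::subjectHits(hits)]
  g <- igraph::graph_from_edgelist(cbind(from, to), directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, length(models) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership[seq_along(models)]
  # renumber components by leftmost genomic position
  chrom <- vapply(models, `[[`, character(1), "chrom")
  start <- vapply(models, function(m) m$starts[1L], integer(1))
  left <- data.frame(comp = comp, chrom = chrom, start = start)
  first <- left[order(left$chrom, left$start), ]
  first <- first[!duplicated(first$comp), ]
  rank <- stats::setNames(seq_len(nrow(first)), first$comp)
  stats::setNames(as.integer(rank[as.character(comp)]), ids)
}

#' Render a three-part A-B-C lncRNA name
#'
#' Names have three parts, A-B-C: a three-letter species code, a gene number
#' and a transcript number, rendered as `"<code>-lncRNA<gene>-<tx>"` (e.g.
#' `hsa-lncRNA10932-8` is the 8th transcript of gene lncRNA10932 in human).
#'
#' @param species_code Lower-case three-letter species code.
#' @param gene_number,transcript_number Positive integers.
#' @return Character scalar name.
#' @export
render_lncrna_name <- function(species_code, gene_number, transcript_number) {
  if (!grepl("^[a-z]{3}$", species_code)) {
    stop("species_code must match ^[a-z]{3}$")
  }
  stopifnot(gene_number >= 1, transcript_number >= 1)
  sprintf("%s-lncRNA%d-%d", species_code, as.integer(gene_number),
          as.integer(transcript_number))
}

#' Parse a three-part A-B-C lncRNA name
#'
#' Inverse of [render_lncrna_name()].
#'
#' @param name Name such as `"hsa-lncRNA10932-8"`.
#' @return List with `species_code`, `gene_number`, `transcript_number`.
#' @export
parse_lncrna_name <- function(name) {
  m <- regmatches(name, regexec("^([a-z]{3})-lncRNA([0-9]+)-([0-9]+)$", name))[[1L]]
  if (length(m) != 4L) stop("not a valid lncRNA name: ", name)
  list(
    species_code = m[2L],
    gene_number = as.integer(m[3L]),
    transcript_number = as.integer(m[4L])
  )
}

#' Assign A-B-C names to clustered transcripts
#'
#' Transcript numbers are 1-based within each gene, ordered by (start, end,
#' transcript_id) for determinism; gene numbers come from
#' [cluster_into_genes()] (genome-wide, left to right).
#'
#' @param models List of [transcript_model()] objects.
#' @param species_code Lower-case three-letter species code.
#' @param clusters Optional precomputed output of [cluster_into_genes()].
#' @return Data frame with columns `transcript_id`, `gene_number`,
#'   `transcript_number`, `gene_name`, `name`, one row per model, in input
#'   order.
#' @export
assign_names <- function(models, species_code, clusters = NULL) {
  if (!grepl("^[a-z]{3}$", species_code)) {
    stop("species_code must match ^[a-z]{3}$")
  }
  if (is.null(clusters)) clusters <- cluster_into_genes(models)
  ids <- vapply(models, `[[`, character(1), "transcript_id")
  start <- vapply(models, function(m) m$starts[1L], integer(1))
  end <- vapply(models, function(m) m$ends[n_exons(m)], integer(1))
  gene <- as.integer(clusters[ids])
  tx_number <- integer(length(models))
  for (gidx in unique(gene)) {
    members <- which(gene == gidx)
    ord <- members[order(start[members], end[members], ids[members])]
    tx_number[ord] <- seq_along(ord)
  }
  data.frame(
    transcript_id = ids,
    gene_number = gene,
    transcript_number = tx_number,
    gene_name = sprintf("%s-lncRNA%d", species_code, gene),
    name = vapply(seq_along(models), function(i) {
      render_lncrna_name(species_code, gene[i], tx_number[i])
    }, character(1)),
    stringsAsFactors = FALSE
  )
}
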