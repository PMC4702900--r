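#' Fragments per kilobase of transcript per million mapped fragments
#'
#' `FPKM = count * 1e9 / (length_nt * total_mapped)`: the fragment count
#' normalised by transcript length in kb and sequencing depth in millions.
#'
#' @param fragment_count Number of fragments assigned to the transcript
#'   (>= 0; vectorised).
#' @param transcript_length_nt Transcript length in nt (> 0).
#' @param total_mapped_fragments Library size in fragments (> 0).
#' @return Numeric FPKM value(s).
#' @export
compute_fpkm <- function(fragment_count, transcript_length_nt,
                         total_mapped_fragments) {
  if (any(transcript_length_nt <= 0)) stop("transcript length must be > 0")
  if (any(total_mapped_fragments <= 0)) stop("total mapped fragments must be > 0")
  if (any(fragment_count < 0)) stop("fragment count must be >= 0")
  fragment_count * 1e9 / (transcript_length_nt * total_mapped_fragments)
}

#' Pearson correlation with a two-sided t-test p-value
#'
#' The product-moment correlation r, with a two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom. Perfect
#' correlation (|r| = 1) gets p = 0. Zero variance in either vector makes the
#' coefficient undefined; this is flagged rather than returned as NaN.
#'
#' @param x,y Equal-length numeric vectors, n >= 3.
#' @return List with `r`, `p`, and logical `defined`.
#' @export
pearson_r_p <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(r = NA_real_, p = NA_real_, defined = FALSE))
  }
  r <- stats::cor(x, y)
  if (abs(r) >= 1) return(list(r = sign(r), p = 0, defined = TRUE))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * stats::pt(-abs(tstat), df = n - 2), defined = TRUE)
}

#' Benjamini-Hochberg and Bonferroni multiple-testing corrections
#'
#' `bh_fdr` applies the step-up false-discovery-rate procedure
#' (q(i) = min over j >= i of p(j) * m / j on the sorted p-values, mapped
#' back to input order, capped at 1); `bonferroni` returns `min(1, p * m)`.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values in input order.
#' @export
bh_fdr <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' @rdname bh_fdr
#' @export
bonferroni <- function(p_values) {
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "bonferroni")
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) when drawing `n` genes without replacement from a population of
#' `N` genes of which `K` carry the annotation:
#' `sum_{i=k}^{min(K,n)} C(K,i) C(N-K, n-i) / C(N,n)`.
#'
#' @param k Observed count of annotated genes in the draw.
#' @param K Annotated genes in the population.
#' @param n Draw (gene set) size.
#' @param N Population size.
#' @return The upper-tail probability.
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  if (any(c(k, K, n, N) < 0) || k > n || n > N || K > N) {
    stop("require 0 <= k <= n <= N and K <= N")
  }
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Read an expression matrix from TSV
#'
#' Rows are features (first column = feature id), remaining header columns
#' are samples; values are non-negative abundances (FPKM).
#'
#' @param path Path to the TSV.
#' @return Numeric matrix with feature rownames and sample colnames.
#' @export
read_expression_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  if (anyDuplicated(rownames(m))) stop("duplicate feature ids in matrix")
  if (anyDuplicated(colnames(m))) stop("duplicate sample ids in matrix")
  if (any(!is.finite(m))) stop("expression matrix contains non-finite values")
  m
}

#' Read a gene-to-GO annotation table
#'
#' TSV with header columns `gene_id`, `go_term` and optionally `category`
#' (GO namespace).
#'
#' @param path Path to the TSV.
#' @return Data frame with one row per (gene, term) pair.
#' @export
read_go_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  if (!all(c("gene_id", "go_term") %in% names(df))) {
    stop("GO annotation must have columns gene_id, go_term")
  }
  df
}

#' Build lncRNA-to-coding co-expression edges
#'
#' Scores every lncRNA x coding-gene pair by Pearson correlation across
#' samples, converts to two-sided t-test p-values, applies Benjamini-Hochberg
#' over the full family of tested pairs, and keeps edges with q below
#' `q_threshold` and correlation magnitude at least `r_threshold`
#' (or r >= r_threshold when `positive_only`). Pairs involving a
#' constant-expression row are skipped with a warning.
#'
#' @param lnc_ids,coding_ids Row ids in `matrix` to correlate.
#' @param matrix Expression matrix (features x samples).
#' @param q_threshold BH q-value cutoff (edges kept where q < threshold),
#'   default 0.05.
#' @param r_threshold Minimum correlation magnitude, default 0.7.
#' @param positive_only If TRUE only positive correlations form edges.
#' @return Data frame of edges: `lnc_id`, `coding_id`, `r`, `p`, `q`,
#'   ordered by q then p then ids.
#' @export
build_coexpression <- function(lnc_ids, coding_ids, matrix,
                               q_threshold = 0.05, r_threshold = 0.7,
                               positive_only = FALSE) {
  missing_ids <- setdiff(c(lnc_ids, coding_ids), rownames(matrix))
  if (length(missing_ids)) {
    stop("ids absent from matrix: ", paste(utils::head(missing_ids, 5L),
                                           collapse = ", "))
  }
  n <- ncol(matrix)
  if (n < 3L) stop("need at least 3 samples")
  sds <- apply(matrix[unique(c(lnc_ids, coding_ids)), , drop = FALSE], 1L,
               stats::sd)
  constant <- names(sds)[sds == 0]
  if (length(constant)) {
    warning("skipping constant-expression rows: ",
            paste(utils::head(constant, 5L), collapse = ", "))
  }
  lnc_use <- setdiff(lnc_ids, constant)
  cod_use <- setdiff(coding_ids, constant)
  grid <- expand.grid(lnc_id = lnc_use, coding_id = cod_use,
                      stringsAsFactors = FALSE)
  if (nrow(grid) == 0L) {
    return(data.frame(lnc_id = character(), coding_id = character(),
                      r = numeric(), p = numeric(), q = numeric(),
                      stringsAsFactors = FALSE))
  }
  rmat <- stats::cor(t(matrix[lnc_use, , drop = FALSE]),
                     t(matrix[cod_use, , drop = FALSE]))
  r <- rmat[cbind(match(grid$lnc_id, lnc_use), match(grid$coding_id, cod_use))]
  r <- pmin(1, pmax(-1, r))
  p <- ifelse(abs(r) >= 1, 0,
              2 * stats::pt(-abs(r * sqrt((n - 2) / (1 - r^2))), df = n - 2))
  q <- bh_fdr(p)
  keep <- q < q_threshold &
    (if (positive_only) r >= r_threshold else abs(r) >= r_threshold)
  out <- data.frame(lnc_id = grid$lnc_id, coding_id = grid$coding_id,
                    r = r, p = p, q = q, stringsAsFactors = FALSE)[keep, ]
  out <- out[order(out$q, out$p, out$lnc_id, out$coding_id), ]
  rownames(out) <- NULL
  out
}

#' Hypergeometric GO enrichment of a partner gene set
#'
#' For every GO term annotated in the population, tests whether the partner
#' set is enriched for the term with an upper-tail hypergeometric test, then
#' applies Bonferroni and Benjamini-Hochberg over the per-term family.
#'
#' @param partner_ids Genes of interest (e.g. co-expression partners);
#'   must be a subset of `population_ids`.
#' @param go_annotation Data frame with columns `gene_id`, `go_term`.
#' @param population_ids Background gene universe.
#' @return Data frame sorted by p (ties by term id): `go_term`, `k`
#'   (partners with the term), `K` (population genes with the term), `n`
#'   (partner-set size), `N` (population size), `p`, `p_bonferroni`, `q`.
#' @export
go_enrichment <- function(partner_ids, go_annotation, population_ids) {
  partner_ids <- unique(partner_ids)
  population_ids <- unique(population_ids)
  if (!all(partner_ids %in% population_ids)) {
    stop("partner_ids must be a subset of population_ids")
  }
  empty <- data.frame(go_term = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      p_bonferroni = numeric(), q = numeric(),
                      stringsAsFactors = FALSE)
  if (length(partner_ids) == 0L) {
    warning("empty partner set; no enrichment computed")
    return(empty)
  }
  ann <- go_annotation[go_annotation$gene_id %in% population_ids, , drop = FALSE]
  ann <- unique(ann[, c("gene_id", "go_term")])
  if (nrow(ann) == 0L) return(empty)
  terms <- sort(unique(ann$go_term))
  n <- length(partner_ids)
  N <- length(population_ids)
  rows <- lapply(terms, function(term) {
    genes_with_term <- ann$gene_id[ann$go_term == term]
    K <- length(genes_with_term)
    k <- sum(partner_ids %in% genes_with_term)
    data.frame(go_term = term, k = k, K = K, n = n, N = N,
               p = hypergeom_upper_tail(k, K, n, N),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_bonferroni <- bonferroni(out$p)
  out$q <- bh_fdr(out$p)
  out <- out[order(out$p, out$go_term), ]
  rownames(out) <- NULL
  out
}

#' Count reads fully contained in annotated gene regions
#'
#' A read contributes to a gene's count iff its interval is entirely inside
#' the gene interval on the same strand ("perfectly located"); a read inside
#' several genes counts once for each. Intervals are 0-based half-open data
#' frames with columns `chrom`, `start`, `end`, `strand` (genes additionally
#' `id`).
#'
#' @param read_intervals Data frame of read alignments.
#' @param gene_intervals Data frame of gene regions.
#' @return Named integer vector of read counts per gene id (zeros included).
#' @export
assign_reads_to_genes <- function(read_intervals, gene_intervals) {
  counts <- stats::setNames(integer(nrow(gene_intervals)), gene_intervals$id)
  if (nrow(read_intervals) == 0L || nrow(gene_intervals) == 0L) return(counts)
  reads <- GenomicRanges::GRanges(
    read_intervals$chrom,
    IRanges::IRanges(read_intervals$start + 1L, read_intervals$end),
    strand = read_intervals$strand
  )
  genes <- GenomicRanges::GRanges(
    gene_intervals$chrom,
    IRanges::IRanges(gene_intervals$start + 1L, gene_intervals$end),
    strand = gene_intervals$strand
  )
  hits <- GenomicRanges::findOverlaps(reads, genes, type = "within",
                                      ignore.strand = FALSE)
  tab <- table(S4Vectors::subjectHits(hits))
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}
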