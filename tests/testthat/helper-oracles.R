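# Independent brute-force oracles. These deliberately avoid the package's
# own code paths (and Biostrings) so that agreement is informative.

COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N")

oracle_revcomp <- function(s) {
  paste(rev(COMPLEMENT[strsplit(s, "")[[1]]]), collapse = "")
}

# full codon table, written out by hand
ORACLE_CODON_TABLE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

oracle_translate <- function(s, frame) {
  L <- nchar(s)
  n_codons <- (L - frame) %/% 3
  if (n_codons < 1) return("")
  aas <- vapply(seq_len(n_codons), function(i) {
    codon <- substr(s, frame + 3 * (i - 1) + 1, frame + 3 * i)
    if (codon %in% names(ORACLE_CODON_TABLE)) ORACLE_CODON_TABLE[[codon]]
    else "X"
  }, character(1))
  paste(aas, collapse = "")
}

# exhaustive ATG-to-stop enumeration over every start position
oracle_longest_orf <- function(s) {
  L <- nchar(s)
  best <- NULL
  for (start in seq_len(max(0, L - 2))) {
    if (substr(s, start, start + 2) != "ATG") next
    frame <- (start - 1) %% 3
    aa <- 0
    pos <- start
    has_stop <- FALSE
    while (pos + 2 <= L) {
      codon <- substr(s, pos, pos + 2)
      if (codon %in% c("TAA", "TAG", "TGA")) { has_stop <- TRUE; break }
      aa <- aa + 1
      pos <- pos + 3
    }
    cand <- list(frame = frame, start_offset = start - 1, aa_length = aa,
                 nt_length = if (has_stop) 3 * aa + 3 else 3 * aa,
                 has_stop = has_stop)
    if (is.null(best) || cand$aa_length > best$aa_length ||
        (cand$aa_length == best$aa_length &&
         (cand$start_offset < best$start_offset ||
          (cand$start_offset == best$start_offset &&
           cand$frame < best$frame)))) {
      best <- cand
    }
  }
  best
}

# all-pairs scan implementing the annotation-overlap rules directly on
# data frames, no interval index
oracle_annotation_verdict <- function(model, annotations, thresholds) {
  gap_to <- function(f_start, f_end) {
    # min gap between any exon [s,e) and feature [fs,fe); 0 when overlapping
    gaps <- vapply(seq_along(model$starts), function(k) {
      s <- model$starts[k]; e <- model$ends[k]
      if (f_start < e && f_end > s) return(0)
      if (f_start >= e) return(f_start - e)
      s - f_end
    }, numeric(1))
    min(gaps)
  }
  for (set_name in c("coding_exons", "pseudogene_exons")) {
    df <- annotations[[set_name]]
    status <- if (set_name == "coding_exons") "FAIL_CODING_OVERLAP"
              else "FAIL_PSEUDOGENE_OVERLAP"
    if (nrow(df)) {
      for (j in seq_len(nrow(df))) {
        if (df$chrom[j] != model$chrom || df$strand[j] != model$strand) next
        if (gap_to(df$start[j], df$end[j]) <= thresholds$flank_nt) {
          return(status)
        }
      }
    }
  }
  srna <- annotations$small_rna_genes
  if (nrow(srna)) {
    for (j in seq_len(nrow(srna))) {
      if (srna$chrom[j] != model$chrom || srna$strand[j] != model$strand) next
      ov <- sum(vapply(seq_along(model$starts), function(k) {
        max(0, min(model$ends[k], srna$end[j]) -
               max(model$starts[k], srna$start[j]))
      }, numeric(1)))
      if (ov / (srna$end[j] - srna$start[j]) >=
          thresholds$precursor_cover_frac) {
        return("FAIL_SMALLRNA_OVERLAP")
      }
    }
  }
  "PASS"
}

# BH step-up by direct enumeration: sort, q_i = min_{j>=i} p_(j) m / j
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    q_sorted[i] <- min(1, min(ps[i:m] * m / (i:m)))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# hypergeometric upper tail by exhaustive enumeration of all C(N, n) draws
oracle_hyper_tail <- function(k, K, n, N) {
  if (n == 0) return(as.numeric(k <= 0))
  draws <- utils::combn(N, n)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(d) sum(d %in% marked))
  mean(hits >= k)
}

# transitive closure of the same-strand exonic-overlap relation
oracle_gene_components <- function(models) {
  n <- length(models)
  adj <- diag(TRUE, n)
  overlaps <- function(a, b) {
    if (a$chrom != b$chrom || a$strand != b$strand) return(FALSE)
    for (i in seq_along(a$starts)) for (j in seq_along(b$starts)) {
      if (a$starts[i] < b$ends[j] && a$ends[i] > b$starts[j]) return(TRUE)
    }
    FALSE
  }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && overlaps(models[[i]], models[[j]])) {
      adj[i, j] <- adj[j, i] <- TRUE
    }
  }
  repeat {
    nxt <- (adj %*% adj) > 0
    if (identical(nxt, adj)) break
    adj <- nxt
  }
  membership <- integer(n)
  comp <- 0
  for (i in seq_len(n)) {
    if (membership[i] == 0) {
      comp <- comp + 1
      membership[which(adj[i, ])] <- comp
    }
  }
  membership
}

# random multi-exon transcript model on a toy genome
random_model <- function(id, chrom = "chr1", max_pos = 10000) {
  n_ex <- sample(1:4, 1)
  width <- sample(30:200, n_ex, replace = TRUE)
  gaps <- sample(10:300, n_ex, replace = TRUE)
  origin <- sample(0:max_pos, 1)
  starts <- origin + cumsum(c(0, (width + gaps)[-n_ex]))
  transcript_model(id, chrom, sample(c("+", "-"), 1), starts, starts + width)
}

random_sequence <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE), collapse = "")
}
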