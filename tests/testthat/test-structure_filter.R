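two_exon_model <- function(id, total_len, strand = "+", origin = 1000) {
  e1 <- total_len %/% 2
  transcript_model(id, "chr1", strand,
                   c(origin, origin + e1 + 100),
                   c(origin + e1, origin + total_len + 100))
}

test_that("length filter is strict at 200 nt and requires two exons", {
  th <- filter_thresholds()
  expect_equal(filter_length_exons(two_exon_model("a", 201), th)$status, "PASS")
  expect_equal(filter_length_exons(two_exon_model("b", 200), th)$status,
               "FAIL_LENGTH")
  single <- transcript_model("c", "chr1", "+", 0, 5000)
  expect_equal(filter_length_exons(single, th)$status, "FAIL_EXONS")
})

test_that("coding-exon proximity is strand-specific with an inclusive 50 nt flank", {
  th <- filter_thresholds()
  tx <- transcript_model("t", "chr1", "+", c(100, 400), c(300, 600))
  coding_at_gap <- function(gap, strand) {
    annotation_set(coding_exons = data.frame(
      chrom = "chr1", start = 600 + gap, end = 700 + gap, strand = strand,
      id = "cod1", stringsAsFactors = FALSE))
  }
  expect_equal(filter_known_annotation(tx, coding_at_gap(40, "+"), th)$status,
               "FAIL_CODING_OVERLAP")
  expect_equal(filter_known_annotation(tx, coding_at_gap(50, "+"), th)$status,
               "FAIL_CODING_OVERLAP")
  expect_equal(filter_known_annotation(tx, coding_at_gap(51, "+"), th)$status,
               "PASS")
  # identical geometry on the opposite strand never triggers (antisense kept)
  expect_equal(filter_known_annotation(tx, coding_at_gap(0, "-"), th)$status,
               "PASS")
  ann_overlap <- annotation_set(coding_exons = data.frame(
    chrom = "chr1", start = 250, end = 350, strand = "-", id = "cod2",
    stringsAsFactors = FALSE))
  expect_equal(filter_known_annotation(tx, ann_overlap, th)$status, "PASS")
})

test_that("pseudogene exons use the same flank rule with their own status", {
  th <- filter_thresholds()
  tx <- transcript_model("t", "chr1", "+", c(100, 400), c(300, 600))
  ann <- annotation_set(pseudogene_exons = data.frame(
    chrom = "chr1", start = 620, end = 700, strand = "+", id = "ps1",
    stringsAsFactors = FALSE))
  v <- filter_known_annotation(tx, ann, th)
  expect_equal(v$status, "FAIL_PSEUDOGENE_OVERLAP")
  expect_equal(v$evidence, "ps1")
})

test_that("small-RNA genes fail only at >= 80% coverage of the gene", {
  th <- filter_thresholds()
  # 80-nt precursor at 1000-1080; exon overlap controlled by exon end
  precursor <- function() data.frame(
    chrom = "chr1", start = 1000, end = 1080, strand = "+", id = "mir1",
    class = "miRNA_precursor", stringsAsFactors = FALSE)
  ann <- annotation_set(small_rna_genes = precursor())
  tx64 <- transcript_model("t64", "chr1", "+", c(500, 990), c(600, 1064))
  tx63 <- transcript_model("t63", "chr1", "+", c(500, 990), c(600, 1063))
  expect_equal(filter_known_annotation(tx64, ann, th)$status,
               "FAIL_SMALLRNA_OVERLAP")  # 64/80 = 80%
  expect_equal(filter_known_annotation(tx63, ann, th)$status, "PASS")
  # coverage is summed over exons but introns do not count
  tx_span <- transcript_model("ts", "chr1", "+", c(900, 1070), c(1010, 1200))
  # exonic overlap = 10 + 10 = 20 nt of 80 -> pass despite spanning the gene
  expect_equal(filter_known_annotation(tx_span, ann, th)$status, "PASS")
})

random_annotation <- function(n, max_pos = 20000) {
  cats <- sample(c("coding", "pseudo", "srna"), n, replace = TRUE,
                 prob = c(0.4, 0.3, 0.3))
  start <- sample(0:max_pos, n, replace = TRUE)
  width <- sample(20:150, n, replace = TRUE)
  df <- data.frame(
    chrom = "chr1", start = start, end = start + width,
    strand = sample(c("+", "-"), n, replace = TRUE),
    id = sprintf("f%d", seq_len(n)), stringsAsFactors = FALSE
  )
  srna <- df[cats == "srna", , drop = FALSE]
  if (nrow(srna))

    srna$class <- sample(c("miRNA_precursor", "miRNA", "tRNA", "rRNA",
                           "snRNA", "snoRNA"), nrow(srna), replace = TRUE)
  annotation_set(
    coding_exons = df[cats == "coding", , drop = FALSE],
    pseudogene_exons = df[cats == "pseudo", , drop = FALSE],
    small_rna_genes = srna
  )
}

test_that("interval-index verdicts match the brute-force all-pairs oracle", {
  set.seed(42)
  th <- filter_thresholds()
  ann <- random_annotation(300)
  for (i in 1:60) {
    tx <- random_model(sprintf("tx%d", i), max_pos = 20000)
    expect_equal(
      filter_known_annotation(tx, ann, th)$status,
      oracle_annotation_verdict(tx, ann, th),
      info = sprintf("transcript %d", i)
    )
  }
})

flip_strand <- function(x) chartr("+-", "-+", x)

test_that("verdicts are invariant under flipping every strand", {
  set.seed(7)
  th <- filter_thresholds()
  ann <- random_annotation(150)
  flipped <- annotation_set(
    coding_exons = transform(ann$coding_exons, strand = flip_strand(strand)),
    pseudogene_exons = transform(ann$pseudogene_exons,
                                 strand = flip_strand(strand)),
    small_rna_genes = transform(ann$small_rna_genes,
                                strand = flip_strand(strand))
  )
  for (i in 1:25) {
    tx <- random_model(sprintf("tx%d", i), max_pos = 20000)
    tx_flipped <- transcript_model(tx$transcript_id, tx$chrom,
                                   flip_strand(tx$strand), tx$starts, tx$ends)
    expect_equal(filter_known_annotation(tx, ann, th)$status,
                 filter_known_annotation(tx_flipped, flipped, th)$status)
  }
})

test_that("enlarging the flank never converts a FAIL into a PASS", {
  set.seed(13)
  ann <- random_annotation(150)
  for (i in 1:25) {
    tx <- random_model(sprintf("tx%d", i), max_pos = 20000)
    statuses <- vapply(c(10, 50, 120, 400), function(flank) {
      filter_known_annotation(tx, ann, filter_thresholds(flank_nt = flank))$status
    }, character(1))
    first_fail <- match(TRUE, statuses != "PASS")
    if (!is.na(first_fail) && first_fail < length(statuses)) {
      expect_true(all(statuses[first_fail:length(statuses)] != "PASS"))
    }
  }
})

test_that("annotation features on unrelated chromosomes are ignored", {
  th <- filter_thresholds()
  tx <- transcript_model("t", "chr1", "+", c(100, 400), c(300, 600))
  ann <- annotation_set(coding_exons = data.frame(
    chrom = "chr9", start = 100, end = 700, strand = "+", id = "other",
    stringsAsFactors = FALSE))
  expect_equal(filter_known_annotation(tx, ann, th)$status, "PASS")
})
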