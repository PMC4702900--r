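test_that("find_longest_orf handles the canonical small cases", {
  orf <- find_longest_orf("ATGAAATAG")
  expect_equal(orf$aa_length, 2L)
  expect_equal(orf$nt_length, 9L)
  expect_true(orf$has_stop)
  expect_equal(orf$frame, 0L)
  expect_equal(orf$nt_length / nchar("ATGAAATAG"), 1.0)

  expect_null(find_longest_orf("CCCCCC"))

  open <- find_longest_orf("ATGTTT")  # runs off the 3' end
  expect_equal(open$aa_length, 2L)
  expect_equal(open$nt_length, 6L)
  expect_false(open$has_stop)

  expect_error(find_longest_orf("AT"), "at least 3")
  expect_error(find_longest_orf("ATGXX"), "outside")
})

test_that("find_longest_orf agrees with exhaustive enumeration", {
  set.seed(99)
  for (i in 1:500) {
    s <- random_sequence(sample(3:300, 1))
    got <- find_longest_orf(s)
    want <- oracle_longest_orf(s)
    if (is.null(want)) {
      expect_null(got, info = s)
    } else {
      expect_equal(got[c("frame", "start_offset", "aa_length", "nt_length",
                         "has_stop")],
                   want[c("frame", "start_offset", "aa_length", "nt_length",
                          "has_stop")],
                   info = s)
    }
  }
})

test_that("surrogate CDS score is anchored, deterministic and monotone", {
  expect_equal(score_cds("CCCCCC", NULL), 0)
  s <- "GGGATGAAAAAATTTTAG"
  orf <- find_longest_orf(s)
  expect_identical(score_cds(s, orf), score_cds(s, orf))
  expect_gte(score_cds(s, orf), 0)
  expect_lte(score_cds(s, orf), 1000)

  # extending a fixture ORF by 30 codons strictly increases the score
  make_seq <- function(n_codons) {
    paste0("GCC", "ATG", strrep("GGC", n_codons), "TAA", "GCC")
  }
  for (n in c(5, 50, 150, 400)) {
    s1 <- make_seq(n)
    s2 <- make_seq(n + 30)
    sc1 <- score_cds(s1, find_longest_orf(s1))
    sc2 <- score_cds(s2, find_longest_orf(s2))
    expect_true(sc2 > sc1 || (sc1 == 1000 && sc2 == 1000),
                info = sprintf("n=%d: %f -> %f", n, sc1, sc2))
  }
})

test_that("absent or empty ORFs anchor the score at zero", {
  s <- "CCATGTAACC"  # ATG immediately followed by a stop: a bare methionine
  orf <- find_longest_orf(s)
  expect_equal(orf$aa_length, 1L)
  expect_lt(score_cds(s, orf), 100)
  # no ORF at all, and the degenerate 0-aa case, both score exactly zero
  expect_equal(score_cds(s, NULL), 0)
  expect_equal(score_cds(s, list(aa_length = 0L, has_stop = TRUE,
                                 start_offset = 2L)), 0)
})

# the published rules, restated directly from their printed form
published_class <- function(aa, cov, score) {
  if (aa < 100 && cov < 0.30 && score < 800) return("LNCRNA")
  if (cov >= 0.30 && cov <= 0.90 && score < 800) return("TUCP")
  if (score >= 800 || cov > 0.90) return("CODING_LIKE")
  "TUCP"  # unassigned corner (aa >= 100, cov < 30%, score < 800)
}

test_that("classification matches the decision table on the boundary grid", {
  for (aa in c(99, 100, 101)) {
    for (cov in c(0.29, 0.30, 0.90, 0.91)) {
      for (score in c(799, 800)) {
        expect_equal(
          classify_transcript(aa_length = aa, orf_coverage = cov,
                              cds_score = score),
          published_class(aa, cov, score),
          info = sprintf("aa=%d cov=%.2f score=%d", aa, cov, score)
        )
      }
    }
  }
})

test_that("classification worked examples", {
  expect_equal(classify_transcript(aa_length = 50, orf_coverage = 0.20,
                                   cds_score = 500), "LNCRNA")
  expect_equal(classify_transcript(aa_length = 150, orf_coverage = 0.45,
                                   cds_score = 700), "TUCP")
  expect_equal(classify_transcript(aa_length = 300, orf_coverage = 0.95,
                                   cds_score = 900), "CODING_LIKE")
})

test_that("crossing the 100-aa threshold alone flips LNCRNA to TUCP only", {
  below <- classify_transcript(aa_length = 99, orf_coverage = 0.20,
                               cds_score = 700)
  above <- classify_transcript(aa_length = 100, orf_coverage = 0.20,
                               cds_score = 700)
  expect_equal(below, "LNCRNA")
  expect_equal(above, "TUCP")  # adjacent class, never CODING_LIKE
})

test_that("classifier metrics reproduce direct arithmetic", {
  truth <- c(rep("positive", 10), rep("negative", 90))
  pred <- c(rep("positive", 7), rep("negative", 3), rep("negative", 90))
  m <- classifier_metrics(truth, pred)
  expect_equal(m$accuracy, 0.97)
  expect_equal(m$sensitivity, 0.70)
  expect_equal(m$specificity, 1.00)

  perfect <- classifier_metrics(truth, truth)
  expect_equal(perfect$accuracy, 1.0)
  expect_equal(perfect$sensitivity, 1.0)
  expect_equal(perfect$specificity, 1.0)

  no_pos <- classifier_metrics(rep("negative", 5), rep("negative", 5))
  expect_false(no_pos$sensitivity_defined)
  expect_true(is.na(no_pos$sensitivity))
  expect_true(no_pos$specificity_defined)

  expect_error(classifier_metrics(character(), character()), "empty")
  expect_error(classifier_metrics("positive", c("positive", "negative")),
               "equal length")
})

test_that("external CDS scores override the surrogate", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("tx1\t950", "tx2\t10"), path)
  scores <- read_cds_scores(path)
  expect_equal(unname(scores["tx1"]), 950)
  a <- assess_coding("CCATGGGCGGCTAACC", cds_score = scores[["tx1"]])
  expect_equal(a$cds_score, 950)
})
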