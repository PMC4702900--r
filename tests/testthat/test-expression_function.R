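test_that("FPKM follows its defining formula", {
  expect_equal(compute_fpkm(10, 1000, 1e6), 10.0)
  expect_equal(compute_fpkm(0, 1000, 1e6), 0.0)
  expect_equal(compute_fpkm(5, 500, 2e6), 5.0)
  expect_error(compute_fpkm(1, 0, 1e6), "length")
  expect_error(compute_fpkm(1, 100, 0), "total")
})

test_that("Pearson r and t-based p behave on canonical vectors", {
  expect_equal(pearson_r_p(1:4, 1:4)$r, 1)
  expect_equal(pearson_r_p(1:4, 1:4)$p, 0)
  expect_equal(pearson_r_p(c(1, 2, 3, 4), c(1, 3, 2, 4))$r, 0.8)
  expect_equal(pearson_r_p(c(1, 2, 3), c(6, 4, 2))$r, -1)

  flat <- pearson_r_p(c(1, 1, 1), c(1, 2, 3))
  expect_false(flat$defined)
  expect_true(is.na(flat$r))

  # cross-check p against the independent implementation in cor.test
  set.seed(4)
  for (i in 1:20) {
    x <- rnorm(sample(5:40, 1))
    y <- rnorm(length(x)) + 0.5 * x
    got <- pearson_r_p(x, y)
    ref <- stats::cor.test(x, y)
    expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
    expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  }

  # affine invariance of the coefficient's sign and magnitude
  x <- rnorm(10)
  expect_equal(pearson_r_p(x, 3 * x + 2)$r, 1)
  expect_equal(pearson_r_p(x, -0.5 * x + 1)$r, -1)
})

test_that("BH matches the step-up oracle; Bonferroni caps at one", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(0.37), 0.37)
  expect_equal(bonferroni(c(0.3, 0.01, 0.2, 0.5)),
               pmin(1, c(0.3, 0.01, 0.2, 0.5) * 4))
  expect_equal(bonferroni(0.3)[1], 0.3)
  expect_error(bh_fdr(c(0.5, 1.2)), "\\[0, 1\\]")

  set.seed(20)
  for (i in 1:100) {
    p <- runif(sample(1:40, 1))
    q <- bh_fdr(p)
    expect_equal(q, oracle_bh(p), tolerance = 1e-12)
    # permutation invariance
    perm <- sample(seq_along(p))
    expect_equal(bh_fdr(p[perm]), q[perm], tolerance = 1e-12)
    # monotone in rank: sorting p sorts q
    expect_true(all(diff(q[order(p)]) >= -1e-12))
  }
})

test_that("hypergeometric upper tail matches exhaustive enumeration", {
  expect_equal(hypergeom_upper_tail(0, 4, 3, 10), 1.0)
  expect_equal(hypergeom_upper_tail(2, 4, 3, 10), 1 / 3, tolerance = 1e-12)
  expect_equal(hypergeom_upper_tail(3, 10, 3, 10), 1.0)  # K = N forces k = n
  expect_error(hypergeom_upper_tail(4, 2, 3, 10), "require")

  for (N in c(5, 8, 10)) {
    for (n in c(1, 3, N)) {
      for (K in c(0, 2, N)) {
        for (k in 0:min(K, n)) {
          expect_equal(
            hypergeom_upper_tail(k, K, n, N),
            oracle_hyper_tail(k, K, n, N),
            tolerance = 1e-12,
            info = sprintf("k=%d K=%d n=%d N=%d", k, K, n, N)
          )
        }
      }
    }
  }
})

planted_matrix <- function(seed = 2, n_samples = 15) {
  set.seed(seed)
  base <- rlnorm(n_samples, 2, 1)
  rows <- rbind(
    lnc1 = base,
    pg1 = base * exp(rnorm(n_samples, 0, 0.05)),
    pg2 = base * exp(rnorm(n_samples, 0, 0.05)),
    pg3 = base * exp(rnorm(n_samples, 0, 0.05)),
    bg1 = rlnorm(n_samples, 2, 1),
    bg2 = rlnorm(n_samples, 2, 1),
    bg3 = rlnorm(n_samples, 2, 1)
  )
  colnames(rows) <- sprintf("s%d", seq_len(n_samples))
  rows
}

test_that("co-expression recovers planted partners and only them", {
  m <- planted_matrix()
  edges <- build_coexpression("lnc1", c("pg1", "pg2", "pg3",
                                        "bg1", "bg2", "bg3"), m)
  expect_setequal(edges$coding_id, c("pg1", "pg2", "pg3"))
  expect_true(all(edges$q < 0.05))
  expect_true(all(abs(edges$r) >= 0.7))
  # per-pair agreement with the direct computation
  for (k in seq_len(nrow(edges))) {
    direct <- pearson_r_p(m["lnc1", ], m[edges$coding_id[k], ])
    expect_equal(edges$r[k], direct$r, tolerance = 1e-12)
    expect_equal(edges$p[k], direct$p, tolerance = 1e-12)
  }

  expect_equal(nrow(build_coexpression("lnc1", c("pg1", "bg1"), m,
                                       r_threshold = 1.01)), 0)

  single <- build_coexpression("lnc1", "pg1", m, q_threshold = 1.1,
                               r_threshold = 0)
  expect_equal(single$q, single$p)  # BH on a single test is the identity

  const <- rbind(m, flatrow = rep(3, ncol(m)))
  expect_warning(build_coexpression("lnc1", c("pg1", "flatrow"), const),
                 "constant")
})

test_that("GO enrichment ranks a planted term first and handles edge cases", {
  population <- sprintf("g%03d", 1:200)
  partners <- population[1:12]
  # 10 of 12 partners carry T; background frequency 20/200
  with_term <- c(partners[1:10], population[101:110])
  go <- rbind(
    data.frame(gene_id = with_term, go_term = "GO:T",
               stringsAsFactors = FALSE),
    data.frame(gene_id = population, go_term = "GO:COMMON",
               stringsAsFactors = FALSE),
    data.frame(gene_id = population[51:150], go_term = "GO:OTHER",
               stringsAsFactors = FALSE)
  )
  res <- go_enrichment(partners, go, population)
  expect_equal(res$go_term[1], "GO:T")
  t_row <- res[res$go_term == "GO:T", ]
  expect_equal(t_row$k, 10)
  expect_equal(t_row$K, 20)
  expect_equal(t_row$n, 12)
  expect_equal(t_row$N, 200)
  expect_equal(t_row$p, hypergeom_upper_tail(10, 20, 12, 200))
  expect_equal(t_row$p_bonferroni, min(1, t_row$p * nrow(res)))

  # a term annotating everyone is never significant
  common <- res[res$go_term == "GO:COMMON", ]
  expect_equal(common$p, 1)

  # partner set = population: every term has p = 1
  all_res <- go_enrichment(population, go, population)
  expect_true(all(all_res$p == 1))

  expect_warning(empty <- go_enrichment(character(), go, population), "empty")
  expect_equal(nrow(empty), 0)
  expect_error(go_enrichment("not_in_pop", go, population), "subset")
})

test_that("read counting requires strand-matched full containment", {
  genes <- data.frame(
    chrom = "chr1", start = c(50, 500), end = c(200, 700),
    strand = c("+", "-"), id = c("gA", "gB"), stringsAsFactors = FALSE
  )
  reads <- data.frame(
    chrom = "chr1",
    start = c(100, 190, 550, 550, 100),
    end = c(120, 210, 600, 600, 120),
    strand = c("+", "+", "-", "+", "-"),
    stringsAsFactors = FALSE
  )
  counts <- assign_reads_to_genes(reads, genes)
  # read 1: inside gA, same strand -> counted
  # read 2: overhangs gA end 200 -> not counted
  # read 3: inside gB, same strand; read 4: inside gB, wrong strand
  # read 5: inside gA span, wrong strand
  expect_equal(unname(counts["gA"]), 1L)
  expect_equal(unname(counts["gB"]), 1L)

  # brute-force strand-specific containment oracle on random intervals
  set.seed(14)
  genes2 <- data.frame(
    chrom = "chr1", start = seq(0, 900, by = 100),
    end = seq(0, 900, by = 100) + sample(40:90, 10, replace = TRUE),
    strand = sample(c("+", "-"), 10, replace = TRUE),
    id = sprintf("g%d", 1:10), stringsAsFactors = FALSE
  )
  rs <- sample(0:950, 200, replace = TRUE)
  reads2 <- data.frame(
    chrom = "chr1", start = rs, end = rs + sample(10:60, 200, replace = TRUE),
    strand = sample(c("+", "-"), 200, replace = TRUE),
    stringsAsFactors = FALSE
  )
  got <- assign_reads_to_genes(reads2, genes2)
  for (j in seq_len(nrow(genes2))) {
    manual <- sum(
      reads2$start >= genes2$start[j] & reads2$end <= genes2$end[j] &
      reads2$strand == genes2$strand[j]
    )
    expect_equal(unname(got[genes2$id[j]]), manual, info = genes2$id[j])
  }

  # a read inside two nested genes counts once per gene
  nested <- data.frame(
    chrom = "chr1", start = c(0, 10), end = c(100, 50), strand = "+",
    id = c("outer", "inner"), stringsAsFactors = FALSE
  )
  one <- data.frame(chrom = "chr1", start = 20, end = 40, strand = "+",
                    stringsAsFactors = FALSE)
  both <- assign_reads_to_genes(one, nested)
  expect_equal(unname(both), c(1L, 1L))
})
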