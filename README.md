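# lncseekr

Identification, naming, conservation and functional annotation of long
non-coding RNAs (lncRNAs) from assembled transcript models.

## What it does and for whom

Transcriptome assemblies mix real lncRNAs with mRNAs, gene fragments and
assembly noise. `lncseekr` is for researchers building lncRNA catalogues from
such assemblies. It implements the standard elimination cascade:

1. **Structure** — keep multi-exonic transcripts with spliced length
   strictly > 200 nt.
2. **Known annotation** — drop transcripts whose exons overlap, or lie within
   50 nt of, same-strand coding or pseudogene exons, or whose exons cover
   ≥ 80% of a same-strand small-RNA gene. Strand-specific throughout, so
   antisense lncRNAs are retained.
3. **Coding potential** — from the spliced sequence, compute the longest
   forward-frame ORF, its coverage c = ORF nt / transcript nt, and a CDS
   score s ∈ [0, 1000]. Classify:
   * lncRNA iff ORF < 100 aa **and** c < 30% **and** s < 800
   * TUCP (transcript of uncertain coding potential) iff
     30% ≤ c ≤ 90% **and** s < 800
   * coding-like otherwise (s ≥ 800 or c > 90%)
4. **Protein similarity** — remove candidates with a BLASTX hit at
   E < 1e-30, or a single Pfam hit with full-sequence **and** best-domain
   E < 1e-5 (tabular BLAST/HMMER outputs are consumed; the tools run
   externally).

Survivors are clustered into loci (same-strand exonic overlap, transitive)
and named `<sp>-lncRNA<gene>-<tx>`, e.g. `hsa-lncRNA10932-8` = 8th transcript
of gene lncRNA10932 in human. Cross-species conservation is called as the
lowest-E-value best hit per query and species, with lineage labels
(species-specific / clade-specific / conserved). Function is predicted by
guilt-by-association: Pearson correlation r between the target lncRNA and
coding genes, two-sided p from t = r·√((n−2)/(1−r²)), Benjamini–Hochberg over
all pairs (edges at q < 0.05, |r| ≥ 0.7), then upper-tail hypergeometric GO
enrichment of the partners with Bonferroni and BH corrections.

A seeded synthetic-fixture generator (`generate_fixture()`) plants
transcripts of every class by explicit codon construction, plus hit tables,
an expression matrix with a planted co-expression block and a planted GO
signal, so the whole pipeline runs and is tested without any external data.

See `vignettes/lncrna-identification.Rmd` for the methods and design
rationale.

## Worked example

```r
library(lncseekr)

fx <- generate_fixture(fixture_spec(seed = 1), file.path(tempdir(), "fx"))
res <- run_identify(fx$paths$transcripts, fx$paths$genome,
                    fx$paths$annotations,
                    blastx_hits = fx$paths$blastx,
                    pfam_hits = fx$paths$pfam)
table(res$report$status)
#>           CODING_LIKE   FAIL_CODING_OVERLAP FAIL_SMALLRNA_OVERLAP
#>                     5                     2                     1
#>                LNCRNA        REMOVED_BLASTX          REMOVED_PFAM
#>                     8                     1                     1
#>                  TUCP
#>                     3
```

Every transcript keeps the verdict of the stage that decided its fate:
5 planted coding transcripts are called coding-like at stage 3, the
stage-2 positives fail on annotation overlap, the domain-evidence plants are
removed at stage 4, and the 5 planted lncRNAs plus 3 antisense plants
survive as lncRNAs. Survivors carry ORF metrics and names:

```r
head(res$report[res$report$status == "LNCRNA",
     c("transcript_id", "length", "aa_length", "orf_coverage",
       "cds_score", "name")], 4)
#>   transcript_id length aa_length orf_coverage cds_score          name
#> 6  TX006_lncRNA    400        10       0.0825       136 hsa-lncRNA1-1
#> 7  TX007_lncRNA    400        10       0.0825       136 hsa-lncRNA2-1
#> 8  TX008_lncRNA    400        10       0.0825       136 hsa-lncRNA3-1
#> 9  TX009_lncRNA    400        10       0.0825       136 hsa-lncRNA4-1
```

(10-aa ORF over a 400-nt transcript: coverage 33/400 = 0.0825, CDS score 136,
well under every threshold.) Function prediction for the planted target:

```r
fn <- run_function(fx$target_lnc, fx$paths$expression, fx$paths$go)
head(fn$enrichment[, c("go_term", "k", "K", "n", "N", "p", "q")], 3)
#>      go_term  k  K  n  N        p        q
#> 1 GO:0006412 10 14 10 50 9.74e-08 1.07e-06
#> 2 GO:0000005  4  7 10 50 2.28e-02 1.26e-01
#> 3 GO:0000009  1  2 10 50 3.63e-01 9.99e-01
```

All 10 co-expression partners carry the planted term `GO:0006412` (10 of its
14 carriers among the 50 annotated genes), which ranks first at
q ≈ 1e-6.

A thin command-line front end over the same functions ships at
`inst/cli/lncseeker.R` with subcommands `fixtures`, `convert`, `identify`,
`name`, `conserve`, `function`; every threshold is a flag.

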