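test_that("intergenic gap is start-to-end distance floored at zero", {
  g <- gene_table("c", c(1, 1001, 1200), c(1000, 1100, 1500),
                  list(NA, NA, NA))
  expect_equal(intergenic_gap(g[1, ], g[3, ]), 199)  # ends 1000, starts 1200
  expect_equal(intergenic_gap(g[1, ], g[2, ]), 0)    # book-ended
  ov <- gene_table("c", c(1, 400), c(500, 900), list(NA, NA))
  expect_equal(intergenic_gap(ov[1, ], ov[2, ]), 0)  # overlap floors at 0
  other <- gene_table("d", 1, 100, list(NA))
  expect_error(intergenic_gap(g[1, ], other), "different contigs")
})

test_that("the three clustering rules are enforced on hand-traced layouts", {
  # two PUP genes, one gene between, gaps 199 and 99: a valid cluster
  g <- gene_table("c", c(100, 1200, 1600), c(1000, 1500, 2400),
                  list("FR1", NA, "HR1"))
  pg <- detect_pgcs(g)
  expect_equal(nrow(pg), 1)
  expect_equal(pg$n_pup, 2)
  expect_equal(pg$n_other, 1)
  expect_equal(pg$start, 100)
  expect_equal(pg$end, 2400)

  # four genes between two PUP genes: rule (ii) violated
  starts <- c(100, 1200, 1700, 2200, 2700, 3200)
  ends <- starts + 300
  g2 <- gene_table("c", starts, ends, list("FR1", NA, NA, NA, NA, "HR1"))
  expect_equal(nrow(detect_pgcs(g2)), 0)

  # adjacent PUP genes with a 1,099 bp gap: rule (iii) violated
  g3 <- gene_table("c", c(100, 2100), c(1000, 2900), list("FR1", "HR1"))
  expect_equal(nrow(detect_pgcs(g3)), 0)
  # at 999 bp the same pair clusters
  g4 <- gene_table("c", c(100, 2000), c(1000, 2900), list("FR1", "HR1"))
  expect_equal(nrow(detect_pgcs(g4)), 1)
})

test_that("clusters are trimmed to PUP boundaries and PUP genes used once", {
  # non-PUP genes flank a valid pair: excluded from the cluster span
  g <- gene_table("c", c(100, 600, 1100, 1600), c(500, 1000, 1500, 2000),
                  list(NA, "FR1", "HR1", NA))
  pg <- detect_pgcs(g)
  expect_equal(pg$start, 600)
  expect_equal(pg$end, 1500)
  expect_equal(pg$n_genes, 2)
  # a chain of three linkable PUPs is one maximal cluster, not two
  g2 <- gene_table("c", c(100, 700, 1300), c(600, 1200, 1800),
                   list("FR1", "HR1", "OR6"))
  pg2 <- detect_pgcs(g2)
  expect_equal(nrow(pg2), 1)
  expect_equal(pg2$n_pup, 3)
})

test_that("detection agrees exactly with the window-enumeration oracle", {
  set.seed(42)
  for (rep in 1:200) {
    g <- random_gene_table(sample(2:50, 1))
    expect_identical(as_pgc_keys(detect_pgcs(g)),
                     oracle_keys(oracle_pgcs(g)))
  }
})

test_that("raising the thresholds never drops PUP genes out of clusters", {
  set.seed(7)
  for (rep in 1:50) {
    g <- random_gene_table(40)
    base <- sum(detect_pgcs(g)$n_pup)
    expect_gte(sum(detect_pgcs(g, max_gap_bp = 2000)$n_pup), base)
    expect_gte(sum(detect_pgcs(g, max_between = 5)$n_pup), base)
  }
})

test_that("detection is invariant to whole-contig coordinate translation", {
  set.seed(11)
  g <- random_gene_table(40)
  shifted <- g
  shifted$start <- g$start + 50000L
  shifted$end <- g$end + 50000L
  a <- detect_pgcs(g); b <- detect_pgcs(shifted)
  expect_equal(nrow(a), nrow(b))
  expect_identical(a$gene_ids, b$gene_ids)
})

test_that("substrate vote: unanimity, majority, and ties returned together", {
  cat_ <- mini_catalog()   # FR1 daidzin, HR1 luteolin, OR6 genistein
  mk <- function(fams) {
    n <- length(fams)
    g <- gene_table("c", seq(100, by = 700, length.out = n),
                    seq(700, by = 700, length.out = n), as.list(fams))
    list(genes = g)
  }
  expect_equal(infer_substrates(mk(c("OR6", "OR6")), cat_), "genistein")
  expect_equal(infer_substrates(mk(c("FR1", "FR1", "HR1")), cat_), "daidzin")
  expect_equal(infer_substrates(mk(c("FR1", "HR1")), cat_),
               c("daidzin", "luteolin"))
})

test_that("a multi-family gene votes once per distinct substrate", {
  cat_ <- mini_catalog()
  g <- gene_table("c", c(100, 900), c(800, 1600),
                  list(c("FR1", "UC1"), "HR1"))  # both FR1 and UC1: daidzin
  expect_equal(infer_substrates(list(genes = g), cat_),
               c("daidzin", "luteolin"))
})

test_that("genes from substrate-less families are excluded with a warning", {
  fam <- data.frame(family_id = c("FR1", "HR1"), enzyme_class = c("FR", "HR"),
                    n_seeds = c(1L, 1L), stringsAsFactors = FALSE)
  fam$signature_domains <- list("A", "B")
  fam$substrates <- list("daidzin", character(0))
  cat_ <- pup_catalog(fam)
  g <- gene_table("c", c(100, 900), c(800, 1600), list("FR1", "HR1"))
  expect_warning(s <- infer_substrates(list(genes = g), cat_), "excluded")
  expect_equal(s, "daidzin")
})

test_that("PGC summaries histogram sizes and substrates", {
  g1 <- gene_table("c", c(100, 900), c(800, 1600), list("FR1", "HR1"))
  g2 <- gene_table("c", c(5000, 5700, 6400), c(5600, 6300, 7000),
                   list("FR1", NA, "FR1"))
  pg <- detect_pgcs(rbind(g1, g2))
  s <- pgc_summary(pg)
  expect_equal(as.integer(s$size_histogram[c("2", "3")]), c(1L, 1L))
  expect_equal(s$n_pgcs, 2L)
  e <- pgc_summary(detect_pgcs(gene_table("c", 1, 10, list(NA))))
  expect_equal(e$n_pgcs, 0L)
  # a cluster of 4 PUP + 4 other genes lands in the size-8 bin, pup fraction 0.5
  starts <- seq(100, by = 700, length.out = 8)
  fams <- list("FR1", NA, "HR1", NA, "OR6", NA, "FR1", NA)
  # trailing non-PUP would be trimmed; swap so boundaries are PUPs
  fams <- list("FR1", NA, "HR1", NA, "OR6", NA, NA, "FR1")
  g3 <- gene_table("c", starts, starts + 600, fams)
  s3 <- pgc_summary(detect_pgcs(g3))
  expect_equal(names(s3$size_histogram), "8")
  expect_equal(s3$pup_fraction, 0.5)
})

test_that("GFF gene models load sorted and linked to annotations", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "c1\tsrc\tCDS\t900\t1600\t.\t+\t0\tID=gB",
               "c1\tsrc\tCDS\t100\t800\t.\t-\t0\tID=gA",
               "c2\tsrc\tCDS\t10\t500\t.\t+\t0\tID=gC"), gff)
  ann <- data.frame(protein_id = "gB", family_id = "FR1",
                    evidence = "signature_domains", stringsAsFactors = FALSE)
  genes <- load_gene_features(gff, ann)
  expect_equal(genes$gene_id, c("gA", "gB", "gC"))   # sorted despite input order
  expect_equal(genes$is_pup, c(FALSE, TRUE, FALSE))
  expect_equal(genes$family_ids[[2]], "FR1")
})

test_that("PGC tables export to TSV and BED with coordinate conversion", {
  g <- gene_table("c", c(100, 900), c(800, 1600), list("FR1", "HR1"))
  pg <- detect_pgcs(g)
  pg$substrates <- list(c("daidzin"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_pgc_tsv(pg, tsv)
  write_pgc_bed(pg, bed)
  row <- read.delim(tsv)
  expect_equal(row$gene_ids, "g001+g002")
  expect_equal(row$substrates, "daidzin")
  b <- read.delim(bed, header = FALSE)
  expect_equal(b$V2, 99)    # 0-based half-open start
  expect_equal(b$V3, 1600)
})
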