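make_profiles <- function() {
  data.frame(
    genome_id = sprintf("G%02d", 1:8),
    n_proteins = c(4000, 2600, 3000, 3000, 2000, 2500, 1800, 2200),
    n_pup = c(8, 26, 0, 3, 2, 0, 5, 1),
    n_pgc_genes = c(0, 26, 0, 2, 0, 0, 4, 0),
    lineage = c(rep("d__Bacteria;p__Firmicutes;c__Bacilli", 4),
                rep("d__Bacteria;p__Actinobacteriota;c__Coriobacteriia", 4)),
    continent = c("Africa", "Africa", "Europe", "Europe",
                  "Africa", "Europe", "Europe", ""),
    stringsAsFactors = FALSE
  )
}

test_that("genome abundance is percent of proteins, by either numerator", {
  p <- make_profiles()
  expect_equal(genome_abundance(p, "pup")[1], 0.2)       # 8 / 4000
  expect_equal(genome_abundance(p, "pgc_genes")[2], 1.0) # 26 / 2600
  expect_equal(genome_abundance(p, "pup")[3], 0)
  expect_true(all(genome_abundance(p, "pup") >= 0 &
                  genome_abundance(p, "pup") <= 100))
  bad <- p; bad$n_proteins[1] <- 0
  expect_error(genome_abundance(bad, "pup"), "positive")
})

test_that("prevalence counts genomes with at least one indicator gene", {
  p <- make_profiles()
  prev <- group_prevalence(p, "phylum", "pup")
  firm <- prev[prev$group == "Firmicutes", ]
  expect_equal(firm$n_genomes, 4L)
  expect_equal(firm$prevalence_pct, 75)        # 3 of 4 genomes
  actino <- prev[prev$group == "Actinobacteriota", ]
  expect_equal(actino$prevalence_pct, 75)
  byc <- group_prevalence(p, "continent", "pgc_genes")
  expect_equal(byc$prevalence_pct[byc$group == "Africa"], 100 * 1 / 3)
  expect_true("unknown" %in% byc$group)        # empty continent grouped
  expect_equal(sum(byc$n_genomes), nrow(p))
  expect_equal(nrow(group_prevalence(p[0, ], "phylum", "pup")), 0)
})

test_that("bubble table medians, counts and competition ranks", {
  p <- data.frame(
    genome_id = sprintf("G%d", 1:5),
    n_proteins = 1000, n_pup = c(1, 3, 2, 2, 2), n_pgc_genes = 0,
    lineage = "d__B;p__Phy1",
    continent = c("Africa", "Africa", "Europe", "Asia", ""),
    stringsAsFactors = FALSE
  )
  tab <- median_bubble_table(p, "pup")
  # Africa median of {0.1, 0.3} = 0.2; Europe 0.2; Asia 0.2: three-way tie
  expect_equal(tab$median_pct, rep(0.2, 3))
  expect_equal(tab$rank, rep(1L, 3))           # minimum (competition) rank
  expect_equal(tab$n_genomes[tab$continent == "Africa"], 2L)
  expect_equal(unique(tab$n_total), 5L)        # unknown continent still counted
  one <- median_bubble_table(p[1, ], "pup")
  expect_equal(one$median_pct, 0.1)
  expect_equal(one$rank, 1L)
})

test_that("medians lie between group extremes and sizes sum correctly", {
  set.seed(31)
  p <- data.frame(
    genome_id = sprintf("G%03d", 1:60),
    n_proteins = sample(1500:4000, 60, replace = TRUE),
    n_pup = rpois(60, 4), n_pgc_genes = 0,
    lineage = paste0("d__B;p__", sample(c("P1", "P2", "P3"), 60, TRUE)),
    continent = sample(c("Africa", "Asia", "Europe"), 60, TRUE),
    stringsAsFactors = FALSE
  )
  tab <- median_bubble_table(p, "pup")
  pct <- genome_abundance(p, "pup")
  phy <- lineage_rank(p$lineage, "p")
  for (i in seq_len(nrow(tab))) {
    grp <- pct[phy == tab$phylum[i] & p$continent == tab$continent[i]]
    expect_gte(tab$median_pct[i], min(grp))
    expect_lte(tab$median_pct[i], max(grp))
  }
  expect_equal(sum(tab$n_genomes), 60L)
})

test_that("hypergeometric upper tail matches hand-enumerated example", {
  expect_equal(hyper_upper_tail(4, K = 5, n = 6, N = 20), 540 / 38760,
               tolerance = 1e-12)
  expect_equal(hyper_upper_tail(0, K = 5, n = 6, N = 20), 1)
  expect_equal(hyper_upper_tail(5, K = 5, n = 20, N = 20), 1)  # fg == bg
  # non-increasing in k
  ps <- hyper_upper_tail(0:5, K = 5, n = 6, N = 20)
  expect_true(all(diff(ps) <= 0))
})

test_that("domain enrichment counts per protein and orders by occurrence", {
  bg <- c(
    setNames(rep(list("DomX"), 5), sprintf("b%d", 1:5)),
    setNames(rep(list(c("DomY", "DomY")), 8), sprintf("c%d", 1:8)),
    setNames(rep(list("DomZ"), 7), sprintf("d%d", 1:7))
  )
  fg <- bg[c("b1", "b2", "b3", "b4", "c1", "d1")]
  res <- enrich_domains(fg, bg)
  expect_equal(res$domain_name[1], "DomX")       # top occurrence first
  x <- res[res$domain_name == "DomX", ]
  expect_equal(x$fg_count, 4L)                   # duplicates count once
  expect_equal(x$bg_count, 5L)
  expect_equal(x$fg_size, 6L)
  expect_equal(x$bg_size, 20L)
  expect_equal(x$p_value, 540 / 38760, tolerance = 1e-12)
  expect_true(all(res$p_adjusted >= res$p_value))
  expect_error(enrich_domains(list(zz = "DomX"), bg), "subset")
})

test_that("lineage rank parsing handles missing ranks", {
  expect_equal(lineage_rank("d__Bacteria;p__Firmicutes;c__Bacilli"),
               "Firmicutes")
  expect_equal(lineage_rank("d__Bacteria"), "unknown")
  expect_equal(lineage_rank("d__Bacteria;p__Firmicutes", rank = "d"),
               "Bacteria")
})
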