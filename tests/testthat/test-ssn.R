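test_that("edge loading collapses duplicate pairs and drops self-hits", {
  df <- data.frame(query = c("A", "B", "A"), subject = c("B", "A", "A"),
                   evalue = c(1e-10, 1e-12, 0), stringsAsFactors = FALSE)
  ed <- load_edges(df)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$evalue, 1e-12)  # best E of the unordered pair
  expect_equal(c(ed$a, ed$b), c("A", "B"))
  empty <- load_edges(data.frame(query = character(0),
                                 subject = character(0),
                                 evalue = numeric(0)))
  expect_equal(nrow(empty), 0)
  bad <- data.frame(query = "A", subject = "B", evalue = -1)
  expect_error(load_edges(bad), "negative")
})

test_that("12-column tabular search reports load through columns 1, 2, 11", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("A", "B", 98.5, 100, 1, 0, 1, 100, 1, 100, "1e-50", 200,
                   sep = "\t"), f)
  ed <- load_edges(f)
  expect_equal(nrow(ed), 1)
  expect_equal(ed$evalue, 1e-50)
})

test_that("thresholding keeps strict-below edges but all nodes", {
  ed <- load_edges(data.frame(query = c("A", "C"), subject = c("B", "D"),
                              evalue = c(1e-3, 1e-181)))
  g <- threshold_network(ed, 1e-5)
  expect_setequal(igraph::V(g)$name, c("A", "B", "C", "D"))
  expect_equal(igraph::ecount(g), 1)    # only the 1e-181 edge survives
  g2 <- threshold_network(ed, 1e-180)
  expect_equal(igraph::ecount(g2), 1)   # 1e-181 beats even a 1e-180 cutoff
})

test_that("subfamily calling enforces the 10-member floor", {
  s <- simulate_ssn(c(12, 12), rng_seed = 1)
  g <- threshold_network(load_edges(s$edges), 1e-5)
  sub <- call_subfamilies(g, "HR8")
  expect_equal(nrow(sub), 2)
  expect_equal(sub$size, c(12L, 12L))
  expect_equal(sub$subfamily_id, c("HR8_1", "HR8_2"))

  s9 <- simulate_ssn(9, rng_seed = 2)
  g9 <- threshold_network(load_edges(s9$edges), 1e-5)
  expect_equal(nrow(call_subfamilies(g9, "HR8")), 0)
})

test_that("component vs 2-core modes differ on a path graph", {
  path_edges <- data.frame(query = sprintf("n%02d", 1:11),
                           subject = sprintf("n%02d", 2:12),
                           evalue = 1e-50)
  g <- threshold_network(load_edges(path_edges), 1e-5)
  expect_equal(nrow(call_subfamilies(g, "X", mode = "component")), 1)
  expect_equal(nrow(call_subfamilies(g, "X", mode = "kcore")), 0)
})

test_that("planted blocks are recovered exactly and tagged for seeds", {
  s <- simulate_ssn(c(15, 12, 10), rng_seed = 5)
  g <- threshold_network(load_edges(s$edges), 1e-5)
  sub <- call_subfamilies(g, "OR3", seed_ids = s$blocks[[2]][1])
  expect_equal(nrow(sub), 3)
  got <- lapply(sub$members, sort)
  want <- lapply(s$blocks, sort)
  expect_true(all(vapply(want, function(b)
    any(vapply(got, identical, logical(1), b)), logical(1))))
  expect_equal(sum(sub$contains_seed), 1)
  expect_equal(sub$size, c(15L, 12L, 10L))  # numbered by decreasing size
})

test_that("subfamily membership partitions a subset of the nodes", {
  s <- simulate_ssn(c(11, 14, 6), rng_seed = 9)
  g <- threshold_network(load_edges(s$edges), 1e-5)
  sub <- call_subfamilies(g, "F")
  members <- unlist(sub$members)
  expect_equal(anyDuplicated(members), 0)
  expect_lte(length(members), igraph::vcount(g))
})

test_that("subfamily numbering is invariant to node input order", {
  s <- simulate_ssn(c(12, 11), rng_seed = 3)
  ed <- s$edges
  perm <- ed[sample(nrow(ed)), ]
  g1 <- threshold_network(load_edges(ed), 1e-5)
  g2 <- threshold_network(load_edges(perm), 1e-5)
  s1 <- call_subfamilies(g1, "F")
  s2 <- call_subfamilies(g2, "F")
  expect_identical(s1$subfamily_id, s2$subfamily_id)
  expect_identical(s1$members, s2$members)
})

test_that("more stringent cutoffs never merge separate subfamilies", {
  s <- simulate_ssn(c(12, 12), within_e = 1e-40, between_e = 1e-10,
                    rng_seed = 4)
  ed <- load_edges(s$edges)
  loose <- call_subfamilies(threshold_network(ed, 1e-5), "F")    # merged
  strict <- call_subfamilies(threshold_network(ed, 1e-20), "F")  # split
  expect_equal(nrow(loose), 1)
  expect_equal(nrow(strict), 2)
  # every strict subfamily is inside one loose subfamily
  for (m in strict$members) {
    expect_true(any(vapply(loose$members, function(L) all(m %in% L),
                           logical(1))))
  }
})

test_that("networks export to GraphML and edge TSV round-trips", {
  s <- simulate_ssn(c(12), rng_seed = 6)
  ed <- load_edges(s$edges)
  g <- threshold_network(ed, 1e-5)
  sub <- call_subfamilies(g, "F")
  gm <- withr::local_tempfile(fileext = ".graphml")
  export_network(g, sub, gm, format = "graphml", seed_ids = s$blocks[[1]][1])
  back <- igraph::read_graph(gm, format = "graphml")
  expect_equal(igraph::vcount(back), 12)
  expect_true("subfamily_id" %in% igraph::vertex_attr_names(back))

  et <- withr::local_tempfile(fileext = ".tsv")
  export_network(g, sub, et, format = "edge_tsv")
  ed2 <- load_edges(et)
  expect_equal(ed2[order(ed2$a, ed2$b), ], ed[order(ed$a, ed$b), ],
               tolerance = 1e-12)
})
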