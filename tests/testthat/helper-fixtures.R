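# Fixtures built in code: a miniature catalog with real substrate names,
# domain-hit rows in the per-domain tabular dialect, gene layouts, and the
# independent brute-force oracles used to cross-check the implementation.

# catalog of 4 families with known substrates (labels the source text uses)
mini_catalog <- function() {
  fam <- data.frame(
    family_id = c("FR1", "HR1", "OR6", "UC1"),
    enzyme_class = c("FR", "HR", "OR", "UC"),
    n_seeds = c(3L, 3L, 1L, 1L),
    stringsAsFactors = FALSE
  )
  fam$signature_domains <- list("Alpha-amylase", "Glyco_hydro_1",
                                c("HpaB", "HpaB_N"), character(0))
  fam$substrates <- list("daidzin", "luteolin", "genistein", "daidzin")
  pup_catalog(fam)
}

empty_hits <- function() parse_domain_hits(text = character(0))

# one per-domain table row (23 whitespace-separated fields)
domtbl_row <- function(domain, protein, evalue, hmm_len, hmm_from, hmm_to,
                       ali_from = hmm_from, ali_to = hmm_to) {
  sprintf("%s - %d %s - %d %.2e 100.0 0.1 1 1 %.2e %.2e 95.0 0.1 %d %d %d %d %d %d 0.95 -",
          domain, hmm_len, protein, ali_to + 20L, evalue, evalue / 10,
          evalue, hmm_from, hmm_to, ali_from, ali_to, ali_from, ali_to)
}

# a gene table as load_gene_features would produce it
gene_table <- function(contig, starts, ends, families) {
  stopifnot(length(starts) == length(ends), length(ends) == length(families))
  g <- data.frame(
    gene_id = sprintf("g%03d", seq_along(starts)),
    contig = contig, start = as.integer(starts), end = as.integer(ends),
    strand = ".", stringsAsFactors = FALSE
  )
  g$family_ids <- lapply(families, function(f) if (is.na(f[1])) character(0)
                         else as.character(f))
  g$is_pup <- lengths(g$family_ids) > 0
  g
}

# brute-force PGC oracle: enumerate every window bounded by PUP genes, test
# the three rules directly, keep maximal valid windows
oracle_pgcs <- function(genes, max_between = 3, max_gap_bp = 1000) {
  out <- list()
  for (g in split(genes, genes$contig)) {
    g <- g[order(g$start, g$end, g$gene_id), , drop = FALSE]
    pup <- which(g$is_pup)
    valid <- list()
    for (i in pup) for (j in pup[pup > i]) {
      w <- i:j
      wp <- pup[pup >= i & pup <= j]
      if (length(wp) < 2) next
      ok <- TRUE
      for (k in seq_len(length(wp) - 1)) {
        if (wp[k + 1] - wp[k] - 1 > max_between) { ok <- FALSE; break }
      }
      if (ok) {
        gaps <- g$start[w[-1]] - g$end[w[-length(w)]] - 1
        if (any(pmax(0, gaps) >= max_gap_bp)) ok <- FALSE
      }
      if (ok) valid[[length(valid) + 1]] <- c(i, j)
    }
    if (length(valid) > 0) {
      keep <- vapply(valid, function(v) {
        !any(vapply(valid, function(u)
          (u[1] <= v[1] && v[2] <= u[2]) && !identical(u, v), logical(1)))
      }, logical(1))
      for (v in valid[keep]) {
        out[[length(out) + 1]] <- data.frame(
          contig = g$contig[1],
          first_gene = g$gene_id[v[1]], last_gene = g$gene_id[v[2]],
          stringsAsFactors = FALSE)
      }
    }
  }
  if (length(out) == 0) return(data.frame(contig = character(0),
                                          first_gene = character(0),
                                          last_gene = character(0)))
  res <- do.call(rbind, out)
  res[order(res$contig, res$first_gene), , drop = FALSE]
}

# random contig layout for the oracle comparison
random_gene_table <- function(n_genes, pup_prob = 0.35) {
  lens <- sample(200:1500, n_genes, replace = TRUE)
  gaps <- sample(0:1500, n_genes, replace = TRUE)
  starts <- cumsum(gaps + c(0, lens[-n_genes]))
  is_pup <- stats::runif(n_genes) < pup_prob
  fams <- ifelse(is_pup, "FR1", NA)
  gene_table("ctg", starts + 1, starts + lens, as.list(fams))
}

# exact hypergeometric upper tail by enumerating the support with choose()
oracle_hyper_tail <- function(k, K, n, N) {
  ks <- max(0, n - (N - K)):min(n, K)
  dens <- choose(K, ks) * choose(N - K, n - ks) / choose(N, n)
  sum(dens[ks >= k])
}

oracle_keys <- function(oracle) {
  if (nrow(oracle) == 0) return(character(0))
  sort(paste(oracle$contig, oracle$first_gene, oracle$last_gene, sep = "|"))
}

as_pgc_keys <- function(pgcs) {
  if (nrow(pgcs) == 0) return(character(0))
  sort(vapply(seq_len(nrow(pgcs)), function(i) {
    ids <- pgcs$gene_ids[[i]]
    paste(pgcs$contig[i], ids[1], ids[length(ids)], sep = "|")
  }, character(1)))
}
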