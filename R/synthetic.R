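# Seeded synthetic-data generators for every input the pipeline consumes:
# annotated genomes with planted PUP gene clusters, domain-hit tables,
# similarity edge lists with planted blocks, and metagenome count tables.
# All generators are deterministic for a fixed seed and leave the caller's
# RNG state untouched.

with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

#' Configuration for the synthetic genome generator
#'
#' Describes the layout the generator emulates: contigs carrying planted PUP
#' gene clusters (each satisfying all three clustering rules with margin),
#' decoy arrangements that each violate exactly one rule, and background
#' genes separated by gaps too large to cluster. Defaults plant clusters of
#' 2-4 PUP genes with 0-3 intervening genes, intra-cluster gaps of 50-400 bp
#' (comfortably under the 1 kb rule) and background gaps of 1,200-3,000 bp.
#'
#' @param rng_seed integer RNG seed.
#' @param n_contigs number of contigs.
#' @param genes_per_contig length-2 range of background gene counts per
#'   contig.
#' @param n_planted_pgcs number of planted clusters (distributed round-robin
#'   over contigs).
#' @param decoys named integer vector: counts of `rule_i` (a lone PUP gene),
#'   `rule_ii` (two PUP genes with four genes between) and `rule_iii` (two
#'   PUP genes separated by a >= 1 kb gap) violators.
#' @param intra_gap_bp length-2 range for gaps inside planted clusters
#'   (upper end must stay below 1000).
#' @param background_gap_bp length-2 range for gaps between unrelated genes
#'   (lower end must be >= 1000 so background never clusters).
#' @param catalog [pup_catalog()] whose families (with signatures and
#'   substrates) are sampled for planted PUP genes; defaults to the packaged
#'   catalog.
#' @return a `pup_sim_config` list.
#' @export
sim_config <- function(rng_seed = 1, n_contigs = 4,
                       genes_per_contig = c(8, 15), n_planted_pgcs = 3,
                       decoys = c(rule_i = 1, rule_ii = 1, rule_iii = 1),
                       intra_gap_bp = c(50, 400),
                       background_gap_bp = c(1200, 3000),
                       catalog = NULL) {
  if (is.null(catalog)) catalog <- load_catalog(pup_catalog_path())
  stopifnot(intra_gap_bp[2] < 1000, background_gap_bp[1] >= 1000,
            n_contigs >= 1, n_planted_pgcs >= 0)
  dec <- c(rule_i = 0L, rule_ii = 0L, rule_iii = 0L)
  dec[names(decoys)] <- as.integer(decoys)
  structure(list(rng_seed = as.integer(rng_seed), n_contigs = n_contigs,
                 genes_per_contig = genes_per_contig,
                 n_planted_pgcs = n_planted_pgcs, decoys = dec,
                 intra_gap_bp = intra_gap_bp,
                 background_gap_bp = background_gap_bp, catalog = catalog),
            class = "pup_sim_config")
}

# majority substrate call, written independently of infer_substrates: tally
# one vote per gene per distinct substrate and keep all argmax labels
expected_substrate_call <- function(per_gene_substrates) {
  votes <- unlist(lapply(per_gene_substrates, unique))
  if (length(votes) == 0) return(character(0))
  tab <- table(votes)
  sort(names(tab)[tab == max(tab)])
}

#' Simulate an annotated genome with planted PUP gene clusters
#'
#' Writes a GFF3 gene model, a protein FASTA, a HMMER-style per-domain hit
#' table, and a JSON truth manifest into `dir`. Planted clusters satisfy all
#' three PGC rules; each decoy violates exactly one; background genes are
#' separated by gaps of at least 1 kb so they can never join a cluster.
#' Protein sequences are random 20-letter strings (no biological realism
#' claimed); domain hits are written directly with E-values and coverages
#' that pass the homolog filter, plus some deliberately failing rows to
#' exercise filtering.
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return list with file paths (`gff`, `fasta`, `domtbl`, `manifest_json`)
#'   and the parsed `manifest`.
#' @export
simulate_genome <- function(config, dir = tempfile("pupsim")) {
  stopifnot(inherits(config, "pup_sim_config"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  fam <- config$catalog$families
  fam <- fam[lengths(fam$signature_domains) > 0, , drop = FALSE]
  if (nrow(fam) == 0) stop("catalog has no families with signature domains")

  with_seed(config$rng_seed, {
    rint <- function(rng) sample(seq(rng[1], rng[2]), 1)
    # plan items per contig: planted clusters and decoys round-robin, plus
    # background genes
    items <- list()
    for (i in seq_len(config$n_planted_pgcs)) {
      items[[length(items) + 1]] <- list(kind = "planted", id = i)
    }
    for (d in names(config$decoys)) {
      for (i in seq_len(config$decoys[[d]])) {
        items[[length(items) + 1]] <- list(kind = d, id = i)
      }
    }
    contig_of_item <- if (length(items) > 0)
      rep(seq_len(config$n_contigs), length.out = length(items)) else integer(0)

    genes <- list(); planted <- list(); decoys <- list()
    gene_n <- 0
    for (ci in seq_len(config$n_contigs)) {
      contig <- sprintf("ctg%02d", ci)
      pos <- rint(c(500, 2000))
      emit <- function(len, is_pup, families, substrates) {
        gene_n <<- gene_n + 1
        g <- list(gene_id = sprintf("gene%04d", gene_n), contig = contig,
                  start = pos, end = pos + len - 1, is_pup = is_pup,
                  families = families, substrates = substrates)
        genes[[length(genes) + 1]] <<- g
        g
      }
      advance <- function(gap) pos <<- genes[[length(genes)]]$end + gap + 1
      bg_gene <- function() {
        emit(rint(c(300, 1500)), FALSE, character(0), character(0))
        advance(rint(config$background_gap_bp))
      }
      pup_gene <- function() {
        fi <- sample(nrow(fam), 1)
        emit(rint(c(600, 1800)), TRUE, fam$family_id[fi],
             tolower(fam$substrates[[fi]]))
      }
      n_bg <- rint(config$genes_per_contig)
      my_items <- items[contig_of_item == ci]
      # interleave: background genes, with items inserted at random slots
      slots <- if (length(my_items) > 0) sort(sample(n_bg + 1, length(my_items),
                                                     replace = TRUE)) else integer(0)
      for (b in seq_len(n_bg + 1)) {
        for (it in my_items[slots == b]) {
          if (it$kind == "planted") {
            n_pup <- sample(2:4, 1)
            members <- character(0); member_subs <- list()
            for (p in seq_len(n_pup)) {
              if (p > 1) {
                for (k in seq_len(sample(0:3, 1))) {   # <= 3 genes between
                  emit(rint(c(300, 1200)), FALSE, character(0), character(0))
                  members <- c(members, genes[[length(genes)]]$gene_id)
                  advance(rint(config$intra_gap_bp))
                }
              }
              g <- pup_gene()
              members <- c(members, g$gene_id)
              member_subs[[length(member_subs) + 1]] <- g$substrates
              if (p < n_pup) advance(rint(config$intra_gap_bp))
            }
            first <- genes[[length(genes) - length(members) + 1]]
            planted[[length(planted) + 1]] <- list(
              pgc = it$id, contig = contig,
              start = first$start, end = genes[[length(genes)]]$end,
              gene_ids = members,
              pup_gene_ids = members[vapply(
                genes[(length(genes) - length(members) + 1):length(genes)],
                `[[`, logical(1), "is_pup")],
              n_pup = n_pup,
              expected_substrates = expected_substrate_call(member_subs))
          } else if (it$kind == "rule_i") {
            g <- pup_gene()                      # a lone PUP gene
            decoys[[length(decoys) + 1]] <- list(type = "rule_i",
                                                 contig = contig,
                                                 gene_ids = g$gene_id)
          } else if (it$kind == "rule_ii") {
            ids <- character(0)
            g <- pup_gene(); ids <- g$gene_id
            advance(rint(config$intra_gap_bp))
            for (k in 1:4) {                     # 4 genes between: too many
              emit(rint(c(300, 900)), FALSE, character(0), character(0))
              ids <- c(ids, genes[[length(genes)]]$gene_id)
              advance(rint(config$intra_gap_bp))
            }
            g <- pup_gene(); ids <- c(ids, g$gene_id)
            decoys[[length(decoys) + 1]] <- list(type = "rule_ii",
                                                 contig = contig,
                                                 gene_ids = ids)
          } else if (it$kind == "rule_iii") {
            ids <- character(0)
            g <- pup_gene(); ids <- g$gene_id
            advance(rint(c(1100, 1600)))         # gap >= 1 kb
            g <- pup_gene(); ids <- c(ids, g$gene_id)
            decoys[[length(decoys) + 1]] <- list(type = "rule_iii",
                                                 contig = contig,
                                                 gene_ids = ids)
          }
          advance(rint(config$background_gap_bp))
        }
        if (b <= n_bg) bg_gene()
      }
    }

    gff <- file.path(dir, "genome.gff3")
    fasta <- file.path(dir, "proteins.faa")
    domtbl <- file.path(dir, "domain_hits.domtbl")
    manifest_json <- file.path(dir, "truth.json")

    gff_lines <- c("##gff-version 3",
                   sprintf("# pupminer simulate_genome rng_seed=%d",
                           config$rng_seed))
    for (g in genes) {
      gff_lines <- c(gff_lines, sprintf(
        "%s\tpupminer\tCDS\t%d\t%d\t.\t%s\t0\tID=%s",
        g$contig, g$start, g$end, sample(c("+", "-"), 1), g$gene_id))
    }
    writeLines(gff_lines, gff)

    aa <- vapply(genes, function(g) {
      n <- max(10L, (g$end - g$start + 1) %/% 3L - 1L)
      paste(sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], n,
                   replace = TRUE), collapse = "")
    }, character(1))
    names(aa) <- vapply(genes, `[[`, character(1), "gene_id")
    Biostrings::writeXStringSet(Biostrings::AAStringSet(aa), fasta)

    sig_map <- stats::setNames(fam$signature_domains, fam$family_id)
    dom_rows <- character(0)
    dom_row <- function(domain, protein, evalue, hmm_len, hmm_from, hmm_to,
                        ali_from, ali_to) {
      sprintf(paste("%s - %d %s - %d %.1e 100.0 0.1 1 1 %.1e %.1e 95.0 0.1",
                    "%d %d %d %d %d %d 0.95 -"),
              domain, hmm_len, protein, max(50L, ali_to + 10L), evalue,
              evalue / 10, evalue, hmm_from, hmm_to, ali_from, ali_to,
              max(1L, ali_from - 2L), ali_to + 2L)
    }
    for (g in genes) {
      if (g$is_pup) {
        sig <- sig_map[[g$families]]
        off <- 1L
        for (dm in sig) {
          hl <- rint(c(100, 300))
          hf <- sample(1:5, 1)
          ht <- hf + as.integer(ceiling(0.75 * hl))   # coverage > 0.6
          alen <- ht - hf + 1L
          dom_rows <- c(dom_rows, dom_row(dm, g$gene_id,
                                          10^-rint(c(8, 40)), hl, hf,
                                          min(ht, hl), off, off + alen - 1L))
          off <- off + alen + 5L
        }
      } else if (stats::runif(1) < 0.3) {
        # a non-signature domain, or a signature hit too weak to pass
        weak <- stats::runif(1) < 0.5
        dm <- if (weak) sample(unlist(sig_map), 1) else
          sprintf("DUF%04d", rint(c(1, 9999)))
        hl <- rint(c(100, 300))
        ht <- if (weak) as.integer(0.3 * hl) else as.integer(0.9 * hl)
        ev <- if (weak) 1e-3 else 1e-20
        dom_rows <- c(dom_rows, dom_row(dm, g$gene_id, ev, hl, 1L, ht, 1L, ht))
      }
    }
    writeLines(c(sprintf("# pupminer simulate_genome rng_seed=%d",
                         config$rng_seed),
                 "# per-domain hit table (hmmscan --domtblout dialect)",
                 dom_rows), domtbl)

    manifest <- list(rng_seed = config$rng_seed,
                     n_genes = length(genes),
                     planted_pgcs = planted, decoys = decoys)
    jsonlite::write_json(manifest, manifest_json, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
    list(gff = gff, fasta = fasta, domtbl = domtbl,
         manifest_json = manifest_json, manifest = manifest, dir = dir)
  })
}

#' Simulate a similarity edge table with planted blocks
#'
#' Emits dense within-block edges (a ring plus random chords, so every block
#' is connected and lies in its own 2-core) at `within_e` and sparse
#' between-block edges at `between_e`; with a cutoff between the two
#' E-values the blocks are exactly the thresholded network's components.
#'
#' @param block_sizes integer vector of planted block sizes (all positive).
#' @param within_e E-value of within-block edges (default 1e-30).
#' @param between_e E-value of between-block edges (default 1e-3).
#' @param rng_seed RNG seed.
#' @param chord_prob probability of each extra within-block chord.
#' @return list with `edges` (data.frame `query`, `subject`, `evalue`) and
#'   `blocks` (list of member id vectors).
#' @export
simulate_ssn <- function(block_sizes, within_e = 1e-30, between_e = 1e-3,
                         rng_seed = 1, chord_prob = 0.3) {
  if (any(block_sizes <= 0)) stop("block sizes must be positive")
  with_seed(rng_seed, {
    blocks <- list(); rows <- list()
    for (b in seq_along(block_sizes)) {
      n <- block_sizes[b]
      ids <- sprintf("B%02dP%03d", b, seq_len(n))
      blocks[[b]] <- ids
      if (n >= 2) {
        ring <- cbind(ids, ids[c(2:n, 1)])
        if (n == 2) ring <- ring[1, , drop = FALSE]
        rows[[length(rows) + 1]] <- data.frame(
          query = ring[, 1], subject = ring[, 2],
          evalue = within_e * 10^stats::runif(nrow(ring), 0, 2),
          stringsAsFactors = FALSE)
        if (n >= 4) {
          extra <- t(utils::combn(ids, 2))
          pick <- stats::runif(nrow(extra)) < chord_prob
          if (any(pick)) {
            rows[[length(rows) + 1]] <- data.frame(
              query = extra[pick, 1], subject = extra[pick, 2],
              evalue = within_e * 10^stats::runif(sum(pick), 0, 2),
              stringsAsFactors = FALSE)
          }
        }
      }
    }
    if (length(block_sizes) >= 2) {
      for (b in seq_len(length(block_sizes) - 1)) {
        rows[[length(rows) + 1]] <- data.frame(
          query = blocks[[b]][1], subject = blocks[[b + 1]][1],
          evalue = between_e, stringsAsFactors = FALSE)
      }
    }
    edges <- if (length(rows) > 0) do.call(rbind, rows) else
      data.frame(query = character(0), subject = character(0),
                 evalue = numeric(0), stringsAsFactors = FALSE)
    rownames(edges) <- NULL
    list(edges = edges, blocks = blocks)
  })
}

#' Simulate metagenome count tables for grouped samples
#'
#' Negative-binomial read counts per target per sample, with a common
#' per-group mean and dispersion. Defaults mirror a wet-season versus
#' dry-season versus Western-control contrast with a large seasonal effect:
#' per-target means 250 (wet), 100 (dry) and 60 (hmp) at dispersion 10,
#' which puts the wet-dry difference in per-sample totals above two pooled
#' standard deviations.
#'
#' @param group_means named numeric vector of per-target mean counts.
#' @param n_samples samples per group (>= 2).
#' @param dispersion negative-binomial size parameter (larger = tighter).
#' @param n_targets number of reference targets.
#' @param rng_seed RNG seed.
#' @return list with `sample_sheet` (`sample_id`, `group`, `total_reads`)
#'   and `counts` (`sample_id`, `target_id`, `length_bp`, `count`).
#' @export
simulate_metagenome_counts <- function(group_means = c(wet = 250, dry = 100,
                                                       hmp = 60),
                                       n_samples = 15, dispersion = 10,
                                       n_targets = 20, rng_seed = 1) {
  if (any(group_means <= 0)) stop("group means must be positive")
  if (n_samples < 2) stop("need at least 2 samples per group")
  with_seed(rng_seed, {
    lengths_bp <- sample(seq(900, 3000, by = 3), n_targets, replace = TRUE)
    targets <- sprintf("PUP%03d", seq_len(n_targets))
    sheets <- list(); counts <- list()
    for (g in names(group_means)) {
      for (s in seq_len(n_samples)) {
        sid <- sprintf("%s_%02d", g, s)
        cnt <- stats::rnbinom(n_targets, size = dispersion,
                              mu = group_means[[g]])
        counts[[length(counts) + 1]] <- data.frame(
          sample_id = sid, target_id = targets, length_bp = lengths_bp,
          count = cnt, stringsAsFactors = FALSE)
        sheets[[length(sheets) + 1]] <- data.frame(
          sample_id = sid, group = g,
          total_reads = max(sum(cnt),
                            round(stats::rnorm(1, mean = 2e6, sd = 1e5))),
          stringsAsFactors = FALSE)
      }
    }
    list(sample_sheet = do.call(rbind, sheets),
         counts = do.call(rbind, counts))
  })
}
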