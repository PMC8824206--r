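# Detection of physically linked PUP gene clusters (PGCs) on annotated
# contigs, and substrate inference by majority vote.
#
# A PGC is a run of genes on one contig that (i) contains at least two PUP
# homolog genes, (ii) has no more than `max_between` non-PUP genes between
# any two adjacent PUP genes, and (iii) has every consecutive intergenic gap
# inside the cluster span shorter than `max_gap_bp`.

#' Build per-contig gene models from a GFF3 file
#'
#' Imports gene features (default type `CDS`) with `rtracklayer`, links them
#' to PUP annotations through the GFF `ID` attribute, and returns them
#' sorted by contig, then start (ties by end, then gene id).
#'
#' @param gff_path GFF3 file path (1-based inclusive coordinates).
#' @param annotations data.frame from [assign_families()] (or
#'   [read_annotations()]); may be `NULL` for an unannotated gene model.
#' @param feature_type GFF feature type to keep (default `"CDS"`; use
#'   `"gene"` for annotations that attach products to parent features).
#' @return data.frame of gene features: `gene_id`, `contig`, `start`, `end`,
#'   `strand`, `is_pup`, `family_ids` (list column of family codes).
#' @export
load_gene_features <- function(gff_path, annotations = NULL,
                               feature_type = "CDS") {
  gr <- as.data.frame(rtracklayer::import(gff_path, format = "gff3"))
  gr <- gr[as.character(gr$type) == feature_type, , drop = FALSE]
  if (nrow(gr) == 0) stop("no features of type ", feature_type, " in ", gff_path)
  ids <- as.character(gr$ID)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("features without an ID attribute in ", gff_path, ": ",
         sum(is.na(ids) | !nzchar(ids)), " offending feature(s)")
  }
  genes <- data.frame(
    gene_id = ids,
    contig = as.character(gr$seqnames),
    start = as.integer(gr$start),
    end = as.integer(gr$end),
    strand = as.character(gr$strand),
    stringsAsFactors = FALSE
  )
  genes$strand[genes$strand == "*"] <- "."
  fam_map <- list()
  if (!is.null(annotations) && nrow(annotations) > 0) {
    fam_map <- split(annotations$family_id, annotations$protein_id)
  }
  genes$family_ids <- lapply(genes$gene_id, function(id) {
    f <- fam_map[[id]]
    if (is.null(f)) character(0) else sort(unique(f))
  })
  genes$is_pup <- lengths(genes$family_ids) > 0
  sort_genes(genes)
}

sort_genes <- function(genes) {
  ord <- order(genes$contig, genes$start, genes$end, genes$gene_id)
  genes <- genes[ord, , drop = FALSE]
  rownames(genes) <- NULL
  genes
}

#' Intergenic gap between two genes on one contig
#'
#' The number of base pairs strictly between the upstream gene's end and the
#' downstream gene's start on 1-based inclusive coordinates:
#' `max(0, start2 - end1 - 1)`. Overlapping or book-ended genes yield 0.
#'
#' @param g1,g2 single-row gene features (`g1$start <= g2$start`), or
#'   vectors via the `end1`/`start2` columns.
#' @return integer gap in bp.
#' @export
intergenic_gap <- function(g1, g2) {
  if (!all(g1$contig == g2$contig)) {
    stop("intergenic_gap: genes on different contigs")
  }
  if (any(g1$start > g2$start)) stop("intergenic_gap: g1 must not start after g2")
  pmax(0L, g2$start - g1$end - 1L)
}

gaps_along <- function(genes) {
  n <- nrow(genes)
  if (n < 2) return(integer(0))
  pmax(0L, genes$start[-1] - genes$end[-n] - 1L)
}

#' Detect PUP gene clusters on sorted contigs
#'
#' Scans each contig left to right and chains PUP genes: the next PUP gene
#' joins the growing cluster when at most `max_between` non-PUP genes lie
#' between it and the previous PUP gene and every consecutive intergenic gap
#' along that stretch is shorter than `max_gap_bp`. Clusters are trimmed to
#' start and end at PUP genes, are maximal, and each PUP gene belongs to at
#' most one cluster; chains with fewer than two PUP genes are discarded.
#'
#' @param genes gene feature data.frame (see [load_gene_features()]); must
#'   be sorted within contigs.
#' @param max_between maximum number of non-PUP genes between adjacent PUP
#'   genes (default 3).
#' @param max_gap_bp strict upper bound on every intergenic gap inside the
#'   cluster, in bp (default 1000).
#' @return data.frame with one row per PGC: `pgc_id`, `contig`, `start`,
#'   `end`, `n_genes`, `n_pup`, `n_other`, and list columns `gene_ids`,
#'   `families`, `genes` (the member gene sub-table).
#' @export
detect_pgcs <- function(genes, max_between = 3, max_gap_bp = 1000) {
  stopifnot(is.data.frame(genes), max_between >= 0, max_gap_bp > 0)
  if (nrow(genes) == 0) return(empty_pgcs())
  per_contig <- split(genes, genes$contig)
  clusters <- list()
  for (ctg in names(per_contig)) {
    g <- per_contig[[ctg]]
    if (is.unsorted(g$start)) stop("genes not sorted by start on contig ", ctg)
    pup_idx <- which(g$is_pup)
    if (length(pup_idx) < 2) next
    gaps <- gaps_along(g)          # gaps[i] between gene i and i+1
    # adjacent PUP pair i is linkable when rules (ii) and (iii) hold
    linkable <- vapply(seq_len(length(pup_idx) - 1), function(k) {
      a <- pup_idx[k]; b <- pup_idx[k + 1]
      (b - a - 1) <= max_between && all(gaps[a:(b - 1)] < max_gap_bp)
    }, logical(1))
    # maximal runs of linkable adjacent pairs
    r <- rle(linkable)
    pos <- cumsum(c(1, r$lengths))
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      first <- pup_idx[pos[j]]
      last <- pup_idx[pos[j + 1]]
      clusters[[length(clusters) + 1]] <- g[first:last, , drop = FALSE]
    }
  }
  if (length(clusters) == 0) return(empty_pgcs())
  rows <- lapply(seq_along(clusters), function(i) {
    cl <- clusters[[i]]
    data.frame(
      pgc_id = sprintf("PGC%04d", i),
      contig = cl$contig[1],
      start = cl$start[1],
      end = cl$end[nrow(cl)],
      n_genes = nrow(cl),
      n_pup = sum(cl$is_pup),
      n_other = sum(!cl$is_pup),
      stringsAsFactors = FALSE
    )
  })
  pgcs <- do.call(rbind, rows)
  pgcs$gene_ids <- lapply(clusters, function(cl) cl$gene_id)
  pgcs$families <- lapply(clusters, function(cl)
    sort(unique(unlist(cl$family_ids))))
  pgcs$genes <- clusters
  rownames(pgcs) <- NULL
  pgcs
}

empty_pgcs <- function() {
  out <- data.frame(pgc_id = character(0), contig = character(0),
                    start = integer(0), end = integer(0), n_genes = integer(0),
                    n_pup = integer(0), n_other = integer(0),
                    stringsAsFactors = FALSE)
  out$gene_ids <- list()
  out$families <- list()
  out$genes <- list()
  out
}

#' Infer the substrate(s) of a PUP gene cluster by majority vote
#'
#' Each PUP gene in the cluster votes once for every distinct substrate of
#' its families (a gene annotated with two families contributes one vote per
#' distinct substrate across both). The substrate(s) with the most votes are
#' returned; ties are returned together, so a cluster split evenly between
#' two substrate groups is inferred to target both. Genes whose families
#' carry no substrates are excluded with a warning.
#'
#' @param pgc one row of the [detect_pgcs()] table (or any list with a
#'   `genes` member gene table).
#' @param catalog a [pup_catalog()] whose families carry substrate sets.
#' @return character vector of substrate labels (possibly empty, with a
#'   warning, when no member family has substrates).
#' @export
infer_substrates <- function(pgc, catalog) {
  stopifnot(inherits(catalog, "pup_catalog"))
  genes <- if (is.data.frame(pgc$genes)) pgc$genes else pgc$genes[[1]]
  pup <- genes[genes$is_pup, , drop = FALSE]
  fam <- catalog$families
  sub_map <- stats::setNames(fam$substrates, fam$family_id)
  votes <- character(0)
  n_excluded <- 0
  for (i in seq_len(nrow(pup))) {
    fams <- pup$family_ids[[i]]
    unknown <- setdiff(fams, fam$family_id)
    if (length(unknown) > 0) {
      stop("PGC member annotated with families missing from catalog: ",
           paste(unknown, collapse = ", "))
    }
    subs <- unique(tolower(unlist(sub_map[fams])))
    if (length(subs) == 0) {
      n_excluded <- n_excluded + 1
      next
    }
    votes <- c(votes, subs)        # one vote per distinct substrate per gene
  }
  if (n_excluded > 0) {
    warning(n_excluded, " PUP gene(s) excluded from substrate vote (family has no substrates)")
  }
  if (length(votes) == 0) return(character(0))
  tab <- table(votes)
  sort(names(tab)[tab == max(tab)])
}

#' Summarise a set of detected PGCs
#'
#' @param pgcs data.frame from [detect_pgcs()]; a `substrates` list column
#'   (added by the caller via [infer_substrates()]) feeds the substrate
#'   histogram when present.
#' @return list with `size_histogram` (total genes per PGC), `n_pgcs`,
#'   `total_pup`, `total_other`, `pup_fraction` per PGC, and
#'   `substrate_histogram` when available.
#' @export
pgc_summary <- function(pgcs) {
  if (nrow(pgcs) == 0) {
    return(list(n_pgcs = 0L, size_histogram = table(integer(0)),
                total_pup = 0L, total_other = 0L,
                pup_fraction = numeric(0),
                substrate_histogram = table(character(0))))
  }
  out <- list(
    n_pgcs = nrow(pgcs),
    size_histogram = table(pgcs$n_genes),
    total_pup = sum(pgcs$n_pup),
    total_other = sum(pgcs$n_other),
    pup_fraction = pgcs$n_pup / pgcs$n_genes
  )
  if ("substrates" %in% names(pgcs)) {
    out$substrate_histogram <- sort(table(unlist(pgcs$substrates)),
                                    decreasing = TRUE)
  }
  out
}

#' Write PGC tables
#'
#' `write_pgc_tsv` writes one row per cluster with "+"-joined gene lists;
#' `write_pgc_bed` writes cluster spans as BED (0-based half-open: start-1).
#'
#' @param pgcs data.frame from [detect_pgcs()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pgc_tsv <- function(pgcs, path) {
  out <- data.frame(
    pgc_id = pgcs$pgc_id, contig = pgcs$contig, start = pgcs$start,
    end = pgcs$end, n_genes = pgcs$n_genes, n_pup = pgcs$n_pup,
    n_other = pgcs$n_other,
    gene_ids = join_field(pgcs$gene_ids, "+"),
    families = join_field(pgcs$families, "+"),
    substrates = if ("substrates" %in% names(pgcs))
      join_field(pgcs$substrates, ";") else "",
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_pgc_tsv
#' @export
write_pgc_bed <- function(pgcs, path) {
  bed <- data.frame(chrom = pgcs$contig, chromStart = pgcs$start - 1L,
                    chromEnd = pgcs$end, name = pgcs$pgc_id)
  utils::write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
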