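# Genome-level abundance/prevalence profiling and Pfam-domain enrichment in
# gene clusters.

#' Extract a rank from a GTDB-style lineage string
#'
#' Lineages look like `d__Bacteria;p__Firmicutes;...`; returns the label at
#' the requested one-letter rank prefix, or `"unknown"` when absent.
#'
#' @param lineage character vector of lineage strings.
#' @param rank one-letter rank prefix (default `"p"`, phylum).
#' @return character vector of labels.
#' @export
lineage_rank <- function(lineage, rank = "p") {
  pat <- sprintf(".*(^|;)%s__([^;]*).*", rank)
  out <- ifelse(grepl(sprintf("(^|;)%s__", rank), lineage),
                sub(pat, "\\2", lineage), "")
  out[is.na(out) | !nzchar(out)] <- "unknown"
  out
}

#' Percent of a genome's proteins that are PUP homologs or PGC genes
#'
#' @param profiles data.frame of genome profiles with columns `genome_id`,
#'   `n_proteins`, `n_pup`, `n_pgc_genes` (plus `lineage`, `continent` for
#'   grouped statistics).
#' @param numerator `"pup"` or `"pgc_genes"`.
#' @return numeric vector of percentages (one per genome).
#' @export
genome_abundance <- function(profiles, numerator = c("pup", "pgc_genes")) {
  numerator <- match.arg(numerator)
  if (any(profiles$n_proteins <= 0)) {
    stop("genome_abundance: n_proteins must be positive")
  }
  num <- if (numerator == "pup") profiles$n_pup else profiles$n_pgc_genes
  if (any(num > profiles$n_proteins)) {
    stop("genome_abundance: numerator count exceeds n_proteins")
  }
  100 * num / profiles$n_proteins
}

#' Prevalence of PUP-containing genomes per taxonomy or geography group
#'
#' For each group, the percentage of genomes containing at least one PUP
#' homolog (or at least one PGC gene).
#'
#' @param profiles genome profile data.frame (see [genome_abundance()]).
#' @param group_by `"phylum"` (parsed from `lineage`) or `"continent"`.
#' @param indicator `"pup"` or `"pgc_genes"`.
#' @return data.frame with `group`, `n_genomes`, `n_positive`,
#'   `prevalence_pct`.
#' @export
group_prevalence <- function(profiles, group_by = c("phylum", "continent"),
                             indicator = c("pup", "pgc_genes")) {
  group_by <- match.arg(group_by)
  indicator <- match.arg(indicator)
  if (nrow(profiles) == 0) {
    return(data.frame(group = character(0), n_genomes = integer(0),
                      n_positive = integer(0), prevalence_pct = numeric(0)))
  }
  grp <- if (group_by == "phylum") lineage_rank(profiles$lineage, "p")
         else {
           ct <- as.character(profiles$continent)
           ct[is.na(ct) | !nzchar(ct)] <- "unknown"
           ct
         }
  cnt <- if (indicator == "pup") profiles$n_pup else profiles$n_pgc_genes
  n <- tapply(rep(1L, length(grp)), grp, sum)
  pos <- tapply(cnt >= 1, grp, sum)
  out <- data.frame(group = names(n), n_genomes = as.integer(n),
                    n_positive = as.integer(pos),
                    prevalence_pct = 100 * as.integer(pos) / as.integer(n),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out[order(-out$prevalence_pct, out$group), , drop = FALSE]
}

#' Median abundance per phylum-by-continent cell, with within-phylum ranks
#'
#' For every (phylum, continent) cell with at least one genome: the median
#' per-genome abundance percentage, the number of genomes, and the rank of
#' the cell within its phylum (1 = largest median; ties get the minimum,
#' i.e. competition, rank). This is the table behind bubble plots of which
#' continent leads each phylum. Genomes with unknown continent are excluded
#' from cells but still counted in `n_total` per phylum.
#'
#' @param profiles genome profile data.frame.
#' @param numerator `"pup"` or `"pgc_genes"`.
#' @return data.frame with `phylum`, `continent`, `median_pct`, `rank`,
#'   `n_genomes`, `n_total`.
#' @export
median_bubble_table <- function(profiles, numerator = c("pup", "pgc_genes")) {
  numerator <- match.arg(numerator)
  if (nrow(profiles) == 0) {
    return(data.frame(phylum = character(0), continent = character(0),
                      median_pct = numeric(0), rank = integer(0),
                      n_genomes = integer(0), n_total = integer(0)))
  }
  pct <- genome_abundance(profiles, numerator)
  phylum <- lineage_rank(profiles$lineage, "p")
  continent <- as.character(profiles$continent)
  continent[is.na(continent) | !nzchar(continent)] <- "unknown"
  phylum_totals <- table(phylum)
  keep <- continent != "unknown"
  df <- data.frame(phylum = phylum[keep], continent = continent[keep],
                   pct = pct[keep], stringsAsFactors = FALSE)
  if (nrow(df) == 0) {
    return(data.frame(phylum = character(0), continent = character(0),
                      median_pct = numeric(0), rank = integer(0),
                      n_genomes = integer(0), n_total = integer(0)))
  }
  agg <- stats::aggregate(pct ~ phylum + continent, data = df,
                          FUN = stats::median)
  names(agg)[names(agg) == "pct"] <- "median_pct"
  cnt <- stats::aggregate(cbind(n_genomes = rep(1L, nrow(df))) ~ phylum + continent,
                          data = df, FUN = sum)
  out <- merge(agg, cnt, by = c("phylum", "continent"))
  # competition rank of medians within each phylum (1 = largest)
  out$rank <- as.integer(stats::ave(out$median_pct, out$phylum,
    FUN = function(m) vapply(m, function(x) 1 + sum(m > x), numeric(1))))
  out <- out[order(out$phylum, out$rank, out$continent), , drop = FALSE]
  out$n_total <- as.integer(phylum_totals[out$phylum])
  rownames(out) <- NULL
  out
}

#' Upper-tail hypergeometric probability
#'
#' P(X >= k) for X hypergeometric with `K` carriers in a background of `N`
#' and a sample of size `n`; the enrichment p-value of seeing at least `k`
#' carriers in the foreground.
#'
#' @param k observed foreground carriers.
#' @param K background carriers.
#' @param n foreground size.
#' @param N background size.
#' @return numeric probability in (0, 1].
#' @export
hyper_upper_tail <- function(k, K, n, N) {
  stopifnot(all(k >= 0), all(K <= N), all(n <= N), all(k <= pmin(n, K)))
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Pfam-domain enrichment in gene-cluster proteins
#'
#' Tests each Pfam domain seen in the foreground (proteins inside PGCs)
#' for overrepresentation against the background (all proteins of the
#' PGC-containing genomes) with an upper-tail hypergeometric test. Counting
#' is per protein: a protein carrying two copies of a domain counts once.
#' Results are ordered by foreground occurrence (descending) to mirror
#' ranking domains by their occurrence count; Benjamini-Hochberg adjusted
#' p-values are reported alongside the raw ones.
#'
#' @param fg_proteins named list protein_id -> character vector of domains
#'   for the foreground proteins.
#' @param bg_proteins same, for the background; must contain every
#'   foreground protein id.
#' @return data.frame with `domain_name`, `fg_count`, `fg_size`, `bg_count`,
#'   `bg_size`, `p_value`, `p_adjusted`.
#' @export
enrich_domains <- function(fg_proteins, bg_proteins) {
  if (!all(names(fg_proteins) %in% names(bg_proteins))) {
    stop("foreground proteins must be a subset of the background")
  }
  N <- length(bg_proteins)
  n <- length(fg_proteins)
  fg_doms <- lapply(fg_proteins, unique)
  bg_doms <- lapply(bg_proteins, unique)
  fg_tab <- table(unlist(fg_doms))
  bg_tab <- table(unlist(bg_doms))
  doms <- names(fg_tab)
  k <- as.integer(fg_tab[doms])
  K <- as.integer(bg_tab[doms])
  if (anyNA(K) || any(k > K)) {
    stop("foreground domain content inconsistent with background")
  }
  p <- hyper_upper_tail(k, K, n, N)
  out <- data.frame(domain_name = doms, fg_count = k, fg_size = n,
                    bg_count = K, bg_size = N, p_value = p,
                    stringsAsFactors = FALSE)
  out$p_adjusted <- stats::p.adjust(out$p_value, method = "BH")
  out <- out[order(-out$fg_count, out$p_value, out$domain_name), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a genome metadata table
#'
#' @param path TSV with columns `genome_id`, `n_proteins`, `n_pup`,
#'   `n_pgc_genes`, `lineage`, `continent`.
#' @return data.frame of genome profiles.
#' @export
read_genome_profiles <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    quote = "", comment.char = "#")
}
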