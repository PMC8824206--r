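# Domain-hit filtering and signature-based PUP family assignment.

#' Parse a HMMER per-domain tabular file
#'
#' Reads the whitespace-delimited per-domain table written by `hmmscan
#' --domtblout` (one row per domain hit, `#` comment lines). The protein is
#' the query and the Pfam model the target, so `tlen` is the HMM length. The
#' independent E-value (i-Evalue) column is used as the hit E-value. HMM
#' coverage is computed as the HMM-coordinate span over the HMM length.
#'
#' @param path file path, or a character vector of lines via `text =`.
#' @param text optional character vector of table lines (overrides `path`).
#' @return data.frame of domain hits with columns `protein_id`,
#'   `domain_name`, `evalue`, `hmm_from`, `hmm_to`, `hmm_length`, `ali_from`,
#'   `ali_to`, `coverage`.
#' @export
parse_domain_hits <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) text else readLines(path, warn = FALSE)
  keep <- !grepl("^#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) return(empty_domain_hits())
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf < 22)
  if (length(bad) > 0) {
    stop(sprintf(
      "malformed domain-hit row at line %d: expected >= 22 columns, got %d",
      lineno[bad[1]], nf[bad[1]]))
  }
  col <- function(i) vapply(fields, `[[`, character(1), i)
  hits <- data.frame(
    protein_id = col(4),
    domain_name = col(1),
    evalue = as.numeric(col(13)),
    hmm_from = as.integer(col(16)),
    hmm_to = as.integer(col(17)),
    hmm_length = as.integer(col(3)),
    ali_from = as.integer(col(18)),
    ali_to = as.integer(col(19)),
    stringsAsFactors = FALSE
  )
  if (anyNA(hits$evalue) || any(hits$evalue < 0)) {
    stop("invalid E-value in domain-hit table")
  }
  if (any(hits$hmm_from > hits$hmm_to) || any(hits$hmm_to > hits$hmm_length) ||
      any(hits$ali_from > hits$ali_to)) {
    stop("inconsistent coordinates in domain-hit table")
  }
  hits$coverage <- (hits$hmm_to - hits$hmm_from + 1) / hits$hmm_length
  hits
}

empty_domain_hits <- function() {
  data.frame(protein_id = character(0), domain_name = character(0),
             evalue = numeric(0), hmm_from = integer(0), hmm_to = integer(0),
             hmm_length = integer(0), ali_from = integer(0),
             ali_to = integer(0), coverage = numeric(0),
             stringsAsFactors = FALSE)
}

#' Filter domain hits by E-value and HMM coverage
#'
#' Seed-curation mode keeps hits with E-value below 1e-5 and HMM coverage
#' above 0.3; homolog-recruitment mode uses the stricter coverage threshold
#' of 0.6 at the same E-value. Both inequalities are strict. Input order is
#' preserved and the operation is idempotent.
#'
#' @param hits data.frame from [parse_domain_hits()].
#' @param mode `"seed"` or `"homolog"`.
#' @param evalue_max E-value threshold (default 1e-5).
#' @return the filtered data.frame.
#' @export
filter_hits <- function(hits, mode = c("homolog", "seed"), evalue_max = 1e-5) {
  mode <- match.arg(mode)
  cov_min <- if (mode == "seed") 0.3 else 0.6
  hits[hits$evalue < evalue_max & hits$coverage > cov_min, , drop = FALSE]
}

#' Resolve overlapping domain hits on one protein
#'
#' When two hits overlap on the protein by more than half the shorter
#' alignment, only the better hit is kept: lower E-value first, ties broken
#' by longer alignment, then by lexicographically smaller domain name.
#' Applied independently per protein when hits for several proteins are
#' supplied.
#'
#' @param hits data.frame of domain hits.
#' @return data.frame of retained hits.
#' @export
resolve_overlaps <- function(hits) {
  if (nrow(hits) <= 1) return(hits)
  parts <- split(seq_len(nrow(hits)), hits$protein_id)
  keep_idx <- unlist(lapply(parts, function(idx) {
    h <- hits[idx, , drop = FALSE]
    len <- h$ali_to - h$ali_from + 1
    ord <- order(h$evalue, -len, h$domain_name)
    kept <- integer(0)
    for (i in ord) {
      clash <- FALSE
      for (j in kept) {
        ov <- min(h$ali_to[i], h$ali_to[j]) - max(h$ali_from[i], h$ali_from[j]) + 1
        if (ov > 0.5 * min(len[i], len[j])) { clash <- TRUE; break }
      }
      if (!clash) kept <- c(kept, i)
    }
    idx[sort(kept)]
  }), use.names = FALSE)
  hits[sort(keep_idx), , drop = FALSE]
}

#' Assign proteins to PUP families by signature domains
#'
#' A protein is annotated with a family when every domain of that family's
#' signature combination is present among its (filtered, overlap-resolved)
#' domain hits; domain order on the protein does not matter. A protein can
#' satisfy several signatures and then receives all of them, flagged
#' `multi_family`. The two domain-less UC families are assigned from the
#' final round of an iterative similarity search: rows of `similarity_hits`
#' with E-value below `uc_evalue_max` become annotations with evidence
#' `similarity_search`.
#'
#' @param hits data.frame of domain hits (already homolog-filtered and
#'   overlap-resolved; see [filter_hits()], [resolve_overlaps()]).
#' @param catalog a [pup_catalog()].
#' @param similarity_hits optional data.frame with columns `protein_id`,
#'   `family_id`, `evalue` carrying UC-family similarity evidence.
#' @param uc_evalue_max E-value threshold for similarity evidence
#'   (default 0.001).
#' @return data.frame with columns `protein_id`, `family_id`, `evidence`,
#'   `domains` ("+"-joined supporting domains, "" for similarity evidence),
#'   `best_evalue`, `multi_family`.
#' @export
assign_families <- function(hits, catalog, similarity_hits = NULL,
                            uc_evalue_max = 0.001) {
  stopifnot(inherits(catalog, "pup_catalog"))
  fam <- catalog$families
  out <- list()
  if (nrow(hits) > 0) {
    by_prot <- split(hits, hits$protein_id)
    sig_fams <- fam[lengths(fam$signature_domains) > 0, , drop = FALSE]
    for (pid in names(by_prot)) {
      h <- by_prot[[pid]]
      doms <- unique(h$domain_name)
      for (i in seq_len(nrow(sig_fams))) {
        sig <- sig_fams$signature_domains[[i]]
        if (all(sig %in% doms)) {
          sup <- h[h$domain_name %in% sig, , drop = FALSE]
          out[[length(out) + 1]] <- data.frame(
            protein_id = pid,
            family_id = sig_fams$family_id[i],
            evidence = "signature_domains",
            domains = paste(sort(sig), collapse = "+"),
            best_evalue = min(sup$evalue),
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!is.null(similarity_hits) && nrow(similarity_hits) > 0) {
    unknown <- setdiff(similarity_hits$family_id, fam$family_id)
    if (length(unknown) > 0) {
      stop("similarity hits reference unknown families: ",
           paste(unique(unknown), collapse = ", "))
    }
    sh <- similarity_hits[similarity_hits$evalue < uc_evalue_max, , drop = FALSE]
    if (nrow(sh) > 0) {
      agg <- stats::aggregate(evalue ~ protein_id + family_id, data = sh, FUN = min)
      for (i in seq_len(nrow(agg))) {
        out[[length(out) + 1]] <- data.frame(
          protein_id = agg$protein_id[i],
          family_id = agg$family_id[i],
          evidence = "similarity_search",
          domains = "",
          best_evalue = agg$evalue[i],
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(out) == 0) {
    return(data.frame(protein_id = character(0), family_id = character(0),
                      evidence = character(0), domains = character(0),
                      best_evalue = numeric(0), multi_family = logical(0),
                      stringsAsFactors = FALSE))
  }
  ann <- do.call(rbind, out)
  ann <- ann[order(ann$protein_id, ann$family_id), , drop = FALSE]
  rownames(ann) <- NULL
  nfam <- table(ann$protein_id)
  ann$multi_family <- as.vector(nfam[ann$protein_id] > 1)
  if (any(ann$multi_family)) {
    warning(sum(nfam > 1), " protein(s) matched the signatures of multiple families")
  }
  ann
}

#' Write / read an annotation table
#'
#' @param annotations data.frame from [assign_families()].
#' @param path output TSV path.
#' @return `path` invisibly (`write_annotations`); data.frame
#'   (`read_annotations`).
#' @export
write_annotations <- function(annotations, path) {
  utils::write.table(annotations, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_annotations
#' @export
read_annotations <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    colClasses = c(domains = "character"))
}
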