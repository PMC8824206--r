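FAMILY_CODE_RE <- "^(FR|OR|HR|NCR|IR|UC)([0-9]+)$"
ENZYME_CLASSES <- c("FR", "OR", "HR", "NCR", "IR", "UC")

#' Construct a PUP family catalog from data frames
#'
#' A catalog holds the seed families of polyphenol utilization proteins
#' (PUPs): for each family its enzyme class, the signature Pfam domain (or
#' all-required multidomain combination) that defines membership, the number
#' of experimentally characterized seed proteins, the substrates those seeds
#' act on, and optional homolog counts in the Swiss-Prot, TrEMBL and UHGP
#' databases. The two unclassified (UC) families have no Pfam domains and an
#' empty signature; their members are recruited by iterative similarity
#' search instead (see [assign_families()]).
#'
#' @param families data.frame with columns `family_id`, `enzyme_class`,
#'   `signature_domains` (list of character vectors, or "+"-joined strings),
#'   `n_seeds`, `substrates` (list of character vectors, or ";"-joined
#'   strings), and optionally `swissprot`, `trembl`, `uhgp`.
#' @param seeds optional data.frame of individual seed proteins with columns
#'   `seed_id`, `family_id`, and optionally `organism`, `ec_number`,
#'   `domains`, `substrates`.
#' @return an object of class `pup_catalog`.
#' @export
pup_catalog <- function(families, seeds = NULL) {
  stopifnot(is.data.frame(families))
  req <- c("family_id", "enzyme_class", "signature_domains", "n_seeds",
           "substrates")
  missing_cols <- setdiff(req, names(families))
  if (length(missing_cols) > 0) {
    stop("catalog families table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  if (!is.list(families$signature_domains)) {
    families$signature_domains <- split_field(families$signature_domains, "+")
  }
  if (!is.list(families$substrates)) {
    families$substrates <- split_field(tolower(families$substrates), ";")
  } else {
    families$substrates <- lapply(families$substrates, tolower)
  }
  families$family_id <- as.character(families$family_id)
  families$enzyme_class <- as.character(families$enzyme_class)
  families$n_seeds <- as.integer(families$n_seeds)

  dup <- families$family_id[duplicated(families$family_id)]
  if (length(dup) > 0) {
    stop("duplicate family_id in catalog: ", paste(unique(dup), collapse = ", "))
  }
  bad_code <- !grepl(FAMILY_CODE_RE, families$family_id)
  if (any(bad_code)) {
    stop("malformed family codes: ",
         paste(families$family_id[bad_code], collapse = ", "))
  }
  if (!is.null(seeds)) {
    stopifnot(is.data.frame(seeds), all(c("seed_id", "family_id") %in% names(seeds)))
    unknown <- setdiff(seeds$family_id, families$family_id)
    if (length(unknown) > 0) {
      stop("seeds reference unknown families: ", paste(unknown, collapse = ", "))
    }
    if (anyDuplicated(seeds$seed_id)) stop("duplicate seed_id in catalog seeds")
  }
  structure(list(families = families, seeds = seeds), class = "pup_catalog")
}

#' @export
print.pup_catalog <- function(x, ...) {
  cls <- table(x$families$enzyme_class)
  cat(sprintf("PUP catalog: %d families, %d enzyme classes, %d seeds\n",
              nrow(x$families), length(cls), sum(x$families$n_seeds)))
  cat("  classes:", paste(sprintf("%s=%d", names(cls), cls), collapse = " "), "\n")
  invisible(x)
}

# split "+"- or ";"-joined fields into character vectors; "" -> character(0)
split_field <- function(x, sep) {
  lapply(as.character(x), function(s) {
    if (is.na(s) || !nzchar(s)) character(0)
    else strsplit(s, sep, fixed = TRUE)[[1]]
  })
}

join_field <- function(x, sep) {
  vapply(x, function(v) paste(v, collapse = sep), character(1))
}

#' Path to the packaged PUP family catalog
#'
#' The transcription of the 26-family seed catalog (signature Pfam domains,
#' seed counts, and per-database homolog counts). Substrate labels in this
#' file are synthetic placeholders; see the file header.
#'
#' @return file path of the packaged TSV.
#' @export
pup_catalog_path <- function() {
  system.file("extdata", "pup_families.tsv", package = "pupminer",
              mustWork = TRUE)
}

#' Load a PUP family catalog from a TSV file
#'
#' The TSV has header columns `family_id`, `enzyme_class`,
#' `signature_domains` ("+"-joined), `n_seeds`, `substrates` (";"-joined),
#' and optionally `swissprot`, `trembl`, `uhgp` homolog counts. Lines
#' starting with `#` are comments.
#'
#' @param path file path.
#' @return a [pup_catalog()] object.
#' @export
load_catalog <- function(path) {
  if (!file.exists(path)) stop("catalog file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0) stop("catalog file has no header: ", path)
  header <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  req <- c("family_id", "enzyme_class", "signature_domains", "n_seeds",
           "substrates")
  if (!all(req %in% header)) {
    stop("catalog header must contain: ", paste(req, collapse = ", "))
  }
  body <- lines[-1]
  if (length(body) == 0) {
    warning("catalog file contains a header but no families: ", path)
    fam <- data.frame(family_id = character(0), enzyme_class = character(0),
                      n_seeds = integer(0))
    fam$signature_domains <- list()
    fam$substrates <- list()
    return(pup_catalog(fam))
  }
  fields <- strsplit(body, "\t", fixed = TRUE)
  nf <- lengths(fields)
  # trailing empty fields are dropped by strsplit; pad, but flag short rows
  bad <- which(nf < length(header) - 1L | nf > length(header))
  if (length(bad) > 0) {
    stop(sprintf("malformed catalog row at line %d: expected %d fields, got %d",
                 lineno[-1][bad[1]], length(header), nf[bad[1]]))
  }
  fields <- lapply(fields, function(f) c(f, rep("", length(header) - length(f))))
  mat <- do.call(rbind, fields)
  colnames(mat) <- header
  df <- as.data.frame(mat, stringsAsFactors = FALSE)
  df$n_seeds <- as.integer(df$n_seeds)
  for (col in c("swissprot", "trembl", "uhgp")) {
    if (col %in% names(df)) df[[col]] <- as.integer(df[[col]])
  }
  pup_catalog(df)
}

#' Write a PUP family catalog to TSV
#'
#' Inverse of [load_catalog()]: signature domain combinations are "+"-joined
#' and substrate sets ";"-joined, so `load_catalog(write_catalog(x, f))`
#' reproduces `x` field for field.
#'
#' @param catalog a `pup_catalog`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path) {
  stopifnot(inherits(catalog, "pup_catalog"))
  fam <- catalog$families
  out <- data.frame(
    family_id = fam$family_id,
    enzyme_class = fam$enzyme_class,
    signature_domains = join_field(fam$signature_domains, "+"),
    n_seeds = fam$n_seeds,
    substrates = join_field(fam$substrates, ";"),
    stringsAsFactors = FALSE
  )
  for (col in c("swissprot", "trembl", "uhgp")) {
    if (col %in% names(fam)) out[[col]] <- fam[[col]]
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Enzyme class of a PUP family code
#'
#' Family codes are an enzyme-class prefix plus an ordinal: oxidation/
#' reduction (OR), functional group transfer (FR), hydrolysis (HR),
#' nonhydrolytic cleavage (NCR), isomerization (IR), and unclassified (UC).
#'
#' @param family_id character vector of family codes (e.g. "OR3").
#' @return character vector of class codes.
#' @export
family_class <- function(family_id) {
  m <- regmatches(family_id, regexec(FAMILY_CODE_RE, family_id))
  bad <- lengths(m) == 0
  if (any(bad)) {
    stop("malformed family code: ", paste(family_id[bad], collapse = ", "))
  }
  vapply(m, `[[`, character(1), 2)
}

#' Derive the signature Pfam domain set of a family
#'
#' Given the domain architectures of a family's seed proteins, selects the
#' signature: a single-domain seed contributes its domain; if all members
#' share the same multidomain architecture, that combination is the
#' signature; if members share only one domain, that single domain is; and
#' in all cases only domains on the enzymatic allowlist count (non-enzymatic
#' accessory domains are removed first).
#'
#' @param seed_domains list of character vectors, one per family member, in
#'   any order (the result is order-invariant).
#' @param enzymatic_allowlist character vector of domain names considered
#'   enzymatic, or `NULL` to treat every domain as enzymatic.
#' @return sorted character vector of signature domain names.
#' @export
derive_signature <- function(seed_domains, enzymatic_allowlist = NULL) {
  stopifnot(is.list(seed_domains), length(seed_domains) >= 1)
  members <- lapply(seed_domains, function(d) {
    d <- unique(as.character(d))
    if (!is.null(enzymatic_allowlist)) d <- intersect(d, enzymatic_allowlist)
    sort(d)
  })
  shared <- Reduce(intersect, members)
  if (length(shared) == 0) {
    stop("no signature derivable: members share no enzymatic domain")
  }
  architectures <- unique(vapply(members, paste, character(1), collapse = "+"))
  if (length(architectures) == 1) {
    return(members[[1]])           # identical (possibly multidomain) architecture
  }
  if (length(shared) == 1) {
    return(shared)                 # a single shared enzymatic domain
  }
  sort(shared)                     # shared multidomain core
}

#' Validate a PUP catalog and summarise its totals
#'
#' Report-only check of the catalog invariants: family codes well formed and
#' matching their enzyme class; signatures empty exactly for UC families; no
#' two families sharing the same signature domain combination; seed counts
#' consistent with any seed table. Also returns the totals used for
#' consistency checks against a printed source table.
#'
#' @param catalog a `pup_catalog`.
#' @return a list with `violations` (data.frame of `type`, `message`) and
#'   `totals` (n_families, n_seeds, class_counts, and homolog column sums
#'   when present).
#' @export
validate_catalog <- function(catalog) {
  stopifnot(inherits(catalog, "pup_catalog"))
  fam <- catalog$families
  v <- list()
  add <- function(type, message) {
    v[[length(v) + 1]] <<- data.frame(type = type, message = message,
                                      stringsAsFactors = FALSE)
  }
  ok_code <- grepl(FAMILY_CODE_RE, fam$family_id)
  for (id in fam$family_id[!ok_code]) add("malformed_code", id)
  if (any(ok_code)) {
    pref <- family_class(fam$family_id[ok_code])
    mism <- fam$family_id[ok_code][pref != fam$enzyme_class[ok_code]]
    for (id in mism) add("class_mismatch",
                         sprintf("family %s: class does not equal code prefix", id))
  }
  is_uc <- fam$enzyme_class == "UC"
  empty_sig <- lengths(fam$signature_domains) == 0
  for (id in fam$family_id[is_uc & !empty_sig])
    add("uc_with_signature", sprintf("UC family %s has signature domains", id))
  for (id in fam$family_id[!is_uc & empty_sig])
    add("missing_signature", sprintf("family %s has no signature domains", id))
  sig_key <- join_field(lapply(fam$signature_domains, sort), "+")
  nonempty <- nzchar(sig_key)
  dup_keys <- unique(sig_key[nonempty][duplicated(sig_key[nonempty])])
  for (k in dup_keys) {
    ids <- fam$family_id[sig_key == k]
    add("duplicate_signature",
        sprintf("signature {%s} shared by families %s", k,
                paste(ids, collapse = ", ")))
  }
  no_substrate <- lengths(fam$substrates) == 0
  for (id in fam$family_id[no_substrate])
    add("empty_substrates", sprintf("family %s has no substrates", id))
  if (!is.null(catalog$seeds)) {
    cnt <- table(catalog$seeds$family_id)
    for (id in fam$family_id) {
      n <- if (id %in% names(cnt)) as.integer(cnt[[id]]) else 0L
      if (n != fam$n_seeds[fam$family_id == id]) {
        add("seed_count_mismatch",
            sprintf("family %s: n_seeds=%d but %d seed records", id,
                    fam$n_seeds[fam$family_id == id], n))
      }
    }
  }
  violations <- if (length(v) > 0) do.call(rbind, v) else
    data.frame(type = character(0), message = character(0))
  totals <- list(
    n_families = nrow(fam),
    n_seeds = sum(fam$n_seeds),
    class_counts = table(factor(fam$enzyme_class, levels = ENZYME_CLASSES))
  )
  for (col in c("swissprot", "trembl", "uhgp")) {
    if (col %in% names(fam)) totals[[paste0(col, "_total")]] <- sum(fam[[col]])
  }
  list(violations = violations, totals = totals)
}
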