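# In-memory LCA database: two named lists keyed by sample name — one
# holding the samples' hashes, one their taxonomic lineages — supporting
# direct hash look-up, k-mer LCA classification and mixture summarization,
# plus linear-scan search/gather as an alternative to the SBT backend.

# --- lineages --------------------------------------------------------------

# A lineage is a character vector of rank names in canonical rank order
# (superkingdom..strain), with no internal gaps; unranked tails are absent.

lineage_from_row <- function(row) {
  vals <- as.character(unlist(row[TAXONOMY_RANKS[TAXONOMY_RANKS %in% names(row)]]))
  vals[is.na(vals)] <- ""
  filled <- which(vals != "")
  if (length(filled) == 0) return(character(0))
  last <- max(filled)
  if (any(vals[seq_len(last)] == ""))
    stop("lineage has a gap before its last filled rank")
  vals[seq_len(last)]
}

lineage_str <- function(lin) paste(lin, collapse = ";")

# Lowest common ancestor (longest common prefix) of a list of lineages.
# Idempotent, commutative and order-invariant.
lca_of <- function(lineages) {
  if (length(lineages) == 0) return(character(0))
  out <- lineages[[1]]
  for (lin in lineages[-1]) {
    n <- min(length(out), length(lin))
    if (n == 0) return(character(0))
    eq <- out[seq_len(n)] == lin[seq_len(n)]
    keep <- if (all(eq)) n else which(!eq)[1] - 1L
    if (keep == 0) return(character(0))
    out <- out[seq_len(keep)]
  }
  out
}

#' Read a taxonomy table
#'
#' CSV dialect: a header row with an `accession` column followed by ranked
#' lineage columns among `superkingdom, phylum, class, order, family,
#' genus, species, strain`; a blank cell means unranked from that rank on.
#'
#' @param path CSV path.
#' @return A data.frame with character columns.
#' @export
read_taxonomy <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (!"accession" %in% names(tab))
    stop("taxonomy table must have an 'accession' column")
  unknown <- setdiff(names(tab), c("accession", TAXONOMY_RANKS))
  if (length(unknown) > 0)
    stop(sprintf("unknown taxonomy columns: %s", paste(unknown, collapse = ", ")))
  tab
}

# --- database --------------------------------------------------------------

#' Build an in-memory LCA database
#'
#' Stores each signature's (flattened, scale-aligned) hashes and its
#' lineage, keyed by sample name. Every retained hash thereby maps to the
#' set of lineages of the samples containing it.
#'
#' @param signatures List of `signature` objects with scaled sketches.
#' @param taxonomy Taxonomy data.frame ([read_taxonomy()]) mapping each
#'   signature name (accession) to a lineage. Signatures missing from the
#'   table are skipped with a warning (count in attribute `n_skipped` —
#'   see the return value).
#' @param ksize K size to index.
#' @param scaled Common scale; defaults to the coarsest scale among the
#'   signatures (finer sketches are downsampled).
#' @return An object of class `lca_db` with an `n_skipped` attribute.
#' @export
lca_index <- function(signatures, taxonomy, ksize = NULL, scaled = NULL) {
  if (inherits(signatures, "signature")) signatures <- list(signatures)
  stopifnot(length(signatures) >= 1)
  nms <- vapply(signatures, `[[`, "", "name")
  if (anyDuplicated(nms))
    stop(sprintf("duplicate sample names: %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")))
  mol <- signatures[[1]]$sketches[[1]]$molecule
  sks <- lapply(signatures, sig_sketch, ksize = ksize, molecule = mol)
  if (any(!vapply(sks, is_scaled, TRUE)))
    stop("LCA indexing requires scaled-mode sketches")
  if (is.null(scaled)) scaled <- max(vapply(sks, `[[`, 0L, "scaled"))
  sks <- lapply(sks, downsample, new_scaled = scaled)

  keep <- nms %in% taxonomy$accession
  n_skipped <- sum(!keep)
  if (n_skipped > 0) {
    warning(sprintf("%d signature(s) missing from the taxonomy were skipped: %s",
                    n_skipped, paste(nms[!keep], collapse = ", ")))
  }
  if (!any(keep)) stop("no signature has a taxonomy entry")
  lineages <- lapply(nms[keep], function(n) {
    lineage_from_row(taxonomy[taxonomy$accession == n, , drop = FALSE][1, ])
  })
  db <- structure(
    list(
      ksize = sks[[1]]$ksize, molecule = mol, seed = sks[[1]]$seed,
      scaled = as.integer(scaled),
      samples = stats::setNames(lapply(sks[keep], `[[`, "mins"), nms[keep]),
      lineages = stats::setNames(lineages, nms[keep])
    ),
    class = "lca_db"
  )
  attr(db, "n_skipped") <- n_skipped
  db
}

#' @export
print.lca_db <- function(x, ...) {
  cat(sprintf("<lca_db: %d samples, k=%d %s scaled=%d>\n",
              length(x$samples), x$ksize, x$molecule, x$scaled))
  invisible(x)
}

# Sample hash lists at an effective (possibly coarser) scale.
lca_sample_mins <- function(db, s_eff) {
  if (s_eff == db$scaled) return(db$samples)
  cap <- max_hash_for_scaled(s_eff)
  lapply(db$samples, hashes_below, max_hash = cap)
}

lca_sample_sketches <- function(db, s_eff = db$scaled) {
  params <- sketch_params(db$ksize, scaled = s_eff, molecule = db$molecule,
                          seed = db$seed)
  lapply(lca_sample_mins(db, s_eff), function(m) sketch_from_hashes(params, m))
}

align_query_to_db <- function(db, query) {
  query <- query_sketch_for(db, query)
  s_eff <- max(query$scaled, db$scaled)
  list(query = downsample(query, s_eff), s_eff = s_eff)
}

# Per-hash LCA lineages for a set of query hashes. Returns a list parallel
# to the classifiable hashes plus the classifiable hash vector itself.
per_hash_lca <- function(db, qmins, s_eff) {
  smins <- lca_sample_mins(db, s_eff)
  member <- vapply(smins, function(m) qmins %in% m,
                   logical(length(qmins)))
  member <- matrix(member, nrow = length(qmins),
                   dimnames = list(NULL, names(smins)))
  classifiable <- which(rowSums(member) > 0)
  lcas <- lapply(classifiable, function(i) {
    lca_of(db$lineages[member[i, ]])
  })
  list(hashes = qmins[classifiable], lcas = lcas)
}

#' Classify a query sketch against an LCA database
#'
#' Each query hash found in the database is assigned the LCA of the
#' lineages of all samples containing it. The reported lineage is the
#' deepest one whose cumulative hash support reaches the `majority`
#' fraction of classifiable hashes (default 1.0, strict consensus). Status
#' is `"nomatch"` when no query hash is in the database, `"disagree"` when
#' even the highest rank lacks a consensus, and `"found"` otherwise.
#'
#' @param db An `lca_db`.
#' @param query A `minhash` sketch or single-sketch `signature`.
#' @param majority Required support fraction `F` in `(0, 1]`.
#' @return A list with `lineage` (character vector by rank), `status`,
#'   `support` (fraction of classifiable hashes supporting the lineage),
#'   `n_classified` and `n_query`.
#' @export
lca_classify <- function(db, query, majority = 1.0) {
  stopifnot(majority > 0, majority <= 1)
  al <- align_query_to_db(db, query)
  qmins <- al$query$mins
  ph <- per_hash_lca(db, qmins, al$s_eff)
  n <- length(ph$hashes)
  if (n == 0) {
    return(list(lineage = character(0), status = "nomatch", support = 0,
                n_classified = 0L, n_query = length(qmins)))
  }
  counts <- prefix_support(ph$lcas)
  need <- majority * n
  ok <- counts$count >= need - 1e-9
  if (!any(ok)) {
    return(list(lineage = character(0), status = "disagree", support = 0,
                n_classified = n, n_query = length(qmins)))
  }
  cand <- counts[ok, , drop = FALSE]
  pick <- cand[order(-cand$depth, -cand$count, cand$lineage,
                     method = "radix")[1], ]
  list(
    lineage = strsplit(pick$lineage, ";", fixed = TRUE)[[1]],
    status = "found",
    support = pick$count / n,
    n_classified = n,
    n_query = length(qmins)
  )
}

# Count, for every observed lineage prefix, how many per-hash LCAs it is a
# prefix of (a hash counted at its LCA contributes to every prefix).
prefix_support <- function(lcas) {
  all_prefixes <- unlist(lapply(lcas, function(lin) {
    if (length(lin) == 0) return(character(0))
    vapply(seq_along(lin), function(d) lineage_str(lin[seq_len(d)]), "")
  }))
  if (length(all_prefixes) == 0) {
    return(data.frame(lineage = character(0), depth = integer(0),
                      count = integer(0), stringsAsFactors = FALSE))
  }
  tab <- table(all_prefixes)
  data.frame(
    lineage = names(tab),
    depth = lengths(strsplit(names(tab), ";", fixed = TRUE)),
    count = as.integer(tab),
    stringsAsFactors = FALSE
  )
}

#' Summarize the taxonomic mixture in one or more query sketches
#'
#' Assigns each classifiable hash (of each query) to the LCA of its
#' lineages, then aggregates counts up the taxonomy: a hash counted at its
#' LCA contributes to every prefix of that lineage. Fractions are relative
#' to the total number of classifiable hashes; rows are sorted by count
#' descending.
#'
#' @param db An `lca_db`.
#' @param queries A query or list of queries (`minhash` sketches or
#'   single-sketch `signature`s).
#' @return A data.frame with columns `rank`, `lineage`, `count`,
#'   `fraction`, plus attributes `n_classified` and `n_query_hashes`.
#' @export
lca_summarize <- function(db, queries) {
  if (!is.list(queries) || inherits(queries, c("minhash", "signature")))
    queries <- list(queries)
  stopifnot(length(queries) >= 1)
  all_lcas <- list()
  n_class <- 0L
  n_total <- 0L
  for (qry in queries) {
    al <- align_query_to_db(db, qry)
    ph <- per_hash_lca(db, al$query$mins, al$s_eff)
    all_lcas <- c(all_lcas, ph$lcas)
    n_class <- n_class + length(ph$hashes)
    n_total <- n_total + length(al$query$mins)
  }
  counts <- prefix_support(all_lcas)
  counts <- counts[order(-counts$count, counts$depth, counts$lineage,
                         method = "radix"), , drop = FALSE]
  rownames(counts) <- NULL
  out <- data.frame(
    rank = TAXONOMY_RANKS[counts$depth],
    lineage = counts$lineage,
    count = counts$count,
    fraction = if (n_class > 0) counts$count / n_class else numeric(0),
    stringsAsFactors = FALSE
  )
  attr(out, "n_classified") <- n_class
  attr(out, "n_query_hashes") <- n_total
  out
}

# --- search/gather backend -------------------------------------------------

#' @export
index_search.lca_db <- function(index, query, threshold = 0.08,
                                mode = c("similarity", "containment")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold <= 1)
  query <- query_sketch_for(index, query)
  sks <- lca_sample_sketches(index)
  linear_search(names(index$samples), sks, query, threshold, mode)
}

#' @export
best_overlap.lca_db <- function(db, mins, scaled) {
  sks <- lca_sample_sketches(db, scaled)
  best_from_leaves(names(sks), sks, mins, scaled)
}

# --- persistence -----------------------------------------------------------

#' Save an LCA database to a JSON file
#'
#' @param db An `lca_db`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
lca_save <- function(db, path) {
  stopifnot(inherits(db, "lca_db"))
  payload <- list(
    format = "minhashr_lca", version = 1L,
    ksize = db$ksize, molecule = db$molecule, seed = db$seed,
    scaled = db$scaled,
    samples = lapply(db$samples, as.list),
    lineages = lapply(db$lineages, as.list)
  )
  writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                              null = "null"), path)
  invisible(path)
}

#' Load an LCA database from a JSON file
#'
#' @param path Path written by [lca_save()].
#' @return An `lca_db`.
#' @export
lca_load <- function(path) {
  x <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (!identical(x$format, "minhashr_lca"))
    stop_with("minhashr_parse_error", "'%s' is not an LCA database file", path)
  structure(
    list(
      ksize = as.integer(x$ksize), molecule = x$molecule,
      seed = as.numeric(x$seed), scaled = as.integer(x$scaled),
      samples = lapply(x$samples, function(m) sort_hashes(unlist(m))),
      lineages = lapply(x$lineages, function(l) as.character(unlist(l)))
    ),
    class = "lca_db"
  )
}
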