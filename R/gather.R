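# Greedy best-first metagenome decomposition. Each round finds, across all
# databases, the reference sketch with the largest overlap with the
# remaining query, reports it, subtracts its hashes from the query, and
# repeats until the best overlap falls below a bp threshold.

as_query_sketch <- function(query) {
  if (inherits(query, "signature")) {
    if (length(query$sketches) != 1)
      stop("query signature holds several sketches; pass a single sketch")
    query <- query$sketches[[1]]
  }
  stopifnot(inherits(query, "minhash"))
  query
}

# Best-overlap candidate in one database against `mins` (hashes at scale
# `scaled`): list(name, count, leaf_size, mins). Ties are not broken here;
# candidates() returns all leaves achieving the maximum count.
best_overlap <- function(db, mins, scaled) UseMethod("best_overlap")

best_from_leaves <- function(names, sketches, mins, scaled) {
  if (length(sketches) == 0) return(NULL)
  entries <- lapply(seq_along(sketches), function(i) {
    sk <- downsample(sketches[[i]], scaled)
    list(name = names[i],
         count = length(intersect(mins, sk$mins)),
         leaf_size = length(sk$mins),
         mins = sk$mins)
  })
  counts <- vapply(entries, `[[`, 0, "count")
  entries[counts == max(counts)]
}

#' @export
best_overlap.leaf_list <- function(db, mins, scaled) {
  best_from_leaves(db$names, db$sketches, mins, scaled)
}

#' @export
best_overlap.sbt_index <- function(db, mins, scaled) {
  if (is.null(db$root)) return(NULL)
  best <- list(count = -1)
  cands <- list()
  visit <- function(node) {
    if (node_is_leaf(node)) {
      sk <- downsample(node$sketch, scaled)
      cnt <- length(intersect(mins, sk$mins))
      if (cnt > best$count) {
        best <<- list(count = cnt)
        cands <<- list(list(name = node$name, count = cnt,
                            leaf_size = length(sk$mins), mins = sk$mins))
      } else if (cnt == best$count) {
        cands[[length(cands) + 1L]] <<- list(
          name = node$name, count = cnt,
          leaf_size = length(sk$mins), mins = sk$mins
        )
      }
      return(invisible(NULL))
    }
    # m_v bounds |remaining n L| for every descendant leaf; explore
    # children best-bound-first, pruning only strictly dominated subtrees
    bounds <- vapply(node$children, function(ch) {
      if (node_is_leaf(ch)) {
        sum(ch$sketch$mins %in% mins)
      } else {
        sum(bloom_contains(ch$filter, mins))
      }
    }, 0)
    for (i in order(-bounds)) {
      if (bounds[i] < best$count) next
      visit(node$children[[i]])
    }
    invisible(NULL)
  }
  visit(db$root)
  if (best$count < 0) NULL else cands
}

# Deterministic tie-break among equal-count candidates: smaller leaf first
# (higher p_match), then lexicographically smaller name.
pick_candidate <- function(cands) {
  sizes <- vapply(cands, `[[`, 0, "leaf_size")
  nms <- vapply(cands, `[[`, "", "name")
  cands[[order(sizes, nms, method = "radix")[1]]]
}

#' Greedy decomposition of a query against reference databases
#'
#' Repeatedly finds the reference with the largest hash overlap with the
#' remaining query (best-first, across all databases), records it, removes
#' its hashes from the query, and repeats until the best remaining overlap
#' represents fewer than `threshold_bp` base pairs. `p_query` is reported
#' relative to the ORIGINAL query, so the per-match values sum to the total
#' recovered fraction; `p_match` is the fraction of the match covered by
#' the remaining query at that step. Ties are broken toward the smaller
#' reference, then by name.
#'
#' @param databases An index (`sbt_index`, `lca_db`, or list of signatures)
#'   or a list of such databases.
#' @param query A scaled `minhash` sketch or single-sketch `signature`.
#' @param threshold_bp Minimum overlap, in estimated bp, for a match to be
#'   reported (default `3 * scaled`).
#' @return A data.frame with columns `name`, `overlap_bp`, `p_query`,
#'   `p_match`, `avg_abund`, `n_intersect`; attributes `intersect_hashes`
#'   (list of the disjoint per-match hash sets), `recovered` (total
#'   fraction of the original query recovered) and `scaled`.
#' @export
gather <- function(databases, query, threshold_bp = NULL) {
  if (inherits(databases, c("sbt_index", "lca_db")) ||
      (is.list(databases) && length(databases) > 0 &&
       inherits(databases[[1]], "signature"))) {
    databases <- list(databases)
  }
  if (length(databases) == 0) stop("no databases supplied")
  query <- as_query_sketch(query)
  if (!is_scaled(query)) stop("gather requires a scaled-mode query")
  if (length(query$mins) == 0) stop("empty query sketch")

  # normalize plain signature lists into (name, sketch) leaf lists matched
  # to the query's k and molecule
  databases <- lapply(databases, function(db) {
    if (inherits(db, c("sbt_index", "lca_db"))) return(db)
    sks <- lapply(db, function(s) {
      sig_sketch(s, ksize = query$ksize, molecule = query$molecule)
    })
    structure(list(names = vapply(db, `[[`, "", "name"), sketches = sks,
                   scaled = sks[[1]]$scaled),
              class = "leaf_list")
  })
  db_scaled <- vapply(databases, function(db) db$scaled, 0L)
  s_eff <- max(query$scaled, db_scaled)
  q <- downsample(query, s_eff)
  orig_mins <- q$mins
  orig_n <- length(orig_mins)
  if (orig_n == 0) stop("query sketch is empty after downsampling to the database scale")
  if (is.null(threshold_bp)) threshold_bp <- 3 * s_eff

  remaining <- orig_mins
  res <- list()
  isects <- list()
  repeat {
    if (length(remaining) == 0) break
    cands <- list()
    for (db in databases) {
      c_db <- best_overlap(db, remaining, s_eff)
      if (!is.null(c_db)) cands <- c(cands, c_db)
    }
    if (length(cands) == 0) break
    counts <- vapply(cands, `[[`, 0, "count")
    best <- pick_candidate(cands[counts == max(counts)])
    if (best$count * s_eff < threshold_bp || best$count == 0) break
    isect <- sort_hashes(intersect(remaining, best$mins))
    avg_abund <- if (q$track_abundance) mean(q$abund[isect]) else NA_real_
    res[[length(res) + 1L]] <- data.frame(
      name = best$name,
      overlap_bp = best$count * as.numeric(s_eff),
      p_query = best$count / orig_n,
      p_match = best$count / best$leaf_size,
      avg_abund = avg_abund,
      n_intersect = best$count,
      stringsAsFactors = FALSE
    )
    isects[[length(isects) + 1L]] <- isect
    remaining <- hash_setdiff(remaining, best$mins)
  }
  out <- if (length(res) == 0) {
    data.frame(name = character(0), overlap_bp = numeric(0),
               p_query = numeric(0), p_match = numeric(0),
               avg_abund = numeric(0), n_intersect = numeric(0),
               stringsAsFactors = FALSE)
  } else {
    do.call(rbind, res)
  }
  attr(out, "intersect_hashes") <- isects
  attr(out, "recovered") <- sum(out$p_query)
  attr(out, "scaled") <- s_eff
  out
}
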