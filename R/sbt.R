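# Sequence Bloom Tree over MinHash leaves (SBTMH). Leaves hold sketches;
# each internal node holds a Bloom filter containing every hash of every
# descendant leaf, plus the cardinality of the smallest descendant leaf,
# which makes the similarity bound provable (see search).

# --- Bloom filter ----------------------------------------------------------

# Size a filter for `n_expected` elements at false-positive target `fp`.
bloom_new <- function(n_expected, fp) {
  n_expected <- max(1, n_expected)
  m <- max(64, ceiling(-n_expected * log(fp) / log(2)^2))
  nh <- max(1, round(m / n_expected * log(2)))
  list(bits = raw(ceiling(m / 8)), num_funcs = as.integer(nh),
       element_count = 0L)
}

bloom_add <- function(bf, hashes) {
  if (length(hashes) == 0) return(bf)
  bf$bits <- cpp_bloom_add(bf$bits, hashes, bf$num_funcs)
  bf$element_count <- bf$element_count + length(hashes)
  bf
}

bloom_contains <- function(bf, hashes) {
  if (length(hashes) == 0) return(logical(0))
  cpp_bloom_query(bf$bits, hashes, bf$num_funcs)
}

# --- tree nodes ------------------------------------------------------------

sbt_leaf <- function(name, sketch) {
  list(type = "leaf", name = name, sketch = sketch)
}

node_is_leaf <- function(node) identical(node$type, "leaf")

node_n_leaves <- function(node) {
  if (node_is_leaf(node)) 1L else node$n_leaves
}

node_min_leaf_n <- function(node) {
  if (node_is_leaf(node)) length(node$sketch$mins) else node$min_leaf_n
}

node_all_hashes <- function(node) {
  if (node_is_leaf(node)) return(node$sketch$mins)
  unique(unlist(lapply(node$children, node_all_hashes), use.names = FALSE))
}

node_leaves <- function(node) {
  if (node_is_leaf(node)) return(list(node))
  do.call(c, lapply(node$children, node_leaves))
}

# Internal node over a list of children; filter sized with 2x growth
# headroom for later inserts (filters are never resized: a tree whose
# filters saturate can only over-visit, never miss — rebuild to re-tighten).
sbt_internal <- function(children, fp_target) {
  hashes <- unique(unlist(lapply(children, node_all_hashes), use.names = FALSE))
  bf <- bloom_new(2 * max(length(hashes), 1), fp_target)
  bf <- bloom_add(bf, hashes)
  list(
    type = "internal",
    filter = bf,
    min_leaf_n = min(vapply(children, node_min_leaf_n, 0L)),
    n_leaves = sum(vapply(children, node_n_leaves, 0L)),
    children = children
  )
}

# --- index -----------------------------------------------------------------

sbt_check_sig <- function(index, sig) {
  sk <- sig_sketch(sig, ksize = index$ksize, molecule = index$molecule)
  if (!is_scaled(sk)) stop("SBT indexing requires scaled-mode sketches")
  if (sk$seed != index$seed || sk$scaled != index$scaled) {
    stop(sprintf(
      "signature '%s' is incompatible with the index (seed %g/scaled %d vs seed %g/scaled %d)",
      sig$name, sk$seed, sk$scaled, index$seed, index$scaled
    ))
  }
  sk
}

#' Build a Sequence Bloom Tree index over signatures
#'
#' Leaves are MinHash sketches; every internal node's Bloom filter contains
#' all values of all descendant leaves, so the root contains every hash in
#' the index. Nodes also store the cardinality of the smallest leaf below
#' them, which is what makes the pruned similarity bound valid.
#'
#' @param signatures List of `signature` objects with comparable
#'   scaled-mode sketches (same k, molecule, seed, scaled).
#' @param ksize K size to index (needed if signatures hold several sketches).
#' @param arity Maximum children per internal node (default binary).
#' @param fp_target Bloom-filter false-positive target at design load.
#' @return An object of class `sbt_index`.
#' @export
sbt_build <- function(signatures, ksize = NULL, arity = 2, fp_target = 0.05) {
  if (inherits(signatures, "signature")) signatures <- list(signatures)
  stopifnot(length(signatures) >= 1, arity >= 2)
  sk1 <- sig_sketch(signatures[[1]], ksize = ksize,
                    molecule = signatures[[1]]$sketches[[1]]$molecule)
  if (!is_scaled(sk1)) stop("SBT indexing requires scaled-mode sketches")
  index <- structure(
    list(
      ksize = sk1$ksize, molecule = sk1$molecule, seed = sk1$seed,
      scaled = sk1$scaled, arity = as.integer(arity),
      fp_target = fp_target, root = NULL
    ),
    class = "sbt_index"
  )
  bad <- character(0)
  for (sig in signatures) {
    ok <- tryCatch({ sbt_check_sig(index, sig); TRUE },
                   error = function(e) FALSE)
    if (!ok) bad <- c(bad, sig$name)
  }
  if (length(bad) > 0) {
    stop(sprintf("signatures with mismatched parameters: %s",
                 paste(bad, collapse = ", ")))
  }
  for (sig in signatures) index <- sbt_insert(index, sig)
  index
}

#' @export
print.sbt_index <- function(x, ...) {
  n <- if (is.null(x$root)) 0L else node_n_leaves(x$root)
  cat(sprintf("<sbt_index: %d leaves, k=%d %s scaled=%d arity=%d>\n",
              n, x$ksize, x$molecule, x$scaled, x$arity))
  invisible(x)
}

#' Insert a signature into an SBT index
#'
#' Only the ancestors of the new leaf are modified (their filters gain the
#' new hashes and their minimum-leaf cardinalities are updated); all other
#' nodes are untouched. Placement descends toward the child whose filter
#' shares the most hashes with the new sketch (best fit).
#'
#' @param index An `sbt_index`.
#' @param sig A compatible `signature`.
#' @return The updated index.
#' @export
sbt_insert <- function(index, sig) {
  stopifnot(inherits(index, "sbt_index"))
  sk <- sbt_check_sig(index, sig)
  leaf <- sbt_leaf(sig$name, sk)
  index$root <- if (is.null(index$root)) leaf
                else insert_node(index$root, leaf, index$arity, index$fp_target)
  index
}

insert_node <- function(node, leaf, arity, fp_target) {
  if (node_is_leaf(node)) {
    return(sbt_internal(list(node, leaf), fp_target))
  }
  if (length(node$children) < arity) {
    node$children <- c(node$children, list(leaf))
  } else {
    # best fit: most hashes of the new leaf present in the child
    scores <- vapply(node$children, function(ch) {
      if (node_is_leaf(ch)) {
        length(intersect(leaf$sketch$mins, ch$sketch$mins))
      } else {
        sum(bloom_contains(ch$filter, leaf$sketch$mins))
      }
    }, 0)
    i <- which.max(scores)
    node$children[[i]] <- insert_node(node$children[[i]], leaf, arity,
                                      fp_target)
  }
  node$filter <- bloom_add(node$filter, leaf$sketch$mins)
  node$min_leaf_n <- min(node$min_leaf_n, length(leaf$sketch$mins))
  node$n_leaves <- node$n_leaves + 1L
  node
}

#' Combine two SBT indexes
#'
#' Joins the trees under a new root whose filter is updated with the
#' content of the previous roots; no other node changes. Searches over the
#' combined tree return the union of results over the parts.
#'
#' @param a,b `sbt_index` objects with identical parameters.
#' @return The combined `sbt_index`.
#' @export
sbt_combine <- function(a, b) {
  stopifnot(inherits(a, "sbt_index"), inherits(b, "sbt_index"))
  for (field in c("ksize", "molecule", "seed", "scaled")) {
    if (!identical(a[[field]], b[[field]]))
      stop(sprintf("incompatible indexes: %s differs", field))
  }
  if (is.null(a$root)) return(b)
  if (is.null(b$root)) return(a)
  a$root <- sbt_internal(list(a$root, b$root), a$fp_target)
  a$arity <- max(a$arity, b$arity, 2L)
  a
}

# --- search ----------------------------------------------------------------

# Provable upper bounds at an internal node, given m_v = number of query
# hashes present in the node filter (>= true |Q n L| for any descendant
# leaf L, since Bloom filters have no false negatives) and
# min_leaf_n <= |L|:
#   jaccard(Q, L)    = |QnL| / (|Q| + |L| - |QnL|) <= m_v / (|Q| + min_leaf_n - m_v)
#   containment(Q,L) = |QnL| / |Q|                 <= m_v / |Q|
sbt_sim_bound <- function(m_v, q_size, min_leaf_n) {
  m_v / (q_size + max(min_leaf_n, m_v) - m_v)
}

sbt_cont_bound <- function(m_v, q_size) m_v / q_size

#' Search an index for similar or containing signatures
#'
#' Returns exactly the leaves whose true Jaccard similarity (mode
#' `"similarity"`) or containment of the query in the leaf (mode
#' `"containment"`) reaches `threshold`, sorted by score descending then
#' name ascending. Subtrees are pruned using per-node upper bounds that can
#' never exclude a true result; Bloom-filter false positives only cost
#' extra node visits.
#'
#' @param index An `sbt_index`, `lca_db`, or plain list of signatures.
#' @param query A `minhash` sketch or `signature`.
#' @param threshold Score threshold in `(0, 1]` (default 0.08).
#' @param mode `"similarity"` or `"containment"`.
#' @return A data.frame with columns `name`, `score`, `digest`.
#' @export
index_search <- function(index, query, threshold = 0.08,
                         mode = c("similarity", "containment")) {
  UseMethod("index_search")
}

query_sketch_for <- function(index, query) {
  if (inherits(query, "signature"))
    query <- sig_sketch(query, ksize = index$ksize, molecule = index$molecule)
  stopifnot(inherits(query, "minhash"))
  if (length(query$mins) == 0) stop("empty query sketch")
  if (query$ksize != index$ksize || query$molecule != index$molecule ||
      query$seed != index$seed) {
    stop("query parameters (k/molecule/seed) do not match the index")
  }
  if (!is_scaled(query)) stop("index search requires a scaled-mode query")
  query
}

search_result <- function(names, scores, sketches) {
  digests <- vapply(sketches, sketch_digest, "")
  o <- order(-scores, names, method = "radix")
  data.frame(name = names, score = scores, digest = digests,
             stringsAsFactors = FALSE)[o, , drop = FALSE]
}

# Exhaustive scoring over leaf sketches (used for coarse queries and the
# non-tree backends; also the reference the pruned search must agree with).
linear_search <- function(leaf_names, leaf_sketches, query, threshold, mode) {
  scores <- vapply(leaf_sketches, function(sk) {
    if (mode == "similarity") jaccard(query, sk) else containment(query, sk)
  }, 0)
  keep <- scores >= threshold
  search_result(leaf_names[keep], scores[keep], leaf_sketches[keep])
}

#' @export
index_search.sbt_index <- function(index, query, threshold = 0.08,
                                   mode = c("similarity", "containment")) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold <= 1)
  query <- query_sketch_for(index, query)
  if (is.null(index$root)) {
    return(search_result(character(0), numeric(0), list()))
  }
  if (query$scaled > index$scaled) {
    # leaves would need downsampling, invalidating stored min_leaf_n
    # bounds; fall back to an exhaustive scan
    leaves <- node_leaves(index$root)
    return(linear_search(
      vapply(leaves, `[[`, "", "name"),
      lapply(leaves, `[[`, "sketch"), query, threshold, mode
    ))
  }
  query <- downsample(query, index$scaled)
  qmins <- query$mins
  qn <- length(qmins)
  if (qn == 0) stop("query sketch is empty after downsampling to the index scale")
  hits_names <- character(0)
  hits_scores <- numeric(0)
  hits_sketches <- list()
  eps <- 1e-9
  visit <- function(node) {
    if (node_is_leaf(node)) {
      score <- if (mode == "similarity") jaccard(query, node$sketch)
               else containment(query, node$sketch)
      if (score >= threshold) {
        hits_names <<- c(hits_names, node$name)
        hits_scores <<- c(hits_scores, score)
        hits_sketches[[length(hits_sketches) + 1L]] <<- node$sketch
      }
      return(invisible(NULL))
    }
    m_v <- sum(bloom_contains(node$filter, qmins))
    bound <- if (mode == "similarity") sbt_sim_bound(m_v, qn, node$min_leaf_n)
             else sbt_cont_bound(m_v, qn)
    if (bound < threshold - eps) return(invisible(NULL))
    for (ch in node$children) visit(ch)
    invisible(NULL)
  }
  visit(index$root)
  search_result(hits_names, hits_scores, hits_sketches)
}

#' @export
index_search.list <- function(index, query, threshold = 0.08,
                              mode = c("similarity", "containment")) {
  mode <- match.arg(mode)
  stopifnot(all(vapply(index, inherits, TRUE, "signature")))
  query <- as_query_sketch(query)
  sks <- lapply(index, function(s) sig_sketch(s, ksize = query$ksize,
                                              molecule = query$molecule))
  linear_search(vapply(index, `[[`, "", "name"), sks, query, threshold, mode)
}

# --- persistence -----------------------------------------------------------

#' Save an SBT index to a directory
#'
#' Writes a JSON manifest (parameters and tree structure) plus one file per
#' node: leaves as signature JSON, internal filters as hex-encoded bit
#' arrays, so nodes can be inspected or loaded individually.
#'
#' @param index An `sbt_index`.
#' @param path Output directory (created if needed).
#' @return `path`, invisibly.
#' @export
sbt_save <- function(index, path) {
  stopifnot(inherits(index, "sbt_index"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  counter <- new.env()
  counter$i <- 0L
  dump_node <- function(node) {
    counter$i <- counter$i + 1L
    id <- counter$i
    if (node_is_leaf(node)) {
      fn <- sprintf("leaf%04d.sig.json", id)
      save_signatures(signature(node$sketch, name = node$name),
                      file.path(path, fn))
      list(type = "leaf", name = node$name, file = fn)
    } else {
      kids <- lapply(node$children, dump_node)
      fn <- sprintf("node%04d.bf.json", id)
      writeLines(jsonlite::toJSON(list(
        bits = paste(as.character(node$filter$bits), collapse = ""),
        num_funcs = node$filter$num_funcs,
        element_count = node$filter$element_count
      ), auto_unbox = TRUE), file.path(path, fn))
      list(type = "internal", file = fn, min_leaf_n = node$min_leaf_n,
           n_leaves = node$n_leaves, children = kids)
    }
  }
  manifest <- list(
    format = "minhashr_sbt", version = 1L,
    ksize = index$ksize, molecule = index$molecule, seed = index$seed,
    scaled = index$scaled, arity = index$arity, fp_target = index$fp_target,
    tree = if (is.null(index$root)) NULL else dump_node(index$root)
  )
  writeLines(jsonlite::toJSON(manifest, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             file.path(path, "manifest.json"))
  invisible(path)
}

#' Load an SBT index from a directory
#'
#' @param path Directory written by [sbt_save()].
#' @return An `sbt_index`.
#' @export
sbt_load <- function(path) {
  mf <- jsonlite::fromJSON(file.path(path, "manifest.json"),
                           simplifyVector = FALSE)
  if (!identical(mf$format, "minhashr_sbt"))
    stop_with("minhashr_parse_error", "'%s' is not an SBT index directory", path)
  read_node <- function(spec) {
    if (identical(spec$type, "leaf")) {
      sig <- load_signatures(file.path(path, spec$file))[[1]]
      sbt_leaf(spec$name, sig$sketches[[1]])
    } else {
      kids <- lapply(spec$children, read_node)
      bf_raw <- jsonlite::fromJSON(file.path(path, spec$file),
                                   simplifyVector = FALSE)
      bits_hex <- bf_raw$bits
      bits <- as.raw(strtoi(substring(bits_hex,
                                      seq(1, nchar(bits_hex), 2),
                                      seq(2, nchar(bits_hex), 2)), 16L))
      list(
        type = "internal",
        filter = list(bits = bits,
                      num_funcs = as.integer(bf_raw$num_funcs),
                      element_count = as.integer(bf_raw$element_count)),
        min_leaf_n = as.integer(spec$min_leaf_n),
        n_leaves = as.integer(spec$n_leaves),
        children = kids
      )
    }
  }
  structure(
    list(
      ksize = as.integer(mf$ksize), molecule = mf$molecule,
      seed = as.numeric(mf$seed), scaled = as.integer(mf$scaled),
      arity = as.integer(mf$arity), fp_target = as.numeric(mf$fp_target),
      root = if (is.null(mf$tree)) NULL else read_node(mf$tree)
    ),
    class = "sbt_index"
  )
}
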