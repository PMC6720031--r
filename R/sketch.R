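#' Sketch parameters
#'
#' Parameters shared by all sketches that are to be compared: k-mer size,
#' retention mode (scaled factor `s` or bottom-n size `num`, exactly one),
#' molecule type, hash seed and the abundance-tracking flag.
#'
#' In scaled mode the 2^64 hash space is divided into `s` equal bands and
#' every hash in the minimum band — strictly below `floor(2^64 / s)` — is
#' retained, so a fixed fraction 1/s of distinct k-mers is kept and sketch
#' size grows with input complexity. In num mode the `num` smallest hashes
#' ever observed are kept (classic bottom-n MinHash).
#'
#' @param ksize Positive integer k-mer length (bases or residues).
#' @param scaled Positive integer scaling factor `s`, or `NULL`.
#' @param num Positive integer bottom-n size, or `NULL`.
#' @param molecule `"DNA"` (canonicalized) or `"protein"` (not).
#' @param seed Hash seed (default 42).
#' @param track_abundance Keep per-hash occurrence counts?
#' @return An object of class `sketch_params`.
#' @export
sketch_params <- function(ksize, scaled = NULL, num = NULL, molecule = "DNA",
                          seed = .default_seed, track_abundance = FALSE) {
  if (is.null(scaled) == is.null(num))
    stop("exactly one of `scaled` and `num` must be set")
  stopifnot(length(ksize) == 1, ksize >= 1, ksize == floor(ksize))
  molecule <- match.arg(molecule, c("DNA", "protein"))
  if (!is.null(scaled)) stopifnot(scaled >= 1, scaled == floor(scaled))
  if (!is.null(num)) stopifnot(num >= 1, num == floor(num))
  structure(
    list(
      ksize = as.integer(ksize),
      scaled = if (is.null(scaled)) NA_integer_ else as.integer(scaled),
      num = if (is.null(num)) NA_integer_ else as.integer(num),
      molecule = molecule,
      seed = as.numeric(seed),
      track_abundance = isTRUE(track_abundance)
    ),
    class = "sketch_params"
  )
}

is_scaled <- function(x) !is.na(x$scaled)

params_of <- function(sk) {
  sketch_params(sk$ksize,
    scaled = if (is.na(sk$scaled)) NULL else sk$scaled,
    num = if (is.na(sk$num)) NULL else sk$num,
    molecule = sk$molecule, seed = sk$seed,
    track_abundance = sk$track_abundance
  )
}

#' Create an empty MinHash sketch
#'
#' @param params A [sketch_params()] object.
#' @return An object of class `minhash` with no retained hashes.
#' @export
new_sketch <- function(params) {
  stopifnot(inherits(params, "sketch_params"))
  sk <- unclass(params)
  sk$mins <- character(0)
  sk$abund <- if (params$track_abundance) {
    stats::setNames(numeric(0), character(0))
  } else {
    NULL
  }
  class(sk) <- "minhash"
  sk
}

#' Build a sketch directly from hash values
#'
#' Mainly useful for constructing fixtures and for index internals; the
#' hashes must already respect the retention rule of `params`.
#'
#' @param params A [sketch_params()] object.
#' @param hashes Character vector of decimal hash values.
#' @param abundances Optional numeric vector of counts parallel to `hashes`.
#' @return A `minhash` sketch.
#' @export
sketch_from_hashes <- function(params, hashes, abundances = NULL) {
  sk <- new_sketch(params)
  o <- order(nchar(hashes), hashes, method = "radix")
  hashes <- hashes[o]
  dup <- duplicated(hashes)
  sk$mins <- hashes[!dup]
  if (sk$track_abundance) {
    ab <- if (is.null(abundances)) rep(1, length(hashes)) else abundances[o]
    sk$abund <- vapply(split(ab, factor(hashes, levels = sk$mins)), sum, 0)
  } else if (!is.null(abundances)) {
    stop("abundances supplied but params do not track abundance")
  }
  sk
}

#' Sketch one or more sequences
#'
#' Convenience wrapper: creates an empty sketch and adds the sequences.
#'
#' @param sequence Character vector of sequences.
#' @inheritParams new_sketch
#' @return A `minhash` sketch.
#' @export
sketch_sequence <- function(sequence, params) {
  add_sequence(new_sketch(params), sequence)
}

#' Add sequence data to a sketch
#'
#' In scaled mode every produced hash below the retention threshold
#' `floor(2^64 / s)` is inserted (set-idempotent; abundance incremented per
#' occurrence) and no retained hash is ever evicted — the streaming
#' guarantee. In num mode the running set of the `num` smallest hashes is
#' maintained.
#'
#' @param sk A `minhash` sketch.
#' @param sequence Character vector of sequences in the sketch's alphabet
#'   (translate upstream for protein sketches of DNA input).
#' @return The updated sketch.
#' @export
add_sequence <- function(sk, sequence) {
  stopifnot(inherits(sk, "minhash"))
  cap <- if (is_scaled(sk)) max_hash_for_scaled(sk$scaled) else ""
  stream <- kmer_hashes(sequence, sk$ksize, sk$molecule, sk$seed, cap)
  add_hash_stream(sk, stream)
}

# Insert a stream of (possibly repeated, pre-capped for scaled mode) hashes.
add_hash_stream <- function(sk, stream) {
  if (length(stream) == 0) return(sk)
  if (is_scaled(sk)) {
    new_mins <- hash_union(sk$mins, stream)
    if (sk$track_abundance) {
      counts <- table(stream)
      ab <- stats::setNames(numeric(length(new_mins)), new_mins)
      ab[sk$mins] <- sk$abund
      idx <- names(counts)
      ab[idx] <- ab[idx] + as.numeric(counts)
      sk$abund <- ab
    }
    sk$mins <- new_mins
  } else {
    new_mins <- hash_union(sk$mins, stream)
    keep <- head(new_mins, sk$num)
    if (sk$track_abundance) {
      counts <- table(stream)
      ab <- stats::setNames(numeric(length(keep)), keep)
      old <- intersect(keep, sk$mins)
      ab[old] <- sk$abund[old]
      inc <- intersect(keep, names(counts))
      ab[inc] <- ab[inc] + as.numeric(counts[inc])
      sk$abund <- ab
    }
    sk$mins <- keep
  }
  sk
}

#' @export
print.minhash <- function(x, ...) {
  mode <- if (is_scaled(x)) paste0("scaled=", x$scaled) else paste0("num=", x$num)
  cat(sprintf(
    "<minhash sketch: k=%d %s %s seed=%g, %d hashes%s>\n",
    x$ksize, x$molecule, mode, x$seed, length(x$mins),
    if (x$track_abundance) ", with abundance" else ""
  ))
  invisible(x)
}

# --- compatibility ---------------------------------------------------------

# Check comparability and normalize two sketches onto common parameters.
# Scaled sketches with different s are silently downsampled to the coarser
# scale (recorded in attribute "downsampled_to").
align_sketches <- function(a, b) {
  for (field in c("ksize", "molecule", "seed")) {
    if (!identical(a[[field]], b[[field]])) {
      stop(sprintf(
        "incompatible sketches: %s differs (%s vs %s)",
        field, format(a[[field]]), format(b[[field]])
      ), call. = FALSE)
    }
  }
  if (is_scaled(a) != is_scaled(b))
    stop("incompatible sketches: one is scaled, the other bottom-n", call. = FALSE)
  note <- NULL
  if (is_scaled(a) && a$scaled != b$scaled) {
    s <- max(a$scaled, b$scaled)
    a <- downsample(a, s)
    b <- downsample(b, s)
    note <- s
  }
  structure(list(a = a, b = b), downsampled_to = note)
}

# --- comparisons -----------------------------------------------------------

#' Jaccard similarity of two sketches
#'
#' `|A n B| / |A u B|` over the retained hash sets. Scaled sketches with
#' different `s` are downsampled to the coarser scale first; bottom-n
#' sketches are compared over the `n` smallest hashes of the union (classic
#' bottom-n MinHash estimator). Two empty sketches compare as 0 with a
#' warning rather than NaN.
#'
#' @param a,b `minhash` sketches with equal k, molecule and seed.
#' @return Similarity in `[0, 1]`.
#' @export
jaccard <- function(a, b) {
  al <- align_sketches(a, b)
  a <- al$a; b <- al$b
  if (length(a$mins) == 0 && length(b$mins) == 0) {
    warning("both sketches are empty; Jaccard defined as 0")
    return(0)
  }
  if (is_scaled(a)) {
    ni <- length(intersect(a$mins, b$mins))
    nu <- length(a$mins) + length(b$mins) - ni
    ni / nu
  } else {
    n <- min(a$num, b$num)
    u <- head(hash_union(a$mins, b$mins), n)
    shared <- intersect(a$mins, b$mins)
    length(intersect(u, shared)) / length(u)
  }
}

#' Containment of one sketch in another
#'
#' `|A n B| / |A|`: the fraction of `a`'s hashes found in `b`. Robust to
#' set-size disparity (e.g. a genome within a metagenome).
#'
#' @param a Query sketch (must be non-empty).
#' @param b Subject sketch.
#' @return Containment in `[0, 1]`.
#' @export
containment <- function(a, b) {
  al <- align_sketches(a, b)
  a <- al$a; b <- al$b
  if (length(a$mins) == 0)
    stop("containment undefined for an empty query sketch")
  length(intersect(a$mins, b$mins)) / length(a$mins)
}

#' Abundance-weighted cosine similarity
#'
#' Treats each sketch as a sparse count vector indexed by hash and returns
#' the cosine of the angle between them; missing hashes count as 0. Both
#' sketches must track abundance.
#'
#' @param a,b Compatible `minhash` sketches with abundances.
#' @return Cosine similarity in `[0, 1]`.
#' @export
cosine_sim <- function(a, b) {
  if (!a$track_abundance || !b$track_abundance)
    stop("cosine similarity requires abundance tracking on both sketches")
  al <- align_sketches(a, b)
  a <- al$a; b <- al$b
  na <- sqrt(sum(a$abund^2))
  nb <- sqrt(sum(b$abund^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for a zero vector")
  shared <- intersect(a$mins, b$mins)
  sum(a$abund[shared] * b$abund[shared]) / (na * nb)
}

#' Count of shared hashes between two sketches
#'
#' @param a,b Compatible `minhash` sketches.
#' @return Integer number of hashes in common (after scale alignment).
#' @export
sketch_overlap <- function(a, b) {
  al <- align_sketches(a, b)
  length(intersect(al$a$mins, al$b$mins))
}

# --- resizing --------------------------------------------------------------

#' Downsample a scaled sketch to a coarser scale
#'
#' Retains exactly the hashes below `floor(2^64 / new_scaled)`. Because the
#' retention bands nest, this equals the sketch that would have been built
#' directly at `new_scaled`.
#'
#' @param sk A scaled-mode `minhash` sketch.
#' @param new_scaled Target scale, `>=` the current scale.
#' @return The downsampled sketch.
#' @export
downsample <- function(sk, new_scaled) {
  stopifnot(inherits(sk, "minhash"))
  if (!is_scaled(sk)) stop("downsample requires a scaled-mode sketch")
  if (new_scaled < sk$scaled)
    stop("cannot downsample to a finer scale: discarded hashes cannot be recovered")
  if (new_scaled == sk$scaled) return(sk)
  keep <- hashes_below(sk$mins, max_hash_for_scaled(new_scaled))
  sk$mins <- keep
  if (sk$track_abundance) sk$abund <- sk$abund[keep]
  sk$scaled <- as.integer(new_scaled)
  sk
}

#' Convert a scaled sketch to a bottom-n sketch
#'
#' Possible whenever the requested subset retention size `n` is equal to or
#' smaller than the number of hashes in the scaled sketch: the `n` smallest
#' retained hashes are exactly the `n` smallest hashes of the full input.
#'
#' @param sk A scaled-mode `minhash` sketch.
#' @param n Bottom-n size, `n <= length of the sketch`.
#' @return A num-mode sketch holding the `n` smallest hashes.
#' @export
to_bottom_n <- function(sk, n) {
  if (!is_scaled(sk)) stop("sketch is already in bottom-n mode")
  if (n > length(sk$mins)) {
    stop(sprintf(
      "cannot convert: n (%d) exceeds the number of retained hashes (%d); conversion requires n <= sketch size",
      n, length(sk$mins)
    ))
  }
  keep <- head(sk$mins, n)
  sk$mins <- keep
  if (sk$track_abundance) sk$abund <- sk$abund[keep]
  sk$num <- as.integer(n)
  sk$scaled <- NA_integer_
  sk
}

# --- set algebra -----------------------------------------------------------

check_same_params <- function(a, b) {
  for (field in c("ksize", "molecule", "seed", "scaled", "num")) {
    if (!identical(a[[field]], b[[field]])) {
      stop(sprintf("incompatible sketches: %s differs", field), call. = FALSE)
    }
  }
}

#' Set algebra on sketches
#'
#' `sketch_merge()` takes the union of hashes, summing abundances on shared
#' hashes; `sketch_intersect()` and `sketch_subtract()` take the set
#' intersection and difference (a minus b) and return flattened
#' (abundance-free) sketches; `sketch_flatten()` drops the abundance map
#' only.
#'
#' @param a,b `minhash` sketches with identical parameters.
#' @return A `minhash` sketch.
#' @name sketch-set-ops
NULL

#' @rdname sketch-set-ops
#' @export
sketch_merge <- function(a, b) {
  check_same_params(a, b)
  mins <- hash_union(a$mins, b$mins)
  out <- a
  out$mins <- mins
  if (a$track_abundance) {
    ab <- stats::setNames(numeric(length(mins)), mins)
    ab[a$mins] <- a$abund
    ab[b$mins] <- ab[b$mins] + b$abund
    out$abund <- ab
  }
  out
}

#' @rdname sketch-set-ops
#' @export
sketch_intersect <- function(a, b) {
  check_same_params(a, b)
  out <- sketch_flatten(a)
  out$mins <- hash_intersect(a$mins, b$mins)
  out
}

#' @rdname sketch-set-ops
#' @export
sketch_subtract <- function(a, b) {
  check_same_params(a, b)
  out <- sketch_flatten(a)
  out$mins <- hash_setdiff(a$mins, b$mins)
  out
}

#' @rdname sketch-set-ops
#' @export
sketch_flatten <- function(a, b) {
  if (!missing(b)) stop("flatten takes a single sketch")
  a$abund <- NULL
  a$track_abundance <- FALSE
  a
}

#' Estimated number of distinct k-mers represented
#'
#' For a scaled sketch, `|hashes| * s` is the unbiased estimate of the
#' number of distinct k-mers in the sketched input (reported as bp for DNA).
#'
#' @param sk A scaled-mode `minhash` sketch.
#' @return Estimated distinct k-mer count.
#' @export
estimated_bp <- function(sk) {
  if (!is_scaled(sk)) stop("estimated_bp requires a scaled-mode sketch")
  length(sk$mins) * as.numeric(sk$scaled)
}
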