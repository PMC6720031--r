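#' Create a signature
#'
#' A signature is a named container of one or more sketches (possibly at
#' several k sizes or molecule types) computed from one sequence source; it
#' is the unit of persistence and of all database operations.
#'
#' @param sketches A `minhash` sketch or list of sketches; each must carry a
#'   distinct (ksize, molecule) pair.
#' @param name Signature name.
#' @param filename Source path the sketches were computed from.
#' @return An object of class `signature`.
#' @export
signature <- function(sketches, name = "", filename = "") {
  if (inherits(sketches, "minhash")) sketches <- list(sketches)
  stopifnot(all(vapply(sketches, inherits, TRUE, "minhash")))
  keys <- vapply(sketches, function(s) paste(s$ksize, s$molecule), "")
  if (anyDuplicated(keys))
    stop("sketches must carry distinct (ksize, molecule) pairs")
  structure(
    list(name = name, filename = filename, sketches = sketches,
         format_version = 1L),
    class = "signature"
  )
}

#' @export
print.signature <- function(x, ...) {
  cat(sig_describe(x), sep = "\n")
  invisible(x)
}

# Integrity digest over the parameters and sorted hash list of one sketch.
sketch_digest <- function(sk) {
  payload <- paste(sk$ksize, format(sk$seed), sk$molecule,
                   paste(sk$mins, collapse = ","), sep = ":")
  as.character(cpp_hash_strings(payload, 42))
}

#' Select a sketch from a signature
#'
#' @param sig A `signature`.
#' @param ksize Required k size, or `NULL` if the signature has one sketch.
#' @param molecule Molecule type to match.
#' @return The matching `minhash` sketch.
#' @export
sig_sketch <- function(sig, ksize = NULL, molecule = "DNA") {
  hits <- Filter(function(s) {
    (is.null(ksize) || s$ksize == ksize) && s$molecule == molecule
  }, sig$sketches)
  if (length(hits) == 0) {
    stop(sprintf(
      "signature '%s' has no %s sketch%s", sig$name, molecule,
      if (is.null(ksize)) "" else sprintf(" at k=%d", ksize)
    ))
  }
  if (length(hits) > 1)
    stop("signature has multiple sketches; specify `ksize`")
  hits[[1]]
}

# --- JSON persistence ------------------------------------------------------

sig_to_list <- function(sig) {
  list(
    class = "minhash_signature",
    format_version = sig$format_version,
    name = sig$name,
    filename = sig$filename,
    sketches = lapply(sig$sketches, function(sk) {
      list(
        ksize = sk$ksize,
        molecule = sk$molecule,
        seed = sk$seed,
        scaled = if (is_scaled(sk)) sk$scaled else NULL,
        num = if (is_scaled(sk)) NULL else sk$num,
        max_hash = if (is_scaled(sk)) max_hash_for_scaled(sk$scaled) else "",
        # mins as decimal strings: JSON numbers cannot carry 64-bit
        # integers exactly through standard parsers
        mins = as.list(sk$mins),
        abundances = if (sk$track_abundance) as.list(unname(sk$abund)) else NULL,
        digest = sketch_digest(sk)
      )
    })
  )
}

#' Save signatures to a JSON file
#'
#' The file holds a top-level JSON list of signatures. Serialization is
#' canonical — fixed key order, hashes sorted ascending — so saving the
#' same signatures twice yields byte-identical files. Hash values are
#' stored as decimal strings for exact 64-bit round trips, and each sketch
#' carries an integrity digest over (k, seed, molecule, sorted hashes) that
#' is verified on load.
#'
#' @param sigs A `signature` or list of signatures.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_signatures <- function(sigs, path) {
  if (inherits(sigs, "signature")) sigs <- list(sigs)
  stopifnot(all(vapply(sigs, inherits, TRUE, "signature")))
  json <- jsonlite::toJSON(lapply(sigs, sig_to_list),
                           auto_unbox = TRUE, digits = NA, null = "null")
  writeLines(json, path, useBytes = TRUE)
  invisible(path)
}

stop_with <- function(class, fmt, ...) {
  stop(structure(
    class = c(class, "error", "condition"),
    list(message = sprintf(fmt, ...), call = sys.call(-1))
  ))
}

list_to_sig <- function(x) {
  if (!identical(x$class, "minhash_signature"))
    stop_with("minhashr_parse_error", "not a signature record")
  if (!identical(as.integer(x$format_version), 1L))
    stop_with("minhashr_version_error", "unknown signature format_version: %s",
              format(x$format_version))
  sketches <- lapply(x$sketches, function(e) {
    params <- sketch_params(
      ksize = e$ksize,
      scaled = e$scaled, # NULL when absent
      num = e$num,
      molecule = e$molecule,
      seed = e$seed,
      track_abundance = !is.null(e$abundances)
    )
    mins <- vapply(e$mins, as.character, "")
    ab <- if (!is.null(e$abundances)) as.numeric(unlist(e$abundances)) else NULL
    sk <- sketch_from_hashes(params, mins, ab)
    if (!identical(sketch_digest(sk), e$digest))
      stop_with("minhashr_digest_error",
                "integrity digest mismatch for sketch k=%d", e$ksize)
    sk
  })
  signature(sketches, name = x$name, filename = x$filename)
}

#' Load signatures from a JSON file
#'
#' Accepts plain or gzip-compressed JSON. A truncated or malformed file
#' raises a parse error rather than loading partially; digest mismatches
#' and unknown format versions raise distinct error classes
#' (`minhashr_digest_error`, `minhashr_version_error`).
#'
#' @param path Path to a signature file.
#' @return A list of `signature` objects.
#' @export
load_signatures <- function(path) {
  if (!file.exists(path)) stop(sprintf("signature file not found: '%s'", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  on.exit(close(con))
  txt <- paste(readLines(con, warn = FALSE), collapse = "\n")
  parsed <- tryCatch(
    jsonlite::fromJSON(txt, simplifyVector = FALSE),
    error = function(e) {
      stop_with("minhashr_parse_error", "malformed signature JSON in '%s': %s",
                path, conditionMessage(e))
    }
  )
  lapply(parsed, list_to_sig)
}

# --- handling utilities ----------------------------------------------------

#' Rename a signature
#'
#' Replaces the name only; sketches and digests are untouched.
#'
#' @param sig A `signature`.
#' @param new_name Replacement name.
#' @return The renamed signature.
#' @export
sig_rename <- function(sig, new_name) {
  stopifnot(inherits(sig, "signature"))
  sig$name <- new_name
  sig
}

#' Describe a signature
#'
#' @param sig A `signature`.
#' @return Character vector of report lines: name, source filename, and one
#'   parameter block per sketch (k, molecule, scaled/num, hash count,
#'   abundance flag).
#' @export
sig_describe <- function(sig) {
  stopifnot(inherits(sig, "signature"))
  out <- c(
    sprintf("signature: %s", sig$name),
    sprintf("source file: %s", sig$filename)
  )
  for (sk in sig$sketches) {
    mode <- if (is_scaled(sk)) sprintf("scaled=%d", sk$scaled)
            else sprintf("num=%d", sk$num)
    out <- c(out, sprintf(
      "  k=%d molecule=%s %s seed=%g num_hashes=%d track_abundance=%s digest=%s",
      sk$ksize, sk$molecule, mode, sk$seed, length(sk$mins),
      tolower(sk$track_abundance), sketch_digest(sk)
    ))
  }
  out
}

# --- computing signatures from sequence files ------------------------------

#' Compute signatures from a sequence file
#'
#' Reads FASTA or FASTQ (plain or gzip; quality values ignored) and builds
#' one signature holding one sketch per requested k size. With
#' `singleton = TRUE` a separate signature is computed per record, named
#' from the record header. For protein sketches of nucleotide input each
#' record is 6-frame translated first.
#'
#' @param path Input sequence file.
#' @param ksizes Integer vector of k sizes.
#' @param scaled,num Retention mode (exactly one).
#' @param molecule `"DNA"` or `"protein"`.
#' @param seed Hash seed.
#' @param track_abundance Track per-hash counts?
#' @param singleton One signature per record instead of per file?
#' @param name Signature name; default is the file name, or the first
#'   record header with `name_from_first = TRUE`.
#' @param name_from_first Name the signature from the first record header.
#' @param input_is_protein Records are amino acid sequences (no translation).
#' @return A list of `signature` objects.
#' @export
compute_signatures <- function(path, ksizes = 31, scaled = 1000, num = NULL,
                               molecule = "DNA", seed = .default_seed,
                               track_abundance = FALSE, singleton = FALSE,
                               name = NULL, name_from_first = FALSE,
                               input_is_protein = FALSE) {
  recs <- read_sequences(path, protein = input_is_protein)
  if (!is.null(scaled) && !is.null(num))
    stop("exactly one of `scaled` and `num` may be set")
  params <- lapply(ksizes, function(k) {
    sketch_params(k, scaled = scaled, num = num, molecule = molecule,
                  seed = seed, track_abundance = track_abundance)
  })
  build_one <- function(seqs, nm) {
    sketches <- lapply(params, function(p) {
      if (molecule == "protein" && !input_is_protein) {
        sk <- new_sketch(p)
        for (s in seqs) sk <- add_sequence(sk, translate_6frames(s))
        sk
      } else {
        sketch_sequence(seqs, p)
      }
    })
    signature(sketches, name = nm, filename = path)
  }
  if (singleton) {
    lapply(seq_along(recs), function(i) build_one(recs[[i]], names(recs)[i]))
  } else {
    nm <- if (!is.null(name)) name
          else if (name_from_first) names(recs)[1]
          else basename(path)
    list(build_one(unname(unlist(recs)), nm))
  }
}
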