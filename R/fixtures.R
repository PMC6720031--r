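# Deterministic synthetic-data generation and sequence file I/O. Every
# component of the package is testable from these generators alone; no
# external downloads are required.

# Run code under a seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate a random genome sequence
#'
#' Uniform i.i.d. ACGT sequence, reproducible per seed.
#'
#' @param length Sequence length in bp.
#' @param seed RNG seed.
#' @return A single DNA string.
#' @export
random_genome <- function(length, seed) {
  with_seed(seed, paste(
    sample(c("A", "C", "G", "T"), length, replace = TRUE),
    collapse = ""
  ))
}

#' Mutate a genome by independent substitutions
#'
#' Each base is substituted, independently with probability `rate`, by a
#' base drawn uniformly from the three alternatives (never the original).
#' No indels: substitutions suffice for the k-mer identities studied here.
#'
#' @param genome A DNA string.
#' @param rate Per-base substitution probability in `[0, 1]`.
#' @param seed RNG seed.
#' @return The mutated DNA string.
#' @export
mutate_genome <- function(genome, rate, seed) {
  stopifnot(rate >= 0, rate <= 1)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    x <- strsplit(genome, "")[[1]]
    hit <- which(runif(length(x)) < rate)
    if (length(hit) > 0) {
      x[hit] <- vapply(x[hit], function(b) sample(setdiff(bases, b), 1), "")
    }
    paste(x, collapse = "")
  })
}

#' Simulate a read mixture from several genomes
#'
#' Draws reads from the genomes proportional to `weights`, with uniform
#' start positions and a fixed quality string (no error model; substitution
#' noise belongs in [mutate_genome()]).
#'
#' @param genomes Named character vector (or list) of genome sequences.
#' @param weights Numeric mixture weights (normalized internally).
#' @param read_length Read length in bp.
#' @param n_reads Number of reads.
#' @param seed RNG seed.
#' @param path Optional FASTQ output path (plain text).
#' @return Invisibly, a list with `reads` (character vector), `origin`
#'   (genome name per read) and `path`.
#' @export
make_mixture <- function(genomes, weights, read_length, n_reads, seed,
                         path = NULL) {
  genomes <- as.list(genomes)
  stopifnot(length(genomes) == length(weights), !is.null(names(genomes)))
  with_seed(seed, {
    origin <- sample(names(genomes), n_reads, replace = TRUE,
                     prob = weights / sum(weights))
    reads <- vapply(origin, function(g) {
      gseq <- genomes[[g]]
      start <- sample.int(nchar(gseq) - read_length + 1, 1)
      substr(gseq, start, start + read_length - 1)
    }, "", USE.NAMES = FALSE)
    if (!is.null(path)) {
      ids <- sprintf("@read%d origin=%s", seq_len(n_reads), origin)
      qual <- strrep("I", read_length)
      writeLines(rbind(ids, reads, "+", qual), path)
    }
    invisible(list(reads = reads, origin = origin, path = path))
  })
}

TAXONOMY_RANKS <- c("superkingdom", "phylum", "class", "order", "family",
                    "genus", "species", "strain")

#' Generate a consistent synthetic taxonomy
#'
#' Builds ranked lineages for a set of genomes with controllable sharing:
#' genomes in the same group share every rank except `species` (siblings);
#' groups within the same family share ranks down to `family`. The LCA of
#' two siblings is therefore their common prefix through `genus` by
#' construction.
#'
#' @param genome_names Accession/name per genome.
#' @param groups Integer group (genus) id per genome; defaults to one genus
#'   per genome.
#' @param genera_per_family How many genera share a family.
#' @param path Optional CSV output path (columns `accession`, then the
#'   eight canonical ranks; blank = unranked).
#' @return A data.frame taxonomy table.
#' @export
make_taxonomy <- function(genome_names, groups = seq_along(genome_names),
                          genera_per_family = 2, path = NULL) {
  stopifnot(length(groups) == length(genome_names))
  fam <- (as.integer(groups) - 1L) %/% genera_per_family + 1L
  tab <- data.frame(
    accession = genome_names,
    superkingdom = "sk_synth",
    phylum = "p_synth",
    class = "c_synth",
    order = "o_synth",
    family = paste0("f_", fam),
    genus = paste0("g_", groups),
    species = paste0("s_", genome_names),
    strain = "",
    stringsAsFactors = FALSE
  )
  if (!is.null(path)) write.csv(tab, path, row.names = FALSE)
  tab
}

# --- sequence file I/O -----------------------------------------------------

#' Read sequence records from FASTA or FASTQ
#'
#' Format is detected from the first byte (`>` FASTA, `@` FASTQ); gzip
#' accepted; quality values ignored. `path = "-"` reads FASTA/FASTQ text
#' from standard input.
#'
#' @param path Sequence file path, or `"-"`.
#' @param protein Read as amino-acid sequences?
#' @return Named list of sequence strings (names = record headers).
#' @export
read_sequences <- function(path, protein = FALSE) {
  if (identical(path, "-")) {
    lines <- readLines(file("stdin"))
    tmp <- tempfile(fileext = ".seq")
    on.exit(unlink(tmp))
    writeLines(lines, tmp)
    path <- tmp
  }
  if (!file.exists(path)) stop(sprintf("input file not found: '%s'", path))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "rt") else file(path, "rt")
  first <- readLines(con, n = 1)
  close(con)
  if (length(first) == 0) stop(sprintf("empty sequence file: '%s'", path))
  fmt <- if (startsWith(first, ">")) "fasta"
         else if (startsWith(first, "@")) "fastq"
         else stop(sprintf("unrecognized sequence format in '%s'", path))
  set <- if (protein) {
    Biostrings::readAAStringSet(path, format = fmt)
  } else {
    Biostrings::readDNAStringSet(path, format = fmt)
  }
  out <- as.list(as.character(set))
  names(out) <- names(set)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs Named character vector/list of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  seqs <- as.list(seqs)
  stopifnot(!is.null(names(seqs)))
  lines <- unlist(lapply(names(seqs), function(n) {
    c(paste0(">", n), seqs[[n]])
  }))
  writeLines(lines, path)
  invisible(path)
}
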