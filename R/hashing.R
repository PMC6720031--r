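#' Canonical form of a DNA k-mer
#'
#' Returns the lexicographically smaller of the upper-cased k-mer and its
#' reverse complement, so that a k-mer and its reverse complement hash
#' identically (strand-neutral hashing). Idempotent.
#'
#' @param kmer Character vector of DNA k-mers (A/C/G/T, case-insensitive).
#' @return Character vector of canonical k-mers.
#' @examples
#' canonical_kmer(c("ACG", "TTT", "ACGT"))
#' @export
canonical_kmer <- function(kmer) {
  cpp_canonical_kmers(kmer)
}

#' Reverse complement of DNA strings
#'
#' @param x Character vector of DNA strings.
#' @return Character vector of reverse complements (upper-cased; non-ACGT
#'   characters become `N`).
#' @export
revcomp <- function(x) {
  cpp_revcomp(x)
}

#' Hash a k-mer to a 64-bit value
#'
#' Deterministic 64-bit hash (MurmurHash3, x64 variant, low 64 bits) of a
#' string, uniform over `[0, 2^64)`. The value is returned as a decimal
#' string because R doubles cannot represent all 64-bit integers exactly.
#' DNA k-mers should be canonicalized with [canonical_kmer()] first;
#' [kmer_hashes()] does this automatically.
#'
#' @param kmer Character vector of non-empty strings.
#' @param seed Hash seed (default 42).
#' @return Character vector of decimal hash values in `[0, 2^64)`.
#' @export
hash_kmer <- function(kmer, seed = .default_seed) {
  stopifnot(all(nchar(kmer) > 0))
  cpp_hash_strings(kmer, as.numeric(seed))
}

#' Stream of k-mer hashes over a sequence
#'
#' Yields one 64-bit hash (decimal string) per valid k-mer window, in
#' sequence order. For DNA, windows are canonicalized before hashing and a
#' valid window contains only A/C/G/T (case-insensitive); for protein, only
#' the 20 standard residues are valid. Windows containing any invalid
#' character (e.g. `N`, a stop codon `*`, or an ambiguous residue `X`) are
#' skipped entirely, never substituted. A sequence shorter than `k` yields
#' an empty stream.
#'
#' @param sequence Character vector of sequences (all windows are pooled in
#'   order).
#' @param k K-mer length.
#' @param molecule `"DNA"` or `"protein"`.
#' @param seed Hash seed.
#' @param max_hash Optional decimal-string cap; only hashes strictly below
#'   it are returned (`""` = no cap).
#' @return Character vector of decimal hash values, one per retained window.
#' @export
kmer_hashes <- function(sequence, k, molecule = "DNA", seed = .default_seed,
                        max_hash = "") {
  stopifnot(k >= 1)
  molecule <- match.arg(molecule, c("DNA", "protein"))
  cpp_seq_hashes(sequence, as.integer(k), as.numeric(seed),
                 molecule == "DNA", max_hash)
}

#' Six-frame translation of a nucleotide sequence
#'
#' Translates reading frames +1, +2, +3 of the sequence and of its reverse
#' complement under the standard genetic code. Trailing partial codons are
#' dropped. Stop codons are emitted as `*` and codons containing ambiguous
#' bases as `X`; both act as window breakers in [kmer_hashes()], so protein
#' k-mers never span a stop.
#'
#' @param nucleotide A single DNA string of length >= 3 (shorter frames
#'   translate to the empty string).
#' @return Character vector of 6 protein strings, named `fwd1..3`, `rev1..3`.
#' @export
translate_6frames <- function(nucleotide) {
  stopifnot(length(nucleotide) == 1)
  s <- toupper(nucleotide)
  r <- revcomp(s)
  out <- c(
    fwd1 = translate_frame(s, 1), fwd2 = translate_frame(s, 2),
    fwd3 = translate_frame(s, 3),
    rev1 = translate_frame(r, 1), rev2 = translate_frame(r, 2),
    rev3 = translate_frame(r, 3)
  )
  out
}

# Translate a single frame (offset 1..3) with the standard code.
translate_frame <- function(s, frame) {
  L <- nchar(s)
  n_codons <- (L - frame + 1) %/% 3
  if (n_codons <= 0) return("")
  starts <- frame + 3 * (seq_len(n_codons) - 1)
  codons <- substring(s, starts, starts + 2)
  aa <- Biostrings::GENETIC_CODE[codons]
  aa[is.na(aa)] <- "X" # ambiguous base in codon
  paste(aa, collapse = "")
}
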