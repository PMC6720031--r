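# Independent oracles: exact k-mer set arithmetic built from substring
# enumeration and Biostrings reverse complement, deliberately sharing no
# code with the package's C++ hashing path.

oracle_kmer_set <- function(seq, k) {
  L <- nchar(seq)
  if (L < k) return(character(0))
  km <- substring(seq, seq_len(L - k + 1), k:L)
  km <- km[!grepl("[^ACGT]", km)]
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(km)))
  unique(pmin(km, rc))
}

oracle_jaccard <- function(x, y, k) {
  a <- oracle_kmer_set(x, k)
  b <- oracle_kmer_set(y, k)
  length(intersect(a, b)) / length(union(a, b))
}

oracle_containment <- function(x, y, k) {
  a <- oracle_kmer_set(x, k)
  b <- oracle_kmer_set(y, k)
  length(intersect(a, b)) / length(a)
}

# Brute-force greedy decomposition over flat (name, hash set) lists, with
# the same tie-break contract as gather(): max overlap, then smaller
# reference, then lexicographic name.
oracle_greedy_gather <- function(ref_names, ref_mins, query_mins,
                                 threshold_hashes) {
  remaining <- query_mins
  out_names <- character(0)
  out_counts <- integer(0)
  repeat {
    counts <- vapply(ref_mins, function(m) length(intersect(remaining, m)), 0L)
    best <- max(counts)
    if (best < threshold_hashes || best == 0) break
    tied <- which(counts == best)
    sizes <- lengths(ref_mins)[tied]
    pick <- tied[order(sizes, ref_names[tied], method = "radix")[1]]
    out_names <- c(out_names, ref_names[pick])
    out_counts <- c(out_counts, best)
    remaining <- setdiff(remaining, ref_mins[[pick]])
  }
  list(names = out_names, counts = out_counts)
}

# Random signatures over random genomes, one sketch each.
make_test_signatures <- function(n, genome_len, params, seed0 = 1000) {
  lapply(seq_len(n), function(i) {
    signature(sketch_sequence(random_genome(genome_len, seed0 + i), params),
              name = sprintf("sig%03d", i))
  })
}

lineage_str_of <- function(tax, acc) {
  paste(minhashr:::lineage_from_row(tax[tax$accession == acc, ]),
        collapse = ";")
}

expect_same_search <- function(a, b) {
  expect_identical(a$name, b$name)
  expect_equal(a$score, b$score, tolerance = 1e-12)
}
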