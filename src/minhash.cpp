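// 64-bit hashing core: MurmurHash3 x64_128 (low word), canonical k-mer
// window streaming, and a flat Bloom filter. Hash values cross the R
// boundary as decimal strings because R doubles cannot represent all
// integers up to 2^64 exactly.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <string>
#include <vector>

using namespace Rcpp;

static inline uint64_t rotl64(uint64_t x, int8_t r) {
  return (x << r) | (x >> (64 - r));
}

static inline uint64_t fmix64(uint64_t k) {
  k ^= k >> 33;
  k *= 0xff51afd7ed558ccdULL;
  k ^= k >> 33;
  k *= 0xc4ceb9fe1a85ec53ULL;
  k ^= k >> 33;
  return k;
}

// MurmurHash3 x64_128; returns h1 (the low 64 bits of the 128-bit digest).
static uint64_t murmur3_64(const char *data, size_t len, uint64_t seed) {
  const size_t nblocks = len / 16;
  uint64_t h1 = seed, h2 = seed;
  const uint64_t c1 = 0x87c37b91114253d5ULL;
  const uint64_t c2 = 0x4cf5ad432745937fULL;
  const uint8_t *d = reinterpret_cast<const uint8_t *>(data);

  for (size_t i = 0; i < nblocks; i++) {
    uint64_t k1, k2;
    std::memcpy(&k1, d + i * 16, 8);
    std::memcpy(&k2, d + i * 16 + 8, 8);
    k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
    h1 = rotl64(h1, 27); h1 += h2; h1 = h1 * 5 + 0x52dce729;
    k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2;
    h2 = rotl64(h2, 31); h2 += h1; h2 = h2 * 5 + 0x38495ab5;
  }

  const uint8_t *tail = d + nblocks * 16;
  uint64_t k1 = 0, k2 = 0;
  switch (len & 15) {
  case 15: k2 ^= static_cast<uint64_t>(tail[14]) << 48; // fall through
  case 14: k2 ^= static_cast<uint64_t>(tail[13]) << 40; // fall through
  case 13: k2 ^= static_cast<uint64_t>(tail[12]) << 32; // fall through
  case 12: k2 ^= static_cast<uint64_t>(tail[11]) << 24; // fall through
  case 11: k2 ^= static_cast<uint64_t>(tail[10]) << 16; // fall through
  case 10: k2 ^= static_cast<uint64_t>(tail[9]) << 8;   // fall through
  case 9:  k2 ^= static_cast<uint64_t>(tail[8]);
           k2 *= c2; k2 = rotl64(k2, 33); k2 *= c1; h2 ^= k2; // fall through
  case 8:  k1 ^= static_cast<uint64_t>(tail[7]) << 56;  // fall through
  case 7:  k1 ^= static_cast<uint64_t>(tail[6]) << 48;  // fall through
  case 6:  k1 ^= static_cast<uint64_t>(tail[5]) << 40;  // fall through
  case 5:  k1 ^= static_cast<uint64_t>(tail[4]) << 32;  // fall through
  case 4:  k1 ^= static_cast<uint64_t>(tail[3]) << 24;  // fall through
  case 3:  k1 ^= static_cast<uint64_t>(tail[2]) << 16;  // fall through
  case 2:  k1 ^= static_cast<uint64_t>(tail[1]) << 8;   // fall through
  case 1:  k1 ^= static_cast<uint64_t>(tail[0]);
           k1 *= c1; k1 = rotl64(k1, 31); k1 *= c2; h1 ^= k1;
  }

  h1 ^= static_cast<uint64_t>(len);
  h2 ^= static_cast<uint64_t>(len);
  h1 += h2;
  h2 += h1;
  h1 = fmix64(h1);
  h2 = fmix64(h2);
  h1 += h2;
  return h1;
}

static std::string u64_to_dec(uint64_t v) {
  char buf[24];
  std::snprintf(buf, sizeof(buf), "%llu", static_cast<unsigned long long>(v));
  return std::string(buf);
}

static uint64_t dec_to_u64(const char *s) {
  uint64_t v = 0;
  for (; *s >= '0' && *s <= '9'; s++) v = v * 10 + (*s - '0');
  return v;
}

static inline char dna_complement(char c) {
  switch (c) {
  case 'A': return 'T';
  case 'C': return 'G';
  case 'G': return 'C';
  case 'T': return 'A';
  default:  return 'N';
  }
}

static inline char dna_upper(char c) {
  if (c >= 'a' && c <= 'z') return c - 32;
  return c;
}

static inline bool is_acgt(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// The 20 standard amino acids; '*' (stop) and 'X' (ambiguous) are invalid
// and break k-mer windows.
static inline bool is_aa(char c) {
  static const bool tab[26] = {
    /*A*/ true,  /*B*/ false, /*C*/ true,  /*D*/ true,  /*E*/ true,
    /*F*/ true,  /*G*/ true,  /*H*/ true,  /*I*/ true,  /*J*/ false,
    /*K*/ true,  /*L*/ true,  /*M*/ true,  /*N*/ true,  /*O*/ false,
    /*P*/ true,  /*Q*/ true,  /*R*/ true,  /*S*/ true,  /*T*/ true,
    /*U*/ false, /*V*/ true,  /*W*/ true,  /*X*/ false, /*Y*/ true,
    /*Z*/ false
  };
  if (c < 'A' || c > 'Z') return false;
  return tab[c - 'A'];
}

// [[Rcpp::export]]
CharacterVector cpp_hash_strings(CharacterVector x, double seed) {
  uint64_t s = static_cast<uint64_t>(seed);
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) {
    const char *p = CHAR(STRING_ELT(x, i));
    out[i] = u64_to_dec(murmur3_64(p, std::strlen(p), s));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) {
    std::string s(CHAR(STRING_ELT(x, i)));
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); j++)
      r[j] = dna_complement(dna_upper(s[s.size() - 1 - j]));
    out[i] = r;
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_canonical_kmers(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); i++) {
    std::string s(CHAR(STRING_ELT(x, i)));
    for (size_t j = 0; j < s.size(); j++) {
      s[j] = dna_upper(s[j]);
      if (!is_acgt(s[j])) stop("non-ACGT character in k-mer: '%s'", s.c_str());
    }
    std::string r(s.size(), 'N');
    for (size_t j = 0; j < s.size(); j++)
      r[j] = dna_complement(s[s.size() - 1 - j]);
    out[i] = (r < s) ? r : s;
  }
  return out;
}

// One hash per valid k-mer window, in sequence order, over one or more
// sequences. DNA windows are canonicalized (lexicographic min of the
// upper-cased window and its reverse complement); windows containing any
// invalid character are skipped entirely. If max_hash is a non-empty decimal
// string only hashes strictly below it are emitted.
// [[Rcpp::export]]
CharacterVector cpp_seq_hashes(CharacterVector seqs, int k, double seed,
                               bool dna, std::string max_hash) {
  uint64_t sd = static_cast<uint64_t>(seed);
  bool capped = !max_hash.empty();
  uint64_t cap = capped ? dec_to_u64(max_hash.c_str()) : 0;
  std::vector<std::string> out;

  std::string fwd, rev;
  for (R_xlen_t si = 0; si < seqs.size(); si++) {
    std::string s(CHAR(STRING_ELT(seqs, si)));
    const int L = static_cast<int>(s.size());
    if (L < k) continue;
    for (int j = 0; j < L; j++) s[j] = dna_upper(s[j]);

    // valid_run[j]: length of valid-character run ending at j
    int run = 0;
    std::vector<int> run_at(L);
    for (int j = 0; j < L; j++) {
      bool ok = dna ? is_acgt(s[j]) : is_aa(s[j]);
      run = ok ? run + 1 : 0;
      run_at[j] = run;
    }

    fwd.resize(k);
    rev.resize(k);
    for (int j = 0; j + k <= L; j++) {
      if (run_at[j + k - 1] < k) continue; // window touches an invalid char
      std::memcpy(&fwd[0], s.data() + j, k);
      const char *kp = fwd.data();
      if (dna) {
        for (int t = 0; t < k; t++) rev[t] = dna_complement(fwd[k - 1 - t]);
        if (rev < fwd) kp = rev.data();
      }
      uint64_t h = murmur3_64(kp, k, sd);
      if (capped && h >= cap) continue;
      out.push_back(u64_to_dec(h));
    }
  }
  return wrap(out);
}

// --- Bloom filter ----------------------------------------------------------
// Bit positions derived from the hash value itself via double hashing
// (Kirsch & Mitzenmacher): pos_i = (g1 + i*g2) mod m.

static inline void bloom_gs(uint64_t v, uint64_t &g1, uint64_t &g2) {
  g1 = fmix64(v ^ 0x9e3779b97f4a7c15ULL);
  g2 = fmix64(v + 0x9e3779b97f4a7c15ULL) | 1ULL;
}

// [[Rcpp::export]]
RawVector cpp_bloom_add(RawVector bits, CharacterVector hashes, int num_funcs) {
  RawVector out = clone(bits);
  uint64_t m = static_cast<uint64_t>(out.size()) * 8ULL;
  for (R_xlen_t i = 0; i < hashes.size(); i++) {
    uint64_t v = dec_to_u64(CHAR(STRING_ELT(hashes, i)));
    uint64_t g1, g2;
    bloom_gs(v, g1, g2);
    for (int f = 0; f < num_funcs; f++) {
      uint64_t pos = (g1 + static_cast<uint64_t>(f) * g2) % m;
      out[pos >> 3] = out[pos >> 3] | static_cast<Rbyte>(1 << (pos & 7));
    }
  }
  return out;
}

// [[Rcpp::export]]
LogicalVector cpp_bloom_query(RawVector bits, CharacterVector hashes,
                              int num_funcs) {
  uint64_t m = static_cast<uint64_t>(bits.size()) * 8ULL;
  LogicalVector out(hashes.size());
  for (R_xlen_t i = 0; i < hashes.size(); i++) {
    uint64_t v = dec_to_u64(CHAR(STRING_ELT(hashes, i)));
    uint64_t g1, g2;
    bloom_gs(v, g1, g2);
    bool present = true;
    for (int f = 0; f < num_funcs && present; f++) {
      uint64_t pos = (g1 + static_cast<uint64_t>(f) * g2) % m;
      present = (bits[pos >> 3] & (1 << (pos & 7))) != 0;
    }
    out[i] = present;
  }
  return out;
}
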