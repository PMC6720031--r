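P1 <- function(k = 21, ...) sketch_params(k, scaled = 1, ...)

from_h <- function(h, k = 21, scaled = 1, ...) {
  sketch_from_hashes(sketch_params(k, scaled = scaled, ...), as.character(h))
}

test_that("params require exactly one retention mode", {
  expect_error(sketch_params(21), "exactly one")
  expect_error(sketch_params(21, scaled = 10, num = 5), "exactly one")
  expect_silent(sketch_params(21, scaled = 10))
  expect_silent(sketch_params(21, num = 500))
})

test_that("the retention threshold at scaled=2000 is floor(2^64/2000)", {
  expect_identical(minhashr:::max_hash_for_scaled(2000), "9223372036854775")
  expect_identical(minhashr:::max_hash_for_scaled(1), "") # whole space
})

test_that("scaled=1 retains every distinct canonical k-mer", {
  g <- random_genome(2000, 11)
  sk <- sketch_sequence(g, P1())
  expect_identical(length(sk$mins), length(oracle_kmer_set(g, 21)))
  expect_identical(estimated_bp(sk), length(oracle_kmer_set(g, 21)) * 1)
})

test_that("re-adding a sequence leaves the hash set fixed and doubles abundances", {
  g <- random_genome(500, 3)
  sk1 <- sketch_sequence(g, P1(track_abundance = TRUE))
  sk2 <- add_sequence(sk1, g)
  expect_identical(sk1$mins, sk2$mins)
  expect_identical(unname(sk2$abund), unname(sk1$abund) * 2)
})

test_that("jaccard matches hand-enumerated set arithmetic", {
  a <- from_h(c(1, 2, 3))
  b <- from_h(c(2, 3, 4))
  expect_identical(jaccard(a, a), 1)
  expect_identical(jaccard(a, b), 0.5)
  expect_identical(jaccard(a, from_h(c(7, 8))), 0)
  expect_warning(j0 <- jaccard(from_h(character(0)), from_h(character(0))),
                 "empty")
  expect_identical(j0, 0)
})

test_that("containment is the asymmetric fraction of the query found", {
  a <- from_h(c(1, 2))
  b <- from_h(c(1, 2, 3, 4))
  expect_identical(containment(a, a), 1)
  expect_identical(containment(a, b), 1)
  expect_identical(containment(b, a), 0.5)
  expect_identical(containment(a, from_h(character(0))), 0)
  expect_error(containment(from_h(character(0)), a), "empty")
})

test_that("cosine similarity treats sketches as sparse count vectors", {
  pa <- sketch_params(21, scaled = 1, track_abundance = TRUE)
  a <- sketch_from_hashes(pa, c("10", "20"), c(1, 2))
  b <- sketch_from_hashes(pa, c("10", "20"), c(2, 4))
  d <- sketch_from_hashes(pa, c("30", "40"), c(1, 1))
  expect_equal(cosine_sim(a, a), 1)
  expect_equal(cosine_sim(a, b), 1) # proportional vectors
  expect_equal(cosine_sim(a, d), 0) # orthogonal
  expect_error(cosine_sim(a, from_h(c(1, 2))), "abundance")
})

test_that("incompatible sketches fail naming the mismatched field", {
  expect_error(jaccard(from_h(1, k = 21), from_h(1, k = 31)), "ksize")
  expect_error(jaccard(from_h(1), from_h(1, seed = 7)), "seed")
  expect_error(
    jaccard(from_h(1), sketch_from_hashes(sketch_params(21, num = 5), "1")),
    "scaled"
  )
})

test_that("comparing different scales silently downsamples to the coarser", {
  g1 <- random_genome(20000, 21)
  g2 <- mutate_genome(g1, 0.02, 22)
  a <- sketch_sequence(g1, sketch_params(21, scaled = 100))
  b <- sketch_sequence(g2, sketch_params(21, scaled = 500))
  expect_identical(jaccard(a, b),
                   jaccard(downsample(a, 500), b))
})

test_that("downsampling reproduces a directly built coarser sketch", {
  g <- random_genome(5000, 31)
  fine <- sketch_sequence(g, sketch_params(21, scaled = 100))
  coarse <- sketch_sequence(g, sketch_params(21, scaled = 1000))
  via <- downsample(fine, 1000)
  expect_identical(via$mins, coarse$mins)
  expect_identical(downsample(fine, 100), fine)
  expect_true(all(via$mins %in% fine$mins))
  expect_error(downsample(coarse, 100), "finer")
  expect_error(downsample(sketch_from_hashes(sketch_params(21, num = 5), "1"), 10),
               "scaled")
})

test_that("scaled sketches convert to bottom-n by keeping the smallest hashes", {
  sk <- from_h(c(5, 9, 14, 20))
  bn <- to_bottom_n(sk, 2)
  expect_identical(bn$mins, c("5", "9"))
  expect_true(is.na(bn$scaled) && bn$num == 2L)
  expect_error(to_bottom_n(sk, 10), "n <= sketch size|exceeds")
  same <- to_bottom_n(sk, 4)
  expect_identical(same$mins, sk$mins)
  # equivalent to a directly built bottom-n sketch
  g <- random_genome(1000, 17)
  direct <- sketch_sequence(g, sketch_params(21, num = 50))
  converted <- to_bottom_n(sketch_sequence(g, P1()), 50)
  expect_identical(direct$mins, converted$mins)
})

test_that("bottom-n jaccard uses the n smallest hashes of the union", {
  pa <- sketch_params(21, num = 4)
  a <- sketch_from_hashes(pa, c("1", "2", "3", "4"))
  b <- sketch_from_hashes(pa, c("1", "2", "5", "6"))
  # union smallest 4 = {1,2,3,4}; of those, {1,2} are in both
  expect_identical(jaccard(a, b), 0.5)
  expect_identical(jaccard(a, a), 1)
})

test_that("set algebra obeys the expected laws", {
  A <- from_h(c(1, 2, 3))
  B <- from_h(c(2, 3, 4))
  C <- from_h(c(4, 5))
  expect_identical(sketch_intersect(A, B)$mins, c("2", "3"))
  expect_identical(sketch_subtract(A, B)$mins, "1")
  expect_identical(sketch_merge(A, from_h(character(0)))$mins, A$mins)
  expect_length(sketch_subtract(A, A)$mins, 0)
  expect_identical(sketch_merge(sketch_merge(A, B), C)$mins,
                   sketch_merge(A, sketch_merge(B, C))$mins)
  expect_true(all(sketch_intersect(A, B)$mins %in% A$mins))
  expect_length(sketch_intersect(sketch_subtract(A, B), B)$mins, 0)
})

test_that("merge sums abundances; intersect/subtract/flatten drop them", {
  pa <- sketch_params(21, scaled = 1, track_abundance = TRUE)
  a <- sketch_from_hashes(pa, c("1", "2"), c(2, 3))
  b <- sketch_from_hashes(pa, c("2", "3"), c(5, 7))
  m <- sketch_merge(a, b)
  expect_identical(unname(m$abund[c("1", "2", "3")]), c(2, 8, 7))
  expect_false(sketch_intersect(a, b)$track_abundance)
  expect_false(sketch_subtract(a, b)$track_abundance)
  fl <- sketch_flatten(a)
  expect_false(fl$track_abundance)
  expect_identical(fl$mins, a$mins)
})

test_that("scaled sketching is streaming-monotone: prefixes never lose hashes", {
  for (i in 1:5) {
    g <- random_genome(4000, 40 + i)
    full <- sketch_sequence(g, sketch_params(21, scaled = 20))
    for (cut in c(500, 1500, 3000)) {
      prefix <- sketch_sequence(substr(g, 1, cut), sketch_params(21, scaled = 20))
      expect_true(all(prefix$mins %in% full$mins))
    }
  }
})

test_that("estimated_bp scales the retained count by s", {
  expect_identical(estimated_bp(from_h(1:100, scaled = 2000)), 200000)
  expect_identical(estimated_bp(from_h(character(0), scaled = 2000)), 0)
  expect_error(estimated_bp(sketch_from_hashes(sketch_params(21, num = 5), "1")),
               "scaled")
})
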