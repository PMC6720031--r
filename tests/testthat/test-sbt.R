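sbt_params <- sketch_params(21, scaled = 10)

build_sbt_fixture <- function(n = 12, len = 3000, fp = 0.05, seed0 = 500) {
  sigs <- make_test_signatures(n, len, sbt_params, seed0 = seed0)
  list(sigs = sigs, idx = sbt_build(sigs, fp_target = fp))
}

# every hash of every leaf must be present in every ancestor filter
check_filters_cover_leaves <- function(node, ancestors = list()) {
  if (minhashr:::node_is_leaf(node)) {
    for (anc in ancestors) {
      expect_true(all(minhashr:::bloom_contains(anc$filter, node$sketch$mins)))
    }
    return(invisible(NULL))
  }
  for (ch in node$children) {
    check_filters_cover_leaves(ch, c(ancestors, list(node)))
  }
}

test_that("built trees satisfy the structural invariants", {
  fx <- build_sbt_fixture(n = 9)
  root <- fx$idx$root
  check_filters_cover_leaves(root)
  leaves <- minhashr:::node_leaves(root)
  expect_length(leaves, 9)
  leaf_sizes <- vapply(leaves, function(l) length(l$sketch$mins), 0L)
  expect_identical(root$min_leaf_n, min(leaf_sizes))
  # root filter contains all the values from all signatures
  all_h <- unique(unlist(lapply(leaves, function(l) l$sketch$mins)))
  expect_true(all(minhashr:::bloom_contains(root$filter, all_h)))
})

test_that("a single signature builds a single-leaf tree", {
  sig <- make_test_signatures(1, 1000, sbt_params)[[1]]
  idx <- sbt_build(sig)
  expect_true(minhashr:::node_is_leaf(idx$root))
  hit <- index_search(idx, sig$sketches[[1]], threshold = 1)
  expect_identical(hit$name, sig$name)
  expect_equal(hit$score, 1)
})

test_that("mixed-parameter signature sets are rejected with the offender named", {
  sigs <- make_test_signatures(2, 1000, sbt_params)
  odd <- signature(sketch_sequence(random_genome(1000, 77),
                                   sketch_params(21, scaled = 50)),
                   name = "odd-scale")
  expect_error(sbt_build(c(sigs, list(odd))), "odd-scale")
})

test_that("the similarity bound matches its arithmetic definition", {
  # node filter covering {1,2,3}, min_leaf_n = 3, query of 4 hashes with
  # m_v = 2 present: bound = 2 / (4 + 3 - 2) = 0.4, pruned at 0.5
  expect_equal(minhashr:::sbt_sim_bound(2, 4, 3), 0.4)
  expect_equal(minhashr:::sbt_cont_bound(2, 4), 0.5)
})

test_that("pruned search equals a brute-force linear scan at every threshold", {
  fx <- build_sbt_fixture(n = 15)
  base <- lapply(fx$sigs[c(2, 7, 11)], function(s) s$sketches[[1]])
  queries <- c(
    base, # exact members
    lapply(1:3, function(i) {
      sketch_sequence(mutate_genome(random_genome(3000, 500 + i), 0.01, 900 + i),
                      sbt_params)
    }),
    list(sketch_merge(base[[1]], base[[2]]))
  )
  for (q in queries) {
    for (thr in seq(0.1, 0.9, by = 0.2)) {
      for (mode in c("similarity", "containment")) {
        expect_same_search(index_search(fx$idx, q, thr, mode),
                           index_search(fx$sigs, q, thr, mode))
      }
    }
  }
})

test_that("an adversarially small Bloom filter only costs visits, never results", {
  fx_bad <- build_sbt_fixture(n = 15, fp = 0.9)
  fx_good <- build_sbt_fixture(n = 15, fp = 0.05)
  q <- fx_bad$sigs[[4]]$sketches[[1]]
  for (thr in c(0.2, 0.6)) {
    expect_same_search(index_search(fx_bad$idx, q, thr),
                       index_search(fx_good$idx, q, thr))
  }
})

test_that("insert touches only the new leaf's ancestors", {
  fx <- build_sbt_fixture(n = 8)
  new_sig <- make_test_signatures(1, 3000, sbt_params, seed0 = 999)[[1]]
  before <- fx$idx$root
  after <- sbt_insert(fx$idx, new_sig)$root
  # exactly one child subtree on the path changed; its sibling is untouched
  changed <- which(!vapply(seq_along(before$children), function(i) {
    identical(before$children[[i]], after$children[[i]])
  }, TRUE))
  expect_lte(length(changed), 1)
  # the new leaf is searchable at threshold 1 with itself
  hit <- index_search(after <- sbt_insert(fx$idx, new_sig), new_sig$sketches[[1]],
                      threshold = 1)
  expect_true(new_sig$name %in% hit$name)
  # insert into an empty-equivalent index equals build
  one <- sbt_insert(sbt_build(new_sig), make_test_signatures(1, 1000, sbt_params)[[1]])
  expect_identical(minhashr:::node_n_leaves(one$root), 2L)
})

test_that("combining trees unions their leaves and their search results", {
  a <- build_sbt_fixture(n = 3, seed0 = 100)
  b <- build_sbt_fixture(n = 3, seed0 = 200)
  comb <- sbt_combine(a$idx, b$idx)
  expect_identical(minhashr:::node_n_leaves(comb$root), 6L)
  q <- a$sigs[[1]]$sketches[[1]]
  for (thr in c(0.1, 0.5, 1)) {
    got <- index_search(comb, q, thr)
    want <- rbind(index_search(a$idx, q, thr), index_search(b$idx, q, thr))
    want <- want[order(-want$score, want$name, method = "radix"), , drop = FALSE]
    expect_identical(got$name, want$name)
    expect_equal(got$score, want$score)
  }
})

test_that("a saved index reloads with identical search behaviour", {
  fx <- build_sbt_fixture(n = 6)
  d <- tempfile("sbt")
  sbt_save(fx$idx, d)
  idx2 <- sbt_load(d)
  q <- sketch_merge(fx$sigs[[1]]$sketches[[1]], fx$sigs[[5]]$sketches[[1]])
  expect_same_search(index_search(fx$idx, q, 0.1), index_search(idx2, q, 0.1))
  expect_same_search(index_search(fx$idx, q, 0.1, "containment"),
                     index_search(idx2, q, 0.1, "containment"))
})
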