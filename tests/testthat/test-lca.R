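lp <- sketch_params(21, scaled = 1)

lin_sig <- function(name, hashes) {
  signature(sketch_from_hashes(lp, as.character(hashes)), name = name)
}

two_lineage_tax <- data.frame(
  accession = c("x", "y"),
  superkingdom = "A", phylum = "B", class = c("C", "D"),
  stringsAsFactors = FALSE
)

test_that("LCA of lineages is the longest common prefix and is well-behaved", {
  lca <- minhashr:::lca_of
  a <- c("A", "B", "C")
  b <- c("A", "B", "D")
  expect_identical(lca(list(a, b)), c("A", "B"))
  expect_identical(lca(list(a, a)), a)
  expect_identical(lca(list(a, b)), lca(list(b, a)))
  expect_identical(lca(list(a, b, c("E"))), character(0))
  perms <- list(list(a, b, c("A", "B")), list(c("A", "B"), b, a))
  expect_identical(lca(perms[[1]]), lca(perms[[2]]))
})

test_that("a single indexed genome maps every hash to its own lineage", {
  tax <- make_taxonomy("solo")
  db <- lca_index(lin_sig("solo", 1:30), tax)
  cls <- lca_classify(db, sketch_from_hashes(lp, as.character(1:30)))
  expect_identical(cls$status, "found")
  expect_identical(cls$lineage,
                   c("sk_synth", "p_synth", "c_synth", "o_synth",
                     "f_1", "g_1", "s_solo"))
  expect_identical(cls$n_classified, 30L)
})

test_that("a hash shared by two samples carries both lineages (their LCA)", {
  db <- lca_index(list(lin_sig("x", c(1, 2)), lin_sig("y", c(2, 3))),
                  two_lineage_tax)
  cls <- lca_classify(db, sketch_from_hashes(lp, "2"))
  expect_identical(cls$lineage, c("A", "B"))
  expect_identical(cls$status, "found")
})

test_that("classification reports the deepest majority lineage", {
  # hashes split 50/50 between (A;B;C) and (A;B;D): at F=0.95 neither leaf
  # has a majority, so the consensus is (A;B)
  db <- lca_index(list(lin_sig("x", 1:10), lin_sig("y", 11:20)),
                  two_lineage_tax)
  q <- sketch_from_hashes(lp, as.character(1:20))
  cls <- lca_classify(db, q, majority = 0.95)
  expect_identical(cls$lineage, c("A", "B"))
  # at F=0.5 the deeper lineages tie at exactly half support; the
  # deterministic tie-break picks one leaf-level lineage
  cls50 <- lca_classify(db, q, majority = 0.5)
  expect_identical(length(cls50$lineage), 3L)
})

test_that("queries absent from the database report nomatch", {
  db <- lca_index(lin_sig("x", 1:5), two_lineage_tax)
  cls <- lca_classify(db, sketch_from_hashes(lp, as.character(100:105)))
  expect_identical(cls$status, "nomatch")
  expect_length(cls$lineage, 0)
})

test_that("summarize conserves counts and aggregates up the taxonomy", {
  db <- lca_index(list(lin_sig("x", 1:70), lin_sig("y", 101:130)),
                  two_lineage_tax)
  q <- sketch_from_hashes(lp, as.character(c(1:70, 101:130)))
  tab <- lca_summarize(db, q)
  expect_identical(attr(tab, "n_classified"), 100L)
  # disjoint 70/30 mixture: class-level rows at exactly 0.7 and 0.3
  cls_rows <- tab[tab$rank == "class", ]
  expect_equal(sort(cls_rows$fraction), c(0.3, 0.7))
  expect_identical(cls_rows$count[order(cls_rows$fraction)], c(30L, 70L))
  # prefixes accumulate: the shared (A;B) prefix holds every hash
  expect_identical(tab$count[tab$lineage == "A;B"], 100L)
  expect_equal(tab$fraction[tab$lineage == "A"], 1)
})

test_that("taxonomy tables round-trip through CSV and encode sibling structure", {
  f <- tempfile(fileext = ".csv")
  tax <- make_taxonomy(c("g1", "g2", "g3"), groups = c(1, 1, 2), path = f)
  back <- read_taxonomy(f)
  expect_equal(back, tax)
  l1 <- minhashr:::lineage_from_row(tax[1, ])
  l2 <- minhashr:::lineage_from_row(tax[2, ])
  l3 <- minhashr:::lineage_from_row(tax[3, ])
  # siblings share everything but species; their LCA is the genus prefix
  expect_identical(minhashr:::lca_of(list(l1, l2)), l1[1:6])
  # groups 1 and 2 share a family (two genera per family by default)
  expect_identical(minhashr:::lca_of(list(l1, l3)), l1[1:5])
})

test_that("missing taxonomy entries skip with a warning; duplicates error", {
  sigs <- list(lin_sig("x", 1:5), lin_sig("nota", 6:10))
  expect_warning(db <- lca_index(sigs, two_lineage_tax), "nota")
  expect_identical(attr(db, "n_skipped"), 1L)
  expect_length(db$samples, 1)
  expect_error(lca_index(list(lin_sig("x", 1:5), lin_sig("x", 6:10)),
                         two_lineage_tax), "duplicate")
})

test_that("the LCA backend searches and gathers like the SBT backend", {
  p <- sketch_params(21, scaled = 10)
  sigs <- make_test_signatures(10, 3000, p, seed0 = 820)
  tax <- make_taxonomy(vapply(sigs, `[[`, "", "name"))
  db <- lca_index(sigs, tax)
  idx <- sbt_build(sigs)
  q <- sketch_merge(sigs[[2]]$sketches[[1]], sigs[[9]]$sketches[[1]])
  for (mode in c("similarity", "containment")) {
    expect_same_search(index_search(db, q, 0.2, mode),
                       index_search(idx, q, 0.2, mode))
  }
  g_lca <- gather(db, q, threshold_bp = 100)
  g_sbt <- gather(idx, q, threshold_bp = 100)
  expect_identical(g_lca$name, g_sbt$name)
  expect_equal(g_lca$overlap_bp, g_sbt$overlap_bp)
})

test_that("LCA databases persist as a single JSON file", {
  db <- lca_index(list(lin_sig("x", 1:10), lin_sig("y", 5:15)),
                  two_lineage_tax)
  f <- tempfile(fileext = ".json")
  lca_save(db, f)
  db2 <- lca_load(f)
  expect_identical(db2$samples, db$samples)
  expect_identical(db2$lineages, db$lineages)
  cls <- lca_classify(db2, sketch_from_hashes(lp, "7"))
  expect_identical(cls$lineage, c("A", "B"))
})
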