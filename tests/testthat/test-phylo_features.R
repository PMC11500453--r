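test_that("lineage-built trees share prefixes and keep single-child chains", {
  lin <- c("k__B|g__G1|s__S1", "k__B|g__G1|s__S2", "k__B|g__G2|s__S3")
  tr <- build_taxonomy_tree(lin)
  expect_equal(microhdf:::n_nodes(tr), 7L)  # root + kingdom + 2 genera + 3 species
  expect_equal(sum(lengths(tr$children) == 0L), 3L)
  expect_equal(sum(tr$rank == "genus", na.rm = TRUE), 2L)
  # single lineage gives a linear chain
  chain <- build_taxonomy_tree("k__B|p__P|c__C|o__O|f__F|g__G|s__S")
  expect_equal(microhdf:::n_nodes(chain), 8L)
  expect_true(all(lengths(chain$children) <= 1L))
  expect_error(build_taxonomy_tree(c("k__B|s__X", "k__C|s__X")),
               "conflicting lineages")
  expect_error(build_taxonomy_tree(character(0)), "empty profile")
})

test_that("templates give the hand-derived level and post orders", {
  tr <- toy_tree()
  expect_equal(level_template(tr)$ids, c("R", "C", "E", "A", "B", "D"))
  expect_equal(postorder_template(tr)$ids, c("A", "B", "D"))
  # single leaf chain and star tree
  chain <- read_newick(text = "((A)B)R;")
  expect_equal(level_template(chain)$ids, c("R", "B", "A"))
  star <- read_newick(text = "(X,Y,Z)R;")
  expect_equal(level_template(star)$ids, c("R", "X", "Y", "Z"))
  expect_equal(postorder_template(star)$ids, c("X", "Y", "Z"))
  # mirroring the subtrees reverses the groups, keeps within-group order
  mir <- read_newick(text = "((D)E,(A,B)C)R;")
  expect_equal(postorder_template(mir)$ids, c("D", "A", "B"))
})

test_that("populated templates carry leaf abundances and ancestor sums", {
  tr <- toy_tree()
  prof <- toy_profile()
  lv <- populate_template(prof, tr, level_template(tr))
  expect_equal(unname(lv["s1", ]), c(1.0, 0.8, 0.2, 0.5, 0.3, 0.2))
  po <- populate_template(prof, tr, postorder_template(tr))
  expect_equal(unname(po["s1", ]), c(0.5, 0.3, 0.2))
  # all-zero sample row stays all-zero
  zp <- abundance_profile(matrix(c(0, 0, 0), 1, 3,
    dimnames = list("z", c("A", "B", "D"))))
  expect_equal(unname(populate_template(zp, tr, level_template(tr))[1, ]),
               rep(0, 6))
})

test_that("internal node values satisfy hierarchical consistency", {
  dat <- simulate_microbiome(synthetic_spec(n_taxa = 30L, n_case = 5L,
                                            n_control = 5L, seed = 4L))
  tr <- dat$tree
  lv <- populate_template(dat$profile, tr, level_template(tr))
  lab <- node_labels <- colnames(lv)
  idx <- level_template(tr)$index
  for (pos in seq_along(idx)) {
    node <- idx[pos]
    ch <- tr$children[[node]]
    if (length(ch)) {
      ch_pos <- match(ch, idx)
      expect_equal(lv[, pos], rowSums(lv[, ch_pos, drop = FALSE]),
                   tolerance = 1e-12)
    }
  }
  # root equals the total abundance (1 after renormalization)
  expect_equal(unname(lv[, 1]), rep(1, nrow(lv)), tolerance = 1e-12)
})

test_that("templates are stable under taxon permutation", {
  lin <- simulate_microbiome(
    synthetic_spec(n_taxa = 20L, n_case = 3L, n_control = 3L, seed = 8L))
  taxa <- colnames(lin$profile)
  set.seed(1)
  t1 <- build_taxonomy_tree(taxa)
  t2 <- build_taxonomy_tree(sample(taxa))
  expect_equal(level_template(t1)$ids, level_template(t2)$ids)
  expect_equal(postorder_template(t1)$ids, postorder_template(t2)$ids)
  # post-order leaves are a permutation of the profile taxa
  expect_setequal(t1$taxon_id[tree_leaves(t1)], taxa)
})

test_that("views assemble with provenance prefixes and width checks", {
  tr <- toy_tree()
  prof <- toy_profile()
  lv <- populate_template(prof, tr, level_template(tr))
  po <- populate_template(prof, tr, postorder_template(tr))
  all3 <- assemble_views(prof, lv, po, mode = "O+L+P")
  expect_equal(ncol(all3), 3L + 6L + 3L)
  expect_true(all(grepl("^(raw|lvl|post):", colnames(all3))))
  o <- assemble_views(prof, mode = "O")
  expect_equal(unname(o), unname(unclass(prof)), ignore_attr = TRUE)
  prof2 <- abundance_profile(unclass(prof)[2:1, ])
  lv2 <- populate_template(prof2, tr, level_template(tr))
  expect_error(assemble_views(prof, lv2, po, mode = "O+L+P"),
               "sample-id mismatch")
})

test_that("supplied trees reconcile with the profile by terminal token", {
  prof <- toy_profile()
  # tree with an extra leaf Z and missing D
  tr <- read_newick(text = "((A,B)C,Z)R;")
  expect_warning(expect_warning(rec <- reconcile_tree(tr, prof),
                                "pruned"), "appended")
  expect_setequal(rec$taxon_id[tree_leaves(rec)], c("A", "B", "D"))
})
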