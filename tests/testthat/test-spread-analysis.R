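# Toy annotated trees: normal -> A(stem,4) -> B(2) -> C(2)
#                                          \-> D(3)

test_that("IGD follows the stem-normalized diversity formula", {
  meta <- mk_meta(c("P1", "N1"), c("primary", "neck"),
                  c("primary", "lymph-node"))
  tree <- mk_tree(list(A = c(P1 = 0.5), B = c(P1 = 0.3), D = c(P1 = 0.2)),
                  meta)
  # all subclones at their common node
  expect_equal(igd(tree, c("A", "A")), 0)
  # d = {2, 3} from A to B and D, stem l = 4, N = 2: 5 / (5 + 8)
  expect_equal(igd(tree, c("B", "D")), 5 / 13)
  # hand case d = {2,2}, l = 4: 4/12
  tree2 <- mk_tree(list(A = c(P1 = 0.5)), meta,
                   parents = c(NA, 1L, 2L, 2L),
                   labels = c("normal", "A", "B", "C"),
                   lengths = c(0L, 4L, 2L, 2L))
  expect_equal(igd(tree2, c("B", "C")), 1 / 3)
  # zero stem with nonzero distances is maximal diversity
  tree3 <- mk_tree(list(A = c(P1 = 0.5)), meta,
                   parents = c(NA, 1L, 2L),
                   labels = c("normal", "A", "B"),
                   lengths = c(0L, 0L, 1L))
  expect_equal(igd(tree3, c("A", "B")), 1)
  # zero stem and zero distances is undefined: 0 with a QC flag
  expect_warning(z <- igd(tree3, "A"), class = "clonetrace_qc_warning")
  expect_equal(z, 0)
  expect_error(igd(tree, character()), class = "invalid_input")
})

test_that("IGD is invariant to subclone order and decreasing in stem length", {
  meta <- mk_meta("P1", "primary", "primary")
  for (l in c(2L, 4L, 8L)) {
    tree <- mk_tree(list(A = c(P1 = 1)), meta, lengths = c(0L, l, 2L, 2L, 3L))
    expect_equal(igd(tree, c("B", "D")), igd(tree, c("D", "B")))
  }
  vals <- vapply(c(2L, 4L, 8L), function(l) {
    tree <- mk_tree(list(A = c(P1 = 1)), meta, lengths = c(0L, l, 2L, 2L, 3L))
    igd(tree, c("B", "D"))
  }, 0)
  expect_true(all(diff(vals) < 0))
})

test_that("the primary MRCA is the deepest ancestor of all primary subclones", {
  meta <- mk_meta(c("P1", "P2", "N1"), c("primary", "primary", "neck"),
                  c("primary", "primary", "lymph-node"))
  # chain: deepest common ancestor on the chain
  t1 <- mk_tree(list(B = c(P1 = 0.6), C = c(P2 = 0.5)), meta)
  expect_equal(t1$label[primary_mrca(t1)], "B")
  # two branches: their join node
  t2 <- mk_tree(list(B = c(P1 = 0.6), D = c(P2 = 0.5)), meta)
  expect_equal(t2$label[primary_mrca(t2)], "A")
  # single primary subclone: itself
  t3 <- mk_tree(list(C = c(P1 = 0.6), D = c(N1 = 0.5)), meta)
  expect_equal(t3$label[primary_mrca(t3)], "C")
  # no primary detection at all
  t4 <- mk_tree(list(C = c(N1 = 0.6)), meta)
  expect_error(primary_mrca(t4), class = "no_primary")
})

test_that("seeding lineages count independent colonizations of a site", {
  meta <- mk_meta(c("P1", "N1"), c("primary", "neck"),
                  c("primary", "lymph-node"))
  # two site subclones, one ancestral to the other: one lineage
  t1 <- mk_tree(list(A = c(P1 = 0.9), B = c(N1 = 0.5), C = c(N1 = 0.4)),
                meta)
  expect_length(seeding_lineages(t1, "neck"), 1)
  # two site subclones joining only at a node absent from the site
  t2 <- mk_tree(list(A = c(P1 = 0.9), C = c(N1 = 0.5), D = c(N1 = 0.4)),
                meta)
  lin <- seeding_lineages(t2, "neck")
  expect_length(lin, 2)
  # single subclone: monoclonal
  t3 <- mk_tree(list(A = c(P1 = 0.9), D = c(N1 = 0.9)), meta)
  expect_length(seeding_lineages(t3, "neck"), 1)
})

test_that("timing is dated against the primary MRCA", {
  meta <- mk_meta(c("P1", "N1"), c("primary", "neck"),
                  c("primary", "lymph-node"))
  # metastasis branching off above the primary MRCA: earlier
  t1 <- mk_tree(list(B = c(P1 = 0.8), C = c(P1 = 0.5), D = c(N1 = 0.9)),
                meta)
  expect_equal(classify_timing(t1, "neck"), "earlier")
  # metastasis descending from a primary-detected subclone: later
  t2 <- mk_tree(list(A = c(P1 = 0.5), B = c(P1 = 0.4), C = c(N1 = 0.9)),
                meta)
  expect_equal(classify_timing(t2, "neck"), "later")
  # one lineage of each kind: both
  t3 <- mk_tree(list(B = c(P1 = 0.8), C = c(N1 = 0.4), D = c(N1 = 0.5)),
                meta)
  expect_equal(classify_timing(t3, "neck"), "both")
  # a lineage attaching exactly at the primary MRCA is later
  t4 <- mk_tree(list(A = c(P1 = 0.8), D = c(N1 = 0.9)), meta)
  expect_equal(classify_timing(t4, "neck"), "later")
})

test_that("phyletic classification asks whether one branch feeds all metastases", {
  meta <- mk_meta(c("P1", "N1", "BM1"), c("primary", "neck", "marrow"),
                  c("primary", "lymph-node", "distant"))
  # all metastases descend from one subclone
  t1 <- mk_tree(list(A = c(P1 = 0.9), B = c(N1 = 0.8), C = c(BM1 = 0.9)),
                meta)
  expect_equal(classify_phyletic(t1), "monophyletic")
  # lymph-node and marrow lineages from different branches
  t2 <- mk_tree(list(A = c(P1 = 0.9), B = c(N1 = 0.8), D = c(BM1 = 0.9)),
                meta)
  expect_equal(classify_phyletic(t2), "polyphyletic")
  # single metastasis
  meta1 <- mk_meta(c("P1", "N1"), c("primary", "neck"),
                   c("primary", "lymph-node"))
  t3 <- mk_tree(list(A = c(P1 = 0.9), D = c(N1 = 0.9)), meta1)
  expect_equal(classify_phyletic(t3), "monophyletic")
})

test_that("intermetastatic spread needs a metastasis-private mediating subclone", {
  meta <- mk_meta(c("P1", "L1", "Br1"), c("primary", "lung", "brain"),
                  c("primary", "distant", "distant"))
  # lung-private subclone with a descendant in the brain: lung -> brain
  t1 <- mk_tree(list(A = c(P1 = 0.9), B = c(L1 = 0.8), C = c(Br1 = 0.9)),
                meta)
  edges <- detect_intermetastatic(t1)
  expect_true(any(edges$source == "lung" & edges$target == "brain" &
                    edges$resolved))
  expect_false(any(edges$source == "brain" & edges$resolved))
  # metastases sharing only primary-detected ancestors: no edge
  t2 <- mk_tree(list(A = c(P1 = 0.9, L1 = 0.2, Br1 = 0.2),
                     B = c(L1 = 0.7), D = c(Br1 = 0.7)), meta)
  expect_equal(nrow(detect_intermetastatic(t2)), 0)
  # shared subclone at both sites with no private ancestor: unresolved,
  # both orientations
  t3 <- mk_tree(list(A = c(P1 = 0.9), D = c(L1 = 0.8, Br1 = 0.8)), meta)
  e3 <- detect_intermetastatic(t3)
  expect_equal(nrow(e3), 2)
  expect_false(any(e3$resolved))
  # fewer than two metastatic sites is not evaluable
  meta1 <- mk_meta(c("P1", "L1"), c("primary", "lung"),
                   c("primary", "distant"))
  t4 <- mk_tree(list(A = c(P1 = 0.9), B = c(L1 = 0.8)), meta1)
  expect_error(detect_intermetastatic(t4), class = "not_evaluable")
})

test_that("classify_spread aggregates sites into a patient report", {
  meta <- mk_meta(c("P1", "L1", "Br1"), c("primary", "lung", "brain"),
                  c("primary", "distant", "distant"))
  tree <- mk_tree(list(A = c(P1 = 0.9), B = c(L1 = 0.8), C = c(Br1 = 0.9)),
                  meta)
  rep <- classify_spread(tree, "PT")
  expect_equal(rep$n_met_sites, 2)
  expect_false(rep$earlier)
  expect_true(rep$later)
  expect_true(rep$monoclonal)
  expect_equal(rep$phyletic, "monophyletic")
  expect_true(is.data.frame(rep$intermetastatic))
  expect_true(is.na(rep$igd[["relapse"]]))
  # single-site patient: intermetastatic not evaluable
  meta1 <- mk_meta(c("P1", "L1"), c("primary", "lung"),
                   c("primary", "distant"))
  t1 <- mk_tree(list(A = c(P1 = 0.9), B = c(L1 = 0.8)), meta1)
  r1 <- classify_spread(t1, "PT")
  expect_true(is.na(r1$intermetastatic[1]))
  flags <- label_flags(r1)
  expect_true(is.na(flags["intermetastatic"]))
})

test_that("cohort tests wrap the standard two-sample procedures", {
  # exact rank enumeration: {1,2,3} vs {4,5,6} gives U = 0, p = 0.1
  res <- cohort_tests(list(a = c(1, 2, 3), b = c(4, 5, 6)))
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 0.1)
  expect_false(res$significant)
  # identical groups are far from significance
  res2 <- cohort_tests(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_gt(res2$p_value, 0.5)
  # paired differences all zero: t = 0
  res3 <- cohort_tests(list(a = c(0.2, 0.4, 0.5), b = c(0.2, 0.4, 0.5)),
                       paired = TRUE)
  expect_equal(res3$statistic, 0)
  expect_equal(res3$p_value, 1)
  # degenerate group sizes are reported not-evaluable
  res4 <- cohort_tests(list(a = 1, b = c(2, 3)))
  expect_true(is.na(res4$p_value))
  expect_error(cohort_tests(list(a = 1:3)), class = "invalid_input")
})
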