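rand_matrix <- function(seed, max_sub = 7L, max_ev = 14L) {
  set.seed(seed)
  n_sub <- sample(2:max_sub, 1)
  n_ev <- sample(4:max_ev, 1)
  repeat {
    m <- matrix(rbinom(n_sub * n_ev, 1, 0.45), n_sub, n_ev)
    m <- m[, colSums(m) > 0, drop = FALSE]
    if (ncol(m) >= 2 && !any(duplicated(m)) && !any(rowSums(m) == 0)) break
  }
  dimnames(m) <- list(paste0("SC", seq_len(nrow(m))),
                      paste0("E", seq_len(ncol(m))))
  m
}

# independent exhaustive oracle: minimum Fitch score over all unrooted
# topologies, enumerated by ape and scored by phangorn
oracle_min_score <- function(m) {
  tips <- rbind(normal = 0L, m)
  pd <- phangorn::phyDat(tips, type = "USER", levels = c(0L, 1L))
  trees <- phangorn::allTrees(nrow(tips), tip.label = rownames(tips))
  min(phangorn::fitch(trees, pd))
}

test_that("Fitch scoring counts the minimum number of event changes", {
  # chain of nested sets {}, {A}, {A,B}
  m <- rbind(S0 = c(0, 0), SA = c(1, 0), SAB = c(1, 1))
  colnames(m) <- c("A", "B")
  chain <- rbind(c(1, 5), c(2, 5), c(5, 6), c(3, 6), c(4, 6))
  expect_equal(fitch_score(chain, m), 2)

  # single subclone: all events on the stem
  m1 <- rbind(S1 = c(1, 1, 1))
  colnames(m1) <- c("A", "B", "C")
  t1 <- max_parsimony_tree(m1)
  expect_equal(t1$score, 3)
  expect_equal(t1$edge_length[2], 3L)  # stem-only tree

  # {A,B} and {A,C}: 3 changes with A below the join
  m2 <- rbind(S1 = c(1, 1, 0), S2 = c(1, 0, 1))
  colnames(m2) <- c("A", "B", "C")
  expect_equal(max_parsimony_tree(m2)$score, 3)
})

test_that("exact search matches exhaustive enumeration on random matrices", {
  for (seed in 1:20) {
    m <- rand_matrix(seed)
    tree <- max_parsimony_tree(m)
    expect_equal(tree$score, oracle_min_score(m),
                 info = paste("seed", seed))
    # the clone tree rescored from scratch reproduces its own score
    expect_equal(fitch_score(tree), tree$score)
  }
})

test_that("duplicate subclone rows do not change the score", {
  for (seed in 31:36) {
    m <- rand_matrix(seed)
    s1 <- max_parsimony_tree(m)$score
    m2 <- rbind(m, m[nrow(m), , drop = FALSE])
    rownames(m2)[nrow(m2)] <- "DUP"
    t2 <- max_parsimony_tree(m2)
    expect_equal(t2$score, s1)
    # the duplicate shares its twin's node
    node <- which(vapply(t2$subclones, function(s) "DUP" %in% s, TRUE))
    expect_true(rownames(m)[nrow(m)] %in% t2$subclones[[node]])
  }
})

test_that("homoplasy-free matrices map every event to exactly one edge", {
  for (seed in 41:46) {
    pt <- simulate_patient(sim_config(), seed = seed)
    tree <- max_parsimony_tree(pt$truth$matrix)
    expect_equal(tree$score, ncol(pt$truth$matrix))
    placed <- unlist(tree$edge_events)
    expect_equal(sort(placed), sort(colnames(pt$truth$matrix)))
    # and the score equals the sum of edge lengths (no hidden homoplasy)
    expect_equal(sum(tree$edge_length), tree$score)
  }
})

test_that("the heuristic search stays near the exact optimum and is deterministic", {
  set.seed(9)
  n_sub <- 11L
  m <- matrix(rbinom(11 * 18, 1, 0.4), n_sub, 18)
  m <- m[, colSums(m) > 0, drop = FALSE]
  m <- m[!duplicated(m), , drop = FALSE]
  dimnames(m) <- list(paste0("SC", seq_len(nrow(m))),
                      paste0("E", seq_len(ncol(m))))
  t1 <- max_parsimony_tree(m, exhaustive_limit = 5L)
  t2 <- max_parsimony_tree(m, exhaustive_limit = 5L)
  expect_identical(newick(t1), newick(t2))
  expect_gte(t1$score, ncol(m))  # lower bound: one change per event
})

test_that("Newick output is stable and carries edge lengths and events", {
  m <- rbind(SCa = c(1, 0, 0), SCb = c(1, 1, 0), SCc = c(1, 1, 1))
  colnames(m) <- c("e1", "e2", "e3")
  tree <- max_parsimony_tree(m)
  nwk <- newick(tree)
  expect_match(nwk, "^\\(.*\\)normal;$")
  expect_match(nwk, "SCc:1\\[&events=e3\\]")
  path <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tree, path)
  expect_equal(readLines(path), nwk)
  et <- edge_table(tree)
  expect_equal(et$n_events, c(1L, 1L, 1L))
  expect_equal(et$parent[1], "normal")
})

test_that("tree annotation attaches site detections and validates samples", {
  meta <- mk_meta(c("P1", "N1"), c("primary", "neck"),
                  c("primary", "lymph-node"))
  m <- rbind(SCa = c(1, 0), SCb = c(1, 1))
  colnames(m) <- c("e1", "e2")
  tree <- max_parsimony_tree(m)
  fr <- matrix(c(0.6, 0.5, 0.4, 0), 2, 2,
               dimnames = list(c("SCa", "SCb"), c("P1", "N1")))
  at <- annotate_tree(tree, meta, fr)
  expect_equal(sort(colnames(at$detections)[at$detections["SCa", ] > 0]),
               c("N1", "P1"))
  expect_error(annotate_tree(tree, meta[1, ], fr), class = "invalid_input")
})
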