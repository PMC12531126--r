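test_that("event merging unifies recurrent CNAs and exact-locus SNVs", {
  segs <- rbind(
    mk_segment(sample = "P1", chrom = "chr17", start = 3e7, end = 8e7,
               mcf = 1, clonal = TRUE),
    mk_segment(sample = "P2", chrom = "chr17", start = 3e7, end = 8e7,
               mcf = 0.6, clonal = FALSE),
    mk_segment(sample = "P1", chrom = "chr2", start = 1e6, end = 1e6,
               type = "snv", mcf = 0.5, clonal = FALSE)
  )
  segs$hgvs[3] <- "A>T"
  ev <- merge_events(segs)
  expect_equal(nrow(ev$events), 2)
  gain <- ev$mcf["gain_chr17_30000000_80000000", ]
  expect_equal(unname(gain), c(1, 0.6))
  expect_equal(unname(ev$mcf["snv_chr2_1000000_A>T", ]), c(0.5, 0))
})

test_that("reciprocal overlap controls CNA merging; kind always separates", {
  # 95% reciprocal overlap: one event
  segs <- rbind(
    mk_segment(sample = "P1", start = 1e6, end = 1e8, mcf = 0.8),
    mk_segment(sample = "P2", start = 1e6, end = 9.5e7, mcf = 0.7)
  )
  expect_equal(nrow(merge_events(segs)$events), 1)
  # 50% overlap: distinct events
  segs2 <- rbind(
    mk_segment(sample = "P1", start = 1e6, end = 1e8, mcf = 0.8),
    mk_segment(sample = "P2", start = 1e6, end = 5e7, mcf = 0.7)
  )
  expect_equal(nrow(merge_events(segs2)$events), 2)
  # same footprint, different kind: two events
  segs3 <- rbind(
    mk_segment(sample = "P1", start = 1e6, end = 1e8, type = "gain", mcf = 0.8),
    mk_segment(sample = "P1", start = 1e6, end = 1e8, type = "loss",
               nt = 1L, na_ = 0L, nb = 1L, mcf = 0.7)
  )
  expect_equal(nrow(merge_events(segs3)$events), 2)
  # contradictory duplicate rows for one sample are an ambiguity error
  segs4 <- rbind(
    mk_segment(sample = "P1", start = 1e6, end = 1e8, mcf = 0.9),
    mk_segment(sample = "P1", start = 1e6, end = 1e8, mcf = 0.2)
  )
  expect_error(merge_events(segs4), class = "ambiguity_error")
})

test_that("within-sample deconvolution stacks clusters by the pigeonhole rule", {
  # B-cells must be a subset of A-cells
  fr <- deconvolve_sample(mk_event_table(c(A = 1.0, B = 0.4)), "S1")
  expect_length(fr, 2)
  expect_equal(fr[[1]]$events, "A")
  expect_equal(fr[[1]]$fraction, 0.6)
  expect_equal(sort(fr[[2]]$events), c("A", "B"))
  expect_equal(fr[[2]]$fraction, 0.4)

  # 0.6 + 0.6 > 1 forces co-occurrence
  fr2 <- deconvolve_sample(mk_event_table(c(B = 0.6, C = 0.6)), "S1")
  expect_length(fr2, 1)
  expect_equal(sort(fr2[[1]]$events), c("B", "C"))
  expect_equal(fr2[[1]]$mcf, 0.6)
  expect_false(fr2[[1]]$ambiguous)

  # 0.3 + 0.3 is ambiguous: reported disjoint with a flag
  fr3 <- deconvolve_sample(mk_event_table(c(B = 0.3, C = 0.3)), "S1")
  expect_length(fr3, 2)
  expect_true(all(vapply(fr3, function(f) f$ambiguous, TRUE)))
  expect_equal(sort(vapply(fr3, function(f) f$events, "")), c("B", "C"))
})

test_that("cross-sample reconciliation builds the expected subclones", {
  # two samples, each stem + stem,X: two subclones, 2x2 matrix
  m <- rbind(stem = c(1, 1), X = c(0.4, 0.5))
  colnames(m) <- c("S1", "S2")
  ss <- reconcile_subclones(mk_event_table(m))
  expect_equal(dim(ss$matrix), c(2L, 2L))
  sets <- apply(ss$matrix, 1, function(r) paste(sort(colnames(ss$matrix)[r == 1]),
                                                collapse = "|"))
  expect_setequal(unname(sets), c("stem", "X|stem"))

  # cross-sample evidence resolves a within-sample ambiguity: in S1 both B
  # and C sit at 0.45, but S2 shows C nested far below B
  m2 <- rbind(stem = c(1, 1), B = c(0.45, 0.9), C = c(0.45, 0.2))
  colnames(m2) <- c("S1", "S2")
  ss2 <- reconcile_subclones(mk_event_table(m2))
  sets2 <- apply(ss2$matrix, 1, function(r) paste(sort(colnames(ss2$matrix)[r == 1]),
                                                  collapse = "|"))
  expect_true("B|C|stem" %in% sets2)  # C imposed inside B

  # identical event profiles across samples collapse to one subclone row
  m3 <- rbind(stem = c(1, 1, 1), a = c(0.5, 0.4, 0.7), b = c(0.5, 0.4, 0.7))
  colnames(m3) <- c("S1", "S2", "S3")
  ss3 <- reconcile_subclones(mk_event_table(m3))
  expect_equal(nrow(ss3$matrix), 2)
})

test_that("event matrices have no duplicate rows or empty columns and round-trip", {
  pt <- simulate_patient(sim_config(), seed = 77)
  ss <- reconcile_subclones(pt$truth$events)
  expect_false(any(duplicated(ss$matrix)))
  expect_true(all(colSums(ss$matrix) > 0))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_event_matrix(ss, path)
  expect_equal(read_event_matrix(path), ss$matrix)
})

test_that("deconvolution is deterministic", {
  pt <- simulate_patient(sim_config(), seed = 101)
  a <- reconcile_subclones(pt$truth$events)
  b <- reconcile_subclones(pt$truth$events)
  expect_identical(a$matrix, b$matrix)
  expect_identical(a$fractions, b$fractions)
})

test_that("noise-free deconvolution recovers the simulated subclones exactly", {
  for (seed in 301:310) {
    pt <- simulate_patient(sim_config(), seed = seed)
    ss <- reconcile_subclones(pt$truth$events)
    truth_sets <- apply(pt$truth$matrix, 1, function(r) {
      paste(sort(colnames(pt$truth$matrix)[r == 1]), collapse = "|")
    })
    est_sets <- apply(ss$matrix, 1, function(r) {
      paste(sort(colnames(ss$matrix)[r == 1]), collapse = "|")
    })
    expect_setequal(unname(est_sets), unname(truth_sets))
  }
})

test_that("fraction conservation: subclone fractions sum to the event MCF", {
  pt <- simulate_patient(sim_config(), seed = 55)
  ss <- reconcile_subclones(pt$truth$events)
  tol <- 0.1
  for (e in colnames(ss$matrix)) {
    carriers <- ss$matrix[, e] == 1
    total <- colSums(ss$fractions[carriers, , drop = FALSE])
    mcf <- pt$truth$events$mcf[e, colnames(ss$fractions)]
    mcf[mcf < 0.05] <- 0
    expect_true(all(abs(total - mcf) <= 2 * tol + 1e-9))
  }
  # per-sample fractions never exceed the tumor compartment
  expect_true(all(colSums(ss$fractions) <= 1 + tol))
})
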