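test_that("log2R inversion recovers the clone fraction of known mixtures", {
  # fully clonal one-copy gain on a diploid background
  expect_equal(msf_from_log2r(log2(3 / 2), 2, 3), 1)
  # no intensity shift means no altered cells
  expect_equal(msf_from_log2r(0, 2, 3), 0)
  # 40% of cells at 3 copies: mean copy number 2.4
  expect_equal(msf_from_log2r(log2(1.2), 2, 3), 0.4, tolerance = 1e-9)
  # copy-neutral segments cannot be quantified from log2R
  expect_error(msf_from_log2r(0.1, 2, 2), class = "invalid_input")
  # noisy values outside the plausible band warn and clamp
  expect_warning(out <- msf_from_log2r(log2(3.2 / 2), 2, 3),
                 class = "clonetrace_qc_warning")
  expect_equal(out, 1)
})

test_that("log2R inversion round-trips the forward mixture model", {
  for (np_ in c(2L, 4L)) {
    for (nt in setdiff(0:8, np_)) {
      for (msf in seq(0, 1, by = 0.1)) {
        mean_cn <- np_ + msf * (nt - np_)
        if (mean_cn <= 0) next
        expect_equal(msf_from_log2r(log2(mean_cn / np_), np_, nt), msf,
                     tolerance = 1e-9)
      }
    }
  }
})

test_that("mBAF inversion handles copy-neutral imbalances", {
  expect_equal(msf_from_mbaf(1.0, 0, 2), 1)    # pure copy-neutral LOH
  expect_equal(msf_from_mbaf(0.5, 0, 2), 0)    # balanced alleles
  expect_equal(msf_from_mbaf(0.75, 0, 2), 0.5) # half the cells are (B,B)
  expect_error(msf_from_mbaf(0.8, 2, 2), class = "invalid_input")
})

test_that("mBAF inversion round-trips its forward model", {
  # forward model: altered cells (n_a, n_b) against a diploid heterozygous
  # normal compartment
  for (comp in list(c(0L, 2L), c(1L, 3L))) {
    n_a <- comp[1]; n_b <- comp[2]
    for (msf in seq(0, 1, by = 0.1)) {
      mbaf <- (msf * n_b + (1 - msf)) / (msf * (n_a + n_b) + 2 * (1 - msf))
      expect_equal(msf_from_mbaf(mbaf, n_a, n_b), msf, tolerance = 1e-9)
    }
  }
})

test_that("purity estimation and the clonal interval follow the anchors", {
  p <- estimate_tcf(c(0.8, 0.8))
  expect_equal(p$tcf, 0.8)
  expect_equal(p$sd_msf, 0)
  expect_equal(c(p$clonal_low, p$clonal_high), c(1, 1))

  p2 <- estimate_tcf(c(0.75, 0.85))
  expect_equal(p2$tcf, 0.8)
  expect_equal(p2$sd_msf, 0.0707107, tolerance = 1e-6)
  expect_equal(p2$clonal_low, 0.8232233, tolerance = 1e-6)
  expect_equal(p2$clonal_high, 1.1767767, tolerance = 1e-6)

  p3 <- estimate_tcf(0.6)
  expect_equal(p3$tcf, 0.6)
  expect_equal(c(p3$clonal_low, p3$clonal_high), c(1, 1))

  expect_error(estimate_tcf(numeric()), class = "insufficient_anchors")
})

test_that("clone-fraction normalization calls clonality from the interval", {
  p <- sample_purity(0.8, sd_msf = 0.05)
  r <- mcf_normalize(0.72, p)  # raw 0.9 inside [0.875, 1.125]
  expect_equal(r$mcf, 1)
  expect_true(r$is_clonal)

  p0 <- sample_purity(0.8, sd_msf = 0)
  r2 <- mcf_normalize(0.4, p0)
  expect_equal(r2$mcf, 0.5)
  expect_false(r2$is_clonal)
  r3 <- mcf_normalize(0.8, p0)  # raw exactly 1
  expect_equal(r3$mcf, 1)
  expect_true(r3$is_clonal)
})

test_that("normalization is monotone in MSF and capped at 1", {
  p <- sample_purity(0.7, sd_msf = 0.04)
  msf <- seq(0, 1, by = 0.01)
  mcf <- mcf_normalize(msf, p)$mcf
  expect_true(all(diff(mcf) >= -1e-12))
  expect_true(all(mcf <= 1))
  # with zero spread, exactly raw MCF 1 is clonal
  p0 <- sample_purity(0.5, sd_msf = 0)
  out <- mcf_normalize(c(0.49, 0.5), p0)
  expect_equal(out$is_clonal, c(FALSE, TRUE))
})

test_that("quantify_sample routes segments and estimates purity", {
  segs <- rbind(
    mk_segment(sample = "S1", chrom = "chr1", type = "gain", nt = 3L,
               log2r = log2((2 + 0.8) / 2)),
    mk_segment(sample = "S1", chrom = "chr2", type = "cnni", nt = 2L,
               na_ = 0L, nb = 2L,
               mbaf = (0.8 * 2 + 0.2) / (0.8 * 2 + 2 * 0.2))
  )
  q <- quantify_sample(segs, anchors = 1:2)
  expect_equal(q$purity$tcf, 0.8, tolerance = 1e-9)
  expect_true(all(q$segments$clonal))
  expect_true(all(q$segments$MCF == 1))

  segs2 <- rbind(
    mk_segment(sample = "S1", chrom = "chr1", log2r = log2((2 + 0.8) / 2)),
    mk_segment(sample = "S1", chrom = "chr2", log2r = log2((2 + 0.8) / 2)),
    mk_segment(sample = "S1", chrom = "chr3", log2r = log2((2 + 0.32) / 2))
  )
  q2 <- quantify_sample(segs2, anchors = 1:2)
  expect_equal(q2$segments$MCF[3], 0.4, tolerance = 1e-9)
  expect_false(q2$segments$clonal[3])

  # snv-only rows cannot anchor purity
  expect_error(quantify_sample(mk_segment(type = "snv")),
               class = "insufficient_anchors")
})

test_that("segment tables round-trip through the tab-delimited format", {
  segs <- rbind(
    mk_segment(sample = "S1", chrom = "chr1", log2r = 0.3, mcf = 0.9,
               clonal = TRUE, gene = "MYCN"),
    mk_segment(sample = "S2", chrom = "chr17", type = "cnni", nt = 2L,
               na_ = 0L, nb = 2L, mbaf = 0.77, mcf = 0.4, clonal = FALSE)
  )
  segs$MSF <- c(0.7, NA)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segment_table(segs, path)
  hdr <- strsplit(readLines(path, n = 1), "\t")[[1]]
  expect_equal(hdr[8], "NA")  # the A-allele column keeps its short name
  back <- read_segment_table(path)
  expect_equal(back$MCF, segs$MCF)
  expect_equal(back$NA., segs$NA.)
  expect_equal(back$clonal, segs$clonal)
})
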