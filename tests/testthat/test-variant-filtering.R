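test_that("quality filter applies the tumor/normal VAF, depth and mapq rules", {
  calls <- rbind(
    mk_call(vaf_t = 0.04, dp_t = 100, dp_n = 100),              # low tumor VAF
    mk_call(vaf_t = 0.20, vaf_n = 0.06),                        # normal contamination
    mk_call(vaf_t = 0.20, dp_t = 19, dp_n = 100),               # shallow tumor
    mk_call(vaf_t = 0.20, dp_t = 100, dp_n = 19),               # shallow normal
    mk_call(vaf_t = 0.20, mapq = 49),                           # poor mapping
    mk_call(vaf_t = 0.20, passed_internal = FALSE),             # caller-internal fail
    mk_call(vaf_t = 0.20, in_popdb = TRUE),                     # population variant
    mk_call(vaf_t = 0.05, vaf_n = 0.05, dp_t = 20, dp_n = 20, mapq = 50),
    mk_call(vaf_t = 0.20, vaf_n = 0.01)
  )
  kept <- exclude_low_quality(calls)
  expect_equal(nrow(kept), 2)   # only the two boundary-satisfying calls
  expect_true(all(kept$vaf_t >= 0.05))
})

test_that("consensus keep-rule needs two samples and two callers overall, or two callers in one sample", {
  bed <- wide_bed()
  # one sample, two callers: kept
  c1 <- rbind(mk_call(sample = "S1", caller = "mutect2", pos = 100L),
              mk_call(sample = "S1", caller = "strelka2", pos = 100L))
  expect_equal(nrow(consensus_keep(c1, bed)), 1)
  # three samples, one caller only: removed
  c2 <- rbind(mk_call(sample = "S1", caller = "varscan2", pos = 200L),
              mk_call(sample = "S2", caller = "varscan2", pos = 200L),
              mk_call(sample = "S3", caller = "varscan2", pos = 200L))
  expect_equal(nrow(consensus_keep(c2, bed)), 0)
  # two samples, two callers across them: kept (one row per sample)
  c3 <- rbind(mk_call(sample = "S1", caller = "mutect2", pos = 300L),
              mk_call(sample = "S2", caller = "strelka2", pos = 300L))
  expect_equal(nrow(consensus_keep(c3, bed)), 2)
  # missing BED is a configuration error
  expect_error(consensus_keep(c1, NULL), class = "configuration_error")
})

test_that("loci outside the targeted regions are dropped (half-open BED)", {
  bed <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))  # BED 100-200
  inside <- rbind(mk_call(pos = 101L, caller = "mutect2"),
                  mk_call(pos = 101L, caller = "strelka2"))
  outside <- rbind(mk_call(pos = 100L, caller = "mutect2"),
                   mk_call(pos = 100L, caller = "strelka2"))
  expect_equal(nrow(consensus_keep(inside, bed)), 1)
  expect_equal(nrow(consensus_keep(outside, bed)), 0)
  # alleles at one position are distinct loci
  two_alleles <- rbind(
    mk_call(pos = 150L, alt = "G", caller = "mutect2"),
    mk_call(pos = 150L, alt = "G", caller = "strelka2"),
    mk_call(pos = 150L, alt = "C", caller = "mutect2"),
    mk_call(pos = 150L, alt = "C", caller = "strelka2")
  )
  expect_equal(nrow(consensus_keep(two_alleles, bed)), 2)
})

test_that("consensus filtering is order-independent and monotone", {
  bed <- wide_bed()
  calls <- rbind(
    mk_call(sample = "S1", caller = "mutect2", pos = 100L),
    mk_call(sample = "S2", caller = "strelka2", pos = 100L),
    mk_call(sample = "S1", caller = "varscan2", pos = 500L),
    mk_call(sample = "S1", caller = "mutect2", pos = 900L),
    mk_call(sample = "S1", caller = "manta", pos = 900L)
  )
  set.seed(11)
  base <- consensus_keep(calls, bed)
  for (i in 1:5) {
    perm <- consensus_keep(calls[sample(nrow(calls)), ], bed)
    expect_equal(perm, base)
  }
  # adding a supporting call never removes a kept locus
  kept_before <- paste(base$chrom, base$pos)
  more <- consensus_keep(rbind(calls, mk_call(sample = "S3",
                                              caller = "manta", pos = 500L)),
                         bed)
  expect_true(all(kept_before %in% paste(more$chrom, more$pos)))
})

test_that("VAF to clone fraction conversion matches the purity/copy-number model", {
  # clonal heterozygous variant in a pure diploid tumor
  expect_equal(mcf_from_vaf(0.5, tcf = 1), list(mcf = 1, m_used = 1L))
  expect_equal(mcf_from_vaf(0.25, tcf = 1)$mcf, 0.5)
  # raw 1.2 > 1.1 escalates the allele multiplicity to 2
  r <- mcf_from_vaf(0.6, tcf = 1)
  expect_equal(r$m_used, 2L)
  expect_equal(r$mcf, 0.6)
  # still out of range at m = 2: clamped with a QC warning
  expect_warning(r2 <- mcf_from_vaf(0.9, tcf = 0.7),
                 class = "clonetrace_qc_warning")
  expect_equal(r2$mcf, 1)
  expect_error(mcf_from_vaf(0.2, tcf = 0), class = "invalid_purity")
})

test_that("the diploid copy-neutral limit reduces to 2*VAF/TCF", {
  for (tcf in c(0.4, 0.7, 1)) {
    for (vaf in c(0.05, 0.1, 0.2)) {
      for (f in c(0, 0.3, 0.8)) {
        expect_equal(mcf_from_vaf(vaf, cn1 = 2, f1 = f, cn2 = 2, f2 = f,
                                  tcf = tcf)$mcf,
                     min(2 * vaf / tcf, 1), tolerance = 1e-12)
      }
    }
  }
})

test_that("patient-level variant filtering yields snv segment rows with clone fractions", {
  bed <- wide_bed()
  calls <- rbind(
    mk_call(sample = "S1", caller = "mutect2", pos = 100L, vaf_t = 0.2),
    mk_call(sample = "S1", caller = "strelka2", pos = 100L, vaf_t = 0.22),
    mk_call(sample = "S1", caller = "varscan2", pos = 999L, vaf_t = 0.3)
  )
  rows <- filter_patient_variants(calls, bed,
                                  list(S1 = sample_purity(0.8)))
  expect_equal(nrow(rows), 1)  # the single-caller locus is dropped
  expect_equal(rows$type, "snv")
  expect_equal(rows$MCF, 2 * 0.21 / 0.8, tolerance = 0.01)
  expect_false(rows$clonal)
})

test_that("variant tables round-trip through the flat TSV format", {
  calls <- rbind(mk_call(), mk_call(sample = "S2", in_popdb = TRUE))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(calls, path)
  back <- read_variant_table(path)
  expect_equal(back$vaf_t, calls$vaf_t)
  expect_equal(back$in_popdb, calls$in_popdb)
})
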