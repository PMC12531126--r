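# Multi-caller, multi-sample consensus filtering of targeted deep-sequencing
# somatic variant calls, and conversion of VAFs to mutated clone fractions.

#' Quality filter for somatic variant calls
#'
#' Removes likely FFPE and alignment artifacts. A call is kept when, in the
#' tumor/normal pair: tumor VAF >= 0.05, normal VAF <= 0.05 (normals are
#' sampled from the tumor periphery and may carry minor contamination),
#' read depth >= 20 in both samples, and mapping quality >= 50. Calls must
#' already have passed each caller's internal filters and the
#' population-database / panel-of-normals removal (boolean input columns).
#'
#' @param calls Variant-call data frame ([read_variant_table()] layout).
#' @param vaf_tumor_min,vaf_normal_max,dp_min,mapq_min Thresholds; defaults
#'   are the values used throughout this pipeline.
#' @return The kept subset of `calls`.
#' @export
exclude_low_quality <- function(calls, vaf_tumor_min = 0.05,
                                vaf_normal_max = 0.05, dp_min = 20,
                                mapq_min = 50) {
  keep <- calls$passed_internal &
    !calls$in_pon & !calls$in_popdb &
    calls$vaf_t >= vaf_tumor_min &
    calls$vaf_n <= vaf_normal_max &
    calls$dp_t >= dp_min &
    calls$dp_n >= dp_min &
    calls$mapq >= mapq_min
  calls[which(keep), , drop = FALSE]
}

locus_key <- function(calls) {
  paste(calls$chrom, calls$pos, calls$ref, calls$alt, sep = ":")
}

#' Consensus keep-rule across samples and callers
#'
#' Collapses per-caller calls of one patient to loci and keeps a locus iff
#' it was detected in at least two samples and by at least two different
#' callers in total, or — when seen in a single sample only — by at least
#' two callers in that sample. Loci must also fall inside the targeted
#' regions. Loci sharing a position but differing in alleles are distinct.
#'
#' @param calls Quality-filtered calls of one patient.
#' @param bed `GRanges` of targeted regions ([read_bed()]); required.
#' @param vaf_weight How to combine VAFs of concordant callers within a
#'   sample: `"depth"` (depth-weighted mean, default) or `"mean"`.
#' @return Data frame with one row per kept locus per supporting sample:
#'   columns `patient, chrom, pos, ref, alt, gene, sample, vaf, dp,
#'   n_samples, n_callers`.
#' @export
consensus_keep <- function(calls, bed, vaf_weight = c("depth", "mean")) {
  if (missing(bed) || is.null(bed)) {
    stop_ct("a BED of targeted regions is required", "configuration_error")
  }
  vaf_weight <- match.arg(vaf_weight)
  empty_kept <- data.frame(patient = character(), chrom = character(),
                           pos = integer(), ref = character(),
                           alt = character(), gene = character(),
                           sample = character(), vaf = numeric(),
                           dp = numeric(), n_samples = integer(),
                           n_callers = integer())
  if (nrow(calls) == 0) return(empty_kept)
  gr <- GenomicRanges::GRanges(calls$chrom,
                               IRanges::IRanges(calls$pos, calls$pos))
  inside <- GenomicRanges::countOverlaps(gr, bed) > 0
  calls <- calls[inside, , drop = FALSE]
  if (nrow(calls) == 0) return(empty_kept)
  key <- locus_key(calls)
  out <- lapply(split(seq_len(nrow(calls)), key), function(ix) {
    cc <- calls[ix, , drop = FALSE]
    n_samples <- length(unique(cc$sample))
    n_callers <- length(unique(cc$caller))
    kept <- (n_samples >= 2 && n_callers >= 2) ||
      (n_samples == 1 && n_callers >= 2)
    if (!kept) return(NULL)
    per_sample <- lapply(split(cc, cc$sample), function(s) {
      w <- if (vaf_weight == "depth") s$dp_t else rep(1, nrow(s))
      data.frame(
        patient = s$patient[1], chrom = s$chrom[1], pos = s$pos[1],
        ref = s$ref[1], alt = s$alt[1], gene = s$gene[1],
        sample = s$sample[1],
        vaf = sum(s$vaf_t * w) / sum(w), dp = max(s$dp_t),
        n_samples = n_samples, n_callers = n_callers,
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, per_sample)
  })
  out <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(out)) out <- empty_kept
  out <- out[order(out$chrom, out$pos, out$ref, out$alt, out$sample), ,
             drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Mutated clone fraction from a variant allele frequency
#'
#' Converts a VAF to the fraction of tumor cells carrying the variant,
#' correcting for purity and the local copy-number mixture. With `cn1` the
#' copy number in the CNA-bearing tumor fraction `f1`, `cn2` the copy
#' number of the remaining tumor cells, normal cells diploid, and `m`
#' variant-bearing alleles per mutated cell:
#' `MCF = VAF * (cn1*TCF*f1 + cn2*(TCF - TCF*f2) + 2*(1 - TCF)) / (m*TCF)`.
#' `f2` defaults to `f1`, which makes the numerator VAF times the mean
#' locus copy number — the only reading that reduces to the textbook
#' diploid `2*VAF/TCF`. `m` starts at 1; when the raw MCF exceeds 1.1 it is
#' recomputed with `m = 2` (the variant sits on both copies). Values still
#' above 1.1 at `m = 2` are clamped to 1 with a QC warning.
#'
#' @param vaf Variant allele frequency in \[0, 1\].
#' @param cn1,cn2 Locus copy numbers (CNA-bearing / CNA-free tumor cells).
#' @param f1 MCF of the CNA at the locus (0 when copy-neutral).
#' @param f2 Defaults to `f1`; see Details.
#' @param tcf Tumor cell fraction in (0, 1].
#' @param m Initial variant allele multiplicity, 1 or 2.
#' @return List with `mcf` (clamped to \[0, 1\]) and `m_used`.
#' @examples
#' mcf_from_vaf(0.5, tcf = 1)   # clonal heterozygous, pure diploid: MCF 1
#' mcf_from_vaf(0.6, tcf = 1)   # raw 1.2 > 1.1 escalates to m = 2
#' @export
mcf_from_vaf <- function(vaf, cn1 = 2, f1 = 0, cn2 = cn1, f2 = f1,
                         tcf, m = 1L) {
  if (tcf <= 0 || tcf > 1) stop_ct("tcf must lie in (0, 1]", "invalid_purity")
  if (!m %in% c(1L, 2L)) stop_ct("m must be 1 or 2", "invalid_input")
  raw_at <- function(mm) {
    vaf * (cn1 * tcf * f1 + cn2 * (tcf - tcf * f2) + 2 * (1 - tcf)) / (mm * tcf)
  }
  raw <- raw_at(m)
  m_used <- m
  if (raw > 1.1 && m == 1L) {
    m_used <- 2L
    raw <- raw_at(2L)
  }
  if (raw > 1.1) {
    warn_qc(sprintf("MCF %.3f > 1.1 at m = 2; clamped to 1", raw))
  }
  list(mcf = min(max(raw, 0), 1), m_used = m_used)
}

#' Filter a patient's variant calls and attach clone fractions
#'
#' Convenience wrapper: [exclude_low_quality()] then [consensus_keep()],
#' then [mcf_from_vaf()] per kept locus and sample using that sample's
#' purity, returning rows appendable to the segment table as `type = "snv"`.
#'
#' @param calls Variant calls of one patient.
#' @param bed Targeted-region `GRanges`.
#' @param purities Named list of `sample_purity` objects keyed by sample id.
#' @param cna_context Optional function `(chrom, pos, sample) -> list(cn1,
#'   f1)` providing the local copy-number context; default assumes diploid.
#' @return Segment-table rows (internal layout) with `type = "snv"` and
#'   `MCF` filled; zero rows when nothing survives.
#' @export
filter_patient_variants <- function(calls, bed, purities,
                                    cna_context = NULL) {
  kept <- consensus_keep(exclude_low_quality(calls), bed)
  if (nrow(kept) == 0) return(empty_segment_table(0))
  rows <- empty_segment_table(nrow(kept))
  rows$patient <- kept$patient
  rows$sample <- kept$sample
  rows$chrom <- kept$chrom
  rows$start <- kept$pos
  rows$end <- kept$pos
  rows$type <- "snv"
  rows$gene <- kept$gene
  rows$hgvs <- paste0(kept$ref, ">", kept$alt)
  rows$.mcf_sd <- NA_real_
  for (i in seq_len(nrow(kept))) {
    p <- purities[[kept$sample[i]]]
    if (is.null(p)) {
      stop_ct(paste0("no purity for sample ", kept$sample[i]), "invalid_input")
    }
    ctx <- if (is.null(cna_context)) list(cn1 = 2, f1 = 0) else {
      cna_context(kept$chrom[i], kept$pos[i], kept$sample[i])
    }
    # a raw single-allele MCF inside the sample's clonal interval is a
    # clonal variant (set to 1, like clonal CNAs). The window is extended
    # toward 1.4: purity underestimation inflates the raw values of clonal
    # heterozygous variants, while a genuinely biallelic clonal variant
    # sits near 2 — only clearly larger values go through escalation.
    raw1 <- kept$vaf[i] * (ctx$cn1 * p$tcf * ctx$f1 +
                             ctx$cn1 * (p$tcf - p$tcf * ctx$f1) +
                             2 * (1 - p$tcf)) / p$tcf
    m_used <- 1L
    if (raw1 >= p$clonal_low && raw1 <= max(p$clonal_high, 1.4)) {
      mcf <- 1
    } else {
      mv <- mcf_from_vaf(kept$vaf[i], cn1 = ctx$cn1, f1 = ctx$f1,
                         tcf = p$tcf)
      mcf <- mv$mcf
      m_used <- mv$m_used
    }
    rows$MCF[i] <- mcf
    rows$clonal[i] <- mcf >= 1 - 1e-9
    # measurement error: binomial read-count noise propagated through the
    # diploid conversion, plus the sample-wide purity uncertainty (a VAF
    # at deep coverage is precise, but the MCF it implies scales with
    # 1/TCF, so a purity error shifts all of a sample's variant MCFs)
    binom_sd <- 2 * sqrt(max(kept$vaf[i] * (1 - kept$vaf[i]), 1e-6) /
                           max(kept$dp[i], 1)) / (m_used * p$tcf)
    tcf_rel <- if (p$sd_msf < 1e-9) 0 else
      max(p$sd_msf / sqrt(max(p$n_clonal_anchors, 1)), 0.05) / p$tcf
    rows$.mcf_sd[i] <- sqrt(binom_sd^2 + (tcf_rel * mcf)^2)
  }
  rows
}
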