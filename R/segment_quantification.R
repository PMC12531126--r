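# Clone-fraction quantification from SNP-array segment measurements.
#
# Terminology used throughout:
#   MSF — mutated sample fraction: proportion of *all* cells in a sample that
#         carry an alteration.
#   MCF — mutated clone fraction: proportion of tumor (non-normal) cells that
#         carry it; MCF = MSF / TCF.
#   TCF — tumor cell fraction (sample purity), estimated as the mean MSF of
#         the clearly clonal alterations.

#' Mutated sample fraction from a segment log2 ratio
#'
#' Inverts the intensity mixture model for a copy-number altered segment: a
#' fraction `MSF` of cells carry `nt` copies while the background carries
#' `np_` copies, so the observed mean copy number is
#' `np_ + MSF * (nt - np_)` and
#' `MSF = (np_ * 2^log2r - np_) / (nt - np_)`.
#'
#' @param log2r Segment log2 intensity ratio, normalized so that 0 means
#'   `np_` copies.
#' @param np_ Integer background ploidy at the locus (the ploidy the log2
#'   ratio is normalized against; 4 for whole-genome-doubled samples).
#' @param nt Integer copy number of the altered cells; must differ from
#'   `np_` (a copy-number-neutral imbalance has no log2R signal — use
#'   [msf_from_mbaf()]).
#' @return MSF clamped into \[0, 1\]. Raw values outside \[-0.02, 1.05\]
#'   (possible under FFPE noise) trigger a QC warning before clamping.
#' @examples
#' msf_from_log2r(log2(3 / 2), np_ = 2, nt = 3)  # fully clonal trisomy: 1
#' msf_from_log2r(0, np_ = 2, nt = 3)            # no shift: 0
#' @seealso [msf_from_mbaf()], [estimate_tcf()], [mcf_normalize()]
#' @export
msf_from_log2r <- function(log2r, np_ = 2L, nt) {
  if (np_ < 1) stop_ct("`np_` must be a positive integer ploidy", "invalid_input")
  if (any(nt == np_)) {
    stop_ct(paste0(
      "nt equals the background ploidy (", np_, "): the segment is copy-number",
      " neutral; use msf_from_mbaf() on its allelic imbalance instead"
    ), "invalid_input")
  }
  raw <- (np_ * 2^log2r - np_) / (nt - np_)
  if (any(raw < -0.02 | raw > 1.05)) {
    warn_qc(sprintf(
      "raw MSF outside [-0.02, 1.05] (%s): possible noise or wrong Nt/Np",
      paste(signif(raw[raw < -0.02 | raw > 1.05], 3), collapse = ", ")
    ))
  }
  pmin(pmax(raw, 0), 1)
}

#' Mutated sample fraction from mirrored B-allele frequency (CNNI)
#'
#' Copy-number-neutral imbalances (e.g. copy-neutral LOH) leave no log2R
#' footprint; their clone size is recovered from the mirrored BAF. With
#' altered cells of allelic composition `(n_a, n_b)`, `n_b > n_a`, mixed
#' into a diploid heterozygous background,
#' `MSF = (1 - 2 mBAF) / (mBAF (n_a + n_b - 2) - n_b + 1)`.
#'
#' @param mbaf Mirrored B-allele frequency in \[0.5, 1\].
#' @param n_a,n_b Integer allele counts of the altered state (`n_b > n_a`).
#' @return MSF clamped into \[0, 1\].
#' @examples
#' msf_from_mbaf(1.0, 0, 2)   # pure copy-neutral LOH: 1
#' msf_from_mbaf(0.75, 0, 2)  # half the cells (B,B): 0.5
#' @export
msf_from_mbaf <- function(mbaf, n_a, n_b) {
  if (any(n_b <= n_a)) stop_ct("CNNI requires n_b > n_a", "invalid_input")
  if (any(mbaf < 0.5 - 1e-9 | mbaf > 1 + 1e-9)) {
    stop_ct("mbaf must lie in [0.5, 1]", "invalid_input")
  }
  den <- mbaf * (n_a + n_b - 2) - n_b + 1
  if (any(abs(den) < 1e-12)) {
    stop_ct("degenerate allelic composition: mBAF denominator is zero",
            "degenerate_composition")
  }
  raw <- (1 - 2 * mbaf) / den
  pmin(pmax(raw, 0), 1)
}

#' Estimate tumor cell fraction from clonal anchor segments
#'
#' The purity of a sample is taken as the mean MSF of its clearly clonal
#' alterations; the spread of those anchors defines the interval (in MCF
#' space, centered on 1) inside which an alteration is still called clonal:
#' `(TCF - 2 SD) / TCF` to `(TCF + 2 SD) / TCF`.
#'
#' @param clonal_msfs Numeric vector of anchor MSFs in (0, 1].
#' @param sample_id Optional sample identifier carried on the result.
#' @return An object of class `sample_purity`: list with `tcf`, `sd_msf`,
#'   `clonal_low`, `clonal_high`, `n_clonal_anchors`, `sample_id`.
#' @examples
#' estimate_tcf(c(0.75, 0.85))
#' @export
estimate_tcf <- function(clonal_msfs, sample_id = NA_character_) {
  clonal_msfs <- clonal_msfs[!is.na(clonal_msfs)]
  if (length(clonal_msfs) == 0) {
    stop_ct(paste0(
      "no clonal anchor segments: designate anchors or supply the tumor cell",
      " fraction directly"
    ), "insufficient_anchors")
  }
  if (any(clonal_msfs <= 0 | clonal_msfs > 1)) {
    stop_ct("anchor MSFs must lie in (0, 1]", "invalid_input")
  }
  tcf <- mean(clonal_msfs)
  sd_msf <- if (length(clonal_msfs) > 1) stats::sd(clonal_msfs) else 0
  structure(
    list(
      sample_id = sample_id,
      tcf = tcf,
      sd_msf = sd_msf,
      clonal_low = (tcf - 2 * sd_msf) / tcf,
      clonal_high = (tcf + 2 * sd_msf) / tcf,
      n_clonal_anchors = length(clonal_msfs)
    ),
    class = "sample_purity"
  )
}

#' @export
print.sample_purity <- function(x, ...) {
  cat(sprintf(
    "<sample_purity%s> TCF %.3f (sd_MSF %.3f, %d anchors); clonal MCF interval [%.3f, %.3f]\n",
    if (is.na(x$sample_id)) "" else paste0(" ", x$sample_id),
    x$tcf, x$sd_msf, x$n_clonal_anchors, x$clonal_low, x$clonal_high
  ))
  invisible(x)
}

#' Purity object from a known tumor cell fraction
#'
#' Used when purity is supplied externally (e.g. pathologist estimate)
#' rather than derived from clonal anchors; the clonal interval collapses
#' to the point MCF = 1 unless `sd_msf` is given.
#'
#' @param tcf Tumor cell fraction in (0, 1].
#' @param sd_msf Standard deviation to build the clonal interval from.
#' @inheritParams estimate_tcf
#' @return A `sample_purity` object.
#' @export
sample_purity <- function(tcf, sd_msf = 0, sample_id = NA_character_) {
  if (tcf <= 0 || tcf > 1) stop_ct("tcf must lie in (0, 1]", "invalid_input")
  structure(
    list(
      sample_id = sample_id, tcf = tcf, sd_msf = sd_msf,
      clonal_low = (tcf - 2 * sd_msf) / tcf,
      clonal_high = (tcf + 2 * sd_msf) / tcf,
      n_clonal_anchors = 0L
    ),
    class = "sample_purity"
  )
}

#' Normalize an MSF to a clone fraction and call clonality
#'
#' Divides by purity and compares the raw MCF against the sample's clonal
#' interval: alterations inside the interval are deemed clonal and their MCF
#' set to 1; the rest keep their (capped) raw MCF.
#'
#' @param msf Mutated sample fraction in \[0, 1\].
#' @param purity A `sample_purity` object.
#' @return List with `mcf` and `is_clonal`. Vectorized over `msf`.
#' @examples
#' p <- sample_purity(0.8, sd_msf = 0.05)
#' mcf_normalize(0.72, p)  # raw 0.9 falls in the clonal interval -> MCF 1
#' @export
mcf_normalize <- function(msf, purity) {
  stopifnot(inherits(purity, "sample_purity"))
  if (purity$tcf <= 0) stop_ct("purity tcf must be positive", "invalid_input")
  raw <- msf / purity$tcf
  clonal <- raw >= purity$clonal_low & raw <= purity$clonal_high
  list(mcf = ifelse(clonal, 1, pmin(raw, 1)), is_clonal = clonal)
}

# Pick "clearly clonal" anchors from raw MSFs when the user supplies none:
# 1D single-linkage clustering of the MSFs (gap > gap_min splits), then the
# highest-mean cluster that is substantial — tiny top clusters are noise
# outliers, not the clonal plateau read off an allelic-imbalance plot.
auto_anchor_idx <- function(raw_msf, gap_min = 0.1) {
  ok <- which(!is.na(raw_msf) & raw_msf > 0)
  if (length(ok) == 0) return(integer())
  cl <- cluster_1d(raw_msf[ok], gap_min)
  # isolated top values are noise outliers, not the clonal plateau: accept
  # the highest cluster with >= 3 members, or a pair only when it is an
  # exact plateau (identical values, as in noise-free data)
  for (i in seq_len(max(cl))) {  # clusters ordered by decreasing MSF
    members <- ok[cl == i]
    if (length(members) >= min(3L, length(ok)) ||
        (length(members) == 2L && diff(range(raw_msf[members])) < 1e-6)) {
      return(members)
    }
  }
  ok[cl == 1L]
}

#' Calibrate per-row clone-fraction measurement errors
#'
#' Estimates the log2R (and mBAF) measurement noise of a patient's arrays
#' from the residuals of clonal segments — whose expected signal is fixed
#' by the sample purity — pooled across samples, and propagates it through
#' the inversion derivative of each row. This gives type-aware errors
#' (a one-copy loss pins the log2 ratio much harder than a high-level
#' gain) and corrects the downward bias of the anchor-gap spread. The
#' clonal residuals are themselves interval-truncated (a clonal call
#' requires the value to fall inside roughly +/- 2 sd), so the pooled sd
#' is divided by the corresponding truncated-normal factor 0.88.
#'
#' @param segments Quantified rows for one patient across samples (with
#'   `.mcf_sd` from [quantify_sample()]).
#' @param purities Named list of `sample_purity` objects.
#' @return `segments` with `.mcf_sd` recalibrated for CNA rows.
#' @export
calibrate_errors <- function(segments, purities) {
  tcf_of <- vapply(purities, function(p) p$tcf, 0)
  res_l <- numeric()
  res_b <- numeric()
  for (i in seq_len(nrow(segments))) {
    if (!isTRUE(segments$clonal[i])) next
    tcf <- tcf_of[segments$sample[i]]
    if (is.na(tcf)) next
    if (segments$type[i] %in% c("gain", "loss")) {
      l_exp <- log2((segments$Np[i] + tcf * (segments$Nt[i] - segments$Np[i])) /
                      segments$Np[i])
      res_l <- c(res_l, segments$log2R[i] - l_exp)
    } else if (segments$type[i] == "cnni") {
      na_ <- segments$NA.[i]; nb <- segments$NB[i]
      b_exp <- (tcf * nb + (1 - tcf)) / (tcf * (na_ + nb) + 2 * (1 - tcf))
      res_b <- c(res_b, segments$mBAF[i] - b_exp)
    }
  }
  sig_l <- if (length(res_l) >= 5) stats::sd(res_l) / 0.88 else NA_real_
  if (is.na(sig_l)) return(segments)
  sig_b <- if (length(res_b) >= 5) stats::sd(res_b) / 0.88 else sig_l * 0.3
  for (i in seq_len(nrow(segments))) {
    tcf <- tcf_of[segments$sample[i]]
    if (is.na(tcf)) next
    sd_msf <- if (segments$type[i] %in% c("gain", "loss")) {
      segments$Np[i] * 2^segments$log2R[i] * log(2) /
        abs(segments$Nt[i] - segments$Np[i]) * sig_l
    } else if (segments$type[i] == "cnni") {
      na_ <- segments$NA.[i]; nb <- segments$NB[i]
      m <- segments$mBAF[i]
      den <- m * (na_ + nb - 2) - nb + 1
      abs((-2 * den - (1 - 2 * m) * (na_ + nb - 2)) / den^2) * sig_b
    } else NA_real_
    if (!is.na(sd_msf)) segments$.mcf_sd[i] <- sd_msf / tcf
  }
  segments
}

#' Quantify clone fractions for all segments of one sample
#'
#' Routes each segment to the log2R inversion (gains/losses) or the mBAF
#' inversion (CNNIs), estimates the tumor cell fraction from anchor
#' segments, and fills `msf`, `mcf` and `clonal` on every row.
#'
#' @param segments Data frame of segment calls for one sample, in the layout
#'   of [read_segment_table()] (columns `sample`, `type`, `Nt`, `NA.`,
#'   `NB`, `Np`, `log2R`, `mBAF`, ...).
#' @param anchors Optional character vector of `event` identifiers (or row
#'   indices) to use as clonal purity anchors. When `NULL`, the highest-MSF
#'   cluster (single-linkage, gap > `anchor_gap`) is used.
#' @param tcf Optional externally supplied purity overriding estimation.
#' @param anchor_gap Gap (in MSF units) that terminates the top cluster
#'   during automatic anchor selection.
#' @return List with `segments` (the input with `MSF`, `MCF`, `clonal`
#'   filled) and `purity` (a `sample_purity`).
#' @export
quantify_sample <- function(segments, anchors = NULL, tcf = NULL,
                            anchor_gap = 0.1) {
  stopifnot(is.data.frame(segments))
  if (length(unique(segments$sample)) > 1) {
    stop_ct("all segments must share one sample id", "invalid_input")
  }
  n <- nrow(segments)
  raw <- numeric(n)
  for (i in seq_len(n)) {
    raw[i] <- switch(segments$type[i],
      gain = ,
      loss = msf_from_log2r(segments$log2R[i], segments$Np[i], segments$Nt[i]),
      cnni = msf_from_mbaf(segments$mBAF[i], segments$NA.[i], segments$NB[i]),
      snv = NA_real_,  # SNV clone fractions come from the variant module
      stop_ct(paste0("unknown alteration type: ", segments$type[i]),
              "invalid_input")
    )
  }
  cn <- which(!is.na(raw))
  purity <- if (!is.null(tcf)) {
    sample_purity(tcf, sd_msf = 0, sample_id = segments$sample[1])
  } else {
    idx <- if (!is.null(anchors)) {
      if (is.numeric(anchors)) as.integer(anchors) else which(segments$event %in% anchors)
    } else {
      auto_anchor_idx(raw, gap_min = anchor_gap)
    }
    idx <- intersect(idx, cn)
    if (length(idx) == 0) {
      stop_ct("anchor resolution found no usable clonal segments",
              "insufficient_anchors")
    }
    estimate_tcf(raw[idx], sample_id = segments$sample[1])
  }
  segments$MSF[cn] <- raw[cn]
  nm <- mcf_normalize(raw[cn], purity)
  segments$MCF[cn] <- nm$mcf
  segments$clonal[cn] <- nm$is_clonal
  # per-row MCF measurement error, propagated downstream so the
  # deconvolution can scale its clustering bands. The anchor spread sd_msf
  # estimates the MSF-space noise of array segments but is biased low by
  # the gap-based anchor truncation, so noisy samples are floored at half
  # the anchor gap; noise-free data (zero anchor spread) keeps exact
  # bands. Clonal pinning is a classification, not a certainty, so pinned
  # values keep the sample's measurement error.
  segments$.mcf_sd <- NA_real_
  sd_eff <- if (purity$sd_msf < 1e-9) 0 else
    max(purity$sd_msf, anchor_gap / 2)
  segments$.mcf_sd[cn] <- sd_eff / purity$tcf
  list(segments = segments, purity = purity)
}
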