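# Subclonal deconvolution from mutated-clone-fraction profiles across the
# multiregional samples of one patient.
#
# Alterations acquired on the same branch of the clone tree share one MCF
# profile across samples (an event's MCF is the summed fraction of all
# subclones descending through that branch), so events are clustered by
# profile similarity; the clusters are then stacked into a nesting forest
# under the pigeonhole constraint that fractions of co-resident clones
# cannot exceed the tumor compartment.

#' Merge per-sample alterations into patient-level events
#'
#' CNAs of the same kind whose footprints reciprocally overlap at least
#' `reciprocal_overlap` across samples are one event; SNVs merge by exact
#' locus. Samples where an event was not observed get MCF 0 (absence is
#' assumed verified upstream).
#'
#' @param segments Quantified segment rows (internal layout, `MCF` filled)
#'   across all samples of one patient.
#' @param samples Optional character vector fixing the sample set/order
#'   (defaults to the samples present in `segments`).
#' @param reciprocal_overlap Minimum reciprocal footprint overlap for two
#'   CNAs to be the same event.
#' @return An object of class `event_table`: list with `events` (data frame
#'   `event, kind, chrom, start, end, gene`) and `mcf` (events x samples
#'   matrix), plus `clonal` (logical matrix, same shape).
#' @export
merge_events <- function(segments, samples = NULL,
                         reciprocal_overlap = 0.9) {
  stopifnot(is.data.frame(segments))
  if (length(unique(segments$patient)) > 1) {
    stop_ct("segments must come from one patient", "invalid_input")
  }
  samples <- samples %||% unique(segments$sample)
  segments$.row <- seq_len(nrow(segments))

  groups <- list()
  snv <- segments[segments$type == "snv", , drop = FALSE]
  if (nrow(snv)) {
    key <- paste0("snv_", snv$chrom, "_", snv$start, "_", snv$hgvs)
    groups <- c(groups, split(snv$.row, key))
  }
  cna <- segments[segments$type != "snv", , drop = FALSE]
  if (nrow(cna)) {
    for (grp in split(cna$.row, paste(cna$type, cna$chrom))) {
      sub <- segments[grp, , drop = FALSE]
      n <- nrow(sub)
      if (n == 1) {
        comp <- 1L
      } else {
        ir <- IRanges::IRanges(sub$start, sub$end)
        ov <- IRanges::findOverlaps(ir, ir)
        qi <- S4Vectors::queryHits(ov); si <- S4Vectors::subjectHits(ov)
        w <- IRanges::width(IRanges::pintersect(ir[qi], ir[si]))
        recip <- w / pmax(IRanges::width(ir)[qi], IRanges::width(ir)[si])
        keep <- recip >= reciprocal_overlap & qi < si
        # single-linkage connected components over qualifying pairs
        comp <- seq_len(n)
        for (k in which(keep)) {
          a <- comp[qi[k]]; b <- comp[si[k]]
          if (a != b) comp[comp == max(a, b)] <- min(a, b)
        }
      }
      for (cc in split(sub$.row, comp)) {
        rows <- segments[cc, , drop = FALSE]
        id <- sprintf("%s_%s_%d_%d", rows$type[1], rows$chrom[1],
                      min(rows$start), max(rows$end))
        groups[[id]] <- cc
      }
    }
  }
  if (length(groups) == 0) {
    stop_ct("no alterations to merge", "invalid_input")
  }
  # deterministic genomic order
  ord <- order(vapply(groups, function(ix) segments$chrom[ix[1]], ""),
               vapply(groups, function(ix) min(segments$start[ix]), 0),
               names(groups))
  groups <- groups[ord]

  ev <- data.frame(
    event = names(groups),
    kind = vapply(groups, function(ix) segments$type[ix[1]], ""),
    chrom = vapply(groups, function(ix) segments$chrom[ix[1]], ""),
    start = vapply(groups, function(ix) min(segments$start[ix]), 0),
    end = vapply(groups, function(ix) max(segments$end[ix]), 0),
    gene = vapply(groups, function(ix) segments$gene[ix[1]], ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
  mcf <- matrix(0, nrow(ev), length(samples),
                dimnames = list(ev$event, samples))
  clonal <- matrix(FALSE, nrow(ev), length(samples),
                   dimnames = list(ev$event, samples))
  mcf_sd <- matrix(0, nrow(ev), length(samples),
                   dimnames = list(ev$event, samples))
  for (i in seq_along(groups)) {
    rows <- segments[groups[[i]], , drop = FALSE]
    dup <- rows[duplicated(rows$sample) | duplicated(rows$sample, fromLast = TRUE), ]
    if (nrow(dup) && any(tapply(dup$MCF, dup$sample,
                                function(v) diff(range(v)) > 0.25))) {
      stop_ct(paste0("conflicting rows merged into event ", ev$event[i], ": ",
                     paste(dup$.row, collapse = ", ")), "ambiguity_error")
    }
    m <- tapply(rows$MCF, rows$sample, mean)
    m <- m[names(m) %in% samples]
    mcf[i, names(m)] <- m
    cl <- tapply(rows$clonal, rows$sample, any)
    cl <- cl[names(cl) %in% samples]
    clonal[i, names(cl)] <- cl
    if (!is.null(segments$.mcf_sd)) {
      sdv <- tapply(segments$.mcf_sd[groups[[i]]], rows$sample, mean)
      sdv <- sdv[names(sdv) %in% samples]
      mcf_sd[i, names(sdv)] <- sdv
    }
  }
  structure(list(events = ev, mcf = mcf, clonal = clonal,
                 mcf_sd = if (is.null(segments$.mcf_sd)) NULL else mcf_sd,
                 samples = samples),
            class = "event_table")
}

#' @export
print.event_table <- function(x, ...) {
  cat(sprintf("<event_table> %d events x %d samples (%s)\n",
              nrow(x$events), length(x$samples),
              paste(table(x$events$kind), names(table(x$events$kind)),
                    collapse = ", ")))
  invisible(x)
}

# 1D single-linkage clustering of MCF values: sorted descending, a new
# cluster starts when the gap to the previous value exceeds `tol`.
cluster_1d <- function(values, tol) {
  o <- order(values, decreasing = TRUE)
  cl <- integer(length(values))
  cur <- 1L
  for (i in seq_along(o)) {
    if (i > 1 && values[o[i - 1]] - values[o[i]] > tol) cur <- cur + 1L
    cl[o[i]] <- cur
  }
  cl
}

#' Deconvolve subclones within a single sample
#'
#' Clusters the events present in one sample by MCF and stacks the clusters
#' into a nesting chain under the pigeonhole principle: a cluster nests
#' inside any cluster of larger fraction, and two clusters whose fractions
#' sum to more than `1 + mcf_tolerance` cannot be disjoint. Clusters at
#' indistinguishable fractions whose co-occurrence is not forced are
#' ambiguous (nested or disjoint): they are reported as disjoint per-event
#' fragments with `ambiguous = TRUE`; cross-sample reconciliation
#' ([reconcile_subclones()]) supersedes this within-sample reading.
#'
#' @param events An `event_table` ([merge_events()]).
#' @param sample_id Sample to deconvolve.
#' @param mcf_tolerance MCF clustering tolerance.
#' @param detection Minimum MCF for an event to count as present.
#' @return List of subclone fragments: each a list with `events`
#'   (cumulative event ids), `fraction` (identity fraction of cells whose
#'   latest acquisition is this cluster), `mcf` (the cluster's MCF), and
#'   `ambiguous`.
#' @export
deconvolve_sample <- function(events, sample_id, mcf_tolerance = 0.1,
                              detection = 0.05) {
  stopifnot(inherits(events, "event_table"))
  if (!sample_id %in% colnames(events$mcf)) {
    stop_ct(paste0("unknown sample ", sample_id), "invalid_input")
  }
  v <- events$mcf[, sample_id]
  present <- which(v >= detection)
  if (length(present) == 0) return(list())
  vv <- v[present]
  cl <- cluster_1d(vv, mcf_tolerance)
  k <- max(cl)
  cl_mcf <- vapply(seq_len(k), function(i) mean(vv[cl == i]), 0)
  # clusters come out ordered by decreasing MCF
  frags <- list()
  cum <- character()
  for (i in seq_len(k)) {
    members <- names(vv)[cl == i]
    forced <- 2 * cl_mcf[i] > 1 + mcf_tolerance
    ambiguous <- length(members) > 1 && !forced &&
      diff(range(vv[cl == i])) <= mcf_tolerance
    nxt <- if (i < k) cl_mcf[i + 1] else 0
    if (ambiguous) {
      # disjoint reading: each event its own subclone at the cluster MCF
      for (e in members) {
        frags[[length(frags) + 1]] <- list(
          events = c(cum, e), fraction = unname(v[e] - nxt),
          mcf = unname(v[e]), ambiguous = TRUE
        )
      }
      # ambiguous clusters are not stacked into the chain below them
      cum <- cum
    } else {
      cum <- c(cum, members)
      frags[[length(frags) + 1]] <- list(
        events = cum, fraction = unname(cl_mcf[i] - nxt),
        mcf = unname(cl_mcf[i]), ambiguous = FALSE
      )
    }
  }
  frags
}

#' Reconcile subclones across samples into an event matrix
#'
#' The patient-level deconvolution. Events are clustered by their full MCF
#' profile across samples (average linkage): two clusters merge while their
#' mean profiles agree, in every sample, within the larger of
#' `mcf_tolerance` and a z-band derived from the per-event measurement
#' error (when supplied). Clusters are then stacked into a rooted nesting
#' forest: each cluster attaches below the deepest already-placed cluster
#' whose profile dominates it componentwise (within the same slack),
#' subject to the pigeonhole capacity constraint that the identity
#' fractions of a parent's children cannot exceed the parent's own
#' fraction. Finally, pass-through clusters — an undetected cluster with a
#' single child, the signature of a noise-split branch — are collapsed
#' into their child. Subclones are the cumulative event sets along each
#' chain.
#'
#' @param events An `event_table` for one patient.
#' @param mcf_tolerance Minimum profile agreement tolerance (per sample).
#' @param detection Minimum MCF for presence.
#' @param strict When `TRUE`, an irreconcilable configuration (no parent
#'   satisfies the capacity constraint) is an error of class
#'   `deconvolution_conflict`; when `FALSE` the best-fitting parent is used
#'   and the subclone flagged.
#' @param noise Optional events x samples matrix of MCF standard errors
#'   (populated automatically by [merge_events()] when the segment rows
#'   carry measurement errors from [quantify_sample()]). Widens the merge
#'   and nesting bands where measurements are poor; zero errors reproduce
#'   the fixed-tolerance behavior.
#' @return An object of class `subclone_set`: list with
#'   \describe{
#'     \item{matrix}{binary subclones x events incidence matrix,}
#'     \item{fractions}{subclones x samples identity-fraction matrix,}
#'     \item{profiles}{subclones x samples cluster MCF profiles,}
#'     \item{parent}{integer vector of parent subclone indices (NA = top),}
#'     \item{cluster_events}{events acquired by each subclone itself,}
#'     \item{flags}{character vector of per-subclone QC flags.}
#'   }
#' @export
reconcile_subclones <- function(events, mcf_tolerance = 0.1,
                                detection = 0.05, strict = FALSE,
                                noise = NULL) {
  stopifnot(inherits(events, "event_table"))
  M <- events$mcf
  M[M < detection] <- 0
  n_ev <- nrow(M)
  if (n_ev == 0) stop_ct("empty event table", "invalid_input")
  noise <- noise %||% events$mcf_sd %||% (M * 0)
  # events never observed in a sample are certain zeros; events zeroed by
  # the detection threshold keep their measurement uncertainty
  V <- noise^2
  z_merge <- 2; z_anc <- 2.5; z_frac <- 2

  # --- profile clustering (average linkage) ---
  # two clusters merge when their mean profiles are statistically
  # compatible over the whole profile: a regularized chi-square per
  # informative sample. Single noisy events cannot be assigned per sample,
  # but a genuine branch difference shows up in several samples at once
  # and vetoes the merge, while pure measurement scatter averages out.
  tau2 <- (mcf_tolerance / 2)^2
  cluster_pass <- function(V) {
    cl <- as.list(seq_len(n_ev))
    prof <- M
    sumv <- V
    nmem <- rep(1L, n_ev)
    reldist <- function(i, j) {
      se2 <- sumv[i, ] / nmem[i]^2 + sumv[j, ] / nmem[j]^2
      informative <- prof[i, ] > 0 | prof[j, ] > 0 | se2 > 0
      m <- max(sum(informative), 1L)
      sum((prof[i, ] - prof[j, ])^2 / (se2 + tau2)) / (z_merge * m)
    }
    repeat {
      k <- length(cl)
      if (k == 1) break
      best <- c(NA, NA); bestd <- Inf
      for (i in seq_len(k - 1)) {
        for (j in (i + 1):k) {
          d <- reldist(i, j)
          if (d < bestd - 1e-12) { bestd <- d; best <- c(i, j) }
        }
      }
      if (bestd > 1) break
      i <- best[1]; j <- best[2]
      ni <- nmem[i]; nj <- nmem[j]
      prof[i, ] <- (prof[i, ] * ni + prof[j, ] * nj) / (ni + nj)
      sumv[i, ] <- sumv[i, ] + sumv[j, ]
      nmem[i] <- ni + nj
      cl[[i]] <- c(cl[[i]], cl[[j]])
      cl <- cl[-j]
      prof <- prof[-j, , drop = FALSE]
      sumv <- sumv[-j, , drop = FALSE]
      nmem <- nmem[-j]
    }
    k <- length(cl)
    list(cl = cl, prof = prof[seq_len(k), , drop = FALSE],
         vm = sumv[seq_len(k), , drop = FALSE] / nmem[seq_len(k)]^2)
  }

  pass <- cluster_pass(V)
  if (any(noise > 0)) {
    # calibrate the claimed measurement errors against the within-cluster
    # scatter actually observed (anchor-based errors are biased low), then
    # re-cluster with the inflated variances
    z_res <- numeric()
    for (i in seq_along(pass$cl)) {
      members <- pass$cl[[i]]
      if (length(members) < 2) next
      for (s in seq_len(ncol(M))) {
        pres <- members[M[members, s] > 0 | V[members, s] > 0]
        if (length(pres) < 2) next
        r <- M[pres, s] - mean(M[pres, s])
        z_res <- c(z_res, r / sqrt(V[pres, s] + tau2))
      }
    }
    infl <- if (length(z_res) >= 10) {
      max(1, 1.4826 * stats::median(abs(z_res)) * sqrt(2))
    } else 1
    if (infl > 1) {
      V <- V * infl^2
      pass <- cluster_pass(V)
    }
  }
  # refinement: reassign each event to the statistically closest cluster
  # profile (k-means style, fixed iterations), undoing early agglomeration
  # mistakes; clusters emptied by reassignment are dropped
  if (any(noise > 0) && length(pass$cl) > 1) {
    for (iter in 1:3) {
      k <- length(pass$cl)
      asgn <- integer(n_ev)
      for (e in seq_len(n_ev)) {
        d <- vapply(seq_len(k), function(i) {
          nm <- length(pass$cl[[i]])
          own <- e %in% pass$cl[[i]]
          mu <- pass$prof[i, ]
          if (own && nm > 1) {
            mu <- (mu * nm - M[e, ]) / (nm - 1)
          } else if (own) {
            return(0)
          }
          sum((M[e, ] - mu)^2 / (V[e, ] + tau2))
        }, 0)
        asgn[e] <- which.min(d)
      }
      new_cl <- split(seq_len(n_ev), asgn)
      if (identical(unname(new_cl), lapply(pass$cl, sort))) break
      pass$cl <- unname(new_cl)
      pass$prof <- do.call(rbind, lapply(pass$cl, function(ix) {
        colMeans(M[ix, , drop = FALSE])
      }))
      pass$vm <- do.call(rbind, lapply(pass$cl, function(ix) {
        colSums(V[ix, , drop = FALSE]) / length(ix)^2
      }))
    }
  }
  cl <- pass$cl
  prof <- pass$prof
  vm <- pass$vm
  k <- length(cl)
  rownames(prof) <- NULL

  # --- nesting forest ---
  ord <- order(-rowSums(prof), vapply(cl, min, 0L))
  parent <- rep(NA_integer_, k)
  flags <- character(k)
  placed <- integer()
  root_cap <- rep(1, ncol(prof))
  cap <- prof  # remaining capacity per placed cluster
  depth <- integer(k)
  anc_tol <- function(c_i, d) {
    pmax(mcf_tolerance, z_anc * sqrt(vm[c_i, ] + vm[d, ]))
  }
  absorbed_into <- rep(NA_integer_, k)
  for (c_i in ord) {
    p <- prof[c_i, ]
    # a cluster statistically indistinguishable from an already placed one
    # is a split fragment of the same branch: absorb it instead of
    # creating a phantom subclone
    if (length(placed)) {
      twin <- placed[vapply(placed, function(d) {
        all(abs(p - prof[d, ]) <= anc_tol(c_i, d))
      }, TRUE)]
      if (length(twin)) {
        d2 <- vapply(twin, function(d) sum((p - prof[d, ])^2), 0)
        absorbed_into[c_i] <- twin[which.min(d2)]
        next
      }
    }
    valid <- placed[vapply(placed, function(d) {
      all(p <= prof[d, ] + anc_tol(c_i, d))
    }, TRUE)]
    chosen <- NA_integer_
    if (length(valid)) {
      # deepest (most recent) consistent ancestor first; ties by smaller
      # profile sum, then by event order. Candidates dominating within the
      # plain tolerance are preferred over those valid only through the
      # measurement-error slack: an apparent dominance violation is weak
      # evidence that the clusters are disjoint, not nested.
      sums <- rowSums(prof[valid, , drop = FALSE])
      valid <- valid[order(-depth[valid], sums, vapply(cl[valid], min, 0L))]
      strong <- valid[vapply(valid, function(d) {
        all(p <= prof[d, ] + mcf_tolerance)
      }, TRUE)]
      for (d in c(strong, setdiff(valid, strong))) {
        cap_tol <- pmax(2 * mcf_tolerance, anc_tol(c_i, d))
        if (all(p <= cap[d, ] + cap_tol)) { chosen <- d; break }
      }
    }
    if (is.na(chosen)) {
      if (all(p <= root_cap + pmax(2 * mcf_tolerance,
                                   z_anc * sqrt(vm[c_i, ])))) {
        chosen <- 0L
      } else {
        # overflow: no consistent placement
        if (strict) {
          stop_ct(paste0(
            "irreconcilable subclone configuration at cluster with events ",
            paste(rownames(M)[cl[[c_i]]], collapse = ","),
            "; consider relaxing mcf_tolerance"
          ), "deconvolution_conflict")
        }
        # no consistent placement: if some placed cluster has a profile
        # compatible within twice the nesting band, this is a split
        # fragment of that cluster and is absorbed; otherwise attach at
        # the least-violating parent and flag the conflict
        flags[c_i] <- "overflow"
        near <- placed[vapply(placed, function(d) {
          all(abs(p - prof[d, ]) <= 2 * anc_tol(c_i, d))
        }, TRUE)]
        if (length(near)) {
          d2 <- vapply(near, function(d) sum((p - prof[d, ])^2), 0)
          absorbed_into[c_i] <- near[which.min(d2)]
          next
        }
        cand <- if (length(valid)) valid else 0L
        overflow <- vapply(cand, function(d) {
          capd <- if (d == 0) root_cap else cap[d, ]
          sum(pmax(p - capd, 0))
        }, 0)
        chosen <- cand[which.min(overflow)]
      }
    }
    if (chosen == 0L) {
      root_cap <- root_cap - p
      depth[c_i] <- 1L
    } else {
      cap[chosen, ] <- cap[chosen, ] - p
      depth[c_i] <- depth[chosen] + 1L
      parent[c_i] <- chosen
    }
    placed <- c(placed, c_i)
  }

  # fold absorbed split fragments into their target clusters
  if (any(!is.na(absorbed_into))) {
    find_live <- function(i) {
      while (!is.na(absorbed_into[i])) i <- absorbed_into[i]
      i
    }
    for (i in which(!is.na(absorbed_into))) {
      t <- find_live(i)
      cl[[t]] <- c(cl[[t]], cl[[i]])
    }
    keep <- which(is.na(absorbed_into))
    remap <- match(seq_len(k), keep)
    cl <- cl[keep]
    flags <- flags[keep]
    parent <- vapply(parent[keep], function(pp) {
      if (is.na(pp)) NA_integer_ else remap[pp]
    }, 0L)
    k <- length(cl)
    prof <- do.call(rbind, lapply(cl, function(ix) {
      colMeans(M[ix, , drop = FALSE])
    }))
    vm <- do.call(rbind, lapply(cl, function(ix) {
      colSums(V[ix, , drop = FALSE]) / length(ix)^2
    }))
  }

  # --- collapse pass-through splits -------------------------------------
  # a cluster whose identity fraction is below detection in every sample
  # and that has exactly one child carries no cells of its own: it is a
  # noise-split fragment of its child's branch (a genuinely swept unary
  # ancestor would share its child's profile and have merged above)
  repeat {
    kids_of <- lapply(seq_along(cl), function(i) {
      which(!is.na(parent) & parent == i)
    })
    frac_i <- function(i) {
      kk <- kids_of[[i]]
      if (!length(kk)) return(prof[i, ])
      r <- pmax(prof[i, ] - colSums(prof[kk, , drop = FALSE]), 0)
      se <- sqrt(vm[i, ] + colSums(vm[kk, , drop = FALSE]))
      r[r <= pmin(z_frac * se, 0.25)] <- 0
      r
    }
    drop_i <- NA_integer_
    for (i in seq_along(cl)) {
      if (length(kids_of[[i]]) == 1L && all(frac_i(i) < detection)) {
        drop_i <- i; break
      }
    }
    if (is.na(drop_i)) break
    child <- kids_of[[drop_i]]
    cl[[child]] <- c(cl[[drop_i]], cl[[child]])
    parent[child] <- parent[drop_i]
    keep <- setdiff(seq_along(cl), drop_i)
    remap <- match(seq_along(cl), keep)
    cl <- cl[keep]
    prof <- prof[keep, , drop = FALSE]
    vm <- vm[keep, , drop = FALSE]
    flags <- flags[keep]
    parent <- vapply(parent[keep], function(pp) {
      if (is.na(pp)) NA_integer_ else remap[pp]
    }, 0L)
  }
  k <- length(cl)

  # --- cumulative event sets, identity fractions ---
  ev_ids <- rownames(M)
  cum_events <- vector("list", k)
  get_cum <- function(i) {
    if (!is.null(cum_events[[i]])) return(cum_events[[i]])
    own <- ev_ids[sort(cl[[i]])]
    res <- if (is.na(parent[i])) own else c(get_cum(parent[i]), own)
    cum_events[[i]] <<- res
    res
  }
  for (i in seq_len(k)) get_cum(i)

  # effective cluster profiles: clip each cluster at the capacity its
  # parent has left (siblings in decreasing-sum order). Nesting slack can
  # let profiles double-count cells — typically when a noise-split
  # fragment landed as a sibling of its own branch — and clipping charges
  # the excess to the later (smaller) cluster instead of corrupting the
  # whole sample's accounting.
  eff <- prof
  ord2 <- order(-rowSums(prof), vapply(cl, min, 0L))
  remaining_root <- rep(1, ncol(prof))
  remaining <- prof * 0
  for (c_i in ord2) {
    if (is.na(parent[c_i])) {
      eff[c_i, ] <- pmin(prof[c_i, ], remaining_root)
      remaining_root <- remaining_root - eff[c_i, ]
    } else {
      eff[c_i, ] <- pmin(prof[c_i, ], remaining[parent[c_i], ])
      remaining[parent[c_i], ] <- remaining[parent[c_i], ] - eff[c_i, ]
    }
    remaining[c_i, ] <- eff[c_i, ]
  }

  # identity fractions: the bookkeeping estimate is the (clipped) cluster
  # profile minus the children's, conserving the event MCF along each
  # chain; for presence calls, a residual compatible with zero given the
  # measurement errors is additionally screened out — it is a noise
  # artifact, not evidence that ancestral cells persist
  fractions <- eff
  signif_frac <- eff
  for (i in seq_len(k)) {
    kids <- which(!is.na(parent) & parent == i)
    if (length(kids)) {
      resid <- pmax(eff[i, ] - colSums(eff[kids, , drop = FALSE]), 0)
      fractions[i, ] <- resid
      se <- sqrt(vm[i, ] + colSums(vm[kids, , drop = FALSE]))
      resid[resid <= pmin(z_frac * se, 0.25)] <- 0
      signif_frac[i, ] <- resid
    }
  }
  detected <- signif_frac >= detection

  bin <- matrix(0L, k, n_ev, dimnames = list(NULL, ev_ids))
  for (i in seq_len(k)) bin[i, cum_events[[i]]] <- 1L
  sub_ids <- paste0("SC", seq_len(k))
  rownames(bin) <- sub_ids
  rownames(prof) <- sub_ids
  rownames(fractions) <- sub_ids
  rownames(detected) <- sub_ids

  structure(
    list(
      matrix = bin, fractions = fractions, detected = detected,
      profiles = prof, parent = parent,
      cluster_events = lapply(cl, function(ix) ev_ids[sort(ix)]),
      flags = flags, samples = colnames(M), events = events$events
    ),
    class = "subclone_set"
  )
}

#' @export
print.subclone_set <- function(x, ...) {
  cat(sprintf("<subclone_set> %d subclones, %d events, %d samples\n",
              nrow(x$matrix), ncol(x$matrix), length(x$samples)))
  if (any(nzchar(x$flags))) {
    cat("  flags:", paste(which(nzchar(x$flags)), x$flags[nzchar(x$flags)],
                          collapse = "; "), "\n")
  }
  invisible(x)
}

#' Write / read the binary event matrix
#'
#' Tab-delimited: rows are subclones, columns event ids, entries 0/1.
#'
#' @param x A `subclone_set` (or bare 0/1 matrix with dimnames).
#' @param path Output path.
#' @export
write_event_matrix <- function(x, path) {
  m <- if (inherits(x, "subclone_set")) x$matrix else x
  df <- data.frame(subclone = rownames(m), m, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_event_matrix
#' @export
read_event_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
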