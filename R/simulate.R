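# Synthetic multiregional cohorts with known ground truth.
#
# A patient is built in four steps: (1) a rooted subclone tree is grown with
# explicit roles realizing the requested spread modes (earlier lineages
# diverge above the primary MRCA, polyclonal sites receive two incomparable
# lineages, intermetastatic spread is a metastasis-private subclone whose
# descendant colonizes a second site); (2) every detected subclone is given
# a "home" sample where it dominates, emulating the regional segregation of
# clones that multiregional sampling exploits, and per-sample identity
# fractions are drawn with a rejection step enforcing that distinct branch
# profiles stay distinguishable; (3) each branch receives CNA/SNV events on
# hg38-sized chromosomes; (4) noisy measurements are emitted by running the
# clone-fraction mixture models forward (log2R with Gaussian noise, mBAF
# with Beta noise, VAF as binomial read counts split over synthetic callers).

#' Simulation configuration
#'
#' Defaults describe the cohort conditions this package targets: 17
#' patients, a median of about eight samples each, 9/17 patients with
#' metastases in at least two anatomical sites, and spread-mode target
#' rates matching the observed cohort rates (earlier 11/17, later 9/17,
#' polyclonal 3/17, polyphyletic 6/17, intermetastatic 8/9 of eligible
#' patients).
#'
#' @param n_patients Cohort size.
#' @param subclones Range of subclones per patient (the constructive roles
#'   may exceed the lower bound).
#' @param events_per_branch Range of events acquired per tree edge.
#' @param cna_fraction Fraction of events that are CNAs (rest are SNVs).
#' @param cnni_fraction Fraction of CNAs that are copy-neutral imbalances.
#' @param primary_samples,met_samples Ranges of samples per site.
#' @param met_site_probs Probabilities of 1, 2, 3 metastatic sites.
#' @param p_earlier,p_later,p_polyclonal,p_polyphyletic,p_intermetastatic
#'   Spread-mode target probabilities (intermetastatic applies to patients
#'   with >= 2 metastatic sites).
#' @param tcf_range Tumor cell fraction range.
#' @param depth Sequencing depth for SNVs (`Inf` = noise-free VAFs).
#' @param log2r_sd Gaussian noise sd on segment log2 ratios.
#' @param baf_precision Beta precision of mBAF noise (`Inf` = noise-free).
#' @param caller_dropout Per-caller probability of missing a true variant.
#' @param home_fraction Range of the mixture weight of a sample's dominant
#'   ("home") subclones before normalization.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_patients = 17L,
                       subclones = c(4L, 8L),
                       events_per_branch = c(3L, 6L),
                       cna_fraction = 0.8,
                       cnni_fraction = 0.15,
                       primary_samples = c(2L, 4L),
                       met_samples = c(1L, 3L),
                       met_site_probs = c(8, 6, 3) / 17,
                       p_earlier = 11 / 17,
                       p_later = 9 / 17,
                       p_polyclonal = 3 / 17,
                       p_polyphyletic = 6 / 17,
                       p_intermetastatic = 8 / 9,
                       tcf_range = c(0.6, 0.95),
                       depth = 1000,
                       log2r_sd = 0.1,
                       baf_precision = 250,
                       caller_dropout = 0.15,
                       home_fraction = c(0.6, 0.8)) {
  cfg <- as.list(environment())
  stopifnot(all(cfg$met_site_probs >= 0), cfg$depth >= 1,
            diff(cfg$subclones) >= 0, diff(cfg$tcf_range) >= 0)
  structure(cfg, class = "sim_config")
}

sim_callers <- c("mutect2", "strelka2", "varscan2", "manta")

ri <- function(range) if (range[1] >= range[2]) range[1] else
  sample(seq(range[1], range[2]), 1)

# sample one element safely (sample() treats a scalar as 1:n)
pick1 <- function(x) x[sample.int(length(x), 1)]

# ---- tree + site construction -----------------------------------------

build_patient_structure <- function(config, n_met, modes) {
  earlier <- modes$earlier
  later <- modes$later
  polyclonal <- modes$polyclonal
  polyphyletic <- modes$polyphyletic
  intermet <- modes$intermetastatic

  parent <- NA_integer_  # node 1 = tumor MRCA
  add_node <- function(p) {
    parent[length(parent) + 1L] <<- p
    length(parent)
  }
  if (earlier) {
    p_root <- add_node(1L)    # primary MRCA
    e_root <- add_node(1L)    # early lineage root (above primary MRCA)
    primary_set <- p_root
  } else {
    p_root <- 1L
    primary_set <- 1L
  }
  for (i in seq_len(ri(c(1L, 3L)))) {
    primary_set <- c(primary_set, add_node(pick1(primary_set)))
  }

  site_nodes <- list(primary = primary_set)
  met_names <- paste0("M", seq_len(n_met))
  mk_later_root <- function() add_node(pick1(primary_set))

  if (!polyphyletic) {
    if (intermet && n_met >= 2) {
      # stepwise chain: each site's private subclone spawns the next site's
      x <- if (earlier) e_root else mk_later_root()
      site_nodes[[met_names[1]]] <- x
      for (s in 2:n_met) {
        x <- add_node(x)
        site_nodes[[met_names[s]]] <- x
      }
    } else if (n_met >= 2) {
      # independent colonizations from one branch: all sites detect the
      # same seeding subclone, each with a private descendant
      shared <- if (earlier) e_root else pick1(primary_set)
      for (s in seq_len(n_met)) {
        site_nodes[[met_names[s]]] <- c(shared, add_node(shared))
      }
    } else {
      site_nodes[[met_names[1]]] <- if (earlier) e_root else mk_later_root()
    }
  } else {
    roots <- integer(n_met)
    roots[1] <- if (earlier) e_root else mk_later_root()
    if (n_met >= 2) {
      for (s in 2:n_met) roots[s] <- mk_later_root()
    }
    for (s in seq_len(n_met)) site_nodes[[met_names[s]]] <- roots[s]
    if (polyclonal) {
      site_nodes[[met_names[1]]] <-
        c(site_nodes[[met_names[1]]], mk_later_root())
    }
    if (intermet && n_met >= 2) {
      y <- add_node(roots[2])
      site_nodes[[met_names[2]]] <- c(site_nodes[[met_names[2]]], y)
      site_nodes[[met_names[1]]] <- c(site_nodes[[met_names[1]]], y)
    }
  }

  # filler subclones up to the drawn size, attached within existing sites
  target <- ri(config$subclones)
  while (length(parent) < target) {
    s <- pick1(names(site_nodes))
    host <- pick1(site_nodes[[s]])
    site_nodes[[s]] <- c(site_nodes[[s]], add_node(host))
  }
  list(parent = parent, site_nodes = site_nodes,
       primary_set = site_nodes$primary)
}

subtree_of <- function(parent, u) {
  n <- length(parent)
  below <- rep(FALSE, n)
  below[u] <- TRUE
  repeat {
    grow <- !below & !is.na(parent) & below[pmax(parent, 1L)]
    grow[is.na(parent)] <- FALSE
    if (!any(grow)) break
    below[grow] <- TRUE
  }
  which(below)
}

# ---- mixtures ----------------------------------------------------------

draw_mixtures <- function(structure, config, sample_meta) {
  parent <- structure$parent
  n_nodes <- length(parent)
  samples <- sample_meta$sample
  frac <- matrix(0, n_nodes, length(samples),
                 dimnames = list(NULL, samples))
  for (site in unique(sample_meta$site)) {
    s_ids <- sample_meta$sample[sample_meta$site == site]
    d_s <- structure$site_nodes[[if (site == "primary") "primary" else site]]
    d_s <- unique(d_s)
    # assign homes round-robin, at most two homes per sample
    homes <- split(d_s, rep(seq_along(s_ids), length.out = length(d_s)))
    for (k in seq_along(s_ids)) {
      h <- homes[[as.character(k)]] %||% integer()
      extras <- setdiff(d_s, h)
      extras <- extras[stats::runif(length(extras)) < 0.35]
      if (length(h) == 0 && length(extras) == 0) {
        extras <- pick1(d_s)  # every tumor sample carries tumor cells
      }
      w <- c(rep(stats::runif(1, config$home_fraction[1],
                              config$home_fraction[2]) / max(length(h), 1),
                 length(h)),
             stats::runif(length(extras), 0.08, 0.18))
      ids <- c(h, extras)
      frac[ids, s_ids[k]] <- w / sum(w)
    }
  }
  frac
}

edge_profiles <- function(parent, frac) {
  n <- length(parent)
  P <- matrix(0, n, ncol(frac), dimnames = dimnames(frac))
  for (u in seq_len(n)) {
    P[u, ] <- colSums(frac[subtree_of(parent, u), , drop = FALSE])
  }
  P
}

# identifiability of branch profiles: merged clusters need > 3*tol
# separation somewhere; incomparable branches need signed separation both
# ways so nesting direction is determined
profiles_identifiable <- function(parent, P, merge_gap = 0.3,
                                  dir_gap = 0.2) {
  n <- length(parent)
  anc <- matrix(FALSE, n, n)
  for (u in seq_len(n)) anc[u, subtree_of(parent, u)] <- TRUE
  for (u in seq_len(n)) anc[u, u] <- FALSE
  for (u in seq_len(n - 1)) {
    for (v in (u + 1):n) {
      duv <- max(P[u, ] - P[v, ])
      dvu <- max(P[v, ] - P[u, ])
      if (anc[u, v]) {
        if (duv <= merge_gap) return(FALSE)
      } else if (anc[v, u]) {
        if (dvu <= merge_gap) return(FALSE)
      } else {
        if (duv <= dir_gap || dvu <= dir_gap) return(FALSE)
      }
    }
  }
  TRUE
}

# ---- events ------------------------------------------------------------

sim_bed <- function(n_intervals = 300L) {
  chroms <- names(hg38_chrom_sizes)
  ch <- chroms[(seq_len(n_intervals) - 1L) %% length(chroms) + 1L]
  idx <- ave(seq_len(n_intervals), ch, FUN = seq_along)
  start1 <- 5e6 + (idx - 1L) * 4e5 + 1
  GenomicRanges::GRanges(ch, IRanges::IRanges(start = start1,
                                              end = start1 + 2999))
}

assign_events <- function(parent, config) {
  n_nodes <- length(parent)
  n_ev_per_edge <- vapply(seq_len(n_nodes + 1L), function(i) {
    ri(config$events_per_branch)
  }, 0L)  # index 1 = stem (edge into node 1 counts as index 1)
  cursor <- setNames(rep(10e6, length(hg38_chrom_sizes)),
                     names(hg38_chrom_sizes))
  bed <- sim_bed()
  bed_used <- 0L
  events <- list()
  for (edge in seq_len(n_nodes)) {
    for (j in seq_len(n_ev_per_edge[edge])) {
      if (stats::runif(1) < config$cna_fraction) {
        len <- round(stats::runif(1, 5e5, 6e7))
        ok <- names(cursor)[cursor + len + 2e6 <
                              hg38_chrom_sizes[names(cursor)]]
        chrom <- pick1(ok)
        start <- cursor[chrom] + 1e6
        end <- start + len
        cursor[chrom] <- end
        if (stats::runif(1) < config$cnni_fraction) {
          type <- "cnni"; nt <- 2L; na_ <- 0L; nb <- 2L
        } else if (stats::runif(1) < 0.55) {
          type <- "gain"; nt <- sample(c(3L, 3L, 4L), 1); na_ <- 1L
          nb <- nt - 1L
        } else {
          type <- "loss"; nt <- 1L; na_ <- 0L; nb <- 1L
        }
        events[[length(events) + 1]] <- list(
          edge = edge, kind = type, chrom = chrom, start = start, end = end,
          nt = nt, na_ = na_, nb = nb, np = 2L, gene = ""
        )
      } else {
        bed_used <- bed_used + 1L
        if (bed_used > length(bed)) next
        iv <- bed[bed_used]
        pos <- GenomicRanges::start(iv) + 100L
        ref <- sample(c("A", "C", "G", "T"), 1)
        alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
        events[[length(events) + 1]] <- list(
          edge = edge, kind = "snv",
          chrom = as.character(GenomicRanges::seqnames(iv)),
          start = pos, end = pos, ref = ref, alt = alt,
          gene = paste0("GENE", bed_used)
        )
      }
    }
  }
  list(events = events, bed = bed, bed_used = bed_used)
}

event_id <- function(e) {
  if (e$kind == "snv") {
    sprintf("snv_%s_%d_%s>%s", e$chrom, e$start, e$ref, e$alt)
  } else {
    sprintf("%s_%s_%d_%d", e$kind, e$chrom, e$start, e$end)
  }
}

# ---- measurements ------------------------------------------------------

emit_measurements <- function(patient_id, structure, events, frac, P,
                              tcf, config, sample_meta) {
  parent <- structure$parent
  samples <- sample_meta$sample
  seg <- list()
  var <- list()
  edge_mcf <- function(edge, s) {
    if (edge == 1L) 1 else P[edge, s]  # stem events are clonal everywhere
  }
  for (e in events) {
    id <- event_id(e)
    for (s in samples) {
      mcf <- if (e$edge == 1L) 1 else P[e$edge, s]
      if (mcf <= 0) next
      msf <- mcf * tcf[s]
      if (e$kind == "snv") {
        vaf_true <- msf / 2
        for (caller in sim_callers) {
          if (stats::runif(1) < config$caller_dropout) next
          vaf <- if (is.infinite(config$depth)) vaf_true else {
            stats::rbinom(1, config$depth, vaf_true) / config$depth
          }
          dp <- if (is.infinite(config$depth)) 10000 else config$depth
          var[[length(var) + 1]] <- data.frame(
            patient = patient_id, sample = s, caller = caller,
            chrom = e$chrom, pos = e$start, ref = e$ref, alt = e$alt,
            vaf_t = vaf,
            vaf_n = if (is.infinite(config$depth)) 0 else
              stats::rbinom(1, config$depth, 0.002) / config$depth,
            dp_t = dp, dp_n = dp, mapq = 60,
            passed_internal = TRUE, in_pon = FALSE, in_popdb = FALSE,
            gene = e$gene, annotation = "exonic",
            stringsAsFactors = FALSE
          )
        }
      } else {
        row <- empty_segment_table(1)
        row$patient <- patient_id; row$sample <- s
        row$chrom <- e$chrom; row$start <- e$start; row$end <- e$end
        row$type <- e$kind
        row$Nt <- e$nt; row$NA. <- e$na_; row$NB <- e$nb; row$Np <- e$np
        row$gene <- e$gene; row$hgvs <- ""
        row$clonal <- NA
        if (e$kind == "cnni") {
          mbaf <- (msf * e$nb + (1 - msf)) / (msf * (e$na_ + e$nb) +
                                                2 * (1 - msf))
          if (is.finite(config$baf_precision)) {
            mbaf <- stats::rbeta(1, mbaf * config$baf_precision,
                                 (1 - mbaf) * config$baf_precision)
            mbaf <- max(mbaf, 1 - mbaf)
          }
          row$mBAF <- mbaf
        } else {
          l2r <- log2((e$np + msf * (e$nt - e$np)) / e$np)
          row$log2R <- l2r + stats::rnorm(1, 0, config$log2r_sd)
        }
        seg[[length(seg) + 1]] <- row
      }
    }
  }
  list(segments = if (length(seg)) do.call(rbind, seg) else
    empty_segment_table(0),
    variants = if (length(var)) do.call(rbind, var) else NULL)
}

# decoy variant calls exercising the quality and consensus filters; all are
# removed by a correct filter chain
decoy_variants <- function(patient_id, samples, bed, bed_from) {
  mk <- function(i, sample, caller, vaf_t, vaf_n, dp_t, dp_n, mapq,
                 in_popdb = FALSE, chrom = NULL, pos = NULL) {
    iv <- bed[bed_from + i]
    data.frame(
      patient = patient_id, sample = sample, caller = caller,
      chrom = chrom %||% as.character(GenomicRanges::seqnames(iv)),
      pos = pos %||% (GenomicRanges::start(iv) + 50L),
      ref = "G", alt = "T", vaf_t = vaf_t, vaf_n = vaf_n,
      dp_t = dp_t, dp_n = dp_n, mapq = mapq, passed_internal = TRUE,
      in_pon = FALSE, in_popdb = in_popdb, gene = "DECOY",
      annotation = "artifact", stringsAsFactors = FALSE
    )
  }
  s1 <- samples[1]
  rbind(
    mk(1, s1, "mutect2", 0.03, 0, 500, 500, 60),    # tumor VAF below 0.05
    mk(1, s1, "strelka2", 0.03, 0, 500, 500, 60),
    mk(2, s1, "mutect2", 0.20, 0.08, 500, 500, 60), # normal contamination
    mk(2, s1, "strelka2", 0.20, 0.08, 500, 500, 60),
    mk(3, s1, "mutect2", 0.20, 0, 15, 500, 60),     # shallow tumor depth
    mk(3, s1, "strelka2", 0.20, 0, 15, 500, 60),
    mk(4, s1, "varscan2", 0.25, 0, 500, 500, 40),   # poor mapping quality
    mk(5, s1, "varscan2", 0.25, 0, 500, 500, 60),   # single caller, 1 sample
    mk(6, s1, "mutect2", 0.30, 0, 500, 500, 60,     # off-target locus
       chrom = "chr1", pos = 2e6L),
    mk(6, s1, "strelka2", 0.30, 0, 500, 500, 60,
       chrom = "chr1", pos = 2e6L),
    mk(7, s1, "mutect2", 0.30, 0, 500, 500, 60, in_popdb = TRUE),
    mk(7, s1, "strelka2", 0.30, 0, 500, 500, 60, in_popdb = TRUE)
  )
}

# ---- truth -------------------------------------------------------------

truth_clone_tree <- function(structure, events, frac, sample_meta) {
  parent <- structure$parent
  n <- length(parent)
  labels <- c("normal", paste0("S", seq_len(n)))
  tparent <- c(NA_integer_, ifelse(is.na(parent), 1L, parent + 1L))
  ev_by_edge <- split(vapply(events, event_id, ""),
                      vapply(events, function(e) e$edge, 0L))
  edge_events <- vector("list", n + 1L)
  edge_events[[1]] <- character()
  for (u in seq_len(n)) {
    edge_events[[u + 1L]] <- sort(ev_by_edge[[as.character(u)]] %||% character())
  }
  all_ev <- sort(unlist(edge_events))
  bin <- matrix(0L, n, length(all_ev),
                dimnames = list(paste0("S", seq_len(n)), all_ev))
  for (u in seq_len(n)) {
    path <- u
    while (!is.na(parent[path[1]])) path <- c(parent[path[1]], path)
    bin[u, unlist(edge_events[path + 1L])] <- 1L
  }
  tree <- structure(
    list(
      label = labels,
      parent = tparent,
      edge_events = edge_events,
      edge_length = vapply(edge_events, length, 0L),
      subclones = c(list(character()),
                    as.list(paste0("S", seq_len(n)))),
      root = 1L,
      matrix = bin,
      score = sum(vapply(edge_events, length, 0L)),
      detections = NULL, meta = NULL
    ),
    class = "clone_tree"
  )
  fr <- frac
  rownames(fr) <- paste0("S", seq_len(n))
  tree <- annotate_tree(tree, sample_meta, fr)
  list(tree = tree, matrix = bin, fractions = fr)
}

# ---- patient / cohort --------------------------------------------------

#' Simulate one patient with known ground truth
#'
#' @param config A [sim_config()].
#' @param seed Integer seed (all randomness derives from it).
#' @param patient_id Identifier used in the emitted tables.
#' @param n_met_sites Number of metastatic sites (drawn from
#'   `config$met_site_probs` when `NULL`).
#' @param modes Optional named list forcing spread modes (`earlier`,
#'   `later`, `polyclonal`, `polyphyletic`, `intermetastatic`); entries not
#'   given are drawn. Requesting intermetastatic spread with fewer than two
#'   metastatic sites is a configuration error.
#' @return List with `truth` (`tree`, `report`, `matrix`, `fractions`,
#'   `modes`), `segments`, `variants`, `bed`, `metadata`, `tcf`.
#' @export
simulate_patient <- function(config = sim_config(), seed = 1L,
                             patient_id = "P01", n_met_sites = NULL,
                             modes = list()) {
  for (attempt in 0:24) {
    set.seed((seed + attempt * 100003L) %% .Machine$integer.max)
    out <- try(build_patient(config, patient_id, n_met_sites, modes),
               silent = TRUE)
    if (!inherits(out, "try-error")) return(out)
    if (inherits(attr(out, "condition"), "configuration_error")) {
      stop(attr(out, "condition"))
    }
  }
  stop_ct("could not build an identifiable patient; relax the configuration",
          "simulation_error")
}

build_patient <- function(config, patient_id, n_met_sites, forced_modes) {
  n_met <- n_met_sites %||%
    sample(seq_along(config$met_site_probs), 1, prob = config$met_site_probs)
  if (isTRUE(forced_modes$intermetastatic) && n_met < 2) {
    stop_ct("intermetastatic spread requires >= 2 metastatic sites",
            "configuration_error")
  }
  draw <- function(name, p) {
    if (!is.null(forced_modes[[name]])) forced_modes[[name]] else
      stats::runif(1) < p
  }
  earlier <- draw("earlier", config$p_earlier)
  later <- if (n_met == 1) {
    if (!is.null(forced_modes$later)) forced_modes$later else !earlier
  } else draw("later", config$p_later)
  if (!earlier && !later) later <- TRUE
  polyclonal <- draw("polyclonal", config$p_polyclonal)
  p_extra <- max(0, (config$p_polyphyletic - config$p_polyclonal) /
                   (1 - config$p_polyclonal))
  polyphyletic <- polyclonal || (earlier && later) ||
    draw("polyphyletic", p_extra)
  if (polyphyletic && n_met < 2 && !polyclonal) polyphyletic <- FALSE
  if (earlier && later && !polyphyletic) later <- FALSE
  intermet <- if (n_met >= 2) draw("intermetastatic",
                                   config$p_intermetastatic) else FALSE
  modes <- list(earlier = earlier, later = later, polyclonal = polyclonal,
                polyphyletic = polyphyletic, intermetastatic = intermet)

  structure <- build_patient_structure(config, n_met, modes)

  # sample metadata
  met_classes <- sample(c("lymph-node", "distant", "relapse"), n_met,
                        replace = TRUE, prob = c(0.45, 0.45, 0.1))
  sm <- list(data.frame(
    patient = patient_id,
    sample = paste0("P", seq_len(max(ri(config$primary_samples),
                                     ceiling(length(structure$primary_set) / 2)))),
    site = "primary", class = "primary", timepoint = "diagnosis",
    stringsAsFactors = FALSE
  ))
  for (s in seq_len(n_met)) {
    ds <- unique(structure$site_nodes[[paste0("M", s)]])
    ns <- max(ri(config$met_samples), ceiling(length(ds) / 2))
    sm[[s + 1]] <- data.frame(
      patient = patient_id,
      sample = paste0("M", s, "_", seq_len(ns)),
      site = paste0("M", s),
      class = met_classes[s],
      timepoint = if (met_classes[s] == "relapse") "relapse" else "diagnosis",
      stringsAsFactors = FALSE
    )
  }
  sample_meta <- do.call(rbind, sm)

  # mixtures with identifiability rejection
  frac <- NULL
  for (try_i in seq_len(60)) {
    f <- draw_mixtures(structure, config, sample_meta)
    P <- edge_profiles(structure$parent, f)
    if (profiles_identifiable(structure$parent, P)) { frac <- f; break }
  }
  if (is.null(frac)) {
    stop_ct("mixture rejection failed", "identifiability_error")
  }
  P <- edge_profiles(structure$parent, frac)

  ae <- assign_events(structure$parent, config)
  tcf <- stats::setNames(stats::runif(nrow(sample_meta), config$tcf_range[1],
                                      config$tcf_range[2]),
                         sample_meta$sample)
  meas <- emit_measurements(patient_id, structure, ae$events, frac, P, tcf,
                            config, sample_meta)
  decoys <- decoy_variants(patient_id, sample_meta$sample, ae$bed,
                           ae$bed_used + 1L)
  variants <- rbind(meas$variants, decoys)

  tr <- truth_clone_tree(structure, ae$events, frac, sample_meta)
  report <- classify_spread(tr$tree, patient_id)

  # noise-free event table (true per-sample MCFs for every event): the
  # ground-truth input to subclonal deconvolution
  ev_df <- data.frame(
    event = vapply(ae$events, event_id, ""),
    kind = vapply(ae$events, function(e) e$kind, ""),
    chrom = vapply(ae$events, function(e) e$chrom, ""),
    start = vapply(ae$events, function(e) e$start, 0),
    end = vapply(ae$events, function(e) e$end, 0),
    gene = vapply(ae$events, function(e) e$gene, ""),
    stringsAsFactors = FALSE
  )
  true_mcf <- t(vapply(ae$events, function(e) {
    if (e$edge == 1L) rep(1, ncol(P)) else P[e$edge, ]
  }, numeric(ncol(P))))
  dimnames(true_mcf) <- list(ev_df$event, colnames(P))
  o <- order(ev_df$chrom, ev_df$start, ev_df$event)
  truth_events <- structure(
    list(events = ev_df[o, ], mcf = true_mcf[o, , drop = FALSE],
         clonal = true_mcf[o, , drop = FALSE] >= 1 - 1e-12,
         samples = colnames(P)),
    class = "event_table"
  )

  list(
    truth = list(tree = tr$tree, report = report, matrix = tr$matrix,
                 fractions = tr$fractions, modes = modes,
                 events = truth_events, parent = structure$parent),
    segments = meas$segments,
    variants = variants,
    bed = ae$bed,
    metadata = sample_meta,
    tcf = tcf
  )
}

#' Write a simulated patient to interchange files
#'
#' Emits the segment table, variant table, BED, sample metadata and a
#' ground-truth JSON (true event matrix, per-sample subclone fractions,
#' spread modes and the true tree in Newick form) for one
#' [simulate_patient()] bundle.
#'
#' @param patient A [simulate_patient()] bundle.
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix; defaults to the patient id.
#' @return The directory, invisibly.
#' @export
write_simulation <- function(patient, dir, prefix = NULL) {
  prefix <- prefix %||% patient$metadata$patient[1]
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_segment_table(patient$segments,
                      file.path(dir, paste0(prefix, "_segments.tsv")))
  write_variant_table(patient$variants,
                      file.path(dir, paste0(prefix, "_variants.tsv")))
  utils::write.table(patient$metadata,
                     file.path(dir, paste0(prefix, "_metadata.tsv")),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  bed <- patient$bed
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(bed)),
               GenomicRanges::start(bed) - 1L, GenomicRanges::end(bed)),
    file.path(dir, paste0(prefix, "_targets.bed")),
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  jsonlite::write_json(
    list(
      modes = patient$truth$modes,
      tcf = as.list(patient$tcf),
      newick = newick(patient$truth$tree),
      event_matrix = as.data.frame(patient$truth$matrix),
      subclone = rownames(patient$truth$matrix),
      fractions = as.data.frame(patient$truth$fractions)
    ),
    file.path(dir, paste0(prefix, "_truth.json")),
    auto_unbox = TRUE, digits = NA
  )
  invisible(dir)
}

#' Simulate a cohort
#'
#' Patients are generated independently with per-patient seeds derived
#' from the master seed and the patient's index, so permuting the patient
#' list leaves each patient's data unchanged.
#'
#' @param config A [sim_config()].
#' @param seed Master seed.
#' @param met_sites Optional integer vector of metastatic-site counts per
#'   patient (length `n_patients`); defaults to draws from
#'   `config$met_site_probs`. The default 17-patient cohort uses the fixed
#'   mix `rep(c(1, 2, 3), c(8, 6, 3))` so that 9 of 17 patients are
#'   evaluable for intermetastatic spread.
#' @return List of class `sim_cohort`: `patients` (list of
#'   [simulate_patient()] bundles), `truth_grid` (spread-mode x patient
#'   matrix of "present"/"absent"/"not-evaluable").
#' @export
simulate_cohort <- function(config = sim_config(), seed = 1L,
                            met_sites = NULL) {
  n <- config$n_patients
  if (is.null(met_sites) && n == 17L) {
    met_sites <- rep(c(1L, 2L, 3L), c(8L, 6L, 3L))
  }
  ids <- sprintf("P%02d", seq_len(n))
  patients <- lapply(seq_len(n), function(i) {
    simulate_patient(config,
                     seed = (seed %% 1000003) * 1000 + i,
                     patient_id = ids[i],
                     n_met_sites = if (is.null(met_sites)) NULL else
                       met_sites[i])
  })
  names(patients) <- ids
  structure(list(patients = patients,
                 truth_grid = spread_grid(lapply(patients,
                                                 function(p) p$truth$report))),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  cat(sprintf("<sim_cohort> %d patients\n", length(x$patients)))
  print(x$truth_grid)
  invisible(x)
}
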