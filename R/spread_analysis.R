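# Classification of metastatic spread modes from an annotated clone tree,
# and the index of genomic diversity.

met_sites <- function(tree, include_relapse = TRUE) {
  meta <- tree$meta
  primary_sites <- unique(meta$site[meta$class == "primary"])
  cls_ok <- meta$class %in%
    c("lymph-node", "distant", if (include_relapse) "relapse")
  sites <- unique(meta$site[cls_ok])
  setdiff(sites, primary_sites)
}

site_nodes <- function(tree, site) {
  s <- tree$meta$sample[tree$meta$site == site]
  which(rowSums(tree$detections[, s, drop = FALSE] > 0) > 0)
}

class_nodes <- function(tree, class) {
  s <- tree$meta$sample[tree$meta$class == class]
  if (!length(s)) return(integer())
  which(rowSums(tree$detections[, s, drop = FALSE] > 0) > 0)
}

primary_nodes <- function(tree) class_nodes(tree, "primary")

#' Most recent common ancestor of the primary tumor
#'
#' The deepest node ancestral to (or equal to) every subclone detected in
#' any primary-class sample.
#'
#' @param tree An annotated `clone_tree` ([annotate_tree()]).
#' @return Node index.
#' @export
primary_mrca <- function(tree) {
  pn <- primary_nodes(tree)
  if (length(pn) == 0) {
    stop_ct("no subclone detected in any primary sample", "no_primary")
  }
  node_lca(tree, pn)
}

#' Index of genomic diversity
#'
#' `IGD = sum(d) / (sum(d) + l * N)` where `d` are the edge-length
#' distances from the subset's closest common node to each subclone, `l`
#' is the stem length (truncal event count) and `N` the number of
#' subclones. 0 means all subclones sit at their common node (no
#' diversification relative to the stem); values near 1 mean diversity
#' dominates the truncal history.
#'
#' @param tree A `clone_tree`.
#' @param subclone_subset Node indices or node labels.
#' @return IGD in \[0, 1\]. When both the stem and all distances are zero
#'   the index is undefined; 0 is returned with a QC warning.
#' @export
igd <- function(tree, subclone_subset) {
  if (length(subclone_subset) == 0) {
    stop_ct("empty subclone subset", "invalid_input")
  }
  nodes <- if (is.character(subclone_subset)) {
    match(subclone_subset, tree$label)
  } else as.integer(subclone_subset)
  if (anyNA(nodes)) stop_ct("unknown subclone labels", "invalid_input")
  lca <- node_lca(tree, nodes)
  d <- vapply(nodes, function(u) path_length(tree, lca, u), 0L)
  l <- stem_length(tree)
  n <- length(nodes)
  if (sum(d) == 0 && l == 0) {
    warn_qc("IGD undefined: zero stem and zero distances; returning 0")
    return(0)
  }
  sum(d) / (sum(d) + l * n)
}

#' IGD per sample class
#'
#' @param tree An annotated `clone_tree`.
#' @param classes Sample classes to evaluate.
#' @return Named numeric vector (NA where a class has no detected
#'   subclones).
#' @export
igd_by_class <- function(tree, classes = c("primary", "lymph-node",
                                           "distant", "relapse")) {
  vapply(classes, function(cl) {
    nodes <- class_nodes(tree, cl)
    if (length(nodes) == 0) return(NA_real_)
    igd(tree, nodes)
  }, 0)
}

#' Seeding lineages of a metastatic site
#'
#' A seeding lineage is a maximal group of subclones detected at the site
#' whose topmost member has no proper ancestor detected there: each
#' lineage corresponds to one independent colonization. One lineage means
#' monoclonal, two or more polyclonal seeding.
#'
#' @param tree An annotated `clone_tree`.
#' @param site Anatomical site label (from the metadata).
#' @return List of lineages, each a list with `root` (node index) and
#'   `members` (node indices).
#' @export
seeding_lineages <- function(tree, site) {
  v <- site_nodes(tree, site)
  if (length(v) == 0) {
    stop_ct(paste0("no subclone detected at site ", site), "invalid_input")
  }
  roots <- v[vapply(v, function(u) {
    !any(vapply(setdiff(v, u), function(a) is_ancestor(tree, a, u), TRUE))
  }, TRUE)]
  lapply(roots, function(r) {
    list(root = r,
         members = v[vapply(v, function(u) is_ancestor(tree, r, u, strict = FALSE), TRUE)])
  })
}

# deepest node that is ancestor-or-self of `node` and ancestor-or-self of
# at least one primary-detected subclone: where the lineage splits off the
# primary tumor's known history
divergence_node <- function(tree, node, pn) {
  u <- node
  repeat {
    if (any(vapply(pn, function(p) is_ancestor(tree, u, p, strict = FALSE), TRUE))) {
      return(u)
    }
    u <- tree$parent[u]
    if (is.na(u)) return(tree$root)
  }
}

#' Timing of metastatic seeding at a site
#'
#' Each seeding lineage is dated against the most recent common ancestor
#' (MRCA) of the primary tumor: a lineage whose divergence from the
#' primary-detected part of the tree lies strictly above the primary MRCA
#' seeded earlier (before the MRCA emerged); at or below it, later. A
#' lineage attaching exactly at the MRCA is classified later.
#'
#' @inheritParams seeding_lineages
#' @return `"earlier"`, `"later"`, or `"both"`.
#' @export
classify_timing <- function(tree, site) {
  pn <- primary_nodes(tree)
  if (length(pn) == 0) stop_ct("no primary samples", "no_primary")
  m <- primary_mrca(tree)
  lin <- seeding_lineages(tree, site)
  lab <- vapply(lin, function(l) {
    d <- divergence_node(tree, l$root, pn)
    if (is_ancestor(tree, d, m, strict = TRUE)) "earlier" else "later"
  }, "")
  if (all(lab == "earlier")) "earlier"
  else if (all(lab == "later")) "later"
  else "both"
}

#' Monophyletic versus polyphyletic dissemination
#'
#' Monophyletic: the attachment points of all seeding lineages across all
#' metastatic sites lie on a single root-to-leaf path of the tree (one
#' phylogenetic branch feeds every metastasis); otherwise polyphyletic.
#'
#' @param tree An annotated `clone_tree`.
#' @param sites Metastatic site labels; defaults to all non-primary sites.
#' @param include_relapse Count anatomically distinct relapse sites as
#'   metastatic.
#' @return `"monophyletic"` or `"polyphyletic"`.
#' @export
classify_phyletic <- function(tree, sites = NULL, include_relapse = TRUE) {
  sites <- sites %||% met_sites(tree, include_relapse)
  if (length(sites) == 0) stop_ct("no metastatic sites", "invalid_input")
  roots <- unique(unlist(lapply(sites, function(s) {
    vapply(seeding_lineages(tree, s), function(l) l$root, 0L)
  })))
  if (length(roots) <= 1) return("monophyletic")
  for (i in seq_along(roots)[-1]) {
    for (j in seq_len(i - 1)) {
      comparable <- is_ancestor(tree, roots[i], roots[j], strict = FALSE) ||
        is_ancestor(tree, roots[j], roots[i], strict = FALSE)
      if (!comparable) return("polyphyletic")
    }
  }
  "monophyletic"
}

#' Intermetastatic spread between anatomical sites
#'
#' Emits a directed edge A -> B when a subclone detected at metastatic
#' site A — but never in the primary tumor — has a descendant (or itself)
#' detected at metastatic site B. When the only shared evidence is a
#' subclone present at both sites with no source-private ancestor, the
#' direction cannot be resolved and both orientations are reported with
#' `resolved = FALSE`.
#'
#' @inheritParams classify_phyletic
#' @return Data frame `source, target, subclones, resolved`; zero rows
#'   when no spread between metastases is supported. Errors with class
#'   `not_evaluable` when fewer than two metastatic sites exist.
#' @export
detect_intermetastatic <- function(tree, sites = NULL,
                                   include_relapse = TRUE) {
  sites <- sites %||% met_sites(tree, include_relapse)
  if (length(sites) < 2) {
    stop_ct("fewer than two metastatic sites: intermetastatic spread not evaluable",
            "not_evaluable")
  }
  pn <- primary_nodes(tree)
  det_at <- lapply(sites, function(s) site_nodes(tree, s))
  names(det_at) <- sites
  out <- data.frame(source = character(), target = character(),
                    subclones = character(), resolved = logical(),
                    stringsAsFactors = FALSE)
  for (a in sites) for (b in setdiff(sites, a)) {
    med <- Filter(function(x) {
      x %in% det_at[[a]] && !(x %in% pn) &&
        any(vapply(det_at[[b]], function(y) {
          is_ancestor(tree, x, y, strict = FALSE)
        }, TRUE))
    }, seq_along(tree$label))
    if (length(med) == 0) next
    private <- Filter(function(x) !(x %in% det_at[[b]]), med)
    if (length(private)) {
      out <- rbind(out, data.frame(
        source = a, target = b,
        subclones = paste(tree$label[unlist(private)], collapse = "|"),
        resolved = TRUE, stringsAsFactors = FALSE
      ))
    } else {
      out <- rbind(out, data.frame(
        source = a, target = b,
        subclones = paste(tree$label[unlist(med)], collapse = "|"),
        resolved = FALSE, stringsAsFactors = FALSE
      ))
    }
  }
  out
}

#' Classify a patient's full spread pattern
#'
#' Runs the timing, clonality, phyletic and intermetastatic classifiers
#' over every metastatic site of an annotated clone tree.
#'
#' @param tree An annotated `clone_tree`.
#' @param patient_id Identifier carried on the report.
#' @param include_relapse Count anatomically distinct relapse sites as
#'   metastatic sites.
#' @return A `spread_report`: list with `patient_id`, `sites` (per-site
#'   data frame `site, timing, n_lineages, clonality`), `earlier`,
#'   `later`, `monoclonal`, `polyclonal` (patient-level flags),
#'   `phyletic`, `intermetastatic` (data frame or NA when not evaluable),
#'   `n_met_sites`, `igd` (per sample class).
#' @export
classify_spread <- function(tree, patient_id = NA_character_,
                            include_relapse = TRUE) {
  stopifnot(inherits(tree, "clone_tree"))
  if (is.null(tree$detections)) {
    stop_ct("tree must be annotated with annotate_tree()", "invalid_input")
  }
  sites <- met_sites(tree, include_relapse)
  sites <- sites[vapply(sites, function(s) length(site_nodes(tree, s)) > 0, TRUE)]
  per_site <- do.call(rbind, lapply(sites, function(s) {
    lin <- seeding_lineages(tree, s)
    data.frame(
      site = s,
      timing = classify_timing(tree, s),
      n_lineages = length(lin),
      clonality = if (length(lin) >= 2) "polyclonal" else "monoclonal",
      stringsAsFactors = FALSE
    )
  }))
  inter <- if (length(sites) >= 2) {
    detect_intermetastatic(tree, sites, include_relapse)
  } else NA
  structure(
    list(
      patient_id = patient_id,
      sites = per_site,
      n_met_sites = length(sites),
      earlier = length(sites) > 0 &&
        any(per_site$timing %in% c("earlier", "both")),
      later = length(sites) > 0 &&
        any(per_site$timing %in% c("later", "both")),
      monoclonal = length(sites) > 0 &&
        any(per_site$clonality == "monoclonal"),
      polyclonal = length(sites) > 0 &&
        any(per_site$clonality == "polyclonal"),
      phyletic = if (length(sites) > 0) {
        classify_phyletic(tree, sites, include_relapse)
      } else NA_character_,
      intermetastatic = inter,
      igd = igd_by_class(tree)
    ),
    class = "spread_report"
  )
}

#' @export
print.spread_report <- function(x, ...) {
  cat(sprintf("<spread_report%s> %d metastatic site(s)\n",
              if (is.na(x$patient_id)) "" else paste0(" ", x$patient_id),
              x$n_met_sites))
  if (!is.null(x$sites)) print(x$sites, row.names = FALSE)
  cat(sprintf("  phyletic: %s; earlier: %s; later: %s; polyclonal: %s\n",
              x$phyletic, x$earlier, x$later, x$polyclonal))
  if (is.data.frame(x$intermetastatic)) {
    if (nrow(x$intermetastatic)) {
      cat("  intermetastatic:",
          paste(x$intermetastatic$source, "->", x$intermetastatic$target,
                collapse = "; "), "\n")
    } else cat("  intermetastatic: none detected\n")
  } else {
    cat("  intermetastatic: not evaluable (single metastatic site)\n")
  }
  invisible(x)
}

#' Cohort-level significance tests
#'
#' Thin contracts over the standard tests used for cohort comparisons:
#' two-sided Mann-Whitney U for independent groups and a paired Student
#' t-test for matched per-patient values (e.g. IGD of primary versus
#' metastasis). Significance is declared at p < 0.05.
#'
#' @param values_by_group Named list of numeric vectors (>= 2 groups).
#' @param paired Use the paired t-test (requires exactly two groups of
#'   equal length; NA pairs are dropped).
#' @return Data frame `group1, group2, test, statistic, p_value,
#'   significant`; a comparison with fewer than two observations per group
#'   is reported with NA p-value (not evaluable).
#' @export
cohort_tests <- function(values_by_group, paired = FALSE) {
  if (length(values_by_group) < 2) {
    stop_ct("need at least two groups", "invalid_input")
  }
  gn <- names(values_by_group)
  if (paired) {
    if (length(values_by_group) != 2) {
      stop_ct("paired test requires exactly two groups", "invalid_input")
    }
    a <- values_by_group[[1]]; b <- values_by_group[[2]]
    if (length(a) != length(b)) {
      stop_ct("paired test requires matched vectors", "invalid_input")
    }
    ok <- !is.na(a) & !is.na(b)
    if (sum(ok) < 2) {
      return(data.frame(group1 = gn[1], group2 = gn[2], test = "paired-t",
                        statistic = NA_real_, p_value = NA_real_,
                        significant = NA))
    }
    tt <- if (stats::sd(a[ok] - b[ok]) == 0) {
      list(statistic = c(t = 0), p.value = 1)
    } else stats::t.test(a[ok], b[ok], paired = TRUE)
    return(data.frame(group1 = gn[1], group2 = gn[2], test = "paired-t",
                      statistic = unname(tt$statistic),
                      p_value = tt$p.value,
                      significant = tt$p.value < 0.05))
  }
  pairs <- utils::combn(seq_along(values_by_group), 2)
  do.call(rbind, lapply(seq_len(ncol(pairs)), function(k) {
    i <- pairs[1, k]; j <- pairs[2, k]
    a <- values_by_group[[i]][!is.na(values_by_group[[i]])]
    b <- values_by_group[[j]][!is.na(values_by_group[[j]])]
    if (length(a) < 2 || length(b) < 2) {
      return(data.frame(group1 = gn[i], group2 = gn[j],
                        test = "mann-whitney-u", statistic = NA_real_,
                        p_value = NA_real_, significant = NA))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b, alternative = "two.sided"))
    data.frame(group1 = gn[i], group2 = gn[j], test = "mann-whitney-u",
               statistic = unname(wt$statistic), p_value = wt$p.value,
               significant = wt$p.value < 0.05)
  }))
}
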