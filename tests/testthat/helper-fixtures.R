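# In-code fixtures shared across the test files.

# event_table from a plain events x samples MCF matrix
mk_event_table <- function(mcf, mcf_sd = NULL) {
  if (is.null(dim(mcf))) mcf <- matrix(mcf, ncol = 1,
                                       dimnames = list(names(mcf), "S1"))
  structure(
    list(
      events = data.frame(event = rownames(mcf), kind = "gain",
                          chrom = "chr1",
                          start = seq_len(nrow(mcf)) * 1e6,
                          end = seq_len(nrow(mcf)) * 1e6 + 5e5,
                          gene = "", stringsAsFactors = FALSE),
      mcf = mcf,
      clonal = mcf >= 1 - 1e-12,
      mcf_sd = mcf_sd,
      samples = colnames(mcf)
    ),
    class = "event_table"
  )
}

# one CNA segment row in the internal table layout
mk_segment <- function(patient = "PT", sample = "S1", chrom = "chr1",
                       start = 1000000L, end = 50000000L, type = "gain",
                       nt = 3L, na_ = 1L, nb = 2L, np = 2L,
                       log2r = NA_real_, mbaf = NA_real_,
                       mcf = NA_real_, clonal = NA, gene = "") {
  df <- clonetrace:::empty_segment_table(1)
  df$patient <- patient; df$sample <- sample; df$chrom <- chrom
  df$start <- as.integer(start); df$end <- as.integer(end); df$type <- type
  df$Nt <- nt; df$NA. <- na_; df$NB <- nb; df$Np <- np
  df$log2R <- log2r; df$mBAF <- mbaf
  df$MCF <- mcf; df$clonal <- clonal; df$gene <- gene
  df
}

# one variant call row
mk_call <- function(patient = "PT", sample = "S1", caller = "mutect2",
                    chrom = "chr1", pos = 1000L, ref = "A", alt = "T",
                    vaf_t = 0.2, vaf_n = 0, dp_t = 100, dp_n = 100,
                    mapq = 60, passed_internal = TRUE, in_pon = FALSE,
                    in_popdb = FALSE, gene = "G", annotation = "exonic") {
  data.frame(patient = patient, sample = sample, caller = caller,
             chrom = chrom, pos = pos, ref = ref, alt = alt,
             vaf_t = vaf_t, vaf_n = vaf_n, dp_t = dp_t, dp_n = dp_n,
             mapq = mapq, passed_internal = passed_internal,
             in_pon = in_pon, in_popdb = in_popdb, gene = gene,
             annotation = annotation, stringsAsFactors = FALSE)
}

wide_bed <- function() {
  GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 2e8))
}

# a hand-built annotated clone tree:
#   normal -> A(stem) -> B -> C
#                     \-> D
# detections given as list(node_label = c(sample = fraction))
mk_tree <- function(detections, meta,
                    parents = c(NA, 1L, 2L, 3L, 2L),
                    labels = c("normal", "A", "B", "C", "D"),
                    lengths = c(0L, 4L, 2L, 2L, 3L)) {
  n <- length(labels)
  edge_events <- lapply(seq_len(n), function(i) {
    if (lengths[i] == 0) character() else
      paste0("e", i, "_", seq_len(lengths[i]))
  })
  all_ev <- unlist(edge_events)
  bin <- matrix(0L, n - 1, length(all_ev),
                dimnames = list(labels[-1], all_ev))
  for (i in 2:n) {
    path <- i
    while (!is.na(parents[path[1]])) path <- c(parents[path[1]], path)
    bin[i - 1, unlist(edge_events[setdiff(path, 1)])] <- 1L
  }
  tree <- structure(
    list(label = labels, parent = parents, edge_events = edge_events,
         edge_length = vapply(edge_events, length, 0L),
         subclones = c(list(character()), as.list(labels[-1])),
         root = 1L, matrix = bin, score = sum(lengths),
         detections = NULL, meta = NULL),
    class = "clone_tree"
  )
  fr <- matrix(0, n - 1, nrow(meta),
               dimnames = list(labels[-1], meta$sample))
  for (lab in names(detections)) {
    fr[lab, names(detections[[lab]])] <- detections[[lab]]
  }
  annotate_tree(tree, meta, fr)
}

mk_meta <- function(samples, sites, classes, patient = "PT") {
  data.frame(patient = patient, sample = samples, site = sites,
             class = classes, timepoint = "diagnosis",
             stringsAsFactors = FALSE)
}

# per-patient spread-label flags (truth vs estimate comparisons)
label_flags <- function(report) clonetrace:::report_flags(report)
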