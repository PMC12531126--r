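# Methods for the clone_tree S3 class.

#' @export
print.clone_tree <- function(x, ...) {
  n_sc <- sum(vapply(x$subclones, length, 0L))
  cat(sprintf(
    "<clone_tree> %d subclones, %d nodes, %d events, parsimony score %d\n",
    n_sc, length(x$label), ncol(x$matrix), x$score
  ))
  cat(sprintf("  stem length %d (normal -> %s)\n",
              stem_length(x), x$label[stem_node(x)]))
  print_subtree(x, x$root, "", TRUE)
  invisible(x)
}

print_subtree <- function(x, node, prefix, last) {
  if (node != x$root) {
    branch <- if (last) "\\-" else "+-"
    det <- ""
    if (!is.null(x$detections)) {
      s <- colnames(x$detections)[x$detections[node, ] > 0]
      if (length(s)) det <- paste0("  [", paste(s, collapse = ","), "]")
    }
    cat(prefix, branch, x$label[node], " (", x$edge_length[node], ")",
        det, "\n", sep = "")
    prefix <- paste0(prefix, if (last) "  " else "| ")
  } else {
    cat(" normal\n")
  }
  kids <- which(!is.na(x$parent) & x$parent == node)
  for (i in seq_along(kids)) {
    print_subtree(x, kids[i], prefix, i == length(kids))
  }
}

#' @export
summary.clone_tree <- function(object, ...) {
  df <- data.frame(
    node = seq_along(object$label),
    label = object$label,
    parent = ifelse(is.na(object$parent), NA,
                    object$label[object$parent]),
    n_events = object$edge_length,
    events = vapply(object$edge_events, paste, "", collapse = "|"),
    stringsAsFactors = FALSE
  )
  if (!is.null(object$detections)) {
    df$samples <- vapply(seq_along(object$label), function(i) {
      paste(colnames(object$detections)[object$detections[i, ] > 0],
            collapse = ",")
    }, "")
  }
  df
}

# node id of the tumor MRCA (child of the normal root); the stem is the
# edge normal -> MRCA
stem_node <- function(tree) {
  kids <- which(!is.na(tree$parent) & tree$parent == tree$root)
  kids[1]
}

stem_length <- function(tree) {
  tree$edge_length[stem_node(tree)]
}

# sum of edge lengths on the path from ancestor `a` down to node `u`
path_length <- function(tree, a, u) {
  len <- 0L
  while (u != a) {
    len <- len + tree$edge_length[u]
    u <- tree$parent[u]
    if (is.na(u)) stop_ct("node is not a descendant of the ancestor",
                          "invalid_input")
  }
  len
}

is_ancestor <- function(tree, a, u, strict = TRUE) {
  if (a == u) return(!strict)
  u <- tree$parent[u]
  while (!is.na(u)) {
    if (u == a) return(TRUE)
    u <- tree$parent[u]
  }
  FALSE
}

node_lca <- function(tree, nodes) {
  nodes <- unique(nodes)
  if (length(nodes) == 1) return(nodes)
  anc_path <- function(u) {
    p <- u
    while (!is.na(tree$parent[u])) { u <- tree$parent[u]; p <- c(p, u) }
    p
  }
  common <- Reduce(intersect, lapply(nodes, anc_path))
  common[1]  # paths list root-last, so first common element is deepest
}

#' Newick serialization of a clone tree
#'
#' Branch lengths are event counts; each node carries a comment listing
#' the event ids acquired on its parent edge.
#'
#' @param tree A `clone_tree`.
#' @param comments Include `[&events=...]` comments.
#' @return A single Newick string (terminated by `;`).
#' @export
newick <- function(tree, comments = TRUE) {
  rec <- function(node) {
    kids <- which(!is.na(tree$parent) & tree$parent == node)
    inner <- if (length(kids)) {
      paste0("(", paste(vapply(kids, rec, ""), collapse = ","), ")")
    } else ""
    if (node == tree$root) return(paste0(inner, tree$label[node]))
    com <- if (comments && tree$edge_length[node] > 0) {
      paste0("[&events=", paste(tree$edge_events[[node]], collapse = "|"), "]")
    } else ""
    paste0(inner, tree$label[node], ":", tree$edge_length[node], com)
  }
  paste0(rec(tree$root), ";")
}

#' @rdname newick
#' @param path Output file.
#' @export
write_newick <- function(tree, path, comments = TRUE) {
  writeLines(newick(tree, comments), path)
  invisible(path)
}

#' Edge table of a clone tree
#'
#' @param tree A `clone_tree`.
#' @return Data frame `parent, child, n_events, event_ids`.
#' @export
edge_table <- function(tree) {
  ix <- which(!is.na(tree$parent))
  data.frame(
    parent = tree$label[tree$parent[ix]],
    child = tree$label[ix],
    n_events = tree$edge_length[ix],
    event_ids = vapply(tree$edge_events[ix], paste, "", collapse = "|"),
    stringsAsFactors = FALSE
  )
}

#' Plot a clone tree
#'
#' Simple rectangular cladogram: x position is the cumulative number of
#' events from the normal root, leaves are spread vertically. Nodes
#' detected in annotated samples are labeled with their sites.
#'
#' @param x A `clone_tree`.
#' @param cex Label size.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.clone_tree <- function(x, cex = 0.8, ...) {
  n <- length(x$label)
  depth <- numeric(n)
  for (u in root_order(ifelse(is.na(x$parent), 0L, x$parent))) {
    if (!is.na(x$parent[u])) {
      depth[u] <- depth[x$parent[u]] + x$edge_length[u]
    }
  }
  y <- rep(NA_real_, n)
  leaves <- which(!seq_len(n) %in% x$parent)
  y[leaves] <- seq_along(leaves)
  for (u in rev(root_order(ifelse(is.na(x$parent), 0L, x$parent)))) {
    if (is.na(y[u])) {
      kids <- which(!is.na(x$parent) & x$parent == u)
      y[u] <- mean(y[kids])
    }
  }
  graphics::plot(NA, xlim = c(0, max(depth) * 1.25 + 1),
                 ylim = c(0.5, length(leaves) + 0.5),
                 xlab = "events from normal", ylab = "", yaxt = "n",
                 bty = "n", ...)
  for (u in seq_len(n)) {
    p <- x$parent[u]
    if (is.na(p)) next
    graphics::segments(depth[p], y[p], depth[p], y[u])
    graphics::segments(depth[p], y[u], depth[u], y[u])
  }
  lab <- x$label
  if (!is.null(x$detections) && !is.null(x$meta)) {
    for (i in seq_len(n)) {
      s <- colnames(x$detections)[x$detections[i, ] > 0]
      if (length(s)) {
        sites <- unique(x$meta$site[match(s, x$meta$sample)])
        lab[i] <- paste0(lab[i], " @", paste(sites, collapse = "/"))
      }
    }
  }
  graphics::text(depth, y, lab, pos = 4, cex = cex)
  invisible(x)
}
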