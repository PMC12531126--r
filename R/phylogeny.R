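# Rooted maximum-parsimony clone trees from binary event matrices.
#
# Subclones (matrix rows) plus an all-zero "normal" outgroup are the tips of
# an unrooted binary tree; the minimum-Fitch-score tree is found exactly
# (branch and bound) up to `exhaustive_limit` subclones, else by stepwise
# addition with nearest-neighbor-interchange refinement. Events are mapped
# to edges by Fitch backtrace, zero-change edges are collapsed (ancestral
# subclones become internal nodes), and the tree is rooted at normal with
# the stem edge leading to the tumor MRCA.

# ---- state encoding ----------------------------------------------------
# characters are binary; sets are bitmasks: 1 = {0}, 2 = {1}, 3 = {0,1}
row_masks <- function(matrix01) {
  m <- matrix(1L, nrow(matrix01), ncol(matrix01))
  m[matrix01 == 1L] <- 2L
  m
}

validate_event_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) < 1) {
    stop_ct("event matrix must have >= 1 subclone row", "invalid_input")
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("SC", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("E", seq_len(ncol(m)))
  if (!all(m %in% c(0L, 1L))) {
    stop_ct("event matrix entries must be 0/1", "invalid_input")
  }
  storage.mode(m) <- "integer"
  m
}

# ---- generic Fitch score ----------------------------------------------

#' Fitch parsimony score of a tree against an event matrix
#'
#' Counts the minimum number of character changes over all ancestral-state
#' assignments, with the all-zero normal outgroup forcing ancestral state 0
#' at the root. Works for multifurcating trees and for trees whose internal
#' nodes are themselves observed subclones.
#'
#' @param tree A `clone_tree`, or a 2-column edge matrix (1-based node ids,
#'   tips `1..nrow(matrix)+1` with tip 1 = normal, tip `i+1` = row `i`).
#' @param matrix Binary subclones x events matrix. Defaults to the matrix
#'   stored on a `clone_tree`.
#' @return Integer parsimony score.
#' @export
fitch_score <- function(tree, matrix = NULL) {
  if (inherits(tree, "clone_tree")) {
    matrix <- matrix %||% tree$matrix
    matrix <- validate_event_matrix(matrix)
    if (!setequal(unlist(tree$subclones), rownames(matrix))) {
      stop_ct("tree subclones do not match matrix rows", "invalid_input")
    }
    ex <- expand_for_scoring(tree, matrix)
    return(cpp_fitch_parent(ex$parent, ex$mask))
  }
  matrix <- validate_event_matrix(matrix)
  edges <- tree
  n_tip <- nrow(matrix) + 1L
  if (!setequal(unique(as.vector(edges))[unique(as.vector(edges)) <= n_tip],
                seq_len(n_tip))) {
    stop_ct("edge matrix tips must be 1..nrow(matrix)+1", "invalid_input")
  }
  rt <- root_edges(edges, n_tip)
  mask <- matrix(0L, length(rt$parent), ncol(matrix))
  mask[1, ] <- 1L  # normal
  mask[2:n_tip, ] <- row_masks(matrix)
  cpp_fitch_parent(rt$parent, mask)
}

# attach each observed-internal subclone as a pseudo-leaf so the C++ scorer
# only sees masks on leaves-or-self
expand_for_scoring <- function(tree, matrix) {
  n <- length(tree$label)
  parent <- ifelse(is.na(tree$parent), 0L, tree$parent)
  mask <- matrix(0L, n, ncol(matrix))
  mask[1, ] <- 1L
  for (i in seq_len(n)) {
    scs <- tree$subclones[[i]]
    if (length(scs)) {
      mask[i, ] <- row_masks(matrix[scs[1], , drop = FALSE])
    }
  }
  list(parent = as.integer(parent), mask = mask)
}

# root an unrooted edge matrix at tip `root` (BFS); children visited in
# ascending node-id order for determinism
root_edges <- function(edges, n_tip, root = 1L) {
  n_nodes <- max(edges)
  adj <- vector("list", n_nodes)
  for (i in seq_len(nrow(edges))) {
    a <- edges[i, 1]; b <- edges[i, 2]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  parent <- rep(NA_integer_, n_nodes)
  parent[root] <- 0L
  queue <- root
  order <- integer()
  while (length(queue)) {
    u <- queue[1]; queue <- queue[-1]
    order <- c(order, u)
    for (v in sort(adj[[u]])) {
      if (is.na(parent[v])) {
        parent[v] <- u
        queue <- c(queue, v)
      }
    }
  }
  list(parent = as.integer(parent), order = order)
}

# Fitch up-pass + down-pass on a rooted tree: returns final states (0/1
# matrix nodes x chars) and per-edge change columns
fitch_backtrace <- function(parent, mask) {
  n <- length(parent)
  n_char <- ncol(mask)
  kids <- split(seq_len(n)[parent > 0], parent[parent > 0])
  # postorder
  root <- which(parent == 0L)
  ord <- integer(); stack <- root
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, u)
    stack <- c(stack, kids[[as.character(u)]])
  }
  prelim <- matrix(0L, n, n_char)
  for (u in rev(ord)) {
    acc <- mask[u, ]
    for (v in kids[[as.character(u)]]) {
      sv <- prelim[v, ]
      first <- acc == 0L
      acc[first] <- sv[first]
      rest <- !first
      inter <- bitwAnd(acc, sv)
      use_i <- rest & inter > 0L
      acc[use_i] <- inter[use_i]
      use_u <- rest & inter == 0L
      acc[use_u] <- bitwOr(acc[use_u], sv[use_u])
    }
    prelim[u, ] <- acc
  }
  final <- matrix(0L, n, n_char)  # stores chosen state as 0/1
  for (u in ord) {
    if (parent[u] == 0L) {
      # root (normal outgroup): prefer state 0 where ambiguous
      final[u, ] <- ifelse(bitwAnd(prelim[u, ], 1L) > 0L, 0L, 1L)
    } else {
      pf <- final[parent[u], ]
      pf_mask <- ifelse(pf == 1L, 2L, 1L)
      keep <- bitwAnd(prelim[u, ], pf_mask) > 0L
      final[u, ] <- ifelse(keep, pf, 1L - pf)
    }
  }
  changes <- vector("list", n)
  for (u in seq_len(n)) {
    if (parent[u] == 0L) changes[[u]] <- integer() else {
      changes[[u]] <- which(final[u, ] != final[parent[u], ])
    }
  }
  list(final = final, changes = changes)
}

# collapse zero-change edges of a rooted tip-tree into a clone tree.
# tip_labels: labels of tips 1..n_tip (tip 1 = "normal").
build_clone_tree <- function(parent, changes, n_tip, tip_labels, matrix,
                             score) {
  n <- length(parent)
  root <- which(parent == 0L)
  # representative (root-ward) of each node after collapsing
  rep_of <- seq_len(n)
  find_rep <- function(u) {
    while (rep_of[u] != u) u <- rep_of[u]
    u
  }
  # preorder
  ord <- root_order(parent)
  for (u in ord) {
    p <- parent[u]
    if (p == 0L) next
    if (length(changes[[u]]) == 0L) {
      pr <- find_rep(p)
      if (pr == root) next  # keep the MRCA node distinct from normal
      rep_of[u] <- pr
    }
  }
  reps <- vapply(seq_len(n), find_rep, 0L)
  keep <- sort(unique(reps))
  new_id <- match(reps, keep)
  k <- length(keep)
  subclones <- vector("list", k)
  for (t in seq_len(n_tip)[-1]) {
    subclones[[new_id[t]]] <- c(subclones[[new_id[t]]], tip_labels[t])
  }
  new_parent <- rep(NA_integer_, k)
  edge_events_idx <- vector("list", k)
  for (u in keep) {
    id <- new_id[u]
    p <- parent[u]
    if (p == 0L) next
    new_parent[id] <- new_id[find_rep(p)]
    edge_events_idx[[id]] <- changes[[u]]
  }
  # order nodes: root first, then preorder (deterministic)
  lab <- character(k)
  lab[new_id[root]] <- "normal"
  ev_names <- colnames(matrix)
  edge_events <- lapply(edge_events_idx, function(ix) {
    if (is.null(ix)) character() else ev_names[sort(ix)]
  })
  internal_ct <- 0L
  for (i in seq_len(k)) {
    if (nzchar(lab[i])) next
    if (length(subclones[[i]])) {
      lab[i] <- subclones[[i]][1]
    } else {
      internal_ct <- internal_ct + 1L
      lab[i] <- paste0("node", internal_ct)
    }
  }
  tree <- structure(
    list(
      label = lab,
      parent = new_parent,
      edge_events = edge_events,
      edge_length = vapply(edge_events, length, 0L),
      subclones = subclones,
      root = new_id[root],
      matrix = matrix,
      score = score,
      detections = NULL,
      meta = NULL
    ),
    class = "clone_tree"
  )
  reorder_clone_tree(tree)
}

root_order <- function(parent) {
  n <- length(parent)
  kids <- split(seq_len(n)[parent > 0 & !is.na(parent)],
                parent[parent > 0 & !is.na(parent)])
  root <- which(parent == 0L | is.na(parent))[1]
  ord <- integer(); stack <- root
  while (length(stack)) {
    u <- stack[length(stack)]; stack <- stack[-length(stack)]
    ord <- c(ord, u)
    ks <- kids[[as.character(u)]]
    if (length(ks)) stack <- c(stack, rev(sort(ks)))
  }
  ord
}

# renumber nodes so the root is 1 and the rest follow in preorder
reorder_clone_tree <- function(tree) {
  p <- ifelse(is.na(tree$parent), 0L, tree$parent)
  ord <- root_order(p)
  new_of <- match(seq_along(ord), ord)
  tree$label <- tree$label[ord]
  tree$edge_events <- tree$edge_events[ord]
  tree$edge_length <- tree$edge_length[ord]
  tree$subclones <- tree$subclones[ord]
  tree$parent <- vapply(tree$parent[ord], function(pp) {
    if (is.na(pp)) NA_integer_ else new_of[pp]
  }, 0L)
  tree$root <- 1L
  tree
}

# canonical signature for tie-breaking: sorted clade strings
tree_signature <- function(tree) {
  n <- length(tree$label)
  below <- vector("list", n)
  for (u in rev(root_order(ifelse(is.na(tree$parent), 0L, tree$parent)))) {
    own <- tree$subclones[[u]]
    kids <- which(!is.na(tree$parent) & tree$parent == u)
    below[[u]] <- sort(unique(c(own, unlist(below[kids]))))
  }
  paste(sort(vapply(below, paste, "", collapse = ",")), collapse = ";")
}

# ---- search ------------------------------------------------------------

#' Maximum-parsimony clone tree from a binary event matrix
#'
#' Finds a minimum-Fitch-score tree over the subclone rows plus the normal
#' outgroup. Up to `exhaustive_limit` distinct subclones the search is
#' exact (branch and bound over all unrooted topologies); beyond it,
#' greedy stepwise addition followed by nearest-neighbor-interchange hill
#' climbing is used (deterministic: taxa in row order, first-improvement).
#' Ties between optimal topologies are broken by (1) fewer internal nodes
#' after collapsing zero-change edges, (2) lexicographic order of the
#' sorted clade partition. Events are mapped to edges by Fitch backtrace
#' with ambiguities resolved toward the ancestral state, so homoplasy-free
#' characters map to a single gain edge.
#'
#' @param matrix Binary subclones x events matrix (rownames = subclone ids,
#'   colnames = event ids).
#' @param exhaustive_limit Maximum number of distinct subclones for exact
#'   search.
#' @return A [`clone_tree`][fitch_score] object: fields `label`, `parent`
#'   (node 1 is the normal root), `edge_events`, `edge_length`,
#'   `subclones` (per node), `score`, `matrix`.
#' @export
max_parsimony_tree <- function(matrix, exhaustive_limit = 9L) {
  matrix <- validate_event_matrix(matrix)
  zero_col <- colSums(matrix) == 0
  if (any(zero_col)) matrix <- matrix[, !zero_col, drop = FALSE]
  if (ncol(matrix) == 0) stop_ct("no events in matrix", "invalid_input")
  dup <- duplicated(apply(matrix, 1, paste, collapse = ""))
  um <- matrix[!dup, , drop = FALSE]
  n_sub <- nrow(um)
  tip_labels <- c("normal", rownames(um))
  n_tip <- n_sub + 1L

  if (n_sub <= exhaustive_limit) {
    mask <- rbind(rep(1L, ncol(um)), row_masks(um))
    res <- cpp_mp_search(mask, capTrees = 128L)
    cands <- res$trees
    score <- res$score
  } else {
    edges <- stepwise_addition(um)
    edges <- nni_refine(edges, um)
    cands <- list(edges)
    score <- score_edges(edges, um)
  }

  built <- lapply(cands, function(ed) {
    rt <- root_edges(ed, n_tip)
    mask <- matrix(0L, length(rt$parent), ncol(um))
    mask[1, ] <- 1L
    mask[2:n_tip, ] <- row_masks(um)
    bt <- fitch_backtrace(rt$parent, mask)
    build_clone_tree(rt$parent, bt$changes, n_tip, tip_labels, matrix, score)
  })
  n_internal <- vapply(built, function(tr) {
    sum(!vapply(tr$subclones, length, 0L) & tr$label != "normal")
  }, 0L)
  built <- built[n_internal == min(n_internal)]
  sigs <- vapply(built, tree_signature, "")
  tree <- built[[order(sigs)[1]]]
  # re-attach duplicate rows to the node of their twin
  if (any(dup)) {
    keys <- apply(matrix, 1, paste, collapse = "")
    for (d in which(dup)) {
      twin <- rownames(matrix)[which(keys == keys[d])[1]]
      node <- which(vapply(tree$subclones, function(s) twin %in% s, TRUE))
      tree$subclones[[node]] <- c(tree$subclones[[node]], rownames(matrix)[d])
    }
  }
  tree
}

# score an edge matrix that may contain only a subset of the tips (used
# during stepwise addition); nodes are compacted before scoring
score_edges <- function(edges, um) {
  n_tip <- nrow(um) + 1L
  nodes <- sort(unique(as.vector(edges)))
  idmap <- match(seq_len(max(edges)), nodes)
  e2 <- matrix(idmap[edges], ncol = 2)
  rt <- root_edges(e2, length(nodes), root = idmap[1])
  mask <- matrix(0L, length(nodes), ncol(um))
  for (t in nodes[nodes <= n_tip]) {
    mask[idmap[t], ] <- if (t == 1L) 1L else row_masks(um[t - 1L, , drop = FALSE])
  }
  cpp_fitch_parent(rt$parent, mask)
}

# greedy stepwise addition over rows of um (deterministic)
stepwise_addition <- function(um) {
  n_tip <- nrow(um) + 1L
  edges <- matrix(c(1L, 2L, 3L, rep(n_tip + 1L, 3)), ncol = 2)
  next_internal <- n_tip + 2L
  if (n_tip < 4L) return(edges)
  for (tip in 4:n_tip) {
    best_score <- Inf; best_edges <- NULL
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      cand <- rbind(edges[-i, , drop = FALSE],
                    c(a, next_internal), c(next_internal, b),
                    c(next_internal, tip))
      s <- score_edges(cand, um)
      if (s < best_score) { best_score <- s; best_edges <- cand }
    }
    edges <- best_edges
    next_internal <- next_internal + 1L
  }
  edges
}

# first-improvement NNI until local optimum
nni_refine <- function(edges, um) {
  repeat {
    cur <- score_edges(edges, um)
    improved <- FALSE
    n_tip <- nrow(um) + 1L
    internal <- which(edges[, 1] > n_tip & edges[, 2] > n_tip)
    for (i in internal) {
      u <- edges[i, 1]; v <- edges[i, 2]
      u_nbr <- setdiff(c(edges[edges[, 1] == u, 2], edges[edges[, 2] == u, 1]), v)
      v_nbr <- setdiff(c(edges[edges[, 1] == v, 2], edges[edges[, 2] == v, 1]), u)
      if (length(u_nbr) < 2 || length(v_nbr) < 2) next
      for (swap in 1:2) {
        e2 <- edges
        a <- u_nbr[1]; b <- v_nbr[swap]
        e2 <- swap_endpoint(e2, u, a, b)
        e2 <- swap_endpoint(e2, v, b, a)
        s <- score_edges(e2, um)
        if (s < cur) { edges <- e2; improved <- TRUE; break }
      }
      if (improved) break
    }
    if (!improved) return(edges)
  }
}

swap_endpoint <- function(edges, node, old, new) {
  for (i in seq_len(nrow(edges))) {
    if (edges[i, 1] == node && edges[i, 2] == old) { edges[i, 2] <- new; return(edges) }
    if (edges[i, 2] == node && edges[i, 1] == old) { edges[i, 1] <- new; return(edges) }
  }
  edges
}

# ---- annotation --------------------------------------------------------

#' Annotate a clone tree with sample detections and anatomical sites
#'
#' Attaches, to every node, the samples in which its subclone is detected
#' (identity fraction at or above `detection`) together with the sample's
#' anatomical site and class.
#'
#' @param tree A `clone_tree`.
#' @param metadata Data frame with columns `sample`, `site`, `class`
#'   ([read_metadata()] layout).
#' @param fractions Subclones x samples identity-fraction matrix (e.g.
#'   `subclone_set$fractions`).
#' @param detection Detection threshold.
#' @return The tree with `detections` (nodes x samples matrix) and `meta`
#'   filled.
#' @export
annotate_tree <- function(tree, metadata, fractions, detection = 0.05) {
  stopifnot(inherits(tree, "clone_tree"))
  samples <- colnames(fractions)
  unknown <- setdiff(samples, metadata$sample)
  if (length(unknown)) {
    stop_ct(paste0("samples missing from metadata: ",
                   paste(unknown, collapse = ", ")), "invalid_input")
  }
  n <- length(tree$label)
  det <- matrix(0, n, length(samples),
                dimnames = list(tree$label, samples))
  for (i in seq_len(n)) {
    for (sc in tree$subclones[[i]]) {
      if (sc %in% rownames(fractions)) {
        det[i, ] <- det[i, ] + fractions[sc, ]
      }
    }
  }
  det[det < detection] <- 0
  tree$detections <- det
  tree$meta <- metadata[match(samples, metadata$sample),
                        c("sample", "site", "class")]
  tree$detection <- detection
  tree
}
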