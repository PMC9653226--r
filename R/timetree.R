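#' Time-scaled cell phylogenies with an origin node
#'
#' A \code{timetree} is a time-scaled rooted binary tree augmented with a
#' degree-1 origin node marking the start of the experiment. Node times run
#' forward from 0 at the origin; every sampled tip sits at the sampling time
#' \code{t_s}; every child is strictly younger (larger time) than its parent.
#' Degree-2 nodes are permitted (they arise from subdividing branches at the
#' scarring-window boundaries) which is why the structure is a plain node
#' table rather than an \code{ape::phylo}; converters to and from
#' \code{phylo} are provided for I/O and interoperability.
#'
#' @param parent Integer vector; \code{parent[i]} is the parent of node i,
#'   \code{NA} for the origin.
#' @param time Numeric node times (forward from 0 at the origin).
#' @param label Character tip labels (\code{NA} for internal nodes).
#' @param t_s Sampling time; all tips must sit at \code{t_s}.
#' @param validate Check structural invariants (default TRUE).
#' @return An object of class \code{timetree}.
#' @export
new_timetree <- function(parent, time, label, t_s, validate = TRUE) {
  n_nodes <- length(parent)
  stopifnot(length(time) == n_nodes, length(label) == n_nodes)
  tr <- structure(list(parent = as.integer(parent), time = as.numeric(time),
                       label = as.character(label), t_s = as.numeric(t_s)),
                  class = "timetree")
  if (validate) validate_timetree(tr)
  tr
}

validate_timetree <- function(tree, tol = 1e-6) {
  origin <- which(is.na(tree$parent))
  if (length(origin) != 1L)
    stop("timetree needs exactly one origin node (parent NA)", call. = FALSE)
  if (abs(tree$time[origin]) > tol)
    stop("origin node must sit at time 0", call. = FALSE)
  nc <- tabulate(tree$parent[!is.na(tree$parent)], nbins = length(tree$parent))
  if (nc[origin] != 1L)
    stop("origin node must have exactly one child", call. = FALSE)
  if (any(nc > 2L))
    stop("timetree must be binary (at most 2 children per node)", call. = FALSE)
  tips <- which(nc == 0L)
  if (any(abs(tree$time[tips] - tree$t_s) > tol))
    stop("all tips must be sampled contemporaneously at t_s", call. = FALSE)
  if (anyNA(tree$label[tips]) || anyDuplicated(stats::na.omit(tree$label[tips])))
    stop("tips need unique labels", call. = FALSE)
  ok <- !is.na(tree$parent)
  if (any(tree$time[ok] <= tree$time[tree$parent[ok]]))
    stop("every child must be strictly younger than its parent", call. = FALSE)
  invisible(tree)
}

n_nodes <- function(tree) length(tree$parent)

# Node indices of tips / origin; child lists.
tree_tips <- function(tree) {
  nc <- tabulate(tree$parent[!is.na(tree$parent)], nbins = n_nodes(tree))
  which(nc == 0L)
}

tree_origin <- function(tree) which(is.na(tree$parent))

tree_children <- function(tree) {
  kids <- vector("list", n_nodes(tree))
  for (i in seq_along(tree$parent)) {
    p <- tree$parent[i]
    if (!is.na(p)) kids[[p]] <- c(kids[[p]], i)
  }
  kids
}

#' Number of sampled cells (tips) in a timetree
#' @param tree A \code{timetree}.
#' @return Integer tip count.
#' @export
n_tips <- function(tree) length(tree_tips(tree))

#' @export
print.timetree <- function(x, ...) {
  cat(sprintf("<timetree> %d tips sampled at t_s = %g, MRCA at time %g\n",
              n_tips(x), x$t_s, mrca_time(x)))
  invisible(x)
}

#' Node table of a timetree
#'
#' @param tree A \code{timetree}.
#' @return A tibble with one row per node: \code{node}, \code{parent},
#'   \code{time}, \code{label}, \code{is_tip}.
#' @export
node_times <- function(tree) {
  tips <- tree_tips(tree)
  tibble::tibble(node = seq_along(tree$parent), parent = tree$parent,
                 time = tree$time, label = tree$label,
                 is_tip = seq_along(tree$parent) %in% tips)
}

#' Convert an ape phylo into a timetree
#'
#' Tips of the (ultrametric) phylogeny are placed at \code{origin_height}
#' (the sampling time t_s) and the origin node at time 0, so the root sits at
#' \code{origin_height - tree height}; \code{origin_height} must therefore be
#' at least the tree height.
#'
#' @param phy An ultrametric \code{ape::phylo} with branch lengths.
#' @param origin_height Time span from experiment start to sampling (t_s).
#' @param tol Ultrametricity tolerance on tip depths.
#' @return A \code{timetree}.
#' @export
timetree_from_phylo <- function(phy, origin_height, tol = 1e-6) {
  stopifnot(inherits(phy, "phylo"))
  if (is.null(phy$edge.length)) stop("branch lengths required", call. = FALSE)
  nt <- length(phy$tip.label)
  depth <- ape::node.depth.edgelength(phy)
  height <- max(depth[seq_len(nt)])
  if (max(depth[seq_len(nt)]) - min(depth[seq_len(nt)]) > tol)
    stop("tree is not ultrametric: tips are not contemporaneous", call. = FALSE)
  if (origin_height < height - tol)
    stop("origin_height must be at least the tree height", call. = FALSE)
  root_time <- origin_height - height
  nn <- nt + phy$Nnode
  parent <- rep(NA_integer_, nn + 1L)          # +1 for the origin node
  parent[phy$edge[, 2]] <- phy$edge[, 1]
  origin <- nn + 1L
  root <- nt + 1L
  parent[root] <- origin
  time <- c(root_time + depth, 0)
  time[seq_len(nt)] <- origin_height           # snap tips exactly to t_s
  label <- c(phy$tip.label, rep(NA_character_, nn - nt + 1L))
  new_timetree(parent, time, label, t_s = origin_height)
}

#' Convert a timetree to an ape phylo
#'
#' Degree-2 (window-subdivision) nodes are suppressed and the origin branch
#' is exported as the \code{root.edge}, so the result is a standard binary
#' rooted phylo whose height is \code{t_s - mrca_time(tree)}.
#'
#' @param x A \code{timetree}.
#' @param ... Unused.
#' @return An \code{ape::phylo} with \code{root.edge}.
#' @importFrom ape as.phylo
#' @method as.phylo timetree
#' @export
as.phylo.timetree <- function(x, ...) {
  kids <- tree_children(x)
  tips <- tree_tips(x)
  nt <- length(tips)
  tip_id <- integer(n_nodes(x)); tip_id[tips] <- seq_len(nt)
  # walk down from origin skipping degree-2 chains
  next_real <- function(node) {
    while (length(kids[[node]]) == 1L && !(node %in% tips))
      node <- kids[[node]][1L]
    node
  }
  root <- next_real(kids[[tree_origin(x)]][1L])
  n_internal <- 0L
  edge <- matrix(0L, 0, 2); elen <- numeric(0)
  internal_id <- integer(n_nodes(x))
  # assign internal ids in preorder starting at root = nt+1
  assign_ids <- function(node) {
    n_internal <<- n_internal + 1L
    internal_id[node] <<- nt + n_internal
    for (ch in kids[[node]]) {
      real <- next_real(ch)
      if (!(real %in% tips)) assign_ids(real)
    }
  }
  if (root %in% tips) stop("cannot convert a single-tip timetree to phylo", call. = FALSE)
  # iterative preorder to avoid deep recursion on large trees
  stack <- root
  order_internal <- integer(0)
  while (length(stack)) {
    node <- stack[[1]]; stack <- stack[-1]
    order_internal <- c(order_internal, node)
    ch_real <- vapply(kids[[node]], next_real, integer(1))
    stack <- c(ch_real[!(ch_real %in% tips)], stack)
  }
  internal_id[order_internal] <- nt + seq_along(order_internal)
  for (node in order_internal) {
    for (ch in kids[[node]]) {
      real <- next_real(ch)
      id <- if (real %in% tips) tip_id[real] else internal_id[real]
      edge <- rbind(edge, c(internal_id[node], id))
      elen <- c(elen, x$time[real] - x$time[node])
    }
  }
  phy <- list(edge = edge, edge.length = elen,
              tip.label = x$label[tips], Nnode = length(order_internal),
              root.edge = x$time[root])
  class(phy) <- "phylo"
  attr(phy, "order") <- "cladewise"
  phy
}

#' Parse a Newick tree into a timetree
#'
#' @param text Newick string (or a file path when \code{file = TRUE}).
#' @param origin_height Sampling time t_s; at least the tree height.
#' @param file Treat \code{text} as a path.
#' @return A \code{timetree} with tips at \code{origin_height}.
#' @export
parse_newick <- function(text, origin_height, file = FALSE) {
  phy <- suppressWarnings(
    if (file) ape::read.tree(text) else ape::read.tree(text = text))
  if (is.null(phy)) stop("malformed Newick input", call. = FALSE)
  timetree_from_phylo(phy, origin_height)
}

#' Write a timetree as Newick
#'
#' @param tree A \code{timetree}.
#' @param path Optional output file; when NULL the Newick string is returned.
#' @param root_edge Include the origin branch as a root edge.
#' @return Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, path = NULL, root_edge = TRUE) {
  phy <- as.phylo.timetree(tree)
  if (!root_edge) phy$root.edge <- NULL
  txt <- ape::write.tree(phy)
  if (!is.null(path)) { writeLines(txt, path); return(invisible(txt)) }
  txt
}

#' Subdivide branches at the scarring-window boundaries
#'
#' Inserts a degree-2 node at time t1 and/or t2 on every branch that strictly
#' crosses that time point. Path lengths are unchanged and the operation is
#' idempotent. The likelihood is invariant to this subdivision
#' (Chapman-Kolmogorov); the subdivided view is what the pruning likelihood
#' sums over.
#'
#' @param tree A \code{timetree}.
#' @param t1,t2 Window boundaries within \code{[0, t_s]}.
#' @return A \code{timetree} possibly containing degree-2 nodes.
#' @export
subdivide_at_window <- function(tree, t1, t2) {
  stopifnot(t1 <= t2)
  parent <- tree$parent; time <- tree$time; label <- tree$label
  for (tc in unique(c(t1, t2))) {
    n <- length(parent)
    for (i in seq_len(n)) {
      p <- parent[i]
      if (is.na(p)) next
      if (time[p] < tc && time[i] > tc) {
        parent <- c(parent, p)          # new degree-2 node at time tc
        time <- c(time, tc)
        label <- c(label, NA_character_)
        parent[i] <- length(parent)
      }
    }
  }
  new_timetree(parent, time, label, tree$t_s)
}

#' Time of the most recent common ancestor of all sampled cells
#'
#' The MRCA is the first node below the origin with two children (the root of
#' the sampled tree proper). Its time, forward from the origin, classifies a
#' dataset's phylogenetic signal: an MRCA inside the scarring window lets
#' lineages acquire distinguishing edits, one after the window cannot.
#'
#' @param tree A \code{timetree}.
#' @return MRCA time (forward from origin at 0).
#' @export
mrca_time <- function(tree) {
  kids <- tree_children(tree)
  tips <- tree_tips(tree)
  node <- tree_origin(tree)
  while (length(kids[[node]]) == 1L) node <- kids[[node]][1L]
  tree$time[node]
}

#' Height and total length of the sampled tree
#'
#' \code{tree_height} is the age of the MRCA at sampling, \code{t_s -
#' mrca_time}; \code{tree_length} is the sum of all branch lengths of the
#' sampled tree (excluding the origin branch).
#'
#' @param tree A \code{timetree}.
#' @return A single number.
#' @rdname tree-summaries
#' @export
tree_height <- function(tree) tree$t_s - mrca_time(tree)

#' @rdname tree-summaries
#' @export
tree_length <- function(tree) {
  kids <- tree_children(tree)
  tips <- tree_tips(tree)
  node <- tree_origin(tree)
  while (length(kids[[node]]) == 1L) node <- kids[[node]][1L]
  mrca <- node
  total <- 0
  # sum branch lengths below the MRCA, merging degree-2 chains
  stack <- kids[[mrca]]
  anchor <- rep(tree$time[mrca], length(stack))
  while (length(stack)) {
    nd <- stack[[1]]; at <- anchor[[1]]
    stack <- stack[-1]; anchor <- anchor[-1]
    if (length(kids[[nd]]) == 1L) {     # degree-2: continue the same branch
      stack <- c(stack, kids[[nd]]); anchor <- c(anchor, at)
    } else {
      total <- total + tree$time[nd] - at
      if (length(kids[[nd]])) { stack <- c(stack, kids[[nd]]); anchor <- c(anchor, rep(tree$time[nd], length(kids[[nd]]))) }
    }
  }
  total
}

#' Clades (tip-label sets) of a timetree
#'
#' @param tree A \code{timetree}.
#' @param include_full Include the full tip set (the root clade).
#' @return A list of character vectors, each the sorted tip labels of one
#'   internal node's clade; singleton clades are excluded.
#' @export
tree_clades <- function(tree, include_full = TRUE) {
  kids <- tree_children(tree)
  tips <- tree_tips(tree)
  nn <- n_nodes(tree)
  below <- vector("list", nn)
  for (nd in order(tree$time, decreasing = TRUE)) {
    below[[nd]] <- if (nd %in% tips) tree$label[nd]
                   else sort(unlist(lapply(kids[[nd]], function(ch) below[[ch]])))
  }
  all_tips <- sort(tree$label[tips])
  out <- list()
  for (nd in seq_len(nn)) {
    if (length(kids[[nd]]) == 2L && length(below[[nd]]) >= 2L) {
      if (!include_full && length(below[[nd]]) == length(all_tips)) next
      out[[length(out) + 1L]] <- below[[nd]]
    }
  }
  unique(out)
}

#' Canonical topology key of a timetree
#'
#' A string identifying the unranked labelled tree shape, invariant to child
#' order and node times; used to key topologies in credible-set construction.
#'
#' @param tree A \code{timetree}.
#' @return A character scalar.
#' @export
topology_key <- function(tree) {
  kids <- tree_children(tree)
  tips <- tree_tips(tree)
  key <- character(n_nodes(tree))
  for (nd in order(tree$time, decreasing = TRUE)) {
    if (nd %in% tips) key[nd] <- tree$label[nd]
    else if (length(kids[[nd]]) == 1L) key[nd] <- key[kids[[nd]]]
    else key[nd] <- paste0("(", paste(sort(key[kids[[nd]]]), collapse = ","), ")")
  }
  key[tree_origin(tree)]
}
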