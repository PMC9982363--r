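# Tree data model and surgery. Trees are `ape::phylo` objects throughout:
# tips are numbered 1..n, internal nodes n+1..n+Nnode, and the anchor of an
# unrooted tree is stored as a trifurcating "root" node, as usual for ape.

#' Parse a Newick string into a validated phylogenetic tree
#'
#' Wraps [ape::read.tree()] with the validation every downstream module
#' relies on: unique, non-empty leaf labels; non-negative branch lengths
#' (absent lengths are filled with `default_branch_length`, with a warning);
#' and an explicit multifurcation policy. Internal-node labels (typically
#' support values) are preserved verbatim.
#'
#' A tree is considered rooted when its top-level node has exactly two
#' children; otherwise it is an unrooted tree stored with a trifurcating
#' anchor node.
#'
#' @param text Newick string (quoted labels and bootstrap-as-internal-label
#'   dialects are accepted).
#' @param multifurcations One of `"resolve"` (default; resolve
#'   multifurcations left-to-right with zero-length branches, keeping an
#'   unrooted tree's trifurcating anchor), `"reject"` (fail loudly), or
#'   `"keep"`.
#' @param default_branch_length Value used for absent branch lengths, or
#'   `NA` to forbid them.
#' @return An object of class `phylo`.
#' @export
#' @examples
#' tr <- parse_newick("((A:1,B:1):1,C:2);")
#' ape::is.rooted(tr)
parse_newick <- function(text, multifurcations = c("resolve", "reject", "keep"),
                         default_branch_length = 1) {
  multifurcations <- match.arg(multifurcations)
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e), call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unreadable tree string", call. = FALSE)
  tree$tip.label <- unquote_label(tree$tip.label)
  if (!is.null(tree$node.label)) tree$node.label <- unquote_label(tree$node.label)
  validate_tree(tree, default_branch_length = default_branch_length,
                multifurcations = multifurcations)
}

# Cheap syntax pre-check so malformed strings fail with a character offset.
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  in_quote <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (ch == "'") in_quote <- !in_quote
    if (in_quote) next
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L) {
        stop("Newick parse error at character ", i, ": unmatched ')'", call. = FALSE)
      }
    }
  }
  if (depth != 0L) {
    stop("Newick parse error at character ", length(chars),
         ": ", depth, " unclosed '('", call. = FALSE)
  }
  if (!grepl(";\\s*$", text)) {
    stop("Newick parse error at character ", nchar(text),
         ": missing terminal ';'", call. = FALSE)
  }
  invisible(TRUE)
}

validate_tree <- function(tree, default_branch_length = 1,
                          multifurcations = "resolve") {
  labs <- tree$tip.label
  if (any(is.na(labs) | labs == "")) {
    stop("leaf labels must be non-empty", call. = FALSE)
  }
  if (anyDuplicated(labs)) {
    stop("duplicate leaf labels: ",
         paste(unique(labs[duplicated(labs)]), collapse = ", "), call. = FALSE)
  }
  if (is.null(tree$edge.length)) {
    if (is.na(default_branch_length)) {
      stop("tree has no branch lengths and no default is allowed", call. = FALSE)
    }
    warning("tree has no branch lengths; using default ", default_branch_length,
            call. = FALSE)
    tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
  } else if (anyNA(tree$edge.length)) {
    if (is.na(default_branch_length)) {
      stop("tree has missing branch lengths and no default is allowed", call. = FALSE)
    }
    warning("missing branch lengths replaced by default ", default_branch_length,
            call. = FALSE)
    tree$edge.length[is.na(tree$edge.length)] <- default_branch_length
  }
  if (any(tree$edge.length < 0)) {
    stop("negative branch lengths are not allowed", call. = FALSE)
  }
  rooted <- ape::is.rooted(tree)
  max_deg <- if (rooted) 2L else 3L
  kids <- tabulate(tree$edge[, 1], nbins = ape::Ntip(tree) + tree$Nnode)
  root <- ape::Ntip(tree) + 1L
  internal_multi <- any(kids[-root] > 2L) || kids[root] > max_deg
  if (internal_multi) {
    if (multifurcations == "reject") {
      stop("tree contains multifurcations and policy is 'reject'", call. = FALSE)
    }
    if (multifurcations == "resolve") {
      was_rooted <- rooted
      tree <- ape::multi2di(tree, random = FALSE)
      if (!was_rooted) tree <- ape::unroot(tree)
    }
  }
  tree
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return The Newick string, invisibly when writing to file.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Leaf-to-leaf path distances
#'
#' @param tree A `phylo` object with branch lengths.
#' @return A symmetric matrix of patristic distances with zero diagonal,
#'   rows/columns named by leaf label.
#' @export
pairwise_distances <- function(tree) {
  if (is.null(tree$edge.length)) {
    stop("branch lengths are required for pairwise distances", call. = FALSE)
  }
  n <- ape::Ntip(tree)
  d <- ape::dist.nodes(tree)[seq_len(n), seq_len(n), drop = FALSE]
  dimnames(d) <- list(tree$tip.label, tree$tip.label)
  d
}

# Resolve a node given as tip label, internal label, or node id.
resolve_node <- function(tree, node) {
  if (is.character(node)) {
    hit <- match(node, tree$tip.label)
    if (is.na(hit) && !is.null(tree$node.label)) {
      h2 <- match(node, tree$node.label)
      if (!is.na(h2)) hit <- ape::Ntip(tree) + h2
    }
    if (is.na(hit)) stop("node '", node, "' not found in tree", call. = FALSE)
    return(as.integer(hit))
  }
  node <- as.integer(node)
  if (node < 1L || node > ape::Ntip(tree) + tree$Nnode) {
    stop("node id ", node, " out of range", call. = FALSE)
  }
  node
}

#' Reroot a tree at a position along a branch
#'
#' Places a new root on the edge above `child` (in the tree's stored
#' orientation), at `fraction` of the edge length measured from the child
#' end. Rerooting is isometric: no leaf-pair path length changes. A former
#' root left with a single child is spliced out, summing branch lengths.
#'
#' @param tree A `phylo` object, rooted or unrooted.
#' @param child Child endpoint of the target edge: a tip label, internal
#'   node label, or node id.
#' @param fraction Position of the new root on the edge, in `[0, 1]`,
#'   measured from the child end.
#' @return A rooted, binary `phylo` object.
#' @export
reroot_at <- function(tree, child, fraction = 0.5) {
  stopifnot(is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction <= 1)
  child <- resolve_node(tree, child)
  ei <- which(tree$edge[, 2] == child)
  if (length(ei) != 1L) {
    stop("no edge has node ", child, " as its child (is it the root?)", call. = FALSE)
  }
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  parent <- tree$edge[ei, 1]
  len <- tree$edge.length[ei]

  # undirected adjacency over all nodes, dropping the split edge
  adj <- vector("list", m)
  for (k in seq_len(nrow(tree$edge))) {
    if (k == ei) next
    a <- tree$edge[k, 1]; b <- tree$edge[k, 2]; w <- tree$edge.length[k]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  node_lab <- function(v) {
    if (v <= n) return(quote_label(tree$tip.label[v]))
    if (!is.null(tree$node.label)) {
      lab <- tree$node.label[v - n]
      if (!is.na(lab) && nzchar(lab)) return(quote_label(lab))
    }
    ""
  }
  fmt <- function(x) sprintf("%.15g", x)
  recurse <- function(v, from, len_in) {
    nbrs <- adj[[v]]
    kids <- if (is.null(nbrs)) integer(0) else nbrs[nbrs[, 1] != from, , drop = FALSE]
    if (v <= n) {
      return(paste0(node_lab(v), ":", fmt(len_in)))
    }
    if (nrow(kids) == 0L) {
      stop("internal node of degree 1 encountered during rerooting", call. = FALSE)
    }
    if (nrow(kids) == 1L) {  # spliced-out former root
      return(recurse(kids[1, 1], v, len_in + kids[1, 2]))
    }
    parts <- vapply(seq_len(nrow(kids)),
                    function(i) recurse(kids[i, 1], v, kids[i, 2]), character(1))
    paste0("(", paste(parts, collapse = ","), ")", node_lab(v), ":", fmt(len_in))
  }
  left <- recurse(child, parent, len * fraction)
  right <- recurse(parent, child, len * (1 - fraction))
  newick <- paste0("(", left, ",", right, ");")
  parse_newick(newick, multifurcations = "keep")
}

unquote_label <- function(labs) {
  quoted <- grepl("^'.*'$", labs)
  labs[quoted] <- gsub("''", "'", sub("^'(.*)'$", "\\1", labs[quoted]))
  labs
}

quote_label <- function(lab) {
  if (grepl("[ (),:;\\[\\]']", lab)) {
    paste0("'", gsub("'", "''", lab), "'")
  } else {
    lab
  }
}

#' Leaves on the child side of an edge
#'
#' @param tree A `phylo` object.
#' @param child Child endpoint of the edge (label or node id).
#' @return Sorted character vector of leaf labels below `child`.
#' @export
edge_bipartition <- function(tree, child) {
  child <- resolve_node(tree, child)
  n <- ape::Ntip(tree)
  if (child <= n) return(tree$tip.label[child])
  kids_of <- split(tree$edge[, 2], tree$edge[, 1])
  out <- integer(0)
  stack <- child
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    if (v <= n) out <- c(out, v) else stack <- c(stack, kids_of[[as.character(v)]])
  }
  sort(tree$tip.label[out])
}

# Canonical string key for an unrooted split of `leaves`: the side that
# contains the lexicographically smallest leaf label.
split_key <- function(side, leaves) {
  side <- sort(side)
  leaves <- sort(leaves)
  if (!(leaves[1] %in% side)) side <- setdiff(leaves, side)
  paste(side, collapse = "\r")
}

#' Do two branches describe the same leaf bipartition?
#'
#' Bipartitions from different trees are compared on the intersection of
#' their leaf sets; a split that becomes trivial (one side empty) on the
#' intersection matches nothing.
#'
#' @param side_a,side_b Character vectors: the leaves on one side of each
#'   bipartition.
#' @param leaves_a,leaves_b Full leaf sets of the respective trees.
#' @return Logical scalar.
#' @export
same_bipartition <- function(side_a, leaves_a, side_b, leaves_b) {
  common <- intersect(leaves_a, leaves_b)
  a1 <- intersect(side_a, common)
  b1 <- intersect(side_b, common)
  if (length(a1) == 0L || length(a1) == length(common)) return(FALSE)
  if (length(b1) == 0L || length(b1) == length(common)) return(FALSE)
  setequal(a1, b1) || setequal(a1, setdiff(common, b1))
}

#' Topology-and-length equality of two trees
#'
#' Two trees are equal when they carry the same leaf set and the same set
#' of leaf bipartitions (clades, for rooted trees), with per-bipartition
#' branch lengths agreeing within `tol`.
#'
#' @param a,b `phylo` objects.
#' @param tol Absolute-or-relative length tolerance.
#' @return Logical scalar.
#' @export
trees_equal <- function(a, b, tol = 1e-9) {
  if (!setequal(a$tip.label, b$tip.label)) return(FALSE)
  if (ape::is.rooted(a) != ape::is.rooted(b)) return(FALSE)
  ka <- edge_length_map(a)
  kb <- edge_length_map(b)
  if (!setequal(names(ka), names(kb))) return(FALSE)
  kb <- kb[names(ka)]
  all(abs(ka - kb) <= tol * pmax(1, abs(ka)))
}

# Map from bipartition key to branch length; clade keys for rooted trees,
# canonical split keys for unrooted ones.
edge_length_map <- function(tree) {
  leaves <- tree$tip.label
  rooted <- ape::is.rooted(tree)
  keys <- character(nrow(tree$edge))
  for (k in seq_len(nrow(tree$edge))) {
    side <- edge_bipartition(tree, tree$edge[k, 2])
    keys[k] <- if (rooted) paste(side, collapse = "\r") else split_key(side, leaves)
  }
  lens <- tree$edge.length
  if (anyDuplicated(keys)) {  # the two root edges of a rooted tree share a split
    lens <- vapply(split(lens, keys), sum, numeric(1))
    keys <- names(lens)
  }
  stats::setNames(lens, keys)
}

#' All rootings of an unrooted tree
#'
#' @param tree An unrooted `phylo` object (a rooted input is unrooted
#'   first). An n-leaf binary tree yields `2n - 3` rooted trees.
#' @param fraction Root position on each edge (default mid-edge).
#' @return Named list of rooted trees, one per edge; names are the child
#'   node ids of the corresponding edges in the unrooted tree.
#' @export
enumerate_rootings <- function(tree, fraction = 0.5) {
  if (ape::is.rooted(tree)) tree <- ape::unroot(tree)
  out <- lapply(seq_len(nrow(tree$edge)), function(k) {
    reroot_at(tree, tree$edge[k, 2], fraction)
  })
  names(out) <- tree$edge[, 2]
  attr(out, "unrooted") <- tree
  out
}

#' Read a gene-leaf to species-leaf map
#'
#' Two tab-separated columns, `gene_leaf<TAB>species_leaf`; lines starting
#' with `#` are ignored.
#'
#' @param path File path.
#' @return Named character vector mapping gene leaf labels to species
#'   leaf labels.
#' @export
read_leaf_map <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("gene", "species"))
  if (anyDuplicated(tab$gene)) {
    stop("duplicate gene leaves in map: ",
         paste(unique(tab$gene[duplicated(tab$gene)]), collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(tab$species, tab$gene)
}
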