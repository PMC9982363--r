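# Gene-tree rooting: outgroup, midpoint, minimal ancestor deviation (MAD),
# reconciliation-based, and a consensus rule across methods and subunits.
#
# A rooting candidate is a plain list describing a root position together
# with the method that proposed it and a method-specific score (lower is
# better). The branch is identified both by the child node of the edge and,
# for cross-tree comparison, by the leaf bipartition it induces.

new_rooting_candidate <- function(method, tree, child, fraction, score,
                                  subunit = NA_character_) {
  side <- edge_bipartition(tree, child)
  structure(list(
    method = method,
    subunit = subunit,
    child = child,
    fraction = fraction,
    score = score,
    side = side,
    leaves = sort(tree$tip.label)
  ), class = "rooting_candidate")
}

#' @export
print.rooting_candidate <- function(x, ...) {
  cat(sprintf("<rooting candidate> method=%s score=%.6g split={%s | %s}\n",
              x$method, x$score, paste(x$side, collapse = ","),
              paste(setdiff(x$leaves, x$side), collapse = ",")))
  invisible(x)
}

#' Root on the rooted tree implied by a candidate
#'
#' @param tree The tree the candidate was derived from.
#' @param candidate A rooting candidate.
#' @return A rooted `phylo`.
#' @export
apply_rooting <- function(tree, candidate) {
  reroot_at(unrooted_form(tree), candidate$child, candidate$fraction)
}

# The rooting methods operate on the unrooted topology; an existing root is
# discarded first so scores do not depend on the stored anchor.
unrooted_form <- function(tree) {
  if (ape::is.rooted(tree)) ape::unroot(tree) else tree
}

#' Outgroup rooting
#'
#' Places the root on the edge separating the outgroup clade from the rest
#' of the tree, at mid-edge. Errors if the outgroup is not monophyletic in
#' any rooting, listing the leaves that break monophyly.
#'
#' @param tree A `phylo` object (root, if any, is ignored).
#' @param outgroup Character vector of outgroup leaf labels (a strict,
#'   non-empty subset of the leaves).
#' @param subunit Optional subunit identifier carried into consensus.
#' @return A `rooting_candidate` (score 0: outgroup placement is
#'   definitional, not scored).
#' @export
outgroup_root <- function(tree, outgroup, subunit = NA_character_) {
  utree <- unrooted_form(tree)
  leaves <- utree$tip.label
  if (!all(outgroup %in% leaves)) {
    stop("outgroup leaves not in tree: ",
         paste(setdiff(outgroup, leaves), collapse = ", "), call. = FALSE)
  }
  if (length(outgroup) == 0L || setequal(outgroup, leaves)) {
    stop("outgroup must be a non-empty strict subset of the leaves", call. = FALSE)
  }
  best_mismatch <- NULL
  best_bad <- Inf
  for (k in seq_len(nrow(utree$edge))) {
    child <- utree$edge[k, 2]
    below <- edge_bipartition(utree, child)
    for (side in list(below, setdiff(leaves, below))) {
      bad <- union(setdiff(side, outgroup), setdiff(outgroup, side))
      if (length(bad) == 0L) {
        return(new_rooting_candidate("outgroup", utree, child, 0.5, 0, subunit))
      }
      if (length(bad) < best_bad) {
        best_bad <- length(bad)
        best_mismatch <- sort(bad)
      }
    }
  }
  stop("outgroup {", paste(sort(outgroup), collapse = ", "),
       "} is not monophyletic under any rooting; conflicting leaves: ",
       paste(best_mismatch, collapse = ", "), call. = FALSE)
}

#' Midpoint rooting
#'
#' Roots at the midpoint of the longest leaf-to-leaf path, so the two
#' largest root-to-leaf distances are equal. The score is the maximal
#' root-to-leaf distance (half the tree diameter). Ties among diameter
#' pairs are broken by lexicographic leaf-pair order.
#'
#' @inheritParams outgroup_root
#' @return A `rooting_candidate`.
#' @export
midpoint_root <- function(tree, subunit = NA_character_) {
  utree <- unrooted_form(tree)
  if (is.null(utree$edge.length)) stop("branch lengths required", call. = FALSE)
  d <- pairwise_distances(utree)
  diam <- max(d)
  if (diam <= 0) stop("zero-diameter tree cannot be midpoint rooted", call. = FALSE)
  labs <- rownames(d)
  ord <- order(labs)
  pairs <- which(d == diam, arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  key <- apply(pairs, 1, function(p) paste(sort(labs[p]), collapse = "\r"))
  p <- pairs[order(key)[1], ]
  i <- p[[1]]; j <- p[[2]]
  path <- ape::nodepath(utree, i, j)
  dn <- ape::dist.nodes(utree)
  target <- diam / 2
  cum <- 0
  for (k in seq_len(length(path) - 1L)) {
    a <- path[k]; b <- path[k + 1L]
    seg <- dn[a, b]
    if (cum + seg >= target - 1e-12) {
      pos <- target - cum  # distance from a along the edge
      ei <- which((utree$edge[, 1] == a & utree$edge[, 2] == b) |
                    (utree$edge[, 1] == b & utree$edge[, 2] == a))[1]
      child <- utree$edge[ei, 2]
      len <- utree$edge.length[ei]
      frac <- if (child == a) pos / len else (len - pos) / len
      frac <- min(max(frac, 0), 1)
      return(new_rooting_candidate("midpoint", utree, child, frac, diam / 2, subunit))
    }
    cum <- cum + seg
  }
  stop("internal error: midpoint not located on diameter path") # nocov
}

#' Minimal ancestor deviation (MAD) rooting
#'
#' For every branch, finds the root position minimizing the root-mean-square
#' relative ancestor deviation over all leaf pairs, where the deviation of
#' pair (i, j) with induced ancestor a is `|2 d(a,i)/d(i,j) - 1|`. The
#' per-branch optimum is closed form (the objective is quadratic in the
#' root position); candidates are returned sorted ascending by score, ties
#' broken by smallest lexicographic leaf bipartition.
#'
#' @inheritParams outgroup_root
#' @return A list of `rooting_candidate`s, best first.
#' @export
mad_root <- function(tree, subunit = NA_character_) {
  utree <- unrooted_form(tree)
  n <- ape::Ntip(utree)
  if (n < 3L) stop("MAD requires at least 3 leaves", call. = FALSE)
  if (is.null(utree$edge.length) || sum(utree$edge.length) <= 0) {
    stop("MAD requires positive total branch length", call. = FALSE)
  }
  dn <- ape::dist.nodes(utree)
  dl <- dn[seq_len(n), seq_len(n)]
  if (any(dl[upper.tri(dl)] <= 0)) {
    stop("MAD undefined: some leaf pair is at zero distance", call. = FALSE)
  }
  leaves <- utree$tip.label
  cands <- vector("list", nrow(utree$edge))
  for (k in seq_len(nrow(utree$edge))) {
    u <- utree$edge[k, 1]; v <- utree$edge[k, 2]
    len <- utree$edge.length[k]
    below <- match(edge_bipartition(utree, v), leaves)
    above <- setdiff(seq_len(n), below)
    # deviation of pair (i, j) given root r: |d(i,r) - d(j,r)| / d(i,j)
    same_sq <- 0
    for (side in list(below, above)) {
      if (length(side) >= 2L) {
        dr <- dn[side, v]
        dd <- outer(dr, dr, "-") / dl[side, side, drop = FALSE]
        same_sq <- same_sq + sum(dd[upper.tri(dd)]^2)
      }
    }
    div <- dl[below, above, drop = FALSE]
    x <- (outer(dn[below, v], dn[above, u], "-") - len) / div
    s <- (2 * len) / div
    sxs <- sum(x * s); sss <- sum(s * s)
    rho <- if (sss > 0) min(max(-sxs / sss, 0), 1) else 0.5
    cross_sq <- sum((x + s * rho)^2)
    npairs <- n * (n - 1) / 2
    score <- sqrt((same_sq + cross_sq) / npairs)
    cands[[k]] <- new_rooting_candidate("mad", utree, v, rho, score, subunit)
  }
  keys <- vapply(cands, function(cc) split_key(cc$side, leaves), character(1))
  scores <- vapply(cands, `[[`, numeric(1), "score")
  cands[order(scores, keys)]
}

#' Reconciliation-based rooting
#'
#' Scores every rooting of the gene tree by its minimum DTL reconciliation
#' cost against a rooted species tree (see [opt_root_dtl()]); all co-optimal
#' rootings are returned as candidates with the parsimony cost as score.
#'
#' @param tree Unrooted (or rooted; root ignored) gene tree.
#' @param species Rooted species tree.
#' @param map Named character vector, gene leaf -> species leaf.
#' @param costs A [dtl_costs()] object.
#' @param subunit Optional subunit identifier.
#' @param all_edges If `TRUE`, return a candidate for every edge rather
#'   than only the co-optimal ones.
#' @return A list of `rooting_candidate`s, best first.
#' @export
reconciliation_root <- function(tree, species, map, costs,
                                subunit = NA_character_, all_edges = FALSE) {
  res <- opt_root_dtl(tree, species, map, costs)
  utree <- res$unrooted
  rows <- if (all_edges) seq_len(nrow(res$table)) else which(res$table$optimal)
  cands <- lapply(rows, function(r) {
    new_rooting_candidate("reconciliation", utree, res$table$child[r], 0.5,
                          res$table$cost[r], subunit)
  })
  keys <- vapply(cands, function(cc) split_key(cc$side, utree$tip.label), character(1))
  scores <- vapply(cands, `[[`, numeric(1), "score")
  cands[order(scores, keys)]
}

#' Consensus rooting across methods and subunits
#'
#' Groups candidates by the leaf bipartition of their root branch
#' (bipartitions are compared on intersections of leaf sets, so subunit
#' trees with differing taxon sampling can vote on the same branch) and
#' picks the branch with the most supporting methods, then the most
#' supporting subunits. The decision is `accepted` only when at least two
#' methods and a strict majority of the subunits considered support it.
#' When an outgroup candidate exists its branch is reported first
#' (outgroup evidence is prioritized) irrespective of the vote.
#'
#' @param candidates List of `rooting_candidate`s (possibly nested lists,
#'   e.g. the full output of [mad_root()]; they are flattened).
#' @param subunits Character vector of all subunit identifiers considered;
#'   defaults to the subunits present among the candidates.
#' @return A list with elements `side` (leaf labels of the chosen branch),
#'   `methods`, `subunits` (supporters), `accepted`, `outgroup_side`
#'   (branch of the outgroup candidate, or `NULL`), and `table` (one row
#'   per branch with its support).
#' @export
consensus_root <- function(candidates, subunits = NULL) {
  if (inherits(candidates, "rooting_candidate")) candidates <- list(candidates)
  flat <- list()
  for (x in candidates) {
    if (inherits(x, "rooting_candidate")) flat[[length(flat) + 1L]] <- x
    else flat <- c(flat, Filter(function(y) inherits(y, "rooting_candidate"), x))
  }
  if (length(flat) == 0L) stop("no rooting candidates supplied", call. = FALSE)
  if (is.null(subunits)) {
    subunits <- unique(stats::na.omit(vapply(flat, `[[`, character(1), "subunit")))
    if (length(subunits) == 0L) subunits <- NA_character_
  }
  n_subunits <- max(length(subunits), 1L)

  # Group by canonical split key first (exact for identical leaf sets);
  # groups from trees with differing leaf sets are then merged by
  # restricted-bipartition comparison.
  keys <- vapply(flat, function(cc)
    paste0(split_key(cc$side, cc$leaves), "\n",
           paste(sort(cc$leaves), collapse = "\r")), character(1))
  groups <- lapply(split(flat, factor(keys, levels = unique(keys))),
                   function(members) list(rep = members[[1L]], members = members))
  names(groups) <- NULL
  leafsets <- vapply(groups, function(g) paste(sort(g$rep$leaves), collapse = "\r"),
                     character(1))
  if (length(unique(leafsets)) > 1L) {
    merged <- list()
    for (g in groups) {
      hit <- 0L
      for (mi in seq_along(merged)) {
        rep <- merged[[mi]]$rep
        if (same_bipartition(g$rep$side, g$rep$leaves, rep$side, rep$leaves)) {
          hit <- mi
          break
        }
      }
      if (hit > 0L) merged[[hit]]$members <- c(merged[[hit]]$members, g$members)
      else merged[[length(merged) + 1L]] <- g
    }
    groups <- merged
  }
  tab <- do.call(rbind, lapply(groups, function(g) {
    methods <- unique(vapply(g$members, `[[`, character(1), "method"))
    subs <- unique(stats::na.omit(vapply(g$members, `[[`, character(1), "subunit")))
    data.frame(
      split = paste(g$rep$side, collapse = ","),
      n_methods = length(methods),
      n_subunits = max(length(subs), if (anyNA(subunits)) 1L else 0L),
      methods = paste(sort(methods), collapse = "+"),
      key = split_key(g$rep$side, g$rep$leaves),
      stringsAsFactors = FALSE
    )
  }))
  ord <- order(-tab$n_methods, -tab$n_subunits, tab$key)
  tab <- tab[ord, , drop = FALSE]
  groups <- groups[ord]
  best <- groups[[1L]]
  methods <- sort(unique(vapply(best$members, `[[`, character(1), "method")))
  subs <- sort(unique(stats::na.omit(vapply(best$members, `[[`, character(1), "subunit"))))
  sub_support <- if (anyNA(subunits)) 1L else length(subs)
  accepted <- length(methods) >= 2L && sub_support > n_subunits / 2

  og <- Filter(function(x) x$method == "outgroup", flat)
  list(
    side = best$rep$side,
    methods = methods,
    subunits = subs,
    accepted = accepted,
    outgroup_side = if (length(og)) og[[1L]]$side else NULL,
    table = tab[, c("split", "n_methods", "n_subunits", "methods")]
  )
}
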