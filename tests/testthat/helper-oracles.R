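# Independent oracles and fixture builders used across the suite. Each
# oracle computes its quantity by a route disjoint from the implementation
# it checks (enumeration, graph algorithms, closed forms, or a third-party
# package).

# Random reconciliation instance: coalescent species tree, random gene
# tree, random (possibly many-to-one) leaf map.
rand_dtl_instance <- function(max_species = 6, max_gene = 6) {
  ns <- sample(3:max_species, 1)
  st <- ape::rcoal(ns, tip.label = paste0("S", seq_len(ns)))
  ng <- sample(3:max_gene, 1)
  gt <- ape::rtree(ng, tip.label = paste0("g", seq_len(ng)))
  map <- stats::setNames(sample(st$tip.label, ng, replace = TRUE), gt$tip.label)
  list(gene = gt, species = st, map = map)
}

# Classic LCA-mapping duplication-loss reconciliation (no transfers): maps
# every gene node to the LCA of its children's images; duplication when a
# child maps to the same node; losses counted along unmet species edges.
lca_duploss_cost <- function(gene, species, map, dup, loss) {
  sp <- methanotrace:::index_species(species)
  gi <- methanotrace:::index_gene(gene, map, sp)
  lca <- function(a, b) {
    while (a != b) {
      if (sp$depth[a] > sp$depth[b]) a <- sp$parent[a] else b <- sp$parent[b]
    }
    a
  }
  M <- integer(gi$ng)
  ndup <- 0L
  nloss <- 0L
  for (g in gi$postorder) {
    if (is.na(gi$children[g, 1])) {
      M[g] <- gi$leaf_species[g]
      next
    }
    c1 <- gi$children[g, 1]; c2 <- gi$children[g, 2]
    M[g] <- lca(M[c1], M[c2])
    isdup <- M[g] == M[c1] || M[g] == M[c2]
    ndup <- ndup + isdup
    for (c in c(c1, c2)) {
      nloss <- nloss + (sp$depth[M[c]] - sp$depth[M[g]]) - (!isdup)
    }
  }
  dup * ndup + loss * nloss
}

# Leaf distances by graph shortest paths (igraph), independent of ape's
# patristic distances.
graph_leaf_distances <- function(tree) {
  g <- igraph::graph_from_edgelist(apply(tree$edge, 2, as.character),
                                   directed = FALSE)
  igraph::E(g)$weight <- tree$edge.length
  d <- igraph::distances(g)
  tips <- as.character(seq_len(ape::Ntip(tree)))
  out <- d[tips, tips]
  dimnames(out) <- list(tree$tip.label, tree$tip.label)
  out
}

# MAD grid oracle: for every edge, scores `grid_n` root positions from
# the definitional deviation |2 d(a,i)/d(i,j) - 1|, with same-side
# ancestors found by rooting the tree on that edge and asking ape::mrca.
mad_grid_oracle <- function(utree, grid_n = 1000) {
  n <- ape::Ntip(utree)
  dn <- ape::dist.nodes(utree)
  dl <- dn[seq_len(n), seq_len(n)]
  labs <- utree$tip.label
  rho_grid <- seq(0, 1, length.out = grid_n)
  best <- list(score = Inf)
  for (k in seq_len(nrow(utree$edge))) {
    v <- utree$edge[k, 2]
    len <- utree$edge.length[k]
    rooted <- reroot_at(utree, v, 0.5)
    dr <- ape::dist.nodes(rooted)
    rn <- ape::Ntip(rooted) + 1L  # new root id
    mr <- ape::mrca(rooted)
    ri <- match(labs, rooted$tip.label)
    below <- match(edge_bipartition(utree, v), labs)
    side_of <- ifelse(seq_len(n) %in% below, 1L, -1L)
    fixed_sq <- 0
    cross <- NULL
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      a <- mr[ri[i], ri[j]]
      if (a != rn) {
        dev <- 2 * dr[a, ri[i]] / dl[i, j] - 1
        fixed_sq <- fixed_sq + dev^2
      } else {
        # d(root, i) at fraction rho = d at 0.5 + side * (rho - 0.5) * len
        cross <- rbind(cross, c(dr[rn, ri[i]], side_of[i], dl[i, j]))
      }
    }
    npairs <- n * (n - 1) / 2
    cs <- if (is.null(cross)) rep(0, length(rho_grid)) else {
      dev <- 2 * (outer(cross[, 1], rep(1, length(rho_grid))) +
                    cross[, 2] %o% ((rho_grid - 0.5) * len)) /
        cross[, 3] - 1
      colSums(dev^2)
    }
    sc <- sqrt((fixed_sq + cs) / npairs)
    k_best <- which.min(sc)
    if (sc[k_best] < best$score) {
      best <- list(score = sc[k_best], child = v, rho = rho_grid[k_best])
    }
  }
  best
}

# Exhaustive Fitch parsimony score: minimize implied changes over all
# assignments of internal-node states, per site.
fitch_brute_score <- function(alignment, tree) {
  states <- c("A", "C", "G", "U")
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  total <- 0L
  combos <- as.matrix(expand.grid(rep(list(states), tree$Nnode),
                                  stringsAsFactors = FALSE))
  for (site in seq_len(ncol(alignment))) {
    leaf <- alignment[tree$tip.label, site]
    leaf[leaf == "T"] <- "U"
    best <- Inf
    for (r in seq_len(nrow(combos))) {
      assign <- c(leaf, combos[r, ])
      changes <- 0L
      ok <- TRUE
      for (k in seq_len(nrow(tree$edge))) {
        p <- assign[tree$edge[k, 1]]; c <- assign[tree$edge[k, 2]]
        if (c %in% c("-", "N")) next  # missing leaf matches anything
        if (p != c) changes <- changes + 1L
      }
      if (ok && changes < best) best <- changes
    }
    total <- total + best
  }
  total
}

# Simple fixture trees reused across files
tree3 <- function() parse_newick("((A:1,B:1):1,C:2);")
tree4 <- function() parse_newick("((A:1,B:1):1,(C:1,D:1):1);")
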