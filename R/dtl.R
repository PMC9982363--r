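# Undated duplication-transfer-loss (DTL) parsimony reconciliation of a
# rooted binary gene tree against a rooted binary species tree.
#
# The dynamic program fills, for every gene node g and species node s, the
# minimum cost c(g, s) of reconciling the gene subtree at g with g mapped
# to s, together with the loss-chain quantity in(g, s) = min over species
# nodes t inside the subtree of s of c(g, t) + L * dist(s, t), and the
# transfer quantity out(g, s) = min over t incomparable to s of c(g, t).
# Transfers are allowed between any two incomparable species branches
# (undated model); the transferred child lands directly on its recipient,
# so no losses are charged on the recipient side.
#
# All cost arithmetic is carried out on an exact integer scale (costs are
# small rationals multiplied up by their common denominator), so "minimum"
# never depends on floating-point comparisons.

#' DTL event costs
#'
#' Speciation costs 0 by convention; duplication, transfer, and loss costs
#' are non-negative rationals.
#'
#' @param dup,transfer,loss Non-negative event costs.
#' @return A `dtl_costs` object.
#' @export
#' @examples
#' dtl_costs(dup = 2, transfer = 3, loss = 1)
dtl_costs <- function(dup = 2, transfer = 3, loss = 1) {
  stopifnot(dup >= 0, transfer >= 0, loss >= 0)
  rd <- as_rational(dup); rt <- as_rational(transfer); rl <- as_rational(loss)
  den <- lcm2(lcm2(rd[2], rt[2]), rl[2])
  structure(list(
    dup = dup, transfer = transfer, loss = loss,
    int = c(dup = rd[1] * den / rd[2],
            transfer = rt[1] * den / rt[2],
            loss = rl[1] * den / rl[2]),
    den = den
  ), class = "dtl_costs")
}

#' @export
print.dtl_costs <- function(x, ...) {
  cat(sprintf("<DTL costs> D=%g T=%g L=%g (speciation 0)\n",
              x$dup, x$transfer, x$loss))
  invisible(x)
}

DTL_INF <- 2^52  # sentinel on the integer cost scale

# Precomputed species-tree structure shared by the DP and the brute force.
index_species <- function(species) {
  if (!ape::is.rooted(species)) stop("species tree must be rooted", call. = FALSE)
  if (!ape::is.binary(species)) stop("species tree must be binary", call. = FALSE)
  n <- ape::Ntip(species)
  ns <- n + species$Nnode
  parent <- integer(ns); parent[] <- NA_integer_
  children <- matrix(NA_integer_, ns, 2)
  for (k in seq_len(nrow(species$edge))) {
    p <- species$edge[k, 1]; c <- species$edge[k, 2]
    parent[c] <- p
    children[p, if (is.na(children[p, 1])) 1 else 2] <- c
  }
  root <- n + 1L
  depth <- integer(ns)
  ord <- integer(0)  # preorder
  stack <- root
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    ord <- c(ord, v)
    if (!is.na(children[v, 1])) {
      depth[children[v, ]] <- depth[v] + 1L
      stack <- c(children[v, 1], children[v, 2], stack)
    }
  }
  postorder <- rev(ord)
  anc <- matrix(FALSE, ns, ns)  # anc[s, t]: s ancestor-or-equal of t
  for (t in seq_len(ns)) {
    v <- t
    repeat {
      anc[v, t] <- TRUE
      if (is.na(parent[v])) break
      v <- parent[v]
    }
  }
  incomp <- !anc & !t(anc)
  list(tree = species, n = n, ns = ns, root = root, parent = parent,
       children = children, depth = depth, postorder = postorder,
       anc = anc, incomp = incomp, tips = species$tip.label)
}

index_gene <- function(gene, map, sp) {
  if (!ape::is.rooted(gene)) stop("gene tree must be rooted", call. = FALSE)
  if (!ape::is.binary(gene)) stop("gene tree must be binary", call. = FALSE)
  n <- ape::Ntip(gene)
  ng <- n + gene$Nnode
  if (!all(gene$tip.label %in% names(map))) {
    stop("unmapped gene leaves: ",
         paste(setdiff(gene$tip.label, names(map)), collapse = ", "), call. = FALSE)
  }
  sp_of_leaf <- match(map[gene$tip.label], sp$tips)
  if (anyNA(sp_of_leaf)) {
    bad <- gene$tip.label[is.na(sp_of_leaf)]
    stop("gene leaves mapped to unknown species: ",
         paste(map[bad], collapse = ", "), call. = FALSE)
  }
  children <- matrix(NA_integer_, ng, 2)
  parent <- integer(ng); parent[] <- NA_integer_
  for (k in seq_len(nrow(gene$edge))) {
    p <- gene$edge[k, 1]; c <- gene$edge[k, 2]
    parent[c] <- p
    children[p, if (is.na(children[p, 1])) 1 else 2] <- c
  }
  root <- n + 1L
  ord <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    ord <- c(ord, v)
    if (!is.na(children[v, 1])) stack <- c(children[v, 1], children[v, 2], stack)
  }
  list(tree = gene, n = n, ng = ng, root = root, parent = parent,
       children = children, postorder = rev(ord), leaf_species = sp_of_leaf)
}

# Core DP. Returns the filled tables (integer cost scale).
dtl_dp <- function(gi, sp, costs) {
  D <- costs$int[["dup"]]; Tc <- costs$int[["transfer"]]; L <- costs$int[["loss"]]
  ns <- sp$ns
  cmat <- matrix(DTL_INF, gi$ng, ns)
  inn <- matrix(DTL_INF, gi$ng, ns)
  outn <- matrix(DTL_INF, gi$ng, ns)
  for (g in gi$postorder) {
    if (is.na(gi$children[g, 1])) {
      cmat[g, gi$leaf_species[g]] <- 0
    } else {
      g1 <- gi$children[g, 1]; g2 <- gi$children[g, 2]
      in1 <- inn[g1, ]; in2 <- inn[g2, ]
      out1 <- outn[g1, ]; out2 <- outn[g2, ]
      for (s in sp$postorder) {
        best <- DTL_INF
        k1 <- sp$children[s, 1]
        if (!is.na(k1)) {
          k2 <- sp$children[s, 2]
          best <- min(best, in1[k1] + in2[k2], in1[k2] + in2[k1])
        }
        best <- min(best, D + in1[s] + in2[s])
        tr <- Tc + min(in1[s] + out2[s], in2[s] + out1[s])
        cmat[g, s] <- min(best, tr, DTL_INF)
      }
    }
    crow <- cmat[g, ]
    irow <- crow
    for (s in sp$postorder) {
      k1 <- sp$children[s, 1]
      if (!is.na(k1)) {
        k2 <- sp$children[s, 2]
        irow[s] <- min(irow[s], irow[k1] + L, irow[k2] + L)
      }
    }
    inn[g, ] <- pmin(irow, DTL_INF)
    outn[g, ] <- vapply(seq_len(ns), function(s) {
      m <- crow[sp$incomp[s, ]]
      if (length(m)) min(m, DTL_INF) else DTL_INF
    }, numeric(1))
  }
  list(cmat = cmat, inn = inn, outn = outn, costs = costs, gi = gi, sp = sp,
       optimum = min(cmat[gi$root, ]))
}

# Nodes t in the subtree of s whose loss chain realizes in(g, s).
chain_argmins <- function(dp, g, s) {
  sp <- dp$sp
  L <- dp$costs$int[["loss"]]
  cand <- which(sp$anc[s, ])
  vals <- dp$cmat[g, cand] + L * (sp$depth[cand] - sp$depth[s])
  cand[vals == dp$inn[g, s]]
}

# Sample one minimum-cost event history, choosing uniformly among the
# optimal alternatives at each decision point.
dtl_sample <- function(dp, seed = 1L) {
  gi <- dp$gi; sp <- dp$sp
  D <- dp$costs$int[["dup"]]; Tc <- dp$costs$int[["transfer"]]
  events <- list()
  mapping <- integer(gi$ng); mapping[] <- NA_integer_
  n_loss <- 0L
  pick <- function(x) if (length(x) == 1L) x[[1L]] else x[[sample.int(length(x), 1L)]]

  descend <- function(g, s_from) {
    # choose the realized node of the loss chain starting at s_from
    t <- pick(chain_argmins(dp, g, s_from))
    n_loss <<- n_loss + (sp$depth[t] - sp$depth[s_from])
    resolve(g, t)
    t
  }
  resolve <- function(g, s) {
    mapping[g] <<- s
    if (is.na(gi$children[g, 1])) return(invisible(NULL))
    g1 <- gi$children[g, 1]; g2 <- gi$children[g, 2]
    cval <- dp$cmat[g, s]
    opts <- list()
    k1 <- sp$children[s, 1]
    if (!is.na(k1)) {
      k2 <- sp$children[s, 2]
      if (dp$inn[g1, k1] + dp$inn[g2, k2] == cval) {
        opts[[length(opts) + 1L]] <- list(type = "S", a = g1, sa = k1, b = g2, sb = k2)
      }
      if (dp$inn[g1, k2] + dp$inn[g2, k1] == cval) {
        opts[[length(opts) + 1L]] <- list(type = "S", a = g1, sa = k2, b = g2, sb = k1)
      }
    }
    if (D + dp$inn[g1, s] + dp$inn[g2, s] == cval) {
      opts[[length(opts) + 1L]] <- list(type = "D", a = g1, sa = s, b = g2, sb = s)
    }
    if (Tc + dp$inn[g1, s] + dp$outn[g2, s] == cval) {
      opts[[length(opts) + 1L]] <- list(type = "T", a = g1, sa = s, moved = g2)
    }
    if (Tc + dp$inn[g2, s] + dp$outn[g1, s] == cval) {
      opts[[length(opts) + 1L]] <- list(type = "T", a = g2, sa = s, moved = g1)
    }
    if (length(opts) == 0L) stop("internal error: no optimal event at node ", g) # nocov
    op <- pick(opts)
    if (op$type == "T") {
      kept_to <- descend(op$a, op$sa)
      recips <- which(sp$incomp[s, ] & dp$cmat[op$moved, ] == dp$outn[op$moved, s])
      r <- pick(as.list(recips))
      events[[length(events) + 1L]] <<- list(gene_node = g, event = "T",
                                             species = s, recipient = r)
      resolve(op$moved, r)
    } else {
      events[[length(events) + 1L]] <<- list(gene_node = g, event = op$type,
                                             species = s, recipient = NA_integer_)
      descend(op$a, op$sa)
      descend(op$b, op$sb)
    }
    invisible(NULL)
  }

  with_seed(seed, {
    roots <- which(dp$cmat[gi$root, ] == dp$optimum)
    s0 <- pick(as.list(roots))
    resolve(gi$root, s0)
  })
  ev <- if (length(events)) {
    data.frame(
      gene_node = vapply(events, `[[`, integer(1), "gene_node"),
      event = vapply(events, `[[`, character(1), "event"),
      species = vapply(events, `[[`, integer(1), "species"),
      recipient = vapply(events, `[[`, integer(1), "recipient")
    )
  } else {
    data.frame(gene_node = integer(0), event = character(0),
               species = integer(0), recipient = integer(0))
  }
  list(events = ev, mapping = mapping, n_loss = n_loss)
}

species_node_name <- function(sp, s) {
  if (s <= sp$n) return(sp$tips[s])
  below <- sort(sp$tips[which(sp$anc[s, seq_len(sp$n)])])
  paste0("lca(", below[1], ",", below[length(below)], ")")
}

#' Reconcile a rooted gene tree against a rooted species tree
#'
#' Computes a minimum-cost undated DTL reconciliation by dynamic
#' programming and samples one optimal event history uniformly at each
#' decision point among the co-optimal alternatives, using `seed`.
#'
#' @param gene Rooted binary gene tree (`phylo`).
#' @param species Rooted binary species tree (`phylo`).
#' @param map Named character vector mapping gene leaf labels to species
#'   leaf labels (many-to-one allowed).
#' @param costs A [dtl_costs()] object.
#' @param seed Integer seed for co-optimum sampling.
#' @return A `dtl_reconciliation`: list with `cost` (total parsimony
#'   cost), `counts` (named S/D/T/L event counts), `events` (one row per
#'   internal gene node: event, mapped species node, transfer recipient),
#'   `mapping` (species node per gene node), and the inputs.
#' @export
reconcile <- function(gene, species, map, costs = dtl_costs(), seed = 1L) {
  sp <- index_species(species)
  gi <- index_gene(gene, map, sp)
  dp <- dtl_dp(gi, sp, costs)
  if (dp$optimum >= DTL_INF) stop("no feasible reconciliation", call. = FALSE)
  samp <- dtl_sample(dp, seed)
  counts <- c(S = sum(samp$events$event == "S"),
              D = sum(samp$events$event == "D"),
              T = sum(samp$events$event == "T"),
              L = samp$n_loss)
  cost <- (costs$int[["dup"]] * counts[["D"]] +
             costs$int[["transfer"]] * counts[["T"]] +
             costs$int[["loss"]] * counts[["L"]]) / costs$den
  stopifnot(isTRUE(all.equal(cost, dp$optimum / costs$den)))
  ev <- samp$events
  ev$species_label <- vapply(ev$species, function(s) species_node_name(sp, s), character(1))
  ev$recipient_label <- ifelse(is.na(ev$recipient), NA_character_,
                               vapply(ev$recipient, function(s)
                                 if (is.na(s)) NA_character_ else species_node_name(sp, s),
                                 character(1)))
  structure(list(cost = cost, counts = counts, events = ev,
                 mapping = samp$mapping, gene = gene, species = species,
                 map = map, costs = costs, seed = seed),
            class = "dtl_reconciliation")
}

#' @export
print.dtl_reconciliation <- function(x, ...) {
  cat(sprintf("<DTL reconciliation> cost=%g | S=%d D=%d T=%d L=%d\n",
              x$cost, x$counts[["S"]], x$counts[["D"]], x$counts[["T"]],
              x$counts[["L"]]))
  invisible(x)
}

#' Exhaustive DTL reconciliation for small instances
#'
#' Enumerates every mapping of the internal gene nodes onto species nodes
#' and, for each, the cheapest event labelling; serves as an independent
#' oracle for [reconcile()]. Refuses instances above 8 gene or species
#' leaves.
#'
#' @inheritParams reconcile
#' @param max_leaves Size cap on either tree.
#' @return List with `cost` (exact optimum) and `n_optimal_mappings`.
#' @export
brute_force_reconcile <- function(gene, species, map, costs = dtl_costs(),
                                  max_leaves = 8L) {
  if (ape::Ntip(gene) > max_leaves || ape::Ntip(species) > max_leaves) {
    stop("instance too large for brute force (cap ", max_leaves, " leaves)",
         call. = FALSE)
  }
  sp <- index_species(species)
  gi <- index_gene(gene, map, sp)
  D <- costs$int[["dup"]]; Tc <- costs$int[["transfer"]]; L <- costs$int[["loss"]]
  ns <- sp$ns
  internals <- gi$postorder[!is.na(gi$children[gi$postorder, 1])]
  k <- length(internals)
  if (k == 0L) {  # single-leaf gene tree cannot occur (phylo needs >= 2 tips)
    return(list(cost = 0, n_optimal_mappings = 1L))
  }
  grid <- as.matrix(expand.grid(rep(list(seq_len(ns)), k)))
  nrows <- nrow(grid)
  total <- numeric(nrows)
  node_col <- stats::setNames(seq_len(k), internals)
  mapping_of <- function(node) {
    if (is.na(gi$children[node, 1])) rep(gi$leaf_species[node], nrows)
    else grid[, node_col[[as.character(node)]]]
  }
  aidx <- function(s, t) sp$anc[cbind(s, t)]
  for (g in internals) {
    s <- mapping_of(g)
    s1 <- mapping_of(gi$children[g, 1])
    s2 <- mapping_of(gi$children[g, 2])
    best <- rep(DTL_INF, nrows)
    cl <- sp$children[s, 1]; cr <- sp$children[s, 2]
    int_s <- !is.na(cl)
    for (orient in 1:2) {
      a <- if (orient == 1) s1 else s2
      b <- if (orient == 1) s2 else s1
      ok <- int_s & aidx(ifelse(int_s, cl, 1L), a) & aidx(ifelse(int_s, cr, 1L), b)
      cost <- L * ((sp$depth[a] - sp$depth[ifelse(int_s, cl, 1L)]) +
                     (sp$depth[b] - sp$depth[ifelse(int_s, cr, 1L)]))
      best <- ifelse(ok, pmin(best, cost), best)
    }
    ok <- aidx(s, s1) & aidx(s, s2)
    cost <- D + L * ((sp$depth[s1] - sp$depth[s]) + (sp$depth[s2] - sp$depth[s]))
    best <- ifelse(ok, pmin(best, cost), best)
    for (orient in 1:2) {
      moved <- if (orient == 1) s1 else s2
      kept <- if (orient == 1) s2 else s1
      ok <- sp$incomp[cbind(s, moved)] & aidx(s, kept)
      cost <- Tc + L * (sp$depth[kept] - sp$depth[s])
      best <- ifelse(ok, pmin(best, cost), best)
    }
    total <- total + best
    total[total > DTL_INF] <- DTL_INF
  }
  opt <- min(total)
  if (opt >= DTL_INF) stop("no feasible reconciliation", call. = FALSE)
  list(cost = opt / costs$den, n_optimal_mappings = sum(total == opt))
}

#' Optimal rootings of an unrooted gene tree under DTL parsimony
#'
#' Reconciles every rooting of the gene tree (one per edge, `2n - 3` for a
#' binary tree) and returns the full cost table plus the set of rootings
#' attaining the minimum.
#'
#' @param gene Unrooted gene tree (a rooted input is unrooted first).
#' @inheritParams reconcile
#' @return List with `unrooted` (the anchored unrooted tree whose edge
#'   child ids index the table), `table` (child, cost, optimal flag),
#'   `min_cost`, and `optimal_splits` (list of leaf-label vectors, one per
#'   co-optimal root branch).
#' @export
opt_root_dtl <- function(gene, species, map, costs = dtl_costs()) {
  utree <- unrooted_form(gene)
  sp <- index_species(species)
  kids <- utree$edge[, 2]
  cost <- vapply(kids, function(child) {
    rt <- reroot_at(utree, child, 0.5)
    gi <- index_gene(rt, map, sp)
    dtl_dp(gi, sp, costs)$optimum
  }, numeric(1)) / costs$den
  tab <- data.frame(child = kids, cost = cost, optimal = cost == min(cost))
  splits <- lapply(kids[tab$optimal], function(child) edge_bipartition(utree, child))
  list(unrooted = utree, table = tab, min_cost = min(cost),
       optimal_splits = splits)
}

#' Smallest transfer cost recovering a target rooting
#'
#' Sweeps an ascending grid of transfer costs and reports the smallest one
#' for which the target root branch (given as a leaf bipartition) is among
#' the co-optimal rootings found by [opt_root_dtl()]; mirrors the
#' transfer-cost calibration step of the reconciliation protocol.
#'
#' @inheritParams opt_root_dtl
#' @param target_side Leaf labels on one side of the target root branch.
#' @param t_grid Ascending positive transfer costs to try.
#' @param loss Loss cost (fixed).
#' @param dup Duplication cost, either a number or a function of the
#'   transfer cost; defaults to `T/2`, the midpoint of the `{T/4, T/2,
#'   3T/4}` sweep used downstream.
#' @return List with `transfer_cost` (the smallest recovering value, or
#'   `NA` if none), and `per_t` (a logical vector over the grid).
#' @export
optimize_transfer_cost <- function(gene, species, map, target_side,
                                   t_grid, loss = 1, dup = NULL) {
  if (length(t_grid) == 0L) stop("empty transfer-cost grid", call. = FALSE)
  if (is.unsorted(t_grid, strictly = TRUE) || any(t_grid <= 0)) {
    stop("t_grid must be strictly ascending and positive", call. = FALSE)
  }
  dup_of <- if (is.function(dup)) dup else if (is.null(dup)) function(t) t / 2 else function(t) dup
  utree <- unrooted_form(gene)
  leaves <- utree$tip.label
  hit <- vapply(t_grid, function(tc) {
    res <- opt_root_dtl(utree, species, map,
                        dtl_costs(dup = dup_of(tc), transfer = tc, loss = loss))
    any(vapply(res$optimal_splits, function(sd)
      same_bipartition(sd, leaves, target_side, leaves), logical(1)))
  }, logical(1))
  list(transfer_cost = if (any(hit)) t_grid[which(hit)[1]] else NA_real_,
       per_t = stats::setNames(hit, t_grid))
}

#' Event supports from repeated reconciliations over a duplication-cost sweep
#'
#' Runs the reconciliation `n_runs` times with duplication costs drawn from
#' `{T/4, T/2, 3T/4}` (runs split as evenly as possible, remainder assigned
#' to the smallest value) and seeded co-optimum sampling, then reports, for
#' every internal gene node, the fraction of runs assigning each event
#' (transfers keyed by recipient).
#'
#' @inheritParams reconcile
#' @param transfer_cost Transfer cost `T`.
#' @param loss_cost Loss cost `L`.
#' @param n_runs Number of runs (>= 1).
#' @return An `event_support` object: data frame with columns `gene_node`,
#'   `event` (`"S"`, `"D"`, or `"T->recipient"`), `support` in `[0, 1]`;
#'   supports per node sum to 1 over exactly `n_runs` runs.
#' @export
aggregate_reconciliations <- function(gene, species, map, transfer_cost,
                                      loss_cost = 1, n_runs = 100L, seed = 1L) {
  stopifnot(n_runs >= 1L)
  d_values <- transfer_cost * c(0.25, 0.5, 0.75)
  base <- n_runs %/% 3L
  runs_per_d <- c(base + n_runs %% 3L, base, base)
  sp <- index_species(species)
  gi <- index_gene(gene, map, sp)
  tallies <- list()
  run <- 0L
  for (di in seq_along(d_values)) {
    if (runs_per_d[di] == 0L) next
    dp <- dtl_dp(gi, sp, dtl_costs(dup = d_values[di], transfer = transfer_cost,
                                   loss = loss_cost))
    for (r in seq_len(runs_per_d[di])) {
      run <- run + 1L
      samp <- dtl_sample(dp, child_seed(seed, run))
      ev <- samp$events
      key <- ev$event
      tr <- which(ev$event == "T")
      if (length(tr)) {
        key[tr] <- paste0("T->", vapply(ev$recipient[tr], function(s)
          species_node_name(sp, s), character(1)))
      }
      for (i in seq_len(nrow(ev))) {
        id <- paste0(ev$gene_node[i], "\r", key[i])
        tallies[[id]] <- (tallies[[id]] %||% 0L) + 1L
      }
    }
  }
  parts <- strsplit(names(tallies), "\r", fixed = TRUE)
  out <- data.frame(
    gene_node = as.integer(vapply(parts, `[[`, character(1), 1)),
    event = vapply(parts, `[[`, character(1), 2),
    support = unlist(tallies, use.names = FALSE) / n_runs
  )
  out <- out[order(out$gene_node, -out$support, out$event), ]
  rownames(out) <- NULL
  structure(out, class = c("event_support", "data.frame"),
            n_runs = n_runs, transfer_cost = transfer_cost,
            d_values = d_values, runs_per_d = runs_per_d)
}
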