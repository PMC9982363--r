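# Seeded synthetic-data generators. Every generator is a pure function of
# its seed (the caller's RNG state is saved and restored), and every
# artifact satisfies the input contracts of the module that consumes it.

#' Simulate an ultrametric birth-death species tree
#'
#' Forward (Gillespie) birth-death simulation from a single lineage,
#' conditioned on reaching exactly `n_leaves` extant lineages; the tree is
#' cut at a uniformly drawn time between reaching `n_leaves` and the next
#' event, extinct lineages are pruned, and extant leaves are labelled
#' `s1..sn` in tree order.
#'
#' @param n_leaves Number of extant leaves (>= 3).
#' @param birth,death Per-lineage birth and death rates (birth > death >= 0).
#' @param seed Integer seed.
#' @param max_tries Resimulation cap when all lineages die out.
#' @return A rooted, ultrametric `phylo` with `n_leaves` tips.
#' @export
sim_species_tree <- function(n_leaves, birth = 1, death = 0, seed = 1L,
                             max_tries = 100L) {
  stopifnot(n_leaves >= 3L, birth > 0, death >= 0, birth > death)
  with_seed(child_seed(seed, 1L), {
    for (try in seq_len(max_tries)) {
      tree <- try_birth_death(n_leaves, birth, death)
      if (!is.null(tree)) return(tree)
    }
    stop("species-tree simulation failed ", max_tries,
         " times (all lineages died out)", call. = FALSE)
  })
}

try_birth_death <- function(n_leaves, birth, death) {
  # each lineage: id, parent id, birth time; node ids are creation order
  parent <- c(NA_integer_)
  btime <- c(0)
  alive <- c(1L)
  t <- 0
  while (length(alive) < n_leaves) {
    k <- length(alive)
    if (k == 0L) return(NULL)
    t <- t + stats::rexp(1, k * (birth + death))
    who <- alive[sample.int(k, 1L)]
    if (stats::runif(1) < birth / (birth + death)) {
      id1 <- length(parent) + 1L; id2 <- id1 + 1L
      parent <- c(parent, who, who)
      btime <- c(btime, t, t)
      alive <- c(setdiff(alive, who), id1, id2)
    } else {
      alive <- setdiff(alive, who)
    }
  }
  stop_t <- t + stats::runif(1) * stats::rexp(1, length(alive) * (birth + death))
  # assemble Newick over surviving lineages only
  children_of <- split(seq_along(parent), factor(parent, levels = seq_along(parent)))
  survives <- logical(length(parent))
  survives[alive] <- TRUE
  for (v in rev(seq_along(parent))) {
    if (survives[v] && !is.na(parent[v])) survives[parent[v]] <- TRUE
  }
  build <- function(v, t0) {
    kids <- Filter(function(x) survives[x], children_of[[v]])
    if (length(kids) == 0L) {
      return(sprintf("L%d:%.12g", v, stop_t - t0))
    }
    if (length(kids) == 1L) {  # splice through extinct sister
      return(build(kids[[1]], t0))
    }
    t1 <- btime[kids[[1]]]
    sprintf("(%s,%s):%.12g", build(kids[[1]], t1), build(kids[[2]], t1), t1 - t0)
  }
  if (!survives[1L]) return(NULL)
  root_kids <- Filter(function(x) survives[x], children_of[[1L]])
  nw <- if (length(root_kids) < 2L) {
    return(NULL)  # degenerate: no branching survived
  } else {
    t1 <- btime[root_kids[[1]]]
    paste0("(", build(root_kids[[1]], t1), ",", build(root_kids[[2]], t1), ");")
  }
  tree <- ape::read.tree(text = nw)
  if (is.null(tree) || ape::Ntip(tree) != n_leaves) return(NULL)
  tree$tip.label <- paste0("s", seq_len(n_leaves))
  tree
}

#' Simulate a gene tree along a species tree with logged D/T/L events
#'
#' Grows a gene family top-down along an ultrametric rooted species tree.
#' Each gene copy entering a species branch experiences at most one event
#' on that branch: loss (probability `loss`), duplication (`dup`), or
#' transfer (`transfer`), at a uniform position; duplication daughters
#' continue to the branch end, a transferred copy restarts on a recipient
#' branch drawn uniformly among time-overlapping (contemporaneous, hence
#' incomparable) branches. The complete event log is returned and
#' [replay_event_log()] rebuilds the identical tree from it.
#'
#' @param species Rooted ultrametric `phylo`.
#' @param dup,transfer,loss Per-branch event probabilities in `[0, 1)`
#'   summing to < 1.
#' @param seed Integer seed.
#' @param max_tries Resimulation cap when fewer than 2 gene copies survive.
#' @return List with `gene` (rooted `phylo`), `map` (named character,
#'   gene leaf -> species leaf), `log` (data frame of true events), and
#'   `species`.
#' @export
sim_gene_tree_dtl <- function(species, dup = 0, transfer = 0, loss = 0,
                              seed = 1L, max_tries = 50L) {
  stopifnot(dup >= 0, transfer >= 0, loss >= 0, dup + transfer + loss < 1)
  with_seed(child_seed(seed, 2L), {
    for (try in seq_len(max_tries)) {
      log <- draw_event_log(species, dup, transfer, loss)
      out <- try(replay_event_log(species, log), silent = TRUE)
      if (!inherits(out, "try-error")) {
        out$log <- log
        out$species <- species
        return(out)
      }
    }
    stop("gene-tree simulation failed ", max_tries,
         " times (family went extinct)", call. = FALSE)
  })
}

# Branch time spans of an ultrametric rooted tree, keyed by child node.
branch_spans <- function(species) {
  n <- ape::Ntip(species)
  depths <- ape::node.depth.edgelength(species)
  data.frame(child = species$edge[, 2],
             start = depths[species$edge[, 1]],
             end = depths[species$edge[, 2]])
}

draw_event_log <- function(species, dup, transfer, loss) {
  spans <- branch_spans(species)
  root <- ape::Ntip(species) + 1L
  kids_of <- split(species$edge[, 2], species$edge[, 1])
  log <- list()
  walk <- function(lineage, child, t_in) {
    # one event draw for this copy on this branch
    row <- spans[spans$child == child, ]
    u <- stats::runif(1)
    t_ev <- stats::runif(1, max(t_in, row$start), row$end)
    if (u < loss) {
      log[[length(log) + 1L]] <<- list(lineage = lineage, branch = child,
                                       event = "L", time = t_ev, recipient = NA)
      return(invisible(NULL))
    } else if (u < loss + dup) {
      log[[length(log) + 1L]] <<- list(lineage = lineage, branch = child,
                                       event = "D", time = t_ev, recipient = NA)
      continue_to_end(paste0(lineage, ".d1"), child)
      continue_to_end(paste0(lineage, ".d2"), child)
      return(invisible(NULL))
    } else if (u < loss + dup + transfer) {
      recips <- spans$child[spans$start < t_ev & spans$end > t_ev &
                              spans$child != child]
      if (length(recips)) {
        r <- recips[sample.int(length(recips), 1L)]
        log[[length(log) + 1L]] <<- list(lineage = lineage, branch = child,
                                         event = "T", time = t_ev, recipient = r)
        continue_to_end(paste0(lineage, ".x"), r)  # moved copy, no more events here
        continue_to_end(lineage, child)            # donor copy continues
        return(invisible(NULL))
      }
      # no contemporaneous recipient: fall through to no event
    }
    continue_to_end(lineage, child)
  }
  continue_to_end <- function(lineage, child) {
    kk <- kids_of[[as.character(child)]]
    if (is.null(kk)) return(invisible(NULL))  # reaches a species leaf
    for (k in kk) walk(lineage, k, spans$start[spans$child == k])
  }
  for (k in kids_of[[as.character(root)]]) {
    walk("1", k, 0)
  }
  if (length(log) == 0L) {
    return(data.frame(lineage = character(0), branch = integer(0),
                      event = character(0), time = numeric(0),
                      recipient = integer(0)))
  }
  data.frame(lineage = vapply(log, `[[`, character(1), "lineage"),
             branch = vapply(log, function(x) as.integer(x$branch), integer(1)),
             event = vapply(log, `[[`, character(1), "event"),
             time = vapply(log, `[[`, numeric(1), "time"),
             recipient = vapply(log, function(x) as.integer(x$recipient %||% NA),
                                integer(1)))
}

#' Rebuild the gene tree implied by an event log
#'
#' Deterministically replays a log of duplication/transfer/loss events
#' (as emitted by [sim_gene_tree_dtl()]) from a single copy at the
#' species root, reproducing the emitted gene tree exactly.
#'
#' @param species The species tree the log refers to.
#' @param log Event-log data frame (`lineage`, `branch`, `event`, `time`,
#'   `recipient`).
#' @return List with `gene` and `map` as in [sim_gene_tree_dtl()].
#' @export
replay_event_log <- function(species, log) {
  spans <- branch_spans(species)
  n <- ape::Ntip(species)
  root <- n + 1L
  kids_of <- split(species$edge[, 2], species$edge[, 1])
  leaf_count <- new.env()
  leaves <- list()

  grow <- function(lineage, child, t_in, events_allowed) {
    # returns node = list(time, children) | list(time, leaf_label) | NULL (lost)
    row <- spans[spans$child == child, ]
    ev <- log[log$lineage == lineage & log$branch == child, , drop = FALSE]
    ev <- ev[ev$time > t_in, , drop = FALSE]
    if (events_allowed && nrow(ev)) {
      e <- ev[which.min(ev$time), ]
      if (e$event == "L") return(NULL)
      if (e$event == "D") {
        a <- grow(paste0(lineage, ".d1"), child, e$time, FALSE)
        b <- grow(paste0(lineage, ".d2"), child, e$time, FALSE)
        return(join(e$time, a, b))
      }
      if (e$event == "T") {
        moved <- grow(paste0(lineage, ".x"), e$recipient, e$time, FALSE)
        kept <- grow(lineage, child, e$time, FALSE)
        return(join(e$time, kept, moved))
      }
    }
    at_end(lineage, child, row$end)
  }
  at_end <- function(lineage, child, t_end) {
    kk <- kids_of[[as.character(child)]]
    if (is.null(kk)) {
      sp_label <- species$tip.label[child]
      cnt <- (get0(sp_label, envir = leaf_count) %||% 0L) + 1L
      assign(sp_label, cnt, envir = leaf_count)
      lab <- paste0(sp_label, "_", cnt)
      leaves[[lab]] <<- sp_label
      return(list(time = t_end, leaf = lab))
    }
    a <- grow(lineage, kk[1], spans$start[spans$child == kk[1]], TRUE)
    b <- grow(lineage, kk[2], spans$start[spans$child == kk[2]], TRUE)
    join(t_end, a, b)
  }
  join <- function(time, a, b) {
    if (is.null(a) && is.null(b)) return(NULL)
    if (is.null(a)) return(b)
    if (is.null(b)) return(a)
    list(time = time, children = list(a, b))
  }

  rk <- kids_of[[as.character(root)]]
  top <- join(0, grow("1", rk[1], 0, TRUE), grow("1", rk[2], 0, TRUE))
  if (is.null(top) || !is.null(top$leaf)) {
    stop("fewer than two gene copies survived", call. = FALSE)
  }
  to_newick <- function(node, t_parent) {
    if (!is.null(node$leaf)) {
      return(sprintf("%s:%.12g", node$leaf, node$time - t_parent))
    }
    sprintf("(%s,%s):%.12g",
            to_newick(node$children[[1]], node$time),
            to_newick(node$children[[2]], node$time),
            node$time - t_parent)
  }
  nw <- paste0("(", to_newick(top$children[[1]], top$time), ",",
               to_newick(top$children[[2]], top$time), ");")
  gene <- ape::read.tree(text = nw)
  map <- unlist(leaves)
  list(gene = gene, map = map[gene$tip.label])
}

#' Simulate trait-linked RNA alignments
#'
#' A continuous trait (e.g. growth temperature) evolves by Brownian motion
#' along the tree; each node's target uracil fraction is a linear function
#' of its trait, clipped to `clip`; leaf sequences are drawn
#' site-independently with that uracil probability (A/C/G uniform
#' otherwise).
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param sites Number of alignment columns (>= 1).
#' @param sigma Brownian standard deviation per unit branch length (> 0
#'   unless 0 for a constant trait).
#' @param root_trait Trait value at the root.
#' @param slope,intercept Linear map from trait to uracil fraction.
#' @param clip Two-element clipping interval for the target fraction.
#' @param seed Integer seed.
#' @return List with `alignment` (leaf character matrix), `traits` (data
#'   frame per node: trait, target uracil fraction, clipped flag), and
#'   `n_clipped`.
#' @export
sim_sequences_with_trait <- function(tree, sites, sigma, root_trait,
                                     slope, intercept, clip = c(0.05, 0.95),
                                     seed = 1L) {
  stopifnot(sites >= 1L, sigma >= 0, clip[1] > 0, clip[2] < 1, clip[1] < clip[2])
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  with_seed(child_seed(seed, 3L), {
    trait <- numeric(m)
    trait[n + 1L] <- root_trait
    pre <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    for (k in seq_len(nrow(pre$edge))) {
      p <- pre$edge[k, 1]; c <- pre$edge[k, 2]
      trait[c] <- trait[p] + stats::rnorm(1, 0, sigma * sqrt(pre$edge.length[k]))
    }
    raw <- slope * trait + intercept
    target <- pmin(pmax(raw, clip[1]), clip[2])
    clipped <- raw != target
    aln <- matrix(NA_character_, n, sites)
    rownames(aln) <- tree$tip.label
    for (i in seq_len(n)) {
      is_u <- stats::runif(sites) < target[i]
      aln[i, ] <- ifelse(is_u, "U", sample(c("A", "C", "G"), sites, replace = TRUE))
    }
    traits <- data.frame(node = seq_len(m),
                         label = c(tree$tip.label, rep(NA, tree$Nnode)),
                         trait = trait, target_fraction = target,
                         clipped = clipped)
    list(alignment = aln, traits = traits, n_clipped = sum(clipped))
  })
}

#' Simulate genome gene content under per-gene dropout
#'
#' Each genome carries each required gene family (including members of
#' isoenzyme alternative groups) independently with probability
#' `1 - dropout`. Ground-truth capability flags are computed from the
#' realized gene sets with the scoring rule itself, so they are
#' self-consistent by construction.
#'
#' @param catalogue A `pathway_catalogue`.
#' @param n_genomes Number of genomes.
#' @param dropout Per-gene loss probability in `[0, 1)`.
#' @param seed Integer seed.
#' @return List with `content` (named list of family vectors) and `truth`
#'   (the `capacity_profile` of the realized content).
#' @export
sim_genome_content <- function(catalogue, n_genomes, dropout = 0.1, seed = 1L) {
  stopifnot(dropout >= 0, dropout < 1, n_genomes >= 1L)
  if (length(catalogue) == 0L) stop("empty pathway catalogue", call. = FALSE)
  families <- unique(unlist(lapply(catalogue, function(p) unlist(p$genes))))
  with_seed(child_seed(seed, 4L), {
    content <- lapply(seq_len(n_genomes), function(i) {
      families[stats::runif(length(families)) >= dropout]
    })
    names(content) <- sprintf("genome%03d", seq_len(n_genomes))
    list(content = content, truth = score_genomes(content, catalogue))
  })
}
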