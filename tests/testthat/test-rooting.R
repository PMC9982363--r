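test_that("outgroup rooting separates the outgroup clade at mid-edge", {
  utree <- ape::unroot(tree4())
  cand <- outgroup_root(utree, c("C", "D"))
  expect_setequal(cand$side, c("C", "D"))
  rooted <- apply_rooting(utree, cand)
  expect_true(ape::is.monophyletic(rooted, c("C", "D")))
  expect_true(ape::is.monophyletic(rooted, c("A", "B")))

  expect_error(outgroup_root(utree, c("A", "B", "C", "D")), "strict subset")
  # the error names the minimal set of conflicting leaves
  expect_error(outgroup_root(utree, c("A", "C")),
               "not monophyletic.*conflicting leaves: [AC]")
})

test_that("a planted outgroup is recovered on simulated trees", {
  for (s in 1:50) {
    st <- sim_species_tree(sample(4:8, 1), seed = 100 + s)
    # plant an outgroup clade as sister to everything
    inner <- sub(";$", "", write_newick(st))
    depth <- max(pairwise_distances(st)) / 2
    planted <- parse_newick(sprintf("(%s:%g,(og1:%g,og2:%g):%g);", inner,
                                    depth, depth * 0.5, depth * 0.5, depth))
    cand <- outgroup_root(planted, c("og1", "og2"))
    expect_setequal(cand$side, c("og1", "og2"))
  }
})

test_that("midpoint rooting equalizes the two deepest root-to-leaf paths", {
  cand <- midpoint_root(tree3())
  rooted <- apply_rooting(tree3(), cand)
  n <- ape::Ntip(rooted)
  depths <- ape::node.depth.edgelength(rooted)[seq_len(n)]
  expect_equal(cand$score, 2)
  expect_equal(sort(depths, decreasing = TRUE)[1:2], c(2, 2))

  # ultrametric tree: midpoint recovers the original root split
  st <- sim_species_tree(8, seed = 5)
  cand <- midpoint_root(st)
  root_split <- edge_bipartition(st, st$edge[1, 2])
  expect_true(same_bipartition(cand$side, st$tip.label, root_split, st$tip.label))

  tiny <- parse_newick("(A:0,B:0,C:0);", multifurcations = "keep")
  expect_error(midpoint_root(tiny), "zero-diameter")
})

test_that("midpoint agrees with exhaustive (edge x fraction) search", {
  set.seed(11)
  for (i in 1:5) {
    utree <- ape::unroot(ape::rtree(7))
    cand <- midpoint_root(utree)
    best <- Inf
    for (k in seq_len(nrow(utree$edge))) {
      for (f in seq(0, 1, by = 0.02)) {
        r <- reroot_at(utree, utree$edge[k, 2], f)
        best <- min(best, max(ape::node.depth.edgelength(r)[seq_len(ape::Ntip(r))]))
      }
    }
    expect_lt(cand$score, best + 1e-9)
  }
})

test_that("MAD scores a clock-like tree at zero on the true root branch", {
  for (s in 1:5) {
    st <- sim_species_tree(7, seed = 200 + s)
    cands <- mad_root(st)
    expect_equal(cands[[1]]$score, 0, tolerance = 1e-9)
    root_split <- edge_bipartition(st, st$edge[1, 2])
    expect_true(same_bipartition(cands[[1]]$side, st$tip.label,
                                 root_split, st$tip.label))
  }
})

test_that("MAD head candidate matches the definitional grid oracle", {
  set.seed(21)
  for (i in 1:6) {
    utree <- ape::unroot(ape::rtree(sample(5:8, 1)))
    cands <- mad_root(utree)
    oracle <- mad_grid_oracle(utree, grid_n = 200)
    expect_equal(cands[[1]]$score, oracle$score, tolerance = 1e-4)
    expect_true(same_bipartition(cands[[1]]$side, utree$tip.label,
                                 edge_bipartition(utree, oracle$child),
                                 utree$tip.label))
  }
})

test_that("MAD ties on a symmetric 3-leaf star break lexicographically", {
  star <- parse_newick("(A:1,B:1,C:1);", multifurcations = "keep")
  cands <- mad_root(star)
  scores <- vapply(cands, `[[`, numeric(1), "score")
  expect_equal(diff(range(scores)), 0)
  expect_equal(cands[[1]]$side, "A")
})

test_that("MAD is invariant to the unrooted anchor and to length rescaling", {
  set.seed(31)
  utree <- ape::unroot(ape::rtree(7))
  c1 <- mad_root(utree)
  reanchored <- ape::unroot(reroot_at(utree, utree$edge[5, 2], 0.4))
  c2 <- mad_root(reanchored)
  expect_equal(c1[[1]]$score, c2[[1]]$score, tolerance = 1e-9)
  expect_true(same_bipartition(c1[[1]]$side, utree$tip.label,
                               c2[[1]]$side, reanchored$tip.label))
  scaled <- utree
  scaled$edge.length <- scaled$edge.length * 17.3
  c3 <- mad_root(scaled)
  expect_true(same_bipartition(c1[[1]]$side, utree$tip.label,
                               c3[[1]]$side, scaled$tip.label))
  expect_equal(c3[[1]]$score, c1[[1]]$score, tolerance = 1e-9)

  # scaling also leaves midpoint's chosen branch alone
  m1 <- midpoint_root(utree)
  m3 <- midpoint_root(scaled)
  expect_true(same_bipartition(m1$side, utree$tip.label,
                               m3$side, scaled$tip.label))
})

test_that("consensus requires two methods and a subunit majority", {
  utree <- ape::unroot(tree4())
  mk <- function(method, sub, child) {
    methanotrace:::new_rooting_candidate(method, utree, child, 0.5, 1, sub)
  }
  # edge child 6 realizes the {A,B}|{C,D} split, child 1 the {A}|{B,C,D} split
  x <- which(vapply(utree$edge[, 2], function(v)
    setequal(edge_bipartition(utree, v), c("C", "D")), logical(1)))
  child_x <- utree$edge[x, 2]

  # 3 methods agree on X for 4 of 5 subunits
  cands <- list()
  for (sub in paste0("su", 1:4)) {
    for (m in c("midpoint", "mad", "reconciliation")) {
      cands[[length(cands) + 1L]] <- mk(m, sub, child_x)
    }
  }
  cands[[length(cands) + 1L]] <- mk("midpoint", "su5", 1L)
  res <- consensus_root(cands)
  expect_true(res$accepted)
  expect_true(same_bipartition(res$side, utree$tip.label, c("C", "D"),
                               utree$tip.label))

  # one method only, all subunits: fails the two-method requirement
  cands1 <- lapply(paste0("su", 1:5), function(sub) mk("mad", sub, child_x))
  expect_false(consensus_root(cands1)$accepted)

  # two methods but only 2 of 5 subunits: no majority
  cands2 <- list()
  for (sub in paste0("su", 1:2)) {
    cands2[[length(cands2) + 1L]] <- mk("mad", sub, child_x)
    cands2[[length(cands2) + 1L]] <- mk("midpoint", sub, child_x)
  }
  expect_false(consensus_root(cands2, subunits = paste0("su", 1:5))$accepted)

  # an outgroup candidate is reported first regardless of the vote
  cands3 <- c(cands1, list(mk("outgroup", "su1", 1L)))
  res3 <- consensus_root(cands3)
  expect_equal(res3$outgroup_side, "A")

  expect_error(consensus_root(list()), "no rooting candidates")
})
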