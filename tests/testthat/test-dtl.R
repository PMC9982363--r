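test_that("a congruent single-copy family reconciles at cost 0, all speciations", {
  sp <- tree3()
  g <- parse_newick("((a:1,b:1):1,c:2);")
  map <- c(a = "A", b = "B", c = "C")
  r <- reconcile(g, sp, map, dtl_costs(2, 3, 1))
  expect_equal(r$cost, 0)
  expect_true(all(r$events$event == "S"))
  expect_equal(unname(r$counts[c("D", "T", "L")]), c(0, 0, 0))
})

test_that("known small instances match exhaustive enumeration", {
  sp <- tree3()
  g <- parse_newick("((a1:1,(a2:1,b:1):1):1,c:2);")
  map <- c(a1 = "A", a2 = "A", b = "B", c = "C")
  cs <- dtl_costs(2, 3, 1)
  r <- reconcile(g, sp, map, cs)
  bf <- brute_force_reconcile(g, sp, map, cs)
  expect_equal(r$cost, bf$cost)
  expect_equal(r$cost, 3)  # duplication-with-loss ties a single transfer

  sp4 <- tree4()
  g4 <- parse_newick("((a:1,c:1):1,(b:1,d:1):1);")
  map4 <- c(a = "A", b = "B", c = "C", d = "D")
  r4 <- reconcile(g4, sp4, map4, dtl_costs(1, 1, 1))
  expect_equal(r4$cost, brute_force_reconcile(g4, sp4, map4, dtl_costs(1, 1, 1))$cost)
  expect_gte(r4$counts[["T"]], 1)
})

test_that("stored totals recompute exactly from event counts", {
  set.seed(17)
  for (i in 1:20) {
    inst <- rand_dtl_instance()
    cs <- dtl_costs(sample(1:4, 1), sample(1:6, 1), 1)
    r <- reconcile(inst$gene, inst$species, inst$map, cs, seed = i)
    expect_identical(
      r$cost,
      cs$dup * r$counts[["D"]] + cs$transfer * r$counts[["T"]] +
        cs$loss * r$counts[["L"]]
    )
    # transfer donors and recipients are incomparable
    tr <- r$events[r$events$event == "T", ]
    if (nrow(tr)) {
      spx <- methanotrace:::index_species(inst$species)
      for (k in seq_len(nrow(tr))) {
        expect_true(spx$incomp[tr$species[k], tr$recipient[k]])
      }
    }
  }
})

test_that("raising the transfer cost never lowers the optimum", {
  set.seed(23)
  for (i in 1:15) {
    inst <- rand_dtl_instance()
    costs <- lapply(1:5, function(t) dtl_costs(2, t, 1))
    opts <- vapply(costs, function(cs)
      reconcile(inst$gene, inst$species, inst$map, cs)$cost, numeric(1))
    expect_true(all(diff(opts) >= -1e-12))
  }
})

test_that("fractional costs stay exact on the integer scale", {
  sp <- tree3()
  g <- parse_newick("((a1:1,(a2:1,b:1):1):1,c:2);")
  map <- c(a1 = "A", a2 = "A", b = "B", c = "C")
  r <- reconcile(g, sp, map, dtl_costs(2.5, 7.25, 0.5))
  bf <- brute_force_reconcile(g, sp, map, dtl_costs(2.5, 7.25, 0.5))
  expect_identical(r$cost, bf$cost)
})

test_that("opt_root equals an explicit reroot-and-reconcile loop", {
  set.seed(29)
  for (i in 1:5) {
    inst <- rand_dtl_instance(max_species = 5, max_gene = 5)
    cs <- dtl_costs(2, 3, 1)
    res <- opt_root_dtl(inst$gene, inst$species, inst$map, cs)
    utree <- res$unrooted
    loop <- vapply(seq_len(nrow(utree$edge)), function(k) {
      reconcile(reroot_at(utree, utree$edge[k, 2], 0.5),
                inst$species, inst$map, cs)$cost
    }, numeric(1))
    expect_equal(res$min_cost, min(loop))
    expect_equal(sort(res$table$cost), sort(loop))
    expect_length(res$table$child, 2 * ape::Ntip(utree) - 3)
  }
})

test_that("a congruent family's true rooting is in the opt_root set at cost 0", {
  st <- sim_species_tree(6, seed = 77)
  fam <- sim_gene_tree_dtl(st, 0, 0, 0, seed = 1)
  res <- opt_root_dtl(fam$gene, st, fam$map, dtl_costs(2, 3, 1))
  expect_equal(res$min_cost, 0)
  root_split_sp <- edge_bipartition(st, st$edge[1, 2])
  root_split_gene <- fam$map[fam$map %in% root_split_sp]
  expect_true(any(vapply(res$optimal_splits, function(sd)
    setequal(sd, names(root_split_gene)) ||
      setequal(sd, setdiff(fam$gene$tip.label, names(root_split_gene))),
    logical(1))))
})

test_that("species relabelling leaves the optimal cost unchanged", {
  set.seed(31)
  inst <- rand_dtl_instance()
  cs <- dtl_costs(2, 3, 1)
  base <- opt_root_dtl(inst$gene, inst$species, inst$map, cs)$min_cost
  perm <- sample(inst$species$tip.label)
  names(perm) <- inst$species$tip.label
  sp2 <- inst$species
  sp2$tip.label <- unname(perm[sp2$tip.label])
  map2 <- stats::setNames(unname(perm[inst$map]), names(inst$map))
  expect_equal(opt_root_dtl(inst$gene, sp2, map2, cs)$min_cost, base)
})

test_that("transfer-cost calibration finds the smallest recovering T", {
  st <- sim_species_tree(6, seed = 55)
  fam <- sim_gene_tree_dtl(st, 0, 0, 0, seed = 3)
  res0 <- opt_root_dtl(fam$gene, st, fam$map, dtl_costs(1, 2, 1))
  target <- res0$optimal_splits[[1]]
  sw <- optimize_transfer_cost(fam$gene, st, fam$map, target,
                               t_grid = c(2, 4, 8), loss = 1)
  expect_equal(sw$transfer_cost, 2)  # congruent: recovered at any T

  # explicit grid scan agrees
  scan <- vapply(c(2, 4, 8), function(t) {
    r <- opt_root_dtl(fam$gene, st, fam$map, dtl_costs(t / 2, t, 1))
    any(vapply(r$optimal_splits, function(sd)
      same_bipartition(sd, fam$gene$tip.label, target, fam$gene$tip.label),
      logical(1)))
  }, logical(1))
  expect_equal(unname(sw$per_t), scan)

  # an impossible target reports NA without raising
  fake <- fam$gene$tip.label[1:2]
  if (!any(vapply(res0$optimal_splits, function(sd) setequal(sd, fake),
                  logical(1)))) {
    sw2 <- optimize_transfer_cost(fam$gene, st, fam$map, fake,
                                  t_grid = c(1000), loss = 1)
    expect_true(is.na(sw2$transfer_cost) || sw2$transfer_cost == 1000)
  }
  expect_error(optimize_transfer_cost(fam$gene, st, fam$map, target,
                                      t_grid = numeric(0)), "empty")
})

test_that("aggregation splits runs over {T/4, T/2, 3T/4} and normalizes supports", {
  sp4 <- tree4()
  g4 <- parse_newick("((a:1,b:1):1,(c:1,d:1):1);")
  map4 <- c(a = "A", b = "B", c = "C", d = "D")
  agg <- aggregate_reconciliations(g4, sp4, map4, transfer_cost = 8,
                                   n_runs = 10, seed = 1)
  expect_equal(attr(agg, "runs_per_d"), c(4, 3, 3))
  expect_equal(attr(agg, "d_values"), c(2, 4, 6))
  # unique optimum: support 1 everywhere
  expect_true(all(agg$support == 1))
  expect_true(all(agg$event == "S"))

  # per-node supports always sum to one
  set.seed(41)
  for (i in 1:5) {
    inst <- rand_dtl_instance()
    agg <- aggregate_reconciliations(inst$gene, inst$species, inst$map,
                                     transfer_cost = 4, n_runs = 12, seed = i)
    sums <- as.numeric(tapply(agg$support, agg$gene_node, sum))
    expect_equal(sums, rep(1, length(sums)))
  }
})

test_that("symmetric co-optima split support near one half", {
  # two transfers, each with two symmetric recipients (see the two
  # co-optimal scenarios of the crossed 4-taxon family)
  sp4 <- tree4()
  g4 <- parse_newick("((a:1,c:1):1,(b:1,d:1):1);")
  map4 <- c(a = "A", b = "B", c = "C", d = "D")
  agg <- aggregate_reconciliations(g4, sp4, map4, transfer_cost = 1,
                                   loss_cost = 1, n_runs = 100, seed = 7)
  tr <- agg[grepl("^T", agg$event), ]
  expect_gt(nrow(tr), 0)
  expect_true(all(abs(tr$support - 0.5) <= 0.15))
})
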