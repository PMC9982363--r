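RT298 <- 8.314e-3 * 298.15

toy_species <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(name = r[[1]], phase = r[[2]], role = r[[3]],
               value = as.numeric(r[[4]]))))
}

test_that("delta_g reproduces the closed form and its symmetries", {
  rxn <- list(name = "iso", stoich = c(A = -1, B = 1), dg0 = 0)
  vals <- c(A = 1000, B = 1000)  # both at 1 M
  expect_equal(delta_g(rxn, vals), 0)

  rxn2 <- list(name = "iso", stoich = c(A = -1, B = 1), dg0 = 5)
  expect_equal(delta_g(rxn2, vals), 5)  # Q = 1 leaves dG = dG0

  vals10 <- c(A = 1, B = 10)
  expect_equal(delta_g(rxn, vals10), RT298 * log(10), tolerance = 1e-12)
  expect_equal(RT298 * log(10), 5.708, tolerance = 1e-3)

  rev <- list(name = "osi", stoich = c(A = 1, B = -1), dg0 = 0)
  expect_equal(delta_g(rev, vals10), -delta_g(rxn, vals10))

  # gases use partial pressure, aqueous mM / 1 M
  rg <- list(name = "gas", stoich = c(H2 = -1, X = 1), dg0 = 0)
  expect_equal(delta_g(rg, c(H2 = 0.1, X = 100), phases = c(H2 = "gas", X = "aqueous")),
               RT298 * log(0.1 / 0.1))
  expect_error(delta_g(rxn, c(A = 0, B = 1)), "nonpositive")
})

test_that("solve_reaction inverts the closed form", {
  rxn <- list(name = "iso", stoich = c(A = -1, B = 1), dg0 = 0, target = 0)
  out <- solve_reaction(rxn, c(A = 1, B = 99), adjust = "B")
  expect_equal(out[["B"]], 1)
  expect_error(solve_reaction(rxn, c(A = 1, B = 99)), "adjustable")

  rxn2 <- list(name = "iso", stoich = c(A = -1, B = 1), dg0 = -RT298 * log(10),
               target = 0)
  out2 <- solve_reaction(rxn2, c(A = 1, B = 1), adjust = "B")
  expect_equal(out2[["B"]], 10, tolerance = 1e-9)

  # a negative target pushes the product below the equilibrium solution
  out3 <- solve_reaction(rxn2, c(A = 1, B = 1), adjust = "B", target = -10)
  expect_lt(out3[["B"]], out2[["B"]])
})

test_that("a two-form pool under a symmetric equilibrium splits evenly", {
  m <- thermo_model(
    species = toy_species(list("X", "aqueous", "cofactor", 1.5),
                          list("Y", "aqueous", "cofactor", 0.5)),
    reactions = list(list(name = "iso", stoich = c(X = -1, Y = 1), dg0 = 0,
                          mode = "equilibrium", target = 0, adjust = "Y")),
    pools = list(list(name = "p", members = c("X", "Y"), total = 2))
  )
  st <- solve_equilibrium(m)
  expect_true(st$converged)
  expect_equal(st$values[["X"]], 1, tolerance = 1e-9)
  expect_equal(st$values[["Y"]], 1, tolerance = 1e-9)
})

test_that("a three-reaction chain matches the algebraic solution", {
  # chain W <-> X <-> Y <-> Z with dG0 (0, -q, +q), q = RT ln 10, and one
  # pool over all four forms: equilibrium ratios W:X:Y:Z = 1:1:10:1, so
  # with total 2.6 mM the closed form is W = X = Z = 0.2, Y = 2.0.
  q <- RT298 * log(10)
  m <- thermo_model(
    species = toy_species(list("W", "aqueous", "cofactor", 0.65),
                          list("X", "aqueous", "cofactor", 0.65),
                          list("Y", "aqueous", "cofactor", 0.65),
                          list("Z", "aqueous", "cofactor", 0.65)),
    reactions = list(
      list(name = "r1", stoich = c(W = -1, X = 1), dg0 = 0,
           mode = "equilibrium", target = 0, adjust = "X"),
      list(name = "r2", stoich = c(X = -1, Y = 1), dg0 = -q,
           mode = "equilibrium", target = 0, adjust = "Y"),
      list(name = "r3", stoich = c(Y = -1, Z = 1), dg0 = +q,
           mode = "equilibrium", target = 0, adjust = "Z")
    ),
    pools = list(list(name = "p", members = c("W", "X", "Y", "Z"), total = 2.6))
  )
  st <- solve_equilibrium(m, tol = 1e-10)
  expect_true(st$converged)
  expect_equal(unname(st$values[c("W", "X", "Y", "Z")]),
               c(0.2, 0.2, 2.0, 0.2), tolerance = 1e-8)
})

test_that("iterative solution matches a simultaneous nonlinear solve", {
  skip_if_not_installed("pracma")
  # four unknowns: W, X, Y, Z; two reactions + two pools (4 constraints)
  q <- 3.1
  m <- thermo_model(
    species = toy_species(list("H2", "gas", "boundary", 0.05),
                          list("W", "aqueous", "cofactor", 1),
                          list("X", "aqueous", "cofactor", 1),
                          list("Y", "aqueous", "cofactor", 0.8),
                          list("Z", "aqueous", "cofactor", 0.2)),
    reactions = list(
      list(name = "rx", stoich = c(W = -1, H2 = -1, X = 1), dg0 = -q,
           mode = "equilibrium", target = 0, adjust = "X"),
      list(name = "ry", stoich = c(X = -1, Y = -1, Z = 1, W = 1), dg0 = q,
           mode = "fixed", target = -2, adjust = "Z")
    ),
    pools = list(list(name = "wx", members = c("W", "X"), total = 2),
                 list(name = "yz", members = c("Y", "Z"), total = 1))
  )
  st <- solve_equilibrium(m, tol = 1e-10)
  expect_true(st$converged)

  rt <- RT298
  resid <- function(u) {
    v <- exp(u)  # mM, positivity by construction
    names(v) <- c("W", "X", "Y", "Z")
    c(-q + rt * log((v[["X"]] / 1000) / ((v[["W"]] / 1000) * 0.05)),
      q + rt * log((v[["Z"]] / 1000) * (v[["W"]] / 1000) /
                     ((v[["X"]] / 1000) * (v[["Y"]] / 1000))) + 2,
      v[["W"]] + v[["X"]] - 2,
      v[["Y"]] + v[["Z"]] - 1)
  }
  sol <- pracma::fsolve(resid, log(c(1, 1, 0.8, 0.2)))
  direct <- exp(sol$x)
  names(direct) <- c("W", "X", "Y", "Z")
  expect_equal(st$values[names(direct)], direct, tolerance = 1e-6)
})

test_that("pool totals are conserved to 1e-9 and dG targets met at convergence", {
  for (p in c("co2_reduction", "methanol_reduction")) {
    m <- read_thermo_model(system.file("extdata/thermo", paste0(p, ".yaml"),
                                       package = "methanotrace"))
    st <- solve_equilibrium(m)
    expect_true(st$converged)
    for (pool in m$pools) {
      expect_equal(sum(st$values[pool$members]) / pool$total, 1, tolerance = 1e-9)
    }
    targets <- vapply(m$reactions, function(r) r$target, numeric(1))
    expect_equal(unname(st$delta_g), targets, tolerance = 1e-6)
    expect_true(all(st$values > 0))
  }
})

test_that("raising H2 never lowers the reduced member of an H2 couple", {
  co2 <- read_thermo_model(system.file("extdata/thermo/co2_reduction.yaml",
                                       package = "methanotrace"))
  reduced <- numeric(0)
  for (h2 in c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1)) {
    m <- co2
    m$species$value[m$species$name == "H2"] <- h2
    st <- solve_equilibrium(m)
    reduced <- c(reduced, st$values[["F420H2"]])
  }
  expect_true(all(diff(reduced) >= -1e-12))
})

test_that("doubling pools and aqueous boundaries doubles a dG0=0 toy model", {
  base <- thermo_model(
    species = toy_species(list("A0", "aqueous", "boundary", 1),
                          list("X", "aqueous", "cofactor", 1),
                          list("Y", "aqueous", "cofactor", 1)),
    reactions = list(
      list(name = "r1", stoich = c(A0 = -1, X = 1), dg0 = 0,
           mode = "equilibrium", target = 0, adjust = "X"),
      list(name = "r2", stoich = c(X = -1, Y = 1), dg0 = 0,
           mode = "equilibrium", target = 0, adjust = "Y")
    ),
    pools = list(list(name = "p", members = c("X", "Y"), total = 2))
  )
  st1 <- solve_equilibrium(base)
  doubled <- base
  doubled$species$value <- base$species$value * 2
  doubled$pools[[1]]$total <- 4
  st2 <- solve_equilibrium(doubled)
  expect_equal(unname(st2$values[c("X", "Y")]),
               unname(st1$values[c("X", "Y")]) * 2, tolerance = 1e-9)
})

test_that("scenario reports keep declaration order and round-trip JSON", {
  m <- read_thermo_model(system.file("extdata/thermo/methanol_reduction.yaml",
                                     package = "methanotrace"))
  st <- solve_equilibrium(m)
  rep <- scenario_report(st)
  expect_equal(rep$species$name, m$species$name)
  expect_true(all(abs(rep$reactions$dg[rep$reactions$mode == "equilibrium"]) < 1e-6))
  f <- withr::local_tempfile()
  write_report(rep, f)
  back <- read_report(paste0(f, ".json"))
  expect_equal(back$species$value, rep$species$value, tolerance = 1e-12)
  expect_equal(back$reactions$dg0, rep$reactions$dg0)
})

test_that("model validation flags structural problems", {
  sp <- toy_species(list("A", "aqueous", "boundary", 1),
                    list("X", "aqueous", "cofactor", 1),
                    list("Y", "aqueous", "cofactor", 1))
  rxn <- function(adj) list(list(name = "r", stoich = c(A = -1, X = 1),
                                 dg0 = 0, mode = "equilibrium", target = 0,
                                 adjust = adj))
  expect_error(thermo_model(sp, rxn("A")), "boundary")
  expect_error(thermo_model(sp, list(list(name = "r", stoich = c(A = -1, Q = 1),
                                          dg0 = 0, adjust = "Q"))), "undeclared")
  expect_warning(thermo_model(sp, rxn("X")), "under-determined")
  expect_warning(
    thermo_model(sp, c(rxn("X"), rxn("X")),
                 pools = list(list(name = "p", members = c("X", "Y"), total = 2))),
    "over-determined")
})
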