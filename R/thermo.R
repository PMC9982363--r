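# Quasi-equilibrium solver for pathway thermodynamics.
#
# A model declares species (aqueous in mM, gases as partial pressures in
# atm), reactions with standard transformed Gibbs energies (kJ/mol) and a
# per-reaction mode (equilibrium: target dG = 0; fixed: target dG equal to
# a stated value, negative for energy conservation/dissipation, positive
# for energy investment), and cofactor pools whose member concentrations
# must sum to a fixed total. Boundary species never change; each reaction
# names the single species it adjusts. The solver sweeps the reactions in
# order, solving each single-unknown equation in closed form, rescales
# every pool to its total after each sweep (a Gauss-Seidel-like fixed
# point), and declares convergence when all pool sums and all reaction dG
# values are on target. Redox couples tied to H2 are ordinary two-member
# pools whose internal ratio is pinned by an equilibrium reaction with H2:
# pool rescaling preserves ratios, so the coupling survives conservation.

GAS_CONSTANT_KJ <- 8.314e-3  # kJ mol^-1 K^-1

#' Construct a pathway thermodynamic model
#'
#' @param species Data frame with columns `name`, `phase` (`"aqueous"` in
#'   mM or `"gas"` in atm), `role` (`"boundary"`, `"intermediate"`, or
#'   `"cofactor"`), `value` (initial value; fixed forever for boundary
#'   species).
#' @param reactions List of reactions, each a list with `name`, `stoich`
#'   (named numeric, products positive), `dg0` (kJ/mol), `mode`
#'   (`"equilibrium"` or `"fixed"`), `target` (kJ/mol, used for mode
#'   `"fixed"`; 0 otherwise), `adjust` (the species solved for).
#' @param pools List of pools, each a list with `name`, `members`
#'   (character, >= 2), `total` (mM).
#' @param temperature Temperature in kelvin.
#' @param name Optional scenario name.
#' @return A `thermo_model`.
#' @export
thermo_model <- function(species, reactions, pools = list(),
                         temperature = 298.15, name = "scenario") {
  stopifnot(is.data.frame(species),
            all(c("name", "phase", "role", "value") %in% names(species)))
  if (anyDuplicated(species$name)) stop("duplicate species names", call. = FALSE)
  if (any(species$value <= 0)) {
    stop("species values must be strictly positive", call. = FALSE)
  }
  if (!all(species$phase %in% c("aqueous", "gas"))) {
    stop("phase must be 'aqueous' or 'gas'", call. = FALSE)
  }
  if (!all(species$role %in% c("boundary", "intermediate", "cofactor"))) {
    stop("role must be boundary/intermediate/cofactor", call. = FALSE)
  }
  seen_in_pool <- character(0)
  for (p in pools) {
    stopifnot(length(p$members) >= 2L, is.numeric(p$total), p$total > 0)
    if (!all(p$members %in% species$name)) {
      stop("pool '", p$name, "' names unknown species", call. = FALSE)
    }
    dup <- intersect(p$members, seen_in_pool)
    if (length(dup)) {
      stop("species in more than one pool: ", paste(dup, collapse = ", "),
           call. = FALSE)
    }
    seen_in_pool <- c(seen_in_pool, p$members)
  }
  adjusted <- character(0)
  for (r in reactions) {
    stopifnot(!is.null(r$name), !is.null(r$stoich), !is.null(r$adjust))
    if (!all(names(r$stoich) %in% species$name)) {
      stop("reaction '", r$name, "' names undeclared species: ",
           paste(setdiff(names(r$stoich), species$name), collapse = ", "),
           call. = FALSE)
    }
    if (!any(r$stoich > 0) || !any(r$stoich < 0)) {
      stop("reaction '", r$name, "' needs at least one reactant and one product",
           call. = FALSE)
    }
    if (!(r$adjust %in% names(r$stoich))) {
      stop("reaction '", r$name, "' does not involve its adjustable species",
           call. = FALSE)
    }
    role <- species$role[species$name == r$adjust]
    if (role == "boundary") {
      stop("reaction '", r$name, "' adjusts a boundary species", call. = FALSE)
    }
    adjusted <- c(adjusted, r$adjust)
  }
  over <- unique(adjusted[duplicated(adjusted)])
  if (length(over)) {
    warning("over-determined: species adjusted by more than one reaction: ",
            paste(over, collapse = ", "), call. = FALSE)
  }
  free <- species$name[species$role != "boundary"]
  under <- setdiff(free, c(adjusted, seen_in_pool))
  if (length(under)) {
    warning("under-determined: free species never adjusted nor pooled: ",
            paste(under, collapse = ", "), call. = FALSE)
  }
  structure(list(species = species, reactions = reactions, pools = pools,
                 temperature = temperature, name = name),
            class = "thermo_model")
}

#' @export
print.thermo_model <- function(x, ...) {
  cat(sprintf("<thermo model '%s'> %d species, %d reactions, %d pools, T=%g K\n",
              x$name, nrow(x$species), length(x$reactions), length(x$pools),
              x$temperature))
  invisible(x)
}

#' Read a pathway thermodynamic model from a YAML config
#'
#' Reactions are written as equations, e.g. `"2 A + B -> C"`; coefficients
#' default to 1 and products are positive in the resulting stoichiometry.
#'
#' @param path Path to the YAML scenario file.
#' @return A [thermo_model()].
#' @export
read_thermo_model <- function(path) {
  cfg <- yaml::read_yaml(path)
  species <- do.call(rbind, lapply(cfg$species, function(s) {
    data.frame(name = s$name, phase = s$phase %||% "aqueous",
               role = s$role %||% "intermediate", value = as.numeric(s$value))
  }))
  reactions <- lapply(cfg$reactions, function(r) {
    list(name = r$name, stoich = parse_equation(r$equation),
         dg0 = as.numeric(r$dg0), mode = r$mode %||% "equilibrium",
         target = as.numeric(r$target %||% 0), adjust = r$adjust)
  })
  pools <- lapply(cfg$pools %||% list(), function(p) {
    list(name = p$name, members = as.character(p$members),
         total = as.numeric(p$total))
  })
  thermo_model(species, reactions, pools,
               temperature = as.numeric(cfg$temperature %||% 298.15),
               name = cfg$name %||% tools::file_path_sans_ext(basename(path)))
}

parse_equation <- function(eq) {
  sides <- strsplit(eq, "->", fixed = TRUE)[[1]]
  if (length(sides) != 2L) stop("equation must contain one '->': ", eq, call. = FALSE)
  parse_side <- function(side, sign) {
    terms <- strsplit(side, " + ", fixed = TRUE)[[1]]
    out <- numeric(0)
    for (term in trimws(terms)) {
      m <- regmatches(term, regexec("^([0-9.]+)\\s+(.+)$", term))[[1]]
      if (length(m) == 3L) {
        out[m[3]] <- sign * as.numeric(m[2])
      } else {
        out[term] <- sign
      }
    }
    out
  }
  lhs <- parse_side(sides[1], -1)
  rhs <- parse_side(sides[2], +1)
  both <- intersect(names(lhs), names(rhs))
  st <- c(lhs, rhs)
  if (length(both)) {  # net out species appearing on both sides
    for (b in both) {
      st <- st[names(st) != b]
      net <- lhs[b] + rhs[b]
      if (net != 0) st[b] <- net
    }
  }
  st
}

# Activities: aqueous values are mM relative to a 1 M standard state,
# gases are partial pressures relative to 1 atm. Water, if present, is
# expected to be declared aqueous with value 1000 (activity 1).
activities <- function(values, phases) {
  ifelse(phases[names(values)] == "gas", values, values / 1000)
}

#' Gibbs energy of a reaction at a given state
#'
#' Computes `dG = dG0' + R T ln Q`, with Q the product of activities
#' raised to their stoichiometric coefficients (products positive).
#'
#' @param rxn A reaction (list with `stoich` and `dg0`), as stored in a
#'   [thermo_model()].
#' @param values Named numeric vector of species values (mM for aqueous,
#'   atm for gas).
#' @param temperature Temperature in kelvin.
#' @param phases Named character vector of species phases; species absent
#'   from it are treated as aqueous.
#' @return dG in kJ/mol.
#' @export
delta_g <- function(rxn, values, temperature = 298.15, phases = NULL) {
  sto <- rxn$stoich
  miss <- setdiff(names(sto), names(values))
  if (length(miss)) stop("state lacks species: ", paste(miss, collapse = ", "),
                         call. = FALSE)
  v <- values[names(sto)]
  if (any(v <= 0)) stop("nonpositive species value in reaction '", rxn$name, "'",
                        call. = FALSE)
  ph <- rep("aqueous", length(sto))
  names(ph) <- names(sto)
  if (!is.null(phases)) ph[names(sto)] <- ifelse(is.na(phases[names(sto)]),
                                                 "aqueous", phases[names(sto)])
  a <- ifelse(ph == "gas", v, v / 1000)
  rxn$dg0 + GAS_CONSTANT_KJ * temperature * sum(sto * log(a))
}

#' Solve one reaction for its adjustable species
#'
#' Sets the adjustable species so that the realized dG equals the
#' reaction's target (0 for equilibrium mode); the single-unknown equation
#' is solved in closed form.
#'
#' @inheritParams delta_g
#' @param adjust Name of the species to solve for (must appear in the
#'   reaction).
#' @param target Target dG in kJ/mol.
#' @return The updated `values` vector.
#' @export
solve_reaction <- function(rxn, values, adjust = rxn$adjust,
                           target = rxn$target %||% 0,
                           temperature = 298.15, phases = NULL) {
  sto <- rxn$stoich
  if (is.null(adjust)) {
    stop("an adjustable species must be named for reaction '", rxn$name, "'",
         call. = FALSE)
  }
  if (!(adjust %in% names(sto))) {
    stop("species '", adjust, "' does not appear in reaction '", rxn$name, "'",
         call. = FALSE)
  }
  nu <- sto[[adjust]]
  rest <- sto[names(sto) != adjust]
  ph <- rep("aqueous", length(sto)); names(ph) <- names(sto)
  if (!is.null(phases)) ph[names(sto)] <- ifelse(is.na(phases[names(sto)]),
                                                 "aqueous", phases[names(sto)])
  v <- values[names(rest)]
  if (any(v <= 0)) stop("nonpositive species value in reaction '", rxn$name, "'",
                        call. = FALSE)
  a_rest <- ifelse(ph[names(rest)] == "gas", v, v / 1000)
  rt <- GAS_CONSTANT_KJ * temperature
  ln_ax <- ((target - rxn$dg0) / rt - sum(rest * log(a_rest))) / nu
  ax <- exp(ln_ax)
  if (!is.finite(ax) || ax <= 0) {
    stop("reaction '", rxn$name, "' is infeasible: no positive value of '",
         adjust, "' reaches its target dG", call. = FALSE)
  }
  values[[adjust]] <- if (ph[[adjust]] == "gas") ax else ax * 1000
  values
}

#' Solve a quasi-equilibrium pathway model
#'
#' Fixed-point iteration: sweep the reactions in declaration order,
#' solving each for its designated species, then rescale every cofactor
#' pool to its total. Converged when every pool-sum relative residual is
#' below `tol` and every reaction's |dG - target| is below `tol * R * T`.
#'
#' @param model A [thermo_model()].
#' @param tol Relative tolerance.
#' @param max_iter Iteration cap.
#' @param damping Update damping in (0, 1]; 1 applies each closed-form
#'   solution fully, smaller values move the species geometrically toward
#'   it.
#' @return An `equilibrium_state`: list with `values` (named vector, mM or
#'   atm), `delta_g` (realized dG per reaction), `iterations`,
#'   `converged`, and `residuals` (`pool` and `dg`).
#' @export
solve_equilibrium <- function(model, tol = 1e-6, max_iter = 10000, damping = 1) {
  stopifnot(inherits(model, "thermo_model"), damping > 0, damping <= 1)
  sp <- model$species
  values <- stats::setNames(sp$value, sp$name)
  phases <- stats::setNames(sp$phase, sp$name)
  boundary <- sp$name[sp$role == "boundary"]
  rt <- GAS_CONSTANT_KJ * model$temperature
  pool_res <- dg_res <- Inf
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    for (rxn in model$reactions) {
      new <- solve_reaction(rxn, values, adjust = rxn$adjust,
                            target = rxn$target %||% 0,
                            temperature = model$temperature, phases = phases)
      if (damping < 1) {
        x <- rxn$adjust
        new[[x]] <- values[[x]]^(1 - damping) * new[[x]]^damping
      }
      values <- new
      values[boundary] <- sp$value[match(boundary, sp$name)]
    }
    for (p in model$pools) {
      s <- sum(values[p$members])
      values[p$members] <- values[p$members] * (p$total / s)
    }
    pool_res <- if (length(model$pools)) {
      max(vapply(model$pools, function(p)
        abs(sum(values[p$members]) / p$total - 1), numeric(1)))
    } else 0
    dg_now <- vapply(model$reactions, function(rxn)
      delta_g(rxn, values, model$temperature, phases), numeric(1))
    targets <- vapply(model$reactions, function(rxn) rxn$target %||% 0, numeric(1))
    dg_res <- max(abs(dg_now - targets))
    if (pool_res < tol && dg_res < tol * abs(rt)) break
  }
  converged <- pool_res < tol && dg_res < tol * abs(rt)
  if (!converged) {
    warning("equilibrium iteration did not converge in ", max_iter,
            " sweeps (pool residual ", signif(pool_res, 3), ", dG residual ",
            signif(dg_res, 3), " kJ/mol)", call. = FALSE)
  }
  dg_now <- vapply(model$reactions, function(rxn)
    delta_g(rxn, values, model$temperature, phases), numeric(1))
  names(dg_now) <- vapply(model$reactions, `[[`, character(1), "name")
  structure(list(values = values, delta_g = dg_now, iterations = iter,
                 converged = converged,
                 residuals = list(pool = pool_res, dg = dg_res),
                 model = model),
            class = "equilibrium_state")
}

#' @export
print.equilibrium_state <- function(x, ...) {
  cat(sprintf("<equilibrium state '%s'> %s after %d sweeps\n",
              x$model$name,
              if (x$converged) "converged" else "NOT converged", x$iterations))
  print(signif(x$values, 4))
  invisible(x)
}

#' Tabulate a solved scenario
#'
#' @param state An `equilibrium_state`.
#' @param model The model it solves (defaults to the one stored in the
#'   state).
#' @return List of two data frames in model declaration order: `species`
#'   (name, phase, role, unit, value) and `reactions` (name, dg0, mode,
#'   target, dg).
#' @export
scenario_report <- function(state, model = state$model) {
  sp <- model$species
  species <- data.frame(
    name = sp$name, phase = sp$phase, role = sp$role,
    unit = ifelse(sp$phase == "gas", "atm", "mM"),
    value = as.numeric(state$values[sp$name])
  )
  reactions <- data.frame(
    name = vapply(model$reactions, `[[`, character(1), "name"),
    dg0 = vapply(model$reactions, `[[`, numeric(1), "dg0"),
    mode = vapply(model$reactions, `[[`, character(1), "mode"),
    target = vapply(model$reactions, function(r) r$target %||% 0, numeric(1)),
    dg = as.numeric(state$delta_g)
  )
  list(species = species, reactions = reactions,
       converged = state$converged, scenario = model$name)
}
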