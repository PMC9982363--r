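# Ancestral optimal-growth-temperature estimation from 16S rRNA base
# composition: Fitch parsimony ancestral sequences, uracil fractions, and
# a configurable linear uracil-OGT correlation.

#' Read an aligned RNA (or DNA) FASTA file
#'
#' Sequences must be aligned (equal length); `T` is read as `U` and
#' everything is uppercased. Allowed characters are `A C G U - N`;
#' anything else errors loudly.
#'
#' @param path FASTA file path.
#' @return Character matrix, one row per sequence (rownames = ids), one
#'   column per alignment site.
#' @export
read_rna_alignment <- function(path) {
  recs <- seqinr::read.fasta(path, seqtype = "AA", as.string = FALSE,
                             forceDNAtolower = FALSE)
  ids <- names(recs)
  if (anyDuplicated(ids)) stop("duplicate sequence ids", call. = FALSE)
  lens <- lengths(recs)
  if (length(unique(lens)) != 1L) {
    stop("sequences are not aligned (unequal lengths)", call. = FALSE)
  }
  mat <- do.call(rbind, lapply(recs, function(s) toupper(as.character(s))))
  rownames(mat) <- ids
  as_rna_matrix(mat)
}

as_rna_matrix <- function(mat) {
  mat[mat == "T"] <- "U"
  bad <- setdiff(unique(as.vector(mat)), c("A", "C", "G", "U", "-", "N"))
  if (length(bad)) {
    stop("unsupported characters in alignment: ", paste(bad, collapse = " "),
         "; only A C G U (T) - N are accepted", call. = FALSE)
  }
  mat
}

#' Uracil fraction of a sequence
#'
#' `#U / (#A + #C + #G + #U)`; gaps and `N` are excluded from both
#' numerator and denominator. `T` counts as `U`.
#'
#' @param seq A single sequence string, a character vector of residues,
#'   or a character matrix (one row per sequence).
#' @return Numeric fraction in `[0, 1]` (vector for matrix input), with
#'   attribute `n_sites` giving the number of counted (unambiguous,
#'   ungapped) bases.
#' @export
#' @examples
#' uracil_fraction("UUCA")
uracil_fraction <- function(seq) {
  if (is.matrix(seq)) {
    out <- apply(seq, 1, uracil_fraction)
    n <- vapply(seq_len(nrow(seq)), function(i)
      attr(uracil_fraction(seq[i, ]), "n_sites"), integer(1))
    attributes(out) <- list(names = rownames(seq), n_sites = n)
    return(out)
  }
  if (length(seq) == 1L && nchar(seq) > 1L) seq <- strsplit(seq, "")[[1]]
  seq <- toupper(seq)
  seq[seq == "T"] <- "U"
  bad <- setdiff(unique(seq), c("A", "C", "G", "U", "-", "N"))
  if (length(bad)) {
    stop("unsupported characters: ", paste(bad, collapse = " "), call. = FALSE)
  }
  counted <- seq %in% c("A", "C", "G", "U")
  n <- sum(counted)
  if (n == 0L) stop("no unambiguous bases to count", call. = FALSE)
  structure(sum(seq == "U") / n, n_sites = n)
}

#' Fitch parsimony ancestral sequences
#'
#' Per-site Fitch parsimony on a rooted binary tree: bottom-up state sets
#' (gaps and `N` at leaves act as fully missing, i.e. the full state
#' set), then top-down resolution keeping the parent state when the
#' child's set allows it and otherwise taking the alphabetically smallest
#' member. The total number of implied changes equals the Fitch parsimony
#' score.
#'
#' @param alignment Character matrix from [read_rna_alignment()] (rows
#'   must cover all tree leaves).
#' @param tree Rooted binary `phylo`; leaf labels index the alignment.
#' @return List with `ancestors` (character matrix, one row per internal
#'   node, rownames are node ids), `states` (ancestors plus leaves), and
#'   `score` (total parsimony changes).
#' @export
fitch_ancestral <- function(alignment, tree) {
  if (!ape::is.rooted(tree) || !ape::is.binary(tree)) {
    stop("a rooted binary tree is required", call. = FALSE)
  }
  miss <- setdiff(tree$tip.label, rownames(alignment))
  if (length(miss)) {
    stop("leaves without sequence: ", paste(miss, collapse = ", "), call. = FALSE)
  }
  alignment <- as_rna_matrix(alignment)
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  nsites <- ncol(alignment)
  bit_of <- c(A = 1L, C = 2L, G = 4L, U = 8L, "-" = 15L, N = 15L)
  state_of_bit <- c("A", "C", "G", "U")  # lowest set bit, alphabetical order
  lowest_bit <- function(x) bitwAnd(x, -x)

  kids <- matrix(NA_integer_, m, 2)
  for (k in seq_len(nrow(tree$edge))) {
    p <- tree$edge[k, 1]
    kids[p, if (is.na(kids[p, 1])) 1 else 2] <- tree$edge[k, 2]
  }
  root <- n + 1L
  ord <- integer(0); stack <- root
  while (length(stack)) {
    v <- stack[[1]]; stack <- stack[-1]
    ord <- c(ord, v)
    if (!is.na(kids[v, 1])) stack <- c(kids[v, 1], kids[v, 2], stack)
  }
  sets <- matrix(0L, m, nsites)
  score <- 0L
  for (v in rev(ord)) {
    if (is.na(kids[v, 1])) {
      sets[v, ] <- bit_of[alignment[tree$tip.label[v], ]]
    } else {
      a <- sets[kids[v, 1], ]; b <- sets[kids[v, 2], ]
      inter <- bitwAnd(a, b)
      un <- bitwOr(a, b)
      disjoint <- inter == 0L
      score <- score + sum(disjoint)
      sets[v, ] <- ifelse(disjoint, un, inter)
    }
  }
  states <- matrix(NA_integer_, m, nsites)
  for (v in ord) {
    if (v == root) {
      states[v, ] <- lowest_bit(sets[v, ])
    } else {
      p <- parent_of(tree, v)
      keep <- bitwAnd(sets[v, ], states[p, ]) != 0L
      states[v, ] <- ifelse(keep, states[p, ], lowest_bit(sets[v, ]))
    }
  }
  chr <- matrix(state_of_bit[as.integer(log2(states)) + 1L], m, nsites)
  internal <- (n + 1L):m
  anc <- chr[internal, , drop = FALSE]
  rownames(anc) <- as.character(internal)
  all_states <- chr
  rownames(all_states) <- c(tree$tip.label, as.character(internal))
  list(ancestors = anc, states = all_states, score = score)
}

parent_of <- function(tree, v) tree$edge[tree$edge[, 2] == v, 1]

#' A linear uracil-content to growth-temperature model
#'
#' @param slope Slope in degrees Celsius per unit uracil fraction.
#' @param intercept Intercept in degrees Celsius.
#' @param domain Valid uracil-fraction interval; predictions outside it
#'   are still returned but flagged (and warned about), never silently
#'   clipped.
#' @return An `ogt_model`.
#' @export
ogt_model <- function(slope, intercept, domain = c(0, 1)) {
  stopifnot(is.finite(slope), is.finite(intercept),
            length(domain) == 2L, domain[1] < domain[2])
  structure(list(slope = slope, intercept = intercept, domain = domain),
            class = "ogt_model")
}

#' @export
print.ogt_model <- function(x, ...) {
  cat(sprintf("<OGT model> T = %g * U + %g (degC), domain U in [%g, %g]\n",
              x$slope, x$intercept, x$domain[1], x$domain[2]))
  invisible(x)
}

#' Estimate growth temperature from a uracil fraction
#'
#' @param fraction Uracil fraction(s) in `[0, 1]`.
#' @param model An [ogt_model()].
#' @return Estimated temperature(s) in degrees Celsius, with attribute
#'   `out_of_domain` (logical) flagging fractions outside the model's
#'   calibrated domain.
#' @export
estimate_ogt <- function(fraction, model) {
  if (!inherits(model, "ogt_model")) stop("model must be an ogt_model", call. = FALSE)
  stopifnot(all(fraction >= 0 & fraction <= 1))
  out <- model$slope * fraction + model$intercept
  oob <- fraction < model$domain[1] | fraction > model$domain[2]
  if (any(oob)) {
    warning(sum(oob), " fraction(s) outside the model domain [",
            model$domain[1], ", ", model$domain[2], "]", call. = FALSE)
  }
  attr(out, "out_of_domain") <- oob
  out
}

#' Fit a uracil-OGT model by ordinary least squares
#'
#' @param fractions Uracil fractions (>= 2 distinct values).
#' @param temperatures Known growth temperatures (degrees Celsius).
#' @return An [ogt_model()] with the fitted domain set to the observed
#'   fraction range and attributes `residual_sd` and `stderr` (slope
#'   standard error).
#' @export
fit_ogt_model <- function(fractions, temperatures) {
  stopifnot(length(fractions) == length(temperatures), length(fractions) >= 2L)
  if (length(unique(fractions)) < 2L) {
    stop("degenerate fit: all uracil fractions identical", call. = FALSE)
  }
  fit <- stats::lm(temperatures ~ fractions)
  cf <- stats::coef(fit)
  model <- ogt_model(slope = unname(cf[2]), intercept = unname(cf[1]),
                     domain = range(fractions))
  attr(model, "residual_sd") <- stats::sigma(fit)
  attr(model, "stderr") <- unname(sqrt(diag(stats::vcov(fit)))[2])
  model
}

#' Per-node uracil fraction and growth-temperature estimate
#'
#' Reconstructs ancestral sequences with [fitch_ancestral()], then applies
#' the uracil-OGT model to every node of the tree.
#'
#' @inheritParams fitch_ancestral
#' @param model An [ogt_model()].
#' @param sites Optional site mask (integer positions or logical vector)
#'   restricting the composition to part of the alignment; default all
#'   sites.
#' @return Data frame: `node` (id), `label`, `is_leaf`, `uracil_fraction`,
#'   `n_sites`, `ogt`.
#' @export
ancestral_ogt <- function(alignment, tree, model, sites = NULL) {
  fa <- fitch_ancestral(alignment, tree)
  n <- ape::Ntip(tree)
  m <- n + tree$Nnode
  seqs <- rbind(alignment[tree$tip.label, , drop = FALSE],
                fa$ancestors)
  if (!is.null(sites)) seqs <- seqs[, sites, drop = FALSE]
  fr <- uracil_fraction(seqs)
  ogt <- suppressWarnings(estimate_ogt(as.numeric(fr), model))
  data.frame(
    node = seq_len(m),
    label = c(tree$tip.label, rownames(fa$ancestors)),
    is_leaf = seq_len(m) <= n,
    uracil_fraction = as.numeric(fr),
    n_sites = attr(fr, "n_sites"),
    ogt = as.numeric(ogt),
    out_of_domain = attr(ogt, "out_of_domain")
  )
}
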