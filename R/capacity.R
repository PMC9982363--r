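# Genome biosynthetic-capacity scoring by pathway completeness, with a
# size-dependent number of tolerated missing genes.

#' Missing genes tolerated for a pathway of a given size
#'
#' Piecewise rule: pathways of 1-3 genes tolerate 0 missing genes, 4-5
#' tolerate 1, 6-10 tolerate 2, 11-15 tolerate 3, and 16 or more tolerate
#' 4. Non-decreasing in pathway size and capped at 4.
#'
#' @param pathway_size Positive integer vector of pathway gene counts.
#' @return Integer vector of tolerated missing-gene counts.
#' @export
#' @examples
#' allowed_missing(c(3, 4, 10, 16))
allowed_missing <- function(pathway_size) {
  if (any(pathway_size < 1)) stop("pathway size must be >= 1", call. = FALSE)
  findInterval(pathway_size, c(1, 4, 6, 11, 16)) - 1L
}

#' Read a pathway catalogue
#'
#' YAML schema: a list of pathways, each with `id`, `category`
#' (`"amino-acid"` or `"vitamin-cofactor"`), `compound`, and `genes`. A
#' `genes` entry is either a gene-family id or a list of alternative ids
#' (isoenzymes); an alternative group counts as a single gene for the
#' size rule and is satisfied by any one of its members.
#'
#' @param path YAML file path.
#' @return A `pathway_catalogue`: list of pathways with fields `id`,
#'   `category`, `compound`, `genes` (list of character vectors).
#' @export
read_pathway_catalogue <- function(path) {
  cfg <- yaml::read_yaml(path)
  paths <- lapply(cfg$pathways, function(p) {
    genes <- lapply(p$genes, function(g) as.character(unlist(g)))
    list(id = p$id, category = p$category %||% "amino-acid",
         compound = p$compound %||% p$id, genes = genes)
  })
  validate_catalogue(paths)
}

validate_catalogue <- function(paths) {
  if (length(paths) == 0L) stop("empty pathway catalogue", call. = FALSE)
  ids <- vapply(paths, `[[`, character(1), "id")
  if (anyDuplicated(ids)) stop("duplicate pathway ids", call. = FALSE)
  for (p in paths) {
    if (length(p$genes) < 1L) {
      stop("pathway '", p$id, "' has no genes", call. = FALSE)
    }
    flat <- unlist(p$genes)
    if (anyDuplicated(flat)) {
      stop("pathway '", p$id, "' repeats gene-family ids", call. = FALSE)
    }
  }
  structure(paths, class = "pathway_catalogue")
}

#' @export
print.pathway_catalogue <- function(x, ...) {
  cats <- table(vapply(x, `[[`, character(1), "category"))
  cat(sprintf("<pathway catalogue> %d pathways (%s)\n", length(x),
              paste(names(cats), cats, sep = ": ", collapse = ", ")))
  invisible(x)
}

#' Read genome gene content
#'
#' Two tab-separated columns, `genome<TAB>family`; `#` comments ignored.
#' Duplicate annotations collapse to presence.
#'
#' @param path File path.
#' @return Named list of character vectors (gene-family ids per genome).
#' @export
read_gene_content <- function(path) {
  tab <- utils::read.table(path, sep = "\t", comment.char = "#",
                           stringsAsFactors = FALSE,
                           col.names = c("genome", "family"))
  lapply(split(tab$family, tab$genome), unique)
}

#' Score genomes for biosynthetic capacity
#'
#' A genome is capable of a pathway when the number of unsatisfied genes
#' (an alternative group is satisfied by any member) does not exceed
#' [allowed_missing()] of the pathway size. Copy number is ignored:
#' presence of one annotation hit counts.
#'
#' @param content Named list of character vectors: present gene families
#'   per genome (or the output of [read_gene_content()]).
#' @param catalogue A `pathway_catalogue`.
#' @return A `capacity_profile` data frame: one row per genome with a
#'   logical column per pathway id and a `capacity` count.
#' @export
score_genomes <- function(content, catalogue) {
  if (length(catalogue) == 0L) stop("empty pathway catalogue", call. = FALSE)
  ids <- vapply(catalogue, `[[`, character(1), "id")
  rows <- lapply(names(content), function(gname) {
    present <- content[[gname]]
    caps <- vapply(catalogue, function(p) {
      missing <- sum(!vapply(p$genes, function(g) any(g %in% present), logical(1)))
      missing <= allowed_missing(length(p$genes))
    }, logical(1))
    c(list(genome = gname), as.list(stats::setNames(caps, ids)),
      list(capacity = sum(caps)))
  })
  out <- do.call(rbind, lapply(rows, function(r) as.data.frame(r, check.names = FALSE)))
  rownames(out) <- NULL
  class(out) <- c("capacity_profile", "data.frame")
  out
}

#' Distribution of capacity counts per genome group
#'
#' @param profile A `capacity_profile` from [score_genomes()].
#' @param grouping Named character vector mapping genome id to group
#'   label; every scored genome must be assigned.
#' @return Data frame with one row per group: n, min, q1, median, mean,
#'   q3, max (quartiles type 7), ordered by group label.
#' @export
summarize_by_group <- function(profile, grouping) {
  miss <- setdiff(profile$genome, names(grouping))
  if (length(miss)) {
    stop("genomes missing from grouping: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  groups <- grouping[profile$genome]
  out <- do.call(rbind, lapply(sort(unique(groups)), function(g) {
    x <- profile$capacity[groups == g]
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(group = g, n = length(x), min = min(x), q1 = q[1],
               median = q[2], mean = mean(x), q3 = q[3], max = max(x))
  }))
  rownames(out) <- NULL
  out
}
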