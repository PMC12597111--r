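#' Founder pedigrees containing multiple cases
#'
#' For every genealogy founder (individual with no recorded parents) whose
#' recorded descendants include at least `min_cases` cases, builds a
#' `founder_pedigree`: the founder, all descendants, the case descendants
#' and the observed case count. Pedigrees may overlap, and a founder
#' couple yields two pedigrees with identical descendant sets (reports
#' deduplicate these; see [high_risk_scan()]).
#'
#' @param g a [genealogy()].
#' @param cases case ids.
#' @param min_cases minimum case descendants (>= 2 by convention).
#' @return List of objects of class `founder_pedigree`, each a list with
#'   `founder`, `descendants`, `case_descendants`, `observed` (and, after
#'   [pedigree_excess_test()], `expected` and `p`).
#' @export
founder_pedigrees <- function(g, cases, min_cases = 2L) {
  stopifnot(inherits(g, "genealogy"), min_cases >= 1L)
  cases <- as.character(cases)
  case_idx <- .resolve_ids(g, cases)
  # tally case descendants per founder by walking up from each case
  counts <- integer(nrow(g$df))
  for (ci in case_idx) {
    anc <- .ancestor_idx(g, ci)
    roots <- anc[g$fid[anc] == 0L & g$mid[anc] == 0L]
    roots <- setdiff(roots, ci)
    counts[roots] <- counts[roots] + 1L
  }
  hits <- which(counts >= min_cases)
  hits <- hits[order(g$df$birth_year[hits], g$df$id[hits])]
  lapply(hits, function(f) {
    desc <- .descendant_idx(g, f)
    cd <- intersect(desc, case_idx)
    structure(list(founder = g$df$id[f],
                   descendants = g$df$id[desc],
                   case_descendants = g$df$id[cd],
                   observed = length(cd),
                   expected = NULL, p = NULL),
              class = "founder_pedigree")
  })
}

# All ancestors of i including i itself (indices).
.ancestor_idx <- function(g, i) {
  seen <- i
  frontier <- i
  while (length(frontier) > 0L) {
    up <- c(g$fid[frontier], g$mid[frontier])
    up <- unique(up[up > 0L])
    up <- setdiff(up, seen)
    seen <- c(seen, up)
    frontier <- up
  }
  seen
}

# All strict descendants of i (indices).
.descendant_idx <- function(g, i) {
  seen <- integer(0)
  frontier <- g$kids[[i]]
  while (length(frontier) > 0L) {
    frontier <- setdiff(unique(frontier), seen)
    seen <- c(seen, frontier)
    frontier <- unlist(g$kids[frontier])
  }
  seen
}

#' @export
print.founder_pedigree <- function(x, ...) {
  cat(sprintf("founder pedigree: founder %s, %d descendants, %d case(s)",
              x$founder, length(x$descendants), x$observed))
  if (!is.null(x$p)) {
    cat(sprintf(", expected %.3g, p = %.3g", x$expected, x$p))
  }
  cat("\n")
  invisible(x)
}

#' Partition cases into non-overlapping related clusters
#'
#' Connected components of the case-relatedness graph, with an edge
#' between two cases whenever their kinship is positive (equivalently,
#' whenever they share a recorded common ancestor). Cases related to no
#' other case form singleton clusters; clusters of size >= 2 are the
#' reportable familial clusters.
#'
#' @param g a `genealogy`.
#' @param cases case ids.
#' @return List of character vectors: disjoint sets whose union is
#'   `cases`, ordered by decreasing size.
#' @export
nonoverlapping_clusters <- function(g, cases) {
  stopifnot(inherits(g, "genealogy"))
  cases <- as.character(cases)
  if (length(cases) == 0L) return(list())
  case_idx <- .resolve_ids(g, cases)
  # two cases share a common ancestor iff they share an ancestral founder,
  # so union-find over each case's founder-ancestor set gives the components
  parent <- seq_len(nrow(g$df))
  find <- function(x) {
    while (parent[x] != x) {
      parent[x] <<- parent[parent[x]]
      x <- parent[x]
    }
    x
  }
  union_ <- function(a, b) {
    ra <- find(a); rb <- find(b)
    if (ra != rb) parent[rb] <<- ra
  }
  for (ci in case_idx) {
    anc <- .ancestor_idx(g, ci)
    roots <- anc[g$fid[anc] == 0L & g$mid[anc] == 0L]
    for (r in roots) union_(ci, r)
  }
  comp <- vapply(case_idx, find, integer(1))
  groups <- split(g$df$id[case_idx], comp)
  names(groups) <- NULL
  groups[order(-lengths(groups), vapply(groups, `[`, character(1), 1L))]
}

#' Poisson excess-case test for a founder pedigree
#'
#' The expected case count is the sum of cohort-specific rates over all
#' descendants of the founder; significance is the one-tailed Poisson
#' upper tail P(X >= observed) with mean equal to the expected count (the
#' same [poisson_upper_p()] used for relative risks). The degenerate
#' combination expected = 0 with observed > 0 is flagged with a warning
#' and the smallest representable p.
#'
#' @param ped a `founder_pedigree` from [founder_pedigrees()].
#' @param g the `genealogy` the pedigree came from.
#' @param rates a [build_rate_table()] result from the same genealogy.
#' @return The `founder_pedigree` with `expected` and `p` filled in.
#' @export
pedigree_excess_test <- function(ped, g, rates) {
  stopifnot(inherits(ped, "founder_pedigree"), inherits(g, "genealogy"))
  ped$expected <- sum(cohort_rates(g, rates, ped$descendants))
  if (ped$expected > 0) {
    ped$p <- poisson_upper_p(ped$observed, ped$expected)
  } else if (ped$observed > 0) {
    warning("expected count is 0 with observed > 0; reporting smallest ",
            "representable p for founder ", ped$founder)
    ped$p <- .Machine$double.xmin
  } else {
    ped$p <- 1
  }
  ped
}

#' Scan founder pedigrees for a significant excess of cases
#'
#' Runs [founder_pedigrees()] and [pedigree_excess_test()] over the whole
#' genealogy and flags pedigrees as high risk when the observed case count
#' significantly exceeds expectation (p < `alpha`, with at least
#' `min_cases` observed). No multiplicity correction is applied, by
#' design: the scan prioritizes sensitivity and the discrete Poisson test
#' is conservative (per-pedigree type-I error at most `alpha`). Pedigrees
#' of founder couples have identical descendant sets; by default only the
#' earlier-born founder of each such pair is reported.
#'
#' @param g a `genealogy`.
#' @param cases case ids.
#' @param rates optional rate table; built from `g` and `cases` if omitted.
#' @param alpha significance threshold (default 0.05).
#' @param min_cases minimum observed cases for a pedigree to be scanned.
#' @param dedupe drop later-born founders whose descendant set duplicates
#'   an earlier-born founder's (founder couples).
#' @return data.frame sorted by ascending p with columns `founder`,
#'   `n_descendants`, `observed`, `expected`, `p`, `high_risk`, plus the
#'   tested `founder_pedigree` objects in attribute `"pedigrees"`.
#' @export
high_risk_scan <- function(g, cases, rates = NULL, alpha = 0.05,
                           min_cases = 2L, dedupe = TRUE) {
  stopifnot(inherits(g, "genealogy"), alpha >= 0, alpha <= 1)
  cases <- as.character(cases)
  if (is.null(rates)) rates <- build_rate_table(g, cases)
  peds <- founder_pedigrees(g, cases, min_cases)
  if (dedupe && length(peds) > 1L) {
    keys <- vapply(peds, function(p)
      paste(sort(p$descendants), collapse = "\r"), character(1))
    peds <- peds[!duplicated(keys)]  # peds are sorted by founder birth year
  }
  peds <- lapply(peds, pedigree_excess_test, g = g, rates = rates)
  if (length(peds) == 0L) {
    out <- data.frame(founder = character(), n_descendants = integer(),
                      observed = integer(), expected = numeric(),
                      p = numeric(), high_risk = logical())
    attr(out, "pedigrees") <- list()
    return(out)
  }
  out <- data.frame(
    founder = vapply(peds, `[[`, character(1), "founder"),
    n_descendants = vapply(peds, function(p) length(p$descendants),
                           integer(1)),
    observed = vapply(peds, `[[`, integer(1), "observed"),
    expected = vapply(peds, `[[`, numeric(1), "expected"),
    p = vapply(peds, `[[`, numeric(1), "p"),
    stringsAsFactors = FALSE)
  out$high_risk <- out$p < alpha & out$observed >= 2L
  ord <- order(out$p, out$founder)
  out <- out[ord, ]
  rownames(out) <- NULL
  attr(out, "pedigrees") <- peds[ord]
  out
}
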