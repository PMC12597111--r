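#' Malecot kinship coefficient between two individuals
#'
#' The kinship coefficient phi(i, j) is the probability that one gene
#' sampled at random from i and one from j are identical by descent from a
#' shared ancestor recorded in the genealogy. Computed by the standard
#' recursion: phi(i, i) = (1 + phi(father_i, mother_i)) / 2 and, recursing
#' on whichever individual is not an ancestor of the other,
#' phi(i, j) = (phi(father_i, j) + phi(mother_i, j)) / 2, with a missing
#' parent contributing 0. Inbreeding loops are handled exactly, so
#' phi(i, i) exceeds 0.5 for inbred individuals.
#'
#' @param g a [genealogy()].
#' @param i,j individual ids (may be equal).
#' @return phi in \[0, 1\].
#' @seealso [kinship_matrix()] for the batch form, [gene_drop_kinship()] for
#'   a Monte Carlo oracle.
#' @export
kinship <- function(g, i, j) {
  stopifnot(inherits(g, "genealogy"))
  a <- .resolve_ids(g, i)
  b <- .resolve_ids(g, j)
  memo <- new.env(parent = emptyenv(), hash = TRUE)
  .phi_pair(g, a, b, memo)
}

# Memoized pairwise recursion, independent of the matrix recurrence so the
# two implementations can cross-check each other. Recurses on the individual
# with the larger generation number, which can never be an ancestor of the
# other (ancestors have strictly smaller generation numbers).
.phi_pair <- function(g, a, b, memo) {
  if (a == 0L || b == 0L) return(0)
  key <- if (a <= b) paste0(a, ":", b) else paste0(b, ":", a)
  hit <- memo[[key]]
  if (!is.null(hit)) return(hit)
  val <- if (a == b) {
    0.5 * (1 + .phi_pair(g, g$fid[a], g$mid[a], memo))
  } else {
    deep <- if (g$gen[a] >= g$gen[b]) a else b
    other <- if (deep == a) b else a
    if (g$fid[deep] == 0L && g$mid[deep] == 0L) {
      0  # founder vs a non-descendant
    } else {
      0.5 * (.phi_pair(g, g$fid[deep], other, memo) +
             .phi_pair(g, g$mid[deep], other, memo))
    }
  }
  memo[[key]] <- val
  val
}

#' Kinship matrix over a set of individuals
#'
#' Computes the full pedigree kinship matrix by the vectorized
#' parents-before-children recurrence (each row is the half-sum of the
#' parental rows; the diagonal is (1 + phi(father, mother)) / 2) and
#' returns the submatrix for `ids`. Runs in O(n^2) time and memory for a
#' genealogy of n individuals.
#'
#' @param g a `genealogy`.
#' @param ids ids of the rows/columns wanted; default all individuals.
#' @return Symmetric numeric matrix with `ids` as dimnames; diagonal
#'   >= 0.5.
#' @export
kinship_matrix <- function(g, ids = NULL) {
  stopifnot(inherits(g, "genealogy"))
  phi <- .phi_full(g)
  if (is.null(ids)) {
    dimnames(phi) <- list(g$df$id, g$df$id)
    return(phi)
  }
  idx <- .resolve_ids(g, ids)
  out <- phi[idx, idx, drop = FALSE]
  dimnames(out) <- list(as.character(ids), as.character(ids))
  out
}

.phi_full <- function(g) {
  n <- nrow(g$df)
  phi <- matrix(0, n, n)
  for (i in g$ord) {
    f <- g$fid[i]; m <- g$mid[i]
    if (f == 0L && m == 0L) {
      phi[i, i] <- 0.5
      next
    }
    v <- if (f > 0L && m > 0L) 0.5 * (phi[f, ] + phi[m, ])
         else if (f > 0L) 0.5 * phi[f, ]
         else 0.5 * phi[m, ]
    phi[i, ] <- v
    phi[, i] <- v
    phi[i, i] <- 0.5 * (1 + if (f > 0L && m > 0L) phi[f, m] else 0)
  }
  phi
}

#' Meiotic genetic distance between two individuals
#'
#' The minimum number of meioses on any valid genealogical path connecting
#' i and j, i.e. a path that ascends from each to a common ancestor
#' (possibly one of the pair). Parent-offspring pairs are at distance 1,
#' full or half siblings and grandparent-grandchild pairs at 2, avuncular
#' pairs at 3, first cousins at 4, second cousins at 6. `Inf` when the two
#' share no recorded common ancestor.
#'
#' @param g a `genealogy`.
#' @param i,j distinct individual ids.
#' @return Positive integer number of meioses, or `Inf`.
#' @export
genetic_distance <- function(g, i, j) {
  stopifnot(inherits(g, "genealogy"))
  a <- .resolve_ids(g, i)
  b <- .resolve_ids(g, j)
  if (a == b) stop("genetic distance requires two distinct individuals")
  ma <- .ancestor_meioses(g, a)
  mb <- .ancestor_meioses(g, b)
  shared <- intersect(names(ma), names(mb))
  if (length(shared) == 0L) return(Inf)
  min(ma[shared] + mb[shared])
}

# Named vector: minimum meiosis count from i up to each ancestor (self = 0).
.ancestor_meioses <- function(g, i) {
  res <- c(0L)
  names(res) <- i
  frontier <- i
  d <- 0L
  while (length(frontier) > 0L) {
    d <- d + 1L
    up <- c(g$fid[frontier], g$mid[frontier])
    up <- unique(up[up > 0L])
    up <- up[!as.character(up) %in% names(res)]  # keep the minimum count
    if (length(up) == 0L) break
    add <- rep(d, length(up))
    names(add) <- up
    res <- c(res, add)
    frontier <- up
  }
  res
}

#' Genetic distance matrix over a set of individuals
#'
#' Batch form of [genetic_distance()], computed by a vectorized
#' parents-before-children recurrence: a non-founder's row is
#' `pmin(row(father), row(mother)) + 1` and the diagonal is 0. Unrelated
#' pairs are `Inf`.
#'
#' @inheritParams kinship_matrix
#' @return Symmetric numeric matrix (entries positive integers or `Inf`).
#' @export
distance_matrix <- function(g, ids = NULL) {
  stopifnot(inherits(g, "genealogy"))
  D <- .dist_full(g)
  if (is.null(ids)) {
    dimnames(D) <- list(g$df$id, g$df$id)
    return(D)
  }
  idx <- .resolve_ids(g, ids)
  out <- D[idx, idx, drop = FALSE]
  dimnames(out) <- list(as.character(ids), as.character(ids))
  out
}

#' Gene-dropping Monte Carlo estimate of kinship
#'
#' Assigns every founder two unique alleles, transmits one uniformly chosen
#' parental allele per meiosis down the pedigree, and estimates phi(i, j)
#' as the fraction of simulated drops in which one allele sampled at random
#' from i matches (is identical by descent with) one sampled at random from
#' j. This is an unbiased estimator of the Malecot coefficient and serves
#' as an implementation-independent oracle for [kinship()]. An individual
#' with a missing parent receives a fresh unique allele on that side, which
#' is equivalent to an unrecorded unrelated founder parent.
#'
#' @param g a `genealogy` (intended for small pedigrees).
#' @param i,j individual ids (may be equal, estimating self-kinship).
#' @param n_drops number of simulated transmissions (>= 1e4 recommended).
#' @param seed integer seed; the estimate is deterministic given the seed.
#' @return Estimated phi.
#' @export
gene_drop_kinship <- function(g, i, j, n_drops = 1e5, seed = 1L) {
  stopifnot(inherits(g, "genealogy"), n_drops >= 1)
  a <- .resolve_ids(g, i)
  b <- .resolve_ids(g, j)
  n <- nrow(g$df)
  .with_seed(seed, {
    al1 <- vector("list", n)
    al2 <- vector("list", n)
    next_allele <- 0L
    for (k in g$ord) {
      f <- g$fid[k]; m <- g$mid[k]
      if (f > 0L) {
        pick <- stats::runif(n_drops) < 0.5
        al1[[k]] <- ifelse(pick, al1[[f]], al2[[f]])
      } else {
        next_allele <- next_allele + 1L
        al1[[k]] <- rep.int(next_allele, n_drops)
      }
      if (m > 0L) {
        pick <- stats::runif(n_drops) < 0.5
        al2[[k]] <- ifelse(pick, al1[[m]], al2[[m]])
      } else {
        next_allele <- next_allele + 1L
        al2[[k]] <- rep.int(next_allele, n_drops)
      }
    }
    pick_i <- stats::runif(n_drops) < 0.5
    pick_j <- stats::runif(n_drops) < 0.5
    gi <- ifelse(pick_i, al1[[a]], al2[[a]])
    gj <- ifelse(pick_j, al1[[b]], al2[[b]])
    mean(gi == gj)
  })
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards.
.with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}
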