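#' Genealogical Index of Familiality statistic
#'
#' The GIF of a set of individuals is the average pairwise Malecot kinship
#' over all unordered distinct pairs, multiplied by a scaling constant
#' (10^5 by convention, so population-scale values land in a readable
#' 0--10 range). Raw mean kinship is recovered by dividing by `scale`.
#'
#' @param g a [genealogy()].
#' @param ids ids of the case (or control) set; at least 2.
#' @param scale scaling constant (default 1e5).
#' @param kin optional precomputed kinship matrix for `ids` (as returned by
#'   [kinship_matrix()]), to avoid recomputation in resampling loops.
#' @return Nonnegative scalar.
#' @export
gif_statistic <- function(g, ids, scale = 1e5, kin = NULL) {
  if (is.null(kin)) {
    if (length(ids) < 2L) stop("GIF requires at least 2 individuals")
    kin <- kinship_matrix(g, ids)
  }
  if (nrow(kin) < 2L) stop("GIF requires at least 2 individuals")
  ut <- upper.tri(kin)
  scale * mean(kin[ut])
}

#' Distant GIF: familial aggregation beyond close relatives
#'
#' Identical to [gif_statistic()] except that pairs closer than
#' `min_distance` meioses contribute zero kinship. The pair count in the
#' denominator is unchanged, so dGIF is on the same scale as the GIF and
#' never exceeds it; dGIF equals GIF when no pair is closer than
#' `min_distance`. The default `min_distance = 3` removes parent-offspring,
#' sibling and grandparent-grandchild pairs, isolating more distant
#' aggregation.
#'
#' @inheritParams gif_statistic
#' @param min_distance smallest meiotic distance still included (>= 1).
#' @param dist optional precomputed distance matrix for `ids`.
#' @return Nonnegative scalar, at most `gif_statistic(g, ids)`.
#' @export
dgif_statistic <- function(g, ids, min_distance = 3L, scale = 1e5,
                           kin = NULL, dist = NULL) {
  stopifnot(min_distance >= 1L)
  if (is.null(kin)) {
    if (length(ids) < 2L) stop("dGIF requires at least 2 individuals")
    kin <- kinship_matrix(g, ids)
  }
  if (nrow(kin) < 2L) stop("dGIF requires at least 2 individuals")
  if (is.null(dist)) dist <- distance_matrix(g, rownames(kin))
  ut <- upper.tri(kin)
  contrib <- ifelse(dist[ut] >= min_distance, kin[ut], 0)
  scale * mean(contrib)
}

#' Decompose the GIF by pairwise genetic distance
#'
#' Partitions the GIF sum over pairs into bins by the pair's meiotic
#' genetic distance (1 = parent-offspring, 2 = sibling or
#' grandparent-grandchild, 3 = avuncular, 4 = first cousin, 6 = second
#' cousin, ...). Pairs with no common ancestor have zero kinship and fall
#' in no bin, so the bin values always sum to the GIF exactly.
#'
#' @inheritParams dgif_statistic
#' @return Named numeric vector; names are genetic distances, values are
#'   each bin's contribution to the GIF.
#' @export
distance_contributions <- function(g, ids, scale = 1e5, kin = NULL,
                                   dist = NULL) {
  if (is.null(kin)) {
    if (length(ids) < 2L) stop("GIF requires at least 2 individuals")
    kin <- kinship_matrix(g, ids)
  }
  if (nrow(kin) < 2L) stop("GIF requires at least 2 individuals")
  if (is.null(dist)) dist <- distance_matrix(g, rownames(kin))
  ut <- upper.tri(kin)
  phis <- kin[ut]
  ds <- dist[ut]
  keep <- is.finite(ds) & phis > 0
  npairs <- sum(ut)
  if (!any(keep)) return(stats::setNames(numeric(0), character(0)))
  sums <- tapply(phis[keep], ds[keep], sum)
  out <- scale * as.numeric(sums) / npairs
  names(out) <- names(sums)
  out[order(as.numeric(names(out)))]
}

#' Matching specification for control sampling
#'
#' Describes how controls are matched to cases: exactly on sex, birth
#' place and genealogical informativeness (at least `min_generations`
#' generations of recorded genealogy, as for the cases), and on birth year
#' within `birth_year_window` years.
#'
#' @param birth_year_window maximum |case birth year - control birth year|.
#' @param match_on subset of `c("sex", "birth_year", "birth_place",
#'   "informativeness")`.
#' @param min_generations informativeness threshold used when matching on
#'   informativeness (see [informative_cases()]).
#' @return An object of class `matching_spec`.
#' @export
matching_spec <- function(birth_year_window = 5L,
                          match_on = c("sex", "birth_year", "birth_place",
                                       "informativeness"),
                          min_generations = 3L) {
  stopifnot(birth_year_window >= 0L)
  match_on <- match.arg(match_on, several.ok = TRUE)
  structure(list(birth_year_window = as.integer(birth_year_window),
                 match_on = match_on,
                 min_generations = as.integer(min_generations)),
            class = "matching_spec")
}

#' Sample matched control sets
#'
#' Draws `n_sets` control sets, each containing one control per case,
#' sampled uniformly among the non-case individuals matching that case on
#' the attributes in `spec`. Within a set controls are sampled without
#' replacement (a person serves as control for at most one case per set);
#' across sets sampling is independent. Cases are never eligible as
#' controls. Output is deterministic given `seed`: set s consumes its own
#' substream seeded with `seed + s`.
#'
#' @param g a `genealogy`.
#' @param cases case ids.
#' @param spec a [matching_spec()].
#' @param n_sets number of control sets.
#' @param seed integer seed.
#' @return List of `n_sets` character vectors of control ids, each aligned
#'   with `cases`.
#' @export
sample_matched_controls <- function(g, cases, spec = matching_spec(),
                                    n_sets = 1000L, seed = 1L) {
  stopifnot(inherits(g, "genealogy"), inherits(spec, "matching_spec"),
            n_sets >= 1L)
  case_idx <- .resolve_ids(g, cases)
  pools <- .matching_pools(g, case_idx, spec)
  empty <- which(lengths(pools) == 0L)
  if (length(empty) > 0L) {
    i <- case_idx[empty[1L]]
    stop(sprintf(
      "no eligible control for case '%s' (sex %s, birth year %d, birth place %s)",
      g$df$id[i], g$df$sex[i], g$df$birth_year[i], g$df$birth_place[i]))
  }
  # sample tight strata first so within-set exhaustion is unlikely
  case_order <- order(lengths(pools))
  ids <- g$df$id
  lapply(seq_len(n_sets), function(s) {
    .with_seed(as.integer(seed) + s, {
      chosen <- integer(length(case_idx))
      taken <- integer(0)
      for (k in case_order) {
        avail <- setdiff(pools[[k]], taken)
        if (length(avail) == 0L) {
          stop(sprintf(
            "control stratum exhausted for case '%s' in set %d",
            ids[case_idx[k]], s))
        }
        pick <- avail[sample.int(length(avail), 1L)]
        chosen[k] <- pick
        taken <- c(taken, pick)
      }
      ids[chosen]
    })
  })
}

.matching_pools <- function(g, case_idx, spec) {
  df <- g$df
  n <- nrow(df)
  eligible <- rep(TRUE, n)
  eligible[case_idx] <- FALSE
  if ("informativeness" %in% spec$match_on) {
    depth <- generation_depth(g)
    informative <- depth >= spec$min_generations - 1L
  }
  lapply(case_idx, function(i) {
    ok <- eligible
    if ("sex" %in% spec$match_on) ok <- ok & df$sex == df$sex[i]
    if ("birth_year" %in% spec$match_on) {
      ok <- ok & abs(df$birth_year - df$birth_year[i]) <= spec$birth_year_window
    }
    if ("birth_place" %in% spec$match_on) {
      ok <- ok & df$birth_place == df$birth_place[i]
    }
    if ("informativeness" %in% spec$match_on) ok <- ok & informative == informative[i]
    which(ok)
  })
}

#' GIF test of excess relatedness against matched controls
#'
#' Computes the case GIF and dGIF, the same statistics for `n_sets`
#' matched control sets, and the empirical one-sided significance
#' p = (1 + #\{control sets with statistic >= case statistic\}) / (1 + n_sets)
#' (the add-one rule, so p is never exactly 0 and the smallest attainable
#' value with 1,000 sets is 1/1001). Also returns the per-genetic-distance
#' decomposition of the case GIF and the mean decomposition over control
#' sets, suitable for a distance-by-distance bar plot.
#'
#' @inheritParams sample_matched_controls
#' @param min_distance_dgif distance cutoff for the dGIF (default 3).
#' @param scale GIF scaling constant.
#' @return An object of class `gif_result`: a list with elements
#'   `n_cases`, `case_gif`, `control_gifs`, `mean_control_gif`,
#'   `p_gif`, `case_dgif`, `control_dgifs`, `mean_control_dgif`, `p_dgif`,
#'   `case_contributions`, `mean_control_contributions`, `n_sets`,
#'   `min_distance_dgif`, `scale`.
#' @export
gif_test <- function(g, cases, spec = matching_spec(), n_sets = 1000L,
                     min_distance_dgif = 3L, seed = 1L, scale = 1e5) {
  stopifnot(inherits(g, "genealogy"))
  if (length(cases) < 2L) stop("GIF test requires at least 2 cases")
  if (n_sets < 1L) stop("n_sets must be at least 1")
  cases <- as.character(cases)

  phi <- .phi_full(g)
  D <- .dist_full(g)
  idx_case <- .resolve_ids(g, cases)

  stat_set <- function(idx) {
    kin <- phi[idx, idx, drop = FALSE]
    dst <- D[idx, idx, drop = FALSE]
    ut <- upper.tri(kin)
    phis <- kin[ut]
    ds <- dst[ut]
    gif <- scale * mean(phis)
    dgif <- scale * mean(ifelse(ds >= min_distance_dgif, phis, 0))
    keep <- is.finite(ds) & phis > 0
    contrib <- if (any(keep)) {
      sums <- tapply(phis[keep], ds[keep], sum)
      stats::setNames(scale * as.numeric(sums) / sum(ut), names(sums))
    } else stats::setNames(numeric(0), character(0))
    list(gif = gif, dgif = dgif, contrib = contrib)
  }

  case_stats <- stat_set(idx_case)
  sets <- sample_matched_controls(g, cases, spec, n_sets, seed)
  ctrl <- lapply(sets, function(s) stat_set(.resolve_ids(g, s)))
  control_gifs <- vapply(ctrl, `[[`, numeric(1), "gif")
  control_dgifs <- vapply(ctrl, `[[`, numeric(1), "dgif")

  all_d <- sort(unique(as.numeric(c(names(case_stats$contrib),
                                    unlist(lapply(ctrl, function(x)
                                      names(x$contrib)))))))
  mean_contrib <- stats::setNames(numeric(length(all_d)), as.character(all_d))
  for (x in ctrl) {
    if (length(x$contrib)) {
      mean_contrib[names(x$contrib)] <-
        mean_contrib[names(x$contrib)] + x$contrib
    }
  }
  mean_contrib <- mean_contrib / n_sets
  case_contrib <- stats::setNames(numeric(length(all_d)), as.character(all_d))
  case_contrib[names(case_stats$contrib)] <- case_stats$contrib

  structure(list(
    n_cases = length(cases),
    case_gif = case_stats$gif,
    control_gifs = control_gifs,
    mean_control_gif = mean(control_gifs),
    p_gif = (1 + sum(control_gifs >= case_stats$gif)) / (1 + n_sets),
    case_dgif = case_stats$dgif,
    control_dgifs = control_dgifs,
    mean_control_dgif = mean(control_dgifs),
    p_dgif = (1 + sum(control_dgifs >= case_stats$dgif)) / (1 + n_sets),
    case_contributions = case_contrib,
    mean_control_contributions = mean_contrib,
    n_sets = n_sets,
    min_distance_dgif = min_distance_dgif,
    scale = scale
  ), class = "gif_result")
}

# Full-pedigree distance matrix without dimnames (internal fast path).
.dist_full <- function(g) {
  n <- nrow(g$df)
  D <- matrix(Inf, n, n)
  for (i in g$ord) {
    f <- g$fid[i]; m <- g$mid[i]
    if (f > 0L || m > 0L) {
      v <- if (f > 0L && m > 0L) pmin(D[f, ], D[m, ]) + 1
           else if (f > 0L) D[f, ] + 1 else D[m, ] + 1
      D[i, ] <- v
      D[, i] <- v
    }
    D[i, i] <- 0
  }
  D
}

#' @export
print.gif_result <- function(x, digits = 3, ...) {
  cat(sprintf("GIF test (%d cases, %d matched control sets)\n",
              x$n_cases, x$n_sets))
  cat(sprintf("  case GIF  %s   mean control GIF  %s   p = %s\n",
              format(x$case_gif, digits = digits),
              format(x$mean_control_gif, digits = digits),
              format(x$p_gif, digits = digits)))
  cat(sprintf("  case dGIF %s   mean control dGIF %s   p = %s  (distance >= %d)\n",
              format(x$case_dgif, digits = digits),
              format(x$mean_control_dgif, digits = digits),
              format(x$p_dgif, digits = digits),
              x$min_distance_dgif))
  if (length(x$case_contributions)) {
    cat("  contributions by genetic distance (case / mean control):\n")
    for (d in names(x$case_contributions)) {
      cat(sprintf("    d=%s: %s / %s\n", d,
                  format(x$case_contributions[[d]], digits = digits),
                  format(x$mean_control_contributions[[d]], digits = digits)))
    }
  }
  invisible(x)
}
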