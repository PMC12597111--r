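#' Cohort-specific incidence rates
#'
#' Groups every individual into a cohort defined by sex, a 5-year birth
#' interval and a binarized birth place (in-state vs out-of-state), and
#' computes each cohort's incidence proportion as cases divided by total
#' individuals in the cohort. The full genealogy population forms the
#' denominator; cases are not excluded. Cohorts with no individuals do not
#' appear.
#'
#' @param g a [genealogy()].
#' @param cases case ids (default: the affected individuals in `g`).
#' @param bin_width width of the birth-year bins in years.
#' @param anchor bins start at years congruent to `anchor` modulo
#'   `bin_width` (default 0, i.e. 1930--1934, 1935--1939, ...).
#' @param in_state the `birth_place` value treated as in-state; all other
#'   values are binned together as out-of-state.
#' @return A data.frame of class `rate_table` with columns `sex`,
#'   `birth_interval` (bin start year), `birth_place`, `n`, `cases`,
#'   `rate`, carrying the binning parameters as attributes.
#' @export
build_rate_table <- function(g, cases = NULL, bin_width = 5L, anchor = 0L,
                             in_state = "in_state") {
  stopifnot(inherits(g, "genealogy"))
  if (is.null(cases)) cases <- g$df$id[g$df$affected]
  is_case <- g$df$id %in% as.character(cases)
  key <- .cohort_keys(g$df, bin_width, anchor, in_state)
  key$n <- 1L
  key$cases <- as.integer(is_case)
  agg <- stats::aggregate(cbind(n, cases) ~ sex + birth_interval + birth_place,
                          data = key, FUN = sum)
  agg$rate <- agg$cases / agg$n
  agg <- agg[order(agg$sex, agg$birth_interval, agg$birth_place), ]
  rownames(agg) <- NULL
  structure(agg, class = c("rate_table", "data.frame"),
            bin_width = as.integer(bin_width), anchor = as.integer(anchor),
            in_state = in_state)
}

.cohort_keys <- function(df, bin_width, anchor, in_state) {
  data.frame(
    sex = df$sex,
    birth_interval = floor((df$birth_year - anchor) / bin_width) * bin_width +
      anchor,
    birth_place = ifelse(df$birth_place == in_state, "in_state",
                         "out_of_state"),
    stringsAsFactors = FALSE)
}

#' Per-individual cohort rates
#'
#' Looks up each individual's cohort rate in a [build_rate_table()] result;
#' the building block for expected case counts among relatives and
#' pedigree descendants.
#'
#' @param g a `genealogy`.
#' @param rates a `rate_table` built from the same genealogy.
#' @param ids ids to look up (default all).
#' @return Named numeric vector of rates.
#' @export
cohort_rates <- function(g, rates, ids = NULL) {
  stopifnot(inherits(g, "genealogy"), inherits(rates, "rate_table"))
  df <- if (is.null(ids)) g$df else g$df[.resolve_ids(g, ids), ]
  key <- .cohort_keys(df, attr(rates, "bin_width"), attr(rates, "anchor"),
                      attr(rates, "in_state"))
  k <- paste(key$sex, key$birth_interval, key$birth_place, sep = "\r")
  kr <- paste(rates$sex, rates$birth_interval, rates$birth_place, sep = "\r")
  out <- rates$rate[match(k, kr)]
  out[is.na(out)] <- 0  # cohorts absent from the table carry no cases
  names(out) <- df$id
  out
}

.parents_of <- function(g, i) c(g$fid[i], g$mid[i])[c(g$fid[i], g$mid[i]) > 0L]

.full_sibs <- function(g, i) {
  f <- g$fid[i]; m <- g$mid[i]
  if (f == 0L || m == 0L) return(integer(0))
  sibs <- intersect(g$kids[[f]], g$kids[[m]])
  setdiff(sibs, i)
}

.half_sibs <- function(g, i) {
  f <- g$fid[i]; m <- g$mid[i]
  through <- integer(0)
  if (f > 0L) through <- c(through, g$kids[[f]])
  if (m > 0L) through <- c(through, g$kids[[m]])
  shared <- if (f > 0L && m > 0L) intersect(g$kids[[f]], g$kids[[m]]) else
    integer(0)
  setdiff(unique(through), c(i, shared))
}

#' Enumerate relatives of a given genetic degree
#'
#' Degree 1: parents, offspring and full siblings. Degree 2: grandparents,
#' grandchildren, (full) aunts/uncles, nieces/nephews and half-siblings.
#' Degree 3: great-grandparents, great-grandchildren, first cousins,
#' half-aunts/uncles, half-nieces/nephews, grand-aunts/uncles and
#' grand-nieces/nephews. An individual qualifying at several degrees (as
#' can happen in inbred pedigrees) is reported once, at the lowest degree,
#' so the three sets are disjoint; the index individual is never included.
#'
#' @param g a `genealogy`.
#' @param i an individual id.
#' @param degree 1, 2 or 3.
#' @return Character vector of relative ids.
#' @export
enumerate_relatives <- function(g, i, degree) {
  stopifnot(inherits(g, "genealogy"), degree %in% 1:3)
  idx <- .resolve_ids(g, i)
  sets <- .relative_sets(g, idx)
  g$df$id[sets[[degree]]]
}

.relative_sets <- function(g, idx) {
  parents <- .parents_of(g, idx)
  offspring <- g$kids[[idx]]
  fsibs <- .full_sibs(g, idx)
  d1 <- unique(c(parents, offspring, fsibs))

  grandparents <- unique(unlist(lapply(parents, .parents_of, g = g)))
  grandchildren <- unique(unlist(lapply(offspring, function(k) g$kids[[k]])))
  aunts <- unique(unlist(lapply(parents, .full_sibs, g = g)))
  niblings <- unique(unlist(lapply(fsibs, function(k) g$kids[[k]])))
  hsibs <- .half_sibs(g, idx)
  d2 <- setdiff(unique(c(grandparents, grandchildren, aunts, niblings,
                         hsibs)), c(idx, d1))

  greatgp <- unique(unlist(lapply(grandparents, .parents_of, g = g)))
  greatgc <- unique(unlist(lapply(grandchildren, function(k) g$kids[[k]])))
  cousins <- unique(unlist(lapply(aunts, function(k) g$kids[[k]])))
  half_aunts <- unique(unlist(lapply(parents, .half_sibs, g = g)))
  half_nib <- unique(unlist(lapply(hsibs, function(k) g$kids[[k]])))
  grand_aunts <- unique(unlist(lapply(grandparents, .full_sibs, g = g)))
  grand_nib <- unique(unlist(lapply(niblings, function(k) g$kids[[k]])))
  d3 <- setdiff(unique(c(greatgp, greatgc, cousins, half_aunts, half_nib,
                         grand_aunts, grand_nib)), c(idx, d1, d2))

  list(as.integer(d1), as.integer(d2), as.integer(d3))
}

#' Observed and expected affected relatives at a given degree
#'
#' Forms the union over all cases of their degree-`degree` relative sets
#' (each person counted once even when related to several cases), counts
#' the affected individuals in that union (a case who is also a relative
#' of another case counts), and sums each union member's cohort rate to
#' obtain the expected count.
#'
#' @param g a `genealogy`.
#' @param cases case ids.
#' @param degree 1, 2 or 3.
#' @param rates a [build_rate_table()] result from the same genealogy.
#' @return List with `n_relatives`, `observed`, `expected`.
#' @export
observed_expected <- function(g, cases, degree, rates) {
  stopifnot(inherits(g, "genealogy"))
  cases <- as.character(cases)
  if (length(cases) == 0L) return(list(n_relatives = 0L, observed = 0L,
                                       expected = 0))
  idx <- .resolve_ids(g, cases)
  rel <- unique(unlist(lapply(idx, function(i) .relative_sets(g, i)[[degree]])))
  if (length(rel) == 0L) return(list(n_relatives = 0L, observed = 0L,
                                     expected = 0))
  ids <- g$df$id[rel]
  list(n_relatives = length(rel),
       observed = sum(ids %in% cases),
       expected = sum(cohort_rates(g, rates, ids)))
}

#' Relative risk as observed over expected
#'
#' @param observed observed affected count.
#' @param expected expected count under cohort rates; must be positive.
#' @return `observed / expected`.
#' @export
relative_risk <- function(observed, expected) {
  if (expected <= 0) stop("relative risk undefined: expected count is 0")
  observed / expected
}

#' One-tailed Poisson excess probability
#'
#' P(X >= observed) for X ~ Poisson(expected): the probability of seeing
#' at least the observed case count if cases arose independently at the
#' cohort rates. Returns 1 when `observed` is 0.
#'
#' @param observed observed count (nonnegative integer).
#' @param expected Poisson mean (positive).
#' @return Upper-tail probability.
#' @export
poisson_upper_p <- function(observed, expected) {
  stopifnot(observed >= 0, expected > 0)
  stats::ppois(observed - 1, expected, lower.tail = FALSE)
}

#' Small-sample confidence interval for a relative risk
#'
#' Confidence interval for RR = observed / expected obtained by inverting
#' one-sided small-sample Poisson tests of H0: RR = r (under which the
#' observed count is Poisson with mean r * expected), in the spirit of
#' Agresti and Min's test-inversion intervals for discrete data. The
#' default `"midp"` flavor inverts mid-P tails (half weight on the
#' observed outcome), giving intervals never wider than the conservative
#' `"exact"` (Garwood) inversion, which is also available. Bounds are
#' found by monotone root-finding to `tol`.
#'
#' @param observed observed count.
#' @param expected expected count (positive).
#' @param level confidence level in (0, 1), default 0.95.
#' @param flavor `"midp"` (default) or `"exact"`.
#' @param tol root-finding tolerance on the Poisson-mean scale.
#' @return Numeric vector `c(low, high)`; `low` is 0 when `observed` is 0.
#'   Contains `observed / expected` whenever `observed > 0`.
#' @export
agresti_min_ci <- function(observed, expected, level = 0.95,
                           flavor = c("midp", "exact"), tol = 1e-6) {
  stopifnot(observed >= 0, expected > 0, level > 0, level < 1)
  flavor <- match.arg(flavor)
  alpha <- 1 - level
  o <- as.integer(observed)
  if (flavor == "exact") {
    low <- if (o == 0L) 0 else stats::qgamma(alpha / 2, o) / expected
    high <- stats::qgamma(1 - alpha / 2, o + 1) / expected
    return(c(low = low, high = high))
  }
  # mid-P inversion: tail probability with half weight on X = observed
  upper_tail <- function(mu) {
    stats::ppois(o - 1, mu, lower.tail = FALSE) - 0.5 * stats::dpois(o, mu)
  }
  lower_tail <- function(mu) {
    stats::ppois(o, mu) - 0.5 * stats::dpois(o, mu)
  }
  hi_bracket <- stats::qgamma(1 - alpha / 4, o + 1) + 1
  low <- if (o == 0L) 0 else {
    stats::uniroot(function(mu) upper_tail(mu) - alpha / 2,
                   lower = tol * 1e-3, upper = hi_bracket,
                   tol = tol)$root / expected
  }
  high <- stats::uniroot(function(mu) lower_tail(mu) - alpha / 2,
                         lower = tol * 1e-3, upper = hi_bracket,
                         tol = tol)$root / expected
  c(low = low, high = high)
}

#' Familial relative risks for first- to third-degree relatives
#'
#' One row per relationship degree: the number of distinct relatives of the
#' cases, observed and expected affected counts among them, the relative
#' risk, its confidence interval ([agresti_min_ci()]) and the one-tailed
#' Poisson significance ([poisson_upper_p()]). When the expected count is
#' 0 the RR, interval and p-value are reported as `NA` (flagged
#' degenerate) rather than raising an error.
#'
#' @param g a `genealogy`.
#' @param cases case ids (must be nonempty).
#' @param rates optional [build_rate_table()] result; built from `g` and
#'   `cases` when omitted.
#' @param degrees subset of 1:3.
#' @param level confidence level for the RR interval.
#' @param flavor interval flavor, see [agresti_min_ci()].
#' @return data.frame with columns `degree`, `n_relatives`, `observed`,
#'   `expected`, `rr`, `ci_low`, `ci_high`, `p`.
#' @export
familial_rr_report <- function(g, cases, rates = NULL, degrees = 1:3,
                               level = 0.95, flavor = "midp") {
  stopifnot(inherits(g, "genealogy"))
  cases <- as.character(cases)
  if (length(cases) == 0L) stop("familial_rr_report requires at least 1 case")
  if (is.null(rates)) rates <- build_rate_table(g, cases)
  rows <- lapply(degrees, function(d) {
    oe <- observed_expected(g, cases, d, rates)
    if (oe$expected > 0) {
      ci <- agresti_min_ci(oe$observed, oe$expected, level = level,
                           flavor = flavor)
      data.frame(degree = d, n_relatives = oe$n_relatives,
                 observed = oe$observed, expected = oe$expected,
                 rr = relative_risk(oe$observed, oe$expected),
                 ci_low = ci[["low"]], ci_high = ci[["high"]],
                 p = poisson_upper_p(oe$observed, oe$expected))
    } else {
      data.frame(degree = d, n_relatives = oe$n_relatives,
                 observed = oe$observed, expected = 0,
                 rr = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 p = NA_real_)
    }
  })
  do.call(rbind, rows)
}
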