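#' Parameters for the forward-time genealogy simulator
#'
#' Defaults emulate, at desk scale, the structure a familial-clustering
#' analysis needs from a population genealogy: a founding generation in
#' the mid-1800s, non-overlapping generations roughly 28 years apart,
#' couples with Poisson offspring counts, and a stream of immigrant
#' spouses marrying into the genealogy so that sibships, avuncular pairs,
#' cousins and second cousins all arise. The defaults yield genealogies
#' of roughly two thousand individuals over five generations.
#'
#' @param n_founders founding-generation size.
#' @param n_generations total number of generations (1 = founders only).
#' @param mean_offspring Poisson mean number of children per couple.
#' @param immigration_rate probability that a person marries an immigrant
#'   (a fresh unrelated founder) even when eligible partners exist within
#'   their generation.
#' @param birth_year_start mean founder birth year.
#' @param generation_gap_years mean years between parent and child births.
#' @param p_in_state probability an individual is born in state.
#' @return List of class `sim_params`.
#' @export
sim_params <- function(n_founders = 65L, n_generations = 5L,
                       mean_offspring = 3, immigration_rate = 0.2,
                       birth_year_start = 1850L, generation_gap_years = 28,
                       p_in_state = 0.8) {
  stopifnot(n_founders >= 2L, n_generations >= 1L, mean_offspring > 0,
            immigration_rate >= 0, immigration_rate <= 1,
            p_in_state >= 0, p_in_state <= 1)
  structure(list(n_founders = as.integer(n_founders),
                 n_generations = as.integer(n_generations),
                 mean_offspring = mean_offspring,
                 immigration_rate = immigration_rate,
                 birth_year_start = as.integer(birth_year_start),
                 generation_gap_years = generation_gap_years,
                 p_in_state = p_in_state),
            class = "sim_params")
}

#' Simulate a multigenerational genealogy
#'
#' Forward-time simulation with non-overlapping generations. Founders are
#' created with sexes in 1:1 expectation, normally scattered birth years
#' and in-state/out-of-state birth places. Each subsequent generation is
#' formed by pairing the previous generation's members while avoiding
#' full- and half-sibling unions (immigrant spouses resolve any shortage
#' of eligible partners, so pairing never fails), drawing each couple's
#' offspring count from a Poisson distribution, and assigning child birth
#' years as the parental mean plus the generation gap plus noise (always
#' at least 16 years after both parents). All phenotypes are initialized
#' unaffected; see [assign_phenotypes_null()] and
#' [assign_phenotypes_clustered()].
#'
#' @param params a [sim_params()].
#' @param seed integer seed; output is deterministic given the seed.
#' @return A validated [genealogy()].
#' @export
simulate_genealogy <- function(params = sim_params(), seed = 1L) {
  stopifnot(inherits(params, "sim_params"))
  .with_seed(seed, .simulate_genealogy_impl(params))
}

.simulate_genealogy_impl <- function(params) {
  chunks <- list()
  next_id <- 0L
  make_ids <- function(k) {
    out <- sprintf("I%06d", next_id + seq_len(k))
    next_id <<- next_id + k
    out
  }
  # each chunk: data.frame(id, father_id, mother_id, sex, birth_year)
  add_chunk <- function(ids, sex, by, f = NA_character_, m = NA_character_) {
    chunks[[length(chunks) + 1L]] <<- data.frame(
      id = ids, father_id = f, mother_id = m, sex = sex,
      birth_year = as.integer(by), stringsAsFactors = FALSE)
  }

  nf <- params$n_founders
  fids <- make_ids(nf)
  fsex <- ifelse(stats::runif(nf) < 0.5, "M", "F")
  fby <- round(params$birth_year_start + stats::rnorm(nf, 0, 5))
  add_chunk(fids, fsex, fby)
  # current generation, with each member's parent ids for sib avoidance
  cur <- data.frame(id = fids, sex = fsex, by = fby,
                    f = NA_character_, m = NA_character_,
                    stringsAsFactors = FALSE)

  n_rounds <- params$n_generations - 1L
  t <- 0L
  while (t < n_rounds && nrow(cur) > 0L) {
    t <- t + 1L
    males <- cur[cur$sex == "M", ][sample.int(sum(cur$sex == "M")), ]
    females <- cur[cur$sex == "F", ][sample.int(sum(cur$sex == "F")), ]

    # random assortment: immigrating males step aside, the rest take the
    # shuffled females in order; sibling conflicts fall back to immigrants
    local <- stats::runif(nrow(males)) >= params$immigration_rate
    mloc <- males[local, ]
    k <- min(nrow(mloc), nrow(females))
    hus <- mloc[seq_len(k), ]
    wif <- females[seq_len(k), ]
    conflict <- (!is.na(hus$f) & !is.na(wif$f) & hus$f == wif$f) |
                (!is.na(hus$m) & !is.na(wif$m) & hus$m == wif$m)
    couples_m <- hus$id[!conflict]
    couples_f <- wif$id[!conflict]
    couples_by <- (hus$by[!conflict] + wif$by[!conflict]) / 2
    couples_max <- pmax(hus$by[!conflict], wif$by[!conflict])

    # males without a local wife marry immigrants
    solo_m <- rbind(males[!local, c("id", "by")],
                    hus[conflict, c("id", "by")],
                    if (nrow(mloc) > k) mloc[-seq_len(k), c("id", "by")])
    if (nrow(solo_m) > 0L) {
      w_ids <- make_ids(nrow(solo_m))
      w_by <- solo_m$by + sample(-3:3, nrow(solo_m), replace = TRUE)
      add_chunk(w_ids, "F", w_by)
      couples_m <- c(couples_m, solo_m$id)
      couples_f <- c(couples_f, w_ids)
      couples_by <- c(couples_by, (solo_m$by + w_by) / 2)
      couples_max <- c(couples_max, pmax(solo_m$by, w_by))
    }
    # females left over marry immigrants
    solo_f <- rbind(if (nrow(females) > k) females[-seq_len(k), c("id", "by")],
                    wif[conflict, c("id", "by")])
    if (nrow(solo_f) > 0L) {
      h_ids <- make_ids(nrow(solo_f))
      h_by <- solo_f$by + sample(-3:3, nrow(solo_f), replace = TRUE)
      add_chunk(h_ids, "M", h_by)
      couples_m <- c(couples_m, h_ids)
      couples_f <- c(couples_f, solo_f$id)
      couples_by <- c(couples_by, (solo_f$by + h_by) / 2)
      couples_max <- c(couples_max, pmax(solo_f$by, h_by))
    }

    nkids <- stats::rpois(length(couples_m), params$mean_offspring)
    tot <- sum(nkids)
    if (tot == 0L) break
    cidx <- rep.int(seq_along(couples_m), nkids)
    gaps <- pmax(16, round(params$generation_gap_years +
                             stats::rnorm(tot, 0, 5)))
    child_by <- round(couples_by[cidx]) + gaps +
      sample(-2:8, tot, replace = TRUE)
    # children must be born after both parents
    child_by <- pmax(child_by, couples_max[cidx] + 16L)
    child_sex <- ifelse(stats::runif(tot) < 0.5, "M", "F")
    child_ids <- make_ids(tot)
    add_chunk(child_ids, child_sex, child_by,
              f = couples_m[cidx], m = couples_f[cidx])
    cur <- data.frame(id = child_ids, sex = child_sex, by = child_by,
                      f = couples_m[cidx], m = couples_f[cidx],
                      stringsAsFactors = FALSE)
  }

  df <- do.call(rbind, chunks)
  df$birth_place <- ifelse(stats::runif(nrow(df)) < params$p_in_state,
                           "in_state", "out_of_state")
  df$affected <- FALSE
  genealogy(df)
}

#' Assign phenotypes independently of family structure (null model)
#'
#' Every individual is affected independently with their cohort rate (or
#' a single scalar rate), so any apparent familial clustering is purely
#' sampling noise. This is the calibration model for the GIF test: under
#' it the empirical p-value is approximately uniform.
#'
#' @param g a `genealogy`.
#' @param rate scalar probability, or a [build_rate_table()] result giving
#'   per-cohort probabilities.
#' @param seed integer seed.
#' @return Character vector of case ids.
#' @export
assign_phenotypes_null <- function(g, rate = 0.008, seed = 1L) {
  stopifnot(inherits(g, "genealogy"))
  p <- if (inherits(rate, "rate_table")) cohort_rates(g, rate)
       else rep(rate, nrow(g$df))
  stopifnot(all(p >= 0 & p <= 1))
  .with_seed(seed, g$df$id[stats::runif(nrow(g$df)) < p])
}

#' Familially clustered phenotype model (carrier transmission)
#'
#' @param baseline_rate per-individual baseline affection probability.
#' @param familial_multiplier risk multiplier applied to carriers (>= 1).
#' @param carrier_founder_fraction fraction of founders seeded as risk
#'   carriers.
#' @param transmission_probability per-parent probability that carrier
#'   status transmits to a child (0.5 emulates a dominant rare variant).
#' @return List of class `phenotype_model`.
#' @export
phenotype_model <- function(baseline_rate = 0.008, familial_multiplier = 13,
                            carrier_founder_fraction = 0.05,
                            transmission_probability = 0.5) {
  stopifnot(baseline_rate >= 0, baseline_rate <= 1, familial_multiplier >= 1,
            carrier_founder_fraction >= 0, carrier_founder_fraction <= 1,
            transmission_probability >= 0, transmission_probability <= 1)
  structure(list(baseline_rate = baseline_rate,
                 familial_multiplier = familial_multiplier,
                 carrier_founder_fraction = carrier_founder_fraction,
                 transmission_probability = transmission_probability),
            class = "phenotype_model")
}

#' Assign phenotypes with familial clustering via carrier transmission
#'
#' Seeds carrier status in a fraction of the founders, transmits it to
#' each child independently with the transmission probability per carrier
#' parent, and affects carriers with the baseline probability times the
#' familial multiplier (clipped to 1) and non-carriers with the baseline
#' probability. With multiplier 1 this reduces exactly to the null model.
#' The resulting vertical (parent-offspring, avuncular) excess is the
#' clustering signal the GIF test is powered against.
#'
#' @param g a `genealogy`.
#' @param model a [phenotype_model()].
#' @param seed integer seed.
#' @return Character vector of case ids; carrier ids in attribute
#'   `"carriers"`.
#' @export
assign_phenotypes_clustered <- function(g, model = phenotype_model(),
                                        seed = 1L) {
  stopifnot(inherits(g, "genealogy"), inherits(model, "phenotype_model"))
  .with_seed(seed, {
    n <- nrow(g$df)
    carrier <- logical(n)
    is_founder <- g$fid == 0L & g$mid == 0L
    carrier[is_founder] <-
      stats::runif(sum(is_founder)) < model$carrier_founder_fraction
    tau <- model$transmission_probability
    for (i in g$ord) {
      if (is_founder[i]) next
      p_inherit <- 1 -
        (1 - tau * (g$fid[i] > 0L && carrier[g$fid[i]])) *
        (1 - tau * (g$mid[i] > 0L && carrier[g$mid[i]]))
      carrier[i] <- stats::runif(1) < p_inherit
    }
    p <- ifelse(carrier,
                pmin(1, model$baseline_rate * model$familial_multiplier),
                model$baseline_rate)
    cases <- g$df$id[stats::runif(n) < p]
    attr(cases, "carriers") <- g$df$id[carrier]
    cases
  })
}

#' Assign phenotypes with a calibrated injected degree-1 relative risk
#'
#' A benchmark generator whose parameter is the degree-1 relative risk the
#' standard observed/expected estimator should recover, used for
#' parameter-recovery testing. Baseline probands are drawn independently
#' at `base_rate`; every first-degree relative of a proband then receives
#' an additional independent affection draw. The extra probability is
#' calibrated analytically (see the methods vignette): a symmetric
#' elevation with per-relative multiplier m' yields a pairwise degree-1
#' relative risk of about 2m' - 1, while the estimator's expected counts
#' are inflated twice by the excess cases themselves: the population
#' cohort rates rise by the factor (1 + rbar (m' - 1) base_rate), with
#' rbar the mean first-degree family size, and each affected relative
#' additionally inflates its own (finite) cohort's realized rate, scaling
#' expected counts by about 1 / (1 - rr h) with h the mean reciprocal
#' cohort size. m' therefore solves
#' (2m' - 1)(1 - rr h) = rr (1 + rbar (m' - 1) base_rate)^2.
#' Both corrections vanish as the genealogy grows; the cohort binning is
#' the [build_rate_table()] default that [familial_rr_report()] also uses.
#'
#' @param g a `genealogy`.
#' @param base_rate baseline affection probability (small).
#' @param rr target degree-1 relative risk (>= 1).
#' @param seed integer seed.
#' @return Character vector of case ids.
#' @export
assign_phenotypes_familial_rr <- function(g, base_rate = 0.004, rr = 6,
                                          seed = 1L) {
  stopifnot(inherits(g, "genealogy"), base_rate > 0, base_rate < 0.5, rr >= 1)
  n <- nrow(g$df)
  # mean first-degree family size: parents + children + full sibs
  npar <- (g$fid > 0L) + (g$mid > 0L)
  nchild <- lengths(g$kids)
  pk <- paste(g$fid, g$mid)
  sibsize <- ave(rep(1L, n), pk, FUN = sum)
  nsib <- ifelse(g$fid > 0L & g$mid > 0L, sibsize - 1L, 0L)
  rbar <- mean(npar + nchild + nsib)
  # mean reciprocal cohort size under the default rate-table binning
  ck <- .cohort_keys(g$df, 5L, 0L, "in_state")
  ckey <- paste(ck$sex, ck$birth_interval, ck$birth_place)
  h <- mean(1 / table(ckey)[ckey])

  mprime <- .solve_elevation(rr, rbar, base_rate, h)
  extra_p <- min(1, (mprime - 1) * base_rate)

  .with_seed(seed, {
    probands <- which(stats::runif(n) < base_rate)
    elevated <- integer(0)
    if (length(probands) > 0L && extra_p > 0) {
      elevated <- unique(unlist(lapply(probands, function(i)
        .relative_sets(g, i)[[1L]])))
    }
    extra <- elevated[stats::runif(length(elevated)) < extra_p]
    g$df$id[sort(unique(c(probands, extra)))]
  })
}

# Solve (2m' - 1)(1 - rr h) = rr (1 + rbar (m' - 1) lambda)^2 for the
# smallest root m' >= 1; errors when the target rr is unattainable at
# this rate or the cohorts are too small (rr h >= 1).
.solve_elevation <- function(rr, rbar, lambda, h = 0) {
  if (rr == 1) return(1)
  if (rr * h >= 1) {
    stop("cohorts too small for the target relative risk: ",
         "the finite-cohort rate inflation exceeds the signal")
  }
  f <- function(m) (2 * m - 1) * (1 - rr * h) -
    rr * (1 + rbar * (m - 1) * lambda)^2
  upper <- 1
  repeat {
    upper <- upper * 2
    if (f(upper) > 0) break
    if (upper > 1e6) stop(
      "target degree-1 relative risk unattainable at this baseline rate: ",
      "the injected excess would inflate the cohort rates too much")
  }
  lo <- 1
  # f(1) = 1 - rr < 0, f(upper) > 0: bisect to the smallest crossing
  stats::uniroot(f, lower = lo, upper = upper, tol = 1e-9)$root
}

#' Deterministic high-risk example pedigree
#'
#' A hand-built four-generation, ~40-person pedigree descending from a
#' single founding couple, with exactly four affected descendants. One
#' second-generation son has offspring with two different partners, so
#' half-sibling lineages are present. The cases are placed so that the
#' affected pairs fall at genetic distances 1 (parent-offspring), 3
#' (avuncular, one of them through a half-sibship) and 4 (first cousins);
#' there are no affected sibling or grandparent-grandchild pairs
#' (distance 2). Used across examples and tests.
#'
#' @return List with elements `genealogy` and `cases` (character ids).
#' @export
example_high_risk_pedigree <- function() {
  r <- function(id, f, m, sex, by, place = "in_state", aff = 0L) {
    data.frame(id = id, father_id = f, mother_id = m, sex = sex,
               birth_year = by, birth_place = place, affected = aff,
               stringsAsFactors = FALSE)
  }
  rows <- rbind(
    r("F01", "0", "0", "M", 1830),                 # founding couple
    r("F02", "0", "0", "F", 1832),
    # generation 2: son S with two partners, daughter T
    r("S01", "F01", "F02", "M", 1856),
    r("P01", "0", "0", "F", 1858),                 # S's first partner
    r("P02", "0", "0", "F", 1861, "out_of_state"), # S's second partner
    r("T01", "F01", "F02", "F", 1858),
    r("T01h", "0", "0", "M", 1855),
    # generation 3: children of S + P1
    r("C01", "S01", "P01", "M", 1880, aff = 1L),
    r("C02", "S01", "P01", "F", 1882),
    # child of S + P2 (half-sib of C01/C02)
    r("C03", "S01", "P02", "M", 1886),
    # children of T + T01h
    r("C04", "T01h", "T01", "M", 1881),
    r("C05", "T01h", "T01", "F", 1884),
    # generation-3 spouses
    r("C01w", "0", "0", "F", 1882),
    r("C02h", "0", "0", "M", 1879),
    r("C03w", "0", "0", "F", 1887, "out_of_state"),
    r("C04w", "0", "0", "F", 1883),
    r("C05h", "0", "0", "M", 1881),
    # generation 4
    r("D01", "C01", "C01w", "M", 1905, aff = 1L),
    r("D02", "C01", "C01w", "F", 1907),
    r("D03", "C02h", "C02", "M", 1906, aff = 1L),
    r("D04", "C02h", "C02", "F", 1909),
    r("D05", "C03", "C03w", "M", 1910, aff = 1L),
    r("D06", "C03", "C03w", "F", 1912),
    r("D07", "C04", "C04w", "M", 1907),
    r("D08", "C04", "C04w", "F", 1910),
    r("D09", "C05h", "C05", "M", 1908),
    # generation-4 spouses and a fifth generation sample
    r("D01w", "0", "0", "F", 1906),
    r("D03w", "0", "0", "F", 1908),
    r("D07w", "0", "0", "F", 1909),
    r("E01", "D01", "D01w", "M", 1931),
    r("E02", "D01", "D01w", "F", 1933),
    r("E03", "D03", "D03w", "M", 1932),
    r("E04", "D07", "D07w", "M", 1933),
    r("E05", "D07", "D07w", "F", 1936),
    # unrelated context families
    r("U01", "0", "0", "M", 1855),
    r("U02", "0", "0", "F", 1857),
    r("U03", "U01", "U02", "M", 1881),
    r("U04", "U01", "U02", "F", 1883),
    r("U05w", "0", "0", "F", 1884),
    r("U06", "U03", "U05w", "M", 1908)
  )
  g <- genealogy(rows)
  list(genealogy = g, cases = c("C01", "D01", "D03", "D05"))
}
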