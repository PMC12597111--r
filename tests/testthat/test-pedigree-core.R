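test_that("a minimal pedigree file parses with correct links", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("f1\t0\t0\tM\t1900\tin_state\t0",
               "m1\t0\t0\tF\t1902\tin_state\t0",
               "k1\tf1\tm1\tF\t1925\tin_state\t1"), path)
  g <- read_pedigree(path)
  expect_equal(nrow(g$df), 3L)
  k <- g$df[g$df$id == "k1", ]
  expect_equal(k$father_id, "f1")
  expect_equal(k$mother_id, "m1")
  expect_true(k$affected)
  expect_equal(founders(g), c("f1", "m1"))
})

test_that("header lines are detected by a non-numeric birth_year field", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tfather_id\tmother_id\tsex\tbirth_year\tbirth_place\taffected",
               "f1\t0\t0\tM\t1900\tin_state\t0",
               "m1\t0\t0\tF\t1902\tin_state\t0"), path)
  expect_equal(nrow(read_pedigree(path)$df), 2L)
})

test_that("malformed rows are rejected with their line number", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("f1\t0\t0\tM\t1900\tin_state\t0",
               "m1\t0\t0\tF\t1902\tin_state"), path)
  expect_error(read_pedigree(path), "line 2")

  writeLines(c("f1\t0\t0\tM\t1900\tin_state\t0",
               "m1\t0\t0\tF\tnineteen\tin_state\t0"), path)
  expect_error(read_pedigree(path), "line 2")
})

test_that("validation catches sex-inconsistent parents, dangling refs and cycles", {
  # father_id pointing at a female individual
  df <- rbind(ped_row("w1", "0", "0", "F", 1900),
              ped_row("m1", "0", "0", "F", 1902),
              ped_row("k1", "w1", "m1", "M", 1925))
  rep <- validate_pedigree(df)
  expect_false(rep$ok)
  expect_true("father_male" %in% rep$errors$rule)
  expect_error(genealogy(df), "father")

  # dangling parent reference
  df <- rbind(ped_row("m1", "0", "0", "F", 1902),
              ped_row("k1", "ghost", "m1", "M", 1925))
  rep <- validate_pedigree(df)
  expect_true("parent_exists" %in% rep$errors$rule)

  # a parent-link cycle (ignore birth years by making them consistent-ish)
  df <- rbind(ped_row("a", "c", "b", "M", 1900),
              ped_row("b", "0", "0", "F", 1899),
              ped_row("c", "a", "b", "M", 1901))
  df$birth_year <- c(1900L, 1899L, 1901L)
  rep <- validate_pedigree(df)
  expect_true("acyclic" %in% rep$errors$rule)

  # birth order: child not later than parent
  df <- rbind(ped_row("d", "0", "0", "M", 1950),
              ped_row("m", "0", "0", "F", 1902),
              ped_row("k", "d", "m", "M", 1925))
  expect_true("birth_order" %in% validate_pedigree(df)$errors$rule)

  # a clean pedigree reports ok with zero errors
  ok <- validate_pedigree(ped_extended())
  expect_true(ok$ok)
  expect_equal(nrow(ok$errors), 0L)
})

test_that("write/read round-trip is the identity on canonical form", {
  fx <- example_high_risk_pedigree()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(fx$genealogy, path)
  g2 <- read_pedigree(path)
  ord1 <- order(fx$genealogy$df$id)
  expect_identical(fx$genealogy$df[ord1, ], g2$df[order(g2$df$id), ],
                   ignore_attr = TRUE)
  # and writing again produces byte-identical output
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_pedigree(g2, path2)
  expect_identical(readLines(path), readLines(path2))
})

test_that("generation depth follows the complete-generations min rule", {
  g <- ped_extended()
  d <- generation_depth(g)
  expect_equal(unname(d["gf"]), 0L)          # founder
  expect_equal(unname(d["p1"]), 1L)          # both parents are founders
  expect_equal(unname(d["c1"]), 1L)          # married-in mother truncates
  # child with both parents and all four grandparents recorded has depth 2
  df <- rbind(ped_row("gf1", "0", "0", "M", 1900),
              ped_row("gm1", "0", "0", "F", 1901),
              ped_row("gf2", "0", "0", "M", 1899),
              ped_row("gm2", "0", "0", "F", 1903),
              ped_row("pa", "gf1", "gm1", "M", 1925),
              ped_row("ma", "gf2", "gm2", "F", 1927),
              ped_row("kid", "pa", "ma", "M", 1950))
  g2 <- genealogy(df)
  expect_equal(unname(generation_depth(g2, "kid")), 2L)
  # only paternal grandparents recorded: min rule gives 1
  df3 <- rbind(ped_row("gf1", "0", "0", "M", 1900),
               ped_row("gm1", "0", "0", "F", 1901),
               ped_row("pa", "gf1", "gm1", "M", 1925),
               ped_row("ma", "0", "0", "F", 1927),
               ped_row("kid", "pa", "ma", "M", 1950))
  expect_equal(unname(generation_depth(genealogy(df3), "kid")), 1L)
  # a single recorded parent terminates the lineage (depth 0)
  df4 <- rbind(ped_row("pa", "0", "0", "M", 1925),
               ped_row("kid", "pa", "0", "M", 1950))
  expect_equal(unname(generation_depth(genealogy(df4), "kid")), 0L)
})

test_that("removing an ancestor never increases any depth", {
  g <- random_pedigree(25, seed = 11)
  d0 <- generation_depth(g)
  anc <- g$df$id[1L]  # a founder
  df <- g$df[g$df$id != anc, ]
  df$father_id[!is.na(df$father_id) & df$father_id == anc] <- NA
  df$mother_id[!is.na(df$mother_id) & df$mother_id == anc] <- NA
  d1 <- generation_depth(genealogy(df))
  expect_true(all(d1 <= d0[names(d1)]))
})

test_that("informative case selection respects the generation convention", {
  # five complete generations in one line of descent
  rows <- list(ped_row("g1m", "0", "0", "M", 1850, aff = 1L),
               ped_row("g1f", "0", "0", "F", 1851))
  for (k in 2:5) {
    rows[[length(rows) + 1L]] <-
      ped_row(sprintf("g%dm", k), sprintf("g%dm", k - 1L),
              sprintf("g%df", k - 1L), "M", 1850L + 25L * (k - 1L), aff = 1L)
    if (k < 5) {
      rows[[length(rows) + 1L]] <-
        ped_row(sprintf("g%df", k), "0", "0", "F", 1851L + 25L * (k - 1L))
    }
  }
  g <- genealogy(do.call(rbind, rows))
  # affected in every generation, but spouses married in each generation,
  # so complete ancestral depth is 0,1,1,1,1 down the line: with the
  # default self-counting convention min_generations = 2 keeps g2..g5
  expect_setequal(informative_cases(g, 2), c("g2m", "g3m", "g4m", "g5m"))
  # an affected founder is never informative at 3 generations
  expect_false("g1m" %in% informative_cases(g, 3))
  # min_generations 0 (or 1) returns every affected individual
  expect_setequal(informative_cases(g, 0),
                  g$df$id[g$df$affected])
  # strict ancestral reading drops one more generation
  expect_setequal(informative_cases(g, 1, count_self = FALSE),
                  c("g2m", "g3m", "g4m", "g5m"))
})

test_that("informative selection with full grandparent coverage keeps cases", {
  df <- rbind(ped_row("gf1", "0", "0", "M", 1900),
              ped_row("gm1", "0", "0", "F", 1901),
              ped_row("gf2", "0", "0", "M", 1899),
              ped_row("gm2", "0", "0", "F", 1903),
              ped_row("pa", "gf1", "gm1", "M", 1925),
              ped_row("ma", "gf2", "gm2", "F", 1927),
              ped_row("kid", "pa", "ma", "M", 1950, aff = 1L))
  expect_equal(informative_cases(genealogy(df), 3), "kid")
})
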