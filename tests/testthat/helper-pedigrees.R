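# Small hand-built pedigrees used across the suite. All are returned as
# genealogy objects with every individual unaffected unless noted.

ped_row <- function(id, f, m, sex, by, place = "in_state", aff = 0L) {
  data.frame(id = id, father_id = f, mother_id = m, sex = sex,
             birth_year = by, birth_place = place, affected = aff,
             stringsAsFactors = FALSE)
}

# father + mother + one child
ped_trio <- function() {
  genealogy(rbind(
    ped_row("dad", "0", "0", "M", 1900),
    ped_row("mom", "0", "0", "F", 1902),
    ped_row("kid", "dad", "mom", "M", 1925)))
}

# parents, two full sibs, one unrelated founder
ped_sibs <- function() {
  genealogy(rbind(
    ped_row("dad", "0", "0", "M", 1900),
    ped_row("mom", "0", "0", "F", 1902),
    ped_row("s1", "dad", "mom", "M", 1925),
    ped_row("s2", "dad", "mom", "F", 1927),
    ped_row("loner", "0", "0", "M", 1926)))
}

# three generations: grandparents, two married sibs, first cousins;
# includes an avuncular pair (uncle2 - cousin1) and half-sibs via a
# remarriage
ped_extended <- function() {
  genealogy(rbind(
    ped_row("gf", "0", "0", "M", 1900),
    ped_row("gm", "0", "0", "F", 1901),
    ped_row("p1", "gf", "gm", "M", 1925),
    ped_row("p2", "gf", "gm", "F", 1927),
    ped_row("uncle2", "gf", "gm", "M", 1929),
    ped_row("p1w", "0", "0", "F", 1926),
    ped_row("p2h", "0", "0", "M", 1924),
    ped_row("c1", "p1", "p1w", "M", 1950),
    ped_row("c2", "p1", "p1w", "F", 1952),
    ped_row("c3", "p2h", "p2", "M", 1951),
    ped_row("p1w2", "0", "0", "F", 1930),
    ped_row("h1", "p1", "p1w2", "F", 1958)))  # half-sib of c1/c2
}

# four generations down two sib lines: d1/d2 are second cousins
ped_second_cousins <- function() {
  genealogy(rbind(
    ped_row("a", "0", "0", "M", 1880),
    ped_row("b", "0", "0", "F", 1882),
    ped_row("s1", "a", "b", "M", 1905),
    ped_row("s2", "a", "b", "F", 1907),
    ped_row("s1w", "0", "0", "F", 1906),
    ped_row("s2h", "0", "0", "M", 1904),
    ped_row("k1", "s1", "s1w", "M", 1930),
    ped_row("k2", "s2h", "s2", "F", 1932),
    ped_row("k1w", "0", "0", "F", 1931),
    ped_row("k2h", "0", "0", "M", 1929),
    ped_row("d1", "k1", "k1w", "M", 1955),
    ped_row("d2", "k2h", "k2", "F", 1957)))
}

# full-sib mating: x is inbred with self-kinship 0.625
ped_inbred <- function() {
  genealogy(rbind(
    ped_row("a", "0", "0", "M", 1900),
    ped_row("b", "0", "0", "F", 1901),
    ped_row("s1", "a", "b", "M", 1925),
    ped_row("s2", "a", "b", "F", 1926),
    ped_row("x", "s1", "s2", "M", 1950)))
}

# Random valid pedigree: n_founders founders then random matings among
# existing individuals (overlapping generations, half-sibs, remarriages).
random_pedigree <- function(n, seed, n_founders = 6L) {
  set.seed(seed)
  id <- sprintf("r%02d", seq_len(n))
  sex <- c(rep(c("M", "F"), length.out = n_founders),
           sample(c("M", "F"), n - n_founders, replace = TRUE))
  father <- mother <- rep(NA_character_, n)
  for (k in seq.int(n_founders + 1L, n)) {
    males <- which(sex[seq_len(k - 1L)] == "M")
    females <- which(sex[seq_len(k - 1L)] == "F")
    father[k] <- id[males[sample.int(length(males), 1L)]]
    mother[k] <- id[females[sample.int(length(females), 1L)]]
  }
  genealogy(data.frame(
    id = id, father_id = father, mother_id = mother, sex = sex,
    birth_year = 1900L + 25L * seq_len(n),  # parents always earlier
    birth_place = sample(c("in_state", "out_of_state"), n, replace = TRUE,
                         prob = c(0.8, 0.2)),
    affected = FALSE, stringsAsFactors = FALSE))
}
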