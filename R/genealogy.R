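#' Construct a genealogy from an individual table
#'
#' A genealogy is a directed acyclic parent-link graph: one row per
#' individual with links to a recorded father and mother (either may be
#' missing), plus the attributes used throughout the package for control
#' matching and cohort construction (sex, birth year, birth place) and the
#' affection status of the phenotype under study.
#'
#' @param df data.frame with columns `id`, `father_id`, `mother_id`
#'   (character; `NA`, `""` or `"0"` denote a missing parent), `sex`
#'   (`"M"`/`"F"`), `birth_year` (integer), `birth_place` (character) and
#'   `affected` (logical or 0/1).
#' @param validate if `TRUE` (default), stop with an informative message
#'   when [validate_pedigree()] reports any violation.
#' @return An object of class `genealogy`: the canonical individual table
#'   plus precomputed parent indices, child lists, generation numbers and a
#'   topological (parents-before-children) ordering.
#' @seealso [read_pedigree()], [validate_pedigree()], [generation_depth()]
#' @export
genealogy <- function(df, validate = TRUE) {
  required <- c("id", "father_id", "mother_id", "sex", "birth_year",
                "birth_place", "affected")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- df[required]
  df$id <- as.character(df$id)
  df$father_id <- .normalize_parent(df$father_id)
  df$mother_id <- .normalize_parent(df$mother_id)
  df$sex <- as.character(df$sex)
  df$birth_year <- as.integer(df$birth_year)
  df$birth_place <- as.character(df$birth_place)
  df$affected <- as.logical(as.integer(as.logical(df$affected)))
  rownames(df) <- NULL

  if (validate) {
    rep <- validate_pedigree(df)
    if (!rep$ok) {
      msgs <- paste0("  [", rep$errors$rule, "] ", rep$errors$id, ": ",
                     rep$errors$message)
      stop("invalid pedigree (", nrow(rep$errors), " error(s)):\n",
           paste(utils::head(msgs, 10L), collapse = "\n"), call. = FALSE)
    }
  }

  n <- nrow(df)
  index <- seq_len(n)
  names(index) <- df$id
  fid <- ifelse(is.na(df$father_id), 0L, index[df$father_id])
  mid <- ifelse(is.na(df$mother_id), 0L, index[df$mother_id])
  fid[is.na(fid)] <- 0L  # dangling refs only reachable with validate = FALSE
  mid[is.na(mid)] <- 0L

  gen <- .generation_numbers(fid, mid)
  kids <- vector("list", n)
  par_edges <- c(fid, mid)
  child_of <- c(seq_len(n), seq_len(n))
  keep <- par_edges > 0L
  if (any(keep)) {
    kids_split <- split(child_of[keep], par_edges[keep])
    kids[as.integer(names(kids_split))] <- kids_split
  }

  structure(list(df = df, index = index, fid = fid, mid = mid,
                 gen = gen, ord = order(gen), kids = kids),
            class = "genealogy")
}

.normalize_parent <- function(x) {
  x <- as.character(x)
  x[is.na(x) | x == "" | x == "0"] <- NA_character_
  x
}

# Generation number: 0 for founders, 1 + max over recorded parents otherwise.
# Returns NA for individuals on a parent-link cycle.
.generation_numbers <- function(fid, mid) {
  n <- length(fid)
  gen <- rep(NA_integer_, n)
  pending <- (fid > 0L) + (mid > 0L)
  queue <- which(pending == 0L)
  gen[queue] <- 0L
  # child adjacency
  par_edges <- c(fid, mid)
  child_of <- c(seq_len(n), seq_len(n))
  keep <- par_edges > 0L
  kids <- split(child_of[keep], par_edges[keep])
  head <- 1L
  queue <- as.integer(queue)
  while (head <= length(queue)) {
    i <- queue[head]; head <- head + 1L
    ch <- kids[[as.character(i)]]
    for (c in ch) {
      pending[c] <- pending[c] - 1L
      if (pending[c] == 0L) {
        g <- 0L
        if (fid[c] > 0L) g <- max(g, gen[fid[c]] + 1L)
        if (mid[c] > 0L) g <- max(g, gen[mid[c]] + 1L)
        gen[c] <- g
        queue <- c(queue, c)
      }
    }
  }
  gen
}

#' Validate a pedigree table
#'
#' Checks the structural invariants a genealogy must satisfy: unique ids,
#' parent references that resolve, fathers male and mothers female, sexes
#' coded, birth years later than both parents', and an acyclic parent-link
#' graph (nobody is their own ancestor).
#'
#' @param df data.frame as for [genealogy()], or a `genealogy` object.
#' @return A list of class `ped_validation` with elements `ok` (logical) and
#'   `errors` (data.frame with columns `rule`, `id`, `message`; zero rows
#'   when `ok`).
#' @export
validate_pedigree <- function(df) {
  if (inherits(df, "genealogy")) df <- df$df
  errors <- list()
  add <- function(rule, id, message) {
    errors[[length(errors) + 1L]] <<- data.frame(
      rule = rule, id = as.character(id), message = message,
      stringsAsFactors = FALSE)
  }

  id <- as.character(df$id)
  dup <- unique(id[duplicated(id)])
  for (d in dup) add("unique_id", d, "duplicated individual id")

  father <- .normalize_parent(df$father_id)
  mother <- .normalize_parent(df$mother_id)
  sex <- as.character(df$sex)
  by <- suppressWarnings(as.integer(df$birth_year))

  bad_sex <- which(!sex %in% c("M", "F"))
  for (i in bad_sex) add("sex_coded", id[i],
                         sprintf("sex must be 'M' or 'F', got '%s'", sex[i]))
  bad_by <- which(is.na(by))
  for (i in bad_by) add("birth_year", id[i], "birth_year is not an integer")

  index <- match(father, id)
  dangling_f <- which(!is.na(father) & is.na(index))
  for (i in dangling_f) add("parent_exists", id[i],
                            sprintf("father_id '%s' not in pedigree", father[i]))
  mindex <- match(mother, id)
  dangling_m <- which(!is.na(mother) & is.na(mindex))
  for (i in dangling_m) add("parent_exists", id[i],
                            sprintf("mother_id '%s' not in pedigree", mother[i]))

  ok_f <- which(!is.na(index))
  wrong_f <- ok_f[sex[index[ok_f]] != "M"]
  for (i in wrong_f) add("father_male", id[i],
                         sprintf("father '%s' is not male", father[i]))
  ok_m <- which(!is.na(mindex))
  wrong_m <- ok_m[sex[mindex[ok_m]] != "F"]
  for (i in wrong_m) add("mother_female", id[i],
                         sprintf("mother '%s' is not female", mother[i]))

  for (i in ok_f) {
    if (!is.na(by[i]) && !is.na(by[index[i]]) && by[i] <= by[index[i]]) {
      add("birth_order", id[i], "birth_year not later than father's")
    }
  }
  for (i in ok_m) {
    if (!is.na(by[i]) && !is.na(by[mindex[i]]) && by[i] <= by[mindex[i]]) {
      add("birth_order", id[i], "birth_year not later than mother's")
    }
  }

  if (anyDuplicated(id) == 0L) {
    fid <- ifelse(is.na(index), 0L, index)
    mid <- ifelse(is.na(mindex), 0L, mindex)
    gen <- .generation_numbers(fid, mid)
    for (i in which(is.na(gen))) {
      add("acyclic", id[i], "individual lies on a parent-link cycle")
    }
  }

  errors <- if (length(errors) > 0L) do.call(rbind, errors) else
    data.frame(rule = character(), id = character(), message = character(),
               stringsAsFactors = FALSE)
  structure(list(ok = nrow(errors) == 0L, errors = errors),
            class = "ped_validation")
}

#' @export
print.ped_validation <- function(x, ...) {
  if (x$ok) {
    cat("Pedigree validation: OK\n")
  } else {
    cat("Pedigree validation:", nrow(x$errors), "error(s)\n")
    print(x$errors)
  }
  invisible(x)
}

#' @export
print.genealogy <- function(x, ...) {
  n <- nrow(x$df)
  nf <- sum(x$fid == 0L & x$mid == 0L)
  cat(sprintf("genealogy: %d individuals, %d founders, %d generations, %d affected\n",
              n, nf, max(x$gen) + 1L, sum(x$df$affected)))
  invisible(x)
}

#' Read a pedigree file
#'
#' Reads a tab- or whitespace-delimited pedigree file with columns
#' `id`, `father_id`, `mother_id`, `sex` (M/F), `birth_year` (integer),
#' `birth_place`, `affected` (0/1). A header line is optional and detected
#' by a non-numeric `birth_year` field. `"0"` or an empty field denotes a
#' missing parent. Row order does not affect the result.
#'
#' @param path path to the file.
#' @param validate passed to [genealogy()].
#' @return A `genealogy` object.
#' @export
read_pedigree <- function(path, validate = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty pedigree file: ", path)
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  bad <- which(nf != 7L)
  first_data <- 1L
  header <- FALSE
  if (nf[1L] == 7L && is.na(suppressWarnings(as.integer(fields[[1L]][5L])))) {
    header <- TRUE
    first_data <- 2L
  }
  bad <- bad[bad >= first_data]
  if (length(bad) > 0L) {
    stop(sprintf("malformed row at line %d: expected 7 fields, found %d",
                 bad[1L], nf[bad[1L]]))
  }
  rows <- fields[seq.int(first_data, length(fields))]
  m <- do.call(rbind, rows)
  by <- suppressWarnings(as.integer(m[, 5L]))
  if (anyNA(by)) {
    line <- which(is.na(by))[1L] + first_data - 1L
    stop(sprintf("malformed row at line %d: birth_year '%s' is not an integer",
                 line, m[is.na(by), 5L][1L]))
  }
  aff <- suppressWarnings(as.integer(m[, 7L]))
  if (any(is.na(aff) | !aff %in% c(0L, 1L))) {
    line <- which(is.na(aff) | !aff %in% c(0L, 1L))[1L] + first_data - 1L
    stop(sprintf("malformed row at line %d: affected must be 0 or 1", line))
  }
  df <- data.frame(id = m[, 1L], father_id = m[, 2L], mother_id = m[, 3L],
                   sex = m[, 4L], birth_year = by, birth_place = m[, 6L],
                   affected = aff == 1L, stringsAsFactors = FALSE)
  genealogy(df, validate = validate)
}

#' Write a pedigree file in canonical form
#'
#' Writes a genealogy as a tab-delimited file with a header, rows sorted by
#' id, missing parents encoded as `0` and affection status as 0/1. Reading
#' the result back with [read_pedigree()] reproduces the genealogy exactly,
#' so the canonical form doubles as an equality witness in tests.
#'
#' @param g a `genealogy`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pedigree <- function(g, path) {
  stopifnot(inherits(g, "genealogy"))
  df <- g$df[order(g$df$id), ]
  out <- data.frame(id = df$id,
                    father_id = ifelse(is.na(df$father_id), "0", df$father_id),
                    mother_id = ifelse(is.na(df$mother_id), "0", df$mother_id),
                    sex = df$sex, birth_year = df$birth_year,
                    birth_place = df$birth_place,
                    affected = as.integer(df$affected),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.resolve_ids <- function(g, ids) {
  idx <- g$index[as.character(ids)]
  if (anyNA(idx)) {
    stop("unknown individual id(s): ",
         paste(utils::head(ids[is.na(idx)], 5L), collapse = ", "))
  }
  unname(idx)
}

#' Number of complete ancestral generations recorded above an individual
#'
#' Depth 0 means no (or only one) recorded parent; depth k means both
#' parents are recorded and each has depth at least k - 1. A missing parent
#' terminates the lineage, so an individual with a single recorded parent
#' has depth 0: depth counts generations that are *completely* recorded.
#'
#' @param g a `genealogy`.
#' @param ids individual ids; default all individuals.
#' @return Named integer vector of depths.
#' @export
generation_depth <- function(g, ids = NULL) {
  stopifnot(inherits(g, "genealogy"))
  n <- nrow(g$df)
  depth <- integer(n)
  for (i in g$ord) {
    f <- g$fid[i]; m <- g$mid[i]
    depth[i] <- if (f > 0L && m > 0L) 1L + min(depth[f], depth[m]) else 0L
  }
  if (is.null(ids)) {
    names(depth) <- g$df$id
    depth
  } else {
    idx <- .resolve_ids(g, ids)
    out <- depth[idx]
    names(out) <- as.character(ids)
    out
  }
}

#' Affected individuals with sufficient recorded genealogy
#'
#' Selects the affected individuals embedded in at least `min_generations`
#' generations of recorded genealogy. By default the individual's own
#' generation counts as one of them (the usual genealogical reading, so
#' "3 generations" means self + parents + grandparents, i.e. ancestral
#' depth >= 2); set `count_self = FALSE` to require `min_generations` fully
#' recorded *ancestral* generations instead.
#'
#' @param g a `genealogy`.
#' @param min_generations minimum generations of genealogy (default 3).
#' @param count_self whether the individual's own generation counts.
#' @return Character vector of ids.
#' @export
informative_cases <- function(g, min_generations = 3L, count_self = TRUE) {
  stopifnot(inherits(g, "genealogy"), min_generations >= 0L)
  need <- min_generations - as.integer(count_self)
  depth <- generation_depth(g)
  g$df$id[g$df$affected & depth >= need]
}

#' Ids of genealogy founders
#'
#' Founders are individuals with no recorded parents; they root the founder
#' pedigrees scanned by [high_risk_scan()].
#'
#' @param g a `genealogy`.
#' @return Character vector of ids.
#' @export
founders <- function(g) {
  stopifnot(inherits(g, "genealogy"))
  g$df$id[g$fid == 0L & g$mid == 0L]
}

#' Replace the affection status of a genealogy
#'
#' @param g a `genealogy`.
#' @param cases ids to mark affected; everyone else is marked unaffected.
#' @return The updated `genealogy`.
#' @export
set_affected <- function(g, cases) {
  stopifnot(inherits(g, "genealogy"))
  idx <- .resolve_ids(g, cases)
  g$df$affected <- FALSE
  g$df$affected[idx] <- TRUE
  g
}
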