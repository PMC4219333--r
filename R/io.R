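# Readers/writers for the plain-text dialects used throughout:
#   network / pair-score TSV:  idA <TAB> idB <TAB> value   (header optional,
#     detected by a non-numeric third field on the first line)
#   catalog TSV:               complex_id <TAB> id1,id2,...
#   localization TSV:          id <TAB> cat1,cat2,...      (2nd field may be
#     empty)
#   cluster file:              one cluster per line, whitespace-separated ids

read_three_col <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(data.frame(a = character(), b = character(), v = numeric(),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    stop("malformed line ", bad[1L], " in '", path,
         "': expected 3 tab-separated fields")
  }
  a <- vapply(parts, `[[`, "", 1L)
  b <- vapply(parts, `[[`, "", 2L)
  v <- vapply(parts, `[[`, "", 3L)
  start <- 1L
  if (is.na(suppressWarnings(as.numeric(v[1L])))) start <- 2L  # header row
  if (start > length(a)) {
    return(data.frame(a = character(), b = character(), v = numeric(),
                      stringsAsFactors = FALSE))
  }
  a <- a[start:length(a)]; b <- b[start:length(b)]; v <- v[start:length(v)]
  vn <- suppressWarnings(as.numeric(v))
  if (anyNA(vn)) {
    stop("malformed line ", which(is.na(vn))[1L] + (start - 1L), " in '",
         path, "': third field is not numeric")
  }
  data.frame(a = a, b = b, v = vn, stringsAsFactors = FALSE)
}

#' Read a weighted PPI network from a 3-column TSV
#'
#' Expects `idA<TAB>idB<TAB>weight` records (header optional; detected by a
#' non-numeric third field).  Self-interactions are removed when `drop_self`
#' is set, duplicate pair records collapse to the maximum weight, and a
#' non-positive weight is a validation error.
#'
#' @param path path to the TSV file.
#' @param drop_self drop self-interactions (default `TRUE`).
#' @return A [ppi_network()].
#' @export
read_ppi_network <- function(path, drop_self = TRUE) {
  df <- read_three_col(path)
  ppi_network(df, drop_self = drop_self)
}

#' Read a complex catalog
#'
#' Each record is `complex_id<TAB>id1,id2,...` (CYC2008-style membership
#' list).  Member lists are deduplicated; a complex with fewer than two
#' distinct members is a validation error.  An empty file yields an empty
#' catalog.
#'
#' @param path path to the TSV file.
#' @return An object of class `complex_catalog`: a named list of character
#'   vectors (complex id -> member proteins).
#' @export
read_complex_catalog <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(complex_catalog(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed line ", bad[1L], " in '", path,
         "': expected complex_id<TAB>members")
  }
  ids <- vapply(parts, `[[`, "", 1L)
  members <- lapply(parts, function(p) {
    unique(trimws(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]]))
  })
  names(members) <- ids
  complex_catalog(members)
}

#' Construct a complex catalog from a list
#'
#' @param complexes named list of character vectors; every complex must have
#'   at least two distinct members (members are deduplicated first).
#' @return An object of class `complex_catalog`.
#' @export
complex_catalog <- function(complexes) {
  stopifnot(is.list(complexes))
  complexes <- lapply(complexes, function(m) unique(as.character(m)))
  small <- which(lengths(complexes) < 2L)
  if (length(small)) {
    stop("complex '", names(complexes)[small[1L]],
         "' has fewer than 2 distinct members")
  }
  structure(complexes, class = "complex_catalog")
}

#' @export
print.complex_catalog <- function(x, ...) {
  sz <- lengths(x)
  cat("Complex catalog: ", length(x), " complexes (",
      sum(sz == 2L), " heterodimers)\n", sep = "")
  invisible(x)
}

#' Read a protein localization table
#'
#' Each record is `id<TAB>cat1,cat2,...`; the second field may be empty
#' (protein assayed but assigned no category).  Category labels are opaque
#' strings.  A protein absent from the table has, by convention, an empty
#' category set.
#'
#' @param path path to the TSV file.
#' @return An object of class `localization_table` (named list of character
#'   vectors).
#' @seealso [localization_categories()], [localization_feature()]
#' @export
read_localization_table <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) return(localization_table(list()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  ids <- vapply(parts, `[[`, "", 1L)
  cats <- lapply(parts, function(p) {
    if (length(p) < 2L || !nzchar(trimws(p[[2L]]))) return(character())
    unique(trimws(strsplit(p[[2L]], ",", fixed = TRUE)[[1L]]))
  })
  names(cats) <- ids
  localization_table(cats)
}

#' Construct a localization table from a list
#'
#' @param categories named list mapping protein id to a character vector of
#'   subcellular category labels (possibly empty).
#' @return An object of class `localization_table`.
#' @export
localization_table <- function(categories) {
  stopifnot(is.list(categories))
  categories <- lapply(categories, as.character)
  structure(categories, class = "localization_table")
}

#' Category set of a protein
#'
#' @param loc a [localization_table()].
#' @param id protein identifier.
#' @return Character vector of category labels; empty for unknown proteins.
#' @export
localization_categories <- function(loc, id) {
  stopifnot(inherits(loc, "localization_table"))
  cats <- loc[[as.character(id)]]
  if (is.null(cats)) character() else cats
}

#' Read a pairwise score table
#'
#' Reads `idA<TAB>idB<TAB>score` records (header optional) into a symmetric
#' pair-score lookup, e.g. precomputed Gene Ontology semantic similarities.
#' A pair recorded twice with conflicting scores is an error; pairs absent
#' from the table take the `default` score (0, the same convention the
#' network uses for absent interactions).
#'
#' @param path path to the TSV file.
#' @param default score returned for absent pairs (default 0).
#' @return An object of class `pair_score_table`.
#' @seealso [table_score()]
#' @export
read_pair_score_table <- function(path, default = 0) {
  df <- read_three_col(path)
  pair_score_table(df, default = default)
}

#' Construct a pair-score table from a data frame
#'
#' @param scores data frame whose first three columns are protein A,
#'   protein B and a numeric score.
#' @param default score returned for absent pairs.
#' @return An object of class `pair_score_table`: list with elements
#'   `scores` (named numeric vector keyed by the canonical pair) and
#'   `default`.
#' @export
pair_score_table <- function(scores, default = 0) {
  stopifnot(is.data.frame(scores), ncol(scores) >= 3L)
  a <- as.character(scores[[1L]])
  b <- as.character(scores[[2L]])
  v <- as.numeric(scores[[3L]])
  key <- pair_key(a, b)
  if (anyDuplicated(key)) {
    d <- duplicated(key) | duplicated(key, fromLast = TRUE)
    agree <- all(vapply(split(v[d], key[d]),
                        function(x) max(x) - min(x) == 0, TRUE))
    if (!agree) {
      k <- unique(key[d])[1L]
      stop("conflicting duplicate scores for pair ",
           gsub("\x1f", " -- ", k, fixed = TRUE))
    }
    keep <- !duplicated(key)
    key <- key[keep]; v <- v[keep]
  }
  structure(list(scores = setNames(v, key), default = default),
            class = "pair_score_table")
}

#' @export
print.pair_score_table <- function(x, ...) {
  cat("Pair score table: ", length(x$scores), " pairs, default ",
      format(x$default), "\n", sep = "")
  invisible(x)
}

#' Look up a pairwise score
#'
#' Symmetric lookup in a [pair_score_table()]; absent pairs return the
#' table's default.
#'
#' @param table a [pair_score_table()].
#' @param u,v protein identifiers (vectors of equal length accepted).
#' @return Numeric vector of scores.
#' @export
table_score <- function(table, u, v) {
  stopifnot(inherits(table, "pair_score_table"))
  s <- table$scores[pair_key(as.character(u), as.character(v))]
  s[is.na(s)] <- table$default
  unname(s)
}

#' Read a cluster file
#'
#' One predicted cluster per line, whitespace-separated member ids -- the
#' output dialect of common complex-prediction tools, accepted by
#' [matching_metrics()] so that external predictions can be scored.
#'
#' @param path path to the cluster file.
#' @return A list of character vectors.
#' @export
read_clusters <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  lapply(strsplit(trimws(lines), "[[:space:]]+"), unique)
}
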