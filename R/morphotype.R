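#' Identify morphotypes from coded specimens
#'
#' A morphotype is a unique combination of character states. With
#' `merge_tolerance = 0` specimens are grouped by exact state-vector equality
#' (zeros compare as equal only to zeros), a true equivalence relation. With
#' tolerance 1 or 2, near-duplicate codes — codes differing in at most that
#' many traits, counted over the traits where both codes are codable — are
#' merged by single linkage, so a group contains every code reachable through
#' a chain of near-duplicates. Each morphotype's canonical code is the
#' lexicographically smallest member state vector, which also breaks ties, so
#' the partition is deterministic.
#'
#' Merging counts differing traits (a Hamming distance over the comparable
#' traits) rather than weighted disparity; set `weighted_tolerance` to merge
#' on normalized disparity instead.
#'
#' @param codes Data frame of validated codes.
#' @param schema A `denticle_schema`.
#' @param merge_tolerance Integer 0, 1 or 2: maximum number of differing
#'   comparable traits for two codes to be considered the same morphotype.
#' @param weighted_tolerance Optional numeric: merge by single linkage on
#'   normalized pairwise disparity at this threshold instead of trait counts.
#' @return Object of class `morphotype_set`: list with `assignments`
#'   (data frame `specimen_id`, `morphotype`), `morphotypes` (list of
#'   `name`, `canonical` named state vector, `members`, `gross_type`), and
#'   `catalog` (coding-sheet-format data frame of canonical codes with a
#'   `morphotype_name` column).
#' @export
assign_morphotypes <- function(codes, schema, merge_tolerance = 0,
                               weighted_tolerance = NULL) {
  m <- code_states(codes, schema)
  n <- nrow(m)
  if (is.null(weighted_tolerance) &&
      !merge_tolerance %in% c(0, 1, 2))
    stop("merge_tolerance must be 0, 1 or 2")
  grp <- if (!is.null(weighted_tolerance)) {
    D <- disparity_matrix(codes, schema)$D
    D[is.na(D)] <- max(D, na.rm = TRUE) + 1  # undefined pairs never merge
    single_link_groups(D, weighted_tolerance)
  } else if (merge_tolerance == 0) {
    key <- apply(m, 1, paste, collapse = ",")
    match(key, unique(key))
  } else {
    H <- comparable_hamming(m)
    single_link_groups(H, merge_tolerance)
  }
  # canonical = lexicographically smallest member vector; order morphotypes
  # by first appearance in the input
  out <- lapply(sort(unique(grp)), function(g) {
    idx <- which(grp == g)
    mem <- m[idx, , drop = FALSE]
    ord <- do.call(order, as.data.frame(mem))
    list(canonical = mem[ord[1], ], members = rownames(m)[idx],
         gross_type = NA_character_)
  })
  first <- vapply(out, function(x) match(x$members[1], rownames(m)), 1L)
  out <- out[order(first)]
  for (i in seq_along(out)) out[[i]]$name <- sprintf("MT%03d", i)
  amap <- stats::setNames(character(n), rownames(m))
  for (mt in out) amap[mt$members] <- mt$name
  assignments <- data.frame(specimen_id = rownames(m),
                            morphotype = unname(amap),
                            stringsAsFactors = FALSE)
  catalog <- do.call(rbind, lapply(out, function(x)
    data.frame(specimen_id = x$name, t(x$canonical),
               morphotype_name = x$name, gross_type = x$gross_type,
               stringsAsFactors = FALSE, check.names = FALSE)))
  structure(list(assignments = assignments, morphotypes = out,
                 catalog = catalog, merge_tolerance = merge_tolerance),
            class = "morphotype_set")
}

#' @export
print.morphotype_set <- function(x, ...) {
  sizes <- vapply(x$morphotypes, function(m) length(m$members), 1L)
  cat(sprintf("%d morphotype(s) over %d specimen(s) (tolerance %s); sizes: %s\n",
              length(sizes), sum(sizes), x$merge_tolerance,
              paste(sizes, collapse = " ")))
  invisible(x)
}

# pairwise count of differing traits over the traits codable in both
comparable_hamming <- function(m) {
  n <- nrow(m)
  H <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
    cmp <- m[i, ] > 0L & m[j, ] > 0L
    H[i, j] <- H[j, i] <- if (any(cmp)) sum(m[i, cmp] != m[j, cmp])
                          else ncol(m) + 1  # no overlap: never near-duplicates
  }
  H
}

# connected components of the graph linking pairs at distance <= tol
single_link_groups <- function(D, tol) {
  n <- nrow(D)
  if (n == 1) return(1L)
  hc <- stats::hclust(stats::as.dist(D), method = "single")
  unname(stats::cutree(hc, h = tol))
}

#' Rank catalog morphotypes by disparity to a query code
#'
#' Compares a (possibly broken) code against every canonical code in a
#' catalog and returns the matches sorted by ascending normalized disparity;
#' matches with no shared codable trait are undefined and ranked last,
#' flagged in the `defined` column. Ranking is invariant under permutation of
#' the catalog rows.
#'
#' @param code A single code (named state vector or one-row data frame).
#' @param catalog Catalog data frame: coding-sheet format plus a
#'   `morphotype_name` column (e.g. the `catalog` element of a
#'   `morphotype_set`, or [read_catalog()]).
#' @param schema A `denticle_schema`.
#' @return Data frame `morphotype_name`, `disparity`, `defined`, sorted.
#' @export
match_to_catalog <- function(code, catalog, schema) {
  if (nrow(catalog) == 0) stop("catalog is empty")
  q <- as_codes_df(code, schema, "query")
  d <- vapply(seq_len(nrow(catalog)), function(i)
    pair_disparity(q, catalog[i, ], schema), numeric(1))
  out <- data.frame(morphotype_name = catalog$morphotype_name,
                    disparity = d, defined = !is.na(d),
                    stringsAsFactors = FALSE)
  out[order(!out$defined, out$disparity,
            out$morphotype_name, method = "radix"), , drop = FALSE]
}

#' Read / write a morphotype catalog
#'
#' A catalog file is a coding sheet whose rows are canonical morphotype codes
#' with extra `morphotype_name` (and optionally `gross_type`) columns.
#' `gross_type` values, when present, are checked against the controlled
#' vocabulary of [gross_types()].
#'
#' @param path Catalog CSV path.
#' @param schema A `denticle_schema`.
#' @return Catalog data frame.
#' @export
read_catalog <- function(path, schema) {
  cat <- read_coding_sheet(path, schema)
  if (!"morphotype_name" %in% names(cat))
    stop("catalog is missing the morphotype_name column")
  if ("gross_type" %in% names(cat)) {
    known <- c(gross_types(), NA_character_, "")
    bad <- setdiff(unique(cat$gross_type), known)
    if (length(bad) > 0)
      warning("unknown gross type label(s): ", paste(bad, collapse = ", "))
  }
  cat
}

#' @rdname read_catalog
#' @param catalog Catalog data frame.
#' @return `path`, invisibly.
#' @export
write_catalog <- function(catalog, path, schema) {
  write_coding_sheet(catalog, path, schema)
}

#' Controlled vocabulary of gross-type labels
#'
#' Gross types are visually determined groupings of morphotypes (for
#' conversation, independent of the disparity calculation); they are carried
#' as metadata labels only.
#'
#' @return Character vector of the 18 gross-type names.
#' @export
gross_types <- function() {
  readLines(system.file("extdata", "gross_types.txt",
                        package = "denticode"))
}
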