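#' Pairwise weighted disparity between all coded specimens
#'
#' For each pair of specimens, disparity is computed over the shared codable
#' traits only — the Venn-diagram overlap `S` of traits where neither code
#' carries the 0 sentinel. The raw disparity is the weighted sum
#' `sum_{t in S} w_t * d_t(a_t, b_t)`; the normalized disparity divides by
#' the maximum attainable weighted distance over the same shared set,
#' `sum_{t in S} w_t * max(d_t)`, making heavily broken fossil pairs
#' commensurable with complete pairs. Pairs with an empty shared set are
#' undefined and reported as `NA`, never silently 0.
#'
#' @param codes Data frame of validated codes (>= 2 rows, unique
#'   `specimen_id`).
#' @param schema A `denticle_schema`.
#' @param normalized Normalize per pair to `[0, 1]` (default) or return raw
#'   weighted sums for diagnostics.
#' @return Object of class `disparity_matrix`: list with `ids`, `D`
#'   (symmetric disparity matrix, `NA` = undefined pair), `shared_weight`
#'   (`sum w_t` over each pair's comparable traits), `comparable_count`,
#'   `normalized`, and the schema `version`.
#' @export
#' @examples
#' sch <- load_schema("denticles_v0.5")
#' codes <- generate_codes(5, sch, seed = 1)
#' dm <- disparity_matrix(codes, sch)
#' round(dm$D, 3)
disparity_matrix <- function(codes, schema, normalized = TRUE) {
  m <- code_states(codes, schema)
  n <- nrow(m)
  if (n < 2) stop("need at least two codes")
  if (anyDuplicated(rownames(m)))
    stop("duplicate specimen ids: ",
         paste(unique(rownames(m)[duplicated(rownames(m))]), collapse = ", "))
  raw <- matrix(0, n, n)
  sw <- matrix(0, n, n)
  cc <- matrix(0L, n, n)
  den <- matrix(0, n, n)
  for (tr in schema$traits) {
    s <- m[, tr$trait_id]
    r <- match(s, nonzero_states(tr))  # NA for the 0 sentinel
    dt <- tr$dist[r, r, drop = FALSE]  # NA rows/cols where not comparable
    cmp <- !is.na(dt)
    raw[cmp] <- raw[cmp] + tr$weight * dt[cmp]
    sw[cmp] <- sw[cmp] + tr$weight
    cc[cmp] <- cc[cmp] + 1L
    den[cmp] <- den[cmp] + tr$weight * max_trait_distance(tr)
  }
  D <- if (normalized) {
    out <- raw / den
    out[den == 0] <- NA_real_
    out
  } else raw
  D[cc == 0L] <- NA_real_
  diag(D) <- 0
  dimnames(D) <- dimnames(sw) <- dimnames(cc) <- list(rownames(m), rownames(m))
  structure(list(ids = rownames(m), D = D, shared_weight = sw,
                 comparable_count = cc, normalized = normalized,
                 version = schema$version),
            class = "disparity_matrix")
}

#' @export
print.disparity_matrix <- function(x, ...) {
  nundef <- sum(is.na(x$D[upper.tri(x$D)]))
  cat(sprintf(
    "Pairwise %s disparity (%s): %d specimens, %d undefined pair(s)\n",
    if (x$normalized) "normalized" else "raw", x$version,
    length(x$ids), nundef))
  invisible(x)
}

#' @export
as.dist.disparity_matrix <- function(m, diag = FALSE, upper = FALSE) {
  stats::as.dist(m$D, diag = diag, upper = upper)
}

#' Disparity between two coded specimens
#'
#' @param a,b Codes: named state vectors or one-row data frames.
#' @param schema A `denticle_schema`.
#' @param normalized Normalize by the maximum attainable weighted distance
#'   over the shared traits.
#' @return A number in `[0, 1]` (normalized) or `>= 0` (raw), or `NA` when
#'   the two codes share no codable trait.
#' @export
pair_disparity <- function(a, b, schema, normalized = TRUE) {
  da <- as_codes_df(a, schema, "a")[c("specimen_id", trait_ids(schema))]
  db <- as_codes_df(b, schema, "b")[c("specimen_id", trait_ids(schema))]
  da$specimen_id <- "a"
  db$specimen_id <- "b"
  codes <- rbind(da, db)
  disparity_matrix(codes, schema, normalized = normalized)$D[1, 2]
}

#' Per-trait decomposition of a pairwise disparity
#'
#' Reports, for every trait, the two states, whether the pair is comparable
#' there, the state distance, and the weighted contribution; contributions
#' over the comparable set sum to the raw disparity. Useful for asking which
#' characters drive the disparity between two specimens.
#'
#' @inheritParams pair_disparity
#' @return Data frame with columns `trait_id`, `weight`, `a`, `b`,
#'   `comparable`, `distance`, `weighted`.
#' @export
trait_contributions <- function(a, b, schema) {
  av <- unlist(as_codes_df(a, schema)[1, trait_ids(schema)])
  bv <- unlist(as_codes_df(b, schema)[1, trait_ids(schema)])
  rows <- lapply(trait_ids(schema), function(id) {
    d <- trait_distance(schema, id, av[[id]], bv[[id]])
    w <- schema$traits[[id]]$weight
    data.frame(trait_id = id, weight = w, a = av[[id]], b = bv[[id]],
               comparable = !is.na(d),
               distance = d, weighted = w * d, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Character-jackknife sensitivity analysis
#'
#' Recomputes the disparity matrix with one or more characters (or whole
#' character groups) excluded, on a schema copy with the dropped traits
#' removed and their nesting rules pruned. Comparing the jackknifed matrix
#' with the full one shows how strongly each character structures the
#' analysis.
#'
#' @param codes Data frame of codes.
#' @param schema A `denticle_schema`.
#' @param drop Trait ids and/or group letters to remove.
#' @param normalized Passed to [disparity_matrix()].
#' @return A `disparity_matrix` over the reduced schema.
#' @export
character_jackknife <- function(codes, schema, drop, normalized = TRUE) {
  disparity_matrix(codes, drop_traits(schema, drop), normalized = normalized)
}

#' Export a disparity matrix as CSV
#'
#' Writes the square disparity matrix with an `id` header column; optionally
#' the companion shared-weight matrix.
#'
#' @param dm A `disparity_matrix`.
#' @param path Output path.
#' @param what `"D"` (default), `"shared_weight"` or `"comparable_count"`.
#' @return `path`, invisibly.
#' @export
write_disparity_csv <- function(dm, path, what = c("D", "shared_weight",
                                                   "comparable_count")) {
  what <- match.arg(what)
  m <- dm[[what]]
  df <- data.frame(id = dm$ids, m, check.names = FALSE)
  utils::write.table(df, path, sep = ",", quote = TRUE, row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Export a disparity matrix in PHYLIP lower-triangle format
#'
#' For interoperability with phylogenetic and disparity tools. Undefined
#' pairs are written as `NA` and a warning is raised.
#'
#' @param dm A `disparity_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_phylip <- function(dm, path) {
  n <- length(dm$ids)
  if (anyNA(dm$D)) warning("undefined pairs written as NA")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", n), con)
  for (i in seq_len(n)) {
    vals <- if (i > 1) sprintf("%.6f", dm$D[i, seq_len(i - 1)]) else character()
    writeLines(paste(c(formatC(dm$ids[i], width = -10), vals),
                     collapse = " "), con)
  }
  invisible(path)
}

#' Remove specimens involved in undefined disparity pairs
#'
#' Iteratively drops the specimen with the most undefined pairs until the
#' matrix is fully defined, warning about what was removed. Undefined pairs
#' arise when two codes share no codable trait (e.g. two extremely broken
#' denticles broken in complementary ways).
#'
#' @param dm A `disparity_matrix`.
#' @return A `disparity_matrix` with the offending specimens removed.
#' @export
prune_undefined <- function(dm) {
  D <- dm$D
  dropped <- character()
  while (anyNA(D)) {
    worst <- which.max(rowSums(is.na(D)))
    dropped <- c(dropped, rownames(D)[worst])
    D <- D[-worst, -worst, drop = FALSE]
  }
  if (length(dropped) > 0) {
    warning("removed specimen(s) with undefined pairs: ",
            paste(dropped, collapse = ", "))
    keep <- match(rownames(D), dm$ids)
    dm$ids <- dm$ids[keep]
    dm$D <- D
    dm$shared_weight <- dm$shared_weight[keep, keep, drop = FALSE]
    dm$comparable_count <- dm$comparable_count[keep, keep, drop = FALSE]
  }
  dm
}
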