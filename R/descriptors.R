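#' Verbal descriptor scale for state-distance matrices
#'
#' Character disparity descriptions are given verbally, per trait, as orderings
#' of how different pairs of states are ("more similar", "equally different",
#' "very different", ...). This scale maps that vocabulary onto a strictly
#' increasing integer dissimilarity rank so that per-trait state-distance
#' matrices can be constructed reproducibly from a curated descriptor table.
#' Any strictly monotone mapping preserves the verbal orderings; external
#' matrices with other numeric conventions can be loaded via
#' [load_schema()] without code changes.
#'
#' The vocabulary (with synonyms encountered in the trait descriptions):
#' * `identical` = 0
#' * `similar`, `more similar`, `step` (one ordinal bin) = 1
#' * `different`, `equally different`, `somewhat different`,
#'   `equally similar/dissimilar` = 2
#' * `very different`, `significantly different`, `most dissimilar` = 3
#' * `maximal` ("very different from all other ...") = 4
#'
#' @return Named numeric vector mapping descriptor words to integer ranks.
#' @seealso [build_matrix_from_descriptors()]
#' @export
#' @examples
#' descriptor_scale()[["equally different"]]
descriptor_scale <- function() {
  c("identical" = 0,
    "similar" = 1, "more similar" = 1, "step" = 1,
    "different" = 2, "equally different" = 2, "somewhat different" = 2,
    "equally similar/dissimilar" = 2,
    "very different" = 3, "significantly different" = 3,
    "most dissimilar" = 3,
    "maximal" = 4)
}

#' Build a state-distance matrix from pairwise verbal descriptors
#'
#' Turns a table of pairwise descriptors (see [descriptor_scale()]) into a
#' symmetric, zero-diagonal state-distance matrix over the non-zero states of
#' a trait. Ordinal traits may be specified by adjacent `"step"` descriptors
#' only; with `complete = "path"` the remaining pairs are filled by min-plus
#' shortest path over the supplied entries, which expands one-step-increment
#' chains to `|i - j|` unit steps and keeps the filled entries consistent with
#' the triangle inequality within the trait.
#'
#' @param states Integer vector of non-zero state indices (consecutive,
#'   starting at the trait's first codable state).
#' @param pairs Data frame with columns `a`, `b` (state indices) and
#'   `descriptor` (a word from [descriptor_scale()]). Each unordered pair may
#'   appear at most once; later rows override earlier ones.
#' @param trait_id Optional trait label used in error messages.
#' @param complete `"error"` (default) requires every unordered pair to be
#'   covered; `"path"` fills missing pairs by shortest descriptor path.
#' @return Symmetric numeric matrix with `dimnames` equal to `states`.
#' @export
#' @examples
#' # two-state trait coded as "equally different"
#' build_matrix_from_descriptors(1:2,
#'   data.frame(a = 1, b = 2, descriptor = "equally different"))
build_matrix_from_descriptors <- function(states, pairs, trait_id = NULL,
                                          complete = c("error", "path")) {
  complete <- match.arg(complete)
  states <- as.integer(states)
  stopifnot(length(states) >= 1, !anyDuplicated(states))
  lab <- if (is.null(trait_id)) "" else paste0(" [", trait_id, "]")
  scale <- descriptor_scale()
  n <- length(states)
  m <- matrix(NA_real_, n, n, dimnames = list(states, states))
  diag(m) <- 0
  if (nrow(pairs) > 0) {
    unknown <- setdiff(unique(pairs$descriptor), names(scale))
    if (length(unknown) > 0)
      stop("unknown descriptor(s)", lab, ": ",
           paste(unknown, collapse = ", "))
    ia <- match(pairs$a, states)
    ib <- match(pairs$b, states)
    if (anyNA(ia) || anyNA(ib))
      stop("descriptor pair references unknown state", lab)
    for (r in seq_len(nrow(pairs))) {
      v <- scale[[pairs$descriptor[r]]]
      m[ia[r], ib[r]] <- v
      m[ib[r], ia[r]] <- v
    }
  }
  if (anyNA(m)) {
    if (complete == "error") {
      miss <- which(is.na(m) & upper.tri(m), arr.ind = TRUE)
      stop("missing descriptor for state pair(s)", lab, ": ",
           paste(sprintf("(%s,%s)", states[miss[, 1]], states[miss[, 2]]),
                 collapse = " "))
    }
    # min-plus shortest-path completion over supplied descriptors
    g <- m
    g[is.na(g)] <- Inf
    for (k in seq_len(n)) {
      g <- pmin(g, outer(g[, k], g[k, ], `+`))
    }
    if (any(!is.finite(g)))
      stop("descriptor graph is disconnected; cannot complete", lab)
    m[is.na(m)] <- g[is.na(m)]
  }
  m
}

# Curation helpers: all-pairs descriptor table with a default word, plus
# targeted overrides. `a`/`b` may be vectors; all cross pairs (a != b) are set.
pairs_default <- function(states, default = "different") {
  if (length(states) < 2)
    return(data.frame(a = integer(), b = integer(),
                      descriptor = character()))
  cmb <- utils::combn(as.integer(states), 2)
  data.frame(a = cmb[1, ], b = cmb[2, ], descriptor = default,
             stringsAsFactors = FALSE)
}

pairs_set <- function(pairs, a, b, descriptor) {
  for (x in a) for (y in b) {
    if (x == y) next
    hit <- (pairs$a == x & pairs$b == y) | (pairs$a == y & pairs$b == x)
    pairs$descriptor[hit] <- descriptor
  }
  pairs
}
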