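#' Non-metric multidimensional scaling of a disparity matrix
#'
#' Ordinates specimens into a k-dimensional morphospace by NMDS, minimizing
#' Kruskal stress-1, `sqrt(sum((dhat - delta)^2) / sum(dhat^2))`, where the
#' reference distances come from monotone (isotonic) regression on the ranks
#' of the disparities with Kruskal's primary (weak) treatment of ties. The
#' fit is the best of `n_restarts` random starts plus one metric
#' (principal-coordinates) start, and is reproducible given `seed`.
#' Coordinates are centered at the origin.
#'
#' Defaults follow common practice for categorical disparity data: three
#' dimensions, 20 restarts, convergence when the stress change falls below
#' `1e-6` within 300 iterations.
#'
#' @param dm A `disparity_matrix`, `dist`, or square symmetric matrix. All
#'   pairs must be defined; see [prune_undefined()].
#' @param k Number of ordination dimensions (`>= 1`, `< n`).
#' @param seed Integer seed for the random restarts.
#' @param n_restarts Number of random starts.
#' @param maxit Maximum iterations per start.
#' @return Object of class `denticle_ordination`: `ids`, `coords`
#'   (n x k, centered), `k`, `stress` (in `[0, 1]`), `seed`, `n_restarts`,
#'   `converged`, and `restart_stress` (best stress seen at each start,
#'   non-increasing).
#' @export
#' @examples
#' sch <- load_schema("denticles_v0.5")
#' codes <- generate_codes(12, sch, seed = 4)
#' ord <- nmds(disparity_matrix(codes, sch), k = 2, seed = 1, n_restarts = 5)
#' ord$stress
nmds <- function(dm, k = 3, seed = 1, n_restarts = 20, maxit = 300) {
  D <- if (inherits(dm, "disparity_matrix")) dm$D
       else if (inherits(dm, "dist")) as.matrix(dm)
       else as.matrix(dm)
  ids <- rownames(D)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(D)))
  if (anyNA(D)) {
    bad <- unique(ids[rowSums(is.na(D)) > 0])
    stop("disparity matrix has undefined pairs involving: ",
         paste(bad, collapse = ", "),
         "; remove them (see prune_undefined) before ordination")
  }
  n <- nrow(D)
  if (k < 1 || n < k + 1) stop("need k >= 1 and at least k + 1 specimens")
  d <- stats::as.dist(D)
  set.seed(seed)
  best <- NULL
  trace <- numeric(0)
  fit_one <- function(init) {
    f <- vegan::monoMDS(d, y = init, k = k, model = "global",
                        maxit = maxit, weakties = TRUE, stress = 1,
                        sfgrmin = 1e-7, smin = 1e-6)
    f
  }
  # metric start, then random starts
  pco <- suppressWarnings(stats::cmdscale(d, k = k))
  if (ncol(pco) < k)
    pco <- cbind(pco, matrix(stats::rnorm(n * (k - ncol(pco)), 0, 1e-4),
                             n, k - ncol(pco)))
  starts <- c(list(pco), replicate(n_restarts, matrix(stats::runif(n * k, -1, 1),
                                                      n, k), simplify = FALSE))
  for (init in starts) {
    f <- fit_one(init)
    if (is.null(best) || f$stress < best$stress) best <- f
    trace <- c(trace, best$stress)
  }
  coords <- sweep(best$points, 2, colMeans(best$points))
  rownames(coords) <- ids
  colnames(coords) <- paste0("NMDS", seq_len(k))
  structure(list(ids = ids, coords = coords, k = k, stress = best$stress,
                 seed = seed, n_restarts = n_restarts,
                 converged = best$icause %in% c(3, 4),
                 restart_stress = trace),
            class = "denticle_ordination")
}

#' @export
print.denticle_ordination <- function(x, ...) {
  cat(sprintf("NMDS ordination: %d specimens in %d dimensions, stress-1 = %.4f%s\n",
              length(x$ids), x$k, x$stress,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Summarize ordination groupings by the states of one trait
#'
#' Computes, for each state of a trait, the centroid of its specimens in
#' ordination space and the mean distance of those specimens to their
#' centroid (spread), plus an overall between/within ratio — the mean
#' pairwise distance between state centroids divided by the mean within-state
#' spread. A high ratio means the trait's states form distinct clouds in the
#' morphospace; comparing ratios across traits shows which characters carry
#' the grouping signal.
#'
#' @param ord A `denticle_ordination`.
#' @param codes The codes that produced the ordination (matched by
#'   `specimen_id`).
#' @param trait_id Trait whose states to overlay.
#' @param schema A `denticle_schema`.
#' @return List with `per_state` (data frame `state`, `n`, centroid columns,
#'   `spread`) and `ratio` (`NA` when fewer than two states or zero spread).
#' @export
overlay_grouping <- function(ord, codes, trait_id, schema) {
  m <- code_states(codes, schema)
  idx <- match(ord$ids, rownames(m))
  if (anyNA(idx)) stop("codes are missing specimens: ",
                       paste(ord$ids[is.na(idx)], collapse = ", "))
  st <- m[idx, trait_id]
  states <- sort(unique(st))
  cent <- t(vapply(states, function(s)
    colMeans(ord$coords[st == s, , drop = FALSE]), numeric(ord$k)))
  spread <- vapply(seq_along(states), function(i) {
    pts <- ord$coords[st == states[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(pts, 2, cent[i, ])^2)))
  }, numeric(1))
  per_state <- data.frame(state = states,
                          n = as.integer(table(factor(st, states))),
                          cent, spread = spread, check.names = FALSE)
  ratio <- NA_real_
  if (length(states) >= 2) {
    between <- mean(stats::dist(cent))
    within <- mean(spread)
    if (within > 0) ratio <- between / within
  }
  list(per_state = per_state, ratio = ratio, trait_id = trait_id)
}

#' Export NMDS coordinates as CSV
#'
#' Writes `specimen_id` and the k coordinate columns; the final stress is
#' recorded in a `# stress:` comment on the first line.
#'
#' @param ord A `denticle_ordination`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ordination_csv <- function(ord, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# stress: %.6f", ord$stress), con)
  utils::write.table(data.frame(specimen_id = ord$ids, ord$coords,
                                check.names = FALSE),
                     con, sep = ",", quote = TRUE, row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

#' Scatter plot of an NMDS morphospace
#'
#' Base-graphics scatter of two ordination axes, optionally colored by the
#' states of one trait.
#'
#' @param x A `denticle_ordination`.
#' @param codes,trait_id,schema Optional: color points by this trait's states.
#' @param dims Which two dimensions to draw.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.denticle_ordination <- function(x, codes = NULL, trait_id = NULL,
                                     schema = NULL, dims = c(1, 2), ...) {
  col <- 1
  if (!is.null(codes) && !is.null(trait_id) && !is.null(schema)) {
    st <- code_states(codes, schema)[x$ids, trait_id]
    col <- as.integer(factor(st)) + 1L
  }
  graphics::plot(x$coords[, dims[1]], x$coords[, dims[2]], col = col,
                 pch = 19, xlab = colnames(x$coords)[dims[1]],
                 ylab = colnames(x$coords)[dims[2]],
                 main = sprintf("NMDS morphospace (stress %.3f)", x$stress),
                 ...)
  invisible(x)
}
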