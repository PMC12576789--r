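#' Configuration for the synthetic coded-specimen generator
#'
#' @param seed Integer seed.
#' @param n_morphotypes Number of simulated morphotypes (cluster centroids).
#' @param specimens_per_type Specimens per morphotype, including the
#'   canonical exemplar that anchors each type.
#' @param mutation_rate Per-trait probability that a member deviates from its
#'   centroid state.
#' @param breakage_fraction Per-trait probability that a zero-capable trait
#'   is zeroed (taphonomic degradation) in every generated specimen; 0
#'   disables. For degrading a subset of specimens use [degrade_code()].
#' @param base_loss Fossil mode: force all base (O-group) characters to 0,
#'   emulating the crown-only preservation typical of fossil denticles.
#' @return A validated list of class `generator_config`.
#' @export
generator_config <- function(seed = 1, n_morphotypes = 5,
                             specimens_per_type = 10, mutation_rate = 0.05,
                             breakage_fraction = 0, base_loss = FALSE) {
  stopifnot(n_morphotypes >= 1, specimens_per_type >= 1,
            mutation_rate >= 0, mutation_rate <= 1,
            breakage_fraction >= 0, breakage_fraction <= 1)
  structure(list(seed = as.integer(seed), n_morphotypes = n_morphotypes,
                 specimens_per_type = specimens_per_type,
                 mutation_rate = mutation_rate,
                 breakage_fraction = breakage_fraction,
                 base_loss = isTRUE(base_loss)),
            class = "generator_config")
}

# forced-value bookkeeping: given the states fixed so far, which dependents
# are pinned (to 0, or to a "lacks the feature" state such as G1 = 1)?
forced_values <- function(schema, states) {
  forced <- integer(0)
  for (rule in schema$nesting_rules) {
    ctrl <- states[rule$controller]
    if (is.na(ctrl) || !ctrl %in% rule$when) next
    forced[names(rule$requires)] <- unlist(rule$requires)
  }
  forced
}

sample_states <- function(schema, rng_free = TRUE) {
  ids <- trait_ids(schema)
  states <- stats::setNames(rep(NA_integer_, length(ids)), ids)
  for (id in ids) {
    forced <- forced_values(schema, states)
    states[id] <- if (id %in% names(forced)) forced[[id]]
                  else resample1(nonzero_states(schema$traits[[id]]))
  }
  # lower-score-first convention for the B2/C2 pair on denticles without
  # directionality
  if (all(c("B1", "C1", "B2", "C2") %in% ids) &&
      states["B1"] == 4L && states["C1"] == 4L &&
      states["B2"] > states["C2"])
    states[c("B2", "C2")] <- states[c("C2", "B2")]
  states
}

resample1 <- function(x) if (length(x) == 1) x else sample(x, 1)

#' Generate one valid random denticle code
#'
#' Samples controller traits first and conditions dependents on them
#' (nesting-aware sampling), so every generated code passes
#' [validate_code()] with zero issues. Controllers are drawn uniformly over
#' their non-zero states.
#'
#' @param schema A `denticle_schema`.
#' @param seed Optional seed for reproducibility.
#' @param base_loss Fossil mode: zero all O-group characters.
#' @param specimen_id Id for the returned one-row data frame.
#' @return One-row `denticle_codes` data frame.
#' @export
#' @examples
#' sch <- load_schema("denticles_v0.5")
#' code <- generate_code(sch, seed = 7)
#' nrow(validate_code(code, sch))  # 0
generate_code <- function(schema, seed = NULL, base_loss = FALSE,
                          specimen_id = "synthetic-1") {
  if (!is.null(seed)) set.seed(seed)
  states <- sample_states(schema)
  if (base_loss) states <- apply_base_loss(schema, states)
  df <- as_codes_df(states, schema, specimen_id)
  class(df) <- c("denticle_codes", "data.frame")
  df
}

#' @rdname generate_code
#' @param n Number of codes.
#' @export
generate_codes <- function(n, schema, seed = NULL, base_loss = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  rows <- lapply(seq_len(n), function(i)
    generate_code(schema, seed = NULL, base_loss = base_loss,
                  specimen_id = sprintf("synthetic-%d", i)))
  out <- do.call(rbind, rows)
  class(out) <- c("denticle_codes", "data.frame")
  out
}

apply_base_loss <- function(schema, states) {
  ogroup <- trait_ids(schema)[
    vapply(schema$traits, `[[`, "", "group") == "O"]
  states[ogroup] <- 0L
  repair_zero_rules(schema, states)
}

# after zeroing, re-fire the rules whose requirement is a 0 so dependents of
# a zeroed/changed controller stay consistent
repair_zero_rules <- function(schema, states) {
  forced <- forced_values(schema, states)
  zf <- forced[forced == 0L]
  states[names(zf)] <- 0L
  states
}

#' Generate a clustered synthetic dataset with known morphotype labels
#'
#' Draws `n_morphotypes` centroid codes (re-drawn until every pair differs in
#' at least 5 traits), then emits `specimens_per_type` specimens per type:
#' the centroid itself as the type's canonical exemplar, plus members mutated
#' per trait with probability `mutation_rate` (a deviating trait is resampled
#' to a different non-zero state). After mutation the nesting rules are
#' re-applied: dependents pinned by a controller are reset, and dependents
#' freed by a controller mutation are resampled to a valid non-zero state, so
#' every member validates cleanly. With `breakage_fraction > 0` every
#' specimen is additionally degraded via [degrade_code()]; with `base_loss`
#' the whole dataset is crown-only (all O-group characters 0).
#'
#' @param schema A `denticle_schema`.
#' @param cfg A [generator_config()].
#' @return List with `codes` (a `denticle_codes` data frame, with a
#'   `true_morphotype` metadata column) and `labels` (named character vector).
#' @export
make_cluster_dataset <- function(schema, cfg) {
  stopifnot(inherits(cfg, "generator_config"))
  set.seed(cfg$seed)
  ids <- trait_ids(schema)
  # centroids: pairwise distinct in >= 5 traits
  cents <- list()
  tries <- 0
  while (length(cents) < cfg$n_morphotypes) {
    cand <- sample_states(schema)
    if (cfg$base_loss) cand <- apply_base_loss(schema, cand)
    ok <- all(vapply(cents, function(cc) sum(cc != cand) >= 5, TRUE))
    if (ok) cents[[length(cents) + 1L]] <- cand
    tries <- tries + 1
    if (tries > 200 * cfg$n_morphotypes)
      stop("cannot place ", cfg$n_morphotypes,
           " centroids pairwise distinct in >= 5 traits")
  }
  rows <- list()
  labels <- character(0)
  for (i in seq_len(cfg$n_morphotypes)) {
    for (j in seq_len(cfg$specimens_per_type)) {
      x <- cents[[i]]
      if (j > 1 && cfg$mutation_rate > 0)
        x <- mutate_states(schema, x, cfg$mutation_rate)
      if (cfg$breakage_fraction > 0)
        x <- degrade_states(schema, x, cfg$breakage_fraction)
      sp <- sprintf("T%02d-%02d", i, j)
      rows[[sp]] <- x
      labels[sp] <- sprintf("type-%02d", i)
    }
  }
  codes <- do.call(rbind, lapply(names(rows), function(sp)
    as_codes_df(rows[[sp]], schema, sp)))
  codes$true_morphotype <- unname(labels)
  class(codes) <- c("denticle_codes", "data.frame")
  list(codes = codes, labels = labels)
}

mutate_states <- function(schema, states, rate) {
  ids <- names(states)
  hit <- stats::runif(length(ids)) < rate
  # a morphotype member deviates from its canonical code in at most two
  # traits (the near-duplicate bound that defines morphotype membership);
  # cap the per-trait proposals so the true labels stay consistent with it
  if (sum(hit) > 2) {
    keep <- sample(which(hit), 2)
    hit[] <- FALSE
    hit[keep] <- TRUE
  }
  for (id in ids[hit]) {
    nz <- nonzero_states(schema$traits[[id]])
    alt <- setdiff(nz, states[[id]])
    if (length(alt) > 0) states[id] <- resample1(alt)
  }
  # re-repair: walk traits in order; pinned dependents are reset, freed
  # dependents holding an orphaned 0 are resampled to a codable state
  for (id in ids) {
    forced <- forced_values(schema, states)
    if (id %in% names(forced)) {
      states[id] <- forced[[id]]
    } else if (states[[id]] == 0L) {
      states[id] <- resample1(nonzero_states(schema$traits[[id]]))
    }
  }
  if (all(c("B1", "B2", "C1", "C2") %in% ids) &&
      states[["B1"]] == 4L && states[["C1"]] == 4L &&
      states[["B2"]] > states[["C2"]])
    states[c("B2", "C2")] <- states[c("C2", "B2")]
  states
}

degrade_states <- function(schema, states, breakage_fraction) {
  zc <- names(states)[vapply(schema$traits[names(states)],
                             `[[`, TRUE, "has_zero_state")]
  hit <- zc[stats::runif(length(zc)) < breakage_fraction]
  states[hit] <- 0L
  repair_zero_rules(schema, states)
}

#' Taphonomically degrade a code
#'
#' Zeroes a random subset of the zero-capable traits (each with probability
#' `breakage_fraction`), then re-applies the nesting rules so dependents of a
#' zeroed controller are zeroed too; the result always validates. With
#' breakage 0 the code is returned unchanged; with breakage 1 every
#' zero-capable trait is 0. Because surviving traits keep their states, the
#' disparity between a code and its degraded copy is 0 whenever it is
#' defined.
#'
#' @param code A single code (named state vector or one-row data frame).
#' @param schema A `denticle_schema`.
#' @param breakage_fraction Per-trait zeroing probability in `[0, 1]`.
#' @param seed Optional seed.
#' @return One-row `denticle_codes` data frame.
#' @export
degrade_code <- function(code, schema, breakage_fraction, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  df <- as_codes_df(code, schema)
  states <- stats::setNames(as.integer(df[1, trait_ids(schema)]),
                            trait_ids(schema))
  states <- degrade_states(schema, states, breakage_fraction)
  out <- as_codes_df(states, schema, df$specimen_id[1])
  class(out) <- c("denticle_codes", "data.frame")
  out
}

#' Write a cluster dataset and its true labels
#'
#' Emits a standard coding sheet plus a labels CSV (`specimen_id`,
#' `true_morphotype`). Identical configurations produce byte-identical files.
#'
#' @param dataset Result of [make_cluster_dataset()].
#' @param sheet_path,labels_path Output paths.
#' @param schema A `denticle_schema`.
#' @return `sheet_path`, invisibly.
#' @export
write_cluster_dataset <- function(dataset, sheet_path, labels_path, schema) {
  write_coding_sheet(dataset$codes, sheet_path, schema)
  utils::write.table(data.frame(specimen_id = names(dataset$labels),
                                true_morphotype = unname(dataset$labels)),
                     labels_path, sep = ",", quote = TRUE, row.names = FALSE,
                     qmethod = "double")
  invisible(sheet_path)
}
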