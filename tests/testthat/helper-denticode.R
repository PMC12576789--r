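# Shared fixtures: a tiny hand-set schema, an independent brute-force
# disparity oracle, and random schema/code generators for property tests.

v05 <- load_schema("denticles_v0.5")

# three-trait toy schema (weights 2, 1, 0.5) with hand-set matrices; X2 and
# X3 are zero-capable, and X2 = 1 pins X3 = 0
toy_schema <- function() {
  mk <- function(id, group, name, weight, idx, labels, dist,
                 zero = NA_character_) {
    trait_def(id, group, name, weight,
              data.frame(index = idx, label = labels), dist, zero)
  }
  d1 <- matrix(c(0, 1, 3,
                 1, 0, 2,
                 3, 2, 0), 3, 3, dimnames = list(1:3, 1:3))
  d2 <- matrix(c(0, 2,
                 2, 0), 2, 2, dimnames = list(1:2, 1:2))
  d3 <- matrix(c(0, 1, 2,
                 1, 0, 1,
                 2, 1, 0), 3, 3, dimnames = list(1:3, 1:3))
  traits <- list(
    mk("X1", "X", "toy one", 2, 1:3, c("a", "b", "c"), d1),
    mk("X2", "X", "toy two", 1, 0:2, c("none", "p", "q"), d2,
       "broken/unobservable"),
    mk("X3", "X", "toy three", 0.5, 0:3, c("none", "r", "s", "t"), d3,
       "absent-nested"))
  rules <- list(list(controller = "X2", when = 1L,
                     requires = list(X3 = 0L)))
  denticode:::new_schema("toy_v1.0", traits, rules)
}

toy_code <- function(id, x1, x2, x3) {
  data.frame(specimen_id = id, X1 = x1, X2 = x2, X3 = x3,
             stringsAsFactors = FALSE)
}

# independent naive double-loop reference for the disparity engine
oracle_pair <- function(av, bv, schema, normalized = TRUE) {
  raw <- 0; den <- 0; cnt <- 0
  for (tr in schema$traits) {
    a <- as.integer(av[[tr$trait_id]])
    b <- as.integer(bv[[tr$trait_id]])
    if (a != 0L && b != 0L) {
      raw <- raw + tr$weight * tr$dist[as.character(a), as.character(b)]
      den <- den + tr$weight * max(tr$dist)
      cnt <- cnt + 1
    }
  }
  if (cnt == 0) return(NA_real_)
  if (!normalized) return(raw)
  if (den == 0) return(NA_real_)
  raw / den
}

oracle_matrix <- function(codes, schema, normalized = TRUE) {
  n <- nrow(codes)
  D <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    D[i, j] <- oracle_pair(codes[i, ], codes[j, ], schema, normalized)
  }
  D
}

# per-pair maximum attainable weighted distance over the shared codable set
oracle_attainable <- function(codes, schema) {
  n <- nrow(codes)
  A <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    for (tr in schema$traits) {
      a <- as.integer(codes[i, tr$trait_id])
      b <- as.integer(codes[j, tr$trait_id])
      if (a != 0L && b != 0L) A[i, j] <- A[i, j] + tr$weight * max(tr$dist)
    }
  }
  A
}

# random schema with <= 6 traits and <= 5 states, random weights and
# symmetric integer distance matrices; no nesting rules (engine-level tests)
random_schema <- function(n_traits = sample(2:6, 1), max_states = 5) {
  traits <- lapply(seq_len(n_traits), function(i) {
    ns <- sample(2:max_states, 1)
    first <- sample(c(0L, 1L), 1)
    idx <- seq(first, length.out = ns)
    nz <- idx[idx != 0L]
    m <- matrix(0, length(nz), length(nz), dimnames = list(nz, nz))
    vals <- sample(1:4, sum(upper.tri(m)), replace = TRUE)
    m[upper.tri(m)] <- vals
    m <- m + t(m)
    trait_def(paste0("T", i), "T", paste("random trait", i),
              sample(c(0.5, 1, 2), 1),
              data.frame(index = idx, label = paste0("s", idx)), m,
              if (first == 0L) "broken/unobservable" else NA_character_)
  })
  denticode:::new_schema("random_v1.0", traits, list())
}

random_codes <- function(n, schema, p_zero = 0.3) {
  rows <- lapply(seq_len(n), function(i) {
    st <- vapply(schema$traits, function(tr) {
      nz <- tr$states$index[tr$states$index != 0L]
      if (tr$has_zero_state && stats::runif(1) < p_zero) 0L
      else if (length(nz) == 1) nz else sample(nz, 1)
    }, 1L)
    df <- as.data.frame(as.list(st))
    names(df) <- trait_ids(schema)
    cbind(data.frame(specimen_id = paste0("r", i)), df)
  })
  do.call(rbind, rows)
}

# apply 40% breakage to every other specimen, in place
degrade_half <- function(codes, schema, breakage, seed) {
  set.seed(seed)
  for (i in seq(1, nrow(codes), by = 2)) {
    d <- degrade_code(codes[i, ], schema, breakage)
    codes[i, trait_ids(schema)] <- d[1, trait_ids(schema)]
  }
  codes
}
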