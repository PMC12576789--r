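#' Construct a single character-trait definition
#'
#' A trait is one discrete morphological character: an identifier
#' (letter + number, e.g. `"F1"`), a group letter, a human-readable name, a
#' disparity weight in \{0.5, 1, 2\}, an ordered set of enumerated states, and
#' a symmetric state-distance matrix over the non-zero states. Traits whose
#' first state index is 0 carry a sentinel state meaning the character is
#' broken/unobservable, not applicable, or absent because a controlling
#' character lacks the feature; state 0 is always excluded from pairwise
#' comparison.
#'
#' @param trait_id Short label, letter + number.
#' @param group Single letter A-O.
#' @param name Human-readable trait name.
#' @param weight Disparity weight; one of 0.5, 1, 2.
#' @param states Data frame with columns `index` (integer, consecutive,
#'   starting at 0 or 1) and `label`.
#' @param dist Symmetric numeric matrix over the non-zero state indices
#'   (dimnames must equal those indices), zero diagonal.
#' @param zero_meaning For zero-capable traits, one of
#'   `"broken/unobservable"`, `"not-applicable"`, `"absent-nested"`;
#'   `NA` otherwise.
#' @return An object of class `trait_def`.
#' @export
trait_def <- function(trait_id, group, name, weight, states, dist,
                      zero_meaning = NA_character_) {
  states <- data.frame(index = as.integer(states$index),
                       label = as.character(states$label),
                       stringsAsFactors = FALSE)
  structure(list(trait_id = trait_id, group = group, name = name,
                 weight = weight, states = states,
                 has_zero_state = 0L %in% states$index,
                 zero_meaning = zero_meaning,
                 dist = dist),
            class = "trait_def")
}

nonzero_states <- function(trait) trait$states$index[trait$states$index != 0L]

#' @export
print.trait_def <- function(x, ...) {
  cat(sprintf("Trait %s (%s, group %s): %d states, weight %g\n",
              x$trait_id, x$name, x$group, nrow(x$states), x$weight))
  invisible(x)
}

new_schema <- function(version, traits, nesting_rules,
                       historical = FALSE, note = NULL) {
  names(traits) <- vapply(traits, `[[`, "", "trait_id")
  structure(list(version = version, traits = traits,
                 nesting_rules = nesting_rules,
                 historical = historical, note = note),
            class = "denticle_schema")
}

#' @export
print.denticle_schema <- function(x, ...) {
  cat(sprintf("Denticle character schema %s: %d traits, %d nesting rules%s\n",
              x$version, length(x$traits), length(x$nesting_rules),
              if (isTRUE(x$historical)) " [historical stub]" else ""))
  invisible(x)
}

#' Trait identifiers of a schema
#' @param schema A `denticle_schema`.
#' @return Character vector of trait ids in schema order.
#' @export
trait_ids <- function(schema) names(schema$traits)

#' Disparity weights of all traits
#' @param schema A `denticle_schema`.
#' @return Named numeric vector of weights in schema order.
#' @export
trait_weights <- function(schema) {
  vapply(schema$traits, `[[`, numeric(1), "weight")
}

get_trait <- function(schema, trait_id) {
  tr <- schema$traits[[trait_id]]
  if (is.null(tr)) stop("unknown trait: ", trait_id)
  tr
}

#' Distance between two states of a trait
#'
#' Looks up the state-distance matrix of a trait. When either state is the
#' 0 sentinel (broken / unobservable / not applicable), the pair is not
#' comparable and `NA` is returned — never a numeric 0, so missingness can
#' never masquerade as similarity.
#'
#' @param schema A `denticle_schema`.
#' @param trait_id Trait label.
#' @param a,b State indices.
#' @return Non-negative distance, or `NA_real_` when either state is 0.
#' @export
#' @examples
#' sch <- load_schema("denticles_v0.5")
#' trait_distance(sch, "A1", 3, 3)   # 0
#' trait_distance(sch, "B1", 0, 2)   # NA: anterior too broken to code
trait_distance <- function(schema, trait_id, a, b) {
  tr <- get_trait(schema, trait_id)
  ok <- c(a, b) %in% tr$states$index
  if (!all(ok))
    stop("state out of range for trait ", trait_id, ": ",
         paste(c(a, b)[!ok], collapse = ", "))
  if (a == 0L || b == 0L) return(NA_real_)
  tr$dist[as.character(a), as.character(b)]
}

max_trait_distance <- function(trait) max(trait$dist)

#' Validate a schema against its structural invariants
#'
#' Checks every trait (weight domain, consecutive state indices, square /
#' symmetric / zero-diagonal / non-negative distance matrix over exactly the
#' non-zero states) and the schema-level rules (unique trait ids, nesting
#' rules referencing known traits, zero-required dependents being
#' zero-capable). Issues are returned as data, not thrown.
#'
#' @param schema A `denticle_schema`.
#' @return Data frame with columns `trait_id`, `rule`, `message`;
#'   zero rows iff the schema is valid.
#' @export
validate_schema <- function(schema) {
  iss <- list()
  add <- function(trait_id, rule, message)
    iss[[length(iss) + 1L]] <<- data.frame(trait_id = trait_id, rule = rule,
                                           message = message,
                                           stringsAsFactors = FALSE)
  ids <- vapply(schema$traits, `[[`, "", "trait_id")
  if (anyDuplicated(ids))
    add(ids[duplicated(ids)][1], "duplicate-trait", "duplicated trait id")
  for (tr in schema$traits) {
    id <- tr$trait_id
    if (!tr$weight %in% c(0.5, 1, 2))
      add(id, "weight-domain",
          sprintf("weight %g not in {0.5, 1, 2}", tr$weight))
    sidx <- sort(tr$states$index)
    if (!(sidx[1] %in% c(0L, 1L)) ||
        !all(diff(sidx) == 1L))
      add(id, "state-indices",
          "state indices must be consecutive from 0 or 1")
    nz <- as.character(nonzero_states(tr))
    d <- tr$dist
    if (!is.matrix(d) || nrow(d) != ncol(d) ||
        !identical(rownames(d), nz) || !identical(colnames(d), nz)) {
      add(id, "dist-states",
          "distance matrix must be square over exactly the non-zero states")
      next
    }
    if (any(diag(d) != 0))
      add(id, "diagonal", "distance diagonal must be zero")
    if (!isSymmetric(unname(d)))
      add(id, "symmetry", "distance matrix must be symmetric")
    if (any(d < 0))
      add(id, "nonnegative", "distances must be non-negative")
  }
  for (rule in schema$nesting_rules) {
    miss <- setdiff(c(rule$controller, names(rule$requires)), ids)
    if (length(miss) > 0) {
      add(miss[1], "nesting-unknown-trait",
          sprintf("nesting rule on %s references unknown trait %s",
                  rule$controller, paste(miss, collapse = ", ")))
      next
    }
    zero_req <- names(rule$requires)[unlist(rule$requires) == 0]
    for (dep in zero_req) {
      if (!schema$traits[[dep]]$has_zero_state)
        add(dep, "nesting-zero-state",
            sprintf("dependent %s of rule on %s lacks a zero state",
                    dep, rule$controller))
    }
  }
  if (length(iss) == 0)
    return(data.frame(trait_id = character(), rule = character(),
                      message = character(), stringsAsFactors = FALSE))
  do.call(rbind, iss)
}

bundled_schema_path <- function(version) {
  system.file("extdata", "schemas", paste0(version, ".json"),
              package = "denticode")
}

bundled_schema_versions <- function() {
  dir <- system.file("extdata", "schemas", package = "denticode")
  sub("\\.json$", "", list.files(dir, pattern = "\\.json$"))
}

#' Load a character schema by version name or from a file
#'
#' Bundled versions are addressed by name (`"denticles_v0.5"` is the current
#' full schema; `v0.1`, `v0.2` and `v0.4` ship as historical stubs whose
#' distance matrices are unavailable). A path to a schema file in JSON (or
#' YAML, by file extension) is also accepted, so externally curated distance
#' matrices can be dropped in without code changes. The loaded schema is
#' validated; a malformed file raises an error naming the offending trait.
#'
#' @param version_or_path Bundled version identifier or path to a schema file.
#' @return A validated `denticle_schema`.
#' @export
#' @examples
#' sch <- load_schema("denticles_v0.5")
#' length(sch$traits)  # 46
load_schema <- function(version_or_path) {
  path <- version_or_path
  if (!file.exists(path)) {
    path <- bundled_schema_path(version_or_path)
    if (!nzchar(path) || !file.exists(path))
      stop("unknown schema version or unreadable file: ", version_or_path,
           "\nbundled versions: ",
           paste(bundled_schema_versions(), collapse = ", "))
  }
  ext <- tolower(tools::file_ext(path))
  lst <- if (ext %in% c("yaml", "yml")) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE,
                       simplifyMatrix = FALSE)
  }
  schema <- schema_from_list(lst)
  if (!isTRUE(schema$historical)) {
    issues <- validate_schema(schema)
    if (nrow(issues) > 0)
      stop("malformed schema '", schema$version, "': ",
           paste(sprintf("[%s] %s: %s", issues$trait_id, issues$rule,
                         issues$message), collapse = "; "))
  }
  schema
}

schema_from_list <- function(lst) {
  traits <- lapply(lst$traits, function(t) {
    st <- data.frame(
      index = vapply(t$states, function(s) as.integer(s$index), 1L),
      label = vapply(t$states, function(s) as.character(s$label), ""),
      stringsAsFactors = FALSE)
    nz <- as.character(st$index[st$index != 0L])
    d <- do.call(rbind, lapply(t$dist, function(row) as.numeric(row)))
    if (is.null(d)) d <- matrix(numeric(0), 0, 0)
    dimnames(d) <- list(nz, nz)
    trait_def(t$trait_id, t$group, t$name, as.numeric(t$weight), st, d,
              zero_meaning = if (is.null(t$zero_meaning)) NA_character_
                             else t$zero_meaning)
  })
  rules <- lapply(lst$nesting_rules, function(r) {
    list(controller = r$controller, when = as.integer(unlist(r$when)),
         requires = lapply(r$requires, as.integer))
  })
  new_schema(lst$version, traits, rules,
             historical = isTRUE(lst$historical), note = lst$note)
}

schema_to_list <- function(schema) {
  list(
    version = schema$version,
    historical = isTRUE(schema$historical),
    note = schema$note,
    traits = lapply(unname(schema$traits), function(t) {
      list(trait_id = t$trait_id, group = t$group, name = t$name,
           weight = t$weight,
           states = lapply(seq_len(nrow(t$states)), function(i)
             list(index = t$states$index[i], label = t$states$label[i])),
           zero_meaning = if (is.na(t$zero_meaning)) NULL else t$zero_meaning,
           dist = lapply(seq_len(nrow(t$dist)), function(i)
             unname(t$dist[i, ])))
    }),
    nesting_rules = lapply(schema$nesting_rules, function(r)
      list(controller = r$controller, when = r$when, requires = r$requires))
  )
}

#' Write a schema to a JSON (or YAML) file
#'
#' Round-trip safe: `load_schema(write_schema_file(s, path))` reproduces the
#' schema field by field.
#'
#' @param schema A `denticle_schema`.
#' @param path Output path; `.yaml`/`.yml` selects the YAML dialect,
#'   anything else JSON.
#' @return `path`, invisibly.
#' @export
write_schema_file <- function(schema, path) {
  lst <- schema_to_list(schema)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    yaml::write_yaml(lst, path)
  } else {
    jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA,
                         null = "null", pretty = TRUE)
  }
  invisible(path)
}

#' Drop traits (or whole trait groups) from a schema
#'
#' Used by the character-jackknife sensitivity analysis: removes the named
#' traits, prunes nesting rules whose controller was dropped and removes
#' dropped dependents from the remaining rules.
#'
#' @param schema A `denticle_schema`.
#' @param drop Character vector of trait ids and/or single group letters.
#' @return The reduced `denticle_schema` (version suffixed with `-jackknife`).
#' @export
drop_traits <- function(schema, drop) {
  ids <- trait_ids(schema)
  groups <- vapply(schema$traits, `[[`, "", "group")
  expand <- unique(unlist(lapply(drop, function(d) {
    if (d %in% ids) return(d)
    if (nchar(d) == 1 && d %in% groups) return(ids[groups == d])
    stop("unknown trait or group: ", d)
  })))
  keep <- setdiff(ids, expand)
  if (length(keep) == 0) stop("cannot drop all traits")
  rules <- lapply(schema$nesting_rules, function(r) {
    if (!r$controller %in% keep) return(NULL)
    r$requires <- r$requires[intersect(names(r$requires), keep)]
    if (length(r$requires) == 0) return(NULL)
    r
  })
  new_schema(paste0(schema$version, "-jackknife"),
             schema$traits[keep], Filter(Negate(is.null), rules))
}

#' Bump a schema version number
#'
#' State additions to existing traits increment the version by 0.1; new
#' character traits increment it by 1. All historical versions remain
#' loadable by name.
#'
#' @param version Version string such as `"denticles_v0.5"`.
#' @param change `"state"` (+0.1) or `"trait"` (+1).
#' @return The incremented version string.
#' @export
#' @examples
#' bump_version("denticles_v0.5", "state")  # "denticles_v0.6"
#' bump_version("denticles_v0.5", "trait")  # "denticles_v1.5"
bump_version <- function(version, change = c("state", "trait")) {
  change <- match.arg(change)
  m <- regmatches(version, regexec("^(.*_v)([0-9]+)\\.([0-9]+)$", version))[[1]]
  if (length(m) == 0) stop("unparseable version: ", version)
  major <- as.integer(m[3]); minor <- as.integer(m[4])
  if (change == "state") minor <- minor + 1L else major <- major + 1L
  paste0(m[2], major, ".", minor)
}
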