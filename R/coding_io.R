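#' Read a specimen coding sheet
#'
#' A coding sheet is delimited text (comma or tab, sniffed from the header
#' line) with one row per denticle specimen: a `specimen_id` column, one
#' integer column per schema trait (any column order), and arbitrary extra
#' metadata columns (taxon, body position, source, ...), which are preserved.
#' Missing trait columns and blank or non-integer trait cells are errors —
#' a blank is never silently imputed as the 0 ("too broken to code") state,
#' which would bias disparity downward.
#'
#' @param path Path to a CSV/TSV file.
#' @param schema A `denticle_schema`; its trait ids define the required
#'   columns.
#' @return Data frame of class `denticle_codes`: `specimen_id`, trait columns
#'   in schema order, then metadata columns.
#' @export
read_coding_sheet <- function(path, schema) {
  if (!file.exists(path)) stop("unreadable coding sheet: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep, quote = "\"",
                          colClasses = "character", check.names = FALSE,
                          stringsAsFactors = FALSE, comment.char = "")
  ids <- trait_ids(schema)
  missing <- setdiff(c("specimen_id", ids), names(df))
  if (length(missing) > 0)
    stop("coding sheet is missing required column(s): ",
         paste(missing, collapse = ", "))
  for (id in ids) {
    cell <- df[[id]]
    bad <- is.na(cell) | !grepl("^-?[0-9]+$", trimws(cell))
    if (any(bad))
      stop(sprintf("trait %s has blank or non-integer value(s) in row(s) %s",
                   id, paste(which(bad), collapse = ", ")))
    df[[id]] <- as.integer(cell)
  }
  meta <- setdiff(names(df), c("specimen_id", ids))
  out <- df[, c("specimen_id", ids, meta), drop = FALSE]
  class(out) <- c("denticle_codes", "data.frame")
  out
}

#' Write a coding sheet
#'
#' Trait columns are written in canonical schema order with RFC 4180 quoting;
#' [read_coding_sheet()] on the result reproduces the codes exactly.
#'
#' @param codes Data frame of codes (as returned by [read_coding_sheet()] or
#'   the synthetic generator).
#' @param path Output path; a `.tsv` extension selects tab separation.
#' @param schema A `denticle_schema`.
#' @return `path`, invisibly.
#' @export
write_coding_sheet <- function(codes, path, schema) {
  ids <- trait_ids(schema)
  missing <- setdiff(c("specimen_id", ids), names(codes))
  if (length(missing) > 0)
    stop("codes are missing column(s): ", paste(missing, collapse = ", "))
  meta <- setdiff(names(codes), c("specimen_id", ids))
  out <- as.data.frame(codes)[, c("specimen_id", ids, meta), drop = FALSE]
  sep <- if (tolower(tools::file_ext(path)) == "tsv") "\t" else ","
  utils::write.table(out, path, sep = sep, quote = TRUE, row.names = FALSE,
                     qmethod = "double")
  invisible(path)
}

# specimen x trait integer state matrix, rownames = specimen ids
code_states <- function(codes, schema) {
  ids <- trait_ids(schema)
  missing <- setdiff(ids, names(codes))
  if (length(missing) > 0)
    stop("codes are missing trait column(s): ",
         paste(missing, collapse = ", "))
  m <- as.matrix(as.data.frame(codes)[, ids, drop = FALSE])
  storage.mode(m) <- "integer"
  rownames(m) <- as.character(codes$specimen_id)
  m
}

#' Validate coded specimens against a schema
#'
#' Three closed-vocabulary rules are checked per specimen:
#' * `range` — every state lies within the trait's declared index range
#'   (state 0 only where the trait has a zero state);
#' * `nesting` — whenever a controlling trait is in a state that makes a
#'   dependent character inapplicable, the dependent carries the required
#'   value (usually 0);
#' * `ordering-B2C2` — for denticles lacking directionality (B1 = 4 and
#'   C1 = 4) the anterior macro texture must carry the lower score of the
#'   B2/C2 pair.
#'
#' Issues are returned as data in deterministic order (specimen, then trait).
#'
#' @param codes Data frame of codes.
#' @param schema A `denticle_schema`.
#' @return Data frame with columns `specimen_id`, `trait_id`, `rule`,
#'   `message`; zero rows iff all codes are valid.
#' @export
validate_codes <- function(codes, schema) {
  m <- code_states(codes, schema)
  iss <- list()
  add <- function(sp, tr, rule, msg)
    iss[[length(iss) + 1L]] <<- data.frame(specimen_id = sp, trait_id = tr,
                                           rule = rule, message = msg,
                                           stringsAsFactors = FALSE)
  for (i in seq_len(nrow(m))) {
    sp <- rownames(m)[i]
    for (id in colnames(m)) {
      tr <- schema$traits[[id]]
      if (!m[i, id] %in% tr$states$index)
        add(sp, id, "range",
            sprintf("state %d out of range [%d..%d]%s", m[i, id],
                    min(nonzero_states(tr)), max(nonzero_states(tr)),
                    if (tr$has_zero_state) " (or 0)" else ""))
    }
    for (rule in schema$nesting_rules) {
      ctrl <- m[i, rule$controller]
      if (!ctrl %in% rule$when) next
      for (dep in names(rule$requires)) {
        req <- rule$requires[[dep]]
        if (m[i, dep] != req)
          add(sp, dep, "nesting",
              sprintf("%s=%d requires %s=%d (found %d)",
                      rule$controller, ctrl, dep, req, m[i, dep]))
      }
    }
    if (all(c("B1", "B2", "C1", "C2") %in% colnames(m)) &&
        m[i, "B1"] == 4L && m[i, "C1"] == 4L &&
        m[i, "B2"] > 0L && m[i, "C2"] > 0L && m[i, "B2"] > m[i, "C2"])
      add(sp, "B2", "ordering-B2C2",
          sprintf("B2=%d exceeds C2=%d on a denticle without directionality",
                  m[i, "B2"], m[i, "C2"]))
  }
  if (length(iss) == 0)
    return(data.frame(specimen_id = character(), trait_id = character(),
                      rule = character(), message = character(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, iss)
  out[order(match(out$specimen_id, rownames(m)), out$trait_id), ,
      drop = FALSE]
}

#' @rdname validate_codes
#' @param code A single code: one-row data frame or named vector of states.
#' @export
validate_code <- function(code, schema) {
  validate_codes(as_codes_df(code, schema), schema)
}

# accept a named integer vector or 1-row df as a single code
as_codes_df <- function(code, schema, specimen_id = "specimen") {
  if (is.data.frame(code)) {
    if (!"specimen_id" %in% names(code))
      code$specimen_id <- specimen_id
    return(code)
  }
  df <- as.data.frame(as.list(as.integer(code[trait_ids(schema)])))
  names(df) <- trait_ids(schema)
  cbind(data.frame(specimen_id = specimen_id, stringsAsFactors = FALSE), df)
}

#' Write a validation report as JSON lines
#'
#' One issue per line, ready for machine consumption.
#'
#' @param issues Data frame from [validate_codes()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_validation_report <- function(issues, path) {
  lines <- vapply(seq_len(nrow(issues)), function(i)
    jsonlite::toJSON(as.list(issues[i, ]), auto_unbox = TRUE), "")
  writeLines(lines, path)
  invisible(path)
}
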