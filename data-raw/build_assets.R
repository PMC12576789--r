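# Generates the bundled extdata assets. Run from the package root:
#   Rscript data-raw/build_assets.R
# The v0.5 schema JSON is produced from the curated descriptor tables in
# R/schema_v05.R and then frozen; a test asserts the two stay identical.

suppressMessages(pkgload::load_all(".", quiet = TRUE))

dir.create("inst/extdata/schemas", showWarnings = FALSE, recursive = TRUE)

## current schema ------------------------------------------------------------
sch <- build_v05_schema()
write_schema_file(sch, "inst/extdata/schemas/denticles_v0.5.json")

## historical stubs ----------------------------------------------------------
for (v in c("denticles_v0.1", "denticles_v0.2", "denticles_v0.4")) {
  stub <- list(version = v, historical = TRUE,
               note = paste("historical version retained for replication of",
                            "prior studies; structure only, distance",
                            "matrices unavailable"),
               traits = list(), nesting_rules = list())
  jsonlite::write_json(stub,
                       file.path("inst/extdata/schemas", paste0(v, ".json")),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
}

## synthetic morphotype catalog ----------------------------------------------
# A stand-in catalog of 160 generated canonical codes plus the two catch-all
# types ("Generic Linear", "Generic Geometric"); synthetic — it emulates the
# structure of a coded morphotype catalog, not any real one.
set.seed(20260501)
codes <- generate_codes(200, sch)
key <- apply(code_states(codes, sch), 1, paste, collapse = ",")
codes <- codes[!duplicated(key), ][seq_len(160), ]
codes$specimen_id <- sprintf("MT%03d", seq_len(160))
codes$morphotype_name <- codes$specimen_id
codes$gross_type <- NA_character_

catch_all <- function(id, name, f1, gross) {
  st <- stats::setNames(rep(0L, 46), trait_ids(sch))
  st[c("A1", "B3", "C3", "D1", "E1")] <- c(7L, 1L, 1L, 1L, 1L)
  st[c("F1", "G1", "G2", "L1", "M1", "N1")] <- c(f1, 4L, 3L, 2L, 1L, 2L)
  df <- as_codes_df(st, sch, id)
  df$morphotype_name <- name
  df$gross_type <- gross
  df
}
catalog <- rbind(codes,
                 catch_all("MT161", "Generic Linear", 2L, "Other Linear"),
                 catch_all("MT162", "Generic Geometric", 3L, "Other Geometric"))
stopifnot(nrow(catalog) == 162,
          !anyDuplicated(apply(code_states(catalog, sch), 1, paste,
                               collapse = ",")),
          nrow(validate_codes(catalog, sch)) == 0)
write_coding_sheet(catalog, "inst/extdata/synthetic_morphotype_catalog.csv",
                   sch)
cat("assets written\n")
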