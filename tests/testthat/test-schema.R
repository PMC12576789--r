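test_that("bundled v0.5 schema has the printed structure and weights", {
  expect_equal(length(v05$traits), 46)
  expect_equal(sort(unique(vapply(v05$traits, `[[`, "", "group"))),
               LETTERS[1:15])
  w <- trait_weights(v05)
  expect_equal(unname(w[c("A1", "F1")]), c(2, 2))
  expect_equal(unname(w[c("A2", "E2", "E3", "E4", "H1", "K2")]),
               rep(0.5, 6))
  expect_equal(unname(w[c("B1", "B2", "B3", "C1", "C2", "C3", "D1", "E1",
                          "G1", "G2", "G3", "K1", "M1", "N1")]),
               rep(1, 14))
  expect_equal(unname(w[paste0("O", 1:10)]), rep(1, 10))
  expect_equal(unname(w[c("I1", "I2", "I3", "J1", "J2",
                          "L1", "L2", "L3", "L4",
                          "M2", "M3", "M4", "N2", "N3")]),
               rep(0.5, 14))
  # state counts at the extremes of the scheme
  expect_equal(nrow(v05$traits$F1$states), 6)
  expect_equal(max(v05$traits$E1$states$index), 11)
  expect_equal(max(v05$traits$O1$states$index), 12)
  expect_equal(max(v05$traits$K1$states$index), 11)
  expect_equal(nrow(v05$traits$B3$states), 2)
})

test_that("shipped schema self-validates and all matrices satisfy invariants", {
  expect_equal(nrow(validate_schema(v05)), 0)
  for (tr in v05$traits) {
    nz <- tr$states$index[tr$states$index != 0L]
    expect_identical(rownames(tr$dist), as.character(nz))
    expect_true(all(diag(tr$dist) == 0))
    expect_true(isSymmetric(unname(tr$dist)))
    expect_true(all(tr$dist >= 0))
    expect_true(all(tr$dist[upper.tri(tr$dist)] > 0))
    expect_true(tr$weight %in% c(0.5, 1, 2))
  }
})

test_that("frozen v0.5 asset is identical to the curated generator output", {
  expect_equal(build_v05_schema(), v05)
})

test_that("every qualitative ordering from the disparity descriptions holds", {
  ch <- matrix_ordering_checks(v05)
  expect_gte(nrow(ch), 30)
  expect_true(all(ch$ok), info = paste(ch$check[!ch$ok], collapse = "; "))
})

test_that("trait_distance handles identity, zero sentinels and bad input", {
  expect_equal(trait_distance(v05, "A1", 3, 3), 0)
  expect_true(is.na(trait_distance(v05, "B1", 0, 2)))
  expect_true(is.na(trait_distance(v05, "E2", 1, 0)))
  expect_error(trait_distance(v05, "ZZ", 1, 1), "unknown trait")
  expect_error(trait_distance(v05, "B3", 1, 9), "out of range")
})

test_that("schema files round-trip exactly through JSON and YAML", {
  for (ext in c("json", "yaml")) {
    path <- withr::local_tempfile(fileext = paste0(".", ext))
    write_schema_file(v05, path)
    expect_equal(load_schema(path), v05)
  }
})

test_that("validate_schema reports constructed violations as data", {
  bad <- v05
  bad$traits$K1$dist[1, 2] <- 99  # break symmetry
  iss <- validate_schema(bad)
  expect_equal(iss$rule[iss$trait_id == "K1"], "symmetry")

  bad2 <- v05
  bad2$traits$D1$weight <- 0.7
  iss2 <- validate_schema(bad2)
  expect_equal(iss2$rule[iss2$trait_id == "D1"], "weight-domain")

  # deleting a trait referenced by nesting rules is caught at load time
  lst <- jsonlite::fromJSON(system.file("extdata", "schemas",
                                        "denticles_v0.5.json",
                                        package = "denticode"),
                            simplifyDataFrame = FALSE,
                            simplifyMatrix = FALSE)
  keep <- vapply(lst$traits, function(t) t$trait_id != "F1", TRUE)
  lst$traits <- lst$traits[keep]
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(lst, path, auto_unbox = TRUE, digits = NA)
  expect_error(load_schema(path), "F1")
})

test_that("unknown versions error and historical stubs load flagged", {
  expect_error(load_schema("denticles_v9.9"), "unknown schema version")
  stub <- load_schema("denticles_v0.2")
  expect_true(stub$historical)
  expect_equal(length(stub$traits), 0)
})

test_that("descriptor matrices honour the scale and ordinal expansion", {
  # a two-state trait coded "equally different" gets distance 2
  m <- build_matrix_from_descriptors(
    1:2, data.frame(a = 1, b = 2, descriptor = "equally different"))
  expect_equal(m["1", "2"], 2)
  expect_equal(diag(m), c("1" = 0, "2" = 0))
  # ordinal chain expands to |i - j| unit steps
  m3 <- build_matrix_from_descriptors(
    1:3, data.frame(a = 1:2, b = 2:3, descriptor = "step"),
    complete = "path")
  expect_equal(m3["1", "3"], 2 * m3["1", "2"])
  # errors: missing pair, unknown descriptor
  expect_error(build_matrix_from_descriptors(
    1:3, data.frame(a = 1, b = 2, descriptor = "step")), "missing")
  expect_error(build_matrix_from_descriptors(
    1:2, data.frame(a = 1, b = 2, descriptor = "sorta the same")),
    "unknown descriptor")
})

test_that("jackknife schema reduction prunes traits and rules", {
  red <- drop_traits(v05, c("F1", "O"))
  expect_equal(length(red$traits), 46 - 11)
  ctrls <- vapply(red$nesting_rules, `[[`, "", "controller")
  expect_false("F1" %in% ctrls)
  expect_false(any(grepl("^O", ctrls)))
  expect_error(drop_traits(v05, LETTERS[1:15]), "cannot drop all")
  expect_error(drop_traits(v05, "Q9"), "unknown trait")
})

test_that("version numbering bumps by 0.1 for states and 1.0 for traits", {
  expect_equal(bump_version("denticles_v0.5", "state"), "denticles_v0.6")
  expect_equal(bump_version("denticles_v0.5", "trait"), "denticles_v1.5")
})
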