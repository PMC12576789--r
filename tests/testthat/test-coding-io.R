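test_that("coding sheets round-trip exactly, with metadata and quoting", {
  codes <- generate_codes(10, v05, seed = 11)
  codes$taxon <- paste0("sp", seq_len(10))
  codes$note <- "body position, unknown"  # embedded comma forces quoting
  path <- withr::local_tempfile(fileext = ".csv")
  write_coding_sheet(codes, path, v05)
  back <- read_coding_sheet(path, v05)
  expect_equal(as.data.frame(back), as.data.frame(codes))

  # tab-separated dialect is sniffed from the header
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_coding_sheet(codes, tsv, v05)
  expect_equal(as.data.frame(read_coding_sheet(tsv, v05)),
               as.data.frame(codes))

  # empty input writes a header-only parseable file
  hdr <- withr::local_tempfile(fileext = ".csv")
  write_coding_sheet(codes[0, ], hdr, v05)
  expect_equal(nrow(read_coding_sheet(hdr, v05)), 0)
})

test_that("missing trait columns and unparseable cells are errors", {
  codes <- generate_codes(3, v05, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_coding_sheet(codes, path, v05)

  df <- utils::read.csv(path, check.names = FALSE)
  df$O10 <- NULL
  p2 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p2, row.names = FALSE)
  expect_error(read_coding_sheet(p2, v05), "O10")

  df <- utils::read.csv(path, check.names = FALSE)
  df$D1[2] <- ""  # blank cell must not become an implicit 0
  p3 <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(df, p3, row.names = FALSE)
  expect_error(read_coding_sheet(p3, v05), "D1")
})

test_that("trait columns may arrive in any order; writes are canonical", {
  codes <- generate_codes(4, v05, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  shuffled <- codes[, c("specimen_id", rev(trait_ids(v05)))]
  utils::write.csv(shuffled, path, row.names = FALSE)
  back <- read_coding_sheet(path, v05)
  expect_identical(names(back), c("specimen_id", trait_ids(v05)))
  expect_equal(as.data.frame(back)[trait_ids(v05)],
               as.data.frame(codes)[trait_ids(v05)])
})

test_that("nesting violations are reported per dependent trait", {
  code <- generate_code(v05, seed = 8)
  code$E1 <- 1L  # no cusps ...
  code$E2 <- 2L  # ... but a cusp-ridge association is coded
  code$E3 <- 0L
  code$E4 <- 0L
  iss <- validate_code(code, v05)
  expect_equal(iss$rule, "nesting")
  expect_equal(iss$trait_id, "E2")
})

test_that("B2/C2 lower-score convention applies only without directionality", {
  code <- generate_code(v05, seed = 9)
  code$B1 <- 4L; code$C1 <- 4L
  code$B2 <- 3L; code$C2 <- 2L
  iss <- validate_code(code, v05)
  expect_true("ordering-B2C2" %in% iss$rule)

  code$C2 <- 4L  # now ordered correctly: no issue
  expect_false("ordering-B2C2" %in% validate_code(code, v05)$rule)

  code$B1 <- 2L  # directional denticle: convention does not govern
  code$B2 <- 3L; code$C2 <- 2L
  expect_false("ordering-B2C2" %in% validate_code(code, v05)$rule)
})

test_that("range violations name the offending state", {
  code <- generate_code(v05, seed = 10)
  code$B3 <- 0L   # B3 has no zero state
  code$A1 <- 42L
  iss <- validate_code(code, v05)
  expect_setequal(iss$trait_id, c("A1", "B3"))
  expect_true(all(iss$rule == "range"))
})

test_that("every nesting rule is exercised by a failing fixture", {
  for (rule in v05$nesting_rules) {
    # construct a code that triggers the rule and violates each dependent
    repeat {
      code <- generate_code(v05, seed = sample.int(1e6, 1))
      ctrl_states <- setdiff(rule$when, 0L)
      if (length(ctrl_states) == 0) ctrl_states <- rule$when
      code[[rule$controller]] <- ctrl_states[1]
      ok <- TRUE
      for (dep in names(rule$requires)) {
        req <- rule$requires[[dep]]
        nz <- v05$traits[[dep]]$states$index
        alt <- setdiff(nz, req)
        if (length(alt) == 0) { ok <- FALSE; break }
        code[[dep]] <- alt[length(alt)]
      }
      if (ok) break
    }
    iss <- validate_codes(code, v05)
    nest <- iss[iss$rule == "nesting", ]
    expect_setequal(intersect(nest$trait_id, names(rule$requires)),
                    names(rule$requires))
  }
})

test_that("validator is idempotent and order-insensitive across specimens", {
  codes <- generate_codes(6, v05, seed = 21)
  codes$E2[2] <- 3L  # may or may not violate depending on E1; force one:
  codes$E1[2] <- 1L; codes$E3[2] <- 0L; codes$E4[2] <- 0L
  a <- validate_codes(codes, v05)
  b <- validate_codes(codes, v05)
  expect_identical(a, b)
  rev_iss <- validate_codes(codes[rev(seq_len(nrow(codes))), ], v05)
  expect_setequal(paste(rev_iss$specimen_id, rev_iss$trait_id, rev_iss$rule),
                  paste(a$specimen_id, a$trait_id, a$rule))
})

test_that("validation reports serialize as one JSON line per issue", {
  code <- generate_code(v05, seed = 3)
  code$E1 <- 1L; code$E2 <- 2L; code$E3 <- 0L; code$E4 <- 0L
  iss <- validate_code(code, v05)
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_validation_report(iss, path)
  lines <- readLines(path)
  expect_length(lines, nrow(iss))
  parsed <- jsonlite::fromJSON(lines[1])
  expect_equal(parsed$rule, "nesting")
})
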