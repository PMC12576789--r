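test_that("self-disparity is zero and identical codes give an all-zero matrix", {
  x <- generate_code(v05, seed = 1)
  expect_equal(pair_disparity(x, x, v05), 0)
  codes <- do.call(rbind, lapply(1:4, function(i) {
    x$specimen_id <- paste0("s", i); x
  }))
  dm <- disparity_matrix(codes, v05)
  expect_true(all(dm$D == 0))
})

test_that("toy-schema disparity equals the hand-computed weighted sum", {
  sch <- toy_schema()
  a <- toy_code("a", 1L, 2L, 3L)
  b <- toy_code("b", 3L, 1L, 1L)
  # by hand: X1: w2 * d(1,3)=3 -> 6; X2: w1 * d(2,1)=2 -> 2;
  #          X3: w0.5 * d(3,1)=2 -> 1; raw = 9
  expect_equal(pair_disparity(a, b, sch, normalized = FALSE), 9)
  # denominators: 2*3 + 1*2 + 0.5*2 = 9 -> normalized 1 (both at maxima)
  expect_equal(pair_disparity(a, b, sch), 1)
  # zero on X3 shrinks the shared set: raw 8 over denom 8
  b2 <- toy_code("b", 3L, 1L, 0L)
  expect_equal(pair_disparity(a, b2, sch, normalized = FALSE), 8)
  expect_equal(pair_disparity(a, b2, sch), 1)
  c2 <- toy_code("c", 2L, 2L, 2L)
  # vs a: X1 w2*d(1,2)=1 ->2; X2 0; X3 w.5*d(3,2)=1 -> .5; raw 2.5 / 9
  expect_equal(pair_disparity(a, c2, sch, normalized = FALSE), 2.5)
  expect_equal(pair_disparity(a, c2, sch), 2.5 / 9)
})

test_that("codes broken on complementary traits are undefined, never 0", {
  sch <- toy_schema()
  # X1 has no zero state; drop it for this case
  sch2 <- drop_traits(sch, "X1")
  a <- data.frame(specimen_id = "a", X2 = 1L, X3 = 0L)
  b <- data.frame(specimen_id = "b", X2 = 0L, X3 = 2L)
  expect_true(is.na(pair_disparity(a, b, sch2)))
  dm <- disparity_matrix(rbind(a, b), sch2)
  expect_true(is.na(dm$D[1, 2]))
  expect_equal(dm$comparable_count[1, 2], 0)
  expect_equal(diag(dm$D), c(a = 0, b = 0))
})

test_that("engine equals the naive double-loop oracle on random inputs", {
  set.seed(99)
  for (rep in 1:25) {
    sch <- random_schema()
    codes <- random_codes(sample(3:8, 1), sch)
    for (norm in c(TRUE, FALSE)) {
      dm <- disparity_matrix(codes, sch, normalized = norm)
      expect_equal(unname(dm$D), oracle_matrix(codes, sch, norm),
                   tolerance = 0)
    }
    # invariants: symmetry, bounds, zero diagonal
    dm <- disparity_matrix(codes, sch)
    expect_true(isSymmetric(dm$D))
    expect_true(all(diag(dm$D) == 0))
    ok <- !is.na(dm$D)
    expect_true(all(dm$D[ok] >= 0 & dm$D[ok] <= 1))
  }
})

test_that("engine matches the oracle on full v0.5 codes", {
  codes <- generate_codes(12, v05, seed = 31)
  codes <- degrade_half(codes, v05, 0.5, seed = 32)
  dm <- disparity_matrix(codes, v05)
  expect_equal(unname(dm$D), oracle_matrix(codes, v05), tolerance = 0)
})

test_that("normalization reaches 1 for codes at per-trait maxima", {
  sch <- toy_schema()
  a <- toy_code("a", 1L, 1L, 1L)
  b <- toy_code("b", 3L, 2L, 3L)  # attains max distance on every trait
  expect_equal(pair_disparity(a, b, sch), 1)
})

test_that("zeroing traits changes only the shared set; twins stay at 0", {
  codes <- generate_codes(8, v05, seed = 41)
  twin <- codes[1, ]
  twin$specimen_id <- "twin"
  broken <- degrade_code(twin, v05, 0.5, seed = 42)
  all_codes <- rbind(codes, broken)
  dm <- disparity_matrix(all_codes, v05)
  # degraded copy of codes[1,] agrees with it wherever comparable
  expect_equal(dm$D["synthetic-1", "twin"], 0)
  expect_true(all(!is.nan(dm$D)))
  # rows to other specimens: recomputing from scratch over the reduced
  # shared set must agree with the full-matrix entries
  for (j in 2:8) {
    expect_equal(dm$D["twin", paste0("synthetic-", j)],
                 oracle_pair(broken, codes[j, ], v05))
  }
})

test_that("trait contributions decompose the raw disparity", {
  a <- generate_code(v05, seed = 51)
  b <- generate_code(v05, seed = 52)
  tc <- trait_contributions(a, b, v05)
  expect_equal(sum(tc$weighted[tc$comparable]),
               pair_disparity(a, b, v05, normalized = FALSE))
  expect_true(all(is.na(tc$distance[!tc$comparable])))
  # identical codes: all comparable distances 0
  tc0 <- trait_contributions(a, a, v05)
  expect_true(all(tc0$distance[tc0$comparable] == 0))
  # codes differing only in F1 concentrate the whole disparity there
  b1 <- a
  b1$F1 <- setdiff(2:6, a$F1)[1]  # stay off smooth: nesting unaffected?
  # force valid: mutate via schema-aware path instead
  tcf <- trait_contributions(a, b1, v05)
  expect_equal(sum(tcf$weighted[tcf$comparable]),
               tcf$weighted[tcf$trait_id == "F1"])
})

test_that("character jackknife equals recomputation on the reduced schema", {
  codes <- generate_codes(10, v05, seed = 61)
  # dropping a trait on which all codes agree only rescales denominators
  codes$D1 <- 2L
  full <- disparity_matrix(codes, v05)
  jk <- character_jackknife(codes, v05, "D1")
  red <- disparity_matrix(codes, drop_traits(v05, "D1"))
  expect_equal(jk$D, red$D)
  # raw disparities are unchanged by dropping an agreed trait
  expect_equal(character_jackknife(codes, v05, "D1", normalized = FALSE)$D,
               disparity_matrix(codes, v05, normalized = FALSE)$D)

  # fossil codes have no base characters: dropping group O changes nothing
  fossil <- generate_codes(8, v05, seed = 62, base_loss = TRUE)
  expect_equal(character_jackknife(fossil, v05, "O")$D,
               disparity_matrix(fossil, v05)$D)

  # codes differing only in F1 collapse to zero disparity without F1
  a <- generate_code(v05, seed = 63, specimen_id = "a")
  b <- a; b$specimen_id <- "b"
  b$F1 <- setdiff(2:6, a$F1)[1]
  dmj <- character_jackknife(rbind(a, b), v05, "F1")
  expect_equal(dmj$D["a", "b"], 0)
})

test_that("matrix exports are readable and faithful", {
  codes <- generate_codes(5, v05, seed = 71)
  dm <- disparity_matrix(codes, v05)
  csv <- withr::local_tempfile(fileext = ".csv")
  write_disparity_csv(dm, csv)
  back <- utils::read.csv(csv, check.names = FALSE)
  expect_equal(as.matrix(back[, -1]), dm$D, ignore_attr = TRUE)
  phy <- withr::local_tempfile(fileext = ".phy")
  write_phylip(dm, phy)
  lines <- readLines(phy)
  expect_equal(as.integer(trimws(lines[1])), 5)
  expect_length(lines, 6)
})

test_that("undefined pairs can be pruned with a warning", {
  sch <- drop_traits(toy_schema(), "X1")
  codes <- rbind(data.frame(specimen_id = "a", X2 = 1L, X3 = 0L),
                 data.frame(specimen_id = "b", X2 = 0L, X3 = 2L),
                 data.frame(specimen_id = "c", X2 = 2L, X3 = 2L))
  dm <- disparity_matrix(codes, sch)
  expect_warning(pruned <- prune_undefined(dm), "removed")
  expect_false(anyNA(pruned$D))
  expect_lt(length(pruned$ids), 3)
})
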