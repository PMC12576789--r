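test_that("tolerance 0 groups by exact state-vector equality", {
  a <- generate_code(v05, seed = 1, specimen_id = "a")
  b <- a; b$specimen_id <- "b"
  c3 <- generate_code(v05, seed = 2, specimen_id = "c")
  mt <- assign_morphotypes(rbind(a, b, c3), v05)
  expect_length(mt$morphotypes, 2)
  expect_equal(mt$assignments$morphotype[1], mt$assignments$morphotype[2])
  expect_false(mt$assignments$morphotype[1] == mt$assignments$morphotype[3])
  # zeros compare as equal only to zeros
  d <- a; d$specimen_id <- "d"; d$B1 <- 0L
  mt2 <- assign_morphotypes(rbind(a, d), v05)
  expect_length(mt2$morphotypes, 2)
})

test_that("tolerance 0 grouping is an equivalence relation", {
  codes <- generate_codes(6, v05, seed = 3)
  codes <- rbind(codes, codes, codes)  # deliberate duplicates
  codes$specimen_id <- paste0("s", seq_len(nrow(codes)))
  mt <- assign_morphotypes(codes, v05)
  key <- unname(apply(denticode:::code_states(codes, v05), 1,
                      paste, collapse = ","))
  grp <- mt$assignments$morphotype
  for (i in seq_along(key)) for (j in seq_along(key)) {
    expect_equal(grp[i] == grp[j], key[i] == key[j])
  }
})

test_that("near-duplicates merge within tolerance; beyond it they split", {
  a <- generate_code(v05, seed = 7, specimen_id = "a")
  # differ in exactly 3 always-codable traits
  b <- a; b$specimen_id <- "b"
  flip <- function(code, id) {
    nz <- setdiff(v05$traits[[id]]$states$index, c(0L, code[[id]]))
    code[[id]] <- nz[1]
    code
  }
  for (id in c("A1", "D1", "B3")) b <- flip(b, id)
  two <- rbind(a, b)
  expect_length(assign_morphotypes(two, v05, merge_tolerance = 2)$morphotypes,
                2)
  # differ in 2 traits: merged at tolerance 2, split at 0 and 1
  c2 <- flip(flip(a, "A1"), "D1"); c2$specimen_id <- "c"
  pair <- rbind(a, c2)
  expect_length(assign_morphotypes(pair, v05, 2)$morphotypes, 1)
  expect_length(assign_morphotypes(pair, v05, 1)$morphotypes, 2)
  expect_length(assign_morphotypes(pair, v05, 0)$morphotypes, 2)
  # single linkage chains: a-b distance 3 but bridged by c (a~c 2, c~b 1)
  chain <- rbind(a, b, c2)
  expect_length(assign_morphotypes(chain, v05, 2)$morphotypes, 1)
})

test_that("broken specimens count differences over comparable traits only", {
  a <- generate_code(v05, seed = 12, specimen_id = "a")
  b <- a; b$specimen_id <- "b"
  nz <- setdiff(v05$traits$D1$states$index, c(0L, a$D1))
  b$D1 <- nz[1]
  # zero three zero-capable traits on b: differences there don't count
  for (id in c("B1", "C1", "M2")) b[[id]] <- 0L
  b <- denticode:::as_codes_df(
    denticode:::repair_zero_rules(
      v05, stats::setNames(as.integer(b[1, trait_ids(v05)]),
                           trait_ids(v05))), v05, "b")
  mt <- assign_morphotypes(rbind(a, b), v05, merge_tolerance = 1)
  expect_length(mt$morphotypes, 1)
})

test_that("catalog matching ranks the parent first, undefined last", {
  cat_codes <- generate_codes(12, v05, seed = 21)
  mt <- assign_morphotypes(cat_codes, v05)
  catalog <- mt$catalog
  # a canonical code queried against its own catalog: itself at rank 1
  q <- catalog[5, ]
  res <- match_to_catalog(q, catalog, v05)
  expect_equal(res$morphotype_name[1], catalog$morphotype_name[5])
  expect_equal(res$disparity[1], 0)
  # a 30%-degraded copy still matches its parent first
  degr <- degrade_code(catalog[5, ], v05, 0.3, seed = 22)
  res2 <- match_to_catalog(degr, catalog, v05)
  expect_equal(res2$morphotype_name[1], catalog$morphotype_name[5])
  # permutation of the catalog does not change the ranking
  perm <- catalog[sample(nrow(catalog)), ]
  res3 <- match_to_catalog(degr, perm, v05)
  expect_equal(res3$morphotype_name, res2$morphotype_name)
  # an all-zero code matches nothing: every pair undefined, flagged
  allzero <- stats::setNames(rep(0L, 46), trait_ids(v05))
  res4 <- match_to_catalog(allzero, catalog, v05)
  expect_true(all(!res4$defined))
  expect_true(all(is.na(res4$disparity)))
})

test_that("the bundled synthetic catalog loads with 162 unique entries", {
  path <- system.file("extdata", "synthetic_morphotype_catalog.csv",
                      package = "denticode")
  catalog <- read_catalog(path, v05)
  expect_equal(nrow(catalog), 162)
  expect_equal(nrow(validate_codes(catalog, v05)), 0)
  mt <- assign_morphotypes(catalog, v05, merge_tolerance = 0)
  expect_length(mt$morphotypes, 162)
  expect_setequal(catalog$gross_type[catalog$morphotype_name %in%
                                       c("Generic Linear",
                                         "Generic Geometric")],
                  c("Other Linear", "Other Geometric"))
})

test_that("gross types form the fixed 18-label controlled vocabulary", {
  gt <- gross_types()
  expect_length(gt, 18)
  expect_true("Smooth" %in% gt)
  expect_true("Other Meandering" %in% gt)
})
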