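test_that("canonicalization unifies notations and is idempotent", {
  can <- standardize_smiles(c("c1ccccc1", "C1=CC=CC=C1"))
  expect_identical(can[[1]], can[[2]])
  set <- make_classification_set(15, 15, seed = 11)
  expect_identical(standardize_smiles(set$smiles), setNames(set$smiles, NULL))
  expect_error(standardize_smiles("C1CC"), "C1CC")
})

test_that("molecular weights match hand-computed masses", {
  expect_equal(molecular_weight("NCC(=O)O"), 75.07, tolerance = 1e-3)
  expect_equal(molecular_weight("C"), 16.04, tolerance = 1e-3)
})

test_that("mw_filter applies inclusive bounds and preserves subsets", {
  recs <- molecule_records(c("a", "b", "c", "d"),
                           c("C", "CC", "CCC", "CCCC"),
                           standardize = FALSE,
                           mw = c(299.9, 300.0, 600.0, 600.1))
  kept <- mw_filter(recs, 300, 600)
  expect_identical(kept$id, c("b", "c"))
  gly <- molecule_records("gly", "NCC(=O)O")
  expect_equal(nrow(mw_filter(gly, 300, 600)), 0)
  empty <- recs[0, ]
  expect_equal(nrow(mw_filter(empty)), 0)
  # output independent of input order
  shuf <- recs[c(3, 1, 4, 2), ]
  expect_setequal(mw_filter(shuf, 300, 600)$id, kept$id)
  expect_error(mw_filter(recs, 600, 300))
})

test_that("decoy selection matches by weight, audits shortfalls, is seeded", {
  actives <- molecule_records("a1", "C", standardize = FALSE, mw = 400)
  pool <- molecule_records(c("p1", "p2"), c("CCO", "CCCO"),
                           standardize = FALSE, mw = c(398, 500))
  sel <- select_mw_decoys(actives, pool, tol = 25, ratio = 1, seed = 1)
  expect_identical(sel$decoys$id, "p1")
  expect_identical(sel$decoys$role, "decoy")
  expect_equal(sel$audit$shortfall, 0)

  # an active with no pool member in range contributes nothing
  actives2 <- molecule_records(c("a1", "a2"), c("C", "CC"),
                               standardize = FALSE, mw = c(400, 1000))
  sel2 <- select_mw_decoys(actives2, pool, tol = 25, ratio = 1, seed = 1)
  expect_equal(sel2$audit$n_found, c(1, 0))
  expect_equal(sel2$audit$shortfall, c(0, 1))

  # 3 actives, 3 eligible, ratio 1 -> 3 distinct decoys; reproducible;
  # every decoy within tolerance of some active
  actives3 <- molecule_records(paste0("a", 1:3), c("C", "CC", "CCC"),
                               standardize = FALSE, mw = c(310, 320, 330))
  pool3 <- molecule_records(paste0("p", 1:5),
                            c("CO", "CCO", "CCCO", "CCCCO", "CCCCCO"),
                            standardize = FALSE,
                            mw = c(305, 325, 335, 900, 950))
  s1 <- select_mw_decoys(actives3, pool3, tol = 25, ratio = 1, seed = 7)
  s2 <- select_mw_decoys(actives3, pool3, tol = 25, ratio = 1, seed = 7)
  expect_identical(s1$decoys$id, s2$decoys$id)
  expect_equal(length(unique(s1$decoys$id)), 3)
  expect_true(all(vapply(s1$decoys$mw, function(m)
    any(abs(actives3$mw - m) <= 25), TRUE)))
  expect_error(select_mw_decoys(actives3, actives3, seed = 1), "disjoint|active")
})

test_that("SMILES and validation CSV round-trip through readers", {
  recs <- molecule_records(c("x1", "x2"), c("CCO", "c1ccccc1"))
  smi <- tempfile(fileext = ".smi")
  write_smiles_file(recs, smi)
  back <- read_smiles_file(smi)
  expect_identical(back$smiles, recs$smiles)
  expect_identical(back$id, recs$id)

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(id = c("v1", "v2"), smiles = c("CCO", "CCCCO"),
                       role = c("active", "decoy"), px = c(7.5, NA)),
            csv, row.names = FALSE)
  v <- read_validation_csv(csv)
  expect_identical(v$role, c("active", "decoy"))
  expect_equal(v$px, c(7.5, NA))
  expect_error(read_validation_csv(smi))
})

test_that("PAINS flagging hits planted alerts and spares ethanol", {
  cat <- pains_catalogue()
  expect_true(all(c("id", "smarts") %in% names(cat)))
  # a quinone: present in the bundled catalogue
  res <- pains_flag(c(q = "O=C1C=CC(=O)C=C1", clean = "CCO"))
  expect_true(res$flagged[1])
  expect_match(res$matched_alerts[1], "quinone")
  expect_false(res$flagged[2])
  expect_identical(res$matched_alerts[2], "")
  res2 <- pains_flag(c(q = "O=C1C=CC(=O)C=C1", clean = "CCO"))
  expect_identical(res, res2)
  # SMARTS with '#' (triple bond) survive catalogue parsing intact,
  # and a plain sulfonamide is not an alert
  expect_true(any(grepl("#", cat$smarts, fixed = TRUE)))
  res3 <- pains_flag(c(s = "CCCOc1ccc(NS(=O)(=O)c2ccccc2)cc1"))
  expect_false(res3$flagged)
})
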