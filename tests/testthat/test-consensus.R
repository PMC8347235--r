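stage_keep <- function(ids) function(recs) recs[recs$id %in% ids, ]

test_that("funnel reports record monotone survivor sets per stage", {
  lib <- molecule_records(paste0("m", 1:10), rep("CCO", 10),
                          standardize = FALSE, mw = rep(350, 10))
  rep1 <- run_target_funnel(lib, list(
    random_forest = stage_keep(paste0("m", 1:6)),
    pharmacophore = stage_keep(paste0("m", c(1:3, 5, 8:10))),
    electrostatics = stage_keep(paste0("m", 2:3))), target = "T1")
  expect_equal(unname(rep1$counts), c(10, 6, 4, 2))
  expect_setequal(rep1$survivors$pharmacophore, paste0("m", c(1, 2, 3, 5)))
  # subset invariant holds for every consecutive stage pair
  for (k in 2:length(rep1$survivors))
    expect_true(all(rep1$survivors[[k]] %in% rep1$survivors[[k - 1]]))

  # a stage inventing compounds aborts with the stage named
  bad <- function(recs) lib[lib$id == "m9", ]
  expect_error(run_target_funnel(lib, list(
    rf = stage_keep("m1"), oops = bad)), "oops")

  # MMP-1-style short funnel: no docking/electrostatics rows
  short <- run_target_funnel(lib, list(
    random_forest = stage_keep(paste0("m", 1:6)),
    pharmacophore = stage_keep(paste0("m", 1:3))), target = "T2")
  expect_identical(short$stages, c("random_forest", "pharmacophore"))
  tab <- funnel_table(list(rep1, short))
  expect_true(is.na(tab$T2[tab$stage == "electrostatics"]))
  expect_equal(tab$T1[tab$stage == "initial"], 10)
})

test_that("consensus collection equals brute-force counting", {
  lib <- molecule_records(c("a", "b", "c"), rep("CCO", 3),
                          standardize = FALSE, mw = rep(350, 3))
  mk_rep <- function(ids, target, from = lib) run_target_funnel(
    from, list(final = stage_keep(ids)), target = target)
  reports <- list(mk_rep(c("a", "b"), "T1"), mk_rep(c("b", "c"), "T2"),
                  mk_rep("c", "T3"))
  hits <- collect_consensus(reports, min_targets = 2)
  expect_setequal(hits$compound_id, c("b", "c"))
  expect_equal(hits$n_targets_hit, c(2, 2))
  expect_equal(nrow(collect_consensus(reports, min_targets = 3)), 0)

  set.seed(31)
  big_lib <- molecule_records(sprintf("c%03d", 1:200), rep("CCO", 200),
                              standardize = FALSE, mw = rep(350, 200))
  for (trial in 1:20) {
    membership <- matrix(runif(200 * 10) < 0.3, 200, 10,
                         dimnames = list(big_lib$id, paste0("T", 1:10)))
    reps <- lapply(1:10, function(t)
      mk_rep(big_lib$id[membership[, t]], paste0("T", t), from = big_lib))
    mt <- sample(2:5, 1)
    got <- collect_consensus(reps, min_targets = mt)
    want <- oracle_consensus(membership, mt)
    expect_setequal(got$compound_id, want$compound_id)
    expect_equal(got$n_targets_hit[order(got$compound_id)],
                 unname(want$n_targets_hit[order(want$compound_id)]))
  }
})

test_that("clustering groups near-duplicates with actives and isolates the rest", {
  # hit1 shares the scaffold of the known active; hit2/hit3 are alkanes
  hits <- molecule_records(
    c("hit1", "hit2", "hit3"),
    c("O=S(=O)(Nc1ccc(CCCC)cc1)c1ccc(CCCC)cc1",
      "CCCCCCCCCCCCCCCCCCCCCC",
      "c1ccc2ccccc2c1"))
  known <- molecule_records(
    "act1", "O=S(=O)(Nc1ccc(CCCCC)cc1)c1ccc(CCCC)cc1", role = "active")
  cl <- cluster_with_known_actives(hits, known)
  expect_equal(nrow(cl), 4)
  expect_identical(cl$cluster[cl$compound_id == "hit1"],
                   cl$cluster[cl$compound_id == "act1"])
  expect_true(all(cl$contains_known_active[cl$compound_id %in%
                                             c("hit1", "act1")]))
  expect_false(any(cl$contains_known_active[cl$compound_id %in%
                                              c("hit2", "hit3")]))
  expect_true(all(cl$is_noise[cl$compound_id %in% c("hit2", "hit3")]))
  # deterministic
  expect_identical(cl, cluster_with_known_actives(hits, known))
})

test_that("novel-hit selection honours flags, clusters, ranking and ties", {
  assignments <- data.frame(
    compound_id = c("h1", "act", "h2", "h3", "h4"),
    is_hit = c(TRUE, FALSE, TRUE, TRUE, TRUE),
    cluster = c("c1", "c1", "c2", "c2", "c3"),
    is_noise = FALSE,
    contains_known_active = c(TRUE, TRUE, FALSE, FALSE, FALSE))
  hits <- data.frame(compound_id = c("h1", "h2", "h3", "h4"),
                     n_targets_hit = c(5, 3, 2, 3))
  sel <- select_novel_hits(assignments, hits, n_select = 20)
  expect_identical(sel$compound_id, c("h2", "h4"))  # h1 flagged, h3 same cluster
  expect_false(any(sel$compound_id == "h1"))
  expect_equal(anyDuplicated(sel$cluster), 0)

  # tie on n_targets_hit: lexicographically smaller id first
  hits2 <- data.frame(compound_id = c("h2", "h3", "h4"),
                      n_targets_hit = c(3, 3, 3))
  a2 <- assignments[assignments$compound_id %in% c("h2", "h3", "h4"), ]
  a2$cluster <- c("x", "y", "z")
  sel2 <- select_novel_hits(a2, hits2, n_select = 2)
  expect_identical(sel2$compound_id, c("h2", "h3"))

  # n_select beyond eligibility returns everything eligible
  sel3 <- select_novel_hits(a2, hits2, n_select = 50)
  expect_equal(nrow(sel3), 3)
})
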