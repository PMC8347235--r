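test_that("feature perception places textbook features at centroids", {
  # benzene: exactly one aromatic feature at the ring-carbon centroid
  mb <- vsfunnel:::.molblocks_from_smiles("c1ccccc1", gen2d = TRUE)[[1]]
  f <- perceive_features("c1ccccc1")
  expect_identical(f$kind, "R")
  expect_equal(as.numeric(f[1, c("x", "y", "z")]),
               unname(colMeans(mb$xyz)), tolerance = 1e-9)

  # acetate: one negative feature at the carboxylate centroid, two acceptors
  fa <- perceive_features("CC(=O)[O-]")
  expect_equal(sum(fa$kind == "N"), 1)
  expect_equal(sum(fa$kind == "A"), 2)
  mba <- vsfunnel:::.molblocks_from_smiles("CC(=O)[O-]", gen2d = TRUE)[[1]]
  grp <- which(mba$elem %in% "O" | seq_along(mba$elem) == 2)  # C2 + both O
  expect_equal(as.numeric(fa[fa$kind == "N", c("x", "y", "z")]),
               unname(colMeans(mba$xyz[grp, ])), tolerance = 1e-9)

  # methane: nothing to perceive
  expect_equal(nrow(perceive_features("C")), 0)

  # determinism
  expect_identical(perceive_features("CC(=O)Nc1ccc(O)cc1"),
                   perceive_features("CC(=O)Nc1ccc(O)cc1"))
})

test_that("hypothesis strings parse kinds and required flags", {
  h <- parse_hypothesis_string("A (+) A (+) R (+)")
  expect_equal(nrow(h$sites), 3)
  expect_true(all(h$sites$required))
  expect_identical(h$sites$kind, c("A", "A", "R"))

  h2 <- parse_hypothesis_string("A (+) A (−) D (−) D (−) D (−) D (−) R (+)")
  expect_equal(nrow(h2$sites), 7)
  expect_equal(sum(h2$sites$required), 2)
  expect_identical(h2$sites$kind[h2$sites$required], c("A", "R"))

  h3 <- parse_hypothesis_string("A (−) A(+) D (−) D (−) H (−) N (+) R (−) R (−)")
  expect_equal(nrow(h3$sites), 8)
  expect_identical(h3$sites$kind[h3$sites$required], c("A", "N"))

  expect_error(parse_hypothesis_string(""), "token")
  expect_error(parse_hypothesis_string("A (+) X (+)"), "X")
})

test_that("in-place screening applies tolerances without re-alignment", {
  h <- hypothesis(data.frame(kind = c("A", "R"), x = c(0, 5), y = 0, z = 0,
                             tolerance = 2, required = TRUE, weight = 1))
  ok <- feature_pose(data.frame(kind = c("A", "R"), x = c(0.5, 5.1),
                                y = 0, z = 0), "ok")
  far <- feature_pose(data.frame(kind = c("A", "R"), x = c(0.5, 7.5),
                                 y = 0, z = 0), "far")
  res <- screen_inplace(h, list(ok, far))
  expect_identical(res$compound_id, "ok")
  expect_equal(res$rmsd, sqrt(mean(c(0.5, 0.1)^2)), tolerance = 1e-9)
  h_nocoord <- parse_hypothesis_string("A (+) R (+)")
  expect_error(screen_inplace(h_nocoord, list(ok)), "coordinates")
})

test_that("matcher is equivalent to the exhaustive assignment oracle", {
  set.seed(123)
  for (i in 1:300) {
    inst <- random_match_instance()
    p <- feature_pose(inst$feats, "c")
    h <- hypothesis(inst$sites, min_optional_matches = inst$min_opt)
    got <- nrow(screen_inplace(h, list(p))) == 1
    want <- oracle_match(inst$sites, inst$feats, inst$min_opt)
    expect_identical(got, want)
  }
})

test_that("flexible screening is rigid-motion invariant but not mirror-blind", {
  sites <- data.frame(kind = c("A", "D", "R", "N"),
                      x = c(0, 4, 0, 1), y = c(0, 0, 3, 1),
                      z = c(0, 0, 0, 2.5),
                      tolerance = 0.5, required = TRUE, weight = 1)
  h <- hypothesis(sites)
  moved <- sites
  moved[, c("x", "y", "z")] <- rigid_rotate(sites[, c("x", "y", "z")])
  conf <- feature_pose(moved, "rot")
  res <- screen_flexible(h, list(rot = list(conf)))
  expect_equal(nrow(res), 1)
  expect_lt(res$rmsd, 1e-9)

  mirrored <- sites
  mirrored$x <- -mirrored$x  # improper transform of a chiral arrangement
  mconf <- feature_pose(mirrored, "mir")
  expect_equal(nrow(screen_flexible(h, list(mir = list(mconf)))), 0)

  expect_equal(nrow(screen_flexible(h, list(none = list()))), 0)
})

test_that("fragment-derived hypotheses recover planted clusters", {
  set.seed(77)
  poses <- lapply(1:20, function(i) {
    feats <- rbind(
      data.frame(kind = "A", x = rnorm(1, 0, 0.2), y = rnorm(1, 0, 0.2),
                 z = rnorm(1, 0, 0.2)),
      data.frame(kind = "R", x = 5 + rnorm(1, 0, 0.2), y = rnorm(1, 0, 0.2),
                 z = rnorm(1, 0, 0.2)))
    p <- feature_pose(feats, paste0("frag", i))
    p$score <- -runif(1, 5, 10)
    p
  })
  hyps <- generate_epharmacophore(poses, n_clusters = 15, max_sites = 8)
  two <- hyps[[2]]
  expect_equal(nrow(two$sites), 2)
  a <- two$sites[two$sites$kind == "A", ]
  r <- two$sites[two$sites$kind == "R", ]
  expect_lt(sqrt(a$x^2 + a$y^2 + a$z^2), 0.5)
  expect_lt(sqrt((r$x - 5)^2 + r$y^2 + r$z^2), 0.5)

  # identical poses: sites at exactly the shared positions
  feats0 <- data.frame(kind = c("A", "R"), x = c(1, 6), y = 2, z = 3)
  same <- lapply(1:5, function(i) {
    p <- feature_pose(feats0, paste0("s", i)); p$score <- -7; p
  })
  hs <- generate_epharmacophore(same, n_clusters = 15, max_sites = 8)
  expect_equal(sort(hs[[2]]$sites$x), c(1, 6), tolerance = 1e-12)

  h1 <- generate_epharmacophore(same, n_clusters = 15, max_sites = 1)
  expect_length(h1, 1)
  expect_equal(nrow(h1[[1]]$sites), 1)
})

test_that("ligand-based search recovers a planted common triangle", {
  tri <- data.frame(kind = c("A", "A", "R"), x = c(0, 4, 2),
                    y = c(0, 0, 3), z = 0)
  confs <- list()
  for (i in 1:4) {
    m <- tri
    m[, c("x", "y", "z")] <- rigid_rotate(tri[, c("x", "y", "z")],
                                          angles = c(i, -i / 2, i / 3),
                                          shift = c(i, 2 * i, -i))
    confs[[paste0("act", i)]] <- list(feature_pose(m, paste0("act", i)))
  }
  hyps <- generate_ligand_hypothesis(confs, min_active_fraction = 0.5,
                                     n_features = 3, tolerance = 1)
  expect_gte(length(hyps), 1)
  expect_equal(attr(hyps[[1]], "match_fraction"), 1)
  expect_setequal(attr(hyps[[1]], "matched"), names(confs))
  expect_identical(sort(hyps[[1]]$sites$kind), c("A", "A", "R"))

  # full-match requirement still recovers it
  hyps100 <- generate_ligand_hypothesis(confs, min_active_fraction = 1,
                                        n_features = 3, tolerance = 1)
  expect_gte(length(hyps100), 1)

  # self-consistency: re-screening matches the stored fraction
  res <- screen_flexible(hyps[[1]], confs, tolerance_default = 1)
  expect_equal(nrow(res) / length(confs), attr(hyps[[1]], "match_fraction"))

  # no shared arrangement -> empty with warning
  bad <- list(a = list(feature_pose(data.frame(kind = c("A", "A", "D"),
                                               x = c(0, 9, 5), y = 0, z = 0), "a")),
              b = list(feature_pose(data.frame(kind = c("R", "R", "N"),
                                               x = c(0, 9, 5), y = 2, z = 1), "b")))
  expect_warning(out <- generate_ligand_hypothesis(bad, min_active_fraction = 1,
                                                   n_features = 3,
                                                   tolerance = 0.5),
                 "no common")
  expect_length(out, 0)
})

test_that("hypothesis validation selects by sensitivity first", {
  h3 <- parse_hypothesis_string("A (+) A (+) R (+)", id = "h3")
  h7 <- parse_hypothesis_string("A (+) A (−) D (−) D (−) D (−) D (−) R (+)",
                                id = "h7")
  # 100 actives, 100 decoys: h3 matches 89 actives/67 decoys,
  # h7 matches 67 actives/14 decoys -> h3 wins on sensitivity alone
  sel <- validate_and_select(
    list(h3, h7),
    active_matches = list(paste0("a", 1:89), paste0("a", 1:67)),
    decoy_matches = list(paste0("d", 1:67), paste0("d", 1:14)),
    n_actives = 100, n_decoys = 100)
  expect_identical(sel$best$id, "h3")
  expect_equal(sel$metrics[[1]][["sensitivity"]], 0.89)
  expect_equal(sel$metrics[[2]][["sensitivity"]], 0.67)

  # perfect hypothesis: all metrics 1
  sel2 <- validate_and_select(list(h3), list(paste0("a", 1:10)),
                              list(character(0)), 10, 10)
  expect_identical(sel2$best$id, h3$id)
  expect_equal(unname(sel2$metrics[[1]]["matthews_cc"]), 1)
  expect_error(validate_and_select(list(h3), list(character(0)),
                                   list(character(0)), 0, 0), "empty")
})

test_that("hypotheses serialize to JSON and back", {
  h <- hypothesis(data.frame(kind = c("A", "R"), x = c(0, 5), y = 0, z = 0,
                             tolerance = 2, required = c(TRUE, FALSE),
                             weight = 1), id = "io")
  path <- tempfile(fileext = ".json")
  write_hypotheses_json(h, path)
  back <- read_hypotheses_json(path)[[1]]
  expect_identical(back$sites$kind, h$sites$kind)
  expect_equal(back$sites$x, h$sites$x)
  expect_identical(back$sites$required, h$sites$required)
})
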