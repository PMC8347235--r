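test_that("charge assignment respects the as-given policy and neutrality", {
  p <- make_charged_pose(5, "dipolar", seed = 1)
  expect_identical(assign_partial_charges(p, "as-given"), p)
  expect_error(assign_partial_charges(p, "nonsense"))

  q <- pose(data.frame(element = c("C", "O"), x = c(0, 1.2), y = 0, z = 0),
            compound_id = "co")
  q1 <- assign_partial_charges(q, "eneg", structure = "C=O")
  q2 <- assign_partial_charges(q, "eneg", structure = "C=O")
  expect_identical(q1$atoms$charge, q2$atoms$charge)
  expect_lt(abs(sum(q1$atoms$charge)), 1e-3)  # neutral molecule
  expect_gt(q1$atoms$charge[1], 0)  # carbon positive against oxygen
})

test_that("potential obeys the Coulomb limit, linearity and masking", {
  p <- pose(data.frame(element = "C", x = 0, y = 0, z = 0, charge = 1),
            compound_id = "pt")
  bb <- list(lo = c(-5, -5, -5), hi = c(5, 5, 5))
  g <- compute_potential_grid(p, spacing = 1, bounds = bb,
                              dielectric = "vacuum")
  at <- function(grid, xyz) {
    i <- round((xyz - grid$origin) / grid$spacing) + 1
    grid$values[i[1] + grid$dims[1] * (i[2] - 1) +
                  grid$dims[1] * grid$dims[2] * (i[3] - 1)]
  }
  expect_equal(at(g, c(2, 0, 0)) / at(g, c(4, 0, 0)), 2, tolerance = 1e-12)
  gd <- compute_potential_grid(p, spacing = 1, bounds = bb,
                               dielectric = "distance")
  expect_equal(at(gd, c(2, 0, 0)) / at(gd, c(4, 0, 0)), 4, tolerance = 1e-12)

  p2 <- p; p2$atoms$charge <- 2
  g2 <- compute_potential_grid(p2, spacing = 1, bounds = bb,
                               dielectric = "vacuum")
  expect_equal(g2$values[g2$mask], 2 * g$values[g$mask], tolerance = 1e-12)

  m <- function(grid, xyz) {
    i <- round((xyz - grid$origin) / grid$spacing) + 1
    grid$mask[i[1] + grid$dims[1] * (i[2] - 1) +
                grid$dims[1] * grid$dims[2] * (i[3] - 1)]
  }
  expect_false(m(g, c(1, 0, 0)))  # inside the 1.7 A vdW envelope
  expect_true(m(g, c(2, 0, 0)))
  expect_error(compute_potential_grid(
    pose(data.frame(element = character(0), x = numeric(0), y = numeric(0),
                    z = numeric(0))[0, ], compound_id = "e")), "atom")
})

test_that("electrostatic Tanimoto algebra: identity, negation, scaling", {
  p <- make_charged_pose(5, "neutral", seed = 42)
  g <- compute_potential_grid(p)
  expect_identical(electrostatic_tanimoto(g, g), 1)

  pn <- p; pn$atoms$charge <- -pn$atoms$charge
  gn <- compute_potential_grid(pn)
  expect_equal(electrostatic_tanimoto(g, gn), -1 / 3, tolerance = 1e-12)

  for (lam in c(0.5, 2, 5)) {
    pl <- p; pl$atoms$charge <- lam * pl$atoms$charge
    gl <- compute_potential_grid(pl)
    expect_equal(electrostatic_tanimoto(g, gl),
                 lam / (1 + lam^2 - lam), tolerance = 1e-9)
  }

  z <- p; z$atoms$charge <- 0
  gz <- compute_potential_grid(z)
  expect_error(electrostatic_tanimoto(gz, gz), "zero")
  gsmall <- compute_potential_grid(p, spacing = 1)
  expect_error(electrostatic_tanimoto(g, gsmall), "compatible")
})

test_that("et_pb stays in range and symmetric on random fixtures", {
  for (i in 1:60) {
    a <- make_charged_pose(4, "neutral", seed = 100 + i, box = 6)
    b <- make_charged_pose(4, "dipolar", seed = 200 + i, box = 6)
    bb <- shared_grid_bounds(list(a, b), padding = 3)
    ga <- compute_potential_grid(a, spacing = 1, bounds = bb,
                                 mask_poses = list(a, b))
    gb <- compute_potential_grid(b, spacing = 1, bounds = bb,
                                 mask_poses = list(a, b))
    t1 <- electrostatic_tanimoto(ga, gb)
    t2 <- electrostatic_tanimoto(gb, ga)
    expect_lt(abs(t1 - t2), 1e-12)
    expect_gte(t1, -1 / 3 - 1e-12)
    expect_lte(t1, 1 + 1e-12)
  }
})

test_that("grid refinement changes et_pb only marginally", {
  a <- make_charged_pose(5, "neutral", seed = 7, box = 6)
  b <- make_charged_pose(5, "dipolar", seed = 8, box = 6)
  bb <- shared_grid_bounds(list(a, b), padding = 4)
  et_at <- function(sp) {
    ga <- compute_potential_grid(a, spacing = sp, bounds = bb,
                                 mask_poses = list(a, b))
    gb <- compute_potential_grid(b, spacing = sp, bounds = bb,
                                 mask_poses = list(a, b))
    electrostatic_tanimoto(ga, gb)
  }
  expect_lt(abs(et_at(0.5) - et_at(0.25)), 0.02)
})

test_that("best-reference keeps the top pose across references jointly", {
  ref <- make_charged_pose(5, "neutral", seed = 42)
  exact <- ref; exact$compound_id <- "cand"; exact$pose_id <- "cand_exact"
  neg <- ref; neg$compound_id <- "cand"; neg$pose_id <- "cand_neg"
  neg$atoms$charge <- -neg$atoms$charge
  other_ref <- make_charged_pose(5, "dipolar", seed = 9)
  other_ref$pose_id <- "refB"
  ref$pose_id <- "refA"

  res <- best_reference_similarity(list(neg, exact), list(ref, other_ref))
  expect_equal(nrow(res), 1)
  expect_identical(res$pose_id, "cand_exact")
  expect_identical(res$best_reference, "refA")
  expect_equal(res$et_pb, 1)

  res2 <- best_reference_similarity(list(neg, exact), list(other_ref, ref))
  expect_identical(res2$best_reference, res$best_reference)
  expect_equal(res2$et_pb, res$et_pb)
  expect_error(best_reference_similarity(list(exact), list()), "empty")
})

test_that("pose SDF round-trips coordinates, charges and scores", {
  p <- make_charged_pose(6, "neutral", seed = 12)
  p$score <- -7.25
  path <- tempfile(fileext = ".sdf")
  write_poses_sdf(list(p), path)
  back <- read_poses_sdf(path)[[1]]
  expect_equal(back$atoms$x, p$atoms$x, tolerance = 1e-4)
  expect_equal(back$atoms$charge, p$atoms$charge, tolerance = 1e-6)
  expect_equal(back$score, -7.25)
  expect_identical(back$compound_id, p$compound_id)
})
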