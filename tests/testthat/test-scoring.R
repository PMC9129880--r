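static_pair <- function(sep, n_frames = 10) {
  pos <- array(0, dim = c(n_frames, 2, 2))
  pos[, , 1] <- 8
  pos[, 1, 2] <- 50 + sep
  pos[, 2, 2] <- 50
  trajectory(pos, identities = c("leader", "follower"))
}

test_that("chain cohesion passes below and fails above 57 um", {
  r50 <- score_cohesion(static_pair(50))
  expect_true(r50$pass)
  expect_equal(r50$max_adjacent_gap, 50)
  expect_false(score_cohesion(static_pair(60))$pass)
  expect_error(score_cohesion(trajectory(array(0, dim = c(3, 1, 2)),
                                         identities = "leader")),
               "single-cell")
})

test_that("the cohesion pass/fail boundary bisects to 57.0 um", {
  expect_equal(locate_cohesion_boundary(tol = 1e-4), 57, tolerance = 1e-3)
})

test_that("gaps are measured between chain-order neighbours", {
  # three cells: y-order differs from index order
  pos <- array(0, dim = c(2, 3, 2))
  pos[, , 1] <- 8
  pos[, 1, 2] <- 0; pos[, 2, 2] <- 80; pos[, 3, 2] <- 40
  tr <- trajectory(pos, identities = c("leader", "follower", "follower"))
  expect_equal(score_cohesion(tr)$max_adjacent_gap, 40)
})

test_that("single-file score counts frames and flips at 80%", {
  sf <- function(k) {
    tr <- crestchain:::controlled_single_file_trajectory(k, 100)
    score_single_file(tr)
  }
  expect_equal(sf(100)$fraction, 1)
  expect_true(sf(100)$pass)
  expect_false(sf(79)$pass)
  expect_equal(sf(79)$fraction, 0.79)
  expect_true(sf(80)$pass)
  expect_equal(locate_single_file_threshold(), 80)
})

test_that("overtaking categories follow the sustained-crossing rule", {
  n_frames <- 40
  base <- matrix(rep(c(30, 20, 10), each = n_frames), n_frames, 3)
  # leader strictly most ventral throughout
  tr <- trajectory_from_y(base)
  ov <- detect_overtakings(tr)
  expect_equal(ov$category, "0")
  expect_equal(ov$front_cell, 1)

  # one follower crossing and staying ahead for 10 frames
  y <- base
  y[25:34, 2] <- 30 + 5
  ov <- detect_overtakings(trajectory_from_y(y))
  expect_equal(ov$category, "1")
  expect_equal(ov$overtakers, 2L)

  # two distinct sustained overtakers
  y[15:20, 3] <- 30 + 5
  ov <- detect_overtakings(trajectory_from_y(y))
  expect_equal(ov$category, ">1")

  # a crossing shorter than overtake_min_frames does not count
  y2 <- base
  y2[25:26, 2] <- 30 + 5
  expect_equal(detect_overtakings(trajectory_from_y(y2))$category, "0")
})

test_that("overtaking detection agrees with a brute-force rank oracle", {
  cfg <- score_config()
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(3:5, 1)
    y <- random_y_trajectory(n, 50)
    got <- detect_overtakings(trajectory_from_y(y), cfg)
    want <- brute_force_overtakers(y, cfg$overtake_delta,
                                   cfg$overtake_min_frames)
    expect_identical(got$category, want$category)
    expect_identical(got$overtakers, want$overtakers)
  }
})

test_that("leader-front and path-completion scores apply their rules", {
  n_frames <- 30
  y <- cbind(seq(30, 158, length.out = n_frames),
             seq(20, 120, length.out = n_frames),
             seq(10, 100, length.out = n_frames))
  tr <- trajectory_from_y(y)
  lf <- score_leader_front(tr)
  expect_true(lf$pass)
  expect_equal(lf$retention_fraction, 1)

  pc <- score_path_completion(tr, arena())
  expect_true(pc$pass)
  expect_false(pc$over_migrated)

  # front cell ending beyond y_end + 2 * margin is over-migrated
  cfg <- score_config()
  y2 <- y; y2[n_frames, 1] <- arena()$y_end + 2 * cfg$overmigration_margin
  pc2 <- score_path_completion(trajectory_from_y(y2), arena(), cfg)
  expect_true(pc2$over_migrated)

  # chain stalling at the NT/not boundary never completes the path
  y3 <- y * 0 + cbind(rep(65, n_frames), rep(50, n_frames),
                      rep(40, n_frames))
  expect_false(score_path_completion(trajectory_from_y(y3), arena())$pass)
})

test_that("score_all aggregates and a single wide frame breaks cohesion", {
  n_frames <- 120
  y <- cbind(seq(40, 170, length.out = n_frames),
             seq(28, 140, length.out = n_frames),
             seq(16, 110, length.out = n_frames),
             seq(4, 80, length.out = n_frames))
  # sustained follower swap: cells 3 and 4 cross near the end
  y[100:120, 4] <- y[100:120, 3] + 6
  tr <- trajectory_from_y(y)
  rep_ <- score_all(tr, arena())
  expect_true(rep_$all_pass)
  expect_gte(rep_$follower_rearrangement$swap_count, 1)

  y2 <- y
  y2[60, 1] <- y2[60, 2] + 58
  rep2 <- score_all(trajectory_from_y(y2), arena())
  expect_false(rep2$cohesion$pass)
  expect_false(rep2$all_pass)
})

test_that("scoring is invariant to rigid anteroposterior translation", {
  set.seed(5)
  y <- random_y_trajectory(4, 60)
  pos <- array(0, dim = c(60, 4, 2))
  pos[, , 1] <- 8; pos[, , 2] <- y
  tr1 <- trajectory(pos, c("leader", rep("follower", 3)))
  pos2 <- pos; pos2[, , 1] <- pos2[, , 1] + 3
  tr2 <- trajectory(pos2, c("leader", rep("follower", 3)))
  r1 <- score_all(tr1, arena(width = 30))
  r2 <- score_all(tr2, arena(width = 30))
  expect_equal(r1$cohesion$max_adjacent_gap, r2$cohesion$max_adjacent_gap)
  expect_equal(r1$single_file$fraction, r2$single_file$fraction)
  expect_identical(r1$all_pass, r2$all_pass)
})

test_that("raising cohesion_max never turns a pass into a fail", {
  set.seed(13)
  for (rep in 1:20) {
    tr <- trajectory_from_y(random_y_trajectory(4, 30))
    loose <- score_cohesion(tr, score_config(cohesion_max = 80))
    tight <- score_cohesion(tr, score_config(cohesion_max = 57))
    if (tight$pass) expect_true(loose$pass)
    strict <- score_single_file(tr, score_config(singlefile_min_fraction = .9))
    lax <- score_single_file(tr, score_config(singlefile_min_fraction = .5))
    if (strict$pass) expect_true(lax$pass)
  }
})
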