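test_that("init_chain places a non-overlapping ventrally-headed chain", {
  ag <- init_chain(composition("LFFF"), arena(), model_params(), seed = 1)
  expect_equal(nrow(ag), 4)
  expect_equal(ag$identity[1], "leader")
  expect_true(all(ag$identity[-1] == "follower"))
  d <- as.matrix(dist(cbind(ag$x, ag$y)))
  rsum <- outer(ag$radius, ag$radius, "+")
  expect_true(all(d[upper.tri(d)] >= rsum[upper.tri(rsum)]))
  expect_true(all(ag$hy > 0.99))  # ventral with small jitter
  expect_equal(sqrt(ag$hx^2 + ag$hy^2), rep(1, 4), tolerance = 1e-12)
  # chain order: front (first) most ventral, inside the premigratory band
  expect_true(all(diff(ag$y) < 0))
  expect_lte(ag$y[1], arena()$y_premigratory)

  ag2 <- init_chain(composition("LFFF"), arena(), model_params(), seed = 1)
  expect_identical(ag, ag2)
})

test_that("chains that cannot fit dorsally raise a configuration error", {
  long <- composition(paste(rep("L", 20), collapse = ""))
  p <- model_params(cell_radius = c(leader = 5.7, follower = 4.79))
  expect_error(init_chain(long, arena(), p, seed = 1), "20 agents")
})

test_that("a free agent moves exactly speed*dt along its heading", {
  p <- model_params(cil_mode = "off", coattraction_strength = 0,
                    zeta = 0)
  ag <- data.frame(agent_id = 1L, identity = "leader", x = 8, y = 10,
                   hx = 0, hy = 1, radius = 5.7, speed = 0.7,
                   persist = 0L, stringsAsFactors = FALSE)
  out <- step_chain(ag, p, arena())
  expect_equal(out$x, 8)
  expect_equal(out$y, 10 + 0.7 * p$dt)
})

test_that("volume exclusion pushes an overlapping pair apart", {
  p <- model_params(cil_mode = "off", coattraction_strength = 0, zeta = 0,
                    base_speed = c(leader = 0, follower = 0))
  ag <- data.frame(agent_id = 1:2, identity = c("follower", "follower"),
                   x = c(8, 8), y = c(10, 16.5), hx = c(0, 0), hy = c(1, 1),
                   radius = c(4.79, 4.79), speed = c(0, 0),
                   persist = c(0L, 0L), stringsAsFactors = FALSE)
  pre <- 6.5  # overlap of 9.58 - 6.5 = 3.08 um
  out <- step_chain(ag, p, arena())
  post <- abs(diff(out$y))
  expect_gt(post, pre)
  expect_gte(post, sum(ag$radius) - p$exclusion_tol)
})

test_that("an agent heading into the anteroposterior wall is reflected", {
  p <- model_params(cil_mode = "off", coattraction_strength = 0, zeta = 0)
  a <- arena()
  ag <- data.frame(agent_id = 1L, identity = "leader",
                   x = a$width - 5.75, y = 10, hx = 1, hy = 0,
                   radius = 5.7, speed = 0.7, persist = 0L,
                   stringsAsFactors = FALSE)
  out <- step_chain(ag, p, a)
  expect_lte(out$x, a$width - out$radius)
  expect_lt(out$hx, 0)  # normal component reversed
})

test_that("resolve_cil honours mode, identity and intensity", {
  mk <- function(id, x, y, hx, hy, r = 5)
    data.frame(agent_id = 1L, identity = id, x = x, y = y, hx = hx,
               hy = hy, radius = r, speed = 0.5, persist = 0L,
               stringsAsFactors = FALSE)
  p <- model_params()
  # follower-follower under differential CIL: unchanged
  f1 <- mk("follower", 8, 10, 0, 1)
  f2 <- mk("follower", 8, 18, 0, -1)
  out <- resolve_cil(f1, f2, p)
  expect_equal(out$heading_a, c(0, 1))
  expect_equal(out$heading_b, c(0, -1))

  # head-on leader-follower collision, all_pairs, intensities (high, low):
  # the leader turns further than the follower
  pa <- model_params(cil_mode = "all_pairs",
                     cil_intensity = c(leader = "high", follower = "low"))
  ld <- mk("leader", 8, 10, 0, 1)
  fo <- mk("follower", 8, 19.5, 0, -1)
  out <- resolve_cil(ld, fo, pa)
  ang <- function(h0, h1) abs(atan2(h0[1] * h1[2] - h0[2] * h1[1],
                                    sum(h0 * h1)))
  expect_gt(ang(c(0, 1), out$heading_a), ang(c(0, -1), out$heading_b))
  expect_equal(sqrt(sum(out$heading_a^2)), 1, tolerance = 1e-12)
  expect_equal(sqrt(sum(out$heading_b^2)), 1, tolerance = 1e-12)

  # zero intensity on both sides: unchanged
  pz <- model_params(cil_mode = "all_pairs",
                     cil_intensity = c(leader = 0, follower = 0))
  out <- resolve_cil(ld, fo, pz)
  expect_equal(out$heading_a, c(0, 1))
  expect_equal(out$heading_b, c(0, -1))
})

test_that("co-attraction pulls distant neighbours and respects its range", {
  p <- model_params(coattraction_strength = "medium",
                    coattraction_range = 25)
  eps <- level_map()$coattraction[["medium"]]
  mk <- function(x, y) data.frame(agent_id = 1L, identity = "follower",
                                  x = x, y = y, hx = 0, hy = 1,
                                  radius = 4.79, speed = 0.5, persist = 0L,
                                  stringsAsFactors = FALSE)
  none <- coattraction_displacement(mk(8, 10), mk(8, 10)[0, ], p)
  expect_equal(none, c(0, 0))

  a <- mk(8, 10); b <- mk(8, 30)
  da <- coattraction_displacement(a, b, p)
  db <- coattraction_displacement(b, a, p)
  expect_equal(da, -db)
  expect_equal(sqrt(sum(da^2)), eps * p$dt)

  far <- mk(8, 10 + p$coattraction_range + 1)
  expect_equal(coattraction_displacement(a, far, p), c(0, 0))
  # touching cells exert no pull
  touch <- mk(8, 10 + 2 * 4.79 - 0.5)
  expect_equal(coattraction_displacement(a, touch, p), c(0, 0))
})

test_that("co-attraction magnitude is monotone in the strength level", {
  mk <- function(x, y) data.frame(agent_id = 1L, identity = "follower",
                                  x = x, y = y, hx = 0, hy = 1,
                                  radius = 4.79, speed = 0.5, persist = 0L,
                                  stringsAsFactors = FALSE)
  mags <- vapply(c("low", "medium", "high"), function(lv) {
    p <- model_params(coattraction_strength = lv)
    sqrt(sum(coattraction_displacement(mk(8, 10), mk(8, 30), p)^2))
  }, numeric(1))
  expect_true(all(diff(mags) > 0))
})

test_that("simulate_chain is deterministic and frozen without dynamics", {
  p0 <- model_params(cil_mode = "off", coattraction_strength = 0, zeta = 0,
                     base_speed = c(leader = 0, follower = 0),
                     n_steps = 50)
  tr <- simulate_chain(composition("LFF"), arena(), p0, seed = 3)
  for (f in 2:dim(tr$positions)[1])
    expect_equal(tr$positions[f, , ], tr$positions[1, , ])

  p <- model_params(n_steps = 100)
  t1 <- simulate_chain(composition_preset("1:3"), arena(), p, seed = 11)
  t2 <- simulate_chain(composition_preset("1:3"), arena(), p, seed = 11)
  expect_identical(t1$positions, t2$positions)
  t3 <- simulate_chain(composition_preset("1:3"), arena(), p, seed = 12)
  expect_false(identical(t1$positions, t3$positions))
})

test_that("a lone leader with zero noise advances ballistically", {
  big <- arena(width = 400, y_max = 1000)
  p <- model_params(cil_mode = "off", coattraction_strength = 0, zeta = 0,
                    n_steps = 200)
  tr <- simulate_chain(composition("L"), big, p, seed = 5)
  disp <- tr$positions[dim(tr$positions)[1], 1, ] - tr$positions[1, 1, ]
  # free ballistic motion: |displacement| = speed * time exactly, along
  # the (jittered) initial ventral heading
  expect_equal(sqrt(sum(disp^2)), 0.7 * 200, tolerance = 1e-9)
  expect_gt(disp[2] / sqrt(sum(disp^2)), 0.99)
})

test_that("a single R step reproduces the compiled single-step update", {
  p <- model_params(n_steps = 1, sample_every = 1)
  comp <- composition("LFFLF")
  set.seed(99)
  ag <- init_chain(comp, arena(), p)
  ref <- step_chain(ag, p, arena())
  set.seed(99)
  tr <- simulate_chain(comp, arena(), p, seed = 99)
  expect_equal(unname(tr$positions[2, , 1]), ref$x, tolerance = 1e-12)
  expect_equal(unname(tr$positions[2, , 2]), ref$y, tolerance = 1e-12)
})

test_that("trajectories stay inside the corridor and nearly non-overlapping", {
  a <- arena()
  for (s in 1:6) {
    tr <- simulate_chain(composition_preset("1:3"), a, model_params(),
                         seed = s)
    pos <- tr$positions
    for (i in seq_along(tr$radius)) {
      expect_true(all(pos[, i, 1] >= tr$radius[i] - 1e-9))
      expect_true(all(pos[, i, 1] <= a$width - tr$radius[i] + 1e-9))
      expect_true(all(pos[, i, 2] >= a$y_min + tr$radius[i] - 1e-9))
      expect_true(all(pos[, i, 2] <= a$y_max - tr$radius[i] + 1e-9))
    }
    tol <- model_params()$exclusion_tol
    for (f in seq(1, dim(pos)[1], by = 5)) {
      d <- as.matrix(dist(pos[f, , ]))
      rsum <- outer(tr$radius, tr$radius, "+")
      expect_true(all(d[upper.tri(d)] >= rsum[upper.tri(rsum)] - tol))
    }
  }
})

test_that("identical followers are exchangeable (zero-noise limit)", {
  # dynamics depend on identity only: with the noise silenced, permuting
  # two identical followers' initial states permutes their trajectories
  p <- model_params(zeta = 0, n_steps = 60)
  set.seed(31)
  a <- init_chain(composition("LFFF"), arena(), p)
  b <- a[c(1, 3, 2, 4), ]
  rownames(b) <- NULL
  run <- function(ag) {
    for (k in 1:60) ag <- step_chain(ag, p, arena())
    ag
  }
  fa <- run(a)
  fb <- run(b)
  expect_equal(fb$x, fa$x[c(1, 3, 2, 4)], tolerance = 1e-12)
  expect_equal(fb$y, fa$y[c(1, 3, 2, 4)], tolerance = 1e-12)
})

test_that("trajectory container validates its contract", {
  pos <- array(0, dim = c(3, 2, 2))
  expect_error(trajectory(pos, identities = c("leader", "follower"),
                          times = c(0, 5, 5)), "strictly increasing")
  tr <- trajectory(pos, identities = c("leader", "follower"))
  df <- as.data.frame(tr)
  expect_equal(nrow(df), 6)
  expect_equal(unique(df$z_um), 0)
})
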