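test_that("state initialization puts init_soil on every edge", {
  p <- iwd_params(m = 2, init_soil = 1000)
  st <- iwd_init_state(5, p)
  off_diag <- st$soil[upper.tri(st$soil)]
  expect_identical(dim(st$soil), c(6L, 6L))  # 5 features + start node
  expect_true(all(off_diag == 1000))
  expect_null(st$best_subset)
  expect_error(iwd_init_state(0, p), "at least one")
  expect_error(iwd_init_state(3, iwd_params(m = 4)), ">= subset size")
})

test_that("transition probabilities follow the shifted inverse-soil rule", {
  p <- iwd_params(m = 2, epsilon_p = 0.01)
  st <- iwd_init_state(4, p)
  # all soils equal -> uniform
  pr <- iwd_transition_probs(0L, integer(), st, p)
  expect_equal(unname(pr), rep(0.25, 4))
  # soils 0 and 1000: low-soil edge takes essentially all mass
  st$soil[1, 2] <- 0; st$soil[1, 3] <- 1000
  pr2 <- iwd_transition_probs(0L, c(3L, 4L), st, p)
  expect_equal(unname(pr2[1]),
               (1 / 0.01) / ((1 / 0.01) + (1 / 1000.01)))
  expect_gt(pr2[1], 0.99999)
  # one candidate left -> probability one
  pr3 <- iwd_transition_probs(0L, c(1L, 2L, 3L), st, p)
  expect_identical(unname(pr3), 1)
  expect_error(iwd_transition_probs(0L, 1:4, st, p), "no unvisited")
})

test_that("transition probabilities sum to one even with negative soils", {
  p <- iwd_params(m = 2)
  set.seed(21)
  for (rep_ in 1:20) {
    st <- iwd_init_state(6, p)
    st$soil[] <- matrix(stats::runif(49, -500, 500), 7, 7)
    pr <- iwd_transition_probs(sample(0:6, 1), sample(1:6, 2), st, p)
    expect_true(all(pr >= 0))
    expect_lt(abs(sum(pr) - 1), 1e-12)
  }
})

test_that("velocity update matches the canonical closed form", {
  expect_equal(iwd_update_velocity(4, 0, iwd_params(a_v = 1, b_v = 1, c_v = 1)),
               5)
  p0 <- iwd_params(a_v = 2, b_v = 0.5, c_v = 0)
  expect_equal(iwd_update_velocity(1, 123, p0), 1 + 2 / 0.5)
  # huge soil: increment vanishes
  expect_equal(iwd_update_velocity(7, 1e9, iwd_params()), 7, tolerance = 1e-9)
})

test_that("soil delta uses traversal time = HUD / velocity", {
  p <- iwd_params(a_s = 1, b_s = 0.01, c_s = 1)
  expect_equal(iwd_soil_delta(2, 1, p), 1 / (0.01 + 4))
  expect_equal(iwd_soil_delta(5, 10, iwd_params(a_s = 3, b_s = 2, c_s = 0)),
               3 / 2)
  # faster drop, same HUD -> more soil removed
  expect_gt(iwd_soil_delta(2, 10, p), iwd_soil_delta(2, 1, p))
  expect_error(iwd_soil_delta(1, 0, p), "positive")
})

test_that("local soil update erodes symmetrically", {
  p <- iwd_params(rho_n = 0.9)
  st <- iwd_init_state(3, p)
  st$soil[1, 2] <- st$soil[2, 1] <- 100
  iwd_local_update(st, 0L, 1L, 10, p)
  expect_equal(st$soil[1, 2], 0.1 * 100 - 0.9 * 10)  # = 1.0
  expect_equal(st$soil[2, 1], 1.0)
  # zero delta: pure decay
  st$soil[1, 2] <- st$soil[2, 1] <- 50
  iwd_local_update(st, 0L, 1L, 0, p)
  expect_equal(st$soil[1, 2], 5)
})

test_that("global update reinforces the best tour and keeps the incumbent", {
  p <- iwd_params(rho_iwd = 0.9, m = 3)
  st <- iwd_init_state(4, p)
  st$soil[] <- 10
  tour <- list(visited = c(2L, 1L, 3L), carried_soil = 18)
  iwd_global_update(st, tour, fitness = 0.7, p)
  expect_equal(st$soil[1, 3], 1.9 * 10 - 0.9 * (18 / 2))  # = 10.9
  expect_identical(st$best_subset, c(1L, 2L, 3L))
  # a worse iteration best never replaces the incumbent
  iwd_global_update(st, list(visited = c(1L, 2L, 4L), carried_soil = 5),
                    fitness = 0.5, p)
  expect_identical(st$best_subset, c(1L, 2L, 3L))
  expect_equal(st$best_fitness, 0.7)
})

test_that("a forced tour visits every feature and is seed-deterministic", {
  p <- iwd_params(m = 4)
  st <- iwd_init_state(4, p)
  tour <- iwd_construct_solution(st, p, hud = rep(1, 4))
  expect_setequal(tour$visited, 1:4)
  expect_gt(tour$velocity, p$init_vel)  # a_v > 0: strictly increasing
  p2 <- iwd_params(m = 2)
  run <- function() {
    set.seed(99)
    iwd_construct_solution(iwd_init_state(6, p2), p2, rep(1, 6))$visited
  }
  expect_identical(run(), run())
})

test_that("fresh-state tours sample m-subsets uniformly (chi-square)", {
  p <- iwd_params(m = 2)
  hud <- rep(1, 5)
  n_tours <- 10000L
  set.seed(17)
  keys <- replicate(n_tours, paste(
    sort(iwd_construct_solution(iwd_init_state(5, p), p, hud)$visited),
    collapse = ","))
  obs <- table(keys)
  expect_identical(length(obs), 10L)  # C(5,2) subsets all reached
  chi <- stats::chisq.test(as.vector(obs), p = rep(1 / 10, 10))
  expect_gt(chi$p.value, 0.001)
})

test_that("wrapper fitness is 1 on separable data and near chance on noise", {
  fm <- separable_fm(9)
  cfg <- fitness_config(fm, lambda_penalty = 0, seed = 2)
  expect_equal(iwd_fitness(c(1L, 2L), fm, cfg), 1.0)
  # subset-size penalty is exact arithmetic
  cfg5 <- fitness_config(fm, lambda_penalty = 0.5, seed = 2)
  expect_equal(iwd_fitness(1:4, fm, cfg5),
               iwd_fitness(1:4, fm, fitness_config(fm, 0L + 3, 0, 2)) - 0.5)
  # shuffled labels: accuracy hovers around 1/2
  set.seed(31)
  shuf <- feature_matrix(fm$values, sample(fm$labels), fm$class_names)
  f <- iwd_fitness(1:4, shuf, fitness_config(shuf, lambda_penalty = 0, seed = 2))
  expect_gt(f, 0.2); expect_lt(f, 0.8)
  expect_error(iwd_fitness(integer(), fm, cfg), "non-empty")
})

test_that("select over the full feature set is the forced solution", {
  fm <- separable_fm(6)
  p <- iwd_params(m = 4, n_iterations = 2, n_drops = 2, seed = 1)
  r <- iwd_select(fm, p)
  expect_identical(r$indices, 1:4)
  cfg <- fitness_config(fm, lambda_penalty = p$lambda_penalty,
                        seed = stage_seed(p$seed, "iwd_folds"))
  expect_equal(r$fitness, iwd_fitness(1:4, fm, cfg))
  expect_error(iwd_select(fm, iwd_params(m = 2, n_iterations = 0)),
               "n_iterations")
})

test_that("best fitness is non-decreasing and the search is reproducible", {
  fm <- oracle_toy()
  p <- iwd_params(m = 3, n_iterations = 15, n_drops = 5, seed = 8)
  r1 <- iwd_select(fm, p)
  r2 <- iwd_select(fm, p)
  expect_identical(r1$indices, r2$indices)
  expect_identical(r1$trace, r2$trace)
  expect_true(all(diff(r1$trace$best_fitness) >= 0))
})

test_that("the search finds the exhaustive optimum on a small landscape", {
  fm <- oracle_toy()
  cfg <- fitness_config(fm, lambda_penalty = 0.01, seed = 7)
  combs <- utils::combn(10, 3)
  opt <- max(apply(combs, 2, function(s) iwd_fitness(s, fm, cfg)))
  p <- iwd_params(m = 3, rho_n = 0.1, n_iterations = 60, seed = 4)
  r <- iwd_select(fm, p,
                  fitness_fn = function(idx, x) iwd_fitness(idx, x, cfg))
  expect_equal(r$fitness, opt)
})

test_that("HUD scores rank label-associated features as desirable", {
  fm <- oracle_toy()
  hud <- iwd_hud_scores(fm)
  expect_true(all(hud >= 0.05 & hud <= 1))
  informative <- c(1, 4, 7)
  expect_lt(max(hud[informative]), min(hud[-informative]))
})
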