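sphere <- function(x) sum((x - 0.5)^2)

test_that("population initialization respects the box and the seed", {
  cfg <- hso_config(m = 10L, seed = 1L)
  sw <- withr::with_seed(1L, init_population(sphere, 3L, cfg))
  expect_length(sw$agents, 10L)
  pos <- t(vapply(sw$agents, `[[`, numeric(3), "position"))
  expect_true(all(pos >= 0 & pos <= 1))
  fits <- vapply(sw$agents, `[[`, numeric(1), "fitness")
  expect_equal(sw$best_fitness, min(fits))
  sw2 <- withr::with_seed(1L, init_population(sphere, 3L, cfg))
  expect_identical(sw, sw2)
})

test_that("corvid move reduces to its algebraic special cases", {
  cfg <- hso_config(awareness_prob = 1, flight_length = 1)
  ag <- list(position = 0.2, fitness = sphere(0.2))
  expect_equal(withr::with_seed(1L, corvid_update(ag, 0.8, cfg, lambda1 = 0)),
               0.2)
  expect_equal(withr::with_seed(1L, corvid_update(ag, 0.8, cfg, lambda1 = 1)),
               0.8)
  expect_equal(withr::with_seed(1L, corvid_update(ag, 0.8, cfg, lambda1 = 0.5)),
               0.5)
})

test_that("gregarious move contracts toward the best and guards degeneracy", {
  cfg <- hso_config(v1 = 0, omega = 0)
  sw <- list(best_position = c(0.6, 0.6), best_fitness = 0.01,
             worst_fitness = 0.5, worst_position = c(0.9, 0.9),
             velocity = c(0, 0))
  worse <- list(position = c(0.2, 0.2), fitness = 0.3)
  expect_equal(gregarious_update(worse, sw, cfg, theta = 0), c(0.6, 0.6))
  expect_equal(gregarious_update(worse, sw, cfg, theta = 1), c(0.2, 0.2))
  # the agent at the global best is pushed off the worst, finitely
  best <- list(position = c(0.6, 0.6), fitness = 0.01)
  sw_deg <- sw
  sw_deg$worst_fitness <- 0.01   # all-equal fitness
  out <- gregarious_update(best, sw_deg, cfg, chi = 0.5)
  expect_true(all(is.finite(out)))
  expect_true(all(out >= 0 & out <= 1))
})

test_that("memory updates are greedy with strict improvement", {
  ag <- list(position = 0.4, fitness = sphere(0.4),
             memory = 0.4, memory_fitness = sphere(0.4))
  worse <- greedy_memory_update(ag, 0.9, sphere)
  expect_equal(worse$memory, 0.4)
  expect_equal(worse$position, 0.9)   # position still moves
  better <- greedy_memory_update(ag, 0.55, sphere)
  expect_equal(better$memory, 0.55)
  expect_equal(better$memory_fitness, sphere(0.55))
  tied <- greedy_memory_update(ag, 0.6, function(x) sphere(0.4))
  expect_equal(tied$memory, 0.4)      # equal fitness keeps the old memory
  infeasible <- greedy_memory_update(ag, 0.7, function(x) NaN)
  expect_equal(infeasible$position, 0.4)
})

test_that("optimization converges on the sphere and is reproducible", {
  res <- hso_optimize(sphere, 2L, hso_config(seed = 5L))
  expect_true(all(diff(res$trace) <= 0))
  expect_lt(res$value, 1e-2)
  res2 <- hso_optimize(sphere, 2L, hso_config(seed = 5L))
  expect_identical(res$trace, res2$trace)
  pos <- t(vapply(res$swarm$agents, `[[`, numeric(2), "position"))
  expect_true(all(pos >= 0 & pos <= 1))
  one <- hso_optimize(sphere, 2L, hso_config(max_iterations = 1L, seed = 2L))
  expect_length(one$trace, 1L)
})

test_that("HSO beats same-budget random search on a convex quadratic", {
  n_seeds <- 20L
  cfg <- function(s) hso_config(m = 20L, max_iterations = 200L, seed = s)
  hso_vals <- vapply(seq_len(n_seeds), function(s) {
    hso_optimize(sphere, 2L, cfg(s))$value
  }, numeric(1))
  rand_vals <- vapply(seq_len(n_seeds), function(s) {
    withr::with_seed(10000L + s, {
      min(apply(matrix(stats::runif(2 * 20L * 201L), ncol = 2), 1, sphere))
    })
  }, numeric(1))
  expect_lt(stats::median(hso_vals), 1e-2)
  expect_gte(sum(hso_vals < rand_vals), 16L)
})

test_that("fusion tuning recovers a perfect member and never falls below it", {
  n <- 60L
  labs <- rep(c("ictal", "normal"), n / 2)
  classes <- c("ictal", "normal")
  perfect <- matrix(0, n, 2, dimnames = list(NULL, classes))
  perfect[cbind(seq_len(n), match(labs, classes))] <- 1
  noisy <- withr::with_seed(8L, {
    m <- matrix(stats::runif(2 * n), n, 2)
    m / rowSums(m)
  })
  colnames(noisy) <- classes
  fp <- tune_fusion(list(perfect, noisy), labs,
                    hso_config(m = 15L, max_iterations = 30L, seed = 2L))
  w <- fp$weights / sum(fp$weights)
  expect_gte(w[1], 0.8)
  expect_gte(attr(fp, "accuracy"), 1)   # the perfect member's accuracy
  # a single member fuses to itself
  fp1 <- tune_fusion(list(noisy), labs,
                     hso_config(m = 5L, max_iterations = 5L, seed = 1L))
  acc_single <- mean(classes[max.col(noisy, ties.method = "first")] == labs)
  expect_equal(attr(fp1, "accuracy"), acc_single)
  expect_error(tune_fusion(list(perfect), character(0), hso_config()),
               "empty validation")
  expect_error(tune_fusion(list(perfect), rep("ictal", n), hso_config()),
               "both classes")
})
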