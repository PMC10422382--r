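with_seed <- get("with_seed", asNamespace("octaco"))

test_that("colony sizing follows the Kn = V x d rule, capped under auto", {
  pt <- make_planted_table(n_per_class = 5, n_classes = 2, n_informative = 2,
                           n_noise = 3, seed = 1)  # V = 10, d = 5
  ini <- init_state(pt$table, aco_config(n_ants = "literal"))
  expect_equal(ini$colony$Kn, 50)
  expect_equal(ini$colony$V, 10)
  expect_equal(ini$colony$d, 5)
  ini_auto <- init_state(pt$table, aco_config(n_ants = "auto"))
  expect_equal(ini_auto$colony$Kn, 32)
})

test_that("pheromone initializes uniformly at delta0", {
  tab <- feature_table(matrix(rnorm(24), 6, 4), rep(1:2, each = 3))
  ini <- init_state(tab, aco_config(delta0 = 1.0))
  expect_identical(ini$state$pheromone, c(1, 1, 1, 1))
  ini2 <- init_state(tab, aco_config(delta0 = 2.5))
  expect_identical(ini2$state$pheromone, rep(2.5, 4))
})

test_that("Fisher visibility matches hand-computed ratios", {
  # class 1: -0.5, 0.5 (pop var 0.25, mean 0); class 2: 0.5, 1.5 (mean 1)
  # between-class pop var of means {0, 1} = 0.25 -> ratio exactly 1
  X <- cbind(f1 = c(-0.5, 0.5, 0.5, 1.5), f2 = c(7, 7, 7, 7))
  tab <- feature_table(X, c(1L, 1L, 2L, 2L))
  v <- fisher_visibility(tab)
  expect_equal(v[[1]], 1.0)
  expect_equal(v[[2]], 0.0)  # constant feature
})

test_that("a perfectly separating feature dominates the visibility vector", {
  # 6-sample fixture; feature 1 separates classes with nonzero within-class
  # variance; oracle computed directly from the definition
  f1 <- c(0, 0.5, -0.5, 5, 5.5, 4.5)
  y <- c(1L, 1L, 1L, 2L, 2L, 2L)
  with_seed(2, X <- cbind(f1, matrix(rnorm(12), 6, 2)))
  tab <- feature_table(X, y)
  v <- fisher_visibility(tab)
  pop_var <- function(x) mean((x - mean(x))^2)
  within <- mean(c(pop_var(f1[1:3]), pop_var(f1[4:6])))
  means <- c(mean(f1[1:3]), mean(f1[4:6]))
  expect_equal(v[[1]], pop_var(means) / within)
  expect_equal(which.max(v), 1L)
})

test_that("Fisher visibility is invariant to sample order and needs 2 classes", {
  pt <- make_planted_table(n_per_class = 8, n_classes = 3, n_informative = 2,
                           n_noise = 3, seed = 5)
  v <- fisher_visibility(pt$table)
  perm <- with_seed(1, sample(nrow(pt$table$matrix)))
  tab_perm <- feature_table(pt$table$matrix[perm, ], pt$table$labels[perm],
                            pt$table$class_names)
  expect_equal(fisher_visibility(tab_perm), v)
  single <- feature_table(pt$table$matrix, rep(1L, nrow(pt$table$matrix)))
  expect_error(fisher_visibility(single), "two classes")
})

test_that("transition probabilities follow the pheromone-visibility product rule", {
  st <- list(pheromone = rep(1, 4), visibility = c(3, 1, 4, 2))
  p <- transition_probabilities(st, aco_config(beta = 0))
  expect_equal(p, rep(0.25, 4))  # uniform pheromone, visibility silenced

  st2 <- list(pheromone = c(2, 1), visibility = c(1, 1))
  p2 <- transition_probabilities(st2, aco_config(alpha = 1, beta = 7))
  expect_equal(p2, c(2 / 3, 1 / 3))

  # 5-feature brute-force oracle over the products
  st3 <- list(pheromone = c(1, 2, 3, 4, 5), visibility = c(5, 4, 3, 2, 1))
  p3 <- transition_probabilities(st3, aco_config(alpha = 1, beta = 1))
  prod <- c(1, 2, 3, 4, 5) * c(5, 4, 3, 2, 1)
  expect_equal(p3, prod / sum(prod))
  expect_equal(sum(p3), 1, tolerance = 1e-12)
})

test_that("excluded features get exactly zero probability", {
  st <- list(pheromone = c(1, 2, 3), visibility = c(1, 1, 1))
  p <- transition_probabilities(st, aco_config(), excluded = c(1L, 3L))
  expect_identical(p[c(1, 3)], c(0, 0))
  expect_equal(sum(p), 1)
  expect_error(transition_probabilities(st, aco_config(), excluded = 1:3),
               "all features")
})

test_that("pure exploitation picks the top products; exhaustion picks everything", {
  st <- list(pheromone = c(5, 1, 4, 2, 3), visibility = rep(1, 5))
  s <- with_seed(1, construct_subset(st, aco_config(q0 = 1), 3))
  expect_identical(s, c(1L, 3L, 5L))
  s_all <- with_seed(1, construct_subset(list(pheromone = rep(1, 3),
                                              visibility = rep(1, 3)),
                                         aco_config(q0 = 0), 3))
  expect_identical(s_all, 1:3)
  expect_error(construct_subset(st, aco_config(), 6), "exceeds")
})

test_that("sampled first picks match the binomial oracle", {
  st <- list(pheromone = c(2, 1), visibility = c(1, 1))
  cfg <- aco_config(q0 = 0, alpha = 1, beta = 0)
  n <- 10000
  picks <- with_seed(99, vapply(seq_len(n), function(i)
    construct_subset(st, cfg, 1L), integer(1)))
  p_hat <- mean(picks == 1L)
  se <- sqrt((2 / 3) * (1 / 3) / n)
  expect_lt(abs(p_hat - 2 / 3), 3 * se)
})

test_that("subset fitness is 1-NN holdout accuracy with its documented limits", {
  tab <- sign_table(n = 40)
  expect_equal(subset_fitness(tab, 1L, aco_config(seed = 2)), 1.0)
  f_all <- subset_fitness(tab, 1:5, aco_config(seed = 2))
  expect_lte(f_all, 1.0 + 1e-12)
  expect_error(subset_fitness(tab, 99L, aco_config()), "out-of-range")

  # random labels, 2 balanced classes: accuracy ~ 0.5 within 3 sigma
  n <- 400
  with_seed(7, {
    X <- matrix(rnorm(n * 4), n, 4)
    y <- rep(1:2, each = n / 2)
  })
  tab_null <- feature_table(X, y)
  cfg <- aco_config(seed = 5, fitness_holdout = 0.3)
  f <- subset_fitness(tab_null, 1:4, cfg)
  n_hold <- round(0.3 * n)
  expect_lt(abs(f - 0.5), 3 * sqrt(0.25 / n_hold))
})

test_that("local update is the stated convex deposit, only on the best subset", {
  st <- list(pheromone = c(1, 1, 1, 1), visibility = rep(1, 4))
  cfg <- aco_config(mu = 0.5)
  st2 <- local_update(st, best_subset = 2L, best_fitness = 0.8, cfg)
  expect_equal(st2$pheromone[2], 0.9)           # (1-.5)*1 + .5*.8
  expect_identical(st2$pheromone[-2], st$pheromone[-2])
  # mu -> 0 limit leaves pheromone unchanged
  cfg_eps <- aco_config(mu = 1e-12)
  st3 <- local_update(st, 1:2, 0.3, cfg_eps)
  expect_equal(st3$pheromone, st$pheromone, tolerance = 1e-10)
})

test_that("global update evaporates toward delta0 with its exact fixed point", {
  cfg <- aco_config(theta = 0.1, delta0 = 1)
  st <- list(pheromone = c(2, 1, 0.5), visibility = rep(1, 3))
  st2 <- global_update(st, cfg)
  expect_equal(st2$pheromone, c(0.9 * 2 + 0.1, 1, 0.9 * 0.5 + 0.1))
  at_fp <- list(pheromone = rep(1, 3), visibility = rep(1, 3))
  expect_identical(global_update(at_fp, cfg)$pheromone, at_fp$pheromone)
})

test_that("repeated evaporation contracts geometrically at rate (1 - theta)", {
  cfg <- aco_config(theta = 0.2, delta0 = 1)
  st <- list(pheromone = c(3, 0.2, 1.7), visibility = rep(1, 3))
  gap0 <- max(abs(st$pheromone - 1))
  for (k in 1:6) {
    st <- global_update(st, cfg)
    expect_equal(max(abs(st$pheromone - 1)), gap0 * 0.8^k)
  }
})

test_that("pheromone stays strictly positive under arbitrary update sequences", {
  for (seed in 1:5) {
    with_seed(seed, {
      cfg <- aco_config(mu = runif(1, 0.01, 0.99), theta = runif(1, 0.01, 0.99),
                        delta0 = runif(1, 0.1, 2))
      st <- list(pheromone = rep(cfg$delta0, 10), visibility = runif(10))
      for (k in 1:50) {
        if (runif(1) < 0.5)
          st <- local_update(st, sample(10, 3), runif(1), cfg)
        else
          st <- global_update(st, cfg)
        expect_true(all(st$pheromone > 0))
      }
    })
  }
})

test_that("a degenerate one-ant one-iteration greedy run is fully deterministic", {
  pt <- make_planted_table(n_per_class = 10, n_classes = 2, n_informative = 3,
                           n_noise = 7, seed = 8)
  cfg <- aco_config(n_iterations = 1, n_ants = 1, subset_size = 5, q0 = 1,
                    seed = 1)
  sel <- run_aco(pt$table, cfg)
  # pure argmax: selected = top-5 by pheromone^a * visibility^b
  v <- fisher_visibility(pt$table)
  top5 <- sort(order(-v)[1:5])
  expect_identical(sel$selected_indices, top5)
  pr <- prune_redundant(pt$table, top5, 0.2, visibility = v)
  expect_identical(sel$kept_indices, pr$kept)
  expect_identical(sel$pruned_indices, pr$pruned)
})

test_that("run_aco is reproducible and its elitist trace never decreases", {
  pt <- make_planted_table(n_per_class = 15, n_classes = 2, n_informative = 2,
                           n_noise = 8, class_sep = 1, seed = 3)
  cfg <- aco_config(n_iterations = 15, n_ants = 8, subset_size = 3, seed = 21)
  s1 <- run_aco(pt$table, cfg)
  s2 <- run_aco(pt$table, cfg)
  expect_identical(s1$kept_indices, s2$kept_indices)
  expect_identical(s1$best_fitness_per_iteration, s2$best_fitness_per_iteration)
  expect_identical(s1$final_pheromone, s2$final_pheromone)
  expect_false(is.unsorted(s1$best_fitness_per_iteration))
  expect_length(s1$best_fitness_per_iteration, 15)
  expect_true(all(s1$final_pheromone > 0))
  expect_length(intersect(s1$kept_indices, s1$pruned_indices), 0)
  expect_error(run_aco(pt$table, aco_config(n_iterations = 0)), "n_iterations")
})

test_that("a generous budget attains the exhaustive-search optimum", {
  tab <- planted_instance(n_per_class = 20, gap = 3, seed = 12)
  cfg <- aco_config(n_iterations = 20, n_ants = 10, subset_size = 3, seed = 77)
  sel <- run_aco(tab, cfg)
  combos <- combn(8, 3)
  best <- max(apply(combos, 2, function(s)
    subset_fitness(tab, s, cfg)))
  expect_equal(sel$best_fitness, best)
})

test_that("config validation enforces the documented parameter ranges", {
  expect_error(aco_config(mu = 0), "mu")
  expect_error(aco_config(mu = 1), "mu")
  expect_error(aco_config(theta = 1.2), "theta")
  expect_error(aco_config(delta0 = -1), "delta0")
  expect_error(aco_config(prune_fraction = 0.5), "prune_fraction")
  expect_silent(aco_config(prune_fraction = 0.5, allow_prune_override = TRUE))
})

test_that("redundancy pruning removes floor(fraction * size) features", {
  pt <- make_planted_table(n_per_class = 10, n_classes = 2, n_informative = 5,
                           n_noise = 20, seed = 4)
  pr <- prune_redundant(pt$table, 1:20, 0.2)
  expect_length(pr$pruned, 4)
  expect_length(pr$kept, 16)
  expect_setequal(c(pr$kept, pr$pruned), 1:20)
  # size-1 subsets pass through untouched
  pr1 <- prune_redundant(pt$table, 3L, 0.2)
  expect_identical(pr1$kept, 3L)
  expect_length(pr1$pruned, 0)
})

test_that("an exact duplicate column is pruned first", {
  with_seed(6, X <- matrix(rnorm(60), 20, 3))
  X <- cbind(X, dup = X[, 2])
  tab <- feature_table(X, rep(1:2, 10))
  pr <- prune_redundant(tab, 1:4, 0.2, visibility = c(4, 3, 2, 1),
                        override = FALSE)
  expect_length(pr$pruned, 0)   # floor(0.2 * 4) = 0: nothing removed
  pr <- prune_redundant(tab, 1:4, 0.19, visibility = c(4, 1, 2, 3),
                        override = TRUE)
  expect_length(pr$pruned, 0)
  pr2 <- prune_redundant(tab, 1:4, 0.25, visibility = c(4, 1, 2, 3),
                         override = TRUE)
  expect_identical(pr2$pruned, 2L)  # the lower-visibility twin goes
})

test_that("with orthogonal features pruning falls back to lowest visibility", {
  X <- cbind(a = c(1, 1, -1, -1), b = c(1, -1, 1, -1), c = c(1, -1, -1, 1))
  X <- rbind(X, X)  # 8 samples, columns exactly orthogonal and zero-mean
  tab <- feature_table(X, rep(1:2, each = 4))
  vis <- c(0.9, 0.1, 0.5)
  pr <- prune_redundant(tab, 1:3, 0.34, visibility = vis, override = TRUE)
  expect_identical(pr$pruned, 2L)   # floor(.34*3) = 1: lowest visibility
})
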