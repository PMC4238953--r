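# The generator is first-class code: these tests pin its contracts (exact
# determinism, simplex ground truth, the Poisson design, label-frequency
# consistency) rather than just smoke-testing it.

small_params <- function(seed = 3L, mean_extra_pairs = 2, ...) {
  sim_params(N = 5L, C = 30L, K = 3L, L = 4L, mean_reactions = 60,
             mean_extra_pairs = mean_extra_pairs, seed = seed, ...)
}

test_that("simulation is fully deterministic given the seed", {
  a <- simulate_dataset(small_params())
  b <- simulate_dataset(small_params())
  expect_identical(a$catalog, b$catalog)
  expect_identical(a$dataset, b$dataset)
  expect_identical(a$truth, b$truth)
  c <- simulate_dataset(small_params(seed = 4L))
  expect_false(identical(a$dataset, c$dataset))
})

test_that("ground-truth rows are simplexes and labels are in range", {
  sim <- simulate_dataset(small_params())
  tr <- sim$truth
  for (m in list(tr$theta_true, tr$phi_true, tr$delta_true, tr$gamma_true)) {
    expect_equal(rowSums(m), rep(1, nrow(m)), tolerance = 1e-9)
    expect_true(all(m >= 0))
  }
  expect_true(all(tr$z_true >= 1L & tr$z_true <= 3L))
  expect_true(all(tr$y_true >= 1L & tr$y_true <= 4L))
  expect_length(tr$z_true, sum(sim$dataset$I))
})

test_that("every reaction has at least one substrate-product pair", {
  sim <- simulate_dataset(small_params(mean_extra_pairs = 0.2))
  expect_true(all(sim$catalog$J >= 1L))
})

test_that("per-sample token counts follow the Poisson(1000) design", {
  sim <- simulate_dataset(sim_params(N = 40, C = 100, K = 3, L = 10,
                                     seed = 5))
  m <- mean(sim$dataset$I)
  se <- sqrt(1000 / 40)
  expect_lt(abs(m - 1000), 5 * se)
})

test_that("token label frequencies converge to theta_true", {
  sim <- simulate_dataset(sim_params(N = 3, C = 50, K = 3, L = 5,
                                     mean_reactions = 10000, seed = 8))
  for (n in 1:3) {
    emp <- tabulate(sim$truth$z_true[sim$truth$token_sample == n], 3) /
      sim$dataset$I[n]
    expect_lt(sum(abs(emp - sim$truth$theta_true[n, ])), 0.05)
  }
})

test_that("smaller generating alpha gives sparser mixtures", {
  sparse <- simulate_dataset(small_params(alpha_theta_gen = 0.05, seed = 21))
  mixed <- simulate_dataset(small_params(alpha_theta_gen = 0.20, seed = 21))
  expect_gt(mean(apply(sparse$truth$theta_true, 1, max)),
            mean(apply(mixed$truth$theta_true, 1, max)))
})

test_that("the abundance multiset matches the generated tokens", {
  sim <- simulate_dataset(small_params())
  tr <- sim$truth
  tok <- table(tr$token_sample, tr$token_reaction)
  for (i in seq_len(nrow(sim$dataset$counts))) {
    row <- sim$dataset$counts[i, ]
    expect_equal(unname(tok[as.character(row$sample),
                            as.character(row$reaction)]),
                 row$count)
  }
  expect_equal(sum(sim$dataset$I), length(tr$z_true))
})

test_that("the factorial simulation grid has the stated design", {
  grid <- simulation_grid()
  expect_length(grid, 4 * 3 * 2 * 3 * 3)
  expect_true(all(vapply(grid, function(p) p$mean_reactions, 0) == 1000))
  expect_true(all(vapply(grid, function(p) p$mean_extra_pairs, 0) == 2))
  expect_true(all(vapply(grid, function(p) {
    p$alpha_theta_gen == p$alpha_phi_gen
  }, NA)))
  seeds <- vapply(grid, function(p) p$seed, 0L)
  expect_false(anyDuplicated(seeds) > 0)
  expect_setequal(unique(vapply(grid, function(p) p$N, 0L)),
                  c(40L, 60L, 80L, 100L))
  expect_setequal(unique(vapply(grid, function(p) p$alpha_theta_gen, 0)),
                  c(0.05, 0.10, 0.20))
})

test_that("simulated catalog and abundances round-trip through files", {
  sim <- simulate_dataset(small_params())
  fc <- withr::local_tempfile(fileext = ".tsv")
  fa <- withr::local_tempfile(fileext = ".tsv")
  write_catalog(sim$catalog, fc)
  write_abundances(sim$dataset, sim$catalog, fa)
  cat2 <- read_catalog(fc, pairing = "zip")
  ds2 <- read_abundances(fa, cat2)
  expect_equal(cat2$reaction_ids, sim$catalog$reaction_ids)
  slot_ids <- function(cat, slots) {
    lapply(slots, function(s) cat$compound_ids[s])
  }
  expect_equal(slot_ids(cat2, cat2$sub_slots),
               slot_ids(sim$catalog, sim$catalog$sub_slots))
  expect_equal(slot_ids(cat2, cat2$prod_slots),
               slot_ids(sim$catalog, sim$catalog$prod_slots))
  expect_equal(ds2$counts, sim$dataset$counts)
  expect_equal(ds2$I, sim$dataset$I)
})
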