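# Sampler correctness is anchored on the brute-force gamma-function oracle
# in helper-oracle.R: the conditional table must reproduce exact joint-
# probability ratios, and the chain's stationary distribution must match
# exact enumeration (including under a reversed visit order).

state_invariants_hold <- function(state, dataset, catalog) {
  expect_equal(rowSums(state$count_nk), dataset$I)
  expect_equal(rowSums(state$count_kl), state$count_k)
  expect_equal(rowSums(state$dcount_lc), state$dcount_l)
  expect_equal(rowSums(state$gcount_lc), state$gcount_l)
  total_J <- sum(catalog$J[state$token_reaction])
  expect_equal(sum(state$dcount_l), total_J)
  expect_equal(sum(state$gcount_l), total_J)
  expect_true(all(state$count_nk >= 0) && all(state$dcount_lc >= 0) &&
                all(state$gcount_lc >= 0))
}

test_that("init_state builds consistent count tables, reproducibly", {
  ti <- tiny_instance()
  spec <- model_spec(2, 2, alpha = 0.1)
  s1 <- init_state(ti$dataset, ti$catalog, spec, seed = 9)
  s2 <- init_state(ti$dataset, ti$catalog, spec, seed = 9)
  state_invariants_hold(s1, ti$dataset, ti$catalog)
  expect_identical(s1$z, s2$z)
  expect_identical(s1$y, s2$y)
  s3 <- init_state(ti$dataset, ti$catalog, model_spec(1, 1, alpha = 0.1))
  expect_true(all(s3$z == 1L) && all(s3$y == 1L))
})

test_that("a lone token with symmetric priors gets a uniform conditional", {
  catalog <- reaction_catalog("Ca", "R1", list(1L), list(1L))
  dataset <- sample_dataset("s1", 1L, 1L, 1L, catalog)
  spec <- model_spec(3, 4, alpha = 0.01)
  state <- init_state(dataset, catalog, spec, seed = 1)
  ct <- conditional_table(state, 1)
  expect_equal(ct, matrix(1 / 12, 3, 4), tolerance = 1e-14)
})

test_that("conditional tables equal exact joint-probability ratios", {
  for (seed in 1:20) {
    ri <- random_instance(seed)
    spec <- model_spec(2, 2,
                       alpha_theta = 0.05 + 0.3 * (seed %% 3),
                       alpha_phi = 0.1, alpha_delta = 0.07,
                       alpha_gamma = 0.2)
    T_ <- length(ri$inst$token_sample)
    set.seed(seed + 500)
    z <- sample.int(2, T_, TRUE); y <- sample.int(2, T_, TRUE)
    state <- state_with_labels(ri$dataset, ri$catalog, spec, z, y)
    tok <- sample.int(T_, 1)
    ct <- conditional_table(state, tok)
    oc <- oracle_conditional(z, y, tok, ri$inst, spec)
    expect_equal(ct, oc, tolerance = 1e-12)
    expect_equal(sum(ct), 1, tolerance = 1e-12)
    expect_true(all(ct >= 0))
  }
})

test_that("direct and log-space conditional paths agree to 1e-10", {
  for (seed in 1:10) {
    ri <- random_instance(seed + 40)
    spec <- model_spec(2, 2, alpha = 0.05)
    T_ <- length(ri$inst$token_sample)
    set.seed(seed)
    state <- state_with_labels(ri$dataset, ri$catalog, spec,
                               sample.int(2, T_, TRUE),
                               sample.int(2, T_, TRUE))
    tok <- sample.int(T_, 1)
    direct <- conditional_table(state, tok, log_space = FALSE)
    logged <- conditional_table(state, tok, log_space = TRUE)
    expect_equal(direct, logged, tolerance = 1e-10)
  }
})

test_that("log joint matches the oracle's gamma-function evaluation", {
  ti <- tiny_instance()
  spec <- model_spec(2, 2, alpha = 0.1)
  set.seed(3)
  z <- sample.int(2, 6, TRUE); y <- sample.int(2, 6, TRUE)
  state <- state_with_labels(ti$dataset, ti$catalog, spec, z, y)
  expect_equal(log_joint(state), oracle_log_joint(z, y, ti$inst, spec),
               tolerance = 1e-10)
})

test_that("sweeps conserve tokens and are seed-reproducible", {
  ti <- tiny_instance()
  spec <- model_spec(2, 2, alpha = 0.1)
  s <- init_state(ti$dataset, ti$catalog, spec, seed = 2)
  for (i in 1:5) {
    s <- gibbs_sweep(s)
    state_invariants_hold(s, ti$dataset, ti$catalog)
  }
  a <- gibbs_sweep(init_state(ti$dataset, ti$catalog, spec, seed = 2), 10)
  b <- gibbs_sweep(init_state(ti$dataset, ti$catalog, spec, seed = 2), 10)
  expect_identical(a$z, b$z)
  expect_identical(a$y, b$y)
  # degenerate single-component model: sweeps cannot move labels
  s1 <- init_state(ti$dataset, ti$catalog, model_spec(1, 1, alpha = 0.1))
  s1 <- gibbs_sweep(s1, 3)
  expect_true(all(s1$z == 1L) && all(s1$y == 1L))
})

test_that("run_sampler honours the schedule and logs finite joints", {
  ti <- tiny_instance()
  spec <- model_spec(2, 2, alpha = 0.1)
  sch <- sampler_schedule(burn_in = 5, n_retained = 7, lag = 2, seed = 4)
  fit <- run_sampler(ti$dataset, ti$catalog, spec, sch)
  expect_length(fit$draws, 7L)
  expect_equal(dim(fit$theta), c(2, 2, 7))
  expect_true(all(is.finite(fit$log_joint)))
  expect_equal(total_sweeps(sampler_schedule()), 100 + 500 * 20)
  # identical schedule + seed => identical retained labels
  fit2 <- run_sampler(ti$dataset, ti$catalog, spec, sch)
  expect_identical(fit$draws, fit2$draws)
})

test_that("a reversed visit order leaves the stationary distribution unchanged", {
  ti <- tiny_instance3()
  spec <- model_spec(2, 2, alpha = 0.2)
  ex <- oracle_enumerate(ti$inst, spec)
  state <- init_state(ti$dataset, ti$catalog, spec, seed = 6)
  T_ <- length(state$z)
  state <- gibbs_sweep(state, n_sweeps = 500, order = rev(seq_len(T_)))
  n_draws <- 200000L
  ids <- integer(n_draws)
  for (i in seq_len(n_draws)) {
    state <- gibbs_sweep(state, order = rev(seq_len(T_)))
    ids[i] <- config_id(state$z, state$y, spec$K, spec$L)
  }
  emp <- tabulate(ids, nbins = length(ex$prob)) / n_draws
  expect_lt(sum(abs(emp - ex$prob)) / 2, 0.01)
})
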