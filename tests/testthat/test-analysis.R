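test_that("jsd matches direct evaluation of its two KL terms", {
  p <- c(0.5, 0.5); q <- c(0.9, 0.1); m <- (p + q) / 2
  direct <- 0.5 * sum(p * log2(p / m)) + 0.5 * sum(q * log2(q / m))
  expect_equal(jsd(p, q), direct, tolerance = 1e-14)
  expect_equal(jsd(c(0.2, 0.3, 0.5), c(0.2, 0.3, 0.5)), 0)
  expect_equal(jsd(c(1, 0), c(0, 1)), 1)
  expect_error(jsd(c(0.5, 0.5), c(0.5, 0.4, 0.1)),
               class = "metabonet_usage_error")
  expect_error(jsd(c(0.7, 0.7), c(0.5, 0.5)),
               class = "metabonet_usage_error")
})

test_that("reaction composition mixes subnetwork profiles by phi", {
  # toy K=2, L=2, R=3 case against hand-computed mixtures
  prof <- rbind(c(0.6, 0.3, 0.1), c(0.1, 0.1, 0.8))
  phi <- rbind(c(0.25, 0.75), c(0, 1))
  summ <- structure(list(phi_mean = phi, subnetwork_reaction_profile = prof),
                    class = "posterior_summary")
  comp <- reaction_composition(summ)
  expect_equal(unname(comp[1, ]), 0.25 * prof[1, ] + 0.75 * prof[2, ])
  expect_equal(unname(comp[2, ]), prof[2, ])  # indicator row
  expect_equal(unname(rowSums(comp)), c(1, 1), tolerance = 1e-12)
})

test_that("divergence matrices are symmetric, zero-diagonal and entrywise jsd", {
  set.seed(1)
  mk <- function() {
    m <- matrix(stats::rgamma(2 * 5, 0.5), 2, 5)
    m <- m / rowSums(m)
    colnames(m) <- paste0("R", 1:5)
    m
  }
  p1 <- mk(); p2 <- mk()
  dm <- divergence_matrix(list(a = p1, b = p2))
  expect_equal(dim(dm), c(4L, 4L))
  expect_equal(dm, t(dm))
  expect_equal(diag(dm), stats::setNames(rep(0, 4), rownames(dm)))
  expect_equal(dm["a:M1", "b:M2"], jsd(p1[1, ], p2[2, ]))
  expect_true(all(dm >= 0 & dm <= 1))
  # duplicated profiles give a zero off-diagonal block
  dm2 <- divergence_matrix(list(a = p1, b = p1))
  expect_equal(unname(dm2[1:2, 3:4]), unname(dm2[1:2, 1:2]))
  expect_error(divergence_matrix(list(p1, mk()[, 1:4])),
               class = "metabonet_usage_error")
})

test_that("match_components recovers permutations and is assignment-optimal", {
  set.seed(7)
  ref <- matrix(stats::rgamma(4 * 6, 0.3), 4, 6)
  ref <- ref / rowSums(ref)
  expect_equal(match_components(ref, ref), 1:4)
  perm <- c(3L, 1L, 4L, 2L)
  expect_equal(match_components(ref, ref[perm, ]), order(perm))
  # against exhaustive search over all K! permutations, random profiles
  perms4 <- as.matrix(expand.grid(1:4, 1:4, 1:4, 1:4))
  perms4 <- perms4[apply(perms4, 1, function(p) !anyDuplicated(p)), ]
  for (rep in 1:5) {
    other <- matrix(stats::rgamma(4 * 6, 0.3), 4, 6)
    other <- other / rowSums(other)
    for (method in c("jsd", "l1")) {
      costf <- function(i, j) {
        if (method == "jsd") jsd(ref[i, ], other[j, ])
        else mean(abs(ref[i, ] - other[j, ]))
      }
      tot <- apply(perms4, 1, function(p) {
        sum(vapply(1:4, function(i) costf(i, p[i]), 0))
      })
      got <- match_components(ref, other, method = method)
      got_cost <- sum(vapply(1:4, function(i) costf(i, got[i]), 0))
      expect_equal(got_cost, min(tot), tolerance = 1e-12)
    }
  }
  expect_error(match_components(ref, ref[1:3, ]),
               class = "metabonet_usage_error")
})

test_that("principal subnetworks use the strict 2/L rule", {
  phi_row <- c(0.001, 0.001, 0.2, 0.001, 0.001, 0.1, 0.001, 0.001, 0.7,
               0.001)
  phi_row <- phi_row / sum(phi_row)  # renormalize the illustration vector
  phi <- rbind(phi_row, rep(1 / 10, 10), diag(10)[3, ])
  ps <- principal_subnetworks(phi)
  # 0.2 is not > 2/L = 0.2: only the 0.7 subnetwork passes for row 1
  expect_equal(ps$per_metabosystem[[1]], 9L)
  expect_equal(ps$per_metabosystem[[2]], integer(0))  # uniform row
  expect_equal(ps$per_metabosystem[[3]], 3L)          # indicator row
  expect_equal(ps$union, c(3L, 9L))
  expect_equal(ps$threshold, 0.2)
})

test_that("membership scores are absolute log ratios against the runner-up", {
  phi <- cbind(c(0.7, 0.2, 0.05))
  expect_equal(membership_score(phi, 1, 1), log(3.5))
  expect_equal(membership_score(phi, 2, 1), abs(log(0.2 / 0.7)))
  expect_equal(membership_score(cbind(c(0.3, 0.3, 0.3)), 1, 1), 0)
  # invariant to which other metabosystem holds the maximum
  phi2 <- cbind(c(0.5, 0.3, 0.2)); phi3 <- cbind(c(0.5, 0.2, 0.3))
  expect_equal(membership_score(phi2, 1, 1), membership_score(phi3, 1, 1))
  expect_error(membership_score(cbind(0.5), 1, 1),
               class = "metabonet_usage_error")
})

test_that("discriminatory and core flags follow the thresholds and are disjoint", {
  L <- 10
  phi <- matrix(0.001, 3, L)
  phi[, 1] <- c(0.7, 0.2, 0.05)   # principal + discriminatory
  phi[, 2] <- c(0.25, 0.25, 0.25) # principal everywhere, score 0 -> core
  phi[, 3] <- c(0.01, 0.01, 0.01) # not abundant anywhere
  disc <- discriminatory_subnetworks(phi)
  expect_true(disc[1, 1])
  expect_false(any(disc[, 2]))
  expect_false(any(disc[, 3]))
  expect_equal(core_subnetworks(phi), 2L)
  # infinite threshold: nothing discriminatory
  expect_false(any(discriminatory_subnetworks(phi, score_threshold = Inf)))
  # core and discriminatory never overlap
  set.seed(2)
  rphi <- matrix(stats::rgamma(3 * L, 0.2), 3, L)
  rphi <- rphi / rowSums(rphi)
  dsc <- discriminatory_subnetworks(rphi)
  expect_length(intersect(core_subnetworks(rphi), which(colSums(dsc) > 0)),
                0)
})

test_that("principal reactions apply the inclusive 2/R filter", {
  prof <- rbind(c(1, rep(0, 99)),
                rep(1 / 100, 100),
                c(0.5, 0.3, 0.15, 0.05, rep(0, 96)))
  pr <- principal_reactions(prof, r_unique = 100)
  expect_equal(pr$threshold, 0.02)
  expect_equal(nrow(pr$per_subnetwork[[1]]), 1L)
  expect_equal(pr$per_subnetwork[[1]]$cumulative, 1)
  expect_equal(nrow(pr$per_subnetwork[[2]]), 0L)  # 0.01 < 0.02
  expect_equal(pr$per_subnetwork[[3]]$probability, c(0.5, 0.3, 0.15, 0.05))
  expect_equal(max(pr$per_subnetwork[[3]]$cumulative), 1)
})

test_that("the subnetwork report is internally consistent", {
  set.seed(5)
  phi <- matrix(stats::rgamma(3 * 8, 0.3), 3, 8)
  phi <- phi / rowSums(phi)
  rep_ <- subnetwork_report(phi)
  tab <- rep_$table
  expect_equal(nrow(tab), 24L)
  expect_equal(tab$principal, tab$membership > 2 / 8)
  expect_true(all(tab$subnetwork[tab$discriminatory] %in%
                    rep_$principal_union))
  expect_length(intersect(rep_$core,
                          tab$subnetwork[tab$discriminatory]), 0)
})

test_that("subnetwork edge lists expose the bipartite reaction-compound graph", {
  sim <- simulate_dataset(sim_params(N = 3, C = 15, K = 2, L = 3,
                                     mean_reactions = 30, seed = 12))
  fit <- run_sampler(sim$dataset, sim$catalog, model_spec(2, 3, 0.01),
                     sampler_schedule(10, 3, 2, seed = 1))
  summ <- summarize_posterior(fit, diagnose_switching = FALSE)
  el <- subnetwork_edgelist(summ, sim$catalog, 1,
                            currency = sim$catalog$compound_ids[1])
  expect_true(all(el$from_type %in% c("compound", "reaction")))
  if (nrow(el) > 0) {
    expect_true(all(el$reaction_probability > 0))
    expect_true(is.logical(el$currency))
  }
})
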