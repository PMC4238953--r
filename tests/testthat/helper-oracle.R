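# Independent brute-force oracle for the collapsed model, used to verify the
# sampler. Everything here is computed from first principles with plain R
# loops and Dirichlet-multinomial normalizing constants (products of gamma
# functions); none of it shares code with the package's sampler.

# Naive count tables from labels (loops on purpose).
oracle_counts <- function(z, y, inst, K, L) {
  cnk <- matrix(0L, inst$N, K)
  ckl <- matrix(0L, K, L)
  dlc <- matrix(0L, L, inst$C)
  glc <- matrix(0L, L, inst$C)
  for (t in seq_along(z)) {
    r <- inst$token_reaction[t]
    n <- inst$token_sample[t]
    cnk[n, z[t]] <- cnk[n, z[t]] + 1L
    ckl[z[t], y[t]] <- ckl[z[t], y[t]] + 1L
    for (c in inst$sub_slots[[r]]) dlc[y[t], c] <- dlc[y[t], c] + 1L
    for (c in inst$prod_slots[[r]]) glc[y[t], c] <- glc[y[t], c] + 1L
  }
  list(cnk = cnk, ckl = ckl, dlc = dlc, glc = glc)
}

# log Dirichlet-multinomial normalizing-constant term for one count row.
ldirmult <- function(counts, alpha) {
  d <- length(counts)
  lgamma(d * alpha) - d * lgamma(alpha) +
    sum(lgamma(counts + alpha)) - lgamma(sum(counts) + d * alpha)
}

# log P(Z = z, Y = y, all pairs | alphas) for a full label configuration.
oracle_log_joint <- function(z, y, inst, spec) {
  cts <- oracle_counts(z, y, inst, spec$K, spec$L)
  lp <- 0
  for (n in seq_len(inst$N)) lp <- lp + ldirmult(cts$cnk[n, ], spec$alpha_theta)
  for (k in seq_len(spec$K)) lp <- lp + ldirmult(cts$ckl[k, ], spec$alpha_phi)
  for (l in seq_len(spec$L)) {
    lp <- lp + ldirmult(cts$dlc[l, ], spec$alpha_delta)
    lp <- lp + ldirmult(cts$glc[l, ], spec$alpha_gamma)
  }
  lp
}

# Encode a full configuration as one integer in [1, (K*L)^T]; per-token cell
# index runs k fastest (matching the K x L column-major flattening).
config_id <- function(z, y, K, L) {
  cell <- (z - 1L) + K * (y - 1L)
  sum(cell * (K * L)^(seq_along(cell) - 1L)) + 1L
}

# Exact posterior over all (K*L)^T label configurations.
oracle_enumerate <- function(inst, spec) {
  T_ <- length(inst$token_sample)
  KL <- spec$K * spec$L
  n_cfg <- KL^T_
  logp <- numeric(n_cfg)
  cells <- as.matrix(expand.grid(rep(list(0:(KL - 1L)), T_),
                                 KEEP.OUT.ATTRS = FALSE))
  for (i in seq_len(n_cfg)) {
    z <- cells[i, ] %% spec$K + 1L
    y <- cells[i, ] %/% spec$K + 1L
    logp[i] <- oracle_log_joint(z, y, inst, spec)
  }
  # expand.grid varies the first token fastest, matching config_id's encoding
  prob <- exp(logp - max(logp))
  list(prob = prob / sum(prob), logp = logp)
}

# Exact single-token conditional given all other labels: ratio of joint
# probabilities over the candidate (k, l) cells.
oracle_conditional <- function(z, y, token, inst, spec) {
  out <- matrix(NA_real_, spec$K, spec$L)
  for (l in seq_len(spec$L)) {
    for (k in seq_len(spec$K)) {
      z2 <- z; y2 <- y
      z2[token] <- k; y2[token] <- l
      out[k, l] <- oracle_log_joint(z2, y2, inst, spec)
    }
  }
  p <- exp(out - max(out))
  p / sum(p)
}

# A small fixed instance: N = 2 samples, 6 tokens, K = L = 2, C = 4,
# J <= 2 pairs per reaction. Returns both the package objects and the raw
# `inst` structure the oracle consumes.
tiny_instance <- function() {
  catalog <- reaction_catalog(
    compound_ids = c("Ca", "Cb", "Cc", "Cd"),
    reaction_ids = c("R1", "R2", "R3"),
    substrates = list(1L, 3L, 1L),
    products = list(2L, 4L, c(2L, 4L)))
  dataset <- sample_dataset(
    c("s1", "s2"),
    sample = c(1L, 1L, 2L, 2L),
    reaction = c(1L, 3L, 2L, 1L),
    count = c(2L, 1L, 2L, 1L),
    catalog = catalog)
  inst <- list(
    N = 2L, C = 4L,
    token_sample = rep(dataset$counts$sample, dataset$counts$count),
    token_reaction = rep(dataset$counts$reaction, dataset$counts$count),
    sub_slots = catalog$sub_slots,
    prod_slots = catalog$prod_slots)
  list(catalog = catalog, dataset = dataset, inst = inst)
}

# A 3-token variant (one token with J = 2) whose exact posterior has small
# enough support for total-variation comparison against long Gibbs runs.
tiny_instance3 <- function() {
  catalog <- reaction_catalog(
    compound_ids = c("Ca", "Cb", "Cc", "Cd"),
    reaction_ids = c("R1", "R2", "R3"),
    substrates = list(1L, 3L, 1L),
    products = list(2L, 4L, c(2L, 4L)))
  dataset <- sample_dataset(
    c("s1", "s2"),
    sample = c(1L, 1L, 2L),
    reaction = c(1L, 3L, 2L),
    count = c(1L, 1L, 1L),
    catalog = catalog)
  inst <- list(
    N = 2L, C = 4L,
    token_sample = rep(dataset$counts$sample, dataset$counts$count),
    token_reaction = rep(dataset$counts$reaction, dataset$counts$count),
    sub_slots = catalog$sub_slots,
    prod_slots = catalog$prod_slots)
  list(catalog = catalog, dataset = dataset, inst = inst)
}

# Random small instance (used for parameterised conditional checks).
random_instance <- function(seed, N = 2L, K = 2L, L = 2L, C = 4L,
                            max_reactions = 3L, max_tokens = 6L) {
  set.seed(seed)
  R <- sample(2:max_reactions, 1L)
  substrates <- lapply(seq_len(R), function(r) sample.int(C, sample(1:2, 1L)))
  products <- lapply(seq_len(R), function(r) sample.int(C, sample(1:2, 1L)))
  catalog <- reaction_catalog(sprintf("C%d", 1:C), sprintf("R%d", 1:R),
                              substrates, products)
  T_ <- sample(N:max_tokens, 1L)
  tok_s <- sort(c(seq_len(N), sample.int(N, T_ - N, replace = TRUE)))
  tok_r <- sample.int(R, T_, replace = TRUE)
  agg <- stats::aggregate(list(count = rep(1L, T_)),
                          by = list(sample = tok_s, reaction = tok_r),
                          FUN = sum)
  dataset <- sample_dataset(sprintf("s%d", seq_len(N)), agg$sample,
                            agg$reaction, agg$count, catalog)
  inst <- list(N = N, C = C,
               token_sample = rep(dataset$counts$sample, dataset$counts$count),
               token_reaction = rep(dataset$counts$reaction,
                                    dataset$counts$count),
               sub_slots = catalog$sub_slots,
               prod_slots = catalog$prod_slots)
  list(catalog = catalog, dataset = dataset, inst = inst)
}

# All permutations of 1:n as rows (recursive construction).
all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

# Package state with prescribed labels (counts rebuilt through the package's
# own tabulation).
state_with_labels <- function(dataset, catalog, spec, z, y) {
  state <- init_state(dataset, catalog, spec, seed = 1L)
  state$z <- as.integer(z)
  state$y <- as.integer(y)
  counts <- metabonet:::count_tables(
    state$z, state$y, state$token_sample, state$token_reaction, state$tdata,
    state$N, spec$K, spec$L, state$C)
  state[names(counts)] <- counts
  state
}
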