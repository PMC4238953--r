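# Geweke-style prior-consistency machinery: compare forward simulation from
# the generative prior against a successive-conditional chain that
# alternates (a) exact resampling of the compound data given the labels
# (Polya-urn draws from the collapsed Dirichlet-multinomial) and (b) Gibbs
# label updates through the package sampler. If the sampler targets the
# right conditional, both procedures sample the same joint distribution.

# Fixed token skeleton: sample of each token, and its pair count J.
geweke_design <- function() {
  list(N = 3L, C = 5L, K = 2L, L = 2L,
       token_sample = rep(1:3, each = 4L),
       J = rep(c(1L, 2L), times = 6L))
}

geweke_spec <- function() model_spec(2, 2, alpha = 0.3)

# Scalar summary statistics of one (labels, data) joint draw.
geweke_stats <- function(z, y, subs, prods, des) {
  I_n <- tabulate(des$token_sample, des$N)
  cnk <- table(factor(des$token_sample, 1:des$N), factor(z, 1:des$K))
  s1 <- mean(apply(cnk / I_n, 1, max))          # sample label concentration
  slot_y <- rep(y, des$J)
  dl <- tabulate(slot_y, des$L)
  s2 <- max(dl) / sum(dl)                       # subnetwork slot load
  all_subs <- unlist(subs, use.names = FALSE)
  s3 <- max(tabulate(all_subs, des$C)) / length(all_subs)  # compound skew
  c(s1 = s1, s2 = s2, s3 = s3)
}

# One forward draw: parameters from the prior, then labels and compounds.
geweke_forward <- function(des, spec) {
  T_ <- length(des$token_sample)
  theta <- t(vapply(seq_len(des$N),
                    function(n) metabonet:::rdirichlet1(spec$K, spec$alpha_theta),
                    numeric(spec$K)))
  phi <- t(vapply(seq_len(spec$K),
                  function(k) metabonet:::rdirichlet1(spec$L, spec$alpha_phi),
                  numeric(spec$L)))
  delta <- t(vapply(seq_len(spec$L),
                    function(l) metabonet:::rdirichlet1(des$C, spec$alpha_delta),
                    numeric(des$C)))
  gamma <- t(vapply(seq_len(spec$L),
                    function(l) metabonet:::rdirichlet1(des$C, spec$alpha_gamma),
                    numeric(des$C)))
  z <- integer(T_); y <- integer(T_)
  subs <- vector("list", T_); prods <- vector("list", T_)
  for (t in seq_len(T_)) {
    z[t] <- sample.int(spec$K, 1, prob = theta[des$token_sample[t], ])
    y[t] <- sample.int(spec$L, 1, prob = phi[z[t], ])
    subs[[t]] <- sample.int(des$C, des$J[t], replace = TRUE,
                            prob = delta[y[t], ])
    prods[[t]] <- sample.int(des$C, des$J[t], replace = TRUE,
                             prob = gamma[y[t], ])
  }
  list(z = z, y = y, subs = subs, prods = prods)
}

# Exact draw of all compound slots given labels: per subnetwork, slots are
# exchangeable Dirichlet-multinomial draws, sampled by the urn scheme.
geweke_resample_data <- function(z, y, des, spec) {
  T_ <- length(z)
  subs <- vector("list", T_); prods <- vector("list", T_)
  for (l in seq_len(spec$L)) {
    for (side in c("sub", "prod")) {
      alpha <- if (side == "sub") spec$alpha_delta else spec$alpha_gamma
      toks <- which(y == l)
      n_slots <- sum(des$J[toks])
      counts <- numeric(des$C)
      draws <- integer(n_slots)
      for (i in seq_len(n_slots)) {
        draws[i] <- sample.int(des$C, 1, prob = counts + alpha)
        counts[draws[i]] <- counts[draws[i]] + 1
      }
      pos <- 0L
      for (t in toks) {
        v <- draws[seq_len(des$J[t]) + pos]
        pos <- pos + des$J[t]
        if (side == "sub") subs[[t]] <- v else prods[[t]] <- v
      }
    }
  }
  list(subs = subs, prods = prods)
}

# Package the current data as catalog/dataset (one reaction per token) and
# run `sweeps` Gibbs sweeps from the current labels.
geweke_gibbs_update <- function(z, y, subs, prods, des, spec, seed, sweeps) {
  T_ <- length(z)
  catalog <- reaction_catalog(sprintf("C%d", seq_len(des$C)),
                              sprintf("T%d", seq_len(T_)),
                              substrates = subs, products = prods,
                              pairing = "zip")
  dataset <- sample_dataset(sprintf("s%d", seq_len(des$N)),
                            sample = des$token_sample,
                            reaction = seq_len(T_),
                            count = rep(1L, T_), catalog = catalog)
  state <- state_with_labels(dataset, catalog, spec, z, y)
  state$rng_state <- local({
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    set.seed(seed)
    rs <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    rs
  })
  state <- gibbs_sweep(state, n_sweeps = sweeps)
  list(z = state$z, y = state$y)
}

# Batch-means standard error for an autocorrelated series.
batch_se <- function(x, n_batches = 40L) {
  b <- floor(length(x) / n_batches)
  means <- vapply(seq_len(n_batches), function(i) {
    mean(x[((i - 1L) * b + 1L):(i * b)])
  }, 0)
  stats::sd(means) / sqrt(n_batches)
}
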