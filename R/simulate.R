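#' Simulation parameters
#'
#' The generative process the simulator reproduces: per sample n a
#' metabosystem mixture theta_n ~ Dir(alpha_theta_gen); a reaction (token)
#' count ~ Poisson(`mean_reactions`), redrawn if zero; per token a
#' metabosystem Z ~ Cat(theta_n), a subnetwork Y ~ Cat(phi_Z), a pair count
#' J ~ Poisson(`mean_extra_pairs`) + 1, then J substrate compounds from
#' delta_Y and J product compounds from gamma_Y. The subnetwork-level
#' matrices are drawn once: phi rows ~ Dir(alpha_phi_gen), delta rows ~
#' Dir(alpha_delta_gen), gamma rows ~ Dir(alpha_gamma_gen).
#'
#' Defaults match the simulation design used to validate the inference
#' algorithm: samples carry on the order of 1000 reactions, each reaction
#' around 3 substrate-product pairs, and sparse mixing (alpha = 0.1 at the
#' sample and metabosystem levels). The substrate/product concentrations
#' default to 0.05 so each subnetwork concentrates on a handful of
#' compounds.
#'
#' @param N Number of samples.
#' @param C Number of compounds.
#' @param K Number of metabosystems.
#' @param L Number of subnetworks.
#' @param mean_reactions Poisson mean of the per-sample reaction count.
#' @param mean_extra_pairs Poisson mean of (pairs per reaction - 1); one is
#'   always added so every reaction has at least one pair.
#' @param alpha_theta_gen,alpha_phi_gen,alpha_delta_gen,alpha_gamma_gen
#'   Generating Dirichlet concentrations.
#' @param seed Integer seed; the whole simulation is deterministic given it.
#' @return An object of class `sim_params`.
#' @export
sim_params <- function(N = 40L, C = 100L, K = 3L, L = 10L,
                       mean_reactions = 1000, mean_extra_pairs = 2,
                       alpha_theta_gen = 0.1, alpha_phi_gen = 0.1,
                       alpha_delta_gen = 0.05, alpha_gamma_gen = 0.05,
                       seed = 1L) {
  for (x in list(N, C, K, L)) {
    if (!is_count(x)) stop_usage("N, C, K and L must be positive integers")
  }
  for (x in list(mean_reactions, mean_extra_pairs,
                 alpha_theta_gen, alpha_phi_gen,
                 alpha_delta_gen, alpha_gamma_gen)) {
    if (!is_positive_scalar(x)) {
      stop_usage("rates and generating concentrations must be positive")
    }
  }
  structure(list(N = as.integer(N), C = as.integer(C),
                 K = as.integer(K), L = as.integer(L),
                 mean_reactions = mean_reactions,
                 mean_extra_pairs = mean_extra_pairs,
                 alpha_theta_gen = alpha_theta_gen,
                 alpha_phi_gen = alpha_phi_gen,
                 alpha_delta_gen = alpha_delta_gen,
                 alpha_gamma_gen = alpha_gamma_gen,
                 seed = as.integer(seed)),
            class = "sim_params")
}

# One Dirichlet draw of dimension d; guards against the (vanishingly rare)
# all-zero gamma vector at very small concentrations.
rdirichlet1 <- function(d, alpha) {
  repeat {
    g <- stats::rgamma(d, shape = alpha, rate = 1)
    s <- sum(g)
    if (s > 0 && is.finite(s)) return(g / s)
  }
}

#' Simulate a dataset from the generative process
#'
#' Runs the generative process in [sim_params()] and returns the realised
#' catalog, abundance dataset, and ground truth. A reaction identity is the
#' (sorted substrate multiset, sorted product multiset) of a token's draws,
#' interned into the catalog on first occurrence; identical draws within a
#' sample accumulate multiplicity, so abundances look like real input.
#'
#' The single seed drives one random stream consumed in a fixed order:
#' theta rows (by sample), phi rows, delta rows, gamma rows, then per-sample
#' tokens in sample order (labels, pair counts, substrate draws, product
#' draws per token). Two runs with equal parameters are identical.
#'
#' @param params A [sim_params()] object.
#' @return A list with components `catalog` ([reaction_catalog()], zip
#'   pairing), `dataset` ([sample_dataset()]), and `truth` (list with
#'   `theta_true` (N x K), `phi_true` (K x L), `delta_true`, `gamma_true`
#'   (L x C), and per-token `z_true`, `y_true`, `token_sample`,
#'   `token_reaction` in generation order).
#' @export
simulate_dataset <- function(params) {
  stopifnot(inherits(params, "sim_params"))
  N <- params$N; C <- params$C; K <- params$K; L <- params$L
  old <- globalenv()$.Random.seed
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(params$seed)

  theta <- t(vapply(seq_len(N), function(n) rdirichlet1(K, params$alpha_theta_gen),
                    numeric(K)))
  phi <- t(vapply(seq_len(K), function(k) rdirichlet1(L, params$alpha_phi_gen),
                  numeric(L)))
  delta <- t(vapply(seq_len(L), function(l) rdirichlet1(C, params$alpha_delta_gen),
                    numeric(C)))
  gamma <- t(vapply(seq_len(L), function(l) rdirichlet1(C, params$alpha_gamma_gen),
                    numeric(C)))
  dim(theta) <- c(N, K); dim(phi) <- c(K, L)
  dim(delta) <- c(L, C); dim(gamma) <- c(L, C)

  key_env <- new.env(hash = TRUE, parent = emptyenv())
  rx_subs <- list(); rx_prods <- list()
  n_rx <- 0L

  tok_sample <- integer(0); tok_rx <- integer(0)
  tok_z <- integer(0); tok_y <- integer(0)

  for (n in seq_len(N)) {
    repeat {
      I_n <- stats::rpois(1L, params$mean_reactions)
      if (I_n >= 1L) break
    }
    z <- integer(I_n); y <- integer(I_n); rx <- integer(I_n)
    for (i in seq_len(I_n)) {
      z[i] <- sample.int(K, 1L, prob = theta[n, ])
      y[i] <- sample.int(L, 1L, prob = phi[z[i], ])
      J <- stats::rpois(1L, params$mean_extra_pairs) + 1L
      subs <- sort(sample.int(C, J, replace = TRUE, prob = delta[y[i], ]))
      prods <- sort(sample.int(C, J, replace = TRUE, prob = gamma[y[i], ]))
      key <- paste(paste(subs, collapse = ","), paste(prods, collapse = ","),
                   sep = "|")
      id <- key_env[[key]]
      if (is.null(id)) {
        n_rx <- n_rx + 1L
        id <- n_rx
        key_env[[key]] <- id
        rx_subs[[id]] <- subs
        rx_prods[[id]] <- prods
      }
      rx[i] <- id
    }
    tok_sample <- c(tok_sample, rep(n, I_n))
    tok_rx <- c(tok_rx, rx)
    tok_z <- c(tok_z, z)
    tok_y <- c(tok_y, y)
  }

  catalog <- reaction_catalog(
    compound_ids = sprintf("C%05d", seq_len(C)),
    reaction_ids = sprintf("RX%05d", seq_len(n_rx)),
    substrates = rx_subs, products = rx_prods, pairing = "zip")

  agg <- stats::aggregate(
    list(count = rep(1L, length(tok_sample))),
    by = list(sample = tok_sample, reaction = tok_rx), FUN = sum)
  agg <- agg[order(agg$sample, agg$reaction), ]
  dataset <- sample_dataset(sprintf("S%03d", seq_len(N)),
                            sample = agg$sample, reaction = agg$reaction,
                            count = agg$count, catalog = catalog)

  list(catalog = catalog, dataset = dataset,
       truth = list(theta_true = theta, phi_true = phi,
                    delta_true = delta, gamma_true = gamma,
                    z_true = tok_z, y_true = tok_y,
                    token_sample = tok_sample, token_reaction = tok_rx))
}

#' Full factorial simulation grid
#'
#' The validation design: N in {40, 60, 80, 100} x C in {100, 500, 1000} x
#' K in {3, 5} x L in {10, 20, 50} x generating alpha in
#' {0.05, 0.10, 0.20} (the same alpha at the sample and metabosystem
#' levels), 216 cells, each with mean_reactions = 1000 and
#' mean_extra_pairs = 2 and a distinct deterministic seed.
#'
#' @param base_seed Offset added to each cell's index to form its seed.
#' @return A list of [sim_params()] objects, one per grid cell.
#' @export
simulation_grid <- function(base_seed = 1000L) {
  grid <- expand.grid(N = c(40L, 60L, 80L, 100L),
                      C = c(100L, 500L, 1000L),
                      K = c(3L, 5L),
                      L = c(10L, 20L, 50L),
                      alpha = c(0.05, 0.10, 0.20),
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    sim_params(N = grid$N[i], C = grid$C[i], K = grid$K[i], L = grid$L[i],
               mean_reactions = 1000, mean_extra_pairs = 2,
               alpha_theta_gen = grid$alpha[i], alpha_phi_gen = grid$alpha[i],
               seed = base_seed + i)
  })
}
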