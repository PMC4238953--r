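# Collapsed Gibbs sampling over per-token (metabosystem, subnetwork) labels,
# with theta, phi, delta and gamma integrated out. The compiled core lives in
# src/gibbs.cpp; this file owns state construction, RNG bookkeeping and the
# run loop.

# Flattened per-reaction slot arrays consumed by the compiled core. Each
# reaction's pairs contribute one substrate slot and one product slot per
# pair; sub_rep/prod_rep give, per slot, how many earlier slots of the same
# reaction carry the same compound (ascending-factorial predictive offsets).
prepare_token_data <- function(catalog) {
  rep_counts <- function(v) {
    if (length(v) <= 1L) return(integer(length(v)))
    as.integer(stats::ave(rep(1L, length(v)), v, FUN = cumsum) - 1L)
  }
  sub_flat <- unlist(catalog$sub_slots, use.names = FALSE)
  prod_flat <- unlist(catalog$prod_slots, use.names = FALSE)
  list(slot_off = c(0L, cumsum(catalog$J)),
       sub_flat = sub_flat - 1L,
       sub_rep = unlist(lapply(catalog$sub_slots, rep_counts),
                        use.names = FALSE),
       prod_flat = prod_flat - 1L,
       prod_rep = unlist(lapply(catalog$prod_slots, rep_counts),
                         use.names = FALSE))
}

count_tables <- function(z, y, token_sample, token_reaction, tdata,
                         N, K, L, C) {
  count_nk <- matrix(tabulate((z - 1L) * N + token_sample, N * K), N, K)
  count_kl <- matrix(tabulate((y - 1L) * K + z, K * L), K, L)
  J <- diff(tdata$slot_off)
  slot_token <- rep(seq_along(z), J[token_reaction])
  sl_y <- y[slot_token]
  sub_c <- unlist(lapply(token_reaction, function(r) {
    tdata$sub_flat[(tdata$slot_off[r] + 1L):tdata$slot_off[r + 1L]]
  }), use.names = FALSE) + 1L
  prod_c <- unlist(lapply(token_reaction, function(r) {
    tdata$prod_flat[(tdata$slot_off[r] + 1L):tdata$slot_off[r + 1L]]
  }), use.names = FALSE) + 1L
  dcount_lc <- matrix(tabulate((sub_c - 1L) * L + sl_y, L * C), L, C)
  gcount_lc <- matrix(tabulate((prod_c - 1L) * L + sl_y, L * C), L, C)
  storage.mode(count_nk) <- "integer"
  storage.mode(count_kl) <- "integer"
  storage.mode(dcount_lc) <- "integer"
  storage.mode(gcount_lc) <- "integer"
  list(count_nk = count_nk, count_kl = count_kl,
       count_k = as.integer(rowSums(count_kl)),
       dcount_lc = dcount_lc, dcount_l = as.integer(rowSums(dcount_lc)),
       gcount_lc = gcount_lc, gcount_l = as.integer(rowSums(gcount_lc)))
}

with_state_rng <- function(state, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  assign(".Random.seed", state$rng_state, envir = globalenv())
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  res <- force(expr)
  list(value = res, rng_state = get(".Random.seed", globalenv()))
}

#' Initialize an assignment state
#'
#' Expands the dataset into individual tokens (a reaction of multiplicity m
#' becomes m independently labelled tokens, visited in dataset row order),
#' draws each token's (metabosystem, subnetwork) label uniformly at random,
#' and builds the sufficient-statistic count tables the collapsed sampler
#' updates.
#'
#' @param dataset A [sample_dataset()].
#' @param catalog Its [reaction_catalog()].
#' @param spec A [model_spec()].
#' @param seed Integer seed for the label draw; the state carries its own
#'   random stream thereafter, so runs are reproducible.
#' @return An object of class `assignment_state`: per-token labels `z`, `y`,
#'   token indexing, the count tables (`count_nk`, `count_kl`, `count_k`,
#'   `dcount_lc`, `dcount_l`, `gcount_lc`, `gcount_l`), the flattened
#'   slot arrays, and `rng_state`.
#' @export
init_state <- function(dataset, catalog, spec, seed = 1L) {
  stopifnot(inherits(dataset, "sample_dataset"),
            inherits(catalog, "reaction_catalog"),
            inherits(spec, "model_spec"))
  if (n_tokens(dataset) < 1L) stop_usage("dataset has no tokens")
  N <- n_samples(dataset)
  C <- n_compounds(catalog)
  K <- spec$K; L <- spec$L

  token_sample <- rep(dataset$counts$sample, dataset$counts$count)
  token_reaction <- rep(dataset$counts$reaction, dataset$counts$count)
  T_ <- length(token_sample)

  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  }
  set.seed(seed)
  z <- sample.int(K, T_, replace = TRUE)
  y <- sample.int(L, T_, replace = TRUE)
  rng_state <- get(".Random.seed", globalenv())
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())

  tdata <- prepare_token_data(catalog)
  counts <- count_tables(z, y, token_sample, token_reaction, tdata,
                         N, K, L, C)
  structure(
    c(list(z = z, y = y,
           token_sample = token_sample, token_reaction = token_reaction,
           N = N, C = C, spec = spec, tdata = tdata,
           rng_state = rng_state),
      counts),
    class = "assignment_state")
}

#' @export
print.assignment_state <- function(x, ...) {
  cat(sprintf("<assignment_state> %d tokens, N = %d, K = %d, L = %d, C = %d\n",
              length(x$z), x$N, x$spec$K, x$spec$L, x$C))
  invisible(x)
}

#' Full conditional over (metabosystem, subnetwork) for one token
#'
#' Computes the collapsed conditional distribution of a single token's joint
#' label given all other labels: the token's entire contribution (one unit
#' in the sample and metabosystem tables, J slots in each compound table) is
#' removed, and entry (k, l) is proportional to
#' `(count_nk + a_t) * (count_kl + a_p)/(count_k + L a_p)` times the
#' Dirichlet-multinomial predictive of the token's J substrate slots under
#' delta_l and its J product slots under gamma_l, taken in slot order with
#' within-token ascending-factorial increments. The table is normalized to
#' sum to one.
#'
#' @param state An [init_state()] assignment state (consistent, with the
#'   token's labels still counted; they are excluded internally).
#' @param token Token index in `[1, total tokens]`.
#' @param log_space `NULL` (auto: log space when the token has more than 32
#'   pairs), `TRUE`, or `FALSE`. Both paths agree to near machine precision.
#' @return A K x L matrix of probabilities summing to 1.
#' @export
conditional_table <- function(state, token, log_space = NULL) {
  stopifnot(inherits(state, "assignment_state"))
  if (!is_count(token) || token > length(state$z)) {
    stop_usage("token index out of range")
  }
  mode <- if (is.null(log_space)) 0L else if (isTRUE(log_space)) 2L else 1L
  s <- state$spec
  cpp_conditional_table(as.integer(token), state$z, state$y,
                        state$token_sample, state$token_reaction,
                        state$tdata$slot_off, state$tdata$sub_flat,
                        state$tdata$sub_rep, state$tdata$prod_flat,
                        state$tdata$prod_rep, state$count_nk, state$count_kl,
                        state$count_k, state$dcount_lc, state$dcount_l,
                        state$gcount_lc, state$gcount_l, state$C,
                        s$alpha_theta, s$alpha_phi, s$alpha_delta,
                        s$alpha_gamma, mode)
}

#' Run Gibbs sweeps over all tokens
#'
#' One sweep visits every token exactly once (by default in token order:
#' sample index, then token index within sample), removes its contribution
#' from the count tables, draws a new joint (z, y) label from
#' [conditional_table()] by inverse CDF over the flattened K x L table
#' (consuming exactly one uniform deviate per token), and restores the
#' counts. The state's own random stream is used and advanced.
#'
#' @param state An [init_state()] assignment state.
#' @param n_sweeps Number of full sweeps to run.
#' @param order Optional permutation of token indices giving the visit
#'   order within each sweep.
#' @return The updated `assignment_state`.
#' @export
gibbs_sweep <- function(state, n_sweeps = 1L, order = NULL) {
  stopifnot(inherits(state, "assignment_state"))
  if (!is_count(n_sweeps)) stop_usage("n_sweeps must be a positive integer")
  T_ <- length(state$z)
  if (is.null(order)) {
    order <- seq_len(T_)
  } else {
    order <- as.integer(order)
    if (length(order) != T_ || anyDuplicated(order) ||
        any(order < 1L | order > T_)) {
      stop_usage("order must be a permutation of the token indices")
    }
  }
  s <- state$spec
  res <- with_state_rng(state, cpp_sweeps(
    state$z, state$y, state$token_sample, state$token_reaction,
    state$tdata$slot_off, state$tdata$sub_flat, state$tdata$sub_rep,
    state$tdata$prod_flat, state$tdata$prod_rep, state$count_nk,
    state$count_kl, state$count_k, state$dcount_lc, state$dcount_l,
    state$gcount_lc, state$gcount_l, state$C, s$alpha_theta, s$alpha_phi,
    s$alpha_delta, s$alpha_gamma, as.integer(n_sweeps), order, 32L))
  out <- res$value
  state[names(out)] <- out
  state$rng_state <- res$rng_state
  state
}

#' Log collapsed joint probability of a state
#'
#' The log of P(labels, substrate-product pairs | concentrations) with all
#' Dirichlet parameters integrated out: a product of Dirichlet-multinomial
#' normalizing constants at the four levels of the model.
#'
#' @param state An [init_state()] assignment state.
#' @return A finite scalar.
#' @export
log_joint <- function(state) {
  stopifnot(inherits(state, "assignment_state"))
  s <- state$spec
  cpp_log_joint(state$count_nk, state$count_kl, state$dcount_lc,
                state$gcount_lc, s$alpha_theta, s$alpha_phi, s$alpha_delta,
                s$alpha_gamma)
}

#' Run the collapsed Gibbs sampler
#'
#' Initializes labels uniformly at random, runs `burn_in` sweeps, then
#' retains one draw every `lag` sweeps until `n_retained` draws are
#' collected. Each retained draw stores the label snapshot and the per-draw
#' theta and phi estimates (relative assignment frequencies; see
#' [theta_from_draw()]).
#'
#' @param dataset A [sample_dataset()].
#' @param catalog Its [reaction_catalog()].
#' @param spec A [model_spec()].
#' @param schedule A [sampler_schedule()]; its seed drives initialization
#'   and all sweeps.
#' @param progress_every Log (via [message()]) the sweep number and log
#'   collapsed joint probability every this many retained draws; 0 disables.
#' @param store_labels Keep per-draw label snapshots (needed for the
#'   compound-level and reaction-profile summaries). Disable to save memory
#'   when only theta/phi are of interest.
#' @return An object of class `gibbs_fit`: `draws` (list of `list(z, y)` or
#'   `NULL`s), `theta` (N x K x n_retained), `phi` (K x L x n_retained),
#'   `log_joint` per draw, the final `state`, and the inputs.
#' @export
run_sampler <- function(dataset, catalog, spec, schedule = sampler_schedule(),
                        progress_every = 0L, store_labels = TRUE) {
  stopifnot(inherits(schedule, "sampler_schedule"))
  state <- init_state(dataset, catalog, spec, seed = schedule$seed)
  N <- n_samples(dataset)
  if (schedule$burn_in > 0L) {
    state <- gibbs_sweep(state, n_sweeps = schedule$burn_in)
  }
  D <- schedule$n_retained
  theta <- array(NA_real_, c(N, spec$K, D),
                 dimnames = list(dataset$sample_ids,
                                 paste0("M", seq_len(spec$K)), NULL))
  phi <- array(NA_real_, c(spec$K, spec$L, D),
               dimnames = list(paste0("M", seq_len(spec$K)),
                               paste0("SN", seq_len(spec$L)), NULL))
  lj <- numeric(D)
  draws <- vector("list", D)
  for (d in seq_len(D)) {
    state <- gibbs_sweep(state, n_sweeps = schedule$lag)
    theta[, , d] <- state$count_nk / dataset$I
    phi[, , d] <- phi_from_counts(state$count_kl, state$count_k,
                                  warn_empty = FALSE)
    lj[d] <- log_joint(state)
    if (store_labels) draws[[d]] <- list(z = state$z, y = state$y)
    if (progress_every > 0L && d %% progress_every == 0L) {
      message(sprintf("draw %d/%d (sweep %d): log joint %.2f", d, D,
                      schedule$burn_in + d * schedule$lag, lj[d]))
    }
  }
  structure(list(draws = draws, theta = theta, phi = phi, log_joint = lj,
                 state = state, spec = spec, schedule = schedule,
                 dataset = dataset, catalog = catalog),
            class = "gibbs_fit")
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat(sprintf(
    "<gibbs_fit> %d retained draws (burn-in %d, lag %d), K = %d, L = %d, final log joint %.2f\n",
    x$schedule$n_retained, x$schedule$burn_in, x$schedule$lag, x$spec$K,
    x$spec$L, x$log_joint[length(x$log_joint)]))
  invisible(x)
}
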