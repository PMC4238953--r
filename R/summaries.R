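# Posterior estimates from retained Gibbs draws. theta and phi follow the
# relative-frequency estimator (unsmoothed); the compound-level distributions
# delta/gamma and the per-subnetwork reaction profile are prior-smoothed so
# downstream divergence measures always see full-support distributions.

phi_from_counts <- function(count_kl, count_k, warn_empty = TRUE) {
  K <- nrow(count_kl); L <- ncol(count_kl)
  phi <- count_kl / ifelse(count_k == 0L, 1, count_k)
  empty <- count_k == 0L
  if (any(empty)) {
    phi[empty, ] <- 1 / L
    if (warn_empty) {
      warning(sprintf("metabosystem(s) %s hold no tokens; phi row set uniform",
                      paste(which(empty), collapse = ", ")))
    }
  }
  phi
}

#' Per-draw estimate of the sample-level mixture weights
#'
#' For one retained draw, row n is the relative frequency among sample n's
#' tokens of assignment to each metabosystem: `count_nk[n, ] / I_n`.
#'
#' @param draw A `list(z, y)` label snapshot (one element of a `gibbs_fit`'s
#'   `draws`), with labels in dataset token order.
#' @param dataset The [sample_dataset()] that was fitted.
#' @param spec The [model_spec()] used.
#' @return An N x K matrix with rows summing to 1.
#' @export
theta_from_draw <- function(draw, dataset, spec) {
  N <- n_samples(dataset)
  token_sample <- rep(dataset$counts$sample, dataset$counts$count)
  cnk <- matrix(tabulate((draw$z - 1L) * N + token_sample, N * spec$K),
                N, spec$K)
  cnk / dataset$I
}

#' Per-draw estimate of the metabosystem-level mixture weights
#'
#' Row k is the relative frequency of subnetwork assignments among all
#' tokens assigned to metabosystem k, pooled across samples. A metabosystem
#' holding no tokens gets a uniform row (with a warning).
#'
#' @inheritParams theta_from_draw
#' @return A K x L matrix with rows summing to 1.
#' @export
phi_from_draw <- function(draw, dataset, spec) {
  K <- spec$K; L <- spec$L
  ckl <- matrix(tabulate((draw$y - 1L) * K + draw$z, K * L), K, L)
  phi_from_counts(ckl, rowSums(ckl))
}

#' Posterior summary of a fitted model
#'
#' Averages the per-draw estimates over retained draws: `theta_mean` and
#' `phi_mean` are arithmetic means of the relative-frequency estimates;
#' `delta_mean`/`gamma_mean` rows are the prior-smoothed compound
#' frequencies `(dcount_lc + a_d) / (dcount_l + C a_d)` averaged over draws;
#' `subnetwork_reaction_profile` row l is the smoothed relative frequency,
#' over catalog reactions, of tokens assigned to subnetwork l, averaged over
#' draws.
#'
#' @param fit A `gibbs_fit` from [run_sampler()] with stored labels.
#' @param alpha_r Smoothing concentration for the reaction profile; defaults
#'   to the fit's `alpha_delta`.
#' @param diagnose_switching Compare consecutive draws' phi rows by their
#'   best-match permutation and warn if any is non-identity (a symptom of
#'   within-chain label switching). Only attempted for K <= 8.
#' @return An object of class `posterior_summary` with the matrices above
#'   (all rows simplexes), plus the per-draw `theta_draws`/`phi_draws`
#'   trajectories and chain metadata.
#' @export
summarize_posterior <- function(fit, alpha_r = NULL,
                                diagnose_switching = TRUE) {
  stopifnot(inherits(fit, "gibbs_fit"))
  if (length(fit$draws) == 0L || is.null(fit$draws[[1]])) {
    stop_usage("fit has no stored label draws; rerun with store_labels = TRUE")
  }
  spec <- fit$spec
  dataset <- fit$dataset
  catalog <- fit$catalog
  K <- spec$K; L <- spec$L
  C <- n_compounds(catalog)
  R <- n_reactions(catalog)
  D <- length(fit$draws)
  if (is.null(alpha_r)) alpha_r <- spec$alpha_delta

  token_reaction <- rep(dataset$counts$reaction, dataset$counts$count)
  J <- catalog$J
  slot_token <- rep(seq_along(token_reaction), J[token_reaction])
  slot_sub <- unlist(catalog$sub_slots[token_reaction], use.names = FALSE)
  slot_prod <- unlist(catalog$prod_slots[token_reaction], use.names = FALSE)

  delta_acc <- matrix(0, L, C)
  gamma_acc <- matrix(0, L, C)
  prof_acc <- matrix(0, L, R)
  for (d in seq_len(D)) {
    y <- fit$draws[[d]]$y
    sl_y <- y[slot_token]
    dlc <- matrix(tabulate((slot_sub - 1L) * L + sl_y, L * C), L, C)
    glc <- matrix(tabulate((slot_prod - 1L) * L + sl_y, L * C), L, C)
    delta_acc <- delta_acc + (dlc + spec$alpha_delta) /
      (rowSums(dlc) + C * spec$alpha_delta)
    gamma_acc <- gamma_acc + (glc + spec$alpha_gamma) /
      (rowSums(glc) + C * spec$alpha_gamma)
    clr <- matrix(tabulate((token_reaction - 1L) * L + y, L * R), L, R)
    prof_acc <- prof_acc + (clr + alpha_r) / (rowSums(clr) + R * alpha_r)
  }

  theta_mean <- apply(fit$theta, c(1, 2), mean)
  phi_mean <- apply(fit$phi, c(1, 2), mean)
  dimnames(theta_mean) <- dimnames(fit$theta)[1:2]
  dimnames(phi_mean) <- dimnames(fit$phi)[1:2]
  sn <- paste0("SN", seq_len(L))
  delta_mean <- delta_acc / D
  gamma_mean <- gamma_acc / D
  profile <- prof_acc / D
  dimnames(delta_mean) <- list(sn, catalog$compound_ids)
  dimnames(gamma_mean) <- list(sn, catalog$compound_ids)
  dimnames(profile) <- list(sn, catalog$reaction_ids)

  if (diagnose_switching && K >= 2L && K <= 8L && D >= 2L) {
    for (d in 2:D) {
      p <- match_components(fit$phi[, , d - 1, drop = FALSE][, , 1],
                            fit$phi[, , d, drop = FALSE][, , 1],
                            method = "l1")
      if (!identical(p, seq_len(K))) {
        warning(sprintf(
          "possible within-chain label switching between draws %d and %d",
          d - 1L, d))
        break
      }
    }
  }

  structure(list(theta_mean = theta_mean, phi_mean = phi_mean,
                 delta_mean = delta_mean, gamma_mean = gamma_mean,
                 subnetwork_reaction_profile = profile,
                 theta_draws = fit$theta, phi_draws = fit$phi,
                 log_joint = fit$log_joint, spec = spec,
                 schedule = fit$schedule, alpha_r = alpha_r),
            class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat(sprintf(
    "<posterior_summary> %d samples x %d metabosystems x %d subnetworks (%d draws)\n",
    nrow(x$theta_mean), x$spec$K, x$spec$L, dim(x$theta_draws)[3]))
  invisible(x)
}

#' Write the posterior summary matrices to a directory
#'
#' Writes `theta.tsv`, `phi.tsv`, `delta.tsv`, `gamma.tsv` and
#' `subnetwork_reactions.tsv` in [write_result_matrix()] format.
#'
#' @param summary A [summarize_posterior()] result.
#' @param dir Output directory (created if needed).
#' @export
write_summary <- function(summary, dir) {
  stopifnot(inherits(summary, "posterior_summary"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  w <- function(m, file) {
    write_result_matrix(m, rownames(m), colnames(m), file.path(dir, file))
  }
  w(summary$theta_mean, "theta.tsv")
  w(summary$phi_mean, "phi.tsv")
  w(summary$delta_mean, "delta.tsv")
  w(summary$gamma_mean, "gamma.tsv")
  w(summary$subnetwork_reaction_profile, "subnetwork_reactions.tsv")
  invisible(NULL)
}
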