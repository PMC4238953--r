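# Downstream summaries of a fitted decomposition: metabosystem reaction
# compositions, Jensen-Shannon divergence profiling, and the extraction of
# principal, discriminatory and core subnetworks and principal reactions.

#' Jensen-Shannon divergence between two distributions
#'
#' `JSD(p, q) = KL(p || m)/2 + KL(q || m)/2` with `m = (p + q)/2`, using the
#' `0 * log(0/x) = 0` convention. With the default base-2 logarithm the
#' divergence lies in `[0, 1]` and equals 1 exactly for distributions with
#' disjoint support.
#'
#' @param p,q Numeric simplex vectors of equal length (each summing to 1
#'   within 1e-6).
#' @param base Logarithm base (2 by default).
#' @return A non-negative scalar.
#' @export
jsd <- function(p, q, base = 2) {
  if (length(p) != length(q)) stop_usage("p and q must have equal length")
  if (any(p < -1e-12) || any(q < -1e-12) ||
      abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    stop_usage("p and q must be probability vectors summing to 1")
  }
  m <- (p + q) / 2
  kl <- function(a) {
    i <- a > 0
    sum(a[i] * (log(a[i], base = base) - log(m[i], base = base)))
  }
  (kl(p) + kl(q)) / 2
}

#' Reaction composition of each metabosystem
#'
#' Mixes the per-subnetwork reaction profiles by the metabosystem's
#' subnetwork weights: row k is
#' `sum_l phi_mean[k, l] * subnetwork_reaction_profile[l, ]`, a
#' distribution over the catalog reactions that characterizes metabosystem
#' k independently of the (arbitrary) subnetwork labels, and is therefore
#' the right space in which to compare metabosystems across runs and
#' across L values.
#'
#' @param summary A [summarize_posterior()] result.
#' @return A K x R matrix with simplex rows (class `metabosystem_profile`).
#' @export
reaction_composition <- function(summary) {
  stopifnot(inherits(summary, "posterior_summary"))
  comp <- summary$phi_mean %*% summary$subnetwork_reaction_profile
  structure(comp, class = c("metabosystem_profile", class(comp)))
}

#' Pairwise divergence matrix over tagged metabosystem profiles
#'
#' Stacks the reaction-composition rows of several runs (e.g. fits with
#' different L) and computes all pairwise Jensen-Shannon divergences. The
#' row/column labels `"<run>:M<k>"` let within- and between-metabosystem
#' blocks be assembled into the usual heat-map layout.
#'
#' @param profiles A named list of K_i x R composition matrices sharing one
#'   reaction catalog (equal columns).
#' @param base Logarithm base passed to [jsd()].
#' @return A symmetric matrix with zero diagonal.
#' @export
divergence_matrix <- function(profiles, base = 2) {
  if (!is.list(profiles) || length(profiles) == 0L) {
    stop_usage("profiles must be a non-empty list of composition matrices")
  }
  if (is.null(names(profiles))) {
    names(profiles) <- paste0("run", seq_along(profiles))
  }
  R <- ncol(profiles[[1]])
  cols <- colnames(profiles[[1]])
  for (p in profiles) {
    if (ncol(p) != R || !identical(colnames(p), cols)) {
      stop_usage("all profiles must share one reaction catalog")
    }
  }
  rows <- do.call(rbind, lapply(unname(profiles), as.matrix))
  labels <- unlist(lapply(seq_along(profiles), function(i) {
    paste0(names(profiles)[i], ":M", seq_len(nrow(profiles[[i]])))
  }), use.names = FALSE)
  n <- nrow(rows)
  m <- matrix(0, n, n, dimnames = list(labels, labels))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1L)) {
      m[i, j] <- m[j, i] <- jsd(rows[i, ], rows[j, ], base = base)
    }
  }
  m
}

#' Principal subnetworks
#'
#' A subnetwork is principal for metabosystem k when its mixture weight
#' exceeds 2/L there (strictly); the principal subnetworks of a dataset are
#' the union over metabosystems. With L subnetworks a uniform weight is
#' 1/L, so the 2/L cutoff keeps subnetworks carrying at least twice the
#' uniform share.
#'
#' @param phi_mean K x L matrix of posterior metabosystem-subnetwork
#'   weights.
#' @return A list with `per_metabosystem` (list of integer subnetwork index
#'   vectors), `union` (sorted integer vector) and `threshold` (2/L).
#' @export
principal_subnetworks <- function(phi_mean) {
  phi_mean <- as.matrix(phi_mean)
  L <- ncol(phi_mean)
  thr <- 2 / L
  per <- lapply(seq_len(nrow(phi_mean)), function(k) {
    which(phi_mean[k, ] > thr)
  })
  names(per) <- rownames(phi_mean)
  list(per_metabosystem = per,
       union = sort(unique(unlist(per, use.names = FALSE))),
       threshold = thr)
}

#' Relative membership score of a subnetwork in a metabosystem
#'
#' The absolute log-ratio of subnetwork l's membership in metabosystem k to
#' its largest membership among the other metabosystems:
#' `|log(phi[k, l] / max_{k' != k} phi[k', l])|` (natural logarithm).
#' Weights are floored at `eps` before the ratio so empty components yield
#' large finite scores rather than infinities.
#'
#' @inheritParams principal_subnetworks
#' @param k Metabosystem index.
#' @param l Subnetwork index.
#' @param eps Floor applied to the weights (default 1e-12).
#' @return A non-negative scalar.
#' @export
membership_score <- function(phi_mean, k, l, eps = 1e-12) {
  phi_mean <- as.matrix(phi_mean)
  if (nrow(phi_mean) < 2L) {
    stop_usage("membership scores require at least two metabosystems")
  }
  col <- pmax(phi_mean[, l], eps)
  abs(log(col[k] / max(col[-k])))
}

# All membership scores at once (K x L).
membership_scores <- function(phi_mean, eps = 1e-12) {
  phi_mean <- as.matrix(phi_mean)
  K <- nrow(phi_mean); L <- ncol(phi_mean)
  s <- matrix(0, K, L, dimnames = dimnames(phi_mean))
  for (l in seq_len(L)) {
    for (k in seq_len(K)) s[k, l] <- membership_score(phi_mean, k, l, eps)
  }
  s
}

#' Discriminatory subnetworks
#'
#' Subnetwork l is discriminatory for metabosystem k when l is principal
#' for at least one metabosystem and its [membership_score()] for k reaches
#' `score_threshold`. The default threshold `log(2)` requires at least a
#' two-fold weight ratio between k and the nearest other metabosystem.
#'
#' @inheritParams principal_subnetworks
#' @param score_threshold Minimum membership score (natural-log scale).
#' @param eps Floor passed to [membership_score()].
#' @return A K x L logical matrix of flags.
#' @export
discriminatory_subnetworks <- function(phi_mean, score_threshold = log(2),
                                       eps = 1e-12) {
  phi_mean <- as.matrix(phi_mean)
  princ <- principal_subnetworks(phi_mean)
  is_principal_any <- seq_len(ncol(phi_mean)) %in% princ$union
  flags <- membership_scores(phi_mean, eps) >= score_threshold
  flags & rep(is_principal_any, each = nrow(phi_mean))
}

#' Core subnetworks
#'
#' Core subnetworks are abundant in every metabosystem and distinguish
#' none: subnetwork l is core when `phi_mean[k, l] > 2/L` for every k and l
#' is discriminatory for no metabosystem. By construction the core and
#' discriminatory sets are disjoint.
#'
#' @inheritParams discriminatory_subnetworks
#' @return A sorted integer vector of subnetwork indices.
#' @export
core_subnetworks <- function(phi_mean, score_threshold = log(2),
                             eps = 1e-12) {
  phi_mean <- as.matrix(phi_mean)
  L <- ncol(phi_mean)
  abundant_everywhere <- colSums(phi_mean > 2 / L) == nrow(phi_mean)
  disc <- discriminatory_subnetworks(phi_mean, score_threshold, eps)
  which(abundant_everywhere & colSums(disc) == 0L)
}

#' Principal reactions of each subnetwork
#'
#' Filters each subnetwork's reaction profile at 2/R (inclusive), where R
#' is the number of unique reactions observed in the dataset, and reports
#' the retained reactions sorted by descending probability together with
#' the cumulative probability they carry.
#'
#' @param profile L x R matrix of per-subnetwork reaction probabilities
#'   (rows are simplexes), e.g. the `subnetwork_reaction_profile` of a
#'   [summarize_posterior()] result.
#' @param r_unique Number of distinct reactions in the dataset (defaults to
#'   `ncol(profile)`).
#' @return A list with `threshold` (2/R) and `per_subnetwork`, a list of
#'   data frames (`reaction`, `probability`, `cumulative`), one per row of
#'   `profile`.
#' @export
principal_reactions <- function(profile, r_unique = ncol(profile)) {
  profile <- as.matrix(profile)
  if (!is_count(r_unique)) stop_usage("r_unique must be a positive integer")
  thr <- 2 / r_unique
  rx <- colnames(profile)
  if (is.null(rx)) rx <- paste0("R", seq_len(ncol(profile)))
  per <- lapply(seq_len(nrow(profile)), function(l) {
    keep <- which(profile[l, ] >= thr)
    keep <- keep[order(profile[l, keep], decreasing = TRUE)]
    data.frame(reaction = rx[keep], probability = profile[l, keep],
               cumulative = cumsum(profile[l, keep]),
               row.names = NULL)
  })
  names(per) <- rownames(profile)
  list(threshold = thr, per_subnetwork = per)
}

#' Combined per-subnetwork report
#'
#' One row per (subnetwork, metabosystem): membership weight, principal
#' flag, membership score, discriminatory flag; plus the core subnetwork
#' set as an attribute-style list entry.
#'
#' @inheritParams discriminatory_subnetworks
#' @return A list with `table` (long data frame), `core` (integer vector)
#'   and `principal_union`.
#' @export
subnetwork_report <- function(phi_mean, score_threshold = log(2),
                              eps = 1e-12) {
  phi_mean <- as.matrix(phi_mean)
  K <- nrow(phi_mean); L <- ncol(phi_mean)
  princ <- principal_subnetworks(phi_mean)
  scores <- membership_scores(phi_mean, eps)
  disc <- discriminatory_subnetworks(phi_mean, score_threshold, eps)
  tab <- data.frame(
    subnetwork = rep(seq_len(L), each = K),
    metabosystem = rep(seq_len(K), times = L),
    membership = as.vector(phi_mean),
    principal = as.vector(phi_mean > princ$threshold),
    score = as.vector(scores),
    discriminatory = as.vector(disc))
  list(table = tab,
       core = core_subnetworks(phi_mean, score_threshold, eps),
       principal_union = princ$union)
}

#' Bipartite edge list of a subnetwork
#'
#' Exports subnetwork l as a reaction-compound bipartite graph restricted
#' to its principal reactions: one edge per substrate (compound ->
#' reaction) and per product (reaction -> compound), suitable for GraphML
#' conversion or plotting (reactions as squares, compounds as circles).
#'
#' @param summary A [summarize_posterior()] result.
#' @param catalog The fitted [reaction_catalog()].
#' @param l Subnetwork index.
#' @param currency Optional character vector of currency compound IDs;
#'   matching edges are flagged in the `currency` column rather than
#'   removed.
#' @return A data frame with columns `from`, `to`, `from_type`, `to_type`,
#'   `reaction_probability`, `currency`.
#' @export
subnetwork_edgelist <- function(summary, catalog, l, currency = NULL) {
  stopifnot(inherits(summary, "posterior_summary"),
            inherits(catalog, "reaction_catalog"))
  profile <- summary$subnetwork_reaction_profile
  pr <- principal_reactions(profile)$per_subnetwork[[l]]
  if (nrow(pr) == 0L) {
    return(data.frame(from = character(0), to = character(0),
                      from_type = character(0), to_type = character(0),
                      reaction_probability = numeric(0),
                      currency = logical(0)))
  }
  ridx <- match(pr$reaction, catalog$reaction_ids)
  rows <- lapply(seq_along(ridx), function(i) {
    r <- ridx[i]
    subs <- catalog$compound_ids[unique(catalog$substrates[[r]])]
    prods <- catalog$compound_ids[unique(catalog$products[[r]])]
    rbind(
      data.frame(from = subs, to = pr$reaction[i], from_type = "compound",
                 to_type = "reaction", reaction_probability = pr$probability[i],
                 currency = subs %in% currency),
      data.frame(from = pr$reaction[i], to = prods, from_type = "reaction",
                 to_type = "compound", reaction_probability = pr$probability[i],
                 currency = prods %in% currency))
  })
  do.call(rbind, rows)
}
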