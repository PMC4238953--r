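# Optimal component matching. Mixture-component indices are arbitrary
# (label switching), so components from different runs, different L values,
# or simulation ground truth are coordinated by minimum-cost assignment on
# a divergence between component profiles.

# Minimum-cost perfect assignment on a square cost matrix
# (Jonker/e-maxx shortest-augmenting-path formulation, O(n^3)).
# Returns an integer vector a with a[i] = column assigned to row i.
solve_assignment <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  if (!all(is.finite(cost))) stop_usage("assignment costs must be finite")
  n <- nrow(cost)
  if (n == 1L) return(1L)
  # index 1 plays the role of the virtual column 0
  u <- numeric(n + 1)
  v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j+1]: row currently matched to column j
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- 0L
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0 + 1] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          u[p[j + 1] + 1] <- u[p[j + 1] + 1] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(n)) a[p[j + 1]] <- j
  a
}

#' Match mixture components between two sets of profiles
#'
#' Finds the permutation of `other`'s components that minimizes the total
#' pairwise divergence to `reference`'s components, solving the assignment
#' problem exactly. Used to coordinate metabosystems (or subnetworks)
#' across runs, across L values, or against simulation ground truth.
#'
#' @param reference,other Numeric matrices with one component profile per
#'   row and equally many rows.
#' @param method `"jsd"` (base-2 Jensen-Shannon divergence; rows must be
#'   simplexes) or `"l1"` (mean absolute difference; any scale).
#' @return An integer permutation `perm` with `perm[i]` the row of `other`
#'   matched to row i of `reference`.
#' @export
match_components <- function(reference, other, method = c("jsd", "l1")) {
  method <- match.arg(method)
  reference <- as.matrix(reference)
  other <- as.matrix(other)
  if (nrow(reference) != nrow(other)) {
    stop_usage("component counts differ between reference and other")
  }
  if (ncol(reference) != ncol(other)) {
    stop_usage("profile dimensions differ between reference and other")
  }
  n <- nrow(reference)
  cost <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      cost[i, j] <- if (method == "jsd") {
        jsd(reference[i, ], other[j, ])
      } else {
        mean(abs(reference[i, ] - other[j, ]))
      }
    }
  }
  solve_assignment(cost)
}
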