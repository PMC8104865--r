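# Linear assignment machinery for particle linking.
#
# lap_solve() is a dense Jonker-Volgenant-style successive-shortest-path
# solver (O(n^3)) for square cost matrices with Inf marking forbidden
# cells. solve_linking() wraps it in the standard extended cost matrix
# with per-particle birth/death alternatives, after decomposing the
# candidate graph into connected components (links across components are
# all forbidden, so the decomposition is exact and keeps each dense
# solve tiny).

#' Solve a square linear assignment problem
#'
#' Minimizes `sum(cost[i, assign[i]])` over permutations. `Inf` entries
#' are forbidden; a feasible perfect matching must exist.
#'
#' @param cost Square numeric matrix; `Inf` forbids a pairing.
#' @return Integer vector `assign` with `assign[i]` the column matched to
#'   row `i`.
#' @export
lap_solve <- function(cost) {
  stopifnot(is.matrix(cost), nrow(cost) == ncol(cost))
  n <- nrow(cost)
  if (n == 0L) return(integer(0L))
  u <- numeric(n)        # row potentials (rows 1..n)
  v <- numeric(n + 1L)   # column potentials, v[j + 1], virtual column 0
  p <- integer(n + 1L)   # p[j + 1] = row matched to column j (0 = free)
  way <- integer(n + 1L)
  for (i in seq_len(n)) {
    p[1L] <- i
    j0 <- 0L
    minv <- rep(Inf, n + 1L)
    used <- logical(n + 1L)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      jfree <- which(!used) - 1L           # unused real columns
      cur <- cost[i0, jfree] - u[i0] - v[jfree + 1L]
      upd <- which(cur < minv[jfree + 1L])
      if (length(upd) > 0L) {
        minv[jfree[upd] + 1L] <- cur[upd]
        way[jfree[upd] + 1L] <- j0
      }
      k <- which.min(minv[jfree + 1L])
      delta <- minv[jfree[k] + 1L]
      if (!is.finite(delta)) stop("assignment problem is infeasible", call. = FALSE)
      j1 <- jfree[k]
      sel <- used
      u[p[which(sel)]] <- u[p[which(sel)]] + delta
      v[which(sel)] <- v[which(sel)] - delta
      minv[!sel] <- minv[!sel] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {   # augment along the alternating path
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  assign <- integer(n)
  for (j in seq_len(n)) assign[p[j + 1L]] <- j
  assign
}

# Extended (n + m)^2 cost matrix of Jaqaman-style linking: top-left the
# link costs, diagonal birth/death blocks at `alt_cost`, bottom-right the
# transposed link block (so a link is taken exactly when its cost is
# below `alt_cost`).
extended_cost_matrix <- function(link_cost, alt_cost) {
  n <- nrow(link_cost); m <- ncol(link_cost)
  big <- matrix(Inf, n + m, n + m)
  big[seq_len(n), seq_len(m)] <- link_cost
  if (n > 0L) big[cbind(seq_len(n), m + seq_len(n))] <- alt_cost
  if (m > 0L) big[cbind(n + seq_len(m), seq_len(m))] <- alt_cost
  lower <- t(link_cost)
  lower[is.finite(lower)] <- 0
  big[n + seq_len(m), m + seq_len(n)] <- lower
  big
}

#' Globally optimal one-to-one linking with birth/death alternatives
#'
#' Matches `n` sources to `m` targets minimizing total cost, where every
#' source may instead "die" and every target "be born" at `alt_cost`.
#' Only candidate pairs with finite cost may link. The solution is the
#' exact optimum of the extended assignment problem; it links a pair iff
#' doing so lowers the total cost relative to the birth+death
#' alternative.
#'
#' @param link_cost `n x m` matrix of link costs, `Inf` = forbidden.
#' @param alt_cost Cost of leaving one particle unmatched.
#' @return List with `links` (2-column matrix of source, target indices)
#'   and `cost` (sum of link costs plus `alt_cost` per unmatched
#'   particle).
#' @export
solve_linking <- function(link_cost, alt_cost) {
  stopifnot(is.matrix(link_cost), is.finite(alt_cost), alt_cost > 0)
  n <- nrow(link_cost); m <- ncol(link_cost)
  links <- matrix(integer(0L), 0L, 2L)
  if (n > 0L && m > 0L) {
    # connected components of the bipartite candidate graph
    cand <- which(is.finite(link_cost), arr.ind = TRUE)
    parent <- uf_new(n + m)
    if (nrow(cand) > 0L) {
      for (r in seq_len(nrow(cand))) {
        parent <- uf_union(parent, cand[r, 1L], n + cand[r, 2L])
      }
    }
    roots <- vapply(seq_len(n + m), function(i) uf_find(parent, i), integer(1L))
    for (root in unique(roots[seq_len(n)])) {
      rows <- which(roots[seq_len(n)] == root)
      cols <- which(roots[n + seq_len(m)] == root)
      if (length(cols) == 0L) next
      sub <- link_cost[rows, cols, drop = FALSE]
      a <- lap_solve(extended_cost_matrix(sub, alt_cost))
      ns <- length(rows); ms <- length(cols)
      for (i in seq_len(ns)) {
        if (a[i] <= ms) links <- rbind(links, c(rows[i], cols[a[i]]))
      }
    }
  }
  cost <- sum(link_cost[links]) + alt_cost * (n - nrow(links)) +
    alt_cost * (m - nrow(links))
  list(links = links, cost = cost)
}
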