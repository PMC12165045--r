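# Kuhn-Munkres (Hungarian) assignment and the hard-assignment baseline
# contour supervision: every predicted point is matched one-to-one to a
# ground-truth point at minimal total Euclidean cost, and the training loss
# is smooth-L1 over the matched coordinate pairs.

#' Minimum-cost perfect matching (Kuhn-Munkres / Jonker-Volgenant)
#'
#' O(n^3) shortest-augmenting-path implementation with dual potentials.
#'
#' @param cost square numeric cost matrix.
#' @return integer vector `p` with `p[i]` the column assigned to row i.
#' @export
solve_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  if (ncol(cost) != n) stop("cost matrix must be square")
  u <- numeric(n + 1); v <- numeric(n + 1)
  p <- integer(n + 1)            # p[j]: row matched to column j (0 = none)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 1L                      # column index + 1 offsets: slot 1 = virtual
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0] <- TRUE
      i0 <- p[j0]; delta <- Inf; j1 <- 0L
      for (j in 2:(n + 1)) {
        if (!used[j]) {
          cur <- cost[i0, j - 1] - u[i0] - v[j]
          if (cur < minv[j]) { minv[j] <- cur; way[j] <- j0 }
          if (minv[j] < delta) { delta <- minv[j]; j1 <- j }
        }
      }
      for (j in 1:(n + 1)) {
        if (used[j]) { u[p[j]] <- u[p[j]] + delta; v[j] <- v[j] - delta }
        else minv[j] <- minv[j] - delta
      }
      j0 <- j1
      if (p[j0] == 0L) break
    }
    repeat {
      j1 <- way[j0]
      p[j0] <- p[j1]
      j0 <- j1
      if (j0 == 1L) break
    }
  }
  ans <- integer(n)
  for (j in 2:(n + 1)) if (p[j] > 0) ans[p[j]] <- j - 1L
  ans
}

smooth_l1 <- function(err, beta = 1) {
  a <- abs(err)
  ifelse(a < beta, 0.5 * a^2 / beta, a - 0.5 * beta)
}

smooth_l1_grad <- function(err, beta = 1) {
  ifelse(abs(err) < beta, err / beta, sign(err))
}

#' Hard-assignment (Kuhn-Munkres) contour supervision baseline
#'
#' Matches predicted points one-to-one to ground-truth points at minimal
#' total Euclidean cost, then scores the matching with a smooth-L1 loss on
#' the matched coordinate differences (mean over all coordinates).
#'
#' @param pred,truth equal-length N x 2 point matrices.
#' @param beta smooth-L1 transition point.
#' @return list with `permutation` (truth index matched to each predicted
#'   point), `loss`, `matched_cost` (total Euclidean cost of the matching)
#'   and `gradient` (d loss / d pred, N x 2).
#' @export
km_hard_assign <- function(pred, truth, beta = 1) {
  pred <- as.matrix(pred); truth <- as.matrix(truth)
  if (nrow(pred) != nrow(truth)) stop("point lists must have equal length")
  C <- build_cost_matrix(pred, truth)
  perm <- solve_assignment(C)
  err <- pred - truth[perm, , drop = FALSE]
  loss <- mean(smooth_l1(err, beta))
  grad <- smooth_l1_grad(err, beta) / length(err)
  list(permutation = perm, loss = loss,
       matched_cost = sum(C[cbind(seq_len(nrow(C)), perm)]),
       gradient = grad)
}
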