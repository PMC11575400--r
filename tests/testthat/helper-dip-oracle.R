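# Independent slow oracle for the dip statistic.
#
# Encodes the definition directly: dip = min over unimodal CDFs g of
# sup|Fn - g|.  A unimodal g is convex left of its mode and concave right
# of it, with an atom allowed at the mode.  For a candidate mode (an atom
# at a sample value, or a position inside a gap between adjacent values,
# scanned on a grid) the sup-distance constraints at the sample points are
# linear in the values of g, so feasibility at a given eps is a convex
# feasibility problem, checked with quadprog (dual active set, numerically
# robust); the minimal eps per candidate is found by bisection and the dip
# is the minimum over candidates.

dip_case_feasible <- function(pos, lo, hi, conv_l, conc_r, eps) {
  K <- length(pos)
  A <- NULL
  b <- NULL
  add <- function(row, rhs) {        # row . g >= rhs
    s <- max(abs(row), abs(rhs), 1e-12)
    A <<- rbind(A, row / s)
    b <<- c(b, rhs / s)
  }
  for (k in seq_len(K)) {
    r <- numeric(K); r[k] <- 1
    add(r, lo[k] - eps)
    add(-r, -(hi[k] + eps))
  }
  for (k in seq_len(K - 1)) {
    r <- numeric(K); r[k] <- -1; r[k + 1] <- 1
    add(r, 0)
  }
  smooth <- function(idx, convex) {
    if (length(idx) < 3) return()
    for (t in seq_len(length(idx) - 2)) {
      i <- idx[t]; j <- idx[t + 1]; k <- idx[t + 2]
      d1 <- pos[j] - pos[i]; d2 <- pos[k] - pos[j]
      r <- numeric(K)
      r[i] <- 1 / d1; r[j] <- -(1 / d1 + 1 / d2); r[k] <- 1 / d2
      if (convex) add(r, 0) else add(-r, 0)
    }
  }
  if (conv_l >= 1) smooth(seq_len(conv_l), TRUE)
  if (conc_r <= K) smooth(conc_r:K, FALSE)
  sol <- try(quadprog::solve.QP(Dmat = diag(K), dvec = rep(0, K),
                                Amat = t(A), bvec = b),
             silent = TRUE)
  !inherits(sol, "try-error")
}

dip_case_eps <- function(pos, lo, hi, conv_l, conc_r, tol = 1e-9) {
  lo_e <- 0; hi_e <- 0.5
  if (dip_case_feasible(pos, lo, hi, conv_l, conc_r, lo_e)) return(0)
  while (hi_e - lo_e > tol) {
    mid <- (lo_e + hi_e) / 2
    if (dip_case_feasible(pos, lo, hi, conv_l, conc_r, mid)) {
      hi_e <- mid
    } else {
      lo_e <- mid
    }
  }
  hi_e
}

dip_oracle <- function(x, gap_grid = 9, tol = 1e-9) {
  xs <- sort(x)
  ux <- unique(xs)
  N <- length(ux)
  if (N == 1) return(0)
  top <- vapply(ux, function(v) mean(xs <= v), numeric(1))
  bot <- vapply(ux, function(v) mean(xs < v), numeric(1))

  best <- Inf
  for (j in seq_len(N)) {
    left <- seq_len(j - 1)
    right <- if (j < N) (j + 1):N else integer(0)
    v <- dip_case_eps(c(ux[left], ux[j], ux[j], ux[right]),
                      c(top[left], bot[j], top[j], top[right]),
                      c(bot[left], bot[j], top[j], bot[right]),
                      conv_l = j, conc_r = j + 1, tol = tol)
    best <- min(best, v)
  }
  for (j in seq_len(N - 1)) {
    cn <- top[j]
    for (frac in seq(0.02, 0.98, length.out = gap_grid)) {
      m <- ux[j] + (ux[j + 1] - ux[j]) * frac
      v <- dip_case_eps(c(ux[seq_len(j)], m, m, ux[(j + 1):N]),
                        c(top[seq_len(j)], cn, cn, top[(j + 1):N]),
                        c(bot[seq_len(j)], cn, cn, bot[(j + 1):N]),
                        conv_l = j + 1, conc_r = j + 2, tol = tol)
      best <- min(best, v)
      if (v > best + 0.05) break     # far past the minimum for this gap
    }
  }
  best <- min(best,
              dip_case_eps(ux, top, bot, N, N + 1, tol),   # pure convex
              dip_case_eps(ux, top, bot, 0, 1, tol))       # pure concave
  best
}
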