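# Independent brute-force oracles used across the suite. These never call
# back into the code paths they check.

# Exhaustive KKT solver for linear eps-SVR (dual variable beta_i = alpha_i -
# alpha_i* in [-C, C], sum(beta) = 0). Each sample is assigned one of five
# KKT states; every assignment's linear system is solved and checked for
# feasibility. Any feasible point is optimal (convex problem). Weights are
# unique; the intercept can be an interval when no free SV pins it, so only
# weights should be compared in that case.
svr_kkt_oracle <- function(X, y, C = 1, eps = 0.1, tol = 1e-9) {
  n <- nrow(X)
  K <- X %*% t(X)
  states <- c("I", "U", "L", "UB", "LB")  # beta: 0, (0,C), (-C,0), C, -C
  grid <- do.call(expand.grid,
                  c(rep(list(states), n), stringsAsFactors = FALSE))
  for (g in seq_len(nrow(grid))) {
    st <- as.character(unlist(grid[g, ]))
    beta <- numeric(n)
    beta[st == "UB"] <- C
    beta[st == "LB"] <- -C
    free <- which(st %in% c("U", "L"))
    nf <- length(free)
    if (nf == 0) next  # intercept not pinned; skip (interval solutions)
    fixed <- which(!(st %in% c("U", "L")))
    A <- matrix(0, nf + 1, nf + 1)
    rhs <- numeric(nf + 1)
    for (r in seq_len(nf)) {
      i <- free[r]
      A[r, seq_len(nf)] <- K[i, free]
      A[r, nf + 1] <- 1
      s <- if (st[i] == "U") eps else -eps  # U: y - f = eps
      rhs[r] <- y[i] - s - sum(K[i, fixed] * beta[fixed])
    }
    A[nf + 1, seq_len(nf)] <- 1
    rhs[nf + 1] <- -sum(beta[fixed])
    sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    beta[free] <- sol[seq_len(nf)]
    b <- sol[nf + 1]
    ok <- all(beta[free][st[free] == "U"] > -tol &
                beta[free][st[free] == "U"] < C + tol) &&
      all(beta[free][st[free] == "L"] < tol &
            beta[free][st[free] == "L"] > -C - tol)
    if (ok) {
      f <- as.vector(K %*% beta) + b
      res <- y - f
      for (i in seq_len(n)) {
        if (st[i] == "I" && abs(res[i]) > eps + tol) ok <- FALSE
        if (st[i] == "UB" && res[i] < eps - tol) ok <- FALSE
        if (st[i] == "LB" && res[i] > -eps + tol) ok <- FALSE
      }
    }
    if (ok)
      return(list(w = as.vector(t(X) %*% beta), b = b, beta = beta))
  }
  stop("KKT oracle: no feasible assignment found")
}

# 6-connectivity connected components of a logical 3-D array by flood fill
flood_components <- function(vol) {
  d <- dim(vol)
  lab <- array(0L, d)
  cur <- 0L
  offs <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0),
                c(0, -1, 0), c(0, 0, 1), c(0, 0, -1))
  for (start in which(vol)) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      v <- queue[1]
      queue <- queue[-1]
      ijk <- arrayInd(v, d)
      for (o in 1:6) {
        nb <- ijk + offs[o, ]
        if (any(nb < 1) || any(nb > d)) next
        lin <- nb[1] + d[1] * (nb[2] - 1) + d[1] * d[2] * (nb[3] - 1)
        if (vol[lin] && lab[lin] == 0L) {
          lab[lin] <- cur
          queue <- c(queue, lin)
        }
      }
    }
  }
  list(n = cur, labels = lab)
}

# brute-force Benjamini-Hochberg: scan all candidate thresholds
bh_bruteforce <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  pass <- which(ps <= seq_len(m) * q / m)
  mask <- logical(m)
  if (length(pass)) mask[ord[seq_len(max(pass))]] <- TRUE
  mask
}

# two-sided exact binomial p by direct pmf summation
binom_p_bruteforce <- function(k, n, p0 = 0.5) {
  pmf <- stats::dbinom(0:n, n, p0)
  sum(pmf[pmf <= pmf[k + 1] + 1e-12])
}

tiny_mask <- function(shape = c(6, 6, 6), radius_mm = 5, voxel = 2) {
  spherical_mask(shape, voxel, radius_mm)
}

# small default-structure cohort for integration-style tests
small_cohort <- function(n_participants = 10, seed = 1, ...) {
  mask <- spherical_mask(c(10, 10, 10), 2, 8)
  spec <- synth_spec(n_participants = n_participants, seed = seed, ...)
  simulate_cohort(spec, mask, n_blobs = 2, blob_radius_mm = 4)
}

cohort_maps <- function(cohort) {
  agg <- unlist(lapply(cohort$participants, aggregate_by_rating),
                recursive = FALSE)
  list(X = do.call(rbind, lapply(agg, function(m) m$values)),
       ratings = vapply(agg, function(m) as.numeric(m$meta$rating), 1),
       participants = vapply(agg, function(m)
         as.character(m$meta$participant), ""))
}

cosine_sim <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))
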