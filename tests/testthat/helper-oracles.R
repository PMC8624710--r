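# Independent oracles used by the test suite. Each deliberately takes a
# different route than the package implementation it checks.

# --- Finite-difference PDE oracle for the one-membrane diffusion problem ---
# Semidiscrete central-difference operator on >= 200 spatial nodes,
# propagated *exactly* in time through its eigenmodes (so the only error is
# spatial), then Richardson-extrapolated from nx and 2*nx to O(dx^4).
fd_modes_q <- function(model, C_donor, times, nx) {
  D <- model$D; h <- model$h; K <- model$K
  dx <- h / nx
  n_int <- nx - 1L
  u0 <- K * C_donor
  A <- matrix(0, n_int, n_int)
  for (i in seq_len(n_int)) {
    A[i, i] <- -2
    if (i > 1) A[i, i - 1] <- 1
    if (i < n_int) A[i, i + 1] <- 1
  }
  us <- u0 * (1 - seq_len(n_int) / nx)       # discrete steady state (linear)
  eg <- eigen(A, symmetric = TRUE)
  V <- eg$vectors
  mu <- eg$values * D / dx^2                 # decay rates, all negative
  cvec <- drop(crossprod(V, -us))            # transient w(0) = -steady
  # second-order one-sided flux at the sink face (u_N = 0)
  wflux <- D * (4 * V[n_int, ] - V[n_int - 1L, ]) / (2 * dx)
  Jss <- D * u0 / h
  vapply(times, function(t)
    Jss * t + sum(wflux * cvec * (exp(mu * t) - 1) / mu), numeric(1))
}

pde_oracle_q <- function(model, C_donor, times, nx = 200L) {
  q1 <- fd_modes_q(model, C_donor, times, nx)
  q2 <- fd_modes_q(model, C_donor, times, 2L * nx)
  (4 * q2 - q1) / 3
}

# --- Exhaustive steady-state window search built on lm() ---
# Returns the argmax-r2 contiguous window (>= min_points, positive slope),
# ties broken by longer window then earlier start.
brute_force_window <- function(t, q, min_points = 4L) {
  n <- length(t)
  best <- NULL
  for (s in seq_len(n - min_points + 1L)) {
    for (e in seq.int(s + min_points - 1L, n)) {
      fit <- stats::lm(qq ~ tt, data = data.frame(tt = t[s:e], qq = q[s:e]))
      slope <- stats::coef(fit)[["tt"]]
      r2 <- summary(fit)$r.squared
      if (!is.finite(slope) || slope <= 0) next
      if (is.null(best) || r2 > best$r2 ||
          (r2 == best$r2 && (e - s) > (best$e - best$s)) ||
          (r2 == best$r2 && (e - s) == (best$e - best$s) && s < best$s))
        best <- list(s = s, e = e, r2 = r2, slope = slope,
                     intercept = stats::coef(fit)[["(Intercept)"]])
    }
  }
  best
}

# --- Brute-force compact letter display via maximal cliques of the ---
# --- non-significance graph (subset enumeration; fine for k <= ~10) ---
brute_force_cld_sharing <- function(signif) {
  k <- nrow(signif)
  nonsig <- !signif
  diag(nonsig) <- TRUE
  is_clique <- function(members) all(nonsig[members, members])
  subsets <- lapply(seq_len(2^k - 1), function(mask)
    which(bitwAnd(mask, bitwShiftL(1L, seq_len(k) - 1L)) > 0L))
  cliques <- Filter(is_clique, subsets)
  maximal <- Filter(function(a)
    !any(vapply(cliques, function(b)
      length(b) > length(a) && all(a %in% b), logical(1))), cliques)
  # sharing relation implied by assigning one letter per maximal clique
  share <- diag(TRUE, k)
  for (cl in maximal) share[cl, cl] <- TRUE
  share
}

# sharing relation implied by a letter vector (groups share >= 1 letter)
letters_to_sharing <- function(letter_vec) {
  k <- length(letter_vec)
  sets <- strsplit(letter_vec, "")
  share <- diag(TRUE, k)
  for (i in seq_len(k)) for (j in seq_len(k))
    share[i, j] <- length(intersect(sets[[i]], sets[[j]])) > 0L || i == j
  share
}

# --- Textbook sum-formula Pearson r ---
pearson_sum_formula <- function(x, y) {
  n <- length(x)
  (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
}

# --- Adjusted Rand index between two partitions ---
adjusted_rand_index <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n <- length(a)
  expected <- sum_a * sum_b / choose2(n)
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
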