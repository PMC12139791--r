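# Independent brute-force oracles and tiny fixture builders. These stay
# loop-based and deliberately naive so they share no code path with the
# implementation they check.

# Pairwise Fisher-z correlation by explicit per-pair loops over covariance
# and standard deviations.
oracle_fc <- function(ts) {
  n <- nrow(ts)
  tt <- ncol(ts)
  z <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      xi <- ts[i, ]
      xj <- ts[j, ]
      num <- sum((xi - mean(xi)) * (xj - mean(xj))) / (tt - 1)
      den <- sqrt(sum((xi - mean(xi))^2) / (tt - 1)) *
        sqrt(sum((xj - mean(xj))^2) / (tt - 1))
      r <- num / den
      r <- min(max(r, -(1 - 1e-7)), 1 - 1e-7)
      z[i, j] <- atanh(r)
    }
  }
  z
}

# Mean of connectome values over mask edges by a double loop on the upper
# triangle.
oracle_strength <- function(values, mask_matrix) {
  acc <- c()
  n <- nrow(values)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (mask_matrix[i, j] == 1 && !is.na(values[i, j])) {
        acc <- c(acc, values[i, j])
      }
    }
  }
  if (length(acc) == 0) NA_real_ else mean(acc)
}

# Canonical-network grid by explicit pair loops.
oracle_grid <- function(values, assignment) {
  f <- factor(assignment)
  labs <- levels(f)
  k <- length(labs)
  grid <- matrix(NA_real_, k, k, dimnames = list(labs, labs))
  n <- nrow(values)
  for (a in seq_len(k)) {
    for (b in seq_len(k)) {
      acc <- c()
      for (i in seq_len(n - 1)) {
        for (j in (i + 1):n) {
          lab_i <- as.character(f[i])
          lab_j <- as.character(f[j])
          hit <- (lab_i == labs[a] && lab_j == labs[b]) ||
            (lab_i == labs[b] && lab_j == labs[a])
          if (hit && !is.na(values[i, j])) acc <- c(acc, values[i, j])
        }
      }
      if (length(acc)) grid[a, b] <- mean(acc)
    }
  }
  grid
}

oracle_overlap <- function(ma, mb) {
  n <- nrow(ma)
  count <- 0L
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      if (ma[i, j] == 1 && mb[i, j] == 1) count <- count + 1L
    }
  }
  count
}

# Exact upper-tail overlap probability by enumerating every possible draw of
# the second edge set (combn over all M edges), feasible for M <= 12.
oracle_hyper_enum <- function(x, K, n, M) {
  first <- seq_len(K)  # which edges are in set 1 is arbitrary by symmetry
  draws <- utils::combn(M, n)
  hits <- apply(draws, 2, function(d) sum(d %in% first) >= x)
  mean(hits)
}

# Regularised incomplete beta by Lentz continued fraction, used to get
# two-tailed t-test p-values independently of pt().
oracle_betainc <- function(x, a, b) {
  if (x <= 0) return(0)
  if (x >= 1) return(1)
  lbeta_ab <- lgamma(a) + lgamma(b) - lgamma(a + b)
  front <- exp(log(x) * a + log(1 - x) * b - lbeta_ab) / a
  # modified Lentz algorithm
  f <- 1; c <- 1; d <- 0
  for (i in 0:200) {
    m <- i %/% 2
    numerator <- if (i == 0) 1 else if (i %% 2 == 0) {
      m * (b - m) * x / ((a + 2 * m - 1) * (a + 2 * m))
    } else {
      -(a + m) * (a + b + m) * x / ((a + 2 * m) * (a + 2 * m + 1))
    }
    d <- 1 + numerator * d
    if (abs(d) < 1e-30) d <- 1e-30
    d <- 1 / d
    c <- 1 + numerator / c
    if (abs(c) < 1e-30) c <- 1e-30
    f <- f * c * d
    if (abs(1 - c * d) < 1e-15) break
  }
  front * (f - 1)
}

oracle_t_pvalue <- function(t, df) {
  # two-tailed via I_{df/(df+t^2)}(df/2, 1/2)
  oracle_betainc(df / (df + t^2), df / 2, 0.5)
}

# Tiny fixture builders ------------------------------------------------------

mask_from_edges <- function(n_nodes, edges, label = "toy") {
  m <- matrix(0, n_nodes, n_nodes)
  for (e in edges) m[e[1], e[2]] <- m[e[2], e[1]] <- 1
  edge_mask(m, label = label)
}

random_mask <- function(n_nodes, n_edges) {
  ut <- which(upper.tri(diag(n_nodes)))
  m <- matrix(0, n_nodes, n_nodes)
  m[sample(ut, n_edges)] <- 1
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  edge_mask(m)
}

random_symmetric <- function(n_nodes) {
  m <- matrix(rnorm(n_nodes^2), n_nodes, n_nodes)
  m <- (m + t(m)) / 2
  diag(m) <- 0
  m
}

toy_manifest <- function(...) {
  rows <- list(...)
  defaults <- list(subject_id = "S1", condition = "MA", run_type = "rest",
                   path = "x", max_displacement_mm = 1,
                   mean_censored_motion_mm = 0.05, frac_censored = 0.1)
  out <- do.call(rbind, lapply(rows, function(r) {
    as.data.frame(utils::modifyList(defaults, r))
  }))
  out <- tibble::as_tibble(out)
  out$missing_nodes <- rep(list(integer(0)), nrow(out))
  out
}
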