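# Independent brute-force / enumeration oracles used to check the package's
# statistical operations, plus small fixture builders. The oracles never call
# the code paths they verify.

# --- fixtures ---------------------------------------------------------------

make_matrix <- function(values, calls = NULL, prefix = "ps") {
  values <- as.matrix(values)
  rownames(values) <- sprintf("%s%03d_at", prefix, seq_len(nrow(values)))
  colnames(values) <- sprintf("S%02d", seq_len(ncol(values)))
  if (!is.null(calls)) {
    calls <- matrix(calls, nrow(values), ncol(values))
    dimnames(calls) <- dimnames(values)
  }
  expression_matrix(values, calls)
}

random_matrix <- function(n_probesets, n_samples, seed = 1, with_calls = FALSE) {
  set.seed(seed)
  vals <- matrix(exp(rnorm(n_probesets * n_samples, 4, 1)),
                 n_probesets, n_samples)
  calls <- if (with_calls) {
    sample(c("P", "M", "A"), n_probesets * n_samples, replace = TRUE,
           prob = c(0.7, 0.1, 0.2))
  } else NULL
  make_matrix(vals, calls)
}

simple_annotation <- function(em, symbols = NULL) {
  ids <- rownames(em$values)
  if (is.null(symbols)) symbols <- sprintf("GENE%03d", seq_along(ids))
  data.frame(probeset_id = ids, symbol = symbols, stringsAsFactors = FALSE)
}

# --- enumeration / closed-form oracles --------------------------------------

# Welch t from first principles
oracle_welch <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- var(a) / na; vb <- var(b) / nb
  t <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (na - 1) + vb^2 / (nb - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

# Benjamini-Hochberg step-up, literal definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  adj <- numeric(m)
  prev <- 1
  for (i in m:1) {
    prev <- min(prev, p[ord[i]] * m / i)
    adj[ord[i]] <- prev
  }
  pmin(adj, 1)
}

# Ansari-Bradley statistic (midrank scores) for one labelling
ab_statistic <- function(x, y) {
  pooled <- c(x, y)
  n <- length(pooled)
  r <- rank(pooled)
  sum(pmin(r, n + 1 - r)[seq_along(x)])
}

# exact two-sided AB p by enumeration over all C(n+m, n) assignments
oracle_ansari_exact <- function(x, y) {
  pooled <- c(x, y)
  n <- length(x)
  stat <- ab_statistic(x, y)
  combs <- utils::combn(length(pooled), n)
  stats <- apply(combs, 2L, function(idx) {
    ab_statistic(pooled[idx], pooled[-idx])
  })
  pl <- mean(stats <= stat)
  pu <- mean(stats >= stat)
  list(statistic = stat, p = min(1, 2 * min(pl, pu)))
}

# exact two-sided Mann-Whitney p by enumeration
oracle_mannwhitney_exact <- function(x, y) {
  u_stat <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  pooled <- c(x, y)
  n <- length(x)
  u <- u_stat(x, y)
  combs <- utils::combn(length(pooled), n)
  us <- apply(combs, 2L, function(idx) u_stat(pooled[idx], pooled[-idx]))
  list(U = u, p = min(1, 2 * min(mean(us <= u), mean(us >= u))))
}

# Spearman rho from the rank definition
oracle_spearman <- function(a, b) {
  cor(rank(a), rank(b), method = "pearson")
}

# O(n^3) agglomerative clustering on a distance matrix; returns the
# cophenetic matrix (height at which each pair first joins) for average or
# complete linkage
oracle_agglomerate <- function(d, linkage = c("average", "complete")) {
  linkage <- match.arg(linkage)
  d <- as.matrix(d)
  n <- nrow(d)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n)
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_len(i - 1L)) {
        pd <- d[clusters[[i]], clusters[[j]], drop = FALSE]
        dd <- if (linkage == "average") mean(pd) else max(pd)
        if (dd < best_d) { best_d <- dd; best <- c(j, i) }
      }
    }
    a <- clusters[[best[1]]]; b <- clusters[[best[2]]]
    coph[a, b] <- best_d; coph[b, a] <- best_d
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(a, b)
    clusters[[best[2]]] <- NULL
  }
  list(cophenetic = coph, heights = heights)
}
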