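# Independent brute-force oracles used to cross-check the implementation.
# These are deliberately naive (full DP matrices, exhaustive enumeration)
# and are only run at tiny problem sizes.

# full (unbanded) Needleman-Wunsch of the overlap region implied by laying
# read b at every offset against read a; returns the best dovetail or
# containment overlap as list(len, identity) or NULL
oracle_best_overlap <- function(a, b, min_overlap, min_identity) {
  nw_global <- function(x, y) {
    n <- nchar(x); m <- nchar(y)
    xs <- strsplit(x, "")[[1]]; ys <- strsplit(y, "")[[1]]
    S <- matrix(0, n + 1, m + 1)
    S[, 1] <- -2 * (0:n); S[1, ] <- -2 * (0:m)
    for (i in seq_len(n)) for (j in seq_len(m)) {
      S[i + 1, j + 1] <- max(S[i, j] + ifelse(xs[i] == ys[j], 1, -1),
                             S[i, j + 1] - 2, S[i + 1, j] - 2)
    }
    # traceback for columns/matches
    i <- n; j <- m; cols <- 0; matches <- 0
    while (i > 0 || j > 0) {
      if (i > 0 && j > 0 &&
          S[i + 1, j + 1] == S[i, j] + ifelse(xs[i] == ys[j], 1, -1)) {
        if (xs[i] == ys[j]) matches <- matches + 1
        i <- i - 1; j <- j - 1
      } else if (i > 0 && S[i + 1, j + 1] == S[i, j + 1] - 2) {
        i <- i - 1
      } else j <- j - 1
      cols <- cols + 1
    }
    list(cols = cols, matches = matches)
  }
  la <- nchar(a); lb <- nchar(b)
  best <- NULL
  for (d in (-lb + 1):(la - 1)) {   # offset of b's start on a's coordinates
    qs <- max(0, d); rs <- max(0, -d)
    L <- min(la - qs, lb - rs)
    if (L < min_overlap) next
    r <- nw_global(substr(a, qs + 1, qs + L), substr(b, rs + 1, rs + L))
    ident <- r$matches / r$cols
    if (ident >= min_identity) {
      if (is.null(best) || r$cols > best$len)
        best <- list(len = r$cols, identity = ident)
    }
  }
  best
}

# exhaustive all-vs-all overlap edge set on a read set (ids, seqs)
oracle_edge_set <- function(ids, seqs, min_overlap, min_identity) {
  out <- list()
  n <- length(ids)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    b <- oracle_best_overlap(seqs[i], seqs[j], min_overlap, min_identity)
    if (!is.null(b))
      out[[length(out) + 1]] <- data.frame(u = min(ids[i], ids[j]),
                                           v = max(ids[i], ids[j]),
                                           overlap_len = b$len)
  }
  if (length(out) == 0)
    return(data.frame(u = character(0), v = character(0),
                      overlap_len = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$u, df$v), , drop = FALSE]
}

# brute-force transitive reduction with the same removal rule as the
# implementation: ascending (w, u, v), surviving witnesses only
oracle_transitive_reduction <- function(edges) {
  e <- edges[order(edges$w, edges$u, edges$v), , drop = FALSE]
  alive <- rep(TRUE, nrow(e))
  for (k in seq_len(nrow(e))) {
    a <- e$u[k]; c_ <- e$v[k]; w <- e$w[k]
    for (m in which(alive)) {
      if (m == k) next
      for (l in which(alive)) {
        if (l == m || l == k) next
        ends_m <- c(e$u[m], e$v[m]); ends_l <- c(e$u[l], e$v[l])
        b1 <- setdiff(ends_m, a); b2 <- setdiff(ends_l, c_)
        if (a %in% ends_m && c_ %in% ends_l &&
            length(b1) == 1 && length(b2) == 1 && b1 == b2 &&
            e$w[m] >= w && e$w[l] >= w) {
          alive[k] <- FALSE
        }
      }
    }
  }
  e[alive, , drop = FALSE]
}

# k-neighborhood by Floyd-Warshall all-pairs shortest paths (hop counts)
oracle_k_neighborhood <- function(nodes, edges, center, k) {
  n <- length(nodes)
  D <- matrix(Inf, n, n); diag(D) <- 0
  for (r in seq_len(nrow(edges))) {
    i <- match(edges$u[r], nodes); j <- match(edges$v[r], nodes)
    D[i, j] <- 1; D[j, i] <- 1
  }
  for (m in seq_len(n)) for (i in seq_len(n)) for (j in seq_len(n))
    if (D[i, m] + D[m, j] < D[i, j]) D[i, j] <- D[i, m] + D[m, j]
  sort(nodes[D[match(center, nodes), ] <= k])
}

# one-sided (greater) Fisher p by direct hypergeometric tail summation for
# table rbind(c(a, b), c(c, d)): P(X >= a), X ~ Hypergeom
oracle_fisher_greater <- function(a, b, c_, d) {
  m <- a + b          # inside total
  K <- a + c_         # class total
  N <- a + b + c_ + d
  xs <- max(0, m + K - N):min(m, K)
  num <- vapply(xs, function(x) choose(K, x) * choose(N - K, m - x), numeric(1))
  sum(num[xs >= a]) / sum(num)
}

# exhaustive heavy-edge matching oracle: replay the documented visit rules
# (greedy by the specified orders) -- independent simple implementation
oracle_hem <- function(n, edges, min_w = -Inf, min_density = 0,
                       nw = rep(1, n), ew = rep(0, n), n_passes = 4) {
  maxw <- rep(-Inf, n)
  for (r in seq_len(nrow(edges))) {
    maxw[edges$u[r]] <- max(maxw[edges$u[r]], edges$w[r])
    maxw[edges$v[r]] <- max(maxw[edges$v[r]], edges$w[r])
  }
  cand <- which(is.finite(maxw))
  rk <- rank(-maxw[cand], ties.method = "min")
  bucket <- ceiling(rk * n_passes / length(cand))
  visit <- cand[order(bucket, cand)]
  matched <- rep(FALSE, n)
  pairs <- NULL
  for (vi in visit) {
    if (matched[vi]) next
    inc <- which(edges$u == vi | edges$v == vi)
    nbr <- ifelse(edges$u[inc] == vi, edges$v[inc], edges$u[inc])
    o <- order(-edges$w[inc], nbr)
    for (t in o) {
      w <- edges$w[inc[t]]
      if (w < min_w) break
      vj <- nbr[t]
      if (matched[vj]) next
      s <- nw[vi] + nw[vj]
      dens <- 2 * (ew[vi] + ew[vj] + w) / (s * (s - 1))
      if (dens >= min_density) {
        matched[c(vi, vj)] <- TRUE
        pairs <- rbind(pairs, c(vi, vj))
        break
      }
    }
  }
  pairs
}

# deterministic random DNA
rand_dna <- function(n, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
}

# random weighted graph helper for conservation checks
rand_graph_edges <- function(n, p, wmax = 100) {
  pairs <- t(combn(n, 2))
  keep <- stats::runif(nrow(pairs)) < p
  pairs <- pairs[keep, , drop = FALSE]
  data.frame(u = pairs[, 1], v = pairs[, 2],
             w = sample.int(wmax, nrow(pairs), TRUE))
}
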