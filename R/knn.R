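# Deterministic exact nearest-neighbour queries. RANN's kd-tree is exact in
# distance but breaks distance ties arbitrarily; every caller in this
# package requires ties broken by ascending row index, so results are
# post-sorted by (distance, index) and rows whose ties straddle the
# candidate cutoff are recomputed by brute force.

.knnBruteRow <- function(x, i, k) {
  d <- sqrt(colSums((t(x) - x[i, ])^2))
  ord <- order(d, seq_len(nrow(x)))
  ord <- ord[ord != i]
  ord[seq_len(k)]
}

# k nearest neighbours of every row of x among the other rows; returns an
# n x k integer matrix ordered by (distance, index)
.knnIndices <- function(x, k) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (n < k + 1L) stop("need at least k + 1 = ", k + 1L, " cells, got ", n)
  if (n <= 1500L) {
    d <- as.matrix(stats::dist(x))
    out <- matrix(0L, n, k)
    for (i in seq_len(n)) {
      ord <- order(d[i, ], seq_len(n))
      ord <- ord[ord != i]
      out[i, ] <- ord[seq_len(k)]
    }
    return(out)
  }
  pad <- 10L
  kq <- min(n, k + 1L + pad)
  nn <- RANN::nn2(x, x, k = kq, eps = 0)
  out <- matrix(0L, n, k)
  eps <- 1e-9
  for (i in seq_len(n)) {
    idx <- nn$nn.idx[i, ]
    dd <- nn$nn.dists[i, ]
    keep <- idx != i
    idx <- idx[keep]; dd <- dd[keep]
    ord <- order(dd, idx)
    idx <- idx[ord]; dd <- dd[ord]
    # ambiguity: candidates beyond the query set could tie with the k-th
    if (length(dd) > k && dd[length(dd)] <= dd[k] + eps) {
      out[i, ] <- .knnBruteRow(x, i, k)
    } else {
      out[i, ] <- idx[seq_len(k)]
    }
  }
  out
}

# number of points of `data` within (closed) radius r of each row of `query`;
# exact: kd-tree candidates are re-filtered on the true distance
.radiusCounts <- function(query, data, r, excludeSelf = FALSE) {
  query <- as.matrix(query); data <- as.matrix(data)
  nq <- nrow(query); nd <- nrow(data)
  if (nd == 0L || nq == 0L) return(integer(nq))
  kcap <- min(nd, 32L)
  repeat {
    nn <- RANN::nn2(data, query, k = kcap, searchtype = "radius",
                    radius = r * (1 + 1e-9), eps = 0)
    found <- rowSums(nn$nn.idx > 0L)
    if (all(found < kcap) || kcap == nd) break
    kcap <- min(nd, kcap * 4L)
  }
  counts <- integer(nq)
  for (i in seq_len(nq)) {
    idx <- nn$nn.idx[i, ]
    idx <- idx[idx > 0L]
    if (!length(idx)) next
    d <- sqrt(colSums((t(data[idx, , drop = FALSE]) - query[i, ])^2))
    ok <- d <= r
    if (excludeSelf) ok <- ok & !(idx == i & d == 0)
    counts[i] <- sum(ok)
  }
  counts
}
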