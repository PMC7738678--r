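# Independent oracles. These deliberately use naive exhaustive strategies
# and share no code with the implementation they check.

# all motif windows within a Hamming budget, by per-window character loop
oracle_hamming_hits <- function(seq, motif, max_mismatch) {
  s <- strsplit(seq, "")[[1]]
  mo <- strsplit(motif, "")[[1]]
  m <- length(mo)
  out <- list()
  if (m > length(s)) {
    return(data.frame(start = integer(), mismatches = integer()))
  }
  for (i in seq_len(length(s) - m + 1L)) {
    w <- s[i:(i + m - 1L)]
    d <- sum(w != mo | w == "X")
    if (d <= max_mismatch) {
      out[[length(out) + 1L]] <- data.frame(start = i - 1L,
                                            mismatches = as.integer(d))
    }
  }
  if (!length(out)) return(data.frame(start = integer(), mismatches = integer()))
  do.call(rbind, out)
}

# maximal valid runs by brute force over every character window
oracle_runs <- function(s, res, min_seed = 2L, max_gap = 1L,
                        max_frac = 0.34) {
  ch <- strsplit(s, "")[[1]]
  L <- length(ch)
  valid <- list()
  for (i in seq_len(L)) {
    for (j in i:L) {
      w <- ch[i:j]
      if (w[1] != res || w[length(w)] != res) next
      r <- rle(w == res)
      if (any(!r$values & r$lengths > max_gap)) next
      ni <- sum(w != res)
      if (ni / length(w) > max_frac) next
      if (max(r$lengths[r$values]) < min_seed) next
      valid[[length(valid) + 1L]] <- c(i, j)
    }
  }
  if (!length(valid)) return(list())
  keep <- vapply(seq_along(valid), function(k) {
    v <- valid[[k]]
    !any(vapply(seq_along(valid), function(k2) {
      if (k2 == k) return(FALSE)
      v2 <- valid[[k2]]
      v2[1] <= v[1] && v2[2] >= v[2]
    }, logical(1)))
  }, logical(1))
  kept <- valid[keep]
  kept <- kept[order(vapply(kept, `[`, numeric(1), 1))]
  lapply(kept, function(v) {
    w <- ch[v[1]:v[2]]
    list(start = v[1] - 1L, end = v[2], count = sum(w == res))
  })
}

# maximal uninterrupted homopolymer runs of `res` with length >= min_seed
oracle_homopolymer <- function(s, res, min_seed = 2L) {
  r <- rle(strsplit(s, "")[[1]] == res)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  i <- which(r$values & r$lengths >= min_seed)
  lapply(i, function(k) list(start = starts[k], end = ends[k],
                             count = r$lengths[k]))
}

# exhaustive parsimony: minimum change count over every assignment of
# states to internal nodes
oracle_parsimony <- function(phy, leaf_states, n_states = 4L,
                             ordered = FALSE) {
  ntip <- length(phy$tip.label)
  nint <- phy$Nnode
  edges <- phy$edge
  st <- integer(ntip + nint)
  st[seq_len(ntip)] <- leaf_states[phy$tip.label]
  grid <- as.matrix(expand.grid(rep(list(seq_len(n_states)), nint)))
  best <- Inf
  for (g in seq_len(nrow(grid))) {
    st[(ntip + 1L):(ntip + nint)] <- grid[g, ]
    cost <- if (ordered) {
      sum(abs(st[edges[, 1]] - st[edges[, 2]]))
    } else {
      sum(st[edges[, 1]] != st[edges[, 2]])
    }
    if (cost < best) best <- cost
  }
  best
}

# closed-form squared Pearson correlation
oracle_r2 <- function(x, y) {
  n <- length(x)
  sxy <- sum(x * y) - sum(x) * sum(y) / n
  sxx <- sum(x^2) - sum(x)^2 / n
  syy <- sum(y^2) - sum(y)^2 / n
  (sxy / sqrt(sxx * syy))^2
}
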