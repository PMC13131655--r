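# Independent brute-force oracles. Every oracle works base-by-base (or by
# exhaustive enumeration) and shares no code with the implementation.

# per-base reciprocal overlap of two intervals
oracle_reciprocal <- function(a, b) {
  if (a$chrom != b$chrom) return(c(0, 0))
  ba <- seq(a$start, a$end - 1)
  bb <- seq(b$start, b$end - 1)
  ov <- length(intersect(ba, bb))
  c(ov / length(ba), ov / length(bb))
}

# naive repeated pairwise merging under the strict-gap rule
oracle_merge <- function(x, max_gap, key = NULL) {
  k <- if (is.null(key)) rep("", nrow(x)) else as.character(x[[key]])
  iv <- lapply(seq_len(nrow(x)), function(i) {
    list(chrom = x$chrom[i], key = k[i], start = x$start[i], end = x$end[i])
  })
  dead <- rep(FALSE, length(iv))
  repeat {
    merged_any <- FALSE
    for (i in seq_along(iv)) {
      if (dead[i]) next
      for (j in seq_along(iv)) {
        if (i == j || dead[i] || dead[j]) next
        a <- iv[[i]]; b <- iv[[j]]
        if (a$chrom != b$chrom || a$key != b$key) next
        gap <- max(a$start, b$start) - min(a$end, b$end)
        if (gap < max_gap) {
          iv[[i]] <- list(chrom = a$chrom, key = a$key,
                          start = min(a$start, b$start),
                          end = max(a$end, b$end))
          dead[j] <- TRUE
          merged_any <- TRUE
        }
      }
    }
    if (!merged_any) break
  }
  iv <- iv[!dead]
  out <- do.call(rbind, lapply(iv, function(v) {
    data.frame(chrom = v$chrom, key = v$key, start = v$start, end = v$end)
  }))
  out[order(out$chrom, out$key, out$start), c("chrom", "key", "start", "end")]
}

# per-base winner-by-score bitmap; ties by earlier start then input order
oracle_resolve_bitmap <- function(hits, chrom_len) {
  out <- list()
  for (ch in unique(hits$chrom)) {
    winner <- rep(NA_integer_, chrom_len)
    idx <- which(hits$chrom == ch)
    for (i in idx) {
      for (p in seq(hits$start[i] + 1, hits$end[i])) {  # 1-based base index
        w <- winner[p]
        if (is.na(w)) { winner[p] <- i; next }
        better <- hits$score[i] > hits$score[w] ||
          (hits$score[i] == hits$score[w] && hits$start[i] < hits$start[w]) ||
          (hits$score[i] == hits$score[w] && hits$start[i] == hits$start[w] &&
             i < w)
        if (better) winner[p] <- i
      }
    }
    out[[ch]] <- winner
  }
  out
}

# resolved hits -> per-base winner map for comparison
resolved_to_bitmap <- function(res, chroms, chrom_len) {
  out <- list()
  for (ch in chroms) {
    winner <- rep(NA_integer_, chrom_len)
    idx <- which(res$chrom == ch)
    for (i in idx) {
      winner[seq(res$start[i] + 1, res$end[i])] <- res$source_row[i]
    }
    out[[ch]] <- winner
  }
  out
}

# bitmap union coverage of a window
oracle_fraction <- function(window, annotation) {
  bases <- seq(window$start, window$end - 1)
  cov <- rep(FALSE, length(bases))
  ann <- annotation[annotation$chrom == window$chrom, , drop = FALSE]
  for (i in seq_len(nrow(ann))) {
    cov <- cov | (bases >= ann$start[i] & bases < ann$end[i])
  }
  mean(cov)
}

# exhaustive-scan nearest distance
oracle_distance <- function(x, targets) {
  tt <- targets[targets$chrom == x$chrom, , drop = FALSE]
  if (nrow(tt) == 0) return(NA_real_)
  d <- numeric(nrow(tt))
  for (i in seq_len(nrow(tt))) {
    if (tt$start[i] < x$end && tt$end[i] > x$start) d[i] <- 0
    else d[i] <- max(tt$start[i] - x$end, x$start - tt$end[i])
  }
  min(d)
}

# exact one-sided rank-sum p by full enumeration of group assignments
oracle_wilcoxon_enum <- function(x, y) {
  n <- length(x); m <- length(y)
  vals <- c(x, y)
  r <- rank(vals)
  u_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  combs <- utils::combn(n + m, n)
  u_all <- apply(combs, 2, function(id) sum(r[id]) - n * (n + 1) / 2)
  mean(u_all <= u_obs)
}

# does the unrooted tree have a bipartition separating exactly `tips`?
# independent route: drop each internal edge and flood-fill the two halves
oracle_bipartition <- function(phy, tips) {
  ntip <- length(phy$tip.label)
  target <- sort(match(tips, phy$tip.label))
  if (length(target) == 1) return(TRUE)
  if (length(target) >= ntip) return(FALSE)
  edges <- phy$edge
  nn <- max(edges)
  for (k in seq_len(nrow(edges))) {
    adj <- lapply(seq_len(nn), function(i) integer(0))
    for (j in seq_len(nrow(edges))) {
      if (j == k) next
      a <- edges[j, 1]; b <- edges[j, 2]
      adj[[a]] <- c(adj[[a]], b); adj[[b]] <- c(adj[[b]], a)
    }
    comp <- rep(NA_integer_, nn)
    for (root in edges[k, ]) {
      lab <- edges[k, 1] == root
      stack <- root
      while (length(stack)) {
        v <- stack[length(stack)]; stack <- stack[-length(stack)]
        if (!is.na(comp[v])) next
        comp[v] <- as.integer(lab)
        stack <- c(stack, adj[[v]])
      }
    }
    side1 <- sort(which(comp[seq_len(ntip)] == 1))
    side0 <- sort(which(comp[seq_len(ntip)] == 0))
    if (identical(side1, target) || identical(side0, target)) return(TRUE)
  }
  FALSE
}

# brute-force best tandem token repeat (copies x length, ties: more copies,
# then earlier start)
oracle_tandem <- function(tok, is_gene) {
  n <- length(tok)
  best <- list(score = 0, copies = 0, first = Inf, unit = NULL)
  for (L in 2:floor(n / 2)) {
    for (i in 1:(n - 2 * L + 1)) {
      if (sum(is_gene[i:(i + L - 1)]) < 2) next
      k <- 1
      while (i + (k + 1) * L - 1 <= n &&
             all(tok[(i + k * L):(i + (k + 1) * L - 1)] ==
                   tok[i:(i + L - 1)])) k <- k + 1
      if (k < 2) next
      s <- k * L
      if (s > best$score || (s == best$score && k > best$copies) ||
          (s == best$score && k == best$copies && i < best$first)) {
        best <- list(score = s, copies = k, first = i,
                     unit = tok[i:(i + L - 1)])
      }
    }
  }
  best
}

# all maximal strictly-alternating runs of a strand string (enumeration)
oracle_alternating <- function(strands, min_run) {
  n <- length(strands)
  runs <- list()
  for (i in seq_len(n)) {
    for (j in i:n) {
      ok <- j == i || all(strands[(i + 1):j] != strands[i:(j - 1)])
      if (!ok) next
      # maximal: cannot extend left or right while staying alternating
      left_ext <- i > 1 && strands[i - 1] != strands[i]
      right_ext <- j < n && strands[j + 1] != strands[j]
      if (!left_ext && !right_ext && (j - i + 1) >= min_run) {
        runs[[length(runs) + 1]] <- c(i, j)
      }
    }
  }
  runs
}
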