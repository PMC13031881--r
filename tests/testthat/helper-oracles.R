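## Independent brute-force oracles used to validate the fast implementations.
## These are deliberately written from the definitions, not from the package
## code paths: plain loops over integer coordinates.

## Proximity label of one interval against a reference set: base-by-base
## definitions on 1-based closed coordinates.
oracleProximity <- function(qs, qe, rs, re, d) {
  if (length(rs) == 0L) return("distal")
  overlap <- any(qs <= re & qe >= rs)
  if (overlap) return("overlapping")
  gap <- pmin(abs(rs - qe), abs(qs - re)) - 1L
  if (min(gap) <= d) "proximal" else "distal"
}

## Connected components of sorted positions where any pair within dMax links
## them (equivalent to the adjacency-run definition, derived differently via
## union-find over all pairs).
oracleClusters <- function(positions, dMax) {
  n <- length(positions)
  if (n == 0L) return(list())
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && abs(positions[i] - positions[j]) <= dMax) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- split(positions, roots)
  Filter(function(x) length(x) >= 2L, lapply(comps, sort))
}

## Exhaustive G4Hunter window scan: per-base run scores computed by explicit
## position-wise run measurement (no rle/cumsum), every window averaged by
## direct summation, then the documented merge rule applied by loop.
oracleG4Windows <- function(chars, window, threshold) {
  n <- length(chars)
  if (n < window) return(NULL)
  base <- numeric(n)
  for (i in seq_len(n)) {
    b <- chars[i]
    if (b == "G" || b == "C") {
      lo <- i; while (lo > 1L && chars[lo - 1L] == b) lo <- lo - 1L
      hi <- i; while (hi < n && chars[hi + 1L] == b) hi <- hi + 1L
      L <- min(hi - lo + 1L, 4L)
      base[i] <- if (b == "G") L else -L
    }
  }
  means <- vapply(seq_len(n - window + 1L), function(i)
    sum(base[i:(i + window - 1L)]) / window, 0)
  hit <- which(abs(means) >= threshold)
  if (!length(hit)) return(NULL)
  sg <- ifelse(means[hit] > 0, "+", "-")
  out <- NULL
  cs <- hit[1]; ce <- hit[1] + window - 1L; csg <- sg[1]
  for (k in seq_along(hit)[-1]) {
    if (sg[k] == csg && hit[k] <= ce + window) {
      ce <- hit[k] + window - 1L
    } else {
      out <- rbind(out, data.frame(start = cs, end = ce, strand = csg))
      cs <- hit[k]; ce <- hit[k] + window - 1L; csg <- sg[k]
    }
  }
  rbind(out, data.frame(start = cs, end = ce, strand = csg))
}

## Consensus peaks by explicit pairwise overlap graph + union-find, then a
## sort-and-sweep merge; independent of the reduce()-based implementation.
oracleConsensus <- function(starts, ends, strands, reps, minRec,
                            mergeWithin, stranded) {
  n <- length(starts)
  if (n == 0L) return(NULL)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i < j && starts[i] <= ends[j] && ends[i] >= starts[j] &&
        (!stranded || strands[i] == strands[j])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[ri] <- rj
    }
  }
  roots <- vapply(seq_len(n), find, 0L)
  comps <- unique(roots)
  kept <- NULL
  for (cp in comps) {
    idx <- which(roots == cp)
    if (length(unique(reps[idx])) >= minRec) {
      kept <- rbind(kept, data.frame(
        start = min(starts[idx]), end = max(ends[idx]),
        strand = if (stranded) strands[idx][1] else "*"))
    }
  }
  if (is.null(kept)) return(NULL)
  merged <- NULL
  for (sg in unique(kept$strand)) {
    k <- kept[kept$strand == sg, , drop = FALSE]
    k <- k[order(k$start, k$end), , drop = FALSE]
    cs <- k$start[1]; ce <- k$end[1]
    for (i in seq_len(nrow(k))[-1]) {
      if (k$start[i] - ce - 1L <= mergeWithin) {
        ce <- max(ce, k$end[i])
      } else {
        merged <- rbind(merged, data.frame(start = cs, end = ce,
                                           strand = sg))
        cs <- k$start[i]; ce <- k$end[i]
      }
    }
    merged <- rbind(merged, data.frame(start = cs, end = ce, strand = sg))
  }
  merged[order(merged$start, merged$end, merged$strand), , drop = FALSE]
}

## Exact hypergeometric upper tail by direct enumeration.
oracleHyper <- function(overlap, setSize, universe, nHits) {
  ks <- overlap:min(setSize, nHits)
  sum(choose(setSize, ks) * choose(universe - setSize, nHits - ks)) /
    choose(universe, nHits)
}

## Reverse complement for character strings.
rcStr <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
                ""))
}
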