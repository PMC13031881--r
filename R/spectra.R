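## Mutation spectrum analysis: pyrimidine-normalised trinucleotide
## classification, 96-channel spectra, KL-NMF signature extraction, cosine
## similarity and clustered-hypermutation (omikli/kataegis) detection.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

#' Canonical 96-channel order
#'
#' Channels are ordered by substitution class (C>A, C>G, C>T, T>A, T>C, T>G),
#' then 5' flank, then 3' flank, each alphabetical — the COSMIC convention.
#'
#' @return Character vector of 96 channel keys, e.g. \code{"A[C>A]A"}.
#' @export
spectrumChannels <- function() {
  flanks <- c("A", "C", "G", "T")
  unlist(lapply(SUBSTITUTION_CLASSES, function(cl)
    unlist(lapply(flanks, function(l)
      paste0(l, "[", cl, "]", flanks)))))
}

revcompChar <- function(x) {
  chartr("ACGT", "TGCA",
         vapply(strsplit(x, ""), function(s) paste(rev(s), collapse = ""),
                ""))
}

#' Classify substitutions in trinucleotide context
#'
#' Purine-centred substitutions are reverse-complemented to the pyrimidine
#' convention.  \code{is_TCW} is true iff the normalised context is
#' \code{T[C>N]A} or \code{T[C>N]T} (the APOBEC hotspot); \code{is_CpG} iff
#' the normalised centre is C with a 3' G.  The pyrimidine strand records
#' which genomic strand carries the pyrimidine of the normalised change.
#'
#' @param muts width-1 \code{GRanges} with \code{ref} and \code{alt} columns.
#' @param genome named \code{DNAStringSet}.
#' @return A \code{DataFrame} with columns \code{class}, \code{channel},
#'   \code{is_TCW}, \code{is_CpG}, \code{pyr_strand}.
#' @examples
#' g <- Biostrings::DNAStringSet(c(chr1 = "ATCAG"))
#' m <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3, 3),
#'                             ref = "C", alt = "T")
#' classifySubstitution(m, g)
#' @export
classifySubstitution <- function(muts, genome) {
  if (length(muts) == 0L)
    return(DataFrame(class = character(), channel = character(),
                     is_TCW = logical(), is_CpG = logical(),
                     pyr_strand = character()))
  sl <- genomeSeqlengths(genome)
  ctg <- as.character(seqnames(muts))
  pos <- start(muts)
  if (any(pos < 2L | pos > sl[ctg] - 1L))
    stop("mutation at contig edge (position ",
         paste(pos[pos < 2L | pos > sl[ctg] - 1L][1]),
         "): trinucleotide context undefined")
  ctx <- vapply(seq_along(muts), function(i)
    as.character(subseq(genome[[ctg[i]]], pos[i] - 1L, pos[i] + 1L)), "")
  ref <- toupper(mcols(muts)$ref)
  alt <- toupper(mcols(muts)$alt)
  bad <- substr(ctx, 2L, 2L) != ref
  if (any(bad))
    stop("reference mismatch at ", ctg[bad][1], ":", pos[bad][1],
         " (genome ", substr(ctx[bad][1], 2L, 2L), ", record ",
         ref[bad][1], ")")
  if (any(ref == alt)) stop("ref equals alt for some records")
  isPurine <- ref %in% c("A", "G")
  nctx <- ifelse(isPurine, revcompChar(ctx), ctx)
  nref <- ifelse(isPurine, chartr("ACGT", "TGCA", ref), ref)
  nalt <- ifelse(isPurine, chartr("ACGT", "TGCA", alt), alt)
  cls <- paste0(nref, ">", nalt)
  l <- substr(nctx, 1L, 1L)
  r <- substr(nctx, 3L, 3L)
  DataFrame(
    class = cls,
    channel = paste0(l, "[", cls, "]", r),
    is_TCW = nref == "C" & l == "T" & r %in% c("A", "T"),
    is_CpG = nref == "C" & r == "G",
    pyr_strand = ifelse(isPurine, "-", "+"))
}

#' Build 96-channel spectra and a 7-class summary
#'
#' Counts are conserved: every classified SNV lands in exactly one channel.
#' The summary splits C>T into CpG and non-CpG, giving seven classes.
#'
#' @param muts width-1 \code{GRanges} with \code{ref}, \code{alt} and
#'   optionally \code{sample} metadata columns.
#' @param genome named \code{DNAStringSet}.
#' @return A list: \code{spectrum} (96 x samples integer matrix in canonical
#'   channel order), \code{summary} (7 x samples matrix with C>T split by CpG
#'   status), \code{classification} (per-mutation \code{DataFrame}).
#' @export
build96Spectrum <- function(muts, genome) {
  cl <- classifySubstitution(muts, genome)
  sample <- if (!is.null(mcols(muts)$sample)) as.character(mcols(muts)$sample)
            else rep("sample1", length(muts))
  channels <- spectrumChannels()
  samples <- sort(unique(sample))
  if (!length(samples)) samples <- "sample1"
  spectrum <- matrix(0L, 96L, length(samples),
                     dimnames = list(channels, samples))
  if (length(muts)) {
    tab <- table(factor(cl$channel, levels = channels),
                 factor(sample, levels = samples))
    spectrum <- matrix(as.integer(tab), 96L, length(samples),
                       dimnames = list(channels, samples))
  }
  sumClasses <- c("C>A", "C>G", "C>T_CpG", "C>T_other",
                  "T>A", "T>C", "T>G")
  key <- ifelse(cl$class == "C>T", ifelse(cl$is_CpG, "C>T_CpG", "C>T_other"),
                cl$class)
  stab <- table(factor(key, levels = sumClasses),
                factor(sample, levels = samples))
  summary <- matrix(as.integer(stab), length(sumClasses), length(samples),
                    dimnames = list(sumClasses, samples))
  list(spectrum = spectrum, summary = summary, classification = cl)
}

#' Cosine similarity between non-negative spectra
#'
#' Scale-invariant and symmetric; errors on zero vectors.
#'
#' @param a,b numeric vectors of equal length.
#' @return The cosine of the angle between \code{a} and \code{b}.
#' @examples
#' cosineSimilarity(c(1, 1, 0), c(1, 0, 0))  # 1/sqrt(2)
#' @export
cosineSimilarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors must have equal length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

## Generalised KL divergence D(V || WH), the NMF objective.
klDivergence <- function(V, WH, eps = 1e-10) {
  WH <- pmax(WH, eps)
  pos <- V > 0
  sum(V[pos] * log(V[pos] / WH[pos])) - sum(V) + sum(WH)
}

#' De novo signature extraction by KL-NMF
#'
#' Multiplicative-update non-negative matrix factorisation minimising the
#' generalised Kullback-Leibler divergence, the standard model for mutation
#' count matrices.  The best of \code{nRestarts} random restarts (ties broken
#' by lowest restart index) is returned; signature columns are normalised to
#' sum 1 with exposures rescaled accordingly.  The objective is non-increasing
#' per iteration.
#'
#' @param V non-negative matrix, channels x samples (typically 96 x n).
#' @param k rank (number of signatures); must be < min(dim(V)).
#' @param seed integer seed.
#' @param nRestarts random restarts (default 20).
#' @param maxIter maximal multiplicative updates per restart (default 200).
#' @param tol relative objective-change tolerance for early stop (1e-6).
#' @return A list: \code{signatures} (channels x k, columns sum to 1),
#'   \code{exposures} (k x samples), \code{divergence} (final objective),
#'   \code{objective} (per-iteration trace of the winning restart),
#'   \code{restart} (winning restart index).
#' @export
extractSignaturesNMF <- function(V, k, seed = 1L, nRestarts = 20L,
                                 maxIter = 200L, tol = 1e-6) {
  V <- as.matrix(V)
  if (any(V < 0)) stop("V must be non-negative")
  if (sum(V) == 0) stop("V is all zero")
  if (k >= min(dim(V))) stop("rank k must be < min(dim(V))")
  eps <- 1e-10
  best <- NULL
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nRestarts)
  for (r in seq_len(nRestarts)) {
    set.seed(seeds[r])
    W <- matrix(runif(nrow(V) * k, 0.1, 1), nrow(V), k)
    H <- matrix(runif(k * ncol(V), 0.1, 1), k, ncol(V))
    H <- H * sum(V) / sum(W %*% H)
    obj <- numeric(0)
    prev <- Inf
    for (it in seq_len(maxIter)) {
      WH <- pmax(W %*% H, eps)
      W <- W * ((V / WH) %*% t(H)) /
        pmax(matrix(rowSums(H), nrow(V), k, byrow = TRUE), eps)
      WH <- pmax(W %*% H, eps)
      H <- H * (t(W) %*% (V / WH)) / pmax(matrix(colSums(W), k, ncol(V)), eps)
      d <- klDivergence(V, W %*% H, eps)
      obj <- c(obj, d)
      if (is.finite(prev) && abs(prev - d) <= tol * max(1, abs(prev))) {
        prev <- d
        break
      }
      prev <- d
    }
    if (is.null(best) || prev < best$divergence - 1e-12) {
      best <- list(W = W, H = H, divergence = prev, objective = obj,
                   restart = r)
    }
  }
  colScale <- colSums(best$W)
  colScale[colScale == 0] <- 1
  W <- sweep(best$W, 2L, colScale, "/")
  H <- sweep(best$H, 1L, colScale, "*")
  colnames(W) <- rownames(H) <- paste0("signature_", seq_len(k))
  rownames(W) <- rownames(V)
  colnames(H) <- colnames(V)
  list(signatures = W, exposures = H, divergence = best$divergence,
       objective = best$objective, restart = best$restart)
}

#' Per-mutation intermutation distance
#'
#' Distance (bp) to the nearest preceding mutation of the same sample on the
#' same contig; the first mutation of each contig/sample has \code{NA}.
#'
#' @param muts width-1 \code{GRanges}; optional \code{sample} column.
#' @return Integer vector parallel to \code{muts} (input order preserved).
#' @export
intermutationDistance <- function(muts) {
  n <- length(muts)
  imd <- rep(NA_integer_, n)
  if (n == 0L) return(imd)
  sample <- if (!is.null(mcols(muts)$sample)) as.character(mcols(muts)$sample)
            else rep("sample1", n)
  key <- paste(sample, as.character(seqnames(muts)))
  ord <- order(key, start(muts))
  pos <- start(muts)[ord]
  kk <- key[ord]
  d <- c(NA_integer_, diff(pos))
  d[c(TRUE, kk[-1] != kk[-length(kk)])] <- NA_integer_
  imd[ord] <- d
  imd
}

#' Detect clustered hypermutation (omikli/kataegis)
#'
#' Clusters are maximal runs of consecutive same-sample mutations on one
#' contig whose adjacent intermutation distances are all <= \code{dMax}
#' (strict).  Runs of size 2-4 are classed \code{omikli}, size >= 5
#' \code{kataegis} — a transparent adjacency rule standing in for heavier
#' cluster callers.  Per-sample significance of the observed cluster count is
#' assessed by permuting that sample's mutation positions uniformly within
#' the callable regions: \code{p = (1 + #perm >= observed) / (1 + nPerm)}.
#'
#' @param muts width-1 \code{GRanges} with optional \code{sample} column;
#'   auto-sorted with a warning if unsorted.
#' @param callable \code{GRanges} of callable regions (must cover all
#'   mutations) used for the permutation null.
#' @param dMax adjacency threshold in bp (default 1000).
#' @param nPerm permutations per sample (default 1000).
#' @param seed integer seed for the permutation null.
#' @return A list: \code{clusters} (data.frame with sample, contig, start,
#'   end, size, span, class and member positions as a comma string) and
#'   \code{perSample} (data.frame with cluster counts by class and the
#'   empirical p-value).
#' @export
detectClusters <- function(muts, callable, dMax = 1000L, nPerm = 1000L,
                           seed = 1L) {
  emptyClusters <- data.frame(
    sample = character(), contig = character(), start = integer(),
    end = integer(), size = integer(), span = integer(),
    class = character(), members = character(), stringsAsFactors = FALSE)
  if (length(muts) == 0L)
    return(list(clusters = emptyClusters,
                perSample = data.frame(sample = character(),
                                       n_omikli = integer(),
                                       n_kataegis = integer(),
                                       n_clusters = integer(),
                                       p = numeric())))
  sample <- if (!is.null(mcols(muts)$sample)) as.character(mcols(muts)$sample)
            else rep("sample1", length(muts))
  inOrder <- order(as.character(seqnames(muts)), start(muts))
  if (is.unsorted(inOrder))
    warning("mutations were not sorted; sorting by (contig, position)")
  ord <- order(sample, as.character(seqnames(muts)), start(muts))
  pos <- start(muts)[ord]
  ctg <- as.character(seqnames(muts))[ord]
  smp <- sample[ord]

  runsOf <- function(positions) {
    ## cluster membership run ids for sorted positions on one contig
    if (length(positions) == 0L) return(integer(0))
    brk <- c(TRUE, diff(positions) > dMax)
    cumsum(brk)
  }
  clusters <- list()
  key <- paste(smp, ctg, sep = "\r")
  for (k in unique(key)) {
    sel <- key == k
    p <- pos[sel]
    run <- runsOf(p)
    sizes <- tabulate(run)
    for (ri in which(sizes >= 2L)) {
      mem <- p[run == ri]
      clusters[[length(clusters) + 1L]] <- data.frame(
        sample = smp[sel][1], contig = ctg[sel][1],
        start = min(mem), end = max(mem),
        size = length(mem), span = max(mem) - min(mem),
        class = if (length(mem) >= 5L) "kataegis" else "omikli",
        members = paste(mem, collapse = ","),
        stringsAsFactors = FALSE)
    }
  }
  clusters <- if (length(clusters)) do.call(rbind, clusters)
              else emptyClusters

  ## permutation null on per-sample cluster counts
  if (any(!overlapsAny(muts, callable, ignore.strand = TRUE)))
    stop("callable regions must cover all mutations")
  callable <- reduce(callable, ignore.strand = TRUE)
  cw <- as.numeric(width(callable))
  cumw <- cumsum(cw)
  total <- sum(cw)
  countClusters <- function(positions, contigs) {
    n <- 0L
    for (ct in unique(contigs)) {
      p <- sort(positions[contigs == ct])
      run <- runsOf(p)
      n <- n + sum(tabulate(run) >= 2L)
    }
    n
  }
  set.seed(seed)
  perSample <- lapply(unique(smp), function(s) {
    sel <- smp == s
    obs <- sum(clusters$sample == s)
    nmut <- sum(sel)
    ge <- 0L
    for (b in seq_len(nPerm)) {
      offs <- sample.int(total, nmut, replace = TRUE)
      idx <- findInterval(offs - 1, c(0, cumw))
      permPos <- start(callable)[idx] + (offs - 1) - c(0, cumw)[idx]
      permCtg <- as.character(seqnames(callable))[idx]
      if (countClusters(permPos, permCtg) >= obs) ge <- ge + 1L
    }
    data.frame(sample = s,
               n_omikli = sum(clusters$sample == s &
                                clusters$class == "omikli"),
               n_kataegis = sum(clusters$sample == s &
                                  clusters$class == "kataegis"),
               n_clusters = obs,
               p = (1 + ge) / (1 + nPerm),
               stringsAsFactors = FALSE)
  })
  list(clusters = clusters, perSample = do.call(rbind, perSample))
}
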