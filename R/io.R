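## On-disk format handling.  All disk conventions are the field's standard
## ones: BED/bedGraph 0-based half-open (delegated to rtracklayer), VCF
## 1-based (written here, read back through VariantAnnotation), FASTA wrapped
## at 60 columns.  In memory everything is 1-based closed GRanges; the
## conversion lives only in this file.

#' Write a genome to FASTA
#'
#' @param genome a named \code{DNAStringSet}.
#' @param path output file; wrapped at 60 columns.
#' @return \code{path}, invisibly.
#' @export
writeGenomeFasta <- function(genome, path) {
  writeXStringSet(genome, filepath = path, width = 60L)
  invisible(path)
}

#' Read a genome FASTA
#'
#' @param path FASTA file.
#' @return A named \code{DNAStringSet}; names are truncated at the first
#'   whitespace.
#' @export
readGenomeFasta <- function(path) {
  genome <- readDNAStringSet(path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  genome
}

## seqlengths helper for a DNAStringSet genome
genomeSeqlengths <- function(genome) {
  setNames(Biostrings::width(genome), names(genome))
}

#' Write stranded intervals to BED6
#'
#' @param gr a \code{GRanges}; \code{name} and \code{score} metadata columns
#'   are used when present.
#' @param path output BED file (0-based half-open on disk).
#' @return \code{path}, invisibly.
#' @export
writeBed6 <- function(gr, path) {
  if (is.null(mcols(gr)$name))
    mcols(gr)$name <- sprintf("feature_%05d", seq_along(gr))
  if (is.null(mcols(gr)$score)) mcols(gr)$score <- 0
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}

#' Read a BED file into GRanges
#'
#' @param path BED file.
#' @param seqlengths optional named integer vector to attach contig lengths.
#' @return A \code{GRanges} (1-based closed in memory).
#' @export
readBed <- function(path, seqlengths = NULL) {
  gr <- rtracklayer::import(path, format = "BED")
  if (!is.null(seqlengths)) {
    GenomeInfoDb::seqlevels(gr) <- names(seqlengths)
    GenomeInfoDb::seqlengths(gr) <- seqlengths
  }
  gr
}

#' Export a BinnedTrack to bedGraph
#'
#' Missing bins are omitted from the file (bedGraph is sparse by design).
#'
#' @param track a [BinnedTrack-class].
#' @param path output bedGraph file.
#' @return \code{path}, invisibly.
#' @export
writeBedGraph <- function(track, path) {
  gr <- trackAsGRanges(track, dropMissing = TRUE)
  rtracklayer::export(gr, path, format = "bedGraph")
  invisible(path)
}

#' Read a bedGraph file into a BinnedTrack
#'
#' @param path bedGraph file whose intervals are aligned to a fixed bin grid.
#' @param binWidth the bin width of that grid (bp).
#' @param seqlengths named integer vector of contig lengths.
#' @return A [BinnedTrack-class]; bins absent from the file are \code{NA}.
#' @export
readBedGraphTrack <- function(path, binWidth, seqlengths) {
  gr <- rtracklayer::import(path, format = "bedGraph")
  values <- lapply(setNames(names(seqlengths), names(seqlengths)),
                   function(ctg) {
    n <- ceiling(seqlengths[[ctg]] / binWidth)
    v <- rep(NA_real_, n)
    sel <- as.character(seqnames(gr)) == ctg
    if (any(sel)) {
      idx <- (start(gr)[sel] - 1L) %/% binWidth + 1L
      v[idx] <- mcols(gr)$score[sel]
    }
    v
  })
  binnedTrack(values, binWidth, seqlengths)
}

#' Convert a BinnedTrack to bin-level GRanges
#'
#' @param track a [BinnedTrack-class].
#' @param dropMissing drop \code{NA} bins?
#' @return A \code{GRanges} with one range per bin and a \code{score} column.
#' @export
trackAsGRanges <- function(track, dropMissing = FALSE) {
  bw <- track@binWidth
  pieces <- lapply(names(track@values), function(ctg) {
    v <- track@values[[ctg]]
    n <- length(v)
    starts <- (seq_len(n) - 1L) * bw + 1L
    ends <- pmin(seq_len(n) * bw, track@seqlengths[[ctg]])
    GRanges(ctg, IRanges(starts, ends), score = v,
            seqlengths = track@seqlengths)
  })
  gr <- do.call(c, pieces)
  if (dropMissing) gr <- gr[!is.na(mcols(gr)$score)]
  gr
}

#' Write point mutations to a minimal VCF v4.2
#'
#' Positions are 1-based per the VCF convention; the sample identifier is
#' carried in the INFO field as \code{SAMPLE=}.  An empty mutation set yields
#' a valid header-only VCF.
#'
#' @param muts a \code{GRanges} of width-1 ranges with metadata columns
#'   \code{ref}, \code{alt} and \code{sample}.
#' @param path output VCF file.
#' @param seqlengths named contig lengths for the header.
#' @return \code{path}, invisibly.
#' @export
writeMutationsVcf <- function(muts, path, seqlengths) {
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=rloopedit",
    sprintf("##contig=<ID=%s,length=%d>", names(seqlengths), seqlengths),
    "##INFO=<ID=SAMPLE,Number=1,Type=String,Description=\"Sample identifier\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t")
  )
  lines <- header
  if (length(muts)) {
    body <- paste(as.character(seqnames(muts)), start(muts), ".",
                  mcols(muts)$ref, mcols(muts)$alt, ".", "PASS",
                  paste0("SAMPLE=", mcols(muts)$sample), sep = "\t")
    lines <- c(lines, body)
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read point mutations from VCF
#'
#' Single-nucleotide records only; the \code{SAMPLE} INFO tag (when present)
#' is returned as the \code{sample} column.
#'
#' @param path a VCF file.
#' @return A width-1 \code{GRanges} with \code{ref}, \code{alt}, \code{sample}
#'   metadata columns.
#' @export
readMutationsVcf <- function(path) {
  vcf <- VariantAnnotation::readVcf(path, genome = "synthetic")
  rr <- SummarizedExperiment::rowRanges(vcf)
  ref <- as.character(VariantAnnotation::ref(vcf))
  altList <- VariantAnnotation::alt(vcf)
  alt <- vapply(as.list(altList), function(a) as.character(a)[1], "")
  info <- VariantAnnotation::info(vcf)
  sample <- if ("SAMPLE" %in% colnames(info)) as.character(info$SAMPLE)
            else rep("sample1", length(rr))
  gr <- GRanges(seqnames(rr), IRanges(start(rr), width = 1L),
                ref = ref, alt = alt, sample = sample)
  keep <- nchar(mcols(gr)$ref) == 1L & nchar(mcols(gr)$alt) == 1L
  gr[keep]
}

#' Write a data frame as TSV
#'
#' @param df a data.frame.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeTsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a TSV written by [writeTsv()]
#'
#' @param path input file.
#' @return A data.frame.
#' @export
readTsv <- function(path) {
  read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
             check.names = FALSE)
}

#' Write a count matrix with a `feature` column
#'
#' @param counts integer matrix, features x samples, with dimnames.
#' @param path output TSV (`feature<TAB>sample...`).
#' @return \code{path}, invisibly.
#' @export
writeCountsTsv <- function(counts, path) {
  df <- data.frame(feature = rownames(counts), counts, check.names = FALSE,
                   stringsAsFactors = FALSE)
  writeTsv(df, path)
}

#' Read a count matrix written by [writeCountsTsv()]
#'
#' @param path input TSV.
#' @return An integer matrix with feature rownames.
#' @export
readCountsTsv <- function(path) {
  df <- readTsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  mode(m) <- "integer"
  rownames(m) <- df[[1]]
  m
}
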