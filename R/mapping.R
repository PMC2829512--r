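## Read placement: an internal ungapped mapper for synthetic data (exact pass
## plus trusted-band passes over Biostrings::matchPDict, pigeonhole-complete
## for the configured mismatch budget) and SAM ingestion for external data.

#' Build a mapping index over a genome
#'
#' The index supports exact-location lookup of every `read_len` window of the
#' genome and its reverse complement, and batch read placement via
#' [map_reads()].
#'
#' @param genome a `genome` object.
#' @param read_len read length the index serves (>= 12).
#' @return a `read_index` object.
#' @export
build_index <- function(genome, read_len) {
  read_len <- as.integer(read_len)
  if (read_len < 12L) stop("read_len must be >= 12")
  if (read_len > min(chrom_lengths(genome)))
    stop("read_len is longer than the shortest chromosome")
  structure(list(genome = genome, read_len = read_len,
                 subjects = Biostrings::DNAStringSet(genome$sequences)),
            class = "read_index")
}

#' Locate a k-mer in an indexed genome
#'
#' @param index a `read_index`.
#' @param kmer a DNA string of the index read length.
#' @return `list(count, hits)` where `hits` has columns `chrom`, `start`,
#'   `strand`; `count` totals occurrences on both strands.
#' @export
lookup_kmer <- function(index, kmer) {
  if (nchar(kmer) != index$read_len) stop("kmer length must equal index read_len")
  pats <- c(`+` = kmer, `-` = revcomp(kmer))
  hits <- list()
  for (ch in names(index$genome$sequences)) {
    subj <- index$subjects[[ch]]
    for (st in names(pats)) {
      m <- Biostrings::matchPattern(pats[[st]], subj)
      if (length(m) > 0)
        hits[[length(hits) + 1L]] <- data.frame(chrom = ch,
                                                start = BiocGenerics::start(m),
                                                strand = st)
    }
  }
  hits <- if (length(hits)) do.call(rbind, hits) else
    data.frame(chrom = character(), start = integer(), strand = character())
  list(count = nrow(hits), hits = hits)
}

# Collect (read index, chrom, strand, start) hits from one matchPDict call.
mindex_hits <- function(m, chrom, strand) {
  k <- S4Vectors::elementNROWS(m)
  if (sum(k) == 0)
    return(data.frame(read = integer(), chrom = character(),
                      strand = character(), start = integer()))
  ir <- unlist(m, use.names = FALSE)
  data.frame(read = rep(seq_along(k), k), chrom = chrom, strand = strand,
             start = BiocGenerics::start(ir))
}

# Count mismatches between reference-oriented read sequences and the reference
# windows they claim, via a raw-byte comparison.
count_mismatches <- function(oriented, chromseq, starts, read_len) {
  if (length(oriented) == 0) return(integer(0))
  refwin <- substring(chromseq, starts, starts + read_len - 1L)
  a <- charToRaw(paste(oriented, collapse = ""))
  b <- charToRaw(paste(refwin, collapse = ""))
  d <- a != b
  as.integer(rowsum(as.integer(d), rep(seq_along(oriented), each = read_len))[, 1])
}

#' Map a batch of reads to the reference
#'
#' Ungapped placement on either strand with at most `max_mismatches`
#' substitutions. Every read receives its best placement set: a unique best
#' placement gives class `unique-high`; two or more equally good placements
#' give class `multi-zero` (recorded at the lexicographically first placement
#' but excluded from pileups, mirroring mapping-quality filtering); reads with
#' no qualifying placement enter the unmapped pool.
#'
#' The search is exhaustive: an exact pass resolves error-free reads, and
#' `max_mismatches + 1` trusted-band passes cover every placement with at
#' most `max_mismatches` mismatches (pigeonhole).
#'
#' @param reads data frame with columns `id`, `seq` (all of the index read
#'   length), or a character vector of sequences.
#' @param index a `read_index`.
#' @param max_mismatches mismatch budget (default 2).
#' @return `list(alignments, unmapped)`: `alignments` has columns `read_id`,
#'   `chrom`, `start`, `strand`, `mismatches`, `mapq_class`, `seq`
#'   (reference-oriented); `unmapped` has columns `id`, `seq`.
#' @export
map_reads <- function(reads, index, max_mismatches = 2L) {
  if (is.character(reads)) reads <- data.frame(id = paste0("r", seq_along(reads)),
                                               seq = reads)
  L <- index$read_len
  if (!all(nchar(reads$seq) == L))
    stop("all reads must have length equal to the index read_len")
  n <- nrow(reads)
  empty_aln <- data.frame(read_id = character(), chrom = character(),
                          start = integer(), strand = character(),
                          mismatches = integer(), mapq_class = character(),
                          seq = character())
  if (n == 0) return(list(alignments = empty_aln,
                          unmapped = data.frame(id = character(), seq = character())))

  fwd <- Biostrings::DNAStringSet(reads$seq)
  rev <- Biostrings::reverseComplement(fwd)
  chroms <- names(index$genome$sequences)

  run_pass <- function(sub_idx, tb = NULL, max_mm = 0L) {
    out <- list()
    for (st in c("+", "-")) {
      pats <- if (st == "+") fwd[sub_idx] else rev[sub_idx]
      pd <- if (is.null(tb)) Biostrings::PDict(pats) else
        Biostrings::PDict(pats, tb.start = tb[1], tb.end = tb[2])
      for (ch in chroms) {
        m <- Biostrings::matchPDict(pd, index$subjects[[ch]], max.mismatch = max_mm)
        h <- mindex_hits(m, ch, st)
        if (nrow(h) > 0) {
          h$read <- sub_idx[h$read]
          out[[length(out) + 1L]] <- h
        }
      }
    }
    if (length(out)) do.call(rbind, out) else NULL
  }

  # exact pass
  hits0 <- run_pass(seq_len(n))
  if (!is.null(hits0)) hits0$mm <- 0L
  resolved <- if (is.null(hits0)) integer(0) else unique(hits0$read)

  # inexact passes for the rest
  hits2 <- NULL
  todo <- setdiff(seq_len(n), resolved)
  if (max_mismatches > 0 && length(todo) > 0) {
    nb <- max_mismatches + 1L
    cuts <- floor(seq(0, L, length.out = nb + 1L))
    parts <- lapply(seq_len(nb), function(i) c(cuts[i] + 1L, cuts[i + 1L]))
    hh <- list()
    for (tb in parts) {
      h <- run_pass(todo, tb = tb, max_mm = max_mismatches)
      if (!is.null(h)) hh[[length(hh) + 1L]] <- h
    }
    if (length(hh)) {
      hits2 <- unique(do.call(rbind, hh))
      # actual mismatch counts per claimed placement
      hits2$mm <- NA_integer_
      ori <- as.character(fwd)
      ori_rev <- as.character(rev)
      for (ch in unique(hits2$chrom)) {
        sel <- hits2$chrom == ch
        o <- ifelse(hits2$strand[sel] == "+", ori[hits2$read[sel]],
                    ori_rev[hits2$read[sel]])
        hits2$mm[sel] <- count_mismatches(o, index$genome$sequences[[ch]],
                                          hits2$start[sel], L)
      }
      hits2 <- hits2[hits2$mm <= max_mismatches, , drop = FALSE]
    }
  }

  hits <- rbind(hits0, hits2)
  if (is.null(hits) || nrow(hits) == 0) {
    return(list(alignments = empty_aln,
                unmapped = data.frame(id = reads$id, seq = reads$seq)))
  }

  # per read: keep placements at the minimum mismatch count
  hits <- hits[order(hits$read, hits$mm, hits$chrom, hits$start, hits$strand), ,
               drop = FALSE]
  idx0 <- which(!duplicated(hits$read))
  per_read <- diff(c(idx0, nrow(hits) + 1L))
  keep <- hits$mm == rep(hits$mm[idx0], per_read)
  hits <- hits[keep, , drop = FALSE]
  idx0 <- which(!duplicated(hits$read))
  nbest <- diff(c(idx0, nrow(hits) + 1L))
  first <- hits[idx0, , drop = FALSE]
  first$mapq_class <- ifelse(nbest > 1L, "multi-zero", "unique-high")

  ori_seq <- ifelse(first$strand == "+", as.character(fwd)[first$read],
                    as.character(rev)[first$read])
  alignments <- data.frame(read_id = reads$id[first$read], chrom = first$chrom,
                           start = first$start, strand = first$strand,
                           mismatches = first$mm, mapq_class = first$mapq_class,
                           seq = ori_seq)
  unm <- setdiff(seq_len(n), first$read)
  list(alignments = alignments,
       unmapped = data.frame(id = reads$id[unm], seq = reads$seq[unm]))
}

#' Map a single read
#'
#' @param read a read sequence (character) or one-row data frame.
#' @param index a `read_index`.
#' @param max_mismatches mismatch budget.
#' @return a one-row alignment data frame (class `unique-high` or
#'   `multi-zero`), or `NULL` if the read is unmapped.
#' @export
map_read <- function(read, index, max_mismatches = 2L) {
  res <- map_reads(read, index, max_mismatches)
  if (nrow(res$alignments) == 0) NULL else res$alignments
}

#' Ingest alignments from a SAM file
#'
#' Mapped records become alignments (mapping quality below 10 is demoted to
#' the depth-excluded `multi-zero` class); unmapped records populate the
#' unmapped pool. Sequences are stored reference-oriented, as in the SAM.
#'
#' @param path SAM file path.
#' @param genome optional `genome`; when supplied, per-alignment mismatch
#'   counts are recomputed against it.
#' @param min_mapq mapping-quality threshold separating `unique-high` from
#'   `multi-zero` (default 10).
#' @return `list(alignments, unmapped)`, as for [map_reads()].
#' @export
read_sam <- function(path, genome = NULL, min_mapq = 10L) {
  bam <- Rsamtools::asBam(path, destination = tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(c(bam, paste0(bam, ".bai"))), add = TRUE)
  p <- Rsamtools::ScanBamParam(what = c("qname", "flag", "rname", "pos",
                                        "strand", "mapq", "seq"))
  b <- Rsamtools::scanBam(bam, param = p)[[1]]
  seqs <- as.character(b$seq)
  if (length(unique(nchar(seqs))) > 1L)
    stop("SAM contains reads of inconsistent lengths")
  mapped <- bitwAnd(b$flag, 4L) == 0L
  aln <- data.frame(read_id = b$qname[mapped],
                    chrom = as.character(b$rname[mapped]),
                    start = b$pos[mapped],
                    strand = as.character(b$strand[mapped]),
                    mismatches = NA_integer_,
                    mapq_class = ifelse(b$mapq[mapped] < min_mapq,
                                        "multi-zero", "unique-high"),
                    seq = seqs[mapped])
  if (!is.null(genome) && nrow(aln) > 0) {
    L <- nchar(aln$seq[1])
    for (ch in unique(aln$chrom)) {
      sel <- aln$chrom == ch
      aln$mismatches[sel] <- count_mismatches(aln$seq[sel],
                                              get_chrom(genome, ch),
                                              aln$start[sel], L)
    }
  }
  list(alignments = aln,
       unmapped = data.frame(id = b$qname[!mapped], seq = seqs[!mapped]))
}

#' Compute the mappability mask
#'
#' A position is mappable iff the `read_len` window starting there occurs
#' exactly once in the genome, counting both strands. Windows overrunning a
#' chromosome end are unmappable.
#'
#' @param genome a `genome` object.
#' @param read_len window length in bp.
#' @return a `mappability_mask`: per-chromosome logical vectors plus the
#'   window length.
#' @export
mappability_mask <- function(genome, read_len) {
  read_len <- as.integer(read_len)
  lens <- chrom_lengths(genome)
  wins <- list(); idx_chrom <- list()
  for (ch in names(genome$sequences)) {
    nw <- lens[[ch]] - read_len + 1L
    if (nw < 1L) { wins[[ch]] <- character(0); next }
    wins[[ch]] <- substring(genome$sequences[[ch]], seq_len(nw),
                            seq_len(nw) + read_len - 1L)
  }
  allw <- unlist(wins, use.names = FALSE)
  u <- unique(allw)
  idx <- match(allw, u)
  cnt <- tabulate(idx, nbins = length(u))
  rc <- revcomp(allw)
  rcidx <- match(rc, u)
  rccnt <- ifelse(is.na(rcidx), 0L, cnt[rcidx])
  total <- cnt[idx] + rccnt
  uniq <- total == 1L

  mask <- list(); off <- 0L
  for (ch in names(genome$sequences)) {
    nw <- max(0L, lens[[ch]] - read_len + 1L)
    v <- logical(lens[[ch]])
    if (nw > 0) v[seq_len(nw)] <- uniq[off + seq_len(nw)]
    mask[[ch]] <- v
    off <- off + nw
  }
  structure(list(mask = mask, read_len = read_len), class = "mappability_mask")
}

#' Count mappable bases in a mask
#' @param mask a `mappability_mask`.
#' @param genome optional `genome`; when given, only nuclear chromosomes count.
#' @return number of mappable positions.
#' @export
mappable_bases <- function(mask, genome = NULL) {
  chroms <- names(mask$mask)
  if (!is.null(genome)) chroms <- chroms[genome$nuclear[chroms]]
  sum(vapply(mask$mask[chroms], sum, numeric(1)))
}
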