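## Per-position depth and base counts from unique-high alignments; the
## substrate for SNP calling and depth-ratio binning.

base_code_table <- local({
  tab <- integer(256)
  tab[utf8ToInt("A")] <- 1L; tab[utf8ToInt("C")] <- 2L
  tab[utf8ToInt("G")] <- 3L; tab[utf8ToInt("T")] <- 4L
  tab
})

#' Compute pileup columns and a depth track
#'
#' Only `unique-high` alignments contribute (multi-zero placements are
#' depth-excluded, emulating mapping-quality filtering). Reverse-strand reads
#' are stored reference-oriented, so their bases contribute directly at the
#' covered positions.
#'
#' @param alignments alignment data frame from [map_reads()] or [read_sam()].
#' @param genome the reference `genome`.
#' @return a `pileup` object: per-chromosome integer `depth` vectors,
#'   per-chromosome 4 x length base-count matrices (`counts`, rows A/C/G/T),
#'   the read length and `total_nuclear_bases` (the normaliser for
#'   depth-ratio analysis).
#' @export
pileup <- function(alignments, genome) {
  aln <- alignments[alignments$mapq_class == "unique-high", , drop = FALSE]
  L <- if (nrow(aln) > 0) nchar(aln$seq[1]) else NA_integer_
  lens <- chrom_lengths(genome)
  depth <- list(); counts <- list()
  for (ch in names(genome$sequences)) {
    n <- lens[[ch]]
    sel <- aln$chrom == ch
    starts <- aln$start[sel]
    if (length(starts) > 0 && (min(starts) < 1 || max(starts) + L - 1L > n))
      stop("alignment overruns chromosome end on ", ch)
    cov <- if (length(starts) == 0) integer(n) else
      as.integer(IRanges::coverage(IRanges::IRanges(starts, width = L), width = n))
    refcode <- base_code_table[utf8ToInt(genome$sequences[[ch]])]

    cnt <- numeric(4L * n)
    cnt[(seq_len(n) - 1L) * 4L + refcode] <- cov
    if (length(starts) > 0) {
      a <- charToRaw(paste(aln$seq[sel], collapse = ""))
      b <- charToRaw(paste(substring(genome$sequences[[ch]], starts,
                                     starts + L - 1L), collapse = ""))
      d <- which(a != b)
      if (length(d) > 0) {
        ri <- ((d - 1L) %/% L) + 1L
        off <- ((d - 1L) %% L) + 1L
        pos <- starts[ri] + off - 1L
        obs <- base_code_table[as.integer(a[d])]
        cnt <- cnt - tabulate((pos - 1L) * 4L + refcode[pos], nbins = 4L * n)
        cnt <- cnt + tabulate((pos - 1L) * 4L + obs, nbins = 4L * n)
      }
    }
    m <- matrix(as.integer(cnt), nrow = 4L,
                dimnames = list(BASES, NULL))
    depth[[ch]] <- cov
    counts[[ch]] <- m
  }
  nuc <- names(genome$sequences)[genome$nuclear]
  structure(list(depth = depth, counts = counts, read_len = L,
                 nuclear = genome$nuclear,
                 total_nuclear_bases = sum(vapply(depth[nuc], function(x)
                   sum(as.double(x)), numeric(1)))),
            class = "pileup")
}

#' Extract the depth track from a pileup
#'
#' @param pile a `pileup`.
#' @return a `depth_track`: per-chromosome depth vectors plus
#'   `total_nuclear_bases`.
#' @export
depth_track <- function(pile) {
  structure(list(depth = pile$depth, nuclear = pile$nuclear,
                 total_nuclear_bases = pile$total_nuclear_bases),
            class = "depth_track")
}
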