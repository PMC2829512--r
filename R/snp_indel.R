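## Dual-genome heuristic SNP calling (depth + base-call concordance in both
## strains) and a small-indel screen over split alignments of unmapped reads.

#' SNP-calling thresholds
#'
#' Defaults follow the adopted heuristic: at least 6 reads per position with
#' >= 80% concordant calls in the evolved strain, and at least 5 reads with
#' >= 70% concordant calls for a different base in the parental strain.
#' All thresholds are inclusive.
#'
#' @param evolved_min_depth,parent_min_depth minimum read depths.
#' @param evolved_min_fraction,parent_min_fraction minimum concordant
#'   base-call fractions, in (0, 1].
#' @return a `snp_thresholds` list.
#' @export
snp_thresholds <- function(evolved_min_depth = 6L, evolved_min_fraction = 0.80,
                           parent_min_depth = 5L, parent_min_fraction = 0.70) {
  stopifnot(evolved_min_depth >= 1, parent_min_depth >= 1,
            evolved_min_fraction > 0, evolved_min_fraction <= 1,
            parent_min_fraction > 0, parent_min_fraction <= 1)
  structure(list(evolved_min_depth = as.integer(evolved_min_depth),
                 evolved_min_fraction = evolved_min_fraction,
                 parent_min_depth = as.integer(parent_min_depth),
                 parent_min_fraction = parent_min_fraction),
            class = "snp_thresholds")
}

# majority base code and count for a 4 x n count matrix (ties -> first base;
# a tie can never pass a > 50% fraction threshold anyway)
majority_base <- function(m) {
  top <- pmax(m[1, ], m[2, ], m[3, ], m[4, ])
  code <- max.col(t(m), ties.method = "first")
  list(code = code, count = top)
}

#' Call SNPs between an evolved and a parental strain
#'
#' A position is called iff it is mappable, the evolved pileup has depth
#' `>= evolved_min_depth` with a single base making up
#' `>= evolved_min_fraction` of the calls, and the parental pileup has depth
#' `>= parent_min_depth` with a *different* base making up
#' `>= parent_min_fraction` of its calls.
#'
#' @param pileup_evolved,pileup_parent `pileup` objects over the same
#'   reference.
#' @param mask a `mappability_mask` over the same reference.
#' @param thresholds a [snp_thresholds()].
#' @return data frame of calls sorted by (chrom, pos): `chrom`, `pos`,
#'   `parent_base`, `evolved_base`, `evolved_depth`, `evolved_fraction`,
#'   `parent_depth`, `parent_fraction`.
#' @export
call_snps <- function(pileup_evolved, pileup_parent, mask,
                      thresholds = snp_thresholds()) {
  chroms <- names(pileup_evolved$depth)
  if (!identical(chroms, names(pileup_parent$depth)) ||
      !identical(lengths(pileup_evolved$depth), lengths(pileup_parent$depth)))
    stop("pileups were not computed over the same reference")
  thr <- thresholds
  out <- list()
  for (ch in chroms) {
    de <- pileup_evolved$depth[[ch]]
    dp <- pileup_parent$depth[[ch]]
    me <- majority_base(pileup_evolved$counts[[ch]])
    mp <- majority_base(pileup_parent$counts[[ch]])
    ok <- mask$mask[[ch]] &
      de >= thr$evolved_min_depth & me$count >= thr$evolved_min_fraction * de &
      dp >= thr$parent_min_depth & mp$count >= thr$parent_min_fraction * dp &
      me$code != mp$code
    pos <- which(ok)
    if (length(pos) > 0)
      out[[ch]] <- data.frame(chrom = ch, pos = pos,
                              parent_base = BASES[mp$code[pos]],
                              evolved_base = BASES[me$code[pos]],
                              evolved_depth = de[pos],
                              evolved_fraction = me$count[pos] / de[pos],
                              parent_depth = dp[pos],
                              parent_fraction = mp$count[pos] / dp[pos])
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), pos = integer(),
                      parent_base = character(), evolved_base = character(),
                      evolved_depth = integer(), evolved_fraction = numeric(),
                      parent_depth = integer(), parent_fraction = numeric()))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$chrom, res$pos), , drop = FALSE]
}

#' Fraction of the mappable genome examinable for SNPs
#'
#' @inheritParams call_snps
#' @return the fraction of mappable positions at which the evolved depth meets
#'   `evolved_min_depth` and the parental depth meets `parent_min_depth`.
#' @export
callable_fraction <- function(pileup_evolved, pileup_parent, mask,
                              thresholds = snp_thresholds()) {
  num <- 0; den <- 0
  for (ch in names(pileup_evolved$depth)) {
    m <- mask$mask[[ch]]
    den <- den + sum(m)
    num <- num + sum(m & pileup_evolved$depth[[ch]] >= thresholds$evolved_min_depth &
                       pileup_parent$depth[[ch]] >= thresholds$parent_min_depth)
  }
  if (den == 0) return(0)
  num / den
}

# longest exact prefix length of `read` matching ref starting at s (and the
# mirrored longest suffix, matching ref ending at e)
lcp_len <- function(read, refseq, s) {
  L <- nchar(read)
  end <- min(s + L - 1L, nchar(refseq))
  if (s < 1 || end < s) return(0L)
  a <- charToRaw(read); b <- charToRaw(substr(refseq, s, end))
  n <- length(b)
  d <- which(a[seq_len(n)] != b)
  if (length(d) == 0) n else d[1] - 1L
}

lcs_len <- function(read, refseq, e) {
  L <- nchar(read)
  s <- max(1L, e - L + 1L)
  if (e > nchar(refseq) || e < 1) return(0L)
  a <- rev(charToRaw(read)); b <- rev(charToRaw(substr(refseq, s, e)))
  n <- length(b)
  d <- which(a[seq_len(n)] != b)
  if (length(d) == 0) n else d[1] - 1L
}

# split-align one read sequence: two ungapped same-strand ordered pieces with
# a reference gap (deletion) or read gap (insertion)
split_align_read <- function(seq, genome, seed_len = 12L, min_piece = 12L) {
  L <- nchar(seq)
  out <- list()
  for (orient in c("+", "-")) {
    s <- if (orient == "+") seq else revcomp(seq)
    pre <- substr(s, 1L, seed_len)
    suf <- substr(s, L - seed_len + 1L, L)
    for (ch in names(genome$sequences)) {
      refseq <- genome$sequences[[ch]]
      p1 <- BiocGenerics::start(Biostrings::matchPattern(pre, Biostrings::DNAString(refseq)))
      p2 <- BiocGenerics::start(Biostrings::matchPattern(suf, Biostrings::DNAString(refseq)))
      if (length(p1) == 0 || length(p2) == 0) next
      for (s1 in p1) {
        a <- lcp_len(s, refseq, s1)
        if (a < min_piece || a >= L) next
        for (t2 in p2) {
          e2 <- t2 + seed_len - 1L
          b <- lcs_len(s, refseq, e2)
          if (b < min_piece || b >= L) next
          if (e2 - b + 1L <= s1) next        # pieces must be ordered
          if (a + b >= L) {                  # deletion (possibly micro-homologous)
            D <- e2 - s1 + 1L - L
            if (D >= 1L)
              out[[length(out) + 1L]] <- data.frame(
                chrom = ch, type = "deletion", coord = s1 + L - b, size = D,
                strand = orient)
          } else if (e2 - b + 1L == s1 + a) { # insertion
            out[[length(out) + 1L]] <- data.frame(
              chrom = ch, type = "insertion", coord = s1 + a - 1L,
              size = L - a - b, strand = orient)
          }
        }
      }
    }
  }
  if (length(out) == 0) return(NULL)
  unique(do.call(rbind, out)[, c("chrom", "type", "coord", "size")])
}

#' Screen unmapped reads for small insertions and deletions
#'
#' Each unmapped read is split-aligned as two ungapped, ordered, same-strand
#' pieces separated by a reference gap (deletion) or a read gap (insertion).
#' Coordinates supported by at least `min_support` reads in one strain, with
#' no wild-type-spanning reads in that strain but wild-type-spanning reads in
#' the comparison strain, are reported.
#'
#' @param unmapped_evolved,unmapped_parent unmapped pools from [map_reads()]
#'   or [read_sam()].
#' @param genome the reference `genome`.
#' @param alignments_evolved,alignments_parent mapped alignment tables for the
#'   wild-type-spanning check.
#' @param min_support minimum supporting reads ("multiple" = 2 by default).
#' @param min_span half-width (bp) of the wild-type-spanning window.
#' @return data frame of candidates: `chrom`, `coord`, `type`, `size`,
#'   `strain`, `support`, `support_other`.
#' @export
screen_indels <- function(unmapped_evolved, unmapped_parent, genome,
                          alignments_evolved, alignments_parent,
                          min_support = 2L, min_span = 5L) {
  gather <- function(pool) {
    if (nrow(pool) == 0) return(NULL)
    res <- lapply(pool$seq, split_align_read, genome = genome)
    res <- res[!vapply(res, is.null, logical(1))]
    if (length(res) == 0) return(NULL)
    do.call(rbind, res)
  }
  cand <- list(evolved = gather(unmapped_evolved),
               parent = gather(unmapped_parent))
  aln <- list(evolved = alignments_evolved, parent = alignments_parent)
  out <- list()
  for (strain in c("evolved", "parent")) {
    cc <- cand[[strain]]
    if (is.null(cc)) next
    key <- paste(cc$chrom, cc$type, cc$coord, cc$size)
    tab <- table(key)
    for (k in names(tab[tab >= min_support])) {
      row <- cc[match(k, key), , drop = FALSE]
      other <- setdiff(c("evolved", "parent"), strain)
      wt_self <- wildtype_support(aln[[strain]], genome, row$chrom, row$coord,
                                  min_span = min_span)
      wt_other <- wildtype_support(aln[[other]], genome, row$chrom, row$coord,
                                   min_span = min_span)
      if (!wt_self$supported && wt_other$supported)
        out[[length(out) + 1L]] <- data.frame(
          chrom = row$chrom, coord = row$coord, type = row$type,
          size = row$size, strain = strain,
          support = as.integer(tab[[k]]), support_other = wt_other$n_reads)
    }
  }
  if (length(out) == 0)
    return(data.frame(chrom = character(), coord = integer(), type = character(),
                      size = integer(), strain = character(),
                      support = integer(), support_other = integer()))
  res <- do.call(rbind, out)
  res[order(res$chrom, res$coord), , drop = FALSE]
}
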