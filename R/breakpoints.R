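## Breakpoint-sequence recovery: de Bruijn assembly of unmapped reads into
## contigs, split ungapped alignment of contigs back to the reference,
## contig filtering, inversion / micro-homology classification, wild-type
## junction support, a background-probability statistic, and
## rearrangement-structure inference.

canonical_kmer <- function(kmers) {
  rc <- revcomp(kmers)
  ifelse(kmers <= rc, kmers, rc)
}

#' Assemble unmapped reads into contigs
#'
#' Builds a de Bruijn graph over canonical k-mers of both strands, drops
#' low-coverage k-mers (`min_kmer_count`, default 2, suppresses singleton
#' sequencing-error k-mers), and emits maximal unitigs. At a branch the walk
#' continues only through a candidate whose k-mer count dominates every
#' alternative by `dominance` (default 4), which resolves branches caused by
#' coincidentally duplicated sequencing errors without any wider graph
#' simplification; otherwise the unitig ends. Output is deterministic:
#' contigs are orientation-normalised and ordered by (length desc, sequence).
#'
#' @param reads unmapped pool (data frame with `seq`, or character vector).
#' @param k odd k-mer size with `12 <= k <` read length.
#' @param min_contig_len minimum contig length (bp).
#' @param min_kmer_count k-mer coverage cutoff.
#' @param dominance branch-resolution dominance ratio.
#' @return data frame of contigs: `id`, `seq`, `length`, `reads` (supporting
#'   read count).
#' @export
assemble_contigs <- function(reads, k = 21L, min_contig_len = 30L,
                             min_kmer_count = 2L, dominance = 4) {
  seqs <- if (is.character(reads)) reads else reads$seq
  empty <- data.frame(id = character(), seq = character(), length = integer(),
                      reads = integer())
  if (length(seqs) == 0) return(empty)
  k <- as.integer(k)
  if (k < 12L || k >= max(nchar(seqs))) stop("k must satisfy 12 <= k < read length")
  if (k %% 2L == 0L) stop("k must be odd (a canonical k-mer must have a strand)")

  per_read <- lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
  })
  allk <- canonical_kmer(unlist(per_read, use.names = FALSE))
  u <- unique(allk)
  cnt <- tabulate(match(allk, u), nbins = length(u))
  keep <- cnt >= min_kmer_count
  u <- u[keep]; cnt <- cnt[keep]
  if (length(u) == 0) return(empty)
  cnt_env <- new.env(hash = TRUE, size = length(u) * 2L)
  for (i in seq_along(u)) assign(u[i], cnt[i], envir = cnt_env)
  used <- new.env(hash = TRUE, size = length(u) * 2L)

  kcount <- function(km) {
    can <- canonical_kmer(km)
    v <- mget(can, envir = cnt_env, ifnotfound = 0L)
    unlist(v, use.names = FALSE)
  }
  # pick the dominant present candidate, or NA if the branch is ambiguous
  dominant <- function(cands) {
    cc <- kcount(cands)
    pres <- which(cc > 0)
    if (length(pres) == 0) return(NA_character_)
    if (length(pres) == 1) return(cands[pres])
    o <- order(cc[pres], decreasing = TRUE)
    if (cc[pres][o[1]] >= dominance * cc[pres][o[2]]) cands[pres[o[1]]]
    else NA_character_
  }
  extend_right <- function(start_kmer) {
    path <- character(0)
    cur <- start_kmer
    repeat {
      nxt <- dominant(paste0(substr(cur, 2L, k), BASES))
      if (is.na(nxt)) break
      can <- canonical_kmer(nxt)
      if (!is.null(get0(can, envir = used))) break
      # the incoming edge must dominate from the other side too
      back <- dominant(paste0(BASES, substr(nxt, 1L, k - 1L)))
      if (is.na(back) || back != cur) break
      assign(can, TRUE, envir = used)
      path <- c(path, substr(nxt, k, k))
      cur <- nxt
    }
    paste(path, collapse = "")
  }

  contigs <- character(0)
  for (seed in sort(u)) {
    if (!is.null(get0(seed, envir = used))) next
    assign(seed, TRUE, envir = used)
    right <- extend_right(seed)
    left <- extend_right(revcomp(seed))   # left extension = right of revcomp
    s <- paste0(revcomp(left), seed, right)
    if (nchar(s) >= min_contig_len) contigs <- c(contigs, s)
  }
  if (length(contigs) == 0) return(empty)
  rc <- revcomp(contigs)
  contigs <- ifelse(contigs <= rc, contigs, rc)
  contigs <- contigs[order(-nchar(contigs), contigs)]

  # supporting reads: reads sharing at least one retained k-mer with the contig
  support <- vapply(contigs, function(ctg) {
    n <- nchar(ctg)
    ck <- canonical_kmer(substring(ctg, seq_len(n - k + 1L),
                                   seq_len(n - k + 1L) + k - 1L))
    sum(vapply(per_read, function(rk)
      length(rk) > 0 && any(canonical_kmer(rk) %in% ck), logical(1)))
  }, integer(1))
  data.frame(id = sprintf("contig_%03d", seq_along(contigs)), seq = contigs,
             length = nchar(contigs), reads = as.integer(support))
}

# best-scoring ungapped run on one diagonal (Kadane; mismatch penalty set so
# any positive-score run exceeds the identity threshold)
best_run <- function(match_vec, min_identity) {
  penalty <- min_identity / (1 - min_identity)
  sc <- ifelse(match_vec, 1, -penalty)
  best <- 0; cur <- 0; cur_start <- 1L; bs <- 0L; be <- -1L
  for (t in seq_along(sc)) {
    if (cur <= 0) { cur <- 0; cur_start <- t }
    cur <- cur + sc[t]
    if (cur > best) { best <- cur; bs <- cur_start; be <- t }
  }
  if (be < bs) return(NULL)
  # trim mismatched ends (Kadane already ends on matches, kept for safety)
  while (bs <= be && !match_vec[bs]) bs <- bs + 1L
  while (be >= bs && !match_vec[be]) be <- be - 1L
  if (be < bs) return(NULL)
  list(start = bs, end = be, identity = mean(match_vec[bs:be]))
}

#' Align a contig to the reference as maximal ungapped local alignments
#'
#' Seeds exact `seed_len`-mer matches on both strands, extends each seeded
#' diagonal to its best ungapped run, and reports runs of identity at least
#' `min_identity` and length at least `seed_len`. Alignments whose contig
#' interval is contained in a longer alignment's interval are pruned, so a
#' two-part junction contig yields exactly its two pieces.
#'
#' @param contig contig sequence (character) or a one-row contig data frame.
#' @param genome the reference `genome`.
#' @param min_identity minimum ungapped identity (default 0.9).
#' @param seed_len exact seed length (default 12).
#' @return data frame of alignments: `contig_start`, `contig_end` (1-based in
#'   contig coordinates), `chrom`, `ref_start`, `ref_end`, `strand`,
#'   `identity`.
#' @export
align_contig <- function(contig, genome, min_identity = 0.9, seed_len = 12L) {
  ctg <- if (is.character(contig)) contig else contig$seq
  empty <- data.frame(contig_start = integer(), contig_end = integer(),
                      chrom = character(), ref_start = integer(),
                      ref_end = integer(), strand = character(),
                      identity = numeric())
  if (length(ctg) == 0) return(empty)
  n <- nchar(ctg)
  if (n < seed_len) return(empty)
  out <- list()
  for (st in c("+", "-")) {
    pat <- if (st == "+") ctg else revcomp(ctg)
    npos <- n - seed_len + 1L
    seeds <- substring(pat, seq_len(npos), seq_len(npos) + seed_len - 1L)
    pd <- Biostrings::PDict(seeds)
    for (ch in names(genome$sequences)) {
      refseq <- genome$sequences[[ch]]
      m <- Biostrings::matchPDict(pd, Biostrings::DNAString(refseq))
      h <- mindex_hits(m, ch, st)
      if (nrow(h) == 0) next
      diags <- unique(h$start - h$read + 1L)   # ref position of pat position 1
      for (dg in diags) {
        p1 <- max(1L, 2L - dg)
        p2 <- min(n, nchar(refseq) - dg + 1L)
        if (p2 - p1 + 1L < seed_len) next
        a <- charToRaw(substr(pat, p1, p2))
        b <- charToRaw(substr(refseq, dg + p1 - 1L, dg + p2 - 1L))
        run <- best_run(a == b, min_identity)
        if (is.null(run)) next
        ps <- p1 + run$start - 1L; pe <- p1 + run$end - 1L
        if (pe - ps + 1L < seed_len || run$identity < min_identity) next
        cs <- if (st == "+") ps else n - pe + 1L
        ce <- if (st == "+") pe else n - ps + 1L
        out[[length(out) + 1L]] <- data.frame(
          contig_start = cs, contig_end = ce, chrom = ch,
          ref_start = dg + ps - 1L, ref_end = dg + pe - 1L, strand = st,
          identity = run$identity)
      }
    }
  }
  if (length(out) == 0) return(empty)
  aln <- unique(do.call(rbind, out))
  # prune alignments contained (in contig coordinates) in a longer alignment
  len <- aln$contig_end - aln$contig_start + 1L
  aln <- aln[order(-len, aln$contig_start), , drop = FALSE]
  keep <- rep(TRUE, nrow(aln))
  for (i in seq_len(nrow(aln))) {
    if (!keep[i]) next
    contained <- keep & aln$contig_start >= aln$contig_start[i] &
      aln$contig_end <= aln$contig_end[i]
    contained[i] <- FALSE
    keep[contained] <- FALSE
  }
  aln <- aln[keep, , drop = FALSE]
  rownames(aln) <- NULL
  aln
}

# TRUE iff some unique mapping window contains position p on chromosome ch
position_mappable <- function(mask, ch, p) {
  m <- mask$mask[[ch]]
  rl <- mask$read_len
  lo <- max(1L, p - rl + 1L)
  hi <- min(p, length(m) - rl + 1L)
  hi >= lo && any(m[lo:hi])
}

#' Filter contig alignments
#'
#' Retains only contigs that (a) are not explained end-to-end by a single
#' reference region, (b) whose end-anchoring alignments land in mappable
#' positions, and (c) whose retained subsequence alignments cover at least
#' `min_coverage` of the contig.
#'
#' @param contigs contig data frame from [assemble_contigs()].
#' @param alignments data frame with a `contig_id` column binding each
#'   alignment row (as from [align_contig()]) to its contig.
#' @param mask a `mappability_mask`.
#' @param full_span_frac fraction of the contig a single alignment must reach
#'   to count as spanning it (rule a; default 0.95).
#' @param min_coverage minimum fraction of contig bases covered by the
#'   alignments (rule c; default 0.9).
#' @return `list(contigs, alignments)` restricted to retained contigs.
#' @export
filter_contigs <- function(contigs, alignments, mask, full_span_frac = 0.95,
                           min_coverage = 0.9) {
  keep_ids <- character(0)
  for (i in seq_len(nrow(contigs))) {
    id <- contigs$id[i]
    n <- contigs$length[i]
    aln <- alignments[alignments$contig_id == id, , drop = FALSE]
    if (nrow(aln) == 0) next
    len <- aln$contig_end - aln$contig_start + 1L
    if (any(len >= full_span_frac * n)) next                    # rule (a)
    left <- aln[which.min(aln$contig_start), ]
    right <- aln[which.max(aln$contig_end), ]
    left_ref <- if (left$strand == "+") left$ref_start else left$ref_end
    right_ref <- if (right$strand == "+") right$ref_end else right$ref_start
    if (!position_mappable(mask, left$chrom, left_ref) ||
        !position_mappable(mask, right$chrom, right_ref)) next  # rule (b)
    cov <- sum(IRanges::width(IRanges::reduce(
      IRanges::IRanges(aln$contig_start, aln$contig_end))))
    if (cov < min_coverage * n) next                            # rule (c)
    keep_ids <- c(keep_ids, id)
  }
  list(contigs = contigs[contigs$id %in% keep_ids, , drop = FALSE],
       alignments = alignments[alignments$contig_id %in% keep_ids, , drop = FALSE])
}

#' Classify a two-part contig as a breakpoint call
#'
#' The micro-homology overlap is the number of contig bases claimed by both
#' parts: `len(A) + len(B) - contig length`, computed from the contig
#' intervals (never from reference coordinates). Orientation is `inverted`
#' when the parts align to opposite strands. Junction reference coordinates
#' are the reference positions of the innermost aligned base of each part.
#'
#' @param contig contig sequence or one-row contig data frame.
#' @param alignments exactly two retained alignments of this contig.
#' @param segment optional one-row segment (from [cbs_segment()]) used to set
#'   the in-amplification flag.
#' @param uncertainty boundary uncertainty in bp for the in-amplification
#'   window (default 25).
#' @return a one-row data frame: `orientation`, `overlap`, `chrom`,
#'   `coord_a`, `coord_b`, `in_amplification`.
#' @export
classify_breakpoint <- function(contig, alignments, segment = NULL,
                                uncertainty = 25L) {
  if (nrow(alignments) != 2L)
    stop("a breakpoint call needs exactly two retained alignments")
  ctg <- if (is.character(contig)) contig else contig$seq
  n <- nchar(ctg)
  aln <- alignments[order(alignments$contig_start), , drop = FALSE]
  a <- aln[1, ]; b <- aln[2, ]
  len_a <- a$contig_end - a$contig_start + 1L
  len_b <- b$contig_end - b$contig_start + 1L
  overlap <- len_a + len_b - n
  orientation <- if (a$strand != b$strand) "inverted" else "direct"
  coord_a <- if (a$strand == "+") a$ref_end else a$ref_start  # inner end of A
  coord_b <- if (b$strand == "+") b$ref_start else b$ref_end  # inner end of B
  in_amp <- NA
  if (!is.null(segment)) {
    u <- as.integer(uncertainty)
    lo <- segment$start - u; hi <- segment$end + u
    in_amp <- (a$chrom == segment$chrom && coord_a >= lo && coord_a <= hi) ||
      (b$chrom == segment$chrom && coord_b >= lo && coord_b <= hi)
  }
  data.frame(orientation = orientation, overlap = as.integer(overlap),
             chrom = a$chrom, coord_a = as.integer(coord_a),
             coord_b = as.integer(coord_b), in_amplification = in_amp)
}

#' Wild-type spanning support at a coordinate
#'
#' Reports whether at least one unique-high read alignment covers
#' `[coordinate - min_span, coordinate + min_span]` and matches the reference
#' contiguously across that window.
#'
#' @param alignments alignment data frame (with reference-oriented `seq`).
#' @param genome the reference `genome`.
#' @param chrom chromosome name.
#' @param coordinate 1-based reference position.
#' @param min_span window half-width in bp (default 5).
#' @return `list(supported, n_reads)`.
#' @export
wildtype_support <- function(alignments, genome, chrom, coordinate,
                             min_span = 5L) {
  refseq <- get_chrom(genome, chrom)
  if (coordinate < 1 || coordinate > nchar(refseq))
    stop("coordinate out of range")
  w1 <- coordinate - min_span; w2 <- coordinate + min_span
  if (w1 < 1 || w2 > nchar(refseq)) return(list(supported = FALSE, n_reads = 0L))
  aln <- alignments[alignments$mapq_class == "unique-high" &
                      alignments$chrom == chrom, , drop = FALSE]
  if (nrow(aln) == 0) return(list(supported = FALSE, n_reads = 0L))
  L <- nchar(aln$seq[1])
  cover <- aln$start <= w1 & aln$start + L - 1L >= w2
  aln <- aln[cover, , drop = FALSE]
  if (nrow(aln) == 0) return(list(supported = FALSE, n_reads = 0L))
  ref_win <- substr(refseq, w1, w2)
  read_win <- substring(aln$seq, w1 - aln$start + 1L, w2 - aln$start + 1L)
  n <- sum(read_win == ref_win)
  list(supported = n >= 1L, n_reads = as.integer(n))
}

#' Background probability of breakpoint-like contigs
#'
#' Given `n_background_contigs` breakpoint-like contigs observed in the
#' comparison (ancestor) data over `mappable_bases` mappable nuclear bases,
#' the per-base rate is `r = n_background_contigs / mappable_bases` and the
#' probability of observing such contigs within `n_breakpoints` windows of
#' `window` bp each is `(r * window)^n_breakpoints`, capped at 1.
#'
#' @param n_background_contigs background contig count (>= 0).
#' @param mappable_bases mappable nuclear-genome size (> 0).
#' @param window coordinate window in bp (>= 1).
#' @param n_breakpoints number of predicted breakpoints.
#' @return the probability.
#' @export
background_probability <- function(n_background_contigs, mappable_bases,
                                   window, n_breakpoints) {
  if (mappable_bases <= 0) stop("mappable_bases must be positive")
  if (window < 1) stop("window must be >= 1")
  stopifnot(n_background_contigs >= 0, n_breakpoints >= 0)
  r <- n_background_contigs / mappable_bases
  min(1, (r * window)^n_breakpoints)
}

#' Infer the structure of an amplification
#'
#' Labels the amplification `tandem_inverted` iff both boundary breakpoint
#' calls are inverted-class, both fall within the segment boundaries (plus
#' uncertainty), and wild-type-spanning reads support both boundaries
#' (an odd-copy tandem-inverted array retains wild-type sequence at its outer
#' flanks); otherwise `unresolved`, with the evidence listed.
#'
#' @param segment one-row amplified segment from [cbs_segment()].
#' @param copy_ratio_est copy-ratio estimate (from [copy_ratio()], or a
#'   number).
#' @param left_call,right_call breakpoint calls from [classify_breakpoint()],
#'   or `NULL`.
#' @param wildtype_left,wildtype_right results of [wildtype_support()] at the
#'   two boundaries (or logicals).
#' @return an `amplification_model` list with fields `segment`, `copy_ratio`,
#'   `copy_number`, `left_call`, `right_call`, `wildtype_left`,
#'   `wildtype_right`, `structure`.
#' @export
infer_structure <- function(segment, copy_ratio_est, left_call, right_call,
                            wildtype_left, wildtype_right) {
  cr <- if (is.numeric(copy_ratio_est)) copy_ratio_est else
    copy_ratio_est$copy_ratio
  wt_l <- if (is.logical(wildtype_left)) wildtype_left else wildtype_left$supported
  wt_r <- if (is.logical(wildtype_right)) wildtype_right else wildtype_right$supported
  ok_call <- function(call) {
    !is.null(call) && nrow(call) == 1L && call$orientation == "inverted" &&
      isTRUE(call$in_amplification)
  }
  label <- if (ok_call(left_call) && ok_call(right_call) && wt_l && wt_r)
    "tandem_inverted" else "unresolved"
  structure(list(segment = segment, copy_ratio = cr,
                 copy_number = as.integer(round(cr)),
                 left_call = left_call, right_call = right_call,
                 wildtype_left = wt_l, wildtype_right = wt_r,
                 structure = label),
            class = "amplification_model")
}
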