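## Synthetic-data generator: a toy haploid genome, an "evolved" derivative
## carrying planted SNPs and a tandem-inverted segmental amplification with
## micro-homology junctions, and simulated single-end short reads.

#' Generate a random reference genome
#'
#' Bases are drawn i.i.d. at the requested GC content; chromosomes are named
#' `chr1`, `chr2`, ...
#'
#' @param n_chroms number of chromosomes.
#' @param lengths integer vector of chromosome lengths (bp), recycled to
#'   `n_chroms`.
#' @param gc GC fraction in (0, 1).
#' @param seed RNG seed; the same seed always yields the same genome.
#' @return a `genome` object.
#' @export
generate_reference <- function(n_chroms, lengths, gc = 0.38, seed = 1) {
  stopifnot(n_chroms >= 1)
  lengths <- rep_len(as.integer(lengths), n_chroms)
  if (any(lengths <= 0)) stop("chromosome lengths must be positive")
  if (!is.numeric(gc) || gc <= 0 || gc >= 1) stop("gc must be in (0, 1)")
  prob <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  seqs <- with_seed(seed, {
    vapply(lengths, function(n) {
      paste(sample(BASES, n, replace = TRUE, prob = prob), collapse = "")
    }, character(1))
  })
  genome(stats::setNames(seqs, paste0("chr", seq_len(n_chroms))))
}

#' Plant an inverted-repeat pair
#'
#' Edits the genome so that the `arm_len` bases ending at `boundary` are the
#' reverse complement of an arm placed `spacer` bases downstream: after the
#' call, `ref[boundary - arm_len + 1 .. boundary]` equals
#' `revcomp(ref[boundary + spacer + 1 .. boundary + spacer + arm_len])`.
#' The downstream arm is the one rewritten; all other bases are unchanged.
#'
#' @param genome a `genome` object.
#' @param chrom chromosome name.
#' @param boundary 1-based position at which the upstream arm ends.
#' @param arm_len arm length in nt (0 returns the genome unchanged).
#' @param spacer gap between the arms in nt (>= 0).
#' @return the edited `genome`.
#' @export
plant_inverted_repeats <- function(genome, chrom, boundary, arm_len, spacer = 0) {
  if (arm_len == 0L) return(genome)
  stopifnot(arm_len >= 1)
  if (spacer < 0) stop("arms would overlap (spacer < 0)")
  seq <- get_chrom(genome, chrom)
  n <- nchar(seq)
  up_start <- boundary - arm_len + 1
  dn_start <- boundary + spacer + 1
  dn_end <- dn_start + arm_len - 1
  if (up_start < 1 || dn_end > n) stop("arms do not fit on the chromosome")
  arm <- substr(seq, up_start, boundary)
  substr(seq, dn_start, dn_end) <- revcomp(arm)
  genome$sequences[[chrom]] <- seq
  genome
}

#' Describe a tandem-inverted amplification
#'
#' The amplified interval is `[left, right]` (1-based, inclusive) at
#' `copy_number` alternating-orientation copies. Each inverted junction is
#' mediated by a planted inverted-repeat pair: at the right boundary the
#' proximal arm is the last `microhomology_right` bases of the segment with its
#' reverse complement `spacer_right` bases downstream, and mirrorwise at the
#' left boundary. A contig crossing an inverted junction aligns back to the
#' reference as two opposite-strand ungapped pieces whose contig intervals
#' overlap by exactly the arm length.
#'
#' @param chrom chromosome carrying the amplification.
#' @param left,right 1-based inclusive boundaries of the amplified segment.
#' @param copy_number total copy number `k >= 1` (odd `k` leaves wild-type
#'   sequence at both outer flank junctions).
#' @param microhomology_left,microhomology_right arm lengths in nt (>= 0).
#' @param spacer_left,spacer_right arm separations in nt (>= 1 when the
#'   corresponding arm length is positive).
#' @return an `amplification_spec` list.
#' @export
amplification_spec <- function(chrom, left, right, copy_number,
                               microhomology_left = 7L, microhomology_right = 13L,
                               spacer_left = 10L, spacer_right = 12L) {
  stopifnot(left < right, copy_number >= 1,
            microhomology_left >= 0, microhomology_right >= 0)
  if (microhomology_left > 0 && spacer_left < 1)
    stop("spacer_left must be >= 1 for a positive left micro-homology")
  if (microhomology_right > 0 && spacer_right < 1)
    stop("spacer_right must be >= 1 for a positive right micro-homology")
  structure(list(chrom = chrom, left = as.integer(left), right = as.integer(right),
                 copy_number = as.integer(copy_number),
                 h_left = as.integer(microhomology_left),
                 h_right = as.integer(microhomology_right),
                 spacer_left = as.integer(spacer_left),
                 spacer_right = as.integer(spacer_right)),
            class = "amplification_spec")
}

#' Describe the evolved derivative of a reference genome
#'
#' @param snps data frame with columns `chrom`, `pos` (1-based), `alt`;
#'   may be `NULL` or empty.
#' @param amplification an [amplification_spec()], or `NULL`.
#' @return an `evolution_spec` list.
#' @export
evolution_spec <- function(snps = NULL, amplification = NULL) {
  if (is.null(snps)) snps <- data.frame(chrom = character(), pos = integer(),
                                        alt = character())
  stopifnot(all(c("chrom", "pos", "alt") %in% names(snps)))
  structure(list(snps = snps, amplification = amplification),
            class = "evolution_spec")
}

# Margin around the amplified interval occupied by junction machinery
# (spacers, distal arms and the palindrome-breaking base on each side).
amp_margin <- function(amp) {
  c(left = amp$spacer_left + amp$h_left + 1L,
    right = amp$spacer_right + amp$h_right + 1L)
}

#' Plant the junction-forming inverted-repeat arms for an amplification
#'
#' Installs, on the reference, the two inverted-repeat pairs through which the
#' amplification's head-to-head and tail-to-tail junctions form, and then
#' breaks any chance extension of the palindromic pairing by rewriting at most
#' four flank bases, so the realised micro-homology lengths are exactly the
#' requested arm lengths.
#'
#' @param genome the reference `genome`.
#' @param amp an [amplification_spec()].
#' @return the edited reference `genome`.
#' @export
plant_junction_arms <- function(genome, amp) {
  L <- amp$left; R <- amp$right
  hL <- amp$h_left; hR <- amp$h_right
  spL <- amp$spacer_left; spR <- amp$spacer_right
  seq <- get_chrom(genome, amp$chrom)
  n <- nchar(seq)
  if (L - spL - hL - 1 < 1 || R + spR + hR + 1 > n)
    stop("junction arms do not fit on the chromosome")

  if (hR > 0) {
    # proximal arm = last hR bases of the segment; distal arm spR bases past R
    arm1 <- substr(seq, R - hR + 1, R)
    substr(seq, R + spR + 1, R + spR + hR) <- revcomp(arm1)
  }
  if (hL > 0) {
    # proximal arm = first hL bases of the segment; distal arm spL bases before L
    arm1 <- substr(seq, L, L + hL - 1)
    substr(seq, L - spL - hL, L - spL - 1) <- revcomp(arm1)
  }

  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  # Force base at `pos` to differ from complement of base at `partner`.
  break_pal <- function(seq, pos, partner) {
    if (pos == partner) return(seq)          # a base never equals its own complement
    forbidden <- comp1(substr(seq, partner, partner))
    if (substr(seq, pos, pos) == forbidden)
      substr(seq, pos, pos) <- setdiff(BASES, forbidden)[1L]
    seq
  }
  if (hR > 0) {
    seq <- break_pal(seq, R + spR, R + 1)              # stop the (+) piece at the junction
    seq <- break_pal(seq, R + spR + hR + 1, R - hR)    # cap the arm at exactly hR
  }
  if (hL > 0) {
    seq <- break_pal(seq, L - spL, L - 1)
    seq <- break_pal(seq, L - spL - hL - 1, L + hL)
  }
  genome$sequences[[amp$chrom]] <- seq
  genome
}

# Check that the junction arms are present and exact on the reference.
check_junction_arms <- function(seq, amp) {
  L <- amp$left; R <- amp$right
  hL <- amp$h_left; hR <- amp$h_right
  spL <- amp$spacer_left; spR <- amp$spacer_right
  comp1 <- function(b) chartr("ACGT", "TGCA", b)
  ok <- TRUE
  if (hR > 0) {
    ok <- ok && identical(substr(seq, R + spR + 1, R + spR + hR),
                          revcomp(substr(seq, R - hR + 1, R)))
    if (spR > 1)
      ok <- ok && substr(seq, R + spR, R + spR) != comp1(substr(seq, R + 1, R + 1))
    ok <- ok && substr(seq, R + spR + hR + 1, R + spR + hR + 1) !=
      comp1(substr(seq, R - hR, R - hR))
  }
  if (hL > 0) {
    ok <- ok && identical(substr(seq, L - spL - hL, L - spL - 1),
                          revcomp(substr(seq, L, L + hL - 1)))
    if (spL > 1)
      ok <- ok && substr(seq, L - spL, L - spL) != comp1(substr(seq, L - 1, L - 1))
    ok <- ok && substr(seq, L - spL - hL - 1, L - spL - hL - 1) !=
      comp1(substr(seq, L + hL, L + hL))
  }
  ok
}

#' Derive the evolved genome and its truth record
#'
#' Applies the planted SNPs and replaces the amplified segment `S = [left,
#' right]` by an alternating-orientation array `S(+), S(-), S(+), ...` of
#' `copy_number` copies. Inverted copies run through the planted
#' inverted-repeat arms (`S(-) = revcomp(ref[left - spacer_left .. right +
#' spacer_right])`), which gives every inverted junction the split-alignment
#' signature of two opposite-strand pieces whose contig intervals overlap by
#' exactly the arm length. For odd `copy_number` the outer flank junctions read
#' as wild-type reference sequence.
#'
#' @param genome the reference `genome`, with junction arms already planted
#'   (see [plant_junction_arms()]).
#' @param spec an [evolution_spec()].
#' @param junction_window half-width (nt) of the recorded truth junction
#'   sequences.
#' @return `list(genome = evolved genome, truth = truth_set)`; the truth set
#'   records planted SNPs, amplification coordinates and structure, expected
#'   micro-homology lengths, and the junction sequences as substrings of the
#'   evolved genome.
#' @export
apply_evolution <- function(genome, spec, junction_window = 30L) {
  snps <- spec$snps
  amp <- spec$amplification

  # validate SNPs
  if (nrow(snps) > 0) {
    for (i in seq_len(nrow(snps))) {
      seq <- get_chrom(genome, snps$chrom[i])
      p <- snps$pos[i]
      if (p < 1 || p > nchar(seq)) stop("SNP position out of range")
      if (!snps$alt[i] %in% BASES) stop("SNP alt base must be one of A/C/G/T")
      if (substr(seq, p, p) == snps$alt[i])
        stop("SNP alt base equals the reference base at position ", p)
    }
  }
  truth_snps <- data.frame(chrom = character(), pos = integer(),
                           ref = character(), alt = character())
  if (nrow(snps) > 0) {
    refb <- vapply(seq_len(nrow(snps)), function(i)
      substr(get_chrom(genome, snps$chrom[i]), snps$pos[i], snps$pos[i]),
      character(1))
    truth_snps <- data.frame(chrom = snps$chrom, pos = as.integer(snps$pos),
                             ref = refb, alt = snps$alt)
  }

  evolved <- genome
  junctions <- data.frame(side = character(), junction_pos_evolved = integer(),
                          expected_overlap = integer(), sequence = character())
  amp_truth <- NULL

  if (!is.null(amp)) {
    k <- amp$copy_number
    L <- amp$left; R <- amp$right
    margin <- amp_margin(amp)
    if (nrow(snps) > 0) {
      inside <- snps$chrom == amp$chrom &
        snps$pos >= L - margin["left"] & snps$pos <= R + margin["right"]
      if (any(inside))
        stop("planted SNPs must not fall inside the amplified segment or its junction margin")
    }
    seq <- get_chrom(genome, amp$chrom)
    if ((amp$h_left > 0 || amp$h_right > 0) && !check_junction_arms(seq, amp))
      stop("junction arms are absent or inexact; call plant_junction_arms() first")

    if (k > 1) {
      c_plus <- substr(seq, L, R)
      c_minus <- revcomp(substr(seq, L - amp$spacer_left, R + amp$spacer_right))
      n_pairs <- (k - 1L) %/% 2L
      body <- paste(rep(c(c_minus, c_plus), n_pairs), collapse = "")
      if (k %% 2L == 0L) body <- paste0(body, c_minus)
      evo_seq <- paste0(substr(seq, 1, R), body, substr(seq, R + 1, nchar(seq)))
      evolved$sequences[[amp$chrom]] <- evo_seq

      # truth junctions: first tail-to-tail at evolved position R, first
      # head-to-head at R + nchar(c_minus)
      w <- as.integer(junction_window)
      jr <- R
      jl <- R + nchar(c_minus)
      junctions <- data.frame(
        side = c("right", "left"),
        junction_pos_evolved = c(jr, jl),
        expected_overlap = c(amp$h_right, amp$h_left),
        sequence = c(substr(evo_seq, jr - w + 1, jr + w),
                     substr(evo_seq, jl - w + 1, jl + w)))
    }
    amp_truth <- data.frame(chrom = amp$chrom, left = L, right = R,
                            copy_number = k,
                            h_left = amp$h_left, h_right = amp$h_right,
                            spacer_left = amp$spacer_left,
                            spacer_right = amp$spacer_right,
                            structure = if (k > 1) "tandem_inverted" else "none")
  }

  # apply SNPs on evolved coordinates (positions after the amplified segment
  # shift by the inserted length)
  if (nrow(truth_snps) > 0) {
    for (i in seq_len(nrow(truth_snps))) {
      ch <- truth_snps$chrom[i]
      p <- truth_snps$pos[i]
      if (!is.null(amp) && ch == amp$chrom && p > amp$right)
        p <- p + nchar(evolved$sequences[[ch]]) - nchar(genome$sequences[[ch]])
      s <- evolved$sequences[[ch]]
      substr(s, p, p) <- truth_snps$alt[i]
      evolved$sequences[[ch]] <- s
    }
  }

  truth <- structure(list(snps = truth_snps, amplification = amp_truth,
                          junctions = junctions),
                     class = "truth_set")
  list(genome = evolved, truth = truth)
}

#' Simulate single-end reads
#'
#' Read start positions are uniform over valid starts on each chromosome,
#' strands are drawn with probability 1/2 each, and each base is substituted
#' independently at `error_rate`. Quality strings are constant high quality:
#' the downstream heuristics are count-based, not quality-based.
#'
#' @param genome the `genome` to sequence (reference or evolved).
#' @param mean_depth target mean fold-coverage (> 0).
#' @param read_len read length in bp (default 36).
#' @param error_rate per-base substitution probability.
#' @param seed RNG seed.
#' @param both_strands draw reads from both strands (default `TRUE`).
#' @return `list(reads = data.frame(id, seq, qual), origins = data.frame(id,
#'   chrom, start, strand))`; `origins` records each read's true origin on the
#'   sequenced genome.
#' @export
simulate_reads <- function(genome, mean_depth, read_len = 36L,
                           error_rate = 0.005, seed = 1, both_strands = TRUE) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  read_len <- as.integer(read_len)
  lens <- chrom_lengths(genome)
  if (read_len > min(lens)) stop("read_len exceeds the shortest chromosome")

  with_seed(seed, {
    all_seq <- character(0); all_chrom <- character(0); all_start <- integer(0)
    for (ch in names(genome$sequences)) {
      n <- round(mean_depth * lens[[ch]] / read_len)
      if (n == 0) next
      starts <- sample.int(lens[[ch]] - read_len + 1L, n, replace = TRUE)
      all_seq <- c(all_seq, substring(genome$sequences[[ch]], starts,
                                      starts + read_len - 1L))
      all_chrom <- c(all_chrom, rep(ch, n))
      all_start <- c(all_start, starts)
    }
    n_tot <- length(all_seq)
    strand <- if (both_strands) {
      ifelse(stats::runif(n_tot) < 0.5, "+", "-")
    } else rep("+", n_tot)
    minus <- strand == "-"
    if (any(minus)) all_seq[minus] <- revcomp(all_seq[minus])

    if (error_rate > 0 && n_tot > 0) {
      err <- which(stats::runif(n_tot * read_len) < error_rate)
      if (length(err) > 0) {
        ri <- ((err - 1L) %/% read_len) + 1L
        pj <- ((err - 1L) %% read_len) + 1L
        shift <- sample.int(3L, length(err), replace = TRUE)
        # several errors can hit one read: substitute in rounds
        while (length(ri) > 0) {
          first <- !duplicated(ri)
          i <- ri[first]; j <- pj[first]; s <- shift[first]
          orig <- substring(all_seq[i], j, j)
          newb <- BASES[((match(orig, BASES) - 1L + s) %% 4L) + 1L]
          all_seq[i] <- paste0(substring(all_seq[i], 1L, j - 1L), newb,
                               substring(all_seq[i], j + 1L, read_len))
          ri <- ri[!first]; pj <- pj[!first]; shift <- shift[!first]
        }
      }
    }
    ids <- sprintf("read_%07d", seq_len(n_tot))
    list(reads = data.frame(id = ids, seq = all_seq,
                            qual = strrep("I", read_len)),
         origins = data.frame(id = ids, chrom = all_chrom, start = all_start,
                              strand = strand))
  })
}

#' Write simulation fixtures to disk
#'
#' Writes the reference and evolved genomes as FASTA, each read set as FASTQ,
#' the truth SNPs and junctions as TSV and the amplification interval as BED
#' (0-based half-open, per the BED standard; all other outputs are 1-based
#' inclusive).
#'
#' @param reference,evolved `genome` objects.
#' @param readsets named list of read sets (as returned by
#'   [simulate_reads()]`$reads`).
#' @param truth a `truth_set` from [apply_evolution()].
#' @param out_dir output directory (created if absent).
#' @return named character vector of the written paths, invisibly.
#' @export
write_fixtures <- function(reference, evolved, readsets, truth, out_dir) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  paths <- c(reference = file.path(out_dir, "reference.fa"),
             evolved = file.path(out_dir, "evolved.fa"),
             snps = file.path(out_dir, "truth_snps.tsv"),
             junctions = file.path(out_dir, "truth_junctions.tsv"),
             amplification = file.path(out_dir, "truth_amplification.bed"))
  write_genome_fasta(reference, paths[["reference"]])
  write_genome_fasta(evolved, paths[["evolved"]])
  for (nm in names(readsets)) {
    p <- file.path(out_dir, paste0(nm, ".fastq"))
    write_reads_fastq(readsets[[nm]], p)
    paths[[nm]] <- p
  }
  utils::write.table(truth$snps, paths[["snps"]], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(truth$junctions, paths[["junctions"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(truth$amplification)) {
    gr <- GenomicRanges::GRanges(
      truth$amplification$chrom,
      IRanges::IRanges(truth$amplification$left, truth$amplification$right),
      name = truth$amplification$structure)
    rtracklayer::export(gr, paths[["amplification"]], format = "BED")
  } else {
    file.create(paths[["amplification"]])
  }
  invisible(paths)
}

#' Write reads to FASTQ
#' @param reads data frame with columns `id`, `seq`, `qual`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_reads_fastq <- function(reads, path) {
  ss <- Biostrings::DNAStringSet(reads$seq)
  names(ss) <- reads$id
  Biostrings::writeXStringSet(ss, path, format = "fastq",
                              qualities = Biostrings::BStringSet(reads$qual))
  invisible(path)
}

#' Read reads from FASTQ
#' @param path FASTQ path.
#' @return data frame with columns `id`, `seq`, `qual`.
#' @export
read_reads_fastq <- function(path) {
  ss <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  data.frame(id = names(ss), seq = as.character(ss),
             qual = as.character(S4Vectors::mcols(ss)$qualities))
}
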