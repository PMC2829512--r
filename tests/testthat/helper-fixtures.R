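# Shared fixtures, built in code and memoised for the test session.

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- force(expr)
  .fixture_cache[[key]]
}

# A small evolved/parent scenario (60 kb, 6 kb five-copy inverted
# amplification, 4 SNPs) mapped end to end; used by several module tests.
small_scenario <- function() {
  memo("small", {
    params <- within(strainscan::demo_scenario(), {
      genome_length <- 60000L
      amp_left <- 20007L
      amp_right <- 26044L
      snp_pos <- c(5000L, 12017L, 40234L, 50501L)
    })
    demo <- strainscan::build_demo(seed = 1, params = params)
    idx <- strainscan::build_index(demo$reference, params$read_len)
    me <- strainscan::map_reads(demo$reads_evolved, idx)
    mp <- strainscan::map_reads(demo$reads_parent, idx)
    mask <- strainscan::mappability_mask(demo$reference, params$read_len)
    list(demo = demo, params = params, index = idx,
         evolved = me, parent = mp, mask = mask,
         pile_e = strainscan::pileup(me$alignments, demo$reference),
         pile_p = strainscan::pileup(mp$alignments, demo$reference))
  })
}

# The full-scale scenario of the acceptance criteria: 200 kb reference,
# 11,038 bp five-copy tandem-inverted amplification, 4 SNPs, 35x/28x reads.
full_scenario <- function() {
  memo("full", {
    demo <- strainscan::build_demo(seed = 1)
    cfg <- strainscan::pipeline_config(reference = demo$reference,
                                       reads_evolved = demo$reads_evolved,
                                       reads_parent = demo$reads_parent,
                                       seed = 1)
    list(demo = demo, report = strainscan::run_pipeline(cfg))
  })
}

# hand-built containers for unit tests ------------------------------------

# depth_track with the given per-base depth vector(s)
fake_depth_track <- function(depth, total = NULL) {
  if (!is.list(depth)) depth <- list(chr1 = depth)
  total <- total %||% sum(vapply(depth, function(x) sum(as.double(x)),
                                 numeric(1)))
  structure(list(depth = depth,
                 nuclear = stats::setNames(rep(TRUE, length(depth)),
                                           names(depth)),
                 total_nuclear_bases = total),
            class = "depth_track")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# all-mappable mask of the given chromosome lengths
fake_mask <- function(lens, read_len = 36L) {
  structure(list(mask = lapply(lens, function(n) rep(TRUE, n)),
                 read_len = as.integer(read_len)),
            class = "mappability_mask")
}

# pileup with given depth vector and a single base everywhere, plus optional
# per-position overrides of the count column
fake_pileup <- function(depth, base = "A", overrides = NULL) {
  n <- length(depth)
  counts <- matrix(0L, 4, n, dimnames = list(c("A", "C", "G", "T"), NULL))
  counts[base, ] <- as.integer(depth)
  if (!is.null(overrides)) {
    for (i in seq_len(nrow(overrides))) {
      counts[, overrides$pos[i]] <- 0L
      for (b in c("A", "C", "G", "T")) {
        v <- overrides[[b]][i]
        if (!is.null(v) && !is.na(v)) counts[b, overrides$pos[i]] <- v
      }
    }
    depth[overrides$pos] <- colSums(counts)[overrides$pos]
  }
  structure(list(depth = list(chr1 = as.integer(colSums(counts))),
                 counts = list(chr1 = counts), read_len = 36L,
                 nuclear = c(chr1 = TRUE),
                 total_nuclear_bases = sum(colSums(counts))),
            class = "pileup")
}

# brute-force best ungapped placement of one read over a small genome
brute_force_map <- function(read, genome, max_mismatches = 2L) {
  L <- nchar(read)
  best <- NULL
  for (ch in names(genome$sequences)) {
    refseq <- genome$sequences[[ch]]
    n <- nchar(refseq)
    for (st in c("+", "-")) {
      q <- if (st == "+") read else strainscan::revcomp(read)
      qr <- charToRaw(q)
      for (s in seq_len(n - L + 1L)) {
        mm <- sum(qr != charToRaw(substr(refseq, s, s + L - 1L)))
        if (mm <= max_mismatches) {
          hit <- data.frame(chrom = ch, start = s, strand = st, mm = mm)
          best <- rbind(best, hit)
        }
      }
    }
  }
  if (is.null(best)) return(NULL)
  best <- best[best$mm == min(best$mm), , drop = FALSE]
  best[order(best$chrom, best$start, best$strand), , drop = FALSE]
}

# brute-force maximal-t arc over all contiguous arcs (independent oracle)
brute_force_max_t <- function(x) {
  n <- length(x)
  T <- sum(x)
  best <- list(t2 = -Inf, start = 0L, end = 0L, sign = 0)
  for (i in seq_len(n)) {
    jmax <- if (i == 1) n - 1 else n
    for (j in i:jmax) {
      arc <- x[i:j]
      comp <- x[-(i:j)]
      m <- length(arc); m2 <- n - m
      d <- mean(arc) - mean(comp)
      ssw <- sum((arc - mean(arc))^2) + sum((comp - mean(comp))^2)
      s2 <- ssw / (n - 2)
      den <- s2 * (1 / m + 1 / m2)
      t2 <- if (den <= 0) { if (d != 0) Inf else 0 } else d^2 / den
      if (t2 > best$t2 + 1e-9) best <- list(t2 = t2, start = i, end = j,
                                            sign = sign(d))
    }
  }
  best$t <- best$sign * sqrt(best$t2)
  best
}
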