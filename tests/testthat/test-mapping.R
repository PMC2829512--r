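test_that("index lookups count k-mer occurrences on both strands", {
  g <- generate_reference(1, 20000, seed = 11)
  # plant an exact distant duplication
  s <- g$sequences[["chr1"]]
  substr(s, 15001, 15100) <- substr(s, 5001, 5100)
  g$sequences[["chr1"]] <- s
  idx <- build_index(g, 36)
  uniq <- substr(s, 1000, 1035)
  expect_equal(lookup_kmer(idx, uniq)$count, 1)
  dup <- substr(s, 5010, 5045)
  expect_gte(lookup_kmer(idx, dup)$count, 2)
  absent <- paste(rep("ACGT", 9), collapse = "")
  if (!grepl(absent, s) && !grepl(revcomp(absent), s))
    expect_equal(lookup_kmer(idx, absent)$count, 0)
  expect_error(build_index(g, 8), ">= 12")
})

test_that("map_read places clean reads and rejects junction/error reads", {
  sc <- small_scenario()
  ref <- sc$demo$reference
  idx <- sc$index
  read <- substr(ref$sequences[["chr1"]], 3001, 3036)
  a <- map_read(read, idx)
  expect_identical(a$mapq_class, "unique-high")
  expect_equal(a$start, 3001)
  expect_identical(a$strand, "+")
  expect_equal(a$mismatches, 0)

  # reverse-strand read maps to the same origin
  a2 <- map_read(revcomp(read), idx)
  expect_equal(a2$start, 3001)
  expect_identical(a2$strand, "-")

  # three errors exceed the budget
  bad <- read
  substr(bad, 5, 5) <- chartr("ACGT", "CATG", substr(bad, 5, 5))
  substr(bad, 15, 15) <- chartr("ACGT", "CATG", substr(bad, 15, 15))
  substr(bad, 25, 25) <- chartr("ACGT", "CATG", substr(bad, 25, 25))
  expect_null(map_read(bad, idx, max_mismatches = 2))

  # a read straddling an inverted junction has no ungapped placement
  jseq <- sc$demo$truth$junctions$sequence[1]
  jread <- substr(jseq, 13, 48)   # centred on the junction
  expect_null(map_read(jread, idx))
  expect_null(brute_force_map(jread, ref))

  expect_error(map_read(substr(read, 1, 20), idx), "length")
})

test_that("map_read agrees with a brute-force scan on a small genome", {
  g <- generate_reference(1, 5000, seed = 12)
  idx <- build_index(g, 36)
  set.seed(13)
  for (rep_i in 1:60) {
    start <- sample(4965, 1)
    read <- substr(g$sequences[["chr1"]], start, start + 35)
    n_err <- sample(0:3, 1)
    if (n_err > 0) {
      at <- sample(36, n_err)
      for (p in at)
        substr(read, p, p) <- chartr("ACGT", "CATG", substr(read, p, p))
    }
    if (sample(c(TRUE, FALSE), 1)) read <- revcomp(read)
    mine <- map_read(read, idx)
    oracle <- brute_force_map(read, g)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      expect_false(is.null(mine))
      expect_equal(mine$mismatches, oracle$mm[1])
      if (nrow(oracle) == 1) {
        expect_identical(mine$mapq_class, "unique-high")
        expect_equal(mine$start, oracle$start)
        expect_identical(mine$strand, oracle$strand)
      } else {
        expect_identical(mine$mapq_class, "multi-zero")
      }
    }
  }
})

test_that("depth is conserved and pileup columns are consistent", {
  sc <- small_scenario()
  aln <- sc$evolved$alignments
  n_uh <- sum(aln$mapq_class == "unique-high")
  expect_equal(sc$pile_e$total_nuclear_bases, n_uh * 36)
  # depth equals the column sum of base counts everywhere
  expect_identical(sc$pile_e$depth[["chr1"]],
                   as.integer(colSums(sc$pile_e$counts[["chr1"]])))
})

test_that("pileup handles single reads, disagreements and multi-zero", {
  g <- genome(c(chr1 = paste(rep("ACGTTGCAAC", 10), collapse = "")))
  read <- substr(g$sequences[["chr1"]], 11, 46)
  disagree <- read
  substr(disagree, 20, 20) <- "T"  # covered position 30
  aln <- data.frame(
    read_id = c("r1", "r2", "r3"),
    chrom = "chr1", start = c(11L, 11L, 1L),
    strand = c("+", "+", "+"),
    mismatches = c(0L, 1L, 0L),
    mapq_class = c("unique-high", "unique-high", "multi-zero"),
    seq = c(read, disagree, substr(g$sequences[["chr1"]], 1, 36)))
  p <- pileup(aln[1, ], g)
  expect_identical(p$depth[["chr1"]][11:46], rep(1L, 36))
  expect_identical(sum(p$depth[["chr1"]]), 36L)
  refbases <- strsplit(read, "")[[1]]
  got <- apply(p$counts[["chr1"]][, 11:46], 2, function(cl) names(which(cl == 1)))
  expect_identical(unname(got), refbases)

  p2 <- pileup(aln[1:2, ], g)
  col <- p2$counts[["chr1"]][, 30]
  expect_equal(sum(col == 1), 2)  # two different bases with one call each

  p3 <- pileup(aln, g)  # multi-zero contributes nothing
  expect_identical(p3$depth, p2$depth)
  expect_identical(p3$counts, p2$counts)
})

test_that("read_sam ingests mapped, low-quality and unmapped records", {
  g <- generate_reference(1, 1000, seed = 14)
  s <- g$sequences[["chr1"]]
  sam <- tempfile(fileext = ".sam")
  qual <- strrep("I", 36)
  writeLines(c(
    "@HD\tVN:1.6\tSO:unsorted",
    "@SQ\tSN:chr1\tLN:1000",
    paste("r1", 0, "chr1", 101, 30, "36M", "*", 0, 0,
          substr(s, 101, 136), qual, sep = "\t"),
    paste("r2", 16, "chr1", 201, 5, "36M", "*", 0, 0,
          substr(s, 201, 236), qual, sep = "\t"),
    paste("r3", 4, "*", 0, 0, "*", "*", 0, 0,
          strrep("ACGTACGTA", 4), qual, sep = "\t")), sam)
  res <- read_sam(sam, genome = g)
  expect_equal(nrow(res$alignments), 2)
  expect_equal(nrow(res$unmapped), 1)
  expect_identical(res$alignments$mapq_class[res$alignments$read_id == "r2"],
                   "multi-zero")
  expect_identical(res$alignments$mapq_class[res$alignments$read_id == "r1"],
                   "unique-high")
  expect_identical(res$alignments$mismatches, c(0L, 0L))
  # SAM-derived alignments feed the same pileup machinery
  p <- pileup(res$alignments, g)
  expect_equal(sum(p$depth[["chr1"]]), 36)
})

test_that("mappability mask marks unique windows, repeats and chromosome ends", {
  g <- generate_reference(1, 50000, seed = 15)
  mask <- mappability_mask(g, 36)
  m <- mask$mask[["chr1"]]
  expect_gte(mean(m), 0.99)
  expect_false(any(m[(50000 - 34):50000]))

  # exact 1 kb duplication: windows wholly inside either copy are unmappable
  s <- g$sequences[["chr1"]]
  substr(s, 30001, 31000) <- substr(s, 10001, 11000)
  g2 <- genome(c(chr1 = s))
  m2 <- mappability_mask(g2, 36)$mask[["chr1"]]
  expect_false(any(m2[10001:(11000 - 35)]))
  expect_false(any(m2[30001:(31000 - 35)]))
  expect_true(all(m2[1000:9000]))
})

test_that("longer windows never shrink the mappable set away from ends", {
  g <- generate_reference(1, 8000, seed = 16)
  s <- g$sequences[["chr1"]]
  substr(s, 6001, 6200) <- substr(s, 2001, 2200)  # force some repeats
  g <- genome(c(chr1 = s))
  m24 <- mappability_mask(g, 24)$mask[["chr1"]]
  m36 <- mappability_mask(g, 36)$mask[["chr1"]]
  interior <- seq_len(8000 - 36 + 1)
  expect_true(all(which(m24[interior]) %in% which(m36[interior])))
})
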