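test_that("assembler reconstructs an unambiguous junction template", {
  g <- generate_reference(1, 2000, seed = 61)
  template <- substr(g$sequences[["chr1"]], 501, 560)  # 60 bp
  starts <- rep(1:25, each = 8)
  reads <- substring(template, starts, starts + 35)
  reads[seq(1, length(reads), 2)] <- revcomp(reads[seq(1, length(reads), 2)])
  ctgs <- assemble_contigs(data.frame(id = seq_along(reads), seq = reads),
                           k = 21)
  expect_equal(nrow(ctgs), 1)
  expect_true(ctgs$seq == template || ctgs$seq == revcomp(template))
  expect_equal(ctgs$reads, length(reads))

  expect_equal(nrow(assemble_contigs(character(0))), 0)
  expect_error(assemble_contigs(reads, k = 10), "12 <= k")
})

test_that("assembler recovers a repeat-free template from tiling reads", {
  g <- generate_reference(1, 1500, seed = 62)
  template <- g$sequences[["chr1"]]
  starts <- seq(1, 1500 - 35, by = 1)
  reads <- substring(template, starts, starts + 35)
  reads <- c(reads, reads)  # coverage 2 everywhere
  ctgs <- assemble_contigs(reads, k = 21)
  expect_equal(nrow(ctgs), 1)
  expect_true(ctgs$seq == template || ctgs$seq == revcomp(template))
})

test_that("align_contig reports exact, absent and junction contigs correctly", {
  sc <- small_scenario()
  ref <- sc$demo$reference
  exact <- substr(ref$sequences[["chr1"]], 4001, 4050)
  a <- align_contig(exact, ref)
  expect_equal(nrow(a), 1)
  expect_equal(a$contig_start, 1); expect_equal(a$contig_end, 50)
  expect_equal(a$ref_start, 4001); expect_equal(a$ref_end, 4050)
  expect_equal(a$identity, 1)

  set.seed(63)
  random <- paste(sample(c("A", "C", "G", "T"), 50, replace = TRUE),
                  collapse = "")
  if (nrow(align_contig(random, ref)) > 0) skip("random 50-mer hit the genome")
  expect_equal(nrow(align_contig(random, ref)), 0)

  jseq <- sc$demo$truth$junctions$sequence[
    sc$demo$truth$junctions$side == "left"]
  aj <- align_contig(jseq, ref)
  expect_equal(nrow(aj), 2)
  expect_setequal(aj$strand, c("+", "-"))
  lens <- aj$contig_end - aj$contig_start + 1
  expect_equal(sum(lens) - nchar(jseq), 7)
})

test_that("contig filters drop single-region and unmappable-end contigs", {
  sc <- small_scenario()
  ref <- sc$demo$reference
  mask <- sc$mask

  plain <- substr(ref$sequences[["chr1"]], 8001, 8060)
  jseq <- sc$demo$truth$junctions$sequence[1]
  ctgs <- data.frame(id = c("c1", "c2"), seq = c(plain, jseq),
                     length = nchar(c(plain, jseq)), reads = c(5L, 5L))
  aln <- do.call(rbind, lapply(1:2, function(i)
    cbind(contig_id = ctgs$id[i], align_contig(ctgs$seq[i], ref))))
  fl <- filter_contigs(ctgs, aln, mask)
  expect_identical(fl$contigs$id, "c2")   # full-length single region removed

  # junction-like contig whose one end lies in a planted unmappable repeat
  s <- ref$sequences[["chr1"]]
  substr(s, 45001, 46000) <- substr(s, 41001, 42000)
  g2 <- genome(c(chr1 = s))
  mask2 <- mappability_mask(g2, 36)
  chim <- paste0(substr(s, 41401, 41430), revcomp(substr(s, 3001, 3030)))
  ctg3 <- data.frame(id = "c3", seq = chim, length = nchar(chim), reads = 3L)
  aln3 <- cbind(contig_id = "c3", align_contig(chim, g2))
  fl3 <- filter_contigs(ctg3, aln3, mask2)
  expect_equal(nrow(fl3$contigs), 0)
  # the same chimera anchored in unique sequence is retained
  chim2 <- paste0(substr(s, 30001, 30030), revcomp(substr(s, 3001, 3030)))
  ctg4 <- data.frame(id = "c4", seq = chim2, length = nchar(chim2), reads = 3L)
  aln4 <- cbind(contig_id = "c4", align_contig(chim2, g2))
  fl4 <- filter_contigs(ctg4, aln4, mask2)
  expect_equal(nrow(fl4$contigs), 1)
})

test_that("classification reproduces the published junction geometries", {
  g <- generate_reference(1, 30000, seed = 64)
  # keep the micro-homology at exactly the arm length: the base at `pos` must
  # not pair with the base at `partner`
  break_pal <- function(g, pos, partner) {
    s <- g$sequences[["chr1"]]
    forbidden <- chartr("ACGT", "TGCA", substr(s, partner, partner))
    if (substr(s, pos, pos) == forbidden)
      substr(s, pos, pos) <- setdiff(c("A", "C", "G", "T"), forbidden)[1]
    g$sequences[["chr1"]] <- s
    g
  }
  # left-style junction: arm 7, spacer 18; contig pieces 26 and 33 on 52 nt
  q <- 10000L; sp <- 18L
  g7 <- plant_inverted_repeats(g, "chr1", boundary = q, arm_len = 7,
                               spacer = sp)
  g7 <- break_pal(g7, q + sp, q + 1)
  g7 <- break_pal(g7, q + sp + 8, q - 7)
  s <- g7$sequences[["chr1"]]
  ctg <- paste0(substr(s, q - 25, q), revcomp(substr(s, q + sp - 25, q + sp)))
  expect_equal(nchar(ctg), 52)
  a <- align_contig(ctg, g7)
  expect_equal(nrow(a), 2)
  call <- classify_breakpoint(ctg, a)
  lens <- sort(a$contig_end - a$contig_start + 1)
  expect_equal(lens, c(26, 33))
  expect_identical(call$orientation, "inverted")
  expect_equal(call$overlap, 7)

  # right-style junction: arm 13, spacer 42; pieces 32 and 32 on 51 nt
  q2 <- 20000L; sp2 <- 42L
  g13 <- plant_inverted_repeats(g, "chr1", boundary = q2, arm_len = 13,
                                spacer = sp2)
  g13 <- break_pal(g13, q2 + sp2, q2 + 1)
  g13 <- break_pal(g13, q2 + sp2 + 14, q2 - 13)
  s2 <- g13$sequences[["chr1"]]
  ctg2 <- paste0(substr(s2, q2 - 31, q2),
                 revcomp(substr(s2, q2 + sp2 - 18, q2 + sp2)))
  expect_equal(nchar(ctg2), 51)
  a2 <- align_contig(ctg2, g13)
  expect_equal(nrow(a2), 2)
  call2 <- classify_breakpoint(ctg2, a2)
  lens2 <- sort(a2$contig_end - a2$contig_start + 1)
  expect_equal(lens2, c(32, 32))
  expect_identical(call2$orientation, "inverted")
  expect_equal(call2$overlap, 13)

  # direct-orientation abutting parts classify as direct with zero overlap
  fake_aln <- data.frame(contig_start = c(1L, 26L), contig_end = c(25L, 50L),
                         chrom = "chr1", ref_start = c(100L, 500L),
                         ref_end = c(124L, 524L), strand = "+",
                         identity = 1)
  call3 <- classify_breakpoint(strrep("A", 50), fake_aln)
  expect_identical(call3$orientation, "direct")
  expect_equal(call3$overlap, 0)
  expect_error(classify_breakpoint(strrep("A", 50), fake_aln[1, ]), "two")
})

test_that("wild-type spanning support behaves at junctions and deletions", {
  sc <- small_scenario()
  ref <- sc$demo$reference
  tr <- sc$demo$truth$amplification
  wl <- wildtype_support(sc$evolved$alignments, ref, "chr1", tr$left)
  wr <- wildtype_support(sc$evolved$alignments, ref, "chr1", tr$right)
  expect_true(wl$supported); expect_gt(wl$n_reads, 5)
  expect_true(wr$supported); expect_gt(wr$n_reads, 5)

  # a clean deletion boundary has no wild-type spanning reads
  g <- generate_reference(1, 10000, seed = 65)
  s <- g$sequences[["chr1"]]
  evo <- genome(c(chr1 = paste0(substr(s, 1, 5000), substr(s, 5051, 10000))))
  re <- simulate_reads(evo, 25, 36, 0, seed = 66)
  idx <- build_index(g, 36)
  me <- map_reads(re$reads, idx)
  wt <- wildtype_support(me$alignments, g, "chr1", 5010)
  expect_false(wt$supported)

  # a window wider than the read length can never be spanned
  wt2 <- wildtype_support(sc$evolved$alignments, ref, "chr1", 30000,
                          min_span = 40)
  expect_false(wt2$supported)
  expect_error(wildtype_support(sc$evolved$alignments, ref, "chr1", -5),
               "range")
})

test_that("background probability matches its definition and monotonicity", {
  expect_equal(background_probability(0, 1e7, 50, 2), 0)
  expect_equal(background_probability(1e7, 1e7, 2, 1), 1)  # capped
  p0 <- background_probability(2, 1.132e7, 50, 2)
  for (w in c(60, 100)) expect_gte(background_probability(2, 1.132e7, w, 2), p0)
  for (nb in 3:4) expect_gte(background_probability(nb, 1.132e7, 50, 2), p0)
  expect_lte(background_probability(2, 2e7, 50, 2), p0)
  expect_error(background_probability(2, 0, 50, 2), "mappable")
})

test_that("structure inference requires inversion, location and wild-type", {
  seg <- data.frame(chrom = "chr1", start = 1000L, end = 2000L, n_bins = 40L,
                    mean_log2 = log2(5), copy_ratio = 5, uncertainty = 25L)
  inv <- data.frame(orientation = "inverted", overlap = 7L, chrom = "chr1",
                    coord_a = 1000L, coord_b = 990L, in_amplification = TRUE)
  dir <- transform(inv, orientation = "direct")
  m1 <- infer_structure(seg, copy_ratio(log2(5)), inv, inv, TRUE, TRUE)
  expect_identical(m1$structure, "tandem_inverted")
  expect_equal(m1$copy_number, 5)
  m2 <- infer_structure(seg, 5, inv, inv, TRUE, FALSE)
  expect_identical(m2$structure, "unresolved")
  m3 <- infer_structure(seg, 5, dir, dir, TRUE, TRUE)
  expect_identical(m3$structure, "unresolved")
})

test_that("junctions are recovered with planted overlaps across seeds", {
  params <- within(strainscan::demo_scenario(), {
    genome_length <- 40000L
    amp_left <- 15007L
    amp_right <- 19044L
    snp_pos <- integer(0)
  })
  hits <- 0L
  for (s in 1:10) {
    demo <- build_demo(seed = 1000 + s, params = params)
    idx <- build_index(demo$reference, 36)
    me <- map_reads(demo$reads_evolved, idx)
    mask <- mappability_mask(demo$reference, 36)
    ctgs <- assemble_contigs(me$unmapped)
    if (nrow(ctgs) == 0) next
    aln <- do.call(rbind, lapply(seq_len(nrow(ctgs)), function(i) {
      a <- align_contig(ctgs$seq[i], demo$reference)
      if (nrow(a) == 0) return(NULL)
      cbind(contig_id = ctgs$id[i], a)
    }))
    fl <- filter_contigs(ctgs, aln, mask)
    overlaps <- integer(0)
    for (id in fl$contigs$id) {
      a <- fl$alignments[fl$alignments$contig_id == id, ]
      if (nrow(a) != 2) next
      ctg <- fl$contigs$seq[fl$contigs$id == id]
      call <- classify_breakpoint(ctg, a)
      # overlap identity invariant for every retained two-part contig
      lens <- a$contig_end - a$contig_start + 1
      expect_equal(call$overlap, sum(lens) - nchar(ctg))
      # a sequencing error adjacent to the junction can trim one alignment
      # and leave a 1-base gap; only gap-free calls are junction evidence
      if (call$orientation == "inverted" && call$overlap >= 0)
        overlaps <- c(overlaps, call$overlap)
    }
    if (all(c(7L, 13L) %in% overlaps)) hits <- hits + 1L
  }
  expect_gte(hits, 9)
})
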