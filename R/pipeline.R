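## Pipeline orchestration: configuration, the end-to-end run
## (simulate/ingest -> map -> SNP/indel -> CNV -> breakpoints -> structure
## report) and the one-command demo scenario generator.

#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default. Inputs may be
#' in-memory objects (`genome`, read data frames) or file paths (FASTA,
#' FASTQ, SAM).
#'
#' @param reference reference genome (`genome` object or FASTA path).
#' @param reads_evolved,reads_parent read sets (data frame or FASTQ path), or
#'   `NULL` when SAM input is used.
#' @param sam_evolved,sam_parent optional SAM paths; take precedence over
#'   FASTQ input.
#' @param out_dir output directory, or `NULL` for no file output.
#' @param read_len read length (bp).
#' @param max_mismatches mapper mismatch budget.
#' @param snp [snp_thresholds()].
#' @param bin_width CNV bin width (bp).
#' @param cbs [cbs_params()].
#' @param assembly_k,assembly_min_contig_len,assembly_min_kmer_count assembler
#'   settings.
#' @param min_identity contig alignment identity threshold.
#' @param min_contig_coverage contig-filter coverage threshold.
#' @param uncertainty boundary uncertainty window (bp).
#' @param indel_min_support minimum supporting reads for an indel candidate.
#' @param wildtype_min_span wild-type-spanning window half-width (bp).
#' @param stages character vector of stages to run (subset of `"snps"`,
#'   `"indels"`, `"cnv"`, `"breakpoints"`).
#' @param seed seed forwarded to every stage that uses randomness.
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(reference,
                            reads_evolved = NULL, reads_parent = NULL,
                            sam_evolved = NULL, sam_parent = NULL,
                            out_dir = NULL,
                            read_len = 36L, max_mismatches = 2L,
                            snp = snp_thresholds(),
                            bin_width = 25L, cbs = NULL,
                            assembly_k = 21L, assembly_min_contig_len = 30L,
                            assembly_min_kmer_count = 2L,
                            min_identity = 0.9, min_contig_coverage = 0.9,
                            uncertainty = 25L, indel_min_support = 2L,
                            wildtype_min_span = 5L,
                            stages = c("snps", "indels", "cnv", "breakpoints"),
                            seed = 1L) {
  if (is.null(cbs)) cbs <- cbs_params(seed = derive_seed(seed, 101L))
  cfg <- structure(list(
    reference = reference, reads_evolved = reads_evolved,
    reads_parent = reads_parent, sam_evolved = sam_evolved,
    sam_parent = sam_parent, out_dir = out_dir,
    read_len = as.integer(read_len), max_mismatches = as.integer(max_mismatches),
    snp = snp, bin_width = as.integer(bin_width), cbs = cbs,
    assembly_k = as.integer(assembly_k),
    assembly_min_contig_len = as.integer(assembly_min_contig_len),
    assembly_min_kmer_count = as.integer(assembly_min_kmer_count),
    min_identity = min_identity, min_contig_coverage = min_contig_coverage,
    uncertainty = as.integer(uncertainty),
    indel_min_support = as.integer(indel_min_support),
    wildtype_min_span = as.integer(wildtype_min_span),
    stages = stages, seed = as.integer(seed)), class = "pipeline_config")
  validate_config(cfg)
  cfg
}

validate_config <- function(cfg) {
  fail <- function(field, why) stop("invalid config field `", field, "`: ", why,
                                    call. = FALSE)
  if (is.null(cfg$reference)) fail("reference", "missing")
  if (is.character(cfg$reference) && !file.exists(cfg$reference))
    fail("reference", "file does not exist")
  for (f in c("sam_evolved", "sam_parent")) {
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]])) fail(f, "file does not exist")
  }
  for (f in c("reads_evolved", "reads_parent")) {
    v <- cfg[[f]]
    if (is.character(v) && !file.exists(v)) fail(f, "file does not exist")
  }
  has_ev <- !is.null(cfg$reads_evolved) || !is.null(cfg$sam_evolved)
  has_pa <- !is.null(cfg$reads_parent) || !is.null(cfg$sam_parent)
  if (!has_ev) fail("reads_evolved", "no evolved-strain input (FASTQ/SAM)")
  if (!has_pa) fail("reads_parent", "no parent-strain input (FASTQ/SAM)")
  if (cfg$read_len < 12) fail("read_len", "must be >= 12")
  if (cfg$bin_width < 1) fail("bin_width", "must be >= 1")
  if (!all(cfg$stages %in% c("snps", "indels", "cnv", "breakpoints")))
    fail("stages", "unknown stage name")
  invisible(cfg)
}

load_reference <- function(ref) {
  if (inherits(ref, "genome")) return(ref)
  read_genome_fasta(ref)
}

load_strain <- function(cfg, strain, ref, index) {
  sam <- cfg[[paste0("sam_", strain)]]
  if (!is.null(sam)) return(read_sam(sam, genome = ref))
  reads <- cfg[[paste0("reads_", strain)]]
  if (is.character(reads)) reads <- read_reads_fastq(reads)
  map_reads(reads, index, cfg$max_mismatches)
}

config_as_list <- function(cfg) {
  keep <- setdiff(names(cfg), c("reference", "reads_evolved", "reads_parent"))
  out <- lapply(cfg[keep], function(v) if (is.list(v)) unclass(v) else v)
  out$reference <- if (is.character(cfg$reference)) cfg$reference else "<in-memory>"
  for (f in c("reads_evolved", "reads_parent"))
    out[[f]] <- if (is.character(cfg[[f]])) cfg[[f]] else
      if (is.null(cfg[[f]])) NULL else "<in-memory>"
  out
}

#' Run the full comparison pipeline
#'
#' Maps (or ingests) reads for both strains, then runs the requested stages:
#' SNP calling, the small-indel screen, copy-number segmentation and
#' breakpoint/structure analysis. When `out_dir` is set, writes SNPs as VCF,
#' segments as BED + TSV, breakpoint calls as TSV with a FASTA of junction
#' contigs, indel candidates as TSV, a JSON structure report, the serialized
#' configuration (YAML) and a run log.
#'
#' @param config a [pipeline_config()].
#' @return a report list with elements `snps`, `callable_fraction`, `indels`,
#'   `segments`, `amplified_segment`, `breakpoints`, `structure`
#'   (`amplification_model`), `background_probability`, `files`.
#' @export
run_pipeline <- function(config) {
  cfg <- validate_config(config)
  logline <- character(0)
  say <- function(...) logline <<- c(logline, paste0(...))

  ref <- load_reference(cfg$reference)
  index <- build_index(ref, cfg$read_len)
  say("reference loaded: ", sum(chrom_lengths(ref)), " bp, ",
      length(ref$sequences), " chromosome(s)")
  evolved <- load_strain(cfg, "evolved", ref, index)
  parent <- load_strain(cfg, "parent", ref, index)
  say("evolved: ", nrow(evolved$alignments), " aligned, ",
      nrow(evolved$unmapped), " unmapped")
  say("parent: ", nrow(parent$alignments), " aligned, ",
      nrow(parent$unmapped), " unmapped")

  mask <- mappability_mask(ref, cfg$read_len)
  pile_e <- pileup(evolved$alignments, ref)
  pile_p <- pileup(parent$alignments, ref)

  report <- list(files = character(0))
  out <- cfg$out_dir
  if (!is.null(out) && !dir.exists(out)) dir.create(out, recursive = TRUE)
  emit <- function(name, path) report$files[[name]] <<- path

  if ("snps" %in% cfg$stages) {
    report$snps <- call_snps(pile_e, pile_p, mask, cfg$snp)
    report$callable_fraction <- callable_fraction(pile_e, pile_p, mask, cfg$snp)
    say("snps: ", nrow(report$snps), " call(s); callable fraction ",
        sprintf("%.4f", report$callable_fraction))
    if (!is.null(out)) {
      p <- file.path(out, "snps.vcf")
      write_snp_vcf(report$snps, ref, p)
      emit("snps_vcf", p)
    }
  }

  if ("indels" %in% cfg$stages) {
    report$indels <- screen_indels(evolved$unmapped, parent$unmapped, ref,
                                   evolved$alignments, parent$alignments,
                                   min_support = cfg$indel_min_support,
                                   min_span = cfg$wildtype_min_span)
    say("indels: ", nrow(report$indels), " candidate(s)")
    if (!is.null(out)) {
      p <- file.path(out, "indels.tsv")
      utils::write.table(report$indels, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit("indels_tsv", p)
    }
  }

  segments <- NULL
  if ("cnv" %in% cfg$stages) {
    bins <- bin_depth(pile_e, pile_p, mask, width = cfg$bin_width)
    segments <- cbs_segment(bins, cfg$cbs)
    report$segments <- segments
    report$bins <- bins
    say("cnv: ", nrow(segments), " segment(s)")
    if (!is.null(out)) {
      p <- file.path(out, "segments.tsv")
      utils::write.table(segments, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit("segments_tsv", p)
      gr <- GenomicRanges::GRanges(segments$chrom,
                                   IRanges::IRanges(segments$start, segments$end),
                                   score = segments$mean_log2)
      pb <- file.path(out, "segments.bed")
      rtracklayer::export(gr, pb, format = "BED")
      emit("segments_bed", pb)
    }
  }

  if ("breakpoints" %in% cfg$stages) {
    amp <- NULL
    if (!is.null(segments) && nrow(segments) > 0) {
      cand <- segments[abs(segments$mean_log2) > 0.5, , drop = FALSE]
      if (nrow(cand) > 0) amp <- cand[which.max(cand$mean_log2), , drop = FALSE]
    }
    report$amplified_segment <- amp

    bp <- breakpoint_analysis(evolved$unmapped, parent$unmapped, ref, mask,
                              evolved$alignments, amp, cfg)
    report$breakpoints <- bp$calls
    report$contigs <- bp$contigs
    report$background_probability <- bp$background_probability
    report$structure <- bp$model
    say("breakpoints: ", nrow(bp$calls), " call(s); structure ",
        if (is.null(bp$model)) "NA" else bp$model$structure)
    if (!is.null(out)) {
      p <- file.path(out, "breakpoints.tsv")
      utils::write.table(bp$calls, p, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      emit("breakpoints_tsv", p)
      if (nrow(bp$contigs) > 0) {
        pf <- file.path(out, "junction_contigs.fa")
        ss <- Biostrings::DNAStringSet(bp$contigs$seq)
        names(ss) <- bp$contigs$id
        Biostrings::writeXStringSet(ss, pf)
        emit("contigs_fasta", pf)
      }
    }
  }

  if (!is.null(out)) {
    pj <- file.path(out, "structure_report.json")
    jsonlite::write_json(structure_report(report), pj, auto_unbox = TRUE,
                         pretty = TRUE, digits = NA)
    emit("report_json", pj)
    py <- file.path(out, "config.yaml")
    yaml::write_yaml(config_as_list(cfg), py)
    emit("config_yaml", py)
    pl <- file.path(out, "run.log")
    writeLines(logline, pl)
    emit("run_log", pl)
  }
  report$log <- logline
  report
}

# evolved-side contig/breakpoint analysis plus the ancestor background
breakpoint_analysis <- function(unmapped_evolved, unmapped_parent, ref, mask,
                                alignments_evolved, amp, cfg) {
  assemble <- function(pool) {
    assemble_contigs(pool, k = cfg$assembly_k,
                     min_contig_len = cfg$assembly_min_contig_len,
                     min_kmer_count = cfg$assembly_min_kmer_count)
  }
  align_all <- function(contigs) {
    if (nrow(contigs) == 0) return(NULL)
    do.call(rbind, lapply(seq_len(nrow(contigs)), function(i) {
      a <- align_contig(contigs$seq[i], ref, min_identity = cfg$min_identity)
      if (nrow(a) == 0) return(NULL)
      cbind(contig_id = contigs$id[i], a)
    }))
  }
  filter_all <- function(contigs) {
    aln <- align_all(contigs)
    if (is.null(aln) || nrow(aln) == 0)
      return(list(contigs = contigs[0, ], alignments = NULL))
    filter_contigs(contigs, aln, mask,
                   min_coverage = cfg$min_contig_coverage)
  }

  ev <- filter_all(assemble(unmapped_evolved))
  calls <- NULL
  for (id in ev$contigs$id) {
    a <- ev$alignments[ev$alignments$contig_id == id, , drop = FALSE]
    if (nrow(a) != 2L) next
    cl <- classify_breakpoint(ev$contigs$seq[ev$contigs$id == id], a,
                              segment = amp, uncertainty = cfg$uncertainty)
    cl <- cbind(contig_id = id, cl)
    calls <- rbind(calls, cl)
  }
  if (is.null(calls))
    calls <- data.frame(contig_id = character(), orientation = character(),
                        overlap = integer(), chrom = character(),
                        coord_a = integer(), coord_b = integer(),
                        in_amplification = logical())

  # ancestor background: breakpoint-like contigs on nuclear chromosomes
  pa <- filter_all(assemble(unmapped_parent))
  n_bg <- if (nrow(pa$contigs) == 0) 0L else {
    nuc <- names(ref$sequences)[ref$nuclear]
    sum(vapply(pa$contigs$id, function(id) {
      a <- pa$alignments[pa$alignments$contig_id == id, , drop = FALSE]
      all(a$chrom %in% nuc)
    }, logical(1)))
  }

  model <- NULL
  bgp <- NA_real_
  if (!is.null(amp)) {
    inamp <- calls[isTRUE_vec(calls$in_amplification), , drop = FALSE]
    left_call <- right_call <- NULL
    if (nrow(inamp) > 0) {
      d_left <- pmin(abs(inamp$coord_a - amp$start), abs(inamp$coord_b - amp$start))
      d_right <- pmin(abs(inamp$coord_a - amp$end), abs(inamp$coord_b - amp$end))
      side <- ifelse(d_left <= d_right, "left", "right")
      if (any(side == "left"))
        left_call <- inamp[side == "left", ][which.min(d_left[side == "left"]), ]
      if (any(side == "right"))
        right_call <- inamp[side == "right", ][which.min(d_right[side == "right"]), ]
    }
    wt_l <- wildtype_support(alignments_evolved, ref, amp$chrom, amp$start,
                             min_span = cfg$wildtype_min_span)
    wt_r <- wildtype_support(alignments_evolved, ref, amp$chrom, amp$end,
                             min_span = cfg$wildtype_min_span)
    bgp <- background_probability(n_bg, mappable_bases(mask, ref),
                                  window = 2L * cfg$uncertainty,
                                  n_breakpoints = 2L)
    model <- infer_structure(amp, copy_ratio(amp), left_call, right_call,
                             wt_l, wt_r)
  }
  list(contigs = ev$contigs, calls = calls, background_probability = bgp,
       model = model, n_background = n_bg)
}

isTRUE_vec <- function(x) !is.na(x) & x

structure_report <- function(report) {
  model <- report$structure
  list(
    snps = if (is.null(report$snps)) NULL else nrow(report$snps),
    callable_fraction = report$callable_fraction,
    indel_candidates = if (is.null(report$indels)) NULL else nrow(report$indels),
    n_segments = if (is.null(report$segments)) NULL else nrow(report$segments),
    amplified_segment = if (is.null(report$amplified_segment)) NULL else
      as.list(report$amplified_segment),
    copy_ratio = if (is.null(model)) NULL else model$copy_ratio,
    copy_number = if (is.null(model)) NULL else model$copy_number,
    structure = if (is.null(model)) NULL else model$structure,
    breakpoint_overlaps = if (is.null(report$breakpoints) ||
                              nrow(report$breakpoints) == 0) NULL else
      report$breakpoints$overlap,
    background_probability = report$background_probability)
}

#' Write SNP calls as a haploid VCF
#'
#' The parent base is the REF allele and the evolved base the single ALT;
#' the strains are haploid and the caller count-based, so no genotype fields
#' are emitted.
#'
#' @param snps SNP data frame from [call_snps()].
#' @param genome the reference `genome` (for contig lengths).
#' @param path output VCF path.
#' @return `path`, invisibly.
#' @export
write_snp_vcf <- function(snps, genome, path) {
  lens <- chrom_lengths(genome)
  gr <- GenomicRanges::GRanges(
    snps$chrom, IRanges::IRanges(snps$pos, width = 1L),
    seqlengths = stats::setNames(as.integer(lens), names(lens)))
  names(gr) <- sprintf("snp%d", seq_along(gr))
  fixed <- S4Vectors::DataFrame(
    REF = Biostrings::DNAStringSet(snps$parent_base),
    ALT = Biostrings::DNAStringSetList(as.list(snps$evolved_base)),
    QUAL = rep(NA_real_, nrow(snps)),
    FILTER = rep("PASS", nrow(snps)))
  vcf <- VariantAnnotation::VCF(rowRanges = gr, fixed = fixed,
                                collapsed = TRUE)
  VariantAnnotation::writeVcf(vcf, path)
  # htslib-compatible parsers require ##fileformat as the first line
  lines <- readLines(path)
  ff <- grepl("^##fileformat=", lines)
  lines <- c(if (any(ff)) lines[ff][1] else "##fileformat=VCFv4.2", lines[!ff])
  writeLines(lines, path)
  invisible(path)
}

## ---- demo scenario -------------------------------------------------------

#' Default demo scenario parameters
#'
#' The bundled scenario emulates the structure of an adaptive amplification in
#' a laboratory-evolved haploid yeast strain at toy scale: a 200 kb single
#' chromosome, four planted SNPs, and a five-copy tandem-inverted
#' amplification of an 11,038 bp segment whose junctions carry 7 nt and 13 nt
#' micro-homology overlaps, sequenced as 36-bp single-end reads at 35x
#' (evolved) and 28x (parent) with 0.5% base error.
#'
#' @return a list of scenario parameters.
#' @export
demo_scenario <- function() {
  list(genome_length = 200000L, gc = 0.38,
       amp_left = 120007L, amp_right = 131044L, copy_number = 5L,
       h_left = 7L, h_right = 13L, spacer_left = 10L, spacer_right = 12L,
       snp_pos = c(30000L, 60017L, 90234L, 170501L),
       depth_evolved = 35, depth_parent = 28,
       read_len = 36L, error_rate = 0.005)
}

# alt base: deterministic transversion of the reference base
# (A -> C, C -> A, G -> T, T -> G)
transversion <- function(b) chartr("ACGT", "CATG", b)

#' Build the demo scenario in memory
#'
#' Generates the reference (with junction arms planted), the evolved genome,
#' both read sets and the truth record.
#'
#' @param seed RNG seed; all randomness derives from it.
#' @param params scenario parameters (see [demo_scenario()]).
#' @return list with `reference`, `evolved`, `truth`, `reads_evolved`,
#'   `reads_parent`, `origins_evolved`, `origins_parent`, `spec`, `params`.
#' @export
build_demo <- function(seed = 1L, params = demo_scenario()) {
  p <- params
  ref <- generate_reference(1L, p$genome_length, gc = p$gc,
                            seed = derive_seed(seed, 1L))
  amp <- amplification_spec("chr1", p$amp_left, p$amp_right, p$copy_number,
                            microhomology_left = p$h_left,
                            microhomology_right = p$h_right,
                            spacer_left = p$spacer_left,
                            spacer_right = p$spacer_right)
  ref <- plant_junction_arms(ref, amp)
  snps <- NULL
  if (length(p$snp_pos) > 0) {
    snp_ref <- vapply(p$snp_pos, function(q)
      substr(ref$sequences[["chr1"]], q, q), character(1))
    snps <- data.frame(chrom = "chr1", pos = p$snp_pos,
                       alt = transversion(snp_ref))
  }
  spec <- evolution_spec(snps = snps, amplification = amp)
  evo <- apply_evolution(ref, spec)
  re <- simulate_reads(evo$genome, p$depth_evolved, p$read_len, p$error_rate,
                       seed = derive_seed(seed, 2L))
  rp <- simulate_reads(ref, p$depth_parent, p$read_len, p$error_rate,
                       seed = derive_seed(seed, 3L))
  list(reference = ref, evolved = evo$genome, truth = evo$truth,
       reads_evolved = re$reads, reads_parent = rp$reads,
       origins_evolved = re$origins, origins_parent = rp$origins,
       spec = spec, params = p)
}

#' Generate the demo fixture bundle on disk
#'
#' One-command generation of the demo scenario: genomes (FASTA), reads
#' (FASTQ) and truth files (TSV + BED), byte-stable for a fixed seed.
#'
#' @param out_dir output directory.
#' @param seed RNG seed.
#' @return list with `paths` (written files) and the in-memory `demo` bundle,
#'   invisibly.
#' @export
make_demo <- function(out_dir, seed = 1L) {
  demo <- build_demo(seed)
  paths <- write_fixtures(demo$reference, demo$evolved,
                          list(evolved = demo$reads_evolved,
                               parent = demo$reads_parent),
                          demo$truth, out_dir)
  invisible(list(paths = paths, demo = demo))
}

#' Plot binned log2 ratios with segment means
#'
#' @param bins a `bin_series`.
#' @param segments segment data frame from [cbs_segment()].
#' @param chrom chromosome to plot (default: first).
#' @return invisibly, `NULL`.
#' @export
plot_segments <- function(bins, segments, chrom = NULL) {
  chrom <- chrom %||% names(bins$bins)[1]
  b <- bins$bins[[chrom]]
  plot((b$start + b$end) / 2, b$log2_ratio, pch = ".", col = "grey40",
       xlab = paste0(chrom, " position (bp)"), ylab = "log2 depth ratio")
  seg <- segments[segments$chrom == chrom, , drop = FALSE]
  graphics::segments(seg$start, seg$mean_log2, seg$end, seg$mean_log2,
                     col = "red", lwd = 2)
  invisible(NULL)
}
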