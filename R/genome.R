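#' In-memory genome
#'
#' A minimal container for a haploid genome: a named set of uppercase
#' A/C/G/T chromosome sequences plus a per-chromosome nuclear flag.
#' Chromosomes whose name contains "chrM", "mito" or "MT" are treated as
#' non-nuclear by default; non-nuclear chromosomes are excluded from
#' depth-normalisation totals, segmentation and the breakpoint background
#' estimate.
#'
#' @param sequences named character vector of chromosome sequences.
#' @param nuclear optional named logical vector; defaults from chromosome names.
#' @return an object of class `genome`.
#' @export
genome <- function(sequences, nuclear = NULL) {
  if (is.null(names(sequences)) || anyDuplicated(names(sequences)))
    stop("chromosome names must be present and unique")
  nms <- names(sequences)
  sequences <- stats::setNames(toupper(as.character(sequences)), nms)
  if (any(nchar(sequences) == 0L)) stop("chromosome sequences must be non-empty")
  if (any(grepl("[^ACGT]", sequences)))
    stop("genome alphabet is restricted to A/C/G/T")
  if (is.null(nuclear)) {
    nuclear <- !grepl("chrM|mito|^MT$", names(sequences), ignore.case = TRUE)
    names(nuclear) <- names(sequences)
  }
  stopifnot(identical(sort(names(nuclear)), sort(names(sequences))))
  structure(list(sequences = sequences, nuclear = nuclear[names(sequences)]),
            class = "genome")
}

#' @export
print.genome <- function(x, ...) {
  cat("genome with", length(x$sequences), "chromosome(s):\n")
  for (nm in names(x$sequences))
    cat(sprintf("  %s  %s bp%s\n", nm, format(nchar(x$sequences[[nm]]), big.mark = ","),
                if (x$nuclear[[nm]]) "" else "  [non-nuclear]"))
  invisible(x)
}

chrom_lengths <- function(genome) nchar(genome$sequences)

get_chrom <- function(genome, chrom) {
  seq <- genome$sequences[[chrom]]
  if (is.null(seq)) stop("unknown chromosome: ", chrom)
  seq
}

#' Read a genome from a FASTA file
#'
#' @param path FASTA file path.
#' @param nuclear optional named logical vector (see [genome()]).
#' @return a `genome` object.
#' @export
read_genome_fasta <- function(path, nuclear = NULL) {
  ss <- Biostrings::readDNAStringSet(path)
  genome(stats::setNames(as.character(ss), names(ss)), nuclear = nuclear)
}

#' Write a genome to FASTA
#'
#' @param genome a `genome` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_genome_fasta <- function(genome, path) {
  ss <- Biostrings::DNAStringSet(genome$sequences)
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}
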