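## Copy-number detection: 25-bp binning of mappable per-base depth,
## cross-strain normalisation by total nuclear bases, log2 ratios, circular
## binary segmentation with a permutation test, and segment smoothing.

#' Circular-binary-segmentation parameters
#'
#' @param alpha change-point significance level (default 0.01).
#' @param n_permutations permutations per significance test (>= 100,
#'   default 1000).
#' @param sd_multiplier smoothing threshold: adjacent segments whose means
#'   differ by less than `sd_multiplier` residual standard deviations are
#'   merged (default 3).
#' @param min_span minimum segment span in bp (default 1000).
#' @param seed seed for the deterministic permutation RNG.
#' @return a `cbs_params` list.
#' @export
cbs_params <- function(alpha = 0.01, n_permutations = 1000L, sd_multiplier = 3,
                       min_span = 1000L, seed = 1L) {
  stopifnot(alpha > 0, alpha < 1, n_permutations >= 100)
  structure(list(alpha = alpha, n_permutations = as.integer(n_permutations),
                 sd_multiplier = sd_multiplier, min_span = as.integer(min_span),
                 seed = as.integer(seed)),
            class = "cbs_params")
}

extract_depth <- function(x) {
  if (inherits(x, "pileup")) depth_track(x) else x
}

#' Bin and normalise depth ratios
#'
#' Averages per-base depth over the mappable positions of fixed-width bins
#' (anchored at position 1 of each nuclear chromosome; a final partial bin is
#' kept if at least half its width is mappable), normalises each strain by its
#' total nuclear bases, and takes the log2 ratio evolved/parent per bin.
#' Bins with no mappable position or zero parental coverage are flagged
#' unusable and excluded from segmentation. By default the usable-bin log2
#' ratios are recentred on their genome-wide median so the neutral copy state
#' sits at 0; at whole-genome scale this correction is negligible, but it
#' keeps copy-ratio estimates calibrated when an amplification occupies a
#' non-trivial fraction of a small genome.
#'
#' @param depth_evolved,depth_parent `depth_track` (or `pileup`) objects over
#'   the same reference.
#' @param mask a `mappability_mask`.
#' @param width bin width in bp (default 25).
#' @param center median-centre the usable log2 ratios (default `TRUE`).
#' @return a `bin_series`: per-chromosome data frames with columns `bin`,
#'   `start`, `end`, `mean_evolved`, `mean_parent`, `log2_ratio`, `usable`.
#' @export
bin_depth <- function(depth_evolved, depth_parent, mask, width = 25L,
                      center = TRUE) {
  if (width < 1) stop("width must be >= 1")
  de <- extract_depth(depth_evolved); dp <- extract_depth(depth_parent)
  if (!identical(lengths(de$depth), lengths(dp$depth)))
    stop("depth tracks were not computed over the same reference")
  width <- as.integer(width)
  chroms <- names(de$depth)[de$nuclear[names(de$depth)]]
  out <- list()
  for (ch in chroms) {
    n <- length(de$depth[[ch]])
    nbins <- ceiling(n / width)
    b <- ((seq_len(n) - 1L) %/% width) + 1L
    m <- mask$mask[[ch]]
    mappable_n <- as.vector(rowsum(as.integer(m), b))
    sum_e <- as.vector(rowsum(de$depth[[ch]] * as.integer(m), b))
    sum_p <- as.vector(rowsum(dp$depth[[ch]] * as.integer(m), b))
    mean_e <- ifelse(mappable_n > 0, sum_e / mappable_n, NA_real_)
    mean_p <- ifelse(mappable_n > 0, sum_p / mappable_n, NA_real_)
    usable <- mappable_n > 0 & !is.na(mean_p) & mean_p > 0
    # final partial bin: keep only if at least half-width mappable
    last_width <- n - (nbins - 1L) * width
    if (last_width < width && mappable_n[nbins] < width / 2)
      usable[nbins] <- FALSE
    lr <- rep(NA_real_, nbins)
    lr[usable] <- log2((mean_e[usable] / de$total_nuclear_bases) /
                         (mean_p[usable] / dp$total_nuclear_bases))
    out[[ch]] <- data.frame(
      bin = seq_len(nbins),
      start = (seq_len(nbins) - 1L) * width + 1L,
      end = pmin(seq_len(nbins) * width, n),
      mean_evolved = mean_e, mean_parent = mean_p,
      log2_ratio = lr, usable = usable)
  }
  offset <- 0
  if (center) {
    all_lr <- unlist(lapply(out, function(d) d$log2_ratio[d$usable]),
                     use.names = FALSE)
    if (length(all_lr) > 0) {
      offset <- stats::median(all_lr)
      for (ch in names(out))
        out[[ch]]$log2_ratio <- out[[ch]]$log2_ratio - offset
    }
  }
  structure(list(bins = out, width = width, center_offset = offset),
            class = "bin_series")
}

#' Maximal-t arc split of a ratio series
#'
#' Scans all circular arcs of the series and returns the arc maximising the
#' absolute two-sample t-statistic (pooled variance) between the arc and its
#' complement. Ties are broken towards the lexicographically smallest
#' (start, end); a zero-variance series returns `t = 0` with
#' `flag_zero_variance = TRUE`.
#'
#' @param series numeric vector of log2 ratios (length >= 4).
#' @return `list(start, end, t, flag_zero_variance)`; the arc spans positions
#'   `start..end` inclusive.
#' @export
max_t_split <- function(series) {
  .arc_max_t_cpp(as.numeric(series))
}

# recursive CBS over one usable-ratio vector; returns sorted split boundaries
# (last index of each segment)
cbs_recurse <- function(x, lo, hi, params, counter) {
  len <- hi - lo + 1L
  if (len < 4L) return(integer(0))
  sp <- .arc_max_t_cpp(x[lo:hi])
  if (sp$flag_zero_variance) return(integer(0))
  if (sp$start == 1L && sp$end == len) return(integer(0))
  counter$n <- counter$n + 1L
  pt <- .arc_perm_test_cpp(x[lo:hi], abs(sp$t), params$n_permutations,
                           params$alpha, derive_seed(params$seed, counter$n))
  if (!pt$significant) return(integer(0))
  cuts <- integer(0)
  if (sp$start > 1L) cuts <- c(cuts, lo + sp$start - 2L)   # end of left part
  if (sp$end < len) cuts <- c(cuts, lo + sp$end - 1L)      # end of arc
  bounds <- c(lo - 1L, sort(unique(cuts)), hi)
  out <- cuts
  for (k in seq_len(length(bounds) - 1L)) {
    out <- c(out, cbs_recurse(x, bounds[k] + 1L, bounds[k + 1L], params, counter))
  }
  sort(unique(out))
}

segments_from_cuts <- function(chrom, bdf, uidx, x, cuts, width) {
  ends <- c(cuts, length(x))
  starts <- c(1L, utils::head(ends, -1L) + 1L)
  data.frame(
    chrom = chrom,
    start = bdf$start[uidx[starts]],
    end = bdf$end[uidx[ends]],
    n_bins = ends - starts + 1L,
    mean_log2 = vapply(seq_along(starts), function(k)
      mean(x[starts[k]:ends[k]]), numeric(1)),
    first_u = starts, last_u = ends)
}

finalize_segments <- function(seg, width) {
  seg$copy_ratio <- 2^seg$mean_log2
  seg$uncertainty <- as.integer(width)
  seg[, c("chrom", "start", "end", "n_bins", "mean_log2", "copy_ratio",
          "uncertainty")]
}

#' Segment binned log2 ratios by circular binary segmentation
#'
#' Recursively splits each chromosome at the maximal-t arc while the split is
#' significant at `alpha` under a seeded permutation null; the returned
#' segments tile the usable bins. Smoothing (see [smooth_segments()]) is
#' applied afterwards unless `smooth = FALSE`.
#'
#' @param bins a `bin_series` from [bin_depth()].
#' @param params a [cbs_params()].
#' @param smooth apply [smooth_segments()] to the raw segmentation
#'   (default `TRUE`).
#' @return data frame of segments: `chrom`, `start`, `end` (1-based inclusive,
#'   bin-aligned), `n_bins`, `mean_log2`, `copy_ratio` (`2^mean_log2`) and
#'   `uncertainty` (+/- one bin width, in bp).
#' @export
cbs_segment <- function(bins, params = cbs_params(), smooth = TRUE) {
  all_segs <- list()
  for (ch in names(bins$bins)) {
    bdf <- bins$bins[[ch]]
    uidx <- which(bdf$usable)
    if (length(uidx) == 0) next
    x <- bdf$log2_ratio[uidx]
    cuts <- if (length(uidx) >= 4L) {
      counter <- new.env(); counter$n <- 0L
      cbs_recurse(x, 1L, length(x), params, counter)
    } else integer(0)
    seg <- segments_from_cuts(ch, bdf, uidx, x, cuts, bins$width)
    if (smooth) seg <- smooth_one_chrom(seg, x, params)
    all_segs[[ch]] <- finalize_segments(seg, bins$width)
  }
  if (length(all_segs) == 0)
    return(data.frame(chrom = character(), start = integer(), end = integer(),
                      n_bins = integer(), mean_log2 = numeric(),
                      copy_ratio = numeric(), uncertainty = integer()))
  res <- do.call(rbind, all_segs)
  rownames(res) <- NULL
  res
}

# merge segment k into k+1 (or k-1) keeping tiling; seg carries first_u/last_u
merge_rows <- function(seg, k, x) {
  seg$end[k] <- seg$end[k + 1L]
  seg$last_u[k] <- seg$last_u[k + 1L]
  seg$n_bins[k] <- seg$n_bins[k] + seg$n_bins[k + 1L]
  seg$mean_log2[k] <- mean(x[seg$first_u[k]:seg$last_u[k]])
  seg[-(k + 1L), , drop = FALSE]
}

smooth_one_chrom <- function(seg, x, params) {
  repeat {
    merged <- FALSE
    # rule 1: adjacent means closer than sd_multiplier x residual SD
    if (nrow(seg) > 1L) {
      resid <- x - rep(seg$mean_log2, seg$n_bins)
      sd_r <- stats::sd(resid)
      if (is.na(sd_r)) sd_r <- 0
      diffs <- abs(diff(seg$mean_log2))
      k <- which(diffs < params$sd_multiplier * sd_r)
      if (length(k) > 0) {
        seg <- merge_rows(seg, k[which.min(diffs[k])], x)
        merged <- TRUE
      }
    }
    # rule 2: short segments absorbed into the more similar neighbour
    if (!merged && nrow(seg) > 1L) {
      span <- seg$end - seg$start + 1L
      k <- which(span < params$min_span)
      if (length(k) > 0) {
        k <- k[which.min(span[k])]
        if (k == 1L) into <- 1L
        else if (k == nrow(seg)) into <- k - 1L
        else into <- if (abs(seg$mean_log2[k] - seg$mean_log2[k - 1L]) <=
                         abs(seg$mean_log2[k] - seg$mean_log2[k + 1L]))
          k - 1L else k
        seg <- merge_rows(seg, into, x)
        merged <- TRUE
      }
    }
    if (!merged) break
  }
  seg
}

#' Smooth a raw segmentation
#'
#' Adjacent segments whose mean log2 ratios differ by less than
#' `sd_multiplier` times the chromosome-wide residual standard deviation (the
#' SD of bin ratios about their segment means) are merged, repeatedly until
#' stable; segments spanning less than `min_span` bp are then absorbed into
#' the more similar neighbour. The output still tiles the usable bins.
#'
#' @param segments raw segment data frame from `cbs_segment(..., smooth =
#'   FALSE)`.
#' @param bins the `bin_series` the segments came from.
#' @param params a [cbs_params()].
#' @return smoothed segment data frame (same columns as [cbs_segment()]).
#' @export
smooth_segments <- function(segments, bins, params = cbs_params()) {
  out <- list()
  for (ch in unique(segments$chrom)) {
    bdf <- bins$bins[[ch]]
    uidx <- which(bdf$usable)
    x <- bdf$log2_ratio[uidx]
    seg <- segments[segments$chrom == ch, , drop = FALSE]
    # recover usable-index bounds from genomic coordinates
    seg$first_u <- match(seg$start, bdf$start[uidx])
    seg$last_u <- match(seg$end, bdf$end[uidx])
    if (anyNA(seg$first_u) || anyNA(seg$last_u))
      stop("segments do not align with the usable bins of this series")
    seg <- smooth_one_chrom(seg, x, params)
    out[[ch]] <- finalize_segments(seg, bins$width)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Copy-ratio estimate of a segment
#'
#' @param segment one segment row (or any object with a `mean_log2` field),
#'   or a bare numeric mean log2 ratio.
#' @return `list(copy_ratio = 2^mean, nearest_integer, distance)`.
#' @export
copy_ratio <- function(segment) {
  mean_log2 <- if (is.numeric(segment)) segment else segment$mean_log2
  cr <- 2^mean_log2
  list(copy_ratio = cr, nearest_integer = round(cr), distance = abs(cr - round(cr)))
}
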