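#' Assign peaks to genomic features by anchor point
#'
#' Each peak gets the single feature label found at its anchor: the recorded
#' summit when present, otherwise the midpoint `floor((start + end) / 2)`.
#' An alternative `"max_overlap"` rule labels each peak by the feature with
#' the largest bp share of the peak (ties broken by feature priority).
#'
#' @param peaks Peak tibble ([read_bed()]).
#' @param index A [build_feature_index()].
#' @param rule `"anchor"` (default) or `"max_overlap"`.
#' @return `peaks` with a `feature` column added.
#' @export
assign_peaks <- function(peaks, index, rule = c("anchor", "max_overlap")) {
  rule <- match.arg(rule)
  if (nrow(peaks) == 0) {
    peaks$feature <- factor(character(), levels = FEATURE_LEVELS)
    return(peaks)
  }
  if (rule == "anchor") {
    anchor <- ifelse(!is.na(peaks$summit), peaks$summit, floor((peaks$start + peaks$end) / 2))
    peaks$feature <- classify_position(index, peaks$chrom, anchor)
  } else {
    peaks$feature <- factor(purrr::map_chr(seq_len(nrow(peaks)), function(i) {
      seg <- index[index$chrom == peaks$chrom[i] &
                     index$end > peaks$start[i] & index$start < peaks$end[i], , drop = FALSE]
      bp <- pmin(seg$end, peaks$end[i]) - pmax(seg$start, peaks$start[i])
      share <- tapply(bp, seg$feature, sum)
      share[is.na(share)] <- 0
      names(share)[order(-share, match(names(share), FEATURE_LEVELS))][1]
    }), levels = FEATURE_LEVELS)
  }
  peaks
}

#' Feature distribution of an assigned peak set
#'
#' @param assigned Output of [assign_peaks()].
#' @return Tibble `feature`, `n`, `fraction` over all six labels; fractions
#'   sum to 1. Errors on an empty peak set rather than returning silent zeros.
#' @export
feature_distribution <- function(assigned) {
  if (nrow(assigned) == 0) stop("feature distribution is undefined for an empty peak set")
  n <- table(assigned$feature)
  tibble::tibble(feature = factor(names(n), levels = FEATURE_LEVELS),
                 n = as.numeric(n), fraction = as.numeric(n) / nrow(assigned))
}

#' Genes marked by a peak set
#'
#' A gene is marked iff at least one bp of any peak overlaps its promoter
#' joined with its gene body (see [gene_regions()]); the half-open convention
#' means a peak ending exactly at the region start shares zero bases and does
#' not mark the gene.
#'
#' @param peaks Peak tibble.
#' @param genes Gene models.
#' @param layout A [genome_layout()].
#' @param promoter_window Promoter size in bp (default 2000).
#' @return Character vector of marked gene ids (each gene at most once).
#' @export
marked_genes <- function(peaks, genes, layout, promoter_window = 2000) {
  regions <- gene_regions(genes, layout, promoter_window)
  hit <- overlaps_any(regions, peaks)
  regions$gene_id[hit]
}

#' Region counts of a multi-set Venn diagram
#'
#' @param sets Named list of 2 to 4 character vectors (e.g. gene ids marked
#'   by each histone modification). Names must be unique.
#' @return Tibble with one row per non-empty combination pattern: logical
#'   membership columns (one per set), a `region` label like `"A&B"`, and the
#'   exclusive count `n`. Region counts partition the union.
#' @export
multiway_venn <- function(sets) {
  k <- length(sets)
  if (k < 2 || k > 4) stop("multiway_venn takes between 2 and 4 sets")
  if (is.null(names(sets)) || anyDuplicated(names(sets)) || any(!nzchar(names(sets)))) {
    stop("sets must have unique non-empty names")
  }
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1, dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), k))
  names(combos) <- names(sets)
  combos <- combos[rowSums(combos) > 0, , drop = FALSE]
  n <- apply(combos, 1, function(pattern) {
    sum(apply(member, 1, function(m) all(m == pattern)))
  })
  out <- tibble::as_tibble(combos)
  out$region <- apply(combos, 1, function(pattern) paste(names(sets)[as.logical(pattern)], collapse = "&"))
  out$n <- as.numeric(n)
  out
}

#' Fraction of the genome covered by a peak set
#'
#' Overlapping peaks are merged first, so duplicates are never double-counted.
#'
#' @inheritParams marked_genes
#' @return A single number in `[0, 1]`.
#' @export
genome_coverage <- function(peaks, layout) {
  covered_bp(peaks) / sum(layout$length)
}

#' Histogram of peak lengths
#'
#' @param peaks Peak tibble.
#' @param bin_edges Increasing numeric vector of edges; each peak falls in the
#'   right-open bin `[edge_i, edge_{i+1})` containing its length.
#' @return Tibble `bin_lo`, `bin_hi`, `n`; counts total to the peak count for
#'   lengths inside the covered range.
#' @export
peak_length_histogram <- function(peaks, bin_edges) {
  if (is.unsorted(bin_edges, strictly = TRUE)) stop("bin edges must be strictly increasing")
  len <- peaks$end - peaks$start
  idx <- findInterval(len, bin_edges)
  nb <- length(bin_edges) - 1
  counts <- tabulate(idx[idx >= 1 & idx <= nb], nbins = nb)
  tibble::tibble(bin_lo = bin_edges[-length(bin_edges)],
                 bin_hi = bin_edges[-1], n = as.numeric(counts))
}

#' TSS-TTS metagene profile
#'
#' Averages signal over genes on a common axis: a fixed-width upstream flank
#' before the TSS, the gene body rescaled to `body_bins` bins, and a
#' fixed-width downstream flank after the TTS. Minus-strand genes are
#' reversed so the axis always runs TSS to TTS. Flank bins running off the
#' chromosome are treated as missing and excluded from the mean. When `signal`
#' is a peak set the per-base signal is merged peak occupancy (0/1);
#' a bedGraph tibble (with a `value` column) is used as a weighted track.
#'
#' @param signal Peak tibble or bedGraph tibble (`value` column).
#' @param genes Gene models.
#' @param layout A [genome_layout()].
#' @param flank_up,flank_down Flank widths in bp (defaults 1000 and 2000,
#'   i.e. -1 kb of the TSS to +2 kb of the TTS).
#' @param body_bins Number of scaled gene-body bins (default 100).
#' @param flank_bin Width of fixed flank bins in bp (default 50).
#' @return A `metagene_profile` tibble: `bin`, `zone` (upstream/body/
#'   downstream), `position` (bp for flanks, percent for body), `mean_signal`;
#'   attribute `n_genes`.
#' @export
metagene_profile <- function(signal, genes, layout, flank_up = 1000,
                             flank_down = 2000, body_bins = 100, flank_bin = 50) {
  if (nrow(genes) == 0) stop("metagene profile needs at least one gene")
  n_up <- as.integer(flank_up / flank_bin)
  n_down <- as.integer(flank_down / flank_bin)
  n_bins <- n_up + body_bins + n_down

  weighted <- "value" %in% names(signal)
  covs <- lapply(seq_len(nrow(layout)), function(i) {
    ch <- layout$chrom[i]; len <- as.integer(layout$length[i])
    s <- signal[signal$chrom == ch, , drop = FALSE]
    if (nrow(s) == 0) return(S4Vectors::Rle(0, len))
    if (weighted) {
      IRanges::coverage(.to_ir(s), weight = s$value, width = len)
    } else {
      m <- merge_intervals(s)
      IRanges::coverage(.to_ir(m), width = len)
    }
  })
  names(covs) <- layout$chrom

  # per-gene bin boundaries on genomic coordinates (0-based half-open)
  mat <- matrix(NA_real_, nrow = nrow(genes), ncol = n_bins)
  for (ch in unique(genes$chrom)) {
    rows <- which(genes$chrom == ch)
    len <- .layout_len(layout, ch)
    starts <- ends <- matrix(NA_real_, nrow = length(rows), ncol = n_bins)
    for (j in seq_along(rows)) {
      g <- genes[rows[j], ]
      lo <- min(g$tss, g$tts); hi <- max(g$tss, g$tts)
      # offsets from the TSS along transcription, shared by both strands so a
      # minus-strand gene is the exact mirror of its reflected plus twin
      body_off <- floor(seq(0, hi - lo, length.out = body_bins + 1))
      up_off <- seq(flank_up, 0, by = -flank_bin)
      down_off <- seq(0, flank_down, by = flank_bin)
      if (g$strand == "+") {
        b_start <- c(lo - up_off[-length(up_off)],
                     lo + body_off[-length(body_off)],
                     hi + down_off[-length(down_off)])
        b_end <- c(lo - up_off[-1], lo + body_off[-1], hi + down_off[-1])
      } else {
        b_end <- c(hi + up_off[-length(up_off)],
                   hi - body_off[-length(body_off)],
                   lo - down_off[-length(down_off)])
        b_start <- c(hi + up_off[-1], hi - body_off[-1], lo - down_off[-1])
      }
      b_end <- pmax(b_end, b_start + 1)  # zero-width body bins of tiny genes
      starts[j, ] <- b_start; ends[j, ] <- b_end
    }
    ok <- starts >= 0 & ends <= len
    vs <- as.integer(starts[ok]) + 1L
    ve <- as.integer(ends[ok])
    if (length(vs)) {
      v <- IRanges::Views(covs[[ch]], start = vs, end = ve)
      vals <- IRanges::viewMeans(v)
      tmp <- matrix(NA_real_, nrow = length(rows), ncol = n_bins)
      tmp[ok] <- vals
      mat[rows, ] <- tmp
    }
  }
  prof <- colMeans(mat, na.rm = TRUE)
  zone <- rep(c("upstream", "body", "downstream"), c(n_up, body_bins, n_down))
  position <- c(seq(-flank_up, -flank_bin, by = flank_bin),
                seq_len(body_bins) * (100 / body_bins),
                seq(flank_bin, flank_down, by = flank_bin))
  out <- tibble::tibble(bin = seq_len(n_bins), zone = zone,
                        position = position, mean_signal = prof)
  structure(out, n_genes = nrow(genes),
            class = c("metagene_profile", class(out)))
}
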