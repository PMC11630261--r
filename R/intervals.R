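# Internal bridge between tibble intervals (0-based half-open) and IRanges
# (1-based closed). All interval arithmetic in the package funnels through
# these helpers so the coordinate convention is converted in exactly one place.

.to_ir <- function(x) {
  IRanges::IRanges(start = as.integer(x$start) + 1L, end = as.integer(x$end))
}

.from_ir <- function(ir, chrom) {
  tibble::tibble(chrom = chrom,
                 start = as.numeric(IRanges::start(ir)) - 1,
                 end = as.numeric(IRanges::end(ir)))
}

# Split an interval tibble into a named list of IRanges, one per chromosome
# present in `chroms` (defaults to chromosomes observed in x).
.ir_by_chrom <- function(x, chroms = NULL) {
  if (is.null(chroms)) chroms <- unique(x$chrom)
  sp <- split(x[c("start", "end")], factor(x$chrom, levels = chroms))
  lapply(sp, .to_ir)
}

# Merge (reduce) intervals; returns a sorted tibble.
merge_intervals <- function(x, layout = NULL) {
  chroms <- if (is.null(layout)) sort(unique(x$chrom)) else layout$chrom
  irl <- .ir_by_chrom(x, chroms)
  out <- purrr::imap_dfr(irl, function(ir, ch) .from_ir(IRanges::reduce(ir), ch))
  out[out$end > out$start, , drop = FALSE]
}

# Total bp covered by the merged intervals.
covered_bp <- function(x) {
  if (nrow(x) == 0) return(0)
  m <- merge_intervals(x)
  sum(m$end - m$start)
}

# bp in the intersection of two interval sets (after merging each).
intersect_bp <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(chroms) == 0 || nrow(a) == 0 || nrow(b) == 0) return(0)
  ira <- .ir_by_chrom(a, chroms)
  irb <- .ir_by_chrom(b, chroms)
  sum(purrr::map_dbl(chroms, function(ch) {
    sum(IRanges::width(IRanges::intersect(IRanges::reduce(ira[[ch]]),
                                          IRanges::reduce(irb[[ch]]))))
  }))
}

# Interval-set intersection as a tibble of intervals.
intersect_intervals <- function(a, b) {
  chroms <- intersect(unique(a$chrom), unique(b$chrom))
  if (length(chroms) == 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric()))
  }
  ira <- .ir_by_chrom(a, chroms)
  irb <- .ir_by_chrom(b, chroms)
  purrr::map_dfr(chroms, function(ch) {
    .from_ir(IRanges::intersect(IRanges::reduce(ira[[ch]]), IRanges::reduce(irb[[ch]])), ch)
  })
}

# Does each interval in `a` overlap (>= min_bp shared bases) anything in `b`?
overlaps_any <- function(a, b, min_bp = 1) {
  if (nrow(a) == 0) return(logical(0))
  if (nrow(b) == 0) return(rep(FALSE, nrow(a)))
  out <- rep(FALSE, nrow(a))
  idx <- split(seq_len(nrow(a)), a$chrom)
  irb <- .ir_by_chrom(b)
  for (ch in names(idx)) {
    if (!ch %in% names(irb)) next
    ira <- .to_ir(a[idx[[ch]], ])
    out[idx[[ch]]] <- IRanges::overlapsAny(ira, irb[[ch]], minoverlap = min_bp)
  }
  out
}

# bp-level Jaccard of two interval sets. Both-empty is 0 by convention.
jaccard_bp <- function(a, b) {
  bp_a <- covered_bp(a)
  bp_b <- covered_bp(b)
  if (bp_a == 0 && bp_b == 0) return(0)
  inter <- intersect_bp(a, b)
  inter / (bp_a + bp_b - inter)
}

# Shared bp between an interval set and each of a set of regions (vectorised
# over regions; the interval set is merged first).
region_overlap_bp <- function(iv, regions) {
  out <- numeric(nrow(regions))
  if (nrow(iv) == 0 || nrow(regions) == 0) return(out)
  idx <- split(seq_len(nrow(regions)), regions$chrom)
  ivl <- .ir_by_chrom(iv)
  for (ch in names(idx)) {
    if (!ch %in% names(ivl) || length(ivl[[ch]]) == 0) next
    irr <- .to_ir(regions[idx[[ch]], ])
    irv <- IRanges::reduce(ivl[[ch]])
    h <- IRanges::findOverlaps(irr, irv)
    if (length(h) == 0) next
    w <- IRanges::width(IRanges::pintersect(irr[S4Vectors::queryHits(h)],
                                            irv[S4Vectors::subjectHits(h)]))
    agg <- tapply(w, S4Vectors::queryHits(h), sum)
    out[idx[[ch]][as.integer(names(agg))]] <- as.numeric(agg)
  }
  out
}

# Clip intervals to chromosome bounds, dropping empties.
clip_intervals <- function(x, layout) {
  if (nrow(x) == 0) return(x)
  len <- .layout_len(layout, x$chrom)
  x$start <- pmax(x$start, 0)
  x$end <- pmin(x$end, len)
  x[x$end > x$start, , drop = FALSE]
}
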