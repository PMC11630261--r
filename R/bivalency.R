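#' Call bivalent domains from two antagonistic mark peak sets
#'
#' A bivalent domain is a merged connected component of pairwise
#' intersections between peaks of the two marks, keeping intersections of at
#' least `min_overlap_bp` shared bases. In the default `"intersection"` mode
#' the domain extent is the co-marked bases only; `"union"` mode extends each
#' component to the union of the contributing peaks. A peak is *involved* iff
#' it contributes to at least one domain; per-mark involved fractions are the
#' analogue of the reported shares of H3K27me3 and H3K9ac peaks falling in
#' the bivalent state. The call is symmetric in its two arguments.
#'
#' @param peaks_a,peaks_b Peak tibbles of two distinct marks (a `mark` column,
#'   when present, must differ between the two).
#' @param layout A [genome_layout()].
#' @param min_overlap_bp Minimum shared bp for a pairwise intersection
#'   (default 1, the most permissive, matching plain bedtools-intersect use).
#' @param mode `"intersection"` (default) or `"union"` domain extent.
#' @param genes Optional gene models; when given, genes covered by domains
#'   (promoter-plus-body rule) are reported.
#' @param promoter_window Promoter size in bp.
#' @return A `bivalent_domains` list: `domains` (sorted non-overlapping
#'   tibble), `n_peaks_a/b`, `involved_a/b`, `frac_a/b`, `marks`, `genes`.
#' @export
call_bivalent <- function(peaks_a, peaks_b, layout, min_overlap_bp = 1,
                          mode = c("intersection", "union"),
                          genes = NULL, promoter_window = 2000) {
  mode <- match.arg(mode)
  mark_a <- if ("mark" %in% names(peaks_a)) unique(peaks_a$mark) else "A"
  mark_b <- if ("mark" %in% names(peaks_b)) unique(peaks_b$mark) else "B"
  if (length(mark_a) == 1 && length(mark_b) == 1 && identical(mark_a, mark_b)) {
    stop("bivalency needs two distinct marks, got '", mark_a, "' twice")
  }
  involved_a <- logical(nrow(peaks_a))
  involved_b <- logical(nrow(peaks_b))
  domains <- tibble::tibble(chrom = character(), start = numeric(), end = numeric())
  idx_a <- split(seq_len(nrow(peaks_a)), peaks_a$chrom)
  idx_b <- split(seq_len(nrow(peaks_b)), peaks_b$chrom)
  for (ch in intersect(names(idx_a), names(idx_b))) {
    ia <- idx_a[[ch]]; ib <- idx_b[[ch]]
    ira <- .to_ir(peaks_a[ia, ]); irb <- .to_ir(peaks_b[ib, ])
    h <- IRanges::findOverlaps(ira, irb, minoverlap = min_overlap_bp)
    if (length(h) == 0) next
    qa <- S4Vectors::queryHits(h); qb <- S4Vectors::subjectHits(h)
    involved_a[ia[qa]] <- TRUE
    involved_b[ib[qb]] <- TRUE
    pieces <- if (mode == "intersection") {
      IRanges::pintersect(ira[qa], irb[qb])
    } else {
      IRanges::punion(ira[qa], irb[qb], fill.gap = TRUE)
    }
    domains <- dplyr::bind_rows(domains, .from_ir(IRanges::reduce(pieces), ch))
  }
  domains <- .sort_intervals(domains, layout)
  out <- list(domains = domains,
              marks = c(mark_a[1], mark_b[1]),
              n_peaks_a = nrow(peaks_a), n_peaks_b = nrow(peaks_b),
              involved_a = sum(involved_a), involved_b = sum(involved_b),
              frac_a = if (nrow(peaks_a)) mean(involved_a) else 0,
              frac_b = if (nrow(peaks_b)) mean(involved_b) else 0,
              genes = if (!is.null(genes)) {
                marked_genes(domains, genes, layout, promoter_window)
              })
  structure(out, class = "bivalent_domains")
}

#' @export
print.bivalent_domains <- function(x, ...) {
  cat(sprintf("Bivalent domains (%s + %s): %d domains, %d bp\n",
              x$marks[1], x$marks[2], nrow(x$domains),
              sum(x$domains$end - x$domains$start)))
  cat(sprintf("involved peaks: %d/%d (%.1f%%) %s, %d/%d (%.1f%%) %s\n",
              x$involved_a, x$n_peaks_a, 100 * x$frac_a, x$marks[1],
              x$involved_b, x$n_peaks_b, 100 * x$frac_b, x$marks[2]))
  if (!is.null(x$genes)) cat(sprintf("genes covered: %d\n", length(x$genes)))
  invisible(x)
}

#' Validate bivalent domains against reciprocal reChIP peak sets
#'
#' A domain is supported iff it overlaps (>= `min_overlap_bp` shared bases)
#' peaks from *both* sequential-ChIP directions. The both-direction fraction
#' is by construction no larger than either single-direction fraction.
#' Support is reported at the domain level, and also as bp and gene-count
#' fractions, since the overlap unit of the published validation rate is
#' ambiguous.
#'
#' @param domains A [call_bivalent()] result (or a domain tibble).
#' @param rechip_ab,rechip_ba Peak tibbles of the two reChIP directions
#'   (e.g. H3K27me3 then H3K9ac, and the reverse).
#' @param layout A [genome_layout()].
#' @param min_overlap_bp Minimum shared bp (default 1).
#' @param genes Optional gene models for the gene-level fraction.
#' @param promoter_window Promoter size in bp.
#' @return Tibble with `n_domains`, `frac_both`, `frac_ab`, `frac_ba`,
#'   `frac_bp_both`, and `frac_genes_both` when genes are supplied.
#' @export
validate_rechip <- function(domains, rechip_ab, rechip_ba, layout,
                            min_overlap_bp = 1, genes = NULL,
                            promoter_window = 2000) {
  dom <- if (inherits(domains, "bivalent_domains")) domains$domains else domains
  if (nrow(dom) == 0) {
    warning("no bivalent domains to validate")
    return(tibble::tibble(n_domains = 0, frac_both = NA_real_,
                          frac_ab = NA_real_, frac_ba = NA_real_,
                          frac_bp_both = NA_real_))
  }
  in_ab <- overlaps_any(dom, rechip_ab, min_bp = min_overlap_bp)
  in_ba <- overlaps_any(dom, rechip_ba, min_bp = min_overlap_bp)
  both <- in_ab & in_ba
  bp <- dom$end - dom$start
  out <- tibble::tibble(
    n_domains = nrow(dom),
    frac_both = mean(both), frac_ab = mean(in_ab), frac_ba = mean(in_ba),
    frac_bp_both = sum(bp[both]) / sum(bp)
  )
  if (!is.null(genes)) {
    g_all <- marked_genes(dom, genes, layout, promoter_window)
    g_sup <- marked_genes(dom[both, , drop = FALSE], genes, layout, promoter_window)
    out$frac_genes_both <- if (length(g_all)) length(g_sup) / length(g_all) else NA_real_
  }
  stopifnot(out$frac_both <= min(out$frac_ab, out$frac_ba) + 1e-12)
  out
}

#' Permutation null for the bivalent domain count
#'
#' Shuffles the second mark's peaks uniformly within their chromosomes
#' (lengths preserved) and recomputes the domain count, giving an empirical
#' p-value `(1 + #{permuted count >= observed}) / (n_perm + 1)` for the
#' observed co-occurrence.
#'
#' @inheritParams call_bivalent
#' @param n_perm Number of permutations (>= 100 recommended).
#' @param seed Integer seed.
#' @return Tibble `observed`, `n_perm`, `p_value`, `mean_null`.
#' @export
permutation_null <- function(peaks_a, peaks_b, layout, n_perm = 200, seed = 1,
                             min_overlap_bp = 1) {
  if (n_perm < 100) warning("n_perm < 100 gives a coarse p-value resolution")
  len <- .layout_len(layout, peaks_b$chrom)
  w <- peaks_b$end - peaks_b$start
  if (any(w > len)) stop("peak longer than its chromosome cannot be shuffled")
  observed <- nrow(call_bivalent(peaks_a, peaks_b, layout,
                                 min_overlap_bp = min_overlap_bp)$domains)
  counts <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      new_start <- floor(stats::runif(nrow(peaks_b)) * (len - w + 1))
      shuf <- tibble::tibble(chrom = peaks_b$chrom, start = new_start,
                             end = new_start + w,
                             summit = NA_real_, mark = "shuffled")
      nrow(call_bivalent(peaks_a, shuf, layout,
                         min_overlap_bp = min_overlap_bp)$domains)
    }, numeric(1))
  })
  tibble::tibble(observed = observed, n_perm = n_perm,
                 p_value = (1 + sum(counts >= observed)) / (n_perm + 1),
                 mean_null = mean(counts))
}
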