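FEATURE_LEVELS <- c("promoter", "utr5", "coding_exon", "utr3", "intron", "intergenic")

#' Build the six-way genomic feature partition
#'
#' Every base of the genome is assigned exactly one of six labels:
#' `promoter`, `utr5`, `coding_exon`, `utr3`, `intron`, `intergenic`.
#' Overlapping claims are resolved by the fixed priority
#' promoter > utr5 > coding_exon > utr3 > intron > intergenic, so e.g. a
#' promoter of one gene overlapping the intron of another is labelled
#' promoter. Promoters are a fixed window upstream of the TSS (strand aware)
#' and are clipped at chromosome edges. Genes without annotated CDS keep
#' their exonic bases as `coding_exon` so the scheme stays total.
#'
#' @param genes Gene-model tibble ([read_gff3()]).
#' @param layout A [genome_layout()].
#' @param promoter_window Promoter size in bp upstream of the TSS (default
#'   2000).
#' @return A tibble of disjoint labelled intervals (`chrom`, `start`, `end`,
#'   `feature`) jointly covering the layout, with attributes `layout` and
#'   `promoter_window`; class `feature_index`.
#' @export
build_feature_index <- function(genes, layout, promoter_window = 2000) {
  stopifnot(promoter_window > 0)
  prio <- c(intron = 2, utr3 = 3, coding_exon = 4, utr5 = 5, promoter = 6)
  cand <- if (nrow(genes) == 0) {
    tibble::tibble(chrom = character(), start = numeric(), end = numeric(), prio = numeric())
  } else {
    .check_intervals(genes, layout, "gene")
    purrr::map_dfr(seq_len(nrow(genes)), function(i) {
      g <- genes[i, ]
      body_lo <- min(g$tss, g$tts); body_hi <- max(g$tss, g$tts)
      prom <- if (g$strand == "+") {
        c(g$tss - promoter_window, g$tss)
      } else {
        c(g$tss, g$tss + promoter_window)
      }
      ex <- g$exons[[1]]; cd <- g$cds[[1]]
      coding <- if (nrow(cd) > 0) cd else ex
      pieces <- dplyr::bind_rows(
        tibble::tibble(start = prom[1], end = prom[2], prio = prio[["promoter"]]),
        if (nrow(g$utr5[[1]])) dplyr::mutate(g$utr5[[1]], prio = prio[["utr5"]]),
        if (nrow(coding)) dplyr::mutate(coding, prio = prio[["coding_exon"]]),
        if (nrow(g$utr3[[1]])) dplyr::mutate(g$utr3[[1]], prio = prio[["utr3"]]),
        tibble::tibble(start = body_lo, end = body_hi, prio = prio[["intron"]])
      )
      pieces$chrom <- g$chrom
      pieces
    })
  }
  out <- purrr::map2_dfr(layout$chrom, layout$length, function(ch, len) {
    cc <- cand[cand$chrom == ch, , drop = FALSE]
    cc$start <- pmax(cc$start, 0)
    cc$end <- pmin(cc$end, len)
    cc <- cc[cc$end > cc$start, , drop = FALSE]
    if (nrow(cc) == 0) {
      return(tibble::tibble(chrom = ch, start = 0, end = len, feature = "intergenic"))
    }
    ir <- .to_ir(cc)
    d <- IRanges::disjoin(ir)
    hits <- IRanges::findOverlaps(d, ir)
    q <- S4Vectors::queryHits(hits)
    p <- cc$prio[S4Vectors::subjectHits(hits)]
    o <- order(p)  # assign ascending so the highest priority lands last
    best <- numeric(length(d))
    best[q[o]] <- p[o]
    lab <- names(prio)[match(best, prio)]
    seg <- .from_ir(d, ch)
    seg$feature <- lab
    gaps <- IRanges::gaps(IRanges::reduce(d), start = 1L, end = as.integer(len))
    if (length(gaps)) {
      gseg <- .from_ir(gaps, ch)
      gseg$feature <- "intergenic"
      seg <- dplyr::bind_rows(seg, gseg)
    }
    seg <- dplyr::arrange(seg, .data$start)
    # collapse adjacent runs with identical labels
    run <- cumsum(c(TRUE, seg$feature[-1] != seg$feature[-nrow(seg)] |
                      seg$start[-1] != seg$end[-nrow(seg)]))
    dplyr::summarise(dplyr::group_by(seg, run = run),
                     chrom = ch, start = min(.data$start), end = max(.data$end),
                     feature = .data$feature[1], .groups = "drop")[, -1]
  })
  out$feature <- factor(out$feature, levels = FEATURE_LEVELS)
  structure(out, layout = layout, promoter_window = promoter_window,
            class = c("feature_index", class(out)))
}

#' Look up the feature label at genomic positions
#'
#' @param index A [build_feature_index()] result.
#' @param chrom Chromosome name (scalar or vector recycled against `pos`).
#' @param pos 0-based positions.
#' @return Factor of feature labels, one per position.
#' @export
classify_position <- function(index, chrom, pos) {
  layout <- attr(index, "layout")
  n <- max(length(chrom), length(pos))
  chrom <- rep_len(chrom, n); pos <- rep_len(pos, n)
  len <- .layout_len(layout, chrom)
  if (any(pos < 0 | pos >= len)) stop("position outside chromosome bounds")
  out <- factor(rep(NA_character_, n), levels = FEATURE_LEVELS)
  for (ch in unique(chrom)) {
    sel <- chrom == ch
    seg <- index[index$chrom == ch, , drop = FALSE]
    i <- findInterval(pos[sel], seg$start)
    stopifnot(all(i >= 1), all(pos[sel] < seg$end[i]))
    out[sel] <- seg$feature[i]
  }
  out
}

#' Per-gene promoter-plus-body regions
#'
#' The region used throughout the package to attribute peaks to genes: the
#' promoter window joined with the gene body `[min(tss,tts), max(tss,tts))`.
#' The two pieces abut at the TSS, so each gene yields one interval, clipped
#' to the chromosome.
#'
#' @inheritParams build_feature_index
#' @return Tibble `gene_id`, `chrom`, `start`, `end`.
#' @export
gene_regions <- function(genes, layout, promoter_window = 2000) {
  if (nrow(genes) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          start = numeric(), end = numeric()))
  }
  lo <- pmin(genes$tss, genes$tts)
  hi <- pmax(genes$tss, genes$tts)
  start <- ifelse(genes$strand == "+", lo - promoter_window, lo)
  end <- ifelse(genes$strand == "+", hi, hi + promoter_window)
  out <- tibble::tibble(gene_id = genes$gene_id, chrom = genes$chrom,
                        start = start, end = end)
  len <- .layout_len(layout, out$chrom)
  out$start <- pmax(out$start, 0)
  out$end <- pmin(out$end, len)
  out
}
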