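#' Threshold a differential-expression table into up/down sets
#'
#' A gene is upregulated iff `log2FC >= lfc_min` and `FDR < fdr_max`,
#' downregulated iff `log2FC <= -lfc_min` and `FDR < fdr_max` (the boundary
#' `|log2FC| = lfc_min` is included; the FDR bound is strict). The sets are
#' disjoint by construction.
#'
#' @param de DE tibble (`gene_id`, `log2FC`, `FDR`; see [read_de_table()]).
#' @param lfc_min Absolute log2 fold-change threshold (default 1).
#' @param fdr_max FDR threshold (default 0.05).
#' @return `de` with a `direction` column (`up`, `down`, `ns`).
#' @export
call_de <- function(de, lfc_min = 1, fdr_max = 0.05) {
  de$direction <- dplyr::case_when(
    de$log2FC >= lfc_min & de$FDR < fdr_max ~ "up",
    de$log2FC <= -lfc_min & de$FDR < fdr_max ~ "down",
    TRUE ~ "ns"
  )
  de
}

#' Simple two-condition differential expression from FPKM
#'
#' A lightweight contrast for pipelines that start from expression tables
#' rather than read counts: log2 fold change on pseudocounted condition
#' means, a two-sided Welch t-test on `log2(FPKM + pseudocount)` per gene,
#' and Benjamini-Hochberg FDR over all genes. Genes with zero variance in
#' both groups get p = 1 when the means are equal (and p = 0 when a
#' noiseless shift is present).
#'
#' @param expr Expression tibble.
#' @param condition_a,condition_b Condition labels (reference first; log2FC
#'   is b over a). Both need >= 2 replicates.
#' @param pseudocount Added to FPKM before the log (default 1).
#' @return DE tibble `gene_id`, `mean_a`, `mean_b`, `log2FC`, `pvalue`, `FDR`.
#' @export
simple_de <- function(expr, condition_a = "CK", condition_b = "NaCl", pseudocount = 1) {
  cond <- expression_conditions(expr)
  sa <- cond$sample[cond$condition == condition_a]
  sb <- cond$sample[cond$condition == condition_b]
  if (length(sa) < 2 || length(sb) < 2) stop("need >= 2 replicates per condition")
  A <- log2(as.matrix(expr[sa]) + pseudocount)
  B <- log2(as.matrix(expr[sb]) + pseudocount)
  mean_a <- rowMeans(as.matrix(expr[sa]))
  mean_b <- rowMeans(as.matrix(expr[sb]))
  lfc <- log2((mean_b + pseudocount) / (mean_a + pseudocount))
  p <- vapply(seq_len(nrow(expr)), function(i) {
    a <- A[i, ]; b <- B[i, ]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      return(if (isTRUE(all.equal(mean(a), mean(b)))) 1 else 0)
    }
    stats::t.test(b, a)$p.value
  }, numeric(1))
  tibble::tibble(gene_id = expr$gene_id, mean_a = mean_a, mean_b = mean_b,
                 log2FC = lfc, pvalue = p, FDR = stats::p.adjust(p, "BH"))
}

#' Per-gene mark gain/loss between two conditions
#'
#' Classifies each gene's mark status transition between a control and a
#' treated peak set of the same mark. The marked state follows the
#' promoter-plus-body overlap rule; the per-gene mark signal is the summed
#' peak bp overlapping that region (occupancy), with a bp pseudocount for
#' the log-ratio. Genes marked in both conditions are `stable` when the
#' bp-Jaccard of their condition-specific peak bases is at least
#' `min_jaccard_stable`; below the floor (peak replacement) the sign of the
#' signal log-ratio decides gain/loss. Swapping the two conditions swaps
#' gain and loss exactly.
#'
#' @param peaks_ck,peaks_nacl Peak tibbles of the same mark under the control
#'   and treated condition.
#' @param genes Gene models.
#' @param layout A [genome_layout()].
#' @param promoter_window Promoter size in bp (default 2000).
#' @param min_jaccard_stable Jaccard floor for calling marked-in-both genes
#'   stable (default 0.25).
#' @param pseudocount_bp Occupancy pseudocount in bp (default 100).
#' @return Tibble, one row per gene: `gene_id`, `mark`, `marked_ck`,
#'   `marked_nacl`, `signal_ck`, `signal_nacl`, `log_ratio`, `jaccard`,
#'   `status` in `{gain, loss, stable, absent}` (a partition).
#' @export
mark_gain_loss <- function(peaks_ck, peaks_nacl, genes, layout,
                           promoter_window = 2000, min_jaccard_stable = 0.25,
                           pseudocount_bp = 100) {
  m_ck <- if ("mark" %in% names(peaks_ck)) unique(peaks_ck$mark) else NA
  m_na <- if ("mark" %in% names(peaks_nacl)) unique(peaks_nacl$mark) else NA
  if (length(m_ck) == 1 && length(m_na) == 1 && !identical(m_ck, m_na) &&
      !anyNA(c(m_ck, m_na))) {
    stop("peak sets carry different marks: ", m_ck, " vs ", m_na)
  }
  mark <- if (!is.na(m_ck[1])) m_ck[1] else "mark"
  regions <- gene_regions(genes, layout, promoter_window)
  ck_m <- merge_intervals(peaks_ck, layout)
  na_m <- merge_intervals(peaks_nacl, layout)
  both_m <- intersect_intervals(ck_m, na_m)
  s_ck <- region_overlap_bp(ck_m, regions)
  s_na <- region_overlap_bp(na_m, regions)
  s_both <- region_overlap_bp(both_m, regions)
  s_union <- s_ck + s_na - s_both
  res <- tibble::tibble(gene_id = regions$gene_id,
                        signal_ck = s_ck, signal_nacl = s_na,
                        jaccard = ifelse(s_union > 0, s_both / s_union, 0))
  res$mark <- mark
  res$marked_ck <- res$signal_ck > 0
  res$marked_nacl <- res$signal_nacl > 0
  res$log_ratio <- log2((res$signal_nacl + pseudocount_bp) /
                          (res$signal_ck + pseudocount_bp))
  res$status <- dplyr::case_when(
    !res$marked_ck & !res$marked_nacl ~ "absent",
    !res$marked_ck & res$marked_nacl ~ "gain",
    res$marked_ck & !res$marked_nacl ~ "loss",
    res$jaccard >= min_jaccard_stable ~ "stable",
    res$log_ratio > 0 ~ "gain",
    res$log_ratio < 0 ~ "loss",
    TRUE ~ "stable"
  )
  res[c("gene_id", "mark", "marked_ck", "marked_nacl", "signal_ck",
        "signal_nacl", "log_ratio", "jaccard", "status")]
}

CONCORDANCE_CLASSES <- tibble::tibble(
  mark = c("H3K4me3", "H3K4me3", "H3K9ac", "H3K9ac", "H3K27me3", "H3K27me3"),
  mark_status = c("gain", "loss", "gain", "loss", "gain", "loss"),
  de_direction = c("up", "down", "up", "down", "down", "up")
)

#' Concordance between mark dynamics and differential expression
#'
#' The six concordant classes pair activating-mark changes with same-sign
#' expression changes and repressive-mark changes with opposite-sign ones:
#' H3K4me3-gain/up, H3K4me3-loss/down, H3K9ac-gain/up, H3K9ac-loss/down,
#' H3K27me3-gain/down, H3K27me3-loss/up. Also reports how much of each DEG
#' set is covered by at least one class.
#'
#' @param de A [call_de()] table (with `direction`).
#' @param dynamics Named list of [mark_gain_loss()] tables, names =
#'   mark labels (H3K4me3, H3K9ac, H3K27me3).
#' @return A `concordance_report`: `classes` tibble (`class`, `mark`,
#'   `mark_status`, `de_direction`, `n`, `genes` list-column) and `coverage`
#'   tibble (per DE direction: total DEGs, covered by >= 1 class, fraction).
#' @export
concordance <- function(de, dynamics) {
  up <- de$gene_id[de$direction == "up"]
  down <- de$gene_id[de$direction == "down"]
  classes <- purrr::pmap_dfr(CONCORDANCE_CLASSES, function(mark, mark_status, de_direction) {
    dyn <- dynamics[[mark]]
    genes <- if (is.null(dyn)) character(0) else {
      changed <- dyn$gene_id[dyn$status == mark_status]
      intersect(changed, if (de_direction == "up") up else down)
    }
    tibble::tibble(class = paste0(mark, "-", mark_status, "/", de_direction),
                   mark = mark, mark_status = mark_status,
                   de_direction = de_direction, n = length(genes),
                   genes = list(sort(genes)))
  })
  covered_up <- unique(unlist(classes$genes[classes$de_direction == "up"]))
  covered_down <- unique(unlist(classes$genes[classes$de_direction == "down"]))
  coverage <- tibble::tibble(
    de_direction = c("up", "down"),
    n_deg = c(length(up), length(down)),
    n_covered = c(length(covered_up), length(covered_down)),
    fraction = c(if (length(up)) length(covered_up) / length(up) else NA_real_,
                 if (length(down)) length(covered_down) / length(down) else NA_real_)
  )
  structure(list(classes = classes, coverage = coverage),
            class = "concordance_report")
}

#' @export
print.concordance_report <- function(x, ...) {
  cat("Mark-expression concordance classes:\n")
  print(x$classes[c("class", "n")])
  cat("DEG coverage by any class:\n")
  print(x$coverage)
  invisible(x)
}

#' Tidy a concordance report
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @export
tidy.concordance_report <- function(x, ...) x$classes

#' One-row summary of a concordance report
#' @param x A `concordance_report`.
#' @param ... Unused.
#' @export
glance.concordance_report <- function(x, ...) {
  tibble::tibble(
    n_classes = nrow(x$classes),
    n_concordant = sum(x$classes$n),
    frac_up_covered = x$coverage$fraction[x$coverage$de_direction == "up"],
    frac_down_covered = x$coverage$fraction[x$coverage$de_direction == "down"]
  )
}

#' Promoter enrichment rate of condition-specific peaks over a gene class
#'
#' Changed peaks are peaks present in only one condition (no overlap with
#' the other condition's peak set) that overlap the class genes'
#' promoter-plus-body regions. Each changed peak is labelled by its anchor
#' feature; the peak-level rate is the promoter-labelled share. A gene-level
#' rate (share of class genes whose changed peaks include a
#' promoter-anchored one) is reported alongside, since the published rates
#' do not state their unit.
#'
#' @param class_genes Character vector of gene ids in the concordance class.
#' @param peaks_cond Peaks of the condition where the mark is present
#'   (the treated set for a gain class, the control set for a loss class).
#' @param peaks_other The same mark's peaks in the other condition.
#' @param index A [build_feature_index()].
#' @param genes Gene models.
#' @param layout A [genome_layout()].
#' @param promoter_window Promoter size in bp.
#' @return One-row tibble: `n_changed_peaks`, `promoter_rate_peaks`,
#'   `n_genes`, `promoter_rate_genes`. Rates are `NA` (with a warning) when
#'   no changed peaks exist.
#' @export
promoter_rate <- function(class_genes, peaks_cond, peaks_other, index, genes,
                          layout, promoter_window = 2000) {
  regions <- gene_regions(genes[genes$gene_id %in% class_genes, , drop = FALSE],
                          layout, promoter_window)
  changed <- peaks_cond[!overlaps_any(peaks_cond, peaks_other), , drop = FALSE]
  hit_gene <- overlaps_any(changed, regions)
  changed <- changed[hit_gene, , drop = FALSE]
  if (nrow(changed) == 0) {
    warning("no condition-specific peaks over the class genes")
    return(tibble::tibble(n_changed_peaks = 0, promoter_rate_peaks = NA_real_,
                          n_genes = length(class_genes),
                          promoter_rate_genes = NA_real_))
  }
  ann <- assign_peaks(changed, index)
  prom <- ann[ann$feature == "promoter", , drop = FALSE]
  gene_hit_any <- regions$gene_id[overlaps_any(regions, changed)]
  gene_hit_prom <- regions$gene_id[overlaps_any(regions, prom)]
  tibble::tibble(
    n_changed_peaks = nrow(changed),
    promoter_rate_peaks = mean(ann$feature == "promoter"),
    n_genes = length(class_genes),
    promoter_rate_genes = if (length(gene_hit_any)) {
      length(intersect(gene_hit_prom, gene_hit_any)) / length(gene_hit_any)
    } else NA_real_
  )
}

#' Fold-change correlations between marks and expression
#'
#' Pairwise correlations of per-gene log2 signal ratios (one per mark, from
#' [mark_gain_loss()]) and the expression log2 fold change, over genes with
#' both values defined. Pearson by default, Spearman available. Constant
#' vectors give `NA` with a warning.
#'
#' @param dynamics Named list of [mark_gain_loss()] tables.
#' @param de DE tibble (`gene_id`, `log2FC`).
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Tibble `var1`, `var2`, `n`, `r`, `p_value`, `method` covering all
#'   mark-expression and mark-mark pairs.
#' @export
fc_correlation <- function(dynamics, de, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  vals <- tibble::tibble(gene_id = de$gene_id, expression = de$log2FC)
  for (m in names(dynamics)) {
    d <- dynamics[[m]]
    vals[[m]] <- d$log_ratio[match(vals$gene_id, d$gene_id)]
  }
  vars <- c(names(dynamics), "expression")
  pairs <- utils::combn(vars, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    ok <- stats::complete.cases(vals[[pr[1]]], vals[[pr[2]]])
    a <- vals[[pr[1]]][ok]; b <- vals[[pr[2]]][ok]
    if (sum(ok) < 3) stop("fewer than 3 genes with finite values for pair ",
                          pr[1], " vs ", pr[2])
    if (stats::sd(a) == 0 || stats::sd(b) == 0) {
      warning("constant vector in pair ", pr[1], " vs ", pr[2], "; r undefined")
      return(tibble::tibble(var1 = pr[1], var2 = pr[2], n = sum(ok),
                            r = NA_real_, p_value = NA_real_, method = method))
    }
    ct <- suppressWarnings(stats::cor.test(a, b, method = method))
    tibble::tibble(var1 = pr[1], var2 = pr[2], n = sum(ok),
                   r = unname(ct$estimate), p_value = ct$p.value, method = method)
  })
}

#' Basepair-level variability score between two peak sets
#'
#' `1 - Jaccard` on merged covered bases: 0 for identical sets, 1 for
#' disjoint sets. Two empty sets score 0 by convention (flagged).
#'
#' @param peaks_a,peaks_b Peak tibbles on the same layout.
#' @return One-row tibble: `bp_a`, `bp_b`, `bp_intersect`, `bp_union`,
#'   `jaccard`, `score`.
#' @export
variability_score <- function(peaks_a, peaks_b) {
  bp_a <- covered_bp(peaks_a)
  bp_b <- covered_bp(peaks_b)
  if (bp_a == 0 && bp_b == 0) {
    warning("both peak sets are empty; variability score 0 by convention")
    return(tibble::tibble(bp_a = 0, bp_b = 0, bp_intersect = 0, bp_union = 0,
                          jaccard = 1, score = 0))
  }
  inter <- intersect_bp(peaks_a, peaks_b)
  uni <- bp_a + bp_b - inter
  tibble::tibble(bp_a = bp_a, bp_b = bp_b, bp_intersect = inter, bp_union = uni,
                 jaccard = inter / uni, score = 1 - inter / uni)
}

#' Filter differential metabolites
#'
#' The standard untargeted-metabolomics gate: a metabolite is upregulated
#' iff `VIP > vip_min`, `FC > fc_up` and `p < p_max`; downregulated iff
#' `VIP > vip_min`, `FC < fc_down` and `p < p_max`. Defaults follow the
#' VIP > 1.0, FC > 1.5 / FC < 0.667, p < 0.05 convention; the stricter
#' FC >= 2 / FC <= 0.5 preset is reachable via the arguments.
#'
#' @param tab Metabolite tibble ([read_metabolite_table()]).
#' @param vip_min,fc_up,fc_down,p_max Gate thresholds.
#' @return `tab` with a `direction` column (`up`, `down`, `ns`).
#' @export
filter_metabolites <- function(tab, vip_min = 1.0, fc_up = 1.5,
                               fc_down = 0.667, p_max = 0.05) {
  tab$direction <- dplyr::case_when(
    tab$VIP > vip_min & tab$FC > fc_up & tab$pvalue < p_max ~ "up",
    tab$VIP > vip_min & tab$FC < fc_down & tab$pvalue < p_max ~ "down",
    TRUE ~ "ns"
  )
  tab
}

#' Summarise differential metabolites per ion mode
#' @param filtered A [filter_metabolites()] result.
#' @return Tibble `ion_mode`, `n_total`, `n_up`, `n_down`.
#' @export
metabolite_summary <- function(filtered) {
  dplyr::summarise(dplyr::group_by(filtered, .data$ion_mode),
                   n_total = dplyr::n(),
                   n_up = sum(.data$direction == "up"),
                   n_down = sum(.data$direction == "down"),
                   .groups = "drop")
}
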