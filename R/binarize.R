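#' Binarize mark presence in genomic bins
#'
#' Two methods:
#' * `peak_overlap`: a bin is 1 iff it shares at least one bp with a peak.
#' * `poisson_signal`: a bin is 1 iff the upper-tail Poisson p-value of the
#'   bin's count under the genome-wide mean rate is below `p_threshold`
#'   (the ChromHMM-style signal binarization).
#'
#' @param x For `peak_overlap` a named list of peak tibbles (one per mark) or
#'   a single peak tibble; for `poisson_signal` a named list of numeric count
#'   vectors aligned with `bins` (or a single vector).
#' @param bins A [bin_genome()] tibble.
#' @param method `"peak_overlap"` or `"poisson_signal"`.
#' @param p_threshold Poisson tail threshold (default 1e-4).
#' @return `bins` with one 0/1 integer column per mark appended.
#' @export
binarize_marks <- function(x, bins, method = c("peak_overlap", "poisson_signal"),
                           p_threshold = 1e-4) {
  method <- match.arg(method)
  if (method == "peak_overlap" && is.data.frame(x)) {
    nm <- if ("mark" %in% names(x) && length(unique(x$mark)) == 1) unique(x$mark) else "mark"
    x <- stats::setNames(list(x), nm)
  }
  if (method == "poisson_signal" && !is.list(x)) x <- list(signal = x)
  out <- bins
  for (nm in names(x)) {
    if (method == "peak_overlap") {
      out[[nm]] <- as.integer(overlaps_any(bins, x[[nm]]))
    } else {
      counts <- x[[nm]]
      stopifnot(length(counts) == nrow(bins))
      lambda <- mean(counts)
      if (lambda == 0) {
        warning(sprintf("all-zero signal for '%s'; binarized column is all zero", nm))
        out[[nm]] <- integer(nrow(bins))
      } else {
        p <- stats::ppois(counts - 1, lambda, lower.tail = FALSE)
        out[[nm]] <- as.integer(p < p_threshold)
      }
    }
  }
  out
}

#' Summarise decoded chromatin states
#'
#' Per state: genome fraction (bp), mean emission per mark (from the model if
#' given), fold enrichment over each feature label and each TE class
#' (observed bp / expected bp), and the mean expression of genes whose
#' promoter-plus-body region overlaps the state. States absent from the
#' segmentation get missing (NA) enrichments, never 0.
#'
#' @param seg A [decode_states()] segmentation.
#' @param index A [build_feature_index()] (optional).
#' @param te Optional TE annotation: interval tibble with a `class` column.
#' @param expr Optional expression tibble ([read_expression()]).
#' @param genes Gene models (required with `expr`).
#' @param layout A [genome_layout()].
#' @param promoter_window Promoter size in bp.
#' @return List of tibbles: `states` (fraction and mean expression),
#'   `feature_enrichment`, `te_enrichment` (long, one row per state x class).
#' @export
annotate_states <- function(seg, layout, index = NULL, te = NULL, expr = NULL,
                            genes = NULL, promoter_window = 2000) {
  K <- attr(seg, "K")
  if (is.null(K)) K <- max(seg$state)
  genome_bp <- sum(layout$length)
  state_iv <- split(seg[c("chrom", "start", "end")], factor(seg$state, levels = seq_len(K)))
  state_bp <- purrr::map_dbl(state_iv, covered_bp)

  states <- tibble::tibble(state = seq_len(K), bp = state_bp,
                           genome_fraction = state_bp / genome_bp)

  enrich_one <- function(classes_iv, class_bp) {
    purrr::imap_dfr(state_iv, function(siv, st) {
      purrr::imap_dfr(classes_iv, function(civ, cl) {
        fe <- if (state_bp[[as.integer(st)]] == 0 || class_bp[[cl]] == 0) NA_real_ else {
          obs <- intersect_bp(siv, civ) / state_bp[[as.integer(st)]]
          exp <- class_bp[[cl]] / genome_bp
          obs / exp
        }
        tibble::tibble(state = as.integer(st), class = cl, fold_enrichment = fe)
      })
    })
  }

  feature_enrichment <- NULL
  if (!is.null(index)) {
    fidx <- tibble::as_tibble(index)
    f_iv <- split(fidx[c("chrom", "start", "end")], fidx$feature)
    f_bp <- purrr::map_dbl(f_iv, function(x) sum(x$end - x$start))
    feature_enrichment <- enrich_one(f_iv, f_bp)
  }
  te_enrichment <- NULL
  if (!is.null(te) && nrow(te) > 0) {
    t_iv <- split(te[c("chrom", "start", "end")], te$class)
    t_bp <- purrr::map_dbl(t_iv, covered_bp)
    te_enrichment <- enrich_one(t_iv, t_bp)
  }
  if (!is.null(expr) && !is.null(genes)) {
    regions <- gene_regions(genes, layout, promoter_window)
    vals <- rowMeans(expr[setdiff(names(expr), "gene_id")])
    gene_fpkm <- stats::setNames(vals, expr$gene_id)
    states$mean_expression <- purrr::map_dbl(seq_len(K), function(st) {
      siv <- state_iv[[st]]
      if (nrow(siv) == 0) return(NA_real_)
      ids <- regions$gene_id[overlaps_any(regions, siv)]
      if (length(ids) == 0) return(NA_real_)
      mean(gene_fpkm[ids], na.rm = TRUE)
    })
  }
  list(states = states, feature_enrichment = feature_enrichment,
       te_enrichment = te_enrichment)
}

#' Chromatin-state dynamics between two segmentations
#'
#' 200-bp bins whose state labels differ between two conditions are counted
#' as dynamic.
#'
#' @param seg_a,seg_b Two [decode_states()] segmentations on the same binned
#'   genome.
#' @return List: `fraction_dynamic` (in `[0,1]`) and `transitions`, a long
#'   tibble (`state_a`, `state_b`, `n`) whose row sums over `state_b` equal
#'   the state-A bin counts.
#' @export
state_dynamics <- function(seg_a, seg_b) {
  if (nrow(seg_a) != nrow(seg_b) ||
      !identical(seg_a$chrom, seg_b$chrom) || !identical(seg_a$start, seg_b$start)) {
    stop("segmentations are not on the same binned genome")
  }
  Ka <- max(attr(seg_a, "K"), max(seg_a$state))
  Kb <- max(attr(seg_b, "K"), max(seg_b$state))
  tab <- table(factor(seg_a$state, levels = seq_len(Ka)),
               factor(seg_b$state, levels = seq_len(Kb)))
  trans <- tibble::as_tibble(tab, .name_repair = "minimal")
  names(trans) <- c("state_a", "state_b", "n")
  trans$state_a <- as.integer(trans$state_a)
  trans$state_b <- as.integer(trans$state_b)
  list(fraction_dynamic = mean(seg_a$state != seg_b$state),
       transitions = dplyr::arrange(trans, .data$state_a, .data$state_b))
}

#' Write a state segmentation as BED
#'
#' Adjacent bins with the same state are collapsed; the state label goes in
#' the BED name column as `CS<k>`.
#' @param seg A segmentation tibble.
#' @param path Output path.
#' @export
write_segmentation_bed <- function(seg, path) {
  run <- cumsum(c(TRUE, seg$state[-1] != seg$state[-nrow(seg)] |
                    seg$chrom[-1] != seg$chrom[-nrow(seg)]))
  coll <- dplyr::summarise(dplyr::group_by(seg, run = run),
                           chrom = .data$chrom[1], start = min(.data$start),
                           end = max(.data$end),
                           name = paste0("CS", .data$state[1]), .groups = "drop")
  write_bed(coll[c("chrom", "start", "end", "name")], path)
}

#' Serialize an HMM model to JSON
#' @param model A `bernoulli_hmm`.
#' @param path Output path.
#' @export
write_hmm_json <- function(model, path) {
  jsonlite::write_json(
    list(K = model$K, marks = model$marks, pi = model$pi,
         A = model$A, E = model$E, loglik = model$loglik, seed = model$seed),
    path, digits = NA, auto_unbox = TRUE, matrix = "rowmajor")
  invisible(path)
}
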