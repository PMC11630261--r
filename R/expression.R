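#' Stratify genes by expression level
#'
#' Uses the conventional FPKM strata: non-expressed (FPKM = 0),
#' low (0 < FPKM <= 1), medium (1 < FPKM <= 10) and high (FPKM > 10).
#' Boundary values, which the open strata definitions leave unassigned, are
#' closed on the lower stratum's upper edge (FPKM = 1 is low, FPKM = 10 is
#' medium). A gene's value under a condition is the mean FPKM over that
#' condition's replicates.
#'
#' @param expr Expression tibble ([read_expression()]).
#' @param condition Condition label to average over (defaults to all samples).
#' @return Tibble `gene_id`, `fpkm`, `category` (ordered factor
#'   none < low < mid < high). Every gene receives exactly one category.
#' @export
categorize_expression <- function(expr, condition = NULL) {
  samples <- setdiff(names(expr), "gene_id")
  if (!is.null(condition)) {
    cond <- expression_conditions(expr)
    samples <- cond$sample[cond$condition == condition]
    if (length(samples) == 0) stop("no samples for condition '", condition, "'")
  }
  v <- rowMeans(expr[samples])
  category <- dplyr::case_when(
    v == 0 ~ "none",
    v <= 1 ~ "low",
    v <= 10 ~ "mid",
    TRUE ~ "high"
  )
  tibble::tibble(gene_id = expr$gene_id, fpkm = v,
                 category = factor(category, levels = c("none", "low", "mid", "high"),
                                   ordered = TRUE))
}

#' Expression-category composition of a marked gene set
#'
#' @param marked Character vector of marked gene ids.
#' @param cats A [categorize_expression()] map covering every marked gene.
#' @return Tibble `category`, `n`, `fraction`; counts partition the marked
#'   set and fractions sum to 1.
#' @export
mark_by_category <- function(marked, cats) {
  marked <- unique(marked)
  if (length(marked) == 0) stop("empty marked gene set: category fractions undefined")
  unknown <- setdiff(marked, cats$gene_id)
  if (length(unknown)) stop("unknown gene id(s): ", paste(utils::head(unknown, 3), collapse = ", "))
  cc <- cats$category[match(marked, cats$gene_id)]
  n <- table(cc)
  tibble::tibble(category = factor(names(n), levels = levels(cats$category), ordered = TRUE),
                 n = as.numeric(n), fraction = as.numeric(n) / length(marked))
}

#' Two-sided Wilcoxon rank-sum comparison of two expression groups
#'
#' The exact mode computes the permutation null distribution of the rank-sum
#' statistic (midranks, so ties are handled exactly) by dynamic programming
#' and reports `P(|W - E W| >= |w - E W|)`; for tie-free data this coincides
#' with the classic two-tail convention. The normal mode uses the
#' tie-corrected normal approximation. By default the exact mode is used
#' whenever both groups have at most 20 observations. Deterministic.
#'
#' @param x,y Numeric vectors (both non-empty).
#' @param mode `"auto"` (default), `"exact"` or `"normal"`.
#' @return One-row tibble: `statistic` (rank sum of `x`), `p_value`,
#'   `median_x`, `median_y`, `method`.
#' @export
rank_compare <- function(x, y, mode = c("auto", "exact", "normal")) {
  mode <- match.arg(mode)
  if (length(x) == 0 || length(y) == 0) stop("both groups must be non-empty")
  nx <- length(x); ny <- length(y); N <- nx + ny
  r <- rank(c(x, y))  # midranks
  W <- sum(r[seq_len(nx)])
  muW <- nx * (N + 1) / 2
  all_tied <- length(unique(c(x, y))) == 1
  if (mode == "auto") mode <- if (max(nx, ny) <= 20) "exact" else "normal"
  if (all_tied) {
    warning("all values tied across both groups; p = 1")
    p <- 1
  } else if (mode == "exact") {
    p <- .ranksum_exact_p(r, nx)
  } else {
    ties <- table(r)
    sigma2 <- nx * ny / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
    z <- (W - muW) / sqrt(sigma2)
    p <- min(1, 2 * stats::pnorm(-abs(z)))
  }
  tibble::tibble(statistic = W, p_value = p,
                 median_x = stats::median(x), median_y = stats::median(y),
                 method = mode)
}

# Exact two-sided p for the rank-sum of a size-nx subset of the midranks r:
# P(|W - mu| >= |w - mu|) over all C(N, nx) equally likely subsets, computed
# with a subset-sum DP over doubled midranks (integers even under ties).
.ranksum_exact_p <- function(r, nx) {
  r2 <- as.integer(round(2 * r))  # doubled midranks are whole numbers
  N <- length(r2)
  total <- sum(r2)
  # dp[k+1, s+1] = number of size-k subsets with doubled-rank sum s
  maxs <- sum(sort(r2, decreasing = TRUE)[seq_len(nx)])
  dp <- matrix(0, nrow = nx + 1, ncol = maxs + 1)
  dp[1, 1] <- 1
  for (v in r2) {
    kmax <- nx
    for (k in kmax:1) {
      nz <- which(dp[k, ] > 0)
      nz <- nz[nz - 1 + v <= maxs]
      if (length(nz)) dp[k + 1, nz + v] <- dp[k + 1, nz + v] + dp[k, nz]
    }
  }
  counts <- dp[nx + 1, ]
  sums <- (seq_along(counts) - 1) / 2  # back to rank-sum scale
  w <- sum(r[seq_len(nx)])
  mu <- nx * sum(r) / N
  extreme <- abs(sums - mu) >= abs(w - mu) - 1e-9
  sum(counts[extreme]) / choose(N, nx)
}

#' Sample a random gene set
#'
#' Uniform sampling without replacement, seeded; mirrors the common use of
#' 10,000 randomly selected genes as a background set.
#'
#' @param gene_ids Character vector to sample from.
#' @param n Number of genes (default 10000). If `n` exceeds the pool, the
#'   whole pool is returned with a warning.
#' @param seed Integer seed.
#' @export
sample_random_genes <- function(gene_ids, n = 10000, seed = 1) {
  if (n > length(gene_ids)) {
    warning("n exceeds the number of genes; returning all genes")
    return(gene_ids)
  }
  withr::with_seed(seed, sample(gene_ids, n))
}

#' Expression breadth per gene
#'
#' Breadth is the fraction of samples in which a gene is expressed at or
#' above `threshold` FPKM — a proxy for how constitutive versus
#' sample-specific its expression is.
#'
#' @param expr Expression tibble (needs >= 2 samples).
#' @param threshold Expressed-sample threshold in FPKM (default 1).
#' @return Tibble `gene_id`, `breadth` in `[0, 1]`.
#' @export
expression_breadth <- function(expr, threshold = 1) {
  samples <- setdiff(names(expr), "gene_id")
  if (length(samples) < 2) stop("expression breadth needs at least 2 samples")
  m <- as.matrix(expr[samples])
  tibble::tibble(gene_id = expr$gene_id, breadth = rowMeans(m >= threshold))
}

#' Tissue-specificity index tau
#'
#' The tau index, an alternative breadth/specificity summary:
#' `tau = sum(1 - x_i / max(x)) / (n - 1)` over samples, 0 for uniformly
#' expressed genes and 1 for single-sample expression. Genes silent
#' everywhere get `NA`.
#'
#' @inheritParams expression_breadth
#' @return Tibble `gene_id`, `tau`.
#' @export
expression_tau <- function(expr) {
  samples <- setdiff(names(expr), "gene_id")
  if (length(samples) < 2) stop("tau needs at least 2 samples")
  m <- as.matrix(expr[samples])
  mx <- apply(m, 1, max)
  tau <- ifelse(mx > 0, rowSums(1 - m / ifelse(mx > 0, mx, 1)) / (ncol(m) - 1), NA_real_)
  tibble::tibble(gene_id = expr$gene_id, tau = tau)
}
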