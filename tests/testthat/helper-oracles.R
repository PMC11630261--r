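# Shared fixtures and independent brute-force oracles. Oracles work per base
# (boolean/label arrays) or by explicit enumeration and are deliberately
# independent of the package's interval and HMM code paths.

make_layout <- function(lens = c(chrA = 1000, chrB = 700)) {
  genome_layout(names(lens), unname(lens))
}

# Build a gene-model row like read_gff3 produces. Single CDS exon by default.
make_gene <- function(gene_id, chrom, start, end, strand = "+",
                      exons = NULL, cds = NULL) {
  if (is.null(exons)) exons <- tibble::tibble(start = start, end = end)
  if (is.null(cds)) cds <- exons
  utr <- chromdyn:::.derive_utrs(exons, cds, strand)
  tibble::tibble(gene_id = gene_id, chrom = chrom, strand = strand,
                 start = start, end = end,
                 tss = if (strand == "+") start else end,
                 tts = if (strand == "+") end else start,
                 exons = list(exons), cds = list(cds),
                 utr5 = list(utr$utr5), utr3 = list(utr$utr3))
}

rand_genes <- function(layout, n, seed, min_len = 200, max_len = 3000) {
  withr::with_seed(seed, {
    purrr::map_dfr(seq_len(n), function(i) {
      ci <- sample(nrow(layout), 1)
      len <- sample(min_len:min(max_len, layout$length[ci] - 1), 1)
      start <- sample(0:(layout$length[ci] - len), 1)
      strand <- sample(c("+", "-"), 1)
      # random CDS inset inside the single exon
      u5 <- sample(0:100, 1); u3 <- sample(0:100, 1)
      cds_lo <- start + if (strand == "+") u5 else u3
      cds_hi <- start + len - if (strand == "+") u3 else u5
      make_gene(sprintf("g%03d", i), layout$chrom[ci], start, start + len, strand,
                cds = tibble::tibble(start = cds_lo, end = cds_hi))
    })
  })
}

rand_peaks <- function(layout, n, seed, max_len = 500, mark = "H3K4me3",
                       condition = "CK") {
  withr::with_seed(seed, {
    ci <- sample(nrow(layout), n, replace = TRUE)
    len <- sample(seq_len(max_len), n, replace = TRUE)
    start <- floor(runif(n) * (layout$length[ci] - len))
    tibble::tibble(chrom = layout$chrom[ci], start = start, end = start + len,
                   summit = NA_real_, mark = mark, condition = condition) |>
      dplyr::arrange(chrom, start)
  })
}

# --- per-base oracles ---------------------------------------------------

# Label every base by painting candidate features in increasing priority.
oracle_base_labels <- function(genes, layout, promoter_window = 2000) {
  labs <- lapply(seq_len(nrow(layout)), function(i) {
    rep("intergenic", layout$length[i])
  })
  names(labs) <- layout$chrom
  paint <- function(chrom, lo, hi, lab) {
    lo <- max(lo, 0); hi <- min(hi, length(labs[[chrom]]))
    if (hi > lo) labs[[chrom]][(lo + 1):hi] <<- lab
  }
  for (lab in c("intron", "utr3", "coding_exon", "utr5", "promoter")) {
    for (i in seq_len(nrow(genes))) {
      g <- genes[i, ]
      body_lo <- min(g$tss, g$tts); body_hi <- max(g$tss, g$tts)
      if (lab == "intron") paint(g$chrom, body_lo, body_hi, lab)
      if (lab == "utr3") {
        u <- g$utr3[[1]]
        for (j in seq_len(nrow(u))) paint(g$chrom, u$start[j], u$end[j], lab)
      }
      if (lab == "coding_exon") {
        cc <- if (nrow(g$cds[[1]])) g$cds[[1]] else g$exons[[1]]
        for (j in seq_len(nrow(cc))) paint(g$chrom, cc$start[j], cc$end[j], lab)
      }
      if (lab == "utr5") {
        u <- g$utr5[[1]]
        for (j in seq_len(nrow(u))) paint(g$chrom, u$start[j], u$end[j], lab)
      }
      if (lab == "promoter") {
        if (g$strand == "+") paint(g$chrom, g$tss - promoter_window, g$tss, lab)
        else paint(g$chrom, g$tss, g$tss + promoter_window, lab)
      }
    }
  }
  labs
}

# Boolean coverage arrays per chromosome.
oracle_cover <- function(x, layout) {
  cov <- lapply(seq_len(nrow(layout)), function(i) rep(FALSE, layout$length[i]))
  names(cov) <- layout$chrom
  for (i in seq_len(nrow(x))) {
    if (x$end[i] > x$start[i]) {
      cov[[x$chrom[i]]][(x$start[i] + 1):x$end[i]] <- TRUE
    }
  }
  cov
}

oracle_coverage_fraction <- function(peaks, layout) {
  cov <- oracle_cover(peaks, layout)
  sum(unlist(cov)) / sum(layout$length)
}

oracle_jaccard <- function(a, b, layout) {
  ca <- unlist(oracle_cover(a, layout)); cb <- unlist(oracle_cover(b, layout))
  inter <- sum(ca & cb); uni <- sum(ca | cb)
  if (uni == 0) 0 else inter / uni
}

# Bivalent domains as runs of bases covered by both sets.
oracle_bivalent_domains <- function(a, b, layout) {
  purrr::map_dfr(seq_len(nrow(layout)), function(i) {
    ch <- layout$chrom[i]
    both <- oracle_cover(a[a$chrom == ch, ], layout)[[ch]] &
      oracle_cover(b[b$chrom == ch, ], layout)[[ch]]
    r <- rle(both)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    keep <- r$values
    tibble::tibble(chrom = ch, start = starts[keep], end = ends[keep])
  })
}

# --- enumeration oracles ------------------------------------------------

# HMM log-likelihood by summing over every K^T hidden path.
enum_hmm_loglik <- function(X, pi, A, E) {
  Tn <- nrow(X); K <- length(pi)
  emis <- function(k, t) prod(E[k, ]^X[t, ] * (1 - E[k, ])^(1 - X[t, ]))
  paths <- expand.grid(rep(list(seq_len(K)), Tn))
  tot <- sum(apply(paths, 1, function(p) {
    pr <- pi[p[1]] * emis(p[1], 1)
    for (t in seq_len(Tn - 1)) pr <- pr * A[p[t], p[t + 1]] * emis(p[t + 1], t + 1)
    pr
  }))
  log(tot)
}

# Joint probability of one specific path (for Viterbi optimality checks).
enum_hmm_path_logprob <- function(path, X, pi, A, E) {
  emis <- function(k, t) prod(E[k, ]^X[t, ] * (1 - E[k, ])^(1 - X[t, ]))
  lp <- log(pi[path[1]]) + log(emis(path[1], 1))
  for (t in seq_len(nrow(X) - 1)) {
    lp <- lp + log(A[path[t], path[t + 1]]) + log(emis(path[t + 1], t + 1))
  }
  lp
}

# Exact two-sided rank-sum p by full enumeration of all C(N, nx) subsets,
# with the same symmetric-tail rule the package documents.
enum_ranksum_p <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  w <- sum(r[seq_len(nx)])
  mu <- nx * (N + 1) / 2
  subsets <- utils::combn(N, nx)
  ws <- apply(subsets, 2, function(s) sum(r[s]))
  mean(abs(ws - mu) >= abs(w - mu) - 1e-9)
}

expect_equal_intervals <- function(a, b) {
  expect_equal(as.data.frame(a[order(a$chrom, a$start), c("chrom", "start", "end")]),
               as.data.frame(b[order(b$chrom, b$start), c("chrom", "start", "end")]),
               ignore_attr = TRUE)
}
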