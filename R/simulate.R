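SIM_MARKS <- c("H3K4me3", "H3K9ac", "H3K27me3", "H3K9me2")
GENE_MARKS <- c("H3K4me3", "H3K9ac", "H3K27me3")

#' Configuration for the synthetic epigenome generator
#'
#' Bundles every knob of the simulated world: genome and gene geometry, the
#' background chromatin-state HMM truth, per-class promoter mark
#' probabilities, bivalent promoter planting, mark-expression coupling
#' effect sizes, condition-shift (gain/loss) rates coupled to expression
#' shifts, replicate noise, reChIP dropout and the metabolite table mix.
#' The defaults describe the standard simulated study: a 10-Mb genome in
#' five chromosomes, 2,000 genes, four marks, two conditions (CK and NaCl)
#' and five replicates. The `"noisefree"` preset switches off background
#' dynamics, latent-factor expression coupling and reChIP dropout, and
#' shrinks replicate noise, so every planted assignment is exactly
#' recoverable; it is the configuration for ground-truth recovery checks.
#'
#' @param seed Integer master seed; identical seeds give byte-identical
#'   simulated worlds.
#' @param preset `"default"` or `"noisefree"`.
#' @param ... Named overrides of any configuration field.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1, preset = c("default", "noisefree"), ...) {
  preset <- match.arg(preset)
  cfg <- list(
    seed = seed,
    # genome geometry
    n_chrom = 5, chrom_length = 2e6, bin_size = 200,
    n_genes = 2000, promoter_window = 2000,
    gene_meanlog = log(2000), gene_sdlog = 0.35, gene_min = 600, gene_max = 5000,
    region_gap_min = 300, region_gap_max = 1100,
    # transposable elements
    te_fraction = 0.25,
    te_classes = c(Gypsy = 0.35, Copia = 0.25, LINE = 0.15, SINE = 0.10, DNA = 0.15),
    te_len_min = 500, te_len_max = 5000,
    te_het_bias = 0.5,
    # background chromatin-state HMM truth (4 marks)
    hmm_truth = .default_hmm_truth(),
    background_resample = 0.03,
    # gene expression classes and promoter mark probabilities
    class_probs = c(high = 0.30, mid = 0.30, low = 0.25, none = 0.15),
    mark_probs = rbind(
      high = c(H3K4me3 = 0.85, H3K9ac = 0.85, H3K27me3 = 0.15),
      mid  = c(H3K4me3 = 0.55, H3K9ac = 0.55, H3K27me3 = 0.50),
      low  = c(H3K4me3 = 0.25, H3K9ac = 0.30, H3K27me3 = 0.45),
      none = c(H3K4me3 = 0.10, H3K9ac = 0.15, H3K27me3 = 0.35)
    ),
    bivalent_fraction = 0.10,
    # expression model (log2 FPKM)
    base_log2fpkm = c(high = 5, mid = 1.5, low = -2, none = NA),
    base_sd = 0.8,
    e_active = 3, e_repressive = 2,
    bivalent_dropout = 0.4,
    rep_sigma = 0.25, n_replicates = 5,
    # condition dynamics (CK -> NaCl)
    n_concordant = 300,
    concordant_lfc_min = 2, concordant_lfc_max = 3,
    antagonistic_co_change = 0.6,
    background_gain = c(H3K4me3 = 0.10, H3K9ac = 0.05, H3K27me3 = 0.08),
    background_loss = c(H3K4me3 = 0.04, H3K9ac = 0.12, H3K27me3 = 0.03),
    dynamics_coupling = 3,
    lfc_mark_effect = 0.9, lfc_z_effect = 0.25, lfc_noise_sd = 0.2,
    label_noise = 0,
    # reChIP and metabolites
    rechip_dropout = c(ab = 0.10, ba = 0.15),
    n_metab_pos = 622, n_metab_neg = 537,
    metab_frac_up = 0.25, metab_frac_down = 0.08
  )
  if (preset == "noisefree") {
    cfg$background_gain[] <- 0
    cfg$background_loss[] <- 0
    cfg$background_resample <- 0
    cfg$lfc_z_effect <- 0
    cfg$lfc_noise_sd <- 0.02
    cfg$rep_sigma <- 0.1
    cfg$rechip_dropout <- c(ab = 0, ba = 0)
    cfg$label_noise <- 0
  }
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown sim_config fields: ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  .validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

.default_hmm_truth <- function() {
  E <- rbind(
    c(0.90, 0.90, 0.05, 0.02),  # active TSS-like
    c(0.60, 0.30, 0.10, 0.02),  # transcription
    c(0.10, 0.80, 0.80, 0.02),  # bivalent (H3K9ac + H3K27me3)
    c(0.05, 0.05, 0.85, 0.05),  # polycomb
    c(0.02, 0.02, 0.10, 0.90),  # heterochromatin
    c(0.02, 0.02, 0.02, 0.02),  # quiescent
    c(0.70, 0.70, 0.05, 0.02)   # active intergenic
  )
  colnames(E) <- SIM_MARKS
  w <- c(0.05, 0.07, 0.05, 0.08, 0.35, 0.30, 0.10)
  w <- w / sum(w)
  K <- nrow(E)
  A <- 0.85 * diag(K) + 0.15 * matrix(w, K, K, byrow = TRUE)
  A <- A / rowSums(A)
  list(K = K, pi = w, A = A, E = E)
}

.validate_sim_config <- function(cfg) {
  probs <- c(cfg$class_probs, as.vector(cfg$mark_probs), cfg$bivalent_fraction,
             cfg$background_gain, cfg$background_loss, cfg$background_resample,
             cfg$rechip_dropout, cfg$metab_frac_up, cfg$metab_frac_down,
             cfg$label_noise, cfg$te_fraction, cfg$bivalent_dropout,
             cfg$antagonistic_co_change)
  if (any(probs < 0 | probs > 1)) stop("sim_config probabilities must lie in [0, 1]")
  if (abs(sum(cfg$class_probs) - 1) > 1e-9) stop("class_probs must sum to 1")
  if (any(cfg$background_gain + cfg$background_loss > 1)) {
    stop("background gain + loss rates must not exceed 1")
  }
  if (cfg$metab_frac_up + cfg$metab_frac_down > 1) stop("metabolite fractions exceed 1")
  ht <- cfg$hmm_truth
  if (abs(sum(ht$pi) - 1) > 1e-9 || any(abs(rowSums(ht$A) - 1) > 1e-9)) {
    stop("hmm_truth pi and transition rows must sum to 1")
  }
  invisible(cfg)
}

#' Simulate a synthetic epigenome with planted ground truth
#'
#' Builds a miniature genome end to end: gene models placed so that each
#' gene's promoter-plus-body region is disjoint from every other's; a
#' background chromatin-state path sampled from the configured HMM truth
#' over fixed-width bins, with heterochromatin biased onto transposable
#' elements; planted promoter/body peaks per gene per condition (including
#' a seeded bivalent subset carrying both H3K9ac and H3K27me3 over the
#' promoter); FPKM tables whose means couple multiplicatively to the
#' planted marks; a NaCl condition with planted gain/loss transitions and
#' coupled expression shifts; reChIP peak sets derived from the true
#' bivalent domains minus seeded dropout; and a metabolite table with known
#' differential classes. All planted per-gene mark statuses are exactly
#' re-derivable from the emitted peak files because planted peaks never
#' leave their own gene region.
#'
#' @param config A [sim_config()].
#' @param outdir Optional directory; when given, all files (GFF3, BED per
#'   mark and condition, reChIP BEDs, TE BED, FPKM TSV, metabolite TSV and
#'   truth tables) are written there.
#' @return A `sim_world` list: `layout`, `genes`, `te`, `peaks` (nested list
#'   peaks[[mark]][[condition]]), `rechip`, `expression`, `metabolites`,
#'   `truth`, `config`.
#' @export
simulate_epigenome <- function(config = sim_config(), outdir = NULL) {
  cfg <- config
  world <- withr::with_seed(cfg$seed, .simulate_impl(cfg))
  if (!is.null(outdir)) write_world(world, outdir)
  world
}

.simulate_impl <- function(cfg) {
  layout <- genome_layout(paste0("chr", seq_len(cfg$n_chrom)),
                          rep(cfg$chrom_length, cfg$n_chrom))
  bins <- bin_genome(layout, cfg$bin_size)
  genes <- .sim_place_genes(cfg, layout)
  te <- .sim_place_te(cfg, layout, genes)
  n_genes <- nrow(genes)

  # --- per-gene classes and CK mark states ------------------------------
  class <- sample(names(cfg$class_probs), n_genes, replace = TRUE,
                  prob = cfg$class_probs)
  bivalent <- rep(FALSE, n_genes)
  eligible <- which(class != "none")
  n_biv <- round(cfg$bivalent_fraction * n_genes)
  biv_idx <- sample(eligible, min(n_biv, length(eligible)))
  bivalent[biv_idx] <- TRUE
  class[biv_idx] <- "mid"

  mark_ck <- matrix(0L, n_genes, 3, dimnames = list(NULL, GENE_MARKS))
  for (m in GENE_MARKS) {
    mark_ck[, m] <- as.integer(stats::runif(n_genes) < cfg$mark_probs[class, m])
  }
  mark_ck[bivalent, "H3K9ac"] <- 1L
  mark_ck[bivalent, "H3K27me3"] <- 1L
  mark_ck[bivalent, "H3K4me3"] <- as.integer(stats::runif(sum(bivalent)) < 0.3)

  # --- condition dynamics ----------------------------------------------
  z <- stats::rnorm(n_genes)
  mark_na <- mark_ck
  planted <- rep(NA_character_, n_genes)  # concordance class label or NA
  lfc_true <- cfg$lfc_z_effect * z + stats::rnorm(n_genes, 0, cfg$lfc_noise_sd)

  # background gain/loss coupled to the latent stress response z
  for (m in GENE_MARKS) {
    s <- if (m == "H3K27me3") -cfg$dynamics_coupling else cfg$dynamics_coupling
    pg <- cfg$background_gain[[m]]
    pl <- cfg$background_loss[[m]]
    p_gain <- if (pg > 0) 2 * pg * stats::plogis(s * z) else rep(0, n_genes)
    p_loss <- if (pl > 0) 2 * pl * stats::plogis(-s * z) else rep(0, n_genes)
    u <- stats::runif(n_genes)
    gain <- mark_ck[, m] == 0 & u < pmin(p_gain, 1)
    loss <- mark_ck[, m] == 1 & u < pmin(p_loss, 1)
    mark_na[gain, m] <- 1L
    mark_na[loss, m] <- 0L
    eff <- if (m == "H3K27me3") -cfg$lfc_mark_effect else cfg$lfc_mark_effect
    lfc_true <- lfc_true + eff * (as.integer(gain) - as.integer(loss))
  }

  # planted concordant genes: forced clean transitions + coupled DE
  pool <- which(class != "none" & !bivalent)
  n_conc <- min(cfg$n_concordant, length(pool))
  conc_idx <- sample(pool, n_conc)
  classes6 <- CONCORDANCE_CLASSES
  assign6 <- rep(seq_len(nrow(classes6)), length.out = n_conc)
  noise_mask <- stats::runif(n_conc) < cfg$label_noise
  for (j in seq_len(n_conc)) {
    g <- conc_idx[j]
    cl <- classes6[assign6[j], ]
    # planted responders sit in the expressed tier so their shifts stay
    # measurable on the pseudocounted FPKM fold-change scale
    class[g] <- "high"
    mag <- stats::runif(1, cfg$concordant_lfc_min, cfg$concordant_lfc_max)
    lfc_true[g] <- if (cl$de_direction == "up") mag else -mag
    apply_change <- !noise_mask[j]
    if (apply_change) {
      if (cl$mark_status == "gain") {
        mark_ck[g, cl$mark] <- 0L; mark_na[g, cl$mark] <- 1L
      } else {
        mark_ck[g, cl$mark] <- 1L; mark_na[g, cl$mark] <- 0L
      }
      # antagonistic co-change between the bivalent pair under stress
      if (cl$mark %in% c("H3K9ac", "H3K27me3") &&
          stats::runif(1) < cfg$antagonistic_co_change) {
        other <- setdiff(c("H3K9ac", "H3K27me3"), cl$mark)
        if (cl$mark_status == "gain") {
          mark_ck[g, other] <- 1L; mark_na[g, other] <- 0L
        } else {
          mark_ck[g, other] <- 0L; mark_na[g, other] <- 1L
        }
      }
    }
    planted[g] <- paste0(cl$mark, "-", cl$mark_status, "/", cl$de_direction)
  }

  # --- background chromatin and bin matrices ---------------------------
  ht <- cfg$hmm_truth
  chrom_bins <- split(seq_len(nrow(bins)), factor(bins$chrom, levels = layout$chrom))
  sim <- simulate_hmm_sequence(ht$pi, ht$A, ht$E, lengths = lengths(chrom_bins),
                               seed = sample.int(.Machine$integer.max, 1))
  state_ck <- sim$states
  X_ck <- sim$X
  colnames(X_ck) <- SIM_MARKS

  # heterochromatin bias onto TE bins
  if (nrow(te) > 0 && cfg$te_het_bias > 0) {
    te_bin <- overlaps_any(bins, te)
    het <- which(te_bin & stats::runif(nrow(bins)) < cfg$te_het_bias)
    state_ck[het] <- 5L
    X_ck[het, ] <- matrix(stats::rbinom(length(het) * 4, 1, ht$E[5, ]),
                          ncol = 4, byrow = TRUE)
  }

  state_na <- state_ck
  X_na <- X_ck
  if (cfg$background_resample > 0) {
    res <- which(stats::runif(nrow(bins)) < cfg$background_resample)
    if (length(res)) {
      state_na[res] <- sample.int(ht$K, length(res), replace = TRUE, prob = ht$pi)
      X_na[res, ] <- matrix(stats::rbinom(length(res) * 4, 1,
                                          t(ht$E[state_na[res], , drop = FALSE])),
                            ncol = 4, byrow = TRUE)
    }
  }

  # --- clear gene regions, then plant gene marks ------------------------
  regions <- gene_regions(genes, layout, cfg$promoter_window)
  region_bins <- which(overlaps_any(bins, regions))
  X_ck[region_bins, ] <- 0L
  X_na[region_bins, ] <- 0L

  bin_offset <- c(0, cumsum(lengths(chrom_bins)))
  names(bin_offset) <- c(layout$chrom, "end")
  mark_extent <- function(g, m) {
    lo <- min(g$tss, g$tts); hi <- max(g$tss, g$tts)
    if (m == "H3K4me3") c(g$tss - 600, g$tss + 600)
    else if (m == "H3K9ac") c(g$tss - 400, g$tss + 400)
    else if (bivalent[g$idx]) c(g$tss - 400, g$tss + 400)  # promoter bivalency
    else if (g$strand == "+") c(lo, min(hi, lo + 1500))
    else c(max(lo, hi - 1500), hi)
  }
  genes$idx <- seq_len(n_genes)
  for (i in seq_len(n_genes)) {
    g <- genes[i, ]
    off <- bin_offset[[g$chrom]]
    for (m in GENE_MARKS) {
      if (mark_ck[i, m] == 0 && mark_na[i, m] == 0) next
      ext <- mark_extent(g, m)
      ext[1] <- max(ext[1], 0); ext[2] <- min(ext[2], cfg$chrom_length)
      b <- off + seq(floor(ext[1] / cfg$bin_size) + 1,
                     ceiling(ext[2] / cfg$bin_size))
      if (mark_ck[i, m] == 1) X_ck[b, m] <- 1L
      if (mark_na[i, m] == 1) X_na[b, m] <- 1L
    }
  }

  # --- peaks from bin runs ---------------------------------------------
  bins_to_peaks <- function(X, m) {
    on <- bins[X[, m] == 1, c("chrom", "start", "end")]
    if (nrow(on) == 0) {
      return(tibble::tibble(chrom = character(), start = numeric(),
                            end = numeric(), summit = numeric()))
    }
    pk <- merge_intervals(on, layout)
    pk$summit <- NA_real_
    pk
  }
  peaks <- purrr::map(stats::setNames(SIM_MARKS, SIM_MARKS), function(m) {
    list(CK = dplyr::mutate(bins_to_peaks(X_ck, m), mark = m, condition = "CK"),
         NaCl = dplyr::mutate(bins_to_peaks(X_na, m), mark = m, condition = "NaCl"))
  })

  # --- bivalent truth and reChIP ---------------------------------------
  biv_on <- bins[X_ck[, "H3K9ac"] == 1 & X_ck[, "H3K27me3"] == 1,
                 c("chrom", "start", "end")]
  biv_domains <- if (nrow(biv_on)) merge_intervals(biv_on, layout) else biv_on
  keep_ab <- stats::runif(nrow(biv_domains)) >= cfg$rechip_dropout[["ab"]]
  keep_ba <- stats::runif(nrow(biv_domains)) >= cfg$rechip_dropout[["ba"]]
  rechip <- list(ab = biv_domains[keep_ab, , drop = FALSE],
                 ba = biv_domains[keep_ba, , drop = FALSE])

  # --- expression tables ------------------------------------------------
  base <- cfg$base_log2fpkm[class] + stats::rnorm(n_genes, 0, cfg$base_sd)
  mu_ck <- base +
    log2(cfg$e_active) * (mark_ck[, "H3K4me3"] + mark_ck[, "H3K9ac"]) -
    log2(cfg$e_repressive) * mark_ck[, "H3K27me3"]
  mu_na <- mu_ck + lfc_true
  nrep <- cfg$n_replicates
  sample_fpkm <- function(mu) {
    vals <- matrix(0, n_genes, nrep)
    expressed <- class != "none"
    vals[expressed, ] <- 2^(mu[expressed] +
                              matrix(stats::rnorm(sum(expressed) * nrep, 0, cfg$rep_sigma),
                                     ncol = nrep))
    if (any(bivalent)) {  # variable-breadth regime: per-sample silencing
      drop <- matrix(stats::runif(n_genes * nrep) < cfg$bivalent_dropout, n_genes, nrep)
      drop[!bivalent, ] <- FALSE
      vals[drop] <- stats::runif(sum(drop), 0, 0.5)
    }
    round(vals, 4)
  }
  fpkm_ck <- sample_fpkm(mu_ck)
  fpkm_na <- sample_fpkm(mu_na)
  expression <- tibble::as_tibble(cbind(fpkm_ck, fpkm_na), .name_repair = "minimal")
  names(expression) <- c(paste0("CK_", seq_len(nrep)), paste0("NaCl_", seq_len(nrep)))
  expression <- dplyr::bind_cols(tibble::tibble(gene_id = genes$gene_id), expression)

  metabolites <- .sim_metabolites(cfg)

  status <- function(ck, na) {
    dplyr::case_when(ck == 0 & na == 0 ~ "absent", ck == 0 & na == 1 ~ "gain",
                     ck == 1 & na == 0 ~ "loss", TRUE ~ "stable")
  }
  truth_genes <- tibble::tibble(
    gene_id = genes$gene_id, class = class, bivalent = bivalent, z = z,
    lfc_true = lfc_true,
    de_direction = dplyr::case_when(lfc_true >= 1 ~ "up", lfc_true <= -1 ~ "down",
                                    TRUE ~ "none"),
    planted_class = planted
  )
  for (m in GENE_MARKS) {
    truth_genes[[paste0(m, "_ck")]] <- mark_ck[, m]
    truth_genes[[paste0(m, "_nacl")]] <- mark_na[, m]
    truth_genes[[paste0(m, "_status")]] <- status(mark_ck[, m], mark_na[, m])
  }
  truth <- list(
    genes = truth_genes,
    states = dplyr::mutate(bins, state_ck = state_ck, state_nacl = state_na),
    bivalent_genes = genes$gene_id[bivalent],
    bivalent_domains = biv_domains,
    rechip_kept = tibble::tibble(domain = seq_len(nrow(biv_domains)),
                                 kept_ab = keep_ab, kept_ba = keep_ba),
    metabolites = metabolites[c("metabolite_id", "planted")]
  )
  genes$idx <- NULL
  list(layout = layout, genes = genes, te = te, peaks = peaks, rechip = rechip,
       expression = expression, metabolites = metabolites[names(metabolites) != "planted"],
       truth = truth, config = cfg)
}

.sim_place_genes <- function(cfg, layout) {
  quota <- rep(floor(cfg$n_genes / cfg$n_chrom), cfg$n_chrom)
  extra <- cfg$n_genes - sum(quota)
  if (extra > 0) quota[seq_len(extra)] <- quota[seq_len(extra)] + 1
  w <- cfg$promoter_window
  out <- purrr::map_dfr(seq_len(cfg$n_chrom), function(ci) {
    ch <- layout$chrom[ci]; len <- layout$length[ci]
    pos <- 0; rows <- list()
    for (k in seq_len(quota[ci])) {
      gap <- stats::runif(1, cfg$region_gap_min, cfg$region_gap_max)
      glen <- round(pmin(pmax(stats::rlnorm(1, cfg$gene_meanlog, cfg$gene_sdlog),
                              cfg$gene_min), cfg$gene_max))
      rs <- round(pos + gap)
      re <- rs + w + glen
      if (re + cfg$region_gap_min > len) break
      strand <- sample(c("+", "-"), 1)
      if (strand == "+") {
        g_lo <- rs + w; g_hi <- re
      } else {
        g_lo <- rs; g_hi <- re - w
      }
      rows[[k]] <- tibble::tibble(chrom = ch, strand = strand,
                                  start = g_lo, end = g_hi)
      pos <- re
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(out) < cfg$n_genes) {
    warning(sprintf("placed %d of %d requested genes before running out of space",
                    nrow(out), cfg$n_genes))
  }
  out$gene_id <- sprintf("gene%05d", seq_len(nrow(out)))
  out$tss <- ifelse(out$strand == "+", out$start, out$end)
  out$tts <- ifelse(out$strand == "+", out$end, out$start)
  # exon/CDS structure: 60% single exon, otherwise two exons with an intron
  structure_one <- function(i) {
    g <- out[i, ]
    lo <- g$start; hi <- g$end; glen <- hi - lo
    if (stats::runif(1) < 0.6 || glen < 1500) {
      ex <- tibble::tibble(start = lo, end = hi)
    } else {
      ilen <- round(stats::runif(1, 150, min(800, glen - 600)))
      istart <- round(lo + stats::runif(1, 250, glen - ilen - 250))
      ex <- tibble::tibble(start = c(lo, istart + ilen), end = c(istart, hi))
    }
    u5 <- round(stats::runif(1, 80, 250))
    u3 <- round(stats::runif(1, 100, 300))
    cds_span <- if (g$strand == "+") c(lo + u5, hi - u3) else c(lo + u3, hi - u5)
    cd <- intersect_intervals(dplyr::mutate(ex, chrom = g$chrom),
                              tibble::tibble(chrom = g$chrom, start = cds_span[1],
                                             end = cds_span[2]))
    utr <- .derive_utrs(ex, cd[c("start", "end")], g$strand)
    list(exons = ex, cds = cd[c("start", "end")], utr5 = utr$utr5, utr3 = utr$utr3)
  }
  parts <- purrr::map(seq_len(nrow(out)), structure_one)
  out$exons <- purrr::map(parts, "exons")
  out$cds <- purrr::map(parts, "cds")
  out$utr5 <- purrr::map(parts, "utr5")
  out$utr3 <- purrr::map(parts, "utr3")
  out[c("gene_id", "chrom", "strand", "start", "end", "tss", "tts",
        "exons", "cds", "utr5", "utr3")]
}

.sim_place_te <- function(cfg, layout, genes) {
  if (cfg$te_fraction <= 0) {
    return(tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          class = character()))
  }
  regions <- gene_regions(genes, layout, cfg$promoter_window)
  out <- purrr::map_dfr(seq_len(nrow(layout)), function(ci) {
    ch <- layout$chrom[ci]; len <- layout$length[ci]
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    gaps <- .from_ir(IRanges::gaps(IRanges::reduce(.to_ir(reg)),
                                   start = 1L, end = as.integer(len)), ch)
    rows <- list(); k <- 0
    for (i in seq_len(nrow(gaps))) {
      pos <- gaps$start[i]
      while (gaps$end[i] - pos > cfg$te_len_min) {
        if (stats::runif(1) < cfg$te_fraction / 0.5) {
          tl <- round(stats::runif(1, cfg$te_len_min,
                                   min(cfg$te_len_max, gaps$end[i] - pos)))
          k <- k + 1
          rows[[k]] <- tibble::tibble(chrom = ch, start = pos, end = pos + tl)
          pos <- pos + tl + round(stats::runif(1, 100, 1000))
        } else {
          pos <- pos + round(stats::runif(1, 500, 2000))
        }
      }
    }
    dplyr::bind_rows(rows)
  })
  if (nrow(out) > 0) {
    out$class <- sample(names(cfg$te_classes), nrow(out), replace = TRUE,
                        prob = cfg$te_classes)
  } else {
    out$class <- character(0)
  }
  out
}

.sim_metabolites <- function(cfg) {
  one_mode <- function(mode, n) {
    n_up <- round(cfg$metab_frac_up * n)
    n_down <- round(cfg$metab_frac_down * n)
    n_ns <- n - n_up - n_down
    planted <- sample(c(rep("up", n_up), rep("down", n_down), rep("ns", n_ns)))
    vip <- fc <- p <- numeric(n)
    up <- planted == "up"; down <- planted == "down"; ns <- planted == "ns"
    vip[up] <- stats::runif(sum(up), 1.05, 3)
    fc[up] <- stats::runif(sum(up), 1.6, 5)
    p[up] <- stats::runif(sum(up), 1e-4, 0.049)
    vip[down] <- stats::runif(sum(down), 1.05, 3)
    fc[down] <- stats::runif(sum(down), 0.1, 0.6)
    p[down] <- stats::runif(sum(down), 1e-4, 0.049)
    # null rows fail exactly one randomly chosen gate
    fail <- sample(c("vip", "fc", "p"), sum(ns), replace = TRUE)
    vip[ns] <- ifelse(fail == "vip", stats::runif(sum(ns), 0, 0.99),
                      stats::runif(sum(ns), 1.05, 3))
    fc[ns] <- ifelse(fail == "fc", stats::runif(sum(ns), 0.68, 1.49),
                     ifelse(stats::runif(sum(ns)) < 0.5,
                            stats::runif(sum(ns), 1.6, 5), stats::runif(sum(ns), 0.1, 0.6)))
    p[ns] <- ifelse(fail == "p", stats::runif(sum(ns), 0.051, 1),
                    stats::runif(sum(ns), 1e-4, 0.049))
    tibble::tibble(metabolite_id = sprintf("M_%s_%04d", mode, seq_len(n)),
                   ion_mode = mode, VIP = round(vip, 4), FC = round(fc, 4),
                   pvalue = signif(p, 6), planted = planted)
  }
  dplyr::bind_rows(one_mode("pos", cfg$n_metab_pos), one_mode("neg", cfg$n_metab_neg))
}

#' Write a simulated world to disk in standard formats
#'
#' Emits `genome.tsv`, `genes.gff3`, `te.bed`, one BED per mark and
#' condition under `peaks/`, `rechip_AB.bed` / `rechip_BA.bed`,
#' `expression.tsv`, `metabolites.tsv` and the truth tables under `truth/`.
#' Output is byte-identical for a fixed configuration seed.
#'
#' @param world A [simulate_epigenome()] result.
#' @param outdir Output directory (created if needed).
#' @export
write_world <- function(world, outdir) {
  dir.create(file.path(outdir, "peaks"), recursive = TRUE, showWarnings = FALSE)
  write_tsv_stable(world$layout, file.path(outdir, "genome.tsv"))
  write_gff3(world$genes, file.path(outdir, "genes.gff3"))
  te <- world$te
  if (nrow(te)) te$name <- te$class
  write_bed(te[c("chrom", "start", "end", if (nrow(te)) "name")],
            file.path(outdir, "te.bed"))
  for (m in names(world$peaks)) {
    for (cond in names(world$peaks[[m]])) {
      write_bed(world$peaks[[m]][[cond]],
                file.path(outdir, "peaks", paste0(m, "_", cond, ".bed")))
    }
  }
  write_bed(world$rechip$ab, file.path(outdir, "rechip_AB.bed"))
  write_bed(world$rechip$ba, file.path(outdir, "rechip_BA.bed"))
  write_tsv_stable(world$expression, file.path(outdir, "expression.tsv"))
  write_tsv_stable(world$metabolites, file.path(outdir, "metabolites.tsv"))
  truth_report(world$truth, file.path(outdir, "truth"))
  invisible(outdir)
}

#' Write the planted ground truth as TSV files
#'
#' Machine-readable truth for every recovery check: per-gene classes, mark
#' states and statuses, true expression shifts, the true per-bin state path,
#' planted bivalent genes and domains, reChIP dropout bookkeeping and
#' metabolite classes.
#'
#' @param truth The `truth` element of a [simulate_epigenome()] world.
#' @param outdir Output directory (created if needed).
#' @export
truth_report <- function(truth, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_tsv_stable(truth$genes, file.path(outdir, "genes.tsv"))
  write_tsv_stable(truth$states, file.path(outdir, "states.tsv"))
  write_tsv_stable(tibble::tibble(gene_id = truth$bivalent_genes),
                   file.path(outdir, "bivalent_genes.tsv"))
  write_tsv_stable(truth$bivalent_domains, file.path(outdir, "bivalent_domains.tsv"))
  write_tsv_stable(truth$rechip_kept, file.path(outdir, "rechip_kept.tsv"))
  write_tsv_stable(truth$metabolites, file.path(outdir, "metabolites.tsv"))
  invisible(outdir)
}
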