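#' Default pipeline configuration
#'
#' A single list holding every threshold, window and seed used by any stage,
#' so a run's parameters are auditable in one place. Written to and read
#' from YAML.
#'
#' @param seed Master seed.
#' @param outdir Run directory.
#' @param ... Named overrides (nested lists are replaced wholesale).
#' @return A `run_config` list.
#' @export
pipeline_config <- function(seed = 1, outdir = "chromdyn_run", ...) {
  cfg <- list(
    seed = seed,
    outdir = outdir,
    simulate = list(preset = "default"),
    thresholds = list(
      promoter_window = 2000, bin_size = 200,
      hmm_k = 13, n_restarts = 3, hmm_tol = 1e-4, hmm_max_iter = 500,
      lfc_min = 1, fdr_max = 0.05, pseudocount = 1,
      min_jaccard_stable = 0.25, pseudocount_bp = 100,
      min_overlap_bp = 1, n_perm = 200,
      breadth_threshold = 1, n_random_genes = 10000,
      vip_min = 1.0, fc_up = 1.5, fc_down = 0.667, p_max = 0.05
    ),
    marks = c("H3K4me3", "H3K9ac", "H3K27me3", "H3K9me2"),
    gene_marks = c("H3K4me3", "H3K9ac", "H3K27me3"),
    conditions = c("CK", "NaCl")
  )
  dots <- list(...)
  for (nm in names(dots)) cfg[[nm]] <- dots[[nm]]
  structure(cfg, class = "run_config")
}

#' Run the analysis pipeline
#'
#' Orchestrates the stages in dependency order behind subcommands:
#' `simulate` (write the synthetic world), `annotate` (feature partition,
#' peak annotation, marked genes, Venn, coverage, lengths, metagene),
#' `states` (binarize, HMM fit, decoding, state annotation and CK/NaCl
#' state dynamics), `bivalent` (domain calls, reChIP validation,
#' permutation null), `expression` (strata, marked-vs-all rank tests,
#' breadth), `dynamics` (DE, gain/loss, concordance, promoter rates,
#' correlations, variability, metabolites) or `all`. Every stage reads its
#' inputs from files under the run directory and writes TSV/JSON reports
#' carrying the configuration hash and seed; reruns with the same
#' configuration are bit-identical for deterministic stages. A stage whose
#' upstream files are missing fails fast naming the missing role.
#'
#' @param stage One of `simulate`, `annotate`, `states`, `bivalent`,
#'   `expression`, `dynamics`, `all`.
#' @param config A [pipeline_config()] (or path to a YAML file of one).
#' @return Invisibly, the run directory.
#' @export
run_pipeline <- function(stage = c("all", "simulate", "annotate", "states",
                                   "bivalent", "expression", "dynamics"),
                         config = pipeline_config()) {
  stage <- match.arg(stage)
  if (is.character(config)) config <- yaml::yaml.load_file(config)
  cfg <- config
  outdir <- cfg$outdir
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  cfg_path <- file.path(outdir, "config.yaml")
  yaml::write_yaml(cfg[setdiff(names(cfg), "outdir")], cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  stages <- if (stage == "all") {
    c("simulate", "annotate", "states", "bivalent", "expression", "dynamics")
  } else stage
  for (s in stages) {
    .log_json(stage = s, event = "start")
    switch(s,
           simulate = .stage_simulate(cfg),
           annotate = .stage_annotate(cfg, cfg_hash),
           states = .stage_states(cfg, cfg_hash),
           bivalent = .stage_bivalent(cfg, cfg_hash),
           expression = .stage_expression(cfg, cfg_hash),
           dynamics = .stage_dynamics(cfg, cfg_hash))
    .log_json(stage = s, event = "done")
  }
  invisible(outdir)
}

.log_json <- function(...) {
  message(jsonlite::toJSON(list(...), auto_unbox = TRUE))
}

.need_file <- function(path, role, stage_hint) {
  if (!file.exists(path)) {
    stop(sprintf("missing input '%s' (%s); run the '%s' stage first",
                 path, role, stage_hint))
  }
  path
}

.load_world_inputs <- function(cfg) {
  dd <- file.path(cfg$outdir, "data")
  layout_path <- .need_file(file.path(dd, "genome.tsv"), "genome layout", "simulate")
  lay_tab <- readr::read_tsv(layout_path, show_col_types = FALSE, progress = FALSE)
  layout <- genome_layout(lay_tab$chrom, lay_tab$length)
  genes <- read_gff3(.need_file(file.path(dd, "genes.gff3"), "gene models", "simulate"),
                     layout)
  peaks <- list()
  for (m in cfg$marks) {
    peaks[[m]] <- list()
    for (cond in cfg$conditions) {
      p <- .need_file(file.path(dd, "peaks", paste0(m, "_", cond, ".bed")),
                      paste0(m, " ", cond, " peaks"), "simulate")
      peaks[[m]][[cond]] <- read_bed(p, layout, mark = m, condition = cond)
    }
  }
  te_path <- file.path(dd, "te.bed")
  te <- if (file.exists(te_path)) {
    x <- read_bed(te_path, layout)
    if ("name" %in% names(x)) x$class <- x$name
    x
  }
  expr <- read_expression(.need_file(file.path(dd, "expression.tsv"),
                                     "expression table", "simulate"))
  list(layout = layout, genes = genes, peaks = peaks, te = te, expr = expr, dd = dd)
}

.report <- function(obj, outdir, name, cfg_hash, seed) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  obj$config_hash <- cfg_hash
  obj$seed <- seed
  jsonlite::write_json(obj, file.path(outdir, paste0(name, ".json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

.stage_simulate <- function(cfg) {
  sim_args <- cfg$simulate
  sim_args$seed <- cfg$seed
  scfg <- do.call(sim_config, sim_args)
  simulate_epigenome(scfg, outdir = file.path(cfg$outdir, "data"))
}

.stage_annotate <- function(cfg, cfg_hash) {
  w <- .load_world_inputs(cfg)
  th <- cfg$thresholds
  sd_dir <- file.path(cfg$outdir, "annotate")
  dir.create(sd_dir, recursive = TRUE, showWarnings = FALSE)
  index <- build_feature_index(w$genes, w$layout, th$promoter_window)
  summary <- list()
  marked_sets <- list()
  for (m in cfg$marks) {
    for (cond in cfg$conditions) {
      pk <- w$peaks[[m]][[cond]]
      ann <- assign_peaks(pk, index)
      dist <- feature_distribution(ann)
      write_tsv_stable(dist, file.path(sd_dir, paste0("featdist_", m, "_", cond, ".tsv")))
      hist <- peak_length_histogram(pk, c(0, 200, 700, 1500, Inf))
      mg <- marked_genes(pk, w$genes, w$layout, th$promoter_window)
      if (cond == "CK") marked_sets[[m]] <- mg
      summary[[paste0(m, "_", cond)]] <- list(
        n_peaks = nrow(pk),
        genome_coverage = genome_coverage(pk, w$layout),
        n_marked_genes = length(mg),
        promoter_fraction = dist$fraction[dist$feature == "promoter"],
        peaks_200_700 = hist$n[2] / max(1, sum(hist$n))
      )
    }
  }
  venn <- multiway_venn(marked_sets[cfg$gene_marks])
  write_tsv_stable(venn, file.path(sd_dir, "venn_marked_genes.tsv"))
  for (m in cfg$gene_marks) {
    prof <- metagene_profile(w$peaks[[m]][["CK"]], w$genes, w$layout)
    write_tsv_stable(tibble::as_tibble(prof), file.path(sd_dir, paste0("metagene_", m, ".tsv")))
  }
  .report(summary, sd_dir, "summary", cfg_hash, cfg$seed)
}

.stage_states <- function(cfg, cfg_hash) {
  w <- .load_world_inputs(cfg)
  th <- cfg$thresholds
  sd_dir <- file.path(cfg$outdir, "states")
  dir.create(sd_dir, recursive = TRUE, showWarnings = FALSE)
  bins <- bin_genome(w$layout, th$bin_size)
  index <- build_feature_index(w$genes, w$layout, th$promoter_window)
  segs <- list()
  model <- NULL
  for (cond in cfg$conditions) {
    bx <- binarize_marks(purrr::map(w$peaks, cond), bins)
    if (is.null(model)) {
      model <- fit_hmm(bx, K = th$hmm_k, seed = cfg$seed,
                       n_restarts = th$n_restarts, tol = th$hmm_tol,
                       max_iter = th$hmm_max_iter)
      write_hmm_json(model, file.path(sd_dir, "hmm_model.json"))
    }
    seg <- decode_states(bx, model)
    segs[[cond]] <- seg
    write_segmentation_bed(seg, file.path(sd_dir, paste0("segmentation_", cond, ".bed")))
    ann <- annotate_states(seg, w$layout, index = index, te = w$te,
                           expr = w$expr, genes = w$genes,
                           promoter_window = th$promoter_window)
    write_tsv_stable(ann$states, file.path(sd_dir, paste0("state_summary_", cond, ".tsv")))
    write_tsv_stable(ann$feature_enrichment,
                     file.path(sd_dir, paste0("state_features_", cond, ".tsv")))
    if (!is.null(ann$te_enrichment)) {
      write_tsv_stable(ann$te_enrichment,
                       file.path(sd_dir, paste0("state_te_", cond, ".tsv")))
    }
  }
  dyn <- state_dynamics(segs[[1]], segs[[2]])
  write_tsv_stable(dyn$transitions, file.path(sd_dir, "state_transitions.tsv"))
  .report(list(K = model$K, loglik = model$loglik,
               fraction_dynamic = dyn$fraction_dynamic),
          sd_dir, "summary", cfg_hash, cfg$seed)
}

.stage_bivalent <- function(cfg, cfg_hash) {
  w <- .load_world_inputs(cfg)
  th <- cfg$thresholds
  sd_dir <- file.path(cfg$outdir, "bivalent")
  dir.create(sd_dir, recursive = TRUE, showWarnings = FALSE)
  biv <- call_bivalent(w$peaks[["H3K9ac"]][["CK"]], w$peaks[["H3K27me3"]][["CK"]],
                       w$layout, min_overlap_bp = th$min_overlap_bp,
                       genes = w$genes, promoter_window = th$promoter_window)
  write_bed(biv$domains, file.path(sd_dir, "bivalent_domains.bed"))
  rc_ab <- read_bed(.need_file(file.path(w$dd, "rechip_AB.bed"), "reChIP A->B", "simulate"),
                    w$layout)
  rc_ba <- read_bed(.need_file(file.path(w$dd, "rechip_BA.bed"), "reChIP B->A", "simulate"),
                    w$layout)
  val <- validate_rechip(biv, rc_ab, rc_ba, w$layout,
                         min_overlap_bp = th$min_overlap_bp, genes = w$genes,
                         promoter_window = th$promoter_window)
  write_tsv_stable(val, file.path(sd_dir, "rechip_validation.tsv"))
  perm <- permutation_null(w$peaks[["H3K9ac"]][["CK"]], w$peaks[["H3K27me3"]][["CK"]],
                           w$layout, n_perm = th$n_perm, seed = cfg$seed,
                           min_overlap_bp = th$min_overlap_bp)
  .report(list(n_domains = nrow(biv$domains), frac_H3K9ac = biv$frac_a,
               frac_H3K27me3 = biv$frac_b, n_genes = length(biv$genes),
               rechip_frac_both = val$frac_both,
               permutation_p = perm$p_value),
          sd_dir, "summary", cfg_hash, cfg$seed)
}

.stage_expression <- function(cfg, cfg_hash) {
  w <- .load_world_inputs(cfg)
  th <- cfg$thresholds
  sd_dir <- file.path(cfg$outdir, "expression")
  dir.create(sd_dir, recursive = TRUE, showWarnings = FALSE)
  cats <- categorize_expression(w$expr, condition = "CK")
  write_tsv_stable(cats, file.path(sd_dir, "expression_categories.tsv"))
  breadth <- expression_breadth(w$expr, th$breadth_threshold)
  write_tsv_stable(breadth, file.path(sd_dir, "expression_breadth.tsv"))
  summary <- list()
  all_vals <- cats$fpkm
  for (m in cfg$gene_marks) {
    mg <- marked_genes(w$peaks[[m]][["CK"]], w$genes, w$layout, th$promoter_window)
    comp <- mark_by_category(mg, cats)
    write_tsv_stable(comp, file.path(sd_dir, paste0("categories_", m, ".tsv")))
    rc <- rank_compare(cats$fpkm[cats$gene_id %in% mg], all_vals, mode = "normal")
    summary[[m]] <- list(n_marked = length(mg),
                         median_marked = rc$median_x, median_all = rc$median_y,
                         wilcoxon_p = rc$p_value)
  }
  rnd <- sample_random_genes(cats$gene_id,
                             n = min(th$n_random_genes, nrow(cats)), seed = cfg$seed)
  summary$random_set_size <- length(rnd)
  .report(summary, sd_dir, "summary", cfg_hash, cfg$seed)
}

.stage_dynamics <- function(cfg, cfg_hash) {
  w <- .load_world_inputs(cfg)
  th <- cfg$thresholds
  sd_dir <- file.path(cfg$outdir, "dynamics")
  dir.create(sd_dir, recursive = TRUE, showWarnings = FALSE)
  index <- build_feature_index(w$genes, w$layout, th$promoter_window)
  de <- simple_de(w$expr, cfg$conditions[1], cfg$conditions[2], th$pseudocount)
  de <- call_de(de, th$lfc_min, th$fdr_max)
  write_tsv_stable(de, file.path(sd_dir, "de_table.tsv"))
  dynamics <- list()
  variability <- list()
  for (m in cfg$gene_marks) {
    dynamics[[m]] <- mark_gain_loss(w$peaks[[m]][["CK"]], w$peaks[[m]][["NaCl"]],
                                    w$genes, w$layout, th$promoter_window,
                                    th$min_jaccard_stable, th$pseudocount_bp)
    write_tsv_stable(dynamics[[m]], file.path(sd_dir, paste0("gain_loss_", m, ".tsv")))
  }
  for (m in cfg$marks) {
    variability[[m]] <- variability_score(w$peaks[[m]][["CK"]], w$peaks[[m]][["NaCl"]])$score
  }
  conc <- concordance(de, dynamics)
  write_tsv_stable(conc$classes[setdiff(names(conc$classes), "genes")],
                   file.path(sd_dir, "concordance_classes.tsv"))
  write_tsv_stable(conc$coverage, file.path(sd_dir, "concordance_coverage.tsv"))
  corr <- fc_correlation(dynamics, de)
  write_tsv_stable(corr, file.path(sd_dir, "fc_correlations.tsv"))
  prom_rates <- list()
  for (i in seq_len(nrow(conc$classes))) {
    cl <- conc$classes[i, ]
    gl <- cl$genes[[1]]
    if (length(gl) == 0) next
    pr <- if (cl$mark_status == "gain") {
      promoter_rate(gl, w$peaks[[cl$mark]][["NaCl"]], w$peaks[[cl$mark]][["CK"]],
                    index, w$genes, w$layout, th$promoter_window)
    } else {
      promoter_rate(gl, w$peaks[[cl$mark]][["CK"]], w$peaks[[cl$mark]][["NaCl"]],
                    index, w$genes, w$layout, th$promoter_window)
    }
    prom_rates[[cl$class]] <- pr$promoter_rate_peaks
  }
  metab <- filter_metabolites(
    read_metabolite_table(.need_file(file.path(w$dd, "metabolites.tsv"),
                                     "metabolite table", "simulate")),
    th$vip_min, th$fc_up, th$fc_down, th$p_max)
  msum <- metabolite_summary(metab)
  write_tsv_stable(msum, file.path(sd_dir, "metabolite_summary.tsv"))
  .report(list(n_up = sum(de$direction == "up"), n_down = sum(de$direction == "down"),
               coverage_up = conc$coverage$fraction[1],
               coverage_down = conc$coverage$fraction[2],
               promoter_rates = prom_rates,
               variability = variability,
               correlations = stats::setNames(as.list(corr$r),
                                              paste(corr$var1, corr$var2, sep = "_vs_"))),
          sd_dir, "summary", cfg_hash, cfg$seed)
}
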