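#' Read a BED or narrowPeak file into a peak tibble
#'
#' Accepts BED3/BED6 and 10-column narrowPeak. For narrowPeak the 10th column
#' is the summit offset relative to `start`; an offset of -1 (no summit) is
#' stored as `NA`. Every malformed line is rejected with its line number;
#' there are no partial silent loads.
#'
#' @param path Path to a tab-separated BED-like file.
#' @param layout A [genome_layout()]; every interval must fall inside it and
#'   chromosome names must match exactly (no "chr" normalisation).
#' @param mark,condition Optional labels recorded as columns (e.g. the histone
#'   mark and the experimental condition the peaks belong to).
#' @return A tibble with columns `chrom`, `start`, `end`, `summit` (absolute
#'   bp or `NA`), plus `name`/`score` when present and `mark`/`condition` when
#'   given, sorted by (chrom, start) in layout order.
#' @export
read_bed <- function(path, layout, mark = NULL, condition = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    out <- tibble::tibble(chrom = character(), start = numeric(), end = numeric(),
                          summit = numeric())
    if (!is.null(mark)) out$mark <- character(0)
    if (!is.null(condition)) out$condition <- character(0)
    return(out)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncol <- lengths(fields)
  if (any(ncol < 3)) {
    stop(sprintf("%s line %d: fewer than 3 tab-separated columns", path,
                 which(ncol < 3)[1]))
  }
  get_col <- function(i) vapply(fields, function(f) if (length(f) >= i) f[i] else NA_character_, "")
  chrom <- get_col(1)
  start <- .parse_int(get_col(2), path, "start")
  end <- .parse_int(get_col(3), path, "end")
  bad <- which(!chrom %in% layout$chrom)
  if (length(bad)) stop(sprintf("%s line %d: unknown chromosome '%s'", path, bad[1], chrom[bad[1]]))
  bad <- which(start >= end)
  if (length(bad)) stop(sprintf("%s line %d: start >= end", path, bad[1]))
  len <- .layout_len(layout, chrom)
  bad <- which(start < 0 | end > len)
  if (length(bad)) stop(sprintf("%s line %d: interval outside chromosome bounds", path, bad[1]))
  out <- tibble::tibble(chrom = chrom, start = start, end = end)
  if (all(ncol >= 10)) {
    off <- .parse_int(get_col(10), path, "summit offset")
    out$summit <- ifelse(off < 0, NA_real_, start + off)
    bad <- which(!is.na(out$summit) & out$summit >= end)
    if (length(bad)) stop(sprintf("%s line %d: summit outside peak", path, bad[1]))
  } else {
    out$summit <- NA_real_
  }
  if (all(ncol >= 4)) out$name <- get_col(4)
  if (all(ncol >= 5)) out$score <- suppressWarnings(as.numeric(get_col(5)))
  if (!is.null(mark)) out$mark <- mark
  if (!is.null(condition)) out$condition <- condition
  .sort_intervals(out, layout)
}

.parse_int <- function(x, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v != floor(v))
  if (length(bad)) {
    stop(sprintf("%s line %d: non-integer %s '%s'", path, bad[1], what, x[bad[1]]))
  }
  v
}

#' Write intervals as BED
#'
#' Coordinates round-trip bit-exactly through [read_bed()] for valid inputs.
#'
#' @param x Interval tibble with `chrom`, `start`, `end` and optionally `name`.
#' @param path Output path.
#' @export
write_bed <- function(x, path) {
  cols <- c("chrom", "start", "end")
  if ("name" %in% names(x)) cols <- c(cols, "name")
  lines <- do.call(paste, c(lapply(cols, function(cc) {
    v <- x[[cc]]
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE) else as.character(v)
  }), sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Parses gene/mRNA/exon/CDS features. GFF3 1-based inclusive coordinates are
#' converted to 0-based half-open at this boundary. When a gene has several
#' mRNAs the first one in file order is used. 5'/3' UTR segments are derived
#' as exon minus CDS on the strand-appropriate side; genes without CDS keep
#' all exonic bases as coding exon downstream (see [build_feature_index()]).
#'
#' @param path GFF3 file path.
#' @param layout A [genome_layout()].
#' @return A tibble of gene models: `gene_id`, `chrom`, `strand`, `start`,
#'   `end` (gene span, 0-based half-open), `tss`, `tts` (strand-aware anchor
#'   positions), and list-columns `exons`, `cds`, `utr5`, `utr3` of interval
#'   tibbles.
#' @export
read_gff3 <- function(path, layout) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  keep <- nzchar(lines) & !startsWith(lines, "#")
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != 9)
  if (length(bad)) stop(sprintf("%s line %d: expected 9 GFF3 columns", path, lineno[bad[1]]))
  f <- function(i) vapply(fields, `[`, "", i)
  tab <- tibble::tibble(
    chrom = f(1), type = f(3),
    start = .parse_int(f(4), path, "start") - 1,  # to 0-based half-open
    end = .parse_int(f(5), path, "end"),
    strand = f(7), attr = f(9), line = lineno
  )
  tab <- tab[tab$type %in% c("gene", "mRNA", "exon", "CDS"), , drop = FALSE]
  tab$id <- .gff_attr(tab$attr, "ID")
  tab$parent <- .gff_attr(tab$attr, "Parent")

  genes <- tab[tab$type == "gene", , drop = FALSE]
  if (nrow(genes) == 0) {
    return(tibble::tibble(gene_id = character(), chrom = character(),
                          strand = character(), start = numeric(), end = numeric(),
                          tss = numeric(), tts = numeric(),
                          exons = list(), cds = list(), utr5 = list(), utr3 = list()))
  }
  bad <- which(!genes$strand %in% c("+", "-"))
  if (length(bad)) stop(sprintf("%s line %d: gene without strand", path, genes$line[bad[1]]))
  bad <- which(!genes$chrom %in% layout$chrom)
  if (length(bad)) stop(sprintf("%s line %d: unknown chromosome '%s'", path,
                                genes$line[bad[1]], genes$chrom[bad[1]]))
  .check_intervals(genes, layout, "gene")

  mrna <- tab[tab$type == "mRNA", , drop = FALSE]
  parts <- tab[tab$type %in% c("exon", "CDS"), , drop = FALSE]
  # first mRNA per gene, in file order
  first_mrna <- mrna[!duplicated(mrna$parent), , drop = FALSE]
  mrna_of_gene <- stats::setNames(first_mrna$id, first_mrna$parent)

  out <- purrr::map_dfr(seq_len(nrow(genes)), function(i) {
    g <- genes[i, ]
    mid <- unname(mrna_of_gene[g$id])
    if (is.na(mid)) mid <- character(0)
    own <- parts[parts$parent %in% c(mid, g$id), , drop = FALSE]
    bad <- which(own$start < g$start | own$end > g$end | own$chrom != g$chrom)
    if (length(bad)) {
      stop(sprintf("%s line %d: child feature outside parent gene span", path, own$line[bad[1]]))
    }
    ex <- own[own$type == "exon", c("start", "end")]
    cd <- own[own$type == "CDS", c("start", "end")]
    if (nrow(ex) == 0) ex <- g[, c("start", "end")]  # exonless gene: whole span
    ex <- dplyr::arrange(ex, .data$start)
    cd <- dplyr::arrange(cd, .data$start)
    utr <- .derive_utrs(ex, cd, g$strand)
    tibble::tibble(
      gene_id = g$id, chrom = g$chrom, strand = g$strand,
      start = g$start, end = g$end,
      tss = if (g$strand == "+") g$start else g$end,
      tts = if (g$strand == "+") g$end else g$start,
      exons = list(tibble::as_tibble(ex)), cds = list(tibble::as_tibble(cd)),
      utr5 = list(utr$utr5), utr3 = list(utr$utr3)
    )
  })
  .sort_intervals(out, layout)
}

.gff_attr <- function(attr, key) {
  pat <- paste0("(^|;)", key, "=([^;]+)")
  m <- regmatches(attr, regexpr(pat, attr))
  out <- rep(NA_character_, length(attr))
  hit <- regexpr(pat, attr) > 0
  out[hit] <- sub(pat, "\\2", m)
  out
}

# exon minus CDS, split into 5' and 3' sides by strand.
.derive_utrs <- function(ex, cd, strand) {
  empty <- tibble::tibble(start = numeric(), end = numeric())
  if (nrow(cd) == 0) return(list(utr5 = empty, utr3 = empty))
  ire <- .to_ir(ex)
  irc <- .to_ir(cd)
  diff <- IRanges::setdiff(ire, irc)
  if (length(diff) == 0) return(list(utr5 = empty, utr3 = empty))
  d <- tibble::tibble(start = as.numeric(IRanges::start(diff)) - 1,
                      end = as.numeric(IRanges::end(diff)))
  cds_lo <- min(cd$start); cds_hi <- max(cd$end)
  before <- d[d$end <= cds_lo, , drop = FALSE]
  after <- d[d$start >= cds_hi, , drop = FALSE]
  if (strand == "+") list(utr5 = before, utr3 = after) else list(utr5 = after, utr3 = before)
}

#' Write gene models as GFF3
#' @param genes Gene-model tibble as returned by [read_gff3()].
#' @param path Output path.
#' @export
write_gff3 <- function(genes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  for (i in seq_len(nrow(genes))) {
    g <- genes[i, ]
    row <- function(type, s, e, id, parent = NULL) {
      attr <- paste0("ID=", id, if (!is.null(parent)) paste0(";Parent=", parent) else "")
      paste(g$chrom, "chromdyn", type, format(s + 1, scientific = FALSE),
            format(e, scientific = FALSE), ".", g$strand, ".", attr, sep = "\t")
    }
    mid <- paste0(g$gene_id, ".1")
    lines <- c(row("gene", g$start, g$end, g$gene_id),
               row("mRNA", g$start, g$end, mid, g$gene_id))
    ex <- g$exons[[1]]
    for (j in seq_len(nrow(ex))) {
      lines <- c(lines, row("exon", ex$start[j], ex$end[j], paste0(mid, ".exon", j), mid))
    }
    cd <- g$cds[[1]]
    for (j in seq_len(nrow(cd))) {
      lines <- c(lines, row("CDS", cd$start[j], cd$end[j], paste0(mid, ".cds", j), mid))
    }
    writeLines(lines, con)
  }
  invisible(path)
}

#' Read a 4-column bedGraph signal track
#' @inheritParams read_bed
#' @return Tibble `chrom`, `start`, `end`, `value`.
#' @export
read_bedgraph <- function(path, layout) {
  x <- read_bed(path, layout)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 4)
  if (length(bad)) stop(sprintf("%s line %d: bedGraph needs 4 columns", path, bad[1]))
  val <- suppressWarnings(as.numeric(vapply(fields, `[`, "", 4)))
  bad <- which(is.na(val))
  if (length(bad)) stop(sprintf("%s line %d: non-numeric value", path, bad[1]))
  raw <- tibble::tibble(chrom = vapply(fields, `[`, "", 1),
                        start = .parse_int(vapply(fields, `[`, "", 2), path, "start"),
                        end = .parse_int(vapply(fields, `[`, "", 3), path, "end"),
                        value = val)
  .sort_intervals(raw, layout)
}

#' Read an FPKM expression table
#'
#' TSV with a `gene_id` column and one numeric column per sample. Sample names
#' are expected to encode the condition as `<condition>_<replicate>`.
#'
#' @param path TSV path.
#' @return Tibble, one row per gene. Rejects negative FPKM and duplicated
#'   gene ids (reporting how many).
#' @export
read_expression <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!"gene_id" %in% names(x)) stop("expression table needs a gene_id column")
  dup <- sum(duplicated(x$gene_id))
  if (dup > 0) stop(sprintf("expression table has %d duplicated gene ids", dup))
  vals <- as.matrix(x[setdiff(names(x), "gene_id")])
  if (!is.numeric(vals)) stop("expression columns must be numeric")
  if (anyNA(vals) || any(vals < 0)) stop("FPKM values must be non-negative and non-missing")
  x
}

#' Map expression samples to conditions
#'
#' @param expr Expression tibble from [read_expression()].
#' @return Tibble `sample`, `condition` where condition is the sample name
#'   with a trailing `_<replicate>` stripped.
#' @export
expression_conditions <- function(expr) {
  s <- setdiff(names(expr), "gene_id")
  tibble::tibble(sample = s, condition = sub("_[0-9]+$", "", s))
}

#' Read a differential-expression result table
#'
#' Expects columns `gene_id`, `log2FC`, `pvalue`, `FDR`.
#' @param path TSV path.
#' @export
read_de_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("gene_id", "log2FC", "pvalue", "FDR")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("DE table missing columns: ", paste(miss, collapse = ", "))
  dup <- sum(duplicated(x$gene_id))
  if (dup > 0) stop(sprintf("DE table has %d duplicated gene ids", dup))
  for (cc in c("pvalue", "FDR")) {
    v <- x[[cc]]
    if (any(is.na(v) | v < 0 | v > 1)) stop(cc, " values must lie in [0, 1]")
  }
  if (any(!is.finite(x$log2FC))) stop("log2FC must be finite")
  x
}

#' Read a metabolite table
#'
#' Expects columns `metabolite_id`, `ion_mode` (pos/neg), `VIP`, `FC`, `pvalue`.
#' @param path TSV path.
#' @export
read_metabolite_table <- function(path) {
  x <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("metabolite_id", "ion_mode", "VIP", "FC", "pvalue")
  miss <- setdiff(need, names(x))
  if (length(miss)) stop("metabolite table missing columns: ", paste(miss, collapse = ", "))
  if (any(!x$ion_mode %in% c("pos", "neg"))) stop("ion_mode must be 'pos' or 'neg'")
  if (any(x$VIP < 0)) stop("VIP must be non-negative")
  if (any(x$FC <= 0)) stop("FC must be positive")
  if (any(x$pvalue < 0 | x$pvalue > 1)) stop("pvalue values must lie in [0, 1]")
  x
}

#' Write a tibble as TSV with stable formatting
#' @param x Tibble.
#' @param path Output path.
#' @export
write_tsv_stable <- function(x, path) {
  df <- as.data.frame(lapply(x, function(v) {
    if (is.numeric(v)) format(v, scientific = FALSE, trim = TRUE, digits = 15) else v
  }), check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
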