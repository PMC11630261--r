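#' Define a genome layout
#'
#' A genome layout is the ordered set of chromosome names and lengths that all
#' interval-valued objects in the package are validated against. Coordinates
#' everywhere in chromdyn are 0-based, half-open `[start, end)`, BED style;
#' 1-based formats (GFF3) are converted at the file boundary.
#'
#' @param chrom Character vector of unique chromosome names.
#' @param length Integer vector of chromosome lengths in bp (all > 0).
#' @return A tibble with columns `chrom`, `length`, ordered as given.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(1e6, 5e5))
#' @export
genome_layout <- function(chrom, length) {
  chrom <- as.character(chrom)
  length <- as.numeric(length)
  if (anyDuplicated(chrom)) stop("chromosome names must be unique")
  if (length(chrom) != base::length(length)) stop("chrom and length differ in length")
  if (any(!is.finite(length)) || any(length <= 0) || any(length != floor(length))) {
    stop("chromosome lengths must be positive integers")
  }
  tibble::tibble(chrom = chrom, length = length)
}

.layout_len <- function(layout, chrom) {
  i <- match(chrom, layout$chrom)
  if (anyNA(i)) stop("unknown chromosome: ", paste(unique(chrom[is.na(i)]), collapse = ", "))
  layout$length[i]
}

#' Partition a genome layout into fixed-width bins
#'
#' Bins are numbered globally in layout order; the last bin of each chromosome
#' may be shorter than `bin_size` and is kept (it is weighted like a full bin
#' by downstream state analyses).
#'
#' @param layout A [genome_layout()].
#' @param bin_size Bin width in bp (default 200, the resolution used for
#'   chromatin-state segmentation).
#' @return A tibble with columns `chrom`, `start`, `end`, `bin` (1-based global
#'   index).
#' @export
bin_genome <- function(layout, bin_size = 200) {
  stopifnot(is.numeric(bin_size), length(bin_size) == 1, bin_size > 0)
  res <- purrr::map2_dfr(layout$chrom, layout$length, function(ch, len) {
    starts <- seq(0, len - 1, by = bin_size)
    tibble::tibble(chrom = ch, start = starts, end = pmin(starts + bin_size, len))
  })
  res$bin <- seq_len(nrow(res))
  res
}

# Validate an interval tibble (chrom,start,end[,summit]) against a layout.
.check_intervals <- function(x, layout, what = "interval") {
  if (nrow(x) == 0) return(invisible(x))
  len <- .layout_len(layout, x$chrom)
  bad <- which(!(x$start >= 0 & x$start < x$end & x$end <= len))
  if (length(bad)) {
    stop(sprintf("%s %d out of bounds on %s: [%s, %s)", what, bad[1],
                 x$chrom[bad[1]], format(x$start[bad[1]], scientific = FALSE),
                 format(x$end[bad[1]], scientific = FALSE)))
  }
  if ("summit" %in% names(x)) {
    s <- x$summit
    bad <- which(!is.na(s) & !(s >= x$start & s < x$end))
    if (length(bad)) stop(sprintf("summit of %s %d outside [start, end)", what, bad[1]))
  }
  invisible(x)
}

.sort_intervals <- function(x, layout = NULL) {
  if (!is.null(layout)) {
    x$chrom <- factor(x$chrom, levels = layout$chrom)
    x <- dplyr::arrange(x, .data$chrom, .data$start, .data$end)
    x$chrom <- as.character(x$chrom)
    x
  } else {
    dplyr::arrange(x, .data$chrom, .data$start, .data$end)
  }
}

#' @importFrom rlang .data
NULL

utils::globalVariables(".")
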