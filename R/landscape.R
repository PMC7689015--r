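# Per-chromosome repeat landscapes: windowed density tracks, TE-order
# proportion tables, chi-square homogeneity tests and genome-fraction
# arithmetic.

# merged (union) ranges of a set of 1-based annotation rows
merged_ranges <- function(ann) {
  IRanges::reduce(ranges1(ann$start, ann$end))
}

#' Windowed feature-density tracks
#'
#' For each non-overlapping window the fraction of window bases covered
#' by each feature class is computed; overlapping same-class features
#' are merged before counting, so a value can never exceed 1.  The last
#' window of a chromosome may be short; its fraction uses its actual
#' width.
#'
#' @param annotations GFF3 `data.frame`.
#' @param chrom_lengths Named numeric vector of chromosome lengths.
#' @param window Window size in bp (>= 1000).
#' @param classes Controlled classes to track (default: every class
#'   present).
#' @param class_map Vocabulary mapping for [classify_features()].
#' @return Long `data.frame(seqid, window_start, window_end, class,
#'   fraction)` with 0-based half-open window coordinates.
#' @export
compute_density_tracks <- function(annotations, chrom_lengths, window = 100000,
                                   classes = NULL,
                                   class_map = default_class_map()) {
  stopifnot(window >= 1000)
  unknown <- setdiff(unique(annotations$seqid), names(chrom_lengths))
  if (length(unknown)) stop_format("unknown seqid '%s' in annotations", unknown[1L])
  cls <- classify_features(annotations$type, class_map)
  if (is.null(classes)) classes <- sort(unique(as.character(cls)))
  out <- list()
  for (ch in names(chrom_lengths)) {
    L <- chrom_lengths[[ch]]
    starts <- seq(0, L - 1, by = window)
    ends <- pmin(starts + window, L)
    win_r <- ranges0(starts, ends)
    ann_ch <- annotations[annotations$seqid == ch, , drop = FALSE]
    cls_ch <- cls[annotations$seqid == ch]
    for (cl in classes) {
      m <- merged_ranges(ann_ch[cls_ch == cl, , drop = FALSE])
      cov_bp <- numeric(length(win_r))
      if (length(m)) {
        hits <- IRanges::findOverlaps(win_r, m)
        if (length(hits)) {
          inter <- IRanges::pintersect(win_r[S4Vectors::queryHits(hits)],
                                       m[S4Vectors::subjectHits(hits)])
          cov_bp <- cov_bp + as.numeric(
            tapply(IRanges::width(inter),
                   factor(S4Vectors::queryHits(hits), levels = seq_along(win_r)),
                   sum, default = 0))
        }
      }
      out[[length(out) + 1L]] <- data.frame(
        seqid = ch, window_start = starts, window_end = ends, class = cl,
        fraction = cov_bp / (ends - starts), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Per-chromosome TE-order proportions
#'
#' Cumulative merged bp and percent of chromosome length per TE order
#' (`LTR_gypsy, LTR_copia, LINE, ClassI_other, ClassII`).  Overlapping
#' same-order annotations are merged before counting.
#'
#' @param annotations GFF3 `data.frame`.
#' @param chrom_lengths Named numeric vector.
#' @param class_map Vocabulary mapping.
#' @return `data.frame(seqid, class, bp, pct)`.
#' @export
te_order_proportions <- function(annotations, chrom_lengths,
                                 class_map = default_class_map()) {
  cls <- classify_features(annotations$type, class_map)
  out <- list()
  for (ch in names(chrom_lengths)) {
    sel <- annotations$seqid == ch
    for (cl in TE_CLASSES) {
      m <- merged_ranges(annotations[sel & cls == cl, , drop = FALSE])
      bp <- sum(IRanges::width(m))
      out[[length(out) + 1L]] <- data.frame(
        seqid = ch, class = cl, bp = bp,
        pct = 100 * bp / chrom_lengths[[ch]], stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# long proportion table -> chromosomes x classes count matrix in `unit`
proportion_count_matrix <- function(prop, unit = c("kb", "bp", "Mb")) {
  unit <- match.arg(unit)
  div <- c(kb = 1000, bp = 1, Mb = 1e6)[[unit]]
  tab <- tapply(prop$bp / div, list(prop$seqid, prop$class), sum, default = 0)
  tab[, colSums(tab) > 0, drop = FALSE]
}

#' Pearson chi-square test of homogeneity
#'
#' Classical Pearson statistic on a counts matrix with expected counts
#' from the row/column margins; the p-value comes from the upper tail
#' of the chi-square distribution with `(r-1)(c-1)` degrees of freedom.
#' For repeat-content tables, counts are usually cumulative bp scaled
#' to kb (see [proportion_count_matrix()]); raw bp would inflate the
#' statistic.
#'
#' @param table Numeric matrix of non-negative counts.
#' @return `list(statistic, df, p)`.
#' @export
chi_square_homogeneity <- function(table) {
  m <- as.matrix(table)
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop_format("chi_square_homogeneity: zero row or column margin")
  }
  ht <- suppressWarnings(chisq.test(m, correct = FALSE))
  if (any(ht$expected <= 0)) stop_format("expected count <= 0")
  list(statistic = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Genome fraction occupied by a cumulative length
#'
#' @param cum_te_bp Cumulative merged bp.
#' @param genome_size_bp Genome size in bp.
#' @return Percent, rounded to 2 decimals.
#' @export
genome_te_fraction <- function(cum_te_bp, genome_size_bp) {
  if (any(genome_size_bp <= 0)) stop_format("genome size must be positive")
  round(100 * cum_te_bp / genome_size_bp, 2)
}

#' Rescale a genome-fraction percentage to a new genome size
#'
#' A fraction quoted against one genome-size estimate is converted to
#' another by exact inverse proportionality:
#' `pct_new = pct_old * size_old / size_new`.
#'
#' @param pct_old Percent against `size_old`.
#' @param size_old,size_new Genome sizes (same unit).
#' @return Percent against `size_new`, rounded to 2 decimals.
#' @export
rescale_fraction <- function(pct_old, size_old, size_new) {
  if (any(size_old <= 0) || any(size_new <= 0)) {
    stop_format("genome sizes must be positive")
  }
  round(pct_old * size_old / size_new, 2)
}
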