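# Flow-cytometry genome-size arithmetic and accession comparisons:
# G1-peak ratios to 1C content, pg to Mbp conversion, one-way ANOVA,
# Tukey HSD compact letter displays and a Shapiro normality check.

#' Read a flow-cytometry G1-peak table
#'
#' @param path CSV with columns `accession, replicate, sample_g1_mean,
#'   standard_g1_mean`.
#' @return `data.frame` with those columns.
#' @export
read_flow_peaks <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("accession", "replicate", "sample_g1_mean", "standard_g1_mean")
  if (!all(need %in% names(df))) {
    stop_format("peak table '%s' must have columns %s", path,
                paste(need, collapse = ", "))
  }
  df
}

#' 1C DNA content from G1 peak means
#'
#' `1C = (sample_g1_mean / standard_g1_mean) * standard_1c_pg`, using an
#' internal reference standard of known DNA content run with each
#' sample.
#'
#' @param sample_g1_mean,standard_g1_mean G1 peak means (channel units).
#' @param standard_1c_pg 1C content of the internal standard in pg
#'   (default 4.45 pg, a garden pea standard).
#' @return 1C content in pg.
#' @export
estimate_1c <- function(sample_g1_mean, standard_g1_mean, standard_1c_pg = 4.45) {
  if (any(sample_g1_mean <= 0) || any(standard_g1_mean <= 0) ||
      any(standard_1c_pg <= 0)) {
    stop_format("peak means and the standard 1C value must be positive")
  }
  sample_g1_mean / standard_g1_mean * standard_1c_pg
}

#' Convert 1C content (pg) to haploid genome size (Mbp)
#'
#' Uses the standard 978 Mbp per pg.
#'
#' @param pg 1C content in pg.
#' @param round_to_int Round for reporting (default TRUE).
#' @return Genome size in Mbp.
#' @export
pg_to_mbp <- function(pg, round_to_int = TRUE) {
  stopifnot(all(pg >= 0))
  mbp <- pg * 978
  if (round_to_int) round(mbp) else mbp
}

#' Percent difference of `a` relative to `b`
#'
#' @param a,b Values to compare (`b > 0`).
#' @param headline Round to the nearest integer (the convention for
#'   headline figures); otherwise 2 decimals.
#' @return `100 * (a - b) / b`, rounded per `headline`.
#' @export
percent_difference <- function(a, b, headline = TRUE) {
  if (any(b <= 0)) stop_format("reference value must be positive")
  x <- 100 * (a - b) / b
  if (headline) round(x) else round(x, 2)
}

#' Per-accession genome-size estimates from a peak table
#'
#' @param peaks `data.frame` as from [read_flow_peaks()].
#' @param standard_1c_pg 1C of the internal standard (pg).
#' @return `list(replicates, accessions)`: per-replicate 1C (pg) and
#'   size (Mbp), and per-accession mean/median of both.
#' @export
size_estimates <- function(peaks, standard_1c_pg = 4.45) {
  pg <- estimate_1c(peaks$sample_g1_mean, peaks$standard_g1_mean,
                    standard_1c_pg)
  reps <- data.frame(accession = peaks$accession, replicate = peaks$replicate,
                     c1_pg = pg, size_mbp = pg_to_mbp(pg, round_to_int = FALSE),
                     stringsAsFactors = FALSE)
  acc <- do.call(rbind, lapply(split(reps, reps$accession), function(d) {
    data.frame(accession = d$accession[1L], n = nrow(d),
               mean_1c_pg = round(mean(d$c1_pg), 3),
               median_1c_pg = round(median(d$c1_pg), 3),
               mean_size_mbp = round(mean(d$size_mbp)),
               median_size_mbp = round(median(d$size_mbp)),
               stringsAsFactors = FALSE)
  }))
  rownames(acc) <- NULL
  list(replicates = reps, accessions = acc)
}

as_groups <- function(groups) {
  if (is.data.frame(groups)) groups <- split(groups[[2L]], groups[[1L]])
  stopifnot(is.list(groups), length(groups) >= 2L)
  if (any(lengths(groups) < 2L)) {
    stop_format("every group needs at least 2 values")
  }
  groups
}

#' One-way analysis of variance
#'
#' Classical fixed-effects decomposition; the p-value is the upper tail
#' of the F distribution on `(k - 1, N - k)` degrees of freedom.
#'
#' @param groups Named list of numeric vectors (>= 2 groups, each with
#'   >= 2 values), or a two-column `data.frame` (group, value).
#' @return `list(F, df_between, df_within, p)`.
#' @export
anova_oneway <- function(groups) {
  groups <- as_groups(groups)
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(seq_along(groups), lengths(groups)))
  ht <- oneway.test(values ~ fac, var.equal = TRUE)
  list(F = unname(ht$statistic),
       df_between = unname(ht$parameter[1L]),
       df_within = unname(ht$parameter[2L]),
       p = unname(ht$p.value))
}

#' Tukey HSD comparisons with a compact letter display
#'
#' Pairwise studentized-range p-values come from Tukey's honestly
#' significant difference on the one-way fit (`method = "analytic"`,
#' the default) or from a seeded permutation of the pooled residuals
#' using the max studentized-range statistic (`method =
#' "permutation"`).  Letters are assigned by the usual
#' insert-and-absorb sweep so that groups sharing a letter are not
#' significantly different at `alpha`.
#'
#' @param groups Named list of numeric vectors (or two-column
#'   `data.frame`).
#' @param alpha Significance level.
#' @param method `"analytic"` or `"permutation"`.
#' @param n_perm,seed Permutation parameters.
#' @return `list(p_matrix, letters)`; `letters` is a named character
#'   vector over the group names.
#' @export
tukey_groups <- function(groups, alpha = 0.05,
                         method = c("analytic", "permutation"),
                         n_perm = 10000L, seed = 1L) {
  method <- match.arg(method)
  groups <- as_groups(groups)
  gnames <- names(groups)
  if (is.null(gnames)) gnames <- paste0("g", seq_along(groups))
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(gnames, lengths(groups)), levels = gnames)
  k <- length(groups)
  pmat <- matrix(1, k, k, dimnames = list(gnames, gnames))

  if (method == "analytic") {
    fit <- aov(values ~ fac)
    tk <- TukeyHSD(fit)$fac
    pair <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (r in seq_along(pair)) {
      i <- pair[[r]][1L]; j <- pair[[r]][2L]
      pmat[i, j] <- pmat[j, i] <- tk[r, "p adj"]
    }
  } else {
    means <- vapply(groups, mean, numeric(1))
    ns <- lengths(groups)
    resid <- values - means[as.character(fac)]
    mse <- sum(resid^2) / (length(values) - k)
    tstat <- function(m, msq) {
      # studentized range per pair with unequal n (Tukey-Kramer scaling)
      outer(seq_len(k), seq_len(k), Vectorize(function(i, j)
        abs(m[i] - m[j]) / sqrt(msq / 2 * (1 / ns[i] + 1 / ns[j]))))
    }
    obs <- tstat(means, mse)
    exceed <- matrix(0, k, k)
    with_seed(seed, {
      for (b in seq_len(n_perm)) {
        perm <- sample(resid)
        pm <- tapply(perm, fac, mean)
        pr <- perm - pm[as.character(fac)]
        pmse <- sum(pr^2) / (length(values) - k)
        pq <- max(tstat(pm, pmse))
        exceed <- exceed + (pq >= obs)
      }
    })
    pmat <- (exceed + 1) / (n_perm + 1)
    dimnames(pmat) <- list(gnames, gnames)
    diag(pmat) <- 1
  }

  list(p_matrix = pmat, letters = letter_display(pmat, gnames, alpha))
}

# insert-and-absorb compact letter display from a pairwise p matrix
letter_display <- function(pmat, gnames, alpha) {
  k <- length(gnames)
  sets <- list(seq_len(k))                  # letter groups (index sets)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    if (pmat[i, j] >= alpha) next           # not significantly different
    for (s in seq_along(sets)) {
      if (all(c(i, j) %in% sets[[s]])) {
        # split the offending set into two overlapping subsets
        a <- setdiff(sets[[s]], j)
        b <- setdiff(sets[[s]], i)
        sets[[s]] <- a
        sets[[length(sets) + 1L]] <- b
      }
    }
    # absorb duplicated/contained sets
    sets <- unique(lapply(sets, sort))
    keep <- rep(TRUE, length(sets))
    for (s in seq_along(sets)) for (t in seq_along(sets)) {
      if (s != t && keep[t] && keep[s] && all(sets[[s]] %in% sets[[t]]) &&
          length(sets[[s]]) < length(sets[[t]])) keep[s] <- FALSE
    }
    sets <- sets[keep]
  }
  lab <- rep("", k)
  for (s in seq_along(sets)) {
    lab[sets[[s]]] <- paste0(lab[sets[[s]]], letters[s])
  }
  setNames(lab, gnames)
}

#' Shapiro-Wilk normality test
#'
#' @param values Numeric vector, `3 <= n <= 5000`, non-constant.
#' @return `list(W, p)`.
#' @export
shapiro_normality <- function(values) {
  n <- length(values)
  if (n < 3L || n > 5000L) {
    stop_format("Shapiro test requires 3 <= n <= 5000 (n = %d)", n)
  }
  if (sd(values) == 0) stop_format("Shapiro test undefined for constant input")
  ht <- shapiro.test(values)
  list(W = unname(ht$statistic), p = unname(ht$p.value))
}
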