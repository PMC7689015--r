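# Internal helpers shared across modules.

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' Plain character interface around [Biostrings::reverseComplement()].
#' `N` is its own complement.
#'
#' @param x Character scalar over `A,C,G,T,N`.
#' @return Character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

# Run `expr` under a temporary RNG state seeded with `seed`; restores the
# caller's RNG stream afterwards so seeded helpers do not perturb sessions.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}

# Truncation toward zero, used by the reporting conventions for bp-valued
# statistics (12,179,136.83 -> 12,179,136).
trunc0 <- function(x) trunc(x)

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

# 0-based half-open [start, end) -> IRanges (1-based inclusive)
ranges0 <- function(start, end) IRanges::IRanges(start = start + 1L, end = end)

# annotation rows (1-based inclusive, GFF3 convention) -> IRanges
ranges1 <- function(start, end) IRanges::IRanges(start = start, end = end)
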