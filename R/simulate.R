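# Synthetic genome-pair simulator with planted ground truth.
#
# Genome A is an ancestral haploid genome carrying single-copy genes, TE
# copies and a tandem rDNA array.  Genome B is A plus a SNP overlay at a
# configured divergence, plus planted inversions and large insertions
# (tandem rDNA units, extra TE copies, random filler).  Every planted
# feature and event is recorded in a truth manifest so that downstream
# detectors can be scored against known answers.
#
# Sequences are manipulated as integer UTF-8 code vectors internally;
# this keeps SNP overlay, inversion and insertion surgery vectorised.

BASE_INT <- utf8ToInt("ACGT")
COMP_INT <- integer(128)
COMP_INT[utf8ToInt("A")] <- utf8ToInt("T")
COMP_INT[utf8ToInt("T")] <- utf8ToInt("A")
COMP_INT[utf8ToInt("C")] <- utf8ToInt("G")
COMP_INT[utf8ToInt("G")] <- utf8ToInt("C")
COMP_INT[utf8ToInt("N")] <- utf8ToInt("N")

rand_seq_int <- function(n, gc = 0.36) {
  sample(BASE_INT, n, replace = TRUE,
         prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
}

# substitute each selected position with a uniformly chosen different base
mutate_int <- function(x, rate) {
  if (rate <= 0) return(x)
  n_mut <- rbinom(1L, length(x), rate)
  if (n_mut == 0L) return(x)
  pos <- sample.int(length(x), n_mut)
  shift <- sample.int(3L, n_mut, replace = TRUE)
  idx <- match(x[pos], BASE_INT)
  keep <- !is.na(idx)           # leave N untouched
  x[pos[keep]] <- BASE_INT[((idx[keep] - 1L + shift[keep]) %% 4L) + 1L]
  x
}

revcomp_int <- function(x) COMP_INT[rev(x)]

default_te_library <- function() {
  data.frame(
    family = c("gypsy1", "gypsy2", "copia1", "line1"),
    class = c("LTR_gypsy", "LTR_gypsy", "LTR_copia", "LINE"),
    consensus_length = c(5000, 4000, 3000, 2500),
    copies_A = c(8, 6, 6, 5),
    copies_B = c(12, 6, 8, 5),
    stringsAsFactors = FALSE
  )
}

#' Simulation configuration for a diverged genome pair
#'
#' Defaults describe the study conditions exercised throughout the test
#' suite: two 1-Mb chromosomes, 1% SNP divergence (comfortably inside the
#' >= 95% identity filter regime), a 9-kb rDNA unit, three large planted
#' insertions rich in tandem rDNA and LTR elements, and two planted
#' inversions.
#'
#' @param seed Integer seed; the same config and seed give byte-identical
#'   output.
#' @param n_chromosomes,chrom_length Number and length (bp) of chromosomes.
#' @param gc_content Background GC fraction.
#' @param snp_divergence Per-bp substitution rate between the two genomes.
#' @param n_genes,gene_length Single-copy gene count and length (bp).
#' @param te_library `data.frame` with columns `family, class,
#'   consensus_length, copies_A, copies_B` (`copies_B >= copies_A`; the
#'   surplus copies are planted inside the configured insertions).
#' @param te_copy_divergence Per-copy substitution rate applied
#'   independently to each planted TE copy, so copies of a family cluster
#'   together at a 90% identity threshold.
#' @param rdna_unit_length Length (bp) of one tandem rDNA unit.
#' @param rdna_array_copies_A,rdna_array_copies_B Units in the tandem
#'   array of each genome (an expansion in B is realised as an insertion
#'   at the array end and recorded in the truth manifest).
#' @param planted_insertions `data.frame` with columns `chrom, position,
#'   length, w_rdna, w_te, w_random` (composition weights; positions are
#'   0-based offsets on the ancestral genome).
#' @param planted_inversions `data.frame` with columns `chrom, start,
#'   length` (0-based, ancestral coordinates).
#' @param read_length,read_error_rate,coverage Shotgun-read parameters.
#' @return A validated config (list of class `sim_config`).
#' @export
simulation_config <- function(seed = 1L,
                              n_chromosomes = 2L,
                              chrom_length = 1e6,
                              gc_content = 0.36,
                              snp_divergence = 0.01,
                              n_genes = 20L,
                              gene_length = 1000L,
                              te_library = default_te_library(),
                              te_copy_divergence = 0.02,
                              rdna_unit_length = 9000L,
                              rdna_array_copies_A = 3L,
                              rdna_array_copies_B = 3L,
                              planted_insertions = data.frame(
                                chrom = c(1L, 1L, 2L),
                                position = c(250000, 650000, 400000),
                                length = c(50000, 200000, 120000),
                                w_rdna = c(0.4, 0.35, 0.3),
                                w_te = c(0.3, 0.35, 0.3),
                                w_random = c(0.3, 0.3, 0.4)
                              ),
                              planted_inversions = data.frame(
                                chrom = c(1L, 2L),
                                start = c(450000, 700000),
                                length = c(80000, 60000)
                              ),
                              read_length = 100L,
                              read_error_rate = 0.01,
                              coverage = 20) {
  cfg <- list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
              chrom_length = chrom_length, gc_content = gc_content,
              snp_divergence = snp_divergence, n_genes = as.integer(n_genes),
              gene_length = as.integer(gene_length), te_library = te_library,
              te_copy_divergence = te_copy_divergence,
              rdna_unit_length = as.integer(rdna_unit_length),
              rdna_array_copies_A = as.integer(rdna_array_copies_A),
              rdna_array_copies_B = as.integer(rdna_array_copies_B),
              planted_insertions = planted_insertions,
              planted_inversions = planted_inversions,
              read_length = as.integer(read_length),
              read_error_rate = read_error_rate, coverage = coverage)
  validate_sim_config(cfg)
  class(cfg) <- "sim_config"
  cfg
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$n_chromosomes >= 1L, cfg$chrom_length >= 1000,
            cfg$gc_content >= 0, cfg$gc_content <= 1,
            cfg$snp_divergence >= 0, cfg$snp_divergence <= 1,
            cfg$read_error_rate >= 0, cfg$read_error_rate <= 1,
            cfg$rdna_array_copies_A >= 0L, cfg$rdna_array_copies_B >= 0L)
  if (cfg$rdna_array_copies_B < cfg$rdna_array_copies_A) {
    stop_format("rdna_array_copies_B < rdna_array_copies_A: array contractions are not supported")
  }
  tl <- cfg$te_library
  if (nrow(tl) && any(tl$copies_B < tl$copies_A)) {
    stop_format("te_library: copies_B must be >= copies_A (family '%s')",
                tl$family[tl$copies_B < tl$copies_A][1L])
  }
  ins <- cfg$planted_insertions
  inv <- cfg$planted_inversions
  # planted events must not overlap each other on a chromosome
  ev <- rbind(
    if (nrow(ins)) data.frame(chrom = ins$chrom, start = ins$position,
                              end = ins$position),
    if (nrow(inv)) data.frame(chrom = inv$chrom, start = inv$start,
                              end = inv$start + inv$length)
  )
  if (!is.null(ev) && nrow(ev) > 1L) {
    for (ch in unique(ev$chrom)) {
      e <- ev[ev$chrom == ch, , drop = FALSE]
      e <- e[order(e$start, e$end), , drop = FALSE]
      if (nrow(e) > 1L && any(e$start[-1L] < e$end[-nrow(e)])) {
        stop_format("planted events overlap on chromosome %s", ch)
      }
    }
  }
  if (nrow(inv) && any(inv$start + inv$length > cfg$chrom_length)) {
    stop_format("planted inversion exceeds chromosome bounds")
  }
  if (nrow(ins) && any(ins$position > cfg$chrom_length)) {
    stop_format("planted insertion position exceeds chromosome bounds")
  }
  invisible(cfg)
}

chrom_names <- function(cfg) sprintf("chr%02d", seq_len(cfg$n_chromosomes))

# Sample `n` non-overlapping intervals of lengths `lens` on [1, L] that do
# not contain any of the `forbidden` internal boundary points.  Simple
# rejection sampling; occupancy is kept low by the configs used here.
place_intervals <- function(lens, L, occupied, forbidden) {
  out <- matrix(NA_real_, nrow = length(lens), ncol = 2L)
  for (i in seq_along(lens)) {
    len <- lens[i]
    for (attempt in seq_len(2000L)) {
      s <- sample.int(L - len + 1L, 1L)
      e <- s + len - 1L
      if (nrow(occupied) &&
          any(s <= occupied[, 2L] & e >= occupied[, 1L])) next
      if (length(forbidden) && any(forbidden > s & forbidden < e)) next
      out[i, ] <- c(s, e)
      occupied <- rbind(occupied, c(s, e))
      break
    }
    if (is.na(out[i, 1L])) {
      stop_format("could not place a %d bp feature on a %d bp chromosome", len, L)
    }
  }
  out
}

#' Simulate a diverged genome pair with planted ground truth
#'
#' See [simulation_config()] for the generative model.  The SNP overlay is
#' applied before the structural events, so inverted and flanking sequence
#' carry the same background divergence.
#'
#' @param config A [simulation_config()].
#' @return A list with elements `genome_A`, `genome_B` (named
#'   [Biostrings::DNAStringSet]), `annotations_A`, `annotations_B` (GFF3
#'   `data.frame`s, 1-based inclusive) and `truth` (see Details).
#'   `truth` carries `insertions` and `inversions` tables in 0-based
#'   half-open coordinates of the genome named in each row,
#'   `family_copies` with realised per-genome copy counts, and `genes`.
#' @export
simulate_genome_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  with_seed(config$seed, simulate_genome_pair_impl(config))
}

simulate_genome_pair_impl <- function(cfg) {
  chroms <- chrom_names(cfg)
  L <- cfg$chrom_length
  tl <- cfg$te_library

  # family consensus sequences and the rDNA unit, drawn once
  consensi <- lapply(seq_len(nrow(tl)), function(i)
    rand_seq_int(tl$consensus_length[i], cfg$gc_content))
  names(consensi) <- tl$family
  rdna_unit <- rand_seq_int(cfg$rdna_unit_length, cfg$gc_content)

  # --- genome A ---------------------------------------------------------
  A <- lapply(chroms, function(ch) rand_seq_int(L, cfg$gc_content))
  names(A) <- chroms

  ann <- list()   # rows of annotations_A
  add_ann <- function(seqid, type, start1, end1, id, family = NA) {
    attr_str <- if (is.na(family)) sprintf("ID=%s", id)
                else sprintf("ID=%s;Family=%s", id, family)
    data.frame(seqid = seqid, source = "intrasv_sim", type = type,
               start = start1, end = end1, score = NA_real_, strand = "+",
               phase = ".", attributes = attr_str, stringsAsFactors = FALSE)
  }

  # boundary points (1-based internal positions) features must not straddle
  forbidden <- lapply(chroms, function(ch) numeric(0))
  names(forbidden) <- chroms
  ins_cfg <- cfg$planted_insertions
  inv_cfg <- cfg$planted_inversions
  if (nrow(ins_cfg)) for (i in seq_len(nrow(ins_cfg))) {
    ch <- chroms[ins_cfg$chrom[i]]
    forbidden[[ch]] <- c(forbidden[[ch]], ins_cfg$position[i] + 0.5)
  }
  if (nrow(inv_cfg)) for (i in seq_len(nrow(inv_cfg))) {
    ch <- chroms[inv_cfg$chrom[i]]
    forbidden[[ch]] <- c(forbidden[[ch]], inv_cfg$start[i] + 0.5,
                         inv_cfg$start[i] + inv_cfg$length[i] + 0.5)
  }
  occupied <- lapply(chroms, function(ch) matrix(numeric(0), ncol = 2L))
  names(occupied) <- chroms

  # rDNA array on chromosome 1 (when configured)
  rdna_A <- cfg$rdna_array_copies_A
  array_iv <- NULL
  if (rdna_A > 0L) {
    alen <- rdna_A * cfg$rdna_unit_length
    iv <- place_intervals(alen, L, occupied[[1L]], forbidden[[1L]])
    occupied[[1L]] <- rbind(occupied[[1L]], iv)
    array_iv <- iv[1L, ]
    A[[1L]][iv[1L, 1L]:iv[1L, 2L]] <- rep(rdna_unit, rdna_A)
    for (u in seq_len(rdna_A)) {
      s <- array_iv[1L] + (u - 1L) * cfg$rdna_unit_length
      ann[[length(ann) + 1L]] <- add_ann(chroms[1L], "rDNA_45S", s,
                                         s + cfg$rdna_unit_length - 1L,
                                         sprintf("rdna_array_u%02d", u))
    }
  }

  # single-copy genes, spread round-robin across chromosomes
  gene_seqs <- lapply(seq_len(cfg$n_genes), function(i)
    rand_seq_int(cfg$gene_length, cfg$gc_content))
  gene_chrom <- rep(seq_along(chroms), length.out = cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    ch <- chroms[gene_chrom[i]]
    iv <- place_intervals(cfg$gene_length, L, occupied[[ch]], forbidden[[ch]])
    occupied[[ch]] <- rbind(occupied[[ch]], iv)
    A[[ch]][iv[1L, 1L]:iv[1L, 2L]] <- gene_seqs[[i]]
    ann[[length(ann) + 1L]] <- add_ann(ch, "gene", iv[1L, 1L], iv[1L, 2L],
                                       sprintf("gene%03d", i))
  }

  # TE copies in A
  if (nrow(tl)) for (f in seq_len(nrow(tl))) {
    n_cp <- tl$copies_A[f]
    if (n_cp == 0L) next
    cp_chrom <- rep(seq_along(chroms), length.out = n_cp)
    for (cp in seq_len(n_cp)) {
      ch <- chroms[cp_chrom[cp]]
      copy <- mutate_int(consensi[[f]], cfg$te_copy_divergence)
      iv <- place_intervals(length(copy), L, occupied[[ch]], forbidden[[ch]])
      occupied[[ch]] <- rbind(occupied[[ch]], iv)
      A[[ch]][iv[1L, 1L]:iv[1L, 2L]] <- copy
      ann[[length(ann) + 1L]] <- add_ann(ch, tl$class[f], iv[1L, 1L], iv[1L, 2L],
                                         sprintf("%s_A%02d", tl$family[f], cp),
                                         tl$family[f])
    }
  }

  annotations_A <- do.call(rbind, ann)
  if (is.null(annotations_A)) annotations_A <- empty_gff3()

  # --- genome B: SNP overlay, then inversions, then insertions ----------
  B <- lapply(A, mutate_int, rate = cfg$snp_divergence)
  annotations_B <- annotations_A

  truth_inversions <- NULL
  if (nrow(inv_cfg)) {
    truth_inversions <- data.frame(
      seqid = chroms[inv_cfg$chrom], a_start = inv_cfg$start,
      a_end = inv_cfg$start + inv_cfg$length,
      b_start = inv_cfg$start, b_end = inv_cfg$start + inv_cfg$length)
    for (i in seq_len(nrow(inv_cfg))) {
      ch <- chroms[inv_cfg$chrom[i]]
      s1 <- inv_cfg$start[i] + 1L            # 1-based inclusive
      e1 <- inv_cfg$start[i] + inv_cfg$length[i]
      B[[ch]][s1:e1] <- revcomp_int(B[[ch]][s1:e1])
      # reflect annotations inside the inverted interval
      inside <- annotations_B$seqid == ch & annotations_B$start >= s1 &
        annotations_B$end <= e1
      if (any(inside)) {
        ns <- s1 + (e1 - annotations_B$end[inside])
        ne <- s1 + (e1 - annotations_B$start[inside])
        annotations_B$start[inside] <- ns
        annotations_B$end[inside] <- ne
        annotations_B$strand[inside] <-
          ifelse(annotations_B$strand[inside] == "+", "-", "+")
      }
    }
  }

  # build the insertion work list: configured insertions plus an rDNA
  # array expansion when copies_B > copies_A
  ins_list <- list()
  if (nrow(ins_cfg)) for (i in seq_len(nrow(ins_cfg))) {
    ins_list[[length(ins_list) + 1L]] <-
      list(chrom = chroms[ins_cfg$chrom[i]], position = ins_cfg$position[i],
           length = ins_cfg$length[i],
           w = c(rdna = ins_cfg$w_rdna[i], te = ins_cfg$w_te[i],
                 random = ins_cfg$w_random[i]),
           kind = "planted")
  }
  extra_rdna_array <- cfg$rdna_array_copies_B - cfg$rdna_array_copies_A
  if (extra_rdna_array > 0L) {
    ins_list[[length(ins_list) + 1L]] <-
      list(chrom = chroms[1L], position = array_iv[2L],  # at array end
           length = extra_rdna_array * cfg$rdna_unit_length,
           w = c(rdna = 1, te = 0, random = 0), kind = "rdna_expansion")
  }

  # surplus TE copies (copies_B - copies_A) to distribute into insertions
  extra_pool <- list()
  if (nrow(tl)) for (f in seq_len(nrow(tl))) {
    n_extra <- tl$copies_B[f] - tl$copies_A[f]
    if (n_extra > 0L) for (j in seq_len(n_extra)) {
      extra_pool[[length(extra_pool) + 1L]] <-
        list(family = tl$family[f], class = tl$class[f], n = j)
    }
  }
  pool_i <- 1L
  extra_counts <- setNames(integer(nrow(tl)), tl$family)
  rdna_ins_units <- 0L

  # build each insertion's sequence and its internal annotations
  for (i in seq_along(ins_list)) {
    e <- ins_list[[i]]
    w <- e$w / sum(e$w)
    n_units <- floor(w["rdna"] * e$length / cfg$rdna_unit_length)
    parts <- list(); part_ann <- list(); off <- 0L
    if (n_units > 0L) {
      for (u in seq_len(n_units)) {
        parts[[length(parts) + 1L]] <- rdna_unit
        part_ann[[length(part_ann) + 1L]] <-
          list(type = "rDNA_45S", start = off, len = cfg$rdna_unit_length,
               id = sprintf("rdna_ins%d_u%02d", i, u), family = NA)
        off <- off + cfg$rdna_unit_length
        if (e$kind == "planted") rdna_ins_units <- rdna_ins_units + 1L
        else rdna_ins_units <- rdna_ins_units  # expansion counted via config
      }
    }
    te_budget <- floor(w["te"] * e$length)
    while (te_budget > 0L && pool_i <= length(extra_pool)) {
      item <- extra_pool[[pool_i]]
      cons <- consensi[[item$family]]
      if (length(cons) > te_budget) break
      copy <- mutate_int(cons, cfg$te_copy_divergence)
      parts[[length(parts) + 1L]] <- copy
      part_ann[[length(part_ann) + 1L]] <-
        list(type = item$class, start = off, len = length(copy),
             id = sprintf("%s_B%02d", item$family, tl$copies_A[match(item$family, tl$family)] + item$n),
             family = item$family)
      off <- off + length(copy)
      te_budget <- te_budget - length(copy)
      extra_counts[item$family] <- extra_counts[item$family] + 1L
      pool_i <- pool_i + 1L
    }
    filler <- e$length - off
    if (filler > 0L) parts[[length(parts) + 1L]] <- rand_seq_int(filler, cfg$gc_content)
    ins_list[[i]]$seq <- unlist(parts, use.names = FALSE)
    ins_list[[i]]$ann <- part_ann
  }
  if (pool_i <= length(extra_pool)) {
    stop_format("te_library requests %d surplus genome-B copies but the configured insertions cannot hold them",
                length(extra_pool) - pool_i + 1L)
  }

  # apply insertions from the largest ancestral position downwards so
  # earlier coordinates stay valid
  ord <- order(vapply(ins_list, function(e) e$position, numeric(1)),
               decreasing = TRUE)
  truth_ins <- list()
  for (i in ord) {
    e <- ins_list[[i]]
    ch <- e$chrom
    pos <- e$position                       # 0-based insertion point
    B[[ch]] <- append(B[[ch]], e$seq, after = pos)
    # shift downstream annotations of B
    after <- annotations_B$seqid == ch & annotations_B$start > pos
    annotations_B$start[after] <- annotations_B$start[after] + e$length
    annotations_B$end[after] <- annotations_B$end[after] + e$length
    for (pa in e$ann) {
      annotations_B <- rbind(annotations_B, data.frame(
        seqid = ch, source = "intrasv_sim", type = pa$type,
        start = pos + pa$start + 1L, end = pos + pa$start + pa$len,
        score = NA_real_, strand = "+", phase = ".",
        attributes = if (is.na(pa$family)) sprintf("ID=%s", pa$id)
                     else sprintf("ID=%s;Family=%s", pa$id, pa$family),
        stringsAsFactors = FALSE))
    }
  }
  # B coordinates of planted events after all insertions
  shift_at <- function(ch, a_pos) {
    s <- 0
    for (e in ins_list) if (e$chrom == ch && e$position < a_pos) s <- s + e$length
    s
  }
  for (i in seq_along(ins_list)) {
    e <- ins_list[[i]]
    b_start <- e$position + shift_at(e$chrom, e$position)
    truth_ins[[i]] <- data.frame(
      genome = "B", seqid = e$chrom, start = b_start,
      end = b_start + e$length, length = e$length,
      a_position = e$position, kind = e$kind, stringsAsFactors = FALSE)
  }
  truth_insertions <- if (length(truth_ins)) do.call(rbind, truth_ins) else
    data.frame(genome = character(), seqid = character(), start = numeric(),
               end = numeric(), length = numeric(), a_position = numeric(),
               kind = character(), stringsAsFactors = FALSE)
  if (!is.null(truth_inversions) && nrow(truth_inversions)) {
    for (i in seq_len(nrow(truth_inversions))) {
      sh <- shift_at(truth_inversions$seqid[i], truth_inversions$a_start[i])
      truth_inversions$b_start[i] <- truth_inversions$a_start[i] + sh
      truth_inversions$b_end[i] <- truth_inversions$a_end[i] + sh
    }
  } else {
    truth_inversions <- data.frame(seqid = character(), a_start = numeric(),
                                   a_end = numeric(), b_start = numeric(),
                                   b_end = numeric())
  }

  # realised per-family copy counts (rDNA counted in units)
  family_copies <- data.frame(
    family = c(tl$family, "rDNA_45S"),
    class = c(tl$class, "rDNA_45S"),
    copies_A = c(tl$copies_A, cfg$rdna_array_copies_A),
    copies_B = c(tl$copies_A + extra_counts,
                 cfg$rdna_array_copies_B + rdna_ins_units),
    stringsAsFactors = FALSE
  )

  genes <- annotations_A[annotations_A$type == "gene", c("seqid", "start", "end")]
  rownames(annotations_B) <- NULL

  to_set <- function(G) {
    s <- Biostrings::DNAStringSet(vapply(G, intToUtf8, character(1)))
    names(s) <- names(G)
    s
  }
  list(genome_A = to_set(A), genome_B = to_set(B),
       annotations_A = annotations_A, annotations_B = annotations_B,
       truth = list(insertions = truth_insertions,
                    inversions = truth_inversions,
                    family_copies = family_copies,
                    genes = genes,
                    config = cfg))
}

#' Simulate uniform-coverage single-end shotgun reads
#'
#' Draws `floor(coverage * total_length / read_length)` fixed-length reads
#' with uniform start positions, 50/50 strand choice and independent
#' per-base substitution errors.  Read names encode the origin as
#' `r<i>|<seqid>|<start0>|<strand>`.
#'
#' @param genome A named [Biostrings::DNAStringSet].
#' @param config A [simulation_config()] (uses `read_length`,
#'   `read_error_rate`, `coverage`).
#' @param seed Seed for the read stream; defaults to `config$seed + 101`.
#' @return A named [Biostrings::DNAStringSet] of reads.
#' @export
simulate_reads <- function(genome, config, seed = config$seed + 101L) {
  stopifnot(inherits(config, "sim_config"))
  len <- config$read_length
  lens <- Biostrings::width(genome)
  if (len > min(lens)) {
    stop_format("read_length (%d) exceeds the shortest chromosome (%d bp)",
                len, min(lens))
  }
  total <- sum(lens)
  n_reads <- floor(config$coverage * total / len)
  with_seed(seed, {
    chrom_idx <- sample.int(length(genome), n_reads, replace = TRUE,
                            prob = lens / total)
    starts <- floor(runif(n_reads) * (lens[chrom_idx] - len + 1)) + 1L
    rev <- runif(n_reads) < 0.5
    chars <- lapply(seq_along(genome), function(i)
      utf8ToInt(as.character(genome[[i]])))
    reads <- vector("list", n_reads)
    for (i in seq_len(n_reads)) {
      r <- chars[[chrom_idx[i]]][starts[i]:(starts[i] + len - 1L)]
      if (rev[i]) r <- revcomp_int(r)
      reads[[i]] <- r
    }
    if (config$read_error_rate > 0) {
      n_err <- rbinom(n_reads, len, config$read_error_rate)
      for (i in which(n_err > 0L)) {
        reads[[i]] <- force_mutate_int(reads[[i]], n_err[i])
      }
    }
    out <- Biostrings::DNAStringSet(vapply(reads, intToUtf8, character(1)))
    names(out) <- sprintf("r%d|%s|%d|%s", seq_len(n_reads),
                          names(genome)[chrom_idx], starts - 1L,
                          ifelse(rev, "-", "+"))
    out
  })
}

#' Study configuration for copy-number recovery
#'
#' A single 200-kb chromosome carrying four TE families planted at 1, 5,
#' 20 and 50 copies plus 24 single-copy calibration genes, read at 20x
#' coverage with a 1% per-base error rate.  Family consensus lengths are
#' graded (longer for low-copy families) so every family collects enough
#' reads for a stable depth estimate.
#'
#' @param seed Integer seed.
#' @return A [simulation_config()].
#' @export
cnv_study_config <- function(seed = 1L) {
  simulation_config(
    seed = seed, n_chromosomes = 1L, chrom_length = 2e5,
    n_genes = 24L, gene_length = 1000L,
    te_library = data.frame(
      family = c("famA", "famB", "famC", "famD"),
      class = c("LTR_gypsy", "LTR_copia", "LINE", "ClassII"),
      consensus_length = c(1500, 1200, 650, 550),
      copies_A = c(1L, 5L, 20L, 50L), copies_B = c(1L, 5L, 20L, 50L),
      stringsAsFactors = FALSE),
    rdna_array_copies_A = 0L, rdna_array_copies_B = 0L,
    planted_insertions = data.frame(chrom = integer(), position = numeric(),
                                    length = numeric(), w_rdna = numeric(),
                                    w_te = numeric(), w_random = numeric()),
    planted_inversions = data.frame(chrom = integer(), start = numeric(),
                                    length = numeric()),
    snp_divergence = 0, read_error_rate = 0.01, coverage = 20)
}

# mutate exactly n positions (used for per-read error injection)
force_mutate_int <- function(x, n) {
  pos <- sample.int(length(x), n)
  shift <- sample.int(3L, n, replace = TRUE)
  idx <- match(x[pos], BASE_INT)
  keep <- !is.na(idx)
  x[pos[keep]] <- BASE_INT[((idx[keep] - 1L + shift[keep]) %% 4L) + 1L]
  x
}
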