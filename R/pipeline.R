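# End-to-end orchestration: simulate (optional) -> align/filter ->
# regions + inversions -> landscape -> cnv -> phylo -> gsize, each stage
# skippable, with per-stage TSV/BED/Newick outputs and a machine-readable
# summary recording every parameter, its source (default vs config) and
# every seed.

merge_params <- function(defaults, given) {
  given <- given[intersect(names(given), names(defaults))]
  values <- defaults
  values[names(given)] <- given
  list(values = values,
       source = as.list(setNames(ifelse(names(defaults) %in% names(given),
                                        "config", "default"),
                        names(defaults))))
}

#' Run the full comparative pipeline from a config
#'
#' The config (YAML file or list) either names input files (`inputs:`
#' genome FASTAs, GFF3s, optional block tables, reads, flow-cytometry
#' peaks) or requests simulation (`simulate:` parameters for
#' [simulation_config()]).  Per-stage parameter blocks (`filter`,
#' `regions`, `inversions`, `landscape`, `cnv`, `phylo`, `gsize`)
#' override the documented defaults.  Stages without inputs are
#' skipped.  Identical config and seeds give identical outputs.
#'
#' @param config Path to a YAML config or an equivalent list.
#' @param outdir Output directory (created; default from the config).
#' @return Invisibly, the summary list (also written as
#'   `summary.json`).
#' @export
run_pipeline <- function(config, outdir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config))
  if (is.null(outdir)) outdir <- config$outdir
  if (is.null(outdir)) stop_format("config must name an output directory")
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  summary <- list(seeds = list(), parameters = list(), stages = list(),
                  outputs = list())
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop_format("stage '%s' failed: %s", name, conditionMessage(e))
    })
  }

  genome_A <- genome_B <- NULL
  ann_A <- ann_B <- NULL
  reads <- NULL
  truth <- NULL

  # --- simulate ---------------------------------------------------------
  if (!is.null(config$simulate)) {
    stage("simulate", {
      sim_cfg <- config$simulate
      # YAML represents tabular fields as lists of records
      for (f in c("planted_insertions", "planted_inversions", "te_library")) {
        if (!is.null(sim_cfg[[f]]) && !is.data.frame(sim_cfg[[f]])) {
          sim_cfg[[f]] <- do.call(rbind, lapply(sim_cfg[[f]], as.data.frame))
        }
      }
      mp <- merge_params(formals_defaults(simulation_config), sim_cfg)
      cfg <- do.call(simulation_config, mp$values)
      summary$parameters$simulate <- mp$source
      summary$seeds$simulate <- cfg$seed
      sim <- simulate_genome_pair(cfg)
      genome_A <- sim$genome_A; genome_B <- sim$genome_B
      ann_A <- sim$annotations_A; ann_B <- sim$annotations_B
      truth <- sim$truth
      write_fasta(genome_A, file.path(outdir, "genome_A.fa"))
      write_fasta(genome_B, file.path(outdir, "genome_B.fa"))
      write_gff3(ann_A, file.path(outdir, "genome_A.gff3"))
      write_gff3(ann_B, file.path(outdir, "genome_B.gff3"))
      write.table(truth$insertions, file.path(outdir, "truth_insertions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(truth$inversions, file.path(outdir, "truth_inversions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(truth$family_copies, file.path(outdir, "truth_family_copies.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (isTRUE(config$cnv$enabled)) {
        reads <- simulate_reads(genome_B, cfg)
        summary$seeds$reads <- cfg$seed + 101L
        write_fastq(reads, file.path(outdir, "reads_B.fastq"))
      }
      summary$stages$simulate <- "done"
    })
  } else if (!is.null(config$inputs)) {
    stage("load_inputs", {
      inp <- config$inputs
      if (!is.null(inp$genome_a)) genome_A <- read_fasta(inp$genome_a)
      if (!is.null(inp$genome_b)) genome_B <- read_fasta(inp$genome_b)
      if (!is.null(inp$gff_a)) ann_A <- read_gff3(inp$gff_a)
      if (!is.null(inp$gff_b)) ann_B <- read_gff3(inp$gff_b)
      if (!is.null(inp$reads)) reads <- read_fastq(inp$reads)
      summary$stages$load_inputs <- "done"
    })
  }

  # --- align + filter ---------------------------------------------------
  blocks <- NULL
  if (!is.null(config$inputs$blocks)) {
    blocks <- stage("load_blocks", {
      dialect <- config$inputs$blocks_dialect
      if (is.null(dialect)) dialect <- "internal_tsv"
      read_alignment_blocks(config$inputs$blocks, dialect)
    })
  } else if (!is.null(genome_A) && !is.null(genome_B)) {
    blocks <- stage("align", {
      mp <- merge_params(list(k = 21L, min_block = 1000L,
                              max_anchor_gap = 5000L), config$align)
      summary$parameters$align <- mp$source
      # reference = genome B (the genome whose specific content is sought)
      do.call(anchor_align, c(list(ref_genome = genome_B,
                                   qry_genome = genome_A), mp$values))
    })
  }

  regions <- NULL
  if (!is.null(blocks)) {
    mp_f <- merge_params(list(min_identity = 95, min_len = 4000),
                         config$filter)
    summary$parameters$filter <- mp_f$source
    filtered <- stage("filter", do.call(filter_blocks,
                                        c(list(blocks), mp_f$values)))
    write_alignment_blocks(filtered, file.path(outdir, "blocks.filtered.tsv"))
    summary$stages$filter <- "done"

    if (!is.null(genome_B)) {
      stage("regions", {
        mp <- merge_params(list(min_region = 1e6, merge_gap = 50000),
                           config$regions)
        summary$parameters$regions <- mp$source
        regions <- do.call(detect_specific_regions,
                            c(list(genome_B, list(filtered)), mp$values))
        write_bed(regions, file.path(outdir, "specific_regions.bed"))
        if (!is.null(ann_B) && nrow(regions)) {
          tab <- do.call(rbind, lapply(seq_len(nrow(regions)), function(i)
            summarize_region(regions[i, ], genome_B, ann_B)))
          write.table(tab, file.path(outdir, "specific_regions_summary.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
          stats <- summarize_table(tab)
          write.table(stats, file.path(outdir, "specific_regions_stats.tsv"),
                      sep = "\t", quote = FALSE, row.names = FALSE)
        }
        summary$stages$regions <- "done"
      })
    }

    stage("inversions", {
      mp <- merge_params(list(chain_gap = 100000), config$inversions)
      summary$parameters$inversions <- mp$source
      inv <- do.call(detect_inversions, c(list(filtered), mp$values))
      write.table(inv, file.path(outdir, "inversions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      if (nrow(inv)) {
        write_bed(data.frame(seqid = inv$ref_seqid, start = inv$ref_start,
                             end = inv$ref_end), file.path(outdir, "inversions.bed"))
      }
      summary$stages$inversions <- "done"
    })
  }

  # --- landscape --------------------------------------------------------
  if (!is.null(ann_B) && !is.null(genome_B)) {
    stage("landscape", {
      mp <- merge_params(list(window = 100000), config$landscape)
      summary$parameters$landscape <- mp$source
      lens <- setNames(Biostrings::width(genome_B), names(genome_B))
      dens <- compute_density_tracks(ann_B, lens, window = mp$values$window)
      write.table(dens, file.path(outdir, "density.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      prop <- te_order_proportions(ann_B, lens)
      write.table(prop, file.path(outdir, "te_proportions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$stages$landscape <- "done"
    })
  }

  # --- cnv --------------------------------------------------------------
  if (!is.null(reads) && !is.null(ann_B) && !is.null(genome_B) &&
      isTRUE(config$cnv$enabled)) {
    stage("cnv", {
      mp <- merge_params(list(min_identity = 90, k = 21L,
                              max_mismatch_frac = 0.1), config$cnv)
      summary$parameters$cnv <- mp$source
      feats <- extract_annotated_seqs(genome_B, ann_B)
      cls <- classify_features(ann_B$type)
      res <- estimate_family_copy_numbers(
        reads, feats[is_te_class(cls) | is_rdna_class(cls)],
        feats[cls == "gene"],
        min_identity = mp$values$min_identity, k = mp$values$k,
        max_mismatch_frac = mp$values$max_mismatch_frac)
      write.table(res$table, file.path(outdir, "cnv.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      summary$stages$cnv <- "done"
    })
  }

  # --- phylo ------------------------------------------------------------
  msa <- NULL
  if (!is.null(config$phylo$msa)) {
    msa <- as_alignment(config$phylo$msa)
  } else if (!is.null(ann_B) && !is.null(genome_B) && !is.null(config$phylo)) {
    fam <- config$phylo$family
    if (!is.null(fam)) {
      feats <- extract_annotated_seqs(genome_B, ann_B)
      sel <- grepl(paste0("^", fam), names(feats))
      if (sum(sel) >= 3L && length(unique(Biostrings::width(feats[sel]))) == 1L) {
        msa <- as_alignment(feats[sel])
      }
    }
  }
  if (!is.null(msa)) {
    stage("phylo", {
      mp <- merge_params(list(bootstrap = 100L, seed = 42L,
                              prune_factor = 10, cap = 5), config$phylo)
      summary$parameters$phylo <- mp$source
      summary$seeds$phylo <- mp$values$seed
      m <- trim_alignment(msa)
      tree <- bootstrap_support(m, n_reps = mp$values$bootstrap,
                                seed = mp$values$seed, cap = mp$values$cap)
      pruned <- prune_long_branches(tree, m, factor = mp$values$prune_factor,
                                    cap = mp$values$cap)
      write_newick(tree, file.path(outdir, "tree.nwk"))
      write_newick(pruned$tree, file.path(outdir, "tree.pruned.nwk"))
      summary$stages$phylo <- "done"
    })
  }

  # --- gsize ------------------------------------------------------------
  if (!is.null(config$gsize$peaks)) {
    stage("gsize", {
      mp <- merge_params(list(standard_1c_pg = 4.45, alpha = 0.05),
                         config$gsize)
      summary$parameters$gsize <- mp$source
      peaks <- read_flow_peaks(config$gsize$peaks)
      est <- size_estimates(peaks, standard_1c_pg = mp$values$standard_1c_pg)
      write.table(est$replicates, file.path(outdir, "gsize_replicates.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write.table(est$accessions, file.path(outdir, "gsize_accessions.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      grp <- split(est$replicates$c1_pg, est$replicates$accession)
      if (length(grp) >= 2L && all(lengths(grp) >= 2L)) {
        av <- anova_oneway(grp)
        tk <- tukey_groups(grp, alpha = mp$values$alpha)
        stat <- c(av, list(letters = as.list(tk$letters)))
        jsonlite::write_json(stat, file.path(outdir, "gsize_tests.json"),
                             auto_unbox = TRUE, digits = NA)
      }
      summary$stages$gsize <- "done"
    })
  }

  summary$outputs <- as.list(list.files(outdir))
  jsonlite::write_json(summary, file.path(outdir, "summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(summary)
}

# default values of a function's formals that have defaults (evaluated)
formals_defaults <- function(fn) {
  fl <- formals(fn)
  fl <- fl[!vapply(fl, function(x) is.symbol(x) && !nzchar(as.character(x)),
                   logical(1))]
  lapply(fl, eval, envir = environment(fn))
}

#' Extract annotated feature sequences from a genome
#'
#' @param genome Named [Biostrings::DNAStringSet].
#' @param annotations GFF3 `data.frame`; features on the `-` strand are
#'   reverse complemented.
#' @return Named [Biostrings::DNAStringSet], one element per annotation
#'   row (named from the `ID` attribute when present).
#' @export
extract_annotated_seqs <- function(genome, annotations) {
  ids <- sub("^ID=([^;]+).*$", "\\1", annotations$attributes)
  no_id <- !grepl("^ID=", annotations$attributes)
  ids[no_id] <- sprintf("feat%04d", which(no_id))
  out <- Biostrings::DNAStringSet(vapply(seq_len(nrow(annotations)), function(i) {
    s <- Biostrings::subseq(genome[[annotations$seqid[i]]],
                            annotations$start[i], annotations$end[i])
    s <- as.character(s)
    if (annotations$strand[i] == "-") s <- revcomp(s)
    s
  }, character(1)))
  names(out) <- make.unique(ids)
  out
}
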