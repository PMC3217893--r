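#' Run the full tag-profiling analysis on in-memory inputs
#'
#' Orchestrates the pipeline: catalogue construction from the annotated
#' cDNAs, model extension by genomic flanks, exact tag matching, positional
#' region tally, cpm normalization, owner resolution, the fold-change
#' screen with expression floor, the conditional NB no-replicate test with
#' BH adjustment, and — when read sets are supplied — RNA-Seq mapping,
#' RPKM quantification and DGE/RNA-Seq trend concordance.
#'
#' @param genome Named character vector of chromosome sequences.
#' @param models Annotation `data.frame` (see [read_models()]).
#' @param tag_counts Tag-count table (`tag_id`, `tag_seq`, `count_CS`,
#'   `count_CG`).
#' @param cfg A [dge_config()].
#' @param reads_CS,reads_CG Optional named character vectors of RNA-Seq
#'   reads; both or neither.
#' @return List with elements `catalogs`, `extended`, `region_tally`,
#'   `aligned_total`, `unmatched`, `matches`, `tag_expr`, `owners`,
#'   `model_expr`, `dge_screen`, `nb` (`data.frame` id/p/padj), and when
#'   reads are given `rnaseq` (expression records and totals),
#'   `rnaseq_screen`, `concordance`; plus a `manifest` of configuration
#'   and per-stage row counts.
#' @export
run_dge_pipeline <- function(genome, models, tag_counts,
                             cfg = dge_config(),
                             reads_CS = NULL, reads_CG = NULL) {
  if (xor(is.null(reads_CS), is.null(reads_CG))) {
    stop("supply reads for both libraries or neither")
  }
  cdna <- stats::setNames(models$cdna_seq, models$model_id)
  catalogs <- build_catalogs(cdna, cfg)
  ems <- extend_models(models, genome, cfg$flank_bp)
  index <- build_tag_index(ems, cfg$tag_len)
  filtered <- unique_tag_filter(tag_counts, cfg$min_raw_count)
  mt <- match_tags(filtered, index)
  matches <- annotate_matches(mt$matches, ems, catalogs, cfg$tag_len)
  tally <- region_tally(matches, ems, cfg$tag_len)

  matched_tab <- filtered[filtered$tag_seq %in% matches$tag_seq, ,
                          drop = FALSE]
  tag_expr <- tag_expression(matched_tab, mt$aligned_total)
  owners <- resolve_owners(matches, catalogs)
  owners$tag_id <- matched_tab$tag_id[match(owners$tag_seq,
                                            matched_tab$tag_seq)]
  model_expr <- model_expression_dge(matches, owners, mt$aligned_total)
  dge_screen <- fc_screen(tag_expr, cfg)

  cnt <- as.matrix(matched_tab[, c("count_CS", "count_CG")])
  rownames(cnt) <- matched_tab$tag_id
  nb <- nb_fit(cnt)
  p <- nb_test_noreps(cnt, nb)
  nb_res <- data.frame(id = matched_tab$tag_id, p_value = p,
                       p_adj = bh_adjust(p), stringsAsFactors = FALSE)

  out <- list(
    catalogs = catalogs, extended = ems, region_tally = tally,
    aligned_total = mt$aligned_total, unmatched = mt$unmatched,
    matches = matches, tag_expr = tag_expr, owners = owners,
    model_expr = model_expr, dge_screen = dge_screen, nb = nb_res
  )

  if (!is.null(reads_CS)) {
    rs <- rnaseq_expression(reads_CS, reads_CG, cdna, cfg)
    out$rnaseq <- rs
    out$rnaseq_screen <- fc_screen(rs$records, cfg)
    id_map <- owners[owners$status == "owned",
                     c("tag_id", "owner"), drop = FALSE]
    names(id_map) <- c("tag_id", "model_id")
    out$concordance <- concordance(out$dge_screen, rs$records, id_map)
  }

  out$manifest <- list(
    config = unclass(cfg),
    n_models = nrow(models),
    n_tags_in = nrow(tag_counts),
    n_tags_filtered = nrow(filtered),
    n_tags_matched = length(unique(matches$tag_seq)),
    n_tags_unmatched = length(mt$unmatched),
    aligned_total = as.list(mt$aligned_total),
    n_reads = if (is.null(reads_CS)) NULL else
      list(CS = length(reads_CS), CG = length(reads_CG)),
    region_tally = as.list(tally)
  )
  out
}

#' Materialize a complete synthetic test workspace on disk
#'
#' Generates a genome, annotation (optionally with 3'-truncated models),
#' cDNA FASTA, DGE tag-count table, RNA-Seq read FASTAs and a truth table,
#' all in the plain-text formats the readers consume. Deterministic for a
#' fixed seed.
#'
#' @param dir Output directory (created if needed).
#' @param n_models,seed,de_frac,de_fold Forwarded to the generators.
#' @param truncate_frac Fraction of models whose annotated 3' end is
#'   truncated.
#' @param truncate_range Range of truncation lengths, bases.
#' @param rnaseq_depth Reads per library (0 to skip the RNA-Seq arm).
#' @param dge_depth Tags per library.
#' @param cfg A [dge_config()].
#' @return Invisibly, a list of the generated in-memory objects (`sim`,
#'   `truth`, `dge`, `reads`, `models_annot`) plus the file `paths`.
#' @export
simulate_workspace <- function(dir, n_models = 50L, seed = 1L,
                               de_frac = 0.1, de_fold = 4,
                               truncate_frac = 0, truncate_range = c(100L, 200L),
                               rnaseq_depth = 20000L, dge_depth = 1e6,
                               cfg = dge_config()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim <- make_genome(n_models = n_models, seed = seed,
                     enzyme = cfg$enzyme, tag_len = cfg$tag_len)
  truth <- make_sim_truth(sim$models$model_id, seed = seed,
                          de_frac = de_frac, de_fold = de_fold,
                          depth = dge_depth)
  annot <- sim$models
  trunc <- stats::setNames(integer(0), character(0))
  if (truncate_frac > 0) {
    n_tr <- round(truncate_frac * n_models)
    trunc <- with_seed(seed + 1L, {
      ids <- sample(annot$model_id, n_tr)
      stats::setNames(sample(truncate_range[1]:truncate_range[2], n_tr,
                             replace = TRUE), ids)
    })
    annot <- truncate_annotations(annot, trunc)
  }
  dge <- simulate_dge(truth, sim$cdna, cfg)

  paths <- list(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "models.gff3"),
    cdna = file.path(dir, "cdna.fa"),
    tags = file.path(dir, "tag_counts.tsv"),
    truth = file.path(dir, "truth.tsv")
  )
  write_fasta(sim$genome, paths$genome)
  write_models(annot, paths$annotation)
  write_fasta(stats::setNames(annot$cdna_seq, annot$model_id), paths$cdna)
  write_results(dge$table, paths$tags)
  truth_tab <- data.frame(
    model_id = rownames(truth$abundance),
    abundance_CS = truth$abundance[, "CS"],
    abundance_CG = truth$abundance[, "CG"],
    planted_fold = unname(truth$planted_fold[rownames(truth$abundance)]),
    truncation = ifelse(rownames(truth$abundance) %in% names(trunc),
                        as.integer(trunc[rownames(truth$abundance)]), 0L),
    stringsAsFactors = FALSE
  )
  write_results(truth_tab, paths$truth)

  reads <- NULL
  if (rnaseq_depth > 0) {
    reads <- simulate_rnaseq(truth, sim$cdna, depth = rnaseq_depth,
                             seed = seed + 2L)
    paths$reads_CS <- file.path(dir, "reads_CS.fa")
    paths$reads_CG <- file.path(dir, "reads_CG.fa")
    write_fasta(reads$reads$CS, paths$reads_CS)
    write_fasta(reads$reads$CG, paths$reads_CG)
  }
  invisible(list(sim = sim, truth = truth, dge = dge, reads = reads,
                 models_annot = annot, truncation = trunc, paths = paths))
}

#' Run the pipeline on a workspace directory
#'
#' Reads the files written by [simulate_workspace()] (or any workspace in
#' the same layout), runs [run_dge_pipeline()], and writes the stage
#' outputs — catalogue, region tally, expression tables, screen and test
#' results, concordance and a JSON run manifest — to `out_dir`.
#'
#' @param dir Workspace directory.
#' @param out_dir Output directory (created if needed).
#' @param cfg A [dge_config()].
#' @param skip_rnaseq Ignore read files even if present.
#' @return Invisibly, the [run_dge_pipeline()] result list.
#' @export
run_dge_workspace <- function(dir, out_dir = file.path(dir, "results"),
                              cfg = dge_config(), skip_rnaseq = FALSE) {
  genome <- read_fasta(file.path(dir, "genome.fa"))
  cdna <- read_fasta(file.path(dir, "cdna.fa"))
  models <- read_models(file.path(dir, "models.gff3"), genome, cdna)
  tags <- read_tag_counts(file.path(dir, "tag_counts.tsv"), cfg$tag_len)
  reads_CS <- reads_CG <- NULL
  rcs <- file.path(dir, "reads_CS.fa")
  rcg <- file.path(dir, "reads_CG.fa")
  if (!skip_rnaseq && file.exists(rcs) && file.exists(rcg)) {
    reads_CS <- read_fasta(rcs)
    reads_CG <- read_fasta(rcg)
  }
  res <- run_dge_pipeline(genome, models, tags, cfg, reads_CS, reads_CG)

  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_results(res$catalogs, file.path(out_dir, "catalog.tsv"))
  write_results(data.frame(region = names(res$region_tally),
                           count = as.integer(res$region_tally)),
                file.path(out_dir, "region_tally.tsv"))
  write_results(res$tag_expr, file.path(out_dir, "tag_expression.tsv"))
  write_results(res$model_expr, file.path(out_dir, "model_expression.tsv"))
  write_results(res$dge_screen, file.path(out_dir, "dge_screen.tsv"))
  write_results(res$nb, file.path(out_dir, "nb_test.tsv"))
  if (!is.null(res$rnaseq)) {
    write_results(res$rnaseq$records,
                  file.path(out_dir, "rnaseq_expression.tsv"))
    write_results(res$concordance$table,
                  file.path(out_dir, "concordance.tsv"))
  }
  jsonlite::write_json(res$manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(res)
}
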