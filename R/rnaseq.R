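#' Map reads to transcript models (ungapped, mismatch-bounded)
#'
#' A desk-scale exact/k-mismatch matcher: for each read, both orientations
#' are aligned ungapped against every model with at most
#' `cfg$rnaseq_mismatches` substitutions. Exhaustiveness is guaranteed by
#' pigeonhole seeding: the read is partitioned into `mismatches + 1`
#' disjoint exact seeds, so any qualifying placement leaves at least one
#' seed exact; seed hits are extended and verified by direct Hamming
#' comparison. `N` in a read counts as a mismatch at its position. Per
#' read at most `cfg$rnaseq_max_alignments` placements are reported,
#' best-mismatch-first, then by model id and position.
#'
#' @param reads Named character vector of reads (uniform or mixed lengths;
#'   reads are grouped by length internally).
#' @param models Named character vector of model cDNA sequences.
#' @param cfg A [dge_config()].
#' @return List with `alignments` (`data.frame`: `read_id`, `model_id`,
#'   `start` 0-based in the model, `strand` `sense`/`antisense`,
#'   `mismatches`) and `mapped_total` (number of reads with at least one
#'   placement).
#' @export
map_reads <- function(reads, models, cfg = dge_config()) {
  if (length(models) == 0L) stop("empty model set")
  if (length(reads) == 0L) {
    return(list(alignments = data.frame(
      read_id = character(0), model_id = character(0), start = integer(0),
      strand = character(0), mismatches = integer(0),
      stringsAsFactors = FALSE), mapped_total = 0L))
  }
  mm <- cfg$rnaseq_mismatches
  maxa <- cfg$rnaseq_max_alignments
  models <- toupper(models)
  model_raw <- lapply(models, charToRaw)
  model_len <- nchar(models)
  reads <- toupper(reads)

  pieces <- lapply(split(seq_along(reads), nchar(reads)), function(ri) {
    len <- nchar(reads[ri[1L]])
    n_seeds <- mm + 1L
    s <- len %/% n_seeds
    if (s < 1L) return(NULL)  # read shorter than the seed partition
    offsets <- (seq_len(n_seeds) - 1L) * s
    idx <- .seed_index(models, s)

    out <- vector("list", 2L)
    orientations <- c(sense = FALSE, antisense = TRUE)
    for (o in seq_along(orientations)) {
      qseq <- if (orientations[[o]]) revcomp(reads[ri]) else reads[ri]
      seeds <- data.frame(
        q = rep(seq_along(ri), each = n_seeds),
        off = rep(offsets, times = length(ri)),
        kmer = substring(rep(qseq, each = n_seeds),
                         rep(offsets, times = length(ri)) + 1L,
                         rep(offsets, times = length(ri)) + s),
        stringsAsFactors = FALSE
      )
      hits <- merge(seeds, idx, by = "kmer")
      if (nrow(hits) == 0L) next
      hits$start <- hits$pos - hits$off
      ok <- hits$start >= 0L & hits$start + len <= model_len[hits$model_id]
      hits <- unique(hits[ok, c("q", "model_id", "start")])
      if (nrow(hits) == 0L) next
      qraw <- lapply(qseq, charToRaw)
      d <- vapply(seq_len(nrow(hits)), function(i) {
        mr <- model_raw[[hits$model_id[i]]]
        st <- hits$start[i]
        sum(mr[(st + 1L):(st + len)] != qraw[[hits$q[i]]])
      }, numeric(1))
      keep <- d <= mm
      if (!any(keep)) next
      out[[o]] <- data.frame(
        read_id = names(reads)[ri][hits$q[keep]],
        model_id = hits$model_id[keep],
        start = hits$start[keep],
        strand = names(orientations)[o],
        mismatches = as.integer(d[keep]),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  aln <- do.call(rbind, pieces)
  if (is.null(aln) || nrow(aln) == 0L) {
    aln <- data.frame(read_id = character(0), model_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE)
    return(list(alignments = aln, mapped_total = 0L))
  }
  aln <- aln[order(aln$read_id, aln$mismatches, aln$model_id, aln$start,
                   aln$strand), , drop = FALSE]
  rank <- stats::ave(seq_len(nrow(aln)), aln$read_id,
                     FUN = seq_along)
  aln <- aln[rank <= maxa, , drop = FALSE]
  rownames(aln) <- NULL
  list(alignments = aln, mapped_total = length(unique(aln$read_id)))
}

# Seed index: every s-mer of every model (sense strand), with 0-based pos.
.seed_index <- function(models, s) {
  pieces <- lapply(names(models), function(id) {
    L <- nchar(models[[id]])
    if (L < s) return(NULL)
    starts <- seq_len(L - s + 1L)
    data.frame(kmer = substring(models[[id]], starts, starts + s - 1L),
               model_id = id, pos = starts - 1L, stringsAsFactors = FALSE)
  })
  do.call(rbind, pieces)
}

#' Quantify one library's alignments as fractional counts and RPKM
#'
#' Only each read's best-mismatch stratum contributes: a read whose best
#' placements hit `k` distinct models adds `1/k` to each, so the fractional
#' counts over models sum to the number of mapped reads.
#'
#' @param alignments Alignment table from [map_reads()].
#' @param models Named character vector of model cDNA sequences.
#' @param mapped_total Number of mapped reads in the library.
#' @return `data.frame` with `model_id`, `reads` (fractional), `rpkm` for
#'   every model (zero where unhit).
#' @export
quantify_models <- function(alignments, models, mapped_total) {
  counts <- stats::setNames(numeric(length(models)), names(models))
  if (nrow(alignments) > 0L) {
    best <- stats::ave(alignments$mismatches, alignments$read_id,
                       FUN = min)
    top <- alignments[alignments$mismatches == best, , drop = FALSE]
    rm <- unique(top[, c("read_id", "model_id")])
    w <- 1 / table(rm$read_id)
    frac <- tapply(as.numeric(w[rm$read_id]), rm$model_id, sum)
    counts[names(frac)] <- frac
  }
  data.frame(
    model_id = names(models),
    reads = unname(counts),
    rpkm = if (mapped_total > 0) {
      rpkm(unname(counts), nchar(models), mapped_total)
    } else rep(0, length(models)),
    stringsAsFactors = FALSE
  )
}

#' RNA-Seq expression records for the two libraries
#'
#' Maps both read sets, quantifies each, and assembles RPKM-unit
#' expression records with CS/CG ratios.
#'
#' @param reads_CS,reads_CG Named character vectors of reads.
#' @param models Named character vector of model cDNA sequences.
#' @param cfg A [dge_config()].
#' @return List with `records` (`id`, `value_CS`, `value_CG`, `unit`
#'   `"RPKM"`, `fold_change`), `mapped_total` (named numeric), and the two
#'   alignment tables.
#' @export
rnaseq_expression <- function(reads_CS, reads_CG, models,
                              cfg = dge_config()) {
  cs <- map_reads(reads_CS, models, cfg)
  cg <- map_reads(reads_CG, models, cfg)
  qcs <- quantify_models(cs$alignments, models, cs$mapped_total)
  qcg <- quantify_models(cg$alignments, models, cg$mapped_total)
  records <- data.frame(
    id = qcs$model_id,
    value_CS = qcs$rpkm,
    value_CG = qcg$rpkm,
    unit = "RPKM",
    stringsAsFactors = FALSE
  )
  records$fold_change <- fold_change(records$value_CS, records$value_CG)
  list(records = records,
       mapped_total = c(CS = cs$mapped_total, CG = cg$mapped_total),
       alignments_CS = cs$alignments, alignments_CG = cg$alignments)
}
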