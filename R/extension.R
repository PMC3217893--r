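#' Extend a gene model by genomic flanks
#'
#' Appends up to `flank_bp` bases of contiguous genomic sequence outside
#' the model's outermost genomic coordinates to each end of the spliced
#' cDNA, orienting everything 5'->3' on the model's sense strand: for a
#' minus-strand model the left (5') flank is the reverse complement of the
#' genomic bases just beyond `genomic_end`. Flanks are clipped at
#' chromosome boundaries and the realized lengths recorded, rather than
#' padded with `N` (padding would silently block 0-mismatch matching).
#' This recovers tags that fall past prematurely truncated UTR
#' annotations.
#'
#' @param model One model: a list or one-row `data.frame` with fields
#'   `model_id`, `chrom`, `strand`, `genomic_start`, `genomic_end`
#'   (0-based half-open), `cdna_seq`.
#' @param genome Named character vector of chromosome sequences.
#' @param flank_bp Maximum flank length in bases.
#' @return An object of class `extended_model`: list with `model_id`,
#'   `ext_seq` (left flank + cDNA + right flank), `left_len`, `core_len`,
#'   `right_len`.
#' @export
extend_model <- function(model, genome, flank_bp = 250L) {
  if (!model$chrom %in% names(genome)) {
    stop("chromosome not in genome: ", model$chrom)
  }
  chrom_seq <- genome[[model$chrom]]
  clen <- nchar(chrom_seq)
  gs <- model$genomic_start
  ge <- model$genomic_end
  stopifnot(gs >= 0L, ge <= clen, gs < ge)
  if (model$strand == "+") {
    left_len <- min(flank_bp, gs)
    right_len <- min(flank_bp, clen - ge)
    left <- substr(chrom_seq, gs - left_len + 1L, gs)
    right <- substr(chrom_seq, ge + 1L, ge + right_len)
  } else {
    left_len <- min(flank_bp, clen - ge)   # 5' of a minus-strand model
    right_len <- min(flank_bp, gs)
    left <- revcomp(substr(chrom_seq, ge + 1L, ge + left_len))
    right <- revcomp(substr(chrom_seq, gs - right_len + 1L, gs))
  }
  if (left_len == 0L) left <- ""
  if (right_len == 0L) right <- ""
  structure(
    list(model_id = model$model_id,
         ext_seq = paste0(left, toupper(model$cdna_seq), right),
         left_len = as.integer(left_len),
         core_len = nchar(model$cdna_seq),
         right_len = as.integer(right_len)),
    class = "extended_model"
  )
}

#' Extend every model in an annotation table
#'
#' @param models Model table from [read_models()].
#' @param genome Named character vector of chromosome sequences.
#' @param flank_bp Maximum flank length.
#' @return Named list of `extended_model` objects keyed by `model_id`.
#' @export
extend_models <- function(models, genome, flank_bp = 250L) {
  ems <- lapply(seq_len(nrow(models)), function(i) {
    extend_model(models[i, ], genome, flank_bp)
  })
  names(ems) <- models$model_id
  ems
}

#' Region labels of the extended-model coordinate system
#'
#' @return Character vector of the five labels in left-to-right order.
#' @export
region_labels <- function() {
  c("extra_left", "junction_left", "model", "junction_right", "extra_right")
}

#' Classify a tag interval relative to an extended model
#'
#' The interval `[tag_start, tag_start + tag_len)` is labelled
#' `extra_left` when entirely within the left flank, `junction_left` when
#' it overlaps the left-flank/model boundary, `model` when entirely within
#' the annotated model, `junction_right` when it overlaps the model/right-
#' flank boundary, and `extra_right` when entirely within the right flank.
#' Junction labels take precedence (an interval spanning both boundaries
#' is `junction_left`). The five labels partition all valid intervals.
#'
#' @param tag_start 0-based start position(s) within the extended sequence
#'   (vectorized).
#' @param tag_len Tag length.
#' @param em An `extended_model`.
#' @return Character vector of region labels.
#' @export
classify_region <- function(tag_start, tag_len, em) {
  s <- as.integer(tag_start)
  e <- s + as.integer(tag_len)
  total <- em$left_len + em$core_len + em$right_len
  if (any(s < 0L) || any(e > total)) {
    stop("tag interval out of bounds of extended model")
  }
  lb <- em$left_len
  rb <- em$left_len + em$core_len
  ifelse(e <= lb, "extra_left",
    ifelse(s < lb, "junction_left",
      ifelse(e <= rb, "model",
        ifelse(s < rb, "junction_right", "extra_right"))))
}

#' Tally tag matches by positional region
#'
#' @param matches `data.frame` with columns `model_id` and `tag_start`
#'   (positions within the extended model), e.g. from [match_tags()].
#' @param ems Named list of `extended_model` objects.
#' @param tag_len Tag length.
#' @return Named integer vector over the five [region_labels()], summing
#'   to `nrow(matches)`.
#' @export
region_tally <- function(matches, ems, tag_len = 16L) {
  tally <- stats::setNames(integer(5L), region_labels())
  if (nrow(matches) == 0L) return(tally)
  unknown <- setdiff(unique(matches$model_id), names(ems))
  if (length(unknown)) {
    stop("matches reference unknown models: ",
         paste(unknown, collapse = ", "))
  }
  regions <- vapply(seq_len(nrow(matches)), function(i) {
    classify_region(matches$tag_start[i], tag_len,
                    ems[[matches$model_id[i]]])
  }, character(1))
  counts <- table(factor(regions, levels = region_labels()))
  tally[] <- as.integer(counts)
  tally
}

#' Export extended models as FASTA
#'
#' Headers carry the three segment lengths so the region coordinate system
#' can be reconstructed from the file alone.
#'
#' @param ems Named list of `extended_model` objects.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_extended_fasta <- function(ems, path) {
  seqs <- vapply(ems, `[[`, character(1), "ext_seq")
  names(seqs) <- vapply(ems, function(e) {
    sprintf("%s left=%d core=%d right=%d",
            e$model_id, e$left_len, e$core_len, e$right_len)
  }, character(1))
  write_fasta(seqs, path)
}
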