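#' Analysis configuration
#'
#' Bundles every fixed parameter of the tag-profiling pipeline. Defaults are
#' the values used throughout the analysis: 250-bp model extension, 16-nt
#' tags anchored at DpnII (GATC) sites, a raw-count floor of 5 for unique
#' tags, a 42 tags-per-million expression floor with a 2-fold screen, exact
#' (0-mismatch) tag matching, and RNA-Seq mapping with up to 3 mismatches
#' and 25 reported alignments, with expressed-gene cutoffs at 1 and 10 RPKM.
#'
#' @param flank_bp Bases of genomic flank appended at each model end.
#' @param tag_len Tag length in nucleotides.
#' @param enzyme Restriction-site recognition sequence; `"GATC"` for DpnII,
#'   `"CATG"` for NlaIII.
#' @param min_raw_count Minimum raw tag count in at least one library for a
#'   unique tag to be retained.
#' @param min_cpm Expression floor, tags per million aligned, applied to the
#'   larger of the two library values in the fold-change screen.
#' @param fold_threshold Fold-change threshold of the screen (applied as
#'   `>= fold_threshold` or `<= 1/fold_threshold`).
#' @param dge_mismatches Mismatches tolerated in DGE tag matching (0).
#' @param rnaseq_mismatches Maximum mismatches in RNA-Seq read mapping.
#' @param rnaseq_max_alignments Maximum alignments reported per read.
#' @param rpkm_cutoffs RPKM cutoffs at which expressed genes are counted.
#' @param seed Integer seed forwarded to stochastic components.
#' @return An object of class `dge_config` (a validated named list).
#' @export
dge_config <- function(flank_bp = 250L,
                       tag_len = 16L,
                       enzyme = "GATC",
                       min_raw_count = 5L,
                       min_cpm = 42,
                       fold_threshold = 2,
                       dge_mismatches = 0L,
                       rnaseq_mismatches = 3L,
                       rnaseq_max_alignments = 25L,
                       rpkm_cutoffs = c(1, 10),
                       seed = 1L) {
  cfg <- list(
    flank_bp = as.integer(flank_bp),
    tag_len = as.integer(tag_len),
    enzyme = toupper(as.character(enzyme)),
    min_raw_count = as.integer(min_raw_count),
    min_cpm = as.numeric(min_cpm),
    fold_threshold = as.numeric(fold_threshold),
    dge_mismatches = as.integer(dge_mismatches),
    rnaseq_mismatches = as.integer(rnaseq_mismatches),
    rnaseq_max_alignments = as.integer(rnaseq_max_alignments),
    rpkm_cutoffs = as.numeric(rpkm_cutoffs),
    seed = as.integer(seed)
  )
  if (cfg$flank_bp < 0L) stop("flank_bp must be >= 0")
  if (cfg$tag_len < 1L) stop("tag_len must be >= 1")
  if (!nzchar(cfg$enzyme) || !grepl("^[ACGT]+$", cfg$enzyme)) {
    stop("enzyme must be a non-empty string over {A,C,G,T}")
  }
  if (cfg$fold_threshold <= 1) stop("fold_threshold must be > 1")
  if (cfg$min_raw_count < 0L || cfg$min_cpm < 0 ||
      any(cfg$rpkm_cutoffs < 0)) {
    stop("count/expression cutoffs must be >= 0")
  }
  if (cfg$dge_mismatches < 0L || cfg$rnaseq_mismatches < 0L ||
      cfg$rnaseq_max_alignments < 1L) {
    stop("mismatch/alignment limits out of range")
  }
  structure(cfg, class = "dge_config")
}

#' @export
print.dge_config <- function(x, ...) {
  cat("DGE tag-profiling configuration\n")
  for (nm in names(x)) {
    cat(sprintf("  %-22s %s\n", nm, paste(x[[nm]], collapse = ", ")))
  }
  invisible(x)
}
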