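#' Tags per million aligned
#'
#' @param raw_count Raw count(s) for a tag in one library.
#' @param aligned_total Total raw counts of aligned unique tags in that
#'   library; must be positive.
#' @return `raw_count * 1e6 / aligned_total`.
#' @export
cpm <- function(raw_count, aligned_total) {
  if (length(aligned_total) != 1L || aligned_total <= 0) {
    stop("aligned_total must be a single positive number")
  }
  raw_count * 1e6 / aligned_total
}

#' Reads per kilobase of model per million mapped reads
#'
#' Length- and depth-normalized RNA-Seq expression: read counts are scaled
#' by model length because longer transcripts attract proportionally more
#' reads.
#'
#' @param read_count Read count(s) attributed to the model.
#' @param model_len Model length in nucleotides; must be positive.
#' @param mapped_total Total mapped reads in the library; must be positive.
#' @return `read_count * 1e9 / (model_len * mapped_total)`.
#' @export
rpkm <- function(read_count, model_len, mapped_total) {
  if (any(model_len <= 0)) stop("model_len must be positive")
  if (length(mapped_total) != 1L || mapped_total <= 0) {
    stop("mapped_total must be a single positive number")
  }
  read_count * 1e9 / (model_len * mapped_total)
}

#' Expression ratio between the two libraries
#'
#' With the default zero pseudocount the ratio is `+Inf` when the CG value
#' is zero and the CS value positive, and `NA` when both are zero; extreme
#' ratios are propagated rather than capped.
#'
#' @param v_cs,v_cg Non-negative expression values (vectorized).
#' @param pseudocount Non-negative value added to both before dividing.
#' @return Numeric vector of CS/CG ratios.
#' @export
fold_change <- function(v_cs, v_cg, pseudocount = 0) {
  if (length(pseudocount) != 1L || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number")
  }
  if (any(v_cs < 0, na.rm = TRUE) || any(v_cg < 0, na.rm = TRUE)) {
    stop("expression values must be >= 0")
  }
  if (pseudocount > 0) {
    return((v_cs + pseudocount) / (v_cg + pseudocount))
  }
  ifelse(v_cg > 0, v_cs / v_cg, ifelse(v_cs > 0, Inf, NA_real_))
}

#' Assemble per-tag expression records in cpm units
#'
#' @param table Tag-count table (`tag_id`, `tag_seq`, `count_CS`,
#'   `count_CG`).
#' @param aligned_total Named numeric `c(CS=, CG=)` of aligned totals from
#'   [match_tags()].
#' @return `data.frame` with `id`, `value_CS`, `value_CG`, `unit`
#'   (`"cpm"`), `fold_change`.
#' @export
tag_expression <- function(table, aligned_total) {
  out <- data.frame(
    id = table$tag_id,
    value_CS = cpm(table$count_CS, aligned_total[["CS"]]),
    value_CG = cpm(table$count_CG, aligned_total[["CG"]]),
    unit = "cpm",
    stringsAsFactors = FALSE
  )
  out$fold_change <- fold_change(out$value_CS, out$value_CG)
  out
}

#' Count expressed genes at an expression cutoff
#'
#' A record counts as expressed when its value in the chosen library is
#' greater than or equal to the cutoff (boundary inclusive).
#'
#' @param records Expression records with RPKM unit.
#' @param cutoff Non-negative cutoff.
#' @param library `"CS"` or `"CG"`.
#' @return Integer count.
#' @export
expressed_gene_count <- function(records, cutoff, library = c("CS", "CG")) {
  library <- match.arg(library)
  if (!all(records$unit == "RPKM")) {
    stop("expressed_gene_count requires RPKM-unit records")
  }
  sum(records[[paste0("value_", library)]] >= cutoff)
}

#' Rank records by abundance in one library
#'
#' @param records Expression records or tag table; ranking uses
#'   `value_<library>` if present, else `count_<library>`.
#' @param n Number of top records to return (the whole table if larger).
#' @param library `"CS"` or `"CG"`.
#' @return The top `n` rows, descending by value; ties broken by id
#'   (lexicographic).
#' @export
rank_top <- function(records, n, library = c("CS", "CG")) {
  library <- match.arg(library)
  stopifnot(n >= 1L)
  col <- paste0("value_", library)
  if (!col %in% names(records)) col <- paste0("count_", library)
  idcol <- if ("id" %in% names(records)) "id" else "tag_id"
  ord <- order(-records[[col]], records[[idcol]])
  records[ord[seq_len(min(n, nrow(records)))], , drop = FALSE]
}

#' Filter unique tags by a raw-count floor
#'
#' Keeps tags with at least `min_raw` raw counts in at least one library.
#'
#' @param table Tag-count table.
#' @param min_raw Non-negative raw-count floor.
#' @return Filtered table.
#' @export
unique_tag_filter <- function(table, min_raw = 5L) {
  stopifnot(min_raw >= 0L)
  keep <- table$count_CS >= min_raw | table$count_CG >= min_raw
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Aggregate owned tag counts to model level (cpm units)
#'
#' Counts of tags resolved to an owning model are attributed to that model
#' only; ambiguous tags are excluded so that paralog-shared tags are not
#' double-counted.
#'
#' @param matches Match table from [match_tags()].
#' @param owners Owner table from [resolve_owners()].
#' @param aligned_total Named numeric `c(CS=, CG=)`.
#' @return Expression records (`id` = model id, unit `"cpm"`).
#' @export
model_expression_dge <- function(matches, owners, aligned_total) {
  owned <- owners[owners$status == "owned", , drop = FALSE]
  per_tag <- unique(matches[, c("tag_seq", "count_CS", "count_CG")])
  m <- merge(owned[, c("tag_seq", "owner")], per_tag, by = "tag_seq")
  cs <- tapply(m$count_CS, m$owner, sum)
  cg <- tapply(m$count_CG, m$owner, sum)
  out <- data.frame(
    id = names(cs),
    value_CS = cpm(as.numeric(cs), aligned_total[["CS"]]),
    value_CG = cpm(as.numeric(cg), aligned_total[["CG"]]),
    unit = "cpm",
    stringsAsFactors = FALSE
  )
  out$fold_change <- fold_change(out$value_CS, out$value_CG)
  rownames(out) <- NULL
  out
}
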