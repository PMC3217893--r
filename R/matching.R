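#' Build a k-mer index over extended models
#'
#' Indexes every `tag_len`-mer occurring on either strand of every
#' extended model. An observed tag looked up in the index returns all
#' positions where the tag matches the extended sequence exactly (sense)
#' or matches its reverse complement (antisense). Windows containing `N`
#' are omitted — they can never satisfy a 0-mismatch criterion.
#'
#' @param ems Named list of `extended_model` objects.
#' @param tag_len Tag length to index.
#' @return An object of class `tag_index`: `data.frame` with columns
#'   `kmer`, `model_id`, `tag_start` (0-based within the extended
#'   sequence), `strand`.
#' @export
build_tag_index <- function(ems, tag_len = 16L) {
  stopifnot(tag_len >= 1L)
  pieces <- lapply(ems, function(em) {
    seq <- em$ext_seq
    L <- nchar(seq)
    if (L < tag_len) return(NULL)
    starts <- seq_len(L - tag_len + 1L)
    kmers <- substring(seq, starts, starts + tag_len - 1L)
    rc_full <- revcomp(seq)
    rc_kmers <- substring(rc_full, L - starts - tag_len + 2L, L - starts + 1L)
    keep <- !grepl("N", kmers, fixed = TRUE)
    data.frame(
      kmer = c(kmers[keep], rc_kmers[keep]),
      model_id = em$model_id,
      tag_start = rep.int(starts[keep] - 1L, 2L),
      strand = rep(c("sense", "antisense"), each = sum(keep)),
      stringsAsFactors = FALSE
    )
  })
  idx <- do.call(rbind, pieces)
  if (is.null(idx)) {
    idx <- data.frame(kmer = character(0), model_id = character(0),
                      tag_start = integer(0), strand = character(0),
                      stringsAsFactors = FALSE)
  }
  rownames(idx) <- NULL
  structure(idx, class = c("tag_index", "data.frame"), tag_len = tag_len)
}

#' Match observed tags against the extended-model index
#'
#' Every indexed occurrence of every observed tag is reported. Alignment
#' totals count each sequenced tag once regardless of how many positions
#' or models it matches, mirroring per-million-aligned normalization, so
#' the totals are invariant to match multiplicity.
#'
#' @param table Tag-count table (`tag_id`, `tag_seq`, `count_CS`,
#'   `count_CG`).
#' @param index A `tag_index` from [build_tag_index()].
#' @return List with `matches` (`data.frame`: `tag_id`, `tag_seq`,
#'   `model_id`, `tag_start`, `strand`, `count_CS`, `count_CG`),
#'   `unmatched` (character vector of tag sequences absent from the
#'   index), and `aligned_total` (named numeric, raw counts of matched
#'   unique tags per library).
#' @export
match_tags <- function(table, index) {
  tl <- attr(index, "tag_len")
  if (!all(nchar(table$tag_seq) == tl)) {
    stop("all observed tags must have the indexed tag length")
  }
  hits <- index[index$kmer %in% table$tag_seq, , drop = FALSE]
  matched <- table$tag_seq %in% hits$kmer
  matches <- merge(
    table[matched, c("tag_id", "tag_seq", "count_CS", "count_CG"),
          drop = FALSE],
    data.frame(tag_seq = hits$kmer, model_id = hits$model_id,
               tag_start = hits$tag_start, strand = hits$strand,
               stringsAsFactors = FALSE),
    by = "tag_seq"
  )
  matches <- matches[order(matches$tag_seq, matches$model_id,
                           matches$tag_start, matches$strand), ,
                     drop = FALSE]
  rownames(matches) <- NULL
  list(
    matches = matches,
    unmatched = table$tag_seq[!matched],
    aligned_total = c(CS = sum(table$count_CS[matched]),
                      CG = sum(table$count_CG[matched]))
  )
}

#' Annotate matches with region and catalogue class
#'
#' Adds the positional [region label][classify_region] of each match and,
#' where the matched position coincides with a catalogue entry of that
#' model (catalogue coordinates are model-relative and are shifted by the
#' model's left flank), the catalogue `tag_class`; other positions are
#' labelled `"positional"`.
#'
#' @param matches Match table from [match_tags()].
#' @param ems Named list of `extended_model` objects.
#' @param catalogs Catalogue `data.frame` from [build_catalogs()].
#' @param tag_len Tag length.
#' @return `matches` with extra columns `region` and `tag_class`.
#' @export
annotate_matches <- function(matches, ems, catalogs, tag_len = 16L) {
  if (nrow(matches) == 0L) {
    matches$region <- character(0)
    matches$tag_class <- character(0)
    return(matches)
  }
  matches$region <- vapply(seq_len(nrow(matches)), function(i) {
    classify_region(matches$tag_start[i], tag_len,
                    ems[[matches$model_id[i]]])
  }, character(1))
  left <- vapply(ems, `[[`, integer(1), "left_len")
  cat_ext <- data.frame(
    model_id = catalogs$model_id,
    tag_start = catalogs$tag_start + unname(left[catalogs$model_id]),
    strand = catalogs$strand,
    tag_class = catalogs$tag_class,
    stringsAsFactors = FALSE
  )
  key <- function(d) paste(d$model_id, d$tag_start, d$strand, sep = "\r")
  idx <- match(key(matches), key(cat_ext))
  matches$tag_class <- ifelse(is.na(idx), "positional",
                              cat_ext$tag_class[idx])
  matches
}

#' Resolve the owning model of a multi-model tag
#'
#' A tag shared by several models is attributed to the model holding it as
#' its authentic catalogue entry — the tag adjacent to the 3'-most
#' restriction site of that model. If no matched model, or more than one,
#' holds the tag as authentic, the tag is ambiguous.
#'
#' @param tag_seq A single observed tag sequence.
#' @param matches Match table containing at least this tag.
#' @param catalogs Catalogue `data.frame` from [build_catalogs()].
#' @return List with `owner` (model id or `NA`), `status`
#'   (`"owned"`/`"ambiguous"`), and `candidates` (all matched models).
#' @export
resolve_owner <- function(tag_seq, matches, catalogs) {
  candidates <- unique(matches$model_id[matches$tag_seq == tag_seq])
  if (length(candidates) == 0L) stop("tag has no matches: ", tag_seq)
  auth <- catalogs[catalogs$tag_class == "authentic" &
                     catalogs$tag_seq == tag_seq &
                     catalogs$model_id %in% candidates, , drop = FALSE]
  owners <- unique(auth$model_id)
  if (length(owners) == 1L) {
    list(owner = owners, status = "owned", candidates = candidates)
  } else {
    list(owner = NA_character_, status = "ambiguous",
         candidates = candidates)
  }
}

#' Resolve owners for every matched tag
#'
#' @param matches Match table from [match_tags()].
#' @param catalogs Catalogue `data.frame`.
#' @return `data.frame` with one row per unique tag: `tag_seq`, `owner`
#'   (`NA` when ambiguous), `status`, `n_candidates`.
#' @export
resolve_owners <- function(matches, catalogs) {
  tags <- unique(matches$tag_seq)
  res <- lapply(tags, resolve_owner, matches = matches, catalogs = catalogs)
  data.frame(
    tag_seq = tags,
    owner = vapply(res, `[[`, character(1), "owner"),
    status = vapply(res, `[[`, character(1), "status"),
    n_candidates = vapply(res, function(r) length(r$candidates),
                          integer(1)),
    stringsAsFactors = FALSE
  )
}
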