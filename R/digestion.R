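#' Find restriction recognition sites in a sequence
#'
#' Returns the 0-based start position of every occurrence of the
#' recognition sequence, including overlapping occurrences. `N` in the
#' subject never matches.
#'
#' @param seq A single nucleotide string over `{A,C,G,T,N}`.
#' @param enzyme Recognition sequence over `{A,C,G,T}` (e.g. `"GATC"` for
#'   DpnII, `"CATG"` for NlaIII).
#' @return Strictly increasing integer vector of 0-based site starts.
#' @export
find_sites <- function(seq, enzyme) {
  stopifnot(is.character(seq), length(seq) == 1L)
  enzyme <- toupper(enzyme)
  if (!nzchar(enzyme) || !grepl("^[ACGT]+$", enzyme)) {
    stop("enzyme must be a non-empty string over {A,C,G,T}")
  }
  seq <- toupper(seq)
  if (nchar(seq) < nchar(enzyme)) return(integer(0))
  m <- Biostrings::matchPattern(enzyme, Biostrings::DNAString(seq))
  as.integer(BiocGenerics::start(m)) - 1L
}

#' Build the in-silico tag catalogue of one transcript model
#'
#' Digests the model cDNA at every recognition site and enumerates the tags
#' the protocol can emit. For each site with at least `tag_len` bases
#' downstream, a sense tag starts immediately after the site
#' (`tag_start = site_pos + nchar(enzyme)`); for each site with at least
#' `tag_len` bases upstream, an antisense tag covers the `tag_len` bases
#' ending at the site (`tag_start + tag_len = site_pos`), read on the
#' reverse complement. The sense tag at the 3'-most site with a full-length
#' downstream tag is the `authentic` tag — the one the 3'-anchored protocol
#' is designed to produce; remaining sense tags are `internal_sense`
#' (unwashed restriction fragments) and antisense tags are `antisense`
#' (inefficient restriction). Tags containing `N` are dropped; if the
#' dropped tag would have been authentic, authenticity falls back to the
#' next eligible site upstream.
#'
#' Non-palindromic recognition sequences are searched on both strands; for
#' palindromic sites such as GATC the two searches collapse to one.
#'
#' @param model_seq Model cDNA sequence (5'->3', sense strand).
#' @param model_id Model identifier attached to each entry.
#' @param cfg A [dge_config()].
#' @return `data.frame` with columns `model_id`, `tag_seq`, `site_pos`,
#'   `tag_start` (both 0-based in the model), `strand`
#'   (`sense`/`antisense`), `tag_class`
#'   (`authentic`/`internal_sense`/`antisense`). Zero rows if no site is
#'   eligible.
#' @export
build_tag_catalog <- function(model_seq, model_id, cfg = dge_config()) {
  k <- cfg$tag_len
  enz <- cfg$enzyme
  elen <- nchar(enz)
  seq <- toupper(model_seq)
  L <- nchar(seq)

  sites <- find_sites(seq, enz)
  if (!identical(enz, revcomp(enz))) {
    sites <- sort(unique(c(sites, find_sites(seq, revcomp(enz)))))
  }
  empty <- data.frame(model_id = character(0), tag_seq = character(0),
                      site_pos = integer(0), tag_start = integer(0),
                      strand = character(0), tag_class = character(0),
                      stringsAsFactors = FALSE)
  if (length(sites) == 0L) return(empty)

  sense_sites <- sites[sites + elen + k <= L]
  anti_sites <- sites[sites >= k]

  sense <- if (length(sense_sites)) {
    ts <- sense_sites + elen
    data.frame(model_id = model_id,
               tag_seq = substring(seq, ts + 1L, ts + k),
               site_pos = sense_sites, tag_start = ts,
               strand = "sense", tag_class = "internal_sense",
               stringsAsFactors = FALSE)
  } else empty
  anti <- if (length(anti_sites)) {
    ts <- anti_sites - k
    data.frame(model_id = model_id,
               tag_seq = revcomp(substring(seq, ts + 1L, ts + k)),
               site_pos = anti_sites, tag_start = ts,
               strand = "antisense", tag_class = "antisense",
               stringsAsFactors = FALSE)
  } else empty

  cat <- rbind(sense, anti)
  cat <- cat[!grepl("N", cat$tag_seq, fixed = TRUE), , drop = FALSE]
  is_sense <- cat$strand == "sense"
  if (any(is_sense)) {
    cat$tag_class[is_sense & cat$site_pos ==
                    max(cat$site_pos[is_sense])] <- "authentic"
  }
  cat <- cat[order(cat$site_pos, cat$strand), , drop = FALSE]
  rownames(cat) <- NULL
  cat
}

#' Build catalogues for a set of models
#'
#' @param cdna Named character vector of model cDNA sequences.
#' @param cfg A [dge_config()].
#' @return Row-bound catalogue `data.frame` over all models.
#' @export
build_catalogs <- function(cdna, cfg = dge_config()) {
  pieces <- lapply(names(cdna), function(id) {
    build_tag_catalog(cdna[[id]], id, cfg)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Extract the authentic tag of a single-model catalogue
#'
#' @param catalog Catalogue rows of one model.
#' @return The one-row `data.frame` of the authentic entry, or `NULL` when
#'   the model has no eligible site. Two authentic entries indicate an
#'   internal invariant breach and raise an error.
#' @export
authentic_tag <- function(catalog) {
  if (length(unique(catalog$model_id)) > 1L) {
    stop("catalogue spans more than one model")
  }
  hit <- catalog[catalog$tag_class == "authentic", , drop = FALSE]
  if (nrow(hit) == 0L) return(NULL)
  if (nrow(hit) > 1L) stop("internal error: multiple authentic entries")
  hit
}
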