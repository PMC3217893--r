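#' Generate a synthetic genome with transcript models
#'
#' Emits a deterministic (seeded) single-chromosome genome carrying
#' `n_models` unspliced transcript models separated by random intergenic
#' spacers, a configurable fraction on the minus strand, and a
#' configurable fraction of near-identical model pairs (>= 98% identity)
#' emulating paralogs. Every model cDNA is guaranteed to contain at least
#' one recognition site with a full-length tag downstream (resampled up to
#' `max_retries` times).
#'
#' @param n_models Number of models.
#' @param len_range Length range `(min, max)` of model cDNAs, bases.
#' @param gc GC content of generated sequence.
#' @param seed Integer seed; the generator is a pure function of its
#'   parameters and this seed.
#' @param neg_strand_frac Fraction of models on the minus strand.
#' @param paralog_frac Fraction of models duplicated as a near-identical
#'   pair (`round(paralog_frac * n_models)` pairs).
#' @param spacer_range Length range of intergenic spacers, bases.
#' @param enzyme,tag_len Site and tag length used for the eligibility
#'   guarantee.
#' @param max_retries Resampling bound per model before erroring.
#' @return List with `genome` (named character, one chromosome), `models`
#'   (annotation `data.frame` as from [read_models()]), `cdna` (named
#'   character), `paralog_pairs` (`data.frame` of source/copy ids).
#' @export
make_genome <- function(n_models = 50L, len_range = c(600L, 2000L),
                        gc = 0.35, seed = 1L, neg_strand_frac = 0.3,
                        paralog_frac = 0.1, spacer_range = c(300L, 700L),
                        enzyme = "GATC", tag_len = 16L,
                        max_retries = 50L) {
  stopifnot(n_models >= 1L, len_range[1] >= nchar(enzyme) + tag_len,
            gc > 0, gc < 1)
  with_seed(seed, {
    eligible <- function(s) {
      sites <- find_sites(s, enzyme)
      any(sites + nchar(enzyme) + tag_len <= nchar(s))
    }
    draw_model <- function() {
      for (i in seq_len(max_retries)) {
        L <- sample(len_range[1]:len_range[2], 1L)
        s <- .random_seq(L, gc)
        if (eligible(s)) return(s)
      }
      stop("could not generate an eligible model in ", max_retries,
           " tries")
    }
    cdna <- vapply(seq_len(n_models), function(i) draw_model(),
                   character(1))

    n_pairs <- round(paralog_frac * n_models)
    pairs <- data.frame(source = character(0), copy = character(0))
    if (n_pairs > 0) {
      if (2L * n_pairs > n_models) stop("paralog_frac too large")
      for (j in seq_len(n_pairs)) {
        tgt <- n_models - n_pairs + j
        for (i in seq_len(max_retries)) {
          cand <- .mutate_seq(cdna[j], rate = 0.01)
          if (eligible(cand)) break
          cand <- NA_character_
        }
        if (is.na(cand)) stop("could not generate an eligible paralog")
        cdna[tgt] <- cand
      }
    }
    ids <- sprintf("SynM%04d", seq_len(n_models) * 10L)
    names(cdna) <- ids
    if (n_pairs > 0) {
      pairs <- data.frame(source = ids[seq_len(n_pairs)],
                          copy = ids[n_models - n_pairs + seq_len(n_pairs)],
                          stringsAsFactors = FALSE)
    }
    strand <- ifelse(stats::runif(n_models) < neg_strand_frac, "-", "+")

    chrom_parts <- character(2L * n_models + 1L)
    gstart <- integer(n_models)
    gend <- integer(n_models)
    pos <- 0L
    for (i in seq_len(n_models)) {
      sp <- .random_seq(sample(spacer_range[1]:spacer_range[2], 1L), gc)
      chrom_parts[2L * i - 1L] <- sp
      pos <- pos + nchar(sp)
      gstart[i] <- pos
      seg <- if (strand[i] == "+") cdna[i] else revcomp(cdna[i])
      chrom_parts[2L * i] <- seg
      pos <- pos + nchar(seg)
      gend[i] <- pos
    }
    chrom_parts[2L * n_models + 1L] <-
      .random_seq(sample(spacer_range[1]:spacer_range[2], 1L), gc)
    genome <- c(chr1 = paste(chrom_parts, collapse = ""))

    models <- data.frame(
      model_id = ids, chrom = "chr1", strand = strand,
      genomic_start = gstart, genomic_end = gend,
      cdna_seq = unname(cdna), stringsAsFactors = FALSE
    )
    list(genome = genome, models = models, cdna = cdna,
         paralog_pairs = pairs)
  })
}

.random_seq <- function(L, gc) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

.mutate_seq <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  hit <- which(stats::runif(length(chars)) < rate)
  for (i in hit) {
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Define simulation ground truth with planted fold changes
#'
#' Per-model relative abundances are drawn log-normally for the CG
#' (baseline) library; a planted fraction of models receives a CS/CG fold
#' change (alternating over/under), and each library's abundances are
#' renormalized to sum to 1.
#'
#' @param model_ids Character vector of model ids.
#' @param seed Integer seed.
#' @param de_frac Fraction of models with a planted fold change.
#' @param de_fold Planted fold change (over-expressed models get
#'   `de_fold`, under-expressed `1/de_fold`).
#' @param class_props Named proportions over tag classes
#'   `(authentic, internal_sense, antisense)` summing to 1 — the artifact
#'   mixture of the simulated digestion chemistry.
#' @param depth Tags sequenced per library.
#' @param abund_sdlog Log-SD of the baseline abundance distribution.
#' @return List of class `sim_truth`: `abundance` (matrix models x
#'   `CS`/`CG`, columns summing to 1), `planted_fold` (named, pre-
#'   normalization CS/CG multiplier per model), `class_props`, `depth`,
#'   `seed`.
#' @export
make_sim_truth <- function(model_ids, seed = 1L, de_frac = 0.1,
                           de_fold = 4,
                           class_props = c(authentic = 0.80,
                                           internal_sense = 0.15,
                                           antisense = 0.05),
                           depth = 1e6, abund_sdlog = 1) {
  stopifnot(abs(sum(class_props) - 1) < 1e-9, de_fold > 1)
  n <- length(model_ids)
  with_seed(seed, {
    base <- stats::rlnorm(n, meanlog = 0, sdlog = abund_sdlog)
    mult <- stats::setNames(rep(1, n), model_ids)
    n_de <- round(de_frac * n)
    if (n_de > 0) {
      de_ids <- sample(model_ids, n_de)
      mult[de_ids] <- rep(c(de_fold, 1 / de_fold), length.out = n_de)
    }
    cg <- base / sum(base)
    cs_raw <- base * mult
    cs <- cs_raw / sum(cs_raw)
    structure(
      list(abundance = cbind(CS = cs, CG = stats::setNames(cg, model_ids)),
           planted_fold = mult,
           class_props = class_props, depth = depth, seed = seed),
      class = "sim_truth")
  })
}

#' Truncate annotated model 3' ends
#'
#' Moves the annotated 3' end of selected models upstream by the stated
#' number of bases — trimming the cDNA tail and shrinking the genomic span
#' on the 3' side — while the genome itself is unchanged, so tags derived
#' from the true transcript can fall beyond the annotated end. Emulates
#' prematurely truncated UTR annotations.
#'
#' @param models Annotation `data.frame`.
#' @param truncation Named numeric vector of bases to remove, keyed by
#'   model id (models absent from the vector are untouched).
#' @return Modified annotation `data.frame`.
#' @export
truncate_annotations <- function(models, truncation) {
  if (is.null(names(truncation))) stop("truncation must be named")
  unknown <- setdiff(names(truncation), models$model_id)
  if (length(unknown)) stop("unknown model ids: ",
                            paste(unknown, collapse = ", "))
  for (id in names(truncation)) {
    t <- as.integer(truncation[[id]])
    if (t < 0L) stop("truncation must be >= 0")
    if (t == 0L) next
    i <- which(models$model_id == id)
    L <- nchar(models$cdna_seq[i])
    if (t >= L) stop("truncation >= model length for ", id)
    models$cdna_seq[i] <- substr(models$cdna_seq[i], 1L, L - t)
    if (models$strand[i] == "+") {
      models$genomic_end[i] <- models$genomic_end[i] - t
    } else {
      models$genomic_start[i] <- models$genomic_start[i] + t
    }
  }
  models
}

#' Simulate DGE tag libraries from ground truth
#'
#' Builds the tag catalogue from the TRUE (untruncated) transcripts and
#' draws `depth` tags per library multinomially: a model is chosen by its
#' library abundance, then a catalogue entry by the artifact-class
#' proportions (classes a model lacks are renormalized away, and the
#' class's probability is spread uniformly over its entries). Unique-tag
#' counts are aggregated over entries sharing a tag sequence (paralogs).
#'
#' @param truth A [make_sim_truth()] object.
#' @param cdna Named character vector of TRUE transcript sequences.
#' @param cfg A [dge_config()].
#' @param seed Seed for the sampling step (defaults to the truth's seed).
#' @return List with `table` (tag-count `data.frame`: `tag_id`, `tag_seq`,
#'   `count_CS`, `count_CG`, ids assigned in decreasing total abundance)
#'   and `entries` (the catalogue with per-library entry counts — the
#'   per-entry ground truth).
#' @export
simulate_dge <- function(truth, cdna, cfg = dge_config(),
                         seed = truth$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  catalog <- build_catalogs(cdna, cfg)
  props <- truth$class_props
  w_class <- unname(props[catalog$tag_class])
  n_in_class <- stats::ave(rep(1, nrow(catalog)),
                           catalog$model_id, catalog$tag_class,
                           FUN = sum)
  avail <- tapply(catalog$tag_class, catalog$model_id, function(cl) {
    sum(props[unique(cl)])
  })
  entry_w <- w_class / n_in_class / unname(avail[catalog$model_id])

  counts <- with_seed(seed, {
    sapply(c("CS", "CG"), function(lib) {
      ab <- truth$abundance[catalog$model_id, lib]
      p <- ab * entry_w
      as.integer(stats::rmultinom(1, truth$depth, p / sum(p)))
    })
  })
  entries <- cbind(catalog,
                   data.frame(count_CS = counts[, "CS"],
                              count_CG = counts[, "CG"]))

  cs <- tapply(entries$count_CS, entries$tag_seq, sum)
  cg <- tapply(entries$count_CG, entries$tag_seq, sum)
  tab <- data.frame(tag_seq = names(cs),
                    count_CS = as.integer(cs),
                    count_CG = as.integer(cg),
                    stringsAsFactors = FALSE)
  tab <- tab[tab$count_CS + tab$count_CG > 0L, , drop = FALSE]
  tab <- tab[order(-(tab$count_CS + tab$count_CG), tab$tag_seq), ,
             drop = FALSE]
  tab <- data.frame(tag_id = sprintf("DGE%07d", seq_len(nrow(tab))),
                    tab, stringsAsFactors = FALSE)
  rownames(tab) <- NULL
  list(table = tab, entries = entries)
}

#' Simulate RNA-Seq read sets from ground truth
#'
#' Reads are drawn per library with model probability proportional to
#' abundance times the number of valid start positions
#' (`length - read_len + 1`), start uniform over valid positions, strand
#' random, and independent substitution errors at `error_rate` per base.
#'
#' @param truth A [make_sim_truth()] object.
#' @param cdna Named character vector of transcript sequences.
#' @param read_len Read length, bases.
#' @param depth Reads per library.
#' @param error_rate Per-base substitution rate.
#' @param seed Seed (defaults to the truth's seed).
#' @return List with `reads` (list of named character vectors `CS`, `CG`)
#'   and `sources` (per-read ground truth: library, read id, source model,
#'   start, strand).
#' @export
simulate_rnaseq <- function(truth, cdna, read_len = 75L, depth = 20000L,
                            error_rate = 0.001, seed = truth$seed) {
  stopifnot(inherits(truth, "sim_truth"))
  eff <- nchar(cdna) - read_len + 1L
  if (any(eff < 1L)) stop("read_len exceeds the shortest model length")
  with_seed(seed, {
    out <- list()
    src <- list()
    for (lib in c("CS", "CG")) {
      w <- truth$abundance[names(cdna), lib] * eff
      n_m <- as.integer(stats::rmultinom(1, depth, w / sum(w)))
      reads <- character(depth)
      starts <- integer(depth)
      strands <- character(depth)
      model_of <- character(depth)
      k <- 0L
      for (mi in seq_along(cdna)) {
        n <- n_m[mi]
        if (n == 0L) next
        st <- sample.int(eff[mi], n, replace = TRUE) - 1L
        sr <- ifelse(stats::runif(n) < 0.5, "sense", "antisense")
        sq <- substring(cdna[[mi]], st + 1L, st + read_len)
        rc <- sr == "antisense"
        if (any(rc)) sq[rc] <- revcomp(sq[rc])
        nerr <- stats::rbinom(n, read_len, error_rate)
        for (j in which(nerr > 0L)) {
          ch <- strsplit(sq[j], "")[[1]]
          at <- sample.int(read_len, nerr[j])
          for (pos in at) {
            ch[pos] <- sample(setdiff(c("A", "C", "G", "T"), ch[pos]), 1L)
          }
          sq[j] <- paste(ch, collapse = "")
        }
        idx <- k + seq_len(n)
        reads[idx] <- sq
        starts[idx] <- st
        strands[idx] <- sr
        model_of[idx] <- names(cdna)[mi]
        k <- k + n
      }
      ids <- sprintf("%s_r%06d", lib, seq_len(depth))
      names(reads) <- ids
      out[[lib]] <- reads
      src[[lib]] <- data.frame(library = lib, read_id = ids,
                               model_id = model_of, start = starts,
                               strand = strands, stringsAsFactors = FALSE)
    }
    list(reads = out, sources = do.call(rbind, src))
  })
}
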