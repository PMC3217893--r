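make_em <- function(id, seq, left = 0L, right = 0L) {
  structure(list(model_id = id, ext_seq = seq,
                 left_len = left,
                 core_len = nchar(seq) - left - right,
                 right_len = right),
            class = "extended_model")
}

test_that("the k-mer index records both strands of every window", {
  em <- make_em("m", "ACGTACGTA")
  idx <- build_tag_index(list(m = em), 4L)
  acgt <- idx[idx$kmer == "ACGT" & idx$strand == "sense", ]
  expect_setequal(acgt$tag_start, c(0L, 4L))
  # ACGT is its own reverse complement: same positions, antisense strand
  anti <- idx[idx$kmer == "ACGT" & idx$strand == "antisense", ]
  expect_setequal(anti$tag_start, c(0L, 4L))
  # TACG: one sense window plus the revcomp of the two CGTA windows
  expect_setequal(idx$tag_start[idx$kmer == "TACG" &
                                  idx$strand == "sense"], 3L)
  expect_setequal(idx$tag_start[idx$kmer == "TACG" &
                                  idx$strand == "antisense"], c(1L, 5L))
})

test_that("index size equals 2x windows minus N-containing ones", {
  set.seed(41)
  seqs <- c(a = random_dna(200), b = random_dna(157))
  seqs["b"] <- paste0(substr(seqs["b"], 1, 80), "N",
                      substr(seqs["b"], 82, 157))
  ems <- lapply(names(seqs), function(id) make_em(id, seqs[[id]]))
  names(ems) <- names(seqs)
  idx <- build_tag_index(ems, 16L)
  n_windows <- sum(nchar(seqs) - 16L + 1L)
  n_with_n <- sum(vapply(seqs, function(s) {
    starts <- seq_len(nchar(s) - 15L)
    sum(grepl("N", substring(s, starts, starts + 15L), fixed = TRUE))
  }, numeric(1)))
  expect_equal(nrow(idx), 2L * (n_windows - n_with_n))
})

test_that("match_tags reports every occurrence and verifies exactly", {
  set.seed(42)
  seqs <- c(m1 = random_dna(300), m2 = random_dna(300))
  # plant a shared 16-mer in both models
  shared <- random_dna(16)
  substr(seqs["m1"], 101, 116) <- shared
  substr(seqs["m2"], 201, 216) <- shared
  ems <- lapply(names(seqs), function(id) make_em(id, seqs[[id]]))
  names(ems) <- names(seqs)
  idx <- build_tag_index(ems, 16L)
  tab <- data.frame(tag_id = c("t1", "t2", "t3"),
                    tag_seq = c(shared, substr(seqs["m1"], 51, 66),
                                strrep("T", 16)),
                    count_CS = c(10L, 5L, 3L), count_CG = c(2L, 0L, 9L),
                    stringsAsFactors = FALSE)
  res <- match_tags(tab, idx)
  expect_equal(res$unmatched, strrep("T", 16))
  shared_hits <- res$matches[res$matches$tag_seq == shared &
                               res$matches$strand == "sense", ]
  expect_setequal(shared_hits$model_id, c("m1", "m2"))
  # aligned totals count each unique tag once, despite multi-matching
  expect_equal(res$aligned_total, c(CS = 15, CG = 2))
  # zero-mismatch soundness: re-verify every reported match directly
  for (i in seq_len(nrow(res$matches))) {
    r <- res$matches[i, ]
    window <- substr(ems[[r$model_id]]$ext_seq, r$tag_start + 1L,
                     r$tag_start + 16L)
    expect_equal(if (r$strand == "sense") window else oracle_rc(window),
                 r$tag_seq)
  }
})

test_that("planted tags are recovered at exactly their planted positions", {
  set.seed(43)
  seqs <- c(m1 = random_dna(500), m2 = random_dna(400))
  ems <- lapply(names(seqs), function(id) make_em(id, seqs[[id]]))
  names(ems) <- names(seqs)
  idx <- build_tag_index(ems, 16L)
  starts <- c(10L, 250L, 333L)
  tags <- substring(seqs["m1"], starts + 1L, starts + 16L)
  tab <- data.frame(tag_id = paste0("t", seq_along(tags)), tag_seq = tags,
                    count_CS = 1L, count_CG = 1L, stringsAsFactors = FALSE)
  res <- match_tags(tab, idx)
  # oracle: naive full scan of both models on both strands
  for (j in seq_along(tags)) {
    got <- res$matches[res$matches$tag_seq == tags[j], ]
    part <- function(id, st, strand) {
      if (length(st) == 0L) return(NULL)
      data.frame(model_id = id, tag_start = st, strand = strand,
                 stringsAsFactors = FALSE)
    }
    expect_oracle <- do.call(rbind, lapply(names(seqs), function(id) {
      s <- seqs[[id]]
      w <- seq_len(nchar(s) - 15L)
      win <- substring(s, w, w + 15L)
      rbind(part(id, which(win == tags[j]) - 1L, "sense"),
            part(id, which(oracle_rc(win) == tags[j]) - 1L, "antisense"))
    }))
    expect_equal(nrow(merge(got, expect_oracle)), nrow(got))
    expect_equal(nrow(got), nrow(expect_oracle))
  }
})

test_that("owner resolution follows the authentic-catalogue rule", {
  matches <- data.frame(
    tag_seq = rep("ACACACACACACACAC", 2),
    model_id = c("A", "B"), tag_start = c(5L, 9L), strand = "sense",
    stringsAsFactors = FALSE)
  catalogs <- data.frame(
    model_id = c("A", "B"), tag_seq = "ACACACACACACACAC",
    site_pos = c(1L, 5L), tag_start = c(5L, 9L), strand = "sense",
    tag_class = c("internal_sense", "authentic"),
    stringsAsFactors = FALSE)
  res <- resolve_owner("ACACACACACACACAC", matches, catalogs)
  expect_equal(res$owner, "B")
  expect_equal(res$status, "owned")

  catalogs$tag_class <- "authentic"  # tie: authentic in both
  expect_equal(resolve_owner("ACACACACACACACAC", matches,
                             catalogs)$status, "ambiguous")

  catalogs$tag_class <- "internal_sense"  # authentic nowhere
  res <- resolve_owner("ACACACACACACACAC", matches, catalogs)
  expect_equal(res$status, "ambiguous")
  expect_true(is.na(res$owner))
})

test_that("annotated matches carry region and catalogue class", {
  cfg <- dge_config()
  sim <- make_genome(n_models = 6, seed = 44)
  cat <- build_catalogs(sim$cdna, cfg)
  ems <- extend_models(sim$models, sim$genome, cfg$flank_bp)
  idx <- build_tag_index(ems, cfg$tag_len)
  auth <- cat[cat$tag_class == "authentic", ][1, ]
  tab <- data.frame(tag_id = "t1", tag_seq = auth$tag_seq,
                    count_CS = 7L, count_CG = 7L, stringsAsFactors = FALSE)
  res <- match_tags(tab, idx)
  ann <- annotate_matches(res$matches, ems, cat, cfg$tag_len)
  own_row <- ann[ann$model_id == auth$model_id & ann$strand == "sense", ]
  expect_equal(own_row$tag_class, "authentic")
  expect_equal(own_row$region, "model")
})
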