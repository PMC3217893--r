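cfg <- dge_config()

test_that("generators are pure functions of parameters and seed", {
  a <- make_genome(n_models = 10, seed = 7)
  b <- make_genome(n_models = 10, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a$genome,
                         make_genome(n_models = 10, seed = 8)$genome))

  truth <- make_sim_truth(a$models$model_id, seed = 7, depth = 5e4)
  d1 <- simulate_dge(truth, a$cdna, cfg)
  d2 <- simulate_dge(truth, a$cdna, cfg)
  expect_identical(d1, d2)

  r1 <- simulate_rnaseq(truth, a$cdna, depth = 500, seed = 7)
  r2 <- simulate_rnaseq(truth, a$cdna, depth = 500, seed = 7)
  expect_identical(r1, r2)
})

test_that("every generated model carries an eligible recognition site", {
  sim <- make_genome(n_models = 25, seed = 9)
  for (s in sim$cdna) {
    sites <- find_sites(s, cfg$enzyme)
    expect_true(any(sites + nchar(cfg$enzyme) + cfg$tag_len <= nchar(s)))
  }
  # annotation is consistent with the genomic sequence
  for (i in seq_len(nrow(sim$models))) {
    m <- sim$models[i, ]
    seg <- substr(sim$genome[[m$chrom]], m$genomic_start + 1L,
                  m$genomic_end)
    expect_equal(if (m$strand == "+") seg else oracle_rc(seg), m$cdna_seq)
  }
})

test_that("paralog pairs are near-identical and correctly booked", {
  sim <- make_genome(n_models = 50, seed = 10, paralog_frac = 0.2)
  expect_equal(nrow(sim$paralog_pairs), 10L)
  for (i in seq_len(nrow(sim$paralog_pairs))) {
    a <- strsplit(sim$cdna[[sim$paralog_pairs$source[i]]], "")[[1]]
    b <- strsplit(sim$cdna[[sim$paralog_pairs$copy[i]]], "")[[1]]
    expect_equal(length(a), length(b))
    expect_gte(mean(a == b), 0.98)
  }
})

test_that("truth abundances are normalized with planted folds applied", {
  sim <- make_genome(n_models = 40, seed = 11)
  truth <- make_sim_truth(sim$models$model_id, seed = 11, de_frac = 0.25,
                          de_fold = 4)
  expect_equal(colSums(truth$abundance), c(CS = 1, CG = 1))
  expect_equal(sum(truth$planted_fold != 1), 10L)
  # pre-normalization multiplier is recovered from the abundance columns
  ratio <- (truth$abundance[, "CS"] / truth$abundance[, "CG"])
  rel <- ratio / ratio[truth$planted_fold == 1][1]
  expect_equal(unname(rel[names(truth$planted_fold)]),
               unname(truth$planted_fold), tolerance = 1e-9)
})

test_that("truncation trims annotation but never the genome", {
  sim <- make_genome(n_models = 8, seed = 12)
  same <- truncate_annotations(sim$models,
                               setNames(0L, sim$models$model_id[1]))
  expect_identical(same, sim$models)
  t100 <- setNames(100L, sim$models$model_id[1])
  tr <- truncate_annotations(sim$models, t100)
  i <- 1L
  expect_equal(nchar(tr$cdna_seq[i]), nchar(sim$models$cdna_seq[i]) - 100L)
  span <- tr$genomic_end[i] - tr$genomic_start[i]
  expect_equal(span, sim$models$genomic_end[i] -
                 sim$models$genomic_start[i] - 100L)
  expect_error(
    truncate_annotations(sim$models,
                         setNames(10000L, sim$models$model_id[1])),
    "truncation")
  expect_error(truncate_annotations(sim$models, setNames(5L, "nope")),
               "unknown")
})

test_that("a displaced authentic tag lands in the right junction/flank", {
  sim <- make_genome(n_models = 15, seed = 13)
  cat <- build_catalogs(sim$cdna, cfg)
  auth <- cat[cat$tag_class == "authentic", ]
  # pick a model whose authentic tag sits within 84 bp of the 3' end so a
  # 100-bp truncation displaces it but keeps it within the 250-bp flank
  gap <- nchar(sim$cdna[auth$model_id]) - (auth$tag_start + cfg$tag_len)
  pick <- auth[gap < 84, ][1, ]
  expect_false(is.na(pick$model_id))
  tr <- truncate_annotations(sim$models, setNames(100L, pick$model_id))
  ems <- extend_models(tr, sim$genome, cfg$flank_bp)
  em <- ems[[pick$model_id]]
  pos <- em$left_len + pick$tag_start
  expect_true(classify_region(pos, cfg$tag_len, em) %in%
                c("junction_right", "extra_right"))
  # and the flank sequence still spells the tag: it is matchable
  expect_equal(substr(em$ext_seq, pos + 1L, pos + cfg$tag_len),
               pick$tag_seq)
})

test_that("a pure-authentic mixture emits only authentic tags at expected rates", {
  sim <- make_genome(n_models = 20, seed = 14)
  truth <- make_sim_truth(sim$models$model_id, seed = 14, de_frac = 0,
                          class_props = c(authentic = 1,
                                          internal_sense = 0,
                                          antisense = 0),
                          depth = 2e5)
  dge <- simulate_dge(truth, sim$cdna, cfg)
  cat <- build_catalogs(sim$cdna, cfg)
  auth_seqs <- cat$tag_seq[cat$tag_class == "authentic"]
  expect_true(all(dge$table$tag_seq %in% auth_seqs))
  # observed authentic count within 3 binomial s.e. of depth * abundance
  ent <- dge$entries[dge$entries$tag_class == "authentic", ]
  exp_n <- truth$depth * truth$abundance[ent$model_id, "CS"]
  se <- sqrt(exp_n * (1 - truth$abundance[ent$model_id, "CS"]))
  expect_true(all(abs(ent$count_CS - exp_n) <= pmax(3 * se, 5)))
})

test_that("extreme planted ratios leave the mutant library nearly empty", {
  ids <- sprintf("m%02d", 1:20)
  ab_cs <- c(0.5, rep(0.5 / 19, 19))
  ab_cg <- c(0.5 / 2400, rep((1 - 0.5 / 2400) / 19, 19))
  truth <- structure(list(
    abundance = cbind(CS = setNames(ab_cs, ids), CG = setNames(ab_cg, ids)),
    planted_fold = setNames(c(2400, rep(1, 19)), ids),
    class_props = c(authentic = 1, internal_sense = 0, antisense = 0),
    depth = 1e4, seed = 15), class = "sim_truth")
  sim <- make_genome(n_models = 20, seed = 15)
  names(truth$abundance) <- NULL
  rownames(truth$abundance) <- sim$models$model_id
  dge <- simulate_dge(truth, sim$cdna, cfg)
  ent <- dge$entries[dge$entries$tag_class == "authentic", ]
  first <- ent[ent$model_id == sim$models$model_id[1], ]
  # Poisson tail at rate depth * abundance ~ 2: 5 or fewer w.h.p.
  expect_lte(first$count_CG, 5L)
  expect_gt(first$count_CS, 3000L)
})

test_that("error-free simulated reads map back perfectly to their source", {
  sim <- make_genome(n_models = 10, seed = 16)
  truth <- make_sim_truth(sim$models$model_id, seed = 16)
  rs <- simulate_rnaseq(truth, sim$cdna, read_len = 75L, depth = 300L,
                        error_rate = 0, seed = 16)
  src <- rs$sources[rs$sources$library == "CS", ]
  for (i in sample(nrow(src), 40)) {
    r <- rs$reads$CS[[src$read_id[i]]]
    window <- substr(sim$cdna[[src$model_id[i]]], src$start[i] + 1L,
                     src$start[i] + 75L)
    expect_equal(if (src$strand[i] == "sense") r else oracle_rc(r),
                 window)
  }
})

test_that("read counts scale with length weighting while RPKM stays flat", {
  # two models, equal abundance, lengths ~L and ~2L
  cdna <- c(a = random_dna(800), b = random_dna(1600))
  truth <- structure(list(
    abundance = cbind(CS = c(a = 0.5, b = 0.5), CG = c(a = 0.5, b = 0.5)),
    planted_fold = c(a = 1, b = 1),
    class_props = c(authentic = 1, internal_sense = 0, antisense = 0),
    depth = 1000, seed = 17), class = "sim_truth")
  rs <- simulate_rnaseq(truth, cdna, read_len = 75L, depth = 6000L,
                        error_rate = 0, seed = 17)
  n <- table(rs$sources$model_id[rs$sources$library == "CS"])
  w <- c(800, 1600) - 75 + 1
  expected_b <- 6000 * w[2] / sum(w)
  se <- sqrt(6000 * (w[2] / sum(w)) * (w[1] / sum(w)))
  expect_lt(abs(n[["b"]] - expected_b), 3 * se)
  r <- rpkm(as.numeric(n), nchar(cdna)[names(n)], 6000)
  expect_equal(r[[1]] / r[[2]], w[1] / w[2] * 1600 / 800, tolerance = 0.2)
})
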