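#' Fold-change screen with an expression floor
#'
#' Classifies each record as over-expressed in CS when the CS/CG ratio is
#' at least `fold_threshold`, under-expressed when at most
#' `1/fold_threshold`, and unchanged otherwise. A record passes the screen
#' when it has a direction and the larger of its two library values
#' reaches `min_cpm`; requiring only one library to reach the floor keeps
#' genes silenced in one line (ratio `+Inf`) screenable.
#'
#' @param records Expression records in cpm units (`id`, `value_CS`,
#'   `value_CG`, `fold_change`).
#' @param cfg A [dge_config()].
#' @return `data.frame` with `id`, `cpm_CS`, `cpm_CG`, `fold_change`,
#'   `direction` (`over_in_CS`/`under_in_CS`/`none`), `passes_screen`.
#' @export
fc_screen <- function(records, cfg = dge_config()) {
  fc <- if ("fold_change" %in% names(records)) records$fold_change else
    fold_change(records$value_CS, records$value_CG)
  direction <- rep("none", length(fc))
  direction[!is.na(fc) & fc >= cfg$fold_threshold] <- "over_in_CS"
  direction[!is.na(fc) & fc <= 1 / cfg$fold_threshold] <- "under_in_CS"
  floor_ok <- pmax(records$value_CS, records$value_CG) >= cfg$min_cpm
  data.frame(
    id = records$id,
    cpm_CS = records$value_CS,
    cpm_CG = records$value_CG,
    fold_change = fc,
    direction = direction,
    passes_screen = direction != "none" & floor_ok,
    stringsAsFactors = FALSE
  )
}

#' Median-of-ratios size factors
#'
#' For each library, the size factor is the median over ids (restricted to
#' ids with positive counts in every library) of the ratio of the id's
#' count to its across-library geometric mean; factors are rescaled so
#' their geometric mean is 1.
#'
#' @param counts Integer matrix, ids x libraries (2 columns).
#' @return Numeric vector of size factors, one per column.
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  pos <- rowSums(counts > 0) == ncol(counts)
  if (!any(pos)) stop("no id has positive counts in every library")
  lgm <- rowMeans(log(counts[pos, , drop = FALSE]))
  s <- exp(apply(log(counts[pos, , drop = FALSE]) - lgm, 2, stats::median))
  s / exp(mean(log(s)))
}

#' Blind negative-binomial fit for two unreplicated libraries
#'
#' Treats the two libraries as replicates of one condition (most genes in
#' near-isogenic lines are assumed similarly expressed): per id the base
#' mean is the average of size-factor-normalized counts, the raw
#' dispersion comes from the two-sample variance after subtracting the
#' shot-noise term, and a parametric dispersion function
#' `alpha(q) = a0/q + a1` is fitted to the raw dispersions by least
#' squares, with negative fitted values clamped to zero.
#'
#' @param counts Integer matrix, ids x 2 libraries.
#' @return List of class `nb_fit`: `size_factors`, `q` (base means),
#'   `a0`, `a1`, `alpha` (fitted per-id dispersions, clamped at 0).
#' @export
nb_fit <- function(counts) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2L)
  s <- size_factors(counts)
  x <- sweep(counts, 2, s, "/")
  q <- rowMeans(x)
  w <- (x[, 1] - x[, 2])^2 / 2          # two-sample variance
  z <- q * mean(1 / s)                  # shot-noise term
  araw <- ifelse(q > 0, (w - z) / q^2, NA_real_)
  usable <- is.finite(araw) & q > 0
  if (sum(usable) < 2L) stop("too few ids to fit a dispersion function")
  fit <- stats::lm(araw[usable] ~ I(1 / q[usable]))
  a1 <- unname(stats::coef(fit)[1])
  a0 <- unname(stats::coef(fit)[2])
  alpha <- pmax(0, a1 + a0 / q)
  alpha[q == 0] <- 0
  structure(list(size_factors = s, q = q, a0 = a0, a1 = a1, alpha = alpha),
            class = "nb_fit")
}

#' Conditional negative-binomial test for two unreplicated libraries
#'
#' For each id with counts `(k_CS, k_CG)` the test conditions on the pair
#' total `T`: under independent NB models with means `s_j * q` and common
#' dispersion `alpha(q)`, the two-sided p-value sums the conditional
#' probabilities of all splits `(a, T - a)` whose joint probability does
#' not exceed that of the observed split. Summation is done in log space.
#' For totals above `cap` the enumeration is restricted to a window of
#' +/- 20 conditional standard deviations around the conditional mean and
#' renormalized (a normal-range approximation; the omitted tail mass is
#' negligible at that width).
#'
#' @param counts Integer matrix, ids x 2 libraries.
#' @param fit An [nb_fit()]; refitted from `counts` when omitted.
#' @param cap Total above which the windowed enumeration is used.
#' @return Numeric vector of p-values (`NA` for all-zero pairs).
#' @export
nb_test_noreps <- function(counts, fit = NULL, cap = 10000L) {
  counts <- as.matrix(counts)
  stopifnot(ncol(counts) == 2L)
  if (is.null(fit)) fit <- nb_fit(counts)
  s <- fit$size_factors
  vapply(seq_len(nrow(counts)), function(i) {
    k1 <- counts[i, 1]; k2 <- counts[i, 2]
    tot <- k1 + k2
    if (tot == 0) return(NA_real_)
    q <- fit$q[i]
    alpha <- fit$alpha[i]
    mu1 <- s[1] * q; mu2 <- s[2] * q
    p1 <- mu1 / (mu1 + mu2)
    if (tot > cap) {
      v <- tot * p1 * (1 - p1) * (1 + alpha * max(mu1, mu2))
      half <- ceiling(20 * sqrt(max(v, 1)))
      centre <- round(tot * p1)
      lo <- max(0, min(centre - half, k1))
      hi <- min(tot, max(centre + half, k1))
      a <- lo:hi
    } else {
      a <- 0:tot
    }
    lp <- if (alpha > 0) {
      stats::dnbinom(a, size = 1 / alpha, mu = mu1, log = TRUE) +
        stats::dnbinom(tot - a, size = 1 / alpha, mu = mu2, log = TRUE)
    } else {
      stats::dpois(a, mu1, log = TRUE) +
        stats::dpois(tot - a, mu2, log = TRUE)
    }
    obs <- lp[a == k1]
    keep <- lp <= obs + 1e-7
    min(1, exp(logsumexp(lp[keep]) - logsumexp(lp)))
  }, numeric(1))
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' `NA` p-values propagate to `NA` adjusted values.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]` (`NA` allowed).
#' @return Adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  ok <- is.na(p_values) | (p_values >= 0 & p_values <= 1)
  if (!all(ok)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Trend concordance between DGE and RNA-Seq results
#'
#' Joins tag-level DGE results to model-level RNA-Seq results through the
#' tag-to-model owner map and scores each shared id as agreeing when both
#' fold changes lie on the same side of 1 (both above or both below). Ids
#' where either fold change is undefined (`NA`, e.g. zero expression in
#' both libraries of one platform) are excluded from the denominator and
#' counted separately.
#'
#' @param dge Tag-level screen results from [fc_screen()] (`id` = tag id).
#' @param rnaseq Model-level results (`id` = model id) with a
#'   `fold_change` column.
#' @param id_map `data.frame` with columns `tag_id`, `model_id` mapping
#'   tags to their owning model.
#' @return List with `table` (per-id comparison), `n_comparable`,
#'   `n_excluded`, `fraction_agree`.
#' @export
concordance <- function(dge, rnaseq, id_map) {
  d <- merge(data.frame(tag_id = dge$id, fc_dge = dge$fold_change,
                        stringsAsFactors = FALSE),
             id_map[, c("tag_id", "model_id")], by = "tag_id")
  d <- merge(d, data.frame(model_id = rnaseq$id,
                           fc_rnaseq = rnaseq$fold_change,
                           stringsAsFactors = FALSE), by = "model_id")
  comparable <- !is.na(d$fc_dge) & !is.na(d$fc_rnaseq)
  d$agree <- ifelse(comparable,
                    (d$fc_dge > 1 & d$fc_rnaseq > 1) |
                      (d$fc_dge < 1 & d$fc_rnaseq < 1),
                    NA)
  list(
    table = d[, c("tag_id", "model_id", "fc_dge", "fc_rnaseq", "agree")],
    n_comparable = sum(comparable),
    n_excluded = sum(!comparable),
    fraction_agree = if (any(comparable)) {
      sum(d$agree[comparable]) / sum(comparable)
    } else NA_real_
  )
}
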