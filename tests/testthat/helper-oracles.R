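# Independent brute-force oracles, deliberately implemented with different
# primitives than the package (window scans and base-R string ops).

oracle_rc <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGTN", "TGCAN", s), "")[[1]]),
          collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# All 0-based occurrences of `pat` in `seq` by scanning every window.
oracle_sites <- function(seq, pat) {
  L <- nchar(seq); k <- nchar(pat)
  if (L < k) return(integer(0))
  starts <- seq_len(L - k + 1L)
  which(substring(seq, starts, starts + k - 1L) == pat) - 1L
}

# Quadratic catalogue scanner: every window, every class, by first
# principles.
oracle_catalog <- function(seq, enzyme, tag_len) {
  seq <- toupper(seq)
  L <- nchar(seq)
  elen <- nchar(enzyme)
  sites <- oracle_sites(seq, enzyme)
  if (oracle_rc(enzyme) != enzyme) {
    sites <- sort(unique(c(sites, oracle_sites(seq, oracle_rc(enzyme)))))
  }
  rows <- list()
  for (s in sites) {
    if (s + elen + tag_len <= L) {
      tag <- substr(seq, s + elen + 1L, s + elen + tag_len)
      if (!grepl("N", tag, fixed = TRUE)) {
        rows[[length(rows) + 1L]] <- data.frame(
          site_pos = s, tag_start = s + elen, strand = "sense",
          tag_seq = tag, stringsAsFactors = FALSE)
      }
    }
    if (s >= tag_len) {
      tag <- oracle_rc(substr(seq, s - tag_len + 1L, s))
      if (!grepl("N", tag, fixed = TRUE)) {
        rows[[length(rows) + 1L]] <- data.frame(
          site_pos = s, tag_start = s - tag_len, strand = "antisense",
          tag_seq = tag, stringsAsFactors = FALSE)
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(site_pos = integer(0), tag_start = integer(0),
                      strand = character(0), tag_seq = character(0),
                      tag_class = character(0), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out$tag_class <- ifelse(out$strand == "antisense", "antisense",
                          "internal_sense")
  sense <- out$strand == "sense"
  if (any(sense)) {
    out$tag_class[sense & out$site_pos == max(out$site_pos[sense])] <-
      "authentic"
  }
  out[order(out$site_pos, out$strand), , drop = FALSE]
}

# Exhaustive ungapped mapper: every model, every offset, both
# orientations, Hamming distance by character comparison.
oracle_map <- function(reads, models, max_mm) {
  rows <- list()
  for (ri in seq_along(reads)) {
    for (orient in c("sense", "antisense")) {
      r <- if (orient == "sense") reads[[ri]] else oracle_rc(reads[[ri]])
      rchars <- strsplit(r, "")[[1]]
      lr <- length(rchars)
      for (mi in seq_along(models)) {
        mchars <- strsplit(models[[mi]], "")[[1]]
        if (length(mchars) < lr) next
        for (st in 0:(length(mchars) - lr)) {
          d <- sum(mchars[(st + 1):(st + lr)] != rchars)
          if (d <= max_mm) {
            rows[[length(rows) + 1L]] <- data.frame(
              read_id = names(reads)[ri], model_id = names(models)[mi],
              start = st, strand = orient, mismatches = d,
              stringsAsFactors = FALSE)
          }
        }
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(read_id = character(0), model_id = character(0),
                      start = integer(0), strand = character(0),
                      mismatches = integer(0), stringsAsFactors = FALSE))
  }
  do.call(rbind, rows)
}

# Conditional binomial split test: closed-form Poisson-limit oracle for
# the NB no-replicate test.
oracle_binom_test <- function(k1, k2, s1, s2) {
  tot <- k1 + k2
  if (tot == 0) return(NA_real_)
  pr <- s1 / (s1 + s2)
  lp <- dbinom(0:tot, tot, pr, log = TRUE)
  obs <- lp[k1 + 1L]
  min(1, sum(exp(lp[lp <= obs + 1e-7])))
}

random_dna <- function(L, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), L, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}

sort_catalog <- function(x) {
  x <- x[order(x$site_pos, x$strand, x$tag_start),
         c("site_pos", "tag_start", "strand", "tag_seq", "tag_class")]
  rownames(x) <- NULL
  x
}
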