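# Independent oracles used to validate the package implementations.
# These deliberately share no code with the package internals.

# O(L^2) brute-force ORF scan: for every position, test for ATG, walk
# codon by codon to the first in-frame stop, then walk base by base to the
# next ATG in any frame.
brute_force_orfs <- function(seq) {
  seq <- toupper(seq)
  L <- nchar(seq)
  codon_at <- function(i) substr(seq, i + 1, i + 3) # 0-based offset
  rows <- list()
  if (L >= 3) {
    for (a in 0:(L - 3)) {
      if (codon_at(a) != "ATG") next
      cds_end <- NA
      j <- a + 3
      while (j + 3 <= L) {
        if (codon_at(j) %in% c("TAA", "TAG", "TGA")) {
          cds_end <- j + 3
          break
        }
        j <- j + 3
      }
      if (is.na(cds_end)) next
      utr_end <- L
      k <- cds_end
      while (k + 3 <= L) {
        if (codon_at(k) == "ATG") {
          utr_end <- k
          break
        }
        k <- k + 1
      }
      rows[[length(rows) + 1]] <- data.frame(
        cds_start = as.integer(a), cds_end = as.integer(cds_end),
        utr3_start = as.integer(cds_end), utr3_end = as.integer(utr_end))
    }
  }
  if (!length(rows)) {
    return(data.frame(cds_start = integer(0), cds_end = integer(0),
                      utr3_start = integer(0), utr3_end = integer(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

random_transcript <- function(len) {
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE,
               prob = c(0.3, 0.2, 0.2, 0.3)), collapse = "")
}

# exhaustive two-sided Mann-Whitney permutation p over all label splits
mw_perm_p <- function(values, membership) {
  n <- length(values)
  m <- sum(membership)
  r <- rank(values)
  u_obs <- sum(r[membership]) - m * (m + 1) / 2
  splits <- utils::combn(n, m)
  u_all <- colSums(matrix(r[splits], nrow = m)) - m * (m + 1) / 2
  eps <- 1e-9
  min(1, 2 * min(mean(u_all <= u_obs + eps), mean(u_all >= u_obs - eps)))
}

# hand application of the Benjamini-Hochberg step-up rule
bh_step_up <- function(p) {
  m <- length(p)
  o <- order(p)
  qs <- p[o] * m / seq_len(m)
  qs <- rev(cummin(rev(qs)))
  q <- numeric(m)
  q[o] <- pmin(1, qs)
  q
}

# exhaustive permutation p for the pooled-variance t test (small groups)
ttest_perm_p <- function(a, b) {
  pooled <- c(a, b)
  n <- length(pooled)
  na <- length(a)
  t_of <- function(idx) {
    x <- pooled[idx]
    y <- pooled[-idx]
    sp <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
      (length(x) + length(y) - 2)
    if (sp == 0) return(0)
    (mean(x) - mean(y)) / sqrt(sp * (1 / length(x) + 1 / length(y)))
  }
  t_obs <- abs(t_of(seq_len(na)))
  splits <- utils::combn(n, na)
  t_all <- abs(apply(splits, 2, t_of))
  mean(t_all >= t_obs - 1e-12)
}

# small candidate table used across selection tests
make_candidates <- function() {
  data.frame(
    gene_id = paste0("linc", 1:6),
    chrom = "chr1",
    start = c(100, 1000, 2000, 3000, 4000, 5000),
    end = c(600, 1500, 2500, 3500, 4500, 5500),
    csf_score = c(-250, -205, -200, -14771, NA, -900),
    masspec_tags = c(0, 2, 1, 3, 0, 1),
    has_human_synteny = c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE),
    has_k4me3_k36me3 = TRUE,
    stringsAsFactors = FALSE
  )
}
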