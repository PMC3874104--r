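# Rank-based gene-set enrichment: genes ordered by a signed differential
# test statistic, each set compared against the rest of the ranking with a
# Mann-Whitney U test (exact null distribution for small problems),
# Benjamini-Hochberg correction across the collection, and a standardized
# set-mean z-score giving the direction. Guilt-by-association feeds the
# same machinery with Pearson correlation profiles.

#' Rank genes by differential test statistic
#'
#' Descending by `test_stat`; ties broken lexicographically by gene id so
#' the ordering is deterministic. Rows whose status is not `OK` (e.g.
#' `NOTEST`) are dropped.
#'
#' @param diff Differential table as from [read_diff_table()] or
#'   [gen_diff_table()].
#' @return data.frame with columns `gene_id`, `test_stat`, ordered.
#' @export
rank_by_statistic <- function(diff) {
  ok <- diff[diff$status == "OK", , drop = FALSE]
  if (!nrow(ok)) stop("no OK-status records to rank")
  ok <- ok[order(-ok$test_stat, ok$gene_id), , drop = FALSE]
  rownames(ok) <- NULL
  ok[, c("gene_id", "test_stat")]
}

# exact Mann-Whitney null pmf: distribution of U over all C(m+n2, m)
# equally likely subsets of untied values, via the Gaussian-binomial
# recurrence [j,k]_q = [j-1,k]_q + q^(j-k) [j-1,k-1]_q. Counts are exact in
# doubles up to astronomically large C(n, m); returned as probabilities.
.mw_cache <- new.env(parent = emptyenv())

mw_exact_pmf <- function(m, n2) {
  key <- paste(m, n2)
  hit <- .mw_cache[[key]]
  if (!is.null(hit)) return(hit)
  dp <- vector("list", m + 1L)
  dp[[1L]] <- 1
  for (k in seq_len(m)) dp[[k + 1L]] <- numeric(0)
  for (j in seq_len(m + n2)) {
    for (k in rev(seq_len(min(j, m)))) {
      a <- dp[[k + 1L]]
      b <- dp[[k]]
      shift <- j - k
      out <- numeric(max(length(a), shift + length(b)))
      if (length(a)) out[seq_along(a)] <- a
      if (length(b)) {
        idx <- shift + seq_along(b)
        out[idx] <- out[idx] + b
      }
      dp[[k + 1L]] <- out
    }
  }
  pmf <- dp[[m + 1L]] / sum(dp[[m + 1L]])
  if (length(ls(.mw_cache)) > 30L) rm(list = ls(.mw_cache), envir = .mw_cache)
  .mw_cache[[key]] <- pmf
  pmf
}

#' Mann-Whitney U test of a gene set against the background
#'
#' Compares the scores of set members with those of non-members. `U`
#' counts member-over-background pairs (ties contribute 1/2). The p-value
#' is two-sided. With `method = "auto"` the exact null distribution is
#' used when `|set| * |background| <= 10000`: for untied scores via the
#' in-package exact U distribution, for tied scores via exhaustive
#' enumeration of all label splits when `choose(n, m) <= 20000`. Otherwise
#' the normal approximation with tie correction and continuity correction
#' is used. When every score is identical the test is degenerate and
#' `p = 1` by convention.
#'
#' @param values Numeric score vector (all genes).
#' @param membership Logical vector, `TRUE` for set members.
#' @param method `"auto"`, `"exact"` or `"normal"`.
#' @return List with `U`, `p`, and `method` (the branch actually used).
#' @export
mannwhitney_set_test <- function(values, membership, method = "auto") {
  stopifnot(length(values) == length(membership), is.logical(membership))
  m <- sum(membership)
  n <- length(values)
  n2 <- n - m
  if (m < 1L || n2 < 1L) stop("need 1 <= |set| < n")
  r <- rank(values)
  U <- sum(r[membership]) - m * (m + 1) / 2
  if (all(values == values[1L])) {
    return(list(U = U, p = 1, method = "degenerate"))
  }
  tied <- anyDuplicated(values) > 0L
  use_exact <- switch(method,
                      auto = m * n2 <= 10000,
                      exact = TRUE,
                      normal = FALSE,
                      stop("unknown method"))
  if (use_exact && !tied) {
    pmf <- mw_exact_pmf(m, n2)
    cdf <- cumsum(pmf)
    lower <- cdf[U + 1L]
    upper <- if (U >= 1) 1 - cdf[U] else 1
    return(list(U = U, p = min(1, 2 * min(lower, upper)), method = "exact"))
  }
  if (use_exact && tied && choose(n, m) <= 20000) {
    splits <- utils::combn(n, m)
    u_all <- colSums(matrix(r[splits], nrow = m)) - m * (m + 1) / 2
    eps <- 1e-9
    p <- min(1, 2 * min(mean(u_all <= U + eps), mean(u_all >= U - eps)))
    return(list(U = U, p = p, method = "exact_permutation"))
  }
  # tie-corrected normal approximation with continuity correction
  tab <- table(r)
  tie_term <- sum(tab^3 - tab) / (n * (n - 1))
  sigma2 <- (m * n2 / 12) * ((n + 1) - tie_term)
  mu <- m * n2 / 2
  z <- (U - mu - 0.5 * sign(U - mu)) / sqrt(sigma2)
  list(U = U, p = min(1, 2 * pnorm(-abs(z))), method = "normal")
}

#' Benjamini-Hochberg false-discovery-rate correction
#'
#' Step-up adjustment `q_(i) = min_{j >= i} (m * p_(j) / j)`, returned in
#' the input order.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of q-values, same length and order.
#' @export
bh_correct <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  p.adjust(p_values, method = "BH")
}

#' Standardized set-mean z-score
#'
#' `z = (mean_set - mean_all) / (sd_all / sqrt(|set|))` with `sd_all` the
#' population standard deviation over all values. Positive z means the set
#' sits above the background; the formula is invariant under affine
#' transforms `v -> a v + b`, `a > 0`.
#'
#' @param values Numeric score vector.
#' @param membership Logical membership vector.
#' @return Numeric z, or `NA` when the background standard deviation is 0.
#' @export
set_zscore <- function(values, membership) {
  stopifnot(length(values) == length(membership))
  m <- sum(membership)
  stopifnot(m >= 1)
  sd_all <- sqrt(mean((values - mean(values))^2))
  if (sd_all == 0) return(NA_real_)
  (mean(values[membership]) - mean(values)) / (sd_all / sqrt(m))
}

#' Rank-based gene-set enrichment over a differential table
#'
#' Genes are rank-ordered by their differential test statistic; each gene
#' set is mapped into the ranking and tested with
#' [mannwhitney_set_test()]; p-values are Benjamini-Hochberg corrected
#' across the collection; the standardized set-mean z-score gives the
#' direction of enrichment (`+1` up, `-1` down). Sets mapping fewer than
#' `min_set_size` genes are skipped with a reason and excluded from the
#' correction.
#'
#' @param diff Differential table (`gene_id`, `test_stat`, `status`, ...).
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param q_threshold Sets with `q` below this are flagged `significant`.
#' @param min_set_size Minimum mapped members for a set to be tested.
#' @return data.frame with one row per set: `set`, `n_in_set`, `U`, `p`,
#'   `q`, `z`, `direction`, `significant`, `reason` (`NA` for tested
#'   sets).
#' @export
gsea <- function(diff, collection, q_threshold = 0.001, min_set_size = 5) {
  ranked <- rank_by_statistic(diff)
  values <- ranked$test_stat
  res <- data.frame(set = names(collection),
                    n_in_set = NA_integer_, U = NA_real_, p = NA_real_,
                    q = NA_real_, z = NA_real_, direction = NA_real_,
                    significant = NA, reason = NA_character_,
                    stringsAsFactors = FALSE)
  for (i in seq_along(collection)) {
    membership <- ranked$gene_id %in% collection[[i]]
    k <- sum(membership)
    res$n_in_set[i] <- k
    if (k < min_set_size) {
      res$reason[i] <- "too_few_mapped_members"
      next
    }
    if (k == length(values)) {
      res$reason[i] <- "set_covers_entire_ranking"
      next
    }
    mw <- mannwhitney_set_test(values, membership)
    res$U[i] <- mw$U
    res$p[i] <- mw$p
    res$z[i] <- set_zscore(values, membership)
  }
  tested <- !is.na(res$p)
  if (!any(tested)) stop("no gene set maps >= min_set_size genes into the ranking")
  res$q[tested] <- bh_correct(res$p[tested])
  res$direction <- sign(res$z)
  res$significant[tested] <- res$q[tested] < q_threshold
  res
}

#' Guilt-by-association analysis for a focal lincRNA
#'
#' Pearson correlation of the focal gene's expression profile with every
#' protein-coding gene across the compendium samples; coding genes are
#' then rank-ordered by correlation and the gene sets tested with the
#' Mann-Whitney enrichment of [gsea()]. Set significance is called on the
#' raw p-value at `p_threshold`; Benjamini-Hochberg q-values are reported
#' alongside.
#'
#' @param expression Genes x samples matrix with a `biotype` attribute
#'   (see [read_expression()] / [gen_expression_compendium()]); rows
#'   labelled `coding` form the correlation background. Without a biotype
#'   attribute every non-focal row is used.
#' @param focal_id Row name of the focal lincRNA.
#' @param collection Named list of gene sets.
#' @param p_threshold Raw-p significance threshold.
#' @param min_set_size Minimum mapped members per tested set.
#' @return List with `profile` (data.frame `gene_id`, `r`, plus excluded
#'   zero-variance genes as an attribute) and `enrichment` (as for
#'   [gsea()], with `significant` from the raw p).
#' @export
gba <- function(expression, focal_id, collection, p_threshold = 1e-6,
                min_set_size = 5) {
  if (!focal_id %in% rownames(expression)) stop("focal id not in matrix")
  if (ncol(expression) < 3) stop("need at least 3 samples")
  focal <- expression[focal_id, ]
  if (sd(focal) == 0) stop("zero-variance focal profile")
  biotype <- attr(expression, "biotype")
  coding_ids <- if (!is.null(biotype)) {
    names(biotype)[biotype == "coding"]
  } else {
    setdiff(rownames(expression), focal_id)
  }
  coding_ids <- setdiff(intersect(coding_ids, rownames(expression)), focal_id)
  coding <- expression[coding_ids, , drop = FALSE]
  sds <- apply(coding, 1L, sd)
  dropped <- coding_ids[sds == 0]
  keep <- coding_ids[sds > 0]
  r <- as.vector(cor(focal, t(coding[keep, , drop = FALSE])))
  profile <- data.frame(gene_id = keep, r = r, stringsAsFactors = FALSE)
  attr(profile, "excluded_zero_variance") <- dropped
  pseudo_diff <- data.frame(gene_id = keep, test_stat = r, status = "OK",
                            stringsAsFactors = FALSE)
  enrich <- gsea(pseudo_diff, collection, q_threshold = 1, # flag from raw p below
                 min_set_size = min_set_size)
  tested <- !is.na(enrich$p)
  enrich$significant[tested] <- enrich$p[tested] < p_threshold
  list(profile = profile, enrichment = enrich)
}
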