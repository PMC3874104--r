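# Seeded generators producing inputs with the statistical structure each
# analysis stage assumes. Every generator is a pure function of its
# arguments: the global seed is expanded into a per-generator substream by
# hashing the generator's name, so adding a generator never perturbs the
# draws of another, and the caller's RNG state is restored on exit.

substream_seed <- function(seed, label) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  codes <- utf8ToInt(label)
  h <- sum(codes * seq_along(codes)) %% 65521
  as.integer((abs(seed) %% 2097152) * 1021 + h)  # < 2^31 always
}

with_substream <- function(seed, label, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv(), inherits = FALSE)
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, label))
  expr
}

#' Simulate a genome and gene catalog
#'
#' Draws chromosome lengths around `mean_length` and places
#' non-overlapping gene intervals (per strand) with biotype labels
#' `coding` / `lincRNA`. The transcription start site of a gene is its
#' `start` for `+` strand genes and its `end` for `-` strand genes.
#' Defaults emulate a desk-scale mammalian genome: a handful of ~100 Mb
#' chromosomes carrying ~8 genes per Mb, so a +/-1 Mb window holds a
#' realistic 10-20 genes.
#'
#' @param n_chroms Number of chromosomes (>= 1).
#' @param mean_length Mean chromosome length in bases.
#' @param n_genes Total genes to place.
#' @param seed Integer seed.
#' @param gene_length_range Min/max gene length in bases.
#' @param linc_fraction Fraction of genes labelled `lincRNA`.
#' @return List with `chrom_sizes` (named numeric) and `genes` (data.frame
#'   `chrom`, `start`, `end`, `gene_id`, `biotype`, `strand`; 0-based
#'   half-open).
#' @export
gen_genome <- function(n_chroms = 5, mean_length = 1e8, n_genes = 4000,
                       seed = 1, gene_length_range = c(5e3, 5e4),
                       linc_fraction = 0.2) {
  stopifnot(n_chroms >= 1, n_genes >= 1, mean_length > 0)
  with_substream(seed, "gen_genome", {
    sizes <- round(mean_length * exp(rnorm(n_chroms, 0, 0.15)))
    names(sizes) <- paste0("chr", seq_len(n_chroms))
    chrom <- sample(names(sizes), n_genes, replace = TRUE,
                    prob = sizes / sum(sizes))
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    len <- round(runif(n_genes, gene_length_range[1], gene_length_range[2]))
    start <- numeric(n_genes)
    for (cs in names(sizes)) {
      for (st in c("+", "-")) {
        idx <- which(chrom == cs & strand == st)
        if (!length(idx)) next
        slack <- sizes[[cs]] - sum(len[idx])
        if (slack <= 0) {
          stop("requested genes exceed genome capacity on ", cs, " (", st, ")")
        }
        gaps <- diff(c(0, sort(runif(length(idx))))) * slack
        start[idx] <- cumsum(gaps) + cumsum(c(0, len[idx[-length(idx)]]))
      }
    }
    start <- floor(start)
    genes <- data.frame(
      chrom = chrom, start = start, end = start + len,
      gene_id = sprintf("gene%05d", seq_len(n_genes)),
      biotype = sample(c("coding", "lincRNA"), n_genes, replace = TRUE,
                       prob = c(1 - linc_fraction, linc_fraction)),
      strand = strand, stringsAsFactors = FALSE
    )
    genes <- genes[order(genes$chrom, genes$start), ]
    rownames(genes) <- NULL
    list(chrom_sizes = sizes, genes = genes)
  })
}

#' Transcription start sites of a gene catalog
#'
#' @param genes data.frame with `start`, `end`, `strand`.
#' @return Numeric vector of TSS positions (start on `+`, end on `-`).
#' @export
gene_tss <- function(genes) {
  ifelse(genes$strand == "-", genes$end, genes$start)
}

#' Simulate ribosome-footprint and total-RNA coverage on a transcript
#'
#' Coding transcripts show the stop-codon drop-off the ribosome release
#' score detects: footprint counts are Poisson with mean `depth` inside the
#' first open reading frame and `depth / drop_factor` outside it (both
#' upstream of the start codon and after the stop). Noncoding profiles are
#' uniform Poisson at `depth`. The total-RNA track is uniform at `depth` in
#' both cases.
#'
#' @param sequence Transcript nucleotide string over A/C/G/T/N.
#' @param coding Logical; simulate a translated ORF?
#' @param depth Mean per-base count.
#' @param drop_factor Fold drop in footprint coverage outside the ORF
#'   (coding profiles only).
#' @param seed Integer seed.
#' @param id Transcript id stored in the result.
#' @return List with `id`, `footprint_counts`, `rna_counts` (integer
#'   vectors of transcript length).
#' @export
gen_ribosome_profile <- function(sequence, coding, depth = 50,
                                 drop_factor = 10, seed = 1, id = "tx") {
  stopifnot(depth >= 0, drop_factor > 0)
  L <- nchar(sequence)
  lambda <- rep(depth, L)
  if (coding) {
    orfs <- enumerate_orfs(sequence)
    if (!nrow(orfs)) stop("coding = TRUE but transcript has no ORF")
    orf <- orfs[1L, ]
    lambda <- rep(depth / drop_factor, L)
    lambda[(orf$cds_start + 1):orf$cds_end] <- depth
  }
  with_substream(seed, "gen_ribosome_profile", {
    list(id = id,
         footprint_counts = rpois(L, lambda),
         rna_counts = rpois(L, depth))
  })
}

#' Simulate an expression compendium with a planted coexpression module
#'
#' The focal lincRNA and the planted member genes share a latent sample
#' profile with loading `sqrt(r)`, so the expected pairwise Pearson
#' correlation between any two planted rows is `r` and the empirical
#' correlation converges to `r` as `n_samples` grows. All other genes are
#' independent noise. Values are truncated at zero after adding measurement
#' noise (FPKM is non-negative); the baseline mean is kept several standard
#' deviations above zero so truncation is rare and leaves correlations
#' essentially unchanged.
#'
#' @param n_genes Number of coding background genes.
#' @param n_samples Number of samples (columns).
#' @param planted `NULL`, or `list(focal = <lincRNA id>, members =
#'   <character, ids among the coding genes>, r = <target correlation>)`.
#' @param noise_sd Standard deviation of per-value measurement noise.
#' @param base_mean,base_sd Baseline FPKM mean and biological sd.
#' @param seed Integer seed.
#' @return Matrix (genes x samples) with a named `biotype` attribute
#'   (`coding` for background genes, `lincRNA` for the focal row).
#' @export
gen_expression_compendium <- function(n_genes = 400, n_samples = 24,
                                      planted = NULL, noise_sd = 1,
                                      base_mean = 100, base_sd = 20,
                                      seed = 1) {
  stopifnot(n_genes >= 1, n_samples >= 1)
  ids <- sprintf("gene%05d", seq_len(n_genes))
  biotype <- stats::setNames(rep("coding", n_genes), ids)
  if (!is.null(planted)) {
    stopifnot(is.list(planted), all(c("focal", "members", "r") %in% names(planted)))
    if (planted$r > 1 || planted$r < 0) stop("planted correlation r must be in [0, 1]")
    if (length(planted$members) < 2L) stop("need at least 2 planted members")
    if (!all(planted$members %in% ids)) stop("planted members must be coding gene ids")
    ids <- c(ids, planted$focal)
    biotype <- c(biotype, stats::setNames("lincRNA", planted$focal))
  }
  with_substream(seed, "gen_expression_compendium", {
    m <- matrix(rnorm(length(ids) * n_samples), length(ids), n_samples,
                dimnames = list(ids, sprintf("sample%02d", seq_len(n_samples))))
    if (!is.null(planted)) {
      z <- rnorm(n_samples)
      rows <- c(planted$members, planted$focal)
      loading <- sqrt(planted$r)
      m[rows, ] <- loading * matrix(z, length(rows), n_samples, byrow = TRUE) +
        sqrt(1 - planted$r) * m[rows, , drop = FALSE]
    }
    m <- base_mean + base_sd * m
    if (noise_sd > 0) m <- m + rnorm(length(m), 0, noise_sd)
    m <- pmax(m, 0)
    attr(m, "biotype") <- biotype
    m
  })
}

#' Simulate a differential-expression table with planted local enrichment
#'
#' Exactly `n_local_de` genes with a TSS inside the +/- `half_width` window
#' around the focal gene's TSS, and `n_global_de` genes elsewhere, receive
#' `q < q_sig`; all other genes get `q >= q_sig`. Test statistics and fold
#' changes are drawn consistent with the significance labels, and `p <= q`
#' within every row so the table satisfies the Benjamini-Hochberg
#' monotonicity invariant.
#'
#' @param genes Gene catalog from [gen_genome()].
#' @param focal_id Gene id of the (deleted) focal lincRNA.
#' @param n_local_de,n_global_de Planted significant genes inside / outside
#'   the focal window.
#' @param q_sig Significance threshold separating planted from background.
#' @param half_width Window half-width in bases.
#' @param seed Integer seed.
#' @return data.frame in the differential-table layout of
#'   [read_diff_table()] (including parsed `chrom`, `start`, `end` and
#'   `strand`).
#' @export
gen_diff_table <- function(genes, focal_id, n_local_de = 0, n_global_de = 0,
                           q_sig = 0.05, half_width = 1e6, seed = 1) {
  stopifnot(focal_id %in% genes$gene_id)
  focal <- genes[genes$gene_id == focal_id, ]
  tss <- gene_tss(genes)
  focal_tss <- tss[genes$gene_id == focal_id]
  local <- genes$chrom == focal$chrom &
    tss >= focal_tss - half_width & tss <= focal_tss + half_width &
    genes$gene_id != focal_id
  if (n_local_de > sum(local)) {
    stop("n_local_de exceeds the ", sum(local), " genes within +/-",
         format(half_width, scientific = FALSE), " bp of the focal TSS")
  }
  if (n_global_de > sum(!local) - 1L) stop("n_global_de exceeds available genes")
  with_substream(seed, "gen_diff_table", {
    n <- nrow(genes)
    sig <- rep(FALSE, n)
    sig[sample(which(local), n_local_de)] <- TRUE
    global_pool <- which(!local & genes$gene_id != focal_id)
    sig[sample(global_pool, n_global_de)] <- TRUE
    q <- ifelse(sig, runif(n) * q_sig * 0.999,
                q_sig + runif(n) * (1 - q_sig))
    p <- q * runif(n)
    stat <- ifelse(sig, sample(c(-1, 1), n, replace = TRUE) * (3 + rexp(n)),
                   rnorm(n))
    d <- data.frame(
      gene_id = genes$gene_id,
      locus = sprintf("%s:%d-%d", genes$chrom, genes$start, genes$end),
      test_stat = stat,
      log2fc = stat / 2,
      p_value = p,
      q_value = q,
      status = "OK",
      strand = genes$strand,
      chrom = genes$chrom, start = genes$start, end = genes$end,
      stringsAsFactors = FALSE
    )
    rownames(d) <- NULL
    d
  })
}

#' Simulate genotype counts from an intercross with lethality
#'
#' Offspring genotypes are drawn multinomially at the Mendelian proportions
#' of `cross_type`; null homozygotes (hemizygous null males for the
#' X-linked cross) are then removed independently with probability
#' `lethality_penetrance`, emulating deaths before genotyping.
#'
#' @param n_offspring Litter total before lethality.
#' @param lethality_penetrance Probability in `[0, 1]` that a null
#'   homozygote dies before the census.
#' @param cross_type One of `"autosomal_het_x_het"`,
#'   `"xlinked_hetfemale_x_wtmale"`, `"hom_x_hom"`.
#' @param seed Integer seed.
#' @return Named integer vector of observed genotype counts, with
#'   attributes `cross_type` and `n_offspring`.
#' @export
gen_cross_counts <- function(n_offspring, lethality_penetrance = 0,
                             cross_type = "autosomal_het_x_het", seed = 1) {
  stopifnot(lethality_penetrance >= 0, lethality_penetrance <= 1,
            n_offspring >= 1)
  props <- mendelian_proportions(cross_type)
  lethal_class <- switch(cross_type,
                         autosomal_het_x_het = "-/-",
                         xlinked_hetfemale_x_wtmale = "M-/Y",
                         hom_x_hom = "-/-")
  with_substream(seed, "gen_cross_counts", {
    counts <- as.vector(rmultinom(1, n_offspring, props))
    names(counts) <- names(props)
    deaths <- rbinom(1, counts[[lethal_class]], lethality_penetrance)
    counts[[lethal_class]] <- counts[[lethal_class]] - deaths
    structure(counts, cross_type = cross_type, n_offspring = n_offspring)
  })
}

#' Simulate a morphometry measurement table
#'
#' Independent normal draws per group, as for section thickness or cell
#' count measurements summarised as mean +/- SEM.
#'
#' @param means Named numeric vector of group means.
#' @param sds Per-group standard deviations (recycled).
#' @param n Observations per group (recycled; each >= 2).
#' @param seed Integer seed.
#' @return data.frame with columns `group`, `value`.
#' @export
gen_morphometry <- function(means, sds, n, seed = 1) {
  stopifnot(!is.null(names(means)), all(n >= 2))
  sds <- rep_len(sds, length(means))
  n <- rep_len(n, length(means))
  with_substream(seed, "gen_morphometry", {
    out <- Map(function(g, mu, s, k) {
      data.frame(group = g, value = rnorm(k, mu, s), stringsAsFactors = FALSE)
    }, names(means), means, sds, n)
    do.call(rbind, c(out, list(make.row.names = FALSE)))
  })
}
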