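# The knockout-candidate filter cascade: annotation overlap -> codon
# substitution frequency (CSF) -> mass-spectrometry tags -> ribosome
# release score screen -> boolean genomic criteria; plus the
# developmental-timecourse induction filter used to pick human orthologs.

candidate_chrom_check <- function(candidates, annotations, chrom_sizes) {
  namespace <- if (!is.null(chrom_sizes)) names(chrom_sizes) else
    unique(annotations$chrom)
  unknown <- setdiff(unique(candidates$chrom), namespace)
  if (length(unknown)) {
    stop("candidate chromosome(s) not in the shared namespace: ",
         paste(unknown, collapse = ", "))
  }
}

#' Exclude candidates overlapping non-lncRNA annotations
#'
#' A candidate is excluded iff its locus overlaps at least one base of any
#' annotation whose biotype is not a long noncoding RNA (protein-coding
#' genes, microRNAs, tRNAs, pseudogenes, ...). Overlap is strand-agnostic;
#' half-open abutment (candidate end == annotation start) is not overlap.
#'
#' @param candidates data.frame with `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param annotations data.frame with `chrom`, `start`, `end` and
#'   optionally `biotype`; rows with biotype `lincRNA`/`lncRNA` are
#'   ignored, all other rows (or all rows when there is no biotype column)
#'   are excluding annotations.
#' @param chrom_sizes Optional named vector defining the chromosome
#'   namespace; candidates on a chromosome outside the namespace raise an
#'   error.
#' @return List with data.frames `kept` and `excluded` (the latter with a
#'   `reason` column).
#' @export
filter_annotation_overlap <- function(candidates, annotations,
                                      chrom_sizes = NULL) {
  candidate_chrom_check(candidates, annotations, chrom_sizes)
  excl_ann <- annotations
  if ("biotype" %in% names(annotations)) {
    excl_ann <- annotations[!annotations$biotype %in% c("lincRNA", "lncRNA"), ]
  }
  hit <- if (nrow(excl_ann)) {
    GenomicRanges::countOverlaps(
      gi_granges(candidates$chrom, candidates$start, candidates$end),
      gi_granges(excl_ann$chrom, excl_ann$start, excl_ann$end),
      ignore.strand = TRUE) > 0
  } else {
    rep(FALSE, nrow(candidates))
  }
  excluded <- candidates[hit, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "annotation_overlap"
  list(kept = candidates[!hit, , drop = FALSE], excluded = excluded)
}

#' Filter candidates by codon substitution frequency score
#'
#' Kept iff `csf_score < threshold` (strict inequality; a score exactly at
#' the threshold is excluded). Candidates with a missing score are routed
#' to `excluded` with reason `"no_score"`.
#'
#' @param candidates data.frame with a `csf_score` column.
#' @param threshold CSF cutoff; strongly negative scores indicate no
#'   protein-coding potential.
#' @return List with `kept` and `excluded` data.frames.
#' @export
filter_csf <- function(candidates, threshold = -200) {
  missing <- is.na(candidates$csf_score)
  keep <- !missing & candidates$csf_score < threshold
  excluded <- candidates[!keep, , drop = FALSE]
  if (nrow(excluded)) {
    excluded$reason <- ifelse(is.na(excluded$csf_score), "no_score", "csf")
  }
  list(kept = candidates[keep, , drop = FALSE], excluded = excluded)
}

#' Filter candidates by mass-spectrometry tag count
#'
#' Kept iff `masspec_tags <= max_tags`; transcripts with more mapped
#' peptides are considered potentially coding.
#'
#' @param candidates data.frame with a `masspec_tags` column.
#' @param max_tags Maximum tolerated tag count.
#' @return List with `kept` and `excluded` data.frames.
#' @export
filter_masspec <- function(candidates, max_tags = 2) {
  if (any(candidates$masspec_tags < 0, na.rm = TRUE)) {
    stop("negative mass-spectrometry tag count")
  }
  keep <- !is.na(candidates$masspec_tags) & candidates$masspec_tags <= max_tags
  excluded <- candidates[!keep, , drop = FALSE]
  if (nrow(excluded)) excluded$reason <- "masspec"
  list(kept = candidates[keep, , drop = FALSE], excluded = excluded)
}

#' Run the full candidate-selection cascade
#'
#' Applies, in order: annotation overlap, CSF, mass-spectrometry tags, the
#' ribosome release score screen, and the boolean genomic criteria (human
#' synteny, active-transcription chromatin signature). Filters
#' short-circuit: once a candidate fails, later filters are not evaluated
#' for it (this affects the recorded trace only -- the kept set equals the
#' intersection of the individual filters' keeps).
#'
#' The RRS screen flags a candidate as coding-like when its `max_rrs`
#' exceeds the `rrs_percentile`-th percentile of a supplied coding-gene RRS
#' distribution; candidates with an undefined (`NA`) RRS carry no ribosome
#' evidence and pass. When `config$coding_rrs` is `NULL` the screen passes
#' everyone.
#'
#' @param candidates data.frame with `gene_id`, `chrom`, `start`, `end`,
#'   `csf_score`, `masspec_tags`, `has_human_synteny`,
#'   `has_k4me3_k36me3` (and optionally `has_enhancer_signature`, which is
#'   annotated but never filtered on).
#' @param annotations Annotation intervals as for
#'   [filter_annotation_overlap()].
#' @param rrs_results Optional data.frame `gene_id`, `max_rrs`; must cover
#'   every candidate when supplied. Alternatively candidates may carry a
#'   `max_rrs` column.
#' @param config List of knobs: `csf_threshold` (-200), `max_tags` (2),
#'   `coding_rrs` (numeric vector, default `NULL`), `rrs_percentile` (5),
#'   `chrom_sizes` (`NULL`).
#' @return The candidate data.frame with added columns `kept`,
#'   `fail_stage` and `filter_trace`, and an `attrition` attribute
#'   (per-stage input/kept/excluded counts).
#' @export
run_selection_pipeline <- function(candidates, annotations,
                                   rrs_results = NULL, config = list()) {
  cfg <- utils::modifyList(
    list(csf_threshold = -200, max_tags = 2, coding_rrs = NULL,
         rrs_percentile = 5, chrom_sizes = NULL), config)
  if (!is.null(rrs_results)) {
    missing <- setdiff(candidates$gene_id, rrs_results$gene_id)
    if (length(missing)) {
      stop("no RRS result for candidate(s): ", paste(missing, collapse = ", "))
    }
    candidates$max_rrs <-
      rrs_results$max_rrs[match(candidates$gene_id, rrs_results$gene_id)]
  }
  if (is.null(candidates$max_rrs)) candidates$max_rrs <- NA_real_

  rrs_cut <- if (!is.null(cfg$coding_rrs)) {
    quantile(cfg$coding_rrs, cfg$rrs_percentile / 100, names = FALSE)
  }

  ann_kept <- rep(FALSE, nrow(candidates))
  part <- filter_annotation_overlap(candidates, annotations, cfg$chrom_sizes)
  ann_kept[candidates$gene_id %in% part$kept$gene_id] <- TRUE

  stages <- list(
    annotation = ann_kept,
    csf = !is.na(candidates$csf_score) & candidates$csf_score < cfg$csf_threshold,
    masspec = {
      if (any(candidates$masspec_tags < 0, na.rm = TRUE)) {
        stop("negative mass-spectrometry tag count")
      }
      !is.na(candidates$masspec_tags) & candidates$masspec_tags <= cfg$max_tags
    },
    rrs = if (is.null(rrs_cut)) rep(TRUE, nrow(candidates)) else
      is.na(candidates$max_rrs) | candidates$max_rrs <= rrs_cut,
    flags = (candidates$has_human_synteny %||% rep(TRUE, nrow(candidates))) &
      (candidates$has_k4me3_k36me3 %||% rep(TRUE, nrow(candidates)))
  )

  n <- nrow(candidates)
  alive <- rep(TRUE, n)
  trace <- rep("", n)
  fail_stage <- rep(NA_character_, n)
  attrition <- data.frame(stage = names(stages), n_in = NA_integer_,
                          n_kept = NA_integer_, n_excluded = NA_integer_)
  for (i in seq_along(stages)) {
    nm <- names(stages)[i]
    pass <- stages[[i]]
    attrition$n_in[i] <- sum(alive)
    entry <- ifelse(pass, paste0(nm, ":pass"), paste0(nm, ":fail"))
    trace[alive] <- ifelse(nzchar(trace[alive]),
                           paste(trace[alive], entry[alive], sep = ";"),
                           entry[alive])
    fail_stage[alive & !pass] <- nm
    newly_dead <- alive & !pass
    attrition$n_excluded[i] <- sum(newly_dead)
    alive <- alive & pass
    attrition$n_kept[i] <- sum(alive)
  }
  candidates$kept <- alive
  candidates$fail_stage <- fail_stage
  candidates$filter_trace <- trace
  attr(candidates, "attrition") <- attrition
  candidates
}

#' Select developmentally regulated genes from a differentiation timecourse
#'
#' Two nested gene sets from labelled differential-expression contrasts:
#' genes significant (`q < q_threshold`) in at least one adjacent-timepoint
#' contrast, and the subset of those that are also significantly *induced*
#' (strictly positive direction at the same threshold) relative to day 0.
#'
#' @param timecourse data.frame with columns `gene_id`, `contrast` (either
#'   `"adjacent"` or `"vs_day0"`), `q`, `direction` (sign of the change).
#' @param q_threshold Significance threshold applied to both contrast
#'   classes.
#' @return List of character vectors `de_any_adjacent` and
#'   `induced_vs_day0` (the second a subset of the first).
#' @export
temporal_induction_filter <- function(timecourse, q_threshold = 0.01) {
  stopifnot(all(c("gene_id", "contrast", "q", "direction") %in% names(timecourse)))
  bad <- setdiff(unique(timecourse$contrast), c("adjacent", "vs_day0"))
  if (length(bad)) {
    stop("unlabelled contrast(s): ", paste(bad, collapse = ", "))
  }
  adj <- timecourse$contrast == "adjacent" & timecourse$q < q_threshold
  de_any <- unique(timecourse$gene_id[adj])
  ind <- timecourse$contrast == "vs_day0" & timecourse$q < q_threshold &
    timecourse$direction > 0
  induced <- intersect(de_any, unique(timecourse$gene_id[ind]))
  list(de_any_adjacent = de_any, induced_vs_day0 = induced)
}
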