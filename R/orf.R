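# ORF enumeration and the ribosome release score (RRS).
#
# An open reading frame runs from an ATG to the next in-frame stop codon
# (TAA/TAG/TGA), stop included, so the CDS span is a multiple of 3 and at
# least 6 nt. Its putative 3'-UTR starts immediately after the stop and
# ends at the next ATG in ANY frame (or the transcript end). Codons
# containing N never match a start or stop.

#' Enumerate open reading frames of a transcript
#'
#' One call per ATG that has an in-frame stop codon downstream; ATGs with
#' no in-frame stop yield no call. Coordinates are 0-based transcript
#' offsets; `cds_end` is one past the last base of the stop codon and the
#' 3'-UTR is the half-open span `[utr3_start, utr3_end)` (possibly empty
#' when another ATG immediately follows the stop).
#'
#' @param sequence Nucleotide string over A/C/G/T/N (case-insensitive,
#'   `U` accepted as `T`).
#' @return data.frame with columns `cds_start`, `cds_end`, `utr3_start`,
#'   `utr3_end`, sorted by `cds_start`.
#' @examples
#' enumerate_orfs("ATGAAATAGCCCCCC")
#' @export
enumerate_orfs <- function(sequence) {
  seq <- toupper(chartr("Uu", "Tt", sequence))
  L <- nchar(seq)
  if (L < 1L) stop("empty sequence")
  if (grepl("[^ACGTN]", seq)) stop("sequence must be over A/C/G/T/N")
  empty <- data.frame(cds_start = integer(0), cds_end = integer(0),
                      utr3_start = integer(0), utr3_end = integer(0))
  if (L < 6L) return(empty)
  atg <- as.integer(gregexpr("(?=ATG)", seq, perl = TRUE)[[1L]]) - 1L
  atg <- atg[atg >= 0L]
  if (!length(atg)) return(empty)
  stop0 <- as.integer(gregexpr("(?=TAA|TAG|TGA)", seq, perl = TRUE)[[1L]]) - 1L
  stop0 <- stop0[stop0 >= 0L & stop0 <= L - 3L]
  stops_by_frame <- split(stop0, stop0 %% 3L)
  calls <- lapply(atg, function(a) {
    frame <- a %% 3L
    st <- stops_by_frame[[as.character(frame)]]
    st <- st[st >= a + 3L]
    if (!length(st)) return(NULL)
    cds_end <- min(st) + 3L
    nxt <- atg[atg >= cds_end]
    utr3_end <- if (length(nxt)) min(nxt) else L
    data.frame(cds_start = a, cds_end = cds_end,
               utr3_start = cds_end, utr3_end = utr3_end)
  })
  calls <- calls[!vapply(calls, is.null, logical(1))]
  if (!length(calls)) return(empty)
  out <- do.call(rbind, calls)
  out <- out[order(out$cds_start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Ribosome release score of one ORF
#'
#' `RRS = (F_cds / F_utr) / (R_cds / R_utr)` where `F`/`R` are the
#' footprint / total-RNA count sums over the CDS and 3'-UTR spans. The
#' score is undefined (returned as `NA`) when the 3'-UTR span is empty or
#' any denominator sum (`F_utr`, `R_cds`, `R_utr`) is zero; this is a
#' sentinel, not an error, so degenerate ORFs are simply skipped when
#' maximising.
#'
#' @param profile List with `footprint_counts` and `rna_counts` covering
#'   the transcript (e.g. from [gen_ribosome_profile()]).
#' @param orf One-row data.frame (or list) with `cds_start`, `cds_end`,
#'   `utr3_start`, `utr3_end` as produced by [enumerate_orfs()].
#' @return Non-negative numeric scalar, or `NA` when undefined.
#' @export
compute_rrs <- function(profile, orf) {
  fp <- profile$footprint_counts
  rna <- profile$rna_counts
  L <- length(fp)
  stopifnot(length(rna) == L)
  if (orf$cds_start < 0 || orf$utr3_end > L || orf$cds_end > L) {
    stop("ORF span out of profile bounds")
  }
  cds <- (orf$cds_start + 1L):orf$cds_end
  if (orf$utr3_end <= orf$utr3_start) return(NA_real_)
  utr <- (orf$utr3_start + 1L):orf$utr3_end
  f_cds <- sum(fp[cds]); f_utr <- sum(fp[utr])
  r_cds <- sum(rna[cds]); r_utr <- sum(rna[utr])
  if (f_utr == 0 || r_cds == 0 || r_utr == 0) return(NA_real_)
  (f_cds / f_utr) / (r_cds / r_utr)
}

#' Maximum ribosome release score over all ORFs of a transcript
#'
#' Computes [compute_rrs()] for every enumerated ORF and returns the
#' maximum over defined scores together with the achieving ORF (ties go to
#' the 5'-most ORF). When no ORF has a computable score the result carries
#' `max_rrs = NA`.
#'
#' @param profile Coverage profile as for [compute_rrs()].
#' @param sequence Transcript nucleotide string.
#' @return List with `orfs` (the ORF table plus an `rrs` column),
#'   `max_rrs`, and `best` (row index of the maximising ORF, or `NA`).
#' @export
max_rrs <- function(profile, sequence) {
  orfs <- enumerate_orfs(sequence)
  if (nrow(orfs)) {
    orfs$rrs <- vapply(seq_len(nrow(orfs)),
                       function(i) compute_rrs(profile, orfs[i, ]),
                       numeric(1))
  } else {
    orfs$rrs <- numeric(0)
  }
  defined <- which(!is.na(orfs$rrs))
  if (!length(defined)) {
    return(list(orfs = orfs, max_rrs = NA_real_, best = NA_integer_))
  }
  best <- defined[which.max(orfs$rrs[defined])]  # which.max: first (5'-most) tie
  list(orfs = orfs, max_rrs = orfs$rrs[best], best = best)
}
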