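#' Read transcript sequences from a FASTA file
#'
#' Sequences are uppercased and RNA alphabet is normalised to DNA (`U` is
#' mapped to `T`). The record id is the first whitespace-separated token of
#' the header; a second token, when present, is taken as the parent gene id
#' (otherwise the gene id equals the transcript id).
#'
#' @param path Path to a FASTA file.
#' @return A data.frame with columns `id`, `gene_id`, `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">t1 geneA", "acgu"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  tokens <- strsplit(headers, "[ \t]+")
  id <- vapply(tokens, `[`, character(1), 1L)
  gene_id <- vapply(tokens, function(tk) if (length(tk) >= 2L) tk[2L] else tk[1L],
                    character(1))
  dup <- id[duplicated(id)]
  if (length(dup)) {
    stop("duplicate transcript id(s) in FASTA: ", paste(unique(dup), collapse = ", "))
  }
  seqs <- chartr("Uu", "Tt", as.character(set))
  seqs <- toupper(seqs)
  if (any(!nzchar(seqs))) {
    stop("empty sequence for transcript(s): ",
         paste(id[!nzchar(seqs)], collapse = ", "))
  }
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("non-ACGTN characters in sequence(s): ", paste(id[bad], collapse = ", "))
  }
  data.frame(id = id, gene_id = gene_id, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write transcript records to FASTA
#'
#' @param records data.frame as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path) {
  set <- Biostrings::BStringSet(records$sequence)
  names(set) <- ifelse(records$gene_id == records$id, records$id,
                       paste(records$id, records$gene_id))
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read genomic intervals from a BED file
#'
#' Coordinates are kept 0-based half-open exactly as in the file. Strand is
#' taken from column 6 when present, otherwise `"."`.
#'
#' @param path Path to a BED3+ file.
#' @return data.frame with columns `chrom`, `start`, `end`, `name`, `score`,
#'   `strand`.
#' @export
read_bed <- function(path) {
  stopifnot(file.exists(path))
  # pre-scan so an empty/inverted interval reports its line number
  lines <- readLines(path)
  body <- !grepl("^(track|browser|#)", lines) & nzchar(lines)
  fields <- strsplit(lines[body], "\t")
  starts <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 2L)))
  ends <- suppressWarnings(as.numeric(vapply(fields, `[`, character(1), 3L)))
  bad <- which(is.na(starts) | is.na(ends) | starts >= ends | starts < 0)
  if (length(bad)) {
    stop("invalid BED interval (need 0 <= start < end) at line ",
         which(body)[bad[1L]], " of ", path)
  }
  gr <- rtracklayer::import(path, format = "bed")
  strand <- as.character(GenomicRanges::strand(gr))
  strand[strand == "*"] <- "."
  name <- if (!is.null(gr$name)) as.character(gr$name) else NA_character_
  score <- if (!is.null(gr$score)) as.numeric(gr$score) else NA_real_
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    name = name, score = score, strand = strand,
    stringsAsFactors = FALSE
  )
}

#' Write genomic intervals to a BED6 file
#'
#' Starts and ends are written exactly as stored (0-based half-open); a
#' read/write cycle never shifts coordinates.
#'
#' @param intervals data.frame with at least `chrom`, `start`, `end`;
#'   optional `name`, `score`, `strand`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  stopifnot(all(c("chrom", "start", "end") %in% names(intervals)))
  if (any(intervals$start >= intervals$end)) stop("start >= end in intervals")
  name <- intervals$name %||% rep(".", nrow(intervals))
  score <- intervals$score %||% rep(0, nrow(intervals))
  score[is.na(score)] <- 0
  strand <- intervals$strand %||% rep(".", nrow(intervals))
  lines <- sprintf("%s\t%s\t%s\t%s\t%s\t%s",
                   intervals$chrom,
                   format(intervals$start, scientific = FALSE, trim = TRUE),
                   format(intervals$end, scientific = FALSE, trim = TRUE),
                   name,
                   format(score, scientific = FALSE, trim = TRUE),
                   strand)
  writeLines(lines, path)
  invisible(path)
}

#' Read a gene-set collection from a GMT file
#'
#' MSigDB dialect: tab-separated name, description, member ids. Member ids
#' are deduplicated; an empty set is an error.
#'
#' @param path Path to a GMT file.
#' @return Named list of character vectors (one element per gene set).
#' @export
read_gmt <- function(path) {
  stopifnot(file.exists(path))
  sets <- fgsea::gmtPathways(path)
  sets <- lapply(sets, function(x) unique(x[nzchar(x)]))
  empty <- names(sets)[lengths(sets) == 0L]
  if (length(empty)) {
    stop("gene set(s) with zero members: ", paste(empty, collapse = ", "))
  }
  sets
}

#' Write a gene-set collection to a GMT file
#'
#' The description column is set to the set name, so `write_gmt()` followed
#' by [read_gmt()] reproduces the collection exactly and canonical files
#' round-trip byte-identically.
#'
#' @param collection Named list of character vectors.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  if (is.null(names(collection)) || any(!nzchar(names(collection)))) {
    stop("collection must be a named list")
  }
  if (any(lengths(collection) == 0L)) stop("gene set(s) with zero members")
  lines <- vapply(names(collection), function(nm) {
    paste(c(nm, nm, collection[[nm]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Read a differential-expression table
#'
#' Expects the tab-separated dialect emitted by Cuffdiff2-style tools:
#' required columns `gene_id`, `locus`, `test_stat`, `log2fc`, `p_value`,
#' `q_value`, `status`; extra columns (e.g. `strand`) are kept. The locus
#' string `chrom:start-end` is parsed into 0-based half-open coordinates.
#' Rows with status `NOTEST` are retained but flagged by their status so
#' downstream significance counts can drop them.
#'
#' @param path Path to the TSV file.
#' @return data.frame with the original columns plus `chrom`, `start`, `end`.
#' @export
read_diff_table <- function(path) {
  stopifnot(file.exists(path))
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  required <- c("gene_id", "locus", "test_stat", "log2fc", "p_value",
                "q_value", "status")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  m <- regmatches(d$locus, regexec("^(.+):([0-9]+)-([0-9]+)$", d$locus))
  bad <- which(lengths(m) != 4L)
  if (length(bad)) stop("unparseable locus at row ", bad[1L], ": ", d$locus[bad[1L]])
  d$chrom <- vapply(m, `[`, character(1), 2L)
  d$start <- as.numeric(vapply(m, `[`, character(1), 3L))
  d$end <- as.numeric(vapply(m, `[`, character(1), 4L))
  if (any(d$p_value < 0 | d$p_value > 1, na.rm = TRUE) ||
      any(d$q_value < 0 | d$q_value > 1, na.rm = TRUE)) {
    stop("p/q values outside [0, 1]")
  }
  d
}

#' Write a differential-expression table
#'
#' @param diff data.frame in the layout produced by [read_diff_table()] or
#'   [gen_diff_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_diff_table <- function(diff, path) {
  cols <- c("gene_id", "locus", "test_stat", "log2fc", "p_value", "q_value",
            "status")
  extra <- intersect("strand", names(diff))
  write.table(diff[, c(cols, extra)], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Read an FPKM expression matrix
#'
#' Layout: a `gene_id` column, an optional `biotype` column (labels such as
#' `coding` / `lincRNA`), and one numeric column per sample. Negative
#' values are an invariant breach and raise an error.
#'
#' @param path Path to the TSV file.
#' @return Numeric matrix (genes x samples) with gene ids as rownames and,
#'   when present, a named `biotype` attribute.
#' @export
read_expression <- function(path) {
  stopifnot(file.exists(path))
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (!"gene_id" %in% names(d)) stop("missing required column gene_id")
  if (anyDuplicated(d$gene_id)) stop("duplicate gene ids in expression table")
  biotype <- NULL
  if ("biotype" %in% names(d)) {
    biotype <- stats::setNames(d$biotype, d$gene_id)
  }
  samples <- setdiff(names(d), c("gene_id", "biotype"))
  if (anyDuplicated(samples)) stop("duplicate sample labels")
  m <- as.matrix(d[, samples, drop = FALSE])
  mode(m) <- "numeric"
  rownames(m) <- d$gene_id
  if (any(m < 0)) stop("negative FPKM values in expression table")
  if (!is.null(biotype)) attr(m, "biotype") <- biotype
  m
}

#' Write an FPKM expression matrix
#'
#' @param mat Matrix as returned by [read_expression()] /
#'   [gen_expression_compendium()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression <- function(mat, path) {
  d <- data.frame(gene_id = rownames(mat), check.names = FALSE)
  biotype <- attr(mat, "biotype")
  if (!is.null(biotype)) d$biotype <- unname(biotype[rownames(mat)])
  d <- cbind(d, as.data.frame(mat, check.names = FALSE))
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read chromosome sizes
#'
#' Two-column tab-separated file: chromosome name, length in bases.
#'
#' @param path Path to a chrom.sizes file.
#' @return Named numeric vector of chromosome lengths.
#' @export
read_chrom_sizes <- function(path) {
  stopifnot(file.exists(path))
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(d) < 2L) stop("chrom.sizes needs two columns (name, length)")
  sizes <- stats::setNames(as.numeric(d[[2L]]), as.character(d[[1L]]))
  if (anyDuplicated(names(sizes))) stop("duplicate chromosome names")
  if (any(!is.finite(sizes)) || any(sizes <= 0)) {
    stop("chromosome lengths must be positive")
  }
  sizes
}

#' Write chromosome sizes
#'
#' @param sizes Named numeric vector of chromosome lengths.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%s", names(sizes),
                     format(sizes, scientific = FALSE, trim = TRUE)), path)
  invisible(path)
}

#' log10(FPKM + 1) transform
#'
#' The standard display transform for FPKM matrices: each value `v` maps to
#' `log10(v + 1)`, so zero maps to zero and the transform is monotone from
#' `[0, Inf)` onto `[0, Inf)`.
#'
#' @param mat Non-negative numeric matrix (or vector).
#' @return Object of the same shape, transformed; a `biotype` attribute is
#'   carried through.
#' @examples
#' log10p1(matrix(c(0, 9, 99, 999), 2))
#' @export
log10p1 <- function(mat) {
  if (any(mat < 0)) stop("log10p1 requires non-negative values")
  out <- log10(mat + 1)
  attr(out, "biotype") <- attr(mat, "biotype")
  out
}
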