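#' Construct a gene record
#'
#' A gene record couples one nucleotide sequence (5'->3' of the transcribed
#' strand) with the ordered list of its exon junctions. The \code{i}-th exon is
#' the pair \code{(a_i, d_i)} of 1-based inclusive positions on the sequence:
#' \code{a_i} is the acceptor junction (first exonic base) and \code{d_i} the
#' donor junction (last exonic base).
#'
#' @param id Unique record identifier.
#' @param sequence Character scalar over \{A,C,G,T,N\}; lowercase and U are
#'   normalized on input.
#' @param exons Two-column integer matrix (or coercible) of (acceptor, donor)
#'   positions, one row per exon, ordered and non-overlapping.
#' @param label Optional binary circRNA label (1 = circRNA / contains one).
#' @param group_id Optional paralog-cluster id used by grouped cross-validation.
#' @param true_pair Optional integer pair \code{c(donor_ordinal, acceptor_ordinal)}
#'   marking the ground-truth backsplice pair (simulation only).
#' @return An object of class \code{gene_record}.
#' @export
gene_record <- function(id, sequence, exons, label = NA_integer_,
                        group_id = NULL, true_pair = NULL) {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  sequence <- normalize_sequence(sequence, id)
  exons <- as.matrix(exons)
  if (is.null(dim(exons)) || ncol(exons) != 2L)
    stop("record '", id, "': exons must be a 2-column (acceptor, donor) matrix")
  storage.mode(exons) <- "integer"
  m <- nrow(exons)
  if (m < 1L) stop("record '", id, "': at least one exon is required")
  a <- exons[, 1L]; d <- exons[, 2L]
  n <- nchar(sequence)
  if (any(a < 1L) || any(d > n) || any(a > d))
    stop("record '", id, "': exon out of sequence bounds or acceptor > donor")
  if (m > 1L) {
    if (any(diff(a) <= 0L)) stop("record '", id, "': exons must be sorted by acceptor position")
    if (any(d[-m] >= a[-1L])) stop("record '", id, "': overlapping exons")
  }
  if (!is.na(label) && !label %in% c(0L, 1L))
    stop("record '", id, "': label must be 0, 1 or NA")
  if (!is.null(true_pair)) {
    true_pair <- as.integer(true_pair)
    if (length(true_pair) != 2L || any(true_pair < 1L) || any(true_pair > m))
      stop("record '", id, "': true_pair must be (donor_ordinal, acceptor_ordinal) within 1..", m)
  }
  dimnames(exons) <- list(NULL, c("acceptor", "donor"))
  structure(list(id = id, sequence = sequence, exons = exons,
                 label = if (is.na(label)) NA_integer_ else as.integer(label),
                 group_id = group_id, true_pair = true_pair),
            class = "gene_record")
}

normalize_sequence <- function(sequence, id) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- chartr("u", "t", tolower(sequence))
  sequence <- toupper(sequence)
  if (!nzchar(sequence)) stop("record '", id, "': empty sequence")
  if (grepl("[^ACGTN]", sequence))
    stop("record '", id, "': sequence contains characters outside {A,C,G,T,N}")
  sequence
}

#' @export
print.gene_record <- function(x, ...) {
  cat(sprintf("<gene_record %s> %d nt, %d exon(s), label=%s\n",
              x$id, nchar(x$sequence), nrow(x$exons),
              ifelse(is.na(x$label), "NA", x$label)))
  invisible(x)
}

#' Construct a dataset of gene records
#'
#' @param records List of \code{\link{gene_record}} objects with unique ids.
#' @param level Either \code{"gene"} (all exon-intron boundaries of a gene) or
#'   \code{"isoform"} (one isoform's exon set).
#' @return An object of class \code{junction_dataset}.
#' @export
junction_dataset <- function(records, level = c("gene", "isoform")) {
  level <- match.arg(level)
  stopifnot(is.list(records), length(records) >= 1L)
  ids <- vapply(records, function(r) r$id, character(1))
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate record id(s): ", paste(unique(dup), collapse = ", "))
  labs <- vapply(records, function(r) r$label, integer(1))
  if (any(!is.na(labs) & !labs %in% c(0L, 1L))) stop("labels must be binary")
  structure(list(records = records, level = level), class = "junction_dataset")
}

#' @export
print.junction_dataset <- function(x, ...) {
  labs <- dataset_labels(x)
  cat(sprintf("<junction_dataset> %d records (%s level), %d positive / %d negative / %d unlabeled\n",
              length(x$records), x$level,
              sum(labs == 1L, na.rm = TRUE), sum(labs == 0L, na.rm = TRUE), sum(is.na(labs))))
  invisible(x)
}

#' @export
length.junction_dataset <- function(x) length(x$records)

dataset_labels <- function(dataset) vapply(dataset$records, function(r) r$label, integer(1))
dataset_ids <- function(dataset) vapply(dataset$records, function(r) r$id, character(1))
dataset_groups <- function(dataset) {
  vapply(dataset$records, function(r) if (is.null(r$group_id)) r$id else r$group_id, character(1))
}

#' Subset a dataset by record indices
#' @param dataset A \code{junction_dataset}.
#' @param idx Integer indices of records to keep.
#' @return A \code{junction_dataset} with the selected records.
#' @export
subset_dataset <- function(dataset, idx) {
  junction_dataset(dataset$records[idx], level = dataset$level)
}

#' Read a FASTA file into a named character vector
#'
#' Sequences are uppercased and U is converted to T on read. Record ids are
#' taken as the first whitespace-delimited token of each header.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, id -> sequence over \{A,C,G,T,N\}.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- Biostrings::readBStringSet(path)
  if (length(set) == 0L) stop("FASTA file contains no records: ", path)
  ids <- vapply(strsplit(names(set), "[ \t]"), `[[`, character(1), 1L)
  dup <- ids[duplicated(ids)]
  if (length(dup)) stop("duplicate FASTA id(s): ", paste(unique(dup), collapse = ", "))
  seqs <- as.character(set)
  names(seqs) <- ids
  vapply(ids, function(i) normalize_sequence(seqs[[i]], i), character(1))
}

#' Read a JSONL dataset
#'
#' One JSON object per line with fields \code{id}, \code{exons} (list of
#' 0-based half-open \code{[start, end)} pairs), optional \code{label},
#' \code{sequence} (or a companion FASTA holding it), \code{group} and
#' \code{true_pair}. Intervals are converted to 1-based inclusive junctions
#' \code{a = start + 1}, \code{d = end}.
#'
#' @param path Path to the JSONL file.
#' @param fasta Optional FASTA path supplying sequences for records without an
#'   inline \code{sequence} field.
#' @param level Dataset level, \code{"gene"} or \code{"isoform"}.
#' @return A \code{\link{junction_dataset}}.
#' @export
read_jsonl_dataset <- function(path, fasta = NULL, level = "gene") {
  if (!file.exists(path)) stop("dataset file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("dataset file is empty: ", path)
  seqs <- if (!is.null(fasta)) read_fasta(fasta) else NULL
  records <- lapply(lines, function(line) {
    obj <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    id <- as.character(obj$id)
    sequence <- if (!is.null(obj$sequence)) obj$sequence else {
      if (is.null(seqs) || is.na(seqs[id])) stop("record '", id, "': no sequence inline or in FASTA")
      seqs[[id]]
    }
    ex <- obj$exons
    if (is.list(ex)) ex <- do.call(rbind, ex)
    ex <- matrix(as.integer(ex), ncol = 2L)
    exons <- cbind(ex[, 1L] + 1L, ex[, 2L])  # 0-based half-open -> 1-based inclusive
    gene_record(id = id, sequence = sequence, exons = exons,
                label = if (is.null(obj$label)) NA_integer_ else as.integer(obj$label),
                group_id = if (is.null(obj$group)) NULL else as.character(obj$group),
                true_pair = if (is.null(obj$true_pair)) NULL else as.integer(obj$true_pair))
  })
  junction_dataset(records, level = level)
}

#' Write a dataset as JSONL (plus optional companion FASTA)
#'
#' Inverse of \code{\link{read_jsonl_dataset}}: junctions are exported as
#' 0-based half-open intervals \code{[a - 1, d)}.
#'
#' @param dataset A \code{junction_dataset}.
#' @param path Output JSONL path.
#' @param fasta Optional output FASTA path; if given, sequences are written
#'   there instead of inline.
#' @return Invisibly, \code{path}.
#' @export
write_jsonl_dataset <- function(dataset, path, fasta = NULL) {
  lines <- vapply(dataset$records, function(r) {
    obj <- list(id = r$id,
                exons = unname(lapply(seq_len(nrow(r$exons)), function(i)
                  c(r$exons[i, 1L] - 1L, r$exons[i, 2L]))))
    if (!is.na(r$label)) obj$label <- r$label
    if (!is.null(r$group_id)) obj$group <- r$group_id
    if (!is.null(r$true_pair)) obj$true_pair <- r$true_pair
    if (is.null(fasta)) obj$sequence <- r$sequence
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  }, character(1))
  writeLines(lines, path, useBytes = TRUE)
  if (!is.null(fasta)) {
    hdr <- paste0(">", dataset_ids(dataset))
    writeLines(as.vector(rbind(hdr, vapply(dataset$records, `[[`, character(1), "sequence"))),
               fasta, useBytes = TRUE)
  }
  invisible(path)
}

revcomp <- function(x) {
  paste(rev(strsplit(chartr("ACGTN", "TGCAN", x), "")[[1]]), collapse = "")
}

#' Read isoform structures from a BED12 file
#'
#' Each BED12 line becomes one gene record whose sequence is the chromosomal
#' slice \code{[chromStart, chromEnd)}; blocks define the exons. For minus
#' strand features the slice is reverse-complemented and exon junctions are
#' re-indexed on the reverse-complemented sequence, so the acceptor of each
#' exon stays its 5' junction in transcription order.
#'
#' @param path Path to a BED12 file.
#' @param fasta Path to the FASTA holding the chromosome sequences.
#' @param level Dataset level passed to \code{\link{junction_dataset}}.
#' @return A \code{\link{junction_dataset}}.
#' @export
read_bed12 <- function(path, fasta, level = "isoform") {
  if (!file.exists(path)) stop("BED file not found: ", path)
  chroms <- read_fasta(fasta)
  tab <- utils::read.table(path, sep = "\t", stringsAsFactors = FALSE,
                           colClasses = "character", comment.char = "#")
  if (ncol(tab) < 12L) stop("BED12 requires 12 columns, found ", ncol(tab))
  records <- lapply(seq_len(nrow(tab)), function(r) {
    row <- tab[r, ]
    chrom <- row[[1L]]; start <- as.integer(row[[2L]]); end <- as.integer(row[[3L]])
    name <- row[[4L]]; strand <- row[[6L]]
    n_blocks <- as.integer(row[[10L]])
    sizes <- as.integer(strsplit(row[[11L]], ",")[[1]])
    starts <- as.integer(strsplit(row[[12L]], ",")[[1]])
    if (length(sizes) != n_blocks || length(starts) != n_blocks)
      stop("BED12 line ", r, " ('", name, "'): blockCount=", n_blocks,
           " does not match blockSizes/blockStarts lengths")
    if (is.na(chroms[chrom])) stop("BED12 line ", r, ": chromosome '", chrom, "' not in FASTA")
    if (end > nchar(chroms[[chrom]]) || start < 0L)
      stop("BED12 line ", r, " ('", name, "'): interval outside chromosome")
    slice <- substr(chroms[[chrom]], start + 1L, end)
    len <- end - start
    s <- starts + 1L          # exon starts, 1-based on the slice
    e <- starts + sizes       # exon ends, 1-based inclusive on the slice
    if (identical(strand, "-")) {
      seq_t <- revcomp(slice)
      exons <- cbind(len - rev(e) + 1L, len - rev(s) + 1L)
      gene_record(name, seq_t, exons)
    } else {
      gene_record(name, slice, cbind(s, e))
    }
  })
  junction_dataset(records, level = level)
}

#' Write prediction scores as TSV
#'
#' @param records A \code{junction_dataset} or character vector of record ids.
#' @param scores Numeric scores in \[0, 1\], one per record.
#' @param path Output TSV path.
#' @param threshold Binary-call threshold; the call is \code{1} iff
#'   \code{score > threshold} (strict).
#' @return Invisibly, the written data frame (columns id, score, call).
#' @export
write_predictions <- function(records, scores, path, threshold = 0.5) {
  ids <- if (inherits(records, "junction_dataset")) dataset_ids(records) else as.character(records)
  if (length(ids) != length(scores))
    stop("length mismatch: ", length(ids), " records vs ", length(scores), " scores")
  if (any(!is.finite(scores)) || any(scores < 0) || any(scores > 1))
    stop("scores must be finite and in [0, 1]")
  df <- data.frame(id = ids,
                   score = sprintf("%.6f", scores),
                   call = as.integer(scores > threshold),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(df)
}
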