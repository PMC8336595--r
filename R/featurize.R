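#' Featurization configuration
#'
#' @param L Flanking-window length in positions (number of k-mer slots per
#'   junction).
#' @param K k-mer length.
#' @return A \code{feat_config} list with fields \code{L}, \code{K} and the
#'   reserved \code{pad_index = 4^K} used for out-of-range or ambiguous k-mers.
#' @export
feat_config <- function(L = 4L, K = 3L) {
  L <- as.integer(L); K <- as.integer(K)
  stopifnot(L >= 1L, K >= 1L)
  structure(list(L = L, K = K, pad_index = as.integer(4L^K)), class = "feat_config")
}

#' Positions of the flanking window around a junction
#'
#' The window of length \code{L} centered on a 1-based junction position runs
#' \code{center - floor((L-1)/2)} to \code{center + floor(L/2)}; positions may
#' fall outside the sequence (they later resolve to the pad index).
#'
#' @param center 1-based junction position.
#' @param L Window length.
#' @return Integer vector of exactly \code{L} consecutive positions.
#' @export
flanking_positions <- function(center, L) {
  L <- as.integer(L)
  stopifnot(L >= 1L)
  (center - (L - 1L) %/% 2L):(center + L %/% 2L)
}

# Integer base codes of a sequence: A=0,C=1,G=2,T=3, NA for anything else.
base_codes <- function(sequence) {
  codes <- match(strsplit(sequence, "", fixed = TRUE)[[1]], c("A", "C", "G", "T")) - 1L
  codes
}

#' Vocabulary index of the k-mer centered on a position
#'
#' Extracts the substring at positions \code{center - floor((K-1)/2)} to
#' \code{center + floor(K/2)}. If the window is fully inside the sequence and
#' over \{A,C,G,T\}, returns its base-4 code (A=0, C=1, G=2, T=3, most
#' significant digit first); otherwise returns the pad index \code{4^K}.
#'
#' @param sequence Character scalar.
#' @param center 1-based center position (vectorized).
#' @param K k-mer length.
#' @return Integer vector of indices in \code{[0, 4^K]}.
#' @export
kmer_index <- function(sequence, center, K) {
  K <- as.integer(K)
  stopifnot(K >= 1L)
  codes <- base_codes(sequence)
  kmer_index_codes(codes, center, K)
}

# Same as kmer_index but on precomputed base codes; vectorized over centers.
kmer_index_codes <- function(codes, center, K) {
  n <- length(codes)
  pad <- as.integer(4L^K)
  lo <- center - (K - 1L) %/% 2L
  out <- integer(length(center))
  pow <- 4L^((K - 1L):0L)
  for (t in seq_len(K)) {
    p <- lo + t - 1L
    ok <- p >= 1L & p <= n
    v <- rep(NA_integer_, length(center))
    v[ok] <- codes[p[ok]]
    out <- out + v * pow[t]
  }
  out[is.na(out)] <- pad
  as.integer(out)
}

#' Build a padded, masked batch of junction k-mer indices
#'
#' Each record contributes one acceptor row and one donor row per exon; the
#' site dimension is padded to the per-batch maximum exon count with the pad
#' index and marked off in \code{site_mask}.
#'
#' @param records List of \code{\link{gene_record}} objects (or a
#'   \code{junction_dataset}).
#' @param cfg A \code{\link{feat_config}}.
#' @return A \code{junction_batch} list: integer arrays \code{acceptor_ids}
#'   and \code{donor_ids} of dim \code{[B, M_max, L]}, binary matrix
#'   \code{site_mask} \code{[B, M_max]}, integer vector \code{labels [B]},
#'   exon counts \code{n_exons} and record \code{ids}.
#' @export
build_batch <- function(records, cfg) {
  if (inherits(records, "junction_dataset")) records <- records$records
  stopifnot(length(records) >= 1L)
  B <- length(records)
  m <- vapply(records, function(r) nrow(r$exons), integer(1))
  if (any(m < 1L)) stop("record(s) with zero exons: ",
                        paste(vapply(records[m < 1L], `[[`, character(1), "id"), collapse = ", "))
  M <- max(m)
  L <- cfg$L; K <- cfg$K; pad <- cfg$pad_index
  acc <- array(pad, dim = c(B, M, L))
  don <- array(pad, dim = c(B, M, L))
  mask <- matrix(0L, B, M)
  for (b in seq_len(B)) {
    r <- records[[b]]
    codes <- base_codes(r$sequence)
    for (i in seq_len(m[b])) {
      acc[b, i, ] <- kmer_index_codes(codes, flanking_positions(r$exons[i, 1L], L), K)
      don[b, i, ] <- kmer_index_codes(codes, flanking_positions(r$exons[i, 2L], L), K)
    }
    mask[b, seq_len(m[b])] <- 1L
  }
  storage.mode(acc) <- "integer"; storage.mode(don) <- "integer"
  structure(list(acceptor_ids = acc, donor_ids = don, site_mask = mask,
                 labels = vapply(records, function(r) r$label, integer(1)),
                 n_exons = m, ids = vapply(records, `[[`, character(1), "id"),
                 L = L, K = K, pad_index = pad),
            class = "junction_batch")
}
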