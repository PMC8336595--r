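#' Zero-shot backsplice pair scores from attention maps
#'
#' Interprets the donor site-attention weight as \eqn{P(d_j) = \gamma_j^d} and
#' the donor-side cross-attention weight as \eqn{P(a_i | d_j) = \beta_{j,i}^d},
#' so the joint probability of a backsplice between donor j and acceptor i is
#' \eqn{P(d_j, a_i) = \gamma_j^d \beta_{j,i}^d}. No pair annotation or
#' retraining is used: the scores are a pure function of a circRNA
#' classifier's attention maps.
#'
#' @param maps One record's attention maps (an element of the \code{maps}
#'   output of \code{\link{model_forward}} / \code{\link{predict_model}}).
#' @param record The matching \code{\link{gene_record}}.
#' @param upstream_only If \code{TRUE}, restrict candidates to pairs with
#'   \code{a_i <= d_j} (true backsplices join a donor to an upstream
#'   acceptor); default keeps all ordinal pairs.
#' @return Data frame with columns \code{record_id}, \code{donor_ordinal},
#'   \code{acceptor_ordinal}, \code{donor_pos}, \code{acceptor_pos},
#'   \code{score}; scores over all pairs sum to 1 per record (before any
#'   \code{upstream_only} restriction).
#' @export
backsplice_scores <- function(maps, record, upstream_only = FALSE) {
  m <- nrow(record$exons)
  if (length(maps$gamma_d) != m || !all(dim(maps$beta_d) == c(m, m)))
    stop("record '", record$id, "': attention maps do not match exon count ", m)
  score <- maps$gamma_d * maps$beta_d          # [donor j, acceptor i]
  df <- data.frame(record_id = record$id,
                   donor_ordinal = rep(seq_len(m), times = m),
                   acceptor_ordinal = rep(seq_len(m), each = m),
                   stringsAsFactors = FALSE)
  df$donor_pos <- record$exons[df$donor_ordinal, 2L]
  df$acceptor_pos <- record$exons[df$acceptor_ordinal, 1L]
  df$score <- score[cbind(df$donor_ordinal, df$acceptor_ordinal)]
  if (upstream_only) df <- df[df$acceptor_pos <= df$donor_pos, , drop = FALSE]
  df
}

#' Rank backsplice pair scores
#'
#' Descending by score; ties broken by donor then acceptor ordinal
#' (ascending), so the order is total and stable.
#'
#' @param scores Data frame from \code{\link{backsplice_scores}}.
#' @return The same data frame, ordered, with a \code{rank} column.
#' @export
rank_pairs <- function(scores) {
  stopifnot(nrow(scores) >= 1L)
  ord <- order(-scores$score, scores$donor_ordinal, scores$acceptor_ordinal)
  out <- scores[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Evaluate zero-shot backsplice discovery against planted truth
#'
#' Pools candidate pairs across records (label 1 for each record's true pair,
#' 0 otherwise) and computes the rank-statistic AUC, plus the fraction of
#' records whose top-ranked pair is the true pair.
#'
#' @param records List of \code{\link{gene_record}}s (only those with a
#'   \code{true_pair} are used; others are skipped with a warning).
#' @param score_tables List of data frames from
#'   \code{\link{backsplice_scores}}, parallel to \code{records}.
#' @param pooled If \code{FALSE}, the AUC is computed per record and averaged
#'   instead of pooled.
#' @return List with \code{auc}, \code{top1}, \code{n_records},
#'   \code{n_pairs} and the pooled \code{labels}/\code{scores} used.
#' @export
evaluate_discovery <- function(records, score_tables, pooled = TRUE) {
  stopifnot(length(records) == length(score_tables))
  keep <- vapply(records, function(r) !is.null(r$true_pair), logical(1))
  if (!all(keep)) warning(sum(!keep), " record(s) without true_pair skipped")
  records <- records[keep]; score_tables <- score_tables[keep]
  if (!length(records)) stop("no records with a true backsplice pair")
  labs <- list(); scs <- list(); per_auc <- numeric(0); top1 <- logical(0)
  for (i in seq_along(records)) {
    r <- records[[i]]; tab <- score_tables[[i]]
    if (nrow(tab) < 2L) stop("record '", r$id, "': need >= 2 candidate pairs")
    y <- as.integer(tab$donor_ordinal == r$true_pair[1L] &
                    tab$acceptor_ordinal == r$true_pair[2L])
    if (sum(y) != 1L) stop("record '", r$id, "': true pair not among candidates")
    labs[[i]] <- y; scs[[i]] <- tab$score
    ranked <- rank_pairs(tab)
    top1 <- c(top1, ranked$donor_ordinal[1L] == r$true_pair[1L] &&
                     ranked$acceptor_ordinal[1L] == r$true_pair[2L])
    if (!pooled) per_auc <- c(per_auc, auc_rank(y, tab$score))
  }
  auc <- if (pooled) auc_rank(unlist(labs), unlist(scs)) else mean(per_auc)
  list(auc = auc, top1 = mean(top1), n_records = length(records),
       n_pairs = length(unlist(labs)), labels = unlist(labs), scores = unlist(scs))
}

#' Write ranked backsplice pairs as TSV (and optionally BEDPE)
#'
#' @param score_tables List of data frames from \code{\link{backsplice_scores}}.
#' @param path Output TSV path.
#' @param bedpe Optional BEDPE output path for the top-k pairs per record
#'   (0-based half-open single-base intervals at the junction positions).
#' @param top_k Pairs per record exported to BEDPE.
#' @return Invisibly, the combined ranked data frame.
#' @export
write_pair_scores <- function(score_tables, path, bedpe = NULL, top_k = 1L) {
  ranked <- do.call(rbind, lapply(score_tables, rank_pairs))
  out <- ranked
  out$score <- sprintf("%.6g", out$score)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(bedpe)) {
    top <- do.call(rbind, lapply(score_tables, function(tab) {
      rk <- rank_pairs(tab)
      rk[seq_len(min(top_k, nrow(rk))), , drop = FALSE]
    }))
    bed <- data.frame(chrom1 = top$record_id, start1 = top$donor_pos - 1L,
                      end1 = top$donor_pos, chrom2 = top$record_id,
                      start2 = top$acceptor_pos - 1L, end2 = top$acceptor_pos,
                      name = sprintf("%s_d%d_a%d", top$record_id,
                                     top$donor_ordinal, top$acceptor_ordinal),
                      score = sprintf("%.6g", top$score))
    utils::write.table(bed, bedpe, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  invisible(ranked)
}
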