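#' Simulation configuration
#'
#' Describes the synthetic-gene world used for desk-scale testing: i.i.d.
#' background sequence with a given GC content, genes with variable exon
#' counts, and — in positive genes only — one planted (acceptor, donor) motif
#' pair overwriting the flanking windows of a single backsplice pair. The
#' motifs are centered on the junctions so they fall inside the default
#' L = 4, K = 3 receptive field; users changing L/K should keep the motif
#' centered likewise.
#'
#' @param n_genes Number of genes.
#' @param pos_fraction Fraction labeled positive (rounded to a count).
#' @param exon_count_range Integer (min, max) exons per gene.
#' @param exon_len_range Integer (min, max) exon length in nt.
#' @param intron_len_range Integer (min, max) intron length; also used for
#'   the 5' and 3' terminal flanks.
#' @param acceptor_motif,donor_motif Motifs over \{A,C,G,T\} planted centered
#'   on the chosen acceptor/donor junction of positive genes. Defaults are
#'   consensus-like splice-site 6-mers.
#' @param motif_mutation_prob Per-base probability of substituting a planted
#'   motif base with a random different base.
#' @param gc Background GC content in (0, 1).
#' @param duplication_frac Fraction of genes duplicated (with point mutations
#'   at rate \code{duplication_mut_prob}) into the same paralog group,
#'   exercising grouped cross-validation.
#' @param duplication_mut_prob Point-mutation rate for duplicated copies.
#' @param seed RNG seed; the dataset is fully determined by the config.
#' @return A \code{sim_config} list.
#' @export
sim_config <- function(n_genes = 2000L, pos_fraction = 0.5,
                       exon_count_range = c(2L, 6L),
                       exon_len_range = c(30L, 120L),
                       intron_len_range = c(20L, 80L),
                       acceptor_motif = "TTTCAG", donor_motif = "GTAAGT",
                       motif_mutation_prob = 0.1, gc = 0.5,
                       duplication_frac = 0, duplication_mut_prob = 0.01,
                       seed = 42L) {
  stopifnot(n_genes >= 1L, pos_fraction >= 0, pos_fraction <= 1,
            length(exon_count_range) == 2L, exon_count_range[1L] >= 1L,
            exon_count_range[1L] <= exon_count_range[2L],
            exon_len_range[1L] >= 1L, exon_len_range[1L] <= exon_len_range[2L],
            intron_len_range[1L] >= 1L, intron_len_range[1L] <= intron_len_range[2L],
            motif_mutation_prob >= 0, motif_mutation_prob <= 1,
            gc > 0, gc < 1, duplication_frac >= 0, duplication_frac <= 1)
  for (m in c(acceptor_motif, donor_motif))
    if (grepl("[^ACGT]", m)) stop("motifs must be over {A,C,G,T}: ", m)
  if (max(nchar(acceptor_motif), nchar(donor_motif)) >= exon_len_range[1L])
    stop("motifs must be shorter than the minimum exon length")
  structure(list(n_genes = as.integer(n_genes), pos_fraction = pos_fraction,
                 exon_count_range = as.integer(exon_count_range),
                 exon_len_range = as.integer(exon_len_range),
                 intron_len_range = as.integer(intron_len_range),
                 acceptor_motif = acceptor_motif, donor_motif = donor_motif,
                 motif_mutation_prob = motif_mutation_prob, gc = gc,
                 duplication_frac = duplication_frac,
                 duplication_mut_prob = duplication_mut_prob,
                 seed = as.integer(seed)),
            class = "sim_config")
}

rand_int <- function(n, range) {
  if (range[1L] == range[2L]) rep(range[1L], n)
  else sample(range[1L]:range[2L], n, replace = TRUE)
}

random_background <- function(len, gc) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(c("A", "C", "G", "T"), len, replace = TRUE, prob = p), collapse = "")
}

mutate_string <- function(x, prob) {
  if (prob <= 0) return(x)
  chars <- strsplit(x, "")[[1]]
  hit <- stats::runif(length(chars)) < prob
  if (any(hit)) {
    bases <- c("A", "C", "G", "T")
    chars[hit] <- vapply(chars[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
  }
  paste(chars, collapse = "")
}

plant_motif <- function(sequence, motif, center) {
  w <- nchar(motif)
  pos <- flanking_positions(center, w)
  if (pos[1L] < 1L || pos[w] > nchar(sequence))
    stop("motif window [", pos[1L], ",", pos[w], "] outside sequence of length ",
         nchar(sequence))
  paste0(substr(sequence, 1L, pos[1L] - 1L), motif,
         substr(sequence, pos[w] + 1L, nchar(sequence)))
}

#' Simulate a labeled gene dataset with planted backsplice pairs
#'
#' Each gene is an i.i.d. background sequence with exons drawn from the
#' configured ranges. Positive genes select one (acceptor exon i, donor exon
#' j) pair with i <= j — backsplices join a donor to an upstream acceptor —
#' and overwrite the acceptor motif centered on \code{a_i} and the donor
#' motif centered on \code{d_j}, then mutate each motif base independently.
#' Negatives carry no motif. The true pair is recorded on positives; each
#' gene is its own paralog group unless duplicated.
#'
#' @param cfg A \code{\link{sim_config}}.
#' @return A gene-level \code{\link{junction_dataset}} whose records carry
#'   \code{label}, \code{group_id} and (for positives) \code{true_pair}.
#' @export
simulate_dataset <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    n <- cfg$n_genes
    n_pos <- round(cfg$pos_fraction * n)
    labels <- integer(n)
    labels[sample.int(n, n_pos)] <- 1L
    records <- vector("list", n)
    for (g in seq_len(n)) {
      m <- rand_int(1L, cfg$exon_count_range)
      exon_len <- rand_int(m, cfg$exon_len_range)
      gaps <- rand_int(m + 1L, cfg$intron_len_range)  # 5' flank, introns, 3' flank
      total <- sum(exon_len) + sum(gaps)
      acc <- integer(m); don <- integer(m)
      pos <- gaps[1L]
      for (i in seq_len(m)) {
        acc[i] <- pos + 1L
        don[i] <- pos + exon_len[i]
        pos <- don[i] + gaps[i + 1L]
      }
      sequence <- random_background(total, cfg$gc)
      true_pair <- NULL
      if (labels[g] == 1L) {
        pairs <- which(upper.tri(matrix(0, m, m), diag = TRUE), arr.ind = TRUE)  # i <= j
        sel <- pairs[sample.int(nrow(pairs), 1L), ]
        i <- sel[[1L]]; j <- sel[[2L]]
        am <- mutate_string(cfg$acceptor_motif, cfg$motif_mutation_prob)
        dm <- mutate_string(cfg$donor_motif, cfg$motif_mutation_prob)
        sequence <- plant_motif(sequence, am, acc[i])
        sequence <- plant_motif(sequence, dm, don[j])
        true_pair <- c(j, i)  # (donor ordinal, acceptor ordinal)
      }
      id <- sprintf("gene%05d", g)
      records[[g]] <- gene_record(id, sequence, cbind(acc, don), label = labels[g],
                                  group_id = id, true_pair = true_pair)
    }
    if (cfg$duplication_frac > 0) {
      n_dup <- round(cfg$duplication_frac * n)
      dup_of <- sample.int(n, n_dup)
      extra <- lapply(seq_along(dup_of), function(k) {
        r <- records[[dup_of[k]]]
        gene_record(paste0(r$id, "_dup"), mutate_string(r$sequence, cfg$duplication_mut_prob),
                    r$exons, label = r$label, group_id = r$group_id,
                    true_pair = r$true_pair)
      })
      records <- c(records, extra)
    }
    junction_dataset(records, level = "gene")
  })
}

#' Label-shuffle negative control
#'
#' Returns the same records with the label multiset randomly permuted across
#' records under the given seed; sequences, exons and groups are untouched.
#' Training on this dataset should yield chance-level held-out performance.
#'
#' @param dataset A labeled \code{junction_dataset}.
#' @param seed Permutation seed.
#' @return A \code{junction_dataset} with permuted labels (true pairs are
#'   dropped, as they no longer mean anything).
#' @export
null_dataset <- function(dataset, seed = 1L) {
  labs <- dataset_labels(dataset)
  perm <- with_seed(mix_seed(seed, "label-shuffle"), sample(labs))
  records <- lapply(seq_along(dataset$records), function(i) {
    r <- dataset$records[[i]]
    r$label <- perm[i]
    r$true_pair <- NULL
    r
  })
  junction_dataset(records, level = dataset$level)
}
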