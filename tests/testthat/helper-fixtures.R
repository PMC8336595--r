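# Shared fixtures: tiny random records/configs built in code at test time.

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# A random gene record with m exons, long enough that exons fit comfortably.
random_record <- function(id, m = 2L, label = NA_integer_, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  exon_len <- sample(12:25, m, replace = TRUE)
  gap <- sample(8:20, m + 1L, replace = TRUE)
  acc <- integer(m); don <- integer(m)
  pos <- gap[1L]
  for (i in seq_len(m)) {
    acc[i] <- pos + 1L
    don[i] <- pos + exon_len[i]
    pos <- don[i] + gap[i + 1L]
  }
  gene_record(id, random_seq(pos), cbind(acc, don), label = label)
}

tiny_cfg <- function(...) {
  args <- list(K = 2L, l = 3L, L = 3L, h = 4L, a_dim = 2L, f_dim = 4L, lambda_l2 = 0)
  args[names(list(...))] <- list(...)
  do.call(model_config, args)
}

random_tiny_batch <- function(cfg, B = 2L, max_m = 3L, seed = 1L) {
  set.seed(seed)
  recs <- lapply(seq_len(B), function(b)
    random_record(paste0("r", b), m = sample.int(max_m, 1L),
                  label = sample(0:1, 1L)))
  list(records = recs, batch = build_batch(recs, feat_config(L = cfg$L, K = cfg$K)))
}

# All-zero parameters with the right shapes (degenerate-case tests).
zero_params <- function(cfg) {
  p <- init_params(cfg, seed = 1L)
  for (nm in names(p)) p[[nm]] <- p[[nm]] * 0
  p
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}
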