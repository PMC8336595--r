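test_that("backsplice scores are the product of donor and cross attention", {
  r <- gene_record("g", strrep("ACGT", 30), rbind(c(11, 40), c(61, 90)), label = 1L)
  maps <- list(gamma_d = c(0.6, 0.4),
               beta_d = rbind(c(0.5, 0.5), c(0.25, 0.75)),
               gamma_a = c(0.5, 0.5), beta_a = diag(2))
  tab <- backsplice_scores(maps, r)
  sc <- matrix(0, 2, 2)
  sc[cbind(tab$donor_ordinal, tab$acceptor_ordinal)] <- tab$score
  expect_equal(sc, rbind(c(0.30, 0.30), c(0.10, 0.30)), tolerance = 1e-12)
  expect_equal(sum(tab$score), 1, tolerance = 1e-12)
  # junction positions are carried through
  expect_identical(tab$donor_pos[tab$donor_ordinal == 2][1], 90L)

  # single exon: one pair with probability 1
  r1 <- gene_record("h", strrep("ACGT", 10), rbind(c(11, 30)))
  t1 <- backsplice_scores(list(gamma_d = 1, beta_d = matrix(1, 1, 1)), r1)
  expect_identical(nrow(t1), 1L)
  expect_equal(t1$score, 1)

  expect_error(backsplice_scores(list(gamma_d = c(1), beta_d = matrix(1)), r), "exon count")
})

test_that("rank_pairs orders by score with the documented tie-break", {
  r <- gene_record("g", strrep("ACGT", 30), rbind(c(11, 40), c(61, 90)), label = 1L)
  maps <- list(gamma_d = c(0.6, 0.4), beta_d = rbind(c(0.5, 0.5), c(0.25, 0.75)))
  rk <- rank_pairs(backsplice_scores(maps, r))
  # the 0.10 pair ranks last; the three 0.30 pairs fill the top ranks
  expect_equal(rk$score, c(0.30, 0.30, 0.30, 0.10), tolerance = 1e-9)
  expect_identical(rk$donor_ordinal[4], 2L)
  expect_identical(rk$acceptor_ordinal[4], 1L)
  expect_identical(rk$rank, 1:4)
  # exact ties resolve by (donor, acceptor) ascending
  tied <- data.frame(record_id = "t", donor_ordinal = c(2L, 1L, 1L, 2L),
                     acceptor_ordinal = c(2L, 2L, 1L, 1L),
                     donor_pos = 1L, acceptor_pos = 1L, score = 0.25)
  rkt <- rank_pairs(tied)
  expect_identical(rkt$donor_ordinal, c(1L, 1L, 2L, 2L))
  expect_identical(rkt$acceptor_ordinal, c(1L, 2L, 1L, 2L))

  # all-equal scores -> pure ordinal order
  mu <- list(gamma_d = c(0.5, 0.5), beta_d = matrix(0.5, 2, 2))
  rku <- rank_pairs(backsplice_scores(mu, r))
  expect_identical(rku$donor_ordinal, c(1L, 1L, 2L, 2L))
})

test_that("upstream_only keeps pairs with acceptor position <= donor position", {
  r <- gene_record("g", strrep("ACGT", 30), rbind(c(11, 40), c(61, 90)), label = 1L)
  maps <- list(gamma_d = c(0.6, 0.4), beta_d = rbind(c(0.5, 0.5), c(0.25, 0.75)))
  tab <- backsplice_scores(maps, r, upstream_only = TRUE)
  expect_true(all(tab$acceptor_pos <= tab$donor_pos))
  expect_identical(nrow(tab), 3L)   # (d1,a1), (d2,a1), (d2,a2); not (d1,a2)
})

test_that("evaluate_discovery pools records and matches the pairwise oracle", {
  r1 <- gene_record("g1", strrep("ACGT", 30), rbind(c(11, 40), c(61, 90)),
                    label = 1L, true_pair = c(2L, 1L))
  r2 <- gene_record("g2", strrep("ACGT", 30), rbind(c(11, 40), c(61, 90)),
                    label = 1L, true_pair = c(1L, 1L))
  m1 <- list(gamma_d = c(0.1, 0.9), beta_d = rbind(c(0.5, 0.5), c(0.8, 0.2)))
  m2 <- list(gamma_d = c(0.7, 0.3), beta_d = rbind(c(0.9, 0.1), c(0.5, 0.5)))
  tabs <- list(backsplice_scores(m1, r1), backsplice_scores(m2, r2))
  disc <- evaluate_discovery(list(r1, r2), tabs)
  expect_equal(disc$top1, 1)           # both true pairs rank first
  expect_equal(disc$auc, oracle_auc(disc$labels, disc$scores), tolerance = 1e-12)
  expect_identical(disc$n_pairs, 8L)

  # per-record averaging mode agrees with per-record oracles
  disc2 <- evaluate_discovery(list(r1, r2), tabs, pooled = FALSE)
  expect_equal(disc2$auc,
               mean(c(oracle_auc(disc$labels[1:4], disc$scores[1:4]),
                      oracle_auc(disc$labels[5:8], disc$scores[5:8]))), tolerance = 1e-12)

  # records without truth are skipped with a warning
  r3 <- gene_record("g3", strrep("ACGT", 30), rbind(c(11, 40), c(61, 90)), label = 1L)
  expect_warning(evaluate_discovery(list(r1, r3), list(tabs[[1]], tabs[[1]])), "skipped")
})

test_that("a trained classifier's maps feed discovery end to end", {
  ds <- simulate_dataset(sim_config(n_genes = 60, exon_count_range = c(2L, 3L),
                                    motif_mutation_prob = 0, seed = 31))
  mc <- model_config(l = 8L, h = 8L, a_dim = 4L, f_dim = 8L)
  fit <- train_model(ds, mc, train_config(seed = 3, max_epochs = 3L, batch_size = 32L))
  pred <- predict_model(fit, ds, keep = "maps")
  pos <- which(vapply(ds$records, `[[`, integer(1), "label") == 1L)
  tabs <- lapply(pos, function(i) backsplice_scores(pred$maps[[i]], ds$records[[i]]))
  for (tab in tabs) expect_equal(sum(tab$score), 1, tolerance = 1e-6)
  disc <- evaluate_discovery(ds$records[pos], tabs)
  expect_true(disc$auc >= 0 && disc$auc <= 1)
})
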