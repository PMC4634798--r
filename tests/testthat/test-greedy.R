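# A small deterministic 6-sample toy for hand-audited objective values.
toy <- list(
  feats = list(c(0L, 0L, 1L, 1L, 0L, 1L),
               c(0L, 1L, 1L, 0L, 1L, 0L),
               c(1L, 1L, 0L, 0L, 1L, 0L)),
  y = c(0L, 0L, 1L, 1L, 0L, 1L)
)

test_that("the objective catalog encodes the documented alpha/beta rules", {
  jmi <- make_objective("jmi")
  expect_equal(jmi$alpha(4), 1 / 4)
  expect_equal(jmi$beta(4), 1 / 4)
  mrmr <- make_objective("mRMR")
  expect_equal(mrmr$alpha(3), 1 / 3)
  expect_equal(mrmr$beta(3), 0)
  mim <- make_objective("MIM")
  expect_equal(mim$alpha(5), 0)
  expect_equal(mim$beta(5), 0)
  cife <- make_objective("cife")
  expect_equal(cife$alpha(7), 1)
  expect_equal(cife$beta(7), 1)
  expect_equal(make_objective("mifs")$alpha(9), 1)
  expect_error(make_objective("bogus"), "valid names")
})

test_that("every criterion reduces to I(X;Y) on an empty selected set", {
  state <- list(selected = integer(0))
  rel <- mutual_information(toy$feats[[1]], toy$y)
  for (nm in c("mim", "mifs", "mrmr", "jmi", "cife", "cmim", "icap",
               "disr", "condmi")) {
    expect_equal(objective_score(1L, toy$feats, toy$y, state, nm), rel,
                 info = nm)
  }
  # MIM ignores the selected set entirely
  expect_equal(objective_score(1L, toy$feats, toy$y,
                               list(selected = 2L), "mim"), rel)
  expect_error(objective_score(2L, toy$feats, toy$y,
                               list(selected = 2L), "jmi"),
               "already selected")
})

test_that("JMI score with one selected feature is the hand-summed triple", {
  state <- list(selected = 2L)
  got <- objective_score(1L, toy$feats, toy$y, state, "jmi")
  want <- oracle_mi(toy$feats[[1]], toy$y) -
    oracle_mi(toy$feats[[1]], toy$feats[[2]]) +
    oracle_cmi(toy$feats[[1]], toy$feats[[2]], toy$y)
  expect_equal(got, want, tolerance = 1e-12)
})

test_that("greedy selection is step-optimal and has the prefix property", {
  sim <- synthetic_abundance(K = 25, M = 120, n_informative = 4,
                             n_redundant = 2, n_xor_pairs = 1,
                             effect_size = 1.5, seed = 21)
  al <- extract_labels(sim$table, sim$metadata, "class")
  feats <- lapply(seq_len(25), function(i)
    discretize(al$table$counts[i, ], 10))
  y <- factor(al$labels$values)

  for (nm in c("mim", "mrmr", "jmi", "cmim", "icap", "disr", "condmi")) {
    res <- greedy_select(al$table, al$labels, k = 6, objective = nm)
    sel <- integer(0)
    for (step in seq_len(6)) {
      remaining <- setdiff(seq_len(25), sel)
      scores <- vapply(remaining, function(j)
        objective_score(j, feats, y, list(selected = sel), nm),
        numeric(1))
      expect_identical(res$feature_indices[step],
                       remaining[which.max(scores)],
                       info = paste(nm, "step", step))
      expect_equal(res$scores[step], max(scores), tolerance = 1e-12,
                   info = paste(nm, "step", step))
      sel <- c(sel, res$feature_indices[step])
    }
    # prefix property: k and k+1 agree on the first k picks
    res7 <- greedy_select(al$table, al$labels, k = 7, objective = nm)
    expect_identical(res7$feature_indices[1:6], res$feature_indices)
  }
})

test_that("MIM ordering equals sorting by marginal mutual information", {
  sim <- synthetic_abundance(K = 20, M = 80, n_informative = 3,
                             n_redundant = 0, n_xor_pairs = 0,
                             effect_size = 2, seed = 5)
  al <- extract_labels(sim$table, sim$metadata, "class")
  mi <- vapply(seq_len(20), function(i)
    mutual_information(discretize(al$table$counts[i, ], 10),
                       factor(al$labels$values)), numeric(1))
  res <- greedy_select(al$table, al$labels, k = 20, objective = "mim")
  expect_identical(res$feature_indices, order(-mi))
  expect_equal(res$scores, mi[order(-mi)])
})

test_that("duplicated features are punished by mRMR/JMI but not MIM", {
  sim <- synthetic_abundance(K = 10, M = 100, n_informative = 2,
                             n_redundant = 0, n_xor_pairs = 0,
                             effect_size = 3, seed = 9)
  al <- extract_labels(sim$table, sim$metadata, "class")
  counts <- rbind(al$table$counts, dup = al$table$counts[1, ])
  rownames(counts) <- c(al$table$feature_ids, "dup")
  tab <- abundance_table(counts)
  feats <- lapply(seq_len(11), function(i) discretize(counts[i, ], 10))
  y <- factor(al$labels$values)
  state <- list(selected = 1L)   # the original is selected

  standalone <- mutual_information(feats[[11]], y)
  self_red <- mutual_information(feats[[11]], feats[[1]])
  expect_lte(objective_score(11L, feats, y, state, "mrmr"),
             standalone - self_red + 1e-12)
  expect_lte(objective_score(11L, feats, y, state, "jmi"),
             standalone + 1e-12)
  expect_equal(objective_score(11L, feats, y, state, "mim"), standalone)
})

test_that("conditional redundancy lets JMI pull in an interaction partner", {
  # partially observable interaction: x1 is weakly relevant, its partner
  # x2 = y XOR x1 is exactly marginally independent of y, and together
  # they determine y; JMI must select x2 right after x1, while MIM ranks
  # x2 behind everything that has any marginal signal
  set.seed(31)
  M <- 240
  y <- rep(0:1, each = M / 2)
  x1 <- y
  flip <- c(sample(rep(c(TRUE, FALSE), c(30, 90))),
            sample(rep(c(TRUE, FALSE), c(30, 90))))  # 25% flips per class
  x1[flip] <- 1L - x1[flip]
  x2 <- as.integer(xor(x1, y))         # exactly balanced within classes
  noise <- replicate(15, rbinom(M, 1, 0.5))
  counts <- t(cbind(x1, x2, noise)) * 50 + 1
  tab <- abundance_table(counts, feature_ids = c("x1", "x2",
                                                 paste0("n", 1:15)))
  labs <- label_vector(as.character(y), sample_ids = tab$sample_ids)

  expect_equal(mutual_information(x2, y), 0)
  jmi <- greedy_select(tab, labs, k = 3, objective = "jmi")
  expect_identical(jmi$feature_indices[1:2], c(1L, 2L))
  mim <- greedy_select(tab, labs, k = 17, objective = "mim")
  expect_identical(match(1L, mim$feature_indices), 1L)
  # x2 can only be preceded by features with some empirical marginal MI
  # (noise features occasionally tie with it at exactly zero)
  expect_gt(match(2L, mim$feature_indices), 10L)
})

test_that("constant features are never selected before informative ones", {
  sim <- synthetic_abundance(K = 8, M = 60, n_informative = 2,
                             n_redundant = 0, n_xor_pairs = 0,
                             effect_size = 3, seed = 2)
  al <- extract_labels(sim$table, sim$metadata, "class")
  counts <- rbind(al$table$counts, flat = rep(7, 60))
  tab <- abundance_table(counts,
                         feature_ids = c(al$table$feature_ids, "flat"))
  res <- greedy_select(tab, al$labels, k = 9, objective = "mim")
  flat_pos <- match(9L, res$feature_indices)
  for (i in sim$truth$informative) {
    expect_lt(match(i, res$feature_indices), flat_pos)
  }
})

test_that("greedy_select validates its inputs", {
  sim <- synthetic_abundance(K = 5, M = 20, n_informative = 1,
                             n_redundant = 0, n_xor_pairs = 0, seed = 1)
  al <- extract_labels(sim$table, sim$metadata, "class")
  expect_error(greedy_select(al$table, al$labels, k = 6), "between 1")
  expect_error(greedy_select(al$table, rep("a", 20), k = 2),
               "fewer than two classes")
})
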