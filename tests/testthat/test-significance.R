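test_that("the connected-subgraph sampler is uniform on enumerable instances", {
  # size 1: direct uniform draw over the 6 vertices of the N=4 clique dual
  d4 <- to_edge_dual(4L)
  singles <- unlist(sample_connected_subgraphs(d4, 1L, 6000L, seed = 71))
  tab <- tabulate(singles, 6L)
  expect_true(all(abs(tab - 1000) < 3 * sqrt(6000 * (1 / 6) * (5 / 6))))

  # size 2: uniform over the 12 links of the N=4 clique dual
  pairs2 <- sample_connected_subgraphs(d4, 2L, 6000L, seed = 72)
  keys2 <- vapply(pairs2, set_key, character(1))
  expected2 <- vapply(enumerate_connected_sets(d4, 2L), set_key, character(1))
  expect_length(expected2, 12L)
  expect_true(all(keys2 %in% expected2))
  counts2 <- table(factor(keys2, levels = expected2))
  expect_gt(stats::chisq.test(as.vector(counts2))$p.value, 0.01)

  # size 3 on the N=5 clique dual vs exhaustive enumeration
  d5 <- to_edge_dual(5L)
  trip <- sample_connected_subgraphs(d5, 3L, 6000L, seed = 73)
  keys3 <- vapply(trip, set_key, character(1))
  expected3 <- vapply(enumerate_connected_sets(d5, 3L), set_key, character(1))
  expect_true(all(keys3 %in% expected3))
  counts3 <- table(factor(keys3, levels = expected3))
  expect_gt(stats::chisq.test(as.vector(counts3))$p.value, 0.01)

  expect_error(sample_connected_subgraphs(d4, 7L, 1L), "1..|E|", fixed = TRUE)
})

test_that("subgraph accuracy behaves on separable, null, and redundant features", {
  set.seed(74)
  y <- rep(c("high", "low"), each = 10)
  V <- matrix(runif(5 * 20), 5, 20)
  V[2, ] <- ifelse(y == "high", 1, 0)
  expect_equal(subgraph_accuracy(2L, V, y, seed = 3), 1.0)

  # pure-noise features against permuted labels hover at chance
  accs <- vapply(1:50, function(i) {
    set.seed(100 + i)
    subgraph_accuracy(c(1L, 3L), V[, sample(20)], y, seed = 3)
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)

  # duplicating a feature column leaves accuracy unchanged
  Vdup <- rbind(V, V[3, ])
  expect_equal(subgraph_accuracy(c(1L, 3L), V, y, seed = 3),
               subgraph_accuracy(c(1L, 3L, 6L), Vdup, y, seed = 3))
  expect_error(subgraph_accuracy(integer(0), V, y), "empty")
})

test_that("empirical p-values follow the add-one formula", {
  bg <- c(0.5, 0.6, 0.7, 0.8, 0.95)
  expect_equal(empirical_pvalue(0.9, bg), 2 / 6)
  expect_equal(empirical_pvalue(0.3, bg), 1.0)     # below the minimum
  expect_equal(empirical_pvalue(0.99, bg), 1 / 6)  # above the maximum
  expect_error(empirical_pvalue(1.2, bg), "\\[0, 1\\]")
})

test_that("q-values match the BH step-up oracle at pi0 = 1 and stay monotone", {
  p <- c(0.001, 0.01, 0.02, 0.8)
  expect_equal(compute_qvalues(p), c(0.004, 0.02, 4 * 0.02 / 3, 0.8),
               tolerance = 1e-12)
  expect_equal(compute_qvalues(p), stats::p.adjust(p, "BH"))
  expect_equal(compute_qvalues(rep(0.5, 10)), rep(0.5, 10))

  set.seed(75)
  for (m in c(5, 30, 200)) {
    p <- runif(m)^2
    q <- compute_qvalues(p)
    expect_true(all(q <= 1 + 1e-15))
    # q is a nondecreasing function of p (ties in q are allowed)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q <= stats::p.adjust(p, "BH") + 1e-12))  # pi0 <= 1 only helps
  }
  expect_length(compute_qvalues(numeric(0)), 0L)
})

test_that("null candidates yield near-uniform p-values", {
  # a label-independent study: backgrounds and candidates share one
  # distribution, so add-one p-values are (discretely) uniform
  set.seed(76)
  dual <- to_edge_dual(6L)
  ne <- nrow(dual$pairs)
  y <- rep(c("high", "low"), each = 10)
  V <- matrix(runif(ne * 20, 0.2, 0.8), ne, 20)
  cfg <- study_config(background_samples_per_size = 200L)
  bg <- background_distribution(dual, 2L, V, y, n_samples = 200L,
                                config = cfg, seed = 77)
  cand_sets <- sample_connected_subgraphs(dual, 2L, 80L, seed = 78)
  ps <- vapply(cand_sets, function(vs)
    empirical_pvalue(subgraph_accuracy(vs, V, y, seed = subnetminer:::.derive_seed(77, 19L)),
                     bg), numeric(1))
  ks <- suppressWarnings(stats::ks.test(ps, "punif"))
  expect_gt(ks$p.value, 0.01)
  expect_gt(mean(ps), 0.35)
})

test_that("filtering is boundary inclusive and the planted signal survives it", {
  cands <- lapply(c(0.01, 0.015, 0.02), function(q)
    list(edges = 1L, support = 1L, q_value = q))
  expect_length(filter_significant(cands, 0.015), 2L)
  expect_length(filter_significant(list(), 0.015), 0L)

  # end-to-end on a planted study: the planted signal is retained and edges
  # outside the planted subgraph are kept out of the significant set
  st <- generate_study(plant_spec(n_regions = 12L, n_sessions_per_class = 13L,
                                  rng_seed = 83L))
  cfg <- study_config(cv_folds = 4L, cv_repeats = 2L, inner_folds = 2L,
                      lam_grid = c(0.01, 0.1), k_grid = c(2L, 4L),
                      background_samples_per_size = 1000L, rng_seed = 83L)
  fit <- mine_biomarkers(st$networks, cfg)
  sig_union <- sort(unique(unlist(lapply(fit$significant, `[[`, "edges"))))
  expect_gt(length(fit$significant), 0L)
  expect_true(all(sig_union %in% st$planted_vertices))
  # decoy candidates (those touching unplanted edges) are rejected
  decoy <- Filter(function(s) !all(s$edges %in% st$planted_vertices),
                  fit$candidates)
  if (length(decoy))
    expect_gte(mean(vapply(decoy, `[[`, numeric(1), "q_value") > 0.015), 0.95)
})

test_that("label-permuted studies retain candidates at no more than the FDR rate", {
  # end-to-end type-I control: with labels permuted there is no signal, so
  # the expected fraction of retained candidates must not exceed q_threshold
  st <- generate_study(plant_spec(n_regions = 8L, n_sessions_per_class = 10L,
                                  rng_seed = 84L))
  dual <- to_edge_dual(8L)
  V <- vapply(st$networks, vertex_values, numeric(nrow(dual$pairs)), dual = dual)
  n_cand <- 0L
  n_kept <- 0L
  set.seed(85)
  for (r in 1:50) {
    perm <- sample(length(st$labels))
    cfg <- study_config(cv_folds = 3L, cv_repeats = 1L, inner_folds = 2L,
                        lam_grid = 0.1, k_grid = c(2L, 4L),
                        background_samples_per_size = 200L,
                        rng_seed = 1000L + r)
    nets <- Map(function(nw, l) { nw$label <- l; nw }, st$networks,
                st$labels[perm])
    fit <- mine_biomarkers(nets, cfg)
    n_cand <- n_cand + length(fit$candidates)
    n_kept <- n_kept + length(fit$significant)
  }
  expect_gt(n_cand, 0L)
  expect_lte(n_kept / n_cand, 0.015)
})

test_that("edge summaries match direct mean/correlation formulas", {
  set.seed(82)
  dual <- to_edge_dual(4L)
  V <- matrix(runif(6 * 10), 6, 10)
  y <- rep(c("high", "low"), each = 5)
  d <- runif(10)
  V[3, ] <- d * 0.5                     # exactly proportional to dropoff
  V[4, ] <- 0.42                        # constant edge
  es <- summarize_edges(c(1L, 3L, 4L), V, y, d, dual)
  expect_equal(es$mean_high, rowMeans(V[c(1, 3, 4), y == "high"]))
  expect_equal(es$mean_low, rowMeans(V[c(1, 3, 4), y == "low"]))
  expect_equal(es$correlation[1], cor(V[1, ], d))
  expect_equal(es$correlation[2], 1.0)
  expect_equal(es$correlation[3], 0)
  expect_equal(es$mean_high[3], es$mean_low[3])
})
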