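test_that("repeated CV produces the full run ledger deterministically", {
  st <- small_study()
  dual <- to_edge_dual(8L)
  V <- small_V()
  cfg <- study_config(cv_folds = 2L, cv_repeats = 1L, inner_folds = 2L,
                      lam_grid = 0.1, k_grid = c(2L, 4L), rng_seed = 5L)
  led <- run_repeated_cv(V, st$labels, dual, cfg)
  expect_equal(led$n_runs, 2L)
  held <- lapply(led$runs, `[[`, "heldout")
  expect_length(intersect(held[[1]], held[[2]]), 0L)
  expect_setequal(unlist(held), seq_along(st$labels))
  expect_true(all(lengths(lapply(led$runs, `[[`, "selected")) > 0))

  led2 <- run_repeated_cv(V, st$labels, dual, cfg)
  expect_identical(led, led2)

  cfg9 <- study_config(cv_folds = 9L, cv_repeats = 1L)
  expect_error(run_repeated_cv(V[, 1:10], st$labels[1:10], dual, cfg9),
               "stratification")
})

make_ledger <- function(selections, ne) {
  runs <- lapply(seq_along(selections), function(i)
    list(repeat_id = 1L, fold_id = i, selected = sort(as.integer(selections[[i]])),
         lam = 0.1, k = length(selections[[i]]), accuracy = 0.5,
         heldout = integer(0)))
  structure(list(runs = runs, n_runs = length(runs), n_vertices = ne),
            class = "run_ledger")
}

test_that("conserved mining matches the worked support examples", {
  dual <- to_edge_dual(3L)  # 3 dual vertices, all mutually linked
  led <- make_ledger(list(c(1, 2), c(1, 2), 1, 3), 3L)
  out <- mine_conserved(led, dual, frequency_threshold = 0.5, max_edges = 3L)
  expect_setequal(vapply(out, function(s) set_key(s$edges), character(1)),
                  c("1", "2", "1,2"))
  sup <- setNames(vapply(out, `[[`, integer(1), "support"),
                  vapply(out, function(s) set_key(s$edges), character(1)))
  expect_equal(sup[["1"]], 3L)
  expect_equal(sup[["2"]], 2L)
  expect_equal(sup[["1,2"]], 2L)

  # threshold 1: only subgraphs contained in every run
  all_runs <- mine_conserved(make_ledger(list(c(1, 2), c(1, 2, 3)), 3L),
                             dual, frequency_threshold = 1, max_edges = 3L)
  expect_setequal(vapply(all_runs, function(s) set_key(s$edges), character(1)),
                  c("1", "2", "1,2"))
  expect_error(mine_conserved(led, dual, frequency_threshold = 1.5), "threshold")
})

test_that("the miner equals exhaustive enumeration on random ledgers", {
  dual <- to_edge_dual(6L)  # 15 dual vertices
  ne <- nrow(dual$pairs)
  connected <- lapply(1:3, function(k) enumerate_connected_sets(dual, k))
  set.seed(61)
  for (rep in 1:10) {
    sels <- lapply(1:6, function(i) sample(ne, sample(3:7, 1)))
    led <- make_ledger(sels, ne)
    thr <- sample(c(1 / 3, 0.5), 1)
    mined <- mine_conserved(led, dual, frequency_threshold = thr, max_edges = 3L)
    min_sup <- ceiling(thr * led$n_runs)
    brute <- list()
    for (k in 1:3) for (vs in connected[[k]]) {
      sup <- sum(vapply(sels, function(s) all(vs %in% s), logical(1)))
      if (sup >= min_sup) brute[[length(brute) + 1L]] <- list(edges = vs, sup = sup)
    }
    expect_setequal(vapply(mined, function(s) set_key(s$edges), character(1)),
                    vapply(brute, function(s) set_key(s$edges), character(1)))
    sup_mined <- setNames(vapply(mined, `[[`, integer(1), "support"),
                          vapply(mined, function(s) set_key(s$edges), character(1)))
    for (b in brute) expect_equal(unname(sup_mined[[set_key(b$edges)]]), b$sup)
    # antimonotonicity over all mined pairs + connectivity recheck
    for (a in mined) {
      expect_length(igraph_edge_components(a$edges, dual), 1L)
      for (b in mined) {
        if (all(a$edges %in% b$edges))
          expect_gte(a$support, b$support)
      }
    }
  }
})

test_that("biomarker regions merge shared edges and split disjoint areas", {
  dual <- to_edge_dual(6L)
  v <- function(i, j) which(dual$pairs[, 1] == i & dual$pairs[, 2] == j)
  c1 <- list(edges = c(v(0, 1), v(1, 2)))
  c2 <- list(edges = c(v(1, 2), v(2, 3)))   # shares an edge with c1
  c3 <- list(edges = v(4, 5))               # disjoint brain area
  merged <- merge_biomarker_regions(list(c1, c2), dual)
  expect_length(merged, 1L)
  merged2 <- merge_biomarker_regions(list(c1, c2, c3), dual)
  expect_length(merged2, 2L)
  expect_equal(lengths(merged2), c(3L, 1L))

  # union-find oracle on random candidate lists
  set.seed(62)
  for (rep in 1:20) {
    cands <- lapply(1:4, function(i) list(edges = sample(nrow(dual$pairs),
                                                         sample(1:4, 1))))
    expect_identical(merge_biomarker_regions(cands, dual),
                     igraph_edge_components(
                       sort(unique(unlist(lapply(cands, `[[`, "edges")))), dual))
  }
})
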