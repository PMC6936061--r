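test_that("pairwise winner applies the mutation penalty and tie rule", {
  voter <- make_ranking("S1", c("A", "B", "C"), c(0.90, 1.00, 0),
                        mutated = "A")
  # normalized scores: A 0.9, B 1, C 0; A mutated: 0.9 > 0.85 * 1
  expect_equal(pairwise_winner("A", "B", voter), "A")

  # both unmutated, equal scores: tie falls to the second argument
  v2 <- make_ranking("S1", c("A", "B", "C", "D"), c(1, 1, 0, 2))
  expect_equal(pairwise_winner("A", "B", v2), "B")
  expect_equal(pairwise_winner("B", "A", v2), "A")

  # both mutated, equal: mutation status symmetric, still a tie
  v3 <- make_ranking("S1", c("A", "B", "C"), c(0.5, 0.5, 1),
                     mutated = c("A", "B"))
  expect_equal(pairwise_winner("A", "B", v3), "B")
})

test_that("a single voter with all genes mutated reproduces its own order", {
  voter <- make_ranking("S1", c("a", "b", "c", "d"), c(0.2, 0.9, 0.5, 0.1),
                        mutated = c("a", "b", "c", "d"))
  agg <- condorcet_aggregate(list(voter))
  expect_equal(agg$table$gene, c("b", "c", "a", "d"))
  expect_equal(sum(agg$table$copeland), 0L)
})

test_that("a gene preferred by a majority over every rival ranks first", {
  set.seed(5)
  voters <- lapply(1:5, function(i) {
    sc <- runif(4)
    names(sc) <- c("win", "a", "b", "c")
    sc["win"] <- 2  # strictly best for every voter
    make_ranking(paste0("S", i), names(sc), unname(sc),
                 mutated = sample(names(sc), 2))
  })
  agg <- condorcet_aggregate(voters)
  expect_equal(agg$table$gene[1], "win")
  expect_equal(agg$table$copeland[1], 3L)
})

test_that("aggregation matches an exhaustive brute-force tabulation", {
  set.seed(101)
  for (rep in 1:30) {
    n_g <- sample(2:8, 1)
    n_v <- sample(1:8, 1)
    genes <- paste0("g", seq_len(n_g))
    voters <- list()
    scores <- list()
    muts <- list()
    for (v in seq_len(n_v)) {
      sc <- round(runif(n_g), 2)
      mu <- genes[runif(n_g) < 0.4]
      voters[[v]] <- make_ranking(paste0("S", v), genes, sc, mutated = mu)
      scores[[v]] <- setNames(sc, genes)
      muts[[v]] <- mu
    }
    agg <- suppressWarnings(condorcet_aggregate(voters))
    oracle <- brute_condorcet(scores, muts, delta = 0.85)
    expect_equal(agg$table$gene, oracle$gene)
    expect_equal(agg$table$copeland, oracle$copeland)
    expect_equal(sum(agg$table$copeland), 0L)  # wins and losses balance
  }
})

test_that("aggregate ranking is invariant to voter order", {
  set.seed(77)
  genes <- paste0("g", 1:6)
  voters <- lapply(1:7, function(v) {
    make_ranking(paste0("S", v), genes, runif(6),
                 mutated = genes[runif(6) < 0.3])
  })
  a1 <- condorcet_aggregate(voters)
  a2 <- condorcet_aggregate(rev(voters))
  a2$table$n_patients_mutated <- a1$table$n_patients_mutated  # same by symmetry
  expect_equal(a1$table, a2$table)
})

test_that("no penalty plus identical voters reproduces the common order", {
  genes <- c("a", "b", "c", "d", "e")
  sc <- c(0.1, 0.9, 0.4, 0.7, 0.2)
  voters <- lapply(1:4, function(v) make_ranking(paste0("S", v), genes, sc))
  cfg <- mecorank_config(delta = 1)
  agg <- condorcet_aggregate(voters, cfg)
  expect_equal(agg$table$gene, genes[order(-sc)])
})

test_that("top-k selection clamps, prefixes, and validates k", {
  voters <- list(make_ranking("S1", paste0("g", 1:5), c(5, 4, 3, 2, 1),
                              mutated = paste0("g", 1:5)))
  agg <- condorcet_aggregate(voters)
  expect_equal(select_top_k(agg, 3), paste0("g", 1:3))
  expect_equal(select_top_k(agg, 100), paste0("g", 1:5))
  expect_equal(select_top_k(agg, 2), agg$table$gene[1:2])  # prefix property
  expect_error(select_top_k(agg, 0), "positive")
})

test_that("the candidate pool restricts genes to each voter's best", {
  genes <- paste0("g", 1:6)
  voters <- lapply(1:3, function(v) {
    make_ranking(paste0("S", v), genes, c(6, 5, 4, 3, 2, 1), mutated = genes)
  })
  agg <- condorcet_aggregate(voters, mecorank_config(candidate_pool = 2))
  expect_equal(agg$table$gene, c("g1", "g2"))
})
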