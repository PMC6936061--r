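test_that("damage coefficients follow the keyword filters and summing rule", {
  # neither filter matches: p = 0, y = 1 (mutation still counts as presence)
  dm <- damage_coefficients(make_mutation_table(
    "S1", "g1", polyphen_label = "benign", polyphen_score = 0.3,
    sift_label = "tolerated", sift_score = 0.8))
  expect_equal(dm$p, 0)
  expect_equal(dm$y, 1)

  # two damaging mutations in one gene sum
  dm <- damage_coefficients(make_mutation_table(
    c("S1", "S1"), c("g1", "g1"),
    polyphen_label = "probably_damaging", polyphen_score = c(0.95, 0.80)))
  expect_equal(dm$p, 1.75)
  expect_equal(dm$y, 2.75)
  expect_equal(dm$n_mutations, 2L)

  # no record for a (sample, gene) -> no entry
  expect_false(any(dm$gene == "g2"))

  # SIFT deleterious contributes 1 - score (low SIFT = damaging)
  dm <- damage_coefficients(make_mutation_table(
    "S1", "g1", sift_label = "deleterious", sift_score = 0.01))
  expect_equal(dm$p, 0.99)

  # a single variant matched by both predictors contributes once (the max)
  dm <- damage_coefficients(make_mutation_table(
    "S1", "g1", polyphen_label = "probably_damaging", polyphen_score = 0.7,
    sift_label = "deleterious", sift_score = 0.05))
  expect_equal(dm$p, 0.95)
})

test_that("missing score on a filtered-in label uses the logged default", {
  mt <- make_mutation_table("S1", "g1", polyphen_label = "probably_damaging")
  expect_message(dm <- damage_coefficients(mt), "default 1")
  expect_equal(dm$p, 1)
  expect_message(dm <- damage_coefficients(mt, missing_score = 0.5), "0.5")
  expect_equal(dm$y, 1.5)
})

test_that("damage is additive across split loads", {
  set.seed(42)
  mt <- make_mutation_table(
    sample = sample(c("S1", "S2"), 30, replace = TRUE),
    gene = sample(c("g1", "g2", "g3"), 30, replace = TRUE),
    polyphen_label = sample(c("probably_damaging", "benign"), 30, replace = TRUE),
    polyphen_score = round(runif(30), 2))
  whole <- damage_coefficients(mt)
  split <- sample(c(TRUE, FALSE), 30, replace = TRUE)
  a <- mt[split, ]
  b <- mt[!split, ]
  class(a) <- class(b) <- class(mt)
  merged <- merge_damage(damage_coefficients(a), damage_coefficients(b))
  expect_equal(merged$p, whole$p)
  expect_equal(merged$y, whole$y)
  expect_equal(merged$n_mutations, whole$n_mutations)
})

test_that("standardization is a z-score with population SD over tumor samples", {
  vals <- rbind(g1 = c(1, 3, 7), g2 = c(5, 5, 2))
  em <- make_expression(
    matrix(vals, 2, 3, dimnames = list(c("g1", "g2"), c("T1", "T2", "N1"))),
    c(T1 = "tumor", T2 = "tumor", N1 = "normal"))
  x0 <- standardize_expression(em)
  # oracle: direct mean / population-SD computation on (1, 3)
  mu <- mean(c(1, 3))
  sd_pop <- sqrt(mean((c(1, 3) - mu)^2))
  expect_equal(unname(x0["g1", ]), (c(1, 3) - mu) / sd_pop)  # = c(-1, 1)
  # zero-variance gene pinned to 0
  expect_equal(unname(x0["g2", ]), c(0, 0))
})

test_that("standardization respects sample permutation and sample-count guard", {
  set.seed(7)
  vals <- matrix(rnorm(12), 3, 4,
                 dimnames = list(paste0("g", 1:3), paste0("T", 1:4)))
  em <- make_expression(vals, setNames(rep("tumor", 4), colnames(vals)))
  x0 <- standardize_expression(em)
  perm <- c("T3", "T1", "T4", "T2")
  em2 <- make_expression(vals[, perm], em$condition[perm])
  expect_equal(standardize_expression(em2), x0[, perm])

  em1 <- make_expression(vals[, 1, drop = FALSE], em$condition[1])
  expect_error(standardize_expression(em1), ">= 2 tumor samples")
})

test_that("differential expression subtracts the normal mean and is shift-invariant", {
  vals <- matrix(c(4, 5, 1, 3), 1, 4,
                 dimnames = list("g1", c("T1", "T2", "N1", "N2")))
  em <- make_expression(vals, c(T1 = "tumor", T2 = "tumor",
                                N1 = "normal", N2 = "normal"))
  dx <- differential_expression(em)
  expect_equal(unname(dx["g1", ]), c(4 - 2, 5 - 2))

  em_shift <- make_expression(vals + 10, em$condition)
  expect_equal(differential_expression(em_shift), dx)

  em_eq <- make_expression(
    matrix(c(5, 5, 5), 1, 3, dimnames = list("g1", c("T1", "N1", "N2"))),
    c(T1 = "tumor", N1 = "normal", N2 = "normal"))
  expect_error(standardize_expression(em_eq), ">= 2")
  expect_equal(unname(differential_expression(em_eq)["g1", ]), 0)
})

test_that("profiles cover every tumor sample and exclude orphan mutation samples", {
  set.seed(1)
  genes <- paste0("g", 1:4)
  vals <- matrix(rnorm(20), 4, 5,
                 dimnames = list(genes, c("T1", "T2", "T3", "N1", "N2")))
  em <- make_expression(vals, setNames(c(rep("tumor", 3), rep("normal", 2)),
                                       colnames(vals)))
  mt <- make_mutation_table(c("T1", "T1", "T9"), c("g1", "g2", "g3"),
                            polyphen_label = "probably_damaging",
                            polyphen_score = 0.9)
  dm <- damage_coefficients(mt)
  expect_warning(
    profs <- suppressMessages(build_profiles(em, dm)),
    "absent from expression")
  expect_length(profs, 3L)
  expect_equal(vapply(profs, `[[`, "", "sample"), c("T1", "T2", "T3"))
  # profile gene set = expression gene set; unmutated samples keep empty maps
  expect_equal(names(profs[[1]]$x0), genes)
  expect_equal(names(profs[[1]]$dx), genes)
  expect_equal(sort(names(profs[[1]]$mutated)), c("g1", "g2"))
  expect_length(profs[[2]]$mutated, 0L)
})
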