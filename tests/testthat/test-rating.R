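make_data <- function(ratings_by_cell) {
  # ratings_by_cell: list of lists with participant, condition, ratings
  do.call(rbind, lapply(ratings_by_cell, function(cell) {
    n <- length(cell$ratings)
    data.frame(participant = cell$participant, condition = cell$condition,
               side = rep(c("left", "right"), length.out = n),
               repetition = rep(1:2, each = 2, length.out = n),
               rating = cell$ratings)
  }))
}

test_that("condition_summary computes cell and grand means", {
  d <- make_data(list(list(participant = 1, condition = "A",
                           ratings = c(1, 2, 4, 5)),
                      list(participant = 1, condition = "B",
                           ratings = c(3, 3, 3, 3)),
                      list(participant = 2, condition = "A",
                           ratings = c(2, 2, 2, 2))))
  s <- suppressMessages(condition_summary(d))
  expect_equal(s$participant_means["1", "A"], 3)
  expect_equal(s$participant_means["2", "A"], 2)
  expect_equal(s$condition_means[1], mean(c(1, 2, 4, 5, 2, 2, 2, 2)))
  expect_true(is.na(s$condition_means[3]))  # empty condition -> NA, not 0
  expect_false(s$complete)
  # constant data -> every mean equals the constant
  dc <- generate_ratings(rating_model_params(
    condition_latent_means = c(A = 3, B = 3, C = 3, D = 3, E = 3, F = 3),
    participant_sd = 0, trial_sd = 0))
  sc <- condition_summary(dc)
  expect_true(all(sc$condition_means == 3))
  expect_true(sc$complete)
})

test_that("summaries are invariant to record order", {
  d <- generate_ratings()
  perm <- d[sample.int(nrow(d)), ]
  s1 <- condition_summary(d)
  s2 <- condition_summary(perm)
  expect_equal(s1$condition_means, s2$condition_means)
  expect_equal(s1$participant_means, s2$participant_means)
  expect_equal(within_consistency(d)$value, within_consistency(perm)$value)
})

test_that("wilcoxon exact p matches the spec's worked examples", {
  # differences (1, 2, 3): W+ = 6, one-sided exact p = 1/8
  r <- wilcoxon_signed_rank(c(1, 2, 3), sided = "greater")
  expect_equal(r$w_plus, 6)
  expect_equal(r$p_value, 0.125)
  expect_identical(r$method, "exact_enumeration")
  # all-zero differences: degenerate
  expect_warning(r0 <- wilcoxon_signed_rank(c(0, 0, 0)), "degenerate")
  expect_equal(r0$p_value, 1)
  expect_identical(r0$n_effective, 0L)
  # constant positive shift, n = 10: statistic 0, two-sided p = 2/1024
  y <- rnorm(10)
  r10 <- wilcoxon_signed_rank(y + 3, y)
  expect_equal(r10$statistic, 0)
  expect_equal(r10$p_value, 2 / 1024)
})

test_that("exact p agrees with literal 2^n enumeration, with and without ties", {
  set.seed(7)
  for (i in 1:120) {
    n <- sample(3:12, 1)
    d <- if (i %% 2 == 0) {
      sample(c(-4:-1, 1:4), n, replace = TRUE)     # heavy ties
    } else {
      round(rnorm(n), 3)                            # essentially tie-free
    }
    if (all(d == 0)) next
    for (sided in c("two", "less", "greater")) {
      got <- suppressWarnings(
        wilcoxon_signed_rank(d, sided = sided, method = "exact"))
      want <- enumerate_wilcoxon(d, sided = sided)
      expect_equal(got$p_value, want$p, label = paste("case", i, sided))
      expect_equal(got$w_plus, want$w_plus)
    }
  }
})

test_that("tie-free exact p matches stats::wilcox.test", {
  set.seed(11)
  for (i in 1:20) {
    n <- sample(5:20, 1)
    d <- rnorm(n)
    got <- wilcoxon_signed_rank(d, method = "exact")
    want <- stats::wilcox.test(d, exact = TRUE)$p.value
    expect_equal(got$p_value, want, tolerance = 1e-12)
  }
})

test_that("pratt zero policy ranks zeros but excludes them from the sums", {
  d <- c(0, 0, 1, 2, -3, 5)
  r <- wilcoxon_signed_rank(d, zero_policy = "pratt", method = "exact")
  # |d| ranks over all six values: zeros get midrank 1.5; nonzero 3,4,5,6
  expect_equal(r$w_plus, 3 + 4 + 6)
  expect_identical(r$n_effective, 4L)
  want <- enumerate_wilcoxon(d, zero_policy = "pratt")
  expect_equal(r$p_value, want$p)
})

test_that("normal approximation is close to exact at n = 20 and used for large n", {
  set.seed(3)
  d <- rnorm(20)
  ex <- wilcoxon_signed_rank(d, method = "exact")
  ap <- wilcoxon_signed_rank(d, method = "normal")
  expect_lt(abs(ex$p_value - ap$p_value), 0.02)
  big <- wilcoxon_signed_rank(rnorm(40) + 0.2)
  expect_identical(big$method, "normal_approx")
})

test_that("the test is invariant to adding a constant to both samples", {
  set.seed(5)
  x <- sample(1:5, 12, replace = TRUE)
  y <- sample(1:5, 12, replace = TRUE)
  a <- suppressWarnings(wilcoxon_signed_rank(x, y))
  b <- suppressWarnings(wilcoxon_signed_rank(x + 7, y + 7))
  expect_equal(a$p_value, b$p_value)
  expect_equal(a$statistic, b$statistic)
})

test_that("within_consistency matches the hand-enumerated pair mean", {
  # cell (5, 3, 5, 3): 6 pairs, four differ by 2 -> 8/6
  d <- make_data(list(list(participant = 1, condition = "A",
                           ratings = c(5, 3, 5, 3))))
  expect_equal(within_consistency(d)$value, 8 / 6)
  # identical ratings everywhere -> 0
  dc <- generate_ratings(rating_model_params(participant_sd = 0, trial_sd = 0))
  expect_equal(within_consistency(dc)$value, 0)
  # singleton cells are excluded and counted
  d1 <- make_data(list(list(participant = 1, condition = "A", ratings = 4),
                       list(participant = 1, condition = "B",
                            ratings = c(1, 5))))
  r <- within_consistency(d1)
  expect_identical(r$n_singleton, 1L)
  expect_equal(r$value, 4)
  # noisier generators yield larger consistency values
  lo <- within_consistency(generate_ratings(rating_model_params(trial_sd = 0.3,
                                                                seed = 9)))
  hi <- within_consistency(generate_ratings(rating_model_params(trial_sd = 1.7,
                                                                seed = 9)))
  expect_gt(hi$value, lo$value)
})

test_that("analyze_ratings wires summary, test and consistency together", {
  d <- generate_ratings()
  rep <- analyze_ratings(d, test_pair = c("A", "D"))
  expect_s3_class(rep$wilcoxon, "wilcoxon_result")
  expect_identical(rep$wilcoxon$n_effective <= 15L, TRUE)
  expect_lt(rep$wilcoxon$p_value, 0.05)  # defaults separate A and D clearly
  trial <- analyze_ratings(d, test_pair = c("A", "D"), pairing = "trials")
  expect_s3_class(trial$wilcoxon, "wilcoxon_result")
})

test_that("rating CSV round-trips", {
  d <- generate_ratings()
  path <- withr::local_tempfile(fileext = ".csv")
  write_ratings_csv(d, path)
  back <- read_ratings_csv(path)
  expect_equal(back$rating, d$rating)
  expect_equal(back$condition, d$condition)
})

test_that("rating data validation rejects malformed input", {
  expect_error(condition_summary(data.frame(x = 1)), "must have columns")
  bad <- generate_ratings()
  bad$rating[1] <- 7
  expect_error(condition_summary(bad), "1..5")
})
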