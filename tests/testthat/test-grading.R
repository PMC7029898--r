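make_records <- function(n_expl, n_ctrl) {
  data.frame(
    sample_id = paste0("s", seq_len(n_expl + n_ctrl)),
    condition = c(rep("exploded", n_expl), rep("control", n_ctrl)),
    grade = "Scu 1",
    tailing_factor = runif(n_expl + n_ctrl, 1, 3),
    stringsAsFactors = FALSE
  )
}

test_that("the 50/50 split is condition-balanced and seed-deterministic", {
  set.seed(20)
  rec <- make_records(8, 8)
  sp <- split_train_test(rec, seed = 1)
  expect_equal(as.vector(table(sp$train$condition)), c(4, 4))
  expect_equal(as.vector(table(sp$test$condition)), c(4, 4))
  expect_equal(nrow(sp$train) + nrow(sp$test), 16)

  sp2 <- split_train_test(rec, seed = 1)
  expect_identical(sp, sp2)
  expect_false(identical(sp, split_train_test(rec, seed = 2)))

  odd <- make_records(7, 8)
  expect_warning(sp3 <- split_train_test(odd, seed = 3), "odd")
  expect_equal(sum(sp3$train$condition == "exploded"), 4)
  expect_equal(sum(sp3$test$condition == "exploded"), 3)

  expect_error(split_train_test(make_records(1, 8), seed = 1), "at least 2")
})

test_that("3-NN vote matches the hand-worked example and its oracle", {
  m <- knn_fit(c(1.2, 1.25, 1.3, 1.9, 2.0, 2.4),
               c("Scu 1", "Scu 1", "Scu 1", "Scu 2", "Scu 2", "Scu 3"), k = 3)
  p <- knn_predict(m, 1.95)
  expect_equal(p$predicted_grade, "Scu 2")
  expect_equal(p$probability, 2 / 3)

  # query on a training point with unanimous neighbourhood
  p2 <- knn_predict(m, 1.25)
  expect_equal(p2$predicted_grade, "Scu 1")
  expect_equal(p2$probability, 1)

  # 1-1-1 vote tie: nearest neighbour wins
  m3 <- knn_fit(c(1.0, 2.0, 3.0), c("Scu 1", "Scu 2", "Scu 3"), k = 3)
  expect_message(p3 <- knn_predict(m3, 2.1), "tie")
  expect_equal(p3$predicted_grade, "Scu 2")
  expect_equal(p3$probability, 1 / 3)

  # permutation invariance of the training list
  set.seed(21)
  tf <- runif(20, 1, 3); gr <- sample(scu_grades()[1:3], 20, replace = TRUE)
  q <- runif(10, 1, 3)
  m_a <- knn_fit(tf, gr, k = 3)
  perm <- sample(20)
  m_b <- knn_fit(tf[perm], gr[perm], k = 3)
  expect_equal(knn_predict(m_a, q), knn_predict(m_b, q))

  # agreement with the literal oracle on random queries
  for (qq in runif(50, 0.8, 3.2)) {
    expect_equal(knn_predict(m_a, qq)$predicted_grade, knn_oracle(tf, gr, 3, qq))
  }

  expect_error(knn_fit(c(1, -2), c("Scu 1", "Scu 2")), "positive")
  expect_error(knn_fit(1.5, "Scu 1", k = 3), "k")
})

test_that("evaluation reports accuracy over the test half", {
  set.seed(22)
  # perfectly separated classes: accuracy 1 on held-out data
  rec <- data.frame(
    sample_id = paste0("s", 1:20),
    condition = rep(c("control", "exploded"), each = 10),
    grade = rep(c("Scu 1", "Scu 3"), each = 10),
    tailing_factor = c(rnorm(10, 1.2, 0.05), rnorm(10, 2.4, 0.05)),
    stringsAsFactors = FALSE
  )
  sp <- split_train_test(rec, seed = 9)
  m <- knn_fit(sp$train$tailing_factor, sp$train$grade, k = 3)
  ev <- evaluate(m, sp$test)
  expect_equal(ev$accuracy, 1)
  expect_true(all(c("predicted_grade", "probability") %in% names(ev$table)))
  expect_true(all(ev$table$probability %in% c(1 / 3, 2 / 3, 1)))

  # adversarial fixture: disjoint label sets give zero accuracy
  bad <- sp$test
  bad$grade <- "Scu 4"
  expect_equal(evaluate(m, bad)$accuracy, 0)
  expect_error(evaluate(m, sp$test[0, ]), "empty")
})

test_that("3-NN recovers grade structure from grade-dependent distributions", {
  # tailing factors drawn around 1.2 / 1.8 / 2.4 (sd 0.15) per grade;
  # accuracy must beat chance (1/3) in >= 99% of seeded replicates
  wins <- vapply(1:200, function(s) {
    set.seed(s)
    rec <- data.frame(
      sample_id = paste0("s", 1:24),
      condition = rep(c("control", "exploded", "exploded"), each = 8),
      grade = rep(c("Scu 1", "Scu 2", "Scu 3"), each = 8),
      tailing_factor = pmax(0.2, rnorm(24, rep(c(1.2, 1.8, 2.4), each = 8), 0.15)),
      stringsAsFactors = FALSE
    )
    sp <- split_train_test(rec, seed = s)
    m <- knn_fit(sp$train$tailing_factor, sp$train$grade, k = 3)
    evaluate(m, sp$test)$accuracy > 1 / 3
  }, logical(1))
  expect_gte(mean(wins), 0.99)
})

test_that("the correlation screen matches cor.test and handles edge cases", {
  set.seed(23)
  x <- rnorm(30)
  y <- 0.6 * x + rnorm(30, sd = 0.5)
  got <- pearson_screen(x, y)
  ref <- cor.test(x, y)
  expect_equal(got$r, unname(ref$estimate), tolerance = 1e-12)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  expect_equal(got$df, unname(ref$parameter))

  expect_equal(pearson_screen(x, x)$r, 1)
  # constructed orthogonal pair
  xs <- x - mean(x)
  e <- rnorm(30)
  yo <- e - mean(e) - xs * sum((e - mean(e)) * xs) / sum(xs^2)
  expect_lt(abs(pearson_screen(x, yo)$r), 1e-12)

  expect_error(pearson_screen(rep(1, 10), rnorm(10)), "constant")
  expect_error(pearson_screen(1:2, 1:2), "n >= 3")
})

test_that("per-hair summaries give mean, sd, min, max", {
  expect_warning(s1 <- summarize_sample(1.5), "single record")
  expect_equal(s1, list(mean = 1.5, sd = 0, min = 1.5, max = 1.5, n = 1))

  tf <- c(1.197, 1.306, 1.403, 1.825, 2.145)
  s <- summarize_sample(tf)
  expect_equal(s$min, 1.197)
  expect_equal(s$max, 2.145)
  expect_equal(s$mean, mean(tf))
  # n-1 denominator, against the two-pass formula
  expect_equal(s$sd, sqrt(sum((tf - mean(tf))^2) / (length(tf) - 1)), tolerance = 1e-12)
})

test_that("the published test-set table is internally consistent", {
  t1 <- table1_test_set()
  expect_equal(nrow(t1), 16)
  expect_equal(sort(unique(t1$condition)), c("control", "exploded"))
  expect_true(all(t1$probability %in% c(1, 0.667)))
  expect_true(!is.unsorted(t1$tailing_factor))
  # a 3-NN model trained on the printed rows reproduces the printed
  # predictions wherever the vote was unanimous
  m <- knn_fit(t1$tailing_factor, t1$grade, k = 3)
  pred <- knn_predict(m, t1$tailing_factor[t1$probability == 1])
  expect_true(mean(pred$predicted_grade ==
                     t1$predicted_grade[t1$probability == 1]) >= 0.75)
})
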