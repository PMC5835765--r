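test_that("binary entropy matches the closed form", {
  expect_equal(binary_entropy(0.5), 1)
  expect_equal(binary_entropy(0), 0)
  expect_equal(binary_entropy(1), 0)
  expect_equal(binary_entropy(55 / 75), oracle_entropy(55 / 75))
  expect_equal(binary_entropy(55 / 75), 0.8366407, tolerance = 1e-7)
  expect_error(binary_entropy(1.2), class = "fcdsre_domain_error")
  expect_error(binary_entropy(-0.1), class = "fcdsre_domain_error")
})

test_that("information gain reproduces a hand-worked example", {
  v <- c(1, 2, 3, 4, 5)
  lab <- c(FALSE, FALSE, TRUE, TRUE, FALSE)
  # H(3/5) - [2/5 * H(0) + 3/5 * H(2/3)] worked out by hand
  expect_equal(information_gain(v, lab, 2.5), 0.4199731, tolerance = 1e-7)
  # identical label proportions on both sides: zero gain
  expect_equal(information_gain(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, FALSE),
                                2.5), 0)
  expect_error(information_gain(v, lab, 0.5), "D1",
               class = "fcdsre_domain_error")
  expect_error(information_gain(v, lab, 9), "D2",
               class = "fcdsre_domain_error")
})

test_that("a perfectly separating threshold attains the parent entropy", {
  d <- data.frame(v = c(1, 2, 3, 10, 11, 12),
                  pos = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  thr <- find_threshold(d, v, pos)
  expect_equal(thr$threshold, 6.5)
  expect_equal(thr$gain, 1)
  expect_equal(thr$gain, thr$parent_entropy)
  expect_equal(as.character(thr$data$size),
               c(rep("small", 3), rep("large", 3)))
})

test_that("degenerate threshold inputs raise informative errors", {
  d <- data.frame(v = c(1, 2, 3), pos = c(TRUE, TRUE, TRUE))
  expect_error(find_threshold(d, v, pos), "one label class",
               class = "fcdsre_domain_error")
  d2 <- data.frame(v = c(2, 2, 2), pos = c(TRUE, FALSE, TRUE))
  expect_error(find_threshold(d2, v, pos), "distinct",
               class = "fcdsre_domain_error")
  d3 <- data.frame(v = c(1, NA), pos = c(TRUE, FALSE))
  expect_error(find_threshold(d3, v, pos), class = "fcdsre_domain_error")
})

test_that("gain is nonnegative and bounded by the parent entropy at every candidate", {
  set.seed(31)
  for (i in 1:50) {
    inst <- random_instance()
    thr <- find_threshold(data.frame(v = inst$v, lab = inst$lab), v, lab)
    expect_true(all(thr$gain_curve$gain >= -1e-12))
    expect_true(all(thr$gain_curve$gain <= thr$parent_entropy + 1e-12))
  }
})

test_that("the search matches the exhaustive brute-force oracle", {
  set.seed(32)
  for (i in 1:300) {
    inst <- random_instance()
    thr <- find_threshold(data.frame(v = inst$v, lab = inst$lab), v, lab)
    orc <- oracle_find_threshold(inst$v, inst$lab)
    expect_equal(thr$threshold, orc$threshold)
    expect_equal(thr$gain, orc$gain)
  }
})

test_that("the split is invariant under strictly monotone volume transforms", {
  set.seed(33)
  for (i in 1:20) {
    inst <- random_instance()
    thr <- find_threshold(data.frame(v = inst$v, lab = inst$lab), v, lab)
    thr2 <- find_threshold(data.frame(v = inst$v^2, lab = inst$lab), v, lab)
    # ranks determine the partition; the cutpoint moves to the transformed gap
    expect_identical(as.character(thr$data$size), as.character(thr2$data$size))
    expect_equal(thr2$gain, thr$gain)
    expect_true(sum(inst$v^2 < thr2$threshold) == sum(inst$v < thr$threshold))
  }
})

test_that("gain ties break toward the smallest candidate", {
  # symmetric labels: candidates 1.5 and 3.5 tie; 1.5 must win
  d <- data.frame(v = 1:4, pos = c(FALSE, TRUE, FALSE, TRUE))
  thr <- find_threshold(d, v, pos)
  expect_equal(thr$threshold, 1.5)
})

test_that("literal gain mode reproduces the unweighted difference and can go negative", {
  v <- c(1, 2, 3, 4, 5)
  lab <- c(FALSE, FALSE, TRUE, TRUE, FALSE)
  g <- information_gain(v, lab, 2.5, mode = "literal")
  expect_equal(g, oracle_entropy(3 / 5) - (oracle_entropy(0) -
                                             oracle_entropy(2 / 3)))
  # negative literal gain exists when D2 is purer than D1
  expect_true(information_gain(c(1, 2, 3, 4), c(TRUE, FALSE, TRUE, TRUE),
                               3.5, mode = "literal") < 0)
  # both modes agree at the separating cut of perfectly separable equal halves
  vs <- c(1, 2, 10, 11); ls <- c(FALSE, FALSE, TRUE, TRUE)
  expect_equal(information_gain(vs, ls, 6, mode = "standard"),
               information_gain(vs, ls, 6, mode = "literal"))
})

test_that("size classification is strict at the boundary", {
  expect_equal(as.character(classify_size(c(3216.62, 3217, 290.69), 3217)),
               c("small", "large", "small"))
  expect_true(is.na(classify_size(NA_real_, 3217)))
  expect_error(classify_size(-5, 3217), class = "fcdsre_domain_error")
  # accepts an fcd_threshold directly
  d <- data.frame(v = c(1, 2, 10, 11), pos = c(FALSE, FALSE, TRUE, TRUE))
  thr <- find_threshold(d, v, pos)
  expect_equal(as.character(classify_size(5, thr)), "small")
})

test_that("threshold accessors expose the summary and the gain curve", {
  d <- data.frame(v = c(1, 2, 3, 10, 11, 12),
                  pos = c(FALSE, FALSE, FALSE, TRUE, TRUE, TRUE))
  thr <- find_threshold(d, v, pos)
  g <- glance(thr)
  expect_equal(g$n_small, 3)
  expect_equal(nrow(tidy(thr)), 5) # one candidate per consecutive gap
  p <- autoplot(thr)
  expect_s3_class(p, "ggplot")
})
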