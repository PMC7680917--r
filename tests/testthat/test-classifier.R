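test_that("input encoding is the affine map with the published anchors", {
  g <- published_genome()
  s0 <- encode_inputs(g, 0, 0.5)
  expect_equal(s0$t_ilum[1], 3.78)           # x = 0 -> t_start
  s1 <- encode_inputs(g, 1, 0.5)
  expect_equal(s1$t_ilum[1], 12.10)          # x = 1 -> t_end
  expect_equal(s1$t_ilum[3], 6.37)           # normal oscillator: fixed
  s <- encode_inputs(g, 0.25, 0.75)
  expect_equal(s$t_ilum[1], 3.78 + (12.10 - 3.78) * 0.25)
  expect_equal(s$t_ilum[2], 3.78 + (12.10 - 3.78) * 0.75)
  # input_x / input_y roles re-route the affine encoding to oscillator #3
  gx <- network_genome("input_x", t_ilum3 = 6.37, t_start = 3.78,
                       t_end = 12.10, t_max = 20.23, alpha = 0.849,
                       beta = 0.251)
  expect_equal(encode_inputs(gx, 0.25, 0.75)$t_ilum[3],
               3.78 + (12.10 - 3.78) * 0.25)
  gy <- network_genome("input_y", t_ilum3 = 6.37, t_start = 3.78,
                       t_end = 12.10, t_max = 20.23, alpha = 0.849,
                       beta = 0.251)
  expect_equal(encode_inputs(gy, 0.25, 0.75)$t_ilum[3],
               3.78 + (12.10 - 3.78) * 0.75)
  expect_error(encode_inputs(g, -0.1, 0.5))
  expect_error(encode_inputs(g, 0.5, 1.2))
})

test_that("the optimised network answers 1 maximum in the sun, 2 in the corner", {
  g <- published_genome()
  o_center <- respond(g, list(x = 0.5, y = 0.5), h = 1e-3)
  expect_identical(unname(o_center["o3"]), 1L)
  o_corner <- respond(g, list(x = 0.05, y = 0.05), h = 1e-3)
  expect_identical(unname(o_corner["o3"]), 2L)
})

test_that("swapping x and y swaps the two input oscillators' counts exactly", {
  g <- published_genome()
  d <- sample_flag(12, 301)
  a <- respond_batch(g, d, h = 1e-3)
  b <- respond_batch(g, data.frame(x = d$y, y = d$x, g = d$g), h = 1e-3)
  expect_identical(a$o1, b$o2)
  expect_identical(a$o2, b$o1)
  expect_identical(a$o3, b$o3)
})

test_that("batch responses equal record-wise responses and are deterministic", {
  g <- published_genome()
  d <- sample_flag(3, 77)
  tab <- respond_batch(g, d, h = 1e-3)
  for (i in seq_len(nrow(d))) {
    o <- respond(g, d[i, ], h = 1e-3)
    expect_identical(c(tab$o1[i], tab$o2[i], tab$o3[i]), unname(o))
  }
  # duplicated record gives identical rows
  d2 <- d[c(1, 1), ]
  tab2 <- respond_batch(g, d2, h = 1e-3)
  expect_identical(tab2$o3[1], tab2$o3[2])
  # one-record dataset works
  tab1 <- respond_batch(g, d[1, ], h = 1e-3)
  expect_identical(nrow(tab1), 1L)
})

test_that("the majority rule reproduces the published contingency decision", {
  # counts reported for the training set: at one maximum 369 sun / 30
  # background, at two maxima 8 sun / 393 background
  tab <- data.frame(g = c(rep(1, 369), rep(0, 30), rep(1, 8), rep(0, 393)),
                    o3 = c(rep(1, 399), rep(2, 401)))
  tab$x <- tab$y <- 0.5
  rule <- fit_decision_rule(tab, 3L)
  expect_identical(predict_counts(rule, 1L), 1L)
  expect_identical(predict_counts(rule, 2L), 0L)
  expect_equal(classification_accuracy(tab, rule), (369 + 393) / 800)
  # unseen counts fall back to class 0
  expect_identical(predict_counts(rule, 7L), 0L)
})

test_that("single-class tables and ties resolve deterministically", {
  tab <- data.frame(g = rep(1, 5), o3 = rep(1, 5))
  rule <- fit_decision_rule(tab, 3L)
  expect_identical(predict_counts(rule, 1L), 1L)
  expect_identical(predict_counts(rule, 2L), 0L)   # fallback
  tie <- data.frame(g = c(0, 1), o3 = c(4, 4))
  expect_identical(predict_counts(fit_decision_rule(tie, 3L), 4L), 0L)
})

test_that("a constant-prediction rule scores 1/2 on a balanced table", {
  tab <- data.frame(g = rep(c(0, 1), each = 50), o3 = rep(1, 100))
  rule <- fit_decision_rule(tab, 3L)
  expect_equal(classification_accuracy(tab, rule), 0.5)
})

test_that("accuracy is invariant under a count relabeling bijection", {
  set.seed(5)
  tab <- data.frame(g = sample(0:1, 60, replace = TRUE),
                    o3 = sample(1:3, 60, replace = TRUE))
  rule <- fit_decision_rule(tab, 3L)
  acc <- classification_accuracy(tab, rule)
  tab2 <- tab
  tab2$o3 <- c(7L, 5L, 9L)[tab$o3]  # bijection 1->7, 2->5, 3->9
  expect_equal(classification_accuracy(tab2, fit_decision_rule(tab2, 3L)),
               acc)
})
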