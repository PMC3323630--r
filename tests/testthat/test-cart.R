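test_that("node deviance follows the two-class closed form", {
  expect_equal(node_deviance(c(10, 0)), 0)
  expect_equal(node_deviance(c(4, 4)), 16 * log(2), tolerance = 1e-12)
  expect_equal(node_deviance(c(3, 1)), -2 * (3 * log(0.75) + log(0.25)),
               tolerance = 1e-12)
  expect_error(node_deviance(c(0, 0)), "no observations")
  expect_error(node_deviance(c(-1, 2)), "non-negative")
})

test_that("best_split equals the exhaustive enumeration oracle", {
  # printed 8-row fixture with two predictors
  X <- data.frame(a = c(1, 2, 3, 4, 5, 6, 7, 8),
                  b = c(5, 1, 4, 2, 8, 3, 7, 6))
  y <- c(0, 0, 0, 0, 1, 1, 1, 1)
  ctl <- growth_control(mincut = 2)
  got <- best_split(X, y, ctl)
  want <- oracle_best_split(X, y, mincut = 2)
  expect_equal(got[c("var", "threshold", "reduction")], want)
  # perfect separation recovers the whole parent deviance
  expect_equal(got$reduction, node_deviance(c(4, 4)), tolerance = 1e-12)
  # randomized fixtures (<= 50 rows)
  for (seed in 1:8) {
    set.seed(seed)
    n <- sample(12:50, 1)
    Xr <- data.frame(p = rnorm(n), q = sample(1:4, n, TRUE), r = runif(n))
    yr <- as.integer(runif(n) < plogis(2 * Xr$p))
    if (length(unique(yr)) < 2) next
    g <- best_split(Xr, yr, growth_control())
    w <- oracle_best_split(Xr, yr, mincut = 5)
    if (is.null(w)) {
      expect_null(g)
    } else {
      expect_equal(g[c("var", "threshold")], w[c("var", "threshold")])
      expect_equal(g$reduction, w$reduction, tolerance = 1e-10)
    }
  }
  # constant predictors admit no split
  expect_null(best_split(data.frame(k = rep(1, 20)), rep(0:1, 10),
                         growth_control()))
})

test_that("growing respects purity, separability and structural invariants", {
  X <- data.frame(x = 1:20)
  t0 <- grow_tree(X, rep(1L, 20))
  expect_equal(n_leaves(t0), 1L)
  expect_equal(t0$frame$dev, 0)
  d <- planted_xy(120, seed = 2)
  fit <- grow_tree(d$X, d$y)
  expect_equal(mean((predict_prob(fit, d$X) >= 0.5) != d$y), 0)
  fr <- fit$frame
  for (r in which(fr$var != "<leaf>")) {
    ch <- match(c(2 * fr$id[r], 2 * fr$id[r] + 1), fr$id)
    expect_equal(fr$n0[ch[1]] + fr$n0[ch[2]], fr$n0[r])
    expect_equal(fr$n1[ch[1]] + fr$n1[ch[2]], fr$n1[r])
    expect_lt(fr$dev[ch[1]] + fr$dev[ch[2]], fr$dev[r])
    expect_gt(fr$reduction[r], 0)
  }
  expect_lte(sum(fr$dev[fr$var == "<leaf>"]), fr$dev[1])
  expect_error(grow_tree(data.frame(x = c(1, NA, 3, 4)), c(0, 1, 0, 1)),
               "missing")
})

test_that("grown trees agree with the classic recursive-partitioning engine", {
  skip_if_not_installed("tree")
  set.seed(77)
  n <- 200
  X <- data.frame(u = runif(n), v = rnorm(n), w = runif(n))
  y <- as.integer(X$u + 0.3 * X$v + rnorm(n, 0, 0.25) > 0.6)
  dat <- cbind(X, yf = factor(y))
  fit <- grow_tree(X, y)
  ref <- tree::tree(yf ~ u + v + w, data = dat,
                    control = tree::tree.control(n, mincut = 5, minsize = 10,
                                                 mindev = 0.01))
  expect_equal(n_leaves(fit), sum(ref$frame$var == "<leaf>"))
  expect_equal(unname(predict_prob(fit, X)),
               unname(predict(ref, newdata = dat)[, "1"]), tolerance = 1e-9)
})

test_that("probability prediction routes rows to their leaves", {
  X <- data.frame(x = c(1, 2, 3, 4))
  t1 <- grow_tree(X, c(0, 0, 0, 1), growth_control(minsize = 100))
  expect_equal(predict_prob(t1, X), rep(0.25, 4))
  d <- planted_xy(80, seed = 9)
  fit <- grow_tree(d$X, d$y)
  pr <- predict_prob(fit, d$X)
  expect_true(all(pr >= 0 & pr <= 1))
  expect_equal(mean(pr), mean(d$y), tolerance = 1e-12)
  # hand routing through a three-split tree
  Xh <- data.frame(a = c(rep(0, 8), rep(1, 8)), b = rep(c(0, 0, 1, 1), 4),
                   check.names = FALSE)
  yh <- c(0, 0, 0, 0, 0, 0, 1, 1, 0, 1, 1, 1, 1, 1, 1, 1)
  th <- grow_tree(Xh, yh, growth_control(minsize = 4, mincut = 2,
                                         mindev = 1e-9))
  row <- data.frame(a = 0.9, b = 0.2)
  fr <- th$frame
  id <- 1
  repeat {
    k <- match(id, fr$id)
    if (fr$var[k] == "<leaf>") break
    id <- if (row[[fr$var[k]]] < fr$threshold[k]) 2 * id else 2 * id + 1
  }
  expect_equal(predict_prob(th, row), fr$prob[match(id, fr$id)])
  expect_error(predict_prob(th, data.frame(a = 1)), "missing predictor")
})

test_that("adjusted D-squared follows its penalised closed form", {
  # null single-leaf model explains nothing
  X <- data.frame(x = rep(1, 30))
  y <- rep(c(0L, 1L), 15)
  t0 <- grow_tree(X, y)
  a0 <- adjusted_d2(t0, X, y)
  expect_equal(a0$d2, 0)
  expect_equal(a0$adj_d2, 0)
  # perfectly separating model explains everything
  d <- planted_xy(60, seed = 4)
  fit <- grow_tree(d$X, d$y)
  af <- adjusted_d2(fit, d$X, d$y)
  expect_equal(af$d2, 1, tolerance = 1e-12)
  expect_equal(af$adj_d2, 1, tolerance = 1e-12)
  # printed 5-leaf model with exactly D^2 = 0.64 at n = 100:
  # 64 rows fall in pure leaves (zero deviance), 36 rows in 50/50 leaves
  # (2 ln 2 each), so D_model = 72 ln 2 = 0.36 * D_null (D_null = 200 ln 2)
  Xe <- data.frame(x = c(rep(1, 16), rep(2, 16), rep(3, 32),
                         rep(4, 18), rep(5, 18)))
  ye <- c(rep(1L, 32), rep(0L, 32), rep(c(0L, 1L), 18))
  lf <- function(id, n, n1, prob) {
    data.frame(id = id, var = "<leaf>", threshold = NA_real_, n = n,
               n0 = n - n1, n1 = n1, dev = binom_dev_vec(n - n1, n1),
               prob = prob, reduction = NA_real_, stringsAsFactors = FALSE)
  }
  nd <- function(id, thr, n, n1) {
    data.frame(id = id, var = "x", threshold = thr, n = n, n0 = n - n1,
               n1 = n1, dev = binom_dev_vec(n - n1, n1), prob = n1 / n,
               reduction = 1, stringsAsFactors = FALSE)
  }
  binom_dev_vec <- function(n0, n1) {
    n <- n0 + n1
    -2 * (ifelse(n0 > 0, n0 * log(n0 / n), 0) +
            ifelse(n1 > 0, n1 * log(n1 / n), 0))
  }
  te <- structure(list(
    frame = rbind(nd(1, 2.5, 100, 50), nd(2, 1.5, 32, 32),
                  lf(4, 16, 16, 1), lf(5, 16, 16, 1),
                  nd(3, 3.5, 68, 18), lf(6, 32, 0, 0),
                  nd(7, 4.5, 36, 18), lf(14, 18, 9, 0.5),
                  lf(15, 18, 9, 0.5)),
    predictors = "x", control = growth_control(), n = 100,
    root_dev = 200 * log(2)), class = "benthic_tree")
  expect_equal(n_leaves(te), 5L)
  ae <- adjusted_d2(te, Xe, ye)
  expect_equal(ae$d2, 0.64, tolerance = 1e-12)
  expect_equal(ae$adj_d2, 1 - (99 / 95) * 0.36, tolerance = 1e-12)
  expect_error(adjusted_d2(fit, d$X[1:3, ], d$y[1:3]), "n <= terminal")
})

test_that("explained-deviance attribution sums to 100 and matches bookkeeping", {
  d <- planted_xy(150, seed = 6, noise_preds = 1)
  fit <- grow_tree(d$X, d$y)
  vc <- variable_contribution(fit)
  expect_equal(sum(vc), 100, tolerance = 1e-9)
  fr <- fit$frame
  int <- fr$var != "<leaf>"
  manual <- tapply(fr$reduction[int], fr$var[int], sum)
  manual <- 100 * manual / sum(manual)
  expect_equal(vc[names(manual)], c(manual)[names(manual)], tolerance = 1e-12)
  # one split: everything to that variable
  one <- grow_tree(data.frame(z = c(1:10)), c(rep(0, 5), rep(1, 5)),
                   growth_control(mincut = 2))
  expect_equal(unname(variable_contribution(one)), 100)
  # single leaf: empty attribution
  expect_length(variable_contribution(grow_tree(data.frame(z = 1:10),
                                                rep(1L, 10))), 0)
})

test_that("drop_term quantifies the deviance cost of removing a predictor", {
  d <- planted_xy(200, seed = 12, noise_preds = 1)
  unused <- drop_term(d$X, d$y, "noise1", seed = 3)
  expect_equal(unused$change, 0, tolerance = 1e-9)
  # dropping one of two identical copies changes nothing
  X2 <- d$X
  X2$a_copy <- X2$a
  red <- drop_term(X2, d$y, "a_copy", seed = 3)
  expect_equal(red$change, 0, tolerance = 1e-9)
  # dropping the sole informative predictor loses essentially the whole fit
  X3 <- data.frame(x = d$X$a)
  y3 <- as.integer(d$X$a > 0.5)
  sole <- drop_term(X3, y3, "x", seed = 3)
  expect_equal(sole$change, sole$full_adj_d2)
  expect_gt(sole$full_adj_d2, 0.9)
})

test_that("cost-complexity CV pruning keeps signal and drops noise", {
  # a one-leaf tree passes through unchanged
  X <- data.frame(x = 1:20)
  t0 <- grow_tree(X, rep(1L, 20))
  pr0 <- cv_prune(t0, X, rep(1L, 20), folds = 5, seed = 1)
  expect_equal(pr0$tree$frame, t0$frame)
  # noiseless separable data keep zero training error after pruning
  d <- planted_xy(160, seed = 14)
  fit <- grow_tree(d$X, d$y)
  pr <- cv_prune(fit, d$X, d$y, seed = 2)
  expect_equal(mean((predict_prob(pr$tree, d$X) >= 0.5) != d$y), 0)
  expect_true(all(diff(pr$sequence$size) <= 0))
  # the pruned tree is a rooted subtree of the grown tree
  expect_true(all(pr$tree$frame$id %in% fit$frame$id))
  sub <- fit$frame[match(pr$tree$frame$id, fit$frame$id), ]
  int <- pr$tree$frame$var != "<leaf>"
  expect_identical(pr$tree$frame$var[int], sub$var[int])
  # identical seeds give identical pruning
  pr2 <- cv_prune(fit, d$X, d$y, seed = 2)
  expect_identical(pr$tree$frame, pr2$tree$frame)
  expect_error(cv_prune(fit, d$X, d$y, folds = 1000), "exceeds")
})

test_that("pruning retains planted variables over noise predictors", {
  hits <- 0L
  n_rep <- 20
  for (rep in seq_len(n_rep)) {
    d <- planted_xy(500, seed = 300 + rep, noise_preds = 5)
    # soften the signal so the grown tree picks up some noise splits
    set.seed(400 + rep)
    y <- ifelse(runif(500) < 0.05, 1L - d$y, d$y)
    fit <- grow_tree(d$X, y)
    pr <- cv_prune(fit, d$X, y, seed = 500 + rep)
    used <- setdiff(unique(pr$tree$frame$var), "<leaf>")
    if (length(used) && all(used %in% c("a", "b"))) hits <- hits + 1L
  }
  expect_gte(hits / n_rep, 0.9)
})

test_that("trees serialize to plain text and back", {
  d <- planted_xy(90, seed = 18, noise_preds = 2)
  fit <- grow_tree(d$X, d$y)
  f <- tempfile(fileext = ".txt")
  write_tree(fit, f)
  back <- read_tree(f)
  expect_equal(back$frame, fit$frame, tolerance = 1e-15)
  expect_identical(back$predictors, fit$predictors)
  expect_equal(back$n, fit$n)
  expect_equal(predict_prob(back, d$X), predict_prob(fit, d$X))
})
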