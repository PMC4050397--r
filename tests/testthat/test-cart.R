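test_that("gini impurity matches hand arithmetic and rejects empty nodes", {
  expect_equal(gini_impurity(c(10, 10)), 0.5)
  expect_equal(gini_impurity(c(20, 0)), 0)
  expect_equal(gini_impurity(c(3, 1)), 0.375)
  expect_error(gini_impurity(c(0, 0)), "empty")
})

test_that("best_split enumerates midpoints and maximizes Gini improvement", {
  d <- data.frame(x = 1:4, y = c(0, 0, 1, 1))
  sp <- best_split(d, "x", "y", minbucket = 1)
  expect_equal(sp$variable, "x")
  expect_equal(sp$threshold, 2.5)
  expect_equal(sp$improvement, 0.5)

  # pure node: no split
  expect_null(best_split(data.frame(x = 1:4, y = rep(1, 4)), "x", "y"))

  # duplicated variable: tie broken by input order
  d2 <- data.frame(x1 = 1:4, x2 = 1:4, y = c(0, 0, 1, 1))
  expect_equal(best_split(d2, c("x1", "x2"), "y", minbucket = 1)$variable, "x1")
  expect_equal(best_split(d2, c("x2", "x1"), "y", minbucket = 1)$variable, "x2")

  # minbucket makes the separating split ineligible
  d3 <- data.frame(x = 1:6, y = c(0, 0, 0, 0, 0, 1))
  sp3 <- best_split(d3, "x", "y", minbucket = 2)
  expect_true(is.null(sp3) || sp3$threshold != 5.5)
})

test_that("grow_tree separates separable data and stops on purity", {
  d <- data.frame(x = c(1, 2, 3, 10, 11, 12), y = c(0, 0, 0, 1, 1, 1))
  tr <- grow_tree(d, "x", cart_params(minsplit = 2, minbucket = 1), outcome = "y")
  expect_equal(ssiclaims:::n_leaves(tr$root), 2)
  expect_equal(tree_train_error(tr, d), 0)

  pure <- data.frame(x = 1:10, y = rep(0, 10))
  expect_equal(ssiclaims:::n_leaves(grow_tree(pure, "x", outcome = "y")$root), 1)
})

test_that("best_split matches a slow brute-force Gini-improvement oracle", {
  brute_gini_best <- function(d, variables, outcome) {
    y <- d[[outcome]]
    n <- length(y)
    g <- function(idx) {
      if (!length(idx)) return(0)
      p <- mean(y[idx] == 1)
      1 - p^2 - (1 - p)^2
    }
    best <- NULL
    for (v in variables) {
      xv <- sort(unique(d[[v]]))
      if (length(xv) < 2) next
      for (t in (head(xv, -1) + tail(xv, -1)) / 2) {
        l <- which(d[[v]] <= t)
        r <- which(d[[v]] > t)
        imp <- g(seq_len(n)) -
          length(l) / n * g(l) - length(r) / n * g(r)
        if (is.null(best) || imp > best$improvement + 1e-12) {
          best <- list(variable = v, threshold = t, improvement = imp)
        }
      }
    }
    best
  }
  set.seed(808)
  for (i in 1:30) {
    n <- sample(8:30, 1)
    d <- data.frame(x1 = sample(0:4, n, replace = TRUE),
                    x2 = sample(0:4, n, replace = TRUE),
                    y = c(0, 1, rbinom(n - 2, 1, 0.5)))
    got <- best_split(d, c("x1", "x2"), "y", minbucket = 1)
    want <- brute_gini_best(d, c("x1", "x2"), "y")
    expect_equal(got$improvement, want$improvement, tolerance = 1e-10)
    expect_equal(got$variable, want$variable)
    expect_equal(got$threshold, want$threshold)
  }
})

test_that("fully grown tree beats or ties the best exhaustive depth-2 tree", {
  set.seed(909)
  for (i in 1:30) {
    n <- sample(10:30, 1)
    d <- data.frame(x1 = sample(0:3, n, replace = TRUE),
                    x2 = sample(0:3, n, replace = TRUE),
                    y = c(0, 1, rbinom(n - 2, 1, 0.5)))
    tr <- grow_tree(d, c("x1", "x2"),
                    cart_params(minsplit = 2, minbucket = 1, maxdepth = 8),
                    outcome = "y")
    expect_lte(tree_train_error(tr, d),
               exhaustive_tree_error(d, c("x1", "x2"), "y", 2))
  }
})

test_that("training cost never increases as the tree grows", {
  set.seed(111)
  d <- data.frame(x1 = runif(200), x2 = runif(200))
  d$y <- rbinom(200, 1, plogis(3 * d$x1 - 2))
  errs <- vapply(1:5, function(depth) {
    tr <- grow_tree(d, c("x1", "x2"),
                    cart_params(minsplit = 5, minbucket = 2, maxdepth = depth),
                    outcome = "y")
    tree_train_error(tr, d)
  }, numeric(1))
  expect_true(all(diff(errs) <= 0))
})

test_that("pruning sequence: single internal node yields alpha = leaf-vs-root error gap", {
  d <- data.frame(x = c(1, 1, 2, 2, 2, 2, 2, 2, 2, 2),
                  y = c(1, 1, 0, 0, 0, 0, 0, 0, 0, 0))
  tr <- grow_tree(d, "x", cart_params(minsplit = 2, minbucket = 1), outcome = "y")
  expect_equal(ssiclaims:::n_leaves(tr$root), 2)
  seqs <- cost_complexity_sequence(tr)
  expect_length(seqs, 1)
  # R(root) = 2/10 misclassified, leaves perfect: g = (2/10 - 0) / 1
  expect_equal(seqs[[1]]$alpha, 0.2)
  expect_equal(seqs[[1]]$n_leaves, 1)
})

test_that("root-only trees give an empty pruning sequence", {
  tr <- grow_tree(data.frame(x = 1:5, y = rep(0, 5)), "x", outcome = "y")
  expect_length(cost_complexity_sequence(tr), 0)
})

test_that("alphas strictly increase, leaf counts strictly decrease, subtrees nest", {
  set.seed(222)
  leaf_set <- function(node) {
    if (ssiclaims:::is_leaf(node)) return(list(node$node_id))
    c(leaf_set(node$left), leaf_set(node$right))
  }
  internal_ids <- function(node) {
    if (ssiclaims:::is_leaf(node)) return(integer(0))
    c(node$node_id, internal_ids(node$left), internal_ids(node$right))
  }
  for (i in 1:10) {
    n <- 150
    d <- data.frame(x1 = runif(n), x2 = runif(n), x3 = sample(1:3, n, TRUE))
    d$y <- rbinom(n, 1, plogis(2 * d$x1 + 0.5 * d$x3 - 2))
    tr <- grow_tree(d, c("x1", "x2", "x3"),
                    cart_params(minsplit = 10, minbucket = 3, maxdepth = 6),
                    outcome = "y")
    seqs <- cost_complexity_sequence(tr)
    if (!length(seqs)) next
    alphas <- vapply(seqs, `[[`, numeric(1), "alpha")
    leaves <- vapply(seqs, `[[`, numeric(1), "n_leaves")
    expect_true(all(diff(alphas) > 0))
    expect_true(all(diff(leaves) < 0))
    expect_equal(leaves[length(leaves)], 1)  # ends at the bare root
    # nestedness: each subtree's internal nodes are a subset of the previous
    prev <- internal_ids(tr$root)
    for (s in seqs) {
      cur <- internal_ids(s$root)
      expect_true(all(cur %in% prev))
      prev <- cur
    }
  }
})

test_that("CV pruning keeps a noise-free separating split and is deterministic", {
  d <- data.frame(x = c(rep(1, 40), rep(10, 40)),
                  y = rep(c(0, 1), each = 40))
  pr1 <- select_subtree_cv(d, "x", cart_params(minsplit = 2, minbucket = 1),
                           v = 5, seed = 9, outcome = "y")
  pr2 <- select_subtree_cv(d, "x", cart_params(minsplit = 2, minbucket = 1),
                           v = 5, seed = 9, outcome = "y")
  expect_equal(ssiclaims:::n_leaves(pr1$root), 2)
  expect_equal(min(pr1$pruning_sequence$cv_cost), 0)
  expect_identical(pr1$root, pr2$root)
})

test_that("pure-noise labels usually prune to the bare root", {
  set.seed(333)
  root_only <- 0
  for (s in 1:20) {
    d <- data.frame(x1 = runif(120), x2 = runif(120))
    d$y <- rbinom(120, 1, 0.35)
    pr <- select_subtree_cv(d, c("x1", "x2"),
                            cart_params(minsplit = 10, minbucket = 4),
                            v = 5, seed = s, outcome = "y")
    if (ssiclaims:::n_leaves(pr$root) == 1) root_only <- root_only + 1
  }
  expect_gte(root_only, 11)  # majority of seeds
})

test_that("fold reduction warns when the minority class is smaller than v", {
  d <- data.frame(x = runif(60), y = c(rep(1, 4), rep(0, 56)))
  expect_warning(
    select_subtree_cv(d, "x", cart_params(minsplit = 5, minbucket = 2),
                      v = 10, seed = 1, outcome = "y"),
    "reducing folds"
  )
})

test_that("prediction routes with <= going left and scores with leaf p_ssi", {
  d <- data.frame(x = c(1, 1, 1, 1, 1, 2, 2, 2, 2, 2),
                  y = c(0, 0, 0, 0, 1, 1, 1, 1, 1, 0))
  tr <- grow_tree(d, "x", cart_params(minsplit = 2, minbucket = 1, maxdepth = 1),
                  outcome = "y")
  expect_equal(tr$root$split_threshold, 1.5)
  res <- predict_tree(tr, data.frame(x = c(1.5, 1.4, 1.6)))
  expect_equal(res$prediction, c(0L, 0L, 1L))  # equality goes left
  expect_equal(res$score, c(0.2, 0.2, 0.8))    # (1,4) leaf mirrors an 80% node
  expect_equal(res$model_name, rep("cart", 3))
  expect_error(predict_tree(tr, data.frame(z = 1)), "missing split variable")
})

test_that("leaf ties predict non-SSI and root-only trees predict the majority", {
  d <- data.frame(x = 1:10, y = c(rep(0, 9), 1))
  tr <- grow_tree(d, "x", cart_params(minsplit = 20), outcome = "y")  # too small to split
  expect_equal(ssiclaims:::n_leaves(tr$root), 1)
  expect_true(all(predict_tree(tr, d)$prediction == 0L))

  tie <- data.frame(x = 1:4, y = c(0, 1, 0, 1))
  tr2 <- grow_tree(tie, "x", cart_params(minsplit = 100), outcome = "y")
  expect_equal(tr2$root$predicted_class, 0L)  # tie -> prevalent class
})

test_that("grown tree matches rpart training accuracy under equal settings", {
  skip_if_not_installed("rpart")
  set.seed(444)
  n <- 600
  d <- data.frame(x1 = runif(n, 0, 50), x2 = sample(1:6, n, TRUE))
  d$y <- rbinom(n, 1, plogis(0.15 * d$x1 + 0.4 * d$x2 - 6))
  tr <- grow_tree(d, c("x1", "x2"),
                  cart_params(minsplit = 20, minbucket = 7, maxdepth = 5),
                  outcome = "y")
  ref <- rpart::rpart(y ~ x1 + x2, data = d, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(minsplit = 20, minbucket = 7,
                                                     maxdepth = 5, cp = 0,
                                                     xval = 0))
  ref_err <- sum(predict(ref, d, type = "class") != d$y)
  expect_equal(tree_train_error(tr, d), ref_err)
})
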