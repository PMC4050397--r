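#' Gini impurity of a two-class node
#'
#' `1 - sum(p_k^2)` over the two classes; 0 for a pure node, 0.5 for an even
#' split.
#'
#' @param class_counts length-2 non-negative vector `(non-SSI, SSI)`, total
#'   greater than 0.
#' @return impurity in `[0, 0.5]`.
#' @examples
#' gini_impurity(c(3, 1))  # 0.375
#' @export
gini_impurity <- function(class_counts) {
  stopifnot(length(class_counts) == 2, all(class_counts >= 0))
  n <- sum(class_counts)
  if (n == 0) stop("cannot compute impurity of an empty node")
  p <- class_counts / n
  1 - sum(p^2)
}

#' Growth parameters for the classification tree
#'
#' Defaults are sized for cohorts of around a thousand episodes: a node is
#' split only if it holds at least `minsplit` cases, children must keep at
#' least `minbucket` cases, and the tree grows at most `maxdepth` levels below
#' the root.
#'
#' @param minsplit minimum cases in a node for it to be split (default 20).
#' @param minbucket minimum cases in each child (default 7).
#' @param maxdepth maximum depth, root = depth 0 (default 5).
#' @return a list of class `cart_params`.
#' @export
cart_params <- function(minsplit = 20L, minbucket = 7L, maxdepth = 5L) {
  stopifnot(minsplit >= 2, minbucket >= 1, maxdepth >= 1)
  structure(list(minsplit = as.integer(minsplit),
                 minbucket = as.integer(minbucket),
                 maxdepth = as.integer(maxdepth)),
            class = "cart_params")
}

#' Best binary split of a node by Gini improvement
#'
#' Candidate thresholds are the midpoints between consecutive distinct sorted
#' values of each variable; cases with value `<= threshold` go left. The split
#' maximizing the impurity decrease
#' `G(parent) - (n_L/n) G(left) - (n_R/n) G(right)` is returned, subject to
#' both children holding at least `minbucket` cases. Ties are broken by
#' variable input order, then by the smaller threshold. `NULL` is returned
#' when no eligible split improves impurity.
#'
#' @param data data frame of predictor columns plus the outcome.
#' @param variables character vector of candidate split variables, in
#'   priority order for tie-breaks.
#' @param outcome binary 0/1 outcome column name.
#' @param minbucket minimum child size.
#' @return `NULL`, or a list with `variable`, `threshold`, `improvement`.
#' @examples
#' d <- data.frame(x = 1:4, y = c(0, 0, 1, 1))
#' best_split(d, "x", "y", minbucket = 1)  # x <= 2.5, improvement 0.5
#' @export
best_split <- function(data, variables, outcome = "ssi_label", minbucket = 1L) {
  y <- as.integer(data[[outcome]])
  n <- length(y)
  counts <- c(sum(y == 0L), sum(y == 1L))
  g_parent <- gini_impurity(counts)
  if (g_parent == 0) return(NULL)
  best <- NULL
  tol <- 1e-12
  for (v in variables) {
    x <- data[[v]]
    ord <- order(x)
    xs <- x[ord]
    ys <- y[ord]
    cum_pos <- cumsum(ys)
    i <- seq_len(n - 1)
    ok <- xs[i] < xs[i + 1] & i >= minbucket & (n - i) >= minbucket
    if (!any(ok)) next
    i <- i[ok]
    nl <- i; nr <- n - i
    pl <- cum_pos[i]; pr <- counts[2] - pl
    g_l <- 1 - (pl / nl)^2 - ((nl - pl) / nl)^2
    g_r <- 1 - (pr / nr)^2 - ((nr - pr) / nr)^2
    imp <- g_parent - (nl / n) * g_l - (nr / n) * g_r
    k <- which.max(imp)  # first max = smallest threshold (xs ascending)
    if (imp[k] > tol && (is.null(best) || imp[k] > best$improvement + tol)) {
      best <- list(variable = v,
                   threshold = (xs[i[k]] + xs[i[k] + 1]) / 2,
                   improvement = imp[k])
    }
  }
  best
}

#' @keywords internal
#' @noRd
make_node <- function(id, y, depth) {
  counts <- c(sum(y == 0L), sum(y == 1L))
  list(node_id = id, n = length(y), class_counts = counts,
       predicted_class = as.integer(counts[2] > counts[1]),  # tie -> non-SSI
       p_ssi = counts[2] / length(y),
       depth = depth, split_variable = NULL, split_threshold = NULL,
       left = NULL, right = NULL)
}

#' Grow an unpruned classification tree
#'
#' Recursive partitioning: [best_split()] is applied until a node is pure,
#' too small, at maximum depth, or admits no improving split. Deterministic
#' given the data and variable order.
#'
#' @param data data frame of predictors plus outcome.
#' @param variables candidate split variables.
#' @param params a [cart_params()] object.
#' @param outcome binary 0/1 outcome column name.
#' @return an object of class `ssi_cart` with the root node, parameters and
#'   variables; `pruning_sequence` and `selected_alpha` are `NULL` until
#'   pruning.
#' @export
grow_tree <- function(data, variables, params = cart_params(),
                      outcome = "ssi_label") {
  stopifnot(is.data.frame(data), nrow(data) > 0, length(variables) > 0)
  miss <- setdiff(c(variables, outcome), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  id_env <- new.env()
  id_env$next_id <- 1L
  grow <- function(rows, depth) {
    y <- as.integer(data[[outcome]][rows])
    node <- make_node(id_env$next_id, y, depth)
    id_env$next_id <- id_env$next_id + 1L
    if (node$n < params$minsplit || depth >= params$maxdepth ||
        gini_impurity(node$class_counts) == 0) {
      return(node)
    }
    sp <- best_split(data[rows, , drop = FALSE], variables, outcome,
                     params$minbucket)
    if (is.null(sp)) return(node)
    node$split_variable <- sp$variable
    node$split_threshold <- sp$threshold
    go_left <- data[[sp$variable]][rows] <= sp$threshold
    node$left <- grow(rows[go_left], depth + 1L)
    node$right <- grow(rows[!go_left], depth + 1L)
    node
  }
  root <- grow(seq_len(nrow(data)), 0L)
  structure(list(root = root, params = params, variables = variables,
                 outcome = outcome, n = nrow(data),
                 pruning_sequence = NULL, selected_alpha = NULL),
            class = "ssi_cart")
}

#' @keywords internal
#' @noRd
is_leaf <- function(node) is.null(node$split_variable)

#' @keywords internal
#' @noRd
n_leaves <- function(node) {
  if (is_leaf(node)) 1L else n_leaves(node$left) + n_leaves(node$right)
}

# training misclassification count of the subtree rooted at node
#' @keywords internal
#' @noRd
subtree_error <- function(node) {
  if (is_leaf(node)) min(node$class_counts)
  else subtree_error(node$left) + subtree_error(node$right)
}

# weakest-link statistic g(t) for every internal node, as cost per root case
#' @keywords internal
#' @noRd
link_strengths <- function(node, n_root) {
  if (is_leaf(node)) return(numeric(0))
  g <- (min(node$class_counts) - subtree_error(node)) /
    ((n_leaves(node) - 1) * n_root)
  c(g, link_strengths(node$left, n_root), link_strengths(node$right, n_root))
}

#' @keywords internal collapse every internal node with g <= gmin (weakest links)
#' @noRd
collapse_weakest <- function(node, gmin, n_root, tol = 1e-12) {
  if (is_leaf(node)) return(node)
  g <- (min(node$class_counts) - subtree_error(node)) /
    ((n_leaves(node) - 1) * n_root)
  if (g <= gmin + tol) {
    node$split_variable <- NULL
    node$split_threshold <- NULL
    node$left <- NULL
    node$right <- NULL
    return(node)
  }
  node$left <- collapse_weakest(node$left, gmin, n_root, tol)
  node$right <- collapse_weakest(node$right, gmin, n_root, tol)
  node
}

#' Minimal cost-complexity pruning sequence
#'
#' Weakest-link pruning: repeatedly collapse the internal node(s) minimizing
#' `g(t) = (R(t) - R(T_t)) / (|leaves(T_t)| - 1)`, where `R` is the training
#' misclassification cost per root-level case. Each collapse event is
#' recorded as one entry `(alpha = g, n_leaves, subtree)`; the family is
#' nested, the alphas strictly increase, and the last subtree is the bare
#' root. A root-only tree yields an empty sequence.
#'
#' @param tree an `ssi_cart` from [grow_tree()].
#' @return a list of entries, each with `alpha`, `n_leaves` and `root` (the
#'   collapsed subtree's root node).
#' @export
cost_complexity_sequence <- function(tree) {
  stopifnot(inherits(tree, "ssi_cart"))
  node <- tree$root
  n_root <- node$n
  out <- list()
  while (!is_leaf(node)) {
    g <- link_strengths(node, n_root)
    gmin <- min(g)
    node <- collapse_weakest(node, gmin, n_root)
    out[[length(out) + 1L]] <- list(alpha = gmin, n_leaves = n_leaves(node),
                                    root = node)
  }
  out
}

#' @keywords internal optimal subtree for complexity penalty alpha
#' @noRd
prune_at <- function(tree, alpha) {
  seq <- cost_complexity_sequence(tree)
  root <- tree$root
  for (entry in seq) {
    if (entry$alpha <= alpha + 1e-12) root <- entry$root else break
  }
  out <- tree
  out$root <- root
  out
}

#' Cross-validated subtree selection (cost-complexity pruning)
#'
#' Standard CART V-fold selection: the full-data tree's pruning sequence
#' defines candidate complexity penalties (geometric means of consecutive
#' alphas); on each of `v` class-stratified folds a tree is grown on the
#' training part, pruned at each candidate, and scored on the held-out part
#' by misclassification cost (equal costs, training priors). The penalty with
#' minimal cross-validated cost is chosen (ties toward the simpler tree) and
#' the full-data tree is pruned there. `rule = "1se"` instead picks the
#' simplest tree within one standard error of the minimum.
#'
#' @param data data frame of predictors plus outcome.
#' @param variables candidate split variables.
#' @param params a [cart_params()] object.
#' @param v number of folds (default 10).
#' @param seed RNG seed for fold assignment.
#' @param rule `"min"` (default) or `"1se"`.
#' @param outcome binary 0/1 outcome column name.
#' @return the pruned `ssi_cart`, with `pruning_sequence` (data frame of
#'   `alpha`, `n_leaves`, `cv_cost`) and `selected_alpha` filled in.
#' @export
select_subtree_cv <- function(data, variables, params = cart_params(),
                              v = 10L, seed = 1L, rule = c("min", "1se"),
                              outcome = "ssi_label") {
  rule <- match.arg(rule)
  y <- as.integer(data[[outcome]])
  if (length(unique(y)) < 2) stop("both classes must be present")
  if (v < 2) stop("v must be at least 2")
  n_min_class <- min(table(y))
  if (n_min_class < v) {
    warning(sprintf("minority class has %d cases; reducing folds from %d to %d",
                    n_min_class, v, max(2L, n_min_class)))
    v <- max(2L, as.integer(n_min_class))
  }

  full <- grow_tree(data, variables, params, outcome)
  seq_full <- cost_complexity_sequence(full)
  alphas <- c(0, vapply(seq_full, `[[`, numeric(1), "alpha"))
  # geometric-mean evaluation points; the last region is open-ended
  betas <- if (length(alphas) > 1) {
    c(sqrt(alphas[-length(alphas)] * alphas[-1]), alphas[length(alphas)])
  } else 0

  folds <- with_seed(seed, {
    f <- integer(length(y))
    for (cls in c(0L, 1L)) {
      idx <- which(y == cls)
      f[idx] <- sample(rep_len(seq_len(v), length(idx)))
    }
    f
  })

  errs <- matrix(0, nrow = v, ncol = length(betas))
  for (fold in seq_len(v)) {
    test <- folds == fold
    sub <- grow_tree(data[!test, , drop = FALSE], variables, params, outcome)
    for (b in seq_along(betas)) {
      pr <- prune_at(sub, betas[b])
      pred <- route_predict(pr$root, data[test, , drop = FALSE])$class
      errs[fold, b] <- sum(pred != y[test])
    }
  }
  cv_cost <- colSums(errs) / length(y)
  if (rule == "min") {
    chosen <- max(which(cv_cost <= min(cv_cost) + 1e-12))  # tie: simpler tree
  } else {
    se <- sqrt(min(cv_cost) * (1 - min(cv_cost)) / length(y))
    chosen <- max(which(cv_cost <= min(cv_cost) + se + 1e-12))
  }
  pruned <- prune_at(full, betas[chosen])
  pruned$pruning_sequence <- data.frame(
    alpha = betas,
    n_leaves = vapply(betas, function(b) n_leaves(prune_at(full, b)$root),
                      integer(1)),
    cv_cost = cv_cost
  )
  pruned$selected_alpha <- betas[chosen]
  pruned
}

#' @keywords internal route rows through a tree; returns class and p_ssi
#' @noRd
route_predict <- function(root, data) {
  n <- nrow(data)
  cls <- integer(n)
  p <- numeric(n)
  walk <- function(node, rows) {
    if (!length(rows)) return()
    if (is_leaf(node)) {
      cls[rows] <<- node$predicted_class
      p[rows] <<- node$p_ssi
      return()
    }
    x <- data[[node$split_variable]][rows]
    if (anyNA(x)) stop("missing values in split variable ", node$split_variable)
    left <- x <= node$split_threshold
    walk(node$left, rows[left])
    walk(node$right, rows[!left])
  }
  walk(root, seq_len(n))
  list(class = cls, p_ssi = p)
}

#' Predict SSI status with a classification tree
#'
#' Cases are routed from the root ("value <= threshold goes left", equality
#' goes left); the call at a leaf is its majority class (ties go to non-SSI,
#' the prevalent class) and the score is the leaf's SSI fraction.
#'
#' @param tree an `ssi_cart`.
#' @param cohort an `ssi_cohort`, or a data frame already holding the split
#'   variables.
#' @return a `classifier_result` with `score` = leaf SSI fraction.
#' @export
predict_tree <- function(tree, cohort) {
  stopifnot(inherits(tree, "ssi_cart"))
  d <- if (inherits(cohort, "ssi_cohort") ||
           all(c("atc_codes_used", "ssi_label") %in% names(cohort))) {
    logistic_frame(cohort)
  } else {
    cohort
  }
  used <- tree_variables_used(tree$root)
  miss <- setdiff(used, names(d))
  if (length(miss)) stop("missing split variable(s): ", paste(miss, collapse = ", "))
  r <- route_predict(tree$root, d)
  ids <- if ("patient_id" %in% names(d)) d$patient_id else as.character(seq_len(nrow(d)))
  classifier_result(ids, r$class, r$p_ssi, model_name = "cart")
}

#' @keywords internal
#' @noRd
tree_variables_used <- function(node) {
  if (is_leaf(node)) return(character(0))
  unique(c(node$split_variable,
           tree_variables_used(node$left), tree_variables_used(node$right)))
}

#' Train the classification-tree identification model (model 5)
#'
#' Grows a Gini-improvement tree on the six surrogate variables and selects
#' the final subtree by cross-validated minimal cost-complexity pruning.
#'
#' @param cohort training `ssi_cohort`.
#' @param variables candidate split variables (default the six surrogate
#'   variables).
#' @param params a [cart_params()] object.
#' @param v CV folds.
#' @param seed fold-assignment seed.
#' @param rule alpha-selection rule, see [select_subtree_cv()].
#' @param prune if `FALSE`, return the unpruned tree.
#' @return an `ssi_cart`.
#' @export
train_cart_model <- function(cohort,
                             variables = c("los", "antibiotic_types",
                                           "antibiotic_ddd_total",
                                           "cefazolin_ddd", "second_line",
                                           "vessels_obstructed"),
                             params = cart_params(), v = 10L, seed = 1L,
                             rule = c("min", "1se"), prune = TRUE) {
  d <- logistic_frame(cohort)
  if (prune) {
    select_subtree_cv(d, variables, params, v = v, seed = seed,
                      rule = match.arg(rule))
  } else {
    grow_tree(d, variables, params)
  }
}

#' @export
print.ssi_cart <- function(x, ...) {
  cat(sprintf("<ssi_cart> %d leaves (n = %d)", n_leaves(x$root), x$n))
  if (!is.null(x$selected_alpha)) {
    cat(sprintf(", pruned at alpha = %.6g", x$selected_alpha))
  }
  cat("\n")
  cat(format_tree(x), sep = "\n")
  invisible(x)
}

#' Indented text rendering of a tree
#'
#' @param tree an `ssi_cart`.
#' @return character vector, one line per node.
#' @export
format_tree <- function(tree) {
  render <- function(node, indent) {
    lab <- sprintf("%sn=%d (%d/%d) p_ssi=%.3f -> %s",
                   indent, node$n, node$class_counts[1], node$class_counts[2],
                   node$p_ssi, if (node$predicted_class == 1) "SSI" else "non-SSI")
    if (is_leaf(node)) return(lab)
    c(sprintf("%s [split %s <= %.4g]", lab, node$split_variable,
              node$split_threshold),
      render(node$left, paste0(indent, "  ")),
      render(node$right, paste0(indent, "  ")))
  }
  render(tree$root, "")
}

#' Serialize a tree as nested JSON
#'
#' @param tree an `ssi_cart`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_tree_json <- function(tree, path) {
  stopifnot(inherits(tree, "ssi_cart"))
  as_obj <- function(node) {
    o <- list(node_id = node$node_id, n = node$n,
              class_counts = as.list(node$class_counts),
              predicted_class = node$predicted_class, p_ssi = node$p_ssi)
    if (!is_leaf(node)) {
      o$split_variable <- node$split_variable
      o$split_threshold <- node$split_threshold
      o$left <- as_obj(node$left)
      o$right <- as_obj(node$right)
    }
    o
  }
  obj <- list(selected_alpha = tree$selected_alpha,
              variables = tree$variables, tree = as_obj(tree$root))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
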