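# builders for hand-crafted episodes and tiny cohorts

make_episode <- function(patient_id = "p1", age = 65, sex = "male", los = 12,
                         vessels = 2, types = 1, ddd = 4, cefazolin = 4,
                         atc = "J01DB04", index_dx = character(0),
                         post_dx = character(0), ssi = 0) {
  data.frame(
    patient_id = patient_id, age = age, sex = sex, los = los,
    vessels_obstructed = vessels, antibiotic_types = types,
    antibiotic_ddd_total = ddd, cefazolin_ddd = cefazolin,
    atc_codes_used = I(list(atc)),
    index_secondary_dx = I(list(index_dx)),
    postdischarge_dx = I(list(post_dx)),
    ssi_label = ssi, stringsAsFactors = FALSE
  )
}

make_cohort <- function(...) {
  rows <- list(...)
  for (i in seq_along(rows)) rows[[i]]$patient_id <- sprintf("p%03d", i)
  as_cohort(do.call(rbind, rows))
}

# brute-force AUC: probability a random positive outscores a random negative,
# ties counted one half
auc_pair_count <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  tot <- 0
  for (p in pos) for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  tot / (length(pos) * length(neg))
}

# brute-force Youden: evaluate J at every distinct score under ">= cutoff"
youden_brute <- function(scores, labels) {
  cands <- sort(unique(scores))
  j <- vapply(cands, function(c) {
    pred <- as.integer(scores >= c)
    sens <- sum(pred == 1 & labels == 1) / sum(labels == 1)
    spec <- sum(pred == 0 & labels == 0) / sum(labels == 0)
    sens + spec - 1
  }, numeric(1))
  list(cutoff = cands[which.max(j)], j = max(j))
}

# training misclassifications of the best depth-capped tree by exhaustive
# search over axis-aligned splits (depth 1 or 2, two classes)
exhaustive_tree_error <- function(data, variables, outcome, depth) {
  y <- data[[outcome]]
  leaf_err <- function(idx) if (!length(idx)) 0 else min(sum(y[idx] == 0), sum(y[idx] == 1))
  splits_of <- function(idx) {
    out <- list()
    for (v in variables) {
      xv <- sort(unique(data[[v]][idx]))
      if (length(xv) < 2) next
      for (t in (head(xv, -1) + tail(xv, -1)) / 2) {
        out[[length(out) + 1]] <- list(v = v, t = t)
      }
    }
    out
  }
  best_err <- function(idx, d) {
    err <- leaf_err(idx)
    if (d == 0 || length(idx) < 2) return(err)
    for (s in splits_of(idx)) {
      l <- idx[data[[s$v]][idx] <= s$t]
      r <- setdiff(idx, l)
      if (!length(l) || !length(r)) next
      err <- min(err, best_err(l, d - 1) + best_err(r, d - 1))
    }
    err
  }
  best_err(seq_len(nrow(data)), depth)
}

# training misclassifications of a grown/pruned tree
tree_train_error <- function(tree, data) {
  pred <- predict_tree(tree, data)$prediction
  sum(pred != data[[tree$outcome]])
}
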