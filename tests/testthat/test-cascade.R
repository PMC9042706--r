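test_that("DBI matches hand arithmetic on separated clusters", {
  # zero-spread clusters at distance 10: D = 0, alphabetical order
  v <- cbind(matrix(0, 2, 3), matrix(c(10, 0), 2, 3))
  dimnames(v) <- list(c("g1", "g2"), paste0("s", 1:6))
  lab <- rep(c("B", "A"), each = 3)
  d <- entity_dbi_order(v, lab)
  expect_equal(d$dbi, c(0, 0))
  expect_equal(d$entity, c("A", "B"))

  # A{(0,0),(2,0)}, B{(10,0),(12,0)}: S = 1 each, centroids 10 apart
  v2 <- matrix(c(0, 0, 2, 0, 10, 0, 12, 0), 2, 4,
               dimnames = list(c("x", "y"), paste0("s", 1:4)))
  d2 <- entity_dbi_order(v2, c("A", "A", "B", "B"))
  expect_equal(d2$dbi, c(0.2, 0.2))
})

test_that("DBI equals the brute-force pairwise oracle on toy sets", {
  set.seed(17)
  for (rep in 1:5) {
    v <- matrix(rnorm(3 * 8), 3, 8,
                dimnames = list(paste0("g", 1:3), paste0("s", 1:8)))
    lab <- rep(c("A", "B", "C", "D"), each = 2)
    got <- entity_dbi_order(v, lab)
    want <- oracle_dbi(v, lab)
    expect_equal(got$dbi, unname(want[got$entity]))
  }
})

test_that("shrinking between-centroid distance inflates DBI", {
  base <- matrix(c(0, 0, 1, 0), 2, 2)
  ds <- sapply(c(10, 6, 3, 1.5), function(sep) {
    v <- cbind(base, base + c(sep, 0))
    dimnames(v) <- list(c("x", "y"), paste0("s", 1:4))
    entity_dbi_order(v, c("A", "A", "B", "B"))$dbi[1]
  })
  expect_true(all(diff(ds) > 0))
  v0 <- cbind(base, base)
  dimnames(v0) <- list(c("x", "y"), paste0("s", 1:4))
  expect_error(entity_dbi_order(v0, c("A", "A", "B", "B")), "coincident")
})

test_that("a step separates a shifted entity and is seed-reproducible", {
  tc <- tiny_cohort()
  st1 <- train_step(tc$values, tc$labels, "entA", rownames(tc$values),
                    seed = 7, ntree = 200)
  st2 <- train_step(tc$values, tc$labels, "entA", rownames(tc$values),
                    seed = 7, ntree = 200)
  expect_identical(st1$forest$votes, st2$forest$votes)
  expect_equal(sum(st1$gini_importances), 1)

  # out-of-bag probability of the target clears 0.5 for the target class
  oob <- st1$forest$votes[tc$labels == "entA", "target"]
  expect_gte(mean(oob > 0.5), 0.95)
})

test_that("label permutation destroys the signal", {
  tc <- tiny_cohort()
  set.seed(31)
  perm <- sample(tc$labels)
  st <- train_step(tc$values, perm, "entA", rownames(tc$values),
                   seed = 7, ntree = 200)
  oob_call <- st$forest$votes[, "target"] >= 0.5
  acc <- mean((perm == "entA") == oob_call)
  maj <- mean(perm != "entA")
  expect_lt(abs(acc - maj), 3 * sqrt(maj * (1 - maj) / length(perm)) + 0.05)
})

test_that("refinement drops downregulated genes regardless of importance", {
  set.seed(23)
  n <- 10
  lab <- c(rep("T", n), rep("rest", n))
  v <- rbind(
    dn  = c(rnorm(n, 2, 0.2), rnorm(n, 8, 0.2)),   # strong, DOWN in target
    up1 = c(rnorm(n, 7, 0.4), rnorm(n, 6, 0.4)),   # weak, up
    up2 = c(rnorm(n, 7.5, 0.4), rnorm(n, 6, 0.4))) # weak, up
  colnames(v) <- paste0("s", 1:(2 * n))
  st <- train_step(v, lab, "T", rownames(v), seed = 3, ntree = 300)
  expect_equal(names(which.max(st$gini_importances)), "dn")
  ref <- refine_markers(st, v, lab, k = 2)
  expect_false("dn" %in% ref$marker_genes)
  expect_setequal(ref$marker_genes, c("up1", "up2"))

  # k beyond the available upregulated genes keeps all of them
  ref2 <- refine_markers(st, v, lab, k = 10)
  expect_setequal(ref2$marker_genes, c("up1", "up2"))

  v_dn <- v[1, , drop = FALSE]
  st_dn <- train_step(v_dn, lab, "T", "dn", seed = 3, ntree = 100)
  expect_error(refine_markers(st_dn, v_dn, lab, 1), "no upregulated")
})

test_that("the published marker-set bookkeeping adds up", {
  sizes <- vapply(sbcln_published_markers, length, 0L)
  expect_equal(unname(sizes), c(5L, 6L, 8L, 4L, 6L, 7L))
  u <- marker_union(sbcln_published_markers)
  expect_equal(length(u), 35L)
  shared <- names(which(table(unlist(sbcln_published_markers)) > 1))
  expect_equal(shared, "CCND1")
})

test_that("cascade fit recovers planted marker blocks and orders steps", {
  m <- tiny_model()
  expect_setequal(unlist(m$refined_markers),
                  c(paste0("A", 1:4), paste0("B", 1:4)))
  expect_setequal(m$entity_order, c("entA", "entB"))
  expect_equal(m$entity_order, m$dbi$entity)

  # single-entity config yields a one-step cascade
  tc <- tiny_cohort()
  keep <- tc$labels %in% c("entA", "control")
  m1 <- fit_cascade(tc$values[, keep], tc$labels[keep], k = 4,
                    ntree = 100, seed = 1)
  expect_equal(length(m1$steps), 1L)
})

test_that("prediction gives exactly one call with an inclusive boundary", {
  m <- tiny_model()
  tc <- tiny_cohort()
  pr <- predict(m, tc$values)
  expect_equal(nrow(pr), ncol(tc$values))
  expect_true(all(!is.na(pr$final_call)))
  expect_equal(pr$final_call[tc$labels == "entA"], rep("entA", 6))
  expect_equal(pr$final_call[tc$labels == "control"],
               rep("undetermined", 6))

  # recompute the decision rule from the reported probabilities
  probs <- as.matrix(pr[, paste0("p_", m$entity_order)])
  for (i in seq_len(nrow(probs))) {
    hit <- which(probs[i, ] >= m$threshold)
    want <- if (length(hit)) m$entity_order[hit[1]] else "undetermined"
    expect_equal(pr$final_call[i], want)
  }

  # the boundary is inclusive: a threshold equal to an observed
  # probability still claims the sample
  p_obs <- probs[1, 1]
  m2 <- m
  m2$threshold <- p_obs
  pr2 <- predict(m2, tc$values)
  expect_equal(pr2$final_call[1], m$entity_order[1])

  expect_error(predict(m, tc$values[-1, ]), "A1")
})

test_that("fixed seeds give bit-identical cascades and predictions", {
  m1 <- tiny_model(seed = 5)
  m2 <- tiny_model(seed = 5)
  tc <- tiny_cohort(seed = 5)
  expect_identical(m1$refined_markers, m2$refined_markers)
  expect_identical(predict(m1, tc$values), predict(m2, tc$values))
})

test_that("LOO is perfect on separable data and rejects an outlier", {
  tc <- tiny_cohort()
  # plant a background-like sample labelled entA: no marker elevated
  v <- cbind(tc$values, odd = rnorm(nrow(tc$values), 6, 0.4))
  lab <- c(tc$labels, "entA")
  m <- fit_cascade(v, lab, k = 4, ntree = 100, seed = 9)
  loo <- loo_evaluate(v, lab, model = m)
  expect_equal(loo$predictions$final_call[ncol(v)], "undetermined")
  expect_equal(loo$n_misclassified, 0)
  n_ent <- sum(lab != "control")
  expect_equal(loo$accuracy, (n_ent - 1) / n_ent)
})
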