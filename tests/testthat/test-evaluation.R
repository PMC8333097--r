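# a stub model emitting fixed log-posteriors per frame, for voting tests
stub_model <- function(frame_len, logp_fn, n_classes) {
  structure(list(
    cfg = list(n_classes = n_classes, cw_shift = 5, fs = 1000 * frame_len / 10),
    frame_len = frame_len,
    layers = list()
  ), class = c("stub_model", "sincbird_model"))
}

test_that("frame-posterior voting averages and tie-breaks as specified", {
  # hand-built 3-frame, 3-class posterior matrix
  post <- rbind(c(0.8, 0.1, 0.1),
                c(0.2, 0.5, 0.3),
                c(0.25, 0.45, 0.3))
  mean_post <- colMeans(post)
  expect_equal(which.max(mean_post) - 1L, 0L) # hand computation: class 0
  expect_equal(mean_post, c(1.25, 1.05, 0.7) / 3, tolerance = 1e-9)

  # a model emitting constant uniform posteriors predicts class 0 by tie-break
  cfg <- net_config(frontend = "sinc", n_filt_1 = 4, len_filt_1 = 33,
                    conv_layers = list(c(4, 5)), pool_len = 2,
                    fc_layers = c(8), n_classes = 4, fs = 8000,
                    cw_len = 10, cw_shift = 5, seed = 1)
  m <- build_model(cfg)
  # zero out the output layer: logits all equal -> uniform posterior
  out_lin <- Filter(function(l) l$type == "linear", m$layers)
  out_lin <- out_lin[[length(out_lin)]]
  out_lin$params$W[] <- 0
  out_lin$params$b[] <- 0
  item <- list(samples = rng_stream(2)$rnorm(400), fs = 8000,
               class_index = 2L, tag = "x", dialect = "cut")
  r <- classify_file(m, item)
  expect_equal(r$pred, 0L)
  expect_equal(r$posterior, rep(0.25, 4), tolerance = 1e-9)
  expect_equal(r$n_frames, n_frames(400, 80, 40))

  # single-frame item: prediction equals that frame's argmax
  item1 <- list(samples = item$samples[1:80], fs = 8000, class_index = 0L,
                tag = "x", dialect = "cut")
  m2 <- build_model(cfg)
  r1 <- classify_file(m2, item1)
  lp <- forward(m2, matrix(item1$samples, 1), training = FALSE)
  expect_equal(r1$pred, which.max(lp[1, ]) - 1L)
  expect_equal(r1$n_frames, 1L)

  expect_error(classify_file(m, list(samples = rnorm(10), dialect = "cut")),
               "zero frames")
})

test_that("one-vs-rest AUC equals the exhaustive pairwise rank statistic", {
  # the 4-file, 2-class toy
  truth <- c(0L, 0L, 1L, 1L)
  p1 <- c(0.1, 0.4, 0.35, 0.8)
  post <- cbind(1 - p1, p1)
  auc1 <- brute_force_auc(as.integer(truth == 1), p1)
  auc0 <- brute_force_auc(as.integer(truth == 0), 1 - p1)
  expected <- (2 * auc0 + 2 * auc1) / 4
  expect_equal(roc_auc_ovr(truth, post), expected)
  expect_equal(auc1, 0.75) # exhaustive count: 3 of 4 pairs ranked correctly

  # random multi-class score sets, with ties, against the brute-force count
  r <- rng_stream(17)
  for (rep in 1:5) {
    n <- 30
    k <- 4
    truth <- as.integer(r$sample_int(k, n, replace = TRUE)) - 1L
    post <- matrix(round(r$runif(n * k), 2), n, k) # rounding makes ties
    post <- post / rowSums(post)
    ref <- local({
      aucs <- numeric(0); w <- numeric(0)
      for (c0 in sort(unique(truth))) {
        aucs <- c(aucs, brute_force_auc(as.integer(truth == c0), post[, c0 + 1]))
        w <- c(w, sum(truth == c0))
      }
      sum(aucs * w) / sum(w)
    })
    expect_equal(roc_auc_ovr(truth, post), ref, tolerance = 1e-12)
  }

  # AUC is invariant under strictly monotone transforms of the scores
  truth <- c(0L, 1L, 0L, 1L, 1L, 0L)
  sc <- cbind(c(.9, .2, .6, .1, .3, .8))
  post2 <- cbind(sc, 1 - sc)
  expect_equal(roc_auc_ovr(truth, cbind(exp(3 * sc), exp(3 * (1 - sc)))),
               roc_auc_ovr(truth, post2))

  # cross-check against an established ROC implementation
  if (requireNamespace("pROC", quietly = TRUE)) {
    lab <- c(0, 0, 1, 1, 1)
    s <- c(0.2, 0.6, 0.4, 0.7, 0.7)
    ref <- as.numeric(pROC::auc(pROC::roc(lab, s, quiet = TRUE,
                                          direction = "<")))
    expect_equal(brute_force_auc(lab, s), ref)
  }
})

test_that("metric suite satisfies its internal identities", {
  r <- rng_stream(23)
  n <- 60; k <- 6
  truth <- as.integer(r$sample_int(k, n, replace = TRUE)) - 1L
  post <- matrix(r$runif(n * k), n, k)
  post <- post / rowSums(post)
  pred <- max.col(post, ties.method = "first") - 1L
  rep <- compute_metrics(truth, pred, post)

  # accuracy equals the support-weighted confusion diagonal
  cm <- rep$confusion
  obs <- attr(cm, "observed")
  supp <- as.numeric(table(factor(truth, levels = 0:(k - 1))))
  expect_equal(sum(diag(cm) * supp / n), rep$accuracy)

  # observed rows sum to one; matrix total = number of observed classes
  expect_equal(rowSums(cm)[obs], rep(1, sum(obs)), ignore_attr = TRUE)
  expect_equal(sum(cm), sum(obs))

  # top-k ordering: top-1 = accuracy <= top-3 <= top-5
  expect_equal(topk_accuracy(truth, post, 1), rep$accuracy)
  expect_gte(rep$top3, rep$accuracy)
  expect_gte(rep$top5, rep$top3)

  # k >= n_classes saturates
  truth5 <- as.integer(r$sample_int(5, 20, replace = TRUE)) - 1L
  post5 <- matrix(r$runif(100), 20, 5)
  expect_equal(topk_accuracy(truth5, post5, 5), 1)

  # perfect posteriors: every metric is one
  post_p <- matrix(0, n, k); post_p[cbind(1:n, truth + 1L)] <- 1
  perfect <- compute_metrics(truth, truth, post_p)
  for (m in c("accuracy", "roc_auc", "precision", "recall", "f1",
              "top3", "top5")) {
    expect_equal(perfect[[m]], 1)
  }

  # all-correct predictions give an identity confusion on observed rows
  expect_equal(diag(perfect$confusion)[obs], rep(1, sum(obs)),
               ignore_attr = TRUE)
})

test_that("classes absent from the truth are dropped from AUC with a warning", {
  truth <- c(0L, 0L, 1L)
  post <- matrix(c(.5, .6, .2, .3, .2, .6, .2, .2, .2), 3, 3)
  expect_warning(a <- roc_auc_ovr(truth, post), "absent")
  expect_true(a >= 0 && a <= 1)
})

test_that("overlap credit matches hand counts", {
  # no overlaps: credited equals strict
  truth <- c("A", "B", "A")
  pred <- c("A", "A", "B")
  ov0 <- list(character(), character(), character())
  r0 <- overlap_credit(truth, pred, ov0)
  expect_equal(r0$credited_accuracy, r0$strict_accuracy)
  expect_equal(r0$credit_gain, 0)

  # every wrong prediction lands on an overlapping tag: full credit
  ov1 <- list(character(), "A", "B")
  r1 <- overlap_credit(truth, pred, ov1)
  expect_equal(r1$credited_accuracy, 1)

  # 10 events, 4 with one overlap, 2 errors landing on the overlap: +0.2
  truth2 <- rep("A", 10)
  pred2 <- c("B", "B", rep("A", 8))
  ov2 <- c(list("B", "B", "B", "B"), rep(list(character()), 6))
  r2 <- overlap_credit(truth2, pred2, ov2)
  expect_equal(r2$strict_accuracy, 0.8)
  expect_equal(r2$credited_accuracy, 1.0)
  expect_equal(r2$credit_gain, 0.2)
  expect_equal(r2$errors_on_overlap, 1.0)
  # among the 4 overlap events all predictions hit tag or overlap: 2 vs 2
  expect_equal(r2$on_tag_or_overlap, 1.0)
  expect_equal(unname(r2$split), c(0.5, 0.5))

  # credited - strict never exceeds the overlapping-event fraction
  r <- rng_stream(41)
  for (rep_i in 1:20) {
    n <- 20
    tags <- c("A", "B", "C")
    tr <- r$sample(tags, n, replace = TRUE)
    pr <- r$sample(tags, n, replace = TRUE)
    ov <- lapply(seq_len(n), function(i) {
      if (r$runif(1) < 0.3) r$sample(setdiff(tags, tr[i]), 1) else character()
    })
    res <- overlap_credit(tr, pr, ov)
    expect_gte(res$credit_gain, 0)
    expect_lte(res$credit_gain, mean(vapply(ov, length, 0L) > 0))
  }
})
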