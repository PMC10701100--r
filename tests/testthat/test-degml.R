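# Build a feature table with the registry columns, with `disorder` carrying
# the signal and everything else noise.
make_feature_frame <- function(n, disorder_mean, seed) {
  withr::with_seed(seed, {
    df <- as.data.frame(matrix(stats::runif(n * length(degronr:::FEATURE_REGISTRY)),
                               n, dimnames = list(NULL, degronr:::FEATURE_REGISTRY)))
    df$disorder <- pmin(1, pmax(0, stats::rnorm(n, disorder_mean, 0.05)))
    df
  })
}

test_that("the ensemble separates linearly separable features and is deterministic", {
  pos <- make_feature_frame(100, 0.9, seed = 1)
  neg <- make_feature_frame(100, 0.1, seed = 2)
  ens <- train_degron_ensemble(pos[1:70, ], neg[1:70, ], seed = 1)
  expect_length(ens$models, 10L)

  hold <- rbind(pos[71:100, ], neg[71:100, ])
  y <- rep(c(1, 0), each = 30)
  pr <- predict(ens, hold)
  expect_gte(degronr:::roc_auc(y, pr$probability), 0.95)
  expect_true(all(pr$probability >= 0 & pr$probability <= 1))

  # probe positives overwhelmingly score above threshold
  expect_gte(mean(pr$passed_threshold[1:30]), 0.9)

  ens2 <- train_degron_ensemble(pos[1:70, ], neg[1:70, ], seed = 1)
  pr2 <- predict(ens2, hold)
  expect_identical(pr[paste0("per_model_", 1:10)],
                   pr2[paste0("per_model_", 1:10)])
})

test_that("the internal rank-based AUC agrees with an independent implementation", {
  skip_if_not_installed("pROC")
  withr::local_seed(55)
  y <- rbinom(200, 1, 0.4)
  s <- runif(200) + 0.5 * y
  expect_equal(degronr:::roc_auc(y, s),
               as.numeric(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
})

test_that("ensemble preconditions are enforced", {
  pos <- make_feature_frame(100, 0.9, seed = 1)
  neg <- make_feature_frame(100, 0.1, seed = 2)
  expect_error(train_degron_ensemble(pos[1:5, ], neg, seed = 1),
               "at least 20")
  cst <- neg; cst$rigidity <- 0.5
  expect_error(train_degron_ensemble(transform(pos, rigidity = 0.5), cst,
                                     seed = 1), "all-constant")
})

test_that("probability is the mean of per-model scores and the threshold is strict", {
  pos <- make_feature_frame(40, 0.9, seed = 3)
  neg <- make_feature_frame(40, 0.1, seed = 4)
  ens <- train_degron_ensemble(pos, neg, seed = 5)
  pr <- predict(ens, rbind(pos[1:5, ], neg[1:5, ]))
  expect_equal(pr$probability,
               rowMeans(pr[paste0("per_model_", 1:10)]), tolerance = 1e-9)

  # strict '>' at the boundary, and permutation invariance of the mean
  calls <- data.frame(probability = c(0.5, 0.5 + 1e-9))
  expect_equal(calls$probability > 0.5, c(FALSE, TRUE))
  scores <- as.numeric(pr[1, paste0("per_model_", 1:10)])
  expect_equal(mean(scores), mean(sample(scores)))
})

test_that("window extraction is centered, padded, and always 50 long", {
  prot <- as_proteome(c(P = random_sequence(30)))
  set.seed(8)
  w <- extract_window(prot, "P", 5L, 8L)
  expect_equal(nchar(w), 50L)
  # midpoint 6: window [-18, 31] -> 19 left pads, 1 right pad
  expect_equal(substr(w, 1, 19), strrep("X", 19))
  expect_equal(substr(w, 50, 50), "X")
  expect_equal(substr(w, 20, 49), prot$sequence[1])

  big <- as_proteome(c(Q = random_sequence(200)))
  w2 <- extract_window(big, "Q", 100L, 103L)
  expect_equal(nchar(w2), 50L)
  expect_false(grepl("X", w2))
})

test_that("the sequence fallback model learns an implanted motif and is reproducible", {
  withr::local_seed(9)
  mk <- function(n, with_motif) vapply(seq_len(n), function(i) {
    s <- random_sequence(50)
    if (with_motif) {
      p <- sample(1:42, 1)
      substr(s, p, p + 8) <- "DEDEDEDED"
    }
    s
  }, character(1))
  w <- c(mk(80, TRUE), mk(80, FALSE))
  y <- rep(c(1, 0), each = 80)
  fit <- train_sequence_model(w, y, seed = 2)
  tw <- c(mk(40, TRUE), mk(40, FALSE))
  ty <- rep(c(1, 0), each = 40)
  pr <- predict(fit, tw)
  expect_gte(mean((pr$probability > 0.5) == (ty == 1)), 0.9)

  fit2 <- train_sequence_model(w, y, seed = 2)
  expect_equal(predict(fit2, tw)$probability, pr$probability)

  expect_error(train_sequence_model(w, rep(1, length(w)), seed = 1),
               "single-class")
  expect_error(train_sequence_model(c(w, "SHORT"), c(y, 1), seed = 1),
               "exactly 50")
})

test_that("high-priority ranking uses the per-class verified minimum", {
  calls <- data.frame(motif_name = c("A", "A", "B"),
                      probability = c(0.70, 0.55, 0.99),
                      passed_threshold = c(TRUE, TRUE, TRUE))
  verified <- data.frame(motif_name = "A", probability = c(0.62, 0.80))
  expect_warning(out <- rank_high_priority(calls, verified),
                 "no verified degron")
  expect_equal(out$high_priority, c(TRUE, FALSE, FALSE))

  # high_priority implies passed_threshold
  calls$passed_threshold <- FALSE
  out2 <- suppressWarnings(rank_high_priority(calls, verified))
  expect_false(any(out2$high_priority))
})
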