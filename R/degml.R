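#' Train the bootstrapped gradient-boosting degron ensemble
#'
#' Fits 10 gradient-boosted tree classifiers (xgboost), each on an
#' independent bootstrap resample (with replacement, size equal to the full
#' training set) drawn from a seeded stream, after selecting hyperparameters
#' by stratified 5-fold cross-validation over a small declared grid. The
#' final degron probability of a candidate is the arithmetic mean of the 10
#' per-model scores.
#'
#' @param positive_features Feature table for annotated degrons
#'   (from [aggregate_features()]).
#' @param background_features Feature table for background peptides.
#' @param config Optional list overriding the hyperparameter grid:
#'   `max_depth`, `eta`, `nrounds`, `subsample` (each a vector of values to
#'   try), `n_models`, `cv_folds`.
#' @param seed Integer seed controlling CV folds and bootstrap resamples.
#' @return An object of class `degron_ensemble`: the fitted models, feature
#'   scaling parameters, and a training manifest (seeds, bootstrap indices,
#'   selected hyperparameters) sufficient to retrain reproducibly.
#' @export
train_degron_ensemble <- function(positive_features, background_features,
                                  config = list(), seed = 1L) {
  if (nrow(positive_features) < 20L || nrow(background_features) < 20L)
    abort("at least 20 positive and 20 background rows are required (got %d / %d)",
          nrow(positive_features), nrow(background_features))
  ratio <- max(nrow(positive_features), nrow(background_features)) /
    min(nrow(positive_features), nrow(background_features))
  if (ratio > 100)
    abort("class imbalance %.0f:1 exceeds 100:1; re-sample the larger class",
          ratio)

  X <- feature_matrix(rbind(positive_features[FEATURE_REGISTRY],
                            background_features[FEATURE_REGISTRY]))
  y <- c(rep(1, nrow(positive_features)), rep(0, nrow(background_features)))

  const <- apply(X, 2, function(v) stats::sd(v) == 0)
  if (any(const))
    abort("all-constant feature(s): %s", paste(colnames(X)[const], collapse = ", "))

  scale_mean <- colMeans(X)
  scale_sd <- apply(X, 2, stats::sd)
  Xs <- sweep(sweep(X, 2, scale_mean), 2, scale_sd, `/`)

  grid <- utils::modifyList(
    list(max_depth = c(2L, 3L), eta = c(0.1, 0.3), nrounds = 60L,
         subsample = 0.8, n_models = 10L, cv_folds = 5L), config)
  combos <- expand.grid(max_depth = grid$max_depth, eta = grid$eta,
                        nrounds = grid$nrounds, subsample = grid$subsample)

  seeds <- derive_seeds(seed, grid$n_models + 1L)
  folds <- stratified_folds(y, grid$cv_folds, seeds[grid$n_models + 1L])

  cv_auc <- vapply(seq_len(nrow(combos)), function(ci) {
    aucs <- vapply(seq_len(grid$cv_folds), function(f) {
      tr <- folds != f
      m <- fit_xgb(Xs[tr, , drop = FALSE], y[tr], combos[ci, ],
                   seeds[grid$n_models + 1L])
      roc_auc(y[!tr], predict_xgb(m, Xs[!tr, , drop = FALSE]))
    }, numeric(1))
    mean(aucs)
  }, numeric(1))
  best <- combos[which.max(cv_auc), ]

  n <- nrow(Xs)
  boot_idx <- lapply(seq_len(grid$n_models), function(m)
    withr::with_seed(seeds[m], sample.int(n, n, replace = TRUE)))
  models <- lapply(seq_len(grid$n_models), function(m)
    fit_xgb(Xs[boot_idx[[m]], , drop = FALSE], y[boot_idx[[m]]], best,
            seeds[m]))

  structure(list(
    models = models,
    scale_mean = scale_mean, scale_sd = scale_sd,
    feature_names = colnames(X),
    manifest = list(seed = seed, model_seeds = seeds[seq_len(grid$n_models)],
                    cv_seed = seeds[grid$n_models + 1L],
                    bootstrap_indices = boot_idx,
                    hyperparameters = as.list(best),
                    cv_auc = stats::setNames(cv_auc, apply(combos, 1, paste,
                                                           collapse = "/")),
                    n_positive = sum(y == 1), n_background = sum(y == 0),
                    model_version = "degron_ensemble-1"),
    class_label = "degron"),
    class = "degron_ensemble")
}

fit_xgb <- function(X, y, hp, seed) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic", max_depth = hp$max_depth,
                  eta = hp$eta, subsample = hp$subsample, nthread = 1L,
                  seed = seed),
    data = xgboost::xgb.DMatrix(X, label = y),
    nrounds = hp$nrounds, verbose = 0)
}

predict_xgb <- function(model, X) {
  as.numeric(stats::predict(model, xgboost::xgb.DMatrix(X)))
}

feature_matrix <- function(df) {
  missing <- setdiff(FEATURE_REGISTRY, names(df))
  if (length(missing))
    abort("unknown/missing feature name(s): expected registry columns %s",
          paste(missing, collapse = ", "))
  as.matrix(df[FEATURE_REGISTRY])
}

stratified_folds <- function(y, k, seed) {
  withr::with_seed(seed, {
    folds <- integer(length(y))
    for (cls in unique(y)) {
      i <- which(y == cls)
      folds[i] <- sample(rep_len(seq_len(k), length(i)))
    }
    folds
  })
}

#' Score candidates with a trained degron ensemble
#'
#' @param object A `degron_ensemble` from [train_degron_ensemble()].
#' @param features Feature table (candidate reference columns plus the
#'   feature registry), e.g. from [aggregate_features()].
#' @param threshold Probability threshold; the pass flag is strict
#'   (`probability > threshold`).
#' @param ... Unused.
#' @return A `data.frame`: candidate reference columns, `per_model_1` ...
#'   `per_model_10`, `probability` (their arithmetic mean), and
#'   `passed_threshold`.
#' @export
predict.degron_ensemble <- function(object, features, threshold = 0.5, ...) {
  X <- feature_matrix(features)
  Xs <- sweep(sweep(X, 2, object$scale_mean), 2, object$scale_sd, `/`)
  scores <- vapply(object$models, function(m) predict_xgb(m, Xs),
                   numeric(nrow(Xs)))
  if (nrow(Xs) == 1L) scores <- matrix(scores, nrow = 1L)
  colnames(scores) <- paste0("per_model_", seq_along(object$models))
  prob <- rowMeans(scores)
  ref_cols <- intersect(c("protein_id", "motif_name", "start", "end"),
                        names(features))
  cbind(features[ref_cols], as.data.frame(scores),
        probability = prob, passed_threshold = prob > threshold)
}

#' Extract the fixed-length sequence window around a span
#'
#' The window is centered on the span midpoint (`c = floor((start+end)/2)`),
#' covers `[c - 24, c + 25]` for the default length 50, and is padded with
#' `X` beyond the protein termini, so it is always exactly `length`
#' characters.
#'
#' @param proteome Proteome `data.frame`.
#' @param protein_id Protein identifier.
#' @param start,end Span (1-based inclusive).
#' @param length Window length (default 50).
#' @return The window string.
#' @export
extract_window <- function(proteome, protein_id, start, end, length = 50L) {
  seq <- get_sequence(proteome, protein_id)
  len <- nchar(seq)
  if (start < 1L || end > len || start > end)
    abort("span [%d, %d] outside protein '%s' (length %d)", start, end,
          protein_id, len)
  ctr <- (start + end) %/% 2L
  from <- ctr - (length - 1L) %/% 2L
  padded_substring(seq, from, from + length - 1L)
}

#' Default physicochemical window embedding
#'
#' The built-in, dependency-free embedding provider for the sequence fallback
#' model: each residue is encoded by Kyte-Doolittle hydropathy, formal
#' side-chain charge and side-chain volume (unit-scaled; unknown `X`
#' contributes zero), the window is mean- and max-pooled over each property,
#' and the 20-residue composition is appended — a 27-dimensional vector. A
#' pretrained protein-language-model provider can be injected in its place
#' (any function mapping a character vector of windows to a numeric matrix).
#'
#' @param windows Character vector of sequence windows.
#' @return Numeric matrix, one row per window.
#' @export
physicochemical_embedding <- function(windows) {
  vol <- (AA_VOLUME - min(AA_VOLUME)) / diff(range(AA_VOLUME))
  emb <- t(vapply(windows, function(w) {
    res <- residues(w)
    known <- res[res != AA_UNKNOWN]
    h <- AA_HYDROPATHY[res]; h[is.na(h)] <- 0
    chg <- AA_CHARGE[res]; chg[is.na(chg)] <- 0
    v <- vol[res]; v[is.na(v)] <- 0
    comp <- as.numeric(table(factor(known, levels = AA_ALPHABET))) /
      max(1L, length(res))
    c(mean(h), max(h), mean(chg), max(chg), mean(v), max(v),
      length(known) / length(res), comp)
  }, numeric(27L)))
  rownames(emb) <- NULL
  colnames(emb) <- c("hyd_mean", "hyd_max", "chg_mean", "chg_max",
                     "vol_mean", "vol_max", "frac_known",
                     paste0("comp_", AA_ALPHABET))
  emb
}

#' Train the sequence-only fallback degron model
#'
#' For candidates without feature tracks: 50-residue windows are embedded by
#' an injectable provider (default [physicochemical_embedding()]) and fed to
#' a fixed dense head — 128 ReLU units, then 64 ReLU units, then a single
#' sigmoid output — trained with binary cross-entropy and early stopping on
#' a held-out split.
#'
#' @param windows Character vector of windows, each exactly `window_length`
#'   characters (`X`-padded).
#' @param labels 0/1 vector (1 = degron).
#' @param provider Function mapping windows to a numeric embedding matrix.
#' @param config Optional list: `epochs`, `lr`, `val_frac`, `patience`.
#' @param seed Integer seed.
#' @param window_length Required window length (default 50).
#' @return An object of class `degron_seq_model`.
#' @export
train_sequence_model <- function(windows, labels,
                                 provider = physicochemical_embedding,
                                 config = list(), seed = 1L,
                                 window_length = 50L) {
  if (any(nchar(windows) != window_length))
    abort("every window must be exactly %d characters", window_length)
  if (length(unique(labels)) < 2L)
    abort("degenerate single-class training labels")
  cfg <- utils::modifyList(list(epochs = 300L, lr = 1e-3, val_frac = 0.2,
                                patience = 25L), config)
  X <- provider(windows)
  ctr <- colMeans(X); scl <- apply(X, 2, stats::sd); scl[scl == 0] <- 1
  Xs <- sweep(sweep(X, 2, ctr), 2, scl, `/`)
  fit <- mlp_train(Xs, labels, hidden = c(128L, 64L), seed = seed,
                   epochs = cfg$epochs, lr = cfg$lr, val_frac = cfg$val_frac,
                   patience = cfg$patience)
  structure(list(fit = fit, provider = provider, center = ctr, scale = scl,
                 window_length = window_length,
                 head = c(128L, 64L, 1L), seed = seed),
            class = "degron_seq_model")
}

#' @rdname train_sequence_model
#' @param object A `degron_seq_model`.
#' @param threshold Strict probability threshold for the pass flag.
#' @param ... Unused.
#' @export
predict.degron_seq_model <- function(object, windows, threshold = 0.5, ...) {
  if (any(nchar(windows) != object$window_length))
    abort("every window must be exactly %d characters", object$window_length)
  X <- object$provider(windows)
  Xs <- sweep(sweep(X, 2, object$center), 2, object$scale, `/`)
  prob <- mlp_predict(object$fit, Xs)
  data.frame(window = windows, probability = prob,
             passed_threshold = prob > threshold,
             stringsAsFactors = FALSE)
}

#' Flag high-priority degron calls
#'
#' A call is high priority when its probability exceeds the lowest
#' probability observed among verified degrons of the same motif class *and*
#' it passed the 0.5 threshold. Calls in a class with no verified member are
#' never high priority (with a warning naming the classes).
#'
#' @param calls Prediction table from [predict.degron_ensemble()], with a
#'   `motif_name` column.
#' @param verified_calls Prediction table for verified (known) degrons, with
#'   `motif_name` and `probability`.
#' @return `calls` with a logical `high_priority` column appended.
#' @export
rank_high_priority <- function(calls, verified_calls) {
  mins <- tapply(verified_calls$probability, verified_calls$motif_name, min)
  class_min <- as.numeric(mins[calls$motif_name])
  orphan <- is.na(class_min)
  if (any(orphan))
    warn("no verified degron in class(es): %s; their candidates are not high priority",
         paste(unique(calls$motif_name[orphan]), collapse = ", "))
  hp <- !orphan & calls$passed_threshold & calls$probability > class_min
  hp[is.na(hp)] <- FALSE
  calls$high_priority <- hp
  calls
}
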