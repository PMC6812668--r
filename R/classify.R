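#' Build a feature table from shift records
#'
#' Features are the five ribose shifts (C1'-C5') plus, optionally, a
#' 16-column one-hot encoding of the DN sequence (sequence-aware
#' classification performs better than sequence-blind).  Labels are the
#' record rotamer ids mapped through the requested family scheme; the
#' pseudo-scheme `"rotamer"` keeps the 46 rotamer labels.
#'
#' @param records Data.frame with `rotamer_id`, `sequence` and the shift
#'   columns `C1p ... C5p`; rows with missing shifts are dropped and
#'   counted in attribute `"n_dropped"`.
#' @param scheme_id Labelling scheme (see [family_schemes()]).
#' @param use_sequence Include the sequence one-hot block.
#' @param family_map From [load_family_map()].
#' @return List with `x` (numeric matrix), `y` (character labels) and
#'   `sequence`.
#' @export
featurize <- function(records, scheme_id = "rotamer", use_sequence = TRUE,
                      family_map = load_family_map()) {
  shifts <- as.matrix(records[, nucleus_cols()])
  ok <- rowSums(!is.finite(shifts)) == 0
  records <- records[ok, , drop = FALSE]
  shifts <- shifts[ok, , drop = FALSE]
  x <- shifts
  if (use_sequence) {
    b <- c("A", "C", "G", "U")
    seqs <- as.vector(outer(b, b, paste0))
    onehot <- matrix(0, nrow(records), 16,
                     dimnames = list(NULL, paste0("seq_", seqs)))
    onehot[cbind(seq_len(nrow(records)),
                 match(records$sequence, seqs))] <- 1
    x <- cbind(x, onehot)
  }
  out <- list(x = x,
              y = family_of(records$rotamer_id, scheme_id, family_map),
              sequence = records$sequence)
  attr(out, "n_dropped") <- sum(!ok)
  out
}

#' Classifier specifications
#'
#' The five classifier types plus the random baseline, each a small spec
#' list consumed by [fit_classifier()]: `NN` (k-nearest neighbours, `k`),
#' `DT` (decision tree, `maxdepth`), `RF` (random forest, `ntree`),
#' `MLP` (single-hidden-layer perceptron, `size`, `decay`), `SVM`
#' (RBF-kernel, `cost`) and `RAND` (samples labels from the training
#' label distribution).
#'
#' @param name One of "NN", "DT", "RF", "MLP", "SVM", "RAND".
#' @param ... Hyperparameters overriding the defaults above.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(name = c("NN", "DT", "RF", "MLP", "SVM", "RAND"),
                            ...) {
  name <- match.arg(name)
  defaults <- switch(name,
                     NN = list(k = 3),
                     DT = list(maxdepth = 10),
                     RF = list(ntree = 100),
                     MLP = list(size = 10, decay = 1e-3, maxit = 200),
                     SVM = list(cost = 1),
                     RAND = list())
  spec <- utils::modifyList(defaults, list(...))
  spec$name <- name
  class(spec) <- "classifier_spec"
  spec
}

#' Fit / predict with a classifier spec
#'
#' Shift features are standardised with training-set statistics only; the
#' same transform is applied at prediction time.
#'
#' @param spec From [classifier_spec()].
#' @param x,y Training features and labels.
#' @param seed Integer seed (stochastic learners are seeded per fit).
#' @return A fitted `rotasuite_model`.
#' @export
fit_classifier <- function(spec, x, y, seed = 1) {
  ns <- nucleus_cols()
  ctr <- colMeans(x[, ns, drop = FALSE])
  scl <- apply(x[, ns, drop = FALSE], 2, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  xs <- x
  xs[, ns] <- sweep(sweep(x[, ns, drop = FALSE], 2, ctr), 2, scl, "/")
  y <- factor(y)
  set.seed(seed)
  fit <- switch(spec$name,
    NN = list(x = xs, y = y),
    DT = rpart::rpart(y ~ ., data = data.frame(y = y, xs),
                      method = "class",
                      control = rpart::rpart.control(
                        maxdepth = spec$maxdepth, cp = 0, minsplit = 2,
                        xval = 0)),
    RF = randomForest::randomForest(x = xs, y = y, ntree = spec$ntree),
    MLP = nnet::nnet(xs, nnet::class.ind(y), size = spec$size,
                     decay = spec$decay, maxit = spec$maxit,
                     softmax = nlevels(y) > 1, trace = FALSE,
                     MaxNWts = 100000),
    SVM = e1071::svm(x = xs, y = y, kernel = "radial", cost = spec$cost,
                     scale = FALSE),
    RAND = list(levels = levels(y),
                prob = as.numeric(table(y)) / length(y)),
    stop("unknown classifier: ", spec$name))
  structure(list(spec = spec, fit = fit, center = ctr, scale = scl,
                 levels = levels(y), seed = seed),
            class = "rotasuite_model")
}

#' @param model A fitted `rotasuite_model`.
#' @param newx Feature matrix to predict.
#' @rdname fit_classifier
#' @export
predict_classifier <- function(model, newx) {
  ns <- nucleus_cols()
  xs <- newx
  xs[, ns] <- sweep(sweep(newx[, ns, drop = FALSE], 2, model$center),
                    2, model$scale, "/")
  spec <- model$spec
  set.seed(model$seed + 1L)
  out <- switch(spec$name,
    NN = as.character(class::knn(model$fit$x, xs, model$fit$y,
                                 k = spec$k)),
    DT = as.character(predict(model$fit, data.frame(xs), type = "class")),
    RF = as.character(predict(model$fit, xs)),
    MLP = {
      pr <- predict(model$fit, xs)
      if (length(model$levels) == 1) rep(model$levels, nrow(xs))
      else model$levels[max.col(pr)]
    },
    SVM = as.character(predict(model$fit, xs)),
    RAND = sample(model$fit$levels, nrow(xs), replace = TRUE,
                  prob = model$fit$prob))
  out
}

#' Run one classification regime
#'
#' The three regimes of the study: `exp_vs_theo` trains on the full
#' (theoretical) training set and scores the (experimental-like) test set
#' once; `theo_vs_theo` and `exp_vs_exp` are leave-one-out
#' cross-validations on a single set - at every iteration a unique suite
#' is held out and the rest train the model.
#'
#' @param regime One of "exp_vs_theo", "theo_vs_theo", "exp_vs_exp".
#' @param train,test Shift record tables ([generate_theoretical()] /
#'   [generate_experimental_like()] layout).  For the LOO regimes `test`
#'   defaults to `train`and must be the same set.
#' @param scheme_id Labelling scheme.
#' @param spec From [classifier_spec()].
#' @param rosum Matching ROSUM from [build_rosum()]; built on the fly if
#'   NULL.
#' @param seed Integer seed.
#' @param use_sequence Include sequence one-hot features.
#' @param catalog,family_map Catalog assets (packaged defaults).
#' @return A one-row `eval_report` data.frame: the four scores, the
#'   random-baseline calibration, sizes, seed and a config digest.
#' @export
run_regime <- function(regime = c("exp_vs_theo", "theo_vs_theo",
                                  "exp_vs_exp"),
                       train, test = NULL, scheme_id = "rotamer",
                       spec = classifier_spec("NN"), rosum = NULL,
                       seed = 1, use_sequence = TRUE,
                       catalog = load_catalog(),
                       family_map = load_family_map()) {
  regime <- match.arg(regime)
  if (is.null(test)) test <- train
  ftr <- featurize(train, scheme_id, use_sequence, family_map)
  fte <- featurize(test, scheme_id, use_sequence, family_map)
  if (is.null(rosum))
    rosum <- build_rosum(catalog, scheme_id, family_map = family_map)
  if (!all(fte$y %in% rosum$labels))
    stop("test label(s) outside the scheme: ",
         paste(setdiff(fte$y, rosum$labels), collapse = ", "))
  if (regime == "exp_vs_theo") {
    model <- fit_classifier(spec, ftr$x, ftr$y, seed)
    pred <- predict_classifier(model, fte$x)
    truth <- fte$y
  } else {
    if (!identical(dim(ftr$x), dim(fte$x)))
      stop("LOO regimes require train and test to be the same set")
    pred <- loo_predict(spec, ftr$x, ftr$y, seed)
    truth <- ftr$y
  }
  sm <- standard_metrics(truth, pred)
  base <- random_baseline(truth, rosum)
  report <- data.frame(
    regime = regime, scheme_id = scheme_id, classifier = spec$name,
    params = spec_string(spec),
    weighted_accuracy = weighted_accuracy(truth, pred, rosum),
    precision = sm[["precision"]], recall = sm[["recall"]],
    f1 = sm[["f1"]],
    rand_weighted_accuracy = base[["weighted_accuracy"]],
    rand_accuracy = base[["accuracy"]],
    n_train = nrow(ftr$x), n_test = length(truth), seed = seed,
    config_digest = config_digest(list(regime, scheme_id, spec, seed,
                                       use_sequence)),
    stringsAsFactors = FALSE)
  class(report) <- c("eval_report", "data.frame")
  report
}

# leave-one-out predictions: hold each suite out in turn
loo_predict <- function(spec, x, y, seed = 1) {
  n <- nrow(x)
  pred <- character(n)
  for (i in seq_len(n)) {
    model <- fit_classifier(spec, x[-i, , drop = FALSE], y[-i],
                            seed = seed + i)
    pred[i] <- predict_classifier(model, x[i, , drop = FALSE])
  }
  pred
}

spec_string <- function(spec) {
  p <- spec[setdiff(names(spec), "name")]
  if (!length(p)) return("")
  paste(names(p), unlist(p), sep = "=", collapse = ",")
}

config_digest <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(x), f)
  unname(tools::md5sum(f))
}

#' Default hyperparameter grids
#'
#' Small documented grids per classifier; each grid point becomes one
#' evaluation report, and the per-classifier maxima are extracted.
#'
#' @return Named list of lists of [classifier_spec()]s.
#' @export
default_grids <- function() {
  list(
    NN = lapply(c(1, 3, 5, 7), function(k) classifier_spec("NN", k = k)),
    DT = lapply(c(3, 10, 30), function(d)
      classifier_spec("DT", maxdepth = d)),
    RF = list(classifier_spec("RF", ntree = 100)),
    MLP = lapply(c(10, 50), function(s) classifier_spec("MLP", size = s)),
    SVM = lapply(c(1, 10), function(c_) classifier_spec("SVM", cost = c_)),
    RAND = list(classifier_spec("RAND")))
}

#' Sweep classifier hyperparameters over a regime
#'
#' @inheritParams run_regime
#' @param grids From [default_grids()] (or a subset).
#' @return List with `reports` (all grid points, row-bound) and `best`
#'   (the maximal-F1 row per classifier).
#' @export
hyperparameter_sweep <- function(grids = default_grids(), regime, train,
                                 test = NULL, scheme_id = "rotamer",
                                 rosum = NULL, seed = 1,
                                 use_sequence = TRUE,
                                 catalog = load_catalog(),
                                 family_map = load_family_map()) {
  reports <- list()
  for (cname in names(grids)) for (spec in grids[[cname]]) {
    reports[[length(reports) + 1L]] <-
      run_regime(regime, train, test, scheme_id, spec, rosum, seed,
                 use_sequence, catalog, family_map)
  }
  reports <- do.call(rbind, reports)
  best <- do.call(rbind, lapply(split(reports, reports$classifier),
                                function(d) d[which.max(d$f1), ]))
  rownames(best) <- NULL
  list(reports = reports, best = best)
}

#' Sparsity experiment: dense vs sparsified training coverage
#'
#' Quantifies what the uneven coverage of an experimental dataset costs:
#' every record of the full theoretical set is scored leave-one-out twice,
#' once with the full remaining set as training pool (dense) and once with
#' the training pool thinned to the sparsity profile (sparse).  Scoring
#' identical test items isolates the coverage effect from composition
#' changes; the deltas (dense minus sparse) are reported.
#'
#' @param records Theoretical shift records.
#' @param profile Sparsity profile as in [generate_experimental_like()]:
#'   `rotamer_id -> retention` (probability if <= 1, else a retained count).
#' @inheritParams run_regime
#' @return List of `dense`, `sparse` reports and `delta` scores.
#' @export
sparsity_experiment <- function(records, profile, scheme_id = "rotamer",
                                spec = classifier_spec("NN"), rosum = NULL,
                                seed = 1, catalog = load_catalog(),
                                family_map = load_family_map()) {
  ftr <- featurize(records, scheme_id, TRUE, family_map)
  if (is.null(rosum))
    rosum <- build_rosum(catalog, scheme_id, family_map = family_map)
  set.seed(seed)
  keep <- rep(TRUE, nrow(records))
  for (id in names(profile)) {
    rows <- which(records$rotamer_id == id)
    r <- profile[[id]]
    k <- if (r <= 1) round(r * length(rows)) else min(length(rows),
                                                      as.integer(r))
    if (k < length(rows))
      keep[if (k == 0) rows else rows[-sample(seq_along(rows), k)]] <- FALSE
  }
  n <- nrow(ftr$x)
  pred_dense <- loo_predict(spec, ftr$x, ftr$y, seed)
  pred_sparse <- vapply(seq_len(n), function(i) {
    pool <- setdiff(which(keep), i)
    model <- fit_classifier(spec, ftr$x[pool, , drop = FALSE], ftr$y[pool],
                            seed = seed + i)
    predict_classifier(model, ftr$x[i, , drop = FALSE])
  }, character(1))
  mk_report <- function(pred, n_train) {
    sm <- standard_metrics(ftr$y, pred)
    base <- random_baseline(ftr$y, rosum)
    data.frame(regime = "theo_vs_theo", scheme_id = scheme_id,
               classifier = spec$name, params = spec_string(spec),
               weighted_accuracy = weighted_accuracy(ftr$y, pred, rosum),
               precision = sm[["precision"]], recall = sm[["recall"]],
               f1 = sm[["f1"]],
               rand_weighted_accuracy = base[["weighted_accuracy"]],
               rand_accuracy = base[["accuracy"]],
               n_train = n_train, n_test = n, seed = seed,
               config_digest = config_digest(list("sparsity", scheme_id,
                                                  spec, seed)),
               stringsAsFactors = FALSE)
  }
  dense <- mk_report(pred_dense, n - 1L)
  sparse <- mk_report(pred_sparse, sum(keep) - 1L)
  cols <- c("weighted_accuracy", "precision", "recall", "f1")
  list(dense = dense, sparse = sparse,
       delta = unlist(dense[cols]) - unlist(sparse[cols]))
}

#' Noise experiment: theoretical vs theoretical + noise
#'
#' Trains on the clean theoretical records and tests on copies with
#' Gaussian noise of the stated theory/experiment discrepancy added to
#' the shifts, against a noise-free control.
#'
#' @param records Theoretical shift records.
#' @param noise_sds Noise levels (ppm) to test; 0 is the control.
#' @inheritParams run_regime
#' @return Row-bound reports, one per noise level, with column `noise_sd`.
#' @export
noise_experiment <- function(records, noise_sds = c(0, 1.47),
                             scheme_id = "rotamer",
                             spec = classifier_spec("NN"), rosum = NULL,
                             seed = 1, catalog = load_catalog(),
                             family_map = load_family_map()) {
  out <- lapply(seq_along(noise_sds), function(i) {
    noisy <- generate_experimental_like(records, noise_sd = noise_sds[i],
                                        seed = seed + i)
    rep_ <- run_regime("exp_vs_theo", records, noisy, scheme_id, spec,
                       rosum, seed, catalog = catalog,
                       family_map = family_map)
    rep_$noise_sd <- noise_sds[i]
    rep_
  })
  do.call(rbind, out)
}
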