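#' Small 1-D convolutional classifier configuration
#'
#' The effectiveness study's classifier: two blocks of
#' convolution (kernel 8) - rectifier - max-pool (4), then a dense softmax
#' head, trained with cross-entropy and Adam.  Deliberately the smallest
#' architecture that separates the synthetic classes.
#'
#' @param n_classes number of classes, >= 2.
#' @param input_length spectrum length in channels.
#' @param epochs,batch_size,lr training hyperparameters.
#' @param rng_seed integer seed.
#' @return validated list of class \code{"ClassifierConfig"}.
#' @export
classifierConfig <- function(n_classes, input_length, epochs = 30L,
                             batch_size = 16L, lr = 1e-3, rng_seed = 1L) {
  if (n_classes < 2) stop("'n_classes' must be >= 2")
  structure(list(n_classes = as.integer(n_classes),
                 input_length = as.integer(input_length),
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), lr = lr,
                 rng_seed = as.integer(rng_seed)),
            class = "ClassifierConfig")
}

.build_classifier <- function(cfg) {
  L1 <- cfg$input_length - 7L
  P1 <- L1 %/% 4L
  L2 <- P1 - 7L
  P2 <- L2 %/% 4L
  if (P2 < 1L) stop("'input_length' too short for the classifier")
  nn_sequential(
    nn_conv1d(1L, 8L, 8L, 1L, 0L, bias = TRUE, init = "uniform"),
    nn_act("relu"),
    nn_maxpool1d(4L),
    nn_conv1d(8L, 16L, 8L, 1L, 0L, bias = TRUE, init = "uniform"),
    nn_act("relu"),
    nn_maxpool1d(4L),
    nn_dense(16L * P2, cfg$n_classes))
}

# softmax cross-entropy over logits (n_classes, 1, B); labels 1..n_classes
.softmax_ce <- function(logits, labels) {
  d <- dim(logits)
  z <- matrix(logits, d[1], d[3])
  z <- z - apply(z, 2L, max)
  ez <- exp(z)
  p <- ez / rep(colSums(ez), each = d[1])
  idx <- cbind(labels, seq_len(d[3]))
  loss <- -mean(log(pmax(p[idx], 1e-12)))
  dp <- p
  dp[idx] <- dp[idx] - 1
  dlogits <- array(dp / d[3], d)
  list(loss = loss, dlogits = dlogits, prob = p)
}

#' Train the demo classifier
#'
#' @param x \linkS4class{SpectrumSet} or matrix (channels x spectra).
#' @param labels integer or factor class labels (one per spectrum).
#' @param cfg a \code{\link{classifierConfig}}.
#' @return list of class \code{"classifierState"}: \code{model},
#'   \code{classes}, \code{history} (per-epoch mean cross-entropy cost).
#' @export
trainClassifier <- function(x, labels, cfg) {
  if (is(x, "SpectrumSet")) {
    if (missing(labels) || is.null(labels)) labels <- spectrumLabels(x)
    x <- intensities(x)
  }
  classes <- sort(unique(as.character(labels)))
  if (length(classes) != cfg$n_classes)
    stop("found ", length(classes), " classes but cfg$n_classes is ",
         cfg$n_classes)
  y <- match(as.character(labels), classes)
  n <- ncol(x)
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(cfg$rng_seed)
  model <- .build_classifier(cfg)
  opt <- opt_init("adam", nn_trainable(model), cfg$lr)
  history <- numeric(cfg$epochs)
  for (e in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    costs <- c()
    for (s0 in seq(1L, n, by = cfg$batch_size)) {
      idx <- ord[s0:min(s0 + cfg$batch_size - 1L, n)]
      xb <- array(x[, idx], c(1L, nrow(x), length(idx)))
      f <- nn_model_fwd(model, xb, TRUE); model <- f$model
      ce <- .softmax_ce(f$y, y[idx])
      bwd <- nn_model_bwd(model, f$caches, ce$dlogits)
      su <- opt_step(opt, nn_trainable(model),
                     nn_flatten_grads(model, bwd$grads))
      opt <- su$opt
      model <- nn_set_trainable(model, su$params)
      costs <- c(costs, ce$loss)
    }
    history[e] <- mean(costs)
  }
  structure(list(model = model, classes = classes, cfg = cfg,
                 history = history), class = "classifierState")
}

#' Predict classes for spectra
#'
#' @param state a \code{"classifierState"}.
#' @param x \linkS4class{SpectrumSet} or matrix.
#' @return character vector of predicted class labels.
#' @export
predictClassifier <- function(state, x) {
  if (is(x, "SpectrumSet")) x <- intensities(x)
  xb <- array(x, c(1L, nrow(x), ncol(x)))
  logits <- nn_model_fwd(state$model, xb, training = FALSE)$y
  z <- matrix(logits, dim(logits)[1], dim(logits)[3])
  state$classes[apply(z, 2L, which.max)]
}

#' Duplicate a small seed set to a target size
#'
#' Cyclic duplication, mirroring how scarce real data are replicated to match
#' the size of a generated dataset for a fair comparison.
#'
#' @param seed_set a \linkS4class{SpectrumSet}.
#' @param target_n desired spectrum count, >= the seed count.
#' @return a \linkS4class{SpectrumSet} with exactly \code{target_n} spectra.
#' @export
buildDuplicatedDataset <- function(seed_set, target_n) {
  stopifnot(is(seed_set, "SpectrumSet"))
  n <- nSpectra(seed_set)
  if (target_n < n) stop("'target_n' must be >= the seed count")
  idx <- rep_len(seq_len(n), target_n)
  SpectrumSet(intensities(seed_set)[, idx, drop = FALSE],
              label = spectrumLabels(seed_set)[idx],
              shift = shiftAxis(seed_set), meta = metadata(seed_set))
}

#' Compare classifiers trained on duplicated seeds vs generated spectra
#'
#' Two arms with identical training-set sizes and an identical held-out test
#' set: arm "duplicated" cycles the per-class seed spectra to
#' \code{n_per_class}; arm "generated" draws \code{n_per_class} spectra per
#' class from the trained pipeline models.  One classifier per arm is trained
#' with the same seed, and per-epoch training cost plus held-out accuracy are
#' reported for both.
#'
#' @param seed_sets named list of per-class \linkS4class{SpectrumSet}s (the
#'   scarce "real" data).
#' @param models_per_class list of \code{"pipelineModels"} (from
#'   \code{\link{runTraining}}), parallel to \code{seed_sets}.
#' @param test_sets named list of per-class held-out \linkS4class{SpectrumSet}s.
#' @param cfg a \code{\link{classifierConfig}}.
#' @param n_per_class training spectra per class in each arm.
#' @return list of class \code{"comparisonReport"}: per-arm accuracy, cost
#'   curves, and the within-class variance of each arm's training data.
#' @export
runComparison <- function(seed_sets, models_per_class, test_sets, cfg,
                          n_per_class = 50L) {
  stopifnot(length(seed_sets) >= 2L,
            length(models_per_class) == length(seed_sets),
            length(test_sets) == length(seed_sets))
  classes <- names(seed_sets)
  if (is.null(classes)) classes <- paste0("class_", seq_along(seed_sets))
  gather <- function(sets, labels) {
    x <- do.call(cbind, lapply(sets, intensities))
    SpectrumSet(x, label = rep(labels, vapply(sets, nSpectra, integer(1))))
  }
  dup <- lapply(seed_sets, buildDuplicatedDataset, target_n = n_per_class)
  gen <- lapply(seq_along(classes), function(i) {
    g <- runGeneration(models_per_class[[i]], n_per_class,
                       rng_seed = cfg$rng_seed + 7L * i)
    SpectrumSet(intensities(g), label = classes[i])
  })
  train_dup <- gather(dup, classes)
  train_gen <- gather(gen, classes)
  test <- gather(test_sets, classes)
  stopifnot(nSpectra(train_dup) == nSpectra(train_gen))
  cls_dup <- trainClassifier(train_dup, cfg = cfg)
  cls_gen <- trainClassifier(train_gen, cfg = cfg)
  acc <- function(cls) mean(predictClassifier(cls, test) ==
                            spectrumLabels(test))
  wvar <- function(set) mean(vapply(classes, function(cl) {
    m <- intensities(set)[, spectrumLabels(set) == cl, drop = FALSE]
    mean(apply(m, 1L, var))
  }, numeric(1)))
  structure(list(
    accuracy = c(duplicated = acc(cls_dup), generated = acc(cls_gen)),
    cost = list(duplicated = cls_dup$history, generated = cls_gen$history),
    within_class_variance = c(duplicated = wvar(train_dup),
                              generated = wvar(train_gen)),
    n_per_class = n_per_class, classes = classes),
    class = "comparisonReport")
}

#' @export
print.comparisonReport <- function(x, ...) {
  cat("Classifier effectiveness comparison (", length(x$classes),
      " classes, ", x$n_per_class, " training spectra/class/arm)\n", sep = "")
  cat(sprintf("  held-out accuracy: duplicated %.3f | generated %.3f\n",
              x$accuracy[["duplicated"]], x$accuracy[["generated"]]))
  cat(sprintf("  within-class training variance: duplicated %.3g | generated %.3g\n",
              x$within_class_variance[["duplicated"]],
              x$within_class_variance[["generated"]]))
  invisible(x)
}
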