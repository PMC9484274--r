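#' Stratified train/test split specification
#'
#' Defaults reproduce the study design: 70 training and 21 test spectra with
#' per-class counts (train 12,12,12,12,9,13 / test 4,4,4,3,3,3 for classes
#' 0,20,40,60,80,100 wt%).
#'
#' @param trainCounts,testCounts per-class counts, aligned with
#'   \code{classLabels}.
#' @param classLabels class labels the counts refer to.
#' @param seed split seed.
#' @return list of class \code{"SplitSpec"}.
#' @export
splitSpec <- function(trainCounts = c(12, 12, 12, 12, 9, 13),
                      testCounts = c(4, 4, 4, 3, 3, 3),
                      classLabels = c(0, 20, 40, 60, 80, 100),
                      seed = 1) {
  stopifnot(length(trainCounts) == length(classLabels),
            length(testCounts) == length(classLabels),
            all(trainCounts >= 1), all(testCounts >= 0))
  structure(list(trainCounts = as.integer(trainCounts),
                 testCounts = as.integer(testCounts),
                 classLabels = classLabels, seed = seed),
            class = "SplitSpec")
}

#' Stratified random split of a labeled dataset
#'
#' Uniform sampling without replacement within each class; train and test
#' sets are disjoint and honor the per-class counts exactly.
#'
#' @param labels class label per row/sample.
#' @param spec a [splitSpec()].
#' @return list with integer index vectors \code{train} and \code{test}.
#' @export
splitDataset <- function(labels, spec = splitSpec()) {
  stopifnot(inherits(spec, "SplitSpec"))
  withSeed(spec$seed, {
    train <- integer(0)
    test <- integer(0)
    for (i in seq_along(spec$classLabels)) {
      idx <- which(labels == spec$classLabels[i])
      need <- spec$trainCounts[i] + spec$testCounts[i]
      if (length(idx) < need)
        stop(sprintf("class %s has %d samples but %d are requested",
                     spec$classLabels[i], length(idx), need))
      idx <- sample(idx)
      train <- c(train, idx[seq_len(spec$trainCounts[i])])
      test <- c(test, idx[spec$trainCounts[i] + seq_len(spec$testCounts[i])])
    }
    list(train = sort(train), test = sort(test))
  })
}

#' Classifier specification
#'
#' The four model families compared in the pipeline. Hyperparameter
#' defaults: \code{v_svm} nu = 0.5 with a radial-basis kernel (kernel scale
#' 1/d by default, one-vs-one multiclass voting); \code{neural_network} one
#' hidden layer of 100 rectangularly-capped units trained to an iteration cap
#' of 1000 with mild weight decay; \code{random_forest} 100 trees, unlimited
#' depth; \code{logistic} multinomial regression with mild ridge decay.
#'
#' @param kind one of \code{"logistic"}, \code{"v_svm"},
#'   \code{"neural_network"}, \code{"random_forest"}.
#' @param seed training seed (drives any internal randomness).
#' @param nu nu parameter of the nu-SVM.
#' @param gamma RBF kernel inverse scale; NULL means 1/(feature count).
#' @param hiddenUnits hidden-layer size of the neural network.
#' @param maxIterations iteration cap of the neural network.
#' @param decay ridge/weight-decay strength (logistic and neural network).
#' @param nTrees number of random-forest trees.
#' @return list of class \code{"ClassifierSpec"}.
#' @export
classifierSpec <- function(kind = c("v_svm", "logistic", "neural_network",
                                    "random_forest"),
                           seed = 1, nu = 0.5, gamma = NULL,
                           hiddenUnits = 100, maxIterations = 1000,
                           decay = 1e-3, nTrees = 100) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = seed, nu = nu, gamma = gamma,
                 hiddenUnits = hiddenUnits, maxIterations = maxIterations,
                 decay = decay, nTrees = nTrees),
            class = "ClassifierSpec")
}

#' Train a mineral-content classifier
#'
#' @param spec a [classifierSpec()].
#' @param x training feature/score matrix.
#' @param y training labels (wt%); at least two distinct classes.
#' @param classOrder full ordered set of class labels the model should know.
#' @return an object of class \code{"boneClassifier"}.
#' @export
trainClassifier <- function(spec, x, y, classOrder = sort(unique(y))) {
  stopifnot(inherits(spec, "ClassifierSpec"))
  x <- as.matrix(x)
  if (any(!is.finite(x))) stop("features must be finite")
  if (length(unique(y)) < 2L)
    stop("training labels contain a single class")
  yf <- factor(y, levels = classOrder)
  df <- data.frame(x, check.names = TRUE)
  model <- withSeed(spec$seed, switch(spec$kind,
    logistic = nnet::multinom(.y ~ ., data = cbind(df, .y = yf),
                              decay = spec$decay, maxit = 1000,
                              trace = FALSE),
    v_svm = e1071::svm(x, yf, type = "nu-classification", nu = spec$nu,
                       kernel = "radial",
                       gamma = if (is.null(spec$gamma)) 1 / ncol(x)
                               else spec$gamma),
    neural_network = nnet::nnet(.y ~ ., data = cbind(df, .y = yf),
                                size = spec$hiddenUnits, decay = spec$decay,
                                maxit = spec$maxIterations,
                                MaxNWts = 50000, trace = FALSE),
    random_forest = randomForest::randomForest(x, yf, ntree = spec$nTrees)))
  structure(list(kind = spec$kind, model = model, levels = levels(yf),
                 featureNames = colnames(df)),
            class = "boneClassifier")
}

#' Predict labels with a trained classifier
#'
#' @param classifier a \code{"boneClassifier"} from [trainClassifier()].
#' @param x feature/score matrix.
#' @return factor of predicted class labels with the training class order.
#' @export
predictLabels <- function(classifier, x) {
  stopifnot(inherits(classifier, "boneClassifier"))
  x <- as.matrix(x)
  df <- data.frame(x, check.names = TRUE)
  colnames(df) <- classifier$featureNames
  pred <- switch(classifier$kind,
    logistic = stats::predict(classifier$model, newdata = df, type = "class"),
    v_svm = stats::predict(classifier$model, x),
    neural_network = stats::predict(classifier$model, newdata = df,
                                    type = "class"),
    random_forest = stats::predict(classifier$model, x))
  factor(as.character(pred), levels = classifier$levels)
}

#' Evaluate predictions against true labels
#'
#' Builds the class-by-class confusion matrix (rows = actual, columns =
#' predicted), overall accuracy, per-class precision (correct/predicted per
#' column, 0 for empty columns) and recall, and the class-size-weighted
#' average precision (macro average also stored).
#'
#' @param predicted predicted labels.
#' @param actual true labels, same length.
#' @param classOrder ordered class labels defining the matrix layout.
#' @return an [EvaluationReport].
#' @examples
#' r <- evaluateClassifier(c(0, 20, 20), c(0, 20, 40), c(0, 20, 40))
#' accuracy(r)   # 2/3
#' @export
evaluateClassifier <- function(predicted, actual,
                               classOrder = sort(unique(actual))) {
  if (length(predicted) != length(actual))
    stop("predicted and actual must have the same length")
  pf <- factor(as.character(predicted), levels = as.character(classOrder))
  af <- factor(as.character(actual), levels = as.character(classOrder))
  if (anyNA(pf) || anyNA(af))
    stop("labels outside the declared class order")
  cm <- table(actual = af, predicted = pf)
  cm <- matrix(as.integer(cm), nrow = nrow(cm),
               dimnames = list(actual = as.character(classOrder),
                               predicted = as.character(classOrder)))
  total <- sum(cm)
  acc <- sum(diag(cm)) / total
  colTot <- colSums(cm)
  rowTot <- rowSums(cm)
  prec <- ifelse(colTot > 0, diag(cm) / colTot, 0)
  rec <- ifelse(rowTot > 0, diag(cm) / rowTot, 0)
  new("EvaluationReport",
      accuracy = acc,
      precisionWeighted = sum(rowTot * prec) / total,
      precisionMacro = mean(prec),
      confusion = cm,
      perClass = data.frame(class = as.character(classOrder),
                            precision = unname(prec), recall = unname(rec)))
}

#' Run the full detection pipeline on synthetic data
#'
#' Reproduces the study workflow end to end: generate the labeled synthetic
#' dataset, fit the equivalent circuit to every spectrum, assemble the
#' feature matrix for each requested mode, split stratified into train/test,
#' z-score with training statistics only, project onto the principal
#' components covering \code{varianceThreshold} of the training variance,
#' train each classifier on the 70 training scores and evaluate on the 21
#' test scores.
#'
#' One master \code{seed} fans out to the generator, fit-jitter, split and
#' classifier seeds through fixed offsets, so a single number reproduces a
#' run.
#'
#' @param seed master seed.
#' @param modes feature modes to run.
#' @param classifiers classifier kinds to run.
#' @param config generator configuration; its seed is overridden by the
#'   derived generator seed.
#' @param options circuit-fit options; seed overridden likewise.
#' @param split split specification; seed overridden likewise.
#' @param varianceThreshold cumulative explained-variance target of the PCA.
#' @return list with \code{comparison} (data.frame of accuracy/precision per
#'   mode and model), \code{reports} (nested list of [EvaluationReport]),
#'   \code{pca} (per-mode [PCAModel]), \code{dataset}, \code{fits} and
#'   \code{seeds}.
#' @export
runPipeline <- function(seed = 7,
                        modes = c("impedance_only", "combined"),
                        classifiers = c("logistic", "v_svm",
                                        "neural_network", "random_forest"),
                        config = generatorConfig(),
                        options = fitOptions(),
                        split = splitSpec(),
                        varianceThreshold = 0.90) {
  seeds <- deriveSeeds(seed)
  config$seed <- seeds$generator
  options$seed <- seeds$fit
  split$seed <- seeds$split
  dataset <- generateDataset(config)
  fits <- if ("combined" %in% modes) fitDataset(dataset, options) else NULL
  labels <- mineralContent(dataset)
  idx <- splitDataset(labels, split)
  reports <- list()
  pcas <- list()
  rows <- list()
  for (mode in modes) {
    fm <- buildFeatures(dataset, fits = fits, mode = mode)
    x <- featureValues(fm)
    st <- standardizeFit(x[idx$train, , drop = FALSE])
    xs <- standardizeApply(x, st)
    pca <- pcaFit(xs[idx$train, , drop = FALSE],
                  varianceThreshold = varianceThreshold)
    pca@stdCenter <- st$center
    pca@stdScale <- st$scale
    pcas[[mode]] <- pca
    scores <- pcaTransform(xs, pca)
    reports[[mode]] <- list()
    for (kind in classifiers) {
      cs <- classifierSpec(kind, seed = seeds$classifier)
      model <- trainClassifier(cs, scores[idx$train, , drop = FALSE],
                               labels[idx$train],
                               classOrder = split$classLabels)
      pred <- predictLabels(model, scores[idx$test, , drop = FALSE])
      rep <- evaluateClassifier(pred, labels[idx$test],
                                classOrder = split$classLabels)
      reports[[mode]][[kind]] <- rep
      rows[[length(rows) + 1L]] <- data.frame(
        mode = mode, model = kind, accuracy = accuracy(rep),
        precision_weighted = precisionScore(rep),
        n_components = nComponents(pca))
    }
  }
  list(comparison = do.call(rbind, rows), reports = reports, pca = pcas,
       dataset = dataset, fits = fits, split = idx, seeds = seeds)
}
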