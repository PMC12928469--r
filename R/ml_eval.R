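#' Stratified train/test split
#'
#' Randomly partitions a labelled population, stratified by status so both
#' classes appear on both sides.  Default holdout is 2/3 training, 1/3
#' test.
#'
#' @param pop a [labeled_population()].
#' @param train_fraction fraction of each class assigned to training.
#' @param seed optional integer seed.
#' @return list of two labelled populations, `train` and `test`, with
#'   `meta$partition` set.
#' @export
split_population <- function(pop, train_fraction = 2 / 3, seed = NULL) {
  stopifnot(inherits(pop, "labeled_population"))
  if (!is.null(seed)) set.seed(seed)
  tr <- integer(0)
  for (cl in levels(pop$labels)) {
    idx <- which(pop$labels == cl)
    if (!length(idx)) stop("class ", cl, " absent from population", call. = FALSE)
    k <- round(train_fraction * length(idx))
    if (k < 1 || k >= length(idx))
      stop("split leaves class ", cl, " empty on one side", call. = FALSE)
    tr <- c(tr, idx[sample.int(length(idx), k)])
  }
  tr <- sort(tr)
  mk <- function(rows, part) {
    p <- labeled_population(pop$genotypes[rows, , drop = FALSE],
                            pop$labels[rows], pop$meta)
    p$meta$partition <- part
    p
  }
  list(train = mk(tr, "train"), test = mk(setdiff(seq_along(pop$labels), tr), "test"))
}

#' Classifier specifications
#'
#' The evaluated panel: naive Bayes (`NB`), logistic regression (`LR`),
#' decision tree (`DT`), random forest (`RF`) and a fully connected neural
#' network with one hidden layer of 25 sigmoid units (`NN`).  Comparators
#' use their ecosystem defaults; the NN trains on standardized inputs with
#' a small weight decay.
#'
#' @param kind one of `"NN"`, `"RF"`, `"NB"`, `"LR"`, `"DT"`.
#' @param size hidden-layer width (NN).
#' @param decay weight decay (NN).
#' @param maxit optimizer iteration cap (NN).
#' @param ntree number of trees (RF).
#' @param ... further arguments passed through to the fitting function.
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(kind = c("NN", "RF", "NB", "LR", "DT"),
                            size = 25, decay = 1, maxit = 500,
                            ntree = 300, ...) {
  kind <- match.arg(kind)
  structure(list(kind = kind, size = size, decay = decay, maxit = maxit,
                 ntree = ntree, extra = list(...)),
            class = "classifier_spec")
}

#' Rank-based AUC
#'
#' Area under the ROC curve computed directly as the Mann-Whitney rank
#' statistic: the probability that a random Case outscores a random
#' Control, with ties counted half.
#'
#' @param scores numeric risk scores (higher = more Case-like).
#' @param labels `Case`/`Control` labels.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  labels <- as_status(labels)
  n1 <- sum(labels == "Case")
  n0 <- sum(labels == "Control")
  if (n1 == 0 || n0 == 0) stop("AUC needs both classes", call. = FALSE)
  r <- rank(scores)
  (sum(r[labels == "Case"]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Train one classifier and score held-out data
#'
#' Fits the specified classifier on the training partition only and
#' computes the test AUC from continuous class scores via [auc_score()].
#' For the NN, features are standardized by training-set statistics and
#' non-convergence within the iteration cap is flagged (the AUC is still
#' reported).
#'
#' @param train,test labelled populations from [split_population()].
#' @param spec a [classifier_spec()] or a kind string.
#' @param seed optional integer seed (NN initialisation, RF bootstrap).
#' @return an object of class `trained_classifier`: list with `kind`,
#'   `auc`, `scores` (test Case scores), `fit` (the underlying model,
#'   exposing first-layer weights for the NN) and `converged`.
#' @export
train_and_score <- function(train, test, spec = classifier_spec("NN"),
                            seed = NULL) {
  if (is.character(spec)) spec <- classifier_spec(spec)
  if (!is.null(seed)) set.seed(seed)
  if (nlevels(droplevels(train$labels)) < 2)
    stop("training set must contain both classes", call. = FALSE)
  xtr <- train$genotypes
  xte <- test$genotypes
  ytr <- train$labels
  converged <- TRUE
  if (spec$kind == "NN") {
    mu <- colMeans(xtr)
    sdv <- apply(xtr, 2, stats::sd)
    sdv[sdv == 0] <- 1
    ztr <- scale(xtr, mu, sdv)
    zte <- scale(xte, mu, sdv)
    fit <- nnet::nnet(ztr, as.numeric(ytr == "Case"), size = spec$size,
                      decay = spec$decay, maxit = spec$maxit,
                      entropy = TRUE, trace = FALSE,
                      MaxNWts = (ncol(ztr) + 2) * spec$size + 1)
    converged <- isTRUE(fit$convergence == 0)
    scores <- as.vector(stats::predict(fit, zte))
    fit$scaling <- list(center = mu, scale = sdv)
  } else if (spec$kind == "RF") {
    fit <- randomForest::randomForest(xtr, ytr, ntree = spec$ntree)
    scores <- stats::predict(fit, xte, type = "prob")[, "Case"]
  } else if (spec$kind == "NB") {
    fit <- e1071::naiveBayes(xtr, ytr)
    scores <- stats::predict(fit, xte, type = "raw")[, "Case"]
  } else if (spec$kind == "LR") {
    df <- data.frame(y = as.numeric(ytr == "Case"), xtr)
    fit <- suppressWarnings(stats::glm(y ~ ., data = df, family = stats::binomial()))
    converged <- fit$converged
    scores <- suppressWarnings(
      stats::predict(fit, data.frame(xte), type = "response"))
  } else { # DT
    df <- data.frame(y = ytr, xtr)
    fit <- rpart::rpart(y ~ ., data = df, method = "class")
    scores <- stats::predict(fit, data.frame(xte), type = "prob")[, "Case"]
  }
  if (!converged)
    warning(spec$kind, " did not converge; AUC reported anyway", call. = FALSE)
  structure(list(kind = spec$kind, spec = spec,
                 auc = auc_score(scores, test$labels),
                 scores = scores, fit = fit, converged = converged),
            class = "trained_classifier")
}

#' @export
print.trained_classifier <- function(x, ...) {
  cat(sprintf("%s classifier: test AUC %.4f%s\n", x$kind, x$auc,
              if (!x$converged) " (not converged)" else ""))
  invisible(x)
}

# deterministic per-stage seed lineage from a master seed (kept < 2^31)
derive_seed <- function(master, ...) {
  s <- as.numeric(master)
  for (k in c(...)) s <- (s * 69069 + as.numeric(k) * 104729 + 1) %% 2147483647
  as.integer(s)
}

#' Build one simulated study population
#'
#' One replicate of the generation pipeline: calibrate and sample a fresh
#' synthetic core, prefilter by model status, rectangle-shuffle expand Case
#' and Control sets to `size` times the core group sizes, and bundle them
#' as a labelled population.
#'
#' @param model disease model defining the status oracle.
#' @param profile a [core_profile()].
#' @param size population size as a multiple of the core sizes (1 = 100%,
#'   i.e. 3004 Case + 1949 Control at the default profile).
#' @param seed integer seed for the whole replicate.
#' @return a [labeled_population()]; `meta` records seed and size.
#' @export
simulate_population <- function(model, profile = core_profile(), size = 1,
                                seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  core <- generate_core(profile)
  n_case <- round(size * profile$n_case)
  n_ctrl <- round(size * profile$n_control)
  cases <- expand_population(core$case, model, "Case", n_case)
  ctrls <- expand_population(core$control, model, "Control", n_ctrl)
  labeled_population(rbind(cases$genotypes, ctrls$genotypes),
                     rep(c("Case", "Control"), c(n_case, n_ctrl)),
                     meta = list(model = model$variant, size = size,
                                 seed = if (is.null(seed)) NA else seed,
                                 case_report = cases$report,
                                 control_report = ctrls$report))
}

#' Run a replicated prediction experiment
#'
#' Drives one Results-style experiment: for each replicate and each
#' population size, generate a fresh population ([simulate_population()]),
#' optionally perturb it, split it, train each classifier and record the
#' test AUC.  Every stage seed derives deterministically from `seed`, so
#' results are reproducible end to end.
#'
#' @param model disease model.
#' @param profile a [core_profile()].
#' @param sizes numeric vector of population sizes (multiples of the core).
#' @param classifiers character vector or list of [classifier_spec()]s.
#' @param replicates replicate count per condition.
#' @param perturbation optional list describing a perturbation:
#'   `list(kind = "drop_features"|"add_features"|"mislabel_cases",
#'   fraction = x)`.  Feature perturbations apply to the whole feature
#'   view before splitting; mislabelling applies to the training partition
#'   only.
#' @param train_fraction holdout split (default 2/3 train).
#' @param seed master seed.
#' @param keep_fits keep trained classifier objects (needed for
#'   [extract_weights()] downstream).
#' @return an `experiment_result`: list with `results` (data frame of one
#'   row per replicate x size x classifier) and `fits` (when kept).
#' @export
run_experiment <- function(model, profile = core_profile(), sizes = 1,
                           classifiers = "NN", replicates = 20,
                           perturbation = NULL, train_fraction = 2 / 3,
                           seed = 1, keep_fits = FALSE) {
  if (!is.list(classifiers)) classifiers <- as.list(classifiers)
  rows <- list()
  fits <- list()
  for (size in sizes) {
    for (rep_i in seq_len(replicates)) {
      rseed <- derive_seed(seed, round(100 * size), rep_i)
      pop <- simulate_population(model, profile, size, seed = rseed)
      if (!is.null(perturbation) &&
          perturbation$kind %in% c("drop_features", "add_features"))
        pop <- do.call(perturbation$kind,
                       list(pop, perturbation$fraction,
                            seed = derive_seed(rseed, 1L)))
      parts <- split_population(pop, train_fraction,
                                seed = derive_seed(rseed, 2L))
      if (!is.null(perturbation) && perturbation$kind == "mislabel_cases")
        parts$train <- mislabel_cases(parts$train, perturbation$fraction,
                                      seed = derive_seed(rseed, 3L))
      for (cs in classifiers) {
        if (is.character(cs)) cs <- classifier_spec(cs)
        tc <- train_and_score(parts$train, parts$test, cs,
                              seed = derive_seed(rseed, 4L))
        rows[[length(rows) + 1L]] <-
          data.frame(size = size, classifier = cs$kind, replicate = rep_i,
                     seed = rseed, auc = tc$auc, converged = tc$converged)
        if (keep_fits)
          fits[[length(fits) + 1L]] <-
            list(size = size, classifier = cs$kind, replicate = rep_i,
                 fit = tc, population = pop)
      }
    }
  }
  structure(list(results = do.call(rbind, rows), fits = fits,
                 model = model, seed = seed),
            class = "experiment_result")
}

#' @export
print.experiment_result <- function(x, ...) {
  cat("Replicated prediction experiment (master seed ", x$seed, "):\n", sep = "")
  print(summary(x), row.names = FALSE)
  invisible(x)
}

#' @export
summary.experiment_result <- function(object, ...) {
  res <- object$results
  agg <- stats::aggregate(auc ~ size + classifier, res, function(a)
    c(mean = mean(a), se = stats::sd(a) / sqrt(length(a)), n = length(a)))
  out <- data.frame(size = agg$size, classifier = agg$classifier,
                    mean_auc = agg$auc[, "mean"], se = agg$auc[, "se"],
                    replicates = agg$auc[, "n"])
  out[order(out$classifier, out$size), ]
}

#' One-tailed Welch comparison of two AUC samples
#'
#' Tests whether condition `a` outperforms condition `b`:
#' one-tailed two-sample t-test (Welch, unequal variances) of
#' `mean(a) > mean(b)` on the per-replicate AUCs.  With zero variance in
#' both samples and equal means the p-value is reported as 0.5.
#'
#' @param a,b numeric AUC vectors or `experiment_result`s holding a single
#'   condition.
#' @return the one-tailed p-value.
#' @export
compare_models <- function(a, b) {
  as_auc <- function(x) {
    if (inherits(x, "experiment_result")) x$results$auc else as.numeric(x)
  }
  a <- as_auc(a); b <- as_auc(b)
  if (length(a) < 2 || length(b) < 2)
    stop("at least 2 replicates per sample required", call. = FALSE)
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) return(0.5)
    return(if (mean(a) > mean(b)) 0 else 1)
  }
  stats::t.test(a, b, alternative = "greater", var.equal = FALSE)$p.value
}
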