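#' Extract input-to-hidden weights from a trained neural network
#'
#' Tabulates the first-layer weights of the fitted single-hidden-layer
#' network: one row per input locus, one column per hidden unit (biases are
#' dropped).  When a disease model is supplied each row is annotated with
#' the pathway(s) its locus belongs to; loci outside every pathway (e.g.
#' surplus alleles) are annotated `"none"`, loci shared between overlapping
#' pathways carry both labels.
#'
#' @param fit a `trained_classifier` of kind `"NN"` (or a raw
#'   [nnet::nnet()] object).
#' @param model optional disease model used for the annotation.
#' @return a `weight_table`: L x H numeric matrix with row names = locus
#'   names and attribute `pathways` (list of character vectors per locus).
#' @export
extract_weights <- function(fit, model = NULL) {
  if (inherits(fit, "trained_classifier")) {
    if (fit$kind != "NN")
      stop("first-layer weights are only defined for the NN classifier",
           call. = FALSE)
    fit <- fit$fit
  }
  if (!inherits(fit, "nnet"))
    stop("not a fitted single-hidden-layer network", call. = FALSE)
  L <- fit$n[1]; H <- fit$n[2]
  W <- matrix(NA_real_, L, H)
  for (h in seq_len(H)) {
    # nnet stores, per hidden unit, a bias followed by the L input weights
    block <- fit$wts[((h - 1) * (L + 1) + 1):(h * (L + 1))]
    W[, h] <- block[-1]
  }
  rownames(W) <- if (!is.null(fit$coefnames)) fit$coefnames else paste0("L", seq_len(L))
  colnames(W) <- paste0("H", seq_len(H))
  attr(W, "pathways") <- if (is.null(model)) NULL else pathway_labels(model, L)
  class(W) <- c("weight_table", class(W))
  W
}

#' Pathway membership labels for each locus
#'
#' @param model a disease model.
#' @param L total number of loci in the feature view (loci beyond the
#'   model's reach are labelled `"none"`).
#' @return list of length L; each element a character vector of pathway
#'   ids (subtype pathways are prefixed `s1.`/`s2.`).
#' @export
pathway_labels <- function(model, L = model$L) {
  lab <- rep(list("none"), L)
  add <- function(lab, pathways, prefix = "") {
    for (i in seq_along(pathways))
      for (j in pathways[[i]]) {
        lab[[j]] <- setdiff(c(lab[[j]], paste0(prefix, "P", i)), "none")
      }
    lab
  }
  if (model$variant == "subtype") {
    lab <- add(lab, model$sub1$pathways, "s1.")
    lab <- add(lab, model$sub2$pathways, "s2.")
  } else {
    lab <- add(lab, model$pathways)
  }
  lab
}

# Exact (dense) t-SNE, adequate for a few dozen points: conditional
# Gaussians tuned to the target perplexity by bisection, symmetrised
# affinities, gradient descent with momentum and early exaggeration.
tsne_exact <- function(X, perplexity = 8, max_iter = 500, eta = 100,
                       seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(X)
  if (n - 1 < 3 * perplexity)
    stop("perplexity too large: need n > 3 * perplexity", call. = FALSE)
  D2 <- as.matrix(stats::dist(X))^2
  if (all(D2 == 0))
    warning("all rows identical; embedding is degenerate", call. = FALSE)
  P <- matrix(0, n, n)
  logU <- log(perplexity)
  for (i in seq_len(n)) {
    di <- D2[i, -i]
    lo <- 0; hi <- Inf; beta <- 1
    for (iter in 1:64) {
      p <- exp(-di * beta)
      sp <- sum(p)
      if (sp == 0) { H <- 0; p[] <- 1 / length(p) }
      else {
        p <- p / sp
        H <- -sum(p[p > 0] * log(p[p > 0]))
      }
      if (abs(H - logU) < 1e-5) break
      if (H > logU) { lo <- beta; beta <- if (is.finite(hi)) (lo + hi) / 2 else beta * 2 }
      else { hi <- beta; beta <- (lo + hi) / 2 }
    }
    P[i, -i] <- p
  }
  P <- (P + t(P)) / (2 * n)
  P <- pmax(P, 1e-12)
  Y <- matrix(stats::rnorm(n * 2, sd = 1e-4), n, 2)
  G <- matrix(0, n, 2)
  gains <- matrix(1, n, 2)
  for (iter in seq_len(max_iter)) {
    ex <- if (iter <= 100) 4 else 1
    mom <- if (iter <= 250) 0.5 else 0.8
    d2 <- as.matrix(stats::dist(Y))^2
    num <- 1 / (1 + d2); diag(num) <- 0
    Q <- pmax(num / sum(num), 1e-12)
    W <- (ex * P - Q) * num
    grad <- 4 * (diag(rowSums(W)) - W) %*% Y
    gains <- ifelse(sign(grad) != sign(G), gains + 0.2, gains * 0.8)
    gains[gains < 0.01] <- 0.01
    G <- mom * G - eta * gains * grad
    Y <- Y + G
    Y <- sweep(Y, 2, colMeans(Y))
  }
  Y
}

#' Embed a weight table in two dimensions
#'
#' Runs t-SNE on the rows of the input-to-hidden weight table so that each
#' locus becomes a point in the plane; loci the network treats alike land
#' close together, which is what makes the generating pathway structure
#' visible.  Deterministic under a fixed seed.
#'
#' @param table a `weight_table` from [extract_weights()] (any numeric
#'   matrix works).
#' @param perplexity t-SNE perplexity; default 8, suited to ~48 loci.
#' @param seed optional integer seed.
#' @param max_iter gradient-descent iterations.
#' @return an `embedding2d` data frame: `locus`, `x`, `y`, `pathway`
#'   (comma-joined labels, `NA` when the table is unannotated).
#' @export
embed_weights <- function(table, perplexity = 8, seed = NULL, max_iter = 500) {
  Y <- tsne_exact(unclass(table), perplexity = perplexity, seed = seed,
                  max_iter = max_iter)
  lab <- attr(table, "pathways")
  data.frame(
    locus = if (!is.null(rownames(table))) rownames(table)
            else paste0("L", seq_len(nrow(table))),
    x = Y[, 1], y = Y[, 2],
    pathway = if (is.null(lab)) NA_character_
              else vapply(lab, paste, "", collapse = ","),
    stringsAsFactors = FALSE) -> out
  class(out) <- c("embedding2d", class(out))
  out
}

#' @export
plot.embedding2d <- function(x, ...) {
  grp <- factor(x$pathway)
  graphics::plot(x$x, x$y, col = as.integer(grp), pch = 19,
                 xlab = "t-SNE 1", ylab = "t-SNE 2", ...)
  graphics::legend("topright", legend = levels(grp),
                   col = seq_len(nlevels(grp)), pch = 19, cex = 0.7)
  invisible(x)
}

#' Pathway purity of a weight table or embedding
#'
#' Quantifies how well the network's first-layer representation recovers
#' the generating pathway structure: for each locus, the fraction of its k
#' nearest neighbours (Euclidean, in weight space or in the 2-D embedding)
#' that share at least one pathway label; the mean over loci is returned.
#' Chance level is about 1/P for P equally sized pathways.
#'
#' @param x a `weight_table`, an `embedding2d`, or a numeric matrix.
#' @param labels list of character label vectors per row; defaults to the
#'   annotation carried by `x`.
#' @param k neighbourhood size.
#' @return purity in \[0, 1\].
#' @export
pathway_purity <- function(x, labels = NULL, k = 5) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  if (inherits(x, "embedding2d")) {
    if (is.null(labels))
      labels <- strsplit(x$pathway, ",", fixed = TRUE)
    x <- cbind(x$x, x$y)
  } else {
    if (is.null(labels)) labels <- attr(x, "pathways")
    x <- unclass(x)
  }
  if (is.null(labels)) stop("no pathway labels available", call. = FALSE)
  n <- nrow(x)
  if (k >= n) stop("k must be smaller than the number of loci", call. = FALSE)
  D <- as.matrix(stats::dist(x))
  diag(D) <- Inf
  mean(vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]
    mean(vapply(nb, function(j) length(intersect(labels[[i]], labels[[j]])) > 0,
                logical(1)))
  }, numeric(1)))
}
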