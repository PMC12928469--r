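#' Data-degradation procedures
#'
#' Three perturbations emulate imperfect real-world inputs while the true
#' disease status (fixed by the full genotype) stays put:
#'
#' * `drop_features()` removes a random subset of the predictive alleles
#'   from the feature view ("missing risk alleles").
#' * `add_features()` appends irrelevant alleles with doses drawn from the
#'   pooled empirical 0/1/2 distribution of the original matrix, independent
#'   of the labels ("surplus alleles").
#' * `mislabel_cases()` flips a fixed share of training-set Case labels to
#'   Control (the false-negative direction; the reverse direction is
#'   available via `direction = "control_to_case"` but is not part of the
#'   replicated study).
#'
#' Column counts use `floor(fraction * L)`; individual counts use
#' round-half-up.  All three are deterministic under a fixed seed.
#'
#' @param pop a [labeled_population()].
#' @param fraction perturbation intensity in \[0, 1\].
#' @param seed optional integer seed.
#' @return a perturbed [labeled_population()] (or label factor for
#'   `mislabel_cases()` on a bare factor).
#' @name perturbations
NULL

#' @rdname perturbations
#' @export
drop_features <- function(pop, fraction, seed = NULL) {
  stopifnot(inherits(pop, "labeled_population"), fraction >= 0, fraction < 1)
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(pop$genotypes)
  k <- floor(fraction * L)
  if (k == 0) return(pop)
  if (k >= L) stop("drop_features would leave zero columns", call. = FALSE)
  drop <- sort(sample.int(L, k))
  out <- pop
  out$genotypes <- pop$genotypes[, -drop, drop = FALSE]
  out$meta$dropped_loci <- colnames(pop$genotypes)[drop]
  out
}

#' @rdname perturbations
#' @export
add_features <- function(pop, fraction, seed = NULL) {
  stopifnot(inherits(pop, "labeled_population"), fraction >= 0)
  if (!is.null(seed)) set.seed(seed)
  L <- ncol(pop$genotypes)
  k <- floor(fraction * L)
  if (k == 0) return(pop)
  n <- nrow(pop$genotypes)
  freq <- tabulate(pop$genotypes + 1L, 3L) / length(pop$genotypes)
  extra <- matrix(sample(0:2, n * k, replace = TRUE, prob = freq), n, k)
  colnames(extra) <- paste0("X", seq_len(k))
  out <- pop
  out$genotypes <- cbind(pop$genotypes, extra)
  out$meta$surplus_loci <- colnames(extra)
  out
}

#' @rdname perturbations
#' @param labels a training-partition [labeled_population()] or a bare
#'   label factor.
#' @param direction which flip direction to apply; only Case-to-Control is
#'   part of the study design.
#' @export
mislabel_cases <- function(labels, fraction, seed = NULL,
                           direction = c("case_to_control", "control_to_case")) {
  direction <- match.arg(direction)
  stopifnot(fraction >= 0, fraction <= 1)
  pop <- NULL
  if (inherits(labels, "labeled_population")) {
    if (identical(labels$meta$partition, "test"))
      stop("mislabelling applies to the training partition only", call. = FALSE)
    pop <- labels
    labels <- pop$labels
  }
  labels <- as_status(labels)
  if (!is.null(seed)) set.seed(seed)
  from <- if (direction == "case_to_control") "Case" else "Control"
  to <- setdiff(c("Case", "Control"), from)
  idx <- which(labels == from)
  k <- floor(fraction * length(idx) + 0.5)  # round half up
  if (k > 0) labels[idx[sample.int(length(idx), k)]] <- to
  if (is.null(pop)) return(labels)
  pop$labels <- labels
  pop$meta$mislabeled <- k
  pop
}
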