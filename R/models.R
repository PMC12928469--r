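#' Pathway-threshold disease models
#'
#' A disease model maps a genotype (risk-allele doses 0/1/2 at L loci) to a
#' binary Case/Control status through two thresholds.  Loci are grouped into
#' P pathways of R loci each.  The burden of pathway i is the (optionally
#' weighted) sum of the doses of its loci; the pathway "malfunctions" when
#' its burden strictly exceeds the pathway threshold `Mg`.  An individual is
#' a Case when the (optionally weighted) count of malfunctioning pathways
#' strictly exceeds the individual threshold `Mp`.  Both inequalities are
#' strict.  Four variants are provided:
#'
#' * `simple_model()`: disjoint pathways, unit weights.
#' * `weighted_model()`: disjoint pathways; per-locus weights (high/low risk
#'   alleles) and per-pathway weights (central/peripheral pathways).
#' * `overlap_model()`: unit weights, but pathways come in pairs that share
#'   two loci; a shared dose counts in both pathway burdens.
#' * `subtype_model()`: the union of two locus-disjoint simple models; Case
#'   if either sub-model fires (two genetic aetiologies, one phenotype).
#'
#' Pathways default to consecutive blocks of loci but any assignment can be
#' supplied as a list of locus-index vectors (1-based).
#'
#' @param P number of pathways.
#' @param R loci per pathway.
#' @param Mg pathway burden threshold (malfunction iff burden > Mg).
#' @param Mp individual threshold (Case iff malfunction score > Mp).
#' @param pathways optional list of P integer vectors of locus indices.
#' @param offset first locus index minus one, for block assignments placed
#'   away from locus 1 (used by subtype sub-models).
#' @return an object of class `c("<variant>_model", "disease_model")`.
#' @examples
#' m <- simple_model(P = 2, R = 3, Mg = 2, Mp = 1)
#' classify(m, c(2, 1, 0, 2, 1, 0))
#' @name disease_models
NULL

new_disease_model <- function(variant, assignment, Mg, Mp,
                              locus_weights = NULL, pathway_weights = NULL) {
  assignment <- lapply(assignment, function(ix) as.integer(ix))
  P <- length(assignment)
  L <- max(unlist(assignment))
  for (ix in assignment)
    if (anyDuplicated(ix) || any(ix < 1L))
      stop("pathway locus indices must be distinct positive integers",
           call. = FALSE)
  m <- structure(
    list(variant = variant, pathways = assignment, P = P,
         R = length(assignment[[1]]), L = L, Mg = Mg, Mp = Mp,
         locus_weights = locus_weights, pathway_weights = pathway_weights),
    class = c(paste0(variant, "_model"), "disease_model"))
  m
}

block_assignment <- function(P, R, offset = 0L)
  lapply(seq_len(P), function(i) offset + ((i - 1L) * R + 1L):(i * R))

#' @rdname disease_models
#' @export
simple_model <- function(P = 8, R = 6, Mg = 4, Mp = 6, pathways = NULL,
                         offset = 0L) {
  if (is.null(pathways)) pathways <- block_assignment(P, R, offset)
  check_disjoint(pathways)
  if (Mg < 0 || Mg >= 2 * R)
    stop("Mg must satisfy 0 <= Mg < 2R (otherwise no or every pathway can malfunction)",
         call. = FALSE)
  if (Mp < 0 || Mp >= P)
    stop("Mp must satisfy 0 <= Mp < P (otherwise nobody can be Case)",
         call. = FALSE)
  new_disease_model("simple", pathways, Mg, Mp)
}

#' @rdname disease_models
#' @param n_high high-risk loci per pathway (listed first within a pathway).
#' @param n_central central pathways (listed first).
#' @param w_high,w_low,w_central,w_peripheral weights for high/low-risk loci
#'   and central/peripheral pathways.  The defaults are the study
#'   parameterisation: 2 high-risk (w = 5) + 4 low-risk (w = 2.5) loci per
#'   pathway, 3 central (w = 5) + 5 peripheral (w = 2.2) pathways,
#'   Mg = 20, Mp = 11.
#' @param locus_weights,pathway_weights explicit weight vectors (length L
#'   and P) overriding the high/low and central/peripheral construction.
#' @export
weighted_model <- function(P = 8, R = 6, Mg = 20, Mp = 11, pathways = NULL,
                           n_high = 2, n_central = 3,
                           w_high = 5, w_low = 2.5,
                           w_central = 5, w_peripheral = 2.2,
                           locus_weights = NULL, pathway_weights = NULL) {
  if (is.null(pathways)) pathways <- block_assignment(P, R)
  check_disjoint(pathways)
  L <- max(unlist(pathways))
  if (is.null(locus_weights)) {
    locus_weights <- rep(1, L)
    for (ix in pathways)
      locus_weights[ix] <- c(rep(w_high, n_high), rep(w_low, length(ix) - n_high))
  }
  if (is.null(pathway_weights))
    pathway_weights <- c(rep(w_central, n_central), rep(w_peripheral, P - n_central))
  if (any(locus_weights <= 0) || any(pathway_weights <= 0))
    stop("weights must be positive", call. = FALSE)
  new_disease_model("weighted", pathways, Mg, Mp,
                    locus_weights = locus_weights,
                    pathway_weights = pathway_weights)
}

#' @rdname disease_models
#' @param n_shared loci shared within each pathway pair (default 2).
#' @details The overlap assignment pairs pathways (1,2), (3,4), ...; each
#'   pair shares its `n_shared` lowest-index loci, so P = 8, R = 7 pathways
#'   with 2 shared loci per pair span exactly 8*7 - 4*2 = 48 distinct loci.
#' @export
overlap_model <- function(P = 8, R = 7, Mg = 5, Mp = 6, pathways = NULL,
                          n_shared = 2) {
  if (is.null(pathways)) {
    if (P %% 2 != 0) stop("overlap model needs an even number of pathways",
                          call. = FALSE)
    pathways <- vector("list", P)
    nxt <- 1L
    for (k in seq_len(P / 2)) {
      shared <- nxt:(nxt + n_shared - 1L); nxt <- nxt + n_shared
      ua <- nxt:(nxt + R - n_shared - 1L); nxt <- nxt + R - n_shared
      ub <- nxt:(nxt + R - n_shared - 1L); nxt <- nxt + R - n_shared
      pathways[[2L * k - 1L]] <- c(shared, ua)
      pathways[[2L * k]] <- c(shared, ub)
    }
  }
  if (Mg < 0 || Mg >= 2 * R) stop("Mg must satisfy 0 <= Mg < 2R", call. = FALSE)
  if (Mp < 0 || Mp >= P) stop("Mp must satisfy 0 <= Mp < P", call. = FALSE)
  new_disease_model("overlap", pathways, Mg, Mp)
}

#' @rdname disease_models
#' @param sub1,sub2 two [simple_model()]s over disjoint locus sets.  The
#'   default splits 48 loci into two 24-locus sub-models with P = 4, R = 6,
#'   Mg = 5, Mp = 2 each.
#' @export
subtype_model <- function(sub1 = simple_model(P = 4, R = 6, Mg = 5, Mp = 2),
                          sub2 = simple_model(P = 4, R = 6, Mg = 5, Mp = 2,
                                              offset = 24L)) {
  if (length(intersect(unlist(sub1$pathways), unlist(sub2$pathways))))
    stop("subtype sub-models must use disjoint locus sets", call. = FALSE)
  structure(list(variant = "subtype", sub1 = sub1, sub2 = sub2,
                 P = sub1$P + sub2$P, L = max(sub2$L, sub1$L)),
            class = c("subtype_model", "disease_model"))
}

check_disjoint <- function(pathways) {
  all_ix <- unlist(pathways)
  if (anyDuplicated(all_ix))
    stop("pathways must be disjoint in this model variant", call. = FALSE)
  invisible(TRUE)
}

#' @export
print.disease_model <- function(x, ...) {
  if (x$variant == "subtype") {
    cat("Subtype disease model (Case if either sub-model fires):\n sub1: ")
    print(x$sub1); cat(" sub2: "); print(x$sub2)
    return(invisible(x))
  }
  cat(sprintf("%s disease model: P=%d pathways x R=%d loci (L=%d), Mg=%g, Mp=%g\n",
              tools::toTitleCase(x$variant), x$P, x$R, x$L, x$Mg, x$Mp))
  invisible(x)
}

#' Pathway burden of a genotype
#'
#' Sum of (optionally weighted) risk-allele doses over a set of loci:
#' `sum(w[j] * g[j])` with unit weights when `locus_weights` is `NULL`.
#'
#' @param g genotype vector, or matrix (one burden per row).
#' @param loci integer vector of locus indices (1-based).
#' @param locus_weights optional per-locus weights, indexed like `g`.
#' @return a non-negative numeric scalar (or vector for matrix input).
#' @export
pathway_burden <- function(g, loci, locus_weights = NULL) {
  if (is.matrix(g)) {
    if (any(loci < 1L) || any(loci > ncol(g)))
      stop("locus index out of range", call. = FALSE)
    w <- if (is.null(locus_weights)) rep(1, length(loci)) else locus_weights[loci]
    return(drop(g[, loci, drop = FALSE] %*% w))
  }
  if (any(loci < 1L) || any(loci > length(g)))
    stop("locus index out of range", call. = FALSE)
  w <- if (is.null(locus_weights)) rep(1, length(loci)) else locus_weights[loci]
  sum(w * g[loci])
}

# L x P incidence matrix of locus weights; shared (overlap) loci appear in
# both columns so their dose is counted in both pathway burdens.
incidence_matrix <- function(model, L) {
  W <- matrix(0, nrow = L, ncol = model$P)
  for (i in seq_len(model$P)) {
    ix <- model$pathways[[i]]
    w <- if (is.null(model$locus_weights)) 1 else model$locus_weights[ix]
    W[ix, i] <- w
  }
  W
}

#' Classify genotypes under a disease model
#'
#' The deterministic Case/Control oracle.  A pathway malfunctions iff its
#' burden strictly exceeds `Mg`; the individual is Case iff the (weighted)
#' number of malfunctioning pathways strictly exceeds `Mp`.  A subtype model
#' labels Case iff either sub-model does.
#'
#' @param model a [disease_models] object.
#' @param g genotype vector or genotype matrix (individuals in rows).
#' @return factor with levels `Control`, `Case` (length = rows of `g`).
#' @export
classify <- function(model, g) UseMethod("classify")

#' @export
classify.disease_model <- function(model, g) {
  g <- if (is.matrix(g)) g else matrix(g, nrow = 1)
  if (model$L > ncol(g))
    stop("model indexes locus ", model$L, " but genotype has only ",
         ncol(g), " loci", call. = FALSE)
  W <- incidence_matrix(model, ncol(g))
  malf <- (g %*% W) > model$Mg
  pw <- if (is.null(model$pathway_weights)) rep(1, model$P) else model$pathway_weights
  pe <- drop(malf %*% pw)
  factor(ifelse(pe > model$Mp, "Case", "Control"),
         levels = c("Control", "Case"))
}

#' @export
classify.subtype_model <- function(model, g) {
  s1 <- classify(model$sub1, g)
  s2 <- classify(model$sub2, g)
  factor(ifelse(s1 == "Case" | s2 == "Case", "Case", "Control"),
         levels = c("Control", "Case"))
}

#' In-model disease prevalence
#'
#' Fraction of a genotype matrix (conventionally the core Case set)
#' classified Case by the model; the study's proxy for disease rarity.
#'
#' @param model a disease model.
#' @param g genotype matrix.
#' @return a number in \[0, 1\].
#' @export
prevalence <- function(model, g) {
  if (!is.matrix(g) || nrow(g) == 0)
    stop("prevalence needs a non-empty genotype matrix", call. = FALSE)
  mean(classify(model, g) == "Case")
}

#' Serialize disease models to YAML configs
#'
#' Writes/reads the variant, thresholds, explicit 1-based pathway locus
#' lists and any weight vectors.  Round-trip is lossless.
#'
#' @param model a disease model.
#' @param path file path of the YAML config.
#' @export
write_model_config <- function(model, path) {
  yaml::write_yaml(model_to_list(model), path)
  invisible(path)
}

model_to_list <- function(model) {
  if (model$variant == "subtype")
    return(list(variant = "subtype",
                sub1 = model_to_list(model$sub1),
                sub2 = model_to_list(model$sub2)))
  out <- list(variant = model$variant, P = model$P, R = model$R,
              Mg = model$Mg, Mp = model$Mp, indexing = "1-based",
              pathways = lapply(model$pathways, as.integer))
  if (!is.null(model$locus_weights)) out$locus_weights <- model$locus_weights
  if (!is.null(model$pathway_weights)) out$pathway_weights <- model$pathway_weights
  out
}

#' @rdname write_model_config
#' @export
read_model_config <- function(path) {
  model_from_list(yaml::read_yaml(path))
}

model_from_list <- function(cfg) {
  if (is.null(cfg$variant))
    stop("model config: missing field 'variant'", call. = FALSE)
  if (cfg$variant == "subtype")
    return(subtype_model(model_from_list(cfg$sub1), model_from_list(cfg$sub2)))
  pathways <- lapply(cfg$pathways, as.integer)
  switch(cfg$variant,
    simple = simple_model(P = cfg$P, R = cfg$R, Mg = cfg$Mg, Mp = cfg$Mp,
                          pathways = pathways),
    overlap = overlap_model(P = cfg$P, R = cfg$R, Mg = cfg$Mg, Mp = cfg$Mp,
                            pathways = pathways),
    weighted = weighted_model(P = cfg$P, R = cfg$R, Mg = cfg$Mg, Mp = cfg$Mp,
                              pathways = pathways,
                              locus_weights = cfg$locus_weights,
                              pathway_weights = cfg$pathway_weights),
    stop("model config: unknown variant '", cfg$variant, "'", call. = FALSE))
}
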