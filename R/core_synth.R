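#' Core-data profile
#'
#' Describes the statistical profile the synthetic "core" genotype matrices
#' must reproduce: 48 loci, 3004 Case and 1949 Control individuals, and a
#' small case/control difference in mean risk-allele load (46.5 vs 43.5,
#' about 7%).  Per-locus risk-allele frequencies are heterogeneous;
#' `frequency_dispersion` is their standard deviation before the exact
#' rescaling to the load target.
#'
#' @param L number of loci.
#' @param n_case,n_control group sizes.
#' @param case_load,control_load target mean per-individual risk-allele
#'   loads (sum of doses over the L loci).
#' @param frequency_dispersion standard deviation of the per-locus
#'   frequencies around their mean; must leave all frequencies in (0, 1).
#' @return an object of class `core_profile`.
#' @export
core_profile <- function(L = 48, n_case = 3004, n_control = 1949,
                         case_load = 46.5, control_load = 43.5,
                         frequency_dispersion = 0.15) {
  stopifnot(L >= 1, n_case > 0, n_control > 0,
            case_load > 0, case_load < 2 * L,
            control_load > 0, control_load < 2 * L,
            frequency_dispersion >= 0)
  structure(list(L = L, n_case = n_case, n_control = n_control,
                 case_load = case_load, control_load = control_load,
                 frequency_dispersion = frequency_dispersion),
            class = "core_profile")
}

#' Calibrate per-locus risk-allele frequencies to a load target
#'
#' Samples heterogeneous frequencies from a Beta distribution with mean
#' `target / (2L)` and standard deviation `frequency_dispersion`, then
#' rescales them multiplicatively so that the expected per-individual load
#' `sum(2 * p)` hits the group's target exactly.
#'
#' Case and control cores in real GWAS data differ by a small shift at
#' every locus, not by independent frequency patterns; calibrating both
#' groups from the same seed (or via [generate_core()], which draws the
#' heterogeneity pattern once) reproduces this: the two vectors share the
#' per-locus pattern and differ only by the ~7% load ratio.
#'
#' @param profile a [core_profile()].
#' @param group `"case"` or `"control"`.
#' @param seed optional integer seed.
#' @return numeric vector of L frequencies in (0, 1) with
#'   `sum(2 * p) == target` to numerical precision.
#' @export
calibrate_frequencies <- function(profile, group = c("case", "control"),
                                  seed = NULL) {
  group <- match.arg(group)
  if (!is.null(seed)) set.seed(seed)
  target <- if (group == "case") profile$case_load else profile$control_load
  rescale_freqs(base_frequencies(profile), target)
}

# one draw of the per-locus heterogeneity pattern (mean frequency of the
# two group targets, spread frequency_dispersion)
base_frequencies <- function(profile) {
  L <- profile$L
  m <- (profile$case_load + profile$control_load) / 2 / (2 * L)
  s <- profile$frequency_dispersion
  if (s == 0) return(rep(m, L))
  if (s^2 >= m * (1 - m))
    stop("frequency_dispersion too large for mean frequency ", signif(m, 3),
         call. = FALSE)
  nu <- m * (1 - m) / s^2 - 1
  stats::rbeta(L, m * nu, (1 - m) * nu)
}

rescale_freqs <- function(p0, target) {
  p <- p0 * target / (2 * sum(p0))
  if (any(p <= 0) || any(p >= 1))
    stop("infeasible load target: rescaled frequencies leave (0, 1)",
         call. = FALSE)
  p
}

#' Sample a core genotype matrix at given frequencies
#'
#' Each dose is the number of risk alleles in two independent Bernoulli
#' draws at that locus's frequency (Hardy-Weinberg dose sampling,
#' independent loci).
#'
#' @param freqs per-locus risk-allele frequencies in \[0, 1\].
#' @param n number of individuals.
#' @param seed optional integer seed.
#' @return an n x L genotype matrix.
#' @export
sample_core <- function(freqs, n, seed = NULL) {
  if (n <= 0) stop("n must be positive", call. = FALSE)
  if (any(freqs < 0) || any(freqs > 1))
    stop("frequencies must lie in [0, 1]", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  L <- length(freqs)
  m <- matrix(stats::rbinom(n * L, 2L, rep(freqs, each = n)), nrow = n)
  as_genotype_matrix(m)
}

#' Generate a full calibrated core population
#'
#' Convenience wrapper: draws one per-locus heterogeneity pattern, rescales
#' it to the case and control load targets (so the two groups differ by a
#' small shift at every locus, as in real case/control data) and samples
#' both matrices.
#'
#' @param profile a [core_profile()].
#' @param seed optional integer seed governing both calibration and
#'   sampling.
#' @return list with elements `case`, `control` (genotype matrices),
#'   `case_freqs`, `control_freqs`.
#' @export
generate_core <- function(profile = core_profile(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p0 <- base_frequencies(profile)
  pc <- rescale_freqs(p0, profile$case_load)
  pk <- rescale_freqs(p0, profile$control_load)
  list(case = sample_core(pc, profile$n_case),
       control = sample_core(pk, profile$n_control),
       case_freqs = pc, control_freqs = pk)
}

#' Nearest-neighbour imputation of missing doses
#'
#' Fills each missing entry with the value at that locus in the closest
#' same-class row, where closeness is Hamming distance counted over loci
#' observed in both rows.  If the closest row is also missing there, the
#' next-closest donor is used, and so on.  Ties are broken by lowest row
#' index, making the result deterministic for a fixed row order.
#' Non-missing entries are never altered.
#'
#' @param m genotype matrix possibly containing `NA`.
#' @param labels per-row `Case`/`Control` labels.
#' @return a complete genotype matrix.
#' @export
impute_missing <- function(m, labels) {
  m <- as_genotype_matrix(m, allow_missing = TRUE)
  labels <- as_status(labels)
  if (length(labels) != nrow(m))
    stop("one label per row required", call. = FALSE)
  rows <- which(rowSums(is.na(m)) > 0)
  if (!length(rows)) return(m)
  out <- m
  for (r in rows) {
    same <- setdiff(which(labels == labels[r]), r)
    if (!length(same))
      stop("no same-class donor rows for row ", r, call. = FALSE)
    obs_r <- !is.na(m[r, ])
    if (!any(obs_r))
      stop("row ", r, " has no observed entries", call. = FALSE)
    # Hamming distance over mutually observed loci, ties -> lowest index
    d <- vapply(same, function(s) {
      both <- obs_r & !is.na(m[s, ])
      if (!any(both)) return(Inf)
      sum(m[r, both] != m[s, both])
    }, numeric(1))
    donors <- same[order(d, same)]
    for (j in which(is.na(m[r, ]))) {
      v <- NA_integer_
      for (s in donors) {
        if (!is.na(m[s, j])) { v <- m[s, j]; break }
      }
      if (is.na(v))
        stop("no same-class donor carries a value at locus ", j,
             " for row ", r, call. = FALSE)
      out[r, j] <- v
    }
  }
  out
}
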