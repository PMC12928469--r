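#' Validate and coerce a genotype matrix
#'
#' Genotypes are coded as risk-allele doses: 0 (homozygous non-risk),
#' 1 (heterozygous) or 2 (homozygous risk) at each locus.  Rows are
#' individuals, columns are loci.  Missing entries (`NA`) are permitted only
#' when `allow_missing = TRUE` (pre-imputation matrices).
#'
#' @param x matrix or data frame of doses.
#' @param allow_missing logical; accept `NA` entries.
#' @return an integer matrix with column names `L1..L<L>` if none present.
#' @export
as_genotype_matrix <- function(x, allow_missing = FALSE) {
  m <- as.matrix(x)
  storage.mode(m) <- "integer"
  bad <- !(m %in% c(0L, 1L, 2L) | (allow_missing & is.na(m)))
  if (any(bad))
    stop("genotype entries must be 0, 1 or 2",
         if (allow_missing) " (or NA)", call. = FALSE)
  if (is.null(colnames(m)))
    colnames(m) <- paste0("L", seq_len(ncol(m)))
  m
}

#' Labelled case/control population
#'
#' Bundles a genotype matrix with per-row disease status and provenance
#' metadata (generating model, seeds, size descriptor).  The feature view
#' (`genotypes`) may diverge from the genotypes that determined the labels
#' once perturbations ([drop_features()], [add_features()]) are applied;
#' labels are always those fixed by the full original genotype.
#'
#' @param genotypes genotype matrix (see [as_genotype_matrix()]).
#' @param labels factor or character vector of "Case"/"Control", one per row.
#' @param meta named list of provenance fields (free-form).
#' @return an object of class `labeled_population`.
#' @export
labeled_population <- function(genotypes, labels, meta = list()) {
  genotypes <- as_genotype_matrix(genotypes)
  labels <- as_status(labels)
  if (length(labels) != nrow(genotypes))
    stop("number of labels must equal number of rows", call. = FALSE)
  structure(list(genotypes = genotypes, labels = labels, meta = meta),
            class = "labeled_population")
}

#' @export
print.labeled_population <- function(x, ...) {
  tab <- table(x$labels)
  cat(sprintf("Labelled population: %d individuals x %d loci (%d Case, %d Control)\n",
              nrow(x$genotypes), ncol(x$genotypes),
              tab[["Case"]], tab[["Control"]]))
  flat <- Filter(function(v) is.atomic(v) && length(v) == 1, x$meta)
  if (length(flat))
    cat("  meta:", paste(names(flat), unlist(lapply(flat, format)),
                         sep = "=", collapse = ", "), "\n")
  invisible(x)
}

# Coerce to the canonical Control/Case factor used throughout.
as_status <- function(x) {
  if (is.factor(x)) x <- as.character(x)
  if (!all(x %in% c("Case", "Control")))
    stop("labels must be 'Case' or 'Control'", call. = FALSE)
  factor(x, levels = c("Control", "Case"))
}

#' Read / write genotype matrices
#'
#' CSV/TSV with one header row of locus identifiers, optionally a `status`
#' column holding `Case`/`Control` labels.  A headerless dose matrix plus a
#' separate one-column label file is also accepted.  Missing values are
#' written as empty cells and read back as `NA`; they are never encoded as a
#' fourth dose value.  Locus columns are 1-based and keep their order.
#'
#' @param path file path.
#' @param sep field separator ("," or "\t"; guessed from the extension).
#' @param header logical; does the file carry a header row of locus ids?
#' @param label_file optional path of a separate label file (one label per
#'   line) used when `header = FALSE` or the file has no `status` column.
#' @return `read_genotypes()`: a [labeled_population] when labels are
#'   available, otherwise a genotype matrix.
#' @export
read_genotypes <- function(path, sep = NULL, header = TRUE, label_file = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, sep = sep, header = header,
                          stringsAsFactors = FALSE, na.strings = c("NA", ""),
                          check.names = FALSE)
  labels <- NULL
  if ("status" %in% names(df)) {
    labels <- df[["status"]]
    df <- df[setdiff(names(df), "status")]
  }
  if (!is.null(label_file))
    labels <- readLines(label_file)
  m <- as_genotype_matrix(df, allow_missing = TRUE)
  if (is.null(labels)) m else labeled_population(m, labels)
}

#' @rdname read_genotypes
#' @param x genotype matrix or [labeled_population].
#' @export
write_genotypes <- function(x, path, sep = NULL) {
  if (is.null(sep))
    sep <- if (grepl("\\.tsv$|\\.txt$", path, ignore.case = TRUE)) "\t" else ","
  if (inherits(x, "labeled_population")) {
    df <- as.data.frame(x$genotypes)
    df$status <- as.character(x$labels)
  } else {
    df <- as.data.frame(as_genotype_matrix(x, allow_missing = TRUE))
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE,
                     na = "")
  invisible(path)
}
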