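# Literal per-row evaluator of the pathway-threshold formulas, kept
# deliberately independent of the vectorised classify() implementation.
brute_classify <- function(model, g) {
  if (is.null(dim(g))) g <- matrix(g, nrow = 1)
  if (model$variant == "subtype") {
    s1 <- brute_classify(model$sub1, g)
    s2 <- brute_classify(model$sub2, g)
    return(ifelse(s1 == "Case" | s2 == "Case", "Case", "Control"))
  }
  apply(g, 1, function(row) {
    pe <- 0
    for (i in seq_along(model$pathways)) {
      loci <- model$pathways[[i]]
      re <- 0
      for (j in loci) {
        w <- if (is.null(model$locus_weights)) 1 else model$locus_weights[j]
        re <- re + w * row[j]
      }
      th <- if (re > model$Mg) 1 else 0
      pw <- if (is.null(model$pathway_weights)) 1 else model$pathway_weights[i]
      pe <- pe + pw * th
    }
    if (pe > model$Mp) "Case" else "Control"
  })
}

# every genotype over L loci, one per row
all_genotypes <- function(L) {
  as.matrix(expand.grid(rep(list(0:2), L)))
}

# AUC by direct enumeration of case/control pairs (ties count half)
brute_auc <- function(scores, labels) {
  cs <- scores[labels == "Case"]; ct <- scores[labels == "Control"]
  tot <- 0
  for (a in cs) for (b in ct)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(cs) * length(ct))
}

# small population profile for pipeline tests (48 loci kept, fewer rows)
small_profile <- function()
  core_profile(n_case = 420, n_control = 280)

random_genotypes <- function(n, L) {
  matrix(sample(0:2, n * L, replace = TRUE), n, L)
}
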