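test_that("pathway burden sums weighted doses over the listed loci", {
  expect_equal(pathway_burden(rep(0, 10), 1:5), 0)
  expect_equal(pathway_burden(c(2, 1, 0), 1:3), 3)
  # study weights: two high-risk loci (w = 5), four low-risk (w = 2.5)
  g <- c(2, 2, 0, 0, 0, 1)
  w <- c(5, 5, 2.5, 2.5, 2.5, 2.5)
  expect_equal(pathway_burden(g, 1:6, w), 2 * 5 + 2 * 5 + 1 * 2.5)
  expect_error(pathway_burden(c(0, 1), c(1, 3)), "out of range")
  # matrix input gives one burden per row
  m <- rbind(c(2, 1, 0), c(0, 0, 1))
  expect_equal(pathway_burden(m, 1:3), c(3, 1))
})

test_that("classify applies the strict double-threshold rule", {
  m <- simple_model(P = 2, R = 3, Mg = 2, Mp = 1)
  expect_equal(as.character(classify(m, rep(0, 6))), "Control")
  # both pathways at burden 3 > 2, so Pe = 2 > 1
  expect_equal(as.character(classify(m, c(2, 1, 0, 2, 1, 0))), "Case")
  # one pathway short of its threshold
  expect_equal(as.character(classify(m, c(2, 0, 0, 2, 1, 0))), "Control")
  # burden == Mg must NOT malfunction (strict inequality)
  expect_equal(as.character(classify(m, c(1, 1, 0, 2, 1, 0))), "Control")
})

test_that("weighted model reproduces the central/peripheral arithmetic", {
  wm <- weighted_model()
  # pathway burden > 20 requires both high-risk loci plus a low-risk dose
  g <- rep(0, 48)
  malf <- function(path) { ix <- wm$pathways[[path]]; g[ix[1:3]] <<- 2 }
  malf(1); malf(2)              # two central pathways: Pe = 10, not > 11
  expect_equal(as.character(classify(wm, g)), "Control")
  malf(4)                       # plus one peripheral: Pe = 12.2 > 11
  expect_equal(as.character(classify(wm, g)), "Case")
})

test_that("classify matches the literal brute-force evaluator exhaustively", {
  g6 <- all_genotypes(6)
  m <- simple_model(P = 2, R = 3, Mg = 2, Mp = 1)
  fast <- as.character(classify(m, g6))
  slow <- brute_classify(m, g6)
  expect_identical(fast, slow)
  expect_equal(sum(fast == "Case"), 289)   # frozen enumeration count

  # overlap: two pathways of 3 loci sharing their 2 lowest-index loci
  ov <- overlap_model(P = 2, R = 3, Mg = 3, Mp = 0, n_shared = 2)
  g4 <- all_genotypes(4)
  expect_identical(as.character(classify(ov, g4)), brute_classify(ov, g4))

  # weighted small model
  wm <- weighted_model(P = 2, R = 3, Mg = 4, Mp = 2,
                       n_high = 1, n_central = 1,
                       w_high = 3, w_low = 1, w_central = 2, w_peripheral = 1)
  expect_identical(as.character(classify(wm, g6)), brute_classify(wm, g6))

  # subtype: union of two disjoint 4-locus simple models
  st <- subtype_model(simple_model(P = 2, R = 2, Mg = 1, Mp = 0),
                      simple_model(P = 2, R = 2, Mg = 2, Mp = 0, offset = 4L))
  g8 <- all_genotypes(8)
  expect_identical(as.character(classify(st, g8)), brute_classify(st, g8))
})

test_that("subtype status is the union of its sub-model statuses", {
  st <- subtype_model()
  g <- random_genotypes(200, 48)
  s <- classify(st, g)
  s1 <- classify(st$sub1, g); s2 <- classify(st$sub2, g)
  expect_identical(s == "Case", s1 == "Case" | s2 == "Case")
})

test_that("shared overlap loci count in both pathway burdens", {
  ov <- overlap_model(P = 2, R = 3, Mg = 3, Mp = 0, n_shared = 2)
  g <- c(2, 2, 0, 0)   # loci 1,2 shared between the two pathways
  expect_equal(pathway_burden(g, ov$pathways[[1]]), 4)
  expect_equal(pathway_burden(g, ov$pathways[[2]]), 4)
  expect_equal(as.character(classify(ov, g)), "Case")
})

test_that("raising any single dose never flips Case to Control", {
  set.seed(41)
  models <- list(simple_model(P = 2, R = 3, Mg = 2, Mp = 1),
                 overlap_model(P = 2, R = 3, Mg = 3, Mp = 0, n_shared = 2),
                 weighted_model(P = 2, R = 3, Mg = 4, Mp = 2, n_high = 1,
                                n_central = 1, w_high = 3, w_low = 1,
                                w_central = 2, w_peripheral = 1),
                 subtype_model(simple_model(P = 2, R = 2, Mg = 1, Mp = 0),
                               simple_model(P = 2, R = 2, Mg = 2, Mp = 0,
                                            offset = 4L)))
  for (m in models) {
    g <- random_genotypes(60, m$L)
    before <- classify(m, g)
    for (k in 1:60) {
      j <- sample.int(m$L, 1)
      g2 <- g[k, ]
      if (g2[j] == 2) next
      g2[j] <- g2[j] + 1L
      after <- classify(m, g2)
      if (before[k] == "Case") expect_equal(as.character(after), "Case")
    }
    # determinism: a pure function of the genotype
    expect_identical(classify(m, g), before)
  }
})

test_that("prevalence is the Case fraction with guarded inputs", {
  m <- simple_model(P = 2, R = 3, Mg = 2, Mp = 1)
  all2 <- matrix(2L, 10, 6)
  expect_equal(prevalence(m, all2), 1)
  expect_equal(prevalence(m, matrix(0L, 5, 6)), 0)
  expect_error(prevalence(m, matrix(integer(0), 0, 6)), "non-empty")
})

test_that("model constructors enforce the threshold and disjointness invariants", {
  expect_error(simple_model(P = 2, R = 3, Mg = 6, Mp = 1), "Mg")
  expect_error(simple_model(P = 2, R = 3, Mg = 2, Mp = 2), "Mp")
  expect_error(simple_model(P = 2, R = 2, pathways = list(1:2, 2:3), Mg = 1, Mp = 0),
               "disjoint")
  expect_error(subtype_model(simple_model(P = 2, R = 2, Mg = 1, Mp = 0),
                             simple_model(P = 2, R = 2, Mg = 1, Mp = 0)),
               "disjoint")
  expect_error(weighted_model(locus_weights = rep(-1, 48)), "positive")
})

test_that("model configs round-trip losslessly through YAML", {
  models <- list(simple_model(), weighted_model(), overlap_model(),
                 subtype_model())
  g <- random_genotypes(50, 48)
  for (m in models) {
    path <- withr::local_tempfile(fileext = ".yaml")
    write_model_config(m, path)
    m2 <- read_model_config(path)
    expect_equal(m2$variant, m$variant)
    expect_identical(classify(m2, g), classify(m, g))
    if (m$variant != "subtype") {
      expect_identical(m2$pathways, m$pathways)
      expect_equal(m2$Mg, m$Mg)
      expect_equal(m2$Mp, m$Mp)
      expect_equal(m2$locus_weights, m$locus_weights)
      expect_equal(m2$pathway_weights, m$pathway_weights)
    }
  }
  expect_error(read_model_config(withr::local_tempfile(lines = "P: 3")),
               "variant")
})
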