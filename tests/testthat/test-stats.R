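# Statistical tests: hand-worked oracles, base-R cross-checks (independent
# route), and the degenerate-input contracts.

test_that("pairedT matches the hand-worked example and t.test", {
  pre <- c(1, 2, 3); post <- c(2, 4, 3)
  # d = (1, 2, 0): mean 1, sd 1, t = 1/(1/sqrt(3)) = sqrt(3), df = 2
  res <- pairedT(pre, post)
  expect_equal(res$statistic, sqrt(3), tolerance = 1e-12)
  expect_equal(res$df, 2)
  expect_equal(res$estimate, 1)
  expect_equal(res$p_value, 2 * stats::pt(-sqrt(3), 2), tolerance = 1e-12)
  ref <- stats::t.test(post, pre, paired = TRUE)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("welchT matches the hand-worked example and t.test", {
  a <- c(1, 2, 3, 4); b <- c(3, 4, 5, 6)
  res <- welchT(a, b)
  expect_equal(res$statistic, -2 / sqrt(5 / 6), tolerance = 1e-12)
  expect_equal(res$df, 6, tolerance = 1e-12)
  ref <- stats::t.test(a, b)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("pearsonTest matches the hand-worked example and cor.test", {
  x <- 1:5; y <- c(2, 1, 4, 3, 5)
  res <- pearsonTest(x, y)
  expect_equal(res$estimate, 0.8, tolerance = 1e-12)
  expect_equal(res$statistic, 0.8 * sqrt(3 / 0.36), tolerance = 1e-12)
  expect_equal(res$df, 3)
  ref <- stats::cor.test(x, y)
  expect_equal(res$statistic, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(res$p_value, ref$p.value, tolerance = 1e-12)
})

test_that("exactly collinear input is reported, not divided by zero", {
  res <- pearsonTest(1:5, 2 * (1:5) + 3)
  expect_equal(res$estimate, 1)
  expect_equal(res$statistic, Inf)
  expect_equal(res$p_value, 0)
  expect_match(attr(res, "note"), "collinear")
})

test_that("degenerate inputs raise the documented errors", {
  expect_error(pairedT(c(1, 2, 3), c(2, 3, 4)), "zero variance")
  expect_error(pairedT(1, 2), "at least 2 pairs")
  expect_error(pairedT(c(1, 2), c(1, 2, 3)), "equal length")
  expect_error(welchT(c(1, 1), c(2, 2)), "zero variance in both")
  expect_error(welchT(1, c(1, 2)), "at least 2")
  expect_error(pearsonTest(c(1, 1, 1), c(1, 2, 3)), "zero variance")
  expect_error(pearsonTest(c(1, 2), c(1, 2)), "at least 3 pairs")
})

randomTable <- function(nA, nB, k) {
  animals <- c(sprintf("a%d", seq_len(nA)), sprintf("b%d", seq_len(nB)))
  groups <- rep(c("G1", "G2"), c(nA, nB))
  expand <- expand.grid(animal = animals, phase = sprintf("p%d", seq_len(k)),
                        stringsAsFactors = FALSE)
  expand$group <- groups[match(expand$animal, animals)]
  expand$value <- stats::rnorm(nrow(expand))
  expand
}

test_that("mixedAnova agrees with aov's split-plot decomposition", {
  set.seed(99)
  for (dims in list(c(4, 4, 3), c(4, 6, 2), c(5, 3, 4))) {
    tab <- randomTable(dims[1], dims[2], dims[3])
    res <- mixedAnova(tab)
    fit <- stats::aov(value ~ group * phase + Error(animal / phase),
                      data = transform(tab, animal = factor(animal),
                                       group = factor(group),
                                       phase = factor(phase)))
    s <- summary(fit)
    between <- s[["Error: animal"]][[1]]
    within <- s[["Error: animal:phase"]][[1]]
    getF <- function(tbl, eff) tbl[match(eff, trimws(rownames(tbl))), "F value"]
    getP <- function(tbl, eff) tbl[match(eff, trimws(rownames(tbl))), "Pr(>F)"]
    expect_equal(res$statistic[res$effect == "group"],
                 getF(between, "group"), tolerance = 1e-8)
    expect_equal(res$p_value[res$effect == "group"],
                 getP(between, "group"), tolerance = 1e-8)
    expect_equal(res$statistic[res$effect == "phase"],
                 getF(within, "phase"), tolerance = 1e-8)
    expect_equal(res$statistic[res$effect == "group:phase"],
                 getF(within, "group:phase"), tolerance = 1e-8)
    expect_equal(res$p_value[res$effect == "group:phase"],
                 getP(within, "group:phase"), tolerance = 1e-8)
  }
})

test_that("mixedAnova rejects incomplete or degenerate designs", {
  tab <- randomTable(3, 3, 2)
  expect_error(mixedAnova(tab[-1, ]), "missing a phase")
  one <- tab
  one$group <- "G1"
  expect_error(mixedAnova(one), "at least 2 groups")
  expect_error(mixedAnova(tab[, -4]), "must have columns")
})

test_that("sidakAdjust matches the closed form and caps at 1", {
  expect_equal(sidakAdjust(0.01, m = 4), 1 - 0.99^4, tolerance = 1e-12)
  expect_equal(sidakAdjust(0.01, m = 4), 0.03940399, tolerance = 1e-8)
  expect_equal(sidakAdjust(c(0.5, 0.9)), c(1 - 0.5^2, 1 - 0.1^2))
  expect_equal(sidakAdjust(0.9, m = 50), 1)
  expect_error(sidakAdjust(1.2), "\\[0, 1\\]")
  expect_error(sidakAdjust(0.5, m = 0), "m must be")
})

test_that("sidakPosthoc runs per-phase contrasts with family adjustment", {
  set.seed(11)
  tab <- randomTable(5, 5, 2)
  ph <- sidakPosthoc(tab)
  expect_equal(nrow(ph), 2)
  for (i in 1:2) {
    sub <- tab[tab$phase == ph$phase[i], ]
    ref <- welchT(sub$value[sub$group == "G1"], sub$value[sub$group == "G2"])
    expect_equal(ph$statistic[i], ref$statistic, tolerance = 1e-12)
    expect_equal(ph$p_adj[i], sidakAdjust(ref$p_value, 2), tolerance = 1e-12)
  }
  pooled <- sidakPosthoc(tab, pool = TRUE)
  sub <- tab[tab$phase == pooled$phase[1], ]
  refP <- tracephys:::pooledT(sub$value[sub$group == "G1"],
                              sub$value[sub$group == "G2"])
  expect_equal(pooled$statistic[1], refP$statistic, tolerance = 1e-12)
  three <- tab
  three$group[three$animal == "a1"] <- "G3"
  expect_error(sidakPosthoc(three), "exactly 2 groups")
})

test_that("results tables round-trip through CSV", {
  res <- pairedT(c(1, 2, 3), c(2, 4, 3))
  path <- tempfile(fileext = ".csv")
  writeResultsCsv(res, path)
  back <- utils::read.csv(path)
  expect_equal(back$statistic, res$statistic)
  expect_equal(back$method, res$method)
  unlink(path)
})
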