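test_that("period rates follow the three window definitions", {
  expect_equal(periodRates(c(10, 10, 10), c(21, 24, 30)),
               c(immediate = 0, longterm = 0, global = 0))
  expect_equal(periodRates(c(100, 110, 140), c(23, 25, 31)),
               c(immediate = 5, longterm = 5, global = 5))
  expect_equal(periodRates(c(0, 12, 12), c(20, 24, 30)),
               c(immediate = 3, longterm = 0, global = 1.2))
  # rate-difference reading of the global window, kept behind a switch
  expect_equal(unname(periodRates(c(0, 12, 12), c(20, 24, 30),
                                  global = "difference")["global"]), -3)
  expect_error(periodRates(c(1, 2, 3), c(20, 20, 25)), "increasing")
})

test_that("period rate identities hold on random triples (property)", {
  set.seed(99)
  for (case in seq_len(1000)) {
    x <- rnorm(3, 100, 40)
    ga <- sort(runif(3, 20, 36))
    if (min(diff(ga)) < 1e-3) next
    r <- periodRates(x, ga)
    expect_identical(r[["immediate"]], (x[2] - x[1]) / (ga[2] - ga[1]))
    expect_identical(r[["longterm"]], (x[3] - x[2]) / (ga[3] - ga[2]))
    expect_identical(r[["global"]], (x[3] - x[1]) / (ga[3] - ga[1]))
  }
})

test_that("gestational ages convert from weeks+days to decimal weeks", {
  expect_equal(gaWeeks(23, 3), 23 + 3 / 7)
  expect_equal(gaWeeks(31, 6), 31 + 6 / 7)
})

test_that("ventriculomegaly bands reproduce the clinical classification", {
  expect_equal(as.character(classifyVentriculomegaly(11)), "mild")
  expect_equal(as.character(classifyVentriculomegaly(14)), "moderate")
  expect_equal(as.character(classifyVentriculomegaly(16)), "severe")
  got <- as.character(classifyVentriculomegaly(9:20))
  expect_equal(got, c("none", rep("mild", 3), rep("moderate", 3),
                      rep("severe", 5)))
  # non-integer measurements are rounded half-up to the integer bands
  expect_equal(as.character(classifyVentriculomegaly(c(12.4, 12.6, 15.2,
                                                       15.7))),
               c("mild", "moderate", "moderate", "severe"))
  expect_error(classifyVentriculomegaly(-1), "non-negative")
})

test_that("parcellation reproduces atlas labels and survives transforms", {
  atlas <- atlasSurface(26)
  # the atlas itself
  p0 <- parcellateLobes(atlas, atlas)
  expect_identical(as.character(p0), as.character(vertexData(atlas)$lobe))
  # rotated 30 degrees and scaled 1.1
  th <- pi / 6
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3,
                byrow = TRUE)
  moved <- atlas
  moved@vertices <- 1.1 * vertices(atlas) %*% t(rot)
  p1 <- parcellateLobes(moved, atlas)
  expect_gte(mean(as.character(p1) == as.character(vertexData(atlas)$lobe)),
             0.98)
})

test_that("generator subjects parcellate against the atlas at >= 90%", {
  s <- generateSubject("control", cohortConfig(structures = "wm"), 2)
  mesh <- extractMesh(s$volumes[[2]], 1)
  atlas <- atlasSurface(s$meta$ga_t2)
  p <- parcellateLobes(mesh, atlas)
  expect_true(!anyNA(p))
  # truth: the generator's lobe sectors evaluated at the extracted
  # vertices' directions (the parcellation is defined in parameter space)
  dirs <- vertices(mesh) / sqrt(rowSums(vertices(mesh)^2))
  alpha <- acos(pmin(pmax(dirs[, 1], -1), 1))
  lobe <- ifelse(alpha < pi / 3, "frontal",
                 ifelse(alpha > 3 * pi / 4, "occipital",
                        ifelse(dirs[, 3] >= 0, "parietal", "temporal")))
  hemi <- ifelse(dirs[, 2] >= 0, "left", "right")
  expect_gte(mean(as.character(p) == paste(lobe, hemi, sep = "_")), 0.90)
})

test_that("parcellation is a partition of the vertices", {
  atlas <- atlasSurface(24)
  s <- generateSurface(24, axesMM = c(31, 27, 24), amplitude = 0.08,
                       phases = rep(2, 10))
  p <- parcellateLobes(s, atlas)
  expect_identical(sum(table(p)), nVertices(s))
})

test_that("curvature summaries take signed medians per region", {
  atlas <- atlasSurface(24)
  parc <- factor(vertexData(atlas)$lobe, levels = fetalmorpho:::.LOBE_LEVELS)
  n <- nVertices(atlas)
  cs <- curvatureSummary(rep(0.3, n), parc)
  expect_true(all(cs$median == 0.3))
  expect_identical(cs$n_vertices[cs$region == "whole"], n)
  # +1 left / -1 right
  hemi <- ifelse(grepl("left", parc), 1, -1)
  cs2 <- curvatureSummary(hemi, parc)
  expect_true(all(cs2$median[grepl("left", cs2$region)] == 1))
  expect_true(all(cs2$median[grepl("right", cs2$region)] == -1))
  expect_identical(cs2$median[cs2$region == "whole"], median(hemi))
  # programmed per-lobe offsets recovered
  off <- seq(0.1, 0.8, by = 0.1)[as.integer(parc)]
  field <- off + rnorm(n, 0, 0.01)
  cs3 <- curvatureSummary(field, parc)
  reg <- cs3[cs3$region != "whole", ]
  expect_equal(reg$median,
               seq(0.1, 0.8, by = 0.1)[match(reg$region,
                                             levels(parc))],
               tolerance = 0.1)
  # absolute-change variant
  expect_equal(curvatureSummary(c(-2, 2), absolute = TRUE)$median, 2)
})

test_that("Anderson-Darling gate detects non-normal samples", {
  reject <- nonreject <- 0
  for (s in 1:100) {
    set.seed(s)
    nonreject <- nonreject + !adNormalityTest(rnorm(200))$nonNormal
    set.seed(s)
    reject <- reject + adNormalityTest(exp(rnorm(200)))$nonNormal
  }
  expect_gte(nonreject, 90)
  expect_gte(reject, 90)
  expect_error(adNormalityTest(rnorm(5)), "n >= 8")
  expect_error(adNormalityTest(rep(1, 20)), "degenerate")
})

test_that("Kruskal-Wallis H matches a brute-force rank oracle", {
  bruteH <- function(groups) {
    x <- unlist(groups)
    r <- rank(x)
    N <- length(x)
    Rj <- split(r, rep(seq_along(groups), lengths(groups)))
    H <- 12 / (N * (N + 1)) *
      sum(vapply(Rj, function(rr) length(rr) * mean(rr)^2, 1)) -
      3 * (N + 1)
    ties <- table(x)
    H / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  g1 <- list(c(1, 2, 3), c(4, 5, 6))
  res <- kruskalWallisH(unlist(g1), rep(1:2, each = 3))
  expect_equal(res$H, bruteH(g1))
  g2 <- list(c(2.1, 3.5, 3.5, 7), c(1.0, 3.5, 8, 8), c(5, 6, 2.1))
  res2 <- kruskalWallisH(unlist(g2), rep(1:3, lengths(g2)))
  expect_equal(res2$H, bruteH(g2))
  # identical groups: H defined as 0, p = 1
  expect_equal(kruskalWallisH(rep(5, 6), rep(1:2, 3)),
               list(H = 0, df = 1L, p.value = 1))
})

test_that("Dunn post-hoc reduces to the omnibus direction for two groups", {
  set.seed(3)
  x <- c(rnorm(12), rnorm(12, 3))
  g <- rep(c("a", "b"), each = 12)
  d <- dunnPosthoc(x, g)
  expect_equal(nrow(d), 1L)
  expect_identical(d$p.adjusted, d$p.value)  # single comparison
  expect_lt(d$z, 0)  # group a has the smaller mean rank
  d3 <- dunnPosthoc(c(x, rnorm(12, 6)), c(g, rep("c", 12)),
                    correction = "holm")
  expect_equal(nrow(d3), 3L)
  expect_true(all(d3$p.adjusted >= d3$p.value))
})

test_that("compareGroups reports medians/IQRs matching a sort-based oracle", {
  set.seed(8)
  df <- data.frame(rate = c(rlnorm(29, log(2500), 0.5),
                            rlnorm(12, log(700), 0.5)),
                   group = rep(c("OSB", "control"), c(29, 12)))
  cg <- compareGroups(df)
  for (g in c("OSB", "control")) {
    xs <- sort(df$rate[df$group == g])
    expect_equal(cg$groups$median[cg$groups$group == g],
                 median(xs))
    expect_equal(cg$groups$q25[cg$groups$group == g],
                 unname(quantile(xs, 0.25)))
    expect_equal(cg$groups$q75[cg$groups$group == g],
                 unname(quantile(xs, 0.75)))
  }
  expect_true(cg$significant)
  # the normality gate ran for both groups (n >= 8 in each)
  expect_true(is.logical(cg$adNonNormal) && !anyNA(cg$adNonNormal))
})

test_that("degenerate grouping structures are handled with warnings", {
  df <- data.frame(rate = c(1, 2, 3, 10), group = c("a", "a", "a", "b"))
  expect_warning(cg <- compareGroups(df), "single subject")
  expect_true(is.na(cg$significant))
  expect_equal(nrow(cg$groups), 2L)
  df2 <- data.frame(rate = rnorm(10),
                    group = factor(rep(c("a", "b"), 5),
                                   levels = c("a", "b", "c")))
  expect_warning(compareGroups(df2), "empty")
})
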