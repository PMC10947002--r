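#' Three-period weekly rates of change
#'
#' Paired weekly rates over the three study windows around fetal surgery:
#' immediate (T1 to T2, surgery to ~1 week post-op), long-term (T2 to T3,
#' ~1 to ~6 weeks post-op), and global. The default global rate is the
#' overall T1-to-T3 weekly rate; `global = "difference"` instead returns the
#' long-term minus immediate rate difference.
#'
#' @param x numeric vector of length 3: the parameter at T1, T2, T3.
#' @param ga numeric vector of length 3: gestational ages in decimal weeks,
#'   strictly increasing.
#' @param global `"t1t3"` (default) or `"difference"`.
#' @return named numeric vector: `immediate`, `longterm`, `global`
#'   (parameter units per week).
#' @export
periodRates <- function(x, ga, global = c("t1t3", "difference")) {
  global <- match.arg(global)
  stopifnot(length(x) == 3L, length(ga) == 3L)
  if (any(diff(ga) <= 0)) stop("gestational ages must be strictly increasing")
  imm <- (x[2] - x[1]) / (ga[2] - ga[1])
  lt <- (x[3] - x[2]) / (ga[3] - ga[2])
  gl <- if (global == "t1t3") (x[3] - x[1]) / (ga[3] - ga[1]) else lt - imm
  c(immediate = imm, longterm = lt, global = gl)
}

#' Gestational age in decimal weeks
#'
#' Converts weeks + days notation (e.g. 23 weeks 3 days) to decimal weeks.
#'
#' @param weeks completed weeks.
#' @param days additional days (0-6).
#' @return decimal weeks.
#' @export
gaWeeks <- function(weeks, days = 0) weeks + days / 7

#' Ventriculomegaly severity from atrial diameter
#'
#' Severity bands: mild 10-12 mm, moderate 13-15 mm, severe > 15 mm, below
#' 10 mm none. Bands are integer-valued, so the measurement is rounded half
#' up to the nearest millimetre before lookup.
#'
#' @param atrialDiameter atrial diameter(s), mm, non-negative.
#' @return factor with levels none, mild, moderate, severe.
#' @export
classifyVentriculomegaly <- function(atrialDiameter) {
  if (any(atrialDiameter < 0)) stop("atrial diameter must be non-negative")
  d <- floor(atrialDiameter + 0.5)  # round half up to integer mm
  lev <- c("none", "mild", "moderate", "severe")
  out <- ifelse(d < 10, "none",
                ifelse(d <= 12, "mild", ifelse(d <= 15, "moderate", "severe")))
  factor(out, levels = lev)
}

.LOBE_LEVELS <- as.vector(outer(c("frontal", "parietal", "temporal",
                                  "occipital"), c("left", "right"),
                                paste, sep = "_"))

#' Parcellate a cortical surface into lobes and hemispheres
#'
#' Transfers the 8 lobe-by-hemisphere labels from a labeled atlas surface
#' onto the subject mesh: the subject is aligned to the atlas by a
#' similarity transform (full Procrustes when the meshes share a vertex
#' grid, centroid/scale plus principal-axes otherwise), then each subject
#' vertex takes the label of its nearest atlas vertex.
#'
#' @param mesh subject [SurfaceMesh-class].
#' @param atlas atlas [SurfaceMesh-class] whose `vertexData()` has a `lobe`
#'   column with the 8 levels `frontal/parietal/temporal/occipital x
#'   left/right`.
#' @return factor of length `nVertices(mesh)` with the 8 lobe levels.
#' @export
parcellateLobes <- function(mesh, atlas) {
  vd <- vertexData(atlas)
  if (!"lobe" %in% names(vd)) stop("atlas carries no 'lobe' vertex labels")
  lab <- factor(vd$lobe, levels = .LOBE_LEVELS)
  if (anyNA(lab)) stop("atlas lobe labels outside the 8 expected levels")
  va <- vertices(atlas)
  vs <- vertices(mesh)
  if (nrow(vs) == nrow(va)) {
    # shared parameterization: similarity Procrustes on index-paired points
    cs <- colMeans(vs); ca <- colMeans(va)
    X <- sweep(vs, 2, cs); Y <- sweep(va, 2, ca)
    sv <- svd(crossprod(X, Y))
    R <- sv$u %*% t(sv$v)
    if (det(R) < 0) {
      sv$u[, 3] <- -sv$u[, 3]
      R <- sv$u %*% t(sv$v)
    }
    sc <- sum(sv$d) / sum(X^2)
    aligned <- sc * X %*% R
    idx <- .nnIndex(aligned, Y)
  } else {
    idx <- as.integer(.coarsePairing(vs, va))
  }
  lab[idx]
}

#' Region-wise summary of a per-vertex field
#'
#' Median of the (signed) per-vertex values over each lobe region and over
#' the whole surface, with vertex counts. Medians rather than means are used
#' to match the nonparametric reporting of the cohort statistics; an
#' absolute-value variant is available via `absolute = TRUE`.
#'
#' @param values per-vertex numeric vector (e.g. curvedness, shape index, or
#'   a vertex-wise weekly rate).
#' @param parcellation factor from [parcellateLobes()] (or NULL for a
#'   whole-surface summary only).
#' @param absolute summarize `abs(values)` instead of signed values.
#' @return data.frame with columns `region`, `median`, `n_vertices`.
#' @export
curvatureSummary <- function(values, parcellation = NULL, absolute = FALSE) {
  if (absolute) values <- abs(values)
  out <- data.frame(region = "whole", median = stats::median(values),
                    n_vertices = length(values))
  if (!is.null(parcellation)) {
    if (length(parcellation) != length(values))
      stop("parcellation length must match the field")
    for (lv in levels(parcellation)) {
      sel <- parcellation == lv
      if (!any(sel)) {
        warning("empty region ", lv, ": summary omitted")
        next
      }
      out <- rbind(out, data.frame(region = lv,
                                   median = stats::median(values[sel]),
                                   n_vertices = sum(sel)))
    }
  }
  out
}

#' Anderson-Darling test of normality
#'
#' A-squared statistic with mean and variance estimated from the sample,
#' case-adjusted, as the gate for the nonparametric branch: parameters whose
#' distribution is rejected here are compared with rank statistics.
#'
#' @param x numeric sample, n >= 8.
#' @param alpha significance level for the decision (default 0.05).
#' @return list with `statistic` (A-squared), `p.value`, and `nonNormal`
#'   (TRUE when normality is rejected at `alpha`).
#' @export
adNormalityTest <- function(x, alpha = 0.05) {
  if (length(x) < 8L) stop("Anderson-Darling test needs n >= 8")
  if (stats::sd(x) == 0) stop("degenerate (constant) sample")
  t <- nortest::ad.test(x)
  list(statistic = unname(t$statistic), p.value = t$p.value,
       nonNormal = t$p.value < alpha)
}

#' Kruskal-Wallis H test
#'
#' Tie-corrected H with the chi-square approximation. If every observation
#' is identical across all groups, H is undefined and (H = 0, p = 1) is
#' returned.
#'
#' @param values numeric observations.
#' @param groups grouping factor (>= 2 levels, total n >= 3).
#' @return list with `H`, `df`, `p.value`.
#' @export
kruskalWallisH <- function(values, groups) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L) stop("need at least 2 groups")
  if (length(values) < 3L) stop("need total n >= 3")
  if (length(unique(values)) == 1L)
    return(list(H = 0, df = nlevels(groups) - 1L, p.value = 1))
  t <- stats::kruskal.test(values, groups)
  list(H = unname(t$statistic), df = unname(t$parameter),
       p.value = t$p.value)
}

#' Dunn's post-hoc pairwise z tests
#'
#' Rank-based pairwise comparisons after a Kruskal-Wallis omnibus, using the
#' pooled ranking, the tie-corrected variance, and two-sided normal
#' p-values; adjusted for multiple comparisons with the requested method.
#'
#' @param values numeric observations.
#' @param groups grouping factor.
#' @param correction p-adjustment method (default `"holm"`; any
#'   [stats::p.adjust()] method, e.g. `"bonferroni"`, `"BH"`).
#' @return data.frame with one row per group pair: `group1`, `group2`, `z`,
#'   `p.value`, `p.adjusted`.
#' @export
dunnPosthoc <- function(values, groups, correction = "holm") {
  groups <- droplevels(factor(groups))
  g <- levels(groups)
  N <- length(values)
  r <- rank(values)
  ties <- table(r)
  tieCorr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  pairs <- utils::combn(g, 2)
  z <- p <- numeric(ncol(pairs))
  for (i in seq_len(ncol(pairs))) {
    a <- pairs[1, i]; b <- pairs[2, i]
    se <- sqrt((N * (N + 1) / 12 - tieCorr) * (1 / ns[[a]] + 1 / ns[[b]]))
    z[i] <- (rbar[[a]] - rbar[[b]]) / se
    p[i] <- 2 * stats::pnorm(-abs(z[i]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p.value = p,
             p.adjusted = stats::p.adjust(p, method = correction))
}

#' Group comparison of weekly rates
#'
#' The cohort statistic: per-group median and IQR of a parameter's weekly
#' rate in one period, an Anderson-Darling normality gate, the
#' Kruskal-Wallis omnibus, and Dunn's pairwise post-hoc tests with
#' multiple-comparison correction. Significance is declared at adjusted
#' p < 0.05. Groups with a single subject are summarized but the test is
#' skipped with a warning; empty grouping levels are dropped with a warning.
#'
#' @param rates data.frame with at least the columns named by `value` and
#'   `group`.
#' @param value name of the numeric rate column.
#' @param group name of the grouping column.
#' @param correction p-adjustment method for the post-hoc tests.
#' @param alpha significance level (default 0.05).
#' @return list with `groups` (per-group median/IQR/n), `omnibus` (H, df,
#'   p), `posthoc` (Dunn table or NULL), `significant`, and `adNonNormal`
#'   (per-group normality-gate decisions, NA where n < 8).
#' @export
compareGroups <- function(rates, value = "rate", group = "group",
                          correction = "holm", alpha = 0.05) {
  x <- rates[[value]]
  gr <- rates[[group]]
  gr <- if (is.factor(gr)) gr else factor(gr)
  if (any(table(gr) == 0L)) {
    warning("dropping empty grouping level(s): ",
            paste(levels(gr)[table(gr) == 0L], collapse = ", "))
    gr <- droplevels(gr)
  }
  if (nlevels(gr) < 2L) stop("need >= 2 non-empty groups")
  qs <- t(vapply(levels(gr), function(l)
    stats::quantile(x[gr == l], c(0.25, 0.5, 0.75), names = FALSE),
    numeric(3)))
  gtab <- data.frame(group = levels(gr), n = as.vector(table(gr)),
                     q25 = qs[, 1], median = qs[, 2], q75 = qs[, 3])
  adFlags <- vapply(levels(gr), function(l) {
    xi <- x[gr == l]
    if (length(xi) < 8L || stats::sd(xi) == 0) return(NA)
    adNormalityTest(xi)$nonNormal
  }, logical(1))
  if (any(gtab$n < 2L)) {
    warning("a group has a single subject: test skipped, medians reported")
    return(list(groups = gtab, omnibus = NULL, posthoc = NULL,
                significant = NA, adNonNormal = adFlags))
  }
  omni <- kruskalWallisH(x, gr)
  post <- if (omni$p.value < alpha) dunnPosthoc(x, gr, correction) else NULL
  sig <- omni$p.value < alpha &&
    (is.null(post) || any(post$p.adjusted < alpha))
  list(groups = gtab, omnibus = omni, posthoc = post, significant = sig,
       adNonNormal = adFlags)
}
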