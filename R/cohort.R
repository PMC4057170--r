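# Tumor/normal cohort comparison of mean methylation at site sets.

#' Construct a cohort methylation matrix
#'
#' @param values Numeric samples x sites matrix of methylation beta values
#'   in `[0, 1]` (NA allowed for missing).
#' @param samples Sample identifiers (rows).
#' @param groups Per-sample group label, `"tumor"` or `"normal"`.
#' @param sites Interval data frame, one row per column of `values`.
#' @return A `cohort_matrix` object.
#' @export
cohort_matrix <- function(values, samples, groups, sites) {
  values <- as.matrix(values)
  abort_if(nrow(values) != length(samples) ||
             length(samples) != length(groups),
           "values rows, samples and groups must align")
  abort_if(ncol(values) != nrow(sites),
           "values columns must match the site set")
  abort_if(!all(groups %in% c("tumor", "normal")),
           "groups must be 'tumor' or 'normal'")
  rng <- range(values, na.rm = TRUE)
  abort_if(is.finite(rng[1]) && (rng[1] < 0 || rng[2] > 1),
           "methylation values must lie in [0, 1]")
  validate_intervals(sites, "cohort site set")
  structure(list(values = values, samples = samples, groups = groups,
                 sites = sites),
            class = "cohort_matrix")
}

site_keys <- function(sites) {
  sprintf("%s:%d-%d", sites$chrom, sites$start, sites$end)
}

#' Per-sample mean methylation over a site subset
#'
#' Missing values are excluded per sample-site pair (never imputed);
#' samples missing every subset site are dropped with a reported count.
#'
#' @param m A `cohort_matrix`.
#' @param site_subset Optional interval data frame; matched to the matrix
#'   sites by exact chrom:start-end identity. `NULL` uses all sites.
#' @return Data frame sample / group / mean, with attribute
#'   `n_dropped_samples`.
#' @export
sample_site_means <- function(m, site_subset = NULL) {
  cols <- seq_len(ncol(m$values))
  if (!is.null(site_subset)) {
    cols <- which(site_keys(m$sites) %in% site_keys(site_subset))
    abort_if(length(cols) == 0L,
             "site subset does not intersect the cohort matrix")
  }
  v <- m$values[, cols, drop = FALSE]
  mu <- rowMeans(v, na.rm = TRUE)
  keep <- !is.nan(mu)
  n_dropped <- sum(!keep)
  if (n_dropped > 0) {
    message("sample_site_means: dropped ", n_dropped,
            " samples with no informative site")
  }
  out <- data.frame(sample = m$samples[keep], group = m$groups[keep],
                    mean = mu[keep], stringsAsFactors = FALSE)
  attr(out, "n_dropped_samples") <- n_dropped
  out
}

#' Mann-Whitney U test (two-sided)
#'
#' U with midrank tie handling; the p-value is exact by enumeration when
#' `n_a + n_b <= 16` and there are no ties, otherwise a normal
#' approximation with tie and continuity correction (via
#' `stats::wilcox.test`). The p-value is floored at the smallest positive
#' double, never 0. The raw normal-approximation z-score is reported
#' alongside, since p-values this small are usually displayed as a floor.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @return List: `U`, `p` (two-sided), `z` (tie-corrected normal
#'   approximation with continuity correction), `exact` (logical), `note`
#'   ("underpowered" when either group has fewer than 2 values).
#' @export
mann_whitney_u <- function(group_a, group_b) {
  na <- length(group_a); nb <- length(group_b)
  abort_if(na == 0L || nb == 0L, "both groups must be non-empty")
  ties <- anyDuplicated(c(group_a, group_b)) > 0
  exact <- (na + nb <= 16L) && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(group_a, group_b, alternative = "two.sided",
                       exact = exact, correct = TRUE))
  U <- unname(wt$statistic)
  # tie-corrected normal approximation for the reported z
  n <- na + nb
  r <- rank(c(group_a, group_b))
  tie_tab <- table(r)
  mu <- na * nb / 2
  sigma2 <- (na * nb / 12) * (n + 1 - sum(tie_tab^3 - tie_tab) /
                                (n * (n - 1)))
  d <- U - mu
  z <- if (sigma2 <= 0 || d == 0) 0 else
    (d - sign(d) * 0.5) / sqrt(sigma2)
  # complete ties make the normal approximation degenerate: every rank
  # order is equally likely, so p = 1
  p <- if (is.nan(wt$p.value)) 1 else max(wt$p.value, .Machine$double.xmin)
  note <- if (min(na, nb) < 2L) "underpowered" else ""
  list(U = U, p = p, z = z, exact = exact, note = note)
}

#' Compare tumor and normal methylation across site sets
#'
#' For each named site set: per-sample means per group, group medians, and
#' the two-sided tumor-vs-normal Mann-Whitney test. A random-site matrix
#' (no planted effect) can be supplied for the matched-null comparison.
#'
#' @param m A `cohort_matrix`.
#' @param site_sets Named list of interval data frames (subsets of the
#'   matrix sites). The full matrix is always reported as `all_sites`.
#' @param random_matrix Optional `cohort_matrix` over random sites,
#'   reported as set `random`.
#' @return List: `samples` (set/sample/group/mean, plot-ready), `summary`
#'   (set/group/n/median), `tests` (set/U/z/p/exact/note).
#' @export
cohort_comparison <- function(m, site_sets = list(), random_matrix = NULL) {
  pieces <- list(all_sites = list(m, NULL))
  for (nm in names(site_sets)) pieces[[nm]] <- list(m, site_sets[[nm]])
  if (!is.null(random_matrix)) pieces$random <- list(random_matrix, NULL)
  samples <- list(); summaries <- list(); tests <- list()
  for (nm in names(pieces)) {
    sm <- sample_site_means(pieces[[nm]][[1]], pieces[[nm]][[2]])
    a <- sm$mean[sm$group == "tumor"]
    b <- sm$mean[sm$group == "normal"]
    mw <- mann_whitney_u(a, b)
    samples[[nm]] <- cbind(set = nm, sm)
    summaries[[nm]] <- data.frame(
      set = nm, group = c("tumor", "normal"),
      n = c(length(a), length(b)),
      median = c(stats::median(a), stats::median(b)),
      stringsAsFactors = FALSE)
    tests[[nm]] <- data.frame(set = nm, U = mw$U, z = mw$z, p = mw$p,
                              exact = mw$exact, note = mw$note,
                              stringsAsFactors = FALSE)
  }
  list(samples = do.call(rbind, c(samples, make.row.names = FALSE)),
       summary = do.call(rbind, c(summaries, make.row.names = FALSE)),
       tests = do.call(rbind, c(tests, make.row.names = FALSE)))
}
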