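#' One-way fixed-effects ANOVA
#'
#' Classical one-way ANOVA of a numeric response across groups, returning the
#' F statistic, its p-value and the pooled mean squared error (needed by the
#' pairwise contrasts). Degenerate inputs get explicit conventions: zero
#' between-group variance gives F = 0, p = 1; zero within-group variance with
#' distinct means gives p = 0 with a warning.
#'
#' @param values_by_class named list of numeric vectors (>= 2 groups, each
#'   with >= 2 observations).
#' @return list with `F`, `p`, `df_between`, `df_within`, `mse`, `means`, `ns`.
#' @export
one_way_anova <- function(values_by_class) {
  if (length(values_by_class) < 2L) stop("need at least 2 groups")
  ns <- vapply(values_by_class, length, 0L)
  small <- names(values_by_class)[ns < 2L]
  if (length(small))
    stop("group(s) with fewer than 2 observations: ",
         paste(small, collapse = ", "))
  df <- data.frame(
    value = unlist(values_by_class, use.names = FALSE),
    group = factor(rep(names(values_by_class), ns)))
  fit <- stats::aov(value ~ group, data = df)
  tab <- suppressWarnings(stats::anova(fit))
  ssb <- tab$`Sum Sq`[1]; sse <- tab$`Sum Sq`[2]
  df1 <- tab$Df[1]; df2 <- tab$Df[2]
  means <- vapply(values_by_class, mean, 0)
  if (sse <= 1e-12 * max(ssb, .Machine$double.eps)) {
    if (ssb <= 0) return(list(F = 0, p = 1, df_between = df1, df_within = df2,
                              mse = 0, means = means, ns = ns))
    warning("zero within-group variance with distinct means; p -> 0")
    return(list(F = Inf, p = 0, df_between = df1, df_within = df2,
                mse = 0, means = means, ns = ns))
  }
  Fv <- tab$`F value`[1]; p <- tab$`Pr(>F)`[1]
  if (ssb <= 0) { Fv <- 0; p <- 1 }
  list(F = Fv, p = p, df_between = df1, df_within = df2,
       mse = sse / df2, means = means, ns = ns)
}

#' Welch two-sample t-test
#'
#' Thin wrapper around [stats::t.test] with unequal variances, the
#' appropriate default for the study's unequal class sizes.
#'
#' @param a,b numeric vectors with >= 2 observations each.
#' @return list with `t`, `p`, `df`, `mean_a`, `mean_b`.
#' @export
two_sample_ttest <- function(a, b) {
  if (length(a) < 2L || length(b) < 2L)
    stop("each sample needs at least 2 observations")
  ht <- stats::t.test(a, b, var.equal = FALSE)
  list(t = unname(ht$statistic), p = ht$p.value,
       df = unname(ht$parameter), mean_a = mean(a), mean_b = mean(b))
}

#' Significance star coding
#'
#' The conventional star coding with strict upper boundaries:
#' `ns` for p >= 0.05, `*` for p < 0.05, `**` for p < 0.01,
#' `***` for p < 0.001, `****` for p < 0.0001.
#'
#' @param p numeric vector of p-values in `[0, 1]`.
#' @return character vector of codes.
#' @export
significance_code <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  out <- rep("ns", length(p))
  out[p < 0.05] <- "*"
  out[p < 0.01] <- "**"
  out[p < 0.001] <- "***"
  out[p < 0.0001] <- "****"
  out
}

#' Pairwise class contrasts for a marker matrix
#'
#' For each marker, compares the reference class against every other class
#' present. The default method (`"lsd"`) is the pairwise t-test on the ANOVA
#' pooled standard deviation ([stats::pairwise.t.test] with `pool.sd = TRUE`,
#' no multiplicity adjustment), whose per-contrast type-I error is the
#' nominal alpha. `"protected-lsd"` additionally forces `ns` whenever the
#' omnibus ANOVA is not significant at alpha; `"tukey"` uses Tukey's HSD.
#' Missing marker values are dropped per marker, never propagated.
#'
#' @param marker_matrix data.frame with a `pmi_class` column and one column
#'   per marker (one row per sample; replicates already aggregated).
#' @param reference_class class compared against all others (default 1).
#' @param markers marker columns to test (default: the six core markers
#'   present in the matrix).
#' @param method `"lsd"`, `"protected-lsd"` or `"tukey"`.
#' @param p_adjust p-adjustment applied across markers within each contrast
#'   (any method of [stats::p.adjust]; default `"none"`).
#' @param alpha omnibus gate level for `"protected-lsd"`.
#' @return data.frame: marker, contrast, class_a, class_b, n_a, n_b, mean_a,
#'   mean_b, omnibus_p, p_value, significance.
#' @export
pairwise_class_contrasts <- function(marker_matrix, reference_class = 1L,
                                     markers = NULL,
                                     method = c("lsd", "protected-lsd", "tukey"),
                                     p_adjust = "none", alpha = 0.05) {
  method <- match.arg(method)
  stopifnot("pmi_class" %in% names(marker_matrix))
  if (is.null(markers))
    markers <- intersect(marker_names(), names(marker_matrix))
  ref <- as.integer(reference_class)
  if (sum(marker_matrix$pmi_class == ref, na.rm = TRUE) < 2L)
    stop("reference class ", ref, " absent or has fewer than 2 samples")
  rows <- list()
  for (mk in markers) {
    d <- marker_matrix[!is.na(marker_matrix[[mk]]), c("pmi_class", mk)]
    cnt <- table(d$pmi_class)
    keep <- as.integer(names(cnt)[cnt >= 2L])
    if (!(ref %in% keep) || length(keep) < 2L) next
    d <- d[d$pmi_class %in% keep, ]
    g <- factor(d$pmi_class)
    x <- d[[mk]]
    om <- one_way_anova(split(x, g))
    if (method %in% c("lsd", "protected-lsd")) {
      pt <- stats::pairwise.t.test(x, g, pool.sd = TRUE,
                                   p.adjust.method = "none")
      pmat <- pt$p.value
      get_p <- function(a, b) {
        a <- as.character(a); b <- as.character(b)
        if (a %in% rownames(pmat) && b %in% colnames(pmat) &&
            !is.na(pmat[a, b])) pmat[a, b] else pmat[b, a]
      }
    } else {
      df2 <- data.frame(x = x, g = g)
      tk <- stats::TukeyHSD(stats::aov(x ~ g, data = df2))$g
      get_p <- function(a, b) {
        key1 <- sprintf("%s-%s", a, b); key2 <- sprintf("%s-%s", b, a)
        if (key1 %in% rownames(tk)) tk[key1, "p adj"] else tk[key2, "p adj"]
      }
    }
    for (other in setdiff(keep, ref)) {
      p <- get_p(other, ref)
      rows[[length(rows) + 1L]] <- data.frame(
        marker = mk,
        contrast = sprintf("%d vs %d", ref, other),
        class_a = ref, class_b = other,
        n_a = sum(d$pmi_class == ref), n_b = sum(d$pmi_class == other),
        mean_a = mean(x[d$pmi_class == ref]),
        mean_b = mean(x[d$pmi_class == other]),
        omnibus_p = om$p, p_value = p)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(out)
  if (p_adjust != "none") {
    for (ct in unique(out$contrast)) {
      sel <- out$contrast == ct
      out$p_value[sel] <- stats::p.adjust(out$p_value[sel], method = p_adjust)
    }
  }
  out$significance <- significance_code(pmin(pmax(out$p_value, 0), 1))
  if (method == "protected-lsd")
    out$significance[out$omnibus_p >= alpha] <- "ns"
  out
}
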