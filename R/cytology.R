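#' Per-embryo anaphase/telophase bridge statistics
#'
#' Each embryo is one independent observation: its bridge ratio is
#' bridged / total A/T figures. Per genotype, the mean ratio and its standard
#' error over embryos are reported — never a pooled-figure ratio, which would
#' weight embryos by how many figures happened to be scored. Genotypes are
#' compared by one-way ANOVA on the per-embryo ratios and by two-tailed
#' two-sample t-tests (Welch by default) for the requested pairs. P-values
#' are reported raw; an optional Bonferroni correction is available.
#'
#' @param counts data.frame with `genotype`, `embryo_id`, `bridged`, `total`.
#' @param pairs List of length-2 character vectors of genotypes to compare;
#'   `NULL` compares all pairs.
#' @param var_equal Use the pooled-variance (Student) t-test instead of
#'   Welch's.
#' @param bonferroni Multiply pairwise p-values by the number of comparisons
#'   (capped at 1).
#' @return A `bridge_summary`: `summary` data.frame (genotype, n_embryos,
#'   mean_ratio, sem), `anova_p`, `anova_F`, and `pairwise` data.frame
#'   (genotype1, genotype2, t, df, p).
#' @export
#' @examples
#' counts <- generate_embryo_counts(
#'   data.frame(genotype = c("wt", "aub"), p_bridge = c(0.02, 0.5),
#'              n_embryos = 15, figures = 20), seed = 1)
#' summarize_bridges(counts)
summarize_bridges <- function(counts, pairs = NULL, var_equal = FALSE,
                              bonferroni = FALSE) {
  stopifnot(is.data.frame(counts),
            all(c("genotype", "embryo_id", "bridged", "total") %in% names(counts)))
  if (any(counts$total < 1)) stop("each embryo needs at least one scored figure")
  if (any(counts$bridged < 0 | counts$bridged > counts$total))
    stop("bridged counts must lie in [0, total]")
  counts$ratio <- counts$bridged / counts$total
  genos <- unique(counts$genotype)

  summ <- do.call(rbind, lapply(genos, function(g) {
    r <- counts$ratio[counts$genotype == g]
    if (length(r) < 2) warning("genotype ", g, " has < 2 embryos; SEM undefined")
    data.frame(genotype = g, n_embryos = length(r), mean_ratio = mean(r),
               sem = if (length(r) >= 2) stats::sd(r) / sqrt(length(r)) else NA_real_,
               stringsAsFactors = FALSE)
  }))

  anova_p <- anova_F <- NA_real_
  if (length(genos) >= 2) {
    fit <- stats::aov(ratio ~ genotype, data = counts)
    tab <- summary(fit)[[1]]
    anova_F <- tab[["F value"]][1]
    anova_p <- tab[["Pr(>F)"]][1]
  }

  if (is.null(pairs) && length(genos) >= 2) {
    cmb <- utils::combn(genos, 2, simplify = FALSE)
  } else {
    cmb <- pairs
  }
  pairwise <- NULL
  if (length(cmb)) {
    pairwise <- do.call(rbind, lapply(cmb, function(p) {
      stopifnot(length(p) == 2, all(p %in% genos))
      x <- counts$ratio[counts$genotype == p[1]]
      y <- counts$ratio[counts$genotype == p[2]]
      if (length(x) < 2 || length(y) < 2) {
        warning("pair ", p[1], " vs ", p[2],
                " has a genotype with < 2 embryos; t-test undefined")
        return(data.frame(genotype1 = p[1], genotype2 = p[2], t = NA_real_,
                          df = NA_real_, p = NA_real_, stringsAsFactors = FALSE))
      }
      tt <- stats::t.test(x, y, var.equal = var_equal)
      data.frame(genotype1 = p[1], genotype2 = p[2],
                 t = unname(tt$statistic), df = unname(tt$parameter),
                 p = tt$p.value, stringsAsFactors = FALSE)
    }))
    if (bonferroni) pairwise$p <- pmin(pairwise$p * nrow(pairwise), 1)
  }

  structure(list(summary = summ, anova_p = anova_p, anova_F = anova_F,
                 pairwise = pairwise, var_equal = var_equal),
            class = "bridge_summary")
}

#' @export
print.bridge_summary <- function(x, ...) {
  cat("bridge_summary (per-embryo ratios, mean +/- SEM)\n")
  print(transform(x$summary, mean_ratio = round(mean_ratio, 3),
                  sem = round(sem, 3)))
  cat(sprintf("one-way ANOVA: F = %.3f, p = %.3g\n", x$anova_F, x$anova_p))
  if (!is.null(x$pairwise)) {
    cat(sprintf("pairwise two-tailed %s t-tests:\n",
                if (x$var_equal) "Student" else "Welch"))
    print(transform(x$pairwise, t = round(t, 3), df = round(df, 2),
                    p = signif(p, 3)))
  }
  invisible(x)
}

#' Plot per-genotype bridge frequencies with SEM error bars
#' @param x A `bridge_summary`.
#' @param ... Passed to [graphics::barplot()].
#' @return Invisibly `x`.
#' @export
plot.bridge_summary <- function(x, ...) {
  s <- x$summary
  mid <- graphics::barplot(s$mean_ratio, names.arg = s$genotype,
                           ylim = c(0, min(1, max(s$mean_ratio + s$sem,
                                                  na.rm = TRUE) * 1.2)),
                           ylab = "A/T bridges / total A/T figures", ...)
  ok <- !is.na(s$sem) & s$sem > 0
  graphics::arrows(mid[ok], s$mean_ratio[ok] - s$sem[ok],
                   mid[ok], s$mean_ratio[ok] + s$sem[ok],
                   angle = 90, code = 3, length = 0.06)
  invisible(x)
}
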