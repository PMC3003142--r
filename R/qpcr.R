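#' Fit a qPCR standard curve and estimate primer efficiency
#'
#' Least-squares fit of Ct on log10(template dilution); the per-cycle
#' amplification efficiency is `E = 10^(-1/slope)`. A perfect doubling assay
#' gives slope -3.3219 and E = 2. Efficiencies outside (1, 2.2] after fitting
#' are flagged, not rejected.
#'
#' @param curve data.frame with columns `dilution` (relative template
#'   quantity) and `ct`; replicate rows are used as is. Optionally a
#'   `primer_pair` column naming a single pair.
#' @return A `standard_curve`: `primer_pair`, `slope`, `intercept`,
#'   `efficiency`, `r_squared`, `n_points`, `flagged`.
#' @export
#' @examples
#' d <- data.frame(dilution = 10^-(0:4), ct = 18 + 0:4 * log2(10))
#' fit_efficiency(d)$efficiency  # 2
fit_efficiency <- function(curve) {
  stopifnot(is.data.frame(curve), all(c("dilution", "ct") %in% names(curve)))
  if (length(unique(curve$dilution)) < 3) stop("need >= 3 distinct dilution points")
  if (any(curve$dilution <= 0)) stop("dilutions must be positive")
  pp <- unique(curve$primer_pair %||% NA_character_)
  if (length(pp) > 1) stop("one primer pair per curve; split the table first")
  fit <- stats::lm(ct ~ log10(dilution), data = curve)
  slope <- unname(stats::coef(fit)[2])
  if (!is.finite(slope) || slope >= 0)
    stop("standard curve slope is non-negative; check data orientation")
  eff <- 10^(-1 / slope)
  r2 <- 1 - sum(stats::residuals(fit)^2) / sum((curve$ct - mean(curve$ct))^2)
  structure(list(primer_pair = pp, slope = slope,
                 intercept = unname(stats::coef(fit)[1]), efficiency = eff,
                 r_squared = r2, n_points = nrow(curve),
                 flagged = !(eff > 1 && eff <= 2.2)),
            class = "standard_curve")
}

#' @export
print.standard_curve <- function(x, ...) {
  cat(sprintf("standard_curve [%s]: slope %.4f, E = %.4f (R^2 = %.4f)%s\n",
              x$primer_pair, x$slope, x$efficiency, x$r_squared,
              if (x$flagged) " [FLAGGED: efficiency outside (1, 2.2]]" else ""))
  invisible(x)
}

#' Fit standard curves for every primer pair on a plate
#' @param curve data.frame with `primer_pair`, `dilution`, `ct`.
#' @return Named list of [fit_efficiency()] results.
#' @export
fit_efficiencies <- function(curve) {
  stopifnot("primer_pair" %in% names(curve))
  out <- lapply(split(curve, curve$primer_pair), fit_efficiency)
  out[unique(curve$primer_pair)]
}

efficiency_of <- function(curves, primer_pair) {
  if (is.numeric(curves)) {
    e <- curves[[primer_pair]]
  } else {
    cv <- curves[[primer_pair]]
    if (is.null(cv)) stop("no standard curve for primer pair ", primer_pair)
    e <- cv$efficiency
  }
  if (is.null(e) || !is.finite(e)) stop("no efficiency for primer pair ", primer_pair)
  e
}

drop_nondetect <- function(df, ct_max = 40) {
  nd <- df$ct >= ct_max
  if (any(nd)) {
    warning(sum(nd), " Ct value(s) >= ", ct_max, " treated as non-detect and excluded")
    df <- df[!nd, ]
  }
  df
}

#' Efficiency-corrected ChIP percent input
#'
#' For each sample x primer pair, replicate Cts are averaged on the Ct scale
#' (geometric averaging of quantities), the mean input Ct is adjusted to
#' represent the full chromatin amount the IP saw
#' (`adjusted = mean_input_ct - log_E(1 / input_fraction)`), and
#' `percent_input = 100 * E^(adjusted - mean_ip_ct)`, which equals
#' `100 * input_fraction * E^(mean_input_ct - mean_ip_ct)` exactly: the
#' percent scales linearly with the input fraction. The replicate Ct
#' standard deviations are propagated to the percent scale by the delta
#' method. Ct >= 40 is treated as non-detect and excluded with a warning.
#'
#' @param plate data.frame with `sample`, `primer_pair`, `role` ("input" or
#'   "IP"), `replicate`, `ct`.
#' @param curves Named list of `standard_curve`s (or named numeric
#'   efficiencies) per primer pair.
#' @param input_fraction Fraction of chromatin used as the input sample
#'   (e.g. 0.01 for a 1% input).
#' @return A `chip_result` data.frame: `sample`, `primer_pair`,
#'   `percent_input`, `sd`.
#' @export
#' @examples
#' plate <- data.frame(sample = "wt", primer_pair = "HeT-A",
#'                     role = rep(c("input", "IP"), each = 2),
#'                     replicate = c(1, 2, 1, 2), ct = c(20, 20, 25, 25))
#' percent_input(plate, c("HeT-A" = 2), input_fraction = 1)  # 3.125%
percent_input <- function(plate, curves, input_fraction) {
  stopifnot(is.data.frame(plate),
            all(c("sample", "primer_pair", "role", "ct") %in% names(plate)),
            input_fraction > 0, input_fraction <= 1)
  plate <- drop_nondetect(plate)
  groups <- unique(plate[c("sample", "primer_pair")])
  out <- lapply(seq_len(nrow(groups)), function(i) {
    s <- groups$sample[i]; pp <- groups$primer_pair[i]
    sub <- plate[plate$sample == s & plate$primer_pair == pp, ]
    ip <- sub$ct[sub$role == "IP"]
    inp <- sub$ct[sub$role == "input"]
    if (!length(inp)) stop("missing input measurements for ", s, " / ", pp)
    if (!length(ip)) stop("missing IP measurements for ", s, " / ", pp)
    e <- efficiency_of(curves, pp)
    adj_input <- mean(inp) - log(1 / input_fraction) / log(e)
    pct <- 100 * e^(adj_input - mean(ip))
    var_delta <- stats::var(inp) / length(inp) + stats::var(ip) / length(ip)
    if (!is.finite(var_delta)) var_delta <- 0  # single replicates
    data.frame(sample = s, primer_pair = pp, percent_input = pct,
               sd = pct * log(e) * sqrt(var_delta), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("chip_result", "data.frame")
  out
}

#' Fold change in ChIP binding relative to wild type
#'
#' Divides each sample's percent input by the wild-type value for the same
#' primer pair. Uncertainty combines the two relative standard deviations in
#' quadrature. A zero wild-type value flags the ratio undefined.
#'
#' @param results A `chip_result` (from [percent_input()]).
#' @param wt Wild-type sample label.
#' @return Data.frame: `sample`, `primer_pair`, `fold_vs_wt`, `sd`,
#'   `undefined`.
#' @export
fold_vs_wt <- function(results, wt = "wt") {
  stopifnot(inherits(results, "data.frame"),
            all(c("sample", "primer_pair", "percent_input") %in% names(results)))
  wt_rows <- results[results$sample == wt, ]
  if (!nrow(wt_rows)) stop("wild-type sample '", wt, "' absent from results")
  out <- lapply(seq_len(nrow(results)), function(i) {
    r <- results[i, ]
    w <- wt_rows[wt_rows$primer_pair == r$primer_pair, ]
    if (!nrow(w)) stop("no wild-type value for primer pair ", r$primer_pair)
    undef <- w$percent_input == 0
    fold <- if (undef) NA_real_ else r$percent_input / w$percent_input
    sdv <- if (undef || r$percent_input == 0) NA_real_ else
      fold * sqrt((r$sd / r$percent_input)^2 + (w$sd / w$percent_input)^2)
    data.frame(sample = r$sample, primer_pair = r$primer_pair,
               fold_vs_wt = fold, sd = sdv, undefined = undef,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Relative genomic copy number against a single-copy reference
#'
#' Per sample, the target's relative quantity is `E_t^(-Ct_t) / E_r^(-Ct_r)`
#' with replicate Cts averaged on the Ct scale; fold versus the control
#' sample is the ratio of relative quantities. With both efficiencies equal
#' to 2 this reduces to the textbook `2^(-ddCt)`.
#'
#' @param plate data.frame with `sample`, `primer_pair`, `replicate`, `ct`.
#' @param curves Named list of `standard_curve`s or named efficiencies.
#' @param target,reference Primer-pair names for the element assayed and the
#'   single-copy internal standard.
#' @param control_sample Sample whose copy number defines fold 1.
#' @return A `copy_number_result` data.frame: `sample`, `element`,
#'   `fold_vs_control`, `sd`.
#' @export
copy_number <- function(plate, curves, target, reference, control_sample) {
  stopifnot(is.data.frame(plate),
            all(c("sample", "primer_pair", "ct") %in% names(plate)))
  plate <- drop_nondetect(plate)
  samples <- unique(plate$sample)
  if (!control_sample %in% samples) stop("control sample '", control_sample,
                                         "' absent from plate")
  e_t <- efficiency_of(curves, target)
  e_r <- efficiency_of(curves, reference)
  qty <- function(s) {
    ct_t <- plate$ct[plate$sample == s & plate$primer_pair == target]
    ct_r <- plate$ct[plate$sample == s & plate$primer_pair == reference]
    if (!length(ct_t) || !length(ct_r))
      stop("sample ", s, " lacks target or reference measurements")
    # log-quantity and its delta-method variance
    lq <- -mean(ct_t) * log(e_t) + mean(ct_r) * log(e_r)
    v <- log(e_t)^2 * stats::var(ct_t) / length(ct_t) +
      log(e_r)^2 * stats::var(ct_r) / length(ct_r)
    c(lq = lq, v = if (is.finite(v)) v else 0)
  }
  q0 <- qty(control_sample)
  out <- lapply(samples, function(s) {
    q <- qty(s)
    fold <- exp(q["lq"] - q0["lq"])
    data.frame(sample = s, element = target, fold_vs_control = unname(fold),
               sd = unname(fold * sqrt(q["v"] + q0["v"])),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  class(out) <- c("copy_number_result", "data.frame")
  out
}
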