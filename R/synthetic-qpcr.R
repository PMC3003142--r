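#' Simulate a qPCR plate with standard-curve dilution series
#'
#' Ct values follow the standard exponential-amplification model
#' `Ct = intercept - log(quantity) / log(E)` plus Gaussian noise, where `E` is
#' the per-cycle primer efficiency (2 = perfect doubling). Each primer pair
#' also gets a ten-fold dilution series (>= 4 points) for standard-curve
#' fitting; with `E = 2` and no noise successive dilution Cts differ by
#' exactly `log2(10) ~ 3.3219` cycles.
#'
#' @param truth data.frame with columns `sample`, `primer_pair`, `role`
#'   (e.g. "input"/"IP" for ChIP plates, "target"/"reference" for copy-number
#'   plates) and `quantity` (relative template quantity, > 0).
#' @param efficiencies Named numeric vector, primer pair -> efficiency in
#'   (1, 2].
#' @param noise_sd Gaussian Ct noise standard deviation (cycles).
#' @param n_replicates Technical replicates per well.
#' @param dilutions Dilution series (relative template quantities); at least
#'   4 ten-fold points.
#' @param intercepts Optional named per-primer Ct intercepts (Ct of quantity
#'   1); default 18 cycles for all.
#' @param seed Integer seed.
#' @return List with `plate` (sample, primer_pair, role, replicate, ct),
#'   `curve` (primer_pair, dilution, replicate, ct), `truth` and
#'   `efficiencies`, for recovery tests against planted values.
#' @export
#' @examples
#' truth <- data.frame(sample = c("wt", "mut"), primer_pair = "HeT-A",
#'                     role = "IP", quantity = c(1, 2))
#' p <- generate_qpcr_plate(truth, c("HeT-A" = 2), noise_sd = 0, seed = 1)
#' head(p$plate)
generate_qpcr_plate <- function(truth, efficiencies, noise_sd = 0.1,
                                n_replicates = 3, dilutions = 10^-(0:4),
                                intercepts = NULL, seed = 1L) {
  stopifnot(is.data.frame(truth),
            all(c("sample", "primer_pair", "role", "quantity") %in% names(truth)))
  if (any(truth$quantity <= 0)) stop("quantities must be positive")
  pairs <- unique(truth$primer_pair)
  if (!all(pairs %in% names(efficiencies)))
    stop("efficiency missing for primer pair(s): ",
         paste(setdiff(pairs, names(efficiencies)), collapse = ", "))
  if (any(efficiencies <= 1 | efficiencies > 2))
    stop("efficiencies must lie in (1, 2]")
  if (length(dilutions) < 4) stop("dilution series needs >= 4 points")
  if (is.null(intercepts)) intercepts <- stats::setNames(rep(18, length(pairs)), pairs)

  with_seed(seed, {
    ct_of <- function(pp, quantity) {
      intercepts[[pp]] - log(quantity) / log(efficiencies[[pp]])
    }
    rows <- truth[rep(seq_len(nrow(truth)), each = n_replicates), ]
    rows$replicate <- rep(seq_len(n_replicates), nrow(truth))
    rows$ct <- mapply(ct_of, rows$primer_pair, rows$quantity) +
      stats::rnorm(nrow(rows), 0, noise_sd)
    rows$quantity <- NULL
    rownames(rows) <- NULL

    curve <- expand.grid(primer_pair = names(efficiencies), dilution = dilutions,
                         replicate = seq_len(n_replicates),
                         KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    curve$ct <- mapply(ct_of, curve$primer_pair, curve$dilution) +
      stats::rnorm(nrow(curve), 0, noise_sd)
    list(plate = rows, curve = curve, truth = truth, efficiencies = efficiencies)
  })
}

#' Simulate per-embryo anaphase/telophase bridge counts
#'
#' Each embryo contributes an independent binomial draw: out of `figures`
#' scored anaphase/telophase figures, each shows a bridge with the genotype's
#' probability. The 10-30 embryos-per-genotype range mirrors the scoring
#' regime the statistics assume.
#'
#' @param genotypes data.frame with columns `genotype`, `p_bridge` (in
#'   \[0, 1\]), `n_embryos` (10-30) and `figures` (A/T figures scored per
#'   embryo, >= 1).
#' @param seed Integer seed.
#' @return data.frame with `genotype`, `embryo_id`, `bridged`, `total`.
#' @export
#' @examples
#' g <- data.frame(genotype = c("aub", "ligIV;aub"), p_bridge = c(0.5, 0.15),
#'                 n_embryos = 20, figures = 20)
#' head(generate_embryo_counts(g, seed = 1))
generate_embryo_counts <- function(genotypes, seed = 1L) {
  stopifnot(is.data.frame(genotypes),
            all(c("genotype", "p_bridge", "n_embryos", "figures") %in% names(genotypes)))
  if (any(genotypes$p_bridge < 0 | genotypes$p_bridge > 1))
    stop("bridge probabilities must lie in [0, 1]")
  if (any(genotypes$n_embryos < 10 | genotypes$n_embryos > 30))
    stop("n_embryos must lie in [10, 30]")
  if (any(genotypes$figures < 1)) stop("figures per embryo must be >= 1")
  with_seed(seed, {
    out <- lapply(seq_len(nrow(genotypes)), function(i) {
      g <- genotypes[i, ]
      data.frame(genotype = g$genotype,
                 embryo_id = sprintf("%s_e%02d", g$genotype, seq_len(g$n_embryos)),
                 bridged = stats::rbinom(g$n_embryos, g$figures, g$p_bridge),
                 total = g$figures, stringsAsFactors = FALSE)
    })
    do.call(rbind, out)
  })
}
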