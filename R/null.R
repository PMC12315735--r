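#' Analytic null distribution of ALE scores
#'
#' Under the null hypothesis of random spatial association, an experiment
#' contributes an MA value drawn from its own in-mask MA histogram,
#' independently of all other experiments. The null ALE distribution is
#' built by a non-linear histogram algorithm: histogram each experiment's
#' in-mask MA values on a fixed bin lattice, then fold experiments in one at
#' a time — for every pair of occupied bins (accumulated null value a, next
#' experiment's value m) the product of their masses is deposited at the bin
#' of \eqn{1 - (1 - a)(1 - m)}. Histogramming and deposition use the nearest
#' bin, which keeps the combined null unbiased; conservatism at bin edges is
#' enforced later, at the p-value lookup ([ale_to_p()] reads the survival
#' function at the floor bin of the observed score).
#'
#' @param ma_maps Non-empty list of [build_ma_map()] results or plain arrays.
#' @param grid A [brain_grid]; histograms use in-mask voxels only.
#' @param bin_width Histogram bin width on `[0, 1]`; must be in (0, 0.01].
#' @return An object of class `ale_null`: `bin_edges` (left edges, length
#'   B), `probabilities` (length B, summing to 1), `bin_width`.
#' @export
analytic_null <- function(ma_maps, grid, bin_width = 1e-4) {
  if (length(ma_maps) == 0L) stop("`ma_maps` must contain at least one map")
  if (!is.numeric(bin_width) || bin_width <= 0 || bin_width > 0.01)
    stop("`bin_width` must be in (0, 0.01]")
  arrs <- lapply(ma_maps, function(m) if (inherits(m, "ma_map")) m$values else m)
  B <- as.integer(floor(1 / bin_width)) + 1L
  hists <- lapply(arrs, function(a) {
    v <- as.numeric(a)[grid$mask_idx]
    idx <- pmin(as.integer(floor(v / bin_width + 0.5)), B - 1L)
    tab <- tabulate(idx + 1L, nbins = B)
    nz <- which(tab > 0L)
    list(idx = nz - 1L, probs = tab[nz] / length(v))
  })
  probs <- numeric(B)
  probs[hists[[1]]$idx + 1L] <- hists[[1]]$probs
  for (h in hists[-1])
    probs <- combine_null_cpp(probs, h$idx, h$probs, bin_width)
  structure(list(bin_edges = (seq_len(B) - 1L) * bin_width,
                 probabilities = probs, bin_width = bin_width),
            class = "ale_null")
}

#' Survival function of an ALE null
#'
#' @param null An [analytic_null()] result.
#' @return Numeric vector: `P(ALE >= bin_edges[i])` for each bin.
#' @export
null_survival <- function(null) {
  rev(cumsum(rev(null$probabilities)))
}

#' Convert ALE scores to uncorrected p and z maps
#'
#' `p(v)` is the null survival probability at the floor bin of `ALE(v)`
#' (right-continuous, conservative at bin edges). `z` is the standard-normal
#' quantile of `1 - p`, with `p` clamped to the null's own resolution — the
#' smallest positive survival mass — so z is always finite.
#'
#' @param ale Numeric array or vector of ALE scores.
#' @param null An [analytic_null()] result.
#' @return List with `p` and `z`, each shaped like `ale`.
#' @export
ale_to_p <- function(ale, null) {
  surv <- null_survival(null)
  B <- length(surv)
  idx <- pmin(as.integer(floor(as.numeric(ale) / null$bin_width + 1e-9)),
              B - 1L) + 1L
  p <- surv[idx]
  p_min <- max(min(surv[surv > 0]), .Machine$double.xmin)
  p_capped <- pmin(pmax(p, p_min), 1 - .Machine$double.eps)
  z <- stats::qnorm(p_capped, lower.tail = FALSE)
  if (!is.null(dim(ale))) {
    p <- array(p, dim = dim(ale))
    z <- array(z, dim = dim(ale))
  }
  list(p = p, z = z)
}

# smallest ALE value (bin left edge) whose floor-bin survival is < p;
# +Inf if no bin reaches it
ale_cutoff <- function(null, p) {
  surv <- null_survival(null)
  i <- which(surv < p)
  if (!length(i)) return(Inf)
  (i[1] - 1L) * null$bin_width
}
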