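# Ks-distribution summaries: block-median Ks values, Gaussian-mixture peak
# fitting by expectation-maximization, and molecular-clock divergence dating
# anchored on the core eudicot-common hexaploidy (ECH).

#' Block-median Ks values
#'
#' One value per collinear block: the median of its anchors' Ks values.
#' Saturated (`NA`) anchors are excluded; blocks with no finite anchor Ks are
#' omitted.
#'
#' @param blocks [chain_collinear_blocks()] result.
#' @param ks named numeric vector of per-anchor Ks, names
#'   `"<gene_a>|<gene_b>"` (see [anchor_key()]).
#' @return numeric vector of block medians.
#' @export
ks_distribution <- function(blocks, ks) {
  vals <- vapply(blocks, function(b) {
    k <- ks[anchor_key(b$anchors$gene_a, b$anchors$gene_b)]
    k <- k[is.finite(k)]
    if (length(k) == 0) NA_real_ else stats::median(k)
  }, numeric(1))
  vals[!is.na(vals)]
}

#' Anchor pair key
#'
#' @param gene_a,gene_b gene id vectors.
#' @return `"<gene_a>|<gene_b>"` character vector, used to index per-anchor
#'   Ks maps.
#' @export
anchor_key <- function(gene_a, gene_b) paste(gene_a, gene_b, sep = "|")

#' Fit Gaussian peaks to a Ks distribution
#'
#' Classic univariate Gaussian mixture fitted by expectation-maximization;
#' initialization is a seeded k-means so results are deterministic given the
#' seed. Components are reported in the `mu (± sigma)` convention of genome
#' papers, sorted by `mu`.
#'
#' @param values finite Ks values (at least 50, and at least
#'   `10 * n_components`).
#' @param n_components number of mixture components (>= 1).
#' @param seed integer seed for initialization.
#' @param range optional `c(lo, hi)` restricting the fit to values inside.
#' @param max_iter,tol EM iteration controls.
#' @return data.frame of class `"ks_peaks"` with columns `mu`, `sigma`,
#'   `weight` (weights sum to 1), sorted by `mu`.
#' @export
fit_ks_peaks <- function(values, n_components = 1, seed = 1, range = NULL,
                         max_iter = 1000, tol = 1e-10) {
  x <- values[is.finite(values)]
  if (!is.null(range)) x <- x[x >= range[1] & x <= range[2]]
  k <- as.integer(n_components)
  if (k < 1) stop("n_components must be >= 1")
  if (length(x) < 50) stop("need at least 50 finite Ks values")
  if (length(x) < 10 * k)
    stop("need at least 10 values per mixture component")
  if (stats::sd(x) == 0) stop("degenerate input: zero variance")

  init <- with_seed(seed, stats::kmeans(x, centers = k, nstart = 10))
  mu <- as.numeric(init$centers)
  ord <- order(mu)
  mu <- mu[ord]
  grp <- match(init$cluster, ord)
  sigma <- vapply(seq_len(k), function(j) {
    s <- stats::sd(x[grp == j])
    if (is.na(s) || s < 1e-4) stats::sd(x) / k else s
  }, numeric(1))
  w <- tabulate(grp, k) / length(x)

  loglik <- -Inf
  for (it in seq_len(max_iter)) {
    dens <- vapply(seq_len(k),
                   function(j) w[j] * stats::dnorm(x, mu[j], sigma[j]),
                   numeric(length(x)))
    dens <- matrix(dens, ncol = k)
    tot <- rowSums(dens)
    tot[tot < .Machine$double.xmin] <- .Machine$double.xmin
    ll <- sum(log(tot))
    resp <- dens / tot
    nk <- colSums(resp)
    w <- nk / length(x)
    mu <- colSums(resp * x) / nk
    sigma <- sqrt(colSums(resp * (outer(x, mu, "-")^2)) / nk)
    sigma <- pmax(sigma, 1e-6)
    if (is.finite(loglik) && abs(ll - loglik) < tol) break
    loglik <- ll
  }
  ord <- order(mu)
  out <- data.frame(mu = mu[ord], sigma = sigma[ord], weight = w[ord])
  class(out) <- c("ks_peaks", "data.frame")
  attr(out, "n") <- length(x)
  out
}

#' Format a fitted peak as `mu (± sigma)`
#'
#' @param peaks [fit_ks_peaks()] result.
#' @return character vector, e.g. `"1.25 (± 0.135)"`.
#' @export
format_ks_peaks <- function(peaks) {
  sprintf("%.2f (± %.3f)", peaks$mu, peaks$sigma)
}

#' @export
print.ks_peaks <- function(x, ...) {
  cat("Ks peaks:", paste(format_ks_peaks(x), collapse = ", "), "\n")
  invisible(x)
}

#' Molecular-clock divergence dating against the ECH anchor
#'
#' Linear calibration: `T = ks_ortho * t_ech / ks_ech` (Mya). With the ECH
#' dated at ~130 Mya and ECH-paralog Ks ~1.25-1.29, ortholog Ks ~0.025-0.026
#' places the grape species splits at ~2.3-2.8 Mya.
#'
#' @param ks_ortho ortholog-peak Ks (>= 0).
#' @param ks_ech ECH-paralog-peak Ks (> 0).
#' @param t_ech_mya age of the ECH in Mya (default 130).
#' @return list of class `"divergence_estimate"` with `T_mya` and the echoed
#'   inputs.
#' @export
calibrate_divergence <- function(ks_ortho, ks_ech, t_ech_mya = 130) {
  if (ks_ech <= 0) stop("ks_ech must be > 0")
  if (t_ech_mya <= 0) stop("t_ech_mya must be > 0")
  if (ks_ortho < 0) stop("ks_ortho must be >= 0")
  structure(list(T_mya = ks_ortho * t_ech_mya / ks_ech,
                 ks_ortho = ks_ortho, ks_ech = ks_ech,
                 t_ech_mya = t_ech_mya),
            class = "divergence_estimate")
}

#' @export
print.divergence_estimate <- function(x, ...) {
  cat(sprintf("divergence ~%.2f Mya (Ks_ortho %.4g / Ks_ECH %.4g, ECH %g Mya)\n",
              x$T_mya, x$ks_ortho, x$ks_ech, x$t_ech_mya))
  invisible(x)
}

#' Divergence-time range over Ks ranges
#'
#' Maps `[min, max]` ranges of the ortholog and ECH peak Ks to the implied
#' `[T_min, T_max]` band.
#'
#' @param ks_ortho_range,ks_ech_range numeric vectors of candidate peak
#'   values.
#' @param t_ech_mya ECH age in Mya.
#' @return named numeric `c(T_min, T_max)`.
#' @export
calibrate_divergence_range <- function(ks_ortho_range, ks_ech_range,
                                       t_ech_mya = 130) {
  grid <- outer(ks_ortho_range, ks_ech_range,
                function(o, e) o * t_ech_mya / e)
  c(T_min = min(grid), T_max = max(grid))
}
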