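#' Specify a planar point process
#'
#' @param kind `"csr"` (homogeneous Poisson / binomial when `nPoints` is
#'   fixed) or `"thomas"` (Poisson cluster process: Poisson parents,
#'   Poisson(`mu`) offspring displaced by an isotropic Gaussian of sd
#'   `sigmaUm`).
#' @param window a [Window-class].
#' @param nPoints fixed CSR count (overrides `intensity`).
#' @param intensity CSR intensity, points per um^2.
#' @param kappa Thomas parent intensity, parents per um^2.
#' @param mu Thomas mean offspring per parent.
#' @param sigmaUm Thomas offspring dispersion, um.
#' @param seed integer seed; the same seed reproduces the same pattern.
#' @return a [PointPatternSpec-class].
#' @export
pointPatternSpec <- function(kind = c("csr", "thomas"),
                             window = imageWindow(),
                             nPoints = NA, intensity = NA,
                             kappa = NA, mu = NA, sigmaUm = NA,
                             seed = 1L) {
  kind <- match.arg(kind)
  new("PointPatternSpec", kind = kind, nPoints = as.numeric(nPoints),
      intensity = as.numeric(intensity), kappa = as.numeric(kappa),
      mu = as.numeric(mu), sigmaUm = as.numeric(sigmaUm),
      window = window, seed = as.numeric(seed))
}

#' Simulate a point pattern
#'
#' CSR patterns are uniform in the window (with either a fixed count or a
#' Poisson count at the stated intensity). Thomas patterns simulate parents
#' on a window expanded by 4 `sigmaUm` on every side, so that clusters
#' whose parents fall just outside the field still contribute offspring,
#' and keep only offspring falling inside the window; the expected retained
#' count is `kappa * mu * area`. Values of the pair correlation near 1
#' indicate a random arrangement; the Thomas process provides the clustered
#' alternative with closed form
#' \eqn{g(r) = 1 + \exp(-r^2/(4\sigma^2)) / (4\pi\kappa\sigma^2)}.
#'
#' @param spec a [PointPatternSpec-class].
#' @return data.frame with `xUm`, `yUm` (and, for Thomas, `parent` id).
#' @export
simulatePointPattern <- function(spec) {
  stopifnot(is(spec, "PointPatternSpec"))
  validObject(spec)
  w <- spec@window
  withr::with_seed(as.integer(spec@seed), {
    if (spec@kind == "csr") {
      n <- if (!is.na(spec@nPoints)) as.integer(spec@nPoints)
           else stats::rpois(1, spec@intensity * windowArea(w))
      data.frame(xUm = stats::runif(n, 0, w@widthUm),
                 yUm = stats::runif(n, 0, w@heightUm))
    } else {
      pad <- 4 * spec@sigmaUm
      exW <- w@widthUm + 2 * pad
      exH <- w@heightUm + 2 * pad
      nPar <- stats::rpois(1, spec@kappa * exW * exH)
      px <- stats::runif(nPar, -pad, w@widthUm + pad)
      py <- stats::runif(nPar, -pad, w@heightUm + pad)
      nOff <- stats::rpois(nPar, spec@mu)
      parent <- rep.int(seq_len(nPar), nOff)
      x <- rep.int(px, nOff) + stats::rnorm(sum(nOff), 0, spec@sigmaUm)
      y <- rep.int(py, nOff) + stats::rnorm(sum(nOff), 0, spec@sigmaUm)
      keep <- x >= 0 & x <= w@widthUm & y >= 0 & y <= w@heightUm
      data.frame(xUm = x[keep], yUm = y[keep], parent = parent[keep])
    }
  })
}

#' Closed-form Thomas pair correlation
#'
#' \eqn{g(r) = 1 + \exp(-r^2/(4\sigma^2)) / (4\pi\kappa\sigma^2)}; the CSR
#' limit is the constant 1.
#'
#' @param r radii, um.
#' @param kappa parent intensity, parents per um^2.
#' @param sigmaUm offspring dispersion, um.
#' @export
thomasPcf <- function(r, kappa, sigmaUm) {
  1 + exp(-r^2 / (4 * sigmaUm^2)) / (4 * pi * kappa * sigmaUm^2)
}
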