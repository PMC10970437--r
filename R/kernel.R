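#' Gaussian kernel weight between two drug-sensitivity values
#'
#' Weight given to a cell line with sensitivity `m_i` when estimating the
#' network of a cell line with sensitivity `m_alpha`:
#' `exp(-(m_i - m_alpha)^2 / bandwidth)`.  The bandwidth is on the squared
#' scale of the sensitivity values, so rescaling all sensitivities by a
#' factor `c` corresponds to rescaling the bandwidth by `c^2`.
#'
#' @param m_i Sensitivity value(s) of the weighted cell line(s); vectorized.
#' @param m_alpha Sensitivity value of the cell line whose network is being
#'   estimated.
#' @param bandwidth Positive kernel bandwidth (squared-sensitivity units).
#' @return Weights in `(0, 1]`, symmetric in `m_i` and `m_alpha`.
#' @examples
#' gaussian_kernel(1, 0, 1)   # exp(-1)
#' @export
gaussian_kernel <- function(m_i, m_alpha, bandwidth) {
  if (!is.numeric(bandwidth) || length(bandwidth) != 1L ||
      !is.finite(bandwidth) || bandwidth <= 0) {
    stop("'bandwidth' must be a single positive number", call. = FALSE)
  }
  exp(-(m_i - m_alpha)^2 / bandwidth)
}

#' Select the kernel bandwidth from the sensitivity profile
#'
#' Chooses the bandwidth so that the effective sample size of the kernel
#' weights, `sum_i K(m_i - m_alpha | b)` averaged over all cell lines
#' `alpha`, equals `fraction * n`.  The effective sample size is strictly
#' increasing in `b`, so the equation is solved by bisection on `log(b)`.
#'
#' @param m Numeric vector of sensitivity values (one per cell line).
#' @param fraction Target mean effective sample size as a fraction of `n`;
#'   default 1/3.
#' @param tol Relative tolerance on the achieved effective sample size.
#' @return The selected bandwidth (squared-sensitivity units).  If the
#'   requested effective sample size is (numerically) `n`, i.e. every cell
#'   line must receive full weight, the bandwidth diverges; a capped maximum
#'   is returned with a warning.
#' @export
select_bandwidth <- function(m, fraction = 1 / 3, tol = 1e-4) {
  m <- as.numeric(m)
  if (anyNA(m) || any(!is.finite(m))) stop("'m' contains non-finite values")
  if (length(unique(m)) < 3L) {
    stop("need at least 3 distinct sensitivity values to select a bandwidth")
  }
  if (fraction <= 0 || fraction > 1) stop("'fraction' must be in (0, 1]")
  n <- length(m)
  target <- fraction * n
  d2 <- outer(m, m, "-")^2
  ess <- function(b) mean(colSums(exp(-d2 / b)))
  span <- diff(range(m))
  b_cap <- (1e4 * span)^2
  if (target >= n * (1 - 1e-9) || ess(b_cap) < target) {
    warning("requested effective sample size needs an unbounded bandwidth; ",
            "returning capped maximum")
    return(b_cap)
  }
  lo <- (1e-8 * span)^2
  # as b -> 0 the effective sample size tends to the mean multiplicity of
  # the m values (>= 1); a target at or below that floor is unattainable
  if (target <= ess(lo)) {
    warning("target effective sample size at the attainable minimum; ",
            "returning minimal bandwidth")
    return(lo)
  }
  hi <- b_cap
  for (iter in 1:200) {
    mid <- exp((log(lo) + log(hi)) / 2)
    if (ess(mid) < target) lo <- mid else hi <- mid
    if (abs(ess(mid) - target) < tol * target) break
  }
  exp((log(lo) + log(hi)) / 2)
}
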