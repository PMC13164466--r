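#' @title Validation statistics
#' @description The statistics reported for each of the four compound sets
#'   (determination coefficient, MAE, IIC, CII, leave-one-out Q2, the
#'   external-validation Q2F family, averaged rm2, Fisher F) and the two
#'   Monte Carlo target functions built from them.
#' @name metrics
NULL

.check_pairs <- function(observed, calculated, min_n = 2L) {
  stopifnot(length(observed) == length(calculated))
  if (length(observed) < min_n) {
    stop("need at least ", min_n, " observation pairs")
  }
  if (!all(is.finite(observed)) || !all(is.finite(calculated))) {
    stop("non-finite values in prediction set")
  }
  invisible(NULL)
}

#' Determination coefficient
#'
#' Squared Pearson correlation of observed vs calculated values.
#'
#' @param observed,calculated Numeric vectors of equal length.
#' @return R-squared in \[0, 1\].
#' @export
r2 <- function(observed, calculated) {
  .check_pairs(observed, calculated)
  if (stats::var(observed) == 0 || stats::var(calculated) == 0) {
    stop("zero variance: determination coefficient undefined")
  }
  stats::cor(observed, calculated)^2
}

# R^2 for target-function evaluation: a constant prediction vector explains
# nothing, so it scores 0 instead of erroring mid-optimization.
.safe_r2 <- function(observed, calculated) {
  if (stats::var(observed) == 0 || stats::var(calculated) == 0) return(0)
  stats::cor(observed, calculated)^2
}

#' Mean absolute error
#'
#' @inheritParams r2
#' @return Mean of |observed - calculated|.
#' @export
mae <- function(observed, calculated) {
  .check_pairs(observed, calculated, min_n = 1L)
  mean(abs(observed - calculated))
}

#' Index of ideality of correlation (IIC)
#'
#' The Pearson correlation scaled by the balance of negative-side and
#' positive-side mean absolute residuals,
#' `r * min(MAE-, MAE+) / max(MAE-, MAE+)`, where residuals are
#' `observed - calculated`, MAE- averages over strictly negative residuals
#' and MAE+ over non-negative ones. One-sided residuals give IIC = 0; a
#' perfect fit gives IIC = r. IIC inherits the sign of r.
#'
#' @inheritParams r2
#' @return IIC value, |IIC| <= |r| <= 1.
#' @export
iic <- function(observed, calculated) {
  .check_pairs(observed, calculated)
  r <- if (stats::var(observed) == 0 || stats::var(calculated) == 0) {
    stop("zero variance: correlation undefined")
  } else {
    stats::cor(observed, calculated)
  }
  d <- observed - calculated
  neg <- d < 0
  mae_neg <- if (any(neg)) mean(abs(d[neg])) else 0
  mae_pos <- if (any(!neg)) mean(abs(d[!neg])) else 0
  lo <- min(mae_neg, mae_pos)
  hi <- max(mae_neg, mae_pos)
  ratio <- if (hi == 0) 1 else lo / hi
  r * ratio
}

# IIC for target-function evaluation (0 on degenerate input).
.safe_iic <- function(observed, calculated) {
  if (stats::var(observed) == 0 || stats::var(calculated) == 0) return(0)
  iic(observed, calculated)
}

#' Correlation intensity index (CII)
#'
#' `1 - sum over k of max(0, R2(-k) - R2)`, where `R2(-k)` is the
#' determination coefficient of the n-1 pairs with the k-th removed. Each
#' positive term is the "protest" of a point that opposes the correlation;
#' collinear data has no protests and CII = 1. A leave-one-out subset with
#' zero variance contributes 0.
#'
#' @inheritParams r2
#' @return CII value, always <= 1.
#' @export
cii <- function(observed, calculated) {
  .check_pairs(observed, calculated, min_n = 3L)
  r2_full <- r2(observed, calculated)
  # Center on full-set means: subset correlations are shift-invariant and
  # the centered running sums are numerically well conditioned.
  o <- observed - mean(observed)
  c_ <- calculated - mean(calculated)
  n <- length(o)
  so <- sum(o);  sc <- sum(c_)
  soo <- sum(o^2); scc <- sum(c_^2); soc <- sum(o * c_)
  n1 <- n - 1L
  so_k <- so - o;   sc_k <- sc - c_
  soo_k <- soo - o^2; scc_k <- scc - c_^2; soc_k <- soc - o * c_
  num <- (n1 * soc_k - so_k * sc_k)^2
  den <- (n1 * soo_k - so_k^2) * (n1 * scc_k - sc_k^2)
  r2_k <- ifelse(den <= 0, 0, num / den)
  1 - sum(pmax(0, r2_k - r2_full))
}

.safe_cii <- function(observed, calculated) {
  if (stats::var(observed) == 0 || stats::var(calculated) == 0) return(0)
  cii(observed, calculated)
}

#' Leave-one-out cross-validated Q2
#'
#' For the univariate model `y = c0 + c1 x`: `1 - PRESS / SS_tot`, PRESS
#' summing squared leave-one-out prediction errors of the refit line
#' (computed through the hat-matrix identity `e_i / (1 - h_i)`).
#'
#' @param y Endpoints.
#' @param x Descriptor values.
#' @return Q2 <= 1.
#' @export
q2_loo <- function(y, x) {
  .check_pairs(y, x, min_n = 3L)
  n <- length(y)
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop("degenerate descriptor: zero variance")
  cf <- fit_line(y, x)
  e <- y - (cf[["c0"]] + cf[["c1"]] * x)
  h <- 1 / n + (x - mean(x))^2 / sxx
  if (any(1 - h < 1e-12)) stop("degenerate leave-one-out refit")
  press <- sum((e / (1 - h))^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) stop("constant endpoints: Q2 undefined")
  1 - press / ss_tot
}

#' External-validation Q2F family
#'
#' The three external predictivity criteria for a validation-type set scored
#' against a model trained elsewhere:
#' `Q2F1 = 1 - SSE / sum((y_ext - mean(y_train))^2)`,
#' `Q2F2 = 1 - SSE / sum((y_ext - mean(y_ext))^2)`,
#' `Q2F3 = 1 - (SSE / n_ext) / (SS_train / n_train)`,
#' with `SSE = sum((y_ext - yhat_ext)^2)` and `SS_train` the centered sum of
#' squares of the training endpoints.
#'
#' @param observed,calculated External-set observed and predicted endpoints.
#' @param y_train Active-training-set endpoints (supplies the reference mean
#'   and variance).
#' @return Named numeric vector `q2f1`, `q2f2`, `q2f3`; a zero denominator
#'   yields `NA` for that member.
#' @export
q2f_family <- function(observed, calculated, y_train) {
  .check_pairs(observed, calculated)
  if (length(y_train) < 2L || stats::var(y_train) == 0) {
    stop("training endpoints must be non-constant")
  }
  sse <- sum((observed - calculated)^2)
  d1 <- sum((observed - mean(y_train))^2)
  d2 <- sum((observed - mean(observed))^2)
  ss_tr <- sum((y_train - mean(y_train))^2)
  c(q2f1 = if (d1 == 0) NA_real_ else 1 - sse / d1,
    q2f2 = if (d2 == 0) NA_real_ else 1 - sse / d2,
    q2f3 = 1 - (sse / length(observed)) / (ss_tr / length(y_train)))
}

.rm2_one_direction <- function(y, x) {
  if (stats::var(y) == 0 || stats::var(x) == 0) return(NA_real_)
  r2v <- stats::cor(y, x)^2
  sxx <- sum(x^2)
  if (sxx == 0) return(NA_real_)
  k <- sum(x * y) / sxx                       # through-origin slope
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(NA_real_)
  r02 <- 1 - sum((y - k * x)^2) / ss_tot
  delta <- abs(r2v - r02)
  if (delta < 1e-14) delta <- 0   # sqrt() would amplify float noise
  r2v * (1 - sqrt(delta))
}

#' Averaged rm2 metric
#'
#' `rm2 = r2 * (1 - sqrt(|r2 - r0^2|))` with `r0^2` the through-origin
#' determination coefficient, computed in both regression directions
#' (observed on calculated and calculated on observed) and averaged.
#'
#' @inheritParams r2
#' @return Mean rm2, <= r2; `NA` on degenerate fits.
#' @export
rm2_average <- function(observed, calculated) {
  .check_pairs(observed, calculated, min_n = 3L)
  mean(c(.rm2_one_direction(observed, calculated),
         .rm2_one_direction(calculated, observed)))
}

#' Fisher F-ratio of the univariate model
#'
#' `F = r2 (n - 2) / (1 - r2)`.
#'
#' @inheritParams r2
#' @return F value; `NA` when r2 = 1 (zero residual).
#' @export
f_ratio <- function(observed, calculated) {
  .check_pairs(observed, calculated, min_n = 3L)
  r2v <- r2(observed, calculated)
  n <- length(observed)
  if (1 - r2v <= 0) return(NA_real_)
  r2v * (n - 2L) / (1 - r2v)
}

#' Monte Carlo target function
#'
#' `TF = R2_A + R2_P - |R2_A - R2_P| + coefficient * index_C`, where the
#' index is IIC or CII evaluated on the calibration set. The absolute
#' difference term penalizes divergence between the active and passive
#' training sets; the coefficient defaults to the empirically chosen 0.3.
#'
#' @param r2_a,r2_p Determination coefficients on the active and passive
#'   training sets.
#' @param index_c Calibration-set IIC or CII.
#' @param coefficient Weight of the calibration index (default 0.3).
#' @return TF value.
#' @export
target_function <- function(r2_a, r2_p, index_c, coefficient = 0.3) {
  stopifnot(is.finite(r2_a), is.finite(r2_p), is.finite(index_c))
  r2_a + r2_p - abs(r2_a - r2_p) + coefficient * index_c
}
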