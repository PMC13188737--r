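# Partial least squares regression (NIPALS) with variable importance in
# projection, used to rank genes by their association with log CGE.

#' Fit a PLS regression of a single response on many predictors
#'
#' NIPALS decomposition after column mean-centering and (by default)
#' unit-variance scaling of the predictors; the response is mean-centered.
#' For a univariate response each component's weight vector is
#' `w = X'y / ||X'y||`, scores `t = Xw`, with X deflated by its rank-one
#' reconstruction. The number of components is chosen by minimizing
#' leave-one-out prediction error up to `max_ncomp` unless `ncomp` is given.
#'
#' @param x A numeric matrix or data frame of predictors (samples x
#'   variables), e.g. normalized gene expression with samples as rows.
#' @param y Numeric response vector (e.g. log CGE); must not be constant.
#' @param ncomp Number of components, or `NULL` to select by leave-one-out
#'   cross-validation.
#' @param scale Scale predictor columns to unit variance? (Constant columns
#'   are left centered only.)
#' @param max_ncomp Upper bound for cross-validated component selection.
#' @return An object of class `pls_cge`: list with `weights` (p x a),
#'   `scores`, `loadings`, `q` (y-loadings), `coefficients` (on the original
#'   predictor scale), `ss` (per-component explained sum of squares of y),
#'   `fitted`, `residuals`, `ncomp`, `press` (LOO PRESS per component count,
#'   when cross-validated), centering/scaling vectors, and the data
#'   dimensions.
#' @examples
#' x <- matrix(rnorm(60), 20, 3)
#' y <- x[, 1] + rnorm(20, sd = 0.1)
#' fit <- plsr_fit(x, y, ncomp = 2)
#' fit$ncomp
#' @export
plsr_fit <- function(x, y, ncomp = NULL, scale = TRUE, max_ncomp = 10) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  y <- as.numeric(y)
  if (!all(is.finite(x)) || !all(is.finite(y))) {
    abort("predictors and response must be finite")
  }
  n <- nrow(x)
  p <- ncol(x)
  if (length(y) != n) abort("length(y) must match nrow(x)")
  if (sd(y) == 0) abort("constant response: nothing to regress on")

  a_max <- min(max_ncomp, n - 1, p)
  press <- NULL
  if (is.null(ncomp)) {
    press <- .pls_loo_press(x, y, scale, a_max)
    ncomp <- which.min(press)
  }
  if (n < ncomp + 1) abort("need at least ncomp + 1 samples")

  fit <- .nipals(x, y, ncomp, scale)
  fit$press <- press
  fit
}

.nipals <- function(x, y, ncomp, scale) {
  n <- nrow(x)
  p <- ncol(x)
  x_center <- colMeans(x)
  xc <- sweep(x, 2, x_center)
  x_scale <- rep(1, p)
  if (scale) {
    s <- apply(xc, 2, sd)
    x_scale <- ifelse(s > 0, s, 1)
    xc <- sweep(xc, 2, x_scale, "/")
  }
  y_center <- mean(y)
  yc <- y - y_center

  w_mat <- matrix(0, p, ncomp)
  t_mat <- matrix(0, n, ncomp)
  p_mat <- matrix(0, p, ncomp)
  q <- numeric(ncomp)
  ss <- numeric(ncomp)
  xd <- xc
  yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(xd, yd)[, 1]
    nw <- sqrt(sum(w^2))
    if (nw == 0) {
      ncomp <- a - 1L
      break
    }
    w <- w / nw
    tt <- xd %*% w
    tt2 <- sum(tt^2)
    qa <- sum(yd * tt) / tt2
    pa <- crossprod(xd, tt)[, 1] / tt2
    w_mat[, a] <- w
    t_mat[, a] <- tt
    p_mat[, a] <- pa
    q[a] <- qa
    ss[a] <- qa^2 * tt2 # sum of squares of y explained by component a
    xd <- xd - tt %*% t(pa)
    yd <- yd - tt * qa
  }
  if (ncomp == 0) abort("predictors are orthogonal to the response")
  w_mat <- w_mat[, seq_len(ncomp), drop = FALSE]
  t_mat <- t_mat[, seq_len(ncomp), drop = FALSE]
  p_mat <- p_mat[, seq_len(ncomp), drop = FALSE]
  q <- q[seq_len(ncomp)]
  ss <- ss[seq_len(ncomp)]

  # coefficients on the scaled space, then back to original predictor units
  b_scaled <- w_mat %*% solve(crossprod(p_mat, w_mat), q)
  coefficients <- as.vector(b_scaled) / x_scale
  fitted <- as.vector(x %*% coefficients) +
    (y_center - sum(x_center * coefficients))

  structure(
    list(
      weights = w_mat, scores = t_mat, loadings = p_mat, q = q, ss = ss,
      coefficients = setNames(coefficients,
                              colnames(x) %||% paste0("x", seq_len(p))),
      intercept = y_center - sum(x_center * coefficients),
      fitted = fitted, residuals = y - fitted,
      ncomp = ncomp, n = n, p = p,
      x_center = x_center, x_scale = x_scale, y_center = y_center,
      scaled = scale
    ),
    class = "pls_cge"
  )
}

.pls_loo_press <- function(x, y, scale, a_max) {
  n <- nrow(x)
  errs <- matrix(NA_real_, n, a_max)
  for (i in seq_len(n)) {
    fit <- .nipals(x[-i, , drop = FALSE], y[-i], a_max, scale)
    for (a in seq_len(fit$ncomp)) {
      coefs <- .coef_at(fit, a)
      pred <- sum(x[i, ] * coefs$b) + coefs$b0
      errs[i, a] <- (y[i] - pred)^2
    }
    if (fit$ncomp < a_max) {
      errs[i, seq(fit$ncomp + 1, a_max)] <- errs[i, fit$ncomp]
    }
  }
  colSums(errs)
}

.coef_at <- function(fit, a) {
  w <- fit$weights[, seq_len(a), drop = FALSE]
  pm <- fit$loadings[, seq_len(a), drop = FALSE]
  b_scaled <- w %*% solve(crossprod(pm, w), fit$q[seq_len(a)])
  b <- as.vector(b_scaled) / fit$x_scale
  list(b = b, b0 = fit$y_center - sum(fit$x_center * b))
}

#' @export
print.pls_cge <- function(x, ...) {
  cat("<pls_cge>", x$ncomp, "component(s),", x$p, "predictors,",
      x$n, "samples; R2 =",
      round(1 - sum(x$residuals^2) / sum((x$fitted + x$residuals -
                                            mean(x$fitted + x$residuals))^2),
            3), "\n")
  invisible(x)
}

#' @export
predict.pls_cge <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  as.vector(newdata %*% object$coefficients) + object$intercept
}

#' Variable importance in projection scores
#'
#' `VIP_j = sqrt(p * sum_a SS_a * (w_ja / ||w_a||)^2 / sum_a SS_a)` where
#' `SS_a` is the response sum of squares explained by component `a` and
#' `w_a` its predictor weight vector. The scores satisfy
#' `sum_j VIP_j^2 = p`.
#'
#' @param model A `pls_cge` fit.
#' @return Named numeric vector of VIP scores, one per predictor.
#' @examples
#' x <- matrix(rnorm(40), 20, 2)
#' vip(plsr_fit(x, x[, 1] + rnorm(20, sd = .1), ncomp = 1))
#' @export
vip <- function(model) {
  stopifnot(inherits(model, "pls_cge"))
  if (sum(model$ss) == 0) abort("model explains no response variance")
  wn <- sweep(model$weights, 2,
              sqrt(colSums(model$weights^2)), "/")
  scores <- sqrt(model$p * as.vector(wn^2 %*% model$ss) / sum(model$ss))
  setNames(scores, names(model$coefficients))
}

#' Select the top decile of predictors by VIP
#'
#' Genes with VIP at or above the `1 - fraction` quantile of all VIP scores
#' are selected; ties at the threshold are all included (and noted). The
#' direction of each gene's association is the sign of its regression
#' coefficient.
#'
#' @param model A `pls_cge` fit.
#' @param fraction Fraction of predictors to select (default top 10%).
#' @return A tibble `gene`, `vip`, `coefficient`, `sign`, `selected`,
#'   sorted by decreasing VIP.
#' @export
select_top <- function(model, fraction = 0.10) {
  v <- vip(model)
  thr <- quantile(v, 1 - fraction, type = 7)
  sel <- v >= thr
  n_expect <- ceiling(fraction * length(v))
  if (sum(sel) > n_expect) {
    inform(sprintf("%d genes tie at the VIP threshold; all included",
                   sum(sel) - n_expect + sum(v == thr)))
  }
  tibble(
    gene = names(v),
    vip = unname(v),
    coefficient = unname(model$coefficients),
    sign = sign(unname(model$coefficients)),
    selected = unname(sel)
  ) |>
    arrange(desc(.data$vip))
}

#' @rdname pls_tidiers
#' @export
tidy.pls_cge <- function(x, ...) {
  tibble(
    term = names(x$coefficients),
    estimate = unname(x$coefficients),
    vip = unname(vip(x))
  )
}

#' Broom-style summaries of a PLS fit
#'
#' `tidy()` returns one row per predictor with its regression coefficient
#' (original predictor units) and VIP score; `glance()` returns a one-row
#' model summary.
#'
#' @param x A `pls_cge` fit.
#' @param ... Unused.
#' @return A tibble.
#' @name pls_tidiers
#' @export
glance.pls_cge <- function(x, ...) {
  y <- x$fitted + x$residuals
  tibble(
    ncomp = x$ncomp,
    n = x$n,
    p = x$p,
    r_squared = 1 - sum(x$residuals^2) / sum((y - mean(y))^2),
    press = if (is.null(x$press)) NA_real_ else min(x$press)
  )
}

#' @rdname pls_tidiers
#' @export
tidy <- function(x, ...) UseMethod("tidy")

#' @rdname pls_tidiers
#' @export
glance <- function(x, ...) UseMethod("glance")
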