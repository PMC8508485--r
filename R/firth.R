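#' Build a design matrix from a model frame
#'
#' @param frame A `model_frame` (or any tibble with the term columns).
#' @param terms Character vector of term columns to include.
#' @return Numeric matrix with an intercept column prepended.
#' @export
design_matrix <- function(frame, terms) {
  missing_terms <- setdiff(terms, names(frame))
  if (length(missing_terms) > 0) {
    abort(paste0("frame lacks term columns: ", paste(missing_terms, collapse = ", ")))
  }
  x <- as.matrix(frame[terms])
  storage.mode(x) <- "double"
  cbind(`(Intercept)` = 1, x)
}

# Penalized binomial log-likelihood l(beta) + 0.5 * log det I(beta).
firth_loglik <- function(x, y, beta) {
  eta <- drop(x %*% beta)
  # log(1 + e^eta) computed stably for large |eta|
  log1pe <- ifelse(eta > 30, eta, log1p(exp(pmin(eta, 30))))
  ll <- sum(y * eta - log1pe)
  w <- plogis(eta) * (1 - plogis(eta))
  info <- crossprod(x, x * w)
  ll + 0.5 * determinant(info, logarithm = TRUE)$modulus
}

#' Firth-penalised logistic regression
#'
#' Maximises the binomial log-likelihood plus the Jeffreys-prior penalty
#' `0.5 * log det I(beta)`, which removes the leading-order bias of maximum
#' likelihood and guarantees finite coefficients even under complete
#' separation. Fitting uses Fisher scoring on the modified score
#' `U*(beta) = X'(y - pi + h (1/2 - pi))`, where `h` is the diagonal of the
#' weighted hat matrix, with step-halving to keep the penalised likelihood
#' non-decreasing.
#'
#' @param x Design matrix including an intercept column (see
#'   [design_matrix()]).
#' @param y Logical or 0/1 outcome vector.
#' @param max_iter Maximum scoring iterations (default 50).
#' @param tol Convergence: largest absolute modified-score component below
#'   this (default 1e-6).
#' @param max_halving Maximum step-halvings per iteration (default 10).
#' @return Object of class `firth_fit`: coefficients, standard errors,
#'   covariance, convergence flag, iteration count, penalised log-likelihood.
#' @export
fit_firth <- function(x, y, max_iter = 50, tol = 1e-6, max_halving = 10) {
  x <- as.matrix(x)
  y <- as.numeric(y)
  if (nrow(x) != length(y)) abort("x and y sizes differ")
  if (nrow(x) < 1) abort("need at least one observation")
  qx <- qr(x)
  if (qx$rank < ncol(x)) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
    abort(paste0("design matrix is rank deficient; collinear columns: ",
      paste(bad, collapse = ", ")))
  }
  p <- ncol(x)
  beta <- rep(0, p)
  ll <- firth_loglik(x, y, beta)
  converged <- FALSE
  iter <- 0L
  info <- NULL
  for (iter in seq_len(max_iter)) {
    eta <- drop(x %*% beta)
    pi_hat <- plogis(eta)
    w <- pi_hat * (1 - pi_hat)
    info <- crossprod(x, x * w)
    xinv <- x %*% solve(info)
    h <- rowSums(xinv * x) * w
    score <- drop(crossprod(x, y - pi_hat + h * (0.5 - pi_hat)))
    if (max(abs(score)) < tol) {
      converged <- TRUE
      break
    }
    delta <- solve(info, score)
    step <- 1
    for (half in 0:max_halving) {
      cand <- beta + step * delta
      ll_new <- firth_loglik(x, y, cand)
      if (is.finite(ll_new) && ll_new >= ll - 1e-12) break
      step <- step / 2
    }
    beta <- cand
    ll <- ll_new
  }
  if (!converged) {
    warn("Firth fit did not converge; returning the last iterate")
  }
  vcov <- solve(info)
  names(beta) <- colnames(x)
  dimnames(vcov) <- list(colnames(x), colnames(x))
  structure(
    list(
      coefficients = beta,
      se = sqrt(diag(vcov)),
      vcov = vcov,
      converged = converged,
      iterations = iter,
      loglik = as.numeric(ll),
      n = nrow(x),
      terms = colnames(x)
    ),
    class = "firth_fit"
  )
}

#' Predicted probabilities from a Firth fit
#'
#' @param fit A `firth_fit`.
#' @param newdata Design matrix (with intercept column) or numeric vector of
#'   one row; column count must match the fit.
#' @return Probabilities strictly inside (0, 1).
#' @export
predict_prob <- function(fit, newdata) {
  if (is.vector(newdata)) newdata <- matrix(newdata, nrow = 1)
  if (ncol(newdata) != length(fit$coefficients)) {
    abort(paste0(
      "design has ", ncol(newdata), " columns but the fit has ",
      length(fit$coefficients), " coefficients"
    ))
  }
  plogis(drop(newdata %*% fit$coefficients))
}

#' @export
print.firth_fit <- function(x, ...) {
  cat("Firth-penalised logistic fit (", x$n, " obs, ",
    length(x$coefficients), " coefficients)\n",
    sep = ""
  )
  cat(if (x$converged) "converged" else "NOT converged",
    " in ", x$iterations, " iterations; penalised logLik = ",
    format(x$loglik, digits = 6), "\n",
    sep = ""
  )
  print(round(x$coefficients, 4))
  invisible(x)
}

#' Tidy a Firth fit
#'
#' @param x A `firth_fit`.
#' @param ... Unused.
#' @return Tibble with `term`, `estimate`, `std.error`, `odds.ratio`.
#' @export
tidy.firth_fit <- function(x, ...) {
  tibble::tibble(
    term = x$terms,
    estimate = unname(x$coefficients),
    std.error = unname(x$se),
    odds.ratio = exp(unname(x$coefficients))
  )
}

#' Glance at a Firth fit
#'
#' @param x A `firth_fit`.
#' @param ... Unused.
#' @return One-row tibble with fit-level summaries.
#' @export
glance.firth_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik,
    converged = x$converged,
    iterations = x$iterations,
    nobs = x$n,
    df = length(x$coefficients)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
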