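# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Deterministic sub-seed per pipeline stage; kept within 32-bit integer range.
derive_seed <- function(seed, offset) {
  as.integer((as.double(seed) + 7919 * as.double(offset)) %% 2147483646) + 1L
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x) && x >= 1 && x == floor(x)

# Column-standardize a dosage matrix; monomorphic columns become all-zero
# (flagged via the "monomorphic" attribute) rather than NaN.
standardize_dosages <- function(D) {
  mu <- colMeans(D)
  sdv <- apply(D, 2L, stats::sd)
  mono <- sdv == 0 | is.na(sdv)
  sdv[mono] <- 1
  S <- sweep(D, 2L, mu, "-")
  S <- sweep(S, 2L, sdv, "/")
  S[, mono] <- 0
  attr(S, "monomorphic") <- mono
  S
}

# Newton-Raphson logistic regression on a small fixed design. Returns
# coefficients and observed-information standard errors, or NULL on
# divergence / separation; callers fall back to stats::glm.fit. Much lighter
# than the formula interface, which matters in the pathway scan where
# thousands of three-column fits are run.
fast_logistic <- function(X, y) {
  p <- ncol(X)
  beta <- numeric(p)
  pbar <- min(max(mean(y), 1e-6), 1 - 1e-6)
  beta[1] <- stats::qlogis(pbar)
  XtWX <- NULL
  converged <- FALSE
  for (it in seq_len(30L)) {
    eta <- as.vector(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    XtWX <- crossprod(X, X * w)
    delta <- tryCatch(solve(XtWX, crossprod(X, y - mu)),
                      error = function(e) NULL)
    if (is.null(delta) || !all(is.finite(delta))) return(NULL)
    beta <- beta + as.vector(delta)
    if (max(abs(beta)) > 1e3) return(NULL)
    if (max(abs(delta)) < 1e-8) {
      converged <- TRUE
      break
    }
  }
  if (!converged) return(NULL)
  eta <- as.vector(X %*% beta)
  mu <- stats::plogis(eta)
  if (max(mu) > 1 - 1e-10 || min(mu) < 1e-10) return(NULL)
  XtWX <- crossprod(X, X * (mu * (1 - mu)))
  V <- tryCatch(solve(XtWX), error = function(e) NULL)
  if (is.null(V) || any(!is.finite(diag(V))) || any(diag(V) <= 0)) return(NULL)
  list(coef = beta, se = sqrt(diag(V)))
}

# Weighted least squares on a two-column design (intercept + x); returns
# c(intercept, slope). Small helper used by the LD score regressions.
wls_fit <- function(x, y, w) {
  X <- cbind(1, x)
  fit <- stats::lm.wfit(X, y, w)
  if (fit$rank < 2L) {
    stopf("rank-deficient regression: predictor has no variation")
  }
  unname(fit$coefficients)
}
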