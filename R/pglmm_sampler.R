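## The MCMC engine. All three families share one gaussian mixed-model core
## operating on a working response w:
##   gaussian    w = y
##   probit      w = latent liability, truncated-normal data augmentation
##               (sign of the liability matches the observed 0/1 outcome)
##   zt_poisson  w = latent log-rate, Metropolis updates against the
##               zero-truncated Poisson likelihood with an adaptive
##               random-walk step tuned during burn-in
## Conditional on w the model is linear:
##   w = X beta + sum_k xi_k Z_k u_k + e,  e ~ N(0, sig2_e I)
## with u_k ~ N(0, sig2_k K_k) and parameter expansion: the scalar xi_k is
## updated jointly with beta as a regression coefficient on the column
## Z_k u_k, so the effective variance component is xi_k^2 * sig2_k and the
## implied prior on the effective standard deviation is approximately
## half-Cauchy ("roughly uniform").

## sums of x per level of idx, over exactly nlev levels. `perm` may carry
## the precomputed first-appearance order of the levels (`unique(idx)`),
## which is what rowsum(reorder = FALSE) returns groups in.
level_sums <- function(x, idx, nlev, perm = NULL) {
  out <- numeric(nlev)
  s <- rowsum(x, idx, reorder = FALSE)
  if (is.null(perm)) perm <- as.integer(rownames(s))
  out[perm] <- s
  out
}

draw_inv_gamma <- function(shape, rate) 1 / stats::rgamma(1L, shape, rate = rate)

## one draw from N(P^-1 b, P^-1) given precision P (dense, symmetric p.d.)
draw_gaussian_precision <- function(P, b) {
  R <- chol(P)
  backsolve(R, backsolve(R, b, transpose = TRUE) + stats::rnorm(ncol(P)))
}

## truncated-normal draws: sign(w - 0) must match y (1 -> positive).
## Inverse-CDF draw; the finite clamp stays inside the truncation region.
draw_liability <- function(y, mu, sd) {
  p0 <- stats::pnorm(0, mean = mu, sd = sd)
  u <- ifelse(y == 1,
              stats::runif(length(y), p0, 1),
              stats::runif(length(y), 0, p0))
  u <- pmin(pmax(u, 1e-15), 1 - 1e-15)
  w <- pmin(pmax(stats::qnorm(u, mean = mu, sd = sd), mu - 8 * sd), mu + 8 * sd)
  ifelse(y == 1, pmax(w, 0), pmin(w, 0))
}

## zero-truncated Poisson log-likelihood of latent log-rate w given y >= 1
ztp_loglik_latent <- function(y, w) {
  lam <- exp(w)
  denom <- if (any(lam < .Machine$double.xmin))
    pmax(lam, .Machine$double.xmin) else lam
  y * w - lam - log1mexp(denom)
}

#' Draw from the posterior of a PGLMM
#'
#' Runs the Gibbs/Metropolis sampler described in the package vignette:
#' conjugate updates for fixed effects and random-effect vectors,
#' parameter-expanded variance-component updates, inverse-gamma residual
#' update, truncated-normal data augmentation for the probit family and
#' adaptive Metropolis latent updates for the zero-truncated Poisson
#' family. Chains are bit-reproducible given the seed in
#' `spec$mcmc$seed`.
#'
#' @param design a [build_design()] result (or any `design_data`).
#' @param spec the [model_spec()] used to build it.
#' @return an object of class `posterior_chain`: matrices `beta`
#'   (retained samples x fixed effects) and `vc` (variance components
#'   `sig2_<term>` plus `sig2_resid`), the Metropolis `accept_rate`
#'   (zt_poisson only), `n_dropped`, `separation`, and the settings echo.
#' @export
sample_posterior <- function(design, spec) {
  stopifnot(inherits(design, "design_data"))
  pr <- spec$priors
  mc <- spec$mcmc
  set.seed(mc$seed)

  y <- design$y
  X <- design$X
  n <- length(y)
  p <- ncol(X)
  terms <- design$terms
  K <- length(terms)
  family <- design$family
  fix_resid <- pr$fix_resid

  ## per-term covariance inverses (identity terms have K = NULL)
  Kinv <- vector("list", K)
  for (k in seq_len(K)) {
    if (!is.null(terms[[k]]$K)) {
      Kk <- terms[[k]]$K
      R <- tryCatch(chol(Kk), error = function(e)
        stop("decomposition error: covariance for term '",
             terms[[k]]$label, "' is not positive definite"))
      Kinv[[k]] <- chol2inv(R)
    }
  }
  nlev <- vapply(terms, function(t) length(t$levels), 0L)
  idx <- lapply(terms, `[[`, "index")
  counts <- lapply(seq_len(K), function(k) tabulate(idx[[k]], nlev[k]))
  rows_of <- lapply(seq_len(K), function(k)
    split(seq_along(idx[[k]]), factor(idx[[k]], levels = seq_len(nlev[k]))))
  uperm <- lapply(idx, function(i) unique(i))

  ## initial state
  beta <- numeric(p)
  beta[1L] <- switch(family,
                     gaussian = mean(y),
                     probit = 0,
                     zt_poisson = log(max(mean(y), 1.01)))
  xi <- rep(1, K)
  u <- lapply(nlev, numeric)
  sig2_u <- rep(1, K)     # base variance of the working vector u_k
  sig2_e <- 1
  w <- switch(family,
              gaussian = y,
              probit = ifelse(y == 1, 0.5, -0.5),
              zt_poisson = log(pmax(y, 1)) + 0.05)
  step <- 0.5             # zt_poisson latent random-walk scale
  acc_n <- 0; acc_d <- 0
  ## cached zero-truncated log-likelihood of the current latents: every
  ## Metropolis comparison below then evaluates only its proposal side
  ll_w <- if (family == "zt_poisson") ztp_loglik_latent(y, w)
  iw_step <- rep(0.5, K + 1L)   # interweaving step sizes (intercept, terms)
  iw_acc <- integer(K + 1L); iw_try <- integer(K + 1L)

  n_store <- mc$iterations %/% mc$thin
  beta_out <- matrix(NA_real_, n_store, p, dimnames = list(NULL, colnames(X)))
  vc_names <- c(if (K > 0L) paste0("sig2_", names(terms)), "sig2_resid")
  vc_out <- matrix(NA_real_, n_store, K + 1L,
                   dimnames = list(NULL, vc_names))
  store_i <- 0L
  total_iter <- mc$burnin + mc$iterations
  XtX <- crossprod(X)
  prior_prec <- c(rep(1 / pr$beta_var, p), rep(1 / pr$px_alpha_var, K))
  D_prior <- diag(prior_prec, p + K)
  D_prior_fixed <- diag(prior_prec[seq_len(p)], p)
  y_of <- lapply(rows_of, lapply, function(r) y[r])
  rnorm <- stats::rnorm
  runif <- stats::runif

  ranef_part <- function() {
    out <- numeric(n)
    for (k in seq_len(K)) out <- out + xi[k] * u[[k]][idx[[k]]]
    out
  }

  for (iter in seq_len(total_iter)) {
    eta <- drop(X %*% beta) + ranef_part()

    ## -- family latent update ------------------------------------------
    if (family == "probit") {
      w <- draw_liability(y, eta, sqrt(sig2_e))
    } else if (family == "zt_poisson") {
      prop <- w + step * rnorm(n)
      ll_prop <- ztp_loglik_latent(y, prop)
      log_r <- ll_prop - ll_w -
        ((prop - eta)^2 - (w - eta)^2) / (2 * sig2_e)
      acc <- log(runif(n)) < log_r
      w[acc] <- prop[acc]
      ll_w[acc] <- ll_prop[acc]
      acc_n <- acc_n + sum(acc); acc_d <- acc_d + n
      if (iter <= mc$burnin && iter %% 100L == 0L) {
        rate <- acc_n / acc_d
        step <- min(5, max(0.02, step * exp(rate - 0.3)))
        acc_n <- 0; acc_d <- 0
      }
    }

    ## -- joint update of beta and expansion factors xi -----------------
    ## cross-products assembled blockwise: the X'X block never changes
    if (K > 0L) {
      C <- vapply(seq_len(K), function(k) u[[k]][idx[[k]]], numeric(n))
      if (is.null(dim(C))) C <- matrix(C, n, K)
      XtC <- crossprod(X, C)
      P <- rbind(cbind(XtX, XtC), cbind(t(XtC), crossprod(C))) / sig2_e +
        D_prior
      b <- c(crossprod(X, w), crossprod(C, w)) / sig2_e
    } else {
      P <- XtX / sig2_e + D_prior_fixed
      b <- crossprod(X, w) / sig2_e
    }
    theta <- draw_gaussian_precision(P, b)
    beta <- theta[seq_len(p)]
    xi <- theta[p + seq_len(K)]

    ## -- random-effect vectors ----------------------------------------
    Xb <- drop(X %*% beta)
    contrib <- lapply(seq_len(K), function(k) xi[k] * u[[k]][idx[[k]]])
    for (k in seq_len(K)) {
      r <- w - Xb
      for (j in seq_len(K)) if (j != k) r <- r - contrib[[j]]
      bk <- xi[k] * level_sums(r, idx[[k]], nlev[k], uperm[[k]]) / sig2_e
      diag_part <- xi[k]^2 * counts[[k]] / sig2_e
      if (is.null(Kinv[[k]])) {
        post_var <- 1 / (diag_part + 1 / sig2_u[k])
        u[[k]] <- post_var * bk + sqrt(post_var) * rnorm(nlev[k])
      } else {
        P_u <- Kinv[[k]] / sig2_u[k]
        diag(P_u) <- diag(P_u) + diag_part
        u[[k]] <- draw_gaussian_precision(P_u, bk)
      }
      contrib[[k]] <- xi[k] * u[[k]][idx[[k]]]
    }

    ## -- interweaving moves (zero-truncated Poisson only) --------------
    ## With a drug-level response repeated over trials, the residual
    ## variance collapses toward zero and the centred chain moves the
    ## latents w only O(sd_e) per iteration. These joint translations of
    ## a location parameter and the latents of the rows it touches leave
    ## the gaussian layer invariant (w - eta unchanged) and are accepted
    ## against the count likelihood and the effect's prior, restoring
    ## mixing of intercept and random-effect levels. Run on a schedule:
    ## the slowly mixing components they help (variance components, the
    ## intercept ridge) have autocorrelation times of hundreds of
    ## iterations, so every fifth iteration captures the benefit at a
    ## fraction of the cost.
    if (family == "zt_poisson" && iter %% 5L == 0L) {
      ## global shift of intercept and all latents
      s <- iw_step[1L] * rnorm(1L)
      ll_shift <- ztp_loglik_latent(y, w + s)
      log_r <- sum(ll_shift - ll_w) +
        ((beta[1L])^2 - (beta[1L] + s)^2) / (2 * pr$beta_var)
      if (log(runif(1L)) < log_r) {
        w <- w + s
        ll_w <- ll_shift
        beta[1L] <- beta[1L] + s
        Xb <- Xb + s
        iw_acc[1L] <- iw_acc[1L] + 1L
      }
      iw_try[1L] <- iw_try[1L] + 1L
      ## per-level shifts of each random term
      for (k in seq_len(K)) {
        if (abs(xi[k]) < 1e-12) next
        Kk <- Kinv[[k]]
        uk <- u[[k]]
        Ainv_u <- if (is.null(Kk)) uk else drop(Kk %*% uk)
        rk <- rows_of[[k]]
        sd_k <- iw_step[1L + k]
        for (lev in seq_len(nlev[k])) {
          rows <- rk[[lev]]
          if (!length(rows)) next
          s <- sd_k * rnorm(1L)
          du <- s / xi[k]
          Aii <- if (is.null(Kk)) 1 else Kk[lev, lev]
          dprior <- -(2 * du * Ainv_u[lev] + du^2 * Aii) / (2 * sig2_u[k])
          wr <- w[rows] + s
          ll_shift <- ztp_loglik_latent(y_of[[k]][[lev]], wr)
          log_r <- sum(ll_shift - ll_w[rows]) + dprior
          if (log(runif(1L)) < log_r) {
            w[rows] <- wr
            ll_w[rows] <- ll_shift
            uk[lev] <- uk[lev] + du
            if (is.null(Kk)) Ainv_u[lev] <- Ainv_u[lev] + du
            else Ainv_u <- Ainv_u + Kk[, lev] * du
            iw_acc[1L + k] <- iw_acc[1L + k] + 1L
          }
          iw_try[1L + k] <- iw_try[1L + k] + 1L
        }
        u[[k]] <- uk
        contrib[[k]] <- xi[k] * uk[idx[[k]]]
      }
      if (iter <= mc$burnin && iter %% 500L == 0L) {
        rate <- ifelse(iw_try > 0L, iw_acc / iw_try, 0.3)
        iw_step <- pmin(5, pmax(0.01, iw_step * exp(rate - 0.3)))
        iw_acc[] <- 0L; iw_try[] <- 0L
      }
    }

    ## -- variance components ------------------------------------------
    for (k in seq_len(K)) {
      quad <- if (is.null(Kinv[[k]])) sum(u[[k]]^2) else
        drop(crossprod(u[[k]], Kinv[[k]] %*% u[[k]]))
      sig2_u[k] <- draw_inv_gamma((pr$px_nu + nlev[k]) / 2,
                                  (pr$px_nu * pr$px_V + quad) / 2)
    }
    resid <- w - Xb
    for (k in seq_len(K)) resid <- resid - contrib[[k]]
    if (!fix_resid) {
      sig2_e <- draw_inv_gamma((pr$resid_nu + n) / 2,
                               (pr$resid_nu * pr$resid_V + sum(resid^2)) / 2)
    }

    ## -- store ---------------------------------------------------------
    post <- iter - mc$burnin
    if (post > 0L && post %% mc$thin == 0L) {
      store_i <- store_i + 1L
      beta_out[store_i, ] <- beta
      vc_out[store_i, ] <- c(xi^2 * sig2_u, sig2_e)
    }
    if (!all(is.finite(beta)) || any(!is.finite(sig2_u)) || sig2_e > 1e12)
      stop("divergent chain at iteration ", iter,
           ": variance overflow (sig2_e = ", format(sig2_e), ")")
  }

  structure(list(beta = beta_out, vc = vc_out,
                 accept_rate = if (family == "zt_poisson")
                   acc_n / max(acc_d, 1L) else NA_real_,
                 iw_accept = if (family == "zt_poisson")
                   ifelse(iw_try > 0L, iw_acc / iw_try, NA_real_) else NULL,
                 family = family, response = design$response,
                 fixed = design$fixed, n_dropped = design$n_dropped,
                 separation = design$separation,
                 settings = mc, priors = pr),
            class = "posterior_chain")
}

#' @export
print.posterior_chain <- function(x, ...) {
  cat("PGLMM posterior chain (", x$family, "): ", nrow(x$beta),
      " retained samples, ", ncol(x$beta), " fixed effects\n", sep = "")
  cat("  response: ", x$response, "; seed ", x$settings$seed,
      "; iterations ", x$settings$iterations, " (thin ", x$settings$thin,
      ", burn-in ", x$settings$burnin, ")\n", sep = "")
  if (!is.na(x$accept_rate))
    cat(sprintf("  latent Metropolis acceptance: %.2f\n", x$accept_rate))
  invisible(x)
}
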