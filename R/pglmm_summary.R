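## Posterior summaries: the sign-crossing significance measure p_x, the
## phylogenetic heritability h^2, kernel-density posterior modes, and the
## per-model summary object.

#' Posterior sign-crossing proportion p_x
#'
#' The proportion of retained posterior samples lying on the opposite side
#' of zero from the posterior mean (samples exactly at zero count as
#' crossing). Significance of a coefficient is declared at `p_x < 0.05`.
#' When no sample crosses, the reported value is 0 and the attainable floor
#' `1/N` is recorded in the `"floor"` attribute: with N retained samples
#' the chain cannot distinguish p_x = 0 from p_x < 1/N. The `doubled`
#' variant returns `min(1, 2 p_x)`, the two-sided posterior tail
#' probability; under a true null effect the doubled variant is flagged at
#' level alpha with probability alpha, while the one-sided p_x is flagged
#' at about 2 alpha.
#'
#' @param samples numeric vector of posterior draws of one coefficient.
#' @param doubled logical; return the two-sided variant.
#' @return a proportion in \[0, 1\] with attribute `floor = 1/N`.
#' @examples
#' compute_px(c(-1, 2, 3, 4)) # 0.25
#' @export
compute_px <- function(samples, doubled = FALSE) {
  n <- length(samples)
  if (n < 2L) stop("domain error: p_x needs at least 2 samples")
  m <- mean(samples)
  s <- sign(m)
  px <- if (s == 0) 0.5 else sum(samples * s <= 0) / n
  if (doubled) px <- min(1, 2 * px)
  structure(px, floor = 1 / n)
}

#' Kernel-density posterior mode
#'
#' @param x posterior samples.
#' @param lower,upper optional support bounds; the mode is clamped into
#'   them (used for proportions such as h^2).
#' @return the location of the kernel density maximum.
#' @export
posterior_mode <- function(x, lower = -Inf, upper = Inf) {
  if (length(unique(x)) == 1L) return(x[1L])
  d <- stats::density(x)
  m <- d$x[which.max(d$y)]
  min(max(m, lower), upper)
}

#' Phylogenetic heritability h^2
#'
#' Per retained sample, the share of the total random variance attributed
#' to the phylogenetic component:
#' `h^2 = sig2_phylo / (sig2_phylo + sig2_plant_part + sig2_panellist +
#' sig2_resid)`. It ranges between 0 and 1 and is interpreted like Pagel's
#' lambda: values near 1 indicate very strong phylogenetic signal.
#'
#' @param vc matrix of variance-component samples; phylogenetic component
#'   in column `phylo_col`, all other columns (including the residual)
#'   complete the denominator.
#' @param phylo_col column name or index of the phylogenetic component.
#' @return list with `samples` (per-draw h^2) and `mode` (kernel-density
#'   mode on \[0, 1\]).
#' @export
compute_h2 <- function(vc, phylo_col = "sig2_phylo") {
  vc <- as.matrix(vc)
  total <- rowSums(vc)
  if (any(total <= 0)) stop("domain error: non-positive total variance")
  h2 <- vc[, phylo_col] / total
  list(samples = h2, mode = posterior_mode(h2, 0, 1))
}

#' Summarise a posterior chain
#'
#' Per fixed effect: posterior mean, kernel-density mode, p_x (one-sided
#' crossing) and its doubled two-sided variant, the p_x floor `1/N`, and
#' the central 95% interval. Per variance component: posterior mode.
#' Also reports modal h^2 and echoes separation flags recorded at design
#' time (qualities never observed together with a positive response make
#' the corresponding probit coefficient poorly estimable).
#'
#' @param chain a `posterior_chain`.
#' @param prob central interval probability.
#' @return an object of class `posterior_summary` with elements
#'   `coefficients` (data.frame), `vc_modes`, `h2`, `accept_rate`,
#'   `n_dropped`, `separation`, `response`, `fixed`, `family`, `settings`.
#' @export
summarize_chain <- function(chain, prob = 0.95) {
  stopifnot(inherits(chain, "posterior_chain"))
  if (nrow(chain$beta) < 10L)
    stop("chain too short to summarise (need >= 10 retained samples)")
  a <- (1 - prob) / 2
  coefs <- data.frame(
    term = colnames(chain$beta),
    mean = colMeans(chain$beta),
    mode = apply(chain$beta, 2L, posterior_mode),
    lower = apply(chain$beta, 2L, stats::quantile, probs = a),
    upper = apply(chain$beta, 2L, stats::quantile, probs = 1 - a),
    px = apply(chain$beta, 2L, function(s) as.numeric(compute_px(s))),
    px_doubled = apply(chain$beta, 2L,
                       function(s) as.numeric(compute_px(s, doubled = TRUE))),
    row.names = NULL, stringsAsFactors = FALSE)
  coefs$px_floor <- 1 / nrow(chain$beta)
  h2 <- compute_h2(chain$vc)
  structure(list(
    coefficients = coefs,
    vc_modes = apply(chain$vc, 2L, posterior_mode, lower = 0),
    h2_mode = h2$mode, h2_samples = h2$samples,
    accept_rate = chain$accept_rate,
    n_dropped = chain$n_dropped,
    separation = chain$separation,
    response = chain$response, fixed = chain$fixed, family = chain$family,
    settings = chain$settings),
    class = "posterior_summary")
}

#' @export
print.posterior_summary <- function(x, ...) {
  cat("PGLMM posterior summary - response ", x$response, " (", x$family,
      ", ", x$fixed, " fixed effects)\n", sep = "")
  cf <- x$coefficients
  cf$sig <- ifelse(cf$px < 0.05, "*", "")
  print(format(cf[, c("term", "mode", "mean", "lower", "upper", "px", "sig")],
               digits = 3), row.names = FALSE)
  cat(sprintf("modal h^2 = %.3f; variance component modes: %s\n", x$h2_mode,
              paste(sprintf("%s=%.3g", names(x$vc_modes), x$vc_modes),
                    collapse = ", ")))
  if (x$n_dropped > 0L)
    cat("rows dropped by zero truncation:", x$n_dropped, "\n")
  if (length(x$separation))
    cat("quasi-complete separation flagged for:",
        paste(x$separation, collapse = ", "), "\n")
  invisible(x)
}

#' Export a chain or summary as a delimited table
#'
#' @param x a `posterior_chain` or `posterior_summary`.
#' @param path output file.
#' @param sep field separator.
#' @export
write_chain <- function(x, path, sep = ",") {
  df <- if (inherits(x, "posterior_chain"))
    data.frame(x$beta, x$vc, check.names = FALSE) else x$coefficients
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
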