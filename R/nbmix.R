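#' Fit a two-component negative-binomial mixture to hashtag counts
#'
#' Hashtag counts from a well-performing hashing experiment are bimodal: a
#' low background component (ambient antibody / nonspecific binding, all
#' cells) and a high signal component (cells actually tagged with the
#' hashtag). This fits
#' \deqn{x \sim (1-\pi)\,\mathrm{NB}(\mu_b, \theta_b) + \pi\,\mathrm{NB}(\mu_s, \theta_s)}
#' by EM, with \eqn{\mu_s \ge \mu_b} enforced by ordering the components
#' after convergence. Mean updates are exact weighted means; dispersions are
#' updated by univariate likelihood maximisation, with a safeguard that
#' keeps the previous dispersion whenever the line search does not improve
#' the expected complete-data log-likelihood, so the observed log-likelihood
#' is non-decreasing across iterations.
#'
#' @param counts Integer vector of counts for one hashtag (>= 50 cells,
#'   at least two distinct values).
#' @param max_iter Maximum EM iterations (default 100).
#' @param tol Convergence tolerance on the relative log-likelihood change
#'   (default 1e-6).
#' @return An object of class `nbmix`: list with `mu` and `size` (named
#'   `background`/`signal`), `weight_signal`, `loglik`, `loglik_trace`,
#'   `iterations`, `converged`, `n`.
#' @seealso [posterior_signal()], [call_hashing()]
#' @export
#' @examples
#' set.seed(1)
#' x <- c(rnbinom(1700, mu = 20, size = 10), rnbinom(300, mu = 800, size = 5))
#' fit <- fit_nbmix(x)
#' coef(fit)
fit_nbmix <- function(counts, max_iter = 100L, tol = 1e-6) {
  x <- as.numeric(counts)
  if (anyNA(x) || any(x < 0) || any(x != round(x))) {
    .stopf("counts must be non-negative integers")
  }
  if (length(x) < 50L) {
    .stopf("need at least 50 cells to fit a hashtag mixture (got %d)",
           length(x))
  }
  if (length(unique(x)) < 2L) {
    .stopf(paste0("degenerate counts (all values identical): ",
                  "mark this hashtag unusable"))
  }
  n <- length(x)

  mom <- function(v) {
    mu <- max(mean(v), 1e-3)
    s2 <- stats::var(v)
    size <- if (is.na(s2) || s2 <= mu) 1e4 else mu^2 / (s2 - mu)
    c(mu = mu, size = min(max(size, 1e-3), 1e6))
  }
  # background from the lower half, signal from the top decile
  lo <- x[x <= stats::median(x)]
  hi <- x[x >= stats::quantile(x, 0.9)]
  init_b <- mom(lo)
  init_s <- mom(hi)
  mu <- c(init_b["mu"], init_s["mu"])
  size <- c(init_b["size"], init_s["size"])
  if (mu[2] <= mu[1]) mu[2] <- mu[1] * 1.5 + 1
  w <- c(0.9, 0.1)

  qfun <- function(r, mu_k, size_k) {
    sum(r * stats::dnbinom(x, mu = mu_k, size = size_k, log = TRUE))
  }
  opt_size <- function(r, mu_k, size_old) {
    f <- function(ls) qfun(r, mu_k, exp(ls))
    o <- stats::optimize(f, interval = log(c(1e-3, 1e6)), maximum = TRUE,
                         tol = 1e-4)
    if (o$objective > f(log(size_old))) exp(o$maximum) else size_old
  }

  ll_trace <- numeric(0)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  for (iter in seq_len(max_iter)) {
    ld <- cbind(log(w[1]) + stats::dnbinom(x, mu = mu[1], size = size[1],
                                           log = TRUE),
                log(w[2]) + stats::dnbinom(x, mu = mu[2], size = size[2],
                                           log = TRUE))
    lse <- .logsumexp(ld)
    ll <- sum(lse)
    ll_trace <- c(ll_trace, ll)
    resp <- exp(ld - lse)
    if (is.finite(ll_old) &&
        abs(ll - ll_old) < tol * (abs(ll_old) + tol)) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    nk <- pmax(colSums(resp), 1e-8)
    w <- pmin(pmax(nk / n, 1e-6), 1 - 1e-6)
    w <- w / sum(w)
    for (k in 1:2) {
      mu[k] <- max(sum(resp[, k] * x) / nk[k], 1e-3)
      size[k] <- opt_size(resp[, k], mu[k], size[k])
    }
  }
  if (mu[1] > mu[2]) {
    mu <- rev(mu); size <- rev(size); w <- rev(w)
  }
  structure(list(mu = c(background = unname(mu[1]), signal = unname(mu[2])),
                 size = c(background = unname(size[1]),
                          signal = unname(size[2])),
                 weight_signal = unname(w[2]),
                 loglik = ll_trace[length(ll_trace)],
                 loglik_trace = ll_trace,
                 iterations = iter,
                 converged = converged,
                 n = n),
            class = "nbmix")
}

#' @export
print.nbmix <- function(x, ...) {
  cat("Two-component negative-binomial mixture\n")
  cat(sprintf("  background: mu = %.2f, size = %.2f\n",
              x$mu["background"], x$size["background"]))
  cat(sprintf("  signal:     mu = %.2f, size = %.2f  (weight %.3f)\n",
              x$mu["signal"], x$size["signal"], x$weight_signal))
  cat(sprintf("  logLik %.2f after %d iterations (%s)\n", x$loglik,
              x$iterations, if (x$converged) "converged" else "max_iter hit"))
  invisible(x)
}

#' @export
coef.nbmix <- function(object, ...) {
  c(mu_background = unname(object$mu["background"]),
    mu_signal = unname(object$mu["signal"]),
    size_background = unname(object$size["background"]),
    size_signal = unname(object$size["signal"]),
    weight_signal = object$weight_signal)
}

#' @export
logLik.nbmix <- function(object, ...) {
  structure(object$loglik, df = 5L, nobs = object$n, class = "logLik")
}

#' Posterior probability of the signal component
#'
#' Bayes posterior that a count was drawn from the signal (tagged-cell)
#' component of a fitted hashtag mixture.
#'
#' @param fit An `nbmix` fit.
#' @param counts Integer vector of counts.
#' @return Numeric vector of posterior probabilities in `[0, 1]`.
#' @export
posterior_signal <- function(fit, counts) {
  stopifnot(inherits(fit, "nbmix"))
  x <- as.numeric(counts)
  ls <- log(fit$weight_signal) +
    stats::dnbinom(x, mu = fit$mu["signal"], size = fit$size["signal"],
                   log = TRUE)
  lb <- log(1 - fit$weight_signal) +
    stats::dnbinom(x, mu = fit$mu["background"],
                   size = fit$size["background"], log = TRUE)
  1 / (1 + exp(lb - ls))
}

#' @export
predict.nbmix <- function(object, newdata, ...) {
  posterior_signal(object, newdata)
}

#' @export
plot.nbmix <- function(x, counts = NULL, breaks = 50, ...) {
  if (is.null(counts)) {
    .stopf("supply the counts the model was fitted to")
  }
  h <- graphics::hist(log1p(counts), breaks = breaks, freq = FALSE,
                      xlab = "log1p(count)", main = "NB mixture fit", ...)
  grid <- exp(seq(min(h$breaks), max(h$breaks), length.out = 400)) - 1
  dens <- (1 - x$weight_signal) *
    stats::dnbinom(round(grid), mu = x$mu["background"],
                   size = x$size["background"]) +
    x$weight_signal *
    stats::dnbinom(round(grid), mu = x$mu["signal"], size = x$size["signal"])
  # change of variables to the log1p axis
  graphics::lines(log1p(grid), dens * (grid + 1), col = "red3", lwd = 2)
  invisible(x)
}

#' Classify cells from hashing counts
#'
#' Fits a per-hashtag negative-binomial mixture ([fit_nbmix()]) and labels
#' each cell from the per-hashtag signal posteriors: with
#' `S = {hashtags with posterior >= acceptance}`, a cell is a confident
#' singlet of hashtag `h` when `S = {h}`, a `DOUBLET` when `|S| >= 2`, a
#' `NEGATIVE` when `S` is empty and every posterior is `<= 1 - acceptance`,
#' and `UNCERTAIN` otherwise. The confident singlets are the training data
#' for the SNP classifier; everything else is forwarded for SNP-based
#' prediction.
#'
#' @param counts Cells x hashtags integer matrix (see
#'   [validate_hto_counts()]).
#' @param acceptance Posterior acceptance threshold in (0.5, 1); default
#'   0.75.
#' @param max_iter,tol Passed to [fit_nbmix()].
#' @return A `hashing_calls` data frame: `cell_barcode`, `label`, one
#'   posterior column per hashtag. The fitted mixtures are attached as
#'   attribute `"fits"`.
#' @export
call_hashing <- function(counts, acceptance = 0.75, max_iter = 100L,
                         tol = 1e-6) {
  counts <- validate_hto_counts(counts)
  if (!is.numeric(acceptance) || length(acceptance) != 1L ||
      acceptance <= 0.5 || acceptance >= 1) {
    .stopf("acceptance must be in (0.5, 1); got %s", format(acceptance))
  }
  tags <- colnames(counts)
  fits <- lapply(tags, function(tg) {
    tryCatch(fit_nbmix(counts[, tg], max_iter = max_iter, tol = tol),
             error = function(e) {
               .stopf("hashtag %s is unusable: %s", tg, conditionMessage(e))
             })
  })
  names(fits) <- tags
  post <- vapply(tags, function(tg) posterior_signal(fits[[tg]], counts[, tg]),
                 numeric(nrow(counts)))
  post <- matrix(post, nrow = nrow(counts),
                 dimnames = list(rownames(counts), tags))
  hi <- post >= acceptance
  n_hi <- rowSums(hi)
  all_low <- rowSums(post <= 1 - acceptance) == length(tags)
  label <- character(nrow(counts))
  label[n_hi >= 2] <- "DOUBLET"
  one <- n_hi == 1
  label[one] <- tags[apply(hi[one, , drop = FALSE], 1L, which)]
  label[n_hi == 0 & all_low] <- "NEGATIVE"
  label[label == ""] <- "UNCERTAIN"
  out <- data.frame(cell_barcode = rownames(counts), label = label,
                    post, check.names = FALSE, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "fits") <- fits
  attr(out, "acceptance") <- acceptance
  class(out) <- c("hashing_calls", "data.frame")
  out
}

#' @export
print.hashing_calls <- function(x, ...) {
  cat(sprintf("hashing_calls: %d cells\n", nrow(x)))
  print(table(x$label))
  invisible(x)
}
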