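# Regional average-sarcomere-length signals and Gaussian-process denoising.
#
# The GP uses a sum kernel Periodic + RBF + Matern(nu = 2.5) plus an
# observation-noise term; hyperparameters are fitted by maximizing the
# marginal likelihood with analytic gradients (L-BFGS-B on log-parameters).
# The posterior mean evaluated at every frame time is the denoised signal.

#' GP kernel / training configuration
#'
#' The kernel composition is fixed to the sum of a Periodic, an RBF and a
#' Matern (nu = 2.5) component plus i.i.d. observation noise. A product
#' composition (Periodic x RBF, plus Matern) is available as an alternative.
#'
#' @param composition `"sum"` (default) or `"product"`.
#' @param max_iter maximum L-BFGS-B iterations.
#' @param tol relative convergence tolerance on the marginal likelihood.
#' @param seed integer seed (fitting is deterministic; kept for the contract).
#' @return an object of class `kernel_config`.
#' @export
kernel_config <- function(composition = c("sum", "product"), max_iter = 300L,
                          tol = 1e-5, seed = 1L) {
  structure(list(composition = match.arg(composition),
                 max_iter = as.integer(max_iter), tol = tol,
                 seed = as.integer(seed)),
            class = "kernel_config")
}

#' Per-frame average sarcomere length for a region
#'
#' @param sarcomeres labelled sarcomere data.frame (columns `frame`,
#'   `length_um`, `longitudinal`, `transverse`).
#' @param region `"whole"`, a third (`"left"|"center"|"right"`), a half
#'   (`"top"|"bottom"`), or a sixth (`"left-top"`, ...).
#' @param fps frames per second.
#' @param n_frames total frame count (frames with no sarcomeres in the
#'   region become `NA`).
#' @return an object of class `length_signal`: list with `region`, `t` (s),
#'   `raw` (um, NA where missing), `n` (per-frame sarcomere counts).
#' @export
average_length_signal <- function(sarcomeres, region = "whole", fps = 100,
                                  n_frames = NULL) {
  sel <- region_filter(sarcomeres, region)
  if (is.null(n_frames)) n_frames <- max(sarcomeres$frame) + 1L
  sub <- sarcomeres[sel, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop(sprintf("average_length_signal: region '%s' is empty in all frames",
                 region))
  raw <- rep(NA_real_, n_frames)
  counts <- integer(n_frames)
  agg <- rowsum(sub$length_um, sub$frame)
  cnt <- table(sub$frame)
  fr <- as.integer(rownames(agg)) + 1L
  raw[fr] <- agg[, 1] / as.numeric(cnt)
  counts[fr] <- as.integer(cnt)
  structure(list(region = region, t = (seq_len(n_frames) - 1) / fps,
                 raw = raw, n = counts, fps = fps),
            class = "length_signal")
}

region_filter <- function(sarcomeres, region) {
  if (region == "whole") return(rep(TRUE, nrow(sarcomeres)))
  parts <- strsplit(region, "-", fixed = TRUE)[[1]]
  sel <- rep(TRUE, nrow(sarcomeres))
  for (p in parts) {
    if (p %in% c("left", "center", "right")) {
      sel <- sel & sarcomeres$longitudinal == p
    } else if (p %in% c("top", "bottom")) {
      sel <- sel & sarcomeres$transverse == p
    } else {
      stop(sprintf("unknown region selector '%s'", region))
    }
  }
  sel
}

# ---- kernel machinery -------------------------------------------------

# par: log-parameter vector
# (sig_per, ell_per, period, sig_rbf, ell_rbf, sig_mat, ell_mat, sig_noise)
gp_kernel_parts <- function(r, par, composition = "sum") {
  sp2 <- exp(2 * par[1]); lp <- exp(par[2]); per <- exp(par[3])
  sr2 <- exp(2 * par[4]); lr <- exp(par[5])
  sm2 <- exp(2 * par[6]); lm <- exp(par[7])
  q <- pi * r / per
  S2 <- sin(q)^2
  Kp <- sp2 * exp(-2 * S2 / lp^2)
  Kr <- sr2 * exp(-r^2 / (2 * lr^2))
  a <- sqrt(5) * r / lm
  Km <- sm2 * (1 + a + a^2 / 3) * exp(-a)
  if (composition == "product") {
    # periodic x RBF captures a decaying quasi-periodic signal
    list(K = Kp * Kr / max(sr2, 1e-300) + Km, Kp = Kp, Kr = Kr, Km = Km,
         q = q, S2 = S2, a = a)
  } else {
    list(K = Kp + Kr + Km, Kp = Kp, Kr = Kr, Km = Km, q = q, S2 = S2, a = a)
  }
}

gp_neg_loglik <- function(par, r, y, composition) {
  n <- length(y)
  parts <- gp_kernel_parts(r, par, composition)
  K <- parts$K
  diag(K) <- diag(K) + exp(2 * par[8]) + 1e-8
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) return(list(value = 1e10, grad = rep(0, 8)))
  alpha <- backsolve(L, forwardsolve(t(L), y))
  nll <- 0.5 * sum(y * alpha) + sum(log(diag(L))) + 0.5 * n * log(2 * pi)
  Kinv <- chol2inv(L)
  M <- Kinv - tcrossprod(alpha)   # gradient of the NEGATIVE loglik uses +M
  lp <- exp(par[2]); lr <- exp(par[5]); lm <- exp(par[7])
  dKp_lp <- parts$Kp * (4 * parts$S2 / lp^2)
  dKp_per <- parts$Kp * (2 * parts$q * sin(2 * parts$q) / lp^2)
  dKr_lr <- parts$Kr * (r^2 / lr^2)
  sm2 <- exp(2 * par[6])
  dKm_lm <- sm2 * exp(-parts$a) * parts$a^2 * (1 + parts$a) / 3
  if (composition == "product") {
    sr2 <- exp(2 * par[4])
    B <- parts$Kr / max(sr2, 1e-300)  # unit-variance RBF factor
    g <- c(sum(M * (2 * parts$Kp * B)),
           sum(M * (dKp_lp * B)),
           sum(M * (dKp_per * B)),
           0,
           sum(M * (parts$Kp * dKr_lr / max(sr2, 1e-300))),
           sum(M * (2 * parts$Km)),
           sum(M * dKm_lm),
           2 * exp(2 * par[8]) * sum(diag(M)))
  } else {
    g <- c(sum(M * (2 * parts$Kp)),
           sum(M * dKp_lp),
           sum(M * dKp_per),
           sum(M * (2 * parts$Kr)),
           sum(M * dKr_lr),
           sum(M * (2 * parts$Km)),
           sum(M * dKm_lm),
           2 * exp(2 * par[8]) * sum(diag(M)))
  }
  list(value = nll, grad = 0.5 * g)
}

# dominant FFT period of a mean-centred series (s); NA-safe
dominant_period <- function(t, y) {
  ok <- is.finite(y)
  yc <- y - mean(y[ok])
  yc[!ok] <- 0
  n <- length(yc)
  sp <- Mod(stats::fft(yc))[2:floor(n / 2)]
  if (length(sp) == 0L) return(diff(range(t)) / 2)
  dt <- t[2] - t[1]
  freq <- (seq_along(sp)) / (n * dt)
  1 / freq[which.max(sp)]
}

#' Denoise a length signal with Gaussian-process regression
#'
#' Fits the composite-kernel GP to the non-missing (t, raw) pairs by
#' maximizing the marginal likelihood, then evaluates the posterior mean at
#' every frame time (missing frames are interpolated by the posterior).
#' The period hyperparameter is initialized from the dominant FFT peak of
#' the mean-centred signal; lengthscales start at a quarter period.
#'
#' @param signal a `length_signal` from [average_length_signal()], or a
#'   list with `t` and `raw`.
#' @param cfg a [kernel_config()] object.
#' @return the signal with added `denoised` (um), `noise_level`
#'   (`sd(raw - denoised)` over non-missing frames), `hyperparameters`
#'   (named, natural scale) and `converged`.
#' @export
gpr_denoise <- function(signal, cfg = kernel_config()) {
  t_all <- signal$t
  raw <- signal$raw
  ok <- is.finite(raw)
  if (sum(ok) < 50L)
    stop("gpr_denoise: need at least 50 non-missing samples")
  y0 <- raw[ok]; t0 <- t_all[ok]
  mu <- mean(y0); s <- stats::sd(y0)
  if (!is.finite(s) || s < 1e-9) {  # degenerate constant input
    signal$denoised <- rep(mu, length(t_all))
    signal$noise_level <- 0
    signal$hyperparameters <- NULL
    signal$converged <- TRUE
    return(signal)
  }
  y <- (y0 - mu) / s
  p0 <- dominant_period(t0, y)
  p0 <- min(max(p0, 4 * (t0[2] - t0[1])), diff(range(t0)))
  init <- log(c(sig_per = sqrt(1 / 3), ell_per = 1, period = p0,
                sig_rbf = sqrt(1 / 3), ell_rbf = p0 / 4,
                sig_mat = sqrt(1 / 3), ell_mat = p0 / 4,
                sig_noise = max(stats::sd(diff(y)) / sqrt(2), 1e-3)))
  lower <- rep(-10, 8); upper <- rep(6, 8)
  lower[3] <- log(p0 / 3); upper[3] <- log(3 * p0)
  r <- abs(outer(t0, t0, "-"))
  env <- new.env()
  fn <- function(par) {
    res <- gp_neg_loglik(par, r, y, cfg$composition)
    env$last <- res
    res$value
  }
  gr <- function(par) env$last$grad
  set.seed(cfg$seed)
  fit <- stats::optim(init, fn, gr, method = "L-BFGS-B",
                      lower = lower, upper = upper,
                      control = list(maxit = cfg$max_iter,
                                     factr = cfg$tol / .Machine$double.eps))
  if (fit$convergence != 0 && fit$convergence != 1)
    warning("gpr_denoise: optimizer reported non-convergence; using best-found hyperparameters")
  if (fit$convergence == 1)
    warning("gpr_denoise: iteration limit reached; using best-found hyperparameters")
  par <- fit$par
  parts <- gp_kernel_parts(r, par, cfg$composition)
  K <- parts$K
  diag(K) <- diag(K) + exp(2 * par[8]) + 1e-8
  L <- chol(K)
  alpha <- backsolve(L, forwardsolve(t(L), y))
  r_star <- abs(outer(t_all, t0, "-"))
  Ks <- gp_kernel_parts(r_star, par, cfg$composition)$K
  post <- as.numeric(Ks %*% alpha)
  signal$denoised <- post * s + mu
  signal$noise_level <- stats::sd(raw[ok] - signal$denoised[ok])
  hp <- exp(par)
  hp[c(1, 4, 6, 8)] <- hp[c(1, 4, 6, 8)] * s  # de-standardize output scales
  names(hp) <- c("sig_per", "ell_per", "period", "sig_rbf", "ell_rbf",
                 "sig_mat", "ell_mat", "sig_noise")
  signal$hyperparameters <- hp
  signal$converged <- fit$convergence == 0
  signal
}
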