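#' Krippendorff's alpha for ordinal ratings
#'
#' Chance-corrected inter-rater agreement: `1 - Do/De` with observed and
#' expected disagreement computed from the coincidence matrix and an ordinal
#' distance metric (squared sums of in-between value frequencies). Missing
#' entries (NA) are allowed; units with fewer than 2 ratings are ignored.
#'
#' @param scores integer matrix (image x observer).
#' @param level `"ordinal"` (default) or `"nominal"`.
#' @return alpha in \[-1, 1\].
#' @export
krippendorff_alpha <- function(scores, level = c("ordinal", "nominal")) {
  level <- match.arg(level)
  stopifnot(ncol(scores) >= 2, nrow(scores) >= 2)
  vals <- sort(unique(as.vector(scores[!is.na(scores)])))
  if (length(vals) < 2) stop("no variance: all ratings identical")
  k <- length(vals)
  co <- matrix(0, k, k, dimnames = list(vals, vals))
  for (u in seq_len(nrow(scores))) {
    r <- scores[u, ]
    r <- r[!is.na(r)]
    m <- length(r)
    if (m < 2) next
    for (a in seq_len(m)) for (b in seq_len(m)) if (a != b) {
      ia <- match(r[a], vals); ib <- match(r[b], vals)
      co[ia, ib] <- co[ia, ib] + 1 / (m - 1)
    }
  }
  nc <- rowSums(co)
  n <- sum(nc)
  if (level == "ordinal") {
    delta2 <- matrix(0, k, k)
    for (a in seq_len(k)) for (b in seq_len(k)) if (a != b) {
      lo <- min(a, b); hi <- max(a, b)
      delta2[a, b] <- (sum(nc[lo:hi]) - (nc[a] + nc[b]) / 2)^2
    }
  } else {
    delta2 <- 1 - diag(k)
  }
  Do <- sum(co * delta2) / n
  De <- sum(outer(nc, nc) * delta2) / (n * (n - 1))
  if (De == 0) stop("no variance: expected disagreement undefined")
  1 - Do / De
}

#' Multinomial category-probability model of scores on a quality metric
#'
#' Baseline-category multinomial logistic regression of the ordinal score on
#' the metric value (one row per image-observer rating). The three category
#' intercepts are the metric values where adjacent-category probability
#' curves cross (4|3, 3|2, 2|1), located by bisection on the fitted curves.
#' Complete separation is handled by refitting with a small ridge penalty
#' (flagged in the result).
#'
#' @param ge_values numeric metric values, one per rating (recycled over
#'   observers if `scores` is a matrix).
#' @param scores integer vector or (image x observer) matrix of scores 1..4.
#' @param ridge ridge (weight decay) used on refit after separation.
#' @param model `"multinomial"` (baseline-category, default) or `"ordinal"`
#'   (proportional-odds cumulative logit).
#' @return list with `fit` (the fitted model object), `prob_fun(ge)` returning
#'   the 4-category probability matrix, `category_intercepts` (named, GE at
#'   4|3, 3|2, 2|1), `ridged` flag.
#' @export
fit_category_model <- function(ge_values, scores, ridge = 1e-2,
                               model = c("multinomial", "ordinal")) {
  model <- match.arg(model)
  if (is.matrix(scores)) {
    ge <- rep(ge_values, times = ncol(scores))
    sc <- as.vector(scores)
  } else {
    ge <- ge_values; sc <- scores
  }
  keep <- !is.na(sc)
  ge <- ge[keep]; sc <- sc[keep]
  if (length(unique(sc)) < 2) stop("need at least 2 categories present")
  df <- data.frame(score = factor(sc, levels = 1:4), ge = ge)
  ridged <- FALSE
  if (model == "multinomial") {
    fit <- nnet::multinom(score ~ ge, data = df, trace = FALSE, maxit = 500)
    if (max(abs(coef(fit))) > 50) {  # separation blow-up
      fit <- nnet::multinom(score ~ ge, data = df, trace = FALSE, maxit = 500,
                            decay = ridge)
      ridged <- TRUE
    }
  } else {
    df$score <- droplevels(df$score)
    fit <- MASS::polr(score ~ ge, data = df)
  }
  lev <- levels(droplevels(df$score))
  prob_fun <- function(g) {
    pr <- predict(fit, newdata = data.frame(ge = g), type = "probs")
    if (is.null(dim(pr))) pr <- matrix(pr, nrow = length(g), byrow = FALSE,
                                       dimnames = list(NULL, lev))
    out <- matrix(0, length(g), 4, dimnames = list(NULL, as.character(1:4)))
    out[, colnames(pr)] <- pr
    out
  }
  rng <- range(ge)
  pad <- 0.25 * diff(rng) + 1e-9
  gg <- seq(rng[1] - pad, rng[2] + pad, length.out = 2048)
  pp <- prob_fun(gg)
  cross <- function(hi, lo) {
    # first crossing where the better-category curve drops below the next one
    dfn <- pp[, hi] - pp[, lo]
    s <- which(dfn[-length(dfn)] > 0 & dfn[-1] <= 0)
    if (length(s) == 0) return(NA_real_)
    i <- s[1]
    uniroot(function(g) {
      p <- prob_fun(g)
      p[, hi] - p[, lo]
    }, interval = c(gg[i], gg[i + 1]), tol = 1e-8)$root
  }
  ci <- c("4|3" = cross("4", "3"), "3|2" = cross("3", "2"),
          "2|1" = cross("2", "1"))
  list(fit = fit, prob_fun = prob_fun, category_intercepts = ci,
       ridged = ridged)
}

#' One-way ANOVA of a metric grouped by score category
#'
#' @param ge_values metric values (recycled over observers for matrix scores).
#' @param scores integer vector or matrix of category scores.
#' @return list with `F`, `p`, `df` (numerator, denominator).
#' @export
one_way_anova <- function(ge_values, scores) {
  if (is.matrix(scores)) {
    ge <- rep(ge_values, times = ncol(scores)); sc <- as.vector(scores)
  } else { ge <- ge_values; sc <- scores }
  grp <- factor(sc)
  if (nlevels(droplevels(grp)) < 2 || any(table(droplevels(grp)) < 2))
    stop("need >= 2 groups with >= 2 members")
  a <- anova(stats::aov(ge ~ grp))
  list(F = a$`F value`[1], p = a$`Pr(>F)`[1], df = a$Df)
}

#' Linear RMS model of gradient entropy with optional interaction
#'
#' Ordinary least squares of `Y = b0 + a*X1 + b*X2 (+ c*X1*X2)` where Y is
#' the gradient entropy and X1/X2 the rotational (deg) and translational
#' (mm) RMS. Both candidates are fitted; the Bayesian Information Criterion
#' `n*ln(RSS/n) + k*ln(n)` selects the model (lower wins). When both RSS are
#' at floating-noise level relative to the total sum of squares (an exact
#' fit), the smaller model is selected.
#'
#' @param ge numeric gradient-entropy values.
#' @param rms_rot,rms_trans RMS rotation (deg) and translation (mm).
#' @return list with `no_interaction`, `interaction` (each: coefficients,
#'   RSS, BIC, r_squared, lm fit), `selected` (`"interaction"` or
#'   `"no_interaction"`), and `model` (the selected lm).
#' @export
fit_rms_model <- function(ge, rms_rot, rms_trans) {
  n <- length(ge)
  stopifnot(n >= 10, length(rms_rot) == n, length(rms_trans) == n)
  df <- data.frame(ge = ge, rot = rms_rot, trans = rms_trans)
  f0 <- lm(ge ~ rot + trans, data = df)
  f1 <- lm(ge ~ rot + trans + rot:trans, data = df)
  if (any(!is.finite(coef(f1))) || any(is.na(coef(f1))))
    stop("rank-deficient design")
  tss <- sum((ge - mean(ge))^2)
  mk <- function(f) {
    rss <- sum(resid(f)^2)
    k <- length(coef(f))
    list(coefficients = coef(f), RSS = rss,
         BIC = n * log(rss / n) + k * log(n),
         r_squared = 1 - rss / tss, fit = f)
  }
  m0 <- mk(f0); m1 <- mk(f1)
  exact <- m0$RSS < 1e-12 * tss && m1$RSS < 1e-12 * tss
  selected <- if (exact) "no_interaction"
  else if (m1$BIC < m0$BIC) "interaction" else "no_interaction"
  list(no_interaction = m0, interaction = m1, selected = selected,
       model = if (selected == "interaction") m1$fit else m0$fit)
}

#' Invert the RMS model to motion boundaries at a GE threshold
#'
#' Solves for the rotation at zero translation (the interaction term
#' vanishes) and symmetrically for the translation. Negative solutions are
#' clipped to 0 and flagged unreachable (the quality level cannot be reached
#' at any motion).
#'
#' @param rms_fit result of [fit_rms_model()] (or an lm with terms rot,
#'   trans).
#' @param ge_threshold GE value of the category boundary.
#' @return list with `rot_boundary_deg`, `trans_boundary_mm`,
#'   `rot_unreachable`, `trans_unreachable`.
#' @export
invert_rms_boundary <- function(rms_fit, ge_threshold) {
  cf <- if (inherits(rms_fit, "lm")) coef(rms_fit) else coef(rms_fit$model)
  b0 <- cf["(Intercept)"]; a <- cf["rot"]; b <- cf["trans"]
  if (is.na(a) || a == 0 || is.na(b) || b == 0) stop("zero slope: model not invertible")
  rot <- as.numeric((ge_threshold - b0) / a)
  trans <- as.numeric((ge_threshold - b0) / b)
  list(rot_boundary_deg = max(0, rot), trans_boundary_mm = max(0, trans),
       rot_unreachable = rot < 0, trans_unreachable = trans < 0)
}

#' Linear and logarithmic models of GE on mean framewise displacement
#'
#' Fits `Y = a + b*X` by OLS and `Y = a + b*log(X - c)` (natural log) by
#' Levenberg-Marquardt nonlinear least squares with `c` initialized at
#' `0.9*min(X)` and constrained below `min(X)`; `b > 0` is enforced by
#' bounded restarts. Errors after 5 restarts.
#'
#' @param ge gradient-entropy values.
#' @param mean_fd positive mean framewise displacements (mm).
#' @return list with `linear` (a, b, r_squared, fit) and `logarithmic`
#'   (a, b, c, r_squared, fit).
#' @export
fit_fd_models <- function(ge, mean_fd) {
  stopifnot(length(ge) == length(mean_fd), all(mean_fd > 0))
  lin <- lm(ge ~ mean_fd)
  tss <- sum((ge - mean(ge))^2)
  r2_lin <- 1 - sum(resid(lin)^2) / tss
  mn <- min(mean_fd)
  df <- data.frame(ge = ge, fd = mean_fd)
  fit_log <- NULL
  start_c <- 0.9 * mn
  for (attempt in 1:5) {
    st <- list(a = mean(ge), b = max(1e-3, sd(ge) / max(1e-6, sd(log(mean_fd - start_c)))),
               c = start_c)
    fit_log <- tryCatch(
      minpack.lm::nlsLM(ge ~ a + b * log(fd - c), data = df, start = st,
                        lower = c(a = -Inf, b = 1e-9, c = -Inf),
                        upper = c(a = Inf, b = Inf, c = mn - 1e-9 * max(1, mn)),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit_log) && coef(fit_log)["b"] > 0) break
    start_c <- start_c * 0.5^attempt  # pull c away from min(FD) and retry
    fit_log <- NULL
  }
  if (is.null(fit_log))
    stop("logarithmic FD model failed to converge after 5 restarts")
  r2_log <- 1 - sum(resid(fit_log)^2) / tss
  cl <- coef(fit_log)
  list(linear = list(a = unname(coef(lin)[1]), b = unname(coef(lin)[2]),
                     r_squared = r2_lin, fit = lin),
       logarithmic = list(a = unname(cl["a"]), b = unname(cl["b"]),
                          c = unname(cl["c"]), r_squared = r2_log,
                          fit = fit_log))
}

#' Invert the logarithmic FD model at a GE threshold
#'
#' `X = c + exp((Y - a)/b)`.
#'
#' @param log_model the `logarithmic` element of [fit_fd_models()] (list with
#'   a, b, c).
#' @param ge_threshold GE value of the category boundary.
#' @return FD boundary in mm.
#' @export
invert_fd_boundary <- function(log_model, ge_threshold) {
  with(log_model, c + exp((ge_threshold - a) / b))
}
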