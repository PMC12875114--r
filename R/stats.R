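#' One-way ANOVA over per-cell fractions
#'
#' Classical fixed-effects one-way analysis of variance (between/within
#' mean-square ratio) of a per-cell value — typically a classification
#' fraction — across treatment groups. The model fit is delegated to
#' [stats::aov()].
#'
#' @param data Data frame with one row per cell.
#' @param value,group Column names (strings) of the response and the group
#'   label.
#' @return A tibble of class `chromaflux_anova`:
#'   `F, df_between, df_within, p_value`, with the `aov` fit in
#'   `attr(, "fit")`.
#' @examples
#' d <- data.frame(g = rep(c("a", "b", "c"), each = 4), v = rnorm(12))
#' one_way_anova(d, "v", "g")
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  g <- factor(data[[group]])
  v <- data[[value]]
  if (nlevels(g) < 2) abort("need >= 2 groups")
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("group `", names(sizes)[sizes < 2][1],
                 "` has fewer than 2 rows"))
  }
  fit <- aov(v ~ g)
  sm <- summary(fit)[[1]]
  out <- tibble::tibble(
    F = sm[["F value"]][1],
    df_between = sm[["Df"]][1],
    df_within = sm[["Df"]][2],
    p_value = sm[["Pr(>F)"]][1]
  )
  structure(out, class = c("chromaflux_anova", class(out)), fit = fit)
}

#' Dunnett many-to-one comparisons against a control group
#'
#' Two-sided comparisons of every treatment group against the control
#' using pooled-variance t statistics and the equicoordinate
#' multivariate-t null of the maximum absolute statistic. The
#' multivariate-t probability is evaluated by seeded quasi-Monte-Carlo
#' ([mvtnorm::pmvt()]), which handles arbitrary unbalanced designs; the
#' Monte-Carlo standard error of each adjusted p is reported.
#'
#' @param data Data frame with one row per cell.
#' @param value,group Column names of response and group label.
#' @param control Label of the control group.
#' @param seed Seed for the quasi-Monte-Carlo integration.
#' @param maxpts Maximum integrand evaluations (>= 1e5 by default).
#' @return A tibble of class `chromaflux_dunnett`: one row per treatment
#'   group with `comparison, estimate, t, df, p_unadjusted, p_adjusted,
#'   mc_error`.
#' @export
dunnett_test <- function(data, value = "value", group = "group",
                         control = "control", seed = 1L, maxpts = 2e5) {
  g <- factor(data[[group]])
  v <- data[[value]]
  if (!control %in% levels(g)) {
    abort(paste0("control group `", control, "` not present"))
  }
  sizes <- table(g)
  if (any(sizes < 2)) {
    abort(paste0("group `", names(sizes)[sizes < 2][1],
                 "` has fewer than 2 rows"))
  }
  means <- tapply(v, g, mean)
  N <- length(v)
  k_all <- nlevels(g)
  df <- N - k_all
  s2 <- sum(tapply(v, g, function(x) sum((x - mean(x))^2))) / df
  trt <- setdiff(levels(g), control)
  n_c <- sizes[[control]]
  n_t <- sizes[trt]
  est <- means[trt] - means[control]
  se <- sqrt(s2 * (1 / n_t + 1 / n_c))
  tstat <- ifelse(se > 0, est / se, 0)
  # correlation of the comparison statistics: rho_kl = lambda_k lambda_l
  lam <- sqrt(n_t / (n_t + n_c))
  corr <- outer(lam, lam)
  diag(corr) <- 1
  k <- length(trt)
  p_adj <- numeric(k)
  mc_err <- numeric(k)
  for (i in seq_len(k)) {
    b <- abs(tstat[i])
    set.seed(seed)
    pr <- mvtnorm::pmvt(lower = rep(-b, k), upper = rep(b, k), df = df,
                        corr = corr, sigma = NULL, type = "shifted",
                        algorithm = mvtnorm::GenzBretz(maxpts = maxpts,
                                                       abseps = 1e-5))
    p_adj[i] <- min(1, max(0, 1 - as.numeric(pr)))
    mc_err[i] <- attr(pr, "error") %||% NA_real_
  }
  p_un <- 2 * pt(-abs(tstat), df)
  out <- tibble::tibble(
    comparison = paste(control, "vs", trt),
    estimate = unname(est), t = unname(tstat), df = df,
    p_unadjusted = unname(p_un),
    p_adjusted = pmax(p_adj, p_un),   # adjusted p can never undercut raw p
    mc_error = mc_err
  )
  structure(out, class = c("chromaflux_dunnett", class(out)))
}
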