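# Generalized estimating equations for the pre-post evaluation.
#
# The design is intercept + time (baseline vs follow-up). With an
# independence working correlation the estimating equations coincide with
# the GLM score equations, and the IRLS solution gives the
# population-averaged coefficients; within-person and within-class
# dependence is then accounted for entirely by the cluster-robust
# (sandwich) variance. With a saturated two-time-point mean model the point
# estimates are invariant to the working correlation, and the robust SEs
# are what the evaluation reports -- which is why independence is the
# working correlation used here.

#' Build a long-format outcome record table
#'
#' One row per (person, time) with the outcome value; persons may have one
#' or two rows ("all available longitudinal data": a person missing at
#' follow-up still contributes their baseline row).
#'
#' @param person_id,class_id identifier vectors.
#' @param time `"baseline"` or `"followup"` per row.
#' @param value outcome value (binary 0/1 or count); `NA` marks an
#'   unavailable measurement.
#' @return Tibble with columns `person_id`, `class_id`, `time`, `value`,
#'   `available`.
#' @export
long_records <- function(person_id, class_id, time, value) {
  if (!all(time %in% c("baseline", "followup")))
    abort_input("time must be 'baseline' or 'followup'")
  df <- tibble(person_id = as.character(person_id),
               class_id = as.character(class_id),
               time = time, value = value, available = !is.na(value))
  if (anyDuplicated(df[c("person_id", "time")]))
    abort_input("at most one record per (person, time)")
  df
}

#' Fit a two-point GEE with cluster-robust variance
#'
#' Solves the estimating equations for the model `g(E[y]) = b0 + b1 *
#' I(time = followup)` by iteratively reweighted least squares under an
#' independence working correlation, then computes the sandwich variance
#' with scores aggregated at the cluster level. The exponentiated time
#' effect is the odds ratio (binomial-logit) or incidence rate ratio
#' (poisson-log) of follow-up versus baseline. Wald 95% CI and two-sided
#' p-value use the normal reference distribution.
#'
#' @param records a [long_records()] tibble; rows with `available = FALSE`
#'   or `NA` values are dropped.
#' @param family `"binomial"` (logit link) or `"poisson"` (log link).
#' @param cluster_by `"class"` (school-class clustering, the default:
#'   persons are nested in classes, so class-level score aggregation also
#'   absorbs the within-person repeated measures) or `"person"` (sensitivity
#'   option).
#' @param small_sample if TRUE apply the G/(G-1) cluster correction to the
#'   sandwich; the default (FALSE) matches large-sample practice.
#' @param tol relative coefficient-change convergence tolerance.
#' @param max_iter maximum IRLS iterations; non-convergence is flagged in
#'   the result, never silent.
#' @param conf_level confidence level for the Wald interval.
#' @return Object of class `gee_result`: `coefficients` (intercept, time),
#'   `effect` (exponentiated time coefficient), `effect_type` (`"OR"` or
#'   `"IRR"`), `robust_se` (both coefficients, link scale), `conf_int`
#'   (exponentiated), `p_value`, `n_persons`, `n_obs`, `n_clusters`,
#'   `converged`, `iterations`, `vcov` (robust, link scale).
#' @export
gee_fit <- function(records, family = c("binomial", "poisson"),
                    cluster_by = c("class", "person"),
                    small_sample = FALSE, tol = 1e-8, max_iter = 100L,
                    conf_level = 0.95) {
  family <- match.arg(family)
  cluster_by <- match.arg(cluster_by)
  df <- records[records$available %||% TRUE & !is.na(records$value), ]
  if (nrow(df) == 0) abort_input("no available records")
  if (family == "binomial" && !all(df$value %in% c(0, 1)))
    abort_input("binomial outcomes must be 0/1")
  if (family == "poisson" && any(df$value < 0))
    abort_input("poisson outcomes must be non-negative counts")

  y <- as.numeric(df$value)
  x_time <- as.numeric(df$time == "followup")
  X <- cbind(`(Intercept)` = 1, time = x_time)
  cl <- if (cluster_by == "class") df$class_id else df$person_id
  G <- length(unique(cl))
  if (G < 2) abort_input("need at least 2 clusters for the robust variance")

  linkinv <- if (family == "binomial") function(eta) 1 / (1 + exp(-eta))
             else exp
  varfun <- if (family == "binomial") function(mu) mu * (1 - mu) else identity

  # IRLS (Fisher scoring; canonical links, so weights = variance function)
  beta <- c(0, 0)
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    eta <- drop(X %*% beta)
    mu <- linkinv(eta)
    w <- pmax(varfun(mu), 1e-12)
    z <- eta + (y - mu) / w
    XtW <- t(X * w)
    beta_new <- drop(solve(XtW %*% X, XtW %*% z))
    delta <- max(abs(beta_new - beta) / pmax(abs(beta_new), 1e-4))
    beta <- beta_new
    if (!all(is.finite(beta))) break
    if (delta < tol) { converged <- TRUE; break }
  }
  names(beta) <- colnames(X)

  eta <- drop(X %*% beta)
  mu <- linkinv(eta)
  w <- pmax(varfun(mu), 1e-12)
  bread <- solve(t(X * w) %*% X)
  # cluster-aggregated scores; canonical links: u_i = x_i (y_i - mu_i)
  scores <- X * (y - mu)
  S <- rowsum(scores, cl)
  meat <- t(S) %*% S
  if (small_sample) meat <- meat * G / (G - 1)
  V <- bread %*% meat %*% bread
  se <- sqrt(diag(V))
  zq <- qnorm(1 - (1 - conf_level) / 2)
  est <- beta["time"]
  ci <- exp(est + c(-1, 1) * zq * se["time"])
  p <- 2 * pnorm(-abs(est / se["time"]))

  structure(list(
    coefficients = beta,
    effect = unname(exp(est)),
    effect_type = if (family == "binomial") "OR" else "IRR",
    robust_se = se,
    conf_int = ci,
    p_value = unname(p),
    family = family,
    cluster_by = cluster_by,
    n_persons = length(unique(df$person_id)),
    n_obs = nrow(df),
    n_clusters = G,
    converged = converged,
    iterations = iter,
    vcov = V
  ), class = "gee_result")
}

#' @export
print.gee_result <- function(x, ...) {
  cat(sprintf("GEE (%s, cluster-robust by %s): %s = %.3f, 95%% CI %.3f-%.3f, p = %.4g\n",
              x$family, x$cluster_by, x$effect_type, x$effect,
              x$conf_int[1], x$conf_int[2], x$p_value))
  cat(sprintf("  n = %d persons, %d observations, %d clusters; %s in %d iterations\n",
              x$n_persons, x$n_obs, x$n_clusters,
              if (x$converged) "converged" else "DID NOT CONVERGE", x$iterations))
  invisible(x)
}

#' Pearson chi-square test of independence
#'
#' Plain Pearson statistic (no continuity correction) on an r x c count
#' table, df = (r-1)(c-1), upper-tail p-value.
#'
#' @param table matrix of non-negative counts with positive margins.
#' @return List with `statistic`, `df`, `p_value`, `expected`.
#' @export
chi_square_test <- function(table) {
  table <- as.matrix(table)
  if (any(table < 0)) abort_input("counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    abort_input("degenerate margins: every row and column sum must be > 0")
  E <- outer(rowSums(table), colSums(table)) / sum(table)
  stat <- sum((table - E)^2 / E)
  df <- (nrow(table) - 1) * (ncol(table) - 1)
  list(statistic = stat, df = df,
       p_value = pchisq(stat, df, lower.tail = FALSE), expected = E)
}

#' Mann-Whitney U test
#'
#' U computed from rank sums with mid-ranks for ties. For combined sample
#' sizes up to `exact_limit` the p-value is exact, by enumerating all
#' choose(nx+ny, nx) group labelings of the pooled values (ties handled
#' naturally by the enumeration); otherwise the normal approximation with
#' tie correction is used.
#'
#' @param x,y non-empty numeric samples.
#' @param exact_limit maximum nx+ny for exact enumeration (default 12).
#' @return List with `U` (for sample `x`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(x, y, exact_limit = 12) {
  if (length(x) == 0 || length(y) == 0) abort_input("both samples must be non-empty")
  nx <- length(x); ny <- length(y)
  r <- rank(c(x, y))
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2

  if (nx + ny <= exact_limit) {
    pool <- c(x, y)
    idx <- combn(nx + ny, nx)
    r_all <- rank(pool)
    us <- apply(idx, 2, function(i) sum(r_all[i]) - nx * (nx + 1) / 2)
    mu <- nx * ny / 2
    p <- mean(abs(us - mu) >= abs(U - mu) - 1e-9)
    list(U = U, p_value = p, method = "exact")
  } else {
    n <- nx + ny
    ties <- table(c(x, y))
    tie_corr <- sum(ties^3 - ties) / (n * (n - 1))
    sigma2 <- nx * ny / 12 * ((n + 1) - tie_corr)
    z <- (U - nx * ny / 2) / sqrt(sigma2)
    list(U = U, p_value = 2 * pnorm(-abs(z)), method = "normal")
  }
}
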