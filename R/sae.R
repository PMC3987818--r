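#' Declare a small-area model specification
#'
#' Describes one member of the model family: a sex-stratified logistic
#' mixed-effects regression of a binary smoking outcome on individual
#' demographics and calendar time, with nested state and county-within-state
#' random intercepts (and optionally random year slopes) providing the
#' spatial and temporal pooling. The combined-frame variant additionally
#' includes phone-usage category as a fixed effect so that predictions can
#' be post-stratified to the population's phone composition.
#'
#' @param outcome `"total"` (current smoking, daily or nondaily) or
#'   `"daily"` (daily smoking only).
#' @param sex `"male"` or `"female"`; models are always fit within sex.
#' @param covariates Individual demographic fixed effects to include.
#' @param year_term Include a fixed linear effect of (centered) calendar
#'   year.
#' @param phone_usage Include phone-usage category as a fixed effect (the
#'   combined-frame model).
#' @param random_slopes Give states and counties random year slopes in
#'   addition to random intercepts. Slopes are uncorrelated with
#'   intercepts.
#' @param year_center Centering year for the time trend; centering near the
#'   window midpoint decorrelates intercepts and slopes.
#' @param years Optional year restriction applied before fitting.
#' @param method `"agq0"` (fast joint optimization of the penalized
#'   deviance) or `"laplace"` (full Laplace approximation of the marginal
#'   likelihood).
#' @param maxit Optimizer iteration cap; when it is hit the fit is returned
#'   with `converged = FALSE` rather than an error.
#' @param tol Relative convergence tolerance passed to the optimizer.
#' @return Object of class `sae_spec`.
#' @export
sae_spec <- function(outcome = c("total", "daily"),
                     sex = c("male", "female"),
                     covariates = c("age_group", "race", "marital", "education"),
                     year_term = TRUE,
                     phone_usage = FALSE,
                     random_slopes = TRUE,
                     year_center = 2004,
                     years = NULL,
                     method = c("agq0", "laplace"),
                     maxit = 200L,
                     tol = 1e-6) {
  outcome <- match.arg(outcome)
  sex <- match.arg(sex)
  method <- match.arg(method)
  bad <- setdiff(covariates, .cell_vars)
  if (length(bad)) .stopf("unknown covariate(s): %s", paste(bad, collapse = ", "))
  structure(list(outcome = outcome, sex = sex, covariates = covariates,
                 year_term = year_term, phone_usage = phone_usage,
                 random_slopes = random_slopes, year_center = year_center,
                 years = years, method = method, maxit = as.integer(maxit),
                 tol = tol),
            class = "sae_spec")
}

#' @export
print.sae_spec <- function(x, ...) {
  cat(sprintf("SAE model spec: %s smoking, %ss\n", x$outcome, x$sex))
  cat(sprintf("  fixed: %s%s%s\n",
              paste(x$covariates, collapse = " + "),
              if (x$year_term) " + year" else "",
              if (x$phone_usage) " + phone_usage" else ""))
  cat(sprintf("  random: state + county intercepts%s\n",
              if (x$random_slopes) " and year slopes" else ""))
  invisible(x)
}

.fixed_rhs <- function(spec) {
  terms <- c(spec$covariates,
             if (spec$phone_usage) "phone_usage",
             if (spec$year_term) "year_c")
  if (!length(terms)) terms <- "1"
  paste(terms, collapse = " + ")
}

# aggregate individual microdata to binomial counts over the model cells;
# sufficient statistics for the declared model, and much faster to fit
.aggregate_microdata <- function(md, spec) {
  vars <- c("state_id", "county_id", "year",
            spec$covariates, if (spec$phone_usage) "phone_usage")
  key <- do.call(paste, c(md[vars], sep = "\r"))
  y <- md[[paste0(spec$outcome, "_smoker")]]
  agg <- rowsum(cbind(y = y, n = 1L), key)
  first <- md[!duplicated(key), vars, drop = FALSE]
  first <- first[match(rownames(agg), key[!duplicated(key)]), , drop = FALSE]
  out <- cbind(first, as.data.frame(agg))
  out$year_c <- out$year - spec$year_center
  out$state_id <- factor(out$state_id)
  out$county_id <- factor(out$county_id)
  rownames(out) <- NULL
  out
}

#' Fit a hierarchical small-area smoking prevalence model
#'
#' Fits the model declared by an [sae_spec()] to survey microdata by
#' maximizing an approximate marginal likelihood (through
#' \code{\link[lme4]{glmer}} on binomial sufficient statistics). Individual
#' rows are aggregated to counts per county-year-demographic cell before
#' fitting; design weights do not enter the fit (composition is adjusted
#' through covariates and post-stratification). The returned object carries
#' everything prediction and simulation need: fixed-effect estimates with
#' their covariance, variance components, and per-state/per-county
#' random-effect conditional means and variances.
#'
#' @param md Microdata (validated layout; outcome columns are derived via
#'   [classify_smoking()] if absent).
#' @param spec An `sae_spec`.
#' @param re_zero Fix all variance components to zero, collapsing the model
#'   to an ordinary logistic regression on one pooled group (used for
#'   degenerate and oracle checks).
#' @return Object of class `sae_fit`.
#' @export
sae_fit <- function(md, spec, re_zero = FALSE) {
  stopifnot(inherits(spec, "sae_spec"))
  .check_cols(md, c("state_id", "county_id", "year", "sex", .cell_vars),
              "microdata")
  md <- .ensure_outcomes(md)
  md <- md[md$sex == spec$sex, , drop = FALSE]
  if (!is.null(spec$years)) md <- md[md$year %in% spec$years, , drop = FALSE]
  if (spec$phone_usage) md$phone_usage <- droplevels(md$phone_usage)
  if (!nrow(md)) .stopf("no rows left after sex/year restriction")
  yvec <- md[[paste0(spec$outcome, "_smoker")]]
  if (all(yvec == 0) || all(yvec == 1))
    .stopf("outcome is constant (all %d); cannot fit", yvec[1])
  agg <- .aggregate_microdata(md, spec)

  n_states <- nlevels(agg$state_id)
  if (n_states < 2 && !re_zero)
    .stopf("need data from at least 2 states to estimate state effects")
  cps <- tapply(as.character(agg$county_id), as.character(agg$state_id),
                function(x) length(unique(x)))
  if (any(cps < 2) && !re_zero)
    warning(sprintf("%d state(s) have a single county with data; their state and county effects are not separately identified",
                    sum(cps < 2)), call. = FALSE)

  rhs <- .fixed_rhs(spec)
  X <- stats::model.matrix(stats::as.formula(paste("~", rhs)), data = agg)
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop <- colnames(X)[qrX$pivot[(qrX$rank + 1):ncol(X)]]
    .stopf("singular fixed-effect design; collinear term(s): %s",
           paste(drop, collapse = ", "))
  }

  levels_used <- lapply(md[c(spec$covariates,
                             if (spec$phone_usage) "phone_usage")], levels)

  if (re_zero) {
    df0 <- as.data.frame(X[, -1, drop = FALSE], check.names = TRUE)
    preds <- if (ncol(df0))
      paste(sprintf("`%s`", names(df0)), collapse = " + ") else "1"
    df0$y <- agg$y; df0$n <- agg$n
    fit0 <- stats::glm(stats::as.formula(paste("cbind(y, n - y) ~", preds)),
                       family = stats::binomial(), data = df0)
    beta <- stats::coef(fit0)
    names(beta) <- colnames(X)
    out <- list(spec = spec, beta = beta, vcov = stats::vcov(fit0),
                vc = data.frame(group = character(0), effect = character(0),
                                sd = numeric(0)),
                re_state = NULL, re_county = NULL,
                county_state = NULL,
                levels = levels_used,
                years_fit = range(md$year), n_respondents = sum(agg$n),
                n_cells = nrow(agg), converged = fit0$converged,
                opt_message = "glm (variance components fixed at 0)",
                method = "glm")
    class(out) <- "sae_fit"
    return(out)
  }

  re_terms <- if (spec$random_slopes)
    "(1 + year_c || state_id) + (1 + year_c || county_id)"
  else
    "(1 | state_id) + (1 | county_id)"
  form <- stats::as.formula(paste("cbind(y, n - y) ~", rhs, "+", re_terms))
  ctrl <- lme4::glmerControl(
    optCtrl = list(maxfun = spec$maxit * 1000L),
    check.conv.singular = "ignore",
    calc.derivs = (spec$method == "laplace"))
  fit <- lme4::glmer(form, data = agg, family = stats::binomial(),
                     nAGQ = if (spec$method == "agq0") 0L else 1L,
                     control = ctrl)

  beta <- lme4::fixef(fit)
  V <- as.matrix(stats::vcov(fit))
  vc_df <- as.data.frame(lme4::VarCorr(fit))
  vc <- data.frame(group = sub("\\.\\d+$", "", vc_df$grp),
                   effect = vc_df$var1, sd = vc_df$sdcor,
                   stringsAsFactors = FALSE)
  re <- lme4::ranef(fit, condVar = TRUE)
  get_re <- function(gf) {
    r <- re[[gf]]
    if (is.null(r)) return(NULL)
    pv <- attr(r, "postVar")
    vars <- if (is.list(pv)) {
      vl <- lapply(pv, function(a) a[1, 1, ])
      names(vl) <- colnames(r)
      vl
    } else {
      k <- dim(pv)[1]
      vl <- lapply(seq_len(k), function(i) pv[i, i, ])
      names(vl) <- colnames(r)
      vl
    }
    out <- data.frame(id = rownames(r), stringsAsFactors = FALSE)
    out$u0 <- if ("(Intercept)" %in% colnames(r)) r[["(Intercept)"]] else 0
    out$u0_var <- if ("(Intercept)" %in% names(vars)) vars[["(Intercept)"]] else 0
    out$u1 <- if ("year_c" %in% colnames(r)) r[["year_c"]] else 0
    out$u1_var <- if ("year_c" %in% names(vars)) vars[["year_c"]] else 0
    out
  }
  conv <- length(fit@optinfo$conv$lme4) == 0 && fit@optinfo$conv$opt == 0
  county_state <- unique(agg[, c("county_id", "state_id")])
  re_state <- get_re("state_id"); re_county <- get_re("county_id")
  joint <- .joint_laplace(agg, X, beta, re_state, re_county, vc,
                          spec$random_slopes)
  out <- list(spec = spec, beta = beta, vcov = V, vc = vc, joint = joint,
              re_state = re_state, re_county = re_county,
              county_state = stats::setNames(as.character(county_state$state_id),
                                             as.character(county_state$county_id)),
              levels = levels_used,
              years_fit = range(md$year), n_respondents = sum(agg$n),
              n_cells = nrow(agg), converged = conv,
              opt_message = paste(unlist(fit@optinfo$conv$lme4$messages),
                                  collapse = "; "),
              method = spec$method)
  class(out) <- "sae_fit"
  out
}

# Joint Laplace-approximate posterior of (fixed effects, random effects).
# Simulation draws must respect the (strongly negative) cross-covariance
# between fixed-effect estimates and random-effect conditional modes;
# drawing the two independently from their marginal variances would
# systematically overstate the uncertainty of county-level predictions.
# The joint precision is the standard GLMM working matrix
#   [[X'WX, X'WZ], [Z'WX, Z'WZ + G^-1]]
# evaluated at the conditional modes, with W the binomial IRLS weights.
# Returns the joint mean, the upper Cholesky factor R of the precision
# (so draws are mean + solve(R, z)), and the coordinate layout.
.joint_laplace <- function(agg, X, beta, re_state, re_county, vc, slopes) {
  sl <- levels(agg$state_id); cl <- levels(agg$county_id)
  nS <- length(sl); nC <- length(cl); n <- nrow(agg)
  si <- as.integer(agg$state_id); ci <- as.integer(agg$county_id)
  yc <- agg$year_c
  sizes <- c(s0 = nS, c0 = nC, if (slopes) c(s1 = nS, c1 = nC))
  offs <- stats::setNames(cumsum(c(0, sizes))[seq_along(sizes)], names(sizes))
  jj <- c(si, ci + offs[["c0"]],
          if (slopes) c(si + offs[["s1"]], ci + offs[["c1"]]))
  xx <- c(rep(1, 2 * n), if (slopes) c(yc, yc))
  Z <- Matrix::sparseMatrix(i = rep(seq_len(n), if (slopes) 4L else 2L),
                            j = jj, x = xx, dims = c(n, sum(sizes)))
  pick <- function(tab, ids, col) {
    m <- match(ids, if (is.null(tab)) character(0) else tab$id)
    ifelse(is.na(m), 0, tab[[col]][m])
  }
  u <- c(pick(re_state, sl, "u0"), pick(re_county, cl, "u0"),
         if (slopes) c(pick(re_state, sl, "u1"), pick(re_county, cl, "u1")))
  eta <- drop(X %*% beta) + as.vector(Z %*% u)
  mu <- stats::plogis(eta)
  w <- agg$n * mu * (1 - mu)
  sdv <- function(g, e) {
    s <- vc$sd[vc$group == g & vc$effect == e]
    if (length(s)) s[1] else 0
  }
  prec1 <- function(s) if (s < 1e-6) 1e8 else 1 / s^2
  gprec <- c(rep(prec1(sdv("state_id", "(Intercept)")), nS),
             rep(prec1(sdv("county_id", "(Intercept)")), nC),
             if (slopes) c(rep(prec1(sdv("state_id", "year_c")), nS),
                           rep(prec1(sdv("county_id", "year_c")), nC)))
  Xw <- X * w
  Zw <- Matrix::Diagonal(x = w) %*% Z
  Pxx <- crossprod(X, Xw)
  Pxz <- as.matrix(Matrix::crossprod(X, Zw))
  Pzz <- as.matrix(Matrix::crossprod(Z, Zw)) + diag(gprec)
  P <- rbind(cbind(Pxx, Pxz), cbind(t(Pxz), Pzz))
  R <- tryCatch(chol(P), error = function(e)
    chol(P + diag(1e-8 * max(diag(P)), nrow(P))))
  list(mean = c(beta, u), R = R, p = length(beta), offs = offs,
       sizes = sizes, state_ids = sl, county_ids = cl, slopes = slopes)
}

#' @export
print.sae_fit <- function(x, ...) {
  cat(sprintf("Hierarchical SAE fit: %s smoking, %ss (%s)\n",
              x$spec$outcome, x$spec$sex, x$method))
  cat(sprintf("  %s respondents in %s cells, years %d-%d; converged: %s\n",
              format(x$n_respondents, big.mark = ","),
              format(x$n_cells, big.mark = ","),
              x$years_fit[1], x$years_fit[2], x$converged))
  if (nrow(x$vc)) {
    cat("  variance components (SD, logit scale):\n")
    for (i in seq_len(nrow(x$vc)))
      cat(sprintf("    %s %s: %.4f\n", x$vc$group[i], x$vc$effect[i], x$vc$sd[i]))
  }
  invisible(x)
}

#' @export
summary.sae_fit <- function(object, ...) {
  se <- sqrt(diag(object$vcov))
  coefs <- data.frame(estimate = object$beta, se = se,
                      z = object$beta / se)
  out <- list(spec = object$spec, coefficients = coefs, vc = object$vc,
              converged = object$converged,
              n_respondents = object$n_respondents)
  class(out) <- "summary.sae_fit"
  out
}

#' @export
print.summary.sae_fit <- function(x, ...) {
  cat(sprintf("SAE model: %s smoking, %ss\n", x$spec$outcome, x$spec$sex))
  cat("Fixed effects (logit scale):\n")
  print(round(x$coefficients, 4))
  if (nrow(x$vc)) {
    cat("Variance components (SD):\n")
    print(x$vc, row.names = FALSE)
  }
  invisible(x)
}

#' @export
coef.sae_fit <- function(object, ...) object$beta

#' @export
vcov.sae_fit <- function(object, ...) object$vcov

# random-effect lookup tables for a set of counties; unseen groups get
# conditional mean 0 and, for draws, the estimated prior variance
.re_tables <- function(fit, county_id, state_id) {
  pick <- function(tab, ids, prior0, prior1) {
    m <- match(ids, if (is.null(tab)) character(0) else tab$id)
    data.frame(
      u0 = ifelse(is.na(m), 0, tab$u0[m]),
      u0_var = ifelse(is.na(m), prior0^2, tab$u0_var[m]),
      u1 = ifelse(is.na(m), 0, tab$u1[m]),
      u1_var = ifelse(is.na(m), prior1^2, tab$u1_var[m]))
  }
  prior <- function(group, effect) {
    s <- fit$vc$sd[fit$vc$group == group & fit$vc$effect == effect]
    if (length(s)) s[1] else 0
  }
  list(state = pick(fit$re_state, state_id,
                    prior("state_id", "(Intercept)"), prior("state_id", "year_c")),
       county = pick(fit$re_county, county_id,
                     prior("county_id", "(Intercept)"), prior("county_id", "year_c")))
}

# fixed-effect design matrix on the (year x cell [x phone]) prediction grid
.prediction_grid <- function(fit, years) {
  grid <- .cell_grid()
  if (fit$spec$phone_usage) {
    ph <- fit$levels$phone_usage
    ng <- nrow(grid)
    grid <- grid[rep(seq_len(ng), times = length(ph)), , drop = FALSE]
    grid$phone_usage <- factor(rep(ph, each = ng), levels = ph)
  }
  ncell <- nrow(grid)
  grid <- grid[rep(seq_len(ncell), times = length(years)), , drop = FALSE]
  grid$year <- rep(years, each = ncell)
  grid$year_c <- grid$year - fit$spec$year_center
  rownames(grid) <- NULL
  X <- stats::model.matrix(stats::as.formula(paste("~", .fixed_rhs(fit$spec))),
                           data = grid)
  list(grid = grid, X = X[, names(fit$beta), drop = FALSE], ncell = ncell)
}

#' Predict cell-level probabilities for every county
#'
#' Computes the inverse-logit of the fixed-effect linear predictor plus the
#' predicted state and county random effects for every demographic cell in
#' every requested county-year. Counties (or states) without data receive
#' predictions through the remaining levels of the hierarchy: their random
#' effects sit at the conditional mean of zero, so an unobserved county
#' inherits its state's prediction — the model's pooling contract.
#'
#' @param object An `sae_fit`.
#' @param registry A `county_registry` defining the counties to predict.
#' @param years Years to predict; by default prediction outside the fitted
#'   year range is an error.
#' @param allow_extrapolation Permit years outside the fitted support.
#' @param ... Unused.
#' @return data.frame: `county_id`, `year`, the demographic cell columns
#'   (plus `phone_usage` for combined-frame specs), and probability `p`.
#' @export
predict.sae_fit <- function(object, registry, years,
                            allow_extrapolation = FALSE, ...) {
  if (!allow_extrapolation &&
      (min(years) < object$years_fit[1] || max(years) > object$years_fit[2]))
    .stopf("year(s) outside fitted support %d-%d (set allow_extrapolation = TRUE to override)",
           object$years_fit[1], object$years_fit[2])
  pg <- .prediction_grid(object, years)
  eta_fixed <- drop(pg$X %*% object$beta)
  ids <- registry$counties$county_id
  res <- .re_tables(object, ids, registry$counties$state_id)
  yc <- pg$grid$year_c
  out <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    off <- (res$state$u0[i] + res$county$u0[i]) +
      yc * (res$state$u1[i] + res$county$u1[i])
    out[[i]] <- data.frame(county_id = ids[i], pg$grid,
                           p = stats::plogis(eta_fixed + off),
                           stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Simulate draws of standardized county-year prevalence
#'
#' Propagates estimation uncertainty by jointly drawing fixed effects from
#' a multivariate normal around their estimates and state/county random
#' effects from their conditional normal distributions, pushing each draw
#' through the inverse logit, post-stratifying over the county's
#' demographic cells and age-standardizing — draw-wise, so the resulting
#' intervals propagate correctly through every later transformation.
#'
#' @param object An `sae_fit`.
#' @param nsim Number of draws.
#' @param seed Integer seed; the draw matrices are reproducible.
#' @param registry A `county_registry`.
#' @param years Years to simulate.
#' @param std_pop Standard population age weights.
#' @param phone_comp Year-by-age phone composition table (required for
#'   combined-frame specs), as produced by [phone_composition()].
#' @param allow_extrapolation Permit years outside the fitted support.
#' @param ... Unused.
#' @return Object of class `sae_draws`: an array `draws` of dimension
#'   counties x years x nsim holding age-standardized prevalence in
#'   percent, with county/year indices attached.
#' @export
simulate.sae_fit <- function(object, nsim = 1000L, seed = NULL, registry,
                             years, std_pop = std_pop_us2000(),
                             phone_comp = NULL, allow_extrapolation = FALSE,
                             ...) {
  if (!allow_extrapolation &&
      (min(years) < object$years_fit[1] || max(years) > object$years_fit[2]))
    .stopf("year(s) outside fitted support %d-%d",
           object$years_fit[1], object$years_fit[2])
  .check_std_pop(std_pop)
  if (object$spec$phone_usage && is.null(phone_comp))
    .stopf("combined-frame model needs a phone_comp table for post-stratification")
  .with_seed(seed, {
    pg <- .prediction_grid(object, years)
    ids <- registry$counties$county_id
    n_c <- length(ids)
    if (!is.null(object$joint)) {
      # joint posterior draws of (beta, u): preserves the cross-covariance
      # between fixed effects and conditional modes
      J <- object$joint
      q <- length(J$mean)
      Theta <- J$mean + backsolve(J$R, matrix(stats::rnorm(q * nsim), q, nsim))
      B <- Theta[seq_len(J$p), , drop = FALSE]
      sidx <- match(registry$counties$state_id, J$state_ids)
      cidx <- match(ids, J$county_ids)
      prior_sd <- function(group, effect) {
        s <- object$vc$sd[object$vc$group == group &
                            object$vc$effect == effect]
        if (length(s)) s[1] else 0
      }
      grab <- function(block, idx, psd) {
        out <- matrix(0, n_c, nsim)
        if (!block %in% names(J$offs)) return(out)
        seen <- !is.na(idx)
        if (any(seen))
          out[seen, ] <- Theta[J$p + J$offs[[block]] + idx[seen], ,
                               drop = FALSE]
        if (any(!seen))  # units without data draw from the estimated prior
          out[!seen, ] <- stats::rnorm(sum(!seen) * nsim, 0, psd)
        out
      }
      U0 <- grab("s0", sidx, prior_sd("state_id", "(Intercept)")) +
        grab("c0", cidx, prior_sd("county_id", "(Intercept)"))
      U1 <- grab("s1", sidx, prior_sd("state_id", "year_c")) +
        grab("c1", cidx, prior_sd("county_id", "year_c"))
    } else {
      # marginal fallback (e.g. pooled fits with variance pinned to zero):
      # independent draws around estimates and conditional means
      B <- .mvn_draws(nsim, object$beta, object$vcov)
      res <- .re_tables(object, ids, registry$counties$state_id)
      draw_re <- function(tab) list(
        u0 = matrix(stats::rnorm(n_c * nsim, tab$u0,
                                 sqrt(pmax(tab$u0_var, 0))), n_c, nsim),
        u1 = matrix(stats::rnorm(n_c * nsim, tab$u1,
                                 sqrt(pmax(tab$u1_var, 0))), n_c, nsim))
      rs <- draw_re(res$state); rc <- draw_re(res$county)
      U0 <- rs$u0 + rc$u0; U1 <- rs$u1 + rc$u1
    }
    Feta <- pg$X %*% B                                      # (years*cells) x nsim
    W <- .std_weight_matrix(object, registry, years, std_pop, phone_comp, pg)
    draws <- array(NA_real_, c(n_c, length(years), nsim),
                   dimnames = list(ids, years, NULL))
    for (yi in seq_along(years)) {
      rows <- which(pg$grid$year == years[yi])
      Fy <- Feta[rows, , drop = FALSE]                      # ncell x nsim
      ycv <- years[yi] - object$spec$year_center
      for (ci in seq_len(n_c)) {
        eta <- Fy + rep(U0[ci, ] + ycv * U1[ci, ], each = length(rows))
        draws[ci, yi, ] <- 100 * crossprod(W[[yi]][, ci], stats::plogis(eta))[1, ]
      }
    }
    structure(list(draws = draws, county_id = ids, years = years,
                   sex = object$spec$sex, outcome = object$spec$outcome,
                   nsim = nsim),
              class = "sae_draws")
  })
}

# post-stratification weight matrices (cells x counties), one per year.
# Without a phone term the weights are year-invariant; with one, the
# demographic weights are split over phone categories by the year/age
# composition.
.std_weight_matrix <- function(fit, registry, years, std_pop, phone_comp, pg) {
  base <- .county_cell_weights(registry, std_pop)   # list per county, 108 cells
  Wd <- do.call(cbind, base)
  if (!fit$spec$phone_usage) return(rep(list(Wd), length(years)))
  ph <- fit$levels$phone_usage
  lapply(seq_along(years), function(yi) {
    pcy <- phone_comp[phone_comp$year == years[yi], ]
    if (!nrow(pcy)) .stopf("phone_comp lacks year %d", years[yi])
    g <- .cell_grid()
    pi_mat <- as.matrix(pcy[match(g$age_group, pcy$age_group), ph, drop = FALSE])
    do.call(rbind, lapply(seq_along(ph), function(k) Wd * pi_mat[, k]))
  })
}

#' Point and interval estimates of standardized prevalence
#'
#' Convenience wrapper running [simulate.sae_fit()] and summarizing the
#' draws to the reported quantity: age-standardized prevalence (percent)
#' with a 95% uncertainty interval (2.5th/97.5th draw percentiles) per
#' county-year. The draw array is kept in the `draws` attribute so that
#' later stages (bias correction, trend significance, rank intervals) can
#' work draw-wise.
#'
#' @inheritParams simulate.sae_fit
#' @param fit An `sae_fit`.
#' @param n_draws Number of simulation draws.
#' @return data.frame of class `sae_estimates`: `county_id`, `year`, `sex`,
#'   `outcome`, `mean`, `lower`, `upper` (percent), with attribute `draws`
#'   (an `sae_draws`).
#' @export
sae_estimates <- function(fit, registry, years, std_pop = std_pop_us2000(),
                          n_draws = 1000L, seed = NULL, phone_comp = NULL,
                          allow_extrapolation = FALSE) {
  dr <- simulate.sae_fit(fit, nsim = n_draws, seed = seed, registry = registry,
                         years = years, std_pop = std_pop,
                         phone_comp = phone_comp,
                         allow_extrapolation = allow_extrapolation)
  .summarize_draws(dr)
}

.summarize_draws <- function(dr) {
  d <- dr$draws
  qs <- apply(d, c(1, 2), stats::quantile, probs = c(.025, .975), names = FALSE)
  out <- data.frame(
    county_id = rep(dr$county_id, times = length(dr$years)),
    year = rep(dr$years, each = length(dr$county_id)),
    sex = dr$sex, outcome = dr$outcome,
    mean = as.vector(apply(d, c(1, 2), mean)),
    lower = as.vector(qs[1, , ]),
    upper = as.vector(qs[2, , ]),
    stringsAsFactors = FALSE)
  attr(out, "draws") <- dr
  class(out) <- c("sae_estimates", "data.frame")
  out
}

#' Plug-in point estimates of standardized prevalence (no draws)
#'
#' Standardizes the point predictions directly (fixed effects and
#' random-effect conditional means, no simulation). Used where only point
#' agreement matters, e.g. scoring sampled-down fits against the gold
#' standard.
#'
#' @inheritParams sae_estimates
#' @return data.frame: `county_id`, `year`, `sex`, `outcome`, `mean`
#'   (percent).
#' @export
sae_point_estimates <- function(fit, registry, years,
                                std_pop = std_pop_us2000(), phone_comp = NULL,
                                allow_extrapolation = FALSE) {
  if (fit$spec$phone_usage && is.null(phone_comp))
    .stopf("combined-frame model needs a phone_comp table")
  pg <- .prediction_grid(fit, years)
  if (!allow_extrapolation &&
      (min(years) < fit$years_fit[1] || max(years) > fit$years_fit[2]))
    .stopf("year(s) outside fitted support %d-%d",
           fit$years_fit[1], fit$years_fit[2])
  eta_fixed <- drop(pg$X %*% fit$beta)
  ids <- registry$counties$county_id
  res <- .re_tables(fit, ids, registry$counties$state_id)
  W <- .std_weight_matrix(fit, registry, years, std_pop, phone_comp, pg)
  out <- expand.grid(county_id = ids, year = years,
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$sex <- fit$spec$sex; out$outcome <- fit$spec$outcome
  out$mean <- NA_real_
  for (yi in seq_along(years)) {
    rows <- which(pg$grid$year == years[yi])
    ycv <- years[yi] - fit$spec$year_center
    for (ci in seq_along(ids)) {
      off <- (res$state$u0[ci] + res$county$u0[ci]) +
        ycv * (res$state$u1[ci] + res$county$u1[ci])
      p <- stats::plogis(eta_fixed[rows] + off)
      out$mean[out$county_id == ids[ci] & out$year == years[yi]] <-
        100 * sum(W[[yi]][, ci] * p)
    }
  }
  out
}
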