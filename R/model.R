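#' @title Bayesian hierarchical growth model of anaerobe dynamics
#' @description
#' The per-day log change y of obligate anaerobe density is modeled as
#' normally distributed around a linear predictor,
#'
#'   y_j ~ Normal(mu_j, sigma_m)
#'   mu_j = r + beta_p1 phase1_j + beta_p2 phase2_j
#'          + sum_i beta_a_i A_ij
#'          + sum_g (beta_o + o_dev_g) Pr_gj
#'          + p_int[patient_j] + beta_c N_start_scaled_j
#'
#' with intrinsic growth rate r, conditioning (phase I) and preengraftment
#' neutropenia (phase II) effects, unpooled effects beta_a for the seven
#' empirical antibiotics, a pooled prophylaxis effect beta_o from which each
#' of the four prophylactic agents deviates (partial pooling, o_dev), a
#' per-patient random intercept p_int (partial pooling), and a capacity
#' coefficient beta_c on the scaled start-of-interval density — the
#' growth-limiting term of the logistic growth equation.
#'
#' Priors: Normal(0, sd 100) on r, the phase effects and each empirical
#' antibiotic effect (effectively uninformative on the 1/day scale);
#' regularizing Normal(0, sd sqrt(0.1)) on beta_o and beta_c; the pooled
#' deviations are non-centered, o_dev_g = eta_g * tau_O with eta_g ~
#' Normal(0,1) and half-Normal(sd sqrt(0.1)) hyper-scales tau_O, tau_P;
#' half-Normal(sd 1) on sigma_m.
#' @name anaerobe_model
NULL

#' Build the regression design from a delta table
#'
#' @param deltas table from [build_deltas()].
#' @return list with response `y`, phase vectors, empirical indicator matrix
#'   `A` (n x 7), prophylactic indicator matrix `Pr` (n x 4), integer
#'   `patient` index with level vector `patients`, capacity regressor
#'   `n_scaled`, and `flagged` — covariates with zero variance in this
#'   cohort (their posteriors return the prior).
#' @export
build_design <- function(deltas) {
  stopifnot(nrow(deltas) >= 1)
  emp <- empirical_labels(); pro <- prophylactic_labels()
  A <- as.matrix(deltas[emp]); colnames(A) <- emp
  Pr <- as.matrix(deltas[pro]); colnames(Pr) <- pro
  patients <- sort(unique(deltas$patient_id))
  flagged <- c(emp, pro)[apply(cbind(A, Pr), 2, function(x) length(unique(x))) == 1]
  if (length(flagged))
    message("covariate(s) with zero variance (posterior = prior): ",
            paste(flagged, collapse = ", "))
  list(y = deltas$y, n = nrow(deltas),
       phase1 = deltas$phase1, phase2 = deltas$phase2,
       A = A, Pr = Pr,
       patient = match(deltas$patient_id, patients), patients = patients,
       n_scaled = deltas$N_start_scaled, flagged = flagged)
}

.jags_model_string <- function(with_likelihood = TRUE) {
  lik <- if (with_likelihood) "
  for (j in 1:n) {
    mu[j] <- r + bp1 * phase1[j] + bp2 * phase2[j] + inprod(ba[], A[j, ]) +
             inprod(bpro[], Pr[j, ]) + pint[pat[j]] + bc * nss[j]
    y[j] ~ dnorm(mu[j], prec)
  }" else ""
  paste0("model {", lik, "
  r   ~ dnorm(0, 1.0E-4)
  bp1 ~ dnorm(0, 1.0E-4)
  bp2 ~ dnorm(0, 1.0E-4)
  for (k in 1:K) { ba[k] ~ dnorm(0, 1.0E-4) }
  bo ~ dnorm(0, 10)
  for (g in 1:G) {
    eta_o[g] ~ dnorm(0, 1)
    odev[g] <- eta_o[g] * tauO
    bpro[g] <- bo + odev[g]
  }
  tauO ~ dnorm(0, 10) T(0,)
  for (p in 1:P) {
    eta_p[p] ~ dnorm(0, 1)
    pint[p] <- eta_p[p] * tauP
  }
  tauP ~ dnorm(0, 10) T(0,)
  bc ~ dnorm(0, 10)
  sigma ~ dnorm(0, 1) T(0,)
  prec <- 1 / (sigma * sigma)
}")
}

#' Fit the hierarchical growth model by MCMC
#'
#' Samples the posterior with Gibbs/slice sampling via JAGS, 3 chains by
#' default, and attaches split-chain R-hat and effective-sample-size
#' diagnostics for every monitored parameter. `draws` is the total number of
#' post-warmup draws across all chains (set `per_chain = TRUE` to make it
#' per chain).
#'
#' @param deltas table from [build_deltas()]; may have zero rows, in which
#'   case the prior is sampled (useful for prior-predictive checks).
#' @param chains number of independent chains.
#' @param draws total post-warmup draws (across chains unless `per_chain`).
#' @param warmup burn-in iterations per chain, discarded.
#' @param seed integer seed; chain c uses seed + c.
#' @param per_chain interpret `draws` per chain.
#' @param adapt JAGS adaptation iterations.
#' @param patients patient levels when `deltas` is empty.
#' @return object of class `anaerobe_posterior`: list with `draws` (matrix,
#'   total draws x parameters, named columns such as
#'   `beta_a[piperacillin-tazobactam]`), `chain` index vector, `labels`,
#'   `diagnostics` (parameter, rhat, ess), `flagged` covariates, and
#'   sampler settings.
#' @export
fit_anaerobe_model <- function(deltas, chains = 3, draws = 10000,
                               warmup = 1000, seed = 1, per_chain = FALSE,
                               adapt = 500, patients = NULL) {
  emp <- empirical_labels(); pro <- prophylactic_labels()
  has_data <- nrow(deltas) > 0
  if (has_data) {
    des <- build_design(deltas)
    patients <- des$patients
    flagged <- des$flagged
  } else {
    if (is.null(patients)) patients <- "none"
    flagged <- character(0)
  }
  dat <- list(K = length(emp), G = length(pro), P = length(patients))
  if (has_data)
    dat <- c(dat, list(n = des$n, y = des$y, phase1 = des$phase1,
                       phase2 = des$phase2, A = des$A, Pr = des$Pr,
                       pat = des$patient, nss = des$n_scaled))
  inits <- lapply(seq_len(chains), function(c)
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer(seed) + c))
  n_iter <- if (per_chain) draws else ceiling(draws / chains)

  jm <- rjags::jags.model(textConnection(.jags_model_string(has_data)),
                          data = dat, inits = inits, n.chains = chains,
                          n.adapt = adapt, quiet = TRUE)
  stats::update(jm, warmup, progress.bar = "none")
  monitors <- c("r", "bp1", "bp2", "ba", "bo", "odev", "pint", "bc",
                "sigma", "tauO", "tauP")
  sims <- rjags::coda.samples(jm, monitors, n.iter = n_iter,
                              progress.bar = "none")

  rename <- function(x) {
    x[x == "r"] <- "r"
    x <- sub("^bp1$", "beta_p1", x)
    x <- sub("^bp2$", "beta_p2", x)
    for (k in seq_along(emp)) x[x == sprintf("ba[%d]", k)] <-
        sprintf("beta_a[%s]", emp[k])
    x[x == "bo"] <- "beta_o"
    for (g in seq_along(pro)) x[x == sprintf("odev[%d]", g)] <-
        sprintf("o_dev[%s]", pro[g])
    for (p in seq_along(patients)) x[x == sprintf("pint[%d]", p)] <-
        sprintf("p_int[%s]", patients[p])
    x[x == "bc"] <- "beta_c"
    x[x == "sigma"] <- "sigma_m"
    x[x == "tauO"] <- "tau_O"
    x[x == "tauP"] <- "tau_P"
    x
  }
  diag <- .mcmc_diagnostics(sims)
  mat <- do.call(rbind, lapply(sims, as.matrix))
  colnames(mat) <- rename(colnames(mat))
  diag$parameter <- rename(diag$parameter)

  structure(list(
    draws = mat,
    chain = rep(seq_len(chains), each = n_iter),
    labels = list(empirical = emp, prophylactic = pro, patients = patients),
    diagnostics = diag, flagged = flagged, n_divergent = 0L,
    sampler = list(engine = "JAGS (Gibbs/slice)", chains = chains,
                   draws_per_chain = n_iter, warmup = warmup, seed = seed)),
    class = "anaerobe_posterior")
}

.mcmc_diagnostics <- function(sims) {
  pars <- coda::varnames(sims)
  ess <- coda::effectiveSize(sims)
  rhat <- rep(NA_real_, length(pars))
  if (length(sims) >= 2) {
    keep <- vapply(pars, function(p)
      stats::var(unlist(lapply(sims, function(ch) as.numeric(ch[, p])))) > 0,
      logical(1))
    if (any(keep)) {
      gd <- try(coda::gelman.diag(sims[, pars[keep], drop = FALSE],
                                  multivariate = FALSE, autoburnin = FALSE),
                silent = TRUE)
      if (!inherits(gd, "try-error")) rhat[keep] <- gd$psrf[, 1]
    }
  }
  data.frame(parameter = pars, rhat = rhat, ess = as.numeric(ess[pars]),
             stringsAsFactors = FALSE)
}

#' @export
print.anaerobe_posterior <- function(x, ...) {
  cat("anaerobe growth-model posterior:",
      nrow(x$draws), "draws x", ncol(x$draws), "parameters (",
      x$sampler$chains, "chains )\n")
  bad <- x$diagnostics$parameter[!is.na(x$diagnostics$rhat) &
                                   x$diagnostics$rhat >= 1.05]
  if (length(bad)) cat("  R-hat >= 1.05 for:", paste(bad, collapse = ", "), "\n")
  invisible(x)
}

#' Posterior effect summaries (forest-plot data)
#'
#' Posterior mean and central 95% credible interval per parameter. Each
#' prophylactic agent is reported as the sum beta_o + o_dev of the pooled
#' effect and its deviation; the pooled effect, capacity coefficient and
#' residual sd are reported as well.
#'
#' @param object an `anaerobe_posterior`.
#' @param ... unused.
#' @return data.frame `parameter, mean, lower, upper`.
#' @export
summary.anaerobe_posterior <- function(object, ...) {
  d <- object$draws
  if (nrow(d) < 100) stop("need at least 100 posterior draws to summarize")
  one <- function(label, x) data.frame(
    parameter = label, mean = mean(x),
    lower = unname(stats::quantile(x, 0.025)),
    upper = unname(stats::quantile(x, 0.975)), stringsAsFactors = FALSE)
  rows <- list(one("growth rate (r)", d[, "r"]),
               one("phase I", d[, "beta_p1"]),
               one("phase II", d[, "beta_p2"]))
  for (lab in object$labels$empirical)
    rows <- c(rows, list(one(lab, d[, sprintf("beta_a[%s]", lab)])))
  for (lab in object$labels$prophylactic)
    rows <- c(rows, list(one(lab, d[, "beta_o"] + d[, sprintf("o_dev[%s]", lab)])))
  rows <- c(rows, list(one("prophylaxis (pooled)", d[, "beta_o"]),
                       one("capacity (beta_c)", d[, "beta_c"]),
                       one("sigma_m", d[, "sigma_m"])))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Model log-likelihood at a fixed parameter point
#'
#' Gaussian log density of all observed deltas given one parameter point —
#' the likelihood the MCMC fit targets (priors excluded).
#'
#' @param deltas table from [build_deltas()].
#' @param params list with elements `r`, `beta_p1`, `beta_p2`, `beta_a`
#'   (named over [empirical_labels()]), `beta_o`, `o_dev` (named over
#'   [prophylactic_labels()]), `p_int` (named over patient ids), `beta_c`,
#'   `sigma_m`.
#' @return scalar log-likelihood.
#' @export
delta_loglik <- function(deltas, params) {
  stopifnot(params$sigma_m > 0)
  des <- build_design(deltas)
  mu <- .linear_predictor(des, params)
  sum(stats::dnorm(des$y, mu, params$sigma_m, log = TRUE))
}

.linear_predictor <- function(des, params) {
  ba <- params$beta_a[colnames(des$A)]
  od <- params$o_dev[colnames(des$Pr)]
  pint <- params$p_int[des$patients][des$patient]
  as.numeric(
    params$r + params$beta_p1 * des$phase1 + params$beta_p2 * des$phase2 +
      des$A %*% ba + des$Pr %*% (params$beta_o + od) + pint +
      params$beta_c * des$n_scaled)
}

#' Construct a degenerate (point-mass) posterior
#'
#' All draws equal the supplied parameter values. Useful for what-if
#' predictions with fixed effects and for closed-form validation of the
#' forward simulator and course-loss machinery.
#'
#' @param r,beta_p1,beta_p2,beta_o,beta_c,sigma_m scalars.
#' @param beta_a scalar or named vector over [empirical_labels()].
#' @param o_dev scalar or named vector over [prophylactic_labels()].
#' @param p_int scalar or named vector over `patients`.
#' @param patients patient id levels.
#' @param n_draws number of (identical) draws to emit.
#' @return an `anaerobe_posterior`.
#' @export
point_mass_posterior <- function(r = 0, beta_p1 = 0, beta_p2 = 0,
                                 beta_a = 0, o_dev = 0, beta_o = 0,
                                 beta_c = 0, sigma_m = 0.5, p_int = 0,
                                 patients = "none", n_draws = 1) {
  emp <- empirical_labels(); pro <- prophylactic_labels()
  expand <- function(x, labs) {
    if (length(x) == 1 && is.null(names(x))) return(stats::setNames(rep(x, length(labs)), labs))
    full <- stats::setNames(numeric(length(labs)), labs)
    stopifnot(all(names(x) %in% labs))
    full[names(x)] <- x
    full
  }
  ba <- expand(beta_a, emp); od <- expand(o_dev, pro)
  pi <- expand(p_int, patients)
  vals <- c(r = r, beta_p1 = beta_p1, beta_p2 = beta_p2,
            stats::setNames(ba, sprintf("beta_a[%s]", emp)),
            beta_o = beta_o,
            stats::setNames(od, sprintf("o_dev[%s]", pro)),
            stats::setNames(pi, sprintf("p_int[%s]", patients)),
            beta_c = beta_c, sigma_m = sigma_m, tau_O = 0, tau_P = 0)
  mat <- matrix(rep(vals, each = n_draws), nrow = n_draws,
                dimnames = list(NULL, names(vals)))
  structure(list(draws = mat, chain = rep(1L, n_draws),
                 labels = list(empirical = emp, prophylactic = pro,
                               patients = patients),
                 diagnostics = data.frame(parameter = character(0),
                                          rhat = numeric(0), ess = numeric(0)),
                 flagged = character(0), n_divergent = 0L,
                 sampler = list(engine = "point mass", chains = 1,
                                draws_per_chain = n_draws, warmup = 0,
                                seed = NA)),
            class = "anaerobe_posterior")
}
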