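# Negative-binomial GLM machinery shared by the dispersion estimator and
# the dimorphism tests. Fitting goes through stats::glm.fit with the
# MASS negative-binomial family at fixed dispersion (theta = 1/phi),
# IRLS convergence 1e-8, max 100 iterations.

PHI_FLOOR <- 1e-6

nb_family <- function(phi) {
  MASS::negative.binomial(theta = 1 / max(phi, PHI_FLOOR), link = "log")
}

# Fit one gene; returns fitted means, deviance and log-likelihood.
fit_nb_glm <- function(y, X, offset, phi) {
  fam <- nb_family(phi)
  fit <- suppressWarnings(
    stats::glm.fit(x = X, y = y, family = fam, offset = offset,
                   control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  )
  mu <- fit$fitted.values
  list(coefficients = fit$coefficients,
       fitted = mu,
       deviance = fit$deviance,
       loglik = nb_loglik(y, mu, phi),
       converged = fit$converged)
}

nb_loglik <- function(y, mu, phi) {
  sum(dnbinom(y, mu = pmax(mu, 1e-12), size = 1 / max(phi, PHI_FLOOR),
              log = TRUE))
}

# Cox-Reid adjusted profile log-likelihood for one gene at dispersion phi,
# with fitted means held fixed. The adjustment subtracts half the log
# determinant of the Fisher information X' W X (ridge-stabilised so that
# structurally-zero groups do not blow up).
nb_apl <- function(y, mu, phi, X) {
  w <- mu / (1 + max(phi, PHI_FLOOR) * mu)
  info <- crossprod(X, X * w) + diag(1e-8, ncol(X))
  nb_loglik(y, mu, phi) - 0.5 * determinant(info, logarithm = TRUE)$modulus[1]
}

# Design matrices for the factorial dimorphism models. Sex is coded with
# male as reference so the sex coefficient is log(F/M).
dimorphism_designs <- function(design) {
  tiss <- design$tissue
  sex <- design$sex
  if (nlevels(droplevels(tiss)) < 2L || nlevels(droplevels(sex)) < 2L)
    stop("design must contain both tissues and both sexes")
  gonad <- as.numeric(tiss == "gonad")
  female <- as.numeric(sex == "F")
  n <- length(gonad)
  full <- cbind(intercept = 1, gonad = gonad, female = female,
                gonad_female = gonad * female)
  list(
    full = full,
    # sex effect removed in blastoderm, free in gonad
    no_sex_blastoderm = cbind(intercept = 1, gonad = gonad,
                              gonad_female = gonad * female),
    # sex effect removed in gonad, free in blastoderm
    no_sex_gonad = cbind(intercept = 1, gonad = gonad,
                         blastoderm_female = (1 - gonad) * female),
    additive = cbind(intercept = 1, gonad = gonad, female = female),
    sex_only = cbind(intercept = 1, female = female)
  )
}
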