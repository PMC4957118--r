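# Independent oracles used across the suite. These deliberately avoid the
# package's closed forms: marginal likelihoods by nested adaptive
# quadrature, FDR machinery by brute-force enumeration, AUROC by explicit
# pair counting.

dinvgamma_ <- function(s2, alpha, beta)
  exp(alpha * log(beta) - lgamma(alpha) - (alpha + 1) * log(s2) - beta / s2)

# 2-D quadrature of the H0 marginal: integrate mu then sigma^2. The mu
# integrand is log-quadratic, so its peak (stationary point of the
# exponent, by elementary calculus) and width guide finite integration
# bounds - infinite-range adaptive rules can miss a narrow peak entirely.
quad_log_ml_h0 <- function(y, hp) {
  n <- length(y)
  if (n == 0) return(0)
  m_star <- (sum(y) + hp$mu0) / (n + 1)
  f_outer <- function(s2v) sapply(s2v, function(s2) {
    s <- sqrt(s2)
    w <- 15 * s / sqrt(n + 1)
    inner <- integrate(function(muv) sapply(muv, function(m)
      exp(sum(dnorm(y, m, s, log = TRUE)) +
            dnorm(m, hp$mu0, s, log = TRUE))),
      m_star - w, m_star + w, rel.tol = 1e-10)$value
    inner * dinvgamma_(s2, hp$alpha, hp$beta)
  })
  log(integrate(f_outer, 0, Inf, rel.tol = 1e-9)$value)
}

# 3-D quadrature of the H1 marginal: mu, then tau, then sigma^2. The
# (mu, tau) integrand is log-quadratic with exponent
#   -(1/2s2)[ sum(yc-mu)^2 + sum(yt-mu-tau)^2 + (mu-mu0)^2 + (tau-tau0)^2/k ]
# whose stationary point solves a 2x2 linear system; that peak and the
# implied widths (from the same quadratic) guide finite integration bounds
# at every sigma^2. Values are still computed purely by quadrature.
quad_log_ml_h1 <- function(yc, yt, hp) {
  n <- length(yc) + length(yt)
  if (n == 0) return(0)
  nt <- length(yt)
  a_mat <- rbind(c(n + 1, nt), c(nt, nt + 1 / hp$kappa))
  b_vec <- c(sum(yc) + sum(yt) + hp$mu0, sum(yt) + hp$tau0 / hp$kappa)
  peak <- solve(a_mat, b_vec)                 # (mu_hat, tau_hat)
  tau_sd_unit <- sqrt((n + 1) / det(a_mat))   # tau width in units of s
  f_outer <- function(s2v) sapply(s2v, function(s2) {
    s <- sqrt(s2)
    tau_w <- 15 * s * tau_sd_unit
    mid <- integrate(function(tauv) sapply(tauv, function(tau) {
      m_star <- (sum(yc) + sum(yt) - nt * tau + hp$mu0) / (n + 1)
      mu_w <- 15 * s / sqrt(n + 1)
      inner <- integrate(function(muv) sapply(muv, function(m)
        exp(sum(dnorm(yc, m, s, log = TRUE)) +
              sum(dnorm(yt, m + tau, s, log = TRUE)) +
              dnorm(m, hp$mu0, s, log = TRUE))),
        m_star - mu_w, m_star + mu_w, rel.tol = 1e-10)$value
      inner * dnorm(tau, hp$tau0, sqrt(hp$kappa) * s)
    }), peak[2] - tau_w, peak[2] + tau_w, rel.tol = 1e-9)$value
    mid * dinvgamma_(s2, hp$alpha, hp$beta)
  })
  log(integrate(f_outer, 0, Inf, rel.tol = 1e-8)$value)
}

# brute-force expected FDR: literal sum over the call set
brute_expected_fdr <- function(post, p_th, c = 0) {
  called <- which(post >= p_th)
  if (length(called) == 0 && c == 0) return(NA_real_)
  if (length(called) == 0) return(0)
  s <- 0
  for (i in called) s <- s + (1 - post[i])
  s / (c + length(called))
}

# brute-force threshold selection: try every unique posterior as threshold
brute_select_threshold <- function(post, alpha, c = 0) {
  cand <- sort(unique(post))
  adm <- cand[vapply(cand, function(t) {
    e <- brute_expected_fdr(post, t, c)
    !is.na(e) && e <= alpha
  }, logical(1))]
  if (length(adm)) min(adm) else NA_real_
}

# AUROC by explicit positive-negative pair counting (ties = 1/2)
pairwise_auroc <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + if (a > b) 1 else if (a == b) 0.5 else 0
  tot / (length(pos) * length(neg))
}

# random small protein fixture for the quadrature comparisons
random_obs <- function(seed, max_n = 8) {
  set.seed(seed)
  nc <- sample(0:max_n, 1)
  nt <- sample((if (nc == 0) 1 else 0):max_n, 1)
  group_observations(rnorm(nc, 0, 1.5), rnorm(nt, 0.8, 1.5),
                     n_missing_ctrl = sample(0:3, 1),
                     n_missing_trt = sample(0:3, 1))
}

random_hp <- function(seed) {
  set.seed(seed + 500)
  hyperparams(mu0 = runif(1, -1, 1), alpha = runif(1, 1.2, 5),
              beta = runif(1, 0.5, 3), tau0 = 0,
              kappa = runif(1, 0.3, 4), phi = runif(1, 0.2, 5))
}

# small two-group matrix with controlled missingness, for unit tests
toy_matrix <- function(n_proteins = 20, n_per_group = 4, seed = 1,
                       missing_fraction = 0.15) {
  set.seed(seed)
  v <- matrix(rnorm(n_proteins * 2 * n_per_group, 15, 2), n_proteins)
  im <- intensity_matrix(v, groups = rep(c("CTRL", "TRT"), each = n_per_group))
  censor_detection_limit(im, missing_fraction)
}
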