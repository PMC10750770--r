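# well-conditioned random correlation matrix
rand_cor <- function(p, n = 50 * p, seed = 1) {
  set.seed(seed)
  cor(matrix(rnorm(n * p), n, p))
}

# partial-correlation matrix of a chain graph 1-2-...-p
chain_partial <- function(p, r = 0.3) {
  P <- matrix(0, p, p)
  for (i in seq_len(p - 1)) P[i, i + 1] <- P[i + 1, i] <- r
  dimnames(P) <- list(paste0("V", seq_len(p)), paste0("V", seq_len(p)))
  P
}

# multivariate normal sample via Cholesky
mvn_sample <- function(Sigma, n) {
  L <- t(chol(Sigma))
  t(L %*% matrix(rnorm(n * nrow(Sigma)), nrow(Sigma), n))
}

# small hand-written raw cohort: 3 subjects x 2 timepoints
tiny_cohort <- function() {
  items <- rpq_items()
  grid <- expand.grid(subject_id = c("a", "b", "c"),
                      timepoint = c("W2", "M3"),
                      stringsAsFactors = FALSE)
  set.seed(42)
  m <- matrix(sample(0:4, nrow(grid) * 16, replace = TRUE), nrow(grid),
              dimnames = list(NULL, items))
  cbind(grid, as.data.frame(m),
        gcs = 15L, age = 40, female_sex = 0L, education = 14,
        prior_tbi = 0L, psychiatric_history = 0L, ct_positive = 0L,
        gose = NA_integer_, qolibri = NA_real_, sf12_pcs = NA_real_,
        sf12_mcs = NA_real_)
}

# support (upper-triangular adjacency) of a weight or precision matrix
support_of <- function(M) {
  abs(M[upper.tri(M)]) > 1e-12
}

# outcome-generating coefficients with a single active logistic effect
# (log odds ratio log(2) on the cognitive factor) and quiet linear models
single_effect_coefs <- function(beta_cog = log(2)) {
  zero_cov <- c(age = 0, female_sex = 0, education = 0, prior_tbi = 0,
                psychiatric_history = 0, ct_positive = 0)
  list(
    gose_incomplete = c(intercept = 0, emotional = 0,
                        cognitive = beta_cog, visual = 0, somatic = 0,
                        other = 0, zero_cov),
    qolibri = list(coefs = c(intercept = 70, emotional = 0, cognitive = 0,
                             visual = 0, somatic = 0, other = 0, zero_cov),
                   sd = 10),
    sf12_pcs = list(coefs = c(intercept = 50, emotional = 0, cognitive = 0,
                              visual = 0, somatic = 0, other = 0, zero_cov),
                    sd = 9),
    sf12_mcs = list(coefs = c(intercept = 50, emotional = 0, cognitive = 0,
                              visual = 0, somatic = 0, other = 0, zero_cov),
                    sd = 10)
  )
}
.default_outcome_coefs_for_test <- function() single_effect_coefs()
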