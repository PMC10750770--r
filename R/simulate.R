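#' Latent covariance implied by a target partial-correlation matrix
#'
#' Builds the precision matrix with unit diagonal and off-diagonal
#' `-p_ij`, so that its partial correlations equal `P` exactly, and
#' inverts it to a correlation-scaled covariance. If the assembled
#' precision is not positive definite it is repaired by adding a ridge to
#' the diagonal (diagonal dominance repair), which shrinks the realized
#' partial correlations; the realized matrix is returned in attribute
#' `"partial"` together with a `"repaired"` flag.
#'
#' @param P Symmetric matrix of target partial correlations (diagonal
#'   ignored).
#' @return Latent correlation matrix `Sigma`, with attributes `precision`,
#'   `partial` (realized values) and `repaired`.
#' @export
partial_to_covariance <- function(P) {
  P <- as.matrix(P)
  p <- nrow(P)
  stopifnot(ncol(P) == p, max(abs(P - t(P))) < 1e-10)
  Omega <- -P
  diag(Omega) <- 1
  ev <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
  repaired <- FALSE
  if (ev < 1e-6) {
    Omega <- Omega + diag(abs(ev) + 0.05, p)
    repaired <- TRUE
    ev2 <- min(eigen(Omega, symmetric = TRUE, only.values = TRUE)$values)
    if (ev2 < 1e-8) {
      stop("requested edge-weight configuration is infeasible even after ",
           "diagonal repair", call. = FALSE)
    }
  }
  Sigma <- solve(Omega)
  d <- sqrt(diag(Sigma))
  Sigma <- Sigma / outer(d, d)
  dimnames(Sigma) <- dimnames(P)
  realized <- precision_to_partial(Omega)
  structure(Sigma, precision = Omega, partial = realized,
            repaired = repaired)
}

# default cross-cluster item edges: designed so the cognitive composite
# carries the largest signed connectivity at the node level, fatigue and
# the emotional composite are next, and nausea is weakly tied
.default_cross_edges <- data.frame(
  item_i = c("headache", "dizziness", "noise_sensitivity",
             "sleep_disturbance", "fatigue", "poor_concentration",
             "poor_memory", "irritable", "restlessness"),
  item_j = c("dizziness", "nausea", "headache",
             "fatigue", "slow_thinking", "irritable",
             "headache", "fatigue", "sleep_disturbance"),
  weight = c(0.25, 0.18, 0.15,
             0.20, 0.25, 0.25,
             0.15, 0.10, 0.15),
  stringsAsFactors = FALSE
)

# default ordinal thresholds: 45% symptom-free, tapering severity
.default_thresholds <- function() {
  tau <- qnorm(c(0.45, 0.70, 0.85, 0.95))
  m <- matrix(tau, nrow = 16, ncol = 4, byrow = TRUE,
              dimnames = list(rpq_items(), NULL))
  m
}

# default outcome-generating coefficients on the recoded 0-3 factor scale
.default_outcome_coefs <- function() {
  list(
    gose_incomplete = c(intercept = -0.9,
                        emotional = log(1.39), cognitive = log(1.39),
                        visual = 0, somatic = log(1.84),
                        other = log(1.55),
                        c(age = 0.01, female_sex = 0.3, education = -0.05,
                          prior_tbi = 0.2, psychiatric_history = 0.4,
                          ct_positive = 0.3)),
    qolibri = list(coefs = c(intercept = 78, emotional = -5.27,
                             cognitive = -3.09, visual = -3.00,
                             somatic = 0, other = -3.58,
                             c(age = -0.05, female_sex = 0,
                               education = 0.3, prior_tbi = -1,
                               psychiatric_history = -3,
                               ct_positive = -1)),
                   sd = 14),
    sf12_pcs = list(coefs = c(intercept = 52, emotional = 0,
                              cognitive = 0, visual = 0, somatic = -1.51,
                              other = -2.45,
                              c(age = -0.08, female_sex = 0,
                                education = 0.1, prior_tbi = -0.5,
                                psychiatric_history = -1,
                                ct_positive = -0.5)),
                    sd = 9),
    sf12_mcs = list(coefs = c(intercept = 54, emotional = -2.72,
                              cognitive = -1.40, visual = -1.51,
                              somatic = 0, other = 0,
                              c(age = 0.02, female_sex = -0.5,
                                education = 0.1, prior_tbi = 0,
                                psychiatric_history = -3,
                                ct_positive = 0)),
                    sd = 10)
  )
}

#' Construct the ground-truth specification for synthetic cohorts
#'
#' Assembles a 16-item latent partial-correlation structure with three
#' tight clusters — the emotional (irritable, depressed, frustrated),
#' cognitive (poor memory, poor concentration, slow thinking) and visual
#' (blurred vision, light sensitivity, double vision) triplets, with
#' within-cluster partial correlations drawn uniformly from
#' `cluster_weight_range` — plus configurable cross-cluster edges, ordinal
#' thresholds mapping the latent margins to 0-4 item scores, a
#' within-subject across-timepoint latent correlation, and
#' outcome-generating coefficient vectors. The implied node-level
#' (composite) network and its expected-influence ranking are computed
#' analytically and stored, so every downstream stage has a known truth.
#'
#' @param seed Integer seed; the spec is deterministic given the seed.
#' @param cluster_weight_range Range for within-cluster partial
#'   correlations; default `c(0.29, 0.46)`.
#' @param cross_edges Data frame `item_i`, `item_j`, `weight` of
#'   additional partial correlations; default a fixed set giving the
#'   cognitive composite the largest node-level signed connectivity.
#' @param rho_t Within-subject across-timepoint latent correlation;
#'   default 0.5.
#' @param timepoint_scale Named multiplier on off-diagonal edge weights
#'   per timepoint; default 1 at all four timepoints (stable structure).
#' @param thresholds 16 x 4 matrix of strictly increasing latent
#'   cutpoints per item.
#' @param outcome_coefs Outcome-generating coefficients; see
#'   the package vignette for the defaults.
#' @return A `true_network_spec` list; key elements: `items`, `partial`
#'   (16 x 16 realized partial correlations), `sigma` (latent
#'   correlation), `thresholds`, `rho_t`, `timepoint_scale`,
#'   `node_partial` (implied 10-node network), `node_ei` (its expected
#'   influence), `designed_top` (node with the largest implied EI),
#'   `outcome_coefs`, `seed`.
#' @export
make_true_network <- function(seed = 1,
                              cluster_weight_range = c(0.29, 0.46),
                              cross_edges = .default_cross_edges,
                              rho_t = 0.5,
                              timepoint_scale = c(W2 = 1, M3 = 1,
                                                  M6 = 1, M12 = 1),
                              thresholds = .default_thresholds(),
                              outcome_coefs = .default_outcome_coefs()) {
  items <- rpq_items()
  p <- length(items)
  stopifnot(nrow(thresholds) == p, ncol(thresholds) == 4,
            all(apply(thresholds, 1, function(r) all(diff(r) > 0))))
  set.seed(seed)
  P <- matrix(0, p, p, dimnames = list(items, items))
  for (cl in .composites) {
    pairs <- utils::combn(cl, 2)
    for (k in seq_len(ncol(pairs))) {
      w <- runif(1, cluster_weight_range[1], cluster_weight_range[2])
      P[pairs[1, k], pairs[2, k]] <- w
      P[pairs[2, k], pairs[1, k]] <- w
    }
  }
  if (!is.null(cross_edges) && nrow(cross_edges)) {
    for (k in seq_len(nrow(cross_edges))) {
      i <- cross_edges$item_i[k]; j <- cross_edges$item_j[k]
      stopifnot(i %in% items, j %in% items)
      P[i, j] <- cross_edges$weight[k]
      P[j, i] <- cross_edges$weight[k]
    }
  }
  Sigma <- partial_to_covariance(P)

  # per-timepoint latent structure (edge scaling applied to partials)
  tps <- names(timepoint_scale)
  sigma_t <- lapply(tps, function(tp) {
    s <- timepoint_scale[[tp]]
    if (s == 1) Sigma else partial_to_covariance(P * s)
  })
  names(sigma_t) <- tps

  # implied node-level (composite) network: nodes are linear maps of the
  # latent items, so their partial correlations follow analytically
  A <- matrix(0, length(network_nodes()), p,
              dimnames = list(network_nodes(), items))
  for (g in names(.composites)) A[g, .composites[[g]]] <- 1 / 3
  for (it in setdiff(network_nodes(), names(.composites))) A[it, it] <- 1
  Sn <- A %*% Sigma %*% t(A)
  d <- sqrt(diag(Sn))
  Sn <- Sn / outer(d, d)
  node_partial <- precision_to_partial(solve(Sn))
  node_ei <- rowSums(node_partial)

  structure(list(
    items = items,
    partial = attr(Sigma, "partial"),
    precision = attr(Sigma, "precision"),
    sigma = as.matrix(Sigma)[seq_len(p), , drop = FALSE],
    sigma_t = lapply(sigma_t, function(s) as.matrix(s)),
    repaired = attr(Sigma, "repaired"),
    thresholds = thresholds,
    rho_t = rho_t,
    timepoint_scale = timepoint_scale,
    node_partial = node_partial,
    node_ei = node_ei,
    designed_top = names(which.max(node_ei)),
    outcome_coefs = outcome_coefs,
    cluster_weight_range = cluster_weight_range,
    seed = seed
  ), class = "true_network_spec")
}

#' @export
print.true_network_spec <- function(x, ...) {
  cat("Synthetic ground truth: 16 items, ",
      sum(x$partial[upper.tri(x$partial)] != 0), " latent edges\n", sep = "")
  cat("  within-cluster partial correlations in [",
      x$cluster_weight_range[1], ", ", x$cluster_weight_range[2], "]\n",
      sep = "")
  cat("  across-timepoint latent correlation rho_t =", x$rho_t, "\n")
  cat("  implied top node by expected influence:", x$designed_top, "\n")
  if (x$repaired) cat("  note: precision repaired to positive definite\n")
  invisible(x)
}

# raw 0-4 item matrix for n subjects at the given timepoints, honouring
# the across-timepoint latent correlation
.simulate_items <- function(truth, n, timepoints) {
  p <- length(truth$items)
  rho <- truth$rho_t
  U0 <- matrix(rnorm(n * p), n, p)
  out <- vector("list", length(timepoints))
  names(out) <- timepoints
  for (tp in timepoints) {
    Sig <- truth$sigma_t[[tp]] %||% truth$sigma
    At <- t(chol(Sig))
    Ut <- matrix(rnorm(n * p), n, p)
    Z <- (sqrt(rho) * U0 + sqrt(1 - rho) * Ut) %*% t(At)
    raw <- matrix(0L, n, p, dimnames = list(NULL, truth$items))
    for (j in seq_len(p)) {
      raw[, j] <- findInterval(Z[, j], truth$thresholds[j, ])
    }
    out[[tp]] <- raw
  }
  out
}

# recode a raw item matrix and average into the given groups
.items_to_composites <- function(raw, groups, passthrough = character(0)) {
  rec <- matrix(c(0, 0, 1, 2, 3)[raw + 1L], nrow(raw),
                dimnames = dimnames(raw))
  out <- matrix(NA_real_, nrow(raw), length(groups) + length(passthrough),
                dimnames = list(rownames(raw),
                                c(names(groups), passthrough)))
  for (g in names(groups)) out[, g] <- rowMeans(rec[, groups[[g]],
                                                    drop = FALSE])
  if (length(passthrough)) out[, passthrough] <- rec[, passthrough]
  out
}

#' Simulate a synthetic mTBI cohort
#'
#' Draws latent multivariate-normal item scores with the ground-truth
#' partial-correlation structure and across-timepoint correlation,
#' thresholds them to raw 0-4 RPQ items, draws covariates, and generates
#' outcomes at M6/M12 from the two-week symptom factors plus covariates
#' through the spec's outcome models: incomplete recovery is Bernoulli on
#' the logistic mean (GOSE 7 vs 8); QOLIBRI-OS and the SF-12 component
#' scores are linear with Gaussian noise.
#'
#' @param truth A [make_true_network()] spec.
#' @param n Number of subjects (>= 50).
#' @param timepoints Timepoints to simulate; default all four.
#' @param seed Integer seed; same seed gives an identical cohort.
#' @return Long-format data frame (one row per subject-timepoint): raw
#'   items, `gcs`, covariates, and outcomes (`gose`, `qolibri`,
#'   `sf12_pcs`, `sf12_mcs`; present at M6/M12, `NA` elsewhere).
#' @export
simulate_cohort <- function(truth, n, timepoints = .timepoints, seed = 1) {
  stopifnot(inherits(truth, "true_network_spec"), n >= 50)
  set.seed(seed)
  ids <- sprintf("S%05d", seq_len(n))

  covs <- data.frame(
    subject_id = ids,
    gcs = sample(c(13L, 14L, 15L), n, replace = TRUE,
                 prob = c(0.041, 0.185, 0.774)),
    age = pmin(pmax(round(rlnorm(n, log(38), 0.4)), 17), 90),
    female_sex = rbinom(n, 1, 0.34),
    education = pmin(pmax(round(rnorm(n, 14, 2.5)), 8), 24),
    prior_tbi = rbinom(n, 1, 0.20),
    psychiatric_history = rbinom(n, 1, 0.25),
    ct_positive = rbinom(n, 1, 0.347)
  )

  items <- .simulate_items(truth, n, timepoints)

  # outcomes driven by W2 factors (simulate W2 latently even if not asked)
  w2_raw <- if ("W2" %in% timepoints) items[["W2"]] else
    .simulate_items(truth, n, "W2")[["W2"]]
  fac <- .items_to_composites(w2_raw, .factor_items)
  X <- cbind(intercept = 1, fac,
             as.matrix(covs[, .covariate_names, drop = FALSE]))
  oc <- truth$outcome_coefs

  gen_outcomes <- function() {
    lp_g <- as.numeric(X[, names(oc$gose_incomplete)] %*% oc$gose_incomplete)
    incomplete <- rbinom(n, 1, plogis(lp_g))
    lin <- function(spec) {
      as.numeric(X[, names(spec$coefs)] %*% spec$coefs) +
        rnorm(n, 0, spec$sd)
    }
    data.frame(
      gose = ifelse(incomplete == 1, 7L, 8L),
      qolibri = pmin(pmax(lin(oc$qolibri), 0), 100),
      sf12_pcs = lin(oc$sf12_pcs),
      sf12_mcs = lin(oc$sf12_mcs)
    )
  }

  rows <- lapply(timepoints, function(tp) {
    df <- data.frame(subject_id = ids, timepoint = tp,
                     as.data.frame(items[[tp]]))
    df <- cbind(df, covs[, -1, drop = FALSE])
    if (tp %in% c("M6", "M12")) {
      df <- cbind(df, gen_outcomes())
    } else {
      df$gose <- NA_integer_
      df$qolibri <- NA_real_
      df$sf12_pcs <- NA_real_
      df$sf12_mcs <- NA_real_
    }
    df
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Simulate a pair of node matrices from the identical true network
#'
#' Supports type-I-error and calibration studies of the network
#' comparison test: both datasets come from the same generating network,
#' either as two independent samples or as one paired two-timepoint
#' sample with identical per-timepoint truth.
#'
#' @param truth A [make_true_network()] spec (timepoint edge scale must
#'   be 1 everywhere in paired mode for the per-timepoint truths to be
#'   identical).
#' @param n_per_group Subjects per dataset.
#' @param seed Integer seed.
#' @param paired Return one paired two-timepoint sample? Default `FALSE`
#'   (two independent samples).
#' @return List with node matrices `A` and `B` (subjects x 10 nodes,
#'   recoded composites).
#' @export
null_pair <- function(truth, n_per_group, seed = 1, paired = FALSE) {
  stopifnot(inherits(truth, "true_network_spec"))
  set.seed(seed)
  pass <- setdiff(network_nodes(), names(.composites))
  to_nodes <- function(raw, ids) {
    m <- .items_to_composites(raw, .composites, pass)
    rownames(m) <- ids
    m
  }
  ids <- sprintf("S%05d", seq_len(n_per_group))
  if (paired) {
    it <- .simulate_items(truth, n_per_group, c("W2", "M3"))
    list(A = to_nodes(it[["W2"]], ids), B = to_nodes(it[["M3"]], ids))
  } else {
    a <- .simulate_items(truth, n_per_group, "W2")[["W2"]]
    b <- .simulate_items(truth, n_per_group, "W2")[["W2"]]
    list(A = to_nodes(a, ids), B = to_nodes(b, ids))
  }
}
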