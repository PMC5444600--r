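#' Supervised maximum-likelihood ancestry estimation
#'
#' Maximizes the supervised admixture log-likelihood of a single individual's
#' dosage vector over the K-simplex, holding the reference allele frequencies
#' fixed:
#' \deqn{\ell(q) = \sum_m [g_m \log(\sum_k q_k f_{km}) +
#'       (2 - g_m) \log(\sum_k q_k (1 - f_{km}))]}
#' by expectation-maximization on the complete-data formulation (each allele
#' copy is attributed to an ancestral population). The EM update is monotone
#' in the log-likelihood and keeps iterates on the simplex, so boundary
#' solutions are approached safely; components below 1e-8 at convergence are
#' truncated to exactly 0 and the vector renormalized. Missing dosages drop
#' out of the likelihood sum.
#'
#' @param g_i integer dosage vector (0/1/2, `NA` allowed) over the panel's
#'   variants.
#' @param panel a [reference_panel()].
#' @param tol convergence threshold on the log-likelihood gain between
#'   successive iterations (default 1e-7).
#' @param max_iter maximum EM iterations (default 2000); non-convergence is
#'   flagged and the best iterate returned.
#' @return An `ancestry_estimate`: list with `q` (named simplex vector),
#'   `loglik`, `converged`, `iterations`.
#' @export
estimate_ancestry <- function(g_i, panel, tol = 1e-7, max_iter = 2000) {
  stopifnot(inherits(panel, "reference_panel"))
  F <- panel$freqs
  if (length(g_i) != ncol(F)) stop("dosage vector does not match panel variants", call. = FALSE)
  obs <- !is.na(g_i)
  if (!any(obs)) stop("no called genotypes", call. = FALSE)
  F <- F[, obs, drop = FALSE]
  g <- g_i[obs]
  K <- nrow(F); M <- ncol(F)

  flat <- all(apply(F, 2, function(col) max(col) - min(col) == 0))
  if (flat) {
    warning("all populations share identical frequencies; likelihood is flat, returning uniform proportions")
    q <- rep(1 / K, K); names(q) <- panel$populations
    pm <- colSums(q * F)
    ll <- sum(g * log(pm) + (2 - g) * log1p(-pm))
    return(structure(list(q = q, loglik = ll, converged = TRUE, iterations = 0L),
                     class = "ancestry_estimate"))
  }

  q <- rep(1 / K, K)
  ll_old <- -Inf
  converged <- FALSE
  iter <- 0L
  Fc <- 1 - F
  while (iter < max_iter) {
    iter <- iter + 1L
    qF <- q * F          # K x M (column recycling over K)
    qFc <- q * Fc
    pm <- .colSums(qF, K, M)
    pmc <- .colSums(qFc, K, M)
    if (any(pm <= 0) || any(pmc <= 0)) {
      stop("non-finite likelihood: a model frequency reached 0 or 1", call. = FALSE)
    }
    ll <- sum(g * log(pm) + (2 - g) * log(pmc))
    if (is.finite(ll_old) && ll - ll_old < tol) {
      converged <- TRUE
      break
    }
    ll_old <- ll
    # E-step attribution of allele copies, M-step renormalization
    counts <- as.numeric(qF %*% (g / pm)) + as.numeric(qFc %*% ((2 - g) / pmc))
    q <- counts / (2 * M)
  }
  q[q < 1e-8] <- 0
  q <- q / sum(q)
  names(q) <- panel$populations
  pm <- as.numeric(q %*% F)
  ll <- sum(g * log(pm) + (2 - g) * log1p(-pm))
  if (!converged) warning("EM did not converge within max_iter; returning best iterate")
  structure(list(q = q, loglik = ll, converged = converged, iterations = iter),
            class = "ancestry_estimate")
}

#' @exportS3Method print ancestry_estimate
print.ancestry_estimate <- function(x, ...) {
  cat("<ancestry_estimate>",
      paste(sprintf("%s=%.3f", names(x$q), x$q), collapse = " "),
      sprintf("(loglik %.2f, %d iter%s)\n", x$loglik, x$iterations,
              if (x$converged) "" else ", NOT converged"))
  invisible(x)
}

#' Supervised ancestry estimation for a whole cohort
#'
#' Runs supervised maximum-likelihood estimation for every sample of a
#' genotype matrix against a fixed reference panel, vectorized across
#' individuals. The EM iteration is accelerated with the SQUAREM scheme
#' (two EM steps extrapolated with a per-individual steplength, safeguarded
#' by a log-likelihood monotonicity fallback to the plain double EM step),
#' which converges orders of magnitude faster along the flat likelihood
#' ridge between closely related reference populations. Individuals that
#' reach the convergence threshold drop out of subsequent cycles.
#'
#' @param g a [genotype_matrix()] over the panel's variants.
#' @param panel a [reference_panel()].
#' @param tol convergence threshold on the log-likelihood gain per
#'   acceleration cycle (default 1e-7).
#' @param max_iter maximum acceleration cycles (each cycle applies three EM
#'   updates; default 2000).
#' @return Data frame with `sample_id`, one column per ancestry component,
#'   `loglik`, `converged`, `iterations` (cycles used).
#' @export
estimate_ancestry_matrix <- function(g, panel, tol = 1e-7, max_iter = 2000) {
  stopifnot(inherits(g, "genotype_matrix"), inherits(panel, "reference_panel"))
  Fm <- panel$freqs
  if (ncol(g$dosage) != ncol(Fm)) stop("cohort and panel variant sets differ", call. = FALSE)
  G <- g$dosage
  n <- nrow(G); K <- nrow(Fm)
  miss <- is.na(G)
  G0 <- G; G0[miss] <- 0                # missing loci contribute 0 to both terms
  G2 <- 2 - G; G2[miss] <- 0
  m_obs <- rowSums(!miss)
  tF <- t(Fm); tFc <- 1 - tF            # M x K

  em_step <- function(Q, idx) {
    P <- Q %*% t(tF)
    counts <- (G0[idx, , drop = FALSE] / P) %*% tF * Q +
      (G2[idx, , drop = FALSE] / (1 - P)) %*% tFc * Q
    counts / (2 * m_obs[idx])
  }
  loglik_rows <- function(Q, idx) {
    P <- Q %*% t(tF)
    rowSums(G0[idx, , drop = FALSE] * log(P) +
              G2[idx, , drop = FALSE] * log1p(-P))
  }
  project <- function(Q) {
    Q[Q < 1e-12] <- 1e-12
    Q / rowSums(Q)
  }

  Q <- matrix(1 / K, n, K)
  ll_old <- rep(-Inf, n)
  iters <- integer(n)
  active <- rep(TRUE, n)
  it <- 0L
  while (any(active) && it < max_iter) {
    it <- it + 1L
    idx <- which(active)
    Q0 <- Q[idx, , drop = FALSE]
    Q1 <- em_step(Q0, idx)
    Q2 <- em_step(Q1, idx)
    R <- Q1 - Q0
    V <- Q2 - Q1 - R
    a <- -sqrt(rowSums(R^2)) / pmax(sqrt(rowSums(V^2)), 1e-300)
    a <- pmin(a, -1)                   # SQUAREM SqS3 steplength, capped at -1
    Qs <- project(Q0 - 2 * a * R + a^2 * V)
    Qs <- project(em_step(Qs, idx))    # stabilization EM step
    ll_acc <- loglik_rows(Qs, idx)
    ll_em <- loglik_rows(Q2, idx)
    worse <- !is.finite(ll_acc) | ll_acc < ll_em
    if (any(worse)) {
      Qs[worse, ] <- Q2[worse, , drop = FALSE]
      ll_acc[worse] <- ll_em[worse]
    }
    done <- is.finite(ll_old[idx]) & (ll_acc - ll_old[idx] < tol)
    Q[idx, ] <- Qs
    iters[idx] <- it
    ll_old[idx] <- ll_acc
    active[idx[done]] <- FALSE
  }
  converged <- !active
  Q[Q < 1e-8] <- 0
  Q <- Q / rowSums(Q)
  P <- Q %*% t(tF)
  ll <- rowSums(G0 * log(P) + G2 * log(1 - P))
  out <- data.frame(sample_id = g$samples, stringsAsFactors = FALSE)
  for (k in seq_len(K)) out[[panel$populations[k]]] <- Q[, k]
  out$loglik <- ll
  out$converged <- converged
  out$iterations <- iters
  if (any(!converged)) {
    warning(sprintf("%d individual(s) did not converge within max_iter", sum(!converged)))
  }
  out
}

#' Exhaustive simplex-grid oracle for the supervised likelihood
#'
#' Evaluates the supervised admixture log-likelihood on the full lattice
#' `{q : q_k = j * resolution, sum(q) = 1}` and returns the lattice argmax.
#' Intended as an independent check on the optimizer, not for production use;
#' refuses K > 4 at fine resolutions to keep the lattice manageable.
#'
#' @param g_i dosage vector (0/1/2, `NA` allowed).
#' @param panel a [reference_panel()].
#' @param resolution lattice spacing (default 0.01; must divide 1).
#' @return List with `q` (lattice argmax), `loglik`, `n_evaluated`.
#' @export
grid_oracle <- function(g_i, panel, resolution = 0.01) {
  stopifnot(inherits(panel, "reference_panel"))
  K <- nrow(panel$freqs)
  steps <- round(1 / resolution)
  if (abs(steps * resolution - 1) > 1e-9) stop("resolution must divide 1", call. = FALSE)
  if (K > 4 && steps > 20) stop("lattice too large for K > 4 at this resolution", call. = FALSE)
  lattice <- simplex_lattice(K, steps)
  Q <- lattice / steps
  obs <- !is.na(g_i)
  F <- panel$freqs[, obs, drop = FALSE]
  g <- g_i[obs]
  P <- Q %*% F
  ll <- as.numeric(P_loglik(P, g))
  best <- which.max(ll)
  q <- Q[best, ]; names(q) <- panel$populations
  list(q = q, loglik = ll[best], n_evaluated = nrow(Q))
}

P_loglik <- function(P, g) {
  # rows of P are model frequencies; boundary lattice points can hit 0/1 when
  # panel frequencies are extreme, guard with a tiny clamp
  P <- pmin(pmax(P, 1e-12), 1 - 1e-12)
  log(P) %*% g + log(1 - P) %*% (2 - g)
}

# all K-part compositions of `steps` (rows sum to steps)
simplex_lattice <- function(K, steps) {
  if (K == 1) return(matrix(steps, 1, 1))
  parts <- lapply(0:steps, function(j) {
    cbind(j, simplex_lattice(K - 1, steps - j))
  })
  do.call(rbind, parts)
}
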