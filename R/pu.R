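# Positive-unlabeled ensemble for one view at one iteration.
#
# The "non-traditional" classifier g(x) is trained to separate labeled from
# unlabeled interactions; under the selected-completely-at-random assumption
# P(labeled | x) = c * P(positive | x) with c = P(labeled | positive), so the
# positive-class posterior is recovered as f(x) = g(x) / c (Elkan-Noto).
# Class imbalance is handled by bagging: each ensemble member sees all
# labeled examples plus a with-replacement sample of n unlabeled ones; samples
# are drawn until a fraction gamma of the unlabeled set is covered.

#' Draw unlabeled bagging samples until gamma-coverage
#'
#' Samples of size \code{n} are drawn with replacement from the unlabeled
#' index set until the union of drawn indices covers at least
#' \code{gamma * |U|} distinct elements, or \code{max_W} samples have been
#' drawn (warning). The number of samples W is therefore determined by the
#' coverage target, not fixed in advance.
#'
#' @param unlabeled integer vector of unlabeled row indices.
#' @param n sample size per member.
#' @param gamma coverage target in (0, 1).
#' @param seed RNG seed; the sample sequence is deterministic given it.
#' @param max_W guard on the number of samples (default 500).
#' @return A list of W integer vectors (multisets of row indices).
#' @export
sample_unlabeled <- function(unlabeled, n, gamma, seed, max_W = 500L) {
  stopifnot(n >= 1, gamma > 0, gamma < 1)
  if (length(unlabeled) == 0L) stop("unlabeled set is empty")
  if (n > 10 * length(unlabeled))
    warning("sample size n exceeds 10x the unlabeled set: degenerate oversampling")
  set.seed(seed)
  needed <- gamma * length(unlabeled)
  covered <- logical(length(unlabeled))
  samples <- vector("list", 0L)
  repeat {
    s <- sample(unlabeled, n, replace = TRUE)
    samples[[length(samples) + 1L]] <- s
    covered[match(s, unlabeled)] <- TRUE
    if (sum(covered) >= needed) break
    if (length(samples) >= max_W) {
      warning(sprintf(
        "max_W = %d reached at coverage %.3f < gamma = %.3f", max_W,
        sum(covered) / length(unlabeled), gamma))
      break
    }
  }
  samples
}

# Expected number of samples to reach gamma-coverage when drawing n elements
# with replacement from a set of size u (used as a test oracle, not by the
# sampler itself).
expected_W <- function(u, n, gamma) {
  ceiling(log(1 - gamma) / (n * log(1 - 1 / u)))
}

# Platt sigmoid calibration: fit P(y=1|d) = plogis(A*d + B) by maximum
# likelihood with Platt's regularized targets, so separable decision values
# do not push A to infinity.
platt_fit <- function(dv, y) {
  np <- sum(y == 1); nn <- sum(y == 0)
  t_pos <- (np + 1) / (np + 2)
  t_neg <- 1 / (nn + 2)
  tt <- ifelse(y == 1, t_pos, t_neg)
  nll <- function(par) {
    p <- stats::plogis(par[1] * dv + par[2])
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    -sum(tt * log(p) + (1 - tt) * log(1 - p))
  }
  fit <- stats::optim(c(1, 0), nll, method = "BFGS")
  fit$par
}

seeded_folds <- function(y, k, seed) {
  # stratified folds so every fold holds both classes
  set.seed(seed)
  fold <- integer(length(y))
  for (cls in unique(y)) {
    idx <- which(y == cls)
    fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  fold
}

#' Fit one ensemble member
#'
#' Trains a probabilistic binary classifier with the labeled interactions as
#' class 1 and the unlabeled bagging sample as class 0. Indices present in
#' both sets are used once, as labeled. The reference classifier is a linear
#' SVM whose decision values are mapped to probabilities by a Platt sigmoid
#' fitted on seeded 3-fold out-of-fold decision values; \code{"logistic"}
#' plugs in plain logistic regression instead.
#'
#' @param view_scores numeric matrix of the view's feature columns (all rows).
#' @param labeled integer indices of labeled (positive) rows.
#' @param unlabeled_sample integer multiset of unlabeled rows.
#' @param seed RNG seed for the internal calibration split.
#' @param classifier \code{"linear_svm_platt"} (default) or \code{"logistic"}.
#' @return A \code{pu_member} object usable with \code{predict_member}.
#' @export
fit_member <- function(view_scores, labeled, unlabeled_sample, seed,
                       classifier = c("linear_svm_platt", "logistic")) {
  classifier <- match.arg(classifier)
  labeled <- unique(as.integer(labeled))
  if (length(labeled) == 0L) stop("labeled set is empty")
  neg <- unlabeled_sample[!(unlabeled_sample %in% labeled)]
  if (length(neg) == 0L) stop("no unlabeled examples left after overlap removal")
  rows <- c(labeled, neg)
  X <- view_scores[rows, , drop = FALSE]
  y <- c(rep(1L, length(labeled)), rep(0L, length(neg)))
  member <- switch(classifier,
    linear_svm_platt = fit_svm_platt(X, y, seed),
    logistic = fit_logistic(X, y))
  member$trained_on <- list(labeled = labeled, sample = unlabeled_sample)
  member
}

fit_svm_platt <- function(X, y, seed) {
  fold <- seeded_folds(y, 3L, seed)
  dv_oof <- numeric(length(y))
  for (k in 1:3) {
    tr <- fold != k
    if (length(unique(y[tr])) < 2) { dv_oof[!tr] <- 0; next }
    m <- e1071::svm(X[tr, , drop = FALSE], factor(y[tr], levels = c(0, 1)),
                    kernel = "linear", scale = FALSE)
    w <- crossprod(m$coefs, m$SV)
    dv_oof[!tr] <- drop(X[!tr, , drop = FALSE] %*% t(w)) - m$rho
  }
  cal <- platt_fit(dv_oof, y)
  m <- e1071::svm(X, factor(y, levels = c(0, 1)), kernel = "linear",
                  scale = FALSE)
  w <- crossprod(m$coefs, m$SV)
  # orient the final decision values like the out-of-fold ones the sigmoid
  # was fitted on (e1071's sign depends on which class comes first)
  dv_tr <- drop(X %*% t(w)) - m$rho
  co <- suppressWarnings(stats::cor(dv_tr, dv_oof))
  if (!is.na(co) && co < 0) { w <- -w; m$rho <- -m$rho }
  structure(list(kind = "linear_svm_platt", w = drop(w), rho = m$rho,
                 calibration = cal), class = "pu_member")
}

fit_logistic <- function(X, y) {
  fit <- suppressWarnings(
    stats::glm.fit(cbind(1, X), y, family = stats::binomial()))
  structure(list(kind = "logistic", beta = fit$coefficients),
            class = "pu_member")
}

#' Predict labeled-class probabilities from one member
#'
#' @param member a \code{pu_member} from \code{\link{fit_member}}.
#' @param view_scores the view's feature matrix.
#' @param rows row indices to predict for (default all).
#' @return Probabilities in (0, 1).
#' @export
predict_member <- function(member, view_scores, rows = seq_len(nrow(view_scores))) {
  X <- view_scores[rows, , drop = FALSE]
  p <- switch(member$kind,
    linear_svm_platt = {
      dv <- drop(X %*% member$w) - member$rho
      stats::plogis(member$calibration[1] * dv + member$calibration[2])
    },
    logistic = {
      beta <- member$beta
      beta[is.na(beta)] <- 0
      stats::plogis(drop(cbind(1, X) %*% beta))
    })
  pmin(pmax(p, 1e-12), 1 - 1e-12)
}

#' Ensemble estimate g(x) of the labeled-class probability
#'
#' For an unlabeled interaction covered by at least one bagging sample, g is
#' the unweighted mean of the member outputs over the members whose sample
#' contains it. Labeled interactions and interactions covered by no sample
#' are scored by the mean over all W members (the averaging rule's natural
#' extension, coinciding with it under total coverage).
#'
#' @param ensemble a \code{view_ensemble} from \code{\link{fit_view_ensemble}}.
#' @param view_scores the view's feature matrix.
#' @param x_index row index (scalar or vector).
#' @return g values in (0, 1).
#' @export
ensemble_g <- function(ensemble, view_scores, x_index) {
  ensemble$g[x_index]
}

compute_ensemble_g <- function(members, samples, view_scores, labeled) {
  n <- nrow(view_scores)
  W <- length(members)
  cov_sum <- numeric(n)
  cov_cnt <- integer(n)
  covered_rows <- unique(unlist(lapply(samples, unique)))
  fallback <- sort(unique(c(labeled, setdiff(seq_len(n), covered_rows))))
  fb_sum <- numeric(length(fallback))
  for (j in seq_len(W)) {
    rows_j <- unique(samples[[j]])
    pj <- predict_member(members[[j]], view_scores, rows_j)
    cov_sum[rows_j] <- cov_sum[rows_j] + pj
    cov_cnt[rows_j] <- cov_cnt[rows_j] + 1L
    fb_sum <- fb_sum + predict_member(members[[j]], view_scores, fallback)
  }
  g <- numeric(n)
  has_cov <- cov_cnt > 0L
  g[has_cov] <- cov_sum[has_cov] / cov_cnt[has_cov]
  g[fallback] <- fb_sum / W # labeled + uncovered rows: all-member average
  g
}

#' Estimate the label frequency c
#'
#' The Elkan-Noto label frequency c = P(labeled | positive) is estimated as
#' the mean of g over the labeled interactions, clamped below at 1e-6 to
#' protect the subsequent division (a clamp is logged).
#'
#' @inheritParams ensemble_g
#' @param labeled integer indices of labeled rows.
#' @return A scalar c in (0, 1].
#' @export
estimate_label_frequency <- function(ensemble, view_scores, labeled) {
  if (length(labeled) == 0L) stop("labeled set is empty")
  cc <- mean(ensemble_g(ensemble, view_scores, labeled))
  if (cc < 1e-6) {
    warning("label-frequency estimate clamped at 1e-6")
    cc <- 1e-6
  }
  cc
}

#' Elkan-Noto correction of g into the positive-class posterior
#'
#' @param g_value labeled-class probability estimate(s) in [0, 1].
#' @param c label frequency in (0, 1].
#' @return min(g / c, 1): the corrected posterior, capped at 1 since the
#'   plug-in ratio can exceed it.
#' @export
pu_correct <- function(g_value, c) {
  if (c <= 0) stop("label frequency c must be positive")
  pmin(g_value / c, 1)
}

#' Fit the full PU ensemble for one view
#'
#' Orchestrates one view's learning at one iteration: draws gamma-coverage
#' bagging samples of the unlabeled set, fits one calibrated member per
#' sample, averages the members into g, estimates the label frequency c over
#' the labeled interactions, and returns the corrected posterior
#' f(x) = min(g(x)/c, 1) for every candidate interaction.
#'
#' @param view_table an \code{\link{interaction_table}} (or plain numeric
#'   matrix) holding the view's feature columns.
#' @param labeled integer indices of labeled (positive) rows.
#' @param n unlabeled sample size per member; \code{NULL} uses
#'   \code{n_mode}.
#' @param n_mode \code{"balance"} (n = |labeled|, the default) or
#'   \code{"double"} (n = 2|labeled|), used when \code{n} is \code{NULL}.
#' @param gamma coverage target (default 0.99).
#' @param seed RNG seed.
#' @param max_W sample-count guard (default 500).
#' @param classifier see \code{\link{fit_member}}.
#' @return A \code{view_ensemble}: list with \code{members}, \code{samples},
#'   \code{W}, \code{label_frequency}, \code{g}, and the per-row corrected
#'   posterior \code{f}.
#' @export
fit_view_ensemble <- function(view_table, labeled, n = NULL,
                              n_mode = c("balance", "double"),
                              gamma = 0.99, seed = 1L, max_W = 500L,
                              classifier = c("linear_svm_platt", "logistic")) {
  n_mode <- match.arg(n_mode)
  classifier <- match.arg(classifier)
  X <- if (inherits(view_table, "interaction_table")) view_table$scores else
    as.matrix(view_table)
  labeled <- sort(unique(as.integer(labeled)))
  if (length(labeled) == 0L) stop("labeled set is empty")
  unlabeled <- setdiff(seq_len(nrow(X)), labeled)
  if (length(unlabeled) == 0L) stop("no unlabeled interactions")
  if (is.null(n))
    n <- if (n_mode == "balance") length(labeled) else 2L * length(labeled)
  samples <- sample_unlabeled(unlabeled, n, gamma, seed, max_W)
  members <- lapply(seq_along(samples), function(j)
    fit_member(X, labeled, samples[[j]], seed = seed + j, classifier = classifier))
  g <- compute_ensemble_g(members, samples, X, labeled)
  ens <- structure(list(members = members, samples = samples,
                        W = length(samples), n = n, gamma = gamma,
                        g = g, labeled = labeled),
                   class = "view_ensemble")
  cc <- estimate_label_frequency(ens, X, labeled)
  ens$label_frequency <- cc
  # uncapped Elkan-Noto ratio: used for ranking (cross-view combination and
  # label updates), where capping would collapse the top of the ranking into
  # ties; f is the capped probability emitted to users
  ens$ratio <- g / cc
  ens$f <- pu_correct(g, cc)
  ens
}

#' @export
print.view_ensemble <- function(x, ...) {
  cat(sprintf("view_ensemble: W = %d members, n = %d, gamma = %.2f, c = %.4f\n",
              x$W, x$n, x$gamma, x$label_frequency))
  invisible(x)
}
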