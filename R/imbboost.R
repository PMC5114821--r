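# The imbalance-aware modified AdaBoost ensemble.
#
# Deviations from classical AdaBoost, both aimed at the extreme
# binding/non-binding imbalance:
#   * per-round random sampling touches only the negative class; every
#     positive sample is used in every round;
#   * misclassified negatives have their weights increased "on a small
#     scale": the exponent of the classical update exp(alpha_t) is damped by
#     a factor beta in (0, 1]; beta = 1 recovers the classical update.
# The round error eps_t is, by default, measured on the full training set:
# positives with equal fixed weights, negatives with their current adaptive
# weights, the two classes jointly renormalized to carry half the mass each.

#' Configuration for the boosted ensemble
#'
#' @param rounds Number of boosting rounds `T`.
#' @param ratio Negatives drawn per round, as a multiple of the number of
#'   positives (`ceiling(ratio * n_pos)`, capped at the pool size when
#'   sampling without replacement).
#' @param beta Damping in (0, 1\] of the weight increase for misclassified
#'   negatives; 1 is the classical AdaBoost exponent.
#' @param gamma RBF kernel width of the base classifier (`NULL` = 1 /
#'   (dim * mean feature variance)).
#' @param cost Regularization parameter C of the base classifier.
#' @param threshold Probability cutoff for the binary call.
#' @param error_on `"full"`: round error on all samples (default);
#'   `"round"`: on the positives plus the round's negative sample only.
#' @param replace Sample negatives with replacement (required if
#'   `ratio * n_pos` exceeds the pool).
#' @param max_centers Center cap of the kernel base learner.
#' @param seed RNG seed for sampling (and center selection).
#' @return A list of class `"imbboost_config"`.
#' @export
imbboost_config <- function(rounds = 15L, ratio = 1, beta = 0.5,
                            gamma = NULL, cost = 1, threshold = 0.5,
                            error_on = c("full", "round"), replace = FALSE,
                            max_centers = 512L, seed = NULL) {
  if (rounds < 1L) stop_ligbind("rounds must be >= 1")
  if (ratio <= 0) stop_ligbind("ratio must be positive")
  if (beta <= 0 || beta > 1) stop_ligbind("beta must lie in (0, 1]")
  if (threshold <= 0 || threshold >= 1) stop_ligbind("threshold must lie in (0, 1)")
  structure(list(rounds = as.integer(rounds), ratio = ratio, beta = beta,
                 gamma = gamma, cost = cost, threshold = threshold,
                 error_on = match.arg(error_on), replace = replace,
                 max_centers = as.integer(max_centers), seed = seed),
            class = "imbboost_config")
}

#' Fit the imbalance-aware boosted ensemble
#'
#' Trains `rounds` RBF-kernel base classifiers.  Each round draws a weighted
#' sample (without replacement by default) from the negative pool only, of
#' size `ceiling(ratio * n_pos)`, and fits a base classifier on that sample
#' plus all positives.  The round's weighted error determines its vote weight
#' `alpha_t = 0.5 * log((1 - eps_t) / eps_t)`; misclassified negatives are
#' up-weighted by `exp(beta * alpha_t)` and the negative weights renormalized.
#' A round with `eps_t >= 0.5` is discarded; its sampling is retried once,
#' after which training stops early.  `eps_t = 0` is clamped to `1e-6`.
#' Fully deterministic given `seed`.
#'
#' @param x Numeric feature matrix (rows = samples).
#' @param y Binary labels: 1 = binding (positive), 0 = non-binding.
#' @param config An [imbboost_config()].
#' @param ... Convenience overrides of single `config` fields (e.g.
#'   `rounds = 5`, `seed = 7`).
#' @return An object of class `"imbboost"` with the retained base models,
#'   their vote weights `alphas`, per-round errors `epsilons`, the final
#'   negative-pool weights, and the configuration.
#' @seealso [predict.imbboost()], [save_imbboost()]
#' @export
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40, 2), 20), matrix(rnorm(200), 100))
#' y <- rep(c(1, 0), c(20, 100))
#' fit <- imbboost(x, y, rounds = 3, seed = 1)
#' fit
imbboost <- function(x, y, config = imbboost_config(), ...) {
  dots <- list(...)
  if (length(dots)) {
    bad <- setdiff(names(dots), names(unclass(config)))
    if (length(bad)) stop_ligbind("unknown config field(s): %s",
                                  paste(bad, collapse = ", "))
    config[names(dots)] <- dots
    config <- do.call(imbboost_config, unclass(config))
  }
  x <- as.matrix(x)
  if (!is.numeric(x) || anyNA(x)) stop_ligbind("x must be a numeric matrix without NAs")
  y <- as.integer(y)
  if (length(y) != nrow(x)) stop_ligbind("x and y lengths differ")
  if (!all(y %in% c(0L, 1L))) stop_ligbind("labels must be 0/1")
  pos <- which(y == 1L)
  neg <- which(y == 0L)
  if (!length(pos) || !length(neg)) {
    stop_ligbind("training data must contain both classes")
  }
  gamma <- if (is.null(config$gamma)) default_gamma(x) else config$gamma
  n_draw <- ceiling(config$ratio * length(pos))
  if (!config$replace) {
    n_draw <- min(n_draw, length(neg))
  }
  with_seed(config$seed, {
    w <- rep(1 / length(neg), length(neg))
    models <- list()
    alphas <- epsilons <- numeric(0)
    t <- 1L
    stopped_early <- FALSE
    while (t <= config$rounds) {
      retried <- FALSE
      repeat {
        take <- sample(seq_along(neg), n_draw, replace = config$replace,
                       prob = w)
        idx <- c(pos, neg[take])
        base <- klr_fit(x[idx, , drop = FALSE], y[idx], gamma = gamma,
                        cost = config$cost, max_centers = config$max_centers)
        if (config$error_on == "full") {
          p_pos <- klr_prob(base, x[pos, , drop = FALSE])
          p_neg <- klr_prob(base, x[neg, , drop = FALSE])
          mis_pos <- p_pos < 0.5
          mis_neg <- p_neg >= 0.5
          eps <- 0.5 * mean(mis_pos) + 0.5 * sum(w * mis_neg)
        } else {
          p_idx <- klr_prob(base, x[idx, , drop = FALSE])
          mis <- (p_idx >= 0.5) != (y[idx] == 1L)
          ws <- w[take] / sum(w[take])
          eps <- 0.5 * mean(mis[seq_along(pos)]) +
                 0.5 * sum(ws * mis[-seq_along(pos)])
          p_neg <- klr_prob(base, x[neg, , drop = FALSE])
          mis_neg <- p_neg >= 0.5
        }
        if (eps < 0.5) break
        if (retried) { stopped_early <- TRUE; break }
        retried <- TRUE
      }
      if (stopped_early) break
      eps_c <- max(eps, 1e-6)
      alpha <- 0.5 * log((1 - eps_c) / eps_c)
      models[[length(models) + 1L]] <- base
      alphas <- c(alphas, alpha)
      epsilons <- c(epsilons, eps_c)
      w[mis_neg] <- w[mis_neg] * exp(config$beta * alpha)
      w <- w / sum(w)
      t <- t + 1L
    }
    if (!length(models)) {
      stop_ligbind("training failed: every round was discarded (eps >= 0.5)",
                   class = "ligbind_training_error")
    }
    structure(list(base_models = models, alphas = alphas,
                   epsilons = epsilons, neg_weights = w,
                   gamma = gamma, dim = ncol(x),
                   n_pos = length(pos), n_neg = length(neg),
                   config = config, call = match.call()),
              class = "imbboost")
  })
}

#' Predict binding probabilities from a fitted ensemble
#'
#' The ensemble probability is the vote-weighted mean of the base classifier
#' probabilities, `sum_t alpha_t p_t(x) / sum_t alpha_t`, guaranteed to lie
#' between the smallest and largest base probability.
#'
#' @param object A fitted [imbboost()] model.
#' @param newdata Numeric feature matrix (or single vector).
#' @param type `"prob"` for probabilities, `"class"` for thresholded 0/1
#'   calls.
#' @param ... Unused.
#' @return Numeric vector of probabilities in \[0, 1\] or integer 0/1 calls.
#' @export
predict.imbboost <- function(object, newdata,
                             type = c("prob", "class"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  newdata <- as.matrix(newdata)
  if (ncol(newdata) != object$dim) {
    stop_ligbind("feature dimension %d does not match training dimension %d",
                 ncol(newdata), object$dim)
  }
  probs <- vapply(object$base_models, klr_prob, numeric(nrow(newdata)),
                  x = newdata)
  probs <- matrix(probs, nrow = nrow(newdata))
  p <- drop(probs %*% object$alphas) / sum(object$alphas)
  p <- pmin(pmax(p, 0), 1)
  if (type == "prob") p else as.integer(p >= object$config$threshold)
}

#' @export
print.imbboost <- function(x, ...) {
  cat(sprintf("imbalance-aware boosted RBF ensemble: %d/%d rounds retained\n",
              length(x$alphas), x$config$rounds))
  cat(sprintf("  training set: %d positives, %d negatives (ratio %.1f)\n",
              x$n_pos, x$n_neg, x$n_neg / x$n_pos))
  cat(sprintf("  beta = %.2f, per-round negatives = %d, kernel gamma = %.4g\n",
              x$config$beta, ceiling(x$config$ratio * x$n_pos), x$gamma))
  invisible(x)
}

#' @export
#' @method summary imbboost
summary.imbboost <- function(object, ...) {
  out <- data.frame(round = seq_along(object$alphas),
                    epsilon = object$epsilons, alpha = object$alphas)
  structure(list(rounds = out, config = object$config,
                 n_pos = object$n_pos, n_neg = object$n_neg),
            class = "summary.imbboost")
}

#' @export
print.summary.imbboost <- function(x, ...) {
  cat("per-round weighted error and vote weight:\n")
  print(x$rounds, row.names = FALSE)
  invisible(x)
}

#' @export
#' @method coef imbboost
coef.imbboost <- function(object, ...) object$alphas

#' @export
#' @method plot imbboost
plot.imbboost <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$epsilons, type = "b", xlab = "round",
                 ylab = expression(epsilon[t]), ylim = c(0, 0.5), ...)
  graphics::plot(x$alphas, type = "b", xlab = "round",
                 ylab = expression(alpha[t]), ...)
  invisible(x)
}

#' Serialize / restore a fitted ensemble
#'
#' Models are written as a self-describing JSON archive (format version,
#' configuration, per-round vote weights and errors, base-model payloads) at
#' full floating-point precision, so a round-tripped model reproduces its
#' predictions bit for bit.
#'
#' @param model A fitted [imbboost()] object.
#' @param path File path.
#' @return `path` invisibly (save); the restored `"imbboost"` object (load).
#' @export
save_imbboost <- function(model, path) {
  stopifnot(inherits(model, "imbboost"))
  payload <- list(
    format = "ligbind-imbboost", version = "1",
    config = unclass(model$config),
    gamma = model$gamma, dim = model$dim,
    n_pos = model$n_pos, n_neg = model$n_neg,
    alphas = model$alphas, epsilons = model$epsilons,
    neg_weights = model$neg_weights,
    base_models = lapply(model$base_models, function(b) {
      list(b = b$b, gamma = b$gamma, cost = b$cost, alpha = b$alpha,
           centers = b$centers)
    }))
  # I(17) significant digits: exact decimal round-trip for IEEE doubles
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17),
                       null = "null")
  invisible(path)
}

#' @rdname save_imbboost
#' @export
load_imbboost <- function(path) {
  if (!file.exists(path)) stop_ligbind("model file not found: %s", path)
  payload <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                      error = function(e) stop_ligbind(
                        "corrupt model file '%s': %s", path,
                        conditionMessage(e), class = "ligbind_format_error"))
  if (!identical(payload$format, "ligbind-imbboost")) {
    stop_ligbind("'%s' is not an ensemble model archive (field 'format')",
                 path, class = "ligbind_format_error")
  }
  if (!identical(payload$version, "1")) {
    stop_ligbind("model archive version '%s' is not supported (field 'version')",
                 as.character(payload$version), class = "ligbind_format_error")
  }
  need <- c("config", "gamma", "dim", "alphas", "epsilons", "base_models")
  miss <- setdiff(need, names(payload))
  if (length(miss)) {
    stop_ligbind("model archive '%s' lacks field '%s'", path, miss[1],
                 class = "ligbind_format_error")
  }
  cfgl <- payload$config
  cfgl$gamma <- if (is.null(cfgl$gamma)) NULL else cfgl$gamma
  cfg <- do.call(imbboost_config, cfgl[!vapply(cfgl, is.null, logical(1))])
  bm <- payload$base_models
  get_base <- function(i) {
    rec <- if (is.data.frame(bm)) {
      list(b = bm$b[i], gamma = bm$gamma[i], cost = bm$cost[i],
           alpha = bm$alpha[[i]], centers = bm$centers[[i]])
    } else bm[[i]]
    ctr <- rec$centers
    if (!is.matrix(ctr)) ctr <- matrix(unlist(ctr), nrow = length(rec$alpha),
                                       byrow = TRUE)
    structure(list(centers = ctr, gamma = rec$gamma, cost = rec$cost,
                   b = rec$b, alpha = as.numeric(unlist(rec$alpha))),
              class = "ligbind_klr")
  }
  n_base <- if (is.data.frame(bm)) nrow(bm) else length(bm)
  base_models <- lapply(seq_len(n_base), get_base)
  structure(list(base_models = base_models, alphas = payload$alphas,
                 epsilons = payload$epsilons,
                 neg_weights = payload$neg_weights,
                 gamma = payload$gamma, dim = payload$dim,
                 n_pos = payload$n_pos, n_neg = payload$n_neg,
                 config = cfg, call = NULL),
            class = "imbboost")
}
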