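## Adaptive generalized polynomial chaos (gPCE) metamodel with Legendre
## basis (uniform inputs) and Sobol decomposition of the output variance.
## Basis polynomials are ORTHONORMAL on [-1,1]^d with the uniform measure,
## so Sobol indices reduce to sums of squared coefficients.

#' gPCE configuration
#'
#' @param input_dimension number of inputs (4 cluster moduli).
#' @param input_low,input_high per-dimension bounds (scalars or vectors),
#'   affinely mapped to `[-1, 1]`; defaults 1 and 149 kPa.
#' @param max_total_order maximal total polynomial degree of candidate
#'   terms (default 6).
#' @param loo_target stop when the relative leave-one-out error reaches
#'   this (default 0.001; dimensionless: LOO residual sum of squares over
#'   the output variance).
#' @param max_basis_terms cap on the basis size.
#' @param max_interaction_order candidate terms may involve at most this
#'   many dimensions at once (default 2); higher orders are admitted only
#'   if the pool is exhausted without reaching the target.
#' @return object of class `gpce_config`.
#' @export
gpce_config <- function(input_dimension = 4,
                        input_low = 1, input_high = 149,
                        max_total_order = 6,
                        loo_target = 0.001,
                        max_basis_terms = 60,
                        max_interaction_order = 2) {
  if (loo_target <= 0) stop_param("loo_target must be > 0")
  if (max_total_order < 1) stop_param("max_total_order must be >= 1")
  d <- as.integer(input_dimension)
  structure(list(input_dimension = d,
                 input_low = rep(input_low, length.out = d),
                 input_high = rep(input_high, length.out = d),
                 max_total_order = as.integer(max_total_order),
                 loo_target = loo_target,
                 max_basis_terms = as.integer(max_basis_terms),
                 max_interaction_order = as.integer(max_interaction_order)),
            class = "gpce_config")
}

#' Orthonormal Legendre polynomial values
#'
#' Evaluates the Legendre polynomials normalized to unit L2 norm under the
#' uniform measure on `[-1, 1]` (i.e. `sqrt(2n+1) P_n(x)`).
#'
#' @param x evaluation points in `[-1, 1]`.
#' @param degree maximal degree.
#' @return matrix `length(x) x (degree+1)`, column `n+1` holding degree `n`.
#' @export
legendre_orthonormal <- function(x, degree) {
  out <- matrix(0, length(x), degree + 1)
  Pm1 <- rep(1, length(x)); out[, 1] <- Pm1
  if (degree >= 1) { P <- x; out[, 2] <- sqrt(3) * P }
  if (degree >= 2) {
    for (n in 1:(degree - 1)) {
      Pn1 <- ((2 * n + 1) * x * P - n * Pm1) / (n + 1)
      out[, n + 2] <- sqrt(2 * (n + 1) + 1) * Pn1
      Pm1 <- P; P <- Pn1
    }
  }
  out
}

## all multi-indices with given total-degree and interaction-order limits,
## excluding the constant; ordered by (interaction order, total degree, lex)
candidate_multi_indices <- function(d, max_total, max_inter) {
  grid <- as.matrix(expand.grid(rep(list(0:max_total), d)))
  colnames(grid) <- NULL
  tot <- rowSums(grid)
  nint <- rowSums(grid > 0)
  keep <- tot >= 1 & tot <= max_total & nint <= max_inter
  g <- grid[keep, , drop = FALSE]
  g[order(rowSums(g > 0), rowSums(g), apply(g, 1, paste, collapse = ",")),
    , drop = FALSE]
}

map_to_unit <- function(x, cfg) {
  x <- as.matrix(x)
  sweep(sweep(x, 2, (cfg$input_low + cfg$input_high) / 2), 2,
        (cfg$input_high - cfg$input_low) / 2, "/")
}

## design matrix for a set of multi-indices on z in [-1,1]^d
gpce_design <- function(z, multi) {
  d <- ncol(z)
  maxdeg <- max(multi)
  legs <- lapply(seq_len(d), function(j) legendre_orthonormal(z[, j], maxdeg))
  X <- matrix(1, nrow(z), nrow(multi))
  for (t in seq_len(nrow(multi))) {
    for (j in which(multi[t, ] > 0)) {
      X[, t] <- X[, t] * legs[[j]][, multi[t, j] + 1]
    }
  }
  X
}

## relative LOO error of an OLS fit, closed form from the hat matrix
loo_error_ols <- function(X, y) {
  XtX <- crossprod(X)
  R <- tryCatch(chol(XtX), error = function(e) NULL)
  if (is.null(R) || min(diag(R))^2 < 1e-12 * max(diag(XtX)))
    return(list(err = Inf, coef = NULL))
  Xty <- crossprod(X, y)
  beta <- backsolve(R, backsolve(R, Xty, transpose = TRUE))
  res <- y - X %*% beta
  # h_ii = x_i' (X'X)^{-1} x_i
  V <- t(backsolve(R, t(X), transpose = TRUE))
  h <- rowSums(V^2)
  h <- pmin(h, 1 - 1e-10)
  press <- mean((res / (1 - h))^2)
  vy <- var(y)
  err <- if (vy > 0) press / vy else press
  list(err = err, coef = as.numeric(beta))
}

#' Fit an adaptive Legendre gPCE metamodel
#'
#' Starts from the constant term and greedily adds, at each step, the
#' candidate basis term whose inclusion most reduces the leave-one-out
#' cross-validation error of the ordinary-least-squares fit; stops when the
#' LOO error reaches `loo_target`, no candidate improves it, or the basis
#' cap is hit. Candidates are all Legendre total-degree terms up to
#' `max_total_order` involving at most `max_interaction_order` dimensions;
#' higher interaction orders are opened up only if the restricted pool is
#' exhausted without reaching the target.
#'
#' @param samples matrix (n x d) of inputs, or a list of
#'   `stiffness_sample` objects.
#' @param outputs numeric vector of model outputs (e.g. PCS in kPa).
#' @param cfg a [gpce_config()].
#' @return object of class `gpce_model`: `multi` (basis multi-indices,
#'   constant first), `coefficients`, `loo_error`, `loo_trace`, `cfg`.
#' @export
fit_gpce <- function(samples, outputs, cfg = gpce_config()) {
  X_in <- if (is.list(samples) && !is.data.frame(samples) &&
              inherits(samples[[1]], "stiffness_sample")) {
    do.call(rbind, lapply(samples, function(s) s$cluster_moduli))
  } else {
    as.matrix(samples)
  }
  y <- as.numeric(outputs)
  n <- length(y)
  if (nrow(X_in) != n) stop_param("samples and outputs length mismatch")
  z <- map_to_unit(X_in, cfg)
  if (any(z < -1 - 1e-9 | z > 1 + 1e-9))
    stop_param("inputs outside the configured bounds")
  d <- cfg$input_dimension

  if (var(y) == 0) {
    multi <- matrix(0L, 1, d)
    return(structure(list(multi = multi, coefficients = mean(y),
                          loo_error = 0, loo_trace = 0, cfg = cfg,
                          constant_output = TRUE),
                     class = "gpce_model"))
  }

  pools <- list(candidate_multi_indices(d, cfg$max_total_order,
                                        cfg$max_interaction_order))
  if (cfg$max_interaction_order < d) {
    full <- candidate_multi_indices(d, cfg$max_total_order, d)
    key <- apply(full, 1, paste, collapse = ",")
    key1 <- apply(pools[[1]], 1, paste, collapse = ",")
    pools[[2]] <- full[!(key %in% key1), , drop = FALSE]
  }
  # inputs without variation contribute nothing to the output variance:
  # drop every candidate involving a (numerically) constant dimension
  const_dim <- apply(z, 2, function(v) diff(range(v)) < 1e-12)
  if (any(const_dim)) {
    pools <- lapply(pools, function(pool) {
      pool[rowSums(pool[, const_dim, drop = FALSE] > 0) == 0, ,
           drop = FALSE]
    })
  }

  multi <- matrix(0L, 1, d)  # constant term
  fit <- loo_error_ols(gpce_design(z, multi), y)
  loo_trace <- fit$err
  repeat {
    if (nrow(multi) >= cfg$max_basis_terms) break
    if (fit$err <= cfg$loo_target) break
    if (nrow(multi) + 1 >= n) break  # keep the regression overdetermined
    best <- NULL
    for (pool in pools) {
      if (nrow(pool) == 0) next
      for (t in seq_len(nrow(pool))) {
        cand <- rbind(multi, pool[t, ])
        f <- loo_error_ols(gpce_design(z, cand), y)
        if (is.finite(f$err) && (is.null(best) || f$err < best$err)) {
          best <- list(err = f$err, row = pool[t, ], fit = f, pool_id = pool)
          best_t <- t; best_pool <- which(vapply(pools, identical,
                                                 logical(1), pool))
        }
      }
      if (!is.null(best) && best$err < fit$err - 1e-15) break
    }
    if (is.null(best) || best$err >= fit$err) break
    multi <- rbind(multi, best$row)
    # drop the accepted term from its pool
    pools[[best_pool]] <- pools[[best_pool]][-best_t, , drop = FALSE]
    fit <- best$fit
    loo_trace <- c(loo_trace, fit$err)
  }
  structure(list(multi = multi, coefficients = fit$coef,
                 loo_error = fit$err, loo_trace = loo_trace, cfg = cfg,
                 constant_output = FALSE),
            class = "gpce_model")
}

#' Evaluate a gPCE metamodel
#'
#' @param object a `gpce_model`.
#' @param newdata matrix (n x d) of inputs on the original scale.
#' @param ... unused.
#' @return predicted outputs.
#' @export
predict.gpce_model <- function(object, newdata, ...) {
  z <- map_to_unit(as.matrix(newdata), object$cfg)
  as.numeric(gpce_design(z, object$multi) %*% object$coefficients)
}

#' Sobol main sensitivity indices from a gPCE metamodel
#'
#' With an orthonormal basis the output variance is the sum of squared
#' non-constant coefficients; the main index of input i is the share from
#' terms involving dimension i alone, and the aggregate interaction term is
#' the remainder, so main indices and interactions sum to 1.
#'
#' @param model a `gpce_model`.
#' @return object of class `sensitivity_result`: `main_indices` (length d),
#'   `interaction_total`, `total_variance`, `degenerate` flag (TRUE when
#'   the metamodel has zero variance; all indices are then 0).
#' @export
sobol_indices <- function(model) {
  multi <- model$multi
  beta <- model$coefficients
  d <- ncol(multi)
  nonconst <- rowSums(multi) > 0
  total_var <- sum(beta[nonconst]^2)
  if (total_var <= 0) {
    return(structure(list(main_indices = rep(0, d), interaction_total = 0,
                          total_variance = 0, degenerate = TRUE),
                     class = "sensitivity_result"))
  }
  main <- vapply(seq_len(d), function(i) {
    only_i <- multi[, i] > 0 & rowSums(multi[, -i, drop = FALSE] > 0) == 0
    sum(beta[only_i]^2) / total_var
  }, numeric(1))
  structure(list(main_indices = main,
                 interaction_total = 1 - sum(main),
                 total_variance = total_var,
                 degenerate = FALSE),
            class = "sensitivity_result")
}

#' @export
print.sensitivity_result <- function(x, ...) {
  cat("Sobol main indices:",
      paste(sprintf("S%d=%.3f", seq_along(x$main_indices), x$main_indices),
            collapse = " "),
      sprintf("| interactions=%.3f | variance=%.3g", x$interaction_total,
              x$total_variance), "\n")
  invisible(x)
}
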