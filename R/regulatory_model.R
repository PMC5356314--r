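#' @importFrom stats glm binomial coef plogis pnorm logLik AIC vcov simulate
#'   rbinom runif
NULL

as_label01 <- function(labels) {
  if (is.logical(labels)) return(as.integer(labels))
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    stop("labels must be numeric 0/1 or logical")
  }
  labels <- as.integer(labels)
  if (!all(labels %in% c(0L, 1L))) stop("labels must be 0/1")
  labels
}

## ridge-penalized logistic IRLS (intercept unpenalized); used when the
## ordinary ML fit separates. Columns are standardized internally so the
## penalty and the linear algebra are scale-free; estimates are mapped back.
ridge_logit <- function(X, y, lambda = 1e-6, maxit = 200L, tol = 1e-10) {
  ctr <- colMeans(X)
  scl <- apply(X, 2L, stats::sd)
  scl[scl == 0 | !is.finite(scl)] <- 1
  Xs <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
  Xd <- cbind(`(Intercept)` = 1, Xs)
  p <- ncol(Xd)
  D <- diag(c(0, rep(1, p - 1L)), p)
  beta <- rep(0, p)
  for (it in seq_len(maxit)) {
    eta <- drop(Xd %*% beta)
    mu <- plogis(eta)
    w <- pmax(mu * (1 - mu), 1e-12)
    z <- eta + (y - mu) / w
    A <- crossprod(Xd * w, Xd) + 2 * lambda * D
    bnew <- drop(solve(A, crossprod(Xd * w, z), tol = 1e-30))
    if (max(abs(bnew - beta)) < tol) {
      beta <- bnew
      break
    }
    beta <- bnew
  }
  eta <- drop(Xd %*% beta)
  mu <- plogis(eta)
  ll <- sum(y * log(pmax(mu, 1e-300)) + (1 - y) * log(pmax(1 - mu, 1e-300)))
  cov_s <- tryCatch(
    solve(crossprod(Xd * pmax(mu * (1 - mu), 1e-12), Xd) + 2 * lambda * D,
          tol = 1e-30),
    error = function(e) matrix(NA_real_, p, p)
  )
  se_s <- sqrt(pmax(diag(cov_s), 0))
  ## back-transform to the raw feature scale
  b_raw <- beta[-1L] / scl
  a_raw <- beta[1L] - sum(b_raw * ctr)
  se_raw <- se_s[-1L] / scl
  ## intercept SE on the raw scale via the delta method (diagonal approx.)
  se_a <- if (anyNA(cov_s)) NA_real_ else {
    grad <- c(1, -ctr / scl)
    sqrt(max(drop(grad %*% cov_s %*% grad), 0))
  }
  list(coef = setNames(c(a_raw, b_raw), c("(Intercept)", colnames(X))),
       loglik = ll,
       se = setNames(c(se_a, se_raw), c("(Intercept)", colnames(X))))
}

#' Fit a logistic model of regulatory potential
#'
#' Maximum-likelihood logistic regression of case/control status on chromatin
#' features, giving each variant a "regulatory potential"
#' \eqn{P(causal \mid X) = 1 / (1 + e^{-(\alpha + \beta X)})}.
#' Per-coefficient Wald P values are retained. Perfect separation (fitted
#' probabilities numerically 0 or 1) is flagged and the model is refitted
#' with a tiny ridge penalty (lambda = 1e-6) so small fixtures never abort a
#' pipeline.
#'
#' Columns that are entirely NA (marks absent from a cell type) are dropped
#' with a message; constant columns are dropped likewise since their
#' coefficient is not identifiable.
#'
#' @param features numeric matrix, rows = variants, named columns = features
#'   (e.g. from [feature_matrix()]).
#' @param labels case/control indicator (1 = case/eQTL, 0 = control);
#'   at least two of each.
#' @param meta optional named list of training metadata (study label,
#'   control scheme, ...), stored on the model.
#' @param standardize z-scale non-binary columns before fitting (default
#'   FALSE; features are used in their native units).
#' @return an object of class `regpot_logit` with components `alpha`,
#'   `beta` (named), `feature_names`, `se`, `wald_p`, `loglik`, `aic`,
#'   `n`, `separation`, `scaling`, `training_meta`.
#' @seealso [predict_potential()], [stepwise_backward_aic()]
#' @export
fit_logit <- function(features, labels, meta = list(), standardize = FALSE) {
  features <- as.matrix(features)
  if (is.null(colnames(features))) {
    colnames(features) <- paste0("x", seq_len(ncol(features)))
  }
  y <- as_label01(labels)
  if (length(y) != nrow(features)) stop("labels and feature rows differ")
  if (sum(y == 0L) < 2L || sum(y == 1L) < 2L) {
    stop("need at least 2 observations of each label")
  }
  all_na <- apply(features, 2L, function(v) all(is.na(v)))
  if (any(all_na)) {
    message("dropping all-NA feature column(s): ",
            paste(colnames(features)[all_na], collapse = ", "))
    features <- features[, !all_na, drop = FALSE]
  }
  if (anyNA(features)) {
    keep <- stats::complete.cases(features)
    message("dropping ", sum(!keep), " row(s) with missing feature values")
    features <- features[keep, , drop = FALSE]
    y <- y[keep]
  }
  constant <- apply(features, 2L, function(v) length(unique(v)) < 2L)
  if (any(constant)) {
    message("dropping constant feature column(s): ",
            paste(colnames(features)[constant], collapse = ", "))
    features <- features[, !constant, drop = FALSE]
  }
  ## drop exactly collinear columns up front (rank-deficient design)
  if (ncol(features)) {
    qx <- qr(cbind(1, features))
    if (qx$rank < ncol(features) + 1L) {
      drop_idx <- qx$pivot[-seq_len(qx$rank)] - 1L
      drop_idx <- drop_idx[drop_idx >= 1L]
      if (length(drop_idx)) {
        message("dropping collinear feature column(s): ",
                paste(colnames(features)[drop_idx], collapse = ", "))
        features <- features[, -drop_idx, drop = FALSE]
      }
    }
  }
  scaling <- NULL
  if (standardize && ncol(features)) {
    binary <- apply(features, 2L, function(v) all(v %in% c(0, 1)))
    ctr <- ifelse(binary, 0, colMeans(features))
    scl <- ifelse(binary, 1, apply(features, 2L, stats::sd))
    scl[scl == 0] <- 1
    features <- sweep(sweep(features, 2L, ctr), 2L, scl, "/")
    scaling <- list(center = ctr, scale = scl)
  }
  dat <- data.frame(.y = y, features, check.names = FALSE)
  sep <- FALSE
  fml <- if (ncol(features)) {
    stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(features)),
                                          collapse = " + ")))
  } else {
    .y ~ 1
  }
  fit <- withCallingHandlers(
    glm(fml, family = binomial(), data = dat),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        sep <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  cf <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  ## glm can also separate silently: the symptom is exploding Wald SEs
  if (!sep && (any(!is.finite(se)) || max(se) > 1e3)) sep <- TRUE
  if (sep) {
    warning("separation detected; refitting with ridge penalty (lambda = 1e-6)")
    r <- ridge_logit(features, y)
    cf <- r$coef
    se <- r$se
    ll <- r$loglik
  } else {
    ll <- as.numeric(logLik(fit))
  }
  names(cf) <- gsub("`", "", names(cf), fixed = TRUE)
  names(se) <- names(cf)
  fn <- setdiff(names(cf), "(Intercept)")
  z <- cf / se
  k <- length(cf)
  structure(list(
    alpha = unname(cf["(Intercept)"]),
    beta = cf[fn],
    feature_names = fn,
    se = se,
    wald_p = 2 * pnorm(-abs(z)),
    loglik = ll,
    aic = 2 * k - 2 * ll,
    n = length(y),
    separation = sep,
    scaling = scaling,
    training_meta = c(meta, list(n_cases = sum(y == 1L), n_controls = sum(y == 0L)))
  ), class = "regpot_logit")
}

#' @export
print.regpot_logit <- function(x, ...) {
  cat("Logistic regulatory-potential model\n")
  cat(sprintf("  features: %d   n: %d (%d cases / %d controls)   AIC: %.2f%s\n",
              length(x$feature_names), x$n,
              x$training_meta$n_cases, x$training_meta$n_controls, x$aic,
              if (isTRUE(x$separation)) "   [ridge fallback]" else ""))
  invisible(x)
}

#' @export
coef.regpot_logit <- function(object, ...) {
  c("(Intercept)" = object$alpha, object$beta)
}

#' @export
summary.regpot_logit <- function(object, ...) {
  cf <- coef(object)
  tab <- data.frame(
    estimate = cf, se = object$se[names(cf)],
    z = cf / object$se[names(cf)],
    p = object$wald_p[names(cf)]
  )
  structure(list(table = tab, aic = object$aic, n = object$n,
                 separation = object$separation),
            class = "summary.regpot_logit")
}

#' @export
print.summary.regpot_logit <- function(x, ...) {
  cat("Logistic regulatory-potential model\n")
  print(round(x$table, 4))
  cat(sprintf("n = %d, AIC = %.2f%s\n", x$n, x$aic,
              if (isTRUE(x$separation)) " (ridge fallback)" else ""))
  invisible(x)
}

#' Regulatory potential of variants under a fitted model
#'
#' Evaluates \eqn{1 / (1 + e^{-(\alpha + \beta X)})} for each variant.
#'
#' @param model a `regpot_logit`.
#' @param features named numeric vector (one variant) or matrix with named
#'   columns; must contain every model feature. Missing features raise an
#'   error listing their names.
#' @return numeric vector of potentials in (0, 1).
#' @export
predict_potential <- function(model, features) {
  stopifnot(inherits(model, "regpot_logit"))
  if (is.null(dim(features))) {
    features <- matrix(features, nrow = 1L,
                       dimnames = list(NULL, names(features)))
  }
  miss <- setdiff(model$feature_names, colnames(features))
  if (length(miss)) {
    stop("features missing from input: ", paste(miss, collapse = ", "))
  }
  X <- features[, model$feature_names, drop = FALSE]
  if (!is.null(model$scaling)) {
    X <- sweep(sweep(X, 2L, model$scaling$center[model$feature_names]),
               2L, model$scaling$scale[model$feature_names], "/")
  }
  eta <- model$alpha + if (length(model$feature_names)) {
    drop(X %*% model$beta)
  } else {
    rep(0, nrow(features))
  }
  unname(plogis(eta))
}

#' @export
predict.regpot_logit <- function(object, newdata, type = c("response", "link"), ...) {
  type <- match.arg(type)
  p <- predict_potential(object, newdata)
  if (type == "link") stats::qlogis(p) else p
}

#' @export
simulate.regpot_logit <- function(object, nsim = 1, seed = NULL, newdata, ...) {
  if (!is.null(seed)) set.seed(seed)
  p <- predict_potential(object, newdata)
  out <- replicate(nsim, rbinom(length(p), 1L, p))
  as.data.frame(out)
}

#' Backward stepwise feature selection by AIC
#'
#' Starts from the full model and repeatedly removes the single feature whose
#' removal most decreases AIC (= 2k - 2 log L, k counting the intercept),
#' stopping when no removal decreases it. Ties between candidate removals
#' are broken by alphabetical feature name, so the selected set is
#' deterministic. A candidate refit that fails is skipped with a warning.
#'
#' @inheritParams fit_logit
#' @return list with components `model` (the `regpot_logit` on the selected
#'   features), `selected` (feature names, original column order), `path`
#'   (data frame of removal steps with AIC values).
#' @export
stepwise_backward_aic <- function(features, labels, meta = list()) {
  features <- as.matrix(features)
  current <- fit_logit(features, labels, meta = meta)
  feats <- current$feature_names
  steps <- list()
  repeat {
    if (!length(feats)) break
    cand_aic <- rep(NA_real_, length(feats))
    names(cand_aic) <- feats
    for (f in feats) {
      sub <- setdiff(feats, f)
      fit <- tryCatch(
        suppressMessages(suppressWarnings(
          if (length(sub)) {
            fit_logit(features[, sub, drop = FALSE], labels, meta = meta)
          } else {
            fit_logit_intercept(labels, meta = meta)
          }
        )),
        error = function(e) NULL
      )
      if (is.null(fit)) {
        warning("removal candidate `", f, "` failed to fit; skipped")
        next
      }
      cand_aic[f] <- fit$aic
    }
    if (all(is.na(cand_aic))) break
    best <- min(cand_aic, na.rm = TRUE)
    if (best >= current$aic - 1e-10) break
    drop_f <- sort(names(cand_aic)[!is.na(cand_aic) &
                                     abs(cand_aic - best) < 1e-10],
                   method = "radix")[1L]
    feats <- setdiff(feats, drop_f)
    steps[[length(steps) + 1L]] <- data.frame(removed = drop_f, aic = best)
    current <- if (length(feats)) {
      suppressMessages(suppressWarnings(
        fit_logit(features[, feats, drop = FALSE], labels, meta = meta)
      ))
    } else {
      fit_logit_intercept(labels, meta = meta)
    }
  }
  list(
    model = current,
    selected = intersect(colnames(features), feats),
    path = if (length(steps)) do.call(rbind, steps) else
      data.frame(removed = character(0), aic = numeric(0))
  )
}

## intercept-only logistic fit (closed form)
fit_logit_intercept <- function(labels, meta = list()) {
  y <- as_label01(labels)
  p <- mean(y)
  alpha <- stats::qlogis(min(max(p, 1e-12), 1 - 1e-12))
  ll <- sum(y * log(p) + (1 - y) * log(1 - p))
  structure(list(
    alpha = alpha, beta = setNames(numeric(0), character(0)),
    feature_names = character(0),
    se = c("(Intercept)" = sqrt(1 / (length(y) * p * (1 - p)))),
    wald_p = c("(Intercept)" = 2 * pnorm(-abs(alpha * sqrt(length(y) * p * (1 - p))))),
    loglik = ll, aic = 2 - 2 * ll, n = length(y),
    separation = FALSE, scaling = NULL,
    training_meta = c(meta, list(n_cases = sum(y == 1L), n_controls = sum(y == 0L)))
  ), class = "regpot_logit")
}

#' Cross-study feature occurrence and the shared feature set
#'
#' A feature is shared when it was selected in strictly more than half of
#' the per-study models.
#'
#' @param selected_by_study named list of character vectors, one per study,
#'   each the features selected for that study.
#' @return list of class `feature_selection_report`: `per_study` (the input),
#'   `occurrence` (named integer vector), `shared` (character vector),
#'   `n_studies`.
#' @export
feature_selection_report <- function(selected_by_study) {
  if (length(selected_by_study) < 2L) stop("need at least 2 studies")
  occ <- table(unlist(lapply(selected_by_study, unique), use.names = FALSE))
  occ <- setNames(as.integer(occ), names(occ))
  occ <- occ[sort(names(occ), method = "radix")]
  shared <- names(occ)[occ > length(selected_by_study) / 2]
  structure(list(per_study = selected_by_study, occurrence = occ,
                 shared = shared, n_studies = length(selected_by_study)),
            class = "feature_selection_report")
}

#' @export
print.feature_selection_report <- function(x, ...) {
  cat(sprintf("<feature_selection_report> %d studies, %d features seen, %d shared\n",
              x$n_studies, length(x$occurrence), length(x$shared)))
  invisible(x)
}

#' Features shared by more than half of the per-study models
#'
#' @inheritParams feature_selection_report
#' @return character vector of shared feature names.
#' @export
select_shared_features <- function(selected_by_study) {
  feature_selection_report(selected_by_study)$shared
}

#' Fit a generalized model on pooled studies
#'
#' Pools the per-study feature matrices row-wise, restricts to the shared
#' feature set, and fits one logistic model usable on any cell type's
#' features.
#'
#' @param feature_list list of feature matrices (one per study), or a single
#'   pooled matrix.
#' @param labels_list list of label vectors matching `feature_list` (or a
#'   single vector).
#' @param shared character vector of shared feature names.
#' @param meta optional metadata list.
#' @return a `regpot_logit`.
#' @export
fit_generalized <- function(feature_list, labels_list, shared, meta = list()) {
  if (is.matrix(feature_list) || is.data.frame(feature_list)) {
    feature_list <- list(as.matrix(feature_list))
    labels_list <- list(labels_list)
  }
  pooled <- do.call(rbind, lapply(feature_list, function(m) {
    m <- as.matrix(m)
    miss <- setdiff(shared, colnames(m))
    if (length(miss)) stop("study matrix lacks shared feature(s): ",
                           paste(miss, collapse = ", "))
    m[, shared, drop = FALSE]
  }))
  labels <- unlist(labels_list, use.names = FALSE)
  fit_logit(pooled, labels, meta = c(meta, list(pooled_studies = length(feature_list))))
}

#' Serialize a fitted model as JSON
#'
#' Numbers are written at full precision so a written-then-read model equals
#' the original bit for bit.
#'
#' @param model a `regpot_logit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_logit_model <- function(model, path) {
  obj <- list(
    class = "regpot_logit",
    alpha = model$alpha,
    feature_names = as.list(model$feature_names),
    beta = as.list(model$beta),
    se = as.list(model$se),
    wald_p = as.list(model$wald_p),
    loglik = model$loglik, aic = model$aic, n = model$n,
    separation = model$separation,
    scaling = if (is.null(model$scaling)) NULL else
      list(center = as.list(model$scaling$center),
           scale = as.list(model$scaling$scale)),
    training_meta = model$training_meta
  )
  # 17 significant digits: doubles reload bit-exactly
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Reload a model written by [write_logit_model()]
#'
#' @param path path to the JSON file.
#' @return a `regpot_logit`.
#' @export
read_logit_model <- function(path) {
  obj <- jsonlite::read_json(path)
  num <- function(x) setNames(vapply(x, as.numeric, 0), names(x))
  fn <- as.character(unlist(obj$feature_names))
  structure(list(
    alpha = as.numeric(obj$alpha),
    beta = if (length(obj$beta)) num(obj$beta)[fn] else
      setNames(numeric(0), character(0)),
    feature_names = fn,
    se = num(obj$se),
    wald_p = num(obj$wald_p),
    loglik = as.numeric(obj$loglik),
    aic = as.numeric(obj$aic),
    n = as.integer(obj$n),
    separation = isTRUE(obj$separation),
    scaling = if (is.null(obj$scaling)) NULL else
      list(center = num(obj$scaling$center), scale = num(obj$scaling$scale)),
    training_meta = obj$training_meta
  ), class = "regpot_logit")
}
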