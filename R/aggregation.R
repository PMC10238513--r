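#' Build a patient's site vector
#'
#' Orders one clip-level probability per thoracic site into the canonical
#' length-8 vector. Patients missing any of the eight recordings are excluded
#' from aggregation: a missing site raises an incomplete-patient error.
#'
#' @param predictions Named numeric vector or list, names drawn from
#'   [ausc_sites], values in \[0, 1\].
#' @return Numeric vector of length 8 in canonical site order.
#' @export
build_site_vector <- function(predictions) {
  predictions <- unlist(predictions)
  missing <- setdiff(ausc_sites, names(predictions))
  if (length(missing))
    stop("incomplete patient: missing site(s) ", paste(missing, collapse = ", "))
  v <- as.numeric(predictions[ausc_sites])
  if (any(v < 0 | v > 1)) stop("site scores must lie in [0, 1]")
  names(v) <- ausc_sites
  v
}

## Ridge-penalized logistic fit via glmnet. `reg` is the total L2 strength:
## the objective is -(1/n) loglik + reg/(2n) * ||w||^2, i.e. glmnet's
## lambda = reg / n at alpha = 0 (reg = 0 gives the unpenalized fit).
glmnet_lambda <- function(reg, n) max(reg, 0) / n

## Shared deterministic penalized logistic fit (alpha = 0 ridge by default).
## Returns intercept + weights at the requested strength; used by the binary
## aggregator, the inference sweep and the clinical baseline so that all
## logistic fits in the pipeline share one solver configuration.
ridge_logistic_fit <- function(x, y, reg = 1.0, alpha = 0) {
  y <- as.integer(as.logical(y))
  if (length(unique(y)) < 2L)
    stop("degenerate fit: training labels contain a single class")
  if (all(apply(x, 2L, stats::var) < 1e-24)) {
    # constant features: intercept-only fit predicts the class prevalence
    return(list(intercept = stats::qlogis(mean(y)), weights = numeric(ncol(x))))
  }
  p <- ncol(x)
  if (p == 1L) x <- cbind(x, 0)       # glmnet requires >= 2 columns
  lam <- glmnet_lambda(reg, nrow(x))
  lams <- sort(unique(c(lam * c(100, 10, 1), lam + 1e-4)), decreasing = TRUE)
  fit <- glmnet::glmnet(x, y, family = "binomial", alpha = alpha,
                        lambda = lams, standardize = FALSE, thresh = 1e-12)
  co <- as.numeric(stats::coef(fit, s = lam, exact = TRUE, x = x, y = y))
  list(intercept = co[1L], weights = co[1L + seq_len(p)])
}

#' Fit the binary patient-level aggregator
#'
#' Logistic regression on the length-8 site vectors, fitted on the pooled
#' train + tune folds (the aggregator needs no tuning set of its own).
#' L2-regularized with a fixed strength, deterministic given the data.
#'
#' @param vectors Matrix `n x 8` of site vectors (one row per patient).
#' @param labels Binary vector (0/1 or logical), length `n`.
#' @param reg L2 regularization strength (default 1).
#' @return An object of class `aggregator`.
#' @export
fit_binary_aggregator <- function(vectors, labels, reg = 1.0) {
  vectors <- as.matrix(vectors)
  co <- ridge_logistic_fit(vectors, labels, reg)
  structure(list(type = "binary", intercept = co$intercept,
                 weights = co$weights, sites = ausc_sites, reg = reg),
            class = "aggregator")
}

#' Predict a patient-level probability
#' @param vector Length-8 site vector (canonical order) or `n x 8` matrix.
#' @param agg A binary `aggregator`.
#' @return Probability in \[0, 1\] (vector if a matrix was given).
#' @export
predict_patient <- function(vector, agg) {
  if (agg$type != "binary") stop("aggregator is not binary")
  m <- if (is.matrix(vector)) vector else matrix(vector, nrow = 1L)
  drop(1 / (1 + exp(-(agg$intercept + m %*% agg$weights))))
}

#' Build multiclass fusion features
#'
#' Stacks the four binary models' site vectors into a 4 (classes) x 8 (sites)
#' array, L1-normalizes each column (a recording scored high by several
#' models should matter less), and flattens class-major into a length-32
#' feature vector. Zero-sum columns are left as zeros.
#'
#' @param site_vectors List of four length-8 site vectors, in [ausc_diagnoses]
#'   order, or a `4 x 8` matrix.
#' @return List with `array` (normalized `4 x 8` matrix) and `flat`
#'   (length-32 vector, class-major).
#' @export
build_multiclass_features <- function(site_vectors) {
  m <- if (is.matrix(site_vectors)) site_vectors else do.call(rbind, site_vectors)
  if (!all(dim(m) == c(4L, 8L))) stop("expected a 4 x 8 prediction array")
  cs <- colSums(m)
  nz <- cs > 0
  m[, nz] <- sweep(m[, nz, drop = FALSE], 2L, cs[nz], "/")
  rownames(m) <- ausc_diagnoses
  colnames(m) <- ausc_sites
  list(array = m, flat = as.vector(t(m)))
}

#' Fit the multinomial diagnostic fusion
#'
#' Multinomial logistic regression on the length-32 fusion features,
#' predicting the four-class diagnosis. All four classes must be present.
#'
#' @param features Matrix `n x 32` of flattened fusion features.
#' @param diagnoses Character vector of true diagnoses ([ausc_diagnoses]).
#' @param reg L2 regularization strength (default 1).
#' @return An object of class `aggregator` (type `"multiclass"`).
#' @export
fit_multiclass <- function(features, diagnoses, reg = 1.0) {
  features <- as.matrix(features)
  y <- factor(diagnoses, levels = ausc_diagnoses)
  if (any(table(y) == 0L))
    stop("degenerate fit: all four diagnoses must be present in training data")
  lam <- glmnet_lambda(reg, nrow(features))
  lams <- sort(unique(c(lam * c(100, 10, 1), lam + 1e-4)), decreasing = TRUE)
  fit <- glmnet::glmnet(features, y, family = "multinomial", alpha = 0,
                        lambda = lams, standardize = FALSE, thresh = 1e-12)
  co <- stats::coef(fit, s = lam, exact = TRUE, x = features, y = y)
  weights <- do.call(cbind, lapply(co, function(b) as.numeric(b)[-1L]))
  intercepts <- vapply(co, function(b) as.numeric(b)[1L], numeric(1))
  colnames(weights) <- ausc_diagnoses
  structure(list(type = "multiclass", intercept = intercepts,
                 weights = weights, classes = ausc_diagnoses,
                 sites = ausc_sites, reg = reg),
            class = "aggregator")
}

#' Predict a patient's diagnosis distribution
#' @param features Length-32 fusion feature vector or `n x 32` matrix.
#' @param agg A multiclass `aggregator`.
#' @return Matrix `n x 4` of class probabilities (rows sum to 1); the argmax
#'   is the predicted diagnosis.
#' @export
predict_diagnosis <- function(features, agg) {
  if (agg$type != "multiclass") stop("aggregator is not multiclass")
  m <- if (is.matrix(features)) features else matrix(features, nrow = 1L)
  z <- sweep(m %*% agg$weights, 2L, agg$intercept, "+")
  ez <- exp(z - apply(z, 1L, max))
  ez / rowSums(ez)
}

#' @export
print.aggregator <- function(x, ...) {
  cat(sprintf("<aggregator> %s, reg = %g\n", x$type, x$reg))
  invisible(x)
}

#' Serialize an aggregator to JSON
#' @param agg An `aggregator`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_aggregator <- function(agg, path) {
  jsonlite::write_json(unclass(agg), path, auto_unbox = TRUE, digits = NA,
                       matrix = "columnmajor")
  invisible(path)
}

#' Read an aggregator from JSON
#' @param path Path written by [write_aggregator].
#' @return An `aggregator`.
#' @export
read_aggregator <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (x$type == "multiclass") {
    w <- x$weights
    # column-major serialization comes back with classes as rows
    w <- if (is.matrix(w)) t(w) else matrix(unlist(w), ncol = 4L)
    colnames(w) <- x$classes
    x$weights <- w
    x$intercept <- stats::setNames(unlist(x$intercept), x$classes)
  }
  structure(x, class = "aggregator")
}
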