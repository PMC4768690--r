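#' Fit the STFT-DA linear discriminant classifier
#'
#' Trains a linear discriminant model (shared, pooled within-class
#' covariance) on otolith feature vectors. The discriminant score of class
#' `k` for a feature vector `x` is
#' `delta_k(x) = x' S^-1 mu_k - 0.5 mu_k' S^-1 mu_k + log pi_k`,
#' with `mu_k` the class mean, `S` the pooled covariance and `pi_k` the
#' prior; a sample is assigned to the class with the largest score.
#'
#' @param x Feature matrix (`n x d`), a data frame of features, or a formula
#'   such as `species ~ .`.
#' @param ... Passed to methods.
#' @return An object of class `"stftda"`; see Details.
#'
#' @details The fitted object is a list with components `means` (`K x d`
#' class means), `cov` (pooled within-class covariance), `cov_inv`,
#' `log_priors`, `classes`, `d`, `ridge` (the ridge actually applied, 0 if
#' none), `counts` (training samples per class) and `call`. If the pooled
#' covariance has 2-norm condition number above `1e12` and `ridge > 0`,
#' `ridge * trace(S)/d` is added to the diagonal and recorded.
#'
#' @examples
#' set.seed(1)
#' x <- rbind(matrix(rnorm(40), 20), matrix(rnorm(40, 3), 20))
#' g <- rep(c("a", "b"), each = 20)
#' fit <- stftda(x, g)
#' predict(fit, x[1:3, , drop = FALSE])
#' @export
stftda <- function(x, ...) UseMethod("stftda")

#' @rdname stftda
#' @param formula Model formula; the left-hand side names the class label
#'   column, the right-hand side the feature columns (`.` for all others).
#' @param data Data frame containing the variables in `formula`.
#' @export
stftda.formula <- function(formula, data, ...) {
  mf <- stats::model.frame(formula, data)
  grouping <- mf[[1L]]
  xm <- as.matrix(mf[, -1L, drop = FALSE])
  fit <- stftda.default(xm, grouping, ...)
  fit$call <- match.call()
  fit
}

#' @rdname stftda
#' @param grouping Factor or character vector of class labels, one per row
#'   of `x`.
#' @param prior `"uniform"` (default; the study designs are balanced) or
#'   `"empirical"` (class frequencies in the training set).
#' @param ridge Ridge factor applied only when the pooled covariance is
#'   ill-conditioned (condition number `> 1e12`): `ridge * trace(S)/d` is
#'   added to the diagonal. With the default 0, a singular covariance is an
#'   error.
#' @export
stftda.default <- function(x, grouping, prior = c("uniform", "empirical"),
                           ridge = 0, ...) {
  prior <- match.arg(prior)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (any(!is.finite(x))) stop("features must be finite", call. = FALSE)
  g <- factor(grouping)
  if (nrow(x) != length(g)) {
    stop("number of rows of x must match length of grouping", call. = FALSE)
  }
  classes <- levels(g)
  K <- length(classes)
  if (K < 2L) stop("need at least 2 classes", call. = FALSE)
  counts <- table(g)
  if (any(counts < 2L)) {
    stop("insufficient data: every class needs >= 2 training samples ",
         "(offending: ", paste(names(counts)[counts < 2], collapse = ", "),
         ")", call. = FALSE)
  }
  n <- nrow(x)
  d <- ncol(x)
  if (n - K < 1L) stop("need at least K + 1 training samples", call. = FALSE)

  means <- matrix(0, nrow = K, ncol = d,
                  dimnames = list(classes, colnames(x)))
  SS <- matrix(0, d, d)
  for (k in seq_len(K)) {
    xk <- x[g == classes[k], , drop = FALSE]
    means[k, ] <- colMeans(xk)
    cx <- sweep(xk, 2L, means[k, ])
    SS <- SS + crossprod(cx)
  }
  S <- SS / (n - K)

  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  ridge_applied <- 0
  if ((min(ev) <= 0 || max(ev) / min(ev) > 1e12)) {
    if (ridge > 0) {
      tr <- sum(diag(S))
      ridge_applied <- if (tr > 0) ridge * tr / d else ridge
      S <- S + diag(ridge_applied, d)
    } else if (min(ev) <= 0) {
      stop("singular pooled covariance; refit with ridge > 0 ",
           "(e.g. stftda(..., ridge = 1e-6))", call. = FALSE)
    }
  }
  cov_inv <- tryCatch(
    solve(S),
    error = function(e) stop("pooled covariance is not invertible; ",
                             "refit with ridge > 0", call. = FALSE)
  )
  priors <- if (prior == "uniform") rep(1 / K, K) else as.numeric(counts) / n
  structure(
    list(means = means, cov = S, cov_inv = cov_inv,
         log_priors = log(priors), priors = priors, classes = classes,
         d = d, ridge = ridge_applied, counts = as.integer(counts),
         prior = prior, call = match.call()),
    class = "stftda"
  )
}

# n x K matrix of linear discriminant scores
da_scores <- function(object, x) {
  W <- object$cov_inv %*% t(object$means)            # d x K
  const <- -0.5 * colSums(t(object$means) * W) + object$log_priors
  sweep(x %*% W, 2L, const, "+")
}

#' Predict species from a fitted STFT-DA model
#'
#' @param object A fitted `"stftda"` model.
#' @param newdata Feature matrix or data frame with `object$d` columns (a
#'   single feature vector may be given as a plain numeric vector).
#' @param type `"class"` for labels (default), `"scores"` for the full
#'   discriminant score matrix, `"both"` for a list of the two.
#' @param ... Unused.
#' @return Factor of predicted classes, a score matrix, or a list with both.
#'   Ties are broken deterministically in favour of the earlier class in
#'   `object$classes`.
#' @export
predict.stftda <- function(object, newdata,
                           type = c("class", "scores", "both"), ...) {
  type <- match.arg(type)
  if (is.null(dim(newdata))) newdata <- matrix(newdata, nrow = 1L)
  x <- as.matrix(newdata)
  storage.mode(x) <- "double"
  if (ncol(x) != object$d) {
    stop("feature dimension mismatch: model expects ", object$d,
         " features, got ", ncol(x), call. = FALSE)
  }
  sc <- da_scores(object, x)
  colnames(sc) <- object$classes
  if (type == "scores") return(sc)
  cls <- factor(object$classes[max.col(sc, ties.method = "first")],
                levels = object$classes)
  if (type == "class") cls else list(class = cls, scores = sc)
}

#' @export
print.stftda <- function(x, ...) {
  cat("STFT-DA linear discriminant model\n")
  cat("  classes:  ", length(x$classes), " (",
      paste(x$classes, collapse = ", "), ")\n", sep = "")
  cat("  features: ", x$d, "\n", sep = "")
  cat("  training samples per class: ",
      paste(x$counts, collapse = ", "), "\n", sep = "")
  cat("  priors:   ", x$prior, "\n", sep = "")
  if (x$ridge > 0) {
    cat("  ridge applied to pooled covariance: ",
        format(x$ridge, digits = 4), "\n", sep = "")
  }
  invisible(x)
}

#' @export
summary.stftda <- function(object, ...) {
  out <- list(
    classes = object$classes, d = object$d, counts = object$counts,
    prior = object$prior, ridge = object$ridge,
    mean_range = range(object$means),
    cov_condition = {
      ev <- eigen(object$cov, symmetric = TRUE, only.values = TRUE)$values
      max(ev) / min(ev)
    }
  )
  class(out) <- "summary.stftda"
  out
}

#' @export
print.summary.stftda <- function(x, ...) {
  cat("STFT-DA model summary\n")
  cat("  ", length(x$classes), " classes, ", x$d, " features, ",
      sum(x$counts), " training samples\n", sep = "")
  cat("  pooled covariance condition number: ",
      format(x$cov_condition, digits = 3), "\n", sep = "")
  cat("  ridge: ", format(x$ridge, digits = 3), "\n", sep = "")
  invisible(x)
}

#' @export
coef.stftda <- function(object, ...) {
  W <- object$cov_inv %*% t(object$means)
  const <- -0.5 * colSums(t(object$means) * W) + object$log_priors
  rbind(intercept = const, W)
}

#' Plot class separation of a fitted model
#'
#' Projects feature vectors onto the first two canonical discriminant
#' directions (eigenvectors of `S^-1 B` with `B` the between-class scatter
#' of the stored class means) and draws a scatter plot coloured by label.
#'
#' @param x A fitted `"stftda"` model.
#' @param data Feature matrix to project.
#' @param labels Class labels for colouring (optional; defaults to the
#'   model's predictions).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.stftda <- function(x, data, labels = NULL, ...) {
  xm <- as.matrix(data)
  if (is.null(labels)) labels <- predict(x, xm)
  mu <- colMeans(x$means)
  B <- crossprod(sweep(x$means, 2L, mu))
  e <- eigen(x$cov_inv %*% B)
  V <- Re(e$vectors[, 1:2, drop = FALSE])
  proj <- xm %*% V
  g <- factor(labels, levels = x$classes)
  graphics::plot(proj[, 1], proj[, 2], col = as.integer(g), pch = 16,
                 xlab = "LD1", ylab = "LD2", ...)
  graphics::legend("topright", legend = x$classes,
                   col = seq_along(x$classes), pch = 16, cex = 0.8)
  invisible(proj)
}

#' Confusion matrix of target vs predicted classes
#'
#' @param truth Vector of true class labels (rows of the matrix).
#' @param predicted Vector of predicted class labels (columns).
#' @param classes Optional ordered class labels; defaults to the union of
#'   levels found in `truth` and `predicted`.
#' @return Object of class `"confusion_matrix"`: an integer `K x K` matrix
#'   with classes on both dimnames.
#' @export
confusion_matrix <- function(truth, predicted, classes = NULL) {
  if (is.null(classes)) {
    classes <- union(levels(factor(truth)), levels(factor(predicted)))
  }
  t_f <- factor(truth, levels = classes)
  p_f <- factor(predicted, levels = classes)
  if (any(is.na(t_f)) || any(is.na(p_f))) {
    stop("labels outside the supplied class set", call. = FALSE)
  }
  m <- table(target = t_f, predicted = p_f)
  cm <- matrix(as.integer(m), nrow = length(classes),
               dimnames = list(target = classes, predicted = classes))
  structure(cm, class = c("confusion_matrix", "matrix"))
}

#' Overall accuracy of a confusion matrix
#'
#' @param cm A `"confusion_matrix"` (or plain square count matrix).
#' @param percent If `TRUE`, return the percentage rounded to the nearest
#'   integer (the conventional reporting scale); otherwise the exact
#'   fraction.
#' @return Numeric scalar.
#' @export
overall_accuracy <- function(cm, percent = FALSE) {
  acc <- sum(diag(as.matrix(cm))) / sum(cm)
  if (percent) round(100 * acc) else acc
}

#' Per-class accuracy of a confusion matrix
#'
#' @param cm A `"confusion_matrix"`.
#' @return Named numeric vector of per-class accuracies (fractions).
#' @export
class_accuracy <- function(cm) {
  m <- as.matrix(cm)
  diag(m) / rowSums(m)
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- as.matrix(x)
  class(m) <- "matrix"
  cat("Confusion matrix (rows = target, cols = predicted)\n")
  print(m)
  pc <- class_accuracy(x)
  cat("Per-class accuracy: ",
      paste(sprintf("%s %.0f%%", names(pc), 100 * pc), collapse = ", "),
      "\n", sep = "")
  cat(sprintf("Overall accuracy: %d/%d = %.1f%% (~%d%%)\n",
              sum(diag(m)), sum(m), 100 * overall_accuracy(x),
              overall_accuracy(x, percent = TRUE)))
  invisible(x)
}

#' Evaluate a fitted model on labelled test data
#'
#' @param model A fitted `"stftda"` model.
#' @param x Test feature matrix or data frame.
#' @param labels True class labels; must all be known to the model.
#' @return List with `confusion` (a `"confusion_matrix"`), `accuracy`
#'   (fraction) and `accuracy_pct` (rounded percent).
#' @export
evaluate <- function(model, x, labels) {
  labs <- as.character(labels)
  unknown <- setdiff(unique(labs), model$classes)
  if (length(unknown)) {
    stop("unknown class label(s) in test data: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  pred <- predict(model, x)
  cm <- confusion_matrix(labs, pred, classes = model$classes)
  list(confusion = cm, accuracy = overall_accuracy(cm),
       accuracy_pct = overall_accuracy(cm, percent = TRUE))
}

#' Deterministic per-class train/test split
#'
#' Shuffles indices within each class with a fixed seed and assigns the
#' first `n_train` to the training set and the next `n_test` to the test
#' set.
#'
#' @param labels Vector of class labels.
#' @param n_train,n_test Samples per class for each split.
#' @param seed Integer seed.
#' @return List with integer index vectors `train` and `test` (disjoint).
#' @export
train_test_split <- function(labels, n_train, n_test, seed = 1) {
  g <- factor(labels)
  tr <- integer(0)
  te <- integer(0)
  rs <- local_rng(seed)
  on.exit(restore_rng(rs))
  for (cl in levels(g)) {
    idx <- which(g == cl)
    if (length(idx) < n_train + n_test) {
      stop("class ", cl, " has ", length(idx), " samples; need ",
           n_train + n_test, call. = FALSE)
    }
    idx <- sample(idx)
    tr <- c(tr, idx[seq_len(n_train)])
    te <- c(te, idx[n_train + seq_len(n_test)])
  }
  list(train = sort(tr), test = sort(te))
}

#' Save a fitted model as JSON
#'
#' @param model A fitted `"stftda"` model.
#' @param path Output file path.
#' @param config Optional configuration list echoed into the file.
#' @return `path`, invisibly.
#' @export
write_stftda <- function(model, path, config = NULL) {
  obj <- list(
    format = "stftda-model", version = 1L,
    classes = model$classes, d = model$d,
    means = model$means, cov = model$cov,
    priors = model$priors, prior = model$prior,
    ridge = model$ridge, counts = model$counts,
    config = if (is.null(config)) NULL else unclass(config)
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a model saved by [write_stftda()]
#'
#' @param path JSON file path.
#' @return A fitted `"stftda"` model.
#' @export
read_stftda <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "stftda-model") {
    stop("not an stftda model file: ", path, call. = FALSE)
  }
  means <- as.matrix(obj$means)
  rownames(means) <- obj$classes
  S <- as.matrix(obj$cov)
  dimnames(S) <- NULL
  structure(
    list(means = means, cov = S, cov_inv = solve(S),
         log_priors = log(obj$priors), priors = obj$priors,
         classes = obj$classes, d = obj$d, ridge = obj$ridge,
         counts = obj$counts, prior = obj$prior,
         call = call("read_stftda", path)),
    class = "stftda"
  )
}

# Seed-scoped RNG helpers: save and restore the global .Random.seed so that
# seeded package internals do not perturb the caller's RNG stream.
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  set.seed(as.integer(seed %% 2147483647))
  old
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}
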